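# Quality control: instrument-level file flags and the Chauvenet outlier
# criterion for derived quantities.

#' Instrument quality flags
#'
#' A file fails the pressure check when its stream pressure deviates by
#' strictly more than \code{pressure_tol} (fraction) from the mean pressure
#' of its cruise, and fails the event-rate check when the acquisition rate
#' strictly exceeds \code{rate_max} particles per second (particle
#' coincidence becomes likely above that). Flags are tri-state: 0 pass,
#' 1 fail, \code{NA} not evaluable (missing values).
#'
#' @param meta metadata table (needs \code{cruise_id},
#'   \code{stream_pressure}, \code{event_rate}).
#' @param pressure_tol allowed relative deviation from the cruise mean
#'   pressure (default 0.05).
#' @param rate_max maximum acceptable event rate in particles per second
#'   (default 18000).
#' @return Data frame with \code{file_id}, \code{flag_pressure},
#'   \code{flag_rate}.
#' @export
flag_instrument <- function(meta, pressure_tol = 0.05, rate_max = 18000) {
  stopifnot(pressure_tol > 0, rate_max > 0)
  flag_p <- rep(NA_integer_, nrow(meta))
  for (cr in unique(meta$cruise_id)) {
    idx <- which(meta$cruise_id == cr)
    p <- meta$stream_pressure[idx]
    ok <- is.finite(p)
    if (sum(ok) >= 2) {
      m <- mean(p[ok])
      # tiny relative guard so exact-boundary deviations stay "not more than"
      flag_p[idx[ok]] <- as.integer(abs(p[ok] - m) / m > pressure_tol * (1 + 1e-9))
    }
  }
  r <- meta$event_rate
  flag_r <- ifelse(is.finite(r), as.integer(r > rate_max), NA_integer_)
  data.frame(file_id = meta$file_id, flag_pressure = flag_p,
             flag_rate = flag_r, stringsAsFactors = FALSE)
}

#' Chauvenet outlier criterion
#'
#' Classical single-pass Chauvenet rule: a point is an outlier when the
#' expected number of equally extreme points in a normal sample of the
#' same size falls below one half, i.e. when
#' \code{N * P(|Z| >= |x - mean| / sd) < 0.5}. Equivalently, points fall
#' outside the band around the mean holding probability 1 - 1/(2N). The
#' rule is applied once, without re-computing mean and sd after removals,
#' and is invariant under affine transforms of the data.
#'
#' @param values numeric vector, N >= 4, finite.
#' @return Logical outlier mask (all \code{FALSE} when the sd is zero).
#' @export
chauvenet <- function(values) {
  if (length(values) < 4) stop_cyto("Chauvenet criterion needs N >= 4 (got %d)", length(values))
  if (any(!is.finite(values))) stop_cyto("Chauvenet criterion requires finite values")
  s <- sd(values)
  if (s == 0) return(rep(FALSE, length(values)))
  z <- abs(values - mean(values)) / s
  n <- length(values)
  n * 2 * pnorm(z, lower.tail = FALSE) < 0.5
}

#' Chauvenet screening of derived per-population quantities
#'
#' Applies \code{\link{chauvenet}} per cruise and population to cell
#' abundance and to the median ESD and carbon quota (at the mid refractive
#' index), attaching tri-state flag columns \code{flag_abundance},
#' \code{flag_esd} and \code{flag_carbon}. Groups with fewer than 4
#' evaluable files get \code{NA} flags; flagged rows are retained, never
#' dropped.
#'
#' @param records merged per-population records (needs \code{cruise},
#'   \code{population} and the screened columns).
#' @param variables named character vector mapping flag names to record
#'   columns.
#' @return \code{records} with the flag columns filled in.
#' @export
qc_screen <- function(records,
                      variables = c(flag_abundance = "abundance",
                                    flag_esd = "esd_n138_med",
                                    flag_carbon = "carbon_n138_med")) {
  for (fl in names(variables)) records[[fl]] <- NA_integer_
  groups <- split(seq_len(nrow(records)),
                  list(records$cruise, records$population), drop = TRUE)
  for (idx in groups) {
    for (fl in names(variables)) {
      v <- records[[variables[fl]]][idx]
      ok <- is.finite(v)
      if (sum(ok) >= 4)
        records[[fl]][idx[ok]] <- as.integer(chauvenet(v[ok]))
    }
  }
  records
}
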