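#' Construct a growth-curve set for killing-curve analysis
#'
#' Time-indexed optical density (OD) readings for a phage-free control and
#' a ladder of MOIs (multiplicities of infection), replicate-averaged.
#'
#' @param times Sampling times in minutes, strictly ascending.
#' @param control_od OD of the phage-free control at each time.
#' @param moi_curves Named list mapping MOI (as character of the numeric
#'   value, or numeric names) to an OD vector per time.
#' @param window_end Integration endpoint T in minutes; `NULL` to detect
#'   the onset of the control's stationary phase (see
#'   [detect_window_end()]).
#' @return A `growth_curve_set`.
#' @export
growth_curve_set <- function(times, control_od, moi_curves,
                             window_end = NULL) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly ascending", call. = FALSE)
  if (length(control_od) != length(times))
    stop("control_od length must match times", call. = FALSE)
  if (any(control_od < 0)) stop("OD must be non-negative", call. = FALSE)
  mois <- as.numeric(names(moi_curves))
  if (anyNA(mois) || any(mois <= 0))
    stop("moi_curves must be named by positive numeric MOIs", call. = FALSE)
  if (anyDuplicated(mois)) stop("MOIs must be distinct", call. = FALSE)
  for (v in moi_curves) {
    if (length(v) != length(times) || any(v < 0))
      stop("each MOI curve must match times and be non-negative",
           call. = FALSE)
  }
  if (is.null(window_end)) window_end <- detect_window_end(times, control_od)
  if (window_end > max(times) || window_end <= min(times))
    stop("window_end must lie within the sampled time range", call. = FALSE)
  structure(list(times = times, control_od = as.numeric(control_od),
                 moi_curves = lapply(moi_curves, as.numeric),
                 window_end = window_end),
            class = "growth_curve_set")
}

#' Detect the onset of the stationary phase of a control growth curve
#'
#' The integration endpoint of the virulence assay is the onset of the
#' stationary phase in the phage-free control, detected as the first
#' sampling time at which the forward difference of the OD falls below
#' `frac` of its maximum forward difference (default 5%). Falls back to
#' the last time point if no such slowdown occurs after growth started.
#'
#' @param times Sampling times (minutes).
#' @param od Control OD readings.
#' @param frac Slope threshold as a fraction of the maximum slope.
#' @return A time (minutes) from `times`.
#' @export
detect_window_end <- function(times, od, frac = 0.05) {
  slopes <- diff(od) / diff(times)
  peak <- which.max(slopes)
  late <- which(slopes < frac * max(slopes))
  late <- late[late > peak]
  if (length(late) == 0L) return(times[length(times)])
  times[late[1L] + 1L]
}

#' Local virulence at one MOI
#'
#' `v = max(0, 1 - A_phage / A_control)` where `A` is the trapezoidal
#' integral of OD over time from the first sampling time to the window
#' end. Identical curves give 0; complete suppression gives 1. Negative
#' values (phage-enhanced growth) are clamped to 0.
#'
#' @param curves A [growth_curve_set()].
#' @param moi The MOI to evaluate (must be present in `curves`).
#' @return A list with `moi` and `v`.
#' @export
local_virulence <- function(curves, moi) {
  stopifnot(inherits(curves, "growth_curve_set"))
  key <- match(as.numeric(moi), as.numeric(names(curves$moi_curves)))
  if (is.na(key)) stop("MOI ", moi, " not present in curves", call. = FALSE)
  keep <- curves$times <= curves$window_end
  a_ctrl <- pracma::trapz(curves$times[keep], curves$control_od[keep])
  if (a_ctrl == 0)
    stop("control area is zero; local virulence undefined", call. = FALSE)
  a_moi <- pracma::trapz(curves$times[keep],
                         curves$moi_curves[[key]][keep])
  list(moi = as.numeric(moi), v = max(0, 1 - a_moi / a_ctrl))
}

#' Integrated virulence index over an MOI ladder
#'
#' Trapezoidal area under local virulence versus `log10(MOI)`, normalized
#' by the maximal possible area (`v = 1` over the same log-MOI range), so
#' the index lies in `[0, 1]`.
#'
#' @param locals A list of `local_virulence` results, or a data frame with
#'   columns `moi` and `v`.
#' @return The virulence index (scalar in `[0, 1]`).
#' @export
virulence_index <- function(locals) {
  if (is.data.frame(locals)) {
    moi <- locals$moi; v <- locals$v
  } else {
    moi <- vapply(locals, `[[`, numeric(1L), "moi")
    v <- vapply(locals, `[[`, numeric(1L), "v")
  }
  if (length(moi) < 2L)
    stop("virulence_index needs at least two MOIs", call. = FALSE)
  if (anyDuplicated(moi)) stop("duplicate MOI in input", call. = FALSE)
  ord <- order(moi)
  x <- log10(moi[ord]); y <- v[ord]
  pracma::trapz(x, y) / (max(x) - min(x))
}

#' Construct a titer time series
#'
#' @param times Sampling times (minutes), ascending.
#' @param titer Phage titer (PFU/mL) at each time, non-negative.
#' @param lod Detection limit (PFU/mL).
#' @param n0 Total number of infective phage input at t0 (PFU), used as
#'   the infective-center denominator for burst size.
#' @param volume_ml Culture volume (mL) converting titer to total PFU.
#' @return A `titer_series`.
#' @export
titer_series <- function(times, titer, lod = 0, n0 = NA_real_,
                         volume_ml = 1) {
  times <- as.numeric(times); titer <- as.numeric(titer)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly ascending", call. = FALSE)
  if (length(titer) != length(times))
    stop("titer length must match times", call. = FALSE)
  if (any(titer < 0)) stop("titer must be non-negative", call. = FALSE)
  structure(list(times = times, titer = titer, lod = lod, n0 = n0,
                 volume_ml = volume_ml),
            class = "titer_series")
}

#' One-step growth analysis: latent period, plateau and burst size
#'
#' The baseline is the titer at the first sampling time. The latent period
#' is the last sampling time with titer at most `rise_factor` times the
#' baseline before the first sustained rise. The plateau is seeded by the
#' first pair of consecutive post-rise points whose relative difference is
#' at most `plateau_tol`, then extended forward while each next point lies
#' within `plateau_tol` of the running plateau mean (so a second burst
#' terminates it); the plateau titer is the mean over that run. Burst size
#' is plateau titer times culture volume divided by the phage input `n0`
#' (infective centers taken as the phage input at t0).
#'
#' @param series A [titer_series()] with `n0` set.
#' @param rise_factor Titer multiple of baseline marking the rise.
#' @param plateau_tol Maximum relative difference between consecutive
#'   plateau points.
#' @return A list with `latent_min`, `rise_min`, `plateau_titer` and
#'   `burst_size`.
#' @export
one_step <- function(series, rise_factor = 1.5, plateau_tol = 0.10) {
  stopifnot(inherits(series, "titer_series"))
  t <- series$times; y <- series$titer
  if (length(t) < 4L) stop("one_step needs >= 4 time points", call. = FALSE)
  if (is.na(series$n0) || series$n0 <= 0)
    stop("one_step needs a positive n0", call. = FALSE)
  baseline <- y[1L]
  risen <- y > rise_factor * baseline
  if (!any(risen)) stop("no burst detected: titer never rises above ",
                        rise_factor, " x baseline", call. = FALSE)
  first_rise <- which(risen)[1L]
  latent_idx <- first_rise - 1L
  if (latent_idx < 1L)
    stop("no burst detected: titer already above baseline at t0",
         call. = FALSE)
  latent_min <- t[latent_idx]

  # plateau seed: first pair of consecutive post-rise points at the
  # post-rise level whose relative difference is within tolerance
  reldiff <- abs(diff(y)) / pmax(head(y, -1L), tail(y, -1L))
  ok <- reldiff <= plateau_tol &
    head(y, -1L) > rise_factor * baseline &
    seq_along(reldiff) >= first_rise
  run_start <- which(ok)[1L]
  if (is.na(run_start))
    stop("unterminated rise: no plateau found", call. = FALSE)
  # extend while each next point stays within tolerance of the running
  # plateau mean; a second burst breaks the band and ends the plateau
  idx <- c(run_start, run_start + 1L)
  j <- run_start + 2L
  while (j <= length(y)) {
    m <- mean(y[idx])
    if (abs(y[j] - m) / max(y[j], m) > plateau_tol) break
    idx <- c(idx, j)
    j <- j + 1L
  }
  plateau_titer <- mean(y[idx])
  list(latent_min = latent_min,
       rise_min = t[idx[1L]] - latent_min,
       plateau_titer = plateau_titer,
       burst_size = plateau_titer * series$volume_ml / series$n0)
}

#' Adsorption kinetics from a free-phage titer series
#'
#' The fraction of unadsorbed phage is `P(t)/P(0)`; percent adsorbed is
#' `100 * (1 - P/P0)`. With a known cell density the adsorption rate
#' constant is the least-squares slope through the origin of
#' `-ln(P/P0)` versus `cell_density * t` (units mL cell^-1 min^-1).
#'
#' @param series A [titer_series()] of free (unadsorbed) phage.
#' @param cell_density Host density in cells/mL, or `NULL`.
#' @return A list with `times`, `fraction_unadsorbed`,
#'   `percent_adsorbed` and `rate_constant` (`NA` without `cell_density`).
#' @export
adsorption <- function(series, cell_density = NULL) {
  stopifnot(inherits(series, "titer_series"))
  p0 <- series$titer[1L]
  if (p0 <= 0) stop("adsorption: P(0) must be positive", call. = FALSE)
  frac <- series$titer / p0
  rate <- NA_real_
  if (!is.null(cell_density)) {
    keep <- series$titer > 0 & series$times > 0
    x <- cell_density * series$times[keep]
    yy <- -log(frac[keep])
    rate <- if (length(x) > 0L && sum(x^2) > 0) sum(x * yy) / sum(x^2) else 0
  }
  list(times = series$times,
       fraction_unadsorbed = frac,
       percent_adsorbed = 100 * (1 - frac),
       rate_constant = rate)
}

#' Crystal-violet biofilm inhibition percentage
#'
#' `100 * (mean(control) - mean(phage)) / mean(control)`. Negative values
#' (biofilm enhancement) are reported as-is, not clamped.
#'
#' @param od_control OD readings of untreated biofilm wells.
#' @param od_phage OD readings of phage-treated wells.
#' @return Inhibition percentage (scalar).
#' @export
biofilm_inhibition <- function(od_control, od_phage) {
  mc <- mean(od_control)
  if (!is.finite(mc) || mc <= 0)
    stop("mean control OD must be positive", call. = FALSE)
  100 * (mc - mean(od_phage)) / mc
}

#' Log10 titer reduction with censoring at the detection limit
#'
#' `value = log10(titer_ref) - log10(max(titer_treated, lod))`. When the
#' treated titer falls below the detection limit the value is a lower
#' bound ("complete inactivation") and `censored` is `TRUE`.
#'
#' @param titer_ref Reference titer (PFU/mL), positive.
#' @param titer_treated Treated titer (PFU/mL).
#' @param lod Detection limit (PFU/mL).
#' @return A list with `value` (log10 units) and `censored`.
#' @export
log_reduction <- function(titer_ref, titer_treated, lod = 0) {
  if (titer_ref <= 0) stop("titer_ref must be positive", call. = FALSE)
  censored <- titer_treated < lod
  list(value = log10(titer_ref) - log10(max(titer_treated, lod)),
       censored = censored)
}

#' Read a long-format assay table
#'
#' Plate-reader and titration data are exchanged as long-format TSV/CSV
#' with columns `time_min`, `condition`, `replicate`, `value`.
#'
#' @param path File path.
#' @param sep Field separator (tab by default).
#' @return A data frame with the four columns, types coerced.
#' @export
read_assay_table <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  needed <- c("time_min", "condition", "replicate", "value")
  if (!all(needed %in% names(df)))
    stop("assay table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  df$time_min <- as.numeric(df$time_min)
  df$value <- as.numeric(df$value)
  df
}

#' Build a growth-curve set from a long-format assay table
#'
#' Replicates are averaged per condition and time. The control condition
#' is named `"control"`; every other condition name must be the numeric
#' MOI it represents.
#'
#' @param df Data frame from [read_assay_table()].
#' @param window_end Passed to [growth_curve_set()].
#' @return A `growth_curve_set`.
#' @export
curves_from_table <- function(df, window_end = NULL) {
  times <- sort(unique(df$time_min))
  avg <- function(cond) {
    sub <- df[df$condition == cond, ]
    m <- tapply(sub$value, sub$time_min, mean)
    as.numeric(m[as.character(times)])
  }
  conds <- setdiff(unique(df$condition), "control")
  if (!("control" %in% df$condition))
    stop("table must contain a 'control' condition", call. = FALSE)
  moi_curves <- setNames(lapply(conds, avg), conds)
  growth_curve_set(times, avg("control"), moi_curves,
                   window_end = window_end)
}
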