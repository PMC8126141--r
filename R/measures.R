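.traj_col <- function(traj, var) {
  if (!var %in% names(traj))
    stop("unknown trajectory column '", var, "'")
  traj[[var]]
}

.check_traj <- function(traj) {
  if (!is.data.frame(traj) || nrow(traj) == 0L || !"time" %in% names(traj))
    stop("need a non-empty trajectory data.frame with a 'time' column")
}

#' Temporal maximum of a concentration
#'
#' Maximum of the selected concentration over the trajectory, refined by a
#' parabola through the three samples bracketing the discrete argmax (the
#' output grid is non-uniform). Ties at the discrete stage resolve to the
#' earliest time; maxima at the grid ends are returned unrefined.
#'
#' @param traj A trajectory from [simulate_cell()].
#' @param var Column name, e.g. `"c1_ic"` (intracellular H2O2) or
#'   `"c4_ic"` (intracellular ONOO-).
#' @return List with `value` (M) and `time` (s).
#' @export
temporal_max <- function(traj, var = "c1_ic") {
  .check_traj(traj)
  y <- .traj_col(traj, var)
  t <- traj$time
  i <- which.max(y)
  if (i == 1L || i == length(y))
    return(list(value = y[i], time = t[i]))
  # parabola through (t[i-1], t[i], t[i+1]) in Newton form; vertex of the
  # quadratic unless the three points are effectively collinear
  t0 <- t[i - 1L]; t1 <- t[i]; t2 <- t[i + 1L]
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  d1 <- (y1 - y0) / (t1 - t0)
  d2 <- (y2 - y1) / (t2 - t1)
  a <- (d2 - d1) / (t2 - t0)
  if (!is.finite(a) || a >= 0)
    return(list(value = y1, time = t1))
  tv <- (t0 + t1) / 2 - d1 / (2 * a)
  tv <- min(max(tv, t0), t2)
  yv <- y0 + d1 * (tv - t0) + a * (tv - t0) * (tv - t1)
  if (yv < y1) { yv <- y1; tv <- t1 }
  list(value = yv, time = tv)
}

#' System response time of intracellular H2O2
#'
#' Time for intracellular H2O2 to return within a tolerance band above its
#' pre-treatment baseline (the trajectory's initial value): the last time
#' the concentration crosses `(1 + tolerance) * baseline` from above, by
#' linear interpolation between the bracketing samples. Returns 0 if the
#' threshold is never exceeded (the system never leaves its tolerance
#' band) and the final time if still above the threshold at the end.
#'
#' `rule = "literal"` instead uses `baseline / (1 + tolerance)` as the
#' threshold, i.e. a band below the baseline.
#'
#' @param traj A trajectory.
#' @param tolerance Fractional band width (default 0.10).
#' @param rule Threshold convention, `"increase"` (default) or
#'   `"literal"`.
#' @return Response time, s.
#' @export
response_time <- function(traj, tolerance = 0.10,
                          rule = c("increase", "literal")) {
  .check_traj(traj)
  stopifnot(tolerance > 0)
  rule <- match.arg(rule)
  y <- as.numeric(traj$c1_ic)
  t <- as.numeric(traj$time)
  baseline <- y[1L]
  thr <- if (rule == "increase") (1 + tolerance) * baseline
         else baseline / (1 + tolerance)
  above <- y > thr
  if (!any(above)) return(0)
  i <- max(which(above))            # last sample above the threshold
  if (i == length(y)) return(t[length(t)])
  # interpolate the downward crossing between samples i and i+1
  t[i] + (thr - y[i]) * (t[i + 1L] - t[i]) / (y[i + 1L] - y[i])
}

#' Load: time integral of a concentration
#'
#' Trapezoidal integral of the selected concentration over the full
#' (non-uniform) output grid, in M s.
#'
#' @param traj A trajectory.
#' @param var Column name (default intracellular H2O2).
#' @return Integral, M s.
#' @export
load_integral <- function(traj, var = "c1_ic") {
  .check_traj(traj)
  pracma::trapz(traj$time, .traj_col(traj, var))
}

#' Load over a baseline concentration
#'
#' Signed trapezoidal integral of (concentration - baseline); negative
#' stretches are not clipped. The conventional baseline is the
#' steady-state intracellular H2O2 of the most resistant phenotype
#' (catalase at the upper sweep limit, 1e-5 M).
#'
#' @param traj A trajectory.
#' @param baseline Baseline concentration, M.
#' @param var Column name.
#' @return Integral, M s.
#' @export
load_over_baseline <- function(traj, baseline, var = "c1_ic") {
  .check_traj(traj)
  stopifnot(is.numeric(baseline), baseline >= 0)
  pracma::trapz(traj$time, .traj_col(traj, var) - baseline)
}

#' Extracellular H2O2 consumption rates and their inverses
#'
#' The average consumption rate over the run follows from the fundamental
#' theorem of calculus: `r_bar = |c1_ec(tf) - c1_ec(0)| / tf`. The maximal
#' instantaneous rate `r_max` is the largest `|dc1_ec/dt|` over adjacent
#' output samples. The susceptibility-style inverses are `s_bar = 1/r_bar`
#' and `s_max = 1/r_max`, reported as `NA` when the corresponding rate is
#' zero.
#'
#' @param traj A trajectory.
#' @return List with `r_bar`, `r_max` (M s-1) and `s_bar`, `s_max`
#'   (s M-1).
#' @export
ec_consumption <- function(traj) {
  .check_traj(traj)
  t <- traj$time
  y <- traj$c1_ec
  n <- length(t)
  tf <- t[n] - t[1L]
  r_bar <- if (tf > 0) abs(y[n] - y[1L]) / tf else 0
  r_max <- if (n > 1L) max(abs(diff(y) / diff(t))) else 0
  list(r_bar = r_bar, r_max = r_max,
       s_bar = if (r_bar > 0) 1 / r_bar else NA_real_,
       s_max = if (r_max > 0) 1 / r_max else NA_real_)
}

#' All susceptibility measures of one trajectory
#'
#' Aggregates the dependent variables defined on a single run: temporal
#' maxima of intracellular H2O2 and ONOO- (with their times), the response
#' time, the loads of both species, the load over baseline, and the
#' extracellular consumption rates with their inverses.
#'
#' @param traj A trajectory from [simulate_cell()].
#' @param baseline Baseline for the load-over-baseline measure, M. The
#'   default (`NULL`) uses the steady-state intracellular H2O2 at catalase
#'   1e-5 M under the trajectory's constants.
#' @return Object of class `ptl_measures`: named list with fields
#'   `c1_max`, `t_c1_max`, `c4_max`, `t_c4_max`, `tau`, `l1`, `l4`,
#'   `l1_bs`, `baseline`, `r_bar`, `r_max`, `s_bar`, `s_max`.
#' @export
compute_measures <- function(traj, baseline = NULL) {
  .check_traj(traj)
  if (is.null(baseline)) {
    cons <- attr(traj, "constants")
    if (is.null(cons)) cons <- model_constants()
    baseline <- steady_state_h2o2(cons, cat0 = 1e-5)
  }
  m1 <- temporal_max(traj, "c1_ic")
  m4 <- temporal_max(traj, "c4_ic")
  rates <- ec_consumption(traj)
  structure(list(
    c1_max = m1$value, t_c1_max = m1$time,
    c4_max = m4$value, t_c4_max = m4$time,
    tau = response_time(traj),
    l1 = load_integral(traj, "c1_ic"),
    l4 = load_integral(traj, "c4_ic"),
    l1_bs = load_over_baseline(traj, baseline),
    baseline = baseline,
    r_bar = rates$r_bar, r_max = rates$r_max,
    s_bar = rates$s_bar, s_max = rates$s_max
  ), class = "ptl_measures")
}

#' @export
print.ptl_measures <- function(x, ...) {
  cat("Susceptibility measures:\n")
  cat(sprintf("  c1_max  %.4e M at t = %.4g s\n", x$c1_max, x$t_c1_max))
  cat(sprintf("  c4_max  %.4e M at t = %.4g s\n", x$c4_max, x$t_c4_max))
  cat(sprintf("  tau     %.4g s\n", x$tau))
  cat(sprintf("  l1      %.4e M s   l4 %.4e M s   l1_bs %.4e M s\n",
              x$l1, x$l4, x$l1_bs))
  cat(sprintf("  r_bar   %.4e M/s   r_max %.4e M/s\n", x$r_bar, x$r_max))
  invisible(x)
}

#' @export
as.data.frame.ptl_measures <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}
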