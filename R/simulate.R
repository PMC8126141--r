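#' Integrate the stiff two-compartment system
#'
#' Solves the coupled rate equations with an implicit stiff method
#' (deSolve's `lsoda`, which switches to BDF on stiffness) from t = 0 to
#' the grid's final time, sampling the solution at the grid's output
#' times. Internal solver steps are adaptive and independent of the
#' output grid.
#'
#' The default absolute tolerance (1e-22 M) is far below every initial
#' concentration but also below the sub-femtomolar peroxynitrite
#' transients, which carry the nitrite-synergy signal; a looser atol
#' leaves those components uncontrolled. The model is deterministic:
#' identical inputs give identical trajectories.
#'
#' @param phenotype A [cell_phenotype()].
#' @param scenario A [treatment_scenario()].
#' @param constants A [model_constants()].
#' @param grid A [time_grid()]; default the full-resolution grid.
#' @param rtol,atol Relative / absolute solver tolerances.
#' @param y0 Optional initial-state override (named over [state_names()]);
#'   default [initial_state()].
#' @return Object of class `ptl_trajectory`: a data.frame with column
#'   `time` (s) and one column per state component (M), with the inputs
#'   and solver settings attached as attributes (`phenotype`, `scenario`,
#'   `constants`, `grid`, `rtol`, `atol`, `diagnostics`).
#' @examples
#' \donttest{
#' tr <- simulate_cell(cell_phenotype(920, 1e-8),
#'                     treatment_scenario("selective_nonsynergistic"),
#'                     grid = sweep_time_grid())
#' max(tr$c1_ic)
#' }
#' @export
simulate_cell <- function(phenotype, scenario,
                          constants = model_constants(),
                          grid = time_grid(),
                          rtol = 1e-8, atol = 1e-22,
                          y0 = NULL) {
  stopifnot(inherits(phenotype, "ptl_phenotype"),
            inherits(scenario, "ptl_scenario"),
            inherits(grid, "ptl_time_grid"),
            rtol > 0, atol > 0)
  if (is.null(y0)) {
    y0 <- initial_state(phenotype, scenario, constants)
  } else {
    y0 <- y0[.state_names]
    if (anyNA(y0)) stop("y0 must be named over state_names()")
  }
  p <- .pack_params(phenotype, constants)
  func <- function(t, y, parms) list(.rhs_raw(y, parms))
  out <- deSolve::ode(y = y0, times = grid$times, func = func, parms = p,
                      method = "lsoda", rtol = rtol, atol = atol)
  istate <- attr(out, "istate")
  diag_ <- list(steps = istate[2L], fevals = istate[3L],
                jacobians = istate[14L], return_code = istate[1L])
  if (istate[1L] < 0)
    stop("stiff integration failed (istate = ", istate[1L],
         ") near t = ", out[nrow(out), "time"], " s")
  traj <- as.data.frame(out)
  names(traj) <- c("time", .state_names)
  structure(traj, class = c("ptl_trajectory", "data.frame"),
            phenotype = phenotype, scenario = scenario,
            constants = constants, grid = grid,
            rtol = rtol, atol = atol, diagnostics = diag_)
}

#' Fixed-step reference integration (verification oracle)
#'
#' Classical 4th-order Runge-Kutta with a fixed step, integrating the same
#' right-hand side as [simulate_cell()]. Being explicit, it is only stable
#' for very small steps on this stiff system; it is intended solely for
#' short-horizon verification of the stiff solver (default step 1e-9 s
#' for horizons up to ~1e-4 s), never for production runs.
#'
#' @param phenotype,scenario,constants As in [simulate_cell()].
#' @param t_end Integration horizon, s.
#' @param dt_fixed Fixed step, s.
#' @param sample_every Keep every `sample_every`-th step in the output
#'   (the first and last step are always kept).
#' @param y0 Optional initial-state override (named over [state_names()]).
#' @return A data.frame with `time` plus the state columns.
#' @export
reference_integrate <- function(phenotype, scenario,
                                constants = model_constants(),
                                t_end = 1e-4, dt_fixed = 1e-9,
                                sample_every = 100L, y0 = NULL) {
  stopifnot(inherits(phenotype, "ptl_phenotype"),
            inherits(scenario, "ptl_scenario"),
            t_end > 0, dt_fixed > 0, dt_fixed <= t_end)
  p <- .pack_params(phenotype, constants)
  if (is.null(y0)) y0 <- initial_state(phenotype, scenario, constants)
  else {
    y0 <- y0[.state_names]
    if (anyNA(y0)) stop("y0 must be named over state_names()")
  }
  y <- as.numeric(y0)
  n <- ceiling(t_end / dt_fixed)
  keep <- unique(c(seq(0L, n, by = as.integer(sample_every)), n))
  times <- keep * dt_fixed
  out <- matrix(NA_real_, nrow = length(keep), ncol = length(y))
  out[1L, ] <- y
  row <- 2L
  scale0 <- max(abs(y))
  for (i in seq_len(n)) {
    h <- dt_fixed
    k1 <- .rhs_raw(y, p)
    k2 <- .rhs_raw(y + h / 2 * k1, p)
    k3 <- .rhs_raw(y + h / 2 * k2, p)
    k4 <- .rhs_raw(y + h * k3, p)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(y)) || max(abs(y)) > 1e3 * scale0)
      stop("fixed-step oracle unstable at t = ", i * dt_fixed,
           " s; reduce dt_fixed")
    if (row <= length(keep) && i == keep[row]) {
      out[row, ] <- y
      row <- row + 1L
    }
  }
  traj <- as.data.frame(cbind(times, out))
  names(traj) <- c("time", .state_names)
  traj
}
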