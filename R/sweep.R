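#' Phenotype sweep grid
#'
#' Axes of the (kd1, cat0) phenotype plane. Defaults follow the study
#' ranges: kd1 in 100-2000 s-1 and catalase in 1e-8 to 1e-5 M, 100 steps
#' each, linearly spaced (logarithmic spacing available per axis).
#'
#' @param kd1_min,kd1_max H2O2 diffusion-rate range, s-1.
#' @param kd1_steps,cat0_steps Number of grid values per axis.
#' @param cat0_min,cat0_max Catalase range, M.
#' @param kd1_spacing,cat0_spacing `"linear"` or `"log"`.
#' @return Object of class `ptl_grid` with `kd1` and `cat0` value vectors.
#' @export
grid_spec <- function(kd1_min = 100, kd1_max = 2000, kd1_steps = 100,
                      cat0_min = 1e-8, cat0_max = 1e-5, cat0_steps = 100,
                      kd1_spacing = c("linear", "log"),
                      cat0_spacing = c("linear", "log")) {
  kd1_spacing <- match.arg(kd1_spacing)
  cat0_spacing <- match.arg(cat0_spacing)
  stopifnot(kd1_min > 0, kd1_max > kd1_min, kd1_steps >= 2,
            cat0_min > 0, cat0_max > cat0_min, cat0_steps >= 2)
  ax <- function(lo, hi, n, mode)
    if (mode == "log") exp(seq(log(lo), log(hi), length.out = n))
    else seq(lo, hi, length.out = n)
  structure(list(
    kd1 = ax(kd1_min, kd1_max, kd1_steps, kd1_spacing),
    cat0 = ax(cat0_min, cat0_max, cat0_steps, cat0_spacing),
    kd1_spacing = kd1_spacing, cat0_spacing = cat0_spacing
  ), class = "ptl_grid")
}

.measure_cols <- c("c1_max", "t_c1_max", "c4_max", "t_c4_max", "tau",
                   "l1", "l4", "l1_bs", "baseline",
                   "r_bar", "r_max", "s_bar", "s_max")

#' Sweep the phenotype plane
#'
#' Runs one simulation per (kd1, cat0, scenario) combination — the
#' intracellular H2O2 steady state is recomputed for every catalase value
#' — and computes all susceptibility measures per run. Ordering is
#' deterministic (scenario, then cat0, then kd1). Failed integrations are
#' recorded with `ok = FALSE` and an error message, never dropped; the
#' sweep fails only if every point fails.
#'
#' @param grid A [grid_spec()].
#' @param scenarios A list of [treatment_scenario()] objects (or a single
#'   one).
#' @param constants A [model_constants()].
#' @param time_grid Output grid; default [sweep_time_grid()].
#' @param rtol,atol Solver tolerances, as in [simulate_cell()].
#' @param baseline Baseline for the load-over-baseline measure (`NULL` =
#'   convention of [compute_measures()]).
#' @param checkpoint Optional path to a TSV file; finished rows are
#'   appended as the sweep runs and, on restart, rows already present are
#'   not recomputed.
#' @param progress Print a line every completed scenario block.
#' @return Object of class `ptl_surface`: a long-format data.frame with
#'   columns `kd1`, `cat0`, `regime`, `h2o2_ec0`, `no2_ec0`, `ok`,
#'   `error`, and one column per measure.
#' @export
run_sweep <- function(grid, scenarios, constants = model_constants(),
                      time_grid = sweep_time_grid(),
                      rtol = 1e-8, atol = 1e-22,
                      baseline = NULL, checkpoint = NULL,
                      progress = FALSE) {
  stopifnot(inherits(grid, "ptl_grid"))
  if (inherits(scenarios, "ptl_scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) >= 1L,
            all(vapply(scenarios, inherits, TRUE, "ptl_scenario")))

  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.delim(checkpoint, sep = "\t",
                              stringsAsFactors = FALSE)
    if (nrow(done)) done$error[is.na(done$error)] <- ""
  }
  chk_con <- NULL
  if (!is.null(checkpoint)) {
    chk_con <- file(checkpoint, open = "at")
    on.exit(close(chk_con), add = TRUE)
  }

  key <- function(kd1, cat0, regime)
    sprintf("%.17g|%.17g|%s", kd1, cat0, regime)
  done_keys <- if (!is.null(done) && nrow(done))
    key(done$kd1, done$cat0, done$regime) else character()

  rows <- vector("list", length(scenarios) * length(grid$cat0) *
                   length(grid$kd1))
  idx <- 0L
  for (sc in scenarios) {
    for (cat0 in grid$cat0) {
      for (kd1 in grid$kd1) {
        idx <- idx + 1L
        k <- key(kd1, cat0, sc$regime)
        hit <- match(k, done_keys)
        if (!is.na(hit)) {
          rows[[idx]] <- done[hit, , drop = FALSE]
          next
        }
        rec <- data.frame(kd1 = kd1, cat0 = cat0, regime = sc$regime,
                          h2o2_ec0 = sc$h2o2_ec0, no2_ec0 = sc$no2_ec0,
                          ok = TRUE, error = "",
                          stringsAsFactors = FALSE)
        res <- tryCatch({
          tr <- simulate_cell(cell_phenotype(kd1, cat0), sc, constants,
                              grid = time_grid, rtol = rtol, atol = atol)
          as.data.frame(compute_measures(tr, baseline))
        }, error = function(e) e)
        if (inherits(res, "error")) {
          rec$ok <- FALSE
          rec$error <- conditionMessage(res)
          for (cn in .measure_cols) rec[[cn]] <- NA_real_
        } else {
          rec <- cbind(rec, res)
        }
        rows[[idx]] <- rec
        if (!is.null(chk_con)) {
          # 17 significant digits so the keys round-trip exactly
          fmt <- as.data.frame(lapply(rec, function(x)
            if (is.numeric(x)) sprintf("%.17g", x) else x),
            stringsAsFactors = FALSE)
          utils::write.table(fmt, chk_con, sep = "\t",
                             col.names = is.null(done) && idx == 1L,
                             row.names = FALSE, quote = FALSE)
          flush(chk_con)
        }
      }
    }
    if (progress)
      message("sweep: finished regime ", sc$regime)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!any(out$ok)) stop("every sweep point failed to integrate")
  structure(out, class = c("ptl_surface", "data.frame"),
            grid = grid, constants = constants, time_grid = time_grid,
            rtol = rtol, atol = atol)
}

.surface_regime <- function(surface, regime) {
  if (!is.null(regime)) {
    surface <- surface[surface$regime == regime, , drop = FALSE]
    if (!nrow(surface)) stop("no surface rows for regime '", regime, "'")
  }
  surface
}

#' Selectivity ratio between phenotype extremes
#'
#' Ratio of a measure at the most susceptible corner of the phenotype
#' plane (max kd1, min cat0 — cancer-like) to the most resistant corner
#' (min kd1, max cat0 — normal-like).
#'
#' @param surface A [run_sweep()] result.
#' @param regime Restrict to one regime label (`NULL` = use all rows).
#' @param measure Measure column (default `"c1_max"`).
#' @return Dimensionless fold.
#' @export
selectivity_ratio <- function(surface, regime = NULL, measure = "c1_max") {
  stopifnot(is.data.frame(surface))
  s <- .surface_regime(surface, regime)
  if (!measure %in% names(s)) stop("unknown measure '", measure, "'")
  pick <- function(kd1, cat0) {
    i <- which(s$kd1 == kd1 & s$cat0 == cat0)
    if (!length(i)) stop("surface is missing the corner point (kd1 = ",
                         kd1, ", cat0 = ", cat0, ")")
    s[[measure]][i[1L]]
  }
  susceptible <- pick(max(s$kd1), min(s$cat0))
  resistant <- pick(min(s$kd1), max(s$cat0))
  susceptible / resistant
}

#' Per-point synergy folds between two surfaces
#'
#' Elementwise ratio of a measure between two sweeps on identical grids
#' (conventionally with- over without-nitrite), plus summary statistics.
#'
#' @param surface_with,surface_without [run_sweep()] results on the same
#'   (kd1, cat0) grid.
#' @param measure Measure column (default `"c4_max"`, the peroxynitrite
#'   peak probed for nitrite synergy).
#' @return List with `ratios` (data.frame: kd1, cat0, fold) and `median`,
#'   `min`, `max`.
#' @export
synergy_ratio <- function(surface_with, surface_without,
                          measure = "c4_max") {
  stopifnot(is.data.frame(surface_with), is.data.frame(surface_without))
  for (s in list(surface_with, surface_without))
    if (!measure %in% names(s)) stop("unknown measure '", measure, "'")
  a <- surface_with[order(surface_with$cat0, surface_with$kd1), ]
  b <- surface_without[order(surface_without$cat0, surface_without$kd1), ]
  if (nrow(a) != nrow(b) ||
      !isTRUE(all.equal(a$kd1, b$kd1)) ||
      !isTRUE(all.equal(a$cat0, b$cat0)))
    stop("the two surfaces are not on the same (kd1, cat0) grid")
  fold <- a[[measure]] / b[[measure]]
  list(ratios = data.frame(kd1 = a$kd1, cat0 = a$cat0, fold = fold),
       median = stats::median(fold), min = min(fold), max = max(fold))
}

#' Relative spread of a measure across the kd1 axis
#'
#' For every catalase value, the relative spread (max - min) / min of the
#' measure across all kd1 values. A near-zero spread means the measure is
#' insensitive to the membrane diffusion rate at that catalase level; the
#' growth of the spread with catalase locates the regime shift of the
#' susceptibility surface.
#'
#' @param surface A [run_sweep()] result.
#' @param measure Measure column (default `"c1_max"`).
#' @param regime Restrict to one regime label (`NULL` = all rows).
#' @return data.frame with columns `cat0` and `spread`, ordered by
#'   `cat0`.
#' @export
kd1_dependence_profile <- function(surface, measure = "c1_max",
                                   regime = NULL) {
  stopifnot(is.data.frame(surface))
  s <- .surface_regime(surface, regime)
  if (!measure %in% names(s)) stop("unknown measure '", measure, "'")
  cats <- sort(unique(s$cat0))
  spread <- vapply(cats, function(ct) {
    v <- s[[measure]][s$cat0 == ct]
    if (length(v) < 2L)
      stop("need at least two kd1 values per cat0")
    (max(v) - min(v)) / min(v)
  }, numeric(1))
  data.frame(cat0 = cats, spread = spread)
}
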