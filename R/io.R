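.config_sections <- c("constants", "phenotype", "scenario", "time_grid",
                      "solver", "grid", "output")

#' Full run configuration
#'
#' Aggregates everything needed to reproduce a run: model constants, cell
#' phenotype, treatment scenario, output time grid, solver tolerances, the
#' sweep grid, and output settings. All concentrations are in molar and
#' all rates in SI units; no unit conversion is performed anywhere.
#'
#' @param constants A [model_constants()].
#' @param phenotype A [cell_phenotype()].
#' @param scenario A [treatment_scenario()].
#' @param time_grid A [time_grid()].
#' @param rtol,atol Solver tolerances.
#' @param grid A [grid_spec()] (for sweeps).
#' @param out_dir Output directory for command-style runs.
#' @return Object of class `ptl_config`.
#' @export
run_config <- function(constants = model_constants(),
                       phenotype = cell_phenotype(),
                       scenario = treatment_scenario("selective_nonsynergistic"),
                       time_grid = ptlkin::time_grid(),
                       rtol = 1e-8, atol = 1e-22,
                       grid = grid_spec(),
                       out_dir = ".") {
  stopifnot(inherits(constants, "ptl_constants"),
            inherits(phenotype, "ptl_phenotype"),
            inherits(scenario, "ptl_scenario"),
            inherits(time_grid, "ptl_time_grid"),
            inherits(grid, "ptl_grid"),
            rtol > 0, atol > 0)
  structure(list(constants = constants, phenotype = phenotype,
                 scenario = scenario, time_grid = time_grid,
                 rtol = rtol, atol = atol, grid = grid,
                 out_dir = out_dir),
            class = "ptl_config")
}

.known_keys <- list(
  constants = c("k1", "k2", "k3", "pka", "k_minus4", "k5", "k6", "kP",
                "kD4", "kD5", "kD7"),
  phenotype = c("kd1", "cat0"),
  scenario = c("regime", "h2o2_ec0", "no2_ec0"),
  time_grid = c("t1", "t2", "tf", "dt1", "dt2", "dt3"),
  solver = c("rtol", "atol"),
  grid = c("kd1_min", "kd1_max", "kd1_steps", "cat0_min", "cat0_max",
           "cat0_steps", "kd1_spacing", "cat0_spacing"),
  output = "out_dir"
)

#' Load a run configuration from a YAML file
#'
#' The file holds sections `constants`, `phenotype`, `scenario`,
#' `time_grid`, `solver`, `grid` and `output`, each with the keys of the
#' corresponding constructor. Every key is optional: an empty file yields
#' the all-defaults configuration. Unknown sections or keys are rejected
#' with an error naming the offender.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping")
  bad <- setdiff(names(raw), .config_sections)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(raw)) {
    extra <- setdiff(names(raw[[sec]]), .known_keys[[sec]])
    if (length(extra))
      stop("unknown key(s) in section '", sec, "': ",
           paste(extra, collapse = ", "))
  }
  take <- function(sec) raw[[sec]] %||% list()
  constants <- do.call(model_constants, take("constants"))
  phenotype <- do.call(cell_phenotype, take("phenotype"))
  sc <- take("scenario")
  scenario <- if (length(sc)) do.call(treatment_scenario, sc)
              else treatment_scenario("selective_nonsynergistic")
  tg <- do.call(time_grid, take("time_grid"))
  solver <- take("solver")
  grid <- do.call(grid_spec, take("grid"))
  out <- take("output")
  run_config(constants = constants, phenotype = phenotype,
             scenario = scenario, time_grid = tg,
             rtol = solver$rtol %||% 1e-8, atol = solver$atol %||% 1e-22,
             grid = grid, out_dir = out$out_dir %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration to a YAML file
#'
#' Writes every parameter explicitly so that [load_config()] round-trips
#' the configuration exactly.
#'
#' @param config A [run_config()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "ptl_config"))
  cons <- config$constants
  tg <- config$time_grid
  g <- config$grid
  out <- list(
    constants = cons[c("k1", "k2", "k3", "pka", "k_minus4", "k5", "k6",
                       "kP", "kD4", "kD5", "kD7")],
    phenotype = list(kd1 = config$phenotype$kd1,
                     cat0 = config$phenotype$cat0),
    scenario = if (config$scenario$regime == "custom")
      list(h2o2_ec0 = config$scenario$h2o2_ec0,
           no2_ec0 = config$scenario$no2_ec0)
    else list(regime = config$scenario$regime),
    time_grid = tg[c("t1", "t2", "tf", "dt1", "dt2", "dt3")],
    solver = list(rtol = config$rtol, atol = config$atol),
    grid = list(kd1_min = min(g$kd1), kd1_max = max(g$kd1),
                kd1_steps = length(g$kd1),
                cat0_min = min(g$cat0), cat0_max = max(g$cat0),
                cat0_steps = length(g$cat0),
                kd1_spacing = g$kd1_spacing,
                cat0_spacing = g$cat0_spacing),
    output = list(out_dir = config$out_dir)
  )
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

.fmt17 <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

#' Write a trajectory to CSV
#'
#' One row per output time, one column per state component, numbers at 17
#' significant digits (so that re-reading preserves determinism checks).
#'
#' @param traj A trajectory from [simulate_cell()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  .check_traj(traj)
  df <- as.data.frame(lapply(as.data.frame(traj), .fmt17),
                      stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return data.frame with `time` plus the state columns.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  utils::read.csv(path)
}

.run_manifest <- function(config, extra = list()) {
  cons <- config$constants
  c(list(
    package = "ptlkin",
    version = as.character(utils::packageVersion("ptlkin")),
    constants = cons[c("k1", "k2", "k3", "pka", "k_minus4", "k4", "k5",
                       "k6", "kP", "kD4", "kD5", "kD7")],
    phenotype = unclass(config$phenotype),
    scenario = unclass(config$scenario),
    time_grid = config$time_grid[c("t1", "t2", "tf", "dt1", "dt2", "dt3")],
    solver = list(method = "lsoda", rtol = config$rtol,
                  atol = config$atol)
  ), extra)
}

#' Run one simulation end to end and write its outputs
#'
#' Initializes, integrates, computes all measures, and writes
#' `trajectory.csv`, `measures.tsv` and `manifest.json` to the
#' configuration's output directory.
#'
#' @param config A [run_config()].
#' @return The `ptl_measures` object, invisibly.
#' @export
run_simulate_command <- function(config) {
  stopifnot(inherits(config, "ptl_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- simulate_cell(config$phenotype, config$scenario,
                        config$constants, grid = config$time_grid,
                        rtol = config$rtol, atol = config$atol)
  meas <- compute_measures(traj)
  write_trajectory(traj, file.path(config$out_dir, "trajectory.csv"))
  mrow <- cbind(data.frame(kd1 = config$phenotype$kd1,
                           cat0 = config$phenotype$cat0,
                           regime = config$scenario$regime),
                as.data.frame(meas))
  mfmt <- as.data.frame(lapply(mrow, .fmt17), stringsAsFactors = FALSE)
  utils::write.table(mfmt, file.path(config$out_dir, "measures.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(.run_manifest(config),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(meas)
}

#' Run a phenotype sweep end to end and write its outputs
#'
#' Sweeps the configuration's grid for the requested regimes, writes the
#' long-format surface table (`surface.tsv`), a manifest, and a summary
#' JSON holding the selectivity ratio per regime and — when both members
#' of a with/without-nitrite pair are present — the synergy summaries for
#' the peroxynitrite peak and the H2O2 peak.
#'
#' @param config A [run_config()] (its `grid`, `constants`, solver
#'   settings, and `out_dir` are used; the sweep uses
#'   [sweep_time_grid()]).
#' @param regimes Character vector of regime labels, or `"all"`.
#' @param checkpoint Optional checkpoint TSV path for resumable sweeps
#'   (see [run_sweep()]).
#' @return The `ptl_surface`, invisibly.
#' @export
run_sweep_command <- function(config, regimes = "all", checkpoint = NULL) {
  stopifnot(inherits(config, "ptl_config"))
  if (identical(regimes, "all")) regimes <- canonical_regimes()
  scenarios <- lapply(regimes, treatment_scenario)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  surf <- run_sweep(config$grid, scenarios, config$constants,
                    rtol = config$rtol, atol = config$atol,
                    checkpoint = checkpoint)
  sfmt <- as.data.frame(lapply(as.data.frame(surf), .fmt17),
                        stringsAsFactors = FALSE)
  utils::write.table(sfmt, file.path(config$out_dir, "surface.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  summary <- list()
  for (rg in regimes)
    summary[[paste0("selectivity_", rg)]] <-
      selectivity_ratio(surf, regime = rg)
  pairs <- list(c("selective_synergistic", "selective_nonsynergistic"),
                c("nonselective_synergistic", "nonselective_nonsynergistic"))
  for (pr in pairs) {
    if (all(pr %in% regimes)) {
      w <- surf[surf$regime == pr[1L], ]
      wo <- surf[surf$regime == pr[2L], ]
      for (ms in c("c4_max", "c1_max")) {
        sr <- synergy_ratio(w, wo, measure = ms)
        summary[[paste0("synergy_", ms, "_", pr[2L])]] <-
          sr[c("median", "min", "max")]
      }
    }
  }
  jsonlite::write_json(
    .run_manifest(config, list(grid = list(
      kd1 = config$grid$kd1, cat0 = config$grid$cat0))),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(surf)
}
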