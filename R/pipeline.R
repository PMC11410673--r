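# End-to-end pipeline: energy matrix -> asymmetry / relay / variability ->
# network nulls -> spatial screens -> predictors, with a JSON manifest
# recording parameters, seeds and per-stage runtimes.

#' Default pipeline configuration
#'
#' Returns the run configuration with the main analysis settings:
#' \code{T = 1}, \code{rho = 1}, \code{c = 0}, \code{alpha = 0.05}. All
#' other entries control problem sizes and null-model budgets.
#'
#' @param ... overrides of default entries.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # input paths (NULL = simulate internally)
    connectome = NULL, regions = NULL, states = NULL, maps = NULL,
    # transition parameters
    T = 1, rho = 1, c = 0, n_steps = 1000,
    # statistics
    n_perm = 10000, alpha = 0.05,
    # null models
    n_nulls = 100, null_kind = "degree_preserving", n_rot = 200,
    # modes
    weights_mode = "uniform", unit_norm = FALSE, run_screen = TRUE,
    # synthetic fallback
    synth = list(n = 68, density = 0.27, k_states = 10),
    seed = 1, out_dir = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full transition-energy pipeline
#'
#' Orchestrates, in order: (1) optimal transition energies between all state
#' pairs; (2) asymmetry, variability and relay statistics; (3) comparison
#' against rewired network nulls; (4) spin-null screening of modulation
#' maps (when maps are available); (5) the state predictor report. Inputs
#' are read from the paths in \code{config}, or generated with
#' \code{\link{make_synthetic_dataset}} when paths are NULL. All outputs are
#' deterministic for a fixed config and seed.
#'
#' @param config list from \code{\link{pipeline_config}}.
#' @return List of stage results (also written to \code{config$out_dir} as
#'   tab-separated tables plus a JSON manifest, when set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t_start <- Sys.time()
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    res
  }
  paths <- config[c("connectome", "regions", "states", "maps")]
  if (any(!vapply(paths, is.null, logical(1)))) {
    given <- !vapply(paths, is.null, logical(1))
    missing_files <- unlist(paths[given])[!file.exists(unlist(paths[given]))]
    if (length(missing_files) > 0)
      .stopf("input file(s) not found: %s", paste(missing_files, collapse = ", "))
    if (is.null(config$regions) || is.null(config$connectome) ||
        is.null(config$states))
      .stopf("connectome, regions and states paths must all be given (or all NULL to simulate)")
    reg <- read_region_table(config$regions)
    w <- read_matrix_table(config$connectome, square_required = TRUE)
    if (nrow(w) != length(reg$labels))
      .stopf("connectome size (%d) does not match region table (%d rows)",
             nrow(w), length(reg$labels))
    conn <- connectome(w, labels = reg$labels, coords3d = reg$coords3d,
                       hemisphere = reg$hemisphere,
                       sphere_coords = reg$sphere_coords)
    smat <- read_matrix_table(config$states)
    states <- lapply(seq_len(ncol(smat)), function(j)
      state_map(smat[, j], colnames(smat)[j],
                unit_norm = isTRUE(config$unit_norm)))
    maps <- if (!is.null(config$maps)) read_matrix_table(config$maps) else NULL
    hierarchy <- if (!is.null(maps) && "hierarchy" %in% colnames(maps))
      maps[, "hierarchy"] else NULL
    partition <- reg$module
  } else {
    synth <- do.call(make_synthetic_dataset,
                     c(config$synth, list(seed = config$seed)))
    conn <- synth$connectome
    states <- synth$states
    maps <- cbind(receptor = synth$modulation_maps$receptor$values,
                  atrophy = synth$modulation_maps$atrophy$values)
    hierarchy <- synth$hierarchy_map
    partition <- synth$partition
  }
  sys <- normalize_adjacency(conn, c = config$c)
  weights <- if (identical(config$weights_mode, "uniform")) NULL
             else build_control_weights(config$weights_mode,
                                        map = maps[, config$weights_mode])

  te <- clock("energy", transition_energy_matrix(
    sys, weights, states, states,
    T = config$T, rho = config$rho, n_steps = config$n_steps))

  stats_res <- clock("stats", {
    asym <- asymmetry_measures(te)
    vt <- variability_test(te, n_perm = config$n_perm,
                           seed = config$seed + 101)
    relay <- relay_analysis(te)
    der <- distance_energy_relation(
      vapply(states, function(s) s$values, numeric(conn$n)), te)
    list(asymmetry = asym, variability = vt, relay = relay,
         distance_energy = der)
  })

  nulls_res <- clock("nulls", {
    ens <- null_ensemble(conn, kind = config$null_kind,
                         n_members = config$n_nulls,
                         seed = config$seed + 200)
    compare_empirical_vs_nulls(conn, ens, states, T = config$T,
                               rho = config$rho, c = config$c,
                               n_steps = config$n_steps, weights = weights)
  })

  screen_res <- NULL
  if (isTRUE(config$run_screen) && !is.null(maps) &&
      !is.null(conn$sphere_coords)) {
    screen_res <- clock("screen", {
      spin <- spin_permutations(conn$sphere_coords, conn$hemisphere,
                                n_rot = config$n_rot,
                                seed = config$seed + 300)
      out <- list()
      if ("receptor" %in% colnames(maps))
        out$receptor <- screen_modulation_map(
          sys, states, maps[, "receptor"], "receptor", spin,
          T = config$T, rho = config$rho, alpha = config$alpha)
      if ("atrophy" %in% colnames(maps))
        out$atrophy <- screen_modulation_map(
          sys, states, maps[, "atrophy"], "thickness_delta", spin,
          T = config$T, rho = config$rho, alpha = config$alpha)
      out
    })
  }

  pred_res <- NULL
  if (!is.null(hierarchy)) {
    # the 5-predictor dominance analysis needs n > p + 2 states; with fewer
    # states only the characterization table is produced
    pred_res <- clock("predictors",
      if (length(states) > 7)
        predictor_report(states, conn, hierarchy, te, partition)
      else
        list(table = state_predictor_table(states, conn, hierarchy, te,
                                           partition)))
  }

  result <- list(connectome = conn, energy = te, stats = stats_res,
                 nulls = nulls_res, screen = screen_res,
                 predictors = pred_res,
                 manifest = list(
                   package_version = as.character(utils::packageVersion("ctrlnet")),
                   parameters = config[c("T", "rho", "c", "n_steps",
                                         "n_perm", "n_nulls", "n_rot",
                                         "alpha", "weights_mode")],
                   seed = config$seed,
                   stage_seeds = list(variability = config$seed + 101,
                                      nulls = config$seed + 200,
                                      spin = config$seed + 300),
                   timings = timings,
                   total_seconds = round(as.numeric(Sys.time() - t_start,
                                                    units = "secs"), 3)))
  if (!is.null(config$out_dir)) .write_pipeline_outputs(result, config)
  invisible(result)
}

.write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(config$out_dir, f)
  write_matrix_table(result$energy$energies, fp("energy_matrix.tsv"))
  a <- result$stats$asymmetry
  asym_tab <- cbind(reach_minus_leave = a$reach_minus_leave,
                    source_sd = a$source_sd, target_sd = a$target_sd)
  write_matrix_table(asym_tab, fp("asymmetry.tsv"))
  if (!is.null(result$predictors))
    utils::write.table(result$predictors$table, fp("predictors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$screen)) {
    for (nm in names(result$screen)) {
      sc <- result$screen[[nm]]
      write_matrix_table(rbind(facilitated = sc$pct_facilitated,
                               disfacilitated = -sc$pct_disfacilitated),
                         fp(sprintf("screen_%s.tsv", nm)))
      write_matrix_table(sc$p_facilitated,
                         fp(sprintf("screen_%s_p_facilitated.tsv", nm)))
    }
  }
  vt <- result$stats$variability
  summary <- list(
    variability = list(t = vt$t, p = vt$p, d = vt$d),
    relayed_fraction = result$stats$relay$relayed_fraction,
    distance_energy = result$stats$distance_energy,
    null_comparison = list(kind = result$nulls$kind,
                           empirical_mean = result$nulls$empirical_mean,
                           null_mean_median = stats::median(result$nulls$null_means,
                                                            na.rm = TRUE),
                           p_lower = result$nulls$p_lower),
    manifest = result$manifest)
  jsonlite::write_json(summary, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(NULL)
}
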