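# End-to-end orchestration: generate (or read) the ensemble and endpoint
# references, featurize, fit the landscape, extract states, profile geometry
# and packing per state, optionally fit a binding curve, and emit a
# machine-readable report. All randomness is routed through named seeds
# recorded in the report, so a re-run with the same config reproduces every
# number.

#' Default pipeline configuration
#'
#' Returns the nested configuration list understood by [run_pipeline()];
#' fields mirror the analysis stages. Override entries (or supply a YAML
#' file of the same shape) to change the run.
#'
#' @param out_dir output directory.
#' @param n_frames ensemble size for the generator.
#' @param seed master seed; stage seeds derive from it.
#' @return Nested configuration list.
#' @export
default_config <- function(out_dir = tempfile("barrelswitch_run_"),
                           n_frames = 5000L, seed = 1L) {
  list(
    out_dir = out_dir,
    generator = list(preset = "paperlike", n_frames = n_frames, seed = seed),
    references = list(open_pdb = NULL, closed_pdb = NULL, ensemble_pdb = NULL),
    features = list(exclude_zero_occ = FALSE),
    landscape = list(component_range = 1:10, kT = KT_293, n_grid = 151L,
                     seed = seed + 1L, f_cap = 6),
    states = list(responsibility_min = 0.5, density_quantile = 0.20),
    geometry = list(step = 1, n_rep = 60L, seed = seed + 2L),
    packing = list(cutoff = 7.0, sasa_threshold = 10, probe = 1.4,
                   n_points = 960L, n_rep = 60L, seed = seed + 3L,
                   resno = 13L, register_offset = 1L),
    binding = list(enabled = TRUE, kd = 0.23, bmax = 10, c = 0.1,
                   x = c(2.4, 4, 6.5, 10, 16, 25, 40, 60, 90, 120),
                   noise_sd = 0.2, n_boot = 200L, seed = seed + 4L),
    convergence = list(enabled = FALSE, fraction = 1 / 50)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Entries present in the file override the defaults; everything else keeps
#' its default value.
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

#' Run the full conformational-state analysis pipeline
#'
#' Stages, in dependency order: build or read the endpoint references and
#' ensemble; featurize every frame (symmetry-aware RMSDs); fit the mixture
#' density and evaluate the free-energy landscape; extract metastable core
#' states and their populations; per-state channel radii; knobs-into-holes
#' comparison of the endpoint structures; population-weighted CB burial of
#' the reporter residue; optional binding-curve simulation and fit. Stage
#' outputs (CSV/JSON/PDB/PNG) are written under `config$out_dir`, plus a
#' `report.json` collecting the key numbers, seeds and stage status.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config()].
#' @return The report, invisibly (a nested list).
#' @export
run_pipeline <- function(config = default_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("barrelswitch")),
                 seeds = list(generator = config$generator$seed,
                              landscape = config$landscape$seed,
                              geometry = config$geometry$seed,
                              packing = config$packing$seed,
                              binding = config$binding$seed),
                 stages = list())
  t_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    ok <- !inherits(res, "error")
    report$stages[[name]] <<- list(
      status = if (ok) "ok" else "failed",
      message = if (ok) "" else conditionMessage(res))
    if (!ok) stop("stage '", name, "' failed: ", conditionMessage(res),
                  call. = FALSE)
    res
  }

  refs <- t_stage("references", {
    if (!is.null(config$references$open_pdb)) {
      open <- get_frame(read_pdb(config$references$open_pdb, "single"), 1L)
      closed <- get_frame(read_pdb(config$references$closed_pdb, "single"), 1L)
    } else {
      open <- build_open_barrel()
      closed <- build_closed_sandwich(open)
    }
    write_pdb(open, file.path(config$out_dir, "reference_open.pdb"))
    write_pdb(closed, file.path(config$out_dir, "reference_closed.pdb"))
    list(open = open, closed = closed)
  })

  ensemble <- t_stage("ensemble", {
    if (!is.null(config$references$ensemble_pdb)) {
      read_pdb(config$references$ensemble_pdb, "all")
    } else {
      spec <- paperlike_spec(n_frames = config$generator$n_frames,
                             seed = config$generator$seed)
      sample_ensemble(refs$open, refs$closed, spec)
    }
  })

  features <- t_stage("featurize", {
    fx <- featurize_ensemble(ensemble, refs$open, refs$closed,
                             exclude_zero_occ = config$features$exclude_zero_occ)
    write_features(fx, file.path(config$out_dir, "features.csv"))
    fx
  })

  model <- t_stage("landscape", {
    m <- fit_density(features, config$landscape$component_range,
                     seed = config$landscape$seed)
    land <- evaluate_landscape(m, features, kT = config$landscape$kT,
                               n_grid = config$landscape$n_grid,
                               f_cap = config$landscape$f_cap)
    write_landscape(land, file.path(config$out_dir, "landscape.csv"))
    grDevices::png(file.path(config$out_dir, "landscape.png"),
                   width = 900, height = 800, res = 130)
    plot_landscape(land)
    grDevices::dev.off()
    m
  })

  states <- t_stage("states", {
    st <- extract_core_states(model, features,
                              responsibility_min = config$states$responsibility_min,
                              density_quantile = config$states$density_quantile)
    write_states(st, file.path(config$out_dir, "states.json"))
    st
  })

  geometry <- t_stage("geometry", {
    radii <- state_mean_channel_radius(states, ensemble,
                                       n_rep = config$geometry$n_rep,
                                       seed = config$geometry$seed,
                                       step = config$geometry$step)
    utils::write.csv(radii, file.path(config$out_dir, "state_channel_radii.csv"),
                     row.names = FALSE)
    open_prof <- channel_radius_profile(refs$open, step = config$geometry$step)
    list(state_radii = radii,
         open_reference_mean_radius = attr(open_prof, "mean_radius"))
  })

  packing <- t_stage("packing", {
    kih_open <- detect_kih(refs$open, config$packing$cutoff,
                           register_offset = config$packing$register_offset)
    kih_closed <- detect_kih(refs$closed, config$packing$cutoff,
                             register_offset = config$packing$register_offset)
    write_kih(kih_open, file.path(config$out_dir, "kih_open.tsv"))
    write_kih(kih_closed, file.path(config$out_dir, "kih_closed.tsv"))
    burial <- burial_occupancy(states, ensemble,
                               resno = config$packing$resno,
                               threshold = config$packing$sasa_threshold,
                               probe = config$packing$probe,
                               n_points = config$packing$n_points,
                               n_rep = config$packing$n_rep,
                               seed = config$packing$seed)
    jsonlite::write_json(
      list(per_state = burial$per_state,
           weighted_buried = burial$weighted_buried,
           weighted_exposed = burial$weighted_exposed),
      file.path(config$out_dir, "burial.json"), auto_unbox = TRUE, digits = NA)
    list(kih_count_open = nrow(kih_open), kih_count_closed = nrow(kih_closed),
         kih_percent_difference =
           100 * (nrow(kih_closed) - nrow(kih_open)) / max(1L, nrow(kih_open)),
         burial = burial)
  })

  binding <- if (isTRUE(config$binding$enabled)) {
    t_stage("binding", {
      curve <- simulate_binding_curve(
        kd = config$binding$kd, bmax = config$binding$bmax,
        c = config$binding$c, x = config$binding$x,
        noise_sd = config$binding$noise_sd, seed = config$binding$seed)
      write_binding_curve(curve, file.path(config$out_dir, "binding_curve.csv"))
      fit <- fit_binding(curve, n_boot = config$binding$n_boot,
                         seed = config$binding$seed)
      write_binding_fit(fit, file.path(config$out_dir, "binding_fit.json"))
      fit
    })
  } else NULL

  report$key_outputs <- list(
    n_frames = n_frames(ensemble),
    n_core_states = length(states),
    state_populations = as.list(state_populations(states)),
    state_channel_radii = geometry$state_radii$mean_radius,
    open_reference_mean_radius = geometry$open_reference_mean_radius,
    kih_count_open = packing$kih_count_open,
    kih_count_closed = packing$kih_count_closed,
    kih_percent_difference = packing$kih_percent_difference,
    weighted_buried = packing$burial$weighted_buried,
    weighted_exposed = packing$burial$weighted_exposed,
    binding_kd = if (!is.null(binding)) binding$estimates[["kd"]] else NULL,
    binding_ci_kd = if (!is.null(binding)) binding$ci_kd else NULL
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Download a structure from the RCSB PDB
#'
#' Convenience fetcher for the worked example against the deposited crystal
#' structure of the switchable hexamer (PDB accession 6ZT1, whose asymmetric
#' unit contains both the open barrel and the collapsed sandwich). Requires
#' network access.
#'
#' @param id four-character PDB accession (e.g. `"6ZT1"`).
#' @param path destination file; defaults to a file in `tempdir()`.
#' @return The path to the downloaded PDB file.
#' @export
fetch_rcsb_structure <- function(id, path = file.path(tempdir(),
                                                      paste0(id, ".pdb"))) {
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  ok <- tryCatch(utils::download.file(url, path, quiet = TRUE) == 0L,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path) || file.size(path) == 0L) {
    stop("could not download ", id, " from the RCSB PDB (network required)")
  }
  path
}
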