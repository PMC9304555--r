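# Validated pipeline configuration and the end-to-end runner.

config_template <- function() {
  list(
    probe = list(spring_constant = 0.035, bead_radius_um = 18.5,
                 set_force_nN = 3.0, approach_speed_um_s = 10),
    grid = list(n_rows_DV = 3, n_segments = 3, step_um = 15),
    truth = list(C_true = 40, alpha_true = 2 * pi,
                 segment_length_points = 15, phase = 0,
                 profile = "sinusoid", omega = NULL, first_stage = 8),
    noise = list(deflection_sd_um = 0.005, k_sd_Pa = 0),
    fitting = list(max_force_nN = 3.0, n_samples = 160,
                   refine_contact = FALSE),
    periodicity = list(segment_length_points = 15, starts_with = "unknown"),
    stats = list(gate_alpha = 0.01, center = "mean",
                 normalization = "mean-of-all-ROIs",
                 paired_wilcoxon = FALSE),
    seed = NULL,
    paths = list(outdir = NULL)
  )
}

merge_validate <- function(template, user, path = "config") {
  unknown <- setdiff(names(user), names(template))
  if (length(unknown) > 0) {
    stop_input("%s: unknown key(s): %s", path,
               paste(paste0(path, "$", unknown), collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      if (!is.list(user[[k]])) {
        stop_input("%s$%s must be a named list", path, k)
      }
      template[[k]] <- merge_validate(template[[k]], user[[k]],
                                      paste0(path, "$", k))
    } else {
      template[k] <- user[k]
    }
  }
  template
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the documented defaults and rejects unknown
#' keys. The defaults describe the standard synthetic study: a 3-row strip
#' of 3 somite segments (45 columns at 15 um), probe with 0.035 N/m spring
#' constant, 18.5 um bead and 3 nN set force, a sinusoidal truth field
#' with `C = 40` Pa and `alpha = 2*pi` Pa (which makes the anterior /
#' posterior half means 36 and 44 Pa), 5 nm deflection noise. A seed is
#' mandatory whenever the simulation stage will run.
#'
#' @param ... Top-level sections to override (e.g. `seed = 1`,
#'   `truth = list(C_true = 40)`). Partial section lists are merged over
#'   the defaults.
#' @param simulate Will the pipeline simulate its input? (Seed required.)
#' @return A validated list of class `somistiff_config`.
#' @examples
#' cfg <- somistiff_config(seed = 7, noise = list(deflection_sd_um = 0))
#' cfg$truth$C_true
#' @export
somistiff_config <- function(..., simulate = TRUE) {
  user <- list(...)
  cfg <- merge_validate(config_template(), user)
  if (simulate && is.null(cfg$seed)) {
    stop_input("somistiff_config: seed is mandatory for any simulation step")
  }
  if (!is.null(cfg$seed) && (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))) {
    stop_input("somistiff_config: seed must be an integer")
  }
  cfg$probe <- do.call(probe_spec, cfg$probe)
  class(cfg) <- "somistiff_config"
  cfg
}

#' Run the full synthetic-to-statistics pipeline
#'
#' Executes simulate -> fit-curves -> map/profile -> periodicity -> stats
#' from a validated configuration, persisting every intermediate artifact
#' (CSV + JSON sidecars) under `outdir` and writing a run manifest with
#' the config hash, stage timings, warnings and per-stage output paths.
#' Rerunning with the same config and seed reproduces all numeric outputs.
#' A stage failure aborts with the stage name after persisting the partial
#' manifest.
#'
#' @param config A `somistiff_config`.
#' @param outdir Output directory (default from the config; a temporary
#'   directory if neither is set).
#' @return The manifest (list, class `run_manifest`), invisibly; its
#'   `results` element holds the in-memory stage products (`truth`,
#'   `fits`, `map`, `profile`, `sin_fit`, `region_comparison`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "somistiff_config"))
  if (is.null(outdir)) outdir <- config$paths$outdir
  if (is.null(outdir)) outdir <- tempfile("somistiff_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_plain <- unclass(config)
  cfg_plain$probe <- unclass(cfg_plain$probe)
  hash <- hash_object(cfg_plain)
  manifest <- list(config_hash = hash, created = format(Sys.time()),
                   outdir = outdir, stages = list(), warnings = character())
  results <- list()
  persist <- function() {
    jsonlite::write_json(manifest[setdiff(names(manifest), "results")],
                         file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        manifest$stages[[name]] <<- list(status = "failed",
                                         error = conditionMessage(e))
        persist()
        stop_input("run_pipeline: stage '%s' failed: %s", name,
                   conditionMessage(e))
      }),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    out$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
    manifest$stages[[name]] <<- out[setdiff(names(out), "value")]
    out$value
  }

  sim <- run_stage("simulate", {
    truth <- make_truth_field(
      config$truth$C_true, config$truth$alpha_true,
      segment_length_points = config$truth$segment_length_points,
      n_segments = config$grid$n_segments,
      n_rows_DV = config$grid$n_rows_DV,
      phase = config$truth$phase, profile = config$truth$profile,
      omega = config$truth$omega, k_noise_sd = config$noise$k_sd_Pa,
      step_um = config$grid$step_um, seed = config$seed,
      first_stage = config$truth$first_stage)
    bundle <- simulate_grid(truth, probe = config$probe,
                            noise_sd_um = config$noise$deflection_sd_um,
                            seed = config$seed,
                            n_samples = config$fitting$n_samples)
    path <- file.path(outdir, "force_bundle.csv")
    write_force_bundle(bundle, path, config_hash = hash)
    list(status = "ok", outputs = c(path, default_sidecar_path(path)),
         value = list(truth = truth, bundle = bundle))
  })

  fits <- run_stage("fit_curves", {
    f <- fit_grid(sim$bundle,
                  max_force_nN = config$fitting$max_force_nN,
                  refine_contact = config$fitting$refine_contact)
    path <- file.path(outdir, "curve_fits.csv")
    write_curve_fits(f, path)
    list(status = "ok", outputs = path,
         n_converged = sum(f$converged), value = f)
  })

  mp <- run_stage("map_profile", {
    map <- assemble_map(fits, step_um = config$grid$step_um)
    prof <- ap_profile(map)
    p1 <- file.path(outdir, "stiffness_map.csv")
    p2 <- file.path(outdir, "ap_profile.csv")
    write_stiffness_map(map, p1, config_hash = hash)
    write_ap_profile(prof, p2, config_hash = hash)
    list(status = "ok",
         outputs = c(p1, default_sidecar_path(p1), p2,
                     default_sidecar_path(p2)),
         value = list(map = map, profile = prof))
  })

  sin_fit <- run_stage("periodicity", {
    ft <- fit_sinusoid(mp$profile,
                       segment_length_points =
                         config$periodicity$segment_length_points,
                       starts_with = config$periodicity$starts_with)
    path <- file.path(outdir, "sinusoid_fit.json")
    jsonlite::write_json(
      list(C = ft$C, alpha = ft$alpha, omega = ft$omega, phi = ft$phi,
           rss = ft$rss, pearson_R = ft$pearson_R, converged = ft$converged,
           n_points = ft$n_points, phi0_chosen = ft$phi0_chosen,
           config_hash = hash),
      path, auto_unbox = TRUE, digits = NA, null = "null")
    list(status = "ok", outputs = path, value = ft)
  })

  stats_out <- run_stage("stats", {
    ann <- assign_halves(ncol(mp$map$K_grid),
                         config$truth$segment_length_points,
                         starts_with = sim$truth$starts_with,
                         first_stage = config$truth$first_stage)
    summ <- summarize_regions(mp$map, ann, center = config$stats$center)
    cmp <- compare_regions(summ,
                           paired_wilcoxon = config$stats$paired_wilcoxon)
    path <- file.path(outdir, "region_comparison.json")
    jsonlite::write_json(
      list(test_name = cmp$test_name, statistic = cmp$statistic,
           p_value = cmp$p_value, direction_Pa = cmp$direction_Pa,
           n_segments = cmp$n_segments, config_hash = hash),
      path, auto_unbox = TRUE, digits = NA, null = "null")
    p2 <- file.path(outdir, "region_summary.csv")
    write_csv9(as.data.frame(summ), p2)
    list(status = "ok", outputs = c(path, p2), value = cmp)
  })

  persist()
  manifest$results <- list(truth = sim$truth, fits = fits, map = mp$map,
                           profile = mp$profile, sin_fit = sin_fit,
                           region_comparison = stats_out)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run %s (%d stage(s), %d warning(s)) -> %s\n",
              substr(x$config_hash, 1, 8), length(x$stages),
              length(x$warnings), x$outdir))
  for (nm in names(x$stages)) {
    cat(sprintf("  %-12s %s (%.2fs)\n", nm, x$stages[[nm]]$status,
                x$stages[[nm]]$elapsed_s))
  }
  invisible(x)
}
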