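pipeline_stage_keys <- list(
  membrane = c("seed", "n_lipids_per_leaflet", "sterol_fraction", "box_xy",
               "box_z", "leaflet_z", "clustering", "n_saponins", "p_bound",
               "dwell_frames", "n_frames", "jitter_sd", "n_waters",
               "saponin_angle", "sterol_resname"),
  rdf = c("selection", "leaflet", "bin_width", "r_max", "frame_range",
          "phosphate_selection", "smoothing_window", "r_min"),
  density_map = c("selection", "grid_size", "frame_window"),
  binding = c("saponin_resname", "phosphate_selection", "aglycone_name",
              "depth_threshold", "stability_fraction", "window"),
  leakage = c("true_4pl", "concentrations", "noise_sd", "n_reps",
              "dilution_factor", "c_max", "composition"),
  viability = c("groups", "n_cells", "n_reps"))

validate_run_config <- function(config) {
  top_keys <- c("seed", "output_dir", "stages")
  bad <- setdiff(names(config), top_keys)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(config$seed)) stop("config requires an explicit 'seed' ",
                                 "(no implicit clock seeding)", call. = FALSE)
  if (is.null(config$stages) || !length(config$stages))
    stop("config requires a non-empty 'stages' block", call. = FALSE)
  bad_stage <- setdiff(names(config$stages), names(pipeline_stage_keys))
  if (length(bad_stage))
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  for (st in names(config$stages)) {
    bad_key <- setdiff(names(config$stages[[st]]), pipeline_stage_keys[[st]])
    if (length(bad_key))
      stop("unknown key(s) in stage '", st, "': ",
           paste(bad_key, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

md5_of_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  path
}

#' Run an end-to-end analysis pipeline from a single configuration
#'
#' Executes the requested stages in dependency order (membrane generation,
#' then RDF / density map / binding classification on the generated
#' trajectory; leakage-assay simulation and 4PL fitting; viability
#' simulation with lysis fractions and group statistics), writing per-stage
#' CSV/JSON outputs, a manifest with the config hash, seed, and per-file
#' checksums, and a human-readable summary. Identical config and seed yield
#' byte-identical outputs. A stage failure halts the run with the stage name
#' while preserving partial outputs.
#'
#' @param config a nested list, or path to a YAML file, with top-level keys
#'   `seed`, `output_dir` (optional here, can be given as argument) and
#'   `stages` (any of `membrane`, `rdf`, `density_map`, `binding`,
#'   `leakage`, `viability`). Unknown keys raise a validation error naming
#'   the key.
#' @param output_dir output directory (created if needed); overrides
#'   `config$output_dir`.
#' @return (invisibly) list with `outputs` (named file paths), `results`
#'   (in-memory stage results), and `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  validate_run_config(config)
  outdir <- output_dir %||% config$output_dir %||%
    stop("no output directory given", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  stages <- config$stages
  outputs <- character(0)
  results <- list()
  log <- function(...) message(sprintf(...))

  run_stage <- function(name, expr) {
    log("[sapomem] stage %s ...", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sys <- NULL
  if (!is.null(stages$membrane)) {
    sys <- run_stage("membrane", {
      args <- stages$membrane
      args$seed <- args$seed %||% seed
      gen_membrane_system(do.call(membrane_config, args))
    })
    results$membrane <- sys
    p <- file.path(outdir, "trajectory.gro")
    write_gro(sys$trajectory, p)
    outputs["trajectory"] <- p
  }

  if (!is.null(stages$rdf)) {
    if (is.null(sys)) stop("pipeline stage 'rdf' requires stage 'membrane'",
                           call. = FALSE)
    res <- run_stage("rdf", {
      a <- stages$rdf
      sel <- select_atoms(sys$trajectory,
                          a$selection %||% "name O3")
      rdf <- lateral_rdf(sys$trajectory, sel,
                         leaflet = a$leaflet %||% "both",
                         bin_width = a$bin_width %||% 0.05,
                         r_max = a$r_max,
                         frame_range = a$frame_range)
      peak <- first_peak(rdf, smoothing_window = a$smoothing_window %||% 5L,
                         r_min = a$r_min %||% 0.3)
      list(rdf = rdf, peak = peak)
    })
    results$rdf <- res
    p <- file.path(outdir, "rdf.csv")
    utils::write.csv(data.frame(r = res$rdf$bin_centers, g = res$rdf$g,
                                g_se = res$rdf$g_se), p, row.names = FALSE)
    outputs["rdf"] <- p
    p2 <- file.path(outdir, "rdf_peak.json")
    write_json_out(res$peak[c("found", "r", "g", "index")], p2)
    outputs["rdf_peak"] <- p2
  }

  if (!is.null(stages$density_map)) {
    if (is.null(sys)) stop("pipeline stage 'density_map' requires stage ",
                           "'membrane'", call. = FALSE)
    dm <- run_stage("density_map", {
      a <- stages$density_map
      sel <- select_atoms(sys$trajectory, a$selection %||% "name O3")
      density_map(sys$trajectory, sel, grid_size = a$grid_size %||% 25L,
                  frame_window = a$frame_window)
    })
    results$density_map <- dm
    p <- file.path(outdir, "density_map.csv")
    utils::write.csv(as.data.frame(dm$grid), p, row.names = FALSE)
    outputs["density_map"] <- p
  }

  if (!is.null(stages$binding)) {
    if (is.null(sys)) stop("pipeline stage 'binding' requires stage ",
                           "'membrane'", call. = FALSE)
    bt <- run_stage("binding", {
      a <- stages$binding
      phos <- select_atoms(sys$trajectory,
                           a$phosphate_selection %||%
                             "resname DOPC and name P")
      classify_binding(sys$trajectory,
                       saponin_resname = a$saponin_resname %||% "SAP",
                       phosphate_selection = phos,
                       aglycone_name = a$aglycone_name %||% "AGL",
                       depth_threshold = a$depth_threshold %||% 0,
                       stability_fraction = a$stability_fraction %||% 0.8,
                       window = a$window %||% 0.5)
    })
    results$binding <- bt
    p <- file.path(outdir, "binding_trace.csv")
    utils::write.csv(bt$trace, p, row.names = FALSE)
    outputs["binding_trace"] <- p
    p2 <- file.path(outdir, "binding_summary.json")
    write_json_out(list(population_fraction = bt$population_fraction,
                        molecules = bt$summary), p2)
    outputs["binding_summary"] <- p2
  }

  if (!is.null(stages$leakage)) {
    lk <- run_stage("leakage", {
      a <- stages$leakage
      tbl <- gen_leakage_experiment(
        true_4pl = as.numeric(a$true_4pl %||% c(-1.5, 0, 100, 20)),
        concentrations = as.numeric(a$concentrations %||%
                                      c(0, 2, 5, 10, 20, 35, 50, 75, 100)),
        noise_sd = a$noise_sd %||% 0.05, n_reps = a$n_reps %||% 3L,
        dilution_factor = a$dilution_factor %||% 0.89,
        seed = seed + 101L, composition = a$composition %||% "LUV")
      tbl$release <- as.numeric(percent_release(
        tbl, dilution_factor = a$dilution_factor %||% 0.89))
      fit <- fit_4pl(tbl)
      if (fit$converged) fit$ci <- ec50_profile_ci(fit)
      fit <- censor_ec50(fit, c_max = a$c_max %||% 100)
      list(table = tbl, fit = fit)
    })
    results$leakage <- lk
    p <- file.path(outdir, "leakage_table.csv")
    utils::write.csv(lk$table, p, row.names = FALSE)
    outputs["leakage_table"] <- p
    p2 <- file.path(outdir, "leakage_fit.json")
    f <- lk$fit
    write_json_out(list(b = f$b, c = f$c, d = f$d, ec50 = f$e,
                        se = as.list(f$se), rss = f$rss,
                        ci = if (!is.null(f$ci)) as.list(f$ci),
                        converged = f$converged, censored = f$censored,
                        censor_label = f$censor_label), p2)
    outputs["leakage_fit"] <- p2
  }

  if (!is.null(stages$viability)) {
    vb <- run_stage("viability", {
      a <- stages$viability
      groups <- unlist(a$groups %||% c(CHL = 0.9, ERG = 0.75))
      tbl <- gen_viability_experiment(groups, n_cells = a$n_cells %||% 20000L,
                                      n_reps = a$n_reps %||% 5L,
                                      seed = seed + 202L)
      lys <- lysis_fraction(tbl)
      cmp <- if (length(groups) >= 2L)
        compare_groups(100 * tbl$pi_positive / tbl$total_cells, tbl$group)
      list(table = tbl, lysis = lys, comparison = cmp)
    })
    results$viability <- vb
    p <- file.path(outdir, "viability.csv")
    utils::write.csv(vb$table, p, row.names = FALSE)
    outputs["viability"] <- p
    p2 <- file.path(outdir, "lysis.csv")
    utils::write.csv(vb$lysis, p2, row.names = FALSE)
    outputs["lysis"] <- p2
  }

  manifest <- list(
    config_hash = md5_of_object(config),
    seed = seed,
    package = "sapomem",
    version = as.character(utils::packageVersion("sapomem")),
    files = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  pm <- file.path(outdir, "manifest.json")
  write_json_out(manifest, pm)

  summ <- c(sprintf("sapomem pipeline run (seed %d)", seed),
            sprintf("stages: %s", paste(names(stages), collapse = ", ")),
            if (!is.null(results$rdf))
              sprintf("rdf first peak: %s",
                      if (results$rdf$peak$found)
                        sprintf("%.3f nm", results$rdf$peak$r) else "none"),
            if (!is.null(results$binding))
              sprintf("population bound fraction: %.3f",
                      results$binding$population_fraction),
            if (!is.null(results$leakage))
              sprintf("EC50: %.4g uM%s", results$leakage$fit$e,
                      if (isTRUE(results$leakage$fit$censored))
                        paste0(" (censored ",
                               results$leakage$fit$censor_label, ")") else ""),
            if (!is.null(results$viability))
              sprintf("lysis means: %s",
                      paste(sprintf("%s %.1f%%", results$viability$lysis$group,
                                    results$viability$lysis$mean),
                            collapse = ", ")))
  ps <- file.path(outdir, "summary.txt")
  writeLines(summ, ps)

  invisible(list(outputs = c(outputs, manifest = pm, summary = ps),
                 results = results, manifest = manifest))
}
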