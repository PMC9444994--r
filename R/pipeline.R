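# End-to-end pipeline runner: generate -> detect phases -> fit ED/ES meshes
# -> exclusion filter -> atlases -> two-stage mode selection -> model
# comparison, with a stage-count manifest and reproducible text outputs.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] (carries the master seed).
#' @param fit A [fit_config()].
#' @param variance_fraction Variance share retained per atlas.
#' @param k,repeats Cross-validation settings.
#' @param alpha Stepwise threshold.
#' @param nested_selection Re-select variables in each CV training fold.
#' @param out_dir Output directory for the run.
#' @param verbose Print stage progress.
#' @return Object of class `pipeline_config`, serializable with
#'   [save_pipeline_config()].
#' @export
pipeline_config <- function(cohort = cohort_config(), fit = fit_config(),
                            variance_fraction = 0.95, k = 10, repeats = 100,
                            alpha = 0.05, nested_selection = FALSE,
                            out_dir = "lvshape_run", verbose = TRUE) {
  structure(list(cohort = cohort, fit = fit,
                 variance_fraction = variance_fraction, k = k,
                 repeats = repeats, alpha = alpha,
                 nested_selection = nested_selection,
                 out_dir = out_dir, verbose = verbose),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' The configuration (including the seed) is archived with every run so that
#' each output file is reproducible from the archive alone.
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `path` (save) or the restored `pipeline_config` (load).
#' @export
save_pipeline_config <- function(config, path) {
  plain <- config
  plain$cohort <- unclass(plain$cohort)
  plain$fit <- unclass(plain$fit)
  jsonlite::write_json(unclass(plain), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_pipeline_config
#' @export
load_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_args <- raw$cohort[setdiff(names(raw$cohort),
                                    c("es_rho", "outcome_beta0",
                                      "outcome_beta"))]
  pipeline_config(
    cohort = do.call(cohort_config, cohort_args),
    fit = do.call(fit_config, raw$fit),
    variance_fraction = raw$variance_fraction, k = raw$k,
    repeats = raw$repeats, alpha = raw$alpha,
    nested_selection = raw$nested_selection,
    out_dir = raw$out_dir, verbose = raw$verbose
  )
}

# Default candidate pools, matching the clinical-baseline / 3D / multivariable
# comparison layout.
default_model_configs <- function(es_vars, c_vars) {
  list(
    esv = "esv",
    lvef = "lvef",
    es_shape = es_vars,
    contraction = c_vars,
    cmr = c("esv", "edv", "lvef", "is_ml", "mvo_ml", es_vars, c_vars),
    all = c("esv", "edv", "lvef", "is_ml", "mvo_ml", "age", "sex_male",
            "smoking", "hypertension", "diabetes", "killip", "vessels",
            es_vars, c_vars)
  )
}

#' Run the full shape-analysis pipeline on a synthetic cohort
#'
#' Executes every stage on rasterized mask stacks: phase detection, contour
#' extraction, ED/ES template fitting, mesh volume computation, exclusion of
#' degenerate subjects, atlas construction (ED, ES, contraction), two-stage
#' mode selection and model comparison. Writes the cohort table, fit report,
#' exclusion log, atlases, comparison report and a manifest with stage counts
#' to `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run directory, manifest, comparison and
#'   selection.
#' @export
run_pipeline <- function(config) {
  t0 <- proc.time()["elapsed"]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(sprintf(...))

  say("stage 1/6: generating cohort (n = %d)", config$cohort$n_subjects)
  cohort <- generate_cohort(config$cohort, rasterize = TRUE,
                            keep_meshes = FALSE)
  n <- nrow(cohort$table)
  template <- build_template(config$cohort$n_circ, config$cohort$n_long,
                             config$cohort$geometry)

  say("stage 2/6: phase detection + mesh personalization")
  p_nodes <- 3L * nrow(template$nodes)
  ed_fit <- matrix(NA_real_, n, p_nodes)
  es_fit <- matrix(NA_real_, n, p_nodes)
  contr <- matrix(NA_real_, n, p_nodes)
  fit_rows <- vector("list", n)
  phase_ok <- 0L
  fitted_n <- 0L
  for (i in seq_len(n)) {
    stack <- cohort$subjects[[i]]$stack
    ph <- tryCatch(detect_phases(stack), error = function(e) NULL)
    if (is.null(ph)) {
      fit_rows[[i]] <- data.frame(id = i, phase_detected = FALSE,
                                  ed_frame = NA, es_frame = NA,
                                  edv = NA, esv = NA, lvef = NA,
                                  accuracy_ed = NA, accuracy_es = NA)
      next
    }
    phase_ok <- phase_ok + 1L
    fits <- lapply(c(ph$ed_frame, ph$es_frame), function(f) {
      ct <- extract_contours(stack, f)
      fit_mesh(template, ct, config$fit)
    })
    acc <- mapply(function(m, f) {
      fit_accuracy(m, extract_contours(stack, f))$median
    }, fits, c(ph$ed_frame, ph$es_frame))
    vols <- mesh_volumes(fits[[1]], fits[[2]])
    ed_fit[i, ] <- as_shape_vector(fits[[1]])
    es_fit[i, ] <- as_shape_vector(fits[[2]])
    contr[i, ] <- as_shape_vector(contraction_field(fits[[1]],
                                                    fits[[2]])$displacements)
    fitted_n <- fitted_n + 1L
    fit_rows[[i]] <- data.frame(id = i, phase_detected = TRUE,
                                ed_frame = ph$ed_frame,
                                es_frame = ph$es_frame,
                                edv = vols$edv, esv = vols$esv,
                                lvef = vols$lvef,
                                accuracy_ed = acc[1], accuracy_es = acc[2])
  }
  fit_report <- do.call(rbind, fit_rows)

  say("stage 3/6: exclusion filter")
  vol_df <- fit_report[fit_report$phase_detected & !is.na(fit_report$lvef),
                       c("id", "lvef")]
  excl <- exclusion_filter(vol_df)
  kept <- excl$kept

  say("stage 4/6: atlases (%d subjects analyzed)", length(kept))
  atlas_ed <- build_atlas(ed_fit[kept, , drop = FALSE], kind = "ED")
  atlas_es <- build_atlas(es_fit[kept, , drop = FALSE], kind = "ES")
  atlas_c <- build_atlas(contr[kept, , drop = FALSE], kind = "contraction")
  k_es <- modes_for_variance(atlas_es, config$variance_fraction)
  k_c <- modes_for_variance(atlas_c, config$variance_fraction)
  es_scores <- project_atlas(atlas_es, es_fit[kept, , drop = FALSE])
  c_scores <- project_atlas(atlas_c, contr[kept, , drop = FALSE])

  say("stage 5/6: two-stage mode selection (K_es = %d, K_c = %d)", k_es, k_c)
  tab <- cohort$table[kept, , drop = FALSE]
  tab$edv <- fit_report$edv[kept]
  tab$esv <- fit_report$esv[kept]
  tab$lvef <- fit_report$lvef[kept]
  sel <- two_stage_mode_selection(es_scores[, seq_len(k_es), drop = FALSE],
                                  c_scores[, seq_len(k_c), drop = FALSE],
                                  tab$mace, alpha = config$alpha)
  mode_cols <- sel$data[, setdiff(names(sel$data), "mace"), drop = FALSE]
  tab <- cbind(tab, mode_cols)

  say("stage 6/6: model comparison (k = %d, %d repeats)", config$k,
      config$repeats)
  configs <- default_model_configs(
    es_vars = colnames(sel$data)[grep("^es_mode_", colnames(sel$data))],
    c_vars = colnames(sel$data)[grep("^c_mode_", colnames(sel$data))])
  comparison <- compare_models(tab, configs, k = config$k,
                               repeats = config$repeats,
                               seed = config$cohort$seed,
                               alpha = config$alpha,
                               nested_selection = config$nested_selection)

  # outputs -----------------------------------------------------------------
  od <- config$out_dir
  utils::write.csv(tab, file.path(od, "cohort.csv"), row.names = FALSE)
  utils::write.csv(fit_report, file.path(od, "fit_report.csv"),
                   row.names = FALSE)
  utils::write.csv(excl$log, file.path(od, "exclusions.csv"),
                   row.names = FALSE)
  utils::write.csv(comparison$table, file.path(od, "comparison.csv"),
                   row.names = FALSE)
  writeLines(format_comparison_text(comparison),
             file.path(od, "report.txt"))
  save_atlas(atlas_es, file.path(od, "atlas_es"))
  save_atlas(atlas_c, file.path(od, "atlas_contraction"))
  save_atlas(atlas_ed, file.path(od, "atlas_ed"))
  save_pipeline_config(config, file.path(od, "config.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("lvshape")),
    seed = config$cohort$seed,
    counts = list(generated = n, phase_detected = phase_ok,
                  fitted = fitted_n, excluded = length(excl$excluded),
                  analyzed = length(kept)),
    modes = list(k_es = k_es, k_contraction = k_c,
                 selected = sel$selected)
  )
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline done in %.1f s", proc.time()["elapsed"] - t0)
  invisible(list(dir = od, manifest = manifest, comparison = comparison,
                 selection = sel, atlases = list(ed = atlas_ed, es = atlas_es,
                                                 contraction = atlas_c),
                 fit_report = fit_report, table = tab))
}
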