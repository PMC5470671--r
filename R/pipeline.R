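#' Pipeline configuration
#'
#' Bundles the stage options for [run_pipeline()]. The defaults give a
#' small but complete end-to-end run: a synthetic cohort, full EEG
#' simulation and preprocessing for a few subjects (spectrograms for
#' the rest come from the forward model plus observation noise, which
#' is orders of magnitude cheaper), inversion of a configurable model
#' subset, group model selection, feature extraction and
#' classification.
#'
#' @param n_favorable,n_poor cohort class sizes.
#' @param sim a [simulation_config()]; its seed drives every stage.
#' @param models named list of [model_spec()]s to invert (default DCM1
#'   and the all-linear model).
#' @param generator name (in `models`) of the architecture generating
#'   the data.
#' @param n_eeg subjects that get full EEG simulation + preprocessing.
#' @param spect_noise_sd observation noise added to forward-model
#'   spectrograms for non-EEG subjects (percent-power units).
#' @param cv list: `k`, `repeats`, `regularization`.
#' @param rule an [outcome_rule()].
#' @param out_dir run directory to create.
#' @return list of validated options.
#' @export
pipeline_config <- function(n_favorable = 5L, n_poor = 5L,
                            sim = simulation_config(
                              sample_rate = 250, n_trials = 8L,
                              noise_sd = 0.5),
                            models = build_model_space()[c("DCM1", "all_linear")],
                            generator = names(models)[1],
                            n_eeg = 2L, spect_noise_sd = 2,
                            cv = list(k = 5L, repeats = 20L,
                                      regularization = 1),
                            rule = outcome_rule(),
                            out_dir = tempfile("motornet_run_")) {
  stopifnot(n_favorable >= 1, n_poor >= 1, n_eeg >= 0)
  if (!generator %in% names(models))
    stop("generator must name one of the models")
  list(n_favorable = n_favorable, n_poor = n_poor, sim = sim,
       models = models, generator = generator, n_eeg = n_eeg,
       spect_noise_sd = spect_noise_sd, cv = cv, rule = rule,
       out_dir = out_dir)
}

#' Run the full pipeline
#'
#' Executes simulate -> preprocess -> model inversion (all configured
#' models) -> group model selection -> features -> classification ->
#' outcome statistics, writing each stage's outputs and a manifest of
#' MD5 hashes into the run directory. A rerun with the same
#' configuration and seed reproduces the deterministic stages
#' bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the run directory path.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  written <- character()
  note <- function(path) written <<- c(written, path)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  bands <- config$sim$bands
  cohort <- stage("simulate", {
    ch <- generate_cohort(config$n_favorable, config$n_poor, config$sim,
                          model = config$models[[config$generator]])
    write_clinical_table(ch$clinical, out("clinical.csv"))
    note(out("clinical.csv"))
    ch
  })

  n <- length(cohort$ground_truth$coupling)
  model_gen <- cohort$ground_truth$model
  specs <- stage("preprocess", {
    lapply(seq_len(n), function(i) {
      p <- cohort$ground_truth$coupling[[i]]
      if (i <= config$n_eeg) {
        ep <- simulate_eeg_trials(model_gen, p,
                                  cohort$ground_truth$lead_field,
                                  config$sim, seed = config$sim$seed + i)
        sp <- preprocess_epochs(ep, cohort$ground_truth$lead_field,
                                frequencies = config$sim$frequencies)
        sp <- project_to_bands(sp, bands)
        # thin the time axis to ~25 ms before inversion
        step <- max(1L, round(25 / (1000 / config$sim$sample_rate)))
        keep <- seq(1, length(sp$times), by = step)
        source_spectrogram(sp$power[, , keep, drop = FALSE],
                           sp$frequencies, sp$times[keep],
                           sp$source_labels, sp$n_trials_used)
      } else {
        sp <- simulate_induced_power(model_gen, p)
        old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
        set.seed(config$sim$seed + 1000L + i)
        sp$power <- sp$power + array(rnorm(length(sp$power), 0,
                                           config$spect_noise_sd),
                                     dim(sp$power))
        sp
      }
    })
  })

  fits <- stage("dcm", {
    lapply(specs, function(sp)
      lapply(config$models, function(m) invert_dcm(m, sp)))
  })
  Fmat <- t(vapply(fits, function(fl)
    vapply(fl, function(f) f$free_energy, numeric(1)),
    numeric(length(config$models))))
  colnames(Fmat) <- names(config$models)
  write_evidence(Fmat, out("evidence.csv")); note(out("evidence.csv"))

  bmsres <- stage("bms", {
    b <- rfx_compare(Fmat, seed = config$sim$seed)
    jsonlite::write_json(
      list(ffx_posterior = as.list(b$ffx_posterior),
           expected_prob = as.list(b$expected_prob),
           exceedance_prob = as.list(b$exceedance_prob),
           best_per_subject = b$best_per_subject),
      out("bms.json"), auto_unbox = TRUE, digits = NA)
    note(out("bms.json"))
    b
  })
  best_model <- names(which.max(bmsres$exceedance_prob))

  feats <- stage("features", {
    fv <- lapply(fits, function(fl)
      extract_connection_features(fl[[best_model]], bands))
    X <- feature_matrix(fv)
    write_features(X, out("features.csv"),
                   labels = cohort$ground_truth$labels)
    note(out("features.csv"))
    sv <- lapply(specs, function(sp) extract_source_features(sp, bands))
    Xs <- feature_matrix(sv)
    write_features(Xs, out("source_features.csv"),
                   labels = cohort$ground_truth$labels)
    note(out("source_features.csv"))
    list(connection = X, source = Xs)
  })

  clsf <- stage("classify", {
    y <- cohort$ground_truth$labels
    cv <- crossval_accuracy(feats$connection, y, k = config$cv$k,
                            repeats = config$cv$repeats,
                            seed = config$sim$seed,
                            regularization = config$cv$regularization)
    bandtab <- band_combination_search(feats$connection, y, bands,
                                       k = config$cv$k,
                                       repeats = config$cv$repeats,
                                       seed = config$sim$seed,
                                       regularization = config$cv$regularization)
    write.csv(bandtab, out("band_combinations.csv"), row.names = FALSE)
    note(out("band_combinations.csv"))
    jsonlite::write_json(list(mean_accuracy = cv$mean_accuracy,
                              sd_accuracy = cv$sd_accuracy),
                         out("cv.json"), auto_unbox = TRUE, digits = NA)
    note(out("cv.json"))
    list(cv = cv, bands = bandtab)
  })

  stage("outcomes", {
    labeled <- label_table(cohort$clinical, config$rule)
    st <- cohort_stats(labeled)
    jsonlite::write_json(
      list(numeric = st$numeric, notes = st$notes,
           n_label_discrepancies = sum(labeled$label_discrepancy)),
      out("cohort_stats.json"), auto_unbox = TRUE, digits = NA, na = "null")
    note(out("cohort_stats.json"))
  })

  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  write.csv(manifest, out("manifest.csv"), row.names = FALSE)
  invisible(config$out_dir)
}

#' Render a run directory into a markdown report
#'
#' Deterministic rendering of stored stage outputs: cohort statistics,
#' the band-combination accuracy table, model-selection results, and —
#' when a clinical table with recorded predictions is supplied — a
#' confusion-matrix block with sensitivity, specificity, PPV and
#' accuracy.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @param clinical optional clinical table with `prediction` filled in
#'   (e.g. [motor_clinical_table()]) for the validation block.
#' @return the report text, invisibly; also written to
#'   `report.md` in `run_dir`.
#' @export
render_report <- function(run_dir, clinical = NULL) {
  need <- c("evidence.csv", "bms.json", "band_combinations.csv", "cv.json")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("incomplete run; missing stage outputs: ",
         paste(missing, collapse = ", "))
  lines <- c("# motornet run report", "")
  bms <- jsonlite::read_json(file.path(run_dir, "bms.json"),
                             simplifyVector = TRUE)
  lines <- c(lines, "## Model selection",
             paste0("- exceedance probabilities: ",
                    paste(names(bms$exceedance_prob),
                          sprintf("%.3f", bms$exceedance_prob),
                          sep = " = ", collapse = ", ")), "")
  cv <- jsonlite::read_json(file.path(run_dir, "cv.json"),
                            simplifyVector = TRUE)
  lines <- c(lines, "## Classification",
             sprintf("- cross-validated accuracy: %.1f%% +/- %.1f%%",
                     cv$mean_accuracy, cv$sd_accuracy), "",
             "## Band combinations (top 5)")
  bt <- read.csv(file.path(run_dir, "band_combinations.csv"))
  top <- head(bt, 5)
  lines <- c(lines, sprintf("- %s: %.1f%% +/- %.1f%%", top$combination,
                            top$mean_accuracy, top$sd_accuracy), "")
  if (!is.null(clinical)) {
    val <- clinical[clinical$dataset == "validation" &
                      !is.na(clinical$prediction) &
                      clinical$prediction != "", ]
    if (nrow(val)) {
      ev <- evaluate(val$prediction, val$true_condition)
      fmt <- function(v) if (is.na(v)) "n/a" else
        sprintf("%.1f%%", round_half_up(v, 1))
      lines <- c(lines, "## External validation",
                 paste0("- counts: ", paste(names(ev$counts), ev$counts,
                                            sep = "=", collapse = " ")),
                 paste0("- sensitivity ", fmt(ev$sensitivity),
                        ", specificity ", fmt(ev$specificity),
                        ", PPV ", fmt(ev$positive_predictive_value),
                        ", accuracy ", fmt(ev$accuracy)), "")
      sg <- subgroup_accuracy(val, "lesion_site")
      lines <- c(lines, "### Accuracy by lesion site",
                 sprintf("- %s: n = %d, accuracy %s", sg$bin, sg$n,
                         ifelse(is.na(sg$accuracy), "n = 0",
                                sprintf("%.0f%%", sg$accuracy))), "")
    }
  }
  txt <- paste(lines, collapse = "\n")
  writeLines(txt, file.path(run_dir, "report.md"))
  invisible(txt)
}
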