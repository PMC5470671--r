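#' Outcome rule: 10% of each scale's maximum score
#'
#' Favorable outcome = post-rehabilitation improvement reaching 10% of
#' the maximum score on any scale: 6.6 points on the FMA (max 66), 7.5
#' on the WMFT, 16.2 on the TEMPA. Comparisons use `>=` ("reaching"
#' the level).
#'
#' @param fma,wmft,tempa improvement thresholds in points.
#' @return named list of thresholds.
#' @export
outcome_rule <- function(fma = 6.6, wmft = 7.5, tempa = 16.2) {
  if (any(c(fma, wmft, tempa) <= 0)) stop("thresholds must be positive")
  list(fma = fma, wmft = wmft, tempa = tempa)
}

#' Label rehabilitation outcome from pre/post scores
#'
#' @param rec one clinical record (data frame row or list) with
#'   `fma_pre`, `fma_post`, `wmft_pre`, `wmft_post`, `tempa_pre`,
#'   `tempa_post`. TEMPA is negative-scored; improvement is
#'   `post - pre` on all scales.
#' @param rule an [outcome_rule()].
#' @return `"F"` (favorable) or `"P"` (poor).
#' @export
label_outcome <- function(rec, rule = outcome_rule()) {
  need <- c("fma_pre", "fma_post", "wmft_pre", "wmft_post",
            "tempa_pre", "tempa_post")
  vals <- lapply(need, function(k) rec[[k]])
  if (any(vapply(vals, function(v) is.null(v) || is.na(v), logical(1))))
    stop("labeling error: missing pre/post score")
  fav <- (rec[["fma_post"]] - rec[["fma_pre"]] >= rule$fma) ||
    (rec[["wmft_post"]] - rec[["wmft_pre"]] >= rule$wmft) ||
    (rec[["tempa_post"]] - rec[["tempa_pre"]] >= rule$tempa)
  if (fav) "F" else "P"
}

#' Apply the outcome rule to a whole table and report discrepancies
#'
#' The recorded `true_condition` column stays authoritative; rows where
#' the re-applied rule disagrees are flagged, not overwritten.
#'
#' @param table clinical table (see [motor_clinical_table()]).
#' @param rule an [outcome_rule()].
#' @return the table with `rule_label` and logical `label_discrepancy`
#'   columns appended.
#' @export
label_table <- function(table, rule = outcome_rule()) {
  table$rule_label <- vapply(seq_len(nrow(table)),
                             function(i) label_outcome(table[i, ], rule),
                             character(1))
  table$label_discrepancy <- table$rule_label != table$true_condition
  table
}

#' Packaged clinical table
#'
#' The 53-patient clinical table shipped with the package: 37 training
#' rows and 16 validation rows with demographics, lesion descriptors,
#' FMA/TEMPA/WMFT pre/post scores, the recorded outcome
#' (`true_condition`) and, for validation rows, the model's recorded
#' per-patient prediction. The `lesion_site` column is a manual
#' cortical/subcortical judgement from the MRI report text.
#'
#' @return data frame with one row per patient.
#' @export
motor_clinical_table <- function() {
  read_clinical_table(system.file("extdata", "table1.csv",
                                  package = "motornet", mustWork = TRUE))
}

#' Read/write clinical tables
#' @param path CSV path with the packaged table's column names.
#' @export
read_clinical_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("dataset", "id", "fma_pre", "fma_post", "tempa_pre",
            "tempa_post", "wmft_pre", "wmft_post", "true_condition")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("clinical table lacks columns: ",
                            paste(missing, collapse = ", "))
  tab
}

#' @rdname read_clinical_table
#' @param table clinical data frame.
#' @export
write_clinical_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Per-variable cohort statistics between two groups
#'
#' For each numeric variable: group means and SDs plus two-sample
#' t-tests — pooled-variance and Welch, one- and two-tailed p-values
#' are all reported. For each categorical variable: per-group counts.
#' Groups with fewer than 2 observations skip the tests with a note.
#'
#' @param table clinical data frame.
#' @param grouping name of the 2-level grouping column.
#' @param numeric_vars,categorical_vars variables to summarize;
#'   defaults cover the packaged schema.
#' @return list `numeric` (data frame), `categorical` (named list of
#'   count tables), `notes`.
#' @export
cohort_stats <- function(table, grouping = "true_condition",
                         numeric_vars = NULL, categorical_vars = NULL) {
  g <- factor(table[[grouping]])
  if (nlevels(g) != 2) stop("grouping must have exactly 2 levels")
  if (is.null(numeric_vars)) {
    cand <- c("age", "time_poststroke", "brunnstrom_proximal",
              "brunnstrom_distal", "fma_pre", "tempa_pre", "wmft_pre",
              "fma_improvement", "tempa_improvement", "wmft_improvement")
    derived <- paste0(c("fma", "tempa", "wmft"), "_improvement")
    numeric_vars <- cand[cand %in% names(table) | cand %in% derived]
  }
  if (is.null(categorical_vars)) {
    categorical_vars <- intersect(
      c("gender", "affected_hemisphere", "lesion_site", "stroke_type",
        "hand_dominance"), names(table))
  }
  tab <- table
  for (sc in c("fma", "tempa", "wmft")) {
    imp <- paste0(sc, "_improvement")
    pre <- paste0(sc, "_pre"); post <- paste0(sc, "_post")
    if (!imp %in% names(tab) && all(c(pre, post) %in% names(tab)))
      tab[[imp]] <- tab[[post]] - tab[[pre]]
  }
  numeric_vars <- intersect(numeric_vars, names(tab))
  notes <- character()
  rows <- lapply(numeric_vars, function(v) {
    x <- split(tab[[v]], g)
    out <- data.frame(variable = v,
                      group1 = levels(g)[1], mean1 = mean(x[[1]]), sd1 = sd(x[[1]]), n1 = length(x[[1]]),
                      group2 = levels(g)[2], mean2 = mean(x[[2]]), sd2 = sd(x[[2]]), n2 = length(x[[2]]),
                      p_pooled_two = NA_real_, p_pooled_one = NA_real_,
                      p_welch_two = NA_real_, p_welch_one = NA_real_,
                      stringsAsFactors = FALSE)
    if (any(lengths(x) < 2)) {
      notes <<- c(notes, paste0(v, ": a group has n < 2; tests skipped"))
      return(out)
    }
    if (sd(x[[1]]) == 0 && sd(x[[2]]) == 0 &&
        mean(x[[1]]) == mean(x[[2]])) {
      out[, c("p_pooled_two", "p_pooled_one", "p_welch_two",
              "p_welch_one")] <- c(1, 0.5, 1, 0.5)
      return(out)
    }
    tp <- t.test(x[[1]], x[[2]], var.equal = TRUE)
    tw <- t.test(x[[1]], x[[2]], var.equal = FALSE)
    out$p_pooled_two <- tp$p.value
    out$p_pooled_one <- tp$p.value / 2
    out$p_welch_two <- tw$p.value
    out$p_welch_one <- tw$p.value / 2
    out
  })
  cats <- lapply(categorical_vars, function(v) table(tab[[v]], g))
  names(cats) <- categorical_vars
  list(numeric = do.call(rbind, rows), categorical = cats, notes = notes)
}

#' Mean and SD of score improvement over a selection
#'
#' @param table clinical data frame.
#' @param scale `"fma"`, `"tempa"` or `"wmft"`.
#' @param dataset optional filter on the `dataset` column.
#' @param condition optional filter on `true_condition`.
#' @return list `mean`, `sd`, `n`.
#' @export
improvement_summary <- function(table, scale = c("fma", "tempa", "wmft"),
                                dataset = NULL, condition = NULL) {
  scale <- match.arg(scale)
  keep <- rep(TRUE, nrow(table))
  if (!is.null(dataset)) keep <- keep & table$dataset %in% dataset
  if (!is.null(condition)) keep <- keep & table$true_condition %in% condition
  if (!any(keep)) stop("empty selection")
  d <- table[[paste0(scale, "_post")]][keep] -
    table[[paste0(scale, "_pre")]][keep]
  list(mean = mean(d), sd = sd(d), n = sum(keep))
}

#' Prediction accuracy within clinical subgroups
#'
#' Partitions rows by a clinical variable — numeric bins given as a
#' list of `c(lo, hi)` ranges (inclusive), or the levels of a
#' categorical column — and reports per-bin n, correct count and
#' accuracy of the recorded predictions.
#'
#' @param table clinical data frame with `prediction` and
#'   `true_condition` filled in.
#' @param variable column name.
#' @param bins list of named `c(lo, hi)` ranges for numeric variables;
#'   `NULL` for categorical (one bin per level).
#' @return data frame `bin`, `n`, `n_correct`, `accuracy` (percent;
#'   `NA` for empty bins).
#' @export
subgroup_accuracy <- function(table, variable, bins = NULL) {
  if (!all(c("prediction", "true_condition") %in% names(table)))
    stop("table must carry prediction and true_condition")
  tab <- table[!is.na(table$prediction) & table$prediction != "", ]
  correct <- tab$prediction == tab$true_condition
  x <- tab[[variable]]
  if (is.null(bins)) {
    levs <- sort(unique(x))
    rows <- lapply(levs, function(l) {
      inb <- x == l
      data.frame(bin = as.character(l), n = sum(inb),
                 n_correct = sum(correct[inb]),
                 accuracy = if (sum(inb)) 100 * mean(correct[inb]) else NA_real_,
                 stringsAsFactors = FALSE)
    })
  } else {
    nm <- names(bins)
    if (is.null(nm)) nm <- vapply(bins, function(b)
      paste0("[", b[1], ",", b[2], "]"), character(1))
    rows <- lapply(seq_along(bins), function(i) {
      b <- bins[[i]]
      inb <- x >= b[1] & x <= b[2]
      data.frame(bin = nm[i], n = sum(inb), n_correct = sum(correct[inb]),
                 accuracy = if (sum(inb)) 100 * mean(correct[inb]) else NA_real_,
                 stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, rows)
}

#' One-way ANOVA of each feature across outcome groups
#'
#' Per feature: F statistic and p-value of a one-way ANOVA across the
#' two outcome groups, with no multiple-testing correction by default
#' (a `p.adjust` method can be requested).
#'
#' @param X feature matrix (subjects x features).
#' @param labels binary outcome labels.
#' @param adjust `p.adjust` method, default `"none"`.
#' @return data frame `feature`, `F`, `p`, `p_adjusted`,
#'   `zero_variance` flag.
#' @export
anova_features <- function(X, labels, adjust = "none") {
  g <- factor(labels)
  if (min(table(g)) < 2) stop("need at least 2 subjects per class")
  rows <- lapply(colnames(X), function(f) {
    x <- X[, f]
    zv <- all(vapply(split(x, g), function(v) var(v) == 0, logical(1)))
    if (zv) {
      return(data.frame(feature = f, F = NA_real_, p = NA_real_,
                        zero_variance = TRUE, stringsAsFactors = FALSE))
    }
    a <- stats::anova(stats::aov(x ~ g))
    data.frame(feature = f, F = a$`F value`[1], p = a$`Pr(>F)`[1],
               zero_variance = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  out
}

#' Mean spectral difference between two sources
#'
#' Per subject, the mean over frequencies and time of
#' `power_a - power_b` in baseline-corrected percent-power units; the
#' group statistic is a paired t-test across subjects.
#'
#' @param specs list of [source_spectrogram()]s, one per subject; both
#'   sources must be present in each.
#' @param source_a,source_b source labels.
#' @return list `msd` (per subject), `mean_msd`, `t`, `p` (`t`, `p`
#'   `NA` for a single subject).
#' @export
spectral_difference <- function(specs, source_a, source_b) {
  msd <- vapply(specs, function(sp) {
    ia <- match(source_a, sp$source_labels)
    ib <- match(source_b, sp$source_labels)
    if (is.na(ia) || is.na(ib)) stop("source not present in every subject")
    mean(sp$power[ia, , ] - sp$power[ib, , ])
  }, numeric(1))
  if (length(msd) < 2) {
    return(list(msd = msd, mean_msd = mean(msd), t = NA_real_, p = NA_real_))
  }
  tt <- t.test(msd)
  list(msd = msd, mean_msd = mean(msd), t = unname(tt$statistic),
       p = tt$p.value)
}
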