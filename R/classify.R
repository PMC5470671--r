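as_binary_labels <- function(y, positive = "F") {
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("labels must be binary (got ",
                             paste(lev, collapse = ", "), ")")
  if (!positive %in% lev) positive <- lev[2]
  list(y01 = as.integer(y == positive), positive = positive,
       negative = setdiff(lev, positive))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit on standardized features with an
#' optional ridge penalty (intercept unpenalized; standardization
#' parameters are estimated from the training data and stored in the
#' model). Perfect separation without a penalty is detected
#' (diverging coefficients) and a ridge fallback applied with a flag.
#'
#' @param X numeric feature matrix (rows = subjects).
#' @param y binary labels; `positive` names the class coded 1
#'   (favorable).
#' @param regularization ridge strength on standardized features.
#' @param positive positive-class label.
#' @param max_iter,tol IRLS controls.
#' @return object of class `logit_model`: `coefficients` (intercept
#'   first, standardized scale), `se`, `p_values` (Wald),
#'   `selected_features`, `center`, `scale`, `separation_flag`.
#' @export
fit_logistic <- function(X, y, regularization = 0, positive = "F",
                         max_iter = 100L, tol = 1e-10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  lab <- as_binary_labels(y, positive)
  if (min(table(lab$y01)) < 2) stop("need at least 2 samples per class")
  if (anyNA(X)) stop("missing values in features")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- cbind(`(Intercept)` = 1, sweep(sweep(X, 2, ctr), 2, scl, "/"))
  pen <- c(0, rep(regularization, ncol(X)))

  irls <- function(lambda) {
    beta <- numeric(ncol(Xs))
    sep <- FALSE
    info <- NULL
    for (it in seq_len(max_iter)) {
      eta <- as.numeric(Xs %*% beta)
      mu <- 1 / (1 + exp(-eta))
      wv <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (lab$y01 - mu) / wv
      info <- crossprod(Xs * sqrt(wv)) + diag(c(0, rep(lambda, ncol(X))),
                                              ncol(Xs))
      new <- tryCatch(solve(info, crossprod(Xs, wv * z)),
                      error = function(e) NULL)
      if (is.null(new)) return(NULL)
      new <- as.numeric(new)
      if (max(abs(new)) > 30 && lambda == 0) { sep <- TRUE }
      if (max(abs(new - beta)) < tol) { beta <- new; break }
      beta <- new
      if (sep) break
    }
    list(beta = beta, info = info, separated = sep)
  }

  fit <- irls(regularization)
  separation_flag <- FALSE
  lambda_used <- regularization
  if (is.null(fit) || fit$separated) {
    separation_flag <- TRUE
    lambda_used <- max(regularization, 1)
    fit <- irls(lambda_used)
    if (is.null(fit)) stop("logistic fit failed even with ridge fallback")
  }
  covb <- tryCatch(solve(fit$info), error = function(e) MASS::ginv(fit$info))
  se <- sqrt(pmax(diag(covb), 0))
  zstat <- fit$beta / se
  pv <- 2 * pnorm(-abs(zstat))
  nm <- c("(Intercept)", colnames(X))
  structure(list(coefficients = setNames(fit$beta, nm),
                 se = setNames(se, nm), p_values = setNames(pv, nm),
                 selected_features = colnames(X),
                 center = ctr, scale = scl,
                 regularization = lambda_used,
                 separation_flag = separation_flag,
                 positive = lab$positive, negative = lab$negative),
            class = "logit_model")
}

#' @export
predict.logit_model <- function(object, newdata,
                                type = c("label", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (is.null(colnames(X)) && ncol(X) == length(object$selected_features))
    colnames(X) <- object$selected_features
  X <- X[, object$selected_features, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$center[object$selected_features]), 2,
              object$scale[object$selected_features], "/")
  eta <- object$coefficients[1] +
    as.numeric(Xs %*% object$coefficients[-1])
  prob <- 1 / (1 + exp(-eta))
  if (type == "prob") return(prob)
  ifelse(prob >= 0.5, object$positive, object$negative)
}

#' Repeated stratified k-fold cross-validated accuracy
#'
#' Stratified folds (each class shuffled and dealt round-robin),
#' repeated with reshuffling; standardization and fitting happen inside
#' each training fold only. Reports mean and SD of the per-repetition
#' mean accuracies, in percent.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param k folds (default 5).
#' @param repeats repetitions (default 100).
#' @param seed RNG seed.
#' @param regularization ridge strength passed to [fit_logistic()].
#' @param positive positive-class label.
#' @return object of class `cv_report`: `mean_accuracy`, `sd_accuracy`
#'   (percent), `per_repetition`, `seed`, `k`, `repeats`.
#' @export
crossval_accuracy <- function(X, y, k = 5L, repeats = 100L, seed = 1L,
                              regularization = 1, positive = "F") {
  X <- as.matrix(X)
  y <- as.character(y)
  if (k < 2) stop("k must be at least 2")
  if (nrow(X) < k) stop("need at least k samples")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(X)
  per_rep <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold <- integer(n)
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      te <- !tr
      if (!any(te)) next
      m <- fit_logistic(X[tr, , drop = FALSE], y[tr],
                        regularization = regularization,
                        positive = positive)
      pred <- predict(m, X[te, , drop = FALSE])
      correct <- correct + sum(pred == y[te])
    }
    per_rep[r] <- 100 * correct / n
  }
  structure(list(mean_accuracy = mean(per_rep), sd_accuracy = sd(per_rep),
                 per_repetition = per_rep, seed = seed, k = k,
                 repeats = repeats),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold x %d repeats: %.1f%% +/- %.1f%%\n",
              x$k, x$repeats, x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

#' Accuracy of every frequency-band combination
#'
#' Evaluates all non-empty subsets of the bands (15 for four bands) by
#' restricting the feature matrix to attributes of those bands and
#' cross-validating each subset.
#'
#' @param X feature matrix from [feature_matrix()] (carries the `band`
#'   attribute), or any matrix plus an explicit `band` vector.
#' @param y binary labels.
#' @param bands a [band_scheme()].
#' @param band column band labels; defaults to `attr(X, "band")`.
#' @inheritParams crossval_accuracy
#' @return data frame `combination`, `n_features`, `mean_accuracy`,
#'   `sd_accuracy`, sorted by decreasing mean accuracy.
#' @export
band_combination_search <- function(X, y, bands = band_scheme(),
                                    band = attr(X, "band"),
                                    k = 5L, repeats = 20L, seed = 1L,
                                    regularization = 1, positive = "F") {
  if (is.null(band)) stop("X carries no band attribute; pass `band`")
  bn <- names(bands)
  combos <- unlist(lapply(seq_along(bn), function(m)
    combn(bn, m, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(seq_along(combos), function(i) {
    keep <- band %in% combos[[i]]
    cv <- crossval_accuracy(X[, keep, drop = FALSE], y, k = k,
                            repeats = repeats, seed = seed + i,
                            regularization = regularization,
                            positive = positive)
    data.frame(combination = paste(combos[[i]], collapse = "+"),
               n_features = sum(keep),
               mean_accuracy = cv$mean_accuracy,
               sd_accuracy = cv$sd_accuracy, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean_accuracy), ]
}

#' Backward elimination of non-significant features
#'
#' Iteratively refits the logistic model and removes the feature with
#' the largest Wald p-value while that p-value exceeds `alpha`,
#' stopping when all remaining features are significant or one feature
#' remains. Ties on the p-value are broken by removing the feature
#' latest in name order (so the earliest name survives).
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param alpha significance level (default 0.05).
#' @param regularization ridge strength for the refits.
#' @param positive positive-class label.
#' @return list `model` (final [fit_logistic()] fit), `removed` (data
#'   frame `feature`, `p_value` in removal order), `retained`.
#' @export
backward_eliminate <- function(X, y, alpha = 0.05, regularization = 1,
                               positive = "F") {
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("starting feature set is empty")
  current <- colnames(X)
  trace <- list()
  repeat {
    m <- tryCatch(
      fit_logistic(X[, current, drop = FALSE], y,
                   regularization = regularization, positive = positive),
      error = function(e) NULL)
    if (is.null(m)) {
      # non-convergent refit: drop the last feature and flag it
      drop <- current[length(current)]
      trace[[length(trace) + 1]] <- data.frame(feature = drop,
                                               p_value = NA_real_,
                                               stringsAsFactors = FALSE)
      current <- setdiff(current, drop)
      if (length(current) <= 1) break
      next
    }
    pv <- m$p_values[-1]
    if (length(current) <= 1 || max(pv) <= alpha) break
    worst <- which(pv >= max(pv) - 1e-9) # numerical ties count as ties
    drop <- names(pv)[worst[order(names(pv)[worst],
                                  decreasing = TRUE)[1]]]
    trace[[length(trace) + 1]] <- data.frame(feature = drop,
                                             p_value = unname(max(pv)),
                                             stringsAsFactors = FALSE)
    current <- setdiff(current, drop)
  }
  model <- fit_logistic(X[, current, drop = FALSE], y,
                        regularization = regularization,
                        positive = positive)
  removed <- if (length(trace)) do.call(rbind, trace)
             else data.frame(feature = character(), p_value = numeric())
  list(model = model, removed = removed, retained = current)
}

#' Confusion-matrix validation metrics
#'
#' Counts with favorable as the positive class; sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive value
#' `TP/(TP+FP)` and accuracy `(TP+TN)/n`, all in percent at full
#' precision (the print method rounds to 1 decimal). A zero denominator
#' yields `NA` (not applicable), never 0.
#'
#' @param predicted,truth equal-length binary label vectors.
#' @param positive positive-class label (favorable).
#' @return object of class `validation_report`.
#' @export
evaluate <- function(predicted, truth, positive = "F") {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) == 0) stop("empty input")
  if (length(predicted) != length(truth)) stop("length mismatch")
  tp <- sum(predicted == positive & truth == positive)
  fp <- sum(predicted == positive & truth != positive)
  fn <- sum(predicted != positive & truth == positive)
  tn <- sum(predicted != positive & truth != positive)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(list(counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 positive_predictive_value = ratio(tp, tp + fp),
                 accuracy = ratio(tp + tn, length(truth)),
                 n = length(truth), positive = positive),
            class = "validation_report")
}

#' Round half away from zero (display convention for percentages)
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> counts:",
      paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  fmt <- function(v) if (is.na(v)) "n/a" else
    sprintf("%.1f%%", round_half_up(v, 1))
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s  accuracy %s\n",
              fmt(x$sensitivity), fmt(x$specificity),
              fmt(x$positive_predictive_value), fmt(x$accuracy)))
  invisible(x)
}

#' Best dichotomous cutoff on a single clinical variable
#'
#' Exhaustive scan over midpoints between sorted unique values, in both
#' orientations (high predicts favorable, or low predicts favorable);
#' returns the cutoff maximizing accuracy, ties resolved toward the
#' smallest cutoff.
#'
#' @param variable numeric vector, one value per subject.
#' @param y binary labels.
#' @param positive positive-class label.
#' @return list `cutoff`, `orientation` (`">="` means
#'   `variable >= cutoff` predicts favorable), `accuracy` (percent),
#'   `constant_flag`.
#' @export
dichotomous_cutoff <- function(variable, y, positive = "F") {
  lab <- as_binary_labels(y, positive)
  u <- sort(unique(variable))
  if (length(u) < 2) {
    maj <- max(mean(lab$y01), 1 - mean(lab$y01))
    return(list(cutoff = NA_real_, orientation = NA_character_,
                accuracy = 100 * maj, constant_flag = TRUE))
  }
  cuts <- (head(u, -1) + u[-1]) / 2
  best <- list(accuracy = -Inf)
  for (cut in cuts) for (orient in c(">=", "<=")) {
    pred <- if (orient == ">=") variable >= cut else variable <= cut
    acc <- 100 * mean(pred == (lab$y01 == 1))
    if (acc > best$accuracy + 1e-12) {
      best <- list(cutoff = cut, orientation = orient, accuracy = acc,
                   constant_flag = FALSE)
    }
  }
  best
}
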