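test_that("outcome labeling follows the 10%-of-maximum rule with >= boundaries", {
  tab <- motor_clinical_table()
  # training patient 1: FMA 23 -> 37 is favorable
  expect_equal(label_outcome(tab[tab$dataset == "training" & tab$id == 1, ]),
               "F")
  rec0 <- list(fma_pre = 30, fma_post = 30, wmft_pre = 40, wmft_post = 40,
               tempa_pre = -50, tempa_post = -50)
  expect_equal(label_outcome(rec0), "P")
  # exactly at a threshold counts as favorable
  recb <- rec0; recb$fma_post <- 36.6
  expect_equal(label_outcome(recb), "F")
  recw <- rec0; recw$wmft_post <- 47.5
  expect_equal(label_outcome(recw), "F")
  rect <- rec0; rect$tempa_post <- -33.8
  expect_equal(label_outcome(rect), "F")
  recna <- rec0; recna$fma_post <- NA
  expect_error(label_outcome(recna), "missing")
  # monotonicity: raising any post score never flips favorable -> poor
  set.seed(1)
  for (i in 1:25) {
    rec <- list(fma_pre = runif(1, 5, 60), wmft_pre = runif(1, 10, 70),
                tempa_pre = runif(1, -100, -10))
    rec$fma_post <- rec$fma_pre + runif(1, -2, 12)
    rec$wmft_post <- rec$wmft_pre + runif(1, -2, 12)
    rec$tempa_post <- rec$tempa_pre + runif(1, -5, 20)
    l1 <- label_outcome(rec)
    rec$fma_post <- rec$fma_post + runif(1, 0, 10)
    l2 <- label_outcome(rec)
    expect_false(l1 == "F" && l2 == "P")
  }
})

test_that("re-applying the rule to the packaged table flags only the two known label discrepancies", {
  tab <- label_table(motor_clinical_table())
  disc <- tab[tab$label_discrepancy, ]
  expect_equal(nrow(disc), 2L)
  expect_equal(disc$dataset, c("training", "training"))
  expect_equal(sort(disc$id), c(31L, 36L))
  # both are labeled poor although WMFT improvement reaches 7.5
  expect_true(all(disc$true_condition == "P"))
  expect_true(all(disc$wmft_post - disc$wmft_pre >= 7.5))
})

test_that("cohort statistics reproduce the training-group contrasts and a manual t oracle", {
  tab <- motor_clinical_table()
  training <- tab[tab$dataset == "training", ]
  st <- cohort_stats(training)
  tp <- st$numeric[st$numeric$variable == "time_poststroke", ]
  # favorable first (level order F, P)
  expect_equal(tp$mean1, 5.10, tolerance = 0.005)
  expect_equal(tp$mean2, 8.22, tolerance = 0.005)
  expect_equal(tp$sd1, 4.63, tolerance = 0.005)
  expect_equal(tp$sd2, 5.39, tolerance = 0.005)
  # the printed p = .03 is the one-tailed pooled test (2 decimals)
  expect_equal(round(tp$p_pooled_one, 2), 0.03)
  # identical groups -> p = 1 two-tailed
  same <- data.frame(true_condition = rep(c("F", "P"), each = 3),
                     age = rep(c(50, 60, 70), 2),
                     fma_pre = 1, fma_post = 1, tempa_pre = -1,
                     tempa_post = -1, wmft_pre = 1, wmft_post = 1)
  st2 <- cohort_stats(same, numeric_vars = "age")
  expect_equal(st2$numeric$p_pooled_two, 1, tolerance = 1e-12)
  # 3 + 3 toy sample against the pooled-variance formula
  toy <- data.frame(true_condition = rep(c("F", "P"), each = 3),
                    age = c(1, 2, 3, 5, 6, 10))
  st3 <- cohort_stats(toy, numeric_vars = "age", categorical_vars = character())
  m1 <- 2; m2 <- 7
  sp2 <- (2 * var(c(1, 2, 3)) + 2 * var(c(5, 6, 10))) / 4
  tstat <- (m1 - m2) / sqrt(sp2 * (2 / 3))
  p_manual <- 2 * stats::pt(-abs(tstat), df = 4)
  expect_equal(st3$numeric$p_pooled_two, p_manual, tolerance = 1e-12)
})

test_that("improvement summaries agree with direct arithmetic on any selection", {
  tab <- motor_clinical_table()
  expect_equal(improvement_summary(tab, "fma", "training", "P")$mean,
               24 / 18, tolerance = 1e-12)
  # pre = post everywhere -> 0 +/- 0
  flat <- data.frame(dataset = "training", true_condition = "F",
                     fma_pre = c(10, 20), fma_post = c(10, 20),
                     tempa_pre = -5, tempa_post = -5,
                     wmft_pre = 3, wmft_post = 3, id = 1:2)
  s <- improvement_summary(flat, "fma")
  expect_equal(s$mean, 0)
  expect_equal(s$sd, 0)
  # arbitrary selection against a direct oracle
  v <- improvement_summary(tab, "wmft", "validation")
  d <- tab$wmft_post[tab$dataset == "validation"] -
    tab$wmft_pre[tab$dataset == "validation"]
  expect_equal(v$mean, mean(d), tolerance = 1e-12)
  expect_equal(v$sd, sd(d), tolerance = 1e-12)
  expect_error(improvement_summary(tab, "fma", dataset = "nope"), "empty")
})

test_that("subgroup accuracies match the validation predictions and an exhaustive filter", {
  val <- motor_clinical_table()
  val <- val[val$dataset == "validation", ]
  overall <- subgroup_accuracy(val, "time_poststroke",
                               bins = list(all = c(-Inf, Inf)))
  expect_equal(overall$n, 16L)
  expect_equal(overall$n_correct, 13L)
  # under the stated 1-6 / 7-12 / >12 binning the recorded times give
  # bins of 4, 8 and 4 patients (one 7-month patient sits in the middle
  # bin); accuracies follow from the three recorded misclassifications
  tsb <- subgroup_accuracy(val, "time_poststroke",
                           bins = list(`1-6` = c(1, 6), `7-12` = c(7, 12),
                                       `>12` = c(13, Inf)))
  expect_equal(tsb$n, c(4L, 8L, 4L))
  expect_equal(tsb$accuracy, c(100, 87.5, 50), tolerance = 1e-9)
  # the <= 9 / > 9 month split is consistent with the recorded times
  t9 <- subgroup_accuracy(val, "time_poststroke",
                          bins = list(le9 = c(-Inf, 9), gt9 = c(10, Inf)))
  expect_equal(t9$n, c(10L, 6L))
  expect_equal(t9$n_correct, c(9L, 4L))
  lesion <- subgroup_accuracy(val, "lesion_site")
  expect_equal(lesion$accuracy[lesion$bin == "subcortical"], 100)
  expect_equal(lesion$n[lesion$bin == "subcortical"], 12L)
  expect_equal(lesion$accuracy[lesion$bin == "cortical"], 25)
  wm <- subgroup_accuracy(val, "wmft_pre",
                          bins = list(le45 = c(-Inf, 45), gt45 = c(45.5, Inf)))
  expect_equal(wm$n, c(4L, 12L))
  expect_equal(round(wm$accuracy), c(50, 92))
  # all-correct table: every bin 100%
  allc <- val
  allc$prediction <- allc$true_condition
  acc <- subgroup_accuracy(allc, "lesion_site")
  expect_true(all(acc$accuracy == 100))
  # random toy table against exhaustive filtering
  set.seed(3)
  toy <- data.frame(x = sample(1:5, 40, TRUE),
                    prediction = sample(c("F", "P"), 40, TRUE),
                    true_condition = sample(c("F", "P"), 40, TRUE))
  sg <- subgroup_accuracy(toy, "x", bins = list(lo = c(1, 2), hi = c(3, 5)))
  lo <- toy[toy$x <= 2, ]
  expect_equal(sg$n[1], nrow(lo))
  expect_equal(sg$n_correct[1], sum(lo$prediction == lo$true_condition))
  # empty bin reported with n = 0
  e <- subgroup_accuracy(toy, "x", bins = list(none = c(90, 99)))
  expect_equal(e$n, 0L)
  expect_true(is.na(e$accuracy))
})

test_that("feature ANOVA: two-group F equals squared t, strong effects are tiny p", {
  set.seed(4)
  g <- rep(c("F", "P"), each = 10)
  X <- cbind(shift = c(rnorm(10, 0, 0.01), rnorm(10, 5, 0.01)),
             flat = rnorm(20))
  out <- anova_features(X, g)
  expect_lt(out$p[out$feature == "shift"], 1e-6)
  tt <- t.test(X[g == "F", "flat"], X[g == "P", "flat"], var.equal = TRUE)
  expect_equal(out$F[out$feature == "flat"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(out$p[out$feature == "flat"], tt$p.value, tolerance = 1e-10)
  # null simulation: p-values roughly uniform
  set.seed(5)
  Xn <- matrix(rnorm(40 * 200), 40, 200,
               dimnames = list(NULL, paste0("f", 1:200)))
  outn <- anova_features(Xn, rep(c("F", "P"), each = 20))
  expect_gt(mean(outn$p < 0.05), 0.005)
  expect_lt(mean(outn$p < 0.05), 0.12)
  # zero-variance flag
  Xz <- cbind(z = rep(1, 20))
  outz <- anova_features(Xz, g)
  expect_true(outz$zero_variance)
  expect_true(is.na(outz$p))
})

test_that("mean spectral difference is exact for constant offsets and matches manual computation", {
  labels <- default_source_set()$label
  freqs <- c(6, 11.5, 22.5, 39)
  times <- seq(-500, 800, by = 100)
  mk <- function(pw) source_spectrogram(pw, freqs, times, labels)
  base <- array(rnorm(5 * 4 * length(times)), c(5, 4, length(times)))
  # identical sources -> msd 0
  same <- mk(base)
  r0 <- spectral_difference(list(same, same), "iM1", "iM1")
  expect_equal(r0$mean_msd, 0)
  # constant offset -> msd equals the offset exactly
  off <- base
  off[4, , ] <- base[2, , ] - 12.5 # iPM = iM1 - 12.5
  so <- mk(off)
  r1 <- spectral_difference(list(so), "iM1", "iPM")
  expect_equal(unname(r1$msd), 12.5, tolerance = 1e-12)
  expect_true(is.na(r1$t))
  # 4 subjects against manual computation
  set.seed(6)
  specs <- lapply(1:4, function(i)
    mk(array(rnorm(5 * 4 * length(times)), c(5, 4, length(times)))))
  r2 <- spectral_difference(specs, "cM1", "cPM")
  manual <- vapply(specs, function(sp)
    mean(sp$power["cM1", , ] - sp$power["cPM", , ]), numeric(1))
  expect_equal(unname(r2$msd), manual, tolerance = 1e-12)
  tt <- t.test(manual)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-12)
})
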