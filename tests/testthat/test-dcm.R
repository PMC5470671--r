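test_that("the model space has the documented structure", {
  ms <- build_model_space()
  expect_length(ms, 7)
  expect_equal(nrow(ms$DCM1$edges), 18L)
  expect_true(all(ms$DCM1$edges$nonlinear))
  # the all-linear model has no cross-frequency terms anywhere
  expect_equal(sum(ms$all_linear$edges$nonlinear), 0L)
  expect_false(ms$all_linear$intrinsic_nonlinear)
  expect_equal(nrow(ms$all_linear$edges), 18L)
  # every model's edge set is a subset of DCM1's
  full_ids <- motornet:::edge_ids(ms$DCM1$edges)
  for (m in ms) {
    expect_true(all(motornet:::edge_ids(m$edges) %in% full_ids))
  }
  # reduced variants drop one reciprocal pair
  expect_equal(nrow(ms$DCM4$edges), 16L)
  expect_error(model_spec("bad", data.frame(a = "SMA", b = "Oz")),
               "subset")
})

test_that("mode reduction is lossless with a full basis and matches an SVD oracle", {
  set.seed(8)
  pw <- array(rnorm(5 * 6 * 10), c(5, 6, 10))
  spec <- source_spectrogram(pw, seq(5, 30, by = 5), seq(0, 900, by = 100),
                             default_source_set()$label)
  full <- reduce_to_modes(spec, 6)
  X <- matrix(aperm(pw, c(2, 1, 3)), nrow = 6)
  recon <- full$projector %*% (t(full$projector) %*% X)
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_equal(full$energy_retained, 1, tolerance = 1e-12)
  # rank-1 spectrogram: one mode suffices
  r1 <- outer(1:6, rnorm(50))
  pw1 <- aperm(array(r1, c(6, 5, 10)), c(2, 1, 3))
  spec1 <- source_spectrogram(pw1, 1:6 * 5, seq(0, 900, by = 100),
                              default_source_set()$label)
  red1 <- reduce_to_modes(spec1, 1)
  expect_lt(red1$reconstruction_error, 1e-12)
  # retained energy equals the direct-SVD cumulative energy
  sv <- svd(X)$d
  for (m in 1:5) {
    expect_equal(reduce_to_modes(spec, m)$energy_retained,
                 sum(sv[1:m]^2) / sum(sv^2), tolerance = 1e-12)
  }
  expect_error(reduce_to_modes(spec, 0), "n_modes")
  expect_error(reduce_to_modes(spec, 7), "exceed")
})

test_that("masking an edge equals removing it; cross-frequency coupling moves power across bands", {
  ms <- build_model_space()
  set.seed(12)
  p_full <- random_coupling(ms$DCM1)
  # zero one edge's matrix vs dropping the pair entirely, with the
  # reciprocal edge also zeroed to keep architectures comparable
  pair_drop <- motor_pairs()[-8, ] # drop iPM-cM1
  m_red <- model_spec("red", pair_drop, TRUE, TRUE)
  p_mask <- p_full
  p_mask$A[["iPM->cM1"]][] <- 0
  p_mask$A[["cM1->iPM"]][] <- 0
  p_red <- coupling_params(m_red)
  for (id in names(p_red$A)) p_red$A[[id]] <- p_mask$A[[id]]
  p_red$intrinsic <- p_mask$intrinsic
  p_red$C <- p_mask$C
  s1 <- simulate_induced_power(ms$DCM1, p_mask)
  s2 <- simulate_induced_power(m_red, p_red)
  expect_equal(s1$power, s2$power, tolerance = 1e-12)

  # theta -> beta coupling with positive weight raises beta power after
  # theta-only input
  m2 <- model_spec("pair", motor_pairs()[1, , drop = FALSE], TRUE, FALSE)
  base <- coupling_params(m2)
  base$C["SMA", "theta"] <- 100
  with_cf <- base
  with_cf$A[["SMA->cM1"]]["beta", "theta"] <- 0.8
  s_base <- simulate_induced_power(m2, base)
  s_cf <- simulate_induced_power(m2, with_cf)
  beta_cm1 <- function(s) sum(s$power["cM1", 3, ])  # band 3 = beta
  expect_equal(beta_cm1(s_base), 0, tolerance = 1e-10)
  expect_gt(beta_cm1(s_cf), 1)

  # a linear-only model keeps unforced, uncoupled bands at zero power
  m_lin <- model_spec("lin", motor_pairs()[1, , drop = FALSE], FALSE, FALSE)
  p_lin <- coupling_params(m_lin)
  p_lin$C["SMA", "theta"] <- 100
  diag(p_lin$A[["SMA->cM1"]]) <- 0.3
  s_lin <- simulate_induced_power(m_lin, p_lin)
  expect_equal(sum(abs(s_lin$power[, 2:4, ])), 0,
               tolerance = 1e-10)
})

test_that("conformity checks reject cross-frequency terms on linear edges", {
  m_lin <- build_model_space()$all_linear
  p <- coupling_params(m_lin)
  p$A[["SMA->cM1"]]["beta", "theta"] <- 0.5
  expect_error(check_conform(p, m_lin), "cross-frequency")
})

test_that("inversion is self-consistent at zero noise and deterministic", {
  ms <- build_model_space()
  set.seed(3)
  truth <- random_coupling(ms$DCM2, sd_cross = 0.3)
  spec <- simulate_induced_power(ms$DCM2, truth,
                                 times = seq(-500, 800, by = 25))
  fit <- invert_dcm(ms$DCM2, spec, priors = study_priors())
  # posterior mean close to truth in the well-determined directions:
  # predicted trajectories match the data closely
  expect_gt(cor(as.numeric(fit$predicted$power), as.numeric(spec$power)),
            0.999)
  # F at the optimum beats perturbed-parameter evaluations
  th_true <- motornet:::params_to_theta(truth, fit$param_table)
  nz <- th_true != 0 & fit$param_table$kind %in% c("A", "intrinsic")
  expect_gt(cor(th_true[nz], fit$theta[nz]), 0.9)
  fit2 <- invert_dcm(ms$DCM2, spec, priors = study_priors())
  expect_identical(fit$theta, fit2$theta)
  expect_identical(fit$free_energy, fit2$free_energy)
})

test_that("free energy reduces to the residual log-likelihood under infinitely tight priors at truth", {
  ms <- build_model_space()
  model <- ms$all_linear
  # truth at the prior means: couplings 0, intrinsic decay -2, C = 0
  truth <- coupling_params(model)
  spec <- simulate_induced_power(model, truth,
                                 times = seq(-500, 800, by = 50))
  set.seed(4)
  spec$power <- spec$power + array(rnorm(length(spec$power), 0, 1),
                                   dim(spec$power))
  tight <- default_priors(sd_linear = 1e-5, sd_cross = 1e-5,
                          sd_intrinsic = 1e-5, sd_input = 1e-5,
                          sd_logtau = 1e-5)
  fit <- invert_dcm(model, spec, priors = tight)
  # theta pinned to the prior mean
  expect_lt(max(abs(fit$theta - fit$param_table$pm)), 1e-6)
  # manual Gaussian log-likelihood of the residuals, noise profiled
  res <- spec$power - fit$predicted$power
  ll <- 0
  for (s in 1:5) {
    e <- as.numeric(res[s, , ])
    s2 <- fit$sigma2[s]
    ll <- ll - 0.5 * unname(sum(e^2) / s2 + length(e) * log(2 * pi * s2))
  }
  expect_equal(fit$free_energy, ll, tolerance = 1e-3)
  expect_equal(fit$accuracy, ll, tolerance = 1e-6)
})

test_that("an added edge never reduces accuracy, while F penalizes unused structure", {
  ms <- build_model_space()
  dat <- make_dataset(ms$DCM5, seed = 31, noise_frac = 0.05)
  fit_small <- invert_dcm(ms$DCM5, dat$spec, priors = study_priors())
  fit_big <- invert_dcm(ms$DCM2, dat$spec, priors = study_priors())
  # DCM5's edges are a subset of DCM2's; the larger model fits at least
  # as well but carries a complexity penalty for the unused pair
  expect_gte(fit_big$accuracy, fit_small$accuracy - 1)
  expect_gt(fit_small$free_energy, fit_big$free_energy - 3)
})

test_that("inversion recovers generating couplings from moderately noisy data", {
  ms <- build_model_space()
  dat <- make_dataset(ms$DCM1, seed = 1, noise_frac = 0.1)
  fit <- invert_dcm(ms$DCM1, dat$spec, priors = study_priors())
  th_true <- motornet:::params_to_theta(dat$truth, fit$param_table)
  nz <- th_true != 0 & fit$param_table$kind %in% c("A", "intrinsic")
  expect_gt(cor(th_true[nz], fit$theta[nz]), 0.8)
})

test_that("inversion validates its inputs", {
  ms <- build_model_space()
  spec <- simulate_induced_power(ms$all_linear,
                                 coupling_params(ms$all_linear))
  bad <- spec
  bad$frequencies <- 4:48
  bad$power <- array(0, c(5, 45, length(spec$times)))
  expect_error(invert_dcm(ms$all_linear, bad), "one frequency bin")
})
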