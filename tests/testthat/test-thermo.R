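test_that("RNAP occupancy follows the two-state formula", {
  # longhand scalar evaluation
  tp <- thermo_params(P = 1000, eps_P = -5, R = 130, eps_R = -15.3)
  pol <- (1000 / 4.6e6) * exp(5)
  rep_w <- (2 * 130 / 4.6e6) * exp(15.3)
  expect_equal(p_bound(tp), pol / (1 + pol + rep_w), tolerance = 1e-12)

  expect_equal(p_bound(thermo_params(P = 0)), 0)
  # weak promoter, no repressor: p_bound ~ (P/N_NS) e^(-eps_P)
  weak <- thermo_params(P = 10, eps_P = -2, R = 0)
  expect_equal(p_bound(weak), (10 / 4.6e6) * exp(2), tolerance = 1e-4)
  expect_error(thermo_params(N_NS = 0), "N_NS")
})

test_that("occupancy is monotone in repressor and polymerase numbers", {
  R_grid <- seq(0, 1000, by = 100)
  pb_R <- vapply(R_grid, function(R) p_bound(thermo_params(R = R)),
                 numeric(1))
  expect_true(all(diff(pb_R) < 0))
  P_grid <- seq(100, 2000, by = 100)
  pb_P <- vapply(P_grid, function(P) p_bound(thermo_params(P = P)),
                 numeric(1))
  expect_true(all(diff(pb_P) > 0))
  expect_true(all(pb_R >= 0 & pb_R < 1))
})

test_that("simple-repression fold-change matches longhand values and limits", {
  expect_equal(fold_change_simple(0, -15.3), 1)
  expect_equal(fold_change_simple(130, 30), 1, tolerance = 1e-6)
  expect_equal(fold_change_simple(130, -15.3),
               1 / (1 + (260 / 4.6e6) * exp(15.3)), tolerance = 1e-12)
  # partial derivative signs via finite differences
  eps_grid <- seq(-16, -9, by = 0.5)
  expect_true(all(diff(fold_change_simple(130, eps_grid)) > 0))
  R_grid <- c(11, 30, 62, 130, 610, 870)
  fc <- fold_change_simple(R_grid, -13.9)
  expect_true(all(diff(fc) < 0))
  expect_true(all(fc > 0 & fc <= 1))
})

test_that("weak-promoter expression ratio matches the fold-change model", {
  # expression ratio from occupancies vs the closed-form fold-change
  for (P in c(100, 500, 1000)) {
    with_rep <- p_bound(thermo_params(P = P, eps_P = -2.9, R = 130,
                                      eps_R = -13.9))
    without <- p_bound(thermo_params(P = P, eps_P = -2.9, R = 0))
    expect_equal(with_rep / without, fold_change_simple(130, -13.9),
                 tolerance = 0.05)
  }
})

test_that("induction fold-change matches longhand evaluation on a c grid", {
  ap <- allostery_params()  # K_A = 139, K_I = 0.53, eps_AI = 4.5, n = 2
  for (c in c(0, 1, 10, 100, 5000)) {
    a <- (1 + c / 139)^2
    i <- (1 + c / 0.53)^2
    bracket <- a / (a + exp(-4.5) * i)
    expected <- 1 / (1 + bracket * (260 / 4.6e6) * exp(13.9))
    expect_equal(fold_change_induction(c, ap, R = 130, eps_R = -13.9),
                 expected, tolerance = 1e-12)
  }
})

test_that("equal dissociation constants give a flat response", {
  ap <- allostery_params(K_A = 5, K_I = 5)
  fc <- fold_change_induction(c(0, 1, 10, 100, 1e4), ap, R = 130,
                              eps_R = -13.9)
  expect_equal(fc, rep(fc[1], 5), tolerance = 1e-12)
})

test_that("the always-active limit collapses induction onto simple repression", {
  ap <- allostery_params(eps_AI = 60)  # exp(-eps_AI) -> 0
  c_grid <- c(0, 1, 10, 100, 1000)
  expect_equal(fold_change_induction(c_grid, ap, R = 130, eps_R = -13.9),
               rep(fold_change_simple(130, -13.9), 5), tolerance = 1e-9)
})

test_that("phenotypes are the limits and midpoint of the induction curve", {
  ap <- allostery_params()
  ph <- induction_phenotypes(ap, R = 130, eps_R = -13.9)
  expect_equal(ph$leakiness,
               fold_change_induction(1e-9, ap, R = 130, eps_R = -13.9),
               tolerance = 1e-6)
  expect_equal(ph$saturation,
               fold_change_induction(1e9, ap, R = 130, eps_R = -13.9),
               tolerance = 1e-4)
  expect_equal(ph$dynamic_range, ph$saturation - ph$leakiness)
  expect_true(ph$leakiness <= ph$saturation && ph$saturation <= 1)
  # midpoint identity at the EC50
  mid <- (ph$leakiness + ph$saturation) / 2
  expect_equal(fold_change_induction(ph$ec50, ap, R = 130, eps_R = -13.9),
               mid, tolerance = 1e-6 * mid)

  none <- induction_phenotypes(ap, R = 0)
  expect_equal(none$leakiness, 1)
  expect_equal(none$saturation, 1)
  expect_equal(none$dynamic_range, 0)
  flat <- induction_phenotypes(allostery_params(K_A = 5, K_I = 5), R = 130)
  expect_true(is.na(flat$ec50))
})

test_that("EC50 decreases as the binding energy weakens", {
  eps_grid <- seq(-16, -9, by = 1)
  ec50 <- vapply(eps_grid, function(e) {
    induction_phenotypes(allostery_params(), R = 130, eps_R = e)$ec50
  }, numeric(1))
  expect_true(all(diff(ec50) < 0))
})

test_that("fluorescence fold-change normalizes out autofluorescence", {
  expect_equal(fold_change_from_fluorescence(300, 1100, 100), 0.2)
  expect_equal(fold_change_from_fluorescence(100, 1100, 100), 0)
  expect_equal(fold_change_from_fluorescence(1100, 1100, 100), 1)
  expect_error(fold_change_from_fluorescence(300, 100, 200), "exceeds")
})

test_that("titration fitting recovers a noiseless binding energy exactly", {
  tit <- make_titration(-13.9, noise_cv = 0)
  fit <- fit_binding_energy(tit)
  expect_equal(fit$estimate, -13.9, tolerance = 1e-6)
  expect_lte(fit$ci_low, fit$estimate)
  expect_gte(fit$ci_high, fit$estimate)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
  td <- tidy(fit)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_identical(td$term, "eps_R")
  expect_equal(td$estimate, fit$estimate)
  expect_identical(glance(fit)$n_points, 6L)
})

test_that("a single titration point inverts the model algebraically", {
  fit <- fit_binding_energy(data.frame(R = 130, fold_change = 0.5))
  # closed form: fc = 1/(1 + (2R/N) e^(-eps)) at fc = 0.5
  expect_equal(fit$estimate, -log(4.6e6 / 260), tolerance = 1e-12)
  expect_identical(fit$n_points, 1L)
  expect_error(fit_binding_energy(data.frame(R = 0, fold_change = 1)),
               "unidentifiable")
})

test_that("noisy titrations give nearly unbiased energy estimates", {
  ests <- vapply(1:200, function(i) {
    tit <- make_titration(-13.9, noise_cv = 0.1, seed = i)
    fit_binding_energy(tit)$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests) + 13.9), 0.2)
})
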