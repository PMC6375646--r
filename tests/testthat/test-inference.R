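test_that("replicate splitting is disjoint, equal-sized and seeded", {
  recs <- tibble::tibble(sequence = random_seqs(10, 21, seed = 31),
                         bin = rep(0:1, 5), count = 1L)
  ds <- sortseq_dataset(recs, n_bins = 4, ref_seq = O1)
  parts <- split_replicates(ds, k = 3, seed = 9)
  expect_identical(sort(vapply(parts, nrow, integer(1))), c(3L, 3L, 4L))
  all_seqs <- unlist(lapply(parts, function(p) p$sequence))
  expect_setequal(all_seqs, ds$sequence)
  expect_identical(length(all_seqs), 10L)
  again <- split_replicates(ds, k = 3, seed = 9)
  expect_identical(lapply(parts, as.data.frame),
                   lapply(again, as.data.frame))

  nine <- sortseq_dataset(recs[1:9, ], n_bins = 4, ref_seq = O1)
  expect_identical(vapply(split_replicates(nine, 3, 1), nrow, integer(1)),
                   rep(3L, 3))
})

test_that("dataset TSV round-trips and rejects malformed rows", {
  sim <- default_simulation(n_variants = 500, seed = 60)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sortseq_tsv(sim$dataset, path)
  back <- read_sortseq_tsv(path)
  expect_identical(as.data.frame(back), as.data.frame(sim$dataset))
  expect_identical(attr(back, "ref_seq"), O1)
  expect_identical(attr(back, "n_bins"), 4L)

  lines <- readLines(path)
  lines[5] <- "AATT\t1"
  writeLines(lines, path)
  expect_error(read_sortseq_tsv(path), "line 5")

  expect_error(sortseq_dataset(tibble::tibble(sequence = O1, bin = 7L,
                                              count = 1L),
                               n_bins = 4, ref_seq = O1), "\\[0, 4\\)")
})

test_that("the sampler recovers a known matrix from simulated sorting", {
  sim <- default_simulation(seed = 42)
  post <- mcmc_infer_matrix(sim$dataset,
                            mcmc_config(n_iterations = 1500,
                                        n_burnin = 750, seed = 7))
  expect_gte(compare_matrices(post$mean_matrix, sim$truth), 0.9)
  expect_gt(post$acceptance_rate, 0)
  expect_lt(post$acceptance_rate, 1)
  expect_identical(attr(post$mean_matrix, "gauge"), "reference")
  # orientation + unit normalization: mean non-reference entry is 1
  ref_idx <- sortseqthermo:::encode_seqs(O1)[1, ]
  nonref <- matrix(TRUE, 21, 4)
  nonref[cbind(1:21, ref_idx)] <- FALSE
  expect_equal(mean(unclass(post$mean_matrix)[nonref]), 1,
               tolerance = 1e-9)
})

test_that("chains are reproducible and seed-robust", {
  sim <- default_simulation(n_variants = 4000, seed = 43)
  cfg <- mcmc_config(n_iterations = 800, n_burnin = 400, seed = 11)
  p1 <- mcmc_infer_matrix(sim$dataset, cfg)
  p2 <- mcmc_infer_matrix(sim$dataset, cfg)
  expect_identical(unclass(p1$mean_matrix), unclass(p2$mean_matrix))
  p3 <- mcmc_infer_matrix(sim$dataset,
                          mcmc_config(n_iterations = 800, n_burnin = 400,
                                      seed = 222))
  expect_gte(compare_matrices(p1$mean_matrix, p3$mean_matrix), 0.95)
})

test_that("replicate matrices from one experiment agree", {
  sim <- default_simulation(seed = 42)
  parts <- split_replicates(sim$dataset, k = 3, seed = 5)
  mats <- lapply(seq_along(parts), function(i) {
    mcmc_infer_matrix(parts[[i]],
                      mcmc_config(n_iterations = 1200, n_burnin = 600,
                                  seed = 6 + i))$mean_matrix
  })
  combs <- utils::combn(3, 2)
  for (j in 1:3) {
    expect_gte(compare_matrices(mats[[combs[1, j]]], mats[[combs[2, j]]]),
               0.9)
  }
})

test_that("positions without diversity are flagged and zeroed", {
  # constant base at position 1: splice the reference base back in
  variants <- mutagenize(O1, 0.10, 2000, seed = 61)
  substr(variants, 1, 1) <- substr(O1, 1, 1)
  truth <- make_ground_truth_matrix(mean_penalty = 2, seed = 62)
  ds <- simulate_sorting(variants, truth, eps_wt = -15.3,
                         tp = thermo_params(R = 130), noise_cv = 0.3,
                         seed = 63)
  post <- mcmc_infer_matrix(ds, mcmc_config(200, 100, seed = 64))
  expect_identical(post$flagged_positions, 1L)
  expect_equal(unclass(post$mean_matrix)[1, ], rep(0, 4),
               ignore_attr = TRUE)
})

test_that("scaling by least squares recovers alpha and offset exactly", {
  m <- random_matrix(L = 21, seed = 32, ref_seq = O1, gauge = "reference")
  anchors <- tibble::tibble(sequence = random_seqs(8, 21, seed = 33))
  anchors$eps_R <- 1.2 * score_sequence(m, anchors$sequence) - 15.3
  sc <- scale_by_least_squares(m, anchors)
  expect_equal(sc$alpha, 1.2, tolerance = 1e-10)
  expect_equal(sc$offset_wt, -15.3, tolerance = 1e-10)
  expect_equal(sc$residuals, rep(0, 8), tolerance = 1e-10)

  two <- anchors[1:2, ]
  sc2 <- scale_by_least_squares(m, two)
  pred <- sc2$alpha * score_sequence(m, two$sequence) + sc2$offset_wt
  expect_equal(pred, two$eps_R, tolerance = 1e-10)

  same <- tibble::tibble(sequence = rep(anchors$sequence[1], 3),
                         eps_R = c(-15, -14, -13))
  expect_error(scale_by_least_squares(m, same), "singular")

  noisy <- anchors
  noisy$eps_R <- noisy$eps_R + withr::with_seed(34, rnorm(8, 0, 0.5))
  scn <- scale_by_least_squares(m, noisy)
  expect_identical(length(scn$residuals), 8L)
  expect_gt(stats::sd(scn$residuals), 0)
})

test_that("theoretical-penalty scaling is a simple ratio", {
  m <- random_matrix(L = 21, seed = 35, ref_seq = O1, gauge = "reference")
  ref_idx <- sortseqthermo:::encode_seqs(O1)[1, ]
  nonref <- matrix(TRUE, 21, 4)
  nonref[cbind(1:21, ref_idx)] <- FALSE
  cur_mean <- mean(unclass(m)[nonref])
  a <- scale_by_theoretical_penalty(m, 1.2)
  expect_equal(a * cur_mean, 1.2, tolerance = 1e-9)
  expect_equal(scale_by_theoretical_penalty(m, cur_mean), 1)

  doubled <- energy_matrix(unclass(m) * 2, gauge = "reference",
                           ref_seq = O1)
  expect_equal(scale_by_theoretical_penalty(doubled, 1.2), a / 2)
})

test_that("scaling-factor inference recovers the simulated alpha", {
  truth <- make_ground_truth_matrix(mean_penalty = 1.5, seed = 42)
  variants <- mutagenize(O1, 0.10, 1e4, seed = 43)
  tp <- thermo_params(R = 130)
  ds <- simulate_sorting(variants, truth, eps_wt = -15.3, tp = tp,
                         noise_cv = 0.3, seed = 44)
  # normalized arbitrary-unit version of the truth: true alpha = 1.5
  arb <- energy_matrix(unclass(truth) / 1.5, units = "arbitrary",
                       gauge = "reference", ref_seq = O1)
  sc <- infer_scaling_factor(ds, arb, eps_wt = -15.3, tp = tp,
                             cfg = mcmc_config(600, 200,
                                               proposal_sd = 0.1,
                                               seed = 8))
  expect_lt(abs(sc$alpha - 1.5) / 1.5, 0.2)
  expect_true(sc$identifiable)
  expect_gt(sc$alpha_sd, 0)
})

test_that("rescaling the matrix inversely rescales alpha", {
  truth <- make_ground_truth_matrix(mean_penalty = 1.5, seed = 42)
  variants <- mutagenize(O1, 0.10, 3000, seed = 43)
  tp <- thermo_params(R = 130)
  ds <- simulate_sorting(variants, truth, eps_wt = -15.3, tp = tp,
                         noise_cv = 0.3, seed = 44)
  arb <- energy_matrix(unclass(truth) / 1.5, units = "arbitrary",
                       gauge = "reference", ref_seq = O1)
  halfm <- energy_matrix(unclass(arb) * 2, units = "arbitrary",
                         gauge = "reference", ref_seq = O1)
  cfg <- mcmc_config(200, 100, proposal_sd = 0.1, seed = 8)
  a1 <- infer_scaling_factor(ds, arb, -15.3, tp, cfg, alpha_init = 1)
  a2 <- infer_scaling_factor(ds, halfm, -15.3, tp, cfg, alpha_init = 0.5)
  # identical chain on log-alpha, shifted by log(2): exact halving
  expect_equal(a2$alpha, a1$alpha / 2, tolerance = 1e-9)
})

test_that("bin labels independent of sequence leave alpha unidentifiable", {
  sim <- default_simulation(n_variants = 3000, seed = 45)
  shuffled <- sim$dataset
  shuffled$bin <- withr::with_seed(46, sample(shuffled$bin))
  ds <- sortseq_dataset(shuffled, n_bins = 4, ref_seq = O1)
  arb <- energy_matrix(unclass(sim$truth) / 2, units = "arbitrary",
                       gauge = "reference", ref_seq = O1)
  sc <- infer_scaling_factor(ds, arb, eps_wt = -15.3,
                             tp = thermo_params(R = 130),
                             cfg = mcmc_config(300, 100,
                                               proposal_sd = 0.1,
                                               seed = 47))
  expect_false(sc$identifiable)
})
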