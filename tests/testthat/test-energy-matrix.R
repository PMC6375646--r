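test_that("scoring sums the indexed cells (brute-force oracle)", {
  m <- random_matrix(L = 3, seed = 11)
  s <- "ACG"
  # independent per-position loop
  base_order <- c(A = 1, C = 2, G = 3, T = 4)
  expected <- 0
  for (i in 1:3) {
    expected <- expected + unclass(m)[i, base_order[substr(s, i, i)]]
  }
  expect_equal(score_sequence(m, s), unname(expected))

  zero <- energy_matrix(matrix(0, 4, 4))
  expect_equal(score_sequence(zero, "ACGT"), 0)

  mref <- random_matrix(L = 21, seed = 2, ref_seq = O1, gauge = "reference")
  expect_equal(score_sequence(mref, O1), 0)
})

test_that("scoring is additive over mismatched positions", {
  m <- random_matrix(L = 21, seed = 3)
  s1 <- random_seqs(1, 21, seed = 4)
  s2 <- random_seqs(1, 21, seed = 5)
  diff_positions <- which(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
  contrib <- function(s, pos) {
    b <- match(substring(s, pos, pos), c("A", "C", "G", "T"))
    sum(unclass(m)[cbind(pos, b)])
  }
  expect_equal(score_sequence(m, s1) - score_sequence(m, s2),
               unname(contrib(s1, diff_positions) -
                        contrib(s2, diff_positions)))
})

test_that("gauge fixing preserves pairwise score differences", {
  m <- random_matrix(L = 21, seed = 6, ref_seq = O1)
  for (mode in c("reference", "position_mean")) {
    g <- fix_gauge(m, mode)
    validate <- sortseqthermo:::validate_energy_matrix(g)
    pairs <- replicate(100, random_seqs(2, 21, seed = sample.int(1e6, 1)))
    before <- score_sequence(m, pairs[1, ]) - score_sequence(m, pairs[2, ])
    after <- score_sequence(g, pairs[1, ]) - score_sequence(g, pairs[2, ])
    expect_equal(after, before, tolerance = 1e-9)
  }
})

test_that("gauge fixing is idempotent and handles flat rows", {
  m <- random_matrix(L = 5, seed = 7, ref_seq = "ACGTA", gauge = "reference")
  expect_equal(unclass(fix_gauge(m, "reference")), unclass(m))
  flat <- energy_matrix(matrix(1, 1, 4))
  expect_equal(as.vector(unclass(fix_gauge(flat, "position_mean"))),
               rep(0, 4))
  noref <- random_matrix(L = 3, seed = 8)
  expect_error(fix_gauge(noref, "reference"), "reference")
})

test_that("kBT conversion applies alpha and offset linearly", {
  m <- random_matrix(L = 21, seed = 9, ref_seq = O1, gauge = "reference")
  ident <- to_kbt(m, alpha = 1, offset_wt = 0)
  expect_equal(unclass(ident), unclass(m), ignore_attr = TRUE)
  expect_identical(attr(ident, "units"), "kBT")

  scaled <- to_kbt(m, alpha = 2, offset_wt = -15.3)
  expect_equal(predict_binding_energy(scaled, O1), -15.3)
  s <- random_seqs(10, 21, seed = 10)
  d1 <- diff(predict_binding_energy(to_kbt(m, 1, 0), s))
  d2 <- diff(predict_binding_energy(scaled, s))
  expect_equal(d2, 2 * d1)
  expect_equal(predict_binding_energy(scaled, s),
               2 * score_sequence(m, s) - 15.3)

  expect_error(to_kbt(m, alpha = 0, offset_wt = 0), "nonzero")
  expect_error(to_kbt(scaled, 1, 0), "already")
  expect_error(predict_binding_energy(m, O1), "kBT")
})

test_that("matrix comparison is a Pearson correlation in mean gauge", {
  m <- random_matrix(L = 21, seed = 12, ref_seq = O1)
  expect_equal(compare_matrices(m, m), 1)
  neg <- energy_matrix(-unclass(m), ref_seq = O1)
  expect_equal(compare_matrices(m, neg), -1)

  m2 <- random_matrix(L = 21, seed = 13, ref_seq = O1)
  # textbook formula on mean-gauged cells
  c1 <- unclass(m) - rowMeans(unclass(m))
  c2 <- unclass(m2) - rowMeans(unclass(m2))
  x <- as.vector(c1) - mean(c1)
  y <- as.vector(c2) - mean(c2)
  expect_equal(compare_matrices(m, m2),
               sum(x * y) / sqrt(sum(x^2) * sum(y^2)))

  flat <- energy_matrix(matrix(2, 21, 4))
  expect_warning(r <- compare_matrices(flat, m), "constant")
  expect_true(is.nan(r))
})

test_that("matrix TSV round-trips values and metadata", {
  m <- random_matrix(L = 21, seed = 14, ref_seq = O1, gauge = "reference")
  m <- to_kbt(m, alpha = 1.37, offset_wt = -15.3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_energy_matrix(m, path)
  back <- read_energy_matrix(path)
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)
  expect_identical(attr(back, "units"), "kBT")
  expect_identical(attr(back, "gauge"), "reference")
  expect_identical(attr(back, "ref_seq"), O1)
  expect_equal(attr(back, "alpha"), 1.37)
  expect_equal(attr(back, "offset_wt"), -15.3)
})

test_that("tidy and mean_matrix behave like cell-wise operations", {
  m1 <- random_matrix(L = 2, seed = 15)
  m2 <- random_matrix(L = 2, seed = 16)
  avg <- mean_matrix(list(m1, m2))
  expect_equal(unclass(avg), (unclass(m1) + unclass(m2)) / 2,
               ignore_attr = TRUE)
  td <- tidy(m1)
  expect_s3_class(autoplot(m1), "ggplot")
  expect_identical(nrow(td), 8L)
  expect_equal(td$energy[td$position == 1 & td$base == "C"],
               unname(unclass(m1)[1, 2]))
})
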