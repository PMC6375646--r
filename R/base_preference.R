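#' Test for a preferred base at a matrix position
#'
#' Converts each replicate matrix to Boltzmann base probabilities
#' ([base_probabilities()]) at the given position, then asks whether the
#' four bases differ in mean probability across replicates using a
#' one-way Welch ANOVA (unequal variances). If the ANOVA is significant at
#' `anova_alpha`, Games-Howell pairwise comparisons are run and the most
#' probable base is declared preferred only if it beats every other base
#' at `pairwise_alpha`.
#'
#' @param replicate_matrices List of at least 3 [energy_matrix()] replicate
#'   objects with equal dimensions.
#' @param position Position (1-based) to test.
#' @param anova_alpha Welch-ANOVA significance gate (default 0.01).
#' @param pairwise_alpha Pairwise significance threshold (default 0.05).
#' @return List with `anova_p`, `pairwise` (tibble of Games-Howell
#'   comparisons: `base1`, `base2`, `diff`, `t`, `df`, `p`),
#'   `preferred_base` (single base or `NA`), and `probabilities` (replicate
#'   x base matrix).
#' @export
base_preference_test <- function(replicate_matrices, position,
                                 anova_alpha = 0.01, pairwise_alpha = 0.05) {
  if (length(replicate_matrices) < 3L) {
    stop("at least 3 replicate matrices are required to estimate variance",
         call. = FALSE)
  }
  probs <- t(vapply(replicate_matrices, function(m) {
    p <- base_probabilities(m)
    unlist(p[position, DNA_BASES])
  }, numeric(4L)))
  colnames(probs) <- DNA_BASES

  long <- data.frame(
    prob = as.vector(probs),
    base = factor(rep(DNA_BASES, each = nrow(probs)), levels = DNA_BASES)
  )
  # degenerate within-group variance (identical replicates) breaks the
  # Welch statistic; treat an exactly-constant-within-base table with
  # differing means as maximally significant
  wvar <- tapply(long$prob, long$base, stats::var)
  if (all(wvar == 0)) {
    anova_p <- if (length(unique(colMeans(probs))) > 1L) 0 else 1
  } else {
    anova_p <- stats::oneway.test(prob ~ base, data = long,
                                  var.equal = FALSE)$p.value
  }

  pairwise <- games_howell(probs)
  preferred <- NA_character_
  if (!is.na(anova_p) && anova_p < anova_alpha) {
    top <- DNA_BASES[which.max(colMeans(probs))]
    vs_top <- pairwise[pairwise$base1 == top | pairwise$base2 == top, ]
    if (all(vs_top$p < pairwise_alpha)) preferred <- top
  }
  list(anova_p = anova_p, pairwise = pairwise, preferred_base = preferred,
       probabilities = probs)
}

# Games-Howell post-hoc comparisons on a replicates x groups matrix.
# Welch t statistic per pair, Welch-Satterthwaite df, p from the
# studentized range distribution with k groups.
games_howell <- function(groups) {
  k <- ncol(groups)
  n <- nrow(groups)
  means <- colMeans(groups)
  vars <- apply(groups, 2L, stats::var)
  combs <- utils::combn(k, 2L)
  out <- purrr::map_dfr(seq_len(ncol(combs)), function(j) {
    a <- combs[1L, j]; b <- combs[2L, j]
    se2 <- vars[a] / n + vars[b] / n
    if (se2 == 0) {
      tval <- if (means[a] == means[b]) 0 else Inf
      df <- 2 * (n - 1)
    } else {
      tval <- abs(means[a] - means[b]) / sqrt(se2)
      df <- se2^2 / ((vars[a] / n)^2 / (n - 1) + (vars[b] / n)^2 / (n - 1))
    }
    p <- stats::ptukey(tval * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    tibble::tibble(base1 = colnames(groups)[a], base2 = colnames(groups)[b],
                   diff = unname(means[a] - means[b]), t = unname(tval),
                   df = unname(df), p = unname(p))
  })
  out
}
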