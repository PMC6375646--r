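#' Draw a ground-truth energy matrix
#'
#' Generates a reference-gauge matrix for simulation studies whose
#' non-reference entries have a requested mean penalty (kBT). Most
#' mutations penalize binding; about 10% of entries are beneficial
#' (negative), mirroring what a strong operator's matrix looks like.
#'
#' @param ref_seq Reference sequence (default O1); its length sets L.
#' @param mean_penalty Mean of the 3L non-reference entries (kBT,
#'   default 2).
#' @param seed Integer seed.
#' @return A reference-gauge [energy_matrix()] in kBT units (constructed
#'   directly in absolute units).
#' @export
make_ground_truth_matrix <- function(ref_seq = lac_operators[["O1"]],
                                     mean_penalty = 2, seed = 1L) {
  ref_seq <- as_operator_seq(ref_seq)
  L <- nchar(ref_seq)
  ref_idx <- encode_seqs(ref_seq)[1L, ]
  withr::with_seed(seed, {
    beneficial <- stats::runif(3L * L) < 0.10
    mag <- stats::rgamma(3L * L, shape = 2, rate = 2)
    raw <- ifelse(beneficial, -0.3 * mag, mag)
    raw <- raw * (mean_penalty / mean(raw))
    vals <- matrix(0, L, 4L)
    nonref <- matrix(TRUE, L, 4L)
    nonref[cbind(seq_len(L), ref_idx)] <- FALSE
    vals[nonref] <- raw
    energy_matrix(vals, units = "kBT", gauge = "reference", ref_seq = ref_seq)
  })
}

#' Mutagenize a reference sequence
#'
#' Each base of each variant is independently substituted with probability
#' `rate`, uniformly among the three alternative bases -- the standard
#' mutagenized-oligo library model. At 10% per base on a 21-bp site the
#' average variant carries about 2 mutations.
#'
#' @param ref Reference sequence.
#' @param rate Per-base substitution probability in (0, 1) (default 0.10).
#' @param n_variants Number of library variants to draw (default 1e4).
#' @param seed Integer seed.
#' @return Character vector of `n_variants` sequences.
#' @export
mutagenize <- function(ref, rate = 0.10, n_variants = 1e4, seed = 1L) {
  ref <- as_operator_seq(ref)
  stopifnot(rate > 0, rate < 1, n_variants >= 1)
  L <- nchar(ref)
  ref_idx <- encode_seqs(ref)[1L, ]
  withr::with_seed(seed, {
    idx <- matrix(rep(ref_idx, each = n_variants), nrow = n_variants)
    hit <- matrix(stats::runif(n_variants * L) < rate, nrow = n_variants)
    n_hit <- sum(hit)
    # uniform among the 3 alternatives: shift the base code by 1..3 mod 4
    shift <- sample.int(3L, n_hit, replace = TRUE)
    idx[hit] <- ((idx[hit] - 1L + shift) %% 4L) + 1L
    decode_seqs(idx)
  })
}

#' Simulate FACS sorting of an expression library
#'
#' Per variant, expression is the RNAP occupancy `p_bound` (with the
#' repressor binding energy predicted from the ground-truth matrix)
#' multiplied by log-normal cell-to-cell noise. Gate boundaries are placed
#' at quantiles of the pooled expression distribution so that each of
#' `n_bins` gates covers `gate_fraction` of cells, evenly spaced from the
#' bottom to the top of the histogram; cells falling between gates are
#' discarded, as in a FACS experiment.
#'
#' @param variants Character vector of library sequences.
#' @param truth Ground-truth [energy_matrix()] in kBT units (reference
#'   gauge) with known reference-sequence energy `eps_wt`.
#' @param eps_wt Binding energy of the reference sequence (kBT).
#' @param tp A [thermo_params()] giving P, eps_P, R, N_NS.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal fluorescence noise (default 0.3).
#' @param n_bins Number of sorting gates (default 4).
#' @param gate_fraction Fraction of the histogram each gate covers
#'   (default 0.15, so 4 gates keep 60% of cells).
#' @param cells_per_variant Cells drawn per variant (default 1).
#' @param seed Integer seed.
#' @return A [sortseq_dataset()] of the cells that fell inside gates.
#' @export
simulate_sorting <- function(variants, truth, eps_wt = -15.3,
                             tp = thermo_params(), noise_cv = 0.3,
                             n_bins = 4L, gate_fraction = 0.15,
                             cells_per_variant = 1L, seed = 1L) {
  stopifnot(inherits(truth, "energy_matrix"),
            identical(attr(truth, "units"), "kBT"),
            n_bins >= 2L, gate_fraction > 0, n_bins * gate_fraction <= 1)
  withr::with_seed(seed, {
    eps_R <- score_sequence(truth, variants) + eps_wt
    pb <- p_bound(tp, eps_R = eps_R)
    n_cells <- length(variants) * cells_per_variant
    variant_of <- rep(seq_along(variants), each = cells_per_variant)
    expr <- rep(pb, each = cells_per_variant)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      expr <- expr * stats::rlnorm(n_cells, meanlog = -sdlog^2 / 2,
                                   sdlog = sdlog)
    }
    if (length(unique(expr)) < 2L) {
      stop("degenerate expression distribution: gates are undefined",
           call. = FALSE)
    }
    # evenly spaced gates of width gate_fraction anchored at both ends
    gap <- (1 - n_bins * gate_fraction) / (n_bins - 1)
    starts <- (seq_len(n_bins) - 1L) * (gate_fraction + gap)
    gate_lo <- stats::quantile(expr, probs = pmin(starts, 1), names = FALSE)
    gate_hi <- stats::quantile(expr, probs = pmin(starts + gate_fraction, 1),
                               names = FALSE)
    bin <- rep(NA_integer_, n_cells)
    for (g in seq_len(n_bins)) {
      inside <- expr >= gate_lo[g] & expr <= gate_hi[g]
      bin[inside & is.na(bin)] <- g - 1L
    }
    keep <- !is.na(bin)
    recs <- dplyr::count(
      tibble::tibble(sequence = variants[variant_of[keep]], bin = bin[keep]),
      .data$sequence, .data$bin, name = "count"
    )
    sortseq_dataset(recs, n_bins = n_bins, ref_seq = attr(truth, "ref_seq"))
  })
}

#' Simulate a repressor titration table
#'
#' Fold-change values from the simple-repression model at a set of
#' repressor copy numbers, with multiplicative log-normal measurement
#' noise. Input for [fit_binding_energy()].
#'
#' @param eps_R True binding energy (kBT).
#' @param R_values Repressor copy numbers (all > 0; R = 0 is the
#'   normalizer of a fold-change measurement, not a data point).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 gives exact model values).
#' @param n_reps Replicate measurements per copy number.
#' @param N_NS,heads Passed to [fold_change_simple()].
#' @param seed Integer seed.
#' @return Tibble with columns `R` and `fold_change`.
#' @export
make_titration <- function(eps_R, R_values = c(11, 30, 62, 130, 610, 870),
                           noise_cv = 0.1, n_reps = 1L, N_NS = 4.6e6,
                           heads = 2, seed = 1L) {
  if (length(R_values) == 0L) stop("R_values must be nonempty", call. = FALSE)
  if (any(R_values <= 0)) {
    stop("R = 0 is the fold-change normalizer, not a data point",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    R <- rep(R_values, each = n_reps)
    fc <- fold_change_simple(R, eps_R, N_NS = N_NS, heads = heads)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      fc <- fc * stats::rlnorm(length(fc), meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
    }
    tibble::tibble(R = R, fold_change = fc)
  })
}
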