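#' Predict a binding energy from replicate matrices
#'
#' Scores a sequence with each replicate kBT-unit matrix
#' ([predict_binding_energy()]) and returns the mean and sample standard
#' deviation across replicates. With a single replicate the sd is `NA`,
#' not zero.
#'
#' @param replicates List of [energy_matrix()] objects in kBT units with
#'   equal lengths.
#' @param seqs Character vector of sequences.
#' @return Tibble with columns `sequence`, `predicted`, `predicted_sd`.
#' @export
predict_energy <- function(replicates, seqs) {
  stopifnot(length(replicates) >= 1L)
  preds <- vapply(replicates, predict_binding_energy, numeric(length(seqs)),
                  seqs = seqs)
  preds <- matrix(preds, nrow = length(seqs))
  tibble::tibble(
    sequence = as_operator_seq(seqs),
    predicted = rowMeans(preds),
    predicted_sd = if (length(replicates) == 1L) NA_real_ else
      apply(preds, 1L, stats::sd)
  )
}

#' Build prediction records against measured energies
#'
#' Joins predicted and measured binding energies per sequence, recomputing
#' the mutation count from the sequences themselves.
#'
#' @param data Data frame with columns `sequence`, `predicted`, `measured`
#'   (kBT); optional `predicted_sd`, `ci_low`, `ci_high`.
#' @param ref_seq Reference sequence mutation counts are taken against.
#' @return Tibble with `sequence`, `n_mut`, `predicted`, `measured`,
#'   `abs_error` (plus any optional columns present).
#' @export
prediction_records <- function(data, ref_seq = lac_operators[["O1"]]) {
  stopifnot(is.data.frame(data),
            all(c("sequence", "predicted", "measured") %in% names(data)))
  out <- tibble::as_tibble(data)
  out$sequence <- as_operator_seq(out$sequence, length = nchar(ref_seq))
  out$n_mut <- hamming_distance(out$sequence, ref_seq)
  out$abs_error <- abs(out$predicted - out$measured)
  dplyr::relocate(out, "sequence", "n_mut", "predicted", "measured",
                  "abs_error")
}

#' Summarize prediction error by mutation count
#'
#' Groups prediction records by their number of mutations relative to the
#' reference and summarizes the absolute prediction error per group
#' (median with the standard even-n midpoint convention, quartiles, n).
#'
#' @param records Tibble from [prediction_records()] (needs `n_mut` and
#'   `abs_error`).
#' @return Tibble with columns `n_mut`, `n`, `median_error`, `q1`, `q3`.
#' @export
error_by_mutation_count <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            all(c("n_mut", "abs_error") %in% names(records)))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(records), .data$n_mut),
    n = dplyr::n(),
    median_error = stats::median(.data$abs_error),
    q1 = unname(stats::quantile(.data$abs_error, 0.25)),
    q3 = unname(stats::quantile(.data$abs_error, 0.75)),
    .groups = "drop"
  )
}

O1_MUTANT_TABLE_MD5 <- "33e7aaba7c46ee5a76eab005b60ea118"

#' Bundled O1 operator-mutant energy measurements
#'
#' Loads the packaged table of 26 O1 operator mutants (1, 2 or 3 bp
#' substitutions) with matrix-predicted and titration-measured LacI
#' binding energies in kBT. The file checksum is verified and the
#' mutation count of every row is recomputed from its sequence.
#'
#' @return A [prediction_records()] tibble of 26 rows.
#' @export
load_o1_mutant_energies <- function() {
  path <- system.file("extdata", "o1_mutant_energies.tsv",
                      package = "sortseqthermo", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, O1_MUTANT_TABLE_MD5)) {
    stop("o1_mutant_energies.tsv checksum mismatch: file corrupted",
         call. = FALSE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#",
                           colClasses = c("character", "numeric", "numeric"))
  recs <- prediction_records(tab, ref_seq = lac_operators[["O1"]])
  stopifnot(nrow(recs) == 26L, all(recs$n_mut %in% 1:3))
  recs
}

#' Box-plot of prediction error by mutation count
#'
#' @param records Tibble from [prediction_records()].
#' @return A ggplot: per-record errors with overlaid box plots, by
#'   mutation count.
#' @export
plot_error_by_mutation_count <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = factor(.data$n_mut),
                                        y = .data$abs_error)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_jitter(width = 0.15, color = "#6a3d9a", alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 1.5, linetype = "dashed") +
    ggplot2::labs(x = "mutations relative to reference",
                  y = "|predicted - measured| (kBT)") +
    ggplot2::theme_minimal()
}
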