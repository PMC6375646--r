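#' Design operator mutants with target induction phenotypes
#'
#' Enumerates all single (and optionally double) mutants of the matrix's
#' reference sequence, predicts each mutant's binding energy from the
#' kBT-unit matrix, computes its induction phenotypes (leakiness,
#' saturation, dynamic range, EC50) under the allosteric model, and ranks
#' candidates by distance to the requested targets.
#'
#' @param m An [energy_matrix()] in kBT units (reference gauge).
#' @param targets Named list of target phenotype values; any subset of
#'   `leakiness`, `saturation`, `dynamic_range`, `ec50` (EC50 compared on
#'   a log10 scale).
#' @param ap An [allostery_params()].
#' @param R Repressor copy number.
#' @param N_NS,heads Passed to the thermodynamic model.
#' @param max_mutations 1 (single mutants only, default) or 2.
#' @return Tibble of candidates ranked by `target_distance`, with columns
#'   `sequence`, `n_mut`, `eps_R`, the four phenotypes and
#'   `target_distance`.
#' @export
design_induction <- function(m, targets, ap = allostery_params(), R = 130,
                             N_NS = 4.6e6, heads = 2, max_mutations = 1L) {
  stopifnot(inherits(m, "energy_matrix"))
  if (!identical(attr(m, "units"), "kBT")) {
    stop("matrix is in arbitrary units: scale it to kBT first", call. = FALSE)
  }
  known <- c("leakiness", "saturation", "dynamic_range", "ec50")
  if (length(targets) == 0L || !all(names(targets) %in% known)) {
    stop("targets must be a named list over leakiness/saturation/dynamic_range/ec50",
         call. = FALSE)
  }
  ref <- attr(m, "ref_seq")
  cands <- enumerate_single_mutants(ref)$sequence
  if (max_mutations >= 2L) {
    doubles <- unlist(lapply(cands, function(s) {
      enumerate_single_mutants(s)$sequence
    }))
    cands <- unique(c(cands, doubles))
    cands <- cands[hamming_distance(cands, ref) > 0L]
  }
  eps <- predict_binding_energy(m, cands)
  phen <- purrr::map_dfr(eps, function(e) {
    induction_phenotypes(ap, R = R, eps_R = e, N_NS = N_NS, heads = heads)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(sequence = cands,
                   n_mut = hamming_distance(cands, ref),
                   eps_R = eps),
    phen
  )
  dist2 <- rep(0, nrow(out))
  for (nm in names(targets)) {
    val <- out[[nm]]
    tgt <- targets[[nm]]
    if (nm == "ec50") {
      d <- log10(val) - log10(tgt)
    } else {
      d <- val - tgt
    }
    dist2 <- dist2 + d^2
  }
  out$target_distance <- sqrt(dist2)
  dplyr::arrange(out, .data$target_distance)
}
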