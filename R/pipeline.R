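#' Read and write titration tables
#'
#' Titration tables are TSV files with columns `R` and `fold_change`;
#' induction tables use `iptg_uM` and `fold_change`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_titration_tsv <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("R", "fold_change") %in% names(tab)))
  tab
}

#' @rdname read_titration_tsv
#' @param x Data frame to write.
#' @export
write_titration_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

provenance <- function(stage, seed, config, inputs = character()) {
  list(
    tool = "sortseqthermo",
    version = as.character(utils::packageVersion("sortseqthermo")),
    stage = stage,
    seed = seed,
    config = config,
    input_md5 = as.list(tools::md5sum(inputs))
  )
}

#' Simulate a Sort-Seq experiment to files
#'
#' End-to-end generator stage: draws a ground-truth matrix, mutagenizes
#' the reference, simulates sorting, and writes the dataset TSV, the truth
#' matrix TSV and a provenance JSON next to them. Deterministic given
#' `seed`.
#'
#' @param out_dir Output directory (created if missing).
#' @param ref_seq Reference sequence (default O1).
#' @param mutation_rate Per-base mutation rate (default 0.10).
#' @param n_variants Library size (default 1e4).
#' @param mean_penalty Ground-truth mean single-mutant penalty, kBT.
#' @param eps_wt Reference-sequence binding energy, kBT.
#' @param noise_cv Fluorescence noise CV.
#' @param n_bins,gate_fraction Sorting gates.
#' @param tp [thermo_params()] for the expression model.
#' @param seed Integer seed.
#' @return Invisibly, a list with the output paths and the dataset.
#' @export
run_simulate <- function(out_dir, ref_seq = lac_operators[["O1"]],
                         mutation_rate = 0.10, n_variants = 1e4,
                         mean_penalty = 2, eps_wt = -15.3, noise_cv = 0.3,
                         n_bins = 4L, gate_fraction = 0.15,
                         tp = thermo_params(), seed = 1L) {
  if (n_variants < 1) stop("n_variants must be at least 1", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage("simulate", "library of %d variants at rate %.2f, seed %d",
            n_variants, mutation_rate, seed)
  truth <- make_ground_truth_matrix(ref_seq, mean_penalty, seed = seed)
  variants <- mutagenize(ref_seq, mutation_rate, n_variants, seed = seed + 1L)
  ds <- simulate_sorting(variants, truth, eps_wt = eps_wt, tp = tp,
                         noise_cv = noise_cv, n_bins = n_bins,
                         gate_fraction = gate_fraction, seed = seed + 2L)
  ds_path <- file.path(out_dir, "dataset.tsv")
  truth_path <- file.path(out_dir, "truth_matrix.tsv")
  write_sortseq_tsv(ds, ds_path)
  write_energy_matrix(truth, truth_path)
  cfg <- list(ref_seq = as_operator_seq(ref_seq),
              mutation_rate = mutation_rate, n_variants = n_variants,
              mean_penalty = mean_penalty, eps_wt = eps_wt,
              noise_cv = noise_cv, n_bins = n_bins,
              gate_fraction = gate_fraction)
  json_path <- file.path(out_dir, "simulate_provenance.json")
  jsonlite::write_json(provenance("simulate", seed, cfg,
                                  c(ds_path, truth_path)),
                       json_path, auto_unbox = TRUE, pretty = TRUE)
  log_stage("simulate", "wrote %s (%d records)", ds_path, nrow(ds))
  invisible(list(dataset = ds, truth = truth, dataset_path = ds_path,
                 truth_path = truth_path, provenance_path = json_path))
}

#' Infer replicate energy matrices and a scaling factor from a dataset
#'
#' Pipeline stage wrapping [split_replicates()], [mcmc_infer_matrix()] and
#' [infer_scaling_factor()]: splits the dataset into `n_replicates`
#' groups, infers a matrix per group, writes each replicate matrix, their
#' mean, and a JSON sidecar with the scaling-factor posterior, acceptance
#' rates, final MI and config.
#'
#' @param dataset_path Path to a dataset TSV ([read_sortseq_tsv()]).
#' @param out_dir Output directory.
#' @param eps_wt Reference-sequence binding energy (kBT) used for scaling.
#' @param tp [thermo_params()] with the fixed RNAP term.
#' @param cfg [mcmc_config()] for the matrix chains.
#' @param n_replicates Number of replicate groups (default 3; 1 skips
#'   splitting and sd columns are absent).
#' @param scale_cfg [mcmc_config()] for the scaling chain.
#' @return Invisibly, list with `replicates` (matrix posteriors), `mean`
#'   ([energy_matrix()]), `scaling` (alpha posterior), paths.
#' @export
run_infer <- function(dataset_path, out_dir, eps_wt = -15.3,
                      tp = thermo_params(), cfg = mcmc_config(),
                      n_replicates = 3L,
                      scale_cfg = mcmc_config(n_iterations = 600L,
                                              n_burnin = 200L,
                                              proposal_sd = 0.1,
                                              seed = cfg$seed)) {
  ds <- read_sortseq_tsv(dataset_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage("infer", "dataset %s: %d records, %d bins", dataset_path,
            nrow(ds), attr(ds, "n_bins"))
  groups <- if (n_replicates > 1L) {
    split_replicates(ds, k = n_replicates, seed = cfg$seed)
  } else list(ds)
  posts <- lapply(seq_along(groups), function(i) {
    ci <- cfg
    ci$seed <- cfg$seed + i - 1L
    log_stage("infer", "replicate %d/%d MCMC (%d + %d iterations)", i,
              length(groups), ci$n_burnin, ci$n_iterations)
    mcmc_infer_matrix(groups[[i]], ci)
  })
  mats <- lapply(posts, function(p) p$mean_matrix)
  mmean <- mean_matrix(mats)
  for (i in seq_along(mats)) {
    write_energy_matrix(mats[[i]],
                        file.path(out_dir, sprintf("matrix_rep%d.tsv", i)))
  }
  mean_path <- file.path(out_dir, "matrix_mean.tsv")
  write_energy_matrix(mmean, mean_path)
  log_stage("infer", "scaling-factor MCMC")
  scaling <- infer_scaling_factor(ds, mmean, eps_wt = eps_wt, tp = tp,
                                  cfg = scale_cfg)
  if (!scaling$identifiable) {
    warning("scaling factor unidentifiable: posterior is as wide as the prior walk")
  }
  sidecar <- list(
    provenance = provenance("infer", cfg$seed,
                            list(n_replicates = n_replicates,
                                 n_iterations = cfg$n_iterations,
                                 n_burnin = cfg$n_burnin,
                                 eps_wt = eps_wt),
                            dataset_path),
    replicates = lapply(posts, function(p) {
      list(acceptance_rate = p$acceptance_rate, final_mi = p$final_mi,
           flagged_positions = p$flagged_positions)
    }),
    scaling = scaling[c("alpha", "alpha_sd", "acceptance_rate", "final_mi",
                        "identifiable")]
  )
  sidecar_path <- file.path(out_dir, "inference.json")
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  log_stage("infer", "alpha = %.3f +/- %.3f", scaling$alpha,
            scaling$alpha_sd)
  invisible(list(replicates = posts, mean = mmean, scaling = scaling,
                 mean_path = mean_path, sidecar_path = sidecar_path))
}

#' Rank designed induction mutants to files
#'
#' Pipeline stage over [design_induction()]: reads a kBT-unit matrix,
#' ranks mutants against the phenotype targets, writes the ranked table
#' as TSV plus a provenance JSON.
#'
#' @param matrix_path Path to a kBT-unit matrix TSV.
#' @param out_dir Output directory.
#' @param targets Named list of phenotype targets (see
#'   [design_induction()]).
#' @param ... Passed to [design_induction()].
#' @return Invisibly, the ranked tibble.
#' @export
run_design <- function(matrix_path, out_dir, targets, ...) {
  m <- read_energy_matrix(matrix_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ranked <- design_induction(m, targets, ...)
  out_path <- file.path(out_dir, "designs.tsv")
  readr::write_tsv(ranked, out_path)
  jsonlite::write_json(
    provenance("design", NA, list(targets = targets), matrix_path),
    file.path(out_dir, "design_provenance.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  log_stage("design", "wrote %d ranked designs to %s", nrow(ranked), out_path)
  invisible(ranked)
}
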