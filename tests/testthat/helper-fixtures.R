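# shared fixtures built in code

O1 <- sortseqthermo::lac_operators[["O1"]]
O2 <- sortseqthermo::lac_operators[["O2"]]
O3 <- sortseqthermo::lac_operators[["O3"]]

# seeded random energy matrix in arbitrary units, optionally gauged
random_matrix <- function(L = 5, seed = 1, ref_seq = NULL, gauge = "none") {
  vals <- withr::with_seed(seed, matrix(rnorm(L * 4), L, 4))
  m <- energy_matrix(vals, units = "arbitrary", ref_seq = ref_seq)
  if (gauge != "none") m <- fix_gauge(m, gauge)
  m
}

random_seqs <- function(n, L, seed = 1) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

# a small default simulated experiment reused across inference tests
default_simulation <- function(n_variants = 1e4, mean_penalty = 2,
                               noise_cv = 0.3, seed = 42) {
  truth <- make_ground_truth_matrix(mean_penalty = mean_penalty, seed = seed)
  variants <- mutagenize(O1, 0.10, n_variants, seed = seed + 1)
  ds <- simulate_sorting(variants, truth, eps_wt = -15.3,
                         tp = thermo_params(R = 130), noise_cv = noise_cv,
                         seed = seed + 2)
  list(truth = truth, dataset = ds)
}
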