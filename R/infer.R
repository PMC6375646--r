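#' MCMC configuration
#'
#' Settings for the Metropolis-Hastings samplers. The defaults follow the
#' standard protocol of 30000 recorded iterations after a 10000-iteration
#' burn-in; smaller runs are adequate for simulated data and testing.
#'
#' @param n_iterations Post-burn-in iterations (default 30000).
#' @param n_burnin Burn-in iterations, during which the proposal step size
#'   adapts toward a 20-40% acceptance rate and is then frozen (default
#'   10000).
#' @param proposal_sd Initial per-cell Gaussian proposal standard deviation
#'   (arbitrary energy units).
#' @param seed Integer seed; chains are reproducible bit-for-bit.
#' @param mi_bins Prediction-axis histogram bins for the mutual-information
#'   estimator (`NULL` = automatic, capped at N/50).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 30000L, n_burnin = 10000L,
                        proposal_sd = 0.05, seed = 1L, mi_bins = NULL) {
  stopifnot(n_iterations > 0L, n_burnin >= 0L, proposal_sd > 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin),
                 proposal_sd = proposal_sd, seed = as.integer(seed),
                 mi_bins = mi_bins),
            class = "mcmc_config")
}

# one-hot design matrix over free (non-reference, observed) cells
# returns list(X, free) where free is a data frame of (position, base_idx)
one_hot_free <- function(idx, ref_idx, flagged) {
  L <- ncol(idx)
  free <- list()
  for (pos in seq_len(L)) {
    if (flagged[pos]) next
    observed <- sort(unique(idx[, pos]))
    for (b in setdiff(observed, ref_idx[pos])) {
      free[[length(free) + 1L]] <- c(pos, b)
    }
  }
  free <- do.call(rbind, free)
  X <- matrix(0, nrow = nrow(idx), ncol = nrow(free))
  for (j in seq_len(nrow(free))) {
    X[idx[, free[j, 1L]] == free[j, 2L], j] <- 1
  }
  list(X = X, free = free)
}

#' Infer an energy matrix by mutual-information-maximizing MCMC
#'
#' Metropolis-Hastings sampling of the L x 4 energy-matrix cells. A
#' proposed matrix is scored on every library sequence; the proposal is
#' accepted with probability `min(1, 2^(N * dI))` where `N` is the total
#' read count and `dI` the change in mutual information between matrix
#' scores and expression bins. Reference-sequence cells are pinned at 0
#' (reference gauge). After sampling, the posterior mean matrix is
#' oriented so that mutations penalize binding on average (the sign of an
#' energy model is invisible to mutual information) and normalized so the
#' mean non-reference entry is 1 arbitrary unit.
#'
#' The chain is initialized at a weighted least-squares regression of bin
#' index on one-hot-encoded sequence, which starts the sampler near the
#' informative region.
#'
#' @param ds A [sortseq_dataset()].
#' @param cfg An [mcmc_config()].
#' @return An object of class `matrix_posterior`: list with `mean_matrix`
#'   (reference-gauge [energy_matrix()], arbitrary units), `sd_matrix`
#'   (per-cell sample standard deviations, same normalization),
#'   `acceptance_rate`, `final_mi` (bits), `flagged_positions` (positions
#'   with fewer than 2 observed bases, zeroed), `cfg`.
#' @export
mcmc_infer_matrix <- function(ds, cfg = mcmc_config()) {
  stopifnot(inherits(ds, "sortseq_dataset"), inherits(cfg, "mcmc_config"))
  withr::with_seed(cfg$seed, mcmc_infer_matrix_impl(ds, cfg))
}

mcmc_infer_matrix_impl <- function(ds, cfg) {
  idx <- encode_seqs(ds$sequence)
  L <- ncol(idx)
  counts <- ds$count
  bins <- ds$bin
  N <- sum(counts)
  ref_seq <- attr(ds, "ref_seq")
  ref_idx <- encode_seqs(ref_seq)[1L, ]

  n_base_obs <- vapply(seq_len(L), function(p) length(unique(idx[, p])),
                       integer(1))
  flagged <- n_base_obs < 2L
  if (all(flagged)) {
    stop("no position has mutational diversity; matrix is uninferable",
         call. = FALSE)
  }
  oh <- one_hot_free(idx, ref_idx, flagged)
  X <- oh$X
  n_free <- ncol(X)

  tie_order <- sample.int(nrow(idx))
  # raw plug-in MI: the acceptance rule depends only on differences, for
  # which the finite-sample bias is essentially constant
  mi <- function(score) {
    mutual_information(score, bins, counts, mi_bins = cfg$mi_bins,
                       tie_order = tie_order, bias_correction = "none")
  }

  # regression initialization: bin index ~ one-hot cells, count-weighted
  init_fit <- stats::lm.wfit(cbind(1, X), as.numeric(bins), w = counts)
  theta <- init_fit$coefficients[-1L]
  theta[is.na(theta)] <- 0
  if (stats::sd(theta) > 0) theta <- theta / stats::sd(theta)

  cur_score <- as.vector(X %*% theta)
  cur_mi <- mi(cur_score)
  step <- cfg$proposal_sd
  n_acc_window <- 0L
  n_acc_total <- 0L
  theta_sum <- numeric(n_free)
  theta_sumsq <- numeric(n_free)
  total_iter <- cfg$n_burnin + cfg$n_iterations

  for (it in seq_len(total_iter)) {
    prop <- theta + stats::rnorm(n_free, 0, step)
    prop_score <- as.vector(X %*% prop)
    prop_mi <- mi(prop_score)
    if (stats::runif(1) < 2^(N * (prop_mi - cur_mi))) {
      theta <- prop
      cur_mi <- prop_mi
      n_acc_window <- n_acc_window + 1L
      if (it > cfg$n_burnin) n_acc_total <- n_acc_total + 1L
    } else if (it > cfg$n_burnin) {
      # rejected moves count toward the post-burn-in acceptance rate only
    }
    # adapt the step toward 20-40% acceptance during burn-in, then freeze
    if (it <= cfg$n_burnin && it %% 50L == 0L) {
      rate <- n_acc_window / 50
      if (rate < 0.2) step <- step * 0.8
      if (rate > 0.4) step <- step * 1.25
      n_acc_window <- 0L
    }
    if (it > cfg$n_burnin) {
      theta_sum <- theta_sum + theta
      theta_sumsq <- theta_sumsq + theta^2
    }
  }

  mean_theta <- theta_sum / cfg$n_iterations
  var_theta <- pmax(0, theta_sumsq / cfg$n_iterations - mean_theta^2)
  sd_theta <- sqrt(var_theta)

  # orientation: the reference sequence should be near-optimal, i.e. the
  # average single-mutant entry is a penalty (positive)
  if (mean(mean_theta) < 0) mean_theta <- -mean_theta

  fill_cells <- function(v) {
    vals <- matrix(0, L, 4L)
    vals[oh$free] <- v
    vals
  }
  mean_vals <- fill_cells(mean_theta)
  sd_vals <- fill_cells(sd_theta)
  # unit normalization: mean non-reference entry = 1 arbitrary unit
  nonref <- matrix(TRUE, L, 4L)
  nonref[cbind(seq_len(L), ref_idx)] <- FALSE
  scale <- mean(mean_vals[nonref])
  if (scale > 0) {
    mean_vals <- mean_vals / scale
    sd_vals <- sd_vals / scale
  }

  structure(list(
    mean_matrix = energy_matrix(mean_vals, units = "arbitrary",
                                gauge = "reference", ref_seq = ref_seq),
    sd_matrix = sd_vals,
    acceptance_rate = n_acc_total / cfg$n_iterations,
    final_mi = cur_mi,
    flagged_positions = which(flagged),
    cfg = cfg
  ), class = "matrix_posterior")
}

#' @export
print.matrix_posterior <- function(x, ...) {
  cat(sprintf("<matrix_posterior> %d positions, acceptance %.1f%%, final MI %.3f bits\n",
              nrow(x$mean_matrix), 100 * x$acceptance_rate, x$final_mi))
  if (length(x$flagged_positions)) {
    cat("  flagged (no diversity):", paste(x$flagged_positions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Infer the energy-matrix scaling factor by MCMC
#'
#' Samples the single scaling factor `alpha` that converts arbitrary-unit
#' matrix scores into kBT via `eps_R = alpha * score + eps_wt`. For each
#' proposed `alpha` the promoter occupancy `p_bound` is computed for every
#' library sequence (with a fixed effective RNAP term) and scored against
#' the expression bins with the ordered-probit channel estimator of
#' I(p_bound; bin) ([mutual_information_channel()]) on the
#' log10-occupancy axis, with the channel noise width pinned to the
#' assay's fluorescence noise. A value-sensitive estimator with an
#' anchored scale is essential here: under a rank-based (or free-slope)
#' estimator the energy scale is a diffeomorphic mode and carries little
#' or no information. The channel's free cutpoints stand in for the
#' unknown sorting-gate boundaries; the log axis matches the
#' multiplicative character of fluorescence variation.
#'
#' @param ds A [sortseq_dataset()].
#' @param m Reference-gauge [energy_matrix()] in arbitrary units,
#'   normalized as produced by [mcmc_infer_matrix()].
#' @param eps_wt Known binding energy of the reference sequence (kBT).
#' @param tp A [thermo_params()] supplying the fixed P, eps_P, R and N_NS.
#' @param cfg An [mcmc_config()]; `proposal_sd` here is the step on
#'   log(alpha).
#' @param alpha_init Starting value (default 1).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   cell-to-cell fluorescence noise, treated as a known property of the
#'   assay (default 0.3); sets the channel noise width.
#' @return List with `alpha` (posterior mean), `alpha_sd` (posterior sd),
#'   `acceptance_rate`, `final_mi`, `identifiable` (FALSE when the
#'   posterior is as wide as the explored range, i.e. the data carry no
#'   energy-dependent signal).
#' @export
infer_scaling_factor <- function(ds, m, eps_wt, tp = thermo_params(),
                                 cfg = mcmc_config(proposal_sd = 0.1),
                                 alpha_init = 1, noise_cv = 0.3) {
  stopifnot(inherits(ds, "sortseq_dataset"), inherits(m, "energy_matrix"),
            inherits(tp, "thermo_params"))
  if (!identical(attr(m, "units"), "arbitrary")) {
    stop("scaling inference expects a matrix in arbitrary units", call. = FALSE)
  }
  withr::with_seed(cfg$seed, {
    scores <- score_sequence(m, ds$sequence)
    counts <- ds$count
    bins <- ds$bin
    N <- sum(counts)
    pol <- (tp$P / tp$N_NS) * exp(-tp$eps_P)
    ub <- sort(unique(bins))
    if (length(ub) < 2L) {
      stop("scaling inference needs at least two expression bins",
           call. = FALSE)
    }
    kidx <- match(bins, ub)
    sd_log10 <- sqrt(log(1 + noise_cv^2)) / log(10)
    mi_of <- function(log_alpha, start = NULL) {
      eps <- exp(log_alpha) * scores + eps_wt
      pb <- pol / (1 + pol + (tp$heads * tp$R / tp$N_NS) * exp(-eps))
      # floor keeps the log axis finite when repression saturates
      oprobit_channel(log10(pmax(pb, 1e-300)), kidx, counts,
                      length(ub), start = start, fixed_sd = sd_log10)
    }
    la <- log(alpha_init)
    cur <- mi_of(la)
    cur_mi <- cur$bits
    total_iter <- cfg$n_burnin + cfg$n_iterations
    draws <- numeric(cfg$n_iterations)
    n_acc <- 0L
    for (it in seq_len(total_iter)) {
      la_prop <- la + stats::rnorm(1, 0, cfg$proposal_sd)
      prop <- mi_of(la_prop, start = cur$par)
      if (stats::runif(1) < 2^(N * (prop$bits - cur_mi))) {
        la <- la_prop
        cur <- prop
        cur_mi <- prop$bits
        if (it > cfg$n_burnin) n_acc <- n_acc + 1L
      }
      if (it > cfg$n_burnin) draws[it - cfg$n_burnin] <- la
    }
    alphas <- exp(draws)
    alpha_sd <- stats::sd(alphas)
    # flat-posterior diagnostic: sd of log-alpha comparable to the random
    # walk's unconstrained spread means the data do not pin the scale
    rw_sd <- cfg$proposal_sd * sqrt(cfg$n_iterations) / 2
    identifiable <- stats::sd(draws) < 0.5 * rw_sd
    list(alpha = mean(alphas), alpha_sd = alpha_sd,
         acceptance_rate = n_acc / cfg$n_iterations,
         final_mi = cur_mi, identifiable = identifiable)
  })
}

#' Scale a matrix by least squares against known binding energies
#'
#' Ordinary least squares of measured binding energies on arbitrary-unit
#' matrix scores: the slope is the scaling factor `alpha` and the
#' intercept is the reference-sequence energy `eps_wt`. The alternative to
#' MCMC scaling when sequences with known energies are available.
#'
#' @param m Reference-gauge [energy_matrix()] in arbitrary units.
#' @param anchors Data frame with columns `sequence` and `eps_R` (kBT).
#' @return List with `alpha`, `offset_wt`, `residuals`, and `fit` (the
#'   underlying `lm`).
#' @export
scale_by_least_squares <- function(m, anchors) {
  stopifnot(inherits(m, "energy_matrix"), is.data.frame(anchors),
            all(c("sequence", "eps_R") %in% names(anchors)))
  if (nrow(anchors) < 2L) {
    stop("at least 2 anchor sequences are required", call. = FALSE)
  }
  scores <- score_sequence(m, anchors$sequence)
  if (length(unique(scores)) < 2L) {
    stop("all anchors share one matrix score: scaling is singular",
         call. = FALSE)
  }
  fit <- stats::lm(anchors$eps_R ~ scores)
  co <- stats::coef(fit)
  list(alpha = unname(co[2L]), offset_wt = unname(co[1L]),
       residuals = unname(stats::resid(fit)), fit = fit)
}

#' Scale a matrix to a target mean mutation penalty
#'
#' Chooses `alpha` so that the mean over all 3L single-mutant
#' (non-reference) entries equals a theoretical average binding penalty in
#' kBT. Used when no thermodynamic model or measured anchor energies are
#' available for the architecture.
#'
#' @param m Reference-gauge [energy_matrix()] in arbitrary units.
#' @param target_mean_penalty Desired mean single-mutant penalty (kBT).
#' @return The scaling factor `alpha`.
#' @export
scale_by_theoretical_penalty <- function(m, target_mean_penalty) {
  stopifnot(inherits(m, "energy_matrix"))
  if (!identical(attr(m, "gauge"), "reference")) {
    stop("matrix must be in reference gauge", call. = FALSE)
  }
  ref_idx <- encode_seqs(attr(m, "ref_seq"))[1L, ]
  nonref <- matrix(TRUE, nrow(m), 4L)
  nonref[cbind(seq_len(nrow(m)), ref_idx)] <- FALSE
  cur <- mean(unclass(m)[nonref])
  if (cur == 0) {
    stop("mean single-mutant score is 0: cannot scale", call. = FALSE)
  }
  target_mean_penalty / cur
}
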