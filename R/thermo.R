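#' Thermodynamic model parameters
#'
#' Bundles the statistical-mechanical parameters of the simple-repression
#' promoter model. All energies are in kBT (beta = 1).
#'
#' @param P RNAP copy number.
#' @param eps_P RNAP binding energy (kBT).
#' @param R Repressor copy number (tetramers for LacI).
#' @param eps_R Repressor binding energy (kBT).
#' @param N_NS Number of nonspecific genomic binding sites (~4.6e6 in
#'   *E. coli*).
#' @param heads Binding heads per repressor (2 for the tetrameric LacI, so
#'   the effective repressor count is 2R; 1 for a dimeric repressor).
#' @return A list of class `thermo_params`.
#' @export
thermo_params <- function(P = 1000, eps_P = -5, R = 130, eps_R = -15.3,
                          N_NS = 4.6e6, heads = 2) {
  stopifnot(P >= 0, R >= 0, heads >= 1)
  if (N_NS <= 0) stop("N_NS must be positive", call. = FALSE)
  structure(list(P = P, eps_P = eps_P, R = R, eps_R = eps_R,
                 N_NS = N_NS, heads = heads),
            class = "thermo_params")
}

#' Probability that RNAP occupies the promoter
#'
#' Two-state occupancy model for a simple-repression promoter:
#' `p_bound = (P/N_NS) e^(-eps_P) / (1 + (P/N_NS) e^(-eps_P) +
#' (heads*R/N_NS) e^(-eps_R))`. Expression is assumed proportional to this
#' occupancy (valid in the weak-promoter regime, P up to ~1000 for a
#' lacUV5-like promoter).
#'
#' @param tp A [thermo_params()] object.
#' @param eps_R Optional vector of repressor binding energies (kBT)
#'   overriding `tp$eps_R`, e.g. per-sequence matrix predictions.
#' @return Occupancy probabilities in `[0, 1)`.
#' @export
p_bound <- function(tp, eps_R = NULL) {
  stopifnot(inherits(tp, "thermo_params"))
  eR <- eps_R %||% tp$eps_R
  pol <- (tp$P / tp$N_NS) * exp(-tp$eps_P)
  rep_w <- (tp$heads * tp$R / tp$N_NS) * exp(-eR)
  pol / (1 + pol + rep_w)
}

#' Fold-change of a simple-repression promoter
#'
#' `fold_change = 1 / (1 + (heads*R/N_NS) e^(-eps_R))`: the ratio of
#' expression with R repressors to expression with none, in the
#' weak-promoter limit.
#'
#' @param R Repressor copy number (vectorized).
#' @param eps_R Repressor binding energy in kBT (vectorized).
#' @param N_NS Nonspecific genomic sites.
#' @param heads Binding heads per repressor (2 for tetrameric LacI).
#' @return Fold-change values in `(0, 1]`.
#' @export
fold_change_simple <- function(R, eps_R, N_NS = 4.6e6, heads = 2) {
  stopifnot(all(R >= 0))
  1 / (1 + (heads * R / N_NS) * exp(-eps_R))
}

#' Allosteric (MWC) induction parameters
#'
#' Two-state repressor model: an inducer at concentration `c` binds `n`
#' sites per dimer with dissociation constants `K_A` (active state) and
#' `K_I` (inactive state); `eps_AI` is the free-energy difference between
#' the states. LacI/IPTG defaults: K_A = 139 uM, K_I = 0.53 uM,
#' eps_AI = 4.5 kBT, n = 2.
#'
#' @param K_A,K_I Dissociation constants (uM), both positive.
#' @param eps_AI Active/inactive free-energy difference (kBT).
#' @param n Inducer binding sites per dimer.
#' @return A list of class `allostery_params`.
#' @export
allostery_params <- function(K_A = 139, K_I = 0.53, eps_AI = 4.5, n = 2) {
  stopifnot(K_A > 0, K_I > 0, n >= 1)
  structure(list(K_A = K_A, K_I = K_I, eps_AI = eps_AI, n = n),
            class = "allostery_params")
}

# fraction of repressors in the active (DNA-binding) state at inducer conc c
active_fraction <- function(ap, c) {
  a <- (1 + c / ap$K_A)^ap$n
  i <- (1 + c / ap$K_I)^ap$n
  a / (a + exp(-ap$eps_AI) * i)
}

#' Fold-change of an inducible simple-repression circuit
#'
#' MWC induction model: `fold_change(c) = 1 / (1 + p_act(c) *
#' (heads*R/N_NS) e^(-eps_R))` where `p_act(c)` is the active-state
#' fraction of the repressor. Rises with inducer concentration when
#' `K_I < K_A`.
#'
#' @param c Inducer concentration(s), uM.
#' @param ap An [allostery_params()] object.
#' @param R Repressor copy number.
#' @param eps_R Repressor binding energy (kBT).
#' @param N_NS Nonspecific genomic sites.
#' @param heads Binding heads per repressor.
#' @return Fold-change values in `(0, 1]`.
#' @export
fold_change_induction <- function(c, ap = allostery_params(), R = 130,
                                  eps_R = -13.9, N_NS = 4.6e6, heads = 2) {
  stopifnot(inherits(ap, "allostery_params"), all(c >= 0))
  1 / (1 + active_fraction(ap, c) * (heads * R / N_NS) * exp(-eps_R))
}

#' Phenotypic parameters of an induction response
#'
#' Summarizes an induction curve by its leakiness (fold-change as c -> 0),
#' saturation (c -> infinity), dynamic range (their difference) and EC50
#' (the inducer concentration at the response midpoint). Leakiness and
#' saturation are the analytic limits of the induction model; the EC50 is
#' found by root bracketing on log-concentration to a midpoint tolerance
#' of 1e-8.
#'
#' @inheritParams fold_change_induction
#' @return A one-row tibble with columns `leakiness`, `saturation`,
#'   `dynamic_range`, `ec50`. `ec50` is `NA` when `K_A == K_I` (the
#'   response is flat) or `R == 0`.
#' @export
induction_phenotypes <- function(ap = allostery_params(), R = 130,
                                 eps_R = -13.9, N_NS = 4.6e6, heads = 2) {
  stopifnot(inherits(ap, "allostery_params"))
  w <- (heads * R / N_NS) * exp(-eps_R)
  p_act0 <- 1 / (1 + exp(-ap$eps_AI))
  p_act_inf <- 1 / (1 + exp(-ap$eps_AI) * (ap$K_A / ap$K_I)^ap$n)
  leakiness <- 1 / (1 + p_act0 * w)
  saturation <- 1 / (1 + p_act_inf * w)
  mid <- (leakiness + saturation) / 2
  ec50 <- NA_real_
  if (ap$K_A != ap$K_I && R > 0) {
    f <- function(log_c) {
      fold_change_induction(exp(log_c), ap, R, eps_R, N_NS, heads) - mid
    }
    lo <- log(min(ap$K_A, ap$K_I)) - 25
    hi <- log(max(ap$K_A, ap$K_I)) + 25
    ec50 <- exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
    # refine to midpoint tolerance on the fold-change scale
    stopifnot(abs(fold_change_induction(ec50, ap, R, eps_R, N_NS, heads) - mid)
              < 1e-8)
  }
  tibble::tibble(leakiness = leakiness, saturation = saturation,
                 dynamic_range = saturation - leakiness, ec50 = ec50)
}

#' Fold-change from fluorescence intensities
#'
#' `(I_R - I_auto) / (I_R0 - I_auto)`: mean fluorescence with repressor,
#' normalized by the repressor-free signal after subtracting
#' autofluorescence.
#'
#' @param I_R Mean intensity with repressor present.
#' @param I_R0 Mean intensity with no repressor.
#' @param I_auto Mean autofluorescence (no reporter).
#' @return Fold-change values.
#' @export
fold_change_from_fluorescence <- function(I_R, I_R0, I_auto) {
  denom <- I_R0 - I_auto
  if (any(denom <= 0)) {
    stop("autofluorescence exceeds the unrepressed signal: I_R0 must be > I_auto",
         call. = FALSE)
  }
  (I_R - I_auto) / denom
}

#' Fit a binding energy to repressor titration data
#'
#' Single-parameter nonlinear least-squares fit of the simple-repression
#' fold-change model to (R, fold_change) measurements, returning the
#' binding energy `eps_R` with a 95% confidence interval from the
#' linearized asymptotic standard error. A single data point is inverted
#' algebraically (zero-width interval).
#'
#' @param data Data frame with columns `R` (repressor copy number, > 0) and
#'   `fold_change`; an optional `weight` column gives least-squares weights.
#' @param N_NS Nonspecific genomic sites.
#' @param heads Binding heads per repressor.
#' @return An object of class `eps_fit` with `estimate`, `ci_low`,
#'   `ci_high`, `rss`, `n_points`; see [tidy.eps_fit()] and
#'   [glance.eps_fit()].
#' @export
fit_binding_energy <- function(data, N_NS = 4.6e6, heads = 2) {
  stopifnot(is.data.frame(data),
            all(c("R", "fold_change") %in% names(data)))
  data <- data[data$R > 0, , drop = FALSE]
  if (nrow(data) == 0L) {
    stop("binding energy is unidentifiable: no points with R > 0",
         call. = FALSE)
  }
  invert <- function(R, fc) {
    fc <- min(fc, 1 - 1e-12)
    -log((1 / fc - 1) * N_NS / (heads * R))
  }
  if (nrow(data) == 1L) {
    est <- invert(data$R, data$fold_change)
    fit <- list(estimate = est, ci_low = est, ci_high = est,
                se = 0, rss = 0, n_points = 1L, data = tibble::as_tibble(data))
    class(fit) <- "eps_fit"
    return(fit)
  }
  w <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  point_inv <- mapply(invert, data$R, pmin(pmax(data$fold_change, 1e-12),
                                           1 - 1e-9))
  rss_of <- function(eps) {
    sum(w * (data$fold_change -
               fold_change_simple(data$R, eps, N_NS, heads))^2)
  }
  # one-parameter least squares by golden-section/parabolic search over a
  # bracket around the per-point inversions (robust for zero-residual data,
  # where derivative-based optimizers stall)
  bracket <- range(point_inv) + c(-5, 5)
  opt <- stats::optimize(rss_of, bracket, tol = 1e-10)
  est <- opt$minimum
  rss <- opt$objective
  # linearized asymptotic standard error: d(fold-change)/d(eps) = fc(1-fc)
  fc_hat <- fold_change_simple(data$R, est, N_NS, heads)
  grad <- fc_hat * (1 - fc_hat)
  df <- nrow(data) - 1L
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sum(w * grad^2))
  half <- stats::qt(0.975, df) * se
  fit <- list(estimate = est, ci_low = est - half, ci_high = est + half,
              se = se, rss = rss, n_points = nrow(data),
              data = tibble::as_tibble(data))
  class(fit) <- "eps_fit"
  fit
}

#' @export
print.eps_fit <- function(x, ...) {
  cat(sprintf("<eps_fit> eps_R = %.3f kBT [95%% CI %.3f, %.3f], %d points, rss = %.4g\n",
              x$estimate, x$ci_low, x$ci_high, x$n_points, x$rss))
  invisible(x)
}

#' Tidy a titration fit
#'
#' @param x An `eps_fit` from [fit_binding_energy()].
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.eps_fit <- function(x, ...) {
  tibble::tibble(term = "eps_R", estimate = x$estimate, std.error = x$se,
                 conf.low = x$ci_low, conf.high = x$ci_high)
}

#' Fit diagnostics for a titration fit
#'
#' @param x An `eps_fit` from [fit_binding_energy()].
#' @param ... Unused.
#' @return One-row tibble: `rss`, `n_points`.
#' @export
glance.eps_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_points = x$n_points)
}

#' Plot a titration fit
#'
#' @param object An `eps_fit` from [fit_binding_energy()].
#' @param ... Unused.
#' @return A ggplot of the data with the fitted fold-change curve.
#' @export
autoplot.eps_fit <- function(object, ...) {
  rng <- range(object$data$R)
  curve_df <- tibble::tibble(
    R = exp(seq(log(rng[1]) - 0.5, log(rng[2]) + 0.5, length.out = 200))
  )
  curve_df$fold_change <- fold_change_simple(curve_df$R, object$estimate)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$R,
                                            y = .data$fold_change)) +
    ggplot2::geom_line(data = curve_df, color = "#2166ac") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "repressor copy number R", y = "fold-change") +
    ggplot2::theme_minimal()
}
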