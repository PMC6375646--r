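#' Plug-in mutual information between predictions and expression bins
#'
#' Estimates I(prediction; bin) in bits from a joint histogram. The
#' prediction axis is discretized into `mi_bins` equal-count (rank) bins,
#' which makes the estimate invariant under any strictly monotone
#' transform of the predictions -- the property that lets an arbitrary-unit
#' energy model be fit by mutual-information maximization. Records are
#' weighted by their read counts.
#'
#' @param predictions Numeric vector, one value per record (e.g. matrix
#'   scores).
#' @param bins Integer expression-bin labels per record.
#' @param counts Read counts per record (default all 1).
#' @param mi_bins Number of prediction-axis bins; default
#'   `min(1000, max(2, floor(N / 50)))` where N is the total count.
#' @param tie_order Optional permutation of record indices used to break
#'   prediction ties stably (a seeded shuffle upstream makes tie-breaking
#'   reproducible); default is input order.
#' @param bias_correction `"miller_madow"` (default) subtracts the
#'   Miller-Madow finite-sample bias estimate, clamped to be
#'   non-negative, so shuffled (information-free) data score near 0 even
#'   with many histogram bins; `"none"` gives the raw plug-in estimate.
#' @return Mutual information in bits (nonnegative scalar). Returns 0 with
#'   a warning if only one expression bin is represented.
#' @export
mutual_information <- function(predictions, bins, counts = NULL,
                               mi_bins = NULL, tie_order = NULL,
                               bias_correction = c("miller_madow", "none")) {
  bias_correction <- match.arg(bias_correction)
  n <- length(predictions)
  stopifnot(length(bins) == n)
  counts <- counts %||% rep(1, n)
  ub <- sort(unique(bins))
  if (length(ub) < 2L) {
    warning("only one expression bin represented; mutual information is 0")
    return(0)
  }
  N <- sum(counts)
  mi_bins <- mi_bins %||% min(1000L, max(2L, floor(N / 50)))
  tie_order <- tie_order %||% seq_len(n)
  # stable sort of the shuffled order: ties resolved by tie_order
  ord <- tie_order[order(predictions[tie_order], method = "radix")]
  rank_bin <- ceiling(cumsum(counts[ord]) * mi_bins / N)
  rank_bin[rank_bin < 1L] <- 1L
  joint_mi(rank_bin, match(bins[ord], ub), counts[ord],
           mi_bins, length(ub), bias_correction)
}

# MI in bits of a weighted joint table given integer cell coordinates
joint_mi <- function(row_idx, col_idx, w, n_rows, n_cols,
                     bias_correction = "none") {
  lin <- (col_idx - 1L) * n_rows + row_idx
  agg <- rowsum(w, lin)
  tab <- numeric(n_rows * n_cols)
  tab[as.integer(rownames(agg))] <- agg
  tab <- matrix(tab, n_rows, n_cols)
  p <- tab / sum(tab)
  pr <- rowSums(p)
  pc <- colSums(p)
  h <- function(q) -sum(q[q > 0] * log2(q[q > 0]))
  mi <- max(0, h(pr) + h(pc) - h(p))
  if (identical(bias_correction, "miller_madow")) {
    k_extra <- sum(p > 0) - sum(pr > 0) - sum(pc > 0) + 1L
    mi <- max(0, mi - max(0, k_extra) / (2 * sum(tab) * log(2)))
  }
  mi
}

#' Fixed-width histogram mutual information
#'
#' Like [mutual_information()] but with equal-width bins over a fixed
#' value range, so the estimate is *not* invariant under monotone
#' transforms. This value-sensitive variant is what makes the energy-scale
#' (diffeomorphic) mode visible to scaling-factor inference.
#'
#' @inheritParams mutual_information
#' @param range Numeric length-2 vector giving the fixed bin range;
#'   default spans the observed predictions.
#' @return Mutual information in bits.
#' @export
mutual_information_fixed <- function(predictions, bins, counts = NULL,
                                     mi_bins = 30L, range = NULL) {
  n <- length(predictions)
  counts <- counts %||% rep(1, n)
  ub <- sort(unique(bins))
  if (length(ub) < 2L) {
    warning("only one expression bin represented; mutual information is 0")
    return(0)
  }
  range <- range %||% base::range(predictions)
  edges <- seq(range[1], range[2], length.out = mi_bins + 1L)
  cell <- findInterval(predictions, edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  joint_mi(cell, match(bins, ub), counts, mi_bins, length(ub))
}

#' Ordered-probit channel mutual information
#'
#' Parametric estimate of I(prediction; bin) in bits for ordered
#' expression bins: models the bin of each record as an ordered-probit
#' channel on the prediction axis (free monotone cutpoints, free noise
#' width) and reports the per-observation log-likelihood gain over the
#' bin-frequency-only model, in bits. Because the latent-noise model is
#' metric on the prediction axis, the estimate is *not* invariant under
#' monotone transforms -- it resolves the energy-scale (diffeomorphic)
#' mode that rank-based estimators cannot see -- while the free cutpoints
#' absorb any affine transform.
#'
#' @inheritParams mutual_information
#' @param noise_sd Optional known channel noise standard deviation on the
#'   prediction axis. When supplied, the probit slope is pinned to it
#'   instead of profiled, which anchors the prediction axis's absolute
#'   scale (a free slope makes the estimate insensitive to affine --
#'   i.e. near-linear -- transforms of the predictions).
#' @return Mutual information in bits (nonnegative).
#' @export
mutual_information_channel <- function(predictions, bins, counts = NULL,
                                       noise_sd = NULL) {
  n <- length(predictions)
  counts <- counts %||% rep(1, n)
  ub <- sort(unique(bins))
  B <- length(ub)
  if (B < 2L) {
    warning("only one expression bin represented; mutual information is 0")
    return(0)
  }
  fit <- oprobit_channel(predictions, match(bins, ub), counts, B,
                         fixed_sd = noise_sd)
  fit$bits
}

# ordered-probit channel fit by maximum likelihood with analytic
# gradients; returns per-observation information gain in bits plus the
# fitted parameters (for warm-starting repeated fits). With a free slope
# the parameters are (log-slope, first cutpoint, log-spacings); with
# fixed_sd supplied the slope is pinned and only cutpoints are fitted.
oprobit_channel <- function(predictions, kidx, counts, B, start = NULL,
                            fixed_sd = NULL) {
  n <- length(predictions)
  s <- stats::sd(predictions)
  if (!is.finite(s) || s == 0) return(list(bits = 0, par = NULL))
  free_slope <- is.null(fixed_sd)
  z <- if (free_slope) (predictions - mean(predictions)) / s else
    predictions / fixed_sd
  pk <- prop.table(tapply(counts, kidx, sum))
  null_ll <- sum(counts * log(pk[kidx]))
  N <- sum(counts)
  np_head <- if (free_slope) 2L else 1L  # params before the log-spacings

  pieces <- function(par) {
    b <- if (free_slope) exp(min(par[1L], 20)) else 1
    cuts <- cumsum(c(par[np_head],
                     exp(pmin(par[-seq_len(np_head)], 20))))
    eta <- b * z
    u <- c(cuts, Inf)[kidx] - eta
    l <- c(-Inf, cuts)[kidx] - eta
    P <- pmax(stats::pnorm(u) - stats::pnorm(l), 1e-12)
    list(b = b, P = P, phu = stats::dnorm(u), phl = stats::dnorm(l))
  }
  nll <- function(par) {
    v <- -sum(counts * log(pieces(par)$P))
    if (!is.finite(v)) 1e12 else v
  }
  grad <- function(par) {
    pc <- pieces(par)
    w <- counts / pc$P
    # cutpoint gradients: upper cut of bin j is c_j, lower of bin j+1
    dc <- vapply(seq_len(B - 1L), function(j) {
      -sum(w * pc$phu * (kidx == j)) + sum(w * pc$phl * (kidx == j + 1L))
    }, numeric(1))
    g <- numeric(length(par))
    if (free_slope) {
      g[1L] <- sum(w * z * (pc$phu - pc$phl)) * pc$b
    }
    g[np_head] <- sum(dc)
    if (B > 2L) {
      spac <- exp(pmin(par[-seq_len(np_head)], 20))
      for (m in seq_len(B - 2L)) {
        g[np_head + m] <- sum(dc[(m + 1L):(B - 1L)]) * spac[m]
      }
    }
    if (!all(is.finite(g))) g[] <- 0
    g
  }
  cum_k <- pmin(pmax(cumsum(pk)[seq_len(B - 1L)], 1e-6), 1 - 1e-6)
  cut0 <- if (free_slope) stats::qnorm(cum_k) else
    unname(stats::quantile(rep(z, counts), cum_k))
  default_start <- c(if (free_slope) 0, cut0[1L],
                     if (B > 2L) log(pmax(diff(cut0), 1e-4)))
  start <- start %||% default_start
  if (length(start) != length(default_start) || !all(is.finite(start))) {
    start <- default_start
  }
  fit <- stats::optim(start, nll, gr = grad, method = "BFGS",
                      control = list(maxit = 100, reltol = 1e-9))
  list(bits = max(0, (-fit$value - null_ll) / (N * log(2))), par = fit$par)
}
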