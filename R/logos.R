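#' Boltzmann base probabilities from an energy matrix
#'
#' At each position the probability of base N is
#' `exp(-eps_N) / sum_M exp(-eps_M)`: low-energy (strongly bound) bases are
#' preferred. The mapping is invariant under per-position additive shifts,
#' so it does not depend on the gauge; the per-position minimum is
#' subtracted before exponentiating to guard against overflow.
#'
#' @param m An [energy_matrix()].
#' @return A tibble of class `base_probabilities` with columns `position`,
#'   `A`, `C`, `G`, `T` and `info_bits` (per-position information content).
#' @export
base_probabilities <- function(m) {
  stopifnot(inherits(m, "energy_matrix"))
  vals <- unclass(m)
  dimnames(vals) <- NULL
  shifted <- vals - apply(vals, 1L, min)
  w <- exp(-shifted)
  p <- w / rowSums(w)
  out <- tibble::tibble(
    position = seq_len(nrow(p)),
    A = p[, 1], C = p[, 2], G = p[, 3], T = p[, 4]
  )
  out$info_bits <- as.vector(position_information(p))
  class(out) <- c("base_probabilities", class(out))
  out
}

# Schneider information content: 2 + sum p log2 p, with 0 log 0 := 0
position_information <- function(p) {
  plogp <- ifelse(p > 0, p * log2(p), 0)
  2 + rowSums(plogp)
}

#' Letter heights for an information logo
#'
#' Each base's letter height is its probability times the position's
#' information content (bits), so a fully conserved position stacks to
#' 2 bits and an uninformative one to 0.
#'
#' @param p A [base_probabilities()] tibble.
#' @return Long tibble with columns `position`, `base`, `prob`, `info_bits`,
#'   `height` (bits).
#' @export
information_logo <- function(p) {
  stopifnot(inherits(p, "base_probabilities"))
  long <- tidyr::pivot_longer(p, cols = dplyr::all_of(DNA_BASES),
                              names_to = "base", values_to = "prob")
  long$height <- long$prob * long$info_bits
  dplyr::select(long, "position", "base", "prob", "info_bits", "height")
}

base_fill_scale <- function() {
  ggplot2::scale_fill_manual(values = c(
    A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839"
  ))
}

#' Plot a sequence logo from an energy matrix
#'
#' `kind = "information"` stacks bases by probability x information
#' content (bits); `kind = "energy"` shows mean-centered energies per base
#' (an energy logo), with favorable (negative) energies plotted upward.
#'
#' @param m An [energy_matrix()].
#' @param kind `"information"` or `"energy"`.
#' @return A ggplot object.
#' @export
plot_logo <- function(m, kind = c("information", "energy")) {
  kind <- match.arg(kind)
  if (kind == "information") {
    df <- information_logo(base_probabilities(m))
    df <- df[order(df$position, df$height), ]
    df <- dplyr::mutate(dplyr::group_by(df, .data$position),
                        ymax = cumsum(.data$height),
                        ymin = .data$ymax - .data$height)
    gg <- ggplot2::ggplot(df) +
      ggplot2::geom_rect(ggplot2::aes(
        xmin = .data$position - 0.45, xmax = .data$position + 0.45,
        ymin = .data$ymin, ymax = .data$ymax, fill = .data$base
      ), alpha = 0.9) +
      ggplot2::geom_text(
        data = dplyr::filter(df, .data$height > 0.08),
        ggplot2::aes(x = .data$position, y = (.data$ymin + .data$ymax) / 2,
                     label = .data$base),
        color = "white", fontface = "bold", size = 3
      ) +
      ggplot2::labs(x = "position", y = "information (bits)")
  } else {
    df <- tidy(fix_gauge(m, "position_mean"))
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                           y = -.data$energy,
                                           fill = .data$base)) +
      ggplot2::geom_col(position = "dodge", width = 0.8) +
      ggplot2::labs(x = "position",
                    y = sprintf("-energy (%s, mean-centered)",
                                attr(m, "units")))
  }
  gg + base_fill_scale() + ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
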