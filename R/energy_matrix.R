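#' Construct an energy matrix
#'
#' An energy matrix assigns an additive energy contribution to each base at
#' each position of a binding site; summing the entries selected by a
#' sequence gives that sequence's binding energy, up to an overall scale and
#' offset. Entries are stored as an L x 4 numeric matrix with base columns
#' in the fixed order A, C, G, T.
#'
#' @param values L x 4 numeric matrix (positions x bases A,C,G,T).
#' @param units `"arbitrary"` (raw inference output) or `"kBT"` (absolute
#'   energies).
#' @param gauge `"reference"` (entries of the reference sequence are 0),
#'   `"position_mean"` (each row averages 0) or `"none"`.
#' @param ref_seq Reference ("wild-type") sequence, or `NULL`.
#' @param alpha Scaling factor converting arbitrary units to kBT, or `NULL`.
#' @param offset_wt Binding energy of the reference sequence in kBT
#'   (`Delta epsilon_wt`), or `NULL`.
#' @return An `energy_matrix` object.
#' @export
energy_matrix <- function(values, units = c("arbitrary", "kBT"),
                          gauge = c("none", "reference", "position_mean"),
                          ref_seq = NULL, alpha = NULL, offset_wt = NULL) {
  units <- match.arg(units)
  gauge <- match.arg(gauge)
  values <- as.matrix(values)
  if (ncol(values) != 4L) {
    stop("an energy matrix must have 4 base columns (A, C, G, T)",
         call. = FALSE)
  }
  if (!is.numeric(values)) stop("matrix values must be numeric", call. = FALSE)
  colnames(values) <- DNA_BASES
  rownames(values) <- NULL
  if (!is.null(ref_seq)) {
    ref_seq <- as_operator_seq(ref_seq, length = nrow(values))
  }
  m <- structure(values,
                 units = units, gauge = gauge, ref_seq = ref_seq,
                 alpha = alpha, offset_wt = offset_wt,
                 class = c("energy_matrix", "matrix", "array"))
  validate_energy_matrix(m)
  m
}

validate_energy_matrix <- function(m, tol = 1e-9) {
  gauge <- attr(m, "gauge")
  if (identical(gauge, "reference")) {
    rs <- attr(m, "ref_seq")
    if (is.null(rs)) {
      stop("reference gauge requires a reference sequence", call. = FALSE)
    }
    idx <- encode_seqs(rs)[1L, ]
    ref_vals <- m[cbind(seq_len(nrow(m)), idx)]
    if (any(abs(ref_vals) > tol)) {
      stop("reference gauge violated: reference-sequence entries are not 0",
           call. = FALSE)
    }
  }
  if (identical(gauge, "position_mean")) {
    if (any(abs(rowMeans(unclass(m))) > tol)) {
      stop("position-mean gauge violated: row means are not 0", call. = FALSE)
    }
  }
  if (identical(attr(m, "units"), "kBT")) {
    # fine: either constructed directly in kBT or converted via to_kbt()
  }
  invisible(m)
}

#' @export
print.energy_matrix <- function(x, ...) {
  cat(sprintf("<energy_matrix> %d positions, units: %s, gauge: %s\n",
              nrow(x), attr(x, "units"), attr(x, "gauge")))
  if (!is.null(attr(x, "ref_seq"))) {
    cat("  reference:", attr(x, "ref_seq"), "\n")
  }
  if (!is.null(attr(x, "alpha"))) {
    cat(sprintf("  alpha = %.4g, offset_wt = %.4g kBT\n",
                attr(x, "alpha"), attr(x, "offset_wt") %||% NA_real_))
  }
  print(round(unclass(x), 3), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score sequences with an energy matrix
#'
#' Sums the matrix entries selected by each sequence: the matrix-model
#' binding energy `epsilon_mat` in the matrix's own units.
#'
#' @param m An [energy_matrix()].
#' @param seqs Character vector of sequences with length equal to `nrow(m)`.
#' @return Numeric vector of scores.
#' @export
score_sequence <- function(m, seqs) {
  stopifnot(inherits(m, "energy_matrix"))
  idx <- encode_seqs(as_operator_seq(seqs, length = nrow(m)))
  score_encoded(unclass(m), idx)
}

# idx: n x L integer matrix of base codes; vals: L x 4 numeric
score_encoded <- function(vals, idx) {
  L <- nrow(vals)
  # flatten column-major by position: entry (pos, base) -> (base-1)*L + pos
  flat <- as.vector(vals)                 # (pos, base) column-major: pos + (base-1)*L
  off <- sweep((idx - 1L) * L, 2L, seq_len(L), "+")
  rowSums(matrix(flat[off], nrow = nrow(idx)))
}

#' Fix the gauge of an energy matrix
#'
#' A linear energy model is only identified up to per-position additive
#' shifts; a gauge is a convention that removes this freedom. The
#' `"reference"` gauge sets the entries of the reference sequence to 0 so
#' all other entries read as energies relative to wild type; the
#' `"position_mean"` gauge centers each position at 0. Either transform
#' preserves all pairwise score differences.
#'
#' @param m An [energy_matrix()].
#' @param mode `"reference"` or `"position_mean"`.
#' @return A gauge-fixed `energy_matrix`.
#' @export
fix_gauge <- function(m, mode = c("reference", "position_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "energy_matrix"))
  vals <- unclass(m)
  if (mode == "reference") {
    rs <- attr(m, "ref_seq")
    if (is.null(rs)) {
      stop("reference-gauge fixing requires a reference sequence",
           call. = FALSE)
    }
    idx <- encode_seqs(rs)[1L, ]
    shift <- vals[cbind(seq_len(nrow(vals)), idx)]
  } else {
    shift <- rowMeans(vals)
  }
  energy_matrix(vals - shift, units = attr(m, "units"), gauge = mode,
                ref_seq = attr(m, "ref_seq"), alpha = attr(m, "alpha"),
                offset_wt = attr(m, "offset_wt"))
}

#' Convert an arbitrary-unit matrix to absolute kBT units
#'
#' Applies the decomposition `Delta epsilon_R = alpha * epsilon_mat +
#' Delta epsilon_wt`: entries are multiplied by the scaling factor `alpha`
#' and the reference-sequence binding energy `offset_wt` is recorded so that
#' [predict_binding_energy()] returns absolute energies.
#'
#' @param m An [energy_matrix()] in arbitrary units.
#' @param alpha Scaling factor (kBT per arbitrary unit); must be nonzero.
#' @param offset_wt Reference-sequence binding energy in kBT.
#' @return An `energy_matrix` in kBT units.
#' @export
to_kbt <- function(m, alpha, offset_wt) {
  stopifnot(inherits(m, "energy_matrix"))
  if (!identical(attr(m, "units"), "arbitrary")) {
    stop("matrix is already in kBT units", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha == 0) {
    stop("alpha must be a nonzero scaling factor", call. = FALSE)
  }
  energy_matrix(unclass(m) * alpha, units = "kBT", gauge = attr(m, "gauge"),
                ref_seq = attr(m, "ref_seq"), alpha = alpha,
                offset_wt = offset_wt)
}

#' Predict absolute binding energies from a kBT-unit matrix
#'
#' For a reference-gauge matrix in kBT units, the binding energy of a
#' sequence is its matrix score plus the reference-sequence energy
#' `offset_wt`.
#'
#' @param m An [energy_matrix()] in kBT units.
#' @param seqs Character vector of sequences.
#' @return Numeric vector of binding energies (kBT).
#' @export
predict_binding_energy <- function(m, seqs) {
  stopifnot(inherits(m, "energy_matrix"))
  if (!identical(attr(m, "units"), "kBT")) {
    stop("matrix must be in kBT units; scale it first (see to_kbt())",
         call. = FALSE)
  }
  score_sequence(m, seqs) + (attr(m, "offset_wt") %||% 0)
}

#' Compare two energy matrices by Pearson correlation
#'
#' Both matrices are transformed to the position-mean gauge (so the
#' comparison is gauge-independent) and the Pearson correlation is computed
#' over all L x 4 cells.
#'
#' @param m1,m2 [energy_matrix()] objects of equal dimensions.
#' @return Pearson r (scalar); `NaN` with a warning if either matrix has
#'   zero variance after gauge fixing.
#' @export
compare_matrices <- function(m1, m2) {
  stopifnot(inherits(m1, "energy_matrix"), inherits(m2, "energy_matrix"))
  if (!identical(dim(m1), dim(m2))) {
    stop("matrices must have identical dimensions", call. = FALSE)
  }
  v1 <- as.vector(unclass(fix_gauge(m1, "position_mean")))
  v2 <- as.vector(unclass(fix_gauge(m2, "position_mean")))
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("constant matrix: correlation undefined")
    return(NaN)
  }
  stats::cor(v1, v2)
}

#' Average replicate energy matrices cell-wise
#'
#' @param mats List of [energy_matrix()] objects with identical dimensions
#'   and metadata conventions; the first matrix's metadata is retained.
#' @return The mean `energy_matrix`.
#' @export
mean_matrix <- function(mats) {
  stopifnot(length(mats) >= 1L)
  vals <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  m1 <- mats[[1L]]
  energy_matrix(vals, units = attr(m1, "units"), gauge = attr(m1, "gauge"),
                ref_seq = attr(m1, "ref_seq"), alpha = attr(m1, "alpha"),
                offset_wt = attr(m1, "offset_wt"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an energy matrix into long format
#'
#' @param x An [energy_matrix()].
#' @param ... Unused.
#' @return Tibble with columns `position`, `base`, `energy`.
#' @export
tidy.energy_matrix <- function(x, ...) {
  tibble::tibble(
    position = rep(seq_len(nrow(x)), times = 4L),
    base = rep(DNA_BASES, each = nrow(x)),
    energy = as.vector(unclass(x))
  )
}

#' Heat-map of an energy matrix
#'
#' @param object An [energy_matrix()].
#' @param ... Unused.
#' @return A ggplot object (positions on x, bases on y, fill = energy).
#' @export
autoplot.energy_matrix <- function(object, ...) {
  df <- tidy.energy_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = factor(.data$base, levels = rev(DNA_BASES)),
                                   fill = .data$energy)) +
    ggplot2::geom_tile(color = "grey90") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "grey95",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "position", y = NULL,
                  fill = sprintf("energy (%s)", attr(object, "units"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write an energy matrix to TSV
#'
#' The file carries a `pos  A  C  G  T` header plus `#`-prefixed metadata
#' lines (`units`, `gauge`, `reference`, `alpha`, `offset_wt`) so base order
#' and provenance are explicit.
#'
#' @param m An [energy_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_energy_matrix <- function(m, path) {
  stopifnot(inherits(m, "energy_matrix"))
  meta <- c(
    sprintf("# units=%s", attr(m, "units")),
    sprintf("# gauge=%s", attr(m, "gauge")),
    if (!is.null(attr(m, "ref_seq"))) sprintf("# reference=%s", attr(m, "ref_seq")),
    if (!is.null(attr(m, "alpha"))) sprintf("# alpha=%.17g", attr(m, "alpha")),
    if (!is.null(attr(m, "offset_wt"))) sprintf("# offset_wt=%.17g", attr(m, "offset_wt"))
  )
  body <- c(paste(c("pos", DNA_BASES), collapse = "\t"),
            vapply(seq_len(nrow(m)), function(i) {
              paste(c(i, sprintf("%.17g", unclass(m)[i, ])), collapse = "\t")
            }, character(1)))
  writeLines(c(meta, body), path)
  invisible(path)
}

#' Read an energy matrix from TSV
#'
#' Accepts the format written by [write_energy_matrix()]: optional `#`
#' metadata lines followed by a `pos A C G T` header. Base columns are
#' matched by name, never by position alone.
#'
#' @param path Input path.
#' @return An [energy_matrix()].
#' @export
read_energy_matrix <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", ln))[[1]]
    if (length(kv) == 3L) meta[[kv[2]]] <- kv[3]
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", check.names = TRUE)
  need <- c("A", "C", "G", "T")
  if (!all(need %in% names(tab))) {
    stop("matrix TSV must have a header naming columns A, C, G, T",
         call. = FALSE)
  }
  vals <- as.matrix(tab[order(tab$pos), need])
  energy_matrix(
    vals,
    units = meta$units %||% "arbitrary",
    gauge = meta$gauge %||% "none",
    ref_seq = meta$reference,
    alpha = if (!is.null(meta$alpha)) as.numeric(meta$alpha),
    offset_wt = if (!is.null(meta$offset_wt)) as.numeric(meta$offset_wt)
  )
}
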