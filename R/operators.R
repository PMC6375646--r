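#' The natural lac operators
#'
#' The three natural *E. coli* lac operator sequences (21 bp, top strand).
#' O1 is the strongest LacI binding site (-15.3 kBT), O2 intermediate
#' (-13.9 kBT) and O3 the weakest (-9.7 kBT).
#'
#' @format Named character vector with elements `O1`, `O2`, `O3`.
#' @export
lac_operators <- c(
  O1 = "AATTGTGAGCGGATAACAATT",
  O2 = "AAATGTGAGCGAGTAACAACC",
  O3 = "GGCAGTGAGCGCAACGCAATT"
)

#' Measured binding energies of the natural lac operators
#'
#' LacI binding energies in kBT for O1, O2 and O3 as determined from
#' repressor titration measurements.
#'
#' @format Named numeric vector (kBT).
#' @export
lac_operator_energies <- c(O1 = -15.3, O2 = -13.9, O3 = -9.7)

DNA_BASES <- c("A", "C", "G", "T")

#' Validate and canonicalize operator sequences
#'
#' Upper-cases input and checks that every character is one of A, C, G, T.
#' Ambiguity codes are rejected: an additive energy matrix scores definite
#' bases only.
#'
#' @param x Character vector of DNA sequences.
#' @param length Optional required length; an error names both lengths when
#'   violated.
#' @return Character vector of validated uppercase sequences.
#' @export
as_operator_seq <- function(x, length = NULL) {
  if (!is.character(x)) {
    stop("sequences must be supplied as character strings", call. = FALSE)
  }
  x <- toupper(x)
  bad <- regexpr("[^ACGT]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf(
      "invalid base '%s' at position %d of sequence %d (only A/C/G/T allowed)",
      substr(x[i], bad[i], bad[i]), bad[i], i
    ), call. = FALSE)
  }
  if (!is.null(length)) {
    len <- nchar(x)
    if (any(len != length)) {
      i <- which(len != length)[1L]
      stop(sprintf(
        "sequence %d has length %d but length %d is required",
        i, len[i], as.integer(length)
      ), call. = FALSE)
    }
  }
  x
}

# integer encoding: n x L matrix with A=1, C=2, G=3, T=4
encode_seqs <- function(seqs) {
  seqs <- as_operator_seq(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) {
    stop("all sequences must have equal length", call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), ncol = L, byrow = TRUE)
  matrix(match(chars, DNA_BASES), nrow = length(seqs), ncol = L)
}

decode_seqs <- function(idx) {
  apply(idx, 1L, function(row) paste(DNA_BASES[row], collapse = ""))
}

#' Hamming distance between equal-length sequences
#'
#' Counts mismatched positions. Among the natural lac operators,
#' `hamming_distance(lac_operators["O1"], lac_operators["O2"])` is 5 and
#' O2 vs O3 is 11.
#'
#' @param a,b DNA sequences (character, vectorized with recycling of length-1
#'   arguments).
#' @return Integer vector of mismatch counts.
#' @export
hamming_distance <- function(a, b) {
  a <- as_operator_seq(a)
  b <- as_operator_seq(b)
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  if (length(a) != length(b)) {
    stop("a and b must have the same number of sequences", call. = FALSE)
  }
  la <- nchar(a); lb <- nchar(b)
  if (any(la != lb)) {
    i <- which(la != lb)[1L]
    stop(sprintf("length mismatch: sequence lengths %d vs %d", la[i], lb[i]),
         call. = FALSE)
  }
  mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, a, b, USE.NAMES = FALSE)
}

#' Read operator sequences from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A tibble with columns `name` and `sequence` (validated uppercase).
#' @export
read_operator_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  tibble::tibble(
    name = unname(vapply(recs, function(r) attr(r, "name"), character(1))),
    sequence = as_operator_seq(unname(vapply(recs, function(r)
      as.character(r[1]), character(1))))
  )
}

#' Enumerate all single-base mutants of a sequence
#'
#' A 21-bp site has exactly 63 single mutants (3 per position).
#'
#' @param ref Reference sequence.
#' @return Tibble with columns `sequence`, `position`, `ref_base`, `mut_base`.
#' @export
enumerate_single_mutants <- function(ref) {
  ref <- as_operator_seq(ref)
  stopifnot(length(ref) == 1L)
  L <- nchar(ref)
  ref_chars <- strsplit(ref, "")[[1]]
  out <- purrr::map_dfr(seq_len(L), function(i) {
    alts <- setdiff(DNA_BASES, ref_chars[i])
    tibble::tibble(
      position = i,
      ref_base = ref_chars[i],
      mut_base = alts,
      sequence = vapply(alts, function(b) {
        s <- ref_chars; s[i] <- b; paste(s, collapse = "")
      }, character(1))
    )
  })
  dplyr::select(out, "sequence", "position", "ref_base", "mut_base")
}

#' Thermal energy in kcal/mol
#'
#' Converts 1 kBT to kcal/mol at a given temperature; at 37 deg C this is
#' about 0.62 kcal/mol.
#'
#' @param temp_celsius Temperature in degrees Celsius (default 37).
#' @return kBT expressed in kcal/mol.
#' @export
kbt_to_kcal_per_mol <- function(temp_celsius = 37) {
  # gas constant R = N_A * k_B = 1.987204 cal/(mol K)
  1.987204e-3 * (temp_celsius + 273.15)
}
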