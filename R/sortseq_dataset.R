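#' Construct a Sort-Seq dataset
#'
#' A Sort-Seq dataset is a table of (sequence, expression bin, read count)
#' records from a sorted, sequenced mutant library, plus the number of
#' sorting bins and the reference sequence the library was mutagenized
#' from. Bins are 0-based integers ordered by expression (0 = lowest).
#'
#' @param records Data frame with columns `sequence`, `bin`, `count`.
#' @param n_bins Number of sorting bins B (4 in a standard experiment).
#' @param ref_seq Reference ("wild-type") operator sequence.
#' @return A tibble of class `sortseq_dataset` carrying `n_bins` and
#'   `ref_seq` attributes.
#' @export
sortseq_dataset <- function(records, n_bins = 4L, ref_seq) {
  stopifnot(is.data.frame(records),
            all(c("sequence", "bin", "count") %in% names(records)))
  ref_seq <- as_operator_seq(ref_seq)
  seqs <- as_operator_seq(records$sequence, length = nchar(ref_seq))
  bin <- as.integer(records$bin)
  count <- as.integer(records$count)
  if (any(bin < 0L | bin >= n_bins)) {
    stop(sprintf("bins must lie in [0, %d)", n_bins), call. = FALSE)
  }
  if (any(count <= 0L)) stop("counts must be positive", call. = FALSE)
  if (sum(count) <= 0L) stop("dataset is empty", call. = FALSE)
  out <- tibble::tibble(sequence = seqs, bin = bin, count = count)
  structure(out, n_bins = as.integer(n_bins), ref_seq = ref_seq,
            class = c("sortseq_dataset", class(tibble::tibble())))
}

#' @export
print.sortseq_dataset <- function(x, ...) {
  cat(sprintf("<sortseq_dataset> %d records, N = %d reads, %d bins, reference %s\n",
              nrow(x), sum(x$count), attr(x, "n_bins"), attr(x, "ref_seq")))
  NextMethod()
}

#' Write a Sort-Seq dataset to TSV
#'
#' Format: `# n_bins=` and `# reference=` comment lines, then a
#' tab-separated `sequence  bin  count` table with header.
#'
#' @param ds A [sortseq_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sortseq_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "sortseq_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_bins=%d", attr(ds, "n_bins")),
               sprintf("# reference=%s", attr(ds, "ref_seq")),
               "sequence\tbin\tcount"), con)
  writeLines(sprintf("%s\t%d\t%d", ds$sequence, ds$bin, ds$count), con)
  invisible(path)
}

#' Read a Sort-Seq dataset from TSV
#'
#' Validates the alphabet and bin range; a malformed row fails with its
#' line number.
#'
#' @param path Input path (format of [write_sortseq_tsv()]).
#' @return A [sortseq_dataset()].
#' @export
read_sortseq_tsv <- function(path) {
  lines <- readLines(path)
  meta <- list()
  for (ln in grep("^#", lines, value = TRUE)) {
    kv <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", ln))[[1]]
    if (length(kv) == 3L) meta[[kv[2]]] <- kv[3]
  }
  body_at <- which(!grepl("^#", lines))
  body <- lines[body_at]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    bad <- which(nf != 3L)[1L]
    stop(sprintf("malformed dataset row at line %d: expected 3 tab-separated fields, got %d",
                 body_at[bad], nf[bad]), call. = FALSE)
  }
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer", "integer"))
  if (is.null(meta$reference)) {
    stop("dataset TSV is missing the '# reference=' header", call. = FALSE)
  }
  sortseq_dataset(tab, n_bins = as.integer(meta$n_bins %||% 4L),
                  ref_seq = meta$reference)
}

#' Split a Sort-Seq dataset into replicate groups
#'
#' Randomly partitions the records into `k` disjoint groups of equal size
#' (within one record), each carrying the full dataset's metadata. Used to
#' build replicate energy matrices from one experiment.
#'
#' @param ds A [sortseq_dataset()].
#' @param k Number of groups (default 3).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return List of `k` [sortseq_dataset()] objects.
#' @export
split_replicates <- function(ds, k = 3L, seed = 1L) {
  stopifnot(inherits(ds, "sortseq_dataset"), nrow(ds) >= k)
  perm <- withr::with_seed(seed, sample.int(nrow(ds)))
  grp <- rep_len(seq_len(k), nrow(ds))[order(perm)]
  lapply(seq_len(k), function(g) {
    sortseq_dataset(ds[grp == g, , drop = FALSE],
                    n_bins = attr(ds, "n_bins"), ref_seq = attr(ds, "ref_seq"))
  })
}
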