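# Enzyme candidate screening: ortholog thresholding, neighbor-joining
# phylogeny over a distance matrix, and hydropathy-based N-terminal
# membrane-anchor detection / truncation design for P450 expression hosts.

#' Filter ortholog hits by score and similarity thresholds
#'
#' Keeps rows with alignment score strictly greater than `score_threshold`
#' AND percent similarity strictly greater than `similarity_threshold`
#' (defaults 1030 and 39, the screening thresholds used for the CYP79
#' ortholog search; both overridable).
#'
#' @param table A data frame with columns `query`, `subject`, `score`,
#'   `similarity`, or a path to a TSV file with those columns.
#' @param score_threshold Numeric, strict lower bound on `score`.
#' @param similarity_threshold Numeric, strict lower bound on `similarity`
#'   (percent).
#' @return The accepted rows (possibly zero rows).
#' @export
filter_orthologs <- function(table, score_threshold = 1030,
                             similarity_threshold = 39) {
  if (is.character(table)) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  }
  need <- c("query", "subject", "score", "similarity")
  if (!all(need %in% names(table))) {
    stop("ortholog table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) == 0L) return(table)
  bad <- which(!is.finite(table$score) | !is.finite(table$similarity))
  if (length(bad)) {
    stop("malformed ortholog table row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  table[table$score > score_threshold &
          table$similarity > similarity_threshold, , drop = FALSE]
}

read_aligned_fasta <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    aln <- Biostrings::readAAStringSet(x)
    seqs <- stats::setNames(as.character(aln), names(aln))
  } else if (is.character(x) && !is.null(names(x))) {
    seqs <- x
  } else {
    stop("expected a FASTA path or a named character vector of sequences",
         call. = FALSE)
  }
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned sequences must all have equal length", call. = FALSE)
  }
  toupper(seqs)
}

#' Pairwise p-distances from an alignment
#'
#' Computes `d(i, j) = mismatches / positions compared` over an aligned set
#' of sequences, excluding gap-containing columns pairwise (a column is
#' skipped for a pair when either sequence has `-` or `.` there).
#'
#' @param x Path to an aligned FASTA file, or a named character vector of
#'   equal-length aligned sequences (at least 3).
#' @return A symmetric numeric matrix with zero diagonal and the sequence
#'   names as labels.
#' @export
p_distance <- function(x) {
  seqs <- read_aligned_fasta(x)
  n <- length(seqs)
  if (n < 3L) stop("need at least 3 sequences", call. = FALSE)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  gap <- lapply(chars, function(v) v %in% c("-", "."))
  dm <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- !(gap[[i]] | gap[[j]])
      if (!any(use)) stop(sprintf(
        "sequences %s and %s share no gap-free columns",
        names(seqs)[i], names(seqs)[j]), call. = FALSE)
      d <- sum(chars[[i]][use] != chars[[j]][use]) / sum(use)
      dm[i, j] <- d; dm[j, i] <- d
    }
  }
  dm
}

validate_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(dm)) || anyDuplicated(rownames(dm))) {
    stop("distance matrix needs unique row/column labels", call. = FALSE)
  }
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(dm)) > 1e-12)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  if (any(dm < 0)) stop("distances must be non-negative", call. = FALSE)
  invisible(dm)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on a validated symmetric
#' distance matrix. Negative branch lengths, which NJ can produce on
#' non-additive inputs, are clamped to zero and flagged via the
#' `clamped_branches` attribute.
#'
#' @param dm A symmetric numeric matrix with zero diagonal and unique
#'   labels (n >= 3), e.g. from [p_distance()] or [read_distance_tsv()].
#' @return An unrooted `phylo` tree (see \pkg{ape}); write it with
#'   [ape::write.tree()] for Newick output.
#' @export
nj_tree <- function(dm) {
  validate_distance_matrix(dm)
  if (nrow(dm) < 3L) stop("need at least 3 taxa", call. = FALSE)
  tree <- ape::nj(stats::as.dist(dm))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    warning(sprintf("%d negative NJ branch length(s) clamped to 0", sum(neg)))
    tree$edge.length[neg] <- 0
  }
  attr(tree, "clamped_branches") <- sum(neg)
  tree
}

#' Read / write a square distance matrix as TSV
#'
#' PHYLIP-style square matrix with a header row and label column.
#'
#' @param path File path.
#' @return `read_distance_tsv` returns a labeled numeric matrix.
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  dm <- as.matrix(df)
  colnames(dm) <- colnames(df)
  validate_distance_matrix(dm)
  dm
}

#' @rdname read_distance_tsv
#' @param dm A labeled square matrix.
#' @export
write_distance_tsv <- function(dm, path) {
  validate_distance_matrix(dm)
  df <- data.frame(label = rownames(dm), dm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Kyte-Doolittle hydropathy scale
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Sliding-window hydropathy profile
#'
#' Mean Kyte-Doolittle hydropathy over a sliding window. Non-standard
#' residues raise an error rather than being skipped.
#'
#' @param sequence Amino-acid sequence (single string, 20-letter alphabet).
#' @param window Window size in residues (default 19, a typical
#'   transmembrane-helix span).
#' @return Numeric vector of length `nchar(sequence) - window + 1`; entry
#'   `k` is the mean hydropathy of residues `k .. k + window - 1`.
#' @export
hydropathy_profile <- function(sequence, window = 19L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(res), names(KYTE_DOOLITTLE))
  if (length(bad)) {
    stop("non-standard residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(res) < window) {
    stop("sequence shorter than the window", call. = FALSE)
  }
  h <- KYTE_DOOLITTLE[res]
  cs <- cumsum(c(0, unname(h)))
  unname(cs[(window + 1):length(cs)] - cs[1:(length(cs) - window)]) / window
}

#' Detect an N-terminal hydrophobic membrane anchor
#'
#' Scans the Kyte-Doolittle windowed-mean profile for the first maximal run
#' of windows at or above `threshold` whose start lies within the first
#' `limit` residues, and expands it to 1-based inclusive residue
#' coordinates. This is the stand-in the package uses for transmembrane
#' N-terminus prediction when designing P450 truncations.
#'
#' @inheritParams hydropathy_profile
#' @param threshold Minimum mean hydropathy for a window to count
#'   (default 1.6).
#' @param limit Only anchors starting within the first `limit` residues
#'   are considered (default 60).
#' @return Integer vector `c(start, end)` in residue coordinates, or
#'   `NULL` when no anchor is found.
#' @export
detect_nterm_anchor <- function(sequence, window = 19L, threshold = 1.6,
                                limit = 60L) {
  prof <- hydropathy_profile(sequence, window)
  hot <- prof >= threshold
  if (!any(hot)) return(NULL)
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & starts <= limit)
  if (length(runs) == 0L) return(NULL)
  k <- runs[1]
  c(start = starts[k], end = ends[k] + window - 1L)
}

#' Truncate a hydrophobic N-terminus
#'
#' Removes residues `1 .. segment["end"]` and prepends an initiator
#' methionine, the standard redesign for soluble bacterial expression of
#' membrane-anchored P450s. With `segment = NULL` the sequence is returned
#' unchanged.
#'
#' @param sequence Amino-acid sequence (single string).
#' @param segment A `c(start, end)` segment from [detect_nterm_anchor()],
#'   or `NULL`.
#' @return The truncated sequence (length `nchar(sequence) - end + 1`).
#' @export
truncate_nterm <- function(sequence, segment) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.null(segment)) return(sequence)
  end <- as.integer(segment[["end"]])
  if (is.na(end) || end < 1L || end >= nchar(sequence)) {
    stop("truncation segment out of bounds", call. = FALSE)
  }
  paste0("M", substr(sequence, end + 1L, nchar(sequence)))
}
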