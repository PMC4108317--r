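#' Pairwise global alignment with affine gaps
#'
#' Needleman–Wunsch alignment under an affine gap model: a gap run of length
#' L costs `gap_open + L * gap_extend` (both penalties are non-positive).
#' Traceback ties prefer the diagonal move, then a gap in `b`, then a gap in
#' `a`, so the result is deterministic.
#'
#' @param a,b Protein [seq_record] objects or residue strings.
#' @param matrix Substitution matrix over the 20 amino acids (default
#'   BLOSUM62 from Biostrings). `X` scores 0 against everything.
#' @param gap_open,gap_extend Gap penalties, `<= 0` (defaults -10, -1).
#' @return A `pairwise_alignment`: gapped rows of equal length, the optimal
#'   score, and the parameters used.
#' @export
pairwise_align <- function(a, b, matrix = blosum62(), gap_open = -10,
                           gap_extend = -1) {
  sa <- if (inherits(a, "seq_record")) a$residues else toupper(a)
  sb <- if (inherits(b, "seq_record")) b$residues else toupper(b)
  if (nchar(sa) == 0 || nchar(sb) == 0)
    stop("cannot align an empty sequence")
  stopifnot(gap_open <= 0, gap_extend <= 0)
  fa <- seq_profile(sa)
  fb <- seq_profile(sb)
  res <- profile_align_cpp(fa, fb, matrix, gap_open, gap_extend)
  rows <- ops_to_rows(res$ops, list(sa), list(sb))
  structure(list(row_a = rows$a[[1]], row_b = rows$b[[1]],
                 score = res$score,
                 matrix_name = attr(matrix, "name") %||% "BLOSUM62",
                 gap_open = gap_open, gap_extend = gap_extend,
                 id_a = if (inherits(a, "seq_record")) a$id else "a",
                 id_b = if (inherits(b, "seq_record")) b$id else "b"),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment %s / %s: score %.1f over %d columns\n",
              x$id_a, x$id_b, x$score, nchar(x$row_a)))
  invisible(x)
}

# one-hot 20 x L profile for a residue string; X (or unknown) -> zero column
seq_profile <- function(s) {
  ch <- strsplit(s, "")[[1]]
  idx <- match(ch, AA_ALPHABET)
  m <- matrix(0, nrow = 20, ncol = length(ch))
  ok <- !is.na(idx)
  m[cbind(idx[ok], which(ok))] <- 1
  m
}

# apply an ops vector (0 = both, 1 = A-only, 2 = B-only) to gapped row sets
ops_to_rows <- function(ops, rows_a, rows_b) {
  na <- sum(ops != 2); nb <- sum(ops != 1)
  pos_a <- cumsum(ops != 2); pos_b <- cumsum(ops != 1)
  take <- function(rows, present, pos) {
    lapply(rows, function(r) {
      ch <- strsplit(r, "")[[1]]
      out <- rep("-", length(ops))
      out[present] <- ch[pos[present]]
      paste(out, collapse = "")
    })
  }
  list(a = take(rows_a, ops != 2, pos_a),
       b = take(rows_b, ops != 1, pos_b))
}

#' Percent identity and similarity of an alignment
#'
#' Identity: columns where both rows carry the same residue. Similarity:
#' columns that are identical or whose residue pair has a positive
#' substitution score (the "+" convention). Both are percentages of all
#' alignment columns, including gapped ones.
#'
#' @param aln A [pairwise_align] result.
#' @param matrix Substitution matrix (default BLOSUM62).
#' @return Named numeric vector `c(identity, similarity)` in percent,
#'   unrounded.
#' @export
identity_similarity <- function(aln, matrix = blosum62()) {
  ca <- strsplit(aln$row_a, "")[[1]]
  cb <- strsplit(aln$row_b, "")[[1]]
  n <- length(ca)
  ia <- match(ca, AA_ALPHABET); ib <- match(cb, AA_ALPHABET)
  both <- !is.na(ia) & !is.na(ib)
  ident <- both & ca == cb
  pos <- rep(FALSE, n)
  pos[both] <- matrix[cbind(ia[both], ib[both])] > 0
  c(identity = 100 * sum(ident) / n,
    similarity = 100 * sum(ident | pos) / n)
}

# fractional identity over all columns of the optimal global alignment
pair_fid <- function(sa, sb, matrix, gap_open, gap_extend) {
  aln <- pairwise_align(sa, sb, matrix, gap_open, gap_extend)
  unname(identity_similarity(aln, matrix)["identity"]) / 100
}

#' Multiple sequence alignment container
#'
#' @param ids Character vector of row ids.
#' @param rows Gapped residue strings, all the same length.
#' @return An `msa` object.
#' @export
msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows), length(rows) >= 1)
  n_cols <- unique(nchar(rows))
  if (length(n_cols) != 1) stop("MSA rows differ in length")
  structure(list(ids = ids, rows = rows, n_cols = n_cols), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns\n", length(x$rows), x$n_cols))
  invisible(x)
}

#' Progressive multiple alignment
#'
#' Pairwise fractional identities define distances (1 - identity); a UPGMA
#' guide tree (average-linkage `hclust`) is traversed leaf-to-root, merging
#' groups by affine-gap profile–profile alignment (column score = mean
#' substitution score over residue pairs, gaps excluded). Deterministic for
#' a fixed input order; row order is preserved from the input. Two sequences
#' reduce exactly to [pairwise_align]; one sequence is returned ungapped.
#'
#' @param seqs List of protein [seq_record] objects (length >= 1).
#' @inheritParams pairwise_align
#' @return An [msa].
#' @export
progressive_msa <- function(seqs, matrix = blosum62(), gap_open = -10,
                            gap_extend = -1) {
  n <- length(seqs)
  if (n < 1) stop("need at least one sequence")
  ids <- seq_ids(seqs)
  strs <- seq_strings(seqs)
  if (any(nchar(strs) == 0)) stop("cannot align an empty sequence")
  if (n == 1) return(msa(ids, strs))
  if (n == 2) {
    aln <- pairwise_align(seqs[[1]], seqs[[2]], matrix, gap_open, gap_extend)
    return(msa(ids, c(aln$row_a, aln$row_b)))
  }
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- 1 - pair_fid(strs[i], strs[j], matrix,
                                       gap_open, gap_extend)
  }
  tree <- hclust(as.dist(d), method = "average")

  nodes <- lapply(seq_len(n), function(i) list(idx = i, rows = strs[i]))
  merged <- vector("list", nrow(tree$merge))
  get_node <- function(k) if (k < 0) nodes[[-k]] else merged[[k]]
  for (m in seq_len(nrow(tree$merge))) {
    left <- get_node(tree$merge[m, 1])
    right <- get_node(tree$merge[m, 2])
    fa <- rows_profile(left$rows)
    fb <- rows_profile(right$rows)
    res <- profile_align_cpp(fa, fb, matrix, gap_open, gap_extend)
    rows <- ops_to_rows(res$ops, as.list(left$rows), as.list(right$rows))
    merged[[m]] <- list(idx = c(left$idx, right$idx),
                        rows = c(unlist(rows$a), unlist(rows$b)))
  }
  final <- merged[[nrow(tree$merge)]]
  ord <- order(final$idx)
  msa(ids[final$idx][ord], final$rows[ord])
}

# residue frequency profile of a set of gapped rows (20 x n_cols);
# columns are normalised over non-gap residues
rows_profile <- function(rows) {
  chm <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(chm)
  m <- matrix(0, nrow = 20, ncol = L)
  for (j in seq_len(L)) {
    idx <- match(chm[, j], AA_ALPHABET)
    idx <- idx[!is.na(idx)]
    if (length(idx) > 0) {
      tab <- tabulate(idx, nbins = 20)
      m[, j] <- tab / length(idx)
    }
  }
  m
}

#' Read / write an aligned FASTA file
#'
#' Gaps are `-`. `read_msa` allows substituting an externally computed
#' alignment for [progressive_msa].
#'
#' @param path Aligned FASTA file.
#' @return An [msa].
#' @export
read_msa <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  msa(sub("[[:space:]].*$", "", names(ss)),
      unname(toupper(as.character(ss))))
}

#' @rdname read_msa
#' @param aln An [msa].
#' @export
write_msa <- function(aln, path) {
  ss <- Biostrings::BStringSet(setNames(aln$rows, aln$ids))
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

# de-gap an MSA row
degap <- function(row) gsub("-", "", row, fixed = TRUE)
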