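#' Sequence records
#'
#' A minimal sequence record: an identifier, an optional free-text
#' description, a residue string and its alphabet. Sets of sequences are
#' plain lists of these records; converters to and from
#' [Biostrings::XStringSet] objects are used internally for file I/O.
#'
#' @param id Record identifier; must contain no whitespace.
#' @param residues Residue string (upper case; `N` is the only nucleotide
#'   ambiguity code kept verbatim, `X` the only protein one).
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param description Free text carried after the id on the FASTA header.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues, alphabet = c("protein", "nucleotide"),
                       description = "") {
  alphabet <- match.arg(alphabet)
  if (grepl("[[:space:]]", id)) stop("sequence id contains whitespace: ", id)
  structure(list(id = id, description = description,
                 residues = toupper(residues), alphabet = alphabet),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<%s> %s (%d %s residues)\n", x$alphabet, x$id,
              nchar(x$residues),
              if (x$alphabet == "protein") "aa" else "nt"))
  invisible(x)
}

#' Accessors for lists of sequence records
#'
#' @param seqs List of [seq_record] objects.
#' @return Character vector of ids / residue strings, or integer lengths.
#' @export
seq_ids <- function(seqs) vapply(seqs, `[[`, "", "id")

#' @rdname seq_ids
#' @export
seq_strings <- function(seqs) vapply(seqs, `[[`, "", "residues")

#' @rdname seq_ids
#' @export
seq_lengths <- function(seqs) nchar(seq_strings(seqs))

# characters tolerated per alphabet; anything else is coerced to the
# ambiguity code with a warning
.allowed <- list(nucleotide = c("A", "C", "G", "T", "N"),
                 protein = c(AA_ALPHABET, "X"))

sanitize_residues <- function(residues, alphabet) {
  residues <- toupper(residues)
  amb <- if (alphabet == "nucleotide") "N" else "X"
  pat <- paste0("[^", paste(.allowed[[alphabet]], collapse = ""), "]")
  n_bad <- sum(grepl(pat, residues))
  if (n_bad > 0) {
    warning(n_bad, " record(s) contained symbols outside the ", alphabet,
            " alphabet; coerced to '", amb, "'")
    residues <- gsub(pat, amb, residues)
  }
  residues
}

#' Read a FASTA file
#'
#' Record order is preserved, residues are upper-cased, and a single terminal
#' `*` (a translated stop) is stripped. Symbols outside the declared alphabet
#' (beyond the ambiguity codes `N`/`X`) are coerced to the ambiguity code
#' with a warning.
#'
#' @param path FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return List of [seq_record] objects (empty, with a warning, for an empty
#'   file). Duplicate ids are an error.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  res <- sub("\\*$", "", toupper(as.character(ss)))
  res <- sanitize_residues(res, alphabet)
  mapply(function(i, d, r) seq_record(i, r, alphabet, d),
         ids, desc, res, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs List of [seq_record] objects.
#' @param path Output file.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  ss <- Biostrings::BStringSet(setNames(seq_strings(seqs), seq_ids(seqs)))
  dsc <- vapply(seqs, `[[`, "", "description")
  names(ss) <- ifelse(nzchar(dsc), paste(seq_ids(seqs), dsc), seq_ids(seqs))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Translate a nucleotide sequence
#'
#' Codons are translated with the chosen NCBI genetic code; stops are
#' rendered as `*`. Codons containing `N` translate to `X` unless the residue
#' is determined regardless of the ambiguity. No initiator-codon special
#' casing is applied (getorf-style translation).
#'
#' @param nt A [seq_record] (nucleotide) or a nucleotide string.
#' @param table_id NCBI genetic code: 1 (standard) or 11 (bacteria/archaea,
#'   the default for prokaryote-dominated metagenomes).
#' @return Protein string.
#' @export
translate_seq <- function(nt, table_id = 11) {
  s <- if (inherits(nt, "seq_record")) nt$residues else toupper(nt)
  if (!table_id %in% c(1, 11)) stop("table_id must be 1 or 11")
  if (nchar(s) %% 3 != 0)
    stop("sequence length not divisible by 3: ", nchar(s))
  if (nchar(s) == 0) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(s),
    genetic.code = Biostrings::getGeneticCode(as.character(table_id)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
}

# translate several frames in one call; x: character vector of in-frame nt
translate_batch <- function(x, table_id = 11) {
  keep <- nchar(x) > 0
  out <- character(length(x))
  if (any(keep)) {
    out[keep] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(x[keep]),
      genetic.code = Biostrings::getGeneticCode(as.character(table_id)),
      if.fuzzy.codon = "solve", no.init.codon = TRUE))
  }
  out
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Extract open reading frames from a contig
#'
#' Stop-to-stop convention: in each of the six reading frames, an ORF is a
#' maximal stop-free run of codons between stop codons (or the sequence
#' ends). Reverse-strand coordinates are reported on the forward strand,
#' 0-based half-open; `frame` is the offset (0, 1, 2) within the strand read.
#' Codons containing `N` translate to `X` and do not split an ORF.
#'
#' @param contig A nucleotide [seq_record].
#' @param min_aa Minimum protein length to report (default 30).
#' @param table_id Genetic code (default 11).
#' @return `data.frame` with columns `contig_id`, `strand`, `frame`, `start`,
#'   `end`, `protein`, sorted by (`start`, `strand`, `frame`).
#' @export
extract_orfs <- function(contig, min_aa = 30, table_id = 11) {
  stopifnot(inherits(contig, "seq_record"))
  if (contig$alphabet != "nucleotide") stop("contig must be nucleotide")
  if (min_aa < 1) stop("min_aa must be >= 1")
  L <- nchar(contig$residues)
  empty <- data.frame(contig_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      protein = character(), stringsAsFactors = FALSE)
  if (L < 3 * min_aa) return(empty)

  fwd <- contig$residues
  rev <- revcomp(fwd)
  frames <- character(6)
  for (f in 0:2) {
    n_codon <- (L - f) %/% 3
    frames[f + 1] <- if (n_codon > 0) substr(fwd, f + 1, f + 3 * n_codon) else ""
    frames[f + 4] <- if (n_codon > 0) substr(rev, f + 1, f + 3 * n_codon) else ""
  }
  prots <- translate_batch(frames, table_id)

  rows <- vector("list", 6)
  for (k in seq_len(6)) {
    p <- prots[k]
    if (!nzchar(p)) next
    f <- (k - 1) %% 3
    strand <- if (k <= 3) "+" else "-"
    # maximal stop-free runs as codon index ranges (0-based, inclusive)
    segs <- strsplit(p, "*", fixed = TRUE)[[1]]
    if (length(segs) == 0) next
    lens <- nchar(segs)
    starts <- cumsum(c(0L, head(lens, -1) + 1L))  # codon index of run start
    keep <- lens >= min_aa
    if (!any(keep)) next
    k1 <- starts[keep]
    k2 <- k1 + lens[keep] - 1L
    s_local <- f + 3L * k1          # on the read strand
    e_local <- f + 3L * (k2 + 1L)
    if (strand == "+") {
      start <- s_local; end <- e_local
    } else {
      start <- L - e_local; end <- L - s_local
    }
    rows[[k]] <- data.frame(contig_id = contig$id, strand = strand,
                            frame = f, start = as.integer(start),
                            end = as.integer(end),
                            protein = segs[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) return(empty)
  out <- out[order(out$start, out$strand, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ORF table to protein sequence records
#'
#' Ids follow the convention `contigID_start_end_strand_frame`.
#'
#' @param orfs Output of [extract_orfs] (rows from any number of contigs).
#' @return List of protein [seq_record] objects.
#' @export
orfs_to_seqs <- function(orfs) {
  if (nrow(orfs) == 0) return(list())
  ids <- sprintf("%s_%d_%d_%s_%d", orfs$contig_id, orfs$start, orfs$end,
                 orfs$strand, orfs$frame)
  mapply(seq_record, ids, orfs$protein,
         MoreArgs = list(alphabet = "protein"),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write an ORF table
#'
#' Six-column tab-separated table (`contig_id`, `strand`, `frame`, `start`,
#' `end`, `protein`).
#'
#' @param orfs Output of [extract_orfs].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_orf_table <- function(orfs, path) {
  write.table(orfs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
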