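#' Synthetic families, metagenomes and proteomes with known ground truth
#'
#' The generators in this module emulate the data the telescope consumes —
#' a conserved seed family, metagenome contigs carrying divergent homologs
#' among random decoys, and proteomes holding close homologs, remote
#' homologs and decoys — with every sequence labelled, so that the
#' pipeline's sensitivity claims can be evaluated against known truth.
#'
#' Substitution model: a substituted site receives a residue *different*
#' from the current one, drawn from the BLOSUM62-conditional distribution
#' `P(b | a) proportional to p_b * 2^(S_ab / 2)`. Excluding the original
#' residue makes expected per-branch identity essentially `1 - divergence`,
#' which keeps the transitive-chain geometry analytically tractable.
#'
#' @name synthetic
NULL

# conditional substitution matrix P(b | a), zero diagonal, rows sum to 1
blosum_conditional <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    S <- blosum62()
    C <- sweep(2^(S / 2), 2, AA_BACKGROUND, "*")
    diag(C) <- 0
    C <- C / rowSums(C)
    cache <<- C
    C
  }
})

#' Family generator specification
#'
#' @param M Model (ancestor) length in residues.
#' @param n_seed Number of seed sequences (>= 2).
#' @param divergence Expected fraction of substituted sites per branch,
#'   in `[0, 1)`.
#' @param indel_rate Per-site probability of an indel event per branch.
#' @param seed RNG seed.
#' @return A `family_spec` list.
#' @export
family_spec <- function(M = 140, n_seed = 12, divergence = 0.08,
                        indel_rate = 0.01, seed = 1) {
  stopifnot(n_seed >= 2, divergence >= 0, divergence < 1, M >= 1)
  structure(list(M = M, n_seed = n_seed, divergence = divergence,
                 indel_rate = indel_rate, seed = seed),
            class = "family_spec")
}

# random site-wise generative profile: each site mixes a consensus residue
# (weight = its conservation, uniform in [0.5, 0.95]) with background
sample_site_profile <- function(M) {
  cons <- sample.int(20L, M, replace = TRUE, prob = AA_BACKGROUND)
  w <- runif(M, 0.5, 0.95)
  emis <- matrix(rep(AA_BACKGROUND, each = M), nrow = M) * (1 - w)
  emis[cbind(seq_len(M), cons)] <- emis[cbind(seq_len(M), cons)] + w
  emis
}

#' Evolve a protein sequence
#'
#' Applies the BLOSUM62-conditional substitution model (each site
#' substituted independently with probability `divergence`) followed by a
#' geometric indel process: with probability `indel_rate` per site an
#' insertion of geometric(0.5) background residues or a deletion of
#' geometric(0.5) following residues (equally likely). Uses the current
#' RNG state.
#'
#' @param s Residue string.
#' @param divergence Substitution probability per site.
#' @param indel_rate Indel event probability per site.
#' @return Evolved residue string.
#' @export
evolve_protein <- function(s, divergence, indel_rate = 0) {
  C <- blosum_conditional()
  idx <- match(strsplit(s, "")[[1]], AA_ALPHABET)
  idx[is.na(idx)] <- sample.int(20L, sum(is.na(idx)), replace = TRUE,
                                prob = AA_BACKGROUND)
  n <- length(idx)
  sub <- runif(n) < divergence
  if (any(sub)) {
    idx[sub] <- vapply(idx[sub], function(a)
      sample.int(20L, 1, prob = C[a, ]), 0L)
  }
  if (indel_rate > 0 && n > 0) {
    out <- integer(0)
    i <- 1
    while (i <= n) {
      ev <- runif(1) < indel_rate
      if (ev && runif(1) < 0.5) {           # deletion of a geometric run
        i <- i + 1 + stats::rgeom(1, 0.5) + 1
      } else {
        out <- c(out, idx[i])
        if (ev) {                            # insertion after this site
          k <- stats::rgeom(1, 0.5) + 1
          out <- c(out, sample.int(20L, k, replace = TRUE,
                                   prob = AA_BACKGROUND))
        }
        i <- i + 1
      }
    }
    idx <- out
  }
  paste(AA_ALPHABET[idx], collapse = "")
}

# expected identity (and its sd) between two independent descendants of
# `ancestor` at the given per-branch divergence, no indels
expected_sibling_identity <- function(ancestor, divergence) {
  C <- blosum_conditional()
  a <- match(strsplit(ancestor, "")[[1]], AA_ALPHABET)
  coincide <- rowSums(C^2)
  p <- (1 - divergence)^2 + divergence^2 * coincide[a]
  list(mean = mean(p), sd = sqrt(sum(p * (1 - p))) / length(p))
}

#' Sample a seed protein family
#'
#' Draws an ancestor from a random site-wise generative profile, then
#' evolves `n_seed` independent descendants under the substitution + indel
#' model. A `profile_hmm` representation of the generating profile is
#' returned alongside the sequences. Reproducible by `spec$seed`.
#'
#' @param spec A [family_spec].
#' @param prefix Id prefix for the sequences.
#' @return `list(seqs, generator, ancestor)`.
#' @export
sample_family <- function(spec, prefix = "fam") {
  with_seed(spec$seed, {
    emis <- sample_site_profile(spec$M)
    ancestor <- paste(AA_ALPHABET[vapply(seq_len(spec$M), function(j)
      sample.int(20L, 1, prob = emis[j, ]), 0L)], collapse = "")
    seqs <- lapply(seq_len(spec$n_seed), function(k)
      seq_record(sprintf("%s_s%02d", prefix, k),
                 evolve_protein(ancestor, spec$divergence, spec$indel_rate)))
    M <- spec$M
    trans <- matrix(0, M + 1, 7, dimnames = list(NULL, TRANS_COLS))
    trans[, c("MM", "MI", "MD")] <- rep(c(0.96, 0.02, 0.02), each = M + 1)
    trans[, c("IM", "II")] <- rep(c(0.6, 0.4), each = M + 1)
    trans[, c("DM", "DD")] <- rep(c(0.9, 0.1), each = M + 1)
    trans[M + 1, c("MM", "MI")] <- c(0.98, 0.02)
    trans[M + 1, "MD"] <- 0
    trans[M + 1, c("DM", "DD")] <- c(1, 0)
    trans[1, c("DM", "DD")] <- c(1, 0)
    gen <- new_profile_hmm(paste0(prefix, "_generator"), emis,
                           matrix(rep(AA_BACKGROUND, each = M + 1), M + 1),
                           trans)
    list(seqs = seqs, generator = gen, ancestor = ancestor)
  })
}

# random synonymous reverse translation (stops never used)
reverse_translate <- function(protein, table_id = 11) {
  code <- Biostrings::getGeneticCode(as.character(table_id))
  by_aa <- split(names(code), code)
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- by_aa[[a]]
    if (is.null(cods)) cods <- by_aa[["X"]] %||% "NNN"
    cods[sample.int(length(cods), 1)]
  }, ""), collapse = "")
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

#' Generate a synthetic metagenome
#'
#' Implanted homologs are evolved from a random member of each family,
#' reverse-translated with random synonymous codons, and embedded mid-contig
#' between random nucleotide flanks; half the implant contigs are
#' reverse-complemented so both strands occur. Because implant codons never
#' include a stop, each implanted protein is contained in some stop-to-stop
#' ORF of its contig. Decoy contigs are i.i.d. nucleotides.
#'
#' @param families Named list; each element is a list of protein
#'   [seq_record]s or a single residue string to implant from.
#' @param n_decoy_contigs Number of decoy contigs.
#' @param implant_divergence Divergence applied to each implant.
#' @param seed RNG seed.
#' @param n_implants Implants per family (default 20).
#' @param contig_len_range Decoy contig length range (nt).
#' @param flank_range Flank length range (nt) around implants.
#' @param table_id Genetic code for reverse translation.
#' @return `list(contigs, labels)`; `labels` is
#'   `data.frame(id, label, family)` with implant contigs labelled
#'   `"implant"` and decoys `"decoy"`.
#' @export
make_metagenome <- function(families, n_decoy_contigs = 100,
                            implant_divergence = 0.08, seed = 1,
                            n_implants = 20,
                            contig_len_range = c(600, 1200),
                            flank_range = c(30, 150), table_id = 11) {
  with_seed(seed, {
    contigs <- list()
    implants <- character()
    labels <- data.frame(id = character(), label = character(),
                         family = character(), strand = character(),
                         stringsAsFactors = FALSE)
    for (fam in names(families)) {
      src <- families[[fam]]
      pool <- if (is.character(src)) list(src) else lapply(src, `[[`, "residues")
      for (k in seq_len(n_implants)) {
        prot <- evolve_protein(pool[[sample.int(length(pool), 1)]],
                               implant_divergence)
        nt <- reverse_translate(prot, table_id)
        f1 <- random_nt(sample(flank_range[1]:flank_range[2], 1))
        f2 <- random_nt(sample(flank_range[1]:flank_range[2], 1))
        contig <- paste0(f1, nt, f2)
        strand <- if (runif(1) < 0.5) "-" else "+"
        if (strand == "-") contig <- revcomp(contig)
        id <- sprintf("mg_%s_i%03d", fam, k)
        contigs[[length(contigs) + 1]] <-
          seq_record(id, contig, alphabet = "nucleotide")
        implants[id] <- prot
        labels <- rbind(labels, data.frame(id = id, label = "implant",
                                           family = fam, strand = strand))
      }
    }
    for (k in seq_len(n_decoy_contigs)) {
      id <- sprintf("mg_decoy_%04d", k)
      contigs[[length(contigs) + 1]] <- seq_record(
        id, random_nt(sample(contig_len_range[1]:contig_len_range[2], 1)),
        alphabet = "nucleotide")
      labels <- rbind(labels, data.frame(id = id, label = "decoy",
                                         family = NA_character_,
                                         strand = NA_character_))
    }
    list(contigs = contigs, labels = labels, implant_proteins = implants)
  })
}

#' Generate a synthetic proteome
#'
#' Close homologs are evolved directly from each family ancestor; remote
#' homologs from the supplied remote ancestors (the far end of a transitive
#' chain built with [make_chain]); decoys are i.i.d. background proteins.
#'
#' @param families Named list of family ancestor residue strings.
#' @param n_close,n_remote,n_decoy Counts per family (decoys are shared).
#' @param divergences `list(close, within)`: divergence of close homologs
#'   from the family ancestor and of remote homologs from their remote
#'   ancestor.
#' @param seed RNG seed.
#' @param remote_ancestors Named list of remote ancestor strings (same
#'   names as `families`); omit to generate no remote homologs.
#' @param decoy_len_range Decoy protein length range (residues).
#' @return `list(seqs, labels)` with labels in
#'   `{close_homolog, remote_homolog, decoy}`.
#' @export
make_proteome <- function(families, n_close = 3, n_remote = 5,
                          n_decoy = 200,
                          divergences = list(close = 0.12, within = 0.08),
                          seed = 1, remote_ancestors = NULL,
                          decoy_len_range = c(80, 300)) {
  with_seed(seed, {
    seqs <- list()
    labels <- data.frame(id = character(), label = character(),
                         family = character(), stringsAsFactors = FALSE)
    add <- function(id, res, label, fam) {
      seqs[[length(seqs) + 1]] <<- seq_record(id, res)
      labels <<- rbind(labels, data.frame(id = id, label = label,
                                          family = fam))
    }
    for (fam in names(families)) {
      for (k in seq_len(n_close))
        add(sprintf("%s_close%02d", fam, k),
            evolve_protein(families[[fam]], divergences$close),
            "close_homolog", fam)
      if (!is.null(remote_ancestors) && n_remote > 0) {
        for (k in seq_len(n_remote))
          add(sprintf("%s_remote%02d", fam, k),
              evolve_protein(remote_ancestors[[fam]], divergences$within),
              "remote_homolog", fam)
      }
    }
    for (k in seq_len(n_decoy)) {
      L <- sample(decoy_len_range[1]:decoy_len_range[2], 1)
      add(sprintf("decoy_%04d", k),
          paste(AA_ALPHABET[sample.int(20L, L, replace = TRUE,
                                       prob = AA_BACKGROUND)],
                collapse = ""),
          "decoy", NA_character_)
    }
    list(seqs = seqs, labels = labels)
  })
}

#' Build a transitive homology chain
#'
#' Evolves an intermediate ancestor from the family ancestor (link 1) and a
#' remote ancestor from the intermediate (link 2). With the default link
#' divergences the remote end sits at roughly 20-25% identity to the seed
#' family — beyond the direct model's reach — while both ends remain within
#' about 40-55% identity of the intermediates.
#'
#' @param ancestor Family ancestor residue string.
#' @param d_link1 Divergence family -> intermediate (default 0.45).
#' @param d_link2 Divergence intermediate -> remote (default 0.50).
#' @param seed RNG seed.
#' @return `list(intermediate, remote)` residue strings.
#' @export
make_chain <- function(ancestor, d_link1 = 0.45, d_link2 = 0.50, seed = 1) {
  with_seed(seed, {
    intermediate <- evolve_protein(ancestor, d_link1)
    remote <- evolve_protein(intermediate, d_link2)
    list(intermediate = intermediate, remote = remote)
  })
}

#' Benchmark specification and construction
#'
#' Assembles a complete labelled benchmark around one family: seed
#' sequences, a metagenome whose implants descend from the chain's
#' intermediate ancestor, and a proteome holding close homologs, remote
#' homologs (descendants of the chain's remote ancestor) and decoys, plus
#' an annotation table in which remote homologs carry a term absent from
#' the close homologs.
#'
#' @param M,n_seed,d_within,indel_rate Seed-family parameters.
#' @param d_close Divergence of proteome close homologs from the ancestor.
#' @param d_link1,d_link2 Chain link divergences (see [make_chain]).
#' @param n_implant Implants in the metagenome.
#' @param n_decoy_contigs Decoy contigs in the metagenome.
#' @param n_close,n_remote,n_decoy_prot Proteome composition.
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(M = 140, n_seed = 12, d_within = 0.08,
                           indel_rate = 0.01, d_close = 0.12,
                           d_link1 = 0.45, d_link2 = 0.50, n_implant = 25,
                           n_decoy_contigs = 120, n_close = 3, n_remote = 5,
                           n_decoy_prot = 200) {
  structure(as.list(environment()), class = "benchmark_spec")
}

#' @rdname benchmark_spec
#' @param spec A `benchmark_spec`.
#' @param seed Base RNG seed for the whole benchmark.
#' @return For `make_benchmark`: `list(seed_family, metagenome, proteome,
#'   labels, annotations, ancestors, generator)`.
#' @export
make_benchmark <- function(spec = benchmark_spec(), seed = 1) {
  fs <- family_spec(M = spec$M, n_seed = spec$n_seed,
                    divergence = spec$d_within,
                    indel_rate = spec$indel_rate,
                    seed = derive_seed(seed, 11))
  fam <- sample_family(fs)
  chain <- make_chain(fam$ancestor, spec$d_link1, spec$d_link2,
                      seed = derive_seed(seed, 12))
  mg <- make_metagenome(list(fam = chain$intermediate),
                        n_decoy_contigs = spec$n_decoy_contigs,
                        implant_divergence = spec$d_within,
                        seed = derive_seed(seed, 13),
                        n_implants = spec$n_implant)
  pr <- make_proteome(list(fam = fam$ancestor),
                      n_close = spec$n_close, n_remote = spec$n_remote,
                      n_decoy = spec$n_decoy_prot,
                      divergences = list(close = spec$d_close,
                                         within = spec$d_within),
                      seed = derive_seed(seed, 14),
                      remote_ancestors = list(fam = chain$remote))
  labels <- rbind(
    data.frame(id = seq_ids(fam$seqs), label = "seed_family",
               family = "fam", stringsAsFactors = FALSE),
    mg$labels[, c("id", "label", "family")], pr$labels)
  ann <- rbind(
    data.frame(id = pr$labels$id[pr$labels$label == "close_homolog"],
               term = "DNA_repair_core", stringsAsFactors = FALSE),
    data.frame(id = pr$labels$id[pr$labels$label == "remote_homolog"],
               term = "DNA_repair_remote", stringsAsFactors = FALSE))
  list(seed_family = fam$seqs, metagenome = mg$contigs,
       proteome = pr$seqs, labels = labels, annotations = ann,
       ancestors = list(family = fam$ancestor,
                        intermediate = chain$intermediate,
                        remote = chain$remote),
       generator = fam$generator)
}
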