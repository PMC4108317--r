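#' Clustering parameters for the telescope
#'
#' Defaults: `min_pts = 5`, generating radius `eps = Inf`, reachability cut
#' `eps_prime = 0.6` on the 1-minus-identity distance (so family-level
#' groups above roughly 40% identity cohere), and a minimum of 5 sequences
#' to seed a new model.
#'
#' @param min_pts OPTICS core threshold.
#' @param eps OPTICS generating radius.
#' @param eps_prime Reachability cut for flat clusters.
#' @param min_cluster_size Smallest cluster allowed to seed a new HMM.
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(min_pts = 5, eps = Inf, eps_prime = 0.6,
                           min_cluster_size = 5) {
  structure(list(min_pts = min_pts, eps = eps, eps_prime = eps_prime,
                 min_cluster_size = min_cluster_size),
            class = "cluster_params")
}

#' Original projection: seed model against one proteome
#'
#' A single [search] of the seed-family model against a proteome; the hits
#' at the inclusion threshold are the "original hits".
#'
#' @param hmm Calibrated seed-family `profile_hmm`.
#' @param proteome List of protein [seq_record] objects.
#' @param params A [search_params].
#' @return Hit `data.frame` (see [search]).
#' @export
original_projection <- function(hmm, proteome, params = search_params()) {
  if (length(proteome) == 0) {
    warning("empty proteome")
    return(data.frame(model = character(), target = character(),
                      bit_score = numeric(), evalue = numeric(),
                      target_len = integer(), stringsAsFactors = FALSE))
  }
  search(hmm, proteome, params)
}

#' Projection 1: seed model into a metagenome
#'
#' Extracts ORFs from every contig (stop-to-stop, six frames) and searches
#' the resulting protein set with the seed model. The hits are the
#' "metagenome matches". The model is recalibrated against the ORF length
#' distribution before searching.
#'
#' @param hmm Seed-family `profile_hmm` (calibration is refreshed here).
#' @param contigs List of nucleotide [seq_record] contigs.
#' @param orf_min_aa Minimum ORF length in residues (default 30).
#' @param params A [search_params].
#' @param table_id Genetic code for translation (default 11).
#' @param calib_n,calib_seed Calibration sample size and seed.
#' @return `list(hits, orf_db)`: the match table and the full ORF protein
#'   database it was drawn from.
#' @export
projection_1 <- function(hmm, contigs, orf_min_aa = 30,
                         params = search_params(), table_id = 11,
                         calib_n = 1000, calib_seed = 1) {
  orfs <- do.call(rbind, lapply(contigs, extract_orfs,
                                min_aa = orf_min_aa, table_id = table_id))
  orf_db <- if (is.null(orfs)) list() else orfs_to_seqs(orfs)
  if (length(orf_db) == 0) {
    warning("no ORFs of at least ", orf_min_aa, " residues")
    empty <- data.frame(model = character(), target = character(),
                        bit_score = numeric(), evalue = numeric(),
                        target_len = integer(), stringsAsFactors = FALSE)
    return(list(hits = empty, orf_db = orf_db))
  }
  hmm <- calibrate(hmm, calib_n, len_dist = seq_lengths(orf_db),
                   seed = calib_seed)
  list(hits = search(hmm, orf_db, params), orf_db = orf_db)
}

#' Projection 2: from metagenome matches back to proteomes
#'
#' Clusters the match sequences on the 1-minus-identity distance (OPTICS +
#' reachability cut), builds one new profile HMM per retained cluster
#' (progressive alignment then [build_profile]), and searches every
#' proteome with every new model. The telescopic hit set of an organism is
#' the union over cluster models, keeping the best E-value per target.
#'
#' @param matches Hit `data.frame` from [projection_1] (must be non-empty).
#' @param match_seqs Protein [seq_record] list of the matched ORFs (the
#'   whole ORF proteins, named as in `matches$target`).
#' @param cparams A [cluster_params].
#' @param proteomes Named list of proteomes (lists of protein records).
#' @param params A [search_params].
#' @param calib_n,seed Calibration sample size and base seed (per-model
#'   seeds are derived deterministically).
#' @return `list(clusters, new_hmms, telescopic)`; `telescopic` is a named
#'   list of hit tables, one per organism.
#' @export
projection_2 <- function(matches, match_seqs, cparams = cluster_params(),
                         proteomes, params = search_params(),
                         calib_n = 1000, seed = 1) {
  if (nrow(matches) == 0) stop("no metagenome matches to project from")
  keep <- seq_ids(match_seqs) %in% matches$target
  match_seqs <- match_seqs[keep]
  dm <- distance_matrix(match_seqs)
  opt <- optics(dm, min_pts = cparams$min_pts, eps = cparams$eps)
  cs <- extract_clusters(opt, eps_prime = cparams$eps_prime,
                         min_cluster_size = cparams$min_cluster_size)
  empty_sets <- lapply(proteomes, function(p)
    data.frame(model = character(), target = character(),
               bit_score = numeric(), evalue = numeric(),
               target_len = integer(), stringsAsFactors = FALSE))
  if (length(cs$clusters) == 0) {
    warning("telescope degenerate: no cluster reaches min_cluster_size")
    return(list(clusters = cs, new_hmms = list(), telescopic = empty_sets,
                optics = opt))
  }
  by_id <- setNames(match_seqs, seq_ids(match_seqs))
  new_hmms <- list()
  telescopic <- empty_sets
  for (k in seq_along(cs$clusters)) {
    members <- by_id[cs$clusters[[k]]]
    aln <- progressive_msa(members)
    hmm_k <- build_profile(aln, name = sprintf("telescope_c%d", k))
    for (o in names(proteomes)) {
      hk <- calibrate(hmm_k, calib_n,
                      len_dist = seq_lengths(proteomes[[o]]),
                      seed = derive_seed(seed, 100 * k + match(o, names(proteomes))))
      hits <- search(hk, proteomes[[o]], params)
      telescopic[[o]] <- rbind(telescopic[[o]], hits)
    }
    new_hmms[[k]] <- hmm_k
  }
  # union across cluster models: best E-value per target
  for (o in names(proteomes)) {
    h <- telescopic[[o]]
    if (nrow(h) > 1) {
      h <- h[order(h$evalue, h$target), , drop = FALSE]
      h <- h[!duplicated(h$target), , drop = FALSE]
      rownames(h) <- NULL
    }
    telescopic[[o]] <- h
  }
  list(clusters = cs, new_hmms = new_hmms, telescopic = telescopic,
       optics = opt)
}

#' New telescopic hits
#'
#' Target ids present among the telescopic hits but absent from the
#' original hits.
#'
#' @param original,telescopic Hit `data.frame`s.
#' @return Character vector of target ids.
#' @export
compare_hits <- function(original, telescopic) {
  setdiff(unique(telescopic$target), unique(original$target))
}

#' Read an annotation table
#'
#' Two tab-separated columns, no header: protein id and one ontology term
#' per row (a protein may appear on several rows).
#'
#' @param path Annotation file.
#' @return `data.frame(id, term)`.
#' @export
read_annotations <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   col.names = c("id", "term"), stringsAsFactors = FALSE)
  df
}

#' Ontology-term distribution of hit sets
#'
#' Counts annotation terms within each hit set; ids missing from the table
#' are counted under `"unannotated"`. If the sets include `original` and
#' `new_telescopic`, the terms observed only among the new telescopic hits
#' are reported as well.
#'
#' @param hit_sets Named list of character vectors of target ids.
#' @param annotations `data.frame(id, term)` (see [read_annotations]).
#' @return Named list of `data.frame(term, count)` per set, with attribute
#'   `new_only_terms`.
#' @export
summarize_terms <- function(hit_sets, annotations) {
  count_one <- function(ids) {
    if (length(ids) == 0)
      return(data.frame(term = character(), count = integer(),
                        stringsAsFactors = FALSE))
    terms <- annotations$term[annotations$id %in% ids]
    unann <- sum(!ids %in% annotations$id)
    tab <- table(terms)
    df <- data.frame(term = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    if (unann > 0)
      df <- rbind(df, data.frame(term = "unannotated", count = unann))
    df[order(-df$count, df$term), , drop = FALSE]
  }
  out <- lapply(hit_sets, count_one)
  if (all(c("original", "new_telescopic") %in% names(hit_sets))) {
    attr(out, "new_only_terms") <-
      setdiff(out$new_telescopic$term, out$original$term)
  }
  out
}

#' Run the full metagenomic telescope
#'
#' Orchestrates both projections: align the seed family and build the
#' original model; search every proteome directly (original hits); extract
#' ORFs from the metagenomes and search them (metagenome matches); cluster
#' the matches, build new models, and search every proteome again
#' (telescopic hits); report the per-organism set differences (new
#' telescopic hits). Deterministic for a fixed `seed`.
#'
#' @param seed_family List of protein [seq_record]s (aligned internally) or
#'   a pre-computed [msa].
#' @param metagenomes List of metagenomes, each a list of nucleotide
#'   contigs. By default matches from all metagenomes are pooled before
#'   clustering (`pool_metagenomes = FALSE` clusters each separately and
#'   combines the clusters).
#' @param proteomes Named list of proteomes (lists of protein records).
#' @param params A [search_params] applied to every projection.
#' @param orf_min_aa Minimum ORF length (default 30 residues).
#' @param cparams A [cluster_params].
#' @param calib_n Background sample size per calibration (default 1000).
#' @param seed Base RNG seed; all stage seeds derive from it.
#' @param table_id Genetic code for ORF translation (default 11).
#' @param pool_metagenomes Pool matches before clustering (default TRUE).
#' @param family_name Name for the seed model.
#' @return A `telescope_result` with components `original`, `telescopic`
#'   (named lists of hit tables), `new_telescopic` (named list of id
#'   vectors), `metagenome_matches`, `clusters`, `new_hmms`,
#'   `original_hmm`, and the parameters used.
#' @export
run_telescope <- function(seed_family, metagenomes, proteomes,
                          params = search_params(), orf_min_aa = 30,
                          cparams = cluster_params(), calib_n = 1000,
                          seed = 1, table_id = 11, pool_metagenomes = TRUE,
                          family_name = "family") {
  stopifnot(length(metagenomes) >= 1, length(proteomes) >= 1,
            !is.null(names(proteomes)))
  aln <- if (inherits(seed_family, "msa")) seed_family
         else progressive_msa(seed_family)
  hmm0 <- build_profile(aln, name = family_name)

  original <- list()
  for (o in names(proteomes)) {
    h0 <- calibrate(hmm0, calib_n, len_dist = seq_lengths(proteomes[[o]]),
                    seed = derive_seed(seed, match(o, names(proteomes))))
    original[[o]] <- original_projection(h0, proteomes[[o]], params)
  }

  p1 <- list()
  for (m in seq_along(metagenomes)) {
    p1[[m]] <- projection_1(hmm0, metagenomes[[m]], orf_min_aa, params,
                            table_id, calib_n,
                            calib_seed = derive_seed(seed, 1000 + m))
  }
  matches <- do.call(rbind, lapply(p1, `[[`, "hits"))
  orf_db <- do.call(c, lapply(p1, `[[`, "orf_db"))

  run_p2 <- function(mm) projection_2(mm, orf_db, cparams, proteomes,
                                      params, calib_n,
                                      seed = derive_seed(seed, 2))
  if (nrow(matches) == 0) {
    warning("no metagenome matches; telescope is empty")
    p2 <- list(clusters = structure(list(clusters = list(),
                                         noise = character()),
                                    class = "cluster_set"),
               new_hmms = list(),
               telescopic = lapply(proteomes, function(p) matches[0, ]))
  } else if (pool_metagenomes || length(metagenomes) == 1) {
    p2 <- run_p2(matches)
  } else {
    parts <- lapply(p1, function(x)
      if (nrow(x$hits) > 0) run_p2(x$hits) else NULL)
    parts <- parts[!vapply(parts, is.null, TRUE)]
    tel <- lapply(names(proteomes), function(o) {
      h <- do.call(rbind, lapply(parts, function(p) p$telescopic[[o]]))
      h <- h[order(h$evalue, h$target), , drop = FALSE]
      h[!duplicated(h$target), , drop = FALSE]
    })
    names(tel) <- names(proteomes)
    p2 <- list(clusters = structure(
                 list(clusters = do.call(c, lapply(parts, function(p)
                        p$clusters$clusters)),
                      noise = do.call(c, lapply(parts, function(p)
                        p$clusters$noise))), class = "cluster_set"),
               new_hmms = do.call(c, lapply(parts, `[[`, "new_hmms")),
               telescopic = tel)
  }

  new_tel <- lapply(names(proteomes), function(o)
    compare_hits(original[[o]], p2$telescopic[[o]]))
  names(new_tel) <- names(proteomes)

  structure(list(original = original, telescopic = p2$telescopic,
                 new_telescopic = new_tel, metagenome_matches = matches,
                 clusters = p2$clusters, new_hmms = p2$new_hmms,
                 original_hmm = hmm0,
                 params = list(search = params, orf_min_aa = orf_min_aa,
                               cluster = cparams, calib_n = calib_n,
                               seed = seed, table_id = table_id,
                               pool_metagenomes = pool_metagenomes)),
            class = "telescope_result")
}

#' @export
print.telescope_result <- function(x, ...) {
  cat("metagenomic telescope result\n")
  for (o in names(x$original)) {
    cat(sprintf("  %s: %d original, %d telescopic, %d new telescopic\n", o,
                length(unique(x$original[[o]]$target)),
                length(unique(x$telescopic[[o]]$target)),
                length(x$new_telescopic[[o]])))
  }
  cat(sprintf("  metagenome matches: %d; clusters: %d\n",
              nrow(x$metagenome_matches), length(x$clusters$clusters)))
  invisible(x)
}
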