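# a small shared fixture: family, alignment, seed model
fam <- sample_family(family_spec(M = 60, n_seed = 8, seed = 121))
seed_aln <- progressive_msa(fam$seqs)
seed_hmm <- build_profile(seed_aln, name = "fam")

test_that("the original projection recognises the seed family itself", {
  proteome <- c(fam$seqs, lapply(1:40, function(k)
    seq_record(sprintf("bg%02d", k), random_protein_str(65))))
  hmm <- calibrate(seed_hmm, 400, len_dist = seq_lengths(proteome), seed = 2)
  hits <- original_projection(hmm, proteome, search_params(1e-6))
  expect_true(all(seq_ids(fam$seqs) %in% hits$target))
  expect_true(all(hits$evalue <= 1e-6))
})

test_that("a pure background proteome yields no hits at the threshold", {
  set.seed(122)
  proteome <- lapply(1:200, function(k)
    seq_record(sprintf("bg%03d", k), random_protein_str(sample(50:90, 1))))
  hmm <- calibrate(seed_hmm, 500, len_dist = seq_lengths(proteome), seed = 3)
  hits <- original_projection(hmm, proteome, search_params(1e-6))
  expect_equal(nrow(hits), 0)
  expect_warning(original_projection(hmm, list(), search_params()), "empty")
})

test_that("projection 1 recovers implanted homologs and rejects decoys", {
  mg <- make_metagenome(list(fam = fam$ancestor), n_decoy_contigs = 40,
                        implant_divergence = 0.1, seed = 123,
                        n_implants = 8)
  p1 <- projection_1(seed_hmm, mg$contigs, orf_min_aa = 30,
                     params = search_params(1e-6), calib_n = 500,
                     calib_seed = 4)
  implant_contigs <- sub("_\\d+_\\d+_[+-]_\\d$", "", p1$hits$target)
  expect_true(all(grepl("^mg_fam_", implant_contigs)))
  hit_contigs <- unique(implant_contigs)
  expect_gte(length(hit_contigs), 7)  # essentially all implants recovered
  # a decoy-only metagenome yields nothing
  decoys <- make_metagenome(list(), n_decoy_contigs = 40, seed = 124)
  p0 <- projection_1(seed_hmm, decoys$contigs, orf_min_aa = 30,
                     params = search_params(1e-6), calib_n = 500,
                     calib_seed = 5)
  expect_equal(nrow(p0$hits), 0)
  # contigs with no qualifying ORFs warn and return an empty match table
  tiny <- list(seq_record("t", "ATGATGATG", "nucleotide"))
  expect_warning(pe <- projection_1(seed_hmm, tiny, 30), "no ORFs")
  expect_equal(nrow(pe$hits), 0)
})

test_that("projection 2 from the seed family itself covers the original hits", {
  # matches identical to the seed family: one tight cluster whose model
  # must at least recover what the original model found
  proteome <- c(fam$seqs, lapply(1:40, function(k)
    seq_record(sprintf("bg%02d", k), random_protein_str(65))))
  hmm <- calibrate(seed_hmm, 400, len_dist = seq_lengths(proteome), seed = 6)
  orig <- original_projection(hmm, proteome, search_params(1e-6))
  matches <- data.frame(model = "fam", target = seq_ids(fam$seqs),
                        bit_score = 100, evalue = 1e-10,
                        target_len = seq_lengths(fam$seqs),
                        stringsAsFactors = FALSE)
  p2 <- projection_2(matches, fam$seqs, cluster_params(min_pts = 3,
                                                       min_cluster_size = 3),
                     list(org = proteome), search_params(1e-6),
                     calib_n = 400, seed = 7)
  expect_length(p2$clusters$clusters, 1)
  expect_true(all(orig$target %in% p2$telescopic$org$target))
  expect_error(projection_2(matches[0, ], fam$seqs,
                            cluster_params(), list(org = proteome)),
               "no metagenome matches")
})

test_that("a degenerate telescope warns and returns empty telescopic sets", {
  set.seed(125)
  few <- lapply(1:3, function(k)
    seq_record(paste0("x", k), random_protein_str(50)))
  matches <- data.frame(model = "m", target = seq_ids(few), bit_score = 10,
                        evalue = 1e-8, target_len = 50,
                        stringsAsFactors = FALSE)
  expect_warning(
    p2 <- projection_2(matches, few, cluster_params(min_pts = 5,
                                                    min_cluster_size = 5),
                       list(org = few), search_params(), calib_n = 300),
    "degenerate")
  expect_equal(nrow(p2$telescopic$org), 0)
})

test_that("new telescopic hits are the plain set difference of target ids", {
  h <- function(ids) data.frame(target = ids, stringsAsFactors = FALSE)
  expect_setequal(compare_hits(h(c("a", "b")), h(c("a", "b", "c"))), "c")
  expect_length(compare_hits(h(c("a", "b")), h(c("a", "b"))), 0)
  expect_length(compare_hits(h(character()), h(character())), 0)
})

test_that("term summaries count annotations and surface new-only terms", {
  ann <- data.frame(id = c("a", "a", "b", "r1"),
                    term = c("T1", "T2", "T1", "T_new"),
                    stringsAsFactors = FALSE)
  out <- summarize_terms(list(original = c("a", "b"),
                              telescopic = c("a", "b", "r1", "u1"),
                              new_telescopic = c("r1", "u1")), ann)
  expect_equal(out$original$count[out$original$term == "T1"], 2L)
  expect_equal(out$original$count[out$original$term == "T2"], 1L)
  expect_true("T_new" %in% out$new_telescopic$term)
  expect_equal(out$new_telescopic$count[out$new_telescopic$term ==
                                          "unannotated"], 1L)
  expect_true("T_new" %in% attr(out, "new_only_terms"))
  expect_false("T1" %in% attr(out, "new_only_terms"))
  empty <- summarize_terms(list(original = character()), ann)
  expect_equal(nrow(empty$original), 0)
})

test_that("a full telescope run is deterministic and internally consistent", {
  b <- make_benchmark(benchmark_spec(M = 80, n_seed = 8, n_implant = 12,
                                     n_decoy_contigs = 30, n_remote = 3,
                                     n_decoy_prot = 60), seed = 126)
  run1 <- run_telescope(b$seed_family, list(b$metagenome),
                        list(org = b$proteome), calib_n = 400, seed = 127)
  run2 <- run_telescope(b$seed_family, list(b$metagenome),
                        list(org = b$proteome), calib_n = 400, seed = 127)
  expect_identical(run1$original, run2$original)
  expect_identical(run1$telescopic, run2$telescopic)
  expect_identical(run1$new_telescopic, run2$new_telescopic)
  # invariant: new telescopic ids = telescopic targets minus original targets
  expect_setequal(run1$new_telescopic$org,
                  setdiff(unique(run1$telescopic$org$target),
                          unique(run1$original$org$target)))
  # every reported hit satisfies the inclusion threshold
  expect_true(all(run1$original$org$evalue <= 1e-6))
  expect_true(all(run1$telescopic$org$evalue <= 1e-6))
  expect_true(all(run1$metagenome_matches$evalue <= 1e-6))
  # report counts equal the set sizes and satisfy the set identity per row
  rep <- render_report(run1, b$annotations)
  cnt <- rep$counts
  expect_equal(cnt$n_original, length(unique(run1$original$org$target)))
  expect_equal(cnt$n_telescopic, length(unique(run1$telescopic$org$target)))
  inter <- length(intersect(unique(run1$telescopic$org$target),
                            unique(run1$original$org$target)))
  expect_equal(cnt$n_new_telescopic, cnt$n_telescopic - inter)
})
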