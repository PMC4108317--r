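# toy model builder: explicit matrices, bypassing build_profile
toy_hmm <- function(me, ie, tr, bg = rep(1 / 20, 20)) {
  metatelescope:::new_profile_hmm("toy", me, ie, tr, background = bg)
}

test_that("profile construction follows the stated count formulas", {
  aln <- msa(c("r1", "r2"), c("ACD", "ACD"))
  hmm <- build_profile(aln, pseudocount = 1)
  expect_equal(hmm$M, 3)
  # two identical rows: normalized weights are 1 each, so counts are 2
  expect_equal(unname(hmm$match_emis[1, "A"]), 3 / 22)
  expect_equal(unname(hmm$match_emis[2, "C"]), 3 / 22)
  expect_equal(unname(hmm$match_emis[1, "C"]), 1 / 22)
  expect_silent(validate_phmm(hmm))
})

test_that("columns below the occupancy threshold become insert columns", {
  aln <- msa(paste0("r", 1:4), c("AWC", "A-C", "A-C", "A-C"))
  hmm <- build_profile(aln, occupancy = 0.5)
  expect_equal(hmm$M, 2)  # middle column has occupancy 0.25
  # and the W lands in the insert state of node 1
  expect_gt(hmm$ins_emis[2, "W"], hmm$ins_emis[2, "A"])
  # an alignment with no qualifying column is an error
  sparse <- msa(paste0("r", 1:4), c("A---", "-C--", "--D-", "---E"))
  expect_error(build_profile(sparse, occupancy = 0.5), "no match columns")
})

test_that("emission and transition rows are normalised on random alignments", {
  set.seed(91)
  for (k in 1:5) {
    anc <- random_protein_str(25)
    seqs <- lapply(1:6, function(i)
      seq_record(paste0("s", i), evolve_protein(anc, 0.2, 0.05)))
    hmm <- build_profile(progressive_msa(seqs))
    expect_silent(validate_phmm(hmm))
  }
})

test_that("profile emissions approach the observed residues as the pseudocount vanishes", {
  aln <- msa(paste0("r", 1:5), rep("MKLV", 5))
  for (pc in c(1, 0.1, 0.001)) {
    hmm <- build_profile(aln, pseudocount = pc)
    expect_gte(hmm$match_emis[1, "M"], 5 / (5 + 20 * pc))
  }
  expect_gt(build_profile(aln, pseudocount = 0.001)$match_emis[1, "M"], 0.99)
})

test_that("Henikoff weights down-weight duplicated rows", {
  w <- henikoff_weights(c("AAAA", "AAAA", "CCCC"))
  expect_equal(sum(w), 3)
  expect_gt(w[3], w[1])
  expect_equal(w[1], w[2])
})

test_that("a single-path model scores its forced sequence in closed form", {
  eps <- 1e-12
  me <- matrix(eps / 19, 1, 20); me[1, 1] <- 1 - eps
  ie <- matrix(1 / 20, 2, 20)
  tr <- matrix(0, 2, 7)
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  tr[1, ] <- c(1 - 2 * eps, eps, eps, 0.5, 0.5, 1, 0)
  tr[2, ] <- c(1 - eps, eps, 0, 0.5, 0.5, 1, 0)
  hmm <- toy_hmm(me, ie, tr)
  expect_equal(forward_score(hmm, "A"), log2(20), tolerance = 1e-9)
  v <- viterbi(hmm, "A")
  expect_equal(v$bit_score, log2(20), tolerance = 1e-9)
  expect_equal(v$path, c("B", "M1", "E"))
  expect_error(forward_score(hmm, ""), "empty")
})

test_that("forward equals the path-enumeration sum and dominates Viterbi", {
  set.seed(92)
  for (k in 1:20) {
    hmm <- random_test_hmm(sample(1:3, 1))
    for (len in 1:4) {
      s <- paste(sample(c("A", "C", "D", "E"), len, TRUE), collapse = "")
      o <- oracle_path_scores(hmm, s)
      f <- forward_score(hmm, s)
      v <- viterbi(hmm, s)$bit_score
      expect_equal(f, o$forward, tolerance = 1e-9)
      expect_equal(v, o$viterbi, tolerance = 1e-9)
      expect_gte(f, v - 1e-12)
    }
  }
})

test_that("the generative model is (sub)normalised over short sequences", {
  set.seed(93)
  hmm <- random_test_hmm(2)
  # keep insert/delete excursions rare so the probability mass concentrates
  # on short outputs and the partial sums are informative
  hmm$trans[, ] <- rep(c(0.90, 0.05, 0.05, 0.7, 0.3, 0.9, 0.1),
                       each = nrow(hmm$trans))
  hmm$trans[3, c("MM", "MI", "MD")] <- c(0.95, 0.05, 0)
  hmm$trans[3, c("DM", "DD")] <- c(1, 0)
  hmm$trans[1, c("DM", "DD")] <- c(1, 0)
  lo <- metatelescope:::hmm_logodds(hmm)
  bg <- hmm$background
  total <- 0
  for (len in 0:3) {
    if (len == 0) {
      # silent all-delete path
      p0 <- hmm$trans[1, "MD"] * hmm$trans[2, "DD"] * hmm$trans[3, "DM"]
      total <- total + p0
      next
    }
    combos <- as.matrix(expand.grid(rep(list(0:19), len)))
    seqs <- lapply(seq_len(nrow(combos)), function(r) as.integer(combos[r, ]))
    sc <- metatelescope:::phmm_score_batch_cpp(lo$lme, lo$lie, lo$ltr,
                                               seqs, FALSE, 0.9)
    pbg <- apply(combos, 1, function(r) prod(bg[r + 1]))
    total <- total + sum(2^sc * pbg)
  }
  expect_lte(total, 1 + 1e-9)
  expect_gt(total, 0.8)  # mass beyond 3 emissions is limited
})

test_that("tied Viterbi paths resolve by the documented predecessor preference", {
  # two exactly tied paths for a single residue: B-M1-D2-E and B-D1-M2-E;
  # at the END cell the match predecessor is preferred, selecting the latter
  me <- matrix(1 / 38, 2, 20); me[, 1] <- 0.5
  ie <- matrix(1 / 20, 3, 20)
  tr <- matrix(0, 3, 7)
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  tr[1, ] <- c(0.25, 0.25, 0.50, 0.5, 0.5, 1, 0)
  tr[2, ] <- c(0.50, 0.25, 0.25, 0.5, 0.5, 0.5, 0.5)
  tr[3, ] <- c(0.25, 0.75, 0, 0.5, 0.5, 1, 0)
  hmm <- toy_hmm(me, ie, tr)
  v <- viterbi(hmm, "A")
  expect_equal(v$bit_score, log2(1 / 16 * 0.5 / 0.05), tolerance = 1e-12)
  expect_equal(v$path, c("B", "D1", "M2", "E"))
})

test_that("Gumbel tail fitting recovers known parameters", {
  set.seed(94)
  u <- runif(5000)
  x <- -log(-log(u)) / 0.7  # Gumbel(mu = 0, lambda = 0.7)
  fit <- fit_gumbel(x)
  expect_lt(abs(fit$lambda - 0.7) / 0.7, 0.1)
  expect_lt(abs(fit$mu), 0.25)
  expect_error(fit_gumbel(rep(1, 100)), "degenerate")
})

test_that("calibration is deterministic and yields the Gumbel closed forms", {
  fam <- sample_family(family_spec(M = 40, n_seed = 6, seed = 95))
  hmm <- build_profile(progressive_msa(fam$seqs))
  c1 <- calibrate(hmm, 400, len_dist = 60, seed = 7)
  c2 <- calibrate(hmm, 400, len_dist = 60, seed = 7)
  expect_identical(c1$calib, c2$calib)
  expect_error(calibrate(hmm, 100), "at least 200")
  # constant-length calibration: alpha = beta = 0, spec closed forms hold
  expect_equal(c1$calib$beta, 0)
  N <- 5000
  expect_equal(evalue(c1, c1$calib$mu, N), N * (1 - exp(-1)),
               tolerance = 1e-9)
  expect_lt(evalue(c1, 1e6, N), 1e-200)       # E -> 0 as s -> Inf
  sc <- seq(-20, 60, by = 5)
  expect_true(all(diff(evalue(c1, sc, N)) < 0))  # monotone decreasing
  expect_error(evalue(hmm, 10, N), "not calibrated")
})

test_that("degenerate background score variance is a hard error", {
  # match emissions equal to background and deterministic transitions give
  # every background sequence the same score
  M <- 5
  me <- matrix(rep(1 / 20, 20 * M), M, 20)
  ie <- matrix(1 / 20, M + 1, 20)
  tr <- matrix(0, M + 1, 7)
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  tr[, "MM"] <- 1 - 2e-12; tr[, "MI"] <- 1e-12; tr[, "MD"] <- 1e-12
  tr[, "IM"] <- 0.5; tr[, "II"] <- 0.5
  tr[, "DM"] <- 1 - 1e-12; tr[, "DD"] <- 1e-12
  tr[M + 1, c("MM", "MI", "MD")] <- c(1 - 1e-12, 1e-12, 0)
  tr[M + 1, c("DM", "DD")] <- c(1, 0)
  tr[1, c("DM", "DD")] <- c(1, 0)
  hmm <- toy_hmm(me, ie, tr)
  expect_error(calibrate(hmm, 300, len_dist = M, seed = 1), "degenerate")
})

test_that("search applies the inclusion threshold and orders by E-value", {
  set.seed(96)
  fam <- sample_family(family_spec(M = 60, n_seed = 8, seed = 96))
  hmm <- build_profile(progressive_msa(fam$seqs), name = "fam")
  db <- c(fam$seqs,
          lapply(1:60, function(k)
            seq_record(sprintf("decoy%02d", k), random_protein_str(70))))
  hmm <- calibrate(hmm, 500, len_dist = seq_lengths(db), seed = 3)
  hits <- search(hmm, db, search_params(1e-6))
  expect_true(all(hits$evalue <= 1e-6))
  expect_setequal(hits$target, seq_ids(fam$seqs))  # members in, decoys out
  expect_true(!is.unsorted(hits$evalue))
  expect_warning(empty <- search(hmm, list(), search_params()), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("family members separate perfectly from decoys (AUC 1)", {
  set.seed(97)
  fam <- sample_family(family_spec(M = 80, n_seed = 10, divergence = 0.15,
                                   seed = 97))
  hmm <- build_profile(progressive_msa(fam$seqs))
  members <- lapply(1:50, function(k)
    seq_record(sprintf("m%02d", k), evolve_protein(fam$ancestor, 0.25)))
  decoys <- lapply(1:500, function(k)
    seq_record(sprintf("d%03d", k), random_protein_str(80)))
  sm <- vapply(members, function(s) forward_score(hmm, s), 0)
  sd_ <- vapply(decoys, function(s) forward_score(hmm, s), 0)
  expect_gt(min(sm), max(sd_))
})

test_that("model serialization round-trips at full precision", {
  fam <- sample_family(family_spec(M = 30, n_seed = 5, seed = 98))
  hmm <- calibrate(build_profile(progressive_msa(fam$seqs), name = "rt"),
                   300, len_dist = 40:80, seed = 5)
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmm(hmm, f)
  back <- read_hmm(f)
  expect_equal(back$match_emis, hmm$match_emis, ignore_attr = TRUE)
  expect_equal(back$ins_emis, hmm$ins_emis, ignore_attr = TRUE)
  expect_equal(back$trans, hmm$trans, ignore_attr = TRUE)
  expect_equal(back$background, unname(hmm$background))
  expect_equal(back$calib$mu, hmm$calib$mu)
  expect_equal(back$calib$lambda, hmm$calib$lambda)
  expect_equal(back$calib$beta, hmm$calib$beta)
  expect_equal(back$name, "rt")
  # scores computed from the re-read model are identical
  s <- random_protein_str(50)
  expect_equal(forward_score(back, s), forward_score(hmm, s))
})
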