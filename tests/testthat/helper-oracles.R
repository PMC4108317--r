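# Independent reference implementations used as test oracles. These are
# deliberately written as literal, unoptimized transcriptions (enumeration,
# brute force) and share no code with the package internals they check.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# ---- genetic code, typed independently from the published table ------------
# NCBI translation table 11 (bacterial/archaeal); identical amino acids to
# the standard code, differences are only in start codons (irrelevant for
# stop-to-stop translation)
ORACLE_CODE_11 <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")
ORACLE_CODE_1 <- ORACLE_CODE_11  # same amino acid assignments

oracle_translate_codon <- function(codon, code = ORACLE_CODE_11) {
  if (!grepl("N", codon)) return(unname(code[codon]))
  # expand every N, translate all resolutions, keep only a unanimous residue
  pos <- which(strsplit(codon, "")[[1]] == "N")
  expansions <- codon
  for (p in pos) {
    expansions <- unlist(lapply(expansions, function(cd) {
      vapply(c("A", "C", "G", "T"), function(b) {
        ch <- strsplit(cd, "")[[1]]; ch[p] <- b; paste(ch, collapse = "")
      }, "")
    }))
  }
  aas <- unique(unname(code[expansions]))
  if (length(aas) == 1) aas else "X"
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# ---- brute-force six-frame ORF enumeration ---------------------------------
oracle_orfs <- function(contig_str, min_aa, contig_id = "c") {
  L <- nchar(contig_str)
  out <- list()
  for (strand in c("+", "-")) {
    read <- if (strand == "+") contig_str else oracle_revcomp(contig_str)
    for (f in 0:2) {
      n_codon <- (L - f) %/% 3
      if (n_codon < 1) next
      aa <- vapply(seq_len(n_codon) - 1, function(k)
        oracle_translate_codon(substr(read, f + 3 * k + 1, f + 3 * k + 3)), "")
      # walk codons, collecting maximal stop-free runs
      run_start <- 0
      k <- 0
      while (k <= n_codon) {
        if (k == n_codon || aa[k + 1] == "*") {
          run_len <- k - run_start
          if (run_len >= min_aa) {
            s_local <- f + 3 * run_start
            e_local <- f + 3 * k
            if (strand == "+") { st <- s_local; en <- e_local }
            else { st <- L - e_local; en <- L - s_local }
            out[[length(out) + 1]] <- data.frame(
              contig_id = contig_id, strand = strand, frame = f,
              start = st, end = en,
              protein = paste(aa[(run_start + 1):k], collapse = ""),
              stringsAsFactors = FALSE)
          }
          run_start <- k + 1
        }
        k <- k + 1
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(contig_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$strand, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ---- exhaustive alignment enumeration --------------------------------------
# all global alignments of a and b as op strings (M/X/Y), scored with
# affine gaps: a run of k gap columns costs go + k * ge
oracle_best_alignment_score <- function(a, b, S, go, ge) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, ops) {
    if (i == length(ca) && j == length(cb)) {
      score <- 0; prev <- ""
      ii <- 0; jj <- 0
      for (op in ops) {
        if (op == "M") {
          ii <- ii + 1; jj <- jj + 1
          score <- score + S[ca[ii], cb[jj]]
        } else {
          if (op == "X") ii <- ii + 1 else jj <- jj + 1
          score <- score + ge + if (op != prev) go else 0
        }
        prev <- op
      }
      best <<- max(best, score)
      return(invisible())
    }
    if (i < length(ca) && j < length(cb)) recurse(i + 1, j + 1, c(ops, "M"))
    if (i < length(ca)) recurse(i + 1, j, c(ops, "X"))
    if (j < length(cb)) recurse(i, j + 1, c(ops, "Y"))
  }
  recurse(0, 0, character())
  best
}

# independent sum-of-pairs MSA score: per pair of rows, drop double-gap
# columns, then substitution scores plus affine gap runs
oracle_sp_score <- function(rows, S, go, ge) {
  n <- length(rows)
  total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ra <- strsplit(rows[i], "")[[1]]; rb <- strsplit(rows[j], "")[[1]]
    keep <- !(ra == "-" & rb == "-")
    ra <- ra[keep]; rb <- rb[keep]
    prev <- "M"
    for (k in seq_along(ra)) {
      if (ra[k] != "-" && rb[k] != "-") {
        total <- total + S[ra[k], rb[k]]; prev <- "M"
      } else {
        op <- if (ra[k] == "-") "Y" else "X"
        total <- total + ge + if (op != prev) go else 0
        prev <- op
      }
    }
  }
  total
}

# ---- profile-HMM path enumeration ------------------------------------------
# sums (or maximises) linear-space path odds over every legal state path of
# a Plan7-style glocal model for the given residue index sequence
oracle_path_scores <- function(hmm, residues) {
  x <- match(strsplit(residues, "")[[1]], AAS)
  n <- length(x)
  M <- hmm$M
  tr <- hmm$trans
  bg <- hmm$background
  em_odds <- function(j, xi) hmm$match_emis[j, xi] / bg[xi]
  ie_odds <- function(j, xi) hmm$ins_emis[j + 1, xi] / bg[xi]
  total <- 0
  best <- 0
  # state: type in {M, I, D}; node j; i residues consumed; p odds so far
  step <- function(type, j, i, p) {
    if (p == 0) return(invisible())
    if (type == "M" || type == "D") {
      if (j == M) {  # exit to END
        slot <- if (type == "M") "MM" else "DM"
        if (i == n) {
          pe <- p * tr[M + 1, slot]
          total <<- total + pe
          best <<- max(best, pe)
        }
        if (type == "M") {  # M_M -> I_M still possible
          if (i < n) step("I", M, i + 1,
                          p * tr[M + 1, "MI"] * ie_odds(M, x[i + 1]))
        }
        return(invisible())
      }
      pre <- if (type == "M") c("MM", "MI", "MD") else c("DM", NA, "DD")
      if (i < n) step("M", j + 1, i + 1,
                      p * tr[j + 1, pre[1]] * em_odds(j + 1, x[i + 1]))
      if (type == "M" && i < n)
        step("I", j, i + 1, p * tr[j + 1, "MI"] * ie_odds(j, x[i + 1]))
      step("D", j + 1, i, p * tr[j + 1, pre[3]])
    } else {  # insert state I_j
      if (j == M) {
        if (i == n) {
          pe <- p * tr[M + 1, "IM"]
          total <<- total + pe
          best <<- max(best, pe)
        }
        if (i < n) step("I", M, i + 1,
                        p * tr[M + 1, "II"] * ie_odds(M, x[i + 1]))
        return(invisible())
      }
      if (i < n) {
        step("M", j + 1, i + 1,
             p * tr[j + 1, "IM"] * em_odds(j + 1, x[i + 1]))
        step("I", j, i + 1, p * tr[j + 1, "II"] * ie_odds(j, x[i + 1]))
      }
      # i == n at an inner insert state is a dead end (M consumes a residue)
    }
  }
  # BEGIN acts as M0: B->M1 (emit), B->I0 (emit), B->D1
  if (n >= 1) {
    step("M", 1, 1, tr[1, "MM"] * em_odds(1, x[1]))
    step("I", 0, 1, tr[1, "MI"] * ie_odds(0, x[1]))
  }
  step("D", 1, 0, tr[1, "MD"])
  if (M == 0) stop("oracle requires M >= 1")
  list(forward = as.numeric(log2(total)), viterbi = as.numeric(log2(best)))
}

# hmm: I_j -> M_{j+1} consumes a residue, so when i == n an insert state can
# only reach END at node M; handled above. (I -> M at j < M with i == n is a
# dead end and contributes nothing.)

# ---- literal OPTICS pseudocode transcription -------------------------------
# OrderSeeds kept as a named list of current reachability values; the pop
# takes the minimum reachability, ties broken by smallest input index
oracle_optics <- function(d, min_pts, eps = Inf) {
  n <- nrow(d)
  core_dist <- vapply(seq_len(n), function(p) {
    nd <- sort(d[p, ])
    if (sum(nd <= eps) >= min_pts) nd[min_pts] else Inf
  }, 0)
  env <- new.env()
  env$processed <- rep(FALSE, n)
  env$ordering <- integer(0)
  env$reach_out <- numeric(0)
  env$seeds <- list()
  update_seeds <- function(center) {
    for (o in seq_len(n)) {
      if (env$processed[o] || d[center, o] > eps) next
      new_r <- max(core_dist[center], d[center, o])
      key <- as.character(o)
      if (is.null(env$seeds[[key]]) || new_r < env$seeds[[key]])
        env$seeds[[key]] <- new_r
    }
  }
  for (p in seq_len(n)) {
    if (env$processed[p]) next
    env$processed[p] <- TRUE
    env$ordering <- c(env$ordering, p)
    env$reach_out <- c(env$reach_out, Inf)
    if (is.finite(core_dist[p])) {
      env$seeds <- list()
      update_seeds(p)
      while (length(env$seeds) > 0) {
        rs <- unlist(env$seeds)
        ps <- as.integer(names(env$seeds))
        best <- which(rs == min(rs))
        pick <- best[which.min(ps[best])]
        q <- ps[pick]
        r <- rs[pick]
        env$seeds[[as.character(q)]] <- NULL
        env$processed[q] <- TRUE
        env$ordering <- c(env$ordering, q)
        env$reach_out <- c(env$reach_out, unname(r))
        if (is.finite(core_dist[q])) update_seeds(q)
      }
    }
  }
  list(ordering = env$ordering, reachability = unname(env$reach_out),
       core_dist = unname(core_dist[env$ordering]))
}

# ---- brute-force DBSCAN ----------------------------------------------------
# labels: 0 = noise; border points are assigned to the first cluster (in
# expansion order) that reaches them. Also reports which points are border
# points reachable from more than one cluster (assignment is convention-
# dependent for those).
oracle_dbscan <- function(d, eps, min_pts) {
  n <- nrow(d)
  is_core <- vapply(seq_len(n), function(p) sum(d[p, ] <= eps) >= min_pts,
                    TRUE)
  labels <- rep(0L, n)
  cl <- 0L
  for (p in seq_len(n)) {
    if (!is_core[p] || labels[p] != 0L) next
    cl <- cl + 1L
    frontier <- p
    labels[p] <- cl
    while (length(frontier) > 0) {
      q <- frontier[1]; frontier <- frontier[-1]
      nb <- which(d[q, ] <= eps)
      for (o in nb) {
        if (labels[o] == 0L) {
          labels[o] <- cl
          if (is_core[o]) frontier <- c(frontier, o)
        }
      }
    }
  }
  # multi-cluster-reachable border points
  ambiguous <- vapply(seq_len(n), function(p) {
    if (is_core[p]) return(FALSE)
    cls <- unique(labels[is_core & d[p, ] <= eps])
    length(cls) > 1
  }, TRUE)
  list(labels = labels, is_core = is_core, ambiguous = ambiguous)
}

# ---- misc helpers ----------------------------------------------------------
random_protein_str <- function(len) paste(sample(AAS, len, replace = TRUE),
                                          collapse = "")

# random valid profile HMM (Dirichlet-like rows via normalised gamma draws)
random_test_hmm <- function(M, uniform_bg = TRUE) {
  rdir <- function(k, conc = 1) {
    g <- rgamma(k, conc); g / sum(g)
  }
  me <- t(vapply(seq_len(M), function(j) rdir(20, 0.5), numeric(20)))
  ie <- t(vapply(seq_len(M + 1), function(j) rdir(20, 5), numeric(20)))
  tr <- matrix(0, M + 1, 7,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                       "DM", "DD")))
  for (j in 0:M) {
    if (j < M) {
      tr[j + 1, c("MM", "MI", "MD")] <- rdir(3, 3)
      tr[j + 1, c("DM", "DD")] <- rdir(2, 3)
    } else {
      tr[j + 1, c("MM", "MI")] <- rdir(2, 3)
      tr[j + 1, "MD"] <- 0
      tr[j + 1, c("DM", "DD")] <- c(1, 0)
    }
    tr[j + 1, c("IM", "II")] <- rdir(2, 3)
  }
  tr[1, c("DM", "DD")] <- c(1, 0)
  bg <- if (uniform_bg) rep(1 / 20, 20) else metatelescope:::AA_BACKGROUND
  metatelescope:::new_profile_hmm("rnd", me, ie, tr, background = bg)
}

# small random metric from points in the plane
random_metric <- function(n, dims = 2) {
  pts <- matrix(runif(n * dims), ncol = dims)
  as.matrix(dist(pts))
}

make_dm <- function(d) structure(list(ids = paste0("p", seq_len(nrow(d))),
                                      d = d), class = "distance_matrix")
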