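#' Profile hidden Markov models
#'
#' A linear (Plan7-style) profile HMM: per node a match state with its own
#' residue distribution, an insert state, and a silent delete state, plus
#' BEGIN and END. The default scoring mode is glocal — the whole model must
#' align to the whole sequence — with a documented switch to local-in-sequence
#' scoring in which flanking residues are absorbed by background states.
#'
#' Transition storage: an `(M+1) x 7` matrix with columns
#' `MM, MI, MD, IM, II, DM, DD`. Row `j` (0-based node index) holds the
#' transitions out of node `j` into node `j+1`; row 0 is BEGIN (treated as
#' `M0`), and in row `M` the `MM`/`IM`/`DM` slots hold the exits to END.
#'
#' @name profile_hmm
NULL

TRANS_COLS <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

new_profile_hmm <- function(name, match_emis, ins_emis, trans,
                            background = AA_BACKGROUND, mode = "glocal",
                            calib = NULL) {
  M <- nrow(match_emis)
  colnames(match_emis) <- AA_ALPHABET
  colnames(ins_emis) <- AA_ALPHABET
  colnames(trans) <- TRANS_COLS
  structure(list(name = name, M = M, match_emis = match_emis,
                 ins_emis = ins_emis, trans = trans,
                 background = background, mode = mode, calib = calib),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile HMM '%s': %d match states, mode %s, %s\n",
              x$name, x$M, x$mode,
              if (is.null(x$calib)) "uncalibrated"
              else sprintf("calibrated (mu = %.2f bits, lambda = %.3f)",
                           x$calib$mu, x$calib$lambda)))
  invisible(x)
}

#' Validate a profile HMM
#'
#' Checks that every emission row and every reachable state's outgoing
#' transitions sum to 1 within `tol`, and that pseudocounted probabilities
#' are strictly positive (structural zeros — the delete row of the BEGIN
#' node and the `MD`/`DD` slots of the last node — are exempt).
#'
#' @param hmm A `profile_hmm`.
#' @param tol Row-sum tolerance (default 1e-9).
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_phmm <- function(hmm, tol = 1e-9) {
  stopifnot(inherits(hmm, "profile_hmm"))
  M <- hmm$M
  if (M < 1) stop("profile HMM needs at least one match state")
  ok_row <- function(m, what) {
    if (any(abs(rowSums(m) - 1) > tol))
      stop(what, " rows do not sum to 1")
    if (any(m <= 0)) stop(what, " contains non-positive probabilities")
  }
  ok_row(hmm$match_emis, "match emission")
  ok_row(hmm$ins_emis, "insert emission")
  tr <- hmm$trans
  for (j in seq_len(M + 1) - 1L) {
    r <- tr[j + 1, ]
    mrow <- r[c("MM", "MI", "MD")]
    if (j == M) mrow <- r[c("MM", "MI")]  # no M->D out of the last node
    if (abs(sum(mrow) - 1) > tol || any(mrow <= 0))
      stop("match transitions of node ", j, " are invalid")
    irow <- r[c("IM", "II")]
    if (abs(sum(irow) - 1) > tol || any(irow <= 0))
      stop("insert transitions of node ", j, " are invalid")
    if (j >= 1) {
      drow <- r[c("DM", "DD")]
      if (j == M) drow <- r["DM"]
      if (abs(sum(drow) - 1) > tol || any(drow < 0))
        stop("delete transitions of node ", j, " are invalid")
    }
  }
  if (!is.null(hmm$calib) && hmm$calib$lambda <= 0)
    stop("calibrated lambda must be positive")
  invisible(TRUE)
}

#' Henikoff position-based sequence weights
#'
#' Each column contributes `1 / (r * s)` to every row, where `r` is the
#' number of distinct residues in the column and `s` the multiplicity of the
#' row's residue; gap cells contribute nothing. Weights are normalised to
#' sum to the number of rows.
#'
#' @param rows Gapped MSA rows (character vector).
#' @return Numeric weights, one per row.
#' @export
henikoff_weights <- function(rows) {
  chm <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(chm)
  w <- numeric(n)
  for (j in seq_len(ncol(chm))) {
    col <- chm[, j]
    res <- col != "-"
    if (!any(res)) next
    tab <- table(col[res])
    r <- length(tab)
    w[res] <- w[res] + 1 / (r * tab[col[res]])
  }
  if (sum(w) == 0) return(rep(1, n))
  w * n / sum(w)
}

#' Build a profile HMM from a multiple alignment
#'
#' Columns whose non-gap fraction is at least `occupancy` become match
#' states; the remaining columns feed the insert state of the preceding
#' node. Emissions are Laplace-smoothed weighted counts,
#' `(counts + pseudocount) / (total + 20 * pseudocount)`; transitions are
#' estimated from the weighted state paths of the rows with the same
#' pseudocount (transitions outside the Plan7 topology, e.g. delete
#' directly followed by insert, are ignored).
#'
#' @param aln An [msa].
#' @param occupancy Match-column threshold in (0, 1], default 0.5.
#' @param weighting `"henikoff"` (position-based, default) or `"none"`.
#' @param pseudocount Additive pseudocount, default 0.25. (A flat Laplace
#'   pseudocount of 1 flattens the profile of a typical 10-15 sequence seed
#'   family enough to cost tens of bits of sensitivity at 40-50% target
#'   identity; 0.25 keeps family-level homologs comfortably above the
#'   inclusion threshold without admitting background sequences.)
#' @param name Model name.
#' @return An uncalibrated `profile_hmm`.
#' @export
build_profile <- function(aln, occupancy = 0.5, weighting = c("henikoff", "none"),
                          pseudocount = 0.25, name = "model") {
  stopifnot(inherits(aln, "msa"))
  weighting <- match.arg(weighting)
  if (occupancy <= 0 || occupancy > 1) stop("occupancy must be in (0, 1]")
  chm <- do.call(rbind, strsplit(aln$rows, ""))
  n <- nrow(chm); L <- ncol(chm)
  occ <- colMeans(chm != "-")
  is_match <- occ >= occupancy
  M <- sum(is_match)
  if (M == 0) stop("no match columns")
  w <- if (weighting == "henikoff") henikoff_weights(aln$rows) else rep(1, n)

  pc <- pseudocount
  node_of_col <- cumsum(is_match)  # match node index of each match column
  match_cols <- which(is_match)

  match_emis <- matrix(0, M, 20)
  for (k in seq_len(M)) {
    col <- chm[, match_cols[k]]
    idx <- match(col, AA_ALPHABET)
    ok <- !is.na(idx)
    cnt <- numeric(20)
    if (any(ok)) cnt <- vapply(1:20, function(a) sum(w[ok][idx[ok] == a]), 0)
    match_emis[k, ] <- (cnt + pc) / (sum(cnt) + 20 * pc)
  }

  ins_emis <- matrix(0, M + 1, 20)
  ins_region <- node_of_col  # insert columns after match node j belong to I_j
  for (j in 0:M) {
    cols <- which(!is_match & ins_region == j)
    cnt <- numeric(20)
    for (cc in cols) {
      idx <- match(chm[, cc], AA_ALPHABET)
      ok <- !is.na(idx)
      if (any(ok)) cnt <- cnt + vapply(1:20, function(a) sum(w[ok][idx[ok] == a]), 0)
    }
    ins_emis[j + 1, ] <- (cnt + pc) / (sum(cnt) + 20 * pc)
  }

  # weighted transition counts along each row's state path
  cnt_tr <- matrix(0, M + 1, 7, dimnames = list(NULL, TRANS_COLS))
  for (i in seq_len(n)) {
    # states as (type, node): start at BEGIN = M node 0
    type <- "M"; node <- 0L
    for (cc in seq_len(L)) {
      ch <- chm[i, cc]
      if (is_match[cc]) {
        nxt_type <- if (ch == "-") "D" else "M"
        nxt_node <- node_of_col[cc]
      } else {
        if (ch == "-") next
        nxt_type <- "I"; nxt_node <- node_of_col[cc]
      }
      slot <- paste0(type, nxt_type)
      slot <- switch(slot, MM = "MM", MI = "MI", MD = "MD",
                     IM = "IM", II = "II", DM = "DM", DD = "DD", NA)
      if (!is.na(slot)) {
        from_node <- if (slot %in% c("MI", "II")) nxt_node else node
        cnt_tr[from_node + 1, slot] <- cnt_tr[from_node + 1, slot] + w[i]
      }
      type <- nxt_type; node <- nxt_node
    }
    # exit to END from the final state (recorded in the MM/IM/DM slots)
    slot <- switch(type, M = "MM", I = "IM", D = "DM")
    cnt_tr[M + 1, slot] <- cnt_tr[M + 1, slot] + if (node == M) w[i] else 0
  }

  trans <- matrix(0, M + 1, 7, dimnames = list(NULL, TRANS_COLS))
  for (j in 0:M) {
    r <- cnt_tr[j + 1, ]
    if (j < M) {
      m3 <- r[c("MM", "MI", "MD")] + pc
      trans[j + 1, c("MM", "MI", "MD")] <- m3 / sum(m3)
      d2 <- r[c("DM", "DD")] + pc
      trans[j + 1, c("DM", "DD")] <- d2 / sum(d2)
    } else {
      m2 <- r[c("MM", "MI")] + pc  # MM slot = M -> END
      trans[j + 1, c("MM", "MI")] <- m2 / sum(m2)
      trans[j + 1, "MD"] <- 0
      trans[j + 1, c("DM", "DD")] <- c(1, 0)
    }
    i2 <- r[c("IM", "II")] + pc
    trans[j + 1, c("IM", "II")] <- i2 / sum(i2)
  }
  trans[1, c("DM", "DD")] <- c(1, 0)  # no delete state at BEGIN

  new_profile_hmm(name, match_emis, ins_emis, trans)
}

# log2-odds emission and log2 transition matrices for the C++ kernels
hmm_logodds <- function(hmm) {
  lme <- log2(sweep(hmm$match_emis, 2, hmm$background, "/"))
  lie <- log2(sweep(hmm$ins_emis, 2, hmm$background, "/"))
  ltr <- suppressWarnings(log2(hmm$trans))
  ltr[hmm$trans == 0] <- -Inf
  list(lme = lme, lie = lie, ltr = ltr)
}

flank_loop_p <- function(len) len / (len + 2)

#' Forward log-odds score of a sequence
#'
#' `log2(P(w | model) / P(w | background))` where the background emits
#' residues i.i.d. from the model's background frequencies. Computed in log
#' space over all state paths. `X` residues are scored as
#' background-distributed (zero log-odds).
#'
#' @param hmm A `profile_hmm`.
#' @param seq A protein [seq_record] or residue string (non-empty).
#' @return Bit score (log2-odds), a finite scalar.
#' @export
forward_score <- function(hmm, seq) {
  s <- if (inherits(seq, "seq_record")) seq$residues else toupper(seq)
  if (nchar(s) == 0) stop("cannot score an empty sequence")
  lo <- hmm_logodds(hmm)
  phmm_forward_cpp(lo$lme, lo$lie, lo$ltr, aa_encode(s),
                   local = identical(hmm$mode, "local"),
                   loop_p = flank_loop_p(nchar(s)))
}

#' Viterbi decoding
#'
#' Most probable state path and its log2-odds score. Among equal-scoring
#' predecessors of a dynamic-programming cell the match state is preferred
#' over insert, and insert over delete, which makes the decoded path
#' deterministic.
#'
#' @inheritParams forward_score
#' @return `list(bit_score, path)`; `path` is a character vector from
#'   `"B"` to `"E"` with states like `"M3"`, `"I0"`, `"D2"`.
#' @export
viterbi <- function(hmm, seq) {
  s <- if (inherits(seq, "seq_record")) seq$residues else toupper(seq)
  if (nchar(s) == 0) stop("cannot score an empty sequence")
  lo <- hmm_logodds(hmm)
  res <- phmm_viterbi_cpp(lo$lme, lo$lie, lo$ltr, aa_encode(s),
                          local = identical(hmm$mode, "local"),
                          loop_p = flank_loop_p(nchar(s)))
  p <- res$path
  labels <- paste0(c("M", "I", "D")[p[, 1] + 1], p[, 2])
  list(bit_score = res$score, path = c("B", labels, "E"))
}

#' Background score sample
#'
#' Forward scores of `n` i.i.d. background sequences whose lengths are drawn
#' (with replacement) from `len_dist` — typically the lengths of the target
#' database, so that the null distribution matches the search context.
#'
#' @param hmm A `profile_hmm`.
#' @param n Number of sequences.
#' @param len_dist Integer vector of candidate lengths (default: the model
#'   length).
#' @param seed RNG seed.
#' @return Numeric vector of `n` bit scores.
#' @export
sample_background_scores <- function(hmm, n, len_dist = NULL, seed = 1) {
  len_dist <- as.integer(len_dist %||% hmm$M)
  len_dist <- len_dist[len_dist >= 1]
  if (length(len_dist) == 0) stop("len_dist contains no usable lengths")
  lo <- hmm_logodds(hmm)
  local <- identical(hmm$mode, "local")
  with_seed(seed, {
    lens <- if (length(len_dist) == 1) rep(len_dist, n)
            else sample(len_dist, n, replace = TRUE)
    seqs <- lapply(lens, function(L)
      sample.int(20L, L, replace = TRUE, prob = hmm$background) - 1L)
    # local-mode flank loop depends on length; score individually
    scores <- if (local) {
      vapply(seqs, function(sq)
        phmm_forward_cpp(lo$lme, lo$lie, lo$ltr, sq, TRUE,
                         flank_loop_p(length(sq))), 0)
    } else {
      as.numeric(phmm_score_batch_cpp(lo$lme, lo$lie, lo$ltr, seqs, FALSE, 0.9))
    }
    attr(scores, "lengths") <- lens
    scores
  })
}

#' Fit a Gumbel distribution to the upper tail of a score sample
#'
#' Censored maximum likelihood: scores above the `1 - tail_frac` quantile
#' enter through the density, the rest only through the count below the
#' threshold. Tail fitting is used because glocal forward scores of
#' background sequences are sums over many positions — approximately
#' Gaussian in the bulk — and only their upper tail is relevant (and well
#' approximated) for E-values.
#'
#' @param scores Numeric score sample.
#' @param tail_frac Fraction of the sample treated as tail (default 0.10;
#'   the upper decile tracks the local tail decay of the near-Gaussian
#'   glocal null closely, where a lower cut is visibly conservative).
#' @return `list(mu, lambda)` of the fitted Gumbel
#'   `P(S > s) = 1 - exp(-exp(-lambda * (s - mu)))`.
#' @export
fit_gumbel <- function(scores, tail_frac = 0.10) {
  if (length(scores) < 10) stop("need at least 10 scores")
  if (sd(scores) < 1e-9) stop("degenerate score variance")
  t0 <- quantile(scores, 1 - tail_frac, names = FALSE)
  tail <- scores[scores >= t0]
  n_below <- sum(scores < t0)
  lam0 <- 1.2825 / sd(scores)
  mu0 <- mean(scores) - 0.5772 / lam0
  nll <- function(par) {
    mu <- par[1]; lam <- exp(par[2])
    z <- lam * (tail - mu)
    ll_tail <- sum(log(lam) - z - exp(-z))
    ll_cens <- if (n_below > 0)
      n_below * log(max(exp(-exp(-lam * (t0 - mu))), 1e-300)) else 0
    -(ll_tail + ll_cens)
  }
  fit <- optim(c(mu0, log(lam0)), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(mu = fit$par[1], lambda = exp(fit$par[2]))
}

#' Calibrate a profile HMM for E-values
#'
#' Samples background forward scores at the target database's lengths and
#' fits a Gumbel tail (see [fit_gumbel]). Glocal scores have a strong
#' deterministic length trend (short targets pay delete penalties, long
#' ones insert penalties), so when `len_dist` spans several lengths the
#' null is made length-conditional: a linear fit of score on length is
#' removed first and the Gumbel describes the residuals, i.e. the location
#' parameter becomes `mu + alpha + beta * target_len`. With a constant
#' `len_dist` the trend is zero (`alpha = beta = 0`) and the calibration
#' reduces to a plain Gumbel on the scores. Reproducible given `seed`.
#'
#' @inheritParams sample_background_scores
#' @param n_samples Number of background sequences (minimum 200, default
#'   1000).
#' @param tail_frac Passed to [fit_gumbel].
#' @return The calibrated `profile_hmm`.
#' @export
calibrate <- function(hmm, n_samples = 1000, len_dist = NULL, seed = 1,
                      tail_frac = 0.10) {
  if (n_samples < 200) stop("n_samples must be at least 200")
  scores <- sample_background_scores(hmm, n_samples, len_dist, seed)
  lens <- attr(scores, "lengths")
  scores <- as.numeric(scores)
  if (sd(scores) < 1e-9) stop("degenerate score variance")
  if (length(unique(lens)) >= 3) {
    lfit <- stats::lm(scores ~ lens)
    alpha <- unname(stats::coef(lfit)[1])
    beta <- unname(stats::coef(lfit)[2])
    res <- unname(stats::resid(lfit))
  } else {
    alpha <- 0; beta <- 0; res <- scores
  }
  fit <- fit_gumbel(res, tail_frac)
  hmm$calib <- list(mu = fit$mu, lambda = fit$lambda,
                    alpha = alpha, beta = beta,
                    n_samples = n_samples, seed = seed,
                    tail_frac = tail_frac)
  hmm
}

#' E-value of a bit score
#'
#' `E = db_size * (1 - exp(-exp(-lambda * (s - mu_L))))` under the model's
#' Gumbel calibration, where `mu_L = mu + alpha + beta * target_len` is the
#' (possibly length-conditional, see [calibrate]) location parameter.
#' Monotone decreasing in `s`.
#'
#' @param hmm A calibrated `profile_hmm`.
#' @param bit_score Bit score(s).
#' @param db_size Number of sequences in the searched database.
#' @param target_len Target length(s); required when the calibration is
#'   length-conditional.
#' @return E-value(s).
#' @export
evalue <- function(hmm, bit_score, db_size, target_len = NULL) {
  if (is.null(hmm$calib)) stop("model is not calibrated")
  cal <- hmm$calib
  lam <- cal$lambda
  beta <- cal$beta %||% 0
  alpha <- cal$alpha %||% 0
  if (beta != 0 && is.null(target_len))
    stop("length-conditional calibration: target_len is required")
  mu_l <- cal$mu + alpha + beta * (target_len %||% 0)
  db_size * (1 - exp(-exp(-lam * (bit_score - mu_l))))
}

#' Search parameters
#'
#' @param evalue_threshold Inclusion threshold (default `1e-6`).
#' @param db_size Effective database size for E-values; defaults to the
#'   number of sequences actually searched.
#' @return A `search_params` list.
#' @export
search_params <- function(evalue_threshold = 1e-6, db_size = NULL) {
  stopifnot(evalue_threshold > 0)
  structure(list(evalue_threshold = evalue_threshold, db_size = db_size),
            class = "search_params")
}

#' Search a sequence database with a profile HMM
#'
#' Scores every target with the forward algorithm and reports those with
#' `E <= evalue_threshold`, sorted by ascending E-value (ties broken by
#' target id).
#'
#' @param hmm A calibrated `profile_hmm`.
#' @param db List of protein [seq_record] objects.
#' @param params A [search_params].
#' @return `data.frame` with columns `model`, `target`, `bit_score`,
#'   `evalue`, `target_len`.
#' @export
search <- function(hmm, db, params = search_params()) {
  if (is.null(hmm$calib)) stop("model is not calibrated")
  empty <- data.frame(model = character(), target = character(),
                      bit_score = numeric(), evalue = numeric(),
                      target_len = integer(), stringsAsFactors = FALSE)
  if (length(db) == 0) {
    warning("empty target database")
    return(empty)
  }
  strs <- seq_strings(db)
  lo <- hmm_logodds(hmm)
  local <- identical(hmm$mode, "local")
  enc <- lapply(strs, aa_encode)
  scores <- if (local) {
    vapply(enc, function(sq)
      phmm_forward_cpp(lo$lme, lo$lie, lo$ltr, sq, TRUE,
                       flank_loop_p(length(sq))), 0)
  } else {
    as.numeric(phmm_score_batch_cpp(lo$lme, lo$lie, lo$ltr, enc, FALSE, 0.9))
  }
  N <- params$db_size %||% length(db)
  ev <- evalue(hmm, scores, N, target_len = nchar(strs))
  keep <- ev <= params$evalue_threshold
  out <- data.frame(model = rep(hmm$name, sum(keep)),
                    target = seq_ids(db)[keep],
                    bit_score = scores[keep], evalue = ev[keep],
                    target_len = nchar(strs)[keep], stringsAsFactors = FALSE)
  out <- out[order(out$evalue, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a hit table
#'
#' Tab-separated `(model, target, bit_score, evalue, target_len)`.
#'
#' @param hits A hit `data.frame` from [search].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / read a profile HMM (plain text)
#'
#' Key-value header (`NAME`, `M`, `MODE`, optional `CALIB mu lambda`)
#' followed by the background, match-emission, insert-emission and
#' transition tables at full precision. Round-trip safe.
#'
#' @param hmm A `profile_hmm`.
#' @param path Output file.
#' @return `path` (write) or the `profile_hmm` (read).
#' @export
write_hmm <- function(hmm, path) {
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("NAME", hmm$name),
               paste("M", hmm$M),
               paste("MODE", hmm$mode)), con)
  if (!is.null(hmm$calib))
    writeLines(paste("CALIB", sprintf("%.17g", hmm$calib$mu),
                     sprintf("%.17g", hmm$calib$lambda),
                     sprintf("%.17g", hmm$calib$alpha %||% 0),
                     sprintf("%.17g", hmm$calib$beta %||% 0)), con)
  writeLines(paste("BACKGROUND", num(hmm$background)), con)
  writeLines("MATCH", con)
  for (j in seq_len(hmm$M)) writeLines(num(hmm$match_emis[j, ]), con)
  writeLines("INSERT", con)
  for (j in seq_len(hmm$M + 1)) writeLines(num(hmm$ins_emis[j, ]), con)
  writeLines("TRANS", con)
  for (j in seq_len(hmm$M + 1)) writeLines(num(hmm$trans[j, ]), con)
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  ln <- readLines(path)
  kv <- function(key) sub(paste0("^", key, " "), "",
                          grep(paste0("^", key, " "), ln, value = TRUE)[1])
  name <- kv("NAME"); M <- as.integer(kv("M")); mode <- kv("MODE")
  calib <- NULL
  if (any(grepl("^CALIB ", ln))) {
    v <- as.numeric(strsplit(kv("CALIB"), " ")[[1]])
    calib <- list(mu = v[1], lambda = v[2],
                  alpha = if (length(v) >= 3) v[3] else 0,
                  beta = if (length(v) >= 4) v[4] else 0)
  }
  bg <- as.numeric(strsplit(sub("^BACKGROUND ", "",
                                grep("^BACKGROUND ", ln, value = TRUE)), " ")[[1]])
  block <- function(tag, nrow) {
    i0 <- which(ln == tag) + 1
    do.call(rbind, lapply(ln[i0:(i0 + nrow - 1)], function(l)
      as.numeric(strsplit(l, " ")[[1]])))
  }
  new_profile_hmm(name, block("MATCH", M), block("INSERT", M + 1),
                  block("TRANS", M + 1), background = bg, mode = mode,
                  calib = calib)
}
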