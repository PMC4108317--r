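#' Alignment-based distance matrix
#'
#' `d[i, j] = 1 -` fractional identity of the optimal pairwise global
#' alignment (identity over all alignment columns), giving a symmetric
#' matrix with zero diagonal and entries in `[0, 1]`.
#'
#' @param seqs List of protein [seq_record] objects.
#' @inheritParams pairwise_align
#' @return A `distance_matrix`: `list(ids, d)`.
#' @export
distance_matrix <- function(seqs, matrix = blosum62(), gap_open = -10,
                            gap_extend = -1) {
  n <- length(seqs)
  if (n < 1) stop("need at least one sequence")
  strs <- seq_strings(seqs)
  d <- base::matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- 1 - pair_fid(strs[i], strs[j], matrix,
                                         gap_open, gap_extend)
    }
  }
  structure(list(ids = seq_ids(seqs), d = d), class = "distance_matrix")
}

#' OPTICS density ordering
#'
#' Standard OPTICS on a precomputed distance matrix: points are ordered by
#' reachability distance `max(core_dist(q), d(q, o))`, expanding from core
#' points (at least `min_pts` points, the point itself included, within
#' `eps`). Deterministic: the next unprocessed start point, and the seed
#' popped on a reachability tie, is always the earliest in input order.
#'
#' @param dm A [distance_matrix].
#' @param min_pts Core-point threshold (default 5, minimum 2).
#' @param eps Generating radius (default `Inf`).
#' @return An `optics_result`: ids in visiting order, their reachability and
#'   core distances (position-aligned with the ordering; the first point of
#'   every density-connected component has reachability `Inf`).
#' @export
optics <- function(dm, min_pts = 5, eps = Inf) {
  stopifnot(inherits(dm, "distance_matrix"), min_pts >= 2, eps > 0)
  d <- dm$d
  n <- nrow(d)
  core <- vapply(seq_len(n), function(i) {
    neigh <- sort(d[i, ])           # includes d(i, i) = 0
    within <- neigh[neigh <= eps]
    if (length(within) >= min_pts) neigh[min_pts] else Inf
  }, 0)

  processed <- logical(n)
  seedr <- rep(Inf, n)
  in_seeds <- logical(n)
  ord <- integer(0)
  reach_out <- rep(Inf, n)  # by position in ordering

  update <- function(x) {
    nb <- which(!processed & d[x, ] <= eps)
    nr <- pmax(core[x], d[x, nb])
    better <- nr < seedr[nb]
    seedr[nb[better]] <<- nr[better]
    in_seeds[nb[better]] <<- TRUE
  }

  for (p in seq_len(n)) {
    if (processed[p]) next
    processed[p] <- TRUE
    in_seeds[p] <- FALSE
    ord <- c(ord, p)
    if (is.finite(core[p])) {
      update(p)
      while (any(in_seeds)) {
        cand <- which(in_seeds)
        q <- cand[which.min(seedr[cand])]  # ties: earliest input index
        in_seeds[q] <- FALSE
        processed[q] <- TRUE
        ord <- c(ord, q)
        reach_out[length(ord)] <- seedr[q]
        if (is.finite(core[q])) update(q)
      }
    }
  }
  structure(list(ids = dm$ids, ordering = dm$ids[ord], order_idx = ord,
                 reachability = reach_out, core_dist = core[ord],
                 min_pts = min_pts, eps = eps),
            class = "optics_result")
}

#' @export
print.optics_result <- function(x, ...) {
  cat(sprintf("OPTICS ordering of %d points (min_pts = %d, eps = %s)\n",
              length(x$ordering), x$min_pts, format(x$eps)))
  invisible(x)
}

#' Reachability profile
#'
#' Two-column table (ordering position / reachability) suitable for a
#' reachability plot.
#'
#' @param res An [optics] result.
#' @return `data.frame(position, id, reachability)`.
#' @export
reachability_profile <- function(res) {
  data.frame(position = seq_along(res$ordering), id = res$ordering,
             reachability = res$reachability, stringsAsFactors = FALSE)
}

#' Extract flat clusters from an OPTICS ordering
#'
#' DBSCAN-style cut: walking the ordering, a reachability above `eps_prime`
#' either starts a new cluster (if the point is itself core at `eps_prime`)
#' or marks noise; reachabilities at or below the cut join the current
#' cluster. Clusters smaller than `min_cluster_size` are moved to noise.
#'
#' @param res An [optics] result.
#' @param eps_prime Cut distance, `<= res$eps`.
#' @param min_cluster_size Minimum retained cluster size (default 5).
#' @return A `cluster_set`: `list(clusters, noise)` partitioning the ids.
#' @export
extract_clusters <- function(res, eps_prime, min_cluster_size = 5) {
  stopifnot(inherits(res, "optics_result"), eps_prime <= res$eps)
  n <- length(res$ordering)
  lab <- integer(n)
  cur <- 0L
  for (k in seq_len(n)) {
    if (res$reachability[k] > eps_prime) {
      if (res$core_dist[k] <= eps_prime) {
        cur <- cur + 1L
        lab[k] <- cur
      } else lab[k] <- 0L
    } else lab[k] <- cur
  }
  clusters <- list()
  noise <- res$ordering[lab == 0L]
  if (cur > 0) {
    for (c in seq_len(cur)) {
      members <- res$ordering[lab == c]
      if (length(members) >= min_cluster_size) {
        clusters[[length(clusters) + 1]] <- members
      } else noise <- c(noise, members)
    }
  }
  structure(list(clusters = clusters, noise = noise), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster set: %d cluster(s) of sizes [%s]; %d noise point(s)\n",
              length(x$clusters),
              paste(vapply(x$clusters, length, 0L), collapse = ", "),
              length(x$noise)))
  invisible(x)
}

#' Write cluster assignments
#'
#' Tab-separated `(sequence_id, cluster)` with `noise` for unclustered
#' points.
#'
#' @param cs A [extract_clusters] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(cs, path) {
  rows <- data.frame(sequence_id = character(), cluster = character(),
                     stringsAsFactors = FALSE)
  for (i in seq_along(cs$clusters)) {
    rows <- rbind(rows, data.frame(sequence_id = cs$clusters[[i]],
                                   cluster = as.character(i),
                                   stringsAsFactors = FALSE))
  }
  if (length(cs$noise) > 0)
    rows <- rbind(rows, data.frame(sequence_id = cs$noise, cluster = "noise",
                                   stringsAsFactors = FALSE))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
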