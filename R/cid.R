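#' Clustering entropy of a bipartition
#'
#' The information content (in bits) of a two-block partition of n leaves
#' into sides of size a and b = n - a:
#' h = -(a/n) log2(a/n) - (b/n) log2(b/n). A balanced split carries 1 bit; a
#' near-trivial split carries almost none.
#'
#' @param a,b sizes of the two sides (both >= 1).
#' @return Entropy in bits.
#' @export
clustering_entropy <- function(a, b) {
  if (any(a < 1) || any(b < 1)) stop("empty split side", call. = FALSE)
  n <- a + b
  -(a / n) * log2(a / n) - (b / n) * log2(b / n)
}

# One cell of the mutual-information sum: c = cell count, r/k = margins.
mi_cell <- function(cc, r, k, n) {
  out <- numeric(length(cc))
  pos <- cc > 0
  out[pos] <- (cc[pos] / n) * log2(cc[pos] * n / (r[pos] * k[pos]))
  out
}

# Pairwise mutual clustering information between the split columns of two
# leaves x splits membership matrices over the same leaf order. Returns a
# k1 x k2 matrix in bits. Computing per-split entropies as the diagonal of
# mi_matrix(M, M) keeps the floating-point path identical to the cross terms,
# so identical split sets give exactly zero distance.
mi_matrix <- function(A, B) {
  n <- nrow(A)
  a <- colSums(A)
  b <- colSums(B)
  N11 <- crossprod(A, B)
  R <- matrix(a, length(a), length(b))
  K <- matrix(b, length(a), length(b), byrow = TRUE)
  N10 <- R - N11
  N01 <- K - N11
  N00 <- n - R - K + N11
  m <- mi_cell(N11, R, K, n) + mi_cell(N10, R, n - K, n) +
    mi_cell(N01, n - R, K, n) + mi_cell(N00, n - R, n - K, n)
  m <- matrix(m, length(a), length(b))
  m[m < 0] <- 0
  m
}

#' Mutual clustering information of two bipartitions
#'
#' Shared information (bits) between two splits over the same leaf universe,
#' computed from the 2x2 table of side co-memberships:
#' I = sum over cells c of (|c|/n) log2(|c| n / (|row| |col|)), empty cells
#' contributing 0. Always between 0 and min of the two split entropies.
#'
#' @param s1,s2 logical membership vectors over the same leaves (TRUE = side
#'   A), or character vectors of leaf labels with `universe` given.
#' @param universe leaf labels when `s1`/`s2` are label vectors.
#' @return Mutual information in bits.
#' @export
mutual_clustering_info <- function(s1, s2, universe = NULL) {
  if (!is.logical(s1)) {
    if (is.null(universe)) stop("universe required for label input", call. = FALSE)
    if (!all(s1 %in% universe) || !all(s2 %in% universe))
      stop("split labels outside universe", call. = FALSE)
    s1 <- universe %in% s1
    s2 <- universe %in% s2
  }
  if (length(s1) != length(s2)) stop("leaf universe mismatch", call. = FALSE)
  drop(mi_matrix(matrix(s1), matrix(s2)))
}

# Exact solver for the assignment problem (square cost matrix, minimise):
# Jonker-Volgenant style shortest augmenting paths with potentials, O(n^3).
# Returns assigned column for each row. Used for the maximum-weight matching
# of splits inside the clustering information distance; no LSAP solver is
# re-used because the matching over dummy-padded split sets is part of the
# metric's definition.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n)
  vv <- numeric(n + 1)      # vv[j + 1] = potential of column j, col 0 virtual
  pp <- integer(n + 1)      # pp[j + 1] = row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    pp[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- pp[j0 + 1]
      delta <- Inf
      j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - vv[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          if (pp[j + 1] > 0) u[pp[j + 1]] <- u[pp[j + 1]] + delta
          vv[j + 1] <- vv[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (pp[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      pp[j0 + 1] <- pp[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  match_of_row <- integer(n)
  for (j in seq_len(n)) match_of_row[pp[j + 1]] <- j
  match_of_row
}

# Canonicalize split membership columns so the side containing the first
# leaf is TRUE, making identical splits identical columns.
canon_splits <- function(M) {
  flip <- !M[1, , drop = TRUE]
  M[, flip] <- !M[, flip, drop = FALSE]
  M
}

split_keys_of_matrix <- function(M) {
  apply(canon_splits(M) + 0L, 2, paste, collapse = "")
}

# Core CID computation on two aligned membership matrices.
cid_core <- function(S1, S2) {
  k1 <- ncol(S1)
  k2 <- ncol(S2)
  h1v <- if (k1 > 0) diag(mi_matrix(S1, S1)) else numeric(0)
  h2v <- if (k2 > 0) diag(mi_matrix(S2, S2)) else numeric(0)
  h1 <- sum(h1v)
  h2 <- sum(h2v)
  if (k1 == 0 || k2 == 0) {
    raw <- h1 + h2
    return(list(shared = 0, h1 = h1, h2 = h2, raw = raw,
                cid = if (raw > 0) 1 else 0))
  }
  if (k1 == k2 && setequal(split_keys_of_matrix(S1), split_keys_of_matrix(S2))) {
    # identical unrooted split sets: distance is exactly zero by definition
    return(list(shared = (h1 + h2) / 2, h1 = h1, h2 = h2, raw = 0, cid = 0))
  }
  W <- mi_matrix(S1, S2)
  m <- max(k1, k2)
  Wp <- matrix(0, m, m)           # dummy splits carry exactly zero weight
  Wp[seq_len(k1), seq_len(k2)] <- W
  asg <- solve_assignment(-Wp)
  shared <- sum(Wp[cbind(seq_len(m), asg)])
  raw <- max(h1 + h2 - 2 * shared, 0)
  list(shared = shared, h1 = h1, h2 = h2, raw = raw,
       cid = if (h1 + h2 > 0) raw / (h1 + h2) else 0)
}

#' Clustering information distance between two trees
#'
#' Information-theoretic generalized Robinson-Foulds distance: each tree is
#' reduced to its unrooted nontrivial splits, pairwise mutual clustering
#' information between splits is computed, and a maximum-weight matching
#' (smaller side padded with zero-weight dummy splits) gives the shared
#' information S. The raw distance is h1 + h2 - 2 S bits, where h_i is the
#' total clustering information of tree i; normalization divides by h1 + h2
#' so the distance lies in [0, 1], with 0 exactly when the split sets are
#' identical and 1 when no clustering information is shared.
#'
#' @param t1,t2 [ape::phylo] trees; leaf sets are pruned to their
#'   intersection (with a warning) when they differ.
#' @param normalize return the normalized distance (default TRUE).
#' @return list with `cid` (normalized if requested), `raw_distance` (bits),
#'   `h1`, `h2`, `shared_info` (bits) and `n_leaves`.
#' @export
cid <- function(t1, t2, normalize = TRUE) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  common <- intersect(t1$tip.label, t2$tip.label)
  if (length(common) < 4)
    stop("fewer than 4 shared leaves: no nontrivial splits", call. = FALSE)
  if (length(common) < length(t1$tip.label) ||
      length(common) < length(t2$tip.label)) {
    warning("leaf sets differ; pruning to the ", length(common),
            " shared leaves", call. = FALSE)
    t1 <- ape::keep.tip(t1, common)
    t2 <- ape::keep.tip(t2, common)
  }
  labels <- sort(common)
  res <- cid_core(split_matrix(t1, labels), split_matrix(t2, labels))
  list(cid = if (normalize) res$cid else res$raw,
       raw_distance = res$raw, h1 = res$h1, h2 = res$h2,
       shared_info = res$shared, n_leaves = length(labels))
}

#' Tip-shuffle permutation test of topological congruence
#'
#' Computes the (normalized) clustering information distance between a
#' microbiome dendrogram and a host tree, then builds a null distribution by
#' shuffling the dendrogram's tip labels uniformly at random (topology
#' fixed) `n_perm` times. The p-value is the proportion of shuffles with
#' strictly lower CID than the point estimate; `corrected = TRUE` instead
#' uses (#\{null <= point\} + 1) / (n_perm + 1).
#'
#' @param t_micro microbiome dendrogram ([ape::phylo]).
#' @param t_host host tree ([ape::phylo]).
#' @param n_perm number of label shuffles (default 1000).
#' @param seed integer seed.
#' @param normalize use the normalized distance (default TRUE).
#' @param corrected use the add-one small-sample p-value convention.
#' @return list of class `congruence_result`: `cid`, `raw_distance`, `h1`,
#'   `h2`, `shared_info`, `null_cids`, `p_value`, `n_perm`, `seed`.
#' @export
cid_permutation_test <- function(t_micro, t_host, n_perm = 1000, seed,
                                 normalize = TRUE, corrected = FALSE) {
  stopifnot(n_perm >= 1)
  common <- intersect(t_micro$tip.label, t_host$tip.label)
  if (length(common) < 4)
    stop("fewer than 4 shared leaves", call. = FALSE)
  if (length(common) < length(t_micro$tip.label) ||
      length(common) < length(t_host$tip.label)) {
    t_micro <- ape::keep.tip(t_micro, common)
    t_host <- ape::keep.tip(t_host, common)
  }
  labels <- sort(common)
  S1 <- split_matrix(t_micro, labels)
  S2 <- split_matrix(t_host, labels)
  point <- cid_core(S1, S2)
  stat <- function(res) if (normalize) res$cid else res$raw
  obs <- stat(point)
  n <- length(labels)
  null_cids <- with_seed(seed, vapply(seq_len(n_perm), function(r) {
    perm <- sample.int(n)
    stat(cid_core(S1[perm, , drop = FALSE], S2))
  }, 0))
  p <- if (corrected) (sum(null_cids <= obs) + 1) / (n_perm + 1)
       else sum(null_cids < obs) / n_perm
  structure(list(cid = obs, raw_distance = point$raw, h1 = point$h1,
                 h2 = point$h2, shared_info = point$shared,
                 null_cids = null_cids, p_value = p, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "congruence_result")
}

#' @export
print.congruence_result <- function(x, ...) {
  cat(sprintf("CID = %.3f (raw %.3f bits; h1 = %.3f, h2 = %.3f, shared = %.3f)\n",
              x$cid, x$raw_distance, x$h1, x$h2, x$shared_info))
  cat(sprintf("tip-shuffle test: P = %.4g (%d permutations)\n", x$p_value, x$n_perm))
  invisible(x)
}
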