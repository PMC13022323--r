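# Fixture builders and independent oracles shared across the suite.

# Small OTU table from a counts matrix; taxonomy defaults to one genus per OTU.
toy_table <- function(counts, genus = NULL, species = NULL, study = NULL,
                      sample_type = "shark") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("otu", seq_len(ncol(counts)))
  n_otu <- ncol(counts)
  tax <- data.frame(otu_id = colnames(counts),
                    domain = "Bacteria", phylum = "Pseudomonadota",
                    class = "Gammaproteobacteria", order = "ord",
                    family = "fam",
                    genus = genus %||% paste0("g_", seq_len(n_otu)))
  meta <- data.frame(sample_id = rownames(counts),
                     species = species %||% rownames(counts),
                     study = study %||% "study1",
                     sample_type = sample_type)
  otu_table(counts, tax, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_dist <- function(n, seed, labels = sprintf("t%02d", seq_len(n))) {
  set.seed(seed)
  m <- as.matrix(stats::dist(matrix(stats::rnorm(n * 3), n)))
  dimnames(m) <- list(labels, labels)
  dist_matrix(m)
}

# Independent Ward oracle: naive Lance-Williams agglomeration (ward.D2:
# squared dissimilarities, heights square-rooted). Returns the set of leaf
# clusters formed, as a character vector of sorted-label keys.
ward_oracle_clusters <- function(m) {
  m <- as.matrix(m)
  labs <- rownames(m)
  d2 <- m^2
  active <- as.list(seq_along(labs))
  sizes <- rep(1, length(labs))
  cur <- d2
  merges <- character(0)
  while (length(active) > 1) {
    n <- nrow(cur)
    best <- c(Inf, 0, 0)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      w <- cur[i, j]
      if (w < best[1]) best <- c(w, i, j)
    }
    i <- best[2]; j <- best[3]
    ni <- sizes[i]; nj <- sizes[j]
    newclust <- c(active[[i]], active[[j]])
    merges <- c(merges, paste(sort(labs[newclust]), collapse = "|"))
    # Lance-Williams update for Ward on squared dissimilarities
    keep <- setdiff(seq_len(n), c(i, j))
    newrow <- vapply(keep, function(k) {
      nk <- sizes[k]
      ((ni + nk) * cur[i, k] + (nj + nk) * cur[j, k] - nk * cur[i, j]) /
        (ni + nj + nk)
    }, 0)
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newrow),
                 c(newrow, 0))
    active <- c(active[keep], list(newclust))
    sizes <- c(sizes[keep], ni + nj)
  }
  merges
}

# Clade keys of a dendrogram (internal nodes, all sizes).
tree_clade_keys <- function(tree) {
  labs <- tree$tip.label
  vapply(ape::prop.part(tree), function(i) paste(sort(labs[i]), collapse = "|"), "")
}

# Brute-force CID oracle: enumerate every injective assignment of the
# smaller split set into the larger one and maximize total mutual
# clustering information directly from the split definitions.
cid_oracle <- function(t1, t2, normalize = TRUE) {
  labels <- sort(intersect(t1$tip.label, t2$tip.label))
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  n <- length(labels)
  ent <- function(s) clustering_entropy(length(s), n - length(s))
  h1 <- sum(vapply(s1, ent, 0))
  h2 <- sum(vapply(s2, ent, 0))
  if (length(s1) > length(s2)) { tmp <- s1; s1 <- s2; s2 <- tmp }
  k1 <- length(s1); k2 <- length(s2)
  best <- 0
  if (k1 > 0) {
    idx <- utils::combn(k2, k1, simplify = FALSE)
    for (cols in idx) {
      perms <- perms_of(k1)
      for (p in perms) {
        tot <- sum(vapply(seq_len(k1), function(i)
          mutual_clustering_info(s1[[i]], s2[[cols[p[i]]]], universe = labels), 0))
        if (tot > best) best <- tot
      }
    }
  }
  raw <- max(h1 + h2 - 2 * best, 0)
  if (normalize) { if (h1 + h2 > 0) raw / (h1 + h2) else 0 } else raw
}

perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1)) for (i in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p + (p >= i), i, after = i - 1)
  }
  # simpler: use recursion below instead
  out
}

# The append trick above is error-prone; replace with a plain generator.
perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in perms_of(n - 1)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# All permutations of 1..n as a matrix, built independently of the package.
perm_matrix_oracle <- function(n) {
  do.call(rbind, lapply(perms_of(n), as.integer))
}

# Pearson correlation of lower triangles, written independently of the
# package's vectorization helpers.
tri_cor <- function(a, b) {
  stats::cor(a[lower.tri(a)], b[lower.tri(b)])
}
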