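#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerates samples into a binary rooted dendrogram by Ward's
#' minimum-variance criterion. The default "ward.D2" dialect squares the
#' dissimilarities inside the Lance-Williams recurrence and reports merge
#' heights on the original scale; "ward.D" applies the recurrence to raw
#' dissimilarities and is kept for comparison since published analyses do not
#' always name the dialect.
#'
#' @param d a [dist_matrix()].
#' @param method "ward.D2" (default) or "ward.D".
#' @return An [ape::phylo] dendrogram over the labels of `d` (rooted,
#'   binary, with merge heights as branch lengths).
#' @export
ward_cluster <- function(d, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  stopifnot(inherits(d, "dist_matrix"), nrow(d) >= 2)
  if (any(is.na(d))) stop("NaN in distance matrix", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(unclass(d)), method = method)
  ape::as.phylo(hc)
}

# Canonical string key of the bipartition separating `side` from the rest of
# `universe`: the side containing the alphabetically first leaf, sorted.
# Complementary sides map to the same key, so A|B == B|A.
split_key <- function(side, universe) {
  if (!universe[1] %in% side) side <- setdiff(universe, side)
  paste(sort(side), collapse = "\r")
}

#' Extract splits (bipartitions) or clades from a tree
#'
#' With `rooted = FALSE` (default), returns the nontrivial bipartitions of
#' the leaf set induced by the internal edges of the tree read as unrooted
#' (both sides >= 2 leaves; complements identified). With `rooted = TRUE`,
#' returns the clades (leaf subsets of internal nodes, excluding the root and
#' singletons).
#'
#' @param tree an [ape::phylo].
#' @param rooted treat the tree as rooted (clades) or unrooted (splits).
#' @return A list of character vectors of leaf labels, one per split/clade;
#'   for splits, each is the side containing the alphabetically first leaf.
#' @export
tree_splits <- function(tree, rooted = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  universe <- sort(labs)
  n <- length(labs)
  clades <- lapply(ape::prop.part(tree), function(i) labs[i])
  if (rooted) {
    keep <- vapply(clades, function(s) length(s) >= 2 && length(s) < n, TRUE)
    return(unique(clades[keep]))
  }
  keys <- character(0)
  out <- list()
  for (s in clades) {
    if (length(s) < 2 || length(s) > n - 2) next
    side <- if (universe[1] %in% s) s else setdiff(universe, s)
    k <- paste(sort(side), collapse = "\r")
    if (!k %in% keys) {
      keys <- c(keys, k)
      out <- c(out, list(sort(side)))
    }
  }
  out
}

# Splits as a leaves x splits logical membership matrix aligned to `labels`
# (used by the clustering information distance).
split_matrix <- function(tree, labels = sort(tree$tip.label)) {
  sp <- tree_splits(tree, rooted = FALSE)
  m <- matrix(FALSE, length(labels), length(sp),
              dimnames = list(labels, NULL))
  for (j in seq_along(sp)) m[sp[[j]], j] <- TRUE
  m
}

#' Reroot a tree at an outgroup leaf
#'
#' Attaches the outgroup at the root for display; the unrooted split set is
#' unchanged, so congruence statistics are unaffected.
#'
#' @param tree an [ape::phylo].
#' @param outgroup a leaf label.
#' @return A rerooted `phylo`.
#' @export
reroot_tree <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup %in% tree$tip.label)
    stop("unknown leaf label: ", outgroup, call. = FALSE)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()]; support
#' values are carried as internal node labels.
#'
#' @param path Newick file path.
#' @return [read_newick()] returns an [ape::phylo].
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ape::read.tree(path)
}

#' @rdname read_newick
#' @param tree an [ape::phylo].
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' OTU-bootstrap branch support for a sample dendrogram
#'
#' Builds the point-estimate Ward dendrogram from the full table, then
#' resamples OTU columns with replacement (same number of columns) `reps`
#' times; each internal branch of the point tree is annotated with the
#' proportion of replicate dendrograms whose unrooted split set contains that
#' branch's split. Replicates in which some sample loses all reads have an
#' undefined dissimilarity and are skipped (counted and reported).
#'
#' @param table an [otu_table()] (normally rarefied).
#' @param distance "bray_curtis" or "jaccard".
#' @param reps number of bootstrap replicates.
#' @param seed integer seed.
#' @param method Ward dialect, see [ward_cluster()].
#' @return The point-estimate dendrogram with `node.label` holding support
#'   proportions (trivial splits get 1) and attributes `n_reps_used`,
#'   `n_failed`.
#' @export
bootstrap_support <- function(table, distance = c("bray_curtis", "jaccard"),
                              reps = 1000, seed, method = "ward.D2") {
  distance <- match.arg(distance)
  stopifnot(inherits(table, "otu_table"), reps >= 1)
  d_fun <- switch(distance, bray_curtis = bray_curtis, jaccard = jaccard)
  point <- ward_cluster(d_fun(table), method = method)
  universe <- sort(point$tip.label)
  n <- length(universe)
  labs <- point$tip.label
  # clade (and split key) per internal node of the point tree
  clades <- lapply(ape::prop.part(point), function(i) labs[i])
  keys <- vapply(clades, split_key, "", universe = universe)
  trivial <- vapply(clades, function(s) length(s) < 2 | length(s) > n - 2, TRUE)
  hits <- integer(length(keys))
  n_otus <- ncol(table$counts)
  failed <- 0L
  with_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sample.int(n_otus, n_otus, replace = TRUE)
      cts <- table$counts[, idx, drop = FALSE]
      if (any(rowSums(cts) == 0)) { failed <- failed + 1L; next }
      boot <- otu_table_quick(cts, table)
      bt <- ward_cluster(suppressWarnings(d_fun(boot)), method = method)
      bkeys <- vapply(tree_splits(bt), function(s) paste(s, collapse = "\r"), "")
      hits <- hits + (keys %in% bkeys)
    }
  })
  used <- reps - failed
  if (failed > 0)
    warning(failed, " bootstrap replicate(s) skipped (all-zero sample)", call. = FALSE)
  supp <- ifelse(trivial, 1, if (used > 0) hits / used else NA_real_)
  point$node.label <- formatC(supp, format = "fg", digits = 3)
  attr(point, "support") <- supp
  attr(point, "n_reps_used") <- used
  attr(point, "n_failed") <- failed
  point
}

# Rebuild an otu_table around a resampled count matrix without re-running
# full validation (bootstrap inner loop); duplicated columns get unique names.
otu_table_quick <- function(counts, template) {
  colnames(counts) <- make.unique(colnames(counts))
  structure(list(counts = counts, taxonomy = NULL, samples = template$samples),
            class = "otu_table")
}

#' Expand a species-level host tree and distance matrix to sample level
#'
#' Panels may hold several samples of the same host species (replicates
#' across studies). For tree comparison each species tip is replaced by a
#' zero-length polytomy of its sample ids; for distance-based tests the host
#' distance between two samples is the distance between their species (0 for
#' conspecifics).
#'
#' @param host_tree species-level [ape::phylo].
#' @param host_dist species-level [dist_matrix()] (optional).
#' @param samples sample metadata data.frame with `sample_id` and `species`.
#' @return list with `tree` (sample-level phylo) and `dist` (sample-level
#'   dist_matrix or NULL).
#' @export
expand_host_to_samples <- function(host_tree, host_dist = NULL, samples) {
  sp <- as.character(samples$species)
  ids <- as.character(samples$sample_id)
  miss <- setdiff(unique(sp), host_tree$tip.label)
  if (length(miss) > 0)
    stop("species absent from host tree: ", paste(miss, collapse = ", "), call. = FALSE)
  tr <- ape::keep.tip(host_tree, unique(sp))
  nwk <- ape::write.tree(tr)
  for (s in unique(sp)) {
    reps <- ids[sp == s]
    repl <- if (length(reps) == 1) reps else
      paste0("(", paste0(reps, ":0", collapse = ","), ")")
    nwk <- gsub(sprintf("(?<![A-Za-z0-9_.])%s(?![A-Za-z0-9_.])", s), repl,
                nwk, perl = TRUE)
  }
  out_tree <- ape::read.tree(text = nwk)
  out_dist <- NULL
  if (!is.null(host_dist)) {
    m <- unclass(align_dist(host_dist, unique(sp)))[sp, sp, drop = FALSE]
    dimnames(m) <- list(ids, ids)
    out_dist <- dist_matrix(m)
  }
  list(tree = out_tree, dist = out_dist)
}
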