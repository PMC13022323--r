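#' Score OTU-resampling replicates for phylosymbiotic signal
#'
#' The discovery engine: resample OTU columns — bootstrap (with replacement,
#' full size) or subsample (without replacement, size `k`) — `n_reps` times;
#' for each replicate compute Bray-Curtis dissimilarity on the reduced
#' table, the Ward dendrogram and its clustering information distance to the
#' host tree, and the (partial) Mantel correlation between the replicate
#' dissimilarity and host phylogenetic distance. Mantel scoring uses the
#' point correlation only (replicates are thresholded on r, not tested
#' individually). Replicates producing a degenerate dissimilarity (a sample
#' with no reads left) are recorded as failed, not scored.
#'
#' The host tree and distance matrix are species-level and are expanded to
#' the sample panel via [expand_host_to_samples()]; CID scoring keeps all
#' samples of `table`, while Mantel scoring drops `outgroup` samples (no
#' nucleotide distance is defined for the outgroup) and conditions on
#' `design` when given.
#'
#' @param table an [otu_table()] (normally rarefied), the discovery panel.
#' @param host_tree species-level [ape::phylo].
#' @param host_dist species-level [dist_matrix()] of host phylogenetic
#'   distances.
#' @param design optional sample-level conditioning [dist_matrix()] (study
#'   design); NULL for single-study panels.
#' @param mode "subsample" or "bootstrap".
#' @param n_reps number of replicates.
#' @param k subsample size (mode = "subsample"; default 10).
#' @param seed integer seed.
#' @param outgroup species label(s) excluded from Mantel scoring.
#' @param method Ward dialect.
#' @return list of class `replicate_scores`: data.frame `scores`
#'   (replicate, cid, mantel_r, failed), list `otus` of replicate OTU draws,
#'   and the call settings.
#' @export
score_replicates <- function(table, host_tree, host_dist, design = NULL,
                             mode = c("subsample", "bootstrap"),
                             n_reps = 10000, k = 10, seed,
                             outgroup = NULL, method = "ward.D2") {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "otu_table"))
  n_otus <- ncol(table$counts)
  if (n_otus == 0) stop("empty table", call. = FALSE)
  if (mode == "subsample") {
    if (k < 2) stop("k must be >= 2", call. = FALSE)
    if (k > n_otus) stop("k exceeds the number of OTUs", call. = FALSE)
  }
  host <- expand_host_to_samples(host_tree, host_dist, table$samples)
  cid_labels <- sort(rownames(table$counts))
  S_host <- split_matrix(host$tree, cid_labels)
  mantel_ids <- table$samples$sample_id[!(table$samples$species %in% outgroup)]
  mantel_ids <- sort(mantel_ids)
  vb <- lower_vec(host$dist, mantel_ids)
  vc <- if (!is.null(design)) lower_vec(design, mantel_ids) else NULL
  counts <- table$counts
  cid_v <- mantel_v <- rep(NA_real_, n_reps)
  failed <- logical(n_reps)
  otus <- vector("list", n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      idx <- if (mode == "bootstrap") sample.int(n_otus, n_otus, replace = TRUE)
             else sample.int(n_otus, k)
      otus[[r]] <- colnames(counts)[idx]
      cts <- counts[, idx, drop = FALSE]
      if (any(rowSums(cts) == 0)) { failed[r] <- TRUE; next }
      bc <- as.matrix(vegan::vegdist(cts, method = "bray"))
      hc <- stats::hclust(stats::as.dist(bc), method = method)
      S_rep <- split_matrix(ape::as.phylo(hc), cid_labels)
      cid_v[r] <- cid_core(S_rep, S_host)$cid
      va <- bc[mantel_ids, mantel_ids][lower.tri(diag(length(mantel_ids)))]
      if (stats::sd(va) > 0) {
        mantel_v[r] <- tryCatch(
          if (is.null(vc)) stats::cor(va, vb) else partial_r(va, vb, vc, "pearson"),
          error = function(e) NA_real_)
      }
    }
  })
  structure(list(scores = data.frame(replicate = seq_len(n_reps),
                                     cid = cid_v, mantel_r = mantel_v,
                                     failed = failed),
                 otus = otus, mode = mode, k = if (mode == "subsample") k else n_otus,
                 n_reps = n_reps, seed = as.integer(seed),
                 outgroup = outgroup, conditioned = !is.null(design)),
            class = "replicate_scores")
}

#' @export
print.replicate_scores <- function(x, ...) {
  ok <- !x$scores$failed
  cat(sprintf("%s replicates: %d (%d failed); CID range [%.3f, %.3f]; Mantel r range [%.3f, %.3f]\n",
              x$mode, x$n_reps, sum(!ok),
              min(x$scores$cid[ok]), max(x$scores$cid[ok]),
              min(x$scores$mantel_r[ok], na.rm = TRUE),
              max(x$scores$mantel_r[ok], na.rm = TRUE)))
  invisible(x)
}

#' Collect OTUs from qualifying replicates
#'
#' A replicate qualifies on topology when its CID is at most `cid_max`
#' (default 0, i.e. perfect congruence, applied with a 1e-12 floating-point
#' tolerance) and on distance when its Mantel r is at least `r_min`
#' (default 0.9). Each criterion's OTU set is the union of distinct OTU ids
#' over its qualifying replicates; `min_replicates` > 1 gives the
#' frequency-weighted variant (an OTU must occur in at least that many
#' qualifying replicates).
#'
#' @param reps a [score_replicates()] result.
#' @param cid_max CID threshold (default 0 = perfect congruence).
#' @param r_min minimum Mantel correlation (default 0.9).
#' @param min_replicates minimum number of qualifying replicates an OTU
#'   must appear in (default 1 = plain union).
#' @return list of class `discovery_result`: qualifying counts, the
#'   fraction of scored replicates qualifying, and OTU sets `otus_cid`,
#'   `otus_mantel`.
#' @export
qualifying_otus <- function(reps, cid_max = 0, r_min = 0.9, min_replicates = 1) {
  stopifnot(inherits(reps, "replicate_scores"))
  sc <- reps$scores
  q_cid <- !sc$failed & !is.na(sc$cid) & sc$cid <= cid_max + 1e-12
  q_mantel <- !sc$failed & !is.na(sc$mantel_r) & sc$mantel_r >= r_min
  union_of <- function(flags) {
    ids <- unlist(lapply(which(flags), function(i) unique(reps$otus[[i]])))
    if (min_replicates > 1) {
      tab <- table(ids)
      sort(names(tab)[tab >= min_replicates])
    } else sort(unique(ids))
  }
  n_scored <- sum(!sc$failed)
  structure(list(n_reps = reps$n_reps, n_scored = n_scored,
                 n_failed = sum(sc$failed),
                 n_qualifying_cid = sum(q_cid),
                 n_qualifying_mantel = sum(q_mantel),
                 frac_qualifying_cid = sum(q_cid) / n_scored,
                 frac_qualifying_mantel = sum(q_mantel) / n_scored,
                 otus_cid = union_of(q_cid),
                 otus_mantel = union_of(q_mantel),
                 qualifies_cid = q_cid, qualifies_mantel = q_mantel,
                 cid_max = cid_max, r_min = r_min, mode = reps$mode),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("discovery (%s): %d/%d replicates CID-qualifying (<= %g), %d Mantel-qualifying (r >= %g)\n",
              x$mode, x$n_qualifying_cid, x$n_scored, x$cid_max,
              x$n_qualifying_mantel, x$r_min))
  cat(sprintf("OTU sets: %d (CID criterion), %d (Mantel criterion)\n",
              length(x$otus_cid), length(x$otus_mantel)))
  invisible(x)
}

#' Intersections and recovery between criterion OTU sets
#'
#' Given two or more named OTU sets (e.g. bootstrap-CID, subsample-CID and
#' subsample-Mantel), reports each pairwise intersection and the full
#' consensus, together with recovery percentages: `recovery_pct[i, j]` is
#' the percentage of set i also found in set j.
#'
#' @param sets named list of at least two character vectors.
#' @return list of class `consensus_sets`: `sizes`, `intersections` (named
#'   list incl. `consensus` = intersection of all sets), `recovery_pct`
#'   matrix.
#' @export
consensus_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  nm <- names(sets)
  inter <- list()
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i < j)
      inter[[paste(nm[i], nm[j], sep = " & ")]] <-
        sort(intersect(sets[[i]], sets[[j]]))
  }
  inter$consensus <- sort(Reduce(intersect, sets))
  rec <- matrix(NA_real_, length(sets), length(sets), dimnames = list(nm, nm))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    rec[i, j] <- if (length(sets[[i]]) > 0)
      100 * length(intersect(sets[[i]], sets[[j]])) / length(sets[[i]])
    else NA_real_
  }
  structure(list(sizes = vapply(sets, length, 0L), sets = sets,
                 intersections = inter,
                 intersection_sizes = vapply(inter, length, 0L),
                 recovery_pct = rec),
            class = "consensus_sets")
}

#' @export
print.consensus_sets <- function(x, ...) {
  cat("set sizes:", paste(sprintf("%s = %d", names(x$sizes), x$sizes), collapse = ", "), "\n")
  cat("consensus size:", length(x$intersections$consensus), "\n")
  cat("recovery (%):\n")
  print(round(x$recovery_pct, 1))
  invisible(x)
}

#' Re-evaluate a candidate OTU set on a sample panel
#'
#' Subsets the table to the candidate OTUs (typically a consensus set found
#' on the discovery panel) and runs the full tip-shuffle CID test and the
#' (partial) Mantel permutation test on the target panel — which may differ
#' from the discovery panel (e.g. core-study discovery, all-sample
#' validation), keeping the discovery/validation separation explicit.
#'
#' @param candidate_otus character vector of OTU ids, all present in
#'   `table`.
#' @param table an [otu_table()] defining the target panel.
#' @param host_tree,host_dist species-level host tree and distance matrix.
#' @param design optional conditioning [dist_matrix()]; NULL for plain
#'   Mantel.
#' @param n_perm permutations for both tests (default 1000).
#' @param seed integer seed (split between the two tests).
#' @param outgroup species excluded from the Mantel test.
#' @param panel_id optional label carried into the result.
#' @param method Ward dialect.
#' @return list of class `reevaluation`: `cid_test`
#'   ([cid_permutation_test()] result), `mantel_test` ([mantel()] /
#'   [partial_mantel()] result), `dendrogram`, `n_otus`, `panel_id`.
#' @export
reevaluate <- function(candidate_otus, table, host_tree, host_dist,
                       design = NULL, n_perm = 1000, seed, outgroup = NULL,
                       panel_id = "panel", method = "ward.D2") {
  stopifnot(inherits(table, "otu_table"))
  miss <- setdiff(candidate_otus, colnames(table$counts))
  if (length(miss) > 0)
    stop("candidate OTU(s) absent from panel table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  sub <- subset_table(table, otus = candidate_otus)
  if (any(rowSums(sub$counts) == 0))
    stop("candidate set leaves sample(s) empty on this panel", call. = FALSE)
  seeds <- split_seed(seed, 2)
  host <- expand_host_to_samples(host_tree, host_dist, sub$samples)
  dend <- ward_cluster(suppressWarnings(bray_curtis(sub)), method = method)
  cid_test <- cid_permutation_test(dend, host$tree, n_perm = n_perm,
                                   seed = seeds[1])
  mantel_ids <- sub$samples$sample_id[!(sub$samples$species %in% outgroup)]
  msub <- subset_table(sub, samples = mantel_ids)
  bc <- suppressWarnings(bray_curtis(msub))
  hd <- align_dist(host$dist, mantel_ids)
  mantel_test <- if (is.null(design)) {
    mantel(bc, hd, n_perm = n_perm, seed = seeds[2])
  } else {
    partial_mantel(bc, hd, align_dist(design, mantel_ids),
                   n_perm = n_perm, seed = seeds[2])
  }
  structure(list(cid_test = cid_test, mantel_test = mantel_test,
                 dendrogram = dend, n_otus = length(unique(candidate_otus)),
                 panel_id = panel_id, seed = as.integer(seed)),
            class = "reevaluation")
}

#' @export
print.reevaluation <- function(x, ...) {
  cat(sprintf("re-evaluation on panel '%s' (%d OTUs):\n", x$panel_id, x$n_otus))
  print(x$cid_test)
  print(x$mantel_test)
  invisible(x)
}
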