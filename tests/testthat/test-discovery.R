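# A 4-species panel whose every OTU carries the same clean (a,b)|(c,d)
# structure: any subset's Bray-Curtis dendrogram matches the host tree.
clean_panel <- function(n_otus = 6) {
  host <- ape::read.tree(text = "((spa:1,spb:1):1,(spc:1,spd:1):1);")
  hd <- dist_matrix(ape::cophenetic.phylo(host))
  cts <- sapply(seq_len(n_otus), function(j) {
    base <- if (j %% 2 == 0) c(40, 38, 2, 3) else c(2, 3, 40, 41)
    base * j
  })
  rownames(cts) <- paste0("m_", c("spa", "spb", "spc", "spd"))
  colnames(cts) <- paste0("o", seq_len(n_otus))
  tab <- toy_table(cts, species = c("spa", "spb", "spc", "spd"))
  list(table = tab, host_tree = host, host_dist = hd)
}

test_that("replicates on a purely phylosymbiotic table are all perfectly congruent", {
  p <- clean_panel()
  reps <- score_replicates(p$table, p$host_tree, p$host_dist,
                           mode = "subsample", n_reps = 30, k = 2, seed = 5)
  expect_true(all(reps$scores$cid == 0))
  expect_false(any(reps$scores$failed))
  boot <- score_replicates(p$table, p$host_tree, p$host_dist,
                           mode = "bootstrap", n_reps = 20, seed = 6)
  expect_true(all(boot$scores$cid == 0))
  expect_true(all(lengths(boot$otus) == 6))
})

test_that("replicate scoring is deterministic and matches a from-scratch replay", {
  set.seed(91)
  cts <- matrix(rpois(5 * 5, 30) + 1, 5, 5,
                dimnames = list(paste0("m", 1:5), paste0("o", 1:5)))
  host <- ape::rtree(5)
  host$tip.label <- paste0("sp", 1:5)
  hd <- dist_matrix(ape::cophenetic.phylo(host))
  tab <- toy_table(cts, species = paste0("sp", 1:5))
  reps1 <- score_replicates(tab, host, hd, mode = "subsample",
                            n_reps = 3, k = 3, seed = 13)
  reps2 <- score_replicates(tab, host, hd, mode = "subsample",
                            n_reps = 3, k = 3, seed = 13)
  expect_identical(reps1$scores, reps2$scores)
  expect_identical(reps1$otus, reps2$otus)
  # replay the draw stream and recompute both statistics independently
  ex <- expand_host_to_samples(host, hd, tab$samples)
  mids <- sort(tab$samples$sample_id)
  vb <- unclass(align_dist(ex$dist, mids))[lower.tri(diag(5))]
  set.seed(13)
  for (r in 1:3) {
    idx <- sample.int(5, 3)
    expect_identical(reps1$otus[[r]], colnames(cts)[idx])
    sub <- cts[, idx]
    bc <- matrix(0, 5, 5, dimnames = list(rownames(cts), rownames(cts)))
    for (i in 1:4) for (j in (i + 1):5) {
      bc[i, j] <- bc[j, i] <- sum(abs(sub[i, ] - sub[j, ])) /
        sum(sub[i, ] + sub[j, ])
    }
    dend <- ward_cluster(dist_matrix(bc))
    expect_equal(reps1$scores$cid[r], cid_oracle(dend, ex$tree),
                 tolerance = 1e-9)
    va <- bc[mids, mids][lower.tri(diag(5))]
    expect_equal(reps1$scores$mantel_r[r], cor(va, vb), tolerance = 1e-12)
  }
})

test_that("replicates that empty a sample are recorded as failed", {
  cts <- rbind(m1 = c(5, 0, 4), m2 = c(0, 6, 3), m3 = c(4, 5, 0))
  colnames(cts) <- paste0("o", 1:3)
  host <- ape::read.tree(text = "((sp1:1,sp2:1):1,(sp3:2,x:2):1);")
  host <- ape::keep.tip(host, c("sp1", "sp2", "sp3"))
  hd <- dist_matrix(ape::cophenetic.phylo(host))
  # o4 is absent from samples m1 and m2, so the draws {o1,o4} and {o2,o4}
  # leave a sample with no reads and must be recorded as failed
  cts2 <- cbind(cts, o4 = c(0, 0, 9))
  tab2 <- toy_table(cts2, species = paste0("sp", 1:3))
  reps2 <- score_replicates(tab2, host, hd, mode = "subsample",
                            n_reps = 80, k = 2, seed = 4)
  fails <- vapply(which(reps2$scores$failed), function(i)
    setequal(reps2$otus[[i]], c("o2", "o4")) ||
      setequal(reps2$otus[[i]], c("o1", "o4")), TRUE)
  expect_true(any(reps2$scores$failed))
  expect_true(all(fails))
  expect_true(all(is.na(reps2$scores$cid[reps2$scores$failed])))
})

test_that("qualifying sets are unions over qualifying replicates", {
  scores <- data.frame(replicate = 1:4,
                       cid = c(0, 0.4, 0, NA),
                       mantel_r = c(0.95, 0.92, 0.1, NA),
                       failed = c(FALSE, FALSE, FALSE, TRUE))
  reps <- structure(list(scores = scores,
                         otus = list(c("a", "b", "c"), c("b", "d", "e"),
                                     c("e", "f", "g"), c("x", "y", "z")),
                         mode = "subsample", k = 3, n_reps = 4, seed = 1,
                         outgroup = NULL, conditioned = FALSE),
                    class = "replicate_scores")
  q <- qualifying_otus(reps, cid_max = 0, r_min = 0.9)
  expect_equal(q$n_qualifying_cid, 2)      # replicates 1 and 3
  expect_equal(q$n_qualifying_mantel, 2)   # replicates 1 and 2
  expect_equal(q$n_failed, 1)
  expect_equal(q$otus_cid, sort(c("a", "b", "c", "e", "f", "g")))
  expect_equal(q$otus_mantel, sort(c("a", "b", "c", "d", "e")))
  # frequency-weighted variant: OTU must recur across qualifying replicates
  q2 <- qualifying_otus(reps, cid_max = 0.5, r_min = 0.9, min_replicates = 2)
  expect_equal(q2$otus_mantel, "b")
  # no qualifying replicate -> empty set
  q3 <- qualifying_otus(reps, cid_max = -1, r_min = 1.1)
  expect_length(q3$otus_cid, 0)
  expect_length(q3$otus_mantel, 0)
})

test_that("consensus intersections and recovery percentages are correct", {
  s <- list(boot = letters[1:6], sub = letters[4:9])
  cons <- consensus_sets(s)
  expect_equal(cons$intersections$consensus, c("d", "e", "f"))
  expect_equal(cons$recovery_pct["boot", "sub"], 50)
  expect_equal(cons$recovery_pct["sub", "boot"], 50)
  same <- consensus_sets(list(a = letters[1:4], b = letters[1:4]))
  expect_equal(same$intersections$consensus, letters[1:4])
  disj <- consensus_sets(list(a = letters[1:3], b = letters[4:6],
                              c = letters[1:3]))
  expect_length(disj$intersections$consensus, 0)
  expect_equal(unname(disj$intersection_sizes["a & c"]), 3L)
})

test_that("re-evaluating the full OTU set reproduces the whole-microbiome tests", {
  p <- clean_panel(8)
  rv <- reevaluate(colnames(p$table$counts), p$table, p$host_tree, p$host_dist,
                   n_perm = 60, seed = 17)
  # direct computation with the same seed stream
  seeds <- phylofrac:::split_seed(17, 2)
  ex <- expand_host_to_samples(p$host_tree, p$host_dist, p$table$samples)
  dend <- ward_cluster(suppressWarnings(bray_curtis(p$table)))
  ct <- cid_permutation_test(dend, ex$tree, n_perm = 60, seed = seeds[1])
  mt <- mantel(suppressWarnings(bray_curtis(p$table)),
               align_dist(ex$dist, sort(p$table$samples$sample_id)),
               n_perm = 60, seed = seeds[2])
  expect_identical(rv$cid_test$cid, ct$cid)
  expect_identical(rv$cid_test$null_cids, ct$null_cids)
  expect_equal(rv$mantel_test$r, mt$r)
  expect_equal(rv$mantel_test$p_value, mt$p_value)
  expect_error(reevaluate(c("o1", "nope"), p$table, p$host_tree, p$host_dist,
                          n_perm = 9, seed = 1), "absent")
})
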