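# Lower-triangle vectorization of a dist_matrix aligned to a label order.
lower_vec <- function(d, labels = rownames(d)) {
  m <- unclass(align_dist(d, labels))
  m[lower.tri(m)]
}

mantel_perms <- function(n, n_perm, seed, exact) {
  if (exact) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8", call. = FALSE)
    all_permutations(n)
  } else {
    with_seed(seed, t(replicate(n_perm, sample.int(n))))
  }
}

mantel_p <- function(obs, null, tail) {
  switch(tail,
         greater = sum(null >= obs) / length(null),
         less = sum(null <= obs) / length(null),
         two_sided = sum(abs(null) >= abs(obs)) / length(null))
}

#' Mantel test of association between two distance matrices
#'
#' Pearson correlation r of the n(n-1)/2 lower-triangle entries of two
#' label-aligned distance matrices; significance by jointly permuting the
#' rows and columns of the first matrix. The default tail is "greater"
#' (positive association expected under phylosymbiosis); the p-value is
#' the plain proportion #\{null r >= observed r\} / n_perm. With
#' `exact = TRUE` all n! relabelings (including the identity) are
#' enumerated instead of sampled.
#'
#' @param a,b [dist_matrix()] objects over the same label set.
#' @param n_perm number of permutations (default 1000).
#' @param tail "greater", "less" or "two_sided".
#' @param seed integer seed (ignored when `exact = TRUE`).
#' @param exact enumerate all permutations (n <= 8).
#' @param method correlation type, "pearson" (default) or "spearman".
#' @return list of class `mantel_result`: `r`, `p_value`, `null_r`,
#'   `n_perm`, `tail`, `conditioned` (FALSE), `seed`.
#' @export
mantel <- function(a, b, n_perm = 1000, tail = c("greater", "less", "two_sided"),
                   seed = NULL, exact = FALSE, method = c("pearson", "spearman")) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  labels <- sort(rownames(a))
  if (!setequal(rownames(a), rownames(b)))
    stop("label sets differ between matrices", call. = FALSE)
  va <- lower_vec(a, labels)
  vb <- lower_vec(b, labels)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance in vectorized distances", call. = FALSE)
  r_obs <- stats::cor(va, vb, method = method)
  n <- length(labels)
  am <- unclass(align_dist(a, labels))
  perms <- mantel_perms(n, n_perm, seed %||% stop("seed required", call. = FALSE),
                        exact)
  null_r <- apply(perms, 1, function(p) {
    stats::cor(am[p, p][lower.tri(am)], vb, method = method)
  })
  structure(list(r = r_obs, p_value = mantel_p(r_obs, null_r, tail),
                 null_r = null_r, n_perm = nrow(perms), tail = tail,
                 conditioned = FALSE,
                 seed = if (exact) NA_integer_ else as.integer(seed)),
            class = "mantel_result")
}

# First-order partial correlation from three aligned vectors.
partial_r <- function(va, vb, vc, method) {
  r_ab <- stats::cor(va, vb, method = method)
  r_ac <- stats::cor(va, vc, method = method)
  r_bc <- stats::cor(vb, vc, method = method)
  if (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12)
    stop("degenerate conditioning: |r| = 1 with the covariate matrix", call. = FALSE)
  (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
}

#' Partial Mantel test conditioning on a third matrix
#'
#' First-order partial correlation r_ab.c between two distance matrices
#' given a third (typically the binary study design matrix, so that
#' between-study structure does not masquerade as phylogenetic signal).
#' The null permutes the first matrix jointly in rows and columns and
#' recomputes the partial statistic; `b` and `c` stay fixed.
#'
#' @inheritParams mantel
#' @param c conditioning [dist_matrix()] (e.g. from
#'   [build_design_matrix()]).
#' @return list of class `mantel_result` with `conditioned = TRUE`.
#' @export
partial_mantel <- function(a, b, c, n_perm = 1000,
                           tail = c("greater", "less", "two_sided"),
                           seed = NULL, exact = FALSE,
                           method = c("pearson", "spearman")) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  labels <- sort(rownames(a))
  if (!setequal(rownames(a), rownames(b)) || !setequal(rownames(a), rownames(c)))
    stop("label sets differ between matrices", call. = FALSE)
  va <- lower_vec(a, labels)
  vb <- lower_vec(b, labels)
  vc <- lower_vec(c, labels)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0 || stats::sd(vc) == 0)
    stop("zero variance in vectorized distances", call. = FALSE)
  r_obs <- partial_r(va, vb, vc, method)
  n <- length(labels)
  am <- unclass(align_dist(a, labels))
  perms <- mantel_perms(n, n_perm, seed %||% stop("seed required", call. = FALSE),
                        exact)
  null_r <- apply(perms, 1, function(p) {
    partial_r(am[p, p][lower.tri(am)], vb, vc, method)
  })
  structure(list(r = r_obs, p_value = mantel_p(r_obs, null_r, tail),
                 null_r = null_r, n_perm = nrow(perms), tail = tail,
                 conditioned = TRUE,
                 seed = if (exact) NA_integer_ else as.integer(seed)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%sMantel: r = %.3f, P = %.4g (%d permutations, tail = %s)\n",
              if (x$conditioned) "partial " else "", x$r, x$p_value,
              x$n_perm, x$tail))
  invisible(x)
}

#' Binary design matrix from a metadata field
#'
#' Entry (i, j) is 0 when samples i and j share the same value of `field`
#' (e.g. same study) and 1 otherwise; used as the conditioning matrix of
#' partial Mantel tests.
#'
#' @param samples sample metadata data.frame with `sample_id`.
#' @param field metadata field name with no missing values.
#' @return A [dist_matrix()] over the sample ids.
#' @export
build_design_matrix <- function(samples, field) {
  if (!field %in% names(samples))
    stop("unknown metadata field: ", field, call. = FALSE)
  v <- samples[[field]]
  if (anyNA(v) || any(v == ""))
    stop("missing values in field ", field, call. = FALSE)
  m <- 1 - outer(v, v, `==`)
  dimnames(m) <- list(samples$sample_id, samples$sample_id)
  dist_matrix(m)
}

#' Single-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' the total sum of squared distances SS_total = sum_\{i<j\} d_ij^2 / n is
#' partitioned into within-group (SS_within, summed per group with its own
#' n_g) and between-group (SS_model) components; pseudo-F =
#' (SS_model / (k - 1)) / (SS_within / (n - k)) and R^2 = SS_model /
#' SS_total. Significance by permuting group labels.
#'
#' @param d a [dist_matrix()].
#' @param groups group label per sample, aligned to and/or named by the
#'   labels of `d`.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @param exact enumerate all label permutations (n <= 8).
#' @return list of class `permanova_result`: `pseudo_f`, `r2`, `df_model`,
#'   `df_resid`, `p_value`, `null_f`, `n_perm`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = NULL, exact = FALSE) {
  stopifnot(inherits(d, "dist_matrix"))
  n <- nrow(d)
  if (!is.null(names(groups))) groups <- groups[rownames(d)]
  if (length(groups) != n) stop("one group label per sample required", call. = FALSE)
  groups <- as.character(groups)
  k <- length(unique(groups))
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (k == n) stop("no residual degrees of freedom (k = n)", call. = FALSE)
  d2 <- unclass(d)^2
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within_of <- function(g) {
    s <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1)
        s <- s + sum(d2[idx, idx][lower.tri(d2[idx, idx])]) / length(idx)
    }
    s
  }
  f_of <- function(g) {
    ssw <- ss_within_of(g)
    ssm <- ss_total - ssw
    if (ssw <= 0) return(Inf)   # perfect separation
    (ssm / (k - 1)) / (ssw / (n - k))
  }
  ss_within <- ss_within_of(groups)
  ss_model <- ss_total - ss_within
  f_obs <- f_of(groups)
  if (!is.finite(f_obs))
    warning("within-group SS is zero: pseudo-F is infinite", call. = FALSE)
  perms <- mantel_perms(n, n_perm, seed %||% stop("seed required", call. = FALSE),
                        exact)
  null_f <- apply(perms, 1, function(p) f_of(groups[p]))
  structure(list(pseudo_f = f_obs, r2 = ss_model / ss_total,
                 df_model = k - 1, df_resid = n - k,
                 p_value = sum(null_f >= f_obs) / length(null_f),
                 null_f = null_f, n_perm = nrow(perms),
                 seed = if (exact) NA_integer_ else as.integer(seed)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: F_%d,%d = %.3f, R2 = %.3f, P = %.4g (%d permutations)\n",
              x$df_model, x$df_resid, x$pseudo_f, x$r2, x$p_value, x$n_perm))
  invisible(x)
}
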