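#' Labelled symmetric dissimilarity matrix
#'
#' Common container for Bray-Curtis/Jaccard dissimilarities, host
#' phylogenetic distances and binary design matrices. Stored as a square
#' numeric matrix with matching row/column labels, zero diagonal, symmetric
#' within 1e-12.
#'
#' @param m square numeric matrix with dimnames.
#' @return An object of class `dist_matrix`.
#' @export
dist_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  if (is.null(rownames(m))) stop("matrix must be labelled", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels differ", call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate labels", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite entries", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12) stop("matrix not symmetric", call. = FALSE)
  if (max(abs(diag(m))) > 1e-12) stop("diagonal not zero", call. = FALSE)
  if (any(m < 0)) stop("negative dissimilarity", call. = FALSE)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(m, class = c("dist_matrix", "matrix", "array"))
}

as_dist_matrix <- function(d) {
  dist_matrix(as.matrix(d))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d x %d\n", nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Reorder/subset a dist_matrix by labels
#' @param d a [dist_matrix()].
#' @param labels labels to keep, in the desired order.
#' @return A `dist_matrix` over `labels`.
#' @export
align_dist <- function(d, labels) {
  miss <- setdiff(labels, rownames(d))
  if (length(miss) > 0)
    stop("labels absent from matrix: ", paste(miss, collapse = ", "), call. = FALSE)
  dist_matrix(unclass(d)[labels, labels, drop = FALSE])
}

#' Read / write a distance matrix as square TSV
#'
#' Square layout with a header row and first column of labels; the reader
#' validates symmetry and the zero diagonal.
#'
#' @param path TSV path.
#' @return [read_dist_matrix()] returns a `dist_matrix`.
#' @export
read_dist_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- as.matrix(utils::read.delim(path, check.names = FALSE, row.names = 1))
  dist_matrix(m)
}

#' @rdname read_dist_matrix
#' @param d a [dist_matrix()].
#' @export
write_dist_matrix <- function(d, path) {
  df <- data.frame(id = rownames(d), unclass(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Alpha diversity per sample
#'
#' Observed OTU richness, Shannon entropy (natural log) and inverse Simpson
#' index from relative abundances p_j = count_j / total.
#'
#' @param table an [otu_table()].
#' @return data.frame with columns `sample_id`, `observed`, `shannon`,
#'   `inv_simpson`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (any(rowSums(table$counts) == 0))
    stop("all-zero sample(s): ",
         paste(rownames(table$counts)[rowSums(table$counts) == 0], collapse = ", "),
         call. = FALSE)
  data.frame(sample_id = rownames(table$counts),
             observed = rowSums(table$counts > 0),
             shannon = vegan::diversity(table$counts, index = "shannon"),
             inv_simpson = vegan::diversity(table$counts, index = "invsimpson"),
             row.names = NULL)
}

check_counts_for_dist <- function(counts) {
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop("dissimilarity undefined: all-zero sample(s): ",
         paste(rownames(counts)[zero], collapse = ", "), call. = FALSE)
}

#' Bray-Curtis dissimilarity among samples
#'
#' BC(x, y) = sum_j |x_j - y_j| / sum_j (x_j + y_j), in [0, 1]. Intended for
#' depth-equalized (rarefied) counts; a warning is issued when sample totals
#' differ by more than a factor of two.
#'
#' @param table an [otu_table()].
#' @return A [dist_matrix()] over the sample ids.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "otu_table"), nrow(table$counts) >= 2)
  check_counts_for_dist(table$counts)
  tot <- rowSums(table$counts)
  if (max(tot) > 2 * min(tot))
    warning("sample depths differ by >2x; consider rarefying first", call. = FALSE)
  as_dist_matrix(vegan::vegdist(table$counts, method = "bray"))
}

#' Jaccard distance among samples
#'
#' Presence/absence by default: J(x, y) = 1 - |shared OTUs| / |observed
#' OTUs|, quantifying OTU sharing. `binary = FALSE` gives the
#' abundance-weighted (Ruzicka) variant.
#'
#' @param table an [otu_table()].
#' @param binary use presence/absence (default TRUE).
#' @return A [dist_matrix()] over the sample ids.
#' @export
jaccard <- function(table, binary = TRUE) {
  stopifnot(inherits(table, "otu_table"), nrow(table$counts) >= 2)
  check_counts_for_dist(table$counts)
  as_dist_matrix(vegan::vegdist(table$counts, method = "jaccard", binary = binary))
}
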