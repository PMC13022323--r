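#' OTU table with taxonomy and sample metadata
#'
#' The substrate of every analysis in the package: a samples x OTUs matrix of
#' non-negative integer read counts, a ranked taxonomic lineage per OTU, and
#' per-sample metadata (host species, study/bioproject, sample type, and
#' optionally year and location).
#'
#' @param counts integer matrix, samples in rows, OTUs in columns; dimnames
#'   give sample and OTU ids.
#' @param taxonomy data.frame with column `otu_id` plus the six ranks
#'   `domain`, `phylum`, `class`, `order`, `family`, `genus` (NA or "" =
#'   unassigned at that rank).
#' @param samples data.frame with column `sample_id` plus `species`, `study`,
#'   `sample_type` (e.g. "shark" or "seawater"); `year` and `location` are
#'   optional.
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `taxonomy`, `samples`.
#' @export
otu_table <- function(counts, taxonomy, samples) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  obj <- structure(list(counts = counts,
                        taxonomy = as.data.frame(taxonomy),
                        samples = as.data.frame(samples)),
                   class = "otu_table")
  validate_otu_table(obj)
}

tax_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

validate_otu_table <- function(x) {
  counts <- x$counts
  if (is.null(rownames(counts)) || (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have sample (row) and OTU (column) names", call. = FALSE)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("counts must be non-negative integers; offending cell [%s, %s] = %s",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, , drop = FALSE]])), call. = FALSE)
  if (!"otu_id" %in% names(x$taxonomy))
    stop("taxonomy must have an `otu_id` column", call. = FALSE)
  miss <- setdiff(colnames(counts), x$taxonomy$otu_id)
  if (length(miss) > 0)
    stop("OTUs missing from taxonomy: ", paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(x$taxonomy$otu_id, colnames(counts))
  if (length(extra) > 0)
    stop("taxonomy rows with no matching OTU: ", paste(extra, collapse = ", "), call. = FALSE)
  if (!"sample_id" %in% names(x$samples))
    stop("sample metadata must have a `sample_id` column", call. = FALSE)
  miss <- setdiff(rownames(counts), x$samples$sample_id)
  if (length(miss) > 0)
    stop("samples missing from metadata: ", paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(x$samples$sample_id, rownames(counts))
  if (length(extra) > 0)
    stop("metadata rows with no matching sample: ", paste(extra, collapse = ", "), call. = FALSE)
  # align auxiliary tables to the count matrix
  x$taxonomy <- x$taxonomy[match(colnames(counts), x$taxonomy$otu_id), , drop = FALSE]
  x$samples <- x$samples[match(rownames(counts), x$samples$sample_id), , drop = FALSE]
  rownames(x$taxonomy) <- NULL
  rownames(x$samples) <- NULL
  x
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (%s total counts)\n",
              nrow(x$counts), ncol(x$counts), format(sum(x$counts), big.mark = ",")))
  cat("studies:", paste(unique(x$samples$study), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Subset an OTU table by samples and/or OTUs
#'
#' @param table an [otu_table()].
#' @param samples,otus character vectors of ids to keep (NULL = keep all).
#' @return An `otu_table` restricted to the requested ids, in the given order.
#' @export
subset_table <- function(table, samples = NULL, otus = NULL) {
  stopifnot(inherits(table, "otu_table"))
  keep_s <- samples %||% rownames(table$counts)
  keep_o <- otus %||% colnames(table$counts)
  miss <- setdiff(keep_s, rownames(table$counts))
  if (length(miss) > 0) stop("unknown sample ids: ", paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(keep_o, colnames(table$counts))
  if (length(miss) > 0) stop("unknown OTU ids: ", paste(miss, collapse = ", "), call. = FALSE)
  otu_table(table$counts[keep_s, keep_o, drop = FALSE],
            table$taxonomy[match(keep_o, table$taxonomy$otu_id), , drop = FALSE],
            table$samples[match(keep_s, table$samples$sample_id), , drop = FALSE])
}

#' Read an OTU table from three TSV files
#'
#' Counts are oriented samples-in-rows (first column = sample id, remaining
#' header = OTU ids); `transpose = TRUE` accepts the OTUs-in-rows dialect used
#' by some studies. Taxonomy is `otu_id` plus six rank columns (empty cell =
#' unassigned); metadata is `sample_id`, `species`, `study`, `sample_type`,
#' optionally `year` and `location`.
#'
#' @param counts_path,taxonomy_path,metadata_path paths to the TSV files.
#' @param transpose logical; set TRUE when the counts file has OTUs in rows.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(counts_path, taxonomy_path, metadata_path,
                           transpose = FALSE) {
  for (p in c(counts_path, taxonomy_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  cts <- utils::read.delim(counts_path, check.names = FALSE, row.names = 1)
  m <- as.matrix(cts)
  if (transpose) m <- t(m)
  if (!is.numeric(m)) stop("non-numeric value in counts file", call. = FALSE)
  tax <- utils::read.delim(taxonomy_path, check.names = FALSE,
                           colClasses = "character")
  tax[tax == ""] <- NA_character_
  meta <- utils::read.delim(metadata_path, check.names = FALSE)
  names(meta)[1] <- "sample_id"
  meta$sample_id <- as.character(meta$sample_id)
  otu_table(m, tax, meta)
}

#' Write an OTU table to three TSV files
#'
#' Emits the same dialect [read_otu_table()] consumes, so write/read is the
#' identity on valid tables.
#'
#' @inheritParams read_otu_table
#' @param table an [otu_table()].
#' @return Invisibly, the three paths.
#' @export
write_otu_table <- function(table, counts_path, taxonomy_path, metadata_path) {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$taxonomy, taxonomy_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(table$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(counts_path, taxonomy_path, metadata_path))
}

#' Merge replicate libraries by summing counts
#'
#' Optional pre-step for studies that sequenced several libraries of the same
#' species, location and year: counts are summed within groups sharing the
#' given metadata fields (within study), and the first sample id of each
#' group is retained.
#'
#' @param table an [otu_table()].
#' @param by metadata fields defining a library group.
#' @return An `otu_table` with one sample per group.
#' @export
merge_libraries <- function(table, by = c("study", "species", "location", "year")) {
  stopifnot(inherits(table, "otu_table"))
  by <- intersect(by, names(table$samples))
  key <- do.call(paste, c(table$samples[by], sep = "\r"))
  grp <- match(key, unique(key))
  counts <- rowsum(table$counts, grp)
  keep <- !duplicated(grp)
  meta <- table$samples[keep, , drop = FALSE]
  rownames(counts) <- meta$sample_id
  otu_table(counts, table$taxonomy, meta)
}
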