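#' Community count table
#'
#' Container for a taxa-by-samples matrix of non-negative integer counts
#' (an OTU/ASV table) with optional per-taxon taxonomy labels. Counts must
#' be whole numbers: the null models downstream resample individuals, so a
#' relative-abundance table is rejected.
#'
#' @param counts numeric matrix, taxa in rows (rownames = taxon ids),
#'   samples in columns (colnames = sample ids); non-negative integers.
#' @param taxonomy optional character vector of phylum/class labels, either
#'   unnamed (taxon order) or named by taxon id.
#' @return an object of class `community_table` with elements `counts`
#'   (integer matrix) and `taxonomy` (named character or NULL).
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 3,
#'             dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
#' community_table(m)
#' @export
community_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  .assert(is.numeric(counts) || (is.logical(counts) && length(counts) == 0),
          "counts must be numeric")
  storage.mode(counts) <- "numeric"
  # zero-extent dimensions cannot carry dimnames in R; only require names
  # along dimensions that actually have entries
  .assert((nrow(counts) == 0 || !is.null(rownames(counts))) &&
            (ncol(counts) == 0 || !is.null(colnames(counts))),
          "counts must carry taxon rownames and sample colnames")
  .assert(anyDuplicated(rownames(counts)) == 0, "duplicate taxon ids")
  .assert(anyDuplicated(colnames(counts)) == 0, "duplicate sample ids")
  .assert(all(is.finite(counts)), "counts must be finite")
  .assert(all(counts >= 0), "counts must be non-negative")
  if (length(counts) && max(abs(counts - round(counts))) > 1e-8) {
    stop("counts must be whole numbers (individuals); got real values", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    taxonomy <- as.character(taxonomy)
    if (is.null(names(taxonomy))) {
      .assert(length(taxonomy) == nrow(counts),
              "taxonomy length (%d) != number of taxa (%d)",
              length(taxonomy), nrow(counts))
      names(taxonomy) <- rownames(counts)
    } else {
      .assert(all(rownames(counts) %in% names(taxonomy)),
              "taxonomy names do not cover all taxa")
      taxonomy <- taxonomy[rownames(counts)]
    }
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d taxa x %d samples, %s taxonomy\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "no" else "with"))
  invisible(x)
}

#' @rdname community_table
#' @param x a `community_table`.
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' @rdname community_table
#' @export
sample_ids <- function(x) colnames(x$counts)

# subset helper keeping the class and taxonomy consistent
subset_table <- function(x, taxa = NULL, samples = NULL) {
  counts <- x$counts
  if (!is.null(taxa)) counts <- counts[taxa, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  community_table(counts, taxonomy = x$taxonomy[rownames(counts)])
}
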