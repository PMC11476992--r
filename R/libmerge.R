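# Ion-library set accounting: per-source identification counts, the combined
# (union) library used for DIA quantification, cross-source overlap, and the
# fraction of matrix proteins quantifiable in every injection.

#' Merge per-source ion libraries
#'
#' Union over (protein, peptide) pairs, collapsing duplicates to the
#' maximum-confidence entry, plus an overlap summary: unique-protein counts
#' per source, of the union, and of the all-source intersection.
#'
#' @param libraries named list of ion-library data.frames (one per IDA
#'   source/injection).
#' @return List with `library` (the combined data.frame) and `summary` (an
#'   `overlap_summary`).
#' @export
merge_libraries <- function(libraries) {
  if (length(libraries) < 1L) stop("need at least one library", call. = FALSE)
  if (is.null(names(libraries)) || any(names(libraries) == "")) {
    names(libraries) <- paste0("source", seq_along(libraries))
  }
  all <- do.call(rbind, libraries)
  key <- paste(all$protein, all$peptide, sep = "\x1f")
  ord <- order(key, -all$confidence, method = "radix")
  combined <- all[ord, ][!duplicated(key[ord]), ]
  combined <- combined[order(combined$protein, combined$peptide,
                             method = "radix"), ]
  rownames(combined) <- NULL

  prot_sets <- lapply(libraries, function(l) unique(l$protein))
  summary <- structure(list(
    per_source_counts = vapply(prot_sets, length, integer(1)),
    union_count = length(unique(unlist(prot_sets))),
    intersection_count = length(Reduce(intersect, prot_sets))),
    class = "overlap_summary")
  list(library = combined, summary = summary)
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("library overlap: union ", x$union_count, ", all-source intersection ",
      x$intersection_count, "\n", sep = "")
  cat("  per source: ",
      paste(names(x$per_source_counts), x$per_source_counts, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Fraction of proteins quantifiable across all injections
#'
#' Proportion of protein rows with no missing cell -- the "common proteins
#' acquired across all samples" summary that contrasts DIA quantification
#' (high, thanks to library-based extraction) with per-injection IDA
#' identification (low, intensity-dependent sampling).
#'
#' @param x a [quant_matrix()].
#' @return Scalar in \[0, 1\].
#' @export
quantifiable_fraction <- function(x) {
  stopifnot(inherits(x, "quant_matrix"))
  if (nrow(x$areas) == 0L) stop("empty matrix", call. = FALSE)
  mean(rowSums(is.na(x$areas)) == 0L)
}
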