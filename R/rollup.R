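# SWATH-arm intensity roll-up: sum of the top transitions per peptide, then
# sum of the top peptides per protein, after restricting to confidently
# identified, uniquely mapping library peptides. Sums (not means) at both
# levels; the targeted MRM(HR) arm deliberately uses top-k means instead (see
# mrmhr.R) -- the two arms differ by design.

#' Roll-up configuration (SWATH arm)
#'
#' @param max_transitions_per_peptide transitions summed per peptide.
#' @param max_peptides_per_protein peptides summed per protein.
#' @param min_confidence peptide identification confidence threshold.
#' @param aggregation only `"sum"` is defined for the SWATH arm.
#' @return An object of class `rollup_config`.
#' @export
rollup_config <- function(max_transitions_per_peptide = 6L,
                          max_peptides_per_protein = 10L,
                          min_confidence = 0.90,
                          aggregation = "sum") {
  aggregation <- match.arg(aggregation, "sum")
  cfg <- list(max_transitions_per_peptide = as.integer(max_transitions_per_peptide),
              max_peptides_per_protein = as.integer(max_peptides_per_protein),
              min_confidence = min_confidence,
              aggregation = aggregation)
  if (cfg$max_transitions_per_peptide < 1L || cfg$max_peptides_per_protein < 1L) {
    stop("top-k limits must be >= 1", call. = FALSE)
  }
  structure(cfg, class = "rollup_config")
}

#' Filter an ion library by confidence and mapping uniqueness
#'
#' Keeps entries with `confidence >= min_confidence`, then removes entirely
#' any peptide that (after the confidence filter) maps to more than one
#' protein accession. The number of shared peptides removed is reported in
#' the `"n_shared_peptides"` attribute, entries dropped by the confidence
#' cut in `"n_below_confidence"`.
#'
#' @param entries ion-library data.frame (protein, peptide, confidence,
#'   source_injection).
#' @param min_confidence threshold in \[0, 1\].
#' @return Filtered data.frame (possibly empty) with counting attributes.
#' @export
filter_library <- function(entries, min_confidence = 0.90) {
  keep <- entries$confidence >= min_confidence
  kept <- entries[keep, , drop = FALSE]
  n_prot <- tapply(kept$protein, kept$peptide,
                   function(p) length(unique(p)))
  shared <- names(n_prot)[n_prot > 1L]
  out <- kept[!kept$peptide %in% shared, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_below_confidence = sum(!keep),
            n_shared_peptides = length(shared))
}

# top-k selection order: descending area, ties broken by label (lexical) for
# determinism
.topk <- function(area, label, k) {
  ord <- order(-area, label, method = "radix")
  ord[seq_len(min(k, length(ord)))]
}

#' Peptide-level roll-up for one peptide in one injection
#'
#' Sum of the `max_transitions_per_peptide` largest transition areas
#' (descending area, ties broken by fragment label). An empty input yields a
#' missing value, never zero.
#'
#' @param area numeric vector of transition areas.
#' @param fragment_label tie-breaking labels (defaults to input order).
#' @param config a [rollup_config()].
#' @return Scalar area, or `NA` for empty input.
#' @export
rollup_peptide <- function(area, fragment_label = as.character(seq_along(area)),
                           config = rollup_config()) {
  keep <- !is.na(area)
  area <- area[keep]
  fragment_label <- fragment_label[keep]
  if (length(area) == 0L) return(NA_real_)
  sum(area[.topk(area, fragment_label, config$max_transitions_per_peptide)])
}

#' Protein-level roll-up for one protein in one injection
#'
#' Sum of the `max_peptides_per_protein` largest peptide areas. The reported
#' peptide count is `min(number of non-missing peptides, cap)`.
#'
#' @param peptide_area numeric vector of peptide areas.
#' @param peptide names for tie-breaking (defaults to input order).
#' @param config a [rollup_config()].
#' @return List with `area` (`NA` for empty input) and `n_peptides`.
#' @export
rollup_protein <- function(peptide_area,
                           peptide = as.character(seq_along(peptide_area)),
                           config = rollup_config()) {
  keep <- !is.na(peptide_area)
  peptide_area <- peptide_area[keep]
  peptide <- peptide[keep]
  if (length(peptide_area) == 0L) {
    return(list(area = NA_real_, n_peptides = 0L))
  }
  idx <- .topk(peptide_area, peptide, config$max_peptides_per_protein)
  list(area = sum(peptide_area[idx]),
       n_peptides = min(length(peptide_area), config$max_peptides_per_protein))
}

# Vectorized grouped top-k aggregate over a long table. Returns one row per
# group in sorted key order with the aggregated value and the group size
# before capping. fun is "sum" or "mean".
.group_topk <- function(key, area, label, k, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  ord <- order(key, -area, label, method = "radix")
  k_s <- key[ord]
  rl <- rle(k_s)
  rank_in_group <- sequence(rl$lengths)
  keep <- rank_in_group <= k
  sizes <- rl$lengths
  agg <- rowsum(area[ord][keep], group = k_s[keep], reorder = TRUE)
  if (fun == "mean") {
    cnt <- rowsum(rep(1L, sum(keep)), group = k_s[keep], reorder = TRUE)
    agg <- agg / cnt
  }
  data.frame(key = rownames(agg), value = agg[, 1L],
             n = sizes[match(rownames(agg), rl$values)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a protein x injection quant matrix from transition records
#'
#' Applies [filter_library()], drops transitions whose peptide is absent from
#' the filtered library (counted in the `"n_transitions_dropped"` attribute of
#' the result), assigns proteins from the library mapping, rolls transitions
#' up to peptide areas and peptide areas up to protein areas, and assembles a
#' [quant_matrix()]. The matrix carries the full per-(protein, injection)
#' peptide-count grid (`counts`, used by [find_deps()] for per-contrast
#' peptide support) and, as the `peptide_counts` summary, the minimum
#' reported count across the injections in which each protein is observed.
#'
#' @param transitions long-format transition data.frame.
#' @param library ion-library data.frame.
#' @param samples sample sheet covering the transitions' sample ids.
#' @param config a [rollup_config()].
#' @return A [quant_matrix()] with attributes `n_transitions_dropped` and
#'   `n_shared_peptides`.
#' @export
build_matrix <- function(transitions, library, samples,
                         config = rollup_config()) {
  validate_samples(samples)
  if (!all(transitions$sample_id %in% samples$sample_id)) {
    stop("transitions reference sample ids absent from the sample sheet",
         call. = FALSE)
  }
  lib <- filter_library(library, config$min_confidence)
  prot_of <- stats::setNames(lib$protein, lib$peptide)
  in_lib <- transitions$peptide %in% lib$peptide
  n_dropped <- sum(!in_lib)
  tr <- transitions[in_lib, , drop = FALSE]
  if (nrow(tr) == 0L) {
    stop("no overlapping peptides between quant data and filtered library",
         call. = FALSE)
  }
  protein <- unname(prot_of[tr$peptide])

  sep <- "\x1f"
  pk <- paste(tr$sample_id, protein, tr$peptide, sep = sep)
  pep <- .group_topk(pk, tr$area, tr$fragment_label,
                     config$max_transitions_per_peptide, "sum")
  parts <- strsplit(pep$key, sep, fixed = TRUE)
  pep$sample_id <- vapply(parts, `[[`, character(1), 1L)
  pep$protein <- vapply(parts, `[[`, character(1), 2L)
  pep$peptide <- vapply(parts, `[[`, character(1), 3L)

  rk <- paste(pep$sample_id, pep$protein, sep = sep)
  prot <- .group_topk(rk, pep$value, pep$peptide,
                      config$max_peptides_per_protein, "sum")
  parts <- strsplit(prot$key, sep, fixed = TRUE)
  prot$sample_id <- vapply(parts, `[[`, character(1), 1L)
  prot$protein <- vapply(parts, `[[`, character(1), 2L)
  prot$n_peptides <- pmin(prot$n, config$max_peptides_per_protein)

  proteins <- sort(unique(prot$protein))
  areas <- matrix(NA_real_, nrow = length(proteins), ncol = nrow(samples),
                  dimnames = list(proteins, samples$sample_id))
  areas[cbind(match(prot$protein, proteins),
              match(prot$sample_id, samples$sample_id))] <- prot$value
  counts <- matrix(NA_integer_, nrow = length(proteins), ncol = nrow(samples),
                   dimnames = dimnames(areas))
  counts[cbind(match(prot$protein, proteins),
               match(prot$sample_id, samples$sample_id))] <- prot$n_peptides
  min_counts <- apply(counts, 1L, min, na.rm = TRUE)
  peptide_counts <- stats::setNames(as.integer(min_counts), proteins)

  qm <- quant_matrix(areas, samples, peptide_counts, counts = counts)
  attr(qm, "n_transitions_dropped") <- n_dropped
  attr(qm, "n_shared_peptides") <- attr(lib, "n_shared_peptides")
  qm
}
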