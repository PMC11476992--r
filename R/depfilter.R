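# Bilateral-concordance differential-expression filtering. No p-values are
# involved in this arm: a protein is called differentially expressed at a
# timepoint when BOTH eye pools clear the fold-change cutoff in the SAME
# direction and the protein is supported by enough peptides. The concordance
# requirement across independently injected left/right pools is the study
# design's replacement for a significance test; no multiple-testing procedure
# is applied (there are no p-values to correct), and users should read the
# DEP lists as screening calls, not inferential results.

#' DEP filter configuration
#'
#' @param up_cutoff minimum fold change (both eyes) for an UP call.
#' @param down_cutoff maximum fold change (both eyes) for a DOWN call. The
#'   default 0.7 is the study convention, not the symmetric 1/1.5.
#' @param min_peptides minimum supporting peptides per protein.
#' @param min_confidence library confidence threshold (carried for
#'   provenance; applied upstream in [build_matrix()]).
#' @param count_rule how per-contrast peptide support is summarized from the
#'   per-injection counts of the contrast's injections: `"max"` (default; the
#'   protein's best-covered injection -- peptide support is a property of the
#'   quantification evidence, so an injection that happened to catch fewer
#'   peptides does not disqualify the protein) or `"min"` (the conservative
#'   worst-injection reading). Ignored when the matrix carries no
#'   per-injection count grid, in which case the global `peptide_counts`
#'   summary is used.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(up_cutoff = 1.5, down_cutoff = 0.7,
                          min_peptides = 2L, min_confidence = 0.90,
                          count_rule = c("max", "min")) {
  count_rule <- match.arg(count_rule)
  cfg <- list(up_cutoff = up_cutoff, down_cutoff = down_cutoff,
              min_peptides = as.integer(min_peptides),
              min_confidence = min_confidence,
              count_rule = count_rule)
  if (cfg$up_cutoff <= 1) stop("up_cutoff must be > 1", call. = FALSE)
  if (cfg$down_cutoff <= 0 || cfg$down_cutoff >= 1) {
    stop("down_cutoff must be in (0, 1)", call. = FALSE)
  }
  if (cfg$min_peptides < 1L) stop("min_peptides must be >= 1", call. = FALSE)
  structure(cfg, class = "filter_config")
}

# group mean/median of a protein row over the replicate columns of (day, eye)
.group_center <- function(x, protein, eye, day, center) {
  sel <- x$samples$eye == eye & x$samples$day == day
  v <- x$areas[protein, sel]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  if (center == "median") stats::median(v) else mean(v)
}

#' Per-eye fold change vs the reference day
#'
#' `FC = center(areas at (day, eye)) / center(areas at (reference_day, eye))`
#' over technical replicates (arithmetic mean by default). Missing if either
#' group has no observed replicate or the denominator is zero.
#'
#' @param x a (normalized) [quant_matrix()].
#' @param protein accession.
#' @param eye `"OD"` or `"OS"`.
#' @param day test day.
#' @param reference_day baseline day.
#' @param center replicate summary, `"mean"` or `"median"`.
#' @return Positive scalar or `NA`.
#' @export
eye_fold_change <- function(x, protein, eye, day, reference_day = 7L,
                            center = c("mean", "median")) {
  stopifnot(inherits(x, "quant_matrix"))
  center <- match.arg(center)
  num <- .group_center(x, protein, eye, day, center)
  den <- .group_center(x, protein, eye, reference_day, center)
  if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
  num / den
}

#' Classify bilateral fold-change direction
#'
#' UP iff both eyes' fold changes are `>= up_cutoff`; DOWN iff both are
#' `<= down_cutoff`; otherwise NONE. Pairs with a missing fold change are
#' NONE and flagged not evaluable in the `"evaluable"` attribute.
#'
#' @param fc_od,fc_os fold changes for the right and left eye (vectorized).
#' @param config a [filter_config()].
#' @return Character vector in {UP, DOWN, NONE} with attribute `evaluable`.
#' @export
classify_direction <- function(fc_od, fc_os, config = filter_config()) {
  evaluable <- !is.na(fc_od) & !is.na(fc_os)
  out <- rep("NONE", length(evaluable))
  up <- evaluable & fc_od >= config$up_cutoff & fc_os >= config$up_cutoff
  down <- evaluable & fc_od <= config$down_cutoff & fc_os <= config$down_cutoff
  out[up] <- "UP"
  out[down] <- "DOWN"
  structure(out, evaluable = evaluable)
}

#' Average fold change and spread of the two eyes
#'
#' `ave = (fc_od + fc_os) / 2`; `sd` is the two-value sample (n - 1) standard
#' deviation, `|fc_od - fc_os| / sqrt(2)` -- the "AVE FC +/- SD" summary used
#' in reports.
#'
#' @inheritParams classify_direction
#' @return List with numeric vectors `ave` and `sd`.
#' @export
average_fc <- function(fc_od, fc_os) {
  list(ave = (fc_od + fc_os) / 2, sd = abs(fc_od - fc_os) / sqrt(2))
}

#' Round half away from zero
#'
#' Display rounding for report tables (so 0.315 prints as 0.32), as opposed
#' to base R's round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Find differentially expressed proteins for one contrast
#'
#' Computes per-eye fold changes of `day` vs `reference_day` for every
#' protein, classifies bilateral direction, and returns one record per
#' protein passing the filter (direction UP or DOWN, and at least
#' `min_peptides` supporting peptides), ordered by accession. Peptide support
#' is evaluated per contrast: when the matrix carries the per-injection count
#' grid, `n_peptides` summarizes the counts over the contrast's injections
#' with the configured `count_rule`; otherwise the matrix-level
#' `peptide_counts` summary is used.
#'
#' @param x a normalized [quant_matrix()] with peptide counts.
#' @param day test day.
#' @param config a [filter_config()].
#' @param reference_day baseline day.
#' @param center replicate summary passed to [eye_fold_change()].
#' @return data.frame with columns protein, day, reference_day, fc_od, fc_os,
#'   ave_fc, sd_fc, direction, n_peptides.
#' @export
find_deps <- function(x, day, config = filter_config(), reference_day = 7L,
                      center = c("mean", "median")) {
  stopifnot(inherits(x, "quant_matrix"))
  center <- match.arg(center)
  for (d in c(day, reference_day)) {
    if (!d %in% x$samples$day) {
      stop("day ", d, " absent from the sample sheet", call. = FALSE)
    }
  }
  cfun <- if (center == "median") {
    function(m) apply(m, 1L, stats::median, na.rm = TRUE)
  } else {
    function(m) rowMeans(m, na.rm = TRUE)
  }
  grp <- function(eye, d) {
    v <- cfun(x$areas[, x$samples$eye == eye & x$samples$day == d,
                      drop = FALSE])
    v[is.nan(v)] <- NA_real_
    v
  }
  fc_eye <- function(eye) {
    num <- grp(eye, day)
    den <- grp(eye, reference_day)
    fc <- num / den
    fc[is.na(num) | is.na(den) | den == 0] <- NA_real_
    fc
  }
  fc_od <- fc_eye("OD")
  fc_os <- fc_eye("OS")
  direction <- classify_direction(fc_od, fc_os, config)
  af <- average_fc(fc_od, fc_os)
  if (!is.null(x$counts)) {
    cm <- x$counts[, x$samples$day %in% c(day, reference_day), drop = FALSE]
    sfun <- if (config$count_rule == "min") min else max
    n_pep <- apply(cm, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) 0L else as.integer(sfun(v))
    })
  } else {
    n_pep <- x$peptide_counts
  }
  out <- data.frame(protein = rownames(x$areas), day = day,
                    reference_day = reference_day,
                    fc_od = fc_od, fc_os = fc_os,
                    ave_fc = af$ave, sd_fc = af$sd,
                    direction = as.character(direction),
                    n_peptides = n_pep,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$direction != "NONE" & out$n_peptides >= config$min_peptides, ]
  out <- out[order(out$protein, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Intersect DEP lists across contrasts
#'
#' Proteins present in every contrast's DEP list with the same direction in
#' all contrasts, partitioned into UP and DOWN sets.
#'
#' @param dep_lists list (ideally named by contrast) of [find_deps()]
#'   outputs; at least two.
#' @return List with `up` and `down` (sorted accession vectors) and
#'   `records` (the per-contrast rows of the common proteins).
#' @export
intersect_deps <- function(dep_lists) {
  if (length(dep_lists) < 2L) {
    stop("need at least 2 contrasts to intersect", call. = FALSE)
  }
  common <- Reduce(intersect, lapply(dep_lists, `[[`, "protein"))
  consistent <- vapply(common, function(p) {
    dirs <- vapply(dep_lists,
                   function(d) d$direction[match(p, d$protein)], character(1))
    length(unique(dirs)) == 1L
  }, logical(1))
  common <- sort(common[consistent])
  dir_of <- vapply(common, function(p) {
    dep_lists[[1L]]$direction[match(p, dep_lists[[1L]]$protein)]
  }, character(1))
  records <- do.call(rbind, lapply(dep_lists, function(d) {
    d[d$protein %in% common, , drop = FALSE]
  }))
  rownames(records) <- NULL
  list(up = common[dir_of == "UP"], down = common[dir_of == "DOWN"],
       records = records)
}

#' Row-standardize protein abundances (z-scores)
#'
#' For each protein row, `z_j = (A_j - mean(row)) / sd(row)` over the row's
#' non-missing values (sample SD). Rows with zero variance are emitted as all
#' zeros and flagged in the `"zero_variance"` attribute; rows observed fewer
#' than twice are not standardized (all `NA`) and flagged in
#' `"insufficient"`.
#'
#' @param x a [quant_matrix()].
#' @param proteins accession subset (default: all rows).
#' @return Numeric matrix of z-scores with flagging attributes.
#' @export
zscore_matrix <- function(x, proteins = NULL) {
  stopifnot(inherits(x, "quant_matrix"))
  if (is.null(proteins)) proteins <- rownames(x$areas)
  missing_p <- setdiff(proteins, rownames(x$areas))
  if (length(missing_p) > 0L) {
    stop("proteins not in matrix: ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  m <- x$areas[proteins, , drop = FALSE]
  mu <- rowMeans(m, na.rm = TRUE)
  sdv <- apply(m, 1L, stats::sd, na.rm = TRUE)
  nobs <- rowSums(!is.na(m))
  z <- (m - mu) / sdv
  zero_var <- nobs >= 2L & !is.na(sdv) & sdv == 0
  insufficient <- nobs < 2L
  z[zero_var, ] <- ifelse(is.na(m[zero_var, , drop = FALSE]), NA_real_, 0)
  z[insufficient, ] <- NA_real_
  structure(z, zero_variance = rownames(m)[zero_var],
            insufficient = rownames(m)[insufficient])
}
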