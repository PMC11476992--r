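# Targeted MRM(HR) validation arm. Unlike the SWATH roll-up (top-k SUMS over
# pooled technical replicates), the targeted arm AVERAGES the top 3 surviving
# transitions per peptide and the top 3 peptides per protein, normalizes each
# injection by its housekeeping protein, and compares individual animals
# between days with an unpaired t-test. The two arms differ on purpose.

#' MRM(HR) validation configuration
#'
#' @param min_snr signal-to-noise threshold for transitions; kept if
#'   `snr >= min_snr` (set `snr_exclusive = TRUE` for a strict `>`).
#' @param top_transitions transitions averaged per peptide.
#' @param top_peptides peptides averaged per protein.
#' @param housekeeping accession of the normalizer protein (GAPDH analog).
#' @param alpha significance level for the unpaired t-test.
#' @param t_test `"student"` (pooled variance, default) or `"welch"`.
#' @param snr_exclusive use strict `snr > min_snr` instead of `>=`.
#' @return An object of class `mrm_config`.
#' @export
mrm_config <- function(min_snr = 20, top_transitions = 3L, top_peptides = 3L,
                       housekeeping = "GAPDH", alpha = 0.05,
                       t_test = c("student", "welch"), snr_exclusive = FALSE) {
  t_test <- match.arg(t_test)
  cfg <- list(min_snr = min_snr, top_transitions = as.integer(top_transitions),
              top_peptides = as.integer(top_peptides),
              housekeeping = housekeeping, alpha = alpha, t_test = t_test,
              snr_exclusive = isTRUE(snr_exclusive))
  if (cfg$min_snr < 0) stop("min_snr must be >= 0", call. = FALSE)
  if (cfg$top_transitions < 1L || cfg$top_peptides < 1L) {
    stop("top-k limits must be >= 1", call. = FALSE)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "mrm_config")
}

#' Transition-list construction rules
#'
#' @param precursor_charges allowed precursor charge states.
#' @param fragment_ion_charge allowed fragment ion charge.
#' @param ion_types allowed fragment ion series.
#' @param match_tolerance_mz ion match tolerance, applied as +/- half-window.
#' @param top_products most intense product ions kept per peptide.
#' @return An object of class `transition_list_spec`.
#' @export
transition_list_spec <- function(precursor_charges = c(2L, 3L),
                                 fragment_ion_charge = 1L,
                                 ion_types = c("y", "b"),
                                 match_tolerance_mz = 0.5,
                                 top_products = 5L) {
  structure(list(precursor_charges = as.integer(precursor_charges),
                 fragment_ion_charge = as.integer(fragment_ion_charge),
                 ion_types = ion_types,
                 match_tolerance_mz = match_tolerance_mz,
                 top_products = as.integer(top_products)),
            class = "transition_list_spec")
}

#' Build a targeted transition list from a fragment catalog
#'
#' For each library peptide, keeps catalog fragments matching the allowed ion
#' types, fragment charge and precursor charges, and selects the
#' `top_products` most intense (ties broken by ascending m/z). Peptides with
#' no qualifying fragment are excluded and reported in the
#' `"excluded_peptides"` attribute.
#'
#' @param library ion-library data.frame (defines the peptides considered).
#' @param catalog data.frame of candidate fragments with columns peptide,
#'   ion_type, fragment_charge, precursor_charge, mz, intensity.
#' @param spec a [transition_list_spec()].
#' @return data.frame (peptide, ion_type, fragment_charge, precursor_charge,
#'   mz, intensity, rank), sorted by peptide then rank.
#' @export
build_transition_list <- function(library, catalog,
                                  spec = transition_list_spec()) {
  need <- c("peptide", "ion_type", "fragment_charge", "precursor_charge",
            "mz", "intensity")
  .check_columns(catalog, need, "<catalog>")
  cand <- catalog[catalog$peptide %in% unique(library$peptide) &
                  catalog$ion_type %in% spec$ion_types &
                  catalog$fragment_charge == spec$fragment_ion_charge &
                  catalog$precursor_charge %in% spec$precursor_charges, ,
                  drop = FALSE]
  excluded <- setdiff(unique(library$peptide), unique(cand$peptide))
  if (nrow(cand) == 0L) {
    out <- cand[, need]
    out$rank <- integer(0)
    return(structure(out, excluded_peptides = sort(excluded)))
  }
  ord <- order(cand$peptide, -cand$intensity, cand$mz, method = "radix")
  cand <- cand[ord, , drop = FALSE]
  rank <- sequence(rle(cand$peptide)$lengths)
  out <- cand[rank <= spec$top_products, need, drop = FALSE]
  out$rank <- rank[rank <= spec$top_products]
  rownames(out) <- NULL
  structure(out, excluded_peptides = sort(excluded))
}

#' Peptide intensity from surviving transitions
#'
#' Drops transitions below the signal-to-noise threshold, then returns the
#' mean of the `top_transitions` largest surviving areas (the mean of what
#' exists when fewer survive); missing when none survive.
#'
#' @param area transition areas for one peptide in one injection.
#' @param snr matching signal-to-noise ratios.
#' @param config an [mrm_config()].
#' @return Scalar intensity or `NA`.
#' @export
peptide_intensity <- function(area, snr, config = mrm_config()) {
  pass <- !is.na(area) & !is.na(snr) &
    (if (config$snr_exclusive) snr > config$min_snr else snr >= config$min_snr)
  a <- sort(area[pass], decreasing = TRUE)
  if (length(a) == 0L) return(NA_real_)
  mean(a[seq_len(min(config$top_transitions, length(a)))])
}

#' Protein intensity from peptide intensities
#'
#' Mean of the `top_peptides` largest peptide intensities; missing when none.
#'
#' @param peptide_intensities intensities for one protein in one injection.
#' @param config an [mrm_config()].
#' @return Scalar intensity or `NA`.
#' @export
protein_intensity <- function(peptide_intensities, config = mrm_config()) {
  a <- sort(peptide_intensities[!is.na(peptide_intensities)],
            decreasing = TRUE)
  if (length(a) == 0L) return(NA_real_)
  mean(a[seq_len(min(config$top_peptides, length(a)))])
}

#' Housekeeping normalization of a protein intensity matrix
#'
#' Divides every protein's intensity by the housekeeping protein's intensity
#' in the same injection; the housekeeping row maps to exactly 1 everywhere.
#' Per-injection global scaling (loading differences) cancels out.
#'
#' @param intensities numeric matrix, proteins x injections.
#' @param housekeeping accession of the normalizer row.
#' @return Normalized matrix of the same shape.
#' @export
normalize_housekeeping <- function(intensities, housekeeping = "GAPDH") {
  if (!housekeeping %in% rownames(intensities)) {
    stop("housekeeping protein '", housekeeping, "' not in matrix",
         call. = FALSE)
  }
  hk <- intensities[housekeeping, ]
  bad <- colnames(intensities)[is.na(hk) | hk <= 0]
  if (length(bad) > 0L) {
    stop("housekeeping protein not quantified in injection(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- sweep(intensities, 2L, hk, "/")
  out[housekeeping, ] <- 1
  out
}

#' Group fold change between two days
#'
#' Mean normalized intensity over day-`day_a` animals divided by the mean
#' over day-`day_b` animals.
#'
#' @param normalized proteins x injections matrix (housekeeping-normalized).
#' @param protein accession.
#' @param samples sample sheet for the columns.
#' @param day_a,day_b numerator and denominator days.
#' @return Scalar fold change, or `NA` if either group is empty.
#' @export
group_fold_change <- function(normalized, protein, samples, day_a = 14L,
                              day_b = 7L) {
  v <- normalized[protein, ]
  ga <- v[samples$day == day_a]
  gb <- v[samples$day == day_b]
  ga <- ga[!is.na(ga)]
  gb <- gb[!is.na(gb)]
  if (length(ga) == 0L || length(gb) == 0L) return(NA_real_)
  mean(ga) / mean(gb)
}

#' Unpaired two-sample t-test
#'
#' Standard two-sided unpaired t-test: pooled variance (`"student"`, the
#' default) or Satterthwaite degrees of freedom (`"welch"`). Degenerate
#' inputs (fewer than 2 values per group, or zero pooled variance) return a
#' flagged result with no p-value instead of an error.
#'
#' @param group_a,group_b numeric vectors.
#' @param flavor `"student"` or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided) and `degenerate`.
#' @export
unpaired_t_test <- function(group_a, group_b,
                            flavor = c("student", "welch")) {
  flavor <- match.arg(flavor)
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  degenerate <- length(group_a) < 2L || length(group_b) < 2L ||
    (stats::var(group_a) == 0 && stats::var(group_b) == 0)
  if (degenerate) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = flavor == "student")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

# proteins x injections intensity matrix from MRM transition records
.mrm_intensity_matrix <- function(transitions, samples, config) {
  pass <- !is.na(transitions$area) & !is.na(transitions$snr) &
    (if (config$snr_exclusive) transitions$snr > config$min_snr
     else transitions$snr >= config$min_snr)
  tr <- transitions[pass, , drop = FALSE]
  if (nrow(tr) == 0L) {
    stop("no transitions survive the signal-to-noise filter", call. = FALSE)
  }
  sep <- "\x1f"
  pk <- paste(tr$sample_id, tr$protein, tr$peptide, sep = sep)
  pep <- .group_topk(pk, tr$area, tr$fragment_label, config$top_transitions,
                     "mean")
  parts <- strsplit(pep$key, sep, fixed = TRUE)
  pep$sample_id <- vapply(parts, `[[`, character(1), 1L)
  pep$protein <- vapply(parts, `[[`, character(1), 2L)
  pep$peptide <- vapply(parts, `[[`, character(1), 3L)
  rk <- paste(pep$sample_id, pep$protein, sep = sep)
  prot <- .group_topk(rk, pep$value, pep$peptide, config$top_peptides, "mean")
  parts <- strsplit(prot$key, sep, fixed = TRUE)
  prot$sample_id <- vapply(parts, `[[`, character(1), 1L)
  prot$protein <- vapply(parts, `[[`, character(1), 2L)
  proteins <- sort(unique(prot$protein))
  m <- matrix(NA_real_, nrow = length(proteins), ncol = nrow(samples),
              dimnames = list(proteins, samples$sample_id))
  m[cbind(match(prot$protein, proteins),
          match(prot$sample_id, samples$sample_id))] <- prot$value
  m
}

#' Run the targeted MRM(HR) validation
#'
#' Composes the targeted pipeline: signal-to-noise filtering, top-k mean
#' roll-up at the peptide and protein level, per-injection housekeeping
#' normalization, day 14 / day 7 group fold change over individual animals,
#' and an unpaired t-test per target.
#'
#' @param transitions long-format transition data.frame with snr.
#' @param samples sample sheet (individual animals at two days).
#' @param targets accessions to validate.
#' @param config an [mrm_config()].
#' @param day_a,day_b numerator and denominator days of the fold change.
#' @return An object of class `mrmhr_validation`: data.frame with one row per
#'   target (accession order): protein, fc, t, df, p, significant, n_day_a,
#'   n_day_b.
#' @export
run_validation <- function(transitions, samples, targets,
                           config = mrm_config(), day_a = 14L, day_b = 7L) {
  validate_samples(samples)
  m <- .mrm_intensity_matrix(transitions, samples, config)
  missing_t <- setdiff(targets, rownames(m))
  if (length(missing_t) > 0L) {
    stop("target(s) not quantified: ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }
  norm <- normalize_housekeeping(m, config$housekeeping)
  targets <- sort(unique(targets))
  rows <- lapply(targets, function(p) {
    v <- norm[p, ]
    ga <- v[samples$day == day_a]
    gb <- v[samples$day == day_b]
    fc <- group_fold_change(norm, p, samples, day_a, day_b)
    tt <- unpaired_t_test(ga, gb, config$t_test)
    data.frame(protein = p, fc = fc, t = tt$t, df = tt$df, p = tt$p,
               significant = !is.na(tt$p) && tt$p < config$alpha,
               n_day_a = sum(!is.na(ga)), n_day_b = sum(!is.na(gb)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "days") <- c(day_a = day_a, day_b = day_b)
  class(out) <- c("mrmhr_validation", "data.frame")
  out
}

#' @export
print.mrmhr_validation <- function(x, digits = 3L, ...) {
  d <- attr(x, "days")
  cat("MRM(HR) validation, fold change day ", d["day_a"], " / day ",
      d["day_b"], " (", sum(x$significant), "/", nrow(x),
      " significant)\n", sep = "")
  df <- as.data.frame(x)
  df$fc <- round(df$fc, digits)
  df$t <- round(df$t, digits)
  df$p <- signif(df$p, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
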