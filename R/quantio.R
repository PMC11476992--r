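# Bespoke TSV/CSV dialects modeled on PeakView/MultiQuant long-format exports.
# Missing measurements are written as empty fields, never 0: a zero area is a
# (meaningful) measured value, an empty field is "not observed".

.transition_cols <- c("sample_id", "eye", "day", "replicate", "cohort",
                      "protein", "peptide", "precursor_charge",
                      "fragment_label", "area", "snr")
.sample_cols <- c("sample_id", "eye", "day", "replicate", "cohort")
.library_cols <- c("protein", "peptide", "confidence", "source_injection")

# 15 significant digits: round-trips doubles to well below any tolerance used
# downstream while keeping "nice" values (0.95, 1.5) printed verbatim.
.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 15, trim = TRUE, scientific = FALSE)
  }, character(1))
}

.check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("file '", path, "' is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a long-format transition quant table
#'
#' Checks the row-level invariants of transition records: non-negative areas,
#' precursor charge 2 or 3, y/b fragment ion types, OD/OS eye labels.
#' Violations are reported with the offending row indices (1-based data rows;
#' add 1 for the file line when the table came from a TSV with a header).
#'
#' @param transitions data.frame with the transition column set (see
#'   [read_quant_table()]).
#' @param offset integer added to row indices in error messages (use 1 for a
#'   file with a header line so messages cite file lines).
#' @return The input, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_transitions <- function(transitions, offset = 0L) {
  .check_columns(transitions, .transition_cols, "<transitions>")
  bad <- which(!is.na(transitions$area) & transitions$area < 0)
  if (length(bad) > 0L) {
    stop("negative area in row(s) ", paste(bad + offset, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!transitions$precursor_charge %in% c(2L, 3L))
  if (length(bad) > 0L) {
    stop("precursor_charge outside {2, 3} in row(s) ",
         paste(bad + offset, collapse = ", "), call. = FALSE)
  }
  ion <- substr(transitions$fragment_label, 1L, 1L)
  bad <- which(!ion %in% c("y", "b"))
  if (length(bad) > 0L) {
    stop("fragment ion type must be y or b; offending row(s) ",
         paste(bad + offset, collapse = ", "), call. = FALSE)
  }
  bad <- which(!transitions$eye %in% c("OD", "OS"))
  if (length(bad) > 0L) {
    stop("eye must be OD or OS; offending row(s) ",
         paste(bad + offset, collapse = ", "), call. = FALSE)
  }
  invisible(transitions)
}

#' Validate a sample sheet
#'
#' Sample identifiers must be unique, and so must the design coordinates
#' (eye, day, replicate, cohort).
#'
#' @param samples data.frame with columns sample_id, eye, day, replicate,
#'   cohort.
#' @return The input, invisibly, if valid.
#' @export
validate_samples <- function(samples) {
  .check_columns(samples, .sample_cols, "<samples>")
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  key <- paste(samples$eye, samples$day, samples$replicate, samples$cohort)
  if (anyDuplicated(key)) {
    stop("duplicate (eye, day, replicate, cohort) in sample sheet",
         call. = FALSE)
  }
  if (!all(samples$eye %in% c("OD", "OS"))) {
    stop("eye must be OD or OS", call. = FALSE)
  }
  invisible(samples)
}

#' Protein-by-injection quant matrix
#'
#' Container for a rolled-up protein area matrix: a numeric matrix with one
#' row per protein accession and one column per injection (`NA` marks a
#' missing, i.e. unobserved, value -- distinct from a measured zero), the
#' sample sheet describing the columns, and the per-protein supporting
#' peptide counts used by the differential-expression filter.
#'
#' @param areas numeric matrix, rownames = protein accessions, colnames =
#'   sample ids.
#' @param samples sample-sheet data.frame; `samples$sample_id` must match
#'   `colnames(areas)`.
#' @param peptide_counts integer vector named by protein accession; for each
#'   protein, the minimum number of quantified peptides across the injections
#'   in which it was observed.
#' @param counts optional integer matrix of the same shape as `areas` giving
#'   the per-injection number of peptides behind each protein value (`NA`
#'   where the protein was not observed); used by [find_deps()] for
#'   per-contrast peptide support.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(areas, samples, peptide_counts, counts = NULL) {
  stopifnot(is.matrix(areas), is.numeric(areas))
  validate_samples(samples)
  if (!identical(colnames(areas), samples$sample_id)) {
    stop("colnames(areas) must equal samples$sample_id (same order)",
         call. = FALSE)
  }
  if (is.null(rownames(areas))) {
    stop("areas must have protein accessions as rownames", call. = FALSE)
  }
  if (is.null(names(peptide_counts))) {
    if (length(peptide_counts) != nrow(areas)) {
      stop("peptide_counts must cover every protein in areas", call. = FALSE)
    }
    names(peptide_counts) <- rownames(areas)
  }
  peptide_counts <- peptide_counts[rownames(areas)]
  if (anyNA(peptide_counts)) {
    stop("peptide_counts must cover every protein in areas", call. = FALSE)
  }
  observed <- rowSums(!is.na(areas)) > 0
  if (any(observed & peptide_counts < 1L)) {
    stop("peptide_counts must be >= 1 for observed proteins", call. = FALSE)
  }
  if (!is.null(counts) && !identical(dim(counts), dim(areas))) {
    stop("counts must have the same shape as areas", call. = FALSE)
  }
  structure(list(areas = areas, samples = samples,
                 peptide_counts = stats::setNames(as.integer(peptide_counts),
                                                  names(peptide_counts)),
                 counts = counts),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat("quant_matrix: ", nrow(x$areas), " proteins x ", ncol(x$areas),
      " injections\n", sep = "")
  cat("  missing cells: ", sum(is.na(x$areas)),
      sprintf(" (%.1f%%)", 100 * mean(is.na(x$areas))), "\n", sep = "")
  cat("  cohorts: ", paste(unique(x$samples$cohort), collapse = ", "),
      "; days: ", paste(sort(unique(x$samples$day)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$areas)

#' Read a quant table
#'
#' Two dialects are supported. `"transition"` is a long-format TSV with one
#' row per fragment-ion measurement and columns sample_id, eye, day,
#' replicate, cohort, protein, peptide, precursor_charge, fragment_label,
#' area, snr (snr may be empty, e.g. for SWATH-arm rows). `"protein_wide"`
#' is a CSV with the first column `protein` and one column per sample id,
#' accompanied by two sidecar TSVs written by [write_quant_table()]:
#' `<path>.samples.tsv` (sample sheet) and `<path>.peptide_counts.tsv`.
#'
#' @param path file path.
#' @param dialect `"transition"` or `"protein_wide"`.
#' @param sample_sheet for `protein_wide`: a sample-sheet data.frame or a
#'   path to one; defaults to the `<path>.samples.tsv` sidecar.
#' @param peptide_counts for `protein_wide`: a named integer vector or a
#'   path; defaults to the `<path>.peptide_counts.tsv` sidecar (counts of 1
#'   are assumed if the sidecar does not exist).
#' @return A transition data.frame, or a [quant_matrix()].
#' @export
read_quant_table <- function(path, dialect = c("transition", "protein_wide"),
                             sample_sheet = NULL, peptide_counts = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "transition") {
    df <- utils::read.delim(path, sep = "\t", na.strings = "",
                            stringsAsFactors = FALSE)
    .check_columns(df, .transition_cols, path)
    df <- df[, .transition_cols]
    df$day <- as.integer(df$day)
    df$replicate <- as.integer(df$replicate)
    df$precursor_charge <- as.integer(df$precursor_charge)
    df$area <- as.numeric(df$area)
    df$snr <- as.numeric(df$snr)
    validate_transitions(df, offset = 1L)  # +1: header line
    return(df)
  }
  wide <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (names(wide)[1L] != "protein") {
    stop("file '", path, "' is missing mandatory column(s): protein",
         call. = FALSE)
  }
  if (is.null(sample_sheet)) sample_sheet <- paste0(path, ".samples.tsv")
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  areas <- as.matrix(wide[, -1L, drop = FALSE])
  mode(areas) <- "numeric"
  rownames(areas) <- wide$protein
  areas <- areas[, sample_sheet$sample_id, drop = FALSE]
  if (is.null(peptide_counts)) {
    pc_path <- paste0(path, ".peptide_counts.tsv")
    if (file.exists(pc_path)) {
      pc <- utils::read.delim(pc_path, stringsAsFactors = FALSE)
      peptide_counts <- stats::setNames(as.integer(pc$n_peptides), pc$protein)
    } else {
      peptide_counts <- stats::setNames(rep(1L, nrow(areas)), rownames(areas))
    }
  } else if (is.character(peptide_counts)) {
    pc <- utils::read.delim(peptide_counts, stringsAsFactors = FALSE)
    peptide_counts <- stats::setNames(as.integer(pc$n_peptides), pc$protein)
  }
  quant_matrix(areas, sample_sheet, peptide_counts)
}

#' Write a quant table
#'
#' Transition tables are written as TSV in canonical order (sorted by
#' sample_id, protein, peptide, fragment_label) with a fixed column set, so
#' two writes of the same records are byte-identical. A [quant_matrix()] is
#' written as a protein-wide CSV plus `<path>.samples.tsv` and
#' `<path>.peptide_counts.tsv` sidecars. Missing values become empty fields.
#'
#' @param records a transition data.frame or a [quant_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(records, path) {
  if (inherits(records, "quant_matrix")) {
    areas <- records$areas
    wide <- data.frame(protein = rownames(areas), stringsAsFactors = FALSE)
    for (j in seq_len(ncol(areas))) wide[[colnames(areas)[j]]] <- .fmt_num(areas[, j])
    utils::write.table(wide, path, sep = ",", quote = FALSE,
                       row.names = FALSE, na = "")
    write_sample_sheet(records$samples, paste0(path, ".samples.tsv"))
    pc <- data.frame(protein = rownames(areas),
                     n_peptides = records$peptide_counts)
    utils::write.table(pc, paste0(path, ".peptide_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  validate_transitions(records)
  ord <- order(records$sample_id, records$protein, records$peptide,
               records$fragment_label, method = "radix")
  out <- records[ord, .transition_cols]
  out$area <- .fmt_num(out$area)
  out$snr <- .fmt_num(out$snr)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a sample sheet
#'
#' TSV with columns sample_id, eye, day, replicate, cohort.
#'
#' @param path file path.
#' @return A validated sample-sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  .check_columns(df, .sample_cols, path)
  df <- df[, .sample_cols]
  df$day <- as.integer(df$day)
  df$replicate <- as.integer(df$replicate)
  validate_samples(df)
  df
}

#' @rdname read_sample_sheet
#' @param samples sample-sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  validate_samples(samples)
  utils::write.table(samples[, .sample_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read an ion library
#'
#' TSV with columns protein, peptide, confidence, source_injection.
#' Duplicate (protein, peptide, source_injection) rows are collapsed keeping
#' the maximum confidence. Confidence must lie in \[0, 1\].
#'
#' @param path file path.
#' @return data.frame of library entries.
#' @export
read_ion_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  .check_columns(df, .library_cols, path)
  df <- df[, .library_cols]
  df$confidence <- as.numeric(df$confidence)
  bad <- which(is.na(df$confidence) | df$confidence < 0 | df$confidence > 1)
  if (length(bad) > 0L) {
    stop("confidence outside [0, 1] in row(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$protein, df$peptide, df$source_injection, sep = "\x1f")
  if (anyDuplicated(key)) {
    ord <- order(key, -df$confidence, method = "radix")
    df <- df[ord, ][!duplicated(key[ord]), ]
  }
  df <- df[order(df$protein, df$peptide, df$source_injection,
                 method = "radix"), ]
  rownames(df) <- NULL
  df
}

#' @rdname read_ion_library
#' @param entries ion-library data.frame.
#' @export
write_ion_library <- function(entries, path) {
  .check_columns(entries, .library_cols, "<entries>")
  out <- entries[order(entries$protein, entries$peptide,
                       entries$source_injection, method = "radix"),
                 .library_cols]
  out$confidence <- .fmt_num(out$confidence)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
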