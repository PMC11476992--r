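# Most-likely-ratio (MLR) normalization. Each injection is scaled by the most
# likely protein-level ratio against a reference column: the mode of the log2
# ratio distribution over shared proteins, estimated by Gaussian kernel
# density. Taking the mode (rather than a mean/median) makes the factor
# insensitive to the minority of genuinely regulated proteins, which shift the
# tails but not the peak of the ratio distribution.

#' Log2 protein ratios between two injections
#'
#' Ratios are computed over proteins observed (non-missing) in both columns.
#' Shared proteins with a zero area in either column cannot contribute a
#' finite log ratio; they are excluded and counted in the
#' `"n_zero_excluded"` attribute rather than raising an error.
#'
#' @param sample_column,reference_column numeric vectors of protein areas
#'   from the same quant matrix (`NA` = missing).
#' @return Numeric vector of `log2(sample / reference)` over usable shared
#'   proteins (possibly empty), with attributes `n_shared` and
#'   `n_zero_excluded`.
#' @export
log_ratios <- function(sample_column, reference_column) {
  if (length(sample_column) != length(reference_column)) {
    stop("columns must have equal length", call. = FALSE)
  }
  shared <- !is.na(sample_column) & !is.na(reference_column)
  ok <- shared & sample_column > 0 & reference_column > 0
  r <- log2(sample_column[ok] / reference_column[ok])
  structure(r, n_shared = sum(shared), n_zero_excluded = sum(shared) - sum(ok))
}

# Mode of a log2-ratio sample: Gaussian KDE, Silverman's rule-of-thumb
# bandwidth (bw.nrd0), 512-point grid on [min - 1, max + 1], with parabolic
# interpolation through the grid maximum and its neighbours to remove grid
# quantization. Degenerate (zero-spread) samples short-circuit to their
# common value.
.kde_mode <- function(r) {
  if (stats::sd(r) < .Machine$double.eps^0.5) {
    return(list(mode = r[1L], grid_step = 0))
  }
  d <- stats::density(r, bw = "nrd0", n = 512L,
                      from = min(r) - 1, to = max(r) + 1)
  i <- which.max(d$y)
  step <- d$x[2L] - d$x[1L]
  m <- d$x[i]
  if (i > 1L && i < length(d$x)) {
    denom <- d$y[i - 1L] - 2 * d$y[i] + d$y[i + 1L]
    if (denom < 0) {
      off <- 0.5 * (d$y[i - 1L] - d$y[i + 1L]) / denom
      m <- m + max(-0.5, min(0.5, off)) * step
    }
  }
  list(mode = m, grid_step = step)
}

.mlr_factor <- function(sample_column, reference_column, min_shared = 50L) {
  r <- log_ratios(sample_column, reference_column)
  if (length(r) == 0L) {
    stop("no shared proteins between sample and reference; pair is not ",
         "normalizable", call. = FALSE)
  }
  if (length(r) < min_shared) {
    return(list(factor = 2^stats::median(r), n_shared = length(r),
                fallback = TRUE, grid_step = NA_real_))
  }
  m <- .kde_mode(as.numeric(r))
  list(factor = 2^m$mode, n_shared = length(r), fallback = FALSE,
       grid_step = m$grid_step)
}

#' Estimate the most-likely-ratio scale factor of one injection
#'
#' Returns `2^m`, where `m` is the mode of the log2 ratio distribution of the
#' sample against the reference, estimated by Gaussian kernel density
#' (Silverman bandwidth, 512-point grid spanning one log2 unit beyond the
#' ratio range). With fewer than `min_shared` shared proteins the mode is not
#' reliably estimable and `2^median` is returned instead, flagged in the
#' `"fallback"` attribute.
#'
#' @inheritParams log_ratios
#' @param min_shared minimum shared proteins for mode estimation.
#' @return Positive scalar with attributes `n_shared`, `fallback`,
#'   `grid_step` (log2 units).
#' @export
estimate_mlr_factor <- function(sample_column, reference_column,
                                min_shared = 50L) {
  f <- .mlr_factor(sample_column, reference_column, min_shared)
  structure(f$factor, n_shared = f$n_shared, fallback = f$fallback,
            grid_step = f$grid_step)
}

#' MLR-normalize a protein quant matrix
#'
#' Builds a reference column -- the per-protein median across injections
#' (`"median_pseudo"`, default: robust and symmetric across the design) or a
#' named injection -- then estimates one multiplicative factor per injection
#' with [estimate_mlr_factor()] and divides each column by its factor. When a
#' named injection is the reference its own factor is exactly 1; with the
#' pseudo-reference the overall scale of the factors is a convention, fixed
#' so their geometric mean is 1.
#'
#' @param x a [quant_matrix()] with at least two injections.
#' @param reference `"median_pseudo"` or one of `colnames(x$areas)`.
#' @param min_shared passed to [estimate_mlr_factor()].
#' @return An object of class `mlr_normalization`: list with `factors`
#'   (named), `normalized` (quant_matrix), `n_shared`, `fallback`,
#'   `reference` and `method_detail` (bandwidth rule, grid size, per-sample
#'   grid step).
#' @export
normalize_dataset <- function(x, reference = "median_pseudo",
                              min_shared = 50L) {
  stopifnot(inherits(x, "quant_matrix"))
  areas <- x$areas
  if (ncol(areas) < 2L) {
    stop("normalization needs at least 2 samples", call. = FALSE)
  }
  if (identical(reference, "median_pseudo")) {
    ref <- apply(areas, 1L, stats::median, na.rm = TRUE)
    ref[is.nan(ref)] <- NA_real_
    ref_name <- "median_pseudo"
  } else {
    if (!reference %in% colnames(areas)) {
      stop("reference sample '", reference, "' not found in matrix",
           call. = FALSE)
    }
    ref <- areas[, reference]
    ref_name <- reference
  }
  res <- lapply(seq_len(ncol(areas)),
                function(j) .mlr_factor(areas[, j], ref, min_shared))
  factors <- vapply(res, `[[`, numeric(1), "factor")
  names(factors) <- colnames(areas)
  if (ref_name %in% names(factors)) {
    factors[ref_name] <- 1
  } else {
    # a pseudo-reference leaves the overall scale of the factors undefined;
    # fix the convention at geometric mean 1 so factors are comparable
    factors <- factors / 2^mean(log2(factors))
  }
  normalized <- sweep(areas, 2L, factors, "/")
  out <- list(
    factors = factors,
    normalized = quant_matrix(normalized, x$samples, x$peptide_counts,
                              counts = x$counts),
    n_shared = stats::setNames(vapply(res, `[[`, numeric(1), "n_shared"),
                               colnames(areas)),
    fallback = stats::setNames(vapply(res, `[[`, logical(1), "fallback"),
                               colnames(areas)),
    reference = ref_name,
    method_detail = list(
      bandwidth = "nrd0 (Silverman rule of thumb)",
      grid_points = 512L,
      grid_step = stats::setNames(vapply(res, `[[`, numeric(1), "grid_step"),
                                  colnames(areas)),
      min_shared = min_shared))
  class(out) <- "mlr_normalization"
  out
}

#' @export
print.mlr_normalization <- function(x, ...) {
  cat("MLR normalization (reference: ", x$reference, ")\n", sep = "")
  cat("  factors: ", paste(sprintf("%.3f", range(x$factors)), collapse = " .. "),
      " across ", length(x$factors), " injections\n", sep = "")
  if (any(x$fallback)) {
    cat("  median fallback used for: ",
        paste(names(x$fallback)[x$fallback], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
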