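# Shared fixtures, all built in code.

# small, fast simulator configuration
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_proteins = 40L, peptides_per_protein = c(2L, 5L),
                   transitions_per_peptide = 4L, seed = 11L)
  do.call(synth_config, utils::modifyList(defaults, args))
}

# every stochastic term switched off: areas are exact closed forms
noise_free_config <- function(...) {
  base <- list(replicate_cv = 0, eye_jitter_sd_log2 = 0,
               bias_log2_range = c(0, 0), dropout_midpoint_log2 = -Inf,
               de_fraction = 0, decoy_fraction = 0)
  do.call(small_config, utils::modifyList(base, list(...)))
}

# minimal hand-built transition table: 1 sample unless more given
toy_transitions <- function() {
  data.frame(
    sample_id = "S1", eye = "OD", day = 7L, replicate = 1L, cohort = "SWATH",
    protein = c("P1", "P1", "P2"),
    peptide = c("P1_A", "P1_A", "P2_A"),
    precursor_charge = c(2L, 2L, 3L),
    fragment_label = c("y4^1", "b3^1", "y5^1"),
    area = c(100, 50, 10),
    snr = NA_real_,
    stringsAsFactors = FALSE)
}

toy_samples <- function() {
  data.frame(sample_id = c("S1", "S2"),
             eye = c("OD", "OS"), day = c(7L, 7L),
             replicate = c(1L, 1L), cohort = "SWATH",
             stringsAsFactors = FALSE)
}

toy_library <- function() {
  data.frame(protein = c("P1", "P2"),
             peptide = c("P1_A", "P2_A"),
             confidence = c(0.99, 0.97),
             source_injection = "ida1",
             stringsAsFactors = FALSE)
}

# quant matrix built directly from an area matrix
qm_from_matrix <- function(areas, days = NULL, eyes = NULL, counts = NULL) {
  ns <- ncol(areas)
  if (is.null(days)) days <- rep(7L, ns)
  if (is.null(eyes)) eyes <- rep(c("OD", "OS"), length.out = ns)
  if (is.null(colnames(areas))) {
    colnames(areas) <- sprintf("S%02d", seq_len(ns))
  }
  reps <- stats::ave(seq_len(ns), paste(days, eyes), FUN = seq_along)
  samples <- data.frame(sample_id = colnames(areas), eye = eyes, day = days,
                        replicate = reps, cohort = "SWATH",
                        stringsAsFactors = FALSE)
  quant_matrix(areas, samples,
               stats::setNames(rep(2L, nrow(areas)), rownames(areas)),
               counts = counts)
}

# textbook two-sample t-test, coded independently of the implementation
oracle_t_test <- function(a, b, flavor = "student") {
  n1 <- length(a); n2 <- length(b)
  va <- sum((a - mean(a))^2) / (n1 - 1)
  vb <- sum((b - mean(b))^2) / (n2 - 1)
  if (flavor == "student") {
    sp2 <- ((n1 - 1) * va + (n2 - 1) * vb) / (n1 + n2 - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- va / n1 + vb / n2
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / n1)^2 / (n1 - 1) + (vb / n2)^2 / (n2 - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
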