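# Seeded simulator for the two study arms: a pooled-eye SWATH discovery arm
# (days x {OD, OS} x technical replicates) and an individual-animal MRM(HR)
# validation arm (days 7/14, n animals per day). A single master seed expands
# into fixed substreams (truth / SWATH noise / library / MRM noise) so the two
# arms share one ground truth but can be regenerated independently.

.substream <- function(seed, k) {
  s <- abs(as.numeric(seed)) %% 2147483647
  as.integer((s * 48271 + k * 7919) %% 2147483647)
}

.cv_to_sdlog2 <- function(cv) sqrt(log(1 + cv^2)) / log(2)

#' Simulator configuration
#'
#' Parameters of the synthetic SWATH/MRM(HR) data generator. Defaults mirror
#' the study design the package targets: four timepoints (days 7/14/21/28),
#' pooled left/right-eye samples with three technical replicates in the
#' discovery arm (24 injections), and four individual animals per day at days
#' 7 and 14 in the validation arm.
#'
#' @param n_proteins number of simulated proteins (the housekeeping analog,
#'   accession `"GAPDH"`, is one of them).
#' @param peptides_per_protein integer range (min, max); each protein draws a
#'   peptide count uniformly from it.
#' @param transitions_per_peptide fragment ions per peptide.
#' @param days timepoints (days post-hatch); the first is the fold-change
#'   reference.
#' @param tech_replicates technical replicates per pooled sample (SWATH arm).
#' @param animals_per_day individual animals per day (MRM(HR) arm).
#' @param log2_abundance_mean,log2_abundance_sd protein baseline log2 area.
#' @param replicate_cv multiplicative measurement noise (coefficient of
#'   variation) per transition observation.
#' @param eye_jitter_sd_log2 SD of the per-eye jitter added to differential
#'   effects (log2).
#' @param bias_log2_range per-injection loading/spray bias, drawn uniformly
#'   (log2); applied multiplicatively to every area of the injection. This is
#'   exactly the nuisance the MLR normalization step removes.
#' @param de_fraction,decoy_fraction fractions of proteins given concordant
#'   differential effects (same sign in both eyes) and discordant decoy
#'   effects (opposite sign across eyes). Counts use floor rounding.
#' @param de_log2_fc_range magnitude range of true log2 fold changes vs the
#'   reference day.
#' @param dropout_midpoint_log2,dropout_steepness logistic dropout of
#'   peptide-injection observations: an observation with peptide log2 area
#'   `a` is removed with probability `plogis((dropout_midpoint_log2 - a) /
#'   dropout_steepness)`. Use `dropout_midpoint_log2 = -Inf` to disable.
#' @param bio_cv biological coefficient of variation across individual
#'   animals (MRM(HR) arm; replaces pooling).
#' @param mrmhr_peptides,mrmhr_transitions peptides per target and transitions
#'   per peptide generated in the MRM(HR) arm.
#' @param snr_low_fraction fraction of MRM(HR) transitions whose
#'   signal-to-noise ratio falls below 20 (sets the noise floor).
#' @param seed master seed (integer).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 1000L,
                         peptides_per_protein = c(2L, 15L),
                         transitions_per_peptide = 6L,
                         days = c(7L, 14L, 21L, 28L),
                         tech_replicates = 3L,
                         animals_per_day = 4L,
                         log2_abundance_mean = 17,
                         log2_abundance_sd = 2,
                         replicate_cv = 0.10,
                         eye_jitter_sd_log2 = 0.10,
                         bias_log2_range = c(-1, 1),
                         de_fraction = 0.10,
                         decoy_fraction = 0.05,
                         de_log2_fc_range = c(0.8, 2.5),
                         dropout_midpoint_log2 = 12,
                         dropout_steepness = 1.5,
                         bio_cv = 0.20,
                         mrmhr_peptides = 3L,
                         mrmhr_transitions = 5L,
                         snr_low_fraction = 0.10,
                         seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              peptides_per_protein = as.integer(peptides_per_protein),
              transitions_per_peptide = as.integer(transitions_per_peptide),
              days = as.integer(days),
              tech_replicates = as.integer(tech_replicates),
              animals_per_day = as.integer(animals_per_day),
              log2_abundance_mean = log2_abundance_mean,
              log2_abundance_sd = log2_abundance_sd,
              replicate_cv = replicate_cv,
              eye_jitter_sd_log2 = eye_jitter_sd_log2,
              bias_log2_range = bias_log2_range,
              de_fraction = de_fraction,
              decoy_fraction = decoy_fraction,
              de_log2_fc_range = de_log2_fc_range,
              dropout_midpoint_log2 = dropout_midpoint_log2,
              dropout_steepness = dropout_steepness,
              bio_cv = bio_cv,
              mrmhr_peptides = as.integer(mrmhr_peptides),
              mrmhr_transitions = as.integer(mrmhr_transitions),
              snr_low_fraction = snr_low_fraction,
              seed = as.integer(seed))
  if (cfg$n_proteins < 1L) stop("n_proteins must be >= 1", call. = FALSE)
  if (length(cfg$days) < 1L) stop("days must be non-empty", call. = FALSE)
  if (length(cfg$peptides_per_protein) != 2L ||
      diff(cfg$peptides_per_protein) < 0 || cfg$peptides_per_protein[1] < 1L) {
    stop("peptides_per_protein must be an ordered positive range",
         call. = FALSE)
  }
  for (f in c("de_fraction", "decoy_fraction", "snr_low_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]",
                                           call. = FALSE)
  }
  if (cfg$de_fraction + cfg$decoy_fraction > 1) {
    stop("de_fraction + decoy_fraction must be <= 1", call. = FALSE)
  }
  if (diff(cfg$bias_log2_range) < 0 || diff(cfg$de_log2_fc_range) < 0) {
    stop("ranges must be ordered (min, max)", call. = FALSE)
  }
  if (cfg$replicate_cv < 0 || cfg$bio_cv < 0 || cfg$eye_jitter_sd_log2 < 0) {
    stop("noise parameters must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# Ground truth shared by both arms: protein classes, baselines, peptide
# structure, and per-(protein, day, eye) true log2 effects vs the reference
# day. Concordant DE proteins share one sign across eyes; decoys carry
# opposite-sign effects across eyes (built to be rejected by the bilateral
# filter). The housekeeping analog is a null protein pinned at a high baseline
# so it is quantifiable in every injection.
.synth_truth <- function(config) {
  set.seed(.substream(config$seed, 1L))
  n <- config$n_proteins
  n_de <- floor(n * config$de_fraction)
  n_decoy <- floor(n * config$decoy_fraction)
  if (n_de + n_decoy >= n) {
    stop("config leaves no null protein to act as housekeeping", call. = FALSE)
  }
  status <- rep("null", n)
  if (n_de > 0L) status[seq_len(n_de)] <- "de"
  if (n_decoy > 0L) status[n_de + seq_len(n_decoy)] <- "decoy"
  status[n] <- "housekeeping"
  protein <- sprintf("SYNP%05d", seq_len(n))
  protein[n] <- "GAPDH"
  baseline <- stats::rnorm(n, config$log2_abundance_mean,
                           config$log2_abundance_sd)
  baseline[n] <- config$log2_abundance_mean + 2 * config$log2_abundance_sd

  ref_day <- config$days[1L]
  alt_days <- setdiff(config$days, ref_day)
  eff <- expand.grid(protein = protein, day = alt_days, eye = c("OD", "OS"),
                     stringsAsFactors = FALSE)
  eff$log2fc <- 0
  if (length(alt_days) > 0L) {
    sign_de <- sample(c(-1, 1), n, replace = TRUE)     # one direction per protein
    up_eye <- sample(c(1, -1), n, replace = TRUE)      # decoys: which eye goes up
    mag <- matrix(stats::runif(n * length(alt_days), config$de_log2_fc_range[1],
                               config$de_log2_fc_range[2]),
                  nrow = n)
    colnames(mag) <- as.character(alt_days)
    ip <- match(eff$protein, protein)
    m <- mag[cbind(ip, match(as.character(eff$day), colnames(mag)))]
    is_de <- status[ip] == "de"
    is_decoy <- status[ip] == "decoy"
    eye_sign <- ifelse(eff$eye == "OD", 1, -1)
    eff$log2fc[is_de] <- (sign_de[ip] * m)[is_de]
    eff$log2fc[is_decoy] <- (up_eye[ip] * eye_sign * m)[is_decoy]
  }

  k <- if (diff(config$peptides_per_protein) == 0L) {
    rep(config$peptides_per_protein[1], n)
  } else {
    sample(seq(config$peptides_per_protein[1], config$peptides_per_protein[2]),
           n, replace = TRUE)
  }
  peptides <- data.frame(
    protein = rep(protein, k),
    peptide = sprintf("%s_PEP%02d", rep(protein, k),
                      unlist(lapply(k, seq_len), use.names = FALSE)),
    offset_log2 = stats::rnorm(sum(k)),
    stringsAsFactors = FALSE)

  tpp <- config$transitions_per_peptide
  ion <- rep_len(c("y", "b"), tpp)
  labels <- sprintf("%s%d^1", ion, 2L + seq_len(tpp))
  g <- matrix(stats::rexp(nrow(peptides) * tpp), nrow = tpp)
  frac <- g / rep(colSums(g), each = tpp)                # Dirichlet(1, ..., 1)
  transitions <- data.frame(
    protein = rep(peptides$protein, each = tpp),
    peptide = rep(peptides$peptide, each = tpp),
    fragment_label = rep(labels, nrow(peptides)),
    fraction = as.vector(frac),
    stringsAsFactors = FALSE)

  structure(list(
    proteins = data.frame(protein = protein, status = status,
                          is_de = status == "de", is_decoy = status == "decoy",
                          baseline_log2 = baseline, n_peptides = k,
                          stringsAsFactors = FALSE),
    effects = eff,
    peptides = peptides,
    transitions = transitions,
    housekeeping = "GAPDH",
    reference_day = ref_day,
    config = config), class = "synth_truth")
}

#' @export
print.synth_truth <- function(x, ...) {
  tab <- table(x$proteins$status)
  cat("synth_truth: ", nrow(x$proteins), " proteins (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  reference day ", x$reference_day, "; housekeeping analog '",
      x$housekeeping, "'\n", sep = "")
  invisible(x)
}

# log2 biological abundance per (protein, day, eye): baseline + true effect
# (+ per-eye jitter on non-null effects). One draw shared by all technical
# replicates of that pooled sample -- the pooled-eye design.
.bio_abundance <- function(truth, days, config) {
  pr <- truth$proteins
  grp <- expand.grid(day = days, eye = c("OD", "OS"), stringsAsFactors = FALSE)
  B <- matrix(pr$baseline_log2, nrow = nrow(pr), ncol = nrow(grp))
  rownames(B) <- pr$protein
  colnames(B) <- paste(grp$day, grp$eye, sep = "_")
  key <- paste(truth$effects$day, truth$effects$eye, sep = "_")
  for (j in seq_len(nrow(grp))) {
    sel <- key == colnames(B)[j]
    if (!any(sel)) next
    e <- truth$effects[sel, ]
    fc <- stats::setNames(e$log2fc, e$protein)[pr$protein]
    fc[is.na(fc)] <- 0
    jit <- ifelse(fc != 0,
                  stats::rnorm(nrow(pr), 0, config$eye_jitter_sd_log2), 0)
    B[, j] <- B[, j] + fc + jit
  }
  list(B = B, groups = grp)
}

#' Generate a synthetic SWATH discovery-arm dataset
#'
#' Emits one injection per day x eye x technical replicate. Transition areas
#' are built as `2^(baseline + effect + eye jitter + peptide offset +
#' injection bias) * transition fraction * measurement noise`, with logistic
#' abundance-dependent dropout applied at the peptide-injection level
#' (a dropped peptide loses all its transitions; the cell is missing, not 0).
#' Identical seeds give identical output.
#'
#' @param config a [synth_config()].
#' @return A list with elements `transitions` (long-format data.frame, snr
#'   empty), `samples` (sample sheet), `library` (ion-library data.frame) and
#'   `truth` (a `synth_truth` with, additionally, the per-injection
#'   `biases` data.frame).
#' @export
generate_swath <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  truth <- .synth_truth(config)
  set.seed(.substream(config$seed, 2L))

  samples <- expand.grid(replicate = seq_len(config$tech_replicates),
                         eye = c("OD", "OS"), day = config$days,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("eye", "day", "replicate")]
  samples$cohort <- "SWATH"
  samples$sample_id <- sprintf("SW_D%02d_%s_R%d", samples$day, samples$eye,
                               samples$replicate)
  samples <- samples[, .sample_cols]
  ns <- nrow(samples)
  bias <- stats::runif(ns, config$bias_log2_range[1], config$bias_log2_range[2])

  ab <- .bio_abundance(truth, config$days, config)
  grp_of_sample <- match(paste(samples$day, samples$eye, sep = "_"),
                         colnames(ab$B))

  pep <- truth$peptides
  np <- nrow(pep)
  ip <- match(pep$protein, truth$proteins$protein)
  # peptide log2 area per (peptide, injection), injection-major
  pep_log2 <- as.vector(ab$B[ip, grp_of_sample]) +
    rep(pep$offset_log2, times = ns)
  keep_pep <- stats::runif(np * ns) >=
    stats::plogis((config$dropout_midpoint_log2 - pep_log2) /
                  config$dropout_steepness)

  tr <- truth$transitions
  nt <- nrow(tr)
  it <- match(tr$peptide, pep$peptide)
  row_s <- rep(seq_len(ns), each = nt)
  row_t <- rep(seq_len(nt), times = ns)
  pi_idx <- (row_s - 1L) * np + it[row_t]
  sdlog2 <- .cv_to_sdlog2(config$replicate_cv)
  noise <- if (sdlog2 > 0) {
    stats::rnorm(nt * ns, -sdlog2^2 * log(2) / 2, sdlog2)
  } else 0
  area <- 2^(pep_log2[pi_idx] + bias[row_s] + noise) * tr$fraction[row_t]

  keep <- keep_pep[pi_idx]
  out <- data.frame(
    sample_id = samples$sample_id[row_s][keep],
    eye = samples$eye[row_s][keep],
    day = samples$day[row_s][keep],
    replicate = samples$replicate[row_s][keep],
    cohort = "SWATH",
    protein = tr$protein[row_t][keep],
    peptide = tr$peptide[row_t][keep],
    precursor_charge = rep_len(c(2L, 3L), nt)[row_t][keep],
    fragment_label = tr$fragment_label[row_t][keep],
    area = area[keep],
    snr = NA_real_,
    stringsAsFactors = FALSE)

  set.seed(.substream(config$seed, 3L))
  library <- data.frame(protein = pep$protein, peptide = pep$peptide,
                        confidence = round(stats::runif(np, 0.95, 1), 4),
                        source_injection = "combined_ida",
                        stringsAsFactors = FALSE)
  truth$biases <- data.frame(sample_id = samples$sample_id, bias_log2 = bias,
                             stringsAsFactors = FALSE)
  list(transitions = out, samples = samples, library = library, truth = truth)
}

#' Generate a synthetic MRM(HR) validation-arm dataset
#'
#' Individual animals (biological replicates, one random eye each) at days 7
#' and 14, for the requested target proteins plus the housekeeping analog.
#' Biological variation (`bio_cv`) replaces the pooling of the discovery arm.
#' Each target gets `mrmhr_peptides` peptides with `mrmhr_transitions`
#' fragment ions; signal-to-noise is generated proportional to area over a
#' noise floor chosen so that about `snr_low_fraction` of transitions fall
#' below 20.
#'
#' @param config a [synth_config()] (shares its ground truth with
#'   [generate_swath()] at the same seed).
#' @param target_proteins accessions to monitor; must exist in the truth.
#' @return A list with `transitions` (with snr), `samples` and `truth`.
#' @export
generate_mrmhr <- function(config = synth_config(), target_proteins) {
  stopifnot(inherits(config, "synth_config"))
  truth <- .synth_truth(config)
  unknown <- setdiff(target_proteins, truth$proteins$protein)
  if (length(unknown) > 0L) {
    stop("unknown target accession(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  set.seed(.substream(config$seed, 4L))
  days <- intersect(c(7L, 14L), config$days)
  if (length(days) < 2L) days <- config$days[seq_len(min(2L, length(config$days)))]

  prots <- union(target_proteins, truth$housekeeping)
  pr <- truth$proteins[match(prots, truth$proteins$protein), ]

  samples <- expand.grid(replicate = seq_len(config$animals_per_day),
                         day = days, stringsAsFactors = FALSE)
  samples$eye <- sample(c("OD", "OS"), nrow(samples), replace = TRUE)
  samples$cohort <- "MRMHR"
  samples$sample_id <- sprintf("MRM_D%02d_A%d", samples$day, samples$replicate)
  samples <- samples[, .sample_cols]
  ns <- nrow(samples)

  # fresh peptide structure for the targeted assay (different acquisition)
  kp <- config$mrmhr_peptides
  tpp <- config$mrmhr_transitions
  pep <- data.frame(
    protein = rep(prots, each = kp),
    peptide = sprintf("%s_TGT%02d", rep(prots, each = kp),
                      rep(seq_len(kp), length(prots))),
    offset_log2 = stats::rnorm(length(prots) * kp),
    stringsAsFactors = FALSE)
  np <- nrow(pep)
  ion <- rep_len(c("y", "b"), tpp)
  labels <- sprintf("%s%d^1", ion, 2L + seq_len(tpp))
  g <- matrix(stats::rexp(np * tpp), nrow = tpp)
  frac <- g / rep(colSums(g), each = tpp)

  ab <- .bio_abundance(truth, days, config)
  grp_of_sample <- match(paste(samples$day, samples$eye, sep = "_"),
                         colnames(ab$B))
  ipr <- match(pep$protein, rownames(ab$B))
  sd_bio <- .cv_to_sdlog2(config$bio_cv)
  # per (protein, animal) biological deviation, shared by the protein's peptides
  bio_dev <- matrix(if (sd_bio > 0) stats::rnorm(length(prots) * ns, 0, sd_bio)
                    else 0, nrow = length(prots), ncol = ns)
  bias <- stats::runif(ns, config$bias_log2_range[1], config$bias_log2_range[2])

  row_s <- rep(seq_len(ns), each = np * tpp)
  row_p <- rep(rep(seq_len(np), each = tpp), times = ns)
  row_f <- rep(seq_len(tpp), times = np * ns)
  iprot <- match(pep$protein, prots)[row_p]
  log2a <- ab$B[cbind(ipr[row_p], grp_of_sample[row_s])] +
    pep$offset_log2[row_p] + bio_dev[cbind(iprot, row_s)] + bias[row_s]
  sdlog2 <- .cv_to_sdlog2(config$replicate_cv)
  noise <- if (sdlog2 > 0) {
    stats::rnorm(length(log2a), -sdlog2^2 * log(2) / 2, sdlog2)
  } else 0
  area <- 2^(log2a + noise) * frac[cbind(row_f, row_p)]

  floor_q <- if (config$snr_low_fraction > 0) {
    stats::quantile(area, config$snr_low_fraction, names = FALSE) / 20
  } else min(area) / 40
  snr <- area / floor_q

  out <- data.frame(
    sample_id = samples$sample_id[row_s],
    eye = samples$eye[row_s],
    day = samples$day[row_s],
    replicate = samples$replicate[row_s],
    cohort = "MRMHR",
    protein = pep$protein[row_p],
    peptide = pep$peptide[row_p],
    precursor_charge = rep_len(c(2L, 3L), np)[row_p],
    fragment_label = labels[row_f],
    area = area,
    snr = snr,
    stringsAsFactors = FALSE)
  truth$biases <- data.frame(sample_id = samples$sample_id, bias_log2 = bias,
                             stringsAsFactors = FALSE)
  list(transitions = out, samples = samples, truth = truth)
}
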