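test_that("build_transition_list filters ion types and keeps top-5 products", {
  lib <- data.frame(protein = "P1", peptide = "pepA", confidence = 0.99,
                    source_injection = "x", stringsAsFactors = FALSE)
  cat8 <- data.frame(peptide = "pepA",
                     ion_type = c("y", "y", "b", "b", "y", "b", "y", "b"),
                     fragment_charge = 1L, precursor_charge = 2L,
                     mz = seq(300, 1000, length.out = 8),
                     intensity = c(10, 80, 60, 40, 90, 20, 70, 50),
                     stringsAsFactors = FALSE)
  tl <- build_transition_list(lib, cat8)
  expect_equal(nrow(tl), 5L)
  expect_setequal(tl$intensity, c(90, 80, 70, 60, 50))
  expect_equal(tl$rank, 1:5)

  # z ions and multiply charged fragments never qualify
  catz <- cat8
  catz$ion_type[1:4] <- "z"
  catz$fragment_charge[5] <- 2L
  tlz <- build_transition_list(lib, catz)
  expect_false(any(tlz$ion_type == "z"))
  expect_true(all(tlz$fragment_charge == 1L))
  expect_equal(nrow(tlz), 3L)

  none <- build_transition_list(lib, transform(cat8, ion_type = "z"))
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "excluded_peptides"), "pepA")

  # ties on intensity break by ascending m/z
  cat_tie <- cat8
  cat_tie$intensity <- 50
  tie <- build_transition_list(lib, cat_tie,
                               transition_list_spec(top_products = 2))
  expect_equal(tie$mz, sort(cat8$mz)[1:2])

  # brute-force oracle over random catalogs
  set.seed(50)
  for (i in 1:100) {
    cat_r <- data.frame(
      peptide = "pepA",
      ion_type = sample(c("y", "b", "z", "a"), 12, replace = TRUE),
      fragment_charge = sample(1:2, 12, replace = TRUE),
      precursor_charge = sample(2:4, 12, replace = TRUE),
      mz = round(runif(12, 200, 1200), 3),
      intensity = round(runif(12, 1, 100), 3),
      stringsAsFactors = FALSE)
    got <- build_transition_list(lib, cat_r)
    ok <- cat_r[cat_r$ion_type %in% c("y", "b") & cat_r$fragment_charge == 1 &
                cat_r$precursor_charge %in% 2:3, ]
    ok <- ok[order(-ok$intensity, ok$mz), ]
    want <- utils::head(ok, 5)
    expect_equal(got$intensity, want$intensity)
    expect_equal(got$mz, want$mz)
  }
})

test_that("peptide_intensity means the top-3 surviving transitions", {
  cfg <- mrm_config()
  expect_equal(peptide_intensity(c(40, 30, 20, 10), rep(25, 4), cfg), 30)
  expect_equal(peptide_intensity(c(40, 30), c(25, 25), cfg), 35)
  expect_true(is.na(peptide_intensity(c(40, 30), c(19, 5), cfg)))
  # boundary: "above 20" default keeps snr == 20; strict mode drops it
  expect_equal(peptide_intensity(c(40, 30), c(20, 10), cfg), 40)
  strict <- mrm_config(snr_exclusive = TRUE)
  expect_true(is.na(peptide_intensity(40, 20, strict)))
})

test_that("protein_intensity means the top-3 peptides (oracle check)", {
  cfg <- mrm_config()
  expect_equal(protein_intensity(c(30, 20, 10, 5), cfg), 20)
  expect_equal(protein_intensity(12, cfg), 12)
  expect_true(is.na(protein_intensity(c(NA_real_, NA_real_), cfg)))
  set.seed(51)
  for (i in 1:200) {
    n <- sample(1:8, 1); k <- sample(1:5, 1)
    a <- round(runif(n, 0, 50), 3)
    got <- protein_intensity(a, mrm_config(top_peptides = k))
    expect_equal(got, mean(sort(a, decreasing = TRUE)[seq_len(min(k, n))]))
  }
})

test_that("housekeeping normalization self-normalizes and cancels loading", {
  m <- rbind(GAPDH = c(100, 200), T1 = c(200, 100), T2 = c(50, 400))
  colnames(m) <- c("I1", "I2")
  norm <- normalize_housekeeping(m, "GAPDH")
  expect_equal(unname(norm["GAPDH", ]), c(1, 1))
  expect_equal(unname(norm["T1", ]), c(2, 0.5))

  # doubling every intensity of one injection changes nothing
  m2 <- m; m2[, "I2"] <- m2[, "I2"] * 2
  expect_equal(normalize_housekeeping(m2, "GAPDH"), norm)

  m3 <- m; m3["GAPDH", "I2"] <- NA
  expect_error(normalize_housekeeping(m3, "GAPDH"), "I2")
  expect_error(normalize_housekeeping(m, "ACTB"), "not in matrix")
})

test_that("group_fold_change is the ratio of group means", {
  m <- rbind(T1 = c(2, 2, 2, 2, 1, 1, 1, 1))
  colnames(m) <- sprintf("A%d", 1:8)
  samples <- data.frame(sample_id = colnames(m), eye = "OD",
                        day = rep(c(14L, 7L), each = 4), replicate = 1:8,
                        cohort = "MRMHR", stringsAsFactors = FALSE)
  expect_equal(group_fold_change(m, "T1", samples), 2)
  m2 <- rbind(T1 = rep(3, 8)); colnames(m2) <- colnames(m)
  expect_equal(group_fold_change(m2, "T1", samples), 1)
  m3 <- rbind(T1 = c(NA, NA, NA, NA, 1, 1, 1, 1)); colnames(m3) <- colnames(m)
  expect_true(is.na(group_fold_change(m3, "T1", samples)))
})

test_that("unpaired_t_test matches a textbook oracle to 1e-10", {
  same <- unpaired_t_test(1:4, 1:4)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(52)
  for (i in 1:50) {
    a <- rnorm(sample(3:8, 1), 10, 2)
    b <- rnorm(sample(3:8, 1), 11, 3)
    for (fl in c("student", "welch")) {
      got <- unpaired_t_test(a, b, fl)
      want <- oracle_t_test(a, b, fl)
      expect_equal(got$t, want$t, tolerance = 1e-10)
      expect_equal(got$df, want$df, tolerance = 1e-10)
      expect_equal(got$p, want$p, tolerance = 1e-10)
    }
    # swapping groups negates t, keeps p
    sw <- unpaired_t_test(b, a)
    fw <- unpaired_t_test(a, b)
    expect_equal(sw$t, -fw$t)
    expect_equal(sw$p, fw$p)
  }

  deg <- unpaired_t_test(c(1, 1, 1), c(1, 1, 1))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
  expect_true(unpaired_t_test(1, c(1, 2))$degenerate)
})

test_that("run_validation composes the targeted pipeline correctly", {
  # noise-free: estimated FC is exactly 2^(true effect)
  cfg <- noise_free_config(bio_cv = 0, de_fraction = 0.2,
                           snr_low_fraction = 0, seed = 15)
  mr <- generate_mrmhr(cfg, "SYNP00001")
  truth <- mr$truth
  expect_true(truth$proteins$is_de[1])
  v <- run_validation(mr$transitions, mr$samples, "SYNP00001")
  eff <- truth$effects
  want <- 2^eff$log2fc[eff$protein == "SYNP00001" & eff$day == 14 &
                       eff$eye == mr$samples$eye[1]]
  # noise-free MRM effects are eye-independent for concordant DE
  expect_equal(v$fc, unique(want), tolerance = 1e-9)
  expect_true(is.na(v$p))  # zero variance is flagged, no p is emitted

  # the housekeeping protein as target: FC 1, never significant
  hk <- run_validation(mr$transitions, mr$samples, "GAPDH")
  expect_equal(hk$fc, 1)
  expect_false(hk$significant)

  # global per-injection scaling leaves every result unchanged
  cfg2 <- small_config(seed = 16, de_fraction = 0.2)
  mr2 <- generate_mrmhr(cfg2, c("SYNP00001", "SYNP00002"))
  v1 <- run_validation(mr2$transitions, mr2$samples,
                       c("SYNP00001", "SYNP00002"))
  tr_scaled <- mr2$transitions
  one <- tr_scaled$sample_id == mr2$samples$sample_id[1]
  tr_scaled$area[one] <- tr_scaled$area[one] * 7
  tr_scaled$snr[one] <- tr_scaled$snr[one] * 7  # snr scales with signal
  v2 <- run_validation(tr_scaled, mr2$samples, c("SYNP00001", "SYNP00002"))
  expect_equal(v1$fc, v2$fc, tolerance = 1e-12)
  expect_equal(v1$p, v2$p, tolerance = 1e-12)

  expect_error(run_validation(mr2$transitions, mr2$samples, "SYNP99999"),
               "not quantified")
})
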