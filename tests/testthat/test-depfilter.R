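test_that("eye_fold_change averages technical replicates before the ratio", {
  areas <- rbind(P1 = c(100, 110, 90, 50, 55, 45))
  qm <- qm_from_matrix(areas, days = c(14L, 14L, 14L, 7L, 7L, 7L),
                       eyes = rep("OD", 6))
  expect_equal(eye_fold_change(qm, "P1", "OD", 14L), 2)
  expect_equal(eye_fold_change(qm, "P1", "OD", 7L, reference_day = 7L), 1)

  # all-missing denominator propagates to a missing fold change
  areas2 <- rbind(P1 = c(100, 110, NA, NA))
  qm2 <- qm_from_matrix(areas2, days = c(14L, 14L, 7L, 7L), eyes = rep("OD", 4))
  expect_true(is.na(eye_fold_change(qm2, "P1", "OD", 14L)))
  # zero denominator likewise
  areas3 <- rbind(P1 = c(100, 0))
  qm3 <- qm_from_matrix(areas3, days = c(14L, 7L), eyes = rep("OD", 2))
  expect_true(is.na(eye_fold_change(qm3, "P1", "OD", 14L)))
})

test_that("classify_direction implements the bilateral concordance rule", {
  cfg <- filter_config()
  expect_equal(as.character(classify_direction(4.08, 3.02, cfg)), "UP")
  expect_equal(as.character(classify_direction(0.44, 0.44, cfg)), "DOWN")
  expect_equal(as.character(classify_direction(1.6, 0.9, cfg)), "NONE")
  # cutoffs are inclusive
  expect_equal(as.character(classify_direction(1.5, 1.5, cfg)), "UP")
  expect_equal(as.character(classify_direction(0.7, 0.7, cfg)), "DOWN")
  miss <- classify_direction(NA_real_, 3, cfg)
  expect_equal(as.character(miss), "NONE")
  expect_false(attr(miss, "evaluable"))

  # monotone: raising both FCs never moves UP -> NONE or NONE -> DOWN
  set.seed(40)
  rank_of <- c(DOWN = 1L, NONE = 2L, UP = 3L)
  f1 <- runif(500, 0.1, 3); f2 <- runif(500, 0.1, 3)
  bump <- runif(500, 0, 1)
  d0 <- rank_of[as.character(classify_direction(f1, f2, cfg))]
  d1 <- rank_of[as.character(classify_direction(f1 + bump, f2 + bump, cfg))]
  expect_true(all(d1 >= d0))
})

test_that("average_fc reproduces the reported two-value summaries", {
  a <- average_fc(4.08, 3.02)
  expect_equal(round_half_away(a$ave), 3.55)
  expect_equal(round_half_away(a$sd), 0.75)
  b <- average_fc(9.39, 5.11)
  expect_equal(round_half_away(b$ave), 7.25)
  expect_equal(round_half_away(b$sd), 3.03)
  expect_equal(average_fc(1.3, 1.3), list(ave = 1.3, sd = 0))
  # the two-value sample SD identity |a-b|/sqrt(2) == sd()
  set.seed(41)
  x <- runif(50, 0, 5); y <- runif(50, 0, 5)
  got <- average_fc(x, y)
  expect_equal(got$sd, mapply(function(u, v) stats::sd(c(u, v)), x, y),
               tolerance = 1e-12)
  expect_equal(round_half_away(0.315), 0.32)   # half away from zero
  expect_equal(round_half_away(-0.315), -0.32)
})

test_that("find_deps applies peptide and direction filters deterministically", {
  # 2 proteins x (2 days x OD/OS), replicates = 1; P2 has only 1 peptide
  areas <- rbind(P1 = c(40, 44, 10, 11), P2 = c(30, 33, 10, 11))
  counts <- rbind(P1 = c(3L, 3L, 3L, 3L), P2 = c(1L, 1L, 1L, 1L))
  qm <- qm_from_matrix(areas, days = c(14L, 14L, 7L, 7L),
                       eyes = c("OD", "OS", "OD", "OS"), counts = counts)
  deps <- find_deps(qm, 14L)
  expect_equal(deps$protein, "P1")
  expect_equal(deps$direction, "UP")
  expect_equal(deps$fc_od, 4)
  expect_equal(deps$n_peptides, 3L)

  # an all-null noise-free matrix yields no DEPs
  sw <- generate_swath(noise_free_config(seed = 9))
  qm0 <- build_matrix(sw$transitions, sw$library, sw$samples)
  expect_equal(nrow(find_deps(qm0, 14L)), 0L)
  expect_error(find_deps(qm0, 99L), "absent")

  # row order and replicate order do not change the result
  sw2 <- generate_swath(small_config(de_fraction = 0.3, seed = 10))
  qm1 <- build_matrix(sw2$transitions, sw2$library, sw2$samples)
  perm_p <- sample(nrow(qm1$areas))
  perm_s <- order(sw2$samples$day, sw2$samples$eye,
                  rev(sw2$samples$replicate))
  qm_perm <- quant_matrix(qm1$areas[perm_p, perm_s],
                          qm1$samples[perm_s, ],
                          qm1$peptide_counts[perm_p],
                          counts = qm1$counts[perm_p, perm_s])
  expect_equal(find_deps(qm1, 14L), find_deps(qm_perm, 14L))
})

test_that("per-contrast peptide support uses the configured count rule", {
  areas <- rbind(P1 = c(40, 44, 10, 11, 30, 33))
  counts <- rbind(P1 = c(2L, 2L, 2L, 1L, 5L, 5L))
  qm <- qm_from_matrix(areas, days = c(14L, 14L, 7L, 7L, 28L, 28L),
                       eyes = c("OD", "OS", "OD", "OS", "OD", "OS"),
                       counts = counts)
  expect_equal(find_deps(qm, 14L)$n_peptides, 2L)        # max over d7+d14
  expect_equal(nrow(find_deps(qm, 14L, filter_config(count_rule = "min"))), 0L)
  # without the count grid the global summary is used
  qm$counts <- NULL
  expect_equal(find_deps(qm, 14L)$n_peptides,
               unname(qm$peptide_counts["P1"]))
})

test_that("intersect_deps keeps direction-consistent proteins (oracle check)", {
  mk <- function(p, d) data.frame(protein = p, direction = d,
                                  stringsAsFactors = FALSE)
  r <- intersect_deps(list(d14 = mk(c("A", "B"), c("UP", "DOWN")),
                           d21 = mk(c("A", "B", "C"), c("UP", "DOWN", "UP"))))
  expect_equal(r$up, "A")
  expect_equal(r$down, "B")
  r2 <- intersect_deps(list(mk("A", "UP"), mk("A", "DOWN")))
  expect_length(r2$up, 0)
  expect_length(r2$down, 0)
  expect_error(intersect_deps(list(mk("A", "UP"))), "at least 2")

  # brute force over random small instances
  set.seed(43)
  for (i in 1:300) {
    n_lists <- sample(2:4, 1)
    lists <- lapply(seq_len(n_lists), function(j) {
      p <- sample(LETTERS[1:8], sample(1:6, 1))
      mk(p, sample(c("UP", "DOWN"), length(p), replace = TRUE))
    })
    got <- intersect_deps(lists)
    want_up <- character(0); want_down <- character(0)
    for (p in LETTERS[1:8]) {
      dirs <- vapply(lists, function(l)
        if (p %in% l$protein) l$direction[l$protein == p] else NA_character_,
        character(1))
      if (!anyNA(dirs) && all(dirs == "UP")) want_up <- c(want_up, p)
      if (!anyNA(dirs) && all(dirs == "DOWN")) want_down <- c(want_down, p)
    }
    expect_identical(got$up, sort(want_up))
    expect_identical(got$down, sort(want_down))
  }
})

test_that("zscore_matrix standardizes rows and flags degenerate ones", {
  areas <- rbind(A = c(1, 2, 3), B = c(5, 5, 5), C = c(1, NA, NA))
  qm <- qm_from_matrix(areas, days = c(7L, 14L, 21L), eyes = rep("OD", 3))
  z <- zscore_matrix(qm)
  expect_equal(unname(z["A", ]), c(-1, 0, 1))
  expect_equal(unname(z["B", ]), c(0, 0, 0))
  expect_equal(attr(z, "zero_variance"), "B")
  expect_equal(attr(z, "insufficient"), "C")
  expect_true(all(is.na(z["C", ])))
  expect_error(zscore_matrix(qm, "nope"), "not in matrix")

  # random rows match the direct formula; mean 0, sd 1
  set.seed(44)
  m <- matrix(rnorm(80, 20, 4), nrow = 8,
              dimnames = list(paste0("P", 1:8), NULL))
  qm2 <- qm_from_matrix(m, days = rep(c(7L, 14L), 5),
                        eyes = rep(c("OD", "OS"), each = 5))
  z2 <- zscore_matrix(qm2)
  want <- t(apply(m, 1, function(r) (r - mean(r)) / stats::sd(r)))
  dimnames(want) <- dimnames(z2)
  expect_equal(unclass(z2), want, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(abs(rowMeans(z2)) < 1e-9))
  expect_true(all(abs(apply(z2, 1, stats::sd) - 1) < 1e-9))
})
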