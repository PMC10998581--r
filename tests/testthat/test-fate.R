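two_two_labels <- c("TYPE1", "TYPE1", "TYPE17", "TYPE17")

test_that("the exact null of two 2-clone clonotypes is {0: 1/3, 2: 2/3}", {
  pmf <- enumerate_null(c(2, 2), two_two_labels)
  expect_equal(pmf$prob[pmf$value == 0], 1 / 3, tolerance = 1e-12)
  expect_equal(pmf$prob[pmf$value == 2], 2 / 3, tolerance = 1e-12)
  expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
  # expected mixed-clonotype count 4/3
  expect_equal(sum(pmf$value * pmf$prob), 4 / 3, tolerance = 1e-12)
})

test_that("one 2-cell clonotype among singletons mixes with probability 2/3", {
  pmf <- enumerate_null(c(2, 1, 1), two_two_labels)
  expect_equal(sum(pmf$value * pmf$prob), 2 / 3, tolerance = 1e-12)
})

test_that("homogeneous labels give a point mass at zero", {
  pmf <- enumerate_null(c(3, 2), rep("TYPE17", 5))
  expect_equal(pmf$prob[pmf$value == 0], 1)
})

test_that("the DP enumeration agrees with exhaustive permutation on random structures", {
  set.seed(21)
  for (i in 1:8) {
    k <- sample(2:4, 1)
    sizes <- sample(1:3, k, replace = TRUE)
    labels <- sample(c("TYPE1", "TYPE17", "CYCLING"), sum(sizes),
                     replace = TRUE)
    exact <- enumerate_null(sizes, labels)
    brute <- brute_force_mixed_pmf(sizes, labels)
    merged <- merge(exact, brute, by = "value", all = TRUE)
    merged[is.na(merged)] <- 0
    expect_equal(merged$prob.x, merged$prob.y, tolerance = 1e-10)
  }
})

test_that("enumeration refuses structures beyond the placement limit", {
  expect_error(enumerate_null(rep(2, 15), rep(c("TYPE1", "TYPE17"), 15),
                              limit = 1e4),
               "Monte-Carlo")
})

test_that("the clone-label shuffle keeps pooled labels and reports the low tail", {
  ct <- make_clonotype_structure(c(2, 2), c("TYPE1", "TYPE17",
                                            "TYPE1", "TYPE17"))
  res <- mixed_multiclone_test(ct, n_iter = 3000, seed = 5, validate = TRUE)
  expect_s3_class(res, "clonofate_shuffle")
  expect_equal(res$observed_statistic, 2L)
  # Monte-Carlo mean close to the exact 4/3
  expect_equal(mean(res$null_samples), 4 / 3,
               tolerance = 3 * sqrt(8 / 9 / 3000) / (4 / 3))
  # empirical p follows the (r+1)/(n+1) convention
  r <- sum(res$null_samples <= res$observed_statistic)
  expect_equal(res$empirical_p, (r + 1) / (res$n_iter + 1))
})

test_that("clonotypes with impure clones contribute only their pure clones", {
  ct <- make_clonotype_structure(c(3, 2), c("TYPE1", "TYPE17", "TYPE1",
                                            "TYPE17", "TYPE17"))
  ct$clone_annotations[[1]][2] <- "TYPE1_TYPE17"
  ct$clone_annotations[[2]][1] <- "OTHER"
  # group 1 keeps 2 pure clones, group 2 only 1 -> 1 eligible clonotype
  expect_error(mixed_multiclone_test(ct), "fewer than 2")
})

test_that("an all-TYPE17 multi-clone table is degenerate with p = 1", {
  ct <- make_clonotype_structure(c(2, 2), rep("TYPE17", 4))
  res <- mixed_multiclone_test(ct, n_iter = 50, seed = 1)
  expect_true(res$degenerate)
  expect_equal(res$observed_statistic, 0L)
  expect_true(all(res$null_samples == 0))
  expect_equal(res$empirical_p, 1)
})

test_that("the cell-label shuffle reproduces the exact mixing mean", {
  set.seed(2)
  cells <- make_cell_structure(c(2, 1, 1), two_two_labels)
  res <- post_proliferation_test(cells, n_iter = 3000, seed = 9,
                                 validate = TRUE)
  expect_equal(mean(res$null_samples), 2 / 3,
               tolerance = 3 * sqrt(2 / 9 / 3000) / (2 / 3))
})

test_that("singleton-only clonotype structures are flagged degenerate", {
  set.seed(3)
  cells <- make_cell_structure(c(1, 1, 1), c("TYPE1", "TYPE17", "TYPE17"))
  expect_warning(res <- post_proliferation_test(cells, n_iter = 20, seed = 1),
                 "no multi-cell")
  expect_equal(res$observed_statistic, 0L)
  expect_true(all(res$null_samples == 0))
})

test_that("shuffle results are reproducible from the seed", {
  ct <- make_clonotype_structure(c(2, 2, 3), rep(c("TYPE1", "TYPE17"),
                                                 c(3, 4)))
  a <- mixed_multiclone_test(ct, n_iter = 200, seed = 77)
  b <- mixed_multiclone_test(ct, n_iter = 200, seed = 77)
  expect_identical(a$null_samples, b$null_samples)
  expect_identical(a$empirical_p, b$empirical_p)
})

fig_shared <- data.frame(
  key = sprintf("k%02d", 1:19),
  annotation_a = rep(c("TYPE1", "TYPE17"), c(9, 10)),
  annotation_b = c(rep("TYPE1", 1), rep("TYPE17", 8),
                   rep("TYPE17", 5), rep("TYPE1", 5)),
  stringsAsFactors = FALSE)

test_that("cross-dataset concordance counts concordant and discordant pairs", {
  conc <- cross_dataset_concordance(fig_shared)
  expect_equal(conc$n_shared, 19L)
  expect_equal(conc$n_concordant, 6L)
  expect_equal(conc$n_discordant, 13L)
  expect_equal(sum(conc$table), 19)
  # identical annotations -> zero discordant; flipped -> zero concordant
  same <- fig_shared; same$annotation_b <- same$annotation_a
  expect_equal(cross_dataset_concordance(same)$n_discordant, 0L)
  flip <- fig_shared
  flip$annotation_b <- ifelse(flip$annotation_a == "TYPE1", "TYPE17", "TYPE1")
  expect_equal(cross_dataset_concordance(flip)$n_concordant, 0L)
})

test_that("mixed-annotation entries are excluded from concordance with warning", {
  sh <- fig_shared
  sh$annotation_b[1] <- "TYPE1_TYPE17"
  expect_warning(conc <- cross_dataset_concordance(sh), "excluding 1")
  expect_equal(conc$n_shared, 18L)
})

test_that("binomial resampling matches the closed-form expected discordance", {
  # margins 9/10 vs 6/13 over 19: E[discordant] = (9*13 + 10*6)/19
  res <- cross_dataset_test(fig_shared, n_iter = 20000, seed = 3,
                            mechanism = "resample_binomial")
  expect_equal(res$observed_statistic, 13L)
  expected <- (9 * 13 + 10 * 6) / 19
  se <- sqrt(19 * 0.25) / sqrt(20000)   # generous bound on the MC error
  expect_equal(mean(res$null_samples), expected, tolerance = 4 * se / expected)
})

test_that("fixed-margin permutation only reaches odd discordance values", {
  res <- cross_dataset_test(fig_shared, n_iter = 2000, seed = 4,
                            mechanism = "permute_within_datasets")
  expect_true(all(res$null_samples %% 2 == 1))
  expect_true(all(res$null_samples >= 3 & res$null_samples <= 15))
})

test_that("mixed clones are counted directly", {
  cells <- rbind(
    cell_row("m1", subset = "TYPE1", b_nt = "TGTGCCTTT"),
    cell_row("m2", subset = "TYPE17", b_nt = "TGTGCCTTT"),
    cell_row("p1", subset = "TYPE1", b_nt = "TGTCCCTTT"),
    cell_row("p2", subset = "TYPE1", b_nt = "TGTCCCTTT"))
  clones <- assign_clones(cells)
  expect_equal(count_mixed_clones(clones), 1L)
  pure <- assign_clones(cells[3:4, ])
  expect_equal(count_mixed_clones(pure), 0L)
})
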