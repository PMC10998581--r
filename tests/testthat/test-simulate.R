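test_that("the full bundle is seed-deterministic", {
  a <- simulate_development(small_sim_config(seed = 99))
  b <- simulate_development(small_sim_config(seed = 99))
  expect_identical(a$chains, b$chains)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("precursor-level commitment forbids mixed clones", {
  for (s in 1:3) {
    sim <- simulate_development(small_sim_config(seed = s,
                                                 scenario = "pre_commitment"))
    clones <- assign_clones(sim_cells(sim))
    expect_equal(count_mixed_clones(clones), 0L)
  }
})

test_that("stochastic two-cell clones mix at rate 2p(1-p)", {
  # with a single division round after commitment suppressed
  # (round-2 means of 1), sampled cells within a clone commit i.i.d.;
  # a clone with exactly 2 committed cells is mixed w.p. 1/2 at p = 1/2
  mixed <- 0L; total <- 0L
  for (s in 1:6) {
    cfg <- simulation_config(n_precursors = 300, n_animals = 1,
                             round1_mean = 4, round2_mean_type1 = 1,
                             round2_mean_type17 = 1,
                             sampling_fraction = 0.5,
                             stage_label_fraction = 0,
                             compute_pgen = FALSE, seed = 1000 + s)
    clones <- assign_clones(sim_cells(simulate_development(cfg)))
    two <- clones[clones$size == 2, ]
    total <- total + nrow(two)
    mixed <- mixed + sum(two$subset_annotation == "TYPE1_TYPE17")
  }
  expect_gt(total, 250)
  p <- 0.5
  expect_lt(abs(mixed / total - 2 * p * (1 - p)),
            3 * sqrt(0.5 * 0.5 / total))
})

test_that("expected sampled-cell counts follow the branching means", {
  # E[cells] = n_prec * m1 * m2 * sampling
  reps <- vapply(1:8, function(s) {
    cfg <- simulation_config(n_precursors = 200, n_animals = 1,
                             round1_mean = 2, round2_mean_type1 = 3,
                             round2_mean_type17 = 3, max_offspring = 50,
                             sampling_fraction = 0.2,
                             compute_pgen = FALSE, seed = 2000 + s)
    nrow(simulate_development(cfg)$meta)
  }, numeric(1))
  expected <- 200 * 2 * 3 * 0.2
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected), 4 * se)
})

test_that("stage labels replace the configured fraction of fates", {
  sim <- simulate_development(small_sim_config(seed = 5))
  frac <- mean(sim$meta$subset_label %in%
                 c("IMMATURE", "INTERMEDIATE", "CYCLING"))
  n <- nrow(sim$meta)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("instructed commitment follows the hydropathy logistic per precursor", {
  cfg <- small_sim_config(seed = 31, scenario = "instructed")
  sim <- simulate_development(cfg)
  truth <- sim$truth
  prec <- truth$precursors
  p <- clonofate:::.instruct_prob(cfg, prec$cdr3b_aa)
  fates <- merge(truth$cells, prec[c("precursor_id", "cdr3b_aa")],
                 by = "precursor_id")
  # strongly instructed precursors should almost never produce the
  # opposite fate
  hard17 <- fates$precursor_id %in% prec$precursor_id[p > 0.99]
  expect_gt(sum(hard17), 50)
  expect_gt(mean(fates$fate[hard17] == "TYPE17"), 0.95)
})

test_that("paired datasets share amino-acid clonotypes but no nucleotide junctions", {
  cfg <- simulation_config(n_precursors = 350, n_animals = 2,
                           compute_pgen = FALSE, seed = 8)
  pair <- make_paired_datasets(cfg)
  expect_gt(length(pair$shared_keys), 5)
  # shared keys really occur in both clonotype tables
  ct_a <- assign_clonotypes(assign_clones(sim_cells(pair$dataset_a)))
  ct_b <- assign_clonotypes(assign_clones(sim_cells(pair$dataset_b)))
  key <- function(ct) clonofate:::clonotype_key_of(
    ct$va, ct$ja, ct$cdr3a_aa, ct$vb, ct$jb, ct$cdr3b_aa)
  expect_true(all(pair$shared_keys %in% intersect(key(ct_a), key(ct_b))))
  # synonymous recoding keeps nucleotide junctions private to a dataset
  expect_length(intersect(pair$dataset_a$chains$cdr3_nt[
    pair$dataset_a$chains$locus == "TRB"],
    pair$dataset_b$chains$cdr3_nt[pair$dataset_b$chains$locus == "TRB"]), 0)
})

test_that("simulated chains feed the IO module losslessly", {
  sim <- simulate_development(small_sim_config(seed = 17))
  cells <- sim_cells(sim)
  qc <- attr(cells, "qc")
  expect_equal(qc$count[qc$reason == "kept"], nrow(sim$meta))
  expect_equal(nrow(cells), nrow(sim$meta))
  # translations recorded in the chain table are consistent
  expect_identical(translate_dna(cells$cdr3b_nt), cells$cdr3b_aa)
})

test_that("degenerate sampling configurations error out", {
  expect_error(simulation_config(sampling_fraction = 0), "sampling_fraction")
})

test_that("written bundles contain the three artifacts", {
  dir <- withr::local_tempdir()
  sim <- simulate_development(small_sim_config(seed = 3))
  write_sim(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("chains.airr.tsv", "meta.tsv",
                                               "truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$config$scenario, "stochastic")
})
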