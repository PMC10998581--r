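## Degenerate model: one V, one J, no deletions or insertions.
degenerate_model <- function() {
  recomb_model(v_segments = c(V = "TGTGCC"), j_segments = c(J = "TTT"))
}

## Two-outcome model: insertion length 0 or 3 with probability 1/2 each.
ins_model <- function() {
  recomb_model(v_segments = c(V = "TGTGCC"), j_segments = c(J = "TTT"),
               ins_len = c(0.5, 0, 0, 0.5))
}

test_that("the degenerate model always emits CAF with Pgen 1", {
  m <- degenerate_model()
  set.seed(1)
  draws <- sample_tcr(m, 20)
  expect_true(all(draws$nt == "TGTGCCTTT"))
  expect_true(all(draws$aa == "CAF"))
  expect_equal(pgen_aa(m, "CAF"), 1)
  expect_equal(pgen_aa(m, "CAGF"), 0)
})

test_that("hand-enumerated Pgens for the insertion model are exact", {
  m <- ins_model()
  expect_equal(pgen_aa(m, "CAF"), 1 / 2)
  # 4 of the 64 uniform codons encode glycine
  expect_equal(pgen_aa(m, "CAGF"), 1 / 2 * 4 / 64)
  expect_equal(pgen_aa(m, "CAWF"), 1 / 2 * 1 / 64)
  # infeasible lengths have probability zero
  expect_equal(pgen_aa(m, "CAGGF"), 0)
})

test_that("in-frame Pgens sum to 1 over all achievable translations", {
  m <- ins_model()
  # brute-force achievable aa space: enumerate every insertion realization
  nts <- c("TGTGCCTTT",
           paste0("TGTGCC",
                  apply(expand.grid(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T")), 1, paste,
                        collapse = ""),
                  "TTT"))
  aa <- unique(as.character(Biostrings::translate(Biostrings::DNAStringSet(nts))))
  total <- sum(vapply(aa, pgen_aa, numeric(1), model = m))
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("productive conditioning renormalizes over stop-free sequences", {
  m <- ins_model()
  # P(no stop | insertion) = 61/64, so Z = 1/2 + 1/2 * 61/64 = 125/128
  expect_equal(pgen_aa(m, "CAF", conditioning = "productive"), 64 / 125)
  expect_equal(pgen_aa(m, "CA*F", conditioning = "productive"), 0)
  expect_equal(pgen_aa(m, "CA*F"), 1 / 2 * 3 / 64)  # in-frame conditioning
})

test_that("sampled aa frequencies match exact Pgens within 3 sigma", {
  m <- ins_model()
  set.seed(2)
  n <- 20000
  draws <- sample_tcr(m, n)
  for (s in c("CAF", "CAGF", "CALF")) {
    p <- pgen_aa(m, s)
    expect_lt(abs(mean(draws$aa == s) - p), 3 * sqrt(p * (1 - p) / n) + 1e-9)
  }
})

test_that("segment usage matches choice probabilities within 3 sigma", {
  m <- recomb_model(v_segments = c(V1 = "TGTGCC", V2 = "TGTTCC"),
                    j_segments = c(J = "TTT"),
                    v_probs = c(0.3, 0.7))
  set.seed(3)
  n <- 10000
  draws <- sample_tcr(m, n)
  f <- mean(draws$v_name == "V1")
  expect_lt(abs(f - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("event records replay to the emitted nucleotide sequence", {
  m <- default_beta_model()
  set.seed(4)
  draws <- sample_tcr(m, 300, productive_only = TRUE)
  expect_identical(replay_event(m, draws), draws$nt)
  expect_false(any(grepl("*", draws$aa, fixed = TRUE)))
  rej <- attr(draws, "n_rejected")
  expect_gte(rej[["out_of_frame"]], 0)
})

test_that("group Pgen comparisons use the exact rank-sum test", {
  res <- compare_pgen_groups(10^c(1, 2, 3, 10, 20, 30),
                             rep(c("low", "high"), each = 3))
  row <- res$pairwise
  expect_equal(nrow(row), 1L)
  expect_equal(min(row$W, row$n1 * row$n2 - row$W), 0)
  oracle <- stats::wilcox.test(c(1, 2, 3), c(10, 20, 30))$p.value
  expect_equal(row$p, oracle)
  expect_error(suppressWarnings(compare_pgen_groups(10^c(1, 2), c("a", "b"))),
               "at least 2")
})

test_that("identical groups rarely reach significance", {
  set.seed(6)
  hits <- vapply(1:40, function(i) {
    x <- 10^stats::rnorm(12)
    compare_pgen_groups(x, rep(c("a", "b"), 6))$pairwise$p < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.2)
})

test_that("the toy Pgen provider matches pgen_aa and tables round-trip", {
  ct <- data.frame(clonotype_id = c("c1", "c2"),
                   cdr3a_aa = c("CAF", "CAF"),
                   cdr3b_aa = c("CAF", "CAGF"),
                   stringsAsFactors = FALSE)
  prov <- pgen_provider("toy_model", alpha_model = ins_model(),
                        beta_model = ins_model())
  rec <- prov(ct)
  expect_equal(rec$pgen_alpha, c(0.5, 0.5))
  expect_equal(rec$pgen_beta, c(0.5, 1 / 32))
  expect_equal(rec$pgen_joint, rec$pgen_alpha * rec$pgen_beta)

  tab <- data.frame(cdr3a_aa = "CAF", cdr3b_aa = "CAF",
                    pgen_alpha = 1 / 3, pgen_beta = exp(-20),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pgen_table(tab, path)
  back <- read_pgen_table(path)
  expect_identical(back$pgen_alpha, tab$pgen_alpha)
  expect_identical(back$pgen_beta, tab$pgen_beta)
  ext <- pgen_provider("external_table", table = back)
  expect_warning(rec2 <- ext(ct), "skipping 1")
  expect_equal(nrow(rec2), 1L)
  expect_equal(attr(rec2, "n_skipped"), 1L)
})

test_that("invalid model specifications are rejected", {
  expect_error(recomb_model(c(V = "TGTGCC"), c(J = "TTT"),
                            v_probs = c(0.5)), "sum to 1")
  expect_error(recomb_model(c(V = "TGTGCC"), c(J = "TTT"),
                            ins_len = c(0.5, 0.4)), "sum to 1")
  expect_error(recomb_model(c(V = "TGUGCC"), c(J = "TTT")), "A, C, G, T")
  expect_error(recomb_model(c(V = "TGTGCC"), c(J = "TT"),
                            j_del = c(0.5, 0.3, 0.2)), "shorter")
})
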