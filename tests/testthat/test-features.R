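make_ct <- function(seqs, ann = NULL) {
  data.frame(clonotype_id = sprintf("v%03d", seq_along(seqs)),
             cdr3a_aa = "CAVRDSNYQLIW", cdr3b_aa = seqs,
             subset_annotation = ann %||% rep("TYPE1", length(seqs)),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("single-substitution neighbours are connected, others are not", {
  g <- build_similarity_graph(make_ct(c("CASSA", "CASSG", "CATTA")))
  expect_equal(nrow(g$edges), 1L)
  expect_setequal(unlist(g$edges[1, ]), c("v001", "v002"))
  expect_equal(lengths(g$components), c(2L, 1L))
})

test_that("identical sequences are distance 0, not edges", {
  g <- build_similarity_graph(make_ct(c("CASSA", "CASSA")))
  expect_equal(nrow(g$edges), 0L)
})

test_that("the hashed edge search equals the all-pairs oracle", {
  set.seed(31)
  # templates plus single/double mutants so Hamming-1 pairs actually occur
  templates <- rand_aa(40, 14)
  mutants <- unlist(lapply(templates, function(s) {
    vapply(1:4, function(i) {
      p <- sample(14, sample(1:2, 1))
      ch <- strsplit(s, "")[[1]]; ch[p] <- sample(AA20, length(p), TRUE)
      paste(ch, collapse = "")
    }, character(1))
  }))
  seqs <- unique(c(templates, mutants, rand_aa(40, 13)))
  g <- build_similarity_graph(make_ct(seqs))
  oracle <- brute_force_edges(seqs)
  canon <- function(i, j) paste(pmin(i, j), pmax(i, j))
  got <- canon(match(g$edges$from, sprintf("v%03d", seq_along(seqs))),
               match(g$edges$to, sprintf("v%03d", seq_along(seqs))))
  want <- if (is.null(oracle)) character(0) else canon(oracle[, 1], oracle[, 2])
  expect_setequal(got, want)
  expect_gt(length(want), 0)
})

test_that("per-component subset composition is reported", {
  g <- build_similarity_graph(make_ct(c("CASSA", "CASSG", "CATTA"),
                                      c("TYPE1", "TYPE17", "TYPE1")))
  expect_equal(g$composition$n_type1[1], 1L)
  expect_equal(g$composition$n_type17[1], 1L)
})

test_that("consensus breaks ties alphabetically and PFM rows sum to 1", {
  pfm <- cluster_profile(c("CASSA", "CASSG"))
  expect_equal(attr(pfm, "consensus"), "CASSA")
  expect_true(all(abs(rowSums(pfm) - 1) < 1e-12))
  single <- cluster_profile("CAVR")
  expect_equal(attr(single, "consensus"), "CAVR")
  expect_true(all(single %in% c(0, 1)))
  expect_error(cluster_profile(character(0)), "empty")
  expect_error(cluster_profile(c("CA", "CAS")), "equal length")
})

test_that("physicochemical profiles are center-aligned hand-checkably", {
  s <- aa_scales()$hydrophobicity
  prof <- physchem_profile(list(g = "CAS"), property = "hydrophobicity",
                           min_support = 1)
  expect_equal(prof$offset, -1:1)
  expect_equal(prof$mean, unname(s[c("C", "A", "S")]))
  both <- physchem_profile(list(g = c("CAS", "CAASS")),
                           property = "hydrophobicity", min_support = 1)
  expect_equal(both$mean[both$offset == 0], unname((s["A"] + s["A"]) / 2))
  expect_equal(both$mean[both$offset == -2], unname(s["C"]))
  expect_equal(both$n[both$offset == -2], 1L)
  expect_error(physchem_profile(list(g = "CAX1")), "outside alphabet")
})

test_that("a group profile equals a direct per-offset average", {
  set.seed(5)
  seqs <- rand_aa(20, 10:14)
  scale <- aa_scales()$basicity
  grp <- physchem_profile(list(g = seqs), property = "basicity",
                          min_support = 1)
  # independent oracle: accumulate (offset, value) pairs by hand
  acc <- list()
  for (q in seqs) {
    ch <- strsplit(q, "")[[1]]
    off <- seq_along(ch) - 1 - nchar(q) %/% 2
    for (k in seq_along(ch))
      acc[[as.character(off[k])]] <- c(acc[[as.character(off[k])]],
                                       scale[[ch[k]]])
  }
  for (r in seq_len(nrow(grp))) {
    vals <- acc[[as.character(grp$offset[r])]]
    expect_equal(grp$mean[r], mean(vals), tolerance = 1e-12)
    expect_equal(grp$n[r], length(vals))
  }
})

test_that("min_support suppresses sparse offsets", {
  prof <- physchem_profile(list(g = c("CAS", "CAASS")),
                           property = "hydrophobicity", min_support = 2)
  expect_false(any(prof$offset %in% c(-2, 2)))
})

test_that("the short-CDR3 fraction uses the inclusive 10-14 window", {
  ct <- make_ct(c(strrep("A", 10), strrep("G", 14), strrep("S", 15)))
  rs <- repertoire_summaries(ct)
  expect_equal(rs$short_fraction$short_fraction, 2 / 3)
  expect_equal(sum(rs$by_group$TYPE1$cdr3a_freq), 1)
})

test_that("summaries are invariant to input order", {
  set.seed(8)
  ct <- make_ct(rand_aa(30, 10:16),
                sample(c("TYPE1", "TYPE17"), 30, replace = TRUE))
  a <- repertoire_summaries(ct)
  b <- repertoire_summaries(ct[sample(nrow(ct)), ])
  expect_equal(a$short_fraction, b$short_fraction)
  expect_equal(a$by_group$TYPE1$vb_usage, b$by_group$TYPE1$vb_usage)
})

test_that("an untrained weight vector maps to an all-zero enrichment grid", {
  spec <- encoding_spec(6)
  model <- structure(list(
    weights = stats::setNames(numeric(length(spec$feature_ids)),
                              spec$feature_ids),
    intercept = 0, l1 = 1e-4, l2 = 1e-4, spec = spec,
    train_pos = "X", train_neg = "Y"), class = "clonofate_classifier")
  enr <- positional_enrichment(model)
  expect_true(all(enr$forward == 0) && all(enr$reverse == 0))
  expect_equal(dim(enr$forward), c(6L, 20L))
  expect_error(positional_enrichment(list()), "trained")
})

test_that("selection at a fixed position yields a positive enrichment weight", {
  # target repertoire enriched for G at forward position 4 relative to its
  # own background generator; the trained weight should recover the sign
  set.seed(77)
  hits <- 0
  for (rep in 1:10) {
    bg <- rand_aa(400, 12)
    tg <- rand_aa(400, 12)
    sel <- runif(400) < 0.8
    substr(tg[sel], 5, 5) <- "G"   # forward position index 4 (0-based)
    model <- train_classifier(unique(tg), unique(bg),
                              spec = encoding_spec(12),
                              n_train_per_class = 300, seed = rep)
    enr <- positional_enrichment(model)
    if (enr$forward["4", "G"] > 0) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
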