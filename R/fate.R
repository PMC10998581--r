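## Permutation null models for clonal fate sharing, their exact
## enumeration oracle, and the cross-dataset concordance analysis.

new_shuffle_result <- function(statistic_name, observed, null_samples,
                               n_iter, seed, degenerate = FALSE) {
  null_samples <- as.integer(null_samples)
  r <- sum(null_samples <= observed)
  structure(list(
    statistic_name = statistic_name,
    observed_statistic = as.integer(observed),
    null_samples = null_samples,
    null_median = stats::median(null_samples),
    null_ci = stats::quantile(null_samples, c(0.025, 0.975), names = FALSE),
    empirical_p = (r + 1) / (n_iter + 1),
    n_iter = as.integer(n_iter),
    seed = seed,
    degenerate = degenerate),
    class = "clonofate_shuffle")
}

#' @export
print.clonofate_shuffle <- function(x, ...) {
  cat("Permutation null model:", x$statistic_name, "\n")
  cat(sprintf("  observed: %d\n  null median: %g (95%% CI %g-%g)\n",
              x$observed_statistic, x$null_median,
              x$null_ci[1], x$null_ci[2]))
  cat(sprintf("  empirical p (low tail): %.4g  [n_iter = %d, seed = %s]\n",
              x$empirical_p, x$n_iter, format(x$seed)))
  if (x$degenerate) cat("  note: degenerate null (all labels identical)\n")
  invisible(x)
}

#' Write a shuffle result as JSON plus raw null samples
#'
#' @param result A `clonofate_shuffle` object.
#' @param path Output JSON path; the raw null samples go to
#'   `<path>.null.tsv` as a one-column TSV.
#' @param extra Optional named list prepended to the JSON record (e.g. a
#'   run-config hash).
#' @export
write_shuffle_result <- function(result, path, extra = NULL) {
  out <- c(extra,
           result[c("statistic_name", "observed_statistic", "null_median",
                    "null_ci", "empirical_p", "n_iter", "seed",
                    "degenerate")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  utils::write.table(
    data.frame(null_sample = result$null_samples), paste0(path, ".null.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Shared engine: permute pooled labels across slots grouped by `grp`,
## counting groups containing both a TYPE1 and a TYPE17 member.
count_mixed_groups <- function(labels, grp) {
  t1 <- rowsum((labels == "TYPE1") + 0L, grp)
  t17 <- rowsum((labels == "TYPE17") + 0L, grp)
  sum(t1 > 0 & t17 > 0)
}

shuffle_mixed_groups <- function(labels, grp, n_iter, validate = FALSE) {
  ref <- sort(labels)
  vapply(seq_len(n_iter), function(i) {
    perm <- sample(labels)
    if (validate) stopifnot(identical(sort(perm), ref))
    count_mixed_groups(perm, grp)
  }, numeric(1))
}

#' Clone-label shuffle within multi-clone clonotypes
#'
#' Tests whether sublineage commitment is instructed by the TCR. Distinct
#' clones within one clonotype are biological replicates of the same
#' receptor: only clones annotated purely TYPE1 or TYPE17 are considered,
#' the test restricts to clonotypes containing at least two such clones,
#' pools their clone labels, and permutes them across clone slots keeping
#' clonotype membership fixed. The statistic is the number of "mixed" clonotypes
#' containing both a TYPE1 and a TYPE17 clone; TCR-instructed commitment
#' predicts fewer mixed clonotypes than the null (low tail).
#'
#' @param clonotypes Clonotype table from [assign_clonotypes()].
#' @param n_iter Number of shuffles (default 1000).
#' @param seed RNG seed recorded in the result.
#' @param validate If `TRUE`, assert at every iteration that the permuted
#'   label multiset is unchanged.
#' @return A `clonofate_shuffle` object.
#' @export
mixed_multiclone_test <- function(clonotypes, n_iter = 1000, seed = 1,
                                  validate = FALSE) {
  ann <- lapply(clonotypes$clone_annotations,
                function(a) a[a %in% c("TYPE1", "TYPE17")])
  eligible <- lengths(ann) >= 2
  if (sum(eligible) < 2)
    stop("fewer than 2 eligible multi-clone clonotypes")
  ann <- ann[eligible]
  labels <- unlist(ann, use.names = FALSE)
  grp <- rep(seq_along(ann), lengths(ann))
  observed <- count_mixed_groups(labels, grp)
  degenerate <- length(unique(labels)) == 1L
  set.seed(seed)
  null_samples <- shuffle_mixed_groups(labels, grp, n_iter, validate)
  res <- new_shuffle_result("mixed_multiclone_clonotypes", observed,
                            null_samples, n_iter, seed, degenerate)
  res$n_eligible <- sum(eligible)
  res
}

#' Cell-label shuffle: commitment after proliferation?
#'
#' Simulates the scenario in which fate choice happens after all rounds of
#' proliferation: each cell's subset label is independent of its
#' clonotype. The full cell-label column is permuted (preserving the total
#' number of cells, the subset ratio, and the clonotype size distribution)
#' and the number of TYPE1_TYPE17 clonotypes is recomputed each
#' iteration. Observing far fewer mixed clonotypes than this null implies
#' proliferation after commitment (low tail).
#'
#' @param cells Cell table from [filter_cells()].
#' @inheritParams mixed_multiclone_test
#' @return A `clonofate_shuffle` object.
#' @export
post_proliferation_test <- function(cells, n_iter = 1000, seed = 1,
                                    validate = FALSE) {
  key <- clonotype_key_of(cells$va, cells$ja, cells$cdr3a_aa,
                          cells$vb, cells$jb, cells$cdr3b_aa)
  grp <- match(key, unique(key))
  labels <- cells$subset_label
  observed <- count_mixed_groups(labels, grp)
  degenerate <- max(tabulate(grp)) == 1L
  if (degenerate)
    warning("no multi-cell clonotypes: null is identically the observed value")
  set.seed(seed)
  null_samples <- shuffle_mixed_groups(labels, grp, n_iter, validate)
  new_shuffle_result("mixed_clonotypes_cell_shuffle", observed,
                     null_samples, n_iter, seed, degenerate)
}

#' Count clones containing both TYPE1 and TYPE17 cells
#'
#' A nonzero count is direct evidence of proliferation before commitment:
#' if precursors committed before any division, every clone would be pure.
#'
#' @param clones Clone table from [assign_clones()].
#' @return Integer count of clones annotated TYPE1_TYPE17.
#' @export
count_mixed_clones <- function(clones) {
  sum(clones$subset_annotation == "TYPE1_TYPE17")
}

#' Concordance of shared clonotypes across two datasets
#'
#' @param shared Data frame from [shared_clonotypes()]; entries not
#'   annotated TYPE1/TYPE17 on both sides are excluded with a warning.
#' @return A `clonofate_concordance` list: `n_shared`, `n_concordant`,
#'   `n_discordant`, and the 2x2 `table` of side-A x side-B annotations.
#' @export
cross_dataset_concordance <- function(shared) {
  ok <- shared$annotation_a %in% c("TYPE1", "TYPE17") &
    shared$annotation_b %in% c("TYPE1", "TYPE17")
  if (any(!ok)) {
    warning("excluding ", sum(!ok), " shared clonotype(s) not annotated ",
            "TYPE1/TYPE17 on both sides")
    shared <- shared[ok, , drop = FALSE]
  }
  if (nrow(shared) == 0L) warning("no shared clonotypes")
  tab <- table(factor(shared$annotation_a, levels = c("TYPE1", "TYPE17")),
               factor(shared$annotation_b, levels = c("TYPE1", "TYPE17")),
               dnn = c("dataset_a", "dataset_b"))
  structure(list(
    n_shared = nrow(shared),
    n_concordant = sum(shared$annotation_a == shared$annotation_b),
    n_discordant = sum(shared$annotation_a != shared$annotation_b),
    table = tab), class = "clonofate_concordance")
}

#' @export
print.clonofate_concordance <- function(x, ...) {
  cat("Shared clonotypes:", x$n_shared,
      "| concordant:", x$n_concordant,
      "| discordant:", x$n_discordant, "\n")
  print(x$table)
  invisible(x)
}

#' Label-shuffle null for cross-dataset concordance
#'
#' Under stochastic, TCR-independent fate choice, the subset identity of a
#' clonotype in one dataset carries no information about its identity in
#' the other. The default mechanism (`resample_binomial`) redraws each
#' side's label independently with that dataset's observed TYPE17
#' frequency; `permute_within_datasets` instead permutes each side's label
#' vector keeping the counts fixed (note that for fixed margins the
#' discordance then moves in steps of 2, so its support can miss the
#' observed parity). The statistic is the number of discordant shared
#' clonotypes; instruction predicts fewer than the null (low tail).
#'
#' @param shared Data frame from [shared_clonotypes()].
#' @param mechanism `"resample_binomial"` (default) or
#'   `"permute_within_datasets"`.
#' @inheritParams mixed_multiclone_test
#' @return A `clonofate_shuffle` object.
#' @export
cross_dataset_test <- function(shared, n_iter = 1000, seed = 1,
                               mechanism = c("resample_binomial",
                                             "permute_within_datasets")) {
  mechanism <- match.arg(mechanism)
  ok <- shared$annotation_a %in% c("TYPE1", "TYPE17") &
    shared$annotation_b %in% c("TYPE1", "TYPE17")
  shared <- shared[ok, , drop = FALSE]
  n <- nrow(shared)
  if (n < 2) stop("fewer than 2 annotated shared clonotypes")
  a <- shared$annotation_a
  b <- shared$annotation_b
  observed <- sum(a != b)
  set.seed(seed)
  null_samples <- if (mechanism == "resample_binomial") {
    fa <- mean(a == "TYPE17")
    fb <- mean(b == "TYPE17")
    vapply(seq_len(n_iter), function(i) {
      sum((stats::runif(n) < fa) != (stats::runif(n) < fb))
    }, numeric(1))
  } else {
    vapply(seq_len(n_iter), function(i) sum(a != sample(b)), numeric(1))
  }
  res <- new_shuffle_result(paste0("discordant_shared_clonotypes_", mechanism),
                            observed, null_samples, n_iter, seed)
  res$mechanism <- mechanism
  res
}

#' Exact permutation null for the mixed-group count
#'
#' Exact probability mass function of the number of groups containing both
#' a TYPE1 and a TYPE17 member when a fixed multiset of labels is placed
#' uniformly at random across slots partitioned into groups of given
#' sizes. Serves as the independent oracle validating the Monte-Carlo
#' shuffles of [mixed_multiclone_test()] and [post_proliferation_test()].
#' Computed by dynamic programming over groups with multivariate
#' hypergeometric allocation weights.
#'
#' @param sizes Integer vector of group sizes.
#' @param labels Character vector of labels (length `sum(sizes)`); labels
#'   other than TYPE1/TYPE17 act as inert fillers.
#' @param limit Maximum number of distinct label placements; beyond it the
#'   function errors and advises Monte Carlo.
#' @return Data frame with columns `value` and `prob` (probabilities sum
#'   to 1).
#' @export
#' @examples
#' enumerate_null(c(2, 2), c("TYPE1", "TYPE1", "TYPE17", "TYPE17"))
enumerate_null <- function(sizes, labels, limit = 1e6) {
  sizes <- as.integer(sizes)
  stopifnot(all(sizes >= 1), sum(sizes) == length(labels))
  na <- sum(labels == "TYPE1")
  nb <- sum(labels == "TYPE17")
  no <- length(labels) - na - nb
  n_place <- exp(lgamma(length(labels) + 1) - lgamma(na + 1) -
                   lgamma(nb + 1) - lgamma(no + 1))
  if (n_place > limit)
    stop("number of distinct label placements (", format(n_place),
         ") exceeds limit; use the Monte-Carlo shuffle instead")
  G <- length(sizes)
  # pmf[g][[state]] := P(mixed count = k, remaining labels = state) walk
  state_key <- function(a, b) paste(a, b)
  cur <- new.env(parent = emptyenv())
  assign(state_key(na, nb), c(1, rep(0, G)), envir = cur)
  remaining <- sum(sizes)
  for (s in sizes) {
    nxt <- new.env(parent = emptyenv())
    for (k in ls(cur)) {
      ab <- as.integer(strsplit(k, " ")[[1]])
      a <- ab[1]; b <- ab[2]; o <- remaining - a - b
      pmf <- get(k, envir = cur)
      for (i in 0:min(s, a)) for (j in 0:min(s - i, b)) {
        kk <- s - i - j
        if (kk > o) next
        w <- exp(lchoose(a, i) + lchoose(b, j) + lchoose(o, kk) -
                   lchoose(remaining, s))
        add <- pmf * w
        if (i > 0 && j > 0) add <- c(0, add[-length(add)])  # shift mixed +1
        key2 <- state_key(a - i, b - j)
        prev <- if (exists(key2, envir = nxt)) get(key2, envir = nxt) else
          rep(0, G + 1)
        assign(key2, prev + add, envir = nxt)
      }
    }
    cur <- nxt
    remaining <- remaining - s
  }
  final <- get(state_key(0, 0), envir = cur)
  data.frame(value = 0:G, prob = final)
}
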