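## One-hot positional CDR3b selection classifier (linear logistic model
## with L1+L2 penalty over forward/reverse positional features), ROC
## evaluation and stratified cross-validation.

#' One-hot positional encoding specification
#'
#' Each CDR3 amino-acid sequence is encoded in both the forward direction
#' (positions 0, 1, ...) and the reverse direction (positions -1, -2, ...
#' counted from the C terminus), one binary feature per
#' (direction, position, residue). A length-L sequence activates exactly
#' `min(L, max_depth)` forward and as many reverse features.
#'
#' @param max_depth Maximum encoded depth per direction (default 25).
#' @return An `encoding_spec` list with `max_depth`, `alphabet`, and the
#'   full `feature_ids` vector.
#' @export
encoding_spec <- function(max_depth = 25) {
  stopifnot(max_depth >= 1)
  ids <- c(
    as.vector(outer(paste0("f:", seq_len(max_depth) - 1L), AA_ALPHABET,
                    paste, sep = ":")),
    as.vector(outer(paste0("r:", -seq_len(max_depth)), AA_ALPHABET,
                    paste, sep = ":")))
  structure(list(max_depth = as.integer(max_depth), alphabet = AA_ALPHABET,
                 feature_ids = ids), class = "encoding_spec")
}

#' Encode one CDR3 sequence as its active feature set
#'
#' @param sequence Amino-acid string over the 20-letter alphabet.
#' @param spec An [encoding_spec()].
#' @return Character vector of active feature ids (length
#'   `2 * min(nchar(sequence), max_depth)`).
#' @export
#' @examples
#' encode_cdr3("CA", encoding_spec())
encode_cdr3 <- function(sequence, spec = encoding_spec()) {
  ch <- strsplit(sequence, "")[[1]]
  bad <- setdiff(ch, spec$alphabet)
  if (length(bad))
    stop("invalid residue(s) in sequence ", sequence, ": ",
         paste(bad, collapse = ", "))
  L <- length(ch)
  if (L == 0L) return(character(0))
  d <- min(L, spec$max_depth)
  c(paste0("f:", seq_len(d) - 1L, ":", ch[seq_len(d)]),
    paste0("r:", -seq_len(d), ":", ch[L + 1L - seq_len(d)]))
}

## Sparse design matrix (sequences x features) for a character vector.
encode_matrix <- function(seqs, spec = encoding_spec()) {
  feats <- lapply(seqs, encode_cdr3, spec = spec)
  j <- match(unlist(feats, use.names = FALSE), spec$feature_ids)
  i <- rep(seq_along(seqs), lengths(feats))
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(seqs), length(spec$feature_ids)),
                       dimnames = list(NULL, spec$feature_ids))
}

#' Train the positional selection classifier
#'
#' Deduplicates each class to unique sequences, draws a balanced
#' subsample without replacement (`n_train_per_class` each), and fits a
#' logistic model over the one-hot positional features with combined
#' penalty `l1 * ||w||_1 + l2 * ||w||_2^2` (fit via glmnet's elastic net
#' with `lambda = l1 + 2*l2`, `alpha = l1/lambda`). Deterministic given
#' `seed`.
#'
#' @param pos_sequences,neg_sequences Character vectors of CDR3
#'   amino-acid sequences for the positive/negative class.
#' @param spec An [encoding_spec()].
#' @param l1,l2 Penalty strengths (default `1e-4` each).
#' @param n_train_per_class Balanced subsample size per class (default
#'   300).
#' @param seed RNG seed for the subsample.
#' @return A `clonofate_classifier`: named `weights`, `intercept`,
#'   penalties, the encoding spec, the training sequences, and metadata.
#' @export
train_classifier <- function(pos_sequences, neg_sequences,
                             spec = encoding_spec(), l1 = 1e-4, l2 = 1e-4,
                             n_train_per_class = 300, seed = 1) {
  pos <- unique(pos_sequences)
  neg <- unique(neg_sequences)
  if (length(pos) < n_train_per_class || length(neg) < n_train_per_class)
    stop("each class needs >= ", n_train_per_class, " unique sequences ",
         "(have ", length(pos), " and ", length(neg), "); ",
         "reduce n_train_per_class")
  set.seed(seed)
  pos <- sample(pos, n_train_per_class)
  neg <- sample(neg, n_train_per_class)
  x <- encode_matrix(c(pos, neg), spec)
  y <- rep(c(1, 0), c(length(pos), length(neg)))
  lambda <- l1 + 2 * l2
  alpha <- if (lambda > 0) l1 / lambda else 0
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                        lambda = lambda, standardize = FALSE,
                        maxit = 1e4, thresh = 1e-6)
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  structure(list(
    weights = beta,
    intercept = as.numeric(fit$a0),
    l1 = l1, l2 = l2,
    spec = spec,
    train_pos = pos, train_neg = neg,
    n_per_class = n_train_per_class,
    seed = seed), class = "clonofate_classifier")
}

#' @export
print.clonofate_classifier <- function(x, ...) {
  cat("Positional CDR3 selection classifier\n")
  cat(sprintf("  %d features (depth %d), l1 = %g, l2 = %g\n",
              length(x$weights), x$spec$max_depth, x$l1, x$l2))
  cat(sprintf("  trained on %d + %d unique sequences (seed %s)\n",
              length(x$train_pos), length(x$train_neg), format(x$seed)))
  cat(sprintf("  nonzero weights: %d\n", sum(x$weights != 0)))
  invisible(x)
}

#' Linear scores for new sequences
#'
#' @param object A `clonofate_classifier`.
#' @param sequences Character vector of CDR3 amino-acid sequences.
#' @param ... Unused.
#' @return Numeric vector of linear (logit-scale) scores.
#' @export
predict.clonofate_classifier <- function(object, sequences, ...) {
  x <- encode_matrix(sequences, object$spec)
  as.numeric(x %*% object$weights) + object$intercept
}

## Rank-statistic AUC (Mann-Whitney; ties counted half).
auc_rank <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

## Threshold-sweep ROC curve.
roc_sweep <- function(scores_pos, scores_neg) {
  scores <- c(scores_pos, scores_neg)
  labels <- rep(c(1L, 0L), c(length(scores_pos), length(scores_neg)))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores_pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores_neg >= t), numeric(1))
  auc_trap <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  list(thresholds = thr, tpr = tpr, fpr = fpr, auc_trapezoid = auc_trap)
}

#' Evaluate a trained classifier on held-out sequences
#'
#' Asserts that the test sequences are disjoint from the training
#' sequences, scores them, and computes the ROC by threshold sweep with
#' the AUC as the Mann-Whitney rank statistic (ties counted half); the
#' two AUC computations agree to numerical precision.
#'
#' @param model A `clonofate_classifier`.
#' @param test_pos,test_neg Held-out sequences per class.
#' @return A `clonofate_roc`: `auc`, `thresholds`, `tpr`, `fpr`,
#'   `n_pos`, `n_neg`.
#' @export
evaluate_classifier <- function(model, test_pos, test_neg) {
  test_pos <- unique(test_pos)
  test_neg <- unique(test_neg)
  overlap <- intersect(c(test_pos, test_neg),
                       c(model$train_pos, model$train_neg))
  if (length(overlap))
    stop("test sequences overlap the training set: ",
         paste(utils::head(overlap, 5), collapse = ", "),
         if (length(overlap) > 5) " ...")
  sp <- predict(model, test_pos)
  sn <- predict(model, test_neg)
  sweep <- roc_sweep(sp, sn)
  structure(list(
    auc = auc_rank(sp, sn),
    auc_trapezoid = sweep$auc_trapezoid,
    thresholds = sweep$thresholds, tpr = sweep$tpr, fpr = sweep$fpr,
    n_pos = length(test_pos), n_neg = length(test_neg)),
    class = "clonofate_roc")
}

#' @export
print.clonofate_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (n_pos = %d, n_neg = %d)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Write an ROC curve as TSV
#'
#' @param roc A `clonofate_roc`.
#' @param path Output TSV path.
#' @export
write_roc <- function(roc, path) {
  utils::write.table(
    data.frame(threshold = roc$thresholds, tpr = roc$tpr, fpr = roc$fpr),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stratified k-fold cross-validation
#'
#' Splits each class into k folds (reproducibly from `seed`), trains on
#' k-1 folds with classes balanced to the smaller training class, and
#' evaluates on the held-out fold.
#'
#' @param pos,neg Character vectors of sequences per class.
#' @param k Number of folds (default 5).
#' @param spec An [encoding_spec()].
#' @param l1,l2 Penalty strengths.
#' @param seed RNG seed controlling fold assignment and subsampling.
#' @return A `clonofate_cv` list: `folds` (list of `clonofate_roc`),
#'   `mean_auc`, `k`, `seed`.
#' @export
crossvalidate <- function(pos, neg, k = 5, spec = encoding_spec(),
                          l1 = 1e-4, l2 = 1e-4, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  pos <- unique(pos); neg <- unique(neg)
  if (length(pos) < k || length(neg) < k)
    stop("each class needs at least k = ", k, " unique sequences")
  set.seed(seed)
  fold_pos <- sample(rep(seq_len(k), length.out = length(pos)))
  fold_neg <- sample(rep(seq_len(k), length.out = length(neg)))
  fold_seeds <- sample.int(.Machine$integer.max, k)
  folds <- lapply(seq_len(k), function(f) {
    tr_pos <- pos[fold_pos != f]; tr_neg <- neg[fold_neg != f]
    n_train <- min(length(tr_pos), length(tr_neg))
    model <- train_classifier(tr_pos, tr_neg, spec = spec, l1 = l1, l2 = l2,
                              n_train_per_class = n_train,
                              seed = fold_seeds[f])
    evaluate_classifier(model, pos[fold_pos == f], neg[fold_neg == f])
  })
  structure(list(folds = folds,
                 mean_auc = mean(vapply(folds, `[[`, numeric(1), "auc")),
                 k = k, seed = seed),
            class = "clonofate_cv")
}

#' @export
print.clonofate_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV: mean AUC = %.4f (folds: %s)\n", x$k, x$mean_auc,
              paste(sprintf("%.3f", vapply(x$folds, `[[`, numeric(1), "auc")),
                    collapse = ", ")))
  invisible(x)
}

#' Serialize a trained classifier to JSON
#'
#' Full-precision serialization; [load_classifier()] restores a model
#' whose scores are bit-identical.
#'
#' @param model A `clonofate_classifier`.
#' @param path Output JSON path.
#' @export
save_classifier <- function(model, path) {
  out <- list(
    weights = as.list(model$weights),
    intercept = model$intercept,
    l1 = model$l1, l2 = model$l2,
    max_depth = model$spec$max_depth,
    train_pos = model$train_pos, train_neg = model$train_neg,
    n_per_class = model$n_per_class, seed = model$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a classifier serialized by [save_classifier()]
#'
#' @param path JSON path.
#' @return A `clonofate_classifier`.
#' @export
load_classifier <- function(path) {
  raw <- jsonlite::read_json(path)
  spec <- encoding_spec(raw$max_depth)
  w <- setNames(vapply(raw$weights, as.numeric, numeric(1)),
                names(raw$weights))
  # restore full feature order
  weights <- setNames(numeric(length(spec$feature_ids)), spec$feature_ids)
  weights[names(w)] <- w
  structure(list(
    weights = weights, intercept = as.numeric(raw$intercept),
    l1 = raw$l1, l2 = raw$l2, spec = spec,
    train_pos = unlist(raw$train_pos), train_neg = unlist(raw$train_neg),
    n_per_class = raw$n_per_class, seed = raw$seed),
    class = "clonofate_classifier")
}
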