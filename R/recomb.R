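## Toy V(D)J recombination generative model with exact amino-acid
## generation probability (Pgen). The model draws a V segment remnant, a
## J segment remnant (after bounded 3'/5' deletions) and a bounded run of
## untemplated insertions; the CDR3 is V-remnant + insertions + J-remnant.
## Pgen is computed exactly by summing over all event paths and codon
## realizations compatible with a target amino-acid sequence.

NT_ALPHABET <- c("A", "C", "G", "T")

## reverse genetic code: amino acid (incl. "*") -> matrix of codon chars
.rev_codon_table <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) {
      code <- Biostrings::GENETIC_CODE
      gc <<- lapply(split(names(code), unname(code)), function(codons) {
        do.call(rbind, strsplit(codons, ""))
      })
    }
    gc
  }
})

#' Define a toy V(D)J recombination model
#'
#' All event distributions are explicit and bounded, so the generation
#' probability of any amino-acid sequence can be computed exactly. The
#' junction is `V-remnant + insertions + J-remnant`, where the remnants
#' are the V/J germline strings after 3'/5' deletions.
#'
#' @param v_segments,j_segments Named character vectors of germline
#'   nucleotide strings (names are the gene names).
#' @param v_probs,j_probs Segment choice probabilities (default uniform).
#' @param v_del,j_del Numeric probability vectors over deletion lengths
#'   0, 1, ... (shared across segments), summing to 1.
#' @param ins_len Probability vector over insertion lengths 0, 1, ...
#' @param ins_nt Named probability vector over A, C, G, T for each
#'   inserted nucleotide.
#' @return A `clonofate_recomb` model with a precomputed event-skeleton
#'   table.
#' @export
recomb_model <- function(v_segments, j_segments,
                         v_probs = NULL, j_probs = NULL,
                         v_del = 1, j_del = 1, ins_len = 1,
                         ins_nt = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (is.null(v_probs)) v_probs <- rep(1 / length(v_segments),
                                       length(v_segments))
  if (is.null(j_probs)) j_probs <- rep(1 / length(j_segments),
                                       length(j_segments))
  chk1 <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-9) stop(what, " probabilities must sum to 1")
    if (any(p < 0)) stop(what, " probabilities must be nonnegative")
  }
  chk1(v_probs, "V"); chk1(j_probs, "J"); chk1(v_del, "V-deletion")
  chk1(j_del, "J-deletion"); chk1(ins_len, "insertion-length")
  chk1(ins_nt, "insertion-nucleotide")
  stopifnot(identical(sort(names(ins_nt)), NT_ALPHABET))
  if (!all(strsplit(paste(c(v_segments, j_segments), collapse = ""),
                    "")[[1]] %in% NT_ALPHABET))
    stop("segment strings must be over A, C, G, T")
  if (min(nchar(v_segments)) <= length(v_del) - 1 ||
      min(nchar(j_segments)) <= length(j_del) - 1)
    stop("deletion support must be shorter than the segments")

  # enumerate all event skeletons (V, dv, J, dj, insertion length)
  skel <- expand.grid(v = seq_along(v_segments),
                      dv = seq_along(v_del) - 1L,
                      j = seq_along(j_segments),
                      dj = seq_along(j_del) - 1L,
                      li = seq_along(ins_len) - 1L)
  skel$prob <- v_probs[skel$v] * v_del[skel$dv + 1L] * j_probs[skel$j] *
    j_del[skel$dj + 1L] * ins_len[skel$li + 1L]
  skel$prefix <- substr(v_segments[skel$v], 1,
                        nchar(v_segments[skel$v]) - skel$dv)
  skel$suffix <- substr(j_segments[skel$j], skel$dj + 1L,
                        nchar(j_segments[skel$j]))
  skel$total_len <- nchar(skel$prefix) + skel$li + nchar(skel$suffix)
  skel$in_frame <- skel$total_len %% 3L == 0L

  structure(list(v_segments = v_segments, j_segments = j_segments,
                 v_probs = v_probs, j_probs = j_probs,
                 v_del = v_del, j_del = j_del,
                 ins_len = ins_len, ins_nt = ins_nt[NT_ALPHABET],
                 skeletons = skel),
            class = "clonofate_recomb")
}

#' @export
print.clonofate_recomb <- function(x, ...) {
  cat("Toy V(D)J recombination model:",
      length(x$v_segments), "V x", length(x$j_segments), "J segments,",
      "deletions <=", length(x$v_del) - 1, "/", length(x$j_del) - 1,
      ", insertions <=", length(x$ins_len) - 1, "\n")
  cat("  in-frame event probability:",
      format(sum(x$skeletons$prob[x$skeletons$in_frame])), "\n")
  invisible(x)
}

#' Sample receptor junctions from a toy recombination model
#'
#' Draws segments, deletions and insertions per the model; out-of-frame
#' draws (and, with `productive_only`, draws translating to a stop) are
#' rejected and counted.
#'
#' @param model A `clonofate_recomb` model.
#' @param n Number of accepted sequences to return.
#' @param productive_only If `TRUE`, also reject sequences whose
#'   translation contains a stop.
#' @return Data frame of event records (`v_name`, `v_del`, `j_name`,
#'   `j_del`, `ins_nt`, `nt`, `aa`) with attribute `n_rejected`
#'   (named: out_of_frame, stop_codon).
#' @export
sample_tcr <- function(model, n = 1, productive_only = FALSE) {
  skel <- model$skeletons
  out <- NULL
  rej_frame <- 0L; rej_stop <- 0L
  while (is.null(out) || nrow(out) < n) {
    todo <- n - if (is.null(out)) 0L else nrow(out)
    draw <- sample.int(nrow(skel), size = max(todo * 2L, 16L),
                       replace = TRUE, prob = skel$prob)
    inf <- skel$in_frame[draw]
    rej_frame <- rej_frame + sum(!inf)
    draw <- draw[inf]
    if (!length(draw)) next
    ins <- vapply(skel$li[draw], function(L) {
      paste(sample(NT_ALPHABET, L, replace = TRUE, prob = model$ins_nt),
            collapse = "")
    }, character(1))
    nt <- paste0(skel$prefix[draw], ins, skel$suffix[draw])
    aa <- translate_nt(nt)
    if (productive_only) {
      ok <- !grepl("*", aa, fixed = TRUE)
      rej_stop <- rej_stop + sum(!ok)
      draw <- draw[ok]; ins <- ins[ok]; nt <- nt[ok]; aa <- aa[ok]
    }
    if (!length(draw)) next
    batch <- data.frame(
      v_name = names(model$v_segments)[skel$v[draw]],
      v_del = skel$dv[draw],
      j_name = names(model$j_segments)[skel$j[draw]],
      j_del = skel$dj[draw],
      ins_nt = ins, nt = nt, aa = aa,
      stringsAsFactors = FALSE)
    out <- if (is.null(out)) batch else rbind(out, batch)
  }
  out <- out[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- c(out_of_frame = rej_frame,
                               stop_codon = rej_stop)
  out
}

#' Reconstruct the junction sequence from an event record
#'
#' @param model A `clonofate_recomb` model.
#' @param events Data frame of event records as returned by
#'   [sample_tcr()].
#' @return Character vector of nucleotide junctions.
#' @export
replay_event <- function(model, events) {
  v <- model$v_segments[events$v_name]
  j <- model$j_segments[events$j_name]
  paste0(substr(v, 1, nchar(v) - events$v_del),
         events$ins_nt,
         substr(j, events$j_del + 1, nchar(j)))
}

## P(random codon == one coding `aa`) given a 3-char template where NA
## marks a free (insertion) position with nucleotide probabilities p_nt.
.codon_prob <- function(aa, tmpl, p_nt) {
  codons <- .rev_codon_table()[[aa]]
  if (is.null(codons)) return(0)
  tot <- 0
  for (r in seq_len(nrow(codons))) {
    p <- 1
    for (k in 1:3) {
      p <- p * if (is.na(tmpl[k])) p_nt[[codons[r, k]]]
      else as.numeric(codons[r, k] == tmpl[k])
      if (p == 0) break
    }
    tot <- tot + p
  }
  tot
}

## P(no stop codon anywhere) for one skeleton's template.
.no_stop_prob <- function(tmpl, p_nt) {
  p <- 1
  for (c0 in seq_len(length(tmpl) / 3L)) {
    idx <- (3L * (c0 - 1L) + 1L):(3L * c0)
    p <- p * (1 - .codon_prob("*", tmpl[idx], p_nt))
  }
  p
}

.skeleton_template <- function(skel_row) {
  c(strsplit(skel_row$prefix, "")[[1]],
    rep(NA_character_, skel_row$li),
    strsplit(skel_row$suffix, "")[[1]])
}

#' Exact amino-acid generation probability under a toy model
#'
#' Sums over every event path (segment choices, deletions, insertion
#' length) and every nucleotide realization whose translation equals the
#' target sequence. By default the probability is conditioned on in-frame
#' output (the event producing a junction of length divisible by 3);
#' `conditioning = "productive"` additionally conditions on the absence
#' of stop codons, in which case probabilities over the 20-letter
#' sequence space sum to 1.
#'
#' @param model A `clonofate_recomb` model.
#' @param aa_sequence Target amino-acid string (may contain `*` under
#'   `"in_frame"` conditioning).
#' @param conditioning `"in_frame"` (default) or `"productive"`.
#' @return Probability in `[0, 1]`; 0 for infeasible lengths.
#' @export
pgen_aa <- function(model, aa_sequence,
                    conditioning = c("in_frame", "productive")) {
  conditioning <- match.arg(conditioning)
  skel <- model$skeletons
  inframe <- skel[skel$in_frame, , drop = FALSE]
  p_nt <- model$ins_nt
  if (conditioning == "productive" &&
      grepl("*", aa_sequence, fixed = TRUE)) return(0)
  z <- if (conditioning == "in_frame") sum(inframe$prob) else {
    sum(inframe$prob * vapply(seq_len(nrow(inframe)), function(r) {
      .no_stop_prob(.skeleton_template(inframe[r, ]), p_nt)
    }, numeric(1)))
  }
  L_nt <- 3L * nchar(aa_sequence)
  cand <- inframe[inframe$total_len == L_nt, , drop = FALSE]
  if (nrow(cand) == 0L) return(0)
  aa_chars <- strsplit(aa_sequence, "")[[1]]
  num <- sum(vapply(seq_len(nrow(cand)), function(r) {
    tmpl <- .skeleton_template(cand[r, ])
    p <- cand$prob[r]
    for (c0 in seq_along(aa_chars)) {
      idx <- (3L * (c0 - 1L) + 1L):(3L * c0)
      p <- p * .codon_prob(aa_chars[c0], tmpl[idx], p_nt)
      if (p == 0) break
    }
    p
  }, numeric(1)))
  num / z
}

#' Compare generation probabilities between annotation groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparisons of log10 Pgen
#' for every pair of groups, with group medians; optionally repeated
#' within strata of clone counts (so that convergence-driven differences
#' can be separated from residual sequence effects).
#'
#' @param pgen Numeric vector of generation probabilities (> 0).
#' @param group Character vector of group annotations, same length.
#' @param n_clones Optional integer vector of clone counts per record for
#'   the stratified comparison.
#' @param min_n Minimum records per group for a comparison (default 3).
#' @return List with `pairwise` (data frame: groups, n, medians of
#'   log10 Pgen, W, p) and, when `n_clones` is given, `stratified`.
#' @export
compare_pgen_groups <- function(pgen, group, n_clones = NULL, min_n = 3) {
  stopifnot(length(pgen) == length(group), all(pgen > 0))
  lp <- log10(pgen)
  tab <- table(group)
  small <- names(tab)[tab < min_n]
  if (length(small)) {
    warning("omitting group(s) with fewer than ", min_n, " records: ",
            paste(small, collapse = ", "))
  }
  groups <- names(tab)[tab >= min_n]
  if (length(groups) < 2) stop("need at least 2 groups with >= ", min_n,
                               " records")
  do_pairs <- function(lp, group, groups) {
    pairs <- utils::combn(groups, 2)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      g1 <- pairs[1, i]; g2 <- pairs[2, i]
      x <- lp[group == g1]; y <- lp[group == g2]
      wt <- stats::wilcox.test(x, y, exact = length(x) * length(y) <= 400)
      data.frame(group1 = g1, group2 = g2,
                 n1 = length(x), n2 = length(y),
                 median1 = stats::median(x), median2 = stats::median(y),
                 W = unname(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- list(pairwise = do_pairs(lp, group, groups))
  if (!is.null(n_clones)) {
    strata <- sort(unique(n_clones))
    srows <- lapply(strata, function(s) {
      sel <- n_clones == s
      gs <- names(which(table(group[sel]) >= min_n))
      if (length(gs) < 2) return(NULL)
      cbind(n_clones = s, do_pairs(lp[sel], group[sel], gs))
    })
    out$stratified <- do.call(rbind, srows)
  }
  out
}

#' Uniform lookup interface for generation probabilities
#'
#' Returns a function mapping a clonotype table to per-clonotype Pgen
#' records. With `source = "toy_model"` the chain Pgens come from
#' [pgen_aa()] under the supplied alpha/beta models; with
#' `source = "external_table"` they are looked up in a table of
#' externally computed values (e.g. from an inferred recombination
#' model), keyed by `cdr3a_aa` and `cdr3b_aa`. The joint Pgen of a paired
#' clonotype is the product of the chain Pgens (independent
#' rearrangement). Missing keys are skipped and counted.
#'
#' @param source `"toy_model"` or `"external_table"`.
#' @param alpha_model,beta_model `clonofate_recomb` models (toy source).
#' @param table Data frame with columns `cdr3a_aa`, `cdr3b_aa`,
#'   `pgen_alpha`, `pgen_beta` (external source).
#' @return Function taking a clonotype table and returning a data frame
#'   `clonotype_id`, `pgen_alpha`, `pgen_beta`, `pgen_joint` with
#'   attribute `n_skipped`.
#' @export
pgen_provider <- function(source = c("toy_model", "external_table"),
                          alpha_model = NULL, beta_model = NULL,
                          table = NULL) {
  source <- match.arg(source)
  if (source == "toy_model") {
    stopifnot(inherits(alpha_model, "clonofate_recomb"),
              inherits(beta_model, "clonofate_recomb"))
    function(clonotypes) {
      pa <- vapply(unique(clonotypes$cdr3a_aa), pgen_aa, numeric(1),
                   model = alpha_model)
      pb <- vapply(unique(clonotypes$cdr3b_aa), pgen_aa, numeric(1),
                   model = beta_model)
      out <- data.frame(
        clonotype_id = clonotypes$clonotype_id,
        pgen_alpha = unname(pa[clonotypes$cdr3a_aa]),
        pgen_beta = unname(pb[clonotypes$cdr3b_aa]),
        stringsAsFactors = FALSE)
      out$pgen_joint <- out$pgen_alpha * out$pgen_beta
      attr(out, "n_skipped") <- 0L
      out
    }
  } else {
    stopifnot(is.data.frame(table),
              all(c("cdr3a_aa", "cdr3b_aa", "pgen_alpha", "pgen_beta") %in%
                    names(table)))
    key_tab <- paste(table$cdr3a_aa, table$cdr3b_aa, sep = "|")
    function(clonotypes) {
      key <- paste(clonotypes$cdr3a_aa, clonotypes$cdr3b_aa, sep = "|")
      m <- match(key, key_tab)
      skipped <- sum(is.na(m))
      if (skipped) warning("skipping ", skipped,
                           " clonotype(s) missing from the Pgen table")
      out <- data.frame(
        clonotype_id = clonotypes$clonotype_id[!is.na(m)],
        pgen_alpha = table$pgen_alpha[m[!is.na(m)]],
        pgen_beta = table$pgen_beta[m[!is.na(m)]],
        stringsAsFactors = FALSE)
      out$pgen_joint <- out$pgen_alpha * out$pgen_beta
      attr(out, "n_skipped") <- skipped
      out
    }
  }
}

#' Write / read a Pgen table (full precision TSV)
#'
#' @param table Data frame with `cdr3a_aa`, `cdr3b_aa`, `pgen_alpha`,
#'   `pgen_beta`.
#' @param path TSV path.
#' @export
write_pgen_table <- function(table, path) {
  out <- table
  for (col in c("pgen_alpha", "pgen_beta"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pgen_table
#' @export
read_pgen_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(cdr3a_aa = "character",
                                          cdr3b_aa = "character",
                                          pgen_alpha = "numeric",
                                          pgen_beta = "numeric"))
  tab
}
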