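## CDR3 similarity-graph clustering, cluster consensus matrices,
## physicochemical positional profiles, and repertoire summaries.

#' Build the CDR3b single-mismatch similarity graph
#'
#' Vertices are clonotypes; two vertices are connected if their CDR3b
#' amino-acid sequences have equal length and Hamming distance exactly 1
#' (substitution only; indels are not considered). Edges are found by
#' single-position wildcard hashing rather than an all-pairs scan;
#' components are extracted with igraph and sorted by size, largest
#' first.
#'
#' @param clonotypes Clonotype table from [assign_clonotypes()] (uses
#'   `clonotype_id`, `cdr3b_aa`, `subset_annotation`).
#' @param cdr3a_filter Optional CDR3a amino-acid sequence; if given, only
#'   clonotypes with that (canonical) CDR3a enter the graph.
#' @return A `clonofate_simgraph` list: `vertices` (id, sequence,
#'   annotation), `edges` (two id columns), `components` (list of id
#'   vectors, size-descending), `composition` (per-component annotation
#'   counts).
#' @export
build_similarity_graph <- function(clonotypes, cdr3a_filter = NULL) {
  v <- data.frame(id = clonotypes$clonotype_id,
                  cdr3b_aa = clonotypes$cdr3b_aa,
                  annotation = clonotypes$subset_annotation,
                  stringsAsFactors = FALSE)
  if (!is.null(cdr3a_filter))
    v <- v[clonotypes$cdr3a_aa == cdr3a_filter, , drop = FALSE]
  n <- nrow(v)
  pairs <- character(0)
  from <- integer(0); to <- integer(0)
  if (n >= 2) {
    seqs <- v$cdr3b_aa
    L <- nchar(seqs)
    keys <- character(0); idxs <- integer(0)
    for (p in seq_len(max(L))) {
      sel <- which(L >= p)
      masked <- seqs[sel]
      substr(masked, p, p) <- "."
      keys <- c(keys, paste0(L[sel], ":", p, ":", masked))
      idxs <- c(idxs, sel)
    }
    buckets <- split(idxs, keys)
    for (b in buckets) {
      if (length(b) < 2) next
      for (i in seq_len(length(b) - 1)) for (j in seq(i + 1, length(b))) {
        u <- b[i]; w <- b[j]
        if (seqs[u] == seqs[w]) next  # distance 0, not an edge
        key <- paste(min(u, w), max(u, w))
        if (!(key %in% pairs)) {
          pairs <- c(pairs, key)
          from <- c(from, min(u, w)); to <- c(to, max(u, w))
        }
      }
    }
  }
  edges <- data.frame(from = v$id[from], to = v$id[to],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = v$id)
  comp <- igraph::components(g)
  comp_members <- split(v$id, comp$membership[v$id])
  comp_members <- comp_members[order(-lengths(comp_members))]
  names(comp_members) <- NULL
  composition <- do.call(rbind, lapply(seq_along(comp_members), function(i) {
    ann <- v$annotation[match(comp_members[[i]], v$id)]
    data.frame(component = i, size = length(ann),
               n_type1 = sum(ann == "TYPE1"),
               n_type17 = sum(ann == "TYPE17"),
               n_mixed = sum(ann == "TYPE1_TYPE17"),
               n_other = sum(ann == "OTHER"))
  }))
  structure(list(vertices = v, edges = edges, components = comp_members,
                 composition = composition),
            class = "clonofate_simgraph")
}

#' @export
print.clonofate_simgraph <- function(x, ...) {
  cat("CDR3b similarity graph:", nrow(x$vertices), "vertices,",
      nrow(x$edges), "edges,", length(x$components), "components\n")
  if (length(x$components))
    cat("largest component:", length(x$components[[1]]), "sequences\n")
  invisible(x)
}

#' Write a similarity graph as edge-list and membership TSVs
#'
#' @param graph A `clonofate_simgraph`.
#' @param dir Output directory; writes `edges.tsv` and `components.tsv`.
#' @export
write_similarity_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(graph$edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  membership <- data.frame(
    id = unlist(graph$components),
    component = rep(seq_along(graph$components),
                    lengths(graph$components)))
  utils::write.table(membership, file.path(dir, "components.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Position frequency matrix and consensus of an equal-length cluster
#'
#' Column-wise amino-acid relative frequencies of a set of equal-length
#' sequences (e.g. one component of the similarity graph), with the
#' consensus taken as the most frequent residue per position, ties broken
#' alphabetically.
#'
#' @param seqs Character vector of equal-length amino-acid sequences.
#' @return A `clonofate_pfm`: numeric matrix (positions x 20 residues,
#'   rows sum to 1) with attributes `consensus` and `n`.
#' @export
cluster_profile <- function(seqs) {
  if (length(seqs) == 0L) stop("empty component")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal length")
  mat <- matrix(0, nrow = L, ncol = length(AA_ALPHABET),
                dimnames = list(position = seq_len(L), residue = AA_ALPHABET))
  chars <- do.call(rbind, strsplit(seqs, ""))
  for (p in seq_len(L)) {
    tab <- table(factor(chars[, p], levels = AA_ALPHABET))
    mat[p, ] <- as.numeric(tab) / length(seqs)
  }
  consensus <- paste(AA_ALPHABET[apply(mat, 1, which.max)], collapse = "")
  structure(mat, consensus = consensus, n = length(seqs),
            class = c("clonofate_pfm", "matrix"))
}

#' Write a position frequency matrix as TSV
#'
#' @param pfm A `clonofate_pfm`.
#' @param path Output TSV path (position x residue, logo-tool friendly).
#' @export
write_pfm <- function(pfm, path) {
  df <- data.frame(position = seq_len(nrow(pfm)), unclass(pfm),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Center-aligned physicochemical positional profiles
#'
#' For each sequence of length L, the residue at 0-based index p
#' contributes its scale value at offset `p - floor(L/2)` (position
#' relative to the CDR3 center, center-right convention for even
#' lengths), so sequences of different lengths can be averaged
#' position-wise. Group means are reported per offset where at least
#' `min_support` sequences contribute.
#'
#' @param groups Named list of character vectors of amino-acid sequences.
#' @param property One of `"basicity"`, `"hydrophobicity"`,
#'   `"helix_propensity"`, or `"custom"` with `scale` supplied.
#' @param scale Optional named numeric vector over the 20 residues
#'   overriding the bundled scale.
#' @param min_support Minimum sequences per offset for a reported mean.
#' @return Tidy data frame: `group`, `property`, `offset`, `mean`, `n`.
#' @export
physchem_profile <- function(groups,
                             property = c("basicity", "hydrophobicity",
                                          "helix_propensity", "custom"),
                             scale = NULL, min_support = 5) {
  property <- match.arg(property)
  if (is.null(scale)) {
    if (property == "custom") stop("property 'custom' requires a scale")
    scale <- aa_scales()[[property]]
  }
  stopifnot(is.list(groups), !is.null(names(groups)))
  rows <- lapply(names(groups), function(g) {
    seqs <- groups[[g]]
    offs <- vals <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
      ch <- strsplit(seqs[i], "")[[1]]
      bad <- setdiff(ch, names(scale))
      if (length(bad))
        stop("residue(s) outside alphabet in sequence ", seqs[i], ": ",
             paste(bad, collapse = ", "))
      L <- length(ch)
      offs[[i]] <- seq_len(L) - 1L - L %/% 2L
      vals[[i]] <- unname(scale[ch])
    }
    off <- unlist(offs); val <- unlist(vals)
    agg <- aggregate(val, by = list(offset = off),
                     FUN = function(v) c(mean = mean(v), n = length(v)))
    data.frame(group = g, property = property, offset = agg$offset,
               mean = agg$x[, "mean"], n = as.integer(agg$x[, "n"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n >= min_support, , drop = FALSE]
  out <- out[order(out$group, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-group repertoire summaries
#'
#' Per subset annotation: the CDR3b length histogram, the short-sequence
#' fraction (lengths 10 to 14 inclusive), the CDR3a sequence frequency
#' table, and Va/Vb gene usage frequencies.
#'
#' @param clonotypes Clonotype table from [assign_clonotypes()].
#' @return A list with `short_fraction` (data frame per group) and
#'   `by_group` (per-group lists: `cdr3b_lengths`, `cdr3a_freq`,
#'   `va_usage`, `vb_usage`).
#' @export
repertoire_summaries <- function(clonotypes) {
  groups <- split(clonotypes,
                  factor(clonotypes$subset_annotation,
                         levels = ANNOTATION_LEVELS))
  groups <- groups[vapply(groups, nrow, integer(1)) > 0]
  by_group <- lapply(groups, function(ct) {
    len <- nchar(ct$cdr3b_aa)
    list(
      cdr3b_lengths = table(len),
      short_fraction = mean(len >= 10 & len <= 14),
      cdr3a_freq = sort(table(ct$cdr3a_aa) / nrow(ct), decreasing = TRUE),
      va_usage = sort(table(ct$va) / nrow(ct), decreasing = TRUE),
      vb_usage = sort(table(ct$vb) / nrow(ct), decreasing = TRUE))
  })
  short <- data.frame(
    subset_annotation = names(by_group),
    n_clonotypes = vapply(groups, nrow, integer(1)),
    short_fraction = vapply(by_group, `[[`, numeric(1), "short_fraction"),
    stringsAsFactors = FALSE)
  rownames(short) <- NULL
  list(short_fraction = short, by_group = by_group)
}

#' Positional enrichment map from a trained selection classifier
#'
#' Reshapes the weights of a trained one-hot positional classifier (see
#' [train_classifier()]) onto forward and reverse positional grids.
#' When the classifier was trained with an observed repertoire as the
#' positive class and a recombination-model-generated repertoire as the
#' background, positive weights mark residues enriched relative to the
#' generative baseline (i.e. selected), negative weights depletion.
#'
#' @param model A `clonofate_classifier` from [train_classifier()].
#' @return List of two matrices `forward` and `reverse`
#'   (positions x residues).
#' @export
positional_enrichment <- function(model) {
  if (!inherits(model, "clonofate_classifier"))
    stop("model must be a trained clonofate_classifier")
  d <- model$spec$max_depth
  fwd <- matrix(0, nrow = d, ncol = length(AA_ALPHABET),
                dimnames = list(position = seq_len(d) - 1L,
                                residue = AA_ALPHABET))
  rev <- matrix(0, nrow = d, ncol = length(AA_ALPHABET),
                dimnames = list(position = -seq_len(d), residue = AA_ALPHABET))
  w <- model$weights
  parts <- strsplit(names(w), ":", fixed = TRUE)
  pos <- as.integer(vapply(parts, `[`, character(1), 2))
  res <- vapply(parts, `[`, character(1), 3)
  is_fwd <- vapply(parts, `[`, character(1), 1) == "f"
  fwd[cbind(pos[is_fwd] + 1L, match(res[is_fwd], AA_ALPHABET))] <- w[is_fwd]
  rev[cbind(-pos[!is_fwd], match(res[!is_fwd], AA_ALPHABET))] <- w[!is_fwd]
  list(forward = fwd, reverse = rev)
}
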