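## Clone (nucleotide identity within an animal) and clonotype (amino-acid
## identity across animals/datasets) assignment and summaries.

clone_key <- function(cells) {
  paste(cells$va, cells$ja, cells$cdr3a_nt,
        cells$vb, cells$jb, cells$cdr3b_nt, sep = "|")
}

clonotype_key_of <- function(va, ja, cdr3a_aa, vb, jb, cdr3b_aa) {
  paste(va, ja, cdr3a_aa, vb, jb, cdr3b_aa, sep = "|")
}

#' Annotate a group of cells (or clones) by its subset composition
#'
#' A group is TYPE1 if it contains at least one TYPE1 member and no TYPE17
#' member, TYPE17 symmetrically, TYPE1_TYPE17 if it contains both, and
#' OTHER if it contains only immature, intermediate-stage or cycling
#' cells. Permutation-invariant in its input.
#'
#' @param labels Character vector of subset labels (non-empty).
#' @return One of `"TYPE1"`, `"TYPE17"`, `"TYPE1_TYPE17"`, `"OTHER"`.
#' @export
#' @examples
#' annotate_subset(c("TYPE1", "CYCLING"))
annotate_subset <- function(labels) {
  if (length(labels) == 0L) stop("cannot annotate an empty group")
  bad <- setdiff(labels, SUBSET_LEVELS)
  if (length(bad)) stop("unknown subset label(s): ", paste(bad, collapse = ", "))
  has1 <- any(labels == "TYPE1")
  has17 <- any(labels == "TYPE17")
  if (has1 && has17) "TYPE1_TYPE17"
  else if (has1) "TYPE1"
  else if (has17) "TYPE17"
  else "OTHER"
}

#' Group QC-passed cells into clones
#'
#' A clone is the set of cells from one animal sharing the full nucleotide
#' TCR key (Va, Ja, CDR3a nt, Vb, Jb, CDR3b nt); it proxies descent from a
#' single precursor because the generation probability of any particular
#' nucleotide rearrangement is tiny. Clone ids are assigned
#' deterministically in (animal_id, key) order.
#'
#' @param cells Cell table from [filter_cells()] (or the simulator).
#' @return Data frame with one row per clone: `clone_id`, `animal_id`,
#'   the six nucleotide key columns plus the amino-acid translations,
#'   `size`, `subset_annotation`, and list-columns `cell_ids`,
#'   `cell_subsets`.
#' @export
assign_clones <- function(cells) {
  if (nrow(cells) == 0L) {
    return(data.frame(clone_id = character(0), animal_id = character(0)))
  }
  key <- clone_key(cells)
  full <- paste(cells$animal_id, key, sep = "|")
  ord <- order(cells$animal_id, key)
  uniq <- unique(full[ord])
  idx <- match(full, uniq)
  first <- match(uniq, full)
  members <- split(seq_len(nrow(cells)), idx)
  clones <- data.frame(
    clone_id = sprintf("clone_%05d", seq_along(uniq)),
    animal_id = cells$animal_id[first],
    va = cells$va[first], ja = cells$ja[first],
    cdr3a_nt = cells$cdr3a_nt[first], cdr3a_aa = cells$cdr3a_aa[first],
    vb = cells$vb[first], jb = cells$jb[first],
    cdr3b_nt = cells$cdr3b_nt[first], cdr3b_aa = cells$cdr3b_aa[first],
    size = as.integer(lengths(members)),
    stringsAsFactors = FALSE)
  clones$cell_ids <- I(lapply(members, function(i) cells$cell_id[i]))
  clones$cell_subsets <- I(lapply(members, function(i) cells$subset_label[i]))
  clones$subset_annotation <-
    vapply(clones$cell_subsets, annotate_subset, character(1))
  rownames(clones) <- NULL
  clones
}

#' Group clones into clonotypes by amino-acid identity
#'
#' A clonotype is the set of clones (possibly from different animals or
#' datasets) sharing the amino-acid key (Va, Ja, CDR3a aa, Vb, Jb, CDR3b
#' aa). A clonotype composed of several clones arose by convergent
#' recombination in independent precursors.
#'
#' @param clones Clone table from [assign_clones()].
#' @param cdr3_only If `TRUE`, drop V/J genes from the key and match on
#'   CDR3 amino-acid sequences alone.
#' @return Data frame with one row per clonotype: `clonotype_id`, the key
#'   columns, `n_clones`, `n_cells`, `subset_annotation`, and list-columns
#'   `clone_ids`, `clone_annotations`, `cell_ids`, `cell_subsets`.
#' @export
assign_clonotypes <- function(clones, cdr3_only = FALSE) {
  if (nrow(clones) == 0L) {
    return(data.frame(clonotype_id = character(0)))
  }
  key <- if (cdr3_only) {
    paste(clones$cdr3a_aa, clones$cdr3b_aa, sep = "|")
  } else {
    clonotype_key_of(clones$va, clones$ja, clones$cdr3a_aa,
                     clones$vb, clones$jb, clones$cdr3b_aa)
  }
  uniq <- sort(unique(key))
  idx <- match(key, uniq)
  first <- match(uniq, key)
  members <- split(seq_len(nrow(clones)), idx)
  ct <- data.frame(
    clonotype_id = sprintf("clonotype_%05d", seq_along(uniq)),
    va = clones$va[first], ja = clones$ja[first],
    cdr3a_aa = clones$cdr3a_aa[first],
    vb = clones$vb[first], jb = clones$jb[first],
    cdr3b_aa = clones$cdr3b_aa[first],
    n_clones = as.integer(lengths(members)),
    n_cells = vapply(members, function(i) sum(clones$size[i]), integer(1)),
    stringsAsFactors = FALSE)
  ct$clone_ids <- I(lapply(members, function(i) clones$clone_id[i]))
  ct$clone_annotations <-
    I(lapply(members, function(i) clones$subset_annotation[i]))
  ct$cell_ids <- I(lapply(members,
                          function(i) unlist(clones$cell_ids[i], use.names = FALSE)))
  ct$cell_subsets <- I(lapply(members,
                              function(i) unlist(clones$cell_subsets[i], use.names = FALSE)))
  ct$subset_annotation <- vapply(ct$cell_subsets, annotate_subset, character(1))
  rownames(ct) <- NULL
  ct
}

#' Per-subset expansion and clonotype composition summary
#'
#' Reports, per subset annotation: the expansion index (mean clone size),
#' cell and clone counts, and the distribution of the number of clones per
#' clonotype (fractions with 1, 2, and 3+ clones).
#'
#' @param clones Clone table from [assign_clones()].
#' @param clonotypes Clonotype table from [assign_clonotypes()].
#' @return Data frame with one row per annotation present in the input.
#' @export
clonal_summary <- function(clones, clonotypes) {
  groups <- ANNOTATION_LEVELS[ANNOTATION_LEVELS %in%
                                c(clones$subset_annotation,
                                  clonotypes$subset_annotation)]
  absent <- setdiff(ANNOTATION_LEVELS, groups)
  if (length(absent))
    warning("no clones or clonotypes annotated: ",
            paste(absent, collapse = ", "))
  rows <- lapply(groups, function(g) {
    cl <- clones[clones$subset_annotation == g, , drop = FALSE]
    ct <- clonotypes[clonotypes$subset_annotation == g, , drop = FALSE]
    nct <- nrow(ct)
    data.frame(
      subset_annotation = g,
      n_clones = nrow(cl),
      n_cells = sum(cl$size),
      expansion_index = if (nrow(cl)) mean(cl$size) else NA_real_,
      n_clonotypes = nct,
      frac_1_clone = if (nct) mean(ct$n_clones == 1) else NA_real_,
      frac_2_clones = if (nct) mean(ct$n_clones == 2) else NA_real_,
      frac_3plus_clones = if (nct) mean(ct$n_clones >= 3) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Clonotypes shared between two datasets
#'
#' Intersects two annotated clonotype tables on the amino-acid key,
#' restricted to clonotypes annotated TYPE1 or TYPE17 on each side, and
#' carries each side's annotation for concordance analysis.
#'
#' @param clonotypes_a,clonotypes_b Clonotype tables from
#'   [assign_clonotypes()].
#' @return Data frame with columns `key`, `annotation_a`, `annotation_b`.
#' @export
shared_clonotypes <- function(clonotypes_a, clonotypes_b) {
  pure <- function(ct) ct[ct$subset_annotation %in% c("TYPE1", "TYPE17"), ,
                          drop = FALSE]
  a <- pure(clonotypes_a)
  b <- pure(clonotypes_b)
  key_a <- clonotype_key_of(a$va, a$ja, a$cdr3a_aa, a$vb, a$jb, a$cdr3b_aa)
  key_b <- clonotype_key_of(b$va, b$ja, b$cdr3a_aa, b$vb, b$jb, b$cdr3b_aa)
  common <- intersect(key_a, key_b)
  data.frame(
    key = common,
    annotation_a = a$subset_annotation[match(common, key_a)],
    annotation_b = b$subset_annotation[match(common, key_b)],
    stringsAsFactors = FALSE)
}

#' Write clone and clonotype tables as TSV
#'
#' @param clones,clonotypes Tables from [assign_clones()] /
#'   [assign_clonotypes()].
#' @param dir Output directory (created if needed); writes `clones.tsv`
#'   and `clonotypes.tsv`.
#' @export
write_clone_tables <- function(clones, clonotypes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- function(df, listcols) {
    for (lc in intersect(listcols, names(df)))
      df[[lc]] <- vapply(df[[lc]], paste, character(1), collapse = ",")
    df
  }
  utils::write.table(
    flat(clones, c("cell_ids", "cell_subsets")),
    file.path(dir, "clones.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    flat(clonotypes, c("clone_ids", "clone_annotations", "cell_ids",
                       "cell_subsets")),
    file.path(dir, "clonotypes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
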