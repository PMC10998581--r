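## Shared fixture builders and brute-force oracles.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_aa <- function(n, L = 12) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA20, if (length(L) > 1) sample(L, 1) else L,
                 replace = TRUE), collapse = "")
  }, character(1))
}

## minimal chain-table row
chain_row <- function(cell_id, locus, v, cdr3_nt = "TGTGCC", j = "J1",
                      cdr3_aa = "CA", umi = 5L, productive = TRUE) {
  data.frame(cell_id = cell_id, locus = locus, v_gene = v, j_gene = j,
             cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa, umi_count = umi,
             productive = productive, stringsAsFactors = FALSE)
}

meta_row <- function(cell_id, animal = "m1", ds = "d1", subset = "TYPE1") {
  data.frame(cell_id = cell_id, animal_id = animal, dataset_id = ds,
             subset_label = subset, stringsAsFactors = FALSE)
}

## cell-table row with paired chains (already QC-passed shape)
cell_row <- function(cell_id, animal = "m1", subset = "TYPE1",
                     a_nt = "TGTGCTCAG", b_nt = "TGTGCCTTT",
                     va = "TRAV1", vb = "TRBV13-3",
                     ds = "d1") {
  data.frame(cell_id = cell_id, animal_id = animal, dataset_id = ds,
             subset_label = subset,
             va = va, ja = "TRAJ33", cdr3a_nt = a_nt,
             cdr3a_aa = translate_dna(a_nt),
             vb = vb, jb = "TRBJ2-7", cdr3b_nt = b_nt,
             cdr3b_aa = translate_dna(b_nt),
             dual_alpha = FALSE, stringsAsFactors = FALSE)
}

translate_dna <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt)))
}

## clonotype table realizing a (sizes, labels) structure for the
## multi-clone shuffle: each group is one clonotype whose clones carry
## the given pure annotations
make_clonotype_structure <- function(sizes, labels) {
  stopifnot(sum(sizes) == length(labels))
  ann <- split(labels, rep(seq_along(sizes), sizes))
  data.frame(
    clonotype_id = sprintf("ct%03d", seq_along(sizes)),
    cdr3b_aa = rand_aa(length(sizes), 10),
    n_clones = as.integer(sizes),
    clone_annotations = I(unname(ann)),
    stringsAsFactors = FALSE)
}

## cell table realizing a (sizes, labels) structure for the cell-label
## shuffle: each group is one clonotype (distinct aa key) of given size
make_cell_structure <- function(sizes, labels) {
  stopifnot(sum(sizes) == length(labels))
  keys <- rand_aa(length(sizes), 11)
  grp <- rep(seq_along(sizes), sizes)
  data.frame(
    cell_id = sprintf("c%04d", seq_along(labels)),
    animal_id = "m1", dataset_id = "d1",
    subset_label = labels,
    va = "TRAV1", ja = "TRAJ33", cdr3a_nt = "TGTGCT", cdr3a_aa = "CA",
    vb = "TRBV1", jb = "TRBJ1", cdr3b_nt = "NNN", cdr3b_aa = keys[grp],
    dual_alpha = FALSE, stringsAsFactors = FALSE)
}

## exhaustive oracle: pmf of the mixed-group count over all distinct
## placements of the label multiset (tiny n only)
brute_force_mixed_pmf <- function(sizes, labels) {
  n <- length(labels)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (u in unique(v)) {
      rest <- v[-match(u, v)]
      out <- c(out, lapply(perms(rest), function(p) c(u, p)))
    }
    out
  }
  grp <- rep(seq_along(sizes), sizes)
  counts <- table(vapply(perms(labels), function(p) {
    sum(vapply(split(p, grp), function(g)
      any(g == "TYPE1") && any(g == "TYPE17"), logical(1)))
  }, numeric(1)))
  data.frame(value = as.integer(names(counts)),
             prob = as.numeric(counts) / sum(counts))
}

## all-pairs Hamming-1 edge oracle
brute_force_edges <- function(seqs) {
  n <- length(seqs)
  out <- NULL
  if (n < 2) return(out)
  sp <- strsplit(seqs, "")
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (nchar(seqs[i]) == nchar(seqs[j]) &&
        sum(sp[[i]] != sp[[j]]) == 1L)
      out <- rbind(out, c(i, j))
  }
  out
}

## total-variation distance between an empirical sample and an exact pmf
tv_distance <- function(samples, pmf) {
  emp <- table(factor(samples, levels = pmf$value)) / length(samples)
  extra <- !(samples %in% pmf$value)
  sum(abs(as.numeric(emp) - pmf$prob)) / 2 + mean(extra) / 2
}

## tiny simulation config for fast structural tests
small_sim_config <- function(seed, ...) {
  simulation_config(n_precursors = 120, n_animals = 2,
                    compute_pgen = FALSE, seed = seed, ...)
}
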