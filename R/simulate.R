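## Ground-truthed simulator of clonal MAIT-like development: recombine a
## semi-invariant alpha and a variable beta junction per precursor, one
## proliferation round, a commitment event (whose placement and mechanism
## depend on the scenario), a second proliferation round, then sampling.

#' Default semi-invariant alpha-chain toy model
#'
#' Near-degenerate junction: a single V/J pair whose germline join is the
#' canonical CDR3a CAVRDSNYQLIW, with rare 3-nt deletions/insertions, so
#' the dominant germline junction accounts for roughly three quarters of
#' productive chains (mimicking the semi-invariant TRAV1-TRAJ33 alpha).
#'
#' @return A `clonofate_recomb` model.
#' @export
default_alpha_model <- function() {
  recomb_model(
    v_segments = c(TRAV1 = "TGTGCTGTGAGGGATAGCAACTAT"),   # CAVRDSNY
    j_segments = c(TRAJ33 = "CAGCTGATCTGG"),              # QLIW
    v_del = c(0.9, 0, 0, 0.1),
    j_del = c(0.9, 0, 0, 0.1),
    ins_len = c(0.85, 0, 0, 0.15),
    ins_nt = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
}

#' Default variable beta-chain toy model
#'
#' Three V and two J segments with deletions of up to six nucleotides on
#' each side and up to nine untemplated insertions: enough junctional
#' diversity for hundreds of distinct CDR3b amino-acid sequences, with
#' high-probability junctions recurring independently in many precursors
#' (convergent recombination).
#'
#' @return A `clonofate_recomb` model.
#' @export
default_beta_model <- function() {
  recomb_model(
    v_segments = c("TRBV13-3" = "TGTGCCAGCAGTGATGCA",     # CASSDA
                   "TRBV13-2" = "TGTGCCAGCGGTGGGGCA",     # CASGGA
                   "TRBV19"   = "TGTGCCAGCTCTCCAGCA"),    # CASSPA
    j_segments = c("TRBJ2-7" = "TCCTATGAACAGTACTTC",      # SYEQYF
                   "TRBJ1-1" = "AACACAGAAGTCTTCTTT"),     # NTEVFF
    v_probs = c(0.4, 0.35, 0.25),
    j_probs = c(0.6, 0.4),
    v_del = c(0.16, 0.16, 0.16, 0.16, 0.16, 0.1, 0.1),
    j_del = c(0.16, 0.16, 0.16, 0.16, 0.16, 0.1, 0.1),
    ins_len = c(0.05, 0.10, 0.15, 0.15, 0.15, 0.12, 0.10, 0.08, 0.06, 0.04),
    ins_nt = c(A = 0.2, C = 0.3, G = 0.3, T = 0.2))
}

#' Simulation configuration
#'
#' Parameters of the four-stage development model: recombination of a
#' semi-invariant alpha and variable beta per precursor, a first
#' proliferation round, sublineage commitment, a second (fate-biased)
#' proliferation round, then cell sampling. Scenarios move or constrain
#' the commitment event: `stochastic` commits each post-round-1 cell
#' i.i.d. with `p_type17`; `instructed` commits with probability given by
#' a logistic function of the CDR3b mean hydropathy (a documented
#' stand-in for ligand affinity); `pre_commitment` fixes fate at the
#' precursor before any division; `post_proliferation` draws fate i.i.d.
#' per cell after all divisions.
#'
#' @param n_precursors Precursors per animal.
#' @param n_animals Number of animals.
#' @param scenario One of `"stochastic"`, `"instructed"`,
#'   `"pre_commitment"`, `"post_proliferation"`.
#' @param p_type17 Commitment probability to TYPE17 (non-instructed
#'   scenarios).
#' @param instruct_slope,instruct_center Slope and center (on the
#'   Kyte-Doolittle mean-hydropathy scale) of the logistic instructive
#'   commitment function.
#' @param round1_mean Mean offspring per precursor in round 1 (geometric,
#'   support 1..`max_offspring`).
#' @param round2_mean_type1,round2_mean_type17 Fate-specific round-2 mean
#'   offspring (TYPE17 > TYPE1, reflecting stronger type-17 expansion).
#' @param round2_mean_uncommitted Round-2 mean when fate is not yet
#'   chosen (`post_proliferation` scenario).
#' @param max_offspring Upper bound of the offspring distributions.
#' @param sampling_fraction Probability that a final cell is sequenced.
#' @param stage_label_fraction Fraction of sampled cells labeled
#'   IMMATURE/INTERMEDIATE/CYCLING instead of their fate (transcriptome
#'   stage admixture).
#' @param alpha_model,beta_model `clonofate_recomb` chain models.
#' @param resample_synonymous_nt If `TRUE` (default), re-randomize each
#'   junction's nucleotide realization uniformly among synonymous codons,
#'   emulating the enormous nucleotide-level entropy of real junctions so
#'   that independent precursors virtually never collide at the
#'   nucleotide level; the amino-acid generative law is unaffected.
#' @param compute_pgen If `TRUE`, record toy-model chain Pgens per
#'   precursor in the truth table.
#' @param dataset_id Dataset tag used in cell ids and metadata.
#' @param seed RNG seed for the whole bundle.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_precursors = 800, n_animals = 3,
                              scenario = c("stochastic", "instructed",
                                           "pre_commitment",
                                           "post_proliferation"),
                              p_type17 = 0.5,
                              instruct_slope = 20, instruct_center = -0.2,
                              round1_mean = 2,
                              round2_mean_type1 = 2, round2_mean_type17 = 4,
                              round2_mean_uncommitted = 3,
                              max_offspring = 12,
                              sampling_fraction = 0.15,
                              stage_label_fraction = 0.2,
                              alpha_model = default_alpha_model(),
                              beta_model = default_beta_model(),
                              resample_synonymous_nt = TRUE,
                              compute_pgen = TRUE,
                              dataset_id = "sim", seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(n_precursors >= 1, n_animals >= 1,
            p_type17 >= 0, p_type17 <= 1,
            sampling_fraction > 0, sampling_fraction <= 1,
            stage_label_fraction >= 0, stage_label_fraction < 1,
            round1_mean >= 1, round2_mean_type1 >= 1,
            round2_mean_type17 >= 1, max_offspring >= 1)
  structure(as.list(environment()), class = "simulation_config")
}

## Re-draw each codon of an in-frame junction uniformly among the codons
## encoding the same residue. Real V(D)J junctions carry enormous
## nucleotide-level entropy (nucleotide Pgens of observed receptors span
## ~1e-43 to 1e-12), which a bounded, enumerable toy event space cannot
## reach; re-randomizing the synonymous realization restores the
## essential consequence -- independent precursors virtually never share
## a nucleotide sequence -- while leaving the amino-acid generative law
## (and pgen_aa) untouched.
recode_synonymous <- function(nt) {
  if (length(nt) == 0L) return(nt)
  rev_tab <- .rev_codon_table()
  ch <- strsplit(translate_nt(nt), "")
  flat <- unlist(ch, use.names = FALSE)
  codons <- character(length(flat))
  for (a in unique(flat)) {
    idx <- which(flat == a)
    m <- rev_tab[[a]]
    rows <- sample.int(nrow(m), length(idx), replace = TRUE)
    codons[idx] <- paste0(m[rows, 1], m[rows, 2], m[rows, 3])
  }
  grp <- rep(seq_along(nt), lengths(ch))
  unname(vapply(split(codons, grp), paste, character(1), collapse = ""))
}

## Truncated shifted geometric offspring counts with mean `m` (before
## truncation at `max_n`).
.offspring <- function(n, m, max_n) {
  if (m <= 1) return(rep(1L, n))
  pmin(1L + stats::rgeom(n, 1 / m), max_n)
}

.instruct_prob <- function(config, cdr3b_aa) {
  kd <- mean_scale(cdr3b_aa, aa_scales()$hydrophobicity)
  stats::plogis(config$instruct_slope * (kd - config$instruct_center))
}

#' Simulate a ground-truthed paired scTCR dataset
#'
#' Runs the developmental model of [simulation_config()] and emits the
#' dataset in the formats the IO module reads, plus the full ground
#' truth.
#'
#' @param config A [simulation_config()].
#' @return A `clonofate_sim` list: `chains` (AIRR-style chain table, two
#'   rows per cell), `meta` (cell metadata), `truth` (list with `cells`:
#'   cell_id, precursor_id, fate, commitment_time, animal_id;
#'   `precursors`: sequences and optional toy-model Pgens; `config`).
#' @export
simulate_development <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  all_cells <- list(); all_prec <- list()
  for (a in seq_len(config$n_animals)) {
    np <- config$n_precursors
    animal <- sprintf("mouse%d", a)
    alpha <- sample_tcr(config$alpha_model, np, productive_only = TRUE)
    beta <- sample_tcr(config$beta_model, np, productive_only = TRUE)
    if (isTRUE(config$resample_synonymous_nt)) {
      alpha$nt <- recode_synonymous(alpha$nt)
      beta$nt <- recode_synonymous(beta$nt)
    }
    prec <- data.frame(
      precursor_id = sprintf("%s_p%04d", animal, seq_len(np)),
      animal_id = animal,
      va = alpha$v_name, ja = alpha$j_name,
      cdr3a_nt = alpha$nt, cdr3a_aa = alpha$aa,
      vb = beta$v_name, jb = beta$j_name,
      cdr3b_nt = beta$nt, cdr3b_aa = beta$aa,
      stringsAsFactors = FALSE)

    fate_pre <- if (config$scenario == "pre_commitment") {
      ifelse(stats::runif(np) < config$p_type17, "TYPE17", "TYPE1")
    } else rep(NA_character_, np)

    k1 <- .offspring(np, config$round1_mean, config$max_offspring)
    inter_prec <- rep(seq_len(np), k1)
    ni <- length(inter_prec)

    fate_inter <- switch(config$scenario,
      stochastic = ifelse(stats::runif(ni) < config$p_type17,
                          "TYPE17", "TYPE1"),
      instructed = {
        p <- .instruct_prob(config, prec$cdr3b_aa)[inter_prec]
        ifelse(stats::runif(ni) < p, "TYPE17", "TYPE1")
      },
      pre_commitment = fate_pre[inter_prec],
      post_proliferation = rep(NA_character_, ni))

    k2 <- if (config$scenario == "post_proliferation") {
      .offspring(ni, config$round2_mean_uncommitted, config$max_offspring)
    } else {
      m <- ifelse(fate_inter == "TYPE17",
                  config$round2_mean_type17, config$round2_mean_type1)
      pmin(1L + stats::rgeom(ni, 1 / m), config$max_offspring)
    }
    cell_inter <- rep(seq_along(inter_prec), k2)
    nc <- length(cell_inter)
    fate <- if (config$scenario == "post_proliferation") {
      ifelse(stats::runif(nc) < config$p_type17, "TYPE17", "TYPE1")
    } else fate_inter[cell_inter]

    keep <- stats::runif(nc) < config$sampling_fraction
    cell_prec <- inter_prec[cell_inter][keep]
    fate <- fate[keep]
    ns <- sum(keep)
    label <- fate
    if (ns > 0 && config$stage_label_fraction > 0) {
      staged <- stats::runif(ns) < config$stage_label_fraction
      label[staged] <- sample(c("IMMATURE", "INTERMEDIATE", "CYCLING"),
                              sum(staged), replace = TRUE)
    }
    if (ns > 0) {
      cells <- data.frame(
        cell_id = sprintf("%s_%s_c%05d", config$dataset_id, animal,
                          seq_len(ns)),
        precursor_id = prec$precursor_id[cell_prec],
        prec_idx = cell_prec,
        animal_id = animal,
        fate = fate,
        subset_label = label,
        commitment_time = switch(config$scenario,
                                 pre_commitment = "pre",
                                 post_proliferation = "post",
                                 "during"),
        stringsAsFactors = FALSE)
      all_cells[[a]] <- cells
    }
    all_prec[[a]] <- prec
  }
  cells <- do.call(rbind, all_cells)
  prec <- do.call(rbind, all_prec)
  if (is.null(cells) || nrow(cells) == 0L)
    stop("simulation produced no sampled cells; raise sampling_fraction")

  if (isTRUE(config$compute_pgen)) {
    pa <- vapply(unique(prec$cdr3a_aa), pgen_aa, numeric(1),
                 model = config$alpha_model)
    pb <- vapply(unique(prec$cdr3b_aa), pgen_aa, numeric(1),
                 model = config$beta_model)
    prec$pgen_alpha <- unname(pa[prec$cdr3a_aa])
    prec$pgen_beta <- unname(pb[prec$cdr3b_aa])
    prec$pgen_joint <- prec$pgen_alpha * prec$pgen_beta
  }

  pi <- match(cells$precursor_id, prec$precursor_id)
  chains <- rbind(
    data.frame(cell_id = cells$cell_id, locus = "TRA",
               v_gene = prec$va[pi], j_gene = prec$ja[pi],
               cdr3_nt = prec$cdr3a_nt[pi], cdr3_aa = prec$cdr3a_aa[pi],
               umi_count = 1L, productive = TRUE, stringsAsFactors = FALSE),
    data.frame(cell_id = cells$cell_id, locus = "TRB",
               v_gene = prec$vb[pi], j_gene = prec$jb[pi],
               cdr3_nt = prec$cdr3b_nt[pi], cdr3_aa = prec$cdr3b_aa[pi],
               umi_count = 1L, productive = TRUE, stringsAsFactors = FALSE))
  meta <- data.frame(cell_id = cells$cell_id, animal_id = cells$animal_id,
                     dataset_id = config$dataset_id,
                     subset_label = cells$subset_label,
                     stringsAsFactors = FALSE)
  truth <- list(
    cells = cells[c("cell_id", "precursor_id", "animal_id", "fate",
                    "subset_label", "commitment_time")],
    precursors = prec,
    config = config)
  structure(list(chains = chains, meta = meta, truth = truth),
            class = "clonofate_sim")
}

#' @export
print.clonofate_sim <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$meta), "cells,",
      length(unique(x$truth$precursors$precursor_id)), "precursors,",
      "scenario:", x$truth$config$scenario, "\n")
  invisible(x)
}

#' Convenience: QC-passed cell table of a simulated dataset
#'
#' Runs the simulated chain table and metadata through [filter_cells()].
#'
#' @param sim A `clonofate_sim`.
#' @param invariant_v Lineage-defining alpha V segment.
#' @return Cell table as from [filter_cells()].
#' @export
sim_cells <- function(sim, invariant_v = "TRAV1") {
  filter_cells(sim$chains, sim$meta, invariant_v = invariant_v)
}

#' Two replicate datasets from the same generative model
#'
#' Simulates two independent datasets (different animals, same model and
#' scenario) and maps the amino-acid clonotype keys arising independently
#' in both — the ground truth for cross-dataset sharing analyses.
#'
#' @param config A [simulation_config()]; its `seed` drives both
#'   replicates, its `dataset_id` is suffixed `_A` / `_B`.
#' @return List `dataset_a`, `dataset_b` (each `clonofate_sim`) and
#'   `shared_keys` (character vector of aa keys found in both).
#' @export
make_paired_datasets <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2)
  cfg_a <- config; cfg_a$seed <- seeds[1]
  cfg_a$dataset_id <- paste0(config$dataset_id, "_A")
  cfg_b <- config; cfg_b$seed <- seeds[2]
  cfg_b$dataset_id <- paste0(config$dataset_id, "_B")
  sim_a <- simulate_development(cfg_a)
  sim_b <- simulate_development(cfg_b)
  keys <- function(sim) {
    p <- sim$truth$precursors
    i <- match(sim$truth$cells$precursor_id, p$precursor_id)
    unique(clonotype_key_of(p$va[i], p$ja[i], p$cdr3a_aa[i],
                            p$vb[i], p$jb[i], p$cdr3b_aa[i]))
  }
  list(dataset_a = sim_a, dataset_b = sim_b,
       shared_keys = intersect(keys(sim_a), keys(sim_b)))
}

#' Write a simulated dataset bundle to disk
#'
#' @param sim A `clonofate_sim`.
#' @param dir Output directory: `chains.airr.tsv`, `meta.tsv`,
#'   `truth.json`.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_contigs(sim$chains, file.path(dir, "chains.airr.tsv"))
  utils::write.table(sim$meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$config$alpha_model <- NULL
  truth$config$beta_model <- NULL
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = I(17), dataframe = "columns")
  invisible(dir)
}
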