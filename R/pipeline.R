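## End-to-end orchestration: read (or simulate) -> QC -> clones and
## clonotypes -> fate tests -> sequence features -> classifier CV ->
## report bundle, with fixed seeds and a serialized config.

#' Run the full clonal-fate analysis pipeline
#'
#' Takes a run configuration (an R list or a YAML file path), executes
#' every stage, writes the result bundle into `out_dir`, and returns the
#' results invisibly. The configuration is serialized alongside the
#' results and its MD5 hash is embedded in every output written by the
#' run.
#'
#' Configuration fields: either `simulate` (a [simulation_config()] or a
#' list of its arguments) or `contigs`/`dialect`/`meta` input paths;
#' optional `contigs_b`/`meta_b` for a second dataset enabling the
#' cross-dataset analysis; `invariant_v` (default `"TRAV1"`), `n_iter`
#' (default 1000), `seed` (default 1), `classifier` (logical, default
#' `TRUE`: 5-fold CV of TYPE1 vs TYPE17 CDR3b when both classes have
#' enough unique sequences).
#'
#' @param config List or YAML path.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with `cells`, `clones`, `clonotypes`,
#'   `tests`, `graph`, `summaries`, and optionally `cv`,
#'   `cross_dataset`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(invariant_v = "TRAV1", n_iter = 1000, seed = 1,
                   classifier = TRUE)
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ser <- config
  if (inherits(ser$simulate, "simulation_config")) {
    ser$simulate <- unclass(ser$simulate)
    ser$simulate$alpha_model <- NULL
    ser$simulate$beta_model <- NULL
  }
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(ser, cfg_path, auto_unbox = TRUE, digits = I(17),
                       force = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  stamp <- function(path) {
    txt <- readLines(path)
    writeLines(c(paste0("# config_md5: ", cfg_hash), txt), path)
  }

  log_stage <- function(...) message("[clonofate] ", ...)

  # --- input ---------------------------------------------------------
  read_dataset <- function(contigs, dialect, meta) {
    ch <- read_contigs(contigs, dialect)
    mt <- read_cell_meta(meta)
    filter_cells(ch, mt, invariant_v = config$invariant_v)
  }
  if (!is.null(config$simulate)) {
    log_stage("simulating input dataset")
    sc <- config$simulate
    if (!inherits(sc, "simulation_config"))
      sc <- do.call(simulation_config, sc)
    sim <- simulate_development(sc)
    cells <- sim_cells(sim, invariant_v = config$invariant_v)
  } else {
    log_stage("reading ", config$contigs)
    cells <- read_dataset(config$contigs,
                          config$dialect %||% "airr_tsv", config$meta)
  }
  write_qc_report(cells, file.path(out_dir, "qc_report.tsv"))
  stamp(file.path(out_dir, "qc_report.tsv"))
  log_stage("QC-passed cells: ", nrow(cells))

  # --- clonal structure ----------------------------------------------
  clones <- assign_clones(cells)
  clonotypes <- assign_clonotypes(clones)
  write_clone_tables(clones, clonotypes, out_dir)
  stamp(file.path(out_dir, "clones.tsv"))
  stamp(file.path(out_dir, "clonotypes.tsv"))
  log_stage(nrow(clones), " clones, ", nrow(clonotypes), " clonotypes")

  # --- fate inference ------------------------------------------------
  tests <- list()
  tests$mixed_clone_count <- count_mixed_clones(clones)
  eligible <- sum(vapply(clonotypes$clone_annotations, function(a)
    sum(a %in% c("TYPE1", "TYPE17")) >= 2, logical(1)))
  if (eligible >= 2) {
    tests$mixed_multiclone <- mixed_multiclone_test(
      clonotypes, n_iter = config$n_iter, seed = config$seed)
    write_shuffle_result(tests$mixed_multiclone,
                         file.path(out_dir, "mixed_multiclone_test.json"),
                         extra = list(config_md5 = cfg_hash))
  } else log_stage("skipping multi-clone test: ", eligible,
                   " eligible clonotype(s)")
  tests$post_proliferation <- post_proliferation_test(
    cells, n_iter = config$n_iter, seed = config$seed + 1L)
  write_shuffle_result(tests$post_proliferation,
                       file.path(out_dir, "post_proliferation_test.json"),
                       extra = list(config_md5 = cfg_hash))
  jsonlite::write_json(
    list(config_md5 = cfg_hash,
         mixed_clone_count = tests$mixed_clone_count),
    file.path(out_dir, "mixed_clone_count.json"),
    auto_unbox = TRUE, digits = I(17))

  # --- optional second dataset ---------------------------------------
  cross <- NULL
  if (!is.null(config$contigs_b)) {
    log_stage("reading second dataset ", config$contigs_b)
    cells_b <- read_dataset(config$contigs_b,
                            config$dialect_b %||% config$dialect %||%
                              "airr_tsv",
                            config$meta_b)
    ct_b <- assign_clonotypes(assign_clones(cells_b))
    shared <- shared_clonotypes(clonotypes, ct_b)
    if (nrow(shared) >= 2) {
      cross <- list(concordance = cross_dataset_concordance(shared),
                    test = cross_dataset_test(shared,
                                              n_iter = config$n_iter,
                                              seed = config$seed + 2L))
      write_shuffle_result(cross$test,
                           file.path(out_dir, "cross_dataset_test.json"),
                           extra = list(config_md5 = cfg_hash))
    } else log_stage("skipping cross-dataset test: ", nrow(shared),
                     " shared clonotype(s)")
  }

  # --- sequence features ---------------------------------------------
  graph <- build_similarity_graph(clonotypes)
  write_similarity_graph(graph, out_dir)
  stamp(file.path(out_dir, "edges.tsv"))
  stamp(file.path(out_dir, "components.tsv"))
  if (length(graph$components) &&
      length(graph$components[[1]]) >= 2) {
    comp_seqs <- graph$vertices$cdr3b_aa[
      match(graph$components[[1]], graph$vertices$id)]
    write_pfm(cluster_profile(comp_seqs),
              file.path(out_dir, "largest_cluster_pfm.tsv"))
    stamp(file.path(out_dir, "largest_cluster_pfm.tsv"))
  }
  summaries <- repertoire_summaries(clonotypes)
  groups <- split(clonotypes$cdr3b_aa, clonotypes$subset_annotation)
  prof <- do.call(rbind, lapply(
    c("basicity", "hydrophobicity", "helix_propensity"),
    function(p) physchem_profile(groups, property = p)))
  utils::write.table(prof, file.path(out_dir, "physchem_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stamp(file.path(out_dir, "physchem_profiles.tsv"))

  # --- classifier -----------------------------------------------------
  cv <- NULL
  if (isTRUE(config$classifier)) {
    s1 <- unique(clonotypes$cdr3b_aa[clonotypes$subset_annotation == "TYPE1"])
    s17 <- unique(clonotypes$cdr3b_aa[clonotypes$subset_annotation ==
                                        "TYPE17"])
    if (length(s1) >= 25 && length(s17) >= 25) {
      log_stage("5-fold CV, TYPE1 vs TYPE17 CDR3b (",
                length(s1), " vs ", length(s17), " unique sequences)")
      cv <- crossvalidate(s1, s17, k = 5, seed = config$seed + 3L)
      jsonlite::write_json(
        list(config_md5 = cfg_hash, mean_auc = cv$mean_auc,
             fold_auc = vapply(cv$folds, `[[`, numeric(1), "auc")),
        file.path(out_dir, "classifier_cv.json"),
        auto_unbox = TRUE, digits = I(17))
    } else log_stage("skipping classifier: too few unique sequences")
  }

  log_stage("pipeline complete: ", out_dir)
  invisible(list(cells = cells, clones = clones, clonotypes = clonotypes,
                 tests = tests, cross_dataset = cross, graph = graph,
                 summaries = summaries, cv = cv,
                 config_md5 = cfg_hash))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
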