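## Reading single-cell TCR contig tables (10x / AIRR), cell metadata, and
## the chain-level QC producing one designated alpha-beta pair per cell.

.TENX_COLS <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "cdr3_nt",
                "umis", "productive")
.AIRR_COLS <- c("cell_id", "locus", "v_call", "j_call", "junction",
                "junction_aa", "duplicate_count", "productive")

empty_chains <- function() {
  data.frame(cell_id = character(0), locus = character(0),
             v_gene = character(0), j_gene = character(0),
             cdr3_nt = character(0), cdr3_aa = character(0),
             umi_count = integer(0), productive = logical(0),
             stringsAsFactors = FALSE)
}

strip_allele <- function(x) sub("\\*.*$", "", x)

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Read a single-cell TCR contig table
#'
#' Parses either the 10x Cell Ranger VDJ `filtered_contig_annotations.csv`
#' dialect or an AIRR Rearrangement TSV into a normalized chain table with
#' one row per productive contig. Nonproductive rows and rows with an empty
#' CDR3 (nucleotide or amino acid) are dropped with a message; V/J gene
#' names are normalized by stripping allele suffixes (`"*01"`).
#'
#' @param path Path to the contig table.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @return A data frame with columns `cell_id`, `locus` (TRA/TRB),
#'   `v_gene`, `j_gene`, `cdr3_nt`, `cdr3_aa`, `umi_count`, `productive`.
#' @export
read_contigs <- function(path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty contig file: ", path)
    return(empty_chains())
  }
  if (dialect == "tenx_csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    miss <- setdiff(.TENX_COLS, names(raw))
    if (length(miss))
      stop("contig table is missing required column(s): ",
           paste(miss, collapse = ", "))
    chains <- data.frame(
      cell_id = raw$barcode, locus = raw$chain,
      v_gene = strip_allele(raw$v_gene), j_gene = strip_allele(raw$j_gene),
      cdr3_nt = toupper(raw$cdr3_nt), cdr3_aa = raw$cdr3,
      umi_count = as.integer(raw$umis), productive = parse_flag(raw$productive),
      stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    miss <- setdiff(.AIRR_COLS, names(raw))
    if (length(miss))
      stop("contig table is missing required column(s): ",
           paste(miss, collapse = ", "))
    chains <- data.frame(
      cell_id = raw$cell_id, locus = raw$locus,
      v_gene = strip_allele(raw$v_call), j_gene = strip_allele(raw$j_call),
      cdr3_nt = toupper(raw$junction), cdr3_aa = raw$junction_aa,
      umi_count = as.integer(raw$duplicate_count),
      productive = parse_flag(raw$productive),
      stringsAsFactors = FALSE)
  }
  if (nrow(chains) == 0L) {
    warning("contig file has no data rows: ", path)
    return(empty_chains())
  }
  keep <- chains$productive & !is.na(chains$cdr3_nt) & nzchar(chains$cdr3_nt) &
    !is.na(chains$cdr3_aa) & nzchar(chains$cdr3_aa)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("read_contigs: dropped ", n_drop,
            " nonproductive or CDR3-less row(s)")
  chains <- chains[keep, , drop = FALSE]
  rownames(chains) <- NULL
  chains
}

#' Write a chain table as an AIRR Rearrangement TSV
#'
#' Inverse of [read_contigs()] for the AIRR dialect; used to materialize
#' simulated repertoires in a standard interchange format.
#'
#' @param chains Chain table as returned by [read_contigs()].
#' @param path Output TSV path.
#' @export
write_contigs <- function(chains, path) {
  out <- data.frame(
    cell_id = chains$cell_id, locus = chains$locus,
    v_call = chains$v_gene, j_call = chains$j_gene,
    junction = chains$cdr3_nt, junction_aa = chains$cdr3_aa,
    duplicate_count = chains$umi_count,
    productive = ifelse(chains$productive, "T", "F"),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell metadata table
#'
#' Expects a TSV with header `cell_id`, `animal_id`, `dataset_id`,
#' `subset_label`; subset labels come from upstream transcriptome
#' clustering and must be one of TYPE1, TYPE17, IMMATURE, INTERMEDIATE,
#' CYCLING, UNASSIGNED.
#'
#' @param path Path to the metadata TSV.
#' @return Data frame with the four columns above.
#' @export
read_cell_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  req <- c("cell_id", "animal_id", "dataset_id", "subset_label")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata is missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- setdiff(unique(meta$subset_label), SUBSET_LEVELS)
  if (length(bad))
    stop("unknown subset label(s): ", paste(bad, collapse = ", "))
  meta[req]
}

#' Chain-level QC: one designated alpha-beta pair per retained cell
#'
#' Applies the chain-count rules used for semi-invariant T cell
#' repertoires. Cells with two (or more) TRB contigs are excluded as
#' probable doublets; cells with no TRA are excluded; cells with one TRA
#' and one TRB are kept. Cells with exactly two TRA chains are kept only
#' if exactly one of them uses the lineage-defining V segment
#' (`invariant_v`, e.g. TRAV1 for MAIT or TRAV11 for iNKT); that chain
#' becomes the designated alpha and the cell is flagged `dual_alpha`.
#' Duplicate contigs for the same locus that differ only in UMI support
#' are collapsed to the highest-UMI contig before the chain-count rules.
#'
#' @param chains Chain table from [read_contigs()].
#' @param meta Cell metadata from [read_cell_meta()].
#' @param invariant_v Lineage-defining alpha V segment name.
#' @param strip_barcode_suffix If `TRUE`, strip a trailing `"-<digits>"`
#'   from barcodes on both sides before matching. Default `FALSE` (exact
#'   string equality).
#' @return Data frame of retained cells (one row per cell: identifiers,
#'   subset label, designated alpha and beta V/J/CDR3 fields,
#'   `dual_alpha`), with attributes `qc` (per-reason drop counts) and
#'   `unmatched` (barcodes present in `chains` but absent from `meta`).
#' @export
filter_cells <- function(chains, meta, invariant_v = "TRAV1",
                         strip_barcode_suffix = FALSE) {
  if (strip_barcode_suffix) {
    chains$cell_id <- sub("-\\d+$", "", chains$cell_id)
    meta$cell_id <- sub("-\\d+$", "", meta$cell_id)
  }
  all_ids <- unique(chains$cell_id)
  unmatched <- setdiff(all_ids, meta$cell_id)
  chains <- chains[chains$cell_id %in% meta$cell_id, , drop = FALSE]

  # collapse same-chain contigs differing only in UMI support
  if (nrow(chains)) {
    ord <- order(chains$cell_id, chains$locus, -chains$umi_count)
    chains <- chains[ord, , drop = FALSE]
    dup_key <- paste(chains$cell_id, chains$locus, chains$v_gene,
                     chains$j_gene, chains$cdr3_nt, sep = "\r")
    chains <- chains[!duplicated(dup_key), , drop = FALSE]
  }

  ids <- unique(chains$cell_id)
  tra <- chains[chains$locus == "TRA", , drop = FALSE]
  trb <- chains[chains$locus == "TRB", , drop = FALSE]
  n_tra <- table(factor(tra$cell_id, levels = ids))
  n_trb <- table(factor(trb$cell_id, levels = ids))

  reason <- character(length(ids))
  names(reason) <- ids
  reason[n_trb[ids] >= 2] <- "multi_TRB"
  reason[reason == "" & n_trb[ids] == 0] <- "no_TRB"
  reason[reason == "" & n_tra[ids] == 0] <- "no_TRA"
  reason[reason == "" & n_tra[ids] > 2] <- "multi_TRA"

  # dual-TRA resolution
  dual_ids <- ids[reason[ids] == "" & n_tra[ids] == 2]
  dual_alpha <- setNames(rep(FALSE, length(ids)), ids)
  designated <- tra[tra$cell_id %in% ids[reason[ids] == "" & n_tra[ids] == 1],
                    , drop = FALSE]
  if (length(dual_ids)) {
    dtra <- tra[tra$cell_id %in% dual_ids, , drop = FALSE]
    inv <- dtra$v_gene == invariant_v
    n_inv <- tapply(inv, factor(dtra$cell_id, levels = dual_ids), sum)
    reason[dual_ids[n_inv == 0]] <- "dual_TRA_no_invariant"
    reason[dual_ids[n_inv == 2]] <- "dual_TRA_both_invariant"
    keep_dual <- dual_ids[n_inv == 1]
    dual_alpha[keep_dual] <- TRUE
    designated <- rbind(designated,
                        dtra[inv & dtra$cell_id %in% keep_dual, , drop = FALSE])
  }

  kept <- ids[reason[ids] == ""]
  reason[kept] <- "kept"
  a <- designated[match(kept, designated$cell_id), , drop = FALSE]
  b <- trb[match(kept, trb$cell_id), , drop = FALSE]
  m <- meta[match(kept, meta$cell_id), , drop = FALSE]
  cells <- data.frame(
    cell_id = kept, animal_id = m$animal_id, dataset_id = m$dataset_id,
    subset_label = m$subset_label,
    va = a$v_gene, ja = a$j_gene, cdr3a_nt = a$cdr3_nt, cdr3a_aa = a$cdr3_aa,
    vb = b$v_gene, jb = b$j_gene, cdr3b_nt = b$cdr3_nt, cdr3b_aa = b$cdr3_aa,
    dual_alpha = unname(dual_alpha[kept]),
    stringsAsFactors = FALSE)
  rownames(cells) <- NULL

  qc_levels <- c("kept", "multi_TRB", "no_TRB", "no_TRA", "multi_TRA",
                 "dual_TRA_no_invariant", "dual_TRA_both_invariant",
                 "unmatched_barcode")
  counts <- table(factor(reason, levels = qc_levels))
  counts["unmatched_barcode"] <- length(unmatched)
  attr(cells, "qc") <- data.frame(reason = qc_levels,
                                  count = as.integer(counts),
                                  stringsAsFactors = FALSE)
  attr(cells, "unmatched") <- unmatched
  cells
}

#' Write the QC report produced by [filter_cells()]
#'
#' @param cells Result of [filter_cells()].
#' @param path Output TSV path (columns `reason`, `count`).
#' @export
write_qc_report <- function(cells, path) {
  utils::write.table(attr(cells, "qc"), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## Reconstruct a chain table from a cell table (used for idempotence checks
## and for feeding a filtered dataset back through the pipeline).
cells_to_chains <- function(cells) {
  rbind(
    data.frame(cell_id = cells$cell_id, locus = "TRA", v_gene = cells$va,
               j_gene = cells$ja, cdr3_nt = cells$cdr3a_nt,
               cdr3_aa = cells$cdr3a_aa, umi_count = 1L, productive = TRUE,
               stringsAsFactors = FALSE),
    data.frame(cell_id = cells$cell_id, locus = "TRB", v_gene = cells$vb,
               j_gene = cells$jb, cdr3_nt = cells$cdr3b_nt,
               cdr3_aa = cells$cdr3b_aa, umi_count = 1L, productive = TRUE,
               stringsAsFactors = FALSE))
}
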