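#' Build and validate a probe annotation table
#'
#' A probe panel couples exactly one gene to each bead barcode (1:1), in
#' contrast to the standard 978-gene L1000 pool's 2:1 duplexing.  Probes with
#' `invariant_level` in 1..10 form the invariant calibration ladder; level 0
#' marks ordinary panel genes.
#'
#' @param gene_id stable gene identifiers (symbol or Ensembl).
#' @param gene_symbol HGNC symbols (upper-cased).
#' @param bead_barcode bead barcode strings, unique within the panel.
#' @param invariant_level integer 0 (panel gene) or 1..10 (invariant ladder).
#' @param panel panel tag, recycled.
#' @return a `data.frame` with class `probe_table`.
#' @export
probe_table <- function(gene_id, gene_symbol = gene_id, bead_barcode,
                        invariant_level = 0L, panel = "panel") {
  df <- data.frame(gene_id = as.character(gene_id),
                   gene_symbol = toupper(as.character(gene_symbol)),
                   bead_barcode = as.character(bead_barcode),
                   invariant_level = as.integer(invariant_level),
                   panel = as.character(panel),
                   stringsAsFactors = FALSE)
  validate_probe_table(df)
}

#' @rdname probe_table
#' @param probes a candidate probe table.
#' @export
validate_probe_table <- function(probes) {
  need <- c("gene_id", "gene_symbol", "bead_barcode", "invariant_level",
            "panel")
  miss <- setdiff(need, names(probes))
  if (length(miss))
    stop("probe table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(probes[c("panel", "bead_barcode")]))
    stop("bead barcodes must be unique within a panel")
  if (anyDuplicated(probes[c("panel", "gene_id")]))
    stop("each gene may appear once per panel (1:1 barcode:gene coupling)")
  lv <- probes$invariant_level
  if (any(is.na(lv)) || any(lv < 0L) || any(lv > 10L))
    stop("invariant_level must be 0 (panel) or 1..10 (invariant ladder)")
  present <- sort(unique(lv[lv > 0L]))
  if (length(present) && !identical(present, seq_len(max(present))))
    stop("invariant ladder levels must form contiguous non-empty sets 1..K")
  class(probes) <- c("probe_table", "data.frame")
  probes
}

#' Parse a "value unit" string such as "0.5 uM" or "24 h"
#'
#' @param x character vector of dose/time strings.
#' @return data.frame with columns `value` (numeric) and `unit` (character);
#'   unparseable entries yield `NA` value and the verbatim string as unit.
#' @export
parse_value_unit <- function(x) {
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*(\\S*)\\s*$",
                             as.character(x)))
  value <- vapply(m, function(g)
    if (length(g) == 3L) suppressWarnings(as.numeric(g[2L])) else NA_real_,
    numeric(1))
  unit <- vapply(seq_along(m), function(i)
    if (length(m[[i]]) == 3L && !is.na(value[i])) m[[i]][3L]
    else as.character(x[i]), character(1))
  data.frame(value = value, unit = unit, stringsAsFactors = FALSE)
}

#' Build and validate a sample (well) metadata table
#'
#' One row per profiled well.  The replicate-group key is a pure function of
#' (pert_id, cell_id, pert_dose, pert_time): biological replicates of the same
#' perturbagen/cell/dose/time share a key and are collapsed into one signature.
#'
#' @param sample_id unique profile ids.
#' @param plate_id detection-plate grouping key (scope of quantile
#'   normalization and of the robust z-score reference distribution).
#' @param well well position string.
#' @param pert_id perturbagen id (e.g. compound id, or vehicle id for
#'   controls).
#' @param pert_type one of `"CP"` (compound), `"CTRL"` (vehicle control),
#'   `"KD"` (knockdown), `"OE"` (overexpression).
#' @param pert_dose,pert_time verbatim value+unit strings ("0.5 uM", "24 h");
#'   parsed values are stored alongside for numeric filtering.
#' @param cell_id cell line id.
#' @return a `data.frame` with class `sample_table`, including parsed
#'   `dose_value`/`dose_unit`/`time_value`/`time_unit` and the derived
#'   `replicate_group` key.
#' @export
sample_table <- function(sample_id, plate_id, well, pert_id, pert_type,
                         pert_dose, pert_time, cell_id) {
  pert_type <- as.character(pert_type)
  bad <- setdiff(unique(pert_type), c("CP", "CTRL", "KD", "OE"))
  if (length(bad))
    stop("unknown pert_type values: ", paste(bad, collapse = ", "))
  df <- data.frame(sample_id = as.character(sample_id),
                   plate_id = as.character(plate_id),
                   well = as.character(well),
                   pert_id = as.character(pert_id),
                   pert_type = pert_type,
                   pert_dose = as.character(pert_dose),
                   pert_time = as.character(pert_time),
                   cell_id = as.character(cell_id),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("sample_id must be unique")
  d <- parse_value_unit(df$pert_dose)
  tm <- parse_value_unit(df$pert_time)
  df$dose_value <- d$value; df$dose_unit <- d$unit
  df$time_value <- tm$value; df$time_unit <- tm$unit
  df$replicate_group <- replicate_group_key(df$pert_id, df$cell_id,
                                            df$pert_dose, df$pert_time)
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Replicate-group key
#'
#' Deterministic key identifying a replicate set; a pure function of its four
#' components, independent of sample order.
#'
#' @param pert_id,cell_id,dose,time character vectors, recycled.
#' @return character vector of keys.
#' @export
replicate_group_key <- function(pert_id, cell_id, dose, time) {
  paste(pert_id, cell_id, dose, time, sep = ":")
}

#' Read a differential-expression table
#'
#' Reads a delimited DEG table, normalizes gene symbols to upper case,
#' optionally maps Ensembl ids to symbols through a caller-supplied two-column
#' table (no network lookups), and resolves duplicated gene ids by keeping the
#' row with the largest absolute log2 fold change.  Dropped-row counts are
#' reported via `message()`.
#'
#' @param path path to a delimited text file (TSV/CSV autodetected by
#'   `data.table::fread`).
#' @param id_column,lfc_column name of the gene-id and log2-fold-change
#'   columns.
#' @param sig_column optional name of a significance column (p or FDR) carried
#'   through as `fdr`; `NULL` to omit.
#' @param id_map optional two-column data.frame (from-id, symbol) used to map
#'   identifiers (e.g. Ensembl to HGNC); unmappable rows are dropped.
#' @return data.frame with columns `gene_id`, `log2_fold_change` and, when
#'   available, `fdr`; class `deg_table`.
#' @export
read_deg_table <- function(path, id_column = "gene_id",
                           lfc_column = "log2_fold_change",
                           sig_column = NULL, id_map = NULL) {
  df <- as.data.frame(data.table::fread(path))
  deg_table(df, id_column = id_column, lfc_column = lfc_column,
            sig_column = sig_column, id_map = id_map)
}

#' @rdname read_deg_table
#' @param df an in-memory data.frame of DEG rows.
#' @export
deg_table <- function(df, id_column = "gene_id",
                      lfc_column = "log2_fold_change", sig_column = NULL,
                      id_map = NULL) {
  for (col in c(id_column, lfc_column, sig_column)) {
    if (!col %in% names(df))
      stop("column '", col, "' not found; available: ",
           paste(names(df), collapse = ", "))
  }
  out <- data.frame(gene_id = toupper(as.character(df[[id_column]])),
                    log2_fold_change = as.numeric(df[[lfc_column]]),
                    stringsAsFactors = FALSE)
  if (!is.null(sig_column)) out$fdr <- as.numeric(df[[sig_column]])
  if (!is.null(id_map)) {
    id_map <- as.data.frame(id_map)
    key <- toupper(as.character(id_map[[1L]]))
    sym <- toupper(as.character(id_map[[2L]]))
    hit <- match(out$gene_id, key)
    n_unmapped <- sum(is.na(hit))
    if (n_unmapped)
      message(n_unmapped, " DEG rows dropped: id not in mapping table")
    out <- out[!is.na(hit), , drop = FALSE]
    out$gene_id <- sym[hit[!is.na(hit)]]
  }
  bad <- !is.finite(out$log2_fold_change)
  if (any(bad)) {
    message(sum(bad), " DEG rows dropped: non-finite log2 fold change")
    out <- out[!bad, , drop = FALSE]
  }
  if (anyDuplicated(out$gene_id)) {
    ord <- order(out$gene_id, -abs(out$log2_fold_change))
    out <- out[ord, , drop = FALSE]
    dup <- duplicated(out$gene_id)
    message(sum(dup), " duplicate DEG rows dropped (kept max |log2FC|)")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}
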