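# Readers and validators for the external table dialects: conservation
# scores (TargetScan summary-counts style), gene-class annotations, CNV
# event counts, and male/female expression ratios; plus gene-level
# aggregation of interaction scores.

GENE_CLASSES <- c("XY_pair", "X_inactivated", "X_escape",
                  "ZW_pair", "Z_noW", "autosomal")

# accepted column aliases for the conservation-score table
.pct_aliases <- list(
  gene_id = c("gene_id", "Gene Symbol", "Gene ID", "gene"),
  family_id = c("family_id", "miRNA family", "family"),
  pct = c("pct", "Aggregate PCT", "aggregate_pct")
)

.pick_column <- function(df, aliases, table_name) {
  hit <- aliases[aliases %in% names(df)]
  if (length(hit) == 0L) {
    stop(table_name, " lacks a required column; expected one of: ",
         paste(aliases, collapse = ", "),
         " (found: ", paste(names(df), collapse = ", "), ")")
  }
  hit[1]
}

#' Read an interaction-level conservation-score table
#'
#' Accepts the TargetScan summary-counts column names ("Gene Symbol",
#' "miRNA family", "Aggregate PCT") or plain gene_id/family_id/pct.
#' Rows with missing scores are dropped (with a message); duplicate
#' (gene, family) interactions are an error.
#'
#' @param path TSV path.
#' @param family_filter optional character vector of family ids to keep.
#' @return data.frame with columns gene_id, family_id, pct (each in [0,1]).
#' @export
read_pct_table <- function(path, family_filter = NULL) {
  df <- read_tsv_meta(path)
  cols <- vapply(names(.pct_aliases), function(k) {
    .pick_column(df, .pct_aliases[[k]], paste0("score table ", path))
  }, character(1))
  out <- data.frame(gene_id = as.character(df[[cols["gene_id"]]]),
                    family_id = as.character(df[[cols["family_id"]]]),
                    pct = suppressWarnings(as.numeric(df[[cols["pct"]]])),
                    stringsAsFactors = FALSE)
  n_na <- sum(is.na(out$pct))
  if (n_na > 0) {
    message("read_pct_table: dropped ", n_na, " interaction(s) without a score")
    out <- out[!is.na(out$pct), , drop = FALSE]
  }
  if (!is.null(family_filter)) {
    out <- out[out$family_id %in% family_filter, , drop = FALSE]
  }
  key <- paste(out$gene_id, out$family_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- out[duplicated(key), c("gene_id", "family_id")]
    stop("duplicated (gene, family) interaction(s) in ", path, ": ",
         paste(paste(dup$gene_id, dup$family_id, sep = "/"), collapse = ", "))
  }
  if (any(out$pct < 0 | out$pct > 1)) {
    stop("scores outside [0, 1] in ", path)
  }
  rownames(out) <- NULL
  out
}

#' Gene-level mean conservation score
#'
#' Arithmetic mean over each gene's scored interactions; genes without any
#' scored interaction are absent from the output (not imputed at 0).
#'
#' @param records data.frame from [read_pct_table()].
#' @return named numeric vector, gene_id -> mean score.
#' @export
gene_mean_pct <- function(records) {
  if (nrow(records) == 0L) stop("no interaction records")
  tapply(records$pct, records$gene_id, mean)[unique(records$gene_id)]
}

#' Classify genes by copy-number-variation event counts
#'
#' @param gene_events data.frame with columns gene_id, dup_events,
#'   del_events (nonnegative integers).
#' @param dup_threshold,del_threshold minimum event count to flag a gene
#'   as duplicated / deleted (default 1: any event).
#' @return data.frame gene_id, duplicated, deleted.
#' @export
classify_cnv <- function(gene_events, dup_threshold = 1L, del_threshold = 1L) {
  need <- c("gene_id", "dup_events", "del_events")
  missing <- setdiff(need, names(gene_events))
  if (length(missing) > 0) {
    stop("CNV table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(gene_events$dup_events < 0 | gene_events$del_events < 0)) {
    stop("negative CNV event counts")
  }
  data.frame(gene_id = gene_events$gene_id,
             duplicated = gene_events$dup_events >= dup_threshold,
             deleted = gene_events$del_events >= del_threshold,
             stringsAsFactors = FALSE)
}

#' Read a gene-class annotation table
#'
#' Expects columns gene_id and class (one of XY_pair, X_inactivated,
#' X_escape, ZW_pair, Z_noW, autosomal); optional logical `xar` and
#' covariate columns pHI, expression_breadth, dnds.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_gene_annotations <- function(path) {
  df <- read_tsv_meta(path)
  need <- c("gene_id", "class")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("annotation table ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(df$class), GENE_CLASSES)
  if (length(bad) > 0) {
    stop("unknown gene class label(s) in ", path, ": ",
         paste(bad, collapse = ", "),
         " (expected one of: ", paste(GENE_CLASSES, collapse = ", "), ")")
  }
  if (anyDuplicated(df$gene_id)) {
    stop("gene(s) annotated more than once in ", path, ": ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  if ("xar" %in% names(df)) df$xar <- as.logical(df$xar)
  df
}

#' Read a per-gene male/female expression-ratio table
#'
#' @param path TSV with columns gene_id, species, tissue, log2_mf.
#' @return data.frame with finite log2_mf only; non-finite rows are
#'   dropped with a message.
#' @export
read_expression_ratios <- function(path) {
  df <- read_tsv_meta(path)
  need <- c("gene_id", "species", "tissue", "log2_mf")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("expression-ratio table ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  }
  df$log2_mf <- suppressWarnings(as.numeric(df$log2_mf))
  bad <- !is.finite(df$log2_mf)
  if (any(bad)) {
    message("read_expression_ratios: dropped ", sum(bad),
            " non-finite ratio(s)")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}
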