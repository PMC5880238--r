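# File-based pipeline orchestration.
#
# Stages communicate through TSV/FASTA files in a run directory, so any
# stage's inputs can be swapped for real data (e.g. published conservation
# scores) without code changes. Every output carries a '# key=value'
# metadata header recording the configuration hash and seeds; no
# timestamps are written, so reruns with identical configuration are
# byte-identical.

.stage_files <- list(
  simulate = c("alignments.fasta", "families.tsv", "annotations.tsv",
               "cnv.tsv", "pct.tsv", "expression.tsv", "truth_sites.tsv",
               "truth_genes.tsv", "config.tsv"),
  scan = "sites.tsv",
  conserve = "conserved.tsv",
  background = "background.tsv",
  segment = c("segments.tsv", "regional_scores.tsv"),
  compare = c("comparisons.tsv", "resampling.tsv"),
  fit = c("model.tsv", "ablation.tsv"),
  report = "report.md"
)

.run_path <- function(dir, file) file.path(dir, file)

.require_stage_file <- function(dir, file, produced_by) {
  p <- .run_path(dir, file)
  if (!file.exists(p)) {
    stop("missing ", file, " in ", dir, "; run stage '", produced_by,
         "' first")
  }
  p
}

# stable hash of the configuration (via a temp file and md5)
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(config[order(names(config))], file = tf)
  unname(tools::md5sum(tf))
}

.meta_for <- function(config, extra = list()) {
  c(list(package = "mirdosage", config_hash = config_hash(config),
         rng_seed = config$rng_seed), extra)
}

#' Write the simulated inputs of a run
#'
#' Generates alignments, families, annotations, CNV counts, interaction
#' scores and expression ratios under `config` and writes them (plus the
#' planted-site truth tables used only by tests) into `dir`.
#'
#' @param config a [simulation_config()].
#' @param dir run directory (created if absent).
#' @return `dir`, invisibly.
#' @export
stage_simulate <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- .meta_for(config)
  sim <- simulate_utr_alignments(config, rng_seed = config$rng_seed)
  write_utr_alignments(sim$alignments, .run_path(dir, "alignments.fasta"))
  write_mirna_families(sim$families, .run_path(dir, "families.tsv"), meta)
  ann <- simulate_annotations(config, sim$genes,
                              rng_seed = config$rng_seed + 1L)
  write_tsv_meta(ann, .run_path(dir, "annotations.tsv"), meta)
  cnv <- simulate_cnv_status(config, sim$genes,
                             rng_seed = config$rng_seed + 2L)
  write_tsv_meta(cnv, .run_path(dir, "cnv.tsv"), meta)
  pct <- simulate_pct_table(config, sim$genes,
                            rng_seed = config$rng_seed + 3L)
  write_tsv_meta(pct, .run_path(dir, "pct.tsv"), meta)
  scores <- gene_mean_pct(pct)
  expr <- simulate_expression_ratios(config, scores, ann,
                                     rng_seed = config$rng_seed + 4L)
  write_tsv_meta(expr, .run_path(dir, "expression.tsv"), meta)
  if (!is.null(sim$truth)) {
    write_tsv_meta(sim$truth, .run_path(dir, "truth_sites.tsv"), meta)
  }
  write_tsv_meta(sim$genes, .run_path(dir, "truth_genes.tsv"), meta)
  cfg_df <- data.frame(key = names(config),
                       value = vapply(config, function(v)
                         paste(as.character(unlist(v)), collapse = ","),
                         character(1)),
                       stringsAsFactors = FALSE)
  write_tsv_meta(cfg_df, .run_path(dir, "config.tsv"), meta)
  invisible(dir)
}

#' Scan reference UTRs for target sites of every family
#'
#' Reads `alignments.fasta` and `families.tsv`, scans the ungapped
#' reference row of each gene and writes `sites.tsv`.
#'
#' @param config a [simulation_config()] (supplies reference species and
#'   metadata).
#' @param dir run directory.
#' @return `dir`, invisibly.
#' @export
stage_scan <- function(config, dir) {
  fa <- .require_stage_file(dir, "alignments.fasta", "simulate")
  famp <- .require_stage_file(dir, "families.tsv", "simulate")
  alignments <- read_utr_alignments(fa, config$species_list[1])
  families <- read_mirna_families(famp)
  sites <- do.call(rbind, lapply(alignments, function(aln) {
    scan_utr_families(reference_utr(aln), families, gene_id = aln$gene_id)
  }))
  write_tsv_meta(sites, .run_path(dir, "sites.tsv"), .meta_for(config))
  invisible(dir)
}

#' Call conserved sites for each reference/partner species pair
#'
#' @inheritParams stage_scan
#' @return `dir`, invisibly.
#' @export
stage_conserve <- function(config, dir) {
  fa <- .require_stage_file(dir, "alignments.fasta", "simulate")
  famp <- .require_stage_file(dir, "families.tsv", "simulate")
  alignments <- read_utr_alignments(fa, config$species_list[1])
  families <- read_mirna_families(famp)
  ref <- config$species_list[1]
  rows <- list()
  for (partner in config$species_list[-1]) {
    for (aln in alignments) {
      cc <- count_conserved_sites(aln, families, ref, partner)
      if (nrow(cc$sites) > 0) {
        s <- cc$sites
        s$species_a <- ref
        s$species_b <- partner
        rows[[length(rows) + 1L]] <- s
      }
    }
  }
  conserved <- if (length(rows) > 0) do.call(rbind, rows) else
    cbind(empty_sites(), conserved = logical(0),
          species_a = character(0), species_b = character(0))
  write_tsv_meta(conserved, .run_path(dir, "conserved.tsv"),
                 .meta_for(config))
  invisible(dir)
}

#' Shuffled-seed background null for every gene and species pair
#'
#' @inheritParams stage_scan
#' @param n_shuffles shuffle replicates per gene.
#' @return `dir`, invisibly.
#' @export
stage_background <- function(config, dir, n_shuffles = 50L) {
  fa <- .require_stage_file(dir, "alignments.fasta", "simulate")
  famp <- .require_stage_file(dir, "families.tsv", "simulate")
  alignments <- read_utr_alignments(fa, config$species_list[1])
  families <- read_mirna_families(famp)
  ref <- config$species_list[1]
  rows <- list()
  i <- 0L
  for (partner in config$species_list[-1]) {
    for (aln in alignments) {
      i <- i + 1L
      bg <- shuffled_seed_null(aln, families, c(ref, partner),
                               n_shuffles = n_shuffles,
                               rng_seed = config$rng_seed + 100L + i)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = bg$gene_id, species_a = ref, species_b = partner,
        n_sites = bg$n_sites_observed, n_conserved = bg$observed_conserved,
        expected = bg$expected_conserved, sd = bg$sd_conserved, z = bg$z,
        stringsAsFactors = FALSE)
    }
  }
  write_tsv_meta(do.call(rbind, rows), .run_path(dir, "background.tsv"),
                 .meta_for(config, list(n_shuffles = n_shuffles)))
  invisible(dir)
}

#' Segment per-gene conservation signals and score sites regionally
#'
#' @inheritParams stage_scan
#' @param penalty per-breakpoint penalty (default log signal length).
#' @param min_segment_length minimum segment length (nt).
#' @return `dir`, invisibly.
#' @export
stage_segment <- function(config, dir, penalty = NULL,
                          min_segment_length = 50L) {
  fa <- .require_stage_file(dir, "alignments.fasta", "simulate")
  consp <- .require_stage_file(dir, "conserved.tsv", "conserve")
  alignments <- read_utr_alignments(fa, config$species_list[1])
  conserved <- read_tsv_meta(consp)
  ref <- config$species_list[1]
  partner <- config$species_list[2]
  seg_rows <- list()
  score_rows <- list()
  for (aln in alignments) {
    sig <- per_column_conservation_signal(aln, c(ref, partner))
    seg <- segment_utr_conservation(sig, penalty = penalty,
                                    min_segment_length = min_segment_length)
    seg_rows[[length(seg_rows) + 1L]] <- data.frame(
      gene_id = aln$gene_id,
      breakpoints = paste(seg$breakpoints, collapse = ","),
      levels = paste(sprintf("%.6g", seg$segment_levels), collapse = ","),
      stringsAsFactors = FALSE)
    sites <- conserved[conserved$gene_id == aln$gene_id &
                         conserved$species_b == partner, , drop = FALSE]
    if (nrow(sites) > 0) {
      sc <- vapply(seq_len(nrow(sites)), function(i) {
        regional_normalized_score(sites[i, ], sites$conserved[i], seg)
      }, numeric(1))
      score_rows[[length(score_rows) + 1L]] <- data.frame(
        gene_id = aln$gene_id, family_id = sites$family_id,
        site_type = sites$site_type, start = sites$start,
        conserved = sites$conserved, regional_score = sc,
        gene_regional_score = mean(sc), stringsAsFactors = FALSE)
    }
  }
  meta <- .meta_for(config, list(min_segment_length = min_segment_length))
  write_tsv_meta(do.call(rbind, seg_rows), .run_path(dir, "segments.tsv"),
                 meta)
  write_tsv_meta(do.call(rbind, score_rows),
                 .run_path(dir, "regional_scores.tsv"), meta)
  invisible(dir)
}

#' Run the comparison battery
#'
#' Emits class-wise score comparisons, CNV-stratified comparisons,
#' background-adjusted ancestral comparisons, bootstrap resampling
#' summaries, and the compensation-vs-conservation stratification, for
#' whichever gene classes are present with enough genes.
#'
#' @inheritParams stage_scan
#' @param n_boot bootstrap replicates for resampling summaries.
#' @return `dir`, invisibly.
#' @export
stage_compare <- function(config, dir, n_boot = 1000L) {
  pct <- read_pct_table(.require_stage_file(dir, "pct.tsv", "simulate"))
  ann <- read_gene_annotations(
    .require_stage_file(dir, "annotations.tsv", "simulate"))
  cnv <- classify_cnv(read_tsv_meta(
    .require_stage_file(dir, "cnv.tsv", "simulate")))
  bg <- read_tsv_meta(
    .require_stage_file(dir, "background.tsv", "background"))
  out <- list()
  # interaction- and gene-level score comparisons between classes
  x_classes <- intersect(c("XY_pair", "X_inactivated", "X_escape"),
                         unique(ann$class))
  z_classes <- intersect(c("ZW_pair", "Z_noW"), unique(ann$class))
  if (length(x_classes) >= 2) {
    out$x <- compare_classes(pct, ann, x_classes, analysis = "x_classes")
  }
  if (length(z_classes) == 2) {
    out$z <- compare_classes(pct, ann, z_classes, analysis = "z_classes")
  }
  if (any(ann$class == "autosomal")) {
    out$cnv <- compare_cnv_strata(pct, cnv)
  }
  # ancestral, background-adjusted conserved-site comparisons
  bg$excess <- bg$n_conserved - bg$expected
  cls <- ann$class[match(bg$gene_id, ann$gene_id)]
  anc_classes <- intersect(GENE_CLASSES, unique(cls))
  anc <- list()
  for (i in seq_along(anc_classes)) for (j in seq_along(anc_classes)) {
    if (i >= j) next
    a <- anc_classes[i]; b <- anc_classes[j]
    xa <- bg$excess[cls == a & !is.na(cls)]
    xb <- bg$excess[cls == b & !is.na(cls)]
    if (length(xa) < 2 || length(xb) < 2) next
    anc[[length(anc) + 1L]] <- .result_row(
      wilcoxon_rank_sum(xa, xb, c(a, b)), "ancestral_excess", "gene")
  }
  out$anc <- do.call(rbind, anc)
  # compensation stratification per tissue
  comp_rows <- list()
  scores <- gene_mean_pct(pct)
  if ("Z_noW" %in% unique(ann$class)) {
    expr <- read_expression_ratios(
      .require_stage_file(dir, "expression.tsv", "simulate"))
    for (tt in unique(expr$tissue)) {
      cv <- compensation_vs_conservation(expr, scores, ann, tt)
      if (!is.null(cv)) {
        row <- .result_row(cv, paste0("compensation_", tt), "gene")
        row$direction <- cv$direction
        comp_rows[[length(comp_rows) + 1L]] <- row
      }
    }
  }
  comparisons <- do.call(rbind, out)
  if (!is.null(comparisons)) comparisons$direction <- NA_real_
  comparisons <- rbind(comparisons, do.call(rbind, comp_rows))
  rownames(comparisons) <- NULL
  meta <- .meta_for(config, list(n_boot = n_boot))
  write_tsv_meta(comparisons, .run_path(dir, "comparisons.tsv"), meta)
  # resampling summaries over class pairs with scored genes
  res_rows <- list()
  pairs <- rbind(
    if (length(x_classes) >= 2) t(utils::combn(x_classes, 2)),
    if (length(z_classes) == 2) t(utils::combn(z_classes, 2)))
  for (r in seq_len(NROW(pairs))) {
    rs <- resample_class_difference(scores, ann, pairs[r, 1], pairs[r, 2],
                                    n_boot = n_boot,
                                    rng_seed = config$rng_seed + 200L + r)
    res_rows[[length(res_rows) + 1L]] <- data.frame(
      statistic = rs$statistic_name, point_estimate = rs$point_estimate,
      ci_low = rs$ci_low, ci_high = rs$ci_high, n_boot = rs$n_boot,
      rng_seed = rs$rng_seed, stringsAsFactors = FALSE)
  }
  resampling <- if (length(res_rows) > 0) do.call(rbind, res_rows) else
    data.frame(statistic = character(0))
  write_tsv_meta(resampling, .run_path(dir, "resampling.tsv"), meta)
  invisible(dir)
}

#' Fit the class model and run predictor ablations
#'
#' Multinomial logistic regression of class membership on pHI, expression
#' breadth, dN/dS and the mean conservation score, followed by AIC
#' ablation of each predictor.
#'
#' @inheritParams stage_scan
#' @return `dir`, invisibly.
#' @export
stage_fit <- function(config, dir) {
  pct <- read_pct_table(.require_stage_file(dir, "pct.tsv", "simulate"))
  ann <- read_gene_annotations(
    .require_stage_file(dir, "annotations.tsv", "simulate"))
  scores <- gene_mean_pct(pct)
  d <- ann
  d$mean_score <- unname(scores[match(d$gene_id, names(scores))])
  counts <- table(d$class)
  classes <- names(counts)[counts >= 10]
  d <- d[d$class %in% classes, , drop = FALSE]
  predictors <- c("pHI", "expression_breadth", "dnds", "mean_score")
  full <- fit_multinomial_logit(d, "class", predictors)
  coefs <- coef(full)
  model_rows <- do.call(rbind, lapply(rownames(coefs), function(cl) {
    data.frame(class = cl, predictor = colnames(coefs),
               coefficient = coefs[cl, ], stringsAsFactors = FALSE)
  }))
  rownames(model_rows) <- NULL
  meta <- .meta_for(config,
                    list(aic_full = sprintf("%.6f", full$aic),
                         logLik_full = sprintf("%.6f", full$log_likelihood),
                         n = full$n))
  write_tsv_meta(model_rows, .run_path(dir, "model.tsv"), meta)
  abl_rows <- do.call(rbind, lapply(predictors, function(p) {
    ab <- ablation_aic(d, "class", predictors, p)
    data.frame(dropped = p, aic_full = ab$aic_full,
               aic_reduced = ab$aic_reduced, delta = ab$delta,
               stringsAsFactors = FALSE)
  }))
  write_tsv_meta(abl_rows, .run_path(dir, "ablation.tsv"), meta)
  invisible(dir)
}

#' Summarize a completed run as markdown
#'
#' @inheritParams stage_scan
#' @return path of `report.md`, invisibly; an incomplete run produces an
#'   error listing the missing stages.
#' @export
stage_report <- function(config, dir) {
  needed <- unlist(.stage_files[c("simulate", "scan", "conserve",
                                  "background", "segment", "compare",
                                  "fit")])
  present <- file.exists(file.path(dir, needed))
  if (any(!present)) {
    stop("incomplete run in ", dir, "; missing: ",
         paste(needed[!present], collapse = ", "))
  }
  cmp <- read_tsv_meta(.run_path(dir, "comparisons.tsv"))
  bg <- read_tsv_meta(.run_path(dir, "background.tsv"))
  abl <- read_tsv_meta(.run_path(dir, "ablation.tsv"))
  model_meta <- attr(read_tsv_meta(.run_path(dir, "model.tsv")), "meta")
  lines <- c(
    "# Conserved-targeting dosage-sensitivity run report",
    "",
    sprintf("- config hash: %s", config_hash(config)),
    sprintf("- rng seed: %s", config$rng_seed),
    sprintf("- genes with background model: %d", nrow(bg)),
    sprintf("- mean background z: %.3f", mean(bg$z, na.rm = TRUE)),
    "",
    "## Class comparisons",
    "",
    "| analysis | level | test | groups | n | statistic | p |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s vs %s | %d/%d | %.4g | %.3g |",
            cmp$analysis, cmp$level, cmp$test, cmp$group_a, cmp$group_b,
            cmp$n_a, cmp$n_b, cmp$statistic, cmp$p_value),
    "",
    "## Model ablation",
    "",
    sprintf("- full model AIC: %s (logL %s, n = %s)",
            model_meta$aic_full, model_meta$logLik_full, model_meta$n),
    sprintf("- drop %s: AIC %.2f (delta %+.2f)",
            abl$dropped, abl$aic_reduced, abl$delta),
    "")
  out <- .run_path(dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}

#' Run the full pipeline in one call
#'
#' @param config a [simulation_config()].
#' @param dir run directory.
#' @param n_shuffles shuffle replicates for the background stage.
#' @param n_boot bootstrap replicates for resampling summaries.
#' @return `dir`, invisibly.
#' @export
run_pipeline <- function(config, dir, n_shuffles = 50L, n_boot = 1000L) {
  stage_simulate(config, dir)
  stage_scan(config, dir)
  stage_conserve(config, dir)
  stage_background(config, dir, n_shuffles = n_shuffles)
  stage_segment(config, dir)
  stage_compare(config, dir, n_boot = n_boot)
  stage_fit(config, dir)
  stage_report(config, dir)
  invisible(dir)
}
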