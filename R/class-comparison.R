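# Distribution comparisons across gene classes, CNV stratification,
# gene resampling, multinomial logistic regression with AIC-based
# predictor ablation, and dosage-compensation stratification.
#
# Small-sample rank-sum p-values are computed by exact enumeration over
# all group assignments (with midranks, so ties are handled exactly);
# larger samples delegate to stats::wilcox.test's tie- and
# continuity-corrected normal approximation. KS and Fisher tests delegate
# to stats::ks.test / stats::fisher.test.

comparison_result <- function(test_name, group_labels, n_per_group,
                              statistic, p_value) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(test_name = test_name, group_labels = group_labels,
                 n_per_group = n_per_group, statistic = statistic,
                 p_value = min(p_value, 1)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> %s (n = %s): statistic %.4g, p = %.4g\n",
              x$test_name, paste(x$group_labels, collapse = " vs "),
              paste(x$n_per_group, collapse = "/"), x$statistic, x$p_value))
  invisible(x)
}

#' Two-sided Kolmogorov-Smirnov test
#'
#' Exact p-value when n_x * n_y <= 10000 (and no ties), otherwise the
#' asymptotic distribution.
#'
#' @param x,y non-empty numeric samples.
#' @param labels group labels for reporting.
#' @return a `comparison_result` with statistic D = sup |ECDF_x - ECDF_y|.
#' @export
ks_test_two_sided <- function(x, y, labels = c("x", "y")) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample in KS test")
  exact <- length(x) * length(y) <= 10000
  res <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided",
                                         exact = exact))
  comparison_result("ks_two_sided", labels, c(length(x), length(y)),
                    unname(res$statistic), res$p.value)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' For n_x + n_y <= 12 the two-sided p-value is computed by exact
#' enumeration of all group assignments using midranks (so ties are exact);
#' otherwise the normal approximation with tie and continuity correction
#' is used.
#'
#' @inheritParams ks_test_two_sided
#' @return a `comparison_result`; the statistic is the Mann-Whitney U for
#'   the first sample.
#' @export
wilcoxon_rank_sum <- function(x, y, labels = c("x", "y")) {
  nx <- length(x)
  ny <- length(y)
  if (nx == 0L || ny == 0L) stop("empty sample in rank-sum test")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx + ny <= 12L) {
    p <- .exact_ranksum_p(c(x, y), nx)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = FALSE, correct = TRUE)$p.value)
    if (is.na(p)) p <- 1   # zero rank variance: complete ties
  }
  comparison_result("wilcoxon_rank_sum", labels, c(nx, ny), U, p)
}

# exact permutation p: fraction of assignments whose rank-sum deviates
# from its permutation mean by at least the observed deviation
.exact_ranksum_p <- function(pooled, nx) {
  n <- length(pooled)
  r <- rank(pooled)               # midranks
  obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  combos <- utils::combn(n, nx)
  sums <- colSums(matrix(r[combos], nrow = nx))
  eps <- 1e-9
  mean(abs(sums - mu) >= abs(obs - mu) - eps)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed the observed table's. An
#' all-zero table is degenerate and returns p = 1.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param labels group labels for reporting.
#' @return a `comparison_result`; the statistic is the sample odds ratio.
#' @export
fisher_exact <- function(table, labels = c("rows", "cols")) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0)) stop("negative entry in contingency table")
  if (sum(table) == 0) {
    return(comparison_result("fisher_exact", labels, rowSums(table), NA_real_, 1))
  }
  res <- stats::fisher.test(table, alternative = "two.sided")
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  comparison_result("fisher_exact", labels, rowSums(table), or, res$p.value)
}

.result_row <- function(res, analysis, level) {
  data.frame(analysis = analysis, level = level, test = res$test_name,
             group_a = res$group_labels[1], group_b = res$group_labels[2],
             n_a = res$n_per_group[1], n_b = res$n_per_group[2],
             statistic = res$statistic, p_value = res$p_value,
             stringsAsFactors = FALSE)
}

#' Pairwise class comparisons of conservation scores
#'
#' For every pair of the requested classes, compares score distributions at
#' the interaction level (each gene-family score one observation; KS test)
#' and at the gene level (per-gene means; rank-sum test). Groups with
#' fewer than 2 genes are skipped with a message.
#'
#' @param records interaction-level score data.frame (gene_id, family_id,
#'   pct) as from [read_pct_table()].
#' @param annotations annotation data.frame with gene_id and class.
#' @param classes character vector of class labels to compare (default:
#'   all classes present).
#' @param analysis label recorded in the output rows.
#' @return data.frame of comparison rows (one per pair and level).
#' @export
compare_classes <- function(records, annotations, classes = NULL,
                            analysis = "class_comparison") {
  ann <- annotations[, c("gene_id", "class")]
  rec <- merge(records, ann, by = "gene_id")
  if (is.null(classes)) classes <- intersect(GENE_CLASSES, unique(rec$class))
  gm <- gene_mean_pct(rec)
  gene_class <- ann$class[match(names(gm), ann$gene_id)]
  out <- list()
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    if (i >= j) next
    a <- classes[i]; b <- classes[j]
    ga <- gm[gene_class == a & !is.na(gene_class)]
    gb <- gm[gene_class == b & !is.na(gene_class)]
    if (length(ga) < 2L || length(gb) < 2L) {
      message("compare_classes: skipping ", a, " vs ", b,
              " (fewer than 2 genes in a group)")
      next
    }
    ia <- rec$pct[rec$class == a]
    ib <- rec$pct[rec$class == b]
    out[[length(out) + 1L]] <- .result_row(
      ks_test_two_sided(ia, ib, c(a, b)), analysis, "interaction")
    out[[length(out) + 1L]] <- .result_row(
      wilcoxon_rank_sum(ga, gb, c(a, b)), analysis, "gene")
  }
  do.call(rbind, out)
}

#' CNV-stratified comparisons of conservation scores
#'
#' Compares duplicated vs nonduplicated genes within each deletion stratum,
#' and deleted vs nondeleted genes within each duplication stratum, at both
#' the interaction level (KS) and the gene level (rank-sum), controlling
#' each dosage-change axis for the other.
#'
#' @param records interaction-level score data.frame.
#' @param cnv_flags data.frame gene_id, duplicated, deleted (from
#'   [classify_cnv()]).
#' @return data.frame of comparison rows.
#' @export
compare_cnv_strata <- function(records, cnv_flags) {
  rec <- merge(records, cnv_flags, by = "gene_id")
  gm <- gene_mean_pct(rec)
  flag <- cnv_flags[match(names(gm), cnv_flags$gene_id), ]
  out <- list()
  strata <- list(
    list(test_on = "duplicated", within = "deleted"),
    list(test_on = "deleted", within = "duplicated")
  )
  for (st in strata) {
    for (lvl in c(FALSE, TRUE)) {
      sel_rec <- rec[rec[[st$within]] == lvl, ]
      sel_gm <- gm[flag[[st$within]] == lvl]
      sel_flag <- flag[[st$test_on]][flag[[st$within]] == lvl]
      grp <- sel_rec[[st$test_on]]
      lab <- paste0(c("non", ""), st$test_on, "|",
                    ifelse(lvl, "", "non"), st$within)
      if (sum(!sel_flag) < 2L || sum(sel_flag) < 2L) {
        message("compare_cnv_strata: skipping ", st$test_on, " within ",
                st$within, " = ", lvl, " (group too small)")
        next
      }
      analysis <- paste0("cnv_", st$test_on, "_within_", st$within, "_", lvl)
      out[[length(out) + 1L]] <- .result_row(
        ks_test_two_sided(sel_rec$pct[!grp], sel_rec$pct[grp], lab),
        analysis, "interaction")
      out[[length(out) + 1L]] <- .result_row(
        wilcoxon_rank_sum(sel_gm[!sel_flag], sel_gm[sel_flag], lab),
        analysis, "gene")
    }
  }
  do.call(rbind, out)
}

#' Bootstrap the difference in class mean gene-level scores
#'
#' Resamples genes with replacement within each class and reports the
#' percentile confidence interval for the difference of class means,
#' checking that observed class differences are not driven by particular
#' gene subsets.
#'
#' @param scores named numeric vector, gene_id -> gene-level score.
#' @param annotations annotation data.frame with gene_id and class.
#' @param class_a,class_b class labels.
#' @param n_boot bootstrap replicates (a warning is logged below 100).
#' @param rng_seed integer seed.
#' @return list (class `resample_summary`): statistic_name,
#'   point_estimate, ci_low, ci_high, n_boot, rng_seed.
#' @export
resample_class_difference <- function(scores, annotations, class_a, class_b,
                                      n_boot = 1000L, rng_seed = 1L) {
  if (n_boot < 100L) message("resample_class_difference: n_boot < 100")
  cls <- annotations$class[match(names(scores), annotations$gene_id)]
  xa <- scores[cls == class_a & !is.na(cls)]
  xb <- scores[cls == class_b & !is.na(cls)]
  if (length(xa) == 0L || length(xb) == 0L) stop("empty class in resampling")
  set.seed(rng_seed)
  est <- mean(xa) - mean(xb)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(sample(xa, replace = TRUE)) - mean(sample(xb, replace = TRUE))
  }, numeric(1))
  ci <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
  structure(list(statistic_name = paste0("mean_", class_a, "_minus_", class_b),
                 point_estimate = est,
                 ci_low = min(ci[1], est), ci_high = max(ci[2], est),
                 n_boot = as.integer(n_boot), rng_seed = as.integer(rng_seed)),
            class = "resample_summary")
}

#' @export
print.resample_summary <- function(x, ...) {
  cat(sprintf("<resample_summary> %s = %.4g [%.4g, %.4g] (%d boots)\n",
              x$statistic_name, x$point_estimate, x$ci_low, x$ci_high,
              x$n_boot))
  invisible(x)
}

#' Multinomial logistic regression over gene classes
#'
#' Models the probability of each gene's class as a linear function of the
#' supplied predictors (maximum likelihood via nnet::multinom; the
#' reference class is the alphabetically first label). Rows with missing
#' predictor values are dropped listwise with a message.
#'
#' @param data data.frame containing the outcome and predictor columns.
#' @param outcome name of the class-label column (>= 2 classes, >= 10
#'   genes in each).
#' @param predictors character vector of predictor column names; empty for
#'   an intercept-only model.
#' @return object of class `class_model`: coefficients (per non-reference
#'   class), log_likelihood, aic (2k - 2 logL), n_parameters, n, fitted
#'   nnet object, and a `separation` flag set when coefficients diverge.
#' @export
fit_multinomial_logit <- function(data, outcome, predictors) {
  cols <- c(outcome, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  cc <- stats::complete.cases(data[, cols, drop = FALSE])
  if (any(!cc)) {
    message("fit_multinomial_logit: dropped ", sum(!cc),
            " row(s) with missing values")
  }
  d <- data[cc, cols, drop = FALSE]
  d[[outcome]] <- factor(d[[outcome]])       # levels sort alphabetically
  n_cls <- nlevels(d[[outcome]])
  if (n_cls < 2L) stop("outcome has fewer than 2 classes")
  counts <- table(d[[outcome]])
  if (any(counts < 10L)) {
    message("fit_multinomial_logit: class(es) with fewer than 10 genes: ",
            paste(names(counts)[counts < 10], collapse = ", "))
  }
  if (length(predictors) > 0) {
    X <- as.matrix(d[, predictors, drop = FALSE])
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1L) {
      keep <- qrX$pivot[seq_len(qrX$rank)]
      dropped <- setdiff(colnames(cbind(`(Intercept)` = 1, X)),
                         colnames(cbind(`(Intercept)` = 1, X))[keep])
      stop("rank-deficient design; collinear column(s): ",
           paste(dropped, collapse = ", "))
    }
  }
  fml <- stats::as.formula(paste(
    outcome, "~", if (length(predictors) > 0) {
      paste(predictors, collapse = " + ")
    } else "1"))
  fit <- nnet::multinom(fml, data = d, trace = FALSE, maxit = 1000,
                        reltol = 1e-12)
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  coefs <- stats::coef(fit)
  if (n_cls == 2L) coefs <- matrix(coefs, nrow = 1,
                                   dimnames = list(levels(d[[outcome]])[2],
                                                   names(coefs)))
  separation <- any(abs(coefs) > 15)
  if (separation) {
    warning("possible perfect separation: very large coefficient(s)")
  }
  structure(list(outcome_classes = levels(d[[outcome]]),
                 reference_class = levels(d[[outcome]])[1],
                 predictor_names = predictors,
                 coefficients = coefs,
                 log_likelihood = ll,
                 n_parameters = as.integer(k),
                 aic = 2 * k - 2 * ll,
                 n = nrow(d),
                 separation = separation,
                 fit = fit),
            class = "class_model")
}

#' @export
print.class_model <- function(x, ...) {
  cat(sprintf(
    "<class_model> %d classes (ref %s), %d predictor(s), n = %d\n",
    length(x$outcome_classes), x$reference_class,
    length(x$predictor_names), x$n))
  cat(sprintf("  logL = %.3f, k = %d, AIC = %.3f%s\n", x$log_likelihood,
              x$n_parameters, x$aic,
              if (x$separation) "  [separation warning]" else ""))
  invisible(x)
}

#' @export
coef.class_model <- function(object, ...) object$coefficients

#' @export
logLik.class_model <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_parameters,
            class = "logLik")
}

#' AIC-based predictor ablation
#'
#' Fits the full model and the model without one predictor on the same
#' gene rows (complete cases over the full predictor set) and reports the
#' AIC change; a positive delta means the dropped predictor carried
#' information.
#'
#' @param data data.frame with outcome and predictors.
#' @param outcome class-label column name.
#' @param predictors full predictor set.
#' @param drop predictor to remove (must be in `predictors`).
#' @return list with aic_full, aic_reduced, delta (= reduced - full) and
#'   both fitted models.
#' @export
ablation_aic <- function(data, outcome, predictors, drop) {
  if (!drop %in% predictors) stop("'", drop, "' is not among the predictors")
  cc <- stats::complete.cases(data[, c(outcome, predictors), drop = FALSE])
  d <- data[cc, , drop = FALSE]
  full <- fit_multinomial_logit(d, outcome, predictors)
  reduced <- fit_multinomial_logit(d, outcome, setdiff(predictors, drop))
  list(aic_full = full$aic, aic_reduced = reduced$aic,
       delta = reduced$aic - full$aic, full = full, reduced = reduced)
}

#' Dosage compensation versus conservation score
#'
#' Splits Z-linked genes without a W homolog at the median gene-level
#' conservation score and compares |log2 male/female expression| between
#' the high- and low-score halves in one tissue. A negative direction
#' (high-score median minus low-score median) indicates that high-score
#' genes sit closer to a balanced ratio, i.e. more effective dosage
#' compensation.
#'
#' @param ratios expression-ratio data.frame (gene_id, species, tissue,
#'   log2_mf).
#' @param scores named numeric vector, gene_id -> gene-level score.
#' @param annotations annotation data.frame with gene_id, class.
#' @param tissue tissue to analyse.
#' @param class gene class analysed (default "Z_noW").
#' @return a `comparison_result` with an extra `direction` field, or NULL
#'   (with a message) when a half has fewer than 2 genes.
#' @export
compensation_vs_conservation <- function(ratios, scores, annotations,
                                         tissue, class = "Z_noW") {
  cls <- annotations$class[match(names(scores), annotations$gene_id)]
  sc <- scores[cls == class & !is.na(cls)]
  r <- ratios[ratios$tissue == tissue & ratios$gene_id %in% names(sc), ]
  sc <- sc[names(sc) %in% r$gene_id]
  if (length(sc) < 4L) {
    message("compensation_vs_conservation: fewer than 4 usable genes in ",
            tissue)
    return(NULL)
  }
  hi <- sc >= stats::median(sc)
  amf <- abs(r$log2_mf[match(names(sc), r$gene_id)])
  if (sum(hi) < 2L || sum(!hi) < 2L) {
    message("compensation_vs_conservation: a score half has fewer than 2 ",
            "genes in ", tissue)
    return(NULL)
  }
  res <- wilcoxon_rank_sum(amf[hi], amf[!hi],
                           labels = c("high_score", "low_score"))
  res$direction <- stats::median(amf[hi]) - stats::median(amf[!hi])
  res$tissue <- tissue
  res
}
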