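# Statistical layer: exact tests, class comparisons, resampling,
# multinomial regression and ablation.

test_that("KS statistic hits its boundary cases", {
  x <- c(0.1, 0.5, 0.9)
  same <- ks_test_two_sided(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disj <- ks_test_two_sided(c(1, 2, 3), c(4, 5, 6))
  expect_equal(disj$statistic, 1)
  expect_error(ks_test_two_sided(numeric(0), x), "empty")
})

test_that("exact KS p-values match full enumeration at n = 4 vs 4", {
  set.seed(61)
  for (r in 1:10) {
    x <- round(rnorm(4), 2)
    y <- round(rnorm(4), 2)
    if (anyDuplicated(c(x, y))) next  # exact KS assumes no ties
    res <- ks_test_two_sided(x, y)
    orc <- oracle_ks(x, y)
    expect_equal(res$statistic, orc$D, tolerance = 1e-12)
    expect_equal(res$p_value, orc$p, tolerance = 1e-9)
  }
})

test_that("rank-sum p-values match enumeration on small samples", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$statistic, 0)         # U for the first sample
  one <- wilcoxon_rank_sum(1, 1)
  expect_equal(one$p_value, 1)
  set.seed(62)
  for (r in 1:10) {
    x <- sample(1:8, 6, replace = TRUE)  # ties exercised via midranks
    y <- sample(1:8, 6, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("large-sample rank-sum agrees closely with the exact enumeration", {
  set.seed(63)
  for (r in 1:5) {
    x <- rnorm(10)
    y <- rnorm(10, 0.3)
    asym <- wilcoxon_rank_sum(x, y)$p_value
    exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_lt(abs(asym - exact), 0.02)
  }
})

test_that("Fisher p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(0, 2, 2))$p_value, 1)  # degenerate
  expect_error(fisher_exact(matrix(c(-1, 0, 0, 1), 2)), "negative")
  set.seed(64)
  for (r in 1:15) {
    tab <- matrix(rpois(4, 2), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("identical groups compare as indistinguishable", {
  set.seed(65)
  ann <- data.frame(gene_id = sprintf("g%02d", 1:20),
                    class = rep(c("XY_pair", "X_escape"), each = 10))
  # both classes receive exactly the same per-gene score multiset
  shared <- rep(runif(10), each = 3)
  rec <- data.frame(gene_id = rep(ann$gene_id, each = 3),
                    family_id = rep(1:3, 20), pct = c(shared, shared))
  cmp <- compare_classes(rec, ann, c("XY_pair", "X_escape"))
  ks_row <- cmp[cmp$level == "interaction", ]
  expect_equal(ks_row$statistic, 0)
  expect_gte(min(cmp$p_value), 0.9)
})

test_that("a planted class shift is detected at the gene level", {
  set.seed(66)
  n <- 100
  ann <- data.frame(gene_id = sprintf("g%03d", 1:(2 * n)),
                    class = rep(c("XY_pair", "X_escape"), each = n))
  rec <- data.frame(gene_id = rep(ann$gene_id, each = 2),
                    family_id = rep(1:2, 2 * n),
                    pct = pmin(pmax(rnorm(4 * n, 0.4, 0.15) +
                                      rep(c(0.3, 0), each = 2 * n), 0), 1))
  cmp <- compare_classes(rec, ann)
  gene_row <- cmp[cmp$level == "gene", ]
  expect_lt(gene_row$p_value, 0.01)
})

test_that("small groups are skipped with a message", {
  rec <- data.frame(gene_id = c("g1", "g2", "g3"), family_id = 1,
                    pct = c(0.1, 0.2, 0.3))
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    class = c("XY_pair", "XY_pair", "X_escape"))
  expect_message(cmp <- compare_classes(rec, ann), "skipping")
  expect_null(cmp)
})

test_that("CNV stratification equals the base test on each stratum subset", {
  set.seed(67)
  n <- 80
  flags <- data.frame(gene_id = sprintf("g%03d", 1:n),
                      duplicated = rep(c(TRUE, FALSE), n / 2),
                      deleted = rep(c(TRUE, TRUE, FALSE, FALSE), n / 4))
  rec <- data.frame(gene_id = rep(flags$gene_id, each = 3),
                    family_id = rep(1:3, n), pct = runif(3 * n))
  cmp <- compare_cnv_strata(rec, flags)
  expect_equal(nrow(cmp), 8L)  # 2 axes x 2 strata x 2 levels
  # decomposition: recompute one stratum by hand
  gm <- gene_mean_pct(rec)
  sel <- flags$deleted == FALSE
  manual <- wilcoxon_rank_sum(gm[sel & !flags$duplicated],
                              gm[sel & flags$duplicated])
  row <- cmp[cmp$analysis == "cnv_duplicated_within_deleted_FALSE" &
               cmp$level == "gene", ]
  expect_equal(row$statistic, manual$statistic)
  expect_equal(row$p_value, manual$p_value)
})

test_that("gene resampling is reproducible and degenerate-safe", {
  ann <- data.frame(gene_id = c("g1", "g2"),
                    class = c("XY_pair", "X_escape"))
  scores <- c(g1 = 0.7, g2 = 0.7)
  rs <- resample_class_difference(scores, ann, "XY_pair", "X_escape",
                                  n_boot = 200, rng_seed = 1)
  expect_equal(rs$point_estimate, 0)
  expect_equal(rs$ci_low, 0)
  expect_equal(rs$ci_high, 0)
  set.seed(100)
  ann <- data.frame(gene_id = sprintf("g%02d", 1:40),
                    class = rep(c("XY_pair", "X_escape"), 20))
  scores <- setNames(runif(40), ann$gene_id)
  a <- resample_class_difference(scores, ann, "XY_pair", "X_escape",
                                 n_boot = 500, rng_seed = 9)
  b <- resample_class_difference(scores, ann, "XY_pair", "X_escape",
                                 n_boot = 500, rng_seed = 9)
  expect_identical(a, b)
  expect_true(a$ci_low <= a$point_estimate && a$point_estimate <= a$ci_high)
})

test_that("bootstrap CIs cover a planted class difference", {
  set.seed(68)
  cover <- 0L
  n_rep <- 30
  for (r in 1:n_rep) {
    ann <- data.frame(gene_id = sprintf("g%03d", 1:200),
                      class = rep(c("XY_pair", "X_escape"), each = 100))
    scores <- setNames(c(rnorm(100, 0.5, 0.1), rnorm(100, 0.3, 0.1)),
                       ann$gene_id)
    rs <- resample_class_difference(scores, ann, "XY_pair", "X_escape",
                                    n_boot = 400, rng_seed = r)
    if (rs$ci_low <= 0.2 && 0.2 <= rs$ci_high) cover <- cover + 1L
  }
  expect_gte(cover / n_rep, 0.85)   # nominal 95%, binomial noise at n = 30
})

test_that("the intercept-only multinomial fit matches the closed form", {
  d <- data.frame(class = rep(c("XY_pair", "X_inactivated", "X_escape"),
                              each = 10))
  fit <- fit_multinomial_logit(d, "class", character(0))
  expect_equal(fit$log_likelihood, 30 * log(1 / 3), tolerance = 1e-6)
  expect_equal(fit$n_parameters, 2L)
  expect_equal(fit$aic, 2 * 2 - 2 * 30 * log(1 / 3), tolerance = 1e-6)
  expect_equal(fit$aic, 69.917, tolerance = 1e-3)
  # AIC identity and reference class
  expect_equal(fit$aic, 2 * fit$n_parameters - 2 * fit$log_likelihood)
  # reference class is the first factor level of the outcome
  expect_equal(fit$reference_class, levels(factor(d$class))[1])
})

test_that("a perfectly separating predictor triggers a warning", {
  d <- data.frame(class = rep(c("a", "b"), each = 20),
                  x = rep(c(0, 1), each = 20))
  expect_warning(fit <- fit_multinomial_logit(d, "class", "x"), "separation")
  expect_true(fit$separation)
})

test_that("collinear designs are rejected with the offending column", {
  set.seed(69)
  d <- data.frame(class = rep(c("a", "b", "c"), each = 15),
                  x1 = rnorm(45))
  d$x2 <- 2 * d$x1
  expect_error(fit_multinomial_logit(d, "class", c("x1", "x2")),
               "rank-deficient")
})

test_that("rows with missing covariates are dropped listwise", {
  set.seed(70)
  d <- data.frame(class = rep(c("a", "b", "c"), each = 15), x = rnorm(45))
  d$x[3] <- NA
  expect_message(fit <- fit_multinomial_logit(d, "class", "x"), "dropped 1")
  expect_equal(fit$n, 44L)
})

test_that("nested-model likelihoods are ordered and ablation is coherent", {
  set.seed(71)
  n <- 300
  cls <- sample(c("a", "b", "c"), n, replace = TRUE)
  x <- rnorm(n) + (cls == "a") * 1.2
  noise <- rnorm(n)
  d <- data.frame(class = cls, x = x, noise = noise)
  ab_info <- ablation_aic(d, "class", c("x", "noise"), "x")
  ab_noise <- ablation_aic(d, "class", c("x", "noise"), "noise")
  # full likelihood >= nested likelihood
  expect_gte(ab_info$full$log_likelihood, ab_info$reduced$log_likelihood)
  expect_gte(ab_noise$full$log_likelihood, ab_noise$reduced$log_likelihood)
  # dropping the informative predictor hurts; the AIC identity holds
  expect_gt(ab_info$delta, 0)
  expect_equal(ab_info$aic_full,
               2 * ab_info$full$n_parameters -
                 2 * ab_info$full$log_likelihood)
  expect_error(ablation_aic(d, "class", c("x", "noise"), "absent"),
               "not among")
  # dropping from a 1-predictor model leaves the intercept-only closed form
  d30 <- data.frame(class = rep(c("a", "b", "c"), each = 10), x = rnorm(30))
  ab1 <- ablation_aic(d30, "class", "x", "x")
  expect_equal(ab1$aic_reduced, 4 - 2 * 30 * log(1 / 3), tolerance = 1e-6)
})

test_that("compensation stratification detects a planted coupling", {
  set.seed(72)
  n <- 200
  ann <- data.frame(gene_id = sprintf("g%03d", 1:n), class = "Z_noW")
  scores <- setNames(runif(n), ann$gene_id)
  hi <- scores >= median(scores)
  ratios <- data.frame(gene_id = ann$gene_id, species = "chicken",
                       tissue = "brain",
                       log2_mf = ifelse(hi, rnorm(n, 0, 0.1),
                                        rnorm(n, 0.5, 0.1)))
  res <- compensation_vs_conservation(ratios, scores, ann, "brain")
  expect_lt(res$p_value, 0.01)
  expect_lt(res$direction, 0)
  # all-equal ratios: no separation
  ratios$log2_mf <- 0.3
  res0 <- compensation_vs_conservation(ratios, scores, ann, "brain")
  expect_equal(res0$p_value, 1)
  expect_equal(res0$direction, 0)
})
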