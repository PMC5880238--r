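# Synthetic-data generator.
#
# Emulates every input the pipeline consumes: per-gene cross-species UTR
# alignments with segment-wise background identity and planted seed-match
# sites whose cross-species retention depends on gene class; class-shifted
# covariates; interaction-level conservation scores; dosage-coupled CNV
# event counts; and male/female expression ratios coupled to gene scores.
#
# Evolution model: a reference UTR drawn uniformly over {A,C,G,U}; each
# partner species row is generated independently, position by position,
# identical to the reference with the probability of the enclosing
# background segment. Planted sites are copied intact with the class's
# retention probability, otherwise they receive exactly one substitution
# within the site span (the minimal perturbation defeating perfect
# identity). There are no indels, so rows are gapless and equal length.

#' Simulation configuration
#'
#' Defaults describe the study conditions emulated throughout the test
#' suite; see the methods vignette for the rationale behind each value.
#'
#' @param rng_seed integer seed used by the stage runner.
#' @param n_genes_per_class named integer vector, class -> gene count.
#' @param utr_length_range min/max reference UTR length (nt).
#' @param n_families number of miRNA families in the simulated family set.
#' @param sites_per_gene planted sites per gene.
#' @param site_retention_prob named vector, class -> probability that a
#'   planted site is copied intact to a partner species. Classes absent
#'   from this vector (e.g. "autosomal") get a per-gene latent sensitivity
#'   drawn from Beta(2, 2) instead, giving a within-class continuum.
#' @param background_levels range of per-segment background identity rates.
#' @param mean_segment_length mean background-segment length (nt).
#' @param sensitivity_noise SD of per-gene jitter around the class
#'   retention probability (the latent dosage sensitivity).
#' @param covariate_effects named list of per-unit-sensitivity shifts for
#'   pHI, expression_breadth and dnds.
#' @param cnv_dosage_coupling logit slope of duplication probability on
#'   latent sensitivity (negative effect: sensitive genes duplicate less).
#' @param cnv_deletion_coupling analogous (weaker) slope for deletions.
#' @param compensation_coupling strength of the decrease of |log2 M/F|
#'   with gene score for Z-linked genes lacking a W homolog (0 = none,
#'   1 = full range 0.5 -> 0.1).
#' @param pct_base,pct_effect,pct_concentration Beta-model parameters for
#'   interaction scores: mean = pct_base + pct_effect * sensitivity.
#' @param interactions_per_gene min/max scored interactions per gene.
#' @param species_list species names; the first is the reference.
#' @param tissues tissue names for expression ratios.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    rng_seed = 1L,
    n_genes_per_class = c(XY_pair = 100L, X_inactivated = 100L,
                          X_escape = 100L),
    utr_length_range = c(1500L, 2500L),
    n_families = 50L,
    sites_per_gene = 10L,
    site_retention_prob = c(XY_pair = 0.8, X_inactivated = 0.5,
                            X_escape = 0.2, ZW_pair = 0.8, Z_noW = 0.4),
    background_levels = c(0.8, 0.95),
    mean_segment_length = 300L,
    sensitivity_noise = 0.05,
    covariate_effects = list(pHI = 0.5, expression_breadth = 0.3,
                             dnds = -0.8),
    cnv_dosage_coupling = 3,
    cnv_deletion_coupling = 1.5,
    compensation_coupling = 1,
    pct_base = 0.1, pct_effect = 0.5, pct_concentration = 10,
    interactions_per_gene = c(20L, 40L),
    species_list = c("human", "chicken"),
    tissues = c("brain", "kidney", "liver", "heart")) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$site_retention_prob >= 0 & cfg$site_retention_prob <= 1),
            all(cfg$utr_length_range > 0),
            cfg$n_families >= 1,
            length(cfg$species_list) >= 2)
  bad <- setdiff(names(cfg$n_genes_per_class), GENE_CLASSES)
  if (length(bad) > 0) stop("unknown class(es) in config: ",
                            paste(bad, collapse = ", "))
  structure(cfg, class = "simulation_config")
}

# random non-homopolymer, mutually distinct 7-nt seeds
simulate_families <- function(n) {
  seeds <- character(0)
  while (length(seeds) < n) {
    s <- paste(sample(c("A", "C", "G", "U"), 7, replace = TRUE),
               collapse = "")
    if (length(unique(strsplit(s, "", fixed = TRUE)[[1]])) > 1L &&
        !s %in% seeds) {
      seeds <- c(seeds, s)
    }
  }
  lapply(seq_len(n), function(i) {
    mirna_family(sprintf("fam%03d", i), seeds[i])
  })
}

# latent per-gene dosage sensitivity: class retention prob plus jitter,
# or a Beta(2, 2) continuum for classes without a configured retention
.gene_sensitivity <- function(config, classes) {
  n <- length(classes)
  sens <- numeric(n)
  known <- classes %in% names(config$site_retention_prob)
  sens[known] <- clamp(
    config$site_retention_prob[classes[known]] +
      stats::rnorm(sum(known), 0, config$sensitivity_noise), 0, 1)
  sens[!known] <- stats::rbeta(sum(!known), 2, 2)
  unname(sens)
}

# segment boundaries and identity levels for one UTR
.draw_segments <- function(L, mean_len, level_range) {
  ends <- integer(0)
  pos <- 0L
  while (pos < L) {
    pos <- pos + max(1L, stats::rgeom(1, 1 / mean_len) + 1L)
    ends <- c(ends, min(pos, L))
  }
  levels <- stats::runif(length(ends), level_range[1], level_range[2])
  list(ends = ends, levels = levels)
}

# per-position identity level vector from segments
.position_levels <- function(L, seg) {
  rep(seg$levels, times = diff(c(0L, seg$ends)))
}

.other_base <- function(base) {
  nts <- c("A", "C", "G", "U")
  vapply(base, function(b) sample(setdiff(nts, b), 1L), character(1))
}

#' Simulate per-gene UTR alignments with planted target sites
#'
#' @param config a [simulation_config()].
#' @param rng_seed optional seed (defaults to `config$rng_seed`).
#' @return list with `alignments` (named list of [utr_alignment()]),
#'   `families` (the simulated family set), `genes` (data.frame gene_id,
#'   class, sensitivity, utr_length), `truth` (data.frame of planted sites:
#'   gene_id, family_id, site_type, start, end, and one logical
#'   retained_<species> column per partner species).
#' @export
simulate_utr_alignments <- function(config, rng_seed = NULL) {
  set.seed(if (is.null(rng_seed)) config$rng_seed else rng_seed)
  families <- simulate_families(config$n_families)
  classes <- rep(names(config$n_genes_per_class), config$n_genes_per_class)
  n_genes <- length(classes)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sens <- .gene_sensitivity(config, classes)
  ref_sp <- config$species_list[1]
  partners <- config$species_list[-1]

  alignments <- vector("list", n_genes)
  truth <- vector("list", n_genes)
  lengths_out <- integer(n_genes)
  for (g in seq_len(n_genes)) {
    L <- round(stats::runif(1, config$utr_length_range[1],
                            config$utr_length_range[2]))
    made <- NULL
    for (attempt in 1:20) {
      made <- .simulate_one_gene(config, gene_ids[g], L, sens[g],
                                 families, ref_sp, partners)
      if (!is.null(made)) break
      L <- round(L * 1.2)   # planting failed: retry with a longer UTR
      message("simulate_utr_alignments: replanting ", gene_ids[g],
              " with UTR length ", L)
    }
    if (is.null(made)) stop("failed to plant sites for ", gene_ids[g])
    alignments[[g]] <- made$alignment
    truth[[g]] <- made$truth
    lengths_out[g] <- L
  }
  list(alignments = stats::setNames(alignments, gene_ids),
       families = families,
       genes = data.frame(gene_id = gene_ids, class = classes,
                          sensitivity = sens, utr_length = lengths_out,
                          stringsAsFactors = FALSE),
       truth = do.call(rbind, truth))
}

# one gene: returns NULL if site planting or recovery fails
.simulate_one_gene <- function(config, gene_id, L, sensitivity, families,
                               ref_sp, partners) {
  k <- config$sites_per_gene
  ref <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
  planted <- NULL
  if (k > 0L) {
    fams <- sample(families, min(k, length(families)))
    if (k > length(families)) fams <- c(fams, sample(families, k - length(families)))
    types <- sample(SITE_TYPES, k, replace = TRUE)
    starts <- integer(0)
    ends <- integer(0)
    for (i in seq_len(k)) {
      w <- SITE_WIDTHS[types[i]]
      placed <- FALSE
      for (try in 1:100) {
        s0 <- sample.int(L - w + 1L, 1L) - 1L
        # 1-nt buffer between planted spans so flank guards stay disjoint
        if (!any(s0 - 1L < ends & s0 + w + 1L > starts)) {
          starts <- c(starts, s0)
          ends <- c(ends, s0 + w)
          placed <- TRUE
          break
        }
      }
      if (!placed) return(NULL)
    }
    for (i in seq_len(k)) {
      pats <- site_patterns(fams[[i]])
      ref[(starts[i] + 1L):ends[i]] <-
        strsplit(pats[[types[i]]], "", fixed = TRUE)[[1]]
      # guard flanks so a chance neighbouring base cannot extend the
      # planted site into a stronger overlapping type
      if (types[i] == "7mer-m8" && ends[i] < L &&
          ref[ends[i] + 1L] == "A") {
        ref[ends[i] + 1L] <- sample(c("C", "G", "U"), 1L)
      }
      if (types[i] == "7mer-A1" && starts[i] > 0L) {
        m8_first <- substr(pats[["7mer-m8"]], 1L, 1L)
        if (ref[starts[i]] == m8_first) {
          ref[starts[i]] <- sample(setdiff(c("A", "C", "G", "U"), m8_first),
                                   1L)
        }
      }
    }
    planted <- data.frame(
      gene_id = gene_id,
      family_id = vapply(fams, `[[`, character(1), "family_id"),
      site_type = types, start = starts, end = ends,
      stringsAsFactors = FALSE)
    # planting must be recoverable by the scanner on the final sequence
    refseq <- paste(ref, collapse = "")
    idx <- utr_site_index(refseq)
    for (i in seq_len(k)) {
      hits <- scan_utr(NULL, fams[[i]], index = idx)
      if (!any(hits$start == starts[i] & hits$site_type == types[i])) {
        return(NULL)
      }
    }
  }
  seg <- .draw_segments(L, config$mean_segment_length,
                        config$background_levels)
  lv <- .position_levels(L, seg)
  rows <- stats::setNames(vector("list", length(partners) + 1L),
                          c(ref_sp, partners))
  rows[[ref_sp]] <- paste(ref, collapse = "")
  if (!is.null(planted)) {
    retained <- matrix(FALSE, nrow = nrow(planted), ncol = length(partners),
                       dimnames = list(NULL, partners))
  }
  for (sp in partners) {
    ident <- stats::runif(L) < lv
    row <- ref
    row[!ident] <- .other_base(ref[!ident])
    if (!is.null(planted)) {
      keep <- stats::runif(nrow(planted)) < sensitivity
      retained[, sp] <- keep
      for (i in seq_len(nrow(planted))) {
        span <- (planted$start[i] + 1L):planted$end[i]
        row[span] <- ref[span]
        if (!keep[i]) {
          j <- sample(span, 1L)
          row[j] <- .other_base(ref[j])
        }
      }
    }
    rows[[sp]] <- paste(row, collapse = "")
  }
  tr <- planted
  if (!is.null(tr)) {
    for (sp in partners) tr[[paste0("retained_", sp)]] <- retained[, sp]
  }
  list(alignment = utr_alignment(gene_id, unlist(rows), ref_sp), truth = tr)
}

#' Simulate gene annotations with class-shifted covariates
#'
#' Covariates are tied to the latent dosage sensitivity: more sensitive
#' genes get higher haploinsufficiency probability and expression breadth
#' and lower dN/dS (stronger purifying selection).
#'
#' @param config a [simulation_config()].
#' @param genes gene table from [simulate_utr_alignments()] (gene_id,
#'   class, sensitivity).
#' @param rng_seed optional seed.
#' @return annotation data.frame: gene_id, class, xar, pHI,
#'   expression_breadth, dnds.
#' @export
simulate_annotations <- function(config, genes, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- nrow(genes)
  eff <- config$covariate_effects
  s <- genes$sensitivity - 0.5
  data.frame(
    gene_id = genes$gene_id,
    class = genes$class,
    xar = ifelse(grepl("^X", genes$class),
                 stats::runif(n) < 0.4, FALSE),
    pHI = clamp(0.4 + eff$pHI * s + stats::rnorm(n, 0, 0.12), 0, 1),
    expression_breadth = clamp(0.5 + eff$expression_breadth * s +
                                 stats::rnorm(n, 0, 0.15), 0, 1),
    dnds = exp(log(0.15) + eff$dnds * s + stats::rnorm(n, 0, 0.3)),
    stringsAsFactors = FALSE
  )
}

#' Simulate CNV event counts coupled to dosage sensitivity
#'
#' Duplication probability decreases with latent sensitivity through a
#' logit link with slope `cnv_dosage_coupling`; deletions use the
#' (weaker) `cnv_deletion_coupling`. Flagged genes receive a positive
#' event count.
#'
#' @inheritParams simulate_annotations
#' @return data.frame gene_id, dup_events, del_events.
#' @export
simulate_cnv_status <- function(config, genes, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- nrow(genes)
  s <- genes$sensitivity - 0.5
  p_dup <- stats::plogis(-config$cnv_dosage_coupling * s)
  p_del <- stats::plogis(-config$cnv_deletion_coupling * s)
  dup <- stats::runif(n) < p_dup
  del <- stats::runif(n) < p_del
  data.frame(
    gene_id = genes$gene_id,
    dup_events = ifelse(dup, 1L + stats::rpois(n, 1), 0L),
    del_events = ifelse(del, 1L + stats::rpois(n, 1), 0L),
    stringsAsFactors = FALSE
  )
}

#' Simulate an interaction-level conservation-score table
#'
#' Scores are Beta-distributed with mean increasing in the gene's latent
#' sensitivity, mimicking published per-interaction conservation
#' probabilities.
#'
#' @inheritParams simulate_annotations
#' @return data.frame gene_id, family_id, pct.
#' @export
simulate_pct_table <- function(config, genes, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  rows <- lapply(seq_len(nrow(genes)), function(g) {
    n_int <- sample(config$interactions_per_gene[1]:
                      config$interactions_per_gene[2], 1L)
    n_int <- min(n_int, config$n_families)
    mu <- clamp(config$pct_base + config$pct_effect * genes$sensitivity[g],
                0.02, 0.98)
    fams <- sample(sprintf("fam%03d", seq_len(config$n_families)), n_int)
    data.frame(gene_id = genes$gene_id[g], family_id = fams,
               pct = clamp(stats::rbeta(n_int, mu * config$pct_concentration,
                                        (1 - mu) * config$pct_concentration),
                           0, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate male/female expression ratios coupled to gene scores
#'
#' For genes of the focal class (default Z without W homolog), the
#' magnitude of the log2 male/female ratio decreases with the gene score
#' rank: with full coupling, the mean |log2 M/F| runs from 0.5 (lowest
#' scores, uncompensated two-fold male excess direction) down to 0.1
#' (highest scores, near-balanced). Genes of other classes are centred at
#' 0 per the two-copy expectation.
#'
#' @param config a [simulation_config()].
#' @param scores named numeric vector, gene_id -> gene-level score.
#' @param annotations annotation data.frame with gene_id, class.
#' @param species species label stamped on the records.
#' @param rng_seed optional seed.
#' @param class focal class whose ratios couple to the score.
#' @return data.frame gene_id, species, tissue, log2_mf.
#' @export
simulate_expression_ratios <- function(config, scores, annotations,
                                       species = "chicken", rng_seed = NULL,
                                       class = "Z_noW") {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  cls <- annotations$class[match(names(scores), annotations$gene_id)]
  rows <- lapply(config$tissues, function(tt) {
    focal <- !is.na(cls) & cls == class
    mu <- numeric(length(scores))
    if (any(focal)) {
      r01 <- rank01(scores[focal])
      mu[focal] <- 0.5 - 0.4 * config$compensation_coupling * r01
    }
    mag <- pmax(stats::rnorm(length(scores), mu, 0.08), 0)
    sign <- ifelse(focal, sample(c(-1, 1), length(scores), replace = TRUE), 1)
    l2 <- ifelse(focal, sign * mag, stats::rnorm(length(scores), 0, 0.1))
    data.frame(gene_id = names(scores), species = species, tissue = tt,
               log2_mf = l2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
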