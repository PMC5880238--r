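# Shuffled-seed background null for per-gene conserved-site counts.
#
# The observed number of conserved sites in a UTR reflects both targeting
# and the UTR's background conservation. The null replaces every family
# seed with a composition-preserving permutation, re-scans the full site
# grammar, and re-counts conserved sites; the replicate mean and standard
# deviation give a per-gene expectation and a z-score for the observed
# count.

#' Composition-preserving shuffle of a seed
#'
#' Draws a random permutation of the seed's characters that differs from
#' the seed itself and from every seed in `forbid` (typically all real
#' seeds of the family set). Uses R's global RNG; seed the RNG for
#' reproducibility.
#'
#' @param seed 7-nt seed string.
#' @param forbid character vector of seed strings the shuffle must avoid.
#' @param max_tries rejection-sampling attempts before falling back to
#'   exhaustive enumeration of distinct permutations.
#' @return a shuffled 7-nt string.
#' @export
shuffle_seed <- function(seed, forbid = character(), max_tries = 100L) {
  seed <- normalize_rna(seed)
  ch <- strsplit(seed, "", fixed = TRUE)[[1]]
  if (length(unique(ch)) == 1L) {
    stop(unshufflable_error(seed, "homopolymer seed has a single permutation"))
  }
  avoid <- c(seed, forbid)
  for (i in seq_len(max_tries)) {
    cand <- paste(sample(ch), collapse = "")
    if (!cand %in% avoid) return(cand)
  }
  # rare fallback: enumerate all distinct permutations
  perms <- unique(vapply(.permutations(ch), paste, character(1), collapse = ""))
  ok <- setdiff(perms, avoid)
  if (length(ok) == 0L) {
    stop(unshufflable_error(seed, "every permutation collides with a real seed"))
  }
  sample(ok, 1L)
}

unshufflable_error <- function(seed, reason) {
  structure(
    class = c("mirdosage_unshufflable", "error", "condition"),
    list(message = paste0("seed ", seed, " cannot be shuffled: ", reason),
         call = NULL)
  )
}

.permutations <- function(ch) {
  if (length(ch) == 1L) return(list(ch))
  out <- list()
  for (i in seq_along(ch)) {
    rest <- .permutations(ch[-i])
    out <- c(out, lapply(rest, function(r) c(ch[i], r)))
  }
  out
}

#' Identify families whose seed admits a valid shuffle
#' @param families list of [mirna_family()] objects.
#' @return logical vector, TRUE where the seed is shufflable given the
#'   full real-seed set.
#' @export
shufflable_families <- function(families) {
  seeds <- vapply(families, `[[`, character(1), "seed")
  comp <- vapply(strsplit(seeds, "", fixed = TRUE), function(ch) {
    paste(sort(ch), collapse = "")
  }, character(1))
  vapply(seq_along(families), function(i) {
    counts <- table(strsplit(seeds[i], "", fixed = TRUE)[[1]])
    if (length(counts) == 1L) return(FALSE)
    # a shuffle can only collide with seeds of identical composition, so
    # the seed is shufflable iff its distinct permutations
    # (7! / prod(counts!)) outnumber the distinct same-composition seeds
    n_perms <- factorial(7) / prod(factorial(counts))
    n_perms > length(unique(seeds[comp == comp[i]]))
  }, logical(1))
}

#' Shuffled-seed background model for one gene
#'
#' Counts observed conserved sites with the real seeds, then recomputes the
#' count over `n_shuffles` replicates in which every family's seed is
#' independently replaced by a composition-preserving shuffle (re-scanned
#' with the full site grammar, including the A1 anchor). Families whose
#' seed admits no valid shuffle are dropped from both the observed and the
#' null counts.
#'
#' @param alignment a [utr_alignment()].
#' @param families list of [mirna_family()] objects.
#' @param species_pair length-2 character vector.
#' @param n_shuffles number of shuffle replicates (>= 2).
#' @param rng_seed optional integer seed for reproducibility.
#' @return object of class `background_model` with fields gene_id,
#'   species_pair, n_shuffles, observed_conserved, expected_conserved,
#'   sd_conserved, z (NA when sd is 0), n_sites_observed, dropped_families.
#' @export
shuffled_seed_null <- function(alignment, families, species_pair,
                               n_shuffles = 50L, rng_seed = NULL) {
  stopifnot(n_shuffles >= 2L)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  keep <- shufflable_families(families)
  dropped <- vapply(families[!keep], `[[`, character(1), "family_id")
  if (length(dropped) > 0) {
    message("shuffled_seed_null: dropped unshufflable families: ",
            paste(dropped, collapse = ", "))
  }
  families <- families[keep]
  seeds <- vapply(families, `[[`, character(1), "seed")

  ctx <- conservation_context(alignment, species_pair[1], species_pair[2])
  obs <- .count_conserved_for_seeds(ctx, seeds, alignment$gene_id)
  ch_list <- strsplit(seeds, "", fixed = TRUE)
  null_counts <- vapply(seq_len(n_shuffles), function(r) {
    sh <- vapply(seq_along(seeds), function(i) {
      ch <- ch_list[[i]]
      for (try in 1:100) {
        cand <- paste(ch[sample.int(7L)], collapse = "")
        if (cand != seeds[i] && !cand %in% seeds) return(cand)
      }
      shuffle_seed(seeds[i], forbid = seeds)   # pathological composition
    }, character(1))
    .count_conserved_for_seeds(ctx, sh, alignment$gene_id)["conserved"]
  }, numeric(1))
  expected <- mean(null_counts)
  sdv <- stats::sd(null_counts)
  structure(list(
    gene_id = alignment$gene_id,
    species_pair = species_pair,
    n_shuffles = as.integer(n_shuffles),
    observed_conserved = unname(obs["conserved"]),
    n_sites_observed = unname(obs["sites"]),
    expected_conserved = expected,
    sd_conserved = sdv,
    z = if (isTRUE(sdv > 0)) unname((obs["conserved"] - expected) / sdv)
        else NA_real_,
    null_counts = null_counts,
    dropped_families = dropped
  ), class = "background_model")
}

# total sites and conserved sites for a vector of seeds, via the shared
# grammar core (.scan_seed) and per-family overlap resolution
.count_conserved_for_seeds <- function(ctx, seeds, gene_id) {
  n_sites <- 0L
  n_cons <- 0L
  for (s in seeds) {
    hit <- .scan_seed(ctx$index, s)
    if (length(hit$start) > 0L) {
      n_sites <- n_sites + length(hit$start)
      n_cons <- n_cons + sum(.spans_conserved(ctx, hit$start, hit$end))
    }
  }
  c(sites = n_sites, conserved = n_cons)
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "<background_model> %s (%s vs %s): observed %d, expected %.2f +/- %.2f, z = %s\n",
    x$gene_id, x$species_pair[1], x$species_pair[2],
    x$observed_conserved, x$expected_conserved, x$sd_conserved,
    ifelse(is.na(x$z), "undefined", sprintf("%.2f", x$z))))
  invisible(x)
}

#' Observed-minus-expected conserved-site count
#'
#' The background-adjusted count used in class comparisons: the observed
#' conserved-site count minus the shuffled-seed expectation.
#'
#' @param model a `background_model`.
#' @return numeric scalar.
#' @export
background_excess <- function(model) {
  model$observed_conserved - model$expected_conserved
}
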