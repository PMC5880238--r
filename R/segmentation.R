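# Step detection in per-position conservation signals.
#
# UTRs are segmented into regions of homogeneous background conservation by
# minimizing, over all admissible segmentations, the within-segment sum of
# squared deviations from segment means plus a fixed penalty per
# breakpoint. The search is an exact O(n^2) optimal-partitioning dynamic
# program, so the returned breakpoints attain the global minimum of the
# penalized objective (a greedy binary segmentation can miss it when two
# nearby changes mask each other).

#' Segment a conservation signal into homogeneous regions
#'
#' @param signal numeric vector (per-position 0/1 conservation indicator,
#'   or any real signal).
#' @param penalty cost added per breakpoint; default `log(length(signal))`
#'   (a BIC-like per-changepoint penalty).
#' @param min_segment_length minimum positions per segment (default 50 nt).
#' @return object of class `utr_segmentation`: list with `breakpoints`
#'   (0-based positions strictly inside the signal; segment i spans
#'   [b[i-1], b[i])), `segment_levels` (within-segment means), `objective`
#'   (the attained penalized cost) and `n` (signal length).
#' @examples
#' seg <- segment_utr_conservation(c(rep(1, 100), rep(0, 100)),
#'                                 min_segment_length = 20)
#' seg$breakpoints
#' @export
segment_utr_conservation <- function(signal, penalty = NULL,
                                     min_segment_length = 50L) {
  n <- length(signal)
  if (n == 0L) stop("empty signal")
  if (is.null(penalty)) penalty <- log(n)
  if (n < 2L * min_segment_length) {
    # too short to split: single segment
    return(new_segmentation(integer(0), mean(signal),
                            sum((signal - mean(signal))^2), n))
  }
  S1 <- c(0, cumsum(signal))
  S2 <- c(0, cumsum(signal^2))
  sse <- function(i, j) {
    # cost of segment covering positions (i+1)..j, i vector-ok (0-based left)
    len <- j - i
    S2[j + 1L] - S2[i + 1L] - (S1[j + 1L] - S1[i + 1L])^2 / len
  }
  # F[j+1]: minimal penalized cost of positions 1..j with the last segment
  # ending at j; candidate previous ends t satisfy segment length >= minlen
  F <- rep(Inf, n + 1L)
  F[1] <- -penalty                       # first segment carries no penalty
  prev <- integer(n + 1L)
  for (j in seq(min_segment_length, n)) {
    t_cand <- c(0L, seq_len(j - min_segment_length))
    t_cand <- t_cand[t_cand == 0L | t_cand >= min_segment_length]
    costs <- F[t_cand + 1L] + sse(t_cand, j) + penalty
    k <- which.min(costs)
    F[j + 1L] <- costs[k]
    prev[j + 1L] <- t_cand[k]
  }
  # backtrack
  bp <- integer(0)
  j <- n
  while (j > 0L) {
    t <- prev[j + 1L]
    if (t > 0L) bp <- c(t, bp)
    j <- t
  }
  bounds <- c(0L, bp, n)
  levels <- vapply(seq_len(length(bounds) - 1L), function(i) {
    (S1[bounds[i + 1L] + 1L] - S1[bounds[i] + 1L]) / (bounds[i + 1L] - bounds[i])
  }, numeric(1))
  new_segmentation(bp, levels, F[n + 1L], n)
}

new_segmentation <- function(breakpoints, levels, objective, n,
                             gene_id = NA_character_) {
  structure(list(gene_id = gene_id, breakpoints = as.integer(breakpoints),
                 segment_levels = as.numeric(levels),
                 objective = objective, n = as.integer(n)),
            class = "utr_segmentation")
}

#' @export
print.utr_segmentation <- function(x, ...) {
  cat(sprintf("<utr_segmentation> %d positions, %d segment(s) at [%s]\n",
              x$n, length(x$segment_levels),
              paste(sprintf("%.3f", x$segment_levels), collapse = ", ")))
  if (length(x$breakpoints) > 0) {
    cat("  breakpoints:", paste(x$breakpoints, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Regionally normalized conservation score of one site
#'
#' Scores a site as I(conserved) minus the background conservation level of
#' the UTR segment containing the site midpoint, so that sites inside
#' hyper-conserved blocks are not credited for background identity.
#'
#' @param site one-row site data.frame/list with `start`, `end` (0-based,
#'   half-open, ungapped reference coordinates).
#' @param conserved logical: was the site called conserved for the pair.
#' @param segmentation a `utr_segmentation` for the same UTR, or NULL to
#'   fall back to a whole-UTR level of `fallback_level`.
#' @param fallback_level background level used when `segmentation` is NULL.
#' @return numeric in [-1, 1].
#' @export
regional_normalized_score <- function(site, conserved, segmentation,
                                      fallback_level = NA_real_) {
  if (is.null(segmentation) || length(segmentation$segment_levels) == 0L) {
    return(as.numeric(conserved) - fallback_level)
  }
  mid <- floor((site$start + site$end) / 2)
  seg <- findInterval(mid, c(0L, segmentation$breakpoints))
  as.numeric(conserved) - segmentation$segment_levels[seg]
}

#' Gene-level regionally normalized score
#'
#' Mean of [regional_normalized_score()] over a gene's sites.
#'
#' @param sites site data.frame with `start`, `end` and logical `conserved`.
#' @param segmentation a `utr_segmentation` for the gene's reference UTR.
#' @return numeric scalar (NA for a site-free gene).
#' @export
gene_regional_score <- function(sites, segmentation) {
  if (nrow(sites) == 0L) return(NA_real_)
  mean(vapply(seq_len(nrow(sites)), function(i) {
    regional_normalized_score(sites[i, ], sites$conserved[i], segmentation)
  }, numeric(1)))
}
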