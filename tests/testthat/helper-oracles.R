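# Independent oracles and random-input generators for the test suite.
# Everything here is deliberately written from first principles (naive
# loops, exhaustive enumeration) and shares no code with the package
# internals it checks.

# -- alphabet helpers (independent of the package) ---------------------------

oracle_revcomp <- function(x) {
  ch <- rev(strsplit(x, "", fixed = TRUE)[[1]])
  paste(c(A = "U", C = "G", G = "C", U = "A")[ch], collapse = "")
}

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_seed7 <- function() {
  repeat {
    s <- random_rna(7)
    if (length(unique(strsplit(s, "", fixed = TRUE)[[1]])) > 1) return(s)
  }
}

# -- brute-force site scanner ------------------------------------------------

# tests every substring of the UTR against the three patterns, then applies
# the 8mer > 7mer-m8 > 7mer-A1 hierarchy with smaller-start tie-break,
# greedily keeping non-overlapping sites
oracle_scan <- function(utr, seed) {
  utr <- chartr("tT", "uU", toupper(utr))
  m8 <- oracle_revcomp(seed)
  pats <- list(`8mer` = paste0(m8, "A"),
               `7mer-m8` = m8,
               `7mer-A1` = paste0(substr(m8, 2, 7), "A"))
  cand <- data.frame(site_type = character(0), start = integer(0),
                     end = integer(0), stringsAsFactors = FALSE)
  for (ty in names(pats)) {
    w <- nchar(pats[[ty]])
    if (nchar(utr) < w) next
    for (s0 in 0:(nchar(utr) - w)) {
      if (substr(utr, s0 + 1, s0 + w) == pats[[ty]]) {
        cand <- rbind(cand, data.frame(site_type = ty, start = s0,
                                       end = s0 + w,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(cand) == 0) return(cand)
  rank <- match(cand$site_type, c("8mer", "7mer-m8", "7mer-A1"))
  cand <- cand[order(rank, cand$start), ]
  picked <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (nrow(picked) > 0) {
      for (j in seq_len(nrow(picked))) {
        if (cand$start[i] < picked$end[j] && cand$end[i] > picked$start[j]) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) picked <- rbind(picked, cand[i, ])
  }
  picked <- picked[order(picked$start), ]
  rownames(picked) <- NULL
  picked
}

# -- alignment oracles -------------------------------------------------------

# full ungapped -> gapped index map built by walking the row
oracle_index_map <- function(gapped_row) {
  ch <- strsplit(gapped_row, "", fixed = TRUE)[[1]]
  map <- integer(0)
  for (i in seq_along(ch)) if (ch[i] != "-") map <- c(map, i)
  map
}

# conserved iff both rows gap-free and identical on every column the site
# covers (including reference-gap columns inside the span)
oracle_site_conserved <- function(rows, ref_species, a, b, start, end) {
  map <- oracle_index_map(rows[[ref_species]])
  cols <- map[start + 1]:map[end]
  ca <- strsplit(rows[[a]], "", fixed = TRUE)[[1]][cols]
  cb <- strsplit(rows[[b]], "", fixed = TRUE)[[1]][cols]
  all(ca != "-" & cb != "-" & ca == cb)
}

# random gapped alignment over a set of species; gaps inserted per row
random_gapped_alignment <- function(gene_id = "g", width = 120,
                                    species = c("human", "chicken"),
                                    gap_prob = 0.08, n_prob = 0.02) {
  rows <- vapply(species, function(sp) {
    ch <- sample(c("A", "C", "G", "U"), width, replace = TRUE)
    ch[runif(width) < n_prob] <- "N"
    ch[runif(width) < gap_prob] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  # guarantee a non-empty ungapped reference
  if (!grepl("[^-]", rows[[1]])) {
    substr(rows[[1]], 1, 1) <- "A"
  }
  utr_alignment(gene_id, rows, species[1])
}

# -- exact test oracles ------------------------------------------------------

# two-sided rank-sum p by enumerating every assignment of pooled values
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  combos <- combn(n, nx)
  cnt <- 0
  for (j in seq_len(ncol(combos))) {
    if (abs(sum(r[combos[, j]]) - mu) >= abs(obs - mu) - 1e-9) cnt <- cnt + 1
  }
  cnt / ncol(combos)
}

# exact two-sided KS p by enumerating every split of the pooled sample
oracle_ks <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  Dstat <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(g) - ecdf(b)(g)))
  }
  obs <- Dstat(x, y)
  pooled <- c(x, y)
  combos <- combn(nx + ny, nx)
  cnt <- 0
  for (j in seq_len(ncol(combos))) {
    a <- pooled[combos[, j]]
    b <- pooled[-combos[, j]]
    if (Dstat(a, b) >= obs - 1e-9) cnt <- cnt + 1
  }
  list(D = obs, p = cnt / ncol(combos))
}

# two-sided Fisher p: hypergeometric enumeration over tables with the
# observed margins, summing probabilities <= the observed table's
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  if (n == 0) return(1)
  prob_a <- function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }
  a_obs <- tab[1, 1]
  p_obs <- prob_a(a_obs)
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  tot <- 0
  for (a in lo:hi) {
    pa <- prob_a(a)
    if (pa <= p_obs * (1 + 1e-7)) tot <- tot + pa
  }
  min(tot, 1)
}

# -- segmentation oracle -----------------------------------------------------

# exhaustive search over all segmentations with at most 2 breakpoints
oracle_segment_dp <- function(signal, penalty, min_len) {
  n <- length(signal)
  sse <- function(i, j) {
    seg <- signal[(i + 1):j]
    sum((seg - mean(seg))^2)
  }
  best <- sse(0, n)                    # 0 breakpoints
  if (n >= 2 * min_len) {
    for (b in min_len:(n - min_len)) {
      v <- sse(0, b) + sse(b, n) + penalty
      if (v < best) best <- v
    }
  }
  if (n >= 3 * min_len) {
    for (b1 in min_len:(n - 2 * min_len)) {
      for (b2 in (b1 + min_len):(n - min_len)) {
        v <- sse(0, b1) + sse(b1, b2) + sse(b2, n) + 2 * penalty
        if (v < best) best <- v
      }
    }
  }
  best
}

# -- misc --------------------------------------------------------------------

make_families <- function(seeds) {
  lapply(seq_along(seeds), function(i) {
    mirna_family(sprintf("fam%03d", i), seeds[i])
  })
}

expect_same_sites <- function(sites, oracle) {
  expect_equal(nrow(sites), nrow(oracle))
  if (nrow(oracle) > 0) {
    expect_equal(sites$site_type, oracle$site_type)
    expect_equal(sites$start, oracle$start)
    expect_equal(sites$end, oracle$end)
  }
}
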