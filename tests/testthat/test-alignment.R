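# Alignment construction, coordinate mapping, conservation calling.

test_that("alignment construction validates rows", {
  expect_error(utr_alignment("g", c(human = "ACGU", chicken = "ACG"), "human"),
               "unequal widths")
  expect_error(utr_alignment("g", c(human = "ACGU", chicken = "ACGX"), "human"),
               "invalid")
  expect_error(utr_alignment("g", c(human = "ACGU", chicken = "ACGU"), "mouse"),
               "reference species")
  aln <- utr_alignment("g", c(human = "AC-GU", chicken = "ACAGU"), "human")
  expect_equal(reference_utr(aln), "ACGU")
})

test_that("site spans map through gaps correctly", {
  # gapless: identity mapping
  aln <- utr_alignment("g", c(h = "ACGUACGUACGU", c = "ACGUACGUACGU"), "h")
  expect_equal(map_to_alignment(aln, list(start = 2, end = 10)),
               c(start = 2, end = 10))
  # reference "AA--CCGG": ungapped "AACCGG", site [2,4) -> columns [4,6)
  aln <- utr_alignment("g", c(h = "AA--CCGG", c = "AAGGCCGG"), "h")
  expect_equal(map_to_alignment(aln, list(start = 2, end = 4)),
               c(start = 4, end = 6))
  expect_error(map_to_alignment(aln, list(start = 5, end = 7)), "out of range")
})

test_that("span mapping agrees with the full index-map oracle", {
  set.seed(11)
  for (i in 1:40) {
    aln <- random_gapped_alignment(width = sample(40:150, 1))
    ref <- reference_utr(aln)
    L <- nchar(ref)
    if (L < 8) next
    s0 <- sample(0:(L - 8), 1)
    span <- map_to_alignment(aln, list(start = s0, end = s0 + 8))
    map <- oracle_index_map(aln$rows[[aln$reference_species]])
    expect_equal(unname(span["start"]), map[s0 + 1] - 1)
    expect_equal(unname(span["end"]), map[s0 + 8])
    # round trip: the mapped columns, de-gapped on the reference row,
    # reproduce exactly the ungapped span
    cols <- (span["start"] + 1):span["end"]
    ch <- strsplit(aln$rows[[aln$reference_species]], "")[[1]][cols]
    expect_equal(paste(ch[ch != "-"], collapse = ""),
                 substr(ref, s0 + 1, s0 + 8))
  }
})

test_that("perfect-identity calls react to substitutions and gaps", {
  rows <- c(h = "GGUUUUUUUAGG", c = "GGUUUUUUUAGG")
  aln <- utr_alignment("g", rows, "h")
  site <- list(start = 2, end = 10)
  expect_true(call_conserved(aln, site, "h", "c")$conserved)
  # one substitution inside the span
  rows2 <- rows; substr(rows2["c"], 5, 5) <- "G"
  expect_false(call_conserved(utr_alignment("g", rows2, "h"), site,
                              "h", "c")$conserved)
  # a gap inside the span
  rows3 <- rows; substr(rows3["c"], 5, 5) <- "-"
  expect_false(call_conserved(utr_alignment("g", rows3, "h"), site,
                              "h", "c")$conserved)
  # substitution outside the span does not matter
  rows4 <- rows; substr(rows4["c"], 1, 1) <- "C"
  expect_true(call_conserved(utr_alignment("g", rows4, "h"), site,
                             "h", "c")$conserved)
  expect_error(call_conserved(aln, site, "h", "mouse"), "absent")
})

test_that("conservation calls are symmetric in the species pair", {
  set.seed(12)
  for (i in 1:20) {
    aln <- random_gapped_alignment(width = 80)
    L <- nchar(reference_utr(aln))
    if (L < 8) next
    s0 <- sample(0:(L - 8), 1)
    site <- list(start = s0, end = s0 + 8)
    expect_equal(call_conserved(aln, site, "human", "chicken")$conserved,
                 call_conserved(aln, site, "chicken", "human")$conserved)
  }
})

test_that("per-column signal matches a column-wise oracle", {
  aln <- utr_alignment("g", c(h = "AC-GUA", c = "ACAGU-"), "h")
  # ungapped ref positions: cols 1,2,4,5,6 -> identity T,T,T,T,F(gap)
  expect_equal(per_column_conservation_signal(aln, c("h", "c")),
               c(1, 1, 1, 1, 0))
  expect_equal(per_column_conservation_signal(
    utr_alignment("g", c(h = "ACGU", c = "ACGU"), "h"), c("h", "c")),
    rep(1, 4))
  expect_equal(per_column_conservation_signal(
    utr_alignment("g", c(h = "ACGU", c = "----"), "h"), c("h", "c")),
    rep(0, 4))
  set.seed(13)
  for (i in 1:20) {
    aln <- random_gapped_alignment(width = 60)
    sig <- per_column_conservation_signal(aln, c("human", "chicken"))
    ref_row <- strsplit(aln$rows[["human"]], "")[[1]]
    par_row <- strsplit(aln$rows[["chicken"]], "")[[1]]
    keep <- ref_row != "-"
    expect_equal(sig, as.numeric(ref_row[keep] != "-" & par_row[keep] != "-" &
                                   ref_row[keep] == par_row[keep]))
    expect_equal(length(sig), nchar(reference_utr(aln)))
  }
})

test_that("conserved-site counts agree with site-by-site enumeration", {
  set.seed(14)
  fams <- make_families(replicate(5, random_seed7()))
  for (i in 1:15) {
    aln <- random_gapped_alignment(width = 400, gap_prob = 0.03)
    cc <- count_conserved_sites(aln, fams, "human", "chicken")
    # oracle: scan the ungapped reference with the brute-force scanner,
    # then call each site independently
    ref <- reference_utr(aln)
    n_sites <- 0; n_cons <- 0
    for (f in fams) {
      os <- oracle_scan(ref, f$seed)
      n_sites <- n_sites + nrow(os)
      if (nrow(os) > 0) {
        for (j in seq_len(nrow(os))) {
          if (oracle_site_conserved(aln$rows, "human", "human", "chicken",
                                    os$start[j], os$end[j])) {
            n_cons <- n_cons + 1
          }
        }
      }
    }
    expect_equal(cc$n_sites, n_sites)
    expect_equal(cc$n_conserved, n_cons)
    expect_true(cc$n_conserved <= cc$n_sites)
  }
})

test_that("identical rows conserve every planted site; gapped partner none", {
  fam <- mirna_family("t", "ACGUACG")
  pat <- site_patterns(fam)[["8mer"]]
  utr <- paste0("GGGGG", pat, "GGGGG", pat, "GGGGG")
  aln <- utr_alignment("g", c(h = utr, c = utr), "h")
  expect_equal(count_conserved_sites(aln, list(fam), "h", "c")$n_conserved, 2L)
  gapped <- paste(rep("-", nchar(utr)), collapse = "")
  aln2 <- utr_alignment("g", c(h = utr, c = gapped), "h")
  expect_equal(count_conserved_sites(aln2, list(fam), "h", "c")$n_conserved, 0L)
})

test_that("replacing the partner row by the reference never lowers the count", {
  set.seed(15)
  fams <- make_families(replicate(4, random_seed7()))
  for (i in 1:15) {
    aln <- random_gapped_alignment(width = 300, gap_prob = 0.05)
    base <- count_conserved_sites(aln, fams, "human", "chicken")$n_conserved
    rows <- aln$rows
    rows[["chicken"]] <- rows[["human"]]
    self <- count_conserved_sites(utr_alignment("g", rows, "human"),
                                  fams, "human", "chicken")$n_conserved
    expect_gte(self, base)
  }
})

test_that("aligned FASTA round-trips per-gene alignments", {
  set.seed(16)
  alns <- list(random_gapped_alignment("geneA", width = 50),
               random_gapped_alignment("geneB", width = 70,
                                       species = c("human", "chicken",
                                                   "opossum")))
  path <- tempfile(fileext = ".fasta")
  write_utr_alignments(alns, path)
  back <- read_utr_alignments(path, "human")
  expect_equal(names(back), c("geneA", "geneB"))
  expect_equal(back$geneA$rows, alns[[1]]$rows)
  expect_equal(back$geneB$rows, alns[[2]]$rows)
  # malformed header is a parse error naming the record
  writeLines(c(">geneC_nospecies", "ACGU"), path)
  expect_error(read_utr_alignments(path, "human"), "geneID\\|species")
})
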