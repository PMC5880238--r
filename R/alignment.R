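# Per-gene cross-species 3' UTR alignments and conserved-site calling.
#
# An alignment holds one gapped row per species; sites are scanned on the
# ungapped reference row and mapped into alignment columns. A site is
# conserved for a species pair when both rows are gap-free and identical
# over the mapped column span (the strict perfect-identity criterion,
# including the A1 anchor where it is part of the site type).

#' Construct a per-gene UTR alignment
#'
#' @param gene_id gene identifier.
#' @param rows named character vector or list, species -> gapped sequence
#'   over {A,C,G,U,N,-} (T normalized to U). All rows must share one width.
#' @param reference_species the species whose ungapped row is scanned for
#'   sites; must be a name of `rows`.
#' @return object of class `utr_alignment`.
#' @examples
#' aln <- utr_alignment("g1",
#'   c(human = "ACGUACGU", chicken = "ACGU-CGU"), "human")
#' per_column_conservation_signal(aln, c("human", "chicken"))
#' @export
utr_alignment <- function(gene_id, rows, reference_species) {
  rows <- vapply(rows, normalize_rna, character(1))
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("alignment rows must be named by species")
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("gene ", gene_id, ": alignment rows have unequal widths: ",
         paste(widths, collapse = ", "))
  }
  for (sp in names(rows)) {
    assert_rna_alphabet(rows[[sp]], allow = c("A", "C", "G", "U", "N", "-"),
                        what = paste0("row ", sp, " of gene ", gene_id))
  }
  if (!reference_species %in% names(rows)) {
    stop("reference species '", reference_species,
         "' absent from alignment of gene ", gene_id)
  }
  structure(list(gene_id = gene_id, rows = rows,
                 reference_species = reference_species,
                 width = unname(widths[1])),
            class = "utr_alignment")
}

#' @export
print.utr_alignment <- function(x, ...) {
  cat(sprintf("<utr_alignment> %s: %d species x %d columns (ref %s)\n",
              x$gene_id, length(x$rows), x$width, x$reference_species))
  invisible(x)
}

#' Ungapped reference UTR of an alignment
#' @param alignment a [utr_alignment()].
#' @return the reference row with gaps removed.
#' @export
reference_utr <- function(alignment) {
  gsub("-", "", alignment$rows[[alignment$reference_species]], fixed = TRUE)
}

# 1-based alignment columns of the non-gap positions of a row
.ungapped_columns <- function(alignment, species) {
  ch <- strsplit(alignment$rows[[species]], "", fixed = TRUE)[[1]]
  which(ch != "-")
}

#' Map an ungapped-reference site span to alignment columns
#'
#' Columns where the reference row is gapped (insertions in other species)
#' that fall strictly inside the site are included in the span.
#'
#' @param alignment a [utr_alignment()].
#' @param site one-row site data.frame (or list) with 0-based half-open
#'   `start`, `end` on the ungapped reference row.
#' @return integer vector c(start, end), 0-based half-open alignment columns.
#' @export
map_to_alignment <- function(alignment, site) {
  m <- .ungapped_columns(alignment, alignment$reference_species)
  L <- length(m)
  s <- site$start
  e <- site$end
  if (is.na(s) || is.na(e) || s < 0L || e <= s || e > L) {
    stop("site span [", s, ",", e, ") out of range for gene ",
         alignment$gene_id, " (UTR length ", L, ")")
  }
  c(start = m[s + 1L] - 1L, end = m[e])
}

# per-column logical: both rows non-gap and identical
.pair_identity <- function(alignment, species_a, species_b) {
  for (sp in c(species_a, species_b)) {
    if (!sp %in% names(alignment$rows)) {
      stop("species '", sp, "' absent from alignment of gene ",
           alignment$gene_id)
    }
  }
  a <- strsplit(alignment$rows[[species_a]], "", fixed = TRUE)[[1]]
  b <- strsplit(alignment$rows[[species_b]], "", fixed = TRUE)[[1]]
  a != "-" & b != "-" & a == b
}

#' Call perfect-identity conservation of one site for a species pair
#'
#' @inheritParams map_to_alignment
#' @param species_a,species_b species names present in the alignment.
#' @return list with the site fields plus species_a, species_b and logical
#'   `conserved`.
#' @export
call_conserved <- function(alignment, site, species_a, species_b) {
  span <- map_to_alignment(alignment, site)
  ok <- .pair_identity(alignment, species_a, species_b)
  conserved <- all(ok[(span[["start"]] + 1L):span[["end"]]])
  list(site = site, species_a = species_a, species_b = species_b,
       conserved = conserved)
}

#' Per-column conservation signal over ungapped reference positions
#'
#' @inheritParams call_conserved
#' @return numeric 0/1 vector, one entry per ungapped reference position:
#'   1 iff that column is gap-free and identical between the pair.
#' @export
per_column_conservation_signal <- function(alignment, species_pair) {
  ok <- .pair_identity(alignment, species_pair[1], species_pair[2])
  m <- .ungapped_columns(alignment, alignment$reference_species)
  as.numeric(ok[m])
}

# Precomputed per-gene machinery for repeated conserved-site counting:
# substring index of the ungapped reference, the ungapped->gapped column
# map, and a cumulative count of non-identical columns for O(1) span checks.
conservation_context <- function(alignment, species_a, species_b) {
  ref <- reference_utr(alignment)
  ok <- .pair_identity(alignment, species_a, species_b)
  list(index = utr_site_index(ref),
       map = .ungapped_columns(alignment, alignment$reference_species),
       bad_cum = c(0L, cumsum(!ok)),
       utr_length = nchar(ref))
}

# conserved flags for 0-based half-open ungapped spans, given a context
.spans_conserved <- function(ctx, start, end) {
  if (length(start) == 0L) return(logical(0))
  gs <- ctx$map[start + 1L] - 1L          # 0-based gapped start
  ge <- ctx$map[end]                       # gapped end (half-open)
  ctx$bad_cum[ge + 1L] - ctx$bad_cum[gs + 1L] == 0L
}

#' Count conserved target sites for a species pair
#'
#' Scans the ungapped reference row for all families' canonical sites and
#' counts those conserved with perfect identity between the species pair.
#'
#' @param alignment a [utr_alignment()].
#' @param families list of [mirna_family()] objects.
#' @param species_a,species_b the species pair.
#' @return list with `n_sites`, `n_conserved`, per-family integer vectors
#'   `sites_by_family`, `conserved_by_family`, and the site table `sites`
#'   (with a `conserved` column).
#' @export
count_conserved_sites <- function(alignment, families, species_a, species_b) {
  ctx <- conservation_context(alignment, species_a, species_b)
  sites <- scan_utr_families(NULL, families, gene_id = alignment$gene_id,
                             index = ctx$index)
  sites$conserved <- .spans_conserved(ctx, sites$start, sites$end)
  fam_ids <- vapply(families, `[[`, character(1), "family_id")
  ffac <- factor(sites$family_id, levels = fam_ids)
  list(
    gene_id = alignment$gene_id,
    species_pair = c(species_a, species_b),
    n_sites = nrow(sites),
    n_conserved = sum(sites$conserved),
    sites_by_family = as.integer(table(ffac)),
    conserved_by_family = as.integer(table(ffac[sites$conserved])),
    sites = sites
  )
}

# FASTA IO -------------------------------------------------------------------

#' Read per-gene UTR alignments from an aligned multi-FASTA
#'
#' Headers follow the "geneID|species" convention; records sharing a geneID
#' form one alignment. '-' marks gaps.
#'
#' @param path FASTA path.
#' @param reference_species the reference species for every alignment.
#' @return named list of [utr_alignment()] objects, in file order.
#' @export
read_utr_alignments <- function(path, reference_species) {
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) {
    stop("malformed alignment FASTA header (expected 'geneID|species') at ",
         "record ", bad[1], " of ", path, ": '", headers[bad[1]], "'")
  }
  gene <- vapply(parts, `[[`, character(1), 1L)
  species <- vapply(parts, `[[`, character(1), 2L)
  rows <- as.character(seqs)
  out <- lapply(unique(gene), function(g) {
    sel <- gene == g
    utr_alignment(g, stats::setNames(rows[sel], species[sel]),
                  reference_species)
  })
  stats::setNames(out, unique(gene))
}

#' Write per-gene UTR alignments as aligned multi-FASTA
#' @param alignments list of [utr_alignment()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_utr_alignments <- function(alignments, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (aln in alignments) {
    for (sp in names(aln$rows)) {
      writeLines(c(paste0(">", aln$gene_id, "|", sp), aln$rows[[sp]]), con)
    }
  }
  invisible(path)
}
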