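#' @keywords internal
"_PACKAGE"

# RNA alphabet helpers -------------------------------------------------------

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Gap characters ('-') and N are preserved.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over {A,C,G,U,N,-}.
#' @keywords internal
normalize_rna <- function(x) {
  chartr("tT", "uU", toupper(x))
}

#' Reverse complement of an RNA string
#' @param x single RNA string over {A,C,G,U}.
#' @return the reverse complement, same alphabet.
#' @keywords internal
reverse_complement_rna <- function(x) {
  if (grepl("[^ACGU]", x)) {
    ch <- strsplit(x, "", fixed = TRUE)[[1]]
    stop("non-ACGU character in sequence: ",
         paste(unique(ch[!ch %in% names(RNA_COMPLEMENT)]), collapse = ", "))
  }
  chartr("ACGU", "UGCA", intToUtf8(rev(utf8ToInt(x))))
}

assert_rna_alphabet <- function(x, allow = c("A", "C", "G", "U"),
                                what = "sequence") {
  ch <- unique(strsplit(x, "", fixed = TRUE)[[1]])
  bad <- setdiff(ch, allow)
  if (length(bad) > 0) {
    stop(what, " contains invalid characters: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# TSV with metadata header ---------------------------------------------------

#' Write a table as TSV with a '# key=value' metadata header
#'
#' All pipeline outputs use this dialect so that configuration and seeds
#' travel with the data. Metadata lines start with '#' and precede the
#' column header.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named list/vector of metadata values (coerced to character).
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta) > 0) {
    writeLines(sprintf("# %s=%s", names(meta),
                       vapply(meta,
                              function(v) paste(as.character(unlist(v)),
                                                collapse = ","),
                              character(1))), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path input path.
#' @return data.frame with an attribute `"meta"` holding the parsed
#'   key=value header lines.
#' @export
read_tsv_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 200L)
  metalines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in metalines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "meta") <- meta
  df
}

# misc -----------------------------------------------------------------------

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# ranks rescaled to [0, 1]; single value maps to 0.5
rank01 <- function(x) {
  n <- length(x)
  if (n <= 1) return(rep(0.5, n))
  (rank(x, ties.method = "average") - 1) / (n - 1)
}
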