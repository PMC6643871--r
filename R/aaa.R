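# Internal helpers shared across modules.
#
# All genomic intervals inside the package are 0-based half-open [start, end).
# Conversion to/from the 1-based inclusive convention of GFF3/SAM happens only
# in the I/O layer (io0()/io1() below).

# 0-based half-open -> 1-based inclusive
io1 <- function(start0, end0) list(start = start0 + 1L, end = end0)

# 1-based inclusive -> 0-based half-open
io0 <- function(start1, end1) list(start = start1 - 1L, end = end1)

`%||%` <- function(a, b) if (is.null(a)) b else a

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")
SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES, paste0)),
  STOP_CODONS)

#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   reverseComplement subseq
#' @importFrom rlang .data
NULL

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Standard genetic code as a plain lookup table ('*' for stops).
GENETIC_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

# Translate an in-frame nucleotide string; ambiguous codons become 'X'.
# Trailing partial codon is dropped.
translate_nt <- function(s) {
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return("")
  cods <- substring(s, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
  aa <- GENETIC_TABLE[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Positions (1-based, codon units) of '*' in a protein string.
stop_positions <- function(protein) {
  which(strsplit(protein, "", fixed = TRUE)[[1]] == "*")
}

# Substitution matrices used engine-wide ------------------------------------

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

nucl_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = FALSE
      )
    }
    m
  }
})

# interval arithmetic on plain (start, end) 0-based half-open vectors --------

interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# Deterministic TSV writer (no quoting surprises, "\n" endings, NA as "NA").
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  is_list <- vapply(df, is.list, logical(1))
  df <- df[, !is_list, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     eol = "\n")
  invisible(path)
}

new_tbl <- function(...) tibble::tibble(...)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
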