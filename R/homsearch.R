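#' Homology search parameters
#'
#' Desk-scale replacement for blastp/blastn/tblastn. Scores are full
#' Smith--Waterman affine-gap optima (the optional word seed only prunes
#' query/subject pairs, it never alters a reported score). Significance uses
#' Karlin--Altschul statistics `E = K * m * n * exp(-lambda * S)` with raw
#' (uncorrected) query length `m` and total database length `n`. Gapped
#' constants: BLOSUM62 `lambda = 0.267`, `K = 0.041`; nucleotide +2/-3
#' `lambda = 0.625`, `K = 0.41`.
#'
#' @param mode `"pp"` (protein query vs protein db), `"nn"` (nucleotide vs
#'   nucleotide), or `"px"` (protein query vs translated nucleotide db, all
#'   six frames).
#' @param e_max E-value threshold; hits with `e_value <= e_max` are reported
#'   (inclusive, matching the classification cascade's "<=" wording).
#' @param gap_open,gap_ext affine gap costs (a gap of length k costs
#'   `gap_open + k * gap_ext`).
#' @param word_size seed word length (3 aa / 11 nt); `0` disables seeding.
#' @param low_complexity mask low-complexity query segments before searching
#'   (off by default; the classification cascade runs unfiltered).
#' @param lambda,K Karlin--Altschul constants.
#' @return A list of class `search_params`.
#' @export
search_params <- function(mode = c("pp", "nn", "px"),
                          e_max = 1e-3,
                          gap_open = NULL, gap_ext = NULL,
                          word_size = NULL,
                          low_complexity = FALSE,
                          lambda = NULL, K = NULL) {
  mode <- match.arg(mode)
  protein_scoring <- mode %in% c("pp", "px")
  p <- list(
    mode = mode,
    e_max = e_max,
    gap_open = gap_open %||% if (protein_scoring) 11 else 5,
    gap_ext = gap_ext %||% if (protein_scoring) 1 else 2,
    word_size = word_size %||% if (protein_scoring) 3L else 11L,
    low_complexity = low_complexity,
    lambda = lambda %||% if (protein_scoring) 0.267 else 0.625,
    K = K %||% if (protein_scoring) 0.041 else 0.41
  )
  assert_that(p$e_max > 0, "e_max must be positive")
  class(p) <- "search_params"
  p
}

as_seq_set <- function(x, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (is.character(x)) {
    x <- if (type == "AA") Biostrings::AAStringSet(x) else
      Biostrings::DNAStringSet(x)
  }
  x
}

# shared exact word of length w between two plain strings
has_shared_word <- function(q, s, w) {
  nq <- nchar(q); ns <- nchar(s)
  if (nq < w || ns < w) return(FALSE)
  qw <- unique(substring(q, seq_len(nq - w + 1L), seq_len(nq - w + 1L) + w - 1L))
  sw <- unique(substring(s, seq_len(ns - w + 1L), seq_len(ns - w + 1L) + w - 1L))
  any(qw %in% sw)
}

# crude entropy mask: windows of length 12 with <= 2 distinct residues -> X
mask_low_complexity <- function(seq) {
  n <- nchar(seq)
  if (n < 12L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  mask <- logical(n)
  for (i in seq_len(n - 11L)) {
    win <- ch[i:(i + 11L)]
    if (length(unique(win)) <= 2L) mask[i:(i + 11L)] <- TRUE
  }
  ch[mask] <- "X"
  paste(ch, collapse = "")
}

#' Translate a nucleotide sequence in all six frames
#'
#' Frames are labeled `+1, +2, +3` (offsets 0/1/2 on the given strand) and
#' `-1, -2, -3` (offsets 0/1/2 on the reverse complement). Stop codons are
#' rendered `*`.
#'
#' @param nucl a nucleotide string (IUPAC alphabet), length >= 3.
#' @return Tibble: `frame` (integer in `c(1,2,3,-1,-2,-3)`), `protein`.
#' @export
translate_six_frames <- function(nucl) {
  nucl <- toupper(as.character(nucl))
  assert_that(nchar(nucl) >= 3L, "sequence shorter than one codon")
  assert_that(!grepl("[^ACGTRYSWKMBDHVN]", nucl),
              "non-IUPAC characters in nucleotide sequence")
  rc <- revcomp(nucl)
  new_tbl(
    frame = c(1L, 2L, 3L, -1L, -2L, -3L),
    protein = c(
      vapply(1:3, function(o) translate_nt(substr(nucl, o, nchar(nucl))),
             character(1)),
      vapply(1:3, function(o) translate_nt(substr(rc, o, nchar(rc))),
             character(1))
    )
  )
}

# map aa interval (1-based, on a frame translation) to genomic 0-based
frame_to_genomic <- function(frame, aa_start, aa_end, subj_len) {
  off <- abs(frame) - 1L
  s <- off + 3L * (aa_start - 1L)
  e <- off + 3L * aa_end
  if (frame > 0) c(s, e) else c(subj_len - e, subj_len - s)
}

#' Search queries against a subject database
#'
#' Every reported score is the exact Smith--Waterman affine-gap optimum for
#' the query/subject pair (translated mode: per frame); hits are sorted by
#' E-value. In `"px"` mode each subject is scanned in all six frames and a
#' hit records the frame and the genomic interval on the subject.
#'
#' @param queries named character vector or `XStringSet` (protein for
#'   `pp`/`px`, nucleotide for `nn`).
#' @param subjects named character vector or `XStringSet` (nucleotide for
#'   `nn`/`px`).
#' @param params a [search_params()] object.
#' @param db_kind label stamped on hits (`"proteins"`, `"genome"`,
#'   `"annotated-transcripts"`, `"transcriptome-assembly"`, ...).
#' @return Hit tibble: `query_id`, `subject_id`, `mode`, `score`,
#'   `bit_score`, `e_value`, `pct_identity`, `q_start`, `q_end`, `s_start`,
#'   `s_end` (0-based half-open; genomic for `px`), `s_frame` (0 for
#'   non-translated modes), `subject_db_kind`.
#' @export
search_homology <- function(queries, subjects, params = search_params(),
                            db_kind = "proteins") {
  qtype <- if (params$mode == "nn") "DNA" else "AA"
  stype <- if (params$mode == "pp") "AA" else "DNA"
  queries <- as_seq_set(queries, qtype)
  subjects <- as_seq_set(subjects, stype)
  assert_that(length(queries) > 0, "empty query set")
  assert_that(!is.null(names(queries)) && all(nzchar(names(queries))),
              "queries must be named")
  if (length(subjects) > 0)
    assert_that(!is.null(names(subjects)) && all(nzchar(names(subjects))),
                "subjects must be named")
  assert_that(!anyDuplicated(names(subjects)),
              "subject database has duplicate sequence IDs")
  if (length(subjects) == 0) return(empty_hits())

  n_db <- sum(Biostrings::width(subjects))
  submat <- if (params$mode == "nn") nucl_matrix() else blosum62()

  # per-subject search units: for px, the six frame translations
  sub_chr <- as.character(subjects)
  units <- list()
  for (si in seq_along(sub_chr)) {
    sid <- names(sub_chr)[si]
    if (params$mode == "px") {
      fr <- translate_six_frames(sub_chr[[si]])
      for (k in seq_len(nrow(fr))) {
        if (nchar(fr$protein[k]) == 0) next
        units[[length(units) + 1L]] <- list(
          subject_id = sid, frame = fr$frame[k], strand = "+",
          seq = fr$protein[k], subj_len = nchar(sub_chr[[si]]))
      }
    } else if (params$mode == "nn") {
      # both strands, like blastn; minus-strand hits are reported in
      # forward coordinates with s_strand = "-"
      units[[length(units) + 1L]] <- list(
        subject_id = sid, frame = 0L, strand = "+", seq = sub_chr[[si]],
        subj_len = nchar(sub_chr[[si]]))
      units[[length(units) + 1L]] <- list(
        subject_id = sid, frame = 0L, strand = "-",
        seq = revcomp(sub_chr[[si]]), subj_len = nchar(sub_chr[[si]]))
    } else {
      units[[length(units) + 1L]] <- list(
        subject_id = sid, frame = 0L, strand = "+", seq = sub_chr[[si]],
        subj_len = nchar(sub_chr[[si]]))
    }
  }
  unit_seq <- vapply(units, `[[`, "", "seq")
  unit_set <- if (params$mode == "nn") Biostrings::DNAStringSet(unit_seq) else
    Biostrings::AAStringSet(unit_seq)

  out <- list()
  for (qi in seq_along(queries)) {
    qid <- names(queries)[qi]
    qseq <- as.character(queries[[qi]])
    assert_that(nchar(qseq) > 0, paste0("empty query sequence: ", qid))
    if (params$low_complexity) qseq <- mask_low_complexity(qseq)
    m <- nchar(qseq)
    # the word seed only prunes small subjects; scanning words of a long
    # contig costs more than aligning against it
    keep <- if (params$word_size > 0L) {
      vapply(unit_seq, function(s) {
        nchar(s) > 5000L || has_shared_word(qseq, s, params$word_size)
      }, logical(1), USE.NAMES = FALSE)
    } else rep(TRUE, length(units))
    if (!any(keep)) next
    qx <- if (params$mode == "nn") Biostrings::DNAString(qseq) else
      Biostrings::AAString(qseq)
    scores <- Biostrings::pairwiseAlignment(
      unit_set[keep], qx, type = "local", substitutionMatrix = submat,
      gapOpening = params$gap_open, gapExtension = params$gap_ext,
      scoreOnly = TRUE)
    ev <- params$K * m * n_db * exp(-params$lambda * scores)
    hit_idx <- which(ev <= params$e_max)
    if (length(hit_idx) == 0) next
    keep_ids <- which(keep)[hit_idx]
    for (j in seq_along(keep_ids)) {
      u <- units[[keep_ids[j]]]
      pa <- Biostrings::pairwiseAlignment(
        qx,
        if (params$mode == "nn") Biostrings::DNAString(u$seq) else
          Biostrings::AAString(u$seq),
        type = "local", substitutionMatrix = submat,
        gapOpening = params$gap_open, gapExtension = params$gap_ext)
      sc <- Biostrings::score(pa)
      a_start <- Biostrings::start(Biostrings::subject(pa))
      a_end <- Biostrings::end(Biostrings::subject(pa))
      if (u$frame != 0L) {
        g <- frame_to_genomic(u$frame, a_start, a_end, u$subj_len)
        s_start <- g[1]; s_end <- g[2]
      } else if (u$strand == "-") {
        s_start <- u$subj_len - a_end; s_end <- u$subj_len - (a_start - 1L)
      } else {
        s_start <- a_start - 1L; s_end <- a_end
      }
      out[[length(out) + 1L]] <- new_tbl(
        query_id = qid, subject_id = u$subject_id, mode = params$mode,
        score = sc,
        bit_score = (params$lambda * sc - log(params$K)) / log(2),
        e_value = params$K * m * n_db * exp(-params$lambda * sc),
        pct_identity = Biostrings::pid(pa),
        q_start = Biostrings::start(Biostrings::pattern(pa)) - 1L,
        q_end = Biostrings::end(Biostrings::pattern(pa)),
        s_start = s_start, s_end = s_end,
        s_frame = u$frame, s_strand = u$strand,
        align_length = Biostrings::nchar(pa),
        n_ident = Biostrings::nmatch(pa),
        subject_db_kind = db_kind)
    }
  }
  if (length(out) == 0) return(empty_hits())
  hits <- dplyr::bind_rows(out)
  dplyr::arrange(hits, .data$e_value, -.data$score, .data$query_id,
                 .data$subject_id, .data$s_frame)
}

empty_hits <- function() {
  new_tbl(query_id = character(), subject_id = character(),
          mode = character(), score = numeric(), bit_score = numeric(),
          e_value = numeric(), pct_identity = numeric(),
          q_start = integer(), q_end = integer(),
          s_start = integer(), s_end = integer(), s_frame = integer(),
          s_strand = character(),
          align_length = integer(), n_ident = integer(),
          subject_db_kind = character())
}

#' Read/write BLAST tabular (outfmt 6) hit files
#'
#' Interop with external engines for users running real genomes: the reader
#' turns standard 12-column `-outfmt 6` output into the package's hit tibble;
#' the writer does the reverse (coordinates become 1-based inclusive, minus
#' frame hits get `sstart > send`).
#'
#' @param path file path.
#' @param mode,db_kind annotations to stamp on parsed hits.
#' @return `read_outfmt6()`: a hit tibble; `write_outfmt6()`: `path`,
#'   invisibly.
#' @export
read_outfmt6 <- function(path, mode = "pp", db_kind = "proteins") {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("qseqid", "sseqid", "pident",
                                        "length", "mismatch", "gapopen",
                                        "qstart", "qend", "sstart", "send",
                                        "evalue", "bitscore"))
  minus <- df$sstart > df$send
  s_lo <- pmin(df$sstart, df$send); s_hi <- pmax(df$sstart, df$send)
  new_tbl(
    query_id = df$qseqid, subject_id = df$sseqid, mode = mode,
    score = NA_real_, bit_score = df$bitscore, e_value = df$evalue,
    pct_identity = df$pident,
    q_start = df$qstart - 1L, q_end = df$qend,
    s_start = s_lo - 1L, s_end = s_hi,
    s_frame = ifelse(mode == "px", ifelse(minus, -1L, 1L), 0L),
    s_strand = ifelse(minus & mode != "px", "-", "+"),
    align_length = df$length,
    n_ident = as.integer(round(df$length * df$pident / 100)),
    subject_db_kind = db_kind)
}

#' @rdname read_outfmt6
#' @param hits a hit tibble from [search_homology()].
#' @export
write_outfmt6 <- function(hits, path) {
  minus <- hits$s_frame < 0L
  sstart <- ifelse(minus, hits$s_end, hits$s_start + 1L)
  send <- ifelse(minus, hits$s_start + 1L, hits$s_end)
  df <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = sprintf("%.3f", hits$pct_identity),
    length = hits$align_length,
    mismatch = hits$align_length - hits$n_ident,
    gapopen = 0L,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = sstart, send = send,
    evalue = sprintf("%.3g", hits$e_value),
    bitscore = sprintf("%.1f", hits$bit_score))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
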