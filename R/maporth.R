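#' Synteny blocks from best-reciprocal protein hits
#'
#' Anchors are best-reciprocal protein hits between two species (the
#' paralog-robust gene-level notion of orthology); blocks are maximal
#' collinear chains of anchors found by longest-increasing-subsequence
#' chaining of the partner gene order along each contig pair, in both
#' orientations. Chained anchors are consumed, so blocks never overlap on
#' the first species' genome.
#'
#' @param hits protein-protein hit tibble between the two species (queries
#'   from species A, subjects from species B), e.g. from [search_homology()].
#' @param gene_coords tibble with `gene_id`, `species`, `contig`, `start`,
#'   `end`, `strand` for both species (see [gene_spans()]).
#' @param min_anchors minimum anchors per block.
#' @return Tibble: `block_id`, `species_a`, `species_b`, `contig_a`,
#'   `contig_b`, `orientation` (`"+"`/`"-"`), `n_anchors`, `anchors`
#'   (list-column: `gene_a`, `gene_b`, `start_a`, `start_b`).
#' @export
find_synteny_blocks <- function(hits, gene_coords, min_anchors = 3L) {
  empty <- new_tbl(block_id = character(), species_a = character(),
                   species_b = character(), contig_a = character(),
                   contig_b = character(), orientation = character(),
                   n_anchors = integer(), anchors = list())
  if (nrow(hits) == 0) return(empty)
  # best-reciprocal pairing by score
  best_ab <- hits |>
    dplyr::group_by(.data$query_id) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  best_ba <- hits |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  brh <- dplyr::inner_join(
    best_ab[, c("query_id", "subject_id")],
    best_ba[, c("query_id", "subject_id")],
    by = c("query_id", "subject_id"))
  if (nrow(brh) == 0) return(empty)
  ca <- gene_coords[match(brh$query_id, gene_coords$gene_id), ]
  cb <- gene_coords[match(brh$subject_id, gene_coords$gene_id), ]
  anchors <- new_tbl(gene_a = brh$query_id, gene_b = brh$subject_id,
                     contig_a = ca$contig, contig_b = cb$contig,
                     start_a = ca$start, start_b = cb$start,
                     species_a = ca$species, species_b = cb$species)
  blocks <- list()
  for (key in unique(paste(anchors$contig_a, anchors$contig_b))) {
    sub <- anchors[paste(anchors$contig_a, anchors$contig_b) == key, ]
    sub <- sub[order(sub$start_a), ]
    avail <- rep(TRUE, nrow(sub))
    repeat {
      idx <- which(avail)
      if (length(idx) < min_anchors) break
      x <- sub$start_b[idx]
      up <- lis_indices(x)
      dn <- lis_indices(-x)
      chain <- if (length(up) >= length(dn)) list(i = up, o = "+") else
        list(i = dn, o = "-")
      if (length(chain$i) < min_anchors) break
      sel <- idx[chain$i]
      blocks[[length(blocks) + 1L]] <- new_tbl(
        block_id = sprintf("blk%03d", length(blocks) + 1L),
        species_a = sub$species_a[1], species_b = sub$species_b[1],
        contig_a = sub$contig_a[1], contig_b = sub$contig_b[1],
        orientation = chain$o, n_anchors = length(sel),
        anchors = list(sub[sel, c("gene_a", "gene_b", "start_a",
                                  "start_b")]))
      avail[sel] <- FALSE
    }
  }
  if (length(blocks) == 0) return(empty)
  dplyr::bind_rows(blocks)
}

# indices of one longest strictly increasing subsequence (O(n^2) DP;
# earliest chain on ties)
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L; prev[i] <- j
      }
    }
  }
  i <- which.max(len)
  out <- integer(0)
  while (i > 0L) { out <- c(i, out); i <- prev[i] }
  out
}

#' Gene spans of a gene-model table
#'
#' @param genes gene-model tibble.
#' @return Tibble: `gene_id`, `species`, `contig`, `start`, `end`, `strand`.
#' @export
gene_spans <- function(genes) {
  new_tbl(
    gene_id = genes$gene_id, species = genes$species, contig = genes$contig,
    start = vapply(genes$exons, function(e) min(e$start), numeric(1)),
    end = vapply(genes$exons, function(e) max(e$end), numeric(1)),
    strand = genes$strand)
}

#' Orthologous region of a focal locus via synteny anchors
#'
#' Returns the other-species interval between the orthologs of the anchors
#' flanking the locus. When no mappable flanking anchor exists on either
#' side, a typed empty result (`found = FALSE`) is returned, not an error.
#'
#' @param focal_interval list/one-row data frame with `contig`, `start`,
#'   `end` (focal coordinates).
#' @param block one block row from [find_synteny_blocks()].
#' @param gene_coords as in [find_synteny_blocks()].
#' @return One-row tibble: `found`, `species`, `contig`, `start`, `end`,
#'   `orientation`.
#' @export
orthologous_region <- function(focal_interval, block, gene_coords) {
  none <- new_tbl(found = FALSE, species = NA_character_,
                  contig = NA_character_, start = NA_real_, end = NA_real_,
                  orientation = NA_character_)
  if (is.null(block) || nrow(block) == 0) return(none)
  an <- block$anchors[[1]]
  if (block$contig_a[1] != focal_interval$contig) return(none)
  left <- an[an$start_a < focal_interval$start, ]
  right <- an[an$start_a > focal_interval$end, ]
  if (nrow(left) == 0 || nrow(right) == 0) return(none)
  gl <- left$gene_b[which.max(left$start_a)]
  gr <- right$gene_b[which.min(right$start_a)]
  cl <- gene_coords[gene_coords$gene_id == gl, ]
  cr <- gene_coords[gene_coords$gene_id == gr, ]
  lo <- min(cl$end, cr$end); hi <- max(cl$start, cr$start)
  if (hi <= lo) return(none)
  new_tbl(found = TRUE, species = cl$species, contig = cl$contig,
          start = lo, end = hi, orientation = block$orientation[1])
}

#' Orthologous intron interval of a host gene
#'
#' For a locus inside intron `k` (transcription order) of a host gene with a
#' mapped ortholog, returns the ortholog's intron `k` interval.
#'
#' @param host,ortholog one-row gene-model tibbles.
#' @param intron_index intron number in transcription order (1-based).
#' @return One-row tibble as in [orthologous_region()].
#' @export
host_intron_region <- function(host, ortholog, intron_index) {
  none <- new_tbl(found = FALSE, species = NA_character_,
                  contig = NA_character_, start = NA_real_, end = NA_real_,
                  orientation = NA_character_)
  ex <- ortholog$exons[[1]][order(ortholog$exons[[1]]$start), , drop = FALSE]
  n_introns <- nrow(ex) - 1L
  if (n_introns < intron_index) return(none)
  k <- if (ortholog$strand == "+") intron_index else
    n_introns - intron_index + 1L
  new_tbl(found = TRUE, species = ortholog$species,
          contig = ortholog$contig, start = ex$end[k], end = ex$start[k + 1L],
          orientation = if (host$strand == ortholog$strand) "+" else "-")
}

#' Spliced protein-to-genome alignment (simplified)
#'
#' Finds high-scoring local protein/translated-genome segments in all six
#' frames (iterative masking of matched regions), then chains compatible
#' segments (query and genome order both increasing, same strand) with a
#' bonus for canonical `GT..AG` intron boundaries and a penalty for
#' non-canonical gaps. Returns an empty map when the best chain scores
#' below `min_total`.
#'
#' @param protein protein string.
#' @param genomic_window nucleotide string (<= 200 kb).
#' @param splice_bonus,noncanon_penalty chain scoring of inter-segment gaps.
#' @param min_segment segment discovery cutoff (raw SW score).
#' @param min_total minimum chain score for a non-empty result.
#' @return List of class `spliced_map`: `segments` tibble (`q_start`,
#'   `q_end`, `g_start`, `g_end`, `frame`, `score`; 0-based half-open,
#'   genome coordinates on the forward strand of the window), `strand`,
#'   `score`.
#' @export
spliced_align <- function(protein, genomic_window, splice_bonus = 10,
                          noncanon_penalty = 10, min_segment = 25,
                          min_total = 40) {
  assert_that(nchar(genomic_window) <= 2e5,
              "window exceeds 200 kb; narrow it via synteny first")
  L <- nchar(genomic_window)
  segs <- list()
  fr <- translate_six_frames(genomic_window)
  for (k in seq_len(nrow(fr))) {
    subj <- fr$protein[k]
    if (nchar(subj) < 5) next
    for (round in seq_len(8L)) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(protein), Biostrings::AAString(subj),
        type = "local", substitutionMatrix = blosum62(),
        gapOpening = 11, gapExtension = 1)
      sc <- Biostrings::score(pa)
      if (sc < min_segment) break
      qa <- Biostrings::start(Biostrings::pattern(pa))
      qe <- Biostrings::end(Biostrings::pattern(pa))
      sa <- Biostrings::start(Biostrings::subject(pa))
      se <- Biostrings::end(Biostrings::subject(pa))
      g <- frame_to_genomic(fr$frame[k], sa, se, L)
      segs[[length(segs) + 1L]] <- new_tbl(
        q_start = qa - 1L, q_end = qe, g_start = g[1], g_end = g[2],
        frame = fr$frame[k], score = sc)
      # mask matched subject stretch and look for further segments
      substr(subj, sa, se) <- paste(rep("X", se - sa + 1L), collapse = "")
    }
  }
  if (length(segs) == 0)
    return(structure(list(segments = new_tbl(), strand = NA_character_,
                          score = 0), class = "spliced_map"))
  segs <- dplyr::bind_rows(segs)
  best <- chain_spliced_segments(segs, genomic_window, splice_bonus,
                                 noncanon_penalty)
  if (best$score < min_total)
    return(structure(list(segments = new_tbl(), strand = NA_character_,
                          score = best$score), class = "spliced_map"))
  structure(list(segments = best$chain, strand = best$strand,
                 score = best$score), class = "spliced_map")
}

# gap score between two query-ordered segments, allowing the later segment's
# fuzzy start (or the earlier one's end) to be trimmed by up to
# `overlap_tol` residues to recover the exact splice point; returns the best
# achievable gap score and the trims used
splice_gap_score <- function(ss, j, i, strand, genomic_window, splice_bonus,
                             noncanon_penalty, overlap_tol = 6L,
                             trim_cost = 2) {
  k <- max(0L, ss$q_end[j] - ss$q_start[i])
  if (k > overlap_tol) return(NULL)
  if (ss$q_end[i] <= ss$q_end[j] || ss$q_start[i] < ss$q_start[j])
    return(NULL)
  if (strand == "+" && ss$g_start[i] < ss$g_start[j]) return(NULL)
  if (strand == "-" && ss$g_start[i] > ss$g_start[j]) return(NULL)
  best <- NULL
  for (x in 0:k) {                 # x residues trimmed from j's end
    r <- k - x                     # r residues trimmed from i's start
    if (strand == "+") {
      lo <- ss$g_end[j] - 3L * x
      hi <- ss$g_start[i] + 3L * r
      donor <- "GT"; acceptor <- "AG"
    } else {
      lo <- ss$g_end[i] - 3L * r
      hi <- ss$g_start[j] + 3L * x
      donor <- "CT"; acceptor <- "AC"
    }
    if (hi - lo < 4) next
    canonical <- substr(genomic_window, lo + 1L, lo + 2L) == donor &&
      substr(genomic_window, hi - 1L, hi) == acceptor
    sc <- (if (canonical) splice_bonus else -noncanon_penalty) -
      trim_cost * k
    if (is.null(best) || sc > best$score)
      best <- list(score = sc, x = x, r = r)
  }
  best
}

# apply the chosen trims to a chained pair (j before i in query order)
apply_trims <- function(ss, j, i, strand, x, r) {
  ss$q_end[j] <- ss$q_end[j] - x
  ss$q_start[i] <- ss$q_start[i] + r
  if (strand == "+") {
    ss$g_end[j] <- ss$g_end[j] - 3L * x
    ss$g_start[i] <- ss$g_start[i] + 3L * r
  } else {
    ss$g_start[j] <- ss$g_start[j] + 3L * x
    ss$g_end[i] <- ss$g_end[i] - 3L * r
  }
  ss
}

# optimal same-strand chain of segments under the splice-gap scoring
chain_spliced_segments <- function(segs, genomic_window, splice_bonus = 10,
                                   noncanon_penalty = 10) {
  best <- list(score = -Inf, chain = NULL, strand = NA_character_)
  for (strand in c("+", "-")) {
    ss <- segs[sign(segs$frame) == (if (strand == "+") 1 else -1), ]
    if (nrow(ss) == 0) next
    if (strand == "-") {
      # work in transcript order: ascending query, descending genome
      ss <- ss[order(ss$q_start, -ss$g_start), ]
    } else {
      ss <- ss[order(ss$q_start, ss$g_start), ]
    }
    n <- nrow(ss)
    val <- ss$score; prev <- rep(0L, n)
    trims <- vector("list", n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        g <- splice_gap_score(ss, j, i, strand, genomic_window,
                              splice_bonus, noncanon_penalty)
        if (is.null(g)) next
        cand <- val[j] + ss$score[i] + g$score
        if (cand > val[i]) { val[i] <- cand; prev[i] <- j; trims[[i]] <- g }
      }
    }
    i <- which.max(val)
    if (val[i] > best$score) {
      top <- max(val)
      chain <- integer(0)
      while (i > 0L) { chain <- c(i, chain); i <- prev[i] }
      for (k in seq_along(chain)[-1]) {
        tr <- trims[[chain[k]]]
        ss <- apply_trims(ss, chain[k - 1L], chain[k], strand, tr$x, tr$r)
      }
      best <- list(score = top, chain = ss[chain, ], strand = strand)
    }
  }
  best
}

#' @export
print.spliced_map <- function(x, ...) {
  cat("spliced_map: score", x$score, "strand", x$strand, "with",
      nrow(x$segments), "segment(s)\n")
  if (nrow(x$segments)) print(as.data.frame(x$segments))
  invisible(x)
}
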