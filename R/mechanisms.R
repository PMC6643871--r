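# Origin-mechanism detectors over high-confidence species-specific orphans.
#
# Relaxed searches (threshold e_relaxed, default 10) are noise-gated: a hit
# is kept only when its raw score exceeds the search-space random
# expectation ln(K*m*n)/lambda by `noise_margin` (default 15). Without the
# gate, an E < 10 threshold admits the expected random maximum of every
# search and the detectors would fire on noise. Confidence tiers come from
# the structural evidence (missing neighbor, closed frame, single alignable
# species, unknown transcription), not from the E-value alone.

noise_floor <- function(m, n, lambda = 0.267, K = 0.041) log(K * m * n) / lambda

# relaxed translated search with the noise gate
relaxed_px_hits <- function(prot, subjects, e_relaxed = 10,
                            noise_margin = 15, db_kind = "genome",
                            word_size = 3L) {
  h <- search_homology(prot, subjects,
                       search_params("px", e_max = e_relaxed,
                                     word_size = word_size),
                       db_kind = db_kind)
  if (nrow(h) == 0) return(h)
  n_db <- sum(nchar(as.character(subjects)))
  m <- nchar(prot[[1]])
  h[h$score >= noise_floor(m, n_db) + noise_margin, ]
}

mechanism_call <- function(gene_id, mechanism, confidence = "supported",
                           modifiers = character(0), evidence = list()) {
  new_tbl(gene_id = gene_id, mechanism = mechanism,
          confidence = confidence,
          modifiers = paste(modifiers, collapse = ","),
          evidence = list(evidence))
}

no_call <- function() NULL

# CDS codon ranges per exon (transcription order): exon, from_codon, to_codon
exon_codon_ranges <- function(gene) {
  cd <- cds_in_tx_order(gene$cds[[1]], gene$strand)
  widths <- cd$end - cd$start
  ends <- cumsum(widths); starts <- ends - widths
  ex <- gene$exons[[1]][order(gene$exons[[1]]$start), , drop = FALSE]
  if (gene$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  exon_of <- vapply(seq_len(nrow(cd)), function(j)
    which(cd$start[j] >= ex$start & cd$end[j] <= ex$end)[1], integer(1))
  new_tbl(exon = exon_of,
          from_codon = starts %/% 3L + 1L,
          to_codon = (ends + 2L) %/% 3L,
          nt_from = starts, nt_to = ends)
}

#' Detect chimeric origin
#'
#' Fires when at least two coding exons align (per-exon relaxed protein
#' search against the conserved/taxon-restricted proteins of each species,
#' noise-gated) to distinct source genes, no single source gene hits more
#' than one exon, and the two-source explanation outscores the best single
#' whole-protein hit by a clear margin — short duplicated exon fragments
#' whose individual alignments are too weak for the genome-wide cascade.
#'
#' @param gene one-row focal gene-model tibble (>= 2 coding exons).
#' @param ds an `orphan_dataset`.
#' @param classification output of [classify_genes()].
#' @param e_relaxed,noise_margin relaxed-search gate.
#' @return A mechanism-call tibble row, or `NULL`.
#' @export
detect_chimera <- function(gene, ds, classification, e_relaxed = 10,
                           noise_margin = 15) {
  ecr <- exon_codon_ranges(gene)
  if (length(unique(ecr$exon)) < 2) return(no_call())
  prot <- gene_protein(gene[1, ], ds$genomes[[gene$species]])
  sources_ok <- classification$gene_id[classification$class %in%
                                         c("Conserved", "TROG")]
  exon_hits <- list()
  for (e in unique(ecr$exon)) {
    rng <- ecr[ecr$exon == e, ]
    pep <- substr(prot, min(rng$from_codon),
                  min(nchar(prot), max(rng$to_codon)))
    if (nchar(pep) < 8) next
    hits <- list()
    for (sp in ds$species) {
      db <- ds$proteins[[sp]]
      db <- db[intersect(names(db), sources_ok)]
      db <- db[names(db) != gene$gene_id]
      if (length(db) == 0) next
      h <- search_homology(stats::setNames(pep, "exon"), db,
                           search_params("pp", e_max = e_relaxed))
      if (nrow(h) == 0) next
      gate <- noise_floor(nchar(pep), sum(Biostrings::width(db))) +
        noise_margin
      h <- h[h$score >= gate, ]
      if (nrow(h) > 0) {
        h$species <- sp
        hits[[sp]] <- h
      }
    }
    if (length(hits) > 0) {
      hh <- dplyr::bind_rows(hits)
      hh$exon <- e
      exon_hits[[as.character(e)]] <- hh
    }
  }
  if (length(exon_hits) < 2) return(no_call())
  all_hits <- dplyr::bind_rows(exon_hits)
  # a single subject hitting >= 2 exons means plain divergence
  multi <- tapply(all_hits$exon, all_hits$subject_id,
                  function(x) length(unique(x)))
  if (any(multi >= 2)) return(no_call())
  best <- all_hits |>
    dplyr::group_by(.data$exon) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  # the two-source explanation must clearly beat any single source: the
  # summed distinct per-exon scores must exceed the best gated
  # whole-protein hit by a margin (a local alignment can pick up a weak
  # shoulder beyond its true exon, so the raw query span is not trusted)
  best_single <- 0
  for (sp in ds$species) {
    db <- ds$proteins[[sp]]
    db <- db[names(db) != gene$gene_id]
    if (length(db) == 0) next
    h <- search_homology(stats::setNames(prot, "full"), db,
                         search_params("pp", e_max = e_relaxed))
    h <- h[h$score >= noise_floor(nchar(prot),
                                  sum(Biostrings::width(db))) + noise_margin, ]
    if (nrow(h) > 0) best_single <- max(best_single, h$score[1])
  }
  if (sum(best$score) < best_single + 10) return(no_call())
  mechanism_call(gene$gene_id, "chimera",
                 evidence = list(sources = best[, c("exon", "subject_id",
                                                    "species",
                                                    "pct_identity",
                                                    "e_value", "score")]))
}

#' Per-column reading-frame assignment of a protein against a coding region
#'
#' Aligns the protein to the three same-strand frames of the orthologous
#' coding sequence with a small-state dynamic program (states = codon start
#' offsets; moves of +3 keep the frame, +2/+4 switch it at a penalty) and
#' reports the best frame per protein position, the switch points, and the
#' indel length implicated at each switch.
#'
#' @param protein protein string (>= 10 residues usable).
#' @param orth_coding_nt nucleotide sequence of the orthologous coding
#'   region (same strand as the protein's source).
#' @param shift_penalty score penalty per frame switch.
#' @return List: `status` (`"ok"`/`"insufficient"`), `frames` (0/1/2 per
#'   protein position, relative to the first aligned codon), `switches`
#'   (tibble `position` in codon units, `indel` in nt), `score`.
#' @export
detect_frame_shift <- function(protein, orth_coding_nt, shift_penalty = 8) {
  m <- nchar(protein)
  n <- nchar(orth_coding_nt)
  if (m < 10 || n < 30)
    return(list(status = "insufficient", frames = integer(0),
                switches = new_tbl(position = integer(),
                                   indel = integer()), score = NA_real_))
  res <- strsplit(translate_six_frames(orth_coding_nt)$protein[1:3], "")
  # residue at codon start p (0-based nt): frame p %% 3, index p %/% 3 + 1
  n_p <- n - 2L
  sub_res <- vapply(seq_len(n_p) - 1L, function(p) {
    r <- res[[p %% 3L + 1L]]
    i <- p %/% 3L + 1L
    if (i <= length(r)) r[i] else "X"
  }, character(1))
  B <- blosum62()
  pch <- strsplit(protein, "")[[1]]
  emis <- function(i) {
    r <- sub_res
    r[!r %in% rownames(B)] <- "X"
    a <- if (pch[i] %in% rownames(B)) pch[i] else "X"
    B[a, r]
  }
  NEG <- -1e9
  shift_v <- function(v, k) if (k == 0) v else c(rep(NEG, k), utils::head(v, -k))
  dp_prev <- emis(1L)
  choice <- matrix(0L, m, n_p)
  for (i in seq_len(m)[-1]) {
    cands <- rbind(shift_v(dp_prev, 3L),
                   shift_v(dp_prev, 2L) - shift_penalty,
                   shift_v(dp_prev, 4L) - shift_penalty)
    pick <- max.col(t(cands), ties.method = "first")
    dp_prev <- cands[cbind(pick, seq_len(n_p))] + emis(i)
    choice[i, ] <- pick
  }
  end <- which.max(dp_prev)
  score <- dp_prev[end]
  if (score < 10 * 2)
    return(list(status = "insufficient", frames = integer(0),
                switches = new_tbl(position = integer(),
                                   indel = integer()), score = score))
  pos <- integer(m)
  pos[m] <- end - 1L
  for (i in m:2) {
    step <- c(3L, 2L, 4L)[choice[i, pos[i] + 1L]]
    pos[i - 1L] <- pos[i] - step
  }
  frames <- (pos - pos[1]) %% 3L
  d <- diff(pos) - 3L
  sw <- which(d != 0L)
  list(status = "ok", frames = frames,
       switches = new_tbl(position = sw + 1L, indel = as.integer(-d[sw])),
       score = score)
}

#' Detect origin by gene splitting
#'
#' Fires when the candidate aligns (nucleotide level) to a prefix or suffix
#' of a conserved/taxon-restricted gene in the orthologous sister region
#' while an adjacent focal gene covers the complementary part of that
#' protein. Exons with no homology anywhere in the region gain a
#' `de-novo-exon` modifier; a frame disruption on the shared exon gains a
#' `frame-shift` modifier. Without the complementary neighbor the call is
#' weak.
#'
#' @param gene one-row focal gene-model tibble.
#' @param ds an `orphan_dataset`.
#' @param region one-row region tibble (`found`, `species`, `contig`,
#'   `start`, `end`) from [orthologous_region()].
#' @param neighbors gene-model tibble of adjacent focal genes.
#' @param e_nucl nucleotide threshold for the region alignment.
#' @param cover_frac coverage of the sister gene above which the candidate
#'   is a full-length ortholog (no split).
#' @return A mechanism-call tibble row, or `NULL`.
#' @export
detect_gene_split <- function(gene, ds, region, neighbors, e_nucl = 1e-3,
                              cover_frac = 0.8) {
  if (is.null(region) || !isTRUE(region$found[1])) return(no_call())
  sp <- region$species[1]
  reg_seq <- as.character(Biostrings::subseq(
    ds$genomes[[sp]][[region$contig[1]]], region$start[1] + 1L,
    region$end[1]))
  ecr <- exon_codon_ranges(gene)
  cds <- gene_cds_seq(gene[1, ], ds$genomes[[gene$species]])
  exon_pieces <- lapply(unique(ecr$exon), function(e) {
    rng <- ecr[ecr$exon == e, ]
    substr(cds, min(rng$nt_from) + 1L, max(rng$nt_to))
  })
  names(exon_pieces) <- paste0("exon", unique(ecr$exon))
  hits <- search_homology(unlist(exon_pieces), c(region = reg_seq),
                          search_params("nn", e_max = e_nucl),
                          db_kind = "region")
  if (nrow(hits) == 0) return(no_call())
  # sister gene overlapped by the hits
  abs_hits <- hits
  abs_hits$s_start <- abs_hits$s_start + region$start[1]
  abs_hits$s_end <- abs_hits$s_end + region$start[1]
  sis <- ds$genes[ds$genes$species == sp, ]
  overlapped <- vapply(seq_len(nrow(sis)), function(i) {
    cd <- sis$cds[[i]]
    any(vapply(seq_len(nrow(cd)), function(j)
      any(interval_overlap(abs_hits$s_start, abs_hits$s_end,
                           cd$start[j], cd$end[j]) > 0), logical(1)))
  }, logical(1))
  if (!any(overlapped)) return(no_call())
  sis_gene <- sis[which(overlapped)[1], ]
  sis_prot <- gene_protein(sis_gene, ds$genomes[[sp]])
  # which part of the sister protein does the candidate cover?
  sis_cds <- gene_cds_seq(sis_gene, ds$genomes[[sp]])
  hp <- search_homology(c(cand = cds), c(sis = sis_cds),
                        search_params("nn", e_max = e_nucl))
  if (nrow(hp) == 0) return(no_call())
  cov <- range(c(hp$s_start, hp$s_end))
  frac <- (cov[2] - cov[1]) / nchar(sis_cds)
  if (frac >= cover_frac) return(no_call())  # full-length ortholog
  is_prefix <- cov[1] <= 0.2 * nchar(sis_cds)
  is_suffix <- cov[2] >= 0.8 * nchar(sis_cds)
  if (!is_prefix && !is_suffix) return(no_call())
  # complementary coverage by an adjacent focal gene
  complementary <- FALSE; nb_id <- NA_character_
  for (i in seq_len(nrow(neighbors))) {
    nb_prot <- gene_protein(neighbors[i, ], ds$genomes[[gene$species]])
    hn <- search_homology(c(nb = nb_prot), c(sis = sis_prot),
                          search_params("pp", e_max = 1e-3))
    if (nrow(hn) == 0) next
    nb_cov <- c(min(hn$s_start), max(hn$s_end))
    cand_cov_aa <- cov / 3
    overlap <- interval_overlap(nb_cov[1], nb_cov[2], cand_cov_aa[1],
                                cand_cov_aa[2])
    if ((nb_cov[2] - nb_cov[1]) > 0.25 * nchar(sis_prot) &&
        overlap < 0.5 * (nb_cov[2] - nb_cov[1])) {
      complementary <- TRUE; nb_id <- neighbors$gene_id[i]
      break
    }
  }
  # modifiers
  modifiers <- character(0)
  hit_exons <- unique(hits$query_id)
  de_novo_exons <- setdiff(names(exon_pieces), hit_exons)
  if (length(de_novo_exons) > 0)
    modifiers <- c(modifiers, "de-novo-exon")
  shared_exon <- hit_exons[1]
  fs <- detect_frame_shift(
    translate_nt(exon_pieces[[shared_exon]]),
    substr(sis_cds, cov[1] + 1L, cov[2]))
  if (fs$status == "ok" && length(unique(fs$frames)) >= 2)
    modifiers <- c(modifiers, "frame-shift")
  mechanism_call(gene$gene_id, "gene-split",
                 confidence = if (complementary) "supported" else "weak",
                 modifiers = modifiers,
                 evidence = list(source = sis_gene$gene_id, species = sp,
                                 neighbor = nb_id,
                                 candidate_part = if (is_prefix) "prefix"
                                 else "suffix",
                                 de_novo_exons = de_novo_exons,
                                 frame_shift = fs))
}

#' Detect strand-switch origin
#'
#' Relaxed, noise-gated translated search of the candidate protein against
#' sister genomes; fires when the best hit overlaps an annotated CDS exon
#' on the strand opposite to that gene's coding strand (a completely new
#' ORF read antisense from an existing exon). Same-strand hits never fire.
#'
#' @param gene one-row focal gene-model tibble.
#' @param ds an `orphan_dataset`.
#' @param e_relaxed,noise_margin relaxed-search gate.
#' @param e_strong below this E-value the call is supported, else weak.
#' @return A mechanism-call tibble row, or `NULL`.
#' @export
detect_strand_switch <- function(gene, ds, e_relaxed = 10,
                                 noise_margin = 15, e_strong = 1e-3,
                                 species = NULL) {
  prot <- stats::setNames(
    gene_protein(gene[1, ], ds$genomes[[gene$species]]), gene$gene_id)
  species <- species %||% setdiff(ds$species, gene$species)
  for (sp in species) {
    h <- relaxed_px_hits(prot, as.character(ds$genomes[[sp]]),
                         e_relaxed = e_relaxed,
                         noise_margin = noise_margin)
    if (nrow(h) == 0) next
    sis <- ds$genes[ds$genes$species == sp, ]
    for (k in seq_len(nrow(h))) {
      hit_strand <- if (h$s_frame[k] > 0) "+" else "-"
      for (i in seq_len(nrow(sis))) {
        if (sis$contig[i] != h$subject_id[k]) next
        cd <- sis$cds[[i]]
        ov <- any(interval_overlap(rep(h$s_start[k], nrow(cd)),
                                   rep(h$s_end[k], nrow(cd)),
                                   cd$start, cd$end) > 0)
        if (!ov) next
        if (sis$strand[i] == hit_strand) next  # same strand: not this call
        return(mechanism_call(
          gene$gene_id, "strand-switch",
          confidence = if (h$e_value[k] <= e_strong) "supported" else
            "weak",
          evidence = list(species = sp, subject_gene = sis$gene_id[i],
                          frame = h$s_frame[k], e_value = h$e_value[k],
                          score = h$score[k],
                          interval = c(h$s_start[k], h$s_end[k]))))
      }
    }
  }
  no_call()
}

#' Detect overprinting (alternative same-strand reading frame)
#'
#' Fires when the candidate has a within-species paralog at the transcript
#' level (plus-strand nucleotide hit, E <= `e_paralog`) whose annotated ORF
#' runs in a different same-strand frame, and the candidate's frame is open
#' in both copies. A stop closing the candidate frame in the paralog
#' downgrades the call to weak; a same-frame paralog (an ordinary
#' duplicate) never fires.
#'
#' @param gene one-row focal gene-model tibble.
#' @param ds an `orphan_dataset`.
#' @param e_paralog inclusive nucleotide threshold.
#' @return A mechanism-call tibble row, or `NULL`.
#' @export
detect_overprint <- function(gene, ds, e_paralog = 1e-3) {
  sp <- gene$species
  tx_set <- ds$transcripts[[sp]]
  tx_set <- tx_set[names(tx_set) != gene$gene_id]
  if (length(tx_set) == 0) return(no_call())
  cand_tx <- gene_transcript_seq(gene[1, ], ds$genomes[[sp]])
  h <- search_homology(stats::setNames(cand_tx, gene$gene_id), tx_set,
                       search_params("nn", e_max = e_paralog),
                       db_kind = "annotated-transcripts")
  h <- h[h$s_strand == "+", ]
  if (nrow(h) == 0) return(no_call())
  h <- h[order(h$e_value), ]
  par_id <- h$subject_id[1]
  par_gene <- ds$genes[ds$genes$gene_id == par_id, ]
  par_tx <- as.character(tx_set[[par_id]])
  # CDS offsets within each transcript
  tx_cds_offset <- function(g, genome) {
    ex <- g$exons[[1]]; cd <- g$cds[[1]]
    tx_len <- sum(ex$end - ex$start)
    ex <- ex[order(ex$start), , drop = FALSE]
    cum <- cumsum(ex$end - ex$start)
    off <- c(0, cum[-length(cum)])
    cds_lo <- min(cd$start); cds_hi <- max(cd$end)
    j <- which(cds_lo >= ex$start & cds_lo <= ex$end)[1]
    plus_off <- off[j] + (cds_lo - ex$start[j])
    if (g$strand == "+") plus_off else {
      jj <- which(cds_hi >= ex$start & cds_hi <= ex$end)[1]
      tx_len - (off[jj] + (cds_hi - ex$start[jj]))
    }
  }
  c_off <- tx_cds_offset(gene[1, ], ds$genomes[[sp]])
  p_off <- tx_cds_offset(par_gene[1, ], ds$genomes[[sp]])
  mapped <- c_off - h$q_start[1] + h$s_start[1]  # candidate CDS start in
                                                # paralog transcript coords
  frame_delta <- as.integer((mapped - p_off) %% 3L)
  if (frame_delta == 0L) return(no_call())
  # openness of each frame in each copy, over the aligned CDS stretch
  cand_cds_len <- sum(gene$cds[[1]]$end - gene$cds[[1]]$start)
  open_in <- function(tx, start0, len) {
    if (start0 < 0) return(NA)
    s <- substr(tx, start0 + 1L, min(nchar(tx), start0 + len))
    p <- translate_nt(s)
    !grepl("*", substr(p, 1L, nchar(p) - 1L), fixed = TRUE)
  }
  span <- min(cand_cds_len,
              (h$s_end[1] - mapped) %/% 3L * 3L)
  openness <- matrix(c(
    open_in(cand_tx, c_off, cand_cds_len),          # cand frame in cand
    open_in(par_tx, mapped, span),                  # cand frame in paralog
    open_in(cand_tx, c_off + ((p_off - mapped) %% 3L), span),
    open_in(par_tx, p_off,
            sum(par_gene$cds[[1]]$end - par_gene$cds[[1]]$start))),
    nrow = 2, dimnames = list(c("candidate-frame", "paralog-frame"),
                              c("in-candidate", "in-paralog")))
  conf <- if (isTRUE(openness["candidate-frame", "in-paralog"]))
    "supported" else "weak"
  mechanism_call(gene$gene_id, "overprint", confidence = conf,
                 evidence = list(paralog = par_id,
                                 frame_pair = c(0L, frame_delta),
                                 openness = openness,
                                 e_value = h$e_value[1],
                                 pct_identity = h$pct_identity[1]))
}

#' Rescue homologs missed by the heuristic genome-wide search
#'
#' Runs a full (unseeded) translated Smith--Waterman over the syntenic
#' interval only, with low-complexity sequence retained, at the relaxed
#' threshold. Fires when a noise-gated hit covering at least half of the
#' candidate protein exists in the interval while no such hit exists
#' genome-wide — the homolog was findable, the genome-wide search space
#' made it insignificant. Callers reclassify the gene as TROG.
#'
#' @param gene one-row focal gene-model tibble.
#' @param ds an `orphan_dataset`.
#' @param region syntenic interval (one-row region tibble).
#' @param e_relaxed,noise_margin relaxed-search gate.
#' @param min_cover minimum fraction of the candidate protein the
#'   in-interval hit must cover.
#' @return A mechanism-call tibble row, or `NULL`.
#' @export
rescue_heuristic_failure <- function(gene, ds, region, e_relaxed = 10,
                                     noise_margin = 15, min_cover = 0.5,
                                     species = NULL) {
  if (is.null(region) || !isTRUE(region$found[1])) return(no_call())
  prot <- stats::setNames(
    gene_protein(gene[1, ], ds$genomes[[gene$species]]), gene$gene_id)
  species <- species %||% setdiff(ds$species, gene$species)
  # discoverable genome-wide? then the heuristic did not fail
  for (sp in species) {
    hg <- relaxed_px_hits(prot, as.character(ds$genomes[[sp]]),
                          e_relaxed = e_relaxed,
                          noise_margin = noise_margin)
    if (any((hg$q_end - hg$q_start) >= min_cover * nchar(prot[[1]])))
      return(no_call())
  }
  sp <- region$species[1]
  reg_seq <- as.character(Biostrings::subseq(
    ds$genomes[[sp]][[region$contig[1]]], region$start[1] + 1L,
    region$end[1]))
  # full (unseeded) translated DP over the interval, repeats retained; the
  # smaller search space makes the same alignment significant
  h <- relaxed_px_hits(prot, stats::setNames(reg_seq, "interval"),
                       e_relaxed = e_relaxed, noise_margin = noise_margin,
                       db_kind = "syntenic-interval", word_size = 0L)
  h <- h[(h$q_end - h$q_start) >= min_cover * nchar(prot[[1]]), ]
  if (nrow(h) == 0) return(no_call())
  mechanism_call(gene$gene_id, "heuristic-failure",
                 evidence = list(species = sp,
                                 interval = c(region$start[1],
                                              region$end[1]),
                                 score = h$score[1], e_value = h$e_value[1],
                                 coverage = (h$q_end[1] - h$q_start[1]) /
                                   nchar(prot[[1]]),
                                 reclassify = "TROG"))
}

#' Detect de novo origin from ancestrally non-coding sequence
#'
#' For each sister species with an orthologous region, the candidate's
#' reading frame is extracted by per-exon nucleotide alignment and
#' translated; each species is scored intact (open ORF), disrupted (stop
#' codons, positions reported in 1-based codon units), or unalignable.
#' Fires when at least one species is disrupted or unalignable while the
#' region aligns at the nucleotide level in at least one species, and the
#' alignable regions show no transcription evidence. The birth node is the
#' most recent common ancestor of the intact-ORF species (0 when none); the
#' intronic/intergenic subtype comes from the focal annotation context.
#' Only one alignable sister, or unknown transcription evidence, caps the
#' call at weak confidence.
#'
#' @param gene one-row focal gene-model tibble.
#' @param ds an `orphan_dataset`.
#' @param regions tibble of per-species orthologous regions (`species`,
#'   `contig`, `start`, `end`).
#' @param e_nucl nucleotide alignment threshold.
#' @return A mechanism-call tibble row, or `NULL` (zero extractable regions
#'   gives `NULL`; the caller reports `unresolved`).
#' @export
detect_de_novo <- function(gene, ds, regions, e_nucl = 1e-3) {
  if (is.null(regions) || nrow(regions) == 0) return(no_call())
  cds <- gene_cds_seq(gene[1, ], ds$genomes[[gene$species]])
  ecr <- exon_codon_ranges(gene)
  exons <- unique(ecr$exon)
  li <- ladder_index(ds$tree)
  idx <- stats::setNames(li$ladder_index, li$species)

  status <- list()
  for (r in seq_len(nrow(regions))) {
    sp <- regions$species[r]
    reg_seq <- as.character(Biostrings::subseq(
      ds$genomes[[sp]][[regions$contig[r]]], regions$start[r] + 1L,
      regions$end[r]))
    codons_out <- rep(NA_character_, nchar(cds) %/% 3L)
    aligned <- FALSE
    for (e in exons) {
      rng <- ecr[ecr$exon == e, ]
      piece <- substr(cds, min(rng$nt_from) + 1L, max(rng$nt_to))
      h <- search_homology(c(piece = piece), c(region = reg_seq),
                           search_params("nn", e_max = e_nucl))
      if (nrow(h) == 0) next
      aligned <- TRUE
      h <- h[1, ]
      sub <- substr(reg_seq, h$s_start + 1L, h$s_end)
      if (h$s_strand == "-") sub <- revcomp(sub)
      # map subject codons onto candidate codon positions (block mapping)
      q0 <- h$q_start
      piece_cod0 <- min(rng$nt_from) %/% 3L  # candidate codon offset
      # align codon boundaries: skip to the first full codon of the piece
      lead <- (3L - (min(rng$nt_from) + q0) %% 3L) %% 3L
      sub2 <- substr(sub, 1L + lead, nchar(sub))
      start_codon <- (min(rng$nt_from) + q0 + lead) %/% 3L + 1L
      cods <- codons_of(sub2)
      take <- seq_along(cods)
      pos <- start_codon + take - 1L
      ok <- pos <= length(codons_out)
      codons_out[pos[ok]] <- cods[take[ok]]
    }
    if (!aligned) {
      status[[sp]] <- list(species = sp, status = "unalignable",
                           stops = integer(0), codons = NULL)
      next
    }
    known <- which(!is.na(codons_out))
    stops <- known[codons_out[known] %in% STOP_CODONS]
    # the candidate's own terminal stop is not a disruption
    stops <- setdiff(stops, length(codons_out))
    status[[sp]] <- list(species = sp,
                         status = if (length(stops) > 0) "disrupted" else
                           "intact",
                         stops = as.integer(stops), codons = codons_out)
  }
  if (length(status) == 0) return(no_call())
  st <- vapply(status, `[[`, "", "status")
  alignable <- names(st)[st != "unalignable"]
  if (length(alignable) == 0) return(no_call())
  if (!any(st %in% c("disrupted", "unalignable")) &&
      length(st) >= length(regions$species)) {
    return(no_call())  # all intact: no enabling mutation visible
  }
  if (!any(st == "disrupted") && !any(st == "unalignable"))
    return(no_call())
  # transcription evidence over alignable regions
  transcribed <- FALSE; unknown_evidence <- FALSE
  for (sp in alignable) {
    db <- ds$transcriptome[[sp]]
    if (is.null(db)) { unknown_evidence <- TRUE; next }
    if (length(db) == 0) next
    r <- regions[regions$species == sp, ][1, ]
    reg_seq <- as.character(Biostrings::subseq(
      ds$genomes[[sp]][[r$contig]], r$start + 1L, r$end))
    h <- search_homology(c(region = reg_seq), db,
                         search_params("nn", e_max = e_nucl))
    if (nrow(h) > 0) transcribed <- TRUE
  }
  if (transcribed) return(no_call())
  intact <- names(st)[st == "intact"]
  birth <- if (length(intact) == 0) 0L else max(idx[intact])
  # intronic when the candidate sits inside another focal gene's intron
  foc <- ds$genes[ds$genes$species == gene$species &
                    ds$genes$gene_id != gene$gene_id, ]
  span <- c(min(gene$exons[[1]]$start), max(gene$exons[[1]]$end))
  subtype <- "intergenic"
  for (i in seq_len(nrow(foc))) {
    if (foc$contig[i] != gene$contig) next
    ex <- foc$exons[[i]][order(foc$exons[[i]]$start), , drop = FALSE]
    if (nrow(ex) < 2) next
    introns <- cbind(ex$end[-nrow(ex)], ex$start[-1])
    if (any(span[1] >= introns[, 1] & span[2] <= introns[, 2])) {
      subtype <- "intronic"; break
    }
  }
  conf <- if (length(alignable) <= 1 || unknown_evidence) "weak" else
    "supported"
  mechanism_call(gene$gene_id, "de-novo", confidence = conf,
                 evidence = list(subtype = subtype, birth_node = birth,
                                 per_species = status))
}

#' Run all detectors over the high-confidence candidate set
#'
#' Detectors run in a fixed priority order — artifact screen (a re-run
#' structure validation), heuristic-failure rescue, overprinting, chimera,
#' gene split, strand switch, frame shift, de novo — and the first
#' supported call wins, with modifiers preserved; genes matching no
#' detector are `unresolved`. Artifacts and search failures are excluded
#' before any evolutionary claim, and divergence-based calls (which retain
#' ancestral frame or strand evidence) outrank de novo.
#'
#' Orthologous regions come from synteny anchors (or the host gene's intron
#' for candidates inside an intron of a conserved gene), computed against
#' the `n_region_species` closest sister species.
#'
#' @param ds an `orphan_dataset`.
#' @param hc_ids high-confidence gene ids (from [high_confidence_set()]).
#' @param classification output of [classify_genes()].
#' @param statuses structure statuses (re-used for the artifact screen;
#'   recomputed when `NULL`).
#' @param n_region_species number of closest sisters searched for
#'   orthologous regions.
#' @param e_relaxed,noise_margin relaxed-search gate shared by detectors.
#' @return Tibble: `gene_id`, `mechanism`, `confidence`, `modifiers`,
#'   `evidence` (list-column); attribute `"reclassified"` lists genes whose
#'   final class becomes TROG after rescue.
#' @export
call_mechanisms <- function(ds, hc_ids, classification, statuses = NULL,
                            n_region_species = 4L, e_relaxed = 10,
                            noise_margin = 15) {
  focal_genes <- ds$genes[ds$genes$species == ds$focal, ]
  li <- ladder_index(ds$tree)
  sisters <- li$species[seq_len(min(n_region_species, nrow(li)))]
  spans <- gene_spans(ds$genes)

  # synteny blocks focal -> each close sister
  blocks <- list()
  for (sp in sisters) {
    qs <- ds$proteins[[ds$focal]]
    hits <- search_homology(qs, ds$proteins[[sp]],
                            search_params("pp", e_max = 1e-3))
    blocks[[sp]] <- find_synteny_blocks(hits, spans)
  }

  # orthologous region of a focal gene in species sp: host intron when the
  # candidate lies inside another gene's intron, else synteny flanks
  region_of <- function(gene, sp) {
    span <- c(min(gene$exons[[1]]$start), max(gene$exons[[1]]$end))
    host <- NULL; intron_index <- NA_integer_
    for (i in seq_len(nrow(focal_genes))) {
      if (focal_genes$gene_id[i] == gene$gene_id ||
          focal_genes$contig[i] != gene$contig) next
      ex <- focal_genes$exons[[i]][order(focal_genes$exons[[i]]$start), ,
                                   drop = FALSE]
      if (nrow(ex) < 2) next
      introns <- cbind(ex$end[-nrow(ex)], ex$start[-1])
      k <- which(span[1] >= introns[, 1] & span[2] <= introns[, 2])
      if (length(k) > 0) {
        host <- focal_genes[i, ]
        intron_index <- if (host$strand == "+") k[1] else
          nrow(introns) - k[1] + 1L
        break
      }
    }
    if (!is.null(host)) {
      # ortholog of the host via best-reciprocal anchors
      bl <- blocks[[sp]]
      if (nrow(bl) > 0) {
        for (b in seq_len(nrow(bl))) {
          an <- bl$anchors[[b]]
          hit <- an[an$gene_a == host$gene_id, ]
          if (nrow(hit) == 1) {
            orth <- ds$genes[ds$genes$gene_id == hit$gene_b, ]
            return(host_intron_region(host, orth[1, ], intron_index))
          }
        }
      }
    }
    bl <- blocks[[sp]]
    if (nrow(bl) == 0)
      return(new_tbl(found = FALSE, species = NA_character_,
                     contig = NA_character_, start = NA_real_,
                     end = NA_real_, orientation = NA_character_))
    best <- NULL
    for (b in seq_len(nrow(bl))) {
      r <- orthologous_region(list(contig = gene$contig, start = span[1],
                                   end = span[2]), bl[b, ], spans)
      if (isTRUE(r$found[1])) { best <- r; break }
    }
    best %||% new_tbl(found = FALSE, species = NA_character_,
                      contig = NA_character_, start = NA_real_,
                      end = NA_real_, orientation = NA_character_)
  }

  if (is.null(statuses)) {
    hc_rows <- focal_genes[match(hc_ids, focal_genes$gene_id), ]
    statuses <- validate_structures(hc_rows, ds$reads,
                                    stranded = isTRUE(ds$config$stranded))
  }

  out <- list(); reclassified <- character(0)
  for (gid in hc_ids) {
    gene <- focal_genes[focal_genes$gene_id == gid, ]
    assert_that(nrow(gene) == 1, paste0("unknown focal gene ", gid))

    # artifact screen: the structure must survive a re-validation
    stat <- statuses[statuses$gene_id == gid, ]
    if (nrow(stat) == 0 || stat$status[1] != "fully-confirmed") {
      out[[gid]] <- mechanism_call(gid, "artifact",
                                   evidence = list(status = if (nrow(stat))
                                     stat$status[1] else "missing"))
      next
    }

    regions <- dplyr::bind_rows(lapply(sisters, function(sp) {
      r <- region_of(gene, sp)
      if (isTRUE(r$found[1])) r else NULL
    }))

    # rescue and gene-split must see the anchor gene bodies too: a split
    # fragment maps onto the anchor's own coding sequence
    pad_region <- function(r, pad = 1200) {
      if (is.null(r)) return(NULL)
      r$start <- max(0, r$start - pad)
      r$end <- min(length(ds$genomes[[r$species]][[r$contig]]),
                   r$end + pad)
      r
    }
    syn_region <- if (nrow(regions) > 0) pad_region(regions[1, ]) else NULL
    call <- rescue_heuristic_failure(gene, ds, syn_region,
                                     e_relaxed = e_relaxed,
                                     noise_margin = noise_margin,
                                     species = sisters)
    if (!is.null(call)) {
      reclassified <- c(reclassified, gid)
      out[[gid]] <- call; next
    }
    call <- detect_overprint(gene, ds)
    if (!is.null(call)) { out[[gid]] <- call; next }
    call <- detect_chimera(gene, ds, classification,
                           e_relaxed = e_relaxed,
                           noise_margin = noise_margin)
    if (!is.null(call)) { out[[gid]] <- call; next }
    neighbors <- adjacent_genes(gene, focal_genes)
    call <- detect_gene_split(gene, ds, syn_region, neighbors)
    if (!is.null(call)) { out[[gid]] <- call; next }
    call <- detect_strand_switch(gene, ds, e_relaxed = e_relaxed,
                                 noise_margin = noise_margin,
                                 species = sisters)
    if (!is.null(call)) { out[[gid]] <- call; next }
    call <- frame_shift_primary(gene, ds, e_relaxed = e_relaxed,
                                noise_margin = noise_margin,
                                species = sisters)
    if (!is.null(call)) { out[[gid]] <- call; next }
    call <- detect_de_novo(gene, ds, regions)
    if (!is.null(call)) { out[[gid]] <- call; next }
    out[[gid]] <- mechanism_call(gid, "unresolved", confidence = "weak")
  }
  res <- dplyr::bind_rows(out)
  attr(res, "reclassified") <- reclassified
  res
}

# the two flanking annotated genes on the focal genome
adjacent_genes <- function(gene, focal_genes) {
  sp <- gene_spans(focal_genes)
  sp <- sp[sp$contig == gene$contig & sp$gene_id != gene$gene_id, ]
  span <- c(min(gene$exons[[1]]$start), max(gene$exons[[1]]$end))
  left <- sp[sp$end <= span[1], ]
  right <- sp[sp$start >= span[2], ]
  ids <- c(if (nrow(left)) left$gene_id[which.max(left$end)],
           if (nrow(right)) right$gene_id[which.min(right$start)])
  focal_genes[focal_genes$gene_id %in% ids, ]
}

# frame-shift as a primary mechanism: a same-strand, noise-gated relaxed
# translated hit over an annotated sister CDS exon whose frame map runs
# through two or more reading frames
frame_shift_primary <- function(gene, ds, e_relaxed = 10,
                                noise_margin = 15, species = NULL) {
  prot <- stats::setNames(
    gene_protein(gene[1, ], ds$genomes[[gene$species]]), gene$gene_id)
  species <- species %||% setdiff(ds$species, gene$species)
  for (sp in species) {
    h <- relaxed_px_hits(prot, as.character(ds$genomes[[sp]]),
                         e_relaxed = e_relaxed,
                         noise_margin = noise_margin)
    if (nrow(h) == 0) next
    sis <- ds$genes[ds$genes$species == sp, ]
    for (k in seq_len(nrow(h))) {
      hit_strand <- if (h$s_frame[k] > 0) "+" else "-"
      for (i in seq_len(nrow(sis))) {
        if (sis$contig[i] != h$subject_id[k]) next
        if (sis$strand[i] != hit_strand) next
        cd <- sis$cds[[i]]
        ov <- any(interval_overlap(rep(h$s_start[k], nrow(cd)),
                                   rep(h$s_end[k], nrow(cd)),
                                   cd$start, cd$end) > 0)
        if (!ov) next
        orth_nt <- gene_cds_seq(sis[i, ], ds$genomes[[sp]])
        fs <- detect_frame_shift(prot[[1]], orth_nt)
        if (fs$status == "ok" && length(unique(fs$frames)) >= 2)
          return(mechanism_call(
            gene$gene_id, "frame-shift",
            evidence = list(species = sp, subject_gene = sis$gene_id[i],
                            frames = fs$frames, switches = fs$switches)))
      }
    }
  }
  no_call()
}
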