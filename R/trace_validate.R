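#' Trace residual homology of species-specific orphans
#'
#' For every SSOG and every non-focal species, three searches mirror the
#' three target databases: nucleotide transcript query vs annotated
#' transcripts, translated protein query vs the genome assembly, and
#' nucleotide query vs the transcriptome assembly. A species missing a
#' database kind yields an unknown (`NA`) cell, never a silent `FALSE`.
#'
#' Summary categories (union over species of the known cells):
#' `all-three` (hits in all three database kinds), `untraceable` (no hit
#' anywhere), `assembly-gap-candidate` (transcriptome hit but no genome and
#' no annotated-transcript hit anywhere), `partial` (every remaining mixed
#' pattern).
#'
#' @param ssog_ids character vector of focal SSOG gene ids.
#' @param ds an `orphan_dataset`.
#' @param e_transcripts,e_transcriptome inclusive nucleotide thresholds.
#' @param e_genome inclusive threshold of the translated genome search.
#' @return List with `cells` (gene x species x db-kind logical grid, long
#'   tibble) and `summary` (per-gene category tibble).
#' @export
trace_homology <- function(ssog_ids, ds, e_transcripts = 1e-3,
                           e_genome = 1e-5, e_transcriptome = 1e-3) {
  focal_genes <- ds$genes[ds$genes$species == ds$focal, ]
  rows <- focal_genes[match(ssog_ids, focal_genes$gene_id), ]
  assert_that(!anyNA(rows$gene_id), "unknown focal gene id in ssog_ids")
  tx <- stats::setNames(vapply(seq_len(nrow(rows)), function(i)
    gene_transcript_seq(rows[i, ], ds$genomes[[ds$focal]]), character(1)),
    rows$gene_id)
  prot <- stats::setNames(vapply(seq_len(nrow(rows)), function(i)
    gene_protein(rows[i, ], ds$genomes[[ds$focal]]), character(1)),
    rows$gene_id)

  cells <- list()
  for (sp in setdiff(ds$species, ds$focal)) {
    probe <- function(db, params, kind, queries) {
      if (is.null(db)) {
        return(stats::setNames(rep(NA, length(ssog_ids)), ssog_ids))
      }
      if (length(db) == 0) {
        return(stats::setNames(rep(FALSE, length(ssog_ids)), ssog_ids))
      }
      h <- search_homology(queries, db, params, db_kind = kind)
      stats::setNames(ssog_ids %in% h$query_id, ssog_ids)
    }
    hit_tx <- probe(ds$transcripts[[sp]],
                    search_params("nn", e_max = e_transcripts),
                    "annotated-transcripts", tx)
    hit_gen <- probe(as.character(ds$genomes[[sp]]),
                     search_params("px", e_max = e_genome), "genome", prot)
    hit_asm <- probe(ds$transcriptome[[sp]],
                     search_params("nn", e_max = e_transcriptome),
                     "transcriptome-assembly", tx)
    cells[[sp]] <- new_tbl(
      gene_id = rep(ssog_ids, 3L),
      species = sp,
      db_kind = rep(c("annotated-transcripts", "genome",
                      "transcriptome-assembly"), each = length(ssog_ids)),
      hit = c(hit_tx, hit_gen, hit_asm))
  }
  cells <- dplyr::bind_rows(cells)

  summary <- dplyr::bind_rows(lapply(ssog_ids, function(g) {
    cc <- cells[cells$gene_id == g, ]
    yes <- function(kind) any(cc$hit[cc$db_kind == kind], na.rm = TRUE)
    t_tx <- yes("annotated-transcripts")
    t_gen <- yes("genome")
    t_asm <- yes("transcriptome-assembly")
    cat <- if (t_tx && t_gen && t_asm) "all-three"
    else if (!t_tx && !t_gen && !t_asm) "untraceable"
    else if (t_asm && !t_gen && !t_tx) "assembly-gap-candidate"
    else "partial"
    new_tbl(gene_id = g, hit_transcripts = t_tx, hit_genome = t_gen,
            hit_transcriptome = t_asm, category = cat)
  }))
  list(cells = cells, summary = summary)
}

#' Validate a gene structure against spliced read alignments
#'
#' A coding exon is supported by a read when a read block covers at least
#' `min_exon_overlap` of the exon's CDS span, or when a spliced read has a
#' junction matching one of the exon's boundaries (junction reads count
#' toward both flanking exons). A junction is supported only by spliced
#' reads whose consecutive blocks match the annotated exon edges exactly.
#' Genes with a single exon are excluded from validation. Full confirmation
#' requires at least `min_reads` supporting reads for every coding exon and
#' every junction; with strand-specific reads, two or more supporting reads
#' on the wrong strand cap the status at partially-confirmed.
#'
#' @param gene one-row gene-model tibble.
#' @param reads read tibble from [read_sam()] (any superset; filtered to the
#'   gene's contig internally).
#' @param stranded whether the protocol is strand-specific.
#' @param min_reads read-support threshold (default 2).
#' @param min_exon_overlap fraction of an exon's CDS span a block must cover.
#' @return One-row tibble: `gene_id`, `n_exons`, `n_coding_exons`,
#'   `exon_support`, `junction_support` (list-columns of counts), `status`,
#'   `strand_consistent`.
#' @export
validate_structure <- function(gene, reads, stranded = TRUE, min_reads = 2L,
                               min_exon_overlap = 0.8) {
  ex <- gene$exons[[1]][order(gene$exons[[1]]$start), , drop = FALSE]
  cd <- gene$cds[[1]]
  n_exons <- nrow(ex)
  # CDS span per exon
  cds_span <- lapply(seq_len(n_exons), function(j) {
    if (nrow(cd) == 0) return(NULL)
    s <- pmax(ex$start[j], cd$start); e <- pmin(ex$end[j], cd$end)
    k <- which(e > s)
    if (length(k) == 0) NULL else c(min(s[k]), max(e[k]))
  })
  coding <- which(!vapply(cds_span, is.null, logical(1)))
  junctions <- if (n_exons > 1)
    cbind(ex$end[-n_exons], ex$start[-1]) else
      matrix(numeric(0), ncol = 2)

  r <- reads[reads$contig == gene$contig, ]
  exon_sup <- integer(n_exons)
  junc_sup <- integer(nrow(junctions))
  supporting_strands <- character(0)
  if (nrow(r) > 0) {
    for (i in seq_len(nrow(r))) {
      b <- r$blocks[[i]]
      matched_j <- integer(0)
      if (nrow(b) > 1) {
        inner <- cbind(b$end[-nrow(b)], b$start[-1])
        for (jj in seq_len(nrow(junctions))) {
          if (any(inner[, 1] == junctions[jj, 1] &
                  inner[, 2] == junctions[jj, 2]))
            matched_j <- c(matched_j, jj)
        }
      }
      supports <- logical(n_exons)
      for (j in seq_len(n_exons)) {
        sp <- cds_span[[j]]
        if (!is.null(sp)) {
          ov <- max(interval_overlap(b$start, b$end, sp[1], sp[2]))
          if (ov >= min_exon_overlap * (sp[2] - sp[1])) supports[j] <- TRUE
        }
        # junction reads support both flanking exons
        if (length(matched_j) > 0 &&
            any(matched_j == j | matched_j == j - 1L) &&
            any(interval_overlap(b$start, b$end, ex$start[j], ex$end[j]) > 0))
          supports[j] <- TRUE
      }
      if (length(matched_j) > 0) junc_sup[matched_j] <- junc_sup[matched_j] + 1L
      if (any(supports) || length(matched_j) > 0)
        supporting_strands <- c(supporting_strands, r$strand[i])
      exon_sup[supports] <- exon_sup[supports] + 1L
    }
  }

  strand_consistent <- if (!stranded) NA else
    sum(supporting_strands != gene$strand) < min_reads
  status <- if (n_exons < 2L) {
    "single-exon-excluded"
  } else if (length(coding) > 0 &&
             all(exon_sup[coding] >= min_reads) &&
             (nrow(junctions) == 0 || all(junc_sup >= min_reads)) &&
             !isFALSE(strand_consistent)) {
    "fully-confirmed"
  } else if (any(exon_sup[coding] >= min_reads) ||
             any(junc_sup >= min_reads)) {
    "partially-confirmed"
  } else {
    "unconfirmed"
  }
  new_tbl(gene_id = gene$gene_id, n_exons = n_exons,
          n_coding_exons = length(coding),
          exon_support = list(exon_sup),
          junction_support = list(as.integer(junc_sup)),
          status = status, strand_consistent = strand_consistent)
}

#' @rdname validate_structure
#' @param genes gene-model tibble (several genes).
#' @export
validate_structures <- function(genes, reads, stranded = TRUE,
                                min_reads = 2L, min_exon_overlap = 0.8) {
  dplyr::bind_rows(lapply(seq_len(nrow(genes)), function(i)
    validate_structure(genes[i, ], reads, stranded = stranded,
                       min_reads = min_reads,
                       min_exon_overlap = min_exon_overlap)))
}

#' High-confidence candidate set
#'
#' SSOGs that are traceable (not `untraceable`; untraceable loci cannot be
#' investigated further) and whose gene structure is fully confirmed by
#' spliced reads.
#'
#' @param ssog_ids focal SSOG gene ids.
#' @param traces result of [trace_homology()].
#' @param statuses result of [validate_structures()].
#' @return Sorted character vector of gene ids.
#' @export
high_confidence_set <- function(ssog_ids, traces, statuses) {
  traceable <- traces$summary$gene_id[traces$summary$category !=
                                        "untraceable"]
  confirmed <- statuses$gene_id[statuses$status == "fully-confirmed"]
  sort(intersect(ssog_ids, intersect(traceable, confirmed)))
}
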