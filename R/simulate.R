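#' Simulation configuration
#'
#' Defines the study conditions the synthetic dataset emulates: a ladder-like
#' phylogeny of small nematode-style genomes around one focal species, with
#' planted conserved genes, taxon-restricted orphans born at every internal
#' node, species-specific orphans, and one exemplar of each origin mechanism.
#' The defaults are the package's reference conditions (documented in the
#' methods vignette); a seed passed to [simulate_dataset()] fixes the whole
#' dataset.
#'
#' @param n_species number of ingroup species (`sp0` = focal, `sp1` sister,
#'   ...), forming a pure ladder.
#' @param branch_len branch length of every ladder branch
#'   (substitutions/site).
#' @param n_conserved number of conserved gene families (born at the root,
#'   homologs in the outgroup databases). Includes `n_step2` families absent
#'   from the outgroup protein set but present in the outgroup genome, and
#'   `n_step3` families found only in the curated (UniProt-like) database.
#' @param n_trog_per_stratum taxon-restricted families born at each internal
#'   node 1..n_species-1.
#' @param n_ssog_focal plain focal-only orphans (untraceable by design); two
#'   of them are used as structure-validation exemplars (one without reads,
#'   one with single-read junction support).
#' @param n_ssog_other focal-unrelated orphans planted per non-focal species.
#' @param kappa HKY transition/transversion rate ratio used by the mutation
#'   kernel.
#' @param base_freq equilibrium base frequencies (A, C, G, T).
#' @param indel_rate,indel_mean_len per-site indel probability (intergenic
#'   sequence only) and geometric mean indel length.
#' @param igs_len_range intergenic spacer length range (bp, drawn per slot).
#' @param utr_len UTR padding on each side of a coding region (bp); gives
#'   tiled reads full coverage of terminal CDS bases.
#' @param read_len,depth,stranded simulated read length, minimum per-base
#'   coverage over focal exons, and strand-specific protocol flag.
#' @param outgroup_extra extra divergence (subs/site) applied to outgroup
#'   copies of conserved families.
#' @param min_intron minimum intron length (bp).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 10,
                       branch_len = 0.03,
                       n_conserved = 65,
                       n_trog_per_stratum = 2,
                       n_ssog_focal = 5,
                       n_ssog_other = 2,
                       kappa = 2,
                       base_freq = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       indel_rate = 0.0015,
                       indel_mean_len = 3,
                       igs_len_range = c(180L, 300L),
                       utr_len = 60L,
                       read_len = 75L,
                       depth = 5L,
                       stranded = TRUE,
                       outgroup_extra = 0.12,
                       min_intron = 20L) {
  assert_that(n_species >= 5, "need at least 5 species for the plants")
  assert_that(branch_len > 0 && indel_rate >= 0 && depth > 0,
              "rates and depth must be positive")
  cfg <- list(n_species = n_species, branch_len = branch_len,
              n_conserved = n_conserved, n_step2 = 3L, n_step3 = 2L,
              n_trog_per_stratum = n_trog_per_stratum,
              n_ssog_focal = n_ssog_focal, n_ssog_other = n_ssog_other,
              kappa = kappa, base_freq = base_freq / sum(base_freq),
              indel_rate = indel_rate, indel_mean_len = indel_mean_len,
              igs_len_range = as.integer(igs_len_range),
              utr_len = as.integer(utr_len),
              read_len = as.integer(read_len), depth = as.integer(depth),
              stranded = stranded, outgroup_extra = outgroup_extra,
              min_intron = as.integer(min_intron))
  cfg$species <- paste0("sp", seq_len(n_species) - 1L)
  cfg$focal <- cfg$species[1]
  class(cfg) <- "sim_config"
  cfg
}

# --- random sequence primitives --------------------------------------------

rand_dna <- function(n, cfg) {
  paste(sample(BASES, n, replace = TRUE, prob = cfg$base_freq), collapse = "")
}

# Random open reading frame: ATG + (n_codons - 2) sense codons + stop.
# n_codons counts all codons including start and stop.
rand_orf <- function(n_codons, cfg) {
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

codons_of <- function(seq) {
  substring(seq, seq(1L, nchar(seq) - 2L, by = 3L),
            seq(3L, nchar(seq), by = 3L))
}

# Stops present in the frame starting at `offset` (0/1/2), codon indices.
frame_stops <- function(seq, offset = 0L) {
  n <- nchar(seq)
  starts <- seq(1L + offset, n - 2L, by = 3L)
  cods <- substring(seq, starts, starts + 2L)
  which(cods %in% STOP_CODONS)
}

# HKY-like single-base proposal: transition with prob kappa/(kappa+2).
propose_base <- function(old, cfg) {
  ti <- c(A = "G", G = "A", C = "T", T = "C")
  n <- length(old)
  use_ti <- stats::runif(n) < cfg$kappa / (cfg$kappa + 2)
  out <- character(n)
  out[use_ti] <- ti[old[use_ti]]
  tv <- !use_ti
  if (any(tv)) {
    out[tv] <- vapply(old[tv], function(b) {
      sample(setdiff(BASES, c(b, ti[[b]])), 1L)
    }, character(1))
  }
  out
}

# Neutral mutation of non-coding sequence (substitutions only).
mutate_nt <- function(seq, d, cfg) {
  n <- nchar(seq)
  hit <- which(stats::runif(n) < d)
  if (length(hit) == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[hit] <- propose_base(ch[hit], cfg)
  paste(ch, collapse = "")
}

# Intergenic mutation: substitutions plus geometric indels.
mutate_igs <- function(seq, d, cfg) {
  seq <- mutate_nt(seq, d, cfg)
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, cfg$indel_rate * d / cfg$branch_len)
  for (i in seq_len(k)) {
    len <- 1L + stats::rgeom(1L, 1 / cfg$indel_mean_len)
    pos <- sample.int(max(1L, nchar(seq) - len), 1L)
    if (stats::runif(1) < 0.5) {
      seq <- paste0(substr(seq, 1L, pos), rand_dna(len, cfg),
                    substr(seq, pos + 1L, nchar(seq)))
    } else if (nchar(seq) > len + 50L) {
      seq <- paste0(substr(seq, 1L, pos),
                    substr(seq, pos + len + 1L, nchar(seq)))
    }
  }
  seq
}

# Mutate a CDS while keeping the reading frame(s) open: the start codon and
# terminal stop are untouched and any substitution creating a stop codon in a
# protected frame (interior) is reverted.
mutate_cds <- function(seq, d, cfg, protect_frames = 0L) {
  n <- nchar(seq)
  hit <- which(stats::runif(n) < d)
  hit <- hit[hit > 3L & hit <= n - 3L]
  if (length(hit) == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  old <- ch
  ch[hit] <- propose_base(ch[hit], cfg)
  for (f in protect_frames) {
    n_cod <- (n - f) %/% 3L
    starts <- f + 3L * (seq_len(n_cod) - 1L) + 1L
    interior <- if (f == 0L) seq_len(n_cod - 1L)[-1] else
      which(starts > 3L & starts + 2L <= n - 3L)
    for (ci in interior) {
      s <- starts[ci]
      if (paste(ch[s:(s + 2L)], collapse = "") %in% STOP_CODONS)
        ch[s:(s + 2L)] <- old[s:(s + 2L)]
    }
  }
  paste(ch, collapse = "")
}

# --- gene templates and piece sets -----------------------------------------

# A template lists transcript-order pieces: kind utr/cds/intron, length,
# exon id (NA for introns). CDS lengths include the terminal stop codon.
std_template <- function(cfg, cds_lens = c(75L, 81L, 78L),
                         introns = c(47L, 53L)) {
  u <- cfg$utr_len
  list(kind = c("utr", "cds", "intron", "cds", "intron", "cds", "utr"),
       len = c(u, cds_lens[1], introns[1], cds_lens[2], introns[2],
               cds_lens[3], u),
       exon = c(1L, 1L, NA, 2L, NA, 3L, 3L))
}

trog_template <- function(cfg, cds_lens = c(78L, 75L), intron = 61L) {
  u <- cfg$utr_len
  list(kind = c("utr", "cds", "intron", "cds", "utr"),
       len = c(u, cds_lens[1], intron, cds_lens[2], u),
       exon = c(1L, 1L, NA, 2L, 2L))
}

# Root piece set for a template: one ORF split over the cds pieces.
root_pieces <- function(template, cfg, orf = NULL) {
  ic <- which(template$kind == "cds")
  total <- sum(template$len[ic])
  assert_that(total %% 3L == 0L, "template CDS length not a codon multiple")
  orf <- orf %||% rand_orf(total %/% 3L, cfg)
  pieces <- character(length(template$kind))
  off <- 0L
  for (i in seq_along(template$kind)) {
    if (template$kind[i] == "cds") {
      pieces[i] <- substr(orf, off + 1L, off + template$len[i])
      off <- off + template$len[i]
    } else {
      pieces[i] <- rand_dna(template$len[i], cfg)
      if (template$kind[i] == "intron")
        pieces[i] <- impose_splice_motifs(pieces[i])
    }
  }
  pieces
}

# canonical GT..AG intron boundaries
impose_splice_motifs <- function(s) {
  paste0("GT", substr(s, 3L, nchar(s) - 2L), "AG")
}

# Evolve a piece set by distance d; CDS pieces evolve jointly under frame
# protection, introns/UTRs neutrally.
evolve_pieces <- function(pieces, template, d, cfg, protect_frames = 0L) {
  ic <- which(template$kind == "cds")
  cds <- paste(pieces[ic], collapse = "")
  cds <- mutate_cds(cds, d, cfg, protect_frames)
  off <- 0L
  for (i in ic) {
    w <- nchar(pieces[i])
    pieces[i] <- substr(cds, off + 1L, off + w)
    off <- off + w
  }
  for (i in setdiff(seq_along(pieces), ic)) {
    pieces[i] <- mutate_nt(pieces[i], d, cfg)
    if (template$kind[i] == "intron")
      pieces[i] <- impose_splice_motifs(pieces[i])
  }
  pieces
}

# Evolve a root piece set along the ladder from its birth node down to the
# leaves sp0..sp<birth>. Returns a named list of per-species piece sets.
evolve_along_ladder <- function(root, birth, template, cfg,
                                protect_frames = 0L) {
  b <- cfg$branch_len
  anc <- vector("list", birth)
  anc[[birth]] <- root
  if (birth > 1)
    for (k in (birth - 1L):1L)
      anc[[k]] <- evolve_pieces(anc[[k + 1L]], template, b, cfg,
                                protect_frames)
  out <- list()
  out[[cfg$focal]] <- evolve_pieces(anc[[1L]], template, b, cfg,
                                    protect_frames)
  for (j in seq_len(birth))
    out[[cfg$species[j + 1L]]] <- evolve_pieces(anc[[j]], template, b, cfg,
                                                protect_frames)
  out
}

# --- region variants -------------------------------------------------------

# Turn transcript-order pieces into a genomic region (one gene): sequence on
# the + representation of the region plus region-relative exon/CDS intervals.
# cds_tx: transcript-space [start0, end0) of the (contiguous) CDS.
build_gene_region <- function(pieces, template, strand, gene_id,
                              cds_tx = NULL, annotate = TRUE) {
  lens <- nchar(pieces)
  ends <- cumsum(lens)
  starts <- ends - lens
  L <- sum(lens)
  if (is.null(cds_tx)) {
    ic <- which(template$kind == "cds")
    cds_tx <- c(starts[min(ic)], ends[max(ic)])
  }
  ex_ids <- unique(template$exon[!is.na(template$exon)])
  ex_tx <- t(vapply(ex_ids, function(e) {
    i <- which(!is.na(template$exon) & template$exon == e)
    c(starts[min(i)], ends[max(i)])
  }, numeric(2)))
  map <- function(t0, t1) {
    if (strand == "+") c(t0, t1) else c(L - t1, L - t0)
  }
  tx <- paste(pieces, collapse = "")
  region <- if (strand == "+") tx else revcomp(tx)
  exdf <- do.call(rbind, lapply(seq_len(nrow(ex_tx)), function(i) {
    g <- map(ex_tx[i, 1], ex_tx[i, 2]); data.frame(start = g[1], end = g[2])
  }))
  exdf <- exdf[order(exdf$start), , drop = FALSE]
  cdl <- list()
  for (i in seq_len(nrow(ex_tx))) {
    s <- max(ex_tx[i, 1], cds_tx[1]); e <- min(ex_tx[i, 2], cds_tx[2])
    if (e > s) {
      g <- map(s, e)
      cdl[[length(cdl) + 1L]] <- data.frame(start = g[1], end = g[2])
    }
  }
  cddf <- do.call(rbind, cdl)
  cddf <- cddf[order(cddf$start), , drop = FALSE]
  # phases in transcription order
  ord <- if (strand == "+") seq_len(nrow(cddf)) else rev(seq_len(nrow(cddf)))
  cum <- 0L
  ph <- integer(nrow(cddf))
  for (i in ord) {
    ph[i] <- (3L - cum %% 3L) %% 3L
    cum <- cum + (cddf$end[i] - cddf$start[i])
  }
  cddf$phase <- ph
  list(seq = region, len = L,
       genes = list(list(gene_id = gene_id, strand = strand, exons = exdf,
                         cds = cddf, annotate = annotate)))
}

# Bare region (no gene): for planted unannotated homolog copies.
build_bare_region <- function(seq) {
  list(seq = seq, len = nchar(seq), genes = list())
}

# Concatenate region variants with spacers into one multi-gene region.
concat_regions <- function(regions, spacers) {
  seq <- ""
  genes <- list()
  for (i in seq_along(regions)) {
    seq <- paste0(seq, spacers[[i]])
    off <- nchar(seq)
    r <- regions[[i]]
    for (g in r$genes) {
      g$exons$start <- g$exons$start + off; g$exons$end <- g$exons$end + off
      g$cds$start <- g$cds$start + off; g$cds$end <- g$cds$end + off
      genes[[length(genes) + 1L]] <- g
    }
    seq <- paste0(seq, r$seq)
  }
  seq <- paste0(seq, spacers[[length(spacers)]])
  list(seq = seq, len = nchar(seq), genes = genes)
}

# Protein / transcript of a gene inside a region variant (for verification).
region_protein <- function(region, gene_idx = 1L) {
  g <- region$genes[[gene_idx]]
  genome <- Biostrings::DNAStringSet(c(chr = region$seq))
  row <- new_tbl(gene_id = g$gene_id, species = "x", contig = "chr",
                 strand = g$strand, exons = list(g$exons),
                 cds = list(g$cds), pseudo = FALSE)
  gene_protein(row[1, ], genome)
}

sw_score <- function(a, b, protein = TRUE) {
  if (nchar(a) == 0 || nchar(b) == 0) return(0)
  if (protein) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
  } else {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = nucl_matrix(), gapOpening = 5, gapExtension = 2,
      scoreOnly = TRUE)
  }
}

# --- standard locus builders -----------------------------------------------

# A locus: id, per-species region variants, truth metadata.
new_locus <- function(id, kind, birth, per_species, truth,
                      outgroup_protein = NULL, outgroup_cds = NULL,
                      uniprot_protein = NULL, orth = NULL,
                      extra_transcriptome = NULL) {
  list(id = id, kind = kind, birth = birth, per_species = per_species,
       truth = truth, outgroup_protein = outgroup_protein,
       outgroup_cds = outgroup_cds, uniprot_protein = uniprot_protein,
       orth = orth, extra_transcriptome = extra_transcriptome)
}

truth_row <- function(gene_id, species, class, conserved_step = NA_integer_,
                      phylostratum = NA_integer_, mechanism = "none",
                      expected_trace = NA_character_,
                      expected_structure = NA_character_,
                      birth_node = NA_integer_, final_class = class,
                      source_genes = NA_character_) {
  new_tbl(gene_id = gene_id, species = species, class = class,
          conserved_step = as.integer(conserved_step),
          phylostratum = as.integer(phylostratum),
          mechanism = mechanism, expected_trace = expected_trace,
          expected_structure = expected_structure,
          birth_node = as.integer(birth_node),
          final_class = final_class, source_genes = source_genes)
}

# Conserved family: born at the root, present in all species and (depending
# on step) the outgroup protein DB, outgroup genome, or curated DB.
make_conserved_locus <- function(id, cfg, step = 1L, strand = "+",
                                 template = NULL, dual_frame = FALSE,
                                 orf = NULL) {
  template <- template %||% std_template(cfg)
  protect <- if (dual_frame) c(0L, 1L) else 0L
  root <- root_pieces(template, cfg, orf = orf)
  tips <- evolve_along_ladder(root, cfg$n_species - 1L, template, cfg,
                              protect)
  per_species <- lapply(cfg$species, function(sp) {
    gid <- paste0(id, "_", sp)
    build_gene_region(tips[[sp]], template, strand, gid)
  })
  names(per_species) <- cfg$species
  og <- evolve_pieces(root, template, cfg$outgroup_extra, cfg, protect)
  ic <- which(template$kind == "cds")
  og_cds <- paste(og[ic], collapse = "")
  og_prot <- sub("\\*$", "", translate_nt(og_cds))
  truth <- dplyr::bind_rows(lapply(cfg$species, function(sp)
    truth_row(paste0(id, "_", sp), sp, "Conserved", conserved_step = step,
              phylostratum = if (sp == cfg$focal) cfg$n_species else
                NA_integer_,
              expected_structure = if (sp == cfg$focal) "fully-confirmed"
              else NA_character_,
              birth_node = cfg$n_species - 1L)))
  loc <- new_locus(id, "conserved", cfg$n_species - 1L, per_species, truth,
                   outgroup_protein = if (step == 1L) og_prot,
                   outgroup_cds = if (step == 2L) og_cds,
                   uniprot_protein = if (step == 3L) og_prot)
  loc$template <- template; loc$root <- root; loc$tips <- tips
  loc$strand <- strand
  loc
}

# Taxon-restricted family born at ladder node `birth` (1 = shared only with
# the sister species): present in sp0..sp<birth>, nowhere else.
make_trog_locus <- function(id, birth, cfg, strand = "+") {
  template <- trog_template(cfg)
  root <- root_pieces(template, cfg)
  tips <- evolve_along_ladder(root, birth, template, cfg)
  per_species <- lapply(names(tips), function(sp) {
    build_gene_region(tips[[sp]], template, strand, paste0(id, "_", sp))
  })
  names(per_species) <- names(tips)
  truth <- dplyr::bind_rows(lapply(names(tips), function(sp)
    truth_row(paste0(id, "_", sp), sp, "TROG",
              phylostratum = if (sp == cfg$focal) birth else NA_integer_,
              expected_structure = if (sp == cfg$focal) "fully-confirmed"
              else NA_character_,
              birth_node = birth)))
  loc <- new_locus(id, "trog", birth, per_species, truth)
  loc$template <- template; loc$tips <- tips
  loc
}

# Species-specific orphan: present in a single species only.
make_ssog_locus <- function(id, sp, cfg, expected_trace = "untraceable",
                            expected_structure = "fully-confirmed") {
  template <- trog_template(cfg)
  root <- root_pieces(template, cfg)
  per_species <- stats::setNames(
    list(build_gene_region(root, template, "+", paste0(id, "_", sp))), sp)
  truth <- truth_row(paste0(id, "_", sp), sp, "SSOG",
                     phylostratum = if (sp == cfg$focal) 0L else NA_integer_,
                     expected_trace = if (sp == cfg$focal) expected_trace
                     else NA_character_,
                     expected_structure = if (sp == cfg$focal)
                       expected_structure else NA_character_,
                     birth_node = 0L)
  new_locus(id, "ssog", 0L, per_species, truth)
}

# --- materialization -------------------------------------------------------

materialize <- function(loci, cfg) {
  # per-slot intergenic spacers, orthologous across species
  igs_tpl <- list(kind = "igs", len = 1L, exon = NA)
  n_slots <- length(loci) + 1L
  igs <- lapply(seq_len(n_slots), function(i) {
    len <- sample(seq(cfg$igs_len_range[1], cfg$igs_len_range[2]), 1L)
    root <- rand_dna(len, cfg)
    b <- cfg$branch_len
    anc <- vector("list", cfg$n_species - 1L)
    anc[[cfg$n_species - 1L]] <- root
    for (k in (cfg$n_species - 2L):1L)
      anc[[k]] <- mutate_igs(anc[[k + 1L]], b, cfg)
    out <- list()
    out[[cfg$focal]] <- mutate_igs(anc[[1L]], b, cfg)
    for (j in seq_len(cfg$n_species - 1L))
      out[[cfg$species[j + 1L]]] <- mutate_igs(anc[[j]], b, cfg)
    out
  })

  genomes <- list(); gene_rows <- list(); orth_rows <- list()
  for (sp in cfg$species) {
    parts <- character(0); cursor <- 0L; rows <- list()
    for (i in seq_along(loci)) {
      sp_igs <- igs[[i]][[sp]]
      parts <- c(parts, sp_igs); cursor <- cursor + nchar(sp_igs)
      loc <- loci[[i]]
      reg <- loc$per_species[[sp]]
      if (!is.null(reg)) {
        orth_rows[[length(orth_rows) + 1L]] <- new_tbl(
          locus = loc$id, species = sp, contig = "chr1",
          start = cursor, end = cursor + reg$len)
        for (g in reg$genes) {
          if (!isTRUE(g$annotate)) next
          ex <- g$exons; cd <- g$cds
          ex$start <- as.integer(ex$start + cursor)
          ex$end <- as.integer(ex$end + cursor)
          cd$start <- as.integer(cd$start + cursor)
          cd$end <- as.integer(cd$end + cursor)
          cd$phase <- as.integer(cd$phase)
          rownames(ex) <- NULL; rownames(cd) <- NULL
          rows[[length(rows) + 1L]] <- new_tbl(
            gene_id = g$gene_id, species = sp, contig = "chr1",
            strand = g$strand, exons = list(ex), cds = list(cd),
            pseudo = FALSE)
        }
        parts <- c(parts, reg$seq); cursor <- cursor + reg$len
      }
    }
    sp_igs <- igs[[n_slots]][[sp]]
    parts <- c(parts, sp_igs)
    genomes[[sp]] <- Biostrings::DNAStringSet(
      stats::setNames(paste(parts, collapse = ""), "chr1"))
    gene_rows[[sp]] <- validate_gene_models(dplyr::bind_rows(rows))
  }
  list(genomes = genomes, genes = dplyr::bind_rows(gene_rows),
       orth = dplyr::bind_rows(orth_rows))
}

# --- reads -----------------------------------------------------------------

# Tile stranded spliced reads over every focal gene's transcript so each CDS
# base reaches the configured depth; junction reads follow the annotation.
make_reads <- function(genes, genome, cfg, no_read_genes = character(),
                       one_junction_genes = character()) {
  step <- max(1L, cfg$read_len %/% cfg$depth)
  all_reads <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    assert_that(max(g$exons[[1]]$end) <= length(genome[[g$contig]]),
                paste0(g$gene_id, ": exon beyond contig end (",
                       max(g$exons[[1]]$end), " > ",
                       length(genome[[g$contig]]), ")"))
    if (g$gene_id %in% no_read_genes) next
    ex <- g$exons[[1]][order(g$exons[[1]]$start), , drop = FALSE]
    L <- sum(ex$end - ex$start)
    if (L < cfg$read_len) next
    offs <- unique(c(seq(0L, L - cfg$read_len, by = step), L - cfg$read_len))
    # transcript offset (plus-strand order) -> genomic blocks
    ex_cum <- cumsum(ex$end - ex$start)
    ex_off <- c(0L, ex_cum[-length(ex_cum)])
    reads <- lapply(seq_along(offs), function(k) {
      t0 <- offs[k]; t1 <- t0 + cfg$read_len
      bl <- list()
      for (j in seq_len(nrow(ex))) {
        s <- max(t0, ex_off[j]); e <- min(t1, ex_cum[j])
        if (e > s)
          bl[[length(bl) + 1L]] <- data.frame(
            start = ex$start[j] + (s - ex_off[j]),
            end = ex$start[j] + (e - ex_off[j]))
      }
      do.call(rbind, bl)
    })
    keep <- rep(TRUE, length(reads))
    if (g$gene_id %in% one_junction_genes && nrow(ex) > 1) {
      # retain a single spliced read per junction
      junctions <- ex$end[-nrow(ex)]
      spliced <- vapply(reads, nrow, 0L) > 1L
      chosen <- integer(0)
      for (jn in junctions) {
        cand <- which(spliced & vapply(reads, function(b)
          any(b$end[-nrow(b)] == jn), logical(1)))
        cand <- setdiff(cand, chosen)
        if (length(cand) > 0) chosen <- c(chosen, cand[1])
      }
      keep <- !spliced
      keep[chosen] <- TRUE
    }
    reads <- reads[keep]
    if (length(reads) == 0) next
    ctg_seq <- genome[[g$contig]]
    read_seq <- vapply(reads, function(b) {
      paste(vapply(seq_len(nrow(b)), function(j)
        as.character(Biostrings::subseq(ctg_seq, b$start[j] + 1L,
                                        b$end[j])),
        character(1)), collapse = "")
    }, character(1))
    all_reads[[length(all_reads) + 1L]] <- new_tbl(
      read_id = sprintf("%s_r%03d", g$gene_id, seq_along(reads)),
      contig = g$contig,
      strand = if (cfg$stranded) g$strand else "+",
      blocks = reads,
      is_spliced = vapply(reads, nrow, 0L) > 1L,
      seq = read_seq)
  }
  dplyr::bind_rows(all_reads)
}
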