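#' Gene model tables
#'
#' Gene models are kept in an ordinary tibble with one row per gene and two
#' list-columns holding the exon and CDS structure, so the whole annotation of
#' a species pipes through dplyr verbs. All coordinates are 0-based half-open;
#' GFF3's 1-based inclusive convention is applied only when reading/writing.
#'
#' Columns: `gene_id`, `species`, `contig`, `strand` (`"+"`/`"-"`),
#' `exons` (list of data.frames with `start`, `end`), `cds` (list of
#' data.frames with `start`, `end`, `phase`), `pseudo` (logical: translation
#' carries an internal stop).
#'
#' @param gene_id,species,contig,strand character vectors, one entry per gene.
#' @param exons,cds lists of data.frames (`start`, `end`[, `phase`]).
#' @param pseudo logical vector.
#' @return A tibble of gene models.
#' @export
gene_model_table <- function(gene_id, species, contig, strand, exons, cds,
                             pseudo = FALSE) {
  tbl <- new_tbl(
    gene_id = as.character(gene_id),
    species = as.character(species),
    contig = as.character(contig),
    strand = as.character(strand),
    exons = exons,
    cds = cds,
    pseudo = rep_len(pseudo, length(gene_id))
  )
  validate_gene_models(tbl)
  tbl
}

validate_gene_models <- function(tbl) {
  assert_that(all(tbl$strand %in% c("+", "-")), "strand must be '+' or '-'")
  for (i in seq_len(nrow(tbl))) {
    ex <- tbl$exons[[i]]
    cd <- tbl$cds[[i]]
    id <- tbl$gene_id[i]
    assert_that(all(diff(ex$start) > 0) && all(ex$end > ex$start),
                paste0(id, ": exons must be sorted, non-empty"))
    if (nrow(ex) > 1)
      assert_that(all(ex$start[-1] >= ex$end[-nrow(ex)]),
                  paste0(id, ": exons overlap"))
    for (j in seq_len(nrow(cd))) {
      inside <- any(cd$start[j] >= ex$start & cd$end[j] <= ex$end)
      assert_that(inside, paste0(id, ": CDS interval not nested in an exon"))
    }
    if (nrow(cd) > 0 && "phase" %in% names(cd)) {
      cdo <- cds_in_tx_order(cd, tbl$strand[i])
      total <- sum(cd$end - cd$start)
      assert_that((total - cdo$phase[1]) %% 3L == 0L,
                  paste0(id, ": CDS length not a codon multiple after ",
                         "phase adjustment"))
    }
  }
  invisible(tbl)
}

# CDS intervals of one gene in transcription order
cds_in_tx_order <- function(cd, strand) {
  cd <- cd[order(cd$start), , drop = FALSE]
  if (strand == "-") cd <- cd[rev(seq_len(nrow(cd))), , drop = FALSE]
  cd
}

# Spliced CDS nucleotide sequence of one gene (gene row, genome DNAStringSet)
gene_cds_seq <- function(gene, genome) {
  contig <- genome[[gene$contig]]
  cd <- cds_in_tx_order(gene$cds[[1]], gene$strand)
  parts <- vapply(seq_len(nrow(cd)), function(j) {
    s <- as.character(Biostrings::subseq(contig, cd$start[j] + 1L, cd$end[j]))
    if (gene$strand == "-") revcomp(s) else s
  }, character(1))
  seq <- paste(parts, collapse = "")
  phase <- cd$phase[1] %||% 0L
  if (is.na(phase)) phase <- 0L
  if (phase > 0) seq <- substr(seq, phase + 1L, nchar(seq))
  seq
}

# Spliced transcript (all exons) of one gene, transcript orientation
gene_transcript_seq <- function(gene, genome) {
  contig <- genome[[gene$contig]]
  ex <- gene$exons[[1]][order(gene$exons[[1]]$start), , drop = FALSE]
  parts <- vapply(seq_len(nrow(ex)), function(j) {
    as.character(Biostrings::subseq(contig, ex$start[j] + 1L, ex$end[j]))
  }, character(1))
  seq <- paste(parts, collapse = "")
  if (gene$strand == "-") revcomp(seq) else seq
}

# Protein of one gene (terminal stop stripped)
gene_protein <- function(gene, genome) {
  p <- translate_nt(gene_cds_seq(gene, genome))
  sub("\\*$", "", p)
}

#' Extract protein and transcript sequences for a gene-model table
#'
#' @param genes gene-model tibble (see [gene_model_table()]).
#' @param genome named `DNAStringSet` covering the genes' contigs.
#' @return Named `AAStringSet` / `DNAStringSet` keyed by `gene_id`.
#' @export
extract_proteins <- function(genes, genome) {
  out <- vapply(seq_len(nrow(genes)), function(i)
    gene_protein(genes[i, ], genome), character(1))
  Biostrings::AAStringSet(stats::setNames(out, genes$gene_id))
}

#' @rdname extract_proteins
#' @export
extract_transcripts <- function(genes, genome) {
  out <- vapply(seq_len(nrow(genes)), function(i)
    gene_transcript_seq(genes[i, ], genome), character(1))
  Biostrings::DNAStringSet(stats::setNames(out, genes$gene_id))
}

# ---------------------------------------------------------------------------
# GFF3

#' Read a GFF3 annotation together with its genome FASTA
#'
#' Parses gene/mRNA/exon/CDS features (one mRNA per gene) into the package's
#' gene-model tibble. Genes whose CDS length is not a multiple of three after
#' phase adjustment are flagged malformed and excluded with a warning, never
#' silently dropped; a CDS outside its contig is a hard error. Genes whose
#' translation carries an internal stop are kept with `pseudo = TRUE`.
#'
#' @param gff3_path path to a GFF3 file.
#' @param fasta_path path to the matching genome FASTA.
#' @param species species label to stamp on the models.
#' @return A gene-model tibble (attribute `"genome"` carries the sequences).
#' @export
read_annotation <- function(gff3_path, fasta_path, species = NA_character_) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*", "", names(genome))
  lines <- readLines(gff3_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    tbl <- gene_model_table(character(), character(), character(),
                            character(), list(), list())
    attr(tbl, "genome") <- genome
    return(tbl)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  assert_that(all(lengths(f) == 9L), "malformed GFF3: expected 9 columns")
  gff <- new_tbl(
    contig = vapply(f, `[[`, "", 1L),
    type = vapply(f, `[[`, "", 3L),
    start1 = as.integer(vapply(f, `[[`, "", 4L)),
    end1 = as.integer(vapply(f, `[[`, "", 5L)),
    strand = vapply(f, `[[`, "", 7L),
    phase = vapply(f, `[[`, "", 8L),
    attrs = vapply(f, `[[`, "", 9L)
  )
  attr_val <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    out[lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0] <-
      sub(paste0(".*", key, "="), "", m)
    out
  }
  gff$id <- attr_val(gff$attrs, "ID")
  gff$parent <- attr_val(gff$attrs, "Parent")

  mrna <- gff[gff$type == "mRNA", ]
  gene_of_tx <- stats::setNames(mrna$parent, mrna$id)
  genes <- gff[gff$type == "gene", ]
  rows <- list(); malformed <- character()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$id[i]
    tx <- mrna$id[mrna$parent == gid][1]
    sub <- gff[!is.na(gff$parent) & gff$parent == tx, ]
    ex <- sub[sub$type == "exon", ]
    cd <- sub[sub$type == "CDS", ]
    ex <- ex[order(ex$start1), ]; cd <- cd[order(cd$start1), ]
    contig <- genes$contig[i]
    assert_that(contig %in% names(genome),
                paste0(gid, ": contig ", contig, " missing from FASTA"))
    clen <- length(genome[[contig]])
    if (nrow(cd) > 0 && (min(cd$start1) < 1 || max(cd$end1) > clen))
      stop(gid, ": CDS outside contig bounds", call. = FALSE)
    exdf <- data.frame(start = ex$start1 - 1L, end = ex$end1)
    phase <- suppressWarnings(as.integer(cd$phase))
    phase[is.na(phase)] <- 0L
    cddf <- data.frame(start = cd$start1 - 1L, end = cd$end1, phase = phase)
    strand <- genes$strand[i]
    cdo <- cds_in_tx_order(cddf, strand)
    total <- sum(cddf$end - cddf$start)
    if (nrow(cddf) > 0 && (total - cdo$phase[1]) %% 3L != 0L) {
      malformed <- c(malformed, gid)
      next
    }
    rows[[length(rows) + 1L]] <- new_tbl(
      gene_id = gid, species = species, contig = contig, strand = strand,
      exons = list(exdf), cds = list(cddf), pseudo = FALSE
    )
  }
  if (length(malformed) > 0)
    warning("excluded malformed gene(s) (CDS length not a codon multiple): ",
            paste(malformed, collapse = ", "), call. = FALSE)
  tbl <- if (length(rows)) dplyr::bind_rows(rows) else
    gene_model_table(character(), character(), character(), character(),
                     list(), list())
  validate_gene_models(tbl)
  # internal stop => pseudo
  if (nrow(tbl) > 0) {
    tbl$pseudo <- vapply(seq_len(nrow(tbl)), function(i) {
      p <- sub("\\*$", "", translate_nt(gene_cds_seq(tbl[i, ], genome)))
      grepl("*", p, fixed = TRUE)
    }, logical(1))
  }
  attr(tbl, "genome") <- genome
  tbl
}

#' Write gene models as canonical GFF3 text
#'
#' Deterministic: records sorted by contig then start then gene id; one mRNA
#' per gene; CDS phase recomputed from the stored structure.
#' `write_annotation(read_annotation(x))` is byte-identical on canonical
#' input.
#'
#' @param genes gene-model tibble.
#' @param path optional file path; when `NULL` the GFF3 text is returned.
#' @return The GFF3 text, invisibly when written to `path`.
#' @export
write_annotation <- function(genes, path = NULL) {
  ord <- order(genes$contig,
               vapply(genes$exons, function(e) min(e$start), numeric(1)),
               genes$gene_id)
  genes <- genes[ord, ]
  out <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]][order(g$exons[[1]]$start), , drop = FALSE]
    cd <- g$cds[[1]][order(g$cds[[1]]$start), , drop = FALSE]
    gs <- io1(min(ex$start), max(ex$end))
    tx <- paste0(g$gene_id, ".t1")
    line <- function(type, s0, e0, phase, attrs)
      paste(g$contig, "phylorphan", type, s0 + 1L, e0, ".", g$strand,
            phase, attrs, sep = "\t")
    out <- c(out,
             line("gene", min(ex$start), max(ex$end), ".",
                  paste0("ID=", g$gene_id)),
             line("mRNA", min(ex$start), max(ex$end), ".",
                  paste0("ID=", tx, ";Parent=", g$gene_id)))
    for (j in seq_len(nrow(ex)))
      out <- c(out, line("exon", ex$start[j], ex$end[j], ".",
                         paste0("Parent=", tx)))
    # recompute phase in transcription order
    cdo <- cds_in_tx_order(cd, g$strand)
    cum <- c(0L, cumsum(cdo$end - cdo$start))
    ph <- (3L - cum[seq_len(nrow(cdo))] %% 3L) %% 3L
    phase_by_start <- stats::setNames(ph, as.character(cdo$start))
    for (j in seq_len(nrow(cd)))
      out <- c(out, line("CDS", cd$start[j], cd$end[j],
                         phase_by_start[[as.character(cd$start[j])]],
                         paste0("ID=", tx, ".cds;Parent=", tx)))
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(text))
  }
  text
}

# ---------------------------------------------------------------------------
# SAM spliced-read alignments

#' Read spliced-read alignments from a SAM text file
#'
#' Only the fields the structure-validation step needs are kept: read id,
#' contig, alignment strand (from FLAG 0x10), and the aligned blocks derived
#' from the CIGAR (`N` operations open inter-block gaps; soft/hard clips
#' shrink the aligned span; `D` stays inside a block). Unmapped reads are
#' skipped; an unknown CIGAR operation is an error.
#'
#' @param path SAM file path.
#' @param min_intron minimum `N` gap length accepted as an intron (bp).
#' @return Tibble: `read_id`, `contig`, `strand`, `blocks` (list of
#'   data.frames `start`, `end`, 0-based half-open), `is_spliced`.
#' @export
read_sam <- function(path, min_intron = 20L) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(new_tbl(read_id = character(), contig = character(),
                   strand = character(), blocks = list(),
                   is_spliced = logical()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)
  keep <- bitwAnd(flag, 4L) == 0L & rname != "*"
  qname <- qname[keep]; flag <- flag[keep]; rname <- rname[keep]
  pos <- pos[keep]; cigar <- cigar[keep]
  bad <- grepl("[0-9]+[^0-9MIDNSH=X]", paste0(cigar, "!"))
  if (any(bad))
    stop("unknown CIGAR operation in read(s): ",
         paste(utils::head(qname[bad], 3), collapse = ", "), call. = FALSE)
  rl <- GenomicAlignments::extractAlignmentRangesOnReference(cigar, pos = pos)
  blocks <- lapply(seq_along(rl), function(i) {
    r <- rl[[i]]
    df <- data.frame(start = BiocGenerics::start(r) - 1L,
                     end = BiocGenerics::end(r))
    if (nrow(df) > 1) {
      gaps <- df$start[-1] - df$end[-nrow(df)]
      if (any(gaps < min_intron))
        stop("read ", qname[i], ": splice gap shorter than min_intron (",
             min_intron, " bp)", call. = FALSE)
    }
    df
  })
  new_tbl(
    read_id = qname,
    contig = rname,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    blocks = blocks,
    is_spliced = lengths(lapply(blocks, function(b) b$start)) > 1L
  )
}

# Writer used by the simulator. reads: tibble with read_id, contig, strand,
# blocks (0-based), seq. Deterministic: sorted by contig, start, read_id.
write_sam <- function(reads, contig_lengths, path) {
  start0 <- vapply(reads$blocks, function(b) b$start[1], numeric(1))
  reads <- reads[order(reads$contig, start0, reads$read_id), ]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(contig_lengths),
                  "\tLN:", unname(contig_lengths)))
  recs <- vapply(seq_len(nrow(reads)), function(i) {
    b <- reads$blocks[[i]]
    widths <- b$end - b$start
    cig <- paste0(widths[1], "M")
    if (nrow(b) > 1)
      for (j in 2:nrow(b))
        cig <- paste0(cig, b$start[j] - b$end[j - 1], "N", widths[j], "M")
    flag <- if (reads$strand[i] == "-") 16L else 0L
    seq <- reads$seq[i] %||% "*"
    paste(reads$read_id[i], flag, reads$contig[i], b$start[1] + 1L, 60L,
          cig, "*", 0L, 0L, seq, "*", sep = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Species tree

#' Read a rooted species tree with a designated focal species
#'
#' @param newick a Newick string or a file path.
#' @param focal leaf name of the focal species.
#' @return An object of class `species_tree`: list with the `ape::phylo`
#'   tree and the focal leaf name.
#' @export
read_species_tree <- function(newick, focal) {
  phy <- if (file.exists(newick)) ape::read.tree(newick) else
    ape::read.tree(text = newick)
  assert_that(!is.null(phy), "could not parse Newick input")
  assert_that(ape::is.rooted(phy),
              "species tree must be rooted (found an unrooted tree)")
  assert_that(!anyDuplicated(phy$tip.label), "leaf names must be unique")
  assert_that(focal %in% phy$tip.label,
              paste0("focal species '", focal, "' is not a leaf of the tree"))
  structure(list(phy = phy, focal = focal), class = "species_tree")
}

#' Ladder indices of the non-focal species
#'
#' The ladder index of a leaf is the number of internal nodes on the path
#' between it and the focal leaf (1 = sister species). On a pure ladder
#' phylogeny this equals the phylostratum of the corresponding ancestor.
#'
#' @param tree a `species_tree`.
#' @return Tibble: `species`, `ladder_index`, sorted by index.
#' @export
ladder_index <- function(tree) {
  phy <- tree$phy
  others <- setdiff(phy$tip.label, tree$focal)
  from <- match(tree$focal, phy$tip.label)
  idx <- vapply(others, function(sp) {
    path <- ape::nodepath(phy, from, match(sp, phy$tip.label))
    length(path) - 2L
  }, integer(1))
  dplyr::arrange(new_tbl(species = others, ladder_index = unname(idx)),
                 .data$ladder_index)
}

# Ladder Newick builder: (((sp0,sp1),sp2),...); all branch lengths b.
make_ladder_newick <- function(species, branch_len) {
  s <- paste0(species[1], ":", branch_len)
  for (k in 2:length(species)) {
    s <- paste0("(", s, ",", species[k], ":", branch_len, "):", branch_len)
  }
  paste0(sub(paste0(":", branch_len, "$"), "", s), ";")
}
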