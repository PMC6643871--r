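#' Simulate a ladder-phylogeny multi-species dataset with planted truth
#'
#' Generates per-species genomes, annotations, proteins, transcripts and
#' transcriptome assemblies on a pure ladder phylogeny around the focal
#' species, together with outgroup databases, simulated stranded spliced
#' reads for the focal species, and a machine-readable ground-truth table.
#' Planted content: conserved families (classified at cascade steps 1-3),
#' taxon-restricted families born at every internal node, species-specific
#' orphans, and one exemplar of each origin mechanism (chimera, gene split
#' with frameshift and de novo exon, strand switch, overprinting, heuristic
#' search failure, de novo intronic, de novo intergenic) plus an
#' assembly-gap trace exemplar.
#'
#' Planted contracts (orphans undetectable at the cascade thresholds,
#' taxon-restricted genes detectable exactly up to their birth node,
#' mechanism signatures inside their detectability windows) are verified
#' with the package's own search engine and offending random draws are
#' regenerated, so the ground truth holds by construction for any seed.
#'
#' @param config a [sim_config()].
#' @param seed integer; fixes the entire dataset byte-for-byte.
#' @return An object of class `orphan_dataset`: list with `tree`, `genomes`,
#'   `genes`, `proteins`, `transcripts`, `transcriptome`, `outgroup`,
#'   `reads`, `truth`, `plants`, `orth`, `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  set.seed(seed)
  focal <- cfg$focal
  sp1 <- cfg$species[2]

  # --- role families (sources/hosts for the mechanism plants) -------------
  build_role <- function(id, builder) {
    for (t in seq_len(5L)) {
      loc <- builder(id)
      og_ok <- is.null(loc$outgroup_protein) ||
        sw_score(region_protein(loc$per_species[[focal]]),
                 loc$outgroup_protein) > 100
      if (og_ok) return(loc)
    }
    stop("role family ", id, " failed its conservation contract",
         call. = FALSE)
  }
  fx <- build_role("fx", function(id)
    make_conserved_locus(id, cfg, template = std_template(cfg)))
  fy <- build_role("fy", function(id)
    make_conserved_locus(id, cfg, template = std_template(cfg)))
  fs <- build_role("fs", function(id)
    make_conserved_locus(id, cfg, template = std_template(cfg)))
  fv <- build_role("fv", function(id)
    make_conserved_locus(id, cfg, template = std_template(cfg)))
  fp <- build_role("fp", function(id)
    make_conserved_locus(id, cfg, template = std_template(cfg),
                         dual_frame = TRUE,
                         orf = make_dual_frame_orf(cfg)))
  fh <- build_role("fh", function(id) make_dni_host_locus(id, cfg))

  # --- generic conserved families -----------------------------------------
  n_generic <- cfg$n_conserved - 6L
  n_step1 <- n_generic - cfg$n_step2 - cfg$n_step3
  cons <- list()
  for (i in seq_len(n_generic)) {
    step <- if (i <= n_step1) 1L else if (i <= n_step1 + cfg$n_step2) 2L
            else 3L
    tpl <- if (i %% 2L == 0L) std_template(cfg, cds_lens = c(74L, 82L, 78L))
           else std_template(cfg)
    strand <- if (i %% 3L == 0L) "-" else "+"
    cons[[i]] <- make_conserved_locus(sprintf("cons%02d", i), cfg,
                                      step = step, strand = strand,
                                      template = tpl)
  }

  # --- taxon-restricted and species-specific loci -------------------------
  trogs <- list()
  for (k in seq_len(cfg$n_species - 1L))
    for (i in seq_len(cfg$n_trog_per_stratum))
      trogs[[length(trogs) + 1L]] <-
        make_trog_locus(sprintf("trog%d_%d", k, i), k, cfg,
                        strand = if ((k + i) %% 2L == 0L) "-" else "+")

  ssogs <- list()
  struct_of <- c("fully-confirmed", "fully-confirmed", "fully-confirmed",
                 "unconfirmed", "partially-confirmed")
  for (i in seq_len(cfg$n_ssog_focal))
    ssogs[[length(ssogs) + 1L]] <-
      make_ssog_locus(sprintf("ssogf%d", i), focal, cfg,
                      expected_structure =
                        struct_of[min(i, length(struct_of))])
  for (sp in cfg$species[-1])
    for (i in seq_len(cfg$n_ssog_other))
      ssogs[[length(ssogs) + 1L]] <-
        make_ssog_locus(sprintf("oss_%s_%d", sp, i), sp, cfg)
  no_read_genes <- paste0("ssogf4_", focal)
  one_junction_genes <- paste0("ssogf5_", focal)

  # --- mechanism plants ---------------------------------------------------
  fs <- apply_split(fs, cfg)
  fh <- plant_dni(fh, "dni", cfg)
  plants_loci <- list(
    chim = make_chimera_locus("chim", cfg, fx, fy),
    strs = make_strand_switch_locus("strs", cfg, fv),
    ovp = make_overprint_locus("ovp", cfg, fp),
    heur = make_heurfail_locus("heur", cfg),
    dgi = make_dgi_locus("dgi", cfg),
    gap = make_gap_locus("gap", cfg))

  # --- backbone: weave special loci between conserved anchors -------------
  # alternate conserved anchors and special loci so every special locus has
  # conserved flanks on both sides (needed for synteny-derived regions)
  role <- list(fx, fy, fs, fv, fp, fh)
  conserved_all <- c(cons, role)
  specials <- c(trogs, ssogs, unname(plants_loci))
  assert_that(length(conserved_all) > length(specials),
              "need more conserved loci than special loci for anchoring")
  loci <- list()
  ci <- 1L
  for (si in seq_along(specials)) {
    loci[[length(loci) + 1L]] <- conserved_all[[ci]]; ci <- ci + 1L
    loci[[length(loci) + 1L]] <- specials[[si]]
  }
  while (ci <= length(conserved_all)) {
    loci[[length(loci) + 1L]] <- conserved_all[[ci]]; ci <- ci + 1L
  }
  names(loci) <- vapply(loci, `[[`, "", "id")

  # --- verify planted contracts, redrawing offenders ----------------------
  redraw <- function(id) {
    if (startsWith(id, "trog")) {
      k <- as.integer(sub("trog(\\d+)_.*", "\\1", id))
      make_trog_locus(id, k, cfg)
    } else if (startsWith(id, "ssogf")) {
      i <- as.integer(sub("ssogf", "", id))
      make_ssog_locus(id, focal, cfg,
                      expected_structure = struct_of[min(i, 5L)])
    } else if (startsWith(id, "oss_")) {
      sp <- sub("oss_(sp\\d+)_\\d+", "\\1", id)
      make_ssog_locus(id, sp, cfg)
    } else if (id == "gap") {
      make_gap_locus(id, cfg)
    } else if (id == "chim") {
      make_chimera_locus(id, cfg, fx, fy)
    } else if (startsWith(id, "cons")) {
      old <- loci[[id]]
      step <- old$truth$conserved_step[1]
      make_conserved_locus(id, cfg, step = step, strand = old$strand %||% "+",
                           template = old$template)
    } else {
      stop("contract violation in non-redrawable locus ", id, call. = FALSE)
    }
  }

  for (pass in seq_len(6L)) {
    dbs <- dataset_protein_dbs(loci, cfg)
    og <- dataset_outgroup(loci, cfg)
    offenders <- character()

    last_hit <- NULL
    hit_at <- function(prot, db, thr) {
      if (length(db) == 0) return(FALSE)
      h <- search_homology(c(q = prot), db, search_params("pp", e_max = thr))
      if (nrow(h) > 0) last_hit <<- h[1, ]
      nrow(h) > 0
    }

    for (loc in loci) {
      id <- loc$id
      if (loc$kind == "trog") {
        prot <- region_protein(loc$per_species[[focal]])
        carriers <- cfg$species[seq_len(loc$birth) + 1L]
        beyond <- setdiff(cfg$species[-1], carriers)
        ok <- all(vapply(carriers, function(sp)
          hit_at(prot, dbs[[sp]], 1e-3), logical(1))) &&
          !any(vapply(beyond, function(sp)
            hit_at(prot, dbs[[sp]], 1e-3), logical(1))) &&
          !hit_at(prot, og$proteins, 1e-3) &&
          !hit_at(prot, og$uniprot, 1e-3)
        if (!ok) offenders <- c(offenders, id)
      } else if (loc$kind == "ssog" ||
                 loc$kind %in% c("mech_chimera", "mech_strand",
                                 "mech_overprint", "mech_dgi")) {
        sp_own <- names(loc$per_species)[1]
        prot <- region_protein(loc$per_species[[sp_own]])
        others <- setdiff(cfg$species, sp_own)
        ok <- !any(vapply(others, function(sp)
          hit_at(prot, dbs[[sp]], 1e-3), logical(1))) &&
          !hit_at(prot, og$proteins, 1e-3) && !hit_at(prot, og$uniprot, 1e-3)
        if (!ok) {
          offenders <- c(offenders, id)
          if (!is.null(last_hit))
            message("contract leak: ", id, " -> ", last_hit$subject_id,
                    " E=", signif(last_hit$e_value, 3))
        }
      } else if (loc$kind == "conserved") {
        reg <- loc$per_species[[focal]]
        gi <- which(vapply(reg$genes, `[[`, "", "gene_id") ==
                      paste0(loc$id, "_", focal))
        if (length(gi) == 0) next  # focal copy replaced by a plant
        prot <- region_protein(reg, gi[1])
        bad <- if (!is.null(loc$outgroup_protein)) {
          # step-1 family: the outgroup protein hit must exist
          !hit_at(prot, og$proteins, 1e-3)
        } else {
          # step-2/3 family: must NOT leak into the outgroup protein DB
          hit_at(prot, og$proteins, 1e-3)
        }
        if (bad) offenders <- c(offenders, id)
      }
    }

    # orphan candidates planted inside multi-gene loci
    for (embedded in list(list(loc = loci[["fs"]], gene = fs$plant$gene_id),
                          list(loc = loci[["fh"]], gene = fh$plant$gene_id),
                          list(loc = loci[["heur"]],
                               gene = plants_loci$heur$plant$gene_id))) {
      reg <- embedded$loc$per_species[[focal]]
      gi <- which(vapply(reg$genes, `[[`, "", "gene_id") == embedded$gene)
      prot <- region_protein(reg, gi)
      bad <- any(vapply(setdiff(cfg$species, focal), function(sp)
        hit_at(prot, dbs[[sp]], 1e-3), logical(1))) ||
        hit_at(prot, og$proteins, 1e-3) || hit_at(prot, og$uniprot, 1e-3)
      if (bad)
        stop("planted candidate ", embedded$gene,
             " violates its orphan contract", call. = FALSE)
    }

    if (length(offenders) == 0) break
    if (pass == 6L)
      stop("simulation could not satisfy planted contracts for: ",
           paste(offenders, collapse = ", "), call. = FALSE)
    for (id in unique(offenders)) loci[[id]] <- redraw(id)
  }

  # --- untraceability: check the plain focal orphans against sister
  # transcript/genome space, redrawing leaks ------------------------------
  for (pass in seq_len(4L)) {
    mat <- materialize(loci, cfg)
    tx_dbs <- lapply(cfg$species, function(sp) {
      g <- mat$genes[mat$genes$species == sp, ]
      extract_transcripts(g, mat$genomes[[sp]])
    })
    names(tx_dbs) <- cfg$species
    leaks <- character()
    for (i in seq_len(cfg$n_ssog_focal)) {
      id <- sprintf("ssogf%d", i)
      gid <- paste0(id, "_", focal)
      row <- mat$genes[mat$genes$gene_id == gid, ]
      tx <- gene_transcript_seq(row[1, ], mat$genomes[[focal]])
      prot <- gene_protein(row[1, ], mat$genomes[[focal]])
      hit_tx <- any(vapply(cfg$species[-1], function(sp) {
        h <- search_homology(stats::setNames(tx, gid), tx_dbs[[sp]],
                             search_params("nn", e_max = 1e-3))
        nrow(h) > 0
      }, logical(1)))
      hit_gen <- any(vapply(cfg$species[-1], function(sp) {
        h <- search_homology(stats::setNames(prot, gid),
                             as.character(mat$genomes[[sp]]),
                             search_params("px", e_max = 1e-5))
        nrow(h) > 0
      }, logical(1)))
      if (hit_tx || hit_gen) leaks <- c(leaks, id)
    }
    if (length(leaks) == 0) break
    if (pass == 4L)
      stop("untraceable plants keep leaking homology: ",
           paste(leaks, collapse = ", "), call. = FALSE)
    for (id in leaks) loci[[id]] <- redraw(id)
  }

  # --- finalize -----------------------------------------------------------
  genes <- mat$genes
  proteins <- lapply(cfg$species, function(sp)
    extract_proteins(genes[genes$species == sp, ], mat$genomes[[sp]]))
  transcripts <- lapply(cfg$species, function(sp)
    extract_transcripts(genes[genes$species == sp, ], mat$genomes[[sp]]))
  names(proteins) <- names(transcripts) <- cfg$species

  transcriptome <- transcripts
  for (loc in loci) {
    if (!is.null(loc$extra_transcriptome)) {
      for (sp in names(loc$extra_transcriptome)) {
        transcriptome[[sp]] <- c(
          transcriptome[[sp]],
          Biostrings::DNAStringSet(loc$extra_transcriptome[[sp]]))
      }
    }
  }

  og <- dataset_outgroup(loci, cfg)
  reads <- make_reads(genes[genes$species == focal, ], mat$genomes[[focal]],
                      cfg, no_read_genes = no_read_genes,
                      one_junction_genes = one_junction_genes)
  truth <- dplyr::bind_rows(lapply(loci, `[[`, "truth"))
  plants <- Filter(Negate(is.null), lapply(loci, `[[`, "plant"))

  tree <- read_species_tree(make_ladder_newick(cfg$species, cfg$branch_len),
                            focal)
  ds <- list(tree = tree, species = cfg$species, focal = focal,
             genomes = mat$genomes, genes = genes, proteins = proteins,
             transcripts = transcripts, transcriptome = transcriptome,
             outgroup = og, reads = reads, truth = truth, plants = plants,
             orth = mat$orth, config = cfg, seed = seed)
  class(ds) <- "orphan_dataset"
  ds
}

# per-species protein databases straight from the locus variants
dataset_protein_dbs <- function(loci, cfg) {
  out <- lapply(cfg$species, function(sp) {
    seqs <- character(0)
    for (loc in loci) {
      reg <- loc$per_species[[sp]]
      if (is.null(reg)) next
      for (gi in seq_along(reg$genes)) {
        g <- reg$genes[[gi]]
        if (!isTRUE(g$annotate %||% TRUE)) next
        seqs[g$gene_id] <- region_protein(reg, gi)
      }
    }
    Biostrings::AAStringSet(seqs)
  })
  names(out) <- cfg$species
  out
}

dataset_outgroup <- function(loci, cfg) {
  prot <- character(0); uni <- character(0); genome_parts <- character(0)
  for (loc in loci) {
    if (!is.null(loc$outgroup_protein))
      prot[paste0("og_", loc$id)] <- loc$outgroup_protein
    if (!is.null(loc$uniprot_protein))
      uni[paste0("up_", loc$id)] <- loc$uniprot_protein
    if (!is.null(loc$outgroup_cds))
      genome_parts <- c(genome_parts, rand_dna(200L, cfg), loc$outgroup_cds)
  }
  # decoys make the curated database non-trivial
  for (i in seq_len(20L))
    uni[sprintf("up_decoy%02d", i)] <-
      sub("\\*$", "", translate_nt(rand_orf(81L, cfg)))
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(c(genome_parts, rand_dna(200L, cfg)),
                          collapse = ""), "og1"))
  list(proteins = Biostrings::AAStringSet(prot),
       genomes = genome,
       uniprot = Biostrings::AAStringSet(uni))
}

#' Write / read a simulated dataset as plain-text files
#'
#' Layout: `tree.nwk`, `truth.tsv`, `reads.sam` (focal spliced reads),
#' `species/<sp>/{genome.fa, annotation.gff3, proteins.fa, transcripts.fa,
#' transcriptome.fa}` and `outgroup/{proteins.fa, genome.fa, uniprot.fa}`.
#' Writers are deterministic: the same dataset yields byte-identical trees.
#'
#' @param ds an `orphan_dataset`.
#' @param dir output directory (created if missing).
#' @return `write_dataset()`: `dir`, invisibly. `read_dataset()`: an
#'   `orphan_dataset` (without the in-memory-only `plants`/`orth` tables).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(ape::write.tree(ds$tree$phy), file.path(dir, "tree.nwk"))
  write_tsv_plain(ds$truth, file.path(dir, "truth.tsv"))
  for (sp in ds$species) {
    d <- file.path(dir, "species", sp)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(ds$genomes[[sp]], file.path(d, "genome.fa"))
    write_annotation(ds$genes[ds$genes$species == sp, ],
                     file.path(d, "annotation.gff3"))
    Biostrings::writeXStringSet(ds$proteins[[sp]],
                                file.path(d, "proteins.fa"))
    Biostrings::writeXStringSet(ds$transcripts[[sp]],
                                file.path(d, "transcripts.fa"))
    Biostrings::writeXStringSet(ds$transcriptome[[sp]],
                                file.path(d, "transcriptome.fa"))
  }
  d <- file.path(dir, "outgroup")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(ds$outgroup$proteins,
                              file.path(d, "proteins.fa"))
  Biostrings::writeXStringSet(ds$outgroup$genomes, file.path(d, "genome.fa"))
  Biostrings::writeXStringSet(ds$outgroup$uniprot, file.path(d, "uniprot.fa"))
  contig_lengths <- stats::setNames(
    Biostrings::width(ds$genomes[[ds$focal]]),
    names(ds$genomes[[ds$focal]]))
  write_sam(ds$reads, contig_lengths, file.path(dir, "reads.sam"))
  invisible(dir)
}

#' @rdname write_dataset
#' @param dir dataset directory written by `write_dataset()`.
#' @param focal focal species leaf name.
#' @export
read_dataset <- function(dir, focal = "sp0") {
  species <- sort(list.dirs(file.path(dir, "species"), recursive = FALSE,
                            full.names = FALSE))
  tree <- read_species_tree(file.path(dir, "tree.nwk"), focal)
  genomes <- list(); genes <- list(); proteins <- list()
  transcripts <- list(); transcriptome <- list()
  for (sp in species) {
    d <- file.path(dir, "species", sp)
    g <- read_annotation(file.path(d, "annotation.gff3"),
                         file.path(d, "genome.fa"), species = sp)
    genomes[[sp]] <- attr(g, "genome")
    attr(g, "genome") <- NULL
    genes[[sp]] <- g
    proteins[[sp]] <- Biostrings::readAAStringSet(
      file.path(d, "proteins.fa"))
    transcripts[[sp]] <- Biostrings::readDNAStringSet(
      file.path(d, "transcripts.fa"))
    transcriptome[[sp]] <- Biostrings::readDNAStringSet(
      file.path(d, "transcriptome.fa"))
  }
  og <- list(
    proteins = Biostrings::readAAStringSet(
      file.path(dir, "outgroup", "proteins.fa")),
    genomes = Biostrings::readDNAStringSet(
      file.path(dir, "outgroup", "genome.fa")),
    uniprot = Biostrings::readAAStringSet(
      file.path(dir, "outgroup", "uniprot.fa")))
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  ds <- list(tree = tree, species = species, focal = focal,
             genomes = genomes, genes = dplyr::bind_rows(genes),
             proteins = proteins, transcripts = transcripts,
             transcriptome = transcriptome, outgroup = og,
             reads = read_sam(file.path(dir, "reads.sam")),
             truth = tibble::as_tibble(truth), plants = NULL, orth = NULL,
             config = NULL, seed = NA_integer_)
  class(ds) <- "orphan_dataset"
  ds
}

#' @export
print.orphan_dataset <- function(x, ...) {
  cat("orphan_dataset:", length(x$species), "species, focal", x$focal, "\n")
  cat("  genes:", nrow(x$genes), " (focal:",
      sum(x$genes$species == x$focal), ")\n")
  cat("  reads:", nrow(x$reads), " truth rows:", nrow(x$truth), "\n")
  invisible(x)
}
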