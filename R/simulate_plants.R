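# Planted origin-mechanism exemplars.
#
# Each constructor builds one locus whose focal gene reproduces the signature
# of one origin mechanism, tuned by bounded rejection sampling so the planted
# homology falls inside an explicit detectability window: strong enough for
# the targeted (per-exon / in-interval / antisense) search to find it, weak
# enough that the genome-wide protein cascade does not (keeping the gene an
# SSOG). Window arithmetic uses the engine's own statistics
# E = K*m*n*exp(-lambda*S) and is documented in the methods vignette.

# change the first two bases of n randomly chosen codons (nonsynonymous by
# construction, stop-free): drops protein identity fast while retaining
# nucleotide-level traceability at the third positions
diverge_nonsyn <- function(seq, n_codons) {
  cods <- codons_of(seq)
  idx <- sample(seq_along(cods), min(n_codons, length(cods)))
  cods[idx] <- vapply(cods[idx], function(cd) {
    repeat {
      nc <- paste0(sample(BASES, 1L), sample(BASES, 1L),
                   substr(cd, 3L, 3L))
      if (!(nc %in% STOP_CODONS)) return(nc)
    }
  }, character(1))
  paste(cods, collapse = "")
}

# mutate an in-frame codon string (no start/stop bookkeeping) keeping it
# free of stop codons
diverge_inframe <- function(seq, d, cfg) {
  w <- mutate_cds(paste0("ATG", seq, "TAA"), d, cfg)
  substr(w, 4L, nchar(w) - 3L)
}

# replace any stop codon in frame 0 with a random sense codon
repair_orf_interior <- function(seq) {
  cods <- codons_of(seq)
  bad <- which(cods %in% STOP_CODONS)
  if (length(bad)) cods[bad] <- sample(SENSE_CODONS, length(bad), TRUE)
  paste(cods, collapse = "")
}

# diverge `piece` (in-frame codons) until SW score of its translation against
# `ref_peptides` falls inside [lo, hi]; restarts from scratch when it
# overshoots. Bounded; errors out if the window cannot be met.
diverge_to_window <- function(piece, ref_peptides, lo, hi, cfg,
                              step = 0.03, max_restart = 60L) {
  for (r in seq_len(max_restart)) {
    cur <- piece
    for (i in seq_len(200L)) {
      pep <- translate_nt(cur)
      sc <- max(vapply(ref_peptides, function(p) sw_score(pep, p),
                       numeric(1)))
      if (sc <= hi && sc >= lo) return(cur)
      if (sc < lo) break  # overshot; restart
      cur <- diverge_inframe(cur, step, cfg)
    }
  }
  stop("could not tune planted divergence into score window [", lo, ", ",
       hi, "]", call. = FALSE)
}

plant_template <- function(cfg, cds_lens, intron = 47L, utr = NULL) {
  u <- utr %||% cfg$utr_len
  if (length(cds_lens) == 2L) {
    list(kind = c("utr", "cds", "intron", "cds", "utr"),
         len = c(u, cds_lens[1], intron, cds_lens[2], u),
         exon = c(1L, 1L, NA, 2L, 2L))
  } else {
    list(kind = c("utr", "cds", "utr"),
         len = c(u, cds_lens[1], u),
         exon = c(1L, 1L, 1L))
  }
}

# --- chimera ---------------------------------------------------------------
# Two short exons copied from the middle coding exon of two distinct
# conserved source genes, diverged (nonsynonymously, so the nucleotide trace
# survives) until each piece scores 48-59 raw SW against its best source
# copy and the assembled protein stays <= 59: the per-exon relaxed search
# finds both pieces, the whole-protein cascade at 1e-3 finds neither.
make_chimera_locus <- function(id, cfg, fx, fy) {
  pick_piece <- function(fam) {
    ic <- which(fam$template$kind == "cds")[2]
    cds2 <- fam$tips[[cfg$focal]][ic]
    substr(cds2, 4L, 69L)  # codons 2..23 of the middle exon
  }
  refs <- function(fam) {
    lapply(c(cfg$focal, cfg$species[2]), function(sp)
      region_protein(fam$per_species[[sp]]))
  }
  rx <- refs(fx); ry <- refs(fy)
  max_sc <- function(pep, refs) max(vapply(refs, function(p)
    sw_score(pep, p), numeric(1)))
  a <- pick_piece(fx); b <- pick_piece(fy)
  done <- FALSE
  for (it in seq_len(400L)) {
    pep_a <- translate_nt(a); pep_b <- translate_nt(b)
    full <- paste0("M", pep_a, pep_b)
    sa <- max_sc(pep_a, rx); sb <- max_sc(pep_b, ry)
    fa <- max_sc(full, rx); fb <- max_sc(full, ry)
    if (sa < 48) a <- pick_piece(fx)        # overshot, restart the piece
    else if (sb < 48) b <- pick_piece(fy)
    else if (fa > 59) a <- diverge_nonsyn(a, 1L)
    else if (fb > 59) b <- diverge_nonsyn(b, 1L)
    else { done <- TRUE; break }
  }
  assert_that(done, "chimera plant: joint score window not met")
  cds1 <- paste0("ATG", a)                     # 69 nt
  cds2 <- paste0(repair_orf_interior(b), sample(STOP_CODONS, 1L))  # 69 nt
  template <- plant_template(cfg, c(69L, 69L))
  pieces <- root_pieces(template, cfg, orf = paste0(cds1, cds2))
  gid <- paste0(id, "_", cfg$focal)
  per_species <- stats::setNames(
    list(build_gene_region(pieces, template, "+", gid)), cfg$focal)
  truth <- truth_row(gid, cfg$focal, "SSOG", phylostratum = 0L,
                     mechanism = "chimera", expected_trace = "partial",
                     expected_structure = "fully-confirmed", birth_node = 0L,
                     source_genes = paste(fx$id, fy$id, sep = ","))
  loc <- new_locus(id, "mech_chimera", 0L, per_species, truth)
  loc$plant <- list(mechanism = "chimera", gene_id = gid,
                    sources = c(fx$id, fy$id))
  loc
}

# --- gene split ------------------------------------------------------------
# Rewrites a conserved family's focal variant: the first exon survives as a
# new gene carrying a +1 frameshift insertion after codon 13 and a de novo
# second exon; an adjacent neighbor gene keeps the remaining two exons.
apply_split <- function(fs, cfg) {
  ic <- which(fs$template$kind == "cds")
  foc <- fs$tips[[cfg$focal]]
  c1 <- foc[ic[1]]; c2 <- foc[ic[2]]; c3 <- foc[ic[3]]
  sp1_prot <- region_protein(fs$per_species[[cfg$species[2]]])

  shift_pos <- 39L  # after codon 13
  tune <- function() {
    ins <- sample(BASES, 1L)
    shifted <- paste0(substr(c1, 1L, shift_pos), ins,
                      substr(c1, shift_pos + 1L, nchar(c1)))   # 76 nt
    denovo <- paste0(paste(sample(SENSE_CODONS, 25L, TRUE), collapse = ""),
                     substr(rand_dna(2L, cfg), 1L, 2L))        # 77 nt
    cand_cds <- paste0(shifted, denovo, sample(STOP_CODONS, 1L)) # 156 nt
    cand_cds <- paste0(substr(cand_cds, 1L, 3L),
                       repair_orf_interior(substr(cand_cds, 4L,
                                                  nchar(cand_cds) - 3L)),
                       substr(cand_cds, nchar(cand_cds) - 2L,
                              nchar(cand_cds)))
    cand_cds
  }
  cand_cds <- NULL
  for (r in seq_len(60L)) {
    cc <- tune()
    sc <- sw_score(sub("\\*$", "", translate_nt(cc)), sp1_prot)
    if (sc <= 55 && sc >= 18) { cand_cds <- cc; break }
    # prefix too hot: diverge the retained prefix codons 2..13 a little
    pre <- substr(cc, 4L, shift_pos)
    pre2 <- diverge_inframe(pre, 0.06, cfg)
    cc <- paste0(substr(cc, 1L, 3L), pre2,
                 substr(cc, shift_pos + 1L, nchar(cc)))
    sc <- sw_score(sub("\\*$", "", translate_nt(cc)), sp1_prot)
    if (sc <= 55 && sc >= 18) { cand_cds <- cc; break }
  }
  assert_that(!is.null(cand_cds), "gene-split plant: prefix window not met")

  cand_tpl <- plant_template(cfg, c(76L, 80L))
  cand_pieces <- root_pieces(cand_tpl, cfg, orf = cand_cds)
  cand_gid <- paste0(fs$id, "cand_", cfg$focal)
  cand_region <- build_gene_region(cand_pieces, cand_tpl, "+", cand_gid)

  nb_cds <- paste0("ATG", c2, c3)  # 162 nt, keeps ancestral suffix exons
  nb_tpl <- plant_template(cfg, 162L)
  nb_gid <- paste0(fs$id, "nb_", cfg$focal)
  nb_region <- build_gene_region(root_pieces(nb_tpl, cfg, orf = nb_cds),
                                 nb_tpl, "+", nb_gid)

  spacer <- rand_dna(90L, cfg)
  fs$per_species[[cfg$focal]] <- concat_regions(
    list(cand_region, nb_region), list("", spacer, ""))
  fs$truth <- fs$truth[fs$truth$species != cfg$focal, ]
  fs$truth <- dplyr::bind_rows(
    fs$truth,
    truth_row(cand_gid, cfg$focal, "SSOG", phylostratum = 0L,
              mechanism = "gene-split", expected_trace = "partial",
              expected_structure = "fully-confirmed", birth_node = 0L,
              source_genes = fs$id),
    truth_row(nb_gid, cfg$focal, "Conserved", conserved_step = 1L,
              phylostratum = cfg$n_species,
              expected_structure = "fully-confirmed",
              birth_node = cfg$n_species - 1L))
  fs$plant <- list(mechanism = "gene-split", gene_id = cand_gid,
                   neighbor = nb_gid, source = fs$id,
                   shift_codon = 14L, modifiers = c("frame-shift",
                                                    "de-novo-exon"))
  fs
}

# --- strand switch ---------------------------------------------------------
# Candidate ORF engineered on the reverse strand of a conserved gene's middle
# exon, diverged into window [62, 80]: found by the targeted antisense
# translated search, invisible to the protein cascade and below the
# trace-matrix genome threshold.
make_strand_switch_locus <- function(id, cfg, fv) {
  ic <- which(fv$template$kind == "cds")[2]
  rc <- revcomp(fv$tips[[cfg$focal]][ic])      # 81 nt
  core <- repair_orf_interior(rc)
  # reference: antisense frame translation of the sister's middle exon
  sp1_rc_pep <- translate_nt(revcomp(fv$tips[[cfg$species[2]]][ic]))
  cand_core <- NULL
  for (r in seq_len(60L)) {
    sc <- sw_score(translate_nt(core), sp1_rc_pep)
    if (sc <= 80 && sc >= 62) { cand_core <- core; break }
    if (sc < 62) { core <- repair_orf_interior(rc) } else {
      core <- diverge_inframe(core, 0.03, cfg)
    }
  }
  assert_that(!is.null(cand_core), "strand-switch plant: window not met")
  cand_cds <- paste0("ATG", cand_core, sample(STOP_CODONS, 1L))  # 87 nt
  template <- plant_template(cfg, c(45L, 42L))
  pieces <- root_pieces(template, cfg, orf = cand_cds)
  gid <- paste0(id, "_", cfg$focal)
  per_species <- stats::setNames(
    list(build_gene_region(pieces, template, "+", gid)), cfg$focal)
  truth <- truth_row(gid, cfg$focal, "SSOG", phylostratum = 0L,
                     mechanism = "strand-switch", expected_trace = "partial",
                     expected_structure = "fully-confirmed", birth_node = 0L,
                     source_genes = fv$id)
  loc <- new_locus(id, "mech_strand", 0L, per_species, truth)
  loc$plant <- list(mechanism = "strand-switch", gene_id = gid,
                    source = fv$id)
  loc
}

# --- overprinting ----------------------------------------------------------
# Root ORF for the dual-frame source family: both frame 0 and frame +1 are
# open across the coding region; frame +1 terminates at a planted TAA inside
# codons 76/77 so the duplicate's alternative CDS (transcript offset +1,
# 76 codons) is a complete ORF.
make_dual_frame_orf <- function(cfg, n_codons = 78L) {
  for (r in seq_len(200L)) {
    orf <- rand_orf(n_codons, cfg)
    cods <- codons_of(orf)
    cods[76] <- "CTA"
    cods[77] <- sample(SENSE_CODONS[startsWith(SENSE_CODONS, "A")], 1L)
    orf <- paste(cods, collapse = "")
    # clear frame+1 stops ahead of the planted terminator (frame1 codon j
    # occupies nt 3j-1 .. 3j+1)
    ok <- TRUE
    for (i in seq_len(300L)) {
      st <- frame_stops(substr(orf, 2L, 226L), 0L)
      if (length(st) == 0) break
      s <- 3L * st[1] - 1L
      cand_cod <- c((s - 1L) %/% 3L + 1L, (s + 1L) %/% 3L + 1L)
      cand_cod <- cand_cod[cand_cod > 1L & cand_cod < 76L]
      if (length(cand_cod) == 0) { ok <- FALSE; break }
      cods <- codons_of(orf)
      cods[cand_cod[1]] <- sample(SENSE_CODONS, 1L)
      orf <- paste(cods, collapse = "")
    }
    if (!ok || length(frame_stops(substr(orf, 2L, 226L), 0L)) > 0) next
    f1 <- translate_nt(substr(orf, 2L, 229L))
    if (!grepl("*", substr(f1, 1L, 75L), fixed = TRUE) &&
        substr(f1, 76L, 76L) == "*")
      return(orf)
  }
  stop("dual-frame ORF construction failed", call. = FALSE)
}

make_overprint_locus <- function(id, cfg, fp) {
  foc <- fp$tips[[cfg$focal]]
  template <- fp$template
  # duplicate the focal copy, diverge ~8% nt keeping both frames open
  for (r in seq_len(40L)) {
    dup <- evolve_pieces(foc, template, 0.08, cfg, protect_frames = c(0L, 1L))
    ic <- which(template$kind == "cds")
    cds <- paste(dup[ic], collapse = "")
    cods <- codons_of(cds)
    cods[76] <- "CTA"
    cods[77] <- paste0("A", substr(cods[77], 2L, 3L))
    if (cods[77] %in% STOP_CODONS) cods[77] <- "ACT"
    cds <- paste(cods, collapse = "")
    f1 <- translate_nt(substr(cds, 2L, 229L))
    if (grepl("*", substr(f1, 1L, 75L), fixed = TRUE)) next
    off <- 0L
    for (i in ic) { dup[i] <- substr(cds, off + 1L, off + nchar(dup[i]))
                    off <- off + nchar(dup[i]) }
    # the alternative CDS spans coding positions [1, 229) (0-based): map
    # them into transcript coordinates across the interleaved introns
    lens <- nchar(dup)
    piece_off <- cumsum(c(0L, lens[-length(lens)]))
    coding_to_tx <- function(c0) {
      acc <- 0L
      for (i in ic) {
        w <- lens[i]
        if (c0 < acc + w) return(piece_off[i] + (c0 - acc))
        acc <- acc + w
      }
      piece_off[max(ic)] + lens[max(ic)]
    }
    gid <- paste0(id, "_", cfg$focal)
    region <- build_gene_region(dup, template, "+", gid,
                                cds_tx = c(coding_to_tx(1L),
                                           coding_to_tx(228L) + 1L))
    per_species <- stats::setNames(list(region), cfg$focal)
    truth <- truth_row(gid, cfg$focal, "SSOG", phylostratum = 0L,
                       mechanism = "overprint",
                       expected_trace = "all-three",
                       expected_structure = "fully-confirmed",
                       birth_node = 0L, source_genes = fp$id)
    loc <- new_locus(id, "mech_overprint", 0L, per_species, truth)
    loc$plant <- list(mechanism = "overprint", gene_id = gid,
                      paralog = paste0(fp$id, "_", cfg$focal),
                      frame_offset = 1L)
    return(loc)
  }
  stop("overprint plant: dual-frame duplicate construction failed",
       call. = FALSE)
}

# --- heuristic failure -----------------------------------------------------
# Repeat-rich pair (focal gene + sister-species gene in the same syntenic
# slot) sharing a short unique core tuned into SW window [45, 57]: the
# synteny-restricted translated search finds it, the genome-wide cascade and
# trace searches do not.
rep_codons <- function(n) {
  aa2cod <- list(G = c("GGA", "GGC", "GGT", "GGG"),
                 A = c("GCA", "GCC", "GCT"), S = c("AGC", "TCA", "TCT"),
                 N = c("AAC", "AAT"), P = c("CCA", "CCT"))
  res <- character(n)
  for (i in seq_len(n)) {
    aa <- if (stats::runif(1) < 0.5) "G" else sample(c("A", "S", "N", "P"), 1L)
    res[i] <- sample(aa2cod[[aa]], 1L)
  }
  paste(res, collapse = "")
}

make_heurfail_locus <- function(id, cfg) {
  gid_f <- paste0(id, "_", cfg$focal)
  gid_s <- paste0(id, "_", cfg$species[2])
  # a UTR exon plus one coding exon keeps the whole reading frame in a
  # single genomic frame (the in-interval translated DP must recover the
  # homology in one pass) while the spliced junction still supports full
  # structure confirmation
  heur_tpl <- function(cds_len) {
    list(kind = c("utr", "intron", "utr", "cds", "utr"),
         len = c(45L, 47L, 10L, cds_len, 45L),
         exon = c(1L, NA, 2L, 2L, 2L))
  }
  for (r in seq_len(80L)) {
    core <- paste(sample(SENSE_CODONS, 15L, TRUE), collapse = "")
    r_cds <- paste0("ATG", rep_codons(6L), core, rep_codons(7L),
                    sample(STOP_CODONS, 1L))               # 90 nt
    # sister core: resample 1st+2nd codon positions at ~55% of codons
    cods <- codons_of(core)
    nswap <- 8L
    idx <- sample(seq_along(cods), nswap)
    cods[idx] <- vapply(cods[idx], function(cd) {
      repeat {
        nc <- paste0(sample(BASES, 1L), sample(BASES, 1L), substr(cd, 3L, 3L))
        if (!(nc %in% STOP_CODONS)) return(nc)
      }
    }, character(1))
    core_s <- paste(cods, collapse = "")
    s_cds <- paste0("ATG", rep_codons(7L), core_s, rep_codons(7L),
                    sample(STOP_CODONS, 1L))               # 93 nt
    pep_f <- sub("\\*$", "", translate_nt(r_cds))
    pep_s <- sub("\\*$", "", translate_nt(s_cds))
    sc <- sw_score(pep_f, pep_s)
    if (sc < 45 || sc > 57) next
    tpl_f <- heur_tpl(90L)
    tpl_s <- heur_tpl(93L)
    pieces_f <- root_pieces(tpl_f, cfg, orf = r_cds)
    # sister shares UTRs and intron (diverged) for nucleotide traceability
    pieces_s <- pieces_f
    pieces_s[c(1, 3, 5)] <- vapply(pieces_f[c(1, 3, 5)], mutate_nt, "",
                                   d = 0.08, cfg = cfg)
    pieces_s[2] <- impose_splice_motifs(mutate_nt(pieces_f[2], 0.08, cfg))
    pieces_s[4] <- s_cds
    per_species <- list()
    per_species[[cfg$focal]] <- build_gene_region(pieces_f, tpl_f, "+", gid_f)
    per_species[[cfg$species[2]]] <-
      build_gene_region(pieces_s, tpl_s, "+", gid_s)
    truth <- dplyr::bind_rows(
      truth_row(gid_f, cfg$focal, "SSOG", phylostratum = 0L,
                mechanism = "heuristic-failure", expected_trace = "partial",
                expected_structure = "fully-confirmed", birth_node = 1L,
                final_class = "TROG", source_genes = gid_s),
      truth_row(gid_s, cfg$species[2], "SSOG"))
    loc <- new_locus(id, "mech_heurfail", 1L, per_species, truth)
    loc$plant <- list(mechanism = "heuristic-failure", gene_id = gid_f,
                      partner = gid_s, pair_score = sc)
    return(loc)
  }
  stop("heuristic-failure plant: score window not met", call. = FALSE)
}

# --- de novo (intronic) ----------------------------------------------------
# Candidate gene on the minus strand inside intron 2 of a conserved host.
# Sisters sp1/sp2 carry the intact (unannotated, untranscribed) ORF; sp3 has
# two stops mid second exon; sp4 has stops at codons 11 and 14; more distant
# species carry unrelated intron sequence.
make_dni_host_locus <- function(id, cfg) {
  template <- std_template(cfg, introns = c(47L, 480L))
  make_conserved_locus(id, cfg, step = 1L, strand = "+",
                       template = template)
}

plant_dni <- function(host, id, cfg) {
  cand_tpl <- list(kind = c("utr", "cds", "intron", "cds", "utr"),
                   len = c(30L, 75L, 47L, 78L, 30L),
                   exon = c(1L, 1L, NA, 2L, 2L))
  anc <- root_pieces(cand_tpl, cfg)
  tips <- evolve_along_ladder(anc, 2L, cand_tpl, cfg)  # focal, sp1, sp2
  disrupted <- list()
  for (k in c(3L, 4L)) {
    pieces <- anc
    for (step in seq_len(k)) pieces <- evolve_pieces(pieces, cand_tpl, 0.04,
                                                     cfg, protect_frames = 0L)
    ic <- which(cand_tpl$kind == "cds")
    cds <- paste(pieces[ic], collapse = "")
    cods <- codons_of(cds)
    stop_at <- if (k == 3L) c(33L, 36L) else c(11L, 14L)
    cods[stop_at] <- sample(STOP_CODONS, length(stop_at), TRUE)
    cds <- paste(cods, collapse = "")
    off <- 0L
    for (i in ic) { pieces[i] <- substr(cds, off + 1L, off + cand_tpl$len[i])
                    off <- off + cand_tpl$len[i] }
    disrupted[[cfg$species[k + 1L]]] <-
      list(pieces = pieces, stops = stop_at)
  }
  cand_gid <- paste0(id, "_", cfg$focal)
  cand_region <- build_gene_region(tips[[cfg$focal]], cand_tpl, "-", cand_gid)

  m1 <- rand_dna(110L, cfg); m2 <- rand_dna(110L, cfg)
  intron_idx <- 5L  # intron2 piece of the host template
  embed <- function(content)

    impose_splice_motifs(paste0(m1, content, m2))
  for (sp in cfg$species) {
    pieces <- host$tips[[sp]]
    content <- if (sp == cfg$focal) {
      cand_region$seq
    } else if (sp %in% names(tips)) {
      rg <- build_gene_region(tips[[sp]], cand_tpl, "-",
                              paste0(id, "_", sp), annotate = FALSE)
      rg$seq
    } else if (sp %in% names(disrupted)) {
      rg <- build_gene_region(disrupted[[sp]]$pieces, cand_tpl, "-",
                              paste0(id, "_", sp), annotate = FALSE)
      rg$seq
    } else {
      rand_dna(260L, cfg)
    }
    pieces[intron_idx] <- embed(content)
    region <- build_gene_region(pieces, host$template, "+",
                                paste0(host$id, "_", sp))
    if (sp == cfg$focal) {
      off <- sum(nchar(pieces[seq_len(intron_idx - 1L)])) + 110L
      for (g in cand_region$genes) {
        g$exons$start <- g$exons$start + off; g$exons$end <- g$exons$end + off
        g$cds$start <- g$cds$start + off; g$cds$end <- g$cds$end + off
        region$genes[[length(region$genes) + 1L]] <- g
      }
    }
    host$per_species[[sp]] <- region
  }
  host$truth <- dplyr::bind_rows(
    host$truth,
    truth_row(cand_gid, cfg$focal, "SSOG", phylostratum = 0L,
              mechanism = "de-novo", expected_trace = "partial",
              expected_structure = "fully-confirmed", birth_node = 2L,
              source_genes = NA_character_))
  host$plant <- list(mechanism = "de-novo", subtype = "intronic",
                     gene_id = cand_gid, host = host$id, intron_index = 2L,
                     birth_node = 2L,
                     stops = list(sp3 = c(33L, 36L), sp4 = c(11L, 14L)),
                     intact = cfg$species[2:3])
  host
}

# --- de novo (intergenic) --------------------------------------------------
# Two-exon gene with the entire CDS in exon 2; the sister species carries a
# non-transcribed intergenic copy with a stop at codon 4.
make_dgi_locus <- function(id, cfg) {
  template <- list(kind = c("utr", "intron", "utr", "cds", "utr"),
                   len = c(45L, 53L, 10L, 93L, 40L),
                   exon = c(1L, NA, 2L, 2L, 2L))
  pieces <- root_pieces(template, cfg)
  gid <- paste0(id, "_", cfg$focal)
  cand_region <- build_gene_region(pieces, template, "+", gid)

  sis <- vapply(pieces, mutate_nt, "", d = 0.05, cfg = cfg)
  sis[2] <- impose_splice_motifs(sis[2])
  ic <- which(template$kind == "cds")
  cds <- repair_orf_interior(sis[ic])
  cods <- codons_of(cds)
  cods[4] <- "TGA"
  sis[ic] <- paste(cods, collapse = "")
  sis_region <- build_bare_region(paste(sis, collapse = ""))

  per_species <- list()
  per_species[[cfg$focal]] <- cand_region
  per_species[[cfg$species[2]]] <- sis_region
  truth <- truth_row(gid, cfg$focal, "SSOG", phylostratum = 0L,
                     mechanism = "de-novo", expected_trace = "partial",
                     expected_structure = "fully-confirmed", birth_node = 0L)
  loc <- new_locus(id, "mech_dgi", 0L, per_species, truth)
  loc$plant <- list(mechanism = "de-novo", subtype = "intergenic",
                    gene_id = gid, birth_node = 0L,
                    stops = list(sp1 = 4L), intact = character(0))
  loc
}

# --- assembly-gap trace exemplar -------------------------------------------
# Focal orphan whose homolog appears only in the sister's transcriptome
# assembly (region deleted from the sister genome, gene never annotated).
make_gap_locus <- function(id, cfg) {
  loc <- make_ssog_locus(id, cfg$focal, cfg,
                         expected_trace = "assembly-gap-candidate")
  reg <- loc$per_species[[cfg$focal]]
  genome <- Biostrings::DNAStringSet(c(chr = reg$seq))
  g <- reg$genes[[1]]
  row <- new_tbl(gene_id = g$gene_id, species = cfg$focal, contig = "chr",
                 strand = g$strand, exons = list(g$exons), cds = list(g$cds),
                 pseudo = FALSE)
  tx <- gene_transcript_seq(row[1, ], genome)
  ghost <- mutate_nt(tx, 0.05, cfg)
  loc$extra_transcriptome <- stats::setNames(
    list(stats::setNames(ghost, paste0(id, "_asm"))), cfg$species[2])
  loc$plant <- list(mechanism = "none", gene_id = g$gene_id,
                    note = "assembly-gap")
  loc
}
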