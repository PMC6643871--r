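#' Three-step conserved/orphan classification cascade
#'
#' Step 1: protein query vs the outgroup protein database (E <= `e_step1`).
#' Step 2, for the remainder: translated search vs the outgroup genomes
#' (E <= `e_step2`). Step 3, for the remainder: protein query vs the curated
#' (UniProt-like) database (E <= `e_step3`); genes conserved only at step 3
#' are flagged horizontal-transfer candidates. Steps run strictly in order; a
#' gene is tested at step k+1 only if it failed step k. Genes passing no step
#' are orphans. All thresholds are inclusive.
#'
#' A *missing* database argument is an error; an *empty* database is a valid
#' "no hits" database.
#'
#' @param genes gene-model tibble (any number of species).
#' @param proteins named list (species -> `AAStringSet` keyed by gene id).
#' @param outgroup_proteins `AAStringSet` of outgroup proteins.
#' @param outgroup_genomes `DNAStringSet` of outgroup genome contigs.
#' @param uniprot_db `AAStringSet` standing in for the curated knowledgebase.
#' @param e_step1,e_step2,e_step3 inclusive step thresholds.
#' @return Tibble: `gene_id`, `species`, `conserved`, `conserved_step`
#'   (1/2/3 or NA), `hgt_candidate`, `best_hit_evidence`.
#' @export
classify_conserved <- function(genes, proteins, outgroup_proteins,
                               outgroup_genomes, uniprot_db,
                               e_step1 = 1e-3, e_step2 = 1e-5,
                               e_step3 = 1e-3) {
  for (arg in c("outgroup_proteins", "outgroup_genomes", "uniprot_db"))
    if (eval(call("missing", as.name(arg))))
      stop("database argument '", arg, "' is missing (pass an empty ",
           "database for 'no hits')", call. = FALSE)
  out <- list()
  for (sp in unique(genes$species)) {
    ids <- genes$gene_id[genes$species == sp]
    prot <- proteins[[sp]][ids]
    step <- rep(NA_integer_, length(ids))
    evidence <- rep(NA_character_, length(ids))
    note_hits <- function(h, ids_subset, k) {
      best <- h[!duplicated(h$query_id), ]
      i <- match(best$query_id, ids)
      step[i] <<- k
      evidence[i] <<- sprintf("%s:%s:E=%.3g", best$subject_db_kind,
                              best$subject_id, best$e_value)
    }
    h1 <- search_homology(prot, outgroup_proteins,
                          search_params("pp", e_max = e_step1),
                          db_kind = "outgroup-proteins")
    if (nrow(h1)) note_hits(h1, ids, 1L)
    rem <- ids[is.na(step)]
    if (length(rem) > 0 && length(outgroup_genomes) > 0) {
      h2 <- search_homology(prot[rem], outgroup_genomes,
                            search_params("px", e_max = e_step2),
                            db_kind = "outgroup-genome")
      if (nrow(h2)) note_hits(h2, rem, 2L)
    }
    rem <- ids[is.na(step)]
    if (length(rem) > 0 && length(uniprot_db) > 0) {
      h3 <- search_homology(prot[rem], uniprot_db,
                            search_params("pp", e_max = e_step3),
                            db_kind = "curated-proteins")
      if (nrow(h3)) note_hits(h3, rem, 3L)
    }
    out[[sp]] <- new_tbl(gene_id = ids, species = sp,
                         conserved = !is.na(step), conserved_step = step,
                         hgt_candidate = !is.na(step) & step == 3L,
                         best_hit_evidence = evidence)
  }
  dplyr::bind_rows(out)[match(genes$gene_id,
                              dplyr::bind_rows(out)$gene_id), ]
}

#' Split orphans into taxon-restricted (TROG) and species-specific (SSOG)
#'
#' Protein-only homology, deliberately: no translated search against
#' genomes, so pseudogenes and non-coding regions cannot count as protein
#' homologs. An orphan is a TROG iff it has at least one protein hit
#' (E <= `e_ingroup`) in at least one *other* ingroup species; self and
#' within-species paralog hits never count.
#'
#' @param orphans tibble with `gene_id`, `species` (orphans from
#'   [classify_conserved()]).
#' @param proteins named list (species -> `AAStringSet` keyed by gene id).
#' @param e_ingroup inclusive E-value threshold.
#' @return Tibble: `gene_id`, `species`, `class` (TROG/SSOG), `hit_species`
#'   (list-column of species with qualifying hits), `best_hit_evidence`.
#' @export
split_trog_ssog <- function(orphans, proteins, e_ingroup = 1e-3) {
  species <- names(proteins)
  out <- list()
  for (sp in unique(orphans$species)) {
    ids <- orphans$gene_id[orphans$species == sp]
    missing_ids <- setdiff(ids, names(proteins[[sp]]))
    if (length(missing_ids) > 0)
      stop("gene(s) absent from the protein database of species ", sp, ": ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    prot <- proteins[[sp]][ids]
    hit_sp <- stats::setNames(vector("list", length(ids)), ids)
    best <- stats::setNames(rep(NA_character_, length(ids)), ids)
    for (other in setdiff(species, sp)) {
      if (length(proteins[[other]]) == 0) next
      h <- search_homology(prot, proteins[[other]],
                           search_params("pp", e_max = e_ingroup),
                           db_kind = "proteins")
      if (nrow(h) == 0) next
      for (q in unique(h$query_id)) {
        hit_sp[[q]] <- c(hit_sp[[q]], other)
        hq <- h[h$query_id == q, ][1, ]
        prev <- best[[q]]
        if (is.na(prev) ||
            hq$e_value < as.numeric(sub(".*E=", "", prev)))
          best[[q]] <- sprintf("%s:%s:E=%.3g", other, hq$subject_id,
                               hq$e_value)
      }
    }
    out[[sp]] <- new_tbl(
      gene_id = ids, species = sp,
      class = unname(ifelse(lengths(hit_sp) > 0, "TROG", "SSOG")),
      hit_species = unname(hit_sp),
      best_hit_evidence = unname(best))
  }
  res <- dplyr::bind_rows(out)
  res[match(orphans$gene_id, res$gene_id), ]
}

#' Assign phylostrata to focal-species genes
#'
#' The phylostratum of an orphan is the ladder index of the most distant
#' ingroup species carrying a qualifying protein homolog (the most recent
#' common ancestor of the focal species and that species); SSOGs form
#' phylostratum 0. Conserved genes are placed in the oldest stratum, beyond
#' the ingroup (`n_species`), and are excluded from the orphan strata counts.
#'
#' @param focal_assignments tibble for focal genes with `gene_id`, `species`,
#'   `class` and `hit_species` (list-column; as from [split_trog_ssog()],
#'   conserved rows may omit it).
#' @param tree a `species_tree` (see [read_species_tree()]).
#' @return The input with a `phylostratum` integer column.
#' @export
assign_phylostrata <- function(focal_assignments, tree) {
  if (any(focal_assignments$species != tree$focal))
    stop("assign_phylostrata() only applies to genes of the focal species (",
         tree$focal, ")", call. = FALSE)
  li <- ladder_index(tree)
  idx <- stats::setNames(li$ladder_index, li$species)
  n_sp <- length(tree$phy$tip.label)
  ps <- integer(nrow(focal_assignments))
  for (i in seq_len(nrow(focal_assignments))) {
    cls <- focal_assignments$class[i]
    if (cls == "Conserved") {
      ps[i] <- n_sp
    } else if (cls == "SSOG") {
      ps[i] <- 0L
    } else {
      hs <- focal_assignments$hit_species[[i]]
      assert_that(length(hs) > 0, "TROG without ingroup hit species")
      ps[i] <- max(idx[hs])
    }
  }
  focal_assignments$phylostratum <- ps
  focal_assignments
}

#' Full classification of a simulated or loaded dataset
#'
#' Runs the conserved cascade over all species, the TROG/SSOG split over the
#' orphans, and phylostratum assignment for the focal species; asserts the
#' partition invariant (Conserved + TROG + SSOG = all genes, per species).
#'
#' @param ds an `orphan_dataset` (from [simulate_dataset()] or
#'   [read_dataset()]).
#' @param e_step1,e_step2,e_step3,e_ingroup cascade thresholds.
#' @return Tibble: `gene_id`, `species`, `class`, `conserved_step`,
#'   `hgt_candidate`, `phylostratum` (NA for non-focal genes),
#'   `hit_species` (list), `best_hit_evidence`.
#' @export
classify_genes <- function(ds, e_step1 = 1e-3, e_step2 = 1e-5,
                           e_step3 = 1e-3, e_ingroup = 1e-3) {
  cons <- classify_conserved(ds$genes, ds$proteins,
                             outgroup_proteins = ds$outgroup$proteins,
                             outgroup_genomes = ds$outgroup$genomes,
                             uniprot_db = ds$outgroup$uniprot,
                             e_step1 = e_step1, e_step2 = e_step2,
                             e_step3 = e_step3)
  orphans <- cons[!cons$conserved, c("gene_id", "species")]
  split <- split_trog_ssog(orphans, ds$proteins, e_ingroup = e_ingroup)
  res <- cons
  res$class <- ifelse(cons$conserved, "Conserved",
                      split$class[match(cons$gene_id, split$gene_id)])
  res$hit_species <- split$hit_species[match(cons$gene_id, split$gene_id)]
  oe <- split$best_hit_evidence[match(cons$gene_id, split$gene_id)]
  res$best_hit_evidence <- ifelse(cons$conserved, cons$best_hit_evidence, oe)
  # partition invariant, per species
  tab <- table(res$species, res$class)
  assert_that(all(rowSums(tab) == table(res$species)[rownames(tab)]),
              "classification partition violated")
  foc <- res[res$species == ds$focal, ]
  foc <- assign_phylostrata(foc, ds$tree)
  res$phylostratum <- NA_integer_
  res$phylostratum[match(foc$gene_id, res$gene_id)] <- foc$phylostratum
  res[, c("gene_id", "species", "class", "conserved_step", "hgt_candidate",
          "phylostratum", "hit_species", "best_hit_evidence")]
}
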