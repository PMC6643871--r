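# Shared fixtures. The simulated reference dataset (and everything derived
# from it) is generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

test_dataset <- function() {
  if (is.null(.fixture_cache$ds))
    .fixture_cache$ds <- simulate_dataset(sim_config(), seed = 1L)
  .fixture_cache$ds
}

test_classification <- function() {
  if (is.null(.fixture_cache$cls))
    .fixture_cache$cls <- classify_genes(test_dataset())
  .fixture_cache$cls
}

test_ssog_ids <- function() {
  cls <- test_classification()
  ds <- test_dataset()
  sort(cls$gene_id[cls$species == ds$focal & cls$class == "SSOG"])
}

test_traces <- function() {
  if (is.null(.fixture_cache$traces))
    .fixture_cache$traces <- trace_homology(test_ssog_ids(), test_dataset())
  .fixture_cache$traces
}

test_statuses <- function() {
  if (is.null(.fixture_cache$statuses)) {
    ds <- test_dataset()
    rows <- ds$genes[match(test_ssog_ids(), ds$genes$gene_id), ]
    .fixture_cache$statuses <- validate_structures(rows, ds$reads)
  }
  .fixture_cache$statuses
}

test_mechanisms <- function() {
  if (is.null(.fixture_cache$mech)) {
    ds <- test_dataset()
    hc <- high_confidence_set(test_ssog_ids(), test_traces(),
                              test_statuses())
    .fixture_cache$mech <- call_mechanisms(ds, hc, test_classification(),
                                           statuses = test_statuses())
  }
  .fixture_cache$mech
}

# Minimal hand-built dataset for detector unit tests: one focal species and
# one sister, genomes given as plain strings, genes as gene-model rows.
make_mini_ds <- function(genomes, genes, focal = "spA",
                         transcriptome = NULL, reads = NULL) {
  species <- names(genomes)
  gsets <- lapply(genomes, function(s) Biostrings::DNAStringSet(c(chr = s)))
  proteins <- lapply(species, function(sp) {
    g <- genes[genes$species == sp, ]
    if (nrow(g) == 0) return(Biostrings::AAStringSet())
    extract_proteins(g, gsets[[sp]])
  })
  transcripts <- lapply(species, function(sp) {
    g <- genes[genes$species == sp, ]
    if (nrow(g) == 0) return(Biostrings::DNAStringSet())
    extract_transcripts(g, gsets[[sp]])
  })
  names(proteins) <- names(transcripts) <- species
  nwk <- make_ladder_newick_for_test(species)
  ds <- list(
    tree = read_species_tree(nwk, focal),
    species = species, focal = focal,
    genomes = gsets, genes = genes, proteins = proteins,
    transcripts = transcripts,
    transcriptome = transcriptome %||% transcripts,
    outgroup = list(proteins = Biostrings::AAStringSet(),
                    genomes = Biostrings::DNAStringSet(),
                    uniprot = Biostrings::AAStringSet()),
    reads = reads %||% tibble::tibble(read_id = character(),
                                      contig = character(),
                                      strand = character(),
                                      blocks = list(),
                                      is_spliced = logical()),
    truth = NULL, plants = NULL, orth = NULL,
    config = sim_config(), seed = 0L)
  class(ds) <- "orphan_dataset"
  ds
}

make_ladder_newick_for_test <- function(species, b = 0.05) {
  s <- paste0(species[1], ":", b)
  if (length(species) == 1) return(paste0("(", s, ");"))
  for (k in 2:length(species))
    s <- paste0("(", s, ",", species[k], ":", b, "):", b)
  paste0(sub(paste0(":", b, "$"), "", s), ";")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-row gene-model tibble shorthand
mk_gene <- function(gene_id, species, strand, exons, cds, contig = "chr") {
  tibble::tibble(gene_id = gene_id, species = species, contig = contig,
                 strand = strand, exons = list(exons), cds = list(cds),
                 pseudo = FALSE)
}

# spliced reads over a gene's exons for structure tests: n_exonic plain
# reads per exon plus n_junction spliced reads per junction
mk_reads <- function(gene, n_exonic = 3, n_junction = 2, strand = NULL,
                     read_len = NULL) {
  ex <- gene$exons[[1]][order(gene$exons[[1]]$start), , drop = FALSE]
  strand <- strand %||% gene$strand
  out <- list()
  for (j in seq_len(nrow(ex))) {
    for (i in seq_len(n_exonic)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        read_id = sprintf("e%d_%d", j, i), contig = gene$contig,
        strand = strand,
        blocks = list(data.frame(start = ex$start[j], end = ex$end[j])),
        is_spliced = FALSE)
    }
  }
  if (nrow(ex) > 1) {
    for (j in seq_len(nrow(ex) - 1)) {
      for (i in seq_len(n_junction)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          read_id = sprintf("j%d_%d", j, i), contig = gene$contig,
          strand = strand,
          blocks = list(data.frame(
            start = c(max(ex$start[j], ex$end[j] - 30), ex$start[j + 1]),
            end = c(ex$end[j], min(ex$end[j + 1], ex$start[j + 1] + 30)))),
          is_spliced = TRUE)
      }
    }
  }
  dplyr::bind_rows(out)
}

# Reduced end-to-end configuration (all plants retained) plus one pair of
# simulate+run executions under the same seed, shared by the determinism and
# step-isolation checks.
small_config <- function() {
  sim_config(n_conserved = 30, n_trog_per_stratum = 1, n_ssog_focal = 3,
             n_ssog_other = 1)
}

test_small_runs <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- small_config()
    ds_a <- simulate_dataset(cfg, seed = 7L)
    out_a <- file.path(tempdir(), "pl_a")
    res_a <- run_pipeline(ds_a, out_a, seed = 7L)
    ds_b <- simulate_dataset(cfg, seed = 7L)
    out_b <- file.path(tempdir(), "pl_b")
    run_pipeline(ds_b, out_b, seed = 7L)
    .fixture_cache$small <- list(cfg = cfg, ds_a = ds_a, ds_b = ds_b,
                                 out_a = out_a, out_b = out_b,
                                 res_a = res_a)
  }
  .fixture_cache$small
}
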