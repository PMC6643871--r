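# Small constructed databases: a conserved gene with an obvious outgroup
# homolog, a step-2 gene visible only in the outgroup genome, a weak-hit
# orphan, and orphans shared at controlled phylogenetic depths.

mini_classify_fixture <- function() {
  set.seed(41)
  orfA <- rand_orf_fixture(60)   # conserved at step 1
  orfB <- rand_orf_fixture(55)   # conserved at step 2 (genome only)
  orfC <- rand_orf_fixture(50)   # orphan (weak hit only)
  protA <- sub("\\*$", "", translate_oracle(orfA))
  protB <- sub("\\*$", "", translate_oracle(orfB))
  protC <- sub("\\*$", "", translate_oracle(orfC))
  genes <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"), species = "spX", contig = "chr",
    strand = "+", exons = list(data.frame(start = 0, end = 10)),
    cds = list(data.frame(start = 0, end = 9, phase = 0)), pseudo = FALSE)
  proteins <- list(spX = Biostrings::AAStringSet(
    c(gA = protA, gB = protB, gC = protC)))
  # weak homolog of C: E tuned into (1e-3, 1] by truncation/divergence
  weakC <- NULL
  for (i in 1:200) {
    cand <- translate_oracle(mutate_fixture(substr(orfC, 1, 60), 0.35))
    sc <- sw_oracle(protC, cand, phylorphan:::blosum62())
    e <- 0.041 * nchar(protC) * (nchar(cand) + nchar(protA)) *
      exp(-0.267 * sc)
    if (e > 1e-3 && e < 1) { weakC <- cand; break }
  }
  og_prot <- Biostrings::AAStringSet(c(ogA = protA, weakC = weakC))
  og_genome <- Biostrings::DNAStringSet(
    c(og1 = paste0(rand_nt(50), orfB, rand_nt(50))))
  uniprot <- Biostrings::AAStringSet(c(up1 = rand_prot(80)))
  list(genes = genes, proteins = proteins, og_prot = og_prot,
       og_genome = og_genome, uniprot = uniprot)
}

test_that("cascade fires strictly in order with inclusive thresholds", {
  fx <- mini_classify_fixture()
  res <- classify_conserved(fx$genes, fx$proteins, fx$og_prot,
                            fx$og_genome, fx$uniprot)
  expect_identical(res$conserved_step[res$gene_id == "gA"], 1L)
  expect_identical(res$conserved_step[res$gene_id == "gB"], 2L)
  # gC's only hit is weaker than 1e-3: orphan
  expect_false(res$conserved[res$gene_id == "gC"])
  expect_false(any(res$hgt_candidate))

  # step 3 fires for a gene present only in the curated database and flags
  # horizontal transfer
  fx$uniprot <- c(fx$uniprot, fx$proteins$spX["gC"])
  names(fx$uniprot)[length(fx$uniprot)] <- "upC"
  res3 <- classify_conserved(fx$genes, fx$proteins, fx$og_prot,
                             fx$og_genome, fx$uniprot)
  expect_identical(res3$conserved_step[res3$gene_id == "gC"], 3L)
  expect_true(res3$hgt_candidate[res3$gene_id == "gC"])

  # missing database argument is an error; empty database is not
  expect_error(classify_conserved(fx$genes, fx$proteins, fx$og_prot,
                                  fx$og_genome), "missing")
  res_empty <- classify_conserved(fx$genes, fx$proteins,
                                  Biostrings::AAStringSet(),
                                  Biostrings::DNAStringSet(),
                                  Biostrings::AAStringSet())
  expect_false(any(res_empty$conserved))
})

test_that("orphan split uses protein homology only", {
  set.seed(42)
  orf <- rand_orf_fixture(60)
  prot <- sub("\\*$", "", translate_oracle(orf))
  orphans <- tibble::tibble(gene_id = c("o1", "o2"), species = "spX")
  proteins <- list(
    spX = Biostrings::AAStringSet(c(o1 = prot, o2 = rand_prot(60))),
    spY = Biostrings::AAStringSet(c(y1 = prot)))
  res <- split_trog_ssog(orphans, proteins)
  expect_identical(res$class[res$gene_id == "o1"], "TROG")
  expect_identical(res$hit_species[[which(res$gene_id == "o1")]], "spY")
  expect_identical(res$class[res$gene_id == "o2"], "SSOG")

  # no other species at all: everything is species-specific
  res2 <- split_trog_ssog(orphans, proteins["spX"])
  expect_identical(unique(res2$class), "SSOG")

  # a genomic trace without an annotated protein cannot rescue an orphan:
  # the split step consults protein databases only, so o2 stays an SSOG
  # even though spY's genome would carry its CDS
  expect_identical(res$class[res$gene_id == "o2"], "SSOG")

  expect_error(split_trog_ssog(tibble::tibble(gene_id = "zz",
                                              species = "spX"), proteins),
               "absent")
})

test_that("phylostrata follow the deepest qualifying hit", {
  nwk <- make_ladder_newick_for_test(paste0("sp", 0:9))
  tree <- read_species_tree(nwk, "sp0")
  asg <- tibble::tibble(
    gene_id = c("t1", "t2", "s1", "c1"),
    species = "sp0",
    class = c("TROG", "TROG", "SSOG", "Conserved"),
    hit_species = list(c("sp1", "sp2"), "sp9", character(0), NULL))
  out <- assign_phylostrata(asg, tree)
  expect_identical(out$phylostratum,
                   c(2L, 9L, 0L, 10L))

  # monotonicity: adding a deeper hit never lowers the stratum
  asg2 <- asg
  asg2$hit_species[[1]] <- c("sp1", "sp2", "sp5")
  out2 <- assign_phylostrata(asg2, tree)
  expect_gte(out2$phylostratum[1], out$phylostratum[1])

  expect_error(assign_phylostrata(
    tibble::tibble(gene_id = "x", species = "sp3", class = "SSOG",
                   hit_species = list(character(0))), tree), "focal")
})

test_that("classification is invariant to gene input order", {
  fx <- mini_classify_fixture()
  res1 <- classify_conserved(fx$genes, fx$proteins, fx$og_prot,
                             fx$og_genome, fx$uniprot)
  perm <- c(3, 1, 2)
  res2 <- classify_conserved(fx$genes[perm, ], fx$proteins, fx$og_prot,
                             fx$og_genome, fx$uniprot)
  res2 <- res2[match(res1$gene_id, res2$gene_id), ]
  expect_identical(res1$conserved_step, res2$conserved_step)
  expect_identical(res1$conserved, res2$conserved)
})
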