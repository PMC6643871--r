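# Properties of the reference simulated dataset (shared fixture, seed 1).

test_that("tiled reads reach the configured depth over focal coding bases", {
  ds <- test_dataset()
  cfg <- ds$config
  foc <- ds$genes[ds$genes$species == ds$focal, ]
  # the exemplar without reads and the single-junction exemplar are planted
  # exceptions to uniform coverage
  skip_ids <- paste0(c("ssogf4_", "ssogf5_"), ds$focal)
  set.seed(104)
  probe <- foc[sample(which(!foc$gene_id %in% skip_ids), 6), ]
  for (i in seq_len(nrow(probe))) {
    cd <- probe$cds[[i]]
    positions <- unlist(lapply(seq_len(nrow(cd)), function(j)
      seq(cd$start[j], cd$end[j] - 1L, by = 7L)))
    cov <- pileup_oracle(ds$reads, probe$contig[i], positions)
    expect_true(all(cov >= cfg$depth), info = probe$gene_id[i])
  }
})

test_that("protein identity of conserved families decays along the ladder", {
  ds <- test_dataset()
  cls <- test_classification()
  cons <- cls$gene_id[cls$species == ds$focal & cls$class == "Conserved"]
  fams <- sub("_sp0$", "", cons)
  fams <- fams[fams %in% sub("_sp1$", "",
                             ds$genes$gene_id[ds$genes$species == "sp1"])]
  expect_gte(length(fams), 50L)
  B <- phylorphan:::blosum62()
  mean_id <- vapply(ds$species[-1], function(sp) {
    ids <- paste0(fams, "_", sp)
    present <- ids %in% names(ds$proteins[[sp]])
    mean(vapply(fams[present], function(f) {
      pa <- Biostrings::pairwiseAlignment(
        ds$proteins[[ds$focal]][[paste0(f, "_", ds$focal)]],
        ds$proteins[[sp]][[paste0(f, "_", sp)]],
        substitutionMatrix = B, gapOpening = 11, gapExtension = 1,
        type = "global")
      Biostrings::pid(pa)
    }, numeric(1)))
  }, numeric(1))
  # mean identity decreases monotonically with path length on the ladder
  expect_true(all(diff(mean_id) < 0))
  expect_gt(mean_id[1], mean_id[length(mean_id)] + 5)
})

test_that("planted orphans have no coding trace beyond their birth node", {
  ds <- test_dataset()
  # a taxon-restricted family born at node k exists in sp0..spk only
  trog_truth <- ds$truth[grepl("^trog", ds$truth$gene_id), ]
  for (fam in unique(sub("_sp\\d+$", "", trog_truth$gene_id))) {
    birth <- as.integer(sub("trog(\\d+)_.*", "\\1", fam))
    carriers <- unique(trog_truth$species[startsWith(trog_truth$gene_id,
                                                     paste0(fam, "_"))])
    expect_setequal(carriers, ds$config$species[seq_len(birth + 1L)])
  }
})

test_that("the class composition matches the planted design", {
  ds <- test_dataset()
  tab <- table(ds$truth$class[ds$truth$species == ds$focal])
  cfg <- ds$config
  # conserved: families minus the split ancestor, plus the split neighbor
  expect_equal(as.integer(tab["Conserved"]), cfg$n_conserved)
  expect_equal(as.integer(tab["TROG"]),
               cfg$n_trog_per_stratum * (cfg$n_species - 1L))
  # orphans make up roughly a third of the focal gene set
  frac_orphan <- 1 - tab[["Conserved"]] / sum(tab)
  expect_gt(frac_orphan, 0.25)
  expect_lt(frac_orphan, 0.40)
})
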