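# Structure validation boundary behavior on a constructed 2-exon gene, and
# the trace categories on hand-built mini datasets.

two_exon_gene <- function() {
  mk_gene("g2x", "spA", "+",
          exons = data.frame(start = c(100, 300), end = c(190, 380)),
          cds = data.frame(start = c(120, 300), end = c(190, 360),
                           phase = c(0, 0)), contig = "chr1")
}

test_that("read-support thresholds drive the confirmation status", {
  g <- two_exon_gene()
  full <- mk_reads(g, n_exonic = 3, n_junction = 2)
  st <- validate_structure(g[1, ], full)
  expect_identical(st$status, "fully-confirmed")
  expect_true(all(st$exon_support[[1]] >= 2))
  expect_identical(st$junction_support[[1]], 2L)

  one_j <- mk_reads(g, n_exonic = 3, n_junction = 1)
  expect_identical(validate_structure(g[1, ], one_j)$status,
                   "partially-confirmed")

  single <- mk_gene("g1x", "spA", "+",
                    exons = data.frame(start = 100, end = 220),
                    cds = data.frame(start = 110, end = 200, phase = 0),
                    contig = "chr1")
  st1 <- validate_structure(single[1, ], mk_reads(single, n_exonic = 10))
  expect_identical(st1$status, "single-exon-excluded")

  # empty read set: unconfirmed with zeroed counts, not an error
  empty <- full[0, ]
  st0 <- validate_structure(g[1, ], empty)
  expect_identical(st0$status, "unconfirmed")
  expect_identical(sum(st0$exon_support[[1]]), 0L)
})

test_that("support counts equal the brute-force interval-scan oracle", {
  set.seed(51)
  g <- two_exon_gene()
  # a messy read mix: tiled short reads, junction reads, off-target reads
  reads <- dplyr::bind_rows(
    mk_reads(g, n_exonic = 2, n_junction = 3),
    tibble::tibble(
      read_id = sprintf("t%02d", 1:12), contig = "chr1", strand = "+",
      blocks = lapply(seq(60, 390, by = 30), function(s)
        data.frame(start = s, end = s + 40)),
      is_spliced = FALSE),
    tibble::tibble(read_id = "other", contig = "chr9", strand = "+",
                   blocks = list(data.frame(start = 100, end = 190)),
                   is_spliced = FALSE))
  st <- validate_structure(g[1, ], reads)
  oracle <- support_oracle(g[1, ], reads)
  expect_identical(st$exon_support[[1]], oracle$exon)
  expect_identical(st$junction_support[[1]], oracle$junction)
})

test_that("strand-specific disagreement caps confirmation", {
  g <- two_exon_gene()
  good <- mk_reads(g, n_exonic = 3, n_junction = 2)
  wrong <- mk_reads(g, n_exonic = 2, n_junction = 0, strand = "-")
  st <- validate_structure(g[1, ], dplyr::bind_rows(good, wrong),
                           stranded = TRUE)
  expect_false(st$strand_consistent)
  expect_identical(st$status, "partially-confirmed")
  # unstranded protocol: consistency is unknown, status uncapped
  st2 <- validate_structure(g[1, ], dplyr::bind_rows(good, wrong),
                            stranded = FALSE)
  expect_true(is.na(st2$strand_consistent))
  expect_identical(st2$status, "fully-confirmed")
})

test_that("trace categories follow the three-database patterns", {
  set.seed(52)
  orf <- rand_orf_fixture(60)
  focal_gene <- mk_gene("cand_spA", "spA", "+",
                        exons = data.frame(start = c(10, 150),
                                           end = c(100, 320)),
                        cds = data.frame(start = c(20, 150),
                                         end = c(100, 300), phase = c(0, 1)))
  genomeA <- paste0(rand_nt(10), substr(orf, 1, 90), rand_nt(50),
                    substr(orf, 91, nchar(orf)),
                    rand_nt(nchar(orf)))
  # untraceable: sister genome unrelated, no transcripts
  dsU <- make_mini_ds(list(spA = genomeA, spB = rand_nt(4000)),
                      focal_gene)
  dsU$transcripts$spB <- Biostrings::DNAStringSet()
  dsU$transcriptome$spB <- Biostrings::DNAStringSet()
  trU <- trace_homology("cand_spA", dsU)
  expect_identical(trU$summary$category, "untraceable")

  # assembly gap: homolog only in the sister transcriptome assembly
  dsG <- dsU
  tx <- extract_transcripts(focal_gene, dsU$genomes$spA)
  dsG$transcriptome$spB <- Biostrings::DNAStringSet(
    c(ghost = mutate_fixture(as.character(tx[[1]]), 0.05)))
  trG <- trace_homology("cand_spA", dsG)
  expect_identical(trG$summary$category, "assembly-gap-candidate")

  # partial: strong genomic trace only
  dsP <- dsU
  dsP$genomes$spB <- Biostrings::DNAStringSet(
    c(chr = paste0(rand_nt(500), mutate_fixture(genomeA, 0.03),
                   rand_nt(500))))
  trP <- trace_homology("cand_spA", dsP)
  expect_identical(trP$summary$category, "partial")
  expect_true(trP$summary$hit_genome)

  # a species missing a database kind yields unknown cells, never FALSE
  dsN <- dsU
  dsN$transcriptome$spB <- NULL
  trN <- trace_homology("cand_spA", dsN)
  cellsB <- trN$cells[trN$cells$species == "spB", ]
  expect_true(is.na(cellsB$hit[cellsB$db_kind == "transcriptome-assembly"]))
})

test_that("high-confidence set requires traceability and full confirmation", {
  traces <- list(summary = tibble::tibble(
    gene_id = c("a", "b", "c"),
    category = c("partial", "untraceable", "all-three")))
  statuses <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    status = c("fully-confirmed", "fully-confirmed",
               "partially-confirmed"))
  # untraceable-but-confirmed and traceable-but-partial are both excluded
  expect_identical(high_confidence_set(c("a", "b", "c"), traces, statuses),
                   "a")
})
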