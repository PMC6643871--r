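# Detector unit tests on constructed mini datasets; the planted full-dataset
# recovery lives in the acceptance suite.

test_that("frame-shift maps recover planted insertions", {
  set.seed(71)
  anc <- rand_orf_fixture(62)
  anc_cds <- substr(anc, 1, 180)          # 60 codons, stop dropped
  # +1 insertion after codon 20 shifts the remaining 40 codons
  shifted <- paste0(substr(anc_cds, 1, 60), "A", substr(anc_cds, 61, 180))
  prot <- translate_oracle(substr(paste0(shifted, "AA"), 1, 180))
  prot <- gsub("\\*.*", "", prot)  # stop-free prefix of the shifted protein
  fs <- detect_frame_shift(prot, anc_cds)
  expect_identical(fs$status, "ok")
  runs <- rle(fs$frames)
  # the query carries the insertion, so the subject pointer falls one base
  # behind: frame 0 for 20 codons, then the complementary frame
  expect_identical(runs$values[1:2], c(0L, 2L))
  expect_identical(runs$lengths[1], 20L)
  expect_identical(fs$switches$position, 21L)
  expect_identical(fs$switches$indel, 1L)

  # insertion planted in the orthologous region instead: frames 0 then 1
  region_ins <- paste0(substr(anc_cds, 1, 60), "A",
                       substr(anc_cds, 61, 180))
  fs_r <- detect_frame_shift(translate_oracle(anc_cds), region_ins)
  runs_r <- rle(fs_r$frames)
  expect_identical(runs_r$values[1:2], c(0L, 1L))
  expect_identical(fs_r$switches$indel, -1L)

  # no indels: a single frame, zero switches
  fs0 <- detect_frame_shift(translate_oracle(anc_cds), anc_cds)
  expect_identical(unique(fs0$frames), 0L)
  expect_identical(nrow(fs0$switches), 0L)

  # two compensating indels return to frame 0
  comp <- paste0(substr(anc_cds, 1, 45), "G",
                 substr(anc_cds, 46, 105),
                 substr(anc_cds, 107, 180))
  protc <- gsub("\\*.*", "", translate_oracle(substr(comp, 1, 177)))
  fsc <- detect_frame_shift(protc, anc_cds)
  expect_identical(fsc$status, "ok")
  rc <- rle(fsc$frames)
  expect_identical(rc$values, c(0L, 2L, 0L))
  expect_identical(nrow(fsc$switches), 2L)

  expect_identical(detect_frame_shift("MKV", anc_cds)$status,
                   "insufficient")
})

overprint_fixture <- function(same_frame = FALSE, close_frame = FALSE) {
  set.seed(72)
  # coding sequence open in frames 0 and +1
  repeat {
    orf <- rand_orf_fixture(80)
    f1 <- translate_oracle(substr(orf, 2, 235))
    if (!grepl("*", substr(f1, 1, 70), fixed = TRUE)) break
  }
  paralog_gene <- mk_gene("par", "spA", "+",
                          exons = data.frame(start = 20, end = 20 + 240),
                          cds = data.frame(start = 20, end = 260,
                                           phase = 0))
  dup <- mutate_fixture(orf, 0.04)
  # keep both frames open in the duplicate
  for (i in 1:200) {
    f0 <- translate_oracle(dup); f1 <- translate_oracle(substr(dup, 2, 235))
    bad0 <- which(strsplit(substr(f0, 2, 69), "")[[1]] == "*")
    bad1 <- if (close_frame) integer(0) else
      which(strsplit(substr(f1, 1, 69), "")[[1]] == "*")
    if (length(bad0) == 0 && length(bad1) == 0) break
    dup <- orf
    dup <- mutate_fixture(dup, 0.02)
  }
  cds_off <- if (same_frame) 0 else 1
  cand_gene <- mk_gene("cand", "spA", "+",
                       exons = data.frame(start = 500, end = 500 + 240),
                       cds = data.frame(start = 500 + cds_off,
                                        end = 500 + cds_off + 207,
                                        phase = 0))
  genome <- paste0(rand_nt(20), orf, rand_nt(240), dup, rand_nt(100))
  genes <- dplyr::bind_rows(paralog_gene, cand_gene)
  make_mini_ds(list(spA = genome), genes)
}

test_that("overprinting requires a same-strand frame offset", {
  ds <- overprint_fixture()
  gene <- ds$genes[ds$genes$gene_id == "cand", ]
  call <- detect_overprint(gene, ds)
  expect_identical(call$mechanism, "overprint")
  ev <- call$evidence[[1]]
  expect_identical(ev$paralog, "par")
  expect_identical(ev$frame_pair[2], 1L)

  # same-frame duplicate: an ordinary paralog, no call
  ds0 <- overprint_fixture(same_frame = TRUE)
  gene0 <- ds0$genes[ds0$genes$gene_id == "cand", ]
  expect_null(detect_overprint(gene0, ds0))
})

test_that("single-source exon hits are divergence, not chimera", {
  ds <- overprint_fixture(same_frame = TRUE)
  # a two-exon gene whose exons both match the same source is no chimera
  gene <- mk_gene("two", "spA", "+",
                  exons = data.frame(start = c(500, 640),
                                     end = c(590, 740)),
                  cds = data.frame(start = c(501, 640),
                                   end = c(590, 730), phase = c(0, 1)))
  cls <- tibble::tibble(gene_id = c("par", "cand"), species = "spA",
                        class = "Conserved")
  expect_null(detect_chimera(gene, ds, cls))
})

test_that("strand-switch needs an antisense exon overlap", {
  set.seed(73)
  src_orf <- rand_orf_fixture(60)
  sisB <- paste0(rand_nt(300), src_orf, rand_nt(300))
  src_gene <- mk_gene("srcB", "spB", "+",
                      exons = data.frame(start = 300,
                                         end = 300 + nchar(src_orf)),
                      cds = data.frame(start = 300,
                                       end = 300 + nchar(src_orf),
                                       phase = 0))
  # candidate ORF on the reverse strand of the source exon
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(src_orf, 10, 150))))
  rc <- gsub("TAA|TAG|TGA", "CAA", rc)  # crude stop clearing in frame 0
  cand_cds <- paste0("ATG", substr(rc, 1, 3 * (nchar(rc) %/% 3) - 6), "TAA")
  genomeA <- paste0(rand_nt(100), cand_cds, rand_nt(100))
  cand <- mk_gene("cand", "spA", "+",
                  exons = data.frame(start = 100,
                                     end = 100 + nchar(cand_cds)),
                  cds = data.frame(start = 100,
                                   end = 100 + nchar(cand_cds), phase = 0))
  ds <- make_mini_ds(list(spA = genomeA, spB = sisB),
                     dplyr::bind_rows(cand, src_gene))
  call <- detect_strand_switch(cand, ds)
  expect_identical(call$mechanism, "strand-switch")
  ev <- call$evidence[[1]]
  expect_identical(ev$subject_gene, "srcB")
  expect_lt(ev$frame, 0)

  # the same gene planted in the sense orientation is not a strand switch
  genomeB2 <- paste0(rand_nt(300),
                     paste0(substr(sisB, 301, 320), cand_cds,
                            substr(sisB, 321, 400)), rand_nt(300))
  src2 <- mk_gene("srcB", "spB", "+",
                  exons = data.frame(start = 320,
                                     end = 320 + nchar(cand_cds)),
                  cds = data.frame(start = 320,
                                   end = 320 + nchar(cand_cds), phase = 0))
  ds2 <- make_mini_ds(list(spA = genomeA, spB = genomeB2),
                      dplyr::bind_rows(cand, src2))
  expect_null(detect_strand_switch(cand, ds2))
})

test_that("de novo stop positions equal a translate-and-scan oracle", {
  set.seed(74)
  orf <- rand_orf_fixture(50)
  cand <- mk_gene("cand", "spA", "+",
                  exons = data.frame(start = 50, end = 50 + nchar(orf)),
                  cds = data.frame(start = 50, end = 50 + nchar(orf),
                                   phase = 0))
  # sister region: diverged copy with stops planted at codons 7 and 19
  sis_cds <- mutate_fixture(orf, 0.04)
  cods <- substring(sis_cds, seq(1, nchar(sis_cds) - 2, 3),
                    seq(3, nchar(sis_cds), 3))
  gc <- Biostrings::GENETIC_CODE
  cods[gc[cods] == "*"] <- "CAG"       # clear accidental stops
  cods[c(7, 19)] <- c("TAA", "TGA")
  sis_cds <- paste(cods, collapse = "")
  genomeB <- paste0(rand_nt(200), sis_cds, rand_nt(200))
  ds <- make_mini_ds(list(spA = paste0(rand_nt(50), orf, rand_nt(50)),
                          spB = genomeB), cand)
  ds$transcriptome$spB <- Biostrings::DNAStringSet()
  regions <- tibble::tibble(species = "spB", contig = "chr",
                            start = 150, end = 150 + nchar(sis_cds) + 100)
  call <- detect_de_novo(cand, ds, regions)
  expect_identical(call$mechanism, "de-novo")
  st <- call$evidence[[1]]$per_species[["spB"]]
  expect_identical(st$status, "disrupted")
  # oracle: translate the planted region codons directly
  oracle_stops <- which(gc[cods] == "*")
  expect_identical(st$stops, as.integer(oracle_stops))

  # all species intact and transcribed: no call
  ds2 <- ds
  ds2$genomes$spB <- Biostrings::DNAStringSet(
    c(chr = paste0(rand_nt(200), orf, rand_nt(200))))
  ds2$transcriptome$spB <- Biostrings::DNAStringSet(c(t1 = orf))
  expect_null(detect_de_novo(cand, ds2, regions))
})

test_that("rescue refuses homologs discoverable genome-wide", {
  set.seed(75)
  orf <- rand_orf_fixture(60)
  # near-identical homolog: clearly discoverable genome-wide
  sisB <- paste0(rand_nt(400), mutate_fixture(orf, 0.02), rand_nt(400))
  cand <- mk_gene("cand", "spA", "+",
                  exons = data.frame(start = 50, end = 50 + nchar(orf)),
                  cds = data.frame(start = 50, end = 50 + nchar(orf),
                                   phase = 0))
  ds <- make_mini_ds(list(spA = paste0(rand_nt(50), orf, rand_nt(50)),
                          spB = sisB), cand)
  region <- tibble::tibble(found = TRUE, species = "spB", contig = "chr",
                           start = 300, end = 700,
                           orientation = "+")
  expect_null(rescue_heuristic_failure(cand, ds, region))
  # and nothing found even in-interval: no call either
  ds2 <- ds
  ds2$genomes$spB <- Biostrings::DNAStringSet(c(chr = rand_nt(1200)))
  expect_null(rescue_heuristic_failure(cand, ds2, region))
})

test_that("planted mechanisms are recovered on the simulated dataset", {
  ds <- test_dataset()
  me <- test_mechanisms()
  truth <- ds$truth[ds$truth$species == ds$focal &
                      ds$truth$mechanism != "none", ]
  got <- me$mechanism[match(truth$gene_id, me$gene_id)]
  expect_identical(unname(got), truth$mechanism)
})
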