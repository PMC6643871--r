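test_that("coordinate conversion round-trips for random intervals", {
  set.seed(11)
  s0 <- sample.int(1e6, 10000, replace = TRUE) - 1L
  w <- sample.int(500, 10000, replace = TRUE)
  one <- phylorphan:::io1(s0, s0 + w)
  back <- phylorphan:::io0(one$start, one$end)
  expect_identical(back$start, s0)
  expect_identical(back$end, s0 + w)
  # widths agree in both conventions
  expect_identical(one$end - one$start + 1L, w)
})

test_that("annotation round-trips and translation matches hand translation", {
  # minus-strand two-exon gene, 60 bp fixture translated by hand:
  # exons chr:[10,31) and [40,58); CDS = both, phase 0 on the 5'-most
  # (rightmost) CDS segment in transcription order
  left <- "ATGGCCAAAGATTTGCGTACA"      # 21 nt
  right <- "GGTTCTGAAGTGACTTAA"        # 18 nt
  spliced <- paste0(right, left)       # transcription order on minus strand
  genome_str <- paste0(
    rand_nt(10),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(left))),
    rand_nt(9),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(right))),
    rand_nt(12))
  # transcription order (minus strand): "right" exon first
  genes <- mk_gene("gm1", "spA", "-",
                   exons = data.frame(start = c(10, 40), end = c(31, 58)),
                   cds = data.frame(start = c(10, 40), end = c(31, 58),
                                    phase = c(0, 0)))
  genome <- Biostrings::DNAStringSet(c(chr = genome_str))
  got <- phylorphan:::gene_cds_seq(genes[1, ], genome)
  expect_identical(got, paste0(right, left))
  expect_identical(phylorphan:::gene_protein(genes[1, ], genome),
                   sub("\\*$", "", translate_oracle(spliced)))

  # GFF3 round trip: write -> read -> write is byte-identical
  tmp_gff <- tempfile(fileext = ".gff3")
  tmp_fa <- tempfile(fileext = ".fa")
  text1 <- write_annotation(genes)
  writeLines(sub("\n$", "", text1), tmp_gff)
  Biostrings::writeXStringSet(genome, tmp_fa)
  back <- read_annotation(tmp_gff, tmp_fa, species = "spA")
  expect_identical(back$gene_id, "gm1")
  expect_identical(back$exons[[1]]$start, c(10L, 40L))
  expect_identical(back$cds[[1]]$end, c(31L, 58L))
  expect_identical(write_annotation(back), text1)
})

test_that("single-exon plus-strand gene yields the expected protein length", {
  cds_nt <- rand_orf_fixture(33)  # 33 codons = 99 bp including the stop
  genome <- Biostrings::DNAStringSet(c(chr = paste0("GGGG", cds_nt, "CCCC")))
  g <- mk_gene("g1", "spA", "+",
               exons = data.frame(start = 4, end = 4 + 99),
               cds = data.frame(start = 4, end = 4 + 99, phase = 0))
  prot <- phylorphan:::gene_protein(g[1, ], genome)
  expect_identical(nchar(prot), 32L)
  expect_false(grepl("*", prot, fixed = TRUE))
})

test_that("malformed CDS lengths are excluded with a warning, not dropped silently", {
  genome <- Biostrings::DNAStringSet(c(chr = rand_nt(200)))
  good <- mk_gene("ok1", "spA", "+",
                  exons = data.frame(start = 10, end = 70),
                  cds = data.frame(start = 10, end = 70, phase = 0))
  tmp_fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(genome, tmp_fa)
  gff <- c("##gff-version 3",
           "chr\tx\tgene\t11\t70\t.\t+\t.\tID=ok1",
           "chr\tx\tmRNA\t11\t70\t.\t+\t.\tID=ok1.t1;Parent=ok1",
           "chr\tx\texon\t11\t70\t.\t+\t.\tParent=ok1.t1",
           "chr\tx\tCDS\t11\t70\t.\t+\t0\tID=c1;Parent=ok1.t1",
           "chr\tx\tgene\t101\t150\t.\t+\t.\tID=bad1",
           "chr\tx\tmRNA\t101\t150\t.\t+\t.\tID=bad1.t1;Parent=bad1",
           "chr\tx\texon\t101\t150\t.\t+\t.\tParent=bad1.t1",
           "chr\tx\tCDS\t101\t150\t.\t+\t0\tID=c2;Parent=bad1.t1")
  tmp_gff <- tempfile(fileext = ".gff3")
  writeLines(gff, tmp_gff)
  expect_warning(models <- read_annotation(tmp_gff, tmp_fa, "spA"),
                 "malformed")
  expect_identical(models$gene_id, "ok1")

  # CDS beyond the contig is a hard error
  gff_oob <- sub("11\t70", "11\t900", gff[1:5], fixed = TRUE)
  tmp2 <- tempfile(fileext = ".gff3")
  writeLines(gff_oob, tmp2)
  expect_error(read_annotation(tmp2, tmp_fa, "spA"), "contig")
})

test_that("SAM reader derives blocks from CIGAR and validates operations", {
  sam <- c("@HD\tVN:1.6",
           "@SQ\tSN:chr\tLN:1000",
           paste("r1", 0, "chr", 101, 60, "30M200N40M", "*", 0, 0, "*",
                 "*", sep = "\t"),
           paste("r2", 16, "chr", 1, 60, "5S20M", "*", 0, 0, "*", "*",
                 sep = "\t"))
  tmp <- tempfile(fileext = ".sam")
  writeLines(sam, tmp)
  reads <- read_sam(tmp)
  expect_identical(reads$blocks[[1]],
                   data.frame(start = c(100L, 330L), end = c(130L, 370L)))
  expect_true(reads$is_spliced[1])
  expect_identical(reads$strand[2], "-")
  expect_identical(reads$blocks[[2]],
                   data.frame(start = 0L, end = 20L))

  writeLines(c(sam[1:2],
               paste("r3", 0, "chr", 1, 60, "10M5Q10M", "*", 0, 0, "*",
                     "*", sep = "\t")), tmp)
  expect_error(read_sam(tmp), "CIGAR")

  # splice gaps below the minimum intron length are rejected
  writeLines(c(sam[1:2],
               paste("r4", 0, "chr", 1, 60, "10M5N10M", "*", 0, 0, "*",
                     "*", sep = "\t")), tmp)
  expect_error(read_sam(tmp), "min_intron")
})

test_that("species tree: ladder indices and rooting checks", {
  species <- paste0("sp", 0:9)
  nwk <- make_ladder_newick_for_test(species)
  tree <- read_species_tree(nwk, "sp0")
  li <- ladder_index(tree)
  expect_identical(li$species, paste0("sp", 1:9))
  expect_identical(li$ladder_index, 1:9)

  expect_error(read_species_tree(nwk, "nope"), "focal")
  unrooted <- "(a:1,b:1,c:1);"
  expect_error(read_species_tree(unrooted, "a"), "rooted")
})

test_that("read/write SAM round-trips block structure", {
  reads <- tibble::tibble(
    read_id = c("a", "b"),
    contig = "chr",
    strand = c("+", "-"),
    blocks = list(data.frame(start = c(10L, 100L), end = c(40L, 130L)),
                  data.frame(start = 5L, end = 80L)),
    is_spliced = c(TRUE, FALSE),
    seq = c(rand_nt(60), rand_nt(75)))
  tmp <- tempfile(fileext = ".sam")
  phylorphan:::write_sam(reads, c(chr = 1000L), tmp)
  back <- read_sam(tmp)
  expect_identical(back$blocks[[which(back$read_id == "a")]],
                   reads$blocks[[1]])
  expect_identical(back$strand[back$read_id == "b"], "-")
})
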