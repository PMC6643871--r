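synteny_fixture <- function(n = 7, invert = integer(0)) {
  # n orthologous gene pairs in collinear order; `invert` marks pairs whose
  # partner is displaced (breaking collinearity)
  set.seed(61)
  coords <- list(); hits <- list()
  posB <- seq_len(n) * 1000
  posB[invert] <- posB[invert] - 2500  # displaced partner breaks the chain
  for (i in seq_len(n)) {
    ga <- sprintf("a%02d", i); gb <- sprintf("b%02d", i)
    coords[[length(coords) + 1L]] <- tibble::tibble(
      gene_id = c(ga, gb), species = c("spA", "spB"),
      contig = c("cA", "cB"), start = c(i * 1000, posB[i]),
      end = c(i * 1000 + 300, posB[i] + 300), strand = "+")
    hits[[length(hits) + 1L]] <- tibble::tibble(
      query_id = ga, subject_id = gb, score = 200, e_value = 1e-30)
  }
  list(coords = dplyr::bind_rows(coords), hits = dplyr::bind_rows(hits))
}

test_that("collinear orthologs chain into one block; inversions fall out", {
  fx <- synteny_fixture(5)
  blocks <- find_synteny_blocks(fx$hits, fx$coords)
  expect_identical(nrow(blocks), 1L)
  expect_identical(blocks$n_anchors, 5L)
  expect_identical(blocks$orientation, "+")

  fx2 <- synteny_fixture(7, invert = 4)
  blocks2 <- find_synteny_blocks(fx2$hits, fx2$coords)
  an <- blocks2$anchors[[1]]
  expect_false("a04" %in% an$gene_a)
  # chain length matches the exhaustive longest-increasing-subsequence
  ordB <- fx2$coords$start[match(paste0("b0", 1:7),
                                 fx2$coords$gene_id)]
  expect_identical(blocks2$n_anchors[1], lis_oracle_len(ordB))
})

test_that("synteny is symmetric up to orientation", {
  fx <- synteny_fixture(6)
  fwd <- find_synteny_blocks(fx$hits, fx$coords)
  rev_hits <- tibble::tibble(query_id = fx$hits$subject_id,
                             subject_id = fx$hits$query_id,
                             score = fx$hits$score,
                             e_value = fx$hits$e_value)
  bwd <- find_synteny_blocks(rev_hits, fx$coords)
  expect_identical(fwd$n_anchors, bwd$n_anchors)
  expect_identical(sort(fwd$anchors[[1]]$gene_a),
                   sort(bwd$anchors[[1]]$gene_b))
})

test_that("orthologous regions come from flanking anchors", {
  fx <- synteny_fixture(5)
  blocks <- find_synteny_blocks(fx$hits, fx$coords)
  r <- orthologous_region(list(contig = "cA", start = 2400, end = 2600),
                          blocks[1, ], fx$coords)
  expect_true(r$found)
  expect_identical(r$species, "spB")
  expect_identical(c(r$start, r$end), c(2300, 3000))

  # locus beyond the last anchor: typed no-region, not an error
  r2 <- orthologous_region(list(contig = "cA", start = 9000, end = 9100),
                           blocks[1, ], fx$coords)
  expect_false(r2$found)
})

test_that("host intron regions map by intron index in transcription order", {
  host <- mk_gene("h", "spA", "+",
                  exons = data.frame(start = c(0, 200, 500),
                                     end = c(100, 300, 600)),
                  cds = data.frame(start = c(0, 200, 500),
                                   end = c(100, 300, 600),
                                   phase = c(0, 0, 0)))
  orth_plus <- mk_gene("o", "spB", "+",
                       exons = data.frame(start = c(50, 400, 900),
                                          end = c(150, 520, 1000)),
                       cds = data.frame(start = c(50, 400, 900),
                                        end = c(150, 520, 1000),
                                        phase = c(0, 0, 0)))
  r <- host_intron_region(host[1, ], orth_plus[1, ], 2)
  expect_identical(c(r$start, r$end), c(520, 900))
  # minus-strand ortholog counts introns from the right
  orth_minus <- orth_plus; orth_minus$strand <- "-"
  r2 <- host_intron_region(host[1, ], orth_minus[1, ], 2)
  expect_identical(c(r2$start, r2$end), c(150, 400))
  # too few introns: typed no-region
  expect_false(host_intron_region(host[1, ], mk_gene(
    "u", "spB", "+", data.frame(start = 0, end = 90),
    data.frame(start = 0, end = 90, phase = 0))[1, ], 1)$found)
})

test_that("spliced alignment reproduces its own exon structure", {
  set.seed(62)
  orf <- rand_orf_fixture(52)   # 156 nt including stop
  ex1 <- substr(orf, 1, 75); ex2 <- substr(orf, 76, 156)
  intron <- paste0("GT", rand_nt(60), "AG")
  window <- paste0(rand_nt(40), ex1, intron, ex2, rand_nt(40))
  prot <- sub("\\*$", "", translate_oracle(orf))
  sm <- spliced_align(prot, window)
  expect_identical(nrow(sm$segments), 2L)
  expect_identical(sm$strand, "+")
  expect_equal(sm$segments$g_start, c(40, 179))
  expect_equal(sm$segments$g_end, c(115, 257))

  # strand symmetry: the reverse-complemented window maps on the minus
  # strand with mirrored coordinates
  rcw <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(window)))
  sm2 <- spliced_align(prot, rcw)
  expect_identical(sm2$strand, "-")
  expect_equal(sort(nchar(window) - sm2$segments$g_end),
               sm$segments$g_start)

  expect_error(spliced_align(prot, paste(rep("A", 3e5), collapse = "")),
               "200 kb")
})

test_that("segment chaining is optimal against exhaustive enumeration", {
  set.seed(63)
  window <- paste0(rand_nt(200), "GT", rand_nt(50), "AG", rand_nt(200))
  for (trial in 1:5) {
    n <- sample(4:8, 1)
    segs <- tibble::tibble(
      q_start = sort(sample(0:80, n)),
      q_end = 0, g_start = sort(sample(seq(0, 400, 10), n)),
      g_end = 0, frame = sample(c(1, 2, 3), n, TRUE),
      score = sample(25:80, n, TRUE))
    segs$q_end <- segs$q_start + sample(5:15, n, TRUE)
    segs$g_end <- segs$g_start + sample(20:50, n, TRUE)
    got <- phylorphan:::chain_spliced_segments(segs, window)
    want <- chain_oracle(segs, window)
    expect_equal(got$score, want, info = paste("trial", trial))
  }
})
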