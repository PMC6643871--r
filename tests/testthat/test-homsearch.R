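test_that("six-frame translation matches a codon-table oracle", {
  expect_identical(
    translate_six_frames("ATGAAATAG")$protein[1], "MK*")
  set.seed(21)
  s <- rand_nt(300)
  fr <- translate_six_frames(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  # reverse-complement symmetry
  expect_identical(fr$protein[fr$frame == -1],
                   translate_six_frames(rc)$protein[1])
  # all six frames against direct per-codon lookup
  for (o in 0:2) {
    expect_identical(fr$protein[fr$frame == o + 1],
                     translate_oracle(substr(s, o + 1, 300)))
    expect_identical(fr$protein[fr$frame == -(o + 1)],
                     translate_oracle(substr(rc, o + 1, 300)))
  }
  expect_error(translate_six_frames("AT"), "codon")
  expect_error(translate_six_frames("ATGAXATAG"), "IUPAC")
})

test_that("self-hit has full identity and the smallest E-value", {
  set.seed(22)
  q <- rand_prot(100)
  db <- c(self = q, other1 = rand_prot(120), other2 = rand_prot(80))
  hits <- search_homology(c(q = q), db, search_params("pp", e_max = 10))
  expect_identical(hits$subject_id[1], "self")
  expect_equal(hits$pct_identity[1], 100)
  expect_true(all(hits$e_value[1] <= hits$e_value))
})

test_that("reported scores equal the quadratic affine-gap DP oracle", {
  set.seed(23)
  B <- phylorphan:::blosum62()
  for (i in 1:30) {
    n1 <- sample(30:200, 1); n2 <- sample(30:200, 1)
    a <- rand_prot(n1); b <- rand_prot(n2)
    hits <- search_homology(c(q = a), c(s = b),
                            search_params("pp", e_max = Inf, word_size = 0L))
    expect_equal(hits$score[1], sw_oracle(a, b, B), info = paste("pair", i))
  }
  # nucleotide scoring (+2/-3, gaps 5/2)
  M <- phylorphan:::nucl_matrix()
  for (i in 1:5) {
    a <- rand_nt(150); b <- rand_nt(200)
    hits <- search_homology(c(q = a), c(s = b),
                            search_params("nn", e_max = Inf, word_size = 0L))
    fwd <- hits[hits$s_strand == "+", ]
    expect_equal(fwd$score[1], sw_oracle(a, b, M, gap_open = 5, gap_ext = 2))
  }
})

test_that("seeding only prunes: hit sets match the unseeded engine", {
  set.seed(24)
  # homologous pairs at assorted divergence plus unrelated sequences
  base <- rand_orf_fixture(60)
  subjects <- c(
    hom1 = translate_oracle(base),
    hom2 = translate_oracle(mutate_fixture(base, 0.1)),
    hom3 = translate_oracle(mutate_fixture(base, 0.25)),
    junk1 = rand_prot(90), junk2 = rand_prot(120))
  q <- c(q = translate_oracle(base))
  seeded <- search_homology(q, subjects, search_params("pp", e_max = 1e-3))
  unseeded <- search_homology(q, subjects,
                              search_params("pp", e_max = 1e-3,
                                            word_size = 0L))
  expect_identical(seeded$subject_id, unseeded$subject_id)
  expect_equal(seeded$score, unseeded$score)
})

test_that("E-values are monotone in score and thresholds are inclusive", {
  p <- search_params("pp")
  s <- seq(30, 120, by = 10)
  e <- p$K * 100 * 1e4 * exp(-p$lambda * s)
  expect_true(all(diff(e) < 0))
  # inclusive threshold: a hit exactly at e_max is reported
  set.seed(25)
  q <- rand_prot(50)
  hits <- search_homology(c(q = q), c(s = q),
                          search_params("pp", e_max = Inf))
  e_exact <- hits$e_value[1]
  at <- search_homology(c(q = q), c(s = q),
                        search_params("pp", e_max = e_exact))
  expect_identical(nrow(at), 1L)
})

test_that("engine rejects empty queries and duplicate subject ids", {
  expect_error(search_homology(c(q = ""), c(s = "MKL"),
                               search_params("pp")), "empty")
  expect_error(search_homology(character(0), c(s = "MKL"),
                               search_params("pp")), "empty query")
  dup <- Biostrings::AAStringSet(c(a = "MKLV", a = "MKLI"))
  expect_error(search_homology(c(q = "MKLV"), dup, search_params("pp")),
               "duplicate")
})

test_that("translated mode reports frames and genomic intervals", {
  set.seed(26)
  orf <- rand_orf_fixture(40)
  prot <- sub("\\*$", "", translate_oracle(orf))
  pad5 <- rand_nt(17); pad3 <- rand_nt(11)
  genome <- paste0(pad5, orf, pad3)
  h <- search_homology(c(q = prot), c(chr = genome),
                       search_params("px", e_max = 1e-3))
  expect_gt(nrow(h), 0)
  expect_identical(abs(h$s_frame[1]) > 0, TRUE)
  expect_identical(substr(genome, h$s_start[1] + 1, h$s_end[1]),
                   substr(orf, 1, 3 * nchar(prot)))
  # reverse-complement placement is found on a minus frame
  rc_genome <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genome)))
  h2 <- search_homology(c(q = prot), c(chr = rc_genome),
                        search_params("px", e_max = 1e-3))
  expect_lt(h2$s_frame[1], 0)
})

test_that("outfmt6 interop round-trips the essential hit fields", {
  set.seed(27)
  q <- rand_prot(80)
  hits <- search_homology(c(q1 = q), c(s1 = q, s2 = rand_prot(60)),
                          search_params("pp", e_max = 10))
  tmp <- tempfile(fileext = ".tsv")
  write_outfmt6(hits, tmp)
  back <- read_outfmt6(tmp, mode = "pp")
  expect_identical(back$query_id, hits$query_id)
  expect_identical(back$subject_id, hits$subject_id)
  expect_equal(back$q_start, hits$q_start)
  expect_equal(back$s_end, hits$s_end)
})
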