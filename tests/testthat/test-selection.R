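test_that("protein aligner handles identical pairs and clean deletions", {
  a <- "MKVLATQWERHGFDSA"
  out <- align_proteins(c(x = a, y = a))
  expect_identical(unname(out["x"]), a)
  expect_identical(unname(out["y"]), a)

  # one 3-residue internal deletion becomes one gap of length 3
  b <- paste0(substr(a, 1, 6), substr(a, 10, 16))
  out2 <- align_proteins(c(x = a, y = b))
  expect_identical(nchar(out2[["x"]]), nchar(a))
  gaps <- gregexpr("-+", out2[["y"]])[[1]]
  expect_identical(attr(gaps, "match.length"), 3L)

  # progressive case: columns >= longest input, order-independent
  set.seed(31)
  s3 <- c(a = a, b = b, c = paste0("MKV", substr(a, 4, 16)))
  out3 <- align_proteins(s3)
  expect_true(all(nchar(out3) == nchar(out3[1])))
  expect_gte(nchar(out3[1]), max(nchar(s3)))
  out3b <- align_proteins(s3[c(3, 1, 2)])
  expect_identical(out3[sort(names(out3))], out3b[sort(names(out3b))])

  expect_error(align_proteins(c(x = "MK")), "two sequences")
  expect_error(align_proteins(c(x = "", y = "MK")), "empty")
})

test_that("backtranslation mirrors protein columns and masks stops", {
  cds <- rand_orf_fixture(11)            # 10 residues + stop
  cds <- substr(cds, 1, 30)              # drop the stop codon
  prot <- translate_oracle(cds)
  ca <- backtranslate(c(t1 = prot), c(t1 = cds))
  expect_identical(nchar(ca$aln[["t1"]]), 30L)
  expect_identical(ca$aln[["t1"]], cds)

  # a stop at residue 11 is masked with its position logged
  cds2 <- paste0(substr(rand_orf_fixture(21), 1, 30), "TGA",
                 substr(rand_orf_fixture(21), 34, 60))
  prot2 <- translate_oracle(cds2)
  expect_identical(substr(prot2, 11, 11), "*")
  ca2 <- backtranslate(c(t1 = prot2), c(t1 = cds2))
  expect_identical(ca2$masked$codon, 11L)
  expect_identical(substr(ca2$aln[["t1"]], 31, 33), "NNN")

  # degap + concatenate returns the source CDS
  al <- align_proteins(c(t1 = prot, t2 = substr(prot, 1, 8)))
  cds_t2 <- substr(cds, 1, 24)
  ca3 <- backtranslate(al, c(t1 = cds, t2 = cds_t2))
  expect_identical(gsub("-", "", ca3$aln[["t2"]]), cds_t2)

  expect_error(backtranslate(c(t1 = prot), c(t1 = substr(cds, 1, 27))),
               "mismatch")
})

test_that("pruning log-likelihood equals brute-force state summation", {
  set.seed(32)
  pi_nt <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  # two taxa, three codons
  phy2 <- ape::read.tree(text = "(t1:0.2,t2:0.1);")
  ca2 <- simulate_codon_alignment(phy2, 3, omega = 0.5, kappa = 2,
                                  pi_nt = pi_nt)
  pc <- phylorphan:::codon_patterns(ca2)
  t_edges <- phy2$edge.length
  got <- phylorphan:::mg94_lnl(phy2, pc$patterns, pc$counts, t_edges,
                               kappa = 2, omega_edges = rep(0.5, 2), pi_nt)
  want <- lnl_bruteforce(ca2, phy2, t_edges, kappa = 2, omega = 0.5, pi_nt)
  expect_equal(got, unname(want), tolerance = 1e-6)

  # three taxa, five codons (sums over 61^2 ancestral pairs)
  phy3 <- ape::read.tree(text = "((t1:0.15,t2:0.2):0.1,t3:0.3);")
  ca3 <- simulate_codon_alignment(phy3, 5, omega = 1.5, kappa = 3,
                                  pi_nt = pi_nt)
  pc3 <- phylorphan:::codon_patterns(ca3)
  got3 <- phylorphan:::mg94_lnl(phy3, pc3$patterns, pc3$counts,
                                phy3$edge.length, kappa = 3,
                                omega_edges = rep(1.5, 4), pi_nt)
  want3 <- lnl_bruteforce(ca3, phy3, phy3$edge.length, kappa = 3,
                          omega = 1.5, pi_nt)
  expect_equal(got3, unname(want3), tolerance = 1e-6)
})

test_that("fit_omega refuses degenerate input and nests correctly", {
  phy <- ape::read.tree(text = "(t1:0.1,t2:0.1);")
  cds <- substr(rand_orf_fixture(41), 1, 120)
  ca <- backtranslate(
    c(t1 = translate_oracle(cds), t2 = translate_oracle(cds)),
    c(t1 = cds, t2 = cds))
  fit <- fit_omega(ca, phy)
  expect_identical(fit$status, "insufficient-data")

  set.seed(33)
  ca2 <- simulate_codon_alignment(0.4, 120, omega = 0.5)
  fit2 <- fit_omega(ca2, ape::read.tree(text = "(t1:0.2,t2:0.2);"))
  expect_identical(fit2$status, "ok")
  expect_gte(fit2$lnL_alt, fit2$lnL_null - 1e-4)
  expect_gte(min(fit2$omega$omega), 0)
  g <- glance(fit2)
  expect_identical(g$df, 1L)
  expect_identical(nrow(tidy(fit2)), 1L)
})

test_that("NG86 counting behaves on canonical cases", {
  c1 <- paste(rep("TTT", 100), collapse = "")
  r0 <- ng86(c1, c1)
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  expect_true(is.na(r0$omega))

  # one synonymous change: TTT -> TTC (both Phe)
  c2 <- paste(c(rep("TTT", 99), "TTC"), collapse = "")
  r1 <- ng86(c1, c2)
  expect_equal(r1$Nd, 0)
  expect_gt(r1$dS, 0)
  expect_equal(r1$dN, 0)

  # one nonsynonymous change: TTT -> GTT (Phe -> Val)
  c3 <- paste(c(rep("TTT", 99), "GTT"), collapse = "")
  r2 <- ng86(c1, c3)
  expect_equal(r2$Sd, 0)
  expect_gt(r2$dN, 0)

  expect_error(ng86("ATGA", "ATGA"), "multiple of three")
  expect_error(ng86("TAA", "TTT"), "stop")
})
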