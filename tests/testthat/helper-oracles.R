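# Independent oracles. These re-derive results by brute force and must stay
# free of the code paths they check.

# Smith-Waterman / Needleman-Wunsch with affine gaps (Gotoh), nested loops.
# A gap of length k costs gap_open + k * gap_ext.
sw_oracle <- function(a, b, mat, gap_open = 11, gap_ext = 1,
                      type = c("local", "global")) {
  type <- match.arg(type)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)  # gap in A (move along B)
  F <- matrix(NEG, m + 1, n + 1)  # gap in B
  if (type == "global") {
    for (j in seq_len(n)) {
      E[1, j + 1] <- -(gap_open + j * gap_ext)
      H[1, j + 1] <- E[1, j + 1]
    }
    for (i in seq_len(m)) {
      F[i + 1, 1] <- -(gap_open + i * gap_ext)
      H[i + 1, 1] <- F[i + 1, 1]
    }
  }
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(E[i + 1, j] - gap_ext,
                             H[i + 1, j] - gap_open - gap_ext)
      F[i + 1, j + 1] <- max(F[i, j + 1] - gap_ext,
                             H[i, j + 1] - gap_open - gap_ext)
      s <- H[i, j] + mat[A[i], B[j]]
      h <- max(s, E[i + 1, j + 1], F[i + 1, j + 1])
      if (type == "local") h <- max(0, h)
      H[i + 1, j + 1] <- h
      if (h > best) best <- h
    }
  }
  if (type == "local") best else H[m + 1, n + 1]
}

# random protein / dna strings
rand_prot <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"), n, TRUE),
        collapse = "")
}
rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

# translation by direct lookup in the standard code table
translate_oracle <- function(nt) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(nt) - nchar(nt) %% 3
  cods <- substring(nt, seq(1, n - 2, 3), seq(3, n, 3))
  paste(ifelse(cods %in% names(gc), gc[cods], "X"), collapse = "")
}

# per-base read coverage by brute force over SAM blocks
pileup_oracle <- function(reads, contig, positions) {
  vapply(positions, function(p) {
    sum(vapply(seq_len(nrow(reads)), function(i) {
      reads$contig[i] == contig &&
        any(reads$blocks[[i]]$start <= p & reads$blocks[[i]]$end > p)
    }, logical(1)))
  }, numeric(1))
}

# brute-force exon/junction support counting under the validation rules
support_oracle <- function(gene, reads, min_overlap = 0.8) {
  ex <- gene$exons[[1]][order(gene$exons[[1]]$start), , drop = FALSE]
  cd <- gene$cds[[1]]
  n_ex <- nrow(ex)
  spans <- lapply(seq_len(n_ex), function(j) {
    s <- pmax(ex$start[j], cd$start); e <- pmin(ex$end[j], cd$end)
    k <- which(e > s)
    if (length(k) == 0) NULL else c(min(s[k]), max(e[k]))
  })
  juncs <- if (n_ex > 1) cbind(ex$end[-n_ex], ex$start[-1]) else
    matrix(numeric(0), ncol = 2)
  exon_sup <- integer(n_ex); junc_sup <- integer(nrow(juncs))
  rr <- reads[reads$contig == gene$contig, ]
  for (i in seq_len(nrow(rr))) {
    b <- rr$blocks[[i]]
    jm <- integer(0)
    if (nrow(b) > 1) {
      for (q in seq_len(nrow(b) - 1)) {
        for (jj in seq_len(nrow(juncs))) {
          if (b$end[q] == juncs[jj, 1] && b$start[q + 1] == juncs[jj, 2])
            jm <- c(jm, jj)
        }
      }
    }
    junc_sup[jm] <- junc_sup[jm] + 1L
    for (j in seq_len(n_ex)) {
      sup <- FALSE
      sp <- spans[[j]]
      if (!is.null(sp)) {
        for (q in seq_len(nrow(b))) {
          ov <- min(b$end[q], sp[2]) - max(b$start[q], sp[1])
          if (ov >= min_overlap * (sp[2] - sp[1])) sup <- TRUE
        }
      }
      if (!sup && length(jm) > 0 && any(jm == j | jm == j - 1L)) {
        for (q in seq_len(nrow(b))) {
          if (min(b$end[q], ex$end[j]) - max(b$start[q], ex$start[j]) > 0)
            sup <- TRUE
        }
      }
      if (sup) exon_sup[j] <- exon_sup[j] + 1L
    }
  }
  list(exon = exon_sup, junction = junc_sup)
}

# matrix exponential by scaled Taylor series
expm_taylor <- function(Q, t, order = 30, scale_pow = 10) {
  A <- Q * (t / 2^scale_pow)
  P <- diag(nrow(Q))
  term <- diag(nrow(Q))
  for (k in seq_len(order)) {
    term <- term %*% A / k
    P <- P + term
  }
  for (k in seq_len(scale_pow)) P <- P %*% P
  P
}

# brute-force codon log-likelihood: explicit summation over internal node
# states for 2- or 3-taxon rooted trees (root = common ancestor)
lnl_bruteforce <- function(ca, phy, t_edges, kappa, omega, pi_nt) {
  pi_cod <- phylorphan:::codon_freqs_f1x4(pi_nt)
  Q <- phylorphan:::mg94_q(kappa, omega, pi_nt, pi_cod)
  n_tip <- length(phy$tip.label)
  P <- lapply(seq_len(nrow(phy$edge)), function(k)
    expm_taylor(Q, t_edges[k]))
  cods <- lapply(ca$aln, function(s)
    match(phylorphan:::codons_of(s), phylorphan:::CODONS61))
  n_col <- length(cods[[1]])
  root <- n_tip + 1L
  total <- 0
  for (site in seq_len(n_col)) {
    state <- vapply(phy$tip.label, function(tx) cods[[tx]][site],
                    integer(1))
    lik <- 0
    internals <- (n_tip + 1L):(n_tip + phy$Nnode)
    grid <- do.call(expand.grid, rep(list(seq_len(61)), length(internals)))
    for (g in seq_len(nrow(grid))) {
      anc <- as.integer(grid[g, ])
      names(anc) <- internals
      pr <- pi_cod[anc[as.character(root)]]
      for (k in seq_len(nrow(phy$edge))) {
        par <- phy$edge[k, 1]; child <- phy$edge[k, 2]
        from <- anc[as.character(par)]
        to <- if (child <= n_tip) state[child] else
          anc[as.character(child)]
        if (is.na(to)) next  # missing tip: marginalize = factor 1
        pr <- pr * P[[k]][from, to]
      }
      lik <- lik + pr
    }
    total <- total + log(lik)
  }
  total
}

# exhaustive chain score over spliced-alignment segments (<= 12 segments),
# under the same trim-aware splice-gap scoring definition
chain_oracle <- function(segs, window, splice_bonus = 10,
                         noncanon_penalty = 10, overlap_tol = 6,
                         trim_cost = 2) {
  best <- -Inf
  for (strand in c("+", "-")) {
    ss <- segs[sign(segs$frame) == (if (strand == "+") 1 else -1), ]
    if (nrow(ss) == 0) next
    n <- nrow(ss)
    gap_score <- function(j, i) {
      k <- max(0, ss$q_end[j] - ss$q_start[i])
      if (k > overlap_tol) return(NA_real_)
      if (ss$q_end[i] <= ss$q_end[j] || ss$q_start[i] < ss$q_start[j])
        return(NA_real_)
      if (strand == "+" && ss$g_start[i] < ss$g_start[j]) return(NA_real_)
      if (strand == "-" && ss$g_start[i] > ss$g_start[j]) return(NA_real_)
      out <- NA_real_
      for (x in 0:k) {
        r <- k - x
        if (strand == "+") {
          lo <- ss$g_end[j] - 3 * x; hi <- ss$g_start[i] + 3 * r
          donor <- "GT"; acceptor <- "AG"
        } else {
          lo <- ss$g_end[i] - 3 * r; hi <- ss$g_start[j] + 3 * x
          donor <- "CT"; acceptor <- "AC"
        }
        if (hi - lo < 4) next
        canonical <- substr(window, lo + 1, lo + 2) == donor &&
          substr(window, hi - 1, hi) == acceptor
        sc <- (if (canonical) splice_bonus else -noncanon_penalty) -
          trim_cost * k
        if (is.na(out) || sc > out) out <- sc
      }
      out
    }
    recurse <- function(idx_set, last, score) {
      best <<- max(best, score)
      for (i in idx_set) {
        g <- if (is.na(last)) 0 else gap_score(last, i)
        if (is.na(g)) next
        recurse(idx_set[idx_set != i & ss$q_start[idx_set] >=
                          ss$q_start[i]], i, score + g + ss$score[i])
      }
    }
    recurse(seq_len(n), NA, 0)
  }
  best
}

# longest strictly increasing subsequence length by exhaustive subsets
lis_oracle_len <- function(x) {
  n <- length(x)
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= best) next
    v <- x[idx]
    if (all(diff(v) > 0)) best <- length(idx)
  }
  best
}

# random open reading frame (start + sense codons + stop), built from the
# standard code table rather than the package's codon machinery
rand_orf_fixture <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste0("ATG",
         paste(sample(sense, n_codons - 2, TRUE), collapse = ""),
         "TAA")
}

# simple site mutator for fixtures (uniform substitutions, keeps length)
mutate_fixture <- function(nt, p) {
  ch <- strsplit(nt, "")[[1]]
  hit <- which(stats::runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}
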