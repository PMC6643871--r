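# Selection analysis: protein alignment, codon back-translation, MG94xHKY
# (F1x4) maximum likelihood with per-branch or single omega, LRT against
# omega = 1, and an NG86 counting estimator as a cross-check.

CODONS61 <- SENSE_CODONS
CODON_AA <- vapply(CODONS61, function(cd)
  as.character(Biostrings::translate(Biostrings::DNAString(cd))),
  character(1))

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Global progressive protein alignment
#'
#' Center-star progressive alignment: the center sequence maximizes the sum
#' of pairwise global alignment scores (lexicographic tie-break, so the
#' result does not depend on input order); all other sequences are aligned
#' to the center with affine-gap Needleman--Wunsch under BLOSUM62 and merged
#' by the once-a-gap-always-a-gap rule.
#'
#' @param seqs named character vector of protein sequences (>= 2; `*`
#'   allowed and scored by the matrix).
#' @return Named character vector of aligned rows (equal width).
#' @export
align_proteins <- function(seqs) {
  assert_that(length(seqs) >= 2, "need at least two sequences")
  assert_that(!is.null(names(seqs)) && !anyDuplicated(names(seqs)),
              "sequences must have unique names")
  assert_that(all(nchar(seqs) > 0), "empty sequence")
  seqs <- seqs[order(names(seqs))]
  n <- length(seqs)
  pair_aln <- function(a, b) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1)
    list(score = Biostrings::score(pa),
         a = as.character(Biostrings::alignedPattern(pa)),
         b = as.character(Biostrings::alignedSubject(pa)))
  }
  if (n == 2) {
    al <- pair_aln(seqs[[1]], seqs[[2]])
    return(stats::setNames(c(al$a, al$b), names(seqs)))
  }
  score_sum <- numeric(n)
  alns <- vector("list", n)
  for (i in seq_len(n)) alns[[i]] <- vector("list", n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- pair_aln(seqs[[i]], seqs[[j]])
    score_sum[i] <- score_sum[i] + al$score
    score_sum[j] <- score_sum[j] + al$score
    alns[[i]][[j]] <- al
  }
  center <- which.max(score_sum)  # ties: lowest index = lexicographic
  others <- setdiff(seq_len(n), center)
  # master center row with accumulated gaps + aligned others
  master <- strsplit(seqs[[center]], "")[[1]]
  rows <- list()
  for (j in others) {
    al <- if (center < j) alns[[center]][[j]] else {
      tmp <- alns[[j]][[center]]; list(a = tmp$b, b = tmp$a)
    }
    ca <- strsplit(al$a, "")[[1]]   # center as aligned in this pair
    oa <- strsplit(al$b, "")[[1]]
    # merge ca into master: positions where one has a gap and not the other
    mi <- 1L; pi_ <- 1L
    new_master <- character(0); new_rows <- lapply(rows, function(r)
      character(0))
    new_other <- character(0)
    while (mi <= length(master) || pi_ <= length(ca)) {
      m_gap <- mi <= length(master) && master[mi] == "-"
      p_gap <- pi_ <= length(ca) && ca[pi_] == "-"
      m_res <- mi <= length(master) && !m_gap
      p_res <- pi_ <= length(ca) && !p_gap
      if ((m_res && p_res) || (m_gap && p_gap)) {
        new_master <- c(new_master, master[mi])
        for (k in seq_along(rows)) new_rows[[k]] <-
            c(new_rows[[k]], rows[[k]][mi])
        new_other <- c(new_other, oa[pi_])
        mi <- mi + 1L; pi_ <- pi_ + 1L
      } else if (m_gap) {
        new_master <- c(new_master, "-")
        for (k in seq_along(rows)) new_rows[[k]] <-
            c(new_rows[[k]], rows[[k]][mi])
        new_other <- c(new_other, "-")
        mi <- mi + 1L
      } else {  # p_gap or master exhausted
        new_master <- c(new_master, if (pi_ <= length(ca)) ca[pi_] else "-")
        for (k in seq_along(rows)) new_rows[[k]] <- c(new_rows[[k]], "-")
        new_other <- c(new_other, oa[pi_])
        pi_ <- pi_ + 1L
      }
    }
    master <- new_master
    rows <- new_rows
    rows[[length(rows) + 1L]] <- new_other
  }
  out <- c(paste(master, collapse = ""),
           vapply(rows, paste, "", collapse = ""))
  stats::setNames(out, names(seqs)[c(center, others)])[names(seqs)]
}

#' Back-translate a protein alignment to codons
#'
#' Each aligned residue becomes its source codon; gaps become `---`.
#' In-frame stop residues (`*`) are masked as missing data (`NNN`) with
#' their codon positions recorded, so extracted reading frames that still
#' carry ancestral stops stay usable in the codon model while the stop
#' evidence is preserved.
#'
#' @param protein_alignment named character vector of aligned rows.
#' @param cds_map named character vector of the source CDS (no stops
#'   removed; length must be 3x the ungapped residue count).
#' @return Object of class `codon_alignment`: list with `aln` (named gapped
#'   codon rows), `masked` (tibble `taxon`, `codon`; 1-based alignment
#'   columns), `n_col`.
#' @export
backtranslate <- function(protein_alignment, cds_map) {
  taxa <- names(protein_alignment)
  assert_that(all(taxa %in% names(cds_map)), "cds_map is missing rows")
  out <- list(); masked <- list()
  for (tx in taxa) {
    row <- strsplit(protein_alignment[[tx]], "")[[1]]
    res <- row[row != "-"]
    cds <- cds_map[[tx]]
    if (nchar(cds) %% 3L != 0L || nchar(cds) %/% 3L < length(res))
      stop("CDS/protein length mismatch for row '", tx, "' (", nchar(cds),
           " nt vs ", length(res), " aa)", call. = FALSE)
    cods <- codons_of(cds)
    out_row <- character(length(row))
    k <- 0L
    for (i in seq_along(row)) {
      if (row[i] == "-") { out_row[i] <- "---"; next }
      k <- k + 1L
      if (row[i] == "*") {
        out_row[i] <- "NNN"
        masked[[length(masked) + 1L]] <- new_tbl(taxon = tx, codon = i)
      } else out_row[i] <- cods[k]
    }
    out[[tx]] <- paste(out_row, collapse = "")
  }
  structure(list(aln = unlist(out),
                 masked = if (length(masked)) dplyr::bind_rows(masked) else
                   new_tbl(taxon = character(), codon = integer()),
                 n_col = nchar(protein_alignment[[1]]) ),
            class = "codon_alignment")
}

# --- MG94 x HKY (F1x4) machinery -------------------------------------------

# base index of each codon position, computed once
CODON_NT_IDX <- t(vapply(strsplit(CODONS61, ""), function(ch)
  match(ch, BASES), integer(3)))

# F1x4 equilibrium codon frequencies from nucleotide frequencies
codon_freqs_f1x4 <- function(pi_nt) {
  p <- pi_nt[CODON_NT_IDX[, 1]] * pi_nt[CODON_NT_IDX[, 2]] *
    pi_nt[CODON_NT_IDX[, 3]]
  p <- as.numeric(p)
  p / sum(p)
}

# single-nucleotide codon exchange structure, computed once: row i, col j,
# target base, transition flag, nonsynonymous flag
MG94_IDX <- local({
  sp <- strsplit(CODONS61, "")
  rows <- list()
  for (i in seq_along(CODONS61)) {
    ci <- sp[[i]]
    for (pos in 1:3) for (b in BASES) {
      if (b == ci[pos]) next
      cj <- ci; cj[pos] <- b
      j <- match(paste(cj, collapse = ""), CODONS61)
      if (is.na(j)) next
      rows[[length(rows) + 1L]] <- c(i, j, match(b, BASES),
                                     is_transition(ci[pos], b),
                                     CODON_AA[i] != CODON_AA[j])
    }
  }
  m <- do.call(rbind, rows)
  list(i = m[, 1], j = m[, 2], b = m[, 3],
       ti = as.logical(m[, 4]), ns = as.logical(m[, 5]))
})

# MG94 rate matrix, scaled to one expected substitution per codon per unit t
mg94_q <- function(kappa, omega, pi_nt, pi_cod = codon_freqs_f1x4(pi_nt)) {
  n <- length(CODONS61)
  rates <- pi_nt[MG94_IDX$b] *
    ifelse(MG94_IDX$ti, kappa, 1) * ifelse(MG94_IDX$ns, omega, 1)
  Q <- matrix(0, n, n, dimnames = list(CODONS61, CODONS61))
  Q[cbind(MG94_IDX$i, MG94_IDX$j)] <- rates
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi_cod * diag(Q)))
}

# transition probabilities via symmetric eigendecomposition (reversible Q)
mg94_eig <- function(Q, pi_cod) {
  d <- sqrt(pi_cod)
  B <- (d * Q) %*% diag(1 / d)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(vec = e$vectors, val = e$values, d = d)
}

mg94_p <- function(eig, t) {
  P <- diag(1 / eig$d) %*% eig$vec %*% (exp(eig$val * t) * t(eig$vec)) %*%
    diag(eig$d)
  P[P < 0] <- 0
  P
}

# site patterns: matrix patterns x taxa of codon indices (NA = missing)
codon_patterns <- function(ca) {
  taxa <- names(ca$aln)
  mat <- sapply(taxa, function(tx) {
    cods <- codons_of(ca$aln[[tx]])
    idx <- match(cods, CODONS61)
    idx[cods %in% c("---", "NNN")] <- NA
    # anything unexpected (ambiguity) is treated as missing
    idx
  })
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  usable <- rowSums(!is.na(mat)) >= 2
  mat <- mat[usable, , drop = FALSE]
  key <- apply(mat, 1, paste, collapse = ",")
  tab <- table(key)
  pat <- mat[match(names(tab), key), , drop = FALSE]
  list(patterns = pat, counts = as.integer(tab), taxa = taxa)
}

# pruning log-likelihood on a rooted ape tree; P_edges: list per edge row
prune_lnl <- function(phy, pats, counts, P_edges, pi_cod) {
  po <- ape::reorder.phylo(phy, "postorder")
  n_tip <- length(phy$tip.label)
  n_pat <- nrow(pats)
  L <- vector("list", n_tip + phy$Nnode)
  logscale <- rep(0, n_pat)
  ones <- matrix(1, n_pat, length(CODONS61))
  for (k in seq_len(nrow(po$edge))) {
    child <- po$edge[k, 2]; parent <- po$edge[k, 1]
    Lc <- if (child <= n_tip) {
      tipname <- phy$tip.label[child]
      states <- pats[, tipname]
      M <- ones
      has <- !is.na(states)
      # message to the parent: P[s_parent, tip_state], i.e. columns of P
      M[has, ] <- t(P_edges[[k]])[states[has], , drop = FALSE]
      M
    } else {
      L[[child]] %*% t(P_edges[[k]])
    }
    if (is.null(L[[parent]])) L[[parent]] <- Lc else
      L[[parent]] <- L[[parent]] * Lc
  }
  root <- n_tip + 1L
  site <- as.vector(L[[root]] %*% pi_cod)
  sum(counts * log(pmax(site, 1e-300))) + sum(logscale)
}

# order edges as in phy$edge reordered postorder (helper for P assignment)
postorder_edges <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  match(paste(po$edge[, 1], po$edge[, 2]),
        paste(phy$edge[, 1], phy$edge[, 2]))
}

mg94_lnl <- function(phy, pats, counts, t_edges, kappa, omega_edges, pi_nt,
                     pi_cod = codon_freqs_f1x4(pi_nt),
                     po_map = postorder_edges(phy)) {
  eigs <- list()
  P_edges <- vector("list", nrow(phy$edge))
  for (k in seq_len(nrow(phy$edge))) {
    om <- omega_edges[k]
    key <- sprintf("%.12g", om)
    if (is.null(eigs[[key]]))
      eigs[[key]] <- mg94_eig(mg94_q(kappa, om, pi_nt, pi_cod), pi_cod)
    P_edges[[k]] <- mg94_p(eigs[[key]], t_edges[k])
  }
  prune_lnl(phy, pats, counts, P_edges[po_map], pi_cod)
}

nt_freqs_of <- function(ca) {
  s <- paste(gsub("-|N", "", ca$aln), collapse = "")
  ch <- strsplit(s, "")[[1]]
  tab <- table(factor(ch, levels = BASES))
  p <- as.numeric(tab) + 1
  stats::setNames(p / sum(p), BASES)
}

#' Fit branch omega models by maximum likelihood
#'
#' MG94xHKY codon model with F1x4 frequencies: kappa and branch lengths are
#' estimated jointly (the species-tree topology is fixed, branch lengths are
#' re-estimated on the codon scale). The alternative model frees omega (one
#' shared value in `"single"` mode, one per branch in `"per-branch"` mode);
#' the null fixes omega = 1 (neutrality) on the tested branches. The LRT
#' statistic `2(lnL_alt - lnL_null)` is referred to a chi-squared
#' distribution with df = number of freed omega parameters; `significant`
#' flags p < 0.05. Mode `"auto"` follows the sister-count rule: a single
#' omega when only one sister sequence is available, per-branch otherwise.
#'
#' @param ca a `codon_alignment` from [backtranslate()].
#' @param tree a `species_tree` or `ape::phylo` covering the alignment's
#'   taxa (extra leaves are dropped).
#' @param mode `"auto"`, `"single"`, or `"per-branch"`.
#' @param min_codons minimum number of usable codon columns.
#' @return Object of class `omega_fit`; or a typed
#'   `list(status = "insufficient-data", reason = ...)` when the alignment
#'   cannot identify omega (fewer than two taxa, too few columns, or no
#'   substitutions).
#' @export
fit_omega <- function(ca, tree, mode = c("auto", "single", "per-branch"),
                      min_codons = 20L) {
  mode <- match.arg(mode)
  taxa <- names(ca$aln)
  if (length(taxa) < 2)
    return(insufficient("fewer than two taxa"))
  phy <- if (inherits(tree, "species_tree")) tree$phy else tree
  drop <- setdiff(phy$tip.label, taxa)
  if (length(drop) > 0) phy <- ape::drop.tip(phy, drop)
  assert_that(setequal(phy$tip.label, taxa),
              "tree does not cover all alignment taxa")
  pc <- codon_patterns(ca)
  n_usable <- sum(pc$counts)
  if (n_usable < min_codons)
    return(insufficient(paste0("only ", n_usable, " usable codon columns")))
  # substitutions present?
  var_pat <- apply(pc$patterns, 1, function(r) {
    r <- r[!is.na(r)]; length(unique(r)) > 1
  })
  if (!any(var_pat))
    return(insufficient("no substitutions (omega unidentifiable)"))
  if (mode == "auto") mode <- if (length(taxa) <= 2) "single" else
    "per-branch"
  pi_nt <- nt_freqs_of(ca)
  n_edge <- nrow(phy$edge)
  n_omega <- if (mode == "single") 1L else n_edge

  pi_cod <- codon_freqs_f1x4(pi_nt)
  po_map <- postorder_edges(phy)
  phy_post <- ape::reorder.phylo(phy, "postorder")
  make_lnl <- function(free_omega) {
    function(par) {
      t_edges <- exp(par[seq_len(n_edge)])
      kappa <- exp(par[n_edge + 1L])
      omega_edges <- if (free_omega) {
        if (mode == "single") rep(exp(par[n_edge + 2L]), n_edge) else
          exp(par[n_edge + 1L + seq_len(n_edge)])
      } else rep(1, n_edge)
      -mg94_lnl(phy, pc$patterns, pc$counts, t_edges, kappa, omega_edges,
                pi_nt, pi_cod = pi_cod, po_map = po_map)
    }
  }
  fit_one <- function(free_omega, starts) {
    best <- NULL
    for (s in starts) {
      par0 <- c(rep(log(0.1), n_edge), log(2),
                if (free_omega) rep(log(s), n_omega))
      o <- try(stats::optim(par0, make_lnl(free_omega), method = "L-BFGS-B",
                            lower = rep(log(1e-4), length(par0)),
                            upper = rep(log(50), length(par0)),
                            control = list(maxit = 500, factr = 1e9)),
               silent = TRUE)
      if (inherits(o, "try-error")) next
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best))
      stop("optimizer failed on all restarts", call. = FALSE)
    best
  }
  # per-branch mode has many parameters; one start keeps it tractable
  alt <- fit_one(TRUE, if (mode == "single") c(0.5, 2) else 0.8)
  null <- fit_one(FALSE, 1)
  lnl_alt <- -alt$value; lnl_null <- -null$value
  lrt <- max(0, 2 * (lnl_alt - lnl_null))
  df <- n_omega
  p <- stats::pchisq(lrt, df = df, lower.tail = FALSE)
  omega_hat <- exp(alt$par[n_edge + 1L + seq_len(n_omega)])
  branch_labels <- if (mode == "single") "all" else
    apply(phy$edge, 1, function(e) {
      child <- e[2]
      if (child <= length(phy$tip.label)) phy$tip.label[child] else
        paste0("node", child)
    })
  structure(list(
    status = "ok", mode = mode, taxa = taxa, n_codons = n_usable,
    kappa = exp(alt$par[n_edge + 1L]),
    t_edges = exp(alt$par[seq_len(n_edge)]),
    omega = new_tbl(branch = branch_labels,
                    omega = if (mode == "single") omega_hat else omega_hat),
    lnL_alt = lnl_alt, lnL_null = lnl_null, lrt = lrt, df = df,
    p_value = p, significant = p < 0.05,
    convergence = alt$convergence == 0,
    masked = ca$masked), class = "omega_fit")
}

insufficient <- function(reason) {
  structure(list(status = "insufficient-data", reason = reason),
            class = "omega_fit")
}

#' @export
print.omega_fit <- function(x, ...) {
  if (x$status != "ok") {
    cat("omega_fit: insufficient data (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("omega_fit (", x$mode, "): lnL_alt=", round(x$lnL_alt, 3),
      " lnL_null=", round(x$lnL_null, 3), " LRT=", round(x$lrt, 3),
      " df=", x$df, " p=", signif(x$p_value, 3), "\n", sep = "")
  print(as.data.frame(x$omega))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-branch omega estimates
#' @param x an `omega_fit`.
#' @param ... unused.
#' @method tidy omega_fit
#' @export
tidy.omega_fit <- function(x, ...) {
  if (x$status != "ok")
    return(new_tbl(branch = character(), omega = numeric()))
  x$omega
}

#' One-row model summary of an `omega_fit`
#' @param x an `omega_fit`.
#' @param ... unused.
#' @method glance omega_fit
#' @export
glance.omega_fit <- function(x, ...) {
  if (x$status != "ok")
    return(new_tbl(status = x$status, reason = x$reason))
  new_tbl(status = "ok", mode = x$mode, n_taxa = length(x$taxa),
          n_codons = x$n_codons, kappa = x$kappa, lnL_alt = x$lnL_alt,
          lnL_null = x$lnL_null, lrt = x$lrt, df = x$df,
          p_value = x$p_value, significant = x$significant)
}

# --- NG86 ------------------------------------------------------------------

#' Nei--Gojobori (1986) pathway counting with Jukes--Cantor correction
#'
#' Counts synonymous/nonsynonymous sites and differences (averaging over all
#' mutational pathways between codons; paths through stop codons are
#' excluded) and applies the Jukes--Cantor multiple-hit correction. `omega`
#' is `NA` when `dS` is zero or the correction is undefined.
#'
#' @param cds1,cds2 equal-length, gap-free, stop-free in-frame CDS strings.
#' @return One-row tibble: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`,
#'   `omega`.
#' @export
ng86 <- function(cds1, cds2) {
  assert_that(nchar(cds1) == nchar(cds2), "sequences differ in length")
  assert_that(nchar(cds1) %% 3L == 0L, "length not a multiple of three")
  c1 <- codons_of(toupper(cds1)); c2 <- codons_of(toupper(cds2))
  assert_that(!any(c(c1, c2) %in% STOP_CODONS),
              "stop codons are not allowed")
  assert_that(!any(grepl("[^ACGT]", c(c1, c2))), "only ACGT allowed")
  syn_sites <- function(cod) {
    ch <- strsplit(cod, "")[[1]]
    aa <- CODON_AA[[cod]]
    s <- 0
    for (pos in 1:3) {
      alt <- setdiff(BASES, ch[pos])
      ok <- 0L; syn <- 0L
      for (b in alt) {
        cj <- ch; cj[pos] <- b
        cod_j <- paste(cj, collapse = "")
        if (cod_j %in% STOP_CODONS) next
        ok <- ok + 1L
        if (CODON_AA[[cod_j]] == aa) syn <- syn + 1L
      }
      if (ok > 0) s <- s + syn / ok
    }
    s
  }
  path_counts <- function(a, b) {
    # average syn/nonsyn steps over all orderings of the differing positions
    diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (length(diffs) == 0) return(c(0, 0))
    perms <- if (length(diffs) == 1) list(diffs) else {
      if (length(diffs) == 2) list(diffs, rev(diffs)) else {
        idx <- list()
        for (x in seq_along(diffs)) for (y in seq_along(diffs)) for (z in
          seq_along(diffs)) if (length(unique(c(x, y, z))) == 3)
            idx[[length(idx) + 1L]] <- diffs[c(x, y, z)]
        idx
      }
    }
    tot <- c(0, 0); used <- 0L
    bt <- strsplit(b, "")[[1]]
    for (p in perms) {
      cur <- strsplit(a, "")[[1]]
      steps <- c(0, 0); valid <- TRUE
      for (pos in p) {
        nxt <- cur; nxt[pos] <- bt[pos]
        cod_a <- paste(cur, collapse = ""); cod_b <- paste(nxt, collapse = "")
        if (cod_b %in% STOP_CODONS) { valid <- FALSE; break }
        if (CODON_AA[[cod_a]] == CODON_AA[[cod_b]])
          steps[1] <- steps[1] + 1 else steps[2] <- steps[2] + 1
        cur <- nxt
      }
      if (valid) { tot <- tot + steps; used <- used + 1L }
    }
    if (used == 0) {
      # all paths blocked by stops: count every difference nonsynonymous
      return(c(0, length(diffs)))
    }
    tot / used
  }
  S <- mean(c(sum(vapply(c1, syn_sites, numeric(1))),
              sum(vapply(c2, syn_sites, numeric(1)))))
  N <- 3 * length(c1) - S
  sd_nd <- Reduce(`+`, Map(path_counts, c1, c2))
  pS <- sd_nd[1] / S; pN <- sd_nd[2] / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (is.na(dS) || dS <= 0) NA_real_ else dN / dS
  new_tbl(S = S, N = N, Sd = sd_nd[1], Nd = sd_nd[2], pS = pS, pN = pN,
          dS = dS, dN = dN, omega = omega)
}

#' Simulate a codon alignment under MG94xHKY
#'
#' Root codons are drawn from the F1x4 stationary distribution and evolved
#' along the tree with the model's transition probabilities; used for
#' parameter-recovery and LRT-calibration checks.
#'
#' @param phy an `ape::phylo` with branch lengths in expected
#'   substitutions/codon (or a single numeric: a two-taxon tree with that
#'   total divergence, taxa `"t1"`, `"t2"`).
#' @param n_codons alignment length in codons.
#' @param omega,kappa model parameters (single omega on all branches).
#' @param pi_nt nucleotide frequencies.
#' @return A `codon_alignment`.
#' @export
simulate_codon_alignment <- function(phy, n_codons, omega = 1, kappa = 2,
                                     pi_nt = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25)) {
  if (is.numeric(phy) && length(phy) == 1) {
    phy <- ape::read.tree(text = sprintf("(t1:%f,t2:%f);", phy / 2, phy / 2))
  }
  pi_cod <- codon_freqs_f1x4(pi_nt)
  eig <- mg94_eig(mg94_q(kappa, omega, pi_nt, pi_cod), pi_cod)
  n_tip <- length(phy$tip.label)
  states <- vector("list", n_tip + phy$Nnode)
  root <- n_tip + 1L
  states[[root]] <- sample.int(61L, n_codons, replace = TRUE, prob = pi_cod)
  edges <- ape::reorder.phylo(phy, "cladewise")$edge
  lens <- phy$edge.length[match(paste(edges[, 1], edges[, 2]),
                                paste(phy$edge[, 1], phy$edge[, 2]))]
  for (k in seq_len(nrow(edges))) {
    P <- mg94_p(eig, lens[k])
    from <- states[[edges[k, 1]]]
    states[[edges[k, 2]]] <- vapply(from, function(s)
      sample.int(61L, 1L, prob = pmax(P[s, ], 0)), integer(1))
  }
  aln <- stats::setNames(vapply(seq_len(n_tip), function(i)
    paste(CODONS61[states[[i]]], collapse = ""), character(1)),
    phy$tip.label)
  structure(list(aln = aln,
                 masked = new_tbl(taxon = character(), codon = integer()),
                 n_col = n_codons), class = "codon_alignment")
}
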