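#' Run the full orphan-gene pipeline on a dataset
#'
#' classify -> trace -> validate-structure -> synteny -> mechanisms ->
#' selection, writing deterministic TSV/JSON outputs and a summary. All
#' thresholds default to the reference configuration (cascade 1e-3 / 1e-5 /
#' 1e-3, protein-only orphan split at 1e-3, read support 2, relaxed
#' detector threshold 10 with the noise gate) and every threshold used is
#' recorded in `log.txt`. Outputs are byte-identical across reruns with the
#' same inputs and seed.
#'
#' @param ds an `orphan_dataset`, or a directory written by
#'   [write_dataset()].
#' @param out_dir output directory.
#' @param seed seed for any stochastic step (none of the default steps draw
#'   random numbers; kept for interface stability).
#' @param steps character vector of enabled steps, a subset of
#'   `c("classify", "trace", "validate", "map", "mechanisms", "selection")`.
#'   Later steps silently skip when a step they need is disabled.
#' @param params named list overriding thresholds: `e_step1`, `e_step2`,
#'   `e_step3`, `e_ingroup`, `min_reads`, `e_relaxed`, `noise_margin`.
#' @return Invisibly, a list with the in-memory results (`classification`,
#'   `traces`, `statuses`, `high_confidence`, `synteny`, `mechanisms`,
#'   `selection`, `summary`).
#' @export
run_pipeline <- function(ds, out_dir, seed = 1L,
                         steps = c("classify", "trace", "validate", "map",
                                   "mechanisms", "selection"),
                         params = list()) {
  if (is.character(ds)) ds <- read_dataset(ds)
  set.seed(seed)
  p <- utils::modifyList(list(e_step1 = 1e-3, e_step2 = 1e-5,
                              e_step3 = 1e-3, e_ingroup = 1e-3,
                              min_reads = 2L, e_relaxed = 10,
                              noise_margin = 15), params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("phylorphan pipeline",
                 paste0("seed=", seed),
                 paste0("steps=", paste(steps, collapse = ",")),
                 vapply(names(p), function(k)
                   paste0(k, "=", format(p[[k]])), character(1)))
  res <- list()

  focal_genes <- ds$genes[ds$genes$species == ds$focal, ]

  if ("classify" %in% steps) {
    cls <- classify_genes(ds, e_step1 = p$e_step1, e_step2 = p$e_step2,
                          e_step3 = p$e_step3, e_ingroup = p$e_ingroup)
    cls$final_class <- cls$class  # updated by the mechanisms step
    res$classification <- cls
    log_lines <- c(log_lines, paste0("classified_genes=", nrow(cls)))
  }

  ssog_ids <- if (!is.null(res$classification))
    sort(res$classification$gene_id[
      res$classification$species == ds$focal &
        res$classification$class == "SSOG"]) else character(0)

  if ("trace" %in% steps && length(ssog_ids) > 0) {
    res$traces <- trace_homology(ssog_ids, ds)
    log_lines <- c(log_lines,
                   paste0("traced_ssogs=", length(ssog_ids)))
  }

  if ("validate" %in% steps) {
    stranded <- isTRUE((ds$config %||% list(stranded = TRUE))$stranded)
    rows <- focal_genes[match(ssog_ids, focal_genes$gene_id), ]
    if (length(ssog_ids) > 0)
      res$statuses <- validate_structures(rows, ds$reads,
                                          stranded = stranded,
                                          min_reads = p$min_reads)
  }

  if (!is.null(res$traces) && !is.null(res$statuses))
    res$high_confidence <- high_confidence_set(ssog_ids, res$traces,
                                               res$statuses)

  if ("map" %in% steps) {
    spans <- gene_spans(ds$genes)
    li <- ladder_index(ds$tree)
    sisters <- li$species[seq_len(min(4L, nrow(li)))]
    blocks <- lapply(sisters, function(sp) {
      hits <- search_homology(ds$proteins[[ds$focal]], ds$proteins[[sp]],
                              search_params("pp", e_max = p$e_ingroup))
      find_synteny_blocks(hits, spans)
    })
    names(blocks) <- sisters
    res$synteny <- dplyr::bind_rows(blocks)
  }

  if ("mechanisms" %in% steps && !is.null(res$high_confidence) &&
      !is.null(res$classification)) {
    res$mechanisms <- call_mechanisms(ds, res$high_confidence,
                                      res$classification,
                                      statuses = res$statuses,
                                      e_relaxed = p$e_relaxed,
                                      noise_margin = p$noise_margin)
    reclassified <- attr(res$mechanisms, "reclassified")
    res$classification$final_class[
      res$classification$gene_id %in% reclassified] <- "TROG"
  }

  if ("selection" %in% steps && !is.null(res$mechanisms)) {
    res$selection <- selection_on_candidates(ds, res$mechanisms)
  }

  write_pipeline_outputs(ds, res, out_dir, log_lines)
  invisible(res)
}

# selection analysis of the de novo candidates: extracted sister frames
# (stops masked) against the focal ORF, omega by ML with the LRT
selection_on_candidates <- function(ds, mechanisms) {
  cand <- mechanisms$gene_id[mechanisms$mechanism == "de-novo"]
  out <- list()
  focal_genes <- ds$genes[ds$genes$species == ds$focal, ]
  for (gid in cand) {
    ev <- mechanisms$evidence[[which(mechanisms$gene_id == gid)]]
    gene <- focal_genes[focal_genes$gene_id == gid, ]
    cds <- gene_cds_seq(gene[1, ], ds$genomes[[ds$focal]])
    cds <- substr(cds, 1L, nchar(cds) - 3L)  # drop terminal stop
    rows <- stats::setNames(list(cds), ds$focal)
    for (st in ev$per_species) {
      if (st$status == "unalignable") next
      codons <- st$codons
      if (is.null(codons)) next
      codons[is.na(codons)] <- "NNN"
      rows[[st$species]] <- paste(utils::head(codons, nchar(cds) %/% 3L),
                                  collapse = "")
    }
    if (length(rows) < 2) next
    prots <- vapply(rows, function(s) {
      p <- translate_nt(gsub("NNN", "NNN", s))
      p
    }, character(1))
    aln <- align_proteins(prots)
    ca <- backtranslate(aln, unlist(rows))
    fit <- fit_omega(ca, ds$tree)
    g <- glance(fit)
    g$gene_id <- gid
    if (fit$status == "ok")
      g$omega_branches <- paste(sprintf("%s=%.3g", fit$omega$branch,
                                        fit$omega$omega), collapse = ";")
    out[[gid]] <- g
  }
  if (length(out) == 0) return(NULL)
  dplyr::bind_rows(out)
}

write_pipeline_outputs <- function(ds, res, out_dir, log_lines) {
  tsv <- function(x, name) write_tsv_plain(x, file.path(out_dir, name))
  if (!is.null(res$classification)) {
    cls <- res$classification
    cls$hit_species <- NULL
    tsv(cls, "classification.tsv")
  }
  if (!is.null(res$traces)) {
    wide <- tidyr::pivot_wider(
      res$traces$cells,
      names_from = c("species", "db_kind"), values_from = "hit")
    wide <- dplyr::left_join(wide, res$traces$summary[, c("gene_id",
                                                          "category")],
                             by = "gene_id")
    tsv(wide[order(wide$gene_id), ], "trace_matrix.tsv")
  }
  if (!is.null(res$statuses)) {
    st <- res$statuses
    st$exon_support <- vapply(st$exon_support, paste, "", collapse = ",")
    st$junction_support <- vapply(st$junction_support, paste, "",
                                  collapse = ",")
    tsv(st[order(st$gene_id), ], "structure_status.tsv")
  }
  if (!is.null(res$high_confidence))
    writeLines(res$high_confidence, file.path(out_dir,
                                              "high_confidence.txt"))
  if (!is.null(res$synteny)) {
    syn <- res$synteny
    if (nrow(syn) > 0) {
      syn$anchor_genes <- vapply(syn$anchors, function(a)
        paste(a$gene_a, a$gene_b, sep = "~", collapse = ","), character(1))
    }
    syn$anchors <- NULL
    tsv(syn, "synteny_blocks.tsv")
  }
  if (!is.null(res$mechanisms)) {
    me <- res$mechanisms
    ev <- stats::setNames(me$evidence, me$gene_id)
    me$evidence <- NULL
    tsv(me, "mechanisms.tsv")
    jsonlite::write_json(ev, file.path(out_dir, "mechanisms_evidence.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(res$selection))
    tsv(res$selection, "selection.tsv")

  # summary: per-species class fractions, focal phylostratum counts,
  # trace categories, mechanism tally
  summary <- list()
  if (!is.null(res$classification)) {
    cls <- res$classification
    frac <- lapply(split(cls$class, cls$species), function(x) {
      tab <- table(factor(x, levels = c("Conserved", "TROG", "SSOG")))
      as.list(round(as.numeric(tab) / length(x), 4) |>
                stats::setNames(names(tab)))
    })
    summary$class_fractions <- frac
    foc <- cls[cls$species == ds$focal & cls$class != "Conserved", ]
    ps <- table(factor(foc$phylostratum,
                       levels = 0:(length(ds$species) - 1)))
    summary$phylostratum_counts <- as.list(stats::setNames(
      as.integer(ps), paste0("ps", names(ps))))
  }
  if (!is.null(res$traces))
    summary$trace_categories <- as.list(table(res$traces$summary$category))
  if (!is.null(res$high_confidence))
    summary$n_high_confidence <- length(res$high_confidence)
  if (!is.null(res$mechanisms))
    summary$mechanism_tally <- as.list(table(res$mechanisms$mechanism))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sl <- utils::stack(unlist(summary))
  names(sl) <- c("value", "key")
  write_tsv_plain(sl[, c("key", "value")], file.path(out_dir,
                                                     "summary.tsv"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}
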