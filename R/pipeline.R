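# End-to-end pipeline over a simulated (or loaded) paired multiome dataset.

#' Run the full fate-map multiome pipeline
#'
#' QC cascade and lineage purge, fate-map labelling, normalisation, PCA/LSI,
#' equal-weight joint graph and clustering, gene activity, three-assay
#' markers and the multiomic signature, per-condition peak-gene links with
#' regulome counts, exclusive intersections and induced-peak ranking, the
#' Th2-locus report, motif scanning/deviations/enrichment with TF
#' cross-referencing, and preranked GSEA on the fate-map ranking. Fully
#' deterministic given the seed.
#'
#' @param dataset A `multiome_dataset` (e.g. from [simulate_multiome()]).
#' @param config A `run_config`.
#' @param motifs Named PFM list for the motif stages (optional).
#' @param motif_to_gene Motif-to-TF-gene map tibble (optional).
#' @param gene_sets GMT-style list for GSEA (optional).
#' @param signature_genes Optional gene set for the regulome stage; default
#'   is the multiomic signature union.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list of class `fmm_pipeline` with one element per stage.
#' @export
run_multiome_pipeline <- function(dataset, config = default_run_config(),
                                  motifs = NULL, motif_to_gene = NULL,
                                  gene_sets = NULL, signature_genes = NULL,
                                  seed = config$seed) {
  config$seed <- as.integer(seed)
  qc <- run_qc(dataset, config)
  ds <- qc$dataset

  norm_rna <- normalize_rna(ds$rna)
  tfidf <- run_tfidf(ds$atac)
  pca <- run_pca(norm_rna, config$n_pcs)
  lsi <- run_lsi(tfidf, max(config$lsi_dims))
  graph <- joint_neighbor_graph(pca, lsi, config$knn_k)
  clusters <- cluster_graph(graph, config$cluster_resolution, seed)

  ga <- gene_activity(ds$fragments, ds$genes, ds$rna$barcodes)
  ga_norm <- normalize_rna(ga, allow_zero_cells = TRUE)

  ilc2 <- identify_ilc2_cluster(norm_rna, clusters)
  gex_mk <- find_markers(norm_rna, clusters, ilc2, config$marker_min_pct,
                         config$marker_logfc)
  ga_mk <- find_markers(ga_norm, clusters, ilc2, config$marker_min_pct,
                        config$marker_logfc)
  latent <- Matrix::colSums(ds$atac$values)
  da <- find_da_peaks(tfidf, clusters, ilc2, latent, config$da_min_pct,
                      gene_model = ds$genes, peaks = ds$peaks,
                      max_dist = config$nearest_gene_max_dist)
  signature <- build_signature(gex_mk, ga_mk, da, config$signature_top_n)

  fate <- qc$fate_map
  labels <- tibble::tibble(barcode = fate$barcode, fate_map = fate$label)
  if (!is.null(ds$cells) && "disease" %in% names(ds$cells)) {
    labels$disease <- ds$cells$disease[match(labels$barcode,
                                             ds$cells$barcode)]
  }
  gene_set <- signature_genes %||% signature$union
  fate_labels <- dplyr::mutate(labels, condition = .data$fate_map)
  by_fate <- links_by_condition(ds, fate_labels, gene_set = gene_set,
                                config = config)
  regulome <- regulome_counts(by_fate[["RAG_NAIVE"]], by_fate[["RAG_EXP"]],
                              gene_set = gene_set)
  by_state <- NULL; intersections <- NULL; induced <- NULL
  if ("disease" %in% names(labels)) {
    by_state <- links_by_condition(ds, labels, gene_set = gene_set,
                                   config = config)
    system <- lapply(by_state, dedup_peaks)
    intersections <- exclusive_intersections(system)
    induced <- induced_peak_genes(system, by_state)
  }
  th2 <- NULL
  if (all(th2_locus_genes() %in% ds$genes$gene) &&
      "disease" %in% names(labels)) {
    th2 <- th2_locus_report(ds, labels, config)
  }

  motif_res <- NULL
  if (!is.null(motifs)) {
    hits <- scan_motifs(dataset$peak_seqs, motifs)
    devs <- motif_deviations(ds$atac, hits[, ds$atac$feature_ids,
                                           drop = FALSE],
                             ds$peaks$gc[match(ds$atac$feature_ids,
                                               ds$peaks$peak)],
                             seed = seed)
    fg <- da$peak[da$p_adj < 0.05 & da$log_fc > 0]
    enr <- if (length(fg)) {
      enrich_motifs(fg, ds$atac$feature_ids, hits,
                    stats::setNames(ds$peaks$gc, ds$peaks$peak)[
                      ds$atac$feature_ids], seed = seed)
    } else NULL
    xref <- if (!is.null(enr) && !is.null(motif_to_gene)) {
      ilc2_cells <- clusters$barcode[clusters$cluster == ilc2]
      crossref_expression(enr, norm_rna, motif_to_gene, cells = ilc2_cells)
    } else NULL
    motif_res <- list(hits = hits, deviations = devs, enrichment = enr,
                      crossref = xref)
  }

  gsea_res <- NULL; ranked <- NULL
  if (!is.null(gene_sets)) {
    ilc2_cells <- clusters$barcode[clusters$cluster == ilc2]
    if ("disease" %in% names(labels)) {
      ss <- labels$barcode[labels$disease == "SS"]
      ilc2_cells <- intersect(ilc2_cells, ss)
    }
    ranked <- rank_fatemap_degs(norm_rna, fate, cluster_mask = ilc2_cells,
                                min_pct = config$deg_min_pct,
                                logfc_min = config$deg_logfc)
    gsea_res <- gsea_preranked(ranked, gene_sets,
                               min_size = config$gsea_min_size,
                               max_size = config$gsea_max_size,
                               n_perm = config$gsea_n_perm,
                               p_cutoff = config$gsea_p_cutoff, seed = seed)
  }

  structure(list(
    qc = qc$qc, dataset = ds, fate_map = fate, norm_rna = norm_rna,
    tfidf = tfidf, pca = pca, lsi = lsi, clusters = clusters,
    ilc2_cluster = ilc2, gene_activity = ga, gex_markers = gex_mk,
    ga_markers = ga_mk, da_peaks = da, signature = signature,
    links_by_fate = by_fate, regulome = regulome,
    links_by_state = by_state, intersections = intersections,
    induced = induced, th2 = th2, motifs = motif_res, ranked_degs = ranked,
    gsea = gsea_res, config = config, seed = seed
  ), class = "fmm_pipeline")
}

#' Run the pipeline on the default simulated scenario
#'
#' Convenience wrapper: simulates [default_paper_scenario()] and runs
#' [run_multiome_pipeline()] with the scenario's motifs and gene sets.
#'
#' @param seed Integer seed used for both simulation and analysis.
#' @param config A `run_config`.
#' @return List with `sim` (dataset + truth) and `pipeline`.
#' @export
run_default_scenario <- function(seed = 1L,
                                 config = default_run_config()) {
  scen <- default_paper_scenario(seed)
  sim <- simulate_multiome(scen)
  pipe <- run_multiome_pipeline(
    sim$dataset, config,
    motifs = attr(scen, "motifs"),
    motif_to_gene = attr(scen, "motif_to_gene"),
    gene_sets = attr(scen, "gene_sets"),
    seed = seed
  )
  list(sim = sim, pipeline = pipe, scenario = scen)
}

#' @export
print.fmm_pipeline <- function(x, ...) {
  cat(sprintf(paste0("<fmm_pipeline> %d cells after QC/purge, %d clusters ",
                     "(ILC2 = %d), signature of %d genes\n"),
              nrow(x$clusters), length(unique(x$clusters$cluster)),
              x$ilc2_cluster, length(x$signature$union)))
  invisible(x)
}

#' Adjusted Rand index between two label vectors
#'
#' Used to compare cluster assignments with simulated truth labels.
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Write pipeline outputs as TSV/JSON
#'
#' Emits the tables a shell user of the `fmm` CLI expects: per-cell QC,
#' cluster assignments, marker and DA tables, per-condition link tables,
#' regulome counts, exclusive intersections, induced-peak ranking, motif
#' enrichment and deviations summary, the ranked DEG list, GSEA results and
#' the signature JSON.
#'
#' @param pipe An `fmm_pipeline`.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(pipe, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  w <- function(x, f) readr::write_tsv(x, p(f), progress = FALSE)
  w(pipe$qc, "qc.tsv")
  w(pipe$clusters, "clusters.tsv")
  w(pipe$gex_markers, "markers_gex.tsv")
  w(pipe$ga_markers, "markers_ga.tsv")
  w(pipe$da_peaks, "markers_da.tsv")
  jsonlite::write_json(
    list(gex_top = pipe$signature$gex_top, ga_top = pipe$signature$ga_top,
         da_top = pipe$signature$da_top, union = pipe$signature$union,
         overlap_counts = as.list(pipe$signature$overlap_counts)),
    p("signature.json"), auto_unbox = TRUE)
  if (!is.null(pipe$links_by_fate)) {
    w(dplyr::bind_rows(pipe$links_by_fate), "links_by_fate.tsv")
    w(pipe$regulome, "regulome.tsv")
  }
  if (!is.null(pipe$links_by_state)) {
    w(dplyr::bind_rows(pipe$links_by_state), "links_by_state.tsv")
    w(pipe$intersections[, c("combo", "degree", "size")],
      "intersections.tsv")
    w(pipe$induced$ranking, "induced_genes.tsv")
    w(tibble::tibble(peak = pipe$induced$induced_peaks),
      "induced_peaks.tsv")
  }
  if (!is.null(pipe$motifs)) {
    if (!is.null(pipe$motifs$enrichment)) {
      w(pipe$motifs$enrichment, "motif_enrichment.tsv")
    }
    if (!is.null(pipe$motifs$crossref)) {
      w(pipe$motifs$crossref, "motif_crossref.tsv")
    }
    w(tidy(pipe$motifs$deviations), "motif_deviations.tsv")
  }
  if (!is.null(pipe$ranked_degs)) w(pipe$ranked_degs, "ranked_degs.tsv")
  if (!is.null(pipe$gsea)) {
    full <- attr(pipe$gsea, "full")
    full$leading_edge <- vapply(full$leading_edge, paste, character(1),
                                collapse = ",")
    w(full, "gsea.tsv")
  }
  invisible(outdir)
}
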