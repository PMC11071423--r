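# Fate-map differential ranking and preranked gene-set enrichment with
# permutation significance.

#' Ranked fate-map differential genes
#'
#' Runs the marker machinery between RAG-experienced and RAG-naive cells
#' (optionally within a cluster mask) with permissive gates and returns the
#' ranked list: metric = natural-log fold change, positive when higher in
#' RAG-experienced cells; ties broken by -log10(p), then gene name.
#'
#' @param norm_rna A `normalized_matrix`.
#' @param fatemap_labels Tibble (`barcode`, `label` in
#'   `RAG_EXP`/`RAG_NAIVE`).
#' @param cluster_mask Optional barcodes to restrict to (e.g. the ILC2
#'   cluster).
#' @param min_pct,logfc_min Permissive gates (defaults 0.1 / 0.1).
#' @return Tibble (`gene`, `metric`, `p_value`, `pct_in`, `pct_out`) sorted
#'   by decreasing metric; class `ranked_genes`.
#' @export
rank_fatemap_degs <- function(norm_rna, fatemap_labels, cluster_mask = NULL,
                              min_pct = 0.1, logfc_min = 0.1) {
  bcs <- cluster_mask %||% norm_rna$barcodes
  sel <- match(bcs, norm_rna$barcodes)
  sub <- structure(list(values = norm_rna$values[, sel, drop = FALSE],
                        method = norm_rna$method,
                        feature_ids = norm_rna$feature_ids,
                        barcodes = bcs),
                   class = "normalized_matrix")
  lab <- fatemap_labels$label[match(bcs, fatemap_labels$barcode)]
  if (!all(c("RAG_EXP", "RAG_NAIVE") %in% lab)) {
    stop("both fate-map labels must be present within the mask",
         call. = FALSE)
  }
  mk <- find_markers(sub, tibble::tibble(barcode = bcs, cluster = lab),
                     target = "RAG_EXP", min_pct = min_pct,
                     logfc_min = logfc_min)
  out <- tibble::tibble(gene = mk$feature, metric = mk$log_fc,
                        p_value = mk$p_value, pct_in = mk$pct_in,
                        pct_out = mk$pct_out) |>
    dplyr::arrange(dplyr::desc(.data$metric),
                   dplyr::desc(-log10(.data$p_value)), .data$gene)
  class(out) <- c("ranked_genes", class(out))
  out
}

# Weighted Kolmogorov-Smirnov enrichment score from hit positions.
# positions: ranks (1-based, within 1..n) of the set members in the sorted
# list; w: |metric|^weight at those positions. Evaluates the running sum at
# its candidate extrema (just before and at each hit) without materialising
# the full walk.
es_stat <- function(positions, w, n) {
  o <- order(positions)
  pos <- positions[o]
  w <- w[o]
  k <- length(pos)
  sum_w <- sum(w)
  if (sum_w == 0) w <- rep(1 / k, k) else w <- w / sum_w
  miss <- 1 / (n - k)
  cw <- cumsum(w)
  at_hit <- cw - (pos - seq_len(k)) * miss
  before_hit <- c(0, cw[-k]) - (pos - seq_len(k)) * miss
  cand <- c(at_hit, before_hit)
  cand[which.max(abs(cand))]
}

# leading-edge genes for a computed ES
leading_edge <- function(genes_sorted, positions, w, n, es) {
  o <- order(positions)
  pos <- positions[o]
  ww <- w[o]
  k <- length(pos)
  sum_w <- sum(ww)
  ww <- if (sum_w == 0) rep(1 / k, k) else ww / sum_w
  miss <- 1 / (n - k)
  at_hit <- cumsum(ww) - (pos - seq_len(k)) * miss
  if (es >= 0) {
    peak <- which.max(at_hit)
    genes_sorted[pos[seq_len(peak)]]
  } else {
    before_hit <- c(0, cumsum(ww)[-k]) - (pos - seq_len(k)) * miss
    trough <- which.min(before_hit)
    genes_sorted[pos[pos >= pos[trough]]]
  }
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment (hit increments
#' proportional to `|metric|^weight`, uniform miss decrements); ES is the
#' maximum deviation. Significance by gene-label permutation:
#' `p = (1 + #{same-sign |ES_perm| >= |ES|}) / (1 + n_perm)`;
#' `NES = ES / mean(|ES_perm|)` over same-sign permutations; BH across all
#' size-passing sets. The default report keeps `p_adj < p_cutoff`; the full
#' table is attached as attribute `full`.
#'
#' @param ranked A `ranked_genes` tibble (`gene`, `metric`, sorted
#'   descending).
#' @param sets Named list of gene sets ([read_gmt()]).
#' @param min_size,max_size Set-size gates after intersection with the
#'   ranked genes.
#' @param n_perm Number of permutations.
#' @param weight Metric weighting exponent (1 = classic weighted).
#' @param p_cutoff Adjusted-p filter for the default report.
#' @param seed Integer seed.
#' @return Tibble (`set`, `size`, `es`, `nes`, `p_value`, `p_adj`,
#'   `leading_edge` list-column) for sets passing `p_cutoff`; attribute
#'   `full` carries every tested set.
#' @export
gsea_preranked <- function(ranked, sets, min_size = 50, max_size = 500,
                           n_perm = 1000, weight = 1, p_cutoff = 0.05,
                           seed = 1L) {
  if (!nrow(ranked)) stop("empty ranked list", call. = FALSE)
  ord <- order(-ranked$metric)
  genes <- ranked$gene[ord]
  metric <- ranked$metric[ord]
  n <- length(genes)
  wts <- abs(metric)^weight

  members <- lapply(sets, function(s) which(genes %in% s))
  sizes <- lengths(members)
  testable <- sizes >= min_size & sizes <= max_size & sizes < n
  if (any(!testable)) {
    fmm_log("gsea_preranked: %d set(s) size-gated out", sum(!testable))
  }
  keep_sets <- names(sets)[testable]
  if (!length(keep_sets)) {
    out <- tibble::tibble(set = character(), size = integer(),
                          es = numeric(), nes = numeric(),
                          p_value = numeric(), p_adj = numeric(),
                          leading_edge = list())
    attr(out, "full") <- out
    return(out)
  }
  set.seed(seed)
  res <- purrr::map_dfr(keep_sets, function(nm) {
    pos <- members[[nm]]
    k <- length(pos)
    es <- es_stat(pos, wts[pos], n)
    perm <- vapply(seq_len(n_perm), function(b) {
      pp <- sample.int(n, k)
      es_stat(pp, wts[pp], n)
    }, numeric(1))
    same <- perm[sign(perm) == sign(es)]
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    tibble::tibble(set = nm, size = k, es = es, nes = nes, p_value = p,
                   leading_edge = list(leading_edge(genes, pos, wts[pos], n,
                                                    es)))
  })
  res$p_adj <- stats::p.adjust(res$p_value, "BH")
  res <- dplyr::arrange(res, .data$p_value, .data$set)
  res <- res[, c("set", "size", "es", "nes", "p_value", "p_adj",
                 "leading_edge")]
  out <- res[res$p_adj < p_cutoff, ]
  attr(out, "full") <- res
  out
}
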