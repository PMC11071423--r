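# Peak-to-gene links with a matched-background null, per-condition regulome
# counts, peak deduplication, exclusive (UpSet-style) intersections, induced
# peaks and the Th2-locus report.

#' Genes of the Th2 cytokine locus
#' @return Character vector `c("Il4", "Il13", "Rad50", "Il5")`.
#' @export
th2_locus_genes <- function() c("Il4", "Il13", "Rad50", "Il5")

# standardized matching features per peak: GC content, log total
# accessibility, log width
peak_match_features <- function(peaks, peak_norm) {
  tot <- Matrix::rowSums(peak_norm$values)
  f <- cbind(gc = peaks$gc,
             acc = log1p(tot[match(peaks$peak, peak_norm$feature_ids)]),
             width = log(peaks$end - peaks$start))
  apply(f, 2, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
}

#' Peak-to-gene links with a matched-background null
#'
#' Candidate pairs are (gene, peak) with the peak centre within `window` bp
#' of the gene TSS; pairs are tested only if both the gene and the peak are
#' detected in at least `min_cells` cells. The score is the Pearson
#' correlation between normalised peak accessibility and normalised gene
#' expression across cells. The null for each pair is the set of scores of
#' `n_background` peaks matched to the candidate peak on GC content, total
#' accessibility and width (nearest neighbours in standardised 3-feature
#' space, excluding the peak itself); `z = (r - mean(r_bg)) / sd(r_bg)` with
#' a two-sided normal p-value. Links are retained when `p < p_cutoff` and
#' `|r| >= score_cutoff`.
#'
#' @param norm_rna A `normalized_matrix` of gene expression.
#' @param peak_norm A `normalized_matrix` of peak accessibility (TF-IDF).
#' @param gene_model Gene model tibble (with `tss`).
#' @param peaks Peak tibble with `gc` (fraction) per peak.
#' @param window Candidate window around the TSS (bp).
#' @param min_cells Minimum detected cells per gene and per peak.
#' @param n_background Background peaks per candidate peak.
#' @param p_cutoff,score_cutoff Retention thresholds.
#' @param seed Seed for background sampling fallbacks.
#' @param genes Optional gene subset to restrict candidates to.
#' @return A `link_table` tibble (`gene`, `peak`, `score`, `z`, `p_value`,
#'   `condition`), sorted by p; attribute `n_candidates` records the number
#'   of tested pairs.
#' @export
compute_links <- function(norm_rna, peak_norm, gene_model, peaks,
                          window = 1e6, min_cells = 2, n_background = 200,
                          p_cutoff = 0.05, score_cutoff = 0.05, seed = 1L,
                          genes = NULL) {
  stopifnot(identical(norm_rna$barcodes, peak_norm$barcodes))
  gm <- gene_model
  if (!is.null(genes)) gm <- gm[gm$gene %in% genes, ]
  pk <- peaks[match(peak_norm$feature_ids, peaks$peak), ]
  centers <- (pk$start + pk$end) / 2

  # candidate pairs per chromosome
  cand <- purrr::map_dfr(intersect(unique(gm$chrom), unique(pk$chrom)),
                         function(ch) {
    gsel <- which(gm$chrom == ch)
    psel <- which(pk$chrom == ch)
    if (!length(gsel) || !length(psel)) return(NULL)
    d <- abs(outer(gm$tss[gsel], centers[psel], "-"))
    hit <- which(d <= window, arr.ind = TRUE)
    tibble::tibble(gene = gm$gene[gsel[hit[, 1]]],
                   peak_idx = psel[hit[, 2]])
  })
  empty <- tibble::tibble(gene = character(), peak = character(),
                          score = numeric(), z = numeric(),
                          p_value = numeric(), condition = NA_character_)
  if (!nrow(cand)) {
    attr(empty, "n_candidates") <- 0L
    class(empty) <- c("link_table", class(empty))
    return(empty)
  }

  rna_det <- Matrix::rowSums(norm_rna$values > 0)
  peak_det <- Matrix::rowSums(peak_norm$values > 0)
  gi <- match(cand$gene, norm_rna$feature_ids)
  keep <- !is.na(gi) & rna_det[gi] >= min_cells &
    peak_det[cand$peak_idx] >= min_cells
  cand <- cand[keep, ]
  gi <- gi[keep]
  if (!nrow(cand)) {
    attr(empty, "n_candidates") <- 0L
    class(empty) <- c("link_table", class(empty))
    return(empty)
  }

  # correlations between every candidate gene and every peak (needed for
  # backgrounds as well as scores)
  g_idx <- sort(unique(gi))
  R <- as.matrix(norm_rna$values[g_idx, , drop = FALSE])
  P <- as.matrix(peak_norm$values)
  r_sd <- apply(R, 1, stats::sd)
  p_sd <- apply(P, 1, stats::sd)
  ok_gene <- r_sd > 0
  ok_peak <- p_sd > 0
  C <- matrix(NA_real_, length(g_idx), nrow(P))
  if (any(ok_gene) && any(ok_peak)) {
    C[ok_gene, ok_peak] <- stats::cor(t(R[ok_gene, , drop = FALSE]),
                                      t(P[ok_peak, , drop = FALSE]))
  }
  rownames(C) <- norm_rna$feature_ids[g_idx]

  # matched backgrounds: nearest neighbours in standardized feature space
  feats <- peak_match_features(pk, peak_norm)
  pool <- which(ok_peak)
  set.seed(seed)
  u_peaks <- unique(cand$peak_idx)
  bg_sets <- lapply(u_peaks, function(p) {
    others <- setdiff(pool, p)
    if (!length(others)) return(integer(0))
    if (length(others) < n_background) {
      warning("fewer than n_background peaks available; sampling with ",
              "replacement", call. = FALSE)
      return(sample(others, n_background, replace = TRUE))
    }
    d2 <- colSums((t(feats[others, , drop = FALSE]) - feats[p, ])^2)
    others[order(d2, others)[seq_len(n_background)]]
  })
  names(bg_sets) <- as.character(u_peaks)

  gpos <- match(gi, g_idx)
  score <- C[cbind(gpos, cand$peak_idx)]
  z <- p <- rep(NA_real_, nrow(cand))
  for (pstr in names(bg_sets)) {
    pi_ <- as.integer(pstr)
    rows <- which(cand$peak_idx == pi_)
    bg <- bg_sets[[pstr]]
    if (!length(bg)) next
    bgC <- C[gpos[rows], bg, drop = FALSE]
    mu <- rowMeans(bgC, na.rm = TRUE)
    sdv <- apply(bgC, 1, stats::sd, na.rm = TRUE)
    z[rows] <- (score[rows] - mu) / sdv
    p[rows] <- 2 * stats::pnorm(-abs(z[rows]))
  }
  valid <- !is.na(score) & !is.na(p)
  n_cand <- sum(valid)
  retained <- valid & p < p_cutoff & abs(score) >= score_cutoff
  out <- tibble::tibble(
    gene = cand$gene[retained],
    peak = peak_norm$feature_ids[cand$peak_idx[retained]],
    score = score[retained], z = z[retained], p_value = p[retained],
    condition = NA_character_
  )
  out <- dplyr::arrange(out, .data$p_value, .data$gene, .data$peak)
  attr(out, "n_candidates") <- n_cand
  class(out) <- c("link_table", class(out))
  fmm_log("compute_links: %d candidates, %d retained", n_cand, nrow(out))
  out
}

#' Peak-to-gene links computed separately per condition
#'
#' Cells are split by the given labels (fate map, optionally fate map x
#' disease); each condition is normalised and linked independently on its
#' own cells, with a shared background-sampling seed for comparability.
#'
#' @param dataset A `multiome_dataset`.
#' @param labels Tibble with `barcode` and either a `condition` column or
#'   `fate_map` (and optionally `disease`) columns, which are combined as
#'   `"FATE|DISEASE"`.
#' @param gene_set Optional gene filter applied to the results.
#' @param config A `run_config` supplying window/filter parameters.
#' @param min_cells_floor Minimum cells per condition (error below).
#' @return Named list of `link_table`s, one per condition.
#' @export
links_by_condition <- function(dataset, labels = NULL, gene_set = NULL,
                               config = default_run_config(),
                               min_cells_floor = config$link_min_cells_floor) {
  labels <- labels %||% dataset$cells
  if (!"condition" %in% names(labels)) {
    labels$condition <- if ("disease" %in% names(labels)) {
      sim_state(labels$fate_map, labels$disease)
    } else {
      labels$fate_map
    }
  }
  labels <- labels[match(dataset$rna$barcodes, labels$barcode), ]
  conds <- sort(unique(labels$condition))
  out <- lapply(conds, function(cc) {
    bcs <- labels$barcode[labels$condition == cc]
    if (length(bcs) < max(config$link_min_cells, min_cells_floor)) {
      stop("condition '", cc, "' has too few cells (", length(bcs), ")",
           call. = FALSE)
    }
    ds <- filter_dataset(dataset, bcs)
    lt <- compute_links(
      normalize_rna(ds$rna), run_tfidf(ds$atac), ds$genes, ds$peaks,
      window = config$link_window, min_cells = config$link_min_cells,
      n_background = config$link_n_background,
      p_cutoff = config$link_p_cutoff,
      score_cutoff = config$link_score_cutoff, seed = config$seed,
      genes = gene_set
    )
    lt$condition <- cc
    lt
  })
  names(out) <- conds
  out
}

#' Per-gene regulome counts and their fate-map difference
#'
#' Counts links per gene in each population and computes
#' `delta = n_links_naive - n_links_exp`, sorted with naive-rich genes at
#' the top (stable; ties by gene name).
#'
#' @param links_naive,links_exp `link_table`s for the two populations.
#' @param gene_set Optional genes to always report (zero counts included).
#' @return Tibble (`gene`, `n_links_naive`, `n_links_exp`, `delta`).
#' @export
regulome_counts <- function(links_naive, links_exp, gene_set = NULL) {
  tally <- function(lt) dplyr::count(lt, .data$gene)
  genes <- unique(c(gene_set, links_naive$gene, links_exp$gene))
  out <- tibble::tibble(gene = genes) |>
    dplyr::left_join(dplyr::rename(tally(links_naive), n_links_naive = "n"),
                     by = "gene") |>
    dplyr::left_join(dplyr::rename(tally(links_exp), n_links_exp = "n"),
                     by = "gene") |>
    tidyr::replace_na(list(n_links_naive = 0L, n_links_exp = 0L)) |>
    dplyr::mutate(delta = .data$n_links_naive - .data$n_links_exp) |>
    dplyr::arrange(dplyr::desc(.data$delta), .data$gene)
  out
}

#' Deduplicate link peaks
#'
#' Each genomic peak appears once regardless of how many genes it links to
#' (set analysis must not count a region twice).
#'
#' @param links A `link_table` (or anything with a `peak` column).
#' @return Character vector of unique peaks.
#' @export
dedup_peaks <- function(links) unique(links$peak)

#' Exclusive (UpSet-style) intersections of named sets
#'
#' Every element is assigned to exactly one combination: the exact set of
#' conditions containing it. All `2^n - 1` combinations are reported (with
#' zero sizes where empty); sizes sum to the union cardinality.
#'
#' @param system Named list of character vectors (typically the four
#'   deduplicated per-condition peak sets).
#' @return Tibble (`combo`, `degree`, `size`, `members` list-column),
#'   sorted by decreasing size then combo.
#' @export
exclusive_intersections <- function(system) {
  stopifnot(is.list(system), !is.null(names(system)))
  nm <- names(system)
  u <- unique(unlist(system))
  memb <- vapply(system, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1) memb <- matrix(memb, nrow = 1, dimnames = list(NULL,
                                                                     nm))
  key <- apply(memb, 1, function(r) paste(nm[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(nm), function(k) {
    utils::combn(nm, k, paste, collapse = "&")
  }))
  out <- tibble::tibble(
    combo = combos,
    degree = lengths(strsplit(combos, "&", fixed = TRUE)),
    size = unname(vapply(combos, function(cb) sum(key == cb), integer(1))),
    members = lapply(combos, function(cb) u[key == cb])
  )
  dplyr::arrange(out, dplyr::desc(.data$size), .data$combo)
}

#' Disease-induced peaks and their gene ranking
#'
#' Induced peaks are present in both RAG-naive conditions and in
#' RAG-experienced cells under disease, but absent from RAG-experienced
#' steady state: `(naive_SS intersect naive_AD intersect exp_AD) \ exp_SS`.
#' Each induced peak maps back to genes through any condition's links
#' containing it; genes are ranked by their number of distinct induced
#' peaks (ties by name).
#'
#' @param system Named list of four deduplicated peak sets; names must
#'   contain the condition keys used in `required`/`excluded`.
#' @param links_by_cond Named list of per-condition `link_table`s.
#' @param required Conditions whose sets the peak must belong to.
#' @param excluded Condition whose set the peak must not belong to.
#' @return List with `induced_peaks` (character) and `ranking` (tibble
#'   `gene`, `n_induced_peaks`).
#' @export
induced_peak_genes <- function(system, links_by_cond,
                               required = c("RAG_NAIVE|SS", "RAG_NAIVE|AD",
                                            "RAG_EXP|AD"),
                               excluded = "RAG_EXP|SS") {
  stopifnot(all(c(required, excluded) %in% names(system)))
  induced <- Reduce(intersect, system[required])
  induced <- setdiff(induced, system[[excluded]])
  all_links <- dplyr::bind_rows(links_by_cond)
  hits <- all_links[all_links$peak %in% induced, c("gene", "peak")]
  ranking <- hits |>
    dplyr::distinct() |>
    dplyr::count(.data$gene, name = "n_induced_peaks") |>
    dplyr::arrange(dplyr::desc(.data$n_induced_peaks), .data$gene)
  list(induced_peaks = induced, ranking = ranking)
}

#' Regulome report for the Th2 cytokine locus
#'
#' Runs the full per-condition linkage machinery restricted to the Il4,
#' Il13, Rad50, Il5 locus genes: fate-split regulome counts, the four-set
#' exclusive intersections of deduplicated link peaks, and the
#' induced-peak gene ranking. Cross-gene links within the locus are
#' retained (a peak may count for several genes' regulomes while appearing
#' once in the deduplicated sets).
#'
#' @param dataset A `multiome_dataset` whose `cells` carry `fate_map` and
#'   `disease`.
#' @param labels Optional label tibble (defaults to `dataset$cells`).
#' @param config A `run_config`.
#' @param locus_genes Locus gene list (default [th2_locus_genes()]).
#' @return List with `links` (per state), `regulome` (fate-split counts),
#'   `intersections`, `induced`.
#' @export
th2_locus_report <- function(dataset, labels = NULL,
                             config = default_run_config(),
                             locus_genes = th2_locus_genes()) {
  missing_g <- setdiff(locus_genes, dataset$genes$gene)
  if (length(missing_g)) {
    stop("locus gene(s) missing from annotation: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  }
  labels <- labels %||% dataset$cells
  by_state <- links_by_condition(dataset, labels, gene_set = locus_genes,
                                 config = config)
  fate_labels <- dplyr::mutate(labels, condition = .data$fate_map)
  by_fate <- links_by_condition(dataset, fate_labels, gene_set = locus_genes,
                                config = config)
  regulome <- regulome_counts(by_fate[["RAG_NAIVE"]], by_fate[["RAG_EXP"]],
                              gene_set = locus_genes)
  system <- lapply(by_state, dedup_peaks)
  list(links = by_state,
       regulome = regulome,
       intersections = exclusive_intersections(system),
       induced = induced_peak_genes(system, by_state))
}
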