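# Per-cluster differential tests (expression, gene activity, accessibility),
# nearest-gene assignment for peaks, and the three-way multiomic signature.

cluster_vector <- function(clusters, barcodes) {
  if (is.data.frame(clusters)) {
    cl <- clusters$cluster[match(barcodes, clusters$barcode)]
  } else {
    cl <- unname(clusters[barcodes])
  }
  if (anyNA(cl)) stop("cluster assignment missing for some barcodes",
                      call. = FALSE)
  cl
}

# Seurat-style fold change on log1p-normalised values:
# ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))
log_fc_expm1 <- function(m_in, m_out) {
  mean_in <- Matrix::rowSums(expm1_sparse(m_in)) / ncol(m_in)
  mean_out <- Matrix::rowSums(expm1_sparse(m_out)) / ncol(m_out)
  log((mean_in + 1) / (mean_out + 1))
}

expm1_sparse <- function(m) {
  if (methods::is(m, "sparseMatrix")) {
    m@x <- expm1(m@x)
    m
  } else {
    expm1(m)
  }
}

#' One-vs-rest marker detection (Wilcoxon rank-sum)
#'
#' A feature is tested only if its detection fraction reaches `min_pct` in
#' at least one of the two groups and its fold change passes `logfc_min`
#' (Seurat-style gates). Fold change is the natural-log ratio of
#' depth-normalised group means; the test is the two-sided Wilcoxon
#' rank-sum on the normalised values (exact for small tie-free groups).
#' Adjusted p-values are Bonferroni over the tested features by default.
#'
#' @param norm_matrix A `normalized_matrix`.
#' @param clusters Cluster tibble (`barcode`, `cluster`) or named vector.
#' @param target Cluster id tested against all remaining cells.
#' @param min_pct Minimum detection fraction (in the higher group).
#' @param logfc_min Minimum absolute natural-log fold change.
#' @param p_adjust `"bonferroni"` (default) or `"BH"`.
#' @return Tibble (`feature`, `cluster`, `log_fc`, `pct_in`, `pct_out`,
#'   `p_value`, `p_adj`), sorted by p then decreasing |log_fc|.
#' @export
find_markers <- function(norm_matrix, clusters, target, min_pct = 0.20,
                         logfc_min = 0.25, p_adjust = "bonferroni") {
  cl <- cluster_vector(clusters, norm_matrix$barcodes)
  if (!target %in% cl) stop("unknown cluster id: ", target, call. = FALSE)
  in_grp <- cl == target
  if (sum(in_grp) < 2 || sum(!in_grp) < 2) {
    stop("need at least 2 cells in target and rest", call. = FALSE)
  }
  m <- norm_matrix$values
  m_in <- m[, in_grp, drop = FALSE]
  m_out <- m[, !in_grp, drop = FALSE]
  pct_in <- Matrix::rowSums(m_in > 0) / ncol(m_in)
  pct_out <- Matrix::rowSums(m_out > 0) / ncol(m_out)
  lfc <- log_fc_expm1(m_in, m_out)
  tested <- pmax(pct_in, pct_out) >= min_pct & abs(lfc) >= logfc_min
  idx <- which(tested)
  if (!length(idx)) {
    return(tibble::tibble(feature = character(), cluster = target,
                          log_fc = numeric(), pct_in = numeric(),
                          pct_out = numeric(), p_value = numeric(),
                          p_adj = numeric()))
  }
  dm_in <- as.matrix(m_in[idx, , drop = FALSE])
  dm_out <- as.matrix(m_out[idx, , drop = FALSE])
  p <- vapply(seq_along(idx), function(r) {
    rank_sum_p(dm_in[r, ], dm_out[r, ])
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = tolower(p_adjust))
  out <- tibble::tibble(
    feature = norm_matrix$feature_ids[idx], cluster = target,
    log_fc = lfc[idx], pct_in = pct_in[idx], pct_out = pct_out[idx],
    p_value = p, p_adj = p_adj
  )
  dplyr::arrange(out, .data$p_value, dplyr::desc(abs(.data$log_fc)),
                 .data$feature)
}

#' Markers for every cluster
#' @inheritParams find_markers
#' @return Tibble stacking [find_markers()] over all cluster ids.
#' @export
find_all_markers <- function(norm_matrix, clusters, min_pct = 0.20,
                             logfc_min = 0.25, p_adjust = "bonferroni") {
  ids <- sort(unique(cluster_vector(clusters, norm_matrix$barcodes)))
  purrr::map_dfr(ids, function(id) {
    find_markers(norm_matrix, clusters, id, min_pct, logfc_min, p_adjust)
  })
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact permutation p (tie-aware, by full enumeration of group assignments)
#' when the number of assignments is small enough; otherwise the usual
#' normal approximation with tie correction and continuity correction
#' (`stats::wilcox.test`).
#'
#' @param x,y Numeric samples.
#' @param max_enum Enumeration budget (assignments).
#' @return Two-sided p-value.
#' @export
rank_sum_p <- function(x, y, max_enum = 2e5) {
  n1 <- length(x); n2 <- length(y)
  n_comb <- choose(n1 + n2, n1)
  if (n_comb <= max_enum) {
    r <- rank(c(x, y))
    w_obs <- sum(r[seq_len(n1)])
    combos <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
    return(min(p, 1))
  }
  suppressWarnings(stats::wilcox.test(x, y)$p.value)
}

# Ridge-stabilised logistic regression via IRLS. The tiny default ridge
# leaves well-posed fits unchanged to ~1e-6 but keeps perfectly separated
# fits finite. Returns the (unpenalised) log-likelihood at the estimate.
logistic_fit <- function(X, y, ridge = 1e-8, max_iter = 100) {
  beta <- numeric(ncol(X))
  pen <- diag(ridge, ncol(X))
  pen[1, 1] <- 0  # intercept unpenalised
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xw <- X * w
    beta_new <- tryCatch(
      solve(crossprod(X, xw) + pen, crossprod(xw, z)),
      error = function(e) NULL)
    if (is.null(beta_new)) break
    beta <- drop(beta_new)
    mu <- stats::plogis(drop(X %*% beta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (abs(dev_old - dev) < 1e-10) break
    dev_old <- dev
  }
  mu <- stats::plogis(drop(X %*% beta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  list(beta = beta, loglik = sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

#' Differentially accessible peaks by likelihood-ratio logistic regression
#'
#' Per peak, compares a logistic regression of group membership on
#' {normalised peak value, latent} against {latent} alone; the latent
#' variable (total ATAC fragments by default) absorbs sequencing-depth
#' differences. P-values from the chi-squared(1) likelihood-ratio statistic.
#' Peaks pass the gate if detected in at least `min_pct` of either group.
#' Perfect separation is handled by a ridge-stabilised fit and never
#' produces `NaN`.
#'
#' @param peak_norm A `normalized_matrix` of peak values (TF-IDF).
#' @param clusters Cluster assignment.
#' @param target Target cluster id.
#' @param latent Numeric per-cell latent variable (same order as barcodes);
#'   typically total fragment counts.
#' @param min_pct Detection gate (default 0.02).
#' @param gene_model Optional gene model; when supplied, each peak gets its
#'   nearest gene and records further than `max_dist` are dropped.
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `peak`); required when
#'   `gene_model` is supplied.
#' @param max_dist Maximum peak-to-gene distance in bp (default 1e5).
#' @return Tibble (`peak`, `cluster`, `log_fc`, `pct_in`, `pct_out`,
#'   `p_value`, `p_adj`[, `nearest_gene`, `distance`]), sorted by p.
#' @export
find_da_peaks <- function(peak_norm, clusters, target, latent,
                          min_pct = 0.02, gene_model = NULL, peaks = NULL,
                          max_dist = 1e5) {
  cl <- cluster_vector(clusters, peak_norm$barcodes)
  if (!target %in% cl) stop("unknown cluster id: ", target, call. = FALSE)
  y <- as.numeric(cl == target)
  stopifnot(length(latent) == length(y))
  m <- peak_norm$values
  pct_in <- Matrix::rowSums(m[, y == 1, drop = FALSE] > 0) / sum(y == 1)
  pct_out <- Matrix::rowSums(m[, y == 0, drop = FALSE] > 0) / sum(y == 0)
  lfc <- log_fc_expm1(m[, y == 1, drop = FALSE], m[, y == 0, drop = FALSE])
  idx <- which(pmax(pct_in, pct_out) >= min_pct)
  lat_s <- as.numeric(scale(latent))
  if (all(is.na(lat_s))) lat_s <- rep(0, length(latent))
  X0 <- cbind(1, lat_s)
  ll0 <- logistic_fit(X0, y)$loglik
  dm <- as.matrix(m[idx, , drop = FALSE])
  p <- vapply(seq_along(idx), function(r) {
    v <- dm[r, ]
    if (stats::sd(v) == 0) return(1)
    llf <- logistic_fit(cbind(1, as.numeric(scale(v)), lat_s), y)$loglik
    stat <- max(0, 2 * (llf - ll0))
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }, numeric(1))
  out <- tibble::tibble(
    peak = peak_norm$feature_ids[idx], cluster = target,
    log_fc = lfc[idx], pct_in = pct_in[idx], pct_out = pct_out[idx],
    p_value = p, p_adj = stats::p.adjust(p, "bonferroni")
  )
  out <- dplyr::arrange(out, .data$p_value, dplyr::desc(abs(.data$log_fc)),
                        .data$peak)
  if (!is.null(gene_model)) {
    if (is.null(peaks)) stop("peaks tibble required with gene_model",
                             call. = FALSE)
    ng <- assign_nearest_gene(peaks[peaks$peak %in% out$peak, ], gene_model,
                              max_dist)
    out <- dplyr::inner_join(out, ng, by = "peak")
  }
  out
}

#' Nearest gene for each peak
#'
#' Distance is 0 when the peak overlaps the gene body, otherwise the bp gap
#' between the closest interval boundaries. Records further than `max_dist`
#' are dropped; ties go to the gene with the smaller start coordinate, then
#' the lexicographically smaller name. Peaks on chromosomes without genes
#' are dropped with a warning.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `peak`).
#' @param gene_model Gene model tibble.
#' @param max_dist Maximum distance in bp.
#' @return Tibble (`peak`, `nearest_gene`, `distance`).
#' @export
assign_nearest_gene <- function(peaks, gene_model, max_dist = 1e5) {
  res <- purrr::map_dfr(unique(peaks$chrom), function(ch) {
    psel <- peaks[peaks$chrom == ch, ]
    gsel <- gene_model[gene_model$chrom == ch, ]
    if (!nrow(gsel)) {
      warning("peak(s) on chromosome ", ch, " with no genes; dropped")
      return(tibble::tibble(peak = character(), nearest_gene = character(),
                            distance = numeric()))
    }
    # gap between half-open intervals; 0 on overlap
    d <- pmax(outer(psel$start, gsel$end, "-"),
              outer(gsel$start, -psel$end, "+") |> t(), 0)
    ord_gene <- order(gsel$start, gsel$gene)
    best <- vapply(seq_len(nrow(psel)), function(i) {
      cand <- ord_gene[d[i, ord_gene] == min(d[i, ])]
      cand[1]
    }, integer(1))
    tibble::tibble(peak = psel$peak, nearest_gene = gsel$gene[best],
                   distance = d[cbind(seq_len(nrow(psel)), best)])
  })
  res[res$distance <= max_dist, ]
}

#' Multiomic signature from three marker assays
#'
#' Takes the top `top_n` genes from the expression (GEX), gene-activity (GA)
#' and accessibility (DA) marker lists of one cluster; the DA list is
#' deduplicated to genes (keeping best-p order) before truncation. Returns
#' the union and the sizes of all seven Venn regions.
#'
#' @param gex_markers,ga_markers Sorted marker tibbles ([find_markers()]);
#'   only positive-fold-change records are used.
#' @param da_records Sorted DA tibble with a `nearest_gene` column.
#' @param top_n Genes per assay (default 100).
#' @return A `signature_set`: `gex_top`, `ga_top`, `da_top`, `union`,
#'   `overlap_counts` (named 7-vector).
#' @export
build_signature <- function(gex_markers, ga_markers, da_records,
                            top_n = 100) {
  top_genes <- function(tab, col, label) {
    g <- unique(tab[[col]][tab$log_fc > 0])
    if (length(g) < top_n) {
      warning(label, " list shorter than top_n (", length(g), " < ", top_n,
              "); using full list")
    }
    utils::head(g, top_n)
  }
  gex <- top_genes(gex_markers, "feature", "GEX")
  ga <- top_genes(ga_markers, "feature", "GA")
  da <- top_genes(da_records, "nearest_gene", "DA")
  structure(list(
    gex_top = gex, ga_top = ga, da_top = da,
    union = sort(unique(c(gex, ga, da))),
    overlap_counts = venn3_counts(gex, ga, da)
  ), class = "signature_set")
}

#' Sizes of the seven Venn regions of three sets
#' @param a,b,c Character vectors.
#' @return Named integer vector (`a_only`, `b_only`, `c_only`, `ab`, `ac`,
#'   `bc`, `abc`).
#' @export
venn3_counts <- function(a, b, c) {
  u <- unique(c(a, b, c))
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  c(a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab = sum(ina & inb & !inc),
    ac = sum(ina & !inb & inc),
    bc = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc))
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %d unique genes (GEX %d, GA %d, DA %d)\n",
              length(x$union), length(x$gex_top), length(x$ga_top),
              length(x$da_top)))
  invisible(x)
}
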