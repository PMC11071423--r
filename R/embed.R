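# Normalisation, dimensionality reduction, gene activity, the equal-weight
# joint neighbour graph, and modularity clustering.

#' Normalise RNA (or gene-activity) counts
#'
#' Default is log-CP10K: `log1p(1e4 * x / total)` per cell, which is exactly
#' depth-invariant. An analytic Pearson-residual mode (Poisson mean with a
#' fixed overdispersion of 100, residuals clipped at `sqrt(n_cells)`) is
#' available for variance stabilisation of highly expressed genes.
#'
#' @param counts A [count_matrix()].
#' @param method `"log_cp10k"` (default) or `"pearson"`.
#' @param allow_zero_cells Keep all-zero cells as all-zero columns instead
#'   of raising an error (used for derived assays such as gene activity).
#' @return A `normalized_matrix` (list: `values`, `method`, `feature_ids`,
#'   `barcodes`).
#' @export
normalize_rna <- function(counts, method = c("log_cp10k", "pearson"),
                          allow_zero_cells = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "count_matrix"))
  x <- counts$values
  tot <- Matrix::colSums(x)
  if (any(tot == 0)) {
    if (!allow_zero_cells) {
      stop("cell(s) with zero total counts; filter before normalising",
           call. = FALSE)
    }
    tot[tot == 0] <- 1
  }
  if (method == "log_cp10k") {
    v <- x
    v@x <- log1p(1e4 * v@x / rep.int(tot, diff(v@p)))
    meth <- "LOG_CP10K_RESIDUAL"
  } else {
    xd <- as.matrix(x)
    gene_frac <- rowSums(xd) / sum(xd)
    mu <- outer(gene_frac, tot)
    theta <- 100
    v <- (xd - mu) / sqrt(mu + mu^2 / theta)
    v[!is.finite(v)] <- 0
    clip <- sqrt(ncol(xd))
    v <- pmin(pmax(v, -clip), clip)
    v <- as_dgc(v)
    meth <- "PEARSON_RESIDUAL"
  }
  structure(list(values = v, method = meth,
                 feature_ids = counts$feature_ids,
                 barcodes = counts$barcodes),
            class = "normalized_matrix")
}

#' TF-IDF normalisation of peak counts
#'
#' `log1p(1e4 * TF * IDF)` with `TF = x / cell_total` and
#' `IDF = n_cells / n_cells_with_peak`. Peaks detected in no cell stay
#' all-zero rows.
#'
#' @param peak_counts A [count_matrix()] of peak counts.
#' @return A `normalized_matrix` with method `"TFIDF"`.
#' @export
run_tfidf <- function(peak_counts) {
  stopifnot(inherits(peak_counts, "count_matrix"))
  x <- peak_counts$values
  tot <- Matrix::colSums(x)
  tot[tot == 0] <- 1
  n_with <- Matrix::rowSums(x > 0)
  idf <- ifelse(n_with == 0, 0, ncol(x) / n_with)
  v <- x
  tf <- v@x / rep.int(tot, diff(v@p))
  v@x <- log1p(1e4 * tf * idf[v@i + 1L])
  structure(list(values = v, method = "TFIDF",
                 feature_ids = peak_counts$feature_ids,
                 barcodes = peak_counts$barcodes),
            class = "normalized_matrix")
}

# Deterministic sign convention: each component's largest-|loading| feature
# gets a positive loading.
fix_svd_signs <- function(u, v) {
  for (k in seq_len(ncol(u))) {
    j <- which.max(abs(u[, k]))
    if (u[j, k] < 0) {
      u[, k] <- -u[, k]
      v[, k] <- -v[, k]
    }
  }
  list(u = u, v = v)
}

new_embedding <- function(coords, dims_used, modality, sdev) {
  structure(list(coords = coords, dims_used = dims_used, modality = modality,
                 sdev = sdev), class = "fmm_embedding")
}

#' Latent semantic indexing of a TF-IDF matrix
#'
#' Truncated SVD of the TF-IDF matrix; cell coordinates are `V * D`.
#' Component 1, which tracks sequencing depth, is excluded from
#' `dims_used`.
#'
#' @param tfidf A `normalized_matrix` (method TFIDF).
#' @param n_components Number of singular vectors to keep.
#' @return An `fmm_embedding` with `dims_used = 2:n_components`.
#' @export
run_lsi <- function(tfidf, n_components = 25) {
  x <- as.matrix(tfidf$values)
  if (n_components >= min(dim(x))) {
    stop("n_components must be below min(dim)", call. = FALSE)
  }
  s <- svd(x, nu = n_components, nv = n_components)
  fx <- fix_svd_signs(s$u, s$v)
  coords <- fx$v %*% diag(s$d[seq_len(n_components)], n_components)
  rownames(coords) <- tfidf$barcodes
  colnames(coords) <- paste0("LSI_", seq_len(n_components))
  new_embedding(coords, 2:n_components, "ATAC",
                s$d[seq_len(n_components)])
}

#' Principal component analysis of a normalised matrix
#'
#' Features are centred and unit-scaled (zero-variance features are
#' dropped), then decomposed by SVD; cell scores use the same deterministic
#' sign convention as [run_lsi()].
#'
#' @param norm A `normalized_matrix`.
#' @param n_components Number of components.
#' @return An `fmm_embedding` with `dims_used = 1:n_components`.
#' @export
run_pca <- function(norm, n_components = 25) {
  x <- as.matrix(norm$values)
  if (nrow(x) < n_components) {
    stop("fewer features than components", call. = FALSE)
  }
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  keep <- sdv > 0
  xs <- (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  if (n_components >= min(dim(xs))) {
    stop("n_components must be below min(dim) after dropping constant ",
         "features", call. = FALSE)
  }
  s <- svd(xs, nu = n_components, nv = n_components)
  fx <- fix_svd_signs(s$u, s$v)
  coords <- fx$v %*% diag(s$d[seq_len(n_components)], n_components)
  rownames(coords) <- norm$barcodes
  colnames(coords) <- paste0("PC_", seq_len(n_components))
  new_embedding(coords, seq_len(n_components), "RNA",
                s$d[seq_len(n_components)])
}

#' Gene activity scores from fragments
#'
#' For each gene, sums fragment counts overlapping the gene body extended
#' 2,000 bp upstream of the TSS (strand-aware). A fragment overlapping two
#' genes' windows counts for both.
#'
#' @param fragments Fragment tibble.
#' @param gene_model Gene model tibble (with `tss`).
#' @param barcodes Barcode universe (column order of the result).
#' @param upstream Upstream extension in bp.
#' @return A [count_matrix()] with modality `GENE_ACTIVITY`.
#' @export
gene_activity <- function(fragments, gene_model, barcodes, upstream = 2000) {
  gm <- gene_model
  win_start <- ifelse(gm$strand == "+", gm$start - upstream, gm$start)
  win_end <- ifelse(gm$strand == "+", gm$end, gm$end + upstream)
  bc_idx <- match(fragments$barcode, barcodes)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (ch in intersect(unique(gm$chrom), unique(fragments$chrom))) {
    gsel <- which(gm$chrom == ch)
    fsel <- which(fragments$chrom == ch)
    # half-open intervals -> closed IRanges on [start+1, end]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(fragments$start[fsel] + 1, fragments$end[fsel]),
      IRanges::IRanges(win_start[gsel] + 1, win_end[gsel])
    )
    if (length(hits)) {
      trip_i <- c(trip_i, gsel[S4Vectors::subjectHits(hits)])
      trip_j <- c(trip_j, bc_idx[fsel[S4Vectors::queryHits(hits)]])
      trip_x <- c(trip_x, fragments$count[fsel[S4Vectors::queryHits(hits)]])
    }
  }
  m <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(nrow(gm), length(barcodes)))
  count_matrix(m, gm$gene, barcodes, "GENE_ACTIVITY")
}

# k nearest neighbours (including self) by Euclidean distance; returns an
# n x k index matrix with deterministic tie handling
knn_indices <- function(coords, k) {
  n <- nrow(coords)
  if (k >= n) stop("k must be below the number of cells", call. = FALSE)
  g <- tcrossprod(coords)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g
  idx <- matrix(0L, n, k + 1)
  for (i in seq_len(n)) {
    o <- order(d2[i, ], seq_len(n))  # stable under ties
    o <- c(i, setdiff(o, i))         # self first
    idx[i, ] <- o[seq_len(k + 1)]
  }
  idx
}

snn_adjacency <- function(coords, k, prune = 1 / 15) {
  n <- nrow(coords)
  idx <- knn_indices(coords, k)
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(idx)),
                            j = as.vector(idx), x = 1,
                            dims = c(n, n))
  shared <- Matrix::tcrossprod(a)
  jac <- shared
  jac@x <- jac@x / (2 * (k + 1) - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  Matrix::drop0(jac)
}

#' Joint neighbour graph from the RNA and ATAC embeddings
#'
#' Per-modality shared-nearest-neighbour (SNN) Jaccard similarities are
#' computed on Euclidean k-nearest neighbours over each embedding's
#' `dims_used`; the joint edge weight is their fixed equal-weight average
#' `0.5 * S_rna + 0.5 * S_atac`. The graph is undirected.
#'
#' @param emb_rna,emb_atac `fmm_embedding` objects over the same barcodes in
#'   the same order.
#' @param k Number of nearest neighbours.
#' @param prune Jaccard values below this are dropped (SNN pruning).
#' @return A `neighbor_graph` (list: `adjacency` sparse symmetric matrix,
#'   `barcodes`, `k`).
#' @export
joint_neighbor_graph <- function(emb_rna, emb_atac, k = 20, prune = 1 / 15) {
  if (!identical(rownames(emb_rna$coords), rownames(emb_atac$coords))) {
    stop("embeddings must share barcodes in the same order", call. = FALSE)
  }
  s_rna <- snn_adjacency(emb_rna$coords[, emb_rna$dims_used, drop = FALSE],
                         k, prune)
  s_atac <- snn_adjacency(emb_atac$coords[, emb_atac$dims_used, drop = FALSE],
                          k, prune)
  adj <- 0.5 * s_rna + 0.5 * s_atac
  structure(list(adjacency = adj, barcodes = rownames(emb_rna$coords),
                 k = k),
            class = "neighbor_graph")
}

#' Cluster a neighbour graph
#'
#' Leiden community detection on the weighted joint graph with the
#' modularity objective; the resolution parameter scales the null-model
#' term. Cluster ids are contiguous integers from 0, ordered by decreasing
#' cluster size. Deterministic given the seed.
#'
#' @param graph A `neighbor_graph` (or a square sparse adjacency matrix).
#' @param resolution Resolution parameter.
#' @param seed Integer seed.
#' @param n_iterations Leiden refinement iterations.
#' @return Tibble with `barcode`, `cluster`; attributes `resolution`,
#'   `seed`.
#' @export
cluster_graph <- function(graph, resolution = 0.1, seed = 1L,
                          n_iterations = 5) {
  adj <- if (inherits(graph, "neighbor_graph")) graph$adjacency else graph
  barcodes <- if (inherits(graph, "neighbor_graph")) graph$barcodes else
    rownames(adj) %||% as.character(seq_len(nrow(adj)))
  if (is.null(adj) || nrow(adj) == 0) stop("empty graph", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = n_iterations)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  out <- tibble::tibble(barcode = barcodes,
                        cluster = unname(relabel[as.character(memb)]))
  attr(out, "resolution") <- resolution
  attr(out, "seed") <- seed
  fmm_log("cluster_graph: %d clusters at resolution %g", length(sizes),
          resolution)
  out
}

#' Identify the ILC2 cluster by canonical markers
#'
#' Scores each cluster by the mean normalised expression of a small panel of
#' canonical ILC2 genes and returns the top-scoring cluster id.
#'
#' @param norm_rna A `normalized_matrix`.
#' @param clusters Cluster tibble from [cluster_graph()].
#' @param markers Canonical marker panel.
#' @return A single cluster id.
#' @export
identify_ilc2_cluster <- function(norm_rna, clusters,
                                  markers = c("Gata3", "Il1rl1", "Icos",
                                              "Rora", "Bcl11b")) {
  present <- intersect(markers, norm_rna$feature_ids)
  if (!length(present)) stop("no ILC2 marker genes present", call. = FALSE)
  sc <- Matrix::colMeans(norm_rna$values[present, , drop = FALSE])
  means <- tapply(sc[match(clusters$barcode, norm_rna$barcodes)],
                  clusters$cluster, mean)
  as.integer(names(means)[which.max(means)])
}
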