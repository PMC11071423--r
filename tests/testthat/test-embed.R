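# Normalisation, reductions, gene activity, joint graph and clustering.

test_that("log-CP10K normalisation matches its closed form and is depth-invariant", {
  m <- matrix(c(1, 99, 0, 50), nrow = 2)  # cols: c1 = (1, 99), c2 = (0, 50)
  cm <- count_matrix(m, c("g1", "g2"), c("c1", "c2"), "RNA")
  nr <- normalize_rna(cm)
  expect_equal(nr$values[1, 1], log1p(1e4 * 1 / 100))  # ~ log1p(100)
  expect_equal(nr$values[1, 1], 4.61512, tolerance = 1e-5)
  expect_equal(nr$values[1, 2], 0)  # zero count stays 0

  # doubling all counts in a cell leaves its normalised vector unchanged
  cm2 <- count_matrix(cbind(m[, 1] * 2, m[, 2]), c("g1", "g2"),
                      c("c1", "c2"), "RNA")
  expect_equal(as.matrix(normalize_rna(cm2)$values),
               as.matrix(nr$values))

  zero <- count_matrix(matrix(0, 2, 1), c("g1", "g2"), "c1", "RNA")
  expect_error(normalize_rna(zero), "zero total")
  expect_silent(normalize_rna(zero, allow_zero_cells = TRUE))
})

test_that("TF-IDF matches its closed form and a dense oracle", {
  m <- matrix(c(1, 1), nrow = 1)
  cm <- count_matrix(m, "p1", c("c1", "c2"), "ATAC_PEAKS")
  tf <- run_tfidf(cm)
  expect_equal(as.numeric(tf$values), rep(log1p(1e4), 2), tolerance = 1e-12)
  expect_equal(as.numeric(tf$values)[1], 9.2104, tolerance = 1e-4)

  # peak absent everywhere stays a zero row
  m2 <- rbind(c(2, 3), c(0, 0))
  cm2 <- count_matrix(m2, c("p1", "p2"), c("c1", "c2"), "ATAC_PEAKS")
  expect_equal(as.numeric(run_tfidf(cm2)$values[2, ]), c(0, 0))

  # dense brute force on random counts
  set.seed(1)
  x <- matrix(rpois(200, 1), 20, 10)
  cmr <- count_matrix(x, paste0("p", 1:20), paste0("c", 1:10), "ATAC_PEAKS")
  tfr <- as.matrix(run_tfidf(cmr)$values)
  tot <- colSums(x); tot[tot == 0] <- 1
  nwith <- rowSums(x > 0)
  oracle <- matrix(0, 20, 10)
  for (i in 1:20) for (j in 1:10) {
    if (x[i, j] > 0 && nwith[i] > 0) {
      oracle[i, j] <- log1p(1e4 * (x[i, j] / tot[j]) * (10 / nwith[i]))
    }
  }
  expect_lt(max(abs(tfr - oracle)), 1e-12)

  # TF-IDF is depth-invariant per cell
  x2 <- x; x2[, 3] <- x2[, 3] * 5
  cm3 <- count_matrix(x2, paste0("p", 1:20), paste0("c", 1:10),
                      "ATAC_PEAKS")
  expect_equal(as.matrix(run_tfidf(cm3)$values)[, 3], tfr[, 3])
})

test_that("LSI: rank deficiency, determinism, and the dims convention", {
  # a rank-1 input matrix: components beyond the first explain nothing
  set.seed(21)
  u <- runif(30); v <- runif(12)
  tf <- structure(list(values = methods::as(outer(u, v), "CsparseMatrix"),
                       method = "TFIDF", feature_ids = paste0("p", 1:30),
                       barcodes = paste0("c", 1:12)),
                  class = "normalized_matrix")
  emb <- run_lsi(tf, 5)
  expect_true(all(emb$sdev[2:5] < 1e-8 * emb$sdev[1]))
  expect_equal(emb$dims_used, 2:5)

  emb2 <- run_lsi(tf, 5)
  expect_identical(emb$coords, emb2$coords)  # sign-fixed SVD is deterministic

  expect_error(run_lsi(tf, 50), "below min")
})

test_that("LSI component 1 tracks sequencing depth on simulated data", {
  qc <- get_qc1()
  tf <- run_tfidf(qc$dataset$atac)
  lsi <- run_lsi(tf, 25)
  dep <- log(Matrix::colSums(qc$dataset$atac$values))
  cors <- abs(stats::cor(lsi$coords, dep))
  # the depth signal concentrates in component 1, motivating dims 2..25
  expect_equal(which.max(cors), 1)
  expect_gt(cors[1], 2 * max(cors[-1]))
})

test_that("PCA: planar data, determinism, and type separation", {
  set.seed(4)
  # data on a 2-D plane in feature space
  base <- matrix(rnorm(2 * 40), 2, 40)
  load <- matrix(rnorm(12 * 2), 12, 2)
  x <- load %*% base
  nm <- structure(list(values = methods::as(x, "CsparseMatrix"),
                       method = "LOG_CP10K_RESIDUAL",
                       feature_ids = paste0("g", 1:12),
                       barcodes = paste0("c", 1:40)),
                  class = "normalized_matrix")
  emb <- run_pca(nm, 5)
  expect_true(all(emb$sdev[3:5]^2 < 1e-10 * emb$sdev[1]^2))
  expect_identical(run_pca(nm, 5)$coords, emb$coords)
  expect_error(run_pca(nm, 20), "fewer features")

  # a leading component separates the dominant simulated cell type from
  # the rest with a large effect size (the fate-map axis and the cell-type
  # axis share the top two components)
  qc <- get_qc1()
  nr <- normalize_rna(qc$dataset$rna)
  pca <- run_pca(nr, 10)
  ct <- qc$dataset$cells$cell_type
  d <- vapply(1:2, function(k) {
    a <- pca$coords[ct == "ILC2", k]; b <- pca$coords[ct != "ILC2", k]
    abs(mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
  }, numeric(1))
  expect_gt(max(d), 2)
})

test_that("gene activity windows are strand-aware and match brute force", {
  gm <- validate_gene_model(tibble::tibble(
    gene = "g1", chrom = "chr1", start = 10000, end = 12000, strand = "+"))
  fr <- tibble::tibble(chrom = "chr1",
                       start = c(8500, 7900, 11999),
                       end = c(8600, 7950, 12100),
                       barcode = "c1", count = c(1, 1, 2))
  ga <- gene_activity(fr, gm, "c1")
  # [8500,8600) inside the 2 kb upstream window; [7900,7950) outside;
  # [11999,12100) overlaps the body end -> counted with weight 2
  expect_equal(as.numeric(ga$values["g1", "c1"]), 3)

  # minus-strand gene extends downstream in genome coordinates
  gm2 <- validate_gene_model(tibble::tibble(
    gene = "g1", chrom = "chr1", start = 10000, end = 12000, strand = "-"))
  fr2 <- tibble::tibble(chrom = "chr1", start = 13500, end = 13600,
                        barcode = "c1", count = 1)
  expect_equal(as.numeric(gene_activity(fr2, gm2, "c1")$values[1, 1]), 1)
  expect_equal(as.numeric(gene_activity(fr2, gm, "c1")$values[1, 1]), 0)

  # brute-force interval oracle on random instances
  set.seed(8)
  for (rep in 1:5) {
    starts <- sort(sample(seq(5000, 50000, 1000), 4))
    gmr <- validate_gene_model(tibble::tibble(
      gene = paste0("g", 1:4), chrom = "chr1", start = starts,
      end = starts + sample(2000:8000, 4),
      strand = sample(c("+", "-"), 4, replace = TRUE)))
    frr <- tibble::tibble(
      chrom = "chr1", start = sample(0:60000, 30), end = NA,
      barcode = sample(c("c1", "c2"), 30, replace = TRUE),
      count = sample(1:3, 30, replace = TRUE))
    frr$end <- frr$start + sample(50:300, 30, replace = TRUE)
    ga <- gene_activity(frr, gmr, c("c1", "c2"))
    ws <- ifelse(gmr$strand == "+", gmr$start - 2000, gmr$start)
    we <- ifelse(gmr$strand == "+", gmr$end, gmr$end + 2000)
    for (g in 1:4) for (cc in c("c1", "c2")) {
      sel <- frr$barcode == cc & frr$start < we[g] & frr$end > ws[g]
      expect_equal(as.numeric(ga$values[g, cc]), sum(frr$count[sel]))
    }
  }
})

test_that("kNN sets agree with brute-force all-pairs distances", {
  set.seed(12)
  x <- matrix(rnorm(50 * 3), 50, 3)
  idx <- fatemultiome:::knn_indices(x, 5)
  d <- as.matrix(dist(x))
  for (i in 1:50) {
    brute <- order(d[i, ])[1:6]  # self plus 5 nearest
    expect_setequal(idx[i, ], brute)
  }
})

test_that("joint graph: idempotence and degenerate constant modality", {
  set.seed(13)
  x <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(paste0("c", 1:60), NULL))
  emb <- structure(list(coords = x, dims_used = 1:4, modality = "RNA",
                        sdev = rep(1, 4)), class = "fmm_embedding")
  joint <- joint_neighbor_graph(emb, emb, k = 8)
  single <- fatemultiome:::snn_adjacency(x, 8)
  expect_equal(joint$adjacency, single)

  flat <- emb
  flat$coords <- matrix(0, 60, 4, dimnames = list(paste0("c", 1:60), NULL))
  joint2 <- joint_neighbor_graph(emb, flat, k = 8)
  expect_true(all(is.finite(joint2$adjacency@x)))  # edges still defined
  expect_gt(length(joint2$adjacency@x), 0)

  bad <- emb
  rownames(bad$coords) <- rev(rownames(bad$coords))
  expect_error(joint_neighbor_graph(emb, bad, 8), "same order")
  expect_error(joint_neighbor_graph(emb, emb, k = 60), "below the number")
})

test_that("two disjoint cliques yield exactly two clusters, deterministically", {
  n <- 20
  adj <- Matrix::bdiag(matrix(1, n, n), matrix(1, n, n))
  Matrix::diag(adj) <- 0
  rownames(adj) <- colnames(adj) <- paste0("c", 1:(2 * n))
  cl <- cluster_graph(adj, resolution = 0.1, seed = 5)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(length(unique(cl$cluster[1:n])), 1)
  expect_identical(cluster_graph(adj, resolution = 0.1, seed = 5), cl)
  expect_error(cluster_graph(Matrix::Matrix(0, 0, 0, sparse = TRUE)),
               "empty graph")
})

test_that("cluster ids are contiguous from 0 and every barcode is assigned", {
  p <- get_pipe1()
  cl <- p$clusters
  ids <- sort(unique(cl$cluster))
  expect_identical(ids, seq_along(ids) - 1L)
  expect_false(anyNA(cl$cluster))
  expect_equal(nrow(cl), length(unique(cl$barcode)))
})
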