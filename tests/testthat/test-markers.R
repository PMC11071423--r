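# Differential tests, nearest-gene assignment and the multiomic signature.

norm_from <- function(m, features = paste0("g", seq_len(nrow(m))),
                      barcodes = paste0("c", seq_len(ncol(m)))) {
  structure(list(values = methods::as(m, "CsparseMatrix"),
                 method = "LOG_CP10K_RESIDUAL", feature_ids = features,
                 barcodes = barcodes),
            class = "normalized_matrix")
}

two_group_clusters <- function(n1, n2) {
  tibble::tibble(barcode = paste0("c", seq_len(n1 + n2)),
                 cluster = rep(c(1L, 2L), c(n1, n2)))
}

test_that("complete separation gives the exact enumeration p-value", {
  m <- rbind(c(rep(2, 10), rep(0, 10)))
  nm <- norm_from(m, "gA")
  mk <- find_markers(nm, two_group_clusters(10, 10), 1, min_pct = 0.2,
                     logfc_min = 0.25)
  expect_equal(mk$pct_in, 1)
  expect_equal(mk$pct_out, 0)
  expect_equal(mk$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_gte(mk$p_adj, mk$p_value)
})

test_that("detection and fold-change gates exclude features", {
  set.seed(2)
  # pct_in = pct_out = 0.1 -> never tested
  v <- c(rep(0, 9), 5)
  m <- rbind(c(v, v))
  mk <- find_markers(norm_from(m, "gA"), two_group_clusters(10, 10), 1,
                     min_pct = 0.2, logfc_min = 0.25)
  expect_equal(nrow(mk), 0)

  # identical distributions: excluded by the fold-change gate
  w <- rnorm(20, 5)
  m2 <- rbind(c(w, w))
  mk2 <- find_markers(norm_from(m2, "gA"), two_group_clusters(20, 20)[
    c(1:20, 1:20 + 20), ], 1)
  expect_equal(nrow(mk2), 0)

  expect_error(find_markers(norm_from(m2, "gA"),
                            two_group_clusters(20, 20), 99),
               "unknown cluster")
})

test_that("marker fold change uses the expm1 mean ratio convention", {
  x_in <- c(2, 2, 2, 0); x_out <- c(1, 0, 0, 0)
  m <- rbind(c(x_in, x_out))
  mk <- find_markers(norm_from(m, "gA"), two_group_clusters(4, 4), 1,
                     min_pct = 0.2, logfc_min = 0)
  expect_equal(mk$log_fc,
               log((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1)))
})

test_that("rank-sum p-values are uniform under label permutation", {
  set.seed(99)
  n <- 30
  p_vals <- replicate(400, {
    x <- rnorm(2 * n)
    rank_sum_p(x[1:n], x[(n + 1):(2 * n)])
  })
  expect_gt(suppressWarnings(stats::ks.test(p_vals, "punif"))$p.value,
            0.01)
})

test_that("LR accessibility test agrees with a glm oracle", {
  set.seed(5)
  n <- 20
  y <- rep(c(1, 0), each = n / 2)
  lat <- rnorm(n)
  v <- rnorm(n) + 0.8 * y
  m <- rbind(v)
  nm <- norm_from(m, "p1")
  cl <- two_group_clusters(n / 2, n / 2)
  da <- find_da_peaks(nm, cl, 1, latent = lat, min_pct = 0.02)
  f_full <- stats::glm(y ~ scale(v) + scale(lat), family = binomial())
  f_null <- stats::glm(y ~ scale(lat), family = binomial())
  stat <- as.numeric(f_null$deviance - f_full$deviance)
  p_oracle <- stats::pchisq(stat, 1, lower.tail = FALSE)
  expect_equal(da$p_value, p_oracle, tolerance = 1e-6)
})

test_that("LR test handles degenerate designs without NaN", {
  n <- 20
  y <- rep(c(1, 0), each = n / 2)
  cl <- two_group_clusters(n / 2, n / 2)

  # peak values identical across the two groups -> p = 1
  set.seed(6)
  v_null <- rep(abs(rnorm(n / 2)), 2)
  da0 <- find_da_peaks(norm_from(rbind(v_null), "p1"), cl, 1,
                       latent = rep(1, n))
  expect_gt(da0$p_value, 0.9)

  # label perfectly explained by the latent alone -> peak adds nothing
  lat <- c(rnorm(n / 2, 3), rnorm(n / 2, -3))
  v <- abs(rnorm(n))
  da1 <- find_da_peaks(norm_from(rbind(v), "p1"), cl, 1, latent = lat)
  expect_false(is.nan(da1$p_value))
  expect_gt(da1$p_value, 0.9)

  # peak present in all target cells and absent elsewhere (perfect
  # separation): finite, extreme significance
  v2 <- c(rep(3, n / 2), rep(0, n / 2))
  da2 <- find_da_peaks(norm_from(rbind(v2), "p1"), cl, 1,
                       latent = rep(1, n))
  expect_true(is.finite(da2$p_value))
  expect_lt(da2$p_value, 1e-4)
})

test_that("LR type-I error stays near nominal under depth confounding", {
  # groups differ in depth; the latent must absorb it
  set.seed(77)
  n <- 200
  depth <- c(rlnorm(n / 2, 7.2, 0.3), rlnorm(n / 2, 6.8, 0.3))
  cl <- two_group_clusters(n / 2, n / 2)
  n_peaks <- 300
  m <- matrix(0, n_peaks, n)
  for (i in seq_len(n_peaks)) {
    m[i, ] <- log1p(rpois(n, depth / 1000))
  }
  nm <- norm_from(m, paste0("p", seq_len(n_peaks)))
  da <- find_da_peaks(nm, cl, 1, latent = depth, min_pct = 0.02)
  expect_lte(mean(da$p_value < 0.05), 0.07)
})

test_that("nearest-gene assignment: distances, filter and tie rule", {
  gm <- validate_gene_model(tibble::tibble(
    gene = "gA", chrom = "chr1", start = 1200, end = 3000, strand = "+"))
  pk <- tibble::tibble(chrom = "chr1", start = 1000, end = 1500)
  pk$peak <- peak_name(pk)
  ng <- assign_nearest_gene(pk, gm, max_dist = 1e5)
  # overlapping peak -> distance 0
  expect_equal(ng$distance, 0)
  expect_equal(ng$nearest_gene, "gA")

  # peak [0,100) whose nearest gene starts at 150,000 -> dropped (> 1e5)
  gmf <- validate_gene_model(tibble::tibble(
    gene = "gB", chrom = "chr1", start = 150000, end = 160000,
    strand = "+"))
  pkf <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  pkf$peak <- peak_name(pkf)
  expect_equal(nrow(assign_nearest_gene(pkf, gmf, 1e5)), 0)

  # equidistant genes: smaller start wins
  gm2 <- validate_gene_model(tibble::tibble(
    gene = c("gZ", "gY"), chrom = "chr1",
    start = c(500, 2500), end = c(900, 2900), strand = "+"))
  pk2 <- tibble::tibble(chrom = "chr1", start = 1400, end = 2000)
  pk2$peak <- peak_name(pk2)
  ng2 <- assign_nearest_gene(pk2, gm2, 1e5)
  expect_equal(ng2$nearest_gene, "gZ")
  expect_equal(ng2$distance, 500)

  # peak on a chromosome without genes drops with a warning
  pk3 <- tibble::tibble(chrom = "chrM", start = 1, end = 100)
  pk3$peak <- peak_name(pk3)
  expect_warning(ng3 <- assign_nearest_gene(pk3, gm, 1e5), "no genes")
  expect_equal(nrow(ng3), 0)
})

fake_markers <- function(genes) {
  tibble::tibble(feature = genes, cluster = 1L, log_fc = 1,
                 pct_in = 1, pct_out = 0,
                 p_value = seq_along(genes) * 1e-6,
                 p_adj = seq_along(genes) * 1e-5)
}

fake_da <- function(genes) {
  tibble::tibble(peak = paste0("pk", seq_along(genes)), cluster = 1L,
                 log_fc = 1, pct_in = 1, pct_out = 0,
                 p_value = seq_along(genes) * 1e-6,
                 p_adj = seq_along(genes) * 1e-5,
                 nearest_gene = genes, distance = 0)
}

test_that("signature construction: disjoint, identical and mixed lists", {
  g1 <- sprintf("a%03d", 1:100)
  g2 <- sprintf("b%03d", 1:100)
  g3 <- sprintf("c%03d", 1:100)
  s <- build_signature(fake_markers(g1), fake_markers(g2), fake_da(g3))
  expect_length(s$union, 300)
  expect_equal(unname(s$overlap_counts[c("ab", "ac", "bc", "abc")]),
               rep(0L, 4))

  s2 <- build_signature(fake_markers(g1), fake_markers(g1), fake_da(g1))
  expect_length(s2$union, 100)
  expect_equal(unname(s2$overlap_counts["abc"]), 100L)

  # constructed overlaps: 20 shared by all, 10 per pair
  core <- sprintf("core%02d", 1:20)
  ab <- sprintf("ab%02d", 1:10); ac <- sprintf("ac%02d", 1:10)
  bc <- sprintf("bc%02d", 1:10)
  la <- c(core, ab, ac, sprintf("onlya%02d", 1:60))
  lb <- c(core, ab, bc, sprintf("onlyb%02d", 1:60))
  lc <- c(core, ac, bc, sprintf("onlyc%02d", 1:60))
  s3 <- build_signature(fake_markers(la), fake_markers(lb), fake_da(lc))
  expect_equal(unname(s3$overlap_counts),
               c(60L, 60L, 60L, 10L, 10L, 10L, 20L))
  # Venn regions always sum to the union cardinality
  expect_equal(sum(s3$overlap_counts), length(s3$union))

  # short lists warn and fall back to the full list
  expect_warning(build_signature(fake_markers(g1[1:5]), fake_markers(g2),
                                 fake_da(g3)), "shorter than top_n")
})

test_that("DA deduplication to genes precedes top-n truncation", {
  genes <- c("dup", "dup", sprintf("g%03d", 1:120))
  da <- fake_da(genes)
  s <- suppressWarnings(
    build_signature(fake_markers(sprintf("x%03d", 1:100)),
                    fake_markers(sprintf("y%03d", 1:100)), da, top_n = 100))
  expect_length(s$da_top, 100)
  expect_equal(sum(s$da_top == "dup"), 1)
  # best-p order preserved: dup first, then g001..g099
  expect_equal(s$da_top[1:2], c("dup", "g001"))
})

test_that("marker tables from the pipeline satisfy their invariants", {
  p <- get_pipe1()
  for (tab in list(p$gex_markers, p$ga_markers, p$da_peaks)) {
    expect_true(all(tab$pct_in >= 0 & tab$pct_in <= 1))
    expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
    expect_true(all(tab$p_adj >= tab$p_value))
  }
  expect_true(all(p$da_peaks$distance <= 1e5))
  expect_lte(length(p$signature$union), 300)
  expect_equal(sum(p$signature$overlap_counts), length(p$signature$union))
})
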