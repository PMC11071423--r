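# Motif scanning, chromVAR-style deviations, enrichment, cross-referencing.

tata_pfm <- function() {
  m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  m["T", c(1, 3)] <- 100
  m["A", c(2, 4)] <- 100
  m
}

test_that("deterministic motifs hit their consensus on either strand", {
  hits <- scan_motifs(c(fwd = "CCTATACC"), list(TATA = tata_pfm()))
  expect_true(hits["TATA", "fwd"])
  # reverse complement of the context: hit via the minus strand
  rc <- fatemultiome:::revcomp("CCTATACC")
  hits2 <- scan_motifs(stats::setNames(rc, "rev"), list(TATA = tata_pfm()))
  expect_true(hits2["TATA", "rev"])
  # too-short sequences are silently not hits
  hits3 <- scan_motifs(c(s = "TA"), list(TATA = tata_pfm()))
  expect_false(hits3["TATA", "s"])
  # a sequence without the motif is not a hit
  hits4 <- scan_motifs(c(s = "GGGGCCCCGG"), list(TATA = tata_pfm()))
  expect_false(hits4["TATA", "s"])
})

test_that("scanning is strand-symmetric over whole sequence sets", {
  set.seed(31)
  seqs <- vapply(1:30, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("p", 1:30)
  motifs <- list(TATA = tata_pfm())
  h1 <- scan_motifs(seqs, motifs)
  h2 <- scan_motifs(vapply(seqs, fatemultiome:::revcomp, character(1)),
                    motifs)
  expect_identical(h1, h2)
})

test_that("scanning equals an exhaustive per-offset oracle", {
  set.seed(32)
  seqs <- vapply(1:100, function(i) {
    paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("p", 1:100)
  pfm <- matrix(rpois(4 * 8, 5) + 1, 4, 8,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  hits <- scan_motifs(seqs, list(M = pfm), threshold_fraction = 0.8)

  # independent oracle: probability matrix scored position by position
  prob <- sweep(pfm + 0.8 * 0.25, 2, colSums(pfm) + 0.8, "/")
  lo <- log2(prob / 0.25)
  max_sc <- sum(apply(lo, 2, max))
  score_one <- function(s) {
    ch <- strsplit(s, "")[[1]]
    best <- -Inf
    for (str in 1:2) {
      v <- if (str == 1) ch else
        rev(c(A = "T", C = "G", G = "C", T = "A")[ch])
      for (off in seq_len(length(v) - 8 + 1)) {
        sc <- 0
        for (j in 1:8) sc <- sc + lo[v[off + j - 1], j]
        best <- max(best, sc)
      }
    }
    best
  }
  oracle <- vapply(seqs, score_one, numeric(1)) >= 0.8 * max_sc
  expect_identical(unname(hits["M", ]), unname(oracle))
})

test_that("N bases score as background and do not crash the scan", {
  hits <- scan_motifs(c(s = "NNTATANN"), list(TATA = tata_pfm()))
  # TATA present with N context: full motif score attained
  expect_true(hits["TATA", "s"])
})

dev_fixture <- function(n_peaks = 30, n_cells = 40, seed = 41) {
  set.seed(seed)
  x <- matrix(rpois(n_peaks * n_cells, 2), n_peaks, n_cells,
              dimnames = list(paste0("p", seq_len(n_peaks)),
                              paste0("c", seq_len(n_cells))))
  gc <- runif(n_peaks, 0.3, 0.7)
  list(x = x, gc = gc)
}

test_that("a motif occupying every peak has raw deviation exactly 0", {
  f <- dev_fixture()
  hits <- matrix(TRUE, 1, nrow(f$x), dimnames = list("M", rownames(f$x)))
  dv <- motif_deviations(Matrix::Matrix(f$x, sparse = TRUE), hits, f$gc,
                         n_bg = 10, seed = 2)
  expect_true(all(abs(dv$raw) < 1e-12))
})

test_that("deviations are invariant to peak order and flag empty motifs", {
  f <- dev_fixture()
  hits <- rbind(M1 = seq_len(nrow(f$x)) %in% 1:8,
                M2 = rep(FALSE, nrow(f$x)))
  colnames(hits) <- rownames(f$x)
  expect_warning(
    dv <- motif_deviations(Matrix::Matrix(f$x, sparse = TRUE), hits, f$gc,
                           n_bg = 15, seed = 3),
    "zero peaks")
  expect_true(all(is.na(dv$z["M2", ])))

  perm <- sample(nrow(f$x))
  expect_warning(
    dv2 <- motif_deviations(Matrix::Matrix(f$x[perm, ], sparse = TRUE),
                            hits[, perm, drop = FALSE], f$gc[perm],
                            n_bg = 15, seed = 3),
    "zero peaks")
  expect_equal(dv2$raw["M1", ], dv$raw["M1", ])
})

test_that("type-specific motif accessibility yields higher z in that type", {
  p <- get_pipe1()
  sim <- get_sim1()
  z <- p$motifs$deviations$z["MA_GATA", ]
  ct <- sim$truth$cells$cell_type[match(colnames(p$motifs$deviations$z),
                                        sim$truth$cells$barcode)]
  m_in <- mean(z[ct == "ILC2"]); m_out <- mean(z[ct != "ILC2"])
  expect_gte(m_in - m_out, 1)
})

test_that("hypergeometric enrichment matches the closed form and oracle", {
  hits <- matrix(FALSE, 1, 25,
                 dimnames = list("M", paste0("p", 1:25)))
  hits["M", 1:5] <- TRUE  # motif in all 5 foreground peaks, none elsewhere
  gc <- stats::setNames(rep(0.5, 25), colnames(hits))
  enr <- enrich_motifs(paste0("p", 1:5), paste0("p", 1:25), hits, gc)
  expect_equal(enr$p_value, 1 / choose(25, 5), tolerance = 1e-12)
  expect_equal(enr$p_value, 1.882e-5, tolerance = 1e-3)

  # equal fg/bg frequency: fold ~ 1, p large
  hits2 <- matrix(rep(c(TRUE, FALSE), c(2, 3)), 1, 25,
                  dimnames = list("M", paste0("p", 1:25)))
  hits2["M", ] <- rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 5)
  enr2 <- enrich_motifs(paste0("p", 1:5), paste0("p", 1:25), hits2, gc)
  expect_gt(enr2$p_value, 0.5)

  # foreground equal to all peaks: fold enrichment 1 by construction
  enr3 <- enrich_motifs(paste0("p", 1:25), paste0("p", 1:25), hits, gc)
  expect_equal(enr3$fold_enrichment, 1)

  expect_error(enrich_motifs(character(0), paste0("p", 1:25), hits, gc),
               "empty foreground")

  # agreement with an independent exact-test oracle on random configurations
  set.seed(55)
  for (i in 1:20) {
    n_all <- sample(20:60, 1)
    n_fg <- sample(5:10, 1)
    hmat <- matrix(runif(n_all) < 0.4, 1, n_all,
                   dimnames = list("M", paste0("q", seq_len(n_all))))
    gcs <- stats::setNames(rep(0.5, n_all), colnames(hmat))
    fg <- paste0("q", seq_len(n_fg))
    enr_i <- enrich_motifs(fg, colnames(hmat), hmat, gcs)
    k <- sum(hmat[1, seq_len(n_fg)]); K <- sum(hmat[1, ])
    tab <- matrix(c(k, n_fg - k, K - k, (n_all - n_fg) - (K - k)), 2)
    p_fisher <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_lt(abs(enr_i$p_value - p_fisher), 1e-10)
  }
})

test_that("TF cross-referencing joins expression and flags concordance", {
  enr <- tibble::tibble(motif = c("M1", "M2", "M3"),
                        n_fg_with = c(5, 5, 1), n_fg = 5,
                        n_bg_with = c(0, 0, 10), n_bg = 20,
                        fold_enrichment = c(10, 10, 0.4),
                        p_value = c(1e-6, 1e-6, 0.9),
                        p_adj = c(3e-6, 3e-6, 0.9))
  m <- rbind(c(0, 0, 0, 0), c(2, 3, 1, 2))
  nm <- structure(list(values = methods::as(m, "CsparseMatrix"),
                       method = "LOG_CP10K_RESIDUAL",
                       feature_ids = c("TFdead", "TFlive"),
                       barcodes = paste0("c", 1:4)),
                  class = "normalized_matrix")
  map <- tibble::tibble(motif = c("M1", "M2", "M3"),
                        gene = c("TFdead", "TFlive", "TFlive"))
  out <- crossref_expression(enr, nm, map)
  # enriched motif with a silent TF is not concordant
  expect_false(out$concordant[out$motif == "M1"])
  # enriched motif with an expressed TF is concordant
  expect_true(out$concordant[out$motif == "M2"])
  # unenriched motif is not concordant even when expressed
  expect_false(out$concordant[out$motif == "M3"])
  # motifs sharing a TF gene carry identical expression fields
  expect_equal(out$mean_expression[out$motif == "M2"],
               out$mean_expression[out$motif == "M3"])
})

test_that("the planted expressed TF is the unique concordant hit", {
  p <- get_pipe1()
  xr <- p$motifs$crossref
  expect_identical(xr$motif[xr$concordant], "MA_GATA")
})
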