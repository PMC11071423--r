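# Peak-to-gene links, regulome counts, set intersections and induced peaks.

test_that("a strongly coupled pair is retained with high score and z", {
  cfg <- mini_sim_config(
    n_loci = 12, peaks_per_locus = 3, linked = 4, beta = 1,
    cells = tibble::tibble(cell_type = "ILC2", fate_map = "RAG_NAIVE",
                           disease = "SS", n = 500),
    seed = 17)
  sim <- simulate_multiome(cfg)
  lt <- compute_links(normalize_rna(sim$dataset$rna),
                      run_tfidf(sim$dataset$atac),
                      sim$dataset$genes, sim$dataset$peaks, seed = 1)
  key <- paste(lt$gene, lt$peak)
  planted <- paste(sim$truth$links$gene, sim$truth$links$peak)
  expect_true(planted %in% key)
  hit <- lt[key == planted, ]
  expect_gt(hit$score, 0.3)
  expect_gt(hit$z, 3)
})

test_that("pairs below the min.cells detection gate are never tested", {
  cfg <- mini_sim_config(
    n_loci = 5, peaks_per_locus = 1,
    cells = tibble::tibble(cell_type = "ILC2", fate_map = "RAG_NAIVE",
                           disease = "SS", n = 50),
    seed = 23)
  sim <- simulate_multiome(cfg)
  atac <- sim$dataset$atac
  # force peak 1 to be detected in exactly one cell
  m <- as.matrix(atac$values)
  m[1, ] <- 0; m[1, 1] <- 5
  atac1 <- count_matrix(m, atac$feature_ids, atac$barcodes, "ATAC_PEAKS")
  lt <- compute_links(normalize_rna(sim$dataset$rna), run_tfidf(atac1),
                      sim$dataset$genes, sim$dataset$peaks,
                      min_cells = 2, seed = 1)
  expect_false(atac$feature_ids[1] %in% lt$peak)
  lt_all <- compute_links(normalize_rna(sim$dataset$rna), run_tfidf(atac1),
                          sim$dataset$genes, sim$dataset$peaks,
                          min_cells = 1, seed = 1)
  expect_gt(attr(lt_all, "n_candidates"), attr(lt, "n_candidates"))
})

test_that("a degenerate single-condition split equals a plain run", {
  qc <- get_qc1()
  ds <- filter_dataset(qc$dataset, qc$dataset$rna$barcodes[1:200])
  labs <- tibble::tibble(barcode = ds$rna$barcodes, condition = "all")
  byc <- links_by_condition(ds, labs)
  plain <- compute_links(normalize_rna(ds$rna), run_tfidf(ds$atac),
                         ds$genes, ds$peaks,
                         seed = default_run_config()$seed)
  expect_equal(byc[["all"]][, c("gene", "peak", "score", "z", "p_value")],
               plain[, c("gene", "peak", "score", "z", "p_value")],
               ignore_attr = TRUE)
  # too-small conditions raise a named error
  labs$condition[1:10] <- "tiny"
  expect_error(links_by_condition(ds, labs), "tiny")
})

test_that("regulome counts equal a brute-force tally and sort by delta", {
  mk <- function(genes, peaks) {
    tibble::tibble(gene = genes, peak = peaks, score = 0.5, z = 3,
                   p_value = 1e-4, condition = NA_character_)
  }
  naive <- mk(c("g1", "g1", "g2"), c("p1", "p2", "p3"))
  exp_ <- mk("g1", "p1")
  rc <- regulome_counts(naive, exp_)
  expect_equal(rc$delta[rc$gene == "g1"], 1)
  expect_equal(rc$n_links_naive[rc$gene == "g2"], 1)

  # identical lists give all-zero deltas
  rc0 <- regulome_counts(naive, naive)
  expect_true(all(rc0$delta == 0))

  # randomized tables match a group-by oracle
  set.seed(3)
  g <- sample(sprintf("g%02d", 1:10), 200, replace = TRUE)
  p <- sample(sprintf("p%02d", 1:50), 200, replace = TRUE)
  la <- mk(g[1:120], p[1:120]); lb <- mk(g[121:200], p[121:200])
  rc2 <- regulome_counts(la, lb)
  for (gene in unique(c(la$gene, lb$gene))) {
    expect_equal(rc2$n_links_naive[rc2$gene == gene], sum(la$gene == gene))
    expect_equal(rc2$n_links_exp[rc2$gene == gene], sum(lb$gene == gene))
  }
  expect_true(all(diff(rc2$delta) <= 0))  # sorted descending
})

test_that("peak deduplication matches brute-force unique", {
  links <- tibble::tibble(gene = c("g1", "g2", "g1"),
                          peak = c("p1", "p1", "p2"))
  expect_setequal(dedup_peaks(links), c("p1", "p2"))
  expect_length(dedup_peaks(tibble::tibble(peak = character())), 0)
  set.seed(4)
  big <- tibble::tibble(gene = sample(letters, 1000, TRUE),
                        peak = sample(sprintf("p%03d", 1:100), 1000, TRUE))
  expect_setequal(dedup_peaks(big), unique(big$peak))
  expect_lte(length(dedup_peaks(big)), 100)
})

test_that("exclusive intersections follow UpSet semantics", {
  # four identical sets: only the 4-way combination is occupied
  s <- replicate(4, sprintf("p%02d", 1:7), simplify = FALSE)
  names(s) <- c("A", "B", "C", "D")
  xi <- exclusive_intersections(s)
  expect_equal(xi$size[xi$combo == "A&B&C&D"], 7L)
  expect_equal(sum(xi$size), 7L)

  # four disjoint sets: only singletons occupied
  s2 <- list(A = "p1", B = "p2", C = "p3", D = "p4")
  xi2 <- exclusive_intersections(s2)
  expect_true(all(xi2$size[xi2$degree > 1] == 0))
  expect_equal(sum(xi2$size), 4L)
})

test_that("exclusive intersections equal the 2^4 membership oracle", {
  set.seed(9)
  for (rep in 1:50) {
    u <- sprintf("p%03d", 1:200)
    sys <- lapply(1:4, function(i) sample(u, sample(20:150, 1)))
    names(sys) <- c("A", "B", "C", "D")
    xi <- exclusive_intersections(sys)
    # brute force: membership vector per element
    memb <- sapply(sys, function(s) u %in% s)
    key <- apply(memb, 1, function(r) paste(names(sys)[r], collapse = "&"))
    key <- key[nzchar(key)]
    oracle <- table(key)
    for (cb in xi$combo) {
      expect_equal(xi$size[xi$combo == cb],
                   if (cb %in% names(oracle)) unname(oracle[[cb]]) else 0L)
    }
    expect_equal(sum(xi$size), length(unique(unlist(sys))))
  }
})

test_that("induced-peak logic excludes peaks seen at steady state", {
  sys <- list("RAG_NAIVE|SS" = c("p1", "p2", "p3"),
              "RAG_NAIVE|AD" = c("p1", "p2", "p4"),
              "RAG_EXP|AD" = c("p1", "p2"),
              "RAG_EXP|SS" = c("p2"))
  links <- list(tibble::tibble(gene = c("g1", "g1", "g2"),
                               peak = c("p1", "p1", "p1")))
  out <- induced_peak_genes(sys, links)
  # p2 is in all four sets -> not induced; p1 is induced
  expect_equal(out$induced_peaks, "p1")
  # distinct peaks count once per gene regardless of link multiplicity
  expect_equal(out$ranking$n_induced_peaks,
               rep(1L, 2))
  expect_equal(out$ranking$gene, c("g1", "g2"))

  # empty induced set is valid
  sys0 <- sys; sys0[["RAG_EXP|SS"]] <- c("p1", "p2")
  out0 <- induced_peak_genes(sys0, links)
  expect_length(out0$induced_peaks, 0)
  expect_equal(nrow(out0$ranking), 0)
})

test_that("Th2 locus report needs the locus genes and handles empty links", {
  qc <- get_qc1()
  ds <- qc$dataset
  expect_error(th2_locus_report(ds, locus_genes = c("Il4", "Missing9")),
               "Missing9")
  # no links anywhere: zero counts for every locus gene
  rc <- regulome_counts(
    tibble::tibble(gene = character(), peak = character()),
    tibble::tibble(gene = character(), peak = character()),
    gene_set = th2_locus_genes())
  expect_equal(rc$n_links_naive, rep(0L, 4))
  expect_equal(rc$delta, rep(0L, 4))
})

test_that("pipeline link tables respect their invariants", {
  p <- get_pipe1()
  for (lt in c(p$links_by_fate, p$links_by_state)) {
    expect_true(all(abs(lt$score) <= 1))
    expect_true(all(lt$p_value < default_run_config()$link_p_cutoff))
    expect_true(all(abs(lt$score) >=
                      default_run_config()$link_score_cutoff))
  }
  xi <- p$intersections
  expect_equal(sum(xi$size),
               length(unique(unlist(lapply(p$links_by_state, dedup_peaks)))))
})
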