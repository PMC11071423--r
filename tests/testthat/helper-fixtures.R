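# Shared fixtures, memoised so the expensive simulated scenario and pipeline
# are built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# default scenario simulated at seed 1
get_sim1 <- function() {
  fixture("sim1", function() {
    scen <- default_paper_scenario(1)
    c(list(scen = scen), simulate_multiome(scen))
  })
}

# QC-filtered dataset for the default scenario
get_qc1 <- function() {
  fixture("qc1", function() suppressWarnings(run_qc(get_sim1()$dataset)))
}

# full pipeline run at seed 1
get_pipe1 <- function() {
  fixture("pipe1", function() {
    s <- get_sim1()
    suppressWarnings(run_multiome_pipeline(
      s$dataset,
      motifs = attr(s$scen, "motifs"),
      motif_to_gene = attr(s$scen, "motif_to_gene"),
      gene_sets = attr(s$scen, "gene_sets"),
      seed = 1
    ))
  })
}

# a small dense count matrix fixture
tiny_counts <- function(n_genes = 6, n_cells = 4, seed = 7,
                        modality = "RNA") {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 3), n_genes, n_cells)
  count_matrix(m, paste0("g", seq_len(n_genes)),
               paste0("bc", seq_len(n_cells)), modality)
}

# a minimal simulation config: one chromosome of simple loci, each with one
# gene and `peaks_per_locus` peaks near the TSS; optional planted links
mini_sim_config <- function(n_loci = 10, peaks_per_locus = 2,
                            cells = NULL, linked = integer(0),
                            beta = 0.5, active_in = list(), seed = 1,
                            ...) {
  centers <- 2e6 + (seq_len(n_loci) - 1) * 2.5e6
  genes <- tibble::tibble(
    gene = sprintf("G%02d", seq_len(n_loci)), chrom = "chr1",
    start = centers, end = centers + 2000, strand = "+"
  )
  pk <- purrr::map_dfr(seq_len(peaks_per_locus), function(j) {
    tibble::tibble(chrom = "chr1", start = centers + j * 15000,
                   end = centers + j * 15000 + 400)
  })
  pk$peak <- peak_name(pk)
  cells <- cells %||% tibble::tibble(
    cell_type = "ILC2",
    fate_map = rep(c("RAG_NAIVE", "RAG_EXP"), each = 2),
    disease = rep(c("SS", "AD"), 2), n = 150
  )
  lp <- NULL
  if (length(linked)) {
    lp <- tibble::tibble(
      gene = sprintf("G%02d", linked),
      peak = peak_name(tibble::tibble(chrom = "chr1",
                                      start = centers[linked] + 15000,
                                      end = centers[linked] + 15400)),
      beta_atac = beta, beta_rna = beta,
      active_in = if (length(active_in)) active_in else
        rep(list(c("RAG_NAIVE|SS", "RAG_NAIVE|AD", "RAG_EXP|SS",
                   "RAG_EXP|AD")), length(linked)),
      latent_id = sprintf("L%02d", linked), class = "planted"
    )
  }
  sim_config(cells = cells, genes = genes, peaks = pk,
             genome = c(chr1 = max(centers) + 5e6),
             gene_base_rate = setNames(rep(3, n_loci), genes$gene),
             peak_base_access = setNames(rep(2, nrow(pk)), pk$peak),
             linked_pairs = lp, seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
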