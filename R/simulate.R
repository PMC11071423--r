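# Synthetic paired-multiome generator with planted ground truth.
#
# Generative model: per-cell Poisson counts for both modalities. Relative
# gene/peak weights combine a base rate, cell-type and fate-map programs
# (log-fold effects), and -- for planted peak-gene couplings -- a shared
# per-cell gamma latent a_i that multiplies both the peak rate
# (x exp(beta_atac * a_i)) and the gene rate (x exp(beta_rna * a_i)) in cells
# whose (fate_map, disease) state the link is active in. Column weights are
# renormalised to per-cell depths drawn log-normally, so depth and signal are
# decoupled. Fragments are emitted inside counted peaks (two-component length
# mixture controlling the nucleosome signal) plus a uniform genomic
# background; the reporter transcript (tdRFP) is present only in
# RAG-experienced cells, subject to dropout.

SIM_FATES <- c("RAG_NAIVE", "RAG_EXP")
SIM_DISEASES <- c("SS", "AD")

sim_state <- function(fate_map, disease) paste(fate_map, disease, sep = "|")

#' Construct a simulation configuration
#'
#' Most users should start from [default_paper_scenario()]; this constructor
#' is for bespoke scenarios and validates cross-references between the
#' planted links and the gene/peak tables.
#'
#' @param cells Tibble with columns `cell_type`, `fate_map`
#'   (`RAG_NAIVE`/`RAG_EXP`), `disease` (`SS`/`AD`), `n` (cells per group).
#' @param genes Gene model tibble (`gene`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `peak`).
#' @param genome Named numeric vector of chromosome lengths (bp).
#' @param gene_base_rate,peak_base_access Named non-negative vectors of
#'   relative rates (missing names default to 1).
#' @param type_programs Tibble (`gene`, `cell_type`, `log_fc`): cell-type
#'   expression programs.
#' @param peak_programs Tibble (`peak`, `cell_type`, `log_fc`): cell-type
#'   accessibility programs.
#' @param fate_programs Tibble (`gene`, `fate_map`, `log_fc`).
#' @param linked_pairs Tibble (`gene`, `peak`, `beta_atac`, `beta_rna`,
#'   `active_in` list-column of state strings `"FATE|DISEASE"`, `latent_id`,
#'   `class`). Links sharing a `latent_id` share the per-cell latent.
#' @param motif_plants Tibble (`peak`, `seq`): motif instances inserted into
#'   peak sequences.
#' @param rna_depth_mean,atac_depth_mean Mean per-cell totals (counts).
#' @param rna_depth_sdlog,atac_depth_sdlog Log-normal depth spread.
#' @param background_frac Background (non-peak) fragments as a fraction of
#'   in-peak fragment counts.
#' @param frag_sub_shape1,frag_sub_shape2 Beta parameters of the per-cell
#'   sub-nucleosomal fragment fraction (controls nucleosome signal).
#' @param dropout_tdrfp Probability a RAG-experienced cell shows zero
#'   reporter counts.
#' @param reporter_mean Mean of the (shifted) Poisson reporter count in
#'   detected cells.
#' @param reporter_gene Reporter feature name.
#' @param dispersion Gamma shape of the per-cell link latent (rate equal to
#'   shape, so the latent has mean 1).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(cells, genes, peaks, genome,
                       gene_base_rate = NULL, peak_base_access = NULL,
                       type_programs = NULL, peak_programs = NULL,
                       fate_programs = NULL, linked_pairs = NULL,
                       motif_plants = NULL,
                       rna_depth_mean = 3000, rna_depth_sdlog = 0.3,
                       atac_depth_mean = 2000, atac_depth_sdlog = 0.3,
                       background_frac = 0.12,
                       frag_sub_shape1 = 15, frag_sub_shape2 = 5,
                       dropout_tdrfp = 0.2, reporter_mean = 1.5,
                       reporter_gene = "tdRFP",
                       dispersion = 1.5, seed = 1L) {
  genes <- validate_gene_model(tibble::as_tibble(genes))
  peaks <- tibble::as_tibble(peaks)
  if (!"peak" %in% names(peaks)) peaks$peak <- peak_name(peaks)
  stopifnot(all(cells$n > 0), all(cells$fate_map %in% SIM_FATES),
            all(cells$disease %in% SIM_DISEASES))
  if (dropout_tdrfp < 0 || dropout_tdrfp > 1) {
    stop("dropout_tdrfp must be a probability", call. = FALSE)
  }
  if (!all(genes$chrom %in% names(genome)) ||
      !all(peaks$chrom %in% names(genome))) {
    stop("gene/peak chromosome absent from genome", call. = FALSE)
  }
  if (any(peaks$end > genome[peaks$chrom])) {
    stop("peak extends beyond chromosome length", call. = FALSE)
  }
  fill_rate <- function(x, nms) {
    out <- stats::setNames(rep(1, length(nms)), nms)
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  lp <- linked_pairs %||%
    tibble::tibble(gene = character(), peak = character(),
                   beta_atac = numeric(), beta_rna = numeric(),
                   active_in = list(), latent_id = character(),
                   class = character())
  if (nrow(lp)) {
    bad_g <- setdiff(lp$gene, genes$gene)
    bad_p <- setdiff(lp$peak, peaks$peak)
    if (length(bad_g) || length(bad_p)) {
      stop("planted link references unknown gene/peak: ",
           paste(c(bad_g, bad_p), collapse = ", "), call. = FALSE)
    }
    if (any(lp$beta_atac <= 0) || any(lp$beta_rna <= 0)) {
      stop("planted link effect sizes must be positive", call. = FALSE)
    }
    if (any(lengths(lp$active_in) == 0)) {
      stop("planted link with empty active_in", call. = FALSE)
    }
    tss <- stats::setNames(genes$tss, genes$gene)[lp$gene]
    ctr <- stats::setNames((peaks$start + peaks$end) / 2, peaks$peak)[lp$peak]
    if (any(abs(ctr - tss) > 1e6)) {
      stop("planted link peak further than the linkage window (1e6 bp) from ",
           "its gene TSS", call. = FALSE)
    }
  }
  structure(list(
    cells = tibble::as_tibble(cells), genes = genes, peaks = peaks,
    genome = genome,
    gene_base_rate = fill_rate(gene_base_rate, genes$gene),
    peak_base_access = fill_rate(peak_base_access, peaks$peak),
    type_programs = type_programs %||%
      tibble::tibble(gene = character(), cell_type = character(),
                     log_fc = numeric()),
    peak_programs = peak_programs %||%
      tibble::tibble(peak = character(), cell_type = character(),
                     log_fc = numeric()),
    fate_programs = fate_programs %||%
      tibble::tibble(gene = character(), fate_map = character(),
                     log_fc = numeric()),
    linked_pairs = lp, motif_plants = motif_plants,
    rna_depth_mean = rna_depth_mean, rna_depth_sdlog = rna_depth_sdlog,
    atac_depth_mean = atac_depth_mean, atac_depth_sdlog = atac_depth_sdlog,
    background_frac = background_frac,
    frag_sub_shape1 = frag_sub_shape1, frag_sub_shape2 = frag_sub_shape2,
    dropout_tdrfp = dropout_tdrfp, reporter_mean = reporter_mean,
    reporter_gene = reporter_gene,
    dispersion = dispersion, seed = as.integer(seed)
  ), class = "sim_config")
}

random_dna <- function(width, gc) {
  paste(sample(c("A", "T", "G", "C"), width, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Simulate a paired RNA + ATAC multiome dataset
#'
#' Draws counts, fragments and peak sequences from a [sim_config()] and
#' returns the dataset together with the planted truth tables. Identical
#' seeds give bit-identical output.
#'
#' @param config A `sim_config`.
#' @return A list with elements `dataset` (class `multiome_dataset`: `rna`
#'   and `atac` [count_matrix()] objects, `fragments`, `peaks` (with observed
#'   GC content), `genes`, `cells`, `peak_seqs`) and `truth` (class
#'   `truth_tables`: `cells`, `links`, `gene_delta`).
#' @export
simulate_multiome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gm <- config$genes
  pk <- config$peaks
  n_genes <- nrow(gm)
  n_peaks <- nrow(pk)

  cells <- config$cells[rep(seq_len(nrow(config$cells)), config$cells$n), ]
  cells <- tibble::tibble(
    barcode = sprintf("CELL%05d", seq_len(nrow(cells))),
    cell_type = cells$cell_type, fate_map = cells$fate_map,
    disease = cells$disease,
    state = sim_state(cells$fate_map, cells$disease)
  )
  n_cells <- nrow(cells)
  fmm_log("simulate_multiome: %d cells, %d genes, %d peaks",
          n_cells, n_genes, n_peaks)

  rna_depth <- stats::rlnorm(
    n_cells, log(config$rna_depth_mean) - config$rna_depth_sdlog^2 / 2,
    config$rna_depth_sdlog)
  atac_depth <- stats::rlnorm(
    n_cells, log(config$atac_depth_mean) - config$atac_depth_sdlog^2 / 2,
    config$atac_depth_sdlog)

  gene_idx <- stats::setNames(seq_len(n_genes), gm$gene)
  peak_idx <- stats::setNames(seq_len(n_peaks), pk$peak)

  W <- matrix(config$gene_base_rate, n_genes, n_cells)
  for (i in seq_len(nrow(config$type_programs))) {
    p <- config$type_programs[i, ]
    sel <- cells$cell_type == p$cell_type
    W[gene_idx[[p$gene]], sel] <- W[gene_idx[[p$gene]], sel] * exp(p$log_fc)
  }
  for (i in seq_len(nrow(config$fate_programs))) {
    p <- config$fate_programs[i, ]
    sel <- cells$fate_map == p$fate_map
    W[gene_idx[[p$gene]], sel] <- W[gene_idx[[p$gene]], sel] * exp(p$log_fc)
  }
  V <- matrix(config$peak_base_access, n_peaks, n_cells)
  for (i in seq_len(nrow(config$peak_programs))) {
    p <- config$peak_programs[i, ]
    sel <- cells$cell_type == p$cell_type
    V[peak_idx[[p$peak]], sel] <- V[peak_idx[[p$peak]], sel] * exp(p$log_fc)
  }

  # shared latent activity behind each planted link
  lp <- config$linked_pairs
  if (nrow(lp)) {
    lat_ids <- unique(lp$latent_id)
    A <- matrix(stats::rgamma(length(lat_ids) * n_cells,
                              shape = config$dispersion,
                              rate = config$dispersion),
                length(lat_ids), n_cells,
                dimnames = list(lat_ids, NULL))
    for (i in seq_len(nrow(lp))) {
      a <- A[lp$latent_id[i], ]
      active <- cells$state %in% lp$active_in[[i]]
      fr <- ifelse(active, exp(lp$beta_rna[i] * a), 1)
      fa <- ifelse(active, exp(lp$beta_atac[i] * a), 1)
      W[gene_idx[[lp$gene[i]]], ] <- W[gene_idx[[lp$gene[i]]], ] * fr
      V[peak_idx[[lp$peak[i]]], ] <- V[peak_idx[[lp$peak[i]]], ] * fa
    }
  }

  lam_rna <- W * rep(rna_depth / colSums(W), each = n_genes)
  rna <- matrix(stats::rpois(length(lam_rna), lam_rna), n_genes, n_cells)
  rep_gene <- config$reporter_gene
  if (rep_gene %in% gm$gene) {
    is_exp <- cells$fate_map == "RAG_EXP"
    detected <- is_exp & (stats::runif(n_cells) < 1 - config$dropout_tdrfp)
    rep_counts <- ifelse(detected,
                         stats::rpois(n_cells, config$reporter_mean) + 1L, 0L)
    rna[gene_idx[[rep_gene]], ] <- rep_counts
  }

  lam_atac <- V * rep(atac_depth / colSums(V), each = n_peaks)
  atac <- matrix(stats::rpois(length(lam_atac), lam_atac), n_peaks, n_cells)

  # fragments: one record per counted (peak, cell) entry, count = multiplicity
  sub_frac <- stats::rbeta(n_cells, config$frag_sub_shape1,
                           config$frag_sub_shape2)
  nz <- which(atac > 0)
  pi_ <- (nz - 1L) %% n_peaks + 1L
  ci_ <- (nz - 1L) %/% n_peaks + 1L
  is_sub <- stats::runif(length(nz)) < sub_frac[ci_]
  frag_len <- ifelse(is_sub,
                     60L + floor(stats::runif(length(nz)) * 81),   # 60..140
                     147L + floor(stats::runif(length(nz)) * 148)) # 147..294
  p_start <- pk$start[pi_]
  p_width <- pk$end[pi_] - pk$start[pi_]
  f_start <- p_start + floor(stats::runif(length(nz)) *
                               pmax(1, p_width - frag_len))
  frags <- tibble::tibble(
    chrom = pk$chrom[pi_], start = as.numeric(f_start),
    end = as.numeric(f_start + frag_len), barcode = cells$barcode[ci_],
    count = as.numeric(atac[nz])
  )
  # uniform genomic background fragments
  n_bg <- stats::rpois(n_cells, config$background_frac * atac_depth)
  if (sum(n_bg) > 0) {
    bi <- rep(seq_len(n_cells), n_bg)
    chrom_bg <- sample(names(config$genome), length(bi), replace = TRUE,
                       prob = config$genome / sum(config$genome))
    len_bg <- ifelse(stats::runif(length(bi)) < sub_frac[bi],
                     60L + floor(stats::runif(length(bi)) * 81),
                     147L + floor(stats::runif(length(bi)) * 148))
    start_bg <- floor(stats::runif(length(bi)) *
                        (config$genome[chrom_bg] - len_bg))
    frags <- dplyr::bind_rows(frags, tibble::tibble(
      chrom = chrom_bg, start = as.numeric(start_bg),
      end = as.numeric(start_bg + len_bg), barcode = cells$barcode[bi],
      count = 1
    ))
  }
  frags <- dplyr::arrange(frags, .data$chrom, .data$start, .data$end,
                          .data$barcode)

  # peak sequences (random GC per peak, planted motif instances)
  gc_target <- 0.3 + 0.4 * stats::rbeta(n_peaks, 8, 8)
  seqs <- vapply(seq_len(n_peaks), function(i) {
    random_dna(pk$end[i] - pk$start[i], gc_target[i])
  }, character(1))
  names(seqs) <- pk$peak
  if (!is.null(config$motif_plants) && nrow(config$motif_plants)) {
    for (i in seq_len(nrow(config$motif_plants))) {
      p <- config$motif_plants[i, ]
      j <- peak_idx[[p$peak]]
      w <- nchar(seqs[[j]]); mw <- nchar(p$seq)
      off <- sample.int(w - mw + 1L, 1L)
      substr(seqs[[j]], off, off + mw - 1L) <- p$seq
    }
  }
  pk$gc <- vapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    mean(v %in% c("G", "C"))
  }, numeric(1))

  rna_cm <- count_matrix(rna, gm$gene, cells$barcode, "RNA")
  atac_cm <- count_matrix(atac, pk$peak, cells$barcode, "ATAC_PEAKS")

  gene_delta <- expected_gene_delta(lp)
  dataset <- structure(list(
    rna = rna_cm, atac = atac_cm, fragments = frags, peaks = pk,
    genes = gm, cells = cells, peak_seqs = seqs
  ), class = "multiome_dataset")
  truth <- structure(list(
    cells = cells,
    links = lp,
    gene_delta = gene_delta
  ), class = "truth_tables")
  list(dataset = dataset, truth = truth)
}

# Expected per-gene GPL-count difference (naive minus experienced) from the
# planted registry: a link counts for a fate if it is active in any state of
# that fate.
expected_gene_delta <- function(links) {
  if (!nrow(links)) {
    return(tibble::tibble(gene = character(), n_naive = integer(),
                          n_exp = integer(), delta = integer()))
  }
  fate_of <- function(states, fate) {
    any(startsWith(states, paste0(fate, "|")))
  }
  links |>
    dplyr::mutate(
      in_naive = purrr::map_lgl(.data$active_in, fate_of, "RAG_NAIVE"),
      in_exp = purrr::map_lgl(.data$active_in, fate_of, "RAG_EXP")
    ) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_naive = sum(.data$in_naive), n_exp = sum(.data$in_exp),
                     delta = .data$n_naive - .data$n_exp, .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$delta), .data$gene)
}

#' @export
print.multiome_dataset <- function(x, ...) {
  cat(sprintf(paste0("<multiome_dataset> %d cells; RNA %d genes; ",
                     "ATAC %d peaks; %d fragment records\n"),
              nrow(x$cells), nrow(x$rna$values), nrow(x$atac$values),
              nrow(x$fragments)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the exact formats the readers consume: MatrixMarket counts with
#' sidecars for both modalities, a 5-column fragments file, peaks as BED,
#' the gene model TSV, peak sequences as FASTA, cell metadata, and the truth
#' tables under `truth_*.tsv`.
#'
#' @param sim Output of [simulate_multiome()] (or just its `dataset` element
#'   when no truth is available).
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
emit_dataset <- function(sim, outdir) {
  dataset <- if (inherits(sim, "multiome_dataset")) sim else sim$dataset
  truth <- if (inherits(sim, "multiome_dataset")) NULL else sim$truth
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory ", outdir, call. = FALSE)
  }
  p <- function(...) file.path(outdir, ...)
  write_count_matrix(dataset$rna, p("rna_matrix.mtx"), p("rna_features.tsv"),
                     p("rna_barcodes.tsv"))
  write_count_matrix(dataset$atac, p("atac_matrix.mtx"),
                     p("atac_features.tsv"), p("atac_barcodes.tsv"))
  write_fragments(dataset$fragments, p("fragments.tsv"))
  write_peaks_bed(dataset$peaks, p("peaks.bed"))
  write_gene_model(dataset$genes, p("genes.tsv"))
  write_fasta(dataset$peak_seqs, p("peak_seqs.fa"))
  readr::write_tsv(dataset$cells, p("cells.tsv"), progress = FALSE)
  if (!is.null(truth)) {
    readr::write_tsv(truth$cells, p("truth_cells.tsv"), progress = FALSE)
    lk <- truth$links
    lk$active_in <- vapply(lk$active_in, paste, character(1), collapse = ",")
    readr::write_tsv(lk, p("truth_links.tsv"), progress = FALSE)
    readr::write_tsv(truth$gene_delta, p("truth_gene_delta.tsv"),
                     progress = FALSE)
  }
  fmm_log("emit_dataset: wrote %s", outdir)
  invisible(outdir)
}

#' Read a dataset written by [emit_dataset()]
#' @param outdir Directory written by [emit_dataset()].
#' @return A `multiome_dataset`.
#' @export
read_multiome_dataset <- function(outdir) {
  p <- function(...) file.path(outdir, ...)
  rna <- read_count_matrix(p("rna_matrix.mtx"), p("rna_features.tsv"),
                           p("rna_barcodes.tsv"), "RNA")
  atac <- read_count_matrix(p("atac_matrix.mtx"), p("atac_features.tsv"),
                            p("atac_barcodes.tsv"), "ATAC_PEAKS")
  seqs <- read_fasta(p("peak_seqs.fa"))
  peaks <- read_peaks_bed(p("peaks.bed"))
  peaks$gc <- vapply(seqs[peaks$peak], function(s) {
    v <- strsplit(s, "")[[1]]
    mean(v %in% c("G", "C"))
  }, numeric(1))
  structure(list(
    rna = rna, atac = atac,
    fragments = read_fragments(p("fragments.tsv")),
    peaks = peaks,
    genes = read_gene_model(p("genes.tsv")),
    cells = readr::read_tsv(p("cells.tsv"), col_types = readr::cols(),
                            progress = FALSE),
    peak_seqs = seqs
  ), class = "multiome_dataset")
}

#' The default fate-map multiome scenario
#'
#' A ready-made simulation configuration emulating a skin-draining lymph-node
#' mixture: ~2,000 cells over five cell types (ILC2, T, B, NK, DC), each
#' split by fate map (RAG-naive / RAG-experienced) and disease state (steady
#' state / AD-like), with
#' * 50 ILC2-program genes each coupled to one nearby peak, active only in
#'   RAG-naive states;
#' * 12 "induced" couplings active in both RAG-naive states and in
#'   RAG-experienced AD-like cells, but not RAG-experienced steady state;
#' * 8 constitutive couplings active in all four states;
#' * a 4-gene Th2-like cytokine block (Il4, Il13, Rad50, Il5) within one
#'   200 kb window whose peaks cross-link neighbouring genes;
#' * cell-type expression and accessibility programs, lineage-panel and
#'   mitochondrial/ribosomal genes, a tdRFP reporter with dropout, and a
#'   GATA-like motif planted in ILC2-specific peaks.
#'
#' @param seed Integer seed.
#' @return A `sim_config` whose attributes `motifs` (JASPAR-style PFMs),
#'   `motif_to_gene` (tibble) and `gene_sets` (GMT-style list) supply the
#'   downstream motif and GSEA stages.
#' @export
default_paper_scenario <- function(seed = 1L) {
  groups <- tidyr::expand_grid(
    cell_type = c("ILC2", "Tcell", "Bcell", "NK", "DC"),
    fate_map = SIM_FATES, disease = SIM_DISEASES
  )
  groups$n <- dplyr::case_when(
    groups$cell_type == "ILC2" ~ 240L,
    groups$cell_type == "Tcell" ~ 80L,
    TRUE ~ 60L
  )

  genome <- c(chr1 = 140e6, chr2 = 80e6, chr3 = 160e6, chr4 = 100e6,
              chr5 = 60e6)

  ilc2_link_names <- c("Il1rl1", "Icos", "Il2ra", "Il18r1", "Nmur1", "Klrg1",
                       "Arg1", "Areg", "Calca", "Csf2",
                       sprintf("Ilcl%02d", 11:50))
  ind_names <- sprintf("Indg%02d", 1:12)
  con_names <- sprintf("Cong%02d", 1:8)
  th2_names <- c("Il4", "Il13", "Rad50", "Il5")
  acc_names <- sprintf("Acc%02d", 1:60)
  prog_names <- list(
    ILC2 = c("Gata3", "Bcl11b", "Maf", "Ets1", "Rora", "Ptgdr2",
             sprintf("Ilc2p%02d", 7:32)),
    Tcell = c("Lck", "Thy1", "Cd2", sprintf("Tcp%02d", 4:32)),
    Bcell = c("Ms4a1", "Cd79a", "Cd79b", sprintf("Bcp%02d", 4:32)),
    NK = c("Ncr1", "Gzma", "Klrk1", sprintf("Nkp%02d", 4:32)),
    DC = c("Itgax", "Flt3", "Cst3", sprintf("Dcp%02d", 4:32))
  )
  fate_names <- sprintf("Ragx%02d", 1:60)
  mito_names <- c("mt-Co1", "mt-Co2", "mt-Co3", "mt-Cytb", "mt-Atp6",
                  "mt-Atp8", sprintf("mt-Nd%d", 1:6), "mt-Nd4l")
  ribo_names <- c(sprintf("Rps%d", 1:10), sprintf("Rpl%d", 1:10))
  lineage_names <- c("Cd3d", "Cd3e", "Cd3g", "Cd4", "Cd19", "Cd8a", "Itgam")
  tf_names <- c("Ctcf", "Tfx1")
  fill_names <- sprintf("Fill%03d", 1:150)

  # chr1: 50 naive-only link loci (gene + promoter peak + linked peak +
  # neutral peak), 2.5 Mb apart so linkage windows do not overlap
  locus <- function(chrom, centers, gene_names, tag) {
    g <- tibble::tibble(gene = gene_names, chrom = chrom, start = centers,
                        end = centers + 2000, strand = "+")
    pks <- dplyr::bind_rows(
      tibble::tibble(chrom = chrom, start = centers - 250,
                     end = centers + 250, role = "promoter", gene = gene_names),
      tibble::tibble(chrom = chrom, start = centers + 20000,
                     end = centers + 20400, role = paste0(tag, "_link"),
                     gene = gene_names),
      tibble::tibble(chrom = chrom, start = centers - 50000,
                     end = centers - 49600, role = "neutral",
                     gene = gene_names)
    )
    list(genes = g, peaks = pks)
  }
  l1 <- locus("chr1", 2e6 + (0:49) * 2.5e6, ilc2_link_names, "naive")
  # a second coupled peak per naive locus: regulomes carry several links
  l1b <- tibble::tibble(chrom = "chr1", start = 2e6 + (0:49) * 2.5e6 + 40000,
                        end = 2e6 + (0:49) * 2.5e6 + 40400,
                        role = "naive_link2", gene = ilc2_link_names)
  l2 <- locus("chr2", 2e6 + (0:11) * 2.5e6, ind_names, "induced")
  l3 <- locus("chr2", 2e6 + (12:19) * 2.5e6, con_names, "constitutive")

  # chr3: cell-type marker peaks 1 Mb apart; 12 per type sit inside an
  # expression-flat gene body (driving gene activity and DA without linking
  # to expression), the rest are gene-free
  types <- names(prog_names)
  tp_pos <- 2e6 + (0:149) * 1e6
  tp_type <- rep(types, each = 30)
  type_peaks <- tibble::tibble(chrom = "chr3", start = tp_pos,
                               end = tp_pos + 400, role = "type_peak",
                               gene = NA_character_, type = tp_type)
  acc_genes <- tibble::tibble(gene = acc_names, chrom = "chr3",
                              start = NA_real_, end = NA_real_, strand = "+")
  embed_idx <- unlist(lapply(0:4, function(t) t * 30 + 1:12))
  acc_genes$start <- type_peaks$start[embed_idx] - 2000
  acc_genes$end <- type_peaks$start[embed_idx] + 8000

  # chr4: Th2-like block in a 200 kb window, then programme genes (no
  # nearby peaks) spaced along the chromosome
  th2 <- tibble::tibble(
    gene = th2_names, chrom = "chr4",
    start = c(10.00e6, 10.05e6, 10.09e6, 10.15e6),
    end = c(10.01e6, 10.06e6, 10.11e6, 10.16e6),
    strand = c("-", "+", "+", "-")
  )
  th2_peak_pos <- seq(10.005e6, 10.16e6, length.out = 12)
  th2_peaks <- tibble::tibble(chrom = "chr4", start = round(th2_peak_pos),
                              end = round(th2_peak_pos) + 400,
                              role = "th2_block", gene = NA_character_)
  th2_prom <- tibble::tibble(chrom = "chr4",
                             start = ifelse(th2$strand == "+",
                                            th2$start - 250, th2$end - 250),
                             end = ifelse(th2$strand == "+",
                                          th2$start + 250, th2$end + 250),
                             role = "promoter", gene = th2$gene)
  chr4_rest <- c(unlist(prog_names, use.names = FALSE), fate_names)
  g4 <- tibble::tibble(gene = chr4_rest, chrom = "chr4",
                       start = 15e6 + (seq_along(chr4_rest) - 1) * 3e5,
                       end = 15e6 + (seq_along(chr4_rest) - 1) * 3e5 + 2000,
                       strand = "+")

  # chr5: housekeeping-style genes, no peaks
  chr5_genes <- c(mito_names, ribo_names, lineage_names, "tdRFP", tf_names,
                  fill_names)
  g5 <- tibble::tibble(gene = chr5_genes, chrom = "chr5",
                       start = 2e6 + (seq_along(chr5_genes) - 1) * 2.5e5,
                       end = 2e6 + (seq_along(chr5_genes) - 1) * 2.5e5 + 2000,
                       strand = rep(c("+", "-"), length.out =
                                      length(chr5_genes)))

  genes <- dplyr::bind_rows(l1$genes, l2$genes, l3$genes, acc_genes, th2, g4,
                            g5)
  peaks <- dplyr::bind_rows(l1$peaks, l1b, l2$peaks, l3$peaks, type_peaks,
                            th2_peaks, th2_prom)
  peaks$peak <- peak_name(peaks)

  # base rates
  gene_base <- stats::setNames(rep(1, nrow(genes)), genes$gene)
  gene_base[mito_names] <- 1.2
  gene_base[ribo_names] <- 1.5
  gene_base[lineage_names] <- 0.001
  gene_base["tdRFP"] <- 0       # overwritten by the reporter model
  gene_base["Tfx1"] <- 0        # enriched motif without an expressed TF
  gene_base[c(ilc2_link_names, ind_names, con_names, th2_names)] <- 3
  peak_base <- stats::setNames(rep(1, nrow(peaks)), peaks$peak)
  peak_base[peaks$peak[peaks$role == "promoter"]] <- 2
  peak_base[peaks$peak[peaks$role == "type_peak"]] <- 0.7
  peak_base[peaks$peak[peaks$role %in% c("naive_link", "naive_link2",
                                         "induced_link",
                                         "constitutive_link",
                                         "th2_block")]] <- 2

  # programs
  type_programs <- dplyr::bind_rows(
    purrr::imap(prog_names, function(g, t) {
      tibble::tibble(gene = g, cell_type = t, log_fc = log(6))
    })
  )
  type_programs <- dplyr::bind_rows(
    type_programs,
    tibble::tibble(gene = th2_names, cell_type = "ILC2", log_fc = 0.25),
    # lineage-panel genes: tuned so the purge removes roughly half of each
    # non-ILC2 population (detection is Poisson, so removal = 1 - exp(-sum))
    tibble::tibble(gene = c("Cd3d", "Cd3e", "Cd3g", "Cd4", "Cd8a"),
                   cell_type = "Tcell", log_fc = log(26)),
    tibble::tibble(gene = "Cd19", cell_type = "Bcell", log_fc = log(130)),
    tibble::tibble(gene = "Itgam", cell_type = "NK", log_fc = log(65)),
    tibble::tibble(gene = "Itgam", cell_type = "DC", log_fc = log(130)),
    tibble::tibble(gene = "Itgax", cell_type = "DC", log_fc = 0)[0, ]
  )
  fate_programs <- tibble::tibble(gene = fate_names, fate_map = "RAG_EXP",
                                  log_fc = 0.45)
  peak_programs <- tibble::tibble(
    peak = peaks$peak[peaks$role == "type_peak"],
    cell_type = tp_type, log_fc = log(6)
  )

  # planted links
  naive_states <- sim_state("RAG_NAIVE", c("SS", "AD"))
  induced_states <- c(naive_states, sim_state("RAG_EXP", "AD"))
  all_states <- sim_state(rep(SIM_FATES, each = 2), rep(SIM_DISEASES, 2))
  link_peak <- function(tag) peaks$peak[peaks$role == paste0(tag, "_link")]
  lp <- dplyr::bind_rows(
    tibble::tibble(gene = ilc2_link_names, peak = link_peak("naive"),
                   beta_atac = 0.35, beta_rna = 0.3,
                   active_in = rep(list(naive_states), 50),
                   latent_id = paste0("L_naive_", 1:50), class = "naive_only"),
    tibble::tibble(gene = ilc2_link_names,
                   peak = peaks$peak[peaks$role == "naive_link2"],
                   beta_atac = 0.35, beta_rna = 0.3,
                   active_in = rep(list(naive_states), 50),
                   latent_id = paste0("L_naive2_", 1:50),
                   class = "naive_only"),
    tibble::tibble(gene = ind_names, peak = link_peak("induced"),
                   beta_atac = 0.38, beta_rna = 0.33,
                   active_in = rep(list(induced_states), 12),
                   latent_id = paste0("L_ind_", 1:12), class = "induced"),
    tibble::tibble(gene = con_names, peak = link_peak("constitutive"),
                   beta_atac = 0.4, beta_rna = 0.35,
                   active_in = rep(list(all_states), 8),
                   latent_id = paste0("L_con_", 1:8), class = "constitutive")
  )
  # Th2 block: each block peak cross-links its two nearest genes through one
  # shared latent; half naive-only, half induced
  th2_tss <- stats::setNames(ifelse(th2$strand == "+", th2$start,
                                    th2$end - 1), th2$gene)
  th2_pk <- peaks[peaks$role == "th2_block", ]
  th2_links <- purrr::map_dfr(seq_len(nrow(th2_pk)), function(i) {
    ctr <- (th2_pk$start[i] + th2_pk$end[i]) / 2
    nearest2 <- names(sort(abs(th2_tss - ctr)))[1:2]
    st <- if (i %% 4 == 0) induced_states else naive_states
    cls <- if (i %% 4 == 0) "th2_induced" else "th2_naive"
    tibble::tibble(gene = nearest2, peak = th2_pk$peak[i],
                   beta_atac = 0.38, beta_rna = 0.33,
                   active_in = rep(list(st), 2),
                   latent_id = paste0("L_th2_", i), class = cls)
  })
  lp <- dplyr::bind_rows(lp, th2_links)

  # motifs: a GATA-like motif planted in every ILC2 type peak, a CTCF-like
  # motif in a random subset of peaks, and a motif planted nowhere
  set.seed(seed)
  gata_seq <- "AGATAAGA"
  ctcf_seq <- "CCGCGAGGTGGCAG"
  ilc2_pk <- peaks$peak[peaks$role == "type_peak"][tp_type == "ILC2"]
  ctcf_pk <- sample(setdiff(peaks$peak, ilc2_pk),
                    round(0.08 * nrow(peaks)))
  motif_plants <- dplyr::bind_rows(
    tibble::tibble(peak = ilc2_pk, seq = gata_seq),
    tibble::tibble(peak = ctcf_pk, seq = ctcf_seq)
  )

  cfg <- sim_config(
    cells = groups, genes = genes[, c("gene", "chrom", "start", "end",
                                      "strand")],
    peaks = peaks[, c("chrom", "start", "end", "peak")], genome = genome,
    gene_base_rate = gene_base, peak_base_access = peak_base,
    type_programs = type_programs, peak_programs = peak_programs,
    fate_programs = fate_programs, linked_pairs = lp,
    motif_plants = motif_plants, seed = seed
  )
  attr(cfg, "peak_roles") <- peaks[, c("peak", "role")]
  attr(cfg, "motifs") <- scenario_motifs()
  attr(cfg, "motif_to_gene") <- tibble::tibble(
    motif = c("MA_GATA", "MA_CTCF", "MA_TFX"),
    gene = c("Gata3", "Ctcf", "Tfx1")
  )
  attr(cfg, "gene_sets") <- scenario_gene_sets(
    fate_names, c(ilc2_link_names, ind_names, con_names, th2_names),
    fill_names, seed)
  cfg
}

# Consensus-dominated PFMs matching the planted motif instances.
scenario_motifs <- function() {
  pfm_from_consensus <- function(consensus, nm) {
    b <- c(A = 1, C = 2, G = 3, T = 4)
    m <- matrix(1, 4, nchar(consensus),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    idx <- b[strsplit(consensus, "")[[1]]]
    for (j in seq_along(idx)) m[idx[j], j] <- 97
    attr(m, "motif_name") <- nm
    m
  }
  list(MA_GATA = pfm_from_consensus("AGATAAGA", "Gata3"),
       MA_CTCF = pfm_from_consensus("CCGCGAGGTGGCAG", "Ctcf"),
       MA_TFX = pfm_from_consensus("TTGACGTCAA", "Tfx1"))
}

# Gene sets for the preranked GSEA stage: sets carrying the RAG-experience
# expression program and the naive-state regulome genes, plus size-matched
# null sets.
scenario_gene_sets <- function(fate_genes, naive_genes, filler_genes, seed) {
  set.seed(seed + 101L)
  pool <- c(filler_genes, sprintf("Acc%02d", 1:60),
            sprintf("Tcp%02d", 4:32), sprintf("Bcp%02d", 4:32))
  sets <- list(RAG_EXP_PROGRAM = fate_genes,
               RAG_NAIVE_REGULOME = naive_genes)
  for (i in 1:10) {
    sets[[sprintf("NULL_SET_%02d", i)]] <- sample(pool, 55)
  }
  sets
}

#' Null-calibration scenario for the link statistic
#'
#' A single-population configuration with no planted couplings: 50 genes in
#' well-separated loci, each with 20 candidate peaks inside the linkage
#' window (1,000 candidate pairs in total). Permuting expression across
#' cells and re-running the link caller on this scenario measures the
#' empirical retention rate of the matched-background test under the null.
#'
#' @param n_cells Number of cells (default 500).
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
null_calibration_scenario <- function(n_cells = 500, seed = 1L) {
  n_loci <- 50
  centers <- 2e6 + (seq_len(n_loci) - 1) * 2.5e6
  genes <- tibble::tibble(gene = sprintf("G%02d", seq_len(n_loci)),
                          chrom = "chr1", start = centers,
                          end = centers + 2000, strand = "+")
  pk <- purrr::map_dfr(seq_len(20), function(j) {
    off <- -5e5 + j * 47000  # spread across the window, avoiding the TSS
    tibble::tibble(chrom = "chr1", start = centers + off,
                   end = centers + off + 400)
  })
  pk$peak <- peak_name(pk)
  sim_config(
    cells = tibble::tibble(cell_type = "ILC2", fate_map = "RAG_NAIVE",
                           disease = "SS", n = n_cells),
    genes = genes, peaks = pk, genome = c(chr1 = max(centers) + 5e6),
    gene_base_rate = stats::setNames(rep(3, n_loci), genes$gene),
    peak_base_access = stats::setNames(rep(2, nrow(pk)), pk$peak),
    seed = seed
  )
}
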