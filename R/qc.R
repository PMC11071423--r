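# Per-cell QC metrics, the filter cascade, lineage purge and fate-map
# labelling from the reporter transcript.

#' Per-cell ATAC QC metrics from fragments
#'
#' Computes, per barcode: total fragment counts (`n_atac`, the sum of the
#' duplicate-count field), the nucleosome signal (count-weighted fragments of
#' mono-nucleosomal length 147-294 bp divided by sub-nucleosomal fragments
#' < 147 bp; `Inf` when the denominator is zero), and the TSS enrichment
#' (mean per-base insertion coverage within +/-100 bp of any TSS divided by
#' the mean coverage in two 100-bp flanks centred +/-950 bp from the TSS,
#' with a 1e-9 pseudocount in the denominator). Both fragment ends count as
#' insertions.
#'
#' @param fragments Fragment tibble ([read_fragments()]).
#' @param gene_model Gene model tibble with a `tss` column
#'   ([read_gene_model()]).
#' @param barcodes Optional barcode universe; barcodes without fragments get
#'   zero counts.
#' @return Tibble with `barcode`, `n_atac`, `nucleosome_signal`,
#'   `tss_enrichment`.
#' @export
compute_atac_qc <- function(fragments, gene_model, barcodes = NULL) {
  barcodes <- barcodes %||% sort(unique(fragments$barcode))
  bc_idx <- match(fragments$barcode, barcodes)
  if (anyNA(bc_idx)) stop("fragment barcode outside barcode universe",
                          call. = FALSE)
  n_atac <- as.numeric(rowsum_safe(fragments$count, bc_idx,
                                   length(barcodes)))

  len <- fragments$end - fragments$start
  mono <- rowsum_safe(fragments$count * (len >= 147 & len <= 294), bc_idx,
                      length(barcodes))
  sub <- rowsum_safe(fragments$count * (len < 147), bc_idx, length(barcodes))
  ns <- ifelse(sub == 0, Inf, mono / sub)

  # insertions: both fragment ends (0-based positions start and end-1)
  shared <- intersect(unique(fragments$chrom), unique(gene_model$chrom))
  if (!length(shared) && nrow(fragments)) {
    warning("no TSS on any fragment chromosome; TSS enrichment set to 0")
    tssE <- rep(0, length(barcodes))
  } else {
    center_w <- numeric(length(barcodes))
    flank_w <- numeric(length(barcodes))
    for (ch in shared) {
      sel <- fragments$chrom == ch
      tss <- sort(gene_model$tss[gene_model$chrom == ch])
      pos <- c(fragments$start[sel], fragments$end[sel] - 1)
      w <- rep(fragments$count[sel], 2)
      bi <- rep(bc_idx[sel], 2)
      # distance to nearest TSS
      j <- findInterval(pos, tss)
      d_left <- ifelse(j >= 1, pos - tss[pmax(j, 1)], Inf)
      d_right <- ifelse(j < length(tss), tss[pmin(j + 1, length(tss))] - pos,
                        Inf)
      d <- pmin(abs(d_left), abs(d_right))
      in_center <- d <= 100
      in_flank <- d >= 900 & d < 1000
      if (any(in_center)) {
        center_w <- center_w + rowsum_safe(w[in_center], bi[in_center],
                                           length(barcodes))
      }
      if (any(in_flank)) {
        flank_w <- flank_w + rowsum_safe(w[in_flank], bi[in_flank],
                                         length(barcodes))
      }
    }
    tssE <- (center_w / 201) / (flank_w / 200 + 1e-9)
  }
  tibble::tibble(barcode = barcodes, n_atac = n_atac,
                 nucleosome_signal = as.numeric(ns),
                 tss_enrichment = as.numeric(tssE))
}

# rowsum over a fixed number of groups, returning a dense vector
rowsum_safe <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(as.numeric(x), idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Per-cell RNA QC metrics
#'
#' Total counts per cell plus the percentage of counts from mitochondrial
#' genes (`mt-` prefix, case-insensitive) and from ribosomal protein genes
#' (`Rps`/`Rpl` prefixes). All-zero cells get 0 percentages (not `NaN`).
#'
#' @param rna A [count_matrix()] whose feature ids are gene symbols.
#' @return Tibble with `barcode`, `n_rna`, `pct_mito`, `pct_ribo`.
#' @export
compute_rna_qc <- function(rna) {
  stopifnot(inherits(rna, "count_matrix"))
  m <- rna$values
  n_rna <- Matrix::colSums(m)
  mito <- grepl("^mt-", rna$feature_ids, ignore.case = TRUE)
  ribo <- grepl("^Rp[sl]", rna$feature_ids, ignore.case = TRUE)
  pct <- function(rows) {
    s <- if (any(rows)) Matrix::colSums(m[rows, , drop = FALSE]) else 0
    ifelse(n_rna == 0, 0, 100 * s / n_rna)
  }
  tibble::tibble(barcode = rna$barcodes, n_rna = as.numeric(n_rna),
                 pct_mito = as.numeric(pct(mito)),
                 pct_ribo = as.numeric(pct(ribo)))
}

#' Combined per-cell QC table
#'
#' @param dataset A `multiome_dataset`.
#' @return Tibble with one row per barcode and all six QC metrics.
#' @export
compute_cell_qc <- function(dataset) {
  rq <- compute_rna_qc(dataset$rna)
  aq <- compute_atac_qc(dataset$fragments, dataset$genes,
                        barcodes = dataset$rna$barcodes)
  dplyr::left_join(rq, aq, by = "barcode")
}

#' Default QC thresholds
#'
#' Strict bounds for the six-gate filter cascade: nucleosome signal < 1.5,
#' TSS enrichment > 1, RNA counts in (1,000, 15,000), ATAC counts in
#' (100, 75,000), mitochondrial percentage < 5 and ribosomal percentage
#' < 10.
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  cfg <- default_run_config()
  cfg[c("ns_max", "tss_min", "rna_max", "rna_min", "atac_max", "atac_min",
        "mito_max", "ribo_max")]
}

#' Apply the QC filter cascade
#'
#' A barcode is kept iff all six predicates hold with strict inequalities:
#' `nucleosome_signal < ns_max`, `tss_enrichment > tss_min`,
#' `rna_min < n_rna < rna_max`, `atac_min < n_atac < atac_max`,
#' `pct_mito < mito_max`, `pct_ribo < ribo_max`. The cascade is a pure
#' conjunction, so gate order is irrelevant.
#'
#' @param qc QC tibble ([compute_cell_qc()]).
#' @param thresholds Named list ([qc_thresholds()] or a `run_config`).
#' @return Character vector of kept barcodes.
#' @export
apply_qc_filters <- function(qc, thresholds = qc_thresholds()) {
  need <- c("barcode", "n_rna", "n_atac", "pct_mito", "pct_ribo",
            "nucleosome_signal", "tss_enrichment")
  miss <- setdiff(need, names(qc))
  if (length(miss)) {
    stop("QC table missing metric(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vals <- qc[, setdiff(need, "barcode")]
  if (anyNA(vals)) stop("QC table contains missing metric values",
                        call. = FALSE)
  th <- thresholds
  keep <- qc$nucleosome_signal < th$ns_max &
    qc$tss_enrichment > th$tss_min &
    qc$n_rna > th$rna_min & qc$n_rna < th$rna_max &
    qc$n_atac > th$atac_min & qc$n_atac < th$atac_max &
    qc$pct_mito < th$mito_max & qc$pct_ribo < th$ribo_max
  fmm_log("apply_qc_filters: %d / %d barcodes kept", sum(keep), nrow(qc))
  qc$barcode[keep]
}

#' Purge lineage-marker-positive cells
#'
#' Removes every cell with a non-zero count for any gene of the lineage
#' panel (default: Cd3d, Cd3e, Cd3g, Cd4, Cd19, Cd8a, Itgam), mirroring a
#' negative-selection step. Panel genes absent from the features are skipped
#' with a warning; an empty panel keeps all cells.
#'
#' @param rna A [count_matrix()].
#' @param panel Character vector of lineage genes.
#' @return Character vector of kept barcodes.
#' @export
purge_lineage_cells <- function(rna,
                                panel = c("Cd3d", "Cd3e", "Cd3g", "Cd4",
                                          "Cd19", "Cd8a", "Itgam")) {
  stopifnot(inherits(rna, "count_matrix"))
  present <- intersect(panel, rna$feature_ids)
  missing <- setdiff(panel, present)
  if (length(missing)) {
    warning("lineage panel gene(s) absent from features, skipped: ",
            paste(missing, collapse = ", "))
  }
  if (!length(present)) return(rna$barcodes)
  pos <- Matrix::colSums(rna$values[present, , drop = FALSE] > 0) > 0
  fmm_log("purge_lineage_cells: removed %d / %d", sum(pos), length(pos))
  rna$barcodes[!pos]
}

#' Assign fate-map labels from the reporter transcript
#'
#' A cell is labelled `RAG_EXP` iff its reporter count is above the
#' detection threshold (default: any count at all), else `RAG_NAIVE`.
#'
#' @param rna A [count_matrix()].
#' @param reporter Reporter feature name (default `"tdRFP"`).
#' @param min_count Detection threshold; counts strictly greater are called
#'   detected.
#' @return Tibble with `barcode`, `label`.
#' @export
assign_fatemap <- function(rna, reporter = "tdRFP", min_count = 0) {
  stopifnot(inherits(rna, "count_matrix"))
  if (!reporter %in% rna$feature_ids) {
    stop("reporter gene '", reporter, "' absent from features",
         call. = FALSE)
  }
  cnt <- as.numeric(rna$values[reporter, ])
  tibble::tibble(barcode = rna$barcodes,
                 label = ifelse(cnt > min_count, "RAG_EXP", "RAG_NAIVE"))
}

#' Subset a multiome dataset to a set of barcodes
#'
#' @param dataset A `multiome_dataset`.
#' @param barcodes Barcodes to keep (order defines the output order).
#' @return The subsetted `multiome_dataset` (fragments restricted to kept
#'   barcodes).
#' @export
filter_dataset <- function(dataset, barcodes) {
  stopifnot(all(barcodes %in% dataset$rna$barcodes))
  keep <- function(cm) {
    count_matrix(cm$values[, barcodes, drop = FALSE], cm$feature_ids,
                 barcodes, cm$modality)
  }
  dataset$rna <- keep(dataset$rna)
  dataset$atac <- keep(dataset$atac)
  dataset$fragments <- dataset$fragments[
    dataset$fragments$barcode %in% barcodes, ]
  if (!is.null(dataset$cells)) {
    dataset$cells <- dataset$cells[match(barcodes, dataset$cells$barcode), ]
  }
  dataset
}

#' Run the full QC stage
#'
#' Computes the QC table, applies the six-gate cascade, purges
#' lineage-positive cells among the survivors, and assigns fate-map labels.
#' Stage counts are logged (raw, post-QC, post-purge).
#'
#' @param dataset A `multiome_dataset`.
#' @param config A `run_config`.
#' @param lineage_panel Lineage purge panel.
#' @return List with `qc` (per-cell table with `kept_qc`, `kept`,
#'   `fate_map` columns) and `dataset` (filtered).
#' @export
run_qc <- function(dataset, config = default_run_config(),
                   lineage_panel = c("Cd3d", "Cd3e", "Cd3g", "Cd4", "Cd19",
                                     "Cd8a", "Itgam")) {
  qc <- compute_cell_qc(dataset)
  kept_qc <- apply_qc_filters(qc, config)
  ds_qc <- filter_dataset(dataset, kept_qc)
  kept <- purge_lineage_cells(ds_qc$rna, lineage_panel)
  ds <- filter_dataset(ds_qc, kept)
  fm <- assign_fatemap(ds$rna, config$reporter_gene)
  qc$kept_qc <- qc$barcode %in% kept_qc
  qc$kept <- qc$barcode %in% kept
  qc <- dplyr::left_join(qc, fm, by = "barcode") |>
    dplyr::rename(fate_map = "label")
  fmm_log("run_qc: %d raw -> %d post-QC -> %d post-purge",
          nrow(qc), length(kept_qc), length(kept))
  list(qc = qc, dataset = ds, fate_map = fm)
}
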