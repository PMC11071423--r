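# broom-style tidiers and ggplot2 helpers for the result classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a multiomic signature
#' @param x A `signature_set`.
#' @param ... Unused.
#' @return One row per Venn region (`region`, `n_genes`).
#' @method tidy signature_set
#' @export
tidy.signature_set <- function(x, ...) {
  tibble::tibble(region = names(x$overlap_counts),
                 n_genes = as.integer(x$overlap_counts))
}

#' @rdname tidy.signature_set
#' @method glance signature_set
#' @export
glance.signature_set <- function(x, ...) {
  tibble::tibble(n_union = length(x$union),
                 n_gex = length(x$gex_top), n_ga = length(x$ga_top),
                 n_da = length(x$da_top),
                 n_triple = unname(x$overlap_counts["abc"]))
}

#' Tidy per-cell motif deviations
#' @param x A `deviation_result`.
#' @param ... Unused.
#' @return Long tibble (`motif`, `barcode`, `raw`, `z`).
#' @method tidy deviation_result
#' @export
tidy.deviation_result <- function(x, ...) {
  tibble::tibble(
    motif = rep(rownames(x$z), ncol(x$z)),
    barcode = rep(colnames(x$z), each = nrow(x$z)),
    raw = as.vector(x$raw), z = as.vector(x$z)
  )
}

#' @rdname tidy.deviation_result
#' @method glance deviation_result
#' @export
glance.deviation_result <- function(x, ...) {
  tibble::tibble(n_motifs = nrow(x$z), n_cells = ncol(x$z),
                 n_bg = x$n_bg)
}

#' Summarise a pipeline run
#' @param x An `fmm_pipeline`.
#' @param ... Unused.
#' @return One-row tibble with headline counts.
#' @method glance fmm_pipeline
#' @export
glance.fmm_pipeline <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$clusters),
    n_clusters = length(unique(x$clusters$cluster)),
    ilc2_cluster = x$ilc2_cluster,
    n_signature = length(x$signature$union),
    n_links_naive = if (!is.null(x$links_by_fate))
      nrow(x$links_by_fate[["RAG_NAIVE"]]) else NA_integer_,
    n_links_exp = if (!is.null(x$links_by_fate))
      nrow(x$links_by_fate[["RAG_EXP"]]) else NA_integer_,
    n_induced_peaks = if (!is.null(x$induced))
      length(x$induced$induced_peaks) else NA_integer_
  )
}

#' QC scatter plot
#'
#' RNA versus ATAC totals on log scales, coloured by kept status.
#'
#' @param qc QC tibble from [run_qc()] (needs `kept`).
#' @return A ggplot.
#' @export
plot_qc <- function(qc) {
  ggplot2::ggplot(qc, ggplot2::aes(x = .data$n_rna, y = .data$n_atac,
                                   colour = .data$kept)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "RNA counts", y = "ATAC fragment counts",
                  colour = "kept") +
    ggplot2::theme_minimal()
}

#' Regulome difference bar plot
#'
#' Per-gene link counts in the two fate-map populations with the difference
#' overlaid, naive-rich genes at the top.
#'
#' @param regulome Tibble from [regulome_counts()].
#' @param top_n Number of genes shown from each end.
#' @return A ggplot.
#' @export
plot_regulome <- function(regulome, top_n = 20) {
  d <- dplyr::bind_rows(utils::head(regulome, top_n),
                        utils::tail(regulome, top_n)) |>
    dplyr::distinct() |>
    dplyr::mutate(gene = factor(.data$gene, levels = rev(.data$gene)))
  long <- tidyr::pivot_longer(d, c("n_links_naive", "n_links_exp"),
                              names_to = "population", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$n,
                                     fill = .data$population)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_point(data = d,
                        ggplot2::aes(x = .data$gene, y = .data$delta),
                        inherit.aes = FALSE, shape = 18) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "gene-to-peak links") +
    ggplot2::theme_minimal()
}

#' UpSet-style bar plot of exclusive intersections
#'
#' @param intersections Tibble from [exclusive_intersections()].
#' @return A ggplot (bars of exclusive combination sizes).
#' @export
plot_upset <- function(intersections) {
  d <- dplyr::filter(intersections, .data$size > 0) |>
    dplyr::mutate(combo = factor(.data$combo, levels = .data$combo))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$combo, y = .data$size)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "exclusive combination", y = "peaks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' GSEA summary plot
#'
#' Normalised enrichment scores of the tested sets, significant sets
#' highlighted.
#'
#' @param gsea Result of [gsea_preranked()] (the full table attribute is
#'   used when available).
#' @param p_cutoff Highlight threshold on adjusted p.
#' @return A ggplot.
#' @export
plot_gsea <- function(gsea, p_cutoff = 0.05) {
  d <- attr(gsea, "full") %||% gsea
  d <- dplyr::mutate(d, significant = .data$p_adj < p_cutoff,
                     set = stats::reorder(.data$set, .data$nes))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$set, y = .data$nes,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalised enrichment score") +
    ggplot2::theme_minimal()
}

#' @method autoplot signature_set
#' @export
autoplot.signature_set <- function(object, ...) {
  d <- tidy(object)
  d$region <- factor(d$region, levels = d$region)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$n_genes)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Venn region", y = "genes") +
    ggplot2::theme_minimal()
}

#' @method autoplot deviation_result
#' @export
autoplot.deviation_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$barcode, y = .data$motif,
                                  fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
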