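# Motif scanning over peak sequences, chromVAR-style per-cell deviation
# z-scores, hypergeometric motif enrichment, and TF-expression
# cross-referencing.

#' Log-odds position weight matrix from a position frequency matrix
#'
#' Column probabilities use pseudocount 0.8 distributed by the background
#' base frequencies; scores are log2 odds against that background.
#'
#' @param pfm 4 x width matrix of non-negative counts (rows A, C, G, T).
#' @param pseudocount Total pseudocount per column.
#' @param background Base frequencies (default uniform).
#' @return 4 x width log2-odds matrix (class `pwm_motif`), with
#'   `max_score` attribute.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.8,
                       background = rep(0.25, 4)) {
  stopifnot(nrow(pfm) == 4, all(pfm >= 0))
  prob <- sweep(pfm + pseudocount * background, 2,
                colSums(pfm) + pseudocount, "/")
  lo <- log2(prob / background)
  rownames(lo) <- c("A", "C", "G", "T")
  attr(lo, "max_score") <- sum(apply(lo, 2, max))
  attr(lo, "motif_name") <- attr(pfm, "motif_name")
  class(lo) <- c("pwm_motif", class(lo))
  lo
}

encode_dna <- function(seq) {
  code <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L  # N and friends score as background (0 log-odds)
  code
}

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(seq, "")[[1]]),
                                       collapse = ""))
}

# best log-odds score of a motif over all offsets of an encoded sequence
best_pwm_score <- function(code, lo5) {
  w <- ncol(lo5)
  L <- length(code)
  if (L < w) return(-Inf)
  s <- numeric(L - w + 1)
  for (j in seq_len(w)) {
    s <- s + lo5[code[j:(L - w + j)], j]
  }
  max(s)
}

#' Scan motifs over peak sequences
#'
#' A peak is a hit for a motif when the maximal log-odds score over both
#' strands and all offsets reaches `threshold_fraction` of the motif's
#' maximum attainable score. `N` bases score as background (0 log-odds);
#' sequences shorter than the motif are simply not hits.
#'
#' @param peak_sequences Named character vector (one sequence per peak).
#' @param motifs Named list of PFMs ([read_pfm_set()]) or `pwm_motif`s.
#' @param threshold_fraction Fraction of the maximum attainable score.
#' @return Logical motifs x peaks matrix (class preserved as plain matrix)
#'   with dimnames.
#' @export
scan_motifs <- function(peak_sequences, motifs, threshold_fraction = 0.8) {
  pwms <- lapply(motifs, function(m) {
    if (inherits(m, "pwm_motif")) m else pfm_to_pwm(m)
  })
  codes_f <- lapply(peak_sequences, function(s) encode_dna(toupper(s)))
  codes_r <- lapply(peak_sequences, function(s) {
    encode_dna(toupper(revcomp(s)))
  })
  hits <- matrix(FALSE, length(pwms), length(peak_sequences),
                 dimnames = list(names(pwms),
                                 names(peak_sequences) %||%
                                   seq_along(peak_sequences)))
  for (m in seq_along(pwms)) {
    lo5 <- rbind(unclass(pwms[[m]]), 0)
    thr <- threshold_fraction * attr(pwms[[m]], "max_score")
    for (i in seq_along(codes_f)) {
      sc <- max(best_pwm_score(codes_f[[i]], lo5),
                best_pwm_score(codes_r[[i]], lo5))
      hits[m, i] <- sc >= thr
    }
  }
  hits
}

# GC x accessibility bin id per peak (10 x 10 quantile bins)
match_bins <- function(gc, acc, n_bins = 10) {
  bin_of <- function(v) {
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out =
                                                  n_bins + 1)))
    if (length(br) < 2) return(rep(1L, length(v)))
    as.integer(cut(v, br, include.lowest = TRUE))
  }
  paste(bin_of(gc), bin_of(acc), sep = "_")
}

#' chromVAR-style per-cell motif deviations
#'
#' For each motif, the expected per-cell count is the cell total times the
#' fraction of all-cell counts falling in motif-bearing peaks; the raw
#' deviation is `(observed - expected) / expected`. Background iterations
#' resample peaks matched on GC content and mean accessibility (10 x 10
#' quantile bins, seeded) and the z-score standardises the raw deviation
#' against that matched null.
#'
#' @param peak_counts A [count_matrix()] of peak counts (or dgCMatrix).
#' @param hits Logical motifs x peaks matrix ([scan_motifs()]).
#' @param peak_gc GC fraction per peak (same order as rows of counts).
#' @param n_bg Background iterations (default 50).
#' @param seed Integer seed.
#' @return A `deviation_result`: `raw` and `z` (motifs x cells matrices),
#'   `n_bg`. Motifs hitting no peak are all-`NA` with a warning.
#' @export
motif_deviations <- function(peak_counts, hits, peak_gc, n_bg = 50,
                             seed = 1L) {
  X <- if (inherits(peak_counts, "count_matrix")) peak_counts$values else
    peak_counts
  stopifnot(ncol(hits) == nrow(X))
  H <- Matrix::Matrix(hits * 1, sparse = TRUE)
  tot_c <- Matrix::colSums(X)
  frac_p <- Matrix::rowSums(X) / sum(X)
  dev_of <- function(Hm, Xm, fr) {
    O <- as.matrix(Hm %*% Xm)
    E <- as.matrix(Hm %*% fr) %*% rbind(tot_c)
    d <- (O - E) / E
    d[E == 0] <- NA_real_
    d
  }
  raw <- dev_of(H, X, frac_p)
  empty <- Matrix::rowSums(H) == 0
  if (any(empty)) {
    warning("motif(s) hitting zero peaks; deviations undefined: ",
            paste(rownames(hits)[empty], collapse = ", "))
    raw[empty, ] <- NA_real_
  }
  bins <- match_bins(peak_gc, frac_p)
  bin_members <- split(seq_len(nrow(X)), bins)
  set.seed(seed)
  bg_sum <- matrix(0, nrow(hits), ncol(X))
  bg_sq <- matrix(0, nrow(hits), ncol(X))
  for (b in seq_len(n_bg)) {
    mapping <- integer(nrow(X))
    for (g in bin_members) {
      mapping[g] <- g[sample.int(length(g), length(g), replace = TRUE)]
    }
    d <- dev_of(H, X[mapping, , drop = FALSE], frac_p[mapping])
    bg_sum <- bg_sum + d
    bg_sq <- bg_sq + d^2
  }
  mu <- bg_sum / n_bg
  sdv <- sqrt(pmax(bg_sq / n_bg - mu^2, 0) * n_bg / (n_bg - 1))
  z <- (raw - mu) / sdv
  dimnames(raw) <- dimnames(z) <- list(rownames(hits),
                                       colnames(X) %||% seq_len(ncol(X)))
  structure(list(raw = raw, z = z, n_bg = n_bg),
            class = "deviation_result")
}

#' @export
print.deviation_result <- function(x, ...) {
  cat(sprintf("<deviation_result> %d motifs x %d cells (%d background ",
              nrow(x$z), ncol(x$z), x$n_bg), "iterations)\n", sep = "")
  invisible(x)
}

#' Motif enrichment in a peak set
#'
#' Hypergeometric upper-tail test of motif occurrence in the foreground
#' against a GC-matched background sample of the remaining peaks (all of
#' them when fewer than `n_bg_sample`); BH correction across motifs.
#'
#' @param fg_peaks Foreground peak names.
#' @param all_peaks All peak names (superset of `fg_peaks`).
#' @param hits Logical motifs x peaks matrix with peak column names.
#' @param peak_gc Named (or `all_peaks`-ordered) GC fractions.
#' @param n_bg_sample Background sample size cap (default 40000).
#' @param seed Integer seed for background sampling.
#' @return Tibble (`motif`, `n_fg_with`, `n_fg`, `n_bg_with`, `n_bg`,
#'   `fold_enrichment`, `p_value`, `p_adj`), sorted by p.
#' @export
enrich_motifs <- function(fg_peaks, all_peaks, hits, peak_gc,
                          n_bg_sample = 40000, seed = 1L) {
  if (!length(fg_peaks)) stop("empty foreground", call. = FALSE)
  stopifnot(all(fg_peaks %in% all_peaks))
  if (is.null(names(peak_gc))) names(peak_gc) <- all_peaks
  pool <- setdiff(all_peaks, fg_peaks)
  if (!length(pool)) pool <- all_peaks  # degenerate: foreground is all peaks
  set.seed(seed)
  if (length(pool) > n_bg_sample) {
    # sample background matching the foreground GC profile by decile bin
    fg_bin <- match_bins(peak_gc[fg_peaks], rep(0, length(fg_peaks)))
    pool_bin <- match_bins(peak_gc[pool], rep(0, length(pool)))
    want <- round(table(fg_bin) / length(fg_peaks) * n_bg_sample)
    bg <- unlist(lapply(names(want), function(b) {
      cand <- pool[pool_bin == b]
      if (!length(cand)) return(character(0))
      sample(cand, min(length(cand), want[[b]]))
    }))
    if (!length(bg)) bg <- sample(pool, min(length(pool), n_bg_sample))
  } else {
    bg <- pool
  }
  fg_hits <- hits[, fg_peaks, drop = FALSE]
  bg_hits <- hits[, bg, drop = FALSE]
  n_fg <- length(fg_peaks); n_bg <- length(bg)
  out <- tibble::tibble(
    motif = rownames(hits),
    n_fg_with = as.integer(rowSums(fg_hits)),
    n_fg = n_fg,
    n_bg_with = as.integer(rowSums(bg_hits)),
    n_bg = n_bg
  )
  out$fold_enrichment <- (out$n_fg_with / n_fg) /
    pmax(out$n_bg_with / n_bg, 1e-12)
  K <- out$n_fg_with + out$n_bg_with
  out$p_value <- stats::phyper(out$n_fg_with - 1, K, n_fg + n_bg - K, n_fg,
                               lower.tail = FALSE)
  out$p_adj <- stats::p.adjust(out$p_value, "BH")
  dplyr::arrange(out, .data$p_value, .data$motif)
}

#' Cross-reference motif accessibility with TF expression
#'
#' Joins motif-level statistics (enrichment table or deviation z means)
#' with the detection fraction and mean normalised expression of the
#' corresponding transcription factor gene; a motif is concordant when it
#' is enriched (adjusted p below `p_cutoff`) and its TF is detected in at
#' least `detect_floor` of the cells considered.
#'
#' @param enrichment Tibble from [enrich_motifs()] (needs `motif`, `p_adj`,
#'   `fold_enrichment`).
#' @param norm_rna A `normalized_matrix`.
#' @param motif_to_gene Tibble (`motif`, `gene`); unmapped motifs pass
#'   through flagged with `NA` expression fields.
#' @param cells Optional barcode subset over which detection/expression are
#'   computed (default: all cells).
#' @param detect_floor Minimum detection fraction for concordance.
#' @param p_cutoff Enrichment significance cutoff.
#' @return Tibble (`motif`, `fold_enrichment`, `p_adj`, `tf_gene`,
#'   `pct_detected`, `mean_expression`, `concordant`).
#' @export
crossref_expression <- function(enrichment, norm_rna, motif_to_gene,
                                cells = NULL, detect_floor = 0.1,
                                p_cutoff = 0.05) {
  sel <- if (is.null(cells)) seq_along(norm_rna$barcodes) else
    match(cells, norm_rna$barcodes)
  m <- norm_rna$values[, sel, drop = FALSE]
  out <- dplyr::left_join(enrichment, motif_to_gene, by = "motif") |>
    dplyr::rename(tf_gene = "gene")
  gi <- match(out$tf_gene, norm_rna$feature_ids)
  pct <- mean_expr <- rep(NA_real_, nrow(out))
  ok <- !is.na(gi)
  if (any(ok)) {
    sub <- m[gi[ok], , drop = FALSE]
    pct[ok] <- Matrix::rowSums(sub > 0) / ncol(sub)
    mean_expr[ok] <- Matrix::rowMeans(sub)
  }
  out$pct_detected <- pct
  out$mean_expression <- mean_expr
  out$concordant <- !is.na(out$p_adj) & out$p_adj < p_cutoff &
    !is.na(pct) & pct >= detect_floor
  out
}
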