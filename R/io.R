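# File formats: MatrixMarket counts + sidecars, fragments, BED peaks, gene
# model TSV, JASPAR PFMs, GMT gene sets, FASTA, and the run configuration.
# All genomic coordinates in this package are 0-based half-open.

#' Construct a count matrix
#'
#' A light container for a sparse features x cells count matrix together with
#' its feature identifiers, cell barcodes and modality tag. All pipeline
#' stages that consume counts take this class.
#'
#' @param values A non-negative integer matrix or `Matrix::dgCMatrix`
#'   (features x cells).
#' @param feature_ids Character vector of unique feature identifiers
#'   (one per row).
#' @param barcodes Character vector of unique cell barcodes (one per column).
#' @param modality One of `"RNA"`, `"ATAC_PEAKS"`, `"GENE_ACTIVITY"`.
#' @return An object of class `count_matrix` with elements `values`
#'   (dgCMatrix), `feature_ids`, `barcodes`, `modality`.
#' @export
count_matrix <- function(values, feature_ids, barcodes,
                         modality = c("RNA", "ATAC_PEAKS", "GENE_ACTIVITY")) {
  modality <- match.arg(modality)
  values <- as_dgc(values)
  if (nrow(values) != length(feature_ids)) {
    stop("count_matrix: ", nrow(values), " rows but ", length(feature_ids),
         " feature ids", call. = FALSE)
  }
  if (ncol(values) != length(barcodes)) {
    stop("count_matrix: ", ncol(values), " columns but ", length(barcodes),
         " barcodes", call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids", call. = FALSE)
  if (anyDuplicated(barcodes)) stop("duplicate barcodes", call. = FALSE)
  if (length(values@x) && min(values@x) < 0) {
    stop("negative entries in count matrix", call. = FALSE)
  }
  rownames(values) <- feature_ids
  colnames(values) <- barcodes
  structure(
    list(values = values, feature_ids = feature_ids,
         barcodes = barcodes, modality = modality),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %s: %d features x %d cells, %d non-zero\n",
              x$modality, nrow(x$values), ncol(x$values),
              length(x$values@x)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Read a MatrixMarket count matrix with feature/barcode sidecars
#'
#' @param matrix_path Path to a MatrixMarket coordinate file.
#' @param features_path Path to a text file with one feature id per line.
#' @param barcodes_path Path to a text file with one barcode per line.
#' @inheritParams count_matrix
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(matrix_path, features_path, barcodes_path,
                              modality = "RNA") {
  m <- Matrix::readMM(matrix_path)
  features <- readr::read_lines(features_path, progress = FALSE)
  barcodes <- readr::read_lines(barcodes_path, progress = FALSE)
  if (nrow(m) != length(features)) {
    stop("matrix declares ", nrow(m), " rows but features file has ",
         length(features), " lines", call. = FALSE)
  }
  if (ncol(m) != length(barcodes)) {
    stop("matrix declares ", ncol(m), " columns but barcodes file has ",
         length(barcodes), " lines", call. = FALSE)
  }
  out <- count_matrix(m, features, barcodes, modality)
  fmm_log("read_count_matrix: %d x %d (%s)", nrow(m), ncol(m), modality)
  out
}

#' Write a count matrix as MatrixMarket plus sidecars
#'
#' @param x A [count_matrix()].
#' @param matrix_path,features_path,barcodes_path Output paths.
#' @return `x`, invisibly.
#' @export
write_count_matrix <- function(x, matrix_path, features_path, barcodes_path) {
  stopifnot(inherits(x, "count_matrix"))
  Matrix::writeMM(x$values, matrix_path)
  readr::write_lines(x$feature_ids, features_path)
  readr::write_lines(x$barcodes, barcodes_path)
  invisible(x)
}

#' Read ATAC fragments
#'
#' Five tab-separated columns: chrom, start, end, barcode, count
#' (the count is the number of PCR duplicates observed for the fragment).
#' Coordinates are 0-based half-open. Files may be gzip-compressed.
#'
#' @param path Path to a fragments file.
#' @return A tibble with columns `chrom`, `start`, `end`, `barcode`, `count`,
#'   in file order.
#' @export
read_fragments <- function(path) {
  fr <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "barcode", "count"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), barcode = readr::col_character(),
      count = readr::col_double()
    ),
    progress = FALSE
  )
  if (nrow(fr)) {
    if (any(fr$end <= fr$start)) {
      stop("fragment with end <= start", call. = FALSE)
    }
    if (any(fr$count != round(fr$count)) || any(fr$count < 1) ||
        any(!is.finite(fr$count))) {
      stop("fragment count must be a positive integer", call. = FALSE)
    }
  }
  fmm_log("read_fragments: %d records", nrow(fr))
  fr
}

#' Write ATAC fragments
#' @param fragments Tibble as returned by [read_fragments()].
#' @param path Output path (gzip if it ends in `.gz`).
#' @return `fragments`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  readr::write_tsv(fragments[, c("chrom", "start", "end", "barcode", "count")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(fragments)
}

#' Read a gene model table
#'
#' TSV with columns gene, chrom, start, end, strand; coordinates 0-based
#' half-open. The transcription start site (TSS) is `start` for + strand
#' genes and `end - 1` for - strand genes.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `gene`, `chrom`, `start`, `end`, `strand`,
#'   `tss`.
#' @export
read_gene_model <- function(path) {
  gm <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_double(), end = readr::col_double(),
    strand = readr::col_character()
  ), progress = FALSE)
  validate_gene_model(gm)
}

#' Validate a gene model tibble and add the TSS column
#' @param gm Tibble with gene, chrom, start, end, strand.
#' @return The validated tibble with a `tss` column.
#' @export
validate_gene_model <- function(gm) {
  if (anyDuplicated(gm$gene)) {
    stop("duplicate gene name(s): ",
         paste(unique(gm$gene[duplicated(gm$gene)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(gm$strand %in% c("+", "-"))) {
    stop("unknown strand symbol (must be + or -)", call. = FALSE)
  }
  if (any(gm$start >= gm$end)) stop("gene with start >= end", call. = FALSE)
  gm$tss <- ifelse(gm$strand == "+", gm$start, gm$end - 1)
  gm
}

#' Write a gene model table
#' @param gm Gene model tibble.
#' @param path Output path.
#' @export
write_gene_model <- function(gm, path) {
  readr::write_tsv(gm[, c("gene", "chrom", "start", "end", "strand")], path,
                   progress = FALSE)
  invisible(gm)
}

#' Read peak intervals from BED
#'
#' First three columns chrom/start/end (0-based half-open); an optional
#' fourth column supplies the peak name, otherwise `chrom:start-end` is used.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `chrom`, `start`, `end`, `peak`.
#' @export
read_peaks_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  pk <- tibble::tibble(chrom = as.character(bed[[1]]),
                       start = as.numeric(bed[[2]]),
                       end = as.numeric(bed[[3]]))
  if (any(pk$start >= pk$end)) stop("peak with start >= end", call. = FALSE)
  pk$peak <- if (ncol(bed) >= 4) as.character(bed[[4]]) else peak_name(pk)
  pk
}

#' Write peak intervals as BED
#' @param peaks Tibble with chrom, start, end (and optionally peak).
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  cols <- c("chrom", "start", "end", if ("peak" %in% names(peaks)) "peak")
  readr::write_tsv(peaks[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(peaks)
}

#' Canonical peak name from coordinates
#' @param peaks Tibble with chrom, start, end.
#' @return Character vector `chrom:start-end`.
#' @export
peak_name <- function(peaks) {
  sprintf("%s:%d-%d", peaks$chrom, as.integer(peaks$start),
          as.integer(peaks$end))
}

#' Read position frequency matrices in JASPAR text format
#'
#' Records start with `>ID NAME`, followed by four rows (A, C, G, T) of
#' non-negative counts, with or without the `A [ ... ]` bracket dialect.
#'
#' @param path Path to a `.pfm`/`.jaspar` text file.
#' @return Named list of 4 x width numeric matrices with rownames ACGT;
#'   names are motif ids, with a `motif_name` attribute on each matrix.
#' @export
read_pfm_set <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records found", call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    parts <- strsplit(header, "\\s+")[[1]]
    id <- parts[1]
    nm <- if (length(parts) > 1) parts[2] else parts[1]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4) {
      stop("motif ", id, ": expected 4 base rows, found ", length(body),
           call. = FALSE)
    }
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("\\[|\\]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    widths <- lengths(rows)
    if (length(unique(widths)) != 1) {
      stop("motif ", id, ": row lengths differ", call. = FALSE)
    }
    m <- do.call(rbind, rows)
    if (any(!is.finite(m)) || any(m < 0)) {
      stop("motif ", id, ": non-numeric or negative counts", call. = FALSE)
    }
    rownames(m) <- c("A", "C", "G", "T")
    attr(m, "motif_name") <- nm
    out[[id]] <- m
  }
  out
}

#' Write position frequency matrices in JASPAR text format
#' @param pfms Named list of 4 x width matrices (rows A, C, G, T).
#' @param path Output path.
#' @export
write_pfm_set <- function(pfms, path) {
  lines <- unlist(purrr::imap(pfms, function(m, id) {
    nm <- attr(m, "motif_name") %||% id
    c(paste0(">", id, " ", nm),
      vapply(1:4, function(r) {
        paste0(c("A", "C", "G", "T")[r], " [ ",
               paste(m[r, ], collapse = " "), " ]")
      }, character(1)))
  }))
  readr::write_lines(lines, path)
  invisible(pfms)
}

#' Read gene sets in GMT format
#' @param path Path to a `.gmt` file (set name, description, then genes,
#'   tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::imap_chr(sets, function(g, nm) {
    paste(c(nm, "na", g), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(sets)
}

#' Read sequences from FASTA
#' @param path Path to an uncompressed FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no FASTA records", call. = FALSE)
  ids <- sub("^>\\s*", "", lines[heads])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1)
  ends <- c(heads[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(heads), function(i) {
    if (heads[i] + 1L > ends[i]) return("")
    toupper(paste(lines[(heads[i] + 1L):ends[i]], collapse = ""))
  }, character(1))
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  readr::write_lines(
    as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(seqs)
}

#' Default run configuration
#'
#' All tunables of the pipeline with their defaults: QC thresholds,
#' reduction dimensions, clustering resolution, marker and differential
#' accessibility gates, linkage window and filters, GSEA gates, and the
#' random seed.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    # QC gates (all strict inequalities)
    ns_max = 1.5, tss_min = 1, rna_max = 15000, rna_min = 1000,
    atac_max = 75000, atac_min = 100, mito_max = 5, ribo_max = 10,
    # embedding / clustering
    n_pcs = 25, lsi_dims = 2:25, knn_k = 20, cluster_resolution = 0.1,
    # markers
    marker_min_pct = 0.20, marker_logfc = 0.25, da_min_pct = 0.02,
    nearest_gene_max_dist = 1e5, signature_top_n = 100,
    # peak-gene links
    link_window = 1e6, link_min_cells = 2, link_n_background = 200,
    link_p_cutoff = 0.05, link_score_cutoff = 0.05, link_min_cells_floor = 30,
    # GSEA
    gsea_min_size = 50, gsea_max_size = 500, gsea_p_cutoff = 0.05,
    gsea_n_perm = 1000, deg_min_pct = 0.1, deg_logfc = 0.1,
    # misc
    reporter_gene = "tdRFP", seed = 1L
  ), class = "run_config")
}

#' Read a run configuration from YAML (or JSON)
#'
#' Values present in the file override [default_run_config()]; keys not in
#' the default set are an error (fail-fast against typos).
#'
#' @param path Path to a YAML file; if YAML parsing fails, JSON is tried.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  vals <- tryCatch(yaml::read_yaml(path),
                   error = function(e) jsonlite::read_json(path,
                                                           simplifyVector = TRUE))
  cfg <- default_run_config()
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(vals)) cfg[[k]] <- vals[[k]]
  validate_run_config(cfg)
}

#' Validate a run configuration
#' @param cfg A `run_config` list.
#' @return `cfg`, invisibly on success.
#' @export
validate_run_config <- function(cfg) {
  num <- vapply(cfg, is.numeric, logical(1))
  bad <- names(cfg)[num][vapply(cfg[num], function(v) any(v <= 0),
                                logical(1))]
  bad <- setdiff(bad, "seed")  # seed 0 is allowed
  if (length(bad)) {
    stop("config field(s) must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (1 %in% cfg$lsi_dims) {
    stop("lsi_dims must exclude component 1 (depth component)", call. = FALSE)
  }
  invisible(cfg)
}

#' Stage logging
#'
#' INFO-level logging for pipeline stages; silenced unless
#' `options(fatemultiome.verbose = TRUE)`.
#'
#' @param fmt `sprintf` format string.
#' @param ... Values for the format string.
#' @export
fmm_log <- function(fmt, ...) {
  if (isTRUE(getOption("fatemultiome.verbose", FALSE))) {
    message(sprintf(paste0("[INFO] ", fmt), ...))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce any matrix-like input to a general column-sparse (dgC) matrix;
# base matrices go through Matrix() so the sparse classes are initialised
# before any as() dispatch
as_dgc <- function(values) {
  if (is.matrix(values)) {
    storage.mode(values) <- "double"
    values <- Matrix::Matrix(values, sparse = TRUE)
  }
  if (!methods::is(values, "CsparseMatrix")) {
    values <- methods::as(values, "CsparseMatrix")
  }
  if (!methods::is(values, "generalMatrix")) {
    values <- methods::as(values, "generalMatrix")
  }
  values
}
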