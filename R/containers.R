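#' Sparse observation-by-gene count matrix with identity metadata
#'
#' The central container of the pipeline: a sparse non-negative integer
#' matrix of UMI counts, rows = observations (nuclei or Visium spots),
#' columns = genes. Gene identity is carried by `gene_ids` (the primary
#' key, e.g. Ensembl ids); `gene_names` are display names and may repeat.
#'
#' @param counts matrix or Matrix, observations x genes, non-negative
#'   integral values
#' @param obs_ids unique observation barcodes (character)
#' @param gene_ids unique gene identifiers (character)
#' @param gene_names display names parallel to `gene_ids` (duplicates
#'   allowed); defaults to `gene_ids`
#' @param obs_kind `"nucleus"` or `"spot"`
#' @param sample_id sample label attached to every observation
#' @return an object of class `count_matrix`
#' @export
count_matrix <- function(counts, obs_ids, gene_ids, gene_names = gene_ids,
                         obs_kind = c("nucleus", "spot"),
                         sample_id = "sample1") {
  obs_kind <- match.arg(obs_kind)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(obs_ids))
    stopf("counts has %d rows but %d obs_ids given", nrow(counts), length(obs_ids))
  if (ncol(counts) != length(gene_ids))
    stopf("counts has %d columns but %d gene_ids given", ncol(counts), length(gene_ids))
  if (length(gene_names) != length(gene_ids))
    stopf("gene_names and gene_ids must be parallel")
  if (anyDuplicated(obs_ids))
    stopf("duplicate observation barcodes: %s",
          paste(unique(obs_ids[duplicated(obs_ids)])[1:3], collapse = ", "))
  if (anyDuplicated(gene_ids))
    stopf("duplicate gene_ids: %s",
          paste(unique(gene_ids[duplicated(gene_ids)])[1:3], collapse = ", "))
  v <- counts@x
  if (length(v) && (min(v) < 0 || any(abs(v - round(v)) > 1e-8)))
    stopf("counts must be non-negative integers")
  dimnames(counts) <- list(obs_ids, gene_ids)
  structure(list(counts = counts,
                 obs_ids = as.character(obs_ids),
                 gene_ids = as.character(gene_ids),
                 gene_names = as.character(gene_names),
                 obs_kind = obs_kind,
                 sample_id = sample_id),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d %s x %d genes, sample '%s', %.2f%% nonzero\n",
              nrow(x$counts),
              if (x$obs_kind == "nucleus") "nuclei" else "spots",
              ncol(x$counts), x$sample_id,
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by observations and/or genes
#'
#' @param m a [count_matrix()]
#' @param obs,genes character vectors of barcodes / gene ids to keep
#'   (NULL keeps all); order follows the arguments
#' @return a `count_matrix`
#' @export
subset_counts <- function(m, obs = NULL, genes = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  oi <- if (is.null(obs)) seq_along(m$obs_ids) else match(obs, m$obs_ids)
  gi <- if (is.null(genes)) seq_along(m$gene_ids) else match(genes, m$gene_ids)
  if (anyNA(oi)) stopf("unknown observation barcode(s): %s",
                       paste(utils::head(obs[is.na(oi)], 3), collapse = ", "))
  if (anyNA(gi)) stopf("unknown gene id(s): %s",
                       paste(utils::head(genes[is.na(gi)], 3), collapse = ", "))
  count_matrix(m$counts[oi, gi, drop = FALSE],
               m$obs_ids[oi], m$gene_ids[gi], m$gene_names[gi],
               m$obs_kind, m$sample_id)
}

#' Visium-style spot geometry
#'
#' Per-spot tissue flag and hex-array / pixel coordinates. Array
#' coordinates follow the 10x dialect: `(array_row + array_col)` has
#' constant parity, so each row holds every other column.
#'
#' @param barcode spot barcodes (unique)
#' @param in_tissue 0/1 flag
#' @param array_row,array_col integer hex-array coordinates (0-based)
#' @param pxl_row,pxl_col full-resolution pixel coordinates
#' @param sample_id sample label
#' @return an object of class `spot_geometry` (a data.frame)
#' @export
spot_geometry <- function(barcode, in_tissue, array_row, array_col,
                          pxl_row, pxl_col, sample_id = "sample1") {
  if (anyDuplicated(barcode)) stopf("duplicate spot barcodes in geometry")
  if (!all(in_tissue %in% c(0L, 1L))) stopf("in_tissue must be 0 or 1")
  if (any(abs(array_row - round(array_row)) > 1e-8) ||
      any(abs(array_col - round(array_col)) > 1e-8))
    stopf("array coordinates must be integers")
  par <- (as.integer(array_row) + as.integer(array_col)) %% 2L
  if (length(par) > 1L && length(unique(par)) != 1L)
    stopf("(array_row + array_col) parity is not constant: not a valid hex layout")
  g <- data.frame(barcode = as.character(barcode),
                  in_tissue = as.integer(in_tissue),
                  array_row = as.integer(round(array_row)),
                  array_col = as.integer(round(array_col)),
                  pxl_row = as.numeric(pxl_row),
                  pxl_col = as.numeric(pxl_col),
                  stringsAsFactors = FALSE)
  attr(g, "sample_id") <- sample_id
  class(g) <- c("spot_geometry", "data.frame")
  g
}

#' Per-spot cell-type proportion map
#'
#' Output of [deconvolve_spots()]: each row is a spot's estimated
#' cell-type composition (non-negative, summing to 1), with the relative
#' least-squares residual and a flag for degenerate (all-zero) spots.
#'
#' @param proportions numeric matrix, spots x cell types, rownames =
#'   barcodes
#' @param residual per-spot relative residual norm
#' @param flagged logical, spots whose proportions are a fallback
#' @param sample_id sample label
#' @return an object of class `proportion_map`
#' @export
proportion_map <- function(proportions, residual = rep(NA_real_, nrow(proportions)),
                           flagged = rep(FALSE, nrow(proportions)),
                           sample_id = "sample1") {
  proportions <- as.matrix(proportions)
  if (is.null(rownames(proportions)) || is.null(colnames(proportions)))
    stopf("proportions must carry barcode rownames and cell-type colnames")
  if (any(proportions < -1e-12)) stopf("proportions must be non-negative")
  rs <- rowSums(proportions)
  if (any(abs(rs - 1) > 1e-9)) stopf("proportion rows must sum to 1 within 1e-9")
  structure(list(proportions = proportions, residual = residual,
                 flagged = flagged, sample_id = sample_id),
            class = "proportion_map")
}

#' @export
print.proportion_map <- function(x, ...) {
  cat(sprintf("<proportion_map> %d spots x %d cell types (sample '%s'), %d flagged\n",
              nrow(x$proportions), ncol(x$proportions), x$sample_id,
              sum(x$flagged)))
  invisible(x)
}
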