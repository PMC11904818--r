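#' Quality-control parameters for nucleus/gene filtering
#'
#' Defaults follow the conventional snRNA-seq thresholds used for porcine
#' muscle nuclei: a nucleus is kept when it expresses strictly more than
#' `min_genes_per_nucleus` genes and its mitochondrial fraction is strictly
#' below `max_mito_fraction`; a gene is kept when it is detected in at
#' least `min_cells_per_gene` kept observations. Both bounds are strict by
#' design ("over 500", "< 25%"). The mitochondrial filter applies to
#' nuclei; for spots it is off unless `apply_mito = TRUE`.
#'
#' @param min_genes_per_nucleus detected-gene threshold (exclusive)
#' @param max_mito_fraction mitochondrial-fraction ceiling (exclusive)
#' @param min_cells_per_gene gene detection floor (inclusive)
#' @param mito_prefix gene-name prefix marking mitochondrial genes
#' @param max_counts optional per-observation total-count cap (inclusive
#'   upper bound; `Inf` = off); a crude stand-in for doublet screening
#' @return a list of class `qc_params`
#' @export
qc_params <- function(min_genes_per_nucleus = 500, max_mito_fraction = 0.25,
                      min_cells_per_gene = 1, mito_prefix = "MT-",
                      max_counts = Inf) {
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stopf("max_mito_fraction must be in [0, 1]")
  if (min_genes_per_nucleus < 0 || min_cells_per_gene < 0)
    stopf("count thresholds must be >= 0")
  structure(list(min_genes_per_nucleus = min_genes_per_nucleus,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = min_cells_per_gene,
                 mito_prefix = mito_prefix,
                 max_counts = max_counts),
            class = "qc_params")
}

#' Per-observation mitochondrial count fraction
#'
#' Fraction of an observation's counts coming from genes whose *name*
#' starts with `mito_prefix`; 0 when the observation has no counts at all.
#'
#' @param m a [count_matrix()]
#' @param mito_prefix gene-name prefix (default `"MT-"`)
#' @return named numeric vector, one value per observation
#' @export
mito_fraction <- function(m, mito_prefix = "MT-") {
  stopifnot(inherits(m, "count_matrix"))
  is_mito <- startsWith(m$gene_names, mito_prefix)
  tot <- Matrix::rowSums(m$counts)
  mito <- if (any(is_mito)) Matrix::rowSums(m$counts[, is_mito, drop = FALSE])
  else rep(0, length(tot))
  f <- ifelse(tot == 0, 0, mito / tot)
  stats::setNames(as.numeric(f), m$obs_ids)
}

#' Filter a count matrix by the nucleus and gene quality rules
#'
#' Observation filter first (detected genes strictly above the threshold,
#' mitochondrial fraction strictly below the ceiling, optional total-count
#' cap), then the gene filter recomputed on the *kept* observations only.
#' An empty result is returned with a warning, never an error.
#'
#' @param m a [count_matrix()]
#' @param p a [qc_params()]
#' @param apply_mito whether to apply the mitochondrial filter; defaults to
#'   TRUE for nuclei and FALSE for spots
#' @return list with `filtered` (a `count_matrix`) and `report` (class
#'   `qc_report`: input/kept dimensions and per-filter removal counts)
#' @export
filter_matrix <- function(m, p = qc_params(),
                          apply_mito = m$obs_kind == "nucleus") {
  stopifnot(inherits(m, "count_matrix"), inherits(p, "qc_params"))
  detected <- Matrix::rowSums(m$counts > 0)
  mito <- mito_fraction(m, p$mito_prefix)
  total <- Matrix::rowSums(m$counts)
  fail_genes <- detected <= p$min_genes_per_nucleus
  fail_mito <- if (apply_mito) mito >= p$max_mito_fraction else rep(FALSE, nrow(m$counts))
  fail_cap <- total > p$max_counts
  keep_obs <- !(fail_genes | fail_mito | fail_cap)

  kept <- m$counts[keep_obs, , drop = FALSE]
  cells_per_gene <- Matrix::colSums(kept > 0)
  keep_gene <- cells_per_gene >= p$min_cells_per_gene

  report <- structure(list(
    n_input_obs = nrow(m$counts), n_kept_obs = sum(keep_obs),
    n_input_genes = ncol(m$counts), n_kept_genes = sum(keep_gene),
    removed_low_genes = sum(fail_genes),
    removed_high_mito = sum(fail_mito & !fail_genes),
    removed_count_cap = sum(fail_cap & !fail_genes & !fail_mito),
    removed_undetected_genes = sum(!keep_gene),
    params = unclass(p), apply_mito = apply_mito), class = "qc_report")
  if (report$n_kept_obs == 0 || report$n_kept_genes == 0)
    warning("QC removed everything: empty output matrix", call. = FALSE)
  filtered <- count_matrix(kept[, keep_gene, drop = FALSE],
                           m$obs_ids[keep_obs], m$gene_ids[keep_gene],
                           m$gene_names[keep_gene], m$obs_kind, m$sample_id)
  list(filtered = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("<qc_report> %d/%d observations kept (%d low-gene, %d high-mito,",
                     " %d over count cap removed); %d/%d genes kept\n"),
              x$n_kept_obs, x$n_input_obs, x$removed_low_genes,
              x$removed_high_mito, x$removed_count_cap,
              x$n_kept_genes, x$n_input_genes))
  invisible(x)
}

#' Drop spots outside the tissue mask
#'
#' @param m a spot [count_matrix()]
#' @param geom the matching [spot_geometry()]
#' @return a `count_matrix` restricted to `in_tissue == 1` spots
#' @export
filter_spots_tissue <- function(m, geom) {
  stopifnot(inherits(m, "count_matrix"), inherits(geom, "spot_geometry"))
  keep <- geom$barcode[geom$in_tissue == 1L]
  keep <- keep[keep %in% m$obs_ids]
  subset_counts(m, obs = keep)
}

#' Log2 counts-per-million normalization
#'
#' `log2(count / library_size * 1e6 + pseudocount)`. With the default
#' pseudocount of 1 zeros map to zero and sparsity is preserved.
#'
#' @param m a [count_matrix()]
#' @param pseudocount added inside the log (default 1)
#' @return a sparse (pseudocount = 1) or dense numeric matrix,
#'   observations x genes, with dimnames
#' @export
normalize_log_cpm <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "count_matrix"))
  lib <- Matrix::rowSums(m$counts)
  if (any(lib == 0))
    stopf("zero library size for observation(s): %s",
          paste(utils::head(m$obs_ids[lib == 0], 3), collapse = ", "))
  cpm <- Matrix::Diagonal(x = 1e6 / lib) %*% m$counts
  dimnames(cpm) <- dimnames(m$counts)
  if (pseudocount == 1) {
    cpm <- methods::as(cpm, "CsparseMatrix")
    cpm@x <- log2(cpm@x + 1)
    cpm
  } else {
    log2(as.matrix(cpm) + pseudocount)
  }
}

#' Sum counts into group pseudo-bulk profiles
#'
#' @param m a [count_matrix()]
#' @param grouping named character/factor vector mapping every observation
#'   barcode to a group; `NA` entries are explicitly dropped observations.
#'   Every barcode of `m` must appear in `names(grouping)`; unknown
#'   barcodes in `grouping` are an error. Factor levels with no members
#'   yield an all-zero row, recorded in the `"empty_groups"` attribute.
#' @return dense numeric matrix, group x gene, rows in sorted group order
#' @export
pseudobulk <- function(m, grouping) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(names(grouping))) stopf("grouping must be named by barcode")
  unknown <- setdiff(names(grouping), m$obs_ids)
  if (length(unknown))
    stopf("grouping names unknown observation(s): %s",
          paste(utils::head(unknown, 3), collapse = ", "))
  missing <- setdiff(m$obs_ids, names(grouping))
  if (length(missing))
    stopf("observation(s) missing from grouping: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  g <- grouping[m$obs_ids]
  levels_all <- if (is.factor(grouping)) levels(grouping) else
    sort(unique(as.character(g[!is.na(g)])))
  g <- factor(as.character(g), levels = sort(levels_all))
  keep <- !is.na(g)
  ind <- Matrix::sparseMatrix(i = as.integer(g[keep]), j = which(keep),
                              x = 1, dims = c(nlevels(g), nrow(m$counts)))
  out <- as.matrix(ind %*% m$counts)
  dimnames(out) <- list(levels(g), m$gene_ids)
  empty <- levels(g)[tabulate(g[keep], nlevels(g)) == 0]
  attr(out, "empty_groups") <- empty
  out
}
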