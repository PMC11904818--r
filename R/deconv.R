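#' Parameters for FAPs-high / FAPs-low region delineation
#'
#' Spots whose estimated proportion of the target cell type reaches the
#' empirical `high_quantile` are labelled high; those at or below the
#' `low_quantile` are low; everything else is intermediate. Quantiles are
#' order statistics (inverse empirical CDF) over the in-tissue spots of one
#' sample, so ties at the threshold fall into the extreme class.
#'
#' @param target_celltype cell type whose proportion defines the regions
#' @param high_quantile,low_quantile quantile cutpoints in `[0, 1]`
#' @param region_size spots per resampled region (downstream contract)
#' @param allow_overlap whether sampled regions may share spots
#' @param seed integer RNG seed for region resampling
#' @return a list of class `region_params`
#' @export
region_params <- function(target_celltype = "FAPs", high_quantile = 0.75,
                          low_quantile = 0.25, region_size = 25,
                          allow_overlap = TRUE, seed = 1L) {
  if (!(low_quantile >= 0 && low_quantile < high_quantile && high_quantile <= 1))
    stopf("need 0 <= low_quantile < high_quantile <= 1")
  if (!count1(region_size)) stopf("region_size must be >= 1")
  structure(list(target_celltype = target_celltype,
                 high_quantile = high_quantile, low_quantile = low_quantile,
                 region_size = region_size, allow_overlap = allow_overlap,
                 seed = seed),
            class = "region_params")
}

#' Build cell-type mean-expression signatures from a labelled reference
#'
#' Row t is the mean CPM profile over nuclei labelled t. Genes can be
#' restricted to a marker-informed subset: the union of the top
#' `top_k_markers` markers per cell type ranked by p-value (then absolute
#' fold change) from [find_markers()]. `top_k_markers = Inf` keeps all
#' genes.
#'
#' @param ref a nucleus [count_matrix()] (post-QC)
#' @param labels named vector mapping barcodes to cell types; every label
#'   must have at least one nucleus
#' @param top_k_markers markers per type used to restrict the gene space
#' @param p a [de_params()] for the internal marker scan
#' @return matrix, cell type x gene, CPM scale, with attribute
#'   `"provenance"` (the reference sample id)
#' @export
build_signatures <- function(ref, labels, top_k_markers = 50,
                             p = de_params()) {
  stopifnot(inherits(ref, "count_matrix"))
  labels <- labels[ref$obs_ids]
  if (anyNA(labels)) stopf("labels missing for some nuclei")
  types <- sort(unique(as.character(labels)))
  sizes <- table(factor(labels, levels = types))
  if (any(sizes == 0)) stopf("label with 0 nuclei: %s",
                             paste(names(sizes)[sizes == 0], collapse = ", "))
  lib <- Matrix::rowSums(ref$counts)
  if (any(lib == 0)) stopf("nucleus with zero library size; run QC first")
  cpm <- Matrix::Diagonal(x = 1e6 / lib) %*% ref$counts
  sig <- matrix(0, length(types), ncol(cpm),
                dimnames = list(types, ref$gene_ids))
  for (t in types)
    sig[t, ] <- Matrix::colMeans(cpm[labels == t, , drop = FALSE])
  if (is.finite(top_k_markers)) {
    mk <- find_markers(normalize_log_cpm(ref), labels, p)
    mk <- mk[mk$direction == "up", ]
    keep <- unique(unlist(lapply(split(mk, mk$cluster), function(d) {
      d <- d[order(d$p_value, -abs(d$log2fc)), ]
      utils::head(d$gene_id, top_k_markers)
    })))
    if (!length(keep)) stopf("no marker genes found to build signatures")
    sig <- sig[, keep, drop = FALSE]
  }
  if (any(rowSums(sig) == 0)) stopf("all-zero signature row")
  attr(sig, "provenance") <- ref$sample_id
  sig
}

#' Estimate per-spot cell-type proportions by non-negative least squares
#'
#' Each spot's CPM profile (over the genes shared with the signature
#' matrix) is regressed on the cell-type signatures under a non-negativity
#' constraint; coefficients are normalized to sum to one. Spots with no
#' counts on the shared genes (or an all-zero NNLS solution) fall back to
#' uniform proportions and are flagged.
#'
#' @param spots a spot [count_matrix()]
#' @param sig signature matrix from [build_signatures()]
#' @return a [proportion_map()]
#' @export
deconvolve_spots <- function(spots, sig) {
  stopifnot(inherits(spots, "count_matrix"))
  genes <- intersect(colnames(sig), spots$gene_ids)
  if (!length(genes)) stopf("no genes shared between spots and signatures")
  A <- t(sig[, genes, drop = FALSE])               # genes x celltypes
  lib <- Matrix::rowSums(spots$counts)
  sub <- as.matrix(spots$counts[, genes, drop = FALSE])
  K <- ncol(A)
  props <- matrix(0, nrow(sub), K,
                  dimnames = list(spots$obs_ids, colnames(A)))
  residual <- numeric(nrow(sub))
  flagged <- logical(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    if (lib[i] == 0) { props[i, ] <- 1 / K; flagged[i] <- TRUE; residual[i] <- NA; next }
    b <- sub[i, ] / lib[i] * 1e6
    fit <- pracma::lsqnonneg(A, b)
    x <- fit$x
    if (sum(x) <= 0) { props[i, ] <- 1 / K; flagged[i] <- TRUE
    } else props[i, ] <- x / sum(x)
    nb <- sqrt(sum(b^2))
    residual[i] <- if (nb > 0) sqrt(sum((A %*% x - b)^2)) / nb else NA_real_
  }
  proportion_map(props, residual, flagged, sample_id = spots$sample_id)
}

#' Classify spots into FAPs-high / FAPs-low / intermediate regions
#'
#' Thresholds are the type-1 (order statistic) quantiles of the target
#' cell type's proportion over the sample's in-tissue spots; spots are
#' `high` when at or above the upper threshold, `low` when at or below
#' the lower one. Constant proportions yield all-intermediate with a
#' warning. The labelling is invariant to any monotone rescaling of the
#' proportion column.
#'
#' @param pm a [proportion_map()]
#' @param geom the matching [spot_geometry()] (the quantile is computed
#'   over in-tissue spots only); `NULL` uses every spot of `pm`
#' @param p a [region_params()]
#' @return named character vector (barcode -> "high"/"low"/"intermediate")
#'   over the spots entering the quantile
#' @export
classify_regions <- function(pm, geom = NULL, p = region_params()) {
  stopifnot(inherits(pm, "proportion_map"), inherits(p, "region_params"))
  if (!p$target_celltype %in% colnames(pm$proportions))
    stopf("target cell type '%s' not in proportion map", p$target_celltype)
  bcs <- rownames(pm$proportions)
  if (!is.null(geom)) {
    stopifnot(inherits(geom, "spot_geometry"))
    bcs <- intersect(bcs, geom$barcode[geom$in_tissue == 1L])
  }
  v <- pm$proportions[bcs, p$target_celltype]
  if (length(unique(v)) == 1L) {
    warning("constant proportions: all spots labelled intermediate", call. = FALSE)
    return(stats::setNames(rep("intermediate", length(v)), bcs))
  }
  hi <- stats::quantile(v, p$high_quantile, type = 1, names = FALSE)
  lo <- stats::quantile(v, p$low_quantile, type = 1, names = FALSE)
  lab <- ifelse(v >= hi, "high", ifelse(v <= lo, "low", "intermediate"))
  stats::setNames(lab, bcs)
}

#' Differential expression between FAPs-high and FAPs-low spots
#'
#' Delegates to [de_between_groups()] (spot-level Wilcoxon on log-CPM by
#' default) restricted to the spots labelled high or low. Either class
#' with fewer than 3 spots is refused. The contrast is high over low.
#'
#' @param spots a spot [count_matrix()]
#' @param region_labels output of [classify_regions()]
#' @param p a [de_params()] (test defaults to wilcoxon)
#' @return a DE record data.frame (see [de_between_groups()])
#' @export
region_de <- function(spots, region_labels, p = de_params(test = "wilcoxon")) {
  keep <- names(region_labels)[region_labels %in% c("high", "low")]
  n_hi <- sum(region_labels == "high"); n_lo <- sum(region_labels == "low")
  if (n_hi < 3 || n_lo < 3)
    stopf("refusing region DE: need >= 3 spots per class (high = %d, low = %d)",
          n_hi, n_lo)
  sub <- subset_counts(spots, obs = keep)
  de_between_groups(sub, region_labels[keep], p, contrast = c("high", "low"))
}
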