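#' Specification of a synthetic single-nucleus reference
#'
#' Describes a negative-binomial count simulation of a cell-typed
#' single-nucleus RNA-seq reference: `n_celltypes` populations (named after
#' the major populations of adult skeletal muscle: FAPs, myofibers, muscle
#' stem cells, ...), each with a disjoint block of marker genes whose mean
#' is elevated `2^marker_log2fc`-fold over the baseline. A configurable
#' fraction of nuclei is simulated as low-quality (shrunken library) or
#' mitochondria-dominated so that the quality-control thresholds have real
#' work to do.
#'
#' @param n_celltypes number of cell populations (default 8, the number of
#'   major populations identified in adult porcine muscle)
#' @param n_genes total genes, including mitochondrial ones
#' @param n_nuclei_per_type nuclei per population
#' @param markers_per_type marker genes per population (disjoint blocks)
#' @param marker_log2fc log2 fold elevation of a marker's mean in its own
#'   population over `baseline_mean`
#' @param baseline_mean negative binomial mean of background genes
#' @param dispersion negative binomial size parameter (must be > 0)
#' @param mito_gene_count genes named with the `MT-` prefix
#' @param mito_mean NB mean of mitochondrial genes (all populations)
#' @param lowq_fraction fraction of nuclei with all means shrunk by
#'   `lowq_scale` (emulates empty/low-quality GEMs that fail the detected
#'   gene threshold)
#' @param lowq_scale shrink factor for low-quality nuclei
#' @param highmito_fraction fraction of nuclei whose mitochondrial means are
#'   inflated by `highmito_boost` (emulates stressed/broken nuclei)
#' @param highmito_boost multiplier on mito means for those nuclei
#' @param seed integer RNG seed
#' @return a list of class `reference_spec`
#' @export
reference_spec <- function(n_celltypes = 8, n_genes = 1200,
                           n_nuclei_per_type = 150, markers_per_type = 20,
                           marker_log2fc = 3, baseline_mean = 1.5,
                           dispersion = 2, mito_gene_count = 10,
                           mito_mean = 8, lowq_fraction = 0.05,
                           lowq_scale = 0.2, highmito_fraction = 0.02,
                           highmito_boost = 12, seed = 1L) {
  spec <- as.list(environment())
  for (f in c("n_celltypes", "n_genes", "n_nuclei_per_type", "markers_per_type"))
    if (!count1(spec[[f]])) stopf("%s must be a positive count", f)
  if (!num1(dispersion) || dispersion <= 0) stopf("dispersion must be > 0")
  if (!num1(baseline_mean) || baseline_mean <= 0) stopf("baseline_mean must be > 0")
  if (mito_gene_count < 0) stopf("mito_gene_count must be >= 0")
  if (markers_per_type * n_celltypes + mito_gene_count > n_genes)
    stopf("infeasible spec: %d marker genes + %d mito genes exceed %d total genes",
          markers_per_type * n_celltypes, mito_gene_count, n_genes)
  structure(spec, class = "reference_spec")
}

muscle_celltype_names <- function(n) {
  base <- c("FAPs", "Myofibers", "MuSCs", "Myoblasts", "Pericytes",
            "Endothelial", "Myeloid", "Lymphoid")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("CellType", seq(length(base) + 1L, n)))
}

#' Simulate a cell-typed single-nucleus reference with known ground truth
#'
#' Draws negative-binomial counts for every nucleus according to its
#' population's true signature. Marker gene g of population t has mean
#' `baseline_mean * 2^marker_log2fc` in t and `baseline_mean` elsewhere.
#' Identical spec (including seed) gives bit-identical output.
#'
#' @param spec a [reference_spec()]
#' @return a list with elements `counts` (a [count_matrix()] with
#'   `obs_kind = "nucleus"`), `labels` (named character vector,
#'   barcode -> cell type) and `truth` (list: `true_signatures`
#'   cell type x gene mean matrix, `marker_sets`, `celltypes`,
#'   `lowq_barcodes`, `highmito_barcodes`)
#' @export
simulate_reference <- function(spec) {
  stopifnot(inherits(spec, "reference_spec"))
  local_seed(spec$seed, {
    types <- muscle_celltype_names(spec$n_celltypes)
    n_mk <- spec$markers_per_type * spec$n_celltypes
    n_bg <- spec$n_genes - n_mk - spec$mito_gene_count
    gene_ids <- c(sprintf("GENE%05d", seq_len(spec$n_genes - spec$mito_gene_count)),
                  if (spec$mito_gene_count > 0)
                    sprintf("MT-G%02d", seq_len(spec$mito_gene_count)))
    gene_names <- gene_ids

    # true per-population mean signatures
    sig <- matrix(spec$baseline_mean, spec$n_celltypes, spec$n_genes,
                  dimnames = list(types, gene_ids))
    marker_sets <- vector("list", spec$n_celltypes)
    names(marker_sets) <- types
    for (t in seq_len(spec$n_celltypes)) {
      idx <- ((t - 1L) * spec$markers_per_type + 1L):(t * spec$markers_per_type)
      sig[t, idx] <- spec$baseline_mean * 2^spec$marker_log2fc
      marker_sets[[t]] <- gene_ids[idx]
    }
    if (spec$mito_gene_count > 0) {
      mito_idx <- (spec$n_genes - spec$mito_gene_count + 1L):spec$n_genes
      sig[, mito_idx] <- spec$mito_mean
    } else mito_idx <- integer(0)

    n_total <- spec$n_nuclei_per_type * spec$n_celltypes
    barcodes <- sprintf("NUC%06d", seq_len(n_total))
    labels <- stats::setNames(rep(types, each = spec$n_nuclei_per_type), barcodes)

    n_lowq <- round(spec$lowq_fraction * n_total)
    n_hm <- round(spec$highmito_fraction * n_total)
    special <- sample(n_total, n_lowq + n_hm)
    lowq <- special[seq_len(n_lowq)]
    highmito <- special[setdiff(seq_len(n_lowq + n_hm), seq_len(n_lowq))]
    scale_obs <- rep(1, n_total); scale_obs[lowq] <- spec$lowq_scale
    mito_mult <- rep(1, n_total); mito_mult[highmito] <- spec$highmito_boost

    mu <- sig[labels, , drop = FALSE] * scale_obs
    if (length(mito_idx))
      mu[, mito_idx] <- mu[, mito_idx] * mito_mult
    counts <- matrix(stats::rnbinom(length(mu), size = spec$dispersion,
                                    mu = as.vector(mu)),
                     nrow = n_total, ncol = spec$n_genes)
    cm <- count_matrix(counts, barcodes, gene_ids, gene_names,
                       obs_kind = "nucleus", sample_id = "reference")
    list(counts = cm, labels = labels,
         truth = list(true_signatures = sig, marker_sets = marker_sets,
                      celltypes = types,
                      lowq_barcodes = barcodes[lowq],
                      highmito_barcodes = barcodes[highmito]))
  })
}

#' Specification of a synthetic Visium-like spatial sample
#'
#' A hex grid of spots (10x dialect: array_col parity equals array_row
#' parity) with an elliptical tissue mask; per-spot cell-type proportions
#' come from a Dirichlet-ized exponentiated Gaussian-blurred white-noise
#' field per cell type, so composition is positive, sums to one, and is
#' spatially autocorrelated with length-scale `proportion_smoothness`
#' (array units; 0 gives the degenerate structure-free field: identical
#' expected proportions at every spot). Gene pairs listed in
#' `planted_pairs` share a smooth latent log-scale factor weighted so the
#' region-level Pearson correlation targets `rho`.
#'
#' @param grid_rows,grid_cols hex-grid dimensions (rows x cols spots)
#' @param reads_per_spot expected library size per spot
#' @param proportion_smoothness Gaussian blur sd, in array-row units
#' @param proportion_amplitude log-scale sd of the proportion fields
#' @param fap_celltype cell type whose proportion defines FAPs-high/low
#'   regions downstream
#' @param planted_pairs `NULL` or a data.frame with columns `gene_a`,
#'   `gene_b`, `rho` (each `|rho| <= 1`); genes must exist in the reference
#' @param planted_amplitude log-scale sd of the planted latent factors
#' @param planted_smoothness Gaussian blur sd of the planted latent fields;
#'   kept finer than the composition field by default so the tissue holds
#'   many independent patches of the planted signal (pilot-calibrated so
#'   region-level correlations concentrate on `rho`)
#' @param spot_dispersion NB size parameter for spot counts
#' @param tissue_fraction semi-axis scale of the elliptical tissue mask
#'   (1 = ellipse inscribed in the grid)
#' @param sample_id sample label
#' @param seed integer RNG seed
#' @return a list of class `spatial_spec`
#' @export
spatial_spec <- function(grid_rows = 48, grid_cols = 48, reads_per_spot = 5000,
                         proportion_smoothness = 1.5, proportion_amplitude = 1,
                         fap_celltype = "FAPs", planted_pairs = NULL,
                         planted_amplitude = 1, planted_smoothness = 1,
                         spot_dispersion = 20,
                         tissue_fraction = 0.98, sample_id = "sampleA",
                         seed = 1L) {
  spec <- as.list(environment())
  if (!count1(grid_rows) || !count1(grid_cols)) stopf("grid dims must be counts")
  if (grid_rows * grid_cols < 25)
    stopf("grid_rows * grid_cols must be >= 25")
  if (!num1(reads_per_spot) || reads_per_spot <= 0)
    stopf("reads_per_spot must be > 0")
  if (proportion_smoothness < 0) stopf("proportion_smoothness must be >= 0")
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs)
    if (!all(c("gene_a", "gene_b", "rho") %in% names(planted_pairs)))
      stopf("planted_pairs needs columns gene_a, gene_b, rho")
    if (any(abs(planted_pairs$rho) > 1)) stopf("each |rho| must be <= 1")
    spec$planted_pairs <- planted_pairs
  }
  structure(spec, class = "spatial_spec")
}

# Gaussian blur of a rows x cols field with edge renormalization,
# implemented as banded row/column smoothing matrices.
gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- stats::dnorm(d, sd = sigma)
    k[d > ceiling(4 * sigma)] <- 0
    k / rowSums(k)
  }
  band(nrow(mat)) %*% mat %*% t(band(ncol(mat)))
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) x * 0 else (x - mean(x)) / s
}

# smooth standardized latent field over the full grid, one value per spot
smooth_field <- function(rows, cols, sigma) {
  f <- gauss_blur(matrix(stats::rnorm(rows * cols), rows, cols), sigma)
  matrix(standardize(f), rows, cols)
}

#' Simulate a Visium-like spatial sample from a reference ground truth
#'
#' Spot expected expression is `proportions %*% true_signatures`, rescaled
#' to `reads_per_spot`; planted gene pairs additionally carry shared +
#' private smooth latent factors on the log scale, mixed with weights
#' `sqrt(|rho|)` / `sqrt(1 - |rho|)` so the correlation of the two genes'
#' latent log-means equals `rho` (negative `rho` flips the shared factor's
#' sign). Counts are negative binomial. Identical spec + seed gives
#' bit-identical output.
#'
#' @param spec a [spatial_spec()]
#' @param reference_truth the `truth` element returned by
#'   [simulate_reference()] (needs `true_signatures`)
#' @return list with `counts` (a spot [count_matrix()]), `geometry`
#'   (a [spot_geometry()]), and `truth` (list: `true_proportions` spot x
#'   cell type matrix summing to 1 by row, `true_rho` the planted-pair
#'   table, `true_signatures`)
#' @export
simulate_visium <- function(spec, reference_truth) {
  stopifnot(inherits(spec, "spatial_spec"))
  sig <- reference_truth$true_signatures
  if (is.null(sig)) stopf("reference_truth must contain true_signatures")
  if (!spec$fap_celltype %in% rownames(sig))
    stopf("fap_celltype '%s' not present in reference signatures", spec$fap_celltype)
  pp <- spec$planted_pairs
  if (!is.null(pp)) {
    missing <- setdiff(unique(c(pp$gene_a, pp$gene_b)), colnames(sig))
    if (length(missing))
      stopf("planted gene(s) absent from reference: %s",
            paste(missing, collapse = ", "))
  }
  local_seed(spec$seed, {
    R <- spec$grid_rows; C <- spec$grid_cols
    row_idx <- rep(seq_len(R) - 1L, each = C)
    col_idx <- rep(seq_len(C) - 1L, times = R)
    array_row <- row_idx
    array_col <- 2L * col_idx + row_idx %% 2L
    # 100 um center-to-center spacing on a regular hex lattice
    pxl_row <- 1000 + array_row * 86.60254
    pxl_col <- 1000 + array_col * 50
    rr <- (array_row - mean(array_row)) / (max(array_row) - min(array_row) + 1e-9) * 2
    cc <- (array_col - mean(array_col)) / (max(array_col) - min(array_col) + 1e-9) * 2
    in_tissue <- as.integer((rr / spec$tissue_fraction)^2 +
                              (cc / spec$tissue_fraction)^2 <= 1)
    if (sum(in_tissue) < 25) in_tissue <- rep(1L, length(in_tissue))
    barcodes <- sprintf("%s_SPOT%05d", spec$sample_id, seq_len(R * C))
    geom <- spot_geometry(barcodes, in_tissue, array_row, array_col,
                          pxl_row, pxl_col, sample_id = spec$sample_id)

    # spatially autocorrelated positive fields, one per cell type
    K <- nrow(sig)
    fields <- vapply(seq_len(K), function(k) {
      if (spec$proportion_smoothness <= 0) rep(0, R * C)
      else {
        f <- smooth_field(R, C, spec$proportion_smoothness)
        spec$proportion_amplitude * as.vector(t(f))  # t(): spot order is row-major
      }
    }, numeric(R * C))
    props <- exp(fields)
    props <- props / rowSums(props)
    dimnames(props) <- list(barcodes, rownames(sig))

    mu <- props %*% sig  # spots x genes expected profile shape
    colnames(mu) <- colnames(sig)

    if (!is.null(pp) && nrow(pp) > 0) {
      sg <- max(spec$planted_smoothness, 0.25)
      offset <- matrix(0, R * C, ncol(mu), dimnames = list(NULL, colnames(mu)))
      for (i in seq_len(nrow(pp))) {
        w <- abs(pp$rho[i]); s <- sign(pp$rho[i])
        shared <- as.vector(t(smooth_field(R, C, sg)))
        ga <- as.vector(t(smooth_field(R, C, sg)))
        gb <- as.vector(t(smooth_field(R, C, sg)))
        offset[, pp$gene_a[i]] <- offset[, pp$gene_a[i]] +
          spec$planted_amplitude * (sqrt(w) * shared + sqrt(1 - w) * ga)
        offset[, pp$gene_b[i]] <- offset[, pp$gene_b[i]] +
          spec$planted_amplitude * ((if (s < 0) -1 else 1) * sqrt(w) * shared +
                                      sqrt(1 - w) * gb)
      }
      touched <- colSums(offset != 0) > 0
      mu[, touched] <- mu[, touched] * exp(offset[, touched, drop = FALSE])
    }
    mu <- mu * (spec$reads_per_spot / rowSums(mu))
    counts <- matrix(stats::rnbinom(length(mu), size = spec$spot_dispersion,
                                    mu = as.vector(mu)),
                     nrow = nrow(mu), ncol = ncol(mu))
    cm <- count_matrix(counts, barcodes, colnames(sig),
                       reference_truth$gene_names %||% colnames(sig),
                       obs_kind = "spot", sample_id = spec$sample_id)
    list(counts = cm, geometry = geom,
         truth = list(true_proportions = props,
                      true_rho = pp,
                      true_signatures = sig))
  })
}

#' Simulate a UniProt-style subcellular-location annotation table
#'
#' Assigns each gene one location string (multiple compartments joined by
#' `" | "`). A target fraction of genes is labelled secreted; genes listed
#' in `planted_secreted` are always secreted.
#'
#' @param genes character vector of gene ids
#' @param secreted_fraction target fraction of secreted genes in `[0, 1]`
#' @param planted_secreted genes forced to carry a Secreted annotation
#' @param seed integer RNG seed
#' @return data.frame with columns `gene_id`, `location`
#' @export
simulate_location_table <- function(genes, secreted_fraction = 0.1,
                                    planted_secreted = character(0), seed = 1L) {
  if (secreted_fraction < 0 || secreted_fraction > 1)
    stopf("secreted_fraction must be in [0, 1]")
  planted_secreted <- intersect(planted_secreted, genes)
  local_seed(seed, {
    k <- round(secreted_fraction * length(genes))
    extra <- max(0L, k - length(planted_secreted))
    pool <- setdiff(genes, planted_secreted)
    secreted <- c(planted_secreted, sample(pool, min(extra, length(pool))))
    sec_strings <- c("Secreted", "Secreted, extracellular space",
                     "Secreted | Cytoplasm")
    other_strings <- c("Cytoplasm", "Nucleus", "Cell membrane",
                       "Mitochondrion", "Endoplasmic reticulum",
                       "Cytoplasm | Nucleus", "Golgi apparatus")
    loc <- ifelse(genes %in% secreted,
                  sample(sec_strings, length(genes), replace = TRUE),
                  sample(other_strings, length(genes), replace = TRUE))
    data.frame(gene_id = genes, location = loc, stringsAsFactors = FALSE)
  })
}

#' Simulate gene-set collections for enrichment testing
#'
#' Random member sets over the supplied universe, plus optional fixed sets.
#'
#' @param genes universe of gene ids
#' @param n_sets number of random sets
#' @param set_size members per set
#' @param fixed_sets optional named list of character vectors appended as-is
#' @param seed integer RNG seed
#' @return named list of character vectors (a GMT-shaped collection)
#' @export
simulate_genesets <- function(genes, n_sets = 20, set_size = 25,
                              fixed_sets = NULL, seed = 1L) {
  local_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i)
      sample(genes, min(set_size, length(genes))))
    names(sets) <- sprintf("SET%03d", seq_len(n_sets))
    c(sets, fixed_sets)
  })
}
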