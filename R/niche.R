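#' Parameters for random-region correlation analysis
#'
#' Controls the resampling of equal-area spot regions (default 200 regions
#' of 25 spots per sample) and the two significance tiers used to call a
#' secretory-gene/target-gene pair correlated: the standard tier
#' (`|r| > 0.4` and `p < 0.05`) and the strict tier used for myofiber-type
#' markers (`|r| > 0.5` and `p < 0.001`). Pass flags use the raw p; the BH
#' q-value is reported alongside.
#'
#' @param n_regions_per_sample regions drawn per spatial sample
#' @param region_size spots per region
#' @param r_threshold,p_threshold standard-tier cutoffs
#' @param strict_r_threshold,strict_p_threshold strict-tier cutoffs
#' @param mtc `"bh"` or `"none"` for the reported q-value
#' @param seed integer RNG seed
#' @return a list of class `correlation_params`
#' @export
correlation_params <- function(n_regions_per_sample = 200, region_size = 25,
                               r_threshold = 0.4, p_threshold = 0.05,
                               strict_r_threshold = 0.5,
                               strict_p_threshold = 0.001,
                               mtc = c("bh", "none"), seed = 1L) {
  mtc <- match.arg(mtc)
  if (n_regions_per_sample < 0) stopf("n_regions_per_sample must be >= 0")
  if (!count1(region_size)) stopf("region_size must be >= 1")
  for (th in c(p_threshold, strict_p_threshold))
    if (th <= 0 || th >= 1) stopf("p thresholds must be in (0, 1)")
  structure(list(n_regions_per_sample = n_regions_per_sample,
                 region_size = region_size, r_threshold = r_threshold,
                 p_threshold = p_threshold,
                 strict_r_threshold = strict_r_threshold,
                 strict_p_threshold = strict_p_threshold,
                 mtc = mtc, seed = seed),
            class = "correlation_params")
}

#' Extract one equal-area region around a seed spot
#'
#' The region is the seed plus its `region_size - 1` nearest in-tissue
#' spots by Euclidean pixel distance; exact distance ties are broken by
#' lexicographic barcode order, so membership is fully deterministic.
#'
#' @param geom a [spot_geometry()]
#' @param seed_spot barcode of the seed (must be in tissue)
#' @param region_size total spots in the region
#' @return character vector of member barcodes (seed included)
#' @export
extract_region <- function(geom, seed_spot, region_size = 25) {
  stopifnot(inherits(geom, "spot_geometry"))
  tis <- geom[geom$in_tissue == 1L, , drop = FALSE]
  if (nrow(tis) < region_size)
    stopf("only %d in-tissue spots, need %d", nrow(tis), region_size)
  i <- match(seed_spot, tis$barcode)
  if (is.na(i)) stopf("seed spot '%s' is not an in-tissue spot", seed_spot)
  d <- sqrt((tis$pxl_row - tis$pxl_row[i])^2 + (tis$pxl_col - tis$pxl_col[i])^2)
  ord <- order(d, tis$barcode, method = "radix")
  tis$barcode[ord[seq_len(region_size)]]
}

#' Randomly sample equal-area regions and build pseudo-bulk profiles
#'
#' Seed spots are drawn uniformly among the sample's in-tissue spots,
#' without replacement when possible (with replacement, flagged, if more
#' regions than spots are requested); regions may overlap. Each region's
#' profile is the log2-CPM of its summed member counts. Fixed seed gives
#' bit-identical output.
#'
#' @param geom a [spot_geometry()]
#' @param counts the matching spot [count_matrix()]
#' @param p a [correlation_params()]
#' @return object of class `region_set`: list with `regions` (data.frame:
#'   `region_id`, `sample_id`, `seed_spot`, `members` pipe-joined),
#'   `members` (list of barcode vectors), `profiles` (region x gene
#'   log2-CPM matrix), `centroids` (region x 2 pixel coords),
#'   `replacement` flag
#' @export
sample_regions <- function(geom, counts, p = correlation_params()) {
  stopifnot(inherits(geom, "spot_geometry"), inherits(counts, "count_matrix"))
  tis_bc <- geom$barcode[geom$in_tissue == 1L]
  tis_bc <- tis_bc[tis_bc %in% counts$obs_ids]
  if (length(tis_bc) < p$region_size)
    stopf("sample '%s': %d usable in-tissue spots < region_size %d",
          counts$sample_id, length(tis_bc), p$region_size)
  n <- p$n_regions_per_sample
  replacement <- n > length(tis_bc)
  seeds <- local_seed(p$seed,
                      if (n == 0) character(0)
                      else sample(tis_bc, n, replace = replacement))
  members <- lapply(seeds, function(s) extract_region(geom, s, p$region_size))
  ids <- sprintf("%s_R%04d", counts$sample_id, seq_len(n))
  profiles <- matrix(0, n, ncol(counts$counts),
                     dimnames = list(ids, counts$gene_ids))
  centroids <- matrix(NA_real_, n, 2, dimnames = list(ids, c("pxl_row", "pxl_col")))
  for (j in seq_len(n)) {
    mm <- members[[j]]
    s <- Matrix::colSums(counts$counts[mm, , drop = FALSE])
    tot <- sum(s)
    if (tot == 0) stopf("region %s has zero total counts", ids[j])
    profiles[j, ] <- log2(s / tot * 1e6 + 1)
    rows <- match(mm, geom$barcode)
    centroids[j, ] <- c(mean(geom$pxl_row[rows]), mean(geom$pxl_col[rows]))
  }
  structure(list(regions = data.frame(
    region_id = ids, sample_id = rep(counts$sample_id, n),
    seed_spot = as.character(seeds),
    members = vapply(members, paste, "", collapse = "|"),
    stringsAsFactors = FALSE),
    members = members, profiles = profiles, centroids = centroids,
    replacement = replacement),
    class = "region_set")
}

#' Pool region sets from several samples
#'
#' @param ... `region_set` objects over the same gene space
#' @return a pooled `region_set` (profiles row-bound; per-region sample ids
#'   kept)
#' @export
pool_region_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "region_set"))
    sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, TRUE, "region_set")))
  genes <- Reduce(intersect, lapply(sets, function(s) colnames(s$profiles)))
  structure(list(
    regions = do.call(rbind, lapply(sets, `[[`, "regions")),
    members = do.call(c, lapply(sets, `[[`, "members")),
    profiles = do.call(rbind, lapply(sets, function(s)
      s$profiles[, genes, drop = FALSE])),
    centroids = do.call(rbind, lapply(sets, `[[`, "centroids")),
    replacement = any(vapply(sets, `[[`, TRUE, "replacement"))),
    class = "region_set")
}

#' Correlate two gene sets across region pseudo-bulk profiles
#'
#' For every (a, b) pair, the Pearson correlation of log2-CPM region
#' profiles, with the two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` at `n - 2` degrees of freedom
#' (n = number of regions). Zero-variance genes yield records flagged
#' undefined, never a fabricated r. When `sample_groups` maps sample ids
#' to conditions, a stratified r per condition is reported next to the
#' pooled r; tier flags always use the pooled statistics.
#'
#' @param regions a `region_set` from [sample_regions()] /
#'   [pool_region_sets()]
#' @param set_a,set_b character vectors of gene ids (secretory candidates
#'   and targets); intersected with the measured genes
#' @param p a [correlation_params()]
#' @param sample_groups optional named vector sample_id -> condition
#' @return data.frame of class `corr_records`: `gene_a`, `gene_b`, `r`,
#'   `p_value`, `q_value`, `n_regions`, `undefined`, `pass_standard`,
#'   `pass_strict`, plus one `r_<condition>` column per condition
#' @export
correlate_gene_sets <- function(regions, set_a, set_b,
                                p = correlation_params(),
                                sample_groups = NULL) {
  stopifnot(inherits(regions, "region_set"))
  prof <- regions$profiles
  set_a <- intersect(unique(as.character(unlist(set_a))), colnames(prof))
  set_b <- intersect(unique(as.character(unlist(set_b))), colnames(prof))
  if (!length(set_a) || !length(set_b))
    stopf("a gene set is empty after intersecting with measured genes")
  n <- nrow(prof)
  if (n < 3) stopf("need at least 3 regions, have %d", n)
  sds <- apply(prof[, unique(c(set_a, set_b)), drop = FALSE], 2, stats::sd)
  pairs <- expand.grid(gene_a = set_a, gene_b = set_b,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # zero-variance genes are flagged below; silence cor's sd-zero warning
  cors <- suppressWarnings(stats::cor(prof[, set_a, drop = FALSE],
                                      prof[, set_b, drop = FALSE]))
  r <- cors[cbind(match(pairs$gene_a, set_a), match(pairs$gene_b, set_b))]
  undef <- sds[pairs$gene_a] == 0 | sds[pairs$gene_b] == 0
  r[undef] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  pv <- ifelse(is.na(r), NA_real_,
               ifelse(abs(r) >= 1, 0, 2 * stats::pt(-abs(tstat), df = n - 2)))
  qv <- rep(NA_real_, length(pv))
  ok <- !is.na(pv)
  qv[ok] <- if (p$mtc == "bh") stats::p.adjust(pv[ok], "BH") else pv[ok]
  out <- data.frame(pairs, r = r, p_value = pv, q_value = qv,
                    n_regions = n, undefined = undef,
                    pass_standard = !undef & !is.na(pv) &
                      abs(r) > p$r_threshold & pv < p$p_threshold,
                    pass_strict = !undef & !is.na(pv) &
                      abs(r) > p$strict_r_threshold & pv < p$strict_p_threshold,
                    stringsAsFactors = FALSE)
  if (!is.null(sample_groups)) {
    cond <- unname(sample_groups[regions$regions$sample_id])
    for (cd in sort(unique(cond[!is.na(cond)]))) {
      rows <- which(cond == cd)
      rc <- if (length(rows) >= 3)
        suppressWarnings(stats::cor(prof[rows, set_a, drop = FALSE],
                                    prof[rows, set_b, drop = FALSE]))
      else matrix(NA_real_, length(set_a), length(set_b))
      out[[paste0("r_", cd)]] <-
        rc[cbind(match(pairs$gene_a, set_a), match(pairs$gene_b, set_b))]
    }
  }
  class(out) <- c("corr_records", "data.frame")
  out
}

#' Per-spot paired expression table for spatial co-aggregation inspection
#'
#' Joins the log2-CPM normalized expression of the requested genes to the
#' spot coordinates, for plotting the spatial aggregation of a correlated
#' secretory/target gene pair. No statistic beyond the already-computed
#' correlation is claimed.
#'
#' @param counts a spot [count_matrix()]
#' @param geom the matching [spot_geometry()]
#' @param genes gene ids to extract (typically a correlated pair)
#' @return data.frame: `barcode`, `in_tissue`, `array_row`, `array_col`,
#'   `pxl_row`, `pxl_col`, one expression column per gene
#' @export
spatial_aggregation_map <- function(counts, geom, genes) {
  stopifnot(inherits(counts, "count_matrix"), inherits(geom, "spot_geometry"))
  missing <- setdiff(genes, counts$gene_ids)
  if (length(missing))
    stopf("unknown gene(s): %s", paste(missing, collapse = ", "))
  expr <- normalize_log_cpm(counts)
  common <- intersect(geom$barcode, counts$obs_ids)
  g <- as.data.frame(geom)[match(common, geom$barcode), ]
  for (gn in genes) g[[gn]] <- as.numeric(expr[common, gn])
  rownames(g) <- NULL
  g
}
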