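# Shared fixtures and independent oracles. Oracles deliberately use
# different algorithms from the package implementations they check.

# random count matrix with a few MT- genes
rand_cm <- function(n_obs = 60, n_genes = 40, mu = 2, size = 2,
                    n_mito = 4, seed = 1, obs_kind = "nucleus") {
  set.seed(seed)
  n_mito <- min(n_mito, n_genes - 1L)
  cnt <- matrix(rnbinom(n_obs * n_genes, mu = mu, size = size), n_obs)
  ids <- c(sprintf("g%03d", seq_len(n_genes - n_mito)),
           sprintf("MT-x%02d", seq_len(n_mito)))
  count_matrix(cnt, sprintf("bc%04d", seq_len(n_obs)), ids,
               obs_kind = obs_kind)
}

# naive double-loop QC scan: observation rules first, then gene rule on
# the kept observations
qc_oracle <- function(m, p, apply_mito = TRUE) {
  cnt <- as.matrix(m$counts)
  is_mito <- startsWith(m$gene_names, p$mito_prefix)
  keep_obs <- logical(nrow(cnt))
  for (i in seq_len(nrow(cnt))) {
    det <- sum(cnt[i, ] > 0)
    tot <- sum(cnt[i, ])
    mf <- if (tot == 0) 0 else sum(cnt[i, is_mito]) / tot
    keep_obs[i] <- det > p$min_genes_per_nucleus &&
      (!apply_mito || mf < p$max_mito_fraction) && tot <= p$max_counts
  }
  kept <- cnt[keep_obs, , drop = FALSE]
  keep_gene <- logical(ncol(cnt))
  for (j in seq_len(ncol(cnt)))
    keep_gene[j] <- sum(kept[, j] > 0) >= p$min_cells_per_gene
  list(obs = m$obs_ids[keep_obs], genes = m$gene_ids[keep_gene])
}

# exact two-sided rank-sum p by dynamic programming over the multiset of
# doubled ranks (counts of k-subsets per achievable rank sum)
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r2 <- as.integer(round(2 * rank(c(x, y))))
  w <- sum(r2[seq_len(n1)]); mu2 <- n1 * (N + 1L)
  maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  dp <- matrix(0, n1 + 1L, maxs + 1L)
  dp[1L, 1L] <- 1
  for (v in r2) for (k in min(n1, 1e9):1) {
    cols <- which(dp[k, ] > 0)
    if (length(cols)) dp[k + 1L, cols + v] <- dp[k + 1L, cols + v] + dp[k, cols]
  }
  cnt <- dp[n1 + 1L, ]
  sums <- which(cnt > 0) - 1L
  sum(cnt[sums + 1L][abs(sums - mu2) >= abs(w - mu2)]) / choose(N, n1)
}

# small hand-built hex geometry: r rows x c cols, all in tissue
toy_geometry <- function(nr = 8, nc = 8, sample_id = "toy") {
  row <- rep(seq_len(nr) - 1L, each = nc)
  col0 <- rep(seq_len(nc) - 1L, times = nr)
  col <- 2L * col0 + row %% 2L
  spot_geometry(sprintf("%s_s%03d", sample_id, seq_along(row)),
                rep(1L, length(row)), row, col,
                1000 + row * 86.60254, 1000 + col * 50,
                sample_id = sample_id)
}

# brute-force region membership: full sort by (distance, barcode)
region_oracle <- function(geom, seed_spot, k) {
  tis <- geom[geom$in_tissue == 1L, ]
  i <- match(seed_spot, tis$barcode)
  d <- sqrt((tis$pxl_row - tis$pxl_row[i])^2 + (tis$pxl_col - tis$pxl_col[i])^2)
  df <- data.frame(bc = tis$barcode, d = d)
  df <- df[order(df$d, df$bc), ]
  df$bc[seq_len(k)]
}

# small reference truth reused by spatial tests (cheap to build)
small_ref <- function(seed = 3)
  simulate_reference(reference_spec(n_celltypes = 4, n_genes = 300,
                                    n_nuclei_per_type = 40,
                                    markers_per_type = 10, seed = seed))
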