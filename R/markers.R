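#' Parameters for marker detection and differential expression
#'
#' Defaults follow the conventional single-cell screen for this tissue:
#' a marker must be expressed in strictly more than 10% of its cluster's
#' cells with `|log2FC| > 0.26`; a DEG must additionally reach `p < 0.05`.
#' All threshold comparisons are strict inequalities.
#'
#' @param min_expr_fraction minimum within-cluster expression fraction
#' @param min_abs_log2fc minimum absolute log2 fold change
#' @param alpha raw p-value threshold
#' @param fc_pseudocount pseudocount added to de-logged means in the fold
#'   change (Seurat-style)
#' @param test `"wilcoxon"` (rank-sum; exact enumeration when both groups
#'   have at most 8 members, otherwise normal approximation with tie
#'   correction) or `"nb_wald"` (negative binomial Wald with
#'   method-of-moments dispersion, for raw counts)
#' @param mtc multiple-testing correction for the reported q-value
#'   (`"bh"` or `"none"`); pass/fail flags use the raw p by design
#' @return a list of class `de_params`
#' @export
de_params <- function(min_expr_fraction = 0.10, min_abs_log2fc = 0.26,
                      alpha = 0.05, fc_pseudocount = 1,
                      test = c("wilcoxon", "nb_wald"),
                      mtc = c("bh", "none")) {
  test <- match.arg(test); mtc <- match.arg(mtc)
  if (min_expr_fraction < 0 || min_expr_fraction > 1)
    stopf("min_expr_fraction must be in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  structure(list(min_expr_fraction = min_expr_fraction,
                 min_abs_log2fc = min_abs_log2fc, alpha = alpha,
                 fc_pseudocount = fc_pseudocount, test = test, mtc = mtc),
            class = "de_params")
}

#' Exact two-sided rank-sum p-value by full enumeration
#'
#' Enumerates all `choose(n1 + n2, n1)` assignments of the pooled
#' (tie-corrected) ranks to group 1 and returns the fraction whose rank sum
#' is at least as far from its null mean as the observed one. Doubled ranks
#' are integers even under ties, so the comparison is exact.
#'
#' @param x,y numeric vectors (the two groups)
#' @return exact two-sided p-value
#' @export
wilcox_exact_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  if (n1 < 1 || length(y) < 1) stopf("both groups must be non-empty")
  r2 <- as.integer(round(2 * rank(c(x, y))))
  w_obs <- sum(r2[seq_len(n1)])
  mu2 <- n1 * (N + 1L)
  combos <- utils::combn(N, n1)
  W <- colSums(matrix(r2[combos], nrow = n1))
  mean(abs(W - mu2) >= abs(w_obs - mu2))
}

# normal-approximation rank-sum p with tie correction, vectorized over the
# columns of a dense obs x genes matrix; exact enumeration when both groups
# are small. idx1: logical rows of group 1. cols: column subset to test.
wilcox_p_matrix <- function(expr, idx1, cols = seq_len(ncol(expr)),
                            exact_max = 8L) {
  n1 <- sum(idx1); n2 <- sum(!idx1); N <- n1 + n2
  if (n1 <= exact_max && n2 <= exact_max) {
    return(vapply(cols, function(j)
      wilcox_exact_p(expr[idx1, j], expr[!idx1, j]), numeric(1)))
  }
  mu <- n1 * (N + 1) / 2
  vapply(cols, function(j) {
    v <- expr[, j]
    r <- rank(v)
    R1 <- sum(r[idx1])
    tl <- rle(sort(v))$lengths
    tiesum <- sum(tl^3 - tl)
    s2 <- n1 * n2 / 12 * ((N + 1) - tiesum / (N * (N - 1)))
    if (s2 <= 0) return(1)
    min(1, 2 * stats::pnorm(-abs((R1 - mu) / sqrt(s2))))
  }, numeric(1))
}

# log2 fold change on de-logged means with pseudocount (expr is log2 scale)
log2fc_from_log <- function(expr, idx1, pc) {
  lin <- 2^expr - 1
  m1 <- colMeans(lin[idx1, , drop = FALSE])
  m2 <- colMeans(lin[!idx1, , drop = FALSE])
  list(lfc = log2((m1 + pc) / (m2 + pc)), m1 = m1, m2 = m2)
}

#' One-vs-rest marker detection per cluster
#'
#' For each cluster, genes expressed (value > 0) in strictly more than
#' `min_expr_fraction` of the cluster's observations and with
#' `|log2FC| > min_abs_log2fc` (de-logged normalized means, pseudocount 1)
#' are tested with the two-sided Wilcoxon rank-sum test against all other
#' observations. Clusters with fewer than 2 observations are skipped with
#' a warning.
#'
#' @param expr normalized log2 expression matrix (observations x genes,
#'   e.g. from [normalize_log_cpm()]); sparse accepted
#' @param labels named vector mapping every row of `expr` to a cluster
#' @param p a [de_params()]
#' @return data.frame with one row per (cluster, candidate gene):
#'   `cluster`, `gene_id`, `log2fc`, `pct_in`, `pct_out`, `p_value`,
#'   `q_value` (BH within cluster), `direction`, `passes_filter`
#'   (fold-change and expression thresholds plus `p < alpha`)
#' @export
find_markers <- function(expr, labels, p = de_params()) {
  stopifnot(inherits(p, "de_params"))
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stopf("expr must carry barcode rownames and gene colnames")
  labels <- labels[rownames(expr)]
  if (anyNA(labels)) stopf("labels missing for some observations")
  clusters <- sort(unique(as.character(labels)))
  if (length(clusters) < 2) stopf("need at least 2 clusters")
  out <- list()
  for (cl in clusters) {
    idx1 <- labels == cl
    if (sum(idx1) < 2) {
      warning(sprintf("cluster '%s' has fewer than 2 observations: skipped", cl),
              call. = FALSE)
      next
    }
    pct_in <- colMeans(expr[idx1, , drop = FALSE] > 0)
    pct_out <- colMeans(expr[!idx1, , drop = FALSE] > 0)
    fc <- log2fc_from_log(expr, idx1, p$fc_pseudocount)
    cand <- which(pct_in > p$min_expr_fraction &
                    abs(fc$lfc) > p$min_abs_log2fc)
    if (!length(cand)) next
    pv <- wilcox_p_matrix(expr, idx1, cols = cand)
    qv <- if (p$mtc == "bh") stats::p.adjust(pv, "BH") else pv
    out[[cl]] <- data.frame(
      cluster = cl, gene_id = colnames(expr)[cand],
      log2fc = unname(fc$lfc[cand]),
      pct_in = unname(pct_in[cand]), pct_out = unname(pct_out[cand]),
      p_value = pv, q_value = qv,
      direction = ifelse(fc$lfc[cand] > 0, "up", "down"),
      passes_filter = pv < p$alpha, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(cluster = character(), gene_id = character(),
                      log2fc = numeric(), pct_in = numeric(),
                      pct_out = numeric(), p_value = numeric(),
                      q_value = numeric(), direction = character(),
                      passes_filter = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

col_vars <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(NA_real_, ncol(m)))
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

# NB Wald with method-of-moments dispersion, vectorized over genes.
# counts: dense obs x genes; idx1 logical group-1 rows.
nb_wald_matrix <- function(counts, idx1, pc) {
  lib <- rowSums(counts)
  sf <- lib / mean(lib)
  sf[sf == 0] <- 1
  y <- counts / sf
  n1 <- sum(idx1); n2 <- sum(!idx1)
  m1 <- colMeans(y[idx1, , drop = FALSE])
  m2 <- colMeans(y[!idx1, , drop = FALSE])
  v1 <- col_vars(y[idx1, , drop = FALSE])
  v2 <- col_vars(y[!idx1, , drop = FALSE])
  a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, 0)
  a2 <- ifelse(m2 > 0, (v2 - m2) / m2^2, 0)
  alpha <- pmax(0, ((n1 - 1) * a1 + (n2 - 1) * a2) / (n1 + n2 - 2))
  lfc <- log2((m1 + pc) / (m2 + pc))
  vm1 <- (m1 + alpha * m1^2) / n1
  vm2 <- (m2 + alpha * m2^2) / n2
  se2 <- (vm1 / (m1 + pc)^2 + vm2 / (m2 + pc)^2) / log(2)^2
  z <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
  pv <- ifelse(se2 > 0, 2 * stats::pt(-abs(z), df = n1 + n2 - 2), 1)
  untestable <- m1 == 0 & m2 == 0
  pv[untestable] <- 1
  lfc[untestable] <- 0
  list(lfc = lfc, m1 = m1, m2 = m2, p = pv, untestable = untestable)
}

#' Two-group differential expression
#'
#' With `test = "nb_wald"` (the default in [de_params()] only when counts
#' are supplied), each gene gets a negative binomial Wald test: library
#' size-normalized counts, pooled method-of-moments dispersion, delta-method
#' standard error on the log2 fold change, and a t reference distribution
#' with `n1 + n2 - 2` degrees of freedom. With `test = "wilcoxon"`, counts
#' are log-CPM normalized (plain matrices are assumed already normalized)
#' and genes get the rank-sum test. Pass flags use the raw p
#' (`p < alpha`) and `|log2FC| > min_abs_log2fc`; BH q is reported
#' alongside.
#'
#' @param x a [count_matrix()] or a normalized (log2 scale) matrix with
#'   dimnames
#' @param group_labels named vector mapping each observation to one of
#'   exactly two groups
#' @param p a [de_params()]
#' @param contrast length-2 character: (group1, group2); log2fc is group1
#'   over group2. Defaults to the sorted group names.
#' @return data.frame with columns `gene_id`, `group1`, `group2`,
#'   `log2fc`, `mean1`, `mean2`, `p_value`, `q_value`, `direction`,
#'   `untestable`, `passes_filter`
#' @export
de_between_groups <- function(x, group_labels, p = de_params(),
                              contrast = NULL) {
  stopifnot(inherits(p, "de_params"))
  is_cm <- inherits(x, "count_matrix")
  obs <- if (is_cm) x$obs_ids else rownames(x)
  gl <- group_labels[obs]
  if (anyNA(gl)) stopf("group label missing for some observations")
  groups <- sort(unique(as.character(gl)))
  if (length(groups) != 2) stopf("need exactly 2 groups, found %d", length(groups))
  if (is.null(contrast)) contrast <- groups
  if (!setequal(contrast, groups)) stopf("contrast must name the two groups")
  idx1 <- gl == contrast[1]

  if (p$test == "nb_wald") {
    if (!is_cm) stopf("nb_wald requires raw counts (a count_matrix)")
    counts <- as.matrix(x$counts)
    r <- nb_wald_matrix(counts, idx1, p$fc_pseudocount)
    gene_ids <- x$gene_ids
  } else {
    expr <- if (is_cm) as.matrix(normalize_log_cpm(x)) else as.matrix(x)
    gene_ids <- colnames(expr)
    fc <- log2fc_from_log(expr, idx1, p$fc_pseudocount)
    untestable <- fc$m1 == 0 & fc$m2 == 0
    pv <- rep(1, ncol(expr))
    testable <- which(!untestable)
    if (length(testable))
      pv[testable] <- wilcox_p_matrix(expr, idx1, cols = testable)
    lfc <- fc$lfc
    lfc[untestable] <- 0
    r <- list(lfc = lfc, m1 = fc$m1, m2 = fc$m2, p = pv,
              untestable = untestable)
  }
  qv <- if (p$mtc == "bh") stats::p.adjust(r$p, "BH") else r$p
  data.frame(gene_id = gene_ids, group1 = contrast[1], group2 = contrast[2],
             log2fc = unname(r$lfc), mean1 = unname(r$m1),
             mean2 = unname(r$m2), p_value = unname(r$p),
             q_value = unname(qv),
             direction = ifelse(r$lfc > 0, "up",
                                ifelse(r$lfc < 0, "down", "none")),
             untestable = unname(r$untestable),
             passes_filter = unname(r$p < p$alpha &
                                      abs(r$lfc) > p$min_abs_log2fc &
                                      !r$untestable),
             stringsAsFactors = FALSE)
}
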