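#' Flag differential-expression records whose product is secreted
#'
#' A gene counts as secretory when any of its subcellular-location strings
#' contains one of the `secreted_keywords` (case-insensitive substring
#' match, e.g. "Secreted, extracellular space"). Genes absent from the
#' table are flagged not-secreted with `in_location_table = FALSE` so
#' missingness is never silently conflated with a negative annotation.
#'
#' @param records data.frame with a `gene_id` column (e.g. output of
#'   [de_between_groups()])
#' @param table location table: data.frame with `gene_id`, `location`
#'   (pipe-separated compartments)
#' @param secreted_keywords keywords marking a secretory location
#' @return `records` with logical columns `secreted` and
#'   `in_location_table` appended
#' @export
annotate_secretory <- function(records, table,
                               secreted_keywords = "Secreted") {
  stopifnot(is.data.frame(records), "gene_id" %in% names(records))
  if (anyDuplicated(table$gene_id)) stopf("duplicate gene_id in location table")
  locs <- stats::setNames(as.character(table$location), table$gene_id)
  hit <- rep(FALSE, nrow(table))
  for (kw in secreted_keywords)
    hit <- hit | grepl(kw, table$location, ignore.case = TRUE, fixed = FALSE)
  sec <- stats::setNames(hit, table$gene_id)
  present <- records$gene_id %in% table$gene_id
  records$secreted <- ifelse(present, unname(sec[records$gene_id]), FALSE)
  records$in_location_table <- present
  records
}

#' Direction-aware multi-comparison DEG screen
#'
#' Takes two or more named comparisons, each a signed DEG set (genes
#' labelled up or down under that comparison's own sign convention), and
#' computes the genes common to all comparisons, the direction-consistent
#' subset, and each comparison's private genes. A gene listed both up and
#' down within one comparison is a validation error.
#'
#' @param comparisons named list; each element either a list with
#'   character elements `up` and `down`, or a data.frame with `gene_id`
#'   and `direction` ("up"/"down")
#' @return object of class `comparison_screen`: list with `common`,
#'   `common_consistent`, `unique` (named list of private gene sets),
#'   `membership` (gene x comparison direction table, "" = absent) and
#'   `counts`
#' @export
screen_comparisons <- function(comparisons) {
  if (length(comparisons) < 2) stopf("need at least 2 comparisons")
  if (is.null(names(comparisons)) || any(!nzchar(names(comparisons))))
    stopf("comparisons must be named")
  norm <- lapply(names(comparisons), function(nm) {
    x <- comparisons[[nm]]
    if (is.data.frame(x)) {
      up <- x$gene_id[x$direction == "up"]
      down <- x$gene_id[x$direction == "down"]
    } else {
      up <- x$up %||% character(0); down <- x$down %||% character(0)
    }
    both <- intersect(up, down)
    if (length(both))
      stopf("gene(s) both up and down in comparison '%s': %s", nm,
            paste(utils::head(both, 3), collapse = ", "))
    list(up = unique(up), down = unique(down))
  })
  names(norm) <- names(comparisons)
  all_genes <- sort(unique(unlist(lapply(norm, unlist))))
  membership <- sapply(norm, function(cmp)
    ifelse(all_genes %in% cmp$up, "up",
           ifelse(all_genes %in% cmp$down, "down", "")))
  membership <- matrix(membership, nrow = length(all_genes),
                       dimnames = list(all_genes, names(norm)))
  in_all <- rowSums(membership != "") == ncol(membership)
  common <- all_genes[in_all]
  consistent <- common[apply(membership[common, , drop = FALSE], 1,
                             function(r) length(unique(r)) == 1)]
  uniq <- lapply(names(norm), function(nm) {
    present <- membership[, nm] != ""
    others <- rowSums(membership[, setdiff(names(norm), nm), drop = FALSE] != "") > 0
    all_genes[present & !others]
  })
  names(uniq) <- names(norm)
  structure(list(common = common, common_consistent = consistent,
                 unique = uniq, membership = membership,
                 counts = c(list(union = length(all_genes),
                                 common = length(common),
                                 common_consistent = length(consistent)),
                            lapply(uniq, length))),
            class = "comparison_screen")
}

#' @export
print.comparison_screen <- function(x, ...) {
  cat(sprintf("<comparison_screen> %d comparisons, %d genes in union, %d common (%d direction-consistent)\n",
              ncol(x$membership), nrow(x$membership), length(x$common),
              length(x$common_consistent)))
  invisible(x)
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, the upper-tail probability `P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`: universe size N, set size K (after
#' intersecting the set with the universe), query size n, overlap k.
#' Benjamini-Hochberg correction across the tested sets; a set is called
#' significant when `q < q_threshold`. The rich factor is `k / K`.
#'
#' @param query character vector of query genes (must be within universe)
#' @param universe character vector, the background gene universe
#' @param gene_sets named list of character vectors
#' @param q_threshold significance threshold on the BH q-value
#' @return data.frame with columns `set`, `N`, `K`, `n`, `k`, `p`, `q`,
#'   `rich_factor`, `significant`, sorted by p
#' @export
hypergeom_enrich <- function(query, universe, gene_sets, q_threshold = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside))
    stopf("query gene(s) outside the universe: %s",
          paste(utils::head(outside, 3), collapse = ", "))
  if (is.null(names(gene_sets))) stopf("gene_sets must be named")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, N = N, K = K, n = n, k = k, p = p,
               rich_factor = if (K > 0) k / K else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out$significant <- out$q < q_threshold
  out <- out[order(out$p, out$set), c("set", "N", "K", "n", "k", "p", "q",
                                      "rich_factor", "significant")]
  rownames(out) <- NULL
  out
}
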