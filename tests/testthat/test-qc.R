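test_that("kept sets equal a brute-force scan applying the rules in order", {
  m <- rand_cm(200, 60, mu = 1.2, seed = 9)
  p <- qc_params(min_genes_per_nucleus = 30, max_mito_fraction = 0.2,
                 min_cells_per_gene = 2)
  got <- filter_matrix(m, p)
  want <- qc_oracle(m, p)
  expect_identical(got$filtered$obs_ids, want$obs)
  expect_identical(got$filtered$gene_ids, want$genes)
  expect_equal(got$report$n_kept_obs, length(want$obs))
  expect_equal(got$report$n_kept_genes, length(want$genes))
})

test_that("boundaries are strict: mito exactly at the ceiling is removed", {
  cnt <- rbind(c(5, 5, 5, 5),   # mito fraction 5/20 = 0.25 -> removed
               c(1, 5, 5, 5),   # 1/16 = 0.0625 -> kept
               c(0, 0, 0, 0))   # zero detected genes -> removed
  m <- count_matrix(cnt, c("mito25", "ok", "empty"),
                    c("MT-1", "g1", "g2", "g3"))
  got <- filter_matrix(m, qc_params(min_genes_per_nucleus = 2,
                                    max_mito_fraction = 0.25))
  expect_identical(got$filtered$obs_ids, "ok")
  expect_equal(got$report$removed_high_mito, 1)
})

test_that("mito_fraction is counts of MT- names over total, 0 for empty obs", {
  cnt <- rbind(c(3, 7), c(0, 0), c(4, 0))
  m <- count_matrix(cnt, c("a", "b", "c"), c("MT-1", "g1"))
  expect_equal(unname(mito_fraction(m)), c(0.3, 0, 1))
  m2 <- count_matrix(cnt, c("a", "b", "c"), c("x1", "g1"))
  expect_equal(unname(mito_fraction(m2)), c(0, 0, 0))
})

test_that("raising thresholds moves kept counts monotonically", {
  m <- rand_cm(120, 50, mu = 1, seed = 4)
  kept_at <- function(mg, mf) filter_matrix(
    m, qc_params(min_genes_per_nucleus = mg, max_mito_fraction = mf)
  )$report$n_kept_obs
  expect_true(kept_at(10, 0.3) >= kept_at(20, 0.3))
  expect_true(kept_at(10, 0.3) >= kept_at(10, 0.1))
})

test_that("log-CPM normalization: hand value, scale invariance, zero genes", {
  cnt <- rbind(c(10, 990, 0), c(20, 1980, 0))
  m <- count_matrix(cnt, c("o1", "o2"), c("gA", "gB", "gC"))
  x <- normalize_log_cpm(m)
  # count 10 in library 1000: log2(10/1000 * 1e6 + 1) = log2(10001)
  expect_equal(x["o1", "gA"], log2(10001), tolerance = 1e-12)
  # o2 doubles every count of o1 -> identical normalized values
  expect_equal(as.numeric(x["o1", ]), as.numeric(x["o2", ]), tolerance = 1e-12)
  # all-zero gene maps to log2(pseudocount) = 0
  expect_equal(as.numeric(x[, "gC"]), c(0, 0))
  # CPM sums to 1e6 before the log when the pseudocount is removed
  cpm <- 2^as.matrix(normalize_log_cpm(m)) - 1
  expect_equal(unname(rowSums(cpm)), c(1e6, 1e6), tolerance = 1e-6)
})

test_that("zero library size is an error naming the observation", {
  m <- count_matrix(rbind(c(1, 2), c(0, 0)), c("good", "empty"), c("g1", "g2"))
  expect_error(normalize_log_cpm(m), "empty")
})

test_that("pseudobulk sums member counts with deterministic group order", {
  m <- rand_cm(10, 6, seed = 3)
  g <- setNames(rep(c("z_late", "a_early"), 5), m$obs_ids)
  pb <- pseudobulk(m, g)
  expect_identical(rownames(pb), c("a_early", "z_late"))
  cnt <- as.matrix(m$counts)
  expect_equal(pb["a_early", ], colSums(cnt[g[m$obs_ids] == "a_early", ]))
  # one group holding every observation = column sums
  pb1 <- pseudobulk(m, setNames(rep("all", 10), m$obs_ids))
  expect_equal(pb1["all", ], colSums(cnt))
  # singleton groups = identity rows
  pbi <- pseudobulk(m, setNames(m$obs_ids, m$obs_ids))
  expect_equal(unname(pbi[m$obs_ids, ]), unname(cnt))
})

test_that("pseudobulk: empty factor levels kept as zero rows, unknown obs error", {
  m <- rand_cm(4, 3, seed = 5)
  g <- factor(setNames(rep("g1", 4), m$obs_ids), levels = c("g1", "ghost"))
  pb <- pseudobulk(m, g)
  expect_equal(unname(pb["ghost", ]), rep(0, 3))
  expect_identical(attr(pb, "empty_groups"), "ghost")
  expect_error(pseudobulk(m, setNames(rep("x", 2), c("bogus1", "bogus2"))),
               "unknown|missing")
})

test_that("spots outside tissue are dropped before analysis", {
  g <- toy_geometry(4, 4)
  g$in_tissue[1:5] <- 0L
  m <- rand_cm(16, 8, seed = 6, obs_kind = "spot")
  m$obs_ids <- g$barcode; rownames(m$counts) <- g$barcode
  names(m$gene_ids) <- NULL
  tis <- filter_spots_tissue(m, g)
  expect_identical(tis$obs_ids, g$barcode[g$in_tissue == 1L])
})
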