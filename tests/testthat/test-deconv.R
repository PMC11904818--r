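test_that("signatures are per-type mean CPM; duplication leaves them unchanged", {
  cnt <- rbind(c(10, 0, 10), c(20, 10, 10), c(0, 5, 15),   # type A
               c(2, 8, 0), c(4, 16, 0), c(0, 10, 10))      # type B
  m <- count_matrix(cnt, sprintf("n%d", 1:6), c("g1", "g2", "g3"))
  labels <- setNames(rep(c("A", "B"), each = 3), m$obs_ids)
  sig <- build_signatures(m, labels, top_k_markers = Inf)
  cpm <- cnt / rowSums(cnt) * 1e6
  expect_equal(unname(sig["A", ]), unname(colMeans(cpm[1:3, ])), tolerance = 1e-12)
  expect_equal(unname(sig["B", ]), unname(colMeans(cpm[4:6, ])), tolerance = 1e-12)
  # duplicating every nucleus cannot move a mean
  m2 <- count_matrix(rbind(cnt, cnt), sprintf("n%d", 1:12), c("g1", "g2", "g3"))
  sig2 <- build_signatures(m2, setNames(rep(c("A", "B", "A", "B"), each = 3),
                                        m2$obs_ids)[m2$obs_ids],
                           top_k_markers = Inf)
  expect_equal(sig2, sig, ignore_attr = TRUE)
  expect_error(build_signatures(m, setNames(rep("A", 6), m$obs_ids),
                                top_k_markers = Inf), NA)
})

test_that("a spot equal to one signature deconvolves to that type alone", {
  ref <- small_ref()
  S <- ref$truth$true_signatures
  pure <- round(S["FAPs", ] / sum(S["FAPs", ]) * 2e8)
  m <- count_matrix(matrix(pure, 1), "pure_spot", colnames(S), obs_kind = "spot")
  pm <- deconvolve_spots(m, S)
  expect_gt(pm$proportions["pure_spot", "FAPs"], 1 - 1e-6)
  expect_lt(pm$residual, 1e-4)
})

test_that("noiseless two-signature mixtures are recovered to 1e-6", {
  ref <- small_ref()
  S <- ref$truth$true_signatures[c("FAPs", "Myofibers"), ]
  mix <- 0.6 * S[1, ] + 0.4 * S[2, ]
  cnt <- round(mix / sum(mix) * 2e8)
  m <- count_matrix(matrix(cnt, 1), "mix", colnames(S), obs_kind = "spot")
  pm <- deconvolve_spots(m, S)
  expect_equal(unname(pm$proportions["mix", ]), c(0.6, 0.4), tolerance = 1e-6)
})

test_that("an all-zero spot falls back to uniform proportions and is flagged", {
  ref <- small_ref()
  S <- ref$truth$true_signatures
  cnt <- rbind(round(S[1, ] / sum(S[1, ]) * 1e5), 0)
  m <- count_matrix(cnt, c("live", "dead"), colnames(S), obs_kind = "spot")
  pm <- deconvolve_spots(m, S)
  expect_true(pm$flagged["dead" == rownames(pm$proportions)][1] ||
                pm$flagged[2])
  expect_equal(unname(pm$proportions[2, ]), rep(1 / nrow(S), nrow(S)))
})

test_that("no shared genes is an error", {
  ref <- small_ref()
  S <- ref$truth$true_signatures
  m <- count_matrix(matrix(1:4, 1), "s", c("a", "b", "c", "d"), obs_kind = "spot")
  expect_error(deconvolve_spots(m, S), "shared")
})

test_that("region classification matches the sort-and-count oracle", {
  pr <- matrix(c(seq(0.01, 1, by = 0.01), seq(0.99, 0, by = -0.01)), 100,
               dimnames = list(sprintf("s%03d", 1:100), c("FAPs", "Other")))
  pr <- pr / rowSums(pr)
  v <- pr[, "FAPs"]
  pm <- proportion_map(pr)
  lab <- classify_regions(pm, NULL, region_params())
  # oracle: order statistics at ranks ceiling(n*q)
  sv <- sort(v)
  hi <- sv[ceiling(100 * 0.75)]; lo <- sv[ceiling(100 * 0.25)]
  expect_equal(sum(lab == "high"), sum(v >= hi))
  expect_equal(sum(lab == "low"), sum(v <= lo))
  # the canonical 0.01..1.00 example: exactly 26 high
  pr2 <- cbind(FAPs = seq(0.01, 1, by = 0.01))
  pr2 <- cbind(pr2, Other = 1 - pr2[, 1])
  rownames(pr2) <- sprintf("t%03d", 1:100)
  lab2 <- classify_regions(proportion_map(pr2), NULL, region_params())
  expect_equal(sum(lab2 == "high"), 26)
  expect_equal(sum(lab2 == "low"), 25)
})

test_that("degenerate quantiles: all-high at 0, all-intermediate when constant", {
  pr <- cbind(FAPs = rep(0.3, 10), Other = rep(0.7, 10))
  rownames(pr) <- sprintf("s%02d", 1:10)
  expect_warning(lab <- classify_regions(proportion_map(pr), NULL,
                                         region_params()), "constant")
  expect_true(all(lab == "intermediate"))
  pr2 <- cbind(FAPs = seq(0.1, 0.9, length.out = 10))
  pr2 <- cbind(pr2, Other = 1 - pr2[, 1])
  rownames(pr2) <- sprintf("s%02d", 1:10)
  lab2 <- classify_regions(proportion_map(pr2), NULL,
                           region_params(high_quantile = 1e-9,
                                         low_quantile = 0))
  expect_true(all(lab2 == "high"))
})

test_that("classification is invariant to monotone rescaling of proportions", {
  set.seed(8)
  v <- runif(50)
  mk_pm <- function(x) {
    pr <- cbind(FAPs = x / (x + 1), Other = 1 / (x + 1))
    rownames(pr) <- sprintf("s%02d", 1:50)
    proportion_map(pr)
  }
  l1 <- classify_regions(mk_pm(v), NULL, region_params())
  l2 <- classify_regions(mk_pm(v * 3 + 0.2), NULL, region_params())
  expect_identical(l1, l2)
})

test_that("region DE finds a gene planted in high spots; small classes refused", {
  set.seed(12)
  n <- 40
  cnt <- matrix(rpois(2 * n * 10, 20), 2 * n)
  cnt[1:n, 1] <- rpois(n, 80)   # planted high-region gene
  m <- count_matrix(cnt, sprintf("s%03d", 1:(2 * n)),
                    c("planted", sprintf("g%02d", 2:10)), obs_kind = "spot")
  lab <- setNames(rep(c("high", "low"), each = n), m$obs_ids)
  de <- region_de(m, lab)
  row <- de[de$gene_id == "planted", ]
  expect_true(row$passes_filter && row$direction == "up")
  lab2 <- setNames(c(rep("high", 2), rep("low", 2 * n - 2)), m$obs_ids)
  expect_error(region_de(m, lab2), ">= 3 spots")
})

test_that("shuffled region labels pass roughly at the alpha level", {
  set.seed(99)
  n <- 60; G <- 400
  cnt <- matrix(rnbinom(2 * n * G, mu = 10, size = 5), 2 * n)
  m <- count_matrix(cnt, sprintf("s%03d", 1:(2 * n)), sprintf("g%04d", 1:G),
                    obs_kind = "spot")
  lab <- setNames(sample(rep(c("high", "low"), each = n)), m$obs_ids)
  de <- region_de(m, lab)
  expect_lt(mean(de$p_value < 0.05), 0.10)  # null: ~5%, generous margin
})
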