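test_that("region membership equals brute-force distance sort with tie-break", {
  g <- toy_geometry(8, 8)  # 64 spots, plenty of exact hex distance ties
  for (seed_spot in g$barcode[c(1, 28, 64)]) {
    got <- extract_region(g, seed_spot, 25)
    expect_length(got, 25)
    expect_true(seed_spot %in% got)
    expect_identical(got, region_oracle(g, seed_spot, 25))
  }
  expect_identical(extract_region(g, g$barcode[5], 1), g$barcode[5])
  expect_error(extract_region(g, g$barcode[1], 65), "in-tissue")
})

test_that("region sampling is seed-deterministic with exact sizes", {
  g <- toy_geometry(10, 10)
  m <- rand_cm(100, 30, mu = 5, seed = 77, obs_kind = "spot")
  m$obs_ids <- g$barcode
  rownames(m$counts) <- g$barcode
  p <- correlation_params(n_regions_per_sample = 40, region_size = 25, seed = 5)
  a <- sample_regions(g, m, p)
  b <- sample_regions(g, m, p)
  expect_identical(a$regions, b$regions)
  expect_identical(a$profiles, b$profiles)
  expect_true(all(lengths(a$members) == 25))
  expect_true(all(mapply(function(mem, seed) seed %in% mem,
                         a$members, a$regions$seed_spot)))
  # zero regions -> empty, not an error
  z <- sample_regions(g, m, correlation_params(n_regions_per_sample = 0, seed = 1))
  expect_equal(nrow(z$regions), 0)
})

test_that("region profiles are log2-CPM of summed member counts", {
  g <- toy_geometry(6, 6)
  m <- rand_cm(36, 12, mu = 8, seed = 3, obs_kind = "spot")
  m$obs_ids <- g$barcode; rownames(m$counts) <- g$barcode
  p <- correlation_params(n_regions_per_sample = 5, region_size = 9, seed = 2)
  rs <- sample_regions(g, m, p)
  mem <- rs$members[[3]]
  s <- colSums(as.matrix(m$counts[mem, ]))
  expect_equal(unname(rs$profiles[3, ]), unname(log2(s / sum(s) * 1e6 + 1)),
               tolerance = 1e-12)
})

test_that("correlation records: self pair r = 1, constant gene undefined", {
  set.seed(4)
  prof <- matrix(rnorm(50 * 3), 50, dimnames = list(NULL, c("a", "b", "const")))
  prof[, "const"] <- 5
  rs <- structure(list(profiles = prof,
                       regions = data.frame(sample_id = rep("s", 50))),
                  class = "region_set")
  cr <- correlate_gene_sets(rs, c("a", "const"), c("a", "b"),
                            correlation_params())
  self <- cr[cr$gene_a == "a" & cr$gene_b == "a", ]
  expect_equal(self$r, 1)
  expect_true(self$pass_standard && self$pass_strict)
  cst <- cr[cr$gene_a == "const", ]
  expect_true(all(cst$undefined))
  expect_true(all(is.na(cst$r)))
  expect_false(any(cst$pass_standard))
})

test_that("correlation p equals the t-transform closed form; r is symmetric", {
  x <- c(3.1, 4.0, 2.2, 5.5, 4.8, 3.9, 6.1, 2.9, 5.0, 4.2)
  y <- c(2.0, 3.5, 1.9, 4.9, 5.2, 3.1, 5.8, 3.3, 4.1, 3.6)
  prof <- cbind(a = x, b = y)
  rs <- structure(list(profiles = prof,
                       regions = data.frame(sample_id = rep("s", 10))),
                  class = "region_set")
  cr <- correlate_gene_sets(rs, "a", "b", correlation_params())
  r <- cor(x, y); n <- 10
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(cr$r, r, tolerance = 1e-12)
  expect_equal(cr$p_value, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-10)
  # independent check: stats::cor.test uses the same reference distribution
  expect_equal(cr$p_value, cor.test(x, y)$p.value, tolerance = 1e-10)
  # symmetry
  cr2 <- correlate_gene_sets(rs, "b", "a", correlation_params())
  expect_identical(cr$r, cr2$r)
})

test_that("stratified per-condition correlations are reported next to pooled", {
  set.seed(6)
  prof <- matrix(rnorm(60 * 2), 60, dimnames = list(NULL, c("a", "b")))
  rs <- structure(list(profiles = prof,
                       regions = data.frame(
                         sample_id = rep(c("TB", "Duroc"), each = 30))),
                  class = "region_set")
  cr <- correlate_gene_sets(rs, "a", "b", correlation_params(),
                            sample_groups = c(TB = "obese", Duroc = "lean"))
  expect_true(all(c("r_lean", "r_obese") %in% names(cr)))
  expect_equal(cr$r_obese, cor(prof[1:30, "a"], prof[1:30, "b"]),
               tolerance = 1e-12)
})

test_that("spatial aggregation table joins normalized expression to coords", {
  g <- toy_geometry(2, 2)
  cnt <- rbind(c(10, 90), c(50, 50), c(0, 100), c(25, 75))
  m <- count_matrix(cnt, g$barcode, c("gA", "gB"), obs_kind = "spot")
  agg <- spatial_aggregation_map(m, g, c("gA", "gB"))
  expr <- normalize_log_cpm(m)
  expect_equal(agg$gA, as.numeric(expr[agg$barcode, "gA"]), tolerance = 1e-12)
  expect_equal(agg$pxl_row, g$pxl_row[match(agg$barcode, g$barcode)])
  expect_error(spatial_aggregation_map(m, g, "missing_gene"), "unknown")
  # constant gene (equal libraries) gives a constant column
  m2 <- count_matrix(cbind(rep(5, 4), rep(95, 4)), g$barcode, c("cst", "v"),
                     obs_kind = "spot")
  agg2 <- spatial_aggregation_map(m2, g, "cst")
  expect_equal(agg2$cst, rep(log2(5 / 100 * 1e6 + 1), 4), tolerance = 1e-12)
})
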