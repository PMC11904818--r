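test_that("identical spec and seed give bit-identical reference output", {
  sp <- reference_spec(n_celltypes = 3, n_genes = 100, n_nuclei_per_type = 20,
                       markers_per_type = 5, seed = 11)
  a <- simulate_reference(sp)
  b <- simulate_reference(sp)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth$true_signatures, b$truth$true_signatures)
})

test_that("reference counts match the declared generator parameters", {
  sp <- reference_spec(n_celltypes = 2, n_genes = 50, n_nuclei_per_type = 5000,
                       markers_per_type = 1, marker_log2fc = 0,
                       baseline_mean = 5, dispersion = 2, mito_gene_count = 0,
                       lowq_fraction = 0, highmito_fraction = 0, seed = 7)
  ref <- simulate_reference(sp)
  # marker sets of distinct types are disjoint
  ms <- ref$truth$marker_sets
  expect_length(intersect(ms[[1]], ms[[2]]), 0)
  # with marker_log2fc = 0 every gene has mean 5; empirical means should sit
  # within 3 NB standard errors, se = sqrt((mu + mu^2/size)/n)
  n <- nrow(ref$counts$counts)
  se <- sqrt((5 + 25 / 2) / n)
  emp <- Matrix::colMeans(ref$counts$counts)
  expect_true(all(abs(emp - 5) < 3 * se))
  # counts are non-negative integers
  v <- ref$counts$counts@x
  expect_true(all(v >= 0) && all(v == round(v)))
})

test_that("null-signal reference yields no markers downstream", {
  sp <- reference_spec(n_celltypes = 3, n_genes = 80, n_nuclei_per_type = 30,
                       markers_per_type = 4, marker_log2fc = 0,
                       mito_gene_count = 0, lowq_fraction = 0,
                       highmito_fraction = 0, seed = 5)
  ref <- simulate_reference(sp)
  mk <- find_markers(normalize_log_cpm(ref$counts), ref$labels)
  # every reported candidate must clear an FDR bar it cannot clear under null
  expect_true(nrow(mk) == 0 || all(mk$q_value > 0.05))
})

test_that("infeasible marker allocation is rejected", {
  expect_error(reference_spec(n_celltypes = 5, n_genes = 40,
                              markers_per_type = 10, mito_gene_count = 0),
               "infeasible")
})

test_that("visium generator: proportions sum to 1, seed-deterministic, hex parity", {
  ref <- small_ref()
  sp <- spatial_spec(grid_rows = 12, grid_cols = 12, reads_per_spot = 2000,
                     fap_celltype = "FAPs", sample_id = "V", seed = 21)
  a <- simulate_visium(sp, ref$truth)
  b <- simulate_visium(sp, ref$truth)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_lt(max(abs(rowSums(a$truth$true_proportions) - 1)), 1e-9)
  expect_length(unique((a$geometry$array_row + a$geometry$array_col) %% 2), 1)
})

test_that("zero smoothness gives identical expected proportions at every spot", {
  ref <- small_ref()
  sp <- spatial_spec(grid_rows = 8, grid_cols = 8, proportion_smoothness = 0,
                     sample_id = "flat", seed = 2)
  v <- simulate_visium(sp, ref$truth)
  pr <- v$truth$true_proportions
  expect_true(all(abs(sweep(pr, 2, pr[1, ]) ) < 1e-12))
})

test_that("planted genes must exist in the reference", {
  ref <- small_ref()
  sp <- spatial_spec(planted_pairs = data.frame(gene_a = "NOPE",
                                                gene_b = "GENE00001",
                                                rho = 0.5),
                     sample_id = "x", seed = 1)
  expect_error(simulate_visium(sp, ref$truth), "absent")
})

test_that("planted pairs recover their target region-level correlation", {
  ref <- small_ref()
  pp <- data.frame(gene_a = c("GENE00100", "GENE00101"),
                   gene_b = c("GENE00150", "GENE00151"),
                   rho = c(0.7, -0.5))
  ok <- vapply(1:3, function(s) {
    v <- simulate_visium(spatial_spec(grid_rows = 60, grid_cols = 60,
                                      planted_pairs = pp, sample_id = "P",
                                      seed = 100 + s), ref$truth)
    tis <- filter_spots_tissue(v$counts, v$geometry)
    cp <- correlation_params(n_regions_per_sample = 200, seed = 200 + s)
    rs <- sample_regions(v$geometry, tis, cp)
    cr <- correlate_gene_sets(rs, pp$gene_a, pp$gene_b, cp)
    r1 <- cr$r[cr$gene_a == pp$gene_a[1] & cr$gene_b == pp$gene_b[1]]
    r2 <- cr$r[cr$gene_a == pp$gene_a[2] & cr$gene_b == pp$gene_b[2]]
    abs(r1 - 0.7) <= 0.2 && abs(r2 - (-0.5)) <= 0.2
  }, logical(1))
  expect_true(all(ok))
})

test_that("location table hits the secreted fraction and honours planting", {
  genes <- sprintf("G%04d", 1:1000)
  t0 <- simulate_location_table(genes, 0, seed = 1)
  expect_length(grep("Secreted", t0$location), 0)
  t1 <- simulate_location_table(genes, 1, seed = 1)
  expect_true(all(grepl("Secreted", t1$location)))
  t10 <- simulate_location_table(genes, 0.1, seed = 1)
  expect_lte(abs(sum(grepl("Secreted", t10$location)) - 100), 1)
  tp <- simulate_location_table(genes, 0, planted_secreted = c("G0007", "G0009"),
                                seed = 1)
  expect_true(all(grepl("Secreted",
                        tp$location[tp$gene_id %in% c("G0007", "G0009")])))
})
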