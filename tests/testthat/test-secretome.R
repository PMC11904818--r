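test_that("secretory annotation: keyword substring, missing genes marked", {
  tab <- data.frame(gene_id = c("SPARC", "ACTB", "CST3"),
                    location = c("Secreted, extracellular space",
                                 "Cytoplasm", "Secreted"),
                    stringsAsFactors = FALSE)
  rec <- data.frame(gene_id = c("SPARC", "ACTB", "GHOST"),
                    stringsAsFactors = FALSE)
  out <- annotate_secretory(rec, tab)
  expect_equal(out$secreted, c(TRUE, FALSE, FALSE))
  expect_equal(out$in_location_table, c(TRUE, TRUE, FALSE))
  # idempotent and row-order independent
  out2 <- annotate_secretory(out[3:1, ], tab)
  expect_equal(out2$secreted, rev(out$secreted))
})

test_that("three-way screen partitions match naive set algebra", {
  set.seed(31)
  pool <- sprintf("G%03d", 1:60)
  mk <- function() {
    g <- sample(pool, 25)
    list(up = g[1:12], down = g[13:25])
  }
  comps <- list(c1 = mk(), c2 = mk(), c3 = mk())
  scr <- screen_comparisons(comps)
  # naive recomputation
  sets <- lapply(comps, function(x) c(x$up, x$down))
  naive_common <- Reduce(intersect, sets)
  expect_setequal(scr$common, naive_common)
  dirs <- function(g) vapply(comps, function(x)
    if (g %in% x$up) "up" else if (g %in% x$down) "down" else "", "")
  naive_consist <- naive_common[vapply(naive_common, function(g)
    length(unique(dirs(g))) == 1, TRUE)]
  expect_setequal(scr$common_consistent, naive_consist)
  for (nm in names(comps)) {
    others <- unlist(sets[setdiff(names(comps), nm)])
    expect_setequal(scr$unique[[nm]], setdiff(sets[[nm]], others))
  }
  # membership patterns cover the union disjointly per comparison
  expect_setequal(rownames(scr$membership), unique(unlist(sets)))
})

test_that("the two six-gene breed-specific secretory lists screen to 12 common", {
  up_tb <- c("SPARC", "CST3", "COL15A1", "CFD", "GPX3", "COL4A2")
  up_duroc <- c("GSN", "ANXA2", "FN1", "COL14A1", "MGP", "COL1A2")
  scr <- screen_comparisons(list(
    spatial_high_vs_low = list(up = up_tb, down = up_duroc),
    snRNA_TB_vs_Duroc   = list(up = up_tb, down = up_duroc)))
  expect_length(scr$common, 12)
  expect_length(scr$common_consistent, 12)
  expect_equal(sum(scr$membership[, 1] == "up"), 6)
  expect_equal(sum(scr$membership[, 1] == "down"), 6)
})

test_that("disjoint comparisons give an empty common set", {
  scr <- screen_comparisons(list(a = list(up = c("x", "y"), down = "z"),
                                 b = list(up = "p", down = "q")))
  expect_length(scr$common, 0)
})

test_that("a gene up and down in one comparison is a validation error", {
  expect_error(screen_comparisons(list(a = list(up = "g1", down = "g1"),
                                       b = list(up = "g2", down = character(0)))),
               "both up and down")
})

test_that("hypergeometric p matches closed forms exactly", {
  uni <- sprintf("u%02d", 1:20)
  sets <- list(all5 = uni[1:5])
  # N=20, K=5, n=5, k=5 -> 1/C(20,5)
  e <- hypergeom_enrich(uni[1:5], uni, sets)
  expect_equal(e$p[e$set == "all5"], 1 / choose(20, 5), tolerance = 1e-12)
  # N=10, K=4, n=3, k>=2 -> (C(4,2)C(6,1)+C(4,3))/C(10,3) = 40/120
  uni10 <- sprintf("v%02d", 1:10)
  e2 <- hypergeom_enrich(c(uni10[1:2], uni10[5]), uni10,
                         list(s = uni10[1:4]))
  expect_equal(e2$p, 1 / 3, tolerance = 1e-12)
  expect_equal(e2$k, 2)
  expect_equal(e2$rich_factor, 2 / 4)
})

test_that("enrichment edge cases: empty query p = 1, empty universe error", {
  uni <- sprintf("u%02d", 1:20)
  e <- hypergeom_enrich(character(0), uni, list(s = uni[1:5]))
  expect_equal(e$p, 1)
  expect_equal(e$k, 0)
  expect_error(hypergeom_enrich("x", character(0), list(s = "x")), "empty universe")
  expect_error(hypergeom_enrich("not_in_universe", uni, list(s = uni[1:2])),
               "outside")
})

test_that("enrichment p is monotone decreasing in the overlap k", {
  uni <- sprintf("u%03d", 1:100)
  K <- uni[1:20]
  ps <- vapply(5:15, function(k) {
    q <- c(K[seq_len(k)], uni[21:(21 + (15 - k))])
    hypergeom_enrich(q, uni, list(s = K))$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})
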