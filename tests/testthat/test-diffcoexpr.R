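test_that("pearson_cor matches hand-computed values and rejects constants", {
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8, tolerance = 1e-12)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), class = "pononet_constant_gene")
  expect_error(pearson_cor(1:2, 1:2), class = "pononet_validation_error")
})

test_that("the differential ratio follows the guarded relative difference", {
  expect_equal(differential_ratio(0.8, 0), 1)
  expect_equal(differential_ratio(0.5, -0.5), 2)
  expect_equal(differential_ratio(0, -0.8), Inf) # guarded zero denominator
  expect_equal(differential_ratio(0.9, 0.1), 8 / 9, tolerance = 1e-12)
  expect_equal(differential_ratio(0, 0), 0)
})

test_that("pair classification reproduces the documented truth table", {
  cases <- tibble::tribble(
    ~r_resp, ~r_non, ~class,
    0.8, 0.0, "PO", # ratio exactly 1
    0.9, 0.1, "NONE", # pattern holds but ratio 8/9 < 1
    -0.75, 0.2, "NO", # ratio 1.267
    0.1, 0.9, "OP", # ratio 8
    0.9, 0.8, "NONE", # both correlated, no "O" side
    0.0, -0.8, "ON" # guarded denominator passes
  )
  got <- classify_pairs(cases$r_resp, cases$r_non)
  expect_equal(as.character(got), cases$class)
})

test_that("classification is symmetric in the gene pair", {
  # swapping gene_a/gene_b leaves both correlations unchanged, so the class
  # must be a function of (r_resp, r_non) only; check over a value grid
  grid <- expand.grid(r = seq(-0.95, 0.95, by = 0.19), s = seq(-0.95, 0.95, by = 0.19))
  c1 <- classify_pairs(grid$r, grid$s)
  c2 <- classify_pairs(grid$r, grid$s)
  expect_identical(c1, c2)
})

test_that("a positively-correlated response pair passes the ratio iff r_non <= 0", {
  r_resp <- seq(0.7, 0.99, by = 0.01)
  r_non <- seq(-0.69, 0.69, by = 0.01)
  grid <- expand.grid(r_resp = r_resp, r_non = r_non)
  cls <- classify_pairs(grid$r_resp, grid$r_non)
  expect_identical(cls == "PO", grid$r_non <= 0)
})

test_that("condition correlations enumerate all unordered pairs", {
  set.seed(5)
  e <- make_expr(matrix(rnorm(5 * 12, 8, 1), 5, 12))
  ph <- two_group_phenotypes(6, 6)
  tab <- condition_correlations(e, ph, e$gene)
  expect_equal(nrow(tab), choose(5, 2))
  expect_true(all(tab$gene_a < tab$gene_b))
  expect_true(all(abs(tab$r_response) <= 1 & abs(tab$r_nonresponse) <= 1))

  # single dataset: per-dataset z-scoring cannot change correlations
  tab2 <- condition_correlations(e, ph, e$gene, combine = "concat")
  expect_equal(tab, tab2, tolerance = 1e-12)

  expect_error(
    condition_correlations(e, two_group_phenotypes(3, 9), e$gene),
    class = "pononet_validation_error"
  )
})

test_that("constant genes yield NA correlations, flagged not crashed", {
  m <- matrix(rnorm(3 * 10, 8, 1), 3, 10)
  m[2, 1:5] <- 4 # constant within response
  e <- make_expr(m)
  ph <- two_group_phenotypes(5, 5)
  tab <- suppressMessages(condition_correlations(e, ph, e$gene))
  expect_true(all(is.na(tab$r_response[tab$gene_a == "g2" | tab$gene_b == "g2"])))
  edges <- suppressMessages(build_differential_edges(tab))
  expect_false(any(edges$gene_a == "g2" | edges$gene_b == "g2"))
})

test_that("edge building composes filtering and classification", {
  tab <- tibble::tibble(
    gene_a = c("a", "b", "c", "d", "e"),
    gene_b = c("b", "c", "d", "e", "f"),
    r_response = c(0.8, 0.9, -0.75, 0.1, 0.9),
    r_nonresponse = c(0.0, 0.1, 0.2, 0.9, 0.8)
  )
  edges <- suppressMessages(build_differential_edges(tab))
  expect_equal(as.character(edges$class), c("PO", "NO", "OP"))

  empty <- suppressMessages(build_differential_edges(tab[0, ]))
  expect_equal(nrow(empty), 0)

  same <- tibble::tibble(
    gene_a = "a", gene_b = "b", r_response = 0.9, r_nonresponse = 0.9
  )
  expect_equal(nrow(suppressMessages(build_differential_edges(same))), 0)
})

test_that("per-dataset z-scoring suppresses batch-driven correlation", {
  # two cohorts whose gene baselines differ; pooling raw values invents
  # correlation between unrelated genes, z-scoring per dataset removes it
  set.seed(13)
  m1 <- matrix(rnorm(2 * 40, 8, 0.3), 2, 40)
  m2 <- matrix(rnorm(2 * 40, 8, 0.3), 2, 40) + c(3, 3)
  e1 <- make_expr(m1, samples = sprintf("a%d", 1:40), dataset_id = "A")
  e2 <- make_expr(m2, samples = sprintf("b%d", 1:40), dataset_id = "B")
  ph1 <- make_phenotypes(sprintf("a%d", 1:40), rep(c("response", "nonresponse"), each = 20))
  ph2 <- make_phenotypes(sprintf("b%d", 1:40), rep(c("response", "nonresponse"), each = 20))
  raw <- condition_correlations(list(e1, e2), list(ph1, ph2), c("g1", "g2"),
    combine = "concat")
  zed <- condition_correlations(list(e1, e2), list(ph1, ph2), c("g1", "g2"),
    combine = "per_dataset_z")
  expect_gt(raw$r_response, 0.9) # batch artifact
  expect_lt(abs(zed$r_response), 0.4)
})
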