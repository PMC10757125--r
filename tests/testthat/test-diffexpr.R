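test_that("ordinary t matches the pooled two-sample closed form", {
  e <- make_expr(matrix(c(1, 2, 3, 3, 4, 5), nrow = 1), genes = "g1")
  ph <- two_group_phenotypes(3, 3)
  r <- diff_expression(e, ph, moderation = FALSE)
  expect_equal(r$log2_fc, -2)
  expect_equal(r$t, -2.449, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.0705, tolerance = 1e-3)

  # property: agreement with the closed form on random matrices
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(rnorm(30 * 12, 8, 1), 30, 12)
    e <- make_expr(m)
    ph <- two_group_phenotypes(5, 7)
    r <- diff_expression(e, ph, moderation = FALSE)
    for (i in c(1, 15, 30)) {
      ref <- pooled_t(m[i, 1:5], m[i, 6:12])
      expect_equal(r$t[i], ref$t, tolerance = 1e-10)
      expect_equal(r$p_value[i], ref$p, tolerance = 1e-10)
    }
  }
})

test_that("degenerate genes are handled: identical values give t = 0, p = 1", {
  m <- matrix(rnorm(4 * 8, 8, 1), 4, 8)
  m[1, ] <- 5
  e <- make_expr(m)
  ph <- two_group_phenotypes(4, 4)
  r <- diff_expression(e, ph, moderation = FALSE)
  expect_equal(r$t[1], 0)
  expect_equal(r$p_value[1], 1)
  expect_equal(r$log2_fc[1], 0)
  expect_error(
    diff_expression(e, two_group_phenotypes(1, 7)),
    class = "pononet_validation_error"
  )
})

test_that("moderated t agrees with the limma empirical-Bayes reference", {
  skip_if_not_installed("limma")
  set.seed(7)
  m <- matrix(rnorm(200 * 16, 8, 1), 200, 16)
  m[1:20, 1:8] <- m[1:20, 1:8] + 1
  e <- make_expr(m)
  ph <- two_group_phenotypes(8, 8)
  r <- diff_expression(e, ph, moderation = TRUE)
  mod <- attr(r, "moderation")

  design <- cbind(1, rep(c(1, 0), each = 8))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(mod$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(r$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(r$p_value, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("infinite prior df collapses every posterior variance to the prior", {
  # every gene shares the same within-group residuals (identical variances,
  # no spread beyond chi-square sampling) -> d0 = Inf
  set.seed(1)
  n1 <- 5
  n2 <- 5
  base <- rnorm(n1 + n2)
  deltas <- rnorm(50)
  m <- t(vapply(deltas, function(d) {
    8 + base * 0.5 + d * rep(c(1, 0), c(n1, n2))
  }, numeric(n1 + n2)))
  e <- make_expr(m)
  r <- diff_expression(e, two_group_phenotypes(n1, n2), moderation = TRUE)
  mod <- attr(r, "moderation")
  expect_true(is.infinite(mod$d0))
  expect_true(all(is.infinite(r$df)))
  # with d0 = Inf the moderated variance is s0^2 for every gene: identical
  # standard errors, so t is proportional to the mean difference
  expect_equal(cor(abs(r$t), abs(r$log2_fc)), 1, tolerance = 1e-12)
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(c(0.005, 0.03, 0.04)), c(0.015, 0.04, 0.04))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_error(adjust_bh(c(0.1, 1.2)), class = "pononet_validation_error")

  # adjusted values follow their p-values under permutation
  set.seed(3)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
})

test_that("DEG calling applies both down-regulation rules", {
  rec <- tibble::tibble(
    gene = c("up1", "down_soft", "ns"),
    log2_fc = c(0.7, -0.8, 0.9),
    adj_p = c(0.04, 0.04, 0.2)
  )
  soft <- call_degs(rec, down_rule = "reciprocal")
  expect_equal(soft$up, "up1")
  expect_equal(soft$down, "down_soft") # FC = 2^-0.8 = 0.574 <= 1/1.5
  strict <- call_degs(rec, down_rule = "strict_half")
  expect_equal(strict$down, character(0)) # 0.574 is not < 0.5
  expect_equal(strict$up, "up1")
  expect_length(intersect(soft$up, soft$down), 0)
})

test_that("lowering the adjusted-p threshold never adds DEGs", {
  set.seed(11)
  rec <- tibble::tibble(
    gene = sprintf("g%d", 1:200),
    log2_fc = rnorm(200, 0, 1),
    adj_p = runif(200)
  )
  loose <- call_degs(rec, adj_p_max = 0.2)
  tight <- call_degs(rec, adj_p_max = 0.05)
  expect_true(all(tight$up %in% loose$up))
  expect_true(all(tight$down %in% loose$down))
})

test_that("DEG intersection honors the direction mode", {
  a <- structure(list(dataset_id = "a", up = c("x", "y"), down = "z",
    thresholds = list()), class = "deg_set")
  b <- structure(list(dataset_id = "b", up = "y", down = c("z", "w"),
    thresholds = list()), class = "deg_set")
  expect_equal(intersect_degs(a, b, "any_direction"), c("y", "z"))
  expect_equal(intersect_degs(a, b, "same_direction"), c("y", "z"))
  a2 <- structure(list(dataset_id = "a", up = "x", down = character(),
    thresholds = list()), class = "deg_set")
  b2 <- structure(list(dataset_id = "b", up = character(), down = "x",
    thresholds = list()), class = "deg_set")
  expect_equal(intersect_degs(a2, b2, "same_direction"), character(0))
  expect_equal(intersect_degs(a2, b2, "any_direction"), "x")
})
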