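test_that("configuration validation rejects impossible correlation blocks", {
  expect_error(block_spec(5, rho_off = -0.3), class = "pononet_config_error")
  expect_silent(block_spec(2, rho_off = -0.3))
  expect_silent(block_spec(5, rho_off = -0.2))
  expect_error(
    sim_config(n_genes = 5, n_response = 5, n_nonresponse = 5, n_up = 10),
    class = "pononet_config_error"
  )
})

test_that("a fixed seed gives bit-identical output; different seeds differ", {
  cfg <- sim_config(
    n_genes = 30, n_response = 10, n_nonresponse = 10, n_up = 5, n_down = 5,
    blocks = list(block_spec(3, on = "response", rho_off = -0.2)), seed = 5
  )
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(expr_matrix(a$expression), expr_matrix(b$expression))
  cfg2 <- sim_config(
    n_genes = 30, n_response = 10, n_nonresponse = 10, n_up = 5, n_down = 5,
    blocks = list(block_spec(3, on = "response", rho_off = -0.2)), seed = 6
  )
  c_ <- simulate_expression(cfg2)
  expect_false(identical(expr_matrix(a$expression), expr_matrix(c_$expression)))
  expect_identical(dim(expr_matrix(a$expression)), dim(expr_matrix(c_$expression)))
})

test_that("a perfectly correlated block yields sample PCC exactly 1", {
  cfg <- sim_config(
    n_genes = 6, n_response = 10, n_nonresponse = 10,
    blocks = list(list(size = 3, rho_on = 1 - 1e-12, rho_off = 0, on = "response")),
    seed = 3
  )
  sim <- simulate_expression(cfg)
  m <- expr_matrix(sim$expression)
  resp <- sim$phenotypes$sample_id[sim$phenotypes$condition == "response"]
  block <- sim$truth$hubs[[1]]
  cors <- cor(t(m[block, resp]))
  expect_equal(unname(cors[lower.tri(cors)]), rep(1, 3), tolerance = 1e-6)
})

test_that("within-block sample correlation concentrates around rho_on", {
  cfg <- sim_config(
    n_genes = 10, n_response = 1000, n_nonresponse = 4,
    blocks = list(block_spec(5, rho_on = 0.85, rho_off = -0.2, on = "response")),
    seed = 21
  )
  sim <- simulate_expression(cfg)
  m <- expr_matrix(sim$expression)
  resp <- sim$phenotypes$sample_id[sim$phenotypes$condition == "response"]
  cors <- cor(t(m[sim$truth$hubs[[1]], resp]))
  expect_equal(mean(cors[lower.tri(cors)]), 0.85, tolerance = 0.02)
})

test_that("planted pair classes are consistent with the classification rule", {
  cfg <- sim_config(
    n_genes = 20, n_response = 10, n_nonresponse = 10,
    blocks = list(
      block_spec(3, rho_on = 0.85, rho_off = -0.3 / 2, on = "response"),
      block_spec(2, rho_on = 0.85, rho_off = -0.3, on = "nonresponse"),
      block_spec(2, rho_on = -0.85, rho_off = 0.85, on = "response")
    ),
    seed = 2
  )
  truth <- simulate_expression(cfg)$truth
  expect_equal(
    as.character(classify_pairs(truth$pairs$rho_response, truth$pairs$rho_nonresponse)),
    truth$pairs$expected_class
  )
  expect_setequal(
    truth$pairs$expected_class[truth$pairs$block == 1], "PO"
  )
  expect_setequal(
    truth$pairs$expected_class[truth$pairs$block == 2], "OP"
  )
})

test_that("a null cohort yields no discoveries in most seeds", {
  hits <- vapply(1:100, function(s) {
    cfg <- sim_config(
      n_genes = 300, n_response = 10, n_nonresponse = 10,
      n_up = 0, n_down = 0, seed = 1000 + s
    )
    sim <- simulate_expression(cfg)
    r <- diff_expression(sim$expression, sim$phenotypes)
    sum(r$adj_p < 0.05)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("survival generation recovers planted effects and censoring targets", {
  # beta = 0 everywhere, no censoring: every sample has an event
  cfg <- sim_config(n_genes = 5, n_response = 50, n_nonresponse = 0, seed = 12)
  sim <- simulate_expression(cfg)
  s0 <- simulate_survival(sim$expression, censor_rate = 0, seed = 13)
  expect_equal(mean(s0$event), 1)

  # single gene with beta = ln 2 across two expression levels: fitted HR ~ 2
  n <- 1000
  x <- matrix(rep(c(0.5, -0.5), each = n / 2), 1,
    dimnames = list("g1", sprintf("s%d", 1:n)))
  e <- as_expr_df(x, "surv")
  s1 <- simulate_survival(e, setNames(log(2), "g1"), seed = 14)
  # z-scoring maps +-0.5 to +-1, so the group rate ratio is e^(2 ln 2) = 4
  # on the z scale; the per-unit-x HR is recovered via the fitted model
  grp <- factor(rep(c("high", "low"), each = n / 2), levels = c("low", "high"))
  hr <- group_hazard_ratio(s1$time, s1$event, grp)
  expect_equal(log(hr$hr), 2 * log(2), tolerance = 0.15)

  # calibrated censoring rate achieves the target fraction
  rates <- 0.1 * exp(rnorm(1000, 0, 0.5))
  cr <- censor_rate_for(0.3, rates)
  e2 <- as_expr_df(
    matrix(rnorm(1000, 8, 0.5), 1, dimnames = list("g1", sprintf("s%d", 1:1000))),
    "cal"
  )
  s2 <- simulate_survival(e2, baseline_rate = 0.1,
    censor_rate = censor_rate_for(0.3, rep(0.1, 1000)), seed = 15)
  frac <- 1 - mean(s2$event)
  expect_gte(frac, 0.25)
  expect_lte(frac, 0.35)
})

test_that("the two-cohort synthetic study has the documented shape", {
  study <- simulate_study(seed = 7)
  expect_equal(ncol(expr_matrix(study$cohort_a$expression)), 53)
  expect_equal(ncol(expr_matrix(study$cohort_b$expression)), 26)
  expect_equal(
    as.integer(table(study$cohort_a$phenotypes$condition)), c(9, 44)
  )
  expect_equal(
    as.integer(table(study$cohort_b$phenotypes$condition)), c(13, 13)
  )
  expect_gte(nrow(study$truth$degs), 82)
  expect_equal(lengths(study$truth$hubs), c(5L, 5L))

  study2 <- simulate_study(seed = 8)
  expect_false(identical(
    expr_matrix(study$cohort_a$expression),
    expr_matrix(study2$cohort_a$expression)
  ))
  expect_identical(
    dim(expr_matrix(study$cohort_a$expression)),
    dim(expr_matrix(study2$cohort_a$expression))
  )
})
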