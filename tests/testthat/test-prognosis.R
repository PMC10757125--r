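four_subject_fixture <- function() {
  list(
    surv = tibble::tibble(sample_id = sprintf("p%d", 1:4), time = 1:4, event = 1),
    x = matrix(c(1, 0, 1, 0), 4, 1,
      dimnames = list(sprintf("p%d", 1:4), "z"))
  )
}

test_that("Cox fit matches the grid-search oracle and the analytic root", {
  fx <- four_subject_fixture()
  fit <- fit_cox(fx$surv, fx$x, standardize = FALSE)
  beta_grid <- cox_grid_mle(fx$surv$time, fx$surv$event, fx$x[, 1])
  expect_equal(unname(fit$coefficients), beta_grid, tolerance = 1e-4)
  # exp(beta) solves u^2 - u - 4 = 0
  u <- exp(unname(fit$coefficients))
  expect_equal(u^2 - u - 4, 0, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), 0.9406, tolerance = 1e-4)

  # standardized fit is the same model on the z scale
  fitz <- fit_cox(fx$surv, fx$x)
  expect_equal(
    unname(fitz$coefficients) / sd(fx$x[, 1]), beta_grid,
    tolerance = 1e-4
  )
})

test_that("grid-search agreement holds across random small fixtures", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(5:6, 1)
    surv <- tibble::tibble(
      sample_id = sprintf("p%d", 1:n),
      time = sample(100, n), # untied
      event = 1
    )
    x <- matrix(rnorm(n), n, 1, dimnames = list(surv$sample_id, "z"))
    fit <- tryCatch(
      fit_cox(surv, x, standardize = FALSE),
      pononet_separation_error = function(e) NULL
    )
    if (is.null(fit)) next
    expect_equal(
      unname(fit$coefficients),
      cox_grid_mle(surv$time, surv$event, x[, 1]),
      tolerance = 1e-4
    )
  }
})

test_that("perfect separation raises an error naming the covariate", {
  surv <- tibble::tibble(
    sample_id = sprintf("p%d", 1:6), time = 1:6, event = 1
  )
  x <- matrix(c(1, 1, 1, 0, 0, 0), 6, 1,
    dimnames = list(surv$sample_id, "marker"))
  err <- expect_error(
    fit_cox(surv, x, standardize = FALSE),
    class = "pononet_separation_error"
  )
  expect_match(conditionMessage(err), "marker")
  # the ridge fallback instead returns a flagged finite fit
  fit <- suppressMessages(
    fit_cox(surv, x, standardize = FALSE, on_separation = "ridge")
  )
  expect_true(fit$ridge)
  expect_true(is.finite(fit$coefficients))

  const <- matrix(1, 6, 1, dimnames = list(surv$sample_id, "c"))
  expect_error(fit_cox(surv, const), class = "pononet_constant_covariate")
})

test_that("the prognostic index is the linear predictor in model gene order", {
  fx <- four_subject_fixture()
  fit <- fit_cox(fx$surv, fx$x)
  pi1 <- prognostic_index(fit, fx$x)
  z <- (fx$x[, 1] - mean(fx$x[, 1])) / sd(fx$x[, 1])
  expect_equal(unname(pi1), unname(fit$coefficients * z))

  # multivariate: permuting covariate columns does not change PI
  set.seed(2)
  surv <- tibble::tibble(sample_id = sprintf("p%d", 1:30),
    time = rexp(30), event = rep(1, 30))
  x <- matrix(rnorm(90), 30, 3,
    dimnames = list(surv$sample_id, c("ga", "gb", "gc")))
  fit <- fit_cox(surv, x)
  expect_equal(prognostic_index(fit, x), prognostic_index(fit, x[, c(3, 1, 2)]))
  expect_error(prognostic_index(fit, x[, 1:2]),
    class = "pononet_validation_error")
})

test_that("median stratification sends ties to the low-risk group", {
  g <- stratify_risk(c(1, 2, 3, 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  g2 <- stratify_risk(c(1, 2, 2, 3))
  expect_equal(as.character(g2), c("low", "low", "low", "high"))
  expect_error(stratify_risk(rep(1, 5)), class = "pononet_validation_error")

  # invariance to monotone transforms of the PI
  set.seed(4)
  pi_values <- rnorm(101)
  expect_equal(
    as.character(stratify_risk(pi_values)),
    as.character(stratify_risk(exp(pi_values)))
  )
})

test_that("the optimized split never scores below the median split", {
  set.seed(5)
  n <- 120
  x <- rnorm(n)
  surv <- tibble::tibble(
    sample_id = sprintf("p%d", 1:n),
    time = rexp(n, 0.1 * exp(log(2) * x)),
    event = 1
  )
  med <- stratify_risk(x, "median")
  opt <- stratify_risk(x, "optimal", survival_tbl = surv)
  lr_med <- logrank_test(surv$time, surv$event, med)$statistic
  lr_opt <- logrank_test(surv$time, surv$event, opt)$statistic
  expect_gte(lr_opt, lr_med)
})

test_that("Kaplan-Meier estimates match the hand product-limit values", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)
  expect_equal(km$survival[1], 1)

  allcens <- km_estimate(c(2, 3, 4), c(0, 0, 0))
  expect_true(all(allcens$survival == 1))

  # no censoring: equals the empirical survival function
  set.seed(6)
  t_ <- rexp(40)
  km2 <- km_estimate(t_, rep(1, 40))
  ecdf_surv <- vapply(km2$time, function(tt) mean(t_ > tt), numeric(1))
  expect_equal(km2$survival, ecdf_surv, tolerance = 1e-12)
  expect_true(all(diff(km2$survival) <= 0))
  expect_error(km_estimate(numeric(), numeric()),
    class = "pononet_validation_error")
})

test_that("the log-rank statistic matches the hand-computed fixture", {
  time <- c(1, 2, 3, 4)
  event <- rep(1, 4)
  group <- c("X", "X", "Y", "Y")
  # hand sums: O_X = 2, E_X = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36
  lr <- logrank_test(time, event, group)
  expect_equal(lr$statistic, (2 - 5 / 6)^2 / (17 / 36), tolerance = 1e-9)
  expect_equal(lr$p, pchisq(49 / 17, 1, lower.tail = FALSE), tolerance = 1e-9)

  # label symmetry
  lr2 <- logrank_test(time, event, rev(group))
  expect_equal(lr2$statistic, lr$statistic)

  expect_error(logrank_test(time, rep(0, 4), group),
    class = "pononet_validation_error")
  expect_error(logrank_test(time, event, rep("X", 4)),
    class = "pononet_validation_error")
})

test_that("the group hazard ratio exponentiates the two-group Cox fit", {
  fx <- four_subject_fixture()
  hr <- group_hazard_ratio(fx$surv$time, fx$surv$event,
    factor(c("high", "low", "high", "low"), levels = c("high", "low")))
  # low vs high here equals the 4-subject fixture with indicator flipped
  expect_equal(hr$hr, exp(-0.9406), tolerance = 1e-3)
  hr2 <- group_hazard_ratio(fx$surv$time, fx$surv$event,
    factor(c("high", "low", "high", "low"), levels = c("low", "high")))
  expect_equal(hr2$hr, exp(0.9406), tolerance = 1e-3)
  expect_equal(hr2$ci[1] < hr2$hr && hr2$hr < hr2$ci[2], TRUE)
})

test_that("for one gene the fitted-PI split equals the fixed median split", {
  # with a single covariate the high/low partition is {x > median(x)} no
  # matter the sign of the fitted coefficient, so the workflow's log-rank
  # p must equal that of the covariate's own median split
  set.seed(77)
  cfg <- sim_config(n_genes = 1, n_response = 60, n_nonresponse = 0, seed = 77)
  sim <- simulate_expression(cfg)
  x <- as.numeric(expr_matrix(sim$expression)[1, ])
  surv <- simulate_survival(sim$expression, censor_rate = 0.02, seed = 78)
  res <- evaluate_prognosis(sim$expression, surv, sim$expression$gene)
  ref <- logrank_test(surv$time, surv$event, x > median(x))
  expect_equal(res$logrank$p, ref$p, tolerance = 1e-12)
})

test_that("evaluate_prognosis assembles a coherent result object", {
  set.seed(8)
  cfg <- sim_config(
    n_genes = 20, n_response = 80, n_nonresponse = 0,
    blocks = list(block_spec(5, rho_on = 0.85, rho_off = -0.2, on = "response")),
    seed = 8
  )
  sim <- simulate_expression(cfg)
  genes <- sim$truth$hubs[[1]]
  betas <- setNames(rep(0.3, 5), genes)
  surv <- simulate_survival(sim$expression, betas, censor_rate = 0.02, seed = 9)
  res <- evaluate_prognosis(sim$expression, surv, genes)
  expect_s3_class(res, "prognostic_result")
  expect_equal(nrow(res$samples), 80)
  expect_equal(sort(unique(as.character(res$samples$group))), c("high", "low"))
  # the split preserves PI order
  expect_gt(min(res$samples$pi[res$samples$group == "high"]),
    max(res$samples$pi[res$samples$group == "low"]) - 1e-12)
  g <- glance(res)
  expect_true(all(c("hazard_ratio", "logrank_p", "split_method") %in% names(g)))
  td <- tidy(res)
  expect_equal(sum(td$n), 80)

  expect_error(
    evaluate_prognosis(sim$expression, surv, c(genes, "missing_gene")),
    class = "pononet_validation_error"
  )
})
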