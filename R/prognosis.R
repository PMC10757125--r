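#' Fit a multivariate Cox proportional hazards model on module genes
#'
#' Covariates are z-scored (the training means and standard deviations are
#' stored so new samples can be scored consistently) and the partial
#' likelihood is maximized with Efron tie handling by default. Monotone
#' likelihood (perfect separation: some covariate orders all events before
#' all censorings) is detected and raised as an error naming the covariate;
#' `on_separation = "ridge"` instead refits with a small L2 penalty and
#' flags the model.
#'
#' @param survival_tbl survival tibble (`sample_id`, `time`, `event`).
#' @param covariates numeric matrix, samples in rows (rownames matching
#'   `sample_id`), one column per gene.
#' @param ties tie-handling method.
#' @param on_separation behaviour on monotone likelihood.
#' @param standardize z-score the covariates (the default; stabilizes the
#'   Newton iterations and puts coefficients on a per-SD scale). Set to
#'   `FALSE` to fit on the raw scale.
#' @return object of class `cox_model`: coefficients, covariance,
#'   convergence flag, training scaling, the underlying
#'   [survival::coxph()] fit.
#' @export
fit_cox <- function(survival_tbl, covariates, ties = c("efron", "breslow"),
                    on_separation = c("error", "ridge"), standardize = TRUE) {
  ties <- match.arg(ties)
  on_separation <- match.arg(on_separation)
  survival_tbl <- as_survival_table(survival_tbl)
  if (sum(survival_tbl$event) < 2) {
    stop_pononet("Cox fit needs at least 2 events", class = "pononet_validation_error")
  }
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  }
  if (!is.null(rownames(covariates))) {
    idx <- match(survival_tbl$sample_id, rownames(covariates))
    if (any(is.na(idx))) {
      stop_pononet("Survival samples missing from the covariate matrix",
        class = "pononet_validation_error"
      )
    }
    covariates <- covariates[idx, , drop = FALSE]
  } else if (nrow(covariates) != nrow(survival_tbl)) {
    stop_pononet("Covariate rows do not match survival samples",
      class = "pononet_validation_error"
    )
  }
  z <- if (standardize) {
    zscore_cols(covariates)
  } else {
    if (any(apply(covariates, 2, sd) == 0)) {
      stop_pononet("Constant covariate", class = "pononet_constant_covariate")
    }
    structure(covariates,
      center = setNames(rep(0, ncol(covariates)), colnames(covariates)),
      scale = setNames(rep(1, ncol(covariates)), colnames(covariates))
    )
  }
  dat <- data.frame(time = survival_tbl$time, event = survival_tbl$event, z)
  xnames <- colnames(z)
  fml <- stats::as.formula(
    paste("survival::Surv(time, event) ~", paste(xnames, collapse = " + "))
  )
  seps <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
      control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("infinite|converged before", msg)) {
        hits <- xnames[vapply(xnames, function(v) grepl(v, msg, fixed = TRUE), logical(1))]
        if (length(hits) == 0) {
          # coxph reports variable indices, e.g. "converged before variable 1,2"
          idx <- suppressWarnings(as.integer(strsplit(
            gsub("[^0-9,]", "", sub(".*variable", "", msg)), ","
          )[[1]]))
          idx <- idx[!is.na(idx) & idx >= 1 & idx <= length(xnames)]
          hits <- xnames[idx]
        }
        seps <<- union(seps, if (length(hits)) hits else xnames)
      }
      invokeRestart("muffleWarning")
    }
  )
  # a divergent coefficient without a warning is still separation
  seps <- union(seps, xnames[abs(stats::coef(fit)) > 15])
  ridge_used <- FALSE
  if (length(seps) > 0) {
    if (on_separation == "error") {
      stop_pononet(
        paste0(
          "Monotone partial likelihood (perfect separation) for covariate(s): ",
          paste(seps, collapse = ", ")
        ),
        class = "pononet_separation_error"
      )
    }
    inform(paste0(
      "Separation detected for ", paste(seps, collapse = ", "),
      "; refitting with a small ridge penalty"
    ))
    fml_r <- stats::as.formula(paste(
      "survival::Surv(time, event) ~ survival::ridge(",
      paste(xnames, collapse = ", "), ", theta = 0.1)"
    ))
    fit <- survival::coxph(fml_r, data = dat, ties = ties)
    ridge_used <- TRUE
  }
  beta <- stats::coef(fit)
  names(beta) <- xnames
  structure(
    list(
      genes = xnames,
      coefficients = beta,
      vcov = stats::vcov(fit),
      converged = length(seps) == 0 || ridge_used,
      separation = seps,
      ridge = ridge_used,
      ties = ties,
      center = attr(z, "center"),
      scale = attr(z, "scale"),
      n = nrow(dat),
      n_events = sum(dat$event),
      loglik = fit$loglik[length(fit$loglik)],
      fit = fit
    ),
    class = "cox_model"
  )
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf(
    "<cox_model> %d covariates, n = %d (%d events), ties = %s\n",
    length(x$genes), x$n, x$n_events, x$ties
  ))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
tidy.cox_model <- function(x, ...) {
  se <- sqrt(diag(as.matrix(x$vcov)))
  est <- unname(x$coefficients)
  tibble(
    term = x$genes,
    estimate = est,
    std.error = se,
    statistic = est / se,
    p.value = 2 * pnorm(abs(est / se), lower.tail = FALSE)
  )
}

#' @export
glance.cox_model <- function(x, ...) {
  tibble(
    n = x$n, n_events = x$n_events, logLik = x$loglik,
    converged = x$converged, ridge = x$ridge, ties = x$ties
  )
}

#' Per-sample prognostic index
#'
#' The linear predictor `PI = sum_g beta_g * x_g` over the model's genes,
#' with expression z-scored using the model's training statistics.
#'
#' @param model a `cox_model`.
#' @param covariates samples-by-genes matrix on the training scale.
#' @return named numeric vector of prognostic indices.
#' @export
prognostic_index <- function(model, covariates) {
  covariates <- as.matrix(covariates)
  if (!setequal(colnames(covariates), model$genes)) {
    stop_pononet("Covariate genes do not match the fitted model",
      class = "pononet_validation_error"
    )
  }
  covariates <- covariates[, model$genes, drop = FALSE]
  z <- sweep(sweep(covariates, 2, model$center, "-"), 2, model$scale, "/")
  drop(z %*% model$coefficients)
}

#' Split samples into low- and high-risk groups by prognostic index
#'
#' `"median"` assigns high risk to PI strictly above the median (ties go to
#' low risk). `"optimal"` scans candidate splits between the 20th and 80th
#' PI percentiles and picks the one maximizing the log-rank statistic; the
#' resulting log-rank p-value is optimistically biased and is flagged as
#' such wherever it is reported.
#'
#' @param pi_values numeric prognostic indices.
#' @param method split rule.
#' @param survival_tbl survival tibble, required for `"optimal"` (rows in
#'   the same order as `pi_values`).
#' @return factor with levels `low`, `high` and attributes `split_value`
#'   and `method`.
#' @export
stratify_risk <- function(pi_values, method = c("median", "optimal"),
                          survival_tbl = NULL) {
  method <- match.arg(method)
  if (length(pi_values) < 2) {
    stop_pononet("Need at least 2 samples to stratify",
      class = "pononet_validation_error"
    )
  }
  if (length(unique(pi_values)) == 1) {
    stop_pononet("All prognostic indices identical; cannot stratify",
      class = "pononet_validation_error"
    )
  }
  if (method == "median") {
    split <- median(pi_values)
  } else {
    if (is.null(survival_tbl)) {
      stop_pononet("Optimal split needs the survival table",
        class = "pononet_validation_error"
      )
    }
    survival_tbl <- as_survival_table(survival_tbl)
    lo <- quantile(pi_values, 0.2)
    hi <- quantile(pi_values, 0.8)
    cands <- sort(unique(pi_values))
    cands <- cands[cands >= lo & cands <= hi & cands < max(pi_values)]
    if (length(cands) == 0) cands <- median(pi_values)
    best <- -Inf
    split <- cands[1]
    for (s in cands) {
      grp <- pi_values > s
      if (length(unique(grp)) < 2) next
      st <- tryCatch(
        logrank_test(survival_tbl$time, survival_tbl$event, grp)$statistic,
        error = function(e) NA_real_
      )
      if (is.finite(st) && st > best) {
        best <- st
        split <- s
      }
    }
  }
  out <- factor(ifelse(pi_values > split, "high", "low"),
    levels = c("low", "high"))
  attr(out, "split_value") <- unname(split)
  attr(out, "method") <- method
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard convention: censorings at an event time are processed after the
#' events at that time. The returned step function starts at S(0) = 1 and
#' is right-continuous and non-increasing.
#'
#' @param time event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @return tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, beginning with the (0, 1) anchor row.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) {
    stop_pononet("Empty survival input", class = "pononet_validation_error")
  }
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  tibble(
    time = c(0, sf$time),
    n_risk = c(length(time), sf$n.risk),
    n_event = c(0, sf$n.event),
    n_censor = c(0, sf$n.censor),
    survival = c(1, sf$surv)
  )
}

#' Two-group log-rank test
#'
#' Standard chi-square log-rank statistic with 1 degree of freedom, using
#' the hypergeometric variance at each distinct event time.
#'
#' @param time,event survival data.
#' @param group two-level grouping vector.
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop_pononet("Log-rank test needs exactly two non-empty groups",
      class = "pononet_validation_error"
    )
  }
  if (sum(event) < 1) {
    stop_pononet("Log-rank test needs at least one event",
      class = "pononet_validation_error"
    )
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  v <- if (is.matrix(sd_$var)) sd_$var[1, 1] else sd_$var[1]
  if (!is.finite(sd_$chisq) || v <= 0) {
    stop_pononet("Degenerate log-rank test: zero variance",
      class = "pononet_validation_error"
    )
  }
  list(
    statistic = unname(sd_$chisq),
    df = 1,
    p = unname(pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
  )
}

#' Hazard ratio between risk groups
#'
#' Univariate Cox model on the high-group indicator: HR = exp(beta) with a
#' Wald 95% confidence interval and p-value. Under separation the HR is
#' still reported but flagged, with an unbounded confidence interval.
#'
#' @param time,event survival data.
#' @param group factor with levels `low`, `high` (or any two levels, the
#'   second being the numerator).
#' @return list with `hr`, `ci` (length-2), `p`, `separation` flag.
#' @export
group_hazard_ratio <- function(time, event, group) {
  group <- as.factor(group)
  ind <- as.numeric(group == levels(group)[2])
  sep <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ ind),
    warning = function(w) {
      if (grepl("infinite|converged before", conditionMessage(w))) sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(stats::vcov(fit)[1, 1])
  if (sep || abs(beta) > 15) {
    return(list(
      hr = exp(beta), ci = c(0, Inf), p = NA_real_, separation = TRUE
    ))
  }
  list(
    hr = exp(beta),
    ci = exp(beta + c(-1, 1) * qnorm(0.975) * se),
    p = unname(2 * pnorm(abs(beta / se), lower.tail = FALSE)),
    separation = FALSE
  )
}

#' Prognostic evaluation of a gene module
#'
#' The full risk-score workflow for a candidate module: z-score the module
#' genes, fit a joint Cox model, compute each sample's prognostic index,
#' split samples into low- and high-risk groups, and summarize the groups
#' with Kaplan-Meier curves, the log-rank test and the high-versus-low
#' hazard ratio.
#'
#' @param expression expression dataset containing the module genes.
#' @param survival_tbl survival tibble whose `sample_id`s appear among the
#'   expression samples.
#' @param genes module gene symbols.
#' @param split risk-group split rule (see [stratify_risk()]).
#' @param ties Cox tie handling.
#' @param on_separation see [fit_cox()].
#' @return object of class `prognostic_result`: the fitted `cox_model`, a
#'   per-sample tibble (`sample_id`, `pi`, `group`), per-group KM curves,
#'   the log-rank test and the hazard ratio.
#' @export
evaluate_prognosis <- function(expression, survival_tbl, genes,
                               split = c("median", "optimal"),
                               ties = c("efron", "breslow"),
                               on_separation = c("error", "ridge")) {
  split <- match.arg(split)
  survival_tbl <- as_survival_table(survival_tbl)
  m <- expr_matrix(expression)
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0) {
    stop_pononet(
      paste0("Module gene(s) absent from expression: ",
        paste(missing, collapse = ", ")),
      class = "pononet_validation_error"
    )
  }
  missing_s <- setdiff(survival_tbl$sample_id, colnames(m))
  if (length(missing_s) > 0) {
    stop_pononet(
      paste0("Survival sample(s) absent from expression: ",
        paste(head(missing_s, 5), collapse = ", ")),
      class = "pononet_validation_error"
    )
  }
  x <- t(m[genes, survival_tbl$sample_id, drop = FALSE])
  model <- fit_cox(survival_tbl, x, ties = ties, on_separation = on_separation)
  pi_values <- prognostic_index(model, x)
  groups <- stratify_risk(pi_values, method = split, survival_tbl = survival_tbl)
  samples <- tibble(
    sample_id = survival_tbl$sample_id,
    pi = unname(pi_values),
    group = groups
  )
  km <- bind_rows(lapply(levels(groups), function(g) {
    sel <- groups == g
    mutate(
      km_estimate(survival_tbl$time[sel], survival_tbl$event[sel]),
      group = g, .before = 1
    )
  }))
  lr <- logrank_test(survival_tbl$time, survival_tbl$event, groups)
  hr <- group_hazard_ratio(survival_tbl$time, survival_tbl$event, groups)
  structure(
    list(
      genes = genes,
      model = model,
      samples = samples,
      split = list(
        method = split,
        value = attr(groups, "split_value"),
        optimistic_p = split == "optimal"
      ),
      km = km,
      logrank = lr,
      hazard_ratio = hr
    ),
    class = "prognostic_result"
  )
}

#' @export
print.prognostic_result <- function(x, ...) {
  cat(sprintf(
    "<prognostic_result> %d genes; %s split; log-rank p = %.3g%s; HR = %.3g [%.3g, %.3g]\n",
    length(x$genes), x$split$method, x$logrank$p,
    if (x$split$optimistic_p) " (optimistic: optimized cutpoint)" else "",
    x$hazard_ratio$hr, x$hazard_ratio$ci[1], x$hazard_ratio$ci[2]
  ))
  invisible(x)
}

#' @export
tidy.prognostic_result <- function(x, ...) {
  x$samples |>
    group_by(group = .data$group) |>
    summarise(
      n = dplyr::n(),
      mean_pi = mean(.data$pi),
      .groups = "drop"
    )
}

#' @export
glance.prognostic_result <- function(x, ...) {
  tibble(
    n = nrow(x$samples),
    n_events = x$model$n_events,
    n_genes = length(x$genes),
    split_method = x$split$method,
    logrank_statistic = x$logrank$statistic,
    logrank_p = x$logrank$p,
    optimistic_p = x$split$optimistic_p,
    hazard_ratio = x$hazard_ratio$hr,
    hr_low = x$hazard_ratio$ci[1],
    hr_high = x$hazard_ratio$ci[2]
  )
}
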