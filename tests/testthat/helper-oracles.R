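# Independent oracles used to cross-check the package's computations.
# Each is a deliberately naive implementation (enumeration, grid search,
# closed form) that shares no code with the functions it checks.

# Betweenness by exhaustive shortest-path counting (Floyd-Warshall style):
# sigma[s,t] = number of shortest s-t paths; a vertex v lies on
# sigma[s,v] * sigma[v,t] of them when d[s,v] + d[v,t] == d[s,t].
betweenness_exhaustive <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  # path counts layer by layer outward from each source
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (dist in seq_len(n)) {
      for (t in which(d[s, ] == dist)) {
        preds <- which(adj[, t] == 1 & d[s, ] == dist - 1)
        sigma[s, t] <- sum(sigma[s, preds])
      }
    }
  }
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  b
}

# Hand-written Cox partial likelihood for untied, fully observed data,
# maximized by 1-D grid search + golden refinement over beta.
cox_loglik_1d <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  x <- x[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

cox_grid_mle <- function(time, event, x, lower = -10, upper = 10) {
  stats::optimize(function(b) cox_loglik_1d(b, time, event, x),
    c(lower, upper),
    maximum = TRUE, tol = 1e-10
  )$maximum
}

# Exact hypergeometric upper tail by enumerating all C(N, n) draws.
hyper_tail_enumerate <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # WLOG set members are 1..K
  mean(hits >= k)
}

# Pooled two-sample t closed form.
pooled_t <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(abs(t), n1 + n2 - 2, lower.tail = FALSE))
}

# Random simple undirected graph as an adjacency matrix.
random_adjacency <- function(n, p_edge = 0.4) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1
    }
  }
  adj
}
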