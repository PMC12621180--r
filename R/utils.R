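# internal helpers shared across modules

# Evaluate an expression with a temporarily seeded RNG, restoring any
# pre-existing .Random.seed afterwards so library calls never perturb the
# caller's stream.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  force(expr)
}

# Derive a per-stage 32-bit seed from a master seed.
deriveSeed <- function(seed, stage) {
  (as.double(seed) * 7919 + stage * 104729) %% 2147483647
}

# Sliding-window mean and sd over a vector (window w frames, step 1),
# computed from prefix sums. Returns list(mean, sd) of length n - w + 1.
slidingStats <- function(x, w) {
  n <- length(x)
  s1 <- cumsum(x)
  s2 <- cumsum(x * x)
  i <- seq_len(n - w + 1L)
  sw <- s1[i + w - 1L] - c(0, s1)[i]
  sw2 <- s2[i + w - 1L] - c(0, s2)[i]
  m <- sw / w
  v <- pmax(0, (sw2 - sw * sw / w) / (w - 1L))
  list(mean = m, sd = sqrt(v))
}

# Exponentially modified Gaussian shape, numerically stable for small tau
# (Gaussian limit). Unnormalized: the Gaussian(mu, sigma) convolved with a
# unit-area exponential decay of time constant tau, up to a constant factor.
# log h(t) = sigma^2/(2 tau^2) - (t - mu)/tau + log Phi((t - mu)/sigma - sigma/tau)
emgShape <- function(t, mu, sigma, tau) {
  z <- (t - mu) / sigma - sigma / tau
  lg <- sigma^2 / (2 * tau^2) - (t - mu) / tau +
    stats::pnorm(z, log.p = TRUE)
  exp(lg)
}

# EMG scaled to a given peak amplitude; the peak location/height are found
# on a fine grid over the support.
emgPeakInfo <- function(mu, sigma, tau, dt = NULL) {
  if (is.null(dt)) dt <- min(sigma, tau) / 20
  tg <- seq(mu - 5 * sigma, mu + 6 * tau + 5 * sigma, by = dt)
  y <- emgShape(tg, mu, sigma, tau)
  i <- which.max(y)
  list(peakTime = tg[i], peakValue = y[i])
}

# Four-parameter logistic on log10 concentration.
fourPL <- function(logC, bottom, top, logEC50, hill) {
  bottom + (top - bottom) / (1 + 10^((logEC50 - logC) * hill))
}

# Bell (log-Gaussian) curve on log10 concentration.
bellCurve <- function(logC, base, height, center, width) {
  base + height * exp(-(logC - center)^2 / (2 * width^2))
}

# igraph view of the interior-node induced subgraph (or the full graph).
asIgraph <- function(graph, interiorOnly = TRUE) {
  A <- adjacencyMatrix(graph)
  if (interiorOnly) {
    keep <- interiorCells(graph)
    A <- A[keep, keep, drop = FALSE]
  }
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# Empirical percentile of an observed value in a null sample (midrank).
empiricalPercentile <- function(observed, null) {
  100 * (sum(null < observed) + 0.5 * sum(null == observed)) / length(null)
}

# Assemble the standard permutation-null record used across modules.
nullRecord <- function(metric, observed, null) {
  list(metric = metric, observed = observed, null = null,
       nullMean = mean(null), nullSd = stats::sd(null),
       percentile = empiricalPercentile(observed, null))
}
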