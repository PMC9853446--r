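# Brute-force oracles, kept independent of the implementation paths they
# check.

# BH step-up by the textbook recipe: sort, scale by m/rank, enforce
# monotonicity from the largest p downwards, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in seq(m, 1)) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Mean-rank normalization score computed from first principles.
oracle_score <- function(expr, signature) {
  r <- rank(expr, ties.method = "average")
  sig <- intersect(signature, names(expr))
  ns <- length(sig)
  n <- length(expr)
  (mean(r[sig]) - (ns + 1) / 2) / (n - ns)
}

# Exclusive membership-pattern counts by exhaustive per-gene enumeration.
oracle_patterns <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  pat <- vapply(universe, function(g) {
    paste(as.integer(vapply(sets, function(s) g %in% s, logical(1))),
          collapse = "")
  }, character(1))
  table(pat)
}

# Union-DEG criterion via per-dataset set intersection then union.
oracle_union_degs <- function(pairwise) {
  sort(unique(unlist(lapply(pairwise, function(ds) Reduce(intersect, ds)))))
}

# Hand product-limit estimator over unique event times.
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# One-covariate Cox partial likelihood maximised by grid/golden search
# (Breslow form; equals Efron when there are no tied event times).
oracle_cox_beta <- function(time, event, x) {
  loglik <- function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }
  stats::optimize(loglik, c(-10, 10), maximum = TRUE, tol = 1e-9)$maximum
}

# Exhaustive hypergeometric upper-tail sum from binomial coefficients.
oracle_hyper_tail <- function(x, term_size, universe_size, deg_size) {
  js <- x:min(term_size, deg_size)
  sum(choose(term_size, js) * choose(universe_size - term_size, deg_size - js)) /
    choose(universe_size, deg_size)
}
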