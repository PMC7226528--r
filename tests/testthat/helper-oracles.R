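# Independent oracles for the survival operations. These are deliberately
# naive, direct transcriptions of the textbook definitions; they never call
# the survival package.

# product-limit estimator: data.frame(time, surv) at each distinct event time
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (k in seq_along(ts)) {
    t <- ts[k]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out$surv[k] <- s
  }
  out
}

km_oracle_at <- function(time, event, t) {
  or <- km_oracle(time, event)
  steps <- or$surv[or$time <= t]
  if (length(steps) == 0) 1 else steps[length(steps)]
}

# two-group log-rank: sum of observed-minus-expected in group 1 over event
# times, squared over the summed hypergeometric variance
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L     # 0/1
  ts <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1L)
    U <- U + d1 - d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# Efron partial log-likelihood for a single binary covariate x in {0,1}
efron_loglik <- function(beta, time, event, x) {
  ts <- sort(unique(time[event == 1]))
  ll <- 0
  for (t in ts) {
    risk <- time >= t
    dead <- time == t & event == 1
    d <- sum(dead)
    s_risk <- sum(exp(beta * x[risk]))
    s_dead <- sum(exp(beta * x[dead]))
    ll <- ll + beta * sum(x[dead])
    for (l in seq_len(d) - 1L)
      ll <- ll - log(s_risk - (l / d) * s_dead)
  }
  ll
}

# brute-force maximizer of the Efron partial likelihood on a fine grid
grid_cox <- function(time, event, x, lo = -4, hi = 4, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, efron_loglik, numeric(1), time = time, event = event,
               x = x)
  grid[which.max(ll)]
}

# two-group toy survival fixtures; all but the last contain tied event times
toy_surv_fixtures <- function() {
  list(
    tied1 = data.frame(time = c(5, 5, 8, 8, 8, 12, 15, 15, 20, 25),
                       event = c(1, 1, 1, 0, 1, 1, 1, 1, 0, 1),
                       group = rep(c("a", "b"), 5)),
    tied2 = data.frame(time = c(3, 3, 3, 6, 6, 9, 9, 12, 12, 14, 14, 20),
                       event = c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0, 1, 0),
                       group = rep(c("a", "a", "b"), 4)),
    tied3 = data.frame(time = c(2, 2, 4, 4, 7, 7, 7, 10, 13, 13),
                       event = c(1, 0, 1, 1, 1, 1, 0, 1, 1, 1),
                       group = c("a", "b", "a", "b", "a", "b", "a", "b",
                                 "a", "b")),
    tied4 = data.frame(time = c(1, 1, 1, 1, 5, 5, 5, 9, 9, 9, 11, 11),
                       event = c(1, 1, 1, 0, 1, 0, 1, 1, 1, 0, 1, 1),
                       group = rep(c("a", "b"), 6)),
    tied5 = data.frame(time = c(6, 6, 6, 8, 8, 10, 10, 12, 12, 15),
                       event = c(1, 0, 1, 1, 0, 1, 1, 1, 0, 1),
                       group = c("a", "a", "b", "b", "a", "b", "a", "b",
                                 "a", "b")),
    untied = data.frame(time = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                        event = c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1),
                        group = rep(c("a", "b"), 5)))
}
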