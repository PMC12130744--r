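# Independent oracles, written directly from the model definition and kept
# free of the package's matrix builders and forward pass.

# Exhaustive latent-path likelihood: sums the probability of every state path
# (N, L, H, D coded 1..4) over the occasions from first capture to the end.
# Inputs are plain probability-scale parameters.
oracle_history_loglik <- function(history, phi, psi, p, gamma = 1, pi_sb,
                                  measure = "size") {
  T <- length(history)
  t0 <- which(history != 0)[1]
  trans_pr <- function(s1, s2) {
    if (s1 == 4) return(as.numeric(s2 == 4))
    if (s2 == 4) return(1 - phi[s1])
    phi[s1] * psi[s1, s2]
  }
  event_pr <- function(s, e, first) {
    pc <- if (first) 1 else p
    if (s == 4) return(as.numeric(e == 0))
    if (measure == "size") {
      if (e == 0) return(1 - pc)
      return(if (e == s) pc else 0)
    }
    if (e == 0) return(1 - pc)
    if (s == 1) return(if (e == 1) pc else 0)
    if (e == s) return(pc * gamma)
    if (e == 4) return(pc * (1 - gamma))
    0
  }
  init <- c(1 - pi_sb, pi_sb / 2, pi_sb / 2, 0)
  nt <- T - t0 + 1
  paths <- as.matrix(expand.grid(rep(list(1:4), nt)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    pr <- init[path[1]] * event_pr(path[1], history[t0], TRUE)
    if (nt > 1) for (k in 2:nt) {
      if (pr == 0) break
      pr <- pr * trans_pr(path[k - 1], path[k]) *
        event_pr(path[k], history[t0 + k - 1], FALSE)
    }
    total <- total + pr
  }
  log(total)
}

# Closed-form SMA slope oracle: sign of the correlation times the ratio of
# standard deviations.
oracle_sma <- function(x, y) sign(cor(x, y)) * sd(y) / sd(x)

# Random valid history over T occasions for a given measure: a random first
# capture followed by random events, never assigning nonzero events that the
# alphabet forbids.
random_history <- function(T, measure) {
  codes <- if (measure == "mass") 0:4 else 0:3
  t0 <- sample.int(T, 1)
  hist <- integer(T)
  hist[t0] <- sample(codes[-1], 1)
  if (t0 < T)
    hist[(t0 + 1):T] <- sample(codes, T - t0, replace = TRUE)
  hist
}

# Probability-scale parameter list for a random theta under a given spec
# (single-stratum specs only; the bijection itself is tested separately).
real_params <- function(spec, theta) {
  r <- theta_to_real(spec, theta)
  list(phi = unname(r$strata[[1]]$phi), psi = unname(r$strata[[1]]$psi),
       p = unname(r$p[[1]]), gamma = r$gamma, pi = r$pi)
}
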