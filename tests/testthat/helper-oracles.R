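# Independent oracles, deliberately written with different algorithms than
# the package implementation.

# AUROC by exhaustive pairwise comparison: fraction of (set, background)
# pairs the set gene wins, plus one half per tie.
oracle_auroc <- function(scores, set_genes) {
  s <- scores[names(scores) %in% set_genes]
  b <- scores[!(names(scores) %in% set_genes)]
  wins <- outer(s, b, ">") + 0.5 * outer(s, b, "==")
  mean(wins)
}

# Mann-Whitney tail probabilities by full enumeration of all labelings of
# the pooled values.
oracle_mwu <- function(x_set, x_bg) {
  pooled <- c(x_set, x_bg)
  n1 <- length(x_set)
  r <- rank(pooled, ties.method = "average")
  idx <- utils::combn(length(pooled), n1)
  us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  p_ge <- mean(us >= u_obs - eps)
  p_le <- mean(us <= u_obs + eps)
  list(u = u_obs, p_greater = p_ge, p_less = p_le,
       p_two = min(1, 2 * min(p_ge, p_le)))
}

# Benjamini-Hochberg by the textbook step-up definition:
# adj_(i) = min_{j >= i} min(1, m/j * p_(j)) over sorted p.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  adj <- numeric(m)
  running <- Inf
  for (j in m:1) {
    running <- min(running, m / j * sp[j])
    adj[j] <- min(1, running)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric P(X >= k) by log-binomial summation.
oracle_hyper_tail <- function(k, N, K, n) {
  if (k <= 0) return(1)
  js <- k:min(K, n)
  js <- js[n - js <= N - K]
  if (!length(js)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# Fisher's method closed form.
oracle_fisher <- function(p) {
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}
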