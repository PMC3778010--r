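# Independent brute-force oracles used to validate the package's statistics.
# Each is written from the textbook definition, deliberately avoiding the
# code paths (and where possible the base functions) the implementation uses.

# Spearman correlation from first principles: average ranks built by sorting,
# then the Pearson product-moment formula applied to the ranks.
oracle_rank <- function(x) {
  n <- length(x)
  o <- order(x)
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  mx <- sum(rx) / length(rx); my <- sum(ry) / length(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# Exact two-sided rank-sum p-value by enumeration of all label assignments.
# The statistic for an assignment is computed by pairwise comparison counts
# (Mann-Whitney U) converted to a rank sum, a different route from ranking
# the pooled vector.
oracle_ranksum_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); n1 <- length(x)
  stat_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    u <- 0
    for (ai in a) u <- u + sum(ai > b) + 0.5 * sum(ai == b)
    u + n1 * (n1 + 1) / 2
  }
  W_obs <- stat_of(seq_len(n1))
  combos <- utils::combn(n, n1)
  stats <- apply(combos, 2L, stat_of)
  tol <- 1e-9
  pl <- mean(stats <= W_obs + tol)
  pu <- mean(stats >= W_obs - tol)
  min(1, 2 * min(pl, pu))
}

# Upper-tail hypergeometric probability by enumeration over all draws of
# size n from a reference of size N containing K special elements.
oracle_hyper_upper <- function(k, K, N, n) {
  combos <- utils::combn(N, n)
  special <- seq_len(K)
  overlaps <- apply(combos, 2L, function(idx) sum(idx %in% special))
  mean(overlaps >= k)
}

# Two-group logrank chi-square from an explicit risk table walk.
oracle_logrank_chisq <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2L)
  g1 <- unique(group)[1L]
  times <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & group == g1)
    d_t <- sum(time == t & event == 1)
    d1_t <- sum(time == t & event == 1 & group == g1)
    O1 <- O1 + d1_t
    E1 <- E1 + d_t * n1_t / n_t
    if (n_t > 1)
      V <- V + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
  }
  if (V <= 0) return(NA_real_)
  (O1 - E1)^2 / V
}

# Exhaustive 1-D two-cluster WSS minimization (compares every threshold by
# direct recomputation).
oracle_two_means_wss <- function(scores) {
  s <- sort(scores)
  n <- length(s)
  best <- Inf; best_cut <- NA_integer_
  for (k in seq_len(n - 1L)) {
    a <- s[1:k]; b <- s[(k + 1L):n]
    wss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (wss < best) { best <- wss; best_cut <- k }
  }
  list(wss = best, cut = best_cut, low = s[seq_len(best_cut)])
}

# Small helpers for building fixtures in code.
make_panel <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_panel(values)
}

make_pi_table <- function(gene_ids, pi, p_value = rep(0.5, length(pi)),
                          method = "spearman", n = 60L) {
  tab <- data.frame(gene_id = gene_ids, pi = pi, p_value = p_value,
                    flagged = is.na(pi), stringsAsFactors = FALSE)
  class(tab) <- c("pi_table", "data.frame")
  attr(tab, "method") <- method
  attr(tab, "n") <- n
  attr(tab, "normalized") <- FALSE
  tab
}

quiet <- function(expr) suppressMessages(expr)
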