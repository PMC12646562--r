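# Independent oracles: brute-force definitions kept deliberately naive and
# separate from the package's fast implementations.

# pairwise AUC with half-credit for ties
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# exhaustive Youden search over all midpoints and outside sentinels
youden_brute <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
            u[length(u)] + 1)
  best_J <- -Inf
  best_t <- NA
  for (t in cand) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    J <- sens + spec - 1
    if (J > best_J + 1e-12) {
      best_J <- J
      best_t <- t
    }
  }
  list(cutoff = best_t, J = best_J)
}

# DeLong single-AUC variance from explicitly looped structural components
delong_var_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos)
  n <- length(neg)
  v10 <- numeric(m)
  for (i in seq_len(m)) {
    s <- 0
    for (j in seq_len(n)) s <- s + (pos[i] > neg[j]) + 0.5 * (pos[i] == neg[j])
    v10[i] <- s / n
  }
  v01 <- numeric(n)
  for (j in seq_len(n)) {
    s <- 0
    for (i in seq_len(m)) s <- s + (pos[i] > neg[j]) + 0.5 * (pos[i] == neg[j])
    v01[j] <- s / m
  }
  (if (m > 1) var(v10) else 0) / m + (if (n > 1) var(v01) else 0) / n
}

# closed-form Firth odds ratio for a saturated 2x2 table:
# Jeffreys penalty == adding 1/2 to each cell
firth_or_2x2 <- function(a, b, c, d) ((a + 0.5) * (d + 0.5)) /
  ((b + 0.5) * (c + 0.5))

# expand a 2x2 table (a = events|x=1, b = nonevents|x=1, c = events|x=0,
# d = nonevents|x=0) into design + outcome
expand_2x2 <- function(a, b, c, d) {
  x <- c(rep(1, a + b), rep(0, c + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  list(X = cbind(1, x = x), y = y)
}

# independently written penalized log-likelihood (for grid maximization)
pll_indep <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  W <- diag(p * (1 - p), nrow = length(p))
  info <- t(X) %*% W %*% X
  sum(y * log(p) + (1 - y) * log(1 - p)) + 0.5 * log(det(info))
}

# small fully populated valid cohort, built in code
make_tiny_cohort <- function(n = 3) {
  gen <- generate_cohort(default_cohort_config(
    n_total = max(n, 8), n_shunted = max(4, n), n_nonresponders = 2),
    seed = 7)
  gen$cohort[seq_len(n), , drop = FALSE]
}
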