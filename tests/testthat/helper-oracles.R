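# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles, by enumeration or the naive
# formula, and never share code with the package implementation.

# Jensen-Shannon distance between two probability vectors, scalar formula.
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / b[i])
    s
  }
  unname(sqrt(0.5 * kl(p, m) + 0.5 * kl(q, m)))
}

# Optimal k-medoid objective by exhaustive search over all medoid sets.
oracle_pam_objective <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    obj <- sum(apply(D[, med, drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

# Two-sided Fisher p by full hypergeometric enumeration (point-probability
# convention), computed from choose() directly.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p <- exp(logp)
  obs <- p[support == a]
  sum(p[p <= obs * (1 + 1e-7)])
}

# AUC by the explicit pairwise comparison loop (half credit for ties).
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Silhouette widths from the definition (a = mean within, b = min of mean to
# other clusters); singleton clusters take 0.
oracle_silhouette <- function(D, labels) {
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# Mutual information (nats) from explicit nested-loop contingency counts.
oracle_mi <- function(a, b) {
  ua <- unique(a); ub <- unique(b); n <- length(a)
  s <- 0
  for (x in ua) for (y in ub) {
    nxy <- sum(a == x & b == y)
    if (nxy > 0)
      s <- s + (nxy / n) * log((nxy / n) / ((sum(a == x) / n) * (sum(b == y) / n)))
  }
  s
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (pos in seq_len(n))
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# Mantel r over all permutations of one matrix; upper-tail exhaustive p.
oracle_mantel <- function(Dm, Dp) {
  n <- nrow(Dm)
  lower <- lower.tri(Dm)
  r_obs <- cor(Dm[lower], Dp[lower])
  rs <- vapply(all_perms(n), function(p) cor(Dm[lower], Dp[p, p][lower]),
               numeric(1))
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# Small random count table with lineaged taxa, for IO/property tests.
random_count_table <- function(seed, n = 5, t = 6) {
  set.seed(seed)
  lin <- paste0("Bacteria;P", seq_len(t), ";C", seq_len(t), ";O", seq_len(t),
                ";F", seq_len(t), ";G", seq_len(t))
  m <- matrix(rpois(n * t, 40) + 1, n, t,
              dimnames = list(paste0("R", seq_len(n)), NULL))
  abundance_table(m, lin, mode = "counts")
}

expect_tables_equal <- function(x, y) {
  expect_equal(x$mode, y$mode)
  expect_equal(sort(colnames(x$values)), sort(colnames(y$values)))
  expect_equal(x$values[, colnames(x$values)], y$values[, colnames(x$values)],
               tolerance = 1e-10)
}
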