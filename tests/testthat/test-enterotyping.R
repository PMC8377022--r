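relative_table <- function(seed, n = 6, t = 5) {
  set.seed(seed)
  m <- matrix(rgamma(n * t, 1), n, t, dimnames = list(paste0("R", 1:n), NULL))
  abundance_table(m / rowSums(m), paste0("Bacteria;P;C;O;F;G", seq_len(t)),
                  mode = "relative")
}

test_that("JSD matches the scalar formula and is a bounded metric", {
  two <- abundance_table(rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0)),
                         c("Bacteria;X", "Bacteria;Y"), mode = "relative")
  D <- as.matrix(jsd_matrix(two))
  expect_equal(D["a", "c"], 0)
  expect_equal(D["a", "b"], 1)  # disjoint supports are maximally distant

  p <- c(0.5, 0.5, 0); q <- c(0.25, 0.25, 0.5)
  tab <- abundance_table(rbind(s1 = p, s2 = q),
                         paste0("Bacteria;G", 1:3), mode = "relative")
  expect_equal(as.matrix(jsd_matrix(tab))[1, 2], oracle_jsd(p, q),
               tolerance = 1e-12)

  for (seed in 1:10) {
    tab <- relative_table(seed)
    D <- as.matrix(jsd_matrix(tab))
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0 & D <= 1 + 1e-12))
    n <- nrow(D)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
    # entry-wise agreement with the scalar oracle
    expect_equal(D[1, 2], oracle_jsd(tab$values[1, ], tab$values[2, ]),
                 tolerance = 1e-12)
  }

  notnorm <- tab; notnorm$values[1, ] <- notnorm$values[1, ] * 2
  expect_error(jsd_matrix(notnorm), "sum to 1")
})

test_that("PAM recovers separated pairs, handles k = n, matches exhaustive search", {
  pts <- c(0, 0.1, 10, 10.1)
  d <- dist(pts)
  attr(d, "Labels") <- paste0("s", 1:4)
  p <- pam_cluster(d, 2)
  expect_equal(unname(p$labels[1]), unname(p$labels[2]))
  expect_equal(unname(p$labels[3]), unname(p$labels[4]))

  pn <- pam_cluster(d, 4)
  expect_equal(pn$objective, 0)
  expect_equal(sort(pn$medoids), paste0("s", 1:4))
  expect_error(pam_cluster(d, 5), "between 1 and")

  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:8, 1)
    D <- as.matrix(dist(matrix(runif(n * 2), n)))
    d <- as.dist(D)
    for (k in 1:n)
      expect_equal(pam_cluster(d, k)$objective, oracle_pam_objective(D, k),
                   tolerance = 1e-10)
  }
})

test_that("CH index: formula oracle, structure ordering, scale and relabel invariance", {
  set.seed(42)
  X <- rbind(matrix(rnorm(10, 0), 5), matrix(rnorm(10, 6), 5))
  d <- dist(X)
  lab <- rep(1:2, each = 5)
  # direct two-line B/W computation on the configuration itself
  grand <- colMeans(X)
  W <- sum(sweep(X[1:5, ], 2, colMeans(X[1:5, ]))^2) +
    sum(sweep(X[6:10, ], 2, colMeans(X[6:10, ]))^2)
  B <- 5 * sum((colMeans(X[1:5, ]) - grand)^2) +
    5 * sum((colMeans(X[6:10, ]) - grand)^2)
  expect_equal(ch_index(d, lab), (B / 1) / (W / 8), tolerance = 1e-6)

  blob <- dist(matrix(runif(20), 10))
  split_blob <- rep(1:2, 5)
  expect_gt(ch_index(d, lab), ch_index(blob, split_blob))

  expect_equal(ch_index(d * 3, lab), ch_index(d, lab), tolerance = 1e-6)
  relab <- c(2, 1)[lab]
  expect_equal(ch_index(d, relab), ch_index(d, lab))
  expect_error(ch_index(d, rep(1, 10)), "undefined")
})

test_that("silhouette matches the hand definition; singletons take zero", {
  set.seed(7)
  X <- matrix(runif(12), 6)
  D <- as.matrix(dist(X))
  d <- as.dist(D)
  lab <- c(1, 1, 2, 2, 2, 3)  # cluster 3 is a singleton
  s <- silhouette_width(d, lab)
  expect_equal(unname(s$widths), oracle_silhouette(D, lab), tolerance = 1e-10)
  expect_equal(unname(s$widths[6]), 0)

  pairs <- dist(c(0, 0.01, 5, 5.01))
  sp <- silhouette_width(pairs, c(1, 1, 2, 2))
  expect_gt(sp$mean, 0.99)

  relab <- c(2, 3, 1)[lab]
  expect_equal(silhouette_width(d, relab)$mean, s$mean)
})

test_that("select_k reports one row per k and recovers planted cluster counts", {
  coh <- generate_cohort(cohort_config(), seed = 5)
  d <- jsd_matrix(aggregate_to_rank(to_relative(coh$abundance), "genus"))
  tab <- suppressMessages(select_k(d, 2:10))
  expect_equal(tab$k, 2:10)
  expect_equal(attr(tab, "best_k"), 2)

  # three well-separated synthetic communities, each owned by its own genus
  set.seed(9)
  n3 <- 36
  grp <- rep(1:3, each = 12)
  m <- matrix(rgamma(n3 * 6, 0.4), n3, 6)
  for (i in seq_len(n3)) m[i, grp[i]] <- m[i, grp[i]] + 25
  tab3 <- abundance_table(m / rowSums(m), paste0("Bacteria;P;C;O;F;G", 1:6),
                          mode = "relative")
  d3 <- jsd_matrix(tab3)
  k3 <- suppressMessages(select_k(d3, 2:8))
  expect_equal(attr(k3, "best_k"), 3)
})

test_that("PCoA reproduces planar geometry and orthogonality", {
  set.seed(11)
  pts <- matrix(runif(10), 5)
  emb <- pcoa(dist(pts), 2)
  # Procrustes: distances derived from the embedding match the originals
  expect_equal(as.vector(dist(emb$coordinates)), as.vector(dist(pts)),
               tolerance = 1e-6)

  eq3 <- as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  emb3 <- pcoa(eq3, 2)
  expect_equal(emb3$eigenvalues[1], emb3$eigenvalues[2], tolerance = 1e-9)

  coh <- relative_table(3, n = 8, t = 5)
  e <- pcoa(jsd_matrix(coh), 3)
  G <- crossprod(e$coordinates)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_true(all(e$eigenvalues >= 0))

  expect_warning(pcoa(dist(c(0, 1, 2)), 2), "truncating")
})

test_that("enterotype() names E1 by Bacteroides dominance", {
  coh <- generate_cohort(cohort_config(), seed = 8)
  genus <- aggregate_to_rank(to_relative(coh$abundance), "genus")
  fit <- suppressMessages(enterotype(genus))
  expect_s3_class(fit, "enterotype_fit")
  expect_equal(fit$k, 2)
  m_e1 <- mean(genus$values[fit$labels == "ICU_E1", "Bacteroides"])
  m_e2 <- mean(genus$values[fit$labels == "ICU_E2", "Bacteroides"])
  expect_gt(m_e1, m_e2)
  expect_true(all(fit$silhouette >= -1 & fit$silhouette <= 1))
})
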