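#' Multi-rank feature matrix for biomarker screening
#'
#' Aggregates the table at every rank phylum through genus and stacks the
#' blocks side by side, each feature scaled per sample so that every rank
#' block sums to 1e6 (the canonical per-rank scaling for LDA effect-size
#' screening). Feature names carry a rank prefix: `p__`, `c__`, `o__`,
#' `f__`, `g__`.
#'
#' @param x An `abundance_table`.
#' @param ranks Ranks to include (default phylum..genus).
#' @return Numeric matrix, samples x features.
#' @export
multirank_features <- function(x, ranks = TAXONOMIC_RANKS[-1]) {
  rel <- to_relative(x)
  prefix <- c(kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
              family = "f__", genus = "g__")
  blocks <- lapply(ranks, function(r) {
    agg <- aggregate_to_rank(rel, r)
    m <- agg$values * 1e6
    colnames(m) <- paste0(prefix[[r]], colnames(m))
    m
  })
  do.call(cbind, blocks)
}

#' Kruskal-Wallis rank test
#'
#' Thin wrapper over [stats::kruskal.test()] (tie-corrected H statistic,
#' chi-square p on k - 1 df). A vector with no variation returns H = 0 and
#' p = NA.
#'
#' @param values Numeric vector.
#' @param labels Group labels, one per value.
#' @return List with `statistic` and `p`.
#' @export
kruskal_wallis <- function(values, labels) {
  labels <- factor(labels)
  if (any(table(labels) == 0) || nlevels(labels) < 2)
    stop("kruskal_wallis needs >= 2 non-empty groups")
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p = NA_real_))
  kt <- stats::kruskal.test(values, labels)
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

# Ridge-regularised Fisher discriminant direction: compositional multi-rank
# features are exactly collinear (a family equals the sum of its genera), so
# the pooled within-class scatter needs a small ridge to stay invertible.
fisher_direction <- function(X, y) {
  lev <- levels(y)
  m1 <- colMeans(X[y == lev[1], , drop = FALSE])
  m2 <- colMeans(X[y == lev[2], , drop = FALSE])
  Sw <- 0
  for (l in lev) {
    Xl <- sweep(X[y == l, , drop = FALSE], 2, colMeans(X[y == l, , drop = FALSE]))
    Sw <- Sw + crossprod(Xl)
  }
  Sw <- Sw / (nrow(X) - 2)
  lambda <- 1e-6 * mean(diag(Sw)) + 1e-12
  w <- solve(Sw + diag(lambda, ncol(X)), m1 - m2)
  w / sqrt(sum(w^2))
}

#' LDA effect-size screen for class-discriminating taxa
#'
#' Two-stage screen in the LEfSe style: features failing a Kruskal-Wallis
#' test at `alpha` are dropped; survivors are scored over `n_boot` seeded
#' subsamples (fraction `subsample` of each class) by fitting a one-axis
#' linear discriminant on the 1e6-scaled features and taking, per feature,
#' the mean of half the sum of the absolute projected and raw class-mean
#' differences. The reported score is log10 of the effect (floored at 1) and
#' only features with score above `gate` are retained.
#'
#' @param features Samples x features matrix from [multirank_features()].
#' @param labels Two-class factor.
#' @param alpha Kruskal-Wallis screening level (default 0.05).
#' @param gate Log10 LDA score gate (default 2.0).
#' @param n_boot Subsample rounds (default 30).
#' @param subsample Fraction of each class per round (default 2/3).
#' @param seed RNG seed.
#' @return data.frame (feature, enriched_in, kw_p, lda_log10), sorted by
#'   descending score; only gated survivors.
#' @export
lda_effect_size <- function(features, labels, alpha = 0.05, gate = 2.0,
                            n_boot = 30, subsample = 2/3, seed = 1) {
  y <- factor(labels)
  if (nlevels(y) != 2) stop("lda_effect_size requires exactly two classes")
  X <- as.matrix(features)
  kw_p <- apply(X, 2, function(v) kruskal_wallis(v, y)$p)
  keep <- which(!is.na(kw_p) & kw_p < alpha)
  empty <- data.frame(feature = character(), enriched_in = character(),
                      kw_p = numeric(), lda_log10 = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(keep)) return(empty)
  Xs <- X[, keep, drop = FALSE]
  n_by <- table(y)
  take <- pmax(2L, floor(as.numeric(n_by) * subsample))
  set.seed(seed)
  eff <- matrix(0, n_boot, ncol(Xs))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(seq_along(levels(y)), function(i) {
      pool <- which(y == levels(y)[i])
      sample(pool, min(take[i], length(pool)))
    }))
    Xi <- Xs[idx, , drop = FALSE]
    yi <- droplevels(y[idx])
    if (nlevels(yi) < 2 || any(table(yi) < 2)) { eff[b, ] <- NA; next }
    w <- fisher_direction(Xi, yi)
    dm <- colMeans(Xi[yi == levels(yi)[1], , drop = FALSE]) -
      colMeans(Xi[yi == levels(yi)[2], , drop = FALSE])
    proj <- sum(w * dm)
    eff[b, ] <- 0.5 * (abs(w * proj) + abs(dm))
  }
  effect <- colMeans(eff, na.rm = TRUE)
  lda_log10 <- log10(pmax(effect, 1))
  mu1 <- colMeans(Xs[y == levels(y)[1], , drop = FALSE])
  mu2 <- colMeans(Xs[y == levels(y)[2], , drop = FALSE])
  res <- data.frame(feature = colnames(Xs),
                    enriched_in = ifelse(mu1 >= mu2, levels(y)[1], levels(y)[2]),
                    kw_p = kw_p[keep],
                    lda_log10 = lda_log10,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[res$lda_log10 > gate, , drop = FALSE]
  res[order(-res$lda_log10, res$feature), , drop = FALSE]
}

# Discretize a numeric feature into 3 bins at mean +/- 0.5 sd.
discretize3 <- function(v) {
  m <- mean(v); s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(2L, length(v)))
  findInterval(v, c(m - 0.5 * s, m + 0.5 * s)) + 1L
}

# Mutual information (nats) between two discrete vectors via contingency
# counts.
mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  terms <- p * log(p / outer(pa, pb))
  sum(terms[p > 0])
}

#' Greedy mRMR (MID) feature selection
#'
#' Minimum-redundancy maximum-relevance with the difference (MID) criterion:
#' the first pick maximizes mutual information with the class; each further
#' pick maximizes I(f; class) minus the mean mutual information with the
#' already-selected features. Features are discretized into 3 bins at
#' mean +/- 0.5 sd before any MI computation. Ties break towards higher
#' relevance, then lexicographic feature name.
#'
#' @param features Samples x candidate-features matrix.
#' @param labels Class factor.
#' @param n_select Number of features to pick (default 5).
#' @return Character vector of selected feature names in pick order, with a
#'   `scores` attribute (the MID value at each pick).
#' @export
mrmr_select <- function(features, labels, n_select = 5) {
  X <- as.matrix(features)
  y <- factor(labels)
  feats <- colnames(X)
  if (is.null(feats)) stop("features must have column names")
  if (ncol(X) < n_select) {
    warning("only ", ncol(X), " candidate(s) available; returning all")
    n_select <- ncol(X)
  }
  B <- apply(X, 2, discretize3)
  relevance <- apply(B, 2, mutual_information, b = y)
  selected <- character(0)
  scores <- numeric(0)
  remaining <- feats
  redundancy_sum <- stats::setNames(numeric(length(feats)), feats)
  for (step in seq_len(n_select)) {
    crit <- if (!length(selected)) relevance[remaining] else
      relevance[remaining] - redundancy_sum[remaining] / length(selected)
    # tie-break: criterion, then relevance, then name
    ord <- order(-crit, -relevance[remaining], remaining)
    pick <- remaining[ord[1]]
    selected <- c(selected, pick)
    scores <- c(scores, crit[[pick]])
    remaining <- setdiff(remaining, pick)
    if (length(remaining))
      redundancy_sum[remaining] <- redundancy_sum[remaining] +
        vapply(remaining, function(f) mutual_information(B[, f], B[, pick]),
               numeric(1))
  }
  structure(selected, scores = stats::setNames(scores, selected))
}

#' Build the two-enterotype biomarker set
#'
#' Runs the LDA effect-size screen on the multi-rank features, then picks
#' `n_select` non-redundant markers per enterotype by mRMR among the
#' candidates enriched in that enterotype. The E1 markers form the numerator
#' set of the MHI score, the E2 markers the denominator set.
#'
#' @param x An `abundance_table`.
#' @param labels Two-level enterotype factor (`ICU_E1`/`ICU_E2`).
#' @param n_select Markers per enterotype (default 5).
#' @inheritParams lda_effect_size
#' @return Object of class `biomarker_set` with `e1_markers`, `e2_markers`
#'   and `provenance` (the gated effect-size table).
#' @export
build_biomarker_set <- function(x, labels, n_select = 5, alpha = 0.05,
                                gate = 2.0, n_boot = 30, subsample = 2/3,
                                seed = 1) {
  y <- factor(labels)
  if (nlevels(y) != 2) stop("need a two-class enterotype partition")
  feats <- multirank_features(x)
  scored <- lda_effect_size(feats, y, alpha = alpha, gate = gate,
                            n_boot = n_boot, subsample = subsample, seed = seed)
  pick_side <- function(class) {
    cand <- scored$feature[scored$enriched_in == class]
    if (!length(cand))
      stop("no gated candidates enriched in ", class,
           "; inspect the effect-size table")
    mrmr_select(feats[, cand, drop = FALSE], y, n_select = n_select)
  }
  lev <- levels(y)
  e1 <- pick_side(lev[1])
  e2 <- pick_side(lev[2])
  structure(list(e1_markers = as.character(e1), e2_markers = as.character(e2),
                 e1_scores = attr(e1, "scores"), e2_scores = attr(e2, "scores"),
                 provenance = scored, classes = lev),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat("Biomarker set (LDA effect size + mRMR)\n")
  cat("  ", x$classes[1], "(numerator):",
      paste(x$e1_markers, collapse = ", "), "\n")
  cat("  ", x$classes[2], "(denominator):",
      paste(x$e2_markers, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / deserialize a biomarker set as JSON
#' @param x A `biomarker_set`.
#' @param path File path.
#' @export
write_biomarker_set <- function(x, path) {
  scores <- stats::setNames(as.list(x$provenance$lda_log10), x$provenance$feature)
  jsonlite::write_json(list(e1 = x$e1_markers, e2 = x$e2_markers,
                            classes = x$classes, scores = scores),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_biomarker_set
#' @export
read_biomarker_set <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  prov <- data.frame(feature = names(j$scores),
                     enriched_in = NA_character_,
                     kw_p = NA_real_,
                     lda_log10 = as.numeric(unlist(j$scores)),
                     stringsAsFactors = FALSE)
  structure(list(e1_markers = j$e1, e2_markers = j$e2,
                 e1_scores = NULL, e2_scores = NULL,
                 provenance = prov,
                 classes = if (!is.null(j$classes)) j$classes else c("ICU_E1", "ICU_E2")),
            class = "biomarker_set")
}

#' Export the effect-size table as TSV (taxon, direction, lda_log10)
#' @param x A `biomarker_set`.
#' @param path File path.
#' @export
write_effect_size_table <- function(x, path) {
  utils::write.table(
    data.frame(taxon = x$provenance$feature,
               direction = x$provenance$enriched_in,
               lda_log10 = x$provenance$lda_log10),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
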