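marker_rank <- function(marker) {
  prefix <- substr(marker, 1, 3)
  map <- c(k__ = "kingdom", p__ = "phylum", c__ = "class", o__ = "order",
           f__ = "family", g__ = "genus")
  r <- map[prefix]
  ifelse(is.na(r), "genus", r)
}

# Relative abundance of each marker in each sample, resolving rank prefixes
# against per-rank aggregations; unresolvable markers contribute 0.
marker_abundances <- function(x, markers) {
  rel <- to_relative(x)
  out <- matrix(0, nrow(rel$values), length(markers),
                dimnames = list(rownames(rel$values), markers))
  ranks <- marker_rank(markers)
  for (r in unique(ranks)) {
    agg <- aggregate_to_rank(rel, r)
    for (m in markers[ranks == r]) {
      name <- sub("^[kpcofg]__", "", m)
      if (name %in% colnames(agg$values)) out[, m] <- agg$values[, name]
    }
  }
  out
}

#' Microbial-based human index (MHI) score
#'
#' For each sample, the sum of the relative abundances of the five E1
#' biomarkers divided by the sum for the five E2 biomarkers:
#' score = (sum_i ABUr(S_i) + eps) / (sum_j ABUr(S_j) + eps). The small
#' stabilizer keeps the score finite when all denominator taxa are absent
#' and pins a sample lacking all ten markers at exactly 1 (uninformative).
#'
#' @param x An `abundance_table` (converted to relative if needed).
#' @param biomarkers A `biomarker_set`.
#' @param epsilon Stabilizer added to numerator and denominator (default 1e-6).
#' @return data.frame with sample_id, numerator, denominator, score.
#' @export
mhi_score <- function(x, biomarkers, epsilon = 1e-6) {
  stopifnot(inherits(biomarkers, "biomarker_set"))
  a1 <- marker_abundances(x, biomarkers$e1_markers)
  a2 <- marker_abundances(x, biomarkers$e2_markers)
  num <- rowSums(a1); den <- rowSums(a2)
  data.frame(sample_id = rownames(a1),
             numerator = num, denominator = den,
             score = (num + epsilon) / (den + epsilon),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Train the MHI decision threshold by grid sweep
#'
#' The candidate threshold starts at the minimum training score and is
#' raised in steps of (max - min)/`n_steps`; at each of the `n_steps + 1`
#' grid points sensitivity (E1 as positive, calls by score > threshold) and
#' specificity are evaluated, and the threshold maximizing Youden's
#' J = sensitivity + specificity - 1 is selected (smallest such threshold on
#' ties).
#'
#' @param scores Numeric MHI scores (or the data.frame from [mhi_score()]).
#' @param labels Enterotype factor aligned with scores; the first level (or
#'   `"ICU_E1"` if present) is the positive class.
#' @param n_steps Grid steps (default 1000).
#' @param biomarkers Optional `biomarker_set` to embed in the classifier.
#' @param epsilon Stabilizer recorded for later scoring.
#' @return Object of class `mhi_classifier`.
#' @export
mhi_train <- function(scores, labels, n_steps = 1000, biomarkers = NULL,
                      epsilon = 1e-6) {
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score, scores$sample_id)
  y <- factor(labels)
  if (nlevels(y) != 2) stop("training needs both classes present")
  pos <- if ("ICU_E1" %in% levels(y)) "ICU_E1" else levels(y)[1]
  lo <- min(scores); hi <- max(scores)
  if (hi <= lo) stop("zero score range: all training scores identical")
  grid <- lo + (hi - lo) * (0:n_steps) / n_steps
  is_pos <- y == pos
  sens <- vapply(grid, function(t) mean(scores[is_pos] > t), numeric(1))
  spec <- vapply(grid, function(t) mean(scores[!is_pos] <= t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]  # smallest threshold among ties
  structure(list(threshold = grid[best],
                 train_sensitivity = sens[best],
                 train_specificity = spec[best],
                 youden_j = j[best],
                 positive = pos,
                 negative = setdiff(levels(y), pos)[1],
                 n_steps = n_steps,
                 grid_range = c(lo, hi),
                 biomarkers = biomarkers,
                 epsilon = epsilon),
            class = "mhi_classifier")
}

#' @export
print.mhi_classifier <- function(x, ...) {
  cat("MHI classifier\n")
  cat(sprintf("  threshold: %.4f  (grid of %d steps over [%.4f, %.4f])\n",
              x$threshold, x$n_steps, x$grid_range[1], x$grid_range[2]))
  cat(sprintf("  training sensitivity %.3f, specificity %.3f (positive = %s)\n",
              x$train_sensitivity, x$train_specificity, x$positive))
  invisible(x)
}

#' Classify samples with a trained MHI classifier
#'
#' Samples with score strictly above the threshold are called E1
#' (`positive`); scores at or below it are called E2.
#'
#' @param object An `mhi_classifier`.
#' @param newdata Numeric scores, the data.frame from [mhi_score()], or an
#'   `abundance_table` (scored with the embedded biomarkers).
#' @param ... Unused.
#' @return Factor of calls, named by sample where available.
#' @export
predict.mhi_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "abundance_table")) {
    if (is.null(object$biomarkers))
      stop("classifier holds no biomarker set; supply scores instead")
    newdata <- mhi_score(newdata, object$biomarkers, object$epsilon)
  }
  if (is.data.frame(newdata)) newdata <- stats::setNames(newdata$score, newdata$sample_id)
  factor(ifelse(newdata > object$threshold, object$positive, object$negative),
         levels = c(object$positive, object$negative))
}

# Rank (Mann-Whitney) AUC with half credit for ties.
auc_point <- function(scores, is_pos) {
  n1 <- sum(is_pos); n2 <- sum(!is_pos)
  if (n1 == 0 || n2 == 0) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC AUC with stratified bootstrap confidence interval
#'
#' Point AUC by the rank (Mann-Whitney U) construction with half credit for
#' ties; the 95% CI comes from the 2.5/97.5 percentiles of AUCs over
#' class-stratified bootstrap resamples (default 9999 replicates).
#'
#' @param scores Numeric scores.
#' @param labels Two-class factor; `"ICU_E1"` (or the first level) is positive.
#' @param n_boot Bootstrap replicates (default 9999).
#' @param seed RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `auc`, `ci_low`, `ci_high`, `n_boot`.
#' @export
roc_auc <- function(scores, labels, n_boot = 9999, seed = 1, conf = 0.95) {
  y <- factor(labels)
  if (nlevels(y) != 2) stop("AUC needs both classes present")
  pos <- if ("ICU_E1" %in% levels(y)) "ICU_E1" else levels(y)[1]
  is_pos <- y == pos
  point <- auc_point(scores, is_pos)
  p <- scores[is_pos]; q <- scores[!is_pos]
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    sp <- sample(p, length(p), replace = TRUE)
    sq <- sample(q, length(q), replace = TRUE)
    auc_point(c(sp, sq), c(rep(TRUE, length(sp)), rep(FALSE, length(sq))))
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(a, 1 - a)))
  list(auc = point, ci_low = min(ci[1], point), ci_high = max(ci[2], point),
       n_boot = n_boot)
}

f1_score <- function(calls, truth, positive) {
  tp <- sum(calls == positive & truth == positive)
  fp <- sum(calls == positive & truth != positive)
  fn <- sum(calls != positive & truth == positive)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

eval_metrics <- function(scores, truth, classifier, n_boot, seed) {
  calls <- predict(classifier, scores)
  pos <- classifier$positive
  auc <- roc_auc(scores, truth, n_boot = n_boot, seed = seed)
  list(n = length(scores),
       auc = auc$auc, ci_low = auc$ci_low, ci_high = auc$ci_high,
       f1 = f1_score(calls, truth, pos),
       f1_negative_positive = f1_score(calls, truth, classifier$negative),
       sensitivity = mean(calls[truth == pos] == pos),
       specificity = mean(calls[truth != pos] != pos),
       calls = calls)
}

#' Train and evaluate the MHI classifier on a stratified split
#'
#' Samples are split into training and test sets stratified by enterotype
#' (default 80/20); the threshold is trained on the training scores only and
#' both splits are evaluated (AUC with stratified-bootstrap CI, F1 with E1
#' positive, sensitivity, specificity).
#'
#' @param x An `abundance_table`.
#' @param labels Enterotype factor aligned with the table's samples.
#' @param biomarkers A `biomarker_set`.
#' @param split Training fraction (default 0.8).
#' @param seed RNG seed for the split and bootstrap.
#' @param n_boot Bootstrap replicates for the AUC CI (default 9999).
#' @param n_steps Threshold grid steps (default 1000).
#' @param epsilon MHI stabilizer.
#' @return Object of class `mhi_eval`: the classifier, a report data.frame
#'   (one row per split) and per-sample scores/calls.
#' @export
mhi_evaluate <- function(x, labels, biomarkers, split = 0.8, seed = 1,
                         n_boot = 9999, n_steps = 1000, epsilon = 1e-6) {
  y <- factor(labels)
  sc <- mhi_score(x, biomarkers, epsilon)
  scores <- stats::setNames(sc$score, sc$sample_id)
  set.seed(seed)
  train_idx <- unlist(lapply(levels(y), function(l) {
    pool <- which(y == l)
    sample(pool, max(1L, round(length(pool) * split)))
  }))
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(y), train_idx)
  if (length(unique(y[test_idx])) < 2 || length(unique(y[train_idx])) < 2)
    stop("split produced a single-class set; adjust split or sample size")
  clf <- mhi_train(scores[train_idx], y[train_idx], n_steps = n_steps,
                   biomarkers = biomarkers, epsilon = epsilon)
  tr <- eval_metrics(scores[train_idx], y[train_idx], clf, n_boot,
                     seed = seed + 1L)
  te <- eval_metrics(scores[test_idx], y[test_idx], clf, n_boot,
                     seed = seed + 2L)
  report <- do.call(rbind, lapply(list(training = tr, testing = te), function(m)
    data.frame(n = m$n, auc = m$auc, ci_low = m$ci_low, ci_high = m$ci_high,
               f1 = m$f1, sensitivity = m$sensitivity,
               specificity = m$specificity)))
  report <- cbind(set = rownames(report), report)
  rownames(report) <- NULL
  structure(list(classifier = clf, report = report,
                 scores = scores,
                 train_ids = names(scores)[train_idx],
                 test_ids = names(scores)[test_idx],
                 calls = c(tr$calls, te$calls)[names(scores)],
                 f1_negative_positive = c(training = tr$f1_negative_positive,
                                          testing = te$f1_negative_positive)),
            class = "mhi_eval")
}

#' @export
print.mhi_eval <- function(x, ...) {
  print(x$classifier)
  cat("\nPerformance (AUC CI by stratified bootstrap):\n")
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize / deserialize an MHI classifier as JSON
#' @param x An `mhi_classifier`.
#' @param path File path.
#' @export
write_mhi_classifier <- function(x, path) {
  jsonlite::write_json(list(
    threshold = x$threshold,
    train_sensitivity = x$train_sensitivity,
    train_specificity = x$train_specificity,
    positive = x$positive, negative = x$negative,
    n_steps = x$n_steps, epsilon = x$epsilon,
    biomarkers = if (!is.null(x$biomarkers))
      list(e1 = x$biomarkers$e1_markers, e2 = x$biomarkers$e2_markers)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mhi_classifier
#' @export
read_mhi_classifier <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  bm <- NULL
  if (!is.null(j$biomarkers))
    bm <- structure(list(e1_markers = j$biomarkers$e1,
                         e2_markers = j$biomarkers$e2,
                         provenance = NULL,
                         classes = c(j$positive, j$negative)),
                    class = "biomarker_set")
  structure(list(threshold = j$threshold,
                 train_sensitivity = j$train_sensitivity,
                 train_specificity = j$train_specificity,
                 youden_j = j$train_sensitivity + j$train_specificity - 1,
                 positive = j$positive, negative = j$negative,
                 n_steps = j$n_steps, grid_range = c(NA_real_, NA_real_),
                 biomarkers = bm, epsilon = j$epsilon),
            class = "mhi_classifier")
}
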