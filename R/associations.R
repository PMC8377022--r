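#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the point-probability convention: the sum of
#' hypergeometric probabilities (margins fixed) of all tables no more
#' probable than the observed one, as computed by [stats::fisher.test()].
#' The sample odds ratio (ad/bc) is reported alongside the conditional MLE.
#'
#' @param tab 2x2 matrix (or object coercible to one) of non-negative counts.
#' @return List with `p`, `odds_ratio` (sample), `odds_ratio_cmle`, `table`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("fisher_exact expects a 2x2 table")
  if (any(tab < 0)) stop("cells must be non-negative")
  if (sum(tab) == 0) stop("table total must be positive")
  ft <- stats::fisher.test(tab)
  or_sample <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p = ft$p.value, odds_ratio = or_sample,
       odds_ratio_cmle = unname(ft$estimate), table = tab)
}

#' Enterotype vs outcome contingency tests within severity strata
#'
#' Within the high-severity (APACHE II > cutoff) and low-severity strata,
#' builds the (status x enterotype) 2x2 table and applies Fisher's exact
#' test. Empty strata (or strata with an empty margin) are returned with
#' `p = NA`.
#'
#' @param records Clinical data.frame (needs sample_id, status, apache_ii).
#' @param labels Named enterotype factor (names = sample ids).
#' @param cutoff APACHE II stratum boundary (default 18; strictly greater is
#'   "high").
#' @return List with elements `high` and `low`, each holding `table`, `p`
#'   and `odds_ratio`.
#' @export
stratified_enterotype_test <- function(records, labels, cutoff = 18) {
  et <- labels[records$sample_id]
  if (anyNA(et)) stop("enterotype labels missing for some samples")
  strata <- list(high = records$apache_ii > cutoff,
                 low = records$apache_ii <= cutoff)
  lapply(strata, function(sel) {
    sel <- sel & !is.na(records$apache_ii)
    tab <- table(factor(records$status[sel], c("septic_shock", "sepsis")),
                 factor(as.character(et[sel]), c("ICU_E1", "ICU_E2")))
    tab <- as.matrix(unclass(tab))
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("stratum with empty margin: p undefined")
      return(list(table = tab, p = NA_real_, odds_ratio = NA_real_))
    }
    ft <- fisher_exact(tab)
    list(table = tab, p = ft$p, odds_ratio = ft$odds_ratio)
  })
}

#' Enterotype vs serum-lactate-group contingency test
#'
#' One record per patient (the first collected sample); patients with
#' lactate at or above `cutoff` form the high-lactate group. Fisher's exact
#' test on the (lactate group x enterotype) table.
#'
#' @param records Clinical data.frame (needs sample_id, patient_id, day,
#'   lactate).
#' @param labels Named enterotype factor.
#' @param cutoff Lactate boundary in mM (default 2.5; boundary value goes to
#'   the high group).
#' @param first_sample_only Reduce to each patient's first sample (default
#'   TRUE).
#' @return List with `table`, `p`, `odds_ratio`, `n_excluded` (missing
#'   lactate).
#' @export
lactate_group_test <- function(records, labels, cutoff = 2.5,
                               first_sample_only = TRUE) {
  df <- records
  if (first_sample_only) {
    df <- df[order(df$patient_id, df$day), ]
    df <- df[!duplicated(df$patient_id), ]
  }
  n_excluded <- sum(is.na(df$lactate))
  if (n_excluded) message(n_excluded, " record(s) without lactate excluded")
  df <- df[!is.na(df$lactate), ]
  et <- labels[df$sample_id]
  grp <- factor(ifelse(df$lactate >= cutoff, "high", "low"), c("high", "low"))
  tab <- as.matrix(unclass(table(grp, factor(as.character(et), c("ICU_E1", "ICU_E2")))))
  if (any(rowSums(tab) == 0)) {
    warning("empty lactate group: p undefined")
    return(list(table = tab, p = NA_real_, odds_ratio = NA_real_,
                n_excluded = n_excluded))
  }
  ft <- fisher_exact(tab)
  list(table = tab, p = ft$p, odds_ratio = ft$odds_ratio,
       n_excluded = n_excluded)
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; tie-corrected normal approximation otherwise.
#'
#' @param x,y Numeric samples.
#' @return List with `U` (statistic for x) and two-sided `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  exact <- (length(x) + length(y) <= 12) && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Pearson correlation matrix of z-scored clinical parameters
#'
#' Each parameter column is z-score transformed and correlated pairwise
#' (pairwise-complete observations, at least 3 per pair). Zero-variance
#' columns yield NA correlations with a warning.
#'
#' @param records Clinical data.frame.
#' @param parameters Column names to correlate.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
clinical_corr_matrix <- function(records, parameters) {
  miss <- setdiff(parameters, names(records))
  if (length(miss)) stop("unknown parameters: ", paste(miss, collapse = ", "))
  M <- as.matrix(records[, parameters, drop = FALSE])
  storage.mode(M) <- "double"
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0))
    warning("zero-variance parameter(s): ",
            paste(parameters[is.na(sds) | sds == 0], collapse = ", "))
  Z <- scale(M)
  npair <- crossprod(!is.na(Z))
  R <- suppressWarnings(stats::cor(Z, use = "pairwise.complete.obs"))
  R[npair < 3] <- NA
  diag(R) <- 1
  R
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Mantel test of a microbiota distance matrix against a clinical scalar
#'
#' The scalar parameter is z-scored and turned into a distance matrix of
#' absolute z differences; the Mantel statistic is the Pearson correlation
#' over the n(n-1)/2 off-diagonal pairs. The p-value is one-sided (upper
#' tail), (count of permuted r >= observed + 1)/(n_perm + 1), permuting the
#' sample order of the parameter matrix; with `exhaustive = TRUE` (n <= 8)
#' all n! permutations are evaluated instead.
#'
#' @param d_micro A `dist` object (e.g. from [jsd_matrix()]).
#' @param parameter Numeric vector aligned with the distance labels (name it
#'   by sample id to enforce alignment).
#' @param n_perm Permutation count (default 9999).
#' @param seed RNG seed.
#' @param exhaustive Evaluate all permutations (requires n <= 8).
#' @return List with `r`, `p`, `n_perm`, `method`.
#' @export
mantel_test <- function(d_micro, parameter, n_perm = 9999, seed = 1,
                        exhaustive = FALSE) {
  n <- attr(d_micro, "Size")
  if (length(parameter) != n) stop("parameter length must match distance size")
  if (!is.null(names(parameter))) {
    ord <- match(dist_labels(d_micro), names(parameter))
    if (anyNA(ord)) stop("parameter names do not match distance labels")
    parameter <- parameter[ord]
  }
  s <- stats::sd(parameter)
  if (!is.finite(s) || s == 0) stop("parameter has zero variance")
  z <- (parameter - mean(parameter)) / s
  Dm <- as.matrix(d_micro)
  Dp <- abs(outer(z, z, "-"))
  lower <- lower.tri(Dm)
  v_micro <- Dm[lower]
  r_obs <- stats::cor(v_micro, Dp[lower])
  tol <- 1e-12
  if (exhaustive) {
    if (n > 8) stop("exhaustive permutation limited to n <= 8")
    perms <- all_permutations(n)
    r_all <- apply(perms, 1, function(p) stats::cor(v_micro, Dp[p, p][lower]))
    p_val <- mean(r_all >= r_obs - tol)
    return(list(r = r_obs, p = p_val, n_perm = nrow(perms),
                method = "exhaustive"))
  }
  set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(b) {
    p <- sample.int(n)
    stats::cor(v_micro, Dp[p, p][lower])
  }, numeric(1))
  p_val <- (sum(r_perm >= r_obs - tol) + 1) / (n_perm + 1)
  list(r = r_obs, p = p_val, n_perm = n_perm, method = "sampled")
}
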