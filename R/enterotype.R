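#' Jensen-Shannon distance matrix between samples
#'
#' d(x, y) = sqrt(JSD(x, y)) with the Jensen-Shannon divergence taken to log
#' base 2, so distances lie in [0, 1] and form a metric. The convention
#' 0 * log 0 = 0 applies; no pseudocount is added since the mixture
#' m = (x + y)/2 is positive wherever either profile is.
#'
#' @param x A relative-abundance `abundance_table` (rows sum to 1).
#' @return A [stats::dist] object labelled by sample id.
#' @export
jsd_matrix <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$mode != "relative") stop("jsd_matrix requires relative abundances (see to_relative)")
  P <- x$values
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-9))
    stop("rows must sum to 1; offending: ",
         paste(rownames(P)[abs(rs - 1) > 1e-9][1:min(3, sum(abs(rs - 1) > 1e-9))],
               collapse = ", "))
  n <- nrow(P)
  ent <- function(M) rowSums(ifelse(M > 0, -M * log2(M), 0))
  hx <- ent(P)
  D <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    M <- (P[j, , drop = FALSE] +
            matrix(P[i, ], length(j), ncol(P), byrow = TRUE)) / 2
    js <- ent(M) - (hx[i] + hx[j]) / 2
    D[i, j] <- D[j, i] <- sqrt(pmax(js, 0))
  }
  stats::as.dist(D)
}

dist_labels <- function(d) {
  lb <- attr(d, "Labels")
  if (is.null(lb)) as.character(seq_len(attr(d, "Size"))) else lb
}

#' Partitioning around medoids on a distance matrix
#'
#' Deterministic k-medoids. Tiny problems (at most 5000 candidate medoid
#' sets) are solved exactly by enumerating every medoid set, with ties
#' broken towards the lexicographically lowest sample indices; larger
#' problems use the standard BUILD + SWAP heuristic of [cluster::pam()],
#' which terminates when no single swap lowers the total distance to
#' assigned medoids. Both routes are deterministic, so no seed is involved.
#' The degenerate case k = n (every sample its own medoid, objective 0) is
#' handled directly.
#'
#' @param d A `dist` object (e.g. from [jsd_matrix()]).
#' @param k Number of clusters, 1 <= k <= n.
#' @return List with `k`, `labels` (named integer vector), `medoids` (sample
#'   ids) and `objective` (total distance to assigned medoid).
#' @export
pam_cluster <- function(d, k) {
  n <- attr(d, "Size")
  ids <- dist_labels(d)
  if (k < 1 || k > n) stop("k must be between 1 and n = ", n)
  if (k == n) {
    labels <- stats::setNames(seq_len(n), ids)
    return(list(k = k, labels = labels, medoids = ids, objective = 0))
  }
  D <- as.matrix(d)
  if (choose(n, k) <= 5000) {
    best_obj <- Inf
    med_idx <- NULL
    sets <- utils::combn(n, k, simplify = FALSE)  # lexicographic order
    for (med in sets) {
      obj <- sum(apply(D[, med, drop = FALSE], 1, min))
      if (obj < best_obj - 1e-12) { best_obj <- obj; med_idx <- med }
    }
    assign_to <- apply(D[, med_idx, drop = FALSE], 1, which.min)
    labels <- stats::setNames(as.integer(assign_to), ids)
    return(list(k = k, labels = labels, medoids = ids[med_idx],
                objective = best_obj))
  }
  p <- cluster::pam(d, k, diss = TRUE)
  labels <- stats::setNames(as.integer(p$clustering), ids)
  med_idx <- p$id.med
  obj <- sum(D[cbind(seq_len(n), med_idx[labels])])
  list(k = k, labels = labels, medoids = ids[med_idx], objective = obj)
}

#' Calinski-Harabasz index of a partition on a distance matrix
#'
#' Computed on principal-coordinate (classical MDS) axes with positive
#' eigenvalues, the standard route for distance-only data:
#' CH = (B / (k - 1)) / (W / (n - k)) with B and W the between- and
#' within-cluster sums of squared Euclidean deviations from centroids.
#'
#' @param d A `dist` object.
#' @param labels Cluster assignment, one per sample.
#' @return CH value (non-negative scalar).
#' @export
ch_index <- function(d, labels) {
  n <- attr(d, "Size")
  labels <- as.integer(factor(labels))
  if (length(labels) != n) stop("labels length must match distance size")
  k <- length(unique(labels))
  if (k < 2 || k >= n) stop("CH index undefined for k < 2 or k = n")
  coords <- pcoa_coords_full(d)
  ch_from_coords(coords, labels)
}

ch_from_coords <- function(coords, labels) {
  n <- nrow(coords)
  k <- length(unique(labels))
  grand <- colMeans(coords)
  W <- 0; B <- 0
  for (g in unique(labels)) {
    Xg <- coords[labels == g, , drop = FALSE]
    cg <- colMeans(Xg)
    W <- W + sum(sweep(Xg, 2, cg)^2)
    B <- B + nrow(Xg) * sum((cg - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

pcoa_coords_full <- function(d) {
  n <- attr(d, "Size")
  # cmdscale keeps only axes with positive eigenvalues when asked for n - 1
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  fit$points
}

#' Silhouette widths of a partition
#'
#' Per-sample silhouette s(i) = (b - a) / max(a, b) via
#' [cluster::silhouette()]; members of singleton clusters take s = 0.
#'
#' @param d A `dist` object.
#' @param labels Cluster assignment.
#' @return List with `widths` (named per-sample vector) and `mean`.
#' @export
silhouette_width <- function(d, labels) {
  n <- attr(d, "Size")
  labels <- as.integer(factor(labels))
  if (length(labels) != n) stop("labels length must match distance size")
  if (length(unique(labels)) < 2) stop("silhouette requires >= 2 clusters")
  s <- cluster::silhouette(labels, d)
  w <- stats::setNames(s[, "sil_width"], dist_labels(d))
  list(widths = w, mean = mean(w))
}

#' Choose the number of clusters by the CH index
#'
#' PAM is run for each k in `k_range`; the CH index selects the best k and
#' the mean silhouette width is reported alongside. If silhouette would pick
#' a different k than CH a message flags the disagreement (selection stays
#' with CH).
#'
#' @param d A `dist` object.
#' @param k_range Candidate cluster counts (default 2:10).
#' @return data.frame with columns k, ch, si; attributes `best_k` and
#'   `si_best_k`.
#' @export
select_k <- function(d, k_range = 2:10) {
  n <- attr(d, "Size")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("no feasible k in range for n = ", n)
  coords <- pcoa_coords_full(d)
  rows <- lapply(k_range, function(k) {
    p <- pam_cluster(d, k)
    data.frame(k = k,
               ch = ch_from_coords(coords, p$labels),
               si = silhouette_width(d, p$labels)$mean)
  })
  tab <- do.call(rbind, rows)
  best <- tab$k[which.max(tab$ch)]
  si_best <- tab$k[which.max(tab$si)]
  if (best != si_best)
    message("CH selects k = ", best, " but silhouette favours k = ", si_best)
  attr(tab, "best_k") <- best
  attr(tab, "si_best_k") <- si_best
  tab
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical scaling: the doubly centred -d^2/2 matrix is eigendecomposed;
#' negative eigenvalues are clamped to zero and excluded from the explained
#' fractions. Requesting more axes than there are positive eigenvalues
#' truncates with a warning.
#'
#' @param d A `dist` object.
#' @param n_axes Number of axes to return (default 2).
#' @return List with `ids`, `coordinates` (n x m), `eigenvalues` (descending,
#'   clamped at 0) and `explained_fraction` per returned axis.
#' @export
pcoa <- function(d, n_axes = 2) {
  n <- attr(d, "Size")
  if (n < 3) stop("PCoA needs at least 3 samples")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- pmax(fit$eig, 0)
  npos <- sum(fit$eig > max(fit$eig) * 1e-8)
  if (n_axes > npos) {
    warning("only ", npos, " positive axes available; truncating")
    n_axes <- npos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  list(ids = dist_labels(d),
       coordinates = coords,
       eigenvalues = eig[seq_len(npos)],
       explained_fraction = (eig / sum(eig))[seq_len(n_axes)])
}

#' Discover enterotypes in an abundance table
#'
#' The full discovery step: Jensen-Shannon distances between samples, PAM
#' clustering with the number of clusters chosen by the Calinski-Harabasz
#' index (silhouette reported), and, when two clusters emerge, naming of
#' ICU E1 as the cluster with the higher mean *Bacteroides* relative
#' abundance (falling back to `e1_markers` if absent).
#'
#' @param x An `abundance_table` (counts are converted to relative).
#' @param k_range Candidate cluster counts (default 2:10).
#' @param k Optional fixed k, bypassing selection.
#' @param e1_markers Marker genera defining the E1 side, in fallback order.
#' @return Object of class `enterotype_fit`: labels (factor, `ICU_E1`/
#'   `ICU_E2` when k = 2), medoids, diagnostics table, distances, silhouette.
#' @export
enterotype <- function(x, k_range = 2:10, k = NULL,
                       e1_markers = c("Bacteroides", "Enterobacteriaceae*")) {
  stopifnot(inherits(x, "abundance_table"))
  rel <- to_relative(x)
  d <- jsd_matrix(rel)
  diagnostics <- select_k(d, k_range)
  if (is.null(k)) k <- attr(diagnostics, "best_k")
  p <- pam_cluster(d, k)
  si <- silhouette_width(d, p$labels)
  labels <- p$labels
  if (k == 2) {
    cols <- colnames(rel$values)
    marker <- e1_markers[match(TRUE, e1_markers %in% cols)]
    if (!is.na(marker)) {
      m1 <- mean(rel$values[labels == 1, marker])
      m2 <- mean(rel$values[labels == 2, marker])
      e1_cluster <- if (m1 >= m2) 1L else 2L
    } else {
      warning("no configured E1 marker found; keeping PAM cluster order")
      e1_cluster <- 1L
    }
    labels <- factor(ifelse(labels == e1_cluster, "ICU_E1", "ICU_E2"),
                     levels = c("ICU_E1", "ICU_E2"))
    names(labels) <- names(p$labels)
  } else {
    labels <- factor(labels)
  }
  structure(list(k = k, labels = labels, medoids = p$medoids,
                 objective = p$objective, ch = diagnostics$ch[diagnostics$k == k],
                 si = si$mean, silhouette = si$widths,
                 diagnostics = diagnostics, dist = d,
                 table = rel),
            class = "enterotype_fit")
}

#' @export
print.enterotype_fit <- function(x, ...) {
  cat("Enterotype partition (JSD + PAM)\n")
  cat(sprintf("  samples: %d   k: %d (CH = %.2f, mean silhouette = %.3f)\n",
              length(x$labels), x$k, x$ch, x$si))
  print(table(x$labels))
  invisible(x)
}

#' @export
summary.enterotype_fit <- function(object, ...) {
  cat("Cluster-count diagnostics (selection by CH):\n")
  print(object$diagnostics, row.names = FALSE)
  invisible(object$diagnostics)
}

#' Plot an enterotype fit on the first two principal coordinates
#' @param x An `enterotype_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.enterotype_fit <- function(x, ...) {
  emb <- pcoa(x$dist, 2)
  cl <- as.integer(factor(x$labels))
  graphics::plot(emb$coordinates, col = cl, pch = 19,
                 xlab = sprintf("PCo1 (%.1f%%)", 100 * emb$explained_fraction[1]),
                 ylab = sprintf("PCo2 (%.1f%%)", 100 * emb$explained_fraction[2]),
                 ...)
  graphics::legend("topright", legend = levels(factor(x$labels)),
                   col = seq_along(levels(factor(x$labels))), pch = 19, bty = "n")
  invisible(emb)
}
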