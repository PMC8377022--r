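#' Pipeline configuration with the study's protocol defaults
#'
#' Every default that the protocol fixes is fixed here: cluster counts 2-10,
#' Log10 LDA gate 2.0, five mRMR markers per enterotype, 80/20 split, 1000
#' threshold sweep steps, 9999 bootstrap replicates, APACHE II cutoff 18 and
#' lactate cutoff 2.5 mM, rarefaction at 4000 reads.
#'
#' @param k_range Candidate cluster counts.
#' @param lda_gate,lda_alpha Effect-size gate and KW screening level.
#' @param mrmr_n Markers per enterotype.
#' @param split Training fraction.
#' @param n_boot Bootstrap replicates for AUC CIs.
#' @param sweep_steps Threshold grid steps.
#' @param apache_cutoff,lactate_cutoff Clinical strata boundaries.
#' @param rarefaction_depth Reads for alpha diversity.
#' @param epsilon MHI stabilizer.
#' @param seed Global seed; each stochastic stage derives a child seed from
#'   it so toggling one stage never shifts another's random stream.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(k_range = 2:10, lda_gate = 2.0, lda_alpha = 0.05,
                            mrmr_n = 5, split = 0.8, n_boot = 9999,
                            sweep_steps = 1000, apache_cutoff = 18,
                            lactate_cutoff = 2.5, rarefaction_depth = 4000,
                            epsilon = 1e-6, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Derive a per-stage child seed from the global seed
#'
#' Deterministic fan-out keyed by stage name, kept within 32-bit integer
#' range.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

#' Run the full enterotype analysis pipeline
#'
#' Enterotype discovery (JSD + PAM + CH/SI), biomarker selection (LDA effect
#' size + mRMR), MHI training and split evaluation, and the
#' enterotype-outcome association battery (stratified Fisher tests, lactate
#' grouping, Mann-Whitney comparisons, Pearson correlation matrix, Mantel
#' test of microbiota distance against lactate). When `out_dir` is given,
#' every artifact is written together with a manifest of content hashes.
#'
#' @param abundance An `abundance_table` (counts or relative).
#' @param metadata Clinical data.frame (see [read_clinical_metadata()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List of class `mhindex_pipeline` with elements `enterotypes`,
#'   `biomarkers`, `mhi`, `associations`, `alpha` (counts input only) and
#'   `manifest` (when written).
#' @export
run_full_pipeline <- function(abundance, metadata, config = pipeline_config(),
                              out_dir = NULL) {
  metadata <- validate_clinical(metadata)
  if (!setequal(metadata$sample_id, sample_ids(abundance)))
    stop("metadata and abundance table cover different samples")
  metadata <- metadata[match(sample_ids(abundance), metadata$sample_id), ]

  genus <- aggregate_to_rank(to_relative(abundance), "genus")
  et <- enterotype(genus, k_range = config$k_range)
  labels <- et$labels

  bm <- build_biomarker_set(genus, labels, n_select = config$mrmr_n,
                            alpha = config$lda_alpha, gate = config$lda_gate,
                            seed = stage_seed(config$seed, "biomarkers"))
  mhi <- mhi_evaluate(genus, labels, bm, split = config$split,
                      seed = stage_seed(config$seed, "mhi"),
                      n_boot = config$n_boot, n_steps = config$sweep_steps,
                      epsilon = config$epsilon)

  strat <- stratified_enterotype_test(metadata, labels,
                                      cutoff = config$apache_cutoff)
  lact <- lactate_group_test(metadata, labels, cutoff = config$lactate_cutoff)
  first <- metadata[order(metadata$patient_id, metadata$day), ]
  first <- first[!duplicated(first$patient_id), ]
  lab1 <- labels[first$sample_id]
  lact_mw <- if (nlevels(droplevels(lab1)) == 2)
    mann_whitney(first$lactate[lab1 == "ICU_E1"],
                 first$lactate[lab1 == "ICU_E2"]) else list(U = NA, p = NA)
  params <- intersect(c("apache_ii", "sofa", "lactate"), names(metadata))
  corr <- clinical_corr_matrix(first, params)
  d_first <- jsd_matrix(abundance_subset(genus, first$sample_id))
  mantel <- mantel_test(d_first, stats::setNames(first$lactate, first$sample_id),
                        n_perm = min(config$n_boot, 9999),
                        seed = stage_seed(config$seed, "mantel"))
  alpha <- if (abundance$mode == "counts")
    tryCatch(alpha_diversity(abundance, depth = config$rarefaction_depth,
                             seed = stage_seed(config$seed, "rarefaction")),
             error = function(e) NULL) else NULL

  out <- structure(list(enterotypes = et, biomarkers = bm, mhi = mhi,
                        associations = list(stratified = strat,
                                            lactate = lact,
                                            lactate_mw = lact_mw,
                                            correlations = corr,
                                            mantel_lactate = mantel),
                        alpha = alpha, config = config),
                   class = "mhindex_pipeline")
  if (!is.null(out_dir)) out$manifest <- write_pipeline_bundle(out, out_dir)
  out
}

abundance_subset <- function(x, ids) {
  abundance_table(x$values[ids, , drop = FALSE], x$lineages, mode = x$mode)
}

write_pipeline_bundle <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  w <- function(path, writer) { writer(path); files <<- c(files, path); path }
  w(file.path(out_dir, "enterotypes.tsv"), function(p)
    utils::write.table(data.frame(sample_id = names(x$enterotypes$labels),
                                  enterotype = as.character(x$enterotypes$labels)),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))
  w(file.path(out_dir, "k_diagnostics.tsv"), function(p)
    utils::write.table(x$enterotypes$diagnostics, p, sep = "\t",
                       quote = FALSE, row.names = FALSE))
  w(file.path(out_dir, "biomarkers.json"), function(p)
    write_biomarker_set(x$biomarkers, p))
  w(file.path(out_dir, "effect_sizes.tsv"), function(p)
    write_effect_size_table(x$biomarkers, p))
  w(file.path(out_dir, "mhi_classifier.json"), function(p)
    write_mhi_classifier(x$mhi$classifier, p))
  w(file.path(out_dir, "mhi_report.tsv"), function(p)
    utils::write.table(x$mhi$report, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  w(file.path(out_dir, "associations.json"), function(p)
    jsonlite::write_json(list(
      stratified = lapply(x$associations$stratified, function(s)
        list(table = as.vector(s$table), p = s$p, odds_ratio = s$odds_ratio)),
      lactate = list(table = as.vector(x$associations$lactate$table),
                     p = x$associations$lactate$p),
      lactate_mw = x$associations$lactate_mw,
      mantel_lactate = x$associations$mantel_lactate[c("r", "p", "n_perm")]),
      p, auto_unbox = TRUE, digits = NA, force = TRUE))
  w(file.path(out_dir, "clinical_correlations.tsv"), function(p)
    utils::write.table(x$associations$correlations, p, sep = "\t",
                       quote = FALSE, col.names = NA))
  if (!is.null(x$alpha))
    w(file.path(out_dir, "alpha_diversity.tsv"), function(p)
      utils::write.table(x$alpha, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  manifest <- list(seed = x$config$seed,
                   package_version = as.character(utils::packageVersion("mhindex")),
                   files = lapply(stats::setNames(files, basename(files)),
                                  function(f) unname(tools::md5sum(f))))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.mhindex_pipeline <- function(x, ...) {
  print(x$enterotypes)
  cat("\n")
  print(x$biomarkers)
  cat("\n")
  print(x$mhi$report, row.names = FALSE, digits = 4)
  cat(sprintf("\nAPACHE>%g stratum Fisher p = %.4g; lactate-group Fisher p = %.4g\n",
              x$config$apache_cutoff, x$associations$stratified$high$p,
              x$associations$lactate$p))
  invisible(x)
}

#' Evaluate a frozen MHI classifier on an external cohort
#'
#' Applies a trained classifier (frozen biomarkers and threshold) to another
#' cohort's abundance table — the "testing set II" mode. Biomarker taxa are
#' first resolved against the external table's naming; if more than half of
#' the ten are unmatched the classifier is declared non-transferable.
#'
#' @param classifier An `mhi_classifier` carrying its biomarker set.
#' @param abundance External `abundance_table`.
#' @param labels Enterotype labels of the external samples (for evaluation).
#' @param n_boot Bootstrap replicates for the AUC CI.
#' @param seed RNG seed.
#' @return List with the evaluation row (`report`), per-sample `calls` and
#'   `unmatched` biomarkers.
#' @export
external_cohort_eval <- function(classifier, abundance, labels,
                                 n_boot = 9999, seed = 1) {
  stopifnot(inherits(classifier, "mhi_classifier"))
  if (is.null(classifier$biomarkers))
    stop("classifier carries no biomarker set")
  bm <- classifier$biomarkers
  markers <- c(bm$e1_markers, bm$e2_markers)
  rel <- to_relative(abundance)
  resolved <- vapply(markers, function(m) {
    r <- marker_rank(m)
    name <- sub("^[kpcofg]__", "", m)
    name %in% colnames(aggregate_to_rank(rel, r)$values)
  }, logical(1))
  unmatched <- markers[!resolved]
  if (length(unmatched) > length(markers) / 2)
    stop("classifier not transferable: ", length(unmatched), " of ",
         length(markers), " biomarkers unmatched (",
         paste(unmatched, collapse = ", "), ")")
  sc <- mhi_score(rel, bm, classifier$epsilon)
  scores <- stats::setNames(sc$score, sc$sample_id)
  y <- factor(labels[names(scores)])
  m <- eval_metrics(scores, y, classifier, n_boot, seed)
  report <- data.frame(set = "testing_II", n = m$n, auc = m$auc,
                       ci_low = m$ci_low, ci_high = m$ci_high, f1 = m$f1,
                       sensitivity = m$sensitivity,
                       specificity = m$specificity)
  list(report = report, calls = m$calls, scores = scores,
       unmatched = unmatched)
}
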