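# Log-normal parameters from a target arithmetic mean and sd.
lnorm_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Genus roster: 32 genera across 6 phyla, with the three driver taxa of the
# two ICU enterotypes (Bacteroides and an unclassified Enterobacteriaceae
# genus for E1, Enterococcus for E2) embedded among background gut genera.
default_taxa_roster <- function() {
  lin <- function(p, c, o, f, g = NA)
    paste(c("Bacteria", p, c, o, f, g)[!is.na(c("Bacteria", p, c, o, f, g))],
          collapse = ";")
  bacteroidia <- function(f, g) lin("Bacteroidetes", "Bacteroidia", "Bacteroidales", f, g)
  bacilli <- function(f, g) lin("Firmicutes", "Bacilli", "Lactobacillales", f, g)
  clostridia <- function(f, g) lin("Firmicutes", "Clostridia", "Clostridiales", f, g)
  gamma <- function(o, f, g) lin("Proteobacteria", "Gammaproteobacteria", o, f, g)
  data.frame(
    lineage = c(
      bacteroidia("Bacteroidaceae", "Bacteroides"),
      bacteroidia("Bacteroidaceae", "Phocaeicola"),
      bacteroidia("Prevotellaceae", "Prevotella"),
      bacteroidia("Prevotellaceae", "Paraprevotella"),
      bacteroidia("Porphyromonadaceae", "Parabacteroides"),
      bacteroidia("Porphyromonadaceae", "Porphyromonas"),
      bacteroidia("Rikenellaceae", "Alistipes"),
      bacilli("Enterococcaceae", "Enterococcus"),
      bacilli("Enterococcaceae", "Vagococcus"),
      bacilli("Lactobacillaceae", "Lactobacillus"),
      bacilli("Lactobacillaceae", "Pediococcus"),
      bacilli("Streptococcaceae", "Streptococcus"),
      bacilli("Streptococcaceae", "Lactococcus"),
      clostridia("Lachnospiraceae", "Blautia"),
      clostridia("Lachnospiraceae", "Roseburia"),
      clostridia("Lachnospiraceae", "Dorea"),
      clostridia("Ruminococcaceae", "Faecalibacterium"),
      clostridia("Ruminococcaceae", "Ruminococcus"),
      clostridia("Clostridiaceae", "Clostridium"),
      lin("Firmicutes", "Negativicutes", "Veillonellales", "Veillonellaceae", "Veillonella"),
      lin("Firmicutes", "Negativicutes", "Veillonellales", "Veillonellaceae", "Megasphaera"),
      gamma("Enterobacteriales", "Enterobacteriaceae", NA),  # unclassified genus
      gamma("Enterobacteriales", "Enterobacteriaceae", "Escherichia"),
      gamma("Enterobacteriales", "Enterobacteriaceae", "Klebsiella"),
      gamma("Enterobacteriales", "Enterobacteriaceae", "Enterobacter"),
      gamma("Pseudomonadales", "Moraxellaceae", "Acinetobacter"),
      gamma("Pseudomonadales", "Pseudomonadaceae", "Pseudomonas"),
      lin("Actinobacteria", "Actinobacteria", "Bifidobacteriales", "Bifidobacteriaceae", "Bifidobacterium"),
      lin("Actinobacteria", "Coriobacteriia", "Coriobacteriales", "Coriobacteriaceae", "Collinsella"),
      lin("Verrucomicrobia", "Verrucomicrobiae", "Verrucomicrobiales", "Akkermansiaceae", "Akkermansia"),
      lin("Fusobacteria", "Fusobacteriia", "Fusobacteriales", "Fusobacteriaceae", "Fusobacterium"),
      lin("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Sutterellaceae", "Sutterella")),
    background_weight = c(
      0, 2, 5, 1, 5, 1, 3,
      0, 1, 3, 1, 4, 1,
      4, 3, 2, 6, 4, 3, 2, 1,
      0, 8, 6, 3, 3, 2,
      3, 1, 2, 2, 1),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic ICU cohort generator
#'
#' Defaults mirror the study conditions: 131 samples from 64 patients over 9
#' ICU days, an 89:42 enterotype prevalence, log-normal driver-taxon
#' gradients calibrated to the printed cohort moments (unclassified
#' Enterobacteriaceae 0.251 vs 0.082; Bacteroides 0.206 vs 0.024;
#' Enterococcus 0.010 vs 0.180; sds from the printed standard errors),
#' APACHE II 20.37 +/- 8.14, SOFA 10.67 +/- 4.02, per-enterotype log-normal
#' lactate targeting 2.66 +/- 3.30 vs 1.42 +/- 0.52 mM, and septic-shock
#' risk elevated for E1 only within the high-APACHE stratum.
#'
#' @param n_samples,n_patients Cohort size (defaults 131 / 64).
#' @param enterotype_prevalence Probability of ICU_E1 per patient (default
#'   89/131).
#' @param drivers Per-driver, per-enterotype target `mean` and `sd` of the
#'   relative abundance (converted internally to log-normal parameters).
#' @param driver_mass_cap Rescale driver draws whose sum exceeds this
#'   (default 0.85).
#' @param background_concentration Dirichlet concentration spread over the
#'   background genera (default 40).
#' @param depth_meanlog,depth_sdlog,depth_min Log-normal sequencing-depth
#'   distribution.
#' @param apache_mean,apache_sd,sofa_mean,sofa_sd Severity-score normals
#'   (truncated at 0).
#' @param lactate Per-enterotype target mean/sd of serum lactate (mM).
#' @param lactate_floor Minimum lactate (default 0.1 mM).
#' @param shock_risk Septic-shock probability by APACHE stratum and
#'   enterotype.
#' @param apache_cutoff Stratum boundary used by `shock_risk` (default 18).
#' @param taxa Roster data.frame (lineage, background_weight).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 131, n_patients = 64,
                          enterotype_prevalence = 89 / 131,
                          drivers = list(
                            Bacteroides = list(ICU_E1 = c(mean = 0.206, sd = 0.206 * 0.4),
                                               ICU_E2 = c(mean = 0.024, sd = 0.024 * 0.4)),
                            `Enterobacteriaceae*` = list(ICU_E1 = c(mean = 0.251, sd = 0.251 * 0.4),
                                                         ICU_E2 = c(mean = 0.082, sd = 0.082 * 0.4)),
                            Enterococcus = list(ICU_E1 = c(mean = 0.010, sd = 0.010 * 0.4),
                                                ICU_E2 = c(mean = 0.180, sd = 0.180 * 0.4))),
                          driver_mass_cap = 0.85,
                          background_concentration = 40,
                          depth_meanlog = log(15000), depth_sdlog = 0.6,
                          depth_min = 1000,
                          apache_mean = 20.37, apache_sd = 8.14,
                          sofa_mean = 10.67, sofa_sd = 4.02,
                          lactate = list(ICU_E1 = c(mean = 2.66, sd = 3.30),
                                         ICU_E2 = c(mean = 1.42, sd = 0.52)),
                          lactate_floor = 0.1,
                          shock_risk = list(high = c(ICU_E1 = 0.40, ICU_E2 = 0.10),
                                            low = c(ICU_E1 = 0.12, ICU_E2 = 0.12)),
                          apache_cutoff = 18,
                          taxa = default_taxa_roster()) {
  if (enterotype_prevalence <= 0 || enterotype_prevalence >= 1)
    stop("enterotype_prevalence must lie in (0, 1)")
  for (d in names(drivers)) for (e in names(drivers[[d]])) {
    p <- drivers[[d]][[e]]
    if (any(p <= 0)) stop("driver parameters must be positive: ", d, "/", e)
  }
  for (e in c("ICU_E1", "ICU_E2")) {
    total <- sum(vapply(drivers, function(d) d[[e]][["mean"]], numeric(1)))
    if (total >= 1) stop("expected driver mass >= 1 for ", e)
  }
  cfg <- list(n_samples = n_samples, n_patients = n_patients,
              enterotype_prevalence = enterotype_prevalence,
              drivers = drivers, driver_mass_cap = driver_mass_cap,
              background_concentration = background_concentration,
              depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
              depth_min = depth_min,
              apache_mean = apache_mean, apache_sd = apache_sd,
              sofa_mean = sofa_mean, sofa_sd = sofa_sd,
              lactate = lactate, lactate_floor = lactate_floor,
              shock_risk = shock_risk, apache_cutoff = apache_cutoff,
              taxa = taxa)
  structure(cfg, class = "cohort_config")
}

#' Equalize the two enterotypes in a cohort config
#'
#' Sets every E2 generative parameter (drivers, lactate, shock risk) equal
#' to its E1 counterpart, removing the enterotype signal while keeping the
#' marginal structure — the negative control showing that pipeline recovery
#' reflects planted signal, not algorithmic artefact.
#'
#' @param config A `cohort_config`.
#' @return Modified config.
#' @export
equalize_enterotypes <- function(config) {
  for (d in names(config$drivers))
    config$drivers[[d]]$ICU_E2 <- config$drivers[[d]]$ICU_E1
  config$lactate$ICU_E2 <- config$lactate$ICU_E1
  config$shock_risk$high["ICU_E2"] <- config$shock_risk$high[["ICU_E1"]]
  config$shock_risk$low["ICU_E2"] <- config$shock_risk$low[["ICU_E1"]]
  config
}

rtrunc0 <- function(n, mean, sd) pmax(0, stats::rnorm(n, mean, sd))

draw_composition <- function(n, enterotypes, config) {
  roster <- config$taxa
  driver_names <- names(config$drivers)
  display <- lineage_display_name(roster$lineage, "genus")
  driver_idx <- match(driver_names, display)
  if (anyNA(driver_idx)) stop("driver taxa missing from roster")
  bg_idx <- setdiff(seq_len(nrow(roster)), driver_idx)
  w <- roster$background_weight[bg_idx]
  alpha <- config$background_concentration * w / sum(w)
  P <- matrix(0, n, nrow(roster), dimnames = list(NULL, display))
  for (i in seq_len(n)) {
    e <- enterotypes[i]
    dr <- vapply(driver_names, function(d) {
      p <- lnorm_params(config$drivers[[d]][[e]][["mean"]],
                        config$drivers[[d]][[e]][["sd"]])
      stats::rlnorm(1, p[["meanlog"]], p[["sdlog"]])
    }, numeric(1))
    if (sum(dr) > config$driver_mass_cap)
      dr <- dr * config$driver_mass_cap / sum(dr)
    g <- stats::rgamma(length(alpha), shape = alpha)
    bg <- if (sum(g) > 0) g / sum(g) else rep(1 / length(alpha), length(alpha))
    P[i, driver_idx] <- dr
    P[i, bg_idx] <- (1 - sum(dr)) * bg
  }
  P
}

#' Generate a synthetic ICU cohort with known ground truth
#'
#' For each patient an enterotype is drawn by prevalence; each of their
#' samples draws driver relative abundances log-normally with
#' enterotype-specific parameters, fills the remaining mass with a Dirichlet
#' background, and is converted to counts by a multinomial draw at a
#' log-normal sequencing depth. Clinical covariates (APACHE II, SOFA,
#' per-enterotype lactate, septic-shock status by enterotype x APACHE
#' stratum) are drawn per the configuration. Fully deterministic given
#' `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Object of class `synthetic_cohort`: `abundance` (counts
#'   `abundance_table`), `metadata` (clinical data.frame) and `truth`
#'   (per-sample true enterotype and pre-noise driver abundances; never an
#'   input to the pipeline).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  np <- config$n_patients; ns <- config$n_samples
  pat_et <- ifelse(stats::runif(np) < config$enterotype_prevalence,
                   "ICU_E1", "ICU_E2")
  # samples per patient: 1-5 over the 9 observation days, trimmed/padded to
  # the target cohort size
  k <- sample(1:5, np, replace = TRUE, prob = c(0.40, 0.27, 0.17, 0.10, 0.06))
  while (sum(k) > ns) { i <- which.max(k); k[i] <- k[i] - 1L }
  while (sum(k) < ns) { i <- which.min(k); if (k[i] >= 5) break; k[i] <- k[i] + 1L }
  patient <- rep(seq_len(np), k)
  day <- unlist(lapply(k, function(ki) sort(sample(1:9, ki))))
  n <- length(patient)
  et <- pat_et[patient]
  sample_id <- sprintf("S%03d", seq_len(n))

  P <- draw_composition(n, et, config)
  rownames(P) <- sample_id
  depth <- pmax(config$depth_min,
                round(stats::rlnorm(n, config$depth_meanlog, config$depth_sdlog)))
  counts <- t(vapply(seq_len(n), function(i)
    as.numeric(stats::rmultinom(1, depth[i], P[i, ])), numeric(ncol(P))))
  dimnames(counts) <- dimnames(P)
  abundance <- abundance_table(counts, config$taxa$lineage, mode = "counts")

  apache_base <- rtrunc0(np, config$apache_mean, config$apache_sd)
  sofa_base <- rtrunc0(np, config$sofa_mean, config$sofa_sd)
  apache <- round(pmax(0, apache_base[patient] + stats::rnorm(n, 0, 2)))
  sofa <- round(pmax(0, sofa_base[patient] + stats::rnorm(n, 0, 1.5)))
  lact <- vapply(seq_len(n), function(i) {
    p <- lnorm_params(config$lactate[[et[i]]][["mean"]],
                      config$lactate[[et[i]]][["sd"]])
    max(config$lactate_floor, stats::rlnorm(1, p[["meanlog"]], p[["sdlog"]]))
  }, numeric(1))
  stratum <- ifelse(apache > config$apache_cutoff, "high", "low")
  risk <- vapply(seq_len(n), function(i) config$shock_risk[[stratum[i]]][[et[i]]],
                 numeric(1))
  shock <- stats::runif(n) < risk
  carbapenem <- stats::runif(np) < 0.5
  site <- sample(c("lung", "abdomen", "blood", "urinary"), np, replace = TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.1))
  survive <- stats::runif(np) < 0.7

  metadata <- data.frame(
    sample_id = sample_id,
    patient_id = sprintf("P%02d", patient),
    day = day,
    status = ifelse(shock, "septic_shock", "sepsis"),
    apache_ii = apache, sofa = sofa, lactate = round(lact, 2),
    carbapenem_use = carbapenem[patient],
    infection_site = site[patient],
    survival_28d = survive[patient],
    stringsAsFactors = FALSE)
  truth <- data.frame(
    sample_id = sample_id,
    patient_id = metadata$patient_id,
    enterotype = et,
    stringsAsFactors = FALSE)
  for (d in names(config$drivers)) truth[[paste0("driver_", d)]] <- P[, d]
  structure(list(abundance = abundance, metadata = validate_clinical(metadata),
                 truth = truth, config = config, seed = seed),
            class = "synthetic_cohort")
}

#' Generate a single-enterotype null cohort
#'
#' One mixture component only: every sample draws its drivers from
#' parameters pooled across the two enterotypes (log-scale average), and all
#' clinical covariates are drawn independently of the microbiota. Serves as
#' the negative control for clustering diagnostics and association tests.
#'
#' @inheritParams generate_cohort
#' @return A `synthetic_cohort`; `truth$enterotype` is `"E0"` throughout.
#' @export
generate_null_cohort <- function(config = cohort_config(), seed = 1) {
  pooled <- config
  for (d in names(config$drivers)) {
    p1 <- lnorm_params(config$drivers[[d]]$ICU_E1[["mean"]],
                       config$drivers[[d]]$ICU_E1[["sd"]])
    p2 <- lnorm_params(config$drivers[[d]]$ICU_E2[["mean"]],
                       config$drivers[[d]]$ICU_E2[["sd"]])
    ml <- (p1[["meanlog"]] + p2[["meanlog"]]) / 2
    sl <- (p1[["sdlog"]] + p2[["sdlog"]]) / 2
    m <- exp(ml + sl^2 / 2); s <- m * sqrt(exp(sl^2) - 1)
    pooled$drivers[[d]]$ICU_E1 <- c(mean = m, sd = s)
    pooled$drivers[[d]]$ICU_E2 <- c(mean = m, sd = s)
  }
  lm1 <- config$lactate$ICU_E1; lm2 <- config$lactate$ICU_E2
  pooled$lactate$ICU_E1 <- pooled$lactate$ICU_E2 <-
    c(mean = mean(c(lm1[["mean"]], lm2[["mean"]])),
      sd = mean(c(lm1[["sd"]], lm2[["sd"]])))
  pr <- mean(unlist(config$shock_risk))
  pooled$shock_risk <- list(high = c(ICU_E1 = pr, ICU_E2 = pr),
                            low = c(ICU_E1 = pr, ICU_E2 = pr))
  out <- generate_cohort(pooled, seed)
  out$truth$enterotype <- "E0"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples / %d patients (seed %d)\n",
              nrow(x$abundance$values), length(unique(x$metadata$patient_id)),
              x$seed))
  print(table(truth = x$truth$enterotype))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Abundance TSV, metadata CSV and a clearly separated ground-truth TSV.
#'
#' @param x A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files (invisibly).
#' @export
write_cohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "abundance.tsv")
  p2 <- file.path(dir, "metadata.csv")
  p3 <- file.path(dir, "ground_truth.tsv")
  write_abundance_table(x$abundance, p1)
  utils::write.csv(x$metadata, p2, row.names = FALSE)
  utils::write.table(x$truth, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(abundance = p1, metadata = p2, truth = p3))
}

#' Tiny hand-checkable worked example
#'
#' Eight samples by six genera with round relative abundances, split into
#' two groups of four; every core quantity (JSD entries, PAM medoids, MHI
#' ratios) can be verified by hand or exhaustive enumeration.
#'
#' @return List with `table` (relative `abundance_table`), `labels`
#'   (factor), and a ready-made `biomarkers` set (2 numerator, 2 denominator
#'   genera).
#' @export
worked_example_fixture <- function() {
  lin <- c(
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides",
    "Bacteria;Firmicutes;Bacilli;Lactobacillales;Enterococcaceae;Enterococcus",
    "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacteriales;Enterobacteriaceae",
    "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus",
    "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacteriales;Enterobacteriaceae;Escherichia",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Ruminococcaceae;Faecalibacterium")
  v <- rbind(
    c(0.40, 0.05, 0.30, 0.05, 0.10, 0.10),
    c(0.50, 0.05, 0.25, 0.05, 0.05, 0.10),
    c(0.35, 0.10, 0.30, 0.05, 0.10, 0.10),
    c(0.45, 0.05, 0.20, 0.10, 0.10, 0.10),
    c(0.05, 0.40, 0.10, 0.20, 0.10, 0.15),
    c(0.10, 0.45, 0.05, 0.15, 0.10, 0.15),
    c(0.05, 0.35, 0.10, 0.25, 0.15, 0.10),
    c(0.10, 0.50, 0.05, 0.15, 0.10, 0.10))
  rownames(v) <- paste0("WX", 1:8)
  tab <- abundance_table(v, lin, mode = "relative")
  labels <- factor(rep(c("ICU_E1", "ICU_E2"), each = 4),
                   levels = c("ICU_E1", "ICU_E2"))
  names(labels) <- rownames(v)
  bm <- structure(list(
    e1_markers = c("g__Bacteroides", "g__Enterobacteriaceae*"),
    e2_markers = c("g__Enterococcus", "g__Lactobacillus"),
    provenance = NULL, classes = c("ICU_E1", "ICU_E2")),
    class = "biomarker_set")
  list(table = tab, labels = labels, biomarkers = bm)
}
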