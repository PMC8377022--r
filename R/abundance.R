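#' @keywords internal
"_PACKAGE"

TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Parse a semicolon-separated taxonomic lineage
#'
#' Lineages are ordered kingdom -> genus with ";" separating ranks. A lineage
#' may stop early (an OTU classified only to, say, family level); trailing
#' empty fields are treated as missing ranks.
#'
#' @param lineage Character vector of lineage strings.
#' @return A character matrix with one row per lineage and columns
#'   kingdom..genus; missing ranks are `NA`.
#' @export
parse_lineage <- function(lineage) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  out <- matrix(NA_character_, length(parts), length(TAXONOMIC_RANKS),
                dimnames = list(NULL, TAXONOMIC_RANKS))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- p[p != ""]
    if (length(p) > length(TAXONOMIC_RANKS))
      stop("lineage has more than ", length(TAXONOMIC_RANKS), " ranks: ", lineage[i])
    if (length(p)) out[i, seq_along(p)] <- p
  }
  out
}

#' Display name of a lineage at a given rank
#'
#' A taxon classified at `rank` is shown under its own name; a taxon
#' unclassified at that rank is shown as its nearest classified ancestor with
#' an asterisk marker (e.g. an OTU classified only to family
#' Enterobacteriaceae appears at genus rank as `"Enterobacteriaceae*"`).
#'
#' @param lineage Character vector of lineage strings.
#' @param rank One of kingdom, phylum, class, order, family, genus.
#' @return Character vector of display names.
#' @export
lineage_display_name <- function(lineage, rank = "genus") {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  m <- parse_lineage(lineage)
  ri <- match(rank, TAXONOMIC_RANKS)
  vapply(seq_len(nrow(m)), function(i) {
    row <- m[i, seq_len(ri)]
    if (!is.na(row[ri])) return(row[ri])
    anc <- row[!is.na(row)]
    if (!length(anc)) return("unclassified*")
    paste0(anc[length(anc)], "*")
  }, character(1))
}

truncate_lineage <- function(lineage, rank) {
  ri <- match(rank, TAXONOMIC_RANKS)
  m <- parse_lineage(lineage)
  vapply(seq_len(nrow(m)), function(i) {
    row <- m[i, seq_len(ri)]
    paste(row[!is.na(row)], collapse = ";")
  }, character(1))
}

#' Construct a taxonomic abundance table
#'
#' The substrate of every downstream stage: a samples x taxa matrix of
#' non-negative counts or relative abundances, with a taxonomic lineage per
#' column.
#'
#' @param values Numeric matrix, samples as rows; rownames are sample ids.
#' @param lineages Character vector of lineage strings, one per column.
#' @param mode "counts" or "relative". If missing, counts are auto-detected
#'   (all values integral).
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, lineages, mode = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(lineages) != ncol(values))
    stop("need one lineage per column (", ncol(values), "), got ", length(lineages))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(lineages))
    stop("duplicate taxa: ",
         paste(unique(lineages[duplicated(lineages)]), collapse = ", "))
  if (anyNA(values)) stop("abundance values contain NA")
  if (any(values < 0)) stop("abundance values must be non-negative")
  if (is.null(mode))
    mode <- if (all(abs(values - round(values)) < 1e-8)) "counts" else "relative"
  mode <- match.arg(mode, c("counts", "relative"))
  if (mode == "relative") {
    rs <- rowSums(values)
    bad <- which(abs(rs - 1) > 1e-9)
    if (length(bad))
      stop("relative abundance rows must sum to 1; offending samples: ",
           paste(rownames(values)[utils::head(bad, 5)], collapse = ", "))
  }
  colnames(values) <- lineage_display_name(lineages, deepest_rank(lineages))
  # display names can collide across distinct lineages (rare); disambiguate
  if (anyDuplicated(colnames(values)))
    colnames(values) <- make.unique(colnames(values), sep = "#")
  structure(list(values = values, lineages = as.character(lineages), mode = mode),
            class = "abundance_table")
}

deepest_rank <- function(lineages) {
  m <- parse_lineage(lineages)
  TAXONOMIC_RANKS[max(1L, max(rowSums(!is.na(m))))]
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s)\n",
              nrow(x$values), ncol(x$values), x$mode))
  cat("taxa:", paste(utils::head(colnames(x$values), 6), collapse = ", "),
      if (ncol(x$values) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

sample_ids <- function(x) rownames(x$values)

#' Read a taxonomic abundance table from TSV or BIOM
#'
#' TSV layout: first column the lineage string (";"-separated ranks), one
#' column per sample — or transposed (`samples_as_rows = TRUE`: first column
#' sample id, header row of lineages). BIOM 1.0 (JSON) is read through the
#' biomformat package with lineages taken from the observation ids.
#'
#' @param path File path.
#' @param format "tsv" or "biom".
#' @param samples_as_rows For TSV: whether samples are rows rather than columns.
#' @param mode Optional "counts"/"relative" override; default auto-detect.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, format = c("tsv", "biom"),
                                 samples_as_rows = FALSE, mode = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # taxa x samples
    return(abundance_table(t(m), rownames(m), mode = mode))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed abundance TSV (need id column plus data): ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path)
  rownames(m) <- ids
  if (samples_as_rows) abundance_table(m, colnames(m), mode = mode)
  else abundance_table(t(m), ids, mode = mode)
}

#' Write an abundance table as TSV (taxa as rows)
#' @param x An abundance_table.
#' @param path Output path.
#' @export
write_abundance_table <- function(x, path) {
  df <- data.frame(taxon = x$lineages, t(x$values), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Idempotent: an already-relative table is returned unchanged.
#'
#' @param x An abundance_table.
#' @return The table with `mode = "relative"`, rows summing to 1.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$mode == "relative") return(x)
  rs <- rowSums(x$values)
  if (any(rs == 0))
    stop("all-zero sample(s): ",
         paste(rownames(x$values)[rs == 0], collapse = ", "))
  abundance_table(x$values / rs, x$lineages, mode = "relative")
}

#' Aggregate an abundance table to a taxonomic rank
#'
#' Columns sharing a classified label at `rank` are summed; columns
#' unclassified at that rank are pooled under their nearest classified
#' ancestor suffixed with `*`. Per-sample totals are conserved.
#'
#' @param x An abundance_table.
#' @param rank Target rank (kingdom..genus).
#' @return An abundance_table at that rank.
#' @export
aggregate_to_rank <- function(x, rank) {
  stopifnot(inherits(x, "abundance_table"))
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  labels <- lineage_display_name(x$lineages, rank)
  newlin <- truncate_lineage(x$lineages, rank)
  # one merged column per display label; lineage of the group is the shared
  # truncated lineage
  groups <- split(seq_along(labels), labels)
  vals <- vapply(groups, function(ix) rowSums(x$values[, ix, drop = FALSE]),
                 numeric(nrow(x$values)))
  if (nrow(x$values) == 1L) vals <- matrix(vals, nrow = 1, dimnames = list(rownames(x$values), names(groups)))
  lin <- vapply(groups, function(ix) newlin[ix[1]], character(1))
  abundance_table(vals, lin, mode = x$mode)
}

#' Rarefy a count table to a fixed depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (via [vegan::rrarefy()]); samples with fewer than `depth` total reads are
#' dropped with a warning. Deterministic given `seed`.
#'
#' @param x An abundance_table in counts mode.
#' @param depth Target read depth (default 4000).
#' @param seed Integer RNG seed.
#' @return Rarefied counts table.
#' @export
rarefy <- function(x, depth = 4000, seed = 1) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$mode != "counts") stop("rarefy requires a counts table")
  if (depth <= 0) stop("depth must be positive")
  totals <- rowSums(x$values)
  keep <- totals >= depth
  if (!all(keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(utils::head(rownames(x$values)[!keep], 5), collapse = ", "))
  if (!any(keep)) stop("no sample reaches depth ", depth)
  v <- x$values[keep, , drop = FALSE]
  set.seed(seed)
  r <- suppressWarnings(vegan::rrarefy(v, depth))
  abundance_table(r, x$lineages, mode = "counts")
}

#' Alpha diversity (observed taxa and Shannon index) after rarefaction
#'
#' Richness is the number of taxa with nonzero rarefied counts; diversity is
#' the Shannon index on natural logarithms, -sum p_i ln p_i.
#'
#' @param x Counts abundance_table.
#' @param depth Rarefaction depth (default 4000 reads).
#' @param seed RNG seed for rarefaction.
#' @return data.frame with sample_id, observed_units, shannon.
#' @export
alpha_diversity <- function(x, depth = 4000, seed = 1) {
  r <- rarefy(x, depth, seed)
  data.frame(
    sample_id = rownames(r$values),
    observed_units = as.integer(rowSums(r$values > 0)),
    shannon = as.numeric(vegan::diversity(r$values, index = "shannon")),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Read per-sample clinical metadata
#'
#' Expects columns sample_id, patient_id, day, status, apache_ii, sofa,
#' lactate, carbapenem_use, infection_site, survival_28d; extra numeric
#' columns are carried through.
#'
#' @param path CSV (or TSV) file path.
#' @return Validated data.frame, one row per sample.
#' @export
read_clinical_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_clinical(df)
}

validate_clinical <- function(df) {
  need <- c("sample_id", "patient_id", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  for (col in intersect(c("apache_ii", "sofa", "lactate"), names(df))) {
    v <- df[[col]]
    if (any(v < 0, na.rm = TRUE)) stop(col, " must be non-negative")
  }
  bad <- setdiff(unique(df$status), c("sepsis", "septic_shock"))
  if (length(bad)) stop("unknown status values: ", paste(bad, collapse = ", "))
  df
}
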