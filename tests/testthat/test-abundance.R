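test_that("TSV round-trip preserves the table and bad input is rejected", {
  tab <- random_count_table(1, n = 3, t = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, f)
  back <- read_abundance_table(f)
  expect_equal(dim(back), c(3, 4))
  expect_tables_equal(tab, back)

  bad <- data.frame(taxon = c("Bacteria;X", "Bacteria;Y"),
                    S1 = c(1, -2), S2 = c(3, 4))
  fb <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, fb, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_abundance_table(fb), "non-negative")

  expect_error(abundance_table(matrix(1, 2, 1, dimnames = list(c("a", "a"), NULL)),
                               "Bacteria;X"), "duplicate sample")
})

test_that("BIOM and TSV encodings of one table read back identically", {
  skip_if_not_installed("biomformat")
  tab <- random_count_table(2, n = 4, t = 5)
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  fbiom <- withr::local_tempfile(fileext = ".biom")
  write_abundance_table(tab, ftsv)
  m <- t(tab$values)
  rownames(m) <- tab$lineages
  biomformat::write_biom(biomformat::make_biom(m), fbiom)
  expect_tables_equal(read_abundance_table(ftsv),
                      read_abundance_table(fbiom, format = "biom"))
})

test_that("to_relative normalizes rows, errors on empty samples, idempotent", {
  tab <- abundance_table(matrix(c(2, 2, 0, 4), 1, dimnames = list("s1", NULL)),
                         paste0("Bacteria;P;C;O;F;G", 1:4), mode = "counts")
  rel <- to_relative(tab)
  expect_equal(unname(rel$values[1, ]), c(0.25, 0.25, 0, 0.5))
  expect_identical(to_relative(rel), rel)

  zero <- abundance_table(rbind(s1 = c(1, 1), s2 = c(0, 0)),
                          c("Bacteria;A", "Bacteria;B"), mode = "counts")
  expect_error(to_relative(zero), "s2")

  for (seed in 1:100) {
    r <- to_relative(random_count_table(seed))
    expect_true(all(abs(rowSums(r$values) - 1) < 1e-9))
  }
})

test_that("rank aggregation merges duplicates, marks unclassified, conserves totals", {
  lin <- c("Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides",
           "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides2",
           "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacteriales;Enterobacteriaceae")
  tab <- abundance_table(rbind(s1 = c(3, 5, 2), s2 = c(1, 0, 4)), lin,
                         mode = "counts")
  g <- aggregate_to_rank(tab, "genus")
  expect_true("Enterobacteriaceae*" %in% colnames(g$values))
  p <- aggregate_to_rank(tab, "phylum")
  expect_equal(sort(colnames(p$values)), c("Bacteroidetes", "Proteobacteria"))
  expect_equal(unname(p$values[, "Bacteroidetes"]), c(8, 1))

  expect_error(aggregate_to_rank(tab, "species"))

  for (seed in 1:20) {
    t0 <- random_count_table(seed, n = 4, t = 8)
    for (r in c("phylum", "family", "genus"))
      expect_equal(rowSums(aggregate_to_rank(t0, r)$values),
                   rowSums(t0$values), tolerance = 1e-9)
  }
})

test_that("genus duplicates merge by summation", {
  lin <- c("Bacteria;F1;C;O;Fam;GenA", "Bacteria;F1;C;O;Fam2;GenA",
           "Bacteria;F1;C;O;Fam;GenB")
  tab <- abundance_table(rbind(s1 = c(1, 2, 3)), lin, mode = "counts")
  g <- aggregate_to_rank(tab, "genus")
  expect_equal(ncol(g$values), 2)
  expect_equal(unname(g$values[1, "GenA"]), 3)
})

test_that("rarefaction hits exact depth, drops shallow samples, matches the hypergeometric mean", {
  tab <- random_count_table(3, n = 3, t = 5)
  depth <- min(rowSums(tab$values))
  r <- rarefy(tab, depth, seed = 1)
  expect_true(all(rowSums(r$values) == depth))
  # the sample sitting exactly at depth is untouched
  at <- which(rowSums(tab$values) == depth)
  if (length(at))
    expect_equal(r$values[at, ], tab$values[at, ])

  expect_warning(r2 <- rarefy(tab, depth + 1, seed = 1), "dropped")
  expect_false(rownames(tab$values)[which.min(rowSums(tab$values))]
               %in% rownames(r2$values))
  expect_error(rarefy(tab, 0), "positive")

  counts <- c(50, 30, 15, 5)
  one <- abundance_table(matrix(counts, 1, dimnames = list("s", NULL)),
                         paste0("Bacteria;G", 1:4), mode = "counts")
  draws <- t(vapply(1:1000, function(s) rarefy(one, 40, seed = s)$values[1, ],
                    numeric(4)))
  hyper_mean <- 40 * counts / sum(counts)
  hyper_var <- 40 * (counts / 100) * (1 - counts / 100) * (100 - 40) / 99
  se <- sqrt(hyper_var / 1000)
  expect_true(all(abs(colMeans(draws) - hyper_mean) < 3 * se + 1e-9))
})

test_that("alpha diversity matches the Shannon formula and its invariances", {
  eq <- abundance_table(matrix(rep(100, 4), 1, dimnames = list("s", NULL)),
                        paste0("Bacteria;G", 1:4), mode = "counts")
  a <- alpha_diversity(eq, depth = 400, seed = 1)
  expect_equal(a$shannon, log(4), tolerance = 1e-12)
  expect_equal(a$observed_units, 4L)

  single <- abundance_table(matrix(c(500, 0), 1, dimnames = list("s", NULL)),
                            c("Bacteria;G1", "Bacteria;G2"), mode = "counts")
  a1 <- alpha_diversity(single, depth = 500, seed = 1)
  expect_equal(a1$observed_units, 1L)
  expect_equal(a1$shannon, 0)

  counts <- c(1, 2, 3, 4)
  tab <- abundance_table(matrix(counts, 1, dimnames = list("s", NULL)),
                         paste0("Bacteria;G", 1:4), mode = "counts")
  a2 <- alpha_diversity(tab, depth = 10, seed = 1)
  p <- counts / 10
  expect_equal(a2$shannon, -sum(p * log(p)), tolerance = 1e-12)

  perm <- abundance_table(matrix(counts[c(3, 1, 4, 2)], 1,
                                 dimnames = list("s", NULL)),
                          paste0("Bacteria;G", 1:4), mode = "counts")
  expect_equal(alpha_diversity(perm, 10, 1)$shannon, a2$shannon)
})

test_that("clinical metadata reader validates and round-trips", {
  md <- generate_cohort(cohort_config(), seed = 2)$metadata
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(md, f, row.names = FALSE)
  back <- read_clinical_metadata(f)
  expect_equal(back$sample_id, md$sample_id)
  expect_equal(back$lactate, md$lactate)

  md2 <- md; md2$lactate[1] <- -1
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(md2, f2, row.names = FALSE)
  expect_error(read_clinical_metadata(f2), "non-negative")
})
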