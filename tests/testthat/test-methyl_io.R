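test_that("coverage rows parse into counts, with zero-coverage retained as missing", {
  f <- tempfile(fileext = ".cov")
  writeLines(c("chr1\t100\t100\t75.0\t3\t1",
               "chr1\t200\t200\t0.0\t0\t0"), f)
  x <- read_coverage_file(f, "s1")
  expect_equal(x$pos, c(100L, 200L))
  expect_equal(x$methylated, c(3L, 0L))
  expect_equal(x$total, c(4L, 0L))
  expect_identical(attr(x, "sample_id"), "s1")
})

test_that("malformed rows and inconsistent percentages are reported by line", {
  f <- tempfile(fileext = ".cov")
  writeLines(c("chr1\t100\t100\t75.0\t3\t1", "chr1\t200\t200\t50.0"), f)
  expect_error(read_coverage_file(f, "s1"), "line 2")
  writeLines(c("chr1\t100\t100\t10.0\t3\t1"), f)  # 10% printed, 75% actual
  expect_warning(read_coverage_file(f, "s1"), "inconsistent")
})

test_that("a large synthetic file matches a line-by-line text oracle exactly", {
  df <- random_cov_df(1000, seed = 11)
  f <- write_cov_lines(df, tempfile(fileext = ".cov"))
  x <- read_coverage_file(f, "s1")
  # oracle: independent parse of the raw text
  raw <- strsplit(readLines(f), "\t", fixed = TRUE)
  o_meth <- vapply(raw, function(r) as.integer(r[5]), 1L)
  o_tot <- vapply(raw, function(r) as.integer(r[5]) + as.integer(r[6]), 1L)
  expect_identical(x$methylated, o_meth)
  expect_identical(x$total, o_tot)
  ratio <- x$methylated / x$total
  o_ratio <- o_meth / o_tot
  expect_identical(ratio, o_ratio)
})

test_that("coverage files round-trip bit-exactly through write and read", {
  df <- random_cov_df(200, seed = 3)
  f1 <- write_cov_lines(df, tempfile(fileext = ".cov"))
  x <- read_coverage_file(f1, "s1")
  f2 <- tempfile(fileext = ".cov")
  write_coverage_file(x, f2)
  y <- read_coverage_file(f2, "s1")
  expect_identical(x$methylated, y$methylated)
  expect_identical(x$total, y$total)
  expect_identical(x$pos, y$pos)
})

test_that("strand collapsing sums adjacent pairs, is idempotent and conserves reads", {
  x <- data.frame(chrom = "chr1", pos = c(100L, 101L),
                  methylated = c(2L, 1L), total = c(4L, 2L))
  c1 <- collapse_strands(x)
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$pos, 100L)
  expect_equal(c1$methylated, 3L)
  expect_equal(c1$total, 6L)
  expect_identical(collapse_strands(c1)$total, c1$total)

  set.seed(5)
  base <- sort(sample(seq(1, 1e5, by = 3), 300))  # spaced: pairs never chain
  paired <- sample(c(TRUE, FALSE), 300, replace = TRUE)
  pos <- sort(c(base, base[paired] + 1L))
  rnd <- data.frame(chrom = "chr1", pos = pos,
                    methylated = rbinom(length(pos), 20, 0.5),
                    total = 20L)
  cc <- collapse_strands(rnd)
  expect_equal(sum(cc$total), sum(rnd$total))
  expect_equal(sum(cc$methylated), sum(rnd$methylated))
  expect_false(any(duplicated(cc$pos)))
})

test_that("assemble_dataset takes the union of sites and flags absentees as missing", {
  d <- tempfile(); dir.create(d)
  a <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                  pct = 50, meth = 2L, unmeth = 2L)
  b <- a[1:3, ]
  fa <- write_cov_lines(a, file.path(d, "a.cov"))
  fb <- write_cov_lines(b, file.path(d, "b.cov"))
  meta <- tiny_metadata(c("a", "b"))
  ds <- assemble_dataset(c(a = fa, b = fb), meta)
  expect_equal(nrow(ds$sites), 4L)
  expect_equal(sum(ds$total == 0), 1L)
  expect_true(is.na(get_ratios(ds)["chr1:40", "b"]))

  expect_error(assemble_dataset(c(a = fa, b = fb), meta[1, ]), "b")
  expect_error(assemble_dataset(c(a = fa, b = fb, a = fa), meta), "duplicate")
})

test_that("assembly is invariant to input file order and matches per-file row counts", {
  co <- simulate_cohort(cohort_spec(n_individuals = 5, n_sites = 120,
                                    longitudinal_frac = 0, seed = 8))
  d <- tempfile()
  fx <- write_fixture(co, d)
  ds1 <- assemble_dataset(fx$coverage, fx$metadata)
  ds2 <- assemble_dataset(rev(fx$coverage), fx$metadata)
  o <- match(ds1$samples$sample_id, ds2$samples$sample_id)
  expect_identical(ds1$meth, ds2$meth[, o])
  expect_identical(ds1$sites, ds2$sites)
  # per-sample non-missing counts equal per-file row counts with total > 0
  for (id in names(fx$coverage)) {
    n_rows <- length(readLines(fx$coverage[[id]]))
    expect_equal(sum(ds1$total[, id] > 0), n_rows)
  }
})

test_that("dataset archives round-trip losslessly", {
  co <- simulate_cohort(cohort_spec(n_individuals = 4, n_sites = 60, seed = 2))
  d <- tempfile()
  write_dataset(co$dataset, d)
  back <- read_dataset(d)
  expect_identical(back$meth, co$dataset$meth)
  expect_identical(back$total, co$dataset$total)
  expect_equal(back$samples$age_years, co$dataset$samples$age_years)
})

test_that("BED intervals convert to 1-based inclusive and BED12 TSS is strand-aware", {
  f <- tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000", f)
  iv <- read_intervals(f, "bed")
  expect_equal(iv$start, 1000L)
  expect_equal(iv$end, 2000L)

  g <- tempfile(fileext = ".bed")
  writeLines(paste("chr1", 999, 5000, "gminus", 0, "-", 999, 5000, "0",
                   "2", "500,1000", "0,3001", sep = "\t"), g)
  gm <- read_intervals(g, "bed12")
  expect_equal(gm$start, 1000L)
  expect_equal(gm$end, 5000L)
  expect_equal(gm$tss, 5000L)  # minus strand: TSS at the gene end
  expect_equal(nrow(gm$exons[[1]]), 2L)
  expect_equal(gm$exons[[1]]$start[1], 1000L)
  expect_equal(gm$exons[[1]]$end[2], 5000L)
})

test_that("inconsistent BED12 blocks raise an error", {
  g <- tempfile(fileext = ".bed")
  # last block ends short of chromEnd
  writeLines(paste("chr1", 999, 5000, "bad", 0, "+", 999, 5000, "0",
                   "2", "500,1000", "0,2000", sep = "\t"), g)
  expect_error(read_intervals(g, "bed12"), "inconsistent")
})

test_that("island membership agrees with a linear-scan oracle at random positions", {
  ann <- simulate_annotation(n_islands = 50, seed = 4)
  f <- tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d", ann$islands$chrom,
                     ann$islands$start - 1L, ann$islands$end), f)
  iv <- read_intervals(f, "bed")
  set.seed(9)
  q_chr <- sample(iv$chrom, 1000, replace = TRUE)
  q_pos <- sample.int(5e7, 1000)
  member <- classify_density(data.frame(chrom = q_chr, pos = q_pos), iv) == "island"
  oracle <- vapply(seq_len(1000), function(i) {
    any(iv$chrom == q_chr[i] & iv$start <= q_pos[i] & iv$end >= q_pos[i])
  }, logical(1))
  expect_identical(member, oracle)
})
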