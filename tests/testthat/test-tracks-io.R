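test_that("chrom.sizes parsing validates input and preserves order", {
  f <- withr::local_tempfile()
  writeLines("chr3LHet\t2555491", f)
  cs <- read_chrom_sizes(f)
  expect_equal(unclass(cs), c(chr3LHet = 2555491))

  writeLines(c("chrB 400", "chrA 1000"), f)
  expect_equal(names(read_chrom_sizes(f)), c("chrB", "chrA"))

  writeLines(character(0), f)
  expect_error(read_chrom_sizes(f), "no chromosomes")

  writeLines(c("chrA 100", "chrA 200"), f)
  expect_error(read_chrom_sizes(f), "line 2.*duplicate")

  writeLines(c("chrA 100", "chrB 0"), f)
  expect_error(read_chrom_sizes(f), "line 2.*non-positive")

  writeLines(c("chrA 100", "chrB"), f)
  expect_error(read_chrom_sizes(f), "line 2")
})

test_that("BED reading validates intervals and skips non-data lines", {
  sizes <- tiny_sizes()
  f <- withr::local_tempfile()
  writeLines(c("# a comment", "track name=x", "chrA\t0\t100\tgeneX",
               "chrA\t150\t250\tgeneY", "chrB\t10\t20\tgeneZ"), f)
  gr <- read_bed(f, sizes)
  expect_length(gr, 3)
  expect_equal(start(gr), c(1, 151, 11))
  expect_equal(end(gr), c(100, 250, 20))
  expect_equal(mcols(gr)$name, c("geneX", "geneY", "geneZ"))

  writeLines("chrA\t100\t100", f)
  expect_error(read_bed(f, sizes), "line 1.*empty interval")

  writeLines("chrZ\t0\t10", f)
  expect_error(read_bed(f, sizes), "unknown chromosome")
  expect_length(read_bed(f, sizes, skip_unknown = TRUE), 0)

  writeLines("chrB\t0\t500", f)
  expect_error(read_bed(f, sizes), "beyond chromosome")
})

test_that("BED write/read round-trip is the identity", {
  sizes <- tiny_sizes()
  f <- withr::local_tempfile()

  write_bed(GRanges(), f)
  expect_length(read_bed(f, sizes), 0)

  gr <- random_intervals(sizes, 100, seed = 7)
  write_bed(gr, f)
  back <- read_bed(f, sizes)
  expect_equal(as.character(seqnames(back)), as.character(seqnames(gr)))
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(mcols(back)$name, mcols(gr)$name)

  # strand and score survive the trip
  gr6 <- GRanges("chrA", IRanges(5, 50), strand = "-",
                 name = "x", score = 3.5)
  write_bed(gr6, f)
  back6 <- read_bed(f, sizes)
  expect_equal(as.character(strand(back6)), "-")
  expect_equal(mcols(back6)$score, 3.5)
})

test_that("bin grid has ceiling bin counts, short terminal bins, and a
          bijective ordinal mapping", {
  expect_equal(bin_genome(chrom_sizes(c(chrA = 1000)), 200)$n_bins, 5)
  g6 <- bin_genome(chrom_sizes(c(chrA = 1001)), 200)
  expect_equal(g6$n_bins, 6)
  last <- bin_locate(g6, 6)
  expect_equal(last$end - last$start, 1)  # 1-bp terminal bin kept

  g <- bin_genome(tiny_sizes(), 200)
  expect_equal(g$n_bins, 7)
  expect_equal(bin_ordinal(g, "chrB", 1:2), c(6, 7))

  # bijection: invert every global ordinal
  loc <- bin_locate(g, seq_len(g$n_bins))
  expect_equal(bin_ordinal(g, loc$chrom, loc$local), seq_len(g$n_bins))
  expect_error(bin_genome(tiny_sizes(), 0), "positive")
})

test_that("interval projection onto bins matches a per-bp oracle", {
  g <- bin_genome(tiny_sizes(), 200)

  # exactly bin 3 of chrA (0-based bp 400-600)
  one <- GRanges("chrA", IRanges(401, 600))
  tr <- intervals_to_track(one, g, mode = "presence")
  expect_equal(tr$values, c(0, 0, 1, 0, 0, 0, 0))

  half <- GRanges("chrA", IRanges(1, 100))
  expect_equal(intervals_to_track(half, g, "coverage_fraction")$values[1],
               0.5)

  gr <- random_intervals(tiny_sizes(), 60, seed = 3, named = FALSE)
  frac <- intervals_to_track(gr, g, "coverage_fraction")
  pres <- intervals_to_track(gr, g, "presence")

  # brute-force per-bp oracle
  for (ch in names(g$sizes)) {
    covered <- logical(g$sizes[[ch]])
    sub <- gr[seqnames(gr) == ch]
    for (i in seq_along(sub))
      covered[start(sub)[i]:end(sub)[i]] <- TRUE
    for (b in seq_len(g$n_per_chrom[[ch]])) {
      bp <- ((b - 1) * 200 + 1):min(b * 200, g$sizes[[ch]])
      expect_equal(frac$values[g$offset[[ch]] + b],
                   mean(covered[bp]), tolerance = 1e-12)
    }
  }
  # presence equals (coverage_fraction > 0); bp totals conserved
  expect_equal(pres$values, as.numeric(frac$values > 0))
  widths <- bin_locate(g, seq_len(g$n_bins))
  expect_equal(sum(frac$values * (widths$end - widths$start)),
               sum(width(reduce(gr))))
})

test_that("bedGraph values are aggregated bp-weighted per bin", {
  g <- bin_genome(tiny_sizes(), 200)
  f <- withr::local_tempfile()

  writeLines("chrA\t200\t400\t3.5", f)
  tr <- read_bedgraph(f, g)
  expect_equal(tr$values[2], 3.5)
  expect_equal(tr$mask, c(FALSE, TRUE, rep(FALSE, 5)))

  writeLines(c("chrA\t0\t100\t2", "chrA\t100\t200\t4"), f)
  expect_equal(read_bedgraph(f, g)$values[1], 3.0)

  # random disjoint records vs per-bp weighted-mean oracle
  set.seed(11)
  starts <- seq(0, 960, by = 40)
  ends <- starts + sample(10:40, length(starts), replace = TRUE)
  vals <- round(runif(length(starts), -5, 5), 3)
  writeLines(sprintf("chrA\t%d\t%d\t%g", starts, ends, vals), f)
  tr <- read_bedgraph(f, g, aggregate = "mean")
  bp_val <- rep(NA_real_, 1000)
  for (i in seq_along(starts))
    bp_val[(starts[i] + 1):ends[i]] <- vals[i]
  for (b in 1:5) {
    bp <- ((b - 1) * 200 + 1):(b * 200)
    expect_equal(tr$values[b], mean(bp_val[bp], na.rm = TRUE),
                 tolerance = 1e-9)
  }
  trmax <- read_bedgraph(f, g, aggregate = "max")
  for (b in 1:5) {
    bp <- ((b - 1) * 200 + 1):(b * 200)
    expect_equal(trmax$values[b], max(bp_val[bp], na.rm = TRUE))
  }

  writeLines("chrA\t10\t5\t1", f)
  expect_error(read_bedgraph(f, g), "line 1")
})

test_that("gap masking removes bins overlapping gap intervals", {
  g <- bin_genome(tiny_sizes(), 200)
  tr <- intervals_to_track(GRanges("chrA", IRanges(1, 1000)), g,
                           "presence")
  masked <- mask_gaps(tr, GRanges("chrA", IRanges(450, 460)))
  expect_equal(masked$mask, c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
})
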