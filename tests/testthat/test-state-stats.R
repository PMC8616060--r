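test_that("state proportions match a per-bp tally and sum to one", {
  g <- bin_genome(chrom_sizes(c(chrA = 2000)), 200)

  seg1 <- path_to_segmentation(rep(1L, 10), g, labels = "only")
  p1 <- state_proportions(seg1)
  expect_equal(as.numeric(p1), 1)

  seg2 <- path_to_segmentation(rep(c(1L, 2L), each = 5), g,
                               labels = c("a", "b"))
  p2 <- state_proportions(seg2, GRanges("chrA", IRanges(1, 2000)))
  expect_equal(unclass(p2), c(a = 0.5, b = 0.5), ignore_attr = TRUE)

  # random segmentation and regions versus a per-bp oracle
  set.seed(13)
  path <- sample(1:3, 10, replace = TRUE)
  seg3 <- path_to_segmentation(path, g, labels = c("x", "y", "z"))
  regions <- GRanges("chrA", IRanges(c(101, 901), c(450, 1700)))
  p3 <- state_proportions(seg3, regions)
  lab_bp <- rep(c("x", "y", "z")[path], each = 200)
  in_reg <- logical(2000)
  in_reg[c(101:450, 901:1700)] <- TRUE
  oracle <- table(lab_bp[in_reg]) / sum(in_reg)
  expect_equal(unclass(p3)[names(oracle)], c(oracle),
               ignore_attr = TRUE)
  expect_equal(sum(p3), 1, tolerance = 1e-9)

  expect_error(state_proportions(seg2, GRanges("chrA",
                                               IRanges(2001, 2002))),
               "no segmented bp")
})

test_that("the Mann-Whitney U test takes the exact path for small
          untied samples and matches full enumeration", {
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p_value, 0.99)

  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p_value, 0.1)
  expect_true(sep$exact)

  # random small samples: exact path equals permutation enumeration
  set.seed(19)
  for (rep in 1:10) {
    pool <- sample(seq(0.1, 99.9, by = 0.1), 9)
    x <- pool[1:4]
    y <- pool[5:9]
    got <- mann_whitney_u(x, y)
    expect_true(got$exact)
    expect_equal(got$p_value, perm_mw_p(x, y), tolerance = 1e-12)
    # invariance under a strictly monotone transform of the pooled data
    expect_equal(mann_whitney_u(exp(x / 50), exp(y / 50))$p_value,
                 got$p_value)
    # swapping the samples leaves the two-sided p unchanged
    expect_equal(mann_whitney_u(y, x)$p_value, got$p_value)
  }

  # large/tied samples take the corrected normal approximation
  big <- mann_whitney_u(rep(1:10, 3), rep(2:11, 3))
  expect_false(big$exact)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("pairwise rank-sum matrix is symmetric with unit diagonal and
          flags only truly shifted pairs", {
  set.seed(23)
  base <- rnorm(50)
  samples <- list(s1 = base, s2 = base, s3 = base + 10)  # shift >> SD
  p <- pairwise_wilcoxon(samples)
  expect_equal(p, t(p))
  expect_equal(diag(p), c(s1 = 1, s2 = 1, s3 = 1))
  expect_gte(p["s1", "s2"], 0.99)
  expect_lt(p["s1", "s3"], 0.001)
  expect_lt(p["s2", "s3"], 0.001)
  expect_error(pairwise_wilcoxon(list(a = 1:3)), "at least two")
})

test_that("enrichment effect sizes and significance calls behave on
          constructed tracks", {
  g <- bin_genome(chrom_sizes(c(chrA = 100000)), 200)
  n <- g$n_bins  # 500 bins
  path <- rep(c(1L, 2L), each = n / 2)
  seg <- path_to_segmentation(path, g, labels = c("stateA", "stateB"))
  whole <- GRanges("chrA", IRanges(1, 100000))
  half2 <- GRanges("chrA", IRanges(50001, 100000))

  # identical values everywhere: zero enrichment, nothing significant
  flat <- signal_track("flat", rep(2, n), grid = g)
  et <- enrichment_table(list(flat), seg, whole, whole, alpha = 0.001)
  expect_equal(et$log2_enrichment, c(0, 0))
  expect_false(any(et$significant))

  # mean doubled inside stateA relative to a stateB background
  dbl <- signal_track("dbl", ifelse(path == 1L, 2, 1), grid = g)
  et2 <- enrichment_table(list(dbl), seg, whole, half2, alpha = 0.001)
  expect_equal(et2$log2_enrichment[et2$state == "stateA"], 1.0)

  # a 5-SD shift confined to one state is called at p < 0.001 there
  # and nowhere else (>= 100 bins per side)
  set.seed(41)
  shifted <- signal_track("sh", rnorm(n) + 5 * (path == 1L), grid = g)
  et3 <- enrichment_table(list(shifted), seg, whole, half2,
                          alpha = 0.001)
  expect_true(et3$significant[et3$state == "stateA"])
  expect_false(et3$significant[et3$state == "stateB"])
  expect_true(all(et3$n_in >= 100))

  # shuffling the segment labels (fixed seed) kills the signal
  set.seed(42)
  mix <- sample(path)
  seg_mix <- path_to_segmentation(mix, g, labels = c("stateA", "stateB"))
  et4 <- enrichment_table(list(shifted), seg_mix, whole, whole,
                          alpha = 0.001)
  expect_false(any(et4$significant))
})

test_that("empty state-compartment combinations are flagged, not
          errors", {
  g <- bin_genome(chrom_sizes(c(chrA = 2000)), 200)
  seg <- path_to_segmentation(rep(1:2, each = 5), g,
                              labels = c("a", "b"))
  first_half <- GRanges("chrA", IRanges(1, 1000))  # only state "a"
  tr <- signal_track("t", rnorm(10), grid = g)
  et <- enrichment_table(list(tr), seg, first_half, first_half)
  row_b <- et[et$state == "b", ]
  expect_equal(row_b$flag, "empty_sample")
  expect_true(is.na(row_b$p_value))
})

test_that("report TSVs carry commented metadata headers", {
  df <- data.frame(a = 1:2, b = c("x", "y"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(df, f, meta = list(alpha = 0.001, seed = 17))
  lines <- readLines(f)
  expect_true(any(grepl("^# alpha: 0.001", lines)))
  expect_true(any(grepl("^# seed: 17", lines)))
  body <- read.table(f, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(body$a, 1:2)
})
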