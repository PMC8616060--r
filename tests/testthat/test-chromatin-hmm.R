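test_that("quantile binarization uses linear interpolation and a strict
          threshold", {
  g <- bin_genome(chrom_sizes(c(chrA = 2000)), 200)

  const <- signal_track("c", rep(5, 10), grid = g)
  b <- binarize(const, 0.9)
  expect_equal(b$threshold, 5)
  expect_equal(b$bits, rep(0L, 10))  # strict > : constant track all 0

  ramp <- signal_track("r", 1:10, grid = g)
  b <- binarize(ramp, 0.9)
  expect_equal(b$threshold, 9.1)
  expect_equal(b$bits, c(rep(0L, 9), 1L))

  pres <- signal_track("p", c(0, 1, 1, 0, 1, 0, 0, 1, 0, 1), grid = g)
  expect_equal(binarize(pres, 0.5)$bits, as.integer(pres$values))

  allmask <- signal_track("m", rep(0, 10), mask = rep(FALSE, 10),
                          grid = g)
  expect_error(binarize(allmask, 0.9), "masked")
})

test_that("stacking tracks ANDs masks and preserves order", {
  g <- bin_genome(chrom_sizes(c(chrA = 1000)), 200)
  mk <- function(id, bits, mask = rep(TRUE, 5)) {
    structure(list(track_id = id, bits = as.integer(bits),
                   threshold = 0.5, mask = mask, grid = g),
              class = "binary_track")
  }
  one <- stack_tracks(list(mk("a", c(1, 0, 1, 0, 1))))
  expect_equal(dim(one$data), c(1L, 5L))

  two <- stack_tracks(list(mk("a", rep(1, 5)),
                           mk("b", rep(0, 5),
                              mask = c(TRUE, FALSE, TRUE, TRUE, TRUE))))
  expect_equal(two$mask, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(two$track_ids, c("a", "b"))

  fourteen <- stack_tracks(lapply(sprintf("t%02d", 1:14), mk,
                                  bits = c(1, 0, 1, 0, 1)))
  expect_equal(nrow(fourteen$data), 14L)

  g2 <- bin_genome(chrom_sizes(c(chrA = 1200)), 200)
  bad <- structure(list(track_id = "x", bits = rep(0L, 6),
                        threshold = 0, mask = rep(TRUE, 6), grid = g2),
                   class = "binary_track")
  expect_error(stack_tracks(list(mk("a", rep(0, 5)), bad)),
               "differing bin counts")
})

test_that("K=1 training gives the closed-form model", {
  obs <- random_obs(3, 40, seed = 2)
  m <- train_hmm(obs, K = 1, seed = 1)
  expect_equal(m$transitions, matrix(1, 1, 1))
  expect_equal(as.numeric(m$emissions), unname(rowMeans(obs$data)),
               tolerance = 1e-5)
})

test_that("EM log-likelihood is non-decreasing and the model stays
          row-stochastic", {
  obs <- random_obs(4, 300, seed = 9)
  lls <- vapply(1:4, function(it)
    train_hmm(obs, K = 3, seed = 5, n_restarts = 1,
              max_iter = it)$log_likelihood, 0)
  expect_true(all(diff(lls) >= -1e-8))

  m <- train_hmm(obs, K = 3, seed = 5, n_restarts = 2)
  expect_equal(rowSums(m$transitions), rep(1, 3), tolerance = 1e-9)
  expect_equal(sum(m$initial), 1, tolerance = 1e-9)
  expect_true(all(m$emissions >= 0 & m$emissions <= 1))
})

test_that("forward likelihood equals brute-force path enumeration", {
  for (seed in 1:4) {
    K <- sample(2:3, 1)
    T_ <- sample(4:8, 1)
    model <- random_hmm(K, 2, seed)
    obs <- random_obs(2, T_, seed + 100)
    model$track_ids <- obs$track_ids
    colnames(model$emissions) <- obs$track_ids
    expect_equal(forward_loglik(model, obs),
                 brute_force_loglik(model, obs$data),
                 tolerance = 1e-9)
  }
})

test_that("Viterbi decoding matches exhaustive maximization", {
  # T = 1: argmax over initial x emission
  model <- random_hmm(3, 2, seed = 21)
  obs1 <- random_obs(2, 1, seed = 22)
  model$track_ids <- obs1$track_ids
  colnames(model$emissions) <- obs1$track_ids
  lik <- model$initial *
    apply(model$emissions, 1, function(e)
      prod(ifelse(obs1$data[, 1] == 1, e, 1 - e)))
  expect_equal(viterbi_decode(model, obs1)$states, which.max(lik))

  # the decoded path achieves the exhaustively-maximized log-
  # probability (multiple optimal paths may tie; the objective is
  # what Viterbi guarantees)
  for (seed in 5:8) {
    model <- random_hmm(3, 2, seed)
    obs <- random_obs(2, 8, seed + 50)
    model$track_ids <- obs$track_ids
    colnames(model$emissions) <- obs$track_ids
    bf <- brute_force_viterbi(model, obs$data)
    dec <- viterbi_decode(model, obs)$states
    expect_equal(path_logprob(model, obs$data, dec), bf$loglik,
                 tolerance = 1e-9)
  }

  # full symmetry: every path ties, decoding picks the lowest index
  E <- matrix(0.5, 2, 2)
  sym <- chromatin_hmm(c(0.5, 0.5), matrix(0.5, 2, 2), E, c("t1", "t2"))
  obs <- random_obs(2, 6, seed = 3)
  expect_equal(viterbi_decode(sym, obs)$states, rep(1L, 6))
})

test_that("a near-deterministic model decodes its own pattern and masked
          gaps restart the chain", {
  # delta-like emissions: state 1 emits track on, state 2 emits off
  E <- matrix(c(0.999, 0.001), 2, 1)
  A <- matrix(c(0.999, 0.001, 0.001, 0.999), 2, 2, byrow = TRUE)
  model <- chromatin_hmm(c(0.5, 0.5), A, E, "t1")
  pattern <- c(1, 1, 1, 2, 2, 2, 1, 1)
  obs <- binary_tracks("t1", matrix(as.integer(pattern == 1), 1),
                       rep(TRUE, 8))
  expect_equal(viterbi_decode(model, obs)$states, pattern)

  # a masked gap splits decoding into independent segments
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)
  obs_gap <- binary_tracks("t1", obs$data, mask)
  dec <- viterbi_decode(model, obs_gap)
  expect_true(all(is.na(dec$states[4:5])))
  left <- binary_tracks("t1", obs$data[, 1:3, drop = FALSE],
                        rep(TRUE, 3))
  right <- binary_tracks("t1", obs$data[, 6:8, drop = FALSE],
                         rep(TRUE, 3))
  expect_equal(dec$states[1:3], viterbi_decode(model, left)$states)
  expect_equal(dec$states[6:8], viterbi_decode(model, right)$states)

  expect_error(viterbi_decode(model, binary_tracks("zz", obs$data,
                                                   rep(TRUE, 8))),
               "track ids")
})

test_that("state labelling follows the marker rules and is
          order-invariant", {
  E <- rbind(c(0.90, 0.50), c(0.20, 0.80), c(0.05, 0.05), c(0.30, 0.30))
  A <- matrix(0.25, 4, 4)
  m <- chromatin_hmm(rep(0.25, 4), A, E, c("prom", "elong"))
  cfg <- c(promoter = "prom", elongation = "elong")
  lm <- label_states(m, cfg)
  expect_equal(lm$labels,
               c("Aquamarine", "Lazurite", "Ruby", "Malachite"))

  # permuting the states permutes the labels identically
  p <- c(3, 1, 4, 2)
  mp <- chromatin_hmm(rep(0.25, 4), A[p, p], E[p, ], c("prom", "elong"))
  expect_equal(label_states(mp, cfg)$labels, lm$labels[p])

  # exact promoter tie: the tied state with the higher overall mean
  # takes Aquamarine, the other falls through to the later rules
  Et <- rbind(c(0.90, 0.85), c(0.90, 0.80), c(0.05, 0.05),
              c(0.30, 0.30))
  lt <- label_states(chromatin_hmm(rep(0.25, 4), A, Et,
                                   c("prom", "elong")), cfg)
  expect_equal(lt$labels,
               c("Aquamarine", "Lazurite", "Ruby", "Malachite"))

  expect_error(label_states(chromatin_hmm(c(0.5, 0.5),
                                          matrix(0.5, 2, 2),
                                          matrix(0.5, 2, 2),
                                          c("prom", "elong")), cfg),
               "K = 4")
  expect_error(label_states(m, c(promoter = "nope",
                                 elongation = "elong")),
               "not in model")
})

test_that("segmentation is the exact inverse of the state path", {
  g <- bin_genome(chrom_sizes(c(chrA = 800)), 200)
  seg <- path_to_segmentation(c(1L, 1L, 2L, 2L), g,
                              labels = c("s1", "s2"))
  expect_equal(start(seg), c(1, 401))
  expect_equal(end(seg), c(400, 800))
  expect_equal(mcols(seg)$label, c("s1", "s2"))

  expect_length(path_to_segmentation(rep(NA_integer_, 4), g), 0)

  # random path round-trips through interval expansion, across
  # chromosomes, masked runs and a short terminal bin
  g2 <- bin_genome(chrom_sizes(c(chrA = 1001, chrB = 400)), 200)
  set.seed(31)
  path <- sample(c(1:3, NA), g2$n_bins, replace = TRUE)
  seg2 <- path_to_segmentation(path, g2)
  back <- rep(NA_integer_, g2$n_bins)
  for (i in seq_along(seg2)) {
    ch <- as.character(seqnames(seg2))[i]
    b0 <- (start(seg2)[i] - 1) %/% 200 + 1
    b1 <- (end(seg2)[i] - 1) %/% 200 + 1
    back[g2$offset[[ch]] + (b0:b1)] <- mcols(seg2)$state[i]
  }
  expect_equal(back, as.integer(path))

  # unmasked tiling: total segment bp equals summed true bin widths
  loc <- bin_locate(g2, which(!is.na(path)))
  expect_equal(sum(width(seg2)), sum(loc$end - loc$start))
  # adjacent intervals on a chromosome never share a state
  for (ch in c("chrA", "chrB")) {
    sub <- seg2[seqnames(seg2) == ch]
    if (length(sub) > 1) {
      adj <- which(start(sub)[-1] == end(sub)[-length(sub)] + 1)
      expect_true(all(mcols(sub)$state[adj] !=
                        mcols(sub)$state[adj + 1]))
    }
  }
})

test_that("model YAML serialization round-trips", {
  m <- label_states(
    chromatin_hmm(c(0.1, 0.2, 0.3, 0.4),
                  matrix(0.25, 4, 4),
                  matrix(runif(8), 4, 2), c("prom", "elong"),
                  log_likelihood = -123.456, seed = 7L,
                  converged = TRUE),
    c(promoter = "prom", elongation = "elong"))
  f <- withr::local_tempfile(fileext = ".yml")
  write_hmm_model(m, f)
  back <- read_hmm_model(f)
  expect_equal(back$initial, m$initial)
  expect_equal(back$transitions, m$transitions, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(back$emissions), unname(m$emissions),
               tolerance = 1e-12)
  expect_equal(back$labels, m$labels)
  expect_equal(back$log_likelihood, m$log_likelihood)
})
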