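#' Default ground-truth chromatin-state model for simulations
#'
#' A 4-state, 6-track Bernoulli-emission model whose emission profiles
#' follow the qualitative biology of the four states: Aquamarine is
#' marked by a high interband/promoter-marker emission, Lazurite by a
#' high elongation-marker emission, Ruby is depleted of every protein,
#' and Malachite carries moderate levels plus a distinctive
#' band-associated marker. Every pair of states is separated by at
#' least 0.4 in some track. Transitions are sticky (0.95 self) with the
#' remainder spread uniformly.
#'
#' @param self_transition Diagonal transition probability (default
#'   0.95).
#' @return A labelled `"chromatin_hmm"` (states in the order Aquamarine,
#'   Lazurite, Ruby, Malachite) with the marker configuration attached.
#' @export
truth_model <- function(self_transition = 0.95) {
  track_ids <- c("CHRIZ", "PolII", "ISWI", "MRG15", "HP1", "SUUR")
  E <- rbind(
    Aquamarine = c(0.90, 0.40, 0.15, 0.15, 0.15, 0.10),
    Lazurite   = c(0.20, 0.80, 0.20, 0.20, 0.20, 0.10),
    Ruby       = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    Malachite  = c(0.30, 0.30, 0.30, 0.30, 0.30, 0.70))
  K <- 4L
  A <- matrix((1 - self_transition) / (K - 1), K, K)
  diag(A) <- self_transition
  m <- chromatin_hmm(rep(1 / K, K), A, unname(E), track_ids,
                     labels = rownames(E))
  m$marker_config <- c(promoter = "CHRIZ", elongation = "PolII")
  m
}

#' Simulate binary occupancy tracks from a known model
#'
#' Samples a hidden state path from the model's Markov chain (restarted
#' from the initial distribution on each chromosome and after each
#' masked gap), then samples the per-track bits from the state's
#' Bernoulli emissions, optionally flipping each bit with a fixed noise
#' probability. Fully reproducible from the seed; a single seeded
#' pseudorandom stream is used and the global random state is restored
#' on exit.
#'
#' @param model A valid `"chromatin_hmm"` (the generating truth).
#' @param grid A `"binned_genome"`.
#' @param seed Integer seed.
#' @param flip_prob Per-bit flip probability in \[0, 0.5).
#' @param mask Optional logical vector (`TRUE` = observed); masked bins
#'   get no states or bits.
#' @return List with `obs` (a `"binary_tracks"`) and `path` (the true
#'   `"state_path"`).
#' @export
generate_tracks <- function(model, grid, seed, flip_prob = 0,
                            mask = NULL) {
  if (!inherits(model, "chromatin_hmm"))
    .stopf("generate_tracks: model must be a chromatin_hmm")
  if (flip_prob < 0 || flip_prob >= 0.5)
    .stopf("generate_tracks: flip_prob must be in [0, 0.5)")
  if (is.null(mask)) mask <- rep(TRUE, grid$n_bins)
  if (length(mask) != grid$n_bins)
    .stopf("generate_tracks: mask length must equal n_bins")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  K <- model$K
  M <- length(model$track_ids)
  states <- rep(NA_integer_, grid$n_bins)
  # chromosome boundaries also restart the chain
  chrom_of_bin <- rep(seq_along(grid$sizes), grid$n_per_chrom)
  segs <- .mask_segments(mask)
  for (idx in segs) {
    br <- c(0L, which(diff(chrom_of_bin[idx]) != 0L), length(idx))
    for (p in seq_len(length(br) - 1L)) {
      sub <- idx[(br[p] + 1L):br[p + 1L]]
      s <- integer(length(sub))
      s[1] <- sample.int(K, 1L, prob = model$initial)
      if (length(sub) > 1L)
        for (t in 2:length(sub))
          s[t] <- sample.int(K, 1L, prob = model$transitions[s[t - 1], ])
      states[sub] <- s
    }
  }
  data <- matrix(0L, M, grid$n_bins, dimnames =
                   list(model$track_ids, NULL))
  obs_idx <- which(mask)
  p_mat <- t(model$emissions)[, states[obs_idx], drop = FALSE]  # M x n
  bits <- matrix(rbinom(length(p_mat), 1L, as.numeric(p_mat)),
                 nrow = M)
  if (flip_prob > 0) {
    flips <- matrix(rbinom(length(bits), 1L, flip_prob), nrow = M)
    bits <- as.integer(bits != flips)
    dim(bits) <- c(M, length(obs_idx))
  }
  data[, obs_idx] <- bits
  list(obs = binary_tracks(model$track_ids, data, mask, grid),
       path = structure(list(states = states, K = K,
                             labels = model$labels),
                        class = "state_path"))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate region-structured point annotations
#'
#' For each named region with known coordinates, draws a feature count
#' from Poisson(density x length in Mb), places feature starts uniformly
#' within the region and gives every feature a short fixed width.
#' Reproducible from the seed.
#'
#' @param partition A `"region_partition"` (or list of
#'   `"named_region"`); regions with unknown coordinates are skipped.
#' @param densities Named numeric vector: region name -> features per
#'   Mb (all >= 0; regions absent from it get density 0).
#' @param seed Integer seed.
#' @param feature_width Feature width in bp (default 200).
#' @param sizes Optional `"chrom_sizes"`; regions outside the genome are
#'   an error.
#' @return A `GRanges` of features with a `name` column
#'   (`<region>_f<i>`).
#' @export
generate_annotations <- function(partition, densities, seed,
                                 feature_width = 200, sizes = NULL) {
  if (any(densities < 0))
    .stopf("generate_annotations: densities must be >= 0")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  parts <- list()
  for (r in partition) {
    if (is.na(r$chrom) || is.na(r$start) || is.na(r$end)) next
    if (!is.null(sizes)) {
      if (!(r$chrom %in% names(sizes)) || r$end - 1 > sizes[[r$chrom]])
        .stopf("generate_annotations: region '%s' outside genome",
               r$name)
    }
    d <- if (r$name %in% names(densities)) densities[[r$name]] else 0
    n <- rpois(1L, d * region_length_mb(r$start, r$end))
    if (n == 0L) next
    lo <- r$start
    hi <- max(r$start, r$end - feature_width)
    st <- sort(floor(runif(n, lo, hi + 1)))
    gr <- GRanges(r$chrom, IRanges(st, width = feature_width),
                  name = sprintf("%s_f%d", r$name, seq_len(n)))
    parts[[length(parts) + 1L]] <- gr
  }
  if (length(parts) == 0L) {
    gr <- GRanges()
    mcols(gr)$name <- character(0)
    return(gr)
  }
  do.call(c, parts)
}

.rpkm_ranges <- list(
  ExtremelyHigh = c(1000.5, 3000), VeryHigh = c(101, 1000),
  High = c(51, 100), ModerateHigh = c(26, 50), Moderate = c(11, 25),
  Low = c(4, 10), VeryLow = c(1, 3), ExtremelyLowNone = c(0, 1))

#' Simulate a per-tissue RPKM vector with prescribed category counts
#'
#' For each requested expression category the values are drawn uniformly
#' inside that category's RPKM bin (ExtremelyLow/None draws zeros or
#' sub-1 values); the order across tissues is shuffled by the seed.
#' Pushing the result through [expression_profile()] returns exactly the
#' requested tallies.
#'
#' @param category_counts Named integer vector (category -> tissue
#'   count); must sum to `n_tissues`.
#' @param seed Integer seed.
#' @param n_tissues Total number of tissues (default 29).
#' @return Numeric vector of length `n_tissues`.
#' @export
generate_rpkm <- function(category_counts, seed, n_tissues = 29) {
  bad <- setdiff(names(category_counts), names(.rpkm_ranges))
  if (length(bad))
    .stopf("generate_rpkm: unknown category %s", paste(bad,
                                                       collapse = ", "))
  if (sum(category_counts) != n_tissues)
    .stopf("generate_rpkm: category counts must sum to %d (got %d)",
           n_tissues, sum(category_counts))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  vals <- numeric(0)
  for (cat in names(category_counts)) {
    n <- category_counts[[cat]]
    if (n == 0L) next
    rg <- .rpkm_ranges[[cat]]
    v <- if (cat == "ExtremelyLowNone") {
      ifelse(runif(n) < 0.5, 0, runif(n, 0, 1 - 1e-9))
    } else runif(n, rg[1], rg[2])
    vals <- c(vals, v)
  }
  vals[sample.int(n_tissues)]
}

# quota/run construction: a state path whose per-state bin fractions hit
# the targets exactly (up to integer rounding), arranged as shuffled
# runs so the path still looks segmental
.quota_path <- function(n, fractions, run_length) {
  counts <- floor(n * fractions)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(n * fractions - counts, decreasing = TRUE)
    counts[extra[seq_len(rem)]] <- counts[extra[seq_len(rem)]] + 1L
  }
  runs_state <- integer(0)
  runs_len <- integer(0)
  for (k in seq_along(counts)) {
    ck <- counts[k]
    if (ck == 0L) next
    nr <- ceiling(ck / run_length)
    lens <- rep(run_length, nr)
    lens[nr] <- ck - (nr - 1L) * run_length
    runs_state <- c(runs_state, rep(k, nr))
    runs_len <- c(runs_len, lens)
  }
  ord <- sample.int(length(runs_state))
  rep(runs_state[ord], runs_len[ord])
}

#' Simulate the heterochromatin-versus-euchromatin comparison preset
#'
#' Builds two compartments on one bin grid — a "het" chromosome and a
#' "eu" chromosome — whose state paths are constructed (by a quota/run
#' scheme, exact by design) to carry Ruby fractions of 0.700 and 0.519
#' and an Aquamarine+Lazurite fraction three times smaller in het than
#' in eu. Observations are then sampled from the truth model's
#' emissions, so decoding and the proportion bookkeeping can be
#' exercised end to end against known targets. This is a construction
#' for validating the pipeline, not a reproduction of any external
#' dataset.
#'
#' @param seed Integer seed.
#' @param n_bins Bins per compartment (default 50000).
#' @param bin_size Bin width in bp (default 200).
#' @param run_length Run length of the quota construction, in bins
#'   (default 25).
#' @param model Generating `"chromatin_hmm"` (default [truth_model()]).
#' @return List with the `grid`, `obs`, true `path`, the generating
#'   `model`, `compartments` (named list of `GRanges`) and
#'   `target_fractions` (per compartment, in state-index order
#'   Aquamarine, Lazurite, Ruby, Malachite).
#' @export
simulate_het_eu <- function(seed = 17, n_bins = 50000, bin_size = 200,
                            run_length = 25, model = truth_model()) {
  targets <- list(
    het = c(Aquamarine = 0.060, Lazurite = 0.060, Ruby = 0.700,
            Malachite = 0.180),
    eu = c(Aquamarine = 0.180, Lazurite = 0.180, Ruby = 0.519,
           Malachite = 0.121))
  sizes <- chrom_sizes(setNames(rep(n_bins * bin_size, 2),
                                c("chrHet", "chrEu")))
  grid <- bin_genome(sizes, bin_size)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  states <- integer(grid$n_bins)
  for (p in 1:2) {
    frac <- targets[[p]][model$labels]
    idx <- grid$offset[[p]] + seq_len(grid$n_per_chrom[[p]])
    states[idx] <- .quota_path(length(idx), frac, run_length)
  }
  # sample bits from the emissions of the constructed path
  M <- length(model$track_ids)
  p_mat <- t(model$emissions)[, states, drop = FALSE]
  data <- matrix(rbinom(length(p_mat), 1L, as.numeric(p_mat)), nrow = M,
                 dimnames = list(model$track_ids, NULL))
  obs <- binary_tracks(model$track_ids, data, rep(TRUE, grid$n_bins),
                       grid)
  list(
    grid = grid, obs = obs,
    path = structure(list(states = states, K = model$K,
                          labels = model$labels), class = "state_path"),
    model = model,
    compartments = list(
      het = GRanges("chrHet", IRanges(1, sizes[["chrHet"]])),
      eu = GRanges("chrEu", IRanges(1, sizes[["chrEu"]]))),
    target_fractions = targets)
}
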