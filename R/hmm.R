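#' Construct a chromatin-state HMM
#'
#' A hidden Markov model with independent Bernoulli emissions per track
#' within each state (so the emission probability of a bin is the
#' product over tracks of Bernoulli likelihoods).
#'
#' @param initial Length-K probability vector.
#' @param transitions K x K row-stochastic matrix.
#' @param emissions K x M matrix of Bernoulli success probabilities
#'   (state x track).
#' @param track_ids Character vector of M track ids (column order of
#'   `emissions`).
#' @param labels Optional character vector of length K mapping state
#'   index to a state name (for K = 4: Aquamarine, Lazurite, Malachite,
#'   Ruby).
#' @param log_likelihood Training objective at convergence (optional).
#' @param seed Seed the model was trained with (optional).
#' @param converged Logical convergence flag (optional).
#' @return A `"chromatin_hmm"` object.
#' @export
chromatin_hmm <- function(initial, transitions, emissions, track_ids,
                          labels = NULL, log_likelihood = NA_real_,
                          seed = NA_integer_, converged = NA) {
  K <- length(initial)
  transitions <- as.matrix(transitions)
  emissions <- as.matrix(emissions)
  if (!isTRUE(all.equal(sum(initial), 1, tolerance = 1e-9)))
    .stopf("chromatin_hmm: initial probabilities must sum to 1")
  if (nrow(transitions) != K || ncol(transitions) != K)
    .stopf("chromatin_hmm: transitions must be K x K")
  if (any(abs(rowSums(transitions) - 1) > 1e-9))
    .stopf("chromatin_hmm: transition rows must sum to 1")
  if (nrow(emissions) != K)
    .stopf("chromatin_hmm: emissions must have K rows")
  if (any(emissions < 0 | emissions > 1))
    .stopf("chromatin_hmm: emissions must lie in [0, 1]")
  if (ncol(emissions) != length(track_ids))
    .stopf("chromatin_hmm: emissions columns must match track_ids")
  if (!is.null(labels)) {
    if (length(labels) != K)
      .stopf("chromatin_hmm: labels must have length K")
    if (K == 4L && !setequal(labels, .state_names))
      .stopf("chromatin_hmm: 4-state labels must be a bijection onto %s",
             paste(.state_names, collapse = ", "))
  }
  colnames(emissions) <- track_ids
  structure(list(K = K, initial = as.numeric(initial),
                 transitions = transitions, emissions = emissions,
                 track_ids = as.character(track_ids), labels = labels,
                 log_likelihood = log_likelihood, seed = seed,
                 converged = converged),
            class = "chromatin_hmm")
}

#' @export
print.chromatin_hmm <- function(x, ...) {
  cat(sprintf("chromatin_hmm: K=%d states, M=%d tracks", x$K,
              length(x$track_ids)))
  if (!is.null(x$labels))
    cat(" [", paste(x$labels, collapse = ", "), "]", sep = "")
  if (is.finite(x$log_likelihood))
    cat(sprintf(", logLik=%.2f", x$log_likelihood))
  cat("\n")
  invisible(x)
}

# K x T log emission matrix for binary observations X (M x T)
.emission_logB <- function(emissions, X) {
  E <- pmin(pmax(emissions, 1e-12), 1 - 1e-12)
  log(E) %*% X + log1p(-E) %*% (1 - X)
}

.check_tracks_match <- function(model, obs) {
  if (!identical(model$track_ids, obs$track_ids))
    .stopf("track ids of model and observations differ (order matters)")
}

#' Total log-likelihood of observations under a model
#'
#' Computed by the scaled forward algorithm; masked bins split the
#' sequence into independent segments, each restarted from the initial
#' distribution, and their log-likelihoods add.
#'
#' @param model A `"chromatin_hmm"`.
#' @param obs A `"binary_tracks"` object with matching track ids.
#' @return The log-likelihood (a scalar).
#' @export
forward_loglik <- function(model, obs) {
  .check_tracks_match(model, obs)
  segs <- .mask_segments(obs$mask)
  if (length(segs) == 0L) .stopf("forward_loglik: no unmasked bins")
  ll <- 0
  for (idx in segs) {
    logB <- .emission_logB(model$emissions, obs$data[, idx, drop = FALSE])
    cmax <- apply(logB, 2L, max)
    B <- exp(sweep(logB, 2L, cmax))
    fb <- .hmm_forward_backward(B, model$initial, model$transitions)
    ll <- ll + fb$loglik + sum(cmax)
  }
  ll
}

#' Train a Bernoulli-emission HMM by Baum-Welch
#'
#' Expectation-maximization over all observed segments (masked bins
#' break the chain into independent segments rather than being imputed).
#' Several random restarts are run from seeded initializations; the
#' restart with the highest converged log-likelihood wins, ties going to
#' the lowest restart index. Emission and transition estimates are
#' floored at `eps` to avoid degenerate zero-probability lock-in.
#'
#' Initialization per restart: emissions uniform in \[0.1, 0.9\],
#' uniform initial vector, transitions 0.9 on the diagonal with the
#' remainder spread uniformly off-diagonal.
#'
#' @param obs A `"binary_tracks"` object.
#' @param K Number of states (default 4).
#' @param seed Integer seed; restart r uses `seed + r - 1`.
#' @param n_restarts Number of EM restarts (default 5).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Relative log-likelihood improvement below which EM stops
#'   (default 1e-6).
#' @param eps Probability floor (default 1e-6).
#' @return A `"chromatin_hmm"` with `log_likelihood`, `seed` and a
#'   `converged` flag (a non-converged model is returned flagged, not an
#'   error).
#' @export
train_hmm <- function(obs, K = 4, seed = 17, n_restarts = 5,
                      max_iter = 500, tol = 1e-6, eps = 1e-6) {
  if (K < 1) .stopf("train_hmm: K must be >= 1")
  segs <- .mask_segments(obs$mask)
  if (length(segs) == 0L) .stopf("train_hmm: no unmasked bins")
  M <- nrow(obs$data)
  X <- lapply(segs, function(idx) obs$data[, idx, drop = FALSE])

  if (K == 1L) {
    em <- matrix(rowMeans(obs$data[, obs$mask, drop = FALSE]), 1L, M)
    em <- pmin(pmax(em, eps), 1 - eps)
    model <- chromatin_hmm(1, matrix(1, 1, 1), em, obs$track_ids,
                           seed = seed, converged = TRUE)
    model$log_likelihood <- forward_loglik(model, obs)
    return(model)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    E <- matrix(runif(K * M, 0.1, 0.9), K, M)
    A <- matrix((1 - 0.9) / (K - 1), K, K)
    diag(A) <- 0.9
    pi0 <- rep(1 / K, K)
    ll_prev <- -Inf
    converged <- FALSE
    ll <- NA_real_
    for (it in seq_len(max_iter)) {
      g1 <- numeric(K)
      xi <- matrix(0, K, K)
      gsum <- numeric(K)
      gX <- matrix(0, K, M)
      ll <- 0
      for (Xs in X) {
        logB <- .emission_logB(E, Xs)
        cmax <- apply(logB, 2L, max)
        B <- exp(sweep(logB, 2L, cmax))
        fb <- .hmm_forward_backward(B, pi0, A)
        ll <- ll + fb$loglik + sum(cmax)
        g1 <- g1 + fb$gamma1
        xi <- xi + fb$xi_sum
        gsum <- gsum + rowSums(fb$gamma)
        gX <- gX + fb$gamma %*% t(Xs)
      }
      # M-step with probability floors
      pi0 <- pmax(g1 / sum(g1), eps); pi0 <- pi0 / sum(pi0)
      if (sum(xi) > 0) {
        A <- xi / pmax(rowSums(xi), .Machine$double.xmin)
        A <- pmin(pmax(A, eps), 1 - eps)
        A <- A / rowSums(A)
      }
      E <- gX / pmax(gsum, .Machine$double.xmin)
      E <- pmin(pmax(E, eps), 1 - eps)
      if (is.finite(ll_prev) &&
          (ll - ll_prev) < tol * abs(ll_prev)) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
    }
    if (is.null(best) || ll > best$ll + 1e-12) {
      best <- list(ll = ll, E = E, A = A, pi0 = pi0,
                   converged = converged, restart = r)
    }
  }
  chromatin_hmm(best$pi0, best$A, best$E, obs$track_ids,
                log_likelihood = best$ll, seed = seed,
                converged = best$converged)
}

#' Maximum-probability state path (Viterbi)
#'
#' Decodes each observed segment independently (a masked gap restarts
#' the chain from the initial distribution). Ties are broken toward the
#' lowest state index. Decoding is deterministic.
#'
#' @param model A `"chromatin_hmm"`.
#' @param obs A `"binary_tracks"` with track ids matching the model's,
#'   in order.
#' @return A `"state_path"`: integer vector of 1-based state indices
#'   with `NA` at masked bins, plus the model's `K` and labels.
#' @export
viterbi_decode <- function(model, obs) {
  .check_tracks_match(model, obs)
  states <- rep(NA_integer_, ncol(obs$data))
  logInit <- log(pmax(model$initial, 1e-300))
  logA <- log(pmax(model$transitions, 1e-300))
  for (idx in .mask_segments(obs$mask)) {
    logB <- .emission_logB(model$emissions, obs$data[, idx, drop = FALSE])
    states[idx] <- .hmm_viterbi(logB, logInit, logA)
  }
  structure(list(states = states, K = model$K, labels = model$labels),
            class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf("state_path: %d bins (%d decoded), K=%d\n",
              length(x$states), sum(!is.na(x$states)), x$K))
  invisible(x)
}

#' Assign biological state names to a 4-state model
#'
#' The labelling rule follows the biology of the four states: the state
#' with the highest emission of the interband/promoter marker (e.g.
#' CHRIZ) is *Aquamarine*; among the remaining states the highest
#' emission of the elongation marker (e.g. RNA-polII) is *Lazurite*; of
#' the last two, the state with the lower mean emission across all
#' tracks is *Ruby* (the most protein-depleted, most condensed state)
#' and the other is *Malachite*. Exact ties on a marker are broken
#' toward the tied state with the higher overall mean emission (the
#' more protein-rich candidate takes the earlier, more active label);
#' a tie between the final two goes to the lower state index as Ruby.
#'
#' @param model A `"chromatin_hmm"` with K = 4.
#' @param marker_config Named character vector with entries `promoter`
#'   and `elongation` giving the two marker track ids.
#' @return The model with `labels` filled in; the rule is deterministic
#'   given the model.
#' @export
label_states <- function(model, marker_config) {
  if (model$K != 4L)
    .stopf("label_states: labelling is defined for K = 4 (got K = %d)",
           model$K)
  for (role in c("promoter", "elongation")) {
    if (!(role %in% names(marker_config)))
      .stopf("label_states: marker_config lacks role '%s'", role)
    if (!(marker_config[[role]] %in% model$track_ids))
      .stopf("label_states: marker track '%s' not in model",
             marker_config[[role]])
  }
  prom <- model$emissions[, marker_config[["promoter"]]]
  elon <- model$emissions[, marker_config[["elongation"]]]
  overall <- rowMeans(model$emissions)
  labels <- character(4L)
  pool <- 1:4
  aq <- pool[order(-prom[pool], -overall[pool], pool)][1]
  labels[aq] <- "Aquamarine"
  pool <- setdiff(pool, aq)
  lz <- pool[order(-elon[pool], -overall[pool], pool)][1]
  labels[lz] <- "Lazurite"
  pool <- setdiff(pool, lz)
  rb <- pool[order(overall[pool], pool)][1]
  labels[rb] <- "Ruby"
  labels[setdiff(pool, rb)] <- "Malachite"
  model$labels <- labels
  model$marker_config <- marker_config
  model
}

#' Convert a decoded state path to a genomic segmentation
#'
#' Maximal runs of equal state become intervals; masked runs yield no
#' interval; interval bounds are bin-aligned with the final interval of
#' each chromosome clipped to the chromosome end. Re-expanding the
#' intervals over the bins reproduces the path exactly.
#'
#' @param path A `"state_path"` (or plain integer vector with `NA` for
#'   masked bins).
#' @param grid The governing `"binned_genome"`.
#' @param labels Optional character vector mapping state index to label;
#'   defaults to the path's own labels when present.
#' @return A `GRanges` with metadata columns `state` (integer) and
#'   `label`, sorted and non-overlapping; adjacent intervals on a
#'   chromosome carry different states.
#' @export
path_to_segmentation <- function(path, grid, labels = NULL) {
  states <- if (inherits(path, "state_path")) path$states else
    as.integer(path)
  if (is.null(labels) && inherits(path, "state_path"))
    labels <- path$labels
  if (length(states) != grid$n_bins)
    .stopf("path_to_segmentation: path length != n_bins")
  parts <- list()
  for (ch in names(grid$sizes)) {
    nb <- grid$n_per_chrom[[ch]]
    idx <- grid$offset[[ch]] + seq_len(nb)
    st_ch <- states[idx]
    r <- rle(ifelse(is.na(st_ch), -1L, st_ch))
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths + 1L
    keep <- which(r$values != -1L)
    if (length(keep) == 0L) next
    gs <- (starts_bin[keep] - 1) * grid$bin_size + 1
    ge <- pmin(ends_bin[keep] * grid$bin_size, grid$sizes[[ch]])
    gr <- GRanges(factor(ch, levels = names(grid$sizes)),
                  IRanges(gs, ge), state = r$values[keep])
    parts[[length(parts) + 1L]] <- gr
  }
  if (length(parts) == 0L) {
    seg <- GRanges()
    seqinfo(seg) <- .sizes_seqinfo(grid$sizes)
    mcols(seg)$state <- integer(0)
    mcols(seg)$label <- character(0)
    return(seg)
  }
  seg <- do.call(c, parts)
  seqinfo(seg) <- .sizes_seqinfo(grid$sizes)
  mcols(seg)$label <- if (!is.null(labels)) labels[mcols(seg)$state]
                      else as.character(mcols(seg)$state)
  seg
}

#' Write a segmentation as a BED9 file with state colours
#'
#' The state label goes in the name column and a fixed state-to-RGB
#' mapping in the itemRgb column (Aquamarine 127,255,212; Lazurite
#' 38,97,156; Malachite 11,218,81; Ruby 155,17,30).
#'
#' @param seg A segmentation `GRanges` (from [path_to_segmentation()]).
#' @param path Output path.
#' @export
write_segmentation_bed <- function(seg, path) {
  lab <- mcols(seg)$label
  rgb <- unname(.state_rgb[lab])
  rgb[is.na(rgb)] <- "128,128,128"
  df <- data.frame(chrom = as.character(seqnames(seg)),
                   start = start(seg) - 1, end = end(seg),
                   name = lab, score = 0L, strand = ".",
                   thickStart = start(seg) - 1, thickEnd = end(seg),
                   itemRgb = rgb, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a model to a YAML file
#'
#' Matrices are stored row-major under explicit dimension keys, so the
#' file is a plain-text, human-diffable record of the trained model.
#'
#' @param model A `"chromatin_hmm"`.
#' @param path Output path.
#' @export
write_hmm_model <- function(model, path) {
  doc <- list(
    K = model$K,
    track_ids = as.list(model$track_ids),
    initial = as.list(model$initial),
    transitions = as.list(as.numeric(t(model$transitions))),
    emissions = as.list(as.numeric(t(model$emissions))),
    labels = if (is.null(model$labels)) NULL else as.list(model$labels),
    log_likelihood = model$log_likelihood,
    seed = model$seed,
    converged = model$converged)
  yaml::write_yaml(doc[!vapply(doc, is.null, TRUE)], path,
                   precision = 17)
  invisible(path)
}

#' Read a model written by [write_hmm_model()]
#'
#' @param path Path to the YAML model file.
#' @return A `"chromatin_hmm"`.
#' @export
read_hmm_model <- function(path) {
  doc <- yaml::read_yaml(path)
  K <- doc$K
  M <- length(doc$track_ids)
  chromatin_hmm(
    initial = unlist(doc$initial),
    transitions = matrix(unlist(doc$transitions), K, K, byrow = TRUE),
    emissions = matrix(unlist(doc$emissions), K, M, byrow = TRUE),
    track_ids = unlist(doc$track_ids),
    labels = if (is.null(doc$labels)) NULL else unlist(doc$labels),
    log_likelihood = if (is.null(doc$log_likelihood)) NA_real_
                     else doc$log_likelihood,
    seed = if (is.null(doc$seed)) NA_integer_ else doc$seed,
    converged = if (is.null(doc$converged)) NA else doc$converged)
}
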