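# shared test helpers: small fixture builders and independent oracles

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

tiny_sizes <- function() chrom_sizes(c(chrA = 1000, chrB = 400))

random_intervals <- function(sizes, n, seed, named = TRUE) {
  set.seed(seed)
  ch <- sample(names(sizes), n, replace = TRUE)
  len <- unname(sizes[ch])
  start0 <- floor(runif(n, 0, len - 2))
  end0 <- pmin(start0 + 1 + floor(runif(n, 0, 50)), len)
  gr <- GRanges(factor(ch, names(sizes)), IRanges(start0 + 1, end0))
  if (named) mcols(gr)$name <- sprintf("iv%03d", seq_len(n))
  gr
}

# all permutations of a vector (used for 4-state alignment)
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# align fitted states to a truth model by minimal total emission-profile
# distance; returns the permutation p with fit state p[k] ~ truth state k
align_states <- function(fit, truth) {
  best <- NULL
  best_d <- Inf
  for (p in perms(seq_len(truth$K))) {
    d <- sum(abs(fit$emissions[p, , drop = FALSE] - truth$emissions))
    if (d < best_d) {
      best_d <- d
      best <- p
    }
  }
  best
}

# brute-force total likelihood: sum over all K^T state paths
brute_force_loglik <- function(model, X) {
  K <- model$K
  T_ <- ncol(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- model$initial[s[1]]
    if (T_ > 1)
      for (t in 2:T_) p <- p * model$transitions[s[t - 1], s[t]]
    for (t in seq_len(T_)) {
      e <- model$emissions[s[t], ]
      p <- p * prod(ifelse(X[, t] == 1, e, 1 - e))
    }
    total <- total + p
  }
  log(total)
}

# brute-force Viterbi: maximize over all K^T paths with a strict-
# improvement rule, enumerating paths in lexicographic time order so
# ties resolve toward lower state indices at the earliest positions
brute_force_viterbi <- function(model, X) {
  K <- model$K
  T_ <- ncol(X)
  paths <- as.matrix(do.call(expand.grid, rev(rep(list(seq_len(K)),
                                                  T_))))[, T_:1,
                                                         drop = FALSE]
  best_lp <- -Inf
  best <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    lp <- log(model$initial[s[1]])
    if (T_ > 1)
      for (t in 2:T_) lp <- lp + log(model$transitions[s[t - 1], s[t]])
    for (t in seq_len(T_)) {
      e <- model$emissions[s[t], ]
      lp <- lp + sum(log(ifelse(X[, t] == 1, e, 1 - e)))
    }
    if (lp > best_lp + 1e-12) {
      best_lp <- lp
      best <- s
    }
  }
  list(path = unname(best), loglik = best_lp)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

# joint log-probability of a specific state path
path_logprob <- function(model, X, s) {
  lp <- log(model$initial[s[1]])
  T_ <- ncol(X)
  if (T_ > 1)
    for (t in 2:T_) lp <- lp + log(model$transitions[s[t - 1], s[t]])
  for (t in seq_len(T_)) {
    e <- model$emissions[s[t], ]
    lp <- lp + sum(log(ifelse(X[, t] == 1, e, 1 - e)))
  }
  lp
}

# full-permutation two-sided Mann-Whitney p-value (exact oracle)
perm_mw_p <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  combs <- utils::combn(N, n)
  us <- apply(combs, 2L, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

random_hmm <- function(K, M, seed) {
  set.seed(seed)
  A <- matrix(runif(K * K, 0.05, 1), K, K)
  A <- A / rowSums(A)
  init <- runif(K, 0.05, 1)
  init <- init / sum(init)
  E <- matrix(runif(K * M, 0.05, 0.95), K, M)
  chromatin_hmm(init, A, E, paste0("t", seq_len(M)))
}

random_obs <- function(M, T_, seed, grid = NULL) {
  set.seed(seed)
  binary_tracks(paste0("t", seq_len(M)),
                matrix(rbinom(M * T_, 1, 0.5), M, T_),
                rep(TRUE, T_), grid)
}
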