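#' Per-state genome fractions within a compartment
#'
#' Computes, for each state label, the fraction of segmented base pairs
#' carrying that label after intersecting the segmentation with a set of
#' regions (a "compartment", e.g. the heterochromatic arms versus the
#' euchromatic genome). Fractions sum to 1 over the labels.
#'
#' @param seg Segmentation `GRanges` with a `label` metadata column.
#' @param regions Optional `GRanges` restricting the tally; `NULL` uses
#'   the whole segmentation.
#' @param compartment Name recorded on the result (default "genome").
#' @return A named numeric vector of fractions (class
#'   `"state_proportions"`), with attributes `compartment` and
#'   `total_bp`.
#' @export
state_proportions <- function(seg, regions = NULL,
                              compartment = "genome") {
  if (length(seg) == 0L) .stopf("state_proportions: empty segmentation")
  labs <- mcols(seg)$label
  if (is.null(labs)) .stopf("state_proportions: seg lacks a label column")
  all_labs <- if (all(.state_names %in% unique(labs)) ||
                  all(unique(labs) %in% .state_names))
    .state_names else sort(unique(labs))
  bp <- setNames(numeric(length(all_labs)), all_labs)
  if (!is.null(regions)) {
    lev <- union(seqlevels(seg), seqlevels(regions))
    plain <- function(gr)
      GRanges(factor(as.character(seqnames(gr)), lev), ranges(gr))
    regions <- reduce(plain(regions), ignore.strand = TRUE)
    for (lab in all_labs) {
      sub <- seg[labs == lab]
      if (length(sub))
        bp[lab] <- sum(width(intersect(plain(sub), regions,
                                       ignore.strand = TRUE)))
    }
  } else {
    for (lab in all_labs)
      bp[lab] <- sum(width(seg[labs == lab]))
  }
  total <- sum(bp)
  if (total == 0) .stopf("state_proportions: no segmented bp in regions")
  structure(bp / total, class = "state_proportions",
            compartment = compartment, total_bp = total)
}

#' @export
print.state_proportions <- function(x, ...) {
  cat(sprintf("state proportions (%s, %s bp):\n", attr(x, "compartment"),
              format(attr(x, "total_bp"), big.mark = ",",
                     scientific = FALSE)))
  print(round(setNames(as.numeric(x), names(x)), 4))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum statistic with midrank tie handling. The exact null
#' distribution is enumerated when the pooled sample size is at most 16
#' and there are no ties; otherwise a tie-corrected normal approximation
#' with continuity correction is used.
#'
#' @param x,y Nonempty numeric samples.
#' @param exact Force or forbid the exact path; `NULL` (default) applies
#'   the size-and-ties rule above.
#' @return List with `U` (the rank-sum statistic for `x`), the
#'   two-sided `p_value`, and whether the `exact` path was used.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  if (length(x) == 0L || length(y) == 0L)
    .stopf("mann_whitney_u: samples must be nonempty")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    .stopf("mann_whitney_u: samples must be finite")
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact))
    exact <- (length(x) + length(y) <= 16L) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  p <- unname(wt$p.value)
  # degenerate pooled sample (all values tied): no evidence either way
  if (!is.finite(p)) p <- 1
  list(U = unname(wt$statistic), p_value = min(p, 1), exact = exact)
}

#' Pairwise two-sided rank-sum p-values between state samples
#'
#' The samples are unpaired bin-value sets, one per state, so the
#' pairwise test is the two-sided rank-sum (Mann-Whitney) test; a
#' signed-rank mode is available for explicitly paired inputs of equal
#' length.
#'
#' @param samples Named list of numeric samples (one per state); at
#'   least two must be nonempty.
#' @param paired Use the signed-rank test on paired samples (all samples
#'   must then have equal length). Default `FALSE`.
#' @return A symmetric matrix of p-values with unit diagonal.
#' @export
pairwise_wilcoxon <- function(samples, paired = FALSE) {
  samples <- samples[vapply(samples, length, 0L) > 0L]
  k <- length(samples)
  if (k < 2L)
    .stopf("pairwise_wilcoxon: need at least two nonempty samples")
  p <- matrix(1, k, k, dimnames = list(names(samples), names(samples)))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      pij <- if (paired) {
        if (length(samples[[i]]) != length(samples[[j]]))
          .stopf("pairwise_wilcoxon: paired mode needs equal lengths")
        suppressWarnings(wilcox.test(samples[[i]], samples[[j]],
                                     paired = TRUE))$p.value
      } else {
        mann_whitney_u(samples[[i]], samples[[j]])$p_value
      }
      p[i, j] <- p[j, i] <- min(pij, 1)
    }
  }
  p
}

# label per bin: midpoint of each bin located in the segmentation
.bin_labels <- function(grid, seg) {
  bins <- bin_ranges(grid)
  mids <- GRanges(seqnames(bins),
                  IRanges(start(bins) + (width(bins) - 1L) %/% 2L,
                          width = 1L))
  lab <- rep(NA_character_, length(bins))
  hits <- findOverlaps(mids, seg, ignore.strand = TRUE)
  lab[queryHits(hits)] <- mcols(seg)$label[subjectHits(hits)]
  lab
}

.bins_in_regions <- function(grid, regions) {
  bins <- bin_ranges(grid)
  mids <- GRanges(seqnames(bins),
                  IRanges(start(bins) + (width(bins) - 1L) %/% 2L,
                          width = 1L))
  overlapsAny(mids, regions, ignore.strand = TRUE)
}

#' Per (track, state) enrichment table with significance calls
#'
#' For every track and state, compares the track's bin values within
#' that state inside the compartment against the bin values of the
#' background regions (all states pooled). The effect size is the log2
#' ratio of means; significance is the two-sided Mann-Whitney test at
#' the stated alpha, with no multiple-testing correction by default
#' (a Bonferroni option is provided). Bins are assigned to regions and
#' states by their midpoints. Note that neighbouring bins are
#' autocorrelated, so bin-level p-values are anti-conservative; this is
#' recorded in the table metadata.
#'
#' @param tracks List of `"signal_track"` objects on the segmentation's
#'   grid.
#' @param seg Segmentation `GRanges` with a `label` column.
#' @param compartment `GRanges` of the compartment of interest.
#' @param background `GRanges` of the background regions.
#' @param alpha Significance threshold (default 0.001, two-sided).
#' @param bonferroni Divide alpha by the number of tested rows.
#' @return A data.frame (class `"enrichment_table"`) with one row per
#'   (track, state): means, `log2_enrichment`, `U`, `p_value`,
#'   `significant` and a `flag` column marking rows with empty or
#'   degenerate samples. Metadata (`alpha`, bin size, sampling-unit
#'   note) is stored in attributes.
#' @export
enrichment_table <- function(tracks, seg, compartment, background,
                             alpha = 0.001, bonferroni = FALSE) {
  if (!length(tracks)) .stopf("enrichment_table: no tracks")
  grid <- tracks[[1]]$grid
  lab_per_bin <- .bin_labels(grid, seg)
  in_comp <- .bins_in_regions(grid, compartment)
  in_bg <- .bins_in_regions(grid, background)
  labs <- sort(unique(mcols(seg)$label))
  if (all(labs %in% .state_names))
    labs <- .state_names[.state_names %in% labs]
  n_tests <- length(tracks) * length(labs)
  alpha_eff <- if (bonferroni) alpha / n_tests else alpha
  rows <- list()
  for (tr in tracks) {
    bg_idx <- which(in_bg & tr$mask)
    y <- tr$values[bg_idx]
    for (lab in labs) {
      sel <- which(in_comp & tr$mask & !is.na(lab_per_bin) &
                     lab_per_bin == lab)
      x <- tr$values[sel]
      if (length(x) == 0L || length(y) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          track_id = tr$track_id, state = lab,
          n_in = length(x), n_background = length(y),
          mean_in = NA_real_, mean_background = NA_real_,
          log2_enrichment = NA_real_, U = NA_real_, p_value = NA_real_,
          significant = NA, flag = "empty_sample",
          stringsAsFactors = FALSE)
        next
      }
      m_in <- mean(x); m_bg <- mean(y)
      l2 <- if (m_in > 0 && m_bg > 0) log2(m_in / m_bg) else NA_real_
      flag <- if (is.na(l2)) "zero_mean" else ""
      mw <- mann_whitney_u(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = tr$track_id, state = lab,
        n_in = length(x), n_background = length(y),
        mean_in = m_in, mean_background = m_bg,
        log2_enrichment = l2, U = mw$U, p_value = mw$p_value,
        significant = mw$p_value < alpha_eff, flag = flag,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "alpha_effective") <- alpha_eff
  attr(out, "bin_size") <- grid$bin_size
  attr(out, "sampling_unit") <-
    "bins (autocorrelated; p-values anti-conservative)"
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Write a report data.frame as TSV with a commented metadata header
#'
#' @param df A data.frame (attributes whose values are scalars are
#'   emitted as `# key: value` lines).
#' @param path Output path.
#' @param meta Named list of extra metadata lines.
#' @export
write_report_tsv <- function(df, path, meta = list()) {
  auto <- attributes(df)
  auto <- auto[setdiff(names(auto), c("names", "row.names", "class"))]
  meta <- c(auto[vapply(auto, function(v)
    is.atomic(v) && length(v) == 1L, TRUE)], meta)
  con <- file(path, "wt")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
  write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
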