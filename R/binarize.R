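#' Binarize a signal track at an empirical quantile
#'
#' The threshold is the given empirical quantile (linear interpolation,
#' the default quantile type) of the observed (unmasked) values; a bin is
#' set when its value is strictly greater than the threshold, so a
#' constant track binarizes to all zeros. Masked bins stay masked.
#'
#' @param track A `"signal_track"`.
#' @param quantile Quantile in (0, 1); default 0.9.
#' @return A `"binary_track"`: list with `track_id`, integer `bits`
#'   (0/1), the `threshold` used, `mask` and the governing `grid`.
#' @examples
#' g <- bin_genome(chrom_sizes(c(chrA = 2000)), 200)
#' tr <- signal_track("x", 1:10, grid = g)
#' binarize(tr, 0.9)$threshold  # 9.1
#' @export
binarize <- function(track, quantile = 0.9) {
  if (length(quantile) != 1L || !is.finite(quantile) ||
      quantile <= 0 || quantile >= 1)
    .stopf("binarize: quantile must be in (0, 1)")
  obs <- track$values[track$mask]
  if (length(obs) == 0L)
    .stopf("binarize: all bins are masked")
  thr <- unname(stats::quantile(obs, quantile, names = FALSE))
  bits <- as.integer(track$values > thr)
  bits[!track$mask] <- 0L
  structure(list(track_id = track$track_id, bits = bits, threshold = thr,
                 mask = track$mask, grid = track$grid),
            class = "binary_track")
}

#' Treat an already-discrete track as binary
#'
#' For presence tracks (values already in \{0, 1\}, e.g. projected peak
#' calls) quantile binarization is not meaningful; this sets the bit
#' wherever the value exceeds `threshold` (default 0, i.e. any
#' presence).
#'
#' @param track A `"signal_track"`.
#' @param threshold Strict lower bound for a set bit (default 0).
#' @return A `"binary_track"`.
#' @export
as_binary_track <- function(track, threshold = 0) {
  bits <- as.integer(track$values > threshold)
  bits[!track$mask] <- 0L
  structure(list(track_id = track$track_id, bits = bits,
                 threshold = threshold, mask = track$mask,
                 grid = track$grid),
            class = "binary_track")
}

#' Stack binarized tracks into an observation matrix
#'
#' Rows follow the input order; the combined mask is the AND of the
#' per-track masks, so a bin unobserved in any track is excluded from
#' training and decoding.
#'
#' @param tracks List of `"binary_track"` objects on the same grid.
#' @return A `"binary_tracks"` object: `track_ids`, an M x n_bins 0/1
#'   matrix `data`, the combined `mask` and the `grid`.
#' @export
stack_tracks <- function(tracks) {
  if (length(tracks) < 1L)
    .stopf("stack_tracks: need at least one track")
  n <- vapply(tracks, function(t) length(t$bits), 0L)
  if (length(unique(n)) != 1L)
    .stopf("stack_tracks: tracks have differing bin counts")
  grids_ok <- vapply(tracks[-1], function(t)
    .check_grid_match(t$grid, tracks[[1]]$grid), TRUE)
  if (length(grids_ok) && !all(grids_ok))
    .stopf("stack_tracks: tracks are on different bin grids")
  ids <- vapply(tracks, `[[`, "", "track_id")
  if (anyDuplicated(ids))
    .stopf("stack_tracks: duplicate track ids")
  data <- do.call(rbind, lapply(tracks, `[[`, "bits"))
  rownames(data) <- ids
  mask <- Reduce(`&`, lapply(tracks, `[[`, "mask"))
  binary_tracks(ids, data, mask, tracks[[1]]$grid)
}

#' Construct a binary observation matrix directly
#'
#' @param track_ids Character vector of M unique ids.
#' @param data M x n_bins matrix with entries in \{0, 1\} at observed
#'   bins.
#' @param mask Logical vector of length n_bins (`TRUE` = observed).
#' @param grid The governing `"binned_genome"` (optional but required by
#'   segmentation-producing steps).
#' @return A `"binary_tracks"` object.
#' @export
binary_tracks <- function(track_ids, data, mask = NULL, grid = NULL) {
  data <- as.matrix(data)
  if (is.null(mask)) mask <- rep(TRUE, ncol(data))
  if (nrow(data) != length(track_ids))
    .stopf("binary_tracks: row count must match track_ids")
  if (anyDuplicated(track_ids))
    .stopf("binary_tracks: duplicate track ids")
  if (length(mask) != ncol(data))
    .stopf("binary_tracks: mask length must match bin count")
  if (any(mask) && !all(data[, mask] %in% c(0L, 1L)))
    .stopf("binary_tracks: observed entries must be 0 or 1")
  rownames(data) <- track_ids
  structure(list(track_ids = as.character(track_ids),
                 data = data, mask = as.logical(mask), grid = grid),
            class = "binary_tracks")
}

#' @export
print.binary_tracks <- function(x, ...) {
  cat(sprintf("binary_tracks: %d track(s) x %d bins (%d observed)\n",
              nrow(x$data), ncol(x$data), sum(x$mask)))
  invisible(x)
}

# contiguous runs of observed bins; masked bins split the sequence into
# independent segments
.mask_segments <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  Map(function(s, e) s:e, starts[keep], ends[keep])
}
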