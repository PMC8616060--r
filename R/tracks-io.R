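#' Read a UCSC-style chrom.sizes file
#'
#' Parses a two-column whitespace-separated text file of chromosome names
#' and lengths (bp). Order of the file is preserved; it defines the
#' chromosome order of every downstream bin grid.
#'
#' @param path Path to a chrom.sizes file (gzip accepted by extension).
#' @return A named numeric vector of chromosome lengths with class
#'   `"chrom_sizes"`.
#' @examples
#' f <- tempfile()
#' writeLines("chr3LHet\t2555491", f)
#' read_chrom_sizes(f)
#' @export
read_chrom_sizes <- function(path) {
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L)
    .stopf("chrom.sizes '%s': no chromosomes found", path)
  nm <- character(length(keep))
  len <- numeric(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(f) < 2L)
      .stopf("chrom.sizes '%s' line %d: expected two columns", path, ln)
    l <- suppressWarnings(as.numeric(f[2]))
    if (is.na(l) || l != floor(l))
      .stopf("chrom.sizes '%s' line %d: length '%s' is not an integer",
             path, ln, f[2])
    if (l <= 0)
      .stopf("chrom.sizes '%s' line %d: non-positive length %s",
             path, ln, f[2])
    if (f[1] %in% nm[seq_len(i - 1L)])
      .stopf("chrom.sizes '%s' line %d: duplicate chromosome '%s'",
             path, ln, f[1])
    nm[i] <- f[1]
    len[i] <- l
  }
  chrom_sizes(setNames(len, nm))
}

#' Construct a chrom_sizes object from a named vector
#'
#' @param x Named numeric vector: chromosome name -> length in bp.
#' @return A `"chrom_sizes"` object.
#' @export
chrom_sizes <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    .stopf("chrom_sizes: all chromosomes must be named")
  if (anyDuplicated(names(x)))
    .stopf("chrom_sizes: duplicate chromosome names")
  if (any(!is.finite(x)) || any(x <= 0))
    .stopf("chrom_sizes: all lengths must be positive")
  structure(setNames(as.numeric(x), names(x)), class = "chrom_sizes")
}

#' Write a chrom.sizes file
#'
#' @param sizes A `"chrom_sizes"` object.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes), format(unname(sizes), scientific = FALSE,
                                        trim = TRUE), sep = "\t"), path)
  invisible(path)
}

.sizes_seqinfo <- function(sizes) {
  Seqinfo(seqnames = names(sizes), seqlengths = as.integer(unname(sizes)))
}

#' Read a BED file into a GRanges
#'
#' Accepts BED3+ (optional name, score, strand columns); `track`,
#' `browser` and `#` comment lines are skipped. BED coordinates are
#' 0-based half-open on disk and are converted to the 1-based closed
#' GRanges convention. When `sizes` is supplied every interval is
#' validated against it; unknown chromosomes are a hard error unless
#' `skip_unknown = TRUE`.
#'
#' @param path BED file path (gzip accepted by extension).
#' @param sizes Optional `"chrom_sizes"` to validate against.
#' @param skip_unknown Drop intervals on chromosomes absent from `sizes`
#'   instead of erroring. Default `FALSE` (fail loudly on genome-build
#'   mismatch).
#' @return A `GRanges`; `name` and `score` columns appear in `mcols()`
#'   when present in the file.
#' @export
read_bed <- function(path, sizes = NULL, skip_unknown = FALSE) {
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  is_skip <- !nzchar(trimws(lines)) |
    grepl("^(#|track\\b|browser\\b)", lines)
  keep <- which(!is_skip)
  chrom <- character(0); s0 <- numeric(0); e0 <- numeric(0)
  nm <- character(0); sc <- numeric(0); str <- character(0)
  has_name <- FALSE; has_score <- FALSE; has_strand <- FALSE
  out_chrom <- vector("list", length(keep))
  rows <- vector("list", length(keep))
  n_out <- 0L
  for (ln in keep) {
    f <- strsplit(lines[ln], "[ \t]+")[[1]]
    if (length(f) < 3L)
      .stopf("BED '%s' line %d: fewer than 3 columns", path, ln)
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end))
      .stopf("BED '%s' line %d: non-numeric coordinates", path, ln)
    if (start < 0)
      .stopf("BED '%s' line %d: negative start", path, ln)
    if (start >= end)
      .stopf("BED '%s' line %d: start >= end (empty interval)", path, ln)
    if (!is.null(sizes)) {
      if (!(f[1] %in% names(sizes))) {
        if (skip_unknown) next
        .stopf("BED '%s' line %d: unknown chromosome '%s'", path, ln, f[1])
      }
      if (end > sizes[[f[1]]])
        .stopf("BED '%s' line %d: end %s beyond chromosome length %s",
               path, ln, f[3], format(sizes[[f[1]]], scientific = FALSE))
    }
    n_out <- n_out + 1L
    rows[[n_out]] <- list(
      chrom = f[1], start = start, end = end,
      name = if (length(f) >= 4L) f[4] else NA_character_,
      score = if (length(f) >= 5L && f[5] != ".")
        suppressWarnings(as.numeric(f[5])) else NA_real_,
      strand = if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else "*")
    if (length(f) >= 4L) has_name <- TRUE
    if (length(f) >= 5L) has_score <- TRUE
    if (length(f) >= 6L) has_strand <- TRUE
  }
  rows <- rows[seq_len(n_out)]
  if (n_out == 0L) {
    gr <- GRanges()
    if (!is.null(sizes)) seqinfo(gr) <- .sizes_seqinfo(sizes)
    return(gr)
  }
  chrom <- vapply(rows, `[[`, "", "chrom")
  lev <- if (is.null(sizes)) unique(chrom) else names(sizes)
  gr <- GRanges(
    seqnames = factor(chrom, levels = lev),
    ranges = IRanges(start = vapply(rows, `[[`, 0, "start") + 1,
                     end = vapply(rows, `[[`, 0, "end")),
    strand = if (has_strand) vapply(rows, `[[`, "", "strand") else "*")
  if (!is.null(sizes)) seqinfo(gr) <- .sizes_seqinfo(sizes)
  if (has_name) mcols(gr)$name <- vapply(rows, `[[`, "", "name")
  if (has_score) mcols(gr)$score <- vapply(rows, `[[`, 0, "score")
  gr
}

#' Write a GRanges as a BED file
#'
#' Coordinates are written 0-based half-open. `name`, `score` and strand
#' columns are emitted only when present (missing scores print as 0 when
#' a later column forces the field). `read_bed(write_bed(x))` reproduces
#' `x`'s coordinates and names.
#'
#' @param x A `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  if (length(x) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = format(start(x) - 1, scientific = FALSE,
                                  trim = TRUE),
                   end = format(end(x), scientific = FALSE, trim = TRUE),
                   stringsAsFactors = FALSE)
  has_name <- !is.null(mcols(x)$name)
  has_score <- !is.null(mcols(x)$score)
  has_strand <- any(as.character(strand(x)) != "*")
  if (has_name || has_score || has_strand)
    df$name <- if (has_name) mcols(x)$name else "."
  if (has_score || has_strand) {
    sc <- if (has_score) mcols(x)$score else 0
    sc[is.na(sc)] <- 0
    df$score <- sc
  }
  if (has_strand) {
    st <- as.character(strand(x))
    st[st == "*"] <- "."
    df$strand <- st
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Divide a genome into fixed-width bins
#'
#' Bins are laid out chromosome by chromosome in chrom.sizes order; the
#' last bin of each chromosome may be shorter than `bin_size` (it is
#' kept, and downstream coverage fractions use its true width). Global
#' bin ordinals are contiguous 1-based integers.
#'
#' @param sizes A `"chrom_sizes"` object.
#' @param bin_size Bin width in bp (default 200).
#' @return A `"binned_genome"` object.
#' @examples
#' g <- bin_genome(chrom_sizes(c(chrA = 1000, chrB = 400)), 200)
#' g$n_bins  # 7
#' @export
bin_genome <- function(sizes, bin_size = 200) {
  if (!inherits(sizes, "chrom_sizes")) sizes <- chrom_sizes(sizes)
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size <= 0 ||
      bin_size != floor(bin_size))
    .stopf("bin_genome: bin_size must be a positive integer")
  nb <- as.integer(ceiling(unname(sizes) / bin_size))
  offset <- c(0L, cumsum(nb))[seq_along(nb)]
  structure(list(
    sizes = sizes,
    bin_size = as.integer(bin_size),
    n_per_chrom = setNames(nb, names(sizes)),
    offset = setNames(offset, names(sizes)),
    n_bins = sum(nb)
  ), class = "binned_genome")
}

#' @export
print.binned_genome <- function(x, ...) {
  cat(sprintf("binned_genome: %d chromosome(s), bin_size=%d, n_bins=%d\n",
              length(x$sizes), x$bin_size, x$n_bins))
  invisible(x)
}

#' Global bin ordinal of a (chromosome, local ordinal) pair
#'
#' @param grid A `"binned_genome"`.
#' @param chrom Chromosome name(s).
#' @param local 1-based bin ordinal(s) within the chromosome.
#' @return 1-based global ordinal(s).
#' @export
bin_ordinal <- function(grid, chrom, local) {
  if (any(!(chrom %in% names(grid$sizes))))
    .stopf("bin_ordinal: unknown chromosome")
  if (any(local < 1L) || any(local > grid$n_per_chrom[chrom]))
    .stopf("bin_ordinal: local ordinal out of range")
  unname(grid$offset[chrom] + local)
}

#' Locate global bin ordinals on the genome
#'
#' Inverse of [bin_ordinal()]: returns chromosome, local ordinal and
#' 0-based half-open bp coordinates for each global ordinal.
#'
#' @param grid A `"binned_genome"`.
#' @param i 1-based global bin ordinal(s).
#' @return A data.frame with columns chrom, local, start, end (0-based
#'   half-open bp).
#' @export
bin_locate <- function(grid, i) {
  if (any(i < 1L) || any(i > grid$n_bins))
    .stopf("bin_locate: ordinal out of range")
  chrom_idx <- findInterval(i - 1L, unname(grid$offset))
  chrom <- names(grid$sizes)[chrom_idx]
  local <- i - unname(grid$offset)[chrom_idx]
  start <- (local - 1) * grid$bin_size
  end <- pmin(local * grid$bin_size, unname(grid$sizes)[chrom_idx])
  data.frame(chrom = chrom, local = local, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' All bins of a grid as a GRanges
#'
#' @param grid A `"binned_genome"`.
#' @return A `GRanges`, one range per bin in global ordinal order.
#' @export
bin_ranges <- function(grid) {
  sizes <- grid$sizes
  parts <- lapply(names(sizes), function(ch) {
    nb <- grid$n_per_chrom[[ch]]
    st <- seq_len(nb) * grid$bin_size - grid$bin_size + 1
    en <- pmin(seq_len(nb) * grid$bin_size, sizes[[ch]])
    GRanges(factor(ch, names(sizes)), IRanges(st, en))
  })
  gr <- do.call(c, parts)
  seqinfo(gr) <- .sizes_seqinfo(sizes)
  gr
}

.check_grid_match <- function(a, b) {
  identical(unname(a$sizes), unname(b$sizes)) &&
    identical(names(a$sizes), names(b$sizes)) &&
    a$bin_size == b$bin_size
}

#' Project intervals onto a bin grid as a signal track
#'
#' `presence` mode sets a bin to 1.0 when any interval overlaps it;
#' `coverage_fraction` records overlapping bp divided by the bin's true
#' width (intervals are overlap-merged first so depth does not inflate
#' coverage). All bins are observed (mask all `TRUE`).
#'
#' @param intervals A `GRanges` of intervals (validated against the
#'   grid's chromosomes).
#' @param grid A `"binned_genome"`.
#' @param mode `"coverage_fraction"` or `"presence"`.
#' @param track_id Identifier stored on the track.
#' @return A `"signal_track"`.
#' @export
intervals_to_track <- function(intervals, grid,
                               mode = c("coverage_fraction", "presence"),
                               track_id = "track") {
  mode <- match.arg(mode)
  bad <- setdiff(as.character(unique(seqnames(intervals))),
                 names(grid$sizes))
  if (length(bad))
    .stopf("intervals_to_track: chromosome(s) %s not in grid",
           paste(bad, collapse = ", "))
  values <- numeric(grid$n_bins)
  if (length(intervals)) {
    red <- reduce(granges(intervals), ignore.strand = TRUE)
    if (any(end(red) > grid$sizes[as.character(seqnames(red))]))
      .stopf("intervals_to_track: interval beyond chromosome end")
    red <- GRanges(factor(as.character(seqnames(red)),
                          names(grid$sizes)), ranges(red))
    seqinfo(red) <- .sizes_seqinfo(grid$sizes)
    cov <- coverage(red)
    for (ch in names(grid$sizes)) {
      nb <- grid$n_per_chrom[[ch]]
      st <- seq_len(nb) * grid$bin_size - grid$bin_size + 1
      en <- pmin(seq_len(nb) * grid$bin_size, grid$sizes[[ch]])
      covered <- viewSums(Views(cov[[ch]], IRanges(st, en)))
      idx <- grid$offset[[ch]] + seq_len(nb)
      values[idx] <- if (mode == "presence") as.numeric(covered > 0)
                     else covered / (en - st + 1)
    }
  }
  signal_track(track_id, values, mask = rep(TRUE, grid$n_bins),
               grid = grid)
}

#' Construct a signal track
#'
#' @param track_id Track identifier.
#' @param values Numeric vector, one value per bin of `grid`.
#' @param mask Logical vector (`TRUE` = observed); values must be finite
#'   wherever the mask is `TRUE`.
#' @param grid The governing `"binned_genome"`.
#' @return A `"signal_track"` object.
#' @export
signal_track <- function(track_id, values, mask = NULL, grid) {
  if (is.null(mask)) mask <- rep(TRUE, length(values))
  if (length(values) != grid$n_bins || length(mask) != grid$n_bins)
    .stopf("signal_track: values/mask length must equal n_bins (%d)",
           grid$n_bins)
  if (any(!is.finite(values[mask])))
    .stopf("signal_track: non-finite values at observed bins")
  structure(list(track_id = track_id, values = as.numeric(values),
                 mask = as.logical(mask), grid = grid),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track '%s': %d bins (%d observed)\n",
              x$track_id, length(x$values), sum(x$mask)))
  invisible(x)
}

#' Read a bedGraph file onto a bin grid
#'
#' Four-column bedGraph (chrom, start, end, value; 0-based half-open).
#' Each bin receives the bp-weighted mean (or the max) of the records
#' overlapping it; bins no record touches are masked out.
#'
#' @param path bedGraph path (gzip accepted by extension).
#' @param grid A `"binned_genome"`.
#' @param aggregate `"mean"` (bp-weighted) or `"max"`.
#' @param track_id Identifier for the resulting track.
#' @return A `"signal_track"` with `mask = FALSE` at uncovered bins.
#' @export
read_bedgraph <- function(path, grid, aggregate = c("mean", "max"),
                          track_id = NULL) {
  aggregate <- match.arg(aggregate)
  if (is.null(track_id))
    track_id <- sub("\\.(bedgraph|bdg|bedGraph)(\\.gz)?$", "",
                    basename(path))
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^(#|track\\b|browser\\b)", lines))
  chrom <- character(length(keep)); s0 <- numeric(length(keep))
  e0 <- numeric(length(keep)); val <- numeric(length(keep))
  for (j in seq_along(keep)) {
    ln <- keep[j]
    f <- strsplit(lines[ln], "[ \t]+")[[1]]
    if (length(f) < 4L)
      .stopf("bedGraph '%s' line %d: expected 4 columns", path, ln)
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    v <- suppressWarnings(as.numeric(f[4]))
    if (is.na(s) || is.na(e) || is.na(v))
      .stopf("bedGraph '%s' line %d: non-numeric field", path, ln)
    if (s < 0 || s >= e)
      .stopf("bedGraph '%s' line %d: invalid interval", path, ln)
    if (!(f[1] %in% names(grid$sizes)))
      .stopf("bedGraph '%s' line %d: unknown chromosome '%s'",
             path, ln, f[1])
    if (e > grid$sizes[[f[1]]])
      .stopf("bedGraph '%s' line %d: end beyond chromosome", path, ln)
    chrom[j] <- f[1]; s0[j] <- s; e0[j] <- e; val[j] <- v
  }
  values <- numeric(grid$n_bins)
  mask <- rep(FALSE, grid$n_bins)
  if (length(keep)) {
    rec <- GRanges(factor(chrom, names(grid$sizes)),
                   IRanges(s0 + 1, e0))
    bins <- bin_ranges(grid)
    hits <- findOverlaps(bins, rec, ignore.strand = TRUE)
    if (length(hits)) {
      bi <- queryHits(hits); ri <- subjectHits(hits)
      ow <- width(pintersect(bins[bi], rec[ri]))
      if (aggregate == "mean") {
        num <- tapply(val[ri] * ow, bi, sum)
        den <- tapply(ow, bi, sum)
        idx <- as.integer(names(num))
        values[idx] <- as.numeric(num) / as.numeric(den)
      } else {
        mx <- tapply(val[ri], bi, max)
        idx <- as.integer(names(mx))
        values[idx] <- as.numeric(mx)
      }
      mask[idx] <- TRUE
    }
  }
  signal_track(track_id, values, mask = mask, grid = grid)
}

#' Mask bins overlapping assembly gaps
#'
#' Returns a copy of `track` with bins overlapping any gap interval
#' masked out (mask `FALSE`), so they are excluded from binarization,
#' HMM training and decoding.
#'
#' @param track A `"signal_track"`.
#' @param gaps A `GRanges` of gap intervals (e.g. from a gap BED).
#' @return A `"signal_track"`.
#' @export
mask_gaps <- function(track, gaps) {
  hit <- overlapsAny(bin_ranges(track$grid), gaps, ignore.strand = TRUE)
  track$mask[hit] <- FALSE
  track
}
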