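#' Region length in megabases from border coordinates
#'
#' Border coordinates are marker positions (1-based genomic positions as
#' printed in annotation databases); the region spans from one border up
#' to, but not including, the other, so the length is simply the
#' coordinate difference. Full precision is kept; rounding is
#' display-only.
#'
#' @param start,end Border coordinates in bp, `end > start`.
#' @return Length in Mb.
#' @examples
#' region_length_mb(22267604, 23151844)  # 0.88424
#' @export
region_length_mb <- function(start, end) {
  if (any(!is.finite(start)) || any(!is.finite(end)))
    .stopf("region_length_mb: coordinates must be finite")
  if (any(end <= start))
    .stopf("region_length_mb: end must exceed start")
  (end - start) / 1e6
}

#' Construct a named genomic region
#'
#' @param name Region name (e.g. "variability_zone", "10A1-2").
#' @param chrom Chromosome name, or `NA` when unknown.
#' @param start,end 1-based border coordinates (the region spans
#'   `[start, end)` in border terms), or `NA` when the literature gives
#'   no coordinates.
#' @param markers Optional character vector of flanking marker names.
#' @return A `"named_region"` object.
#' @export
named_region <- function(name, chrom = NA_character_, start = NA_real_,
                         end = NA_real_, markers = NULL) {
  if (!is.na(start) && !is.na(end) && end <= start)
    .stopf("named_region '%s': end must exceed start", name)
  structure(list(name = name, chrom = chrom, start = start, end = end,
                 markers = markers), class = "named_region")
}

#' @export
print.named_region <- function(x, ...) {
  coord <- if (is.na(x$start)) "coordinates unknown" else
    sprintf("%s:%s-%s (%.5f Mb)", x$chrom,
            format(x$start, big.mark = ","),
            format(x$end, big.mark = ","),
            region_length_mb(x$start, x$end))
  cat(sprintf("named_region '%s': %s\n", x$name, coord))
  invisible(x)
}

.region_granges <- function(region) {
  if (is.na(region$chrom) || is.na(region$start) || is.na(region$end))
    .stopf("region '%s' has unknown coordinates", region$name)
  # border semantics: region covers [start, end) in 1-based positions
  GRanges(region$chrom, IRanges(region$start, region$end - 1))
}

#' Feature density of a region in features per Mb
#'
#' Counts features by one of three rules — `start_in` (the feature's
#' leftmost bp lies in the region; each feature counted once across a
#' partition), `midpoint_in`, or `any_overlap` — and divides by the
#' region length in Mb. Alternatively a pre-supplied `(count,
#' length_mb)` pair can be given for literature-style worked examples.
#'
#' @param features A `GRanges` of features (genes, ORC sites), or `NULL`
#'   when `count` and `length_mb` are given directly.
#' @param region A `"named_region"` with known coordinates (ignored when
#'   `count`/`length_mb` are supplied, except for its name).
#' @param counting_rule One of `"start_in"`, `"midpoint_in"`,
#'   `"any_overlap"`.
#' @param count,length_mb Direct inputs bypassing interval counting.
#' @return A `"density_report"`: list with `region`, `length_mb`,
#'   `count`, `density_per_mb` (full precision) and `density_display`
#'   (rounded for reporting: one decimal below 15, nearest integer
#'   otherwise).
#' @examples
#' feature_density(region = named_region("10A1-2"),
#'                 count = 18, length_mb = 0.189)$density_display  # 95
#' @export
feature_density <- function(features = NULL, region,
                            counting_rule = c("start_in", "midpoint_in",
                                              "any_overlap"),
                            count = NULL, length_mb = NULL) {
  counting_rule <- match.arg(counting_rule)
  if (is.null(count) != is.null(length_mb))
    .stopf("feature_density: supply both count and length_mb or neither")
  if (is.null(count)) {
    rg <- .region_granges(region)
    length_mb <- region_length_mb(region$start, region$end)
    if (is.null(features)) .stopf("feature_density: no features given")
    pts <- switch(counting_rule,
      start_in = GRanges(seqnames(features),
                         IRanges(start(features), width = 1L)),
      midpoint_in = GRanges(seqnames(features),
                            IRanges(start(features) +
                                      (width(features) - 1L) %/% 2L,
                                    width = 1L)),
      any_overlap = granges(features))
    count <- sum(overlapsAny(pts, rg, ignore.strand = TRUE))
  } else {
    if (length_mb <= 0) .stopf("feature_density: length_mb must be > 0")
    if (count < 0) .stopf("feature_density: count must be >= 0")
    counting_rule <- "supplied"
  }
  density <- count / length_mb
  structure(list(region = region$name, length_mb = length_mb,
                 count = as.integer(count), density_per_mb = density,
                 counting_rule = counting_rule,
                 density_display = format_density(density)),
            class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("%s: %d feature(s) / %.5g Mb = %s per Mb [%s]\n",
              x$region, x$count, x$length_mb,
              format(x$density_display), x$counting_rule))
  invisible(x)
}

#' Display rounding for densities
#'
#' One decimal place below 15 per Mb, nearest integer otherwise —
#' matching the conventions of printed gene-density figures (7.5, 14,
#' 60, 95). Stored values keep full precision; this is display-only.
#'
#' @param x Numeric densities.
#' @return Rounded numeric vector.
#' @export
format_density <- function(x) {
  ifelse(x < 15, round(x, 1), round(x))
}

#' Ratio of two region densities
#'
#' @param a,b `"density_report"` objects (or numbers); `b`'s density
#'   must be positive.
#' @return `a`'s density divided by `b`'s.
#' @export
density_ratio <- function(a, b) {
  da <- if (inherits(a, "density_report")) a$density_per_mb else a
  db <- if (inherits(b, "density_report")) b$density_per_mb else b
  if (db <= 0) .stopf("density_ratio: denominator density must be > 0")
  da / db
}

.expression_levels <- c("ExtremelyLowNone", "VeryLow", "Low", "Moderate",
                        "ModerateHigh", "High", "VeryHigh",
                        "ExtremelyHigh")

#' Classify RPKM values into the eight expression categories
#'
#' Categories and bin edges: ExtremelyHigh (>1000), VeryHigh (101-1000),
#' High (51-100), ModerateHigh (26-50), Moderate (11-25), Low (4-10),
#' VeryLow (1-3), ExtremelyLow/None (0). The classifier is total over
#' nonnegative reals and monotone: fractional values falling between two
#' integer bins (e.g. 100.5) join the upper neighbouring category, and
#' values below 1 join ExtremelyLow/None.
#'
#' @param rpkm Nonnegative finite numeric vector.
#' @return An ordered factor over the eight categories (ascending
#'   expression).
#' @examples
#' classify_expression(c(0, 1000, 1001, 50))
#' @export
classify_expression <- function(rpkm) {
  if (any(!is.finite(rpkm)))
    .stopf("classify_expression: RPKM must be finite")
  if (any(rpkm < 0))
    .stopf("classify_expression: RPKM must be >= 0")
  cat <- rep("ExtremelyLowNone", length(rpkm))
  cat[rpkm >= 1] <- "VeryLow"
  cat[rpkm > 3] <- "Low"
  cat[rpkm > 10] <- "Moderate"
  cat[rpkm > 25] <- "ModerateHigh"
  cat[rpkm > 50] <- "High"
  cat[rpkm > 100] <- "VeryHigh"
  cat[rpkm > 1000] <- "ExtremelyHigh"
  factor(cat, levels = .expression_levels, ordered = TRUE)
}

#' Tally a gene's per-tissue RPKM vector into expression categories
#'
#' @param rpkm_by_tissue Numeric vector of per-tissue RPKM values.
#' @param n_tissues Expected number of tissues (default 29); the vector
#'   length must match and the tallies always sum to it.
#' @return Named integer vector of per-category counts, ordered from
#'   ExtremelyHigh down to ExtremelyLow/None (report order).
#' @export
expression_profile <- function(rpkm_by_tissue, n_tissues = 29) {
  if (length(rpkm_by_tissue) != n_tissues)
    .stopf("expression_profile: expected %d tissues, got %d",
           n_tissues, length(rpkm_by_tissue))
  tab <- table(classify_expression(rpkm_by_tissue))
  out <- setNames(as.integer(tab[rev(.expression_levels)]),
                  rev(.expression_levels))
  out[is.na(out)] <- 0L
  out
}

#' Load a named-region partition file
#'
#' The file is tab-separated with a header (`name`, `chrom`, `start`,
#' `end`, optional `markers`); `start`/`end` are 1-based border
#' coordinates and the literal `unknown` (or `.`) marks coordinates the
#' literature does not provide. Overlapping regions trigger a warning
#' (adjacent regions that share a border do not overlap).
#'
#' A default partition of the pericentromeric regions of chromosome 3,
#' with the published variability-zone borders and explicit unknowns
#' elsewhere, ships with the package:
#' `system.file("extdata", "het3_region_partition.tsv",
#' package = "chromstates")`.
#'
#' @param path Partition file path.
#' @return A list of `"named_region"` (class `"region_partition"`),
#'   in file order.
#' @export
load_region_partition <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, comment.char = "#",
                   quote = "")
  need <- c("name", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    .stopf("partition '%s': missing column(s) %s", path,
           paste(setdiff(need, names(df)), collapse = ", "))
  parse_coord <- function(v) {
    v[v %in% c("unknown", ".", "NA", "")] <- NA
    out <- suppressWarnings(as.numeric(v))
    if (any(is.na(out) & !is.na(v)))
      .stopf("partition '%s': non-numeric coordinate", path)
    out
  }
  start <- parse_coord(as.character(df$start))
  end <- parse_coord(as.character(df$end))
  chrom <- as.character(df$chrom)
  chrom[chrom %in% c("unknown", ".", "")] <- NA
  regions <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    mk <- if ("markers" %in% names(df) && nzchar(df$markers[i]) &&
              !df$markers[i] %in% c("unknown", "."))
      strsplit(df$markers[i], ";")[[1]] else NULL
    regions[[i]] <- named_region(df$name[i], chrom[i], start[i], end[i],
                                 markers = mk)
  }
  known <- which(!is.na(start) & !is.na(end) & !is.na(chrom))
  if (length(known) > 1L) {
    for (i in head(known, -1)) for (j in known[known > i]) {
      if (chrom[i] == chrom[j] &&
          max(start[i], start[j]) < min(end[i], end[j]))
        warning(sprintf("regions '%s' and '%s' overlap", df$name[i],
                        df$name[j]), call. = FALSE)
    }
  }
  structure(regions, class = "region_partition",
            names = vapply(regions, `[[`, "", "name"))
}

#' Write a region partition file
#'
#' Inverse of [load_region_partition()]: `load_region_partition(
#' write_region_partition(x))` reproduces `x`.
#'
#' @param partition A `"region_partition"` (list of `"named_region"`).
#' @param path Output path.
#' @export
write_region_partition <- function(partition, path) {
  fmt <- function(v) ifelse(is.na(v), "unknown",
                            format(v, scientific = FALSE, trim = TRUE))
  df <- data.frame(
    name = vapply(partition, `[[`, "", "name"),
    chrom = fmt(vapply(partition, function(r)
      as.character(r$chrom), "")),
    start = fmt(vapply(partition, function(r)
      as.numeric(r$start), 0)),
    end = fmt(vapply(partition, function(r) as.numeric(r$end), 0)),
    markers = vapply(partition, function(r)
      if (is.null(r$markers)) "unknown"
      else paste(r$markers, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
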