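#' Assemble a pipeline configuration
#'
#' Collects paths and parameters for [run_full()] with the package
#' defaults (bin size 200 bp, 4 states, seed 17, 5 restarts,
#' binarization quantile 0.9, alpha 0.001, start-in gene counting).
#' Values given as arguments override values from `config`, which
#' override the defaults.
#'
#' @param chrom_sizes Path to a chrom.sizes file.
#' @param tracks_manifest Path to a TSV manifest with columns
#'   `track_id`, `path`, `format` (`bed` or `bedgraph`) and `role`
#'   (`promoter`, `elongation` or `other`).
#' @param out_dir Output directory (created if absent).
#' @param gaps Optional BED of assembly gaps to mask.
#' @param compartment,background Optional BED paths defining the
#'   compartment of interest and the background for enrichment.
#' @param annotations Optional BED of features (genes/ORC sites) for the
#'   density report.
#' @param partition Optional region-partition file.
#' @param config Optional named list (e.g. from `yaml::read_yaml`) of
#'   the same fields.
#' @param bin_size,K,seed,restarts,quantile,alpha,counting_rule Scalar
#'   parameters; see defaults above.
#' @return A validated `"pipeline_config"` list.
#' @export
pipeline_config <- function(chrom_sizes = NULL, tracks_manifest = NULL,
                            out_dir = NULL, gaps = NULL,
                            compartment = NULL, background = NULL,
                            annotations = NULL, partition = NULL,
                            config = list(), bin_size = NULL, K = NULL,
                            seed = NULL, restarts = NULL,
                            quantile = NULL, alpha = NULL,
                            counting_rule = NULL) {
  defaults <- list(bin_size = 200, K = 4, seed = 17, restarts = 5,
                   quantile = 0.9, alpha = 0.001,
                   counting_rule = "start_in")
  args <- list(chrom_sizes = chrom_sizes,
               tracks_manifest = tracks_manifest, out_dir = out_dir,
               gaps = gaps, compartment = compartment,
               background = background, annotations = annotations,
               partition = partition, bin_size = bin_size, K = K,
               seed = seed, restarts = restarts, quantile = quantile,
               alpha = alpha, counting_rule = counting_rule)
  args <- args[!vapply(args, is.null, TRUE)]
  cfg <- utils::modifyList(utils::modifyList(defaults, config), args)
  if (is.null(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    .stopf("pipeline_config: alpha must be in (0, 1)")
  for (f in c("chrom_sizes", "tracks_manifest", "gaps", "compartment",
              "background", "annotations", "partition"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      .stopf("pipeline_config: file for '%s' not found: %s", f,
             cfg[[f]])
  structure(cfg, class = "pipeline_config")
}

# hash of the analysis-relevant configuration (the output directory is
# excluded so reruns into different directories stay byte-identical)
.config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  yaml::write_yaml(cfg[order(names(cfg))], tf)
  unname(tools::md5sum(tf))
}

.report_header <- function(cfg) {
  list(package = sprintf("chromstates %s",
                         as.character(packageVersion("chromstates"))),
       seed = cfg$seed, config_hash = .config_hash(cfg))
}

#' Run the full segmentation and statistics pipeline
#'
#' Executes the stages in order: read tracks, project onto the bin
#' grid, binarize, stack, train the HMM, label the states, Viterbi
#' decode, segment, then compute state proportions (per compartment if
#' one is configured), the enrichment table and the feature-density
#' report. Writes `states.bed`, `model.yml`, `proportions.tsv`,
#' `enrichment.tsv`, `densities.tsv`, a `summary.yml` and a run log to
#' the output directory; every table carries a header comment with the
#' package version, seed and config hash. Identical config and inputs
#' produce identical outputs.
#'
#' @param cfg A `"pipeline_config"`.
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, a list with the in-memory results (`model`,
#'   `segmentation`, `proportions`, `enrichment`, `densities`, paths of
#'   files written).
#' @export
run_full <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$chrom_sizes) || is.null(cfg$tracks_manifest) ||
      is.null(cfg$out_dir))
    .stopf("run_full: chrom_sizes, tracks_manifest and out_dir are required")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_con <- file(log_path, "wt")
  on.exit(close(log_con))
  say <- function(stage, fmt, ...) {
    msg <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  say("config", "seed=%d bin_size=%d K=%d restarts=%d quantile=%g alpha=%g",
      cfg$seed, cfg$bin_size, cfg$K, cfg$restarts, cfg$quantile,
      cfg$alpha)

  sizes <- run_stage("chrom_sizes", read_chrom_sizes(cfg$chrom_sizes))
  grid <- bin_genome(sizes, cfg$bin_size)
  say("grid", "%d chromosomes, %d bins", length(sizes), grid$n_bins)

  manifest <- run_stage("manifest", {
    m <- read.table(cfg$tracks_manifest, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
    need <- c("track_id", "path", "format", "role")
    if (!all(need %in% names(m)))
      .stopf("manifest lacks column(s) %s",
             paste(setdiff(need, names(m)), collapse = ", "))
    m
  })
  gaps <- if (!is.null(cfg$gaps))
    run_stage("gaps", read_bed(cfg$gaps, sizes)) else NULL

  tracks <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    tr <- run_stage(paste0("track:", row$track_id), {
      p <- if (file.exists(row$path)) row$path else
        file.path(dirname(cfg$tracks_manifest), row$path)
      switch(row$format,
        bed = intervals_to_track(read_bed(p, sizes), grid,
                                 mode = "presence",
                                 track_id = row$track_id),
        bedgraph = read_bedgraph(p, grid, aggregate = "mean",
                                 track_id = row$track_id),
        .stopf("unknown track format '%s'", row$format))
    })
    if (!is.null(gaps)) tr <- mask_gaps(tr, gaps)
    tracks[[row$track_id]] <- tr
  }
  say("tracks", "%d track(s) loaded", length(tracks))

  # peak-call (presence) tracks are already 0/1; continuous tracks are
  # thresholded at the configured quantile
  track_fmt <- setNames(manifest$format, manifest$track_id)
  obs <- run_stage("binarize",
    stack_tracks(lapply(tracks, function(tr)
      if (track_fmt[[tr$track_id]] == "bed") as_binary_track(tr)
      else binarize(tr, quantile = cfg$quantile))))
  model <- run_stage("train",
    train_hmm(obs, K = cfg$K, seed = cfg$seed,
              n_restarts = cfg$restarts))
  say("train", "logLik=%.2f converged=%s", model$log_likelihood,
      model$converged)
  if (cfg$K == 4) {
    roles <- c(promoter = manifest$track_id[manifest$role ==
                                              "promoter"][1],
               elongation = manifest$track_id[manifest$role ==
                                                "elongation"][1])
    if (any(is.na(roles)))
      .stopf("stage 'label' failed: manifest must mark one promoter and one elongation track")
    model <- run_stage("label", label_states(model, roles))
    say("label", "states: %s", paste(model$labels, collapse = ", "))
  }
  path <- run_stage("decode", viterbi_decode(model, obs))
  seg <- run_stage("segment", path_to_segmentation(path, grid))

  files <- list()
  files$model <- file.path(cfg$out_dir, "model.yml")
  write_hmm_model(model, files$model)
  files$states <- file.path(cfg$out_dir, "states.bed")
  write_segmentation_bed(seg, files$states)

  comp <- if (!is.null(cfg$compartment))
    run_stage("compartment", read_bed(cfg$compartment, sizes)) else NULL
  bg <- if (!is.null(cfg$background))
    run_stage("background", read_bed(cfg$background, sizes)) else NULL

  props <- run_stage("proportions", {
    if (!is.null(comp))
      state_proportions(seg, comp, compartment = "compartment")
    else state_proportions(seg)
  })
  prop_df <- data.frame(state = names(props),
                        fraction = as.numeric(props),
                        stringsAsFactors = FALSE)
  files$proportions <- file.path(cfg$out_dir, "proportions.tsv")
  write_report_tsv(prop_df, files$proportions,
                   meta = c(.report_header(cfg),
                            list(compartment = attr(props,
                                                    "compartment"))))

  enr <- NULL
  if (!is.null(comp) && !is.null(bg)) {
    enr <- run_stage("enrich",
      enrichment_table(tracks, seg, comp, bg, alpha = cfg$alpha))
    files$enrichment <- file.path(cfg$out_dir, "enrichment.tsv")
    write_report_tsv(enr, files$enrichment, meta = .report_header(cfg))
    say("enrich", "%d rows, %d significant at alpha=%g", nrow(enr),
        sum(enr$significant, na.rm = TRUE), cfg$alpha)
  }

  dens <- NULL
  if (!is.null(cfg$annotations) && !is.null(cfg$partition)) {
    dens <- run_stage("density", run_density_report(
      annotations = read_bed(cfg$annotations, sizes),
      partition = load_region_partition(cfg$partition),
      counting_rule = cfg$counting_rule))
    files$densities <- file.path(cfg$out_dir, "densities.tsv")
    write_report_tsv(dens, files$densities, meta = .report_header(cfg))
  }

  summary <- list(
    seed = cfg$seed, config_hash = .config_hash(cfg),
    n_bins = grid$n_bins, n_tracks = length(tracks),
    log_likelihood = model$log_likelihood,
    labels = as.list(if (is.null(model$labels))
      as.character(seq_len(model$K)) else model$labels),
    proportions = as.list(setNames(as.numeric(props), names(props))))
  files$summary <- file.path(cfg$out_dir, "summary.yml")
  yaml::write_yaml(summary, files$summary, precision = 17)
  say("done", "outputs in %s", cfg$out_dir)
  invisible(list(model = model, segmentation = seg, proportions = props,
                 enrichment = enr, densities = dens, files = files))
}

#' Per-region feature-density report
#'
#' One row per named region (with known coordinates) per feature class.
#' Accepts annotation intervals, or — in worked-example mode — a
#' data.frame of literature counts and lengths (`name`, `count`,
#' `length_mb`), which is how published per-band gene densities are
#' reproduced without the underlying annotation.
#'
#' @param annotations A `GRanges` of features, or a named list of such
#'   (one element per feature class, e.g. `list(genes = ..., orc =
#'   ...)`), or `NULL` in worked-example mode.
#' @param partition A `"region_partition"`.
#' @param counting_rule Passed to [feature_density()].
#' @param worked_examples Optional data.frame with columns `name`,
#'   `count`, `length_mb`.
#' @return A data.frame with region, feature class, length (Mb), count,
#'   full-precision density and the display-rounded density.
#' @export
run_density_report <- function(annotations = NULL, partition = NULL,
                               counting_rule = "start_in",
                               worked_examples = NULL) {
  rows <- list()
  if (!is.null(worked_examples)) {
    for (i in seq_len(nrow(worked_examples))) {
      rep_i <- feature_density(
        region = named_region(worked_examples$name[i]),
        count = worked_examples$count[i],
        length_mb = worked_examples$length_mb[i])
      rows[[length(rows) + 1L]] <- data.frame(
        region = rep_i$region, feature_class = "supplied",
        length_mb = rep_i$length_mb, count = rep_i$count,
        density_per_mb = rep_i$density_per_mb,
        density_display = rep_i$density_display,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(annotations)) {
    if (is.null(partition) || length(partition) == 0L)
      .stopf("run_density_report: a nonempty partition is required")
    if (!is.list(annotations) || inherits(annotations, "GRanges"))
      annotations <- list(features = annotations)
    for (cls in names(annotations)) {
      for (r in partition) {
        if (is.na(r$chrom) || is.na(r$start) || is.na(r$end)) next
        rep_i <- feature_density(annotations[[cls]], r,
                                 counting_rule = counting_rule)
        rows[[length(rows) + 1L]] <- data.frame(
          region = rep_i$region, feature_class = cls,
          length_mb = rep_i$length_mb, count = rep_i$count,
          density_per_mb = rep_i$density_per_mb,
          density_display = rep_i$density_display,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    .stopf("run_density_report: nothing to report")
  do.call(rbind, rows)
}

#' Write a simulated input directory
#'
#' Emits everything [run_full()] needs — chrom.sizes, per-track BED
#' files, a tracks manifest, gene annotations and a region partition —
#' plus a `truth.yml` recording the generating model and state path
#' summary, so test harnesses can compare pipeline output against
#' ground truth.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_bins Bins on the simulated chromosome (default 10000).
#' @param bin_size Bin width (default 200).
#' @param model Generating model (default [truth_model()]).
#' @param gene_density Genes per Mb for the simulated annotation
#'   (default 95).
#' @return Invisibly, the directory path.
#' @export
simulate_inputs <- function(dir, seed = 17, n_bins = 10000,
                            bin_size = 200, model = truth_model(),
                            gene_density = 95) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sizes <- chrom_sizes(c(chrSim = n_bins * bin_size))
  grid <- bin_genome(sizes, bin_size)
  write_chrom_sizes(sizes, file.path(dir, "genome.chrom.sizes"))
  sim <- generate_tracks(model, grid, seed = seed)
  bins <- bin_ranges(grid)
  manifest <- data.frame(track_id = model$track_ids,
                         path = paste0(model$track_ids, ".bed"),
                         format = "bed",
                         role = c("promoter", "elongation",
                                  rep("other",
                                      length(model$track_ids) - 2L)),
                         stringsAsFactors = FALSE)
  for (m in seq_along(model$track_ids)) {
    on_bins <- bins[sim$obs$data[m, ] == 1L]
    write_bed(reduce(on_bins),
              file.path(dir, manifest$path[m]))
  }
  write.table(manifest, file.path(dir, "tracks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  part <- structure(list(
    named_region("simulated_region", "chrSim", 1,
                 n_bins * bin_size + 1)),
    class = "region_partition", names = "simulated_region")
  write_region_partition(part, file.path(dir, "regions.tsv"))
  genes <- generate_annotations(part,
                                c(simulated_region = gene_density),
                                seed = seed + 1L, sizes = sizes)
  write_bed(genes, file.path(dir, "genes.bed"))
  yaml::write_yaml(list(
    seed = seed, n_bins = n_bins, bin_size = bin_size,
    model = list(K = model$K, labels = as.list(model$labels),
                 emissions = as.list(as.numeric(t(model$emissions)))),
    state_bin_counts = as.list(table(factor(sim$path$states,
                                            levels = seq_len(model$K))))),
    file.path(dir, "truth.yml"))
  invisible(dir)
}
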