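## Validate a pipeline configuration list against the expected schema.
.validate_pipeline_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list")
  if (is.null(cfg$seed)) stop("config must set a seed")
  an <- cfg$analysis
  if (!is.null(an)) {
    for (f in c("edge_threshold", "cluster_threshold", "bin_width"))
      if (!is.null(an[[f]]) && an[[f]] <= 0)
        stop("config rejected: analysis$", f, " must be > 0")
  }
  if (is.null(cfg$simulate) && (is.null(cfg$swc) || is.null(cfg$puncta)))
    stop("config must either set `simulate` or provide `swc` and `puncta` paths")
  invisible(TRUE)
}

.build_analysis_config <- function(cfg) {
  an <- cfg$analysis
  if (is.null(an)) return(analysis_config())
  do.call(analysis_config, an)
}

#' Run the full input-mapping pipeline
#'
#' Executes simulate (optional) -> assign -> distribute -> cluster -> ephys
#' -> stats on one cell, writing tidy tables, a JSON report, and a run
#' manifest (config snapshot, file digests, seed, timestamp) into the output
#' directory. Reruns with identical config and inputs produce identical
#' output digests (the manifest timestamp aside).
#'
#' @param config a list, or path to a JSON config file, with elements:
#'   `seed` (integer, required); either `simulate` (list: `cell_type` plus
#'   any [generation_params()] overrides) or `swc` + `puncta` (+ optional
#'   `sweeps`, `sweeps_meta`) input paths; optional `analysis` (overrides
#'   for [analysis_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  .validate_pipeline_config(config)
  acfg <- .build_analysis_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sweeps <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      sp <- config$simulate
      gp <- do.call(generation_params,
                    c(list(cell_type = sp$cell_type %||% "SPN"),
                      sp[setdiff(names(sp), "cell_type")]))
      simulate_cell(gp, seed = config$seed, out_dir = out_dir, cfg = acfg)
    })
    m <- sim$morphology
    puncta <- sim$puncta
    sweeps <- sim$sweeps
  } else {
    m <- stage("read", read_swc(config$swc))
    puncta <- stage("read", read_puncta(config$puncta))
    if (!is.null(config$sweeps))
      sweeps <- stage("read", read_sweeps(config$sweeps, config$sweeps_meta))
  }

  inputs <- stage("assign", filter_inputs(puncta, m, acfg))
  write_assignments(inputs, file.path(out_dir, "assignments.tsv"))

  dist_sum <- stage("distribute", distribution_summary(inputs, acfg))
  dist_rows <- do.call(rbind, lapply(names(dist_sum$per_channel), function(ch) {
    pc <- dist_sum$per_channel[[ch]]
    data.frame(channel = ch, count = pc$count,
               proportion_pct = pc$proportion_pct,
               mean_soma_path_distance = pc$mean_soma_path_distance,
               proximal = pc$region_fractions[["proximal"]],
               medial = pc$region_fractions[["medial"]],
               distal = pc$region_fractions[["distal"]])
  }))
  utils::write.table(dist_rows, file.path(out_dir, "distribution.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  clus <- stage("cluster", cluster_summary(inputs, acfg))
  clus_rows <- data.frame(
    statistic = c("nn_m1_m1", "nn_s1_s1", "nn_m1_s1", "nn_s1_m1",
                  "coloc_m1", "coloc_s1"),
    value = c(clus$nn_same[["m1_m1"]], clus$nn_same[["s1_s1"]],
              clus$nn_cross[["m1_s1"]], clus$nn_cross[["s1_m1"]],
              clus$coloc_fraction[["m1"]], clus$coloc_fraction[["s1"]]))
  utils::write.table(clus_rows, file.path(out_dir, "cluster.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  feats <- NULL
  if (!is.null(sweeps)) {
    feats <- stage("ephys", extract_features(sweeps))
    ef <- feats[c("mean_hhw_ms", "mean_iff_hz", "mff_hz", "mean_isi_ms",
                  "rmp_mV", "input_resistance_MOhm", "steady_state",
                  "cell_class")]
    utils::write.table(
      data.frame(feature = names(ef), value = vapply(ef, format, "")),
      file.path(out_dir, "ephys_features.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }

  stats_report <- stage("stats", {
    mm <- morphometrics(m)
    list(
      morphometrics = mm,
      densities = list(
        soma_per_10um2 = compartment_density(inputs, m, "SOMA"),
        dendrite_per_10um2 = compartment_density(inputs, m, c("SHAFT", "SPINE"))),
      distribution = list(total = dist_sum$total,
                          ratio_m1_s1 = as.numeric(dist_sum$ratio_m1_s1)),
      cluster = list(nn_same = as.list(clus$nn_same),
                     nn_cross = as.list(clus$nn_cross),
                     coloc_fraction = as.list(clus$coloc_fraction)),
      ephys = if (!is.null(feats))
        feats[c("mean_hhw_ms", "mean_iff_hz", "mff_hz", "cell_class")]
    )
  })
  jsonlite::write_json(stats_report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)

  outputs <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    tool = paste0("striomap ", as.character(utils::packageVersion("striomap"))),
    seed = config$seed,
    config = config,
    timestamp = format(Sys.time(), tz = "UTC"),
    digests = as.list(tools::md5sum(file.path(out_dir, outputs)))
  )
  names(manifest$digests) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(morphology = m, inputs = inputs, distribution = dist_sum,
                 cluster = clus, ephys = feats, report = stats_report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
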