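#' Versioned CSV interchange
#'
#' Localization, cluster and burst tables travel as UTF-8 CSV with a header
#' row and a schema comment line (`# irclusters-schema: <name>`) so readers
#' can reject tables they do not understand. Numeric columns are rounded to
#' a fixed number of decimals before writing so that identical runs produce
#' byte-identical files.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param schema schema tag, e.g. `"locs-1"`.
#' @param digits decimals kept for numeric columns (default 4).
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path, schema, digits = 4) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# irclusters-schema: ", schema), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @param expected_schema schema the caller requires; mismatch is an error.
#' @export
read_table_csv <- function(path, expected_schema) {
  check_that(file.exists(path), "no such file: ", path)
  first <- readLines(path, n = 1L)
  got <- sub("^# irclusters-schema: *", "", first)
  check_that(startsWith(first, "# irclusters-schema:") &&
               identical(got, expected_schema),
             "schema mismatch in ", path, ": expected '", expected_schema,
             "', found '", first, "'")
  utils::read.csv(path, skip = 1L)
}

#' Assemble and validate a pipeline configuration
#'
#' Bundles the per-stage parameter objects with run metadata. Every section
#' is validated on construction, before any stage runs.
#'
#' @param sim a [sim_config()].
#' @param detection a [detection_params()].
#' @param clustering a [clustering_params()].
#' @param burst_gap_frames dark-gap tolerance handed to [burst_params()]
#'   (the frame rate comes from `sim`).
#' @param short_lifetime_cutoff seconds (default 100).
#' @param segmentation a [segmentation_params()].
#' @param seed master seed; stages derive child seeds via [child_seed()].
#' @param localization_noise_sd nm, for the table fast path (default 20).
#' @param render render movies and run the image-localization stage
#'   (default FALSE: the ground-truth table fast path feeds clustering).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            detection = detection_params(),
                            clustering = clustering_params(),
                            burst_gap_frames = 20L,
                            short_lifetime_cutoff = 100,
                            segmentation = segmentation_params(),
                            seed = 1L, localization_noise_sd = 20,
                            render = FALSE) {
  validate_sim_config(sim)
  check_that(inherits(detection, "detection_params"),
             "detection must be detection_params()")
  check_that(inherits(clustering, "clustering_params"),
             "clustering must be clustering_params()")
  check_that(inherits(segmentation, "segmentation_params"),
             "segmentation must be segmentation_params()")
  burst <- burst_params(max_gap_frames = burst_gap_frames,
                        frame_rate = sim$frame_rate,
                        short_lifetime_cutoff = short_lifetime_cutoff)
  check_that(is_count(seed), "seed must be a non-negative integer")
  structure(list(sim = sim, detection = detection, clustering = clustering,
                 burst = burst, segmentation = segmentation,
                 seed = as.integer(seed),
                 localization_noise_sd = localization_noise_sd,
                 render = isTRUE(render)),
            class = "pipeline_config")
}

config_to_json <- function(config, path) {
  plain <- lapply(config, function(x) {
    if (is.list(x)) unclass(x) else x
  })
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with (any of the) sections `sim`, `detection`,
#'   `clustering`, `burst`, `segmentation` plus top-level `seed`; missing
#'   sections take package defaults.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  check_that(file.exists(path), "no such config file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  call_with <- function(fun, args) {
    do.call(fun, args[intersect(names(args), names(formals(fun)))])
  }
  sim <- if (is.null(raw$sim)) sim_config() else call_with(sim_config, raw$sim)
  pipeline_config(
    sim = sim,
    detection = if (is.null(raw$detection)) detection_params() else
      call_with(detection_params, raw$detection),
    clustering = if (is.null(raw$clustering)) clustering_params() else
      call_with(clustering_params, raw$clustering),
    burst_gap_frames = if (is.null(raw$burst$max_gap_frames)) 20L else
      raw$burst$max_gap_frames,
    short_lifetime_cutoff = if (is.null(raw$burst$short_lifetime_cutoff))
      100 else raw$burst$short_lifetime_cutoff,
    segmentation = if (is.null(raw$segmentation)) segmentation_params() else
      call_with(segmentation_params, raw$segmentation),
    seed = if (is.null(raw$seed)) 1L else raw$seed,
    localization_noise_sd = if (is.null(raw$localization_noise_sd)) 20 else
      raw$localization_noise_sd,
    render = isTRUE(raw$render))
}

#' Run the end-to-end pipeline
#'
#' simulate -> (render + localize | emit table) -> cluster -> bursts ->
#' summary, persisting every stage's output under `out_dir` and writing a
#' run manifest (config hash, output checksums, completed stages) last.
#' Identical config + seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param seed overrides `config$seed` when given.
#' @return the manifest, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  check_that(inherits(config, "pipeline_config"),
             "config must be a pipeline_config")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  completed <- character(0)

  config_to_json(config, p("config.json"))
  run <- function(stage, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest <- list(completed_stages = completed, failed_stage = stage,
                       error = conditionMessage(e))
      jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    completed <<- c(completed, stage)
    res
  }

  truth <- run("simulate", function() {
    simulate_ground_truth(config$sim, seed = config$seed)
  })
  write_table_csv(truth$clusters, p("truth_clusters.csv"), "truth-clusters-1")
  write_table_csv(truth$traces, p("truth_traces.csv"), "truth-traces-1")

  locs <- if (config$render) {
    stack <- run("render", function() {
      render_frames(truth, camera_model(), config$sim, seed = config$seed)
    })
    write_stack(stack$data, p("movie.tif"),
                pixel_size_nm = config$sim$pixel_size,
                frame_rate_hz = config$sim$frame_rate)
    run("localize", function() {
      localize_stack(stack, config$detection)
    })
  } else {
    run("localize", function() {
      emit_localization_table(truth, config$sim,
                              config$localization_noise_sd,
                              seed = config$seed)
    })
  }
  write_table_csv(locs, p("locs.csv"), "locs-1")

  clus <- run("cluster", function() dbscan_cluster(locs, config$clustering))
  write_table_csv(clus$clusters, p("clusters.csv"), "clusters-1")

  bursts <- run("tcpalm", function() {
    extract_bursts_by_cluster(clus$locs, config$burst,
                              n_frames = config$sim$n_frames)
  })
  bursts$class <- classify_lifetime(bursts$lifetime_s, config$burst)
  write_table_csv(bursts, p("bursts.csv"), "bursts-1")

  summary <- run("summarize", function() {
    if (nrow(bursts) == 0) return(NULL)
    s <- summarize_lifetimes(bursts, config$burst)
    stats <- cluster_stats(clus$clusters)
    list(tau_avg_short_s = s$tau_avg_short, sem_tau_s = s$sem_tau,
         fraction_long = s$fraction_long, n_bursts = s$n_bursts,
         n_short = s$n_short, n_clusters = nrow(clus$clusters),
         detections_per_cluster_mean = stats$detections_mean,
         detections_per_cluster_range = stats$detections_range)
  })
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = 8, null = "null")

  outputs <- c("config.json", "truth_clusters.csv", "truth_traces.csv",
               "locs.csv", "clusters.csv", "bursts.csv", "summary.json")
  outputs <- outputs[file.exists(file.path(out_dir, outputs))]
  manifest <- list(
    package_version = as.character(utils::packageVersion("irclusters")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(p("config.json"))),
    output_md5 = as.list(tools::md5sum(file.path(out_dir, outputs))),
    completed_stages = completed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  names(manifest$output_md5) <- outputs
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
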