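# End-to-end pipeline: simulate -> detect -> quantify -> population
# [-> pattern], plus the assay arm simulate-assay -> fit -> titer.
# Stages hand off through plain-text files (TIFF/PNG/CSV/JSON) so each is
# independently inspectable and testable; a JSON manifest records file
# checksums for reproducibility audits.

#' Default pipeline configuration
#'
#' Returns a nested configuration list for [run_pipeline()]. Every block
#' can be overridden; `sim` takes [sim_image_config()] arguments, `assay`
#' takes [assay_config()] arguments. One global seed is fanned out as
#' per-stage derived seeds (seed + stage index) so stages stay independent
#' yet reproducible.
#'
#' @param outdir Output directory.
#' @param seed Global integer seed.
#' @param stages Stages to run, in dependency order; subset of
#'   `c("simulate", "detect", "quantify", "population", "pattern",
#'   "assay", "fit", "titer")`.
#' @param sim,detect,assay,titer,pattern Per-stage parameter blocks.
#' @return Configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            stages = c("simulate", "detect", "quantify",
                                       "population", "assay", "fit",
                                       "titer"),
                            sim = list(), detect = list(), assay = list(),
                            titer = list(stock_conc = 4e-7,
                                         dilution_factors = c(200, 2000),
                                         noise_cv = 0.05),
                            pattern = list(k = 3, c_min = 2)) {
  known <- c("simulate", "detect", "quantify", "population", "pattern",
             "assay", "fit", "titer")
  if (!all(stages %in% known))
    stop(sprintf("unknown stage `%s`", setdiff(stages, known)[1]))
  structure(list(outdir = outdir, seed = as.integer(seed),
                 stages = known[known %in% stages], sim = sim,
                 detect = detect, assay = assay, titer = titer,
                 pattern = pattern),
            class = "pipeline_config")
}

.path <- function(cfg, ...) file.path(cfg$outdir, paste0(...))

.need <- function(cfg, stage, files) {
  p <- file.path(cfg$outdir, files)
  miss <- files[!file.exists(p)]
  if (length(miss) > 0)
    stop(sprintf("stage '%s': missing input file %s", stage, miss[1]))
}

stage_simulate <- function(cfg, seed) {
  sim_args <- utils::modifyList(list(rng_seed = seed), cfg$sim)
  mask <- sim_args$mask
  sim_args$mask <- NULL
  config <- do.call(sim_image_config, sim_args)
  res <- if (is.null(mask)) simulate_field(config) else
    simulate_patterned_field(config, mask)
  write_channel_tiff(get_channel(res$images, "TXR"), .path(cfg, "txr.tiff"))
  write_channel_tiff(get_channel(res$images, "GFP"), .path(cfg, "gfp.tiff"))
  write_table_csv(res$truth, .path(cfg, "truth.csv"))
  if (!is.null(mask)) write_mask_png(mask, .path(cfg, "mask.png"))
  # matched no-DNA control field: same optics, nothing expressing
  ctrl_args <- utils::modifyList(sim_args,
                                 list(expressing_fraction = 0,
                                      rng_seed = seed + 1000L))
  ctrl <- simulate_field(do.call(sim_image_config, ctrl_args))
  write_channel_tiff(get_channel(ctrl$images, "TXR"),
                     .path(cfg, "control_txr.tiff"))
  write_channel_tiff(get_channel(ctrl$images, "GFP"),
                     .path(cfg, "control_gfp.tiff"))
  write_table_csv(ctrl$truth, .path(cfg, "control_truth.csv"))
  list(pixel_size_um = config$pixel_size_um)
}

.load_field <- function(cfg, prefix, pixel_size_um) {
  image_set(
    read_channel_tiff(.path(cfg, prefix, "txr.tiff"), "TXR", pixel_size_um),
    read_channel_tiff(.path(cfg, prefix, "gfp.tiff"), "GFP", pixel_size_um))
}

#' Locate a vesicle-free block for background estimation
#'
#' Scans non-overlapping square blocks and returns the one with the
#' lowest mean intensity, an automated stand-in for manually selecting a
#' vesicle-free region of the field.
#'
#' @param image A `channel_image`.
#' @param block Block side, px.
#' @return List with integer vectors `rows` and `cols`.
#' @export
auto_background_region <- function(image, block = 32L) {
  px <- image$pixels
  nb_r <- max(1L, nrow(px) %/% block)
  nb_c <- max(1L, ncol(px) %/% block)
  best <- NULL; best_val <- Inf
  for (i in seq_len(nb_r)) for (j in seq_len(nb_c)) {
    rows <- ((i - 1L) * block + 1L):min(nrow(px), i * block)
    cols <- ((j - 1L) * block + 1L):min(ncol(px), j * block)
    v <- mean(px[rows, cols])
    if (v < best_val) { best_val <- v; best <- list(rows = rows, cols = cols) }
  }
  best
}

stage_detect <- function(cfg, pixel_size_um) {
  .need(cfg, "detect", c("txr.tiff", "gfp.tiff", "control_txr.tiff",
                         "control_gfp.tiff"))
  main <- .load_field(cfg, "", pixel_size_um)
  ctrl <- .load_field(cfg, "control_", pixel_size_um)
  norm <- normalize_experiment(image_set(c(unclass(main), unclass(ctrl))))
  write_table_csv(norm$model, .path(cfg, "normalization.csv"))
  imgs <- unclass(norm$images)
  main_n <- image_set(imgs[1:2]); ctrl_n <- image_set(imgs[3:4])
  det_args <- cfg$detect
  for (set in list(c("", 1), c("control_", 3))) {
    prefix <- set[1]
    txr <- get_channel(if (prefix == "") main_n else ctrl_n, "TXR")
    det <- do.call(detect_vesicles, c(list(image = txr), det_args))
    write_table_csv(det, .path(cfg, prefix, "detections.csv"))
  }
  # channel backgrounds from the emptiest block of each normalized image
  bgs <- lapply(list(main = main_n, ctrl = ctrl_n), function(set) {
    vapply(c("TXR", "GFP"), function(ch) {
      im <- get_channel(set, ch)
      reg <- auto_background_region(im)
      estimate_background(im, reg$rows, reg$cols)$value
    }, numeric(1))
  })
  jsonlite::write_json(lapply(bgs, as.list), .path(cfg, "background.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_quantify <- function(cfg, pixel_size_um) {
  .need(cfg, "quantify", c("detections.csv", "control_detections.csv",
                           "normalization.csv", "background.json"))
  norm_model <- read_table_csv(.path(cfg, "normalization.csv"))
  bgs <- jsonlite::read_json(.path(cfg, "background.json"),
                             simplifyVector = TRUE)
  for (set in c("", "control_")) {
    imgs <- .load_field(cfg, set, pixel_size_um)
    imgs <- lapply(unclass(imgs), function(im) {
      m <- norm_model[norm_model$channel == im$channel, ]
      im$pixels <- (im$pixels - m$low_anchor) /
        (m$high_anchor - m$low_anchor)
      im
    })
    imgs <- image_set(imgs)
    det <- read_table_csv(.path(cfg, set, "detections.csv"))
    bg <- unlist(if (set == "") bgs$main else bgs$ctrl)
    rec <- quantify_image_set(imgs, det, bg,
                              image_id = if (set == "") "main" else "control")
    write_table_csv(rec, .path(cfg, set, "records.csv"))
  }
  invisible(NULL)
}

stage_population <- function(cfg) {
  .need(cfg, "population", c("records.csv", "control_records.csv"))
  rec <- read_table_csv(.path(cfg, "records.csv"))
  ctrl <- read_table_csv(.path(cfg, "control_records.csv"))
  thr <- control_threshold(ctrl)
  ef <- expressing_fraction(rec, thr)
  rec_un <- rec[!rec$flagged, , drop = FALSE]
  rec_un$expressing <- ef$expressing
  write_table_csv(rec_un, .path(cfg, "records_classified.csv"))
  summ <- summarize_population(rec_un)
  jsonlite::write_json(
    list(threshold = unclass(thr), expressing_fraction = ef$fraction,
         summary = unclass(summ)),
    .path(cfg, "population.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_pattern <- function(cfg, pixel_size_um) {
  .need(cfg, "pattern", c("records_classified.csv", "mask.png"))
  rec <- read_table_csv(.path(cfg, "records_classified.csv"))
  mask <- read_mask_png(.path(cfg, "mask.png"))
  ps <- score_pattern(rec, mask, pixel_size_um,
                      k = cfg$pattern$k, c_min = cfg$pattern$c_min)
  jsonlite::write_json(
    list(contrast = ps$contrast, contrast_flag = ps$contrast_flag,
         fidelity = ps$fidelity,
         min_resolved_width_um = ps$min_resolved_width_um,
         features = ps$features),
    .path(cfg, "pattern.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_assay <- function(cfg, seed) {
  aargs <- utils::modifyList(list(rng_seed = seed), cfg$assay)
  acfg <- do.call(assay_config, aargs)
  dr <- simulate_dose_response(acfg)
  write_table_csv(dr$plate, .path(cfg, "dose_plate.csv"))
  t <- cfg$titer
  ut <- simulate_unknown_titer(t$stock_conc, t$dilution_factors,
                               acfg$true_params,
                               noise_cv = t$noise_cv,
                               rng_seed = seed + 1L)
  write_table_csv(ut$plate, .path(cfg, "titer_plate.csv"))
  jsonlite::write_json(list(true_params = as.list(acfg$true_params),
                            stock_conc = t$stock_conc),
                       .path(cfg, "assay_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_fit <- function(cfg) {
  .need(cfg, "fit", "dose_plate.csv")
  plate <- read_table_csv(.path(cfg, "dose_plate.csv"))
  fit <- fit_dose_response(plate)
  jsonlite::write_json(list(per_replicate = fit$per_replicate,
                            summary = fit$summary,
                            params = as.list(fit$params)),
                       .path(cfg, "fit.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}

stage_titer <- function(cfg) {
  .need(cfg, "titer", c("titer_plate.csv", "fit.json"))
  plate <- read_table_csv(.path(cfg, "titer_plate.csv"))
  fit <- jsonlite::read_json(.path(cfg, "fit.json"), simplifyVector = TRUE)
  est <- estimate_titer(plate, unlist(fit$params))
  jsonlite::write_json(list(stock_molar = est$stock_molar,
                            stock_gsd = est$stock_gsd,
                            n_usable = est$n_usable,
                            wells = est$wells),
                       .path(cfg, "titer.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}

#' Run the end-to-end pipeline
#'
#' Executes the selected stages in dependency order with flat-file
#' handoffs, then writes and returns a manifest recording the package
#' version, a hash of the configuration and an MD5 checksum per output
#' file. Deterministic stages reproduce identical checksums under an
#' identical configuration and seed. A missing input file halts the run
#' naming the failing stage before any work in that stage.
#'
#' @param cfg A `pipeline_config`.
#' @return The manifest, invisibly (also written to
#'   `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config"))
    stop("`cfg` must be a pipeline_config")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- .path(cfg, "config.json")
  jsonlite::write_json(cfg[setdiff(names(cfg), "outdir")], cfg_json,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  all_stages <- c("simulate", "detect", "quantify", "population",
                  "pattern", "assay", "fit", "titer")
  pixel_size_um <- cfg$sim$pixel_size_um
  if (is.null(pixel_size_um))
    pixel_size_um <- formals(sim_image_config)$pixel_size_um
  for (stage in cfg$stages) {
    seed <- cfg$seed + match(stage, all_stages)
    switch(stage,
           simulate = stage_simulate(cfg, seed),
           detect = stage_detect(cfg, pixel_size_um),
           quantify = stage_quantify(cfg, pixel_size_um),
           population = stage_population(cfg),
           pattern = stage_pattern(cfg, pixel_size_um),
           assay = stage_assay(cfg, seed),
           fit = stage_fit(cfg),
           titer = stage_titer(cfg))
  }
  files <- setdiff(list.files(cfg$outdir), "manifest.json")
  sums <- tools::md5sum(file.path(cfg$outdir, files))
  names(sums) <- files
  manifest <- list(
    package = "guvquant",
    version = as.character(utils::packageVersion("guvquant")),
    config_md5 = unname(tools::md5sum(cfg_json)),
    seed = cfg$seed, stages = cfg$stages,
    files = as.list(sums),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, .path(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
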