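#' Schema-checked CSV table I/O
#'
#' Reads or writes tidy pipeline tables with an explicit column schema.
#' Violations are reported by column name; round trips are lossless to at
#' least 12 significant digits (values are written with 15).
#'
#' @param path file path
#' @param table data.frame to write
#' @param schema named character vector, column name -> class
#'   (`"numeric"`, `"integer"`, `"character"`, `"logical"`)
#' @return `read_table()` returns the checked data.frame; `write_table()`
#'   returns `path` invisibly
#' @export
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_table(data.frame(a = 1.5, b = "x"), p)
#' read_table(p, schema = c(a = "numeric", b = "character"))
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    miss <- setdiff(names(schema), names(d))
    if (length(miss))
      stop("missing required column(s): ", paste(miss, collapse = ", "))
    for (col in names(schema)) {
      ok <- switch(schema[[col]],
                   numeric = is.numeric(d[[col]]),
                   integer = is.numeric(d[[col]]) &&
                     all(d[[col]] == round(d[[col]]), na.rm = TRUE),
                   character = is.character(d[[col]]),
                   logical = is.logical(d[[col]]),
                   stop("unknown schema class: ", schema[[col]]))
      if (!ok) stop("column '", col, "' is not of class ", schema[[col]])
      if (schema[[col]] == "integer") d[[col]] <- as.integer(d[[col]])
    }
  }
  d
}

#' @rdname read_table
#' @export
write_table <- function(table, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tb <- as.data.frame(table)
  num <- vapply(tb, is.numeric, TRUE) & !vapply(tb, is.integer, TRUE)
  tb[num] <- lapply(tb[num], function(x) formatC(x, digits = 15,
                                                 format = "g"))
  write.csv(tb, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Photon-trace file I/O
#'
#' Traces are stored as two-column text (`bin_start_s`, `counts`) with a
#' JSON sidecar (`<path>.json`) holding bin width, background rate, site,
#' repetition index and any simulator ground truth.
#'
#' @param trace a [photon_trace()]
#' @param path base file path (`.csv`)
#' @return `read_photon_trace()` returns a [photon_trace()];
#'   `write_photon_trace()` returns `path` invisibly
#' @export
write_photon_trace <- function(trace, path) {
  stopifnot(inherits(trace, "photon_trace"))
  d <- data.frame(bin_start_s = (seq_along(trace$counts) - 1) *
                    trace$bin_width,
                  counts = as.integer(trace$counts))
  write_table(d, path)
  meta <- trace[c("bin_width", "background_rate", "site_label",
                  "repetition_index")]
  meta$ground_truth <- trace$ground_truth
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_photon_trace
#' @export
read_photon_trace <- function(path) {
  d <- read_table(path, schema = c(bin_start_s = "numeric",
                                   counts = "integer"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  photon_trace(d$counts, bin_width = meta$bin_width,
               background_rate = meta$background_rate,
               site_label = meta$site_label,
               repetition_index = meta$repetition_index,
               ground_truth = meta$ground_truth)
}

#' ROI JSON I/O
#'
#' ROIs are stored as a JSON object with a header block (`pixel_size_um`)
#' and a list of named ROIs, each a list of `(x, y)` vertices in pixel
#' coordinates.
#'
#' @param rois named list of vertex matrices/data.frames (columns x, y)
#' @param pixel_size um per pixel
#' @param path file path
#' @return `read_rois()` returns a list with `pixel_size` and `rois`
#' @export
write_rois <- function(rois, pixel_size, path) {
  payload <- list(pixel_size_um = pixel_size,
                  rois = lapply(rois, function(p) {
                    p <- as.matrix(as.data.frame(p)[, 1:2])
                    list(x = p[, 1], y = p[, 2])
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  rois <- lapply(payload$rois, function(r) cbind(x = r$x, y = r$y))
  list(pixel_size = payload$pixel_size_um, rois = rois)
}

#' Waveform file I/O
#'
#' Columnar text (`time_s`, `volts`) with the sample rate in a `# rate_hz:`
#' header line.
#'
#' @param waveform numeric vector
#' @param rate sampling rate, Hz
#' @param path file path
#' @return `read_waveform()` returns a list with `waveform`, `time`, `rate`
#' @export
write_waveform <- function(waveform, rate, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz: %.10g", rate), con)
  writeLines("time_s,volts", con)
  t <- (seq_along(waveform) - 1) / rate
  writeLines(sprintf("%.12g,%.12g", t, waveform), con)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# rate_hz:", hdr)) stop("malformed header: expected # rate_hz:")
  rate <- as.numeric(sub("^# rate_hz:\\s*", "", hdr))
  d <- read.csv(path, skip = 1)
  if (!all(c("time_s", "volts") %in% names(d)))
    stop("missing required column(s): ",
         paste(setdiff(c("time_s", "volts"), names(d)), collapse = ", "))
  list(waveform = d$volts, time = d$time_s, rate = rate)
}

#' 16-bit TIFF image I/O
#'
#' @param image integer matrix (rows x cols), values 0..65535
#' @param path file path
#' @return `read_image_tiff()` returns an integer matrix
#' @export
write_image_tiff <- function(image, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

#' Run configuration for a reproducible pipeline execution
#'
#' @param stages named list of per-stage parameter lists; recognised stages
#'   are `fcs`, `section`, `motion`, `waveform`, `brightness`, `stats`
#' @param seed global integer seed, fanned out to per-stage substreams
#' @param out_dir artifact directory
#' @return object of class `run_config`
#' @export
run_config <- function(stages, seed = 1L, out_dir = tempfile("run")) {
  known <- c("fcs", "section", "motion", "waveform", "brightness", "stats")
  unknown <- setdiff(names(stages), known)
  if (length(unknown))
    stop("unknown stage(s) in config: ", paste(unknown, collapse = ", "))
  for (s in names(stages)) {
    if (!is.list(stages[[s]]))
      stop("stage '", s, "' must be a parameter list")
  }
  structure(list(stages = stages, seed = as.integer(seed),
                 out_dir = out_dir), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with top-level keys `seed`, `out_dir`, `stages`
#' @return a [run_config()]
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  extra <- setdiff(names(y), c("seed", "out_dir", "stages"))
  if (length(extra))
    stop("unknown top-level key(s): ", paste(extra, collapse = ", "))
  run_config(y$stages %||% list(), seed = y$seed %||% 1L,
             out_dir = y$out_dir %||% tempfile("run"))
}

#' Execute a configured pipeline run
#'
#' Runs the requested stages in dependency order (simulation first, then
#' analysis, then statistics), writing every artifact and a provenance
#' record (package version, config digest, seed, per-stage seeds) into the
#' output directory. The same config and seed produce identical artifacts.
#'
#' Stage parameters are passed straight to the corresponding generator and
#' analysis functions:
#' * `fcs`: [fcs_sim_config()] fields -> trace, correlation fit and
#'   brightness CSV
#' * `section`: [section_phantom_config()] fields -> TIFF, ROI JSON and
#'   measurement CSV
#' * `motion`: [motion_phantom_config()] fields -> deflection CSV
#' * `waveform`: [synth_evoked_waveform()] arguments -> waveform file and
#'   tone-response CSV
#' * `brightness`: [brightness_table_config()] fields -> table CSV and GLS
#'   summary JSON
#'
#' @param config a [run_config()]
#' @return the artifact directory, invisibly; artifacts listed in
#'   `manifest.json`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  stage_seed <- function(s) derive_seed(config$seed, s)
  run_stage <- function(name, body) {
    tryCatch(body, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  st <- config$stages

  if (!is.null(st$fcs)) run_stage("fcs", {
    pars <- st$fcs; pars$seed <- stage_seed("fcs")
    cfg <- do.call(fcs_sim_config, pars)
    tr <- simulate_photon_trace(cfg)
    write_photon_trace(tr, file.path(out, "fcs_trace.csv"))
    ft <- fit_anomalous_diffusion(autocorrelate(tr), S = cfg$aspect_ratio_S)
    br <- molecular_brightness(tr, ft)
    write_table(data.frame(site = tr$site_label, N = ft$N,
                           tau_D = ft$tau_D, alpha = ft$alpha,
                           brightness = br$brightness,
                           brightness_khz = br$brightness_khz),
                file.path(out, "fcs_fit.csv"))
    artifacts <- c(artifacts, "fcs_trace.csv", "fcs_fit.csv")
  })

  if (!is.null(st$section)) run_stage("section", {
    pars <- st$section; pars$seed <- stage_seed("section")
    ph <- render_section_phantom(do.call(section_phantom_config, pars))
    write_image_tiff(ph$image, file.path(out, "section.tif"))
    write_rois(list(tm = ph$geometry$tm_roi, ooc = ph$geometry$ooc_roi),
               ph$geometry$pixel_size, file.path(out, "section_rois.json"))
    write_table(measure_section(ph$geometry),
                file.path(out, "section_measurements.csv"))
    artifacts <- c(artifacts, "section.tif", "section_rois.json",
                    "section_measurements.csv")
  })

  if (!is.null(st$motion)) run_stage("motion", {
    pars <- st$motion; pars$seed <- stage_seed("motion")
    sim <- render_motion_sequence(do.call(motion_phantom_config, pars))
    frames <- lowpass_sequence(bin_phases(sim$stream))
    mf <- estimate_motion(frames)
    tip <- region_average(mf, sim$truth$tip$anchor)
    base <- region_average(mf, sim$truth$base$anchor)
    defl <- compute_deflection(tip, base)
    write_table(data.frame(phase = tip$phase_bins,
                           tip_x = tip$displacement[, 1],
                           tip_y = tip$displacement[, 2],
                           base_x = base$displacement[, 1],
                           base_y = base$displacement[, 2],
                           defl_x = defl$deflection_trajectory[, 1],
                           defl_y = defl$deflection_trajectory[, 2]),
                file.path(out, "motion_trajectories.csv"))
    artifacts <- c(artifacts, "motion_trajectories.csv")
  })

  if (!is.null(st$waveform)) run_stage("waveform", {
    pars <- st$waveform; pars$seed <- stage_seed("waveform")
    w <- do.call(synth_evoked_waveform, pars)
    write_waveform(w$waveform, w$rate, file.path(out, "waveform.csv"))
    cm <- cm_component(w$waveform, w$rate, w$truth$frequency)
    sp <- summating_potential(w$waveform, w$rate, w$truth$frequency)
    write_table(data.frame(frequency = w$truth$frequency,
                           cm_amplitude = cm$amplitude, cm_phase = cm$phase,
                           sp = sp$sp, sp_abs = sp$sp_abs),
                file.path(out, "tone_response.csv"))
    artifacts <- c(artifacts, "waveform.csv", "tone_response.csv")
  })

  if (!is.null(st$brightness)) run_stage("brightness", {
    pars <- st$brightness; pars$seed <- stage_seed("brightness")
    tab <- synth_brightness_table(do.call(brightness_table_config, pars))
    write_table(tab, file.path(out, "brightness_table.csv"))
    artifacts <- c(artifacts, "brightness_table.csv")
    if (!is.null(st$stats)) run_stage("stats", {
      g <- fit_gls_cs(tab)
      jsonlite::write_json(
        list(coefficients = cbind(term = rownames(g$coefficients),
                                  g$coefficients),
             rho_hat = g$rho_hat, n_obs = g$n_obs,
             n_clusters = g$n_clusters),
        file.path(out, "gls_summary.json"), auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, "gls_summary.json")
    })
  })

  prov <- list(tool = "cochleametrics",
               version = as.character(packageVersion("cochleametrics")),
               seed = config$seed,
               stage_seeds = setNames(
                 lapply(names(st), stage_seed), names(st)),
               config_digest = config_digest(config),
               artifacts = artifacts)
  jsonlite::write_json(prov, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

# stable digest of a run config (md5 of its canonical JSON serialisation)
config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[c("stages", "seed")], auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
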