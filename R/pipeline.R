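#' Validate a pipeline run configuration
#'
#' A run config is a plain list (usually read from JSON) with fields:
#' \describe{
#'   \item{seed}{integer, mandatory.}
#'   \item{window_s}{temporal lag half-width for STA/st-SCA (default 0.1).}
#'   \item{tau_window_s}{temporal integration half-width for the spatial
#'     component (default 0.035).}
#'   \item{radial_bin_mm}{radial bin width (default: electrode pitch).}
#'   \item{geometry}{path to a geometry JSON; default 96-channel array.}
#'   \item{simulate}{list passed to the synthetic generator: `kernel`
#'     (family, amplitude_uv, spatial_scale_mm, temporal_scale_s),
#'     `n_spikes`, `separation_s`, `noise_sd_uv`, `fs_hz`; exclusive with
#'     `inputs`.}
#'   \item{inputs}{list `recording_prefix`, `spikes_csv` for pre-existing
#'     data; exclusive with `simulate`.}
#'   \item{detection}{optional list `threshold_sd`, `dead_time_ms` (must be
#'     valid even if detection is not run).}
#'   \item{whiten}{logical; spatially whiten the LFP before the st-SCA.}
#'   \item{shuffle_control}{logical; run the spike-time randomization
#'     control (default TRUE).}
#' }
#'
#' @param config List as above.
#' @return The config with defaults filled in; stops on violations.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$seed)) stop("config violation: seed is mandatory")
  defaults <- list(window_s = 0.1, tau_window_s = 0.035,
                   radial_bin_mm = NULL, geometry = NULL,
                   whiten = FALSE, shuffle_control = TRUE)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (config$window_s <= 0) stop("config violation: window_s must be > 0")
  if (!is.null(config$detection)) {
    th <- config$detection$threshold_sd
    if (is.null(th) || th <= 0)
      stop("config violation: detection threshold_sd must be > 0")
  }
  has_sim <- !is.null(config$simulate)
  has_in <- !is.null(config$inputs)
  if (has_sim == has_in)
    stop("config violation: exactly one of simulate/inputs must be given")
  config
}

pipeline_simulate <- function(config, geometry) {
  s <- config$simulate
  ker <- kernel_spec(s$kernel$family, s$kernel$amplitude_uv,
                     s$kernel$spatial_scale_mm, s$kernel$temporal_scale_s)
  fs <- if (is.null(s$fs_hz)) 1000 else s$fs_hz
  sep <- if (is.null(s$separation_s)) 2.5 * config$window_s else s$separation_s
  sched <- spike_schedule(geometry, s$n_spikes, sep,
                          start_s = config$window_s + sep, seed = config$seed)
  dur <- max(sched$time_s) + config$window_s + sep
  sim <- simulate_recording(sim_config(
    geometry, duration_s = dur, fs_hz = fs, kernel = ker, seed = config$seed,
    spike_times = sched,
    noise_sd_uv = if (is.null(s$noise_sd_uv)) 0 else s$noise_sd_uv,
    kernel_support_s = s$kernel_support_s))
  sim
}

#' Run the full analysis pipeline
#'
#' Composes the stages end to end: obtain data (synthetic or from files),
#' form the array-mean LFP and its STA, accumulate the st-SCA with
#' plus-minus SNR and Rose masking, run the spike-time randomization
#' control, reduce to polar coordinates, extract the marginals and the ring
#' peak separation, and write every result under `out_dir` along with a
#' provenance record. Deterministic given config + seed.
#'
#' @param config Run configuration (see [validate_run_config()]), or a path
#'   to a JSON file containing it.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `sta`, `stsca`, `pm` (plus-minus with SNR
#'   map), `radial`, `marginals`, `peaks`, `control` (NULL if disabled) and
#'   `summary`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  config <- validate_run_config(config)
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  geometry <- if (is.null(config$geometry)) mea_geometry() else
    read_geometry_json(config$geometry)
  if (!is.null(config$simulate)) {
    say("simulating recording")
    sim <- pipeline_simulate(config, geometry)
    lfp <- sim$lfp; spikes <- sim$spikes
  } else {
    say("loading recording and spikes")
    lfp <- read_recording_csv(config$inputs$recording_prefix)
    spikes <- read_spikes_csv(config$inputs$spikes_csv, lfp$fs_hz)
  }
  if (!n_spikes(spikes)) stop("empty spike train")
  say(sprintf("%d spikes on %d channels", n_spikes(spikes),
              length(unique(spikes$events$channel_id))))
  if (isTRUE(config$whiten)) {
    say("applying spatial whitening")
    lfp <- apply_whitening(lfp, fit_whitening(lfp))
  }

  mean_lfp <- array_mean_lfp(lfp)
  sta <- compute_sta(mean_lfp, lfp$fs_hz, spike_times_s(spikes),
                     config$window_s)
  write_sta_csv(sta, file.path(out_dir, "sta.csv"))

  say("accumulating st-SCA")
  pm <- stsca_plus_minus(lfp, spikes, geometry, config$window_s)
  stsca <- pm$stsca
  write_stsca_csv(stsca, file.path(out_dir, "stsca"))
  data.table::fwrite(data.table::as.data.table(pm$snr_map_db),
                     file.path(out_dir, "snr_map_db.csv"))

  control <- NULL
  if (isTRUE(config$shuffle_control)) {
    say("spike-time randomization control")
    shuf <- randomize_spike_times(spikes, n_samples(lfp) / lfp$fs_hz,
                                  seed = config$seed + 1)
    control <- compute_stsca(lfp, shuf, geometry, config$window_s)
    write_stsca_csv(control, file.path(out_dir, "stsca_control"))
  }

  radial <- radial_reduce(stsca, config$radial_bin_mm)
  mg <- marginals(radial, config$tau_window_s)
  peaks <- peak_separation(mg$spatial_component)
  write_radial_csv(radial, file.path(out_dir, "radial.csv"))
  data.table::fwrite(data.table::data.table(
    tau_s = radial$tau_s, temporal_uv = mg$temporal_component),
    file.path(out_dir, "temporal_component.csv"))
  data.table::fwrite(data.table::data.table(
    r_mm = radial$r_bin_centers_mm, spatial_uv = mg$spatial_component),
    file.path(out_dir, "spatial_component.csv"))

  summary <- list(
    n_spikes_retained = stsca$n_spikes, n_spikes_dropped = stsca$n_dropped,
    n_cells_defined = sum(stsca$counts[, , 1] > 0),
    snr_db_global = pm$snr_db,
    n_rose_failing = attr(pm$rose, "n_failing"),
    peak_separation_mm = peaks$separation_mm,
    peaks_found = peaks$found,
    symmetry_score = radial_symmetry_score(stsca, config$tau_window_s),
    # ratio of spatial-pattern peaks (radially reduced, count-weighted);
    # raw single-cell maxima are noise-dominated at low counts
    control_peak_ratio = if (!is.null(control)) {
      mg_c <- marginals(radial_reduce(control, config$radial_bin_mm),
                        config$tau_window_s)
      max(abs(mg_c$spatial_component), na.rm = TRUE) /
        max(abs(mg$spatial_component), na.rm = TRUE)
    },
    config = config[setdiff(names(config), c("simulate", "inputs"))],
    package_version = as.character(utils::packageVersion("stsca")))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say(sprintf("done: SNR %.1f dB, peak separation %s mm",
              pm$snr_db,
              if (peaks$found) sprintf("%.2f", peaks$separation_mm) else "-"))
  invisible(list(sta = sta, stsca = stsca, pm = pm, radial = radial,
                 marginals = mg, peaks = peaks, control = control,
                 summary = summary))
}

cli_opts <- function(args) {
  opts <- list(); pos <- character(0); i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        opts[[key]] <- args[i + 1]; i <- i + 2
      } else { opts[[key]] <- TRUE; i <- i + 1 }
    } else { pos <- c(pos, a); i <- i + 1 }
  }
  list(opts = opts, pos = pos)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `detect`, `sta`, `stsca`, `shuffle-control`,
#' `whiten`, `radial`, `run`, plus `--version`. `run --config cfg.json
#' --out dir` executes the full pipeline; the other subcommands operate on
#' the CSV/JSON containers written by [write_recording_csv()] and friends
#' and compose to the same results.
#'
#' @param args Character vector of arguments (defaults to the process
#'   command line).
#' @return Exit status, invisibly (0 on success).
#' @export
stsca_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || identical(args[1], "--version")) {
    cat("stsca", as.character(utils::packageVersion("stsca")), "\n")
    return(invisible(0))
  }
  cmd <- args[1]
  p <- cli_opts(args[-1])
  o <- p$opts
  need <- function(nm) {
    if (is.null(o[[nm]])) stop("missing required option --", nm)
    o[[nm]]
  }
  geom <- function() if (is.null(o$geometry)) mea_geometry() else
    read_geometry_json(o$geometry)
  switch(cmd,
    run = {
      run_pipeline(need("config"), need("out"),
                   quiet = isTRUE(o$quiet))
    },
    simulate = {
      cfg <- jsonlite::read_json(need("config"), simplifyVector = TRUE)
      cfg <- validate_run_config(cfg)
      sim <- pipeline_simulate(cfg, geom())
      write_recording_csv(sim$lfp, need("out"))
      write_spikes_csv(sim$spikes, need("spikes-out"))
    },
    detect = {
      rec <- read_recording_csv(need("recording"))
      spec <- detection_spec(
        threshold_sd = as.numeric(if (is.null(o$threshold)) 4 else o$threshold))
      mua <- bandpass(rec, filter_spec(300, 3000))
      write_spikes_csv(detect_spikes(mua, spec), need("out"))
    },
    sta = {
      rec <- read_recording_csv(need("recording"))
      spikes <- read_spikes_csv(need("spikes"), rec$fs_hz)
      sta <- compute_sta(array_mean_lfp(rec), rec$fs_hz,
                         spike_times_s(spikes),
                         as.numeric(need("window-s")))
      write_sta_csv(sta, need("out"))
    },
    stsca = {
      rec <- read_recording_csv(need("recording"))
      spikes <- read_spikes_csv(need("spikes"), rec$fs_hz)
      res <- compute_stsca(rec, spikes, geom(),
                           as.numeric(need("window-s")))
      write_stsca_csv(res, need("out"))
    },
    `shuffle-control` = {
      rec <- read_recording_csv(need("recording"))
      spikes <- read_spikes_csv(need("spikes"), rec$fs_hz)
      shuf <- randomize_spike_times(spikes, n_samples(rec) / rec$fs_hz,
                                    seed = as.integer(need("seed")))
      res <- compute_stsca(rec, shuf, geom(), as.numeric(need("window-s")))
      write_stsca_csv(res, need("out"))
    },
    whiten = {
      rec <- read_recording_csv(need("recording"))
      write_recording_csv(apply_whitening(rec, fit_whitening(rec)),
                          need("out"))
    },
    radial = {
      res <- read_stsca_csv(need("stsca"))
      rad <- radial_reduce(res, if (is.null(o$`bin-mm`)) NULL else
        as.numeric(o$`bin-mm`))
      write_radial_csv(rad, need("out"))
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0)
}
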