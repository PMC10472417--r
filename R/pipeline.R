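#' End-to-end pipeline: simulate, detect, review, average, invert, evaluate
#'
#' Orchestration of the full workflow on one simulated recording (one
#' recording = one "patient"), plus the cohort-level detection-agreement
#' experiment. Every random stage draws from a seed derived deterministically
#' from the configuration seed, so a run is reproducible from its report.
#'
#' @name hdesi-pipeline
NULL

#' Default pipeline configuration
#'
#' Nested list of all tunable parameters with the package defaults
#' (256-channel montage, three-shell head, 5 mm grid, 0.9 probability
#' threshold, wMNE with snr 3 and depth exponent 0.5, 10 mm distance
#' threshold). Override any entry via `modifyList`-style `...` arguments,
#' e.g. `default_config(electrodes = list(n_channels = 64))`.
#'
#' @param ... Named sublists merged over the defaults.
#' @return A `pipeline_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    head = list(radii_mm = c(80, 85, 92),
                conductivities_S_per_m = c(0.33, 0.004, 0.33)),
    electrodes = list(n_channels = 256L, coverage_polar_deg = 140),
    grid = list(spacing_mm = 5),
    forward = list(n_terms = 60L),
    simulation = list(duration_s = 300, rate = 250L, n_events = 40L,
                      source_radius_frac = 0.6, amplitude_nAm = 800,
                      jitter_amplitude_frac = 0.2, noise_rms_uV = 15,
                      spectral_exponent = 1, moment = "radial"),
    detection = list(min_separation_ms = 200, p_min = 0.9, tol_ms = 100,
                     reviewer_miss_rate = 0.05),
    epochs = list(half_width_s = 2, ptp_threshold_uV = 300),
    inverse = list(snr = 3, depth_exponent = 0.5, loading_frac = 0.05,
                   baseline_window = c(-1.5, -0.5)),
    evaluation = list(resection_radius_mm = 15, Ns = c(5L, 10L, 20L, 30L),
                      n_reps = 25L, threshold_mm = 10,
                      n_sublobes = 19L))
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      utils::modifyList(cfg[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Validate a pipeline configuration
#'
#' @param cfg A configuration list.
#' @return The configuration, invisibly; errors on violations.
#' @export
validate_config <- function(cfg) {
  need <- c("seed", "head", "electrodes", "grid", "forward", "simulation",
            "detection", "epochs", "inverse", "evaluation")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0) {
    stop("config lacks sections: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(
    is.numeric(cfg$seed), length(cfg$seed) == 1,
    cfg$detection$p_min >= 0, cfg$detection$p_min <= 1,
    cfg$simulation$n_events >= 0,
    cfg$evaluation$threshold_mm > 0,
    all(cfg$evaluation$Ns >= 1))
  invisible(cfg)
}

#' Build the forward context (montage, head, grid, lead field) for a config
#'
#' Deterministic in the configuration; exposed so callers can reuse one
#' lead field across a cohort.
#'
#' @param cfg A `pipeline_config`.
#' @return List with `head`, `electrodes`, `grid`, `leadfield`.
#' @export
build_forward_context <- function(cfg) {
  head <- three_shell_head(cfg$head$radii_mm, cfg$head$conductivities_S_per_m)
  electrodes <- build_electrode_array(cfg$electrodes$n_channels,
                                      cfg$electrodes$coverage_polar_deg,
                                      head$radii_mm[["scalp"]])
  grid <- build_source_grid(head, cfg$grid$spacing_mm)
  lf <- compute_leadfield(head, electrodes, grid, cfg$forward$n_terms)
  list(head = head, electrodes = electrodes, grid = grid, leadfield = lf)
}

# deterministic source placement: grid point closest to a target radius in
# a seed-dependent direction
pick_source_index <- function(grid, radius_frac, seed) {
  target_r <- radius_frac * grid$brain_radius_mm
  dir <- with_seed(seed * 13L + 5L, stats::rnorm(3))
  dir <- dir / sqrt(sum(dir^2))
  target <- dir * target_r
  which.min(rowSums(sweep(grid$positions, 2, target)^2))
}

#' Run the full pipeline on one simulated recording
#'
#' simulate -> detect -> probability filter -> cluster -> review -> epoch
#' -> artifact rejection -> average -> half-rise -> wMNE -> source maximum
#' -> distance/concordance -> subsampling curve.
#'
#' @param cfg A `pipeline_config` (see [default_config()]).
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   `events.tsv`, `reviewed.tsv`, `source_map.tsv` and
#'   `subsampling_curve.tsv` there.
#' @param context Optional precomputed [build_forward_context()] result.
#' @return A `run_report` list with per-stage counts, agreement metrics,
#'   localization results and the subsampling curve.
#' @export
run_full_pipeline <- function(cfg = default_config(), out_dir = NULL,
                              context = NULL) {
  validate_config(cfg)
  if (is.null(context)) context <- build_forward_context(cfg)
  lf <- context$leadfield
  grid <- context$grid
  sim <- cfg$simulation

  src_idx <- pick_source_index(grid, sim$source_radius_frac, cfg$seed)
  template <- generate_ied_template(sim$rate)
  rec <- simulate_recording(
    lf, template, n_events = sim$n_events, event_grid_index = src_idx,
    amplitude_nAm = sim$amplitude_nAm,
    jitter_amplitude_frac = sim$jitter_amplitude_frac,
    noise_rms_uV = sim$noise_rms_uV, duration_s = sim$duration_s,
    rate = sim$rate, seed = cfg$seed, moment = sim$moment,
    spectral_exponent = sim$spectral_exponent)
  truth <- marks_from_truth(rec)

  det <- cfg$detection
  detected <- detect_events(rec, template, det$min_separation_ms)
  filtered <- filter_by_probability(detected, det$p_min)
  clusters <- cluster_by_peak_electrode(filtered)
  reviewed <- simulate_review(filtered, truth, det$tol_ms,
                              det$reviewer_miss_rate, seed = cfg$seed + 1L)
  agreement <- agreement_report(truth, marks_from_events(filtered), reviewed,
                                duration_s = sim$duration_s,
                                tol_ms = det$tol_ms)

  ep_cfg <- cfg$epochs
  epochs <- extract_epochs(rec, reviewed, ep_cfg$half_width_s)
  n_edge <- attr(epochs, "n_skipped_edge")
  kept <- reject_artifact_epochs(epochs, ep_cfg$ptp_threshold_uV)
  n_rej <- attr(kept, "n_rejected")
  if (length(kept) == 0) {
    stop("pipeline [epochs]: no epochs survived review and artifact rejection",
         call. = FALSE)
  }

  inv <- cfg$inverse
  ncov <- estimate_noise_covariance(kept, inv$baseline_window,
                                    inv$loading_frac)
  op <- compute_wmne_operator(lf, ncov, inv$snr, inv$depth_exponent)
  avg <- average_epochs(kept)
  half <- find_half_rise(avg, inv$baseline_window)
  smap <- apply_inverse(op, avg, half)
  smax <- find_source_maximum(smap)

  ev <- cfg$evaluation
  mask <- make_resection_mask(grid, src_idx, ev$resection_radius_mm)
  atlas <- build_sublobe_atlas(grid, ev$n_sublobes, seed = cfg$seed)
  conc <- sublobar_concordance(smax, atlas, mask)
  Ns <- as.integer(ev$Ns)
  if (any(Ns > length(kept))) {
    stop(sprintf(
      "pipeline [subsample]: Ns up to %d exceed the %d accepted epochs",
      max(Ns), length(kept)), call. = FALSE)
  }
  curve <- subsample_experiment(kept, op, grid, mask, Ns, ev$n_reps,
                                seed = cfg$seed + 2L)

  report <- list(
    package_version = as.character(utils::packageVersion("hdesi")),
    config = cfg,
    counts = list(
      events_simulated = nrow(rec$events),
      events_detected = nrow(detected),
      events_filtered = nrow(filtered),
      events_reviewed = nrow(reviewed),
      epochs_extracted = length(epochs),
      epochs_skipped_edge = n_edge,
      epochs_rejected_artifact = n_rej,
      epochs_kept = length(kept),
      n_clusters = length(clusters)),
    agreement = unclass(agreement),
    localization = list(
      true_grid_index = src_idx,
      source_max_index = smax,
      half_rise_sample = half,
      localization_error_mm =
        sqrt(sum((grid$positions[smax, ] - grid$positions[src_idx, ])^2)),
      distance_to_resection_mm = distance_to_mask(smax, mask, grid),
      concordant_sublobe = conc$concordant_sublobe,
      concordant_hemisphere = conc$concordant_hemisphere),
    subsampling = list(
      curve = curve$curve,
      full_max_index = curve$full_max_index,
      smallest_N_below_mm =
        smallest_N_below(curve, ev$threshold_mm)))
  class(report) <- c("run_report", "list")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(prep_json(unclass(report)),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_events_tsv(detected, file.path(out_dir, "events.tsv"))
    write_events_tsv(reviewed, file.path(out_dir, "reviewed.tsv"))
    write_source_map_tsv(smap, grid, file.path(out_dir, "source_map.tsv"))
    utils::write.table(curve$curve,
                       file.path(out_dir, "subsampling_curve.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  report
}

# make a report JSON-stable: data frames to column lists, drop NULLs
prep_json <- function(x) {
  if (is.data.frame(x)) return(as.list(x))
  if (is.list(x)) return(lapply(x, prep_json))
  x
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  events: %d simulated, %d detected, %d at p >= %.2f, %d reviewed\n",
              x$counts$events_simulated, x$counts$events_detected,
              x$counts$events_filtered, x$config$detection$p_min,
              x$counts$events_reviewed))
  cat(sprintf("  agreement: sensitivity %.1f%%, PPV %.1f%%, kappa(reviewed) %.3f\n",
              x$agreement$sensitivity_pct, x$agreement$ppv_pct,
              x$agreement$kappa_reviewed))
  cat(sprintf("  localization: error %.1f mm, distance to resection %.1f mm\n",
              x$localization$localization_error_mm,
              x$localization$distance_to_resection_mm))
  cat(sprintf("  subsampling: stable below %g mm from N = %s\n",
              x$config$evaluation$threshold_mm,
              x$subsampling$smallest_N_below_mm))
  invisible(x)
}

#' Cohort experiment: reference vs automated detection agreement
#'
#' Simulates `n_recordings` recordings (seeds `cfg$seed + i`), computes the
#' per-recording agreement metrics, and pools them: mean sensitivity and
#' PPV, mean kappa for raw and reviewed selections, and the success-rate
#' table over cluster ranks 1..10.
#'
#' @param cfg A `pipeline_config`.
#' @param n_recordings Number of simulated recordings (>= 1).
#' @param min_ieds Cluster-size criterion for the success rate. Default 30.
#' @return List with `per_recording` data frame, `success_rate` data frame
#'   (rank 1..10, within-rank mode), and pooled means.
#' @export
run_detection_comparison <- function(cfg = default_config(), n_recordings,
                                     min_ieds = 30) {
  validate_config(cfg)
  if (n_recordings < 1) stop("n_recordings must be >= 1", call. = FALSE)
  context <- build_forward_context(cfg)
  template <- generate_ied_template(cfg$simulation$rate)
  det <- cfg$detection

  rows <- vector("list", n_recordings)
  cluster_counts <- vector("list", n_recordings)
  for (i in seq_len(n_recordings)) {
    seed_i <- cfg$seed + i
    src_idx <- pick_source_index(context$grid,
                                 cfg$simulation$source_radius_frac, seed_i)
    rec <- simulate_recording(
      context$leadfield, template, n_events = cfg$simulation$n_events,
      event_grid_index = src_idx,
      amplitude_nAm = cfg$simulation$amplitude_nAm,
      jitter_amplitude_frac = cfg$simulation$jitter_amplitude_frac,
      noise_rms_uV = cfg$simulation$noise_rms_uV,
      duration_s = cfg$simulation$duration_s, rate = cfg$simulation$rate,
      seed = seed_i, moment = cfg$simulation$moment,
      spectral_exponent = cfg$simulation$spectral_exponent)
    truth <- marks_from_truth(rec)
    detected <- detect_events(rec, template, det$min_separation_ms)
    filtered <- filter_by_probability(detected, det$p_min)
    reviewed <- simulate_review(filtered, truth, det$tol_ms,
                                det$reviewer_miss_rate, seed = seed_i + 1L)
    agr <- agreement_report(truth, marks_from_events(filtered), reviewed,
                            duration_s = cfg$simulation$duration_s,
                            tol_ms = det$tol_ms)
    # clusters of reviewed events carry the review decision back to the
    # filtered detections
    kept_det <- filtered[filtered$peak_time_s %in% reviewed$time_s, ,
                         drop = FALSE]
    cluster_counts[[i]] <- vapply(cluster_by_peak_electrode(kept_det),
                                  function(cl) cl$n, integer(1))
    rows[[i]] <- data.frame(
      recording = i, seed = seed_i,
      sensitivity_pct = agr$sensitivity_pct, ppv_pct = agr$ppv_pct,
      kappa_automated = agr$kappa_automated,
      kappa_reviewed = agr$kappa_reviewed,
      n_detected = agr$n_automated, n_reviewed = nrow(reviewed))
  }
  per_rec <- do.call(rbind, rows)
  sr <- data.frame(
    rank = 1:10,
    success_rate_pct = vapply(1:10, function(r) {
      success_rate(cluster_counts, r, min_ieds, mode = "within")
    }, numeric(1)))
  list(
    per_recording = per_rec,
    success_rate = sr,
    pooled = list(
      mean_sensitivity_pct = mean(per_rec$sensitivity_pct),
      mean_ppv_pct = mean(per_rec$ppv_pct, na.rm = TRUE),
      mean_kappa_automated = mean(per_rec$kappa_automated),
      mean_kappa_reviewed = mean(per_rec$kappa_reviewed),
      n_recordings = n_recordings, min_ieds = min_ieds))
}
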