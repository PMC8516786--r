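# Trace CSV format: columns t_s, dev_h_deg, dev_v_deg, pupil, valid;
# header mandatory; missing values written as empty fields.

#' Write a signal trace to CSV
#'
#' @param trace A [signal_trace()].
#' @param path Output path.
#' @param force Overwrite an existing file; default FALSE.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, force = FALSE) {
  stopifnot(inherits(trace, "signal_trace"))
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)")
  df <- data.frame(t_s = trace$t,
                   dev_h_deg = trace$dev_h,
                   dev_v_deg = trace$dev_v,
                   pupil = trace$pupil,
                   valid = as.integer(trace$valid))
  utils::write.table(format(df, digits = 9, trim = TRUE, scientific = FALSE),
                     path, sep = ",", na = "", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a signal trace from CSV
#'
#' Expects the columns `t_s, dev_h_deg, dev_v_deg, pupil, valid` with a
#' header row; empty fields are missing values.
#'
#' @param path CSV path.
#' @param pupil_unit Unit tag for the pupil column; default `"mm"`.
#' @return A [signal_trace()].
#' @export
read_trace_csv <- function(path, pupil_unit = "mm") {
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  need <- c("t_s", "dev_h_deg", "dev_v_deg", "pupil", "valid")
  if (!all(need %in% names(df)))
    stop("trace file must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("empty trace file: ", path)
  signal_trace(df$t_s, df$dev_h_deg, df$dev_v_deg, df$pupil,
               as.logical(df$valid), pupil_unit = pupil_unit)
}

#' Run the optical-artefact simulation experiment
#'
#' Sweeps both eye-model variants (spherical default and elliptical-cornea)
#' over the standard five viewing angles and the 2-6 mm pupil range, and
#' writes two tables: per-cell deviations and per-angle slopes for each
#' model. Deterministic; rerunning with the same configuration reproduces
#' the files byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param geometries Named list of [eye_geometry()] objects; default the
#'   spherical model and the elliptical variant.
#' @param camera A [camera_model()].
#' @param viewing_angles,pupil_grid,d_cal,step Passed to [simulate_psa()].
#' @param force Overwrite existing outputs.
#' @return Invisibly, a list with the `deviations` and `slopes` tibbles
#'   (file paths in attributes).
#' @export
run_simulation_experiment <- function(out_dir,
                                      geometries = list(
                                        spherical = eye_geometry(),
                                        ellipsoidal = ellipsoidal_eye()),
                                      camera = camera_model(),
                                      viewing_angles = c(-12, -6, 0, 6, 12),
                                      pupil_grid = seq(2, 6, by = 0.25),
                                      d_cal = 4, step = 0.001,
                                      force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sims <- lapply(geometries, simulate_psa, camera = camera,
                 viewing_angles = viewing_angles, pupil_grid = pupil_grid,
                 d_cal = d_cal, step = step)
  dev <- do.call(rbind, lapply(names(sims), function(nm)
    cbind(model = nm, as.data.frame(sims[[nm]]$deviations))))
  slp <- do.call(rbind, lapply(names(sims), function(nm)
    cbind(model = nm, as.data.frame(sims[[nm]]$slopes))))
  names(dev) <- c("model", "viewing_angle_deg", "pupil_diameter_mm",
                  "deviation_deg")
  names(slp) <- c("model", "viewing_angle_deg", "slope_deg_per_mm",
                  "intercept_deg")
  fdev <- file.path(out_dir, "simulated_deviations.csv")
  fslp <- file.path(out_dir, "simulated_slopes.csv")
  for (f in c(fdev, fslp)) if (file.exists(f) && !force)
    stop("refusing to overwrite ", f, " (use force = TRUE)")
  fmt <- function(d) {
    d[] <- lapply(d, function(col)
      if (is.numeric(col)) signif(col, 9) else col)
    d
  }
  utils::write.csv(fmt(dev), fdev, row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(slp), fslp, row.names = FALSE, quote = FALSE)
  invisible(structure(list(deviations = tibble::as_tibble(dev),
                           slopes = tibble::as_tibble(slp)),
                      files = c(fdev, fslp)))
}

#' Run the artefact-quantification workflow over traces
#'
#' Composes the quantification steps in the standard order - velocity
#' filtering, median centering, decile curve, line fit - for a batch of
#' traces, and reports per-trace data-loss proportions alongside the
#' slopes.
#'
#' @param traces A list of [signal_trace()] objects, or a character vector
#'   of trace CSV paths.
#' @param cfg A [filter_config()].
#' @param center Subtract the per-trial median deviation first; default
#'   TRUE.
#' @param component Deviation component for the curves.
#' @return A list with `curves` (tibble: trace, decile k, pupil_mm,
#'   mean_deviation_deg; 7 rows per trace) and `summary` (tibble: trace,
#'   slope_deg_per_mm, intercept_deg, data_loss, filter_threshold).
#' @export
run_psa_workflow <- function(traces, cfg = filter_config(), center = TRUE,
                             component = c("horizontal", "vertical")) {
  component <- match.arg(component)
  if (is.character(traces)) {
    nms <- basename(traces)
    traces <- lapply(traces, read_trace_csv)
    names(traces) <- nms
  }
  if (inherits(traces, "signal_trace")) traces <- list(traces)
  if (is.null(names(traces)) || any(names(traces) == ""))
    names(traces) <- sprintf("trace%02d", seq_along(traces))
  curves <- list(); rows <- list()
  for (nm in names(traces)) {
    tr <- filter_trace(traces[[nm]], cfg)
    if (center) tr <- median_center(tr)
    cur <- decile_curve(tr, component)
    fs <- attr(tr, "filter_stats")
    curves[[nm]] <- tibble::tibble(trace = nm, decile = 2:8,
                                   pupil_mm = cur$decile_x,
                                   mean_deviation_deg = cur$mean_dev_y)
    rows[[nm]] <- tibble::tibble(trace = nm,
                                 slope_deg_per_mm = cur$slope,
                                 intercept_deg = cur$intercept,
                                 data_loss = data_loss_proportion(tr),
                                 filter_threshold = fs$threshold,
                                 n_fast_samples = fs$n_fast)
  }
  list(curves = do.call(rbind, curves),
       summary = do.call(rbind, rows))
}
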