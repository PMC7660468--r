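# Trigger-delay (TD) scout analysis: trace images, circular crop around the
# heart, per-TD mean/SD signal, normalization, and TD-window suggestion for
# early systole, late systole and diastasis.

#' Trace image over diffusion directions
#'
#' Voxelwise arithmetic mean of the per-direction diffusion-weighted
#' images; approximately rotation-invariant.
#'
#' @param images list of equally-sized matrices (one per direction).
#' @return Matrix.
#' @export
trace_image <- function(images) {
  dims <- unique(lapply(images, dim))
  if (length(dims) != 1) stop("direction images must share one shape", call. = FALSE)
  Reduce(`+`, images) / length(images)
}

#' Per-TD scout signal from a circular central crop
#'
#' For each trigger delay, averages the three orthogonal-direction images
#' into a trace image, crops it to a disk (default radius 48 mm) around
#' `center`, and reports the mean and SD of the cropped signal.
#'
#' @param stack a `cdti_stack` with a `td` metadata column (ms).
#' @param center crop centre (mm, image-plane coordinates); default the
#'   image centre, or supply the LV centroid when contours are available.
#' @param radius crop radius (mm).
#' @param rr_ms RR interval used to normalize TD (ms).
#' @return A `cdti_scout_series` tibble: `td_ms`, `td_over_rr`, `mean`,
#'   `sd`, `n_voxels`.
#' @export
scout_signal <- function(stack, center = c(0, 0), radius = 48, rr_ms = 1000) {
  stopifnot(inherits(stack, "cdti_stack"))
  if (all(is.na(stack$meta$td))) stop("stack has no TD metadata", call. = FALSE)
  d <- dim(stack$images[[1]])
  g <- cdti_grid(d, stack$pixel_spacing)
  disk <- (g$x - center[1])^2 + (g$y - center[2])^2 <= radius^2
  if (!any(disk)) stop("empty circular crop", call. = FALSE)
  if (radius > max(abs(g$x)) + stack$pixel_spacing) {
    warning("crop radius extends beyond the field of view")
  }
  tds <- sort(unique(stack$meta$td))
  out <- purrr::map_dfr(tds, function(td) {
    idx <- which(stack$meta$td == td)
    tr <- trace_image(stack$images[idx])
    vals <- tr[disk]
    tibble::tibble(td_ms = td, td_over_rr = td / rr_ms,
                   mean = mean(vals), sd = stats::sd(vals),
                   n_voxels = sum(disk))
  })
  class(out) <- c("cdti_scout_series", class(out))
  out
}

#' Normalize a scout series to its maximum mean signal
#'
#' Divides all per-TD means by the maximum mean across cardiac phases, so
#' the best phase equals 1 (ties broken by the first occurrence, reported
#' in the `max_td_ms` attribute).
#'
#' @param series a `cdti_scout_series` from [scout_signal()].
#' @return The series with a `normalized` column added.
#' @export
normalize_scout <- function(series) {
  if (nrow(series) == 0 || all(series$mean == 0)) {
    stop("cannot normalize an all-zero scout series", call. = FALSE)
  }
  m <- max(series$mean)
  out <- dplyr::mutate(series, normalized = .data$mean / m)
  attr(out, "max_td_ms") <- series$td_ms[which.max(series$mean)]
  class(out) <- c("cdti_scout_series", setdiff(class(out), "cdti_scout_series"))
  out
}

#' Suggest acquisition TD windows from a normalized scout series
#'
#' Within each nominal cardiac-phase TD range (early systole 150-200 ms,
#' late systole 250-350 ms, diastasis 700-900 ms by default), returns the
#' TD maximizing the normalized mean signal together with a pass/fail flag
#' at `threshold`. This is an aid to the visual assessment of the trace
#' signal, not a replacement: the threshold is a tool default, and no phase
#' is ever dropped silently.
#'
#' @param series a normalized `cdti_scout_series` (see [normalize_scout()]).
#' @param windows tibble with `phase`, `lo`, `hi` (ms).
#' @param threshold minimum acceptable normalized signal (default 0.7).
#' @return Tibble: `phase`, `td_ms`, `normalized`, `pass`; phases with no
#'   scouted TD in range are reported with `NA` TD and `pass = NA`.
#' @export
suggest_windows <- function(series,
                            windows = tibble::tibble(
                              phase = c("early_systole", "late_systole", "diastasis"),
                              lo = c(150, 250, 700), hi = c(200, 350, 900)),
                            threshold = 0.7) {
  if (!"normalized" %in% names(series)) {
    stop("series must be normalized first (see normalize_scout)", call. = FALSE)
  }
  purrr::pmap_dfr(windows, function(phase, lo, hi) {
    sel <- series$td_ms >= lo & series$td_ms <= hi
    if (!any(sel)) {
      return(tibble::tibble(phase = phase, td_ms = NA_real_,
                            normalized = NA_real_, pass = NA))
    }
    sub <- series[sel, ]
    best <- which.max(sub$normalized)
    tibble::tibble(phase = phase, td_ms = sub$td_ms[best],
                   normalized = sub$normalized[best],
                   pass = sub$normalized[best] >= threshold)
  })
}
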