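# Preprocessing of diffusion-weighted stacks: rigid (translation-only)
# registration by phase correlation with sub-pixel refinement, repetition
# averaging, and in-plane interpolation by k-space zero-filling.

# sub-pixel image translation by Fourier phase ramp; exact circular shift
# for integer shifts
fourier_shift <- function(img, dx, dy) {
  n1 <- nrow(img); n2 <- ncol(img)
  k1 <- c(0:floor(n1 / 2), -(ceiling(n1 / 2) - 1):-1)[1:n1]
  k2 <- c(0:floor(n2 / 2), -(ceiling(n2 / 2) - 1):-1)[1:n2]
  r1 <- exp(-2i * pi * k1 * dx / n1)
  r2 <- exp(-2i * pi * k2 * dy / n2)
  # real part at the shared Nyquist bin keeps the shifted image real
  if (n1 %% 2 == 0) r1[n1 / 2 + 1] <- cos(pi * dx)
  if (n2 %% 2 == 0) r2[n2 / 2 + 1] <- cos(pi * dy)
  ramp <- outer(r1, r2)
  Re(stats::fft(stats::fft(img) * ramp, inverse = TRUE)) / (n1 * n2)
}

# upsampled cross-correlation in a small neighbourhood of the integer peak
# via matrix-multiply DFT (local zoom of the inverse transform)
upsampled_peak <- function(R, x0, y0, upsample = 20, half_width = 1.5) {
  n1 <- nrow(R); n2 <- ncol(R)
  k1 <- c(0:floor(n1 / 2), -(ceiling(n1 / 2) - 1):-1)[1:n1]
  k2 <- c(0:floor(n2 / 2), -(ceiling(n2 / 2) - 1):-1)[1:n2]
  xs <- x0 + seq(-half_width, half_width, by = 1 / upsample)
  ys <- y0 + seq(-half_width, half_width, by = 1 / upsample)
  Ex <- exp(2i * pi * outer(xs, k1) / n1)        # |xs| x n1
  Ey <- exp(2i * pi * outer(k2, ys) / n2)        # n2 x |ys|
  C <- Re(Ex %*% R %*% Ey) / (n1 * n2)
  pk <- which(C == max(C), arr.ind = TRUE)[1, ]
  list(x = xs[pk[1]], y = ys[pk[2]], value = max(C))
}

#' Estimate the translation between two images by phase correlation
#'
#' Cross-power spectrum phase correlation with 3-point parabolic sub-pixel
#' refinement of the correlation peak. Returns the correcting translation:
#' `fourier_shift(img, dx, dy)` aligns `img` onto `ref` (so for an image
#' displaced by `+d`, the estimate is `-d`).
#'
#' @param ref,img equally-sized matrices.
#' @return List with `dx`, `dy` (px, the correcting translation) and
#'   `peak` (normalized correlation peak height, used as a confidence score).
#' @export
phase_correlation <- function(ref, img) {
  stopifnot(all(dim(ref) == dim(img)))
  n1 <- nrow(ref); n2 <- ncol(ref)
  if (all(ref == 0) || all(img == 0)) {
    return(list(dx = 0, dy = 0, peak = 0))
  }
  Fr <- stats::fft(ref); Fi <- stats::fft(img)
  R <- Fr * Conj(Fi)
  mag <- Mod(R)
  mag[mag < .Machine$double.eps] <- .Machine$double.eps
  Rn <- R / mag
  corr <- Re(stats::fft(Rn, inverse = TRUE)) / (n1 * n2)
  pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)
  x0 <- wrap(pk[1] - 1, n1); y0 <- wrap(pk[2] - 1, n2)
  # two-stage refinement: 1/20 px over +/-1.5 px, then 1/200 px locally
  coarse <- upsampled_peak(Rn, x0, y0, upsample = 20, half_width = 1.5)
  fine <- upsampled_peak(Rn, coarse$x, coarse$y, upsample = 200,
                         half_width = 0.1)
  list(dx = fine$x, dy = fine$y, peak = max(corr))
}

#' Register a DWI stack by in-plane translation
#'
#' Two-pass scheme: the b = 0 images are registered to a reference b = 0
#' image (by default the first), then all diffusion-weighted images are
#' registered to the mean of the registered b = 0 images (the highest-SNR
#' anchor). Images are resampled by Fourier shift, so no interpolation blur
#' is introduced. Shifts with a correlation peak below `min_peak` are
#' flagged low-confidence (the shift is still applied).
#'
#' @param stack a `cdti_stack`.
#' @param reference index of the reference image; default first b = 0 image.
#' @param min_peak confidence floor on the normalized correlation peak.
#' @return List with `stack` (aligned `cdti_stack`) and `shifts` (tibble:
#'   `index`, `dx`, `dy`, `peak`, `flagged`; the reference row is (0,0)).
#' @export
register_stack <- function(stack, reference = NULL, min_peak = 0.03) {
  stopifnot(inherits(stack, "cdti_stack"))
  b0_idx <- which(stack$meta$b == 0)
  if (is.null(reference)) {
    reference <- if (length(b0_idx) > 0) b0_idx[1] else 1L
  }
  if (!reference %in% seq_along(stack$images)) {
    stop("reference image not in stack", call. = FALSE)
  }
  nimg <- length(stack$images)
  dx <- numeric(nimg); dy <- numeric(nimg); peak <- numeric(nimg)
  aligned <- stack$images

  ref_img <- stack$images[[reference]]
  # pass 1: align b0s to the reference b0
  for (v in setdiff(b0_idx, reference)) {
    est <- phase_correlation(ref_img, stack$images[[v]])
    dx[v] <- est$dx; dy[v] <- est$dy; peak[v] <- est$peak
    aligned[[v]] <- fourier_shift(stack$images[[v]], est$dx, est$dy)
  }
  peak[reference] <- 1
  # pass 2: align everything else to the mean registered b0
  anchor <- if (length(b0_idx) > 0) {
    Reduce(`+`, aligned[b0_idx]) / length(b0_idx)
  } else {
    ref_img
  }
  for (v in setdiff(seq_len(nimg), c(b0_idx, reference))) {
    est <- phase_correlation(anchor, stack$images[[v]])
    dx[v] <- est$dx; dy[v] <- est$dy; peak[v] <- est$peak
    aligned[[v]] <- fourier_shift(stack$images[[v]], est$dx, est$dy)
  }
  shifts <- tibble::tibble(
    index = seq_len(nimg), dx = dx, dy = dy, peak = peak,
    flagged = peak < min_peak & seq_len(nimg) != reference
  )
  list(stack = new_dwi_stack(aligned, stack$meta, stack$pixel_spacing),
       shifts = shifts)
}

#' Re-centre a registered stack on a reference point
#'
#' Registration aligns all images to the reference image's frame, which may
#' itself be displaced from the frame the contours were drawn in. This step
#' shifts the whole stack so that the intensity-weighted centroid of the
#' first b = 0 image (thresholded to suppress the noise floor) lands on
#' `center` (mm) - the analogue of drawing contours on the registered data.
#'
#' @param stack a registered `cdti_stack`.
#' @param center target centroid (mm, image-plane coordinates).
#' @param threshold intensity threshold, as a fraction of the b0 maximum.
#' @return List with the shifted `stack` and the applied `shift_px`.
#' @export
recenter_stack <- function(stack, center = c(0, 0), threshold = 0.2) {
  b0_idx <- which(stack$meta$b == 0)[1]
  if (is.na(b0_idx)) b0_idx <- 1L
  img <- stack$images[[b0_idx]]
  g <- cdti_grid(dim(img), stack$pixel_spacing)
  wts <- pmax(img - threshold * max(img), 0)
  cx <- sum(wts * g$x) / sum(wts)
  cy <- sum(wts * g$y) / sum(wts)
  dx <- (center[1] - cx) / stack$pixel_spacing
  dy <- (center[2] - cy) / stack$pixel_spacing
  images <- lapply(stack$images, fourier_shift, dx = dx, dy = dy)
  list(stack = new_dwi_stack(images, stack$meta, stack$pixel_spacing),
       shift_px = c(dx = dx, dy = dy))
}

#' Average repetitions per (b, direction)
#'
#' Arithmetic mean of the (registered) magnitude images within each unique
#' (b-value, direction, phase) group; the published protocol's 12 directions
#' x 8 repetitions + per-repetition b = 0 collapse to 13 images. Warns when
#' repetition counts differ across groups and proceeds with per-group counts.
#'
#' @param stack a registered `cdti_stack`.
#' @return A `cdti_stack` with one image per group.
#' @export
average_repetitions <- function(stack) {
  stopifnot(inherits(stack, "cdti_stack"))
  key <- paste(stack$meta$phase, stack$meta$b,
               round(stack$meta$gx, 6), round(stack$meta$gy, 6),
               round(stack$meta$gz, 6))
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  counts <- lengths(groups)
  if (length(unique(counts)) > 1) {
    warning("unequal repetition counts across (b, direction) groups; ",
            "averaging with per-group counts")
  }
  images <- vector("list", length(groups))
  meta <- list()
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    images[[i]] <- Reduce(`+`, stack$images[idx]) / length(idx)
    row <- stack$meta[idx[1], ]
    row$index <- i
    row$repetition <- 1L
    meta[[i]] <- row
  }
  new_dwi_stack(images, dplyr::bind_rows(meta), stack$pixel_spacing)
}

#' In-plane interpolation by k-space zero-filling
#'
#' Forward FFT, symmetric zero-padding of k-space to `factor` times the
#' matrix size (with the Nyquist bin split for even input sizes so the
#' interpolant stays real and exact), inverse FFT and magnitude. The field
#' of view is preserved; pixel spacing drops by `factor`; the DC level (mean
#' intensity) is preserved; original samples are recovered exactly on the
#' aligned sub-grid.
#'
#' @param img 2D matrix.
#' @param factor integer upsampling factor >= 1.
#' @return Matrix of size `factor * dim(img)`, with attribute
#'   `spacing_factor = 1/factor`.
#' @export
zero_fill <- function(img, factor = 2) {
  if (factor != round(factor) || factor < 1) {
    stop("zero-fill factor must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(img)
  n1 <- nrow(img); n2 <- ncol(img)
  K <- stats::fft(img)

  pad_axis <- function(K, n, axis) {
    nn <- n * factor
    idx_pos <- 1:(floor(n / 2) + 1)              # DC .. +Nyquist
    idx_neg <- if (n > 1) (floor(n / 2) + 2):n else integer(0)
    if (axis == 1) {
      out <- matrix(0 + 0i, nn, ncol(K))
      out[idx_pos, ] <- K[idx_pos, ]
      out[nn - (n - idx_neg), ] <- K[idx_neg, ]
      if (n %% 2 == 0) {
        ny <- n / 2 + 1                          # shared Nyquist bin: split
        out[ny, ] <- K[ny, ] / 2
        out[nn - n / 2 + 1, ] <- K[ny, ] / 2
      }
    } else {
      out <- matrix(0 + 0i, nrow(K), nn)
      out[, idx_pos] <- K[, idx_pos]
      out[, nn - (n - idx_neg)] <- K[, idx_neg]
      if (n %% 2 == 0) {
        ny <- n / 2 + 1
        out[, ny] <- K[, ny] / 2
        out[, nn - n / 2 + 1] <- K[, ny] / 2
      }
    }
    out
  }
  K2 <- pad_axis(pad_axis(K, n1, 1), n2, 2)
  out <- Re(stats::fft(K2, inverse = TRUE)) / (n1 * n2)   # DC-preserving scale
  attr(out, "spacing_factor") <- 1 / factor
  out
}

#' Zero-fill every image of a stack
#' @param stack a `cdti_stack`.
#' @param factor integer upsampling factor.
#' @return A `cdti_stack` at `pixel_spacing / factor`.
#' @export
zero_fill_stack <- function(stack, factor = 2) {
  images <- lapply(stack$images, function(im) {
    out <- zero_fill(im, factor)
    attr(out, "spacing_factor") <- NULL
    out
  })
  new_dwi_stack(images, stack$meta, stack$pixel_spacing / factor)
}
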