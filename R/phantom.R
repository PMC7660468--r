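# Synthetic left-ventricle phantom: an annular mid-ventricular short-axis
# slice with a prescribed transmural helix-angle law, constant E2A per
# cardiac phase, per-phase geometry (contraction modelled geometrically),
# simulated diffusion-weighted signals, repetitions with misregistration
# shifts, and Rician noise.

#' Default per-phase microstructure prescriptions
#'
#' Endocardial/epicardial helix angle, sheetlet angle E2A and sorted
#' eigenvalues for the three imaged cardiac phases, drawn from healthy
#' mid-ventricular values (global medians): HA endo/epi 44.4/-33.8 deg in
#' early systole, 53.3/-41.3 in late systole, 55.0/-33.8 at diastasis;
#' E2A 27.7/45.2/20.7 deg; eigenvalues consistent with MD
#' 1.79/1.53/1.64e-3 mm^2/s and lambda2/lambda1 ~ 0.7.
#'
#' @return Tibble with one row per phase.
#' @export
phase_prescriptions <- function() {
  tibble::tibble(
    phase = c("early_systole", "late_systole", "diastasis"),
    ha_endo = c(44.4, 53.3, 55.0),
    ha_epi = c(-33.8, -41.3, -33.8),
    e2a = c(27.7, 45.2, 20.7),
    ta = c(0, 0, 0),
    lambda1 = c(2.52e-3, 2.08e-3, 2.30e-3),
    lambda2 = c(1.68e-3, 1.45e-3, 1.587e-3),
    lambda3 = c(1.17e-3, 1.06e-3, 1.033e-3),
    # geometric contraction: smaller cavity, thicker wall in late systole
    endo_radius = c(18, 14, 22),
    epi_radius = c(31, 32, 32)
  )
}

#' Phantom specification
#'
#' @param phase one of `"early_systole"`, `"late_systole"`, `"diastasis"`;
#'   selects the default geometry and microstructure row of
#'   [phase_prescriptions()].
#' @param n matrix size (n x n voxels).
#' @param pixel_spacing in-plane voxel size (mm).
#' @param endo_radius,epi_radius annulus radii (mm); epi > endo > 0.
#' @param ha_endo,ha_epi helix angle at depth 0 (endo) and 1 (epi), degrees.
#' @param ta transverse angle (degrees), constant over the wall.
#' @param e2a sheetlet angle (degrees), constant over the wall.
#' @param eigenvalues sorted tensor eigenvalues (mm^2/s), descending.
#' @param s0 baseline (b = 0) signal.
#' @param b b-value of the diffusion-weighted images (s/mm^2).
#' @param directions unit diffusion directions, one per row; default a
#'   12-direction hemisphere set as in the imaging protocol.
#' @param noise_sigma Rician channel noise SD (same units as `s0`).
#' @param n_reps number of repetitions simulated by [corrupt_stack()].
#' @param shift_sigma SD of the per-repetition in-plane translation (px).
#' @param seed RNG seed recorded in the spec and used by the simulators.
#' @return A validated `cdti_phantom_spec` list.
#' @export
phantom_spec <- function(phase = "late_systole",
                         n = 72, pixel_spacing = 1.6,
                         endo_radius = NULL, epi_radius = NULL,
                         ha_endo = NULL, ha_epi = NULL,
                         ta = NULL, e2a = NULL,
                         eigenvalues = NULL,
                         s0 = 1, b = 350,
                         directions = dwi_directions(12),
                         noise_sigma = 0.05, n_reps = 8,
                         shift_sigma = 0.8, seed = 1L) {
  presets <- phase_prescriptions()
  if (!phase %in% presets$phase) {
    stop("unknown phase: ", phase, call. = FALSE)
  }
  row <- presets[presets$phase == phase, ]
  if (is.null(endo_radius)) endo_radius <- row$endo_radius
  if (is.null(epi_radius)) epi_radius <- row$epi_radius
  if (is.null(ha_endo)) ha_endo <- row$ha_endo
  if (is.null(ha_epi)) ha_epi <- row$ha_epi
  if (is.null(ta)) ta <- row$ta
  if (is.null(e2a)) e2a <- row$e2a
  if (is.null(eigenvalues)) eigenvalues <- c(row$lambda1, row$lambda2, row$lambda3)

  if (!(epi_radius > endo_radius && endo_radius > 0)) {
    stop("need epi_radius > endo_radius > 0", call. = FALSE)
  }
  if (any(diff(eigenvalues) > 0) || any(eigenvalues <= 0)) {
    stop("eigenvalues must be positive and sorted descending", call. = FALSE)
  }
  if (any(abs(c(ha_endo, ha_epi, ta)) > 90) || e2a < 0 || e2a > 90) {
    stop("angles out of range: |HA|,|TA| <= 90, E2A in [0, 90]", call. = FALSE)
  }
  if (noise_sigma < 0 || shift_sigma < 0) {
    stop("noise_sigma and shift_sigma must be non-negative", call. = FALSE)
  }
  structure(list(
    phase = phase, n = as.integer(n), pixel_spacing = pixel_spacing,
    endo_radius = endo_radius, epi_radius = epi_radius,
    ha_endo = ha_endo, ha_epi = ha_epi, ta = ta, e2a = e2a,
    eigenvalues = eigenvalues, s0 = s0, b = b, directions = directions,
    noise_sigma = noise_sigma, n_reps = as.integer(n_reps),
    shift_sigma = shift_sigma, seed = as.integer(seed)
  ), class = "cdti_phantom_spec")
}

#' Deterministic hemisphere direction set
#'
#' Spherical Fibonacci points on the upper hemisphere; well-conditioned for
#' tensor estimation and reproducible without a stored table.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
dwi_directions <- function(n = 12) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n                     # upper hemisphere, away from the pole
  r <- sqrt(pmax(0, 1 - z^2))
  g <- cbind(r * cos(phi), r * sin(phi), z)
  g / sqrt(rowSums(g^2))
}

#' Build a tensor from helix, transverse and sheetlet angles
#'
#' Inverse of the angle operators: constructs `D = sum lambda_i E_i E_i^T`
#' where the primary eigenvector E1 has helix angle `ha` and transverse
#' angle `ta` in the local frame, and E2 makes sheetlet angle `e2a` within
#' the cross-myocyte plane (the plane normal to E1's tangent-plane
#' projection). Round-trips exactly through [helix_angle()],
#' [transverse_angle()] and [e2_angle()].
#'
#' @param ha,ta,e2a angles in degrees; |ha| <= 90, |ta| < 90, e2a in [0, 90].
#' @param eigenvalues length-3, sorted descending (mm^2/s).
#' @param frame 3 x 3 orthonormal right-handed matrix with columns
#'   (circumferential, radial, longitudinal).
#' @return List with the symmetric 3 x 3 tensor `D` and eigenvectors
#'   `E1`, `E2`, `E3`.
#' @export
tensor_from_angles <- function(ha, ta, e2a, eigenvalues, frame) {
  stopifnot(length(eigenvalues) == 3)
  if (max(abs(crossprod(frame) - diag(3))) > 1e-8 || det(frame) < 0) {
    stop("frame must be orthonormal and right-handed", call. = FALSE)
  }
  cv <- frame[, 1]; rv <- frame[, 2]; lv <- frame[, 3]
  har <- ha * pi / 180; tar <- ta * pi / 180; e2ar <- e2a * pi / 180

  # E1 with tan(HA) = (E1.l)/(E1.c), tan(TA) = (E1.r)/(E1.c)
  e1 <- cos(har) * cv + sin(har) * lv + cos(har) * tan(tar) * rv
  e1 <- e1 / sqrt(sum(e1^2))

  # tangent-plane projection direction of E1 and the in-plane normal s
  p <- cos(har) * cv + sin(har) * lv
  p <- p / sqrt(sum(p^2))
  s <- pracma::cross(rv, p)              # wall-tangent axis of the cross plane
  s <- s / sqrt(sum(s^2))
  alpha <- sum(e1 * p)                   # E1 component along p
  beta <- sum(e1 * rv)
  m <- -beta * p + alpha * rv            # unit, orthogonal to E1 and to s
  psi <- atan2(tan(e2ar), alpha)         # so that the E2A operator returns e2a
  e2 <- cos(psi) * s + sin(psi) * m
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- pracma::cross(e1, e2)

  D <- eigenvalues[1] * tcrossprod(e1) + eigenvalues[2] * tcrossprod(e2) +
    eigenvalues[3] * tcrossprod(e3)
  list(D = (D + t(D)) / 2, E1 = e1, E2 = e2, E3 = e3)
}

# voxel-centre coordinates in mm, origin at the image centre
grid_coordinates <- function(n, spacing) {
  x <- ((seq_len(n) - 1) + 0.5) * spacing - n * spacing / 2
  list(x = matrix(x, n, n), y = matrix(x, n, n, byrow = TRUE))
}

# radial local frame of a concentric annulus at polar angle phi:
# r outward, l = +z (towards base), c = r x l
annulus_frame <- function(phi) {
  rv <- c(cos(phi), sin(phi), 0)
  lv <- c(0, 0, 1)
  cv <- pracma::cross(rv, lv)
  cbind(cv, rv, lv)
}

circle_contour <- function(radius, n_points = 72) {
  phi <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  tibble::tibble(x_mm = radius * cos(phi), y_mm = radius * sin(phi))
}

#' Generate a noiseless phantom acquisition with ground truth
#'
#' Builds the annulus mask, a helix angle linear in normalized transmural
#' depth between `ha_endo` and `ha_epi`, per-voxel tensors via
#' [tensor_from_angles()], and the noiseless protocol signals
#' `S(g, b) = s0 exp(-b g' D g)` (one b = 0 image plus one image per
#' direction).
#'
#' @param spec a [phantom_spec()].
#' @return List with `stack` (a `cdti_stack` of noiseless images) and
#'   `truth` (maps of HA/TA/E2A/depth, tensors, frames, contours, mask).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "cdti_phantom_spec"))
  n <- spec$n; sp <- spec$pixel_spacing
  if ((spec$epi_radius - spec$endo_radius) < 2 * sp) {
    stop("annulus thinner than two voxels: transmural profile undefined",
         call. = FALSE)
  }
  g <- grid_coordinates(n, sp)
  rho <- sqrt(g$x^2 + g$y^2)
  phi <- atan2(g$y, g$x)
  mask <- rho > spec$endo_radius & rho <= spec$epi_radius
  depth <- matrix(NA_real_, n, n)
  depth[mask] <- (rho[mask] - spec$endo_radius) /
    (spec$epi_radius - spec$endo_radius)

  ha <- matrix(NA_real_, n, n)
  ha[mask] <- spec$ha_endo + depth[mask] * (spec$ha_epi - spec$ha_endo)

  idx <- which(mask)
  nvox <- length(idx)
  tensors <- matrix(NA_real_, nvox, 6)     # xx yy zz xy xz yz
  e1s <- matrix(NA_real_, nvox, 3)
  e2s <- matrix(NA_real_, nvox, 3)
  frames <- matrix(NA_real_, nvox, 9)
  for (k in seq_len(nvox)) {
    fr <- annulus_frame(phi[idx[k]])
    tf <- tensor_from_angles(ha[idx[k]], spec$ta, spec$e2a,
                             spec$eigenvalues, fr)
    D <- tf$D
    tensors[k, ] <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    e1s[k, ] <- tf$E1
    e2s[k, ] <- tf$E2
    frames[k, ] <- as.vector(fr)
  }

  bvals <- c(0, rep(spec$b, nrow(spec$directions)))
  bvecs <- rbind(c(0, 0, 0), spec$directions)
  images <- vector("list", length(bvals))
  for (v in seq_along(bvals)) {
    img <- matrix(0, n, n)
    if (bvals[v] == 0) {
      img[idx] <- spec$s0
    } else {
      gv <- bvecs[v, ]
      # g' D g from the 6 unique components
      quad <- tensors[, 1] * gv[1]^2 + tensors[, 2] * gv[2]^2 +
        tensors[, 3] * gv[3]^2 + 2 * tensors[, 4] * gv[1] * gv[2] +
        2 * tensors[, 5] * gv[1] * gv[3] + 2 * tensors[, 6] * gv[2] * gv[3]
      img[idx] <- spec$s0 * exp(-bvals[v] * quad)
    }
    images[[v]] <- img
  }
  meta <- tibble::tibble(
    index = seq_along(bvals), b = bvals,
    gx = bvecs[, 1], gy = bvecs[, 2], gz = bvecs[, 3],
    repetition = 1L, phase = spec$phase, td = NA_real_
  )
  stack <- new_dwi_stack(images, meta, sp)

  contours <- dplyr::bind_rows(
    dplyr::mutate(circle_contour(spec$endo_radius), surface = "endo"),
    dplyr::mutate(circle_contour(spec$epi_radius), surface = "epi")
  )
  truth <- list(
    mask = mask, depth = depth, ha = ha,
    ta = ifelse(mask, spec$ta, NA_real_),
    e2a = ifelse(mask, spec$e2a, NA_real_),
    voxel_index = idx, tensors = tensors, e1 = e1s, e2 = e2s,
    frames = frames, contours = contours, spec = spec
  )
  list(stack = stack, truth = truth)
}

#' Add Rician noise to a magnitude image
#'
#' `|S + n1 + i n2|` with independent Gaussian channels of SD `sigma`.
#'
#' @param img matrix of noiseless magnitudes.
#' @param sigma channel noise SD; 0 returns the input.
#' @param gaussian if `TRUE`, add plain Gaussian noise instead (linear-regime
#'   tests).
#' @return Noisy matrix.
#' @export
add_noise <- function(img, sigma, gaussian = FALSE) {
  if (sigma == 0) return(img)
  if (gaussian) {
    img + matrix(stats::rnorm(length(img), 0, sigma), nrow(img))
  } else {
    n1 <- matrix(stats::rnorm(length(img), 0, sigma), nrow(img))
    n2 <- matrix(stats::rnorm(length(img), 0, sigma), nrow(img))
    sqrt((img + n1)^2 + n2^2)
  }
}

#' Replicate, shift and noise a stack (acquisition corruption model)
#'
#' Replicates each image `n_reps` times, translates every repetition by an
#' independent in-plane shift drawn from `Normal(0, shift_sigma)` (applied by
#' Fourier shift and recorded in the metadata), and applies Rician noise.
#'
#' @param stack a `cdti_stack` (typically noiseless, repetition 1).
#' @param n_reps repetitions per image.
#' @param shift_sigma SD of the per-repetition translation (px).
#' @param noise_sigma Rician channel SD.
#' @param seed RNG seed; results are reproducible for a fixed seed.
#' @param gaussian use Gaussian instead of Rician noise.
#' @return A `cdti_stack` with `n_reps` repetitions and metadata columns
#'   `true_shift_x`, `true_shift_y` (px).
#' @export
corrupt_stack <- function(stack, n_reps = 8, shift_sigma = 0.8,
                          noise_sigma = 0.05, seed = 1L, gaussian = FALSE) {
  stopifnot(inherits(stack, "cdti_stack"))
  if (noise_sigma < 0) stop("noise_sigma must be non-negative", call. = FALSE)
  withr::local_seed(seed)
  images <- list()
  meta <- list()
  k <- 0
  for (rep_i in seq_len(n_reps)) {
    for (v in seq_len(nrow(stack$meta))) {
      k <- k + 1
      dx <- if (shift_sigma > 0) stats::rnorm(1, 0, shift_sigma) else 0
      dy <- if (shift_sigma > 0) stats::rnorm(1, 0, shift_sigma) else 0
      img <- stack$images[[v]]
      if (dx != 0 || dy != 0) img <- fourier_shift(img, dx, dy)
      img <- add_noise(img, noise_sigma, gaussian)
      images[[k]] <- img
      row <- stack$meta[v, ]
      row$repetition <- rep_i
      row$index <- k
      row$true_shift_x <- dx
      row$true_shift_y <- dy
      meta[[k]] <- row
    }
  }
  new_dwi_stack(images, dplyr::bind_rows(meta), stack$pixel_spacing)
}

#' Simulate a trigger-delay scout series
#'
#' For each trigger delay (TD), generates three orthogonal-direction
#' diffusion-weighted images of the phantom scaled by a signal-dropout
#' profile (1 = no motion dropout), with Rician noise. The default protocol
#' scouts 30 TDs over the cardiac cycle.
#'
#' @param spec a [phantom_spec()] providing geometry and signal level.
#' @param td_list trigger delays (ms); must be non-empty and increasing.
#' @param dropout_profile function TD (ms) -> [0, 1] signal retention.
#' @param noise_sigma Rician channel SD.
#' @param seed RNG seed.
#' @return A `cdti_stack` with `td` metadata, three images per TD.
#' @export
simulate_scout <- function(spec = phantom_spec("diastasis"),
                           td_list = seq(50, 950, length.out = 30),
                           dropout_profile = function(td) rep(1, length(td)),
                           noise_sigma = spec$noise_sigma, seed = 1L) {
  if (length(td_list) == 0) stop("td_list must be non-empty", call. = FALSE)
  drop_vals <- dropout_profile(td_list)
  if (length(drop_vals) == 1) drop_vals <- rep(drop_vals, length(td_list))
  if (length(drop_vals) != length(td_list) || anyNA(drop_vals) ||
      any(drop_vals < 0 | drop_vals > 1)) {
    stop("dropout_profile values must lie in [0, 1]", call. = FALSE)
  }
  dirs <- diag(3)                      # x, y, z
  base_spec <- spec
  base_spec$directions <- dirs
  base <- make_phantom(base_spec)
  dwi_imgs <- base$stack$images[base$stack$meta$b > 0]

  withr::local_seed(seed)
  images <- list(); meta <- list(); k <- 0
  for (i in seq_along(td_list)) {
    for (d in 1:3) {
      k <- k + 1
      img <- add_noise(dwi_imgs[[d]] * drop_vals[i], noise_sigma)
      images[[k]] <- img
      meta[[k]] <- tibble::tibble(
        index = k, b = spec$b, gx = dirs[d, 1], gy = dirs[d, 2],
        gz = dirs[d, 3], repetition = 1L, phase = "scout",
        td = td_list[i]
      )
    }
  }
  new_dwi_stack(images, dplyr::bind_rows(meta), spec$pixel_spacing)
}
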