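# Left-ventricle geometry from endo/epi contours: annular mask, normalized
# transmural depth, local (circumferential, radial, longitudinal) frames,
# and AHA mid-cavity six-segment labels.
#
# Depth convention: 0 at the endocardium, 1 at the epicardium. The
# longitudinal axis is the slice normal pointing base-ward (+z); the
# circumferential axis is chosen so the triad is right-handed
# (l = c x r), which makes endocardial helix angles positive.

AHA_SEGMENTS <- c("anterior", "anteroseptal", "inferoseptal",
                  "inferior", "inferolateral", "anterolateral")

#' Image grid description
#' @param n matrix size (n x n) or length-2 dims.
#' @param spacing pixel spacing (mm).
#' @return A `cdti_grid` list with voxel-centre coordinate matrices (mm,
#'   origin at the image centre).
#' @export
cdti_grid <- function(n, spacing) {
  dims <- if (length(n) == 1) c(n, n) else n[1:2]
  x <- ((seq_len(dims[1]) - 1) + 0.5) * spacing - dims[1] * spacing / 2
  y <- ((seq_len(dims[2]) - 1) + 0.5) * spacing - dims[2] * spacing / 2
  structure(list(dim = dims, spacing = spacing,
                 x = matrix(x, dims[1], dims[2]),
                 y = matrix(y, dims[1], dims[2], byrow = TRUE)),
            class = "cdti_grid")
}

# exact minimum Euclidean distance from points to a closed polygon boundary
polygon_distance <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  x2 <- c(poly_x[-1], poly_x[1]); y2 <- c(poly_y[-1], poly_y[1])
  dmin <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    ex <- x2[i] - poly_x[i]; ey <- y2[i] - poly_y[i]
    len2 <- ex^2 + ey^2
    if (len2 == 0) {
      d2 <- (px - poly_x[i])^2 + (py - poly_y[i])^2
    } else {
      t <- ((px - poly_x[i]) * ex + (py - poly_y[i]) * ey) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (px - (poly_x[i] + t * ex))^2 + (py - (poly_y[i] + t * ey))^2
    }
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

#' Rasterize the myocardial mask from endo/epi contours
#'
#' A voxel belongs to the mask when its centre lies inside the epicardial
#' polygon and outside the endocardial one (even-odd rule).
#'
#' @param contours a `cdti_contours` (see [load_contours()]).
#' @param grid a [cdti_grid()].
#' @return Logical matrix.
#' @export
build_mask <- function(contours, grid) {
  stopifnot(inherits(contours, "cdti_contours"), inherits(grid, "cdti_grid"))
  # containment check: every endo vertex must be inside the epi polygon
  endo_in <- pracma::inpolygon(contours$endo$x_mm, contours$endo$y_mm,
                               contours$epi$x_mm, contours$epi$y_mm)
  if (!all(endo_in)) {
    stop("epicardial contour does not contain the endocardial contour",
         call. = FALSE)
  }
  px <- as.vector(grid$x); py <- as.vector(grid$y)
  in_epi <- pracma::inpolygon(px, py, contours$epi$x_mm, contours$epi$y_mm)
  in_endo <- pracma::inpolygon(px, py, contours$endo$x_mm, contours$endo$y_mm)
  mask <- matrix(in_epi & !in_endo, grid$dim[1], grid$dim[2])
  if (!any(mask)) stop("empty myocardial mask", call. = FALSE)
  mask
}

# continuous normalized depth at arbitrary points (mm)
depth_at <- function(px, py, contours) {
  d_endo <- polygon_distance(px, py, contours$endo$x_mm, contours$endo$y_mm)
  d_epi <- polygon_distance(px, py, contours$epi$x_mm, contours$epi$y_mm)
  d_endo / (d_endo + d_epi)
}

#' Normalized transmural depth map
#'
#' `depth = d_endo / (d_endo + d_epi)` with exact point-to-segment polygon
#' distances: 0 on the endocardial contour, 1 on the epicardial one.
#'
#' @param contours a `cdti_contours`.
#' @param grid a [cdti_grid()].
#' @param mask logical matrix (from [build_mask()]).
#' @return Numeric matrix, `NA` outside the mask.
#' @export
transmural_depth <- function(contours, grid, mask) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  idx <- which(mask)
  depth <- matrix(NA_real_, grid$dim[1], grid$dim[2])
  depth[idx] <- depth_at(grid$x[idx], grid$y[idx], contours)
  depth
}

#' Local cardiac coordinate frames
#'
#' Per voxel: radial axis r = in-plane unit gradient of the transmural
#' depth (pointing outward), longitudinal axis l = slice normal (+z,
#' base-ward), circumferential axis c = r x l, so that the triad (c, r, l)
#' is right-handed with l = c x r. Voxels with a vanishing depth gradient
#' are flagged.
#'
#' @param contours a `cdti_contours`.
#' @param grid a [cdti_grid()].
#' @param mask logical matrix.
#' @param h finite-difference step for the depth gradient (mm).
#' @return A `cdti_frames` list: `frames` (n_voxel x 9; columns c, r, l),
#'   `voxel_index`, `flagged`, `dim`.
#' @export
local_frames <- function(contours, grid, mask, h = 0.05) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  idx <- which(mask)
  px <- grid$x[idx]; py <- grid$y[idx]
  gx <- (depth_at(px + h, py, contours) - depth_at(px - h, py, contours)) / (2 * h)
  gy <- (depth_at(px, py + h, contours) - depth_at(px, py - h, contours)) / (2 * h)
  nrm <- sqrt(gx^2 + gy^2)
  flagged <- nrm < 1e-8
  nrm[flagged] <- 1
  rx <- gx / nrm; ry <- gy / nrm
  # l = (0,0,1); c = r x l = (ry, -rx, 0)
  frames <- cbind(ry, -rx, 0, rx, ry, 0, 0, 0, 1)
  colnames(frames) <- c("cx", "cy", "cz", "rx", "ry", "rz", "lx", "ly", "lz")
  structure(list(frames = frames, voxel_index = idx, flagged = flagged,
                 dim = grid$dim),
            class = "cdti_frames")
}

#' AHA mid-cavity segment labels
#'
#' Six 60-degree angular sectors about the epicardial centroid, ordered
#' anterior, anteroseptal, inferoseptal, inferior, inferolateral,
#' anterolateral going counterclockwise from the anterior reference
#' direction. The anterior sector spans +/- 30 degrees about the reference.
#'
#' @param contours a `cdti_contours`.
#' @param grid a [cdti_grid()].
#' @param mask logical matrix.
#' @param anterior_ref_deg direction of the anterior segment centre,
#'   degrees counterclockwise from the +x image axis. Required; for real
#'   data derive it from the RV insertion points.
#' @return Character matrix of segment labels (`NA` outside the mask).
#' @export
aha_segments <- function(contours, grid, mask, anterior_ref_deg) {
  if (missing(anterior_ref_deg) || is.null(anterior_ref_deg)) {
    stop("anterior reference angle is required", call. = FALSE)
  }
  cx <- mean(contours$epi$x_mm); cy <- mean(contours$epi$y_mm)
  idx <- which(mask)
  ang <- atan2(grid$y[idx] - cy, grid$x[idx] - cx) * 180 / pi
  rel <- (ang - anterior_ref_deg + 30) %% 360
  seg <- AHA_SEGMENTS[pmin(floor(rel / 60) + 1, 6)]
  labels <- matrix(NA_character_, grid$dim[1], grid$dim[2])
  labels[idx] <- seg
  labels
}

#' Full LV geometry bundle
#'
#' Convenience wrapper building mask, depth, frames and segments in one go.
#'
#' @inheritParams aha_segments
#' @return A `cdti_lv_geometry` list: `mask`, `depth`, `frames`, `segments`,
#'   `centroid`, `grid`, `contours`.
#' @export
lv_geometry <- function(contours, grid, anterior_ref_deg = 90) {
  mask <- build_mask(contours, grid)
  depth <- transmural_depth(contours, grid, mask)
  frames <- local_frames(contours, grid, mask)
  segments <- aha_segments(contours, grid, mask, anterior_ref_deg)
  structure(list(
    mask = mask, depth = depth, frames = frames, segments = segments,
    centroid = c(mean(contours$epi$x_mm), mean(contours$epi$y_mm)),
    grid = grid, contours = contours
  ), class = "cdti_lv_geometry")
}
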