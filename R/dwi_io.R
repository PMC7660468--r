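# On-disk formats: NIfTI image stacks with FSL-style .bval/.bvec sidecars,
# CSV contours and result tables, NIfTI scalar maps.
#
# World coordinates are image-plane mm with the origin at the image centre;
# voxel indices are 0-based with voxel centres at (i + 0.5) * spacing.
# bvec directions are in the image coordinate frame (FSL dialect); no
# scanner-frame rotation is attempted.

#' Construct a DWI stack container
#'
#' @param images list of equally-sized 2D matrices.
#' @param meta tibble with one row per image: `index`, `b` (s/mm^2),
#'   `gx`,`gy`,`gz` (unit direction; zeros allowed at b = 0), `repetition`,
#'   `phase`, `td` (ms, `NA` outside scout series).
#' @param pixel_spacing in-plane voxel size (mm).
#' @return A `cdti_stack`.
#' @export
new_dwi_stack <- function(images, meta, pixel_spacing) {
  stopifnot(is.list(images), nrow(meta) == length(images))
  dims <- unique(lapply(images, dim))
  if (length(dims) != 1) stop("all images must share one shape", call. = FALSE)
  if (any(meta$b < 0)) stop("b-values must be non-negative", call. = FALSE)
  nrm <- sqrt(meta$gx^2 + meta$gy^2 + meta$gz^2)
  bad <- which(meta$b > 0 & abs(nrm - 1) > 1e-6)
  if (length(bad) > 0) {
    # normalize, reject true zero vectors at b > 0
    zero <- bad[nrm[bad] < 1e-12]
    if (length(zero) > 0) {
      stop("zero direction vector at b > 0 for image index ", zero[1],
           call. = FALSE)
    }
    meta$gx[bad] <- meta$gx[bad] / nrm[bad]
    meta$gy[bad] <- meta$gy[bad] / nrm[bad]
    meta$gz[bad] <- meta$gz[bad] / nrm[bad]
  }
  structure(list(images = images, meta = meta, pixel_spacing = pixel_spacing),
            class = "cdti_stack")
}

#' @export
print.cdti_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat("<cdti_stack> ", length(x$images), " images of ", d[1], "x", d[2],
      " @ ", x$pixel_spacing, " mm\n", sep = "")
  print(dplyr::count(x$meta, .data$b, .data$phase))
  invisible(x)
}

stack_to_array <- function(stack) {
  d <- dim(stack$images[[1]])
  arr <- array(0, c(d[1], d[2], 1, length(stack$images)))
  for (i in seq_along(stack$images)) arr[, , 1, i] <- stack$images[[i]]
  arr
}

#' Write a DWI stack as NIfTI + bval/bvec sidecars
#'
#' @param stack a `cdti_stack`.
#' @param prefix path prefix; writes `<prefix>.nii.gz`, `<prefix>.bval`,
#'   `<prefix>.bvec` and `<prefix>_meta.csv` (repetition/phase/TD labels).
#' @return The prefix, invisibly.
#' @export
write_dwi <- function(stack, prefix) {
  stopifnot(inherits(stack, "cdti_stack"))
  arr <- stack_to_array(stack)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(stack$pixel_spacing, stack$pixel_spacing, 1, 1)
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  writeLines(paste(stack$meta$b, collapse = " "), paste0(prefix, ".bval"))
  bv <- rbind(stack$meta$gx, stack$meta$gy, stack$meta$gz)
  writeLines(apply(bv, 1, paste, collapse = " "), paste0(prefix, ".bvec"))
  readr::write_csv(stack$meta, paste0(prefix, "_meta.csv"))
  invisible(prefix)
}

#' Load a DWI stack from NIfTI + bval/bvec sidecars
#'
#' Validates that sidecar entry counts match the volume count, normalizes
#' directions, and accepts zero vectors at b = 0 (stored as undefined).
#'
#' @param nifti_path NIfTI file (volumes along the 4th dimension).
#' @param bval_path,bvec_path FSL-style sidecars.
#' @param meta_path optional metadata CSV written by [write_dwi()].
#' @return A `cdti_stack`.
#' @export
load_dwi <- function(nifti_path, bval_path, bvec_path, meta_path = NULL) {
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr)[1:2], 1, dim(arr)[3])
  if (length(dim(arr)) != 4) stop("expected a 4D NIfTI volume", call. = FALSE)
  nvol <- dim(arr)[4]
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_lines <- readLines(bvec_path)
  bvec <- do.call(rbind, lapply(bvec_lines[nzchar(bvec_lines)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  if (length(bvals) != nvol) {
    stop(sprintf("sidecar mismatch: %d b-values for %d volumes (first bad index %d)",
                 length(bvals), nvol, min(length(bvals), nvol) + 1), call. = FALSE)
  }
  if (nrow(bvec) != 3 || ncol(bvec) != nvol) {
    stop(sprintf("sidecar mismatch: bvec is %dx%d, expected 3x%d",
                 nrow(bvec), ncol(bvec), nvol), call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[1]
  images <- lapply(seq_len(nvol), function(v) arr[, , 1, v])
  if (!is.null(meta_path)) {
    meta <- readr::read_csv(meta_path, show_col_types = FALSE)
    if (nrow(meta) != nvol) {
      stop("metadata row count does not match volume count", call. = FALSE)
    }
  } else {
    meta <- tibble::tibble(
      index = seq_len(nvol), b = bvals,
      gx = bvec[1, ], gy = bvec[2, ], gz = bvec[3, ],
      repetition = 1L, phase = "unknown", td = NA_real_
    )
  }
  meta$b <- bvals
  meta$gx <- bvec[1, ]; meta$gy <- bvec[2, ]; meta$gz <- bvec[3, ]
  new_dwi_stack(images, meta, spacing)
}

#' Save named scalar maps as NIfTI files
#'
#' @param maps named list of equally-shaped matrices.
#' @param prefix path prefix; each map goes to `<prefix>_<name>.nii.gz`.
#' @param pixel_spacing voxel size (mm).
#' @return Named character vector of written paths, invisibly. Warns and
#'   writes nothing for an empty map set.
#' @export
save_maps <- function(maps, prefix, pixel_spacing = 1) {
  if (length(maps) == 0) {
    warning("no maps to save")
    return(invisible(character(0)))
  }
  dims <- unique(lapply(maps, dim))
  if (length(dims) != 1) stop("maps must share one shape", call. = FALSE)
  paths <- character(length(maps))
  for (i in seq_along(maps)) {
    p <- paste0(prefix, "_", names(maps)[i], ".nii.gz")
    img <- RNifti::asNifti(maps[[i]])
    RNifti::pixdim(img) <- rep(pixel_spacing, 2)
    RNifti::writeNifti(img, p)
    paths[i] <- p
  }
  names(paths) <- names(maps)
  invisible(paths)
}

#' Load a scalar map written by [save_maps()]
#' @param path NIfTI file.
#' @return Matrix.
#' @export
load_map <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) > 2) dim(arr) <- dim(arr)[1:2]
  arr
}

polygon_signed_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_self_intersects <- function(x, y) {
  n <- length(x)
  pts <- cbind(x, y)
  nxt <- c(seq_len(n)[-1], 1)
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):n) {
      # skip shared-endpoint neighbours
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_intersect(pts[i, ], pts[nxt[i], ], pts[j, ], pts[nxt[j], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Load endo/epi contours from CSV
#'
#' Expects columns `x_mm`, `y_mm`, `surface` (values `endo`/`epi`). Each
#' surface polygon is validated (at least 3 points, no self-intersection)
#' and re-oriented counterclockwise.
#'
#' @param path CSV file, or a data frame in the same layout.
#' @return A `cdti_contours` list with tibbles `endo` and `epi`.
#' @export
#' @examples
#' ct <- load_contours(system.file("extdata", "example_contours_synthetic.csv",
#'                                 package = "cardiodti"))
#' nrow(ct$endo)
load_contours <- function(path) {
  df <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  req <- c("x_mm", "y_mm", "surface")
  if (!all(req %in% names(df))) {
    stop("contours need columns x_mm, y_mm, surface", call. = FALSE)
  }
  out <- list()
  for (s in c("endo", "epi")) {
    poly <- df[df$surface == s, c("x_mm", "y_mm")]
    if (nrow(poly) < 3) {
      stop("surface '", s, "' needs at least 3 points", call. = FALSE)
    }
    if (polygon_self_intersects(poly$x_mm, poly$y_mm)) {
      stop("surface '", s, "' polygon self-intersects", call. = FALSE)
    }
    if (polygon_signed_area(poly$x_mm, poly$y_mm) < 0) {
      poly <- poly[rev(seq_len(nrow(poly))), ]
    }
    out[[s]] <- tibble::as_tibble(poly)
  }
  structure(out, class = "cdti_contours")
}

#' Write contours to CSV
#' @param contours a `cdti_contours` or a data frame with
#'   `x_mm`, `y_mm`, `surface`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  df <- if (inherits(contours, "cdti_contours")) {
    dplyr::bind_rows(
      dplyr::mutate(contours$endo, surface = "endo"),
      dplyr::mutate(contours$epi, surface = "epi")
    )
  } else {
    contours
  }
  readr::write_csv(df, path)
  invisible(path)
}
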