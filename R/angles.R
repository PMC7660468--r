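# Microstructure angle maps and transmural statistics: helix angle (HA),
# transverse angle (TA), sheetlet angle (E2A), the linear-model 180-degree
# unwrap filter, nine-node transmural profiles, helix angle range (HAR)
# and its change between phases (delta HAR).

reduce_axial <- function(a) {
  # axial angle in (-90, 90]
  a <- ((a + 90) %% 180) - 90
  ifelse(a == -90, 90, a)
}

frame_dots <- function(E, frames) {
  list(
    c = E[, 1] * frames[, "cx"] + E[, 2] * frames[, "cy"] + E[, 3] * frames[, "cz"],
    r = E[, 1] * frames[, "rx"] + E[, 2] * frames[, "ry"] + E[, 3] * frames[, "rz"],
    l = E[, 1] * frames[, "lx"] + E[, 2] * frames[, "ly"] + E[, 3] * frames[, "lz"]
  )
}

#' Helix angle map
#'
#' Projects the primary eigenvector onto the local wall-tangent plane
#' (circumferential-longitudinal) and measures the signed angle from the
#' circumferential axis toward the longitudinal one, reduced to (-90, 90]
#' (E1 and -E1 are equivalent). Voxels whose projection norm is below
#' `tol` (fiber pointing radially) are flagged `NA`.
#'
#' @param e1 n x 3 matrix of primary eigenvectors (rows aligned with
#'   `frames$voxel_index`).
#' @param frames a `cdti_frames` object from [local_frames()].
#' @param tol minimum tangent-plane projection norm.
#' @return Numeric vector of HA in degrees (NA where flagged).
#' @export
helix_angle <- function(e1, frames, tol = 1e-6) {
  d <- frame_dots(e1, frames$frames)
  ha <- reduce_axial(atan2(d$l, d$c) * 180 / pi)
  ha[sqrt(d$c^2 + d$l^2) < tol | frames$flagged] <- NA_real_
  unname(ha)
}

#' Transverse angle map
#'
#' Signed angle of the primary eigenvector's projection onto the
#' circumferential-radial ("horizontal") plane, from the circumferential
#' axis toward the outward radial axis, reduced to (-90, 90].
#'
#' @inheritParams helix_angle
#' @return Numeric vector of TA in degrees.
#' @export
transverse_angle <- function(e1, frames, tol = 1e-6) {
  d <- frame_dots(e1, frames$frames)
  ta <- reduce_axial(atan2(d$r, d$c) * 180 / pi)
  ta[sqrt(d$c^2 + d$r^2) < tol | frames$flagged] <- NA_real_
  unname(ta)
}

#' Sheetlet angle (E2A) map
#'
#' The cross-myocyte plane is the plane normal to the tangent-plane
#' projection of E1; E2 is projected into it and E2A is the absolute angle
#' between that projection and the plane's wall-tangent direction:
#' 0 = sheetlet lying in the wall, 90 = sheetlet radial. Reported in
#' [0, 90] and invariant to sign flips of E1 and E2.
#'
#' @param e1,e2 n x 3 matrices of the first two eigenvectors.
#' @inheritParams helix_angle
#' @return Numeric vector of E2A in degrees.
#' @export
e2_angle <- function(e1, e2, frames, tol = 1e-6) {
  f <- frames$frames
  d1 <- frame_dots(e1, f)
  pn <- sqrt(d1$c^2 + d1$l^2)
  # wall-tangent axis s = cross(r, p_hat) expressed in frame coordinates:
  # p_hat = (pc, 0, pl) in (c, r, l); r = (0,1,0); s = r x p_hat = (pl, 0, -pc)
  pc <- d1$c / pn; pl <- d1$l / pn
  d2 <- frame_dots(e2, f)
  comp_s <- d2$c * pl - d2$l * pc
  comp_r <- d2$r
  e2a <- atan2(abs(comp_r), abs(comp_s)) * 180 / pi
  e2a[pn < tol | sqrt(comp_r^2 + comp_s^2) < tol | frames$flagged] <- NA_real_
  unname(e2a)
}

#' Unwrap helix-angle projection errors against a linear transmural model
#'
#' Fits `HA = a * depth + b` by least squares, classifies points with
#' absolute residual above one SD of the residuals as outliers, and shifts
#' by 180 degrees those outliers that are negative on the endocardial half
#' (depth < 0.5) or positive on the epicardial half (depth >= 0.5). Single
#' pass; values may leave (-90, 90] after unwrapping.
#'
#' @param ha helix angles (degrees).
#' @param depth normalized transmural depths aligned with `ha`.
#' @param min_points minimum number of finite samples for a fit.
#' @return Corrected helix angles (degrees).
#' @export
unwrap_ha <- function(ha, depth, min_points = 10) {
  ok <- is.finite(ha) & is.finite(depth)
  if (sum(ok) < min_points) {
    warning("too few samples to fit the unwrap model; returning input")
    return(ha)
  }
  if (stats::sd(depth[ok]) < 1e-12) {
    warning("degenerate unwrap fit (constant depth); returning input")
    return(ha)
  }
  fit <- stats::lm.fit(cbind(1, depth[ok]), ha[ok])
  pred <- rep(NA_real_, length(ha))
  pred[ok] <- fit$fitted.values
  res <- ha - pred
  s <- stats::sd(res[ok])
  out <- ok & abs(res) > s
  flip_up <- out & ha < 0 & depth < 0.5    # endo-to-mid negatives: +180
  flip_dn <- out & ha > 0 & depth >= 0.5   # mid-to-epi positives: -180
  ha[flip_up] <- ha[flip_up] + 180
  ha[flip_dn] <- ha[flip_dn] - 180
  ha
}

#' Nine-node transmural helix-angle profile
#'
#' Assigns every voxel to the nearest of `n_nodes` equally spaced depth
#' nodes in [0, 1] and reports the per-node median of the (unwrapped)
#' helix angle, per AHA segment and globally.
#'
#' @param ha helix angles (degrees), one per masked voxel.
#' @param depth normalized depths aligned with `ha`.
#' @param segments optional segment labels aligned with `ha`; when given,
#'   per-segment profiles are reported alongside the global one.
#' @param n_nodes number of profile nodes (default 9).
#' @param unwrap apply [unwrap_ha()] before profiling (per segment when
#'   segments are given, and globally for the global profile).
#' @param detrend evaluate each node median at the node depth by removing
#'   the fitted linear transmural slope within the bin
#'   (`median(ha - a * (depth - node_depth))`). Interior bins are symmetric
#'   about their node, so this leaves them essentially unchanged; the two
#'   boundary bins are one-sided, and the plain median there reports the
#'   helix angle of the bin interior rather than of the endo/epi surface,
#'   biasing HAR low by about `slope / 16`. Set `FALSE` for the plain
#'   within-bin median.
#' @return Tibble with `segment` (`"global"` plus any segment labels),
#'   `node`, `node_depth`, `median_ha`, `n`. Empty nodes are reported with
#'   `n = 0` and `NA` median.
#' @export
transmural_profile <- function(ha, depth, segments = NULL, n_nodes = 9,
                               unwrap = TRUE, detrend = TRUE) {
  nodes <- seq(0, 1, length.out = n_nodes)
  profile_one <- function(ha_v, depth_v, label) {
    ok <- is.finite(ha_v) & is.finite(depth_v)
    if (unwrap && sum(ok) >= 10) ha_v <- unwrap_ha(ha_v, depth_v)
    node_id <- rep(NA_integer_, length(depth_v))
    node_id[ok] <- vapply(depth_v[ok],
                          function(d) which.min(abs(nodes - d)), integer(1))
    ok <- ok & is.finite(ha_v)
    slope <- 0
    if (detrend && sum(ok) >= 3 && stats::sd(depth_v[ok]) > 1e-12) {
      slope <- stats::lm.fit(cbind(1, depth_v[ok]), ha_v[ok])$coefficients[2]
    }
    purrr::map_dfr(seq_len(n_nodes), function(j) {
      sel <- ok & node_id == j
      tibble::tibble(
        segment = label, node = j, node_depth = nodes[j],
        median_ha = if (any(sel)) {
          stats::median(ha_v[sel] - slope * (depth_v[sel] - nodes[j]))
        } else NA_real_,
        n = sum(sel)
      )
    })
  }
  out <- profile_one(ha, depth, "global")
  if (!is.null(segments)) {
    for (s in unique(stats::na.omit(segments))) {
      sel <- !is.na(segments) & segments == s
      out <- dplyr::bind_rows(out, profile_one(ha[sel], depth[sel], s))
    }
  }
  class(out) <- c("cdti_profile", class(out))
  out
}

#' Helix angle range from a transmural profile
#'
#' HAR = median HA at the endocardial node minus median HA at the
#' epicardial node, per segment.
#'
#' @param profile a tibble from [transmural_profile()].
#' @return Tibble with `segment` and `har` (degrees; `NA` with a warning if
#'   a boundary node is empty).
#' @export
har <- function(profile) {
  out <- profile |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(
      har = .data$median_ha[which.min(.data$node)] -
        .data$median_ha[which.max(.data$node)],
      .groups = "drop"
    )
  if (any(!is.finite(out$har))) {
    warning("HAR undefined for segments with an empty boundary node")
  }
  out
}

#' Change in helix angle range between two phases
#'
#' `delta HAR(a -> b) = HAR(b) - HAR(a)`, computed per subject before any
#' group summary.
#'
#' @param har_a,har_b HAR values (degrees) at the two phases.
#' @return Numeric vector of differences.
#' @export
delta_har <- function(har_a, har_b) har_b - har_a
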