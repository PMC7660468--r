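# Motion-compensated diffusion encoding waveforms: trapezoid lobe trains,
# analytic gradient moments, and b-value.
#
# Internal units are ms and mT/m throughout; conversions to s-based units
# happen only in reporting helpers. Time zero is the excitation pulse centre,
# so M1/M2 carry their usual velocity/acceleration-compensation meaning.

#' Proton gyromagnetic ratio (rad/s/T)
#' @keywords internal
GAMMA_PROTON <- 2.6752218744e8

#' Sequence timing set for the spin-echo diffusion module
#'
#' Durations of the sequence blocks that surround the diffusion encoding
#' lobes, in ms. The defaults reproduce the published protocol: excitation
#' 2 ms, refocusing 4 ms, pre/post encoding windows 24/20 ms, navigator
#' interval 8 ms, EPI echo offset 9 ms, TE 61 ms, and a residual dead time
#' of 4 ms left over by the symmetric waveform optimization.
#'
#' @param d90,d180 excitation / refocusing pulse durations (ms).
#' @param Ta,Tb nominal encoding windows before/after refocusing (ms).
#' @param Tnav navigator echo interval (ms).
#' @param Tepi_echo time from EPI readout start to the echo centre (ms).
#' @param TE nominal echo time (ms).
#' @param dead_time residual encoding-free dead time (ms).
#' @return A `cdti_timings` list.
#' @export
cdti_timings <- function(d90 = 2, d180 = 4, Ta = 24, Tb = 20, Tnav = 8,
                         Tepi_echo = 9, TE = 61, dead_time = 4) {
  vals <- c(d90 = d90, d180 = d180, Ta = Ta, Tb = Tb, Tnav = Tnav,
            Tepi_echo = Tepi_echo, TE = TE, dead_time = dead_time)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all sequence timings must be finite and non-negative", call. = FALSE)
  }
  structure(as.list(vals), class = "cdti_timings")
}

new_lobe <- function(amplitude, flat_top, ramp, start_time) {
  if (ramp <= 0) stop("lobe ramp time must be positive", call. = FALSE)
  if (flat_top < 0) stop("lobe flat top must be non-negative", call. = FALSE)
  tibble::tibble(
    amplitude = amplitude, flat_top = flat_top, ramp = ramp,
    start_time = start_time, duration = flat_top + 2 * ramp
  )
}

#' Build the symmetric motion-compensated encoding waveform
#'
#' Places two trapezoidal lobe pairs symmetrically around the refocusing
#' pulse: lobes 1-2 are packed after the excitation pulse, then an
#' encoding-free interval (navigator + refocusing pulse + dead time)
#' separates them from lobes 3-4. Physical polarities are (+,-,-,+) so
#' that, after the refocusing inversion, the effective polarity pattern is
#' (+,-,+,-) and the effective zeroth moment vanishes exactly for matched
#' pre/post duration pairs.
#'
#' @param timings a [cdti_timings()] set.
#' @param lobe_durations total durations (flat top + both ramps) of the four
#'   lobes (ms). Default is the published 7.2/12.6/12.6/7.2 design.
#' @param ramp ramp time shared by all lobes (ms).
#' @param amplitude gradient amplitude G (mT/m).
#' @return A `cdti_waveform` object: lobes (with physical and effective
#'   signs), timings, refocusing centre, and echo time.
#' @export
#' @examples
#' w <- build_symmetric_waveform(amplitude = 71.3)
#' moments(w, 0)
#' b_value(w)
build_symmetric_waveform <- function(timings = cdti_timings(),
                                     lobe_durations = c(7.2, 12.6, 12.6, 7.2),
                                     ramp = 1.52,
                                     amplitude = 1) {
  stopifnot(length(lobe_durations) == 4)
  if (any(lobe_durations <= 0)) stop("lobe durations must be positive", call. = FALSE)
  if (any(lobe_durations < 2 * ramp)) {
    stop("lobe duration shorter than twice the ramp time", call. = FALSE)
  }

  if (lobe_durations[1] + lobe_durations[2] > timings$Ta + timings$dead_time ||
      lobe_durations[3] + lobe_durations[4] > timings$Tb + timings$dead_time) {
    stop("timing infeasible: encoding lobes exceed the pre/post refocusing ",
         "windows", call. = FALSE)
  }
  t0 <- timings$d90 / 2                      # end of excitation pulse
  s1 <- t0
  s2 <- s1 + lobe_durations[1]
  # encoding-free interval between the pairs: navigator + 180 + dead time
  gap <- timings$Tnav + timings$d180 + timings$dead_time
  t180_start <- s2 + lobe_durations[2] + timings$Tnav
  t180_end <- t180_start + timings$d180
  refocus_center <- t180_start + timings$d180 / 2
  s3 <- s2 + lobe_durations[2] + gap
  s4 <- s3 + lobe_durations[3]
  echo_time <- 2 * refocus_center

  signs_phys <- c(1, -1, -1, 1)
  lobes <- purrr::pmap_dfr(
    list(amplitude * signs_phys, lobe_durations, c(s1, s2, s3, s4)),
    function(a, d, s) new_lobe(a, d - 2 * ramp, ramp, s)
  )
  lobes$effective_sign <- c(1, -1, 1, -1)

  w <- structure(
    list(lobes = lobes, timings = timings, refocus_center = refocus_center,
         echo_time = echo_time, amplitude = amplitude),
    class = "cdti_waveform"
  )
  # lobes must not overlap the refocusing pulse window
  pre_end <- s2 + lobe_durations[2]
  if (pre_end > t180_start + 1e-9 || s3 < t180_end - 1e-9) {
    stop("timing infeasible: encoding lobes overlap the refocusing pulse window",
         call. = FALSE)
  }
  if (echo_time < s4 + lobe_durations[4] - 1e-9) {
    stop("timing infeasible: echo forms before the encoding ends", call. = FALSE)
  }
  w
}

#' Build a waveform from an explicit lobe table
#'
#' Lower-level constructor used for bipolar/monopolar reference waveforms and
#' tests. `effective_sign` gives the lobe polarity after accounting for the
#' refocusing inversion.
#'
#' @param amplitudes,durations,starts per-lobe physical amplitude (mT/m),
#'   total duration and start time (ms).
#' @param ramp shared ramp time (ms).
#' @param effective_signs +1/-1 per lobe; defaults to `sign(amplitudes)`.
#' @param echo_time echo time (ms); defaults to the end of the last lobe.
#' @return A `cdti_waveform`.
#' @export
waveform_from_lobes <- function(amplitudes, durations, starts, ramp,
                                effective_signs = sign(amplitudes),
                                echo_time = NULL) {
  stopifnot(length(amplitudes) == length(durations),
            length(durations) == length(starts))
  lobes <- purrr::pmap_dfr(
    list(amplitudes, durations, starts),
    function(a, d, s) new_lobe(a, d - 2 * ramp, ramp, s)
  )
  lobes$effective_sign <- effective_signs
  ends <- starts + durations
  if (is.null(echo_time)) echo_time <- max(ends)
  structure(
    list(lobes = lobes, timings = NULL, refocus_center = NA_real_,
         echo_time = echo_time, amplitude = max(abs(amplitudes))),
    class = "cdti_waveform"
  )
}

# Piecewise-linear segments of the *effective* gradient (sign convention:
# post-refocusing lobes inverted). Returns tibble with t0, t1, g0, g1.
effective_segments <- function(w) {
  segs <- purrr::pmap_dfr(w$lobes, function(amplitude, flat_top, ramp,
                                            start_time, duration,
                                            effective_sign, ...) {
    a <- abs(amplitude) * effective_sign
    t <- start_time + c(0, ramp, ramp + flat_top, duration)
    tibble::tibble(
      t0 = t[1:3], t1 = t[2:4],
      g0 = c(0, a, a), g1 = c(a, a, 0)
    )
  })
  segs[segs$t1 > segs$t0, ]
}

# integral of (g0 + slope*(t-t0)) * t^k over [t0, t1], exact
segment_moment <- function(t0, t1, g0, g1, k) {
  slope <- (g1 - g0) / (t1 - t0)
  c0 <- g0 - slope * t0                       # g(t) = c0 + slope * t
  c0 * (t1^(k + 1) - t0^(k + 1)) / (k + 1) +
    slope * (t1^(k + 2) - t0^(k + 2)) / (k + 2)
}

#' Gradient moments of an encoding waveform
#'
#' Analytic time moments `M_k = integral G_eff(t) t^k dt` of the effective
#' gradient, evaluated exactly per trapezoid segment. The reference time is
#' the excitation pulse centre (t = 0).
#'
#' @param w a `cdti_waveform`.
#' @param order moment order, 0, 1 or 2.
#' @return Moment in mT/m·ms^(order+1).
#' @export
moments <- function(w, order) {
  stopifnot(inherits(w, "cdti_waveform"))
  if (!order %in% 0:2) stop("unsupported moment order: ", order, call. = FALSE)
  if (order == 0) {
    # signed trapezoid areas: matched pre/post pairs cancel exactly
    l <- w$lobes
    return(sum(abs(l$amplitude) * l$effective_sign * (l$flat_top + l$ramp)))
  }
  segs <- effective_segments(w)
  sum(segment_moment(segs$t0, segs$t1, segs$g0, segs$g1, order))
}

# polynomial helpers: coefficients in increasing powers of the local time s
poly_mul <- function(p, q) {
  r <- numeric(length(p) + length(q) - 1)
  for (i in seq_along(p)) r[i:(i + length(q) - 1)] <- r[i:(i + length(q) - 1)] + p[i] * q
  r
}
poly_int_0_to <- function(p, s) sum(p * s^(seq_along(p)) / seq_along(p))

#' Diffusion weighting (b-value) of an encoding waveform
#'
#' `b = gamma^2 * integral q(t)^2 dt` with `q(t) = integral_0^t G_eff`,
#' integrated analytically: the effective gradient is piecewise linear, so q
#' is piecewise quadratic and q^2 piecewise quartic. Integration runs from
#' t = 0 to the echo time. Warns if the zeroth moment is not nulled at the
#' echo (mis-set echo time).
#'
#' @param w a `cdti_waveform`.
#' @return b-value in s/mm^2.
#' @export
b_value <- function(w) {
  stopifnot(inherits(w, "cdti_waveform"))
  segs <- effective_segments(w)
  # merge in the zero-gradient gaps and order segments over [0, echo]
  segs <- segs[order(segs$t0), ]
  breaks <- sort(unique(c(0, segs$t0, segs$t1, w$echo_time)))
  breaks <- breaks[breaks <= w$echo_time + 1e-12]
  q0 <- 0
  acc <- 0
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    mid <- (t0 + t1) / 2
    row <- segs[segs$t0 <= mid & segs$t1 >= mid, ]
    if (nrow(row) == 0) {
      g0 <- 0; slope <- 0
    } else {
      slope <- (row$g1[1] - row$g0[1]) / (row$t1[1] - row$t0[1])
      g0 <- row$g0[1] + slope * (t0 - row$t0[1])
    }
    # q(s) = q0 + g0 s + slope s^2/2 on s in [0, t1-t0]
    qp <- c(q0, g0, slope / 2)
    acc <- acc + poly_int_0_to(poly_mul(qp, qp), t1 - t0)
    q0 <- q0 + g0 * (t1 - t0) + slope * (t1 - t0)^2 / 2
  }
  if (abs(q0) > 1e-6 * max(abs(w$lobes$amplitude)) * 1) {
    warning("zeroth moment not nulled at the echo; b-value may be mis-set")
  }
  # mT/m·ms -> T·s/m is 1e-6; dt ms -> s is 1e-3; s/m^2 -> s/mm^2 is 1e-6
  GAMMA_PROTON^2 * acc * 1e-21
}

#' Solve the gradient amplitude for a target b-value
#'
#' The b-value scales exactly as G^2, so the amplitude follows from a single
#' unit-amplitude evaluation: `G = sqrt(target_b / b(G = 1))`.
#'
#' @inheritParams build_symmetric_waveform
#' @param target_b target diffusion weighting (s/mm^2), > 0.
#' @return Amplitude G in mT/m.
#' @export
#' @examples
#' solve_amplitude_for_b(target_b = 350)
solve_amplitude_for_b <- function(timings = cdti_timings(),
                                  lobe_durations = c(7.2, 12.6, 12.6, 7.2),
                                  ramp = 1.52, target_b = 350) {
  if (target_b <= 0) stop("target_b must be positive", call. = FALSE)
  b1 <- b_value(build_symmetric_waveform(timings, lobe_durations, ramp,
                                         amplitude = 1))
  if (!is.finite(b1) || b1 <= 0) {
    stop("infeasible waveform geometry: zero diffusion weighting", call. = FALSE)
  }
  sqrt(target_b / b1)
}

#' Sample the effective gradient on a regular time grid
#'
#' Used for plotting and as the numeric cross-check of the analytic moment
#' and b-value integrals.
#'
#' @param w a `cdti_waveform`.
#' @param dt sampling interval (ms).
#' @return Tibble with columns `t` (ms) and `g` (mT/m, effective polarity).
#' @export
gradient_samples <- function(w, dt = 1e-3) {
  t <- seq(0, w$echo_time, by = dt)
  segs <- effective_segments(w)
  g <- numeric(length(t))
  for (i in seq_len(nrow(segs))) {
    idx <- t >= segs$t0[i] & t <= segs$t1[i]
    slope <- (segs$g1[i] - segs$g0[i]) / (segs$t1[i] - segs$t0[i])
    g[idx] <- segs$g0[i] + slope * (t[idx] - segs$t0[i])
  }
  tibble::tibble(t = t, g = g)
}

#' One-row summary of a waveform: moments, b-value, amplitude
#'
#' Moments are reported both in internal ms units and in the s-based units
#' used on sequence printouts.
#'
#' @param w a `cdti_waveform`.
#' @return A one-row tibble.
#' @export
waveform_report <- function(w) {
  m0 <- moments(w, 0); m1 <- moments(w, 1); m2 <- moments(w, 2)
  tibble::tibble(
    amplitude_mT_per_m = w$amplitude,
    b_s_per_mm2 = b_value(w),
    M0_mT_per_m_ms = m0, M1_mT_per_m_ms2 = m1, M2_mT_per_m_ms3 = m2,
    M0_mT_per_m_s = m0 * 1e-3, M1_mT_per_m_s2 = m1 * 1e-6,
    M2_mT_per_m_s3 = m2 * 1e-9,
    TE_ms = w$echo_time
  )
}
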