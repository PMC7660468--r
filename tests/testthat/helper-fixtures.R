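# shared fixture builders (all generated in code)

# single-voxel frames object from a 3x3 frame matrix (columns c, r, l)
frames_from_matrix <- function(fr, n = 1) {
  m <- matrix(rep(as.vector(fr), each = n), n, 9)
  colnames(m) <- c("cx", "cy", "cz", "rx", "ry", "rz", "lx", "ly", "lz")
  structure(list(frames = m, voxel_index = seq_len(n), flagged = rep(FALSE, n),
                 dim = c(n, 1)), class = "cdti_frames")
}

# random right-handed orthonormal frame
random_frame <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

circle_contours_df <- function(r_endo = 20, r_epi = 32, n_points = 72) {
  phi <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  rbind(
    data.frame(x_mm = r_endo * cos(phi), y_mm = r_endo * sin(phi), surface = "endo"),
    data.frame(x_mm = r_epi * cos(phi), y_mm = r_epi * sin(phi), surface = "epi")
  )
}

# small noiseless phantom stack for I/O and preproc tests
tiny_phantom <- function(phase = "late_systole", n = 32, spacing = 3,
                         noise = 0, ...) {
  make_phantom(phantom_spec(phase, n = n, pixel_spacing = spacing,
                            endo_radius = 14, epi_radius = 14 + 6 * spacing / 1.6,
                            noise_sigma = noise, ...))
}
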