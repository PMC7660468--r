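# Angle operators, the unwrap filter, transmural profiles and HAR.

test_that("helix and transverse angles hit the frame axes", {
  fr <- frames_from_matrix(diag(3))        # c = x, r = y, l = z
  expect_equal(helix_angle(matrix(c(1, 0, 0), 1), fr), 0)
  expect_equal(helix_angle(matrix(c(0, 0, 1), 1), fr), 90)
  expect_true(is.na(helix_angle(matrix(c(0, 1, 0), 1), fr)))  # radial fiber
  expect_equal(transverse_angle(matrix(c(1, 0, 0), 1), fr), 0)
  expect_equal(transverse_angle(matrix(c(0, 1, 0), 1), fr), 90)
  # fiber in the tangent plane has TA = 0 whatever its helix angle
  e1 <- matrix(c(cos(pi / 3), 0, sin(pi / 3)), 1)
  expect_equal(transverse_angle(e1, fr), 0)
  expect_equal(helix_angle(e1, fr), 60, tolerance = 1e-10)
})

test_that("sheetlet angle separates in-wall from radial E2", {
  fr <- frames_from_matrix(diag(3))
  e1 <- matrix(c(1, 0, 0), 1)
  expect_equal(e2_angle(e1, matrix(c(0, 1, 0), 1), fr), 90)   # radial sheetlet
  expect_equal(e2_angle(e1, matrix(c(0, 0, 1), 1), fr), 0)    # in-wall sheetlet
})

test_that("angle maps are invariant to eigenvector sign flips", {
  withr::local_seed(21)
  for (i in 1:20) {
    fr <- random_frame()
    tf <- tensor_from_angles(stats::runif(1, -80, 80), stats::runif(1, -25, 25),
                             stats::runif(1, 5, 85), c(2.5, 1.6, 1.1) * 1e-3, fr)
    frames <- frames_from_matrix(fr)
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      expect_equal(helix_angle(matrix(s1 * tf$E1, 1), frames),
                   helix_angle(matrix(tf$E1, 1), frames), tolerance = 1e-10)
      expect_equal(e2_angle(matrix(s1 * tf$E1, 1), matrix(s2 * tf$E2, 1), frames),
                   e2_angle(matrix(tf$E1, 1), matrix(tf$E2, 1), frames),
                   tolerance = 1e-10)
    }
  }
})

test_that("unwrap applies the one-SD linear-model rule to the stated regions", {
  # a clean linear profile passes through unchanged
  depth <- seq(0, 1, length.out = 60)
  ha <- 60 - 120 * depth
  expect_equal(unwrap_ha(ha, depth), ha)
  # endocardial wrap: fit predicts +85, observation -88 -> corrected to +92
  d2 <- c(depth, 0.05)
  ha2 <- c(93.5 - 170 * depth, -88)
  out <- unwrap_ha(ha2, d2)
  expect_equal(out[61], 92)
  expect_equal(out[1:60], ha2[1:60])
  # epicardial-side negative outlier is NOT flipped (rule is one-sided)
  d3 <- c(depth, 0.7)
  ha3 <- c(93.5 - 170 * depth, -70)       # fit predicts about -25.5 at 0.7
  out3 <- unwrap_ha(ha3, d3)
  expect_equal(out3[61], -70)
  # positive epicardial outlier IS flipped down
  d4 <- c(depth, 0.9)
  ha4 <- c(93.5 - 170 * depth, +80)
  expect_equal(unwrap_ha(ha4, d4)[61], 80 - 180)
})

test_that("unwrap is idempotent on wrapped noisy profiles", {
  withr::local_seed(22)
  for (i in 1:15) {
    n <- 120
    depth <- stats::runif(n)
    ha <- 55 - 100 * depth + stats::rnorm(n, 0, 8)
    wrapped <- ha
    # wrap a handful of extreme samples into the opposite sign, as the
    # (-90, 90] projection does near the boundaries
    idx <- which(ha > 85 | ha < -85)
    wrapped[idx] <- wrapped[idx] - sign(wrapped[idx]) * 180
    once <- unwrap_ha(wrapped, depth)
    twice <- unwrap_ha(once, depth)
    expect_identical(twice, once)
  }
})

test_that("unwrap degenerate inputs warn and return the input", {
  expect_warning(out <- unwrap_ha(c(1, 2, 3), c(0.1, 0.2, 0.3)), "too few")
  expect_equal(out, c(1, 2, 3))
  ha <- stats::rnorm(20)
  expect_warning(out2 <- unwrap_ha(ha, rep(0.5, 20)), "degenerate")
  expect_equal(out2, ha)
})

test_that("transmural profiles sample the linear law at nine nodes", {
  withr::local_seed(23)
  n <- 4000
  depth <- stats::runif(n)
  ha <- 60 - 120 * depth
  prof <- transmural_profile(ha, depth, unwrap = FALSE)
  expect_equal(nrow(prof), 9)
  expect_equal(prof$node_depth, seq(0, 1, 0.125))
  expect_lt(max(abs(prof$median_ha - (60 - 120 * prof$node_depth))), 2)
  expect_equal(har(prof)$har, 120, tolerance = 2)
  # uniform helix angle gives a flat profile
  prof2 <- transmural_profile(rep(30, 200), stats::runif(200), unwrap = FALSE)
  expect_equal(prof2$median_ha, rep(30, 9), tolerance = 1e-9)
  # two nodes degenerate to endo/epi medians
  prof3 <- transmural_profile(ha, depth, n_nodes = 2, unwrap = FALSE)
  expect_equal(nrow(prof3), 2)
  # empty nodes are reported with n = 0
  prof4 <- transmural_profile(c(10, 20, 30), c(0.01, 0.02, 0.99),
                              unwrap = FALSE, detrend = FALSE)
  expect_true(any(prof4$n == 0))
  expect_true(all(is.na(prof4$median_ha[prof4$n == 0])))
})

test_that("HAR and delta-HAR are boundary-node differences", {
  prof <- transmural_profile(60 - 120 * seq(0, 1, 0.01), seq(0, 1, 0.01),
                             unwrap = FALSE)
  expect_equal(har(prof)$har, 120, tolerance = 1)
  expect_equal(delta_har(77, 97), 20)
  expect_equal(delta_har(91.7, 91.7), 0)
  empty <- transmural_profile(c(10, 20, 30), c(0.4, 0.5, 0.6),
                              unwrap = FALSE, detrend = FALSE)
  expect_warning(h <- har(empty), "undefined")
  expect_true(is.na(h$har))
})
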