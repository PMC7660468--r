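# Diffusion tensor estimation and invariants.

# forward-model a stack from an explicit per-voxel tensor list
stack_from_tensors <- function(tensors, s0 = 1, b = 350,
                               dirs = dwi_directions(12)) {
  nvox <- length(tensors)
  side <- ceiling(sqrt(nvox))
  bvals <- c(0, rep(b, nrow(dirs)))
  bvecs <- rbind(c(0, 0, 0), dirs)
  images <- lapply(seq_along(bvals), function(v) {
    img <- matrix(NA_real_, side, side)
    for (k in seq_len(nvox)) {
      g <- bvecs[v, ]
      img[k] <- s0 * exp(-bvals[v] * drop(t(g) %*% tensors[[k]] %*% g))
    }
    img[is.na(img)] <- 0
    img
  })
  meta <- tibble::tibble(index = seq_along(bvals), b = bvals,
                         gx = bvecs[, 1], gy = bvecs[, 2], gz = bvecs[, 3],
                         repetition = 1L, phase = "p", td = NA_real_)
  mask <- matrix(FALSE, side, side)
  mask[seq_len(nvox)] <- TRUE
  list(stack = new_dwi_stack(images, meta, 1.6), mask = mask)
}

random_spd_tensors <- function(n, scale = 1e-3) {
  lapply(seq_len(n), function(i) {
    A <- matrix(stats::rnorm(9, sd = 0.5), 3)
    scale * (crossprod(A) + 0.3 * diag(3))
  })
}

test_that("log-linear fit inverts the forward model exactly on noiseless data", {
  d <- 1.2e-3
  iso <- stack_from_tensors(list(d * diag(3)))
  fit <- fit_log_linear(iso$stack, iso$mask)
  expect_equal(fit$D[1, ], c(d, d, d, 0, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  withr::local_seed(11)
  tensors <- random_spd_tensors(30)
  st <- stack_from_tensors(tensors)
  fit2 <- fit_log_linear(st$stack, st$mask)
  for (k in seq_along(tensors)) {
    Dk <- tensors[[k]]
    expect_equal(fit2$D[k, ],
                 c(Dk[1, 1], Dk[2, 2], Dk[3, 3], Dk[1, 2], Dk[1, 3], Dk[2, 3]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("underdetermined designs are rejected", {
  iso <- stack_from_tensors(list(1e-3 * diag(3)), dirs = dwi_directions(6))
  keep <- iso$stack$meta$b > 0
  st <- new_dwi_stack(iso$stack$images[keep], iso$stack$meta[keep, ], 1.6)
  expect_error(fit_log_linear(st, iso$mask), ">= 7")
})

test_that("NLLS matches the log-linear oracle on noiseless voxels", {
  withr::local_seed(12)
  tensors <- random_spd_tensors(40)
  st <- stack_from_tensors(tensors)
  init <- fit_log_linear(st$stack, st$mask)
  fit <- fit_nlls(st$stack, st$mask, init)
  expect_true(all(fit$converged))
  expect_lt(max(abs(fit$D - init$D)), 1e-8)
})

test_that("background voxels are flagged, not fitted", {
  iso <- stack_from_tensors(list(1e-3 * diag(3), 1.5e-3 * diag(3)))
  for (v in seq_along(iso$stack$images)) iso$stack$images[[v]][2] <- 0
  fit <- fit_nlls(iso$stack, iso$mask)
  expect_false(fit$converged[2])
  expect_true(fit$converged[1])
})

test_that("mean fitted MD stays within 2% of truth under Rician noise at SNR 20", {
  withr::local_seed(13)
  d <- 1.5e-3
  nvox <- 1000
  side <- ceiling(sqrt(nvox))
  dirs <- dwi_directions(12)
  bvals <- c(0, rep(350, 12)); bvecs <- rbind(c(0, 0, 0), dirs)
  # SNR(b0) = 20 with 8-repetition averaging
  images <- lapply(seq_along(bvals), function(v) {
    s <- exp(-bvals[v] * d)
    Reduce(`+`, lapply(1:8, function(r) add_noise(matrix(s, side, side), 0.05))) / 8
  })
  meta <- tibble::tibble(index = seq_along(bvals), b = bvals,
                         gx = bvecs[, 1], gy = bvecs[, 2], gz = bvecs[, 3],
                         repetition = 1L, phase = "p", td = NA_real_)
  mask <- matrix(FALSE, side, side); mask[seq_len(nvox)] <- TRUE
  fit <- fit_nlls(new_dwi_stack(images, meta, 1.6), mask)
  md <- rowMeans(fit$D[, 1:3])
  expect_equal(mean(md[fit$converged]), d, tolerance = 0.02)
})

test_that("eigen-decomposition sorts, clips and reconstructs", {
  f <- list(dim = c(2, 2), spacing = 1, voxel_index = 1:3,
            D = rbind(c(2e-3, 1e-3, 0.5e-3, 0, 0, 0),
                      c(2e-3, 1e-3, -1e-5, 0, 0, 0),
                      c(1.5e-3, 1.5e-3, 1.5e-3, 0, 0, 0)),
            s0 = rep(1, 3), converged = rep(TRUE, 3), resid = rep(0, 3),
            method = "log_linear")
  class(f) <- "cdti_tensor_field"
  eig <- tensor_eigen(f)
  expect_equal(eig$lambda[1, ], c(2e-3, 1e-3, 0.5e-3))
  expect_equal(abs(eig$vectors[1, 1:3]), c(1, 0, 0))
  expect_true(eig$clipped[2])
  expect_equal(eig$lambda[2, 3], 1e-7)
  # rotation invariance of eigenvalues
  withr::local_seed(14)
  R <- random_frame()
  D0 <- diag(c(2, 1, 0.5) * 1e-3)
  Dr <- R %*% D0 %*% t(R)
  f2 <- f
  f2$D <- rbind(c(Dr[1, 1], Dr[2, 2], Dr[3, 3], Dr[1, 2], Dr[1, 3], Dr[2, 3]))
  f2$voxel_index <- 1L; f2$converged <- TRUE; f2$s0 <- 1; f2$resid <- 0
  eig2 <- tensor_eigen(f2)
  expect_equal(eig2$lambda[1, ], c(2e-3, 1e-3, 0.5e-3), tolerance = 1e-12)
  # reconstruction Sum lambda_i E_i E_i' recovers the tensor
  V <- matrix(eig2$vectors[1, ], 3, 3)
  Drec <- V %*% diag(eig2$lambda[1, ]) %*% t(V)
  expect_lt(max(abs(Drec - Dr)), 1e-10)
})

test_that("rotational invariants match closed forms", {
  eig <- structure(list(dim = c(2, 2), spacing = 1, voxel_index = 1:3,
                        lambda = rbind(c(1.5e-3, 1.5e-3, 1.5e-3),
                                       c(2e-3, 1e-3, 1e-3),
                                       c(1, 1e-7, 1e-7)),
                        vectors = matrix(rep(as.vector(diag(3)), 3), 3, 9,
                                         byrow = TRUE),
                        clipped = rep(FALSE, 3), converged = rep(TRUE, 3)),
                   class = "cdti_eigen_field")
  inv <- tensor_invariants(eig)
  expect_equal(inv$md[1], 1.5e-3)
  expect_equal(inv$fa[1], 0)
  expect_equal(inv$ratio21[1], 1)
  expect_equal(inv$md[2], 4 / 3 * 1e-3, tolerance = 1e-12)
  # closed-form FA for (2,1,1): sqrt(3/2)*sqrt(2/3 * (1/3)^2 ... ) = 0.4082
  lam <- c(2, 1, 1) * 1e-3; mdv <- mean(lam)
  fa_expected <- sqrt(3 / 2) * sqrt(sum((lam - mdv)^2)) / sqrt(sum(lam^2))
  expect_equal(inv$fa[2], fa_expected, tolerance = 1e-12)
  expect_equal(fa_expected, 0.408, tolerance = 1e-3)
  expect_equal(inv$fa[3], 1, tolerance = 1e-4)    # stick limit
  expect_true(all(inv$fa >= 0 & inv$fa <= 1))
})
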