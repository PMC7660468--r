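# Voxelwise diffusion tensor estimation: log-linear initializer/oracle,
# nonlinear least-squares refinement, eigen-decomposition, and rotational
# invariants (MD, FA, lambda2/lambda1).
#
# Tensor components are stored per voxel in the order
# (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), units mm^2/s.

tensor_design <- function(bvals, bvecs) {
  cbind(
    1,
    -bvals * bvecs[, 1]^2,
    -bvals * bvecs[, 2]^2,
    -bvals * bvecs[, 3]^2,
    -2 * bvals * bvecs[, 1] * bvecs[, 2],
    -2 * bvals * bvecs[, 1] * bvecs[, 3],
    -2 * bvals * bvecs[, 2] * bvecs[, 3]
  )
}

stack_signal_matrix <- function(stack, mask) {
  idx <- which(mask)
  S <- matrix(0, length(idx), length(stack$images))
  for (v in seq_along(stack$images)) S[, v] <- stack$images[[v]][idx]
  S
}

new_tensor_field <- function(dim, spacing, voxel_index, D, s0, converged,
                             resid, method) {
  structure(list(dim = dim, spacing = spacing, voxel_index = voxel_index,
                 D = D, s0 = s0, converged = converged, resid = resid,
                 method = method),
            class = "cdti_tensor_field")
}

#' @export
print.cdti_tensor_field <- function(x, ...) {
  cat("<cdti_tensor_field> ", length(x$voxel_index), " voxels, method ",
      x$method, ", ", sum(!x$converged), " flagged\n", sep = "")
  invisible(x)
}

#' Log-linear diffusion tensor fit
#'
#' Ordinary least squares of `log(S)` on the design
#' `[1, -b g (x) g terms]`; serves as the initializer and the independent
#' oracle for the nonlinear fit. Requires at least 7 measurements including
#' b = 0. Voxels with any non-positive signal are flagged and excluded.
#'
#' @param stack a `cdti_stack` (typically repetition-averaged).
#' @param mask logical matrix of voxels to fit.
#' @return A `cdti_tensor_field`.
#' @export
fit_log_linear <- function(stack, mask) {
  meta <- stack$meta
  if (nrow(meta) < 7 || !any(meta$b == 0)) {
    stop("tensor fit needs >= 7 measurements including b = 0", call. = FALSE)
  }
  X <- tensor_design(meta$b, cbind(meta$gx, meta$gy, meta$gz))
  if (qr(X)$rank < 7) {
    stop("singular design: degenerate direction set", call. = FALSE)
  }
  S <- stack_signal_matrix(stack, mask)
  ok <- apply(S, 1, function(s) all(is.finite(s)) && all(s > 0))
  theta <- matrix(NA_real_, nrow(S), 7)
  resid <- rep(NA_real_, nrow(S))
  if (any(ok)) {
    Y <- t(log(S[ok, , drop = FALSE]))
    fit <- qr.solve(X, Y)
    theta[ok, ] <- t(fit)
    resid[ok] <- sqrt(colSums((Y - X %*% fit)^2))
  }
  new_tensor_field(dim(mask), stack$pixel_spacing, which(mask),
                   D = theta[, 2:7, drop = FALSE],
                   s0 = exp(theta[, 1]),
                   converged = ok, resid = resid, method = "log_linear")
}

#' Nonlinear least-squares diffusion tensor fit
#'
#' Per voxel, minimizes `sum_i (S_i - S0 exp(-b_i g_i' D g_i))^2` by
#' Levenberg-Marquardt (via minpack.lm) with an analytic Jacobian,
#' initialized from the log-linear fit. Non-converged voxels fall back to
#' the initializer and are flagged; voxels with non-finite signals are
#' flagged and excluded.
#'
#' @param stack a `cdti_stack`.
#' @param mask logical matrix of voxels to fit.
#' @param init optional `cdti_tensor_field` initializer; defaults to
#'   [fit_log_linear()] on the same input.
#' @param max_iter,ftol solver controls.
#' @return A `cdti_tensor_field`.
#' @export
fit_nlls <- function(stack, mask, init = NULL, max_iter = 100, ftol = 1e-10) {
  if (is.null(init)) init <- fit_log_linear(stack, mask)
  meta <- stack$meta
  X <- tensor_design(meta$b, cbind(meta$gx, meta$gy, meta$gz))
  S <- stack_signal_matrix(stack, mask)
  nvox <- nrow(S)
  theta <- cbind(log(init$s0), init$D)
  out <- theta
  converged <- logical(nvox)
  resid <- rep(NA_real_, nvox)

  model_fn <- function(th, s) s - exp(drop(X %*% th))
  jac_fn <- function(th, s) {
    m <- exp(drop(X %*% th))
    -m * X
  }
  for (k in seq_len(nvox)) {
    s <- S[k, ]
    if (!all(is.finite(s)) || all(s <= 0) || !all(is.finite(theta[k, ]))) {
      converged[k] <- FALSE
      next
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = theta[k, ], fn = model_fn, jac = jac_fn, s = s,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = ftol, ptol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(fit) || fit$info %in% c(0, 5, 9) ||
        !all(is.finite(fit$par))) {
      converged[k] <- FALSE                # keep the initializer values
      resid[k] <- sqrt(sum(model_fn(theta[k, ], s)^2))
    } else {
      out[k, ] <- fit$par
      converged[k] <- TRUE
      resid[k] <- sqrt(fit$deviance)
    }
  }
  new_tensor_field(dim(mask), stack$pixel_spacing, init$voxel_index,
                   D = out[, 2:7, drop = FALSE], s0 = exp(out[, 1]),
                   converged = converged, resid = resid, method = "nlls")
}

#' Eigen-decomposition of a tensor field
#'
#' Sorted (descending) eigenvalues and orthonormal eigenvectors per voxel.
#' Small negative eigenvalues arising from noise are clipped to `clip` and
#' the voxel flagged. Eigenvector signs are arbitrary; all downstream angle
#' measures are axial (sign-invariant).
#'
#' @param field a `cdti_tensor_field`.
#' @param clip floor for negative eigenvalues (mm^2/s).
#' @return A `cdti_eigen_field`: `lambda` (n x 3), `vectors` (n x 9, columns
#'   E1x,E1y,E1z,E2x,...), `clipped` flags, plus the field geometry.
#' @export
tensor_eigen <- function(field, clip = 1e-7) {
  n <- nrow(field$D)
  lambda <- matrix(NA_real_, n, 3)
  vectors <- matrix(NA_real_, n, 9)
  clipped <- logical(n)
  for (k in seq_len(n)) {
    d <- field$D[k, ]
    if (!all(is.finite(d))) next
    Dm <- matrix(c(d[1], d[4], d[5],
                   d[4], d[2], d[6],
                   d[5], d[6], d[3]), 3, 3)
    e <- eigen(Dm, symmetric = TRUE)     # eigenvalues sorted decreasing
    lam <- e$values
    if (any(lam < 0)) {
      clipped[k] <- TRUE
      lam <- pmax(lam, clip)
    }
    lambda[k, ] <- lam
    vectors[k, ] <- as.vector(e$vectors)
  }
  structure(list(dim = field$dim, spacing = field$spacing,
                 voxel_index = field$voxel_index, lambda = lambda,
                 vectors = vectors, clipped = clipped,
                 converged = field$converged),
            class = "cdti_eigen_field")
}

#' Rotational invariants of an eigen field
#'
#' `MD = (l1 + l2 + l3) / 3`,
#' `FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||`, and the eigenvalue
#' ratio `l2 / l1`. All-zero voxels get FA = 0 and a flag.
#'
#' @param eig a `cdti_eigen_field`.
#' @return Tibble: `voxel_index`, `lambda1..3`, `md`, `fa`, `ratio21`,
#'   `flagged`.
#' @export
tensor_invariants <- function(eig) {
  l <- eig$lambda
  md <- rowMeans(l)
  nrm <- sqrt(rowSums(l^2))
  dev <- sqrt(rowSums((l - md)^2))
  fa <- ifelse(nrm > 0, sqrt(3 / 2) * dev / nrm, 0)
  tibble::tibble(
    voxel_index = eig$voxel_index,
    lambda1 = l[, 1], lambda2 = l[, 2], lambda3 = l[, 3],
    md = md, fa = fa, ratio21 = l[, 2] / l[, 1],
    flagged = (nrm == 0) | eig$clipped | !eig$converged
  )
}

#' Reshape per-voxel values into a map matrix
#' @param values numeric vector aligned with `voxel_index`.
#' @param dim map dimensions.
#' @param voxel_index linear indices of the voxels.
#' @return Matrix with `NA` outside the voxel set.
#' @export
as_map <- function(values, dim, voxel_index) {
  m <- matrix(NA_real_, dim[1], dim[2])
  m[voxel_index] <- values
  m
}
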