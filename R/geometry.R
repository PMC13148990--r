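#' Decompose a late axis into components parallel and orthogonal to the early axis
#'
#' `v2 = v_par + v_perp` with `v_par = <v1_hat, v2> v1_hat` (the early axis is
#' normalized to unit length first, so the decomposition is a true orthogonal
#' projection) and `v_perp = v2 - v_par`. `v_perp` is the "new tuning
#' direction" that emerges at long latency.
#'
#' @param v1 Early-window axis (non-zero).
#' @param v2 Late-window axis.
#' @return An `axis_decomposition`: `v1`, `v2`, `v_par`, `v_perp`,
#'   `par_coef` (signed length of the parallel component), `perp_frac`
#'   (`|v_perp|^2 / |v2|^2`), `no_new_tuning` flag (`v_perp` numerically 0).
#' @export
decompose_axis <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2))
  if (n1 == 0) abort("early axis v1 has zero norm")
  v1h <- v1 / n1
  coef <- sum(v1h * v2)
  v_par <- coef * v1h
  v_perp <- v2 - v_par
  n2 <- sum(v2^2)
  structure(
    list(v1 = v1, v2 = v2, v_par = v_par, v_perp = v_perp, par_coef = coef,
         perp_frac = if (n2 > 0) sum(v_perp^2) / n2 else NA_real_,
         no_new_tuning = sqrt(sum(v_perp^2)) <= 1e-10 * max(1, sqrt(n2))),
    class = "axis_decomposition"
  )
}

#' @export
print.axis_decomposition <- function(x, ...) {
  cat(sprintf("<axis_decomposition> |v_par| = %.3g, |v_perp| = %.3g (%.0f%% of |v2|^2)%s\n",
              abs(x$par_coef), sqrt(sum(x$v_perp^2)), 100 * x$perp_frac,
              if (x$no_new_tuning) " [no new tuning]" else ""))
  invisible(x)
}

#' Principal orthogonal direction to a new tuning direction
#'
#' Removes the `v_perp` component from every stimulus feature vector
#' (`u_perp = u - <u, v_perp_hat> v_perp_hat`), performs PCA over the
#' residuals and returns the first PC (sign-fixed as in
#' [fit_feature_space()]): the stimulus-variance-dominant direction
#' orthogonal to the new tuning axis, used as the second axis of
#' visualization coordinates.
#'
#' @param F stimuli x K feature matrix.
#' @param v_perp New tuning direction (non-zero).
#' @return Unit K-vector orthogonal to `v_perp`.
#' @export
principal_orthogonal_direction <- function(F, v_perp) {
  nv <- sqrt(sum(v_perp^2))
  if (nv == 0) abort("v_perp has zero norm")
  vh <- v_perp / nv
  U <- F - (F %*% vh) %*% t(vh)
  Uc <- sweep(U, 2, colMeans(U))
  sv <- svd(Uc, nu = 0, nv = 1)
  if (sv$d[1] <= 1e-12 * max(1, sqrt(sum(Uc^2)))) abort("residuals have rank 0")
  pc1 <- sv$v[, 1]
  pc1 <- pc1 * sign(pc1[which.max(abs(pc1))])
  pc1
}

#' Sample feature-space locations along a new tuning direction
#'
#' Returns points `m * sigma * v_perp_hat` for each multiplier `m`, where
#' `sigma` is the s.d. of the stimulus-feature projections onto the (unit
#' normalized) direction. The default multipliers sample seven locations at
#' -4 to +4 sigma, the grid used to visualize how stimuli change along an
#' emergent tuning direction (image synthesis from these feature vectors is
#' out of scope).
#'
#' @param v_perp Direction to sample along (non-zero).
#' @param F stimuli x K feature matrix defining the projection s.d.
#' @param multipliers Projection lengths in units of sigma.
#' @return Tibble: `multiplier`, `projection` (= multiplier * sigma) and
#'   `point` (list-column of K-vectors).
#' @export
sample_along_direction <- function(v_perp, F,
                                   multipliers = c(-4, -2, -1, 0, 1, 2, 4)) {
  nv <- sqrt(sum(v_perp^2))
  if (nv == 0) abort("v_perp has zero norm")
  vh <- v_perp / nv
  sigma <- sd(as.vector(F %*% vh))
  if (sigma == 0) abort("stimulus projections onto the direction have zero s.d.")
  tibble::tibble(
    multiplier = multipliers,
    projection = multipliers * sigma,
    point = purrr::map(multipliers, function(m) m * sigma * vh)
  )
}

#' Concentration of new tuning on known generating dimensions
#'
#' Fraction of `v_perp`'s squared norm carried by a named dimension set; on
#' synthetic populations this scores whether the recovered new tuning lies in
#' the generating `new_dims` block.
#'
#' @param v_perp New tuning direction.
#' @param dims Integer indices of the generating dimensions.
#' @export
perp_concentration <- function(v_perp, dims) {
  tot <- sum(v_perp^2)
  if (tot == 0) return(NA_real_)
  sum(v_perp[dims]^2) / tot
}
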