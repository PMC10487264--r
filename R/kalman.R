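#' @title Constant-velocity Kalman filter for box tracking
#' @description
#' The tracker's motion model is the classic deep-sort parameterization: an
#' 8-dimensional state \code{(cx, cy, w, h, vx, vy, vw, vh)} — box centroid,
#' box size, and their per-frame velocities, all in pixels — with a
#' constant-velocity transition and a linear measurement of the first four
#' components. A state is a list with fields \code{mean} (length-8 numeric)
#' and \code{cov} (8x8 covariance matrix).
#' @name kalman-state
#' @keywords internal
NULL

kf_F <- local({
  F <- diag(8)
  F[1, 5] <- F[2, 6] <- F[3, 7] <- F[4, 8] <- 1
  F
})
kf_H <- cbind(diag(4), matrix(0, 4, 4))

#' Initialize a Kalman state from a first measurement
#'
#' Position and size are taken from the measurement; velocities start at
#' zero with a large variance so the first few updates determine them.
#'
#' @param z Numeric length-4 measurement \code{(cx, cy, w, h)} in px.
#' @param measurement_noise_scale Measurement variance (px^2) per measured
#'   component.
#' @param velocity_var Initial variance on the velocity components.
#' @return A Kalman state (list with \code{mean}, \code{cov}).
#' @export
kf_init <- function(z, measurement_noise_scale = 1, velocity_var = 1e4) {
  stopifnot(length(z) == 4, all(is.finite(z)))
  list(mean = c(z, 0, 0, 0, 0),
       cov = diag(c(rep(10 * measurement_noise_scale, 4),
                    rep(velocity_var, 4))))
}

#' Kalman predict step
#'
#' Advances the mean by the constant-velocity transition (\code{cx += vx},
#' etc.) and propagates the covariance with additive process noise. Pure
#' function: the input state is not modified.
#'
#' @param state A Kalman state.
#' @param process_noise_scale Process noise variance added per component.
#' @return The predicted state.
#' @export
kf_predict <- function(state, process_noise_scale = 1) {
  mean <- as.vector(kf_F %*% state$mean)
  cov <- kf_F %*% state$cov %*% t(kf_F) + process_noise_scale * diag(8)
  list(mean = mean, cov = cov)
}

#' Kalman measurement update
#'
#' Standard linear update of the state on a box measurement
#' \code{(cx, cy, w, h)}. The posterior covariance trace in the measured
#' subspace never exceeds the prior's.
#'
#' @param state A (predicted) Kalman state.
#' @param z Numeric length-4 measurement in px.
#' @param measurement_noise_scale Measurement variance (px^2) per component.
#' @return The posterior state.
#' @export
kf_update <- function(state, z, measurement_noise_scale = 1) {
  if (length(z) != 4 || !all(is.finite(z))) {
    stop("measurement must be 4 finite values (cx, cy, w, h)")
  }
  S <- kf_H %*% state$cov %*% t(kf_H) + measurement_noise_scale * diag(4)
  K <- state$cov %*% t(kf_H) %*% solve(S)
  innov <- z - as.vector(kf_H %*% state$mean)
  mean <- state$mean + as.vector(K %*% innov)
  cov <- (diag(8) - K %*% kf_H) %*% state$cov
  # symmetrize against numerical drift
  cov <- (cov + t(cov)) / 2
  list(mean = mean, cov = cov)
}
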