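# Constant-velocity Kalman filter over the box state (cx, cy, a, h) with
# a = w/h, in the style long used by detection-based trackers: process and
# measurement noise scale with the box height, so large (near-camera) boxes
# tolerate proportionally more pixel motion.

KF_DIM <- 8L
KF_STD_POS <- 1 / 20
# at 1 frame per second, inter-frame accelerations are an order of magnitude
# larger than at video rate, so the velocity process noise is set accordingly
KF_STD_VEL <- 1 / 80

kf_transition <- function() {
  f <- diag(KF_DIM)
  f[cbind(1:4, 5:8)] <- 1
  f
}

box_to_measurement <- function(box) {
  c(box$cx, box$cy, box$w / box$h, box$h)
}

measurement_to_box <- function(z) {
  tibble(cx = z[1], cy = z[2], w = z[3] * z[4], h = z[4])
}

#' Initialise, predict and update a trajectory's Kalman state
#'
#' The state is an 8-vector: box center `(cx, cy)`, aspect ratio `a = w/h`,
#' height `h`, and their velocities, propagated under a constant-velocity
#' model. Noise scales follow the usual height-relative convention of
#' detection-based trackers. `kalman_predict()` propagates the mean and
#' grows the covariance by the process noise; `kalman_update()` applies the
#' standard measurement update with the box `(cx, cy, a, h)` as the
#' observation, never increasing the covariance trace. `kalman_box()` reads
#' the state back as a center-form box.
#'
#' @param box One-row data frame (or named vector) with `cx`, `cy`, `w`,
#'   `h`; `h` must be positive for updates.
#' @param state A state as returned by these functions: list with `mean`
#'   (length 8) and `cov` (8 x 8 symmetric positive semi-definite).
#' @param r_scale Scale factor on the measurement-noise covariance; 0 makes
#'   the update adopt the measurement exactly.
#' @return A Kalman state list (`mean`, `cov`); `kalman_box()` returns a
#'   one-row tibble.
#' @export
kalman_init <- function(box) {
  box <- as_box_df(box)
  z <- box_to_measurement(box)
  h <- z[4]
  std <- c(2 * KF_STD_POS * h, 2 * KF_STD_POS * h, 1e-2, 2 * KF_STD_POS * h,
           10 * KF_STD_VEL * h, 10 * KF_STD_VEL * h, 1e-5, 10 * KF_STD_VEL * h)
  list(mean = c(z, rep(0, 4)), cov = diag(std^2))
}

#' @rdname kalman_init
#' @export
kalman_predict <- function(state) {
  f <- kf_transition()
  h <- state$mean[4]
  std <- c(KF_STD_POS * h, KF_STD_POS * h, 1e-2, KF_STD_POS * h,
           KF_STD_VEL * h, KF_STD_VEL * h, 1e-5, KF_STD_VEL * h)
  q <- diag(std^2)
  mean <- as.numeric(f %*% state$mean)
  cov <- f %*% state$cov %*% t(f) + q
  list(mean = mean, cov = symmetrize(cov))
}

#' @rdname kalman_init
#' @export
kalman_update <- function(state, box, r_scale = 1) {
  box <- as_box_df(box)
  if (box$h <= 0 || box$w <= 0) abort("Measurement box must have positive size.")
  z <- box_to_measurement(box)
  hmat <- cbind(diag(4), matrix(0, 4, 4))
  h <- state$mean[4]
  std <- c(KF_STD_POS * h, KF_STD_POS * h, 1e-1, KF_STD_POS * h)
  r <- diag(std^2) * r_scale
  s <- hmat %*% state$cov %*% t(hmat) + r
  k <- state$cov %*% t(hmat) %*% solve(s)
  innov <- z - as.numeric(hmat %*% state$mean)
  mean <- state$mean + as.numeric(k %*% innov)
  cov <- (diag(KF_DIM) - k %*% hmat) %*% state$cov
  list(mean = mean, cov = symmetrize(cov))
}

#' @rdname kalman_init
#' @export
kalman_box <- function(state) {
  measurement_to_box(state$mean[1:4])
}

symmetrize <- function(m) (m + t(m)) / 2
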