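#' Fourier-expansion abduction driver
#'
#' The driven abduction angle is a truncated Fourier series
#' \eqn{Pos(t) = \sum_j A_j \cos(\omega_j t + B_j)} (degrees, t in s).
#' The default profile is the two-term cosine ramp
#' \eqn{Pos(t) = 45 - 45\cos(\pi t / 90)}, i.e. coefficients
#' A = (45, -45), \eqn{\omega} = (0, \eqn{\pi}/90), B = (0, 0): it starts
#' and stops smoothly and satisfies Pos(0) = 0 and Pos(90 s) = 90
#' exactly. User-supplied coefficients are validated at construction:
#' endpoints 0 and 90 degrees within 1e-9 and nondecreasing over the
#' duration.
#'
#' @param coefficients data.frame/list with columns `A` (degrees),
#'   `omega` (rad/s), `B` (radians).
#' @param duration motion duration, s.
#' @param n_steps number of uniformly spaced time steps (default 91, one
#'   record per degree of abduction on average).
#' @return object of class `driver_spec`.
#' @export
driver_spec <- function(coefficients = data.frame(A = c(45, -45),
                                                  omega = c(0, pi / 90),
                                                  B = c(0, 0)),
                        duration = 90, n_steps = 91) {
  if (duration <= 0) stop("duration must be positive")
  if (n_steps < 2) stop("n_steps must be at least 2")
  cf <- as.data.frame(coefficients)
  if (!all(c("A", "omega", "B") %in% names(cf)))
    stop("coefficients need columns A, omega, B")
  spec <- structure(list(coefficients = cf, duration = duration,
                         n_steps = as.integer(n_steps)),
                    class = "driver_spec")
  p0 <- abduction_angle(0, spec)
  p1 <- abduction_angle(duration, spec)
  if (abs(p0) > 1e-9 || abs(p1 - 90) > 1e-9)
    stop(sprintf("driver endpoints must be 0 and 90 degrees (got %.3g, %.3g)",
                 p0, p1))
  dense <- abduction_angle(seq(0, duration, length.out = 361L), spec)
  if (any(diff(dense) < -1e-9))
    stop("driver profile must be nondecreasing over the motion")
  spec
}

#' Driven abduction angle at time t
#'
#' @param t time, s (must lie in [0, duration]); vectorized.
#' @param spec a [driver_spec()].
#' @return abduction angle, degrees.
#' @export
abduction_angle <- function(t, spec) {
  if (any(t < -1e-12 | t > spec$duration + 1e-12))
    stop("t outside [0, duration]")
  cf <- spec$coefficients
  vapply(t, function(ti) sum(cf$A * cos(cf$omega * ti + cf$B)), 0)
}

#' Uniform time grid of the abduction motion
#'
#' @param spec a [driver_spec()].
#' @return data.frame with columns `t` (s) and `angle` (degrees);
#'   `n_steps` rows, first angle 0, last 90, strictly nondecreasing.
#' @export
time_grid <- function(spec) {
  t <- seq(0, spec$duration, length.out = spec$n_steps)
  data.frame(t = t, angle = abduction_angle(t, spec))
}
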