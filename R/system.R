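#' Physical parameters of the cup-and-ball system
#'
#' The cup sliding on the board with a ball rolling inside is modelled as a
#' cart on a line with a suspended pendulum: the pendulum length equals the
#' cup's radius of curvature and the ball escapes once its mechanical energy
#' exceeds the potential energy at the rim angle.
#'
#' @param ball_mass Ball mass \eqn{m_b} in kg (default 0.067, the 67 g steel
#'   ball of the physical device).
#' @param pendulum_length Pendulum length \eqn{l} in m, equal to the cup's
#'   radius of curvature (default 0.075).
#' @param escape_angle Rim height angle \eqn{\theta_{ESC}} in radians; the
#'   deep cup has a 55 deg rim, the shallow cup 40 deg. Must lie in
#'   (0, pi/2).
#' @param cup_mass Cup mass \eqn{m_c} in kg. It cancels out of the ball
#'   dynamics and only enters the interaction force; default 0.1.
#' @param gravity Gravitational acceleration in m/s^2 (default 9.81).
#'
#' @return An object of class `cup_ball_system`.
#' @examples
#' sys <- cup_ball_system()
#' escape_energy(sys)
#' natural_period(sys)
#' @export
cup_ball_system <- function(ball_mass = 0.067,
                            pendulum_length = 0.075,
                            escape_angle = 55 * pi / 180,
                            cup_mass = 0.1,
                            gravity = 9.81) {
  stopifnot(
    is.numeric(ball_mass), length(ball_mass) == 1, is.finite(ball_mass),
    is.numeric(pendulum_length), length(pendulum_length) == 1,
    is.numeric(escape_angle), length(escape_angle) == 1,
    is.numeric(cup_mass), length(cup_mass) == 1,
    is.numeric(gravity), length(gravity) == 1
  )
  if (ball_mass <= 0) stop("ball_mass must be > 0", call. = FALSE)
  if (pendulum_length <= 0) stop("pendulum_length must be > 0", call. = FALSE)
  if (escape_angle <= 0 || escape_angle >= pi / 2) {
    stop("escape_angle must lie in (0, pi/2) radians", call. = FALSE)
  }
  if (cup_mass <= 0) stop("cup_mass must be > 0", call. = FALSE)
  if (gravity <= 0) stop("gravity must be > 0", call. = FALSE)
  structure(
    list(
      ball_mass = ball_mass,
      pendulum_length = pendulum_length,
      escape_angle = escape_angle,
      cup_mass = cup_mass,
      gravity = gravity
    ),
    class = "cup_ball_system"
  )
}

#' @export
print.cup_ball_system <- function(x, ...) {
  cat("<cup_ball_system>\n")
  cat(sprintf("  ball mass       : %.4g kg\n", x$ball_mass))
  cat(sprintf("  pendulum length : %.4g m (cup radius of curvature)\n",
              x$pendulum_length))
  cat(sprintf("  escape angle    : %.4g deg\n", x$escape_angle * 180 / pi))
  cat(sprintf("  cup mass        : %.4g kg\n", x$cup_mass))
  cat(sprintf("  escape energy   : %.4g J\n", escape_energy(x)))
  cat(sprintf("  natural period  : %.4g s\n", natural_period(x)))
  invisible(x)
}

#' Escape energy of the ball
#'
#' \eqn{E_{ESC} = m_b g l (1 - \cos\theta_{ESC})}: the mechanical energy at
#' which the ball reaches the cup rim and would leave the cup.
#'
#' @param system A [cup_ball_system()].
#' @return Escape energy in joules (strictly positive).
#' @export
escape_energy <- function(system) {
  stopifnot(inherits(system, "cup_ball_system"))
  system$ball_mass * system$gravity * system$pendulum_length *
    (1 - cos(system$escape_angle))
}

#' Small-angle natural frequency and period of the ball pendulum
#'
#' @param system A [cup_ball_system()].
#' @return `natural_frequency()`: \eqn{\sqrt{g/l}/(2\pi)} in Hz;
#'   `natural_period()`: \eqn{2\pi\sqrt{l/g}} in seconds.
#' @export
natural_frequency <- function(system) {
  stopifnot(inherits(system, "cup_ball_system"))
  sqrt(system$gravity / system$pendulum_length) / (2 * pi)
}

#' @rdname natural_frequency
#' @export
natural_period <- function(system) {
  1 / natural_frequency(system)
}

#' System parameters for a named difficulty condition
#'
#' Three difficulty conditions are used: `"deep_no_ball"` (deep cup, 55 deg
#' rim, no ball -- a simple reach with added mass), `"deep_ball"` (55 deg rim
#' with ball) and `"shallow_ball"` (40 deg rim with ball, easier escape).
#'
#' @param condition One of `"deep_no_ball"`, `"deep_ball"`, `"shallow_ball"`.
#' @param ... Passed on to [cup_ball_system()] to override other parameters.
#' @return A `cup_ball_system` with the condition's rim angle.
#' @export
condition_system <- function(condition = c("deep_no_ball", "deep_ball",
                                           "shallow_ball"), ...) {
  condition <- match.arg(condition)
  esc <- if (condition == "shallow_ball") 40 * pi / 180 else 55 * pi / 180
  cup_ball_system(escape_angle = esc, ...)
}

#' Does a condition include the ball?
#' @param condition Condition label.
#' @return Logical.
#' @export
condition_has_ball <- function(condition) {
  condition != "deep_no_ball"
}
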