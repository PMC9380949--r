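#' @importFrom rlang .data %||% abort warn
#' @importFrom stats quantile median qgamma pnorm qnorm sd rnorm runif rpois
#'   rgamma setNames confint qt t.test as.formula
#' @importFrom utils combn head tail
NULL

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

# Upper bound of the Yamartino estimator: 90 * 2/sqrt(3) degrees, reached in
# the limit of a uniform circular distribution (epsilon = 1).
SIGMA_THETA_MAX <- 90 * 2 / sqrt(3)

#' Scalar average current speed
#'
#' Arithmetic mean of current speed samples, the conventional scalar average
#' \eqn{\bar{u} = n^{-1} \sum_i u_i} used for daily and hourly speed
#' summaries. Direction is ignored entirely, so the scalar average is always
#' at least as large as the magnitude of the vector-averaged current (see
#' [vector_average()]).
#'
#' @param speeds Numeric vector of current speeds (m s^-1), all non-negative.
#' @param na.rm Drop missing values before averaging?
#' @return Mean speed in m s^-1 (length-1 numeric).
#' @examples
#' scalar_mean_speed(c(0, 0.2))
#' @export
scalar_mean_speed <- function(speeds, na.rm = FALSE) {
  if (na.rm) speeds <- speeds[!is.na(speeds)]
  if (length(speeds) == 0) abort("`speeds` must be non-empty.")
  if (any(speeds < 0, na.rm = TRUE)) abort("`speeds` must be non-negative.")
  mean(speeds)
}

#' Magnitude-weighted vector average of current direction
#'
#' Resolves each (speed, direction) sample into east/north components
#' weighted by speed magnitude, averages the components, and returns the
#' resultant direction mapped to \[0, 360). With the default `heading_to`
#' convention the components are \eqn{u_i = s_i \sin\theta_i},
#' \eqn{v_i = s_i \cos\theta_i} (directions are where the flow is heading
#' to, degrees clockwise from north); `coming_from` applies the
#' meteorological sign flip \eqn{-s_i}, which rotates the resultant by
#' 180 degrees.
#'
#' The resultant direction is computed with the two-argument arctangent,
#' which is algebraically equivalent to a single-argument arctangent plus a
#' quadrant-correction clause of +/-180 degrees; [theta_from_components()]
#' exposes the literal clause form.
#'
#' @param speeds,directions_to Equal-length numeric vectors: speeds (m s^-1,
#'   non-negative) and directions (degrees in \[0, 360)).
#' @param convention `"heading_to"` (oceanographic, default) or
#'   `"coming_from"` (meteorological).
#' @return A one-row tibble of class `reef_vector_average` with columns
#'   `u_bar`, `v_bar` (component means, m s^-1), `theta_bar` (degrees in
#'   \[0, 360), `NA` when the resultant speed is zero), `resultant_speed`,
#'   `scalar_mean_speed` and `n`.
#' @examples
#' vector_average(c(1, 1), c(0, 90))
#' @export
vector_average <- function(speeds, directions_to,
                           convention = c("heading_to", "coming_from")) {
  convention <- match.arg(convention)
  if (length(speeds) != length(directions_to)) {
    abort("`speeds` and `directions_to` must have equal length.")
  }
  keep <- !(is.na(speeds) | is.na(directions_to))
  speeds <- speeds[keep]
  directions_to <- directions_to[keep]
  if (length(speeds) == 0) abort("no complete (speed, direction) pairs.")
  if (any(speeds < 0)) abort("`speeds` must be non-negative.")

  sgn <- if (convention == "heading_to") 1 else -1
  th <- directions_to * DEG2RAD
  u_bar <- mean(sgn * speeds * sin(th))
  v_bar <- mean(sgn * speeds * cos(th))
  resultant <- sqrt(u_bar^2 + v_bar^2)
  theta_bar <- if (resultant == 0) NA_real_ else (atan2(u_bar, v_bar) * RAD2DEG) %% 360

  out <- tibble::tibble(
    u_bar = u_bar, v_bar = v_bar, theta_bar = theta_bar,
    resultant_speed = resultant,
    scalar_mean_speed = mean(speeds),
    n = length(speeds)
  )
  class(out) <- c("reef_vector_average", class(out))
  out
}

#' Resultant direction from component means, literal quadrant-clause form
#'
#' Converts averaged east/north components to a compass direction using a
#' single-argument arctangent plus an explicit +/-180-degree correction
#' clause, rather than `atan2()`. The two forms agree on every quadrant;
#' this one exists so the equivalence is testable.
#'
#' @param u_bar,v_bar Component means (east, north).
#' @return Direction in degrees in \[0, 360), `NA` if both components are 0.
#' @keywords internal
#' @export
theta_from_components <- function(u_bar, v_bar) {
  if (u_bar == 0 && v_bar == 0) return(NA_real_)
  if (v_bar == 0) return(if (u_bar > 0) 90 else 270)
  raw <- atan(u_bar / v_bar) * RAD2DEG
  # arctan lands in (-90, 90): correct into the v <= 0 half-plane by 180.
  f <- if (v_bar < 0) 180 else if (raw < 0) 360 else 0
  (raw + f) %% 360
}

#' Yamartino directional standard deviation
#'
#' Single-pass estimator of the circular standard deviation of directions
#' from the means of the (unweighted) unit vectors: with
#' \eqn{\epsilon = \sqrt{1 - (\bar{u}_n^2 + \bar{v}_n^2)}}, the spread is
#' \eqn{\sigma_\theta = \arcsin(\epsilon)\,[1 + (2/\sqrt{3} - 1)\epsilon^3]}
#' (degrees). It is 0 for identical directions and approaches
#' \eqn{90 \times 2/\sqrt{3} \approx 103.92} degrees for uniformly
#' distributed directions; speeds play no role.
#'
#' @param directions_to Directions in degrees.
#' @param speeds Optional speeds enabling a magnitude-weighted variant of the
#'   component means; the default (NULL) follows the standard unweighted
#'   unit-vector definition.
#' @return A one-row tibble of class `reef_directional_spread` with columns
#'   `epsilon` (in \[0, 1\]), `sigma_theta` (degrees) and `n`.
#' @seealso [angular_deviation()] for the exact (two-pass-free) circular
#'   angular deviation this approximates.
#' @examples
#' yamartino_sd(c(350, 10))
#' @export
yamartino_sd <- function(directions_to, speeds = NULL) {
  directions_to <- directions_to[!is.na(directions_to)]
  if (length(directions_to) == 0) abort("`directions_to` must be non-empty.")
  th <- directions_to * DEG2RAD
  if (is.null(speeds)) {
    su <- sin(th); cv <- cos(th)
  } else {
    w <- speeds[!is.na(speeds)]
    if (length(w) != length(th)) abort("`speeds` must match `directions_to`.")
    tot <- sum(w)
    if (tot <= 0) abort("weighted variant needs a positive total speed.")
    su <- length(th) * w * sin(th) / tot
    cv <- length(th) * w * cos(th) / tot
  }
  ubar <- mean(su); vbar <- mean(cv)
  eps <- sqrt(max(0, min(1, 1 - (ubar^2 + vbar^2))))
  sigma <- asin(eps) * RAD2DEG * (1 + (2 / sqrt(3) - 1) * eps^3)
  out <- tibble::tibble(epsilon = eps, sigma_theta = sigma,
                        n = length(directions_to))
  class(out) <- c("reef_directional_spread", class(out))
  out
}

#' Exact circular angular deviation
#'
#' The closed-form circular angular deviation
#' \eqn{\sqrt{2(1 - R)} \cdot 180/\pi} degrees, where \eqn{R} is the mean
#' resultant length of the unit direction vectors. Serves as the exact
#' reference against which the single-pass Yamartino estimator is checked:
#' the two agree closely (within a couple of percent) for concentrated
#' samples.
#'
#' @param directions_to Directions in degrees.
#' @return Angular deviation in degrees (length-1 numeric).
#' @examples
#' angular_deviation(c(0, 180)) # R = 0 -> sqrt(2) rad = 81.03 degrees
#' @export
angular_deviation <- function(directions_to) {
  directions_to <- directions_to[!is.na(directions_to)]
  if (length(directions_to) == 0) abort("`directions_to` must be non-empty.")
  th <- directions_to * DEG2RAD
  R <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  sqrt(2 * (1 - min(1, R))) * RAD2DEG
}

# Vectorised kernels used by the aggregation layer. Same algebra as
# vector_average()/yamartino_sd(), but operating on pre-resolved components
# inside grouped summarise() calls.
.theta_bar <- function(u_bar, v_bar) {
  ifelse(u_bar == 0 & v_bar == 0, NA_real_, (atan2(u_bar, v_bar) * RAD2DEG) %% 360)
}
.sigma_theta <- function(un_bar, vn_bar) {
  eps <- sqrt(pmax(0, pmin(1, 1 - (un_bar^2 + vn_bar^2))))
  asin(eps) * RAD2DEG * (1 + (2 / sqrt(3) - 1) * eps^3)
}
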