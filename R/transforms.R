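#' 2D rigid transform (rotation + translation)
#'
#' Represents a stiff rotation-plus-translation mapping of 2D pixel
#' coordinates. The convention throughout the package is
#' `p' = R(theta) %*% p + t`, mapping "moving" coordinates into the
#' "fixed" frame. Reflections and scaling are excluded by construction.
#'
#' @param theta rotation angle in radians (counter-clockwise in the
#'   `(x right, y down)` image coordinate system).
#' @param tx,ty translation in pixels.
#' @return An object of class `rigid_transform2d` with elements `theta`
#'   and `t = c(tx, ty)`.
#' @export
rigid_transform2d <- function(theta = 0, tx = 0, ty = 0) {
  theta <- as.numeric(theta); tx <- as.numeric(tx); ty <- as.numeric(ty)
  if (!all(is.finite(c(theta, tx, ty)))) {
    stop("rigid_transform2d: theta, tx, ty must be finite", call. = FALSE)
  }
  structure(list(theta = theta, t = c(tx = tx, ty = ty)),
            class = "rigid_transform2d")
}

#' @rdname rigid_transform2d
#' @export
transform_identity <- function() rigid_transform2d(0, 0, 0)

#' @export
print.rigid_transform2d <- function(x, ...) {
  cat(sprintf("rigid_transform2d: theta = %.6g rad (%.4g deg), t = (%.6g, %.6g) px\n",
              x$theta, x$theta * 180 / pi, x$t[1], x$t[2]))
  invisible(x)
}

.rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Apply a rigid transform to point coordinates
#'
#' @param transform a [rigid_transform2d()].
#' @param points numeric matrix with two columns `(x, y)`, one point per
#'   row (a single point may be given as a length-2 vector).
#' @return Matrix of transformed points, same shape as `points`.
#' @export
transform_apply <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform2d"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("transform_apply: points must be n x 2", call. = FALSE)
  R <- .rotation_matrix(transform$theta)
  sweep(points %*% t(R), 2, transform$t, "+")
}

#' Compose two rigid transforms
#'
#' `transform_compose(a, b)` applies `b` first, then `a`
#' (i.e. `p' = a(b(p))`).
#'
#' @param a,b [rigid_transform2d()] objects.
#' @return The composed [rigid_transform2d()].
#' @export
transform_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform2d"), inherits(b, "rigid_transform2d"))
  Ra <- .rotation_matrix(a$theta)
  t <- as.numeric(Ra %*% b$t) + as.numeric(a$t)
  rigid_transform2d(a$theta + b$theta, t[1], t[2])
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform2d()].
#' @return The inverse [rigid_transform2d()], satisfying
#'   `compose(transform, invert(transform)) = identity`.
#' @export
transform_invert <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform2d"))
  Rinv <- .rotation_matrix(-transform$theta)
  t <- -as.numeric(Rinv %*% transform$t)
  rigid_transform2d(-transform$theta, t[1], t[2])
}
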