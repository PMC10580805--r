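#' Trapezoidal fuzzy membership function
#'
#' Builds the satisfaction curve of one negotiation issue: zero outside
#' \code{[a, d]}, a plateau of height \code{beta} on \code{[b, c]}, and smooth
#' quadratic shoulders on \code{(a, b)} and \code{(c, d)}.
#'
#' Degenerate trapezoids are allowed: when \code{a == b} (or \code{c == d})
#' the corresponding ramp is empty and the plateau rule applies at the shared
#' point, so e.g. \code{(8, 9, 10, 10)} evaluates to \code{beta} at \code{x =
#' 10}.
#'
#' @param a,b,c,d Breakpoints in issue units, \code{a <= b <= c <= d}.
#' @param beta Plateau height in \code{(0, 1]}; defaults to 1.
#' @return An object of class \code{"trapezoid_mf"}.
#' @examples
#' mf <- trapezoid_mf(2, 3.5, 4, 6)
#' eval_membership(mf, c(3.7, 5.16, 6))
#' @export
trapezoid_mf <- function(a, b, c, d, beta = 1) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
  if (!(a <= b && b <= c && c <= d)) {
    stop("invalid trapezoid: breakpoints must satisfy a <= b <= c <= d")
  }
  if (!(beta > 0 && beta <= 1)) {
    stop("invalid trapezoid: beta must lie in (0, 1]")
  }
  structure(list(a = a, b = b, c = c, d = d, beta = beta),
            class = "trapezoid_mf")
}

#' Evaluate a trapezoidal membership function
#'
#' Returns the satisfaction in \code{[0, beta]} of each value in \code{x}:
#' 0 for \code{x <= a} or \code{x >= d}, \code{beta} on the plateau
#' \code{[b, c]}, and \code{beta * (1 - ((x - b)/(b - a))^2)} respectively
#' \code{beta * (1 - ((x - c)/(c - d))^2)} on the rising and falling
#' shoulders. The plateau rule is applied first so degenerate ramps
#' (\code{a == b} or \code{c == d}) evaluate to \code{beta} at the shared
#' breakpoint.
#'
#' @param mf A \code{\link{trapezoid_mf}}.
#' @param x Numeric vector of issue values.
#' @return Numeric vector of memberships, same length as \code{x}.
#' @export
eval_membership <- function(mf, x) {
  stopifnot(inherits(mf, "trapezoid_mf"), is.numeric(x))
  y <- numeric(length(x))
  plateau <- x >= mf$b & x <= mf$c
  left <- !plateau & x > mf$a & x < mf$b
  right <- !plateau & x > mf$c & x < mf$d
  y[plateau] <- mf$beta
  if (any(left)) {
    y[left] <- mf$beta * (1 - ((x[left] - mf$b) / (mf$b - mf$a))^2)
  }
  if (any(right)) {
    y[right] <- mf$beta * (1 - ((x[right] - mf$c) / (mf$c - mf$d))^2)
  }
  y
}

# Vectorized kernel used by the GA: membership of values `x` (length N) under
# many candidate trapezoids with common a, d and per-candidate b, c (length m),
# beta fixed to 1. Returns an m x N matrix. Plateau-first semantics as above.
trapezoid_eval_many <- function(a, b, c, d, x) {
  m <- length(b)
  n <- length(x)
  X <- matrix(x, nrow = m, ncol = n, byrow = TRUE)
  B <- matrix(b, nrow = m, ncol = n)
  C <- matrix(c, nrow = m, ncol = n)
  Y <- matrix(0, nrow = m, ncol = n)
  plateau <- X >= B & X <= C
  left <- !plateau & X > a & X < B
  right <- !plateau & X > C & X < d
  Y[plateau] <- 1
  if (any(left)) Y[left] <- 1 - ((X[left] - B[left]) / (B[left] - a))^2
  if (any(right)) Y[right] <- 1 - ((X[right] - C[right]) / (C[right] - d))^2
  Y
}

#' @export
print.trapezoid_mf <- function(x, ...) {
  cat(sprintf("<trapezoid_mf a=%g b=%g c=%g d=%g beta=%g>\n",
              x$a, x$b, x$c, x$d, x$beta))
  invisible(x)
}
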