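#' Truncated degree-2 bivariate polynomial in the sampling errors
#'
#' The series engine works in the ring of polynomials in the relative sampling
#' errors \eqn{e_0 = (\bar y - \mu_y)/\mu_y} and
#' \eqn{e_1 = (\bar x - \mu_x)/\mu_x}, truncated at total degree 2. A `tpoly`
#' stores the six coefficients of \eqn{1, e_0, e_1, e_0^2, e_0 e_1, e_1^2}.
#' Ring operations (`+`, `-`, `*`, scalar scaling) are closed under the
#' truncation: multiplication drops every term of total degree above 2.
#'
#' @param c00,c10,c01,c20,c11,c02 Coefficients of
#'   \eqn{1, e_0, e_1, e_0^2, e_0 e_1, e_1^2}.
#' @return An object of class `tpoly` (named numeric vector of length 6).
#' @examples
#' e1 <- tpoly(c01 = 1)
#' tp_log1p(e1)               # e1 - e1^2/2
#' tp_expectation(tpoly(c11 = 1), error_moments_values(0.1, 1, 1, 0.5))
#' @export
tpoly <- function(c00 = 0, c10 = 0, c01 = 0, c20 = 0, c11 = 0, c02 = 0) {
  v <- vapply(list(c00, c10, c01, c20, c11, c02), function(z) as.numeric(z)[1],
              numeric(1))
  structure(setNames(v, c("c00", "c10", "c01", "c20", "c11", "c02")),
            class = "tpoly")
}

# coerce scalars to constant polys
as_tpoly <- function(x) {
  if (inherits(x, "tpoly")) return(x)
  if (is.numeric(x) && length(x) == 1) return(tpoly(c00 = x))
  stop("cannot coerce to tpoly")
}

#' @export
print.tpoly <- function(x, digits = 6, ...) {
  terms <- c("1", "e0", "e1", "e0^2", "e0*e1", "e1^2")
  nz <- which(unclass(x) != 0)
  if (!length(nz)) {
    cat("tpoly: 0\n")
  } else {
    cat("tpoly:",
        paste(sprintf("%+g*%s", signif(unclass(x)[nz], digits), terms[nz]),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
Ops.tpoly <- function(e1, e2) {
  if (.Generic %in% c("+", "-")) {
    if (missing(e2)) {
      return(if (.Generic == "-") tp_scale(e1, -1) else e1)
    }
    a <- as_tpoly(e1); b <- as_tpoly(e2)
    out <- if (.Generic == "+") unclass(a) + unclass(b) else
      unclass(a) - unclass(b)
    return(structure(out, class = "tpoly"))
  }
  if (.Generic == "*") {
    if (is.numeric(e1) && length(e1) == 1) return(tp_scale(e2, e1))
    if (is.numeric(e2) && length(e2) == 1) return(tp_scale(e1, e2))
    return(tp_mul(e1, e2))
  }
  stop(sprintf("operation '%s' not defined for tpoly", .Generic))
}

#' Scale a truncated polynomial by a scalar
#' @param p A [tpoly()].
#' @param a Scalar.
#' @return A `tpoly`.
#' @export
tp_scale <- function(p, a) structure(unclass(p) * a, class = "tpoly")

#' Truncated product of two polynomials
#'
#' Multiplies in the degree-2 truncated ring: all terms of total degree
#' greater than 2 are dropped.
#'
#' @param p,q [tpoly()] objects (scalars are promoted).
#' @return A `tpoly`.
#' @export
tp_mul <- function(p, q) {
  p <- unclass(as_tpoly(p)); q <- unclass(as_tpoly(q))
  tpoly(
    c00 = p["c00"] * q["c00"],
    c10 = p["c00"] * q["c10"] + p["c10"] * q["c00"],
    c01 = p["c00"] * q["c01"] + p["c01"] * q["c00"],
    c20 = p["c00"] * q["c20"] + p["c20"] * q["c00"] + p["c10"] * q["c10"],
    c11 = p["c00"] * q["c11"] + p["c11"] * q["c00"] +
      p["c10"] * q["c01"] + p["c01"] * q["c10"],
    c02 = p["c00"] * q["c02"] + p["c02"] * q["c00"] + p["c01"] * q["c01"])
}

# require zero constant term for series composition
check_no_constant <- function(z, what) {
  z <- as_tpoly(z)
  if (z["c00"] != 0)
    stop(sprintf("%s needs a polynomial with zero constant term", what))
  z
}

#' Primitive series: log(1 + z)
#'
#' \eqn{\log(1+z) = z - z^2/2} in the truncated ring, for any `tpoly` `z` with
#' zero constant term. All estimator expansions are built by composing these
#' primitives with ring products; no estimator gets hand-tailored rules.
#'
#' @param z A [tpoly()] with zero constant term.
#' @return A `tpoly`.
#' @export
tp_log1p <- function(z) {
  z <- check_no_constant(z, "tp_log1p")
  z - 0.5 * tp_mul(z, z)
}

#' Primitive series: 1/(1 + z)
#'
#' \eqn{1/(1+z) = 1 - z + z^2} truncated at degree 2.
#'
#' @inheritParams tp_log1p
#' @return A `tpoly`.
#' @export
tp_inv1p <- function(z) {
  z <- check_no_constant(z, "tp_inv1p")
  tpoly(c00 = 1) - z + tp_mul(z, z)
}

#' Primitive series: exp(z)
#'
#' \eqn{e^z = 1 + z + z^2/2} truncated at degree 2.
#'
#' @inheritParams tp_log1p
#' @return A `tpoly`.
#' @export
tp_exp <- function(z) {
  z <- check_no_constant(z, "tp_exp")
  tpoly(c00 = 1) + z + 0.5 * tp_mul(z, z)
}

#' Primitive series: log(1 + z)/z
#'
#' \eqn{\log(1+z)/z = 1 - z/2 + z^2/3} truncated at degree 2 (the division by
#' z is not closed in the truncated ring, so the quotient series is itself a
#' primitive, taken from the degree-3 log expansion).
#'
#' @inheritParams tp_log1p
#' @return A `tpoly`.
#' @export
tp_log1p_over_z <- function(z) {
  z <- check_no_constant(z, "tp_log1p_over_z")
  tpoly(c00 = 1) - 0.5 * z + (1 / 3) * tp_mul(z, z)
}

#' First- and second-order design moments of the sampling errors
#'
#' Under SRSWOR, \eqn{E(e_0)=E(e_1)=0}, \eqn{E(e_0^2)=\lambda C_y^2},
#' \eqn{E(e_1^2)=\lambda C_x^2}, \eqn{E(e_0 e_1)=\lambda C_{yx}} with
#' \eqn{\lambda=(1-f)/n}.
#'
#' @param summary A [population_summary()] with nonzero means.
#' @param design A [design_constants()] object.
#' @return An object of class `error_moments`: list with `E_e0sq`, `E_e1sq`,
#'   `E_e0e1` (first moments are identically zero).
#' @export
error_moments <- function(summary, design) {
  stopifnot(inherits(summary, "population_summary"),
            inherits(design, "design_spec"))
  if (is.na(summary$mu_y) || summary$mu_y == 0 ||
      is.na(summary$mu_x) || summary$mu_x == 0)
    stop("relative sampling errors are undefined when a mean is zero")
  error_moments_values(design$lam, summary$C_y^2, summary$C_x^2, summary$C_yx)
}

#' Error moments from raw design constants
#'
#' Low-level constructor used by [error_moments()] and by tests that supply
#' \eqn{\lambda, C_y^2, C_x^2, C_{yx}} directly.
#'
#' @param lam SRSWOR variance factor \eqn{(1-f)/n}.
#' @param C2_y,C2_x Squared coefficients of variation.
#' @param C_yx Relative covariance.
#' @return An `error_moments` object.
#' @export
error_moments_values <- function(lam, C2_y, C2_x, C_yx) {
  m <- list(E_e0 = 0, E_e1 = 0,
            E_e0sq = lam * C2_y, E_e1sq = lam * C2_x, E_e0e1 = lam * C_yx)
  if (m$E_e0sq < 0 || m$E_e1sq < 0)
    stop("second moments must be nonnegative")
  structure(m, class = "error_moments")
}

#' Expectation of a truncated polynomial under the error-moment contract
#'
#' Linear terms vanish; the quadratic coefficients pick up the second-order
#' design moments:
#' \eqn{E(p) = c_{00} + c_{20}E(e_0^2) + c_{11}E(e_0e_1) + c_{02}E(e_1^2)}.
#'
#' @param poly A [tpoly()].
#' @param moments An [error_moments()] object.
#' @return A number.
#' @export
tp_expectation <- function(poly, moments) {
  stopifnot(inherits(moments, "error_moments"))
  p <- unclass(as_tpoly(poly))
  unname(p["c00"] + p["c20"] * moments$E_e0sq +
           p["c11"] * moments$E_e0e1 + p["c02"] * moments$E_e1sq)
}
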