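#' Knot layout for the restricted cubic spline of age
#'
#' The models use age as the timescale and describe the log cumulative hazard
#' as a restricted cubic spline of (log) age. The default layout places
#' boundary knots at 30 and 90 years and internal knots at 60 and 70 years;
#' with `scale = "log_age"` the spline is evaluated in log-years, with the
#' knots mapped through the log.
#'
#' @param boundary_knots numeric length 2, in years.
#' @param internal_knots numeric vector (possibly empty), in years, strictly
#'   inside the boundary knots. An empty vector reduces the spline to its
#'   linear term, i.e. a Weibull baseline when `scale = "log_age"`.
#' @param scale `"log_age"` (default) evaluates the basis in log-years;
#'   `"age"` evaluates it in years.
#' @return An object of class `knot_spec`: list with `knots` (all knots on the
#'   evaluation scale, increasing), `knots_years`, and `scale`.
#' @examples
#' knot_spec()
#' knot_spec(internal_knots = numeric(0))  # Weibull-type baseline
#' @export
knot_spec <- function(boundary_knots = c(30, 90),
                      internal_knots = c(60, 70),
                      scale = c("log_age", "age")) {
  scale <- match.arg(scale)
  if (length(boundary_knots) != 2L || diff(boundary_knots) <= 0)
    stop("`boundary_knots` must be 2 strictly increasing values")
  ky <- sort(c(boundary_knots, internal_knots))
  if (anyDuplicated(ky) || is.unsorted(ky, strictly = TRUE))
    stop("knots must be strictly increasing")
  if (scale == "log_age" && any(ky <= 0))
    stop("all knots must be > 0 when scale = \"log_age\"")
  if (any(internal_knots <= min(boundary_knots)) ||
      any(internal_knots >= max(boundary_knots)))
    stop("internal knots must lie strictly inside the boundary knots")
  k <- if (scale == "log_age") log(ky) else ky
  structure(list(knots = k, knots_years = ky, scale = scale),
            class = "knot_spec")
}

#' @export
print.knot_spec <- function(x, ...) {
  cat("Restricted cubic spline knots (years):",
      paste(x$knots_years, collapse = ", "),
      sprintf("[scale: %s]\n", x$scale))
  invisible(x)
}

## Transform age (years) to the evaluation scale and its derivative d u / d age.
.spline_u <- function(age, spec) {
  if (spec$scale == "log_age") log(age) else age
}
.spline_du <- function(age, spec) {
  if (spec$scale == "log_age") 1 / age else rep(1, length(age))
}

#' Restricted cubic spline basis of age
#'
#' Evaluates the K-1 basis terms ("First", "Second", "Third" for the default
#' four-knot layout) of the restricted truncated-power cubic spline at age `x`
#' (years). Term 1 is the identity on the evaluation scale (age or log age);
#' terms 2..K-1 follow the Durrleman-Simon construction
#' \deqn{v_j(u) = (u-k_j)_+^3 - (u-k_{K-1})_+^3 \frac{k_K-k_j}{k_K-k_{K-1}}
#'              + (u-k_K)_+^3 \frac{k_{K-1}-k_j}{k_K-k_{K-1}},}
#' for j = 1..K-2, which is continuous with continuous first and second
#' derivatives and exactly linear outside the boundary knots. No centering or
#' orthogonalisation is applied, so spline coefficients are on the raw
#' truncated-power scale.
#'
#' @param x ages in years (any positive reals; the basis is defined on all of
#'   the evaluation scale).
#' @param spec a [knot_spec()].
#' @return numeric matrix, `length(x)` rows and K-1 named columns.
#' @examples
#' b <- rcs_basis(c(25, 55, 95), knot_spec(scale = "age"))
#' b[1, -1]  # below the lower boundary knot: nonlinear terms vanish
#' @export
rcs_basis <- function(x, spec) {
  stopifnot(inherits(spec, "knot_spec"))
  u <- .spline_u(x, spec)
  k <- spec$knots
  K <- length(k)
  nt <- K - 1L
  out <- matrix(0, length(u), nt)
  out[, 1L] <- u
  if (K > 2L) {
    kmax <- k[K]; kpen <- k[K - 1L]
    for (j in seq_len(K - 2L)) {
      w <- (kmax - k[j]) / (kmax - kpen)
      out[, j + 1L] <- pmax(u - k[j], 0)^3 -
        w * pmax(u - kpen, 0)^3 +
        (w - 1) * pmax(u - kmax, 0)^3
    }
  }
  colnames(out) <- paste0("rcs", seq_len(nt))
  out
}

#' Derivative of the restricted cubic spline basis with respect to age
#'
#' Returns d/d(age) of each column of [rcs_basis()], including the chain-rule
#' factor for the log-age scale. Needed to convert the fitted cumulative
#' hazard into a hazard, h(t) = H(t) d/dt log H(t).
#'
#' @inheritParams rcs_basis
#' @return numeric matrix matching [rcs_basis()] in shape.
#' @export
rcs_derivative <- function(x, spec) {
  stopifnot(inherits(spec, "knot_spec"))
  u <- .spline_u(x, spec)
  du <- .spline_du(x, spec)
  k <- spec$knots
  K <- length(k)
  nt <- K - 1L
  out <- matrix(0, length(u), nt)
  out[, 1L] <- 1
  if (K > 2L) {
    kmax <- k[K]; kpen <- k[K - 1L]
    for (j in seq_len(K - 2L)) {
      w <- (kmax - k[j]) / (kmax - kpen)
      out[, j + 1L] <- 3 * pmax(u - k[j], 0)^2 -
        3 * w * pmax(u - kpen, 0)^2 +
        3 * (w - 1) * pmax(u - kmax, 0)^2
    }
  }
  out <- out * du
  colnames(out) <- paste0("rcs", seq_len(nt))
  out
}
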