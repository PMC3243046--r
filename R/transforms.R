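#' Transformation specifications
#'
#' A `transform_spec` ties a transformation family to its parameter vector.
#' Supported families and parameters:
#'
#' * `linlog`: `theta > 0`. Linear below `theta`, logarithmic above, with the
#'   two branches joined continuously at `y = theta`.
#' * `arcsinh`: `a >= 0`, `b > 0`, `c >= 0`. Generalized hyperbolic arcsine
#'   `asinh(a + b*y) + c`.
#' * `biexp`: `a, c` in `(0, 1]`, `b, d >= 0`, `w` real, `f` fixed at 0.
#'   The *transformation* is the inverse of the biexponential function
#'   `a*exp(b*(x - w)) - c*exp(-d*(x - w)) + f` (see [biexp_function()]);
#'   it has no closed form and is evaluated by monotone root finding.
#'   `f` is pinned at 0 because the full parameterization is only weakly
#'   identifiable.
#' * `boxcox`: single real `theta`; signed power transform
#'   `sgn(y)*(|y|^theta - 1)/theta`, with the analytic limit
#'   `sgn(y)*log|y|` at `theta = 0`.
#' * `log`, `identity`: parameter-free baselines.
#'
#' @param family one of `"linlog"`, `"arcsinh"`, `"biexp"`, `"boxcox"`,
#'   `"log"`, `"identity"`.
#' @param ... named numeric parameters for the family (see above). Omitted
#'   parameters take the family defaults (`default_spec`).
#' @param f biexponential translation parameter, accepted for completeness
#'   but required to be 0 (it is fixed for identifiability).
#'
#' @return An object of class `transform_spec`: a list with elements
#'   `family` and `params` (named numeric vector).
#' @seealso [forward()], [inverse()], [log_jacobian()], [fit_transform()]
#' @export
#'
#' @examples
#' transform_spec("arcsinh", a = 1, b = 1, c = 0)
#' transform_spec("boxcox", theta = 0.5)
transform_spec <- function(family = c("linlog", "arcsinh", "biexp", "boxcox",
                                      "log", "identity"), ..., f) {
  family <- match.arg(family)
  supplied <- list(...)
  # 'f' is a separate post-dots formal so that `f = 0` is matched exactly
  # rather than partially matching 'family'
  if (!missing(f)) supplied$f <- f
  params <- default_params(family)
  if (length(supplied)) {
    if (is.null(names(supplied)) || any(names(supplied) == "")) {
      stop("transform parameters must be named", call. = FALSE)
    }
    unknown <- setdiff(names(supplied), names(params))
    if (length(unknown)) {
      stop("unknown parameter(s) for family '", family, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    params[names(supplied)] <- vapply(supplied, as.numeric, numeric(1))
  }
  spec <- structure(list(family = family, params = params),
                    class = "transform_spec")
  validate_spec(spec)
  spec
}

default_params <- function(family) {
  switch(family,
    linlog   = c(theta = 1),
    arcsinh  = c(a = 1, b = 1, c = 0),
    # flowCore-style defaults; f is always 0 (identifiability constraint)
    biexp    = c(a = 0.5, b = 1, c = 0.5, d = 1, f = 0, w = 0),
    boxcox   = c(theta = 1),
    log      = numeric(0),
    identity = numeric(0))
}

#' @rdname transform_spec
#' @export
default_spec <- function(family) {
  do.call(transform_spec, c(list(family = family)))
}

validate_spec <- function(spec) {
  p <- spec$params
  if (any(!is.finite(p))) stop("transform parameters must be finite",
                               call. = FALSE)
  switch(spec$family,
    linlog = if (p[["theta"]] <= 0)
      stop("linlog requires theta > 0", call. = FALSE),
    arcsinh = {
      if (p[["a"]] < 0 || p[["c"]] < 0)
        stop("arcsinh requires a >= 0 and c >= 0", call. = FALSE)
      if (p[["b"]] <= 0)
        stop("arcsinh requires b > 0", call. = FALSE)
    },
    biexp = {
      if (p[["a"]] <= 0 || p[["a"]] > 1 || p[["c"]] <= 0 || p[["c"]] > 1)
        stop("biexp requires a, c in (0, 1]", call. = FALSE)
      if (p[["b"]] < 0 || p[["d"]] < 0)
        stop("biexp requires b, d >= 0", call. = FALSE)
      if (p[["f"]] != 0)
        stop("biexp translation parameter f is fixed at 0", call. = FALSE)
    },
    boxcox = NULL, log = NULL, identity = NULL)
  invisible(spec)
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("transform_spec:", x$family, "\n")
  if (length(x$params)) {
    cat(paste(sprintf("  %s = %g", names(x$params), x$params),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Biexponential function (closed form)
#'
#' Evaluates `a*exp(b*(x - w)) - c*exp(-d*(x - w)) + f`. In flow cytometry
#' usage this closed form is the *inverse* of the biexponential
#' transformation: it maps the transformed (display) scale back to raw
#' intensities, and it is also the map used to corrupt simulated data
#' ("inverse-biexponential transformation"). It is strictly increasing
#' whenever `a*b > 0` or `c*d > 0`.
#'
#' Exponents are clamped at +/-700 so extreme arguments saturate instead of
#' overflowing to `Inf`.
#'
#' @param params named numeric vector or `transform_spec` with elements
#'   `a, b, c, d, f, w`.
#' @param x numeric vector/matrix of values on the transformed scale.
#' @return numeric of the same shape as `x`.
#' @export
#'
#' @examples
#' biexp_function(c(a = 1, b = 1, c = 1, d = 1, f = 0, w = 0), 0)  # 2*sinh(0)
biexp_function <- function(params, x) {
  p <- biexp_pars(params)
  u <- x - p[["w"]]
  p[["a"]] * exp(pmin(p[["b"]] * u, 700)) -
    p[["c"]] * exp(pmin(-p[["d"]] * u, 700)) + p[["f"]]
}

# derivative of the biexponential function w.r.t. x
biexp_function_deriv <- function(params, x) {
  p <- biexp_pars(params)
  u <- x - p[["w"]]
  p[["a"]] * p[["b"]] * exp(pmin(p[["b"]] * u, 700)) +
    p[["c"]] * p[["d"]] * exp(pmin(-p[["d"]] * u, 700))
}

biexp_pars <- function(params) {
  if (inherits(params, "transform_spec")) params <- params$params
  need <- c("a", "b", "c", "d", "f", "w")
  miss <- setdiff(need, names(params))
  if (length(miss)) {
    params <- c(params, stats::setNames(rep(0, length(miss)), miss))
  }
  params[need]
}

# Monotone inversion of the biexponential function: solve g(x) = y for x.
# Start from a closed-form approximation (exact when b == d), then run
# bracket-safeguarded Newton; g is smooth and strictly increasing so the
# root is unique. Convergence is declared on the residual in y,
# |g(x) - y| / max(1, |y|) < tol, which bounds the roundtrip error of the
# forward transform directly.
solve_biexp <- function(params, y, tol = 3e-13, max_iter = 200L,
                        x0 = NULL) {
  p <- biexp_pars(params)
  a <- p[["a"]]; b <- p[["b"]]; cc <- p[["c"]]; d <- p[["d"]]
  w <- p[["w"]]; f <- p[["f"]]
  if (a * b <= 0 && cc * d <= 0) {
    stop("biexponential function is not strictly increasing for these ",
         "parameters (need a*b > 0 or c*d > 0)", call. = FALSE)
  }
  g <- function(x) biexp_function(p, x)
  ylo <- min(y); yhi <- max(y)
  # expand a global bracket [w - r, w + r] covering all y
  r <- 1
  while ((g(w + r) < yhi || g(w - r) > ylo) && r < 1e7) r <- r * 2
  if (g(w + r) < yhi || g(w - r) > ylo) {
    stop(sprintf(paste0("biexponential inversion failed: target outside ",
                        "attainable range (y in [%g, %g], range [%g, %g])"),
                 ylo, yhi, g(w - r), g(w + r)), call. = FALSE)
  }
  # per-element brackets from one-sided exponential bounds: for u >= 0,
  # c >= c*e^{-d*u} >= 0 sandwiches the root below log((y-f+c)/a)/b and
  # above 0 (and symmetrically for u < 0), always containing the root
  gw <- a - cc + f  # g at x = w
  tiny <- 1e-12
  u_hi <- ifelse(y > gw,
                 log(pmax((y - f + cc) / a, 1)) / max(b, tiny), 0)
  u_lo <- ifelse(y < gw,
                 -log(pmax((f - y + a) / cc, 1)) / max(d, tiny), 0)
  lo <- pmax(w + u_lo, w - r)
  hi <- pmin(w + u_hi, w + r)
  if (is.null(x0) || length(x0) != length(y)) {
    # start on the dominant-exponential side: above the root where the
    # positive exponential dominates (g convex there) and below it where
    # the negative exponential dominates (g concave), so Newton converges
    # monotonically
    x0 <- ifelse(y >= gw, hi, lo)
  }
  x <- pmin(pmax(x0, lo), hi)
  # active-set safeguarded Newton: converged elements drop out so late
  # iterations only touch the stragglers
  act <- seq_along(y)
  for (i in seq_len(max_iter)) {
    fa <- g(x[act]) - y[act]
    res <- abs(fa) / pmax(1, abs(y[act]))
    stalled <- (hi[act] - lo[act]) < 1e-14 * pmax(1, abs(x[act]))
    conv <- res < tol | (stalled & res < 1e-9)
    if (any(conv)) {
      act <- act[!conv]
      if (!length(act)) break
      fa <- fa[!conv]
    }
    below <- fa < 0
    lo[act[below]] <- x[act[below]]
    hi[act[!below]] <- x[act[!below]]
    step <- fa / pmax(biexp_function_deriv(p, x[act]),
                      .Machine$double.xmin)
    xn <- x[act] - step
    bad <- !is.finite(xn) | xn <= lo[act] | xn >= hi[act]
    xn[bad] <- 0.5 * (lo[act[bad]] + hi[act[bad]])
    x[act] <- xn
  }
  if (length(act)) {
    stop(sprintf(paste0("biexponential inversion did not converge in %d ",
                        "iterations (%d values unconverged, worst ",
                        "relative residual %.3g)"),
                 max_iter, length(act),
                 max(abs(g(x[act]) - y[act]) / pmax(1, abs(y[act])))),
         call. = FALSE)
  }
  x
}

#' Forward transformation
#'
#' Applies the transformation `f(y; theta)` of a [transform_spec()]
#' elementwise. All families are strictly increasing on their admissible
#' domains. The biexponential forward has no closed form and is computed by
#' monotone root finding on [biexp_function()].
#'
#' @param spec a [transform_spec()].
#' @param y numeric vector, matrix or [event_matrix()] of raw intensities.
#' @return transformed values with the shape of `y` (an `event_matrix` in,
#'   an `event_matrix` out).
#' @export
#'
#' @examples
#' forward(transform_spec("boxcox", theta = 1), 5)   # y - 1 = 4
#' forward(transform_spec("arcsinh"), 0)             # log(1 + sqrt(2))
forward <- function(spec, y) {
  apply_elementwise(spec, y, function(s, v) forward_num(s, v))
}

forward_num <- function(spec, y) {
  if (any(!is.finite(y))) stop("non-finite input to forward()", call. = FALSE)
  p <- spec$params
  switch(spec$family,
    identity = y,
    log = {
      if (any(y <= 0)) stop("log transform requires y > 0", call. = FALSE)
      log(y)
    },
    linlog = {
      th <- p[["theta"]]
      out <- (y - th) / th + log(th)
      up <- y > th
      out[up] <- log(y[up])
      out
    },
    arcsinh = asinh(p[["a"]] + p[["b"]] * y) + p[["c"]],
    boxcox = boxcox_forward(p[["theta"]], y),
    biexp = solve_biexp(p, y))
}

boxcox_forward <- function(theta, y) {
  ay <- abs(y)
  if (theta == 0) return(sign(y) * log(ay))
  # expm1 keeps the theta -> 0 limit numerically exact
  sign(y) * expm1(theta * log(ay)) / theta
}

#' Inverse transformation
#'
#' Inverse of [forward()]: `inverse(spec, forward(spec, y)) == y` on the
#' admissible domain of the family (for the generalized Box-Cox the printed
#' inverse is the true inverse on `y > 0` only; the signed forward is not
#' globally invertible around zero). For the biexponential family the
#' inverse is the closed-form [biexp_function()] itself.
#'
#' @inheritParams forward
#' @param x numeric values on the transformed scale.
#' @return values on the raw scale.
#' @export
inverse <- function(spec, x) {
  apply_elementwise(spec, x, function(s, v) inverse_num(s, v))
}

inverse_num <- function(spec, x) {
  p <- spec$params
  switch(spec$family,
    identity = x,
    log = exp(x),
    linlog = {
      th <- p[["theta"]]
      out <- th * (x - log(th) + 1)
      up <- x >= log(th)
      out[up] <- exp(x[up])
      out
    },
    arcsinh = (sinh(x - p[["c"]]) - p[["a"]]) / p[["b"]],
    boxcox = {
      th <- p[["theta"]]
      if (th == 0) exp(x) else {
        u <- th * x + 1
        sign(u) * abs(u)^(1 / th)
      }
    },
    biexp = biexp_function(p, x))
}

#' Log-Jacobian of a transformation
#'
#' Natural log of the derivative `df/dy` of [forward()], the change-of-scale
#' term that makes likelihoods comparable across transformation parameters.
#' Computed in log space so products over many events do not underflow.
#'
#' For the biexponential family the Jacobian is
#' `1 / (a*b*exp(b*(x - w)) + c*d*exp(-d*(x - w)))` evaluated at
#' `x = forward(y)`.
#'
#' @inheritParams forward
#' @return `log J_theta(y)`, same shape as `y`.
#' @export
#'
#' @examples
#' log_jacobian(transform_spec("linlog", theta = 2), 1)  # log(1/2)
log_jacobian <- function(spec, y) {
  apply_elementwise(spec, y, function(s, v) log_jacobian_num(s, v))
}

log_jacobian_num <- function(spec, y) {
  if (any(!is.finite(y))) stop("non-finite input to log_jacobian()",
                               call. = FALSE)
  p <- spec$params
  switch(spec$family,
    identity = rep(0, length(y)),
    log = -log(y),
    linlog = {
      th <- p[["theta"]]
      out <- rep(-log(th), length(y))
      up <- y > th
      out[up] <- -log(y[up])
      out
    },
    arcsinh = log(p[["b"]]) - 0.5 * log1p((p[["a"]] + p[["b"]] * y)^2),
    boxcox = {
      th <- p[["theta"]]
      if (th != 1 && any(y == 0)) {
        stop("boxcox Jacobian undefined at y = 0 for theta != 1",
             call. = FALSE)
      }
      (th - 1) * log(abs(y))
    },
    biexp = {
      x <- solve_biexp(p, y)
      -log(biexp_function_deriv(p, x))
    })
}

apply_elementwise <- function(spec, y, fn) {
  stopifnot(inherits(spec, "transform_spec"))
  if (inherits(y, "event_matrix")) {
    v <- em_values(y)
    out <- matrix(fn(spec, as.vector(v)), nrow = nrow(v),
                  dimnames = dimnames(v))
    return(event_matrix(out, sample_id = sample_id(y)))
  }
  if (is.matrix(y)) {
    return(matrix(fn(spec, as.vector(y)), nrow = nrow(y),
                  dimnames = dimnames(y)))
  }
  fn(spec, y)
}

#' Read and write transformation specs as plain text
#'
#' A fitted spec can be serialized to a small `key: value` text file and
#' re-applied bit-identically (full `%.17g` precision).
#'
#' @param spec a [transform_spec()].
#' @param path file path.
#' @return `read_transform_spec` returns a [transform_spec()];
#'   `write_transform_spec` returns `path` invisibly.
#' @export
write_transform_spec <- function(spec, path) {
  stopifnot(inherits(spec, "transform_spec"))
  lines <- c(paste0("family: ", spec$family),
             sprintf("%s: %.17g", names(spec$params), spec$params))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform_spec
#' @export
read_transform_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  fam <- vals[keys == "family"]
  if (length(fam) != 1) stop("spec file must contain one 'family' line",
                             call. = FALSE)
  pars <- as.list(as.numeric(vals[keys != "family"]))
  names(pars) <- keys[keys != "family"]
  do.call(transform_spec, c(list(family = fam), pars))
}
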