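#' Parametric hazard specification
#'
#' A small container for a parametric time-to-event distribution used to
#' drive transition probabilities. Three families are supported, each
#' parameterised on the time scale of years:
#'
#' * `exponential`: constant hazard, `params = c(rate)`,
#'   cumulative hazard \eqn{H(t) = \lambda t};
#' * `weibull`: `params = c(shape, scale)` (the [stats::rweibull]
#'   parameterisation), \eqn{H(t) = (t/b)^a};
#' * `gompertz`: `params = c(shape, rate)` (the flexsurv parameterisation),
#'   \eqn{H(t) = (r/a)(e^{a t} - 1)}; `shape` may be negative but not zero
#'   (use `exponential` for the zero-shape limit).
#'
#' @param family one of `"exponential"`, `"weibull"`, `"gompertz"`.
#' @param params named or positional numeric vector of parameters (see
#'   above); rates, shapes (weibull) and scales must be strictly positive.
#' @return an object of class `hazard_spec`.
#' @examples
#' h <- hazard_spec("exponential", c(rate = 0.2))
#' cum_hazard(h, 0:3)
#' @export
hazard_spec <- function(family = c("exponential", "weibull", "gompertz"),
                        params) {
  family <- match.arg(family)
  params <- as.numeric(params)
  npar <- c(exponential = 1L, weibull = 2L, gompertz = 2L)[[family]]
  if (length(params) != npar || anyNA(params)) {
    stop("'", family, "' requires ", npar, " finite parameter(s)",
         call. = FALSE)
  }
  names(params) <- switch(family,
    exponential = "rate",
    weibull = c("shape", "scale"),
    gompertz = c("shape", "rate")
  )
  ok <- switch(family,
    exponential = params[["rate"]] > 0,
    weibull = all(params > 0),
    gompertz = params[["rate"]] > 0 && params[["shape"]] != 0
  )
  if (!ok) stop("invalid parameters for ", family, " hazard", call. = FALSE)
  structure(list(family = family, params = params), class = "hazard_spec")
}

#' Cumulative hazard of a parametric specification
#'
#' @param spec a [hazard_spec].
#' @param t non-negative times (years).
#' @return \eqn{H(t)}, same length as `t`.
#' @export
cum_hazard <- function(spec, t) {
  stopifnot(inherits(spec, "hazard_spec"), all(t >= 0))
  p <- spec$params
  switch(spec$family,
    exponential = p[["rate"]] * t,
    weibull = (t / p[["scale"]])^p[["shape"]],
    gompertz = p[["rate"]] / p[["shape"]] * (exp(p[["shape"]] * t) - 1)
  )
}

# Proportional-hazards scaling: multiply the cumulative hazard by `hr`.
scale_hazard <- function(spec, hr) {
  stopifnot(inherits(spec, "hazard_spec"), is.numeric(hr), hr > 0)
  p <- spec$params
  switch(spec$family,
    exponential = hazard_spec("exponential", c(rate = p[["rate"]] * hr)),
    weibull = hazard_spec("weibull", c(
      shape = p[["shape"]],
      scale = p[["scale"]] * hr^(-1 / p[["shape"]])
    )),
    gompertz = hazard_spec("gompertz", c(
      shape = p[["shape"]], rate = p[["rate"]] * hr
    ))
  )
}

#' @export
print.hazard_spec <- function(x, ...) {
  cat("<hazard_spec> ", x$family, ": ",
      paste(names(x$params), signif(x$params, 6), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
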