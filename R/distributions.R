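#' Distribution specifications for uncertain parameters
#'
#' Each uncertain parameter carries a point value (the base case) and,
#' optionally, a probability distribution used by the probabilistic
#' sensitivity analysis: lognormal for costs, beta for probabilities, gamma
#' for household income, and normal (truncated at zero) for strategy relative
#' risks. `dist_spec()` builds and validates one specification.
#'
#' Parameterisation: lognormal `(p1, p2) = (meanlog, sdlog)`; beta
#' `(alpha, beta)`; gamma `(shape, scale)`; normal `(mean, variance)`.
#' A `point` family has no distribution and always returns its point value.
#'
#' @param family One of `"point"`, `"lognormal"`, `"beta"`, `"gamma"`,
#'   `"normal"`.
#' @param p1,p2 Distribution parameters (ignored for `family = "point"`).
#' @param point Base-case point value.
#' @return A list of class `hef_dist` with fields `family`, `p1`, `p2`,
#'   `point`.
#' @examples
#' dist_spec("lognormal", 3.245, 0.406, point = 27.86)
#' dist_spec("point", point = 0.37)
#' @export
dist_spec <- function(family = "point", p1 = NA_real_, p2 = NA_real_, point) {
  family <- match.arg(family, c("point", "lognormal", "beta", "gamma", "normal"))
  if (!is.numeric(point) || length(point) != 1 || is.na(point)) {
    stop("`point` must be a single numeric value", call. = FALSE)
  }
  if (family %in% c("lognormal", "gamma") && (is.na(p2) || p2 <= 0)) {
    stop(sprintf("%s spec requires p2 > 0", family), call. = FALSE)
  }
  if (family == "beta" && (is.na(p1) || is.na(p2) || p1 <= 0 || p2 <= 0)) {
    stop("beta spec requires p1 > 0 and p2 > 0", call. = FALSE)
  }
  if (family == "normal" && (is.na(p2) || p2 < 0)) {
    stop("normal spec requires variance p2 >= 0", call. = FALSE)
  }
  structure(
    list(family = family, p1 = as.numeric(p1), p2 = as.numeric(p2),
         point = as.numeric(point)),
    class = "hef_dist"
  )
}

#' @export
print.hef_dist <- function(x, ...) {
  if (x$family == "point") {
    cat(sprintf("<dist: point %g>\n", x$point))
  } else {
    cat(sprintf("<dist: %s(%g, %g), point %g>\n", x$family, x$p1, x$p2, x$point))
  }
  invisible(x)
}

#' Draw from a parameter's probability distribution
#'
#' Draws `n` values from the distribution of a [dist_spec()]. Point-mass
#' specifications return the point value; normal draws are truncated at zero
#' (negative relative risks are meaningless); `p2` of a normal spec is a
#' variance, matching how strategy-effect uncertainty is specified.
#'
#' @param spec A `hef_dist` specification.
#' @param n Number of draws.
#' @return Numeric vector of length `n`. Reproducible under `set.seed()`.
#' @examples
#' set.seed(1)
#' mean(sample_parameter(dist_spec("beta", 8.241, 14.057, point = 0.37), 1e4))
#' @export
sample_parameter <- function(spec, n = 1) {
  stopifnot(inherits(spec, "hef_dist"), n >= 1)
  switch(spec$family,
    point = rep(spec$point, n),
    lognormal = rlnorm(n, meanlog = spec$p1, sdlog = spec$p2),
    beta = rbeta(n, spec$p1, spec$p2),
    gamma = rgamma(n, shape = spec$p1, scale = spec$p2),
    normal = pmax(rnorm(n, mean = spec$p1, sd = sqrt(spec$p2)), 0)
  )
}

#' Analytic mean of a parameter distribution
#'
#' Closed-form mean of the distribution in a [dist_spec()] (lognormal
#' `exp(mu + sigma^2/2)`, beta `a/(a+b)`, gamma `shape * scale`, normal
#' `mean`). Used to audit the registry: a distribution whose mean strays from
#' its own point value signals a transcription inconsistency.
#'
#' @param spec A `hef_dist` specification.
#' @return The distribution mean (the point value for a point spec).
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "hef_dist"))
  switch(spec$family,
    point = spec$point,
    lognormal = exp(spec$p1 + spec$p2^2 / 2),
    beta = spec$p1 / (spec$p1 + spec$p2),
    gamma = spec$p1 * spec$p2,
    normal = spec$p1
  )
}

## internal: coerce a YAML node (scalar or {point, family, p1, p2} map) to a
## hef_dist; bare scalars become point masses.
as_dist <- function(x, name) {
  if (inherits(x, "hef_dist")) return(x)
  if (is.numeric(x) && length(x) == 1) return(dist_spec("point", point = x))
  if (is.list(x) && !is.null(x$point)) {
    fam <- if (is.null(x$family)) "point" else x$family
    return(dist_spec(fam, p1 = x$p1 %||% NA_real_, p2 = x$p2 %||% NA_real_,
                     point = x$point))
  }
  stop(sprintf("cannot interpret parameter '%s' as a value or distribution", name),
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
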