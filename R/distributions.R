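#' Distribution specification
#'
#' A small container for the input models the Monte Carlo engine draws from.
#' Supported families: `"point"` (a degenerate constant), `"normal"`,
#' `"lognormal"`, and any of these with optional truncation bounds in natural
#' units (truncation is applied by rejection sampling).
#'
#' @param family One of `"point"`, `"normal"`, `"lognormal"`.
#' @param ... Family parameters: `value` for point; `mean`, `sd` for normal;
#'   `meanlog`, `sdlog` for lognormal.
#' @param lower,upper Optional truncation bounds (natural units); must satisfy
#'   `lower < upper` and leave nonzero mass.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("lognormal", meanlog = log(43.4), sdlog = 0.4)
#' dist_spec("point", value = 60)
#' @export
dist_spec <- function(family = c("point", "normal", "lognormal"),
                      ..., lower = NULL, upper = NULL) {
  family <- match.arg(family)
  params <- list(...)
  switch(family,
    point = {
      if (is.null(params$value) || !is.finite(params$value))
        stop("point distribution needs a finite 'value'", call. = FALSE)
    },
    normal = {
      if (is.null(params$mean) || is.null(params$sd) || params$sd < 0)
        stop("normal distribution needs 'mean' and 'sd' >= 0", call. = FALSE)
    },
    lognormal = {
      if (is.null(params$meanlog) || is.null(params$sdlog) || params$sdlog < 0)
        stop("lognormal distribution needs 'meanlog' and 'sdlog' >= 0",
             call. = FALSE)
    }
  )
  if (!is.null(lower) && !is.null(upper) && lower >= upper) {
    stop("truncation bounds must satisfy lower < upper", call. = FALSE)
  }
  structure(list(family = family, params = params,
                 lower = lower, upper = upper),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- paste(names(x$params), signif(unlist(x$params), 6),
             sep = " = ", collapse = ", ")
  cat("<dist_spec> ", x$family, "(", p, ")", sep = "")
  if (!is.null(x$lower) || !is.null(x$upper)) {
    cat(" truncated to [", x$lower %||% "-Inf", ", ",
        x$upper %||% "Inf", "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a lognormal model to a geometric-mean / arithmetic-SD summary
#'
#' Survey reports often publish only the geometric mean (GM) and the
#' arithmetic standard deviation (SD) of a right-skewed concentration
#' distribution. This fits the lognormal whose geometric mean equals `gm`
#' (i.e. log-scale location mu = log(gm)) and whose arithmetic SD equals
#' `sd`, by solving the moment equation
#' \deqn{sd^2 = (e^{\sigma^2} - 1)\, e^{2\mu + \sigma^2}}
#' for the log-scale sigma. The right-hand side is strictly increasing in
#' sigma, so the root is found by monotone root-finding (bisection via
#' [stats::uniroot()]); a solution exists for every `sd > 0`.
#'
#' @param gm Geometric mean (> 0), natural units.
#' @param sd Arithmetic standard deviation (>= 0), same units. `sd = 0`
#'   degenerates to a point mass at `gm`.
#' @param lower,upper Optional truncation bounds passed to [dist_spec()]
#'   (e.g. an observed min--max range). Truncation perturbs the matched
#'   moments and is therefore off by default.
#' @param tol Relative convergence tolerance for the root.
#' @return A `dist_spec`: lognormal (or point when `sd = 0`).
#' @examples
#' fit_lognormal(gm = 15.5, sd = 16.0)   # national Cd model
#' @export
fit_lognormal <- function(gm, sd, lower = NULL, upper = NULL, tol = 1e-12) {
  if (!is.finite(gm) || gm <= 0) stop("gm must be > 0", call. = FALSE)
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (sd == 0) {
    return(dist_spec("point", value = gm))
  }
  mu <- log(gm)
  f <- function(sigma) {
    (exp(sigma^2) - 1) * exp(2 * mu + sigma^2) - sd^2
  }
  # Bracket: f(0) = -sd^2 < 0; grow the upper bound until positive.
  hi <- 1
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 64) stop("no positive sigma solves the moment equation",
                      call. = FALSE)  # defensive; unreachable for sd > 0
  }
  sigma <- stats::uniroot(f, c(0, hi), tol = tol * max(1, hi))$root
  dist_spec("lognormal", meanlog = mu, sdlog = sigma,
            lower = lower, upper = upper)
}

#' Analytic moments of a distribution specification
#'
#' Untruncated closed-form mean, SD and median; used for convergence checks
#' and for reporting the model a summary was fitted to.
#'
#' @param spec A `dist_spec`.
#' @return Named numeric vector `c(mean, sd, median)`.
#' @export
dist_moments <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
    point = c(mean = p$value, sd = 0, median = p$value),
    normal = c(mean = p$mean, sd = p$sd, median = p$mean),
    lognormal = {
      m <- exp(p$meanlog + p$sdlog^2 / 2)
      s <- sqrt((exp(p$sdlog^2) - 1)) * m
      c(mean = m, sd = s, median = exp(p$meanlog))
    }
  )
}

# Raw (untruncated) sampler for one family.
dist_draw_raw <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
    point = rep(p$value, n),
    normal = stats::rnorm(n, p$mean, p$sd),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog)
  )
}

#' Draw from a distribution specification
#'
#' Truncation (and, for families with real support, the implicit lower bound
#' at zero for positive quantities drawn with `positive = TRUE`) is enforced
#' by rejection: out-of-bounds draws are resampled until `n` valid values are
#' obtained, so the result is the properly renormalised truncated law.
#'
#' Seeding is the caller's responsibility ([generate_samples()] and
#' [edi_mcs()] manage per-stream seeds).
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @param positive Require strictly positive draws (resampling any others).
#' @return Numeric vector of length `n`.
#' @export
dist_draw <- function(spec, n, positive = FALSE) {
  stopifnot(inherits(spec, "dist_spec"), n >= 0)
  lo <- spec$lower %||% -Inf
  hi <- spec$upper %||% Inf
  if (positive) lo <- max(lo, 0)
  x <- dist_draw_raw(spec, n)
  if (spec$family == "point") {
    if (any(x < lo | x > hi) || (positive && any(x <= 0))) {
      stop("point value violates truncation/positivity bounds", call. = FALSE)
    }
    return(x)
  }
  bad <- which(x < lo | x > hi | (positive & x <= 0))
  tries <- 0L
  while (length(bad) > 0) {
    tries <- tries + 1L
    if (tries > 1000L) {
      stop("truncation bounds admit too little mass to sample", call. = FALSE)
    }
    x[bad] <- dist_draw_raw(spec, length(bad))
    bad <- bad[x[bad] < lo | x[bad] > hi | (positive & x[bad] <= 0)]
  }
  x
}
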