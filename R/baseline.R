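#' Baseline hazard specifications
#'
#' Parametric baseline hazards for the recurrence and death submodels:
#' Weibull, with hazard \eqn{h_0(t) = (k/\lambda)(t/\lambda)^{k-1}} and
#' cumulative hazard \eqn{\Lambda_0(t) = (t/\lambda)^k}, or piecewise
#' constant on intervals defined by interior cut points (the last rate
#' extends to infinity).
#'
#' @param shape Weibull shape k > 0.
#' @param scale Weibull scale lambda > 0 (years).
#' @return an object of class `jf_baseline`.
#' @name baseline
NULL

#' @rdname baseline
#' @export
weibull_baseline <- function(shape, scale) {
  stopifnot(is.numeric(shape), length(shape) == 1L, shape > 0,
            is.numeric(scale), length(scale) == 1L, scale > 0)
  structure(list(family = "weibull", shape = shape, scale = scale),
            class = c("jf_weibull", "jf_baseline"))
}

#' @rdname baseline
#' @param cuts increasing interior cut points (> 0); may be empty.
#' @param rates nonnegative rates, one per interval (`length(cuts) + 1`).
#' @export
piecewise_baseline <- function(cuts, rates) {
  cuts <- as.numeric(cuts)
  rates <- as.numeric(rates)
  stopifnot(all(rates >= 0), length(rates) == length(cuts) + 1L)
  if (length(cuts)) stopifnot(all(cuts > 0), !is.unsorted(cuts, strictly = TRUE))
  structure(list(family = "piecewise_constant", cuts = cuts, rates = rates),
            class = c("jf_piecewise", "jf_baseline"))
}

#' Baseline hazard and cumulative hazard
#'
#' @param spec a `jf_baseline` object.
#' @param t nonnegative times (years).
#' @return hazard (or cumulative hazard) values at `t`.
#' @export
baseline_hazard <- function(spec, t) {
  stopifnot(inherits(spec, "jf_baseline"), all(t >= 0))
  exp(log_baseline_hazard(spec, t))
}

# log h0(t); t > 0 required for weibull when shape != 1.
log_baseline_hazard <- function(spec, t) {
  if (inherits(spec, "jf_weibull")) {
    k <- spec$shape
    log(k) - k * log(spec$scale) + (k - 1) * log(t)
  } else {
    log(spec$rates)[findInterval(t, spec$cuts) + 1L]
  }
}

#' @rdname baseline_hazard
#' @export
cumulative_baseline_hazard <- function(spec, t) {
  stopifnot(inherits(spec, "jf_baseline"))
  if (any(t < 0)) stop("negative time in cumulative_baseline_hazard()")
  if (inherits(spec, "jf_weibull")) {
    (t / spec$scale)^spec$shape
  } else {
    bounds <- c(0, spec$cuts)
    # cum[j] = Lambda at bounds[j]
    cum <- c(0, cumsum(spec$rates[seq_len(length(bounds) - 1L)] * diff(bounds)))
    j <- findInterval(t, bounds)
    cum[j] + spec$rates[j] * (t - bounds[j])
  }
}

# Inverse of the cumulative hazard; returns Inf where y exceeds the total
# mass (possible when trailing piecewise rates are 0).  Used by the
# simulator's inverse-transform sampling.
inverse_cumulative_baseline_hazard <- function(spec, y) {
  stopifnot(inherits(spec, "jf_baseline"), all(y >= 0))
  if (inherits(spec, "jf_weibull")) {
    spec$scale * y^(1 / spec$shape)
  } else {
    nseg <- length(spec$rates)
    bounds <- c(0, spec$cuts)
    mass <- spec$rates * c(diff(bounds), Inf)
    mass[nseg] <- if (spec$rates[nseg] > 0) Inf else 0
    cum <- c(0, cumsum(mass))  # Lambda at bounds (and total at the end)
    # rightmost segment whose start mass is <= y; zero-rate segments have
    # equal consecutive cum values and are skipped by findInterval
    j <- findInterval(y, cum)
    jj <- pmin(j, nseg)
    ifelse(j > nseg | spec$rates[jj] == 0, Inf,
           bounds[jj] + (y - cum[jj]) / spec$rates[jj])
  }
}

# Number of free parameters / pack to and unpack from the unconstrained
# (log) estimation scale.
n_baseline_par <- function(spec) {
  if (inherits(spec, "jf_weibull")) 2L else length(spec$rates)
}

pack_baseline <- function(spec) {
  if (inherits(spec, "jf_weibull")) log(c(spec$shape, spec$scale))
  else log(pmax(spec$rates, 1e-10))
}

unpack_baseline <- function(template, logpar) {
  if (inherits(template, "jf_weibull"))
    weibull_baseline(exp(logpar[1]), exp(logpar[2]))
  else piecewise_baseline(template$cuts, exp(logpar))
}

baseline_par_names <- function(spec, prefix) {
  if (inherits(spec, "jf_weibull")) paste0(prefix, c("log_shape", "log_scale"))
  else paste0(prefix, "log_rate", seq_along(spec$rates))
}

#' @export
print.jf_baseline <- function(x, ...) {
  if (inherits(x, "jf_weibull"))
    cat(sprintf("Weibull baseline: shape %.4g, scale %.4g years\n",
                x$shape, x$scale))
  else
    cat("Piecewise-constant baseline:\n  cuts:", x$cuts,
        "\n  rates:", signif(x$rates, 4), "\n")
  invisible(x)
}
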