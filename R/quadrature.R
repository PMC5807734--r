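#' Generalized Gauss-Laguerre quadrature rule
#'
#' Nodes and (normalized) log-weights for integrals of the form
#' \eqn{\int_0^\infty f(x) x^{a} e^{-x} dx}, computed by the Golub-Welsch
#' algorithm on the symmetric tridiagonal Jacobi matrix of the generalized
#' Laguerre polynomials.
#'
#' Weights are returned on the log scale, normalized so that
#' `sum(exp(logw)) == 1`; the raw rule is recovered by adding
#' `lgamma(a + 1)` to `logw`.  With this normalization the rule computes
#' expectations under a Gamma(shape `a + 1`, rate 1) density exactly for
#' polynomial integrands up to degree `2n - 1`.
#'
#' @param n number of nodes (>= 2).
#' @param a generalized Laguerre exponent, must be > -1.
#' @return list with `nodes` (increasing, positive), `logw`
#'   (normalized log-weights), `a`, `n`.
#' @examples
#' r <- gauss_laguerre(16, 0)
#' sum(exp(r$logw) * r$nodes)  # mean of Exp(1) = 1
#' @export
gauss_laguerre <- function(n, a = 0) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2,
            is.numeric(a), length(a) == 1L, a > -1)
  n <- as.integer(n)
  k <- seq_len(n) - 1
  diag_ <- 2 * k + a + 1
  off <- sqrt(seq_len(n - 1) * (seq_len(n - 1) + a))
  J <- diag(diag_, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  eig <- eigen(J, symmetric = TRUE)
  ord <- order(eig$values)
  list(nodes = eig$values[ord],
       logw = 2 * log(abs(eig$vectors[1, ord])),
       a = a, n = n)
}

#' Quadrature rule for expectations over a mean-one gamma frailty
#'
#' Builds a rule whose nodes `u` and normalized log-weights `logw` satisfy
#' \eqn{E[f(u)] \approx \sum_q w_q f(u_q)} for `u ~ Gamma(shape 1/theta,
#' scale theta)` (mean 1, variance `theta`).  The gamma kernel is absorbed
#' into the generalized Laguerre weight, so the normalization
#' \eqn{\int g(u; \theta) du = 1} holds to machine precision for any node
#' count.
#'
#' @param theta frailty variance, > 0.
#' @param nodes number of quadrature nodes (>= 8 recommended).
#' @return list with `u` (nodes on the frailty scale), `logw`, `theta`.
#' @export
frailty_quadrature <- function(theta, nodes = 32) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0, nodes >= 2)
  r <- gauss_laguerre(nodes, 1 / theta - 1)
  list(u = theta * r$nodes, logw = r$logw, theta = theta, n = r$n)
}

#' Gauss-Hermite quadrature rule
#'
#' Nodes and log-weights for \eqn{\int f(z) e^{-z^2} dz} (physicists'
#' convention), by Golub-Welsch.  Used as the backbone of the adaptive
#' quadrature of frailty integrals on the log scale.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `logw` (`sum(exp(logw)) = sqrt(pi)`).
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 2)
  n <- as.integer(n)
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  eig <- eigen(J, symmetric = TRUE)
  ord <- order(eig$values)
  list(nodes = eig$values[ord],
       logw = log(sqrt(pi)) + 2 * log(abs(eig$vectors[1, ord])),
       n = n)
}

# log of I(a, b, c, alpha) = int_0^inf u^(a-1) exp(-b u - c u^alpha) du,
# vectorized over (a, b, c).  This is the frailty integral of every
# subject likelihood contribution and of the dynamic-prediction ratios.
#
# Exact closed forms are used when c = 0 or alpha is 0 or 1.  Otherwise:
#
# method "fixed" (used inside the optimizer, where millions of these are
# evaluated): generalized Gauss-Laguerre with the algebraic factor
# u^(a-1) absorbed exactly into the weight, nodes shared across subjects
# with equal shape a, and the rate matched per subject to the mode u* of
# the full integrand (found by damped Newton on the log scale, where the
# integrand is strictly concave).  Relative accuracy is typically 1e-6
# to 1e-10 and worst-case about 1e-4 near the non-smooth corner alpha in
# (0, 1.5) - ample for likelihood optimization.
#
# method "adaptive" (used by the exposed per-subject likelihood and the
# prediction operations): adaptive quadrature of the smooth transformed
# integrand exp(g(x* + x) - g(x*)) on the log scale x = log u, with
# g(x) = a x - b e^x - c e^(alpha x); accurate to near machine
# precision.
log_gamma_power_integral <- function(a, b, c, alpha, nodes = 64,
                                     method = c("fixed", "adaptive")) {
  method <- match.arg(method)
  m <- max(length(a), length(b), length(c))
  a <- rep_len(a, m); b <- rep_len(b, m); c <- rep_len(c, m)
  out <- numeric(m)
  done <- rep(FALSE, m)
  closed <- function(idx, rate) {
    v <- rep(NaN, length(idx))
    pos <- a[idx] > 0
    v[pos] <- lgamma(a[idx][pos]) - a[idx][pos] * log(rate[pos])
    v
  }
  plain <- c == 0
  if (any(plain)) {
    out[plain] <- closed(which(plain), b[plain])
    done <- done | plain
  }
  if (!all(done) && alpha == 0) {
    i <- which(!done)
    out[i] <- -c[i] + closed(i, b[i])
    done[i] <- TRUE
  }
  if (!all(done) && alpha == 1) {
    i <- which(!done)
    out[i] <- closed(i, b[i] + c[i])
    done[i] <- TRUE
  }
  if (all(done)) return(out)
  i <- which(!done)
  ai <- a[i]; bi <- b[i]; ci <- c[i]
  # mode of g(x) = a x - b e^x - c e^(alpha x) by damped Newton on the
  # strictly decreasing g'
  x <- numeric(length(ai))
  pos <- ai > 0
  x[pos] <- log(ai[pos]) - log(bi[pos] + ci[pos] * max(alpha, 0))
  x[!is.finite(x)] <- 0
  xcap <- 690 / max(1, abs(alpha))
  for (it in 1:80) {
    ex <- exp(x); eax <- exp(alpha * x)
    g1 <- ai - bi * ex - ci * alpha * eax
    g2 <- -bi * ex - ci * alpha^2 * eax
    step <- g1 / g2
    step[!is.finite(step)] <- 0
    step <- pmax(pmin(step, 3), -3)
    x <- pmin(pmax(x - step, -xcap), xcap)
    if (all(abs(step) < 1e-13)) break
  }
  gstar <- ai * x - bi * exp(x) - ci * exp(alpha * x)
  ustar <- exp(x)
  if (method == "adaptive") {
    for (k in seq_along(i)) {
      if (!(ai[k] > 0 || (ci[k] > 0 && alpha < 0))) { out[i[k]] <- NaN; next }
      f <- function(z) exp(ai[k] * (x[k] + z) - bi[k] * exp(x[k] + z) -
                             ci[k] * exp(alpha * (x[k] + z)) - gstar[k])
      I <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-10, abs.tol = 0,
                            subdivisions = 400L)$value
      out[i[k]] <- gstar[k] + log(I)
    }
    return(out)
  }
  bad <- !(ai > 0)
  # shapes repeat across subjects (they depend on J and the death
  # indicator only), so group them and share each group's Laguerre rule
  for (av in unique(ai[!bad])) {
    idx <- which(ai == av & !bad)
    rule <- gauss_laguerre(nodes, av - 1)
    bt <- av / ustar[idx]                      # rate matched to the mode
    U <- outer(1 / bt, rule$nodes)             # u nodes per subject
    lf <- (bt - bi[idx]) * U - ci[idx] * exp(alpha * log(U))
    M <- sweep(lf, 2, rule$logw, "+")
    out[i[idx]] <- lgamma(av) - av * log(bt) + row_logsumexp(M)
  }
  if (any(bad)) {
    ib <- i[bad]
    out[ib] <- log_gamma_power_integral(a[ib], b[ib], c[ib], alpha,
                                        method = "adaptive")
  }
  out
}

#' Density of the mean-one gamma frailty
#'
#' Density of `Gamma(shape 1/theta, scale theta)` (mean 1, variance
#' `theta`), the shared frailty distribution of the joint model.  The
#' degenerate limit `theta = 0` (point mass at u = 1) is handled by the
#' `theta_zero` flag of the fitting functions, not here.
#'
#' @param u evaluation points, > 0.
#' @param theta frailty variance, > 0.
#' @return density values.
#' @examples
#' gamma_frailty_density(1, 1)  # exp(-1)
#' @export
gamma_frailty_density <- function(u, theta) {
  stopifnot(is.numeric(u), all(u > 0),
            is.numeric(theta), length(theta) == 1L, theta > 0)
  stats::dgamma(u, shape = 1 / theta, scale = theta)
}
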