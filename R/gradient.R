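# Joint negative log-likelihood with analytic gradient.
#
# The gradient uses the Fisher-identity form: every derivative of the
# marginal contribution is an expectation under the subject's posterior
# frailty distribution  p_i(u) ~ u^(a_i - 1) exp(-b_i u - c_i u^alpha),
# a_i = 1/theta + J_i + alpha delta_i, b_i = 1/theta + A_Ri, c_i = A_Di:
#   d/d beta_R = X_R' (J - E[u] A_R)
#   d/d beta_D = X_D' (delta - E[u^alpha] A_D)
#   d/d alpha  = delta E[log u] - A_D E[u^alpha log u]
#   d/d log theta = (1/theta) (psi(1/theta) + log theta - 1
#                              + E[u] - E[log u])
# with the corresponding chain-rule terms for the baseline parameters.
# The posterior moments come from the same mode-matched Laguerre nodes
# as the likelihood value, so value and gradient are mutually consistent.
joint_nll_grad <- function(par, dat, spec, nodes = 32) {
  p <- unpack_par(par, spec)
  theta <- p$theta; alpha <- p$alpha
  bR <- p$baseline_R; bD <- p$baseline_D
  n <- dat$n
  etaR <- if (spec$pR) drop(dat$XR %*% p$beta_R) else numeric(n)
  etaD <- if (spec$pD) drop(dat$XD %*% p$beta_D) else numeric(n)
  LamR <- cumulative_baseline_hazard(bR, dat$T)
  LamD <- cumulative_baseline_hazard(bD, dat$T)
  AR <- LamR * exp(etaR)
  AD <- LamD * exp(etaD)
  slr <- 0
  if (length(dat$ev_t))
    slr <- sum(log_baseline_hazard(bR, dat$ev_t))
  log_death_i <- ifelse(dat$delta > 0,
                        log_baseline_hazard(bD, dat$T) + etaD, 0)

  if (spec$theta_zero) {
    Eu <- Eua <- rep(1, n)
    value <- slr + sum(dat$J * etaR) + sum(log_death_i) - sum(AR) - sum(AD)
    Elogu <- NULL
  } else {
    ish <- 1 / theta
    ashape <- ish + dat$J                 # kernel shape, always positive
    extra <- alpha * dat$delta            # u^(alpha delta) stays in f
    b <- ish + AR
    # mode of the full integrand on the log scale
    afull <- ashape + extra
    x <- numeric(n)
    pos <- afull > 0
    x[pos] <- log(afull[pos]) - log(b[pos] + AD[pos] * max(alpha, 0))
    x[!is.finite(x)] <- 0
    xcap <- 690 / max(1, abs(alpha))
    for (it in 1:60) {
      ex <- exp(x); eax <- exp(alpha * x)
      g1 <- afull - b * ex - AD * alpha * eax
      g2 <- -b * ex - AD * alpha^2 * eax
      step <- g1 / g2
      step[!is.finite(step)] <- 0
      step <- pmax(pmin(step, 3), -3)
      x <- pmin(pmax(x - step, -xcap), xcap)
      if (all(abs(step) < 1e-11)) break
    }
    ll_int <- numeric(n)
    Eu <- Elogu <- Eua <- Eualogu <- numeric(n)
    key <- paste(dat$J, dat$delta)
    for (g in unique(key)) {
      idx <- which(key == g)
      av <- afull[idx[1]]
      ex_g <- 0
      if (av <= 1e-3) {            # alpha very negative: keep u^(alpha d)
        av <- ashape[idx[1]]
        ex_g <- extra[idx[1]]
      }
      rule <- gauss_laguerre(nodes, av - 1)
      bt <- av / exp(x[idx])                     # kernel mean at the mode
      U <- outer(1 / bt, rule$nodes)
      logU <- log(U)
      lf <- (bt - b[idx]) * U - AD[idx] * exp(alpha * logU)
      if (ex_g != 0) lf <- lf + ex_g * logU
      M <- sweep(lf, 2, rule$logw, "+")
      lse <- row_logsumexp(M)
      ll_int[idx] <- lgamma(av) - av * log(bt) + lse
      W <- exp(M - lse)                          # posterior node weights
      Eu[idx] <- rowSums(W * U)
      Elogu[idx] <- rowSums(W * logU)
      Ua <- exp(alpha * logU)
      Eua[idx] <- rowSums(W * Ua)
      Eualogu[idx] <- rowSums(W * Ua * logU)
    }
    value <- slr + sum(dat$J * etaR) + sum(log_death_i) -
      n * (lgamma(ish) + ish * log(theta)) + sum(ll_int)
  }
  if (!is.finite(value))
    return(list(value = 1e10, grad = rep(0, length(par))))

  # score components
  gR <- if (spec$pR) drop(crossprod(dat$XR, dat$J - Eu * AR)) else numeric(0)
  gD <- if (spec$pD) drop(crossprod(dat$XD, dat$delta - Eua * AD))
        else numeric(0)
  grad <- c(gR, gD)
  if (!spec$theta_zero) {
    g_lth <- (1 / theta) * (digamma(1 / theta) + log(theta) - 1) * n +
      (1 / theta) * sum(Eu - Elogu)
    g_al <- sum(dat$delta * Elogu) - sum(AD * Eualogu)
    grad <- c(g_lth, g_al, grad)
  }
  # baseline gradients (chain rule through the log parameters)
  bl_grad <- function(spec_bl, side) {
    if (side == "R") {
      Ew <- Eu; A <- AR; ev_t <- dat$ev_t
      n_ev <- length(dat$ev_t); d_i <- NULL
    } else {
      Ew <- Eua; A <- AD; ev_t <- dat$T[dat$delta > 0]
      n_ev <- sum(dat$delta); d_i <- NULL
    }
    if (inherits(spec_bl, "jf_weibull")) {
      k <- spec_bl$shape; s <- spec_bl$scale
      lt_ev <- if (n_ev) sum(log(ev_t / s)) else 0
      ltT <- log(dat$T / s)
      g_lk <- n_ev + k * lt_ev - k * sum(Ew * A * ltT)
      g_ls <- -k * n_ev + k * sum(Ew * A)
      c(g_lk, g_ls)
    } else {
      bounds <- c(0, spec_bl$cuts)
      B <- length(spec_bl$rates)
      upper <- c(spec_bl$cuts, Inf)
      ev_bin <- if (n_ev) tabulate(findInterval(ev_t, bounds), B)
                else rep(0, B)
      # overlap of (0, T_i] with each bin, times the rate: the piece of
      # Lambda(T_i) attributable to each rate parameter
      ov <- vapply(seq_len(B), function(j)
        pmax(pmin(dat$T, upper[j]) - bounds[j], 0) * spec_bl$rates[j],
        numeric(n))
      ev_bin - colSums((Ew * A / pmax(if (side == "R") LamR else LamD,
                                      1e-300)) * ov)
    }
  }
  grad <- c(grad, bl_grad(bR, "R"), bl_grad(bD, "D"))
  list(value = -value, grad = -grad)
}
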