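#' Model configuration for hierarchical fitness inference
#'
#' Weakly-informative defaults at the per-generation scale of microbial
#' competition effects: hyperfitness prior Normal(0, 0.5^2), mean-fitness
#' prior Normal(0, 0.5^2), replicate-deviation scale HalfNormal(0.05),
#' additive observation-noise scale HalfNormal(1), pseudocount 0.5 for
#' zero reads, 95% central credible mass.
#'
#' @param prior_phi_sd prior sd of the hyperfitness phi.
#' @param prior_sbar_sd prior sd of the per-transition mean fitness.
#' @param sigma_hyper_scale HalfNormal scale of the replicate-level
#'   deviation sd (s(j,n) around phi(j)).
#' @param sigma_scale HalfNormal scale of the additive observation-noise sd
#'   (absorbs transfer-bottleneck drift).
#' @param pseudocount added to read counts before log-frequency increments.
#' @param interval_mass central credible mass used for classification.
#' @param max_iter,tol coordinate-ascent iteration cap and convergence
#'   tolerance (max absolute parameter change).
#' @param mcmc_iter,mcmc_warmup total and warmup iterations of the MCMC
#'   engine.
#' @param seed seed for the MCMC engine (the variational engine is
#'   deterministic).
#' @return list of class `screenfit_model_config`.
#' @export
modelConfig <- function(prior_phi_sd = 0.5, prior_sbar_sd = 0.5,
                        sigma_hyper_scale = 0.05, sigma_scale = 1,
                        pseudocount = 0.5, interval_mass = 0.95,
                        max_iter = 300L, tol = 1e-6,
                        mcmc_iter = 2500L, mcmc_warmup = 1000L, seed = 1L) {
  stopifnot(prior_phi_sd > 0, prior_sbar_sd > 0, sigma_hyper_scale > 0,
            sigma_scale > 0, pseudocount >= 0,
            interval_mass > 0, interval_mass < 1)
  structure(list(prior_phi_sd = prior_phi_sd, prior_sbar_sd = prior_sbar_sd,
                 sigma_hyper_scale = sigma_hyper_scale,
                 sigma_scale = sigma_scale, pseudocount = pseudocount,
                 interval_mass = interval_mass,
                 max_iter = as.integer(max_iter), tol = tol,
                 mcmc_iter = as.integer(mcmc_iter),
                 mcmc_warmup = as.integer(mcmc_warmup),
                 seed = as.integer(seed)),
            class = "screenfit_model_config")
}

## Build the increment data for one condition: reads array, log-frequency
## increments Y (E x N x Tm) and replicate labels.
conditionIncrements <- function(agg, cond, pseudocount, tau) {
  cd <- colData(agg)
  sel <- cd$condition == cond
  reps <- sort(unique(cd$replicate[sel]))
  tps <- sort(unique(cd$timepoint[sel]))
  E <- nrow(agg)
  N <- length(reps)
  T <- length(tps)
  r <- array(NA_real_, c(E, N, T))
  mat <- assay(agg, "counts")
  for (n in seq_len(N)) {
    cols <- which(sel & cd$replicate == reps[n])
    for (cc in cols) r[, n, cd$timepoint[cc] + 1L] <- mat[, cc]
  }
  rp <- r + pseudocount
  tot <- matrix(NA_real_, N, T)
  for (n in seq_len(N)) for (t in seq_len(T))
    if (any(!is.na(rp[, n, t]))) tot[n, t] <- sum(rp[, n, t], na.rm = TRUE)
  logf <- log(rp) - rep(log(tot), each = E)
  Tm <- T - 1L
  Y <- logf[, , 2:T, drop = FALSE] - logf[, , 1:Tm, drop = FALSE]
  list(Y = Y, Rp = rp, reps = reps, E = E, N = N, T = T, Tm = Tm, tau = tau)
}

## Vectorized Thomas algorithm: solves the symmetric tridiagonal systems
## Sigma_s x = b for every stream s at once. d (S x Tm) diagonals, e
## (S x Tm-1) off-diagonals, B (S x Tm x K) right-hand sides. Returns the
## solutions and the log-determinants.
tridiagSolve <- function(d, e, B) {
  S <- nrow(d); Tm <- ncol(d); K <- dim(B)[3]
  dh <- d; Bh <- B
  if (Tm > 1) for (t in 2:Tm) {
    m <- e[, t - 1] / dh[, t - 1]
    dh[, t] <- d[, t] - m * e[, t - 1]
    Bh[, t, ] <- Bh[, t, ] - m * Bh[, t - 1, ]
  }
  X <- Bh
  X[, Tm, ] <- Bh[, Tm, ] / dh[, Tm]
  if (Tm > 1) for (t in (Tm - 1):1)
    X[, t, ] <- (Bh[, t, ] - e[, t] * X[, t + 1, ]) / dh[, t]
  list(X = X, logdet = rowSums(log(dh)))
}

## Stream-level observation covariance. The delta-method covariance of
## log-frequency increments sharing interior read counts is tridiagonal:
## diag sigma^2 + 1/r_t + 1/r_{t+1}, off-diagonal -1/r_{t+1}; an additive
## sigma^2 absorbs per-transition drift. Missing increments are decoupled
## and given an effectively infinite variance.
streamData <- function(dat) {
  E <- dat$E; N <- dat$N; T <- dat$T; Tm <- dat$Tm
  S <- E * N
  A <- matrix(1 / dat$Rp, S, T)            # streams x timepoints
  Ym <- matrix(dat$Y, S, Tm)
  valid <- !is.na(Ym) & is.finite(A[, 1:Tm, drop = FALSE]) &
    is.finite(A[, 2:T, drop = FALSE])
  Ym[!valid] <- 0
  A[!is.finite(A)] <- 0
  dBase <- A[, 1:Tm, drop = FALSE] + A[, 2:T, drop = FALSE]
  eBase <- if (Tm > 1) -A[, 2:Tm, drop = FALSE] else
    matrix(0, S, 0)
  eMask <- if (Tm > 1)
    !valid[, 1:(Tm - 1), drop = FALSE] | !valid[, 2:Tm, drop = FALSE]
  else matrix(TRUE, S, 0)
  list(Ym = Ym, valid = valid, dBase = dBase,
       A2 = A[, 2:T, drop = FALSE], eBase = eBase, eMask = eMask,
       S = S, Tm = Tm)
}

BIG_VAR <- 1e8

## kappa scales the frequency-dependent transfer-drift term kappa/r_{t+1}
## (drift variance ~ 1/cells with cells proportional to reads); sigma2 is
## the residual additive scale.
streamCov <- function(sd_, sigma2, kappa = 0) {
  d <- sigma2 + sd_$dBase + kappa * sd_$A2
  d[!sd_$valid] <- BIG_VAR
  e <- sd_$eBase
  e[sd_$eMask] <- 0
  list(d = d, e = e)
}

## Structured variational fit for one condition. Coordinate ascent on
## Gaussian blocks: the per-replicate fitness s(j,n) is collapsed into its
## stream GLS summary shat(j,n) ~ N(phi_j, sigma_h^2 + var_jn) for the
## hyperfitness block; the mean-fitness series and the two variance scales
## (penalized restricted-marginal-likelihood point updates under the
## HalfNormal priors) alternate with it until parameters stabilize.
fitConditionVI <- function(dat, neutral, cfg) {
  E <- dat$E; N <- dat$N; Tm <- dat$Tm; tau <- dat$tau
  sd_ <- streamData(dat)
  S <- sd_$S
  Ym <- sd_$Ym
  editing <- !neutral
  editingS <- rep(editing, times = N)      # stream order: e fastest
  repS <- rep(seq_len(N), each = E)
  psbar <- cfg$prior_sbar_sd^2
  ones <- matrix(1, S, Tm)

  sbarStream <- function(sbar) sbar[repS, , drop = FALSE]

  ## GLS stream summaries at given variance scales and mean-fitness series
  streamStats <- function(sigma2, kappa, sbar) {
    cov <- streamCov(sd_, sigma2, kappa)
    z <- Ym + tau * sbarStream(sbar)
    z[!sd_$valid] <- 0
    B <- array(c(ones, z), c(S, Tm, 2))
    sol <- tridiagSolve(cov$d, cov$e, B)
    q11 <- rowSums(sol$X[, , 1, drop = FALSE])
    q1z <- rowSums(sol$X[, , 2, drop = FALSE])
    zSz <- rowSums(z * sol$X[, , 2])
    shat <- ifelse(q11 > 1 / BIG_VAR, q1z / (tau * q11), 0)
    varen <- ifelse(q11 > 1 / BIG_VAR, 1 / (tau^2 * q11), Inf)
    list(shat = matrix(shat, E, N), varen = matrix(varen, E, N),
         q11 = q11, q1z = q1z, zSz = zSz, logdet = sol$logdet, z = z,
         cov = cov)
  }

  phiUpdate <- function(st, sh2, pphi) {
    a <- 1 / (sh2 + st$varen)
    a[neutral, ] <- 0
    a[!is.finite(st$varen)] <- 0
    prec <- 1 / pphi + rowSums(a)
    mu <- rowSums(a * st$shat) / prec
    mu[neutral] <- 0
    list(mu = mu, var = ifelse(neutral, 0, 1 / prec))
  }

  esUpdate <- function(st, phi, sh2) {
    w1 <- ifelse(is.finite(st$varen), 1 / st$varen, 0)
    w2 <- 1 / max(sh2, 1e-12)
    es <- (w1 * st$shat + w2 * phi$mu) / (w1 + w2)
    vs <- 1 / (w1 + w2) + (w2 / (w1 + w2))^2 * phi$var
    es[neutral, ] <- 0
    vs[neutral, ] <- 0
    list(es = es, vs = vs)
  }

  ## Gaussian block for the mean-fitness series of each replicate
  sbarUpdate <- function(sigma2, kappa, es) {
    cov <- streamCov(sd_, sigma2, kappa)
    B <- array(0, c(S, Tm, Tm + 2L))
    B[, , 1] <- ones
    B[, , 2] <- Ym
    for (t in seq_len(Tm)) B[, t, t + 2L] <- 1
    sol <- tridiagSolve(cov$d, cov$e, B)
    X1 <- sol$X[, , 1, drop = FALSE][, , 1]
    Xy <- sol$X[, , 2, drop = FALSE][, , 1]
    sA <- as.vector(es)                    # stream fitness values
    mean_out <- matrix(0, N, Tm)
    sd_out <- matrix(0, N, Tm)
    for (n in seq_len(N)) {
      sel <- which(repS == n)
      Minv <- matrix(0, Tm, Tm)
      for (k in seq_len(Tm))
        Minv[, k] <- colSums(sol$X[sel, , k + 2L, drop = FALSE][, , 1])
      v <- tau * (tau * colSums(sA[sel] * X1[sel, , drop = FALSE]) -
                  colSums(Xy[sel, , drop = FALSE]))
      P <- diag(1 / psbar, Tm) + tau^2 * Minv
      Pinv <- solve(P)
      mean_out[n, ] <- as.vector(Pinv %*% v)
      sd_out[n, ] <- sqrt(diag(Pinv))
    }
    list(mean = mean_out, sd = sd_out)
  }

  ## penalized restricted marginal negative log-likelihood in the two
  ## variance scales (per-stream fitness profiled out for editing streams)
  remlObjective <- function(sigma2, kappa, sbar) {
    st <- streamStats(sigma2, kappa, sbar)
    quad <- st$zSz
    reml <- rep(0, S)
    ok <- st$q11 > 1 / BIG_VAR
    quad[editingS & ok] <- quad[editingS & ok] -
      st$q1z[editingS & ok]^2 / st$q11[editingS & ok]
    reml[editingS & ok] <- log(tau^2 * st$q11[editingS & ok])
    0.5 * (sum(st$logdet) + sum(quad) + sum(reml)) +
      sigma2 / (2 * cfg$sigma_scale^2) + kappa / (2 * 10^2)
  }

  ## penalized restricted marginal negative log-likelihood in sigma_h^2
  hyperObjective <- function(log_sh2, st, pphi) {
    sh2 <- exp(log_sh2)
    av <- sh2 + st$varen
    a <- 1 / av
    a[neutral, ] <- 0
    a[!is.finite(st$varen)] <- 0
    prec <- 1 / pphi + rowSums(a)
    mu <- rowSums(a * st$shat) / prec
    lav <- log(av)
    lav[a == 0] <- 0
    dev <- (st$shat - mu)^2 * a
    0.5 * (sum(lav[editing, ]) + sum(log(prec[editing])) +
           sum(dev[editing, ])) + sh2 / (2 * cfg$sigma_hyper_scale^2)
  }

  ## marginal-likelihood point update of the hyperfitness population
  ## variance (empirical Bayes); the configured prior_phi_sd is retained as
  ## the scale of a HalfNormal hyperprior. Under an all-null screen the
  ## population scale collapses and estimates shrink to zero, which also
  ## pins the anchor-identified common mode; under a dispersed effect
  ## distribution shrinkage is negligible.
  pphiObjective <- function(log_pv, st, sh2) {
    pv <- exp(log_pv)
    a <- 1 / (sh2 + st$varen)
    a[neutral, ] <- 0
    a[!is.finite(st$varen)] <- 0
    precd <- rowSums(a)
    sel <- editing & precd > 0
    mud <- rowSums(a * st$shat)[sel] / precd[sel]
    tot <- pv + 1 / precd[sel]
    0.5 * sum(log(tot) + mud^2 / tot) + pv / (2 * cfg$prior_phi_sd^2)
  }

  ## initialize the mean-fitness series from the anchors alone
  sigma2 <- 1e-4
  kappa <- 0.1
  sh2 <- 1e-6
  pphi <- cfg$prior_phi_sd^2
  Wn <- 1 / (sd_$dBase + sigma2)
  Wn[!sd_$valid] <- 0
  Wn[editingS, ] <- 0
  num <- den <- matrix(0, N, Tm)
  for (n in seq_len(N)) {
    sel <- repS == n
    num[n, ] <- colSums(Wn[sel, , drop = FALSE] * Ym[sel, , drop = FALSE])
    den[n, ] <- colSums(Wn[sel, , drop = FALSE])
  }
  sbar <- ifelse(den > 0, -num / (tau * den), 0)
  sbar_sd <- matrix(0, N, Tm)

  phi <- list(mu = rep(0, E), var = rep(pphi, E))
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    st <- streamStats(sigma2, kappa, sbar)
    phi_new <- phiUpdate(st, sh2, pphi)
    es <- esUpdate(st, phi_new, sh2)
    sb <- sbarUpdate(sigma2, kappa, es$es)
    sigma2 <- exp(stats::optimize(function(l)
      remlObjective(exp(l), kappa, sb$mean),
      c(log(1e-10), log(1)), tol = 1e-4)$minimum)
    kappa <- exp(stats::optimize(function(l)
      remlObjective(sigma2, exp(l), sb$mean),
      c(log(1e-10), log(100)), tol = 1e-4)$minimum)
    st2 <- streamStats(sigma2, kappa, sb$mean)
    sh2 <- exp(stats::optimize(hyperObjective, c(log(1e-12), log(0.25)),
                               st = st2, pphi = pphi, tol = 1e-4)$minimum)
    pphi <- exp(stats::optimize(pphiObjective, c(log(1e-10), log(1)),
                                st = st2, sh2 = sh2, tol = 1e-4)$minimum)
    delta <- max(abs(phi_new$mu - phi$mu), abs(sb$mean - sbar))
    phi <- phi_new
    sbar <- sb$mean
    sbar_sd <- sb$sd
    trace <- c(trace, remlObjective(sigma2, kappa, sbar))
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  st <- streamStats(sigma2, kappa, sbar)
  phi <- phiUpdate(st, sh2, pphi)
  es <- esUpdate(st, phi, sh2)

  ## Common-mode variance: the level of the mean-fitness series is
  ## identified by the neutral anchors alone (edit fitness values are free
  ## parameters), so the anchor-limited covariance of each replicate's
  ## series propagates as a shared error into every edit's fitness. The
  ## mean-field blocks do not carry this term, so it is added analytically
  ## to the reported posterior variances.
  cov <- streamCov(sd_, sigma2, kappa)
  B <- array(0, c(S, Tm, Tm + 1L))
  B[, , 1] <- ones
  for (t in seq_len(Tm)) B[, t, t + 1L] <- 1
  solc <- tridiagSolve(cov$d, cov$e, B)
  X1 <- solc$X[, , 1, drop = FALSE][, , 1]
  q11v <- rowSums(X1)
  w <- X1 / pmax(q11v, 1 / BIG_VAR)        # stream sensitivity to sbar
  w[q11v <= 1 / BIG_VAR, ] <- 0
  c_s <- numeric(S)
  sbar_var_anchor <- matrix(0, N, Tm)
  anchorS <- !editingS
  for (n in seq_len(N)) {
    sel <- which(repS == n)
    selA <- sel[anchorS[sel]]
    Minv <- matrix(0, Tm, Tm)
    for (k in seq_len(Tm))
      Minv[, k] <- colSums(solc$X[selA, , k + 1L, drop = FALSE][, , 1,
                                                                drop = FALSE])
    Cn <- solve(diag(1 / psbar, Tm) + tau^2 * Minv)
    sbar_var_anchor[n, ] <- diag(Cn)
    c_s[sel] <- rowSums((w[sel, , drop = FALSE] %*% Cn) *
                        w[sel, , drop = FALSE])
  }
  c_en <- matrix(c_s, E, N)
  a <- 1 / (sh2 + st$varen)
  a[neutral, ] <- 0
  a[!is.finite(st$varen)] <- 0
  prec <- 1 / pphi + rowSums(a)
  alpha <- a / prec
  phi_var_tot <- phi$var + rowSums(alpha^2 * c_en)
  phi_var_tot[neutral] <- 0
  vs_tot <- es$vs + c_en
  vs_tot[neutral, ] <- 0
  list(phi_mean = phi$mu, phi_sd = sqrt(phi_var_tot),
       s_mean = es$es, s_sd = sqrt(vs_tot),
       sbar_mean = sbar, sbar_sd = sqrt(sbar_sd^2 + sbar_var_anchor),
       diagnostics = list(converged = converged, n_iter = it,
                          sigma = sqrt(sigma2), kappa = kappa,
                          sigma_hyper = sqrt(sh2),
                          phi_population_sd = sqrt(pphi),
                          objective_trace = trace),
       phi_samples = NULL)
}

## Gibbs/Metropolis MCMC alternative for one condition; initialized at the
## variational solution. Gaussian full conditionals for s, phi and the
## mean-fitness series; log-scale random-walk Metropolis for the two
## variance scales.
fitConditionMCMC <- function(dat, neutral, cfg) {
  vi <- fitConditionVI(dat, neutral, cfg)
  E <- dat$E; N <- dat$N; Tm <- dat$Tm; tau <- dat$tau
  sd_ <- streamData(dat)
  S <- sd_$S
  Ym <- sd_$Ym
  editing <- !neutral
  editingS <- rep(editing, times = N)
  repS <- rep(seq_len(N), each = E)
  psbar <- cfg$prior_sbar_sd^2
  ones <- matrix(1, S, Tm)

  set.seed(cfg$seed)
  phi <- vi$phi_mean
  s <- vi$s_mean
  sbar <- vi$sbar_mean
  sigma2 <- max(vi$diagnostics$sigma^2, 1e-10)
  kappa <- max(vi$diagnostics$kappa, 1e-10)
  sh2 <- max(vi$diagnostics$sigma_hyper^2, 1e-10)
  pphi <- max(vi$diagnostics$phi_population_sd^2, 1e-10)

  residLoglik <- function(sigma2_c, kappa_c) {
    cov <- streamCov(sd_, sigma2_c, kappa_c)
    resid <- Ym - tau * (matrix(as.vector(s), S, Tm) -
                         sbar[repS, , drop = FALSE])
    resid[!sd_$valid] <- 0
    sol <- tridiagSolve(cov$d, cov$e, array(resid, c(S, Tm, 1)))
    -0.5 * (sum(sol$logdet) + sum(resid * sol$X[, , 1]))
  }

  n_iter <- cfg$mcmc_iter
  keep_n <- n_iter - cfg$mcmc_warmup
  phi_samp <- matrix(NA_real_, keep_n, E)
  s_mean_acc <- matrix(0, E, N); s_sq_acc <- matrix(0, E, N)
  b_mean_acc <- matrix(0, N, Tm); b_sq_acc <- matrix(0, N, Tm)
  acc <- c(sigma = 0, kappa = 0, hyper = 0)
  ki <- 0L
  for (it in seq_len(n_iter)) {
    cov <- streamCov(sd_, sigma2, kappa)
    z <- Ym + tau * sbar[repS, , drop = FALSE]
    z[!sd_$valid] <- 0
    K <- Tm + 2L
    B <- array(0, c(S, Tm, K))
    B[, , 1] <- ones
    B[, , 2] <- z
    for (t in seq_len(Tm)) B[, t, t + 2L] <- 1
    sol <- tridiagSolve(cov$d, cov$e, B)
    X1 <- sol$X[, , 1, drop = FALSE][, , 1]
    q11 <- rowSums(X1)
    q1z <- rowSums(sol$X[, , 2, drop = FALSE][, , 1])
    ## common-mode recentering move: shifts all edit fitness values, the
    ## hyperfitness and the mean-fitness series together along the ridge
    ## that only the anchors (and the priors) constrain, which the
    ## one-at-a-time Gibbs updates mix very slowly
    pa <- tau^2 * sum(q11[!editingS])
    if (pa > 0) {
      delta <- stats::rnorm(1, 0, 2 / sqrt(pa))
      dll <- -sum(tau * delta * q1z[!editingS] +
                  0.5 * tau^2 * delta^2 * q11[!editingS]) -
        sum(2 * phi[editing] * delta + delta^2) / (2 * pphi) -
        sum(2 * sbar * delta + delta^2) / (2 * psbar)
      if (is.finite(dll) && log(stats::runif(1)) < dll) {
        phi[editing] <- phi[editing] + delta
        s[editing, ] <- s[editing, ] + delta
        sbar <- sbar + delta
        z <- z + tau * delta
        z[!sd_$valid] <- 0
        q1z <- q1z + tau * delta * q11
      }
    }
    ## s | .
    prec_s <- 1 / sh2 + tau^2 * q11
    mean_s <- (rep(phi, N) / sh2 + tau * q1z) / prec_s
    s <- matrix(mean_s + stats::rnorm(S) / sqrt(prec_s), E, N)
    s[neutral, ] <- 0
    ## phi | s
    prec_p <- 1 / pphi + N / sh2
    phi <- rowSums(s) / sh2 / prec_p + stats::rnorm(E) / sqrt(prec_p)
    phi[neutral] <- 0
    ## sbar | s (multivariate normal per replicate)
    zy <- Ym
    zy[!sd_$valid] <- 0
    soly <- tridiagSolve(cov$d, cov$e, array(zy, c(S, Tm, 1)))
    Xy <- soly$X[, , 1, drop = FALSE][, , 1]
    sA <- as.vector(s)
    for (n in seq_len(N)) {
      sel <- which(repS == n)
      Minv <- matrix(0, Tm, Tm)
      for (k in seq_len(Tm))
        Minv[, k] <- colSums(sol$X[sel, , k + 2L, drop = FALSE][, , 1])
      v <- tau * (tau * colSums(sA[sel] * X1[sel, , drop = FALSE]) -
                  colSums(Xy[sel, , drop = FALSE]))
      P <- diag(1 / psbar, Tm) + tau^2 * Minv
      ch <- chol(P)
      mu_b <- backsolve(ch, forwardsolve(t(ch), v))
      sbar[n, ] <- mu_b + backsolve(ch, stats::rnorm(Tm))
    }
    ## variance scales | . (log-scale MH, HalfNormal priors)
    ll_cur <- residLoglik(sigma2, kappa)
    prop <- sigma2 * exp(0.3 * stats::rnorm(1))
    ll_prop <- residLoglik(prop, kappa)
    lr <- ll_prop - ll_cur + (sigma2 - prop) / (2 * cfg$sigma_scale^2) +
      log(prop) - log(sigma2)
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      sigma2 <- prop
      ll_cur <- ll_prop
      acc["sigma"] <- acc["sigma"] + 1
    }
    prop <- kappa * exp(0.3 * stats::rnorm(1))
    ll_prop <- residLoglik(sigma2, prop)
    lr <- ll_prop - ll_cur + (kappa - prop) / (2 * 10^2) +
      log(prop) - log(kappa)
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      kappa <- prop
      acc["kappa"] <- acc["kappa"] + 1
    }
    ## sigma_h^2 | s, phi
    dev2 <- (s[editing, , drop = FALSE] -
             matrix(phi[editing], sum(editing), N))^2
    prop <- sh2 * exp(0.3 * stats::rnorm(1))
    llh <- function(v) -0.5 * sum(log(v) + dev2 / v)
    lr <- llh(prop) - llh(sh2) + (sh2 - prop) /
      (2 * cfg$sigma_hyper_scale^2) + log(prop) - log(sh2)
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      sh2 <- prop
      acc["hyper"] <- acc["hyper"] + 1
    }
    ## hyperfitness population variance | phi
    phie2 <- phi[editing]^2
    prop <- pphi * exp(0.3 * stats::rnorm(1))
    llp <- function(v) -0.5 * sum(log(v) + phie2 / v)
    lr <- llp(prop) - llp(pphi) + (pphi - prop) /
      (2 * cfg$prior_phi_sd^2) + log(prop) - log(pphi)
    if (is.finite(lr) && log(stats::runif(1)) < lr) pphi <- prop
    if (it > cfg$mcmc_warmup) {
      ki <- ki + 1L
      phi_samp[ki, ] <- phi
      s_mean_acc <- s_mean_acc + s
      s_sq_acc <- s_sq_acc + s^2
      b_mean_acc <- b_mean_acc + sbar
      b_sq_acc <- b_sq_acc + sbar^2
    }
  }
  splitRhat <- function(x) {
    h <- length(x) %/% 2L
    a <- x[1:h]; b <- x[(h + 1):(2 * h)]
    W <- (stats::var(a) + stats::var(b)) / 2
    B <- h * stats::var(c(mean(a), mean(b)))
    if (!is.finite(W) || W <= 0) return(1)
    sqrt((W * (h - 1) / h + B / h) / W)
  }
  list(phi_mean = colMeans(phi_samp),
       phi_sd = apply(phi_samp, 2, stats::sd),
       s_mean = s_mean_acc / ki,
       s_sd = sqrt(pmax(s_sq_acc / ki - (s_mean_acc / ki)^2, 0)),
       sbar_mean = b_mean_acc / ki,
       sbar_sd = sqrt(pmax(b_sq_acc / ki - (b_mean_acc / ki)^2, 0)),
       diagnostics = list(
         converged = TRUE, n_iter = n_iter,
         sigma = sqrt(sigma2), kappa = kappa, sigma_hyper = sqrt(sh2),
         accept_rate = acc / n_iter,
         split_rhat = apply(phi_samp, 2, splitRhat)),
       phi_samples = phi_samp)
}

#' Fit the hierarchical fitness model
#'
#' Infers, independently per condition, the edit-level hyperfitness phi(j),
#' the per-replicate fitness s(j,n) drawn around it, and the per-transition
#' population mean fitness, from edit-level count trajectories. The
#' observation model is Gaussian on log-frequency increments with mean
#' (s(j,n) - sbar_t) * tau; its covariance is the delta-method read-noise
#' covariance (variance sigma^2 + 1/r_t + 1/r_{t+1}, covariance -1/r_{t+1}
#' between increments sharing a read count) so interior timepoints are not
#' double-counted. Neutral anchors are constrained to s = 0 and identify
#' the mean-fitness nuisance series. Missing transitions are dropped from
#' the likelihood, never imputed.
#'
#' @param agg edit-level counts from [aggregateCounts()]; `tau` is taken
#'   from the attached design or from `metadata(agg)$tau`.
#' @param config a [modelConfig()].
#' @param engine `"variational"` (deterministic structured coordinate
#'   ascent, the default) or `"mcmc"` (Gibbs sampler with Metropolis
#'   variance updates, seeded from `config$seed`).
#' @return A [FitnessFit-class], already classified at the configured
#'   credible mass. Non-convergence is reported via
#'   `x@diagnostics[[condition]]$converged`, never silently.
#' @export
fitFitness <- function(agg, config = modelConfig(),
                       engine = c("variational", "mcmc")) {
  engine <- match.arg(engine)
  stopifnot(is(agg, "SummarizedExperiment"),
            all(c("edit_id", "neutral") %in% colnames(rowData(agg))))
  if (!any(rowData(agg)$neutral))
    stop("at least one neutral anchor edit is required")
  design <- metadata(agg)$design
  tau <- if (!is.null(design)) design@tau else metadata(agg)$tau
  if (is.null(tau)) stop("tau not found; supply it via metadata(agg)$tau")
  conds <- unique(colData(agg)$condition)
  neutral <- rowData(agg)$neutral
  edits <- rowData(agg)$edit_id

  hf <- list(); rf <- list(); mf <- list(); diag <- list()
  for (cond in conds) {
    dat <- conditionIncrements(agg, cond, config$pseudocount, tau)
    if (dat$Tm < 1L) stop("condition ", cond, " has < 2 timepoints")
    fit <- if (engine == "variational") fitConditionVI(dat, neutral, config)
           else fitConditionMCMC(dat, neutral, config)
    hf[[cond]] <- data.frame(
      edit_id = edits, condition = cond,
      mean = fit$phi_mean, sd = fit$phi_sd,
      lower = NA_real_, upper = NA_real_,
      classification = NA_character_, neutral_anchor = neutral,
      stringsAsFactors = FALSE)
    rf[[cond]] <- data.frame(
      edit_id = rep(edits, times = dat$N),
      condition = cond,
      replicate = rep(dat$reps, each = length(edits)),
      mean = as.vector(fit$s_mean), sd = as.vector(fit$s_sd),
      stringsAsFactors = FALSE)
    mf[[cond]] <- data.frame(
      condition = cond,
      replicate = rep(dat$reps, times = dat$Tm),
      t = rep(seq_len(dat$Tm) - 1L, each = dat$N),
      mean = as.vector(fit$sbar_mean), sd = as.vector(fit$sbar_sd),
      stringsAsFactors = FALSE)
    dd <- fit$diagnostics
    dd$phi_samples <- fit$phi_samples
    diag[[cond]] <- dd
    if (!dd$converged)
      warning("fitness fit did not converge for condition ", cond)
  }
  out <- new("FitnessFit",
             hyperfitness = do.call(rbind, c(hf, make.row.names = FALSE)),
             replicateFitness = do.call(rbind, c(rf, make.row.names = FALSE)),
             meanFitness = do.call(rbind, c(mf, make.row.names = FALSE)),
             intervalMass = config$interval_mass, engine = engine,
             diagnostics = diag, config = unclass(config))
  classify(out, config$interval_mass)
}

#' Classify edits by their credible interval
#'
#' An edit is non-neutral in a condition when the central credible
#' interval of its hyperfitness excludes zero: beneficial if the lower
#' bound is positive, deleterious if the upper bound is negative.
#'
#' @param x a [FitnessFit-class].
#' @param intervalMass central credible mass (default 0.95).
#' @return The fit with `lower`, `upper` and `classification` refreshed.
#' @rdname classify
#' @export
setMethod("classify", "FitnessFit", function(x, intervalMass = 0.95) {
  stopifnot(intervalMass > 0, intervalMass < 1)
  hf <- x@hyperfitness
  alpha <- (1 - intervalMass) / 2
  if (x@engine == "mcmc") {
    for (cond in unique(hf$condition)) {
      samp <- x@diagnostics[[cond]]$phi_samples
      sel <- hf$condition == cond
      qs <- apply(samp, 2, stats::quantile, probs = c(alpha, 1 - alpha))
      hf$lower[sel] <- qs[1, ]
      hf$upper[sel] <- qs[2, ]
    }
  } else {
    z <- stats::qnorm(1 - alpha)
    hf$lower <- hf$mean - z * hf$sd
    hf$upper <- hf$mean + z * hf$sd
  }
  hf$lower[hf$neutral_anchor] <- 0
  hf$upper[hf$neutral_anchor] <- 0
  hf$classification <- ifelse(hf$lower > 0, "beneficial",
                       ifelse(hf$upper < 0, "deleterious", "neutral"))
  hf$classification[hf$neutral_anchor] <- "neutral"
  x@hyperfitness <- hf
  x@intervalMass <- intervalMass
  x
})

#' Per-edit focal-set flags across conditions
#'
#' Counts, for every edit, the conditions in which it is classified
#' non-neutral, and derives the flags used by the downstream analyses:
#' non-neutral in at least one condition, non-neutral in at least two
#' conditions (the focal set), and beneficial in at least one condition.
#'
#' @param x a classified [FitnessFit-class].
#' @return data.frame: edit_id, neutral_anchor, n_conditions_non_neutral,
#'   beneficial_any, max_abs_fitness, non_neutral_any, non_neutral_2plus.
#' @export
focalSets <- function(x) {
  stopifnot(is(x, "FitnessFit"))
  hf <- x@hyperfitness
  sp <- split(hf, hf$edit_id)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    edit_id = d$edit_id[1],
    neutral_anchor = d$neutral_anchor[1],
    n_conditions_non_neutral = sum(d$classification != "neutral"),
    beneficial_any = any(d$classification == "beneficial"),
    max_abs_fitness = max(abs(d$mean)),
    stringsAsFactors = FALSE)))
  out$non_neutral_any <- out$n_conditions_non_neutral >= 1L
  out$non_neutral_2plus <- out$n_conditions_non_neutral >= 2L
  rownames(out) <- NULL
  out[order(out$edit_id), ]
}

#' Between-replicate concordance of fitness estimates
#'
#' Spearman rank correlation of per-replicate posterior-mean fitness for
#' every replicate pair within each condition, restricted to edits
#' classified non-neutral in that condition. Pairs with fewer than 3
#' non-neutral edits are flagged and return `NA`.
#'
#' @param x a classified [FitnessFit-class].
#' @return data.frame: condition, replicate_a, replicate_b, n_edits, rho,
#'   insufficient.
#' @export
replicateConcordance <- function(x) {
  stopifnot(is(x, "FitnessFit"))
  rf <- x@replicateFitness
  hf <- x@hyperfitness
  out <- list()
  for (cond in unique(rf$condition)) {
    nn <- hf$edit_id[hf$condition == cond &
                     hf$classification != "neutral" & !hf$neutral_anchor]
    sub <- rf[rf$condition == cond & rf$edit_id %in% nn, ]
    reps <- sort(unique(rf$replicate[rf$condition == cond]))
    if (length(reps) < 2L) stop("replicate concordance needs >= 2 replicates")
    for (i in seq_along(reps)) for (j in seq_along(reps)) {
      if (i >= j) next
      a <- sub$mean[sub$replicate == reps[i]][order(sub$edit_id[sub$replicate == reps[i]])]
      b <- sub$mean[sub$replicate == reps[j]][order(sub$edit_id[sub$replicate == reps[j]])]
      ok <- sum(stats::complete.cases(a, b))
      rho <- if (ok >= 3) stats::cor(a, b, method = "spearman",
                                     use = "complete.obs") else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, replicate_a = reps[i], replicate_b = reps[j],
        n_edits = ok, rho = rho, insufficient = ok < 3,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
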