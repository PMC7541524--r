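# ---- small numerical helpers for the sampler ------------------------------

# inverse of the T x T AR(1) correlation matrix C[t,t'] = phi^|t-t'|,
# returned dense (tridiagonal); unit marginal variance
ar1_corr_inverse <- function(TT, phi) {
  if (TT == 1L) return(matrix(1, 1, 1))
  f <- 1 / (1 - phi^2)
  Ci <- diag(c(1, rep(1 + phi^2, TT - 2L), 1) * f, TT)
  for (t in seq_len(TT - 1L)) {
    Ci[t, t + 1L] <- Ci[t + 1L, t] <- -phi * f
  }
  Ci
}

# quadratic/bilinear form x' Cinv y per row-pair of matrices A, B (n x T),
# summed over rows, using the AR(1) factorisation (O(nT), no matrix build)
ar1_bilinear <- function(A, B, phi) {
  TT <- ncol(A)
  tot <- sum(A[, 1] * B[, 1])
  if (TT > 1L) {
    wa <- A[, -1L, drop = FALSE] - phi * A[, -TT, drop = FALSE]
    wb <- B[, -1L, drop = FALSE] - phi * B[, -TT, drop = FALSE]
    tot <- tot + sum(wa * wb) / (1 - phi^2)
  }
  tot
}

# log-likelihood of the dyadic residual pairs E1, E2 (n_pairs x T, one row
# per unordered dyad, E2 the reverse direction) under the stationary
# AR(1)-correlated bivariate model: cov = Sigma_gamma (x) C_T(phi_gg)
dyad_pair_loglik <- function(E1, E2, phi_gg, rho, sigma2) {
  n_p <- nrow(E1)
  TT <- ncol(E1)
  det_sig <- sigma2^2 * (1 - rho^2)
  sd_ <- 1 / (sigma2 * (1 - rho^2))
  so_ <- -rho / (sigma2 * (1 - rho^2))
  m11 <- ar1_bilinear(E1, E1, phi_gg)
  m22 <- ar1_bilinear(E2, E2, phi_gg)
  m12 <- ar1_bilinear(E1, E2, phi_gg)
  quad <- sd_ * (m11 + m22) + 2 * so_ * m12
  ldetC <- (TT - 1) * log(1 - phi_gg^2)
  -0.5 * (n_p * (2 * ldetC + TT * log(det_sig)) + quad) -
    n_p * TT * log(2 * pi)
}

# VAR(1) prior precision of one country's stacked (s_1,r_1,...,s_T,r_T)
# trajectory; t = 1 at the stationary law
var1_prior_precision <- function(Phi, sigma_eps, TT) {
  A <- solve(sigma_eps)
  S0inv <- solve(stationary_var_cov(Phi, sigma_eps))
  PAP <- t(Phi) %*% A %*% Phi
  Q <- matrix(0, 2 * TT, 2 * TT)
  idx <- function(t) (2 * t - 1):(2 * t)
  for (t in seq_len(TT)) {
    Q[idx(t), idx(t)] <- if (t == 1L) S0inv else A
    if (t < TT) {
      Q[idx(t), idx(t)] <- Q[idx(t), idx(t)] + PAP
      Q[idx(t), idx(t + 1)] <- -t(Phi) %*% A
      Q[idx(t + 1), idx(t)] <- -A %*% Phi
    }
  }
  Q
}

draw_mvn_from_precision <- function(P, b) {
  R <- chol(P)
  mu <- backsolve(R, forwardsolve(t(R), b))
  as.vector(mu + backsolve(R, stats::rnorm(length(b))))
}

riwish <- function(df, scale) {
  # inverse-Wishart draw via the Wishart on the inverted scale
  W <- stats::rWishart(1, df, solve(scale))[, , 1]
  solve(W)
}

check_design_rank <- function(design) {
  for (t in seq_along(design$years)) {
    qr_t <- qr(design$X[, , t])
    if (qr_t$rank < ncol(design$X)) {
      dropped <- design$columns[sort(qr_t$pivot[-seq_len(qr_t$rank)])]
      stop("design matrix is rank-deficient in year ", design$years[t],
           "; collinear column(s): ", paste(dropped, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Default priors for the longitudinal dyadic model
#'
#' Weakly informative conjugate/truncated choices: per-year coefficients
#' `beta_t ~ N(0, 100^2 I)` (independent across years); innovation
#' covariance `Sigma_eps ~ InvWishart(4, I_2)`; dyadic variance
#' `sigma2_gamma ~ InvGamma(2, 1)`; reciprocity `rho ~ U(-1, 1)`; VAR
#' transition entries `~ N(0, 1)` truncated to the stationary region;
#' `phi_gg ~ U(-1, 1)`.
#'
#' @return A named list of prior hyperparameters.
#' @export
default_priors <- function() {
  list(beta_sd = 100,
       sigma_eps_df = 4, sigma_eps_scale = diag(2),
       sigma2_gamma_shape = 2, sigma2_gamma_rate = 1,
       phi_prior_sd = 1)
}

#' Fit the longitudinal mixed-effects dyadic network model by MCMC
#'
#' Gibbs sampler with one Metropolis block for the model
#' \deqn{z_{ijt} = x_{ijt}'\beta_t + s_{it} + r_{jt} + \gamma_{ijt}}
#' where per country the sender/receiver pair follows a stationary VAR(1)
#' with transition matrix \eqn{\Phi} and innovation covariance
#' \eqn{\Sigma_\epsilon}, and per unordered dyad the residual pair
#' \eqn{(\gamma_{ijt}, \gamma_{jit})} is stationary AR(1) in time
#' (coefficient \eqn{\phi_{gg}}) with within-pair reciprocity correlation
#' \eqn{\rho} and marginal variance \eqn{\sigma^2_\gamma}.
#'
#' Each iteration cycles: (1) all per-year coefficient vectors jointly, as
#' one conjugate multivariate-normal block under the full dyadic error
#' structure (exact — the per-year conditionals are a scan of the same
#' Gaussian); (2) each country's 2T-dimensional sender/receiver trajectory,
#' sequentially, combining the VAR(1) prior with the likelihood of all
#' dyads touching the country; (3) \eqn{(\phi_{gg}, \rho,
#' \sigma^2_\gamma)} by random-walk Metropolis on the marginal likelihood
#' of the dyad residual pairs (Kronecker form, AR(1) factorised); (4)
#' \eqn{\Phi} by a conjugate matrix-regression draw on the lag-1 latent
#' states, rejected while non-stationary; (5) \eqn{\Sigma_\epsilon} by a
#' conjugate inverse-Wishart draw on the VAR innovations. Metropolis step
#' sizes adapt during burn-in only.
#'
#' @param design a [build_design_matrices()] result with response attached.
#' @param iterations total MCMC iterations (default mirrors the analysis
#'   this package re-implements: 11,000).
#' @param burn_in dropped initial iterations (default 1,000).
#' @param thin keep every `thin`-th post-burn-in draw (default 10).
#' @param seed integer RNG seed; the fit is reproducible given it.
#' @param priors prior hyperparameters, see [default_priors()].
#' @param save_gamma also store the dyadic residual draws (memory-heavy for
#'   large networks; the sender/receiver states are always stored).
#' @param verbose print progress every 500 iterations.
#' @return An object of class `posterior_draws`: list of arrays
#'   `beta [n_save, 11, T]`, `phi_matrix [n_save, 2, 2]`, vectors `phi_gg`,
#'   `rho`, `sigma2_gamma`, array `sigma_eps [n_save, 2, 2]`, latent states
#'   `s`, `r` `[n_save, N, T]` (and `gamma [n_save, n_dyads, T]` if
#'   requested), plus `meta` (chain settings, acceptance rate, dimension
#'   labels).
#' @export
gibbs_fit <- function(design, iterations = 11000L, burn_in = 1000L,
                      thin = 10L, seed = 1L, priors = default_priors(),
                      save_gamma = FALSE, verbose = FALSE) {
  stopifnot(inherits(design, "design_matrices"))
  if (is.null(design$z)) stop("design has no response attached")
  TT <- length(design$years)
  N <- length(design$countries)
  if (TT < 2L) stop("temporal model undefined for a single year (T >= 2)")
  if (N < 3L) stop("need at least 3 countries")
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  check_design_rank(design)
  set.seed(as.integer(seed))

  p <- ncol(design$X)             # 11 columns
  n_d <- nrow(design$dyads)       # ordered dyads
  rev_row <- design$dyads$reverse_row
  si <- design$dyads$sender_idx
  ri <- design$dyads$receiver_idx
  fwd <- which(si < ri)           # one row per unordered dyad
  z <- design$z

  # fixed cross-products for the coefficient block (tridiagonal in years)
  A0 <- vector("list", TT); B0 <- vector("list", TT)
  A1 <- vector("list", TT); B1 <- vector("list", TT)
  for (t in seq_len(TT)) {
    Xt <- design$X[, , t]
    A0[[t]] <- crossprod(Xt)
    B0[[t]] <- crossprod(Xt, Xt[rev_row, , drop = FALSE])
    if (t < TT) {
      Xn <- design$X[, , t + 1L]
      A1[[t]] <- crossprod(Xt, Xn)
      B1[[t]] <- crossprod(Xt, Xn[rev_row, , drop = FALSE])
    }
  }

  # initial state: per-year OLS for beta, zero latent states
  beta <- matrix(0, p, TT)
  for (t in seq_len(TT)) {
    beta[, t] <- qr.coef(qr(design$X[, , t]), z[, t])
  }
  s <- matrix(0, N, TT)
  r <- matrix(0, N, TT)
  resid0 <- z - sapply(seq_len(TT), function(t) design$X[, , t] %*% beta[, t])
  sigma2_gamma <- max(stats::var(as.vector(resid0)), 1e-4)
  rho <- 0; phi_gg <- 0
  Phi <- diag(0.5, 2)
  sigma_eps <- diag(0.1, 2)

  n_save <- floor((iterations - burn_in) / thin)
  if (n_save < 1L) stop("no draws would be saved; shrink thin or burn_in")
  out <- list(
    beta = array(NA_real_, c(n_save, p, TT),
                 dimnames = list(NULL, design$columns, design$years)),
    phi_matrix = array(NA_real_, c(n_save, 2, 2)),
    phi_gg = numeric(n_save), rho = numeric(n_save),
    sigma2_gamma = numeric(n_save),
    sigma_eps = array(NA_real_, c(n_save, 2, 2)),
    s = array(NA_real_, c(n_save, N, TT),
              dimnames = list(NULL, design$countries, design$years)),
    r = array(NA_real_, c(n_save, N, TT),
              dimnames = list(NULL, design$countries, design$years)))
  if (save_gamma) out$gamma <- array(NA_real_, c(n_save, n_d, TT))

  mh_step <- c(0.05, 0.05, 0.1)   # phi_gg, rho, log sigma2_gamma
  mh_acc <- 0L; mh_tries <- 0L
  beta_prior_prec <- 1 / priors$beta_sd^2
  tidx <- function(t) (2 * t - 1):(2 * t)
  saved <- 0L

  for (iter in seq_len(iterations)) {
    sg_inv <- 1 / (sigma2_gamma * (1 - rho^2))
    sd_ <- sg_inv; so_ <- -rho * sg_inv
    Ci <- ar1_corr_inverse(TT, phi_gg)

    ## (1) beta | s, r, error structure  -- joint conjugate MVN over years
    d_resid <- z - s[si, ] - r[ri, ]       # z minus latent, n_d x T
    P <- matrix(0, p * TT, p * TT)
    b <- numeric(p * TT)
    for (t in seq_len(TT)) {
      bt <- ((t - 1) * p + 1):(t * p)
      P[bt, bt] <- Ci[t, t] * (sd_ * A0[[t]] + so_ * B0[[t]]) +
        diag(beta_prior_prec, p)
      if (t < TT) {
        bn <- (t * p + 1):((t + 1) * p)
        blk <- Ci[t, t + 1L] * (sd_ * A1[[t]] + so_ * B1[[t]])
        P[bt, bn] <- blk
        P[bn, bt] <- t(blk)
      }
      Xt <- design$X[, , t]
      acc <- Ci[t, t] * (sd_ * crossprod(Xt, d_resid[, t]) +
                           so_ * crossprod(Xt, d_resid[rev_row, t]))
      if (t > 1L) {
        acc <- acc + Ci[t, t - 1L] *
          (sd_ * crossprod(Xt, d_resid[, t - 1L]) +
             so_ * crossprod(Xt, d_resid[rev_row, t - 1L]))
      }
      if (t < TT) {
        acc <- acc + Ci[t, t + 1L] *
          (sd_ * crossprod(Xt, d_resid[, t + 1L]) +
             so_ * crossprod(Xt, d_resid[rev_row, t + 1L]))
      }
      b[bt] <- acc
    }
    beta_vec <- draw_mvn_from_precision(P, b)
    if (any(!is.finite(beta_vec))) {
      stop("non-finite likelihood state at iteration ", iter)
    }
    beta <- matrix(beta_vec, p, TT)

    ## (2) per-country sender/receiver trajectories (sequential scan)
    D <- z - sapply(seq_len(TT), function(t) design$X[, , t] %*% beta[, t])
    rowS <- matrix(0, N, TT); colS <- matrix(0, N, TT)
    for (t in seq_len(TT)) {
      rowS[, t] <- tapply(D[, t], si, sum)
      colS[, t] <- tapply(D[, t], ri, sum)
    }
    Ssum <- colSums(s); Rsum <- colSums(r)
    Og_inv <- kronecker(Ci, matrix(c(sd_, so_, so_, sd_), 2, 2))
    Qprior <- var1_prior_precision(Phi, sigma_eps, TT)
    Pu <- Qprior + (N - 1) * Og_inv
    Ru <- chol(Pu)
    for (i in seq_len(N)) {
      g <- numeric(2 * TT)
      g[seq(1, 2 * TT, by = 2)] <- rowS[i, ] - (Rsum - r[i, ])
      g[seq(2, 2 * TT, by = 2)] <- colS[i, ] - (Ssum - s[i, ])
      bu <- Og_inv %*% g
      mu <- backsolve(Ru, forwardsolve(t(Ru), bu))
      ui <- as.vector(mu + backsolve(Ru, stats::rnorm(2 * TT)))
      Ssum <- Ssum - s[i, ]; Rsum <- Rsum - r[i, ]
      s[i, ] <- ui[seq(1, 2 * TT, by = 2)]
      r[i, ] <- ui[seq(2, 2 * TT, by = 2)]
      Ssum <- Ssum + s[i, ]; Rsum <- Rsum + r[i, ]
    }

    ## (3) (phi_gg, rho, sigma2_gamma) | residual pairs  -- Metropolis
    E <- D - s[si, ] - r[ri, ]
    E1 <- E[fwd, , drop = FALSE]
    E2 <- E[rev_row[fwd], , drop = FALSE]
    lp_cur <- dyad_pair_loglik(E1, E2, phi_gg, rho, sigma2_gamma) +
      stats::dgamma(1 / sigma2_gamma, priors$sigma2_gamma_shape,
                    priors$sigma2_gamma_rate, log = TRUE) -
      2 * log(sigma2_gamma) + log(sigma2_gamma)  # IG density + log-scale Jacobian
    prop <- c(phi_gg, rho, log(sigma2_gamma)) +
      stats::rnorm(3) * mh_step
    mh_tries <- mh_tries + 1L
    if (abs(prop[1]) < 1 && abs(prop[2]) < 1) {
      s2_prop <- exp(prop[3])
      lp_prop <- dyad_pair_loglik(E1, E2, prop[1], prop[2], s2_prop) +
        stats::dgamma(1 / s2_prop, priors$sigma2_gamma_shape,
                      priors$sigma2_gamma_rate, log = TRUE) -
        2 * log(s2_prop) + log(s2_prop)
      if (is.finite(lp_prop) &&
          log(stats::runif(1)) < lp_prop - lp_cur) {
        phi_gg <- prop[1]; rho <- prop[2]; sigma2_gamma <- s2_prop
        mh_acc <- mh_acc + 1L
      }
    }
    if (iter <= burn_in && iter %% 50L == 0L) {
      rate <- mh_acc / mh_tries
      mh_step <- mh_step * exp(0.5 * (rate - 0.3))
      mh_acc <- 0L; mh_tries <- 0L
    }

    ## (4) Phi | latent states  -- conjugate matrix regression, truncated
    Yc <- cbind(as.vector(s[, 2:TT]), as.vector(r[, 2:TT]))
    Xl <- cbind(as.vector(s[, 1:(TT - 1)]), as.vector(r[, 1:(TT - 1)]))
    Sei <- solve(sigma_eps)
    Pb <- kronecker(Sei, crossprod(Xl)) +
      diag(1 / priors$phi_prior_sd^2, 4)
    bb <- as.vector(crossprod(Xl, Yc) %*% Sei)
    for (try in seq_len(100L)) {
      Bv <- draw_mvn_from_precision(Pb, bb)
      cand <- t(matrix(Bv, 2, 2))     # B = Phi'
      if (spectral_radius(cand) < 1) { Phi <- cand; break }
    }

    ## (5) Sigma_eps | innovations  -- conjugate inverse-Wishart
    Einn <- Yc - Xl %*% t(Phi)
    sigma_eps <- riwish(priors$sigma_eps_df + nrow(Einn),
                        priors$sigma_eps_scale + crossprod(Einn))

    if (iter > burn_in && (iter - burn_in) %% thin == 0L &&
        saved < n_save) {
      saved <- saved + 1L
      out$beta[saved, , ] <- beta
      out$phi_matrix[saved, , ] <- Phi
      out$phi_gg[saved] <- phi_gg
      out$rho[saved] <- rho
      out$sigma2_gamma[saved] <- sigma2_gamma
      out$sigma_eps[saved, , ] <- sigma_eps
      out$s[saved, , ] <- s
      out$r[saved, , ] <- r
      if (save_gamma) out$gamma[saved, , ] <- E
    }
    if (verbose && iter %% 500L == 0L) {
      message(sprintf("iter %d/%d  phi_s=%.3f phi_r=%.3f phi_gg=%.3f",
                      iter, iterations, Phi[1, 1], Phi[2, 2], phi_gg))
    }
  }

  out$meta <- list(iterations = as.integer(iterations),
                   burn_in = as.integer(burn_in), thin = as.integer(thin),
                   seed = as.integer(seed), n_save = saved,
                   mh_acceptance = if (mh_tries > 0) mh_acc / mh_tries else NA,
                   countries = design$countries, years = design$years,
                   columns = design$columns)
  class(out) <- "posterior_draws"
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf(
    "<posterior_draws> %d saved draws (%d iters, %d burn-in, thin %d); %d countries x %d years\n",
    x$meta$n_save, x$meta$iterations, x$meta$burn_in, x$meta$thin,
    length(x$meta$countries), length(x$meta$years)))
  invisible(x)
}

#' Highest posterior density interval
#'
#' The narrowest contiguous interval containing `ceiling(prob * n)` of the
#' sorted draws.
#'
#' @param draws numeric vector of at least 2 finite draws.
#' @param prob coverage probability in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  if (!is.numeric(prob) || length(prob) != 1 || prob <= 0 || prob >= 1) {
    stop("prob must be a single value in (0, 1)")
  }
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 2) stop("need at least 2 finite draws")
  xs <- sort(draws)
  m <- ceiling(prob * n)
  if (m >= n) return(c(lower = xs[1], upper = xs[n]))
  width <- xs[m:n] - xs[1:(n - m + 1)]
  i <- which.min(width)
  c(lower = xs[i], upper = xs[i + m - 1])
}

#' Time-series standard error of an MCMC chain
#'
#' `sqrt(spectral density at frequency zero / n)` with the spectral density
#' estimated by fitting an autoregressive process (AIC order selection) to
#' the chain; accounts for autocorrelation in the MCMC samples and reduces
#' to `sd/sqrt(n)` for white-noise chains.
#'
#' @param draws numeric chain of at least 50 draws.
#' @return The time-series standard error (scalar).
#' @export
time_series_se <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) < 50) stop("need at least 50 draws")
  if (stats::sd(draws) == 0) stop("constant chain has zero variance")
  fit <- stats::ar(draws, aic = TRUE)
  spec0 <- if (length(fit$ar) == 0) fit$var.pred else
    fit$var.pred / (1 - sum(fit$ar))^2
  sqrt(spec0 / length(draws))
}

#' Summarize posterior draws
#'
#' Coefficient summaries use the posterior mean with a 95% HPD interval and
#' a significance flag (HPD excludes zero); temporal-dependence parameters
#' (the \eqn{\Phi} entries and \eqn{\phi_{gg}}) use the median with
#' equal-tail 2.5%/97.5% quantiles; sender/receiver effects are summarized
#' by their posterior mean per country-year and its time-average.
#'
#' @param draws a `posterior_draws` object from [gibbs_fit()].
#' @param prob HPD coverage for coefficients (default 0.95).
#' @return An object of class `posterior_summary`: list of data frames
#'   `coefficients` (coefficient, year, mean, hpd_lo, hpd_hi, significant),
#'   `phi` (parameter, median, q2.5, q97.5; rows phi_s, phi_sr, phi_rs,
#'   phi_r, phi_gg), `variance` (rho, sigma2_gamma, sigma_eps entries) and
#'   `effects` (country, year, sender, receiver) plus `effects_avg`.
#' @export
summarize_posterior <- function(draws, prob = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (draws$meta$n_save < 1) stop("no saved draws to summarize")
  cols <- draws$meta$columns
  years <- draws$meta$years
  co <- do.call(rbind, lapply(seq_along(years), function(t) {
    do.call(rbind, lapply(seq_along(cols), function(k) {
      v <- draws$beta[, k, t]
      h <- hpd_interval(v, prob)
      data.frame(coefficient = cols[k], year = years[t], mean = mean(v),
                 hpd_lo = h[["lower"]], hpd_hi = h[["upper"]],
                 significant = h[["lower"]] > 0 | h[["upper"]] < 0,
                 stringsAsFactors = FALSE)
    }))
  }))
  qsum <- function(v, name) {
    q <- stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(parameter = name, median = q[1], q2.5 = q[2], q97.5 = q[3],
               stringsAsFactors = FALSE)
  }
  phi <- rbind(qsum(draws$phi_matrix[, 1, 1], "phi_s"),
               qsum(draws$phi_matrix[, 1, 2], "phi_sr"),
               qsum(draws$phi_matrix[, 2, 1], "phi_rs"),
               qsum(draws$phi_matrix[, 2, 2], "phi_r"),
               qsum(draws$phi_gg, "phi_gg"))
  variance <- rbind(qsum(draws$rho, "rho"),
                    qsum(draws$sigma2_gamma, "sigma2_gamma"),
                    qsum(draws$sigma_eps[, 1, 1], "sigma_eps_ss"),
                    qsum(draws$sigma_eps[, 2, 2], "sigma_eps_rr"),
                    qsum(draws$sigma_eps[, 1, 2], "sigma_eps_sr"))
  countries <- draws$meta$countries
  s_mean <- apply(draws$s, c(2, 3), mean)
  r_mean <- apply(draws$r, c(2, 3), mean)
  effects <- data.frame(
    country = rep(countries, times = length(years)),
    year = rep(years, each = length(countries)),
    sender = as.vector(s_mean), receiver = as.vector(r_mean),
    stringsAsFactors = FALSE)
  effects_avg <- data.frame(country = countries,
                            sender = rowMeans(s_mean),
                            receiver = rowMeans(r_mean),
                            stringsAsFactors = FALSE)
  structure(list(coefficients = co, phi = phi, variance = variance,
                 effects = effects, effects_avg = effects_avg,
                 prob = prob),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary>\n\nTemporal dependence (median [2.5%, 97.5%]):\n")
  print(x$phi, row.names = FALSE, digits = 3)
  nsig <- sum(x$coefficients$significant)
  cat(sprintf("\n%d of %d coefficient-years significant at %.0f%% HPD\n",
              nsig, nrow(x$coefficients), 100 * x$prob))
  invisible(x)
}
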