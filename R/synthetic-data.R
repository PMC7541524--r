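#' Configuration for the synthetic trade-network generator
#'
#' Bundles every parameter of the generative model behind the longitudinal
#' dyadic mixed-effects analysis: per-year gravity coefficients, the 2x2
#' VAR(1) transition matrix of the sender/receiver random effects, the AR(1)
#' coefficient and reciprocity correlation of the dyadic residual pairs, the
#' innovation covariance, and the covariate ranges the country/dyad panels
#' are drawn from.
#'
#' Default coefficient values give log-scale flows with mean around 7
#' (roughly 1,000 tonnes) so that flooring negative latent flows at zero
#' censors only a small tail; variance defaults put the sender, receiver and
#' dyadic components on comparable scales.
#'
#' @param n_countries number of countries (N >= 3).
#' @param n_years number of years (T >= 2).
#' @param seed integer RNG seed; all generator output is a deterministic
#'   function of the config including this seed.
#' @param beta either a single numeric vector of length 11 (recycled across
#'   years) or an 11 x T matrix of per-year coefficients, ordered as
#'   (intercept, agreement, ln distance, ln GDPpc sender, ln GDPpc receiver,
#'   ln pop sender, ln pop receiver, ln pasture sender, ln pasture receiver,
#'   ln DES sender, ln DES receiver).
#' @param phi_matrix 2x2 VAR(1) transition matrix of the (sender, receiver)
#'   effect pair; spectral radius must be < 1.
#' @param phi_gg AR(1) coefficient of the dyadic residual pairs, |phi_gg|<1.
#' @param rho within-pair (reciprocity) correlation of the dyadic residuals,
#'   |rho| < 1.
#' @param sigma2_gamma stationary marginal variance of each dyadic residual.
#' @param sigma_eps 2x2 positive-definite innovation covariance of the
#'   sender/receiver VAR(1).
#' @param covariate_ranges named list of length-2 numeric ranges:
#'   `gdp_pc` (constant-2010 USD), `population` (thousands),
#'   `pasture_km2`, `des_pct`, `lat`, `lon`. Positive covariates are drawn
#'   log-uniformly within their range; coordinates uniformly.
#' @param agreement_prob probability that an unordered dyad has a trade
#'   agreement in a given year (i.i.d. across dyad-years, symmetric within
#'   a dyad-year).
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_countries = 30L,
                             n_years = 10L,
                             seed = 1L,
                             beta = c(0, 0.5, -0.8, 0.3, 0.3, 0.4, 0.5,
                                      0.1, -0.1, 0.2, 0.5),
                             phi_matrix = matrix(c(0.9, 0, 0, 0.8), 2, 2),
                             phi_gg = 0.3,
                             rho = 0.5,
                             sigma2_gamma = 1,
                             sigma_eps = diag(0.25, 2),
                             covariate_ranges = list(
                               gdp_pc = c(500, 60000),
                               population = c(100, 1.4e6),
                               pasture_km2 = c(100, 1e6),
                               des_pct = c(85, 140),
                               lat = c(-60, 70),
                               lon = c(-179, 180)),
                             agreement_prob = 0.3) {
  n_countries <- as.integer(n_countries)
  n_years <- as.integer(n_years)
  if (is.na(n_countries) || n_countries <= 0) {
    stop("n_countries must be a positive integer")
  }
  if (is.na(n_years) || n_years < 2) stop("n_years must be at least 2")
  beta <- if (is.matrix(beta)) beta else
    matrix(beta, nrow = length(beta), ncol = n_years)
  if (nrow(beta) != 11L) stop("beta must have 11 coefficients per year")
  if (ncol(beta) != n_years) stop("beta must have one column per year")
  phi_matrix <- matrix(as.numeric(phi_matrix), 2, 2)
  if (spectral_radius(phi_matrix) >= 1) {
    stop("phi_matrix must have spectral radius < 1 (stationary VAR)")
  }
  if (abs(phi_gg) >= 1) stop("|phi_gg| must be < 1")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (sigma2_gamma <= 0) stop("sigma2_gamma must be > 0")
  sigma_eps <- matrix(as.numeric(sigma_eps), 2, 2)
  if (!isTRUE(all(eigen(sigma_eps, symmetric = TRUE,
                        only.values = TRUE)$values > 0))) {
    stop("sigma_eps must be positive definite")
  }
  if (agreement_prob < 0 || agreement_prob > 1) {
    stop("agreement_prob must be in [0, 1]")
  }
  needed <- c("gdp_pc", "population", "pasture_km2", "des_pct", "lat", "lon")
  if (!all(needed %in% names(covariate_ranges))) {
    stop("covariate_ranges must name: ", paste(needed, collapse = ", "))
  }
  structure(list(
    n_countries = n_countries, n_years = n_years, seed = as.integer(seed),
    beta = beta, phi_matrix = phi_matrix, phi_gg = phi_gg, rho = rho,
    sigma2_gamma = sigma2_gamma, sigma_eps = sigma_eps,
    covariate_ranges = covariate_ranges, agreement_prob = agreement_prob),
    class = "synthetic_config")
}

#' Read a synthetic-generator configuration from a JSON file
#'
#' The file is a flat JSON object whose keys are the arguments of
#' [synthetic_config()]; `beta` may be a vector or an 11 x T matrix
#' (row-major nested arrays), `phi_matrix`/`sigma_eps` are 2x2 nested
#' arrays, `covariate_ranges` a named object of 2-vectors. Missing keys take
#' the defaults.
#'
#' @param path path to the JSON config file.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw), names(formals(synthetic_config)))]
  if (!is.null(args$phi_matrix)) args$phi_matrix <- matrix(unlist(args$phi_matrix), 2, 2, byrow = TRUE)
  if (!is.null(args$sigma_eps)) args$sigma_eps <- matrix(unlist(args$sigma_eps), 2, 2, byrow = TRUE)
  if (!is.null(args$beta) && is.matrix(args$beta)) args$beta <- t(args$beta)
  do.call(synthetic_config, args)
}

country_codes <- function(n) {
  # synthetic ISO3-like codes: C01 ... Cnn
  sprintf("C%02d", seq_len(n))
}

runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Generate synthetic country and dyad panels
#'
#' Draws a complete country-year covariate grid (per-capita GDP, population,
#' pasture area, dietary-energy-supply adequacy; all strictly positive,
#' log-uniform within the configured ranges), one fixed centroid per
#' country, and a symmetric Bernoulli trade-agreement indicator per
#' dyad-year. Deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A list with `panel` (data frame: country, year, gdp_pc,
#'   population, pasture_km2, des_pct, lat, lon) and `dyads` (data frame:
#'   sender, receiver, year, agreement, distance_km; one row per ordered
#'   dyad-year, agreement and distance symmetric).
#' @export
generate_country_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  N <- config$n_countries
  TT <- config$n_years
  set.seed(config$seed)
  codes <- country_codes(N)
  years <- seq_len(TT) + 1994L  # nominal calendar labelling
  rg <- config$covariate_ranges
  lat <- stats::runif(N, rg$lat[1], rg$lat[2])
  lon <- stats::runif(N, rg$lon[1], rg$lon[2])
  panel <- data.frame(
    country = rep(codes, each = TT),
    year = rep(years, N),
    gdp_pc = runif_log(N * TT, rg$gdp_pc),
    population = runif_log(N * TT, rg$population),
    pasture_km2 = runif_log(N * TT, rg$pasture_km2),
    des_pct = runif_log(N * TT, rg$des_pct),
    lat = rep(lat, each = TT),
    lon = rep(lon, each = TT),
    stringsAsFactors = FALSE)

  pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)  # i < j
  n_pairs <- nrow(pairs)
  agree <- matrix(stats::rbinom(n_pairs * TT, 1, config$agreement_prob),
                  n_pairs, TT)
  dist_km <- great_circle_distance(lat[pairs[, 1]], lon[pairs[, 1]],
                                   lat[pairs[, 2]], lon[pairs[, 2]])
  fwd <- data.frame(
    sender = rep(codes[pairs[, 1]], each = TT),
    receiver = rep(codes[pairs[, 2]], each = TT),
    year = rep(years, n_pairs),
    agreement = as.vector(t(agree)),
    distance_km = rep(dist_km, each = TT),
    stringsAsFactors = FALSE)
  rev <- fwd
  rev$sender <- fwd$receiver
  rev$receiver <- fwd$sender
  dyads <- rbind(fwd, rev)
  dyads <- dyads[order(dyads$sender, dyads$receiver, dyads$year), ,
                 drop = FALSE]
  rownames(dyads) <- NULL
  list(panel = panel, dyads = dyads)
}

#' Stationary covariance of a VAR(1) process
#'
#' Solves the discrete Lyapunov equation `S = Phi S Phi' + Sigma` by the
#' vectorisation identity `(I - Phi (x) Phi) vec(S) = vec(Sigma)`.
#'
#' @param phi square transition matrix with spectral radius < 1.
#' @param sigma innovation covariance (same dimension).
#' @return The stationary covariance matrix `S`.
#' @export
stationary_var_cov <- function(phi, sigma) {
  d <- nrow(phi)
  if (spectral_radius(phi) >= 1) stop("phi is not stationary")
  vecS <- solve(diag(d * d) - kronecker(phi, phi), as.vector(sigma))
  S <- matrix(vecS, d, d)
  (S + t(S)) / 2
}

#' Simulate a trade tensor from the longitudinal dyadic model
#'
#' Draws the latent structure and the response of the gravity model with
#' sender/receiver and reciprocity effects:
#' \deqn{z_{ijt} = x_{ijt}'\beta_t + s_{it} + r_{jt} + \gamma_{ijt}}
#' where per country the pair \eqn{u_{it} = (s_{it}, r_{it})} follows a
#' stationary VAR(1) with transition `phi_matrix` and innovation covariance
#' `sigma_eps` (the year-1 state is drawn from the stationary law), and per
#' unordered dyad the pair \eqn{(\gamma_{ijt}, \gamma_{jit})} follows a
#' stationary AR(1) with coefficient `phi_gg`, marginal variance
#' `sigma2_gamma` and within-pair correlation `rho` (innovations scaled by
#' `1 - phi_gg^2` so the marginal law is time-invariant). Stored trade is
#' `y = exp(z) - 1` floored at zero, the inverse of the `ln(1 + y)`
#' response transform.
#'
#' @param panel,dyads output of [generate_country_panel()].
#' @param config the same [synthetic_config()].
#' @return A list with `tensor` (a [trade_tensor()]), and `latent`: a list
#'   with `s`, `r` (N x T matrices, rows named by country), `gamma`
#'   (N x N x T array, diagonal NA) and `z` (N x N x T log-scale response
#'   before flooring).
#' @export
simulate_trade_tensor <- function(panel, dyads, config) {
  stopifnot(inherits(config, "synthetic_config"))
  N <- config$n_countries
  TT <- config$n_years
  codes <- country_codes(N)
  years <- sort(unique(panel$year))
  if (!setequal(unique(panel$country), codes) || length(years) != TT) {
    stop("panel does not cover the countries/years named in the config")
  }
  # seed offset keeps panel and tensor draws independent but reproducible
  set.seed(config$seed + 1000003L)

  Phi <- config$phi_matrix
  S0 <- stationary_var_cov(Phi, config$sigma_eps)
  L0 <- chol_psd(S0)
  Le <- chol_psd(config$sigma_eps)
  s <- matrix(0, N, TT, dimnames = list(codes, years))
  r <- matrix(0, N, TT, dimnames = list(codes, years))
  u <- t(L0) %*% matrix(stats::rnorm(2 * N), 2, N)  # 2 x N at t=1
  s[, 1] <- u[1, ]
  r[, 1] <- u[2, ]
  for (t in 2:TT) {
    u <- Phi %*% u + t(Le) %*% matrix(stats::rnorm(2 * N), 2, N)
    s[, t] <- u[1, ]
    r[, t] <- u[2, ]
  }

  Sg <- config$sigma2_gamma *
    matrix(c(1, config$rho, config$rho, 1), 2, 2)
  Lg <- chol_psd(Sg)
  Lh <- sqrt(1 - config$phi_gg^2) * Lg  # innovation chol: stationary marginal
  pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  n_pairs <- nrow(pairs)
  gamma <- array(NA_real_, dim = c(N, N, TT),
                 dimnames = list(codes, codes, years))
  v <- t(Lg) %*% matrix(stats::rnorm(2 * n_pairs), 2, n_pairs)
  gamma[cbind(pairs[, 1], pairs[, 2], 1L)] <- v[1, ]
  gamma[cbind(pairs[, 2], pairs[, 1], 1L)] <- v[2, ]
  for (t in 2:TT) {
    v <- config$phi_gg * v +
      t(Lh) %*% matrix(stats::rnorm(2 * n_pairs), 2, n_pairs)
    gamma[cbind(pairs[, 1], pairs[, 2], t)] <- v[1, ]
    gamma[cbind(pairs[, 2], pairs[, 1], t)] <- v[2, ]
  }

  design <- build_design_matrices(panel, dyads,
                                  tensor = NULL, countries = codes,
                                  years = years)
  z <- array(0, dim = c(N, N, TT), dimnames = list(codes, codes, years))
  for (t in seq_len(TT)) {
    xb <- design$X[, , t] %*% config$beta[, t]
    zt <- matrix(0, N, N)
    zt[cbind(design$dyads$sender_idx, design$dyads$receiver_idx)] <- xb
    z[, , t] <- zt + outer(s[, t], rep(1, N)) + outer(rep(1, N), r[, t]) +
      ifelse(is.na(gamma[, , t]), 0, gamma[, , t])
    diag(z[, , t]) <- 0
  }
  y <- pmax(exp(z) - 1, 0)
  for (t in seq_len(TT)) diag(y[, , t]) <- 0
  tensor <- trade_tensor(y, codes, years)
  list(tensor = tensor,
       latent = list(s = s, r = r, gamma = gamma, z = z))
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: panels plus simulated tensor and latent truth.
#'
#' @param config a [synthetic_config()].
#' @return A list with `panel`, `dyads`, `tensor`, `latent`, `config`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  pan <- generate_country_panel(config)
  sim <- simulate_trade_tensor(pan$panel, pan$dyads, config)
  c(pan, sim, list(config = config))
}
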