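#' Great-circle distance between points on the Earth
#'
#' Haversine formula on a sphere of radius 6,371 km. Vectorised; symmetric;
#' zero only for identical points.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees
#'   (latitude in \[-90, 90\], longitude in (-180, 180\]).
#' @return Distance(s) in kilometres.
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) ||
      any(c(lon1, lon2) <= -180) || any(c(lon1, lon2) > 180)) {
    stop("coordinates out of range: lat in [-90,90], lon in (-180,180]")
  }
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  6371 * 2 * asin(pmin(1, sqrt(a)))
}

#' Log response transform for trade quantities
#'
#' `z = ln(1 + y)`: monotone, maps zero flows to exactly zero and is
#' invertible by `y = exp(z) - 1`. Used because the model is linear on the
#' log scale but the zero-filled tensor contains genuine zeros on which
#' `ln(y)` is undefined.
#'
#' @param tensor a [trade_tensor()], or a non-negative numeric array.
#' @return An array of the same shape on the log scale.
#' @export
transform_response <- function(tensor) {
  y <- if (inherits(tensor, "trade_tensor")) tensor$flows else tensor
  if (any(y < 0, na.rm = TRUE)) stop("negative trade quantities")
  log1p(y)
}

#' Design-matrix column names of the gravity model
#' @return Character vector of the 11 column names, intercept first.
#' @export
design_columns <- function() {
  c("intercept", "agreement", "ln_distance",
    "ln_gdp_pc_s", "ln_gdp_pc_r", "ln_pop_s", "ln_pop_r",
    "ln_pasture_s", "ln_pasture_r", "ln_des_s", "ln_des_r")
}

#' Build gravity design matrices for the longitudinal dyadic model
#'
#' Assembles, per year, the covariate matrix of the log-linear gravity
#' model: intercept; trade-agreement indicator (untransformed 0/1); and the
#' natural logs of centroid distance, sender and receiver per-capita GDP,
#' population, pasture area, and dietary-energy-supply adequacy. Rows are
#' ordered dyads (sender, receiver), lexicographic. A pasture area of zero
#' is floored at 1 km^2 before logging so the design stays finite.
#'
#' @param panel country-year covariate data frame with columns `country`,
#'   `year`, `gdp_pc`, `population`, `pasture_km2`, `des_pct` and either
#'   `lat`/`lon` columns or a `distance_km` column in `dyads`.
#' @param dyads dyad data frame with columns `sender`, `receiver`, `year`,
#'   `agreement` and optionally `distance_km` (otherwise distance is
#'   computed from panel centroids).
#' @param tensor optional [trade_tensor()]; when given, the log response
#'   `z = ln(1 + y)` is attached and `countries`/`years` default to its
#'   grid.
#' @param countries,years grid to build over (required if `tensor` absent).
#' @return An object of class `design_matrices`: list with
#'   `X` (array n_dyads x 11 x T), `z` (matrix n_dyads x T, NULL if no
#'   tensor), `dyads` (index map with sender, receiver and their integer
#'   indices), `countries`, `years`, `columns`.
#' @export
build_design_matrices <- function(panel, dyads, tensor = NULL,
                                  countries = NULL, years = NULL) {
  if (!is.null(tensor)) {
    stopifnot(inherits(tensor, "trade_tensor"))
    if (is.null(countries)) countries <- tensor$countries
    if (is.null(years)) years <- tensor$years
  }
  if (is.null(countries) || is.null(years)) {
    stop("countries and years are required when no tensor is given")
  }
  countries <- as.character(countries)
  years <- as.integer(years)
  N <- length(countries)
  TT <- length(years)
  if (N < 2) stop("need at least 2 countries")

  # lexicographic ordered dyads
  grid <- expand.grid(receiver_idx = seq_len(N), sender_idx = seq_len(N))
  grid <- grid[grid$sender_idx != grid$receiver_idx,
               c("sender_idx", "receiver_idx")]
  ord <- order(countries[grid$sender_idx], countries[grid$receiver_idx])
  grid <- grid[ord, , drop = FALSE]
  rownames(grid) <- NULL
  grid$sender <- countries[grid$sender_idx]
  grid$receiver <- countries[grid$receiver_idx]
  n_d <- nrow(grid)
  # row index of the reversed dyad, used by the sampler's reciprocity terms
  grid$reverse_row <- match(paste(grid$receiver, grid$sender),
                            paste(grid$sender, grid$receiver))

  covar_cols <- c("gdp_pc", "population", "pasture_km2", "des_pct")
  pkey <- paste(panel$country, panel$year)

  # distance: prefer dyad-supplied, else centroid haversine
  if (!is.null(dyads$distance_km)) {
    dk <- dyads[!duplicated(paste(dyads$sender, dyads$receiver)), ,
                drop = FALSE]
    dist_km <- dk$distance_km[match(paste(grid$sender, grid$receiver),
                                    paste(dk$sender, dk$receiver))]
  } else {
    if (is.null(panel$lat) || is.null(panel$lon)) {
      stop("need either dyads$distance_km or panel lat/lon centroids")
    }
    cent <- panel[!duplicated(panel$country), c("country", "lat", "lon")]
    ci <- match(grid$sender, cent$country)
    cj <- match(grid$receiver, cent$country)
    dist_km <- great_circle_distance(cent$lat[ci], cent$lon[ci],
                                     cent$lat[cj], cent$lon[cj])
  }
  if (any(!is.finite(dist_km) | dist_km <= 0)) {
    stop("distances must be positive and finite for all dyads")
  }

  akey <- paste(dyads$sender, dyads$receiver, dyads$year)
  X <- array(NA_real_, dim = c(n_d, 11L, TT),
             dimnames = list(NULL, design_columns(), years))
  for (t in seq_len(TT)) {
    yr <- years[t]
    row_of <- match(paste(countries, yr), pkey)
    if (anyNA(row_of)) {
      stop("missing covariate rows for ",
           paste(countries[is.na(row_of)], collapse = ", "),
           " in year ", yr)
    }
    cv <- as.matrix(panel[row_of, covar_cols])
    bad_row <- apply(!is.finite(cv), 1, any) |
      cv[, "gdp_pc"] <= 0 | cv[, "population"] <= 0 |
      cv[, "des_pct"] <= 0 | cv[, "pasture_km2"] < 0
    if (any(bad_row)) {
      stop("invalid covariate values for ",
           paste(countries[bad_row], collapse = ", "), " in year ", yr)
    }
    cv[, "pasture_km2"] <- pmax(cv[, "pasture_km2"], 1)  # floor pre-log
    agree <- dyads$agreement[match(paste(grid$sender, grid$receiver, yr),
                                   akey)]
    if (anyNA(agree)) stop("missing agreement indicator(s) in year ", yr)
    X[, , t] <- cbind(
      1, agree, log(dist_km),
      log(cv[grid$sender_idx, "gdp_pc"]), log(cv[grid$receiver_idx, "gdp_pc"]),
      log(cv[grid$sender_idx, "population"]), log(cv[grid$receiver_idx, "population"]),
      log(cv[grid$sender_idx, "pasture_km2"]), log(cv[grid$receiver_idx, "pasture_km2"]),
      log(cv[grid$sender_idx, "des_pct"]), log(cv[grid$receiver_idx, "des_pct"]))
  }
  if (any(!is.finite(X))) stop("non-finite entries in design matrix")

  z <- NULL
  if (!is.null(tensor)) {
    zt <- transform_response(tensor)
    z <- matrix(0, n_d, TT)
    for (t in seq_len(TT)) {
      z[, t] <- zt[cbind(grid$sender_idx, grid$receiver_idx, t)]
    }
  }
  structure(list(X = X, z = z, dyads = grid, countries = countries,
                 years = years, columns = design_columns()),
            class = "design_matrices")
}

#' @export
print.design_matrices <- function(x, ...) {
  cat(sprintf("<design_matrices> %d ordered dyads x %d columns x %d years%s\n",
              nrow(x$dyads), length(x$columns), length(x$years),
              if (is.null(x$z)) " (no response attached)" else ""))
  invisible(x)
}
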