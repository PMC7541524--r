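#' Construct a trade tensor
#'
#' A trade tensor holds directed bilateral flow quantities `y[i, j, t]`
#' (tonnes) for an ordered set of countries and years. The diagonal
#' (domestic "self-trade") is identically zero and every off-diagonal cell is
#' a finite non-negative number: absent dyad-years are genuine zeros, not
#' missing values.
#'
#' @param flows numeric array of dimension `c(N, N, T)`; `flows[i, j, t]` is
#'   the quantity shipped from `countries[i]` to `countries[j]` in
#'   `years[t]`.
#' @param countries character vector of country codes (length `N`).
#' @param years integer vector of years (length `T`).
#' @return An object of class `trade_tensor`: a list with elements
#'   `countries`, `years` and `flows` (the validated array, dimnames set).
#' @export
trade_tensor <- function(flows, countries, years) {
  countries <- as.character(countries)
  years <- as.integer(years)
  if (anyDuplicated(countries)) stop("duplicate country codes")
  if (anyDuplicated(years)) stop("duplicate years")
  flows <- as.array(flows)
  if (length(dim(flows)) != 3L ||
      dim(flows)[1] != length(countries) ||
      dim(flows)[2] != length(countries) ||
      dim(flows)[3] != length(years)) {
    stop("flows must be an N x N x T array matching countries and years")
  }
  if (any(!is.finite(flows))) stop("flows must be finite")
  if (any(flows < 0)) stop("flows must be non-negative")
  for (t in seq_along(years)) {
    diag(flows[, , t]) <- 0
  }
  dimnames(flows) <- list(countries, countries, years)
  structure(list(countries = countries, years = years, flows = flows),
            class = "trade_tensor")
}

#' @export
print.trade_tensor <- function(x, ...) {
  cat(sprintf("<trade_tensor> %d countries x %d years, total %.1f tonnes\n",
              length(x$countries), length(x$years), sum(x$flows)))
  invisible(x)
}

#' Read a bilateral trade matrix from CSV
#'
#' Long-format CSV with one row per reported flow. Accepts either the
#' canonical header `sender,receiver,year,quantity_tonnes` or the
#' reporter-style header `reporter,partner,year,quantity`.
#'
#' @param path path to a UTF-8 CSV file.
#' @param source label attached to every record, one of
#'   `"exporter_reported"` or `"importer_reported"`.
#' @return A data frame of flow records with columns `reporter`, `partner`,
#'   `year`, `quantity`, `source`.
#' @export
read_trade_matrix <- function(path, source = "exporter_reported") {
  source <- match.arg(source, c("exporter_reported", "importer_reported"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  nm <- names(df)
  canon <- c(sender = "reporter", receiver = "partner",
             quantity_tonnes = "quantity")
  hit <- nm %in% names(canon)
  nm[hit] <- canon[nm[hit]]
  names(df) <- nm
  required <- c("reporter", "partner", "year", "quantity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("trade matrix file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  df$reporter <- as.character(df$reporter)
  df$partner <- as.character(df$partner)
  df$year <- suppressWarnings(as.integer(df$year))
  df$quantity <- suppressWarnings(as.numeric(df$quantity))
  bad <- which(!is.finite(df$quantity) | is.na(df$year))
  if (length(bad)) {
    stop("malformed numeric field in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  neg <- which(df$quantity < 0)
  if (length(neg)) {
    stop("negative quantity in row(s): ",
         paste(utils::head(neg, 5L), collapse = ", "))
  }
  loops <- which(df$reporter == df$partner)
  if (length(loops)) {
    stop("reporter equals partner in row(s): ",
         paste(utils::head(loops, 5L), collapse = ", "))
  }
  df$source <- source
  df
}

#' Merge exporter- and importer-reported flows
#'
#' Reconciles the two reporting perspectives of a bilateral trade matrix.
#' Exporter-reported rows are already oriented sender -> receiver.
#' Importer-reported rows have `reporter` = importer and `partner` =
#' exporter and are flipped during the merge. For every (sender, receiver,
#' year) the exporter-reported value wins; the importer-reported value is
#' used only to fill gaps.
#'
#' @param exports data frame of exporter-reported records
#'   (see [read_trade_matrix()]).
#' @param imports data frame of importer-reported records.
#' @return A data frame with columns `sender`, `receiver`, `year`,
#'   `quantity`, `source`, one row per dyad-year present in either input.
#' @export
merge_reported_flows <- function(exports, imports) {
  orient <- function(df, flip) {
    if (is.null(df) || nrow(df) == 0) {
      return(data.frame(sender = character(), receiver = character(),
                        year = integer(), quantity = numeric(),
                        source = character(), stringsAsFactors = FALSE))
    }
    data.frame(
      sender = if (flip) df$partner else df$reporter,
      receiver = if (flip) df$reporter else df$partner,
      year = df$year, quantity = df$quantity, source = df$source,
      stringsAsFactors = FALSE)
  }
  ex <- orient(exports, flip = FALSE)
  im <- orient(imports, flip = TRUE)
  key <- function(d) paste(d$sender, d$receiver, d$year, sep = "\r")
  im <- im[!(key(im) %in% key(ex)), , drop = FALSE]
  out <- rbind(ex, im)
  out[order(out$sender, out$receiver, out$year), , drop = FALSE]
}

#' Assemble a zero-filled trade tensor from flow records
#'
#' Every ordered dyad-year cell of the tensor is populated: dyad-years with
#' no reported flow become zeros. Flows naming countries outside `countries`
#' are dropped (their count is reported via a message).
#'
#' @param flows data frame with columns `sender`, `receiver`, `year`,
#'   `quantity` (output of [merge_reported_flows()]), or the reporter-style
#'   columns of [read_trade_matrix()].
#' @param countries character vector of country codes to keep.
#' @param years integer vector of years to keep.
#' @return A [trade_tensor()].
#' @export
build_trade_tensor <- function(flows, countries, years) {
  if (length(countries) == 0 || length(years) == 0) {
    stop("countries and years must be non-empty")
  }
  countries <- as.character(countries)
  years <- as.integer(years)
  if (!is.null(flows) && nrow(flows) > 0) {
    if (!"sender" %in% names(flows) && "reporter" %in% names(flows)) {
      flows$sender <- flows$reporter
      flows$receiver <- flows$partner
    }
    keep <- flows$sender %in% countries & flows$receiver %in% countries &
      flows$year %in% years
    dropped <- sum(!keep)
    if (dropped > 0) {
      message(sprintf("build_trade_tensor: dropped %d flow(s) naming countries/years outside the target grid", dropped))
    }
    flows <- flows[keep, , drop = FALSE]
    key <- paste(flows$sender, flows$receiver, flows$year, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)]
      conf <- vapply(unique(dup), function(k) {
        length(unique(flows$quantity[key == k])) > 1L
      }, logical(1))
      if (any(conf)) {
        stop("conflicting duplicate flow(s) for dyad-year(s): ",
             paste(utils::head(gsub("\r", "/", names(conf)[conf]), 3L),
                   collapse = ", "))
      }
      flows <- flows[!duplicated(key), , drop = FALSE]
    }
  }
  arr <- array(0, dim = c(length(countries), length(countries), length(years)))
  if (!is.null(flows) && nrow(flows) > 0) {
    i <- match(flows$sender, countries)
    j <- match(flows$receiver, countries)
    t <- match(flows$year, years)
    arr[cbind(i, j, t)] <- flows$quantity
  }
  trade_tensor(arr, countries, years)
}

#' Filter countries by covariate completeness and trade activity
#'
#' Applies the two exclusion rules used when assembling a panel for the
#' longitudinal network model: (1) drop any country with one or more missing
#' covariate values in any year; (2) drop any country whose total trade
#' (exports plus imports, summed over partners) is zero in at least one
#' year. Rule 2 is re-applied until a fixed point, because removing a
#' country can zero out a remaining country's yearly total.
#'
#' @param tensor a [trade_tensor()].
#' @param panel country panel data frame (see [generate_country_panel()]);
#'   columns `country`, `year`, `gdp_pc`, `population`, `pasture_km2`,
#'   `des_pct`. Countries in the tensor but absent from the panel count as
#'   missing-covariate countries.
#' @return A list with elements `tensor` (restricted to survivors), `panel`
#'   (idem) and `report`, a data frame with columns `country` and `rule`
#'   (`"missing_covariate"` or `"zero_trade"`) for each removed country.
#' @export
filter_countries <- function(tensor, panel) {
  stopifnot(inherits(tensor, "trade_tensor"))
  countries <- tensor$countries
  years <- tensor$years
  covar_cols <- c("gdp_pc", "population", "pasture_km2", "des_pct")
  removed <- data.frame(country = character(), rule = character(),
                        stringsAsFactors = FALSE)

  # rule 1: complete covariates over the full grid
  bad1 <- vapply(countries, function(cc) {
    sub <- panel[panel$country == cc & panel$year %in% years, , drop = FALSE]
    if (nrow(sub) < length(years)) return(TRUE)
    any(!is.finite(as.matrix(sub[covar_cols])))
  }, logical(1))
  if (any(bad1)) {
    removed <- rbind(removed, data.frame(country = countries[bad1],
                                         rule = "missing_covariate",
                                         stringsAsFactors = FALSE))
  }
  keep <- countries[!bad1]

  # rule 2: nonzero total trade every year, iterated to a fixed point
  repeat {
    if (length(keep) == 0) stop("all countries removed by filtering rules")
    idx <- match(keep, countries)
    sub <- tensor$flows[idx, idx, , drop = FALSE]
    tot <- sapply(seq_along(keep), function(k) {
      min(sapply(seq_along(years), function(t) {
        sum(sub[k, , t]) + sum(sub[, k, t])
      }))
    })
    zero <- tot <= 0
    if (!any(zero)) break
    removed <- rbind(removed, data.frame(country = keep[zero],
                                         rule = "zero_trade",
                                         stringsAsFactors = FALSE))
    keep <- keep[!zero]
  }

  idx <- match(keep, countries)
  out_tensor <- trade_tensor(tensor$flows[idx, idx, , drop = FALSE],
                             keep, years)
  out_panel <- panel[panel$country %in% keep, , drop = FALSE]
  list(tensor = out_tensor, panel = out_panel, report = removed)
}

#' Write a trade tensor as a long-format CSV
#'
#' Inverse of [read_trade_matrix()] followed by [build_trade_tensor()]:
#' writing then reading recovers the nonzero flows exactly.
#'
#' @param tensor a [trade_tensor()].
#' @param path output file path.
#' @param omit_zeros drop zero-quantity cells from the file (default TRUE;
#'   they are re-created by zero-filling on assembly).
#' @return `path`, invisibly.
#' @export
write_trade_matrix <- function(tensor, path, omit_zeros = TRUE) {
  stopifnot(inherits(tensor, "trade_tensor"))
  N <- length(tensor$countries)
  TT <- length(tensor$years)
  grid <- expand.grid(i = seq_len(N), j = seq_len(N), t = seq_len(TT))
  grid <- grid[grid$i != grid$j, , drop = FALSE]
  df <- data.frame(
    sender = tensor$countries[grid$i],
    receiver = tensor$countries[grid$j],
    year = tensor$years[grid$t],
    quantity_tonnes = tensor$flows[cbind(grid$i, grid$j, grid$t)],
    stringsAsFactors = FALSE)
  if (omit_zeros) df <- df[df$quantity_tonnes > 0, , drop = FALSE]
  df <- df[order(df$sender, df$receiver, df$year), , drop = FALSE]
  # 17 significant digits so write -> read round-trips doubles bit-exactly
  df$quantity_tonnes <- sprintf("%.17g", df$quantity_tonnes)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write trade matrix to ", path)
  invisible(path)
}
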