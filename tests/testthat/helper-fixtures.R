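# shared fixtures and independent oracles

# two disconnected directed 3-cycles, unit weights (nodes 1-3 and 4-6)
two_cycles <- function() {
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 3] <- W[3, 1] <- 1
  W[4, 5] <- W[5, 6] <- W[6, 4] <- 1
  rownames(W) <- colnames(W) <- paste0("n", 1:6)
  W
}

# barbell: two symmetric 5-cliques joined by one (weak) bridge
barbell <- function() {
  W <- matrix(0, 10, 10)
  for (i in 1:5) for (j in 1:5) if (i != j) W[i, j] <- 1
  for (i in 6:10) for (j in 6:10) if (i != j) W[i, j] <- 1
  W[5, 6] <- W[6, 5] <- 0.5
  rownames(W) <- colnames(W) <- paste0("n", 1:10)
  W
}

random_digraph <- function(n, density = 0.5) {
  W <- matrix(stats::runif(n * n), n, n) *
    (matrix(stats::runif(n * n), n, n) < density)
  diag(W) <- 0
  if (sum(W) == 0) W[1, 2] <- 1
  rownames(W) <- colnames(W) <- paste0("n", seq_len(n))
  W
}

# all set partitions of n items as restricted-growth label vectors
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (c in seq_len(k + 1L)) rec(c(labels, c), max(k, c))
  }
  rec(integer(0), 0L)
  out
}

# brute-force modularity maximum over all partitions (oracle)
brute_force_best_q <- function(W) {
  parts <- all_partitions(nrow(W))
  qs <- vapply(parts, function(p) directed_modularity(W, p), numeric(1))
  list(q = max(qs), assignment = parts[[which.max(qs)]])
}

# brute-force minimal-width HPD window (oracle)
brute_force_hpd <- function(x, prob) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(prob * n)
  if (m >= n) return(c(xs[1], xs[n]))
  lo <- which.min(xs[m:n] - xs[1:(n - m + 1)])
  c(xs[lo], xs[lo + m - 1])
}

# dense-covariance evaluation of the dyadic-pair log-likelihood (oracle
# for the Kronecker/AR(1)-factorised version used by the sampler)
dense_dyad_loglik <- function(E1, E2, phi_gg, rho, sigma2) {
  TT <- ncol(E1)
  C <- sigma2 * phi_gg^abs(outer(1:TT, 1:TT, "-"))
  Sg <- matrix(c(1, rho, rho, 1), 2, 2)
  V <- kronecker(C, Sg)   # time-major pair ordering
  Vi <- solve(V)
  ld <- determinant(V, logarithm = TRUE)$modulus
  tot <- 0
  for (d in seq_len(nrow(E1))) {
    e <- as.vector(rbind(E1[d, ], E2[d, ]))
    tot <- tot - 0.5 * (ld + t(e) %*% Vi %*% e) - TT * log(2 * pi)
  }
  as.numeric(tot)
}

# write a small flows data frame to a temp CSV (canonical dialect)
write_flow_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# tiny hand-built country panel covering a full grid
toy_panel <- function(countries, years) {
  g <- expand.grid(country = countries, year = years,
                   stringsAsFactors = FALSE)
  n <- nrow(g)
  data.frame(g,
             gdp_pc = 1000 + seq_len(n),
             population = 500 + seq_len(n),
             pasture_km2 = 100 + seq_len(n),
             des_pct = 100 + seq_len(n) / 10,
             lat = rep(seq(-40, 40, length.out = length(countries)),
                       times = length(years)),
             lon = rep(seq(-100, 100, length.out = length(countries)),
                       times = length(years)),
             stringsAsFactors = FALSE)
}
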