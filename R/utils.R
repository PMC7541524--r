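spectral_radius <- function(m) max(Mod(eigen(m, only.values = TRUE)$values))

# upper Cholesky factor tolerant of (numerically) semi-definite input
chol_psd <- function(m) {
  out <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(out)) {
    eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    out <- chol(eg$vectors %*% diag(vals + 1e-12, nrow(m)) %*% t(eg$vectors))
  }
  out
}

# deterministic child seed derived from a base seed; stays below 2^31
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629 + 1
}
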