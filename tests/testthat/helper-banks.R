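# seeded random binary item bank used across tests
random_bank <- function(seed, p = 12, arange = c(0.5, 2), brange = c(-2, 2)) {
  set.seed(seed)
  item_bank(a = runif(p, arange[1], arange[2]),
            b = runif(p, brange[1], brange[2]))
}

# brute-force EAP oracle: trapezoid rule on [-6, 6]
eap_trapezoid <- function(bank, x, npts = 2001) {
  th <- seq(-6, 6, length.out = npts)
  w <- dnorm(th)
  w[c(1, npts)] <- w[c(1, npts)] / 2
  L <- matrix(1, nrow(x), npts)
  for (j in seq_along(bank$a)) {
    P <- gpcm_prob(th, bank$a[j], bank$b[[j]])
    L <- L * t(P)[x[, j] + 1L, , drop = FALSE]
  }
  drop(L %*% (th * w)) / drop(L %*% w)
}

# independent step-up implementation of the BH adjustment
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / (m:1)))
  out <- numeric(m)
  out[o] <- adj
  out
}
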