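# Independent oracles used to validate the package implementations.
# These deliberately take a different computational route than the package
# (explicit loops, polyroot, permutation) so agreement is informative.

# Exhaustive Otsu: evaluate the between-class variance at all 256 splits with
# directly computed class means; smallest t within floating-point resolution
# (relative 1e-10) of the maximum wins, mirroring the documented tie rule.
otsu_brute <- function(counts) {
  tot <- sum(counts)
  z <- 0:255
  if (sum(counts > 0) == 1L) return(which(counts > 0) - 1L)
  v <- rep(-Inf, 256)
  for (t in 0:255) {
    lo <- counts[1:(t + 1)]
    w0 <- sum(lo); w1 <- tot - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(z[1:(t + 1)] * lo) / w0
    mu1 <- sum(z[(t + 2):256] * counts[(t + 2):256]) / w1
    v[t + 1] <- (w0 / tot) * (w1 / tot) * (mu0 - mu1)^2
  }
  mx <- max(v)
  as.integer(which(v >= mx - abs(mx) * 1e-10)[1] - 1L)
}

# Direct Tsai moment-preserving solution via polyroot on normalized moments.
moments_oracle <- function(counts) {
  p <- counts / sum(counts)
  z <- 0:255
  nz <- which(counts > 0)
  if (length(nz) == 1L) return(nz - 1L)
  m1 <- sum(p * z); m2 <- sum(p * z^2); m3 <- sum(p * z^3)
  cd <- m2 - m1^2
  if (cd <= .Machine$double.eps * m2) return(nz[1] - 1L)
  c0 <- (m1 * m3 - m2^2) / cd
  c1 <- (m1 * m2 - m3) / cd
  r <- sort(Re(polyroot(c(c0, c1, 1))))
  p0 <- (r[2] - m1) / (r[2] - r[1])
  as.integer(min(which(cumsum(p) >= p0 - 1e-12)) - 1L)
}

# Random 256-bin histograms mixing smooth bimodal and sparse spiky shapes.
random_histogram <- function() {
  if (runif(1) < 0.5) {
    n1 <- sample(50:500, 1); n2 <- sample(50:500, 1)
    x <- c(round(rnorm(n1, runif(1, 30, 100), runif(1, 5, 30))),
           round(rnorm(n2, runif(1, 130, 230), runif(1, 5, 30))))
    x <- pmin(pmax(x, 0), 255)
  } else {
    x <- sample(0:255, sample(100:400, 1), replace = TRUE,
                prob = runif(256)^3)
  }
  tabulate(x + 1L, nbins = 256L)
}

# Explicit Mantel-Cox O/E/V accumulation over distinct event times.
logrank_oracle <- function(time, event, group) {
  grp <- as.character(group)
  g1 <- unique(grp)[1]
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & grp == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
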