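# Brute-force oracles, coded independently of the package implementation.

oracle_set_a <- function(energies, centers) {
  nf <- nrow(energies)
  kurt <- skew <- slope <- c()
  for (i in seq_len(nf)) {
    s <- energies[i, ]
    if (sum(s) <= 0) next
    mu <- 0
    for (k in seq_along(s)) mu <- mu + centers[k] * s[k]
    mu <- mu / sum(s)
    v <- 0
    for (k in seq_along(s)) v <- v + (centers[k] - mu)^2 * s[k]
    v <- v / sum(s)
    if (v <= 0) next
    m3 <- m4 <- 0
    for (k in seq_along(s)) {
      m3 <- m3 + (centers[k] - mu)^3 * s[k]
      m4 <- m4 + (centers[k] - mu)^4 * s[k]
    }
    skew <- c(skew, m3 / (v^1.5 * sum(s)))
    kurt <- c(kurt, m4 / (v^2 * sum(s)))
    num <- den <- 0
    fm <- mean(centers); sm <- mean(s)
    for (k in seq_along(s)) {
      num <- num + (centers[k] - fm) * (s[k] - sm)
      den <- den + (centers[k] - fm)^2
    }
    slope <- c(slope, num / den)
  }
  fl <- c()
  for (i in seq_len(nf - 1)) {
    a <- energies[i, ] / sum(energies[i, ])
    b <- energies[i + 1, ] / sum(energies[i + 1, ])
    fl <- c(fl, sqrt(sum((b - a)^2)))
  }
  list(flux = mean(fl), kurtosis = mean(kurt), skewness = mean(skew),
       slope = mean(slope))
}

oracle_mfcc_dd <- function(energies, n_mfcc = 13) {
  N <- ncol(energies)
  logE <- log(energies + 1e-10)
  cep <- matrix(0, nrow(energies), n_mfcc)
  for (t in seq_len(nrow(energies))) {
    for (k in 0:(n_mfcc - 1)) {
      acc <- 0
      for (n in 0:(N - 1)) {
        acc <- acc + logE[t, n + 1] * cos(pi * k * (n + 0.5) / N)
      }
      cep[t, k + 1] <- acc * sqrt(2 / N) * (if (k == 0) 1 / sqrt(2) else 1)
    }
  }
  delta <- function(m) {
    T <- nrow(m)
    out <- m * 0
    at <- function(t) m[min(max(t, 1), T), ]
    for (t in seq_len(T)) {
      out[t, ] <- (1 * (at(t + 1) - at(t - 1)) +
                     2 * (at(t + 2) - at(t - 2))) / (2 * (1 + 4))
    }
    out
  }
  colMeans(delta(delta(cep)))
}

oracle_ols <- function(y, X) {
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  fitted <- as.numeric(Xi %*% beta)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  p <- ncol(X)
  list(beta = as.numeric(beta), r2 = 1 - ss_res / ss_tot,
       rmse = sqrt(ss_res / (length(y) - p - 1)))
}
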