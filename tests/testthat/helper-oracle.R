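# Fixtures and independent reference implementations used across tests.

bm_fixture <- function(sd_e = 1.80e-3)
  cell_source_params(2.80e-2, 0.120, 29.2, sd_e = sd_e, label = "BM")

uc_fixture <- function(sd_e = 1.99e-3)
  cell_source_params(3.30e-2, 0.332, 49.3, sd_e = sd_e, label = "UC")

small_config <- function(...) process_config(...)

# Reference passage-culture chain, written independently of the package
# internals: plain scalars, explicit formulas, no shared helpers.
oracle_chain <- function(mu_m, K_sr, K_50, Np, th,
                         Xs = 5.0e3, Xm = 6.41e4, S = 1720,
                         nf0 = 1, nfmax = 10, e = rep(0, Np + 1)) {
  sig <- function(cc) mu_m / (1 + exp(K_sr * (cc - K_50)))
  hours <- (th - 1) * 24
  mu <- max(sig(0) + e[1], 0)
  cc <- 0
  nf <- nf0
  mus <- numeric(Np)
  for (i in 1:Np) {
    mus[i] <- mu
    Xh <- min(Xs * exp(mu * hours), Xm)
    cc <- cc + log(Xh / Xs) / log(2)
    if (i < Np) nf <- min(floor(nf * Xh / Xs), nfmax)
    mu <- max(sig(cc) + e[i + 1], 0)
  }
  list(P_sene = mu / sig(0), P_conf = Xh / Xm, N_cell = nf * S * Xh,
       cPDL = cc, Xh = Xh, nflask = nf, mu_next = mu, mus = mus)
}

# Brute-force grid minimiser of the residual sum of squares; used as the
# independent oracle for the nonlinear least-squares fitter.
grid_fit_oracle <- function(obs,
                            mu_m_grid = seq(0.02, 0.04, by = 2.5e-4),
                            K_sr_grid = seq(0.02, 0.5, by = 5e-3),
                            K_50_grid = seq(15, 45, by = 0.25)) {
  x <- obs$cPDL
  y <- obs$mu_exp
  best <- list(rss = Inf)
  for (m in mu_m_grid) for (k in K_sr_grid) {
    # vectorise the innermost loop over K_50 for speed
    pred <- outer(x, K_50_grid, function(xx, k50) m / (1 + exp(k * (xx - k50))))
    rss <- colSums((y - pred)^2)
    j <- which.min(rss)
    if (rss[j] < best$rss)
      best <- list(rss = rss[j], mu_m = m, K_sr = k, K_50 = K_50_grid[j])
  }
  best
}

sample_skewness <- function(v) {
  m <- mean(v)
  s <- sd(v)
  mean((v - m)^3) / s^3
}
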