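#' Cell-source parameter set
#'
#' Bundles the three constants of the senescence growth model together with
#' the growth-rate noise level for one cell source (e.g. bone-marrow or
#' umbilical-cord MSCs). The growth model is
#' \deqn{\mu(cPDL) = \mu_m / (1 + \exp\{K_{sr}(cPDL - K_{50})\})}
#' so that `mu_m` is the maximum specific growth rate, `K_50` the cPDL at
#' which the rate has fallen to half of `mu_m`, and `K_sr` sets how fast the
#' decline proceeds.
#'
#' @param mu_m Maximum specific growth rate (h^-1); must be positive.
#' @param K_sr Senescence rate (dimensionless); must be non-negative.
#' @param K_50 cPDL at half-maximal growth (dimensionless); must be positive.
#' @param sd_e Standard deviation of the additive growth-rate noise
#'   (h^-1); must be non-negative. Zero gives a purely deterministic model.
#' @param label Free-text cell-source name, e.g. `"BM"` or `"UC"`.
#'
#' @return An object of class `cell_source_params`.
#' @seealso [growth_rate()], [load_config()]
#' @examples
#' bm <- cell_source_params(2.80e-2, 0.120, 29.2, sd_e = 1.80e-3, label = "BM")
#' growth_rate(bm, c(0, 29.2))
#' @export
cell_source_params <- function(mu_m, K_sr, K_50, sd_e = 0, label = "cells") {
  stopifnot(is.numeric(mu_m), length(mu_m) == 1L, is.finite(mu_m),
            is.numeric(K_sr), length(K_sr) == 1L, is.finite(K_sr),
            is.numeric(K_50), length(K_50) == 1L, is.finite(K_50),
            is.numeric(sd_e), length(sd_e) == 1L, is.finite(sd_e))
  if (mu_m <= 0) stop("'mu_m' must be > 0")
  if (K_sr < 0) stop("'K_sr' must be >= 0")
  if (K_50 <= 0) stop("'K_50' must be > 0")
  if (sd_e < 0) stop("'sd_e' must be >= 0")
  structure(
    list(mu_m = mu_m, K_sr = K_sr, K_50 = K_50, sd_e = sd_e,
         label = as.character(label)[1L]),
    class = "cell_source_params"
  )
}

#' @export
print.cell_source_params <- function(x, ...) {
  cat("Cell-source parameters [", x$label, "]\n", sep = "")
  cat(sprintf("  mu_m : %.4g h^-1 (maximum specific growth rate)\n", x$mu_m))
  cat(sprintf("  K_sr : %.4g      (senescence rate)\n", x$K_sr))
  cat(sprintf("  K_50 : %.4g      (cPDL at half-maximal growth)\n", x$K_50))
  cat(sprintf("  sd_e : %.4g h^-1 (growth-rate noise SD)\n", x$sd_e))
  invisible(x)
}

#' Process configuration for a passage-culture campaign
#'
#' Collects the culture-ware geometry, seeding policy, design-variable grid,
#' quality thresholds and Monte-Carlo settings. Defaults encode the
#' multilayer-flask case study: seeding at 5.0e3 cells/cm^2, maximum density
#' 6.41e4 cells/cm^2, 1720 cm^2 flasks scaling from 1 to at most 10, a grid
#' of passage numbers 1-15 by harvesting times Day 2.5-5.0 in 0.25-day steps
#' (165 conditions), 10000 Monte-Carlo iterations and a 90% minimum
#' acceptable probability.
#'
#' @param X_s Seeding density (cells cm^-2).
#' @param X_m Maximum cell density reachable before contact inhibition
#'   (cells cm^-2); must exceed `X_s`.
#' @param S Flask surface area (cm^2).
#' @param n_flask_init Number of flasks seeded at the first passage.
#' @param n_flask_max Maximum number of flasks available.
#' @param Np_grid Integer vector of passage numbers to explore.
#' @param th_grid Numeric vector of harvesting times (days); every value
#'   must exceed 1 day because growth is counted from the end of the 1-day
#'   attachment period.
#' @param psene_min Quality threshold: minimum acceptable senescence level
#'   (specification A1, inclusive).
#' @param pconf_max Quality threshold: maximum acceptable confluency level
#'   (specification A2, strict).
#' @param ncell_min Quality threshold: minimum acceptable total cell number
#'   (specification A3, inclusive).
#' @param M Number of Monte-Carlo iterations per grid cell.
#' @param pi Minimum acceptable probability (%) for design-space membership.
#' @param xm_cv Relative standard deviation of the maximum cell density used
#'   by the sensitivity analysis (default 5%).
#' @param seed Master RNG seed; every grid cell derives its own substream
#'   from it (see [substream_seed()]).
#'
#' @return An object of class `process_config`.
#' @examples
#' cfg <- process_config(M = 500)
#' cfg$th_grid
#' @export
process_config <- function(X_s = 5.0e3, X_m = 6.41e4, S = 1720,
                           n_flask_init = 1L, n_flask_max = 10L,
                           Np_grid = 1:15, th_grid = seq(2.5, 5.0, by = 0.25),
                           psene_min = 0.8, pconf_max = 0.9,
                           ncell_min = 3.5e8, M = 10000L, pi = 90,
                           xm_cv = 0.05, seed = 1L) {
  if (!is.numeric(X_s) || X_s <= 0) stop("'X_s' must be > 0")
  if (!is.numeric(X_m) || X_m <= X_s) stop("'X_m' must be > X_s")
  if (!is.numeric(S) || S <= 0) stop("'S' must be > 0")
  n_flask_init <- as.integer(n_flask_init)
  n_flask_max <- as.integer(n_flask_max)
  if (n_flask_init < 1L || n_flask_init > n_flask_max)
    stop("need 1 <= n_flask_init <= n_flask_max")
  Np_grid <- as.integer(Np_grid)
  if (any(Np_grid < 1L)) stop("all 'Np_grid' values must be >= 1")
  if (any(th_grid <= 1)) stop("all 'th_grid' values must be > 1 day")
  if (pi < 0 || pi > 100) stop("'pi' must lie in [0, 100]")
  M <- as.integer(M)
  if (M < 1L) stop("'M' must be >= 1")
  if (xm_cv < 0) stop("'xm_cv' must be >= 0")
  if (psene_min <= 0 || pconf_max <= 0 || ncell_min <= 0)
    stop("quality thresholds must be positive")
  structure(
    list(X_s = X_s, X_m = X_m, S = S,
         n_flask_init = n_flask_init, n_flask_max = n_flask_max,
         Np_grid = Np_grid, th_grid = as.numeric(th_grid),
         psene_min = psene_min, pconf_max = pconf_max,
         ncell_min = ncell_min, M = M, pi = pi, xm_cv = xm_cv,
         seed = as.integer(seed)),
    class = "process_config"
  )
}

#' @export
print.process_config <- function(x, ...) {
  cat("Passage-culture process configuration\n")
  cat(sprintf("  seeding density X_s   : %.4g cells/cm^2\n", x$X_s))
  cat(sprintf("  maximum density X_m   : %.4g cells/cm^2\n", x$X_m))
  cat(sprintf("  flask area S          : %.4g cm^2 (%d -> max %d flasks)\n",
              x$S, x$n_flask_init, x$n_flask_max))
  cat(sprintf("  grid                  : Np %d-%d x th %.2f-%.2f d (%d cells)\n",
              min(x$Np_grid), max(x$Np_grid), min(x$th_grid), max(x$th_grid),
              length(x$Np_grid) * length(x$th_grid)))
  cat(sprintf("  specs                 : Psene >= %.2f, Pconf < %.2f, Ncell >= %.3g\n",
              x$psene_min, x$pconf_max, x$ncell_min))
  cat(sprintf("  Monte-Carlo           : M = %d, pi = %g%%, seed = %d\n",
              x$M, x$pi, x$seed))
  invisible(x)
}
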