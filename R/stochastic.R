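#' Derive a reproducible RNG substream seed for one grid cell
#'
#' Each (Np, th) condition draws its noise from its own substream so that
#' any cell can be recomputed in isolation, in any order, and still produce
#' exactly the ensemble it contributed to a full map. The substream seed is
#' a deterministic function of the master seed and the cell coordinates;
#' offsets are chosen so that all cells of the default grid map to distinct
#' seeds. The same substream is reused when a cell is re-simulated with
#' maximum-density variation, which gives common random numbers for the
#' sensitivity comparison.
#'
#' @param master Master seed (integer).
#' @param Np Passage number of the cell.
#' @param th Harvesting time of the cell (days).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(master, Np, th) {
  p <- 2147483647           # 2^31 - 1, keeps the result a valid integer seed
  base <- as.numeric(master) %% p
  off <- as.numeric(Np) * 131071 + round(th * 100) * 524287
  as.integer((base + off) %% p) + 1L
}

#' Draw growth-rate noise
#'
#' Additive perturbations of the specific growth rate are modelled as iid
#' draws from `N(0, sd)`; `sd = 0` returns exact zeros. Draws consume the
#' current R RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param n Number of draws.
#' @param sd Standard deviation (h^-1), >= 0.
#' @return Numeric vector of length `n`.
#' @export
sample_noise <- function(n, sd) {
  stopifnot(is.numeric(sd), length(sd) == 1L, sd >= 0)
  stats::rnorm(n, mean = 0, sd = sd)
}

#' Stochastic specific growth rate
#'
#' The deterministic senescence model plus an additive noise term, floored
#' at zero: `max(growth_rate(params, cPDL) + e, 0)`. The floor keeps the
#' cultivation model in its domain (the model has no decay phase); at the
#' calibrated noise levels it is essentially never active before deep
#' senescence.
#'
#' @param params A [cell_source_params()] object.
#' @param cPDL Cumulative population doubling level(s).
#' @param e Noise value(s) (h^-1).
#' @return Non-negative growth rate(s) (h^-1).
#' @export
stochastic_growth_rate <- function(params, cPDL, e) {
  pmax(growth_rate(params, cPDL) + e, 0)
}

#' Monte-Carlo ensemble of passage-culture outcomes
#'
#' Simulates `M` independent realisations of a campaign at one (Np, th)
#' condition. Per iteration a fresh noise value is drawn for every
#' cultivation and for the post-harvest rate that enters the senescence
#' level (`Np + 1` draws in total). With `vary_Xm = TRUE` the maximum cell
#' density is additionally drawn once per iteration from
#' `N(X_m, xm_cv * X_m)` and held constant across that iteration's passages
#' (lot-level variability, as opposed to the per-passage growth-rate
#' noise); non-positive draws are rejected and redrawn. The naive rate in
#' the senescence-level denominator stays the noise-free constant.
#'
#' The whole ensemble is vectorised over iterations, so the full default
#' grid (165 cells at M = 10000) runs in seconds.
#'
#' @param params A [cell_source_params()] object.
#' @param config A [process_config()] object.
#' @param Np Passage number (>= 1).
#' @param th Harvesting time (days), > 1.
#' @param vary_Xm Also sample the maximum cell density? Default `FALSE`.
#' @param M Iterations; defaults to `config$M`.
#' @param seed Substream seed; defaults to
#'   `substream_seed(config$seed, Np, th)`.
#' @return An object of class `qi_ensemble`: a list with `qis` (data frame
#'   with columns `P_sene`, `P_conf`, `N_cell`, `M` rows), `Np`, `th`,
#'   `M`, `seed`, `vary_Xm`, `n_floored` (noise draws clipped at zero) and
#'   `n_redrawn` (rejected non-positive Xm draws).
#' @examples
#' bm <- cell_source_params(2.80e-2, 0.120, 29.2, sd_e = 1.80e-3)
#' ens <- simulate_ensemble(bm, process_config(M = 200), Np = 3, th = 3.5)
#' colMeans(ens$qis)
#' @export
simulate_ensemble <- function(params, config, Np, th, vary_Xm = FALSE,
                              M = config$M, seed = NULL) {
  stopifnot(inherits(params, "cell_source_params"),
            inherits(config, "process_config"))
  Np <- as.integer(Np)
  if (Np < 1L) stop("'Np' must be >= 1")
  M <- as.integer(M)
  if (is.null(seed)) seed <- substream_seed(config$seed, Np, th)
  set.seed(seed)

  # noise first, Xm second: the e-stream is identical with and without
  # Xm variation (common random numbers for the sensitivity analysis)
  E <- matrix(sample_noise(M * (Np + 1L), params$sd_e), nrow = M)
  n_redrawn <- 0L
  if (vary_Xm && config$xm_cv > 0) {
    Xm <- stats::rnorm(M, config$X_m, config$xm_cv * config$X_m)
    while (any(bad <- Xm <= 0)) {
      n_redrawn <- n_redrawn + sum(bad)
      Xm[bad] <- stats::rnorm(sum(bad), config$X_m, config$xm_cv * config$X_m)
    }
  } else {
    Xm <- rep(config$X_m, M)
  }

  hrs <- growth_hours(th)
  mu_naive <- growth_rate(params, 0)
  raw <- mu_naive + E[, 1L]
  n_floored <- sum(raw < 0)
  mu <- pmax(raw, 0)
  cPDL <- numeric(M)
  nflask <- rep(as.numeric(config$n_flask_init), M)
  Xh <- numeric(M)
  for (i in seq_len(Np)) {
    Xh <- pmin(config$X_s * exp(mu * hrs), Xm)
    cPDL <- cPDL + log2(Xh / config$X_s)
    if (i < Np)
      nflask <- pmin(floor(nflask * Xh / config$X_s), config$n_flask_max)
    raw <- growth_rate(params, cPDL) + E[, i + 1L]
    n_floored <- n_floored + sum(raw < 0)
    mu <- pmax(raw, 0)
  }

  qis <- data.frame(P_sene = mu / mu_naive,
                    P_conf = Xh / Xm,
                    N_cell = nflask * config$S * Xh)
  structure(list(qis = qis, Np = Np, th = th, M = M, seed = seed,
                 vary_Xm = vary_Xm, n_floored = n_floored,
                 n_redrawn = n_redrawn, label = params$label),
            class = "qi_ensemble")
}

#' @export
print.qi_ensemble <- function(x, ...) {
  cat(sprintf("QI ensemble [%s]: Np = %d, th = %g d, M = %d (seed %d%s)\n",
              x$label, x$Np, x$th, x$M, x$seed,
              if (x$vary_Xm) ", Xm varied" else ""))
  print(vapply(x$qis, function(v) c(mean = mean(v), sd = stats::sd(v)),
               numeric(2)))
  invisible(x)
}

#' Summarise a QI ensemble
#'
#' @param object A `qi_ensemble`.
#' @param probs Quantile probabilities for the summary.
#' @param ... Unused.
#' @return A data frame keyed by QI with mean, SD and quantiles.
#' @export
summary.qi_ensemble <- function(object, probs = c(0.05, 0.5, 0.95), ...) {
  stats_one <- function(v) {
    c(mean = mean(v), sd = stats::sd(v), stats::quantile(v, probs))
  }
  out <- as.data.frame(t(vapply(object$qis, stats_one,
                                numeric(2L + length(probs)))))
  out$qi <- rownames(out)
  rownames(out) <- NULL
  out[, c(ncol(out), seq_len(ncol(out) - 1L))]
}
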