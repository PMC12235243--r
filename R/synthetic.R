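#' Generate a synthetic passage-culture experiment
#'
#' Emulates the triplicate passage-culture experiments used to calibrate
#' the model: each sample is an independent chain of `n_passages`
#' cultivations at harvesting time `th_exp`, where the growth rate of
#' passage `i` is the senescence model evaluated at the cPDL accumulated so
#' far plus one additive Gaussian noise draw (process and measurement noise
#' are not separated, matching how the noise SD is calibrated from real
#' replicates). Each observation records the cPDL the experimentalist
#' would compute from harvest counts before the passage (0 for passage 1)
#' and the noisy growth rate as `mu_exp`.
#'
#' Samples draw from independent, seed-derived substreams, so the
#' experiment is bit-reproducible and individual samples can be
#' regenerated in isolation.
#'
#' @param truth A [cell_source_params()] object (its `sd_e` is the noise
#'   level of the generated data).
#' @param config A [process_config()] (supplies `X_s`, `X_m`).
#' @param n_samples Number of replicate samples (default 3).
#' @param n_passages Passages per sample (default 15).
#' @param th_exp Harvesting time (days, default 4; must exceed 1).
#' @param seed Seed of the experiment.
#' @return An object of class `synthetic_experiment`: list with
#'   `observations` (data frame: `sample_id`, `passage`, `cPDL`,
#'   `mu_exp`), `truth`, `n_samples`, `n_passages`, `th_exp`, `seed`.
#' @examples
#' bm <- cell_source_params(2.80e-2, 0.120, 29.2, sd_e = 1.80e-3)
#' synth <- generate_experiment(bm, process_config(), seed = 7)
#' head(synth$observations)
#' @export
generate_experiment <- function(truth, config = process_config(),
                                n_samples = 3L, n_passages = 15L,
                                th_exp = 4, seed = 1L) {
  stopifnot(inherits(truth, "cell_source_params"),
            inherits(config, "process_config"))
  if (th_exp <= 1) stop("'th_exp' must be > 1 day")
  n_samples <- as.integer(n_samples)
  n_passages <- as.integer(n_passages)
  if (n_samples < 1L || n_passages < 1L)
    stop("'n_samples' and 'n_passages' must be >= 1")

  obs <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    set.seed(substream_seed(seed, s, 999))
    e <- sample_noise(n_passages, truth$sd_e)
    cPDL <- 0
    rows <- data.frame(sample_id = sprintf("sample%d", s),
                       passage = seq_len(n_passages),
                       cPDL = NA_real_, mu_exp = NA_real_)
    for (i in seq_len(n_passages)) {
      mu <- stochastic_growth_rate(truth, cPDL, e[i])
      rows$cPDL[i] <- cPDL
      rows$mu_exp[i] <- mu
      Xh <- single_cultivation(config$X_s, mu, th_exp, config$X_m)
      cPDL <- update_cpdl(cPDL, Xh, config$X_s)$cPDL
    }
    obs[[s]] <- rows
  }
  structure(list(observations = do.call(rbind, obs), truth = truth,
                 n_samples = n_samples, n_passages = n_passages,
                 th_exp = th_exp, seed = as.integer(seed)),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("Synthetic passage-culture experiment [%s]: %d samples x %d passages, th = %g d, seed = %d\n",
              x$truth$label, x$n_samples, x$n_passages, x$th_exp, x$seed))
  cat(sprintf("  cPDL reached: %.1f-%.1f; mu_exp range: %.3g-%.3g h^-1\n",
              min(tapply(x$observations$cPDL, x$observations$sample_id, max)),
              max(tapply(x$observations$cPDL, x$observations$sample_id, max)),
              min(x$observations$mu_exp), max(x$observations$mu_exp)))
  invisible(x)
}
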