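#' Normalized root mean square error
#'
#' RMSE between observed and predicted values, normalized by the range of
#' the observations and expressed in percent:
#' `100 * sqrt(mean((obs - pred)^2)) / (max(obs) - min(obs))`.
#'
#' @param observed Numeric vector of observations (length >= 2, with a
#'   non-zero range).
#' @param predicted Numeric vector of predictions, same length.
#' @return NRMSE in percent; 0 iff the vectors are identical.
#' @examples
#' nrmse(c(0.02, 0.04), c(0.03, 0.03))  # 50
#' @export
nrmse <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length")
  if (length(observed) < 2L) stop("need at least 2 observations")
  rng <- max(observed) - min(observed)
  if (rng == 0) stop("zero observation range: NRMSE undefined")
  100 * sqrt(mean((observed - predicted)^2)) / rng
}

validate_observations <- function(observations) {
  need <- c("sample_id", "passage", "cPDL", "mu_exp")
  if (!all(need %in% names(observations)))
    stop("observations need columns: ", paste(need, collapse = ", "))
  if (any(observations$cPDL < 0)) stop("'cPDL' must be >= 0")
  if (any(observations$mu_exp <= 0)) stop("'mu_exp' must be > 0")
  observations
}

sigmoid_mu <- function(p, cPDL) p[1] / (1 + exp(p[2] * (cPDL - p[3])))

#' Fit the senescence growth model to growth-rate observations
#'
#' Estimates `(mu_m, K_sr, K_50)` by bounded nonlinear least squares
#' (Levenberg-Marquardt via \pkg{minpack.lm}) on the pooled
#' (cPDL, mu_exp) points, minimising the residual sum of squares
#' `RSS = sum((mu_exp - mu(cPDL))^2)`. A multi-start scheme (starting
#' values spanning `mu_m` in `[max(mu_exp), 2 max(mu_exp)]`, `K_50` across
#' the observed cPDL range, `K_sr` in `[0.01, 1]`) guards against local
#' minima; the best converged start is returned.
#'
#' @param observations Data frame with columns `sample_id`, `passage`,
#'   `cPDL`, `mu_exp` (see [generate_experiment()], [read_observations()]).
#' @param n_starts Minimum number of starting points (default 6).
#' @return An object of class `passage_fit`: list with `params`
#'   (a [cell_source_params()]; `sd_e` is left at 0, see [pooled_sd()]),
#'   `rss`, `nrmse_fit` (%), `n_obs`, `starts_converged`.
#' @export
fit_passage_model <- function(observations, n_starts = 6) {
  observations <- validate_observations(observations)
  x <- observations$cPDL
  y <- observations$mu_exp
  if (length(unique(round(x, 10))) < 3L)
    stop("need >= 3 distinct cPDL values to identify the sigmoid")
  if (diff(range(y)) < 1e-3 * max(y))
    warning("growth rates are nearly constant: flat fit, K_sr unidentifiable")

  ymax <- max(y)
  lower <- c(mu_m = 0.5 * ymax, K_sr = 1e-4, K_50 = 0)
  upper <- c(mu_m = 3 * ymax, K_sr = 5, K_50 = 3 * max(x, 1))
  k50_starts <- unique(stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE))
  starts <- expand.grid(mu_m = c(ymax, 1.5 * ymax, 2 * ymax),
                        K_sr = c(0.01, 0.1, 1),
                        K_50 = k50_starts)
  if (nrow(starts) > max(n_starts, 9L))
    starts <- starts[unique(round(seq(1L, nrow(starts),
                                      length.out = max(n_starts, 9L)))), ,
                     drop = FALSE]

  resid_fn <- function(p) y - sigmoid_mu(p, x)
  best <- NULL
  converged <- 0L
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[k, ]), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    converged <- converged + 1L
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    stop("nonlinear least squares failed to converge from any start (",
         nrow(starts), " starts tried)")
  p <- best$par
  params <- cell_source_params(p[1], max(p[2], 0), p[3], sd_e = 0,
                               label = "fitted")
  structure(list(params = params, rss = best$rss,
                 nrmse_fit = nrmse(y, sigmoid_mu(p, x)),
                 n_obs = length(y), starts_converged = converged),
            class = "passage_fit")
}

#' @export
print.passage_fit <- function(x, ...) {
  cat(sprintf("Senescence model fit (%d points): RSS = %.4g, NRMSE = %.2f%%\n",
              x$n_obs, x$rss, x$nrmse_fit))
  print(x$params)
  invisible(x)
}

#' Pooled growth-rate noise level
#'
#' The noise SD of the stochastic model is calibrated as the mean over
#' passages of the per-passage sample standard deviation (n-1 denominator)
#' of `mu_exp` across the replicate samples.
#'
#' @param observations Data frame with columns `sample_id`, `passage`,
#'   `mu_exp`; every passage must carry at least two samples.
#' @return Pooled SD (h^-1).
#' @export
pooled_sd <- function(observations) {
  observations <- validate_observations(observations)
  groups <- split(observations$mu_exp, observations$passage)
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L))
    stop("passage(s) ", paste(names(groups)[n < 2L], collapse = ", "),
         " have a single observation: sample SD undefined")
  mean(vapply(groups, stats::sd, numeric(1)))
}

# Deterministic per-passage growth-rate prediction of the full chained
# model (growth -> harvest -> cPDL -> senescence model) for validation.
predict_mu_by_passage <- function(params, config, n_passages, th) {
  mu <- numeric(n_passages)
  cPDL <- 0
  m <- growth_rate(params, 0)
  for (i in seq_len(n_passages)) {
    mu[i] <- m
    Xh <- single_cultivation(config$X_s, m, th, config$X_m)
    cPDL <- update_cpdl(cPDL, Xh, config$X_s)$cPDL
    m <- growth_rate(params, cPDL)
  }
  mu
}

#' Rotating hold-one-sample-out estimation and validation
#'
#' The replicate samples are combined in rotation: each fold fits the
#' senescence model to all samples but one ([fit_passage_model()] on the
#' pooled training points) and validates the full chained model against the
#' held-out sample by running the deterministic passage culture forward at
#' the experimental harvesting time and comparing predicted and observed
#' growth rates at the same passage numbers ([nrmse()], normalised by the
#' held-out data's range). The final parameter set is the plain arithmetic
#' mean of the per-fold estimates, with `sd_e` calibrated by [pooled_sd()]
#' on all samples.
#'
#' @param observations Data frame with columns `sample_id`, `passage`,
#'   `cPDL`, `mu_exp` holding all samples (classically three).
#' @param config A [process_config()] (supplies `X_s`, `X_m`).
#' @param th_exp Harvesting time of the experiment (days, default 4).
#' @return An object of class `passage_cv`: list with `params` (mean
#'   [cell_source_params()] including the pooled `sd_e`), `folds` (data
#'   frame: `fold_id` = held-out sample, `mu_m`, `K_sr`, `K_50`, `rss`,
#'   `nrmse_fit`, `nrmse_val`).
#' @export
cross_validate <- function(observations, config = process_config(),
                           th_exp = 4) {
  observations <- validate_observations(observations)
  ids <- unique(observations$sample_id)
  if (length(ids) < 2L) stop("need at least 2 samples for cross-validation")
  folds <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    held <- ids[k]
    train <- observations[observations$sample_id != held, , drop = FALSE]
    test <- observations[observations$sample_id == held, , drop = FALSE]
    fit <- tryCatch(fit_passage_model(train), error = function(e)
      stop("fold holding out sample '", held, "' failed: ",
           conditionMessage(e)))
    test <- test[order(test$passage), , drop = FALSE]
    pred <- predict_mu_by_passage(fit$params, config,
                                  max(test$passage), th_exp)
    folds[[k]] <- data.frame(
      fold_id = held,
      mu_m = fit$params$mu_m, K_sr = fit$params$K_sr, K_50 = fit$params$K_50,
      rss = fit$rss, nrmse_fit = fit$nrmse_fit,
      nrmse_val = nrmse(test$mu_exp, pred[test$passage]))
  }
  folds <- do.call(rbind, folds)
  sd_e <- tryCatch(pooled_sd(observations), error = function(e) 0)
  params <- cell_source_params(mean(folds$mu_m), mean(folds$K_sr),
                               mean(folds$K_50), sd_e = sd_e,
                               label = "cross-validated mean")
  structure(list(params = params, folds = folds), class = "passage_cv")
}

#' @export
print.passage_cv <- function(x, ...) {
  cat("Rotating hold-one-sample-out estimation\n")
  print(x$folds, row.names = FALSE)
  cat("Mean parameters:\n")
  print(x$params)
  invisible(x)
}
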