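#' Senescence-dependent specific growth rate
#'
#' Evaluates the sigmoid growth model
#' \deqn{\mu(cPDL) = \frac{\mu_m}{1 + \exp\{K_{sr}(cPDL - K_{50})\}}}
#' which decreases monotonically in cPDL whenever `K_sr > 0`: early in the
#' culture's replicative life the rate is close to `mu_m`, it passes
#' `mu_m / 2` at `cPDL = K_50`, and it decays towards zero as doublings
#' accumulate.
#'
#' @param params A [cell_source_params()] object.
#' @param cPDL Cumulative population doubling level(s); non-negative.
#' @return Specific growth rate(s) in h^-1, same length as `cPDL`.
#' @examples
#' bm <- cell_source_params(2.80e-2, 0.120, 29.2)
#' growth_rate(bm, 29.2)  # half of mu_m
#' @export
growth_rate <- function(params, cPDL) {
  stopifnot(inherits(params, "cell_source_params"), is.numeric(cPDL))
  if (any(cPDL < 0)) stop("'cPDL' must be >= 0")
  params$mu_m / (1 + exp(params$K_sr * (cPDL - params$K_50)))
}

#' Hours of exponential growth within one cultivation
#'
#' Cells attach during the first day after seeding; the exponential phase
#' runs from 24 h to harvest. A harvesting time of `th` days therefore
#' corresponds to `24 * (th - 1)` hours of growth at rate `mu`. This is also
#' the window over which experimental growth rates are computed (density at
#' harvest relative to density one day after seeding).
#'
#' @param th Harvesting time in days; must exceed 1.
#' @return Growth duration in hours.
#' @export
growth_hours <- function(th) {
  if (any(th <= 1)) stop("'th' must be > 1 day (growth starts after 1-day attachment)")
  24 * (th - 1)
}

#' Harvesting density after a single cultivation
#'
#' Exponential growth from the seeding density, capped at the maximum cell
#' density `Xm` by contact inhibition:
#' `Xh = min(Xs * exp(mu * 24 * (th - 1)), Xm)`.
#'
#' @param Xs Seeding density (cells cm^-2), positive.
#' @param mu Specific growth rate (h^-1), non-negative.
#' @param th Harvesting time (days), > 1.
#' @param Xm Maximum cell density (cells cm^-2).
#' @return Harvesting density (cells cm^-2).
#' @examples
#' single_cultivation(5e3, 2.718e-2, th = 4, Xm = 6.41e4)
#' @export
single_cultivation <- function(Xs, mu, th, Xm) {
  stopifnot(is.numeric(Xs), is.numeric(mu), is.numeric(Xm))
  if (any(Xs <= 0)) stop("'Xs' must be > 0")
  if (any(mu < 0)) stop("'mu' must be >= 0")
  pmin(Xs * exp(mu * growth_hours(th)), Xm)
}

#' Update the cumulative population doubling level
#'
#' One cultivation that grows the culture from `Xs` to `Xh` contributes
#' `PDL = log2(Xh / Xs)` doublings; cPDL is the running sum.
#'
#' @param cPDL_prev cPDL carried into this cultivation.
#' @param Xh Harvesting density; must be at least `Xs` (the model has no
#'   decay phase, so a harvest below seeding is a hard error).
#' @param Xs Seeding density.
#' @return A list with components `PDL` and `cPDL`.
#' @export
update_cpdl <- function(cPDL_prev, Xh, Xs) {
  stopifnot(is.numeric(cPDL_prev), is.numeric(Xh), is.numeric(Xs))
  if (any(Xs <= 0)) stop("'Xs' must be > 0")
  if (any(Xh < Xs))
    stop("'Xh' < 'Xs': negative doubling is outside the model domain")
  PDL <- log2(Xh / Xs)
  list(PDL = PDL, cPDL = cPDL_prev + PDL)
}

#' Flask count for the next cultivation
#'
#' All harvested cells are reseeded at density `Xs`, so the culture scales
#' out to `floor(nflask * Xh / Xs)` flasks, capped by the available stock:
#' `min(floor(nflask * Xh / Xs), nflask_max)`.
#'
#' @param nflask Working flasks in the current cultivation (>= 1).
#' @param Xh Harvesting density; at least `Xs`.
#' @param Xs Seeding density.
#' @param nflask_max Maximum available flasks.
#' @return Integer flask count for the next cultivation.
#' @export
update_flasks <- function(nflask, Xh, Xs, nflask_max) {
  stopifnot(is.numeric(nflask), is.numeric(Xh), is.numeric(Xs))
  if (any(nflask < 1)) stop("'nflask' must be >= 1")
  if (any(Xh < Xs)) stop("'Xh' must be >= 'Xs'")
  pmin(floor(nflask * Xh / Xs), nflask_max)
}

#' Quality indicators after the final passage
#'
#' Three quality indicators summarise the state of the lot after `Np`
#' passages:
#' * senescence level `P_sene = mu_next / mu(cPDL = 0)`, the growth rate the
#'   cells would show in a further cultivation relative to their naive rate
#'   (the denominator is the noise-free model value at cPDL 0, a constant);
#' * confluency level `P_conf = Xh / X_m`, how close the final harvest came
#'   to contact inhibition;
#' * total harvested cells `N_cell = nflask * S * Xh`.
#'
#' @param final_state A one-row data frame or list with at least `Xh` and
#'   `nflask` for the final passage (as produced by [run_passage_culture()]).
#' @param mu_next Growth rate predicted from the final cPDL (h^-1); in
#'   stochastic runs this carries its own noise draw, so `P_sene` may
#'   exceed 1.
#' @param params A [cell_source_params()] object.
#' @param config A [process_config()] object.
#' @return A list with components `P_sene`, `P_conf`, `N_cell`.
#' @export
quality_indicators <- function(final_state, mu_next, params, config) {
  stopifnot(inherits(params, "cell_source_params"),
            inherits(config, "process_config"))
  mu_naive <- growth_rate(params, 0)
  list(P_sene = mu_next / mu_naive,
       P_conf = final_state$Xh / config$X_m,
       N_cell = final_state$nflask * config$S * final_state$Xh)
}

#' Run one passage-culture campaign
#'
#' Chains `Np` seed-grow-harvest cycles: the growth rate of cultivation
#' `i` is the senescence model evaluated at the cPDL accumulated over the
#' previous `i - 1` cultivations (plus an optional noise term), the harvest
#' density follows from exponential growth capped at `X_m`, cPDL and the
#' flask count are updated at passage, and quality indicators are evaluated
#' after the final passage using the rate predicted for a hypothetical
#' further cultivation.
#'
#' With `noise_stream = NULL` (or all zeros) the run is fully deterministic.
#' A supplied `noise_stream` must provide at least `Np + 1` values: one per
#' cultivation plus one for the post-harvest rate entering the senescence
#' level. Negative noisy rates are floored at zero.
#'
#' @param params A [cell_source_params()] object.
#' @param config A [process_config()] object.
#' @param Np Number of passages (>= 1).
#' @param th Harvesting time (days), > 1.
#' @param noise_stream Optional numeric vector of additive growth-rate
#'   perturbations (h^-1), length >= `Np + 1`.
#' @return A list of class `passage_run` with
#'   `trajectory` (data frame: `passage`, `mu`, `Xh`, `PDL`, `cPDL`,
#'   `nflask`), `qi` (see [quality_indicators()]), `mu_next`, `Np`, `th`.
#' @examples
#' bm <- cell_source_params(2.80e-2, 0.120, 29.2)
#' run <- run_passage_culture(bm, process_config(), Np = 3, th = 3.5)
#' run$trajectory
#' @export
run_passage_culture <- function(params, config, Np, th, noise_stream = NULL) {
  stopifnot(inherits(params, "cell_source_params"),
            inherits(config, "process_config"))
  Np <- as.integer(Np)
  if (Np < 1L) stop("'Np' must be >= 1")
  if (is.null(noise_stream)) noise_stream <- numeric(Np + 1L)
  if (length(noise_stream) < Np + 1L)
    stop("'noise_stream' must supply at least Np + 1 values")

  mu <- max(growth_rate(params, 0) + noise_stream[1L], 0)
  cPDL <- 0
  nflask <- config$n_flask_init
  traj <- data.frame(passage = seq_len(Np), mu = NA_real_, Xh = NA_real_,
                     PDL = NA_real_, cPDL = NA_real_, nflask = NA_integer_)
  for (i in seq_len(Np)) {
    Xh <- single_cultivation(config$X_s, mu, th, config$X_m)
    upd <- update_cpdl(cPDL, Xh, config$X_s)
    traj[i, -1L] <- list(mu, Xh, upd$PDL, upd$cPDL, as.integer(nflask))
    cPDL <- upd$cPDL
    if (i < Np)
      nflask <- update_flasks(nflask, Xh, config$X_s, config$n_flask_max)
    mu <- max(growth_rate(params, cPDL) + noise_stream[i + 1L], 0)
  }
  qi <- quality_indicators(traj[Np, ], mu, params, config)
  structure(list(trajectory = traj, qi = qi, mu_next = mu, Np = Np, th = th,
                 params = params),
            class = "passage_run")
}

#' @export
print.passage_run <- function(x, ...) {
  cat(sprintf("Passage culture [%s]: Np = %d, th = %g d\n",
              x$params$label, x$Np, x$th))
  print(x$trajectory, row.names = FALSE)
  cat(sprintf("QIs: P_sene = %.4f, P_conf = %.4f, N_cell = %.4g\n",
              x$qi$P_sene, x$qi$P_conf, x$qi$N_cell))
  invisible(x)
}

#' Total process time of a campaign
#'
#' `Np` cultivations of `th` days each, i.e. `Np * th` days (passage
#' handling is instantaneous in the model).
#'
#' @param Np Passage number.
#' @param th Harvesting time (days).
#' @return Total time in days.
#' @examples
#' total_process_time(3, 3.5)
#' @export
total_process_time <- function(Np, th) Np * th
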