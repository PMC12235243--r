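#' Quality specification set
#'
#' The lot passes when all selected conditions hold, with the boundary
#' semantics: senescence level `P_sene >= psene_min` (A1, inclusive),
#' confluency level `P_conf < pconf_max` (A2, strict), total cells
#' `N_cell >= ncell_min` (A3, inclusive). `which` selects a single
#' specification or the joint set `"A" = A1 & A2 & A3`.
#'
#' @param psene_min Minimum senescence level (default 0.8).
#' @param pconf_max Maximum confluency level (default 0.9).
#' @param ncell_min Minimum total cells (default 3.5e8).
#' @param which One of `"A"`, `"A1"`, `"A2"`, `"A3"`.
#' @return An object of class `specification_set`.
#' @export
specification_set <- function(psene_min = 0.8, pconf_max = 0.9,
                              ncell_min = 3.5e8, which = "A") {
  which <- match.arg(which, c("A", "A1", "A2", "A3"))
  if (psene_min <= 0 || pconf_max <= 0 || ncell_min <= 0)
    stop("thresholds must be positive")
  structure(list(psene_min = psene_min, pconf_max = pconf_max,
                 ncell_min = ncell_min, which = which),
            class = "specification_set")
}

spec_from_config <- function(config, which = "A") {
  specification_set(config$psene_min, config$pconf_max, config$ncell_min,
                    which = which)
}

#' Check quality specifications on QI values
#'
#' Vectorised over the rows of `qi`. Boundary semantics are exactly those
#' of [specification_set()].
#'
#' @param qi A list or data frame with elements/columns `P_sene`, `P_conf`,
#'   `N_cell`.
#' @param spec A [specification_set()].
#' @return Logical vector: does each observation meet the selected
#'   specification(s)?
#' @examples
#' check_specs(list(P_sene = 0.8, P_conf = 0.89, N_cell = 3.5e8),
#'             specification_set())
#' @export
check_specs <- function(qi, spec = specification_set()) {
  stopifnot(inherits(spec, "specification_set"))
  a1 <- qi$P_sene >= spec$psene_min
  a2 <- qi$P_conf < spec$pconf_max
  a3 <- qi$N_cell >= spec$ncell_min
  switch(spec$which,
         A1 = a1, A2 = a2, A3 = a3,
         A = a1 & a2 & a3)
}

#' Probability of meeting a specification
#'
#' The fraction of ensemble iterations whose QIs satisfy `spec`, in
#' percent: `h = 100 * mean(I(y in A))`.
#'
#' @param ensemble A `qi_ensemble` from [simulate_ensemble()].
#' @param spec A [specification_set()].
#' @return Probability in percent.
#' @export
probability <- function(ensemble, spec = specification_set()) {
  stopifnot(inherits(ensemble, "qi_ensemble"))
  100 * mean(check_specs(ensemble$qis, spec))
}

# One simulation pass over the whole (Np, th) grid; all four specification
# probabilities are evaluated on the same ensembles.
qi_maps <- function(params, config, vary_Xm = FALSE, M = config$M) {
  grid <- expand.grid(Np = config$Np_grid, th = config$th_grid,
                      KEEP.OUT.ATTRS = FALSE)
  specs <- lapply(c(A = "A", A1 = "A1", A2 = "A2", A3 = "A3"),
                  function(w) spec_from_config(config, w))
  h <- matrix(NA_real_, nrow = nrow(grid), ncol = 4L,
              dimnames = list(NULL, c("h", "h_A1", "h_A2", "h_A3")))
  for (k in seq_len(nrow(grid))) {
    ens <- simulate_ensemble(params, config, grid$Np[k], grid$th[k],
                             vary_Xm = vary_Xm, M = M)
    h[k, ] <- vapply(specs, function(s) probability(ens, s), numeric(1))
  }
  out <- cbind(grid, as.data.frame(h))
  attr(out, "M") <- M
  attr(out, "seed") <- config$seed
  attr(out, "label") <- params$label
  out
}

#' Probability map over the design-variable grid
#'
#' Computes, for every (Np, th) combination of the configured grid, the
#' probability that a Monte-Carlo iteration meets the requested
#' specification. All four maps (joint and per-QI) come from one simulation
#' pass over shared ensembles, so the joint probability never exceeds any
#' marginal by construction.
#'
#' @param params A [cell_source_params()] object.
#' @param config A [process_config()] object.
#' @param which Specification: `"A"` (joint, default), `"A1"`, `"A2"` or
#'   `"A3"`.
#' @param vary_Xm Also sample the maximum cell density per iteration?
#' @param M Iterations per cell; defaults to `config$M`.
#' @return A data frame with columns `Np`, `th`, `h` (%) for the requested
#'   specification, plus a `borderline` flag marking cells whose `h` lies
#'   within one binomial standard error of `config$pi`.
#' @export
probability_map <- function(params, config, which = "A", vary_Xm = FALSE,
                            M = config$M) {
  which <- match.arg(which, c("A", "A1", "A2", "A3"))
  maps <- qi_maps(params, config, vary_Xm = vary_Xm, M = M)
  col <- if (which == "A") "h" else paste0("h_", which)
  out <- maps[, c("Np", "th")]
  out$h <- maps[[col]]
  out$borderline <- is_borderline(out$h, config$pi, M)
  attr(out, "M") <- M
  attr(out, "seed") <- config$seed
  attr(out, "spec") <- which
  attr(out, "label") <- params$label
  out
}

is_borderline <- function(h, pi, M) {
  se <- 100 * sqrt(pmax(h / 100 * (1 - h / 100), 0) / M)
  abs(h - pi) <= se
}

#' Determine the probabilistic design space
#'
#' Runs the Monte-Carlo ensemble on every cell of the (Np, th) grid and
#' returns the feasible set: the cells whose joint probability of meeting
#' all three quality specifications is at least the minimum acceptable
#' probability `pi`. The three per-QI maps are evaluated on the same
#' ensembles and returned alongside. Cells whose joint probability lies
#' within one binomial standard error of `pi` are flagged as borderline:
#' their membership can flip between seeds at finite `M`.
#'
#' @param params A [cell_source_params()] object.
#' @param config A [process_config()] object.
#' @param M Iterations per cell; defaults to `config$M`.
#' @return An object of class `design_space`: list with `feasible` (data
#'   frame of feasible cells with their `h`), `maps` (full grid with
#'   columns `h`, `h_A1`, `h_A2`, `h_A3`, `feasible`, `borderline`),
#'   `pi`, `M`, `seed`, `label`.
#' @examples
#' bm <- cell_source_params(2.80e-2, 0.120, 29.2, sd_e = 1.80e-3)
#' ds <- determine_design_space(bm, process_config(M = 200))
#' nrow(ds$feasible)
#' @export
determine_design_space <- function(params, config, M = config$M) {
  maps <- qi_maps(params, config, M = M)
  maps$feasible <- maps$h >= config$pi
  maps$borderline <- is_borderline(maps$h, config$pi, M)
  feasible <- maps[maps$feasible, c("Np", "th", "h")]
  rownames(feasible) <- NULL
  structure(list(feasible = feasible, maps = maps, pi = config$pi,
                 M = M, seed = config$seed, label = params$label),
            class = "design_space")
}

#' @export
print.design_space <- function(x, ...) {
  n <- nrow(x$maps)
  cat(sprintf("Probabilistic design space [%s]: %d of %d conditions feasible (pi = %g%%, M = %d)\n",
              x$label, nrow(x$feasible), n, x$pi, x$M))
  nb <- sum(x$maps$borderline)
  if (nb > 0)
    cat(sprintf("  %d borderline cell(s) within one binomial SE of pi\n", nb))
  if (nrow(x$feasible) > 0) {
    for (np in sort(unique(x$feasible$Np))) {
      ths <- sort(x$feasible$th[x$feasible$Np == np])
      cat(sprintf("  Np = %2d : th %s d\n", np,
                  paste(format(ths, trim = TRUE), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Sensitivity of the design space to maximum-density variability
#'
#' Re-evaluates every grid cell with the maximum cell density drawn once
#' per iteration from `N(X_m, xm_cv * X_m)` and reports the probability
#' difference `delta_h = h2 - h` per cell. Both runs share each cell's
#' noise substream (common random numbers), so `delta_h` isolates the
#' effect of the density variation from Monte-Carlo noise.
#'
#' @param params A [cell_source_params()] object.
#' @param config A [process_config()] object; `config$xm_cv` sets the
#'   relative SD (default 5%).
#' @param M Iterations per cell; defaults to `config$M`.
#' @return An object of class `xm_sensitivity`: list with `map` (grid with
#'   `h`, `h2`, `delta_h`), `max_abs_delta` (percentage points),
#'   `feasible_changed` (did any cell cross `pi`?), `pi`, `M`, `seed`.
#' @export
sensitivity_delta_h <- function(params, config, M = config$M) {
  base <- qi_maps(params, config, vary_Xm = FALSE, M = M)
  pert <- qi_maps(params, config, vary_Xm = TRUE, M = M)
  map <- base[, c("Np", "th")]
  map$h <- base$h
  map$h2 <- pert$h
  map$delta_h <- pert$h - base$h
  feas1 <- base$h >= config$pi
  feas2 <- pert$h >= config$pi
  structure(list(map = map,
                 max_abs_delta = max(abs(map$delta_h)),
                 feasible_changed = any(feas1 != feas2),
                 n_feasible = sum(feas1), n_feasible2 = sum(feas2),
                 pi = config$pi, M = M, seed = config$seed,
                 label = params$label),
            class = "xm_sensitivity")
}

#' @export
print.xm_sensitivity <- function(x, ...) {
  cat(sprintf("Xm sensitivity [%s]: max |delta h| = %.2f points over %d cells (M = %d)\n",
              x$label, x$max_abs_delta, nrow(x$map), x$M))
  cat(sprintf("  feasible set %s (%d -> %d cells at pi = %g%%)\n",
              if (x$feasible_changed) "CHANGED" else "unchanged",
              x$n_feasible, x$n_feasible2, x$pi))
  invisible(x)
}
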