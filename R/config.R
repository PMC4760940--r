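## Simulation configuration: validated parameter sets and study profiles.

#' Simulation configuration
#'
#' Collects and validates all model parameters. Defaults are the model's
#' standard study conditions: death probability `P_d = 0.1`, migration
#' probability `P_m = 0.1`, liquid carrying capacity `K = 5000`, a
#' 100 x 100 hexagonal surface (10,000 sites), and `n_steps = 400000` time
#' steps. Mutation defaults are `mu_r = 0.01` (per-variable mutation
#' probability at division) and `mu_s = 0.1` (Gaussian step s.d.).
#'
#' `liquid_S_scope` sets the population whose sticky fraction a liquid cell
#' senses: `"global"` (liquid plus surface, the default) or
#' `"liquid_only"`. `event_mode` selects how the five per-cell events are
#' scheduled: `"uniform"` (one event drawn uniformly at random per cell per
#' step, then gated; the default) or `"sequential"` (all five attempted in
#' fixed order, a sensitivity-check mode).
#'
#' @param R relative division rate of sticky cells, in `[0, 1]`.
#' @param P_m probability of a migration-to-surface attempt, in `[0, 1]`.
#' @param P_d death probability, in `[0, 1]`.
#' @param K liquid carrying capacity (positive integer).
#' @param lattice a [lattice_spec()].
#' @param n_steps total number of time steps.
#' @param mu_r per-variable mutation probability at division.
#' @param mu_s mutation step standard deviation.
#' @param strategy strategy kind of the founding genotype: `"pure"`,
#'   `"probabilistic"` or `"decision"`.
#' @param liquid_S_scope `"global"` or `"liquid_only"`.
#' @param event_mode `"uniform"` or `"sequential"`.
#' @param init_liquid initial number of non-sticky liquid cells (defaults
#'   to `K`).
#' @param seed integer seed for the run's single RNG stream.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(R = 0.4, n_steps = 1000, seed = 1)
#' @export
sim_config <- function(R = 0.5, P_m = 0.1, P_d = 0.1, K = 5000L,
                       lattice = lattice_spec(), n_steps = 400000L,
                       mu_r = 0.01, mu_s = 0.1,
                       strategy = c("decision", "pure", "probabilistic"),
                       liquid_S_scope = c("global", "liquid_only"),
                       event_mode = c("uniform", "sequential"),
                       init_liquid = K, seed = 1L) {
  strategy <- match.arg(strategy)
  liquid_S_scope <- match.arg(liquid_S_scope)
  event_mode <- match.arg(event_mode)
  stopifnot(inherits(lattice, "lattice_spec"))
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", nm))
  }
  chk_prob(R, "R"); chk_prob(P_m, "P_m"); chk_prob(P_d, "P_d")
  chk_prob(mu_r, "mu_r")
  if (!is.numeric(mu_s) || mu_s < 0) stop("'mu_s' must be non-negative")
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("'K' must be a positive integer")
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 0L)
    stop("'n_steps' must be a non-negative integer")
  init_liquid <- as.integer(init_liquid)
  if (is.na(init_liquid) || init_liquid < 0L)
    stop("'init_liquid' must be a non-negative integer")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer")
  structure(list(R = R, P_m = P_m, P_d = P_d, K = K, lattice = lattice,
                 n_steps = n_steps, mu_r = mu_r, mu_s = mu_s,
                 strategy = strategy, liquid_S_scope = liquid_S_scope,
                 event_mode = event_mode, init_liquid = init_liquid,
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  strategy: %s   R = %g, P_m = %g, P_d = %g\n",
              x$strategy, x$R, x$P_m, x$P_d))
  cat(sprintf("  K = %d, lattice %d x %d (%s, %s), n_steps = %d\n",
              x$K, x$lattice$height, x$lattice$width,
              x$lattice$neighbourhood, x$lattice$boundary, x$n_steps))
  cat(sprintf("  mu_r = %g, mu_s = %g, liquid_S_scope = %s, seed = %d\n",
              x$mu_r, x$mu_s, x$liquid_S_scope, x$seed))
  invisible(x)
}

#' Study-scale configuration profiles
#'
#' `full_profile()` is the model's standard scale: 100 x 100 hexagonal
#' surface, `K = 5000`, 400,000 steps. `scaled_profile()` is the reduced
#' profile used for replicated desk-scale experiments: 50 x 50 surface,
#' `K = 1250`, 100,000 steps. Both accept overrides via `...` passed to
#' [sim_config()].
#'
#' @param ... overrides passed to [sim_config()].
#' @return a [sim_config()].
#' @export
full_profile <- function(...) {
  args <- modifyList(
    list(lattice = lattice_spec(100L, 100L), K = 5000L, n_steps = 400000L),
    list(...))
  do.call(sim_config, args)
}

#' @rdname full_profile
#' @export
scaled_profile <- function(...) {
  args <- modifyList(
    list(lattice = lattice_spec(50L, 50L), K = 1250L, n_steps = 100000L),
    list(...))
  do.call(sim_config, args)
}
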