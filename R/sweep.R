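## Evolutionary parameter sweeps over (R, P_m, strategy).

#' Sweep evolutionary runs over parameter combinations
#'
#' Runs one evolutionary simulation per combination of `R_values`,
#' `P_m_values`, `strategies` and replicate, and returns the end-state
#' phase table. Each run's seed is derived deterministically from
#' `base_seed`, the combination index and the replicate number.
#'
#' @param R_values relative sticky division rates, in `[0, 1]`.
#' @param P_m_values migration probabilities, in `[0, 0.5]` for the
#'   standard study design.
#' @param strategies subset of `"pure"`, `"probabilistic"`, `"decision"`.
#' @param replicates replicates per combination (the reference replication
#'   level for the R-sweep is 24; default kept small for desk use).
#' @param profile `"scaled"` (50 x 50, K = 1250, 100,000 steps) or
#'   `"full"` (100 x 100, K = 5000, 400,000 steps).
#' @param base_seed integer; per-run seeds are derived from it.
#' @param snapshot_every snapshot cadence passed to [run_simulation()].
#' @param ... further overrides passed to the profile constructor.
#' @return a data frame of class `sweep_table`, one row per run: `R`,
#'   `P_m`, `strategy`, `replicate`, `seed`, `n_surface`, `n_liquid`,
#'   `frac_sticky_surface` (censored at 100 cells), `frac_sticky_liquid`,
#'   `n_genotypes`, `pattern_class`, `life_cycle` (decision runs only).
#' @export
evolve_sweep <- function(R_values = c(0, 0.4, 0.8, 1),
                         P_m_values = 0.1,
                         strategies = c("decision", "probabilistic", "pure"),
                         replicates = 1L,
                         profile = c("scaled", "full"),
                         base_seed = 1L,
                         snapshot_every = NULL, ...) {
  profile <- match.arg(profile)
  make_cfg <- if (profile == "scaled") scaled_profile else full_profile
  combos <- expand.grid(R = R_values, P_m = P_m_values,
                        strategy = strategies, replicate = seq_len(replicates),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    seed <- (as.integer(base_seed) * 1009L + i) %% .Machine$integer.max
    cfg <- make_cfg(R = cb$R, P_m = cb$P_m, strategy = cb$strategy,
                    seed = seed, ...)
    se <- if (is.null(snapshot_every)) max(1L, cfg$n_steps %/% 50L)
          else snapshot_every
    sim <- run_simulation(cfg, snapshot_every = se)
    f <- sim$final
    pattern <- NA_character_; lc <- NA_character_
    if (cb$strategy == "decision") {
      pat <- sticky_components(sim$grid, cfg$lattice)
      pattern <- pat$pattern_class
      cen <- strategy_census(sim$genotypes, cfg$lattice)
      lc <- classify_life_cycle(cen, pat)$label
    }
    data.frame(R = cb$R, P_m = cb$P_m, strategy = cb$strategy,
               replicate = cb$replicate, seed = seed,
               n_surface = f$n_surface, n_liquid = f$n_liquid,
               frac_sticky_surface = f$frac_sticky_surface,
               frac_sticky_liquid = f$frac_sticky_liquid,
               n_genotypes = f$n_genotypes,
               pattern_class = pattern, life_cycle = lc)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}
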