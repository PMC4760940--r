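## Whole-run driver for evolutionary simulations.

#' Run an evolutionary simulation
#'
#' Initializes the liquid at `cfg$init_liquid` non-sticky cells all carrying
#' the all-zero founding genotype of `cfg$strategy` (pure: allele 0;
#' probabilistic: `P = 0`; decision: `W1 = W2 = theta = 0`), executes
#' `cfg$n_steps` time steps, and records a summary snapshot every
#' `snapshot_every` steps. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param snapshot_every snapshot cadence in steps.
#' @param keep_world keep the live [world_new()] object in the result (for
#'   further stepping or inspection).
#' @return an object of class `colonization_sim`: a list with `config`,
#'   `trajectory` (data frame of snapshots), `final` (the end-state summary
#'   from [summarize()]), `grid` (end-state surface table), `genotypes`
#'   (end-state genotype table, abundance-sorted), `counters`, and
#'   optionally `world`.
#' @examples
#' sim <- run_simulation(
#'   sim_config(R = 0.4, K = 100, lattice = lattice_spec(10, 10),
#'              n_steps = 200, seed = 42),
#'   snapshot_every = 50)
#' sim
#' @export
run_simulation <- function(cfg, snapshot_every = max(1L, cfg$n_steps %/% 200L),
                           keep_world = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  w <- world_new(cfg)
  g0 <- switch(cfg$strategy,
               pure = genotype_pure(sticky = FALSE),
               probabilistic = genotype_probabilistic(P = 0),
               decision = genotype_decision(0, 0, 0))
  slot <- world_add_genotype(w, g0)
  world_seed_liquid(w, slot, cfg$init_liquid, sticky = FALSE)
  res <- world_run(w, cfg$n_steps, snapshot_every = snapshot_every,
                   include_initial = TRUE)
  geno <- world_genotypes(w)
  geno <- geno[order(-geno$abundance, geno$id), , drop = FALSE]
  out <- list(config = cfg,
              trajectory = res$trajectory,
              final = summarize(w),
              grid = world_grid(w),
              genotypes = geno,
              counters = world_counters(w))
  if (keep_world) out$world <- w
  class(out) <- "colonization_sim"
  out
}

#' @export
print.colonization_sim <- function(x, ...) {
  f <- x$final
  cat(sprintf("<colonization_sim> %s strategy, R = %g, P_m = %g, %d steps\n",
              x$config$strategy, x$config$R, x$config$P_m,
              x$config$n_steps))
  cat(sprintf("  end state: %d liquid, %d surface cells\n",
              f$n_liquid, f$n_surface))
  cat(sprintf("  sticky fraction: liquid %.3f, surface %s\n",
              f$frac_sticky_liquid,
              if (is.na(f$frac_sticky_surface)) "undefined (<= 100 cells)"
              else sprintf("%.3f", f$frac_sticky_surface)))
  invisible(x)
}

#' @export
summary.colonization_sim <- function(object, ...) {
  out <- list(config = object$config, final = object$final,
              n_genotypes = nrow(object$genotypes),
              top_genotypes = head(object$genotypes, 5L))
  if (object$config$strategy == "decision" && nrow(object$genotypes) > 0) {
    out$census <- strategy_census(object$genotypes, object$config$lattice)
    pat <- sticky_components(object$grid, object$config$lattice)
    out$pattern <- pat
    out$life_cycle <- classify_life_cycle(out$census, pat)
  }
  class(out) <- "summary.colonization_sim"
  out
}

#' @export
print.summary.colonization_sim <- function(x, ...) {
  f <- x$final
  cat(sprintf("Simulation summary (%s strategy, R = %g, P_m = %g)\n",
              x$config$strategy, x$config$R, x$config$P_m))
  cat(sprintf("  liquid: %d cells, sticky fraction %.3f\n",
              f$n_liquid, f$frac_sticky_liquid))
  cat(sprintf("  surface: %d cells, sticky fraction %s\n", f$n_surface,
              if (is.na(f$frac_sticky_surface)) "undefined (<= 100 cells)"
              else sprintf("%.3f", f$frac_sticky_surface)))
  cat(sprintf("  distinct genotypes: %d\n", x$n_genotypes))
  if (!is.null(x$pattern))
    cat(sprintf("  surface pattern: %s (%d sticky components)\n",
                x$pattern$pattern_class, length(x$pattern$component_sizes)))
  if (!is.null(x$life_cycle))
    cat(sprintf("  life cycle: %s\n", x$life_cycle$label))
  invisible(x)
}

#' @export
#' @importFrom graphics legend lines par
plot.colonization_sim <- function(x, ...) {
  tr <- x$trajectory
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(tr$t, tr$n_surface, type = "l", col = "forestgreen",
       xlab = "time step", ylab = "population size",
       ylim = c(0, max(tr$n_surface, tr$n_liquid)), ...)
  lines(tr$t, tr$n_liquid, col = "steelblue")
  legend("topleft", c("surface", "liquid"), lty = 1, bty = "n",
         col = c("forestgreen", "steelblue"))
  plot(tr$t, tr$frac_sticky_surface, type = "l", col = "firebrick",
       xlab = "time step", ylab = "sticky fraction", ylim = c(0, 1), ...)
  lines(tr$t, tr$frac_sticky_liquid, col = "orange")
  legend("topleft", c("surface", "liquid"), lty = 1, bty = "n",
         col = c("firebrick", "orange"))
  invisible(x)
}
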