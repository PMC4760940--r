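## Competition assays between fixed genotypes (mutation off).

#' Detect the inflection point of a population-size curve
#'
#' The inflection step of a (noisy, roughly logistic) total-population
#' trajectory: the index at which a centered moving average of the first
#' differences is maximal. Used to split competitions into phase A
#' (colonization, pre-inflection) and phase B (climax, post-inflection).
#'
#' @param pop numeric vector of population sizes per recorded step.
#' @param window odd window width of the centered moving average.
#' @return integer index into `pop` of the inflection point.
#' @export
detect_inflection <- function(pop, window = 101L) {
  n <- length(pop)
  if (n < 3L) return(max(1L, n %/% 2L))
  d <- diff(pop)
  window <- min(as.integer(window), length(d))
  if (window %% 2L == 0L) window <- window - 1L
  if (window < 1L) window <- 1L
  sm <- stats::filter(d, rep(1 / window, window), sides = 2)
  which.max(as.numeric(sm)) + 1L # +1: diff() shifts by one
}

#' Run a competition between fixed genotypes
#'
#' Competes a list of genotypes with mutation disabled (`mu_r = 0`), so the
#' genotype table is conserved. The standard setup places
#' `n_surface_each` sticky cells of each genotype at uniformly random
#' distinct surface sites and saturates the liquid at `K` non-sticky cells
#' split equally among the genotypes (largest-remainder rounding).
#'
#' @param genotypes a (preferably named) list of [genotype()] objects.
#' @param R,P_m,P_d,K,lattice,n_steps,seed passed to [sim_config()].
#' @param n_surface_each sticky founder cells per genotype on the surface.
#' @param liquid_total initial liquid population (defaults to `K`,
#'   i.e. saturated).
#' @param snapshot_every recording cadence.
#' @param liquid_S_scope passed to [sim_config()].
#' @return an object of class `competition`: list with `trajectory` (data
#'   frame with `t`, `n_total`, `n_surface`, `n_liquid`, per-genotype
#'   overall frequencies `freq_<name>` and frequencies among sticky cells
#'   `sticky_freq_<name>`), `inflection` (recorded-row index),
#'   `phase_means` (per-genotype mean overall frequency in phases A and B),
#'   `genotype_names`, and `config`.
#' @export
run_competition <- function(genotypes, R = 0, P_m = 0.01, P_d = 0.1,
                            K = 5000L, lattice = lattice_spec(),
                            n_steps = 10000L, n_surface_each = 100L,
                            liquid_total = K, snapshot_every = 10L,
                            liquid_S_scope = "global", seed = 1L) {
  stopifnot(length(genotypes) >= 1L)
  nm <- names(genotypes)
  if (is.null(nm)) nm <- paste0("g", seq_along(genotypes))
  cfg <- sim_config(R = R, P_m = P_m, P_d = P_d, K = K, lattice = lattice,
                    n_steps = as.integer(n_steps), mu_r = 0, mu_s = 0,
                    strategy = "decision", liquid_S_scope = liquid_S_scope,
                    seed = seed)
  w <- world_new(cfg)
  slots <- vapply(genotypes, function(g) world_add_genotype(w, g), 0L)
  # equal liquid shares, largest-remainder rounding
  ng <- length(genotypes)
  share <- rep(liquid_total %/% ng, ng)
  extra <- liquid_total - sum(share)
  if (extra > 0) share[seq_len(extra)] <- share[seq_len(extra)] + 1L
  for (i in seq_len(ng)) {
    world_place_cells(w, slots[i], n = n_surface_each, sticky = TRUE)
    world_seed_liquid(w, slots[i], share[i], sticky = FALSE)
  }
  res <- world_run(w, cfg$n_steps, snapshot_every = snapshot_every,
                   include_initial = TRUE, track_genotypes = TRUE)
  tr <- res$trajectory
  counts <- res$genotype_counts[, slots + 1L, drop = FALSE]
  scounts <- res$genotype_sticky_counts[, slots + 1L, drop = FALSE]
  tot <- rowSums(counts)
  stot <- rowSums(scounts)
  freq <- sweep(counts, 1, pmax(tot, 1), "/")
  sfreq <- sweep(scounts, 1, pmax(stot, 1), "/")
  sfreq[stot == 0, ] <- NA_real_
  colnames(freq) <- paste0("freq_", nm)
  colnames(sfreq) <- paste0("sticky_freq_", nm)
  traj <- cbind(data.frame(t = tr$t, n_total = tot,
                           n_surface = tr$n_surface,
                           n_liquid = tr$n_liquid),
                as.data.frame(freq), as.data.frame(sfreq))
  infl <- detect_inflection(traj$n_total,
                            window = max(3L, nrow(traj) %/% 20L * 2L + 1L))
  phase <- function(rows) colMeans(freq[rows, , drop = FALSE])
  nrec <- nrow(traj)
  phase_means <- rbind(A = phase(seq_len(max(infl - 1L, 1L))),
                       B = phase(seq(min(infl, nrec), nrec)))
  colnames(phase_means) <- nm
  structure(list(trajectory = traj, inflection = infl,
                 phase_means = phase_means, genotype_names = nm,
                 genotypes = world_genotypes(w), config = cfg),
            class = "competition")
}

#' @export
print.competition <- function(x, ...) {
  cat(sprintf("<competition> %d genotypes, %d steps, inflection at row %d\n",
              length(x$genotype_names), x$config$n_steps, x$inflection))
  cat("phase mean overall frequencies:\n")
  print(round(x$phase_means, 3))
  invisible(x)
}

#' Death-rate competition between climax genotypes
#'
#' Competes three genotypes sharing the climax decision-making strategy
#' (surface rule `threshold_1`, never sticky in the liquid) that differ
#' only in the death probability of their *sticky* cells
#' (`sticky_death_rates`; non-sticky cells die at `P_d` for all). Sticky
#' cells cannot divide (`R = 0`) and migration is reduced (`P_m = 0.01`) to
#' focus on colony expansion. 100 sticky cells per genotype are placed on
#' the surface; the liquid starts saturated. Higher sticky death rates
#' accelerate colony fission (death -> neighbour differentiation ->
#' refilling division), so the highest-death genotype leads during the
#' colonization phase, while colony longevity wins after the population's
#' inflection point.
#'
#' @param sticky_death_rates death probabilities for sticky cells.
#' @param n_steps steps per replicate (25,000 shows the long-run takeover
#'   by the lowest death rate).
#' @param seeds one replicate per seed.
#' @param ... overrides passed to [run_competition()].
#' @return a list of [run_competition()] objects (one per seed), class
#'   `competition_set`, with attribute `sticky_death_rates`.
#' @export
compete_death_rates <- function(sticky_death_rates = c(0, 0.05, 0.10),
                                n_steps = 10000L, seeds = 1:10, ...) {
  nm <- paste0("death_", sub("\\.", "", format(sticky_death_rates)))
  genos <- lapply(sticky_death_rates, function(d)
    climax_genotype(sticky_death = d))
  names(genos) <- nm
  runs <- lapply(seeds, function(s)
    run_competition(genos, n_steps = n_steps, seed = s, ...))
  structure(runs, class = "competition_set",
            sticky_death_rates = sticky_death_rates, names = paste0("seed_", seeds))
}

#' Filament-versus-island competition
#'
#' Competes the filament-forming colonizing genotype (surface rule
#' `threshold_2`) against the isolated-island climax genotype
#' (`threshold_1`) at `R = 0`, `P_m = 0.01`, 100 sticky founders each and a
#' saturated liquid. The colonizer expands faster before the population's
#' inflection point; the climax genotype produces more propagules and takes
#' over afterwards.
#'
#' @param n_steps steps per replicate.
#' @param seeds one replicate per seed.
#' @param ... overrides passed to [run_competition()].
#' @return a `competition_set` (list of [run_competition()] objects).
#' @export
compete_filament_island <- function(n_steps = 4000L, seeds = 1:10, ...) {
  genos <- list(colonizer = colonizer_genotype(),
                climax = climax_genotype())
  runs <- lapply(seeds, function(s)
    run_competition(genos, n_steps = n_steps, seed = s, ...))
  structure(runs, class = "competition_set", names = paste0("seed_", seeds))
}

#' Average phase frequencies over a competition set
#'
#' @param x a `competition_set`.
#' @return a matrix: rows `A`, `B`; columns genotypes; entries mean-of-means
#'   across replicates.
#' @export
phase_mean_frequencies <- function(x) {
  stopifnot(inherits(x, "competition_set"))
  Reduce(`+`, lapply(x, `[[`, "phase_means")) / length(x)
}

#' @export
print.competition_set <- function(x, ...) {
  cat(sprintf("<competition_set> %d replicates of %d genotypes\n",
              length(x), length(x[[1]]$genotype_names)))
  cat("replicate-averaged phase mean frequencies:\n")
  print(round(phase_mean_frequencies(x), 3))
  invisible(x)
}
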