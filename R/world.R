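## Stateful world objects: thin wrappers around the compiled engine.

.EVENTS <- c(migrate_to_surface = 0L, migrate_to_liquid = 1L,
             differentiate = 2L, death = 3L, divide = 4L)

.geno_to_cpp <- function(world, g) {
  stopifnot(inherits(g, "genotype"))
  cpp_world_add_genotype(
    world$ptr, .KINDS[[g$kind]], g$allele, g$P, g$W1, g$W2, g$theta,
    if (is.null(g$sticky_death)) NA_real_ else g$sticky_death)
}

#' Create a simulation world
#'
#' A `sim_world` holds the full mutable state of one run: the liquid
#' population, the surface occupancy lattice, the genotype table, the time
#' counter and the run's RNG stream (seeded from `cfg$seed`). It starts
#' empty; populate it with [world_add_genotype()], [world_seed_liquid()]
#' and [world_place_cells()], then advance it with [world_step()] or
#' [world_run()].
#'
#' @param cfg a [sim_config()].
#' @return an object of class `sim_world`.
#' @examples
#' w <- world_new(sim_config(K = 10, lattice = lattice_spec(5, 5), seed = 1))
#' g <- world_add_genotype(w, genotype_pure(sticky = FALSE))
#' world_seed_liquid(w, g, n = 10)
#' world_step(w, 5)
#' world_summary(w)
#' @export
world_new <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ptr <- cpp_world_new(cfg$R, cfg$P_m, cfg$P_d, cfg$K,
                       cfg$lattice$height, cfg$lattice$width,
                       .GEOMETRIES[[cfg$lattice$neighbourhood]],
                       .BOUNDARIES[[cfg$lattice$boundary]],
                       cfg$mu_r, cfg$mu_s,
                       match(cfg$liquid_S_scope,
                             c("global", "liquid_only")) - 1L,
                       match(cfg$event_mode,
                             c("uniform", "sequential")) - 1L,
                       as.double(cfg$seed))
  structure(list(ptr = ptr, cfg = cfg), class = "sim_world")
}

#' Register a genotype with a world
#'
#' Adds the genotype to the world's genotype table and returns its engine
#' slot (an integer handle used by the seeding/placement functions).
#' Registered genotypes keep their slot for the whole run, so per-genotype
#' counts from [world_run()] stay aligned.
#'
#' @param world a [world_new()] object.
#' @param g a [genotype()].
#' @return integer slot handle.
#' @export
world_add_genotype <- function(world, g) {
  stopifnot(inherits(world, "sim_world"))
  .geno_to_cpp(world, g)
}

#' Populate the liquid
#'
#' Adds `n` cells of the given genotype slot to the liquid.
#'
#' @param world a [world_new()] object.
#' @param geno genotype slot from [world_add_genotype()].
#' @param n number of cells.
#' @param sticky phenotype of the added cells.
#' @export
world_seed_liquid <- function(world, geno, n, sticky = FALSE) {
  stopifnot(inherits(world, "sim_world"))
  cpp_world_seed_liquid(world$ptr, geno, as.integer(n), isTRUE(sticky))
  invisible(world)
}

#' Place cells on the surface
#'
#' Places `n` cells at uniformly random distinct vacant sites, or at the
#' explicit 1-based `sites` (a two-column `row`, `col` matrix).
#'
#' @param world a [world_new()] object.
#' @param geno genotype slot from [world_add_genotype()].
#' @param n number of cells for random placement.
#' @param sites optional matrix of positions overriding random placement.
#' @param sticky phenotype of the placed cells.
#' @export
world_place_cells <- function(world, geno, n = 1L, sites = NULL,
                              sticky = TRUE) {
  stopifnot(inherits(world, "sim_world"))
  if (is.null(sites)) {
    cpp_world_place_random(world$ptr, geno, as.integer(n), isTRUE(sticky))
  } else {
    sites <- as.matrix(sites)
    for (i in seq_len(nrow(sites)))
      cpp_world_place_at(world$ptr, geno, as.integer(sites[i, 1]) - 1L,
                         as.integer(sites[i, 2]) - 1L, isTRUE(sticky))
  }
  invisible(world)
}

#' Advance a world
#'
#' `world_step()` executes `n` full time steps in place.
#'
#' @param world a [world_new()] object.
#' @param n number of steps.
#' @export
world_step <- function(world, n = 1L) {
  stopifnot(inherits(world, "sim_world"))
  cpp_world_step(world$ptr, as.integer(n))
  invisible(world)
}

#' Run a world while recording a trajectory
#'
#' Advances the world `n_steps` steps and records a summary row every
#' `snapshot_every` steps (plus the final step). With
#' `track_genotypes = TRUE` (fixed genotype table, mutation off) the
#' per-genotype overall and sticky-only cell counts are recorded as well.
#'
#' @param world a [world_new()] object.
#' @param n_steps number of steps to run.
#' @param snapshot_every recording cadence in steps.
#' @param include_initial record the state before the first step too.
#' @param track_genotypes record per-genotype counts (competition assays).
#' @return a list with `trajectory` (data frame: `t`, `n_liquid`,
#'   `n_surface`, `frac_sticky_liquid`, `frac_sticky_surface`,
#'   `n_genotypes`) and, if tracked, count matrices `genotype_counts` and
#'   `genotype_sticky_counts` (one column per genotype slot).
#' @export
world_run <- function(world, n_steps, snapshot_every = 1L,
                      include_initial = FALSE, track_genotypes = FALSE) {
  stopifnot(inherits(world, "sim_world"))
  res <- cpp_world_run(world$ptr, as.integer(n_steps),
                       as.integer(snapshot_every), isTRUE(include_initial),
                       isTRUE(track_genotypes))
  traj <- as.data.frame(res$trajectory)
  traj$frac_sticky_liquid <-
    ifelse(traj$n_liquid > 0, traj$sticky_liquid / traj$n_liquid, NA_real_)
  traj$frac_sticky_surface <-
    ifelse(traj$n_surface > 0, traj$sticky_surface / traj$n_surface,
           NA_real_)
  out <- list(trajectory = traj)
  if (isTRUE(track_genotypes)) {
    out$genotype_counts <- res$genotype_counts
    out$genotype_sticky_counts <- res$genotype_sticky_counts
  }
  out
}

#' Inspect world state
#'
#' `world_state()` returns scalar state (time, population sizes, sticky
#' counts); `world_cells()` the full cell table; `world_grid()` the occupied
#' surface sites sorted by `(row, col)`; `world_genotypes()` the genotype
#' table with abundances; `world_counters()` the cumulative event counters.
#' Positions are 1-based.
#'
#' @param world a [world_new()] object.
#' @return a list or data frame, see above.
#' @export
world_state <- function(world) {
  stopifnot(inherits(world, "sim_world"))
  cpp_world_state(world$ptr)
}

#' @rdname world_state
#' @export
world_cells <- function(world) {
  stopifnot(inherits(world, "sim_world"))
  df <- cpp_world_cells(world$ptr)
  df$row <- df$row + 1L
  df$col <- df$col + 1L
  df$niche <- ifelse(df$on_surface == 1L, "surface", "liquid")
  df$phenotype <- ifelse(df$sticky == 1L, "sticky", "non_sticky")
  df
}

#' @rdname world_state
#' @export
world_grid <- function(world) {
  stopifnot(inherits(world, "sim_world"))
  df <- cpp_world_grid(world$ptr)
  df$row <- df$row + 1L
  df$col <- df$col + 1L
  df$phenotype <- ifelse(df$sticky == 1L, "sticky", "non_sticky")
  df
}

#' @rdname world_state
#' @export
world_genotypes <- function(world) {
  stopifnot(inherits(world, "sim_world"))
  df <- cpp_world_genotypes(world$ptr)
  df$kind <- names(.KINDS)[df$kind + 1L]
  df
}

#' @rdname world_state
#' @export
world_counters <- function(world) {
  stopifnot(inherits(world, "sim_world"))
  cpp_world_counters(world$ptr)
}

#' Apply one event to one cell (assay/test hook)
#'
#' Runs the production code path of a single named event on a single cell
#' (or, with `cell_id = NULL`, on every cell alive at call time in shuffled
#' order). Gates apply as in a normal step; the time counter does not
#' advance and the liquid is not re-normalized (use
#' [world_normalize_liquid()]).
#'
#' @param world a [world_new()] object.
#' @param event one of `"migrate_to_surface"`, `"migrate_to_liquid"`,
#'   `"differentiate"`, `"death"`, `"divide"`.
#' @param cell_id a cell id from [world_cells()], or `NULL` for all cells.
#' @return invisibly, the number of cells the event was applied to.
#' @export
apply_event <- function(world, event, cell_id = NULL) {
  stopifnot(inherits(world, "sim_world"))
  event <- match.arg(event, names(.EVENTS))
  if (is.null(cell_id)) {
    n <- cpp_world_apply_event_all(world$ptr, .EVENTS[[event]])
  } else {
    n <- 0L
    for (id in cell_id)
      n <- n + as.integer(cpp_world_apply_event(world$ptr, as.double(id),
                                                .EVENTS[[event]]))
  }
  invisible(n)
}

#' Dilute the liquid back to carrying capacity
#'
#' Removes uniformly random liquid cells until the liquid population is at
#' most `K`; the end-of-step normalization, exposed for stepwise use with
#' [apply_event()].
#'
#' @param world a [world_new()] object.
#' @export
world_normalize_liquid <- function(world) {
  stopifnot(inherits(world, "sim_world"))
  cpp_world_normalize_liquid(world$ptr)
  invisible(world)
}

#' @export
print.sim_world <- function(x, ...) {
  st <- world_state(x)
  cat(sprintf(
    "<sim_world> t = %d: %d liquid (%d sticky), %d surface (%d sticky)\n",
    as.integer(st$t), st$n_liquid, st$sticky_liquid, st$n_surface,
    st$sticky_surface))
  invisible(x)
}
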