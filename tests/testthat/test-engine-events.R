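# Per-event behaviour, exercised through the production event code paths.

test_that("migration to the surface needs vacancy and sticky support", {
  # a lone sticky liquid cell on an empty lattice with P_m = 1 attaches
  # with certainty (every site is vacant)
  mw <- micro_world(g = genotype_pure(TRUE), P_m = 1)
  world_seed_liquid(mw$world, mw$slot, 1L, sticky = TRUE)
  apply_event(mw$world, "migrate_to_surface")
  expect_equal(world_state(mw$world)$n_surface, 1L)

  # many sticky migrants: draws that hit an occupied site fail, but
  # repeated attempts eventually attach everyone
  mw <- micro_world(g = genotype_pure(TRUE), P_m = 1)
  world_seed_liquid(mw$world, mw$slot, 50L, sticky = TRUE)
  for (i in 1:100) apply_event(mw$world, "migrate_to_surface")
  expect_equal(world_state(mw$world)$n_surface, 50L)

  # non-sticky liquid cell, empty lattice: never attaches
  mw <- micro_world(g = genotype_pure(FALSE), P_m = 1)
  world_seed_liquid(mw$world, mw$slot, 50L, sticky = FALSE)
  for (i in 1:20) apply_event(mw$world, "migrate_to_surface")
  expect_equal(world_state(mw$world)$n_surface, 0L)

  # P_m = 0: no attachment even for sticky cells
  mw <- micro_world(g = genotype_pure(TRUE), P_m = 0)
  world_seed_liquid(mw$world, mw$slot, 50L, sticky = TRUE)
  apply_event(mw$world, "migrate_to_surface")
  expect_equal(world_state(mw$world)$n_surface, 0L)
})

test_that("non-sticky attachment probability equals vacant-neighbour share", {
  # one sticky occupant on a 10x10 hex lattice; a non-sticky migrant can
  # attach only at the 6 vacant neighbours of that cell: p = 6/100.
  # Empirical check over 6000 independent attempts (failed attempts leave
  # the world unchanged; the world is rebuilt after each success).
  n_try <- 6000L
  successes <- 0L
  seed <- 0L
  make <- function(seed) {
    mw <- micro_world(g = climax_genotype(), width = 10L, height = 10L,
                      P_m = 1, K = 10L, seed = seed)
    world_place_cells(mw$world, mw$slot, sites = cbind(5L, 5L),
                      sticky = TRUE)
    world_seed_liquid(mw$world, mw$slot, 1L, sticky = FALSE)
    mw
  }
  mw <- make(seed)
  id <- world_cells(mw$world)$cell_id[
    world_cells(mw$world)$niche == "liquid"]
  for (i in seq_len(n_try)) {
    apply_event(mw$world, "migrate_to_surface", cell_id = id)
    if (world_state(mw$world)$n_surface == 2L) {
      successes <- successes + 1L
      # attached cell must neighbour the sticky cell
      grid <- world_grid(mw$world)
      att <- grid[grid$phenotype == "non_sticky", ]
      nb <- neighbours(lattice_spec(10L, 10L), att$row, att$col)
      expect_true(any(nb[, "row"] == 5L & nb[, "col"] == 5L))
      seed <- seed + 1L
      mw <- make(seed)
      id <- world_cells(mw$world)$cell_id[
        world_cells(mw$world)$niche == "liquid"]
    }
  }
  p <- 6 / 100
  se <- sqrt(p * (1 - p) / n_try)
  expect_lt(abs(successes / n_try - p), 3 * se)
})

test_that("dislodgement requires non-sticky and no sticky neighbour", {
  mw <- micro_world(g = climax_genotype(), width = 6L, height = 6L, K = 50L)
  sp <- lattice_spec(6L, 6L)
  world_place_cells(mw$world, mw$slot, sites = cbind(3L, 3L), sticky = TRUE)
  nb <- neighbours(sp, 3L, 3L)
  world_place_cells(mw$world, mw$slot, sites = nb[1, , drop = FALSE],
                    sticky = FALSE)
  # sticky cell is never dislodged; supported non-sticky stays
  for (i in 1:10) apply_event(mw$world, "migrate_to_liquid")
  expect_equal(world_state(mw$world)$n_surface, 2L)
  # kill the sticky cell (death event with P_d temporarily irrelevant:
  # use a fresh world with P_d = 1 and apply death to the sticky cell only)
  mw <- micro_world(g = climax_genotype(), width = 6L, height = 6L,
                    K = 50L, P_d = 1)
  world_place_cells(mw$world, mw$slot, sites = cbind(3L, 3L), sticky = TRUE)
  world_place_cells(mw$world, mw$slot, sites = nb[1, , drop = FALSE],
                    sticky = FALSE)
  cells <- world_cells(mw$world)
  sticky_id <- cells$cell_id[cells$phenotype == "sticky"]
  ns_id <- cells$cell_id[cells$phenotype == "non_sticky"]
  apply_event(mw$world, "death", cell_id = sticky_id)
  expect_equal(world_state(mw$world)$n_surface, 1L)
  # now unsupported: the dislodgement event moves it to the liquid
  apply_event(mw$world, "migrate_to_liquid", cell_id = ns_id)
  st <- world_state(mw$world)
  expect_equal(st$n_surface, 0L)
  expect_equal(st$n_liquid, 1L)
})

test_that("death applies P_d, or the sticky-death override for sticky cells", {
  # 100,000 cells, one death event each: empirical fraction ~ P_d = 0.1
  mw <- micro_world(g = genotype_pure(FALSE), K = 100000L, P_d = 0.1)
  world_seed_liquid(mw$world, mw$slot, 100000L)
  apply_event(mw$world, "death")
  died <- 100000L - world_state(mw$world)$n_liquid
  se <- sqrt(0.1 * 0.9 / 1e5)
  expect_lt(abs(died / 1e5 - 0.1), 3 * se)

  # sticky cells with override 0.05 die at 5%, not P_d = 10%
  g <- genotype_pure(TRUE, sticky_death = 0.05)
  mw <- micro_world(g = g, K = 100000L, P_d = 0.1)
  world_seed_liquid(mw$world, mw$slot, 100000L, sticky = TRUE)
  apply_event(mw$world, "death")
  died <- 100000L - world_state(mw$world)$n_liquid
  se <- sqrt(0.05 * 0.95 / 1e5)
  expect_lt(abs(died / 1e5 - 0.05), 3 * se)

  # override 0: sticky cells never die
  g <- genotype_pure(TRUE, sticky_death = 0)
  mw <- micro_world(g = g, K = 1000L, P_d = 1)
  world_seed_liquid(mw$world, mw$slot, 1000L, sticky = TRUE)
  apply_event(mw$world, "death")
  expect_equal(world_state(mw$world)$n_liquid, 1000L)
})

test_that("division gates: sticky Bernoulli(R), liquid capacity", {
  # R = 0: sticky cells never divide
  mw <- micro_world(g = genotype_pure(TRUE), R = 0, K = 100L)
  world_seed_liquid(mw$world, mw$slot, 10L, sticky = TRUE)
  for (i in 1:50) apply_event(mw$world, "divide")
  expect_equal(world_state(mw$world)$n_liquid, 10L)
  expect_equal(world_counters(mw$world)$sticky_divisions, 0)

  # liquid at K: no division
  mw <- micro_world(g = genotype_pure(FALSE), K = 10L)
  world_seed_liquid(mw$world, mw$slot, 10L)
  apply_event(mw$world, "divide")
  expect_equal(world_state(mw$world)$n_liquid, 10L)

  # below K: every non-sticky division succeeds
  mw <- micro_world(g = genotype_pure(FALSE), K = 100L)
  world_seed_liquid(mw$world, mw$slot, 10L)
  apply_event(mw$world, "divide")
  expect_equal(world_state(mw$world)$n_liquid, 20L)
})

test_that("daughter placement is uniform over eligible slots (1/(v+1))", {
  # sticky surface parent with 6 vacant neighbours and open liquid:
  # 7 slots, each 1/7. Chi-square over 2100 forced divisions (fresh world
  # each trial so the slot set never changes).
  sp <- lattice_spec(6L, 6L)
  nb <- neighbours(sp, 3L, 3L)
  keys <- paste(nb[, "row"], nb[, "col"])
  counts <- setNames(rep(0L, 7L), c(keys, "liquid"))
  for (i in seq_len(2100L)) {
    mw <- micro_world(g = genotype_pure(TRUE), width = 6L, height = 6L,
                      R = 1, K = 10L, seed = i)
    world_place_cells(mw$world, mw$slot, sites = cbind(3L, 3L),
                      sticky = TRUE)
    pid <- world_cells(mw$world)$cell_id[1]
    apply_event(mw$world, "divide", cell_id = pid)
    cells <- world_cells(mw$world)
    expect_equal(nrow(cells), 2L)
    d <- cells[cells$cell_id != pid, ]
    key <- if (d$niche == "liquid") "liquid" else paste(d$row, d$col)
    counts[key] <- counts[key] + 1L
  }
  expect_equal(sum(counts), 2100L) # daughters only ever in the 7 slots
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("daughters of surface parents go only to supported sites", {
  # non-sticky surface parent next to a sticky cell: daughter (non-sticky)
  # may only be retained at vacant sites that neighbour a sticky cell
  sp <- lattice_spec(8L, 8L)
  for (i in 1:100) {
    mw <- micro_world(g = climax_genotype(), width = 8L, height = 8L,
                      R = 1, K = 10L, seed = 1000L + i)
    world_place_cells(mw$world, mw$slot, sites = cbind(4L, 4L),
                      sticky = TRUE)
    world_place_cells(mw$world, mw$slot, sites = cbind(4L, 5L),
                      sticky = FALSE)
    cells <- world_cells(mw$world)
    pid <- cells$cell_id[cells$phenotype == "non_sticky"]
    apply_event(mw$world, "divide", cell_id = pid)
    cells <- world_cells(mw$world)
    d <- cells[!cells$cell_id %in% pid &
                 cells$phenotype == "non_sticky", ]
    d <- d[d$niche == "surface", ]
    if (nrow(d) == 1L) {
      nb <- neighbours(sp, d$row, d$col)
      expect_true(any(nb[, "row"] == 4L & nb[, "col"] == 4L),
                  info = sprintf("daughter at (%d,%d)", d$row, d$col))
    }
  }
})

test_that("differentiation senses the niche-appropriate stickiness", {
  # surface: S = sticky neighbours / neighbourhood size
  mw <- micro_world(g = genotype_decision(W1 = 0, W2 = 1, theta = 0.3),
                    width = 6L, height = 6L, K = 50L)
  sp <- lattice_spec(6L, 6L)
  nb <- neighbours(sp, 3L, 3L)
  # 2 sticky of 6 neighbours: S = 1/3 > 0.3 -> sticky
  world_place_cells(mw$world, mw$slot, sites = nb[1:2, ], sticky = TRUE)
  world_place_cells(mw$world, mw$slot, sites = cbind(3L, 3L),
                    sticky = FALSE)
  cells <- world_cells(mw$world)
  focal <- cells$cell_id[cells$row == 3L & cells$col == 3L &
                           !is.na(cells$row)]
  apply_event(mw$world, "differentiate", cell_id = focal)
  cells <- world_cells(mw$world)
  expect_equal(cells$phenotype[cells$cell_id == focal], "sticky")

  # with theta = 1/3 exactly, 2/6 sticky is NOT enough (strict rule)
  mw <- micro_world(g = genotype_decision(W1 = 0, W2 = 1, theta = 1 / 3),
                    width = 6L, height = 6L, K = 50L)
  world_place_cells(mw$world, mw$slot, sites = nb[1:2, ], sticky = TRUE)
  world_place_cells(mw$world, mw$slot, sites = cbind(3L, 3L),
                    sticky = FALSE)
  cells <- world_cells(mw$world)
  focal <- cells$cell_id[cells$row == 3L & cells$col == 3L &
                           !is.na(cells$row)]
  apply_event(mw$world, "differentiate", cell_id = focal)
  expect_equal(world_cells(mw$world)$phenotype[
    world_cells(mw$world)$cell_id == focal], "non_sticky")
})

test_that("the transient-attachment genotype is sticky in liquid only", {
  lc4 <- life_cycle_genotypes()$lc4
  mw <- micro_world(g = lc4, width = 6L, height = 6L, K = 50L)
  world_seed_liquid(mw$world, mw$slot, 1L, sticky = FALSE)
  apply_event(mw$world, "differentiate")
  expect_equal(world_state(mw$world)$sticky_liquid, 1L) # differentiates
  # the same genotype de-differentiates on the surface
  world_place_cells(mw$world, mw$slot, sites = cbind(2L, 2L), sticky = TRUE)
  cells <- world_cells(mw$world)
  sid <- cells$cell_id[cells$niche == "surface"]
  apply_event(mw$world, "differentiate", cell_id = sid)
  expect_equal(world_state(mw$world)$sticky_surface, 0L)
})

test_that("a surface cell that de-differentiates is not instantly dislodged", {
  mw <- micro_world(g = life_cycle_genotypes()$lc4, width = 6L, height = 6L,
                    K = 50L)
  world_place_cells(mw$world, mw$slot, sites = cbind(2L, 2L), sticky = TRUE)
  cells <- world_cells(mw$world)
  apply_event(mw$world, "differentiate", cell_id = cells$cell_id[1])
  expect_equal(world_state(mw$world)$n_surface, 1L) # still attached
  apply_event(mw$world, "migrate_to_liquid", cell_id = cells$cell_id[1])
  expect_equal(world_state(mw$world)$n_surface, 0L) # dislodged by its event
})

test_that("liquid dilution removes exactly the excess, uniformly", {
  mw <- micro_world(g = genotype_pure(FALSE), K = 100L)
  world_seed_liquid(mw$world, mw$slot, 100L)
  world_normalize_liquid(mw$world)
  expect_equal(world_state(mw$world)$n_liquid, 100L) # at K: no removal
  mw <- micro_world(g = genotype_pure(FALSE), K = 100L)
  world_seed_liquid(mw$world, mw$slot, 110L)
  world_normalize_liquid(mw$world)
  expect_equal(world_state(mw$world)$n_liquid, 100L) # exactly 10 removed

  # neutrality: two genotype groups at 50/50, dilution from 200 to 100
  # preserves frequencies in expectation (chi-square over 600 repetitions)
  kept <- 0L
  n_rep <- 600L
  for (i in seq_len(n_rep)) {
    w <- world_new(micro_config(K = 100L, seed = 5000L + i))
    a <- world_add_genotype(w, genotype_pure(FALSE))
    b <- world_add_genotype(w, genotype_probabilistic(0))
    world_seed_liquid(w, a, 100L)
    world_seed_liquid(w, b, 100L)
    world_normalize_liquid(w)
    tab <- world_genotypes(w)
    kept <- kept + tab$abundance[tab$kind == "pure"]
  }
  p_hat <- kept / (n_rep * 100L)
  se <- sqrt(0.5 * 0.5 / (n_rep * 100L)) # slight overdispersion ignored
  expect_lt(abs(p_hat - 0.5), 4 * se)
})
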