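# Whole-step behaviour: event scheduling, capacity, invariants, determinism.

test_that("an empty world steps to an empty world with t + 1", {
  w <- world_new(micro_config())
  world_step(w, 3L)
  st <- world_state(w)
  expect_equal(st$t, 3)
  expect_equal(st$n_liquid + st$n_surface, 0L)
})

test_that("each of the five events is drawn with frequency 1/5", {
  mw <- micro_world(g = genotype_pure(FALSE), K = 2000L, P_m = 0, P_d = 0)
  world_seed_liquid(mw$world, mw$slot, 2000L)
  world_step(mw$world, 100L)
  drawn <- world_counters(mw$world)$events_drawn
  total <- sum(drawn)
  expect_equal(total, 2000 * 100)
  se <- sqrt(0.2 * 0.8 / total)
  for (e in names(drawn))
    expect_lt(abs(drawn[[e]] / total - 0.2), 3 * se)
})

test_that("a lone liquid cell gives birth in about 1/5 of single steps", {
  # P_m = 0, P_d = 0, K = 2: only a drawn division event changes anything
  births <- 0L
  n <- 2000L
  for (i in seq_len(n)) {
    mw <- micro_world(g = genotype_pure(FALSE), K = 2L, P_m = 0, P_d = 0,
                      seed = i)
    world_seed_liquid(mw$world, mw$slot, 1L)
    world_step(mw$world, 1L)
    if (world_state(mw$world)$n_liquid == 2L) births <- births + 1L
  }
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(births / n - 0.2), 3 * se)
})

test_that("a liquid at carrying capacity stays constant without death", {
  mw <- micro_world(g = genotype_pure(FALSE), K = 500L, P_m = 0, P_d = 0)
  world_seed_liquid(mw$world, mw$slot, 500L)
  world_run(mw$world, 50L)
  expect_equal(world_state(mw$world)$n_liquid, 500L)
})

test_that("liquid never exceeds K at the end of a step", {
  # busy world with plenty of dislodgement into a small liquid
  cfg <- sim_config(R = 0.5, P_m = 0.3, P_d = 0.1, K = 200L,
                    lattice = lattice_spec(20L, 20L), n_steps = 0L,
                    mu_r = 0.05, mu_s = 0.2, seed = 9L)
  w <- world_new(cfg)
  slot <- world_add_genotype(w, genotype_probabilistic(0.5))
  world_seed_liquid(w, slot, 200L)
  for (i in 1:200) {
    world_step(w)
    expect_lte(world_state(w)$n_liquid, 200L)
  }
})

test_that("occupancy stays consistent with cell positions", {
  cfg <- sim_config(R = 0.5, P_m = 0.2, P_d = 0.1, K = 300L,
                    lattice = lattice_spec(15L, 15L), n_steps = 0L,
                    mu_r = 0.05, mu_s = 0.2, seed = 17L)
  w <- world_new(cfg)
  slot <- world_add_genotype(w, genotype_probabilistic(0.4))
  world_seed_liquid(w, slot, 300L)
  world_step(w, 300L)
  cells <- world_cells(w)
  grid <- world_grid(w)
  surf <- cells[cells$niche == "surface", ]
  expect_equal(nrow(grid), nrow(surf))
  expect_equal(nrow(unique(grid[, c("row", "col")])), nrow(grid))
  m <- merge(surf[, c("cell_id", "row", "col")],
             grid[, c("cell_id", "row", "col")], by = "cell_id")
  expect_equal(m$row.x, m$row.y)
  expect_equal(m$col.x, m$col.y)
  st <- world_state(w)
  expect_equal(st$n_surface, nrow(grid))
  expect_equal(st$n_liquid, sum(cells$niche == "liquid"))
})

test_that("no sticky cell ever divides at R = 0", {
  cfg <- sim_config(R = 0, P_m = 0.2, P_d = 0.1, K = 300L,
                    lattice = lattice_spec(15L, 15L), n_steps = 0L,
                    mu_r = 0.05, mu_s = 0.2, seed = 23L)
  w <- world_new(cfg)
  slot <- world_add_genotype(w, genotype_probabilistic(0.5))
  world_seed_liquid(w, slot, 300L)
  world_step(w, 500L)
  expect_equal(world_counters(w)$sticky_divisions, 0)
  expect_gt(world_counters(w)$divisions, 0)
})

test_that("pure-strategy cells always express their allele", {
  cfg <- sim_config(R = 0.8, P_m = 0.2, P_d = 0.1, K = 400L,
                    lattice = lattice_spec(15L, 15L), n_steps = 0L,
                    mu_r = 0.02, mu_s = 0.1, strategy = "pure", seed = 31L)
  w <- world_new(cfg)
  slot <- world_add_genotype(w, genotype_pure(FALSE))
  world_seed_liquid(w, slot, 400L)
  for (chunk in 1:5) {
    world_step(w, 100L)
    cells <- world_cells(w)
    geno <- world_genotypes(w)
    allele <- setNames(geno$allele, as.character(geno$id))
    expect_true(all(cells$sticky ==
                      allele[as.character(cells$genotype_id)]))
  }
  # and the differentiation event never switched anyone
  expect_equal(world_counters(w)$phenotype_switches, 0)
})

test_that("climax colonies never hold adjacent sticky cells at R = 0", {
  cfg <- sim_config(R = 0, P_m = 0.1, P_d = 0.1, K = 300L,
                    lattice = lattice_spec(20L, 20L), n_steps = 0L,
                    mu_r = 0, seed = 41L)
  w <- world_new(cfg)
  slot <- world_add_genotype(w, climax_genotype())
  world_seed_liquid(w, slot, 300L)
  world_place_cells(w, slot, n = 10L, sticky = TRUE)
  sp <- cfg$lattice
  world_step(w, 200L)
  for (chunk in 1:5) {
    world_step(w, 20L)
    grid <- world_grid(w)
    stick <- grid[grid$phenotype == "sticky", ]
    if (nrow(stick) < 2L) next
    key <- paste(stick$row, stick$col)
    for (i in seq_len(nrow(stick))) {
      nb <- neighbours(sp, stick$row[i], stick$col[i])
      expect_false(any(paste(nb[, "row"], nb[, "col"]) %in% key))
    }
  }
})

test_that("saturated worlds push more cells to the liquid than they admit", {
  # migratory asymmetry: surface-to-liquid flux (dislodgement + divisions
  # dislodged to the liquid) exceeds liquid-to-surface attachment
  cfg <- sim_config(R = 0, P_m = 0.1, P_d = 0.1, K = 300L,
                    lattice = lattice_spec(20L, 20L), n_steps = 0L,
                    mu_r = 0, seed = 43L)
  w <- world_new(cfg)
  slot <- world_add_genotype(w, climax_genotype())
  world_seed_liquid(w, slot, 300L)
  world_place_cells(w, slot, n = 30L, sticky = TRUE)
  world_step(w, 500L) # reach a crowded quasi-steady state
  c0 <- world_counters(w)
  world_step(w, 500L)
  c1 <- world_counters(w)
  to_liquid <- (c1$dislodgements - c0$dislodgements) +
    (c1$surface_divisions_to_liquid - c0$surface_divisions_to_liquid)
  to_surface <- c1$attachments - c0$attachments
  expect_gt(to_liquid, to_surface)
})

test_that("runs are bit-identical under a fixed seed", {
  run_once <- function() {
    cfg <- scaled_profile(R = 0.4, strategy = "decision", seed = 101L,
                          n_steps = 2000L)
    sim <- run_simulation(cfg, snapshot_every = 200L)
    list(tr = sim$trajectory, grid = sim$grid, geno = sim$genotypes)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$tr, b$tr)
  expect_identical(a$grid, b$grid)
  expect_identical(a$geno, b$geno)
  # a different seed gives a different trajectory
  cfg2 <- scaled_profile(R = 0.4, strategy = "decision", seed = 102L,
                         n_steps = 2000L)
  c2 <- run_simulation(cfg2, snapshot_every = 200L)
  expect_false(identical(a$tr, c2$trajectory))
})

test_that("stepping a world in chunks equals one continuous run", {
  mk <- function() {
    cfg <- sim_config(R = 0.5, P_m = 0.1, P_d = 0.1, K = 200L,
                      lattice = lattice_spec(10L, 10L), n_steps = 0L,
                      mu_r = 0.01, seed = 7L)
    w <- world_new(cfg)
    slot <- world_add_genotype(w, genotype_probabilistic(0.3))
    world_seed_liquid(w, slot, 200L)
    w
  }
  w1 <- mk(); world_step(w1, 100L)
  w2 <- mk(); world_step(w2, 60L); world_step(w2, 40L)
  expect_identical(world_cells(w1), world_cells(w2))
  expect_identical(world_state(w1), world_state(w2))
})
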