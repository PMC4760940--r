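# Builders for small worlds used across test files.

micro_config <- function(width = 10L, height = 10L, K = 100L, R = 1,
                         P_m = 1, P_d = 0, mu_r = 0, seed = 1L, ...) {
  sim_config(R = R, P_m = P_m, P_d = P_d, K = K,
             lattice = lattice_spec(width, height),
             n_steps = 0L, mu_r = mu_r, mu_s = 0.1, seed = seed, ...)
}

# world with one registered genotype, returns list(world, slot)
micro_world <- function(g = genotype_pure(FALSE), ...) {
  w <- world_new(micro_config(...))
  slot <- world_add_genotype(w, g)
  list(world = w, slot = slot)
}

# an always-sticky decision genotype (differentiaties everywhere)
always_sticky_genotype <- function() genotype_decision(W1 = 0, W2 = 0,
                                                       theta = -1)
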