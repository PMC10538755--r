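cfg0 <- sim_config(seed = 1)

test_that("configuration defaults match the tortoise parameterisation", {
  expect_equal(cfg0$dispersal_probability, 0.5)
  expect_equal(cfg0$max_dispersal_cells, 10L)
  expect_equal(cfg0$growth_rate, 0.48)
  expect_equal(cfg0$mutation_rate, 5e-4)
  expect_error(sim_config(dispersal_probability = 1.5))
  expect_error(sim_config(mutation_rate = -1))
})

test_that("initial populations match density x landscape exactly", {
  fo <- fixture_founders(12500, seed = 40)
  for (case in list(list("low", 1875L), list("moderate", 8750L),
                    list("high", 12500L))) {
    surf <- build_scenario_surface("no_barrier", density = case[[1]])
    st <- initialize_population(surf, case[[1]], fo, seed = 41)
    expect_equal(st$n, case[[2]])
  }
  vs <- build_scenario_surface("barrier", density = "moderate")
  st <- initialize_population(vs, "variable", fo, seed = 42)
  expect_equal(st$n, sum(vs$carrying_capacity))
  expect_error(initialize_population(vs, "weird", fo), "density")
})

test_that("no one moves when dispersal probability is zero", {
  fo <- fixture_founders(2000)
  for (kernel in c("random_walk", "max_ring")) {
    cfg <- sim_config(dispersal_probability = 0, dispersal_kernel = kernel, seed = 2)
    surf <- build_scenario_surface("no_barrier", density = "low")
    st <- initialize_population(surf, "low", fo, seed = 3)
    moved <- disperse(st, surf, cfg)
    expect_identical(moved$cell, st$cell)
  }
})

test_that("ring-kernel dispersers land exactly ten cells away", {
  fo <- fixture_founders(200)
  cfg <- sim_config(dispersal_probability = 1, dispersal_kernel = "max_ring", seed = 4)
  surf <- build_scenario_surface("no_barrier", density = "low")
  # one individual at the centre cell (13, 13)
  st <- initialize_population(surf, "low", fo, seed = 5)
  st$cell <- rep(tortsim:::cell_id(13L, 13L, 25L), st$n)
  set.seed(6)
  moved <- disperse(st, surf, cfg)
  d <- pmax(abs(tortsim:::cell_row(moved$cell, 25L) - 13),
            abs(tortsim:::cell_col(moved$cell, 25L) - 13))
  expect_true(all(d == 10))
  # and the ring is covered roughly uniformly
  expect_gt(length(unique(moved$cell)), 60)
})

test_that("walk-kernel displacement never exceeds the step budget", {
  fo <- fixture_founders(2000)
  cfg <- sim_config(dispersal_probability = 1, seed = 7)
  surf <- build_scenario_surface("no_barrier", density = "low")
  st <- initialize_population(surf, "low", fo, seed = 8)
  r0 <- tortsim:::cell_row(st$cell, 25L); c0 <- tortsim:::cell_col(st$cell, 25L)
  set.seed(9)
  moved <- disperse(st, surf, cfg)
  d <- pmax(abs(tortsim:::cell_row(moved$cell, 25L) - r0),
            abs(tortsim:::cell_col(moved$cell, 25L) - c0))
  expect_true(all(d <= 10))
  expect_gt(mean(d), 0.5)  # walkers really move
})

test_that("an absolute barrier is impermeable to lineages", {
  # left side carries only allele 1, right side only allele 2 at every locus;
  # with mutation off, any cross-barrier gene flow would mix the two pools
  surf <- build_scenario_surface("barrier", density = "moderate")
  states <- lapply(1:20, function(l) 1:2)
  bc <- 13L
  for (kernel in c("random_walk", "max_ring")) {
    cfg <- sim_config(mutation_rate = 0, dispersal_kernel = kernel, seed = 10)
    hab <- which(as.vector(t(surf$resistance)) < 1)
    cells <- rep(hab, 4L)
    n <- length(cells)
    side <- tortsim:::cell_col(cells, 25L) < bc
    G <- matrix(ifelse(rep(side, 40L), 1L, 2L), n, 40L)
    st <- tortsim:::new_state(cells, stats::runif(n) < 0.5, G, states)
    attr(st, "n_cols") <- 25L
    set.seed(11)
    for (g in 1:10) st <- step_generation(st, surf, cfg)
    col <- tortsim:::cell_col(st$cell, 25L)
    expect_true(all(st$G[col < bc, ] == 1L))
    expect_true(all(st$G[col > bc, ] == 2L))
    expect_true(all(col != bc))
  }
})

test_that("culvert transit quotas are never exceeded", {
  fo <- fixture_founders(12500, seed = 44)
  surf <- build_scenario_surface("culverts", density = "high")
  for (kernel in c("random_walk", "max_ring")) {
    cfg <- sim_config(dispersal_kernel = kernel, seed = 12)
    st <- initialize_population(surf, "high", fo, seed = 13)
    tb <- tortsim:::dispersal_tables(surf, 10L, kernel)
    set.seed(14)
    for (g in 1:5) {
      st <- disperse(st, surf, cfg, tb)
      expect_true(all(st$crossings <= 3L))
      st <- reproduce(st, surf, cfg)
    }
    expect_gt(sum(st$crossings), 0)  # culverts are actually used
  }
})

test_that("recruitment follows the per-cell logistic map", {
  surf <- build_scenario_surface("no_barrier", density = "high")  # K = 24
  states <- lapply(1:20, function(l) 1:3)
  mk_state <- function(n, female) {
    st <- tortsim:::new_state(rep(1L, n), female,
                              matrix(1L, n, 40L), states)
    attr(st, "n_cols") <- 25L
    st
  }
  cfg <- sim_config(seed = 15)
  # a lone individual cannot reproduce
  expect_equal(reproduce(mk_state(1, TRUE), surf, cfg)$n, 0)
  expect_true(reproduce(mk_state(1, TRUE), surf, cfg)$extinct)
  # a single-sex pair cannot either
  expect_equal(reproduce(mk_state(2, c(TRUE, TRUE)), surf, cfg)$n, 0)
  # N = K exactly replaces itself (E = K, no fractional part)
  surf_low <- build_scenario_surface("no_barrier", density = "low")  # K = 3
  set.seed(16)
  for (i in 1:10) {
    out <- reproduce(mk_state(3, c(TRUE, TRUE, FALSE)), surf_low, cfg)
    expect_equal(out$n, 3)
  }
  # N = 2, K = 24: E = 2 + 0.48 * 2 * (22 / 24) = 2.88
  set.seed(17)
  draws <- replicate(3000, reproduce(mk_state(2, c(TRUE, FALSE)), surf, cfg)$n)
  expect_true(all(draws %in% 2:3))
  expect_lt(abs(mean(draws) - 2.88), 0.05)
})

test_that("recruits inherit one allele per parent and conserve alleles", {
  fo <- fixture_founders(2000)
  surf <- build_scenario_surface("no_barrier", density = "moderate")
  cfg <- sim_config(mutation_rate = 0, seed = 18)
  st <- initialize_population(surf, "moderate", fo, seed = 19)
  set.seed(20)
  nxt <- step_generation(st, surf, cfg)
  for (l in c(1L, 7L, 20L)) {
    parent_alleles <- sort(unique(c(st$G[, 2 * l - 1], st$G[, 2 * l])))
    child_alleles <- unique(c(nxt$G[, 2 * l - 1], nxt$G[, 2 * l]))
    expect_true(all(child_alleles %in% parent_alleles))
  }
})

test_that("mutation hits at the configured rate and respects the model", {
  fo <- fixture_founders(4000)
  st <- tortsim:::new_state(rep(1L, 4000), rep(TRUE, 4000),
                            fo$G[1:4000, ], fo$allele_states)
  # mu = 0: untouched
  expect_identical(mutate_genotypes(st, sim_config(mutation_rate = 0))$G, st$G)
  # expected count = n * loci * 2 * mu
  set.seed(21)
  counts <- replicate(20, mutate_genotypes(st, sim_config())$n_mutations)
  expect_lt(abs(mean(counts) - 4000 * 20 * 2 * 5e-4), 15)
  # a two-state locus always flips to the other allele
  two <- tortsim:::new_state(rep(1L, 500), rep(TRUE, 500),
                             matrix(1L, 500, 2L), list(1:2))
  set.seed(22)
  mut <- mutate_genotypes(two, sim_config(mutation_rate = 0.5))
  expect_true(all(mut$G %in% 1:2))
  expect_gt(sum(mut$G == 2L), 0)
  # a monomorphic locus cannot mutate
  mono <- tortsim:::new_state(rep(1L, 100), rep(TRUE, 100),
                              matrix(1L, 100, 2L), list(1L))
  expect_true(all(mutate_genotypes(mono, sim_config(mutation_rate = 1))$G == 1L))
})

test_that("without mutation, allele frequencies drift without bias", {
  fo <- fixture_founders(2000)
  surf <- build_scenario_surface("no_barrier", density = "moderate",
                                 n_rows = 8L, n_cols = 8L)
  cfg <- sim_config(mutation_rate = 0, n_generations = 5, seed = 23)
  p0 <- mean(fo$G[1:896, c(1, 2)] == 1L)
  finals <- vapply(1:12, function(r) {
    set.seed(100 + r)
    st <- initialize_population(surf, "moderate", fo)
    st$G <- fo$G[1:st$n, ]
    for (g in 1:5) st <- step_generation(st, surf, cfg)
    mean(st$G[, c(1, 2)] == 1L)
  }, numeric(1))
  expect_lt(abs(mean(finals) - p0), 0.02)
})

test_that("an all-male population terminates with an extinction flag", {
  fo <- fixture_founders(2000)
  surf <- build_scenario_surface("no_barrier", density = "low")
  st <- initialize_population(surf, "low", fo, seed = 24)
  st$female <- rep(FALSE, st$n)
  nxt <- step_generation(st, surf, sim_config(seed = 25))
  expect_equal(nxt$n, 0)
  expect_true(nxt$extinct)
})

test_that("replicated runs are deterministic and snapshot on schedule", {
  fo <- fixture_founders(8750, seed = 45)
  surf <- build_scenario_surface("no_barrier", density = "moderate")
  cfg <- sim_config(n_generations = 10, sample_interval = 5, n_replicates = 2,
                    seed = 26)
  r1 <- run_replicates(cfg, surf, fo, keep_generations = c(0L, 5L, 10L))
  r2 <- run_replicates(cfg, surf, fo, keep_generations = c(0L, 5L, 10L))
  expect_identical(r1$census, r2$census)
  expect_equal(length(r1$snapshots), 2)
  expect_setequal(names(r1$snapshots[[1]]), c("0", "5", "10", "last"))
  expect_identical(r1$snapshots[[1]][["10"]]$G, r2$snapshots[[1]][["10"]]$G)
  # census tibble covers every generation for both replicates
  expect_equal(nrow(r1$census), 2 * 11)
})
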