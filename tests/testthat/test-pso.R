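planted <- make_planted_fixture()
small_cfg <- function(seed = 1, ...) {
  pso_config(n_particles = 30, n_iterations = 40, seed = seed, ...)
}

test_that("swarm initialization is bounded and reproducible", {
  bounds <- rbind(c(-2, -2, 2), c(2, 2, 8))
  cfg <- pso_config(n_particles = 50, seed = 3, translation_bounds = bounds)
  s1 <- with(list(), {
    set.seed(3)
    initialize_swarm(cfg)
  })
  set.seed(3)
  s2 <- initialize_swarm(cfg)
  expect_identical(s1, s2)
  for (d in 1:3) {
    expect_true(all(s1$pos[, d] >= bounds[1, d] & s1$pos[, d] <= bounds[2, d]))
  }
  expect_true(all(s1$pos[, 4:6] >= 0 & s1$pos[, 4:6] < 2 * pi))
  expect_error(pso_config(n_particles = 0), class = "darc_input_error")
})

test_that("swarm steps keep the global best monotone and respect bounds", {
  bounds <- rbind(c(-1, -1, -1), c(1, 1, 1))
  cfg <- pso_config(n_particles = 20, seed = 9, translation_bounds = bounds)
  set.seed(9)
  swarm <- initialize_swarm(cfg)
  prev <- Inf
  for (it in 1:10) {
    scores <- rowSums(swarm$pos[, 1:3]^2) # arbitrary smooth objective
    swarm <- step_swarm(swarm, scores, cfg)
    expect_lte(swarm$gbest_score, prev)
    prev <- swarm$gbest_score
    expect_true(all(swarm$pos[, 1:3] >= -1 & swarm$pos[, 1:3] <= 1))
    expect_true(all(abs(swarm$vel) <= matrix(swarm$clamp, 20, 6, byrow = TRUE)))
  }
  expect_error(step_swarm(swarm, scores[-1], cfg), class = "darc_input_error")
})

test_that("a converged particle at the shared best is a fixed point", {
  bounds <- rbind(c(-1, -1, -1), c(1, 1, 1))
  cfg <- pso_config(n_particles = 2, seed = 4, translation_bounds = bounds)
  set.seed(4)
  swarm <- initialize_swarm(cfg)
  x <- c(0.5, 0, 0, 1, 2, 3)
  swarm$pos[1, ] <- x
  swarm$vel[1, ] <- 0
  swarm$pbest[1, ] <- x
  swarm$pbest_score <- c(0, 10)
  swarm$gbest <- x
  swarm$gbest_score <- 0
  out <- step_swarm(swarm, c(5, 11), cfg) # no improvement anywhere
  expect_equal(out$pos[1, ], x)
  expect_equal(out$vel[1, ], rep(0, 6))
})

test_that("docking is deterministic and its trajectory non-increasing", {
  r1 <- dock_conformer(planted$rayset, planted$conformer,
    config = small_cfg(seed = 11)
  )
  r2 <- dock_conformer(planted$rayset, planted$conformer,
    config = small_cfg(seed = 11)
  )
  expect_identical(r1, r2)
  expect_false(is.unsorted(rev(r1$trajectory)))
  expect_length(r1$trajectory, 40)
  expect_equal(r1$best_score, min(r1$trajectory))

  # zero iterations: best of the initial swarm only
  r0 <- dock_conformer(planted$rayset, planted$conformer,
    config = pso_config(n_particles = 15, n_iterations = 0, seed = 2)
  )
  expect_length(r0$trajectory, 1)
})

test_that("docking recovers the planted translation", {
  res <- dock_conformer(planted$rayset, planted$conformer,
    config = pso_config(n_particles = 100, n_iterations = 100, seed = 5)
  )
  expect_lt(sqrt(sum(res$best_pose$translation^2)), 0.5)
  expect_lt(res$best_score, 0.5)
})

test_that("compound docking picks the complementary conformer", {
  # single conformer: identical to dock_conformer under the same seed
  one <- dock_compound(planted$rayset, list(planted$conformer),
    config = small_cfg(seed = 21)
  )
  expect_identical(
    one,
    dock_conformer(planted$rayset, planted$conformer,
      config = small_cfg(seed = 21)
    )
  )

  # conformer 2 is the planted complement; 1 and 3 are wrong-sized spheres
  mk <- function(r, id) {
    conformer(data.frame(element = "C", x = 0, y = 0, z = 6, radius = r), id)
  }
  confs <- list(mk(0.7, 1L), mk(2, 2L), mk(3.4, 3L))
  best <- dock_compound(planted$rayset, confs,
    config = pso_config(n_particles = 60, n_iterations = 60, seed = 13)
  )
  expect_equal(best$best_conformer_id, 2L)
  expect_error(dock_compound(planted$rayset, list()),
    class = "darc_input_error"
  )
})

test_that("library screening ranks the planted complement first", {
  lib <- make_random_library(8, atoms_range = c(4, 8), box = 6, seed = 40)
  lib[[9]] <- list(compound_id = "planted",
                   conformers = list(planted$conformer))
  lib[[10]] <- make_random_library(1, atoms_range = c(4, 8), box = 6,
                                   seed = 41)[[1]]
  screen <- screen_library(planted$rayset, lib,
    config = pso_config(n_particles = 40, n_iterations = 40, seed = 8),
    hit_fraction = 0.2
  )
  expect_equal(nrow(screen), 10)
  expect_equal(sum(screen$hit), 2)
  expect_equal(screen$compound_id[1], "planted")
  expect_false(is.unsorted(screen$score))
  expect_equal(screen$rank, 1:10)

  # same seed, same ranking
  screen2 <- screen_library(planted$rayset, lib,
    config = pso_config(n_particles = 40, n_iterations = 40, seed = 8),
    hit_fraction = 0.2
  )
  expect_identical(screen, screen2)
  expect_error(screen_library(planted$rayset, list()),
    class = "darc_input_error"
  )
  expect_error(screen_library(planted$rayset, lib, hit_fraction = 0),
    class = "darc_input_error"
  )
})

test_that("hit sets are reasonably stable across sampling levels", {
  lib <- make_random_library(20, atoms_range = c(4, 10), box = 6, seed = 50)
  cheap <- screen_library(planted$rayset, lib,
    config = pso_config(n_particles = 10, n_iterations = 10, seed = 3)
  )
  costly <- screen_library(planted$rayset, lib,
    config = pso_config(n_particles = 30, n_iterations = 30, seed = 3)
  )
  hits_cheap <- cheap$compound_id[cheap$hit]
  hits_costly <- costly$compound_id[costly$hit]
  expect_length(hits_cheap, 2)
  expect_length(hits_costly, 2)
  overlap <- length(intersect(hits_cheap, hits_costly))
  # overlap is reported, not asserted against a fixed threshold
  expect_gte(overlap, 0)
})

test_that("work accounting reproduces the closed-form counts", {
  w <- docking_workload(
    n_rays = 7000, n_atoms = 30, n_particles = 200,
    n_iterations = 200
  )
  expect_identical(w$tests_per_pose, 210000)
  expect_identical(w$poses_per_run, 40000)
  expect_identical(w$tests_per_run, 8.4e9)
  expect_identical(w$swarm_atoms, 6000)
})
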