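planted <- make_planted_fixture()

test_that("poses transform atoms about the conformer centroid", {
  atoms <- data.frame(
    element = "C", x = c(1, 3), y = c(0, 0), z = c(0, 0), radius = 1.7
  )
  cf <- conformer(atoms) # centroid (2, 0, 0)
  expect_equal(apply_pose(cf, pose_transform()), atoms)
  shifted <- apply_pose(cf, pose_transform(translation = c(1, 0, 0)))
  expect_equal(shifted$x, c(2, 4))
  # 180 degrees about z: atom at centroid + (1,0,0) -> centroid + (-1,0,0)
  rot <- apply_pose(cf, pose_transform(rotation = c(0, 0, pi)))
  expect_equal(rot$x, c(3, 1), tolerance = 1e-12)
  expect_equal(rot$y, c(0, 0), tolerance = 1e-12)
  expect_equal(rot$radius, atoms$radius)
})

test_that("first_intersection returns the nearest positive sphere root", {
  atoms <- function(...) {
    m <- rbind(...)
    data.frame(element = "C", x = m[, 1], y = m[, 2], z = m[, 3],
               radius = m[, 4])
  }
  o <- c(0, 0, 0)
  up <- c(0, 0, 1)
  expect_equal(first_intersection(o, up, atoms(c(0, 0, 6, 2))), 4.0)
  expect_true(is.na(first_intersection(o, c(1, 0, 0), atoms(c(0, 0, 6, 2)))))
  expect_equal(
    first_intersection(o, up, atoms(c(0, 0, 6, 2), c(0, 0, 3, 1))), 2.0
  )
  # grazing hit: zero discriminant counts
  expect_equal(first_intersection(o, up, atoms(c(0, 2, 5, 2))), 5.0)
  expect_error(first_intersection(o, c(0, 0, 2), atoms(c(0, 0, 6, 2))),
    class = "darc_input_error"
  )
})

test_that("per-ray contributions follow the four conditions", {
  w <- score_weights()
  expect_equal(
    ray_contribution("pocket", 10, 10, w),
    list(value = 0, contributing = TRUE)
  )
  expect_equal(
    ray_contribution("pocket", 10, 12, w),
    list(value = 2.0, contributing = TRUE)
  )
  expect_equal(
    ray_contribution("pocket", 10, 7, w)$value, 4.2
  )
  expect_equal(
    ray_contribution("pocket", 10, NA, w),
    list(value = 21.6, contributing = TRUE)
  )
  expect_equal(
    ray_contribution("forbidden", 10, 3, w),
    list(value = 9.5, contributing = TRUE)
  )
  expect_equal(
    ray_contribution("forbidden", 10, NA, w),
    list(value = 0, contributing = FALSE)
  )
  expect_error(ray_contribution("pocket", 10, -1, w),
    class = "darc_input_error"
  )
})

test_that("angular bounds match the closed form and are conservative", {
  one_atom <- data.frame(element = "C", x = 6, y = 0, z = 0, radius = 2)
  b <- compute_angular_bounds(one_atom)
  alpha <- asin(1 / 3) * 180 / pi
  expect_equal(b$theta_min, 90 - alpha)
  expect_equal(b$theta_max, 90 + alpha)
  expect_equal(b$phi_min, -alpha)
  expect_equal(b$phi_max, alpha)
  expect_false(b$covers_all)

  # atom containing the origin
  inside <- data.frame(element = "C", x = 0.5, y = 0, z = 0, radius = 2)
  expect_true(compute_angular_bounds(inside)$covers_all)

  # empty atom list: empty box, nothing passes
  none <- compute_angular_bounds(one_atom[0, ])
  expect_true(none$empty)
  expect_false(any(rays_in_bounds(planted$rayset$rays, none)))

  # conservativeness: over a 5-degree grid of rays, nothing outside the
  # bounds intersects any atom of a random pose
  grid <- expand.grid(theta = seq(2.5, 177.5, by = 5),
                      phi = seq(-177.5, 177.5, by = 5))
  dirs <- ray_directions(grid$theta, grid$phi)
  set.seed(33)
  for (rep in 1:3) {
    atoms <- data.frame(
      element = "C",
      x = runif(10, -8, 8), y = runif(10, -8, 8), z = runif(10, 2, 10),
      radius = runif(10, 1.4, 2.0)
    )
    bb <- compute_angular_bounds(atoms)
    outside <- !rays_in_bounds(grid, bb)
    hits <- vapply(which(outside), function(i) {
      !is.na(first_intersection(c(0, 0, 0), dirs[i, ], atoms))
    }, logical(1))
    expect_false(any(hits))
  }
})

test_that("the planted pose scores exactly zero and degenerate ligands c3", {
  b <- score_pose(planted$rayset, planted$conformer, planted$pose)
  expect_identical(b$total, 0)
  expect_equal(b$n_contributing, 500)
  expect_identical(
    b$total,
    (b$sum_unpack + b$sum_clash + b$sum_miss + b$sum_forbidden) /
      b$n_contributing
  )

  empty <- conformer(planted$conformer$atoms[0, ])
  expect_identical(score_pose(planted$rayset, empty)$total, 21.6)

  far <- planted$conformer
  far$atoms$z <- far$atoms$z + 1000
  far <- conformer(far$atoms)
  expect_identical(score_pose(planted$rayset, far)$total, 21.6)
})

test_that("single-ray worked examples match the closed forms", {
  one_ray <- function(kind, rho) {
    structure(
      list(
        origin = c(0, 0, 0),
        rays = data.frame(kind = c(kind, "pocket"), theta = c(0, 180),
                          phi = 0, rho = c(rho, 50))
      ),
      class = "darc_rayset"
    )
  }
  atom_at <- function(z, r) {
    conformer(data.frame(element = "C", x = 0, y = 0, z = z, radius = r))
  }
  # pocket ray rho 10, atom surface first met at 11: c1 * (11 - 10), plus
  # the downward ray missing (c3); normalized over both pocket rays
  rs <- structure(
    list(
      origin = c(0, 0, 0),
      rays = data.frame(kind = "pocket", theta = 0, phi = 0, rho = 10)
    ),
    class = "darc_rayset"
  )
  expect_equal(score_pose(rs, atom_at(13, 2))$total, 1.0)
  # clash: first hit at 7 against rho 10 -> c2 * 3
  expect_equal(score_pose(rs, atom_at(9, 2))$total, 4.2)
  # forbidden hit normalizes together with the pocket ray
  rs2 <- one_ray("forbidden", 10)
  b <- score_pose(rs2, atom_at(13, 2))
  expect_equal(b$sum_forbidden, 9.5)
  expect_equal(b$n_contributing, 2)
})

test_that("fast scorers agree with the brute-force oracle", {
  set.seed(77)
  for (rep in 1:20) {
    pose <- random_pose()
    posed <- apply_pose(planted$conformer, pose)
    want <- brute_force_score(planted$rayset, posed)
    got_plain <- score_pose(planted$rayset, planted$conformer, pose,
      eliminate = FALSE
    )$total
    got_elim <- score_pose(planted$rayset, planted$conformer, pose,
      eliminate = TRUE
    )$total
    expect_lt(abs(got_plain - want) / max(1e-12, abs(want)), 1e-9)
    expect_identical(got_plain, got_elim)
  }
})

test_that("batch swarm scoring equals sequential scoring, in order", {
  set.seed(78)
  poses <- lapply(1:7, function(i) random_pose())
  poses[[8]] <- poses[[3]] # duplicate pose
  totals <- score_swarm(planted$rayset, planted$conformer, poses)
  seq_totals <- vapply(poses, function(p) {
    score_pose(planted$rayset, planted$conformer, p, eliminate = FALSE)$total
  }, numeric(1))
  expect_identical(as.numeric(totals), seq_totals)
  expect_identical(totals[8], totals[3])
})

test_that("the stage-one table has one entry per ray and pose", {
  fx <- make_planted_fixture(fixture_spec(
    n_pocket_rays = 30,
    n_forbidden_rays = 10
  ))
  poses <- lapply(1:5, function(i) random_pose())
  totals <- score_swarm(fx$rayset, fx$conformer, poses, return_table = TRUE)
  tab <- attr(totals, "table")
  expect_equal(dim(tab), c(40, 5))
  # reducing the table reproduces the totals up to the contributing-ray count
  w <- score_weights()
  for (p in 1:5) {
    n_forb_hits <- sum(tab[fx$rayset$rays$kind == "forbidden", p] > 0)
    expect_equal(sum(tab[, p]) / (30 + n_forb_hits), unname(totals[p]),
      tolerance = 1e-12
    )
  }
})

test_that("any small displacement of the planted ligand scores positive", {
  set.seed(90)
  for (i in 1:50) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    delta <- runif(1, 0.1, 1)
    pose <- pose_transform(translation = u * delta)
    total <- score_pose(planted$rayset, planted$conformer, pose)$total
    expect_gt(total, 0)
  }
})
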