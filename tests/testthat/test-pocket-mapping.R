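test_that("grid dimensions follow floor(2 * extent / spacing) + 1", {
  rec <- make_toy_receptor(pit_radius = 3, slab = c(12, 12, 8))
  g <- build_grid(rec, target = c("A", 1), spacing = 0.5, extent = 10)
  expect_equal(g$dims, rep(41L, 3))
  g2 <- build_grid(rec, spacing = 1, extent = 5, center = c(0, 0, 0))
  expect_equal(g2$dims, rep(11L, 3))
  expect_error(
    build_grid(rec, target = c("B", 99)),
    class = "darc_input_error"
  )
  expect_error(
    build_grid(rec, center = c(0, 0, 0), spacing = -1),
    class = "darc_input_error"
  )
  expect_error(
    build_grid(rec, center = c(0, 0, 0), spacing = 2, extent = 1),
    class = "darc_input_error"
  )
})

test_that("classification marks points within (inclusive) atom radius", {
  protein <- structure(
    list(
      atoms = data.frame(
        element = "C", x = 0, y = 0, z = 0, radius = 2.0,
        chain = "A", resno = 1L, resid = "GLY"
      ),
      center_of_mass = c(0, 0, 0)
    ),
    class = "darc_protein"
  )
  g <- build_grid(protein, spacing = 1, extent = 3, center = c(0, 0, 0))
  g <- classify_grid(g, protein)
  p_pts <- grid_points(g, "P")
  d <- sqrt(rowSums(p_pts^2))
  # every point at distance <= 2 is P, including the boundary at exactly 2
  expect_true(all(d <= 2))
  expect_true(any(abs(d - 2) < 1e-12))
  expect_equal(sum(g$labels == 1), sum(rowSums(as.matrix(
    expand.grid(-3:3, -3:3, -3:3)
  )^2) <= 4))

  # no atoms in range: everything stays solvent
  far <- protein
  far$atoms$x <- 100
  g2 <- classify_grid(build_grid(far, spacing = 1, extent = 3,
                                 center = c(0, 0, 0)), far)
  expect_true(all(g2$labels == 0))
})

test_that("a solvent run flanked by protein becomes pocket; open ends do not", {
  # 1-D row P,S,S,S,P along x
  labels <- array(0L, dim = c(5, 3, 3))
  labels[1, 2, 2] <- 1L
  labels[5, 2, 2] <- 1L
  g <- toy_grid(labels, c(5, 3, 3))
  marked <- mark_pocket(g, max_span = 4)
  arr <- array(marked$labels, dim = c(5, 3, 3))
  expect_equal(arr[2:4, 2, 2], rep(2L, 3))
  # row P,S,S with an open end gains nothing
  labels2 <- array(0L, dim = c(3, 3, 3))
  labels2[1, 2, 2] <- 1L
  g2 <- toy_grid(labels2, c(3, 3, 3))
  expect_true(all(mark_pocket(g2, max_span = 4)$labels != 2L))
})

test_that("pocket marking matches the line-scan oracle on random grids", {
  set.seed(101)
  for (rep in 1:4) {
    dims <- c(11, 11, 11)
    labels <- as.integer(runif(prod(dims)) < 0.15)
    span <- sample(2:6, 1)
    got <- mark_pocket(toy_grid(labels, dims), max_span = span)$labels
    want <- oracle_mark_pocket(labels, dims, span)
    expect_identical(got, want)
  }
})

test_that("shell points require a protein face-neighbour", {
  # pocket point sandwiched between protein along x: it is shell;
  # a pocket point with no P face neighbour is not
  labels <- array(0L, dim = c(7, 5, 5))
  labels[1, 3, 3] <- 1L
  labels[7, 3, 3] <- 1L
  g <- mark_pocket(toy_grid(labels, c(7, 5, 5)), max_span = 6)
  pocket <- extract_shell_and_forbidden(g, largest_component = FALSE)
  # interior pocket points (x index 3..5) have no P face neighbour
  expect_equal(nrow(pocket$shell_points), 2)
  expect_true(all(pocket$shell_points[, 1] %in% c(1, 5)))
})

test_that("label partition is preserved through every stage", {
  rec <- make_toy_receptor(pit_radius = 4, slab = c(16, 16, 10))
  pc <- attr(rec, "pit_center")
  g <- build_grid(rec, center = pc, spacing = 0.5, extent = 7)
  n <- prod(g$dims)
  g <- classify_grid(g, rec)
  expect_equal(sum(g$labels %in% 0:1), n)
  g <- mark_pocket(g)
  expect_equal(sum(g$labels %in% 0:2), n)
  pocket <- extract_shell_and_forbidden(g)
  expect_equal(sum(pocket$grid$labels %in% 0:4), n)
  expect_gt(sum(pocket$grid$labels == 3), 0)
})

test_that("toy receptor shell hugs the analytic pit surface", {
  rec <- make_toy_receptor(pit_radius = 4, slab = c(16, 16, 10))
  pc <- attr(rec, "pit_center")
  spacing <- 0.5
  pocket <- map_pocket(rec, center = pc, spacing = spacing, extent = 7)
  d <- sqrt(rowSums(sweep(pocket$shell_points, 2, pc)^2))
  expect_gt(nrow(pocket$shell_points), 50)
  expect_lt(max(abs(d - 4)), spacing * sqrt(3))
  # shell and forbidden sets are disjoint
  sh <- apply(pocket$shell_points, 1, paste, collapse = ",")
  fb <- apply(pocket$forbidden_points, 1, paste, collapse = ",")
  expect_length(intersect(sh, fb), 0)
})

test_that("a flat receptor has no pocket", {
  rec <- make_toy_receptor(pit_radius = 0, slab = c(12, 12, 8))
  g <- mark_pocket(classify_grid(
    build_grid(rec, center = c(0, 0, 4), spacing = 0.5, extent = 5), rec
  ))
  expect_error(extract_shell_and_forbidden(g), class = "darc_no_pocket")
})

test_that("the ray origin sits offset Angstroms towards the protein COM", {
  pocket <- structure(
    list(
      shell_points = matrix(c(0, 0, 10), 1),
      forbidden_points = matrix(numeric(0), 0, 3), origin = NULL
    ),
    class = "darc_pocket"
  )
  protein <- structure(list(center_of_mass = c(0, 0, 0)),
    class = "darc_protein"
  )
  out <- compute_ray_origin(pocket, protein, offset = 30)
  expect_equal(out$origin, c(0, 0, -20))
  expect_equal(compute_ray_origin(pocket, protein, offset = 0)$origin,
    c(0, 0, 10))
  coincident <- structure(list(center_of_mass = c(0, 0, 10)),
    class = "darc_protein"
  )
  expect_error(
    compute_ray_origin(pocket, coincident),
    class = "darc_geometry_error"
  )
})
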