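#' Specification for a planted analytic fixture
#'
#' Defines a synthetic pocket whose rays are, by construction, exactly
#' complementary to a single-sphere ligand of radius `ligand_radius`
#' centered `center_distance` Angstroms from the ray origin along +z:
#' every pocket ray's stored distance is the analytic first-hit distance on
#' that sphere, so the planted pose scores exactly zero. The cone half-angle
#' must not exceed `asin(ligand_radius / center_distance)` or rays near the
#' cone edge would miss the sphere.
#'
#' @param n_pocket_rays number of pocket rays (>= 1).
#' @param n_forbidden_rays number of forbidden rays (>= 0).
#' @param center_distance D, ligand center distance from origin, Angstroms.
#' @param ligand_radius r, ligand sphere radius, Angstroms (r < D).
#' @param cone_half_angle pocket-ray cone half-angle about +z, degrees.
#' @param seed RNG seed recorded with the fixture.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(n_pocket_rays = 500, n_forbidden_rays = 50,
                         center_distance = 6, ligand_radius = 2,
                         cone_half_angle = 15, seed = 1) {
  if (ligand_radius <= 0 || center_distance <= ligand_radius) {
    darc_input_error("need center_distance > ligand_radius > 0")
  }
  if (n_pocket_rays < 1 || n_forbidden_rays < 0) {
    darc_input_error("ray counts out of range")
  }
  if (cone_half_angle <= 0 || cone_half_angle >= 90) {
    darc_input_error("cone_half_angle must lie in (0, 90) degrees")
  }
  structure(
    list(
      n_pocket_rays = as.integer(n_pocket_rays),
      n_forbidden_rays = as.integer(n_forbidden_rays),
      center_distance = center_distance, ligand_radius = ligand_radius,
      cone_half_angle = cone_half_angle, seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

# Deterministic, evenly spread directions on the spherical band
# cos(theta) in [z_min, z_max] (Fibonacci / golden-angle sampling).
fibonacci_band <- function(n, z_min, z_max) {
  i <- seq_len(n)
  z <- z_max - (i - 0.5) / n * (z_max - z_min)
  golden <- pi * (3 - sqrt(5))
  az <- (i - 1) * golden
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(az), s * sin(az), z)
}

#' Generate a planted pocket/ligand fixture
#'
#' The rayset origin sits at (0, 0, 0) and the ligand is a single carbon
#' sphere of radius r at (0, 0, D). Pocket rays are Fibonacci-sampled in a
#' cone about +z with rho equal to the analytic first-hit distance
#' `t(u) = (u . c) - sqrt((u . c)^2 - D^2 + r^2)`; forbidden rays sample a
#' band outside the cone chosen so they are guaranteed to miss the planted
#' ligand. The planted pose is the identity and scores exactly 0.
#'
#' @param spec a [fixture_spec()].
#' @return List with `rayset`, `conformer`, `pose` (the planted pose) and
#'   `spec`.
#' @export
make_planted_fixture <- function(spec = fixture_spec()) {
  D <- spec$center_distance
  r <- spec$ligand_radius
  max_half <- asin(r / D) * 180 / pi
  dirs0 <- fibonacci_band(
    spec$n_pocket_rays,
    cos(spec$cone_half_angle * pi / 180), 1
  )
  sph <- cartesian_to_spherical(dirs0)
  # re-derive directions from the stored angles with the scorer's own
  # helper, then compute rho with the scorer's arithmetic ordering, so the
  # planted pose scores exactly zero in floating point
  u <- ray_directions(sph$theta, sph$phi)
  b <- u[, 3] * D
  disc <- b * b - (D * D - r * r)
  if (any(disc < 0)) {
    darc_input_error(sprintf(
      "cone half-angle %.2f deg too wide for a guaranteed hit (max %.2f)",
      spec$cone_half_angle, max_half
    ))
  }
  rho <- b - sqrt(disc)
  pocket <- data.frame(
    kind = "pocket", theta = sph$theta, phi = sph$phi, rho = rho,
    stringsAsFactors = FALSE
  )
  rays <- pocket
  if (spec$n_forbidden_rays > 0) {
    lo <- min(max_half + 3, 178)
    hi <- min(lo + 15, 179)
    fdir <- fibonacci_band(
      spec$n_forbidden_rays,
      cos(hi * pi / 180), cos(lo * pi / 180)
    )
    fsph <- cartesian_to_spherical(fdir)
    rays <- rbind(rays, data.frame(
      kind = "forbidden", theta = fsph$theta, phi = fsph$phi, rho = D,
      stringsAsFactors = FALSE
    ))
  }
  atoms <- data.frame(
    element = "C", x = 0, y = 0, z = D, radius = r,
    stringsAsFactors = FALSE
  )
  list(
    rayset = new_rayset(c(0, 0, 0), rays),
    conformer = conformer(atoms, 1L),
    pose = pose_transform(),
    spec = spec
  )
}

#' Generate a random decoy compound library
#'
#' Compounds are random rigid multi-sphere "molecules": each has 1-3
#' conformers sharing atom count and radii (radii uniform in [1.4, 2.0]
#' Angstroms), with conformer coordinates drawn independently inside a cube
#' of side `box`. Reproducible given `seed`.
#'
#' @param n number of compounds (>= 1).
#' @param atoms_range `c(min, max)` heavy atoms per compound.
#' @param box cube side length in Angstroms.
#' @param seed RNG seed.
#' @return List of compounds, each a list with `compound_id` and
#'   `conformers`.
#' @export
make_random_library <- function(n, atoms_range = c(8, 30), box = 8,
                                seed = 1) {
  if (n < 1) darc_input_error("library size must be >= 1")
  if (length(atoms_range) != 2 || atoms_range[1] < 1 ||
    atoms_range[1] > atoms_range[2]) {
    darc_input_error("degenerate atoms_range")
  }
  if (box <= 0) darc_input_error("box must be positive")
  with_seed(seed, {
    lapply(seq_len(n), function(j) {
      n_atoms <- if (atoms_range[1] == atoms_range[2]) {
        atoms_range[1]
      } else {
        sample(atoms_range[1]:atoms_range[2], 1)
      }
      radii <- runif(n_atoms, 1.4, 2.0)
      n_conf <- sample(1:3, 1)
      confs <- lapply(seq_len(n_conf), function(k) {
        atoms <- data.frame(
          element = "C",
          x = runif(n_atoms, -box / 2, box / 2),
          y = runif(n_atoms, -box / 2, box / 2),
          z = runif(n_atoms, -box / 2, box / 2),
          radius = radii, stringsAsFactors = FALSE
        )
        conformer(atoms, k)
      })
      list(compound_id = sprintf("cmpd%04d", j), conformers = confs)
    })
  })
}

#' Generate a toy receptor: a slab with a hemispherical pit
#'
#' A slab of overlapping pseudo-atoms on a cubic lattice with a
#' hemispherical pit carved into the center of its top face. Atoms whose
#' spheres would intrude into the pit ball are removed (centers closer than
#' `pit_radius + atom_radius` to the pit center), so the analytic
#' solvent-protein boundary inside the pit is the hemisphere of radius
#' `pit_radius` itself -- which makes the pit surface an exact oracle for
#' the extracted pocket shell. The default lattice constant and pseudo-atom
#' radius are chosen so the envelope of the atom spheres is smooth at the
#' default grid resolution (larger pseudo-atoms bulge above the slab face
#' and widen the pit mouth beyond the hemisphere). The pit center is
#' attached as attribute `"pit_center"`.
#'
#' @param pit_radius pit radius in Angstroms (0 for no pit).
#' @param slab slab dimensions `c(x, y, z)` in Angstroms.
#' @param lattice pseudo-atom lattice constant in Angstroms.
#' @param atom_radius pseudo-atom radius in Angstroms.
#' @return A `darc_protein` (single chain A, single residue 1).
#' @export
make_toy_receptor <- function(pit_radius = 6, slab = c(24, 24, 16),
                              lattice = 0.5, atom_radius = 0.9) {
  if (pit_radius > slab[3] / 2) {
    darc_input_error("pit_radius must not exceed the slab half-depth")
  }
  gx <- seq(-slab[1] / 2, slab[1] / 2, by = lattice)
  gy <- seq(-slab[2] / 2, slab[2] / 2, by = lattice)
  gz <- seq(-slab[3] / 2, slab[3] / 2, by = lattice)
  centers <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  pit_center <- c(0, 0, max(gz))
  if (pit_radius > 0) {
    d2 <- (centers[, 1] - pit_center[1])^2 +
      (centers[, 2] - pit_center[2])^2 +
      (centers[, 3] - pit_center[3])^2
    centers <- centers[d2 >= (pit_radius + atom_radius)^2, , drop = FALSE]
  }
  atoms <- data.frame(
    element = "C", x = centers[, 1], y = centers[, 2], z = centers[, 3],
    radius = atom_radius, chain = "A", resno = 1L, resid = "SLB",
    stringsAsFactors = FALSE
  )
  p <- new_protein(atoms)
  attr(p, "pit_center") <- pit_center
  attr(p, "pit_radius") <- pit_radius
  p
}

#' Independent brute-force pose score (testing oracle)
#'
#' Plain-R triple loop over rays, atoms and quadratic roots, with no ray
#' elimination and no batching: for every ray the first ligand intersection
#' is found by scanning all atoms, its contribution accumulated by the four
#' conditions, and the total normalized by the number of contributing rays.
#' Serves as the reference the fast scorers are checked against.
#'
#' @param rayset a `darc_rayset`.
#' @param atoms posed atom data frame (x, y, z, radius).
#' @param w a [score_weights()] vector.
#' @return The normalized total score.
#' @export
brute_force_score <- function(rayset, atoms, w = score_weights()) {
  rays <- rayset$rays
  o <- rayset$origin
  sum_unpack <- 0
  sum_clash <- 0
  n_miss <- 0L
  n_forbidden_hit <- 0L
  n_pocket <- 0L
  for (i in seq_len(nrow(rays))) {
    t_rad <- rays$theta[i] * pi / 180
    p_rad <- rays$phi[i] * pi / 180
    u <- c(sin(t_rad) * cos(p_rad), sin(t_rad) * sin(p_rad), cos(t_rad))
    d <- -1
    for (a in seq_len(nrow(atoms))) {
      mx <- atoms$x[a] - o[1]
      my <- atoms$y[a] - o[2]
      mz <- atoms$z[a] - o[3]
      b <- u[1] * mx + u[2] * my + u[3] * mz
      mm <- mx * mx + my * my + mz * mz
      disc <- b * b - (mm - atoms$radius[a]^2)
      if (disc < 0) next
      s <- sqrt(disc)
      t <- b - s
      if (t <= 0) t <- b + s
      if (t > 0 && (d < 0 || t < d)) d <- t
    }
    if (rays$kind[i] == "pocket") {
      n_pocket <- n_pocket + 1L
      if (d < 0) {
        n_miss <- n_miss + 1L
      } else if (d >= rays$rho[i]) {
        sum_unpack <- sum_unpack + w["c1"] * (d - rays$rho[i])
      } else {
        sum_clash <- sum_clash + w["c2"] * (rays$rho[i] - d)
      }
    } else if (d >= 0) {
      n_forbidden_hit <- n_forbidden_hit + 1L
    }
  }
  n_contrib <- n_pocket + n_forbidden_hit
  unname((sum_unpack + sum_clash + n_miss * w["c3"] +
    n_forbidden_hit * w["c4"]) / n_contrib)
}
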