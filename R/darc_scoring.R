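#' Score weights for the four ray conditions
#'
#' `c1` weighs unpacking (the ray reaches the pocket wall before the
#' ligand), `c2` weighs steric clash (ligand hit before the wall), `c3` is
#' the flat penalty for a pocket ray that misses the ligand entirely, and
#' `c4` the flat penalty for a forbidden ray that hits it. Defaults are
#' 1.0, 1.4, 21.6 and 9.5.
#'
#' @param c1,c2,c3,c4 non-negative constants.
#' @return A named numeric vector of class `score_weights`.
#' @export
score_weights <- function(c1 = 1.0, c2 = 1.4, c3 = 21.6, c4 = 9.5) {
  w <- c(c1 = c1, c2 = c2, c3 = c3, c4 = c4)
  if (any(w < 0)) darc_input_error("score weights must be non-negative")
  structure(w, class = "score_weights")
}

#' Rigid-body pose
#'
#' A pose is a rotation about the conformer centroid (ZYX Euler angles,
#' radians, applied as Rz(rz) Ry(ry) Rx(rx)) followed by a translation in
#' Angstroms.
#'
#' @param translation 3-vector, Angstroms.
#' @param rotation 3 angles (rx, ry, rz), radians.
#' @return A `pose_transform`.
#' @export
pose_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, length(rotation) == 3)
  structure(
    list(
      translation = as.numeric(translation),
      rotation = as.numeric(rotation)
    ),
    class = "pose_transform"
  )
}

as_pose_vector <- function(pose) {
  if (inherits(pose, "pose_transform")) {
    return(c(pose$translation, pose$rotation))
  }
  if (is.numeric(pose) && length(pose) == 6) {
    return(as.numeric(pose))
  }
  darc_input_error("pose must be a pose_transform or a 6-vector")
}

#' Apply a pose to a conformer
#'
#' Atoms are rotated about the conformer centroid, then translated; radii
#' are unchanged. Shares its transform kernel with the batch scorer so both
#' paths place atoms identically.
#'
#' @param conformer a `darc_conformer`.
#' @param pose a `pose_transform` (or 6-vector `c(t, r)`).
#' @return The conformer's atom data frame with transformed coordinates.
#' @export
apply_pose <- function(conformer, pose) {
  atoms <- conformer$atoms
  if (nrow(atoms) == 0) return(atoms)
  xyz <- transform_atoms_cpp(
    as.matrix(atoms[, c("x", "y", "z")]),
    as_pose_vector(pose), conformer$centroid
  )
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms
}

#' First ray-sphere intersection distance
#'
#' Smallest positive root over all atoms of
#' `t^2 - 2 t (u . (c - o)) + |c - o|^2 - r^2 = 0`; tangency (zero
#' discriminant) counts as a hit.
#'
#' @param origin ray origin, 3-vector.
#' @param direction unit 3-vector.
#' @param atoms data frame with x, y, z, radius.
#' @return The distance in Angstroms, or `NA_real_` when no atom is hit.
#' @export
first_intersection <- function(origin, direction, atoms) {
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-6) {
    darc_input_error("direction must be a unit vector")
  }
  if (nrow(atoms) == 0) return(NA_real_)
  d <- first_hit_r(origin, direction, atoms)
  if (d < 0) NA_real_ else d
}

# R mirror of the C++ inner loop (used by first_intersection so the
# documented operation works without constructing a rayset).
first_hit_r <- function(origin, u, atoms) {
  best <- -1
  for (i in seq_len(nrow(atoms))) {
    mx <- atoms$x[i] - origin[1]
    my <- atoms$y[i] - origin[2]
    mz <- atoms$z[i] - origin[3]
    b <- u[1] * mx + u[2] * my + u[3] * mz
    mm <- mx * mx + my * my + mz * mz
    disc <- b * b - (mm - atoms$radius[i]^2)
    if (disc < 0) next
    s <- sqrt(disc)
    t <- b - s
    if (t <= 0) t <- b + s
    if (t > 0 && (best < 0 || t < best)) best <- t
  }
  best
}

#' Contribution of a single ray to the pose score
#'
#' Pocket ray with a ligand hit: `c1 * (d - rho)` when the ray reaches the
#' wall first (unpacking), `c2 * (rho - d)` when it hits the ligand first
#' (clash). Pocket ray with no hit: `c3`. Forbidden ray with a hit: `c4`.
#' Forbidden ray with no hit contributes nothing and is excluded from the
#' normalization count.
#'
#' @param kind "pocket" or "forbidden".
#' @param rho stored ray-pocket distance, Angstroms.
#' @param d_lig first ray-ligand intersection distance, or `NA` for a miss.
#' @param w a [score_weights()] vector.
#' @return List with `value` and `contributing`.
#' @export
ray_contribution <- function(kind, rho, d_lig, w = score_weights()) {
  if (!is.na(d_lig) && d_lig <= 0) {
    darc_input_error("d_lig must be positive when present")
  }
  if (kind == "pocket") {
    if (is.na(d_lig)) {
      return(list(value = unname(w["c3"]), contributing = TRUE))
    }
    v <- if (d_lig >= rho) w["c1"] * (d_lig - rho) else w["c2"] * (rho - d_lig)
    return(list(value = unname(v), contributing = TRUE))
  }
  if (is.na(d_lig)) {
    return(list(value = 0, contributing = FALSE))
  }
  list(value = unname(w["c4"]), contributing = TRUE)
}

#' Conservative angular bounds for ray elimination
#'
#' For each posed atom at distance `d` from the origin the set of ray
#' directions that can intersect it is a spherical cap of half-angle
#' `asin(r / d)` about the atom direction. The returned theta/phi box is
#' the union of the exact bounding boxes of these caps: every ray outside
#' the box is guaranteed to miss the ligand. `covers_all` is set when an
#' atom contains the origin or a cap reaches a pole, in which case no ray
#' may be eliminated. An empty atom list yields an empty box (no ray
#' passes).
#'
#' @param atoms posed atom data frame (x, y, z, radius).
#' @param origin ray origin, 3-vector.
#' @return List with `theta_min`, `theta_max`, `phi_min`, `phi_max`
#'   (degrees), `covers_all`, `empty`.
#' @export
compute_angular_bounds <- function(atoms, origin = c(0, 0, 0)) {
  empty_bounds <- list(
    theta_min = NA_real_, theta_max = NA_real_,
    phi_min = NA_real_, phi_max = NA_real_,
    covers_all = FALSE, empty = TRUE
  )
  if (nrow(atoms) == 0) return(empty_bounds)
  m <- cbind(
    atoms$x - origin[1], atoms$y - origin[2],
    atoms$z - origin[3]
  )
  d <- sqrt(rowSums(m^2))
  if (any(d <= atoms$radius)) {
    return(list(
      theta_min = 0, theta_max = 180, phi_min = -180, phi_max = 180,
      covers_all = TRUE, empty = FALSE
    ))
  }
  alpha <- asin(pmin(1, atoms$radius / d)) * 180 / pi
  theta_a <- acos(pmin(1, pmax(-1, m[, 3] / d))) * 180 / pi
  theta_lo <- theta_a - alpha
  theta_hi <- theta_a + alpha
  if (any(theta_lo <= 1e-9) || any(theta_hi >= 180 - 1e-9)) {
    return(list(
      theta_min = 0, theta_max = 180, phi_min = -180, phi_max = 180,
      covers_all = TRUE, empty = FALSE
    ))
  }
  phi_a <- atan2(m[, 2], m[, 1]) * 180 / pi
  # exact longitude extent of a spherical cap away from the poles
  beta <- asin(pmin(1, sin(alpha * pi / 180) / sin(theta_a * pi / 180))) *
    180 / pi
  phi_lo <- phi_a - beta
  phi_hi <- phi_a + beta
  if (any(phi_lo < -180) || any(phi_hi > 180)) {
    phi_lo <- -180
    phi_hi <- 180
  }
  list(
    theta_min = min(theta_lo), theta_max = max(theta_hi),
    phi_min = min(phi_lo), phi_max = max(phi_hi),
    covers_all = FALSE, empty = FALSE
  )
}

#' Which rays survive angular-bounds elimination
#'
#' @param rays ray data frame (theta, phi columns, degrees).
#' @param bounds result of [compute_angular_bounds()].
#' @return Logical vector: TRUE for rays that may intersect the ligand.
#' @export
rays_in_bounds <- function(rays, bounds) {
  if (bounds$empty) return(rep(FALSE, nrow(rays)))
  if (bounds$covers_all) return(rep(TRUE, nrow(rays)))
  rays$theta >= bounds$theta_min & rays$theta <= bounds$theta_max &
    rays$phi >= bounds$phi_min & rays$phi <= bounds$phi_max
}

new_score_breakdown <- function(res) {
  structure(
    list(
      total = res$total,
      sum_unpack = res$sum_unpack, sum_clash = res$sum_clash,
      sum_miss = res$sum_miss, sum_forbidden = res$sum_forbidden,
      n_contributing = res$n_contributing,
      n_miss = res$n_miss, n_forbidden_hit = res$n_forbidden_hit
    ),
    class = "score_breakdown"
  )
}

#' Score a ligand pose against a rayset
#'
#' Casts every ray at the posed ligand, converts first-intersection
#' distances to per-ray contributions, and normalizes by the number of
#' contributing rays (all pocket rays plus forbidden rays that hit). With
#' `eliminate = TRUE`, rays outside the pose's conservative angular bounds
#' skip the intersection tests and are treated as misses; because the
#' bounds are conservative the result is identical to the unpruned score.
#'
#' @param rayset a `darc_rayset`.
#' @param conformer a `darc_conformer` (may have zero atoms).
#' @param pose a `pose_transform` (default: identity).
#' @param w a [score_weights()] vector.
#' @param eliminate use angular-bounds ray elimination.
#' @return A `score_breakdown` (total plus per-condition sums and counts).
#' @export
score_pose <- function(rayset, conformer, pose = pose_transform(),
                       w = score_weights(), eliminate = TRUE) {
  atoms <- apply_pose(conformer, pose)
  rays <- rayset$rays
  dirs <- ray_directions(rays$theta, rays$phi)
  keep <- if (eliminate && nrow(atoms) > 0) {
    rays_in_bounds(rays, compute_angular_bounds(atoms, rayset$origin))
  } else {
    rep(TRUE, nrow(rays))
  }
  res <- score_rays_cpp(
    dirs, rays$rho, rays$kind == "forbidden", keep,
    as.matrix(atoms[, c("x", "y", "z"), drop = FALSE]),
    atoms$radius %||% numeric(0),
    rayset$origin, unclass(w)
  )
  new_score_breakdown(res)
}

#' Score many poses of one conformer in two stages
#'
#' Batch scorer mirroring the decomposition used for massively parallel
#' execution: stage one fills the ray-by-pose contribution table (no ray
#' elimination, so every table entry follows the same branch-free code
#' path); stage two reduces each column to a normalized total. Totals are
#' identical to calling [score_pose()] per pose without elimination.
#'
#' @param rayset a `darc_rayset`.
#' @param conformer a `darc_conformer`.
#' @param poses list of `pose_transform`s or an n x 6 matrix of pose
#'   vectors.
#' @param w a [score_weights()] vector.
#' @param return_table also return the stage-one ray x pose contribution
#'   table as attribute `"table"`.
#' @return Numeric vector of totals in input order.
#' @export
score_swarm <- function(rayset, conformer, poses, w = score_weights(),
                        return_table = FALSE) {
  if (is.list(poses) && !is.data.frame(poses)) {
    poses <- do.call(rbind, lapply(poses, as_pose_vector))
  }
  poses <- as.matrix(poses)
  if (ncol(poses) != 6 || nrow(poses) == 0) {
    darc_input_error("poses must be a non-empty list of 6-dim poses")
  }
  rays <- rayset$rays
  atoms <- conformer$atoms
  res <- score_swarm_cpp(
    ray_directions(rays$theta, rays$phi), rays$rho,
    rays$kind == "forbidden",
    as.matrix(atoms[, c("x", "y", "z"), drop = FALSE]),
    atoms$radius %||% numeric(0),
    conformer$centroid, poses, rayset$origin, unclass(w), return_table
  )
  totals <- as.numeric(res$totals)
  if (return_table) attr(totals, "table") <- res$table
  totals
}

#' Write pose score breakdowns as TSV
#'
#' @param breakdowns a `score_breakdown` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_score_tsv <- function(breakdowns, path) {
  if (inherits(breakdowns, "score_breakdown")) breakdowns <- list(breakdowns)
  df <- do.call(rbind, lapply(seq_along(breakdowns), function(i) {
    b <- breakdowns[[i]]
    data.frame(
      pose = i, total = b$total, sum_unpack = b$sum_unpack,
      sum_clash = b$sum_clash, sum_miss = b$sum_miss,
      sum_forbidden = b$sum_forbidden, n_contributing = b$n_contributing
    )
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<score_breakdown> total %.4f  (unpack %.3f, clash %.3f, miss %.3f,",
      " forbidden %.3f; %d contributing rays)\n"
    ),
    x$total, x$sum_unpack, x$sum_clash, x$sum_miss, x$sum_forbidden,
    x$n_contributing
  ))
  invisible(x)
}
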