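#' Particle swarm optimizer configuration
#'
#' Defaults follow common constriction-coefficient PSO practice
#' (chi = 0.7298, cognitive = social = 2.05) with 200 particles and 200
#' iterations -- the typical-use sampling level at which the docking score
#' is well converged. Velocities are clamped to `v_clamp` times the search
#' range per dimension. Translation bounds default to the pocket shell
#' bounding box padded by 2 Angstroms (derived from the rayset at dock
#' time).
#'
#' @param n_particles swarm size (>= 1).
#' @param n_iterations evaluation/update sweeps (>= 0; 0 degenerates to a
#'   single evaluation of the initial swarm).
#' @param chi constriction factor in (0, 1].
#' @param c_p,c_g cognitive and social acceleration weights.
#' @param v_clamp velocity clamp as a fraction of each dimension's range.
#' @param seed RNG seed; every run is reproducible given the seed.
#' @param translation_bounds optional 2 x 3 matrix (rows: lower, upper) of
#'   translation bounds in Angstroms.
#' @return A `pso_config`.
#' @export
pso_config <- function(n_particles = 200, n_iterations = 200, chi = 0.7298,
                       c_p = 2.05, c_g = 2.05, v_clamp = 0.5, seed = 1,
                       translation_bounds = NULL) {
  if (n_particles < 1) darc_input_error("n_particles must be >= 1")
  if (n_iterations < 0) darc_input_error("n_iterations must be >= 0")
  if (chi <= 0 || chi > 1) darc_input_error("chi must lie in (0, 1]")
  structure(
    list(
      n_particles = as.integer(n_particles),
      n_iterations = as.integer(n_iterations),
      chi = chi, c_p = c_p, c_g = c_g, v_clamp = v_clamp,
      seed = as.integer(seed), translation_bounds = translation_bounds
    ),
    class = "pso_config"
  )
}

# Default translation search region: bounding box of the pocket-ray surface
# points (origin + rho * direction), padded 2 A, shifted so that a zero
# translation leaves the conformer centroid where it is.
default_translation_bounds <- function(rayset, conformer, pad = 2) {
  rays <- rayset$rays[rayset$rays$kind == "pocket", ]
  pts <- spherical_to_cartesian(rays$theta, rays$phi, rays$rho, rayset$origin)
  lo <- apply(pts, 2, min) - pad - conformer$centroid
  hi <- apply(pts, 2, max) + pad - conformer$centroid
  rbind(lo, hi)
}

#' Initialize a particle swarm
#'
#' Particle states are 6-vectors (tx, ty, tz, rx, ry, rz): translations
#' uniform within the configured bounds, rotation angles uniform in
#' [0, 2 pi), velocities uniform within the clamp. Consumes the current RNG
#' stream, so results are reproducible under a fixed seed.
#'
#' @param config a `pso_config` with `translation_bounds` set.
#' @return A `darc_swarm`.
#' @export
initialize_swarm <- function(config) {
  b <- config$translation_bounds
  if (is.null(b)) darc_input_error("translation_bounds must be set")
  n <- config$n_particles
  lo <- c(b[1, ], 0, 0, 0)
  hi <- c(b[2, ], 2 * pi, 2 * pi, 2 * pi)
  clamp <- config$v_clamp * (hi - lo)
  pos <- vapply(1:6, function(d) runif(n, lo[d], hi[d]), numeric(n))
  vel <- vapply(1:6, function(d) runif(n, -clamp[d], clamp[d]), numeric(n))
  pos <- matrix(pos, nrow = n)
  vel <- matrix(vel, nrow = n)
  structure(
    list(
      pos = pos, vel = vel,
      pbest = pos, pbest_score = rep(Inf, n),
      gbest = pos[1, ], gbest_score = Inf,
      lo = lo, hi = hi, clamp = clamp
    ),
    class = "darc_swarm"
  )
}

#' One particle swarm update step
#'
#' Updates personal and global bests from the supplied scores (strict
#' improvement only; ties keep the incumbent), then moves every particle:
#' `v <- chi * (v + c_p r1 (pbest - x) + c_g r2 (gbest - x))`, velocities
#' clamped, `x <- x + v`; rotation dimensions wrap modulo 2 pi and
#' translations are clipped to the bounds with the velocity zeroed on the
#' clipped dimension.
#'
#' @param swarm a `darc_swarm`.
#' @param scores numeric vector of totals aligned with the swarm.
#' @param config the `pso_config`.
#' @return The updated swarm.
#' @export
step_swarm <- function(swarm, scores, config) {
  n <- nrow(swarm$pos)
  if (length(scores) != n) {
    darc_input_error("scores length does not match swarm size")
  }
  improved <- scores < swarm$pbest_score
  swarm$pbest[improved, ] <- swarm$pos[improved, , drop = FALSE]
  swarm$pbest_score[improved] <- scores[improved]
  i <- which.min(swarm$pbest_score)
  if (swarm$pbest_score[i] < swarm$gbest_score) {
    swarm$gbest <- swarm$pbest[i, ]
    swarm$gbest_score <- swarm$pbest_score[i]
  }

  r1 <- matrix(runif(n * 6), n, 6)
  r2 <- matrix(runif(n * 6), n, 6)
  gb <- matrix(swarm$gbest, n, 6, byrow = TRUE)
  v <- config$chi * (swarm$vel +
    config$c_p * r1 * (swarm$pbest - swarm$pos) +
    config$c_g * r2 * (gb - swarm$pos))
  clamp <- matrix(swarm$clamp, n, 6, byrow = TRUE)
  v <- pmin(pmax(v, -clamp), clamp)
  x <- swarm$pos + v
  x[, 4:6] <- x[, 4:6] %% (2 * pi)
  for (d in 1:3) {
    below <- x[, d] < swarm$lo[d]
    above <- x[, d] > swarm$hi[d]
    x[below, d] <- swarm$lo[d]
    x[above, d] <- swarm$hi[d]
    v[below | above, d] <- 0
  }
  swarm$pos <- x
  swarm$vel <- v
  swarm
}

new_dock_result <- function(gbest, gbest_score, conformer_id, trajectory) {
  structure(
    list(
      best_pose = pose_transform(gbest[1:3], gbest[4:6]),
      best_score = gbest_score,
      best_conformer_id = conformer_id,
      trajectory = trajectory
    ),
    class = "dock_result"
  )
}

#' Dock one rigid conformer by particle swarm optimization
#'
#' Each iteration scores the whole swarm with the two-stage batch scorer,
#' updates personal/global bests, and moves the particles; the evaluation of
#' the initial swarm counts as the first iteration, so a run performs
#' `n_particles * n_iterations` pose evaluations. The global-best trajectory
#' is non-increasing by construction, and the whole run is deterministic
#' given `config$seed`.
#'
#' @param rayset a `darc_rayset`.
#' @param conformer a `darc_conformer`.
#' @param weights a [score_weights()] vector.
#' @param config a [pso_config()].
#' @return A `dock_result`: best pose and score, conformer id, and the
#'   per-iteration global-best trajectory.
#' @export
dock_conformer <- function(rayset, conformer, weights = score_weights(),
                           config = pso_config()) {
  if (is.null(config$translation_bounds)) {
    config$translation_bounds <- default_translation_bounds(rayset, conformer)
  }
  with_seed(config$seed, {
    swarm <- initialize_swarm(config)
    n_pass <- max(1L, config$n_iterations)
    trajectory <- numeric(n_pass)
    for (it in seq_len(n_pass)) {
      scores <- score_swarm(rayset, conformer, swarm$pos, weights)
      swarm <- step_swarm(swarm, scores, config)
      trajectory[it] <- swarm$gbest_score
    }
    new_dock_result(
      swarm$gbest, swarm$gbest_score, conformer$conformer_id,
      trajectory
    )
  })
}

#' Dock a compound: best pose over all of its conformers
#'
#' Conformers are docked independently and sequentially (the per-conformer
#' seed is offset by the conformer ordinal, so a single-conformer compound
#' reproduces [dock_conformer()] exactly); the lowest best score wins.
#'
#' @param rayset a `darc_rayset`.
#' @param conformers non-empty list of `darc_conformer`s.
#' @param weights a [score_weights()] vector.
#' @param config a [pso_config()].
#' @return A `dock_result` carrying the winning conformer's id.
#' @export
dock_compound <- function(rayset, conformers, weights = score_weights(),
                          config = pso_config()) {
  if (inherits(conformers, "darc_conformer")) conformers <- list(conformers)
  if (length(conformers) == 0) darc_input_error("no conformers supplied")
  best <- NULL
  for (i in seq_along(conformers)) {
    cfg <- config
    cfg$seed <- config$seed + (i - 1L)
    res <- dock_conformer(rayset, conformers[[i]], weights, cfg)
    if (is.null(best) || res$best_score < best$best_score) best <- res
  }
  best
}

#' Screen a compound library and mark hits
#'
#' Docks every compound with [dock_compound()] (per-compound seed offset by
#' 1000 times the compound ordinal for independent streams), ranks
#' ascending by best score (ties broken by input order), and flags the best
#' `hit_fraction` (default the top 10%) as hits.
#'
#' @param rayset a `darc_rayset`.
#' @param library list of compounds, each a list with `compound_id` and
#'   `conformers` (as produced by [make_random_library()]).
#' @param weights a [score_weights()] vector.
#' @param config a [pso_config()].
#' @param hit_fraction proportion of the library to call hits (0, 1].
#' @return Data frame (class `darc_screen`) with compound_id, conformer_id,
#'   score, pose columns (tx..rz), rank and hit flag, sorted by rank.
#' @export
screen_library <- function(rayset, library, weights = score_weights(),
                           config = pso_config(), hit_fraction = 0.1) {
  if (length(library) == 0) darc_input_error("empty compound library")
  if (hit_fraction <= 0 || hit_fraction > 1) {
    darc_input_error("hit_fraction must lie in (0, 1]")
  }
  rows <- vector("list", length(library))
  for (j in seq_along(library)) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * (j - 1L)
    res <- dock_compound(rayset, library[[j]]$conformers, weights, cfg)
    p <- as_pose_vector(res$best_pose)
    rows[[j]] <- data.frame(
      compound_id = library[[j]]$compound_id %||% as.character(j),
      conformer_id = res$best_conformer_id,
      score = res$best_score,
      tx = p[1], ty = p[2], tz = p[3], rx = p[4], ry = p[5], rz = p[6],
      ordinal = j
    )
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$score, df$ordinal), ]
  df$rank <- seq_len(nrow(df))
  n_hits <- ceiling(hit_fraction * nrow(df))
  df$hit <- df$rank <= n_hits
  df$ordinal <- NULL
  rownames(df) <- NULL
  class(df) <- c("darc_screen", "data.frame")
  df
}

#' Write screening results as TSV
#'
#' Columns: compound_id, conformer_id, score, tx, ty, tz, rx, ry, rz, rank,
#' hit.
#'
#' @param screen a `darc_screen` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(screen, path) {
  write.table(as.data.frame(screen), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Docking work accounting
#'
#' Closed-form operation counts for a docking run without ray elimination:
#' candidate ray-atom intersection tests per pose, pose evaluations per
#' run, candidate tests per run, and the number of swarm atoms one ray is
#' tested against in a batch-scoring pass. At the typical scale of 7,000
#' rays, a 30-atom ligand and a 200 x 200 swarm these are 210,000; 40,000;
#' 8.4e9; and 6,000.
#'
#' @param n_rays number of rays mapping the pocket.
#' @param n_atoms heavy atoms in the ligand.
#' @param n_particles swarm size.
#' @param n_iterations number of iterations.
#' @return List with `tests_per_pose`, `poses_per_run`, `tests_per_run`,
#'   `swarm_atoms`.
#' @export
docking_workload <- function(n_rays, n_atoms, n_particles, n_iterations) {
  tests_per_pose <- n_rays * n_atoms
  poses_per_run <- n_particles * n_iterations
  list(
    tests_per_pose = tests_per_pose,
    poses_per_run = poses_per_run,
    tests_per_run = tests_per_pose * poses_per_run,
    swarm_atoms = n_particles * n_atoms
  )
}

#' @export
print.dock_result <- function(x, ...) {
  p <- as_pose_vector(x$best_pose)
  cat(sprintf(
    paste0(
      "<dock_result> best score %.4f (conformer %s)\n",
      "  pose: t = (%.3f, %.3f, %.3f) A, r = (%.3f, %.3f, %.3f) rad\n",
      "  %d iterations recorded\n"
    ),
    x$best_score, x$best_conformer_id, p[1], p[2], p[3], p[4], p[5], p[6],
    length(x$trajectory)
  ))
  invisible(x)
}
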