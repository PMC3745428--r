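# Grid label codes shared with the C++ kernels.
LABEL_S <- 0L
LABEL_P <- 1L
LABEL_PSP <- 2L
LABEL_SHELL <- 3L
LABEL_FORBIDDEN <- 4L

new_grid <- function(lower, spacing, dims, labels) {
  structure(
    list(
      lower = lower, spacing = spacing, dims = as.integer(dims),
      labels = labels
    ),
    class = "darc_grid"
  )
}

#' Cartesian coordinates of grid points carrying a given label
#'
#' @param grid a `darc_grid`.
#' @param label one of "S", "P", "pocket", "shell", "forbidden" (or an
#'   integer code).
#' @return n x 3 matrix of coordinates in Angstroms.
#' @export
grid_points <- function(grid, label) {
  code <- if (is.numeric(label)) {
    as.integer(label)
  } else {
    switch(label,
      S = LABEL_S, P = LABEL_P, pocket = LABEL_PSP, shell = LABEL_SHELL,
      forbidden = LABEL_FORBIDDEN,
      darc_input_error(paste0("unknown grid label: ", label))
    )
  }
  idx <- which(grid$labels == code) - 1L
  nx <- grid$dims[1]
  ny <- grid$dims[2]
  i <- idx %% nx
  j <- (idx %/% nx) %% ny
  k <- idx %/% (nx * ny)
  cbind(
    grid$lower[1] + i * grid$spacing,
    grid$lower[2] + j * grid$spacing,
    grid$lower[3] + k * grid$spacing
  )
}

#' Build an unlabelled grid over a surface region
#'
#' A cubic grid of side `2 * extent` centered either on the centroid of a
#' target residue or on an explicit point; every point starts labelled
#' solvent. Grid dimensions are `floor(2 * extent / spacing) + 1` per axis.
#'
#' @param protein a `darc_protein`.
#' @param target `c(chain, resno)` identifying the pocket-defining residue
#'   (ignored when `center` is given).
#' @param spacing grid spacing in Angstroms (default 0.5).
#' @param extent half-width of the grid cube in Angstroms (default 15).
#' @param center optional explicit 3-vector grid center.
#' @return A `darc_grid`.
#' @export
build_grid <- function(protein, target = NULL, spacing = 0.5, extent = 15,
                       center = NULL) {
  if (spacing <= 0) darc_input_error("spacing must be positive")
  if (extent <= spacing) darc_input_error("extent must exceed spacing")
  if (is.null(center)) {
    if (is.null(target) || length(target) != 2) {
      darc_input_error("give either a (chain, resno) target or a center")
    }
    res <- residue_atoms(protein, target[[1]], as.integer(target[[2]]))
    center <- colMeans(res[, c("x", "y", "z")])
  }
  n <- floor(2 * extent / spacing) + 1
  dims <- rep(as.integer(n), 3)
  lower <- as.numeric(center) - extent
  new_grid(lower, spacing, dims, integer(prod(dims)))
}

#' Label grid points protein or solvent
#'
#' A point is protein (P) iff it lies within (inclusive) the van der Waals
#' radius of any protein atom; all other points are solvent (S).
#'
#' @param grid a `darc_grid` from [build_grid()].
#' @param protein a `darc_protein`.
#' @return The grid with labels updated.
#' @export
classify_grid <- function(grid, protein) {
  a <- protein$atoms
  grid$labels <- classify_grid_cpp(
    grid$labels, grid$dims, grid$lower, grid$spacing,
    as.matrix(a[, c("x", "y", "z")]), a$radius
  )
  grid
}

#' Mark protein-solvent-protein pocket points
#'
#' A solvent point becomes a pocket point when, along at least one of seven
#' scan directions (the three axes plus the four body diagonals), a protein
#' point occurs within `max_span` grid steps on each side with only
#' solvent/pocket points between.
#'
#' @param grid a classified `darc_grid`.
#' @param max_span maximum gap, in grid steps, to a flanking protein point
#'   (default 12).
#' @return The grid with pocket points labelled.
#' @export
mark_pocket <- function(grid, max_span = 12) {
  if (max_span < 1) darc_input_error("max_span must be >= 1")
  grid$labels <- mark_pocket_cpp(grid$labels, grid$dims, as.integer(max_span))
  grid
}

# Linear indices (1-based) of the 6 face neighbours; NA outside the grid.
face_neighbours <- function(idx, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  z <- idx - 1L
  i <- z %% nx
  j <- (z %/% nx) %% ny
  k <- z %/% (nx * ny)
  offs <- rbind(
    c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
    c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L)
  )
  out <- matrix(NA_integer_, length(idx), 6)
  for (d in 1:6) {
    ii <- i + offs[d, 1]; jj <- j + offs[d, 2]; kk <- k + offs[d, 3]
    ok <- ii >= 0L & ii < nx & jj >= 0L & jj < ny & kk >= 0L & kk < nz
    out[ok, d] <- ii[ok] + nx * (jj[ok] + ny * kk[ok]) + 1L
  }
  out
}

# TRUE where any of the 6 face neighbours carries the protein label.
has_p_face_neighbour <- function(idx, lab, dims) {
  if (length(idx) == 0) return(logical(0))
  nb <- face_neighbours(idx, dims)
  hit <- !is.na(nb)
  hit[hit] <- lab[nb[hit]] == LABEL_P
  rowSums(hit) > 0
}

# Linear indices (1-based) of the 26 vertex-sharing neighbours; NA outside.
vertex_neighbours <- function(idx, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  z <- idx - 1L
  i <- z %% nx
  j <- (z %/% nx) %% ny
  k <- z %/% (nx * ny)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  out <- matrix(NA_integer_, length(idx), nrow(offs))
  for (d in seq_len(nrow(offs))) {
    ii <- i + offs[d, 1]; jj <- j + offs[d, 2]; kk <- k + offs[d, 3]
    ok <- ii >= 0L & ii < nx & jj >= 0L & jj < ny & kk >= 0L & kk < nz
    out[ok, d] <- ii[ok] + nx * (jj[ok] + ny * kk[ok]) + 1L
  }
  out
}

# Largest connected component of the given linear indices. Connectivity is
# the 26-neighbourhood: a pocket shell is a one-grid-point-thick curved
# surface, so adjacent shell points routinely touch only through edges or
# corners and face connectivity would fragment a single contiguous shell.
largest_component_idx <- function(idx, dims) {
  if (length(idx) <= 1) return(idx)
  member <- logical(prod(dims))
  member[idx] <- TRUE
  comp <- integer(prod(dims))
  ncomp <- 0L
  for (start in idx) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    while (length(queue) > 0) {
      nb <- vertex_neighbours(queue, dims)
      nb <- nb[!is.na(nb)]
      nb <- nb[member[nb] & comp[nb] == 0L]
      nb <- unique(nb)
      comp[nb] <- ncomp
      queue <- nb
    }
  }
  sizes <- tabulate(comp[idx], nbins = ncomp)
  idx[comp[idx] == which.max(sizes)]
}

#' Extract the pocket shell and forbidden perimeter
#'
#' Shell points are pocket points in direct (face-neighbour) contact with
#' the protein; forbidden points are solvent points face-adjacent to the
#' protein within `ring_width` grid spacings (Euclidean) of a shell point --
#' they mark the surface just outside the pocket where a bound ligand should
#' not reach. Optionally only the largest connected shell component
#' (26-neighbourhood) is kept, so stray disjoint pockets do not pollute the
#' ray map.
#'
#' @param grid a pocket-marked `darc_grid`.
#' @param ring_width width of the forbidden perimeter in grid steps
#'   (default 2).
#' @param largest_component keep only the largest connected shell component.
#' @return A `darc_pocket`: `shell_points` and `forbidden_points` matrices,
#'   `origin` (unset, see [compute_ray_origin()]), and the relabelled `grid`.
#' @export
extract_shell_and_forbidden <- function(grid, ring_width = 2,
                                        largest_component = TRUE) {
  lab <- grid$labels
  if (!any(lab == LABEL_PSP)) darc_error("no pocket found", "darc_no_pocket")
  psp <- which(lab == LABEL_PSP)
  shell <- psp[has_p_face_neighbour(psp, lab, grid$dims)]
  if (length(shell) == 0) darc_error("no pocket found", "darc_no_pocket")
  if (largest_component) shell <- largest_component_idx(shell, grid$dims)

  grid$labels[shell] <- LABEL_SHELL
  shell_xyz <- grid_points(grid, "shell")

  s_idx <- which(grid$labels == LABEL_S)
  cand <- s_idx[has_p_face_neighbour(s_idx, lab, grid$dims)]
  if (length(cand) > 0) {
    nx <- grid$dims[1]; ny <- grid$dims[2]
    z <- cand - 1L
    cand_xyz <- cbind(
      grid$lower[1] + (z %% nx) * grid$spacing,
      grid$lower[2] + ((z %/% nx) %% ny) * grid$spacing,
      grid$lower[3] + (z %/% (nx * ny)) * grid$spacing
    )
    near <- min_dist_filter_cpp(cand_xyz, shell_xyz,
                                ring_width * grid$spacing)
    grid$labels[cand[near]] <- LABEL_FORBIDDEN
  }
  structure(
    list(
      shell_points = shell_xyz,
      forbidden_points = grid_points(grid, "forbidden"),
      origin = NULL, offset = NA_real_, grid = grid
    ),
    class = "darc_pocket"
  )
}

#' Place the ray origin inside the protein
#'
#' The origin lies `offset` Angstroms from the pocket center of mass along
#' the direction towards the protein center of mass, i.e. buried inside the
#' protein so that every ray looks outward through the pocket. The pocket
#' center of mass is the unweighted mean of the shell points.
#'
#' @param pocket a `darc_pocket`.
#' @param protein the `darc_protein` the pocket was mapped on.
#' @param offset distance in Angstroms from pocket COM to origin (default 30).
#' @return The pocket with `origin` and `offset` set.
#' @export
compute_ray_origin <- function(pocket, protein, offset = 30) {
  if (nrow(pocket$shell_points) == 0) darc_input_error("pocket has no shell")
  pocket_com <- colMeans(pocket$shell_points)
  v <- protein$center_of_mass - pocket_com
  n <- sqrt(sum(v^2))
  if (n < 1e-9) {
    darc_geometry_error("pocket and protein centers of mass coincide")
  }
  pocket$origin <- as.numeric(pocket_com + offset * v / n)
  pocket$offset <- offset
  pocket
}

#' Map a surface pocket end to end
#'
#' Convenience pipeline: [build_grid()], [classify_grid()], [mark_pocket()],
#' [extract_shell_and_forbidden()], [compute_ray_origin()].
#'
#' @inheritParams build_grid
#' @inheritParams mark_pocket
#' @inheritParams extract_shell_and_forbidden
#' @inheritParams compute_ray_origin
#' @return A `darc_pocket` with origin set.
#' @export
map_pocket <- function(protein, target = NULL, center = NULL, spacing = 0.5,
                       extent = 15, max_span = 12, ring_width = 2,
                       offset = 30, largest_component = TRUE) {
  grid <- build_grid(protein, target, spacing, extent, center)
  grid <- classify_grid(grid, protein)
  grid <- mark_pocket(grid, max_span)
  pocket <- extract_shell_and_forbidden(grid, ring_width, largest_component)
  compute_ray_origin(pocket, protein, offset)
}

#' @export
print.darc_pocket <- function(x, ...) {
  cat(sprintf(
    "<darc_pocket> %d shell points, %d forbidden points, origin %s\n",
    nrow(x$shell_points), nrow(x$forbidden_points),
    if (is.null(x$origin)) {
      "unset"
    } else {
      sprintf("(%.2f, %.2f, %.2f)", x$origin[1], x$origin[2], x$origin[3])
    }
  ))
  invisible(x)
}

#' @export
print.darc_grid <- function(x, ...) {
  counts <- table(factor(x$labels,
    levels = 0:4,
    labels = c("S", "P", "pocket", "shell", "forbidden")
  ))
  cat(sprintf(
    "<darc_grid> %d x %d x %d, spacing %.2f A\n", x$dims[1], x$dims[2],
    x$dims[3], x$spacing
  ))
  print(counts)
  invisible(x)
}
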