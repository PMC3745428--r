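#' Cartesian to spherical coordinates about an origin
#'
#' Convention: `theta` is the polar angle from +z in degrees (0 to 180),
#' `phi` the azimuth from +x in the xy-plane in degrees (-180, 180], `rho`
#' the Euclidean distance. `phi` is defined as 0 at the poles.
#'
#' @param points 3-vector or n x 3 matrix, Angstroms.
#' @param origin 3-vector, Angstroms.
#' @return Data frame with columns theta, phi, rho.
#' @export
cartesian_to_spherical <- function(points, origin = c(0, 0, 0)) {
  p <- as_xyz_matrix(points)
  rel <- sweep(p, 2, as.numeric(origin))
  rho <- sqrt(rowSums(rel^2))
  if (any(rho == 0)) darc_geometry_error("point coincides with origin")
  theta <- acos(pmin(1, pmax(-1, rel[, 3] / rho))) * 180 / pi
  phi <- atan2(rel[, 2], rel[, 1]) * 180 / pi
  phi[rel[, 1] == 0 & rel[, 2] == 0] <- 0
  data.frame(theta = theta, phi = phi, rho = rho)
}

#' Spherical to Cartesian coordinates
#'
#' @param theta,phi angles in degrees (see [cartesian_to_spherical()]).
#' @param rho distances in Angstroms.
#' @param origin 3-vector the coordinates are relative to.
#' @return n x 3 matrix.
#' @export
spherical_to_cartesian <- function(theta, phi, rho, origin = c(0, 0, 0)) {
  sweep(ray_directions(theta, phi) * rho, 2, as.numeric(origin), `+`)
}

#' Unit direction vectors from ray angles
#'
#' Shared by the rayfile reader, the fixture generator and the scorer so
#' that a stored ray and a recomputed ray direction agree bit for bit.
#'
#' @param theta,phi angles in degrees.
#' @return n x 3 matrix of unit vectors.
#' @export
ray_directions <- function(theta, phi) {
  t <- theta * pi / 180
  p <- phi * pi / 180
  st <- sin(t)
  cbind(st * cos(p), st * sin(p), cos(t))
}

new_rayset <- function(origin, rays) {
  if (!any(rays$kind == "pocket")) {
    darc_input_error("a rayset needs at least one pocket ray")
  }
  if (any(rays$rho <= 0)) darc_input_error("ray rho must be positive")
  rownames(rays) <- NULL
  structure(list(origin = as.numeric(origin), rays = rays),
    class = "darc_rayset"
  )
}

#' Build a rayset from a mapped pocket
#'
#' One pocket ray per shell point and one forbidden ray per forbidden
#' point, expressed in spherical coordinates about the pocket origin.
#' Collinear points (duplicate angles within 1e-6 degrees) are collapsed,
#' keeping the smaller rho -- the nearer point is the one the ray hits
#' first.
#'
#' @param pocket a `darc_pocket` with origin set (see
#'   [compute_ray_origin()]).
#' @return A `darc_rayset`: `origin` plus a data frame of rays
#'   (kind, theta, phi, rho).
#' @export
build_rayset <- function(pocket) {
  if (is.null(pocket$origin)) {
    darc_input_error("pocket origin is unset; call compute_ray_origin() first")
  }
  if (nrow(pocket$shell_points) == 0) {
    darc_input_error("pocket has no shell points")
  }
  one_kind <- function(points, kind) {
    if (is.null(points) || nrow(points) == 0) {
      return(NULL)
    }
    sph <- cartesian_to_spherical(points, pocket$origin)
    sph <- sph[order(sph$rho), , drop = FALSE]
    key <- paste(round(sph$theta, 6), round(sph$phi, 6))
    sph <- sph[!duplicated(key), , drop = FALSE]
    cbind(kind = kind, sph, stringsAsFactors = FALSE)
  }
  rays <- rbind(
    one_kind(pocket$shell_points, "pocket"),
    one_kind(pocket$forbidden_points, "forbidden")
  )
  new_rayset(pocket$origin, rays)
}

#' Write a rayset to a rayfile
#'
#' Plain-text format, version 1: a `DARC_RAYFILE v1` header, an
#' `origin x y z` line, then one `kind theta phi rho` line per ray, all
#' numeric fields fixed 6-decimal. Writing then reading reproduces every
#' field at file precision, and write-read-write is byte stable.
#'
#' @param rayset a `darc_rayset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rayfile <- function(rayset, path) {
  r <- rayset$rays
  lines <- c(
    "DARC_RAYFILE v1",
    sprintf(
      "origin %.6f %.6f %.6f", rayset$origin[1], rayset$origin[2],
      rayset$origin[3]
    ),
    sprintf("%s %.6f %.6f %.6f", r$kind, r$theta, r$phi, r$rho)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a rayfile
#'
#' @param path a rayfile written by [write_rayfile()].
#' @return A `darc_rayset`.
#' @export
read_rayfile <- function(path) {
  if (!file.exists(path)) darc_input_error(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2 || lines[1] != "DARC_RAYFILE v1") {
    darc_format_error(paste0(
      "not a DARC_RAYFILE v1 file (header mismatch): ", path
    ))
  }
  ofields <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  origin <- suppressWarnings(as.numeric(ofields[-1]))
  if (ofields[1] != "origin" || length(origin) != 3 || any(is.na(origin))) {
    darc_format_error("malformed origin line (line 2)")
  }
  body <- lines[-(1:2)]
  body_no <- seq_along(body) + 2L
  keep <- nzchar(trimws(body))
  body <- body[keep]
  body_no <- body_no[keep]
  if (length(body) == 0) darc_format_error("rayfile contains no rays")
  parts <- strsplit(trimws(body), "\\s+")
  rays <- data.frame(
    kind = NA_character_, theta = NA_real_, phi = NA_real_, rho = NA_real_
  )[rep(1, length(parts)), ]
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (length(f) != 4 || !(f[1] %in% c("pocket", "forbidden")) ||
      any(is.na(vals))) {
      darc_format_error(sprintf("malformed ray line %d in %s", body_no[i], path))
    }
    rays$kind[i] <- f[1]
    rays$theta[i] <- vals[1]
    rays$phi[i] <- vals[2]
    rays$rho[i] <- vals[3]
  }
  new_rayset(origin, rays)
}

#' @export
print.darc_rayset <- function(x, ...) {
  cat(sprintf(
    "<darc_rayset> %d pocket + %d forbidden rays, origin (%.2f, %.2f, %.2f)\n",
    sum(x$rays$kind == "pocket"), sum(x$rays$kind == "forbidden"),
    x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}
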