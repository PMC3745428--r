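# Independent oracles and small fixture builders shared across test files.

# Brute-force protein-solvent-protein marking: enumerate every line in each
# scan direction, locate consecutive protein points, and mark the solvent
# cells between them that lie within max_span steps of both. Independent of
# the walk-based implementation in the package.
oracle_mark_pocket <- function(labels, dims, max_span) {
  arr <- array(labels, dim = dims)
  out <- arr
  dirs <- list(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
  inside <- function(p) all(p >= 1) && all(p <= dims)
  for (d in dirs) {
    # line starting points: cells whose predecessor along d is outside
    for (i in 1:dims[1]) {
      for (j in 1:dims[2]) {
        for (k in 1:dims[3]) {
          p <- c(i, j, k)
          if (inside(p - d)) next
          line <- list()
          q <- p
          while (inside(q)) {
            line[[length(line) + 1]] <- q
            q <- q + d
          }
          lab_line <- vapply(line, function(c3) arr[c3[1], c3[2], c3[3]],
            integer(1)
          )
          p_pos <- which(lab_line == 1L)
          if (length(p_pos) < 2) next
          for (t in seq_len(length(p_pos) - 1)) {
            a <- p_pos[t]
            b <- p_pos[t + 1]
            if (b - a < 2) next
            for (pos in (a + 1):(b - 1)) {
              if (pos - a <= max_span && b - pos <= max_span &&
                lab_line[pos] != 1L) {
                c3 <- line[[pos]]
                out[c3[1], c3[2], c3[3]] <- 2L
              }
            }
          }
        }
      }
    }
  }
  as.integer(out)
}

# A darc_grid with labels set directly (bypasses classification).
toy_grid <- function(labels, dims, spacing = 1, lower = c(0, 0, 0)) {
  structure(
    list(
      lower = lower, spacing = spacing, dims = as.integer(dims),
      labels = as.integer(labels)
    ),
    class = "darc_grid"
  )
}

# Random rigid pose in/near the planted-fixture search region.
random_pose <- function(t_range = 1) {
  pose_transform(runif(3, -t_range, t_range), runif(3, 0, 2 * pi))
}

# Minimal hand-written PDB content (list of lines) for IO tests.
minimal_protein_pdb_lines <- function() {
  c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.722   6.899  -4.246  1.00  0.00           C",
    "END"
  )
}

altloc_pdb_lines <- function() {
  c(
    "ATOM      1  CA AALA A   1       1.000   2.000   3.000  0.50  0.00           C",
    "ATOM      2  CA BALA A   1       1.500   2.000   3.000  0.50  0.00           C",
    "END"
  )
}

# Two-model ligand PDB of a 3-heavy-atom molecule with one hydrogen.
multimodel_ligand_pdb_lines <- function() {
  atom <- function(serial, name, x, y, z, el) {
    sprintf(
      "HETATM%5d %-4s LIG X   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial, name, x, y, z, el
    )
  }
  c(
    "MODEL        1",
    atom(1, "C1", 0, 0, 0, "C"),
    atom(2, "O1", 1.2, 0, 0, "O"),
    atom(3, "N1", 0, 1.3, 0, "N"),
    atom(4, "H1", -0.5, -0.5, 0, "H"),
    "ENDMDL",
    "MODEL        2",
    atom(1, "C1", 0, 0, 1, "C"),
    atom(2, "O1", 1.2, 0, 1, "O"),
    atom(3, "N1", 0, 1.3, 1, "N"),
    atom(4, "H1", -0.5, -0.5, 1, "H"),
    "ENDMDL",
    "END"
  )
}

# Tiny SDF V2000 molecule (methanol-like, with explicit hydrogen).
tiny_sdf_lines <- function() {
  c(
    "tiny",
    "  tester",
    "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.4000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6000    0.9000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0",
    "  1  3  1  0",
    "M  END",
    "$$$$"
  )
}

write_lines_tmp <- function(lines, ext = ".pdb") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
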