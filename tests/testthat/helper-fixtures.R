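# Fixture builders shared across the suite. Everything is generated in
# code; nothing is stored on disk.

# straight Calpha chain along x with exact spacing
straight_chain <- function(n, spacing = 3.8, resnum_start = 1L,
                           id = "chain", variant = "WT") {
  structure3d(id = id,
              resnum = seq(resnum_start, length.out = n),
              chain = "A", resname = rep("ALA", n),
              ca = cbind((seq_len(n) - 1L) * spacing, 0, 0),
              variant = variant)
}

# random globular point cloud
random_cloud <- function(n, scale = 2) {
  matrix(stats::rnorm(n * 3, sd = scale), n, 3)
}

# a random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

apply_rigid <- function(coords, R, tvec) {
  sweep(coords %*% t(R), 2, tvec, "+")
}

# write a minimal PDB text file from explicit atom fields (test-only writer,
# independent of the package's output path)
write_raw_pdb <- function(path, lines) writeLines(lines, path)

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          record = "ATOM", altloc = " ", icode = " ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resname, chain, resno, icode, x, y, z)
}

# a 3-residue toy PDB file; returns the path
toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  write_raw_pdb(path, c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0.5, 0.5, 0.5),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(4, "CA", "VAL", "A", 3, 7.6, 0, 0),
    "END"))
  path
}

# partition of a cluster_result as a canonical list of sorted member sets
partition_sets <- function(cr) {
  sets <- lapply(cr$clusters, function(cl) sort(as.character(cl$members)))
  sets[order(vapply(sets, `[`, "", 1L))]
}

# canonical partition from a membership vector (names = items)
partition_from_assign <- function(assign) {
  sets <- lapply(split(names(assign), assign), sort)
  names(sets) <- NULL
  sets[order(vapply(sets, `[`, "", 1L))]
}
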