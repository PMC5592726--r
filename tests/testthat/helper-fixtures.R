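# Small builders used across test files.

# fixed-column PDB line for hand-made fixtures
pdb_line <- function(record, serial, name, resname, chain, seqnum, x, y, z,
                     occ = 1, altloc = " ", element = substr(name, 1, 1)) {
  name_f <- if (nchar(name) >= 4) name else sprintf(" %-3s", name)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_f, altloc, resname, chain, seqnum, " ",
          x, y, z, occ, 0, element)
}

# a one-residue structure with arbitrary named atoms at given coordinates
toy_structure <- function(atoms, resname = "ALA", chain = "A", seqnum = 1,
                          record = "ATOM") {
  lines <- purrr::imap_chr(atoms, function(xyz, nm) {
    pdb_line(record, match(nm, names(atoms)), nm, resname, chain, seqnum,
             xyz[1], xyz[2], xyz[3])
  })
  parse_structure(c(unname(lines), "END"))
}

# annotation for a tiny single-helix template, anchor at position 4 of 7
toy_annotation <- function(sequence = "MNLLIAV") {
  reference_annotation("toy",
                       data.frame(helix = 1, start = 1, end = 7, anchor = 4),
                       sequence = sequence)
}

rigid_transform <- function(s, angle = 0.7, shift = c(3, -2, 5)) {
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  # tilt as well, so the motion is a generic rigid-body transform
  tilt <- 0.3
  Rt <- matrix(c(1, 0, 0,
                 0, cos(tilt), -sin(tilt),
                 0, sin(tilt), cos(tilt)), 3, 3, byrow = TRUE)
  X <- cbind(s$atoms$x, s$atoms$y, s$atoms$z) %*% t(R %*% Rt)
  s$atoms$x <- X[, 1] + shift[1]
  s$atoms$y <- X[, 2] + shift[2]
  s$atoms$z <- X[, 3] + shift[3]
  s
}
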