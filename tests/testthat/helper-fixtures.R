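# Shared fixture builders: residues at exact coordinates, tiny PDB files,
# and brute-force distance oracles.

fake_residue <- function(resname, coords, resno = 1L, chain = "A") {
  nm <- names(coords)
  xyz <- do.call(rbind, coords)
  data.frame(chain = chain, resno = as.integer(resno), icode = "",
             resname = resname, elety = nm,
             element = substr(sub("^[0-9]*", "", nm), 1, 1),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             altloc = "", occupancy = 1, stringsAsFactors = FALSE)
}

# two single-interacting-atom residues whose named atoms sit exactly `d` apart
residue_pair_at <- function(resname_a, atom_a, resname_b, atom_b, d) {
  ra <- fake_residue(resname_a, stats::setNames(list(c(0, 0, 0), c(1.5, 0, 0)),
                                                c("CA", atom_a)), resno = 1L)
  rb <- fake_residue(resname_b, stats::setNames(list(c(1.5 + d + 1.5, 0, 0),
                                                     c(1.5 + d, 0, 0)),
                                                c("CA", atom_b)), resno = 2L)
  list(a = ra, b = rb)
}

brute_min_heavy <- function(res_a, res_b) {
  A <- as.matrix(res_a[res_a$element != "H", c("x", "y", "z")])
  B <- as.matrix(res_b[res_b$element != "H", c("x", "y", "z")])
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  }
  best
}

write_pdb_lines <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, elety, resname, chain, resno, x, y, z,
                          occ = 1, altloc = " ", element = NULL) {
  if (is.null(element)) element <- substr(elety, 1, 1)
  sprintf("ATOM  %5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(elety) < 4, paste0(" ", elety), elety),
          altloc, resname, chain, resno, x, y, z, occ, 0, element)
}

apply_global_rigid <- function(model, axis = c(1, 2, 3), deg = 25,
                               tvec = c(5, -3, 8)) {
  R <- gphrtmd:::rot_axis_angle(axis, deg)
  a <- model$atoms
  xyz <- t(R %*% t(as.matrix(a[, c("x", "y", "z")]))) +
    matrix(tvec, nrow(a), 3, byrow = TRUE)
  a[, c("x", "y", "z")] <- xyz
  as_tmd_structure(a, id = paste0(model$id, "_moved"),
                   source_format = model$source_format)
}

# the movement plan used for conformational-change fixtures: TM6
# intracellular out, TM5/TM7 intracellular in, TM3 down
fig_movement_plan <- function() {
  list(move_end(6, "intracellular", radial = 5),
       move_end(5, "intracellular", radial = -2),
       move_end(7, "intracellular", radial = -2),
       move_end(3, "intracellular", axial = -2))
}
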