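## Raw fixed-column PDB text builders, used to exercise the parser on
## exactly controlled records (altLocs, legacy names, MODEL blocks).

pdb_atom_line <- function(eleno, name, resid, chain, resno,
                          x, y, z, o = 1, alt = " ", icode = " ",
                          elesy = "", record = "ATOM  ") {
  name_field <- if (nchar(name) >= 4L) sprintf("%-4s", name)
                else sprintf(" %-3s", name)
  sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, eleno, name_field, alt, resid, chain, resno, icode,
          x, y, z, o, 0, elesy)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

## a tiny 1-residue, 3-atom structure
mini_pdb <- function(names = c("P", "C1'", "O5'")) {
  write_pdb_fixture(c(
    pdb_atom_line(1, names[1], "G", "A", 1, 1, 2, 3, elesy = "P"),
    pdb_atom_line(2, names[2], "G", "A", 1, 2.5, 2, 3, elesy = "C"),
    pdb_atom_line(3, names[3], "G", "A", 1, 3, 3.5, 3, elesy = "O")))
}

## independent membership check: which residues' spheres (by raw pairwise
## distance from the center atom) contain any of the given atom keys
expected_hit_rows <- function(reference, radius, keys,
                              center_atom = "C1'") {
  at <- reference$atoms
  vapply(residue_keys(reference), function(rk) {
    ci <- which(at$res_key == rk & at$elety == center_atom)[1]
    d <- sqrt((at$x - at$x[ci])^2 + (at$y - at$y[ci])^2 +
              (at$z - at$z[ci])^2)
    any(at$atom_key[d <= radius] %in% keys)
  }, logical(1))
}

## handy perturbed pair used by several files
helix_pair <- function(n = 12, sigma = 0.8, seed = 11) {
  ref <- generate_helix(n, seed = seed)
  list(ref = ref,
       mod = perturb_structure(ref, "gaussian_noise", sigma, seed = seed + 1))
}
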