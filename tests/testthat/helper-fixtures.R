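# PDB fixture builder: fixed-column ATOM records, one CA per residue unless
# altloc variants are supplied.
pdb_ca_line <- function(serial, resno, x, y, z, chain = "A", altloc = " ",
                        occ = 1.00, resname = "ALA", icode = " ") {
  sprintf("ATOM  %5d  CA %s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, altloc, resname, chain, resno, icode, x, y, z, occ, 0)
}

pdb_from_coords <- function(coords, chain = "A", resno = seq_len(nrow(coords))) {
  vapply(seq_len(nrow(coords)), function(i)
    pdb_ca_line(i, resno[i], coords[i, 1], coords[i, 2], coords[i, 3],
                chain = chain), "")
}

square_cloud <- function() rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))

hexagon_cloud <- function() cbind(cos(2 * pi * (0:5) / 6),
                                  sin(2 * pi * (0:5) / 6), 0)

# random rigid motion applied to a cloud
rigid_motion <- function(P, seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  sweep(P %*% Q, 2, rnorm(3, sd = 5), "+")
}
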