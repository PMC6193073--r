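# Structure fixtures built in code.

# Structure from a list of residues; each element:
#   list(chain, resno, resname, coords = matrix/vector of heavy-atom xyz)
mkStructure <- function(res, id = "fixture") {
  rows <- lapply(res, function(r) {
    xyz <- matrix(r$coords, ncol = 3, byrow = FALSE)
    if (length(r$coords) == 3) xyz <- matrix(r$coords, 1, 3)
    data.frame(chain = r$chain, resno = r$resno, resname = r$resname,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  Structure(do.call(rbind, rows), id = id)
}

# single-atom residue helper
res1 <- function(chain, resno, resname, x, y = 0, z = 0)
  list(chain = chain, resno = resno, resname = resname, coords = c(x, y, z))

# fixed-column PDB record for hand-built parser inputs
pdbLine <- function(type, serial, name, alt, resn, chain, resno, x, y, z,
                    occ = 1, elem = "C") {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name4, alt, resn, chain, resno, x, y, z, occ, 0,
          elem)
}

writePdbFixture <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}
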