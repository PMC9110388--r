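# Builders for small test structures and text fixtures (everything is
# generated in code; nothing binary ships with the package).

toy_structure <- function(xyz, mass = 12, resno = NULL, element = "C") {
  xyz <- matrix(xyz, ncol = 3)
  new_structure(data.frame(
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = mass, element = element,
    resno = if (is.null(resno)) seq_len(nrow(xyz)) else resno))
}

# four single-atom "domains" with one residue each
four_domain_structure <- function(p1, p2, p3, p4) {
  toy_structure(rbind(p1, p2, p3, p4), resno = 1:4)
}

four_domain_partition <- function() domain_partition(1:4, 1:4)

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2+b^2-c^2-d^2, 2*(b*c-a*d),     2*(b*d+a*c),
           2*(b*c+a*d),     a^2-b^2+c^2-d^2, 2*(c*d-a*b),
           2*(b*d-a*c),     2*(c*d+a*b),     a^2-b^2-c^2+d^2),
         3, 3, byrow = TRUE)
}

# minimal but column-correct PDB text
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, bfac = 0, element = "C", alt = " ") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, occ, bfac, element)
}

write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# default-geometry model reused across tests (entropy table is the slow part)
cached_pincer <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_pincer()
    m
  }
})
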