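# Fixture builders shared across tests. Everything is generated in code.

fx_structure <- function(atoms, xyz) {
  if (!is.list(xyz) || is.matrix(xyz)) xyz <- list(as.matrix(xyz))
  tmanatomy:::new_structure3d(atoms, xyz, source_id = "fixture")
}

fx_atoms <- function(res_seq, res_name, atom_name, element = "C",
                     chain = "A", het = FALSE) {
  data.frame(chain = chain, res_seq = as.integer(res_seq), icode = "",
             res_name = res_name, atom_name = atom_name, element = element,
             occupancy = 1, bfactor = 0, het = het, stringsAsFactors = FALSE)
}

# idealised planar 6-ring (Phe-like) with a given centre and plane normal
fx_ring_xyz <- function(center, normal, radius = 1.39) {
  n <- normal / sqrt(sum(normal^2))
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n; u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  t(sapply(0:5, function(k)
    center + radius * (cos(k * pi / 3) * u + sin(k * pi / 3) * v)))
}

fx_phe <- function(res_seq, center, normal) {
  list(atoms = fx_atoms(res_seq, "PHE",
                        c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
       xyz = fx_ring_xyz(center, normal))
}

# crude extended peptide with N, CA, C, O per residue along x (3.8 A pitch)
fx_extended_peptide <- function(n_res, res_name = "ALA", z = 0) {
  rows <- lapply(seq_len(n_res), function(i) {
    x <- 3.8 * i
    list(atoms = fx_atoms(rep(i, 4), res_name, c("N", "CA", "C", "O"),
                          c("N", "C", "C", "O")),
         xyz = rbind(c(x - 1.2, 0.9, z), c(x, 0, z),
                     c(x + 1.2, 0.9, z), c(x + 1.2, 2.1, z)))
  })
  fx_structure(do.call(rbind, lapply(rows, `[[`, "atoms")),
               do.call(rbind, lapply(rows, `[[`, "xyz")))
}

# random proper rotation matrix (seeded by caller)
fx_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

fx_rigid <- function(rotation, translation) {
  structure(list(rotation = rotation, translation = translation, rmsd = 0),
            class = "rigid_transform")
}

# text PDB fixture written programmatically; returns the path
fx_write_pdb <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(lines, file)
  file
}

fx_pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                             occ = 1, b = 0, element = "C", alt = " ") {
  sprintf("ATOM  %5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resn, chain, resno, x, y, z, occ, b, element)
}

# exhaustive global-alignment score oracle with affine gaps: enumerates every
# alignment recursively; a gap run of length L costs open + extend * L
fx_align_enum <- function(a, b, sub, gap_open, gap_extend) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      rec(i + 1, j + 1, score + sub[a[i], b[j]], "m")
    if (i <= length(a))
      rec(i + 1, j, score - gap_extend - if (last != "a") gap_open else 0, "a")
    if (j <= length(b))
      rec(i, j + 1, score - gap_extend - if (last != "b") gap_open else 0, "b")
  }
  rec(1, 1, 0, "m")
  best
}
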