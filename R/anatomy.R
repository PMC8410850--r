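# Donor / acceptor heavy atoms for hydrogen-bond detection in structures
# without explicit hydrogens. Distances only; no angular criterion.
HB_DONORS <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", TRP = "NE1",
  ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  LYS = "NZ", ARG = c("NE", "NH1", "NH2")
)
HB_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2"), MET = "SD"
)
ACID_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASE_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                   HIS = c("ND1", "NE2"))
HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Build the membrane frame of a TM helix bundle
#'
#' Places the origin at the centre of mass of the backbone atoms of the five
#' TM helices and takes the membrane normal as their first principal axis,
#' with the sign chosen so that the extracellular boundary reference residue
#' lies at positive z and the intracellular reference at negative z. The x-y
#' plane at z = 0 is the membrane mid-plane used by the tilt metric.
#'
#' @param s A `structure3d`.
#' @param seg A `segment_map`; the five `helix *` segments define the bundle.
#' @param chain Chain identifier (`NULL`: any).
#' @param ec_ref,ic_ref Extracellular / intracellular boundary reference
#'   residues (CA atoms; defaults 123 and 274).
#' @return A `membrane_frame`: list with `origin`, `z_axis` (unit vector),
#'   `boundary_refs`.
#' @export
build_frame <- function(s, seg = default_segment_map(), chain = NULL,
                        ec_ref = 123, ic_ref = 274) {
  helices <- grep("^helix", seg$name, value = TRUE)
  res <- segment_residues(seg, helices)
  bb <- select_atoms(protein_heavy(s), chain = chain, residues = res,
                     atom_names = BACKBONE_ATOMS)
  if (nrow(bb$atoms) < 10)
    stop("build_frame: too few TM backbone atoms (", nrow(bb$atoms), ")")
  origin <- center_of_mass(bb)
  xyz <- sweep(coords(bb), 2, origin)
  z_axis <- svd(xyz, nu = 0, nv = 3)$v[, 1]
  ca <- function(r) {
    sel <- select_atoms(s, chain = chain, residues = r, atom_names = "CA")
    if (nrow(sel$atoms) == 0)
      stop("build_frame: CA of boundary reference residue ", r, " missing")
    coords(sel)[1, ]
  }
  z_ec <- sum((ca(ec_ref) - origin) * z_axis)
  z_ic <- sum((ca(ic_ref) - origin) * z_axis)
  if (z_ec < z_ic) z_axis <- -z_axis
  structure(list(origin = origin, z_axis = z_axis,
                 boundary_refs = c(extracellular = ec_ref,
                                   intracellular = ic_ref)),
            class = "membrane_frame")
}

# z coordinate (along the membrane normal) of points in a frame
frame_z <- function(xyz, frame) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  as.vector(sweep(xyz, 2, frame$origin) %*% frame$z_axis)
}

# radial distance from the bundle (z) axis
frame_radial <- function(xyz, frame) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  v <- sweep(xyz, 2, frame$origin)
  z <- as.vector(v %*% frame$z_axis)
  sqrt(pmax(0, rowSums(v^2) - z^2))
}

#' ECD tilt angle relative to the membrane plane
#'
#' The angle, in [0, 90] degrees, between the vector from the frame origin to
#' the centre of mass of the CA atoms of the ECD tip residues (the beta-
#' hairpin, residues 32-36) and the x-y membrane plane at z = 0. 90 degrees
#' means the ECD stands perpendicular to the membrane; 0 means it lies in the
#' membrane plane.
#'
#' @param s A `structure3d`.
#' @param frame A `membrane_frame` from [build_frame()].
#' @param tip_residues Residues whose CA centre of mass defines the ECD tip.
#' @param chain Chain identifier (`NULL`: any).
#' @return Tilt angle in degrees.
#' @export
ecd_tilt <- function(s, frame, tip_residues = 32:36, chain = NULL) {
  sel <- select_atoms(s, chain = chain, residues = tip_residues,
                      atom_names = "CA")
  missing <- setdiff(tip_residues, unique(sel$atoms$res_seq))
  if (length(missing) > 0)
    stop("ecd_tilt: tip residue(s) missing: ", paste(missing, collapse = ", "))
  tip <- center_of_mass(sel)
  v <- tip - frame$origin
  sin_t <- abs(sum(v * frame$z_axis)) / sqrt(sum(v^2))
  asin(pmin(1, sin_t)) * 180 / pi
}

#' Inter-segment heavy-atom contacts of a target helix
#'
#' All heavy-atom pairs with one atom in the target segment and one in any
#' other segment at distance <= cutoff. Pairs within the target segment and
#' covalently adjacent residues (|residue difference| <= 1 on the same chain)
#' are excluded. Contacts are classified `hydrophobic` (both atoms carbon or
#' sulphur), `polar` (both atoms N/O) or `other`.
#'
#' @param s A `structure3d`.
#' @param seg A `segment_map`.
#' @param target Target segment name (default `"helix III"`).
#' @param cutoff Distance cutoff in angstrom, conventionally in [3, 5].
#' @param chain Chain identifier (`NULL`: any).
#' @return data.frame: one row per contact with residue/atom identities of
#'   both partners, `distance`, `segment_a` (target), `segment_b`, `class`.
#' @export
segment_contacts <- function(s, seg = default_segment_map(),
                             target = "helix III", cutoff = 3.5,
                             chain = NULL) {
  segment_lookup(seg, target) # errors on unknown segment
  sp <- protein_heavy(s)
  if (!is.null(chain)) sp <- select_atoms(sp, chain = chain)
  a <- atom_table(sp)
  a$segment <- segment_of(a$res_seq, seg)
  a <- a[!is.na(a$segment), , drop = FALSE]
  ta <- a[a$segment == target, , drop = FALSE]
  ob <- a[a$segment != target, , drop = FALSE]
  empty <- data.frame(chain_a = character(), res_a = integer(),
                      res_name_a = character(), atom_a = character(),
                      chain_b = character(), res_b = integer(),
                      res_name_b = character(), atom_b = character(),
                      distance = numeric(), segment_a = character(),
                      segment_b = character(), class = character(),
                      stringsAsFactors = FALSE)
  if (nrow(ta) == 0 || nrow(ob) == 0) return(empty)
  xa <- as.matrix(ta[, c("x", "y", "z")])
  xb <- as.matrix(ob[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  i <- hit[, 1]; j <- hit[, 2]
  same_chain <- ta$chain[i] == ob$chain[j]
  bonded <- same_chain & abs(ta$res_seq[i] - ob$res_seq[j]) <= 1
  i <- i[!bonded]; j <- j[!bonded]
  if (length(i) == 0) return(empty)
  cls <- function(e1, e2) {
    ifelse(e1 %in% c("C", "S") & e2 %in% c("C", "S"), "hydrophobic",
           ifelse(e1 %in% c("N", "O") & e2 %in% c("N", "O"), "polar", "other"))
  }
  out <- data.frame(
    chain_a = ta$chain[i], res_a = ta$res_seq[i],
    res_name_a = ta$res_name[i], atom_a = ta$atom_name[i],
    chain_b = ob$chain[j], res_b = ob$res_seq[j],
    res_name_b = ob$res_name[j], atom_b = ob$atom_name[j],
    distance = sqrt(pmax(0, d2[cbind(i, j)])),
    segment_a = target, segment_b = ob$segment[j],
    class = cls(ta$element[i], ob$element[j]),
    stringsAsFactors = FALSE
  )
  out[order(out$res_a, out$res_b, out$distance), , drop = FALSE]
}

hb_atoms <- function(a, dict) {
  bb <- a$atom_name %in% dict$backbone & !(a$res_name == "PRO" &
                                             a$atom_name == "N")
  sc <- mapply(function(rn, an) an %in% dict[[rn]],
               a$res_name, a$atom_name)
  a[bb | (!is.na(sc) & sc), , drop = FALSE]
}

#' Hydrogen bonds by heavy-atom donor-acceptor distance
#'
#' Crystal structures at moderate resolution carry no hydrogens, so bonds are
#' scored purely on donor-acceptor heavy-atom distance within a window
#' (default 2.2 to 3.5 angstrom), using a residue dictionary of donor and
#' acceptor atoms. Pairs within a residue or between covalently adjacent
#' residues are excluded; symmetric duplicates (atoms that are both donors
#' and acceptors) are reported once.
#'
#' @param s A `structure3d`.
#' @param cutoff Upper distance bound (angstrom).
#' @param min_dist Lower bound excluding covalent contacts (angstrom).
#' @param chain Chain identifier (`NULL`: any).
#' @param side_chain_only Restrict both partners to side-chain atoms.
#' @return data.frame with donor and acceptor identities and `distance`.
#' @export
hydrogen_bonds <- function(s, cutoff = 3.5, min_dist = 2.2, chain = NULL,
                           side_chain_only = FALSE) {
  sp <- protein_heavy(s)
  if (!is.null(chain)) sp <- select_atoms(sp, chain = chain)
  a <- atom_table(sp)
  don <- hb_atoms(a, HB_DONORS)
  acc <- hb_atoms(a, HB_ACCEPTORS)
  if (side_chain_only) {
    don <- don[!(don$atom_name %in% BACKBONE_ATOMS), , drop = FALSE]
    acc <- acc[!(acc$atom_name %in% BACKBONE_ATOMS), , drop = FALSE]
  }
  empty <- data.frame(donor_chain = character(), donor_res = integer(),
                      donor_res_name = character(), donor_atom = character(),
                      acceptor_chain = character(), acceptor_res = integer(),
                      acceptor_res_name = character(),
                      acceptor_atom = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(don) == 0 || nrow(acc) == 0) return(empty)
  xd <- as.matrix(don[, c("x", "y", "z")])
  xa <- as.matrix(acc[, c("x", "y", "z")])
  d2 <- outer(rowSums(xd^2), rowSums(xa^2), "+") - 2 * tcrossprod(xd, xa)
  hit <- which(d2 >= min_dist^2 & d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  i <- hit[, 1]; j <- hit[, 2]
  same_chain <- don$chain[i] == acc$chain[j]
  near <- same_chain & abs(don$res_seq[i] - acc$res_seq[j]) <= 1
  i <- i[!near]; j <- j[!near]
  if (length(i) == 0) return(empty)
  out <- data.frame(
    donor_chain = don$chain[i], donor_res = don$res_seq[i],
    donor_res_name = don$res_name[i], donor_atom = don$atom_name[i],
    acceptor_chain = acc$chain[j], acceptor_res = acc$res_seq[j],
    acceptor_res_name = acc$res_name[j], acceptor_atom = acc$atom_name[j],
    distance = sqrt(pmax(0, d2[cbind(i, j)])),
    stringsAsFactors = FALSE
  )
  # drop symmetric duplicates of the same atom pair
  k1 <- paste(out$donor_chain, out$donor_res, out$donor_atom)
  k2 <- paste(out$acceptor_chain, out$acceptor_res, out$acceptor_atom)
  key <- ifelse(k1 < k2, paste(k1, k2, sep = "|"), paste(k2, k1, sep = "|"))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$donor_res, out$acceptor_res), , drop = FALSE]
}

#' Salt bridges between acidic and basic side chains
#'
#' Reports Asp/Glu vs Lys/Arg/His pairs whose minimal carboxylate-oxygen to
#' amine/guanidinium-nitrogen distance is at or below the cutoff.
#'
#' @param s A `structure3d`.
#' @param cutoff Distance cutoff in angstrom (default 4.0).
#' @param chain Chain identifier (`NULL`: any).
#' @return data.frame: acidic residue, basic residue, `min_distance`.
#' @export
salt_bridges <- function(s, cutoff = 4.0, chain = NULL) {
  sp <- protein_heavy(s)
  if (!is.null(chain)) sp <- select_atoms(sp, chain = chain)
  a <- atom_table(sp)
  pick <- function(dict) {
    sel <- mapply(function(rn, an) an %in% dict[[rn]], a$res_name, a$atom_name)
    a[!is.na(sel) & sel, , drop = FALSE]
  }
  ac <- pick(ACID_ATOMS); ba <- pick(BASE_ATOMS)
  empty <- data.frame(acid_chain = character(), acid_res = integer(),
                      acid_res_name = character(), base_chain = character(),
                      base_res = integer(), base_res_name = character(),
                      min_distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(ac) == 0 || nrow(ba) == 0) return(empty)
  xa <- as.matrix(ac[, c("x", "y", "z")])
  xb <- as.matrix(ba[, c("x", "y", "z")])
  d <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d[d < 0] <- 0
  d <- sqrt(d)
  ka <- paste(ac$chain, ac$res_seq)
  kb <- paste(ba$chain, ba$res_seq)
  out <- empty
  for (ra in unique(ka)) for (rb in unique(kb)) {
    md <- min(d[ka == ra, kb == rb])
    if (md <= cutoff) {
      ia <- which(ka == ra)[1]; ib <- which(kb == rb)[1]
      out <- rbind(out, data.frame(
        acid_chain = ac$chain[ia], acid_res = ac$res_seq[ia],
        acid_res_name = ac$res_name[ia], base_chain = ba$chain[ib],
        base_res = ba$res_seq[ib], base_res_name = ba$res_name[ib],
        min_distance = md, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Intracellular polar network among named residues
#'
#' Side-chain to side-chain polar contacts (hydrogen-bond distance window)
#' restricted to a set of member residues, plus the connected components they
#' form. Missing members produce a warning, not an error.
#'
#' @param s A `structure3d`.
#' @param members Residue numbers of the candidate network members
#'   (default: Q141, K145, H206, Q227, Q264).
#' @param cutoff Distance cutoff in angstrom.
#' @param chain Chain identifier (`NULL`: any).
#' @return List with `bonds` (as [hydrogen_bonds()], side chains only,
#'   members only) and `components` (list of residue-number vectors).
#' @export
ic_polar_network <- function(s, members = c(141, 145, 206, 227, 264),
                             cutoff = 3.5, chain = NULL) {
  present <- unique(protein_heavy(s)$atoms$res_seq)
  gone <- setdiff(members, present)
  if (length(gone) > 0) {
    warning("ic_polar_network: member residue(s) not modelled: ",
            paste(gone, collapse = ", "))
    members <- setdiff(members, gone)
  }
  sel <- select_atoms(s, chain = chain, residues = members)
  hb <- hydrogen_bonds(sel, cutoff = cutoff, side_chain_only = TRUE)
  # connected components over member residues (union-find)
  parent <- stats::setNames(members, members)
  find <- function(x) { while (parent[[as.character(x)]] != x)
    x <- parent[[as.character(x)]]; x }
  if (nrow(hb) > 0) for (r in seq_len(nrow(hb))) {
    ra <- find(hb$donor_res[r]); rb <- find(hb$acceptor_res[r])
    if (ra != rb) parent[[as.character(ra)]] <- rb
  }
  roots <- vapply(members, find, numeric(1))
  comp <- split(members, roots)
  comp <- comp[order(-lengths(comp))]
  names(comp) <- NULL
  list(bonds = hb, components = comp)
}

#' Hydrophobic core layers of the TM bundle
#'
#' A hydrophobic residue (Ala/Val/Leu/Ile/Met/Phe/Trp/Pro) on a TM helix is
#' core-facing when its side-chain centre of mass lies closer to the bundle
#' axis than its CA atom does. Core-facing residues are grouped into layers
#' along the membrane normal by single-linkage clustering of their CA
#' z-coordinates with a gap threshold, and layers are numbered from the
#' extracellular side (layer 1 is the most extracellular).
#'
#' @param s A `structure3d`.
#' @param frame A `membrane_frame`.
#' @param seg A `segment_map`; helix segments define the candidate residues.
#' @param chain Chain identifier (`NULL`: any).
#' @param gap Z-gap (angstrom) separating layers (default 3).
#' @return data.frame: `res_seq`, `res_name`, `segment`, `z`, `core_facing`,
#'   `layer` (NA for non-core-facing residues).
#' @export
hydrophobic_layers <- function(s, frame, seg = default_segment_map(),
                               chain = NULL, gap = 3.0) {
  helices <- grep("^helix", seg$name, value = TRUE)
  res <- segment_residues(seg, helices)
  sp <- protein_heavy(s)
  if (!is.null(chain)) sp <- select_atoms(sp, chain = chain)
  a <- atom_table(sp)
  a <- a[a$res_seq %in% res & a$res_name %in% HYDROPHOBIC_RES, , drop = FALSE]
  if (nrow(a) == 0)
    return(data.frame(res_seq = integer(), res_name = character(),
                      segment = character(), z = numeric(),
                      core_facing = logical(), layer = integer()))
  keys <- unique(a[, c("chain", "res_seq", "res_name")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    r <- a[a$chain == keys$chain[k] & a$res_seq == keys$res_seq[k], ,
           drop = FALSE]
    ca <- r[r$atom_name == "CA", c("x", "y", "z"), drop = FALSE]
    sc <- r[!(r$atom_name %in% BACKBONE_ATOMS), , drop = FALSE]
    if (nrow(ca) == 0 || nrow(sc) == 0) return(NULL)
    sc_com <- center_of_mass(as.matrix(sc[, c("x", "y", "z")]),
                             weighting = "mass", elements = sc$element)
    data.frame(res_seq = keys$res_seq[k], res_name = keys$res_name[k],
               segment = segment_of(keys$res_seq[k], seg),
               z = frame_z(as.matrix(ca), frame)[1],
               core_facing = frame_radial(matrix(sc_com, ncol = 3), frame) <
                 frame_radial(as.matrix(ca), frame),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(res_seq = integer(), res_name = character(),
                      segment = character(), z = numeric(),
                      core_facing = logical(), layer = integer()))
  out <- out[order(-out$z), , drop = FALSE]
  rownames(out) <- NULL
  out$layer <- NA_integer_
  cf <- which(out$core_facing)
  if (length(cf) > 0) {
    z <- out$z[cf] # descending
    lay <- cumsum(c(1, diff(z) < -gap)) # new layer when gap exceeded
    out$layer[cf] <- lay
  }
  out
}

#' Membrane-normal span between the boundary reference residues
#'
#' The z-extent, along the membrane normal, between the CA atoms of the
#' extracellular and intracellular boundary reference residues; the bundle's
#' span across the bilayer. Invariant under rigid motions of the input.
#'
#' @param s A `structure3d`.
#' @param frame A `membrane_frame`.
#' @param chain Chain identifier (`NULL`: any).
#' @return Span in angstrom.
#' @export
helix_span <- function(s, frame, chain = NULL) {
  ca <- function(r) {
    sel <- select_atoms(s, chain = chain, residues = r, atom_names = "CA")
    if (nrow(sel$atoms) == 0)
      stop("helix_span: boundary reference residue ", r, " missing")
    coords(sel)[1, ]
  }
  frame_z(ca(frame$boundary_refs[["extracellular"]]), frame) -
    frame_z(ca(frame$boundary_refs[["intracellular"]]), frame)
}

# principal axis of a CA trace, oriented N-terminus -> C-terminus; the trace
# is first smoothed with a 4-residue running centroid (about one helical
# turn), which places the smoothed points on the helix axis and removes the
# spiral wobble of short arms
directed_axis <- function(xyz) {
  n <- nrow(xyz)
  if (n >= 6) {
    w <- 4
    sm <- vapply(seq_len(n - w + 1), function(i)
      colMeans(xyz[i:(i + w - 1), , drop = FALSE]), numeric(3))
    xyz <- t(sm)
  }
  c0 <- colMeans(xyz)
  v <- svd(sweep(xyz, 2, c0), nu = 0, nv = 1)$v[, 1]
  if (sum((xyz[nrow(xyz), ] - xyz[1, ]) * v) < 0) v <- -v
  v
}

#' Kink angle of a helix about a pivot residue
#'
#' Angle between the directed principal axes of the CA atoms before and after
#' the pivot (pivot excluded from both arms). A straight helix gives ~0
#' degrees; a proline-broken helix gives the bend angle.
#'
#' @param s A `structure3d`.
#' @param seg A `segment_map`.
#' @param helix Helix segment name (default `"helix I"`).
#' @param pivot Pivot residue number (default 131).
#' @param chain Chain identifier (`NULL`: any).
#' @return Kink angle in degrees.
#' @export
kink_angle <- function(s, seg = default_segment_map(), helix = "helix I",
                       pivot = 131, chain = NULL) {
  rng <- segment_lookup(seg, helix)
  ca <- select_atoms(s, chain = chain,
                     residues = seq(rng["start"], rng["end"]),
                     atom_names = "CA")
  at <- atom_table(ca)
  pre <- at[at$res_seq < pivot, c("x", "y", "z"), drop = FALSE]
  post <- at[at$res_seq > pivot, c("x", "y", "z"), drop = FALSE]
  if (nrow(pre) < 4 || nrow(post) < 4)
    stop("kink_angle: need >= 4 CA on each side of the pivot (have ",
         nrow(pre), " and ", nrow(post), ")")
  v1 <- directed_axis(as.matrix(pre))
  v2 <- directed_axis(as.matrix(post))
  acos(pmin(1, pmax(-1, sum(v1 * v2)))) * 180 / pi
}
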