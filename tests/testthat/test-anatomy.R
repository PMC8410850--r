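test_that("membrane frame recovers the bundle axis and sign convention", {
  # straight parallel helices along lab z: axis is exactly (0,0,1)
  toy <- make_toy_receptor(helix_radius = 0)$structure
  fr <- build_frame(toy)
  expect_equal(abs(fr$z_axis[3]), 1, tolerance = 1e-3)
  expect_lt(max(abs(fr$z_axis[1:2])), 1e-3)
  # sign convention: extracellular reference above the plane
  z123 <- tmanatomy:::frame_z(coords(select_atoms(toy, residues = 123,
                                                  atom_names = "CA")), fr)
  z274 <- tmanatomy:::frame_z(coords(select_atoms(toy, residues = 274,
                                                  atom_names = "CA")), fr)
  expect_gt(z123, 0)
  expect_lt(z274, 0)
  # equivariance: a rigidly rotated bundle gives the rotated axis
  set.seed(11)
  R <- fx_rotation()
  rot <- apply_transform(toy, fx_rigid(R, c(5, -3, 2)))
  fr_rot <- build_frame(rot)
  expect_equal(abs(sum(fr_rot$z_axis * as.vector(R %*% fr$z_axis))), 1,
               tolerance = 1e-3)
  expect_error(build_frame(select_atoms(toy, residues = setdiff(
    unique(toy$atoms$res_seq), 123))), "123")
})

test_that("ECD tilt hits its analytic limits and recovers planted angles", {
  toy90 <- make_toy_receptor(tilt_deg = 90, helix_radius = 0)$structure
  toy0 <- make_toy_receptor(tilt_deg = 0, helix_radius = 0)$structure
  expect_equal(ecd_tilt(toy90, build_frame(toy90)), 90, tolerance = 1e-6)
  expect_equal(ecd_tilt(toy0, build_frame(toy0)), 0, tolerance = 1e-6)
  for (t in c(5, 17, 20, 40, 45, 55, 62, 70, 80, 85)) {
    s <- make_toy_receptor(tilt_deg = t)$structure
    got <- ecd_tilt(s, build_frame(s))
    expect_true(got >= 0 && got <= 90)
    expect_lt(abs(got - t), 1)
  }
  s <- make_toy_receptor()$structure
  expect_error(ecd_tilt(select_atoms(s, residues = setdiff(
    unique(s$atoms$res_seq), 33)), build_frame(s)), "33")
})

test_that("segment contacts respect the cutoff boundary exactly", {
  # two CA atoms across helix I / helix II at controlled separation
  mk <- function(d) {
    at <- fx_atoms(c(130, 170), "GLY", c("CA", "CA"))
    fx_structure(at, rbind(c(0, 0, 0), c(d, 0, 0)))
  }
  seg <- default_segment_map()
  expect_equal(nrow(segment_contacts(mk(3.49), seg, "helix II")), 1)
  expect_equal(nrow(segment_contacts(mk(3.51), seg, "helix II")), 0)
  expect_error(segment_contacts(mk(3), seg, "helix IX"), "unknown segment")
})

test_that("segment contacts equal a brute-force pair scan and are monotone", {
  toy <- make_toy_receptor(tier_z = c(10, 0, -8))$structure
  seg <- default_segment_map()
  got <- segment_contacts(toy, seg, "helix III", cutoff = 4.5)
  # exhaustive O(n^2) oracle over heavy atoms
  a <- atom_table(tmanatomy:::protein_heavy(toy))
  a$segment <- tmanatomy:::segment_of(a$res_seq, seg)
  a <- a[!is.na(a$segment), ]
  oracle <- 0
  ta <- a[a$segment == "helix III", ]; ob <- a[a$segment != "helix III", ]
  for (i in seq_len(nrow(ta))) for (j in seq_len(nrow(ob))) {
    d <- sqrt(sum((c(ta$x[i], ta$y[i], ta$z[i]) -
                     c(ob$x[j], ob$y[j], ob$z[j]))^2))
    if (d <= 4.5 && !(ta$chain[i] == ob$chain[j] &&
                      abs(ta$res_seq[i] - ob$res_seq[j]) <= 1))
      oracle <- oracle + 1
  }
  expect_equal(nrow(got), oracle)
  # monotone in the cutoff over the documented [3, 5] range
  key <- function(d) paste(d$res_a, d$atom_a, d$res_b, d$atom_b)
  prev <- character(0)
  for (cut in c(3, 3.5, 4, 4.5, 5)) {
    cur <- key(segment_contacts(toy, seg, "helix III", cutoff = cut))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("hydrogen bonds detect donor-acceptor pairs in the window", {
  # Tyr OH vs backbone carbonyl O at 2.9 A, and amide N at 3.0 A
  at <- rbind(fx_atoms(10, "TYR", "OH", "O"),
              fx_atoms(50, "ILE", "O", "O"),
              fx_atoms(52, "ALA", "N", "N"))
  s <- fx_structure(at, rbind(c(0, 0, 0), c(2.9, 0, 0), c(0, 3.0, 0)))
  hb <- hydrogen_bonds(s)
  expect_equal(nrow(hb), 2)
  expect_equal(sort(round(hb$distance, 2)), c(2.9, 3.0))
  far <- fx_structure(at[1:2, ], rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(nrow(hydrogen_bonds(far)), 0)
  # below the lower window bound: counts as covalent-range, not a bond
  clash <- fx_structure(at[1:2, ], rbind(c(0, 0, 0), c(2.0, 0, 0)))
  expect_equal(nrow(hydrogen_bonds(clash)), 0)
})

test_that("salt bridges match construction and a brute-force scan", {
  glu <- fx_atoms(c(1, 1), "GLU", c("OE1", "OE2"), "O")
  lys <- fx_atoms(5, "LYS", "NZ", "N")
  near <- fx_structure(rbind(glu, lys),
                       rbind(c(0, 0, 0), c(-1, 1, 0), c(3, 0, 0)))
  got <- salt_bridges(near)
  expect_equal(nrow(got), 1)
  expect_equal(got$min_distance, 3)
  far <- fx_structure(rbind(glu, lys),
                      rbind(c(0, 0, 0), c(-1, 1, 0), c(4.5, 0, 0)))
  expect_equal(nrow(salt_bridges(far)), 0)
  # 10-residue random acid/base field vs exhaustive pair scan
  set.seed(3)
  rows <- list(); xyz <- list()
  for (r in 1:10) {
    if (r %% 2 == 1) {
      rows[[r]] <- fx_atoms(c(r, r), "ASP", c("OD1", "OD2"), "O")
      xyz[[r]] <- matrix(rnorm(6, 0, 4), 2)
    } else {
      rows[[r]] <- fx_atoms(r, "ARG", "NH1", "N")
      xyz[[r]] <- matrix(rnorm(3, 0, 4), 1)
    }
  }
  s <- fx_structure(do.call(rbind, rows), do.call(rbind, xyz))
  got <- salt_bridges(s, cutoff = 4)
  a <- atom_table(s)
  oracle <- 0
  for (ra in seq(1, 9, 2)) for (rb in seq(2, 10, 2)) {
    xa <- as.matrix(a[a$res_seq == ra, c("x", "y", "z")])
    xb <- as.matrix(a[a$res_seq == rb, c("x", "y", "z")])
    dmin <- min(sqrt(outer(rowSums(xa^2), rowSums(xb^2), "+") -
                       2 * tcrossprod(xa, xb)))
    if (dmin <= 4) oracle <- oracle + 1
  }
  expect_equal(nrow(got), oracle)
})

test_that("the IC polar network is a subset of general hydrogen bonds", {
  # glutamine cluster: three side-chain amides within bonding distance
  at <- rbind(fx_atoms(141, "GLN", "NE2", "N"),
              fx_atoms(206, "HIS", "NE2", "N"),
              fx_atoms(227, "GLN", "OE1", "O"),
              fx_atoms(264, "GLN", "OE1", "O"))
  s <- fx_structure(at, rbind(c(0, 0, 0), c(20, 0, 0),
                              c(2.9, 0.5, 0), c(20, 2.8, 0)))
  net <- suppressWarnings(ic_polar_network(s))
  all_hb <- hydrogen_bonds(s, side_chain_only = TRUE)
  key <- function(d) paste(d$donor_res, d$donor_atom,
                           d$acceptor_res, d$acceptor_atom)
  expect_true(all(key(net$bonds) %in% key(all_hb)))
  expect_equal(nrow(net$bonds), 2)
  # two components: {141,227} and {206,264}, plus missing 145 warned
  expect_warning(ic_polar_network(s), "145")
  sizes <- sort(lengths(net$components), decreasing = TRUE)
  expect_equal(sizes[1:2], c(2, 2))
  # all members far apart: empty network
  far <- fx_structure(at, rbind(c(0, 0, 0), c(10, 0, 0),
                                c(20, 0, 0), c(30, 0, 0)))
  expect_equal(nrow(suppressWarnings(ic_polar_network(far))$bonds), 0)
})

test_that("hydrophobic layers count planted z-tiers and face the core", {
  lay <- make_toy_receptor(tier_z = c(12, 4, -6), side_chains = "in")
  s <- lay$structure
  hl <- hydrophobic_layers(s, build_frame(s))
  expect_equal(max(hl$layer, na.rm = TRUE), 3)
  expect_equal(sum(hl$core_facing), 15) # 5 helices x 3 tiers
  # layer 1 is the most extracellular tier
  expect_true(all(hl$z[!is.na(hl$layer) & hl$layer == 1] >
                    hl$z[!is.na(hl$layer) & hl$layer == 2]))
  # outward-pointing side chains: zero core-facing residues
  out <- make_toy_receptor(tier_z = c(12, 4, -6), side_chains = "out")
  hl_out <- hydrophobic_layers(out$structure, build_frame(out$structure))
  expect_equal(sum(hl_out$core_facing), 0)
})

test_that("membrane span matches an ideal helix and survives rotation", {
  # ideal 22-residue helix along z, refs at its ends: 21 x 1.5 = 31.5 A
  ca <- tmanatomy:::helix_ca(22, 0, 0, 0, direction = -1)
  at <- fx_atoms(123:144, "GLY", "CA")
  s <- fx_structure(at, ca)
  fr <- structure(list(origin = colMeans(ca), z_axis = c(0, 0, 1),
                       boundary_refs = c(extracellular = 123,
                                         intracellular = 144)),
                  class = "membrane_frame")
  expect_equal(helix_span(s, fr), 31.5, tolerance = 1e-9)
  # full toy receptor: span equals the generator's planted truth
  toy <- make_toy_receptor()
  fr2 <- build_frame(toy$structure)
  expect_equal(helix_span(toy$structure, fr2), toy$truth$span,
               tolerance = 0.2)
  set.seed(5)
  rot <- apply_transform(toy$structure, fx_rigid(fx_rotation(), c(9, 9, 9)))
  expect_equal(helix_span(rot, build_frame(rot)),
               helix_span(toy$structure, fr2), tolerance = 1e-3)
})

test_that("kink angle is ~0 for straight helices and recovers a planted bend", {
  toy <- make_toy_receptor()$structure
  expect_lt(kink_angle(toy), 1.5)
  # two ideal arms with a planted 30 degree bend, numbered inside helix I
  arm1 <- tmanatomy:::helix_ca(9, 0, 0, 0, direction = 1)
  th <- 30 * pi / 180
  Ry <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
               3, 3, byrow = TRUE)
  arm2 <- tmanatomy:::helix_ca(9, 0, 0, 0, direction = 1)
  arm2 <- sweep(arm2, 2, arm2[1, ]) %*% t(Ry)
  arm2 <- sweep(arm2, 2, arm1[9, ] + c(0, 0, 1.5), "+")
  xyz <- rbind(arm1, (arm1[9, ] + arm2[1, ]) / 2, arm2)
  s <- fx_structure(fx_atoms(121:139, "GLY", "CA"), xyz)
  expect_equal(kink_angle(s, pivot = 130), 30, tolerance = 1.5)
  expect_error(kink_angle(select_atoms(s, residues = 128:139), pivot = 130),
               ">= 4")
})

test_that("anatomy scalars are invariant under rigid motions", {
  toy <- make_toy_receptor(tilt_deg = 62, tier_z = c(10, -2))$structure
  fr <- build_frame(toy)
  base <- c(tilt = ecd_tilt(toy, fr), span = helix_span(toy, fr),
            kink = kink_angle(toy),
            contacts = nrow(segment_contacts(toy, cutoff = 5)))
  set.seed(23)
  for (k in 1:3) {
    moved <- apply_transform(toy, fx_rigid(fx_rotation(), rnorm(3, 0, 20)))
    fr_m <- build_frame(moved)
    got <- c(tilt = ecd_tilt(moved, fr_m), span = helix_span(moved, fr_m),
             kink = kink_angle(moved),
             contacts = nrow(segment_contacts(moved, cutoff = 5)))
    expect_equal(got, base, tolerance = 1e-3)
  }
})
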