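# Ideal alpha-helix CA trace: 1.5 angstrom rise and 100 degree twist per
# residue on a circle of radius `helix_radius` about a vertical axis through
# (cx, cy), running from z_top downward (direction = -1) or upward (+1).
helix_ca <- function(n, cx, cy, z_center, direction = -1,
                     helix_radius = 2.3, rise = 1.5, phase = 0) {
  i <- seq_len(n) - 1
  z <- z_center - direction * rise * ((n - 1) / 2) + direction * rise * i
  th <- phase + i * 100 * pi / 180
  cbind(cx + helix_radius * cos(th), cy + helix_radius * sin(th), z)
}

#' Synthetic five-helix receptor with a rigid pseudo-ECD at a known tilt
#'
#' Builds a CA-trace model of the receptor: five ideal alpha-helices
#' (1.5 angstrom rise per residue, 100 degree twist, 2.3 angstrom helix
#' radius) on a pentagonal cross-section, numbered to match
#' [default_segment_map()] and alternating up/down through the membrane, each
#' centred on the membrane mid-plane; loop segments (linker, ECL1, ECL2) as
#' interpolated CA traces; and a rigid pseudo-ECD whose tip residues (32-36)
#' are placed so that the centre of mass of their CA atoms sits at exactly
#' the requested tilt angle from the bundle's own centre of mass. The
#' construction is deterministic: the planted tilt is ground truth up to the
#' (tiny) deviation of the bundle's principal axis from the build axis.
#'
#' Optionally plants core-facing leucine side chains (CB pseudo-atoms) in
#' prescribed z-tiers, one per helix per tier, to exercise the hydrophobic
#' layer detector with a known layer count.
#'
#' @param tilt_deg Planted ECD tilt in degrees, in [0, 90].
#' @param ecd_length Distance from bundle centre to the ECD tip (angstrom).
#' @param bundle_radius Pentagon circumradius (angstrom).
#' @param helix_radius Helix radius; 0 gives straight parallel CA lines.
#' @param tier_z Optional z-coordinates (angstrom) of planted core-facing
#'   side-chain tiers.
#' @param side_chains `"in"` (point toward the bundle axis) or `"out"`, for
#'   the planted tiers.
#' @param seed Kept for interface symmetry; the build is noise-free.
#' @return List with `structure` (a `structure3d`) and `truth` (planted
#'   tilt, tip coordinates, span between the CA atoms of the boundary
#'   references 123 and 274, and tier count).
#' @export
make_toy_receptor <- function(tilt_deg = 80, ecd_length = 40,
                              bundle_radius = 8, helix_radius = 2.3,
                              tier_z = NULL, side_chains = c("in", "out"),
                              seed = 1) {
  stopifnot(tilt_deg >= 0, tilt_deg <= 90)
  side_chains <- match.arg(side_chains)
  seg <- default_segment_map()
  helices <- grep("^helix", seg$name, value = TRUE)
  dirs <- c(-1, 1, -1, 1, -1) # N->C direction along z, alternating topology
  atoms <- list(); xyz <- list()
  add <- function(res_seq, res_name, atom_name, coord) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      chain = "A", res_seq = as.integer(res_seq), icode = "",
      res_name = res_name, atom_name = atom_name, element = "C",
      occupancy = 1, bfactor = 0, het = FALSE, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1]] <<- coord
  }
  named_res <- c(`32` = "ASN", `36` = "VAL", `118` = "TRP", `119` = "PHE",
                 `123` = "GLU", `183` = "GLU", `184` = "TYR", `187` = "LYS",
                 `242` = "ILE", `244` = "ALA", `245` = "CYS", `274` = "VAL")
  rname <- function(r) {
    nm <- unname(named_res[as.character(r)])
    if (is.na(nm)) "GLY" else nm
  }
  vert <- lapply(seq_along(helices), function(k) {
    ang <- 2 * pi * (k - 1) / 5 + pi / 2
    c(bundle_radius * cos(ang), bundle_radius * sin(ang))
  })
  ends <- list()
  for (k in seq_along(helices)) {
    rng <- segment_lookup(seg, helices[k])
    res <- seq(rng["start"], rng["end"])
    ca <- helix_ca(length(res), vert[[k]][1], vert[[k]][2], z_center = 0,
                   direction = dirs[k], helix_radius = helix_radius,
                   phase = (k - 1) * 2.4)
    for (i in seq_along(res)) add(res[i], rname(res[i]), "CA", ca[i, ])
    ends[[helices[k]]] <- list(first = ca[1, ], last = ca[length(res), ])
  }
  # planted core-facing tiers: one LEU CB per helix per tier, CB displaced
  # radially from the CA toward (in) or away from (out) the bundle axis
  n_tiers <- 0
  if (!is.null(tier_z)) {
    n_tiers <- length(tier_z)
    sign_sc <- if (side_chains == "in") -1 else 1
    for (k in seq_along(helices)) {
      rng <- segment_lookup(seg, helices[k])
      res <- seq(rng["start"], rng["end"])
      z_of <- vapply(res, function(r) {
        idx <- which(vapply(atoms, function(a) a$res_seq == r, logical(1)))
        xyz[[idx[1]]][3]
      }, numeric(1))
      for (tz in tier_z) {
        i <- which.min(abs(z_of - tz))
        idx <- which(vapply(atoms, function(a)
          a$res_seq == res[i] && a$atom_name == "CA", logical(1)))[1]
        atoms[[idx]]$res_name <- "LEU"
        ca <- xyz[[idx]]
        u <- c(ca[1], ca[2], 0)
        u <- u / sqrt(sum(u^2))
        add(res[i], "LEU", "CB", ca + sign_sc * 1.5 * u)
      }
    }
  }
  # loop segments as straight CA interpolations between helix ends
  interp_loop <- function(res, from, to, lift = 3) {
    n <- length(res)
    for (i in seq_len(n)) {
      f <- i / (n + 1)
      p <- (1 - f) * from + f * to
      p[3] <- p[3] + lift * sin(pi * f)
      add(res[i], rname(res[i]), "CA", p)
    }
  }
  interp_loop(179:185, ends[["helix II"]]$last, ends[["helix III"]]$first)
  interp_loop(243:250, ends[["helix IV"]]$last, ends[["helix V"]]$first)
  # bundle centre of mass (all helix CA, equal masses) and planted ECD
  helix_rows <- vapply(atoms, function(a)
    !is.na(segment_of(a$res_seq, seg)) &&
      grepl("^helix", segment_of(a$res_seq, seg)) && a$atom_name == "CA",
    logical(1))
  origin0 <- colMeans(do.call(rbind, xyz[helix_rows]))
  t_rad <- tilt_deg * pi / 180
  tip <- origin0 + ecd_length * c(cos(t_rad), 0, sin(t_rad))
  # tip residues 32-36: offsets sum to zero so the CA centre of mass is
  # exactly the planted tip point
  off <- (seq(32, 36) - 34) * 1.2
  for (i in seq_along(32:36))
    add((32:36)[i], rname((32:36)[i]), "CA", tip + c(0, off[i], 0))
  # a short ECD stalk and the linker down to helix I
  stalk_res <- 108:113
  top1 <- ends[["helix I"]]$first
  for (i in seq_along(stalk_res)) {
    f <- (i - 1) / (length(stalk_res))
    add(stalk_res[i], rname(stalk_res[i]), "CA",
        (1 - f * 0.4) * tip + (f * 0.4) * (top1 + c(0, 0, 8)))
  }
  interp_loop(114:120, (0.6 * tip + 0.4 * (top1 + c(0, 0, 8))),
              top1, lift = 0)
  at <- do.call(rbind, atoms)
  rownames(at) <- NULL
  s <- new_structure3d(at, list(do.call(rbind, xyz)),
                       source_id = "synthetic-toy-receptor")
  ca123 <- xyz[[which(at$res_seq == 123 & at$atom_name == "CA")[1]]]
  ca274 <- xyz[[which(at$res_seq == 274 & at$atom_name == "CA")[1]]]
  list(structure = s,
       truth = list(tilt_deg = tilt_deg, tip = tip, origin = origin0,
                    span = unname(ca123[3] - ca274[3]), n_tiers = n_tiers))
}

#' Synthetic two-state tilt trajectory with a known transition
#'
#' Gaussian observations about the first state's mean deviation before the
#' transition time and about the second state's after it, converted to tilt
#' angles theta = theta_ref - deviation (clipped to [0, 90] degrees). Frame
#' times are strictly increasing multiples of the spacing. Bit-reproducible
#' under a fixed seed.
#'
#' @param state_means Planted deviation means in degrees, ascending
#'   (defaults 17 and 40).
#' @param state_sds Planted SDs in degrees (defaults 6 and 3).
#' @param transition_ns Time of the planted switch (default 300).
#' @param frame_spacing_ns Frame spacing (default 0.1).
#' @param n_frames Number of frames (default 10000).
#' @param theta_ref Reference tilt in degrees (default 80).
#' @param seed RNG seed.
#' @return List with `table` (data.frame `time_ns`, `theta`) and `truth`
#'   (planted parameters, including per-frame state labels and occupancies).
#' @export
make_trajectory <- function(state_means = c(17, 40), state_sds = c(6, 3),
                            transition_ns = 300, frame_spacing_ns = 0.1,
                            n_frames = 10000, theta_ref = 80, seed = 1) {
  stopifnot(length(state_means) == 2, state_means[1] <= state_means[2],
            all(state_sds > 0))
  set.seed(seed)
  time_ns <- frame_spacing_ns * seq_len(n_frames)
  in_s2 <- time_ns >= transition_ns
  dev <- ifelse(in_s2,
                rnorm(n_frames, state_means[2], state_sds[2]),
                rnorm(n_frames, state_means[1], state_sds[1]))
  theta <- pmin(90, pmax(0, theta_ref - dev))
  list(table = data.frame(time_ns = time_ns, theta = theta),
       truth = list(state_means = state_means, state_sds = state_sds,
                    transition_ns = transition_ns, theta_ref = theta_ref,
                    occupancies = c(mean(!in_s2), mean(in_s2))))
}

#' Synthetic replicate HDX uptake records with planted uptake
#'
#' Mass shifts are back-computed from the planted percent uptake through the
#' inverse of the uptake formula (shift = uptake/100 x exchangeable amides x
#' D2O fraction) and replicate Gaussian noise is added on the mass shift.
#' With zero noise, [hdx_summarize()] recovers the planted uptake exactly.
#'
#' @param planted data.frame with columns `construct`, `start_res`,
#'   `end_res`, `sequence`, `timepoint_s`, `uptake_pct` (the ground truth).
#' @param noise_sd_da Gaussian noise SD on the mass shift, in Da.
#' @param replicates Replicates per cell (default 2).
#' @param d2o_fraction Deuterium fraction (default 0.917).
#' @param seed RNG seed.
#' @return List with `records` (ready for [hdx_summarize()]) and `truth`.
#' @export
make_hdx_tables <- function(planted, noise_sd_da = 0, replicates = 2,
                            d2o_fraction = 0.917, seed = 1) {
  stopifnot(all(planted$uptake_pct >= 0), all(planted$uptake_pct <= 110))
  set.seed(seed)
  mx <- max_exchangeable(planted$sequence)
  rows <- lapply(seq_len(nrow(planted)), function(i) {
    shift0 <- planted$uptake_pct[i] / 100 * mx[i] * d2o_fraction
    data.frame(construct = planted$construct[i],
               start_res = planted$start_res[i],
               end_res = planted$end_res[i],
               sequence = planted$sequence[i],
               timepoint_s = planted$timepoint_s[i],
               replicate = seq_len(replicates),
               mass_shift_da = pmax(-0.5, shift0 +
                                      rnorm(replicates, 0, noise_sd_da)),
               stringsAsFactors = FALSE)
  })
  list(records = do.call(rbind, rows), truth = planted)
}

#' Synthetic multiple sequence alignment with planted conserved columns
#'
#' A random reference sequence plus derived sequences mutated everywhere
#' except the planted conserved positions: at each non-conserved position,
#' with probability `mutation_rate`, the character is replaced by a
#' different residue (so at rate 1 every non-conserved column differs from
#' the reference in every derived sequence, and the absolutely conserved set
#' equals the planted set exactly).
#'
#' @param n_seqs Number of derived sequences (default 71).
#' @param ref_length Reference length (default 305).
#' @param conserved_positions Planted invariant positions (default 1:62).
#' @param mutation_rate Per-position mutation probability elsewhere.
#' @param seed RNG seed.
#' @return List with `msa` (an [new_msa()] object; reference id `"ref"`)
#'   and `truth`.
#' @export
make_msa <- function(n_seqs = 71, ref_length = 305,
                     conserved_positions = 1:62, mutation_rate = 1,
                     seed = 1) {
  stopifnot(all(conserved_positions >= 1),
            all(conserved_positions <= ref_length))
  set.seed(seed)
  ref <- sample(AA1, ref_length, replace = TRUE)
  mutable <- setdiff(seq_len(ref_length), conserved_positions)
  seqs <- vapply(seq_len(n_seqs), function(k) {
    s <- ref
    hit <- mutable[runif(length(mutable)) < mutation_rate]
    for (p in hit) s[p] <- sample(setdiff(AA1, ref[p]), 1)
    paste(s, collapse = "")
  }, character(1))
  ids <- c("ref", sprintf("sp%03d", seq_len(n_seqs)))
  list(msa = new_msa(ids, c(paste(ref, collapse = ""), seqs)),
       truth = list(conserved_positions = sort(conserved_positions),
                    mutation_rate = mutation_rate))
}
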