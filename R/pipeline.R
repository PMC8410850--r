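#' Default run configuration
#'
#' All tunable parameters of the analysis pipeline with their documented
#' defaults. A configuration round-trips through YAML serialisation.
#'
#' @return Named list of tunables.
#' @export
default_config <- function() {
  list(
    chain = NULL,
    contact_cutoff = 3.5,        # angstrom, inter-segment heavy-atom contacts
    hbond_cutoff = 3.5,          # angstrom, donor-acceptor upper bound
    hbond_min = 2.2,             # angstrom, lower bound
    saltbridge_cutoff = 4.0,     # angstrom, O-N
    probe_radius = 1.4,          # angstrom, SASA probe
    sasa_points = 960,           # sphere sample points per atom
    layer_gap = 3.0,             # angstrom, z-gap between hydrophobic layers
    tip_residues = 32:36,        # ECD tip (beta-hairpin) residues
    ec_ref = 123, ic_ref = 274,  # membrane boundary reference residues
    kink_pivot = 131,            # helix I proline kink
    smoothing_window_ns = 1.0,
    macrostate_restarts = 50,
    macrostate_seed = 1,
    macrostate_dwell_ns = 10,
    event_dwell_ns = 5,
    switch_threshold = 3.5,      # angstrom, Y184 in/out
    d2o_fraction = 0.917
  )
}

#' Write / read a run configuration (YAML)
#'
#' @param cfg Configuration list.
#' @param path File path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  base[names(cfg)] <- cfg
  base
}

#' Full static structural-anatomy report
#'
#' Runs the static analyses on one structure: membrane frame, ECD tilt,
#' membrane span, helix I kink, target-helix contacts, hydrogen bonds, salt
#' bridges, intracellular polar network, hydrophobic layers, the W118/F119
#' ring geometry and buried areas (the latter two only when the needed
#' side-chain atoms are modelled, as in all-atom input). Scalars are
#' returned with the parameters that produced them; tables and a JSON
#' summary are written when `out_dir` is given. Any stage failure aborts
#' with the stage name; tables already written are preserved.
#'
#' @param s A `structure3d` or a path readable by [read_structure()].
#' @param chain Chain identifier (`NULL`: any). An unknown chain is an error
#'   naming the available chains.
#' @param seg A `segment_map`.
#' @param cfg Configuration list from [default_config()].
#' @param out_dir Optional output directory for `contacts.tsv`,
#'   `hbonds.tsv`, `layers.tsv` and `summary.json`.
#' @return List with `scalars`, `contacts`, `hbonds`, `salt_bridges`,
#'   `ic_network`, `layers`, `parameters`.
#' @export
run_anatomy_report <- function(s, chain = NULL, seg = default_segment_map(),
                               cfg = default_config(), out_dir = NULL) {
  if (is.character(s)) s <- read_structure(s)
  stopifnot(inherits(s, "structure3d"))
  chains <- unique(s$atoms$chain)
  if (!is.null(chain) && !all(chain %in% chains))
    stop("chain '", paste(setdiff(chain, chains), collapse = ","),
         "' not present; available chains: ", paste(chains, collapse = ", "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("anatomy report failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE))
  }
  frame <- stage("build_frame",
                 build_frame(s, seg, chain, cfg$ec_ref, cfg$ic_ref))
  tilt <- stage("ecd_tilt", ecd_tilt(s, frame, cfg$tip_residues, chain))
  span <- stage("helix_span", helix_span(s, frame, chain))
  kink <- stage("kink_angle",
                tryCatch(kink_angle(s, seg, "helix I", cfg$kink_pivot, chain),
                         error = function(e) NA_real_))
  contacts <- stage("segment_contacts",
                    segment_contacts(s, seg, "helix III",
                                     cfg$contact_cutoff, chain))
  hbonds <- stage("hydrogen_bonds",
                  hydrogen_bonds(s, cfg$hbond_cutoff, cfg$hbond_min, chain))
  sbr <- stage("salt_bridges", salt_bridges(s, cfg$saltbridge_cutoff, chain))
  icn <- stage("ic_polar_network",
               suppressWarnings(ic_polar_network(s, cutoff = cfg$hbond_cutoff,
                                                 chain = chain)))
  layers <- stage("hydrophobic_layers",
                  hydrophobic_layers(s, frame, seg, chain, cfg$layer_gap))
  has_atoms <- function(res, names) {
    a <- s$atoms
    all(vapply(names, function(nm) any(a$res_seq == res & a$atom_name == nm),
               logical(1)))
  }
  ring <- if (has_atoms(118, RING_ATOMS$TRP) && has_atoms(119, RING_ATOMS$PHE))
    stage("ring_geometry", ring_geometry(s, 118, 119, chain)) else NULL
  swf_burial <- if (!is.null(ring))
    stage("buried_area_swf",
          buried_area(s, c(118, 119), chain, side_chain_only = TRUE,
                      cfg$probe_radius, cfg$sasa_points)) else NULL
  scalars <- list(
    ecd_tilt_deg = tilt, helix_span_A = span, kink_angle_deg = kink,
    n_contacts = nrow(contacts),
    contact_partner_segments = sort(unique(contacts$segment_b)),
    n_hbonds = nrow(hbonds), n_salt_bridges = nrow(sbr),
    ring_interplanar_deg = if (is.null(ring)) NA_real_
    else ring$interplanar_angle,
    swf_buried_A2 = if (is.null(swf_burial)) NA_real_ else swf_burial$buried,
    layer1_residues = layers$res_seq[!is.na(layers$layer) &
                                       layers$layer == 1]
  )
  out <- list(scalars = scalars, contacts = contacts, hbonds = hbonds,
              salt_bridges = sbr, ic_network = icn, layers = layers,
              frame = frame, parameters = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(d, f) utils::write.table(
      d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(contacts, "contacts.tsv")
    wt(hbonds, "hbonds.tsv")
    wt(layers, "layers.tsv")
    jsonlite::write_json(
      list(scalars = scalars,
           parameters = cfg[!vapply(cfg, is.null, logical(1))]),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' End-to-end demonstration on synthetic inputs
#'
#' Generates every synthetic input class, runs the corresponding analyses
#' and compares recovered quantities with the planted ground truth: ECD tilt
#' on the toy receptor, macrostate means/transition on a two-state
#' trajectory, switch and salt-bridge event times on planted distance
#' tables, HDX uptake and a planted differential, and the conserved-column
#' count of a planted alignment.
#'
#' @param seed Seed driving every stochastic generator.
#' @param out_dir Optional directory for a JSON summary.
#' @return List of per-analysis recoveries, each with `planted`,
#'   `recovered`, `ok`.
#' @export
run_full_demo <- function(seed = 1, out_dir = NULL) {
  toy <- make_toy_receptor(tilt_deg = 80)
  rep_an <- run_anatomy_report(toy$structure)
  tilt_chk <- list(planted = toy$truth$tilt_deg,
                   recovered = rep_an$scalars$ecd_tilt_deg)
  tilt_chk$ok <- abs(tilt_chk$recovered - tilt_chk$planted) < 1

  tr <- make_trajectory(seed = seed)
  ts <- tilt_series(tr$table, theta_ref = tr$truth$theta_ref)
  ms <- find_macrostates(ts, seed = seed)
  macro_chk <- list(planted = tr$truth$state_means,
                    recovered = ms$state_means,
                    planted_transition = tr$truth$transition_ns,
                    recovered_transition = ms$transition_time_ns)
  macro_chk$ok <- all(abs(macro_chk$recovered - macro_chk$planted) < 2) &&
    abs(macro_chk$recovered_transition - macro_chk$planted_transition) < 20

  set.seed(seed + 1)
  t_sw <- seq(0.5, 1000, by = 0.5)
  sw_tab <- data.frame(time_ns = t_sw,
                       value = ifelse(t_sw < 300, 2.9, 6.0) +
                         rnorm(length(t_sw), 0, 0.05))
  sw <- track_switch(sw_tab)
  sb_tab <- data.frame(time_ns = t_sw,
                       value = ifelse(t_sw < 200, 7.0, 3.0) +
                         rnorm(length(t_sw), 0, 0.05))
  sb <- saltbridge_occupancy(sb_tab)
  events_chk <- list(planted = c(switch = 300, saltbridge = 200),
                     recovered = c(switch = sw$switch_time_ns,
                                   saltbridge = sb$first_formation_ns))
  events_chk$ok <- all(abs(events_chk$recovered - events_chk$planted) < 5)

  planted <- data.frame(
    construct = rep(c("WT", "MUT"), each = 2),
    start_res = 111, end_res = 126, sequence = "RNDCEQGHILKMFSTW",
    timepoint_s = c(20, 3600, 20, 3600),
    uptake_pct = c(30, 50, 40, 60), stringsAsFactors = FALSE)
  hx <- make_hdx_tables(planted, noise_sd_da = 0.05, replicates = 2,
                        seed = seed)
  sm <- hdx_summarize(hx$records)
  diffs <- hdx_differential(sm[sm$construct == "WT", ],
                            sm[sm$construct == "MUT", ])
  hdx_chk <- list(planted_delta = 10,
                  recovered_delta = mean(diffs$comparison$delta))
  hdx_chk$ok <- abs(hdx_chk$recovered_delta - 10) < 3

  msa <- make_msa(seed = seed)
  cons <- absolute_conservation(msa$msa, "ref")
  cons_chk <- list(planted = length(msa$truth$conserved_positions),
                   recovered = cons$count)
  cons_chk$ok <- cons_chk$recovered == cons_chk$planted

  out <- list(tilt = tilt_chk, macrostates = macro_chk, events = events_chk,
              hdx = hdx_chk, conservation = cons_chk,
              all_ok = tilt_chk$ok && macro_chk$ok && events_chk$ok &&
                hdx_chk$ok && cons_chk$ok)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(out, file.path(out_dir, "demo_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
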