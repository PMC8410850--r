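#' Tilt-angle time series from a trajectory
#'
#' For structural input, every frame's TM-helix backbone is superposed onto
#' the reference structure, the whole frame is moved by that fit, and the ECD
#' tilt is measured in the reference's membrane frame; this makes the series
#' invariant to rigid motions of the stored frames. Alternatively a
#' precomputed table of per-frame angles can be supplied. The deviation is
#' theta_ref - theta_t, the angle away from the reference (starting)
#' orientation, so larger deviation means tilted further toward the membrane.
#'
#' @param x Either a multi-model `structure3d`, or a data.frame with columns
#'   `time_ns` and `theta` (degrees, tilt relative to the membrane plane).
#' @param ref Reference `structure3d` (required for structural input; for
#'   table input it may supply `theta_ref`).
#' @param time_ns Frame times in ns for structural input (vector, or single
#'   spacing).
#' @param theta_ref Reference tilt in degrees for table input; defaults to
#'   the tilt of `ref` if given.
#' @param seg,tip_residues,chain Passed to [build_frame()] / [ecd_tilt()].
#' @return A `tilt_series`: data.frame with `time_ns`, `theta`, `deviation`,
#'   `smoothed` (NA until [rolling_average()] is applied), with attribute
#'   `theta_ref`.
#' @export
tilt_series <- function(x, ref = NULL, time_ns = NULL, theta_ref = NULL,
                        seg = default_segment_map(), tip_residues = 32:36,
                        chain = NULL) {
  if (is.data.frame(x)) {
    th_col <- intersect(c("theta", "value"), names(x))[1]
    if (!("time_ns" %in% names(x)) || is.na(th_col))
      stop("table input needs columns time_ns and theta (or value)")
    if (is.null(theta_ref)) {
      if (is.null(ref)) stop("supply theta_ref (or a reference structure)")
      fr <- build_frame(ref, seg, chain)
      theta_ref <- ecd_tilt(ref, fr, tip_residues, chain)
    }
    out <- data.frame(time_ns = x$time_ns, theta = x[[th_col]])
  } else if (inherits(x, "structure3d")) {
    if (is.null(ref)) stop("structural input needs a reference structure")
    n <- length(x$models)
    if (is.null(time_ns)) time_ns <- seq_len(n)
    if (length(time_ns) == 1) time_ns <- time_ns * seq_len(n)
    helices <- grep("^helix", seg$name, value = TRUE)
    bb_res <- segment_residues(seg, helices)
    fr <- build_frame(ref, seg, chain)
    theta_ref2 <- ecd_tilt(ref, fr, tip_residues, chain)
    if (is.null(theta_ref)) theta_ref <- theta_ref2
    ref_bb <- select_atoms(protein_heavy(ref), chain = chain,
                           residues = bb_res, atom_names = BACKBONE_ATOMS)
    bb_idx <- which(!x$atoms$het & x$atoms$atom_name %in% BACKBONE_ATOMS &
                      x$atoms$res_seq %in% bb_res &
                      (if (is.null(chain)) TRUE else x$atoms$chain %in% chain))
    if (length(bb_idx) != nrow(ref_bb$atoms))
      stop("tilt_series: TM backbone atom sets differ between trajectory (",
           length(bb_idx), ") and reference (", nrow(ref_bb$atoms), ")")
    theta <- vapply(seq_len(n), function(m) {
      mob_bb <- x$models[[m]][bb_idx, , drop = FALSE]
      tr <- superpose(mob_bb, coords(ref_bb))
      frame_s <- new_structure3d(x$atoms,
                                 list(apply_transform(x$models[[m]], tr)),
                                 x$source_id)
      tryCatch(ecd_tilt(frame_s, fr, tip_residues, chain),
               error = function(e) stop("tilt_series: frame ", m, ": ",
                                        conditionMessage(e)))
    }, numeric(1))
    out <- data.frame(time_ns = time_ns, theta = theta)
  } else stop("x must be a structure3d or a data.frame")
  if (is.unsorted(out$time_ns, strictly = TRUE))
    stop("time_ns must be strictly increasing")
  out$deviation <- theta_ref - out$theta
  out$smoothed <- NA_real_
  attr(out, "theta_ref") <- theta_ref
  class(out) <- c("tilt_series", "data.frame")
  out
}

#' Centred rolling time average of a tilt series
#'
#' Mean of the deviation over all frames within +/- window/2 of each frame's
#' time; truncated windows at the edges. Fills the `smoothed` column.
#'
#' @param series A `tilt_series`.
#' @param window Window width in ns (default 1).
#' @return The series with `smoothed` filled.
#' @export
rolling_average <- function(series, window = 1.0) {
  if (window <= 0) stop("window must be positive")
  t <- series$time_ns
  v <- series$deviation
  lo <- findInterval(t - window / 2, t, left.open = TRUE) + 1
  hi <- findInterval(t + window / 2, t)
  cs <- c(0, cumsum(v))
  series$smoothed <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  series
}

#' Frequency distribution of tilt deviations
#'
#' @param series A `tilt_series`.
#' @param bin_width Bin width in degrees (default 1).
#' @return List with `centers` (degrees) and `freq` (normalised to sum 1).
#' @export
deviation_histogram <- function(series, bin_width = 1.0) {
  x <- series$deviation
  if (length(x) == 0) stop("empty series")
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  idx <- pmin(length(breaks) - 1,
              pmax(1, findInterval(x, breaks, rightmost.closed = TRUE)))
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  list(centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
       freq = counts / sum(counts))
}

# one EM run of a 1-D Gaussian mixture from given initial parameters
em_1d <- function(x, mu, sigma, w, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  k <- length(mu)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    r <- dens / tot
    nk <- pmax(colSums(r), 1e-8)
    w <- nk / sum(nk)
    mu <- colSums(r * x) / nk
    sigma <- sqrt(vapply(seq_len(k), function(j)
      sum(r[, j] * (x - mu[j])^2) / nk[j], numeric(1)))
    sigma <- pmax(sigma, 1e-3)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, w = w, loglik = ll, iter = it,
       converged = it < max_iter)
}

#' Identify tilt macrostates by Gaussian mixture modelling
#'
#' Fits a Gaussian mixture to the deviation series by EM with multiple
#' restarts (k-means initialisation on the 1-ns smoothed series under a fixed
#' seed; best likelihood kept). States are reported in ascending order of
#' mean deviation, so state 1 is the orientation closest to the reference.
#' The transition time into the higher-deviation state is the first time the
#' smoothed series enters within one state SD of that state's mean and stays
#' there for at least `dwell_ns`.
#'
#' @param series A `tilt_series` with at least 200 frames.
#' @param n_states 1, 2, or `"auto"` (BIC choice between 1 and 2).
#' @param restarts EM restarts (default 50).
#' @param seed RNG seed for the restarts (default 1).
#' @param window Smoothing window in ns used for initialisation and for the
#'   transition rule (default 1).
#' @param dwell_ns Minimum sustained time in the target state (default 10).
#' @return A `macrostate_summary`: list with `state_means`, `state_sds`,
#'   `occupancies` (mixture weights, sum 1), `transition_time_ns` (NA when no
#'   sustained entry or a single state), `n_states`, `loglik`, `bic`.
#' @export
find_macrostates <- function(series, n_states = 2, restarts = 50, seed = 1,
                             window = 1.0, dwell_ns = 10) {
  x <- series$deviation
  n <- length(x)
  if (n < 200) stop("find_macrostates needs >= 200 frames (have ", n, ")")
  if (all(is.na(series$smoothed)))
    series <- rolling_average(series, window)
  xs <- series$smoothed
  fit_k <- function(k) {
    if (k == 1) {
      mu <- mean(x); s <- max(sd(x), 1e-3)
      ll <- sum(stats::dnorm(x, mu, s, log = TRUE))
      return(list(mu = mu, sigma = s, w = 1, loglik = ll, converged = TRUE))
    }
    best <- NULL
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
    set.seed(seed)
    for (r in seq_len(restarts)) {
      km <- suppressWarnings(kmeans(xs, centers = k, nstart = 1))
      mu0 <- as.vector(km$centers)
      s0 <- vapply(seq_len(k), function(j) {
        xj <- x[km$cluster == j]
        max(if (length(xj) > 1) sd(xj) else sd(x) / k, 1e-3)
      }, numeric(1))
      w0 <- pmax(km$size / n, 1e-6); w0 <- w0 / sum(w0)
      fit <- em_1d(x, mu0, s0, w0)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (is.null(best) || !is.finite(best$loglik))
      stop("find_macrostates: EM failed to converge after ", restarts,
           " restarts")
    best
  }
  pick_bic <- function(fit, k) {
    p <- if (k == 1) 2 else 3 * k - 1
    -2 * fit$loglik + p * log(n)
  }
  if (identical(n_states, "auto")) {
    f1 <- fit_k(1); f2 <- fit_k(2)
    if (pick_bic(f1, 1) <= pick_bic(f2, 2)) {
      fit <- f1; k <- 1
    } else {
      fit <- f2; k <- 2
    }
  } else {
    k <- as.integer(n_states)
    stopifnot(k %in% c(1L, 2L))
    fit <- fit_k(k)
  }
  ord <- order(fit$mu)
  mu <- fit$mu[ord]; sg <- fit$sigma[ord]; w <- fit$w[ord]
  transition <- NA_real_
  if (k == 2) {
    inside <- abs(xs - mu[2]) <= sg[2]
    transition <- first_sustained(series$time_ns, inside, dwell_ns)
  }
  structure(list(state_means = mu, state_sds = sg, occupancies = w / sum(w),
                 transition_time_ns = transition, n_states = k,
                 loglik = fit$loglik, bic = pick_bic(fit, k)),
            class = "macrostate_summary")
}

# first time `flag` becomes TRUE and stays TRUE for >= dwell_ns (or until the
# series ends with at least dwell_ns covered); NA if never
first_sustained <- function(time_ns, flag, dwell_ns) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    dur <- time_ns[ends[i]] - time_ns[starts[i]]
    if (dur >= dwell_ns) return(time_ns[starts[i]])
  }
  NA_real_
}

# per-frame minimum distance between two atom groups across a trajectory
traj_min_distance <- function(x, group_a, group_b) {
  find_idx <- function(spec) {
    cond <- x$atoms$res_seq == spec$res_seq &
      x$atoms$atom_name == spec$atom_name
    if (!is.null(spec$chain)) cond <- cond & x$atoms$chain == spec$chain
    idx <- which(cond)
    if (length(idx) == 0)
      stop("atom not found: residue ", spec$res_seq, " atom ",
           spec$atom_name)
    idx[1]
  }
  ia <- vapply(group_a, find_idx, integer(1))
  ib <- vapply(group_b, find_idx, integer(1))
  vapply(x$models, function(m) {
    min(sqrt(outer(rowSums(m[ia, , drop = FALSE]^2),
                   rowSums(m[ib, , drop = FALSE]^2), "+") -
               2 * tcrossprod(m[ia, , drop = FALSE],
                              m[ib, , drop = FALSE])))
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_distance_table <- function(x, time_ns, group_a, group_b) {
  if (is.data.frame(x)) {
    if (!all(c("time_ns", "value") %in% names(x)))
      stop("distance table needs columns time_ns and value")
    x
  } else if (inherits(x, "structure3d")) {
    n <- length(x$models)
    if (is.null(time_ns)) time_ns <- seq_len(n)
    if (length(time_ns) == 1) time_ns <- time_ns * seq_len(n)
    data.frame(time_ns = time_ns,
               value = traj_min_distance(x, group_a, group_b))
  } else stop("x must be a structure3d or a data.frame")
}

#' Track a conformational switch from an atom-pair distance series
#'
#' Per frame, the minimum distance from a donor atom to a set of acceptor
#' atoms classifies the conformation as `in` (at or below the threshold, the
#' hydrogen-bonded pose) or `out`. The switch time is the first time the
#' state becomes `out` and remains `out` for at least `dwell_ns`. Defaults
#' describe the Y184 hydroxyl against the I242 carbonyl and A244 amide.
#'
#' @param x A multi-model `structure3d` or a data.frame with `time_ns`,
#'   `value` (the precomputed minimum distance, angstrom).
#' @param donor,acceptors Atom specs (lists with `res_seq`, `atom_name`,
#'   optional `chain`) for structural input.
#' @param threshold Distance threshold in angstrom (default 3.5).
#' @param dwell_ns Minimum sustained excursion (default 5).
#' @param time_ns Frame times for structural input.
#' @return An `event_series`: list with `series` (data.frame `time_ns`,
#'   `value`, `state`) and `switch_time_ns` (NA if no sustained switch).
#' @export
track_switch <- function(x, donor = list(res_seq = 184, atom_name = "OH"),
                         acceptors = list(list(res_seq = 242, atom_name = "O"),
                                          list(res_seq = 244, atom_name = "N")),
                         threshold = 3.5, dwell_ns = 5, time_ns = NULL) {
  tab <- as_distance_table(x, time_ns, list(donor), acceptors)
  state <- ifelse(tab$value <= threshold, "in", "out")
  switch_time <- first_sustained(tab$time_ns, state == "out", dwell_ns)
  structure(list(series = data.frame(time_ns = tab$time_ns,
                                     value = tab$value, state = state),
                 switch_time_ns = switch_time, threshold = threshold,
                 dwell_ns = dwell_ns),
            class = "event_series")
}

#' Salt-bridge occupancy and formation time over a trajectory
#'
#' Occupancy is the fraction of frames with the minimal side-chain
#' oxygen-nitrogen distance at or below the cutoff; the formation time is the
#' first time the bridge forms and persists for at least `dwell_ns`. Defaults
#' describe the ECL1 E183 to helix III K187 bridge.
#'
#' @param x A multi-model `structure3d` or a data.frame with `time_ns`,
#'   `value`.
#' @param acid,base Residue numbers (structural input); all carboxylate O and
#'   amine/guanidinium N atoms of those residues are used.
#' @param cutoff Distance cutoff in angstrom (default 4).
#' @param dwell_ns Minimum persistence (default 5).
#' @param time_ns Frame times for structural input.
#' @param chain Chain for structural input.
#' @return List with `occupancy` (fraction of frames formed),
#'   `first_formation_ns` (NA if never sustained) and `series`.
#' @export
saltbridge_occupancy <- function(x, acid = 183, base = 187, cutoff = 4.0,
                                 dwell_ns = 5, time_ns = NULL, chain = NULL) {
  if (inherits(x, "structure3d")) {
    a <- x$atoms
    ga <- lapply(which(a$res_seq == acid &
                         a$atom_name %in% unlist(ACID_ATOMS)),
                 function(i) list(res_seq = a$res_seq[i],
                                  atom_name = a$atom_name[i],
                                  chain = a$chain[i]))
    gb <- lapply(which(a$res_seq == base &
                         a$atom_name %in% unlist(BASE_ATOMS)),
                 function(i) list(res_seq = a$res_seq[i],
                                  atom_name = a$atom_name[i],
                                  chain = a$chain[i]))
    if (length(ga) == 0 || length(gb) == 0)
      stop("saltbridge_occupancy: side-chain atoms of residue ",
           if (length(ga) == 0) acid else base, " not found")
    tab <- as_distance_table(x, time_ns, ga, gb)
  } else tab <- as_distance_table(x, time_ns, NULL, NULL)
  formed <- tab$value <= cutoff
  list(occupancy = mean(formed),
       first_formation_ns = first_sustained(tab$time_ns, formed, dwell_ns),
       series = data.frame(time_ns = tab$time_ns, value = tab$value,
                           formed = formed))
}
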