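test_that("tilt series from structural frames matches planted tilts and is
           rigid-motion invariant", {
  tilts <- c(80, 62, 40, 25)
  toys <- lapply(tilts, function(t) make_toy_receptor(tilt_deg = t))
  ref <- toys[[1]]$structure
  traj <- tmanatomy:::new_structure3d(ref$atoms,
                                      lapply(toys, function(x)
                                        coords(x$structure)), "traj")
  ts <- tilt_series(traj, ref = ref, time_ns = 1)
  expect_equal(ts$theta, tilts, tolerance = 0.5)
  # deviation = theta_ref - theta_t, zero for the self frame
  expect_equal(ts$deviation[1], 0, tolerance = 1e-6)
  expect_equal(ts$deviation, ts$theta[1] - ts$theta, tolerance = 1e-6)
  # rigidly moving every stored frame leaves the series unchanged
  set.seed(9)
  moved <- tmanatomy:::new_structure3d(
    ref$atoms,
    lapply(traj$models, function(m)
      apply_transform(m, fx_rigid(fx_rotation(), rnorm(3, 0, 15)))), "t2")
  ts2 <- tilt_series(moved, ref = ref, time_ns = 1)
  expect_equal(ts2$theta, ts$theta, tolerance = 1e-6)
  # pipeline consistency: a precomputed angle table gives the same series
  tab <- data.frame(time_ns = ts$time_ns, theta = ts$theta)
  ts3 <- tilt_series(tab, theta_ref = attr(ts, "theta_ref"))
  expect_equal(ts3$deviation, ts$deviation)
})

test_that("rolling average is exact on constants and averages planted noise", {
  const <- tilt_series(data.frame(time_ns = seq(0.1, 100, 0.1), theta = 40),
                       theta_ref = 80)
  sm <- rolling_average(const)
  expect_true(all(abs(sm$smoothed - 40) < 1e-12))
  # alternating +/- 1 degree noise about 40, 0.1 ns spacing, 1 ns window
  t <- seq(0.1, 100, 0.1)
  noisy <- tilt_series(data.frame(time_ns = t,
                                  theta = 40 + c(1, -1)), theta_ref = 80)
  smn <- rolling_average(noisy, window = 1)
  expect_true(all(abs(smn$smoothed - 40) < 0.2))
  # near-idempotence on slowly varying series
  slow <- tilt_series(data.frame(time_ns = t, theta = 40 + 0.01 * t),
                      theta_ref = 80)
  s1 <- rolling_average(slow)
  s2 <- s1; s2$deviation <- s1$smoothed
  s2 <- rolling_average(s2)
  mid <- 20:980
  expect_true(all(abs(s2$smoothed[mid] - s1$smoothed[mid]) < 1e-3))
  expect_error(rolling_average(const, window = 0), "positive")
})

test_that("deviation histograms are normalised with modes at planted means", {
  flat <- tilt_series(data.frame(time_ns = 1:10, theta = 63), theta_ref = 80)
  h <- deviation_histogram(flat)
  expect_equal(sum(h$freq), 1)
  expect_equal(max(h$freq), 1)
  tr <- make_trajectory(seed = 6)
  h2 <- deviation_histogram(tilt_series(tr$table, theta_ref = 80))
  expect_equal(sum(h2$freq), 1, tolerance = 1e-12)
  # two modes within a bin width of the planted state means
  pre <- h2$centers < 30
  expect_lt(abs(h2$centers[pre][which.max(h2$freq[pre])] - 17), 1.5)
  expect_lt(abs(h2$centers[!pre][which.max(h2$freq[!pre])] - 40), 1.5)
})

test_that("macrostate fitting recovers planted mixtures across seeds", {
  err_mu <- err_occ <- err_tr <- numeric(0)
  for (sd_ in 1:10) {
    tr <- make_trajectory(seed = sd_)
    ms <- find_macrostates(tilt_series(tr$table, theta_ref = 80))
    err_mu <- c(err_mu, abs(ms$state_means - tr$truth$state_means))
    err_occ <- c(err_occ, abs(ms$occupancies - tr$truth$occupancies))
    err_tr <- c(err_tr, abs(ms$transition_time_ns - tr$truth$transition_ns))
    expect_equal(sum(ms$occupancies), 1, tolerance = 1e-9)
    expect_lte(ms$state_means[1], ms$state_means[2])
  }
  expect_lt(mean(err_mu), 2)
  expect_lt(max(err_mu), 2)
  expect_lt(mean(err_occ), 0.05)
  expect_true(all(err_tr < 20))
})

test_that("macrostate fit is frame-order free and validated by an
           independent mixture fit", {
  tr <- make_trajectory(seed = 2)
  ts <- tilt_series(tr$table, theta_ref = 80)
  ms <- find_macrostates(ts)
  set.seed(1)
  perm <- sample(nrow(tr$table))
  tab_perm <- tr$table[perm, ]
  tab_perm$time_ns <- sort(tab_perm$time_ns)  # times must stay increasing
  ms_perm <- find_macrostates(tilt_series(tab_perm, theta_ref = 80))
  expect_equal(ms_perm$state_means, ms$state_means, tolerance = 0.2)
  expect_equal(ms_perm$occupancies, ms$occupancies, tolerance = 0.02)
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  or <- mclust::Mclust(ts$deviation, G = 2, modelNames = "V",
                       verbose = FALSE)
  expect_equal(sort(as.vector(or$parameters$mean)), ms$state_means,
               tolerance = 0.5)
})

test_that("BIC model choice separates one-state from two-state series", {
  two <- make_trajectory(seed = 4)
  one <- make_trajectory(state_means = c(20, 20.0001), state_sds = c(4, 4),
                         transition_ns = 500, seed = 5)
  expect_equal(find_macrostates(tilt_series(two$table, theta_ref = 80),
                                n_states = "auto")$n_states, 2)
  expect_equal(find_macrostates(tilt_series(one$table, theta_ref = 80),
                                n_states = "auto")$n_states, 1)
  short <- tilt_series(data.frame(time_ns = 1:100, theta = 40),
                       theta_ref = 80)
  expect_error(find_macrostates(short), "200")
})

test_that("switch tracking applies the dwell rule to excursions", {
  t <- seq(0.5, 1000, 0.5)
  always_in <- data.frame(time_ns = t, value = 2.9)
  expect_true(is.na(track_switch(always_in)$switch_time_ns))
  stepped <- data.frame(time_ns = t, value = ifelse(t < 300, 2.9, 6.0))
  expect_equal(track_switch(stepped)$switch_time_ns, 300)
  # a single-frame excursion shorter than the dwell is not a switch
  blip <- always_in
  blip$value[t == 500] <- 6.0
  expect_true(is.na(track_switch(blip)$switch_time_ns))
  expect_equal(sum(track_switch(blip)$series$state == "out"), 1)
})

test_that("salt-bridge occupancy equals the frame ratio and formation time
           is threshold-monotone", {
  t <- seq(0.5, 1000, 0.5)
  never <- data.frame(time_ns = t, value = 8)
  sb0 <- saltbridge_occupancy(never)
  expect_equal(sb0$occupancy, 0)
  expect_true(is.na(sb0$first_formation_ns))
  set.seed(8)
  tab <- data.frame(time_ns = t,
                    value = ifelse(t < 200, 7, 3) + rnorm(length(t), 0, 0.2))
  sb <- saltbridge_occupancy(tab)
  expect_equal(sb$first_formation_ns, 200, tolerance = 2)
  # brute-force frame count oracle
  expect_equal(sb$occupancy, mean(tab$value <= 4))
  # raising the cutoff never delays formation
  prev <- Inf
  for (cut in c(3.5, 4, 4.5, 5, 6)) {
    ft <- saltbridge_occupancy(tab, cutoff = cut)$first_formation_ns
    expect_lte(ft, prev)
    prev <- ft
  }
})

test_that("distance series from structural trajectories match hand geometry", {
  # donor OH moving away from two fixed acceptors across frames
  at <- rbind(fx_atoms(184, "TYR", "OH", "O"),
              fx_atoms(242, "ILE", "O", "O"),
              fx_atoms(244, "ALA", "N", "N"))
  frames <- lapply(c(2.9, 2.9, 6, 6, 6), function(d)
    rbind(c(0, 0, 0), c(d, 0, 0), c(0, d + 0.5, 0)))
  traj <- tmanatomy:::new_structure3d(at, frames, "sw")
  sw <- track_switch(traj, time_ns = 10, dwell_ns = 10)
  expect_equal(sw$series$value, c(2.9, 2.9, 6, 6, 6))
  expect_equal(sw$switch_time_ns, 30)
  expect_error(track_switch(traj, donor = list(res_seq = 99,
                                               atom_name = "OH"),
                            time_ns = 10), "not found")
})
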