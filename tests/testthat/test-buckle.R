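test_that("helical fixtures keep every hydrogen bond formed", {
  traj <- gen_trajectory(trajectory_script(n_residues = 20, n_monomers = 1,
                                           duration_ns = 0.05))
  traces <- hbond_distance_traces(traj, c(1, 20))
  expect_length(traces, 16L)
  expect_true(all(vapply(traces, function(t) all(t$d < 0.35), logical(1))))
  expect_equal(nrow(buckle_event_table(traj, c(1, 20), min_duration = 0)), 0L)
})

test_that("an extended chain breaks every helical hydrogen bond", {
  ext <- hnsmodes:::.build_backbone(20, phi = -139, psi = 135) / 10  # nm
  atoms <- data.frame(elety = rep(c("N", "CA", "C", "O"), 20), resid = "ALA",
                      chain = "A", resno = rep(1:20, each = 4),
                      elesy = rep(c("N", "C", "C", "O"), 20),
                      category = "protein-monomer-A")
  traj <- md_trajectory(array(rep(ext, each = 2), c(2, 80, 3)), atoms,
                        c(0, 10))
  traces <- hbond_distance_traces(traj, c(1, 20))
  expect_true(all(vapply(traces, function(t) all(t$d > 0.35), logical(1))))
})

test_that("missing backbone atoms are reported by residue", {
  traj <- gen_trajectory(trajectory_script(n_residues = 10, n_monomers = 1,
                                           duration_ns = 0.02))
  drop <- !(traj$atoms$resno == 3 & traj$atoms$elety == "O")
  maimed <- md_trajectory(traj$xyz[, drop, , drop = FALSE],
                          traj$atoms[drop, ], traj$times)
  expect_error(hbond_distance_traces(maimed, c(1, 10)), "A:3")
})

test_that("scripted buckles are recovered with their exact boundaries", {
  sc <- trajectory_script(
    n_residues = 20, n_monomers = 1, duration_ns = 2,
    events = list(list(type = "buckle", pair = c(8, 12), t_start_ns = 0.8,
                       t_end_ns = 1.3, target_nm = 0.45)))
  traj <- gen_trajectory(sc)
  traces <- hbond_distance_traces(traj, c(1, 20))
  keys <- vapply(traces, function(t) t$pair[1], integer(1))
  ev <- detect_buckle_events(traces[[which(keys == 8)]])
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$label, "reversible")
  expect_lte(abs(ev$t_start - 800), 10)
  expect_lte(abs(ev$t_end - 1290), 10)
  expect_equal(ev$duration_ns, 0.5, tolerance = 0.011)
  # only the scripted pair buckles
  others <- traces[keys != 8]
  expect_true(all(vapply(others, function(t) all(t$d < 0.35), logical(1))))
})

test_that("events reaching the final frame are irreversible", {
  sc <- trajectory_script(
    n_residues = 20, n_monomers = 1, duration_ns = 1,
    events = list(list(type = "buckle", pair = c(8, 12), t_start_ns = 0.4,
                       t_end_ns = 1, target_nm = 0.5)))
  tab <- buckle_event_table(gen_trajectory(sc), c(1, 20))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$label, "irreversible")
})

test_that("gap merging and minimum duration follow their definitions", {
  dt <- 10  # ps
  d <- rep(0.30, 200)
  d[51:80] <- 0.45            # 0.3 ns excursion
  d[86:115] <- 0.45           # separated by a 50 ps gap -> merged
  d[150:155] <- 0.45          # 60 ps blip -> below min_duration, dropped
  tr <- make_trace(d, dt)
  ev <- detect_buckle_events(tr, min_duration = 0.1, gap_tolerance = 0.05)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$t_start, 500)
  expect_equal(ev$t_end, 1140)
  expect_equal(ev$duration_ns, 0.65)  # merged span includes the gap

  # a wider gap is not merged
  d2 <- rep(0.30, 200); d2[51:80] <- 0.45; d2[88:117] <- 0.45
  ev2 <- detect_buckle_events(make_trace(d2, dt), min_duration = 0.1,
                              gap_tolerance = 0.05)
  expect_equal(nrow(ev2), 2L)
  expect_true(all(ev2$label == "reversible"))
})

test_that("event lists are disjoint, ordered and duration-bounded", {
  set.seed(8)
  d <- 0.30 + 0.12 * (sin(seq(0, 24, length.out = 600)) > 0.2) +
    rnorm(600, 0, 0.005)
  tr <- make_trace(d)
  ev <- detect_buckle_events(tr)
  if (nrow(ev) > 1) {
    expect_true(all(diff(ev$t_start) > 0))
    expect_true(all(ev$t_start[-1] > ev$t_end[-nrow(ev)]))
  }
  expect_lte(sum(ev$duration_ns), diff(range(tr$times)) / 1000 + 0.01)
  # raising the threshold never increases total buckled time
  ev_hi <- detect_buckle_events(tr, threshold = 0.40)
  expect_lte(sum(ev_hi$duration_ns), sum(ev$duration_ns))
})

test_that("detection is stable under stride refinement and mild jitter", {
  sig <- function(t_ps) 0.30 + 0.15 * (t_ps >= 5000 & t_ps < 8000)
  t10 <- seq(0, 20000, by = 10); t20 <- seq(0, 20000, by = 20)
  ev10 <- detect_buckle_events(make_trace(sig(t10), 10))
  ev20 <- detect_buckle_events(make_trace(sig(t20), 20))
  expect_equal(nrow(ev10), 1L); expect_equal(nrow(ev20), 1L)
  expect_equal(ev10$label, ev20$label)
  expect_lte(abs(ev10$t_start - ev20$t_start), 20)
  expect_lte(abs(ev10$t_end - ev20$t_end), 20)

  set.seed(21)
  noisy <- sig(t10) + rnorm(length(t10), 0, 0.02)
  evn <- detect_buckle_events(make_trace(noisy, 10))
  expect_equal(nrow(evn), 1L)
  expect_lte(abs(evn$t_start - 5000), 50)  # within gap_tolerance
  expect_lte(abs(evn$t_end - 7990), 50)
})

test_that("non-uniform time axes are rejected", {
  tr <- make_trace(rep(0.5, 5))
  tr$times <- c(0, 10, 25, 30, 40)
  expect_error(detect_buckle_events(tr), "uniformly")
})

test_that("mean profiles localise the buckle and pool replicas invariantly", {
  sc <- trajectory_script(
    n_residues = 20, n_monomers = 2, duration_ns = 0.42,
    events = list(list(type = "buckle", pair = c(8, 12), monomer = "A",
                       t_start_ns = 0.22, t_end_ns = 0.42, target_nm = 0.45)))
  traj <- gen_trajectory(sc)
  prof <- mean_hbond_profile(traj, c(1, 20), burn_in = 0.01)
  base <- prof$mean_d_nm[prof$acceptor != 8]
  expect_true(all(base < 0.35))
  # buckled in half the retained frames of one of two monomers:
  # mean = (3 * d_helix + 1 * 0.45) / 4
  d_helix <- mean_hbond_profile(
    gen_trajectory(trajectory_script(n_residues = 20, n_monomers = 1,
                                     duration_ns = 0.02)),
    c(1, 20), burn_in = 0)$mean_d_nm[8]
  expect_equal(prof$mean_d_nm[prof$acceptor == 8],
               (3 * d_helix + 0.45) / 4, tolerance = 1e-6)
  prof3 <- mean_hbond_profile(list(traj, traj, traj), c(1, 20), burn_in = 0.01)
  expect_equal(prof3$mean_d_nm, prof$mean_d_nm)
})
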