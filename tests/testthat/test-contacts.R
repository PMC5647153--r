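test_that("min_residue_distance matches construction and brute force", {
  # two single-atom residues 0.5 nm apart
  tr <- make_point_trajectory(list(rbind(c(0, 0, 0), c(0.5, 0, 0))))
  expect_equal(min_residue_distance(tr, 1, "A:1", "A:2"), 0.5)
  expect_equal(min_residue_distance(tr, 1, "A:1", "A:1"), 0)

  # random multi-atom residues versus exhaustive scan
  set.seed(5)
  traj <- gen_trajectory(trajectory_script(n_residues = 8, n_monomers = 1,
                                           duration_ns = 0.05,
                                           jitter_sd_nm = 0.05, seed = 5))
  at <- traj$atoms
  for (f in c(1, 3, 5)) {
    A <- traj$xyz[f, at$resno == 2, ]
    B <- traj$xyz[f, at$resno == 7, ]
    expect_equal(min_residue_distance(traj, f, "A:2", "A:7"),
                 brute_min_dist(A, B), tolerance = 1e-12)
  }
})

test_that("contact probabilities equal scripted frame fractions", {
  # 51 frames at 10 ps; burn-in 0.1 ns retains 40 frames (t = 110..500 ps);
  # contact scripted over t in [210, 510) ns covers exactly 30 of them
  sc <- trajectory_script(
    n_residues = 16, n_monomers = 1, duration_ns = 0.51,
    events = list(list(type = "domain_contact", residue_a = 2, residue_b = 14,
                       t_start_ns = 0.21, t_end_ns = 0.51, target_nm = 0.45)))
  traj <- gen_trajectory(sc)
  cm <- contact_map(traj, burn_in = 0.1)
  expect_equal(cm$n_frames_used, 40L)
  expect_equal(cm$P["A:2", "A:14"], 30 / 40)

  # permanent contact -> 1; distant pair -> 0
  sc2 <- trajectory_script(
    n_residues = 16, n_monomers = 1, duration_ns = 0.2,
    events = list(list(type = "domain_contact", residue_a = 2, residue_b = 14,
                       t_start_ns = 0, t_end_ns = 0.2, target_nm = 0.45)))
  cm2 <- contact_map(gen_trajectory(sc2), burn_in = 0.05)
  expect_equal(cm2$P["A:2", "A:14"], 1)
  sc3 <- trajectory_script(
    n_residues = 16, n_monomers = 1, duration_ns = 0.2,
    events = list(list(type = "domain_contact", residue_a = 2, residue_b = 14,
                       t_start_ns = 0, t_end_ns = 0.2, target_nm = 0.7)))
  cm3 <- contact_map(gen_trajectory(sc3), burn_in = 0.05)
  expect_equal(cm3$P["A:2", "A:14"], 0)
})

test_that("contact matrices are symmetric, bounded and threshold-monotone", {
  traj <- gen_trajectory(trajectory_script(n_residues = 12, n_monomers = 2,
                                           duration_ns = 0.1,
                                           jitter_sd_nm = 0.02, seed = 3))
  cm6 <- contact_map(traj, threshold = 0.6, burn_in = 0.02)
  cm7 <- contact_map(traj, threshold = 0.7, burn_in = 0.02)
  expect_equal(cm6$P, t(cm6$P))
  expect_true(all(diag(cm6$P) == 1))
  expect_true(all(cm6$P >= 0 & cm6$P <= 1))
  expect_true(all(cm7$P >= cm6$P))
})

test_that("burn-in exclusion equals prior frame deletion, pooling is invariant", {
  traj <- gen_trajectory(trajectory_script(
    n_residues = 10, n_monomers = 1, duration_ns = 0.2,
    events = list(list(type = "domain_contact", residue_a = 2, residue_b = 9,
                       t_start_ns = 0.1, t_end_ns = 0.16, target_nm = 0.5))))
  cm <- contact_map(traj, burn_in = 0.05)
  keep <- traj$times > 50
  pre <- md_trajectory(traj$xyz[keep, , , drop = FALSE], traj$atoms,
                       traj$times[keep])
  cm_pre <- contact_map(pre, burn_in = 0.05)
  expect_equal(cm$P, cm_pre$P)
  cm_pool <- contact_map(list(traj, traj, traj), burn_in = 0.05)
  expect_equal(cm_pool$P, cm$P)
  expect_equal(cm_pool$n_replicas, 3L)
})

test_that("ion profiles implement at-least-one-ion and monomer averaging", {
  # ion resident at residue 10 of monomer A for every frame: profile = 1/2
  sc <- trajectory_script(
    n_residues = 20, n_monomers = 2, duration_ns = 0.1,
    events = list(list(type = "ion_residence", species = "Mg2+", residue = 10,
                       monomer = "A", t_start_ns = 0, t_end_ns = 0.1,
                       target_nm = 0.3)))
  traj <- gen_trajectory(sc)
  prof <- ion_contact_profile(traj, "Mg2+", burn_in = 0.02)
  expect_equal(unname(prof$P["10"]), 0.5)
  # residues far from the residence site never see the ion
  expect_true(all(prof$P[c("1", "2", "19", "20")] == 0))

  # scripted residence over 40% of retained frames, both monomers
  sc2 <- trajectory_script(
    n_residues = 20, n_monomers = 2, duration_ns = 0.52,
    events = list(
      list(type = "ion_residence", species = "Mg2+", residue = 10,
           monomer = "A", t_start_ns = 0.13, t_end_ns = 0.33, target_nm = 0.3),
      list(type = "ion_residence", species = "Mg2+", residue = 10,
           monomer = "B", t_start_ns = 0.13, t_end_ns = 0.33, target_nm = 0.3)))
  traj2 <- gen_trajectory(sc2)
  prof2 <- ion_contact_profile(traj2, "Mg2+", burn_in = 0.02)
  # retained: t = 30..510 (49 frames); resident: t = 130..320 (20 frames)
  expect_equal(unname(prof2$P["10"]), 20 / 49)

  expect_warning(p0 <- ion_contact_profile(traj, "Cl-", burn_in = 0.02),
                 "no atoms")
  expect_true(all(p0$P == 0))
})

test_that("domain contact summaries report both directions", {
  sc <- trajectory_script(
    n_residues = 30, n_monomers = 1, duration_ns = 0.1,
    events = list(list(type = "domain_contact", residue_a = 5, residue_b = 25,
                       t_start_ns = 0, t_end_ns = 0.1, target_nm = 0.45)))
  traj <- gen_trajectory(sc)
  dc <- domain_contact_summary(traj, domA = c(1, 10), domB = c(20, 30),
                               burn_in = 0.02)
  expect_equal(unname(dc$P_domA["5"]), 1)
  expect_equal(unname(dc$P_domB["25"]), 1)
  expect_equal(unname(dc$P_domA["1"]), 0)

  # half the retained frames in contact
  sc2 <- trajectory_script(
    n_residues = 30, n_monomers = 1, duration_ns = 0.42,
    events = list(list(type = "domain_contact", residue_a = 5, residue_b = 25,
                       t_start_ns = 0.22, t_end_ns = 0.42, target_nm = 0.45)))
  dc2 <- domain_contact_summary(gen_trajectory(sc2), domA = c(1, 10),
                                domB = c(20, 30), burn_in = 0.01)
  expect_equal(unname(dc2$P_domA["5"]), 0.5)

  expect_error(domain_contact_summary(traj, domA = c(1, 20), domB = c(15, 30)),
               "overlap")
})
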