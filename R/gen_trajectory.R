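#' Script for a synthetic trajectory fixture
#'
#' Describes a geometric trajectory whose observables are known exactly:
#' one or two protein "monomers" built as ideal alpha-helical backbones
#' (N, CA, C, O atoms), optional ions, and a list of scripted events that
#' perturb the baseline geometry over stated time windows. Event types:
#'
#' * `buckle`: displace the backbone carbonyl O of residue `i` so that the
#'   helical hydrogen-bond distance O(i)...N(i+4) equals `target_nm`
#'   (> 0.35 nm breaks the bond) during `[t_start_ns, t_end_ns]`.
#'   Fields: `pair = c(i, i + 4)`, `monomer`, `t_start_ns`, `t_end_ns`,
#'   `target_nm` (default 0.45).
#' * `domain_contact`: rigidly translate residue `residue_b` of
#'   `monomer_b` so its minimum heavy-atom distance to residue `residue_a`
#'   of `monomer_a` equals `target_nm` (default 0.45) during the window.
#' * `ion_residence`: place one ion of `species` (`"Mg2+"`, `"K+"`,
#'   `"Cl-"`) at minimum distance `target_nm` (default 0.3) from residue
#'   `residue` of `monomer` during the window; parked far away otherwise.
#'
#' Events touching the same atoms in overlapping windows are rejected.
#'
#' @param n_residues Residues per monomer.
#' @param n_monomers 1 or 2 protein monomers (chains A, B).
#' @param events List of event lists as above.
#' @param ions Named integer vector of free ions to include beyond those
#'   needed by events, e.g. `c("Mg2+" = 2)`; parked far from the protein.
#' @param dt_ps Frame interval, ps (default 10, the stored-frame cadence of
#'   the simulations being emulated).
#' @param duration_ns Trajectory length, ns (default 50).
#' @param jitter_sd_nm Gaussian positional jitter per coordinate, nm
#'   (default 0; events remain exact only at 0).
#' @param seed RNG seed for jitter.
#' @return An object of class `trajectory_script`.
#' @export
trajectory_script <- function(n_residues = 60, n_monomers = 2, events = list(),
                              ions = c(), dt_ps = 10, duration_ns = 50,
                              jitter_sd_nm = 0, seed = 1) {
  stopifnot(n_residues >= 5, n_monomers %in% 1:2, dt_ps > 0, duration_ns > 0)
  for (ev in events) {
    if (!is.list(ev) || is.null(ev$type))
      stop("each event must be a list with a `type` field")
    if (!ev$type %in% c("buckle", "domain_contact", "ion_residence"))
      stop("unknown event type: ", ev$type)
    t0 <- ev$t_start_ns; t1 <- ev$t_end_ns
    if (is.null(t0) || is.null(t1) || t0 >= t1 || t0 < 0 || t1 > duration_ns)
      stop("event window must satisfy 0 <= t_start < t_end <= duration")
    tg <- ev$target_nm
    if (!is.null(tg) && tg <= 0) stop("event target distance must be positive")
  }
  # conflicting events: same moved atom set, overlapping windows
  ion_counter <- 0L
  key <- vapply(events, function(ev) switch(ev$type,
    buckle = sprintf("O:%s:%d", ev$monomer %||% "A", ev$pair[1]),
    domain_contact = sprintf("RES:%s:%d", ev$monomer_b %||% "A", ev$residue_b),
    ion_residence = {
      # each residence event drives its own ion unless an ion_id is shared
      ion_counter <<- ion_counter + 1L
      sprintf("ION:%s:%d", ev$species, ev$ion_id %||% ion_counter)
    }),
    character(1))
  if (length(events) > 1) {
    for (i in seq_along(events)) for (j in seq_len(i - 1)) {
      if (key[i] == key[j] &&
          events[[i]]$t_start_ns < events[[j]]$t_end_ns &&
          events[[j]]$t_start_ns < events[[i]]$t_end_ns)
        stop("conflicting events on the same atoms at overlapping times")
    }
  }
  structure(list(n_residues = as.integer(n_residues),
                 n_monomers = as.integer(n_monomers),
                 events = events, ions = ions, dt_ps = dt_ps,
                 duration_ns = duration_ns, jitter_sd_nm = jitter_sd_nm,
                 seed = as.integer(seed)),
            class = "trajectory_script")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# NeRF atom placement: D bonded to C with length r (Angstrom), angle B-C-D
# theta (deg), torsion A-B-C-D chi (deg)
.place_atom <- function(A, B, C, r, theta, chi) {
  theta <- theta * pi / 180; chi <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(theta), r * sin(theta) * cos(chi), r * sin(theta) * sin(chi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# ideal backbone (N, CA, C, O per residue) in Angstrom; phi/psi default to
# canonical alpha-helix dihedrals; "extended" uses beta-strand-like values
.build_backbone <- function(n_res, phi = -60, psi = -45) {
  xyz <- matrix(NA_real_, n_res * 4L, 3L)  # rows: N, CA, C, O per residue
  idx <- function(i, a) (i - 1L) * 4L + match(a, c("N", "CA", "C", "O"))
  # seed residue in the xy-plane
  xyz[idx(1, "N"), ] <- c(0, 0, 0)
  xyz[idx(1, "CA"), ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  xyz[idx(1, "C"), ] <- xyz[idx(1, "CA"), ] +
    1.525 * c(-cos(ang), sin(ang), 0)
  for (i in 2:n_res) {
    Ni <- .place_atom(xyz[idx(i - 1, "N"), ], xyz[idx(i - 1, "CA"), ],
                      xyz[idx(i - 1, "C"), ], 1.329, 116.2, psi)
    CAi <- .place_atom(xyz[idx(i - 1, "CA"), ], xyz[idx(i - 1, "C"), ],
                       Ni, 1.458, 121.7, 180)
    Ci <- .place_atom(xyz[idx(i - 1, "C"), ], Ni, CAi, 1.525, 111.2, phi)
    xyz[idx(i, "N"), ] <- Ni
    xyz[idx(i, "CA"), ] <- CAi
    xyz[idx(i, "C"), ] <- Ci
    # carbonyl O of residue i-1: trans to N(i) across the C(i-1) plane
    xyz[idx(i - 1, "O"), ] <- .place_atom(
      xyz[idx(i - 1, "CA"), ], Ni, xyz[idx(i - 1, "C"), ], 1.231, 120.8, 180)
  }
  # last residue's O from its own frame (same in-plane construction)
  xyz[idx(n_res, "O"), ] <- .place_atom(
    xyz[idx(n_res, "N"), ], xyz[idx(n_res, "CA"), ], xyz[idx(n_res, "C"), ],
    1.231, 120.8, psi + 180)
  xyz
}

# solve for translation of point set `mob` along unit vector u so that the
# minimum distance to point set `ref` equals target (Angstrom)
.translate_to_min_dist <- function(mob, ref, target) {
  mind <- function(P) {
    d2 <- outer(rowSums(P^2), rowSums(ref^2), "+") - 2 * P %*% t(ref)
    sqrt(max(min(d2), 0))
  }
  cm <- colMeans(mob); cr <- colMeans(ref)
  u <- cm - cr; u <- u / sqrt(sum(u^2))
  f <- function(s) mind(sweep(mob, 2, s * u, "+")) - target
  # bracket: pulling towards ref decreases min distance; pushing away increases
  lo <- -sqrt(sum((cm - cr)^2)); hi <- sqrt(sum((cm - cr)^2)) + 10 * target
  s <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  sweep(mob, 2, s * u, "+")
}

#' Generate a scripted multi-model PDB trajectory
#'
#' Realises a [trajectory_script()] as coordinates: ideal alpha-helical
#' monomers (chain A, and B translated 6 nm away), ions, and the scripted
#' buckle / domain-contact / ion-residence events applied exactly over their
#' time windows. Event windows are half-open in frame time:
#' a frame at time `t` (ns) is perturbed iff `t_start_ns <= t < t_end_ns`.
#' Coordinates are written in Angstrom in the PDB (the reader converts to
#' nm); each MODEL block is preceded by a `REMARK 250 TIME:` record in ps.
#'
#' @param script A [trajectory_script()].
#' @param path Optional output PDB path; when `NULL` no file is written.
#' @return The [md_trajectory()] realising the script (invisibly the same
#'   object that `path` serialises).
#' @examples
#' sc <- trajectory_script(n_residues = 20, n_monomers = 1, duration_ns = 0.1)
#' traj <- gen_trajectory(sc)
#' @export
gen_trajectory <- function(script, path = NULL) {
  if (!inherits(script, "trajectory_script"))
    stop("`script` must be a trajectory_script")
  nres <- script$n_residues
  base <- .build_backbone(nres)  # Angstrom
  chains <- c("A", "B")[seq_len(script$n_monomers)]
  atoms <- do.call(rbind, lapply(seq_along(chains), function(k) {
    data.frame(elety = rep(c("N", "CA", "C", "O"), nres),
               resid = "ALA", chain = chains[k],
               resno = rep(seq_len(nres), each = 4L),
               elesy = rep(c("N", "C", "C", "O"), nres),
               stringsAsFactors = FALSE)
  }))
  coords0 <- do.call(rbind, lapply(seq_along(chains), function(k) {
    sweep(base, 2, c(0, 0, (k - 1) * 60), "+")  # monomer B offset 6 nm in z
  }))

  # ion roster: event ions first, then free ions; all parked far away
  ev_ions <- Filter(function(e) e$type == "ion_residence", script$events)
  roster <- c(vapply(ev_ions, function(e) e$species, character(1)),
              rep(names(script$ions), times = script$ions))
  ion_rows <- NULL
  if (length(roster)) {
    nm <- c("Mg2+" = "MG", "K+" = "K", "Cl-" = "CL")
    if (any(!roster %in% names(nm)))
      stop("unknown ion species: ",
           paste(setdiff(roster, names(nm)), collapse = ", "))
    ion_rows <- data.frame(elety = nm[roster], resid = nm[roster],
                           chain = "I", resno = seq_along(roster),
                           elesy = nm[roster], stringsAsFactors = FALSE)
    atoms <- rbind(atoms, ion_rows)
    park <- cbind(500 + 20 * seq_along(roster), 500, 500)
    coords0 <- rbind(coords0, park)
  }

  nf <- as.integer(round(script$duration_ns * 1000 / script$dt_ps))
  times <- (seq_len(nf) - 1) * script$dt_ps
  xyz <- array(rep(coords0, each = nf), c(nf, nrow(atoms), 3))

  a_idx <- function(chain, resno, elety)
    which(atoms$chain == chain & atoms$resno == resno & atoms$elety == elety)
  res_idx <- function(chain, resno)
    which(atoms$chain == chain & atoms$resno == resno)
  in_window <- function(ev) {
    t_ns <- times / 1000
    which(t_ns >= ev$t_start_ns & t_ns < ev$t_end_ns)
  }

  ion_serial <- 0L
  for (ev in script$events) {
    frames <- in_window(ev)
    if (ev$type == "buckle") {
      mon <- ev$monomer %||% "A"
      i <- ev$pair[1]; j <- ev$pair[2]
      if (j != i + 4) stop("buckle pair must be (i, i + 4)")
      if (j > nres) stop("buckle pair exceeds monomer length")
      oi <- a_idx(mon, i, "O"); nj <- a_idx(mon, j, "N")
      target <- (ev$target_nm %||% 0.45) * 10
      O0 <- coords0[oi, ]; N0 <- coords0[nj, ]
      u <- O0 - N0; u <- u / sqrt(sum(u^2))
      Onew <- N0 + target * u
      for (k in 1:3) xyz[frames, oi, k] <- Onew[k]
    } else if (ev$type == "domain_contact") {
      mon_a <- ev$monomer_a %||% "A"; mon_b <- ev$monomer_b %||% mon_a
      ra <- res_idx(mon_a, ev$residue_a); rb <- res_idx(mon_b, ev$residue_b)
      if (!length(ra) || !length(rb)) stop("domain_contact residue out of range")
      target <- (ev$target_nm %||% 0.45) * 10
      moved <- .translate_to_min_dist(coords0[rb, , drop = FALSE],
                                      coords0[ra, , drop = FALSE], target)
      for (k in 1:3) xyz[frames, rb, k] <-
        matrix(moved[, k], length(frames), length(rb), byrow = TRUE)
    } else if (ev$type == "ion_residence") {
      ion_serial <- ion_serial + 1L
      ai <- which(atoms$chain == "I")[ion_serial]
      mon <- ev$monomer %||% "A"
      rr <- res_idx(mon, ev$residue)
      if (!length(rr)) stop("ion_residence residue out of range")
      target <- (ev$target_nm %||% 0.3) * 10
      ref <- coords0[rr, , drop = FALSE]
      cm <- colMeans(ref)
      ca <- coords0[a_idx(mon, ev$residue, "CA"), ]
      u <- ca - cm
      if (sqrt(sum(u^2)) < 1e-6) u <- c(0, 1, 0)
      u <- u / sqrt(sum(u^2))
      pos0 <- matrix(ca + 2 * u, 1, 3)
      pos <- .translate_to_min_dist(pos0, ref, target)
      for (k in 1:3) xyz[frames, ai, k] <- pos[1, k]
    }
  }

  if (script$jitter_sd_nm > 0) {
    set.seed(script$seed)
    xyz <- xyz + stats::rnorm(length(xyz), 0, script$jitter_sd_nm * 10)
  }

  atoms$category <- .categorize_atoms(atoms)
  traj <- md_trajectory(xyz / 10, atoms, times)
  if (!is.null(path)) .write_multimodel_pdb(path, traj$xyz, atoms, times)
  traj
}
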