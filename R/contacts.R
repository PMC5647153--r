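#' Minimum heavy-atom distance between two residues in one frame
#'
#' The minimum over all heavy-atom pairs of the Euclidean distance between
#' the two residues (minimum-image convention when the trajectory carries an
#' orthorhombic box). Residues are addressed as `"chain:resno"` labels.
#'
#' @param traj An [md_trajectory()].
#' @param frame Frame index (1-based).
#' @param residue_i,residue_j Residue labels, e.g. `"A:5"`.
#' @return Distance in nm.
#' @examples
#' traj <- gen_trajectory(trajectory_script(n_residues = 12, n_monomers = 1,
#'                                          duration_ns = 0.02))
#' min_residue_distance(traj, 1, "A:1", "A:5")
#' @export
min_residue_distance <- function(traj, frame, residue_i, residue_j) {
  sel <- function(lab) {
    parts <- strsplit(lab, ":", fixed = TRUE)[[1]]
    w <- which(traj$atoms$chain == parts[1] &
                 traj$atoms$resno == as.integer(parts[2]) &
                 .heavy(traj$atoms))
    if (!length(w)) stop("residue ", lab, " has no heavy atoms in the frame")
    w
  }
  ii <- sel(residue_i); jj <- sel(residue_j)
  if (identical(ii, jj)) return(0)
  A <- traj$xyz[frame, ii, , drop = TRUE]
  B <- traj$xyz[frame, jj, , drop = TRUE]
  if (is.null(dim(A))) A <- matrix(A, ncol = 3)
  if (is.null(dim(B))) B <- matrix(B, ncol = 3)
  .min_pair_dist(A, B, traj$box)
}

.min_pair_dist <- function(A, B, box = NULL) {
  if (is.null(box)) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    return(sqrt(max(min(d2), 0)))
  }
  best <- Inf
  for (i in seq_len(nrow(A))) {
    dv <- sweep(B, 2, A[i, ], "-")
    for (k in 1:3) dv[, k] <- dv[, k] - box[k] * round(dv[, k] / box[k])
    best <- min(best, min(rowSums(dv^2)))
  }
  sqrt(best)
}

# residue-by-residue minimum-distance matrix for one frame.
# X: m x 3 heavy-atom coordinates; groups: list of row-index vectors.
.residue_min_matrix <- function(X, groups) {
  D <- as.matrix(stats::dist(X))
  m <- ncol(D)
  # min over the atoms of residue j, for every atom row
  tmp <- vapply(groups, function(ix) {
    if (length(ix) == 1L) D[, ix] else do.call(pmin, asplit(D[ix, , drop = FALSE], 1))
  }, numeric(m))
  # then min over the atoms of residue i
  R <- vapply(groups, function(ix) {
    if (length(ix) == 1L) tmp[ix, ] else do.call(pmin, asplit(tmp[ix, , drop = FALSE], 1))
  }, numeric(length(groups)))
  t(R)
}

#' Residue-residue contact-probability map
#'
#' For every pair of protein residues (both monomers), the probability that
#' their minimum heavy-atom distance is at or below `threshold`, estimated
#' as the fraction of retained frames in contact. Frames within the first
#' `burn_in` ns of each replica are excluded; retained frames are pooled
#' across replicas with equal weight.
#'
#' @param trajs An [md_trajectory()] or a list of them (the replica
#'   ensemble).
#' @param threshold Contact cutoff, nm (default 0.6).
#' @param burn_in Equilibration time excluded from each replica, ns
#'   (default 10).
#' @return An object of class `contact_matrix`: `P` (symmetric probability
#'   matrix with unit diagonal), `labels` (`"chain:resno"`),
#'   `n_frames_used`, `n_replicas`, `threshold`.
#' @export
contact_map <- function(trajs, threshold = 0.6, burn_in = 10) {
  trajs <- .as_traj_list(trajs)
  ref <- trajs[[1]]$atoms
  prot <- grepl("^protein-monomer-", ref$category) & .heavy(ref)
  if (!any(prot)) stop("no protein heavy atoms in the trajectory")
  labels <- unique(paste0(ref$chain[prot], ":", ref$resno[prot]))
  groups <- lapply(labels, function(lb) {
    parts <- strsplit(lb, ":", fixed = TRUE)[[1]]
    which(ref$chain[prot] == parts[1] & ref$resno[prot] == as.integer(parts[2]))
  })
  nres <- length(labels)
  counts <- matrix(0, nres, nres)
  used <- 0L
  for (tr in trajs) {
    if (!identical(dim(tr$xyz)[2], dim(trajs[[1]]$xyz)[2]))
      stop("replicas must share one atom roster")
    keep <- .retained_frames(tr, burn_in)
    for (f in keep) {
      R <- .residue_min_matrix(tr$xyz[f, prot, , drop = TRUE], groups)
      counts <- counts + (R <= threshold)
      used <- used + 1L
    }
  }
  P <- counts / used
  diag(P) <- 1
  dimnames(P) <- list(labels, labels)
  structure(list(P = P, labels = labels, n_frames_used = used,
                 n_replicas = length(trajs), threshold = threshold),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "Contact-probability matrix: %d residues, cutoff %g nm, %d frames over %d replica(s)\n",
    length(x$labels), x$threshold, x$n_frames_used, x$n_replicas))
  invisible(x)
}

#' Heatmap of a contact-probability matrix
#' @param x A `contact_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.contact_matrix <- function(x, ...) {
  n <- length(x$labels)
  graphics::image(1:n, 1:n, x$P, zlim = c(0, 1),
                  xlab = "residue", ylab = "residue",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Write a contact matrix as TSV
#' @param x A `contact_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_tsv <- function(x, path) {
  utils::write.table(x$P, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

# shared scaffolding: per-monomer per-frame contact indicators against a
# partner atom set, pooled over replicas, then averaged over monomers
.monomer_profile <- function(trajs, partner_atoms_fun, threshold, burn_in) {
  trajs <- .as_traj_list(trajs)
  ref <- trajs[[1]]$atoms
  monomers <- sort(unique(ref$chain[grepl("^protein-monomer-", ref$category)]))
  res_per_mon <- lapply(monomers, function(ch)
    sort(unique(ref$resno[ref$chain == ch])))
  nres <- unique(vapply(res_per_mon, length, integer(1)))
  if (length(nres) != 1L) stop("monomers have unequal residue counts")
  prof <- matrix(0, nres, length(monomers))
  used <- 0L
  for (tr in trajs) {
    keep <- .retained_frames(tr, burn_in)
    part_idx <- partner_atoms_fun(tr)
    for (f in keep) {
      used <- used + 1L
      if (!length(part_idx)) next
      B <- tr$xyz[f, part_idx, , drop = TRUE]
      if (is.null(dim(B))) B <- matrix(B, ncol = 3)
      for (m in seq_along(monomers)) {
        ch <- monomers[m]
        for (r in seq_len(nres)) {
          rs <- res_per_mon[[m]][r]
          ii <- which(tr$atoms$chain == ch & tr$atoms$resno == rs &
                        .heavy(tr$atoms))
          A <- tr$xyz[f, ii, , drop = TRUE]
          if (is.null(dim(A))) A <- matrix(A, ncol = 3)
          if (.min_pair_dist(A, B, tr$box) <= threshold)
            prof[r, m] <- prof[r, m] + 1
        }
      }
    }
  }
  list(prof = prof, used = used, monomers = monomers,
       resno = res_per_mon[[1]], n_replicas = length(trajs))
}

#' Per-residue ion (or cofactor) contact probability profile
#'
#' For each residue index of the protein monomer, the probability that at
#' least one particle of `species` lies within `threshold` of the residue in
#' a retained frame. Probabilities are pooled over replicas with equal frame
#' weight and averaged over the two monomers, giving the profiles
#' `P_Mg2+`, `P_K+`, `P_Cl-` (or `P_Hha` for a cofactor chain).
#'
#' @param trajs Trajectory ensemble.
#' @param species One of `"Mg2+"`, `"K+"`, `"Cl-"` or `"Hha"` (cofactor
#'   chain).
#' @param threshold Contact cutoff, nm (default 0.6).
#' @param burn_in Burn-in per replica, ns (default 10).
#' @return An object of class `ion_profile`: `species`, `P` (named by
#'   residue index), `n_frames_used`, `n_replicas`.
#' @export
ion_contact_profile <- function(trajs, species, threshold = 0.6, burn_in = 10) {
  cat_target <- if (species == "Hha") "cofactor" else paste0("ion:", species)
  trl <- .as_traj_list(trajs)
  if (!any(trl[[1]]$atoms$category == cat_target))
    warning("no atoms of species ", species, " in the trajectory; profile is all zero")
  res <- .monomer_profile(trl, function(tr) {
    w <- which(tr$atoms$category == cat_target)
    if (cat_target == "cofactor") w[.heavy(tr$atoms[w, , drop = FALSE])] else w
  }, threshold, burn_in)
  P <- rowMeans(res$prof) / res$used
  names(P) <- res$resno
  structure(list(species = species, P = P, n_frames_used = res$used,
                 n_replicas = res$n_replicas, threshold = threshold),
            class = "ion_profile")
}

#' @export
print.ion_profile <- function(x, ...) {
  cat(sprintf("P_%s profile over %d residues (cutoff %g nm, %d frames)\n",
              x$species, length(x$P), x$threshold, x$n_frames_used))
  top <- sort(x$P[x$P > 0], decreasing = TRUE)
  if (length(top)) {
    show <- utils::head(top, 5)
    cat("  top residues:",
        paste(sprintf("%s=%.3f", names(show), show), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Inter-domain contact probabilities
#'
#' Per-residue probability, for each residue of domain A (default the
#' dimerization domain, residues 1-40), of being within `threshold` of any
#' residue of domain B (default the DNA-binding domain, residues 96-137) of
#' either monomer — and symmetrically for domain B. Both directions are
#' reported explicitly. Pooled over replicas, averaged over monomers.
#'
#' @param trajs Trajectory ensemble.
#' @param domA,domB Integer ranges `c(first, last)` of the two domains
#'   (1-based residue indices within a monomer); must not overlap.
#' @param threshold Cutoff, nm.
#' @param burn_in Burn-in, ns.
#' @return An object of class `domain_contacts` with `P_domA`, `P_domB`
#'   (named numeric vectors), the ranges, `n_frames_used`, `n_replicas`.
#' @export
domain_contact_summary <- function(trajs, domA = c(1, 40), domB = c(96, 137),
                                   threshold = 0.6, burn_in = 10) {
  if (domA[1] <= domB[2] && domB[1] <= domA[2])
    stop("domain ranges overlap")
  trl <- .as_traj_list(trajs)
  ref <- trl[[1]]$atoms
  nres_mon <- max(ref$resno[grepl("^protein-monomer-", ref$category)])
  if (domA[2] > nres_mon || domB[2] > nres_mon)
    stop("domain range exceeds monomer length")
  prof_for <- function(target_range) {
    res <- .monomer_profile(trl, function(tr)
      which(grepl("^protein-monomer-", tr$atoms$category) &
              tr$atoms$resno >= target_range[1] &
              tr$atoms$resno <= target_range[2] & .heavy(tr$atoms)),
      threshold, burn_in)
    P <- rowMeans(res$prof) / res$used
    names(P) <- res$resno
    list(P = P, used = res$used, n_rep = res$n_replicas)
  }
  a <- prof_for(domB)  # residues of domA probed against domain B atoms
  b <- prof_for(domA)
  structure(list(
    P_domA = a$P[as.character(domA[1]:domA[2])],
    P_domB = b$P[as.character(domB[1]:domB[2])],
    domA = domA, domB = domB, threshold = threshold,
    n_frames_used = a$used, n_replicas = a$n_rep),
    class = "domain_contacts")
}

#' @export
print.domain_contacts <- function(x, ...) {
  cat(sprintf(
    "Inter-domain contacts (cutoff %g nm, %d frames over %d replica(s))\n",
    x$threshold, x$n_frames_used, x$n_replicas))
  cat(sprintf("  residues %d-%d vs %d-%d: max P = %.3f / %.3f\n",
              x$domA[1], x$domA[2], x$domB[1], x$domB[2],
              max(x$P_domA), max(x$P_domB)))
  invisible(x)
}
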