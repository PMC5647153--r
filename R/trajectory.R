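#' Construct an MD trajectory object
#'
#' In-memory container for a trajectory ensemble member: frame coordinates in
#' nm, a per-atom topology table and a time axis in ps. Created by
#' [read_trajectory()] or [gen_trajectory()]; rarely built by hand.
#'
#' @param xyz Numeric array `frames x atoms x 3`, nm.
#' @param atoms Data frame with columns `elety` (atom name), `resid`
#'   (residue name), `chain`, `resno` (1-based residue index within its
#'   chain), `elesy` (element) and `category`.
#' @param times Numeric vector of frame times, ps, strictly increasing.
#' @param box Optional orthorhombic box lengths (nm, length 3) for
#'   minimum-image distances; `NULL` for non-periodic fixtures.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(xyz, atoms, times, box = NULL) {
  if (length(dim(xyz)) != 3L || dim(xyz)[3] != 3L)
    stop("`xyz` must be a frames x atoms x 3 array")
  if (nrow(atoms) != dim(xyz)[2])
    stop("atom table and coordinate array disagree on atom count")
  if (length(times) != dim(xyz)[1])
    stop("time axis length must equal the number of frames")
  if (any(diff(times) <= 0))
    stop("frame time stamps must be strictly increasing")
  need <- c("elety", "resid", "chain", "resno", "elesy", "category")
  if (!all(need %in% names(atoms)))
    stop("atom table needs columns: ", paste(need, collapse = ", "))
  structure(list(xyz = xyz, atoms = atoms, times = times, box = box),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("MD trajectory: %d frames x %d atoms, %.3f-%.3f ns\n",
              dim(x$xyz)[1], dim(x$xyz)[2],
              x$times[1] / 1000, x$times[length(x$times)] / 1000))
  tab <- table(x$atoms$category)
  cat("  atoms by category:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[1]

# default assignment of atoms to analysis categories
.categorize_atoms <- function(atoms, chain_map = NULL) {
  if (is.null(chain_map))
    chain_map <- c(A = "protein-monomer-A", B = "protein-monomer-B",
                   C = "cofactor")
  cat <- rep(NA_character_, nrow(atoms))
  res <- toupper(trimws(atoms$resid))
  cat[res %in% c("MG", "MG2")] <- "ion:Mg2+"
  cat[res %in% c("K", "K+", "POT")] <- "ion:K+"
  cat[res %in% c("CL", "CL-", "CLA")] <- "ion:Cl-"
  cat[res %in% c("HOH", "SOL", "WAT", "TIP3")] <- "solvent"
  prot <- is.na(cat)
  cat[prot] <- unname(chain_map[atoms$chain[prot]])
  if (any(is.na(cat)))
    stop("unmapped chain(s): ",
         paste(unique(atoms$chain[is.na(cat)]), collapse = ", "),
         " - extend `chain_map`")
  cat
}

#' Read a multi-model PDB trajectory
#'
#' Parses a multi-model PDB (MODEL/ENDMDL blocks) into an [md_trajectory()].
#' Coordinates are converted from Angstrom to nm. Frame times are taken from
#' `REMARK 250 TIME:` records when present (as written by
#' [gen_trajectory()]); otherwise a uniform cadence of `dt_ps` starting at 0
#' is assumed. Chains are mapped to analysis categories via `chain_map`
#' (default: chain A/B are the two protein monomers, C a cofactor); ion and
#' solvent residues are recognised by residue name (MG, K, CL, HOH, ...).
#'
#' @param path PDB file path.
#' @param dt_ps Frame interval in ps used when the file carries no time
#'   records (default 10 ps).
#' @param chain_map Named character vector chain -> category.
#' @return An `md_trajectory`.
#' @export
read_trajectory <- function(path, dt_ps = 10, chain_map = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nf <- nrow(pdb$xyz)
  na <- nrow(pdb$atom)
  xyz <- array(NA_real_, c(nf, na, 3))
  for (k in 1:3) xyz[, , k] <- pdb$xyz[, seq(k, 3 * na, by = 3), drop = FALSE]
  xyz <- xyz / 10  # Angstrom -> nm
  atoms <- data.frame(
    elety = pdb$atom$elety, resid = pdb$atom$resid,
    chain = pdb$atom$chain, resno = pdb$atom$resno,
    elesy = ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                   substr(trimws(pdb$atom$elety), 1, 1), trimws(pdb$atom$elesy)),
    stringsAsFactors = FALSE)
  atoms$category <- .categorize_atoms(atoms, chain_map)
  tl <- grep("^REMARK 250 TIME:", readLines(path), value = TRUE)
  times <- if (length(tl) == nf) {
    as.numeric(sub("^REMARK 250 TIME:\\s*([-0-9.eE+]+).*$", "\\1", tl))
  } else {
    (seq_len(nf) - 1) * dt_ps
  }
  md_trajectory(xyz, atoms, times)
}

# writes an md_trajectory-style frame set as a multi-model PDB (Angstrom),
# with one REMARK 250 TIME record ahead of each MODEL block
.write_multimodel_pdb <- function(path, xyz_nm, atoms, times_ps) {
  nf <- dim(xyz_nm)[1]
  con <- file(path, "w")
  on.exit(close(con))
  serial <- seq_len(nrow(atoms))
  for (f in seq_len(nf)) {
    writeLines(sprintf("REMARK 250 TIME: %.3f PS", times_ps[f]), con)
    writeLines(sprintf("MODEL     %4d", f), con)
    X <- xyz_nm[f, , , drop = TRUE] * 10  # nm -> Angstrom
    if (is.null(dim(X))) X <- matrix(X, ncol = 3)
    lines <- sprintf(
      "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial, atoms$elety, atoms$resid, atoms$chain, atoms$resno,
      X[, 1], X[, 2], X[, 3], atoms$elesy)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# frames retained after excluding the first `burn_in` ns
.retained_frames <- function(traj, burn_in) {
  keep <- which(traj$times > burn_in * 1000)
  if (!length(keep))
    stop(sprintf("no frames left after excluding the first %g ns", burn_in))
  keep
}

.as_traj_list <- function(trajs) {
  if (inherits(trajs, "md_trajectory")) return(list(trajs))
  if (is.list(trajs) && all(vapply(trajs, inherits, logical(1), "md_trajectory")))
    return(trajs)
  stop("`trajs` must be an md_trajectory or a list of them")
}

# heavy atoms only: cutoff-scale analyses exclude hydrogens
.heavy <- function(atoms) {
  !(toupper(atoms$elesy) == "H" | grepl("^[0-9]*H", trimws(atoms$elety)))
}
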