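#' Helical hydrogen-bond distance traces
#'
#' Time series of the backbone O(i)...N(i+4) heavy-atom distance for every
#' helical hydrogen bond whose donor and acceptor both lie in
#' `residue_range` (acceptor `i` from `range[1]` to `range[2] - 4`), for each
#' protein monomer. A bond is considered formed when the distance is at or
#' below 0.35 nm; distances above mark a local helix rupture ("buckle").
#'
#' @param traj An [md_trajectory()].
#' @param residue_range `c(first, last)` acceptor/donor residue window
#'   (default `c(22, 67)`, the long central helix of H-NS).
#' @return List of `hbond_trace` objects: `pair` `(i, i+4)`, `chain`,
#'   `times` (ps), `d` (nm).
#' @export
hbond_distance_traces <- function(traj, residue_range = c(22, 67)) {
  at <- traj$atoms
  chains <- sort(unique(at$chain[grepl("^protein-monomer-", at$category)]))
  lo <- residue_range[1]; hi <- residue_range[2]
  if (hi - lo < 4) stop("residue range must span at least one (i, i+4) pair")
  traces <- list()
  missing <- character()
  for (ch in chains) {
    for (i in lo:(hi - 4)) {
      oi <- which(at$chain == ch & at$resno == i & at$elety == "O")
      nj <- which(at$chain == ch & at$resno == i + 4 & at$elety == "N")
      if (length(oi) != 1L || length(nj) != 1L) {
        missing <- c(missing, sprintf("%s:%d", ch, i))
        next
      }
      dv <- traj$xyz[, oi, , drop = TRUE] - traj$xyz[, nj, , drop = TRUE]
      if (is.null(dim(dv))) dv <- matrix(dv, ncol = 3)
      traces[[length(traces) + 1L]] <- structure(
        list(pair = c(i, i + 4L), chain = ch, times = traj$times,
             d = sqrt(rowSums(dv^2))),
        class = "hbond_trace")
    }
  }
  if (length(missing))
    stop("missing backbone O/N atoms for residue(s): ",
         paste(missing, collapse = ", "))
  traces
}

#' Mean helical hydrogen-bond distance profile
#'
#' Average O(i)...N(i+4) distance per acceptor residue index, over retained
#' frames (burn-in excluded), all replicas and both monomers. Plotted
#' against residue index this profile localises where a helix buckles: a
#' persistent buckle lifts the mean above the 0.35 nm hydrogen-bond
#' threshold in the affected region only.
#'
#' @param trajs Trajectory ensemble.
#' @param residue_range Acceptor/donor window, default `c(22, 67)`.
#' @param burn_in Burn-in per replica, ns (default 10).
#' @return Data frame with `acceptor`, `donor`, `mean_d_nm`.
#' @export
mean_hbond_profile <- function(trajs, residue_range = c(22, 67), burn_in = 10) {
  trajs <- .as_traj_list(trajs)
  if (!length(trajs)) stop("empty trajectory ensemble")
  sums <- NULL; cnt <- 0
  for (tr in trajs) {
    keep <- .retained_frames(tr, burn_in)
    traces <- hbond_distance_traces(tr, residue_range)
    key <- vapply(traces, function(t) t$pair[1], integer(1))
    acc <- sort(unique(key))
    s <- vapply(acc, function(i) {
      sum(vapply(traces[key == i], function(t) sum(t$d[keep]), numeric(1)))
    }, numeric(1))
    n <- vapply(acc, function(i) sum(key == i) * length(keep), numeric(1))
    if (is.null(sums)) { sums <- s; cnt <- n; acc0 <- acc }
    else {
      if (!identical(acc, acc0)) stop("replicas disagree on residue range")
      sums <- sums + s; cnt <- cnt + n
    }
  }
  data.frame(acceptor = acc0, donor = acc0 + 4L, mean_d_nm = sums / cnt)
}

#' Detect buckle events in a hydrogen-bond trace
#'
#' Finds maximal runs of frames with `d > threshold`, merges runs separated
#' by sub-threshold gaps no longer than `gap_tolerance`, discards events
#' shorter than `min_duration`, and labels each event `irreversible` if it
#' extends to the final frame of the trace (the helix never reforms within
#' the trajectory) or `reversible` otherwise.
#'
#' @param trace An `hbond_trace` from [hbond_distance_traces()] (uniformly
#'   sampled).
#' @param threshold Hydrogen-bond rupture threshold, nm (default 0.35).
#' @param min_duration Minimum event duration, ns (default 0.1; suppresses
#'   single-frame flicker at 10 ps cadence).
#' @param gap_tolerance Maximum sub-threshold gap merged into an event, ns
#'   (default 0.05).
#' @return Data frame of class `buckle_events` with columns `i`, `j`
#'   (residue pair), `chain`, `t_start`, `t_end` (ps), `duration_ns`,
#'   `label`; zero rows when no event qualifies.
#' @export
detect_buckle_events <- function(trace, threshold = 0.35, min_duration = 0.1,
                                 gap_tolerance = 0.05) {
  if (!inherits(trace, "hbond_trace")) stop("`trace` must be an hbond_trace")
  dt <- diff(trace$times)
  if (length(dt) && diff(range(dt)) > 1e-6 * mean(dt))
    stop("trace must be uniformly sampled in time")
  dt <- if (length(dt)) dt[1] else 0
  above <- trace$d > threshold
  empty <- data.frame(i = integer(), j = integer(), chain = character(),
                      t_start = numeric(), t_end = numeric(),
                      duration_ns = numeric(), label = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("buckle_events", class(empty))
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # merge sub-threshold gaps <= gap_tolerance that separate two buckled runs
  is_gap <- !r$values & seq_along(r$values) > 1 &
    seq_along(r$values) < length(r$values) &
    r$lengths * dt <= gap_tolerance * 1000
  merged <- r$values | is_gap
  r2 <- rle(merged)
  ends2 <- cumsum(r2$lengths); starts2 <- ends2 - r2$lengths + 1L
  ev <- which(r2$values)
  rows <- lapply(ev, function(k) {
    f0 <- starts[starts2[k]]; f1 <- ends[ends2[k]]
    nfr <- f1 - f0 + 1L
    data.frame(i = trace$pair[1], j = trace$pair[2], chain = trace$chain,
               t_start = trace$times[f0], t_end = trace$times[f1],
               duration_ns = nfr * dt / 1000,
               label = if (f1 == length(trace$d)) "irreversible" else "reversible",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$duration_ns >= min_duration - 1e-12, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("buckle_events", class(out))
  out
}

#' Buckle events for every hydrogen bond of a trajectory ensemble
#'
#' Convenience wrapper: runs [detect_buckle_events()] on every trace of
#' every replica and binds the results, adding a `replica` column.
#'
#' @param trajs Trajectory ensemble.
#' @param residue_range Acceptor/donor window.
#' @param ... Passed to [detect_buckle_events()].
#' @return A `buckle_events` data frame.
#' @export
buckle_event_table <- function(trajs, residue_range = c(22, 67), ...) {
  trajs <- .as_traj_list(trajs)
  out <- list()
  for (k in seq_along(trajs)) {
    for (tr in hbond_distance_traces(trajs[[k]], residue_range)) {
      ev <- detect_buckle_events(tr, ...)
      if (nrow(ev)) { ev$replica <- k; out[[length(out) + 1L]] <- ev }
    }
  }
  if (!length(out)) {
    empty <- detect_buckle_events(
      structure(list(pair = c(1L, 5L), chain = "A", times = c(0, 10),
                     d = c(0.3, 0.3)), class = "hbond_trace"))
    empty$replica <- integer()
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
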