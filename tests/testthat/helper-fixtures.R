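# shared fixture builders; everything is generated in code at test time

# a bare md_trajectory with hand-placed single-atom "residues"
make_point_trajectory <- function(coords_list, times = NULL) {
  nf <- length(coords_list)
  na <- nrow(coords_list[[1]])
  xyz <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) xyz[f, , ] <- coords_list[[f]]
  atoms <- data.frame(
    elety = "CA", resid = "ALA", chain = "A", resno = seq_len(na),
    elesy = "C", category = "protein-monomer-A", stringsAsFactors = FALSE)
  md_trajectory(xyz, atoms, times %||% ((seq_len(nf) - 1) * 10))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# synthetic hydrogen-bond trace with scripted distance values
make_trace <- function(d, dt = 10, pair = c(45L, 49L), chain = "A") {
  structure(list(pair = pair, chain = chain,
                 times = (seq_along(d) - 1) * dt, d = d),
            class = "hbond_trace")
}

# brute-force minimum distance between two atom coordinate sets
brute_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}
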