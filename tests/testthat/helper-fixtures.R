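# Shared fixtures and independent oracles for the test suite.

# Build a minimal dataset from explicit fragment intervals and a forward
# model of per-residue rates (no noise unless sigma > 0).
make_dataset <- function(sequence, intervals, k_true, times,
                         sigma = 0, b = NULL, seed = NULL) {
  aa <- strsplit(sequence, "")[[1]]
  if (is.null(b)) b <- rep(1, length(aa))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    idx <- intervals$start[i]:intervals$end[i]
    idx <- idx[aa[idx] != "P" & idx > 1L]
    d <- vapply(times, function(t) sum((1 - exp(-k_true[idx] * t)) * b[idx]),
                numeric(1))
    if (sigma > 0) d <- pmax(d + rnorm(length(d), 0, sigma), 0)
    data.frame(start = intervals$start[i], end = intervals$end[i],
               time_s = times, d_uptake = d)
  })
  hdx_dataset(sequence, do.call(rbind, rows))
}

# Brute-force subfragment oracle: label every residue with the set of
# covering fragments; maximal runs of constant non-empty covering set are
# the subfragments.
oracle_partition <- function(intervals, n_res) {
  cover <- lapply(seq_len(n_res), function(p)
    sort(which(intervals$start <= p & intervals$end >= p)))
  sig <- vapply(cover, paste, character(1), collapse = ",")
  sig[vapply(cover, length, integer(1)) == 0L] <- NA
  out <- list()
  pos <- 1L
  while (pos <= n_res) {
    if (is.na(sig[pos])) { pos <- pos + 1L; next }
    endp <- pos
    while (endp + 1L <= n_res && !is.na(sig[endp + 1L]) &&
           sig[endp + 1L] == sig[pos]) endp <- endp + 1L
    out[[length(out) + 1L]] <- c(pos, endp)
    pos <- endp + 1L
  }
  do.call(rbind, out)
}

# Grid oracle for box-constrained least squares: cyclic coordinate descent
# where every 1-D step scans the full 0.01-deuteron grid of that
# coordinate (the objective is strictly convex with the ridge, so the
# sweep converges to the grid-resolution global optimum).
oracle_box_lsq <- function(A, d, cap, step = 0.01, ridge = 1e-8) {
  p <- ncol(A)
  x <- rep(0, p)
  grids <- lapply(seq_len(p), function(j) seq(0, cap[j], by = step))
  obj <- function(x) sum((A %*% x - d)^2) + ridge * sum(x^2)
  best <- obj(x)
  for (sweep in 1:200) {
    changed <- FALSE
    for (j in seq_len(p)) {
      vals <- vapply(grids[[j]], function(v) {
        xx <- x; xx[j] <- v; obj(xx)
      }, numeric(1))
      v <- grids[[j]][which.min(vals)]
      if (v != x[j]) { x[j] <- v; changed <- TRUE }
    }
    if (!changed) break
  }
  x
}

# Closed-form EX2 fragment uptake for a rate vector (the forward model the
# solvers are tested against).
uptake_forward <- function(k, t, b = rep(1, length(k))) {
  sum((1 - exp(-k * t)) * b)
}

default_times <- function() 10^seq(log10(0.3), log10(3.4e5), length.out = 13)
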