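# Synthetic HDX-MS scenario generator.
#
# Emulates the data regime of a dual-protease (pepsin + fungal protease
# XIII) experiment on a two-domain helical protein: a dense overlapping
# peptide library (4-41 residues, per-residue redundancy >= 3), a log-spaced
# labeling time grid, EX2 single-exponential uptake per amide spanning
# ~1e-6..1e2 s^-1, first-order back-exchange loss over the LC lag and
# Gaussian centroid noise. Every random draw is funded by one explicit seed
# and echoed into a manifest so a scenario can be re-instantiated exactly.

# residue frequencies loosely matching a soluble proteome (incl. prolines)
.AA_FREQ <- c(A = 8.3, C = 1.4, D = 5.4, E = 6.8, F = 3.9, G = 7.1, H = 2.3,
              I = 6.0, K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 4.0,
              R = 5.5, S = 6.6, T = 5.4, V = 6.9, W = 1.1, Y = 2.9)

#' Define a synthetic HDX-MS scenario
#'
#' Defaults reproduce the study conditions the pipeline is designed for: a
#' 220-residue helical protein, 200 overlapping peptides of 4-41 residues
#' with per-residue redundancy >= 3, 13 log-spaced labeling times from 0.3 s
#' to 3.4e5 s (the two sub-3-second points folded from on-ice incubations),
#' 0.05 D centroid noise, a 30 s quenched LC lag, labeling at pH-meter 7.0 /
#' 298.15 K and quench at pH-meter 2.5 / 273.15 K.
#'
#' @param length Protein length (ignored when `sequence` is given).
#' @param sequence Optional protein sequence; sampled when `NULL`.
#' @param truth_log10k Optional per-residue ground-truth `log10 k_ex`;
#'   generated from the helix/loop profile model when `NULL`.
#' @param n_fragments Minimum library size.
#' @param frag_len Length range of peptides.
#' @param redundancy_target Minimum per-residue coverage redundancy.
#' @param times Labeling time grid (s).
#' @param sigma Centroid noise standard deviation (deuterons).
#' @param t_lag LC lag time (s).
#' @param labeling,quench [exchange_conditions()] for the two stages.
#' @param n_spikes Number of very-slow anchor residues injected into the
#'   truth profile (mimicking deeply buried core residues).
#' @param seed Integer seed funding all randomness of the scenario.
#' @return Object of class `hdx_scenario` (a list of the above, with the
#'   sequence and truth realised).
#' @export
hdx_scenario <- function(length = 220L, sequence = NULL, truth_log10k = NULL,
                         n_fragments = 200L, frag_len = c(4L, 41L),
                         redundancy_target = 3,
                         times = 10^seq(log10(0.3), log10(3.4e5),
                                        length.out = 13),
                         sigma = 0.05, t_lag = 30,
                         labeling = exchange_conditions(7.0, 298.15, "labeling"),
                         quench = exchange_conditions(2.5, 273.15, "quench"),
                         n_spikes = 4L, seed = 1L) {
  stopifnot(frag_len[1] >= 2L, frag_len[2] >= frag_len[1], sigma >= 0,
            t_lag >= 0, all(times > 0))
  if (is.null(sequence)) {
    sequence <- .with_rng(.scenario_rng(seed, "sequence"),
                          paste(sample(names(.AA_FREQ), length,
                                       replace = TRUE, prob = .AA_FREQ),
                                collapse = ""))
  }
  aa <- .split_sequence(sequence)
  length <- base::length(aa)
  if (is.null(truth_log10k)) {
    truth_log10k <- .truth_profile(length, n_spikes,
                                   .scenario_rng(seed, "truth"))
  }
  stopifnot(base::length(truth_log10k) == length)
  truth_log10k[aa == "P"] <- -Inf
  truth_log10k[1] <- -Inf
  out <- list(sequence = sequence, aa = aa, truth_log10k = truth_log10k,
              n_fragments = as.integer(n_fragments),
              frag_len = as.integer(frag_len),
              redundancy_target = redundancy_target,
              times = times, sigma = sigma, t_lag = t_lag,
              labeling = labeling, quench = quench,
              n_spikes = as.integer(n_spikes), seed = as.integer(seed))
  class(out) <- "hdx_scenario"
  out
}

# derive independent RNG streams from the scenario seed, leaving the
# caller's RNG untouched
.scenario_rng <- function(seed, what) {
  offs <- c(sequence = 11L, truth = 23L, library = 37L, noise = 53L,
            errors = 71L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed((seed * 97L + offs[[what]]) %% .Machine$integer.max)
  s <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

.with_rng <- function(state, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", state, envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Helix/loop ground-truth profile: slow plateaus with parabolic flanks at
# helix positions, fast dips at loops, optional very-slow spike anchors.
.truth_profile <- function(n, n_spikes, rng_state) {
  .with_rng(rng_state, {
    lk <- numeric(n)
    pos <- 1L
    helix <- TRUE
    while (pos <= n) {
      len <- if (helix) sample(18:30, 1) else sample(3:8, 1)
      idx <- pos:min(pos + len - 1L, n)
      if (helix) {
        depth <- runif(1, -5.5, -3)          # log10 k at helix centre
        edge <- runif(1, -1.5, -0.5)         # at helix ends
        rel <- (seq_along(idx) - 1) / max(length(idx) - 1, 1)
        lk[idx] <- edge + (depth - edge) * (1 - (2 * rel - 1)^2)
      } else {
        lk[idx] <- runif(length(idx), -0.5, 1.5)
      }
      pos <- pos + len
      helix <- !helix
    }
    lk <- lk + rnorm(n, 0, 0.15)
    if (n_spikes > 0) {
      at <- sample(seq(10L, n - 10L), n_spikes)
      lk[at] <- runif(n_spikes, -6, -5.5)
    }
    pmin(pmax(lk, -6), 2)
  })
}

#' Generate an overlapping peptide library for a scenario
#'
#' Draws peptides with uniform start and length within the configured range
#' until both the library-size and per-residue redundancy targets are met
#' and the sequence is fully covered. Deterministic under the scenario seed.
#'
#' @param scenario An `hdx_scenario`.
#' @return Data frame of fragments (`start`, `end`).
#' @export
generate_peptide_library <- function(scenario) {
  stopifnot(inherits(scenario, "hdx_scenario"))
  n <- length(scenario$aa)
  fl <- scenario$frag_len
  if (fl[1] > n)
    .stop_pos("fragment length range starts beyond the protein length")
  .with_rng(.scenario_rng(scenario$seed, "library"), {
    frags <- list()
    red <- integer(n)
    pick1 <- function(v) v[sample.int(length(v), 1L)]  # safe for length 1
    draw <- function() {
      len <- pick1(fl[1]:min(fl[2], n))
      start <- pick1(seq_len(n - len + 1L))
      c(start, start + len - 1L)
    }
    guard <- 0L
    while (length(frags) < scenario$n_fragments ||
           min(red) < scenario$redundancy_target) {
      guard <- guard + 1L
      if (guard > 50L * scenario$n_fragments)
        .stop_pos("redundancy target %g unreachable with the configured library parameters",
                  scenario$redundancy_target)
      f <- if (min(red) < scenario$redundancy_target &&
               length(frags) >= scenario$n_fragments) {
        # target the least-covered residue directly
        worst <- which.min(red)
        len <- pick1(fl[1]:min(fl[2], n))
        start <- min(max(1L, worst - sample.int(len, 1) + 1L), n - len + 1L)
        c(start, start + len - 1L)
      } else draw()
      key <- paste(f, collapse = "-")
      if (!is.null(frags[[key]])) next
      frags[[key]] <- f
      red[f[1]:f[2]] <- red[f[1]:f[2]] + 1L
    }
    m <- do.call(rbind, frags)
    out <- data.frame(start = m[, 1], end = m[, 2])
    out[order(out$start, out$end), , drop = FALSE]
  })
}

#' Simulate centroid uptake data for a scenario
#'
#' Applies the EX2 forward model per fragment and time,
#' `D = sum_i (1 - e^(-k_i t)) e^(-k_bk,i t_lag) + eps`, with `k_bk` computed
#' from the bundled random-coil model at the quench conditions and Gaussian
#' noise truncated to the physical range `[0, capacity]`.
#'
#' @param scenario An `hdx_scenario`.
#' @param library Optional fragment data frame; generated when `NULL`.
#' @param fd_reference Emit a fully-deuterated reference column
#'   (`d_max = sum_i e^(-k_bk,i t_lag)`)?
#' @return An `hdx_dataset` carrying the scenario in attribute `scenario`
#'   and the library in its fragment table.
#' @export
simulate_uptake <- function(scenario, library = NULL, fd_reference = TRUE) {
  stopifnot(inherits(scenario, "hdx_scenario"))
  if (is.null(library)) library <- generate_peptide_library(scenario)
  aa <- scenario$aa
  n <- length(aa)
  k <- ifelse(is.finite(scenario$truth_log10k), 10^scenario$truth_log10k, 0)
  k_bk <- compute_back_exchange_rates(scenario$sequence, scenario$quench)
  b <- exp(-k_bk$k * scenario$t_lag)
  active <- function(s, e) {
    idx <- s:e
    idx[aa[idx] != "P" & idx > 1L]
  }
  .with_rng(.scenario_rng(scenario$seed, "noise"), {
    rows <- vector("list", nrow(library))
    for (i in seq_len(nrow(library))) {
      idx <- active(library$start[i], library$end[i])
      cap <- length(idx)
      dmax <- sum(b[idx])
      clean <- vapply(scenario$times, function(t)
        sum((1 - exp(-k[idx] * t)) * b[idx]), numeric(1))
      noisy <- pmin(pmax(clean + rnorm(length(clean), 0, scenario$sigma), 0), cap)
      rows[[i]] <- data.frame(start = library$start[i], end = library$end[i],
                              time_s = scenario$times, d_uptake = noisy,
                              d_max = if (fd_reference) dmax else NA_real_)
    }
    rec <- do.call(rbind, rows)
    if (!fd_reference) rec$d_max <- NULL
    ds <- hdx_dataset(scenario$sequence, rec,
                      conditions_labeling = scenario$labeling,
                      conditions_quench = scenario$quench,
                      t_lag = scenario$t_lag)
    attr(ds, "scenario") <- scenario
    ds
  })
}

#' Inject gross errors into a known fragment subset
#'
#' Adds a constant offset (randomly signed per fragment, as a misassigned
#' peptide may be lighter or heavier than the assigned one; floored at zero
#' uptake) to all time points of a seeded random subset of fragments, so
#' that downstream residual filtering can be exercised against a known
#' answer. A fragment whose uptake never reaches `magnitude` cannot display
#' a negative offset of that size, so such fragments are always shifted
#' upward - the injected error is guaranteed to be gross.
#'
#' @param dataset An `hdx_dataset`.
#' @param fraction Fraction of fragments to corrupt (0..1), or an integer
#'   count if >= 1.
#' @param magnitude Offset magnitude in deuterons.
#' @param seed Seed for the subset and sign draws.
#' @return The corrupted dataset; attribute `corrupted_keys` lists the
#'   affected fragment keys.
#' @export
inject_gross_errors <- function(dataset, fraction, magnitude = 3, seed = 1L) {
  stopifnot(inherits(dataset, "hdx_dataset"), fraction >= 0)
  keys <- dataset$fragments$key
  n_bad <- if (fraction < 1) round(fraction * length(keys)) else as.integer(fraction)
  n_bad <- min(n_bad, length(keys))
  draw <- .with_rng(.scenario_rng(seed, "errors"), {
    bad <- sample(keys, n_bad)
    list(bad = bad, sign = sample(c(-1, 1), n_bad, replace = TRUE))
  })
  bad <- draw$bad
  rec <- dataset$records
  for (i in seq_along(bad)) {
    hit <- rec$key == bad[i]
    sgn <- if (max(rec$d_uptake[hit]) < magnitude) 1 else draw$sign[i]
    rec$d_uptake[hit] <- pmax(rec$d_uptake[hit] + sgn * magnitude, 0)
  }
  out <- hdx_dataset(dataset$sequence, rec, dataset$conditions_labeling,
                     dataset$conditions_quench, dataset$t_lag,
                     dataset$n_term_excl)
  attr(out, "scenario") <- attr(dataset, "scenario")
  attr(out, "corrupted_keys") <- sort(bad)
  out
}

#' Write a scenario manifest (plus FASTA and truth profile)
#'
#' The manifest (YAML) contains every parameter needed to re-instantiate the
#' scenario bit-identically via [scenario_from_manifest()].
#'
#' @param scenario An `hdx_scenario`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_scenario_bundle <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- list(sequence = scenario$sequence,
              truth_log10k = unname(ifelse(is.finite(scenario$truth_log10k),
                                           scenario$truth_log10k, NA)),
              n_fragments = scenario$n_fragments,
              frag_len = scenario$frag_len,
              redundancy_target = scenario$redundancy_target,
              times = scenario$times, sigma = scenario$sigma,
              t_lag = scenario$t_lag,
              labeling = unclass(scenario$labeling),
              quench = unclass(scenario$quench),
              n_spikes = scenario$n_spikes, seed = scenario$seed,
              package_version = as.character(packageVersion("hdxfp")))
  path <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(man, path, precision = 17L)
  write_fasta_sequence(scenario$sequence, file.path(dir, "protein.fasta"),
                       "synthetic-protein")
  truth <- data.frame(position = seq_along(scenario$aa),
                      residue = scenario$aa,
                      log10_k_true = scenario$truth_log10k)
  write.table(truth, file.path(dir, "truth_rates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-instantiate a scenario from its manifest
#' @param path Path to a `scenario.yaml` written by [write_scenario_bundle()].
#' @return An `hdx_scenario` identical to the one that wrote the manifest.
#' @export
scenario_from_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  truth <- unlist(man$truth_log10k)
  truth[is.na(truth)] <- -Inf
  hdx_scenario(sequence = man$sequence, truth_log10k = truth,
               n_fragments = man$n_fragments,
               frag_len = unlist(man$frag_len),
               redundancy_target = man$redundancy_target,
               times = unlist(man$times), sigma = man$sigma,
               t_lag = man$t_lag,
               labeling = exchange_conditions(man$labeling$pH_meter,
                                              man$labeling$temperature,
                                              man$labeling$label),
               quench = exchange_conditions(man$quench$pH_meter,
                                            man$quench$temperature,
                                            man$quench$label),
               n_spikes = man$n_spikes, seed = man$seed)
}

#' @export
print.hdx_scenario <- function(x, ...) {
  cat(sprintf("<hdx_scenario> %d residues, >=%d fragments (len %d-%d, redundancy >=%g), %d times, sigma %.3g D, t_lag %g s, seed %d\n",
              length(x$aa), x$n_fragments, x$frag_len[1], x$frag_len[2],
              x$redundancy_target, length(x$times), x$sigma, x$t_lag, x$seed))
  invisible(x)
}
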