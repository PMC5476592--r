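# Synthetic scenario generator: determinism, forward-model limits,
# gross-error injection, manifest round trips.

test_that("libraries are deterministic under the seed and respect the length range", {
  sc <- hdx_scenario(length = 100L, n_fragments = 60L, seed = 21L)
  l1 <- generate_peptide_library(sc)
  l2 <- generate_peptide_library(sc)
  expect_identical(l1, l2)
  len <- l1$end - l1$start + 1
  expect_true(all(len >= sc$frag_len[1] & len <= sc$frag_len[2]))
  expect_gte(nrow(l1), sc$n_fragments)

  sc2 <- hdx_scenario(length = 100L, n_fragments = 60L, seed = 22L)
  expect_false(identical(generate_peptide_library(sc2), l1))
})

test_that("a redundancy-1 full-length library is the single spanning fragment", {
  sc <- hdx_scenario(length = 30L, n_fragments = 1L, frag_len = c(30L, 30L),
                     redundancy_target = 1, seed = 1L)
  lib <- generate_peptide_library(sc)
  expect_equal(nrow(lib), 1L)
  expect_equal(c(lib$start, lib$end), c(1L, 30L))
})

test_that("an unreachable redundancy target is rejected with an explanation", {
  sc <- hdx_scenario(length = 10L, n_fragments = 2L, frag_len = c(4L, 6L),
                     redundancy_target = 500, seed = 1L)
  expect_error(generate_peptide_library(sc), "unreachable")
})

test_that("noise-free uptake saturates at capacity without lag and below it with lag", {
  long_times <- c(1e7, 1e8)
  sc0 <- hdx_scenario(length = 25L, n_fragments = 10L, frag_len = c(5L, 10L),
                      times = long_times, sigma = 0, t_lag = 0,
                      truth_log10k = rep(-1, 25), seed = 2L)
  ds0 <- simulate_uptake(sc0)
  caps <- ds0$fragments$capacity[match(ds0$records$key, ds0$fragments$key)]
  expect_equal(ds0$records$d_uptake, caps, tolerance = 1e-4)

  sc1 <- hdx_scenario(length = 25L, n_fragments = 10L, frag_len = c(5L, 10L),
                      times = long_times, sigma = 0, t_lag = 120,
                      truth_log10k = rep(-1, 25), seed = 2L)
  ds1 <- simulate_uptake(sc1)
  k_bk <- compute_back_exchange_rates(sc1$sequence, sc1$quench)
  b <- exp(-k_bk$k * sc1$t_lag)
  aa <- sc1$aa
  plateau <- vapply(seq_len(nrow(ds1$records)), function(i) {
    idx <- ds1$records$start[i]:ds1$records$end[i]
    idx <- idx[aa[idx] != "P" & idx > 1L]
    sum(b[idx])
  }, numeric(1))
  expect_equal(ds1$records$d_uptake, plateau, tolerance = 1e-4)
  expect_true(all(ds1$records$d_uptake < caps + 1e-9))
  # the fully-deuterated reference column equals the plateau
  expect_equal(ds1$records$d_max, plateau, tolerance = 1e-9)
})

test_that("a single-amide fragment reproduces the one-residue exponential exactly", {
  times <- default_times()
  k <- 0.02
  truth <- rep(-Inf, 12); truth[5] <- log10(k)
  sc <- hdx_scenario(sequence = strrep("A", 12), truth_log10k = truth,
                     times = times, sigma = 0, t_lag = 0, n_fragments = 1L,
                     seed = 3L)
  lib <- data.frame(start = 4L, end = 5L)
  ds <- simulate_uptake(sc, library = lib)
  expect_equal(ds$records$d_uptake, 1 - exp(-k * times), tolerance = 1e-12)
})

test_that("gross-error injection is seeded, bounded and recorded", {
  sc <- hdx_scenario(length = 60L, n_fragments = 40L, frag_len = c(4L, 12L),
                     seed = 13L)
  ds <- simulate_uptake(sc)
  same <- inject_gross_errors(ds, 0, seed = 13L)
  expect_equal(same$records$d_uptake, ds$records$d_uptake)

  a <- inject_gross_errors(ds, 10L, magnitude = 3, seed = 13L)
  b <- inject_gross_errors(ds, 10L, magnitude = 3, seed = 13L)
  expect_identical(attr(a, "corrupted_keys"), attr(b, "corrupted_keys"))
  expect_length(attr(a, "corrupted_keys"), 10L)
  expect_true(all(a$records$d_uptake >= 0))
  hit <- a$records$key %in% attr(a, "corrupted_keys")
  expect_true(any(abs(a$records$d_uptake[hit] - ds$records$d_uptake[hit]) > 1))
  expect_equal(a$records$d_uptake[!hit], ds$records$d_uptake[!hit])
})

test_that("scenario manifests re-instantiate the identical scenario and data", {
  sc <- hdx_scenario(length = 45L, n_fragments = 30L, frag_len = c(4L, 12L),
                     seed = 17L)
  dir <- withr::local_tempdir()
  res <- run_simulate(sc, dir)
  expect_true(all(file.exists(file.path(dir, c("scenario.yaml",
                                               "protein.fasta",
                                               "truth_rates.tsv",
                                               "uptake.tsv")))))
  sc2 <- scenario_from_manifest(file.path(dir, "scenario.yaml"))
  expect_identical(sc2$sequence, sc$sequence)
  expect_equal(sc2$truth_log10k, sc$truth_log10k, tolerance = 1e-12)
  ds2 <- simulate_uptake(sc2)
  expect_equal(ds2$records$d_uptake, res$dataset$records$d_uptake,
               tolerance = 1e-12)
  truth <- read.table(file.path(dir, "truth_rates.tsv"), header = TRUE,
                      sep = "\t")
  expect_equal(truth$log10_k_true,
               ifelse(is.finite(sc$truth_log10k), sc$truth_log10k, -Inf),
               tolerance = 1e-9)
})

test_that("recovery degrades with noise and improves with redundancy", {
  run_one <- function(sigma, redundancy, seed) {
    sc <- hdx_scenario(length = 60L, n_fragments = as.integer(20 * redundancy),
                       frag_len = c(4L, 14L), sigma = sigma,
                       redundancy_target = redundancy, seed = seed)
    ds <- simulate_uptake(sc)
    p <- compute_partition(ds$fragments, ds$sequence)
    dl <- fit_subfragment_d(ds, p)
    k_bk <- compute_back_exchange_rates(ds$sequence, sc$quench)
    # at the harshest noise level the optimiser may exhaust its iteration
    # budget; the returned best point is still the quantity under study
    pr <- suppressWarnings(
      fit_amide_rates(ds, p, seed_rates(dl), k_bk, t_lag = sc$t_lag))
    # covered residues in the identifiable window; weakly determined ones
    # stay in so that low-redundancy libraries pay for their ambiguity
    ok <- is.finite(sc$truth_log10k) & sc$truth_log10k >= -5 &
      sc$truth_log10k <= 1 &
      pr$profile$flag %in% c("", "weakly determined")
    sqrt(mean((log10(pr$profile$k_ex[ok]) - sc$truth_log10k[ok])^2))
  }
  errs_sigma <- vapply(c(0.01, 0.5), function(s)
    mean(vapply(31:33, function(seed) run_one(s, 3, seed), numeric(1))),
    numeric(1))
  expect_lt(errs_sigma[1], errs_sigma[2])
  errs_red <- vapply(c(2, 5), function(r)
    mean(vapply(34:36, function(seed) run_one(0.1, r, seed), numeric(1))),
    numeric(1))
  expect_lt(errs_red[2], errs_red[1])
})
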