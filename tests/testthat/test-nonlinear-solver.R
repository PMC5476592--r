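# Stage-2 rate seeding and global per-amide non-linear fit.

# minimal hdx_dlevels stand-in for seeding tests
fake_dlevels <- function(x, times, starts, ends, capacities, prot) {
  p <- compute_partition(data.frame(start = starts, end = ends), prot)
  stopifnot(nrow(p$subfragments) == nrow(x))
  p$subfragments$capacity <- capacities
  structure(list(x = x, times = times, partition = p), class = "hdx_dlevels")
}

test_that("seeding recovers the closed-form rate from a half-saturated point", {
  prot <- strrep("A", 6)
  dl <- fake_dlevels(matrix(c(0.5, 1), 1, 2), c(1, 1e6), 2, 2, 1, prot)
  s <- seed_rates(dl)
  expect_equal(s$k_seed[1], log(2), tolerance = 1e-3)
})

test_that("seeding recovers a known rate from a clean 13-point series within 1%", {
  prot <- strrep("A", 10)
  times <- default_times()
  for (k in c(1, 0.01, 1e-4)) {
    f <- 4 * (1 - exp(-k * times))
    dl <- fake_dlevels(matrix(f, 1), times, 2, 6, 4, prot)
    s <- seed_rates(dl)
    expect_equal(s$k_seed[1], k, tolerance = 0.01)
  }
})

test_that("degenerate subfragments are seeded at the bound and flagged", {
  prot <- strrep("A", 10)
  times <- default_times()
  dl <- fake_dlevels(rbind(rep(0, 13), 4 * (1 - exp(-0.01 * times))),
                     times, c(2, 5), c(4, 9), c(3, 4), prot)
  s <- seed_rates(dl)
  expect_equal(s$k_seed[1], 1e-8)
  expect_match(s$flag[1], "no uptake")
  dl0 <- fake_dlevels(matrix(1, 1, 13), times, 2, 3, 0, prot)
  expect_match(seed_rates(dl0)$flag[1], "no capacity")
})

test_that("well-separated rates in one fragment are recovered within 5%", {
  prot <- "AAAA"
  k_true <- c(0, 1, 0.01, 1e-4)
  times <- default_times()
  ints <- data.frame(start = 2, end = 4)
  ds <- make_dataset(prot, ints, k_true, times)
  p <- compute_partition(ints, prot)
  dl <- fit_subfragment_d(ds, p)
  pr <- fit_amide_rates(ds, p, seed_rates(dl), k_bk = NULL, t_lag = 0)
  expect_equal(pr$profile$k_ex[2:4], k_true[2:4], tolerance = 0.05)
  expect_true(pr$converged)
  expect_lte(pr$GE_nonlin, pr$GE_seed + 1e-12)
})

test_that("zero lag time reduces exactly to the uncorrected uptake model", {
  sc <- hdx_scenario(length = 30L, n_fragments = 20L, frag_len = c(4L, 10L),
                     sigma = 0, t_lag = 0, seed = 6L)
  ds <- simulate_uptake(sc)
  p <- compute_partition(ds$fragments, ds$sequence)
  dl <- fit_subfragment_d(ds, p)
  s <- seed_rates(dl)
  k_bk <- compute_back_exchange_rates(ds$sequence, sc$quench)
  a <- fit_amide_rates(ds, p, s, k_bk, t_lag = 0)
  b <- fit_amide_rates(ds, p, s, k_bk = NULL, t_lag = 0)
  expect_equal(a$profile$k_ex, b$profile$k_ex, tolerance = 1e-9)
  expect_true(all(a$b_retention == 1))
})

test_that("prolines and the N-terminus are held at zero through the fit", {
  sc <- hdx_scenario(length = 40L, sequence = NULL, n_fragments = 30L,
                     frag_len = c(4L, 12L), sigma = 0.02, seed = 8L)
  ds <- simulate_uptake(sc)
  p <- compute_partition(ds$fragments, ds$sequence)
  dl <- fit_subfragment_d(ds, p)
  k_bk <- compute_back_exchange_rates(ds$sequence, sc$quench)
  pr <- fit_amide_rates(ds, p, seed_rates(dl), k_bk, t_lag = sc$t_lag)
  pro <- which(strsplit(ds$sequence, "")[[1]] == "P")
  expect_true(all(pr$profile$k_ex[pro] == 0))
  expect_true(all(pr$profile$flag[pro] == "proline"))
  expect_identical(pr$profile$k_ex[1], 0)
})

test_that("log-rate recovery across nine orders with per-residue subfragments", {
  # every residue isolated in a length-1 subfragment: boundaries everywhere
  prot <- strrep("A", 12)
  k_true <- c(0, 10^c(-6, -5, -4, -3, -2, -1, 0, 1, 2, -3.5, -2.5))
  times <- default_times()
  starts <- 2:11
  ints <- rbind(data.frame(start = starts, end = starts + 1L),
                data.frame(start = 2, end = 12))
  ds <- make_dataset(prot, ints, k_true, times)
  p <- compute_partition(ints, prot)
  dl <- fit_subfragment_d(ds, p)
  pr <- fit_amide_rates(ds, p, seed_rates(dl), k_bk = NULL, t_lag = 0)
  est <- log10(pr$profile$k_ex[2:12])
  truth <- log10(k_true[2:12])
  inside <- truth >= -6 & truth <= 2
  expect_lt(max(abs(est[inside] - truth[inside])), 0.05)
  # ordering of well-separated rates is preserved
  expect_true(all(diff(order(est)) == diff(order(truth))))
})

test_that("bounds are respected and censored no-uptake residues sit at the lower bound", {
  prot <- strrep("A", 8)
  k_true <- c(0, rep(1e-12, 7))          # effectively non-exchanging
  times <- default_times()
  ints <- data.frame(start = c(2, 4), end = c(5, 8))
  ds <- make_dataset(prot, ints, k_true, times)
  p <- compute_partition(ints, prot)
  dl <- fit_subfragment_d(ds, p)
  pr <- fit_amide_rates(ds, p, seed_rates(dl), k_bk = NULL, t_lag = 0)
  fitted <- pr$profile[pr$profile$position >= 2, ]
  expect_true(all(fitted$k_ex >= 1e-8 * (1 - 1e-9)))
  expect_true(any(grepl("at lower bound", fitted$flag)))
})

test_that("upper bounds from the intrinsic table cap the fitted rates", {
  sc <- hdx_scenario(length = 30L, n_fragments = 25L, frag_len = c(4L, 10L),
                     sigma = 0.05, seed = 10L)
  ds <- simulate_uptake(sc)
  p <- compute_partition(ds$fragments, ds$sequence)
  dl <- fit_subfragment_d(ds, p)
  k_int <- compute_intrinsic_rates(ds$sequence, sc$labeling)
  k_bk <- compute_back_exchange_rates(ds$sequence, sc$quench)
  pr <- fit_amide_rates(ds, p, seed_rates(dl), k_bk, t_lag = sc$t_lag,
                        bounds = list(lower = 1e-8, upper = k_int))
  idx <- pr$fit_idx
  expect_true(all(pr$profile$k_ex[idx] <=
                    pmax(k_int$k[idx], 1e-7) * (1 + 1e-6)))
})

test_that("multi-start dispersion is small for well-determined residues", {
  prot <- strrep("A", 10)
  k_true <- c(0, 10^runif(9, -3, -1))
  times <- default_times()
  starts <- 2:9
  ints <- rbind(data.frame(start = starts, end = starts + 1L))
  ds <- make_dataset(prot, ints, k_true, times)
  p <- compute_partition(ints, prot)
  dl <- fit_subfragment_d(ds, p)
  set.seed(123)
  pr <- fit_amide_rates(ds, p, seed_rates(dl), k_bk = NULL, t_lag = 0,
                        n_starts = 4L, perturb_sd = 0.5)
  expect_true(all(pr$dispersion_log10k < 0.1))
})

test_that("relabeling residues and fragments consistently permutes the profile", {
  # mirror-image protein: reverse the sequence and the fragment set; a
  # two-residue ladder makes every residue's coverage context unique, so
  # the fit is identifiable and must map position-for-position
  prot <- "AGLKVSWT"
  k_true <- c(0, 0.5, 0.02, 1e-3, 0.3, 5e-3, 0.08, 0)
  times <- default_times()
  ints <- rbind(data.frame(start = 2:7, end = 3:8),
                data.frame(start = 2, end = 8))
  ds <- make_dataset(prot, ints, k_true, times)
  p <- compute_partition(ints, prot)
  pr <- fit_amide_rates(ds, p, seed_rates(fit_subfragment_d(ds, p)),
                        k_bk = NULL, t_lag = 0)

  rprot <- paste(rev(strsplit(prot, "")[[1]]), collapse = "")
  n <- nchar(prot)
  rints <- data.frame(start = n + 1 - ints$end, end = n + 1 - ints$start)
  rk <- rev(k_true)
  # the reversed protein's position 1 must be excluded as its N-terminus,
  # and old position 1 becomes its C-terminal amide; restrict the
  # comparison to interior positions fitted in both orientations
  rds <- make_dataset(rprot, rints, rk, times)
  rp <- compute_partition(rints, rprot)
  rpr <- fit_amide_rates(rds, rp, seed_rates(fit_subfragment_d(rds, rp)),
                         k_bk = NULL, t_lag = 0)
  fwd <- pr$profile$k_ex[2:7]
  rev_ <- rpr$profile$k_ex[n + 1 - (2:7)]   # old position i maps to n+1-i
  expect_equal(log10(rev_), log10(fwd), tolerance = 1e-3)
})
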