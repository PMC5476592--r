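# Ingestion, validation, charge merging, filtering, classification,
# coverage.

write_table_fixture <- function(df, sep = ",") {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

test_that("reading merges charge states by (weighted) mean and validates sequences", {
  prot <- "MKLVAGDEFH"
  tab <- data.frame(start = c(2, 2, 2, 2), end = c(5, 5, 5, 5),
                    sequence = "KLVA", charge = c(1, 2, 1, 2),
                    time_s = c(10, 10, 100, 100),
                    d_uptake = c(2.0, 2.2, 3.0, 3.0))
  ds <- read_uptake_table(write_table_fixture(tab), prot)
  expect_equal(nrow(ds$records), 2L)
  expect_equal(sort(ds$records$d_uptake), c(2.1, 3.0))

  # uncertainty-weighted merging when d_se is present
  tab$d_se <- c(0.1, 0.3, 0.2, 0.2)
  ds2 <- read_uptake_table(write_table_fixture(tab), prot)
  w <- 1 / c(0.1, 0.3)^2
  expect_equal(ds2$records$d_uptake[ds2$records$time_s == 10],
               sum(c(2.0, 2.2) * w) / sum(w))

  bad <- tab
  bad$sequence <- "KLVG"       # disagrees at the 4th residue (position 5)
  expect_error(read_uptake_table(write_table_fixture(bad), prot),
               "residue 5")

  expect_error(read_uptake_table(
    write_table_fixture(tab[, setdiff(names(tab), "time_s")]), prot),
    "time_s")
})

test_that("tab-separated input is autodetected and FASTA sequences are accepted", {
  prot <- "MKLVAGDEFH"
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_sequence(prot, fa, "prot")
  expect_identical(read_fasta_sequence(fa), prot)
  tab <- data.frame(start = 2, end = 6, sequence = "KLVAG", charge = 1,
                    time_s = c(10, 100, 1000), d_uptake = c(1, 2, 3))
  ds <- read_uptake_table(write_table_fixture(tab, sep = "\t"), fa)
  expect_equal(nrow(ds$records), 3L)
})

test_that("write/read round trip preserves records exactly", {
  sc <- hdx_scenario(length = 40L, n_fragments = 25L, frag_len = c(4L, 12L),
                     seed = 3L)
  ds <- simulate_uptake(sc, fd_reference = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_uptake_table(ds, path)
  ds2 <- read_uptake_table(path, sc$sequence)
  o1 <- order(ds$records$key, ds$records$time_s)
  o2 <- order(ds2$records$key, ds2$records$time_s)
  expect_identical(ds2$records$d_uptake[o2], ds$records$d_uptake[o1])
  expect_identical(ds2$records$time_s[o2], ds$records$time_s[o1])
})

test_that("exchangeable-amide capacity discounts prolines, the protein N-terminus and configured exclusions", {
  aa <- strsplit("MPKLPVAG", "")[[1]]
  expect_equal(exchangeable_amides(aa, 1, 8), 5)   # minus M1, P2, P5
  expect_equal(exchangeable_amides(aa, 3, 8), 5)   # minus P5
  expect_equal(exchangeable_amides(aa, 3, 8, n_term_excl = 1), 4)
  expect_equal(exchangeable_amides(aa, 4, 4), 1)
  expect_equal(exchangeable_amides(aa, 5, 5), 0)   # a lone proline
})

test_that("fit-error filtering removes offending fragments entirely and is idempotent", {
  prot <- strrep("A", 30)
  tab <- data.frame(start = c(2, 2, 12, 12, 20, 20),
                    end = c(8, 8, 18, 18, 28, 28),
                    time_s = rep(c(10, 100), 3),
                    d_uptake = c(1, 2, 3, 4, 2, 5))
  ds <- hdx_dataset(prot, tab)
  errs <- c("2-8" = 2.5, "12-18" = 1.0, "20-28" = 0.3)
  expect_message(flt <- filter_by_fit_error(ds, errs, 2), "removed 1 of 3")
  expect_identical(attr(flt, "removed_keys"), "2-8")
  expect_false("2-8" %in% flt$fragments$key)
  expect_equal(nrow(flt$fragments), 2L)
  flt2 <- suppressMessages(filter_by_fit_error(flt, errs[-1], 2))
  expect_equal(attr(flt2, "n_removed"), 0L)
  expect_identical(flt2$fragments, flt$fragments)
  expect_error(filter_by_fit_error(ds, errs, 0), "positive")
})

test_that("t50 classification matches the 1000/3000 s thresholds", {
  times <- default_times()
  for (case in list(list(t50 = 500, cls = "fast"),
                    list(t50 = 2000, cls = "intermediate"),
                    list(t50 = 5000, cls = "slow"))) {
    k <- log(2) / case$t50
    d <- 6 * (1 - exp(-k * times))
    cl <- classify_exchange(times, d, 6)
    expect_equal(cl$class, case$cls)
    # log-time interpolation of an exponential is approximate between the
    # sampled grid points
    expect_equal(cl$t50, case$t50, tolerance = 0.12)
  }
})

test_that("classification is invariant to uniform rescaling and handles degenerate series", {
  times <- default_times()
  d <- 4 * (1 - exp(-0.005 * times))
  a <- classify_exchange(times, d, 4)
  b <- classify_exchange(times, 2.5 * d, 2.5 * 4)
  expect_equal(a$class, b$class)
  expect_equal(a$t50, b$t50, tolerance = 1e-9)

  z <- classify_exchange(times, rep(0, length(times)), 4)
  expect_equal(z$class, "slow")
  expect_identical(z$t50, Inf)
  expect_match(z$flag, "no uptake")

  # 50% never reached within the sampled window
  slow <- classify_exchange(c(10, 100), c(0.1, 0.2), 10)
  expect_equal(slow$class, "slow")
  expect_identical(slow$t50, Inf)
})

test_that("coverage statistics count covering fragments and boundaries", {
  prot <- strrep("A", 20)
  one <- hdx_dataset(prot, data.frame(start = 1, end = 10, time_s = 10,
                                      d_uptake = 1))
  cv1 <- coverage_stats(one)
  expect_equal(cv1$redundancy, c(rep(1, 10), rep(0, 10)))
  expect_equal(nrow(attr(cv1, "gaps")), 1L)

  two <- hdx_dataset(prot, data.frame(start = c(1, 5), end = c(10, 15),
                                      time_s = 10, d_uptake = 1))
  cv2 <- coverage_stats(two)
  expect_equal(cv2$redundancy[5:10], rep(2, 6))
  expect_equal(cv2$redundancy[1:4], rep(1, 4))
  expect_equal(cv2$redundancy[11:15], rep(1, 5))
})

test_that("generated libraries reach the configured redundancy", {
  sc <- hdx_scenario(length = 120L, n_fragments = 80L, frag_len = c(4L, 30L),
                     redundancy_target = 3, seed = 5L)
  lib <- generate_peptide_library(sc)
  cv <- coverage_stats(hdx_dataset(sc$sequence,
                                   data.frame(start = lib$start,
                                              end = lib$end,
                                              time_s = 10, d_uptake = 0.1)))
  expect_true(all(cv$redundancy >= 3))
  expect_gte(attr(cv, "mean_redundancy"), 3)
})
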