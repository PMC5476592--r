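# Random-coil ("intrinsic") amide exchange rates.
#
# The chemical exchange rate of an unstructured backbone amide is the sum of
# acid-, base- and water-catalysed terms, each scaled by multiplicative
# nearest-neighbour factors of the amide's own residue (lambda) and of the
# preceding residue (rho):
#
#   k_int,i = kA 10^(-pD) FA,i + kB 10^(pD - pKD) FB,i + kW FB,i
#   FA,i    = 10^(lambdaA(res_i) + rhoA(res_{i-1}) [+ terminal terms])
#
# with Arrhenius temperature correction of kA/kB/kW. Reference constants and
# factors ship with the package (see inst/extdata/randomcoil_*.tsv).

.hdxfp_cache <- new.env(parent = emptyenv())

.reference_set <- function() {
  if (!is.null(.hdxfp_cache$ref)) return(.hdxfp_cache$ref)
  fpath <- system.file("extdata", "randomcoil_factors_v1.tsv", package = "hdxfp")
  cpath <- system.file("extdata", "randomcoil_constants_v1.tsv", package = "hdxfp")
  fac <- read.table(fpath, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  con <- read.table(cpath, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  constants <- setNames(con$value, con$name)
  rownames(fac) <- fac$residue
  ref <- list(factors = fac, constants = constants,
              provenance = "bai1993-spreadsheet/v1")
  .hdxfp_cache$ref <- ref
  ref
}

# Titration-weighted mixing of protonated/deprotonated log10 factors at a pD.
.mix_titration <- function(log_prot, log_deprot, pKa, pD) {
  log10((10^(log_prot - pD) + 10^(log_deprot - pKa)) /
          (10^(-pD) + 10^(-pKa)))
}

# Effective (lambda, rho) log10 factors for one residue code at a given pD.
# `which` is "acid" or "base". Returns c(lambda, rho).
.residue_factors <- function(code, which, pD, ref) {
  fac <- ref$factors
  k <- ref$constants
  pick <- function(row) as.numeric(fac[row, paste0(which, c("_lambda", "_rho"))])
  switch(code,
    "D" = .mix_titration(pick("D_prot"), pick("D_deprot"), k[["pKa_Asp"]], pD),
    "E" = .mix_titration(pick("E_prot"), pick("E_deprot"), k[["pKa_Glu"]], pD),
    "H" = .mix_titration(pick("H_prot"), pick("H_deprot"), k[["pKa_His"]], pD),
    pick(code))
}

.cterm_lambda <- function(which, pD, ref) {
  fac <- ref$factors
  k <- ref$constants
  pick <- function(row) as.numeric(fac[row, paste0(which, "_lambda")])
  .mix_titration(pick("CT_prot"), pick("CT_deprot"), k[["pKa_Cterm"]], pD)
}

#' Intrinsic (random-coil) amide exchange rates for a sequence
#'
#' Computes the chemical exchange rate every backbone amide of `sequence`
#' would have in a fully unstructured chain at the given conditions, from the
#' bundled nearest-neighbour reference factors. The first residue (a free
#' alpha-amine, no backbone amide) and all prolines get a rate of exactly 0.
#'
#' @param sequence Protein sequence, one-letter codes.
#' @param conditions An [exchange_conditions()] object.
#'
#' @return A data frame of class `hdx_rate_table` with columns `position`,
#'   `residue` and `k` (s^-1), and attributes `conditions`, `provenance` and
#'   `extrapolated` (TRUE when the conditions fall outside the tabulated
#'   validity range of the reference set, in which case a warning is issued).
#' @examples
#' k <- compute_intrinsic_rates("MKDLAPEF", exchange_conditions(7, 298.15))
#' k$k[k$residue == "P"]  # prolines have no amide hydrogen
#' @export
compute_intrinsic_rates <- function(sequence, conditions) {
  conditions <- .as_conditions(conditions)
  aa <- .split_sequence(sequence)
  ref <- .reference_set()
  k <- ref$constants
  pD <- conditions$pD
  temp <- conditions$temperature

  extrapolated <- pD < k[["valid_pD_min"]] || pD > k[["valid_pD_max"]] ||
    temp < k[["valid_T_min"]] || temp > k[["valid_T_max"]]
  if (extrapolated)
    warning(sprintf(paste0("conditions (pD %.2f, %.1f K) fall outside the ",
                           "tabulated validity range of reference set %s; ",
                           "rates are extrapolated"),
                    pD, temp, ref$provenance), call. = FALSE)

  Rcal <- 1.987                      # cal mol^-1 K^-1
  arr <- function(Ea) exp(-Ea / Rcal * (1 / temp - 1 / k[["T_ref"]]))
  kA <- 10^k[["log10_kA_ref"]] * arr(k[["Ea_acid"]])
  kB <- 10^k[["log10_kB_ref"]] * arr(k[["Ea_base"]])
  kW <- 10^k[["log10_kW_ref"]] * arr(k[["Ea_water"]])

  n <- length(aa)
  rate <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1L || aa[i] == "P") next
    own  <- .residue_factors(aa[i], "acid", pD, ref)
    left <- .residue_factors(aa[i - 1L], "acid", pD, ref)
    ownB  <- .residue_factors(aa[i], "base", pD, ref)
    leftB <- .residue_factors(aa[i - 1L], "base", pD, ref)
    logFA <- own[1] + left[2]
    logFB <- ownB[1] + leftB[2]
    if (i == 2L) {                   # succeeding the free N-terminal amine
      logFA <- logFA + ref$factors["NT", "acid_rho"]
      logFB <- logFB + ref$factors["NT", "base_rho"]
    }
    if (i == n) {                    # the C-terminal residue's own amide
      logFA <- logFA + .cterm_lambda("acid", pD, ref)
      logFB <- logFB + .cterm_lambda("base", pD, ref)
    }
    per_min <- kA * 10^logFA * 10^(-pD) +
      kB * 10^logFB * 10^(pD - k[["pKD"]]) +
      kW * 10^logFB
    rate[i] <- per_min / 60          # min^-1 -> s^-1
  }

  out <- data.frame(position = seq_len(n), residue = aa, k = rate,
                    stringsAsFactors = FALSE)
  attr(out, "conditions") <- conditions
  attr(out, "provenance") <- ref$provenance
  attr(out, "extrapolated") <- extrapolated
  class(out) <- c("hdx_rate_table", "data.frame")
  out
}

#' Back-exchange rates under quench conditions
#'
#' Convenience wrapper around [compute_intrinsic_rates()] evaluated at the
#' quench conditions (low pH, low temperature). The resulting rates `k_bk`
#' enter the pipeline only through the label-retention factor
#' `exp(-k_bk * t_lag)` over the chromatographic lag time.
#'
#' @inheritParams compute_intrinsic_rates
#' @param quench_conditions An [exchange_conditions()] object describing the
#'   quench buffer.
#' @return See [compute_intrinsic_rates()].
#' @export
compute_back_exchange_rates <- function(sequence, quench_conditions) {
  quench_conditions <- .as_conditions(quench_conditions)
  if (quench_conditions$pD > 7 || quench_conditions$temperature > 298.15)
    warning("quench conditions are expected to be low pH / low temperature",
            call. = FALSE)
  compute_intrinsic_rates(sequence, quench_conditions)
}

#' Temperature-equivalent labeling time
#'
#' Folds a labeling time measured at one temperature onto the time axis of a
#' reference temperature using the rule of thumb that amide exchange slows
#' 10-fold for every 25 degC decrease in temperature:
#' `t_eq = t * 10^((T_actual - T_ref) / 25)`.
#'
#' @param time Labeling time(s) in seconds, > 0.
#' @param actual_temp Temperature at which the incubation was performed (K).
#' @param reference_temp Temperature of the target time axis (K).
#' @return Equivalent time(s) in seconds at `reference_temp`.
#' @examples
#' equivalent_labeling_time(3, 273.15, 298.15)   # 0.3 s
#' equivalent_labeling_time(10, 273.15, 298.15)  # 1 s
#' @export
equivalent_labeling_time <- function(time, actual_temp, reference_temp) {
  stopifnot(is.numeric(time), all(time > 0),
            is.numeric(actual_temp), is.numeric(reference_temp))
  time * 10^((actual_temp - reference_temp) / 25)
}

#' Intrinsic-rate spread over all flanking-residue contexts
#'
#' Evaluates the intrinsic rate of an interior amide for every pair
#' (preceding residue X, amide residue Y) of the 20 standard amino acids at
#' fixed conditions, by computing rates for the tetrapeptides `A X Y A` and
#' reading position 3. Contexts whose amide residue is proline carry no amide
#' hydrogen and are excluded from the summary statistics.
#'
#' @param conditions An [exchange_conditions()] object.
#' @return A list with the 400-row `contexts` data frame (`left`, `residue`,
#'   `k`) and summary elements `max`, `min`, `mean`, `max_over_mean`,
#'   `max_over_min` over the non-proline contexts.
#' @export
intrinsic_rate_contexts <- function(conditions) {
  conditions <- .as_conditions(conditions)
  grid <- expand.grid(left = .AA_CODES, residue = .AA_CODES,
                      stringsAsFactors = FALSE)
  grid$k <- vapply(seq_len(nrow(grid)), function(i) {
    seqi <- paste0("A", grid$left[i], grid$residue[i], "A")
    compute_intrinsic_rates(seqi, conditions)$k[3]
  }, numeric(1))
  kk <- grid$k[grid$residue != "P"]
  list(contexts = grid, max = max(kk), min = min(kk), mean = mean(kk),
       max_over_mean = max(kk) / mean(kk), max_over_min = max(kk) / min(kk))
}
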