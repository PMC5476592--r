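# Stage 2: per-amide exchange rates by global bounded non-linear least
# squares.
#
# Under EX2 kinetics every amide takes up label mono-exponentially,
# D_i(t) = 1 - exp(-k_ex,i t), and loses a fraction during the quenched LC
# lag, retaining b_i = exp(-k_bk,i t_lag). A fragment's predicted centroid
# uptake is the sum over its exchange-capable residues, and all k_ex,i are
# fitted simultaneously against all (fragment, time) observations.
# Optimisation is performed in log10 k (rates span many orders of
# magnitude) with per-residue box bounds, Levenberg-Marquardt, analytic
# Jacobian, and subfragment-derived seeds.

#' Seed per-subfragment exchange rates from fitted deuterium levels
#'
#' For each subfragment, fits the fractional uptake series
#' `x_{j,t} / capacity_j` to `1 - exp(-k t)` by 1-D least squares in
#' `log10 k`. The seed of a subfragment is the collective (average) rate of
#' the amides it contains and initialises each of them in the global fit.
#'
#' @param dlevels An `hdx_dlevels` from [fit_subfragment_d()].
#' @param k_range Log-uniform search range for the seed rate (s^-1).
#' @return Data frame with one row per subfragment: `index`, `k_seed`,
#'   `rss` (residual sum of squares of the exponential fit) and `flag`
#'   (`"no uptake observed"`, `"non-monotone uptake"`, `"no capacity"` or
#'   empty).
#' @export
seed_rates <- function(dlevels, k_range = c(1e-8, 1e2)) {
  stopifnot(inherits(dlevels, "hdx_dlevels"))
  sf <- dlevels$partition$subfragments
  times <- dlevels$times
  out <- data.frame(index = sf$index, k_seed = NA_real_, rss = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  lg <- log10(k_range)
  for (j in seq_len(nrow(sf))) {
    if (sf$capacity[j] == 0) { out$flag[j] <- "no capacity"; next }
    f <- dlevels$x[j, ] / sf$capacity[j]
    ok <- is.finite(f)
    if (sum(ok) < 2L) { out$flag[j] <- "insufficient time points"; next }
    ft <- f[ok]; tt <- times[ok]
    if (all(ft <= 1e-9)) {
      out$k_seed[j] <- k_range[1]
      out$flag[j] <- "no uptake observed"
      next
    }
    obj <- function(lk) sum((ft - (1 - exp(-10^lk * tt)))^2)
    op <- optimize(obj, lower = lg[1], upper = lg[2], tol = 1e-7)
    out$k_seed[j] <- 10^op$minimum
    out$rss[j] <- op$objective
    if (any(diff(ft) < -0.05)) out$flag[j] <- "non-monotone uptake"
  }
  out
}

# Internal: residue membership incidence (fragments x residues), honouring
# proline / protein-N-terminus / fragment-N-terminal exclusions.
.residue_incidence <- function(partition) {
  frag <- partition$fragments
  aa <- partition$aa
  C <- matrix(0, nrow(frag), length(aa),
              dimnames = list(frag$key, seq_along(aa)))
  for (i in seq_len(nrow(frag))) {
    idx <- frag$astart[i]:frag$end[i]
    idx <- idx[aa[idx] != "P" & idx > 1L]
    C[i, idx] <- 1
  }
  C
}

#' Globally fit per-amide exchange rates
#'
#' Minimises the global error
#' `GE_nonlin = sum_{n,t} (D_exp - sum_i (1 - e^(-k_i t)) e^(-k_bk,i t_lag))^2`
#' over all exchange-capable residues simultaneously, subject to per-residue
#' bounds, with prolines and the protein N-terminus held at rate 0.
#'
#' @param dataset An `hdx_dataset`.
#' @param partition The `hdx_partition` of its fragments.
#' @param seeds Output of [seed_rates()] (or a numeric vector of per-residue
#'   starting rates).
#' @param k_bk Back-exchange rate table from [compute_back_exchange_rates()],
#'   or `NULL` for no back-exchange correction.
#' @param t_lag Chromatographic lag time in seconds (>= 0). With `t_lag = 0`
#'   the model reduces to the uncorrected uptake model.
#' @param bounds Either a list `list(lower = 1e-8, upper = k_int_table)`
#'   where `upper` may be an `hdx_rate_table` (per-residue random-coil cap,
#'   the default policy: no amide exchanges faster than in the unstructured
#'   chain) or a numeric scalar/vector.
#' @param d_max_mode `"model"` (default) applies the `exp(-k_bk t_lag)`
#'   correction; `"reference"` rescales each fragment's measurements by its
#'   fully-deuterated control (`d_max` column) instead, and fits the
#'   uncorrected model. The two modes are mutually exclusive.
#' @param n_starts Number of optimiser starts; starts beyond the first
#'   perturb the seed log-rates (`perturb_sd` log10 units) and the best
#'   solution is kept, with per-residue dispersion reported.
#' @param perturb_sd Multi-start perturbation width in log10 units.
#' @param control List: `ftol`, `ptol`, `maxiter` passed to the
#'   Levenberg-Marquardt optimiser.
#' @return Object of class `hdx_rate_profile`: data frame `profile`
#'   (`position`, `residue`, `k_ex`, `lower`, `upper`, `flag`), matrices of
#'   residuals, `GE_nonlin`, `GE_seed`, convergence diagnostics and
#'   multi-start dispersion (`log10 k` sd per residue, NA when
#'   `n_starts = 1`).
#' @export
fit_amide_rates <- function(dataset, partition, seeds, k_bk = NULL,
                            t_lag = 0,
                            bounds = list(lower = 1e-8, upper = NULL),
                            d_max_mode = c("model", "reference"),
                            n_starts = 1L, perturb_sd = 0.5,
                            control = list(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 500L)) {
  stopifnot(inherits(dataset, "hdx_dataset"), inherits(partition, "hdx_partition"))
  d_max_mode <- match.arg(d_max_mode)
  if (t_lag < 0) .stop_pos("t_lag must be >= 0")
  aa <- partition$aa
  n <- length(aa)
  C <- .residue_incidence(partition)
  covered <- colSums(C) > 0
  if (!any(covered)) .stop_pos("no exchange-capable residues are covered")

  # retention factor per residue
  b <- rep(1, n)
  if (d_max_mode == "model" && !is.null(k_bk) && t_lag > 0) {
    stopifnot(nrow(k_bk) == n)
    b <- exp(-k_bk$k * t_lag)
  }

  # per-residue bounds in log10 space
  lower_k <- rep(if (is.null(bounds$lower)) 1e-8 else bounds$lower, length.out = n)
  upper_k <- if (is.null(bounds$upper)) rep(1e3, n)
    else if (inherits(bounds$upper, "hdx_rate_table")) pmax(bounds$upper$k, lower_k * 10)
    else rep(bounds$upper, length.out = n)
  fit_idx <- which(covered & aa != "P" & seq_len(n) > 1L)
  lo <- log10(lower_k[fit_idx])
  up <- log10(upper_k[fit_idx])

  # seeds: map subfragment seeds onto residues
  if (is.data.frame(seeds)) {
    sk <- rep(NA_real_, n)
    sf <- partition$subfragments
    for (j in seq_len(nrow(sf)))
      sk[sf$start[j]:sf$end[j]] <- seeds$k_seed[j]
  } else sk <- rep(seeds, length.out = n)
  th0 <- pmin(pmax(log10(ifelse(is.na(sk[fit_idx]) | sk[fit_idx] <= 0,
                                1e-4, sk[fit_idx])), lo), up)

  # observations
  rec <- dataset$records
  rec <- rec[rec$key %in% rownames(C), , drop = FALSE]
  d_obs <- rec$d_uptake
  if (d_max_mode == "reference") {
    if (is.null(rec$d_max) || !all(is.finite(rec$d_max)))
      .stop_pos("d_max_mode='reference' needs a complete d_max column")
    capv <- partition$fragments$capacity[match(rec$key, partition$fragments$key)]
    d_obs <- d_obs * capv / pmax(rec$d_max, 1e-9)
  }
  frow <- match(rec$key, rownames(C))
  tvals <- sort(unique(rec$time_s))
  tcol <- match(rec$time_s, tvals)
  Cfit <- C[, fit_idx, drop = FALSE]
  bfit <- b[fit_idx]
  obs_index <- cbind(frow, tcol)

  model_D <- function(theta) {
    k <- 10^theta
    U <- (1 - exp(-outer(k, tvals))) * bfit      # residues x times
    (Cfit %*% U)[obs_index]
  }
  resid_fn <- function(theta) d_obs - model_D(theta)
  jac_fn <- function(theta) {
    k <- 10^theta
    G <- exp(-outer(k, tvals)) * outer(k, tvals) * log(10) * bfit
    J <- matrix(0, nrow(rec), length(theta))
    for (ti in seq_along(tvals)) {
      sel <- which(tcol == ti)
      J[sel, ] <- -Cfit[frow[sel], , drop = FALSE] *
        matrix(G[, ti], length(sel), length(theta), byrow = TRUE)
    }
    J
  }

  ctl <- minpack.lm::nls.lm.control(ftol = control$ftol, ptol = control$ptol,
                                    maxiter = min(control$maxiter, 1024L))
  run_fit <- function(start) {
    minpack.lm::nls.lm(par = start, fn = resid_fn, jac = jac_fn,
                       lower = lo, upper = up, control = ctl)
  }
  fits <- vector("list", n_starts)
  fits[[1]] <- run_fit(th0)
  if (n_starts > 1L) {
    for (s in 2:n_starts) {
      ths <- pmin(pmax(th0 + rnorm(length(th0), 0, perturb_sd), lo), up)
      fits[[s]] <- run_fit(ths)
    }
  }
  dev <- vapply(fits, function(f) f$deviance, numeric(1))
  best <- fits[[which.min(dev)]]
  theta <- best$par
  dispersion <- rep(NA_real_, length(theta))
  if (n_starts > 1L) {
    thmat <- vapply(fits, function(f) f$par, numeric(length(theta)))
    dispersion <- apply(thmat, 1, sd)
  }

  k_ex <- rep(0, n)
  k_ex[fit_idx] <- 10^theta
  flag <- rep("", n)
  flag[aa == "P"] <- "proline"
  flag[1] <- if (aa[1] == "P") "proline" else "n_terminus"
  flag[!covered & flag == ""] <- "no coverage"
  rank_res <- rep(FALSE, n)
  ns <- MASS::Null(t(Cfit))
  if (length(ns)) rank_res[fit_idx] <- rowSums(abs(ns)) > 1e-8
  flag[rank_res & flag == ""] <- "weakly determined"
  at_lo <- fit_idx[abs(theta - lo) < 1e-6]
  flag[at_lo] <- trimws(paste(flag[at_lo], "at lower bound"))

  res_vec <- resid_fn(theta)
  resid_mat <- matrix(NA_real_, nrow(C), length(tvals),
                      dimnames = list(rownames(C), format(tvals, trim = TRUE)))
  resid_mat[obs_index] <- res_vec
  ge_seed <- sum(resid_fn(th0)^2)
  converged <- best$info %in% 1:4
  if (!converged)
    warning("non-linear fit did not converge within the iteration budget; returning best point", call. = FALSE)

  lower_full <- lower_k; lower_full[-fit_idx] <- 0
  upper_full <- upper_k; upper_full[-fit_idx] <- 0
  profile <- data.frame(position = seq_len(n), residue = aa, k_ex = k_ex,
                        lower = lower_full, upper = upper_full,
                        flag = flag, stringsAsFactors = FALSE)
  out <- list(profile = profile, fit_idx = fit_idx,
              residuals = resid_mat, GE_nonlin = best$deviance,
              GE_seed = ge_seed, iterations = best$niter,
              converged = converged, info = best$info,
              dispersion_log10k = dispersion, times = tvals,
              b_retention = b)
  class(out) <- "hdx_rate_profile"
  out
}

#' @export
print.hdx_rate_profile <- function(x, ...) {
  cat(sprintf("<hdx_rate_profile> %d residues (%d fitted), GE_nonlin = %.4g D^2, %s after %d iterations\n",
              nrow(x$profile), length(x$fit_idx), x$GE_nonlin,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Export a per-amide rate profile
#' @param profile An `hdx_rate_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_profile <- function(profile, path) {
  write.table(profile$profile, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
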