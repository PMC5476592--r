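# Data model and I/O for peptide-level uptake data.
#
# A dataset couples a protein sequence with a table of centroid deuterium
# measurements, one row per (peptide fragment, labeling time) after optional
# merging of charge states. Residue numbering is 1-based inclusive throughout.

#' Exchangeable-amide capacity of a residue interval
#'
#' Number of backbone amide hydrogens a fragment can carry deuterium on:
#' the interval length minus prolines, minus the protein's first residue if
#' included (a free alpha-amine has no backbone amide), minus `n_term_excl`
#' additional fragment-N-terminal residues if the common HDX convention of
#' discounting fast-back-exchanging fragment termini is enabled (default 0).
#'
#' @param aa Character vector, the protein split into one-letter codes.
#' @param start,end 1-based inclusive interval bounds.
#' @param n_term_excl Number of fragment N-terminal residues to discount.
#' @return Integer capacity, >= 0.
#' @export
exchangeable_amides <- function(aa, start, end, n_term_excl = 0L) {
  idx <- seq.int(start, end)
  # positions contributing: not proline, not protein position 1,
  # not within the fragment's excluded N-terminal window
  excl_window <- idx < start + n_term_excl
  sum(aa[idx] != "P" & idx > 1L & !excl_window)
}

.fragment_key <- function(start, end) sprintf("%d-%d", start, end)

#' Assemble an uptake dataset
#'
#' Low-level constructor validating a record table against the protein
#' sequence. Most users will call [read_uptake_table()] or
#' [simulate_uptake()] instead.
#'
#' @param protein_sequence Protein sequence (one-letter codes).
#' @param records Data frame with columns `start`, `end`, `time_s`,
#'   `d_uptake` and optionally `sequence`, `charge`, `d_max`, `d_se`.
#' @param conditions_labeling,conditions_quench [exchange_conditions()]
#'   objects (optional, carried as metadata).
#' @param t_lag Chromatographic lag time in seconds (optional metadata).
#' @param n_term_excl Fragment N-terminal exclusions used for capacities.
#'
#' @return An object of class `hdx_dataset`: a list with elements `sequence`
#'   (string), `aa` (split sequence), `fragments` (data frame `start`, `end`,
#'   `sequence`, `capacity`, `key`), `records` (data frame keyed by fragment),
#'   `conditions_labeling`, `conditions_quench`, `t_lag`, `n_term_excl`.
#' @export
hdx_dataset <- function(protein_sequence, records,
                        conditions_labeling = NULL, conditions_quench = NULL,
                        t_lag = NULL, n_term_excl = 0L) {
  aa <- .split_sequence(protein_sequence)
  need <- c("start", "end", "time_s", "d_uptake")
  miss <- setdiff(need, names(records))
  if (length(miss))
    .stop_pos("records are missing required column(s): %s",
              paste(miss, collapse = ", "))
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  if (any(records$start < 1L) || any(records$end > length(aa)) ||
      any(records$start > records$end))
    .stop_pos("fragment interval outside the protein (length %d)", length(aa))
  if (any(records$time_s <= 0)) .stop_pos("labeling times must be > 0 s")
  if (any(records$d_uptake < -1e-9)) .stop_pos("negative deuterium uptake")
  if (!is.null(records$sequence)) {
    for (r in seq_len(nrow(records))) {
      expect <- paste(aa[records$start[r]:records$end[r]], collapse = "")
      got <- toupper(records$sequence[r])
      if (got != expect) {
        d <- which(strsplit(got, "")[[1]] != strsplit(expect, "")[[1]])[1]
        .stop_pos("row %d: peptide sequence disagrees with the protein at residue %d (got '%s', protein has '%s')",
                  r, records$start[r] + d - 1L,
                  substr(got, d, d), substr(expect, d, d))
      }
    }
  }
  records$key <- .fragment_key(records$start, records$end)
  frag <- unique(records[, c("start", "end", "key")])
  frag <- frag[order(frag$start, frag$end), , drop = FALSE]
  frag$sequence <- vapply(seq_len(nrow(frag)), function(i)
    paste(aa[frag$start[i]:frag$end[i]], collapse = ""), character(1))
  frag$capacity <- vapply(seq_len(nrow(frag)), function(i)
    exchangeable_amides(aa, frag$start[i], frag$end[i], n_term_excl),
    numeric(1))
  rownames(frag) <- NULL
  out <- list(sequence = paste(aa, collapse = ""), aa = aa,
              fragments = frag, records = records,
              conditions_labeling = conditions_labeling,
              conditions_quench = conditions_quench,
              t_lag = t_lag, n_term_excl = as.integer(n_term_excl))
  class(out) <- "hdx_dataset"
  out
}

#' @export
print.hdx_dataset <- function(x, ...) {
  cat(sprintf("<hdx_dataset> %d residues, %d fragments, %d records, %d time points\n",
              length(x$aa), nrow(x$fragments), nrow(x$records),
              length(unique(x$records$time_s))))
  invisible(x)
}

#' Read a peptide uptake table
#'
#' Reads a delimited (comma or tab, autodetected) uptake table with header
#' columns `start`, `end`, `sequence`, `charge`, `time_s`, `d_uptake` and
#' optional `d_max`, `d_se`, validates every peptide against the protein
#' sequence, and merges charge states per (fragment, time) by
#' uncertainty-weighted mean (equal weights when no `d_se` column is
#' present). Times can be folded onto a reference temperature axis with
#' [equivalent_labeling_time()] by supplying `fold_times`.
#'
#' @param path Path to the delimited table.
#' @param protein_sequence Protein sequence string (or path to a FASTA file).
#' @param merge_charges Merge charge states per fragment and time (default).
#' @param fold_times Optional list `list(actual_temp=, reference_temp=)`;
#'   when given, all times are folded onto the reference axis.
#' @param ... Passed to [hdx_dataset()] (conditions, `t_lag`,
#'   `n_term_excl`).
#' @return An `hdx_dataset`.
#' @export
read_uptake_table <- function(path, protein_sequence, merge_charges = TRUE,
                              fold_times = NULL, ...) {
  if (!file.exists(path)) .stop_pos("no such file: %s", path)
  if (file.exists(protein_sequence) && !dir.exists(protein_sequence))
    protein_sequence <- read_fasta_sequence(protein_sequence)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("start", "end", "sequence", "charge", "time_s", "d_uptake")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    .stop_pos("uptake table %s is missing required column(s): %s", path,
              paste(miss, collapse = ", "))
  if (!is.null(fold_times))
    tab$time_s <- equivalent_labeling_time(tab$time_s,
                                           fold_times$actual_temp,
                                           fold_times$reference_temp)
  if (merge_charges) tab <- .merge_charge_states(tab)
  hdx_dataset(protein_sequence, tab, ...)
}

.merge_charge_states <- function(tab) {
  keyf <- interaction(tab$start, tab$end, tab$time_s, drop = TRUE)
  dup <- tab[!duplicated(keyf), , drop = FALSE]
  w <- if (!is.null(tab$d_se)) 1 / pmax(tab$d_se, 1e-9)^2 else rep(1, nrow(tab))
  agg_d <- tapply(tab$d_uptake * w, keyf, sum) / tapply(w, keyf, sum)
  dup$d_uptake <- as.numeric(agg_d[as.character(keyf[!duplicated(keyf)])])
  dup$charge <- NULL
  dup$d_se <- NULL
  # conflicting duplicate rows at the same charge are averaged too; a gross
  # disagreement between charge states is the linear stage's job to flag
  rownames(dup) <- NULL
  dup
}

#' Write an uptake dataset back to delimited text
#'
#' Canonical tab-separated formatting; a write/read round trip preserves all
#' records.
#'
#' @param dataset An `hdx_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_uptake_table <- function(dataset, path) {
  rec <- dataset$records
  seqs <- dataset$fragments$sequence[match(rec$key, dataset$fragments$key)]
  out <- data.frame(start = rec$start, end = rec$end, sequence = seqs,
                    charge = if (!is.null(rec$charge)) rec$charge else 1L,
                    time_s = sprintf("%.17g", rec$time_s),
                    d_uptake = sprintf("%.17g", rec$d_uptake),
                    stringsAsFactors = FALSE)
  if (!is.null(rec$d_max)) out$d_max <- sprintf("%.17g", rec$d_max)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the first sequence from a FASTA file
#'
#' @param path FASTA path.
#' @return Sequence string.
#' @export
read_fasta_sequence <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], ">"))
    .stop_pos("%s does not look like a FASTA file", path)
  body <- lines[-1]
  nxt <- which(startsWith(body, ">"))
  if (length(nxt)) body <- body[seq_len(nxt[1] - 1L)]
  paste(gsub("\\s", "", body), collapse = "")
}

#' Write a sequence as FASTA
#' @param sequence Sequence string.
#' @param path Output path.
#' @param name Record name.
#' @return `path`, invisibly.
#' @export
write_fasta_sequence <- function(sequence, path, name = "protein") {
  chunks <- substring(sequence, seq(1, nchar(sequence), 60),
                      pmin(seq(60, nchar(sequence) + 59, 60), nchar(sequence)))
  writeLines(c(paste0(">", name), chunks), path)
  invisible(path)
}

#' Drop fragments whose linear-stage residual error is too large
#'
#' Removes, at all time points, every fragment whose fit error reaches the
#' threshold (default 2 deuterons), the screening rule used to reject
#' misassigned or low-quality peptides before re-fitting.
#'
#' @param dataset An `hdx_dataset`.
#' @param errors Named numeric vector of per-fragment errors (names are
#'   fragment keys `"start-end"`), typically `dlevels$fragment_error$max_abs`
#'   from [fit_subfragment_d()].
#' @param threshold Removal threshold in deuterons; fragments with
#'   `error >= threshold` are dropped. Must be > 0.
#' @return The filtered `hdx_dataset`, with attributes `removed_keys` and
#'   `n_removed`.
#' @export
filter_by_fit_error <- function(dataset, errors, threshold = 2) {
  stopifnot(inherits(dataset, "hdx_dataset"))
  if (!is.numeric(threshold) || threshold <= 0)
    .stop_pos("`threshold` must be a positive number of deuterons")
  if (is.null(names(errors))) .stop_pos("`errors` must be named by fragment key")
  bad <- names(errors)[errors >= threshold]
  keep <- !(dataset$records$key %in% bad)
  removed <- intersect(unique(dataset$records$key), bad)
  message(sprintf("filter_by_fit_error: removed %d of %d fragments (threshold %g D)",
                  length(removed), nrow(dataset$fragments), threshold))
  out <- hdx_dataset(dataset$sequence, dataset$records[keep, , drop = FALSE],
                     dataset$conditions_labeling, dataset$conditions_quench,
                     dataset$t_lag, dataset$n_term_excl)
  attr(out, "removed_keys") <- removed
  attr(out, "n_removed") <- length(removed)
  out
}

#' Iterative residual filtering with refits
#'
#' Sequential outlier deletion: fit the linear stage, remove the grossest
#' fragments (error at least `max(threshold, half the current worst error)`),
#' refit, and repeat until every remaining fragment's error is below the
#' threshold. Removing the worst offenders first stops their error from
#' spilling into overlapping clean peptides, so the deletion set converges
#' to the truly aberrant fragments rather than their neighbours.
#'
#' @param dataset An `hdx_dataset`.
#' @param threshold Removal threshold in deuterons (default 2).
#' @param n_term_excl Passed to [compute_partition()].
#' @param max_rounds Safety cap on refit rounds.
#' @return The filtered dataset with attributes `removed_keys` (all removals,
#'   in removal order), `n_removed`, `rounds` and `final_dlevels` (the
#'   linear fit of the cleaned dataset).
#' @seealso [filter_by_fit_error()] for the one-shot rule.
#' @export
filter_outliers_iteratively <- function(dataset, threshold = 2,
                                        n_term_excl = 0L, max_rounds = 50L) {
  stopifnot(inherits(dataset, "hdx_dataset"))
  if (!is.numeric(threshold) || threshold <= 0)
    .stop_pos("`threshold` must be a positive number of deuterons")
  removed <- character()
  rounds <- 0L
  current <- dataset
  repeat {
    rounds <- rounds + 1L
    partition <- compute_partition(current$fragments, current$sequence,
                                   n_term_excl)
    dl <- fit_subfragment_d(current, partition)
    errs <- setNames(dl$fragment_error$max_abs, dl$fragment_error$key)
    errs <- errs[is.finite(errs)]
    if (!length(errs) || max(errs) < threshold || rounds > max_rounds) break
    # delete in blocks anchored at the current worst offender; clean
    # peptides inflated by a neighbour's spill sit well below that and
    # survive the round
    cut <- max(threshold, 0.6 * max(errs))
    drop <- names(errs)[errs >= cut]
    removed <- c(removed, drop)
    current <- suppressMessages(filter_by_fit_error(current, errs, cut))
  }
  message(sprintf("filter_outliers_iteratively: removed %d of %d fragments in %d rounds (threshold %g D)",
                  length(removed), nrow(dataset$fragments), rounds, threshold))
  attr(current, "removed_keys") <- removed
  attr(current, "n_removed") <- length(removed)
  attr(current, "rounds") <- rounds
  attr(current, "final_dlevels") <- if (exists("dl")) dl else NULL
  current
}

#' Classify a fragment's exchange speed from its uptake series
#'
#' Determines the time at which the fragment reaches 50 % of its maximal
#' uptake by linear interpolation on a log-time axis, then classifies it as
#' fast (`t50 < 1000 s`), intermediate (`1000 <= t50 <= 3000 s`) or slow
#' (`t50 > 3000 s`). If 50 % is never reached within the sampled times the
#' class is slow with `t50 = Inf`.
#'
#' @param times Labeling times in seconds (>= 2 values).
#' @param d Measured deuterium at those times.
#' @param d_max Maximal uptake reference: the fully-deuterated control if
#'   available, else the fragment's exchangeable-amide capacity.
#' @return A list with `class` (factor level `"fast"`, `"intermediate"`,
#'   `"slow"`), `t50` (seconds, possibly `Inf`) and `flag`.
#' @export
classify_exchange <- function(times, d, d_max) {
  stopifnot(length(times) >= 2L, length(d) == length(times), d_max > 0)
  o <- order(times)
  times <- times[o]; d <- d[o]
  f <- d / d_max
  flag <- ""
  if (all(f <= 0)) {
    return(list(class = "slow", t50 = Inf, flag = "no uptake observed"))
  }
  t50 <- if (f[1] >= 0.5) {
    times[1]                       # already past 50 % at the first time
  } else {
    ix <- which(f >= 0.5)[1]
    if (is.na(ix)) Inf else {
      lt <- log10(times)
      10^(lt[ix - 1] + (0.5 - f[ix - 1]) / (f[ix] - f[ix - 1]) *
            (lt[ix] - lt[ix - 1]))
    }
  }
  cls <- if (t50 < 1000) "fast" else if (t50 <= 3000) "intermediate" else "slow"
  list(class = cls, t50 = t50, flag = flag)
}

#' Classify every fragment of a dataset
#'
#' @param dataset An `hdx_dataset`.
#' @return Data frame with one row per fragment: `key`, `start`, `end`,
#'   `t50`, `class`.
#' @export
classify_dataset <- function(dataset) {
  frag <- dataset$fragments
  res <- lapply(seq_len(nrow(frag)), function(i) {
    rec <- dataset$records[dataset$records$key == frag$key[i], , drop = FALSE]
    dmax <- if (!is.null(rec$d_max) && any(is.finite(rec$d_max)))
      mean(rec$d_max[is.finite(rec$d_max)]) else frag$capacity[i]
    if (nrow(rec) < 2L || dmax <= 0)
      return(data.frame(t50 = NA_real_, class = NA_character_))
    cl <- classify_exchange(rec$time_s, rec$d_uptake, dmax)
    data.frame(t50 = cl$t50, class = cl$class, stringsAsFactors = FALSE)
  })
  cbind(frag[, c("key", "start", "end")], do.call(rbind, res))
}

#' Per-residue coverage and redundancy statistics
#'
#' @param dataset An `hdx_dataset` (or a fragment data frame with `start`,
#'   `end`) plus the protein length.
#' @return Data frame with one row per residue: `position`, `redundancy`
#'   (number of covering fragments) and `boundaries` (number of distinct
#'   fragment start/end+1 boundary points falling on the residue), plus
#'   attributes `mean_redundancy` and `gaps` (uncovered intervals as a
#'   data frame).
#' @export
coverage_stats <- function(dataset) {
  frag <- if (inherits(dataset, "hdx_dataset")) dataset$fragments else dataset
  n <- if (inherits(dataset, "hdx_dataset")) length(dataset$aa) else max(frag$end)
  red <- integer(n)
  for (i in seq_len(nrow(frag)))
    red[frag$start[i]:frag$end[i]] <- red[frag$start[i]:frag$end[i]] + 1L
  bpts <- sort(unique(c(frag$start, frag$end + 1L)))
  bounds <- as.integer(tabulate(bpts[bpts <= n], nbins = n))
  out <- data.frame(position = seq_len(n), redundancy = red,
                    boundaries = bounds)
  covered <- red > 0L
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  gaps <- data.frame(start = starts[!r$values], end = ends[!r$values])
  attr(out, "mean_redundancy") <- mean(red[covered])
  attr(out, "gaps") <- gaps
  out
}
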