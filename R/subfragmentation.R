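# Minimal-subfragment decomposition of an overlapping peptide set.
#
# The boundary set is {start_i} U {end_i + 1} over all fragments; consecutive
# boundaries restricted to covered residues define the subfragments: the
# smallest common overlap regions between peptides. Every fragment is then
# exactly a concatenation of consecutive subfragments, which is what turns
# each measured peptide uptake into one linear constraint per time point.

#' Compute the minimal subfragment partition of a fragment set
#'
#' @param fragments Data frame with columns `start`, `end` (1-based
#'   inclusive), e.g. `dataset$fragments`.
#' @param protein_sequence Protein sequence string (capacities need proline
#'   positions).
#' @param n_term_excl Fragment N-terminal exclusions; when > 0, fragment
#'   intervals are trimmed by this many residues at their N-terminus before
#'   partitioning, so that excluded residues never enter the linear system.
#' @return An object of class `hdx_partition`: list with `subfragments`
#'   (data frame `index`, `start`, `end`, `capacity`, `n_covering`),
#'   `membership` (named list: fragment key -> integer vector of subfragment
#'   indices, ordered N to C), `fragments` (the, possibly trimmed, fragment
#'   table with keys and capacities), `aa`, `n_term_excl`.
#' @examples
#' p <- compute_partition(data.frame(start = c(1, 6), end = c(10, 15)),
#'                        strrep("A", 20))
#' p$subfragments[, c("start", "end")]  # [1,5], [6,10], [11,15]
#' @export
compute_partition <- function(fragments, protein_sequence, n_term_excl = 0L) {
  aa <- .split_sequence(protein_sequence)
  if (is.null(fragments) || nrow(fragments) == 0L)
    .stop_pos("at least one fragment is required")
  if (any(fragments$start < 1L) || any(fragments$end > length(aa)))
    .stop_pos("fragment outside the protein sequence")
  frag <- unique(data.frame(start = as.integer(fragments$start),
                            end = as.integer(fragments$end)))
  frag$key <- .fragment_key(frag$start, frag$end)
  # trim the excluded N-terminal window off each measured peptide
  frag$astart <- pmin(frag$start + as.integer(n_term_excl), frag$end)
  frag <- frag[order(frag$start, frag$end), , drop = FALSE]

  covered <- logical(length(aa))
  for (i in seq_len(nrow(frag))) covered[frag$astart[i]:frag$end[i]] <- TRUE
  bounds <- sort(unique(c(frag$astart, frag$end + 1L)))
  is_boundary <- logical(length(aa) + 1L)
  is_boundary[bounds] <- TRUE

  subs <- list()
  pos <- 1L
  while (pos <= length(aa)) {
    if (!covered[pos]) { pos <- pos + 1L; next }
    stopifnot(is_boundary[pos])  # covered runs always open on a boundary
    endp <- pos
    while (endp + 1L <= length(aa) && covered[endp + 1L] &&
           !is_boundary[endp + 1L]) endp <- endp + 1L
    subs[[length(subs) + 1L]] <- c(pos, endp)
    pos <- endp + 1L
  }
  sf <- do.call(rbind, subs)
  subfragments <- data.frame(index = seq_len(nrow(sf)),
                             start = sf[, 1], end = sf[, 2])
  subfragments$capacity <- vapply(seq_len(nrow(subfragments)), function(j)
    exchangeable_amides(aa, subfragments$start[j], subfragments$end[j]),
    numeric(1))

  membership <- lapply(seq_len(nrow(frag)), function(i) {
    js <- which(subfragments$start >= frag$astart[i] &
                  subfragments$end <= frag$end[i])
    # sanity: concatenation of members must tile the (trimmed) fragment
    stopifnot(sum(subfragments$end[js] - subfragments$start[js] + 1L) ==
                frag$end[i] - frag$astart[i] + 1L)
    js
  })
  names(membership) <- frag$key
  subfragments$n_covering <- tabulate(unlist(membership),
                                      nbins = nrow(subfragments))
  frag$capacity <- vapply(membership, function(js)
    sum(subfragments$capacity[js]), numeric(1))

  out <- list(subfragments = subfragments, membership = membership,
              fragments = frag, aa = aa, n_term_excl = as.integer(n_term_excl))
  class(out) <- "hdx_partition"
  out
}

#' @export
print.hdx_partition <- function(x, ...) {
  cat(sprintf("<hdx_partition> %d fragments -> %d subfragments (median length %g aa)\n",
              nrow(x$fragments), nrow(x$subfragments),
              stats::median(x$subfragments$end - x$subfragments$start + 1)))
  invisible(x)
}

#' Fragment-by-subfragment incidence matrix
#'
#' Binary constraint structure of the linear stage: entry (n, j) is 1 iff
#' subfragment j is a member of fragment n. The same matrix applies at every
#' labeling time.
#'
#' @param partition An `hdx_partition`.
#' @param fragments Optional fragment data frame; must match the set the
#'   partition was computed from (checked), defaults to the partition's own.
#' @return Numeric matrix, rows named by fragment key.
#' @export
constraint_matrix <- function(partition, fragments = NULL) {
  stopifnot(inherits(partition, "hdx_partition"))
  if (!is.null(fragments)) {
    keys <- sort(.fragment_key(fragments$start, fragments$end))
    if (!identical(keys, sort(names(partition$membership))))
      .stop_pos("fragment set does not match the partition")
  }
  nsub <- nrow(partition$subfragments)
  A <- matrix(0, nrow = length(partition$membership), ncol = nsub,
              dimnames = list(names(partition$membership),
                              partition$subfragments$index))
  for (i in seq_along(partition$membership))
    A[i, partition$membership[[i]]] <- 1
  A
}

#' Export a subfragment partition as delimited text
#'
#' @param partition An `hdx_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  write.table(partition$subfragments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
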