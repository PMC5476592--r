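# The stability fingerprint: per-residue free energy of exchange.
#
#   dG_ex,i = -R T ln(k_ex,i / k_int,i),   R = 1.987e-3 kcal mol^-1 K^-1
#
# Higher dG_ex = more protected / stable amide; 0 = exchanging at the
# random-coil rate. Prolines (no amide hydrogen) are reported as 0 with a
# flag; uncovered residues carry NA.

#' Compute the per-residue stability fingerprint
#'
#' @param profile An `hdx_rate_profile` from [fit_amide_rates()].
#' @param k_int Intrinsic rate table at labeling conditions
#'   ([compute_intrinsic_rates()]).
#' @param temperature Temperature (K) for the free-energy conversion;
#'   defaults to the labeling temperature stored with `k_int`.
#' @return Object of class `hdx_fingerprint`: data frame with columns
#'   `position`, `residue`, `k_ex`, `k_int`, `dG_ex` (kcal/mol) and `flag`,
#'   plus attributes `temperature` and `provenance`. Residues whose fitted
#'   rate sits at the lower bound get the bound-implied maximum dG with a
#'   `"censored"` flag.
#' @examples
#' # k_ex = k_int gives dG = 0; k_ex/k_int = exp(-1) gives dG = R*T
#' @export
compute_fingerprint <- function(profile, k_int, temperature = NULL) {
  stopifnot(inherits(profile, "hdx_rate_profile"),
            inherits(k_int, "hdx_rate_table"))
  pr <- profile$profile
  if (nrow(pr) != nrow(k_int))
    .stop_pos("rate profile (%d residues) and intrinsic table (%d) disagree",
              nrow(pr), nrow(k_int))
  if (is.null(temperature)) {
    cond <- attr(k_int, "conditions")
    temperature <- if (!is.null(cond)) cond$temperature else 298.15
  }
  dG <- rep(NA_real_, nrow(pr))
  flag <- pr$flag
  fit <- !(pr$flag %in% c("proline", "n_terminus", "no coverage"))
  ok <- fit & pr$k_ex > 0 & k_int$k > 0
  dG[ok] <- -.R_KCAL * temperature * log(pr$k_ex[ok] / k_int$k[ok])
  flag[fit & grepl("at lower bound", pr$flag)] <-
    sub("at lower bound", "censored", flag[fit & grepl("at lower bound", pr$flag)])
  dG[pr$flag == "proline"] <- 0
  dG[pr$flag == "n_terminus"] <- NA_real_
  out <- data.frame(position = pr$position, residue = pr$residue,
                    k_ex = pr$k_ex, k_int = k_int$k, dG_ex = dG,
                    flag = flag, stringsAsFactors = FALSE)
  attr(out, "temperature") <- temperature
  attr(out, "provenance") <- attr(k_int, "provenance")
  class(out) <- c("hdx_fingerprint", "data.frame")
  out
}

#' Export a stability fingerprint as delimited text
#'
#' One row per residue (gap rows included, with empty dG and their flag);
#' the header records the temperature and reference-set provenance.
#'
#' @param fingerprint An `hdx_fingerprint`.
#' @param path Output path.
#' @param plot Optional path to a PDF line plot of dG vs position.
#' @return `path`, invisibly.
#' @export
export_profile <- function(fingerprint, path, plot = NULL) {
  stopifnot(inherits(fingerprint, "hdx_fingerprint"))
  dir <- dirname(path)
  if (!dir.exists(dir)) .stop_pos("directory does not exist: %s", dir)
  con <- file(path, "w")
  writeLines(sprintf("# stability fingerprint; coordinates 1-based inclusive; T = %.2f K; reference set %s",
                     attr(fingerprint, "temperature"),
                     attr(fingerprint, "provenance")), con)
  tab <- as.data.frame(fingerprint)
  for (cc in c("k_ex", "k_int", "dG_ex"))
    tab[[cc]] <- format(tab[[cc]], digits = 12, trim = TRUE)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(plot)) {
    pdf(plot, width = 9, height = 3.2)
    on.exit(dev.off(), add = TRUE)
    plot_fingerprint(fingerprint)
  }
  invisible(path)
}

#' Read a fingerprint table written by [export_profile()]
#' @param path Path to the table.
#' @return Data frame with the numeric columns restored.
#' @export
read_profile <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE,
             colClasses = c("integer", "character", "numeric", "numeric",
                            "numeric", "character"))
}

#' Line plot of a stability fingerprint
#' @param fingerprint An `hdx_fingerprint`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_fingerprint <- function(fingerprint, ...) {
  plot(fingerprint$position, fingerprint$dG_ex, type = "h",
       xlab = "residue", ylab = expression(Delta * G[ex] ~ "(kcal/mol)"),
       ...)
  points(fingerprint$position[fingerprint$flag == "proline"],
         rep(0, sum(fingerprint$flag == "proline")), pch = 4)
  invisible(fingerprint)
}

#' Write per-residue dG values into a structure's B-factor column
#'
#' Copies a PDB structure with the B-factor of every matching residue
#' replaced by its dG_ex (2 decimals; residues without a value get the
#' sentinel 999), and optionally writes a companion PyMOL script applying a
#' low-to-high colour spectrum.
#'
#' @param fingerprint An `hdx_fingerprint`.
#' @param structure_file Input PDB path.
#' @param path Output PDB path.
#' @param script Optional path for a PyMOL colouring script.
#' @param chain Chain identifier; default: first chain in the file.
#' @param offset Added to fingerprint positions to obtain structure residue
#'   numbers (crystal numbering rarely matches construct numbering).
#' @return `path`, invisibly; warns for fingerprint residues absent from the
#'   structure.
#' @export
export_structure_coloring <- function(fingerprint, structure_file, path,
                                      script = NULL, chain = NULL,
                                      offset = 0L) {
  stopifnot(inherits(fingerprint, "hdx_fingerprint"))
  pdb <- tryCatch(bio3d::read.pdb(structure_file),
                  error = function(e) .stop_pos("malformed structure file %s: %s",
                                                structure_file, conditionMessage(e)))
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  sel <- at$chain == chain
  resno <- fingerprint$position + offset
  b <- at$b
  b[sel] <- 999
  n_missing <- 0L
  for (i in seq_len(nrow(fingerprint))) {
    hit <- sel & at$resno == resno[i]
    if (!any(hit)) {
      n_missing <- n_missing + 1L
      next
    }
    val <- fingerprint$dG_ex[i]
    b[hit] <- if (is.finite(val)) round(val, 2) else 999
  }
  if (n_missing > 0L)
    warning(sprintf("%d fingerprint residues are absent from chain %s of the structure",
                    n_missing, chain), call. = FALSE)
  pdb$atom$b <- b
  bio3d::write.pdb(pdb, file = path)
  if (!is.null(script)) {
    rng <- range(fingerprint$dG_ex[is.finite(fingerprint$dG_ex)])
    writeLines(c(sprintf("load %s, fingerprint", basename(path)),
                 "hide everything, fingerprint",
                 "show cartoon, fingerprint",
                 "color grey70, fingerprint and b > 998",
                 sprintf("spectrum b, blue_white_red, fingerprint and b < 998, %.2f, %.2f",
                         rng[1], rng[2])),
               script)
  }
  invisible(path)
}
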