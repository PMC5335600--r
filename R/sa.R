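## Synthetic-accessibility score from fragment (path-fingerprint bit)
## frequencies.
##
## A frequency table is built from a SMILES library: for every molecule
## the 1024-bit path fingerprint is computed; per-bit occupancy counts
## over the library are normalized by the maximum count, and the
## contribution of a bit is the natural log of its normalized count (the
## most common fragment contributes 0, rarer fragments are negative).
## Bits never observed receive a floor of ln(pseudo-count / max).
## Scoring sums the contributions of a molecule's set bits (as a mean),
## subtracts size and complexity penalties (chiral centres, spiro
## fusions, bridged rings, macrocycles — with the classic coefficient
## forms), and maps the raw value onto [1, 10] with an affine transform
## calibrated on the library (stored with the table).

#' Build a fragment-frequency table
#'
#' @param smiles Character vector of SMILES strings (a library), or a
#'   file path (one molecule per line, optional name).
#' @param nbits Fingerprint length (default 1024).
#' @param max_len Maximum path length in bonds (default 7).
#' @param pseudo_count Pseudo-count for never-observed bits
#'   (default 0.5).
#' @param progress Print progress every 100 molecules.
#' @return Object of class \code{adm_freq_table}: per-bit contributions,
#'   bit counts, library size, dialect metadata, and the raw-score
#'   calibration used by \code{\link{sa_score}}.
#' @export
build_frequency_table <- function(smiles, nbits = FP_NBITS,
                                  max_len = FP_MAXLEN,
                                  pseudo_count = 0.5, progress = FALSE) {
  if (length(smiles) == 1L && file.exists(smiles)) {
    smiles <- parse_smiles_list(readLines(smiles, warn = FALSE))$smiles
  }
  smiles <- smiles[nzchar(smiles)]
  if (length(smiles) == 0L) {
    adm_error("adm_empty_library", "no molecules in library")
  }
  counts <- integer(nbits)
  mols <- list()
  n_ok <- 0L
  for (s in smiles) {
    m <- tryCatch(adm_molecule(s), error = function(e) NULL)
    if (is.null(m)) next
    n_ok <- n_ok + 1L
    fp <- path_fingerprint(m, nbits = nbits, max_len = max_len)
    counts <- counts + as.integer(fp$bits)
    mols[[n_ok]] <- list(mol = m, bits = fp$bits)
    if (progress && n_ok %% 100L == 0L) message(n_ok, " molecules")
  }
  if (n_ok == 0L) {
    adm_error("adm_empty_library", "no parseable molecules in library")
  }
  mx <- max(counts)
  if (mx == 0L) {
    adm_error("adm_empty_library",
              "library contains no bonded fragments (no bits set)")
  }
  contrib <- ifelse(counts > 0L, log(counts / mx), log(pseudo_count / mx))
  tab <- structure(list(
    contributions = contrib,
    counts = counts,
    library_size = n_ok,
    nbits = nbits,
    max_len = max_len,
    pseudo_count = pseudo_count,
    dialect = FP_DIALECT,
    calibration = NULL
  ), class = "adm_freq_table")
  ## calibrate the raw -> [1,10] map on the library's raw-score range,
  ## with a margin on the difficult side for unseen harder molecules
  raws <- vapply(mols, function(x) {
    sa_raw(x$mol, tab, bits = x$bits)$raw
  }, 0)
  tab$calibration <- list(raw_easy = max(raws), raw_hard = min(raws) - 3)
  tab
}

#' @export
print.adm_freq_table <- function(x, ...) {
  cat(sprintf(
    "<adm_freq_table> %d-bit %s, %d molecules, %d bits observed\n",
    x$nbits, x$dialect, x$library_size, sum(x$counts > 0)))
  cat(sprintf("  calibration: raw [%.3f (hard), %.3f (easy)]\n",
              x$calibration$raw_hard, x$calibration$raw_easy))
  invisible(x)
}

## raw score: mean fragment contribution minus complexity penalties
sa_raw <- function(mol, table, bits = NULL) {
  if (is.null(bits)) {
    bits <- path_fingerprint(mol, nbits = table$nbits,
                             max_len = table$max_len)$bits
  }
  set <- which(bits)
  frag <- if (length(set)) mean(table$contributions[set]) else 0
  n_heavy <- nrow(mol$atoms)
  cplx <- ring_complexity(mol)
  penalties <- c(
    size = n_heavy^1.005 - n_heavy,
    stereo = log10(mol$n_stereo + 1),
    spiro = log10(cplx$n_spiro + 1),
    bridge = log10(cplx$n_bridgehead + 1),
    macrocycle = if (cplx$n_macrocycle > 0) log10(2) else 0
  )
  list(raw = frag - sum(penalties), fragment_term = frag,
       penalties = penalties)
}

#' Synthetic-accessibility score
#'
#' @param mol An \code{adm_molecule}.
#' @param table \code{adm_freq_table} built with the same fingerprint
#'   dialect (checked).
#' @return Object of class \code{adm_sa_score}: \code{raw},
#'   \code{normalized} in [1, 10] (1 = very easy, 10 = very difficult),
#'   the fragment term and the penalty breakdown.
#' @export
sa_score <- function(mol, table) {
  stopifnot(inherits(table, "adm_freq_table"))
  if (!identical(table$dialect, FP_DIALECT)) {
    adm_error("adm_dialect_mismatch",
              paste0("frequency table uses dialect '", table$dialect,
                     "', scorer expects '", FP_DIALECT, "'"))
  }
  r <- sa_raw(mol, table)
  cal <- table$calibration
  span <- cal$raw_easy - cal$raw_hard
  normalized <- 1 + 9 * (cal$raw_easy - r$raw) / span
  normalized <- min(10, max(1, normalized))
  structure(list(
    raw = r$raw,
    normalized = normalized,
    fragment_term = r$fragment_term,
    penalties = r$penalties
  ), class = "adm_sa_score")
}

#' @export
print.adm_sa_score <- function(x, ...) {
  cat(sprintf("<adm_sa_score> %.2f / 10 (raw %.3f; fragment %.3f; penalties %.3f)\n",
              x$normalized, x$raw, x$fragment_term, sum(x$penalties)))
  invisible(x)
}

#' Persist / load a frequency table
#'
#' Tables are stored as JSON with dialect metadata; loading checks the
#' dialect identifier.
#' @param table \code{adm_freq_table}.
#' @param path Output / input file.
#' @return \code{write_frequency_table}: the path, invisibly.
#'   \code{read_frequency_table}: the table.
#' @export
write_frequency_table <- function(table, path) {
  stopifnot(inherits(table, "adm_freq_table"))
  jsonlite::write_json(unclass(table), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$contributions <- as.numeric(x$contributions)
  x$counts <- as.integer(x$counts)
  structure(x, class = "adm_freq_table")
}

#' Benchmark SA scores against expert marks
#'
#' Given molecules and expert synthetic-accessibility marks, computes the
#' mean absolute error, root-mean-square error and linear correlation of
#' the model scores against the expert scores.
#'
#' @param smiles Character vector of SMILES.
#' @param expert Numeric vector of expert scores (same length).
#' @param table \code{adm_freq_table}.
#' @return List with \code{mae}, \code{rmse}, \code{r}, \code{n}.
#' @export
sa_benchmark <- function(smiles, expert, table) {
  stopifnot(length(smiles) == length(expert))
  pred <- vapply(smiles, function(s) {
    sa_score(adm_molecule(s), table)$normalized
  }, 0)
  err <- pred - expert
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
       r = stats::cor(pred, expert), n = length(pred))
}
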