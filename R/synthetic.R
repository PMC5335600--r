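## Synthetic data: a SMILES library generator (for frequency tables and
## property sweeps) and a labelled-dataset generator for the SVM
## pipeline.  Both are deterministic given a seed.

SMILES_UNITS <- c(
  "C", "CC", "CCC", "O", "N", "CO", "CN", "C(=O)", "C(=O)O", "C(=O)N",
  "C(C)", "C(C)C", "S", "CCl", "CF", "C=C", "C#C",
  "c1ccccc1", "c1ccncc1", "c1ccc(C)cc1", "c1ccc(O)cc1", "c1ccc(N)cc1",
  "c1ccc(Cl)cc1", "c1ccc(F)cc1", "c1ccsc1", "c1ccoc1",
  "C1CCCCC1", "C1CCNCC1", "C1CCOC1", "C1CC1"
)
SMILES_TERMINALS <- c("C", "O", "N", "Cl", "F", "C(=O)O", "C(C)C", "C#N",
                      "c1ccccc1", "C1CCCCC1")

#' Generate a synthetic SMILES library
#'
#' Assembles random linear combinations of valid chain and ring units
#' into parseable drug-like SMILES strings.  Deterministic for a given
#' seed.  The library emulates a vendor-catalog fragment-frequency
#' profile only in a rough, structural sense: it covers common chains,
#' rings and functional groups, but not the size or diversity of a real
#' purchasable-compound collection.
#'
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @param min_units,max_units Units per molecule.
#' @return Character vector of \code{n} SMILES strings.
#' @export
generate_smiles_library <- function(n, seed = 1L, min_units = 2L,
                                    max_units = 5L) {
  stopifnot(is_count(n), n >= 1)
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  out <- character(n)
  for (i in seq_len(n)) {
    k <- sample(min_units:max_units, 1L)
    units <- sample(SMILES_UNITS, k, replace = TRUE)
    term <- sample(SMILES_TERMINALS, 1L)
    out[i] <- paste0(paste(units, collapse = ""), term)
  }
  out
}

## save/restore global RNG state around seeded generators
save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Synthesize a labelled descriptor dataset
#'
#' Two multivariate-Gaussian classes in \code{n_features} dimensions:
#' the first \code{n_informative} features of the positive class are
#' shifted by \code{effect_size} standard deviations; the remaining
#' features are pure noise in both classes.  A matching synthetic binary
#' fingerprint matrix is generated (class-correlated bits) for
#' clustering-based balancing.  Fully reproducible by seed.
#'
#' @param n_pos,n_neg Class sizes (positive integers).
#' @param n_features Number of descriptors (default 50, the size of the
#'   profiling descriptor panel).
#' @param effect_size Mean shift, in SD units, on informative features.
#' @param n_informative Number of informative features (default 10).
#' @param seed Integer seed.
#' @param nbits Fingerprint length for the matching fingerprints.
#' @return Object of class \code{adm_dataset}: \code{x} (matrix),
#'   \code{y} (0/1 vector), \code{feature_names},
#'   \code{fingerprints} (logical matrix), \code{role}.
#' @export
synthesize_dataset <- function(n_pos, n_neg, n_features = 50L,
                               effect_size = 1, n_informative = 10L,
                               seed = 1L, nbits = 128L) {
  stopifnot(is_count(n_pos), is_count(n_neg), n_pos >= 1, n_neg >= 1,
            n_informative <= n_features)
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  n <- n_pos + n_neg
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  x <- matrix(stats::rnorm(n * n_features), nrow = n)
  if (n_informative > 0L) {
    shift <- matrix(0, n, n_informative)
    shift[y == 1L, ] <- effect_size
    x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] + shift
  }
  colnames(x) <- sprintf("D%02d", seq_len(n_features))
  ## class-correlated synthetic fingerprints: per-class bit prevalences
  p_pos <- stats::runif(nbits, 0.05, 0.6)
  p_neg <- stats::runif(nbits, 0.05, 0.6)
  fp <- matrix(FALSE, n, nbits)
  for (i in seq_len(n)) {
    p <- if (y[i] == 1L) p_pos else p_neg
    fp[i, ] <- stats::runif(nbits) < p
  }
  structure(list(x = x, y = y, feature_names = colnames(x),
                 fingerprints = fp, role = "training"),
            class = "adm_dataset")
}

#' @export
print.adm_dataset <- function(x, ...) {
  cat(sprintf("<adm_dataset %s> %d x %d, classes %d/%d\n", x$role,
              nrow(x$x), ncol(x$x), sum(x$y == 1L), sum(x$y == 0L)))
  invisible(x)
}
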