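## Lipophilicity: multiple log P predictors and their consensus.
##
## Implemented in-package: WLOGP (atomistic) and MLOGP (topological).
## A table-driven hybrid fragment/descriptor model is available when a
## coefficient table is supplied.  Predictors that need external physics
## or closed-source programs (GB/SA solvation free energies, the
## knowledge-based atomistic method) are external-value slots: their
## predictions can be supplied per molecule and enter the consensus mean
## like any other value.

#' Table-driven fragment log P
#'
#' Hybrid linear model: SMARTS-keyed fragment match counts plus topological
#' descriptor values, each multiplied by a table-supplied coefficient, plus
#' an intercept.
#'
#' @param mol An \code{adm_molecule}.
#' @param table A data.frame with columns \code{kind}
#'   (\code{"fragment"}, \code{"descriptor"} or \code{"intercept"}),
#'   \code{key} (SMARTS for fragments; descriptor-panel name for
#'   descriptors; ignored for the intercept) and \code{coef}.
#' @param descriptors Optional precomputed \code{adm_descriptors} (saves
#'   recomputation when profiling).
#' @return log P estimate.
#' @export
fragment_logp <- function(mol, table, descriptors = NULL) {
  if (is.null(table)) {
    adm_error("adm_missing_table", "no fragment log P coefficient table")
  }
  stopifnot(is.data.frame(table),
            all(c("kind", "key", "coef") %in% names(table)))
  total <- 0
  frag <- table[table$kind == "fragment", , drop = FALSE]
  if (nrow(frag)) {
    sdf <- as_sdfset(mol)
    for (r in seq_len(nrow(frag))) {
      cnt <- smarts_count(sdf, frag$key[r])
      total <- total + frag$coef[r] * cnt
    }
  }
  desc <- table[table$kind == "descriptor", , drop = FALSE]
  if (nrow(desc)) {
    d <- descriptors %||% compute_descriptor_panel(mol, include_logp = FALSE)
    for (r in seq_len(nrow(desc))) {
      val <- d[[desc$key[r]]]
      if (is.null(val)) {
        adm_error("adm_missing_table",
                  paste0("unknown descriptor in table: ", desc$key[r]))
      }
      total <- total + desc$coef[r] * val
    }
  }
  total + sum(table$coef[table$kind == "intercept"])
}

## SMARTS match count via Open Babel (non-unique matches collapsed to
## unique atom sets).
smarts_count <- function(sdf, smarts) {
  res <- tryCatch(
    ob_quiet(ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = TRUE)),
    error = function(e) {
      adm_error("adm_bad_pattern",
                paste0("SMARTS failed to compile: '", smarts, "'"))
    })
  as.integer(res[[1]])
}

#' Lipophilicity profile and consensus log P
#'
#' Computes the available log P predictions for a molecule and their
#' arithmetic-mean consensus.  Missing predictors (no fragment table, no
#' external values supplied) are simply absent from the mean.
#'
#' @param mol An \code{adm_molecule}.
#' @param external Named numeric vector of externally supplied predictions
#'   (e.g. \code{c(XLOGP3 = 1.2, ILOGP = 1.5)}).  Only finite values are
#'   used.
#' @param fragment_table Optional coefficient table for
#'   \code{\link{fragment_logp}}.
#' @param descriptors Optional precomputed descriptor panel.
#' @return Object of class \code{adm_lipophilicity}: list with individual
#'   predictions, \code{consensus}, and \code{n_predictors}.
#' @examples
#' lp <- lipophilicity_profile(adm_molecule("c1ccccc1"))
#' lp$consensus
#' @export
lipophilicity_profile <- function(mol, external = NULL,
                                  fragment_table = NULL,
                                  descriptors = NULL) {
  preds <- c(
    WLOGP = wlogp(mol),
    MLOGP = mlogp(mol)
  )
  if (!is.null(fragment_table)) {
    fl <- tryCatch(fragment_logp(mol, fragment_table, descriptors),
                   adm_missing_table = function(e) NA_real_)
    if (is.finite(fl)) preds["FRAGMENT"] <- fl
  }
  if (!is.null(external) && length(external)) {
    ext <- external[is.finite(external)]
    preds[names(ext)] <- ext
  }
  structure(list(
    predictions = preds,
    consensus = consensus_logp(preds),
    n_predictors = sum(is.finite(preds))
  ), class = "adm_lipophilicity")
}

#' Consensus log P
#'
#' Arithmetic mean of the available (finite) predictor values.
#' @param values Named or unnamed numeric vector of log P predictions.
#' @return Mean of finite values.
#' @export
consensus_logp <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0L) {
    adm_error("adm_no_predictor", "no lipophilicity predictor available")
  }
  mean(v)
}

#' @export
print.adm_lipophilicity <- function(x, ...) {
  cat("<adm_lipophilicity>\n")
  for (nm in names(x$predictions)) {
    cat(sprintf("  %-9s %8.3f\n", nm, x$predictions[[nm]]))
  }
  cat(sprintf("  consensus %7.3f  (%d predictors)\n",
              x$consensus, x$n_predictors))
  invisible(x)
}

#' Read an external-predictions table
#'
#' CSV with columns \code{name}, \code{predictor}, \code{value}; returns a
#' named list (per molecule name) of named numeric vectors, suitable for
#' the \code{external} argument of profiling functions.
#' @param path CSV file path.
#' @return Named list of named numeric vectors.
#' @export
read_external_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "predictor", "value") %in% names(df)))
  out <- list()
  for (r in seq_len(nrow(df))) {
    nm <- df$name[r]
    out[[nm]] <- c(out[[nm]], stats::setNames(df$value[r], df$predictor[r]))
  }
  out
}
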