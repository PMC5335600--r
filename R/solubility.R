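## Water solubility: three log S estimators, unit conversions and the
## qualitative class scale.

## ESOL linear model: log S = 0.16 - 0.63 logP - 0.0062 MW
##                          + 0.066 RB - 0.74 AP
ESOL_COEF <- c(intercept = 0.16, logp = -0.63, mw = -0.0062,
               rb = 0.066, ap = -0.74)

## log P / TPSA linear solubility model (the melting-point-free
## reformulation of the general solubility equation)
ALI_COEF <- c(intercept = -1.0323, logp = -1.0148, tpsa = -0.0056)

#' ESOL water solubility
#'
#' Linear QSPR in log P, molecular weight, rotatable bonds and aromatic
#' proportion (aromatic heavy atoms over heavy atoms).  The lipophilicity
#' input is pluggable; by default profiling uses WLOGP unless an external
#' atomistic prediction is supplied.
#'
#' @param descriptors \code{adm_descriptors} (needs MW, rotatable_bonds,
#'   aromatic_proportion).
#' @param logp Lipophilicity value to plug in.
#' @return log10 of molar solubility (log S).
#' @export
esol_logs <- function(descriptors, logp) {
  unname(ESOL_COEF["intercept"] +
           ESOL_COEF["logp"] * logp +
           ESOL_COEF["mw"] * descriptors$MW +
           ESOL_COEF["rb"] * descriptors$rotatable_bonds +
           ESOL_COEF["ap"] * descriptors$aromatic_proportion)
}

#' log P/TPSA water solubility
#'
#' Linear model in lipophilicity and topological polar surface area.
#' @inheritParams esol_logs
#' @return log S (log10 mol/l).
#' @export
ali_logs <- function(descriptors, logp) {
  unname(ALI_COEF["intercept"] +
           ALI_COEF["logp"] * logp +
           ALI_COEF["tpsa"] * descriptors$TPSA)
}

#' Table-driven fragmental water solubility
#'
#' Fragmental contributions (SMARTS-keyed counts times coefficients)
#' modulated by the square root of molecular weight:
#' \code{logS = intercept + sum(coef_i * n_i) + coef_mw * sqrt(MW)}.
#'
#' @param mol An \code{adm_molecule}.
#' @param table data.frame with columns \code{kind}
#'   (\code{"fragment"}, \code{"sqrt_mw"} or \code{"intercept"}),
#'   \code{key}, \code{coef}.
#' @param descriptors Optional precomputed panel (for MW).
#' @return log S (log10 mol/l).
#' @export
fragment_logs <- function(mol, table, descriptors = NULL) {
  if (is.null(table)) {
    adm_error("adm_missing_table", "no fragmental solubility table")
  }
  stopifnot(is.data.frame(table),
            all(c("kind", "key", "coef") %in% names(table)))
  mw <- if (!is.null(descriptors)) descriptors$MW else molecular_weight(mol)
  total <- sum(table$coef[table$kind == "intercept"]) +
    sum(table$coef[table$kind == "sqrt_mw"]) * sqrt(mw)
  frag <- table[table$kind == "fragment", , drop = FALSE]
  if (nrow(frag)) {
    sdf <- as_sdfset(mol)
    for (r in seq_len(nrow(frag))) {
      total <- total + frag$coef[r] * smarts_count(sdf, frag$key[r])
    }
  }
  total
}

#' Qualitative solubility class
#'
#' Maps log S onto the qualitative scale
#' insoluble < -10 < poorly < -6 < moderately < -4 < soluble < -2 <
#' very < 0 < highly.  Boundary values take the more soluble label.
#'
#' @param logs log S value (log10 mol/l).
#' @return One of \code{"insoluble"}, \code{"poorly"},
#'   \code{"moderately"}, \code{"soluble"}, \code{"very"},
#'   \code{"highly"}.
#' @examples
#' solubility_class(-5)   # "moderately"
#' @export
solubility_class <- function(logs) {
  stopifnot(is.finite(logs))
  if (logs < -10) "insoluble"
  else if (logs < -6) "poorly"
  else if (logs < -4) "moderately"
  else if (logs < -2) "soluble"
  else if (logs < 0) "very"
  else "highly"
}

SOLUBILITY_CLASS_LEVELS <- c("insoluble", "poorly", "moderately",
                             "soluble", "very", "highly")

#' Convert log S to solubility amounts
#'
#' @param logs log S (log10 mol/l).
#' @param mw Molecular weight (g/mol), must be positive.
#' @return Named numeric vector: \code{mol_per_l} and \code{mg_per_ml}.
#' @examples
#' logs_to_amounts(0, 100)   # 1 mol/l, 100 mg/ml
#' @export
logs_to_amounts <- function(logs, mw) {
  stopifnot(mw > 0)
  mol_l <- 10^logs
  c(mol_per_l = mol_l, mg_per_ml = mol_l * mw)
}

#' Full solubility prediction for one model
#'
#' @param logs log S value.
#' @param mw Molecular weight.
#' @param model Label of the producing model.
#' @return Object of class \code{adm_solubility}.
#' @export
solubility_prediction <- function(logs, mw, model = "ESOL") {
  amounts <- logs_to_amounts(logs, mw)
  structure(list(
    model = model,
    logS = logs,
    mol_per_l = unname(amounts["mol_per_l"]),
    mg_per_ml = unname(amounts["mg_per_ml"]),
    class_label = solubility_class(logs)
  ), class = "adm_solubility")
}

#' @export
print.adm_solubility <- function(x, ...) {
  cat(sprintf("<adm_solubility %s> logS=%.3f (%s; %.3g mol/l, %.3g mg/ml)\n",
              x$model, x$logS, x$class_label, x$mol_per_l, x$mg_per_ml))
  invisible(x)
}
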