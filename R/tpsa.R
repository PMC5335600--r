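## Topological polar surface area: fragmental contributions summed over
## polar atom environments (N, O, and optionally S, P).  Each environment
## is keyed by element, aromaticity, formal charge, hydrogen count, 3-ring
## membership and the pattern of single/double/triple/aromatic bonds.

## contribution key: elem|arom|charge|nH|in3ring|s|d|t|a
TPSA_CONTRIB <- local({
  k <- function(elem, arom, charge, nH, in3, s, d, t, a) {
    paste(elem, as.integer(arom), charge, nH, as.integer(in3),
          s, d, t, a, sep = "|")
  }
  v <- c()
  add <- function(v, val, elem, arom, charge, nH, in3, s, d, t, a) {
    v[k(elem, arom, charge, nH, in3, s, d, t, a)] <- val
    v
  }
  ## nitrogen, neutral, non-aromatic
  v <- add(v, 3.24,  "N", FALSE, 0, 0, FALSE, 3, 0, 0, 0)
  v <- add(v, 12.36, "N", FALSE, 0, 0, FALSE, 1, 1, 0, 0)
  v <- add(v, 23.79, "N", FALSE, 0, 0, FALSE, 0, 0, 1, 0)
  v <- add(v, 11.68, "N", FALSE, 0, 0, FALSE, 1, 2, 0, 0)
  v <- add(v, 13.60, "N", FALSE, 0, 0, FALSE, 0, 1, 1, 0)
  v <- add(v, 3.01,  "N", FALSE, 0, 0, TRUE,  3, 0, 0, 0)
  v <- add(v, 12.03, "N", FALSE, 0, 1, FALSE, 2, 0, 0, 0)
  v <- add(v, 21.94, "N", FALSE, 0, 1, TRUE,  2, 0, 0, 0)
  v <- add(v, 23.85, "N", FALSE, 0, 1, FALSE, 0, 1, 0, 0)
  v <- add(v, 26.02, "N", FALSE, 0, 2, FALSE, 1, 0, 0, 0)
  ## nitrogen, +1, non-aromatic
  v <- add(v, 0.00,  "N", FALSE, 1, 0, FALSE, 4, 0, 0, 0)
  v <- add(v, 3.01,  "N", FALSE, 1, 0, FALSE, 2, 1, 0, 0)
  v <- add(v, 4.36,  "N", FALSE, 1, 0, FALSE, 1, 0, 1, 0)
  v <- add(v, 4.44,  "N", FALSE, 1, 1, FALSE, 3, 0, 0, 0)
  v <- add(v, 13.97, "N", FALSE, 1, 1, FALSE, 1, 1, 0, 0)
  v <- add(v, 16.61, "N", FALSE, 1, 2, FALSE, 2, 0, 0, 0)
  v <- add(v, 25.59, "N", FALSE, 1, 2, FALSE, 0, 1, 0, 0)
  v <- add(v, 27.64, "N", FALSE, 1, 3, FALSE, 1, 0, 0, 0)
  ## nitrogen, aromatic
  v <- add(v, 12.89, "N", TRUE, 0, 0, FALSE, 0, 0, 0, 2)
  v <- add(v, 4.41,  "N", TRUE, 0, 0, FALSE, 0, 0, 0, 3)
  v <- add(v, 4.93,  "N", TRUE, 0, 0, FALSE, 1, 0, 0, 2)
  v <- add(v, 8.39,  "N", TRUE, 0, 0, FALSE, 0, 1, 0, 2)
  v <- add(v, 15.79, "N", TRUE, 0, 1, FALSE, 0, 0, 0, 2)
  v <- add(v, 4.10,  "N", TRUE, 1, 0, FALSE, 0, 0, 0, 3)
  v <- add(v, 3.88,  "N", TRUE, 1, 0, FALSE, 1, 0, 0, 2)
  v <- add(v, 14.14, "N", TRUE, 1, 1, FALSE, 0, 0, 0, 2)
  ## oxygen
  v <- add(v, 9.23,  "O", FALSE, 0, 0, FALSE, 2, 0, 0, 0)
  v <- add(v, 12.53, "O", FALSE, 0, 0, TRUE,  2, 0, 0, 0)
  v <- add(v, 17.07, "O", FALSE, 0, 0, FALSE, 0, 1, 0, 0)
  v <- add(v, 20.23, "O", FALSE, 0, 1, FALSE, 1, 0, 0, 0)
  v <- add(v, 23.06, "O", FALSE, -1, 0, FALSE, 1, 0, 0, 0)
  v <- add(v, 13.14, "O", TRUE, 0, 0, FALSE, 0, 0, 0, 2)
  ## sulfur (polar-S extension)
  v <- add(v, 25.30, "S", FALSE, 0, 0, FALSE, 2, 0, 0, 0)
  v <- add(v, 32.09, "S", FALSE, 0, 0, FALSE, 0, 1, 0, 0)
  v <- add(v, 19.21, "S", FALSE, 0, 0, FALSE, 2, 1, 0, 0)
  v <- add(v, 8.38,  "S", FALSE, 0, 0, FALSE, 2, 2, 0, 0)
  v <- add(v, 38.80, "S", FALSE, 0, 1, FALSE, 1, 0, 0, 0)
  v <- add(v, 28.24, "S", TRUE, 0, 0, FALSE, 0, 0, 0, 2)
  v <- add(v, 21.70, "S", TRUE, 0, 0, FALSE, 0, 1, 0, 2)
  ## phosphorus (polar-P extension)
  v <- add(v, 13.59, "P", FALSE, 0, 0, FALSE, 3, 0, 0, 0)
  v <- add(v, 34.14, "P", FALSE, 0, 0, FALSE, 1, 1, 0, 0)
  v <- add(v, 9.81,  "P", FALSE, 0, 0, FALSE, 3, 1, 0, 0)
  v <- add(v, 23.47, "P", FALSE, 0, 1, FALSE, 2, 1, 0, 0)
  v
})

#' Topological polar surface area
#'
#' Fragmental TPSA: the sum of tabulated surface contributions over polar
#' atom environments.  Sulfur and phosphorus environments are counted as
#' polar by default.  Polar atoms whose environment has no tabulated
#' contribution (rare charged/hypervalent cases) contribute 0.
#'
#' @param mol An \code{adm_molecule}.
#' @param include_sp Include sulfur/phosphorus contributions
#'   (default TRUE).
#' @return TPSA in square Angstroms (non-negative scalar).
#' @examples
#' tpsa(adm_molecule("CCO"))    # one hydroxyl environment: 20.23
#' tpsa(adm_molecule("C"))      # no polar atoms: 0
#' @export
tpsa <- function(mol, include_sp = TRUE) {
  env <- atom_env(mol)
  polar <- c("N", "O", if (include_sp) c("S", "P"))
  total <- 0
  for (i in seq_along(env$elem)) {
    el <- env$elem[i]
    if (!(el %in% polar)) next
    bc <- bond_counts(env, i)
    key <- paste(el, as.integer(env$arom[i]), env$charge[i], env$nH[i],
                 as.integer(env$in3ring[i] && !env$arom[i]),
                 bc["single"], bc["double"], bc["triple"], bc["aromatic"],
                 sep = "|")
    val <- TPSA_CONTRIB[key]
    if (!is.na(val)) total <- total + val
  }
  unname(total)
}
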