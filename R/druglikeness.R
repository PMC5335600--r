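## Rule-based drug-likeness filters, the bioavailability score and the
## six-axis oral-bioavailability radar.  All thresholds are configuration
## data returned by `druglikeness_rules()` / `radar_ranges()` so users can
## re-threshold without touching code.

#' Drug-likeness filter thresholds
#'
#' Returns the default threshold set for the five filters and
#' leadlikeness.  Pass a modified copy to the filter functions to
#' re-threshold.
#' @return Nested named list of thresholds.
#' @export
druglikeness_rules <- function() {
  list(
    lipinski = list(mw_max = 500, mlogp_max = 4.15, hbd_max = 5,
                    hba_max = 10, pass_max_violations = 1L),
    ghose = list(mw = c(160, 480), wlogp = c(-0.4, 5.6), mr = c(40, 130),
                 atoms = c(20, 70)),
    veber = list(rotatable_max = 10, tpsa_max = 140),
    egan = list(wlogp_max = 5.88, tpsa_max = 131.6),
    muegge = list(mw = c(200, 600), xlogp = c(-2, 5), tpsa_max = 150,
                  rings_max = 7, carbons_min = 4, heteroatoms_min = 1,
                  rotatable_max = 15, hba_max = 10, hbd_max = 5),
    leadlikeness = list(mw = c(250, 350), xlogp_max = 3.5,
                        rotatable_max = 7),
    ## bioavailability score class probabilities (config: the default
    ## Lipinski-pass class is printed as 0.56 in the tool this follows,
    ## 0.55 in the original publication)
    bioavailability = list(pass = 0.56, fail = 0.17,
                           anion_low_tpsa = 0.85, anion_mid_tpsa = 0.56,
                           anion_high_tpsa = 0.11,
                           tpsa_low = 75, tpsa_high = 150)
  )
}

filter_result <- function(name, violations) {
  structure(list(name = name, pass = length(violations) == 0L,
                 violations = violations),
            class = "adm_filter")
}

#' @export
print.adm_filter <- function(x, ...) {
  cat(sprintf("<%s> %s", x$name,
              if (x$pass) "pass" else
                paste0(length(x$violations), " violation(s)")))
  if (length(x$violations)) {
    cat(":", paste(x$violations, collapse = "; "))
  }
  cat("\n")
  invisible(x)
}

#' Lipinski rule-of-five filter
#'
#' Violations counted among MW > 500, MLOGP > 4.15, H-bond donors > 5,
#' H-bond acceptors > 10 (N+O counts).  By convention the filter passes
#' with at most one violation; the violation list is always reported.
#'
#' @param descriptors \code{adm_descriptors}.
#' @param mlogp_value Moriguchi log P (defaults to the panel value).
#' @param rules Threshold configuration (see
#'   \code{\link{druglikeness_rules}}).
#' @return \code{adm_filter} with fields \code{name}, \code{pass},
#'   \code{violations}.
#' @export
lipinski <- function(descriptors, mlogp_value = descriptors$MLOGP,
                     rules = druglikeness_rules()) {
  rl <- rules$lipinski
  v <- character(0)
  if (descriptors$MW > rl$mw_max)
    v <- c(v, sprintf("MW > %g", rl$mw_max))
  if (mlogp_value > rl$mlogp_max)
    v <- c(v, sprintf("MLOGP > %g", rl$mlogp_max))
  if (descriptors$HBD > rl$hbd_max)
    v <- c(v, sprintf("HBD > %g", rl$hbd_max))
  if (descriptors$HBA > rl$hba_max)
    v <- c(v, sprintf("HBA > %g", rl$hba_max))
  out <- filter_result("Lipinski", v)
  out$pass <- length(v) <= rl$pass_max_violations
  out
}

#' Ghose filter
#'
#' Closed-interval range checks on MW, WLOGP, molar refractivity and
#' heavy-atom count; boundary values pass.
#' @inheritParams lipinski
#' @param wlogp_value Atomistic log P (defaults to the panel value).
#' @return \code{adm_filter}.
#' @export
ghose <- function(descriptors, wlogp_value = descriptors$WLOGP,
                  rules = druglikeness_rules()) {
  rl <- rules$ghose
  v <- character(0)
  chk <- function(v, val, rng, label) {
    if (val < rng[1]) c(v, sprintf("%s < %g", label, rng[1]))
    else if (val > rng[2]) c(v, sprintf("%s > %g", label, rng[2]))
    else v
  }
  v <- chk(v, descriptors$MW, rl$mw, "MW")
  v <- chk(v, wlogp_value, rl$wlogp, "WLOGP")
  v <- chk(v, descriptors$MR, rl$mr, "MR")
  v <- chk(v, descriptors$heavy_atoms, rl$atoms, "#atoms")
  filter_result("Ghose", v)
}

#' Veber filter
#'
#' Oral-bioavailability heuristics: at most 10 rotatable bonds and TPSA
#' at most 140.
#' @inheritParams lipinski
#' @return \code{adm_filter}.
#' @export
veber <- function(descriptors, rules = druglikeness_rules()) {
  rl <- rules$veber
  v <- character(0)
  if (descriptors$rotatable_bonds > rl$rotatable_max)
    v <- c(v, sprintf("rotatable bonds > %g", rl$rotatable_max))
  if (descriptors$TPSA > rl$tpsa_max)
    v <- c(v, sprintf("TPSA > %g", rl$tpsa_max))
  filter_result("Veber", v)
}

#' Egan filter
#'
#' Absorption-region check: WLOGP at most 5.88 and TPSA at most 131.6
#' (the atomistic log P substitutes for the original closed-source
#' descriptor).
#' @inheritParams ghose
#' @return \code{adm_filter}.
#' @export
egan <- function(descriptors, wlogp_value = descriptors$WLOGP,
                 rules = druglikeness_rules()) {
  rl <- rules$egan
  v <- character(0)
  if (wlogp_value > rl$wlogp_max)
    v <- c(v, sprintf("WLOGP > %g", rl$wlogp_max))
  if (descriptors$TPSA > rl$tpsa_max)
    v <- c(v, sprintf("TPSA > %g", rl$tpsa_max))
  filter_result("Egan", v)
}

#' Muegge filter
#'
#' Pharmacophore-point filter: MW in [200, 600], lipophilicity in
#' [-2, 5] (external atomistic prediction when supplied, otherwise
#' WLOGP), TPSA at most 150, at most 7 rings, more than 4 carbons, more
#' than 1 heteroatom, at most 15 rotatable bonds, at most 10 acceptors,
#' at most 5 donors.
#' @inheritParams lipinski
#' @param logp_value Lipophilicity plugged into the [-2, 5] window.
#' @return \code{adm_filter}.
#' @export
muegge <- function(descriptors, logp_value = descriptors$WLOGP,
                   rules = druglikeness_rules()) {
  rl <- rules$muegge
  v <- character(0)
  if (descriptors$MW < rl$mw[1]) v <- c(v, sprintf("MW < %g", rl$mw[1]))
  if (descriptors$MW > rl$mw[2]) v <- c(v, sprintf("MW > %g", rl$mw[2]))
  if (logp_value < rl$xlogp[1]) v <- c(v, sprintf("XLOGP < %g", rl$xlogp[1]))
  if (logp_value > rl$xlogp[2]) v <- c(v, sprintf("XLOGP > %g", rl$xlogp[2]))
  if (descriptors$TPSA > rl$tpsa_max)
    v <- c(v, sprintf("TPSA > %g", rl$tpsa_max))
  if (descriptors$ring_count > rl$rings_max)
    v <- c(v, sprintf("rings > %g", rl$rings_max))
  if (descriptors$carbon_count <= rl$carbons_min)
    v <- c(v, sprintf("carbons <= %g", rl$carbons_min))
  if (descriptors$heteroatoms <= rl$heteroatoms_min)
    v <- c(v, sprintf("heteroatoms <= %g", rl$heteroatoms_min))
  if (descriptors$rotatable_bonds > rl$rotatable_max)
    v <- c(v, sprintf("rotatable bonds > %g", rl$rotatable_max))
  if (descriptors$HBA > rl$hba_max)
    v <- c(v, sprintf("HBA > %g", rl$hba_max))
  if (descriptors$HBD > rl$hbd_max)
    v <- c(v, sprintf("HBD > %g", rl$hbd_max))
  filter_result("Muegge", v)
}

#' Abbott bioavailability score
#'
#' Semi-quantitative probability of at least 10% oral bioavailability in
#' rat (or measurable Caco-2 permeability), from total charge, TPSA and
#' Lipinski compliance.  Anions (net input charge < 0) are classed by
#' TPSA (<= 75: 0.85; 75-150: 0.56; > 150: 0.11); other molecules score
#' 0.56 when Lipinski-compliant and 0.17 otherwise.
#'
#' @param net_charge Net formal charge of the as-input structure.
#' @param tpsa_value TPSA in square Angstroms.
#' @param lipinski_result \code{adm_filter} from \code{\link{lipinski}}.
#' @param rules Threshold configuration.
#' @return One of 0.11, 0.17, 0.56, 0.85 (under default configuration).
#' @examples
#' # a mono-anion with TPSA ~40 scores 0.85
#' @export
bioavailability_score <- function(net_charge, tpsa_value, lipinski_result,
                                  rules = druglikeness_rules()) {
  rl <- rules$bioavailability
  if (net_charge < 0) {
    if (tpsa_value <= rl$tpsa_low) return(rl$anion_low_tpsa)
    if (tpsa_value <= rl$tpsa_high) return(rl$anion_mid_tpsa)
    return(rl$anion_high_tpsa)
  }
  if (isTRUE(lipinski_result$pass)) rl$pass else rl$fail
}

#' Radar axis ranges
#'
#' Optimal-property ranges of the six-axis oral-bioavailability radar.
#' The lipophilicity ceiling defaults to +6.0 (configurable; the
#' originating figure uses +5.0).
#' @return Named list of two-sided ranges.
#' @export
radar_ranges <- function() {
  list(
    LIPO = c(-0.7, 6.0),      # lipophilicity (external slot or WLOGP)
    SIZE = c(150, 500),       # MW, g/mol
    POLAR = c(20, 130),       # TPSA
    INSOLU = c(-6, Inf),      # ESOL log S (not below -6)
    INSATU = c(0.25, Inf),    # fraction Csp3
    FLEX = c(-Inf, 9)         # rotatable bonds
  )
}

#' Oral-bioavailability radar
#'
#' Six-axis drug-likeness readout: lipophilicity, size, polarity,
#' solubility, saturation, flexibility.  A molecule is flagged drug-like
#' when all six values fall inside their optimal ranges.
#'
#' @param descriptors \code{adm_descriptors}.
#' @param lipo Lipophilicity value for the LIPO axis (external atomistic
#'   prediction when available, otherwise WLOGP).
#' @param esol ESOL log S for the INSOLU axis.
#' @param ranges Axis configuration (see \code{\link{radar_ranges}}).
#' @return Object of class \code{adm_radar}: axis values, per-axis pass
#'   flags, and the overall drug-likeness flag.
#' @export
radar <- function(descriptors, lipo = descriptors$WLOGP,
                  esol = esol_logs(descriptors, lipo),
                  ranges = radar_ranges()) {
  values <- c(
    LIPO = unname(lipo),
    SIZE = descriptors$MW,
    POLAR = descriptors$TPSA,
    INSOLU = unname(esol),
    INSATU = descriptors$fraction_csp3,
    FLEX = descriptors$rotatable_bonds
  )
  pass <- vapply(names(values), function(ax) {
    rng <- ranges[[ax]]
    values[[ax]] >= rng[1] && values[[ax]] <= rng[2]
  }, TRUE)
  structure(list(values = values, pass = pass,
                 drug_like = all(pass)), class = "adm_radar")
}

#' @export
print.adm_radar <- function(x, ...) {
  cat("<adm_radar>", if (x$drug_like) "drug-like" else "not drug-like", "\n")
  for (ax in names(x$values)) {
    cat(sprintf("  %-7s %9.3f  %s\n", ax, x$values[[ax]],
                if (x$pass[[ax]]) "ok" else "out of range"))
  }
  invisible(x)
}
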