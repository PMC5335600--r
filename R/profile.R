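## Per-molecule profiling: assembles descriptors, lipophilicity,
## solubility, pharmacokinetics, drug-likeness, medicinal-chemistry
## sections into one PropertyProfile per molecule, plus batch helpers,
## CSV reporting and the egg plot-data table.

#' Profiling configuration
#'
#' Bundles the pieces a profile needs: alert catalogs, egg geometry,
#' radar ranges, filter thresholds, optional fragment coefficient
#' tables, an optional synthetic-accessibility frequency table, an
#' optional P-gp classifier, and the lipophilicity-slot policy (which
#' external predictor name, when supplied, replaces WLOGP in models that
#' call for an atomistic external log P).
#'
#' @param pains,brenk Alert catalogs (NULL to skip screening).
#' @param egg \code{adm_egg_geometry}.
#' @param ranges Radar ranges.
#' @param rules Filter thresholds.
#' @param logp_slot Name of the external predictor that feeds the
#'   lipophilicity slot when present (default \code{"XLOGP3"}).
#' @param fragment_logp_table,fragment_logs_table Optional coefficient
#'   tables.
#' @param sa_table Optional \code{adm_freq_table} for the synthetic
#'   accessibility score.
#' @param pgp_model Optional \code{adme_svm} P-gp substrate classifier
#'   (operating on the descriptor panel).
#' @param screen_alerts Run PAINS/Brenk screening (default TRUE;
#'   screening several hundred SMARTS per molecule is the slow part of a
#'   profile).
#' @return List of class \code{adm_config}.
#' @export
adme_config <- function(pains = pains_catalog(), brenk = brenk_catalog(),
                        egg = load_egg_geometry(), ranges = radar_ranges(),
                        rules = druglikeness_rules(), logp_slot = "XLOGP3",
                        fragment_logp_table = NULL,
                        fragment_logs_table = NULL,
                        sa_table = NULL, pgp_model = NULL,
                        screen_alerts = TRUE) {
  structure(list(pains = pains, brenk = brenk, egg = egg, ranges = ranges,
                 rules = rules, logp_slot = logp_slot,
                 fragment_logp_table = fragment_logp_table,
                 fragment_logs_table = fragment_logs_table,
                 sa_table = sa_table, pgp_model = pgp_model,
                 screen_alerts = screen_alerts),
            class = "adm_config")
}

#' Profile one molecule
#'
#' Computes the full per-molecule property panel.  A parse or
#' standardization failure returns an error profile (status recorded)
#' instead of raising, so batch profiling never aborts.
#'
#' @param smiles SMILES string.
#' @param name Molecule name.
#' @param config \code{adm_config}.
#' @param external Named numeric vector of external log P predictions
#'   for this molecule (e.g. \code{c(XLOGP3 = 3.1)}).
#' @return Object of class \code{adm_profile}.
#' @export
adme_profile <- function(smiles, name = "Molecule_1",
                         config = adme_config(), external = NULL) {
  mol <- tryCatch(adm_molecule(smiles, name), error = function(e) e)
  if (inherits(mol, "error")) {
    return(structure(list(name = name, input_smiles = smiles,
                          status = conditionMessage(mol), ok = FALSE),
                     class = "adm_profile"))
  }
  d <- compute_descriptor_panel(mol)
  lipo <- lipophilicity_profile(mol, external = external,
                                fragment_table = config$fragment_logp_table,
                                descriptors = d)
  ## lipophilicity slot: external atomistic predictor if supplied,
  ## otherwise WLOGP (substitution recorded)
  slot_name <- config$logp_slot
  if (!is.null(external) && slot_name %in% names(external) &&
      is.finite(external[[slot_name]])) {
    lipo_slot <- external[[slot_name]]
    slot_used <- slot_name
  } else {
    lipo_slot <- d$WLOGP
    slot_used <- "WLOGP (substituted)"
  }

  esol <- esol_logs(d, lipo_slot)
  ali <- ali_logs(d, lipo_slot)
  sol <- list(
    ESOL = solubility_prediction(esol, d$MW, "ESOL"),
    ALI = solubility_prediction(ali, d$MW, "ALI")
  )
  if (!is.null(config$fragment_logs_table)) {
    fs <- tryCatch(fragment_logs(mol, config$fragment_logs_table, d),
                   adm_missing_table = function(e) NA_real_)
    if (is.finite(fs)) {
      sol$FRAGMENT <- solubility_prediction(fs, d$MW, "FRAGMENT")
    }
  }

  egg <- boiled_egg(d$TPSA, d$WLOGP, config$egg)
  pgp <- NULL
  if (!is.null(config$pgp_model)) {
    feat <- matrix(unlist(d), nrow = 1)
    colnames(feat) <- names(d)
    pgp <- tryCatch(predict(config$pgp_model, feat)$class == 1L,
                    error = function(e) NULL)
  }
  pk <- list(log_kp = skin_log_kp(d, lipo_slot),
             hia = egg$hia, bbb = egg$bbb,
             in_plot_range = egg$in_plot_range,
             pgp_substrate = pgp)

  lip <- lipinski(d, rules = config$rules)
  filters <- list(
    Lipinski = lip,
    Ghose = ghose(d, rules = config$rules),
    Veber = veber(d, rules = config$rules),
    Egan = egan(d, rules = config$rules),
    Muegge = muegge(d, logp_value = lipo_slot, rules = config$rules)
  )
  abs_score <- bioavailability_score(mol$input_net_charge, d$TPSA, lip,
                                     rules = config$rules)
  rad <- radar(d, lipo = lipo_slot, esol = esol, ranges = config$ranges)

  alerts <- list()
  if (isTRUE(config$screen_alerts)) {
    if (!is.null(config$pains)) alerts$PAINS <- alert_screen(mol, config$pains)
    if (!is.null(config$brenk)) alerts$Brenk <- alert_screen(mol, config$brenk)
  }
  lead <- leadlikeness(d, logp_value = lipo_slot, rules = config$rules)
  sa <- if (!is.null(config$sa_table)) sa_score(mol, config$sa_table)

  structure(list(
    name = mol$name,
    input_smiles = smiles,
    smiles = canonical_smiles(mol),
    formula = molecular_formula(mol),
    status = "OK",
    ok = TRUE,
    flags = mol$flags,
    descriptors = d,
    lipophilicity = lipo,
    lipo_slot = lipo_slot,
    lipo_slot_source = slot_used,
    solubility = sol,
    pk = pk,
    filters = filters,
    bioavailability_score = abs_score,
    radar = rad,
    alerts = alerts,
    leadlikeness = lead,
    sa = sa
  ), class = "adm_profile")
}

#' @export
print.adm_profile <- function(x, ...) {
  cat("==", x$name, "==\n")
  if (!x$ok) {
    cat("  FAILED:", x$status, "\n")
    return(invisible(x))
  }
  cat("  SMILES:", x$smiles, " (", x$formula, ")\n")
  d <- x$descriptors
  cat(sprintf("  MW %.2f | TPSA %.2f | WLOGP %.2f | MLOGP %.2f | consensus %.2f\n",
              d$MW, d$TPSA, d$WLOGP, d$MLOGP, x$lipophilicity$consensus))
  cat(sprintf("  ESOL logS %.2f (%s) | logKp %.2f cm/s | HIA %s | BBB %s\n",
              x$solubility$ESOL$logS, x$solubility$ESOL$class_label,
              x$pk$log_kp, x$pk$hia, x$pk$bbb))
  pass <- vapply(x$filters, `[[`, TRUE, "pass")
  cat("  filters:", paste(sprintf("%s:%s", names(pass),
                                  ifelse(pass, "pass", "FAIL")),
                          collapse = " "), "\n")
  cat(sprintf("  bioavailability score %.2f | radar %s | leadlikeness %s\n",
              x$bioavailability_score,
              if (x$radar$drug_like) "drug-like" else "not drug-like",
              if (x$leadlikeness$pass) "pass" else "fail"))
  if (length(x$alerts)) {
    for (nm in names(x$alerts)) {
      cat(sprintf("  %s alerts: %d\n", nm, nrow(x$alerts[[nm]])))
    }
  }
  if (!is.null(x$sa)) cat(sprintf("  SA score %.2f\n", x$sa$normalized))
  invisible(x)
}

#' Profile a batch of molecules
#'
#' @param input Multi-line SMILES text (one molecule per line, optional
#'   name) or a data.frame with \code{smiles}/\code{name} columns.
#' @param config \code{adm_config}.
#' @param external Named list (by molecule name) of external prediction
#'   vectors.
#' @return List of \code{adm_profile} (class \code{adm_profile_list});
#'   one entry per input molecule, errors included as failed profiles.
#' @export
adme_profile_batch <- function(input, config = adme_config(),
                               external = NULL) {
  df <- if (is.data.frame(input)) input else parse_smiles_list(input)
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    out[[i]] <- adme_profile(df$smiles[i], df$name[i], config,
                             external = external[[df$name[i]]])
  }
  names(out) <- df$name
  structure(out, class = "adm_profile_list")
}

#' @export
print.adm_profile_list <- function(x, ...) {
  for (p in x) print(p)
  invisible(x)
}

## fixed flat schema for the CSV report
profile_row <- function(p) {
  base <- list(name = p$name, input_smiles = p$input_smiles,
               smiles = if (p$ok) p$smiles else NA_character_,
               formula = if (p$ok) p$formula else NA_character_,
               status = p$status)
  if (!p$ok) {
    return(c(base, stats::setNames(
      as.list(rep(NA, length(REPORT_NUMERIC_COLUMNS))),
      REPORT_NUMERIC_COLUMNS)))
  }
  d <- p$descriptors
  preds <- p$lipophilicity$predictions
  vals <- list(
    MW = d$MW, heavy_atoms = d$heavy_atoms,
    aromatic_heavy_atoms = d$aromatic_heavy_atoms,
    fraction_csp3 = d$fraction_csp3, rotatable_bonds = d$rotatable_bonds,
    HBA = d$HBA, HBD = d$HBD, MR = d$MR, TPSA = d$TPSA,
    net_charge = d$formal_charge, input_charge = d$input_charge,
    WLOGP = d$WLOGP, MLOGP = d$MLOGP,
    XLOGP3_ext = if ("XLOGP3" %in% names(preds)) preds[["XLOGP3"]] else NA,
    ILOGP_ext = if ("ILOGP" %in% names(preds)) preds[["ILOGP"]] else NA,
    consensus_logp = p$lipophilicity$consensus,
    lipo_slot = p$lipo_slot,
    esol_logS = p$solubility$ESOL$logS,
    esol_mol_l = p$solubility$ESOL$mol_per_l,
    esol_mg_ml = p$solubility$ESOL$mg_per_ml,
    ali_logS = p$solubility$ALI$logS,
    fragment_logS = if (!is.null(p$solubility$FRAGMENT))
      p$solubility$FRAGMENT$logS else NA,
    log_kp = p$pk$log_kp,
    hia = p$pk$hia, bbb = p$pk$bbb, egg_in_range = p$pk$in_plot_range,
    pgp_substrate = if (is.null(p$pk$pgp_substrate)) NA else
      p$pk$pgp_substrate,
    lipinski_violations = length(p$filters$Lipinski$violations),
    lipinski_pass = p$filters$Lipinski$pass,
    ghose_pass = p$filters$Ghose$pass,
    veber_pass = p$filters$Veber$pass,
    egan_pass = p$filters$Egan$pass,
    muegge_pass = p$filters$Muegge$pass,
    bioavailability_score = p$bioavailability_score,
    radar_drug_like = p$radar$drug_like,
    pains_alerts = if (!is.null(p$alerts$PAINS)) nrow(p$alerts$PAINS) else NA,
    brenk_alerts = if (!is.null(p$alerts$Brenk)) nrow(p$alerts$Brenk) else NA,
    leadlikeness_pass = p$leadlikeness$pass,
    sa_score = if (!is.null(p$sa)) p$sa$normalized else NA
  )
  c(base, vals)
}

REPORT_NUMERIC_COLUMNS <- c(
  "MW", "heavy_atoms", "aromatic_heavy_atoms", "fraction_csp3",
  "rotatable_bonds", "HBA", "HBD", "MR", "TPSA", "net_charge",
  "input_charge", "WLOGP", "MLOGP", "XLOGP3_ext", "ILOGP_ext",
  "consensus_logp", "lipo_slot", "esol_logS", "esol_mol_l", "esol_mg_ml",
  "ali_logS", "fragment_logS", "log_kp", "hia", "bbb", "egg_in_range",
  "pgp_substrate", "lipinski_violations", "lipinski_pass", "ghose_pass",
  "veber_pass", "egan_pass", "muegge_pass", "bioavailability_score",
  "radar_drug_like", "pains_alerts", "brenk_alerts", "leadlikeness_pass",
  "sa_score")

#' Tabulate profiles
#'
#' Flattens profiles to a data.frame with a stable, documented column
#' order; failed profiles keep their row with empty cells and the error
#' in \code{status}.
#' @param profiles \code{adm_profile_list} (or list of profiles).
#' @return data.frame, one row per molecule.
#' @export
profile_table <- function(profiles) {
  rows <- lapply(profiles, function(p) as.data.frame(profile_row(p)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the CSV report
#'
#' @param profiles \code{adm_profile_list}.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_report <- function(profiles, path) {
  if (length(profiles) == 0L) {
    adm_error("adm_io", "no profiles to write")
  }
  utils::write.csv(profile_table(profiles), path, row.names = FALSE)
  invisible(path)
}

#' Egg plot data
#'
#' One row per molecule with the (TPSA, WLOGP) position and the
#' classification flags; molecules outside the plot range are flagged
#' (and counted in the \code{n_out_of_range} attribute).  The P-gp flag
#' is NA when no classifier is loaded — never fabricated.
#'
#' @param profiles \code{adm_profile_list}.
#' @return data.frame with columns name, TPSA, WLOGP, hia, bbb,
#'   pgp_substrate, in_range.
#' @export
egg_plot_data <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    if (!p$ok) {
      return(data.frame(name = p$name, TPSA = NA_real_, WLOGP = NA_real_,
                        hia = NA, bbb = NA, pgp_substrate = NA,
                        in_range = NA))
    }
    data.frame(
      name = p$name, TPSA = p$descriptors$TPSA, WLOGP = p$descriptors$WLOGP,
      hia = p$pk$hia, bbb = p$pk$bbb,
      pgp_substrate = if (is.null(p$pk$pgp_substrate)) NA else
        p$pk$pgp_substrate,
      in_range = p$pk$in_plot_range)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_out_of_range") <- sum(!out$in_range, na.rm = TRUE)
  out
}
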