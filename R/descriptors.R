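## Molecular and physicochemical descriptors feeding the radar, the
## rule-based filters, the solubility/permeation models and the SVM
## feature panel.

#' Molecular weight
#' @param mol An \code{adm_molecule}.
#' @return Average molecular weight in g/mol (hydrogens included).
#' @export
molecular_weight <- function(mol) {
  sum(atomic_mass(mol$atoms$elem)) + sum(mol$atoms$nH) * ATOMIC_MASS[["H"]]
}

#' Fraction of sp3-hybridized carbons
#'
#' Ratio of sp3 carbons (non-aromatic carbons with only single bonds) over
#' the total carbon count.  Carbon-free molecules return 0 with a warning.
#' @param mol An \code{adm_molecule}.
#' @return Value in [0, 1].
#' @export
fraction_csp3 <- function(mol) {
  env <- atom_env(mol)
  is_c <- env$elem == "C"
  if (!any(is_c)) {
    adm_warn("adm_carbon_free", "carbon-free molecule: fraction Csp3 set to 0")
    return(0)
  }
  sp3 <- vapply(which(is_c), function(i) {
    !env$arom[i] && all(env$bord[[i]] == 1 & !env$barom[[i]])
  }, TRUE)
  sum(sp3) / sum(is_c)
}

#' Rotatable bond count
#'
#' Non-ring single bonds between two non-terminal heavy atoms; amide C-N
#' bonds are excluded (the convention behind the flexibility rules).
#' @param mol An \code{adm_molecule}.
#' @return Integer count.
#' @export
rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(0L)
  env <- atom_env(mol)
  deg <- env$deg
  n <- 0L
  for (r in seq_len(nrow(b))) {
    if (b$order[r] != 1L || b$ring[r] || isTRUE(b$arom[r])) next
    i <- b$a1[r]; j <- b$a2[r]
    if (deg[i] < 2L || deg[j] < 2L) next
    if (is_amide_cn(env, i, j) || is_amide_cn(env, j, i)) next
    n <- n + 1L
  }
  n
}

## C-N single bond where the carbon carries a double bond to oxygen
is_amide_cn <- function(env, ci, ni) {
  env$elem[ci] == "C" && env$elem[ni] == "N" &&
    any(env$bord[[ci]] == 2 & !env$barom[[ci]] &
          env$elem[env$nbr[[ci]]] == "O")
}

#' Lipinski-style hydrogen-bond counts
#'
#' \code{hba_lipinski}: all nitrogen and oxygen atoms.
#' \code{hbd_lipinski}: all N-H and O-H hydrogens.
#' @param mol An \code{adm_molecule}.
#' @return Integer count.
#' @export
hba_lipinski <- function(mol) {
  sum(mol$atoms$elem %in% c("N", "O"))
}

#' @rdname hba_lipinski
#' @export
hbd_lipinski <- function(mol) {
  sum(mol$atoms$nH[mol$atoms$elem %in% c("N", "O")])
}

#' Strict hydrogen-bond acceptor count
#'
#' Conservative acceptor definition: N and O atoms excluding amide and
#' sulfonamide nitrogens, pyrrole-type aromatic nitrogens (three aromatic
#' connections or an aromatic N-H) and nitro-group oxygens.
#' @param mol An \code{adm_molecule}.
#' @return Integer count.
#' @export
hba_strict <- function(mol) {
  env <- atom_env(mol)
  n <- 0L
  for (i in seq_along(env$elem)) {
    el <- env$elem[i]
    if (!(el %in% c("N", "O"))) next
    if (el == "N") {
      if (env$arom[i] && (env$deg[i] >= 3L || env$nH[i] > 0L)) next
      ## amide / sulfonamide N
      nb <- env$nbr[[i]]
      amide <- any(vapply(nb, function(j) {
        env$elem[j] %in% c("C", "S") &&
          any(env$bord[[j]] == 2 & !env$barom[[j]] &
                env$elem[env$nbr[[j]]] == "O")
      }, TRUE))
      if (amide) next
    } else {
      ## nitro O
      nb <- env$nbr[[i]]
      if (length(nb) >= 1L && any(env$elem[nb] == "N" & env$charge[nb] > 0)) next
    }
    n <- n + 1L
  }
  n
}

## Internal: counts used in several descriptor consumers
count_aromatic_rings <- function(mol) {
  if (length(mol$rings) == 0L) return(c(aromatic = 0L, aliphatic = 0L))
  ar <- vapply(mol$rings, function(r) all(mol$atoms$arom[r]), TRUE)
  c(aromatic = sum(ar), aliphatic = sum(!ar))
}

count_amide_bonds <- function(mol) {
  env <- atom_env(mol)
  b <- mol$bonds
  n <- 0L
  for (r in seq_len(nrow(b))) {
    if (b$order[r] != 1L) next
    if (is_amide_cn(env, b$a1[r], b$a2[r]) ||
        is_amide_cn(env, b$a2[r], b$a1[r])) n <- n + 1L
  }
  n
}

#' Compute the full descriptor panel
#'
#' Returns the package's molecular/physicochemical descriptor set: size,
#' polarity, lipophilicity, flexibility, saturation descriptors plus the
#' atom-type and charge counts used as SVM features.
#'
#' @param mol An \code{adm_molecule}.
#' @param include_logp Include the (more expensive) Wildman-Crippen and
#'   Moriguchi log P values in the panel (default TRUE).
#' @return An object of class \code{adm_descriptors}: a named list of
#'   numeric scalars.
#' @examples
#' d <- compute_descriptor_panel(adm_molecule("CCO"))
#' d$MW
#' @export
compute_descriptor_panel <- function(mol, include_logp = TRUE) {
  stopifnot(inherits(mol, "adm_molecule"))
  a <- mol$atoms
  el <- a$elem
  heavy <- nrow(a)
  rc <- count_aromatic_rings(mol)
  cplx <- ring_complexity(mol)
  halogens <- c("F", "Cl", "Br", "I")
  env <- atom_env(mol)
  csp3 <- sum(vapply(seq_len(heavy), function(i) {
    el[i] == "C" && !a$arom[i] && all(env$bord[[i]] == 1 & !env$barom[[i]])
  }, TRUE))
  n_double <- sum(mol$bonds$order == 2 & !mol$bonds$arom)
  n_triple <- sum(mol$bonds$order == 3)
  n_ringb <- sum(mol$bonds$ring)
  ring_atoms <- sum(atom_in_ring(mol))
  d <- list(
    MW = molecular_weight(mol),
    heavy_atoms = heavy,
    aromatic_heavy_atoms = sum(a$arom),
    fraction_csp3 = suppressWarnings(fraction_csp3(mol)),
    rotatable_bonds = rotatable_bonds(mol),
    HBA = hba_lipinski(mol),
    HBD = hbd_lipinski(mol),
    HBA_strict = hba_strict(mol),
    MR = molar_refractivity(mol),
    TPSA = tpsa(mol),
    TPSA_no_SP = tpsa(mol, include_sp = FALSE),
    formal_charge = mol$net_charge,
    input_charge = mol$input_net_charge,
    ring_count = length(mol$rings),
    aromatic_rings = unname(rc["aromatic"]),
    aliphatic_rings = unname(rc["aliphatic"]),
    macrocycles = cplx$n_macrocycle,
    spiro_atoms = cplx$n_spiro,
    bridgehead_atoms = cplx$n_bridgehead,
    max_ring_size = if (length(mol$rings)) max(cplx$ring_sizes) else 0L,
    ring_atoms = ring_atoms,
    ring_bonds = n_ringb,
    heteroatoms = sum(!(el %in% c("C", "H"))),
    carbon_count = sum(el == "C"),
    nitrogen_count = sum(el == "N"),
    oxygen_count = sum(el == "O"),
    sulfur_count = sum(el == "S"),
    phosphorus_count = sum(el == "P"),
    halogen_count = sum(el %in% halogens),
    fluorine_count = sum(el == "F"),
    chlorine_count = sum(el == "Cl"),
    bromine_count = sum(el == "Br"),
    iodine_count = sum(el == "I"),
    csp3_count = csp3,
    sp2_carbon_count = sum(el == "C") - csp3,
    double_bonds = n_double,
    triple_bonds = n_triple,
    amide_bonds = count_amide_bonds(mol),
    h_count = sum(a$nH),
    stereo_centres = mol$n_stereo,
    positive_charges = sum(a$charge > 0),
    negative_charges = sum(a$charge < 0),
    aromatic_proportion = if (heavy > 0) sum(a$arom) / heavy else 0,
    mean_atomic_mass = molecular_weight(mol) / max(heavy, 1L),
    terminal_atoms = sum(env$deg <= 1L),
    branch_atoms = sum(env$deg >= 3L),
    bond_count = nrow(mol$bonds)
  )
  if (include_logp) {
    d$WLOGP <- wlogp(mol)
    d$MLOGP <- mlogp(mol)
  }
  structure(d, class = "adm_descriptors", name = mol$name)
}

#' @export
print.adm_descriptors <- function(x, ...) {
  cat("<adm_descriptors>", attr(x, "name") %||% "", "\n")
  v <- unlist(x)
  print(round(v, 4))
  invisible(x)
}

#' @export
as.data.frame.adm_descriptors <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}
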