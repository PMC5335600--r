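## Wildman-Crippen atomistic log P and molar refractivity: every atom
## (hydrogens included) is assigned to one of the published atom classes by
## ordered structural rules; the property is the sum of per-class
## contributions.  Classes are resolved on the package's kekulized graph
## with aromatic flags; hydrogen classes depend on the heavy atom carrying
## them.

## class -> c(logp, mr); MR entries not defined in the published table are 0
CRIPPEN_CONTRIB <- local({
  m <- rbind(
    C1  = c( 0.1441,  2.503), C2  = c( 0.0000,  2.433),
    C3  = c(-0.2035,  2.753), C4  = c(-0.2051,  2.731),
    C5  = c(-0.2783,  5.007), C6  = c( 0.1551,  3.513),
    C7  = c( 0.0017,  3.888), C8  = c( 0.08452, 2.464),
    C9  = c(-0.1444,  2.412), C10 = c(-0.0516,  2.488),
    C11 = c( 0.1193,  2.582), C12 = c(-0.0967,  2.576),
    C13 = c(-0.5443,  4.041), C14 = c( 0.0000,  3.257),
    C15 = c( 0.2450,  3.564), C16 = c( 0.1980,  3.180),
    C17 = c( 0.0000,  3.104), C18 = c( 0.1581,  3.350),
    C19 = c( 0.2955,  4.346), C20 = c( 0.2713,  3.904),
    C21 = c( 0.1360,  3.509), C22 = c( 0.4619,  4.067),
    C23 = c( 0.5437,  3.853), C24 = c( 0.1893,  2.673),
    C25 = c(-0.8186,  3.135), C26 = c( 0.2640,  4.305),
    C27 = c( 0.2148,  2.693), CS  = c( 0.08129, 3.243),
    H1  = c( 0.1230,  1.057), H2  = c(-0.2677,  1.395),
    H3  = c( 0.2142,  0.9627), H4 = c( 0.2980,  1.805),
    HS  = c( 0.1125,  1.112),
    N1  = c(-1.0190,  2.262), N2  = c(-0.7096,  2.173),
    N3  = c(-1.0270,  2.827), N4  = c(-0.5188,  3.000),
    N5  = c( 0.08387, 1.757), N6  = c( 0.1836,  2.428),
    N7  = c(-0.3187,  1.839), N8  = c(-0.4458,  2.819),
    N9  = c( 0.01508, 1.725), N10 = c(-1.9500,  0.000),
    N11 = c(-0.3239,  2.202), N12 = c(-1.1190,  0.000),
    N13 = c(-0.3396,  0.2604), N14 = c( 0.2887, 3.359),
    NS  = c(-0.4806,  2.134),
    O1  = c( 0.1552,  1.080), O2  = c(-0.2893,  0.8238),
    O3  = c(-0.0684,  1.085), O4  = c(-0.4195,  1.182),
    O5  = c( 0.0335,  3.367), O6  = c(-0.3339,  0.7774),
    O7  = c(-1.1890,  0.000), O8  = c( 0.1788,  3.135),
    O9  = c(-0.1526,  0.000), O10 = c( 0.1129,  0.2215),
    O11 = c( 0.4833,  0.3890), O12 = c(-1.3260,  0.000),
    OS  = c(-0.1188,  0.6865),
    F   = c( 0.4202,  1.108), Cl  = c( 0.6895,  5.853),
    Br  = c( 0.8456,  8.927), I   = c( 0.8857, 14.020),
    Hal = c(-2.9960,  0.000),
    P   = c( 0.8612,  6.920),
    S1  = c( 0.6482,  7.591), S2  = c(-0.0024,  7.365),
    S3  = c( 0.6237,  6.691),
    Me1 = c(-0.3808,  5.754), Me2 = c(-0.0025,  0.000)
  )
  colnames(m) <- c("logp", "mr")
  m
})

HETERO_SET <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")
METALS_1 <- c("Li", "Na", "K", "Rb", "Cs", "Mg", "Ca", "Sr", "Ba", "Be",
              "Al")  # Me1: alkali/alkaline-earth style
## remaining metals / metalloids fall into Me2

## Assign the Wildman-Crippen class of every heavy atom.  Returns a
## character vector of class labels (one per heavy atom).
crippen_types <- function(mol) {
  env <- atom_env(mol)
  n <- length(env$elem)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- crippen_type_one(env, i)
  }
  out
}

crippen_type_one <- function(env, i) {
  el <- env$elem[i]
  ar <- env$arom[i]
  ch <- env$charge[i]
  nH <- env$nH[i]
  nb <- env$nbr[[i]]
  bo <- env$bord[[i]]
  ba <- env$barom[[i]]
  deg <- env$deg[i]
  nel <- env$elem[nb]
  nar <- env$arom[nb]

  all_single <- all(bo == 1 & !ba) || deg == 0L
  has_double <- any(bo == 2 & !ba)
  has_triple <- any(bo == 3 & !ba)
  X4 <- !ar && all_single && (deg + nH) == 4L

  ## neighbour selectors
  ali_C <- nel == "C" & !nar & bo == 1 & !ba
  aro_nb <- nar & bo == 1 & !ba        # single bond to an aromatic atom
  ali_het <- nel %in% HETERO_SET & !nar & bo == 1 & !ba
  dbl_to <- function(pred) any(bo == 2 & !ba & pred)

  if (el == "C") {
    if (!ar) {
      if (all_single) {
        if (nH == 4L) return("C1")
        if (nH == 3L && deg == 1L && all(ali_C)) return("C1")
        if (nH == 2L && deg == 2L && all(ali_C)) return("C1")
        if (nH == 1L && deg == 3L && all(ali_C)) return("C2")
        if (nH == 0L && deg == 4L && all(ali_C)) return("C2")
        ## hetero-substituted sp3 carbon: remaining substituents must all
        ## be aliphatic, otherwise the aromatic-attachment classes win
        if (nH == 3L && deg == 1L && any(ali_het)) return("C3")
        if (nH == 2L && X4 && any(ali_het) && !any(nar)) return("C3")
        if (nH <= 1L && X4 && any(ali_het) && !any(nar)) return("C4")
        if (nH == 3L && deg == 1L && nel == "C" && nar) return("C8")
        if (nH == 3L && deg == 1L && nar) return("C9")
        if (nH == 2L && X4 && any(nar)) return("C10")
        if (nH == 1L && X4 && any(nar)) return("C11")
        if (nH == 0L && X4 && any(nar)) return("C12")
        if (X4 && any(!nar & !(nel %in% c("C", HETERO_SET)))) return("C27")
        return("CS")
      }
      if (has_triple && (deg + nH) <= 2L) return("C7")
      if (dbl_to(nel != "C" & !nar)) return("C5")
      if (dbl_to(nel == "C" & !nar)) {
        ## C=C: aromatic substituent anywhere promotes to C26
        if (any(nar)) return("C26")
        return("C6")
      }
      if (dbl_to(nel == "C" & nar)) return("C26")   # C=c quinoid
      return("CS")
    }
    ## aromatic carbon
    n_ar_bonds <- sum(ba)
    if (nH == 0L && any(!nar & bo == 1 & !ba &
                        !(nel %in% c("C", HETERO_SET)))) return("C13")
    if (any(nel == "F" & bo == 1 & !ba)) return("C14")
    if (any(nel == "Cl" & bo == 1 & !ba)) return("C15")
    if (any(nel == "Br" & bo == 1 & !ba)) return("C16")
    if (any(nel == "I" & bo == 1 & !ba)) return("C17")
    if (nH == 1L) return("C18")
    if (n_ar_bonds >= 3L) return("C19")
    if (any(aro_nb)) return("C20")
    if (any(nel == "C" & !nar & bo == 1 & !ba)) return("C21")
    if (any(nel == "N" & !nar & bo == 1 & !ba)) return("C22")
    if (any(nel == "O" & !nar & bo == 1 & !ba)) return("C23")
    if (any(nel == "S" & !nar & bo == 1 & !ba)) return("C24")
    if (dbl_to(nel %in% c("C", "N", "O"))) return("C25")
    return("CS")
  }

  if (el == "N") {
    if (ar) {
      if (ch > 0) return("N12")
      if (ch == 0) return("N11")
      return("NS")
    }
    if (ch == 0) {
      if (nH == 2L && deg == 1L && !nar[1] && all_single) return("N1")
      if (nH == 1L && deg == 2L && all_single && !any(nar)) return("N2")
      if (nH == 2L && deg == 1L && nar[1]) return("N3")
      if (nH == 1L && deg == 2L && all_single && any(nar)) return("N4")
      if (nH == 1L && has_double) return("N5")
      if (nH == 0L && has_double && deg == 2L) return("N6")
      if (nH == 0L && deg == 3L && all_single && !any(nar)) return("N7")
      if (nH == 0L && deg == 3L && all_single && any(nar)) return("N8")
      if (has_triple && deg == 1L) return("N9")
      return("NS")
    }
    if (ch > 0) {
      if (nH >= 1L) return("N10")
      if (deg == 4L && all_single) return("N13")
      ## one double bond plus two single bonds: iminium, nitro, N-oxide
      if (deg == 3L && sum(bo == 2 & !ba) == 1L) return("N13")
      ## =C and =N doubles (e.g. keteneimine-style cations)
      if (sum(bo == 2 & !ba) == 2L && dbl_to(nel == "C")) return("N13")
      if (has_double || has_triple) return("N14")
      return("NS")
    }
    ## negative nitrogen
    return("N14")
  }

  if (el == "O") {
    if (ar) return("O1")
    if (ch == 0 && nH >= 1L) return("O2")
    if (ch == 0 && deg == 2L && all_single) {
      if (any(nar)) return("O4")
      return("O3")
    }
    if (ch < 0) {
      other <- nel[1]
      if (!is.na(other) && other == "N") return("O5")
      if (!is.na(other) && other == "S") return("O6")
      ## carboxylate / phosphate style
      if (!is.na(other) && other == "C") {
        cj <- nb[1]
        cb <- env$bord[[cj]]; cba <- env$barom[[cj]]
        cne <- env$elem[env$nbr[[cj]]]
        if (any(cb == 2 & !cba & cne == "O")) return("O12")
      }
      return("O7")
    }
    if (has_double) {
      j <- nb[bo == 2 & !ba][1]
      jel <- env$elem[j]
      if (jel %in% c("N", "O")) return("O5")
      if (jel == "S") return("O6")
      if (jel == "C") {
        if (env$arom[j]) return("O8")
        jnb <- env$nbr[[j]]
        jel2 <- env$elem[jnb]
        jar2 <- env$arom[jnb]
        others <- setdiff(seq_along(jnb), which(jnb == i)[1])
        oel <- jel2[others]; oar <- jar2[others]
        n_het <- sum(!(oel %in% "C"))
        carbonyl_nH <- env$nH[j]
        if (n_het >= 2L) return("O11")
        if (any(oar)) return("O10")
        return("O9")
      }
      return("OS")   # O=P, O=other
    }
    return("OS")
  }

  if (el == "F")  return(if (ch == 0) "F" else "Hal")
  if (el == "Cl") return(if (ch == 0) "Cl" else "Hal")
  if (el == "Br") return(if (ch == 0) "Br" else "Hal")
  if (el == "I")  return(if (ch == 0) "I" else "Hal")
  if (el == "P")  return("P")
  if (el == "S") {
    if (ar) return("S3")
    ## charged S and S doubly bonded to N/O (sulfoxide, sulfone,
    ## sulfonamide) share the S2 class; plain thioether/thiol is S1
    if (ch != 0 || dbl_to(nel %in% c("N", "O"))) return("S2")
    return("S1")
  }
  if (el %in% METALS_1) return("Me1")
  ## anything else heavy: metalloid/transition metal bucket
  "Me2"
}

## Hydrogen class given the heavy atom index carrying the hydrogen(s).
crippen_h_class <- function(env, i) {
  el <- env$elem[i]
  if (el == "C") return("H1")
  if (el == "N") return("H3")
  if (el == "O") {
    nb <- env$nbr[[i]]
    if (length(nb) == 0L) return("H2")   # water
    j <- nb[1]
    jel <- env$elem[j]
    if (jel == "N") return("H3")
    if (jel %in% c("O", "S")) return("H4")
    if (jel == "C") {
      if (env$arom[j]) return("H2")
      jb <- env$bord[[j]]; jba <- env$barom[[j]]
      jne <- env$elem[env$nbr[[j]]]
      if (any(jb == 2 & !jba & jne %in% c("C", "N", "O", "S"))) return("H4")
      return("H2")
    }
    return("H2")   # O-H on P, Si, B, ...
  }
  ## H on S, P, B, metals...
  "H2"
}

## Per-heavy-atom contributions (hydrogens folded into their heavy atom).
crippen_contribs <- function(mol) {
  env <- atom_env(mol)
  types <- crippen_types(mol)
  n <- length(types)
  logp <- numeric(n)
  mr <- numeric(n)
  for (i in seq_len(n)) {
    v <- CRIPPEN_CONTRIB[types[i], ]
    hl <- if (env$nH[i] > 0L) CRIPPEN_CONTRIB[crippen_h_class(env, i), ] else c(0, 0)
    logp[i] <- v[1] + env$nH[i] * hl[1]
    mr[i] <- v[2] + env$nH[i] * hl[2]
  }
  data.frame(type = types, logp = logp, mr = mr)
}

#' Wildman-Crippen atomistic log P (WLOGP)
#'
#' Sum of per-atom contributions from the 68-class atom-contribution
#' system (hydrogen contributions included).  Atoms not covered by any
#' class rule fall into the element's wildcard class and are still summed.
#'
#' @param mol An \code{adm_molecule}.
#' @return log P estimate (log-units).
#' @examples
#' wlogp(adm_molecule("c1ccccc1"))   # benzene: 1.6866
#' @export
wlogp <- function(mol) {
  sum(crippen_contribs(mol)$logp)
}

#' Wildman-Crippen molar refractivity
#'
#' @param mol An \code{adm_molecule}.
#' @return Molar refractivity in the conventional units of the
#'   atom-contribution table.
#' @export
molar_refractivity <- function(mol) {
  sum(crippen_contribs(mol)$mr)
}
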