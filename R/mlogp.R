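## Moriguchi topological log P: a linear regression on 13 structural
## parameters.  The parameter definitions below follow the published
## method; the structural dummies that the original authors assessed by
## inspection (intramolecular hydrogen bond, amphoteric character) are
## detected with documented graph heuristics.

MLOGP_COEF <- c(
  intercept = -1.041,
  CX = 1.244,    # (carbon + halogen weight)^0.6
  NO = -1.017,   # (N + O count)^0.9
  PRX = 0.406,   # N/O proximity
  UB = -0.145,   # (unsaturated bonds)^0.8
  HB = 0.511,    # intramolecular H-bond dummy
  POL = 0.268,   # aromatic polar substituents
  AMP = -2.215,  # amphoteric character
  ALK = 0.912,   # alkane/alkene dummy
  RNG = -0.392,  # non-aromatic ring dummy
  QN = -3.684,   # quaternary N (1) / N-oxide (0.5)
  NO2 = 0.474,   # nitro groups
  NCS = 1.582,   # isothiocyanate (1) / thiocyanate (0.5)
  BLM = 0.773    # beta-lactam dummy
)

HALOGEN_CX <- c(F = 0.5, Cl = 1.0, Br = 1.5, I = 2.0)

mlogp_parameters <- function(mol) {
  env <- atom_env(mol)
  el <- env$elem
  a <- mol$atoms
  b <- mol$bonds

  is_nitro_n <- vapply(seq_along(el), function(i) {
    el[i] == "N" && env$charge[i] > 0 &&
      any(env$bord[[i]] == 2 & env$elem[env$nbr[[i]]] == "O") &&
      any(env$bord[[i]] == 1 & env$elem[env$nbr[[i]]] == "O" &
            env$charge[env$nbr[[i]]] < 0)
  }, TRUE)
  n_no2 <- sum(is_nitro_n)

  cx <- sum(el == "C") + sum(HALOGEN_CX[el[el %in% names(HALOGEN_CX)]])
  ## nitro groups carry their own regression term; their N and two O atoms
  ## are kept out of the generic N/O count
  no <- max(0L, sum(el %in% c("N", "O")) - 3L * n_no2)

  ## proximity: N/O pairs bonded (2) or sharing a neighbour (1)
  polar <- which(el %in% c("N", "O") & !is_nitro_n &
                   !vapply(seq_along(el), function(i) {
                     el[i] == "O" && any(el[env$nbr[[i]]] == "N" &
                                           env$charge[env$nbr[[i]]] > 0)
                   }, TRUE))
  prx <- 0
  if (length(polar) >= 2L) {
    for (ii in seq_len(length(polar) - 1L)) {
      for (jj in (ii + 1L):length(polar)) {
        i <- polar[ii]; j <- polar[jj]
        if (j %in% env$nbr[[i]]) {
          prx <- prx + 2
        } else if (length(intersect(env$nbr[[i]], env$nbr[[j]])) > 0L) {
          prx <- prx + 1
        }
      }
    }
  }

  ## unsaturated bonds (kekulized doubles + triples), nitro N=O excluded
  ub <- 0L
  for (r in seq_len(nrow(b))) {
    o <- b$order[r]
    if (o == 1L) next
    if (o == 2L && (is_nitro_n[b$a1[r]] || is_nitro_n[b$a2[r]])) next
    ub <- ub + 1L
  }

  ## aromatic polar substituents: non-ring N/O attached to aromatic atoms
  inring <- atom_in_ring(mol)
  pol <- sum(vapply(seq_along(el), function(i) {
    el[i] %in% c("N", "O") && !inring[i] && !is_nitro_n[i] &&
      any(env$arom[env$nbr[[i]]])
  }, TRUE))

  ## dummies
  only_ch <- all(el == "C")
  alk <- as.numeric(only_ch && sum(b$order == 2) <= 1L &&
                      all(b$order < 3L) && !any(a$arom))

  rng <- as.numeric(any(vapply(mol$rings, function(r) {
    !(all(a$arom[r]) && all(el[r] == "C"))
  }, TRUE)))

  qn <- 0
  for (i in seq_along(el)) {
    if (el[i] != "N") next
    if (env$deg[i] + env$nH[i] >= 4L && all(env$bord[[i]] == 1)) qn <- max(qn, 1)
    ## N-oxide: N+ bonded to O-
    if (env$charge[i] > 0 &&
        any(el[env$nbr[[i]]] == "O" & env$charge[env$nbr[[i]]] < 0 &
              env$bord[[i]] == 1) && !is_nitro_n[i]) qn <- max(qn, 0.5)
  }

  ## N=C=S (1.0) and S-C#N (0.5)
  ncs <- 0
  for (i in which(el == "C")) {
    nb <- env$nbr[[i]]; bo <- env$bord[[i]]
    if (sum(bo == 2) == 2L) {
      nn <- el[nb[bo == 2]]
      if ("N" %in% nn && "S" %in% nn) ncs <- ncs + 1
    }
    if (any(bo == 3 & el[nb] == "N") && any(bo == 1 & el[nb] == "S")) {
      ncs <- ncs + 0.5
    }
  }

  ## beta-lactam: 4-ring with N and an in-ring C bearing exocyclic C=O
  blm <- 0
  for (ring in mol$rings) {
    if (length(ring) != 4L) next
    if (!any(el[ring] == "N")) next
    has_co <- any(vapply(ring, function(i) {
      el[i] == "C" && any(env$bord[[i]] == 2 & el[env$nbr[[i]]] == "O")
    }, TRUE))
    if (has_co) { blm <- 1; break }
  }

  ## intramolecular H-bond: ortho substituent pair on an aromatic ring,
  ## one donor (O-H/N-H) and one N/O acceptor
  hb <- 0
  for (r in seq_len(nrow(b))) {
    if (!isTRUE(b$arom[r])) next
    i <- b$a1[r]; j <- b$a2[r]
    si <- env$nbr[[i]][!env$arom[env$nbr[[i]]]]
    sj <- env$nbr[[j]][!env$arom[env$nbr[[j]]]]
    don <- function(s) any(el[s] %in% c("N", "O") & a$nH[s] > 0)
    acc <- function(s) {
      any(el[s] %in% c("N", "O")) ||
        any(vapply(s, function(k) {
          any(el[env$nbr[[k]]] %in% c("N", "O") &
                env$bord[[k]] == 2)
        }, TRUE))
    }
    if ((don(si) && length(sj) && acc(sj)) ||
        (don(sj) && length(si) && acc(si))) { hb <- 1; break }
  }

  c(CX = cx, NO = no, PRX = prx, UB = ub, HB = hb, POL = pol,
    AMP = mlogp_amphoteric(mol, env, el, a),
    ALK = alk, RNG = rng, QN = qn, NO2 = n_no2, NCS = ncs, BLM = blm)
}

## amphoteric character: alpha-amino acid (1), aminobenzoic or pyridine
## carboxylic acid (0.5)
mlogp_amphoteric <- function(mol, env, el, a) {
  cooh <- which(vapply(seq_along(el), function(i) {
    el[i] == "C" &&
      any(env$bord[[i]] == 2 & el[env$nbr[[i]]] == "O") &&
      any(env$bord[[i]] == 1 & el[env$nbr[[i]]] == "O" &
            a$nH[env$nbr[[i]]] > 0)
  }, TRUE))
  if (length(cooh) == 0L) return(0)
  amines <- which(el == "N" & a$nH > 0 & !a$arom)
  for (ci in cooh) {
    ## alpha carbon = carbon neighbour of the acid carbon
    alphas <- env$nbr[[ci]][el[env$nbr[[ci]]] == "C"]
    for (al in alphas) {
      if (any(env$nbr[[al]] %in% amines)) return(1)
    }
  }
  ## aromatic variants
  for (ci in cooh) {
    ring_nb <- env$nbr[[ci]][env$arom[env$nbr[[ci]]]]
    if (length(ring_nb) == 0L) next
    ring <- NULL
    for (rg in mol$rings) if (ring_nb[1] %in% rg) { ring <- rg; break }
    if (is.null(ring)) next
    if (any(el[ring] == "N")) return(0.5)                 # pyridine acid
    subst <- unlist(lapply(ring, function(k) env$nbr[[k]]))
    if (any(el[subst] == "N" & a$nH[subst] > 0 & !a$arom[subst])) return(0.5)
  }
  0
}

#' Moriguchi topological log P (MLOGP)
#'
#' Linear regression on 13 topological parameters (weighted carbon and
#' halogen counts, N/O counts, proximity effects, unsaturation, and a set
#' of structural dummies).  This is the lipophilicity descriptor behind
#' the Lipinski filter's 4.15 threshold.
#'
#' @param mol An \code{adm_molecule}.
#' @return log P estimate (log-units).
#' @examples
#' mlogp(adm_molecule("CCCCCCCC"))  # n-octane
#' @export
mlogp <- function(mol) {
  p <- mlogp_parameters(mol)
  unname(
    MLOGP_COEF["intercept"] +
      MLOGP_COEF["CX"] * p["CX"]^0.6 +
      MLOGP_COEF["NO"] * p["NO"]^0.9 +
      MLOGP_COEF["PRX"] * p["PRX"] +
      MLOGP_COEF["UB"] * p["UB"]^0.8 +
      MLOGP_COEF["HB"] * p["HB"] +
      MLOGP_COEF["POL"] * p["POL"] +
      MLOGP_COEF["AMP"] * p["AMP"] +
      MLOGP_COEF["ALK"] * p["ALK"] +
      MLOGP_COEF["RNG"] * p["RNG"] +
      MLOGP_COEF["QN"] * p["QN"] +
      MLOGP_COEF["NO2"] * p["NO2"] +
      MLOGP_COEF["NCS"] * p["NCS"] +
      MLOGP_COEF["BLM"] * p["BLM"]
  )
}
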