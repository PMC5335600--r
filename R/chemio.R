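## chemio: molecule input, standardization, canonicalization, reporting.
##
## Parsing and canonicalization are delegated to Open Babel (ChemmineOB).
## The package keeps its own light molecular-graph container (`adm_molecule`)
## with kekulized bond orders, per-atom hydrogen counts, formal charges and
## aromatic flags, on top of which all descriptor code operates.

## ---------------------------------------------------------------------
## Input list parsing
## ---------------------------------------------------------------------

#' Parse a SMILES input list
#'
#' Interprets multi-line text in the one-molecule-per-line convention: each
#' non-blank line holds a SMILES string, optionally followed by a name
#' separated by a space.  Names are truncated at the first whitespace; when
#' absent, identifiers \code{Molecule_<k>} are assigned in (1-based) line
#' order.
#'
#' @param text Character scalar (possibly multi-line) or character vector of
#'   lines.
#' @return A data.frame with columns \code{smiles} and \code{name}, one row
#'   per non-blank input line.  Parse errors in the SMILES themselves are
#'   not raised here; they surface when the molecule is standardized.
#' @examples
#' parse_smiles_list("CCO ethanol\nc1ccccc1")
#' @export
parse_smiles_list <- function(text) {
  stopifnot(is.character(text))
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(smiles = character(), name = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- seq_along(lines)
  toks <- strsplit(lines, "[[:space:]]+")
  smiles <- vapply(toks, `[[`, "", 1L)
  name <- vapply(seq_along(toks), function(i) {
    if (length(toks[[i]]) >= 2L) toks[[i]][[2L]] else paste0("Molecule_", i)
  }, "")
  data.frame(smiles = smiles, name = name, stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------
## SMILES syntax pre-validation
##
## Open Babel 3 recovers silently from some malformed inputs (e.g. "C(" is
## parsed as methane), so the documented InvalidSmiles contract needs a
## token-level check: balanced parentheses and brackets, paired ring-closure
## digits, no dangling bond, only known atom tokens outside brackets.
## ---------------------------------------------------------------------

validate_smiles_syntax <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    return("empty SMILES")
  }
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  depth <- 0L
  in_bracket <- FALSE
  ring <- integer(0)
  prev_bond <- FALSE
  i <- 1L
  atom_seen <- FALSE
  while (i <= n) {
    ch <- chars[i]
    if (in_bracket) {
      if (ch == "[") return("nested '['")
      if (ch == "]") in_bracket <- FALSE
      i <- i + 1L
      next
    }
    if (ch == "[") {
      in_bracket <- TRUE
      prev_bond <- FALSE
      atom_seen <- TRUE
      i <- i + 1L
      next
    }
    if (ch == "]") return("unmatched ']'")
    if (ch == "(") {
      if (!atom_seen) return("branch before any atom")
      depth <- depth + 1L
      i <- i + 1L
      next
    }
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return("unmatched ')'")
      i <- i + 1L
      next
    }
    if (ch %in% c("-", "=", "#", "$", ":", "/", "\\", "~")) {
      prev_bond <- TRUE
      i <- i + 1L
      next
    }
    if (ch == ".") {
      prev_bond <- FALSE
      i <- i + 1L
      next
    }
    if (grepl("[0-9]", ch)) {
      ring <- c(ring, as.integer(ch))
      prev_bond <- FALSE
      i <- i + 1L
      next
    }
    if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
        return("bad %nn ring closure")
      }
      ring <- c(ring, as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L
      next
    }
    ## atom tokens outside brackets
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      atom_seen <- TRUE
      prev_bond <- FALSE
      i <- i + 2L
      next
    }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                  "b", "c", "n", "o", "p", "s", "*")) {
      atom_seen <- TRUE
      prev_bond <- FALSE
      i <- i + 1L
      next
    }
    return(paste0("unexpected character '", ch, "'"))
  }
  if (in_bracket) return("unmatched '['")
  if (depth != 0L) return("unmatched '('")
  if (prev_bond) return("dangling bond")
  if (!atom_seen) return("no atoms")
  tab <- table(ring)
  if (any(tab %% 2L != 0L)) return("unpaired ring closure")
  NULL
}

## ---------------------------------------------------------------------
## Open Babel bridges
## ---------------------------------------------------------------------

ob_convert <- function(from, to, source, add_h = FALSE) {
  opts <- if (add_h) {
    data.frame(names = "h", args = "")
  } else {
    data.frame(names = character(0), args = character(0))
  }
  ob_quiet(ChemmineOB::convertFormat(from, to, source, options = opts))
}

ob_canonical <- function(smiles_line) {
  out <- ob_convert("SMI", "CAN", paste0(smiles_line, "\n"))
  out <- sub("[\t ].*$", "", trimws(strsplit(out, "\n")[[1]][1] %||% ""))
  out
}

## Tokenize the heavy atoms of a SMILES string, in order of appearance.
## Returns a data.frame with element symbols, aromatic flags and the number
## of tetrahedral stereo marks.  Only needs atom tokens; bonds, branches and
## ring closures are skipped.
smiles_atom_tokens <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  elem <- character(0)
  arom <- logical(0)
  n_stereo <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (grepl("@", body, fixed = TRUE)) n_stereo <- n_stereo + 1L
      sym <- sub("^[0-9]*", "", body)              # isotope prefix
      m <- regmatches(sym, regexpr("^(se|as|[A-Z][a-z]?|[bcnops])", sym))
      if (length(m) == 0L) m <- "*"
      is_arom <- m %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      sym_std <- if (is_arom) {
        paste0(toupper(substr(m, 1, 1)), substring(m, 2))
      } else m
      ## bracket H atom itself (e.g. [H], isotopes): element H
      elem <- c(elem, sym_std)
      arom <- c(arom, is_arom)
      i <- j + 1L
      next
    }
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      elem <- c(elem, two); arom <- c(arom, FALSE); i <- i + 2L; next
    }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      elem <- c(elem, ch); arom <- c(arom, FALSE); i <- i + 1L; next
    }
    if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      elem <- c(elem, toupper(ch)); arom <- c(arom, TRUE); i <- i + 1L; next
    }
    if (ch == "%") { i <- i + 3L; next }
    i <- i + 1L
  }
  list(elem = elem, arom = arom, n_stereo = n_stereo)
}

## Parse a V2000 molblock (the first record of an SDF string).
parse_molblock <- function(sdf_text) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) adm_error("adm_sanitization", "empty SDF record")
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) adm_error("adm_sanitization", "bad counts line")
  atom_lines <- lines[5:(4 + na)]
  elem <- trimws(substr(atom_lines, 32, 34))
  charge <- integer(na)
  if (nb > 0) {
    bond_lines <- lines[(5 + na):(4 + na + nb)]
    b1 <- as.integer(substr(bond_lines, 1, 3))
    b2 <- as.integer(substr(bond_lines, 4, 6))
    bo <- as.integer(substr(bond_lines, 7, 9))
  } else {
    b1 <- b2 <- bo <- integer(0)
  }
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substring(l, 7)), "[[:space:]]+")[[1]])
    k <- f[1]
    for (p in seq_len(k)) charge[f[2 * p]] <- f[2 * p + 1]
  }
  list(elem = elem, charge = charge,
       bonds = data.frame(a1 = b1, a2 = b2, order = bo))
}

## Serialize the heavy-atom graph back to a V2000 molblock (no coordinates,
## kekulized orders, formal charges as M CHG).  Open Babel re-derives
## implicit hydrogens and aromaticity from this when canonicalizing.
write_molblock <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  hdr <- c(mol$name %||% "", "  admetk", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   nrow(a), nrow(b)))
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, a$elem)
  bond_lines <- if (nrow(b)) {
    sprintf("%3d%3d%3d  0  0  0  0", b$a1, b$a2, b$order)
  } else character(0)
  chg <- which(a$charge != 0)
  chg_lines <- if (length(chg)) {
    vapply(chg, function(i) sprintf("M  CHG  1 %3d %3d", i, a$charge[i]), "")
  } else character(0)
  paste(c(hdr, atom_lines, bond_lines, chg_lines, "M  END", "$$$$", ""),
        collapse = "\n")
}

## ---------------------------------------------------------------------
## Standardization
## ---------------------------------------------------------------------

#' Standardize a molecule from SMILES
#'
#' Builds the package's working representation of a molecule: the SMILES is
#' syntax-checked, canonicalized and kekulized via Open Babel, hydrogens are
#' made explicit and counted per heavy atom, the largest covalent fragment
#' is kept (salt stripping), and simple protonation states are neutralized
#' (carboxylate-type \code{O-} gains a hydrogen, protonated amines lose
#' one).  The net formal charge of the as-input structure is recorded
#' before neutralization; charge-dependent scores (the bioavailability
#' score) use that value.
#'
#' @param smiles SMILES string (one molecule).
#' @param name Molecule identifier; defaults to \code{"Molecule_1"}.
#' @param strip_salts Keep only the largest covalent fragment
#'   (default TRUE).
#' @param neutralize Neutralize simple protonation-state charges
#'   (default TRUE).  Permanently charged centres (quaternary nitrogen,
#'   nitro/N-oxide oxygens) are left untouched.
#' @return An object of class \code{adm_molecule}: a list with the atom
#'   table (element, formal charge, aromatic flag, hydrogen count), the
#'   kekulized bond table, ring information, the canonical SMILES of the
#'   standardized form, and bookkeeping flags.
#' @examples
#' m <- adm_molecule("CC(=O)[O-]", "acetate")
#' m$input_net_charge   # -1, recorded before neutralization
#' m$net_charge         # 0 after neutralization
#' @export
adm_molecule <- function(smiles, name = "Molecule_1",
                         strip_salts = TRUE, neutralize = TRUE) {
  err <- validate_smiles_syntax(smiles)
  if (!is.null(err)) {
    adm_error("adm_invalid_smiles",
              paste0("invalid SMILES '", smiles, "': ", err))
  }
  can <- ob_canonical(smiles)
  if (!nzchar(can)) {
    adm_error("adm_invalid_smiles",
              paste0("Open Babel could not parse SMILES '", smiles, "'"))
  }
  sdf <- ob_convert("SMI", "SDF", paste0(can, "\n"), add_h = TRUE)
  mb <- parse_molblock(sdf)
  tok <- smiles_atom_tokens(can)

  heavy <- which(mb$elem != "H")
  if (length(heavy) == 0L) {
    adm_error("adm_sanitization", "molecule has no heavy atoms")
  }
  ## aromatic flags come from the canonical SMILES token sequence; assert
  ## the atom order assumption (Open Babel keeps SMILES order in SDF)
  tok_heavy <- which(tok$elem != "H")
  if (!identical(mb$elem[heavy], tok$elem[tok_heavy])) {
    adm_error("adm_sanitization",
              "atom order mismatch between canonical SMILES and SDF")
  }
  arom <- tok$arom[tok_heavy]

  ## hydrogen counts per heavy atom, heavy-heavy bond table
  idx_map <- integer(length(mb$elem))
  idx_map[heavy] <- seq_along(heavy)
  is_h <- mb$elem == "H"
  nH <- integer(length(heavy))
  keep_bond <- !(is_h[mb$bonds$a1] | is_h[mb$bonds$a2])
  hb <- mb$bonds[!keep_bond, , drop = FALSE]
  for (r in seq_len(nrow(hb))) {
    a1 <- hb$a1[r]; a2 <- hb$a2[r]
    hv <- if (is_h[a1]) a2 else a1
    if (!is_h[hv]) nH[idx_map[hv]] <- nH[idx_map[hv]] + 1L
  }
  bonds <- mb$bonds[keep_bond, , drop = FALSE]
  bonds$a1 <- idx_map[bonds$a1]
  bonds$a2 <- idx_map[bonds$a2]

  atoms <- data.frame(
    elem = mb$elem[heavy],
    charge = mb$charge[heavy],
    arom = arom,
    nH = nH,
    stringsAsFactors = FALSE
  )

  flags <- character(0)

  ## fragment handling
  comp <- graph_components(nrow(atoms), bonds)
  n_frag <- max(comp)
  if (strip_salts && n_frag > 1L) {
    sizes <- tabulate(comp)
    keep_c <- which.max(sizes)           # ties: lowest index
    keep_atoms <- which(comp == keep_c)
    remap <- integer(nrow(atoms))
    remap[keep_atoms] <- seq_along(keep_atoms)
    atoms <- atoms[keep_atoms, , drop = FALSE]
    rownames(atoms) <- NULL
    bonds <- bonds[bonds$a1 %in% keep_atoms, , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]
    bonds$a2 <- remap[bonds$a2]
    flags <- c(flags, sprintf("stripped %d counter-fragment(s)", n_frag - 1L))
  }

  input_net_charge <- sum(atoms$charge)

  ## neutralization of simple protonation states
  if (neutralize) {
    nbr <- adjacency_list(nrow(atoms), bonds)
    changed <- FALSE
    for (i in seq_len(nrow(atoms))) {
      ch <- atoms$charge[i]
      el <- atoms$elem[i]
      if (ch == -1 && el %in% c("O", "S")) {
        pos_nbr <- any(atoms$charge[nbr[[i]]] > 0)
        if (!pos_nbr) {
          atoms$charge[i] <- 0L
          atoms$nH[i] <- atoms$nH[i] + 1L
          changed <- TRUE
        }
      } else if (ch == 1 && el == "N" && atoms$nH[i] >= 1L) {
        atoms$charge[i] <- 0L
        atoms$nH[i] <- atoms$nH[i] - 1L
        changed <- TRUE
      }
    }
    if (changed) flags <- c(flags, "neutralized")
  }

  mol <- list(
    name = name,
    input_smiles = smiles,
    atoms = atoms,
    bonds = bonds,
    input_net_charge = input_net_charge,
    net_charge = sum(atoms$charge),
    n_stereo = tok$n_stereo,
    flags = flags
  )
  class(mol) <- "adm_molecule"

  mol$rings <- ring_info(mol)
  mol$bonds$ring <- bond_in_ring(mol)
  mol$bonds$arom <- atoms$arom[mol$bonds$a1] & atoms$arom[mol$bonds$a2] &
    mol$bonds$ring
  mol$smiles <- if (length(flags) == 0L) {
    can
  } else {
    out <- ob_convert("SDF", "CAN", write_molblock(mol))
    sub("[\t ].*$", "", trimws(strsplit(out, "\n")[[1]][1] %||% ""))
  }
  mol
}

#' Canonical SMILES of a standardized molecule
#'
#' @param mol An \code{adm_molecule}.
#' @return Character scalar; deterministic for a given structure, identical
#'   for any input SMILES of the same molecule.
#' @export
canonical_smiles <- function(mol) {
  stopifnot(inherits(mol, "adm_molecule"))
  mol$smiles
}

#' @export
print.adm_molecule <- function(x, ...) {
  cat(sprintf("<adm_molecule> %s\n  SMILES: %s\n  %d heavy atoms, %d bonds, net charge %+d (input %+d)\n",
              x$name, x$smiles, nrow(x$atoms), nrow(x$bonds),
              x$net_charge, x$input_net_charge))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Molecular formula of a standardized molecule
#' @param mol An \code{adm_molecule}.
#' @return Hill-notation formula string (C first, H second, rest
#'   alphabetical).
#' @export
molecular_formula <- function(mol) {
  counts <- table(mol$atoms$elem)
  nh <- sum(mol$atoms$nH)
  els <- names(counts)
  rest <- sort(setdiff(els, c("C", "H")))
  out <- ""
  fmt <- function(el, n) if (n == 0) "" else if (n == 1) el else paste0(el, n)
  if ("C" %in% els) out <- paste0(out, fmt("C", counts[["C"]]))
  if (nh > 0) out <- paste0(out, fmt("H", nh))
  for (el in rest) out <- paste0(out, fmt(el, counts[[el]]))
  out
}

## ---------------------------------------------------------------------
## Graph helpers shared across modules
## ---------------------------------------------------------------------

adjacency_list <- function(n, bonds) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    a1 <- bonds$a1[r]; a2 <- bonds$a2[r]
    adj[[a1]] <- c(adj[[a1]], a2)
    adj[[a2]] <- c(adj[[a2]], a1)
  }
  adj
}

graph_components <- function(n, bonds) {
  adj <- adjacency_list(n, bonds)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

## Convert to an SDFset (single molecule) for ChemmineR-level operations
## (SMARTS matching, Open Babel property cross-checks).
as_sdfset <- function(mol) {
  txt <- strsplit(write_molblock(mol), "\n", fixed = TRUE)[[1]]
  ob_quiet(methods::as(ChemmineR::read.SDFstr(txt), "SDFset"))
}
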