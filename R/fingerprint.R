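## Hashed linear-path fingerprint (1024 bits).
##
## All simple linear paths of 1..7 bonds over heavy atoms are enumerated;
## each path is canonicalized as the lexicographically smaller of its two
## directional encodings of (atomic number, formal charge, bond order)
## tuples, then hashed with 32-bit FNV-1a modulo 1024.  Hydrogens are not
## part of the paths.  The same dialect is shared by the fingerprint
## builder and the synthetic-accessibility scorer (a dialect identifier is
## stored with frequency tables).

FP_DIALECT <- "pathfp-fnv1a-1024-v1"
FP_NBITS <- 1024L
FP_MAXLEN <- 7L

## Encode a path (vector of atom indices) as an integer sequence:
## z1, q1, b12, z2, q2, b23, ..., zn, qn  with q shifted by +8.
encode_path <- function(env, path, bond_order_lookup) {
  k <- length(path)
  out <- integer(3L * k - 1L)
  pos <- 1L
  for (t in seq_len(k)) {
    i <- path[t]
    out[pos] <- atomic_number(env$elem[i]); pos <- pos + 1L
    out[pos] <- env$charge[i] + 8L; pos <- pos + 1L
    if (t < k) {
      out[pos] <- bond_order_lookup[[paste(min(path[t], path[t + 1L]),
                                           max(path[t], path[t + 1L]))]]
      pos <- pos + 1L
    }
  }
  out
}

## lexicographically smaller of the two directional encodings
canonical_path_code <- function(code_fwd, code_rev) {
  for (t in seq_along(code_fwd)) {
    if (code_fwd[t] < code_rev[t]) return(code_fwd)
    if (code_fwd[t] > code_rev[t]) return(code_rev)
  }
  code_fwd
}

## Enumerate canonical path codes (as keys) of 1..max_len bonds.
fp_path_codes <- function(mol, max_len = FP_MAXLEN) {
  env <- atom_env(mol)
  n <- length(env$elem)
  b <- mol$bonds
  lookup <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(b))) {
    o <- if (isTRUE(b$arom[r])) 4L else b$order[r]
    assign(paste(min(b$a1[r], b$a2[r]), max(b$a1[r], b$a2[r])), o,
           envir = lookup)
  }
  bol <- as.list(lookup)
  keys <- character(0)
  path <- integer(max_len + 1L)
  visited <- logical(n)
  emit <- function(len) {
    p <- path[seq_len(len)]
    code <- canonical_path_code(encode_path(env, p, bol),
                                encode_path(env, rev(p), bol))
    keys[[length(keys) + 1L]] <<- paste(code, collapse = ",")
  }
  dfs <- function(v, depth) {
    path[depth] <<- v
    visited[v] <<- TRUE
    if (depth >= 2L) emit(depth)
    if (depth <= max_len) {
      for (w in env$nbr[[v]]) {
        if (!visited[w]) dfs(w, depth + 1L)
      }
    }
    visited[v] <<- FALSE
  }
  for (s in seq_len(n)) dfs(s, 1L)
  unique(keys)
}

#' Linear-path fingerprint
#'
#' @param mol An \code{adm_molecule}.
#' @param nbits Fingerprint length (default 1024).
#' @param max_len Maximum path length in bonds (default 7).
#' @return An object of class \code{adm_fingerprint}: list with
#'   \code{bits} (logical vector of length \code{nbits}), \code{n_paths}
#'   (distinct canonical paths) and the dialect identifier.
#' @examples
#' fp <- path_fingerprint(adm_molecule("CC"))
#' sum(fp$bits)   # ethane: a single C-C path, one bit
#' @export
path_fingerprint <- function(mol, nbits = FP_NBITS, max_len = FP_MAXLEN) {
  keys <- fp_path_codes(mol, max_len)
  bits <- logical(nbits)
  for (k in keys) {
    ints <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
    bits[(fnv1a32(ints) %% nbits) + 1L] <- TRUE
  }
  structure(list(bits = bits, n_paths = length(keys),
                 nbits = nbits, max_len = max_len, dialect = FP_DIALECT),
            class = "adm_fingerprint")
}

#' @export
print.adm_fingerprint <- function(x, ...) {
  cat(sprintf("<adm_fingerprint> %s: %d/%d bits set (%d paths)\n",
              x$dialect, sum(x$bits), x$nbits, x$n_paths))
  invisible(x)
}

#' Tanimoto dissimilarity between two fingerprints
#'
#' @param a,b \code{adm_fingerprint} objects or logical vectors.
#' @return 1 - Tanimoto similarity; 0 for identical non-empty bit sets.
#'   Two empty fingerprints have dissimilarity 0 by convention.
#' @export
tanimoto_dissimilarity <- function(a, b) {
  av <- if (inherits(a, "adm_fingerprint")) a$bits else as.logical(a)
  bv <- if (inherits(b, "adm_fingerprint")) b$bits else as.logical(b)
  stopifnot(length(av) == length(bv))
  un <- sum(av | bv)
  if (un == 0L) return(0)
  1 - sum(av & bv) / un
}
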