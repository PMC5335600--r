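## Per-atom environment snapshot shared by the fragmental descriptor
## systems (TPSA, Wildman-Crippen typing).  Precomputes, for every heavy
## atom: neighbour indices, bond orders and aromatic bond flags, hydrogen
## count, and 3-ring membership.

atom_env <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  n <- nrow(a)
  nbr <- vector("list", n)
  bord <- vector("list", n)
  barom <- vector("list", n)
  for (r in seq_len(nrow(b))) {
    i <- b$a1[r]; j <- b$a2[r]
    o <- b$order[r]; ar <- isTRUE(b$arom[r])
    nbr[[i]] <- c(nbr[[i]], j); bord[[i]] <- c(bord[[i]], o)
    barom[[i]] <- c(barom[[i]], ar)
    nbr[[j]] <- c(nbr[[j]], i); bord[[j]] <- c(bord[[j]], o)
    barom[[j]] <- c(barom[[j]], ar)
  }
  for (i in seq_len(n)) {
    if (is.null(nbr[[i]])) {
      nbr[[i]] <- integer(0)
      bord[[i]] <- integer(0)
      barom[[i]] <- logical(0)
    }
  }
  in3 <- logical(n)
  for (ring in mol$rings) if (length(ring) == 3L) in3[ring] <- TRUE
  list(
    elem = a$elem, arom = a$arom, charge = a$charge, nH = a$nH,
    deg = vapply(nbr, length, 1L),
    nbr = nbr, bord = bord, barom = barom, in3ring = in3
  )
}

## Bond-order counts around one atom, with aromatic bonds tallied
## separately from their kekulized order.
bond_counts <- function(env, i) {
  ar <- env$barom[[i]]
  o <- env$bord[[i]]
  c(single = sum(o == 1 & !ar),
    double = sum(o == 2 & !ar),
    triple = sum(o == 3 & !ar),
    aromatic = sum(ar))
}
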