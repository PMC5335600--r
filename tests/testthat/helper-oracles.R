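## Independent oracles, deliberately implemented differently from the
## package code paths they check.

## Exhaustive path enumerator: breadth-first frontier expansion (the
## package uses depth-first recursion).  Returns the sorted unique set of
## canonical path keys in the same "z,q,b,..." encoding.
brute_force_paths <- function(mol, max_len = 7L) {
  env <- admetk:::atom_env(mol)
  b <- mol$bonds
  bkey <- function(i, j) paste(min(i, j), max(i, j))
  bord <- list()
  for (r in seq_len(nrow(b))) {
    o <- if (isTRUE(b$arom[r])) 4L else b$order[r]
    bord[[bkey(b$a1[r], b$a2[r])]] <- o
  }
  enc <- function(p) {
    parts <- character(0)
    for (t in seq_along(p)) {
      parts <- c(parts, admetk:::atomic_number(env$elem[p[t]]),
                 env$charge[p[t]] + 8L)
      if (t < length(p)) parts <- c(parts, bord[[bkey(p[t], p[t + 1])]])
    }
    paste(parts, collapse = ",")
  }
  canon <- function(p) brute_canon_numeric(enc(p), enc(rev(p)))
  ## frontier expansion
  frontier <- lapply(seq_along(env$elem), identity)
  keys <- character(0)
  for (len in seq_len(max_len)) {
    nxt <- list()
    for (p in frontier) {
      last <- p[length(p)]
      for (w in env$nbr[[last]]) {
        if (!(w %in% p)) nxt[[length(nxt) + 1L]] <- c(p, w)
      }
    }
    keys <- c(keys, vapply(nxt, canon, ""))
    frontier <- nxt
  }
  sort(unique(keys))
}

## string "min" is wrong for multi-digit comparison; do a numeric
## lexicographic canonicalization instead
brute_canon_numeric <- function(fwd, rev_) {
  a <- as.integer(strsplit(fwd, ",")[[1]])
  b <- as.integer(strsplit(rev_, ",")[[1]])
  for (t in seq_along(a)) {
    if (a[t] < b[t]) return(fwd)
    if (a[t] > b[t]) return(rev_)
  }
  fwd
}

## Pairwise-concordance AUC: count over all positive/negative pairs.
auc_bruteforce <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

## Point-in-ellipse by explicit rotation-matrix quadratic form.
in_ellipse_bruteforce <- function(x, y, ell) {
  R <- matrix(c(cos(ell$angle), -sin(ell$angle),
                sin(ell$angle), cos(ell$angle)), 2, 2, byrow = TRUE)
  ## transform the point into the ellipse frame: R^T (p - c)
  v <- t(R) %*% c(x - ell$cx, y - ell$cy)
  q <- (v[1] / ell$a)^2 + (v[2] / ell$b)^2
  q <= 1
}

## Direct re-application of the three descriptor-rejection rules.
filter_bruteforce <- function(x, y, min_nonzero = 0.2, min_cv = 0.03,
                              max_cor = 0.9) {
  x <- as.matrix(x)
  p <- ncol(x)
  ok <- logical(p)
  for (j in seq_len(p)) {
    col <- x[, j]
    frac <- sum(col != 0) / length(col)
    m <- mean(col); s <- sd(col)
    cv <- if (m == 0) { if (s > 0) Inf else 0 } else s / abs(m)
    ok[j] <- frac >= min_nonzero && cv >= min_cv
  }
  keep <- which(ok)
  if (length(keep) < 2) return(keep)
  fs <- admetk::f_score(x[, keep, drop = FALSE], y)
  repeat {
    cm <- suppressWarnings(cor(x[, keep, drop = FALSE]))
    cm[is.na(cm)] <- 0
    diag(cm) <- 0
    viol <- which(abs(cm) > max_cor, arr.ind = TRUE)
    if (nrow(viol) == 0) break
    ## drop the lower-F member of the first violating pair
    i <- viol[1, 1]; j <- viol[1, 2]
    drop <- if (fs[i] < fs[j]) i else j
    keep <- keep[-drop]
    fs <- fs[-drop]
  }
  sort(keep)
}

## Brute-force cluster centre: argmin of summed dissimilarities.
centre_bruteforce <- function(dmat, members) {
  sums <- sapply(members, function(i) sum(dmat[i, members]))
  members[which.min(sums)]
}
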