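## Ring perception: a minimum cycle basis in the Horton style (shortest
## cycle through every edge, then greedy GF(2)-independent selection up to
## the cyclomatic number).  Molecular graphs are small, so the quadratic
## bookkeeping is irrelevant.

## BFS shortest path between two atoms avoiding one forbidden edge.
shortest_path_avoiding <- function(adj, from, to, avoid_a, avoid_b) {
  n <- length(adj)
  prev <- integer(n)
  seen <- logical(n)
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    if (v == to) break
    for (w in adj[[v]]) {
      if ((v == avoid_a && w == avoid_b) || (v == avoid_b && w == avoid_a)) next
      if (!seen[w]) {
        seen[w] <- TRUE
        prev[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  if (!seen[to]) return(NULL)
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  path
}

## Returns a list of rings, each an integer vector of atom indices in ring
## order.  The set is a minimum cycle basis (size = cyclomatic number).
ring_info <- function(mol) {
  bonds <- mol$bonds
  n <- nrow(mol$atoms)
  m <- nrow(bonds)
  if (m == 0L) return(list())
  comp <- graph_components(n, bonds)
  n_cycles <- m - n + max(comp)
  if (n_cycles <= 0L) return(list())
  adj <- adjacency_list(n, bonds)

  edge_id <- function(a, b) paste0(pmin(a, b), "-", pmax(a, b))
  all_edges <- edge_id(bonds$a1, bonds$a2)

  ## candidate cycles: shortest cycle through each edge
  cands <- list()
  seen_keys <- character(0)
  for (r in seq_len(m)) {
    a <- bonds$a1[r]; b <- bonds$a2[r]
    p <- shortest_path_avoiding(adj, a, b, a, b)
    if (is.null(p)) next
    key <- paste(sort(p), collapse = ",")
    if (key %in% seen_keys) next
    seen_keys <- c(seen_keys, key)
    cands[[length(cands) + 1L]] <- p
  }
  if (length(cands) == 0L) return(list())
  cands <- cands[order(vapply(cands, length, 1L))]

  ## greedy GF(2)-independent selection on edge incidence vectors
  to_vec <- function(ring) {
    k <- length(ring)
    eids <- edge_id(ring, ring[c(2:k, 1)])
    as.integer(all_edges %in% eids)
  }
  basis <- list()
  sel <- list()
  for (cand in cands) {
    if (length(sel) >= n_cycles) break
    v <- to_vec(cand)
    w <- v
    for (bv in basis) {
      pivot <- which(bv == 1L)[1]
      if (w[pivot] == 1L) w <- (w + bv) %% 2L
    }
    if (any(w == 1L)) {
      basis[[length(basis) + 1L]] <- w
      sel[[length(sel) + 1L]] <- cand
    }
  }
  sel
}

## Logical vector over bonds: part of any ring (equivalently: not a bridge).
bond_in_ring <- function(mol) {
  bonds <- mol$bonds
  m <- nrow(bonds)
  if (m == 0L) return(logical(0))
  ring_edges <- character(0)
  for (ring in mol$rings) {
    k <- length(ring)
    ring_edges <- c(ring_edges,
                    paste0(pmin(ring, ring[c(2:k, 1)]), "-",
                           pmax(ring, ring[c(2:k, 1)])))
  }
  ## the cycle basis spans all cycles, but an individual basis ring list can
  ## miss chord edges; add any edge whose removal leaves endpoints connected
  ids <- paste0(pmin(bonds$a1, bonds$a2), "-", pmax(bonds$a1, bonds$a2))
  inring <- ids %in% ring_edges
  if (!all(inring)) {
    adj <- adjacency_list(nrow(mol$atoms), bonds)
    for (r in which(!inring)) {
      p <- shortest_path_avoiding(adj, bonds$a1[r], bonds$a2[r],
                                  bonds$a1[r], bonds$a2[r])
      if (!is.null(p)) inring[r] <- TRUE
    }
  }
  inring
}

atom_in_ring <- function(mol) {
  inring <- logical(nrow(mol$atoms))
  for (ring in mol$rings) inring[ring] <- TRUE
  ## atoms on chord edges flagged through ring bonds
  rb <- mol$bonds[mol$bonds$ring, , drop = FALSE]
  inring[unique(c(rb$a1, rb$a2))] <- TRUE
  inring
}

## Ring-complexity counts used by the synthetic-accessibility penalties.
## Spiro atom: shared by two basis rings having exactly that atom in common.
## Bridgehead atoms: endpoints of a shared path of length >= 2 (rings
## sharing two or more bonds).  Macrocycle: basis ring with more than
## `macro_limit` members.
ring_complexity <- function(mol, macro_limit = 8L) {
  rings <- mol$rings
  spiro <- integer(0)
  bridge <- integer(0)
  if (length(rings) >= 2L) {
    for (i in seq_len(length(rings) - 1L)) {
      for (j in (i + 1L):length(rings)) {
        shared <- intersect(rings[[i]], rings[[j]])
        if (length(shared) == 1L) {
          spiro <- c(spiro, shared)
        } else if (length(shared) >= 3L) {
          ## endpoints of the shared path: shared atoms with exactly one
          ## neighbour inside the shared set
          adj <- adjacency_list(nrow(mol$atoms), mol$bonds)
          ends <- shared[vapply(shared, function(a) {
            sum(adj[[a]] %in% shared) == 1L
          }, TRUE)]
          bridge <- c(bridge, ends)
        }
      }
    }
  }
  list(
    n_spiro = length(unique(spiro)),
    n_bridgehead = length(unique(bridge)),
    n_macrocycle = sum(vapply(rings, length, 1L) > macro_limit),
    ring_sizes = vapply(rings, length, 1L)
  )
}
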