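# Hannenhalli-Pevzner reversal distance for signed circular permutations.
#
# A circular genome of n signed blocks is linearized by fixing the
# smallest block forward (canonical form); the reversal distance of the
# circle then equals the linear HP distance of the remaining n-1 blocks,
# which is computed from the breakpoint graph as
#     d = m + 1 - c + h + f
# with m = n - 1 elements, c = number of alternating cycles, h = number
# of hurdles (unoriented components that are minimal under span
# containment, plus the greatest one when it contains all the others)
# and f = 1 for a fortress (an odd number of hurdles, all of them
# superhurdles).

# Exact HP distance of a LINEAR signed permutation pi (signed arrangement
# of 1..m) to the positive identity.
hp_linear_distance <- function(pi) {
  m <- length(pi)
  if (m == 0L) return(0L)
  pi <- as.integer(pi)

  # Doubled (unsigned) representation framed by 0 and 2m+1: element +x
  # contributes (2x-1, 2x), element -x contributes (2x, 2x-1).
  s <- integer(2L * m + 2L)
  s[1L] <- 0L
  for (t in seq_len(m)) {
    x <- pi[t]
    if (x > 0L) {
      s[2L * t] <- 2L * x - 1L
      s[2L * t + 1L] <- 2L * x
    } else {
      s[2L * t] <- -2L * x
      s[2L * t + 1L] <- -2L * x - 1L
    }
  }
  s[2L * m + 2L] <- 2L * m + 1L

  pos <- integer(2L * m + 2L)      # pos[v + 1] = 0-based position of value v
  pos[s + 1L] <- 0:(2L * m + 1L)

  # Alternating cycles: each value has one gray edge (v <-> v xor 1 in
  # value space) and one black edge (position p <-> p xor 1).
  cyc <- integer(2L * m + 2L)      # cycle id per value (index value + 1)
  n_cycles <- 0L
  for (v0 in 0:(2L * m + 1L)) {
    if (cyc[v0 + 1L] != 0L) next
    n_cycles <- n_cycles + 1L
    v <- v0
    repeat {
      cyc[v + 1L] <- n_cycles
      g <- if (v %% 2L == 0L) v + 1L else v - 1L   # gray partner
      cyc[g + 1L] <- n_cycles
      pg <- pos[g + 1L]
      pb <- if (pg %% 2L == 0L) pg + 1L else pg - 1L  # black partner position
      v <- s[pb + 1L]
      if (v == v0) break
    }
  }

  # Gray edges j = 0..m join values 2j and 2j+1.
  gl <- pmin(pos[2L * (0:m) + 1L], pos[2L * (0:m) + 2L])
  gr <- pmax(pos[2L * (0:m) + 1L], pos[2L * (0:m) + 2L])
  goriented <- (pos[2L * (0:m) + 1L] %% 2L) == (pos[2L * (0:m) + 2L] %% 2L)
  gcyc <- cyc[2L * (0:m) + 1L]

  # Trivial cycles (adjacencies) have a single gray edge and no effect on
  # components.
  edge_per_cycle <- tabulate(gcyc, nbins = n_cycles)
  nontrivial <- which(edge_per_cycle[gcyc] > 1L)

  h <- 0L
  f <- 0L
  if (length(nontrivial)) {
    # Union cycles whose gray edges interleave.
    parent <- seq_len(n_cycles)
    find <- function(a) {
      while (parent[a] != a) a <- parent[a]
      a
    }
    idx <- nontrivial
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1L)) {
        e <- idx[a]; e2 <- idx[b]
        if ((gl[e] < gl[e2] && gl[e2] < gr[e] && gr[e] < gr[e2]) ||
            (gl[e2] < gl[e] && gl[e] < gr[e2] && gr[e2] < gr[e])) {
          ra <- find(gcyc[e]); rb <- find(gcyc[e2])
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    comp_of_edge <- vapply(gcyc[idx], find, integer(1))
    comps <- unique(comp_of_edge)
    span_l <- vapply(comps, function(cp) min(gl[idx[comp_of_edge == cp]]), integer(1))
    span_r <- vapply(comps, function(cp) max(gr[idx[comp_of_edge == cp]]), integer(1))
    oriented <- vapply(comps, function(cp) any(goriented[idx[comp_of_edge == cp]]), logical(1))

    un <- which(!oriented)
    if (length(un)) {
      U <- cbind(span_l[un], span_r[un])
      hs <- hurdle_set(U)
      h <- length(hs)
      if (h %% 2L == 1L) {
        # A superhurdle's removal would promote some non-hurdle unoriented
        # component into a hurdle; a fortress has an odd number of
        # hurdles, all of them superhurdles.
        is_h <- logical(nrow(U))
        is_h[hs] <- TRUE
        super <- vapply(hs, function(hi) {
          rest <- setdiff(seq_len(nrow(U)), hi)
          if (!length(rest)) return(FALSE)
          hs2 <- rest[hurdle_set(U[rest, , drop = FALSE])]
          any(!is_h[hs2])
        }, logical(1))
        f <- if (all(super)) 1L else 0L
      }
    }
  }
  m + 1L - n_cycles + h + f
}

# Hurdles among unoriented components given their spans (matrix cols l, r;
# spans are pairwise nested or disjoint): the minimal ones plus the
# greatest one when it contains all others.
hurdle_set <- function(U) {
  k <- nrow(U)
  if (k == 0L) return(integer(0))
  contains <- function(a, b) U[a, 1L] < U[b, 1L] && U[b, 2L] < U[a, 2L]
  minimal <- vapply(seq_len(k), function(i) {
    !any(vapply(seq_len(k)[-i], function(j) contains(i, j), logical(1)))
  }, logical(1))
  hs <- which(minimal)
  if (k > 1L) {
    greatest <- which(vapply(seq_len(k), function(i) {
      all(vapply(seq_len(k)[-i], function(j) contains(i, j), logical(1)))
    }, logical(1)))
    hs <- sort(union(hs, greatest))
  }
  hs
}

# Distance of an scperm to the (circular) identity on its own block set.
distance_to_identity <- function(p) {
  v <- as.integer(canonicalize(p))
  # canonical form starts with the smallest block, positive; rank-map the
  # rest to a linear signed permutation of 1..n-1
  ranks <- rank(abs(v))
  lin <- sign(v[-1L]) * (ranks[-1L] - 1L)
  hp_linear_distance(as.integer(lin))
}

#' Reversal distance between signed circular permutations
#'
#' Exact minimal number of inversions transforming `p` into `q`, under
#' the unichromosomal circular reversal model, computed in polynomial
#' time from the breakpoint graph (cycles, hurdles, fortress).
#'
#' @param p,q [scperm] objects over the same block set.
#' @return Integer distance.
#' @examples
#' p <- scperm(1:5)
#' reversal_distance(p, apply_inversion(p, 1, 3))  # 1
#' @seealso [bfs_distance_oracle()] for an exhaustive-search cross-check
#'   at small n, [sort_by_reversals()] for an explicit optimal scenario.
#' @export
reversal_distance <- function(p, q) {
  distance_to_identity(relabel_to_identity(p, q))
}

# Cache of exhaustive breadth-first distance tables, one per block count.
.oracle_cache <- new.env(parent = emptyenv())

#' Exhaustive BFS oracle for the reversal distance
#'
#' Breadth-first search over all canonical signed circular permutations,
#' independent of the breakpoint-graph machinery; used as the arbiter for
#' Hannenhalli-Pevzner corner cases (hurdles, fortresses). The full
#' distance-to-identity table for each block count is computed once and
#' cached; `d(p, q)` is then a table lookup after relabelling `q` to the
#' identity.
#'
#' @param p,q [scperm] objects over the same block set.
#' @param max_n guard on the state space (`(n-1)! * 2^(n-1)` states).
#' @return Integer distance.
#' @export
bfs_distance_oracle <- function(p, q, max_n = 7) {
  n <- length(p)
  if (n > max_n)
    stop("BFS oracle limited to n <= ", max_n, " blocks (state-space guard)")
  r <- canonicalize(relabel_to_identity(p, q))
  tab <- oracle_table(n)
  d <- tab[[perm_key(r)]]
  if (is.null(d)) stop("internal error: state missing from BFS table")
  d
}

perm_key <- function(p) paste(as.integer(p), collapse = " ")

oracle_table <- function(n) {
  ck <- as.character(n)
  tab <- .oracle_cache[[ck]]
  if (!is.null(tab)) return(tab)
  tab <- new.env(parent = emptyenv(), hash = TRUE)
  invs <- all_inversions(n)
  id <- scperm(seq_len(n))
  tab[[perm_key(id)]] <- 0L
  frontier <- list(id)
  d <- 0L
  while (length(frontier)) {
    nxt <- list()
    for (p in frontier) {
      for (r in seq_len(nrow(invs))) {
        w <- canonicalize(apply_inversion(p, invs[r, 1L], invs[r, 2L]))
        k <- perm_key(w)
        if (is.null(tab[[k]])) {
          tab[[k]] <- d + 1L
          nxt[[length(nxt) + 1L]] <- w
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  .oracle_cache[[ck]] <- tab
  tab
}

#' Optimal inversion scenario between two permutations
#'
#' Greedy optimal sorting: at every step the lexicographically smallest
#' distance-reducing inversion (smallest left cut, then smallest right
#' cut) is applied, so scenarios are deterministic. The scenario length
#' always equals [reversal_distance()].
#'
#' Cut junctions are recorded on the evolving linearization of `p` (the
#' frame of the input vector, updated in place by each inversion), so the
#' scenario can be replayed directly on `p` -- or on a
#' [repeat_config()] sharing `p`'s block order -- with [apply_scenario()].
#'
#' @param p,q [scperm] objects over the same block set.
#' @return An `inversion_scenario`: a list of integer cut pairs `c(i, j)`
#'   with attribute `distance`.
#' @export
sort_by_reversals <- function(p, q) {
  w <- relabel_to_identity(p, q)
  n <- length(w)
  d <- distance_to_identity(w)
  invs <- all_inversions(n)
  steps <- list()
  while (d > 0L) {
    found <- FALSE
    for (r in seq_len(nrow(invs))) {
      w2 <- apply_inversion(w, invs[r, 1L], invs[r, 2L])
      if (distance_to_identity(w2) == d - 1L) {
        w <- w2
        steps[[length(steps) + 1L]] <- c(i = invs[r, 1L], j = invs[r, 2L])
        d <- d - 1L
        found <- TRUE
        break
      }
    }
    if (!found)
      stop("internal error: no distance-reducing inversion found")
  }
  structure(steps, class = "inversion_scenario",
            distance = length(steps))
}

#' @export
print.inversion_scenario <- function(x, ...) {
  cat("<inversion_scenario> ", length(x), " inversion(s)\n", sep = "")
  for (k in seq_along(x))
    cat(sprintf("  step %d: cut junctions (%d, %d)\n", k, x[[k]][1], x[[k]][2]))
  invisible(x)
}

#' Replay an inversion scenario on a permutation
#'
#' @param p an [scperm] in the linear frame the scenario was recorded in.
#' @param scenario an `inversion_scenario` from [sort_by_reversals()].
#' @return The transformed [scperm].
#' @export
apply_scenario <- function(p, scenario) {
  for (st in scenario) p <- apply_inversion(p, st[[1L]], st[[2L]])
  p
}

#' Pairwise reversal-distance matrix
#'
#' @param perms a (preferably named) list of [scperm] objects over a
#'   shared block set.
#' @return A symmetric integer matrix with zero diagonal.
#' @export
distance_matrix <- function(perms) {
  L <- length(perms)
  nm <- names(perms)
  if (is.null(nm)) nm <- paste0("genome", seq_len(L))
  D <- matrix(0L, L, L, dimnames = list(nm, nm))
  if (L > 1L) {
    for (a in seq_len(L - 1L)) for (b in (a + 1L):L) {
      D[a, b] <- D[b, a] <- reversal_distance(perms[[a]], perms[[b]])
    }
  }
  D
}
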