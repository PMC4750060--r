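# MGR-style parsimony tree over gene-order permutations: greedy
# inversion-based merging when the topology is free, internal-node
# labelling (ancestral gene orders) by median/local search when the
# topology is fixed.

#' Parsimony tree with ancestral gene orders
#'
#' Builds a rearrangement tree over a set of signed circular
#' permutations, reconstructing ancestral permutations at internal nodes
#' and counting the inversions along each edge.
#'
#' Without a fixed topology the greedy MGR heuristic is used: repeatedly
#' apply, to some genome, the inversion that maximally decreases the sum
#' of its reversal distances to the other genomes (ties broken by genome
#' input order, then lexicographically smallest cut pair); when two
#' genomes coincide they are merged into a named ancestor. With a fixed
#' topology (an unrooted \pkg{ape} `phylo` whose tip labels match
#' `names(perms)`), internal nodes are labelled to minimize the total
#' edge distance: exact median search over the full state space when the
#' block count allows it, otherwise multi-start local search over
#' single-inversion neighborhoods.
#'
#' Internal nodes are named `A<k>` with `k` counting on from the number
#' of leaves, the usual ancestor-labelling convention for published
#' plastome rearrangement trees.
#'
#' @param perms named list of at least three [scperm] objects over a
#'   shared block set.
#' @param topology optional `ape::phylo` tree (unrooted, binary or
#'   star-like) with tip labels matching `names(perms)`.
#' @param exact_n block-count limit below which internal labels are
#'   optimized by exhaustive median search (default 6).
#' @return A `rearr_tree`: list with `labels` (permutation per node,
#'   leaves first), `edges` (data.frame `from`, `to`, `count`), `total`
#'   (sum of edge counts) and `leaf_names`.
#' @export
mgr_tree <- function(perms, topology = NULL, exact_n = 6) {
  L <- length(perms)
  if (L < 3L) stop("need at least 3 permutations")
  nm <- names(perms)
  if (is.null(nm) || any(!nzchar(nm))) nm <- paste0("genome", seq_len(L))
  names(perms) <- nm
  if (is.null(topology)) {
    mgr_tree_greedy(perms)
  } else {
    mgr_tree_fixed(perms, topology, exact_n)
  }
}

mgr_tree_greedy <- function(perms) {
  L <- length(perms)
  nm <- names(perms)
  labels <- perms              # node labels; grows with ancestors
  node_names <- nm
  edges <- data.frame(from = character(), to = character(),
                      count = integer(), stringsAsFactors = FALSE)
  # active lineages: current (evolving) permutation + node it descends from
  act <- lapply(seq_len(L), function(i) list(perm = perms[[i]], node = nm[i]))
  n <- length(perms[[1]])
  invs <- all_inversions(n)
  next_anc <- L + 1L

  merge_equal <- function() {
    repeat {
      A <- length(act)
      done <- TRUE
      for (a in seq_len(A - 1L)) {
        for (b in (a + 1L):A) {
          if (reversal_distance(act[[a]]$perm, act[[b]]$perm) == 0L) {
            anc_name <- paste0("A", next_anc)
            next_anc <<- next_anc + 1L
            anc <- canonicalize(act[[a]]$perm)
            labels[[anc_name]] <<- anc
            for (x in c(a, b)) {
              edges[nrow(edges) + 1L, ] <<- list(
                from = anc_name, to = act[[x]]$node,
                count = reversal_distance(labels[[act[[x]]$node]], anc))
            }
            act[[a]] <<- list(perm = anc, node = anc_name)
            act[[b]] <<- NULL
            done <- FALSE
            break
          }
        }
        if (!done) break
      }
      if (done) break
    }
  }

  merge_equal()
  while (length(act) > 1L) {
    A <- length(act)
    # current distance sums
    D <- matrix(0L, A, A)
    for (a in seq_len(A - 1L)) for (b in (a + 1L):A)
      D[a, b] <- D[b, a] <- reversal_distance(act[[a]]$perm, act[[b]]$perm)
    best <- list(delta = 0L)
    for (a in seq_len(A)) {
      base <- sum(D[a, ])
      for (r in seq_len(nrow(invs))) {
        cand <- apply_inversion(act[[a]]$perm, invs[r, 1L], invs[r, 2L])
        tot <- 0L
        for (b in seq_len(A)[-a]) tot <- tot + reversal_distance(cand, act[[b]]$perm)
        delta <- base - tot
        if (delta > best$delta) best <- list(delta = delta, a = a, perm = cand)
      }
    }
    if (best$delta > 0L) {
      act[[best$a]]$perm <- best$perm
    } else {
      # no single inversion helps every neighbour sum; collapse the
      # closest pair along an optimal scenario to guarantee progress
      pr <- which(D == min(D[D > 0]), arr.ind = TRUE)[1, ]
      sc <- sort_by_reversals(act[[pr[1]]]$perm, act[[pr[2]]]$perm)
      act[[pr[1]]]$perm <- apply_scenario(act[[pr[1]]]$perm, sc)
    }
    merge_equal()
  }
  new_rearr_tree(labels, edges, leaf_names = nm)
}

mgr_tree_fixed <- function(perms, topology, exact_n = 6) {
  if (!inherits(topology, "phylo")) stop("topology must be an ape 'phylo' tree")
  nm <- names(perms)
  if (!setequal(topology$tip.label, nm))
    stop("topology tip labels must match names(perms)")
  L <- length(nm)
  n <- length(perms[[1]])
  E <- topology$edge
  n_nodes <- max(E)
  adj <- vector("list", n_nodes)
  for (r in seq_len(nrow(E))) {
    adj[[E[r, 1]]] <- c(adj[[E[r, 1]]], E[r, 2])
    adj[[E[r, 2]]] <- c(adj[[E[r, 2]]], E[r, 1])
  }
  tipidx <- match(topology$tip.label, nm)
  internal <- setdiff(seq_len(n_nodes), seq_len(L))

  node_label <- vector("list", n_nodes)
  for (t in seq_len(L)) node_label[[t]] <- perms[[tipidx[t]]]

  total_len <- function(lab) {
    s <- 0L
    for (r in seq_len(nrow(E)))
      s <- s + reversal_distance(lab[[E[r, 1]]], lab[[E[r, 2]]])
    s
  }

  optimize_from <- function(init_perm) {
    lab <- node_label
    for (v in internal) lab[[v]] <- init_perm
    repeat {
      improved <- FALSE
      for (v in internal) {
        nbr <- adj[[v]]
        cur <- lab[[v]]
        score <- function(p) sum(vapply(nbr, function(u)
          reversal_distance(p, lab[[u]]), integer(1)))
        best_p <- cur
        best_s <- score(cur)
        if (n <= exact_n && length(nbr) == 3L) {
          med <- median_permutation(lab[[nbr[1]]], lab[[nbr[2]]], lab[[nbr[3]]])
          if (score(med) < best_s) { best_p <- med; best_s <- score(med) }
        }
        cands <- lapply(nbr, function(u) lab[[u]])
        invs <- all_inversions(n)
        for (r in seq_len(nrow(invs)))
          cands[[length(cands) + 1L]] <-
            apply_inversion(cur, invs[r, 1L], invs[r, 2L])
        for (cp in cands) {
          s <- score(cp)
          if (s < best_s) { best_p <- cp; best_s <- s }
        }
        if (!identical(as.integer(canonicalize(best_p)),
                       as.integer(canonicalize(cur)))) {
          lab[[v]] <- canonicalize(best_p)
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    lab
  }

  best_lab <- NULL
  best_tot <- Inf
  for (t in seq_len(L)) {
    lab <- optimize_from(perms[[t]])
    tot <- total_len(lab)
    if (tot < best_tot) { best_tot <- tot; best_lab <- lab }
  }

  node_names <- c(topology$tip.label, paste0("A", (L + 1L):n_nodes))
  labels <- stats::setNames(best_lab, node_names)
  edges <- data.frame(
    from = node_names[E[, 1]], to = node_names[E[, 2]],
    count = vapply(seq_len(nrow(E)), function(r)
      reversal_distance(best_lab[[E[r, 1]]], best_lab[[E[r, 2]]]), integer(1)),
    stringsAsFactors = FALSE)
  new_rearr_tree(labels, edges, leaf_names = topology$tip.label)
}

#' Exact median permutation of three gene orders
#'
#' Scans the full canonical state space (breadth-first from the identity)
#' for the signed circular permutation minimizing the sum of reversal
#' distances to the three inputs. Exponential in the block count; guarded
#' by `max_n`.
#'
#' @param p1,p2,p3 [scperm] objects over a shared block set.
#' @param max_n state-space guard (default 6).
#' @return The median [scperm] (ties broken by canonical-key order).
#' @export
median_permutation <- function(p1, p2, p3, max_n = 6) {
  n <- length(p1)
  if (n > max_n) stop("exact median limited to n <= ", max_n, " blocks")
  tab <- oracle_table(n)
  keys <- sort(ls(tab))
  best <- NULL
  best_s <- Inf
  ids <- abs(as.integer(canonicalize(p1)))  # original block ids, sorted order
  for (k in keys) {
    v <- as.integer(strsplit(k, " ")[[1]])
    cand <- scperm(sign(v) * sort(ids)[abs(v)])
    s <- reversal_distance(cand, p1) + reversal_distance(cand, p2) +
      reversal_distance(cand, p3)
    if (s < best_s) { best_s <- s; best <- cand }
  }
  best
}

new_rearr_tree <- function(labels, edges, leaf_names) {
  structure(list(labels = labels, edges = edges,
                 total = sum(edges$count), leaf_names = leaf_names),
            class = "rearr_tree")
}

#' @export
print.rearr_tree <- function(x, ...) {
  cat("<rearr_tree> ", length(x$leaf_names), " leaves, ",
      length(x$labels) - length(x$leaf_names), " ancestral node(s), total ",
      x$total, " inversion(s)\n", sep = "")
  for (r in seq_len(nrow(x$edges)))
    cat(sprintf("  %s -- %s : %d\n", x$edges$from[r], x$edges$to[r],
                x$edges$count[r]))
  invisible(x)
}

#' Convert a rearrangement tree to ape's phylo / newick
#'
#' Edge inversion counts become branch lengths; ancestor names become
#' node labels.
#'
#' @param tree a `rearr_tree`.
#' @return `as_phylo`: an `ape::phylo` object. `write_rearr_newick`
#'   writes newick text to `path` and returns it invisibly.
#' @export
as_phylo <- function(tree) {
  leaf <- tree$leaf_names
  anc <- setdiff(names(tree$labels), leaf)
  # ape numbering: tips 1..L, then internal nodes with the root first;
  # the root is the ancestor that never appears as a child
  root <- setdiff(anc, tree$edges$to)
  anc <- c(root, setdiff(anc, root))
  idx <- stats::setNames(seq_along(c(leaf, anc)), c(leaf, anc))
  edge <- cbind(idx[tree$edges$from], idx[tree$edges$to])
  phy <- list(edge = unname(edge), tip.label = leaf,
              Nnode = length(anc),
              edge.length = as.numeric(tree$edges$count),
              node.label = anc)
  class(phy) <- "phylo"
  phy
}

#' @param path file to write newick text to.
#' @rdname as_phylo
#' @export
write_rearr_newick <- function(tree, path) {
  phy <- as_phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(readLines(path, warn = FALSE))
}
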