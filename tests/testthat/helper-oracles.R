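# Independent brute-force oracles, kept free of the package's own
# algorithmic code paths.

# ---- exhaustive transportation optimum --------------------------------
# The optimum of a balanced transportation problem is attained at a basic
# feasible solution, i.e. on a spanning tree of the complete bipartite
# supply/demand graph. Enumerate ALL spanning trees, solve each tree's
# flows by leaf peeling, discard infeasible (negative-flow) bases and
# take the minimum cost. Tree sets are cached per problem shape.

.tree_cache <- new.env(parent = emptyenv())

enum_tree_bases <- function(n, m) {
  key <- paste(n, m, sep = "x")
  if (!is.null(.tree_cache[[key]])) return(.tree_cache[[key]])
  E <- as.matrix(expand.grid(i = seq_len(n), j = seq_len(m)))
  nodes <- n + m
  k <- nodes - 1L
  combs <- utils::combn(nrow(E), k)
  trees <- list()
  for (c in seq_len(ncol(combs))) {
    sel <- combs[, c]
    a <- E[sel, 1L]
    b <- E[sel, 2L] + n
    parent <- seq_len(nodes)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    acyclic <- TRUE
    for (t in seq_len(k)) {
      ra <- find(a[t]); rb <- find(b[t])
      if (ra == rb) { acyclic <- FALSE; break }
      parent[ra] <- rb
    }
    if (!acyclic) next
    # k = nodes - 1 acyclic edges => spanning tree; compute a leaf-peel
    # order (edge index within sel, leaf node) once per tree
    deg <- tabulate(c(a, b), nodes)
    alive <- rep(TRUE, k)
    peel <- matrix(0L, k, 2L)
    for (step in seq_len(k)) {
      e <- which(alive & (deg[a] == 1L | deg[b] == 1L))[1L]
      leaf <- if (deg[a[e]] == 1L) a[e] else b[e]
      peel[step, ] <- c(e, leaf)
      alive[e] <- FALSE
      deg[a[e]] <- deg[a[e]] - 1L
      deg[b[e]] <- deg[b[e]] - 1L
    }
    trees[[length(trees) + 1L]] <- list(i = E[sel, 1L], j = E[sel, 2L],
                                        a = a, b = b, peel = peel)
  }
  .tree_cache[[key]] <- trees
  trees
}

bf_transport_cost <- function(supply, demand, cost) {
  n <- length(supply); m <- length(demand)
  if (n == 1L) return(sum(demand * cost[1L, ]))
  if (m == 1L) return(sum(supply * cost[, 1L]))
  best <- Inf
  for (tr in enum_tree_bases(n, m)) {
    bal <- c(supply, -demand)
    tot <- 0
    feasible <- TRUE
    for (step in seq_len(nrow(tr$peel))) {
      e <- tr$peel[step, 1L]
      leaf <- tr$peel[step, 2L]
      f <- if (leaf <= n) bal[leaf] else -bal[leaf]
      if (f < -1e-9) { feasible <- FALSE; break }
      tot <- tot + f * cost[tr$i[e], tr$j[e]]
      other <- if (leaf == tr$a[e]) tr$b[e] else tr$a[e]
      bal[other] <- bal[other] + bal[leaf]
      bal[leaf] <- 0
    }
    if (feasible && tot < best) best <- tot
  }
  best
}

# plain DP edit distance on label sequences (independent of utils::adist)
bf_levenshtein <- function(a, b) {
  la <- length(a); lb <- length(b)
  d <- matrix(0L, la + 1L, lb + 1L)
  d[, 1L] <- 0:la
  d[1L, ] <- 0:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + (a[i] != b[j]))
    }
  }
  d[la + 1L, lb + 1L]
}

# random stochastic language over a tiny alphabet
random_language <- function(seed, max_variants = 4) {
  set.seed(seed)
  nv <- sample.int(max_variants, 1)
  variants <- list()
  keys <- character(0)
  while (length(variants) < nv) {
    v <- sample(letters[1:4], sample.int(5, 1), replace = TRUE)
    k <- paste(v, collapse = "\r")
    if (!k %in% keys) {
      variants[[length(variants) + 1L]] <- v
      keys <- c(keys, k)
    }
  }
  p <- stats::runif(nv)
  stoch_lang(variants, p / sum(p))
}

# brute-force directly-follows counts: explicit double loop over cases
# and event positions
bf_dfg_counts <- function(log) {
  counts <- new.env(parent = emptyenv())
  for (cid in unique(log$case_id)) {
    ev <- log[log$case_id == cid, , drop = FALSE]
    ev <- ev[order(ev$timestamp), , drop = FALSE]
    if (nrow(ev) < 2) next
    for (i in seq_len(nrow(ev) - 1L)) {
      key <- paste(ev$activity[i], ev$activity[i + 1L], sep = "\r")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) stats::setNames(integer(0), character(0)) else out
}
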