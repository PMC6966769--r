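# Independent brute-force oracles used against the package's algorithms.
# All are exhaustive and therefore only run on small instances.

# exact P(score >= s) by enumerating all 4^w sequences
bfPvalueTable <- function(model, background = model@background) {
  w <- ncol(model@scores)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- apply(grid, 1, function(cs) sum(model@scores[cbind(cs, seq_len(w))]))
  pr <- apply(grid, 1, function(cs) prod(background[cs]))
  function(s) sum(pr[sc >= s])
}

# all simple cycles by enumerating permutations of node subsets
bfCycles <- function(arcsDf) {
  nodes <- sort(unique(c(arcsDf$source, arcsDf$target)))
  hasArc <- function(u, v) any(arcsDf$source == u & arcsDf$target == v)
  out <- character(0)
  res <- list()
  subsets <- unlist(lapply(seq_along(nodes), function(k)
    utils::combn(nodes, k, simplify = FALSE)), recursive = FALSE)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  for (sub in subsets) {
    anchor <- sub[1]
    for (rest in perms(sub[-1])) {
      cyc <- c(anchor, rest)
      nxt <- c(cyc[-1], cyc[1])
      if (all(mapply(hasArc, cyc, nxt))) {
        key <- paste(cyc, collapse = ">")
        if (!(key %in% out)) { out <- c(out, key); res[[length(res) + 1]] <- cyc }
      }
    }
  }
  res
}

# minimum feedback arc sets by exhaustive subset search
bfFas <- function(arcsDf) {
  isAcyclic <- function(keep) {
    if (!nrow(keep)) return(TRUE)
    g <- igraph::graph_from_data_frame(keep[, c("source", "target")],
                                       directed = TRUE)
    igraph::is_dag(g) && !any(keep$source == keep$target)
  }
  m <- nrow(arcsDf)
  for (k in 0:m) {
    hits <- Filter(function(ix)
      isAcyclic(arcsDf[setdiff(seq_len(m), ix), , drop = FALSE]),
                   if (k == 0) list(integer(0)) else
                     utils::combn(m, k, simplify = FALSE))
    if (length(hits))
      return(list(size = k, sets = lapply(hits, function(ix)
        arcsDf[ix, c("source", "target"), drop = FALSE])))
  }
}

# maximum branching by enumerating one-in-arc-per-node choices
bfMaxBranching <- function(arcsDf) {
  nodes <- unique(c(arcsDf$source, arcsDf$target))
  opts <- lapply(nodes, function(v) c(0L, which(arcsDf$target == v)))
  best <- 0L
  grid <- expand.grid(opts, KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(grid))) {
    sel <- as.integer(grid[r, ]); sel <- sel[sel > 0]
    if (length(sel) <= best) next
    keep <- arcsDf[sel, , drop = FALSE]
    if (any(keep$source == keep$target)) next
    g <- igraph::graph_from_data_frame(keep[, c("source", "target")],
                                       directed = TRUE)
    if (igraph::is_dag(g)) best <- length(sel)
  }
  best
}

# reachability by boolean transitive closure
bfReachable <- function(arcsDf, nodes) {
  n <- length(nodes)
  M <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  diag(M) <- TRUE
  for (i in seq_len(nrow(arcsDf)))
    M[arcsDf$source[i], arcsDf$target[i]] <- TRUE
  repeat {
    M2 <- (M %*% M) > 0
    if (identical(M2, M)) break
    M <- M2
  }
  M
}

randomDigraph <- function(seed, nNodes = 6, pArc = 0.3, weights = FALSE) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(nNodes))
  a <- expand.grid(source = nodes, target = nodes, stringsAsFactors = FALSE)
  a <- a[a$source != a$target & stats::runif(nrow(a)) < pArc, , drop = FALSE]
  rownames(a) <- NULL
  if (weights && nrow(a))
    a$weight <- sample(c(1, 2, 4, 8), nrow(a), replace = TRUE)
  a
}

# small two-target weighted digraph for V-shape oracle tests
randomVShapeInstance <- function(seed) {
  set.seed(seed)
  n <- sample(4:8, 1)
  tf <- paste0("T", seq_len(n - 2))
  nodes <- c(tf, "a", "b")
  a <- NULL
  for (u in tf) for (v in setdiff(nodes, u))
    if (stats::runif(1) < 0.35)
      a <- rbind(a, data.frame(source = u, target = v))
  if (is.null(a)) a <- data.frame(source = character(), target = character())
  if (nrow(a)) a$weight <- sample(c(1, 2, 4, 8), nrow(a), replace = TRUE)
  list(arcs = a, tf = tf)
}
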