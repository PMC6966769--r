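# Minimum-weight V-shape machinery.
#
# A V-shape for (a, b) is the union of two directed paths from a common
# apex C ending at a and at b, sharing no node other than C. For a fixed
# apex the minimum total arc weight over such pairs is a 2-unit minimum-
# cost flow on the node-split transformation: every node except C gets
# capacity 1, so the two flow paths are node-disjoint away from the apex.
# Costs are the arc weights (non-negative). Forcing an arc into the
# optimum uses the lower-bound reduction (a unit of demand across the
# arc's endpoints, routed through a super source/sink), which keeps all
# costs non-negative and therefore safe on cyclic networks.

# Successive-shortest-path min-cost flow; edges as parallel arrays with
# interleaved reverse edges. Bellman-Ford tolerates negative residual
# costs; iteration is bounded because no negative cycle can arise.
mcmfRun <- function(env, src, snk, want) {
  flow <- 0L; cost <- 0
  nV <- env$nV
  while (flow < want) {
    dist <- rep(Inf, nV); dist[src] <- 0
    pedge <- integer(nV)
    for (iter in seq_len(nV + 1L)) {
      changed <- FALSE
      for (ei in seq_along(env$efrom)) {
        if (env$ecap[ei] > 0 && is.finite(dist[env$efrom[ei]]) &&
            dist[env$efrom[ei]] + env$ecost[ei] < dist[env$eto[ei]] - 1e-9) {
          dist[env$eto[ei]] <- dist[env$efrom[ei]] + env$ecost[ei]
          pedge[env$eto[ei]] <- ei
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (!is.finite(dist[snk])) return(NULL)
    v <- snk
    while (v != src) {
      ei <- pedge[v]
      env$ecap[ei] <- env$ecap[ei] - 1L
      rv <- if (ei %% 2L == 1L) ei + 1L else ei - 1L
      env$ecap[rv] <- env$ecap[rv] + 1L
      v <- env$efrom[ei]
    }
    cost <- cost + dist[snk]
    flow <- flow + 1L
  }
  list(cost = cost, flow = flow)
}

flowSolve <- function(arcsDf, nodes, apex, a, b, forceArc = NA_integer_) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  vin <- function(v) idx[[v]] * 2L - 1L
  vout <- function(v) idx[[v]] * 2L
  sink <- 2L * n + 1L
  ssrc <- 2L * n + 2L   # super source / sink for the forced-arc reduction
  ssnk <- 2L * n + 3L
  env <- new.env()
  env$efrom <- integer(0); env$eto <- integer(0)
  env$ecap <- integer(0); env$ecost <- numeric(0); env$eorig <- integer(0)
  env$nV <- 2L * n + 3L
  addEdge <- function(u, v, cap, cost, orig = NA_integer_) {
    env$efrom <- c(env$efrom, u, v); env$eto <- c(env$eto, v, u)
    env$ecap <- c(env$ecap, as.integer(cap), 0L)
    env$ecost <- c(env$ecost, cost, -cost)
    env$eorig <- c(env$eorig, orig, NA_integer_)
  }
  for (v in nodes)
    addEdge(vin(v), vout(v), if (v == apex) 2L else 1L, 0)
  for (i in seq_len(nrow(arcsDf))) {
    if (!is.na(forceArc) && i == forceArc) next
    addEdge(vout(arcsDf$source[i]), vin(arcsDf$target[i]), 1L,
            arcsDf$weight[i], i)
  }
  addEdge(vout(a), sink, 1L, 0)
  addEdge(vout(b), sink, 1L, 0)
  if (is.na(forceArc)) {
    res <- mcmfRun(env, vout(apex), sink, 2L)
    extra <- 0
  } else {
    # arc u->v with flow lower bound 1: remove it, give v_in one unit of
    # supply and u_out one unit of demand, and meet all supplies/demands
    # as a 3-unit flow from the super source to the super sink
    u <- arcsDf$source[forceArc]; v <- arcsDf$target[forceArc]
    addEdge(ssrc, vout(apex), 2L, 0)
    addEdge(ssrc, vin(v), 1L, 0)
    addEdge(vout(u), ssnk, 1L, 0)
    addEdge(sink, ssnk, 2L, 0)
    res <- mcmfRun(env, ssrc, ssnk, 3L)
    extra <- arcsDf$weight[forceArc]
  }
  if (is.null(res)) return(NULL)
  fwd <- seq_along(env$efrom)[seq_along(env$efrom) %% 2L == 1L]
  usedArcs <- env$eorig[fwd][env$ecap[fwd] == 0L]
  usedArcs <- as.integer(usedArcs[!is.na(usedArcs)])
  if (!is.na(forceArc)) usedArcs <- sort(c(usedArcs, forceArc))
  list(cost = res$cost + extra, arcs = usedArcs)
}

vshapeApexes <- function(arcsDf, tfNodes) {
  outd <- table(arcsDf$source)
  intersect(tfNodes, names(outd)[outd >= 2])
}

# reachability: named list node -> character vector of nodes reachable
# (including itself), via igraph BFS
reachabilityMap <- function(arcsDf, nodes) {
  if (!nrow(arcsDf))
    return(stats::setNames(as.list(nodes), nodes))
  g <- igraph::graph_from_data_frame(
    arcsDf[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = nodes))
  out <- lapply(nodes, function(v)
    names(igraph::subcomponent(g, v, mode = "out")))
  stats::setNames(out, nodes)
}

#' Minimum-weight V-shape connecting two operons
#'
#' Exact optimum over all apexes and all node-disjoint path pairs, computed
#' per candidate apex by a 2-unit minimum-cost flow on the node-split
#' transformation (every node except the apex and the two targets has
#' capacity 1). Apex candidates are TF nodes with out-degree at least 2 (a
#' necessary condition).
#'
#' @param network an [AffinityNetwork-class] with a `weight` column on its
#'   arcs (see [assignWeights()]), or a data.frame of weighted arcs.
#' @param a,b distinct target (metabolic operon) node names.
#' @param tf TF node names when `network` is a bare data.frame.
#' @return `NULL` when no V-shape exists, else a list with `weight`,
#'   `apex`, `arcs` (rows of the arc table in one optimal V-shape),
#'   `pathA`, `pathB` (node sequences from the apex).
#' @examples
#' arcs <- data.frame(source = c("C", "C"), target = c("A", "B"),
#'                    weight = c(1, 2))
#' minWeightVShape(arcs, "A", "B", tf = "C")$weight  # 3
#' @export
minWeightVShape <- function(network, a, b, tf = NULL) {
  if (a == b) stop("V-shape targets must be distinct")
  arcsDf <- if (is.data.frame(network)) network else arcs(network)
  if (is.null(arcsDf$weight)) stop("arcs must carry weights; run assignWeights()")
  tf <- if (!is.null(tf)) tf else tfNodes(network)
  nodes <- unique(c(arcsDf$source, arcsDf$target, a, b))
  best <- NULL
  reach <- reachabilityMap(arcsDf, nodes)
  for (apex in vshapeApexes(arcsDf, tf)) {
    if (apex %in% c(a, b)) next
    if (!(a %in% reach[[apex]]) || !(b %in% reach[[apex]])) next
    sol <- flowSolve(arcsDf, nodes, apex, a, b)
    if (!is.null(sol) && (is.null(best) || sol$cost < best$cost)) {
      best <- sol; best$apex <- apex
    }
  }
  if (is.null(best)) return(NULL)
  sel <- arcsDf[best$arcs, , drop = FALSE]
  paths <- decomposePaths(sel, best$apex, a, b)
  list(weight = best$cost, apex = best$apex, arcs = sel,
       pathA = paths$a, pathB = paths$b)
}

# The used arcs of an optimal flow form exactly two directed paths from
# the apex, node-disjoint away from it: walk each of the two first arcs.
decomposePaths <- function(sel, apex, a, b) {
  firsts <- which(sel$source == apex)
  walk <- function(i) {
    path <- c(apex, sel$target[i])
    repeat {
      nxt <- which(sel$source == utils::tail(path, 1))
      if (!length(nxt)) return(path)
      path <- c(path, sel$target[nxt[1]])
    }
  }
  paths <- lapply(firsts, walk)
  ends <- vapply(paths, function(p) utils::tail(p, 1), character(1))
  list(a = paths[[match(a, ends)]], b = paths[[match(b, ends)]])
}

#' Arcs belonging to at least one minimum-weight V-shape
#'
#' For each arc, the optimum is recomputed with that arc forced into the
#' solution; the arc is kept iff the forced optimum equals the global
#' optimum. This realises "the set of all minimum-weight V-shapes" without
#' enumerating them (which can be exponential).
#'
#' @inheritParams minWeightVShape
#' @return integer vector of arc-table row indices (empty when no V-shape
#'   exists).
#' @export
optimalVShapeArcs <- function(network, a, b, tf = NULL) {
  arcsDf <- if (is.data.frame(network)) network else arcs(network)
  tf <- if (!is.null(tf)) tf else tfNodes(network)
  nodes <- unique(c(arcsDf$source, arcsDf$target, a, b))
  reach <- reachabilityMap(arcsDf, nodes)
  apexes <- vshapeApexes(arcsDf, tf)
  apexes <- apexes[!apexes %in% c(a, b)]
  apexes <- apexes[vapply(apexes, function(cc)
    a %in% reach[[cc]] && b %in% reach[[cc]], logical(1))]
  if (!length(apexes)) return(integer(0))
  base <- lapply(apexes, function(cc) flowSolve(arcsDf, nodes, cc, a, b))
  ok <- !vapply(base, is.null, logical(1))
  apexes <- apexes[ok]; base <- base[ok]
  if (!length(apexes)) return(integer(0))
  opt <- min(vapply(base, function(s) s$cost, numeric(1)))
  # candidate arcs: on some path apex -> {a, b}
  cand <- which(vapply(seq_len(nrow(arcsDf)), function(i) {
    tgt <- arcsDf$target[i]
    (a %in% reach[[tgt]] || b %in% reach[[tgt]] || tgt %in% c(a, b)) &&
      any(vapply(apexes, function(cc) arcsDf$source[i] %in% reach[[cc]],
                 logical(1)))
  }, logical(1)))
  keep <- integer(0)
  for (e in cand) {
    inOpt <- FALSE
    for (k in seq_along(apexes)) {
      if (base[[k]]$cost == opt && e %in% base[[k]]$arcs) { inOpt <- TRUE; break }
      sol <- flowSolve(arcsDf, nodes, apexes[k], a, b, forceArc = e)
      if (!is.null(sol) && abs(sol$cost - opt) < 1e-6) { inOpt <- TRUE; break }
    }
    if (inOpt) keep <- c(keep, e)
  }
  sort(keep)
}

#' Explicitly enumerate all V-shapes (test oracle)
#'
#' Exhaustive enumeration over apexes and simple-path pairs; exponential,
#' intended for networks of at most ~12 nodes as the independent oracle
#' for [minWeightVShape()] and [optimalVShapeArcs()].
#'
#' @inheritParams minWeightVShape
#' @param maxNodes guard on network size.
#' @return list of V-shapes, each a list(weight, apex, arcIdx, pathA,
#'   pathB); empty list when none exists.
#' @export
enumerateVShapes <- function(network, a, b, tf = NULL, maxNodes = 12L) {
  arcsDf <- if (is.data.frame(network)) network else arcs(network)
  tf <- if (!is.null(tf)) tf else tfNodes(network)
  nodes <- unique(c(arcsDf$source, arcsDf$target, a, b))
  if (length(nodes) > maxNodes)
    stop("enumerateVShapes is an oracle for small networks (<= ", maxNodes,
         " nodes)")
  simplePaths <- function(from, to) {
    res <- list()
    dfs <- function(v, path, arcIdx) {
      if (v == to) { res[[length(res) + 1]] <<- list(nodes = path, arcs = arcIdx); return() }
      for (i in which(arcsDf$source == v)) {
        w <- arcsDf$target[i]
        if (!(w %in% path)) dfs(w, c(path, w), c(arcIdx, i))
      }
    }
    dfs(from, from, integer(0))
    res
  }
  out <- list()
  for (apex in intersect(tf, nodes)) {
    if (apex %in% c(a, b)) next
    pa <- simplePaths(apex, a); pb <- simplePaths(apex, b)
    for (x in pa) for (y in pb) {
      shared <- intersect(setdiff(x$nodes, apex), setdiff(y$nodes, apex))
      if (length(shared)) next
      out[[length(out) + 1]] <- list(
        weight = sum(arcsDf$weight[c(x$arcs, y$arcs)]),
        apex = apex, arcIdx = sort(unique(c(x$arcs, y$arcs))),
        pathA = x$nodes, pathB = y$nodes)
    }
  }
  out
}
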