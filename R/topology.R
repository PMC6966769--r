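roundHalfUp <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Exclusivity percentage of a category
#'
#' Share of a category's operons controlled exclusively by one primary
#' regulator, rounded half-up to the nearest integer percent; the label is
#' the "n (p%)" form used in report tables.
#'
#' @param exclusive number of exclusively controlled operons.
#' @param nOperons category size.
#' @return list(pct = integer, label = character).
#' @export
exclusivityPercent <- function(exclusive, nOperons) {
  pct <- as.integer(roundHalfUp(exclusive / nOperons * 100))
  list(pct = pct, label = sprintf("%d (%d%%)", exclusive, pct))
}

arcTable <- function(network) {
  if (is.data.frame(network)) network else arcs(network)
}

networkNodes <- function(network, arcsDf) {
  if (is.data.frame(network)) unique(c(arcsDf$source, arcsDf$target))
  else c(tfNodes(network), operonNodes(network))
}

#' Enumerate all directed simple cycles
#'
#' Complete Johnson-style enumeration: for every start node s (in order),
#' cycles whose smallest node is s are found by depth-first search
#' restricted to the strongly connected component of s in the subgraph
#' induced on nodes >= s, so acyclic regions are never explored.
#'
#' @param network a network object or arc data.frame (source, target).
#' @param cap abort when more than this many cycles are found.
#' @return list of cycles, each a character vector of nodes in order (the
#'   smallest node first); empty for a DAG.
#' @export
enumerateCycles <- function(network, cap = 10000L) {
  a <- arcTable(network)
  nodes <- sort(unique(networkNodes(network, a)))
  if (!nrow(a)) return(list())
  out <- list()
  for (si in seq_along(nodes)) {
    s <- nodes[si]
    sub <- a[a$source %in% nodes[si:length(nodes)] &
               a$target %in% nodes[si:length(nodes)], , drop = FALSE]
    if (!nrow(sub)) next
    g <- igraph::graph_from_data_frame(
      sub[, c("source", "target")], directed = TRUE,
      vertices = data.frame(name = nodes[si:length(nodes)]))
    comp <- igraph::components(g, mode = "strong")
    scc <- names(comp$membership)[comp$membership == comp$membership[s]]
    selfLoop <- any(sub$source == s & sub$target == s)
    if (selfLoop) out[[length(out) + 1]] <- s
    if (length(scc) < 2) next
    sub <- sub[sub$source %in% scc & sub$target %in% scc, , drop = FALSE]
    adjacency <- split(sub$target, sub$source)
    path <- s
    dfs <- function(v) {
      for (w in adjacency[[v]]) {
        if (w == s && length(path) > 1) {
          out[[length(out) + 1]] <<- path
          if (length(out) > cap)
            stop("cycle cap (", cap, ") exceeded; the network is far from ",
                 "acyclic — raise the cap or inspect it first")
        } else if (!(w %in% path) && w != s) {
          path <<- c(path, w)
          dfs(w)
          path <<- path[-length(path)]
        }
      }
    }
    dfs(s)
  }
  out
}

cycleArcKeys <- function(cycle) {
  nxt <- c(cycle[-1], cycle[1])
  paste(cycle, nxt, sep = "\r")
}

#' All minimum feedback arc sets
#'
#' Enumerates the directed cycles, then finds every minimum-cardinality
#' set of arcs hitting all of them by branch and bound (branching on the
#' arcs of an uncovered cycle, pruning at the incumbent size).
#'
#' @param network network object or arc data.frame.
#' @param cap cycle cap passed to [enumerateCycles()].
#' @param maxSets stop collecting optima beyond this many.
#' @return list with `size`, `sets` (list of data.frames source/target),
#'   `truncated`.
#' @examples
#' toy <- data.frame(
#'   source = c("X","Y","P","Q","R","R","S"),
#'   target = c("Y","X","Q","R","P","S","P"))
#' minFeedbackArcSets(toy)$size  # 2
#' @export
minFeedbackArcSets <- function(network, cap = 10000L, maxSets = 1000L) {
  cycles <- enumerateCycles(network, cap)
  if (!length(cycles))
    return(list(size = 0L, sets = list(data.frame(source = character(),
                                                  target = character())),
                truncated = FALSE))
  cycArcs <- lapply(cycles, cycleArcKeys)
  best <- Inf
  solutions <- new.env(); solutions$seen <- character(0)
  solutions$sets <- list(); solutions$truncated <- FALSE
  search <- function(chosen) {
    if (length(chosen) >= best &&
        !all(vapply(cycArcs, function(cc) any(cc %in% chosen), logical(1))))
      return()
    uncovered <- cycArcs[!vapply(cycArcs, function(cc)
      any(cc %in% chosen), logical(1))]
    if (!length(uncovered)) {
      if (length(chosen) < best) {
        best <<- length(chosen)
        solutions$sets <- list(); solutions$seen <- character(0)
      }
      if (length(chosen) == best) {
        key <- paste(sort(chosen), collapse = "|")
        if (!(key %in% solutions$seen)) {
          if (length(solutions$sets) >= maxSets) {
            solutions$truncated <- TRUE
          } else {
            solutions$seen <- c(solutions$seen, key)
            solutions$sets[[length(solutions$sets) + 1]] <- sort(chosen)
          }
        }
      }
      return()
    }
    if (length(chosen) + 1 > best) return()
    branchCycle <- uncovered[[which.min(lengths(uncovered))]]
    for (arc in unique(branchCycle)) search(c(chosen, arc))
  }
  search(character(0))
  sets <- lapply(solutions$sets, function(keys) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(source = vapply(parts, `[`, character(1), 1),
               target = vapply(parts, `[`, character(1), 2))
  })
  list(size = as.integer(best), sets = sets,
       truncated = solutions$truncated)
}

#' Longest-path hierarchy levels given a feedback arc set
#'
#' Removes the feedback arcs, checks acyclicity, and assigns
#' `level(v) = 1 + max(level(u))` over the remaining in-neighbours (level
#' 1 for sources), so every non-feedback arc goes from a strictly lower
#' to a strictly higher level.
#'
#' @param network network object or arc data.frame.
#' @param fas data.frame (source, target) of feedback arcs.
#' @return list(level = named integer vector, nLevels).
#' @export
assignLevels <- function(network, fas = NULL) {
  a <- arcTable(network)
  nodes <- networkNodes(network, a)
  if (!is.null(fas) && nrow(fas)) {
    drop <- paste(a$source, a$target, sep = "\r") %in%
      paste(fas$source, fas$target, sep = "\r")
    a <- a[!drop, , drop = FALSE]
  }
  level <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  indeg <- table(factor(a$target, levels = nodes))
  queue <- nodes[indeg == 0]
  level[queue] <- 1L
  remaining <- indeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (i in which(a$source == v)) {
      w <- a$target[i]
      level[w] <- max(level[w], level[v] + 1L, na.rm = TRUE)
      remaining[w] <- remaining[w] - 1L
      if (remaining[w] == 0) queue <- c(queue, w)
    }
  }
  if (anyNA(level))
    stop("residual cycle after removing the given feedback arcs; ",
         "the set is not a valid feedback arc set")
  list(level = level, nLevels = max(level))
}

#' Distance of the TF-TF subgraph from a tree
#'
#' Minimum number of arcs to remove so that the remaining TF-TF arcs form
#' a tree. Two senses of "tree" are supported: `"undirected"` (default)
#' removes the cycle rank m - n + c of the underlying undirected
#' multigraph, leaving a spanning forest; `"branching"` removes
#' m - (maximum branching size), where the maximum branching (acyclic,
#' in-degree <= 1) is computed by Edmonds' algorithm with unit weights.
#' The percentage is removals / m * 100 to one decimal.
#'
#' @param network a network object (its TF-TF arcs are used) or an arc
#'   data.frame already restricted to TF nodes.
#' @param mode "undirected" or "branching".
#' @return list(removals, percentage, nArcs, mode).
#' @export
treeDistance <- function(network, mode = c("undirected", "branching")) {
  mode <- match.arg(mode)
  a <- arcTable(network)
  if (!is.data.frame(network)) a <- a[a$kind == "tf-tf", , drop = FALSE]
  m <- nrow(a)
  if (!m) return(list(removals = 0L, percentage = 0.0, nArcs = 0L,
                      mode = mode))
  if (mode == "undirected") {
    g <- igraph::graph_from_data_frame(a[, c("source", "target")],
                                       directed = FALSE)
    ncomp <- igraph::components(g)$no
    removals <- m - (igraph::vcount(g) - ncomp)
  } else {
    removals <- m - length(maxBranching(a))
  }
  list(removals = as.integer(removals),
       percentage = roundHalfUp(removals / m * 100, 1),
       nArcs = as.integer(m), mode = mode)
}

#' Primary regulators
#'
#' TF family nodes with in-degree zero in the co-regulatory network: no
#' other regulator controls them inside the network.
#'
#' @param network a network object.
#' @return character vector of TF family nodes.
#' @export
primaryRegulators <- function(network) {
  a <- arcs(network)
  sort(setdiff(tfNodes(network), a$target))
}

reachableOperons <- function(arcsDf, nodes, from, operonSet) {
  reach <- reachabilityMap(arcsDf, nodes)
  lapply(stats::setNames(from, from), function(r)
    intersect(reach[[r]], operonSet))
}

#' Regulator-by-category reachability table
#'
#' Cell (category S, regulator R) counts the category-S operons reachable
#' from R by a directed path (direct binding or regulatory cascades). The
#' `Operons` column holds each category's operon count in the network;
#' the TOTAL row holds column sums. Categories are ordered ascending by
#' operon count and regulators descending by their totals, mirroring the
#' usual presentation.
#'
#' @param network a [CoRegulatoryNetwork-class].
#' @param categories named list operon -> categories (defaults to the
#'   network's map).
#' @param regulators TF nodes to tabulate (default: primary regulators).
#' @return integer matrix with categories as rows (plus TOTAL) and
#'   `Operons` + regulators as columns.
#' @export
regulatoryTable <- function(network, categories = NULL, regulators = NULL) {
  categories <- if (is.null(categories)) categoryMap(network) else categories
  if (is.null(regulators)) regulators <- primaryRegulators(network)
  stopifnot(all(regulators %in% tfNodes(network)))
  a <- arcs(network)
  nodes <- c(tfNodes(network), operonNodes(network))
  present <- intersect(names(categories), operonNodes(network))
  byCat <- split(rep(present, lengths(categories[present])),
                 unlist(categories[present], use.names = FALSE))
  reach <- reachableOperons(a, nodes, regulators, present)
  byCat <- lapply(byCat, unique)
  cats <- names(byCat)[order(lengths(byCat), names(byCat))]
  mat <- matrix(0L, nrow = length(cats), ncol = length(regulators) + 1,
                dimnames = list(cats, c("Operons", regulators)))
  for (s in cats) {
    mat[s, "Operons"] <- length(unique(byCat[[s]]))
    for (r in regulators)
      mat[s, r] <- length(intersect(reach[[r]], byCat[[s]]))
  }
  totals <- colSums(mat)
  ord <- c(1, 1 + order(totals[-1], decreasing = TRUE))
  mat <- mat[, ord, drop = FALSE]
  out <- rbind(mat, TOTAL = colSums(mat))
  storage.mode(out) <- "integer"
  out
}

#' Exclusive regulation by single primary regulators
#'
#' An operon is exclusive to primary regulator P when P is the only
#' primary from which it is reachable. Counts per category and per
#' primary, with the category percentage rounded to the nearest integer
#' and formatted "n (p%)" in the `total_label` column.
#'
#' @inheritParams regulatoryTable
#' @param primaries the primary regulators (defaults to
#'   [primaryRegulators()]).
#' @return data.frame: category, n_operons, total_exclusive, pct,
#'   total_label, then one count column per primary (ordered as in
#'   [regulatoryTable()]).
#' @export
exclusivityTable <- function(network, categories = NULL, primaries = NULL) {
  categories <- if (is.null(categories)) categoryMap(network) else categories
  if (is.null(primaries)) primaries <- primaryRegulators(network)
  a <- arcs(network)
  nodes <- c(tfNodes(network), operonNodes(network))
  present <- intersect(names(categories), operonNodes(network))
  byCat <- split(rep(present, lengths(categories[present])),
                 unlist(categories[present], use.names = FALSE))
  reach <- reachableOperons(a, nodes, primaries, present)
  regTab <- regulatoryTable(network, categories, primaries)
  primOrder <- setdiff(colnames(regTab), "Operons")
  nReaching <- vapply(present, function(op)
    sum(vapply(reach, function(x) op %in% x, logical(1))), integer(1))
  exclusiveTo <- function(op)
    if (nReaching[[op]] == 1)
      primaries[vapply(reach, function(x) op %in% x, logical(1))] else NA
  cats <- rownames(regTab); cats <- cats[cats != "TOTAL"]
  rows <- lapply(cats, function(s) {
    ops <- unique(byCat[[s]])
    excl <- vapply(ops, function(op) {
      e <- exclusiveTo(op)
      if (length(e) == 1 && !is.na(e)) e else NA_character_
    }, character(1))
    n <- length(ops); ne <- sum(!is.na(excl))
    ep <- exclusivityPercent(ne, n)
    cnt <- vapply(primOrder, function(p) sum(excl == p, na.rm = TRUE),
                  integer(1))
    cbind(data.frame(category = s, n_operons = n, total_exclusive = ne,
                     pct = ep$pct, total_label = ep$label),
          as.data.frame(as.list(cnt)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Minimal sets of regulators controlling a category
#'
#' Smallest subsets of the candidate regulators whose reachable operons
#' jointly cover every operon of the category; exhaustive search in
#' increasing cardinality (candidates are few, e.g. the primary
#' regulators).
#'
#' @param network a [CoRegulatoryNetwork-class].
#' @param categoryOperons operon nodes of the category.
#' @param candidates candidate regulator nodes (<= 20).
#' @return list(size, sets = list of character vectors, unique = flag,
#'   feasible = flag).
#' @export
minimalControllingSets <- function(network, categoryOperons, candidates) {
  stopifnot(length(candidates) <= 20)
  a <- arcs(network)
  nodes <- c(tfNodes(network), operonNodes(network))
  target <- intersect(categoryOperons, operonNodes(network))
  reach <- reachableOperons(a, nodes, candidates, target)
  if (!setequal(intersect(Reduce(union, reach, character(0)), target), target))
    return(list(size = NA_integer_, sets = list(), unique = FALSE,
                feasible = FALSE))
  for (k in seq_along(candidates)) {
    combos <- utils::combn(candidates, k, simplify = FALSE)
    hits <- Filter(function(set)
      setequal(intersect(Reduce(union, reach[set], character(0)), target),
               target), combos)
    if (length(hits))
      return(list(size = k, sets = hits, unique = length(hits) == 1,
                  feasible = TRUE))
  }
  list(size = NA_integer_, sets = list(), unique = FALSE, feasible = FALSE)
}

#' Degree table with flagged hubs
#'
#' @param network a network object.
#' @return data.frame node, kind, in_degree, out_degree, total_degree,
#'   max_in, max_out, max_total (ties all flagged).
#' @export
hubReport <- function(network) {
  tab <- degreeStats(network)$table
  if (!nrow(tab)) return(tab)
  tab$max_in <- tab$in_degree == max(tab$in_degree)
  tab$max_out <- tab$out_degree == max(tab$out_degree)
  tab$max_total <- tab$total_degree == max(tab$total_degree)
  tab
}

#' Full topological report
#'
#' Runs every topology analysis on a co-regulatory network: cycle
#' enumeration, all minimum feedback arc sets, hierarchy levels per
#' feedback-arc choice, TF-TF tree distance, primary regulators, the
#' reachability and exclusivity tables, minimal controlling sets per
#' category (over the primary regulators by default, or all TF nodes),
#' and the degree/hub table.
#'
#' @param network a [CoRegulatoryNetwork-class].
#' @param categories named list operon -> categories (default: network's).
#' @param controlMode "primaries" or "all" TF nodes as candidates for the
#'   minimal controlling sets.
#' @param treeMode passed to [treeDistance()].
#' @return a [TopologyReport-class].
#' @export
topologyReport <- function(network, categories = NULL,
                           controlMode = c("primaries", "all"),
                           treeMode = "undirected") {
  controlMode <- match.arg(controlMode)
  categories <- if (is.null(categories)) categoryMap(network) else categories
  cycles <- enumerateCycles(network)
  fas <- minFeedbackArcSets(network)
  levels <- lapply(fas$sets, function(s) assignLevels(network, s))
  prim <- primaryRegulators(network)
  present <- intersect(names(categories), operonNodes(network))
  byCat <- split(rep(present, lengths(categories[present])),
                 unlist(categories[present], use.names = FALSE))
  candidates <- if (controlMode == "primaries") prim else tfNodes(network)
  ctrl <- lapply(byCat, function(ops)
    minimalControllingSets(network, unique(ops), candidates))
  new("TopologyReport",
      cycles = cycles,
      fasSize = fas$size,
      feedbackArcSets = fas$sets,
      levels = levels,
      treeDistance = treeDistance(network, mode = treeMode),
      primaryRegulators = prim,
      regulatoryTable = regulatoryTable(network, categories, prim),
      exclusivityTable = exclusivityTable(network, categories, prim),
      controllingSets = ctrl,
      hubs = hubReport(network))
}
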