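#' Maximum branching (Edmonds' algorithm)
#'
#' A branching is an acyclic arc subset in which every node has in-degree
#' at most 1. Finds a maximum-weight branching by the classic
#' choose/contract/expand procedure: pick the best positive in-arc per
#' node, contract any cycle among the picks with the standard weight
#' adjustment, recurse, then expand each cycle dropping one of its arcs.
#' With unit weights this maximises the number of arcs, which is the
#' "tree" sense used by [treeDistance()]'s branching mode.
#'
#' @param arcsDf data.frame with columns source, target and optionally
#'   weight (default 1 per arc).
#' @return integer vector of row indices of `arcsDf` forming a maximum
#'   branching.
#' @examples
#' a <- data.frame(source = c("r","r","x"), target = c("x","y","y"))
#' length(maxBranching(a))  # 2: y keeps one of its two in-arcs
#' @export
maxBranching <- function(arcsDf) {
  if (!nrow(arcsDf)) return(integer(0))
  w <- if (!is.null(arcsDf$weight)) as.numeric(arcsDf$weight) else
    rep(1, nrow(arcsDf))
  edges <- data.frame(u = arcsDf$source, v = arcsDf$target, w = w,
                      id = seq_len(nrow(arcsDf)),
                      stringsAsFactors = FALSE)
  solve <- function(edges) {
    edges <- edges[edges$u != edges$v & edges$w > 0, , drop = FALSE]
    if (!nrow(edges)) return(integer(0))
    # best in-arc per node
    best <- do.call(rbind, lapply(split(edges, edges$v), function(e)
      e[which.max(e$w), , drop = FALSE]))
    pick <- stats::setNames(best$u, best$v)
    # find a cycle among the picks
    cyc <- NULL
    for (start in names(pick)) {
      path <- start; v <- start
      repeat {
        if (!(v %in% names(pick))) break
        v <- pick[[v]]
        if (v %in% path) {
          ix <- match(v, path)
          cyc <- path[ix:length(path)]   # nodes on the cycle
          break
        }
        path <- c(path, v)
      }
      if (!is.null(cyc)) break
    }
    if (is.null(cyc)) return(best$id)
    # cycle arcs: the picked in-arc of every cycle node
    cycRows <- best[best$v %in% cyc, , drop = FALSE]
    minW <- min(cycRows$w)
    super <- paste0("\rC", paste(sort(cyc), collapse = ","))
    inW <- stats::setNames(cycRows$w, cycRows$v)  # picked weight per node
    ne <- edges
    enter <- ne$v %in% cyc & !(ne$u %in% cyc)
    ne$w[enter] <- ne$w[enter] - inW[ne$v[enter]] + minW
    entryTarget <- ifelse(enter, ne$v, NA)
    ne$u[ne$u %in% cyc] <- super
    ne$v[ne$v %in% cyc] <- super
    keep <- ne$u != ne$v
    ne <- ne[keep, , drop = FALSE]
    entryTarget <- entryTarget[keep]
    sol <- solve(ne)
    # expand: which contracted arc entered the super node?
    chosenEntry <- intersect(sol, ne$id[!is.na(entryTarget)])
    if (length(chosenEntry)) {
      tgt <- entryTarget[match(chosenEntry[1], ne$id)]
      dropArc <- cycRows$id[cycRows$v == tgt]
    } else {
      dropArc <- cycRows$id[which.min(cycRows$w)]
    }
    c(sol, setdiff(cycRows$id, dropArc))
  }
  sort(solve(edges))
}
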