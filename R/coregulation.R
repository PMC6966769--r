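#' Assign parsimony weights to arcs by p-value quartiles
#'
#' Arcs are sorted ascending by (p-value, arc order) and split into as
#' many contiguous groups as there are weight classes, with sizes as equal
#' as possible (a remainder of r goes to the first r, lowest-p, groups).
#' Group j receives `weightClasses[j]`, so the lowest p-values get weight
#' 1 and the highest weight 8 under the defaults.
#'
#' @param network an [AffinityNetwork-class], or its arc data.frame.
#' @param weightClasses ascending positive integers (default 1, 2, 4, 8).
#' @return the same object with an integer `weight` column added to the
#'   arcs.
#' @examples
#' a <- data.frame(source = "C", target = paste0("O", 1:8),
#'                 kind = "tf-operon", p = (1:8) * 1e-6)
#' assignWeights(a)$weight  # 1 1 2 2 4 4 8 8
#' @export
assignWeights <- function(network, weightClasses = c(1L, 2L, 4L, 8L)) {
  a <- if (is.data.frame(network)) network else arcs(network)
  if (!nrow(a)) stop("cannot assign weights to an empty arc set")
  k <- length(weightClasses)
  n <- nrow(a)
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  ord <- order(a$p, seq_len(n))      # stable: ties keep arc order
  w <- integer(n)
  w[ord] <- rep(as.integer(weightClasses), sizes)
  a$weight <- w
  if (is.data.frame(network)) return(a)
  network@arcs <- a
  network
}

#' Select co-regulatory arcs by minimum-weight V-shapes
#'
#' For every unordered pair of metabolic operons sharing a pathway
#' category, the arcs belonging to at least one minimum-weight V-shape
#' connecting the pair are computed ([optimalVShapeArcs()]) and the union
#' over all pairs is returned, with per-arc provenance recording which
#' category/pair selected it. Pairs admitting no V-shape contribute
#' nothing.
#'
#' @param network a weighted [AffinityNetwork-class] (see
#'   [assignWeights()]).
#' @param categories named list operon node -> categories; defaults to the
#'   network's own category map.
#' @param verbose log pairs with no V-shape.
#' @return data.frame of selected arcs (source, target, kind, p, weight,
#'   provenance) where provenance is a semicolon-joined list of
#'   "category:a|b" tokens.
#' @export
selectCoregulatoryArcs <- function(network, categories = NULL,
                                   verbose = FALSE) {
  categories <- if (is.null(categories)) categoryMap(network) else categories
  a <- arcs(network)
  if (is.null(a$weight)) stop("run assignWeights() first")
  present <- intersect(names(categories), operonNodes(network))
  byCat <- split(rep(present, lengths(categories[present])),
                 unlist(categories[present], use.names = FALSE))
  prov <- vector("list", nrow(a))
  for (cat in names(byCat)) {
    ops <- sort(unique(byCat[[cat]]))
    if (length(ops) < 2) next
    pairs <- utils::combn(ops, 2)
    for (j in seq_len(ncol(pairs))) {
      x <- pairs[1, j]; y <- pairs[2, j]
      sel <- optimalVShapeArcs(a, x, y, tf = tfNodes(network))
      if (!length(sel)) {
        if (verbose)
          message("no V-shape for pair ", x, "/", y, " in ", cat)
        next
      }
      token <- paste0(cat, ":", x, "|", y)
      for (e in sel) prov[[e]] <- c(prov[[e]], token)
    }
  }
  keep <- which(lengths(prov) > 0)
  out <- a[keep, , drop = FALSE]
  out$provenance <- vapply(prov[keep], paste, character(1), collapse = ";")
  rownames(out) <- NULL
  out
}

#' Filter selected arcs and assemble the co-regulatory network
#'
#' Arcs with original p strictly above `finalArcPThreshold` are removed (p
#' equal to the threshold is retained). Operons coding for transcription
#' factors are replaced by their family nodes via `familyMap`; parallel
#' arcs arising from the collapse are merged keeping the minimum p (and
#' the union of provenance); isolated nodes are dropped.
#'
#' @param selected data.frame from [selectCoregulatoryArcs()].
#' @param finalArcPThreshold p-value cutoff (default 9e-5).
#' @param familyMap named character mapping node -> TF family for
#'   TF-coding operon nodes; nodes absent from the map are untouched.
#' @param categories named list operon node -> categories carried through.
#' @return a [CoRegulatoryNetwork-class]; its `show` method reports node
#'   and arc counts split by kind.
#' @export
filterAndAssemble <- function(selected, finalArcPThreshold = 9e-5,
                              familyMap = character(),
                              categories = list()) {
  a <- selected
  dropped <- a$p > finalArcPThreshold
  a <- a[!dropped, , drop = FALSE]
  if (!nrow(a)) {
    warning("all selected arcs exceed the final p threshold; empty network")
    return(newNetwork("CoRegulatoryNetwork", character(), character(),
                      data.frame(source = character(), target = character(),
                                 kind = character(), p = numeric(),
                                 weight = integer(),
                                 provenance = character())))
  }
  remap <- function(v) ifelse(v %in% names(familyMap), familyMap[v], v)
  mapped_tf_targets <- unique(remap(intersect(a$target, names(familyMap))))
  a$source <- remap(a$source)
  isTf <- a$target %in% names(familyMap)
  a$target <- remap(a$target)
  a$kind[isTf] <- "tf-tf"
  # merge parallel arcs keeping min p, union of provenance
  a <- a[order(paste(a$source, a$target, sep = "\r"), a$p), , drop = FALSE]
  key <- paste(a$source, a$target, sep = "\r")
  merged <- lapply(split(seq_len(nrow(a)), key), function(ix) {
    row <- a[ix[1], , drop = FALSE]
    if (!is.null(a$provenance))
      row$provenance <- paste(unique(unlist(
        strsplit(a$provenance[ix], ";", fixed = TRUE))), collapse = ";")
    row
  })
  a <- do.call(rbind, merged)
  a <- a[order(a$source, a$target), , drop = FALSE]
  rownames(a) <- NULL
  tf <- sort(unique(c(a$source, a$target[a$kind == "tf-tf"],
                      mapped_tf_targets[mapped_tf_targets %in%
                                          c(a$source, a$target)])))
  op <- sort(unique(a$target[a$kind == "tf-operon"]))
  newNetwork("CoRegulatoryNetwork", tf, op, a,
             categories = categories[intersect(names(categories), op)])
}

#' Histogram of selected-arc p-values
#'
#' Right-closed bins of the given width covering [0, max p]; the counts
#' sum to the number of arcs.
#'
#' @param arcsOrP selected-arc data.frame (column p) or numeric p-values.
#' @param binWidth positive bin width.
#' @return data.frame with bin_start, bin_end, count.
#' @export
pvalueHistogram <- function(arcsOrP, binWidth) {
  stopifnot(binWidth > 0)
  p <- if (is.data.frame(arcsOrP)) arcsOrP$p else arcsOrP
  if (!length(p))
    return(data.frame(bin_start = numeric(), bin_end = numeric(),
                      count = integer()))
  nb <- max(1L, as.integer(ceiling(max(p) / binWidth - 1e-12)))
  bin <- pmin(pmax(ceiling(p / binWidth - 1e-12), 1L), nb)
  counts <- tabulate(bin, nbins = nb)
  data.frame(bin_start = (seq_len(nb) - 1) * binWidth,
             bin_end = seq_len(nb) * binWidth,
             count = counts)
}
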