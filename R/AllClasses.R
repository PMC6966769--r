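#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

DNA_LETTERS <- c("A", "C", "G", "T")

#' Pipeline configuration
#'
#' Holds every tunable constant of the pipeline: the motif scan p-value
#' threshold (with a stricter "confident" class), the final arc p-value
#' filter applied after V-shape selection, the operon intergenic gap rule,
#' the arc weight classes used for V-shape parsimony, the pathway category
#' names, the background nucleotide model and the RNG seed.
#'
#' @slot scanPThreshold numeric; a motif occurrence is kept when its exact
#'   p-value is at or below this (default 1e-4).
#' @slot confidentPThreshold numeric; occurrences at or below this are
#'   additionally flagged confident (default 1e-5).
#' @slot finalArcPThreshold numeric; arcs with original p above this are
#'   removed from the selected co-regulatory arcs (default 9e-5).
#' @slot operonMaxGap integer; two consecutive same-strand genes share an
#'   operon iff the intergenic gap is strictly below this many bp
#'   (default 50).
#' @slot weightClasses integer vector; weights given to equal-size p-value
#'   groups of arcs, ascending (default 1, 2, 4, 8).
#' @slot categoryNames character; the pathway category vocabulary.
#' @slot background named numeric over A, C, G, T summing to 1.
#' @slot rngSeed integer seed recorded in run manifests.
#' @exportClass PipelineConfig
setClass("PipelineConfig", representation(
  scanPThreshold = "numeric",
  confidentPThreshold = "numeric",
  finalArcPThreshold = "numeric",
  operonMaxGap = "integer",
  weightClasses = "integer",
  categoryNames = "character",
  background = "numeric",
  rngSeed = "integer"
))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  for (s in c("scanPThreshold", "confidentPThreshold", "finalArcPThreshold")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v <= 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a single probability in (0, 1]", s))
  }
  w <- object@weightClasses
  if (length(w) < 1 || any(w <= 0) || any(diff(w) <= 0))
    msg <- c(msg, "weightClasses must be positive and strictly increasing")
  if (length(object@operonMaxGap) != 1 || object@operonMaxGap < 1)
    msg <- c(msg, "operonMaxGap must be a positive integer")
  bg <- object@background
  if (!identical(sort(names(bg)), sort(DNA_LETTERS)) ||
      abs(sum(bg) - 1) > 1e-9 || any(bg < 0))
    msg <- c(msg, "background must be named A/C/G/T probabilities summing to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param scanPThreshold motif scan p-value threshold.
#' @param confidentPThreshold stricter threshold flagging confident matches.
#' @param finalArcPThreshold p-value filter applied to selected arcs.
#' @param operonMaxGap intergenic bp gap below which consecutive same-strand
#'   genes are merged into one operon.
#' @param weightClasses ascending integer weights for the p-value groups.
#' @param categoryNames pathway category vocabulary; defaults to the six
#'   bioleaching-related pathways.
#' @param background named A/C/G/T probabilities.
#' @param rngSeed integer seed recorded in manifests.
#' @return A [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig()
#' cfg
#' @export
pipelineConfig <- function(scanPThreshold = 1e-4,
                           confidentPThreshold = 1e-5,
                           finalArcPThreshold = 9e-5,
                           operonMaxGap = 50L,
                           weightClasses = c(1L, 2L, 4L, 8L),
                           categoryNames = c(
                             "RISC oxidation", "Sulfur assimilation",
                             "Energy generation", "Heme biosynthesis",
                             "Spermidine biosynthesis", "NAD biosynthesis"),
                           background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                           rngSeed = 1L) {
  new("PipelineConfig",
      scanPThreshold = as.numeric(scanPThreshold),
      confidentPThreshold = as.numeric(confidentPThreshold),
      finalArcPThreshold = as.numeric(finalArcPThreshold),
      operonMaxGap = as.integer(operonMaxGap),
      weightClasses = as.integer(weightClasses),
      categoryNames = as.character(categoryNames),
      background = background[DNA_LETTERS],
      rngSeed = as.integer(rngSeed))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n",
      "  scan p <= ", format(object@scanPThreshold),
      " (confident <= ", format(object@confidentPThreshold), ")\n",
      "  final arc filter: p > ", format(object@finalArcPThreshold), " removed\n",
      "  operon gap < ", object@operonMaxGap, " bp; weights ",
      paste(object@weightClasses, collapse = "/"), "\n",
      "  categories: ", paste(object@categoryNames, collapse = ", "), "\n",
      sep = "")
})

#' Position-specific scoring matrix
#'
#' Per-position nucleotide probabilities of a transcription-factor family
#' binding motif. Columns are motif positions, rows A/C/G/T; every column
#' sums to 1 within 1e-9.
#'
#' @slot family TF family name the motif belongs to.
#' @slot probs 4 x width probability matrix with rownames A, C, G, T.
#' @exportClass PSSM
setClass("PSSM", representation(family = "character", probs = "matrix"))

setValidity("PSSM", function(object) {
  p <- object@probs
  if (!identical(rownames(p), DNA_LETTERS))
    return("probs must have rownames A, C, G, T")
  if (ncol(p) < 1) return("motif width must be >= 1")
  if (any(p < 0)) return("probabilities must be non-negative")
  if (any(abs(colSums(p) - 1) > 1e-9))
    return("every PSSM column must sum to 1 within 1e-9")
  TRUE
})

#' @describeIn PSSM-class constructor; columns are renormalised to sum
#'   exactly to 1 when they are within 1e-3 of it (looser input is an error).
#' @param family TF family name.
#' @param probs 4 x width matrix (rows A, C, G, T).
#' @export
pssm <- function(family, probs) {
  probs <- as.matrix(probs)
  rownames(probs) <- DNA_LETTERS
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 0.05))
    stop("PSSM column sums deviate from 1 by more than 5%")
  probs <- sweep(probs, 2, cs, "/")
  new("PSSM", family = as.character(family), probs = probs)
}

#' @describeIn PSSM-class motif width (number of positions).
#' @param x a PSSM.
#' @export
motifWidth <- function(x) ncol(x@probs)

#' @describeIn PSSM-class total information content in bits relative to the
#'   uniform background.
#' @export
informationContent <- function(x) {
  p <- x@probs
  sum(p * ifelse(p > 0, log2(p / 0.25), 0))
}

setMethod("show", "PSSM", function(object) {
  cat(sprintf("PSSM '%s': width %d, %.1f bits\n", object@family,
              motifWidth(object), informationContent(object)))
})

#' Integer-scaled log-odds score model with exact p-values
#'
#' A PSSM converted to integer log-odds scores against a background model,
#' together with the exact distribution of the total score of a random
#' background sequence, obtained by dynamic-programming convolution of the
#' per-position score distributions. `pvalue[s]` is P(score >= s) under the
#' background.
#'
#' @slot family TF family name.
#' @slot scores integer 4 x width matrix of scaled log-odds, shifted so the
#'   column minima are 0 (the shift is recorded separately per column).
#' @slot scale integer scale factor applied before rounding.
#' @slot background named numeric A/C/G/T background.
#' @slot pvalue numeric vector; element k is P(total shifted score >= k - 1).
#' @slot nScore score expected for an ambiguous base, per column.
#' @exportClass ScoreModel
setClass("ScoreModel", representation(
  family = "character",
  scores = "matrix",
  scale = "integer",
  background = "numeric",
  pvalue = "numeric",
  nScore = "integer"
))

setValidity("ScoreModel", function(object) {
  pv <- object@pvalue
  if (any(diff(pv) > 1e-12)) return("pvalue table must be non-increasing")
  if (abs(pv[1] - 1) > 1e-12) return("p at the minimum achievable score must be 1")
  TRUE
})

setMethod("show", "ScoreModel", function(object) {
  cat(sprintf("ScoreModel '%s': width %d, scale %d, max shifted score %d\n",
              object@family, ncol(object@scores), object@scale,
              length(object@pvalue) - 1L))
})

#' Affinity transcriptional regulatory network
#'
#' Directed graph with two node kinds (TF family nodes and operon nodes)
#' and two arc kinds: family -> operon (a binding-site match in the
#' operon's promoter) and family -> family (a match in the promoter of an
#' operon that contains a gene coding for the target family). Several
#' genes of one family are represented by a single family node. Every arc
#' carries the minimum match p-value over its supporting occurrences.
#'
#' @slot tfNodes character; TF family node names.
#' @slot operonNodes character; operon node names.
#' @slot arcs data.frame with columns source, target, kind
#'   ("tf-tf"/"tf-operon"), p.
#' @slot categories named list mapping operon node -> character vector of
#'   pathway categories (may be empty).
#' @exportClass AffinityNetwork
setClass("AffinityNetwork", representation(
  tfNodes = "character",
  operonNodes = "character",
  arcs = "data.frame",
  categories = "list"
))

validateNetworkArcs <- function(object) {
  a <- object@arcs
  need <- c("source", "target", "kind", "p")
  if (!all(need %in% names(a)))
    return("arcs must have columns source, target, kind, p")
  if (anyDuplicated(paste(a$source, a$target)))
    return("duplicate (source, target) arcs are not allowed")
  if (nrow(a) && !all(a$source %in% object@tfNodes))
    return("every arc source must be a TF family node")
  bad <- a$kind == "tf-tf" & !(a$target %in% object@tfNodes)
  bad <- bad | (a$kind == "tf-operon" & !(a$target %in% object@operonNodes))
  if (any(bad)) return("arc kind inconsistent with target node kind")
  if (any(a$p < 0 | a$p > 1)) return("arc p-values must lie in [0, 1]")
  if (any(object@tfNodes %in% object@operonNodes))
    return("a node cannot be both TF family and operon")
  TRUE
}

setValidity("AffinityNetwork", validateNetworkArcs)

#' Co-regulatory network
#'
#' The sub-network of the affinity network whose arcs belong to at least
#' one minimum-weight V-shape connecting two metabolic operons of the same
#' pathway category, after the final p-value filter and TF-family
#' collapsing. Arc provenance records which category/operon pairs selected
#' each arc.
#'
#' @slot tfNodes TF family node names.
#' @slot operonNodes metabolic operon node names.
#' @slot arcs data.frame with columns source, target, kind, p, weight,
#'   provenance (semicolon-joined "category:a|b" tokens).
#' @slot categories named list: operon node -> categories.
#' @exportClass CoRegulatoryNetwork
setClass("CoRegulatoryNetwork", representation(
  tfNodes = "character",
  operonNodes = "character",
  arcs = "data.frame",
  categories = "list"
))

setValidity("CoRegulatoryNetwork", function(object) {
  ok <- validateNetworkArcs(object)
  if (!isTRUE(ok)) return(ok)
  a <- object@arcs
  used <- unique(c(a$source, a$target))
  iso <- setdiff(c(object@tfNodes, object@operonNodes), used)
  if (nrow(a) && length(iso))
    return(paste("isolated nodes present:", paste(iso, collapse = ", ")))
  TRUE
})

newNetwork <- function(class, tfNodes, operonNodes, arcs, categories = list()) {
  rownames(arcs) <- NULL
  new(class, tfNodes = as.character(tfNodes),
      operonNodes = as.character(operonNodes),
      arcs = arcs, categories = categories)
}

showNetwork <- function(object, label) {
  a <- object@arcs
  cat(sprintf("%s: %d nodes (%d TF families, %d operons), %d arcs (%d tf-tf, %d tf-operon)\n",
              label, nodeCount(object), length(object@tfNodes),
              length(object@operonNodes), nrow(a),
              sum(a$kind == "tf-tf"), sum(a$kind == "tf-operon")))
}

setMethod("show", "AffinityNetwork", function(object)
  showNetwork(object, "AffinityNetwork"))
setMethod("show", "CoRegulatoryNetwork", function(object)
  showNetwork(object, "CoRegulatoryNetwork"))

#' Topological report of a co-regulatory network
#'
#' Bundle of every topology analysis: simple cycles, all minimum feedback
#' arc sets, hierarchy levels per feedback-arc choice, TF-TF tree distance,
#' primary regulators, the regulator-by-category reachability table, the
#' exclusivity table, minimal controlling regulator sets per category, and
#' the degree/hub table.
#'
#' @slot cycles list of node-sequence cycles.
#' @slot fasSize integer minimum feedback arc set size.
#' @slot feedbackArcSets list of data.frames (source, target).
#' @slot levels list, one per feedback arc set: list(level = named integer,
#'   nLevels = integer).
#' @slot treeDistance list(removals, percentage, nArcs, mode).
#' @slot primaryRegulators character.
#' @slot regulatoryTable matrix category x regulator with Operons column
#'   and TOTAL row.
#' @slot exclusivityTable data.frame per category with exclusive counts.
#' @slot controllingSets named list per category.
#' @slot hubs data.frame degree table with flagged maxima.
#' @exportClass TopologyReport
setClass("TopologyReport", representation(
  cycles = "list",
  fasSize = "integer",
  feedbackArcSets = "list",
  levels = "list",
  treeDistance = "list",
  primaryRegulators = "character",
  regulatoryTable = "matrix",
  exclusivityTable = "data.frame",
  controllingSets = "list",
  hubs = "data.frame"
))

setMethod("show", "TopologyReport", function(object) {
  cat(sprintf(
    "TopologyReport: %d cycles, min feedback arc set size %d (%d optima),\n",
    length(object@cycles), object@fasSize, length(object@feedbackArcSets)))
  nl <- vapply(object@levels, function(x) x$nLevels, integer(1))
  cat(sprintf("  levels per FAS choice: %s; tree distance %d (%.1f%%)\n",
              paste(unique(nl), collapse = "/"),
              object@treeDistance$removals, object@treeDistance$percentage))
  cat(sprintf("  primary regulators (%d): %s\n",
              length(object@primaryRegulators),
              paste(object@primaryRegulators, collapse = ", ")))
})
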