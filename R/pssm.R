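encodeDNA <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], DNA_LETTERS)
  x[is.na(x)] <- 5L   # ambiguous base
  x
}

revcompCodes <- function(codes) {
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rev(comp[codes])
}

#' Build an integer-scaled log-odds score model with an exact p-value table
#'
#' Converts a PSSM into integer log-odds scores against a background model,
#' `round(scale * log2((p + pc * bg) / ((1 + pc) * bg)))`, and computes the
#' exact null distribution of the total score of a random background
#' sequence by dynamic programming: the per-position integer score
#' distributions are convolved position by position, which is exact because
#' positions are independent under the 0-order background. `pvalue[s+1]`
#' then gives P(score >= s) for every achievable shifted score s, so a
#' scanned score maps to its p-value by table lookup. Ambiguous bases are
#' scored with the (rounded) background-expected column score.
#'
#' @param pssm a [PSSM-class].
#' @param background named A/C/G/T probabilities, strictly positive.
#' @param pseudocount non-negative; admixed proportionally to the
#'   background before taking log-odds (default 0.01).
#' @param scale positive integer score granularity (default 1000).
#' @return a [ScoreModel-class].
#' @examples
#' m <- buildScoreModel(randomPssm(6, seed = 2))
#' m
#' @export
buildScoreModel <- function(pssm, background = c(A = .25, C = .25, G = .25, T = .25),
                            pseudocount = 0.01, scale = 1000L) {
  stopifnot(is(pssm, "PSSM"), pseudocount >= 0, scale >= 1)
  bg <- background[DNA_LETTERS]
  if (any(bg <= 0)) stop("background probabilities must be strictly positive")
  p <- pssm@probs
  if (pseudocount == 0 && any(p == 0))
    stop("zero probability with zero pseudocount gives infinite log-odds; ",
         "use a positive pseudocount")
  padj <- sweep(p, 1, pseudocount * bg, "+") / (1 + pseudocount)
  lod <- log2(sweep(padj, 1, bg, "/"))
  s <- round(scale * lod)
  # shift columns so the minimum per column is 0; p-values are shift-invariant
  mins <- apply(s, 2, min)
  s <- sweep(s, 2, mins)
  storage.mode(s) <- "integer"
  w <- ncol(s)
  # DP convolution of per-position score distributions under the background
  dist <- 1
  for (i in seq_len(w)) {
    mx <- max(s[, i])
    nd <- numeric(length(dist) + mx)
    for (a in 1:4) {
      idx <- seq_along(dist) + s[a, i]
      nd[idx] <- nd[idx] + bg[a] * dist
    }
    dist <- nd
  }
  pv <- rev(cumsum(rev(dist)))
  pv <- pmin(pv, 1)
  nScore <- as.integer(round(colSums(s * as.numeric(bg))))
  new("ScoreModel", family = pssm@family, scores = s,
      scale = as.integer(scale), background = bg, pvalue = pv,
      nScore = nScore)
}

#' Exact p-value of a shifted integer score
#' @param model a [ScoreModel-class].
#' @param score shifted integer total score(s).
#' @return P(score >= x) under the background; 1 below the minimum
#'   achievable score, 0 above the maximum.
#' @export
scorePvalue <- function(model, score) {
  n <- length(model@pvalue)
  idx <- score + 1L
  out <- numeric(length(score))
  out[idx < 1] <- 1
  out[idx > n] <- 0
  ok <- idx >= 1 & idx <= n
  out[ok] <- model@pvalue[idx[ok]]
  out
}

scanCodesOneStrand <- function(model, codes) {
  w <- ncol(model@scores)
  L <- length(codes)
  n <- L - w + 1L
  if (n < 1) return(integer(0))
  total <- integer(n)
  for (i in seq_len(w)) {
    ci <- codes[i:(i + n - 1L)]
    sc <- c(model@scores[, i], model@nScore[i])[ci]
    total <- total + sc
  }
  total
}

#' Scan a promoter sequence with a score model
#'
#' Both strands are scanned at every offset; an occurrence is emitted iff
#' its exact p-value is at or below `pThreshold` (a p equal to the
#' threshold is a match). Offsets are 1-based positions of the leftmost
#' matched base on the forward strand.
#'
#' @param model a [ScoreModel-class].
#' @param sequence promoter DNA (character) or a row of the promoter table.
#' @param pThreshold per-occurrence p-value cutoff.
#' @param promoterId id copied into the result.
#' @return data.frame with columns family, promoter_id, offset, strand,
#'   score (log-odds, descaled), p_value. Empty when the region is shorter
#'   than the motif.
#' @export
scanPromoter <- function(model, sequence, pThreshold = 1e-4,
                         promoterId = NA_character_) {
  codes <- encodeDNA(sequence)
  w <- ncol(model@scores)
  L <- length(codes)
  empty <- data.frame(family = character(), promoter_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), p_value = numeric())
  if (L < w) return(empty)
  res <- list()
  fwd <- scanCodesOneStrand(model, codes)
  pf <- scorePvalue(model, fwd)
  hit <- which(pf <= pThreshold)
  if (length(hit))
    res$f <- data.frame(family = model@family, promoter_id = promoterId,
                        offset = hit, strand = "+",
                        score = fwd[hit] / model@scale, p_value = pf[hit])
  rev <- scanCodesOneStrand(model, revcompCodes(codes))
  pr <- scorePvalue(model, rev)
  hit <- which(pr <= pThreshold)
  if (length(hit))
    # position j on the reverse-complement corresponds to forward-strand
    # leftmost base L - (j + w - 1) + 1
    res$r <- data.frame(family = model@family, promoter_id = promoterId,
                        offset = L - hit - w + 2L, strand = "-",
                        score = rev[hit] / model@scale, p_value = pr[hit])
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Scan all promoters with all score models
#'
#' @param models list of [ScoreModel-class].
#' @param promoters promoter table from [extractPromoters()]; only rows
#'   with at least one downstream operon are scanned.
#' @param pThreshold per-occurrence p-value cutoff.
#' @param confidentPThreshold matches at or below it get `confident = TRUE`.
#' @return match data.frame (possibly 0 rows) with a `confident` flag.
#' @export
scanPromoters <- function(models, promoters, pThreshold = 1e-4,
                          confidentPThreshold = 1e-5) {
  keep <- promoters[promoters$n_downstream > 0, , drop = FALSE]
  out <- list()
  for (m in models) for (i in seq_len(nrow(keep))) {
    h <- scanPromoter(m, keep$sequence[i], pThreshold, keep$promoter_id[i])
    if (nrow(h)) out[[length(out) + 1]] <- h
  }
  if (!length(out))
    return(data.frame(family = character(), promoter_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), p_value = numeric(),
                      confident = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$confident <- res$p_value <= confidentPThreshold
  res
}

#' Assemble the affinity transcriptional regulatory network
#'
#' An arc family F -> operon O is created when at least one occurrence of
#' F's motif lies in a promoter of O, annotated with the minimum p-value
#' over occurrences. When O contains a gene coding for a transcription
#' factor of family G, the target is the family node G instead (tf-tf arc),
#' so families with several coding genes collapse to single nodes. An
#' operon containing both TF genes and other genes contributes a tf-tf arc
#' per member family plus a tf-operon arc for its non-TF content only when
#' it carries pathway categories.
#'
#' @param matches match table from [scanPromoters()].
#' @param operons operon table from [callOperons()].
#' @param promoters promoter table from [extractPromoters()].
#' @param tfFamilies named character: gene id -> family, for TF genes.
#' @param geneCategories named list: gene id -> categories (optional).
#' @return an [AffinityNetwork-class]; operon categories are the union
#'   over member genes.
#' @export
buildAffinityNetwork <- function(matches, operons, promoters, tfFamilies,
                                 geneCategories = list()) {
  og <- operonGenes(operons)
  opFamilies <- lapply(og, function(g)
    unique(stats::setNames(tfFamilies[g], NULL)[!is.na(tfFamilies[g])]))
  opCats <- lapply(og, function(g)
    sort(unique(unlist(geneCategories[intersect(g, names(geneCategories))]))))
  names(opCats) <- names(og)
  unknown <- setdiff(unique(matches$promoter_id), promoters$promoter_id)
  if (length(unknown))
    stop("match references unknown promoter: ", paste(unknown, collapse = ", "))
  down <- stats::setNames(
    strsplit(promoters$downstream_operons, ";", fixed = TRUE),
    promoters$promoter_id)
  rows <- list()
  for (i in seq_len(nrow(matches))) {
    fam <- matches$family[i]; p <- matches$p_value[i]
    for (op in down[[matches$promoter_id[i]]]) {
      fams <- opFamilies[[op]]
      if (length(fams)) {
        for (gfam in fams)
          rows[[length(rows) + 1]] <- data.frame(
            source = fam, target = gfam, kind = "tf-tf", p = p)
        nonTf <- og[[op]][is.na(tfFamilies[og[[op]]])]
        if (length(nonTf) && length(opCats[[op]]))
          rows[[length(rows) + 1]] <- data.frame(
            source = fam, target = op, kind = "tf-operon", p = p)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          source = fam, target = op, kind = "tf-operon", p = p)
      }
    }
  }
  allFams <- sort(unique(c(matches$family,
                           unlist(opFamilies, use.names = FALSE))))
  if (!length(rows)) {
    return(newNetwork("AffinityNetwork", allFams, character(),
                      data.frame(source = character(), target = character(),
                                 kind = character(), p = numeric()),
                      categories = opCats))
  }
  a <- do.call(rbind, rows)
  # dedupe keeping the minimum p per (source, target)
  key <- paste(a$source, a$target, sep = "\r")
  a <- a[order(key, a$p), , drop = FALSE]
  a <- a[!duplicated(paste(a$source, a$target, sep = "\r")), , drop = FALSE]
  opNodes <- sort(unique(a$target[a$kind == "tf-operon"]))
  newNetwork("AffinityNetwork", allFams, opNodes, a,
             categories = opCats[opNodes])
}

#' Per-node degree table and degree histogram
#'
#' @param network an [AffinityNetwork-class] or [CoRegulatoryNetwork-class].
#' @return list with `table` (node, kind, in_degree, out_degree,
#'   total_degree) satisfying sum(in) = sum(out) = number of arcs, and
#'   `histogram` (degree counts of the total degree).
#' @export
degreeStats <- function(network) {
  nodes <- c(tfNodes(network), operonNodes(network))
  if (!length(nodes))
    return(list(table = data.frame(node = character(), kind = character(),
                                   in_degree = integer(),
                                   out_degree = integer(),
                                   total_degree = integer()),
                histogram = table(integer())))
  a <- arcs(network)
  ind <- table(factor(a$target, levels = nodes))
  outd <- table(factor(a$source, levels = nodes))
  tab <- data.frame(node = nodes,
                    kind = c(rep("tf", length(tfNodes(network))),
                             rep("operon", length(operonNodes(network)))),
                    in_degree = as.integer(ind),
                    out_degree = as.integer(outd))
  tab$total_degree <- tab$in_degree + tab$out_degree
  list(table = tab, histogram = table(tab$total_degree))
}
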