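# Synthetic genomes, motifs and networks with planted ground truth.
# Every generator takes a mandatory seed and restores the caller's RNG
# state, so runs are deterministic and generators compose.

resample <- function(x, size = 1, ...) x[sample.int(length(x), size, ...)]

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

randomDNA <- function(n, background = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(DNA_LETTERS, n, replace = TRUE, prob = background[DNA_LETTERS]),
        collapse = "")
}

#' Random information-rich PSSM
#'
#' Draws a random consensus and gives it probability `conservation` per
#' position (the rest spread uniformly), yielding roughly
#' `width * (2 - H(conservation))` bits; the defaults give ~1.4 bits per
#' position.
#'
#' @param width motif width.
#' @param seed RNG seed.
#' @param family family name.
#' @param conservation consensus probability per position.
#' @return a [PSSM-class].
#' @export
randomPssm <- function(width, seed, family = "TF", conservation = 0.91) {
  withSeed(seed, {
    cons <- sample(1:4, width, replace = TRUE)
    m <- matrix((1 - conservation) / 3, nrow = 4, ncol = width)
    m[cbind(cons, seq_len(width))] <- conservation
    rownames(m) <- DNA_LETTERS
    pssm(family, m)
  })
}

#' Generate a synthetic annotated genome with known operon structure
#'
#' Genes are laid down contig by contig; consecutive genes stay in the
#' same operon (same strand, intergenic gap uniform on `intraGap`) with
#' probability `operonContinueProb`, otherwise a new operon starts (gap
#' uniform on `interGap`, fresh random strand). Background sequence is
#' i.i.d. from `background`. The true operon partition is returned.
#'
#' @param nGenes total genes (>= 1).
#' @param nContigs number of contigs genes are split across.
#' @param intraGap,interGap integer ranges (bp) for within-/between-operon
#'   gaps; defaults keep every within gap < 50 and every between gap > 50.
#' @param geneLength integer range of CDS lengths.
#' @param operonContinueProb probability the next gene extends the operon.
#' @param background nucleotide probabilities.
#' @param seed RNG seed (mandatory).
#' @param dir when non-NULL, FASTA/GFF3 are written there.
#' @return list(genome = DNAStringSet, genes = GRanges, truthOperon =
#'   integer vector (operon index per gene), annotationFile, genomeFile).
#' @export
generateGenome <- function(nGenes, nContigs = 1L,
                           intraGap = c(1L, 49L), interGap = c(60L, 500L),
                           geneLength = c(300L, 900L),
                           operonContinueProb = 0.6,
                           background = c(A = .25, C = .25, G = .25, T = .25),
                           seed, dir = NULL) {
  stopifnot(nGenes >= 1, nContigs >= 1, nContigs <= nGenes)
  withSeed(seed, {
    perContig <- diff(floor(seq(0, nGenes, length.out = nContigs + 1)))
    geneRows <- list(); seqs <- character(nContigs)
    truth <- integer(0); operonIdx <- 0L; gid <- 0L
    for (ci in seq_len(nContigs)) {
      pos <- sample(150:400, 1)     # leading flank
      rows <- list(); newOperon <- TRUE; strand <- "+"
      for (gi in seq_len(perContig[ci])) {
        if (newOperon) {
          operonIdx <- operonIdx + 1L
          strand <- sample(c("+", "-"), 1)
        }
        len <- sample(geneLength[1]:geneLength[2], 1)
        gid <- gid + 1L
        rows[[gi]] <- data.frame(
          contig = sprintf("contig%02d", ci),
          start = pos, end = pos + len - 1L, strand = strand,
          gene_id = sprintf("g%05d", gid))
        truth <- c(truth, operonIdx)
        newOperon <- stats::runif(1) > operonContinueProb
        gap <- if (newOperon) sample(interGap[1]:interGap[2], 1) else
          sample(intraGap[1]:intraGap[2], 1)
        pos <- pos + len + gap
      }
      tail_flank <- sample(150:400, 1)
      clen <- rows[[length(rows)]]$end + tail_flank
      seqs[ci] <- randomDNA(clen, background)
      geneRows <- c(geneRows, rows)
    }
    df <- do.call(rbind, geneRows)
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- sprintf("contig%02d", seq_len(nContigs))
    genes <- GenomicRanges::GRanges(df$contig,
      IRanges::IRanges(df$start, df$end), strand = df$strand)
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
      gene_id = df$gene_id, product = rep("hypothetical protein", nrow(df)),
      tf_family = rep(NA_character_, nrow(df)),
      categories = IRanges::CharacterList(rep(list(character()), nrow(df))))
    out <- list(genome = genome, genes = genes, truthOperon = truth,
                annotationFile = NULL, genomeFile = NULL)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      out$genomeFile <- file.path(dir, "genome.fasta")
      out$annotationFile <- file.path(dir, "genes.gff3")
      Biostrings::writeXStringSet(genome, out$genomeFile)
      writeGenes(genes, out$annotationFile)
    }
    out
  })
}

#' Plant motif instances into promoter regions
#'
#' For every planted arc (family -> operon) a site is sampled from the
#' family's PSSM (independent categorical draws per position), verified to
#' pass the scan threshold under the exact score model (resampled up to
#' 100 times otherwise), and written into a promoter of the operon at a
#' recorded offset and strand, avoiding previously planted sites. Both the
#' promoter table and the genome sequence are updated so the pipeline can
#' rediscover the sites from the FASTA.
#'
#' @param genome named DNAStringSet (modified copy returned).
#' @param promoters promoter table from [extractPromoters()].
#' @param pssms named list family -> [PSSM-class].
#' @param truthArcs data.frame(family, operon) to plant.
#' @param seed RNG seed.
#' @param pThreshold scan threshold the sites must pass.
#' @param background background model for the score models.
#' @return list(genome, promoters, sites = data.frame(family, promoter_id,
#'   offset, strand, p_value)).
#' @export
plantMotifs <- function(genome, promoters, pssms, truthArcs, seed,
                        pThreshold = 1e-5,
                        background = c(A = .25, C = .25, G = .25, T = .25)) {
  models <- lapply(pssms, buildScoreModel, background = background)
  down <- strsplit(promoters$downstream_operons, ";", fixed = TRUE)
  occupied <- rep(list(integer(0)), nrow(promoters))
  sites <- list()
  withSeed(seed, {
    for (i in seq_len(nrow(truthArcs))) {
      fam <- truthArcs$family[i]; op <- truthArcs$operon[i]
      pr <- which(vapply(down, function(d) op %in% d, logical(1)))
      if (!length(pr)) stop("operon ", op, " has no promoter to plant into")
      pr <- pr[1]
      p <- pssms[[fam]]; m <- models[[fam]]
      w <- motifWidth(p)
      L <- promoters$length[pr]
      if (L <= w) stop("promoter ", promoters$promoter_id[pr],
                       " shorter than motif of ", fam)
      site <- NULL
      for (try in 1:100) {
        draw <- vapply(seq_len(w), function(j)
          sample(1:4, 1, prob = p@probs[, j]), integer(1))
        sc <- sum(m@scores[cbind(draw, seq_len(w))])
        pv <- scorePvalue(m, sc)
        if (pv <= pThreshold) { site <- list(draw = draw, p = pv); break }
      }
      if (is.null(site))
        stop("could not sample a passing site for ", fam, " after 100 draws",
             sprintf(" (motif information content %.1f bits)",
                     informationContent(p)))
      # free, non-overlapping offset
      cand <- setdiff(seq_len(L - w + 1L),
                      unlist(lapply(occupied[[pr]], function(o)
                        (o - w + 1L):(o + w - 1L))))
      if (!length(cand)) stop("promoter ", promoters$promoter_id[pr],
                              " has no free room for another site")
      off <- resample(cand)
      strand <- sample(c("+", "-"), 1)
      seqChars <- DNA_LETTERS[site$draw]
      if (strand == "-")
        seqChars <- rev(c(A = "T", C = "G", G = "C", T = "A")[seqChars])
      siteSeq <- paste(seqChars, collapse = "")
      old <- promoters$sequence[pr]
      promoters$sequence[pr] <- paste0(substr(old, 1, off - 1), siteSeq,
                                       substr(old, off + w, L))
      ctg <- promoters$contig[pr]
      gstart <- promoters$start[pr] + off - 1L
      genome[[ctg]] <- Biostrings::replaceAt(
        genome[[ctg]], IRanges::IRanges(gstart, gstart + w - 1L), siteSeq)
      occupied[[pr]] <- c(occupied[[pr]], off)
      sites[[length(sites) + 1]] <- data.frame(
        family = fam, promoter_id = promoters$promoter_id[pr],
        offset = off, strand = strand, p_value = site$p)
    }
  })
  list(genome = genome, promoters = promoters,
       sites = do.call(rbind, sites))
}

logUnif <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Plant an affinity network with known co-regulation ground truth
#'
#' Builds a TF hierarchy with designated in-degree-0 primaries, exactly
#' `nCycles` directed cycles (back-arcs are added one at a time and
#' verified by cycle enumeration), category-labelled operon leaves each
#' regulated directly by its category's apex TF ("signal" arcs, p-values
#' log-uniform on [1e-8, 1e-5]), and decoy arcs (p log-uniform on
#' (1e-5, 1e-4]) from other TFs, which by construction belong to no
#' minimum-weight V-shape (a decoy never comes from the target's own
#' category apex, and signal arcs always have the lower p, hence a weight
#' no larger).
#'
#' @param nTfFamilies number of TF family nodes.
#' @param nMetabolicOperons number of operon leaves; must equal
#'   `sum(categories)`.
#' @param categories named integer vector of category sizes.
#' @param nPrimaries number of in-degree-0 TFs.
#' @param nCycles number of directed cycles to plant.
#' @param nTfTfArcs total TF-TF arcs (default: a connected hierarchy plus
#'   a few cross arcs).
#' @param nDecoyArcs number of decoy TF->operon arcs.
#' @param seed RNG seed.
#' @return list(network = [AffinityNetwork-class] with weights not yet
#'   assigned, truth = list(signalArcs, decoyArcs, tfArcs, primaries,
#'   apexes, nCycles, categories, seed)).
#' @export
plantNetwork <- function(nTfFamilies, nMetabolicOperons = sum(categories),
                         categories, nPrimaries = max(1L, nTfFamilies %/% 4L),
                         nCycles = 0L, nTfTfArcs = NULL, nDecoyArcs = NULL,
                         seed) {
  stopifnot(nPrimaries <= nTfFamilies,
            nMetabolicOperons == sum(categories))
  tf <- sprintf("F%02d", seq_len(nTfFamilies))
  ops <- sprintf("O%02d", seq_len(nMetabolicOperons))
  withSeed(seed, {
    # hierarchy: every non-primary gets one parent among earlier TFs
    tfArcs <- NULL
    if (nTfFamilies > nPrimaries) {
      child <- (nPrimaries + 1L):nTfFamilies
      parent <- vapply(child, function(i) resample(seq_len(i - 1L)),
                       integer(1))
      tfArcs <- data.frame(source = tf[parent], target = tf[child])
    }
    baseline <- if (is.null(tfArcs)) 0L else nrow(tfArcs)
    if (is.null(nTfTfArcs))
      nTfTfArcs <- baseline + nCycles + max(0L, nTfFamilies %/% 3L)
    nCross <- nTfTfArcs - baseline - nCycles
    if (nCross < 0) stop("nTfTfArcs too small for the hierarchy and cycles")
    key <- function(d) paste(d$source, d$target)
    tries <- 0
    while (nCross > 0 && tries < 1000) {
      tries <- tries + 1
      i <- resample(seq_len(nTfFamilies))
      pool <- setdiff((nPrimaries + 1L):nTfFamilies, seq_len(i))
      if (!length(pool)) next
      j <- resample(pool)
      cand <- data.frame(source = tf[i], target = tf[j])
      if (key(cand) %in% key(tfArcs)) next
      tfArcs <- rbind(tfArcs, cand)
      nCross <- nCross - 1
    }
    if (nCross > 0) stop("could not place the requested TF-TF cross arcs")
    # back-arcs creating exactly one new cycle each
    added <- 0L; tries <- 0
    while (added < nCycles && tries < 2000) {
      tries <- tries + 1
      pool <- (nPrimaries + 1L):nTfFamilies
      if (length(pool) < 2) stop("need at least two non-primary TFs to plant cycles")
      i <- resample(pool)
      j <- resample(setdiff(pool, i))
      cand <- data.frame(source = tf[i], target = tf[j])
      if (key(cand) %in% key(tfArcs)) next
      trial <- rbind(tfArcs, cand)
      nc <- length(enumerateCycles(trial, cap = 1000L))
      if (nc == added + 1L) { tfArcs <- trial; added <- added + 1L }
    }
    if (added < nCycles) stop("could not plant the requested cycle count")
    # categories and their apex TFs
    catNames <- names(categories)
    opCat <- rep(catNames, categories)
    catMap <- stats::setNames(as.list(opCat), ops)
    apexes <- stats::setNames(sample(tf, length(catNames), replace = FALSE),
                              catNames)
    signal <- data.frame(source = apexes[opCat], target = ops,
                         row.names = NULL)
    if (is.null(nDecoyArcs))
      nDecoyArcs <- max(1L, round(0.4 * nMetabolicOperons))
    decoy <- NULL; tries <- 0
    while ((if (is.null(decoy)) 0 else nrow(decoy)) < nDecoyArcs &&
           tries < 2000) {
      tries <- tries + 1
      op <- resample(ops)
      pool <- setdiff(tf, apexes[catMap[[op]]])
      if (!length(pool)) break   # single-TF networks admit no decoys
      cand <- data.frame(source = resample(pool), target = op)
      if (!is.null(decoy) && key(cand) %in% key(decoy)) next
      decoy <- rbind(decoy, cand)
    }
    nTT <- if (is.null(tfArcs)) 0L else nrow(tfArcs)
    parts <- list(
      if (nTT) data.frame(tfArcs, kind = "tf-tf",
                          p = logUnif(nTT, 1e-8, 1e-5)),
      data.frame(signal, kind = "tf-operon",
                 p = logUnif(nrow(signal), 1e-8, 1e-5)),
      if (!is.null(decoy)) data.frame(decoy, kind = "tf-operon",
                                      p = logUnif(nrow(decoy), 1.0001e-5,
                                                  1e-4)))
    arcsDf <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    rownames(arcsDf) <- NULL
    net <- newNetwork("AffinityNetwork", tf, ops, arcsDf,
                      categories = catMap)
    truth <- list(signalArcs = signal, decoyArcs = decoy, tfArcs = tfArcs,
                  primaries = tf[seq_len(nPrimaries)], apexes = apexes,
                  nCycles = as.integer(nCycles), categories = catMap,
                  seed = seed)
    list(network = net, truth = truth)
  })
}

#' Signal/decoy recovery rates of a V-shape selection
#'
#' @param truth ground-truth list from [plantNetwork()].
#' @param selected selected arcs from [selectCoregulatoryArcs()].
#' @return list(signalRecovered, decoySelected) as fractions in [0, 1].
#' @export
recoveryRates <- function(truth, selected) {
  key <- function(d) paste(d$source, d$target)
  sel <- key(selected)
  list(signalRecovered = mean(key(truth$signalArcs) %in% sel),
       decoySelected = if (is.null(truth$decoyArcs)) 0 else
         mean(key(truth$decoyArcs) %in% sel))
}

#' Write planted ground truth as JSON
#' @param truth list from [plantNetwork()] or site list from
#'   [plantMotifs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Plant a co-regulatory network of exact composition
#'
#' Deterministically (given the seed) builds a [CoRegulatoryNetwork-class]
#' with the requested numbers of TF family nodes, in-degree-0 primaries,
#' category sizes and arcs of each kind. The TF hierarchy is a connected
#' DAG: every primary is given a designated child, the designated children
#' are chained, every other TF attaches to an earlier one, and cross arcs
#' fill the TF-TF arc budget; every operon gets one in-arc from its
#' category's apex TF and extra TF->operon arcs fill the remaining budget.
#' Arc p-values are log-uniform below the final arc threshold, so the
#' object passes the standard assembly filter.
#'
#' @param nTfFamilies,nPrimaries TF node counts (primaries have in-degree
#'   0).
#' @param categorySizes named integer vector; one operon node per unit.
#' @param nTfTfArcs,nTfOperonArcs arc budgets per kind.
#' @param seed RNG seed.
#' @return a [CoRegulatoryNetwork-class] with exactly the requested
#'   composition.
#' @export
plantCoregNetwork <- function(nTfFamilies, nPrimaries, categorySizes,
                              nTfTfArcs, nTfOperonArcs, seed) {
  nOps <- sum(categorySizes)
  stopifnot(nPrimaries < nTfFamilies,
            nTfTfArcs >= (nTfFamilies - nPrimaries) + (nPrimaries - 1),
            nTfOperonArcs >= nOps,
            length(names(categorySizes)) == length(categorySizes))
  tf <- sprintf("T%02d", seq_len(nTfFamilies))
  ops <- sprintf("O%02d", seq_len(nOps))
  opCat <- rep(names(categorySizes), categorySizes)
  withSeed(seed, {
    nonPrim <- (nPrimaries + 1L):nTfFamilies
    parent <- integer(nTfFamilies)
    for (i in nonPrim)
      parent[i] <- resample(seq_len(i - 1L))
    # every primary gets a designated child so the graph is connected
    for (k in seq_len(min(nPrimaries, length(nonPrim))))
      parent[nonPrim[k]] <- k
    tt <- data.frame(source = tf[parent[nonPrim]], target = tf[nonPrim])
    # chain the designated children to join the primary components
    nchain <- min(nPrimaries, length(nonPrim)) - 1L
    if (nchain > 0)
      tt <- rbind(tt, data.frame(source = tf[nonPrim[seq_len(nchain)]],
                                 target = tf[nonPrim[seq_len(nchain) + 1L]]))
    key <- function(d) paste(d$source, d$target)
    tt <- tt[!duplicated(key(tt)), , drop = FALSE]
    tries <- 0
    while (nrow(tt) < nTfTfArcs && tries < 20000) {
      tries <- tries + 1
      j <- resample(nonPrim)
      i <- resample(seq_len(j - 1L))
      cand <- data.frame(source = tf[i], target = tf[j])
      if (key(cand) %in% key(tt)) next
      tt <- rbind(tt, cand)
    }
    if (nrow(tt) != nTfTfArcs)
      stop("cannot place ", nTfTfArcs, " distinct TF-TF arcs")
    apex <- stats::setNames(resample(tf, length(categorySizes)),
                            names(categorySizes))
    to <- data.frame(source = apex[opCat], target = ops)
    tries <- 0
    while (nrow(to) < nTfOperonArcs && tries < 20000) {
      tries <- tries + 1
      cand <- data.frame(source = resample(tf), target = resample(ops))
      if (key(cand) %in% key(to)) next
      to <- rbind(to, cand)
    }
    if (nrow(to) != nTfOperonArcs)
      stop("cannot place ", nTfOperonArcs, " distinct TF-operon arcs")
    sel <- rbind(data.frame(tt, kind = "tf-tf"),
                 data.frame(to, kind = "tf-operon"))
    sel$p <- logUnif(nrow(sel), 1e-8, 9e-5)
    sel <- assignWeights(sel)
    sel$provenance <- "planted"
    filterAndAssemble(sel, 9e-5,
                      categories = stats::setNames(as.list(opCat), ops))
  })
}
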