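#' Predict operons by the intergenic-distance rule
#'
#' Two consecutive genes on the same strand of one contig are placed in the
#' same operon iff the number of bases strictly between them,
#' `start(next) - end(prev) - 1`, is strictly below `maxGap`. A strand
#' change always splits. Overlapping same-strand genes (negative gap) are
#' merged. A gap of exactly `maxGap` splits (it is not `< maxGap`).
#'
#' @param genes GRanges sorted by (contig, start) as from [readGenes()].
#' @param maxGap integer bp threshold (default 50).
#' @return `data.frame` with columns `operon_id`, `contig`, `strand`,
#'   `genes` (semicolon-joined ordered member ids), `start`, `end`,
#'   `n_genes`.
#' @examples
#' files <- generateGenome(nGenes = 10, seed = 7, dir = tempfile())
#' genes <- readGenes(files$annotationFile, files$genomeFile)
#' callOperons(genes)
#' @export
callOperons <- function(genes, maxGap = 50L) {
  contig <- as.character(GenomicRanges::seqnames(genes))
  st <- GenomicRanges::start(genes)
  en <- GenomicRanges::end(genes)
  strand <- as.character(GenomicRanges::strand(genes))
  if (length(genes) && any(order(contig, st) != seq_along(genes)))
    stop("genes must be sorted by (contig, start)")
  n <- length(genes)
  if (n == 0)
    return(data.frame(operon_id = character(), contig = character(),
                      strand = character(), genes = character(),
                      start = integer(), end = integer(),
                      n_genes = integer()))
  brk <- logical(n)
  brk[1] <- TRUE
  if (n > 1) {
    same_contig <- contig[-1] == contig[-n]
    same_strand <- strand[-1] == strand[-n]
    gap <- st[-1] - en[-n] - 1L
    brk[-1] <- !(same_contig & same_strand & gap < maxGap)
  }
  grp <- cumsum(brk)
  ids <- genes$gene_id
  out <- do.call(rbind, lapply(split(seq_len(n), grp), function(ix) {
    data.frame(contig = contig[ix[1]], strand = strand[ix[1]],
               genes = paste(ids[ix], collapse = ";"),
               start = min(st[ix]), end = max(en[ix]),
               n_genes = length(ix))
  }))
  out <- data.frame(operon_id = sprintf("OP%04d", seq_len(nrow(out))), out,
                    row.names = NULL)
  out
}

#' Member gene ids of each operon
#' @param operons operon table from [callOperons()].
#' @return named list operon_id -> character vector of gene ids, 5' to 3'
#'   in genomic order for '+' operons (reversed reading for '-' operons is
#'   not applied; members are stored in genomic order).
#' @export
operonGenes <- function(operons) {
  stats::setNames(strsplit(operons$genes, ";", fixed = TRUE),
                  operons$operon_id)
}

#' Extract putative promoter intergenic regions
#'
#' Every intergenic interval strictly longer than `maxGap` bp is reported
#' once, with its forward-strand sequence. An interval is a promoter of
#' each flanking operon whose 5'-most gene abuts it — the right neighbour
#' when it is on '+', the left neighbour when it is on '-' — so a region
#' between divergently transcribed operons serves two operons, and one
#' between convergent operons serves none (it is kept with
#' `n_downstream = 0` and never scanned). Contig-end flanks longer than
#' `maxGap` upstream of the first/last operon are treated as promoters and
#' flagged `contig_end`.
#'
#' @param operons table from [callOperons()].
#' @param genes the GRanges the operons were called from (unused beyond
#'   coordinate checks; operon spans carry all needed positions).
#' @param genome named [Biostrings::DNAStringSet] of contigs.
#' @param maxGap same threshold used for operon calling.
#' @return `data.frame` with `promoter_id`, `contig`, `start`, `end`,
#'   `length`, `downstream_operons` (semicolon-joined, possibly ""),
#'   `n_downstream`, `contig_end`, `sequence` (forward strand).
#' @export
extractPromoters <- function(operons, genes, genome, maxGap = 50L) {
  rows <- list()
  for (ctg in unique(operons$contig)) {
    ops <- operons[operons$contig == ctg, , drop = FALSE]
    ops <- ops[order(ops$start), , drop = FALSE]
    clen <- Biostrings::width(genome)[match(ctg, names(genome))]
    if (is.na(clen)) stop("contig absent from genome: ", ctg)
    add <- function(s, e, down, contig_end) {
      s <- as.integer(s); e <- as.integer(e)
      if (s < 1 || e > clen) stop("promoter interval outside contig ", ctg)
      rows[[length(rows) + 1]] <<- data.frame(
        contig = ctg, start = s, end = e, length = e - s + 1L,
        downstream_operons = paste(down, collapse = ";"),
        n_downstream = length(down), contig_end = contig_end)
    }
    # left contig end
    if (ops$start[1] - 1 > maxGap && ops$strand[1] == "+")
      add(1L, ops$start[1] - 1L, ops$operon_id[1], TRUE)
    # between consecutive operons
    if (nrow(ops) > 1) for (i in seq_len(nrow(ops) - 1)) {
      s <- ops$end[i] + 1L; e <- ops$start[i + 1] - 1L
      len <- e - s + 1L
      if (len > maxGap) {
        down <- character()
        if (ops$strand[i + 1] == "+") down <- c(down, ops$operon_id[i + 1])
        if (ops$strand[i] == "-") down <- c(down, ops$operon_id[i])
        add(s, e, down, FALSE)
      }
    }
    # right contig end
    nlast <- nrow(ops)
    if (clen - ops$end[nlast] > maxGap && ops$strand[nlast] == "-")
      add(ops$end[nlast] + 1L, clen, ops$operon_id[nlast], TRUE)
  }
  if (!length(rows))
    return(data.frame(promoter_id = character(), contig = character(),
                      start = integer(), end = integer(), length = integer(),
                      downstream_operons = character(),
                      n_downstream = integer(), contig_end = logical(),
                      sequence = character()))
  out <- do.call(rbind, rows)
  out <- data.frame(promoter_id = sprintf("PR%04d", seq_len(nrow(out))), out,
                    row.names = NULL)
  out$sequence <- vapply(seq_len(nrow(out)), function(i)
    as.character(Biostrings::subseq(genome[[out$contig[i]]],
                                    out$start[i], out$end[i])),
    character(1))
  out
}

#' Write the operon table / promoter FASTA
#' @param operons table from [callOperons()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOperons <- function(operons, path) {
  utils::write.table(operons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeOperons
#' @param promoters table from [extractPromoters()].
#' @export
writePromoters <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(promoters$sequence)
  names(seqs) <- paste0(promoters$promoter_id, "|",
                        promoters$downstream_operons)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
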