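# Closed-loop scenario: a synthetic genome with TF genes, pathway
# categories on target operons, motifs planted into real promoter
# sequence, and all input files written to disk for the pipeline.
makeScenario <- function(seed, nGenes = 36, dir = tempfile(),
                         nCatA = 3, nCatB = 2, motifWidth = 12) {
  g <- generateGenome(nGenes, seed = seed)
  op <- callOperons(g$genes)
  pr <- extractPromoters(op, g$genes, g$genome)
  usable <- pr[pr$n_downstream > 0 & pr$length >= 3 * motifWidth, ]
  targets <- unique(unlist(strsplit(usable$downstream_operons, ";")))
  need <- nCatA + nCatB + 2
  if (length(targets) < need)
    return(makeScenario(seed + 1000, nGenes, dir, nCatA, nCatB, motifWidth))
  set.seed(seed)
  picked <- sample(targets, need)
  catA <- picked[seq_len(nCatA)]
  catB <- picked[nCatA + seq_len(nCatB)]
  tfOps <- picked[nCatA + nCatB + 1:2]
  genes <- g$genes
  og <- operonGenes(op)
  setCat <- function(genes, operons, cat) {
    ix <- match(unlist(og[operons]), genes$gene_id)
    genes$categories[ix] <- lapply(as.list(genes$categories[ix]),
                                   function(x) unique(c(x, cat)))
    genes
  }
  genes <- setCat(genes, catA, "RISC oxidation")
  genes <- setCat(genes, catB, "Heme biosynthesis")
  fams <- c("CysB", "Fur")
  genes$tf_family[match(og[[tfOps[1]]][1], genes$gene_id)] <- fams[1]
  genes$tf_family[match(og[[tfOps[2]]][1], genes$gene_id)] <- fams[2]
  pssms <- list(CysB = randomPssm(motifWidth, seed = seed + 7, "CysB"),
                Fur = randomPssm(motifWidth, seed = seed + 8, "Fur"))
  truthArcs <- rbind(
    data.frame(family = fams[1], operon = catA),
    data.frame(family = fams[2], operon = catB),
    data.frame(family = fams[1], operon = tfOps[2]))  # tf-tf cascade
  planted <- plantMotifs(g$genome, pr, pssms, truthArcs, seed + 9)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(genome = file.path(dir, "genome.fasta"),
                annotation = file.path(dir, "genes.gff3"),
                motifs = file.path(dir, "motifs.meme"))
  Biostrings::writeXStringSet(planted$genome, files$genome)
  writeGenes(genes, files$annotation)
  writeMotifs(pssms, files$motifs)
  list(files = files, genes = genes, operons = op, promoters = planted$promoters,
       sites = planted$sites, truthArcs = truthArcs, pssms = pssms,
       catA = catA, catB = catB, tfOps = tfOps, dir = dir)
}
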