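#' Run the full pipeline end to end
#'
#' Stages, in order: operon calling, promoter extraction, motif scanning,
#' affinity network assembly, quartile weighting, V-shape selection, final
#' p filter + family collapsing, topology analysis. All intermediate
#' artifacts, a topology report and a run manifest (config snapshot, input
#' checksums, per-stage node/arc counts) are written to `outdir`.
#'
#' @param config a [PipelineConfig-class] or path to its YAML form.
#' @param genomeFile FASTA of contigs.
#' @param annotationFile GFF3 of genes (optionally with `tf_family` and
#'   `category` attributes).
#' @param motifFile MEME minimal-format motif file (motif name = family).
#' @param categoryFile optional TSV gene -> category (merged with GFF
#'   attributes).
#' @param outdir output directory (created).
#' @return the manifest list, invisibly; artifacts on disk.
#' @export
runPipeline <- function(config, genomeFile, annotationFile, motifFile,
                        categoryFile = NULL, outdir) {
  if (is.character(config)) config <- readConfig(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  genes <- stage("read", readGenes(annotationFile, genomeFile))
  genome <- Biostrings::readDNAStringSet(genomeFile)
  names(genome) <- sub("\\s.*", "", names(genome))
  pssms <- stage("read", readMotifs(motifFile))
  names(pssms) <- vapply(pssms, function(p) p@family, character(1))
  geneCats <- stats::setNames(as.list(genes$categories), genes$gene_id)
  geneCats <- geneCats[lengths(geneCats) > 0]
  if (!is.null(categoryFile)) {
    extra <- readPathwayCategories(categoryFile, config)
    for (g in names(extra))
      geneCats[[g]] <- sort(unique(c(geneCats[[g]], extra[[g]])))
  }
  tfFamilies <- stats::setNames(genes$tf_family, genes$gene_id)
  tfFamilies <- tfFamilies[!is.na(tfFamilies)]

  operons <- stage("operons", callOperons(genes, config@operonMaxGap))
  writeOperons(operons, file.path(outdir, "operons.tsv"))
  promoters <- stage("promoters",
                     extractPromoters(operons, genes, genome,
                                      config@operonMaxGap))
  writePromoters(promoters, file.path(outdir, "promoters.fasta"))
  models <- lapply(pssms, buildScoreModel, background = config@background)
  matches <- stage("scan",
                   scanPromoters(models, promoters, config@scanPThreshold,
                                 config@confidentPThreshold))
  utils::write.table(matches, file.path(outdir, "matches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  affinity <- stage("affinity",
                    buildAffinityNetwork(matches, operons, promoters,
                                         tfFamilies, geneCats))
  writeNetwork(affinity, file.path(outdir, "affinity.tsv"))
  writeNetwork(affinity, file.path(outdir, "affinity.graphml"), "graphml")
  weighted <- stage("weights",
                    if (arcCount(affinity) > 0)
                      assignWeights(affinity, config@weightClasses)
                    else affinity)
  selected <- stage("vshapes",
                    if (arcCount(weighted) > 0)
                      selectCoregulatoryArcs(weighted) else
                        cbind(arcs(weighted),
                              provenance = character(0)))
  utils::write.table(selected, file.path(outdir, "selected_arcs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  coreg <- stage("filter",
                 filterAndAssemble(selected, config@finalArcPThreshold,
                                   categories = categoryMap(affinity)))
  writeNetwork(coreg, file.path(outdir, "coreg.tsv"))
  topo <- if (arcCount(coreg) > 0)
    stage("topology", topologyReport(coreg)) else NULL
  manifest <- list(
    tool = paste0("vshapes ",
                  as.character(utils::packageVersion("vshapes"))),
    seed = config@rngSeed,
    config = yaml::yaml.load(yaml::as.yaml(list(
      scanPThreshold = config@scanPThreshold,
      confidentPThreshold = config@confidentPThreshold,
      finalArcPThreshold = config@finalArcPThreshold,
      operonMaxGap = config@operonMaxGap,
      weightClasses = config@weightClasses))),
    inputs = as.list(tools::md5sum(c(genome = genomeFile,
                                     annotation = annotationFile,
                                     motifs = motifFile))),
    counts = list(
      genes = length(genes), operons = nrow(operons),
      promoters = sum(promoters$n_downstream > 0),
      matches = nrow(matches),
      affinity_nodes = nodeCount(affinity),
      affinity_arcs = arcCount(affinity),
      selected_arcs = nrow(selected),
      final_arcs = arcCount(coreg),
      final_tf_nodes = length(tfNodes(coreg)),
      final_operon_nodes = length(operonNodes(coreg))))
  stopifnot(manifest$counts$final_arcs <= manifest$counts$selected_arcs,
            manifest$counts$selected_arcs <= manifest$counts$affinity_arcs)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(renderReport(manifest, topo), file.path(outdir, "report.txt"))
  invisible(manifest)
}

fmtTable <- function(m) {
  txt <- cbind(rownames(m), apply(m, 2, as.character))
  txt <- rbind(c("", colnames(m)), txt)
  widths <- apply(nchar(txt), 2, max)
  apply(txt, 1, function(r)
    paste(mapply(formatC, r, width = widths), collapse = "  "))
}

#' Render a plain-text analysis report
#'
#' Deterministic human-readable rendering of the manifest and topology
#' report: per-stage counts, the reachability table, the exclusivity table
#' with "n (p%)" entries, hierarchy levels and the degree table.
#'
#' @param manifest list from [runPipeline()].
#' @param topo a [TopologyReport-class] or NULL.
#' @return character vector of report lines.
#' @export
renderReport <- function(manifest, topo = NULL) {
  out <- c("vshapes run report", "==================", "",
           sprintf("%-18s %s", names(manifest$counts),
                   unlist(manifest$counts)), "")
  if (is.null(topo) ||
      (length(topo@regulatoryTable) == 0 && !nrow(topo@hubs)))
    return(c(out, "No co-regulation found."))
  nl <- vapply(topo@levels, function(x) x$nLevels, integer(1))
  out <- c(out,
    sprintf("cycles: %d; minimum feedback arc set size: %d (%d optima)",
            length(topo@cycles), topo@fasSize, length(topo@feedbackArcSets)),
    sprintf("hierarchy levels per feedback-arc choice: %s",
            paste(nl, collapse = ", ")),
    sprintf("TF-TF tree distance: %d of %d arcs (%.1f%%)",
            topo@treeDistance$removals, topo@treeDistance$nArcs,
            topo@treeDistance$percentage),
    sprintf("primary regulators: %s",
            paste(topo@primaryRegulators, collapse = ", ")), "",
    "Reachable operons per primary regulator and category:",
    fmtTable(topo@regulatoryTable), "",
    "Operons exclusively controlled by one primary regulator:")
  ex <- topo@exclusivityTable
  exm <- as.matrix(ex[, c("n_operons", "total_label",
                          setdiff(names(ex), c("category", "n_operons",
                                               "total_exclusive", "pct",
                                               "total_label")))])
  rownames(exm) <- ex$category
  deg <- as.matrix(topo@hubs[, c("in_degree", "out_degree", "total_degree")])
  rownames(deg) <- topo@hubs$node
  c(out, fmtTable(exm), "", "Degrees:", fmtTable(deg))
}
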