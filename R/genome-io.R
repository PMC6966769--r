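#' Read gene records from GFF3 + FASTA
#'
#' Reads gene coordinates (1-based inclusive, GFF3 convention — used
#' unchanged everywhere in this package) and checks them against the
#' genome. Attributes `product`, `tf_family` and `category` (comma
#' separated) are retained when present.
#'
#' @param annotationFile GFF3 path; rows with type "gene" or "CDS" are used.
#' @param genomeFile FASTA path of the contigs.
#' @return A [GenomicRanges::GRanges] sorted by (contig, start) with
#'   metadata columns `gene_id`, `product`, `tf_family` (NA when not a TF
#'   candidate) and `categories` (a CharacterList).
#' @examples
#' files <- generateGenome(nGenes = 6, seed = 1, dir = tempfile())
#' genes <- readGenes(files$annotationFile, files$genomeFile)
#' genes
#' @export
readGenes <- function(annotationFile, genomeFile) {
  genome <- Biostrings::readDNAStringSet(genomeFile)
  names(genome) <- sub("\\s.*", "", names(genome))
  gr <- rtracklayer::import(annotationFile, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("gene", "CDS")]
  if (length(gr) == 0) stop("no gene or CDS records in ", annotationFile)
  contigs <- as.character(GenomicRanges::seqnames(gr))
  missing <- setdiff(unique(contigs), names(genome))
  if (length(missing))
    stop("annotation references contigs absent from the FASTA: ",
         paste(missing, collapse = ", "))
  if (any(GenomicRanges::end(gr) < GenomicRanges::start(gr)))
    stop("gene with end < start in ", annotationFile)
  over <- GenomicRanges::end(gr) > Biostrings::width(genome)[match(contigs, names(genome))]
  if (any(over))
    stop("gene coordinates exceed contig length: ",
         paste(utils::head(gr$ID[over], 3), collapse = ", "))
  mc <- S4Vectors::mcols(gr)
  gene_id <- if (!is.null(mc$ID)) as.character(mc$ID) else
    sprintf("gene%05d", seq_along(gr))
  product <- if (!is.null(mc$product)) as.character(mc$product) else
    rep(NA_character_, length(gr))
  tf_family <- if (!is.null(mc$tf_family)) as.character(mc$tf_family) else
    rep(NA_character_, length(gr))
  tf_family[!is.na(tf_family) & tf_family == ""] <- NA_character_
  cats <- if (!is.null(mc$category)) {
    raw <- mc$category   # multi-valued GFF3 attributes parse as a List
    if (is.list(raw) || is(raw, "List"))
      lapply(as.list(raw), function(x) {
        x <- as.character(x)
        x[!is.na(x) & x != ""]
      })
    else lapply(as.character(raw), function(x)
      if (is.na(x) || x == "") character() else
        strsplit(x, ",", fixed = TRUE)[[1]])
  } else rep(list(character()), length(gr))
  out <- GenomicRanges::GRanges(contigs,
    IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)),
    strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = gene_id, product = product, tf_family = tf_family,
    categories = IRanges::CharacterList(cats))
  std <- as.character(GenomicRanges::strand(out))
  if (any(!std %in% c("+", "-")))
    stop("every gene must have strand '+' or '-'")
  out[order(as.character(GenomicRanges::seqnames(out)),
            GenomicRanges::start(out))]
}

#' Write gene records as GFF3
#'
#' Inverse of [readGenes()]; `readGenes(writeGenes(x))` preserves
#' coordinates, strands and attributes exactly.
#'
#' @param genes GRanges as returned by [readGenes()].
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
writeGenes <- function(genes, path) {
  attr_of <- function(i) {
    a <- sprintf("ID=%s", genes$gene_id[i])
    if (!is.na(genes$product[i]))
      a <- paste0(a, ";product=", genes$product[i])
    if (!is.na(genes$tf_family[i]))
      a <- paste0(a, ";tf_family=", genes$tf_family[i])
    cats <- genes$categories[[i]]
    if (length(cats)) a <- paste0(a, ";category=", paste(cats, collapse = ","))
    a
  }
  lines <- vapply(seq_along(genes), function(i) {
    paste(as.character(GenomicRanges::seqnames(genes))[i], "vshapes", "gene",
          GenomicRanges::start(genes)[i], GenomicRanges::end(genes)[i], ".",
          as.character(GenomicRanges::strand(genes))[i], ".", attr_of(i),
          sep = "\t")
  }, character(1))
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Accepts MEME version 4/5 minimal motif files with alphabet ACGT only.
#' Letter-probability columns are renormalised to sum to 1.
#'
#' @param motifFile path to a MEME minimal-format file.
#' @return list of [PSSM-class]; the MOTIF name is used as the TF family.
#' @examples
#' p <- randomPssm(width = 8, seed = 1, family = "LysR")
#' f <- tempfile(fileext = ".meme")
#' writeMotifs(list(p), f)
#' readMotifs(f)
#' @export
readMotifs <- function(motifFile) {
  lines <- trimws(readLines(motifFile))
  if (!length(lines) || !grepl("^MEME version", lines[1]))
    stop("not a MEME minimal-format file (missing 'MEME version' header): ",
         motifFile)
  al <- grep("^ALPHABET", lines, value = TRUE)
  if (length(al) && !grepl("ACGT", gsub("[^A-Z]", "", al[1])))
    stop("only the ACGT alphabet is supported, got: ", al[1])
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) {
    warning("no motifs found in ", motifFile)
    return(list())
  }
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    name <- strsplit(lines[starts[k]], "\\s+")[[1]][2]
    i <- starts[k] + 1
    while (i <= length(lines) && !grepl("^letter-probability matrix", lines[i]))
      i <- i + 1
    if (i > length(lines))
      stop("motif '", name, "' has no letter-probability matrix (line ",
           starts[k], ")")
    w <- suppressWarnings(as.integer(
      sub(".*w\\s*=\\s*(\\d+).*", "\\1", lines[i])))
    rows <- list(); i <- i + 1
    while (i <= length(lines) && grepl("^[0-9.eE+-]", lines[i])) {
      rows[[length(rows) + 1]] <- as.numeric(strsplit(lines[i], "\\s+")[[1]])
      i <- i + 1
    }
    if (!is.na(w) && length(rows) != w)
      stop("motif '", name, "': expected ", w, " rows, found ", length(rows))
    if (!length(rows)) stop("motif '", name, "' has zero width")
    m <- t(do.call(rbind, rows))
    out[[k]] <- pssm(name, m)
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pssms list of [PSSM-class].
#' @param path output path.
#' @param background named A/C/G/T frequencies written to the header.
#' @return `path`, invisibly.
#' @export
writeMotifs <- function(pssms, path,
                        background = c(A = .25, C = .25, G = .25, T = .25)) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_LETTERS, background[DNA_LETTERS]),
                     collapse = " "), ""), con)
  for (p in pssms) {
    writeLines(sprintf("MOTIF %s", p@family), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       motifWidth(p)), con)
    apply(p@probs, 2, function(col)
      writeLines(paste(sprintf("%.6f", col), collapse = " "), con))
    writeLines("", con)
  }
  invisible(path)
}

#' Read a gene -> pathway category table
#'
#' Two-column TSV (gene id, category). A gene may appear under several
#' categories; duplicated rows are deduplicated with a warning; categories
#' outside `config@categoryNames` are an error.
#'
#' @param path TSV path with a header row.
#' @param config a [PipelineConfig-class] supplying the category vocabulary.
#' @return named list: gene id -> character vector of categories.
#' @export
readPathwayCategories <- function(path, config = pipelineConfig()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) return(list())
  names(tab)[1:2] <- c("gene_id", "category")
  unknown <- setdiff(unique(tab$category), config@categoryNames)
  if (length(unknown))
    stop("unknown pathway category: ", paste(unknown, collapse = ", "))
  dup <- duplicated(tab[, c("gene_id", "category")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (gene, category) rows deduplicated")
    tab <- tab[!dup, ]
  }
  split(tab$category, tab$gene_id)
}

#' Write a gene -> category table
#' @param categories named list gene id -> categories.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePathwayCategories <- function(categories, path) {
  df <- data.frame(
    gene_id = rep(names(categories), lengths(categories)),
    category = unlist(categories, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a network
#'
#' TSV dialect columns: source, target, arc_kind, p_value, weight,
#' selected_flag ('.' for missing). `readNetwork(writeNetwork(x))` is the
#' identity on structure and attributes. GraphML goes through igraph and is
#' readable by any standard graph tool.
#'
#' @param network an [AffinityNetwork-class] or [CoRegulatoryNetwork-class].
#' @param path output path.
#' @param dialect "tsv-edgelist" or "graphml".
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path, dialect = c("tsv-edgelist", "graphml")) {
  dialect <- match.arg(dialect)
  a <- arcs(network)
  if (dialect == "tsv-edgelist") {
    df <- data.frame(
      source = a$source, target = a$target, arc_kind = a$kind,
      p_value = format(a$p, digits = 17),
      weight = if (!is.null(a$weight)) a$weight else ".",
      selected_flag = if (is(network, "CoRegulatoryNetwork")) "1" else ".")
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste0("# tf_nodes=", paste(tfNodes(network), collapse = ","),
                      " operon_nodes=", paste(operonNodes(network), collapse = ",")),
               con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    nodes <- data.frame(name = c(tfNodes(network), operonNodes(network)),
                        kind = c(rep("tf", length(tfNodes(network))),
                                 rep("operon", length(operonNodes(network)))))
    g <- igraph::graph_from_data_frame(
      data.frame(from = a$source, to = a$target, p = a$p, kind = a$kind),
      directed = TRUE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname writeNetwork
#' @param class class of the object to rebuild from a TSV edgelist.
#' @export
readNetwork <- function(path, class = "AffinityNetwork") {
  first <- readLines(path, n = 1)
  if (!grepl("^# tf_nodes=", first))
    stop("not a vshapes network TSV (missing node header): ", path)
  parse_set <- function(tag) {
    m <- sub(paste0(".*", tag, "="), "", first)
    m <- sub(" .*", "", m)
    if (m == "") character() else strsplit(m, ",", fixed = TRUE)[[1]]
  }
  tf <- parse_set("tf_nodes")
  op <- sub(".*operon_nodes=", "", first)
  op <- if (op == "") character() else strsplit(op, ",", fixed = TRUE)[[1]]
  tab <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE,
                           colClasses = "character")
  arcs <- data.frame(source = tab$source, target = tab$target,
                     kind = tab$arc_kind, p = as.numeric(tab$p_value))
  if (any(tab$weight != ".")) arcs$weight <- as.integer(tab$weight)
  newNetwork(class, tf, op, arcs)
}

#' Read / write the pipeline configuration as YAML
#' @param path YAML file mirroring the [PipelineConfig-class] fields.
#' @return a [PipelineConfig-class].
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- formals(pipelineConfig)
  args <- lapply(names(defaults), function(n) if (!is.null(y[[n]])) y[[n]] else
    eval(defaults[[n]]))
  names(args) <- names(defaults)
  if (!is.null(y$background)) args$background <- unlist(y$background)
  do.call(pipelineConfig, args)
}

#' @rdname readConfig
#' @param config a [PipelineConfig-class].
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(list(
    scanPThreshold = config@scanPThreshold,
    confidentPThreshold = config@confidentPThreshold,
    finalArcPThreshold = config@finalArcPThreshold,
    operonMaxGap = config@operonMaxGap,
    weightClasses = config@weightClasses,
    categoryNames = config@categoryNames,
    background = as.list(config@background),
    rngSeed = config@rngSeed), path)
  invisible(path)
}
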