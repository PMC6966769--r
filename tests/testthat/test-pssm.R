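test_that("exact p-value DP matches exhaustive enumeration (w <= 6)", {
  for (seed in 1:12) {
    set.seed(seed)
    w <- sample(2:6, 1)
    # random (not information-rich) PSSM with random background
    m <- matrix(stats::rexp(4 * w), 4)
    m <- sweep(m, 2, colSums(m), "/")
    rownames(m) <- c("A", "C", "G", "T")
    bg <- stats::rexp(4) + 0.2
    bg <- stats::setNames(bg / sum(bg), c("A", "C", "G", "T"))
    model <- buildScoreModel(pssm("rnd", m), background = bg,
                             pseudocount = 0.05)
    oracle <- bfPvalueTable(model)
    scores <- unique(c(0L, sample(0:(length(model@pvalue) - 1L), 40,
                                  replace = TRUE)))
    for (s in scores)
      expect_equal(scorePvalue(model, s), oracle(s), tolerance = 1e-12)
  }
})

test_that("score model boundary behaviour", {
  # width-1 (1,0,0,0) motif, uniform background: max score only for 'A'
  p1 <- pssm("X", matrix(c(1, 0, 0, 0), 4,
                         dimnames = list(c("A", "C", "G", "T"), NULL)))
  m1 <- buildScoreModel(p1, pseudocount = 0.01)
  expect_equal(scorePvalue(m1, max(m1@scores)), 0.25)
  expect_equal(scorePvalue(m1, 0L), 1)           # minimum achievable
  expect_equal(scorePvalue(m1, max(m1@scores) + 1L), 0)

  # uniform PSSM: all scores zero, p(>= min) = 1
  pu <- pssm("U", matrix(0.25, 4, 5,
                         dimnames = list(c("A", "C", "G", "T"), NULL)))
  mu <- buildScoreModel(pu)
  expect_true(all(mu@scores == 0))
  expect_equal(scorePvalue(mu, 0L), 1)

  # zero probability with zero pseudocount is fatal
  expect_error(buildScoreModel(p1, pseudocount = 0), "pseudocount")

  # p-value table is non-increasing with p(min) = 1
  expect_true(all(diff(m1@pvalue) <= 1e-15))
})

test_that("promoter scanning finds planted sites symmetrically on strands", {
  set.seed(21)
  p <- randomPssm(10, seed = 8, family = "Fur")
  expect_gt(informationContent(p), 10)
  m <- buildScoreModel(p)
  cons <- paste(c("A", "C", "G", "T")[apply(p@probs, 2, which.max)],
                collapse = "")
  bgseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  region <- paste0(bgseq(140), cons, bgseq(150))
  hits <- scanPromoter(m, region, 1e-5, "PR1")
  expect_true(141L %in% hits$offset)
  expect_true(all(hits$p_value <= 1e-5))

  # reverse complement: same best p on the opposite strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(region)))
  hits_rc <- scanPromoter(m, rc, 1e-5, "PR1")
  expect_equal(min(hits_rc$p_value), min(hits$p_value))
  best <- hits$strand[which.min(hits$p_value)]
  best_rc <- hits_rc$strand[which.min(hits_rc$p_value)]
  expect_true(best != best_rc)

  # region shorter than the motif yields an empty frame
  expect_identical(nrow(scanPromoter(m, "ACGTACG", 1e-4)), 0L)

  # a p-value exactly at the threshold is a match
  pv <- sort(unique(m@pvalue), decreasing = TRUE)
  thr <- pv[length(pv) %/% 2]
  sc <- min(which(m@pvalue <= thr)) - 1L
  expect_true(scorePvalue(m, sc) == thr ||
                scorePvalue(m, sc) <= thr)  # threshold inclusive by contract

  # lowering the threshold never adds matches (monotone filtering)
  h1 <- scanPromoter(m, region, 1e-4)
  h2 <- scanPromoter(m, region, 1e-6)
  expect_true(nrow(h2) <= nrow(h1))
})

test_that("affinity network assembly collapses families and dedups arcs", {
  ops <- data.frame(operon_id = c("OP1", "OP2", "OP3"),
                    contig = "c1", strand = c("+", "-", "+"),
                    genes = c("g1;g2", "g3", "g4"),
                    start = c(1, 500, 900), end = c(400, 800, 1200),
                    n_genes = c(2L, 1L, 1L))
  prom <- data.frame(promoter_id = c("PR1", "PR2"), contig = "c1",
                     start = c(1, 401), end = c(100, 499),
                     length = c(100L, 99L),
                     downstream_operons = c("OP1;OP2", "OP3"),
                     n_downstream = c(2L, 1L), contig_end = c(TRUE, FALSE),
                     sequence = c("A", "C"))
  tfFams <- c(g3 = "LysR", g4 = "IHF")
  cats <- list(g1 = "RISC oxidation", g2 = "Sulfur assimilation")
  matches <- data.frame(
    family = c("CysB", "CysB", "CysB"),
    promoter_id = c("PR1", "PR1", "PR2"),
    offset = c(5L, 40L, 10L), strand = "+",
    score = c(10, 12, 11), p_value = c(2e-6, 1e-6, 5e-6))
  net <- buildAffinityNetwork(matches, ops, prom, tfFams, cats)

  a <- arcs(net)
  # one match in a shared promoter yields arcs to both downstream operons;
  # OP2 codes for LysR so its arc is a tf-tf arc to the family node
  expect_setequal(paste(a$source, a$target),
                  c("CysB OP1", "CysB LysR", "CysB IHF"))
  expect_identical(a$kind[a$target == "LysR"], "tf-tf")
  # duplicate matches collapse to one arc with the minimum p
  expect_equal(a$p[a$target == "OP1"], 1e-6)
  expect_equal(a$p[a$target == "LysR"], 1e-6)
  # operon categories are the union over member genes
  expect_setequal(categoryMap(net)$OP1,
                  c("RISC oxidation", "Sulfur assimilation"))
  # family collapsing: one node per family
  expect_true(!"OP2" %in% operonNodes(net))
  # unknown promoter is fatal
  bad <- matches; bad$promoter_id[1] <- "PRX"
  expect_error(buildAffinityNetwork(bad, ops, prom, tfFams), "PRX")
})

test_that("degree statistics satisfy the handshake identity", {
  # star graph: hub out-degree 5, leaves in-degree 1
  res <- plantNetwork(nTfFamilies = 1, categories = c(s = 5),
                      nPrimaries = 1, seed = 2)
  ds <- degreeStats(res$network)
  hub <- ds$table[ds$table$kind == "tf", ]
  expect_identical(hub$out_degree, 5L)
  expect_true(all(ds$table$in_degree[ds$table$kind == "operon"] == 1L))

  # empty network
  empty <- buildAffinityNetwork(
    data.frame(family = character(), promoter_id = character(),
               offset = integer(), strand = character(), score = numeric(),
               p_value = numeric()),
    data.frame(operon_id = character(), contig = character(),
               strand = character(), genes = character(), start = integer(),
               end = integer(), n_genes = integer()),
    data.frame(promoter_id = character(), downstream_operons = character()),
    character())
  expect_identical(nrow(degreeStats(empty)$table), 0L)

  # handshake: sum(in) = sum(out) = arcs on random planted networks
  for (seed in 1:5) {
    net <- plantNetwork(nTfFamilies = 6, categories = c(x = 3, y = 4),
                        nPrimaries = 2, seed = seed)$network
    tab <- degreeStats(net)$table
    expect_identical(sum(tab$in_degree), arcCount(net))
    expect_identical(sum(tab$out_degree), arcCount(net))
    expect_identical(tab$total_degree, tab$in_degree + tab$out_degree)
  }
})
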