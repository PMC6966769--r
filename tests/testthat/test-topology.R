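toyFig <- data.frame(source = c("X", "Y", "P", "Q", "R", "R", "S"),
                     target = c("Y", "X", "Q", "R", "P", "S", "P"))

test_that("cycle enumeration is exact and complete", {
  # DAG -> no cycles; 2-cycle -> one cycle
  expect_length(enumerateCycles(data.frame(source = "a", target = "b")), 0)
  two <- enumerateCycles(data.frame(source = c("X", "Y"),
                                    target = c("Y", "X")))
  expect_length(two, 1)
  expect_setequal(two[[1]], c("X", "Y"))
  # the two-feedback-arc toy has exactly three cycles
  expect_length(enumerateCycles(toyFig), 3)
  # agreement with permutation brute force on random digraphs
  for (seed in 1:20) {
    a <- randomDigraph(seed, nNodes = sample(3:6, 1), pArc = 0.35)
    if (!nrow(a)) next
    got <- enumerateCycles(a)
    want <- bfCycles(a)
    expect_identical(length(got), length(want))
    canon <- function(cyc) {
      i <- which(cyc == min(cyc))[1]
      paste(c(cyc[i:length(cyc)], cyc[seq_len(i - 1)]), collapse = ">")
    }
    expect_setequal(vapply(got, canon, character(1)),
                    vapply(want, canon, character(1)))
  }
  # the cap aborts with advice
  dense <- expand.grid(source = paste0("n", 1:8), target = paste0("n", 1:8),
                       stringsAsFactors = FALSE)
  dense <- dense[dense$source != dense$target, ]
  expect_error(enumerateCycles(dense, cap = 50L), "cap")
})

test_that("minimum feedback arc sets match exhaustive subset search", {
  # DAG: size 0, one empty set
  f0 <- minFeedbackArcSets(data.frame(source = "a", target = "b"))
  expect_identical(f0$size, 0L)
  expect_identical(nrow(f0$sets[[1]]), 0L)
  # toy: two cycles sharing a path plus an independent 2-cycle -> size 2,
  # optima = {2-cycle arc} x {shared-path arc}
  ft <- minFeedbackArcSets(toyFig)
  expect_identical(ft$size, 2L)
  expect_length(ft$sets, 4)
  for (s in ft$sets) {
    keys <- paste(s$source, s$target)
    expect_true(any(keys %in% c("X Y", "Y X")))
    expect_true(any(keys %in% c("P Q", "Q R")))
  }
  # random instances against brute force (size and full optimum sets)
  for (seed in 1:15) {
    a <- randomDigraph(seed + 100, nNodes = sample(3:5, 1), pArc = 0.4)
    if (!nrow(a)) next
    got <- minFeedbackArcSets(a)
    want <- bfFas(a)
    expect_identical(got$size, as.integer(want$size))
    canon <- function(s) paste(sort(paste(s$source, s$target)), collapse = "|")
    expect_setequal(vapply(got$sets, canon, character(1)),
                    vapply(want$sets, canon, character(1)))
    # removing any returned set leaves an acyclic graph
    for (s in got$sets) {
      left <- a[!(paste(a$source, a$target) %in%
                    paste(s$source, s$target)), , drop = FALSE]
      expect_length(enumerateCycles(left), 0)
    }
  }
})

test_that("level assignment is a longest-path layering", {
  chain <- data.frame(source = c("A", "B"), target = c("B", "C"))
  lv <- assignLevels(chain)
  expect_identical(lv$level, c(A = 1L, B = 2L, C = 3L))
  expect_identical(lv$nLevels, 3L)
  # shortcut arc: C still at level 3 (longest path wins)
  sc <- rbind(chain, data.frame(source = "A", target = "C"))
  expect_identical(assignLevels(sc)$level[["C"]], 3L)
  # every non-feedback arc strictly increases level, per FAS choice;
  # the level count is reported per choice and may differ
  ft <- minFeedbackArcSets(toyFig)
  counts <- integer(0)
  for (s in ft$sets) {
    lv <- assignLevels(toyFig, s)
    counts <- c(counts, lv$nLevels)
    keep <- !(paste(toyFig$source, toyFig$target) %in%
                paste(s$source, s$target))
    expect_true(all(lv$level[toyFig$target[keep]] >
                      lv$level[toyFig$source[keep]]))
  }
  expect_identical(length(counts), 4L)
  # an invalid feedback set leaves a cycle and is fatal
  expect_error(assignLevels(toyFig, ft$sets[[1]][1, , drop = FALSE]),
               "cycle")
})

test_that("tree distance: undirected cycle rank and Edmonds branching", {
  # arborescence: 0 removals in both senses
  arb <- data.frame(source = c("r", "r", "x"), target = c("x", "y", "z"))
  expect_identical(treeDistance(arb)$removals, 0L)
  expect_identical(treeDistance(arb, "branching")$removals, 0L)
  # node with in-degree 2, no cycles: 1 removal in the branching sense,
  # and 1 undirected cycle too (r->x->y, r->y)
  dd <- data.frame(source = c("r", "r", "x"), target = c("x", "y", "y"))
  expect_identical(treeDistance(dd, "branching")$removals, 1L)
  expect_identical(treeDistance(dd, "undirected")$removals, 1L)
  # percentage is rounded to one decimal
  expect_equal(treeDistance(dd)$percentage, 33.3)
  # empty subgraph
  expect_identical(treeDistance(dd[0, ])$removals, 0L)
  # branching removals equal |arcs| - brute-force maximum branching
  for (seed in 1:20) {
    a <- randomDigraph(seed + 40, nNodes = sample(3:6, 1), pArc = 0.35)
    if (!nrow(a)) next
    expect_identical(length(maxBranching(a)), bfMaxBranching(a))
    td <- treeDistance(a, "branching")
    expect_identical(td$removals, nrow(a) - bfMaxBranching(a))
    # the returned branching really is one: in-degree <= 1 and acyclic
    br <- a[maxBranching(a), , drop = FALSE]
    expect_true(all(table(br$target) <= 1))
    expect_length(enumerateCycles(br), 0)
  }
})

mkCoreg <- function(arcsDf, categories) {
  arcsDf$p <- if (is.null(arcsDf$p)) 1e-6 else arcsDf$p
  arcsDf$weight <- 1L
  arcsDf$provenance <- "t:x|y"
  filterAndAssemble(arcsDf, 1e-4, categories = categories)
}

test_that("primary regulators are the in-degree-0 TF nodes", {
  a <- data.frame(source = c("F", "F"), target = c("G", "op1"),
                  kind = c("tf-tf", "tf-operon"))
  net <- mkCoreg(a, list(op1 = "t"))
  expect_identical(primaryRegulators(net), "F")
  # a 2-cycle leaves neither TF primary
  a2 <- data.frame(source = c("F", "G", "F"), target = c("G", "F", "op1"),
                   kind = c("tf-tf", "tf-tf", "tf-operon"))
  expect_identical(primaryRegulators(mkCoreg(a2, list(op1 = "t"))),
                   character(0))
})

test_that("reachability table counts cascades and matches closure", {
  # R -> F -> op: the cascade counts for R
  a <- data.frame(source = c("R", "F"), target = c("F", "op1"),
                  kind = c("tf-tf", "tf-operon"))
  net <- mkCoreg(a, list(op1 = "t"))
  tab <- regulatoryTable(net, regulators = c("R", "F"))
  expect_identical(tab["t", "R"], 1L)
  expect_identical(tab["t", "F"], 1L)
  expect_identical(tab["t", "Operons"], 1L)
  expect_identical(tab["TOTAL", "Operons"], 1L)
  # random networks against boolean transitive closure
  for (seed in 1:10) {
    res <- plantNetwork(nTfFamilies = 5, categories = c(x = 3, y = 3),
                        nPrimaries = 2, seed = seed)
    net <- res$network
    cats <- categoryMap(net)
    nodes <- c(tfNodes(net), operonNodes(net))
    M <- bfReachable(arcs(net), nodes)
    regs <- tfNodes(net)
    tab <- regulatoryTable(net, cats, regs)
    for (s in setdiff(rownames(tab), "TOTAL")) for (r in regs) {
      ops <- names(cats)[vapply(cats, function(x) s %in% x, logical(1))]
      expect_identical(tab[s, r], sum(M[r, ops]))
    }
    # TOTAL row equals column sums; operons in 2 categories count twice
    expect_equal(tab["TOTAL", ],
                 colSums(tab[rownames(tab) != "TOTAL", , drop = FALSE]),
                 ignore_attr = FALSE, tolerance = 0)
  }
})

test_that("exclusivity counts operons reachable from exactly one primary", {
  # op1 exclusive to P1; op2 reachable from both primaries
  a <- data.frame(source = c("P1", "P1", "P2"),
                  target = c("op1", "op2", "op2"),
                  kind = "tf-operon")
  net <- mkCoreg(a, list(op1 = "t", op2 = "t"))
  ex <- exclusivityTable(net)
  expect_identical(ex$total_exclusive, 1L)
  expect_identical(ex$P1, 1L)
  expect_identical(ex$P2, 0L)
  expect_identical(ex$total_label, "1 (50%)")
  # 2 of 3 exclusive formats as "2 (67%)"
  expect_identical(exclusivityPercent(2, 3)$label, "2 (67%)")
  expect_identical(exclusivityPercent(3, 7)$pct, 43L)
  # exclusivity count never exceeds the reachability count
  for (seed in 1:8) {
    net <- plantNetwork(nTfFamilies = 6, categories = c(x = 4, y = 3),
                        nPrimaries = 3, seed = seed)$network
    sel <- selectCoregulatoryArcs(assignWeights(net))
    cn <- filterAndAssemble(sel, 1e-4, categories = categoryMap(net))
    if (!length(primaryRegulators(cn))) next
    ex <- exclusivityTable(cn)
    tab <- regulatoryTable(cn)
    for (i in seq_len(nrow(ex))) {
      s <- ex$category[i]
      for (p in setdiff(colnames(tab), "Operons"))
        expect_true(ex[[p]][i] <= tab[s, p])
      expect_true(sum(as.integer(ex[i, setdiff(colnames(tab), "Operons")]))
                  <= ex$n_operons[i])
    }
  }
})

test_that("minimal controlling sets are exact and flag uniqueness", {
  # one regulator reaching everything: minimum 1
  a <- data.frame(source = "P", target = c("o1", "o2"), kind = "tf-operon")
  net <- mkCoreg(a, list(o1 = "t", o2 = "t"))
  mc <- minimalControllingSets(net, c("o1", "o2"), "P")
  expect_identical(mc$size, 1L)
  expect_true(mc$unique)
  # two regulators covering disjoint halves: minimum 2, unique
  a2 <- data.frame(source = c("P", "Q"), target = c("o1", "o2"),
                   kind = "tf-operon")
  net2 <- mkCoreg(a2, list(o1 = "t", o2 = "t"))
  mc2 <- minimalControllingSets(net2, c("o1", "o2"), c("P", "Q"))
  expect_identical(mc2$size, 2L)
  expect_true(mc2$unique)
  # infeasible category is reported, not fatal
  mc3 <- minimalControllingSets(net2, c("o1", "o2"), "P")
  expect_false(mc3$feasible)
  # greedy bounds sandwich the exact optimum on random instances
  for (seed in 1:8) {
    net <- plantNetwork(nTfFamilies = 6, categories = c(x = 5),
                        nPrimaries = 3, seed = seed + 50)$network
    ops <- operonNodes(net)
    cand <- tfNodes(net)
    mc <- minimalControllingSets(net, ops, cand)
    if (!mc$feasible) next
    nodes <- c(tfNodes(net), operonNodes(net))
    M <- bfReachable(arcs(net), nodes)
    cover <- lapply(cand, function(r) ops[M[r, ops]])
    names(cover) <- cand
    # greedy upper bound
    left <- ops; g <- 0L
    while (length(left)) {
      gain <- vapply(cover, function(x) length(intersect(x, left)),
                     integer(1))
      if (!max(gain)) break
      left <- setdiff(left, cover[[which.max(gain)]]); g <- g + 1L
    }
    expect_true(mc$size <= g)
    expect_true(mc$size >= 1L)
    # every returned set covers; uniqueness flag consistent
    for (s in mc$sets)
      expect_setequal(intersect(Reduce(union, cover[s]), ops), ops)
    expect_identical(mc$unique, length(mc$sets) == 1L)
  }
})

test_that("hub report flags all tied maxima and the full report assembles", {
  res <- plantNetwork(nTfFamilies = 8, categories = c(x = 3, y = 3),
                      nPrimaries = 3, nCycles = 1, seed = 17)
  net <- res$network
  sel <- selectCoregulatoryArcs(assignWeights(net))
  cn <- filterAndAssemble(sel, 1e-4, categories = categoryMap(net))
  hr <- hubReport(cn)
  expect_identical(hr$total_degree, hr$in_degree + hr$out_degree)
  expect_identical(sum(hr$max_out),
                   sum(hr$out_degree == max(hr$out_degree)))
  expect_true(all(hr$max_total[hr$total_degree == max(hr$total_degree)]))
  tr <- topologyReport(cn)
  expect_s4_class(tr, "TopologyReport")
  expect_identical(tr@primaryRegulators, primaryRegulators(cn))
  expect_identical(tr@fasSize, minFeedbackArcSets(cn)$size)
  expect_output(show(tr), "primary regulators")
})
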