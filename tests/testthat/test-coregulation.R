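test_that("quartile weight assignment follows the equal-groups rule", {
  mk <- function(n) data.frame(source = "C", target = paste0("O", seq_len(n)),
                               kind = "tf-operon", p = seq_len(n) * 1e-6)
  expect_identical(assignWeights(mk(8))$weight, c(1L,1L,2L,2L,4L,4L,8L,8L))
  expect_identical(assignWeights(mk(4))$weight, c(1L, 2L, 4L, 8L))
  # remainder goes to the lowest-p groups: sizes 2,1,1,1
  expect_identical(assignWeights(mk(5))$weight, c(1L, 1L, 2L, 4L, 8L))
  # weights are non-decreasing with p even under shuffling
  a <- mk(11); a <- a[sample(nrow(a)), ]
  w <- assignWeights(a)
  expect_true(all(diff(w$weight[order(w$p)]) >= 0))
  # ties broken stably by arc order
  t2 <- data.frame(source = "C", target = c("O1", "O2"), kind = "tf-operon",
                   p = c(1e-6, 1e-6))
  expect_identical(assignWeights(t2, c(1L, 2L))$weight, c(1L, 2L))
  empty <- data.frame(source = character(), target = character(),
                      kind = character(), p = numeric())
  expect_error(assignWeights(empty), "empty")
})

test_that("minimum-weight V-shape equals exhaustive path-pair search", {
  checked <- 0L
  for (seed in 1:100) {
    inst <- randomVShapeInstance(seed)
    if (nrow(inst$arcs) < 2) next
    vs <- enumerateVShapes(inst$arcs, "a", "b", tf = inst$tf)
    bfW <- if (length(vs)) min(vapply(vs, `[[`, numeric(1), "weight")) else NA
    mv <- minWeightVShape(inst$arcs, "a", "b", tf = inst$tf)
    if (is.na(bfW)) {
      expect_null(mv)
    } else {
      checked <- checked + 1L
      expect_identical(mv$weight, bfW)
      # returned V-shape is valid: node-disjoint paths ending at a and b
      expect_identical(utils::tail(mv$pathA, 1), "a")
      expect_identical(utils::tail(mv$pathB, 1), "b")
      expect_identical(intersect(setdiff(mv$pathA, mv$apex),
                                 setdiff(mv$pathB, mv$apex)), character(0))
      expect_equal(sum(mv$arcs$weight), bfW)
    }
  }
  expect_gt(checked, 30)  # the random instances must exercise the solver
})

test_that("optimal-arc membership equals brute-force over all V-shapes", {
  for (seed in 1:100) {
    inst <- randomVShapeInstance(seed)
    if (nrow(inst$arcs) < 2) next
    vs <- enumerateVShapes(inst$arcs, "a", "b", tf = inst$tf)
    if (!length(vs)) {
      expect_identical(optimalVShapeArcs(inst$arcs, "a", "b", tf = inst$tf),
                       integer(0))
      next
    }
    w <- vapply(vs, `[[`, numeric(1), "weight")
    bfArcs <- sort(unique(unlist(lapply(vs[w == min(w)], `[[`, "arcIdx"))))
    expect_identical(optimalVShapeArcs(inst$arcs, "a", "b", tf = inst$tf),
                     as.integer(bfArcs))
  }
})

test_that("handcrafted V-shape cases behave as the definition forces", {
  # only C->A, C->B: unique V-shape of weight 3
  a <- data.frame(source = c("C", "C"), target = c("A", "B"),
                  weight = c(1, 2))
  mv <- minWeightVShape(a, "A", "B", tf = "C")
  expect_identical(mv$weight, 3)
  expect_identical(mv$apex, "C")
  expect_error(minWeightVShape(a, "A", "A", tf = "C"), "distinct")

  # paths sharing a middle node m: apex C invalid, falls back to apex m
  a2 <- data.frame(source = c("C", "m", "m"), target = c("m", "A", "B"),
                   weight = c(1, 1, 1))
  mv2 <- minWeightVShape(a2, "A", "B", tf = c("C", "m"))
  expect_identical(mv2$apex, "m")
  expect_identical(mv2$weight, 2)
  # with m not a TF there is no V-shape at all
  expect_null(minWeightVShape(a2, "A", "B", tf = "C"))

  # two disjoint equal-weight optima: union of both arc sets
  a3 <- data.frame(source = c("C", "C", "D", "D"),
                   target = c("A", "B", "A", "B"),
                   weight = c(1, 1, 1, 1))
  expect_identical(optimalVShapeArcs(a3, "A", "B", tf = c("C", "D")), 1:4)
})

test_that("V-shape selection honours categories and provenance", {
  res <- plantNetwork(nTfFamilies = 8, categories = c(u = 3, v = 2, w = 1),
                      nPrimaries = 3, seed = 13)
  net <- assignWeights(res$network)
  sel <- selectCoregulatoryArcs(net)
  # every selected arc has provenance referring to same-category pairs
  expect_true(all(nchar(sel$provenance) > 0))
  toks <- strsplit(sel$provenance, ";", fixed = TRUE)
  cats <- categoryMap(net)
  for (tk in unlist(toks)) {
    parts <- strsplit(tk, "[:|]")[[1]]
    expect_true(parts[2] != parts[3])
    expect_true(parts[1] %in% unlist(cats[parts[2]]))
    expect_true(parts[1] %in% unlist(cats[parts[3]]))
  }
  # singleton category contributes no pairs: no provenance mentions it
  expect_false(any(grepl("^w:", unlist(toks))))
  # selected arcs are a subset of the affinity arcs
  expect_true(all(paste(sel$source, sel$target) %in%
                    paste(arcs(net)$source, arcs(net)$target)))
  # planted recovery: every signal arc of a pairable category is selected
  # (the singleton category's arc is unrecoverable by construction), and
  # no decoy is selected
  pairable <- names(cats)[unlist(cats) %in% c("u", "v")]
  sig <- res$truth$signalArcs
  sig <- sig[sig$target %in% pairable, ]
  expect_true(all(paste(sig$source, sig$target) %in%
                    paste(sel$source, sel$target)))
  expect_identical(recoveryRates(res$truth, sel)$decoySelected, 0)
})

test_that("final filter keeps p = 0.00009 exactly and collapses families", {
  sel <- data.frame(
    source = c("F1", "F1", "F2", "F2"),
    target = c("OPX", "O1", "OPX", "O1"),
    kind = "tf-operon",
    p = c(9e-5, 1e-6, 9.5e-5, 2e-6),
    weight = c(8L, 1L, 8L, 1L),
    provenance = c("c:a|b", "c:a|b", "c:a|b", "c:x|y"))
  net <- filterAndAssemble(sel, 9e-5, familyMap = c(OPX = "FamX"),
                           categories = list(O1 = "c"))
  a <- arcs(net)
  # the arc at exactly the threshold survives; the one above is dropped
  expect_true(any(a$p == 9e-5))
  expect_false(any(a$p > 9e-5))
  # TF-coding operon became a family node with a tf-tf arc
  expect_true("FamX" %in% tfNodes(net))
  expect_identical(a$kind[a$target == "FamX"], "tf-tf")
  # parallel arcs merged keeping min p and union of provenance
  merged <- a[a$source == "F2" & a$target == "O1", ]
  expect_identical(nrow(merged), 1L)
  # counts split by kind are reported by show()
  expect_output(show(net), "tf-tf")
  # everything above threshold -> empty network with a warning
  expect_warning(e <- filterAndAssemble(sel[sel$p > 9e-5, , drop = FALSE],
                                        9e-5), "empty")
  expect_identical(arcCount(e), 0L)
  # tightening the threshold never adds arcs
  n1 <- arcCount(filterAndAssemble(sel, 1e-4, categories = list(O1 = "c")))
  n2 <- arcCount(filterAndAssemble(sel, 5e-6, categories = list(O1 = "c")))
  expect_true(n2 <= n1)
})

test_that("p-value histogram bins right-closed and conserves counts", {
  h <- pvalueHistogram(c(1e-5, 2e-5, 9e-5), 2e-5)
  expect_identical(h$count, c(2L, 0L, 0L, 0L, 1L))
  expect_identical(nrow(pvalueHistogram(numeric(0), 1e-5)), 0L)
  for (seed in 1:10) {
    set.seed(seed)
    p <- stats::runif(sample(1:200, 1), 0, 1e-4)
    h <- pvalueHistogram(p, 7e-6)
    expect_identical(sum(h$count), length(p))
  }
})
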