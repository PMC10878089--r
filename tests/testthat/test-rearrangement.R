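test_that("identical orders produce no events and RS 0", {
  ref <- GeneOrder("ref", c("a", "b", "c", "d"))
  ev <- classifyEvents(ref, GeneOrder("t", c("a", "b", "c", "d")))
  expect_equal(sum(ev$score), 0L)
  expect_equal(rearrangementScore(ev), 0L)
})

test_that("a lone strand flip is a pure inversion", {
  ref <- GeneOrder("ref", c("a", "b", "c"))
  tgt <- GeneOrder("t", c("a", "b", "c"), c("+", "-", "+"))
  ev <- classifyEvents(ref, tgt)
  expect_equal(ev$inverted, c(FALSE, TRUE, FALSE))
  expect_equal(sum(ev$score), 1L)
})

test_that("the worked five-gene example decomposes as expected", {
  ref <- GeneOrder("ref", c("a", "b", "c", "d", "e"))
  tgt <- GeneOrder("t", c("a", "c", "b", "d"), c("+", "+", "-", "+"))
  ev <- classifyEvents(ref, tgt)
  row <- function(g) ev[ev$gene == g, ]
  expect_true(row("e")$lost); expect_equal(row("e")$score, 1L)
  expect_true(row("b")$inverted); expect_true(row("b")$translocated)
  expect_equal(row("b")$score, 2L)
  expect_true(row("c")$translocated); expect_equal(row("c")$score, 1L)
  expect_true(row("d")$translocated); expect_equal(row("d")$score, 1L)
  expect_equal(row("a")$score, 0L)
  expect_equal(rearrangementScore(ev), 5L)
})

test_that("disjoint gene sets raise a no-shared-genes error", {
  expect_error(classifyEvents(GeneOrder("r", c("a", "b")),
                              GeneOrder("t", c("x", "y"))),
               "no shared genes")
})

test_that("every reference gene lost gives RS equal to the universe size", {
  ref <- GeneOrder("ref", letters[1:6])
  tgt <- GeneOrder("t", c("a", "zz"))  # only 'a' shared
  ev <- classifyEvents(ref, tgt)
  expect_equal(sum(ev$lost), 5L)
  ref2 <- GeneOrder("ref", letters[1:6])
  # full loss is unreachable (no shared genes), so check the bound with
  # all-but-one lost plus target-private genes ignored
  expect_equal(rearrangementScore(ev), 5L)
})

test_that("RF follows the stated denominator", {
  ref <- GeneOrder("ref", c("g"))
  mk <- function(lost, inv, tra) {
    data.frame(gene = "g", lost = lost, inverted = inv, translocated = tra,
               score = as.integer(lost) + as.integer(inv) + as.integer(tra))
  }
  # translocated in 5/5, inverted in 2/5: scores 2,2,1,1,1 -> RF 70
  evs <- list(mk(FALSE, TRUE, TRUE), mk(FALSE, TRUE, TRUE),
              mk(FALSE, FALSE, TRUE), mk(FALSE, FALSE, TRUE),
              mk(FALSE, FALSE, TRUE))
  expect_equal(rearrangementFrequency(evs)$rf, 70)
  # never rearranged
  evs0 <- replicate(4, mk(FALSE, FALSE, FALSE), simplify = FALSE)
  expect_equal(rearrangementFrequency(evs0)$rf, 0)
  # lost everywhere: 100 * N / (2N) = 50
  evsL <- replicate(6, mk(TRUE, FALSE, FALSE), simplify = FALSE)
  expect_equal(rearrangementFrequency(evsL)$rf, 50)
})

test_that("RF is bounded and RS is invariant to consistent relabeling", {
  set.seed(17)
  ref <- GeneOrder("ref", letters[1:12])
  for (r in 1:20) {
    sim <- evolveGeneOrder(ref, nLoss = 2, nInv = 2, nTrans = 2,
                           seed = 100 + r)
    ev <- classifyEvents(ref, sim$order)
    rf <- rearrangementFrequency(list(ev))$rf
    expect_true(all(rf >= 0 & rf <= 100))
    # permute labels consistently
    perm <- sample(LETTERS[1:12])
    names(perm) <- letters[1:12]
    ref2 <- GeneOrder("ref", unname(perm[orderGenes(ref)]),
                      orderStrands(ref))
    tgt2 <- GeneOrder("t", unname(perm[orderGenes(sim$order)]),
                      orderStrands(sim$order))
    expect_equal(rearrangementScore(classifyEvents(ref2, tgt2)),
                 rearrangementScore(ev))
  }
})

test_that("RS is zero exactly when the shared-restricted orders agree", {
  ref <- GeneOrder("ref", c("a", "b", "c", "d"))
  # target missing nothing, same order and strands: 0
  expect_equal(rearrangementScore(
    classifyEvents(ref, GeneOrder("t", c("a", "b", "c", "d")))), 0L)
  # private target genes do not score
  expect_equal(rearrangementScore(
    classifyEvents(ref, GeneOrder("t", c("a", "p1", "b", "c", "p2", "d")))),
    0L)
  # any difference scores > 0
  expect_gt(rearrangementScore(
    classifyEvents(ref, GeneOrder("t", c("b", "a", "c", "d")))), 0L)
})

test_that("hotspot blocks rank by mean RF with leftmost tie-break", {
  rf <- data.frame(gene = letters[1:6], rf = c(10, 10, 10, 10, 10, 10))
  hb <- hotspotBlocks(rf, k = 3)
  expect_equal(hb$start[1], 1L)  # uniform: leftmost first
  rf2 <- data.frame(gene = letters[1:6], rf = c(0, 0, 90, 0, 0, 0))
  expect_equal(hotspotBlocks(rf2, k = 1)$genes[1], "c")
  rf3 <- data.frame(gene = letters[1:8], rf = c(5, 5, 80, 80, 80, 5, 5, 5))
  expect_equal(hotspotBlocks(rf3, k = 3)$genes[1], "c-d-e")
  expect_error(hotspotBlocks(rf3, k = 9), "between 1")
})

test_that("Welch comparisons match the textbook formula and flag degeneracy", {
  g <- list(A = c(36, 42, 80, 20, 15), B = c(5, 3, 8, 6, 5, 7),
            C = c(2, 4, 1, 3))
  out <- compareRsGroups(g)
  ab <- out[out$groupA == "A" & out$groupB == "B", ]
  oracle <- welchOracle(g$A, g$B)
  expect_equal(ab$t, oracle$t, tolerance = 1e-12)
  expect_equal(ab$p, oracle$p, tolerance = 1e-12)
  expect_equal(ab$seA, sd(g$A) / sqrt(5), tolerance = 1e-12)
  # identical groups -> t = 0, p = 1
  same <- compareRsGroups(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-6)
  # zero variance in both with separation -> degenerate flag
  sep <- compareRsGroups(list(x = c(0, 0, 0), y = c(10, 10, 10)))
  expect_true(sep$degenerate)
  expect_equal(sep$p, 0)
})

test_that("gene orders round-trip through the exchange format", {
  orders <- list(
    GeneOrder("m1", c("cox1", "trnY", "rnl"), c("+", "-", "+")),
    GeneOrder("m2", c("cox1", "rnl"), c("-", "+")))
  path <- withr::local_tempfile(fileext = ".order")
  writeGeneOrders(orders, path)
  back <- readGeneOrders(path)
  expect_equal(names(back), c("m1", "m2"))
  expect_equal(orderGenes(back$m1), orderGenes(orders[[1]]))
  expect_equal(orderStrands(back$m1), orderStrands(orders[[1]]))
  expect_equal(orderStrands(back$m2), c("-", "+"))
})

test_that("position-index translocation mode is available and differs when it should", {
  ref <- GeneOrder("ref", c("a", "b", "c", "d", "e"))
  tgt <- GeneOrder("t", c("a", "c", "b", "d", "e"))
  evPred <- classifyEvents(ref, tgt, translocation = "predecessor")
  evPos <- classifyEvents(ref, tgt, translocation = "position")
  # predecessor: b, c and d change predecessor; position: only b and c move
  expect_equal(sum(evPred$translocated), 3L)
  expect_equal(sum(evPos$translocated), 2L)
})

test_that("full reports aggregate RS and RF across genomes", {
  ref <- GeneOrder("ref", letters[1:8])
  t1 <- evolveGeneOrder(ref, nInv = 2, seed = 4, newId = "t1")$order
  t2 <- evolveGeneOrder(ref, nLoss = 1, nTrans = 1, seed = 5,
                        newId = "t2")$order
  rep <- rearrangementReport(ref, list(t1, t2))
  expect_equal(rep$reference, "ref")
  expect_named(rep$rs, c("t1", "t2"))
  expect_equal(unname(rep$rs["t1"]),
               rearrangementScore(classifyEvents(ref, t1)))
  expect_equal(nrow(rep$rf), 8L)
  expect_equal(rep$rf$rf,
               100 * (rep$events$t1$score + rep$events$t2$score) / 4)
})
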