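test_that("GFF3 coordinates import as 1-based inclusive features", {
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeToyFasta(fa, "m1", "ATGAAATAAG")
  writeToyGff(gff, "m1", list(list(type = "gene", start = 1, end = 6,
                                   strand = "+", id = "g1", name = "orf1")))
  g <- readMitogenome(fa, gff, "gff3")
  fx <- geneFeatures(g)
  expect_equal(GenomicRanges::start(fx), 1L)
  expect_equal(GenomicRanges::end(fx), 6L)
  expect_equal(GenomicRanges::width(fx), 6L)
  expect_equal(as.character(S4Vectors::mcols(fx)$gene), "orf1")
  expect_equal(as.character(S4Vectors::mcols(fx)$category), "PCG")
})

test_that("annotations referencing an absent contig or bad coordinates fail", {
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeToyFasta(fa, "m1", "ATGAAATAAG")
  writeToyGff(gff, "other", list(list(type = "gene", start = 1, end = 6,
                                      strand = "+", id = "g", name = "g")))
  expect_error(readMitogenome(fa, gff, "gff3"), "absent")
  writeToyGff(gff, "m1", list(list(type = "gene", start = 2, end = 60,
                                   strand = "+", id = "g", name = "g")))
  expect_error(readMitogenome(fa, gff, "gff3"), "malformed")
})

test_that("write -> read round trip reproduces a synthetic genome", {
  sim <- buildRepeatGenome(coreLength = 2000, seed = 11,
                           telomere5 = list(unitLength = 10, copies = 6,
                                            gc = 0.4),
                           telomere3 = list(unitLength = 7, copies = 8,
                                            gc = 0.3),
                           cr = list(length = 200, at = 1), nGenes = 4)
  g <- sim$genome
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeMitogenome(g, fa, gff)
  g2 <- readMitogenome(fa, gff, "gff3")
  expect_equal(genomeId(g2), genomeId(g))
  expect_equal(as.character(genomeSequence(g2)),
               as.character(genomeSequence(g)))
  expect_equal(genomeTopology(g2), genomeTopology(g))
  f1 <- geneFeatures(g); f2 <- geneFeatures(g2)
  expect_equal(GenomicRanges::start(f2), GenomicRanges::start(f1))
  expect_equal(GenomicRanges::end(f2), GenomicRanges::end(f1))
  expect_equal(as.character(GenomicRanges::strand(f2)),
               as.character(GenomicRanges::strand(f1)))
  expect_equal(S4Vectors::mcols(f2)$gene, S4Vectors::mcols(f1)$gene)
  expect_equal(S4Vectors::mcols(f2)$category, S4Vectors::mcols(f1)$category)
})

test_that("a GenBank flat file parses locations, strands and labels", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       m1                 30 bp    DNA     linear   01-JAN-2024",
    "FEATURES             Location/Qualifiers",
    "     source          1..30",
    "     CDS             1..9",
    '                     /gene="cox1"',
    "     tRNA            complement(11..17)",
    '                     /product="trnY"',
    "ORIGIN",
    "        1 atgaaataag ttttacgtaa ctgatcgatc",
    "//"), gb)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeToyFasta(fa, "m1", "ATGAAATAAGTTTTACGTAACTGATCGATC")
  g <- readMitogenome(fa, gb, "genbank")
  fx <- geneFeatures(g)
  expect_equal(length(fx), 2L)
  expect_equal(S4Vectors::mcols(fx)$gene, c("cox1", "trnY"))
  expect_equal(S4Vectors::mcols(fx)$category, c("PCG", "tRNA"))
  expect_equal(GenomicRanges::start(fx), c(1L, 11L))
  expect_equal(as.character(GenomicRanges::strand(fx)), c("+", "-"))
})

test_that("gene order extraction sorts by start and drops repeat features", {
  g <- toyGenome(seq = strrep("A", 30), feats = rbind(
    featRow("b", "tRNA", 11, 14, "-"),
    featRow("a", "PCG", 1, 6, "+"),
    featRow("tel", "telomere", 16, 20, "+"),
    featRow("c", "rRNA", 22, 28, "+")))
  go <- extractGeneOrder(g)
  expect_equal(orderGenes(go), c("a", "b", "c"))
  expect_equal(orderStrands(go), c("+", "-", "+"))
  expect_error(extractGeneOrder(toyGenome(feats = featRow("t", "telomere", 1, 4))),
               "no features")
})

test_that("gene order is invariant to feature ordering and matches a sort oracle", {
  set.seed(42)
  n <- 40
  starts <- sort(sample.int(4000, n)) * 2
  feats <- do.call(rbind, lapply(seq_len(n), function(i)
    featRow(paste0("g", i), "PCG", starts[i], starts[i] + 1,
            sample(c("+", "-"), 1))))
  shuffled <- feats[sample.int(n), ]
  g1 <- Mitogenome("a", strrep("A", 9000), feats)
  g2 <- Mitogenome("a", strrep("A", 9000), shuffled)
  expect_equal(orderGenes(extractGeneOrder(g1)),
               orderGenes(extractGeneOrder(g2)))
  # independent oracle: order by start column
  expect_equal(orderGenes(extractGeneOrder(g1)),
               feats$gene[order(feats$start)])
})

test_that("region stats partition the genome and compute class GC", {
  g <- toyGenome(seq = "ATGCATGCAT",
                 feats = featRow("p", "PCG", 1, 10))
  rs <- regionStats(g)
  expect_equal(rs$fraction[rs$class == "PCG"], 1)
  expect_equal(rs$gc[rs$class == "PCG"], 0.4)
  g2 <- Mitogenome("x", "AAAGGCCAAA", featRow("p", "PCG", 4, 7))
  rs2 <- regionStats(g2)
  expect_equal(rs2$gc[rs2$class == "PCG"], 1)
  expect_equal(rs2$gc[rs2$class == "intergenic"], 0)
  expect_equal(sum(rs2$length), 10)
})

test_that("region lengths always sum to genome length on random genomes", {
  for (seed in 1:5) {
    sim <- buildRepeatGenome(coreLength = 1500, seed = seed,
                             telomere5 = list(unitLength = 9, copies = 5,
                                              gc = 0.5),
                             cr = list(length = 150, at = 1), nGenes = 3)
    rs <- regionStats(sim$genome)
    expect_equal(sum(rs$length), genomeLength(sim$genome))
    expect_equal(sum(rs$fraction), 1)
    # excluding telomeres rescales to the telomere-free length
    rs2 <- regionStats(sim$genome, excludeTelomeres = TRUE)
    expect_false("telomere" %in% rs2$class)
    expect_equal(sum(rs2$fraction), 1)
  }
})

test_that("translation follows the mold/protozoan mitochondrial code", {
  expect_equal(translateCds("ATGAAATAA"), "MK")
  expect_equal(translateCds("TGA"), "W")  # Trp, not stop, under table 4
  expect_warning(out <- translateCds("ATGTAAAAA"), "internal stop")
  expect_equal(out, "M*K")
  # versus the standard code: differences exactly at table-divergent codons
  set.seed(7)
  cods <- names(Biostrings::getGeneticCode("1"))
  cds <- paste(sample(cods, 300, replace = TRUE), collapse = "")
  aa4 <- suppressWarnings(translateCds(cds, "4"))
  aa1 <- suppressWarnings(translateCds(cds, "1"))
  n <- min(nchar(aa4), nchar(aa1))
  diffs <- which(strsplit(aa4, "")[[1]][1:n] != strsplit(aa1, "")[[1]][1:n])
  codList <- substring(cds, 3 * diffs - 2, 3 * diffs)
  expect_true(all(codList == "TGA"))  # the only divergent codon
  gc1 <- Biostrings::getGeneticCode("1")
  gc4 <- Biostrings::getGeneticCode("4")
  tgaHere <- which(substring(cds, 3 * (1:n) - 2, 3 * (1:n)) == "TGA")
  expect_setequal(diffs, tgaHere)
})

test_that("stop codon usage counts terminal codons of annotated PCGs", {
  seq <- paste0("ATGAAATAA", "T", "ATGCCCTAG", "ATGAAATAA")
  g <- Mitogenome("m", seq, rbind(
    featRow("g1", "PCG", 1, 9),
    featRow("g2", "PCG", 11, 19),
    featRow("g3", "PCG", 20, 28)))
  su <- stopCodonUsage(g)
  expect_equal(su$TAA, 2L)
  expect_equal(su$TAG, 1L)
  expect_equal(su$other, 0L)
  # empty PCG set: zero counts
  g0 <- Mitogenome("e", "ACGTACGT", featRow("t", "tRNA", 1, 4))
  su0 <- stopCodonUsage(g0)
  expect_equal(su0$TAA + su0$TAG + su0$other, 0L)
})

test_that("duplicate labels get positional suffixes", {
  g <- Mitogenome("m", strrep("A", 100), rbind(
    featRow("nad1", "PCG", 1, 30),
    featRow("nad1", "PCG", 61, 90)))
  expect_equal(S4Vectors::mcols(geneFeatures(g))$gene,
               c("nad1_a", "nad1_b"))
})
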