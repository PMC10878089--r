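# toy proteomes: named lists of protein strings per genome
toyProteomes <- function() {
  list(
    g1 = c(cox1 = "MKKLLVVGGAATT", cob = "MPPQQRRSSTTVV"),
    g2 = c(cox1 = "MKKLLVVGGAATT", cob = "MPPQQRRSSTTVV"),
    g3 = c(cox1 = "MKKLLVVGGAATT", cob = "MPPQQRRSSTTVV"))
}

test_that("by-name orthogrouping groups identical labels", {
  og <- inferOrthogroups(toyProteomes(), mode = "by_name")
  expect_equal(length(unique(og$orthogroup)), 2L)
  expect_equal(unname(table(og$orthogroup)[unique(og$orthogroup)]),
               c(3L, 3L), ignore_attr = TRUE)
})

test_that("a missing gene shrinks its orthogroup and drops it from the core", {
  prot <- toyProteomes()
  prot$g3 <- prot$g3["cox1"]
  og <- inferOrthogroups(prot, mode = "by_name")
  sizes <- table(og$orthogroup)
  expect_setequal(as.integer(sizes), c(3L, 2L))
  core <- coreGenes(og, nGenomes = 3)
  expect_equal(core$count, 1L)
  expect_equal(unique(og$gene[og$orthogroup == core$orthogroups]), "cox1")
})

test_that("core genes require exactly one member per genome", {
  og <- data.frame(
    orthogroup = c(rep("OG1", 6), rep("OG2", 6), rep("OG3", 5),
                   rep("OG4", 7)),
    genome = c(paste0("g", 1:6), paste0("g", 1:6), paste0("g", 1:5),
               paste0("g", c(1:6, 6))),
    gene = "x")
  core <- coreGenes(og, nGenomes = 6)
  # OG3 misses a genome; OG4 has a duplicate in g6
  expect_setequal(core$orthogroups, c("OG1", "OG2"))
  expect_equal(core$count, 2L)
})

test_that("RBH clustering recovers planted families among decoys", {
  set.seed(61)
  mut <- function(p, n) {
    v <- strsplit(p, "")[[1]]
    idx <- sample(seq_along(v), n)
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    v[idx] <- sample(aas, n, replace = TRUE)
    paste(v, collapse = "")
  }
  fam1 <- "MKKLLVVGGAATTPPQQRRSS"  # ~10% divergence between copies
  fam2 <- "MWWYYFFHHNNDDEECCIIKK"
  decoy <- function() paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                   21, replace = TRUE), collapse = "")
  prot <- list(
    gA = c(x1 = mut(fam1, 2), y1 = mut(fam2, 2), d1 = decoy()),
    gB = c(x2 = mut(fam1, 2), y2 = mut(fam2, 2), d2 = decoy()),
    gC = c(x3 = mut(fam1, 2), y3 = mut(fam2, 2)))
  og <- inferOrthogroups(prot, mode = "rbh")
  grpOf <- function(gene) og$orthogroup[og$gene == gene]
  expect_equal(grpOf("x1"), grpOf("x2"))
  expect_equal(grpOf("x1"), grpOf("x3"))
  expect_equal(grpOf("y1"), grpOf("y2"))
  expect_equal(grpOf("y1"), grpOf("y3"))
  expect_false(grpOf("x1") == grpOf("y1"))
})

test_that("by-name and RBH coincide when labels are truthful", {
  og1 <- inferOrthogroups(toyProteomes(), mode = "by_name")
  og2 <- inferOrthogroups(toyProteomes(), mode = "rbh")
  part <- function(og) {
    unname(lapply(split(paste(og$genome, og$gene), og$orthogroup), sort))
  }
  expect_setequal(part(og1), part(og2))
})

test_that("empty proteomes are rejected by name", {
  prot <- toyProteomes()
  prot$g2 <- character(0)
  expect_error(inferOrthogroups(prot), "empty proteome")
})

test_that("concatenation records partitions and preserves columns", {
  cds1 <- c(t1 = "ATGAAACCCGGGTTTAAACCCGGGTTTATG",  # 30 nt
            t2 = "ATGAAACCCGGGTTTAAACCCGGGTTTATG",
            t3 = "ATGAAACCCGGGTTTAAACCCGGGTTTATG")
  cds2 <- c(t1 = strrep("ATGAAACCCGGGTTTAAACCC", 2),
            t2 = strrep("ATGAAACCCGGGTTTAAACCC", 2),
            t3 = strrep("ATGAAACCCGGGTTTAAACCC", 2))  # 42 nt
  cc <- concatCoreAlignment(list(gene1 = cds1, gene2 = cds2))
  expect_equal(unname(cc$partitions), c(30L, 72L))
  mat <- do.call(rbind, strsplit(as.character(cc$aln), ""))
  expect_equal(sum(apply(mat, 2, function(col) length(unique(col)) > 1)), 0L)

  # planted substitutions create exactly that many variable columns
  cds1b <- cds1
  v <- strsplit(cds1b[["t3"]], "")[[1]]
  v[c(4, 10)] <- c("T", "A")  # two substitutions (A->T at 4, G->A at 10)
  cds1b["t3"] <- paste(v, collapse = "")
  cc2 <- concatCoreAlignment(list(gene1 = cds1b, gene2 = cds2))
  mat2 <- do.call(rbind, strsplit(as.character(cc2$aln), ""))
  expect_equal(sum(apply(mat2, 2, function(col) length(unique(col)) > 1)), 2L)

  # a missing taxon sequence is reported as (taxon, gene)
  expect_error(concatCoreAlignment(list(gene1 = cds1[-1], gene2 = cds2)),
               "t1:gene1")
})

test_that("NJ recovers the generating topology from additive distances", {
  # disjoint variable-site blocks realise an additive ((A,B),(C,D)) metric
  L <- 200
  base <- rep("A", L)
  mk <- function(sites, to) { s <- base; s[sites] <- to; paste(s, collapse = "") }
  seqs <- c(A = mk(1:4, "C"),            # tip a: 4 private sites
            B = mk(5:10, "C"),           # tip b: 6
            C = mk(c(41:60, 101:110), "C"),  # internal 20 + tip c: 10
            D = mk(c(41:60, 111:124), "C")) # internal 20 + tip d: 14
  tr <- njTree(seqs, distance = "p", bootstrapN = 50, seed = 2)
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")) ||
              ape::is.monophyletic(ape::unroot(tr), c("C", "D")))
  # NJ reproduces the additive metric exactly on the tree
  D <- cophenetic(tr)
  pd <- function(x, y) mean(strsplit(seqs[[x]], "")[[1]] !=
                            strsplit(seqs[[y]], "")[[1]])
  for (pr in list(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "D")))
    expect_equal(D[pr[1], pr[2]], pd(pr[1], pr[2]), tolerance = 1e-12)
})

test_that("three taxa give the unique topology and identical rows a star", {
  seqs3 <- c(A = "ACGTACGTAC", B = "ACGTACGTAA", C = "ACGTACGGAC")
  tr <- njTree(seqs3, bootstrapN = 20, seed = 1)
  expect_equal(ape::Ntip(tr), 3L)
  same <- c(A = "ACGTACGT", B = "ACGTACGT", C = "ACGTACGT", D = "ACGTACGT")
  tr0 <- njTree(same, bootstrapN = 0)
  expect_true(all(abs(tr0$edge.length) < 1e-12))
})

test_that("bootstrap runs with the same seed are identical", {
  set.seed(63)
  seqs <- setNames(vapply(1:5, function(i) randomDna(120, seed = 70 + i),
                          character(1)), paste0("t", 1:5))
  tr1 <- njTree(seqs, bootstrapN = 50, seed = 99)
  tr2 <- njTree(seqs, bootstrapN = 50, seed = 99)
  expect_identical(tr1$node.label, tr2$node.label)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
})
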