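mkVm <- function(counts, ref = NULL, sites = NULL) {
  # counts: list per strain of matrix sites x 4 (A,C,G,T)
  ns <- length(counts); np <- nrow(counts[[1]])
  d <- array(0L, dim = c(ns, np, 4))
  for (s in seq_len(ns)) d[s, , ] <- as.matrix(counts[[s]])
  if (is.null(ref)) ref <- rep("A", np)
  if (is.null(sites)) sites <- seq_len(np)
  VariantMatrix(paste0("s", seq_len(ns)), sites, ref, d)
}

test_that("consensus calling takes the majority and honours the tie rule", {
  vm <- mkVm(list(rbind(c(10, 0, 0, 0),   # A
                        c(5, 5, 0, 0),    # tie A/C, ref A -> A
                        c(0, 5, 5, 0),    # tie C/G, ref A -> alphabetical C
                        c(1, 0, 0, 2))),  # depth 3 < minDepth -> N
              ref = c("A", "A", "A", "A"))
  cons <- consensusHaplotypes(vm, minDepth = 5)
  expect_equal(unname(cons[1, ]), c("A", "A", "C", "N"))
  # a strain with no covered site errors
  vm2 <- mkVm(list(rbind(c(2, 0, 0, 0)), rbind(c(30, 0, 0, 0))))
  expect_error(consensusHaplotypes(vm2, minDepth = 10), "no site")
})

test_that("consensus equals truth on simulated deep data", {
  sim <- simulatePopulation(800, 5, 0.02, depth = 60, errorRate = 0.01,
                            seed = 121)
  cons <- consensusHaplotypes(sim$vm, minDepth = 20)
  covered <- cons != "N"
  expect_gt(mean(covered), 0.95)
  expect_equal(cons[covered], sim$truth$haplotypes[covered])
})

test_that("SNP calling distinguishes polymorphic from fixed sites", {
  cons <- rbind(s1 = c("A", "A", "G", "N"),
                s2 = c("A", "T", "G", "A"),
                s3 = c("A", "T", "G", "A"))
  colnames(cons) <- c(10, 20, 30, 40)
  out <- callSnps(cons)
  expect_equal(out$count, 1L)
  expect_equal(out$sites, 20L)
  expect_equal(out$coveredSites, 4L)
  expect_equal(out$densityPerKb, 250)
})

test_that("observed SNP density matches the planted theta expectation", {
  L <- 6000; n <- 8; theta <- 0.005
  sim <- simulatePopulation(L, n, theta, depth = 60, errorRate = 0,
                            seed = 122)
  cons <- consensusHaplotypes(sim$vm, minDepth = 10)
  got <- callSnps(cons)$count
  pPoly <- 1 - (1 - theta)^n - 3 * (theta / 3)^n
  expect_lt(abs(got - L * pPoly), 3 * sqrt(L * pPoly * (1 - pPoly)) + 1)
})

test_that("heteroplasmy calls respect the MAF and depth thresholds", {
  vm <- mkVm(list(rbind(c(95, 5, 0, 0),    # maf 0.05 at depth 100 -> called
                        c(98, 2, 0, 0),    # maf 0.02 -> not called
                        c(30, 3, 0, 0))))  # depth 33 < 50 -> not called
  calls <- callHeteroplasmy(vm, mafMin = 0.05, depthMin = 50)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$site, 1L)
  expect_equal(calls$maf, 0.05)
  expect_equal(calls$major, "A")
  expect_equal(calls$minor, "C")
})

test_that("planted heteroplasmy is recovered from simulated depths", {
  het <- data.frame(strain = c(1, 1, 2), site = c(50, 150, 200),
                    fraction = 0.2)
  sim <- simulatePopulation(400, 3, 0, hetSpec = het, depth = 200,
                            errorRate = 0.005, seed = 123)
  calls <- callHeteroplasmy(sim$vm, mafMin = 0.05, depthMin = 50)
  found <- paste(calls$strain, calls$site)
  expect_true(all(c("S01 50", "S01 150", "S02 200") %in% found))
  # no spurious calls at planted-free sites
  expect_lte(nrow(calls), 4L)
})

test_that("pi matches hand-computed pairwise differences", {
  cons <- rbind(s1 = strsplit("AAAAAAAAAA", "")[[1]],
                s2 = strsplit("AAAAAAAAAT", "")[[1]])
  colnames(cons) <- 1:10
  expect_equal(nucleotideDiversity(cons)$pi, 0.1)
  cons3 <- rbind(s1 = strsplit("AAAAAAAAAA", "")[[1]],
                 s2 = strsplit("AAAAAAAAAA", "")[[1]],
                 s3 = strsplit("TTAAAAAAAA", "")[[1]])
  colnames(cons3) <- 1:10
  expect_equal(nucleotideDiversity(cons3)$pi, (0 + 2 + 2) / 3 / 10)
  consSame <- rbind(s1 = rep("A", 8), s2 = rep("A", 8))
  colnames(consSame) <- 1:8
  expect_equal(nucleotideDiversity(consSame)$pi, 0)
})

test_that("pi is strain-order invariant and per-gene restriction works", {
  sim <- simulatePopulation(600, 5, 0.03, depth = 50, errorRate = 0,
                            seed = 124)
  cons <- consensusHaplotypes(sim$vm, 10)
  p1 <- nucleotideDiversity(cons)$pi
  p2 <- nucleotideDiversity(cons[sample(nrow(cons)), ])$pi
  expect_equal(p1, p2)
  expect_gte(p1, 0); expect_lte(p1, 1)
  genes <- data.frame(gene = c("gA", "gB"), start = c(1, 301),
                      end = c(300, 600))
  pg <- nucleotideDiversity(cons, genes)$perGene
  expect_equal(nrow(pg), 2L)
  expect_equal(pg$sites, c(300L, 300L))
})

test_that("haploid r-squared hits the coupling and independence poles", {
  coupled <- rbind(s1 = c("A", "C"), s2 = c("A", "C"),
                   s3 = c("T", "G"), s4 = c("T", "G"))
  colnames(coupled) <- c(100, 900)
  out <- ldR2Decay(coupled)
  expect_equal(out$pairs$r2, 1)
  expect_equal(out$pairs$distance, 800)
  indep <- rbind(s1 = c("A", "C"), s2 = c("A", "G"),
                 s3 = c("T", "C"), s4 = c("T", "G"))
  colnames(indep) <- c(100, 900)
  expect_equal(ldR2Decay(indep)$pairs$r2, 0)
})

test_that("r-squared of a site with itself is 1 and monomorphic pairs are skipped", {
  cons <- rbind(s1 = c("A", "A", "A"), s2 = c("A", "T", "T"),
                s3 = c("T", "A", "T"), s4 = c("T", "T", "A"))
  colnames(cons) <- c(1, 2, 3)
  dup <- cbind(cons, cons[, 2, drop = FALSE])
  colnames(dup) <- c(1, 2, 3, 4)
  out <- ldR2Decay(dup)
  selfPair <- out$pairs[out$pairs$site1 == 2 & out$pairs$site2 == 4, ]
  expect_equal(selfPair$r2, 1)
  mono <- rbind(s1 = c("A", "A"), s2 = c("A", "T"),
                s3 = c("A", "A"), s4 = c("A", "T"))
  colnames(mono) <- c(1, 2)
  expect_error(ldR2Decay(mono), "biallelic")
})

test_that("IBS, haversine and the Mantel wiring behave as specified", {
  cons <- rbind(s1 = c("A", "A", "A", "A"), s2 = c("A", "A", "A", "T"),
                s3 = c("A", "A", "T", "T"), s4 = c("A", "T", "T", "T"))
  colnames(cons) <- 1:4
  ibs <- ibsMatrix(cons)
  expect_equal(ibs["s1", "s2"], 0.75)
  expect_equal(diag(ibs), rep(1, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(ibs))

  meta <- data.frame(strain = paste0("s", 1:4),
                     lat = c(0, 0, 10, 20), lon = c(0, 90, 30, 40))
  km <- haversineKm(meta)
  expect_equal(km["s1", "s2"], pi / 2 * 6371, tolerance = 1e-6)
  expect_equal(km["s1", "s2"], 10007.54, tolerance = 1e-5)

  res1 <- ibsVsGeography(cons, meta, permutations = 199, seed = 11)
  res2 <- ibsVsGeography(cons, meta, permutations = 199, seed = 11)
  expect_equal(res1$p, res2$p)
  expect_equal(res1$r2, res1$mantelR^2)

  metaSame <- data.frame(strain = paste0("s", 1:4), lat = 5, lon = 5)
  expect_true(ibsVsGeography(cons, metaSame)$degenerate)
})

test_that("Mantel detects geography-proportional genetic structure", {
  set.seed(131)
  hits <- replicate(20, {
    # strains on a longitudinal transect; haplotypes along a chain so that
    # pairwise genetic distance is proportional to geographic distance
    n <- 8; L <- 400; perStrain <- 12
    meta <- data.frame(strain = paste0("s", 1:n), lat = 0,
                       lon = seq(0, 40, length.out = n) + rnorm(n, 0, 0.1))
    ref <- strsplit(randomDna(L, seed = sample.int(1e6, 1)), "")[[1]]
    cons <- t(vapply(1:n, function(s) {
      h <- ref
      mutated <- seq_len((s - 1) * perStrain)  # inherit all earlier blocks
      h[mutated] <- "G"
      h
    }, character(L)))
    rownames(cons) <- meta$strain; colnames(cons) <- 1:L
    ibsVsGeography(cons, meta, permutations = 199,
                   seed = sample.int(1e6, 1))$p <= 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("allele-depth tables round-trip through TSV", {
  sim <- simulatePopulation(50, 3, 0.05, depth = 30, seed = 133)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeAlleleDepths(sim$vm, path)
  back <- readAlleleDepths(path)
  expect_equal(strainNames(back), strainNames(sim$vm))
  expect_equal(siteCoords(back), siteCoords(sim$vm))
  expect_equal(refBases(back), refBases(sim$vm))
  expect_equal(unname(alleleDepths(back)), unname(alleleDepths(sim$vm)))
})
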