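# Independent oracle for the seven Venn regions.
oracle_venn <- function(A, B, C) {
  c(kmer_only = length(setdiff(setdiff(A, B), C)),
    family_only = length(setdiff(setdiff(B, A), C)),
    de_only = length(setdiff(setdiff(C, A), B)),
    kmer_family = length(setdiff(intersect(A, B), C)),
    kmer_de = length(setdiff(intersect(A, C), B)),
    family_de = length(setdiff(intersect(B, C), A)),
    all_three = length(intersect(intersect(A, B), C)))
}

test_that("three-way candidate intersection matches set enumeration", {
  A <- c("1", "2", "3"); B <- c("2", "3", "4"); C <- c("3", "4", "5")
  res <- intersectCandidates(A, B, C)
  expect_identical(res$venn, as.numeric(oracle_venn(A, B, C)) |>
                     setNames(names(res$venn)))
  expect_equal(sum(res$venn), length(union(union(A, B), C)))
  # identical sets: everything in the triple intersection
  res2 <- intersectCandidates(A, A, A)
  expect_equal(unname(res2$venn["all_three"]), 3)
  expect_equal(sum(res2$venn[names(res2$venn) != "all_three"]), 0)
  # pairwise disjoint sets: no intersections
  res3 <- intersectCandidates("a", "b", "c")
  expect_equal(unname(res3$venn[c("kmer_family", "kmer_de", "family_de",
                                  "all_three")]), rep(0, 4))
  # random property: regions always partition the union
  set.seed(6)
  for (i in 1:10) {
    S <- as.character(1:15)
    A <- sample(S, sample(0:10, 1)); B <- sample(S, sample(0:10, 1))
    C <- sample(S, sample(0:10, 1))
    r <- intersectCandidates(A, B, C)
    expect_identical(unname(r$venn), unname(as.numeric(oracle_venn(A, B, C))))
    expect_equal(sum(r$venn), length(union(union(A, B), C)))
  }
  # two-set mode
  r2 <- intersectCandidates(A, B, NULL)
  expect_true(all(is.na(r2$venn[c("de_only", "kmer_de", "family_de",
                                  "all_three")])))
})

make_linear_reference <- function(n = 30) {
  gene <- function(i) sprintf("g%02d", i)
  len <- 30
  contig <- random_dna(41 * n + 10)
  StrainGenome("ref", c(c1 = contig),
               data.frame(gene_id = vapply(1:n, gene, character(1)),
                          contig_id = "c1",
                          start = (0:(n - 1)) * 41 + 10,
                          end = (0:(n - 1)) * 41 + 10 + len,
                          strand = "+"))
}

test_that("adjacency calling respects gaps and minimum size", {
  set.seed(10)
  ref <- make_linear_reference()
  gid <- function(i) sprintf("g%02d", i)
  cand <- gid(c(5, 6, 7, 9, 20))
  cl <- callAdjacentClusters(cand, ref, max_gap = 1, min_genes = 3)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]@geneIds, gid(c(5, 6, 7, 9)))
  # max_gap 0: strict consecutive runs only
  cl0 <- callAdjacentClusters(gid(1:3), ref, max_gap = 0, min_genes = 3)
  expect_length(cl0, 1L)
  expect_identical(cl0[[1]]@geneIds, gid(1:3))
  expect_length(callAdjacentClusters(gid(c(1, 3, 5, 7)), ref,
                                     max_gap = 0, min_genes = 3), 0L)
  # min_genes above the candidate count: nothing called
  expect_length(callAdjacentClusters(gid(c(2, 3, 4, 5)), ref,
                                     max_gap = 2, min_genes = 5), 0L)
  # huge gap tolerance: all candidates on the contig form one cluster
  clinf <- callAdjacentClusters(cand, ref, max_gap = 1000, min_genes = 3)
  expect_length(clinf, 1L)
  expect_identical(clinf[[1]]@geneIds, gid(c(5, 6, 7, 9, 20)))
  expect_error(callAdjacentClusters("ghost", ref), "not in reference")
})

test_that("cluster naming runs A..Z then AA, AB in genomic order", {
  set.seed(11)
  ref <- make_linear_reference()
  cl15 <- nameClusterGenes(callAdjacentClusters(
    sprintf("g%02d", 1:15), ref, max_gap = 0, min_genes = 3)[[1]])
  expect_identical(cl15@geneNames[1], "bxdA")
  expect_identical(cl15@geneNames[15], "bxdO")
  cl27 <- nameClusterGenes(callAdjacentClusters(
    sprintf("g%02d", 1:27), ref, max_gap = 0, min_genes = 3)[[1]])
  expect_identical(cl27@geneNames[26], "bxdZ")
  expect_identical(cl27@geneNames[27], "bxdAA")
  cl2 <- nameClusterGenes(callAdjacentClusters(
    sprintf("g%02d", 1:3), ref, max_gap = 0, min_genes = 2)[[1]],
    prefix = "xyz")
  expect_identical(cl2@geneNames, c("xyzA", "xyzB", "xyzC"))
  empty <- new("GeneCluster", contigId = "c1", geneIds = character(0),
               flags = S4Vectors::DataFrame())
  expect_error(nameClusterGenes(empty), "empty")
})

test_that("architecture typing is reversal-invariant and size-ordered", {
  seqs <- list(sA = c("f1", "f2", "f3"),
               sB = c("f1", "f2", "f3"),
               sC = c("f3", "f2", "f1"),        # full reversal: same type
               sD = c("f1", "x1", "x2", "x3", "x4", "x5", "f2", "f3"),
               sE = c("f9", "f8"))
  ty <- typeClusterArchitectures(seqs)
  expect_identical(unname(ty["sA"]), unname(ty["sB"]))
  expect_identical(unname(ty["sA"]), unname(ty["sC"]))
  expect_false(ty[["sD"]] == ty[["sA"]])
  # largest class gets type I
  expect_identical(unname(ty["sA"]), "I")
  expect_setequal(unique(unname(ty)), c("I", "II", "III"))
  expect_error(typeClusterArchitectures(list(s = c("f1", NA))),
               "unlabelled")
})

test_that("the integrated pipeline recovers exactly the planted cluster", {
  sim <- small_sim()
  ref <- referenceStrain(sim$truth)
  counts <- simulateCountMatrix(sim$genomes, sim$truth, seed = 2)
  rep <- runFullPipeline(sim$genomes, ref, counts = counts,
                         families = small_families(),
                         kmer_params = small_kp(),
                         kmer_matrix = small_kmer_matrix(),
                         gene_codes = small_gene_codes())
  expect_s4_class(rep, "ClusterReport")
  expect_gte(length(rep@clusters), 1L)
  planted <- sim$truth@plantedGeneIds[[ref]]
  expect_true(all(planted %in% rep@clusters[[1]]@geneIds))
  expect_identical(unname(rep@status[c("kmer", "family", "de")]),
                   c("ok", "ok", "ok"))
  # carriers dominate one architecture type at zero noise (the reference
  # itself may differ when a decoy candidate sits next to the cluster)
  expect_setequal(names(rep@architectures),
                  names(sim$truth@plantedGeneIds))
  expect_gte(sum(rep@architectures == "I"), 3L)
  # DE channel omitted: two-set Venn, pipeline still completes
  rep2 <- runFullPipeline(sim$genomes, ref,
                          families = small_families(),
                          kmer_params = small_kp(),
                          kmer_matrix = small_kmer_matrix(),
                          gene_codes = small_gene_codes())
  expect_identical(unname(rep2@status["de"]), "skipped")
  expect_true(is.na(rep2@venn["all_three"]))
  expect_true(all(planted %in% rep2@clusters[[1]]@geneIds))
})

test_that("reports export to JSON and TSV", {
  sim <- small_sim()
  ref <- referenceStrain(sim$truth)
  rep <- runFullPipeline(sim$genomes, ref, families = small_families(),
                         kmer_params = small_kp(),
                         kmer_matrix = small_kmer_matrix(),
                         gene_codes = small_gene_codes())
  dir <- withr::local_tempdir()
  path <- exportReport(rep, dir)
  js <- jsonlite::read_json(path)
  expect_identical(js$reference_strain, ref)
  expect_length(js$clusters, length(rep@clusters))
  expect_true(file.exists(file.path(dir, "kmer_association.tsv")))
})
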