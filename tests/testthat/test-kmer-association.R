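test_that("canonical kmer sets match direct window enumeration", {
  expect_identical(canonicalKmers("ACGTA", 4), c("ACGT", "CGTA"))
  expect_identical(canonicalKmers("ACNGT", 3), character(0))
  expect_identical(canonicalKmers("ACG", 4), character(0))
  set.seed(3)
  for (i in 1:15) {
    s <- random_dna(sample(30:120, 1))
    k <- sample(8:21, 1)
    expect_identical(canonicalKmers(s, k), oracle_canonical_kmers(s, k))
    expect_identical(canonicalKmers(reverseComplement(s), k),
                     canonicalKmers(s, k))
  }
  # N interrupts windows exactly as enumeration says
  sN <- paste0(random_dna(30), "N", random_dna(30))
  expect_identical(canonicalKmers(sN, 11), oracle_canonical_kmers(sN, 11))
})

test_that("kmer matrix records presence and phenotype scores", {
  gs <- toy_genomeset()
  kp <- kmerParams(k = 11)
  km <- buildKmerMatrix(gs, kp)
  expect_s4_class(km, "KmerMatrix")
  # score = (#positive carriers) - (#negative carriers), bounded by design
  expect_true(all(km@scores %in% c(-1L, 0L, 1L)))
  in_both <- Matrix::rowSums(km@presence) == 2
  only_pos <- as.vector(km@presence[, 1]) & !as.vector(km@presence[, 2])
  expect_true(all(km@scores[in_both] == 0L))   # +1 (positive) - 1 (negative)
  expect_true(all(km@scores[only_pos] == 1L))
  # kmers of the shared gene are present in both strains
  shared <- canonicalKmers(geneTable(gs, "s1")$nt_seq[1], 11)
  expect_true(all(shared %in% kmerStrings(km, in_both)))
  # memory guard
  expect_error(buildKmerMatrix(gs, kmerParams(max_kmers = 10)), "cap")
})

test_that("kmer scores stay within class-size bounds and rescore under permutations", {
  sim <- small_sim()
  km <- small_kmer_matrix()
  ph <- phenotypeLabels(sim$genomes)
  expect_true(all(km@scores >= -sum(ph == "negative")))
  expect_true(all(km@scores <= sum(ph == "positive")))
  set.seed(1)
  perm <- setNames(sample(unname(ph)), names(ph))
  resc <- kmerScores(km, perm)
  expect_identical(kmerScores(km, ph), km@scores)
  expect_identical(sum(resc == km@scores) == length(resc), FALSE)
  expect_true(all(resc >= -5L & resc <= 4L))
})

test_that("high-scoring kmers map to genes on either strand", {
  sim <- small_sim()
  km <- small_kmer_matrix()
  high <- mapHighKmersToGenes(km, sim$genomes, "S01", small_kp(),
                              gene_codes = small_gene_codes())
  ref <- referenceStrain(sim$truth)
  expect_true(all(sim$truth@plantedGeneIds[[ref]] %in%
                  mapHighKmersToGenes(km, sim$genomes, ref, small_kp())))
  # minus-strand planted genes are still found (canonical invariance)
  g <- geneTable(sim$genomes, ref)
  planted_strands <- g$strand[match(sim$truth@plantedGeneIds[[ref]], g$gene_id)]
  expect_true(any(planted_strands == "-"))
  # unattainable score: empty list, no error
  expect_identical(
    mapHighKmersToGenes(km, sim$genomes, ref, kmerParams(min_score = 10)),
    character(0))
  expect_error(mapHighKmersToGenes(km, sim$genomes, "nope", small_kp()),
               "unknown reference")
})

test_that("greedy clustering joins by alignment identity, verified by oracle", {
  set.seed(8)
  s1 <- random_dna(300)
  s2 <- random_dna(300)
  # oracle: the two random sequences really are below threshold
  aln <- Biostrings::pairwiseAlignment(
    s1, s2, type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
    gapOpening = 2, gapExtension = 1)
  expect_lt(Biostrings::nmatch(aln) / 300, 0.7)
  cl <- greedyClusterGenes(c(a1 = s1, a2 = s1, b = s2), 0.7, "dna")
  expect_length(cl, 2L)
  expect_setequal(
    vapply(cl, function(x) length(x$members), integer(1)), c(2L, 1L))
  # threshold 1 with distinct sequences: every sequence its own centroid
  cl1 <- greedyClusterGenes(c(a = s1, b = s2, c = random_dna(300)), 1, "dna")
  expect_length(cl1, 3L)
  single <- greedyClusterGenes(c(only = s1), 0.7, "dna")
  expect_length(single, 1L)
  expect_identical(single[[1]]$members, "only")
})

test_that("centroid hit lists require kmer containment and identity", {
  sim <- small_sim()
  ref <- referenceStrain(sim$truth)
  g <- geneTable(sim$genomes, ref)
  planted <- sim$truth@plantedGeneIds[[ref]][1]
  seqs <- setNames(g$nt_seq[match(planted, g$gene_id)], planted)
  hits <- centroidHitLists(seqs, sim$genomes, small_kp(),
                           gene_codes = small_gene_codes())
  # a planted gene's orthologs cover exactly the carriers
  expect_setequal(hits[[planted]]$strain_id,
                  names(sim$truth@plantedGeneIds))
  expect_true(planted %in% hits[[planted]]$gene_id)
  # a foreign random sequence hits nothing but itself (absent here)
  alien <- setNames(random_dna(600), "alien")
  h2 <- centroidHitLists(alien, sim$genomes, small_kp(),
                         gene_codes = small_gene_codes())
  expect_identical(nrow(h2$alien), 0L)
})

test_that("presence Fisher test matches the enumeration oracle", {
  sim <- small_sim()
  ph <- phenotypeLabels(sim$genomes)
  pos <- names(ph)[ph == "positive"]
  neg <- names(ph)[ph == "negative"]
  # perfect association, one-sided closed form
  f <- presenceFisher(pos, sim$genomes, alternative = "greater")
  expect_equal(f$p, 1 / choose(9, 4), tolerance = 1e-12)
  # everywhere: uninformative
  expect_equal(presenceFisher(names(ph), sim$genomes)$p, 1)
  # mixed patterns against the oracle, both sidednesses
  set.seed(4)
  for (i in 1:20) {
    carriers <- sample(names(ph), sample(0:9, 1))
    for (alt in c("two.sided", "greater")) {
      f <- presenceFisher(carriers, sim$genomes, alternative = alt)
      expect_equal(f$p, oracle_fisher(f$table[1, 1], f$table[1, 2],
                                      f$table[2, 1], f$table[2, 2], alt),
                   tolerance = 1e-12)
    }
  }
  expect_error(presenceFisher("ghost", sim$genomes), "outside")
})

test_that("kmer association recovers the planted cluster genes", {
  sim <- small_sim()
  ref <- referenceStrain(sim$truth)
  res <- runKmerAssociation(sim$genomes, ref, small_kp(),
                            kmer_matrix = small_kmer_matrix(),
                            gene_codes = small_gene_codes())
  expect_true(all(sim$truth@plantedGeneIds[[ref]] %in%
                  res$significant_genes))
  expect_true(all(res$assoc$p_adj >= res$assoc$p))
  planted_rows <- res$assoc$unit_id %in% sim$truth@plantedGeneIds[[ref]]
  expect_true(all(res$assoc$p[planted_rows] < 0.05))
  # raising the score threshold above the class size empties the result
  res0 <- runKmerAssociation(sim$genomes, ref, kmerParams(min_score = 10),
                             kmer_matrix = small_kmer_matrix(),
                             gene_codes = small_gene_codes())
  expect_identical(res0$significant_genes, character(0))
  expect_identical(nrow(res0$assoc), 0L)
})
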