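# Shared fixtures, built in code and memoized for the duration of a test
# run (helpers are sourced once per session by testthat).

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A hand-built 2-strain genome set: 1 contig, 3 genes each (one on the
# minus strand), with a shared gene and strain-private genes.
toy_genomeset <- function() {
  geneA <- "ATGGCTGAAACTGGTTCTAAA"                 # 21 nt, shared
  geneB <- "ATGCCGCCGCCGAAAGGTTGA"                 # strain-1 private
  geneC <- "ATGTTTGGTAAACCCGGGTAA"                 # strain-2 private
  sp <- "TTTTTTTTTT"
  c1 <- paste0(sp, geneA, sp, geneB, sp,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(geneA))), sp)
  c2 <- paste0(sp, geneA, sp, geneC, sp, geneC, sp)
  g1 <- data.frame(
    gene_id = c("s1g1", "s1g2", "s1g3"),
    contig_id = "c1",
    start = c(10, 41, 72), end = c(31, 62, 93),
    strand = c("+", "+", "-"))
  g2 <- data.frame(
    gene_id = c("s2g1", "s2g2", "s2g3"),
    contig_id = "c1",
    start = c(10, 41, 72), end = c(31, 62, 93),
    strand = "+")
  GenomeSet(list(StrainGenome("s1", c(c1 = c1), g1),
                 StrainGenome("s2", c(c1 = c2), g2)),
            c(s1 = "positive", s2 = "negative"))
}

# A small simulated panel (4+/5-, 40 background genes, 5-gene cluster)
# used by most unit tests; min_score is lowered to the positive-class
# size to match the reduced design.
small_sim <- function() memo("small_sim", simulateGenomeSet(
  SimParams(n_pos = 4, n_neg = 5, genes_per_genome = 40,
            cluster_size = 5, seed = 7)))

small_kp <- function() kmerParams(min_score = 4)

small_kmer_matrix <- function()
  memo("small_km", buildKmerMatrix(small_sim()$genomes, small_kp()))

small_gene_codes <- function()
  memo("small_gc", geneKmerIndex(small_sim()$genomes, small_kp()))

small_families <- function()
  memo("small_fam", buildFamiliesDenovo(small_sim()$genomes))

# Full default-scale study panel (16+/23-, 300 background genes, 15-gene
# cluster, seed 42) shared by the acceptance checks.
default_sim <- function() memo("default_sim", simulateGenomeSet(SimParams()))

default_km <- function()
  memo("default_km", buildKmerMatrix(default_sim()$genomes))

default_gc <- function()
  memo("default_gc", geneKmerIndex(default_sim()$genomes))

default_fam <- function()
  memo("default_fam", buildFamiliesDenovo(default_sim()$genomes))

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_protein <- function(n) paste(sample(strsplit(
  "ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE), collapse = "")

# Independent oracle: canonical kmer set by direct window enumeration.
oracle_canonical_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  win <- substring(seq, 1:(L - k + 1), k:L)
  win <- win[!grepl("[^ACGT]", win)]
  if (!length(win)) return(character(0))
  rc <- vapply(win, function(w) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(w))), character(1))
  sort(unique(pmin(win, rc)))
}

# Independent oracle: hypergeometric enumeration of the Fisher p-value
# over all tables with the observed margins.
oracle_fisher <- function(a, b, c, d, alternative = "two.sided") {
  npos <- a + b; nneg <- c + d; K <- a + c
  xs <- max(0, K - nneg):min(K, npos)
  pr <- exp(lchoose(npos, xs) + lchoose(nneg, K - xs) -
            lchoose(npos + nneg, K))
  pobs <- pr[xs == a]
  if (alternative == "greater") sum(pr[xs >= a])
  else min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}
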