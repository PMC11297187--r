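test_that("simulated panels are reproducible and plant the cluster in positives", {
  p <- SimParams(n_pos = 3, n_neg = 4, genes_per_genome = 30,
                 cluster_size = 4, seed = 11)
  a <- simulateGenomeSet(p)
  b <- simulateGenomeSet(p)
  expect_identical(
    lapply(a$genomes@strains, function(s) as.character(s@contigs)),
    lapply(b$genomes@strains, function(s) as.character(s@contigs)))
  expect_identical(a$truth@phenotype, b$truth@phenotype)
  carriers <- names(a$truth@plantedGeneIds)
  expect_setequal(carriers,
                  names(which(a$truth@phenotype == "positive")))
  # planted genes contiguous in each carrier
  for (sid in carriers) {
    g <- geneTable(a$genomes, sid)
    idx <- match(a$truth@plantedGeneIds[[sid]], g$gene_id)
    expect_identical(diff(idx), rep(1L, length(idx) - 1L))
  }
})

test_that("cluster noise controls carriage", {
  p <- SimParams(n_pos = 3, n_neg = 3, genes_per_genome = 20,
                 cluster_size = 3, cluster_noise_drop = 1.0, seed = 5)
  sim <- simulateGenomeSet(p)
  expect_length(sim$truth@plantedGeneIds, 0L)
  p2 <- SimParams(n_pos = 2, n_neg = 2, genes_per_genome = 20,
                  cluster_size = 3, cluster_noise_gain = 1.0, seed = 5)
  sim2 <- simulateGenomeSet(p2)
  expect_setequal(names(sim2$truth@plantedGeneIds),
                  names(sim2$truth@phenotype))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(SimParams(cluster_size = 0), "cluster_size")
  expect_error(SimParams(cluster_size = 400, genes_per_genome = 300),
               "exceeds")
  expect_error(SimParams(core_fraction = 1.5), "probabilities")
  expect_error(SimParams(n_pos = 0), "class")
})

test_that("count simulation respects the planted fold change and NB limits", {
  sim <- small_sim()
  # null fold change: per-gene condition means agree within sampling error
  se0 <- simulateCountMatrix(sim$genomes, sim$truth,
                             n_reps_per_condition = 50,
                             lfc_cluster = 0, dispersion = 0.01, seed = 3)
  m <- SummarizedExperiment::assay(se0)
  cond <- SummarizedExperiment::colData(se0)$condition
  ratio <- rowMeans(m[, cond == "MBOA"]) / pmax(rowMeans(m[, cond == "control"]), 1)
  expect_lt(max(abs(log2(ratio))), 0.5)
  # Poisson limit: dispersion 0 gives variance ~ mean
  sep <- simulateCountMatrix(sim$genomes, sim$truth,
                             n_reps_per_condition = 200,
                             lfc_cluster = 0, dispersion = 0, seed = 4)
  mp <- SummarizedExperiment::assay(sep)
  vm <- apply(mp, 1, var) / pmax(rowMeans(mp), 1)
  expect_lt(abs(median(vm) - 1), 0.15)
  expect_error(simulateCountMatrix(sim$genomes, sim$truth,
                                   n_reps_per_condition = 1), ">= 2")
})

test_that("assay tables close the loop back to the generated phenotype", {
  sim <- small_sim()
  assays <- simulatePhenotypeAssays(sim$genomes, sim$truth, seed = 2)
  met <- assays$metabolites
  nbc <- met[met$is_control, ]
  expect_identical(nbc$concentration[nbc$compound == "MBOA"], 500)
  expect_identical(nbc$concentration[nbc$compound == "AMPO"], 0)
  cls <- classifyMetaboliteTable(met)
  truth_ph <- sim$truth@phenotype[cls$strain_id]
  expect_identical(unname(cls$phenotype_call), unname(truth_ph))
  expect_true(all(cls$degrader_class[truth_ph == "positive"] == "strong"))
  expect_true(all(cls$degrader_class[truth_ph == "negative"] == "non"))
})

test_that("positive strains gain growth capacity on the carbon source", {
  sim <- small_sim()
  growth <- simulatePhenotypeAssays(sim$genomes, sim$truth, seed = 2)$growth
  aucs <- lapply(split(growth, growth[c("strain_id", "treatment")]),
                 function(d) vapply(split(d, d$replicate), function(r)
                   growthAUC(r$time_h, r$od600), numeric(1)))
  sids <- unique(growth$strain_id)
  tr <- setNames(aucs[paste(sids, "MBOA", sep = ".")], sids)
  ct <- setNames(aucs[paste(sids, "DMSO", sep = ".")], sids)
  res <- growthBenefitTest(tr, ct)
  ph <- sim$truth@phenotype[res$strain_id]
  expect_true(all(res$ratio[ph == "positive"] > 1))
  expect_true(all(res$p_adj[ph == "positive"] < 0.05))
  expect_true(all(abs(res$ratio[ph == "negative"] - 1) < 0.2))
})
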