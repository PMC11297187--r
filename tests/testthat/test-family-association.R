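write_og_table <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("orthogroup tables parse with copy numbers and validation", {
  path <- write_og_table(c("Orthogroup\tsA\tsB",
                           "OG1\ta1, a2\tb1",
                           "OG2\t\tb2"))
  fams <- readOrthogroupTable(path)
  expect_s4_class(fams, "GeneFamilySet")
  expect_length(fams@families, 2L)
  cn <- copyNumberMatrix(fams)
  expect_identical(cn["OG1", ], c(sA = 2L, sB = 1L))
  expect_identical(cn["OG2", ], c(sA = 0L, sB = 1L))
  expect_identical(familyMembers(fams, "OG1")$sA, c("a1", "a2"))
  dup <- write_og_table(c("Orthogroup\tsA", "OG1\tg1", "OG2\tg1"))
  expect_error(readOrthogroupTable(dup), "more than one family")
  expect_error(readOrthogroupTable(path, toy_genomeset()),
               "unknown strain")
})

test_that("de-novo families recover the planted orthology structure", {
  sim <- small_sim()
  fams <- small_families()
  carriers <- names(sim$truth@plantedGeneIds)
  # each planted gene's orthologs across carriers form exactly one family
  planted_first <- vapply(carriers, function(s)
    sim$truth@plantedGeneIds[[s]][1], character(1))
  hit <- vapply(names(fams@families), function(fid) {
    mem <- unlist(familyMembers(fams, fid), use.names = FALSE)
    all(planted_first %in% mem) && length(mem) == length(planted_first)
  }, logical(1))
  expect_identical(sum(hit), 1L)
  # two identical proteomes give 1/1 copy structure everywhere
  set.seed(13)
  genes3 <- vapply(1:3, function(i) paste0(
    "ATG", paste(sample(setdiff(as.vector(outer(outer(c("A","C","G","T"),
      c("A","C","G","T"), paste0), c("A","C","G","T"), paste0)),
      c("TAA", "TAG", "TGA")), 40, replace = TRUE), collapse = ""), "TAA"),
    character(1))
  contig <- paste0("TTTT", paste(genes3, collapse = "TTTT"), "TTTT")
  mk <- function(sid) {
    starts <- 4L + (0:2) * (nchar(genes3[1]) + 4L)
    StrainGenome(sid, c(c1 = contig),
                 data.frame(gene_id = paste0(sid, "_g", 1:3),
                            contig_id = "c1", start = starts,
                            end = starts + nchar(genes3[1]), strand = "+"))
  }
  gs2 <- GenomeSet(list(mk("tw1"), mk("tw2")),
                   c(tw1 = "positive", tw2 = "negative"))
  f2 <- buildFamiliesDenovo(gs2, prescreen_k = NULL)
  expect_length(f2@families, 3L)
  expect_true(all(copyNumberMatrix(f2) == 1L))
})

test_that("unique and specific family calls mirror the planted cluster", {
  sim <- small_sim()
  fams <- small_families()
  res <- uniqueSpecificFamilies(fams, sim$genomes)
  expect_length(res$called, 5L)
  carriers <- names(sim$truth@plantedGeneIds)
  for (fid in res$called)
    expect_setequal(names(familyMembers(fams, fid)), carriers)
  # the perfect pattern achieves the one-sided closed form
  row <- res$assoc[res$assoc$unit_id == res$called[1], ]
  expect_equal(oracle_fisher(row$a, row$b, row$c, row$d, "greater"),
               1 / choose(9, 4), tolerance = 1e-12)
  # a family present everywhere is never called and is uninformative
  everywhere <- res$assoc$a == 4 & res$assoc$c == 5
  expect_true(any(everywhere))
  expect_true(all(!res$assoc$called[everywhere]))
  expect_true(all(res$assoc$p[everywhere] == 1))
})

test_that("relaxing the positive fraction monotonically grows the call set", {
  sim <- small_sim()
  fams <- small_families()
  called <- lapply(c(1, 0.75, 0.5), function(f)
    uniqueSpecificFamilies(fams, sim$genomes,
                           familyCallParams(unique_min_pos_fraction = f))$called)
  expect_true(all(called[[1]] %in% called[[2]]))
  expect_true(all(called[[2]] %in% called[[3]]))
})

test_that("family calls are invariant to family and strain order", {
  sim <- small_sim()
  fams <- small_families()
  shuf <- new("GeneFamilySet",
              families = fams@families[sample(length(fams@families))],
              strainIds = rev(fams@strainIds))
  a <- uniqueSpecificFamilies(fams, sim$genomes)
  b <- uniqueSpecificFamilies(shuf, sim$genomes)
  expect_setequal(a$called, b$called)
})
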