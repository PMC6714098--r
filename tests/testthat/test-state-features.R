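# Gene components, the overlap enrichment formula, state signal means, and
# the feature matrix.

test_that("overlap enrichment matches its formula and boundary cases", {
  expect_equal(overlap_enrichment(20, 100, 200, 1000), 0)  # obs = expected
  expect_equal(overlap_enrichment(0, 0, 200, 1000), 0)     # pseudocount
  expect_equal(overlap_enrichment(40, 100, 200, 1000), log2(41 / 21))
  # monotone in the overlap with other counts fixed
  e <- vapply(0:100, overlap_enrichment, 1.0, n_l = 100, n_c = 200,
              n = 1000)
  expect_true(all(diff(e) > 0))
})

test_that("gene components decompose a 3-exon plus-strand gene correctly", {
  lay <- genome_layout("c1", 100000)
  gm <- gene_models(data.frame(
    gene_id = "g", chrom = "c1", strand = "+",
    start = c(20000, 22000, 25000), end = c(20500, 22800, 26000)))
  comp <- derive_gene_components(gm, lay)
  expect_equal(comp$initial_exon, data.frame(chrom = "c1", start = 20000,
                                             end = 20500))
  expect_equal(comp$internal_exons$start, 22000)
  expect_equal(comp$terminal_exon$start, 25000)
  expect_equal(comp$initial_intron, data.frame(chrom = "c1", start = 20500,
                                               end = 22000))
  expect_equal(comp$internal_introns$start, 22800)
  expect_equal(comp$flank5_near, data.frame(chrom = "c1", start = 19000,
                                            end = 20000))
  expect_equal(comp$flank5_far, data.frame(chrom = "c1", start = 10000,
                                           end = 19000))
  expect_equal(comp$flank3_near, data.frame(chrom = "c1", start = 26000,
                                            end = 27000))
  expect_equal(comp$flank3_far$end, 36000)
})

test_that("minus-strand genes mirror the decomposition and single-exon
           genes contribute only the initial exon and flanks", {
  lay <- genome_layout("c1", 100000)
  gm <- gene_models(data.frame(
    gene_id = "g", chrom = "c1", strand = "-",
    start = c(20000, 22000, 25000), end = c(20500, 22800, 26000)))
  comp <- derive_gene_components(gm, lay)
  expect_equal(comp$initial_exon$start, 25000)   # 5'-most on minus strand
  expect_equal(comp$terminal_exon$start, 20000)
  expect_equal(comp$flank5_near, data.frame(chrom = "c1", start = 26000,
                                            end = 27000))
  expect_equal(comp$initial_intron$start, 22800) # first intron from 5'
  single <- derive_gene_components(gene_models(data.frame(
    gene_id = "s", chrom = "c1", strand = "+", start = 5000, end = 6000)),
    lay)
  expect_equal(single$initial_exon$start, 5000)
  expect_equal(nrow(single$terminal_exon), 0)
  expect_equal(nrow(single$initial_intron), 0)
  # flanks clipped at chromosome boundaries
  near0 <- derive_gene_components(gene_models(data.frame(
    gene_id = "e", chrom = "c1", strand = "+", start = 500, end = 1500)),
    lay)
  expect_equal(near0$flank5_near, data.frame(chrom = "c1", start = 0,
                                             end = 500))
  expect_equal(nrow(near0$flank5_far), 0)  # entirely off-chromosome
  expect_error(gene_models(data.frame(gene_id = "b", chrom = "c1",
                                      strand = "+", start = 10, end = 10)),
               "end <= start")
})

test_that("state mean signal is the base-weighted mean over unmasked bins", {
  ann <- annotation(data.frame(chrom = "c1", start = c(0, 200, 400),
                               end = c(200, 400, 600),
                               state = c(0L, 1L, 0L)), "x")
  tr <- toy_track(c(1, 3, 7, 7, 2, 2), rep(0, 8))
  expect_equal(state_mean_signal(ann, 0, tr), 2)
  expect_equal(state_mean_signal(ann, 1, tr), 7)
  # one 1-bin segment at value 0 and one 3-bin segment at value 1
  ann2 <- annotation(data.frame(chrom = "c1", start = c(0, 100, 200),
                                end = c(100, 200, 500),
                                state = c(5L, 0L, 5L)), "x")
  tr2 <- toy_track(c(0, 9, 1, 1, 1, 0), rep(0, 8))
  expect_equal(state_mean_signal(ann2, 5, tr2), 0.75)
  expect_error(state_mean_signal(ann, 3, tr), "absent")
  expect_error(state_mean_signal(ann, 1, mask_track(tr, data.frame(
    chrom = "c1", start = 200, end = 400))), "masked")
})

test_that("feature matrix has the canonical shape, flags substituted marks,
           and recovers planted signatures", {
  cells <- fix_cells()
  sim <- cells[[1]]
  comp <- derive_gene_components(fix_genes(), fix_layout())
  cat <- track_catalog()
  for (m in canonical_marks())
    cat <- catalog_add(cat, "ct1", m, sim$tracks[[m]])
  fm <- build_feature_matrix(sim$annotation, cat, comp, fix_layout())
  expect_equal(ncol(fm), 15)
  expect_equal(nrow(fm), length(unique(sim$annotation$segments$state)))
  expect_false(any(attr(fm, "substituted")))
  expect_true(all(is.finite(fm)))
  # planted promoter signature: max H3K4me3 mean, positive TSS-flank
  # enrichment
  tt <- sim$truth$state_term
  st <- sort(unique(sim$annotation$segments$state))
  prom <- which(tt[as.character(st)] == "Promoter")
  expect_true(which.max(fm[, "mean_H3K4me3"]) %in% prom)
  expect_true(all(fm[prom, "enr_flank5_near"] > 0))
  # missing mark computed on a donor track and flagged
  cat2 <- track_catalog()
  for (m in setdiff(canonical_marks(), "H3K9me3"))
    cat2 <- catalog_add(cat2, "ct1", m, sim$tracks[[m]])
  for (m in canonical_marks())
    cat2 <- catalog_add(cat2, "ct2", m, cells[[2]]$tracks[[m]])
  fm2 <- build_feature_matrix(sim$annotation, cat2, comp, fix_layout())
  expect_true(attr(fm2, "substituted")[["H3K9me3"]])
  expect_equal(attr(fm2, "donors")[["H3K9me3"]], "ct2")
  expect_equal(fm2[, "mean_H3K4me3"], fm[, "mean_H3K4me3"])
  expect_false(isTRUE(all.equal(fm2[, "mean_H3K9me3"],
                                fm[, "mean_H3K9me3"])))
})

test_that("state overlaps with a component partition the component's
           overlap with annotated territory", {
  ann <- fix_cells()[[1]]$annotation
  comp <- derive_gene_components(fix_genes(), fix_layout())$initial_exon
  st <- sort(unique(ann$segments$state))
  parts <- vapply(st, function(s) overlap_bases(state_intervals(ann, s),
                                                comp), 1.0)
  whole <- overlap_bases(ann$segments[, c("chrom", "start", "end")], comp)
  expect_equal(sum(parts), whole)
})

test_that("feature matrices are equivariant under state relabeling", {
  sim <- fix_cells()[[1]]
  comp <- derive_gene_components(fix_genes(), fix_layout())
  cat <- track_catalog()
  for (m in canonical_marks())
    cat <- catalog_add(cat, "ct1", m, sim$tracks[[m]])
  fm <- build_feature_matrix(sim$annotation, cat, comp, fix_layout())
  # relabel: swap states 0 and 1
  ann2 <- sim$annotation
  s <- ann2$segments$state
  ann2$segments$state <- ifelse(s == 0L, 1L, ifelse(s == 1L, 0L, s))
  fm2 <- build_feature_matrix(ann2, cat, comp, fix_layout())
  expect_equal(unname(fm2[1:2, ]), unname(fm[2:1, ]))
  expect_equal(unname(fm2[-(1:2), ]), unname(fm[-(1:2), ]))
})

test_that("feature TSV round-trips", {
  sim <- fix_cells()[[1]]
  comp <- derive_gene_components(fix_genes(), fix_layout())
  cat <- track_catalog()
  for (m in canonical_marks())
    cat <- catalog_add(cat, "ct1", m, sim$tracks[[m]])
  fm <- build_feature_matrix(sim$annotation, cat, comp, fix_layout())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(fm, f)
  back <- read_feature_tsv(f)
  expect_equal(back, structure(fm, substituted = NULL, donors = NULL),
               tolerance = 1e-10)
})
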