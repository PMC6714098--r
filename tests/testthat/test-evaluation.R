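# Meta-gene profiles, overlap matrices, expression predictiveness, SNP
# enrichment curves.

test_that("meta-gene profile is flat for uniformly random labels and peaked
           for a TSS-only label", {
  lay <- genome_layout(c("m1", "m2"), c(2e6, 2e6))
  genes <- simulate_genes(lay, n_genes = 300, seed = 51)
  set.seed(51)
  # random annotation: iid labels per bin
  nb <- 20000
  segs <- do.call(rbind, lapply(c("m1", "m2"), function(ch) {
    st <- sample(0:3, nb, replace = TRUE)
    r <- rle(st); e <- cumsum(r$lengths) * 100
    data.frame(chrom = ch, start = c(0, e[-length(e)]), end = e,
               state = r$values)
  }))
  ann <- annotation(segs, "rand", n_states = 4)
  terms <- c("0" = "Quiescent", "1" = "Promoter", "2" = "Enhancer",
             "3" = "Transcribed")
  prof <- metagene_profile(ann, terms, genes, n_body_bins = 10,
                           flank_bp = 2000)
  expect_lt(max(abs(prof)), 0.75)  # sampling error only (300 genes)
  # TSS-only label (painted over TSS +- 200 bp): strongly positive at the
  # innermost flank and first body positions, capped far away
  gt <- gene_table(genes)
  segs2 <- do.call(rbind, lapply(c("m1", "m2"), function(ch) {
    st <- integer(nb)
    for (b in floor(gt$tss[gt$chrom == ch] / 100))
      st[pmax(1, b - 1):pmin(nb, b + 3)] <- 1L
    r <- rle(st); e <- cumsum(r$lengths) * 100
    data.frame(chrom = ch, start = c(0, e[-length(e)]), end = e,
               state = r$values)
  }))
  ann2 <- annotation(segs2, "tss", n_states = 2)
  prof2 <- metagene_profile(ann2, c("0" = "Quiescent", "1" = "Promoter"),
                            genes, n_body_bins = 10, flank_bp = 2000,
                            cap = -8)
  npos <- ncol(prof2)
  nf <- 20  # flank columns on each side
  expect_gt(prof2["Promoter", nf], 2)       # innermost upstream position
  expect_gt(prof2["Promoter", nf + 1], 2)   # first body position
  expect_equal(unname(prof2["Promoter", c(1:10, (npos - 9):npos)]),
               rep(-8, 20))
})

test_that("overlap matrix is maximal on the diagonal against itself and
           near zero for an independent shift", {
  sim <- fix_cells()[[1]]
  ann <- sim$annotation
  terms <- sim$truth$state_term
  m <- annotation_overlap_matrix(ann, terms, ann, terms, fix_layout())
  for (tm in rownames(m))
    expect_equal(names(which.max(m[tm, ])), tm)
  # circular shift by half the genome of a stationary random annotation:
  # independent by construction, so all cells are near zero
  set.seed(57)
  nb <- 10000
  rand_segs <- do.call(rbind, lapply(c("chrS1", "chrS2"), function(ch) {
    st <- sample(0:3, nb, replace = TRUE)
    r <- rle(st); e <- cumsum(r$lengths) * 100
    data.frame(chrom = ch, start = c(0, e[-length(e)]), end = e,
               state = r$values)
  }))
  ann_r <- annotation(rand_segs, "rand", n_states = 4)
  terms_r <- c("0" = "Quiescent", "1" = "Promoter", "2" = "Enhancer",
               "3" = "Transcribed")
  shifted <- rand_segs
  shifted$start <- (shifted$start + 5e5) %% 1e6
  shifted$end <- shifted$start + (rand_segs$end - rand_segs$start)
  shifted$end[shifted$end > 1e6] <- 1e6
  shifted <- shifted[shifted$end > shifted$start, ]
  ann_s <- annotation(shifted, "shifted", n_states = 4)
  m2 <- annotation_overlap_matrix(ann_r, terms_r, ann_s, terms_r,
                                  fix_layout())
  expect_lt(max(abs(m2)), 0.1)
  # a term absent from b sits at the formula's floor
  terms_b <- c("0" = "Quiescent", "1" = "Quiescent", "2" = "Enhancer",
               "3" = "Transcribed")
  m3 <- annotation_overlap_matrix(ann_r, terms_r, ann_s, terms_b,
                                  fix_layout())
  expect_false("Promoter" %in% colnames(m3))
})

test_that("one-hot promoter-window features have 38 positions and exactly
           38 ones per gene", {
  offs <- promoter_window_offsets()
  expect_length(offs, 38)
  expect_equal(sum(offs >= -1000 & offs < 1000), 20)
  expect_equal(sum(offs <= -2000), 9)
  expect_equal(sum(offs >= 2000), 9)
  sim <- fix_cells()[[1]]
  feats <- stateatlas:::.one_hot_features(sim$annotation, fix_genes())
  expect_equal(ncol(feats$X), 38 * sim$annotation$n_states)
  expect_true(all(rowSums(feats$X) == 38))
})

test_that("expression predictiveness finds a planted promoter effect and
           nothing in permuted labels", {
  lay <- genome_layout(c("chrE1", "chrE2"), c(2e7, 2e7))
  genes <- simulate_genes(lay, n_genes = 2000, seed = 61)
  genome <- simulate_genome(lay, genes = genes, seed = 61)
  sims <- lapply(1:4, function(i)
    simulate_cell_type(genome, seed = 300 + i, cell_type = paste0("e", i)))
  truths <- stats::setNames(lapply(sims, `[[`, "truth"),
                            paste0("e", 1:4))
  expr <- simulate_expression(truths, genes, alpha = 1.5, sigma = 0.5,
                              seed = 62)
  res <- expression_predictiveness(sims[[1]]$annotation, genes, expr,
                                   seed = 63)
  expect_equal(nrow(res), 5)
  expect_gte(res$r2[res$quintile == 5], 0.5)
  resp <- expression_predictiveness(sims[[1]]$annotation, genes, expr,
                                    seed = 63, permute = TRUE)
  expect_lte(max(resp$r2), 0.05)
  # deterministic given the split seed, invariant to gene order
  res2 <- expression_predictiveness(sims[[1]]$annotation, genes, expr,
                                    seed = 63)
  expect_equal(res, res2)
})

test_that("SNP enrichment curve tracks the diagonal for uniform SNPs and
           is dominated by score-enriched SNPs", {
  sc <- fix_scores()
  snps_u <- simulate_snps(sc, enrichment = 0, n_snps = 3000, seed = 71)
  cu <- snp_enrichment_curve(sc, snps_u)
  expect_true(all(diff(cu$curve$captured) >= 0))
  expect_equal(cu$curve$captured[nrow(cu$curve)], 1.0)
  expect_lt(max(abs(cu$curve$captured - cu$curve$x)), 0.05)
  snps_e <- simulate_snps(sc, enrichment = 3, n_snps = 3000, seed = 72)
  ce <- snp_enrichment_curve(sc, snps_e)
  mid <- cu$curve$x > 0.02 & cu$curve$x < 0.9
  expect_true(all(ce$curve$captured[mid] >= cu$curve$captured[mid] - 0.02))
  expect_gt(mean(ce$curve$captured[mid] - cu$curve$captured[mid]), 0.05)
  expect_gt(ce$median_genome_percentile, 0.5)
  # all SNPs inside the single top bin: curve complete after one bin
  top <- which.max(unlist(sc$total))
  nb <- length(unlist(sc$total))
  ch <- rep(names(sc$total), times = vapply(sc$total, length, 1L))[top]
  off <- top - c(0, cumsum(vapply(sc$total, length, 1L)))[
    match(ch, names(sc$total))]
  snps_top <- data.frame(chrom = ch, pos = (off - 1) * 100 + 5)
  ct <- snp_enrichment_curve(sc, snps_top, grid = c(1 / nb, 0.5, 1))
  expect_equal(ct$curve$captured, c(1, 1, 1))
  # SNPs outside scored territory are dropped with a count
  snps_bad <- rbind(snps_u, data.frame(chrom = "chrX", pos = 1))
  expect_equal(snp_enrichment_curve(sc, snps_bad)$n_dropped, 1)
})

test_that("single-annotation average curve is computed per annotation", {
  cells <- fix_cells()
  anns <- lapply(cells, `[[`, "annotation")
  snps <- simulate_snps(fix_scores(), enrichment = 2, n_snps = 500,
                        seed = 73)
  avg <- snp_curve_single_average(anns, fix_caas(), snps,
                                  grid = seq(0, 1, 0.05))
  expect_true(all(diff(avg$captured) >= -1e-12))
  expect_equal(avg$captured[nrow(avg)], 1)
  expect_true(all(avg$captured_sd >= 0))
})

test_that("CAA plot data reconstructs the total score and round-trips
           through its TSV", {
  sc <- fix_scores()
  segs <- extract_encyclopedia_segments(sc, preset_params())
  cp <- build_caa_plot(sc, "chrS1", 100000, 160000, segments = segs,
                       genes = fix_genes(), phylop = fix_conservation())
  tot <- tapply(cp$data$score, cp$data$pos, sum)
  bins <- (100000 / 100 + 1):(160000 / 100)
  expect_equal(as.numeric(tot), sc$total$chrS1[bins], tolerance = 1e-6)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_caa_plot_data(cp, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(sum(back$score), sum(sc$total$chrS1[bins]),
               tolerance = 1e-6)
  expect_true(inherits(cp$plot, "gg") || inherits(cp$plot, "patchwork"))
  expect_error(build_caa_plot(sc, "chrS1", 5000, 5000), "empty window")
})
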