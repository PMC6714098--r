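# Encyclopedia segment extraction and its brute-force oracle.

test_that("segmentation parameters validate and the preset matches its
           published values", {
  p <- preset_params("paper-2019")
  expect_equal(p[c("Z", "D", "S", "M_min", "L_min")],
               list(Z = 0.775, D = 1, S = 5, M_min = 0.02, L_min = 500))
  expect_error(segmentation_params(S = 0), "S > 0")
  expect_error(preset_params("nope"), "unknown preset")
})

test_that("the brute-force oracle honors every constraint on hand-built
           inputs", {
  p <- segmentation_params(Z = 0, D = 1, S = 5, M_min = 0.02, L_min = 500)
  # all-negative scores: nothing
  expect_equal(nrow(brute_force_segments(rep(-3, 50), p)), 0)
  # scores exactly at baseline (s = 0): nothing
  expect_equal(nrow(brute_force_segments(rep(0, 50), p)), 0)
  # one clean run passing everything: exactly that run
  s <- rep(-40, 40); s[11:20] <- 10
  out <- brute_force_segments(s, p)
  expect_equal(nrow(out), 1)
  expect_equal(out$start_bin, 11)
  expect_equal(out$end_bin, 20)
  expect_equal(out$score, 100)
  expect_equal(out$mean_bp, 0.1)
  # a 400-bp run (< L_min = 500) is rejected
  s2 <- rep(-40, 40); s2[11:14] <- 10
  expect_equal(nrow(brute_force_segments(s2, p)), 0)
  # two peaks joined by a net-profitable deep dip: the merged interval is
  # the unique maximal one and the valley filter rejects it
  s3 <- rep(-40, 60); s3[11:20] <- 10; s3[21] <- -2; s3[22:31] <- 10
  expect_equal(nrow(brute_force_segments(s3, p)), 0)
  # with a shallow dip (> -D) the same layout is one merged segment
  s4 <- s3; s4[21] <- -0.5
  out4 <- brute_force_segments(s4, p)
  expect_equal(nrow(out4), 1)
  expect_equal(c(out4$start_bin, out4$end_bin), c(11, 31))
  # two peaks separated by a long deep gap: crossing is score-decreasing,
  # so each peak is maximal on its own and both are reported
  s5 <- rep(-40, 70); s5[11:20] <- 10; s5[41:50] <- 10
  out5 <- brute_force_segments(s5, p)
  expect_equal(out5$start_bin, c(11, 41))
  expect_equal(out5$end_bin, c(20, 50))
  # literal valley rule: any strong interior subsegment disqualifies
  expect_equal(nrow(brute_force_segments(s, p, valley_rule = "literal")), 0)
  expect_error(brute_force_segments(rep(1, 501), p), "capped")
})

test_that("oracle output always satisfies the segment invariants", {
  set.seed(31)
  p <- preset_params()
  for (rep in 1:20) {
    f <- random_score_track(120)
    s <- (f - p$Z) * 100
    out <- brute_force_segments(s, p)
    if (nrow(out) == 0) next
    expect_true(all(out$score > p$S))
    expect_true(all(out$mean_bp >= p$M_min))
    expect_true(all(out$length_bp >= p$L_min))
    expect_true(all(diff(out$start_bin) > 0))
    expect_true(all(out$start_bin[-1] > out$end_bin[-nrow(out)]))
  }
})

test_that("the production extractor matches the brute-force oracle on
           random tracks under the published preset", {
  set.seed(33)
  p <- preset_params()
  hits <- 0
  for (rep in 1:40) {
    n <- sample(50:200, 1)
    f <- random_score_track(n)
    s <- (f - p$Z) * 100
    bf <- brute_force_segments(s, p)
    sc <- score_track_from(f)
    fast <- extract_encyclopedia_segments(sc, p, normalize = "none")
    expect_equal(nrow(fast), nrow(bf))
    if (nrow(bf) > 0) {
      hits <- hits + 1
      expect_equal((fast$start / 100) + 1, bf$start_bin)
      expect_equal(fast$end / 100, bf$end_bin)
      expect_equal(fast$score, bf$score)
    }
  }
  expect_gt(hits, 10)  # the comparison actually exercised segments
})

test_that("the extractor matches the oracle under random parameter sets and
           both valley rules", {
  set.seed(35)
  for (rep in 1:10) {
    p <- segmentation_params(Z = runif(1, 0.3, 1), D = runif(1, 0.5, 2),
                             S = runif(1, 1, 8), M_min = runif(1, 0, 0.05),
                             L_min = sample(2:8, 1) * 100)
    vr <- sample(c("split", "literal"), 1)
    f <- random_score_track(150)
    s <- (f - p$Z) * 100
    bf <- brute_force_segments(s, p, valley_rule = vr)
    fast <- extract_encyclopedia_segments(score_track_from(f), p,
                                          normalize = "none",
                                          valley_rule = vr)
    expect_equal(nrow(fast), nrow(bf))
    if (nrow(bf) > 0) {
      expect_equal((fast$start / 100) + 1, bf$start_bin)
      expect_equal(fast$score, bf$score)
    }
  }
})

test_that("extraction from an aggregated score track yields sorted,
           non-overlapping segments with coherent term fractions", {
  sc <- fix_scores()
  segs <- extract_encyclopedia_segments(sc, preset_params())
  expect_gt(nrow(segs), 0)
  fr <- as.matrix(segs[, grep("^frac_", names(segs))])
  expect_true(all(abs(rowSums(fr) - 1) < 1e-6))
  expect_true(all(segs$score > preset_params()$S))
  expect_true(all(segs$length_bp >= 500))
  for (ch in unique(segs$chrom)) {
    d <- segs[segs$chrom == ch, ]
    expect_true(all(diff(d$start) > 0))
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  # promoter-dominated segments exist (planted architecture)
  expect_true("Promoter" %in% segs$dominant_term)
  # BED export round-trips coordinates
  f <- withr::local_tempfile(fileext = ".bed")
  write_encyclopedia_bed(segs, f)
  bed <- utils::read.table(f, sep = "\t")
  expect_equal(bed$V2, segs$start)
  expect_equal(bed$V3, segs$end)
})

test_that("an empty or flat track yields no segments", {
  sc <- score_track_from(rep(0.775, 100))
  expect_equal(nrow(extract_encyclopedia_segments(sc, preset_params(),
                                                  normalize = "none")), 0)
  expect_equal(nrow(brute_force_segments(numeric(0), preset_params())), 0)
})
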