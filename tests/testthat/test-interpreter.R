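# Vocabulary curation, the interpretation classifier, the LowConfidence
# rule, and leave-one-out evaluation.

test_that("vocabulary unification collapses synonyms and falls back to
           Unclassified", {
  expect_equal(unify_vocabulary("Polycomb repressed region"),
               "FacultativeHet")
  expect_equal(unify_vocabulary("Weak transcription"), "Transcribed")
  expect_equal(unify_vocabulary("Transcription"), "Transcribed")
  expect_equal(unify_vocabulary("Insulator"), "Unclassified")
  expect_equal(unify_vocabulary("Artifact"), "Unclassified")
  expect_equal(unify_vocabulary("  active tss "), "Promoter")  # normalized
  expect_warning(out <- unify_vocabulary("Totally novel thing"),
                 "unmatched")
  expect_equal(out, "Unclassified")
})

test_that("the LowConfidence rule fires exactly on low-confidence or
           Unclassified argmax predictions", {
  probs <- rbind(
    c(0.80, 0.10, 0.10),
    c(0.24, 0.38, 0.38),  # argmax tie on non-Unclassified at 0.38
    c(0.24, 0.16, 0.60),
    c(0.25, 0.55, 0.20),
    c(0.25, 0.25, 0.50))
  colnames(probs) <- c("Promoter", "Enhancer", "Unclassified")
  r <- lowconfidence_rule(probs)
  expect_equal(r$term[1], "Promoter")
  expect_equal(r$term[2], "Enhancer")        # 0.38 > 0.25, not Unclassified
  expect_equal(r$term[3], "LowConfidence")   # argmax Unclassified
  expect_equal(r$term[4], "Enhancer")
  expect_equal(r$term[5], "LowConfidence")   # argmax Unclassified at 0.50
  # max probability exactly at or below the threshold -> LowConfidence
  p2 <- matrix(c(0.24, 0.19, 0.19, 0.19, 0.19), 1,
               dimnames = list(NULL, c("Promoter", "Enhancer", "Bivalent",
                                       "Transcribed", "Quiescent")))
  expect_equal(lowconfidence_rule(p2)$term, "LowConfidence")
  p3 <- p2; p3[1] <- 0.26; p3[2] <- 0.17
  expect_equal(lowconfidence_rule(p3)$term, "Promoter")
})

# small deterministic corpora ------------------------------------------------

.sep_corpus <- function(n_per = 30, noise = 0, seed = 11,
                        classes = c("Promoter", "Enhancer", "Transcribed",
                                    "Quiescent")) {
  set.seed(seed)
  centers <- diag(length(classes)) * 4
  X <- centers[rep(seq_along(classes), each = n_per), , drop = FALSE] +
    matrix(stats::rnorm(n_per * length(classes)^2, sd = max(noise, 1e-6)),
           ncol = length(classes))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  rownames(X) <- paste0("s", seq_len(nrow(X)))
  list(X = X, y = rep(classes, each = n_per))
}

test_that("training is deterministic given the seed and exposes the class
           list", {
  cp <- .sep_corpus(noise = 0.5)
  m1 <- train_interpreter(cp$X, cp$y, ntree = 100, seed = 3)
  m2 <- train_interpreter(cp$X, cp$y, ntree = 100, seed = 3)
  probe <- .sep_corpus(noise = 2, seed = 99)$X
  expect_identical(predict_terms(m1, probe), predict_terms(m2, probe))
  expect_setequal(m1$classes, unique(cp$y))
  expect_error(train_interpreter(cp$X, rep("Promoter", nrow(cp$X))),
               "2 distinct")
  expect_error(train_interpreter(cp$X, rep("LowConfidence", nrow(cp$X))),
               "not a trainable term")
})

test_that("probabilities sum to one and prediction is invariant to row
           order", {
  cp <- .sep_corpus(noise = 1)
  m <- train_interpreter(cp$X, cp$y, ntree = 100, seed = 3)
  probe <- .sep_corpus(noise = 3, seed = 7)$X
  pr <- predict_terms(m, probe)
  psum <- rowSums(pr[, grep("^p_", names(pr))])
  expect_true(all(abs(psum - 1) < 1e-9))
  # the assignment reapplies the rule stated in the invariant
  pm <- as.matrix(pr[, paste0("p_", m$classes)])
  colnames(pm) <- m$classes
  expect_equal(pr$term, lowconfidence_rule(pm)$term)
  perm <- sample(nrow(probe))
  pr2 <- predict_terms(m, probe[perm, , drop = FALSE])
  expect_equal(pr2$term, pr$term[perm])
  expect_error(predict_terms(m, probe[, rev(seq_len(ncol(probe)))]),
               "feature order")
})

test_that("a separable corpus is classified perfectly in training and in
           leave-one-out", {
  cp <- .sep_corpus(noise = 0.2)
  m <- train_interpreter(cp$X, cp$y, ntree = 100, seed = 3)
  pr <- predict_terms(m, cp$X)
  expect_equal(pr$term, cp$y)
  loo <- loo_evaluate(cp$X, cp$y, ntree = 100, seed = 3)
  expect_equal(loo$accuracy, 1.0)
  expect_true(all(loo$confusion[cbind(unique(cp$y), unique(cp$y))] == 30))
})

test_that("pure-noise features give chance-level LOO accuracy and the
           confusion matrix conserves class counts", {
  set.seed(21)
  X <- matrix(stats::rnorm(120 * 4), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("Promoter", "Enhancer", "Transcribed", "Quiescent"),
           each = 30)
  loo <- loo_evaluate(X, y, ntree = 100, seed = 3)
  expect_lt(abs(loo$accuracy - 0.25), 0.12)  # binomial error at n = 120
  expect_equal(unname(rowSums(loo$confusion)), rep(30, 4))
})

test_that("LOO can score Unclassified as a class and map predictions
           through the LowConfidence rule", {
  cp <- .sep_corpus(noise = 0.2,
                    classes = c("Promoter", "Enhancer", "Unclassified"))
  loo <- loo_evaluate(cp$X, cp$y, ntree = 100, seed = 3, mode = "class")
  expect_equal(loo$accuracy, 1.0)  # Unclassified counted correct as itself
  loo2 <- loo_evaluate(cp$X, cp$y, ntree = 100, seed = 3,
                       mode = "lowconfidence")
  # under the rule, true Unclassified states are predicted LowConfidence
  expect_equal(unname(loo2$confusion["Unclassified", "LowConfidence"]), 30)
})
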