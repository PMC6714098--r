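# Unified interpretation vocabulary, random-forest state interpretation
# classifier, LowConfidence rule, and leave-one-out evaluation.

#' The unified interpretation vocabulary
#'
#' Eight biological terms plus two placeholders: `Unclassified` (reference
#' states that fit no term) and `LowConfidence` (newly predicted states not
#' classified with confidence). `Unclassified` applies only to reference
#' states; `LowConfidence` only to new states.
#'
#' @return character vector of the ten terms.
#' @export
interpretation_terms <- function() {
  c("Quiescent", "ConstitutiveHet", "FacultativeHet", "Transcribed",
    "Promoter", "Enhancer", "RegPermissive", "Bivalent",
    "Unclassified", "LowConfidence")
}

#' Terms a reference state may carry
#' @return character vector (the eight terms plus `Unclassified`).
#' @export
curated_terms <- function() {
  setdiff(interpretation_terms(), "LowConfidence")
}

#' Load the shipped raw-term synonym table
#' @return data frame with columns `raw_term`, `curated_term`.
#' @export
default_synonym_table <- function() {
  path <- system.file("extdata", "term_synonyms.tsv", package = "stateatlas")
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}

#' Map a raw interpretation string to the unified vocabulary
#'
#' Synonyms for the same activity (e.g. "Polycomb repressed region" and
#' "Facultative heterochromatin") collapse to one term; strings that fit no
#' term (e.g. "Insulator", "Artifact") map to `Unclassified`. Matching is
#' case-insensitive and ignores surrounding whitespace; unmatched strings
#' return `Unclassified` with a warning.
#'
#' @param raw_term character vector of raw interpretation strings.
#' @param synonyms synonym table (default: shipped table).
#' @return character vector of curated terms.
#' @export
unify_vocabulary <- function(raw_term, synonyms = default_synonym_table()) {
  key <- tolower(trimws(raw_term))
  tab <- stats::setNames(synonyms$curated_term,
                         tolower(trimws(synonyms$raw_term)))
  out <- unname(tab[key])
  # raw strings that already are curated terms pass through
  ct <- curated_terms()
  direct <- match(key, tolower(ct))
  out[is.na(out) & !is.na(direct)] <- ct[direct[is.na(out) & !is.na(direct)]]
  if (anyNA(out)) {
    warning("unmatched interpretation string(s): ",
            paste(unique(raw_term[is.na(out)]), collapse = ", "),
            " -> Unclassified")
    out[is.na(out)] <- "Unclassified"
  }
  out
}

# ---- model -----------------------------------------------------------------

#' Train the state interpretation classifier
#'
#' Random forest mapping the per-state feature vector to a curated
#' interpretation term. Trees are grown with the Gini impurity criterion
#' and regularized so that every leaf holds at least `min_leaf` training
#' examples; features are fed unstandardized (forests are scale-invariant).
#' Training is deterministic given `seed`.
#'
#' @param features numeric matrix `states x features` (e.g. from
#'   [build_feature_matrix()]).
#' @param terms character vector of curated terms, one per row (may include
#'   `Unclassified`; never `LowConfidence`).
#' @param ntree number of trees.
#' @param min_leaf minimum training examples per leaf.
#' @param seed RNG seed stored with the model.
#' @return an object of class `InterpreterModel`.
#' @export
train_interpreter <- function(features, terms, ntree = 500, min_leaf = 10,
                              seed = 1) {
  stopifnot(is.matrix(features), nrow(features) == length(terms))
  if (any(terms == "LowConfidence"))
    stop("LowConfidence is not a trainable term")
  if (!all(terms %in% curated_terms()))
    stop("unknown term(s): ",
         paste(setdiff(terms, curated_terms()), collapse = ", "))
  classes <- intersect(curated_terms(), unique(terms))
  if (length(classes) < 2) stop("need at least 2 distinct curated terms")
  y <- factor(terms, levels = classes)
  x <- as.data.frame(features)
  set.seed(seed)
  forest <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                       nodesize = min_leaf)
  structure(list(forest = forest, feature_order = colnames(features),
                 classes = classes, ntree = ntree, min_leaf = min_leaf,
                 seed = seed),
            class = "InterpreterModel")
}

#' @export
print.InterpreterModel <- function(x, ...) {
  cat("InterpreterModel:", length(x$classes), "classes,", x$ntree,
      "trees, min leaf", x$min_leaf, "\n")
  invisible(x)
}

#' Save / load an interpretation model
#'
#' Single versioned archive embedding the forest, feature order, class list
#' and hyperparameters.
#'
#' @param model an `InterpreterModel`.
#' @param path archive path.
#' @export
write_interpreter_model <- function(model, path) {
  stopifnot(inherits(model, "InterpreterModel"))
  saveRDS(list(format = "stateatlas-interpreter", version = 1L,
               model = model), path)
  invisible(path)
}

#' @rdname write_interpreter_model
#' @return `read_interpreter_model` returns the `InterpreterModel`.
#' @export
read_interpreter_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "stateatlas-interpreter"))
    stop("not a stateatlas interpreter archive")
  obj$model
}

#' The LowConfidence assignment rule
#'
#' Given per-term probabilities, a state is assigned `LowConfidence`
#' exactly when the highest-probability class is `Unclassified` or when no
#' class exceeds the confidence threshold (25%).
#'
#' @param probs numeric matrix rows = states, columns = class
#'   probabilities (column names = classes); rows sum to 1.
#' @param threshold confidence threshold.
#' @return data frame with `term` and `confidence` (the max probability).
#' @export
lowconfidence_rule <- function(probs, threshold = 0.25) {
  probs <- as.matrix(probs)
  top <- max.col(probs, ties.method = "first")
  conf <- probs[cbind(seq_len(nrow(probs)), top)]
  term <- colnames(probs)[top]
  term[term == "Unclassified" | conf <= threshold] <- "LowConfidence"
  data.frame(term = term, confidence = conf, stringsAsFactors = FALSE)
}

#' Predict interpretation terms for new states
#'
#' Applies the classifier and the LowConfidence rule: a state is assigned
#' `LowConfidence` exactly when the highest-probability class is
#' `Unclassified` or when no class reaches more than 25% probability.
#'
#' @param model an `InterpreterModel`.
#' @param features numeric matrix with the model's feature columns.
#' @param threshold confidence threshold for the LowConfidence rule.
#' @return data frame with columns `state` (rowname), `term`, `confidence`,
#'   plus one `p_<class>` probability column per class (probabilities sum
#'   to 1).
#' @export
predict_terms <- function(model, features, threshold = 0.25) {
  stopifnot(inherits(model, "InterpreterModel"), is.matrix(features))
  if (!identical(colnames(features), model$feature_order))
    stop("feature columns do not match the model's feature order")
  probs <- predict(model$forest, as.data.frame(features), type = "prob")
  probs <- probs[, model$classes, drop = FALSE]
  rule <- lowconfidence_rule(probs, threshold)
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(features)))
  out <- data.frame(state = ids, term = rule$term,
                    confidence = rule$confidence, stringsAsFactors = FALSE)
  pm <- as.data.frame(probs)
  names(pm) <- paste0("p_", colnames(probs))
  cbind(out, pm)
}

#' Leave-one-out evaluation of the interpretation classifier
#'
#' One state is held out per fit; its term is predicted from a forest
#' trained on the remaining states, and accuracy is aggregated over all
#' states. In mode `"class"` (default) the prediction is the raw
#' highest-probability class, so `Unclassified` participates as a class and
#' a reference predicted `Unclassified` counts correct iff its curated term
#' is `Unclassified`. In mode `"lowconfidence"` the LowConfidence rule is
#' applied to each held-out prediction first.
#'
#' @param features numeric matrix `states x features`.
#' @param terms curated term per row.
#' @param ntree,min_leaf,seed forest hyperparameters (see
#'   [train_interpreter()]).
#' @param mode `"class"` or `"lowconfidence"`.
#' @param threshold LowConfidence threshold (mode `"lowconfidence"`).
#' @param unit `"state"` (default, one LOO trial per state) or
#'   `"annotation"` (leave one source annotation out; rows grouped by
#'   `groups`).
#' @param groups source annotation id per row (required for
#'   `unit = "annotation"`).
#' @return list with `accuracy`, `confusion` (rows = true terms, columns =
#'   predicted terms), and `predicted` (character vector).
#' @export
loo_evaluate <- function(features, terms, ntree = 500, min_leaf = 10,
                         seed = 1, mode = c("class", "lowconfidence"),
                         threshold = 0.25, unit = c("state", "annotation"),
                         groups = NULL) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  n <- nrow(features)
  stopifnot(length(terms) == n)
  folds <- if (unit == "state") as.list(seq_len(n)) else {
    if (is.null(groups)) stop("groups required for leave-one-annotation-out")
    split(seq_len(n), groups)
  }
  predicted <- character(n)
  for (idx in folds) {
    fit <- train_interpreter(features[-idx, , drop = FALSE], terms[-idx],
                             ntree = ntree, min_leaf = min_leaf, seed = seed)
    pr <- predict_terms(fit, features[idx, , drop = FALSE],
                        threshold = threshold)
    predicted[idx] <- if (mode == "class") {
      pm <- as.matrix(pr[, paste0("p_", fit$classes), drop = FALSE])
      fit$classes[max.col(pm, ties.method = "first")]
    } else pr$term
  }
  lev_true <- intersect(curated_terms(), unique(terms))
  lev_pred <- union(lev_true, unique(predicted))
  lev_pred <- intersect(interpretation_terms(), lev_pred)
  confusion <- table(true = factor(terms, levels = lev_true),
                     predicted = factor(predicted, levels = lev_pred))
  list(accuracy = mean(predicted == terms), confusion = confusion,
       predicted = predicted)
}

#' Term-feature association table for reporting
#'
#' Mean feature value per term, in standard-deviation units of each feature
#' across states (standardization is for display only; the classifier sees
#' unstandardized features).
#'
#' @param features numeric matrix `states x features`.
#' @param terms term per row.
#' @return matrix `terms x features` of standardized means.
#' @export
term_feature_table <- function(features, terms) {
  z <- scale(features)
  t(vapply(split(seq_along(terms), terms), function(i)
    colMeans(z[i, , drop = FALSE]), numeric(ncol(features))))
}
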