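# Cross-validation harness: stratified k-fold evaluation of the classifier
# registry, best-model selection, full-data training, and thresholded scoring
# of merge candidates.

instances_to_xy <- function(instances) {
  X <- as.matrix(instances[FEATURE_NAMES])
  storage.mode(X) <- "double"
  y <- as.integer(instances$label == "positive")
  list(X = X, y = y)
}

#' Assign stratified cross-validation folds
#'
#' Instances of each label are shuffled (seeded) and dealt round-robin into k
#' folds, so every fold holds out roughly the same class balance. The fold
#' vector is a partition: each instance appears in exactly one fold.
#'
#' @param labels character vector of labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  folds <- integer(length(labels))
  set.seed(as.integer(seed))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (length(idx) < k) {
      stop("label ", sQuote(lab), " has ", length(idx),
           " instance(s); need at least k = ", k)
    }
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Evaluate classifier specs by stratified k-fold cross-validation
#'
#' The same seeded fold assignment is used for every spec, so mean accuracies
#' are directly comparable. Fold accuracy is the fraction of held-out
#' instances whose thresholded score (> 0.5) matches the label.
#'
#' @param instances instance data frame with `label` and the four feature
#'   columns.
#' @param specs list of [classifier_spec()] (default [default_registry()]).
#' @param k number of folds (default 5).
#' @param seed fold/classifier seed.
#' @return data frame with one row per spec: `classifier`, `mean_accuracy`,
#'   `balanced_accuracy`, `acc_fold1..k`, `seed`. Row order = registry order.
#' @export
cross_validate <- function(instances, specs = default_registry(), k = 5L,
                           seed = 1L) {
  xy <- instances_to_xy(instances)
  folds <- stratified_folds(instances$label, k, seed)
  rows <- lapply(specs, function(spec) {
    fold_acc <- numeric(k)
    correct_pos <- 0L; n_pos <- 0L
    correct_neg <- 0L; n_neg <- 0L
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- spec$fit(xy$X[tr, , drop = FALSE], xy$y[tr], seed)
      sc <- spec$predict(fit, xy$X[!tr, , drop = FALSE])
      pred <- as.integer(sc > 0.5)
      truth <- xy$y[!tr]
      fold_acc[f] <- mean(pred == truth)
      correct_pos <- correct_pos + sum(pred == 1L & truth == 1L)
      n_pos <- n_pos + sum(truth == 1L)
      correct_neg <- correct_neg + sum(pred == 0L & truth == 0L)
      n_neg <- n_neg + sum(truth == 0L)
    }
    out <- data.frame(classifier = spec$name,
                      mean_accuracy = mean(fold_acc),
                      balanced_accuracy = (correct_pos / n_pos +
                                             correct_neg / n_neg) / 2,
                      stringsAsFactors = FALSE)
    for (f in seq_len(k)) out[[paste0("acc_fold", f)]] <- fold_acc[f]
    out$seed <- as.integer(seed)
    out
  })
  reports <- do.call(rbind, rows)
  rownames(reports) <- NULL
  attr(reports, "folds") <- folds
  reports
}

#' Select the best classifier from CV reports
#'
#' Highest mean accuracy wins; ties are broken by balanced accuracy (honoring
#' "best on both the positive and negative data"), then by registry order.
#'
#' @param reports output of [cross_validate()].
#' @param registry the spec list the reports were computed from.
#' @return the winning [classifier_spec()].
#' @export
select_best <- function(reports, registry = default_registry()) {
  if (!nrow(reports)) stop("no CV reports to select from")
  ord <- order(-reports$mean_accuracy, -reports$balanced_accuracy,
               seq_len(nrow(reports)))
  registry[[reports$classifier[ord[1]]]]
}

#' Train a spec on all instances
#'
#' @param spec a [classifier_spec()].
#' @param instances instance data frame (both labels must be present).
#' @param seed training seed (recorded; refits are bit-identical).
#' @return an `operon_model`.
#' @export
train_full <- function(spec, instances, seed = 1L) {
  xy <- instances_to_xy(instances)
  if (length(unique(xy$y)) < 2) {
    stop("training requires both positive and negative instances")
  }
  set.seed(as.integer(seed))
  fit <- spec$fit(xy$X, xy$y, seed)
  structure(list(classifier = spec$name, hyper = spec$hyper, fit = fit,
                 feature_names = FEATURE_NAMES, seed = as.integer(seed),
                 format_version = "1"),
            class = "operon_model")
}

#' @export
print.operon_model <- function(x, ...) {
  cat(sprintf("operon_model: %s (seed %d, format v%s)\n",
              x$classifier, x$seed, x$format_version))
  invisible(x)
}

#' Score instances with a trained model
#' @param model an `operon_model`.
#' @param features data frame or matrix with the four feature columns.
#' @return numeric scores in `[0, 1]`.
#' @export
model_scores <- function(model, features) {
  if (is.null(model$fit)) stop("model is not fitted")
  spec <- default_registry()[[model$classifier]]
  if (is.null(spec)) stop("unknown classifier in model: ", model$classifier)
  X <- as.matrix(as.data.frame(features)[model$feature_names])
  storage.mode(X) <- "double"
  spec$predict(model$fit, X)
}

#' Score merge candidates and apply the acceptance threshold
#'
#' Each candidate gains a `score` in `[0, 1]` and `merged = score > threshold`
#' (strict inequality: a score of exactly 0.5 is not merged). The score is a
#' classifier output, not a calibrated probability.
#'
#' @param model a trained `operon_model`.
#' @param candidates featurized candidate data frame
#'   ([featurize_candidates()]).
#' @param threshold acceptance threshold (default 0.5).
#' @return candidates with `score` and `merged` columns.
#' @export
score_and_decide <- function(model, candidates, threshold = 0.5) {
  if (!nrow(candidates)) {
    candidates$score <- numeric(0)
    candidates$merged <- logical(0)
    return(candidates)
  }
  candidates$score <- model_scores(model, candidates)
  candidates$merged <- candidates$score > threshold
  candidates
}

#' Write a CV report TSV
#' @param reports output of [cross_validate()].
#' @param path output path.
#' @param header optional comment lines.
#' @export
write_cv_report <- function(reports, path, header = NULL) {
  write_tsv_with_header(reports, path, header)
}

## ---- model persistence ----------------------------------------------------

# Recursively prepare fit internals for JSON. Matrices and (possibly named)
# vectors get explicit wrappers so the round-trip restores R types exactly.
serialize_payload <- function(x) {
  if (is.matrix(x)) {
    list(.matrix = TRUE, nrow = nrow(x), ncol = ncol(x),
         rownames = rownames(x), colnames = colnames(x), data = as.vector(x))
  } else if (inherits(x, "lmt_fit")) {
    list(.lmt = TRUE, payload = serialize_payload(unclass(x)))
  } else if (is.atomic(x) && !is.null(x) && (length(x) != 1L || !is.null(names(x)))) {
    list(.vector = TRUE, names = names(x), data = unname(as.vector(x)))
  } else if (is.list(x)) {
    lapply(x, serialize_payload)
  } else x
}

deserialize_payload <- function(x) {
  if (!is.list(x)) return(x)
  if (isTRUE(x$.matrix)) {
    m <- matrix(as.numeric(unlist(x$data)), nrow = x$nrow, ncol = x$ncol)
    if (!is.null(x$rownames)) rownames(m) <- unlist(x$rownames)
    if (!is.null(x$colnames)) colnames(m) <- unlist(x$colnames)
    return(m)
  }
  if (isTRUE(x$.vector)) {
    v <- unlist(x$data)
    if (!is.null(x$names)) names(v) <- unlist(x$names)
    return(v)
  }
  if (isTRUE(x$.lmt)) {
    return(structure(deserialize_payload(x$payload), class = "lmt_fit"))
  }
  lapply(x, deserialize_payload)
}

#' Persist / restore a trained model as a self-describing JSON file
#'
#' @param model an `operon_model`.
#' @param path file path (plain-text JSON).
#' @export
write_model <- function(model, path) {
  obj <- list(format = "dieloperon-model", format_version = model$format_version,
              tool_version = dielop_version(), classifier = model$classifier,
              hyper = model$hyper, seed = model$seed,
              feature_names = model$feature_names,
              fit = serialize_payload(model$fit))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "dieloperon-model")) {
    stop("not a dieloperon model file: ", path)
  }
  fit <- deserialize_payload(obj$fit)
  structure(list(classifier = obj$classifier,
                 hyper = lapply(obj$hyper, function(v) v),
                 fit = fit,
                 feature_names = unlist(obj$feature_names),
                 seed = as.integer(obj$seed),
                 format_version = as.character(obj$format_version)),
            class = "operon_model")
}
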