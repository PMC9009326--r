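FEATURE_NAMES <- c("d_min", "d_mean", "d_sd", "d_max")

#' Summarize pairwise distances into the 4-statistic feature vector
#'
#' Classifier instances are represented by the minimum, mean, sample standard
#' deviation (n-1 denominator; 0 for a single distance) and maximum of a set
#' of pairwise ABLIM distances. Permutation-invariant in its input.
#'
#' @param distances numeric vector of >= 1 finite non-negative distances.
#' @return named numeric vector `(d_min, d_mean, d_sd, d_max)`.
#' @examples
#' featurize(c(1, 2, 3, 4))  # sd = sqrt(5/3)
#' @export
featurize <- function(distances) {
  if (!length(distances)) stop("featurize requires at least one distance")
  if (!all(is.finite(distances))) stop("featurize requires finite distances")
  s <- if (length(distances) == 1L) 0 else stats::sd(distances)
  stats::setNames(c(min(distances), mean(distances), s, max(distances)),
                  FEATURE_NAMES)
}

instance_row <- function(instance_id, label, gene_ids, features) {
  data.frame(instance_id = instance_id, label = label,
             gene_ids = paste(gene_ids, collapse = ","),
             n_genes = length(gene_ids),
             d_min = features[["d_min"]], d_mean = features[["d_mean"]],
             d_sd = features[["d_sd"]], d_max = features[["d_max"]],
             stringsAsFactors = FALSE)
}

empty_instance_df <- function() {
  data.frame(instance_id = character(0), label = character(0),
             gene_ids = character(0), n_genes = integer(0),
             d_min = numeric(0), d_mean = numeric(0), d_sd = numeric(0),
             d_max = numeric(0), stringsAsFactors = FALSE)
}

# Distances among the given genes' (usable) profiles, as a flat vector over
# all unordered pairs.
within_group_distances <- function(gene_ids, expr) {
  dm <- pairwise_distances(expr, gene_ids = gene_ids)
  dm[upper.tri(dm)]
}

#' Build positive training instances from prior operon predictions
#'
#' One positive instance per prior with >= 2 genes having usable expression
#' profiles and >= 1 diel gene; features are computed over ALL within-instance
#' gene pairs. Skipped priors are recorded (with the reason) in the
#' `"skipped"` attribute.
#'
#' @param priors a validated [operon_set()].
#' @param expr a mean-centered [expression_matrix()].
#' @param diel output of [diel_calls()].
#' @return instance data frame (one row per instance) with feature columns
#'   `d_min, d_mean, d_sd, d_max`; attribute `skipped`.
#' @export
build_positive_instances <- function(priors, expr, diel) {
  rows <- list()
  skipped <- list()
  diel_map <- stats::setNames(diel$is_diel, diel$gene_id)
  usable_map <- stats::setNames(diel$usable, diel$gene_id)
  for (i in seq_along(priors)) {
    id <- names(priors)[i]
    genes <- priors[[i]]
    usable <- genes[genes %in% names(usable_map) & usable_map[genes] %in% TRUE]
    if (length(usable) < 2) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(operon_id = id, reason = if (length(genes) < 2)
          "single_gene" else "missing_profile", stringsAsFactors = FALSE)
      next
    }
    if (!any(diel_map[usable] %in% TRUE)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(operon_id = id, reason = "no_diel_gene", stringsAsFactors = FALSE)
      next
    }
    feats <- featurize(within_group_distances(usable, expr))
    rows[[length(rows) + 1L]] <- instance_row(id, "positive", usable, feats)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_instance_df()
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(operon_id = character(0), reason = character(0))
  out
}

#' Build negative training instances from mixed-strand gene windows
#'
#' Negatives are windows of consecutive-rank genes within one contig that
#' contain at least one gene on each DNA strand (so they cannot be an operon)
#' and at least one diel gene. Window sizes are drawn per `size_policy`;
#' windows are non-overlapping by default (greedy left-to-right scan).
#' Features use all within-window gene pairs, mirroring the positives.
#'
#' @param catalog a [gene_catalog()].
#' @param expr a mean-centered [expression_matrix()].
#' @param diel output of [diel_calls()].
#' @param size_policy `"match_positive"` (draw sizes from the empirical size
#'   distribution of the positive set; requires `positive_sizes`) or
#'   `"fixed"` (always `k` genes).
#' @param k window size for the fixed policy.
#' @param positive_sizes integer vector of positive-instance sizes (for
#'   `"match_positive"`).
#' @param seed RNG seed; required whenever the policy draws sizes.
#' @param allow_overlap if TRUE the scan advances one gene at a time even
#'   after accepting a window.
#' @param max_instances stop after this many instances (default: no cap).
#' @return instance data frame as in [build_positive_instances()].
#' @export
build_negative_instances <- function(catalog, expr, diel,
                                     size_policy = c("match_positive", "fixed"),
                                     k = 2L, positive_sizes = NULL, seed = NULL,
                                     allow_overlap = FALSE, max_instances = Inf) {
  size_policy <- match.arg(size_policy)
  stochastic <- size_policy == "match_positive" &&
    length(unique(positive_sizes)) > 1L
  if (size_policy == "match_positive" && !length(positive_sizes)) {
    stop("size_policy 'match_positive' requires positive_sizes")
  }
  if (stochastic && is.null(seed)) stop("seed required for a stochastic size policy")
  if (!is.null(seed)) set.seed(as.integer(seed))

  diel_map <- stats::setNames(diel$is_diel, diel$gene_id)
  usable_map <- stats::setNames(diel$usable, diel$gene_id)
  draw_size <- function() {
    if (size_policy == "fixed") as.integer(k)
    else as.integer(positive_sizes[sample.int(length(positive_sizes), 1L)])
  }

  rows <- list()
  counter <- 0L
  for (ctg in unique(catalog$contig)) {
    sub <- catalog[catalog$contig == ctg, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    n <- nrow(sub)
    pos <- 1L
    while (pos <= n - 1L && length(rows) < max_instances) {
      s <- draw_size()
      accepted <- FALSE
      if (s >= 2L && pos + s - 1L <= n) {
        genes <- sub$gene_id[pos:(pos + s - 1L)]
        strands <- sub$strand[pos:(pos + s - 1L)]
        ok <- length(unique(strands)) == 2L &&
          all(genes %in% names(usable_map) & usable_map[genes] %in% TRUE) &&
          any(diel_map[genes] %in% TRUE)
        if (ok) {
          counter <- counter + 1L
          feats <- featurize(within_group_distances(genes, expr))
          rows[[length(rows) + 1L]] <-
            instance_row(sprintf("N%04d", counter), "negative", genes, feats)
          accepted <- TRUE
        }
      }
      pos <- pos + if (accepted && !allow_overlap) s else 1L
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_instance_df()
  rownames(out) <- NULL
  out
}

#' Discover merge candidates among prior predictions
#'
#' An ordered pair of distinct priors (p1 before p2 by rank) is a merge
#' candidate when there are no intervening genes (last rank of p1 + 1 = first
#' rank of p2), all genes share one contig and one DNA strand, and each prior
#' contains at least one diel gene. Cross pairs are every (gene in p1, gene
#' in p2) combination; within-prior gene pairs are deliberately excluded from
#' candidate features. Deterministic: candidates are ordered by contig then
#' rank; excluded adjacent pairs are recorded in the `"excluded"` attribute
#' with the failed condition.
#'
#' @param priors a validated [operon_set()].
#' @param catalog a [gene_catalog()].
#' @param diel output of [diel_calls()].
#' @return data frame with one row per candidate: `prior1_id`, `prior2_id`,
#'   `contig`, `strand`, `genes1`, `genes2` (comma-joined), `n_cross_pairs`.
#' @export
find_merge_candidates <- function(priors, catalog, diel) {
  diel_map <- stats::setNames(diel$is_diel, diel$gene_id)
  info <- data.frame(
    prior_id = names(priors),
    contig = vapply(priors, function(g) contig_of(catalog, g[1]), character(1)),
    strand = vapply(priors, function(g) strand_of(catalog, g[1]), character(1)),
    first_rank = vapply(priors, function(g) min(rank_of(catalog, g)), numeric(1)),
    last_rank = vapply(priors, function(g) max(rank_of(catalog, g)), numeric(1)),
    has_diel = vapply(priors, function(g) any(diel_map[g] %in% TRUE), logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  info <- info[order(info$contig, info$first_rank), , drop = FALSE]

  cand <- list()
  excl <- list()
  if (nrow(info) >= 2) {
    for (i in seq_len(nrow(info) - 1L)) {
      p1 <- info[i, ]
      p2 <- info[i + 1L, ]
      if (p1$contig != p2$contig) next  # not adjacent at all
      reason <- NULL
      if (p2$first_rank != p1$last_rank + 1L) reason <- "intervening_genes"
      else if (p1$strand != p2$strand) reason <- "strand_mismatch"
      else if (!p1$has_diel || !p2$has_diel) reason <- "no_diel_gene"
      if (is.null(reason)) {
        g1 <- priors[[p1$prior_id]]
        g2 <- priors[[p2$prior_id]]
        cand[[length(cand) + 1L]] <- data.frame(
          prior1_id = p1$prior_id, prior2_id = p2$prior_id,
          contig = p1$contig, strand = p1$strand,
          genes1 = paste(g1, collapse = ","),
          genes2 = paste(g2, collapse = ","),
          n_cross_pairs = length(g1) * length(g2),
          stringsAsFactors = FALSE)
      } else {
        excl[[length(excl) + 1L]] <- data.frame(
          prior1_id = p1$prior_id, prior2_id = p2$prior_id, reason = reason,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(cand)) do.call(rbind, cand) else data.frame(
    prior1_id = character(0), prior2_id = character(0), contig = character(0),
    strand = character(0), genes1 = character(0), genes2 = character(0),
    n_cross_pairs = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(prior1_id = character(0), prior2_id = character(0),
               reason = character(0))
  out
}

#' Featurize merge candidates from cross-prior gene pairs only
#'
#' Within-prior distances do not contribute. Candidates touching a gene with
#' an unusable profile are dropped with a warning and recorded in the
#' `"dropped"` attribute.
#'
#' @param candidates output of [find_merge_candidates()].
#' @param expr a mean-centered [expression_matrix()].
#' @return the candidate data frame with feature columns added.
#' @export
featurize_candidates <- function(candidates, expr) {
  usable <- rownames(expr$values)[!apply(expr$values, 1L, anyNA)]
  keep <- logical(nrow(candidates))
  feats <- matrix(NA_real_, nrow(candidates), 4L,
                  dimnames = list(NULL, FEATURE_NAMES))
  for (i in seq_len(nrow(candidates))) {
    g1 <- strsplit(candidates$genes1[i], ",", fixed = TRUE)[[1]]
    g2 <- strsplit(candidates$genes2[i], ",", fixed = TRUE)[[1]]
    if (!all(c(g1, g2) %in% usable)) next
    cross <- as.vector(outer(g1, g2, Vectorize(function(a, b) {
      ablim_distance(expr$values[a, ], expr$values[b, ], expr$timepoints_h)
    })))
    feats[i, ] <- featurize(cross)
    keep[i] <- TRUE
  }
  if (any(!keep)) {
    warning(sum(!keep), " candidate(s) dropped: gene(s) without usable profiles")
  }
  dropped <- candidates[!keep, c("prior1_id", "prior2_id"), drop = FALSE]
  out <- cbind(candidates[keep, , drop = FALSE],
               as.data.frame(feats[keep, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Write / read the feature TSV interchange format
#'
#' Columns `instance_id, label, d_min, d_mean, d_sd, d_max` — the contract
#' between instance construction and the classifier harness.
#'
#' @param instances instance data frame.
#' @param path file path.
#' @param header optional comment lines.
#' @export
write_feature_table <- function(instances, path, header = NULL) {
  write_tsv_with_header(
    instances[c("instance_id", "label", FEATURE_NAMES)], path, header)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read_tsv_plain(path)
  stopifnot(all(c("instance_id", "label", FEATURE_NAMES) %in% names(df)))
  df
}
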