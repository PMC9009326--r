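#' Expression matrix over diel timepoints
#'
#' Container for log2-expression profiles: a genes x timepoints numeric matrix
#' with gene ids as row names, plus the strictly increasing timepoints in
#' hours. Profiles may contain `NA`s; such profiles are flagged unusable by
#' [diel_calls()] and excluded from all distance computations.
#'
#' @param values numeric matrix, rows = genes (rownames required), columns =
#'   timepoints.
#' @param timepoints_h strictly increasing numeric vector of hours, one per
#'   column.
#' @param centered logical; whether profiles have been mean-centered.
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, timepoints_h, centered = FALSE) {
  values <- as.matrix(values)
  timepoints_h <- as.numeric(timepoints_h)
  if (is.null(rownames(values))) stop("expression values must have gene ids as rownames")
  if (ncol(values) != length(timepoints_h)) {
    stop("number of columns (", ncol(values), ") != number of timepoints (",
         length(timepoints_h), ")")
  }
  if (length(timepoints_h) > 1 && any(diff(timepoints_h) <= 0)) {
    stop("timepoints must be strictly increasing")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicate gene row(s): ", paste(unique(dup), collapse = ", "))
  structure(list(values = values, timepoints_h = timepoints_h, centered = centered),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d timepoints (%.4g..%.4g h)%s\n",
              nrow(x$values), length(x$timepoints_h),
              min(x$timepoints_h), max(x$timepoints_h),
              if (isTRUE(x$centered)) ", mean-centered" else ""))
  invisible(x)
}

#' Mean-center expression profiles
#'
#' Normalizes each profile to a mean of zero, the standard preprocessing step
#' before computing curve distances. `NA`s are ignored when computing the mean
#' (profiles containing them are excluded downstream anyway).
#'
#' @param x an [expression_matrix()] or a numeric vector.
#' @return object of the same type with zero-mean profiles.
#' @export
mean_center <- function(x) UseMethod("mean_center")

#' @export
mean_center.numeric <- function(x) {
  if (!length(x)) stop("cannot center an empty profile")
  x - mean(x, na.rm = TRUE)
}

#' @export
mean_center.expression_matrix <- function(x) {
  if (!nrow(x$values)) stop("cannot center an empty expression matrix")
  x$values <- x$values - rowMeans(x$values, na.rm = TRUE)
  x$centered <- TRUE
  x
}

#' Call diel (daily-cycling) genes by log2 range
#'
#' A gene is diel when its transcript abundance changes at least `min_fold`
#' times over the sampled day: on the log2 scale, `max - min >= log2(min_fold)`.
#' The call is invariant to mean-centering. Profiles with any missing value
#' are marked unusable and never diel.
#'
#' @param expr an [expression_matrix()] (log2 scale).
#' @param min_fold minimum fold change; must be > 1. Default 2 (the standard
#'   diel definition).
#' @return data frame with columns `gene_id`, `range_log2`, `is_diel`,
#'   `usable`.
#' @export
diel_calls <- function(expr, min_fold = 2) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!is.numeric(min_fold) || length(min_fold) != 1 || min_fold <= 1) {
    stop("min_fold must be a single number > 1")
  }
  span <- diff(range(expr$timepoints_h))
  if (length(expr$timepoints_h) >= 2 && (span < 20 || span > 28)) {
    warning(sprintf("timepoint span is %.3g h; diel range detection assumes roughly one 24-h cycle", span))
  }
  v <- expr$values
  usable <- !apply(v, 1L, anyNA) & ncol(v) >= 2
  rng <- rep(NA_real_, nrow(v))
  if (any(usable)) {
    rng[usable] <- apply(v[usable, , drop = FALSE], 1L, function(r) max(r) - min(r))
  }
  threshold <- log2(min_fold)
  data.frame(gene_id = rownames(v),
             range_log2 = rng,
             is_diel = !is.na(rng) & rng >= threshold,
             usable = usable,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ABLIM distance between two expression profiles
#'
#' Area Between Linear Interpolations of Measurements: the integral of the
#' absolute difference between the two piecewise-linear interpolants of the
#' profiles over the sampled span. Each inter-timepoint segment is integrated
#' exactly: with endpoint differences d0, d1 and width dt, a segment where the
#' difference does not change sign contributes `dt * (|d0| + |d1|) / 2`
#' (trapezoid), and a sign-crossing segment contributes
#' `dt * (d0^2 + d1^2) / (2 * (|d0| + |d1|))` (two triangles around the zero
#' crossing). With `normalize_by_span` the total is divided by the time span,
#' giving a mean absolute vertical separation that is comparable across
#' studies with different sampling spans.
#'
#' @param a,b numeric profiles of equal length (same timepoints).
#' @param timepoints_h shared, strictly increasing timepoints in hours;
#'   length >= 2.
#' @param normalize_by_span divide the area by `max(t) - min(t)` (default
#'   TRUE).
#' @return a non-negative number; 0 iff the interpolants coincide.
#' @examples
#' ablim_distance(c(0.5, 0.5), c(-0.5, -0.5), c(0, 24))            # 1
#' ablim_distance(c(0, 1), c(1, 0), c(0, 1), normalize_by_span = FALSE) # 0.5
#' @export
ablim_distance <- function(a, b, timepoints_h, normalize_by_span = TRUE) {
  n <- length(timepoints_h)
  if (n < 2) stop("ABLIM needs at least 2 timepoints")
  if (length(a) != n || length(b) != n) {
    stop("profiles and timepoints have mismatched lengths (",
         length(a), ", ", length(b), ", ", n, ")")
  }
  if (any(diff(timepoints_h) <= 0)) stop("timepoints must be strictly increasing")
  if (anyNA(a) || anyNA(b)) stop("ABLIM is undefined for profiles with missing values")
  d <- a - b
  total <- ablim_area_from_diff(d, timepoints_h)
  if (normalize_by_span) total / (timepoints_h[n] - timepoints_h[1]) else total
}

# Exact area under |piecewise-linear d(t)|, given d at the knots.
ablim_area_from_diff <- function(d, tp) {
  n <- length(tp)
  d0 <- d[-n]
  d1 <- d[-1]
  dt <- diff(tp)
  same <- d0 * d1 >= 0
  denom <- abs(d0) + abs(d1)
  area <- numeric(n - 1L)
  area[same] <- dt[same] * denom[same] / 2
  opp <- !same
  area[opp] <- dt[opp] * (d0[opp]^2 + d1[opp]^2) / (2 * denom[opp])
  sum(area)
}

#' Pairwise ABLIM distance matrix
#'
#' @param x an [expression_matrix()] or a numeric matrix (rows = genes).
#' @param gene_ids optional subset of genes (default: all rows).
#' @param timepoints_h timepoints when `x` is a plain matrix.
#' @param normalize_by_span passed to [ablim_distance()].
#' @return symmetric numeric matrix with zero diagonal, dimnames = gene ids.
#' @export
pairwise_distances <- function(x, gene_ids = NULL, timepoints_h = NULL,
                               normalize_by_span = TRUE) {
  if (inherits(x, "expression_matrix")) {
    timepoints_h <- x$timepoints_h
    v <- x$values
  } else {
    v <- as.matrix(x)
    if (is.null(timepoints_h)) stop("timepoints_h required for a plain matrix")
  }
  if (!is.null(gene_ids)) {
    missing_g <- setdiff(gene_ids, rownames(v))
    if (length(missing_g)) {
      stop("gene id(s) absent from expression matrix: ",
           paste(missing_g, collapse = ", "))
    }
    v <- v[gene_ids, , drop = FALSE]
  }
  m <- nrow(v)
  if (m < 2) stop("pairwise distances need at least 2 profiles")
  ids <- rownames(v)
  out <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      dij <- tryCatch(
        ablim_distance(v[i, ], v[j, ], timepoints_h, normalize_by_span),
        error = function(e) stop("ABLIM failed for pair (", ids[i], ", ", ids[j],
                                 "): ", conditionMessage(e)))
      out[i, j] <- dij
      out[j, i] <- dij
    }
  }
  out
}
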