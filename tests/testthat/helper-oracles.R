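# Independent oracles. Each one deliberately avoids the code path it checks.

# Fine midpoint-rule quadrature of the area between the two linear
# interpolants (the ABLIM oracle).
riemann_ablim <- function(a, b, timepoints_h, steps = 1e5,
                          normalize_by_span = TRUE) {
  span <- max(timepoints_h) - min(timepoints_h)
  h <- span / steps
  mids <- min(timepoints_h) + (seq_len(steps) - 0.5) * h
  d <- stats::approx(timepoints_h, a - b, xout = mids)$y
  total <- sum(abs(d)) * h
  if (normalize_by_span) total / span else total
}

# Brute-force merge-candidate scan: every ordered pair of priors, re-deriving
# each rule from the catalog directly.
bf_candidates <- function(priors, catalog, diel) {
  diel_map <- stats::setNames(diel$is_diel, diel$gene_id)
  res <- list()
  for (i in seq_along(priors)) {
    for (j in seq_along(priors)) {
      if (i == j) next
      g1 <- priors[[i]]
      g2 <- priors[[j]]
      idx <- match(c(g1, g2), catalog$gene_id)
      if (length(unique(catalog$contig[idx])) != 1) next
      if (length(unique(catalog$strand[idx])) != 1) next
      r1 <- sort(catalog$rank[match(g1, catalog$gene_id)])
      r2 <- sort(catalog$rank[match(g2, catalog$gene_id)])
      if (max(r1) + 1 != min(r2)) next           # p1 immediately before p2
      if (!all(diff(sort(c(r1, r2))) == 1)) next # no gaps anywhere
      if (!any(diel_map[g1] %in% TRUE) || !any(diel_map[g2] %in% TRUE)) next
      res[[length(res) + 1L]] <- c(names(priors)[i], names(priors)[j])
    }
  }
  if (!length(res)) return(data.frame(prior1_id = character(0),
                                      prior2_id = character(0)))
  df <- as.data.frame(do.call(rbind, res), stringsAsFactors = FALSE)
  names(df) <- c("prior1_id", "prior2_id")
  df[order(df$prior1_id), , drop = FALSE]
}

# Independent greedy left-to-right scan for fixed-size negative windows.
bf_negative_windows_fixed <- function(catalog, diel, k) {
  diel_map <- stats::setNames(diel$is_diel, diel$gene_id)
  usable_map <- stats::setNames(diel$usable, diel$gene_id)
  found <- list()
  for (ctg in unique(catalog$contig)) {
    sub <- catalog[catalog$contig == ctg, ]
    sub <- sub[order(sub$rank), ]
    pos <- 1
    while (pos + k - 1 <= nrow(sub)) {
      genes <- sub$gene_id[pos:(pos + k - 1)]
      ok <- length(unique(sub$strand[pos:(pos + k - 1)])) == 2 &&
        all(usable_map[genes]) && any(diel_map[genes])
      if (ok) {
        found[[length(found) + 1L]] <- genes
        pos <- pos + k
      } else pos <- pos + 1
    }
  }
  found
}

# Connected components of a gene-pair graph by label propagation (no igraph).
bf_chain_components <- function(pairs) {
  genes <- unique(c(pairs[, 1], pairs[, 2]))
  comp <- stats::setNames(seq_along(genes), genes)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(names(comp), comp), sort))
}

# Binomial 99% bounds around 0.5 for n Bernoulli trials.
null_accuracy_bounds <- function(n) {
  half_width <- stats::qnorm(0.995) * sqrt(0.25 / n)
  c(0.5 - half_width, 0.5 + half_width)
}
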