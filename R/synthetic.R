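# Synthetic diel genome + transcriptome generator with planted ground truth.
# Emulates the structure of the real inputs (a draft cyanobacterial genome
# with operons, a multi-timepoint log2 diel expression study, and prior operon
# predictions that sometimes split true operons) so every pipeline stage is
# testable without downloads.

#' Simulation configuration
#'
#' Defaults describe the emulated study: ~4,407 genes, 8 timepoints every 3 h,
#' sinusoidal diel genes with a 2x (1 log2 unit amplitude) swing, 79% of
#' transcription units diel, modest measurement noise and within-operon phase
#' jitter.
#'
#' @param n_genes total genes across contigs.
#' @param n_contigs number of contigs (genes split as evenly as possible).
#' @param operon_size_distribution named numeric vector: multi-gene operon
#'   size -> probability (must sum to 1).
#' @param p_operon_gene probability that a new transcription unit is a
#'   multi-gene operon rather than a singleton.
#' @param diel_fraction probability that a transcription unit is diel.
#' @param timepoints_h sampling times in hours.
#' @param amplitude_log2 sinusoid amplitude (log2 units); 1.0 gives a 2x
#'   peak-to-trough swing at dense sampling.
#' @param phase_jitter_h SD of per-gene phase jitter within an operon (hours).
#' @param noise_sd_log2 SD of additive Gaussian measurement noise.
#' @param p_split_prior probability that a true operon of size >= 2 is cut
#'   into two prior predictions.
#' @param strand_switch_rate probability that consecutive transcription units
#'   lie on opposite strands.
#' @param min_phase_sep_h minimum circular phase separation (hours) enforced
#'   between consecutive diel units (0 = unconstrained).
#' @param seed RNG seed; all outputs are byte-identical given the same seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 4407L, n_contigs = 1L,
                       operon_size_distribution = c(`2` = 0.5, `3` = 0.3, `4` = 0.2),
                       p_operon_gene = 0.5, diel_fraction = 0.79,
                       timepoints_h = seq(0, 21, by = 3),
                       amplitude_log2 = 1.0, phase_jitter_h = 0.5,
                       noise_sd_log2 = 0.1, p_split_prior = 0.15,
                       strand_switch_rate = 0.5, min_phase_sep_h = 0,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_contigs = as.integer(n_contigs),
              operon_size_distribution = operon_size_distribution,
              p_operon_gene = p_operon_gene, diel_fraction = diel_fraction,
              timepoints_h = as.numeric(timepoints_h),
              amplitude_log2 = amplitude_log2, phase_jitter_h = phase_jitter_h,
              noise_sd_log2 = noise_sd_log2, p_split_prior = p_split_prior,
              strand_switch_rate = strand_switch_rate,
              min_phase_sep_h = min_phase_sep_h, seed = as.integer(seed))
  probs <- c(p_operon_gene, diel_fraction, p_split_prior, strand_switch_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(operon_size_distribution) - 1) > 1e-9) {
    stop("operon_size_distribution must sum to 1")
  }
  sizes <- as.integer(names(operon_size_distribution))
  if (anyNA(sizes) || any(sizes < 2)) {
    stop("operon_size_distribution names must be integer sizes >= 2")
  }
  if (length(cfg$timepoints_h) < 2 || any(diff(cfg$timepoints_h) <= 0)) {
    stop("timepoints_h must be strictly increasing, length >= 2")
  }
  structure(cfg, class = c("sim_config", "list"))
}

#' Generate a synthetic genome with planted transcription units
#'
#' Genes are laid out consecutively per contig. Each transcription unit is a
#' multi-gene operon (size drawn from the configured distribution) with
#' probability `p_operon_gene`, otherwise a singleton; consecutive units
#' switch strand with probability `strand_switch_rate`. Deterministic given
#' the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `catalog` (a [gene_catalog()]) and `true_operons` (an
#'   [operon_set()] of all transcription units, ids `op0001`...; attribute
#'   `unit_table` maps unit -> contig/strand/size).
#' @export
generate_genome <- function(config) {
  sizes <- as.integer(names(config$operon_size_distribution))
  probs <- as.numeric(config$operon_size_distribution)
  per_contig <- diff(round(seq(0, config$n_genes, length.out = config$n_contigs + 1L)))
  if (any(per_contig < 1)) stop("infeasible config: more contigs than genes")
  if (min(sizes) > max(per_contig)) {
    stop("infeasible config: smallest operon size exceeds genes per contig")
  }
  set.seed(derive_seed(config$seed, 101L))
  gene_len <- 800L
  gene_gap <- 200L
  gene_counter <- 0L
  unit_counter <- 0L
  records <- list()
  units <- list()
  unit_rows <- list()
  for (ci in seq_len(config$n_contigs)) {
    contig <- sprintf("contig%02d", ci)
    remaining <- per_contig[ci]
    pos <- 0L
    strand <- "+"
    first_unit <- TRUE
    while (remaining > 0L) {
      s <- if (stats::runif(1) < config$p_operon_gene) {
        sizes[sample.int(length(sizes), 1L, prob = probs)]
      } else 1L
      s <- min(s, remaining)
      if (!first_unit && stats::runif(1) < config$strand_switch_rate) {
        strand <- if (strand == "+") "-" else "+"
      }
      first_unit <- FALSE
      unit_counter <- unit_counter + 1L
      ids <- sprintf("g%05d", gene_counter + seq_len(s))
      gene_counter <- gene_counter + s
      starts <- pos + (seq_len(s) - 1L) * (gene_len + gene_gap)
      records[[length(records) + 1L]] <- data.frame(
        gene_id = ids, contig = contig, strand = strand,
        start = starts, end = starts + gene_len, stringsAsFactors = FALSE)
      pos <- starts[s] + gene_len + gene_gap
      units[[unit_counter]] <- ids
      unit_rows[[unit_counter]] <- data.frame(
        operon_id = sprintf("op%04d", unit_counter), contig = contig,
        strand = strand, size = s, stringsAsFactors = FALSE)
      remaining <- remaining - s
    }
  }
  catalog <- gene_catalog(do.call(rbind, records))
  true_operons <- operon_set(units, ids = sprintf("op%04d", seq_along(units)))
  attr(true_operons, "unit_table") <- do.call(rbind, unit_rows)
  list(catalog = catalog, true_operons = true_operons)
}

#' Generate a diel expression matrix for a synthetic genome
#'
#' Each transcription unit is diel with probability `diel_fraction`; a diel
#' unit gets a base phase `phi ~ Uniform[0, 24)` and member gene i the profile
#' `amplitude * sin(2*pi*(t - phi - eps_i)/24) + N(0, noise_sd^2)` with
#' `eps_i ~ N(0, phase_jitter^2)`. Arrhythmic genes are pure noise. Values are
#' log2-scale (mean-center downstream, as in the pipeline).
#'
#' @param catalog catalog from [generate_genome()].
#' @param true_operons transcription units from [generate_genome()].
#' @param config the same [sim_config()].
#' @return an [expression_matrix()]; attributes `unit_diel` (named logical per
#'   unit) and `unit_phase` (named numeric, NA for arrhythmic units).
#' @export
generate_expression <- function(catalog, true_operons, config) {
  set.seed(derive_seed(config$seed, 202L))
  tp <- config$timepoints_h
  vals <- matrix(NA_real_, nrow = nrow(catalog), ncol = length(tp),
                 dimnames = list(catalog$gene_id, NULL))
  unit_diel <- stats::setNames(logical(length(true_operons)), names(true_operons))
  unit_phase <- stats::setNames(rep(NA_real_, length(true_operons)),
                                names(true_operons))
  prev_phase <- NA_real_
  for (i in seq_along(true_operons)) {
    genes <- true_operons[[i]]
    is_diel_unit <- stats::runif(1) < config$diel_fraction
    unit_diel[i] <- is_diel_unit
    if (is_diel_unit) {
      phi <- stats::runif(1, 0, 24)
      if (config$min_phase_sep_h > 0 && !is.na(prev_phase)) {
        tries <- 0L
        while (circular_sep_h(phi, prev_phase) < config$min_phase_sep_h &&
               tries < 1000L) {
          phi <- stats::runif(1, 0, 24)
          tries <- tries + 1L
        }
      }
      unit_phase[i] <- phi
      prev_phase <- phi
      eps <- stats::rnorm(length(genes), 0, config$phase_jitter_h)
      for (k in seq_along(genes)) {
        signal <- config$amplitude_log2 * sin(2 * pi * (tp - phi - eps[k]) / 24)
        vals[genes[k], ] <- signal + stats::rnorm(length(tp), 0, config$noise_sd_log2)
      }
    } else {
      for (g in genes) {
        vals[g, ] <- stats::rnorm(length(tp), 0, config$noise_sd_log2)
      }
    }
  }
  expr <- expression_matrix(vals, tp)
  attr(expr, "unit_diel") <- unit_diel
  attr(expr, "unit_phase") <- unit_phase
  expr
}

circular_sep_h <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  min(d, period - d)
}

#' Split true operons into deliberately fragmented prior predictions
#'
#' Each true operon of size >= 2 is, with probability `p_split_prior`, cut at
#' a uniformly chosen internal boundary into two priors (recorded as a split
#' pair that SHOULD merge); otherwise it is emitted whole. Adjacent priors
#' originating from different true operons on the same strand/contig form the
#' non-merge pairs (should NOT merge).
#'
#' @param true_operons units from [generate_genome()].
#' @param catalog the matching catalog.
#' @param config the same [sim_config()].
#' @return list with `priors` (an [operon_set()]) and `ground_truth`: a list
#'   with `split_pairs` and `non_merge_pairs` data frames (`prior1_id`,
#'   `prior2_id`).
#' @export
generate_split_priors <- function(true_operons, catalog, config) {
  set.seed(derive_seed(config$seed, 303L))
  prior_lists <- list()
  prior_ids <- character(0)
  prior_unit <- character(0)
  split_pairs <- list()
  for (i in seq_along(true_operons)) {
    uid <- names(true_operons)[i]
    genes <- true_operons[[i]]
    s <- length(genes)
    do_split <- s >= 2 && stats::runif(1) < config$p_split_prior
    if (do_split) {
      cut <- if (s == 2L) 1L else sample.int(s - 1L, 1L)
      ida <- paste0(uid, ".a")
      idb <- paste0(uid, ".b")
      prior_lists <- c(prior_lists, list(genes[seq_len(cut)],
                                         genes[seq.int(cut + 1L, s)]))
      prior_ids <- c(prior_ids, ida, idb)
      prior_unit <- c(prior_unit, uid, uid)
      split_pairs[[length(split_pairs) + 1L]] <-
        data.frame(prior1_id = ida, prior2_id = idb, stringsAsFactors = FALSE)
    } else {
      prior_lists <- c(prior_lists, list(genes))
      prior_ids <- c(prior_ids, uid)
      prior_unit <- c(prior_unit, uid)
    }
  }
  priors <- operon_set(prior_lists, ids = prior_ids)

  # adjacent prior pairs from different true operons, same contig + strand
  first_rank <- vapply(priors, function(g) min(rank_of(catalog, g)), numeric(1))
  last_rank <- vapply(priors, function(g) max(rank_of(catalog, g)), numeric(1))
  ctg <- vapply(priors, function(g) contig_of(catalog, g[1]), character(1))
  std <- vapply(priors, function(g) strand_of(catalog, g[1]), character(1))
  ord <- order(ctg, first_rank)
  nm <- list()
  for (k in seq_len(length(priors) - 1L)) {
    i <- ord[k]; j <- ord[k + 1L]
    if (ctg[i] == ctg[j] && last_rank[i] + 1 == first_rank[j] &&
        std[i] == std[j] && prior_unit[i] != prior_unit[j]) {
      nm[[length(nm) + 1L]] <- data.frame(prior1_id = prior_ids[i],
                                          prior2_id = prior_ids[j],
                                          stringsAsFactors = FALSE)
    }
  }
  ground_truth <- list(
    split_pairs = if (length(split_pairs)) do.call(rbind, split_pairs) else
      data.frame(prior1_id = character(0), prior2_id = character(0)),
    non_merge_pairs = if (length(nm)) do.call(rbind, nm) else
      data.frame(prior1_id = character(0), prior2_id = character(0)))
  list(priors = priors, ground_truth = ground_truth)
}

#' Generate the complete synthetic data set
#'
#' Convenience wrapper running [generate_genome()], [generate_expression()]
#' and [generate_split_priors()].
#'
#' @param config a [sim_config()].
#' @return list with `catalog`, `true_operons`, `expr`, `priors`,
#'   `ground_truth`.
#' @export
simulate_dataset <- function(config) {
  gen <- generate_genome(config)
  expr <- generate_expression(gen$catalog, gen$true_operons, config)
  sp <- generate_split_priors(gen$true_operons, gen$catalog, config)
  list(catalog = gen$catalog, true_operons = gen$true_operons, expr = expr,
       priors = sp$priors, ground_truth = sp$ground_truth)
}

#' Write the standard fixture set for a simulated data set
#'
#' Writes `annotation.tsv`, `expression.tsv`, `priors.tsv` (operon_list
#' dialect), `truth_operons.tsv` and `truth_pairs.tsv` into `dir`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param config the generating [sim_config()] (stamped into headers).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- output_header(config$seed, flatten_config(config))
  write_annotation_tsv(sim$catalog, file.path(dir, "annotation.tsv"), hdr)
  write_expression_table(sim$expr, file.path(dir, "expression.tsv"), hdr)
  write_prior_operons(sim$priors, file.path(dir, "priors.tsv"), hdr)
  write_prior_operons(sim$true_operons, file.path(dir, "truth_operons.tsv"), hdr)
  tag <- function(df, val) {
    df$should_merge <- rep(val, nrow(df))
    df
  }
  pairs <- rbind(tag(sim$ground_truth$split_pairs, "true"),
                 tag(sim$ground_truth$non_merge_pairs, "false"))
  write_tsv_with_header(pairs, file.path(dir, "truth_pairs.tsv"), hdr)
  invisible(dir)
}

flatten_config <- function(config) {
  lapply(config, function(v) if (is.numeric(v)) v else as.character(v))
}
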