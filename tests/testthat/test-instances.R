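# Training-instance construction, candidate discovery, featurization.

# shared fixture: 8 genes, strands ++ ++ - + + -, diel sinusoids with two
# phase groups plus one flat (arrhythmic) gene
inst_fixture <- function() {
  cat <- fix_catalog("++++-++-")
  expr <- fix_expr(list(g1 = sinus(0), g2 = sinus(0.3), g3 = sinus(0.6),
                        g4 = sinus(1), g5 = sinus(12), g6 = sinus(12.5),
                        g7 = rep(0, 8), g8 = sinus(6)))
  expr <- mean_center(expr)
  list(cat = cat, expr = expr, diel = diel_calls(expr))
}

test_that("featurize computes (min, mean, sample sd, max)", {
  expect_equal(featurize(0.4),
               c(d_min = 0.4, d_mean = 0.4, d_sd = 0, d_max = 0.4))
  f <- featurize(c(1, 2, 3, 4))
  expect_equal(unname(f), c(1, 2.5, sqrt(5 / 3), 4))
  expect_equal(f[["d_sd"]], 1.2910, tolerance = 1e-4)
  # permutation invariance
  set.seed(3)
  for (i in 1:10) {
    d <- runif(sample(2:10, 1))
    expect_identical(featurize(d), featurize(sample(d)))
  }
  expect_error(featurize(numeric(0)), "at least one")
  expect_error(featurize(c(1, NA)), "finite")
})

test_that("featurize output is ordered d_min <= d_mean <= d_max, d_sd >= 0", {
  set.seed(5)
  for (i in 1:25) {
    f <- featurize(runif(sample(1:12, 1)))
    expect_lte(f[["d_min"]], f[["d_mean"]])
    expect_lte(f[["d_mean"]], f[["d_max"]])
    expect_gte(f[["d_sd"]], 0)
  }
})

test_that("positive instances require >=2 usable genes and >=1 diel gene", {
  fx <- inst_fixture()
  priors <- validate_operons(operon_set(list(
    c("g1", "g2"),                  # 2 genes, diel -> single-pair instance
    c("g2", "g3", "g4"),            # 3 genes -> 3 pairs
    "g6"                            # single gene -> skipped
  ), ids = c("pA", "pB", "pC")), fx$cat)
  pos <- build_positive_instances(priors, fx$expr, fx$diel)
  expect_equal(pos$instance_id, c("pA", "pB"))
  expect_equal(pos$label, rep("positive", 2))

  # single-pair degenerate: d_min = d_mean = d_max, d_sd = 0
  expect_equal(pos$d_min[1], pos$d_max[1])
  expect_equal(pos$d_sd[1], 0)

  # 3-gene prior: direct stats over the 3 pairwise distances
  d <- c(ablim_distance(fx$expr$values["g2", ], fx$expr$values["g3", ], TP8),
         ablim_distance(fx$expr$values["g2", ], fx$expr$values["g4", ], TP8),
         ablim_distance(fx$expr$values["g3", ], fx$expr$values["g4", ], TP8))
  expect_equal(unlist(pos[2, c("d_min", "d_mean", "d_sd", "d_max")]),
               featurize(d), tolerance = 1e-12)
  expect_equal(attr(pos, "skipped")$reason, "single_gene")
})

test_that("priors with no diel gene are skipped", {
  cat <- fix_catalog("++")
  expr <- mean_center(fix_expr(list(g1 = 0.1 * sinus(0), g2 = 0.1 * sinus(1))))
  diel <- diel_calls(expr)
  priors <- validate_operons(operon_set(list(c("g1", "g2"))), cat)
  pos <- build_positive_instances(priors, expr, diel)
  expect_equal(nrow(pos), 0L)
  expect_equal(attr(pos, "skipped")$reason, "no_diel_gene")
})

strand_of_fix <- function(cat, genes) cat$strand[match(genes, cat$gene_id)]

test_that("negative windows need both strands and a diel gene", {
  fx <- inst_fixture()
  # fixed k=2 scan: valid windows are strand changes with a diel gene
  neg <- build_negative_instances(fx$cat, fx$expr, fx$diel,
                                  size_policy = "fixed", k = 2)
  expect_true(all(neg$label == "negative"))
  expect_true(nrow(neg) >= 1)
  for (genes in strsplit(neg$gene_ids, ",")) {
    expect_length(unique(strand_of_fix(fx$cat, genes)), 2L)
  }
  # single-strand windows are rejected: all-plus catalog yields nothing
  cat_plus <- fix_catalog("++++")
  expr <- mean_center(fix_expr(list(g1 = sinus(0), g2 = sinus(1),
                                    g3 = sinus(2), g4 = sinus(3))))
  neg0 <- build_negative_instances(cat_plus, expr, diel_calls(expr),
                                   size_policy = "fixed", k = 2)
  expect_equal(nrow(neg0), 0L)
})

test_that("fixed-k negative scan matches the exhaustive window oracle", {
  # 100-gene alternating-strand fixture: every adjacent pair is mixed-strand
  n <- 100
  cat <- fix_catalog(paste(rep(c("+", "-"), n / 2), collapse = ""))
  set.seed(17)
  profs <- lapply(seq_len(n), function(i) sinus(runif(1, 0, 24)))
  names(profs) <- paste0("g", seq_len(n))
  expr <- mean_center(fix_expr(profs))
  diel <- diel_calls(expr)
  neg <- build_negative_instances(cat, expr, diel, size_policy = "fixed", k = 2)
  oracle <- bf_negative_windows_fixed(cat, diel, 2)
  expect_equal(nrow(neg), length(oracle))
  expect_equal(nrow(neg), 50L)  # all genes diel -> every other pair accepted
  expect_equal(strsplit(neg$gene_ids, ","), oracle)
})

test_that("stochastic size policy requires a seed and matches positive sizes", {
  fx <- inst_fixture()
  expect_error(build_negative_instances(fx$cat, fx$expr, fx$diel,
                                        positive_sizes = c(2, 3)),
               "seed")
  neg <- build_negative_instances(fx$cat, fx$expr, fx$diel,
                                  positive_sizes = c(2, 3), seed = 1)
  expect_true(all(neg$n_genes %in% c(2, 3)))
  # same seed -> identical draw
  neg2 <- build_negative_instances(fx$cat, fx$expr, fx$diel,
                                   positive_sizes = c(2, 3), seed = 1)
  expect_identical(neg, neg2)
})

test_that("candidate discovery applies the adjacency/strand/diel rules", {
  fx <- inst_fixture()
  # the schematic case: two 2-gene priors back to back on + strand
  priors <- validate_operons(operon_set(list(c("g1", "g2"), c("g3", "g4")),
                                        ids = c("red", "blue")), fx$cat)
  cands <- find_merge_candidates(priors, fx$cat, fx$diel)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$prior1_id, "red")
  expect_equal(cands$prior2_id, "blue")
  expect_equal(cands$n_cross_pairs, 4L)

  # an unassigned gene between the priors blocks the merge
  gap <- validate_operons(operon_set(list(c("g1", "g2"), "g4"),
                                     ids = c("red", "blue")), fx$cat)
  cg <- find_merge_candidates(gap, fx$cat, fx$diel)
  expect_equal(nrow(cg), 0L)
  expect_equal(attr(cg, "excluded")$reason, "intervening_genes")

  # strand mismatch: g4 (+) then g5 (-)
  sm <- validate_operons(operon_set(list(c("g3", "g4"), "g5")), fx$cat)
  cs <- find_merge_candidates(sm, fx$cat, fx$diel)
  expect_equal(nrow(cs), 0L)
  expect_equal(attr(cs, "excluded")$reason, "strand_mismatch")

  # non-diel prior: g7 is flat
  nd <- validate_operons(operon_set(list("g6", "g7")), fx$cat)
  cn <- find_merge_candidates(nd, fx$cat, fx$diel)
  expect_equal(nrow(cn), 0L)
  expect_equal(attr(cn, "excluded")$reason, "no_diel_gene")
})

test_that("candidate discovery matches a brute-force scan on random fixtures", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(20:50, 1)
    cat <- fix_catalog(paste(sample(c("+", "-"), n, TRUE, prob = c(0.6, 0.4)),
                             collapse = ""))
    profs <- lapply(seq_len(n), function(i) {
      if (runif(1) < 0.8) sinus(runif(1, 0, 24)) else rnorm(8, sd = 0.05)
    })
    names(profs) <- paste0("g", seq_len(n))
    expr <- mean_center(fix_expr(profs))
    diel <- diel_calls(expr)
    # carve same-strand runs into random priors
    runs <- split(seq_len(n), cumsum(c(1, diff(match(cat$strand, c("+", "-"))) != 0)))
    prior_lists <- list()
    for (r in runs) {
      i <- 1
      while (i <= length(r)) {
        s <- min(sample(1:3, 1), length(r) - i + 1)
        prior_lists[[length(prior_lists) + 1L]] <- paste0("g", r[i:(i + s - 1)])
        i <- i + s
      }
    }
    priors <- validate_operons(operon_set(prior_lists), cat)
    got <- find_merge_candidates(priors, cat, diel)
    oracle <- bf_candidates(priors, cat, diel)
    expect_equal(nrow(got), nrow(oracle))
    expect_setequal(paste(got$prior1_id, got$prior2_id),
                    paste(oracle$prior1_id, oracle$prior2_id))
    # determinism: identical inputs -> identical ordered output
    expect_identical(got, find_merge_candidates(priors, cat, diel))
    # every candidate's gene set is prior1 U prior2 with no intervening ranks
    for (i in seq_len(nrow(got))) {
      genes <- c(strsplit(got$genes1[i], ",")[[1]],
                 strsplit(got$genes2[i], ",")[[1]])
      rk <- sort(cat$rank[match(genes, cat$gene_id)])
      expect_true(all(diff(rk) == 1))
    }
  }
})

test_that("candidate features use cross-prior pairs only", {
  fx <- inst_fixture()
  priors <- validate_operons(operon_set(list(c("g1", "g2"), c("g3", "g4")),
                                        ids = c("p1", "p2")), fx$cat)
  cands <- featurize_candidates(find_merge_candidates(priors, fx$cat, fx$diel),
                                fx$expr)
  v <- fx$expr$values
  cross <- c(ablim_distance(v["g1", ], v["g3", ], TP8),
             ablim_distance(v["g1", ], v["g4", ], TP8),
             ablim_distance(v["g2", ], v["g3", ], TP8),
             ablim_distance(v["g2", ], v["g4", ], TP8))
  expect_equal(unlist(cands[1, c("d_min", "d_mean", "d_sd", "d_max")]),
               featurize(cross), tolerance = 1e-12)
})

test_that("candidates touching unusable profiles are dropped with a warning", {
  cat <- fix_catalog("++++")
  v <- rbind(g1 = sinus(0), g2 = sinus(1), g3 = c(NA, sinus(2)[-1]),
             g4 = sinus(3))
  expr <- mean_center(expression_matrix(v, TP8))
  diel <- diel_calls(expr)
  priors <- validate_operons(operon_set(list(c("g1", "g2"), c("g3", "g4")),
                                        ids = c("p1", "p2")), cat)
  cands <- find_merge_candidates(priors, cat, diel)
  expect_equal(nrow(cands), 1L)
  expect_warning(out <- featurize_candidates(cands, expr), "dropped")
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "dropped")$prior1_id, "p1")
})

test_that("feature table round-trips", {
  fx <- inst_fixture()
  priors <- validate_operons(operon_set(list(c("g1", "g2", "g3"))), fx$cat)
  pos <- build_positive_instances(priors, fx$expr, fx$diel)
  f <- tempfile()
  write_feature_table(pos, f, header = "# features")
  back <- read_feature_table(f)
  expect_equal(back$d_mean, pos$d_mean, tolerance = 1e-12)
  expect_equal(back$label, pos$label)
})
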