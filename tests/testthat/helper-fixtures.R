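# Fixture builders used across the suite. Everything is generated in code;
# no files ship with the package.

TP8 <- seq(0, 21, by = 3)

# Catalog from a strand string like "++-+"; genes g1..gN at starts 100, 200, ...
fix_catalog <- function(strands, contig = "c1") {
  n <- nchar(strands)
  gene_catalog(data.frame(
    gene_id = paste0("g", seq_len(n)),
    contig = contig,
    strand = strsplit(strands, "")[[1]],
    start = 100L * seq_len(n),
    end = 100L * seq_len(n) + 50L,
    stringsAsFactors = FALSE))
}

# Expression matrix with a given per-gene profile list (shared timepoints).
fix_expr <- function(profiles, timepoints_h = TP8) {
  m <- do.call(rbind, profiles)
  rownames(m) <- names(profiles)
  expression_matrix(m, timepoints_h)
}

sinus <- function(phase_h, amplitude = 1, timepoints_h = TP8) {
  amplitude * sin(2 * pi * (timepoints_h - phase_h) / 24)
}

# Random mean-zero-ish profiles as a genes x timepoints matrix.
random_profiles <- function(n, timepoints_h = TP8, seed = 1, sd = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * length(timepoints_h), sd = sd), nrow = n)
  rownames(m) <- sprintf("r%03d", seq_len(n))
  m
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
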