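#' Read a gene annotation into a gene catalog
#'
#' Supports GFF3 (1-based inclusive coordinates, converted to the internal
#' 0-based half-open convention on read; rows of type `gene`, or `CDS` when no
#' `gene` rows exist, must carry an `ID` attribute) and a simple TSV dialect
#' with header `gene_id, contig, strand, start, end` whose coordinates are
#' taken to be already 0-based half-open.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return a [gene_catalog()].
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_usage("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  df <- switch(format, gff3 = gff3_to_df(path), tsv = annotation_tsv_to_df(path))
  gene_catalog(df)
}

gff3_to_df <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  d <- as.data.frame(gr)
  keep <- d$type == "gene"
  if (!any(keep)) keep <- d$type == "CDS"
  d <- d[keep, , drop = FALSE]
  if (!nrow(d)) stop("no gene/CDS features in GFF3 file: ", path)
  id <- if ("ID" %in% names(d)) as.character(d$ID) else NA_character_
  if (anyNA(id) || any(!nzchar(id))) {
    stop("GFF3 gene/CDS rows must carry an ID attribute: ", path)
  }
  # GFF3 is 1-based inclusive; internal convention is 0-based half-open.
  data.frame(gene_id = id,
             contig = as.character(d$seqnames),
             strand = as.character(d$strand),
             start = d$start - 1L,
             end = d$end,
             stringsAsFactors = FALSE)
}

annotation_tsv_to_df <- function(path) {
  df <- read_tsv_plain(path)
  required <- c("gene_id", "contig", "strand", "start", "end")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("annotation TSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df
}

#' Write a gene catalog as the simple annotation TSV
#' @param catalog a [gene_catalog()].
#' @param path output path.
#' @param header optional comment lines (each starting with `#`).
#' @export
write_annotation_tsv <- function(catalog, path, header = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"))
  write_tsv_with_header(
    catalog[c("gene_id", "contig", "strand", "start", "end")], path, header)
}

#' Read a log-expression table
#'
#' TSV with first column `gene_id` and remaining column headers that parse as
#' hours. Columns are reordered to ascending time if needed. Ragged rows,
#' non-numeric cells (other than literal `NA`), duplicate gene rows and
#' non-numeric timepoint headers are hard errors.
#'
#' @param path file path.
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) abort_usage("expression file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1) {
    stop("ragged expression table (rows with ", paste(unique(nf), collapse = "/"),
         " fields): ", path)
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("expression table needs gene_id plus >=1 timepoint column")
  gene_ids <- raw[[1]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene row(s): ", paste(unique(dup), collapse = ", "))

  tp_names <- names(raw)[-1]
  tp <- suppressWarnings(as.numeric(tp_names))
  if (anyNA(tp)) {
    stop("timepoint column header(s) not numeric hours: ",
         paste(tp_names[is.na(tp)], collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(tp),
                 dimnames = list(gene_ids, NULL))
  for (j in seq_along(tp)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & col != "NA")
    if (length(bad)) {
      stop("non-numeric expression value ", sQuote(col[bad[1]]), " for gene ",
           sQuote(gene_ids[bad[1]]), " in column ", sQuote(tp_names[j]))
    }
    vals[, j] <- num
  }
  ord <- order(tp)
  expression_matrix(vals[, ord, drop = FALSE], tp[ord])
}

#' Write an expression matrix as TSV
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @param header optional comment lines.
#' @export
write_expression_table <- function(expr, path, header = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene_id", format(expr$timepoints_h, trim = TRUE, digits = 15))
  write_tsv_with_header(df, path, header)
}

#' Operon prediction set
#'
#' A named list of character vectors: names are operon ids, elements are the
#' ordered gene ids of each prediction. Constructed by the readers and the
#' synthetic generator; [validate_operons()] enforces the invariants (genes
#' present in the catalog, one contig, one strand, consecutive ranks).
#'
#' @param gene_id_lists list of character vectors.
#' @param ids operon ids (default `P0001`, `P0002`, ...).
#' @return an `operon_set`.
#' @export
operon_set <- function(gene_id_lists, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("P%04d", seq_along(gene_id_lists))
  stopifnot(length(ids) == length(gene_id_lists))
  structure(stats::setNames(lapply(gene_id_lists, as.character), ids),
            class = "operon_set")
}

#' @export
print.operon_set <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("operon_set: %d prediction(s), sizes %s..%s\n",
              length(x), if (length(x)) min(sizes) else NA,
              if (length(x)) max(sizes) else NA))
  invisible(x)
}

#' @export
`[.operon_set` <- function(x, i) {
  structure(NextMethod(), class = "operon_set")
}

#' Validate operon predictions against a catalog
#'
#' Each prediction must reference known genes that share one contig and one
#' strand and occupy consecutive ranks (no intervening genes). Gene ids are
#' reordered by rank.
#'
#' @param ops an [operon_set()].
#' @param catalog a [gene_catalog()].
#' @return the validated (rank-ordered) `operon_set`; errors name the
#'   offending prediction.
#' @export
validate_operons <- function(ops, catalog) {
  out <- ops
  for (i in seq_along(ops)) {
    id <- names(ops)[i]
    genes <- ops[[i]]
    if (!length(genes)) stop("operon ", sQuote(id), " has no genes")
    idx <- tryCatch(catalog_index(catalog, genes),
                    error = function(e) stop("operon ", sQuote(id), ": ",
                                             conditionMessage(e)))
    if (length(unique(catalog$contig[idx])) > 1) {
      stop("operon ", sQuote(id), " spans multiple contigs")
    }
    if (length(unique(catalog$strand[idx])) > 1) {
      stop("operon ", sQuote(id), " spans both strands")
    }
    rk <- sort(catalog$rank[idx])
    if (length(rk) > 1 && !all(diff(rk) == 1L)) {
      stop("operon ", sQuote(id), " has non-consecutive gene ranks (",
           paste(rk, collapse = ","), ")")
    }
    out[[i]] <- genes[order(catalog$rank[idx])]
  }
  out
}

#' Read prior operon predictions
#'
#' Two dialects: `operon_list` (one prediction per line, whitespace-separated
#' gene ids) and `gene_pairs` (two-column rows of adjacent gene pairs, chained
#' by connected components into maximal consecutive same-strand runs).
#'
#' @param path file path.
#' @param format `"operon_list"` or `"gene_pairs"`.
#' @param catalog a [gene_catalog()] used for validation and chaining.
#' @return a validated [operon_set()].
#' @export
read_prior_operons <- function(path, format = c("operon_list", "gene_pairs"),
                               catalog) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_usage("prior operon file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (format == "operon_list") {
    gene_lists <- strsplit(lines, "[ \t]+")
    ops <- operon_set(gene_lists)
  } else {
    pairs <- strsplit(lines, "[ \t]+")
    badlen <- which(lengths(pairs) != 2L)
    if (length(badlen)) {
      stop("gene_pairs line ", badlen[1], " does not have exactly 2 fields")
    }
    ops <- chain_gene_pairs(do.call(rbind, pairs), catalog)
  }
  validate_operons(ops, catalog)
}

# Union of adjacent-gene pairs -> maximal runs, via connected components of
# the pair graph. Each pair must itself be a consecutive same-strand,
# same-contig pair.
chain_gene_pairs <- function(pair_mat, catalog) {
  g1 <- pair_mat[, 1]
  g2 <- pair_mat[, 2]
  i1 <- catalog_index(catalog, g1)
  i2 <- catalog_index(catalog, g2)
  for (k in seq_along(g1)) {
    if (catalog$contig[i1[k]] != catalog$contig[i2[k]]) {
      stop("pair (", g1[k], ", ", g2[k], ") spans contigs")
    }
    if (catalog$strand[i1[k]] != catalog$strand[i2[k]]) {
      stop("pair (", g1[k], ", ", g2[k], ") spans strands")
    }
    if (abs(catalog$rank[i1[k]] - catalog$rank[i2[k]]) != 1L) {
      stop("pair (", g1[k], ", ", g2[k], ") is not rank-consecutive")
    }
  }
  g <- igraph::graph_from_edgelist(cbind(g1, g2), directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, function(genes) genes[order(rank_of(catalog, genes))])
  # deterministic order: by contig then first rank
  first_rank <- vapply(members, function(g) rank_of(catalog, g[1]), numeric(1))
  first_contig <- vapply(members, function(g) contig_of(catalog, g[1]), character(1))
  members <- members[order(first_contig, first_rank)]
  operon_set(unname(members))
}

#' Write an operon set in the operon_list dialect
#' @param ops an [operon_set()].
#' @param path output path.
#' @param header optional comment lines.
#' @export
write_prior_operons <- function(ops, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  writeLines(vapply(ops, paste, character(1), collapse = "\t"), con)
  invisible(path)
}

#' Write the merge report
#'
#' One row per scored merge candidate, sorted by descending score, scores
#' printed with 3 decimals. Columns: `score`, `prior1_id`, `prior1_genes`,
#' `prior2_id`, `prior2_genes`, `merged`.
#'
#' @param candidates a scored candidate data frame (see [score_and_decide()]).
#' @param path output path.
#' @param header optional comment lines (see internals of the CLI for the
#'   standard version/seed/hash header).
#' @export
write_merge_report <- function(candidates, path, header = NULL) {
  cols <- c("score", "prior1_id", "prior1_genes", "prior2_id", "prior2_genes",
            "merged")
  if (!nrow(candidates)) {
    df <- stats::setNames(
      data.frame(numeric(0), character(0), character(0), character(0),
                 character(0), character(0), stringsAsFactors = FALSE), cols)
    return(write_tsv_with_header(df, path, header))
  }
  stopifnot(all(c("score", "merged") %in% names(candidates)))
  ord <- order(-candidates$score, candidates$prior1_id)
  df <- data.frame(score = sprintf("%.3f", candidates$score[ord]),
                   prior1_id = candidates$prior1_id[ord],
                   prior1_genes = candidates$genes1[ord],
                   prior2_id = candidates$prior2_id[ord],
                   prior2_genes = candidates$genes2[ord],
                   merged = tolower(as.character(candidates$merged[ord])),
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, header)
}

#' Read a merge report back
#' @param path file written by [write_merge_report()].
#' @return data frame with numeric `score` and logical `merged`.
#' @export
read_merge_report <- function(path) {
  df <- read_tsv_plain(path, colClasses = "character")
  if (!nrow(df)) {
    df$score <- numeric(0)
    df$merged <- logical(0)
    return(df)
  }
  df$score <- as.numeric(df$score)
  df$merged <- df$merged == "true"
  df
}
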