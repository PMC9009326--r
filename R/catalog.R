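#' Gene catalog: ordered, stranded gene records per contig
#'
#' A `gene_catalog` is a data frame with columns `gene_id`, `contig`, `strand`
#' (`"+"` or `"-"`), `start`, `end` (0-based half-open coordinates) and a
#' computed `rank`: the 0-based position of each gene within its contig when
#' genes are ordered by ascending start. Rank order defines adjacency ("no
#' intervening genes") for candidate discovery, ignoring physical overlaps.
#'
#' @param df data frame with columns `gene_id`, `contig`, `strand`, `start`,
#'   `end`. Coordinates must already be 0-based half-open (`start < end`).
#' @return a `gene_catalog` (data frame sorted by contig then start, with a
#'   `rank` column).
#' @examples
#' gene_catalog(data.frame(gene_id = c("g1", "g2"), contig = "c1",
#'                         strand = c("+", "-"), start = c(0, 900),
#'                         end = c(800, 1700)))
#' @export
gene_catalog <- function(df) {
  required <- c("gene_id", "contig", "strand", "start", "end")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$gene_id <- as.character(df$gene_id)
  df$contig <- as.character(df$contig)
  df$strand <- normalize_strand(df$strand, df$gene_id)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)

  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) {
    stop("duplicate gene_id in annotation: ", paste(unique(dup), collapse = ", "))
  }
  bad <- which(!(df$start < df$end))
  if (length(bad)) {
    stop("start must be < end (0-based half-open) for gene(s): ",
         paste(df$gene_id[bad], collapse = ", "))
  }

  df <- df[order(df$contig, df$start, df$end, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df$rank <- stats::ave(seq_len(nrow(df)), df$contig, FUN = seq_along) - 1L
  class(df) <- c("gene_catalog", "data.frame")
  df
}

# Accepts ASCII +/- and the typographic minus; anything else is an error that
# names the offending row.
normalize_strand <- function(strand, gene_id) {
  strand <- as.character(strand)
  strand[strand == "−"] <- "-"
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    stop("unknown strand symbol ", sQuote(strand[bad[1]]), " for gene ",
         sQuote(gene_id[bad[1]]))
  }
  strand
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("gene_catalog: %d genes on %d contig(s)\n",
              nrow(x), length(unique(x$contig))))
  NextMethod()
}

# Fast lookups keyed by gene id; error if a gene is absent.
catalog_index <- function(catalog, gene_ids) {
  idx <- match(gene_ids, catalog$gene_id)
  if (anyNA(idx)) {
    stop("gene id(s) absent from catalog: ",
         paste(gene_ids[is.na(idx)], collapse = ", "))
  }
  idx
}

rank_of <- function(catalog, gene_ids) catalog$rank[catalog_index(catalog, gene_ids)]
contig_of <- function(catalog, gene_ids) catalog$contig[catalog_index(catalog, gene_ids)]
strand_of <- function(catalog, gene_ids) catalog$strand[catalog_index(catalog, gene_ids)]
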