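#' Read non-B DNA motif calls from BED
#'
#' Accepts BED3/BED6 with the motif type in column 4 (one combined file) or
#' a per-type file whose type is supplied explicitly. Coordinates are BED
#' convention: 0-based, half-open.
#'
#' @param path BED file path.
#' @param motif_type optional type applied to every record (for per-type
#'   files); otherwise column 4 must hold the type.
#' @return data.frame with `chrom`, `start`, `end`, `motif_type`, `score`,
#'   `strand`.
#' @export
read_motif_bed <- function(path, motif_type = NULL) {
  df <- as.data.frame(data.table::fread(path, header = FALSE, sep = "\t"))
  if (ncol(df) < 3) stop("BED file must have at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  out$motif_type <- if (!is.null(motif_type)) motif_type
                    else if (ncol(df) >= 4) as.character(df[[4]])
                    else stop("motif type column missing and no 'motif_type' given")
  out$score <- if (ncol(df) >= 5) suppressWarnings(as.numeric(df[[5]])) else NA_real_
  out$strand <- if (ncol(df) >= 6) as.character(df[[6]]) else "."
  bad <- !out$motif_type %in% motif_type_vocab()
  if (any(bad)) {
    stop("unknown motif type(s): ", paste(unique(out$motif_type[bad]), collapse = ", "))
  }
  if (any(out$start >= out$end)) stop("BED intervals must satisfy start < end")
  out
}

#' Assign motif calls to gene bodies
#'
#' A call is assigned to every gene it overlaps by at least 1 bp (half-open
#' coordinates, so a call starting exactly at a gene's end is not assigned);
#' a call spanning two genes is assigned to both. For length statistics each
#' assignment is clipped to the gene interval. Strand is ignored. Calls on
#' chromosomes absent from the gene table are skipped with a warning and
#' counted.
#'
#' Overlap detection uses `GenomicRanges::findOverlaps()`.
#'
#' @param calls data.frame of motif calls (see [read_motif_bed()]).
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open gene bodies, i.e. min start to max end over the gene's
#'   records).
#' @return data.frame of assignments: `gene_id`, `motif_type`, `start`,
#'   `end`, `clipped_start`, `clipped_end`, `clipped_length`, `score`;
#'   attribute `n_skipped` counts calls on unknown chromosomes.
#' @export
intersect_motifs <- function(calls, genes) {
  known <- calls$chrom %in% unique(genes$chrom)
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    warning(sprintf("%d motif call(s) on chromosomes absent from the gene table; skipped",
                    n_skipped))
    calls <- calls[known, , drop = FALSE]
  }
  empty <- data.frame(gene_id = character(), motif_type = character(),
                      start = integer(), end = integer(),
                      clipped_start = integer(), clipped_end = integer(),
                      clipped_length = integer(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0) {
    attr(empty, "n_skipped") <- n_skipped
    return(empty)
  }
  # half-open [start, end) -> 1-based closed [start+1, end] for IRanges
  gr_calls <- GenomicRanges::GRanges(calls$chrom,
                                     IRanges::IRanges(calls$start + 1L, calls$end))
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(gr_calls, gr_genes, minoverlap = 1L,
                                    ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  if (!length(qi)) {
    attr(empty, "n_skipped") <- n_skipped
    return(empty)
  }
  cs <- pmax(calls$start[qi], genes$start[si])
  ce <- pmin(calls$end[qi], genes$end[si])
  out <- data.frame(
    gene_id = genes$gene_id[si],
    motif_type = calls$motif_type[qi],
    start = calls$start[qi], end = calls$end[qi],
    clipped_start = cs, clipped_end = ce,
    clipped_length = ce - cs,
    score = calls$score[qi],
    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Non-B DNA feature schema
#'
#' @return data.frame with `name` and `units`; attribute `version`.
#' @export
nbd_feature_schema <- function() {
  ty <- motif_type_vocab()
  per_type <- as.vector(outer(
    c("presence", "count", "total_length", "mean_length", "max_gap", "mean_gap"),
    ty, function(a, b) paste0(a, "_", b)))
  fields <- c(per_type, "diversity", "total_count", "total_coverage")
  units <- rep("count", length(fields))
  units[grepl("presence", fields)] <- "flag"
  units[grepl("length|gap", fields)] <- "bp"
  units[fields == "total_coverage"] <- "fraction"
  out <- data.frame(name = fields, units = units, stringsAsFactors = FALSE)
  attr(out, "version") <- "1.0"
  out
}

#' Compute the per-gene non-B DNA feature vector
#'
#' Per motif type: presence flag, call count, total and mean clipped length,
#' and gap statistics between consecutive calls of that type (sorted by
#' start; negative gaps from overlapping calls count as 0). Global:
#' diversity (number of distinct types present, 0-8), total call count, and
#' total coverage = sum of clipped lengths / gene length. Overlapping calls
#' are deliberately retained — a locus can support several non-B structures
#' at once — so total coverage can exceed 1.
#'
#' @param assigned data.frame of this gene's assignments from
#'   [intersect_motifs()] (may be empty).
#' @param gene_length gene body length in bp (>= 1).
#' @return named numeric vector following [nbd_feature_schema()].
#' @export
compute_nbd_features <- function(assigned, gene_length) {
  stopifnot(gene_length >= 1)
  schema <- nbd_feature_schema()
  v <- stats::setNames(numeric(nrow(schema)), schema$name)
  if (nrow(assigned) == 0) return(v)
  for (ty in unique(assigned$motif_type)) {
    g <- assigned[assigned$motif_type == ty, , drop = FALSE]
    g <- g[order(g$clipped_start), , drop = FALSE]
    v[paste0("presence_", ty)] <- 1
    v[paste0("count_", ty)] <- nrow(g)
    v[paste0("total_length_", ty)] <- sum(g$clipped_length)
    v[paste0("mean_length_", ty)] <- mean(g$clipped_length)
    if (nrow(g) > 1) {
      gaps <- pmax(0, g$clipped_start[-1] - g$clipped_end[-nrow(g)])
      v[paste0("max_gap_", ty)] <- max(gaps)
      v[paste0("mean_gap_", ty)] <- mean(gaps)
    }
  }
  v["diversity"] <- length(unique(assigned$motif_type))
  v["total_count"] <- nrow(assigned)
  v["total_coverage"] <- sum(assigned$clipped_length) / gene_length
  v
}

#' Non-B DNA feature matrix for a set of genes
#'
#' @param calls motif calls (data.frame or BED path).
#' @param genes gene interval table (`gene_id`, `chrom`, `start`, `end`).
#' @return data.frame, rows named by gene id, columns per
#'   [nbd_feature_schema()].
#' @export
nbd_feature_matrix <- function(calls, genes) {
  if (!is.data.frame(calls)) calls <- read_motif_bed(calls)
  assigned <- intersect_motifs(calls, genes)
  by_gene <- split(assigned, assigned$gene_id)
  schema <- nbd_feature_schema()
  out <- matrix(0, nrow = nrow(genes), ncol = nrow(schema),
                dimnames = list(genes$gene_id, schema$name))
  glen <- stats::setNames(genes$end - genes$start, genes$gene_id)
  for (gid in genes$gene_id) {
    a <- by_gene[[gid]]
    if (is.null(a)) a <- assigned[0, , drop = FALSE]
    out[gid, ] <- compute_nbd_features(a, glen[[gid]])
  }
  as.data.frame(out)
}
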