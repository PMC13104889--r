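#' Parse RepeatMasker .out text
#'
#' Reads the standard RepeatMasker output layout: three header lines (two
#' column-name lines and a blank line) followed by whitespace-separated body
#' rows with 15 columns plus an optional trailing `*` marking a hit that is
#' overlapped by a higher-scoring hit. Repeat class and family are split on
#' the first `/`; hits without a family (e.g. `Simple_repeat`) get family
#' `""`. Query coordinates are 1-based inclusive.
#'
#' @param x character vector of lines, a single string containing newlines,
#'   or a path to a `.out` file.
#' @return data.frame of hits with columns `sw_score`, `pct_div`, `pct_del`,
#'   `pct_ins`, `query_id`, `begin`, `end`, `q_left`, `strand`,
#'   `repeat_name`, `repeat_class`, `repeat_family`, `r_begin`, `r_end`,
#'   `r_left`, `element_id`, `overlap_marker`.
#' @export
parse_repeatmasker_out <- function(x) {
  lines <- clstr_lines(x)  # same dispatch: path / embedded newlines / vector
  # drop the standard 3-line header: any line that is blank or starts with
  # the column-name words
  body <- lines[!grepl("^\\s*$", lines) &
                  !grepl("^\\s*(SW|score)\\b", lines)]
  empty <- data.frame(
    sw_score = integer(), pct_div = numeric(), pct_del = numeric(),
    pct_ins = numeric(), query_id = character(), begin = integer(),
    end = integer(), q_left = integer(), strand = character(),
    repeat_name = character(), repeat_class = character(),
    repeat_family = character(), r_begin = integer(), r_end = integer(),
    r_left = integer(), element_id = integer(), overlap_marker = logical(),
    stringsAsFactors = FALSE)
  if (!length(body)) return(empty)
  strip_paren <- function(v) as.integer(gsub("[()]", "", v))
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (!(length(tok) %in% c(15L, 16L))) {
      stop(sprintf("RepeatMasker parse error at body line %d: expected 15 columns (+ optional '*'), got %d",
                   i, length(tok)))
    }
    cf <- strsplit(tok[11], "/", fixed = TRUE)[[1]]
    rows[[i]] <- data.frame(
      sw_score = as.integer(tok[1]),
      pct_div = as.numeric(tok[2]), pct_del = as.numeric(tok[3]),
      pct_ins = as.numeric(tok[4]),
      query_id = tok[5],
      begin = as.integer(tok[6]), end = as.integer(tok[7]),
      q_left = strip_paren(tok[8]),
      strand = tok[9], repeat_name = tok[10],
      repeat_class = cf[1],
      repeat_family = if (length(cf) > 1) paste(cf[-1], collapse = "/") else "",
      r_begin = strip_paren(tok[12]), r_end = strip_paren(tok[13]),
      r_left = strip_paren(tok[14]),
      element_id = as.integer(tok[15]),
      overlap_marker = length(tok) == 16L && tok[16] == "*",
      stringsAsFactors = FALSE)
    if (is.na(rows[[i]]$begin) || is.na(rows[[i]]$end) ||
        rows[[i]]$begin > rows[[i]]$end) {
      stop(sprintf("RepeatMasker parse error at body line %d: bad query coordinates", i))
    }
  }
  do.call(rbind, rows)
}

#' Resolve overlapping repeat hits on one transcript
#'
#' Overlapping annotations are resolved by confidence: hits are ranked by
#' Smith-Waterman score (descending; ties by longer span, then smaller
#' begin) and accepted greedily. A candidate whose span is already fully
#' covered by accepted hits is dropped; a partially overlapping candidate is
#' trimmed to the largest single uncovered segment of its span. The result
#' is pairwise non-overlapping, sorted by `begin`.
#'
#' Resolution is idempotent: applying it to already-resolved hits returns
#' them unchanged (up to ordering, which is normalized).
#'
#' @param hits data.frame of hits on a single transcript (as from
#'   [parse_repeatmasker_out()]).
#' @return data.frame of non-overlapping hits, sorted by `begin`.
#' @export
resolve_overlaps <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  if (length(unique(hits$query_id)) > 1) {
    stop("resolve_overlaps() expects hits from a single transcript")
  }
  ord <- order(-hits$sw_score, -(hits$end - hits$begin), hits$begin)
  hits <- hits[ord, , drop = FALSE]
  acc_b <- integer(0); acc_e <- integer(0)
  keep <- list()
  for (i in seq_len(nrow(hits))) {
    b <- hits$begin[i]; e <- hits$end[i]
    if (length(acc_b) == 0) {
      seg <- c(b, e)
    } else {
      # uncovered segments of [b, e] after removing accepted spans
      cover <- rep(FALSE, e - b + 1)
      for (j in seq_along(acc_b)) {
        lo <- max(b, acc_b[j]); hi <- min(e, acc_e[j])
        if (lo <= hi) cover[(lo - b + 1):(hi - b + 1)] <- TRUE
      }
      if (all(cover)) next  # fully covered: drop
      r <- rle(cover)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      free <- which(!r$values)
      pick <- free[which.max(r$lengths[free])]  # largest uncovered segment
      seg <- c(b + starts[pick] - 1, b + ends[pick] - 1)
    }
    row <- hits[i, , drop = FALSE]
    row$begin <- seg[1]; row$end <- seg[2]
    keep[[length(keep) + 1L]] <- row
    acc_b <- c(acc_b, seg[1]); acc_e <- c(acc_e, seg[2])
  }
  out <- do.call(rbind, keep)
  out <- out[order(out$begin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate resolved hits into repeat elements
#'
#' RepeatMasker splits one repeat element into multiple fragments that share
#' the ID column. Fragments are regrouped: element length is the sum of
#' fragment lengths, the fragment count is recorded, and class/family are
#' taken from the highest-scoring fragment (a conflicting class within one
#' ID triggers a warning).
#'
#' @param resolved data.frame of non-overlapping hits from
#'   [resolve_overlaps()].
#' @return data.frame with one row per element: `element_id`, `query_id`,
#'   `begin`, `end` (span extremes), `length` (sum of fragment lengths),
#'   `n_fragments`, `repeat_name`, `repeat_class`, `repeat_family`,
#'   `sw_score` (max), `pct_div` (fragment-length-weighted mean).
#' @export
aggregate_elements <- function(resolved) {
  if (nrow(resolved) == 0) {
    return(data.frame(element_id = integer(), query_id = character(),
                      begin = integer(), end = integer(), length = integer(),
                      n_fragments = integer(), repeat_name = character(),
                      repeat_class = character(), repeat_family = character(),
                      sw_score = integer(), pct_div = numeric()))
  }
  out <- lapply(split(resolved, resolved$element_id), function(g) {
    if (length(unique(g$repeat_class)) > 1) {
      warning(sprintf("element %d carries conflicting classes (%s); keeping highest-scoring",
                      g$element_id[1], paste(unique(g$repeat_class), collapse = ", ")))
    }
    top <- g[which.max(g$sw_score), ]
    w <- g$end - g$begin + 1
    data.frame(
      element_id = g$element_id[1], query_id = g$query_id[1],
      begin = min(g$begin), end = max(g$end),
      length = sum(w), n_fragments = nrow(g),
      repeat_name = top$repeat_name, repeat_class = top$repeat_class,
      repeat_family = top$repeat_family,
      sw_score = max(g$sw_score),
      pct_div = sum(g$pct_div * w) / sum(w),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$begin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

repeat_feature_classes <- function() {
  c("LINE", "SINE", "LTR", "DNA", "Retroposon", "Simple_repeat",
    "Low_complexity", "Satellite", "pseudogene", "Other")
}

repeat_feature_families <- function() {
  c("L1", "L2", "Alu", "MIR", "ERVL", "ERV1", "hAT", "TcMar")
}

#' Transcript-level repeat feature schema
#'
#' The repeat feature vector is schema-fixed: field names, order and units
#' are versioned so downstream tables are stable across runs.
#'
#' @return data.frame with `name`, `level`, `units`, `normalization`;
#'   attribute `version`.
#' @export
repeat_feature_schema <- function() {
  cls <- repeat_feature_classes()
  fam <- repeat_feature_families()
  fields <- c(
    "total_hit_count", "total_element_count", "total_coverage_fraction",
    paste0("count_class_", cls), paste0("coverage_class_", cls),
    paste0("presence_class_", cls), paste0("count_family_", fam),
    "mean_fragments_per_element", "max_fragments_per_element",
    "max_gap", "mean_gap", "longest_repeat_free_stretch",
    "hits_per_kb", "elements_per_kb", "mean_divergence")
  units <- rep("count", length(fields))
  units[grepl("coverage", fields)] <- "fraction"
  units[grepl("presence", fields)] <- "flag"
  units[fields %in% c("max_gap", "mean_gap", "longest_repeat_free_stretch")] <- "nt"
  units[grepl("per_kb", fields)] <- "count/kb"
  units[fields == "mean_divergence"] <- "percent"
  units[fields == "mean_fragments_per_element"] <- "ratio"
  out <- data.frame(
    name = fields,
    level = ifelse(grepl("class|family", fields), "class", "transcript"),
    units = units,
    normalization = ifelse(grepl("per_kb", fields), "per_kilobase", "none"),
    stringsAsFactors = FALSE)
  attr(out, "version") <- "1.0"
  out
}

#' Compute the transcript-level repeat feature vector
#'
#' From resolved (non-overlapping) hits on one transcript: total hit and
#' element counts, total and per-class coverage fractions, per-class counts
#' and presence flags, per-family counts, fragmentation statistics,
#' inter-hit gap statistics (gaps between consecutive resolved spans), the
#' longest repeat-free stretch (flanks included), per-kb normalized counts
#' and mean divergence. Coverage uses the resolved spans, so
#' `sum(span lengths) = coverage * length` exactly.
#'
#' @param resolved data.frame of non-overlapping hits from
#'   [resolve_overlaps()] (a single transcript; may be empty).
#' @param transcript_length transcript length in nt (>= 1).
#' @return named numeric vector following [repeat_feature_schema()].
#' @export
compute_repeat_features <- function(resolved, transcript_length) {
  stopifnot(transcript_length >= 1)
  schema <- repeat_feature_schema()
  v <- stats::setNames(numeric(nrow(schema)), schema$name)
  v["longest_repeat_free_stretch"] <- transcript_length
  if (nrow(resolved) == 0) return(v)
  if (length(unique(resolved$query_id)) > 1) {
    stop("compute_repeat_features() expects hits from a single transcript")
  }
  if (any(resolved$begin < 1) || any(resolved$end > transcript_length)) {
    stop("element span outside [1, transcript_length]")
  }
  elements <- aggregate_elements(resolved)
  spans <- resolved[order(resolved$begin), c("begin", "end")]
  widths <- spans$end - spans$begin + 1
  gaps <- if (nrow(spans) > 1) spans$begin[-1] - spans$end[-nrow(spans)] - 1 else numeric(0)
  free <- c(spans$begin[1] - 1, gaps, transcript_length - spans$end[nrow(spans)])

  v["total_hit_count"] <- nrow(resolved)
  v["total_element_count"] <- nrow(elements)
  v["total_coverage_fraction"] <- sum(widths) / transcript_length
  cls_of <- function(x) ifelse(x %in% repeat_feature_classes(), x, "Other")
  hit_cls <- cls_of(resolved$repeat_class)
  for (cl in unique(hit_cls)) {
    sel <- hit_cls == cl
    v[paste0("count_class_", cl)] <- sum(sel)
    v[paste0("coverage_class_", cl)] <- sum(widths[sel]) / transcript_length
    v[paste0("presence_class_", cl)] <- 1
  }
  fam <- resolved$repeat_family
  for (f in intersect(unique(fam), repeat_feature_families())) {
    v[paste0("count_family_", f)] <- sum(fam == f)
  }
  v["mean_fragments_per_element"] <- mean(elements$n_fragments)
  v["max_fragments_per_element"] <- max(elements$n_fragments)
  v["max_gap"] <- if (length(gaps)) max(gaps) else 0
  v["mean_gap"] <- if (length(gaps)) mean(gaps) else 0
  v["longest_repeat_free_stretch"] <- max(free)
  v["hits_per_kb"] <- nrow(resolved) * 1000 / transcript_length
  v["elements_per_kb"] <- nrow(elements) * 1000 / transcript_length
  v["mean_divergence"] <- sum(resolved$pct_div * widths) / sum(widths)
  v
}

#' Repeat feature matrix for a set of transcripts
#'
#' Parses (if needed), splits hits by transcript, resolves overlaps per
#' transcript, and computes the schema-fixed feature vector for every id in
#' `lengths` (transcripts with no hits get the all-zero vector with a full
#' repeat-free stretch).
#'
#' @param hits data.frame of hits (multiple transcripts) or raw `.out`
#'   text/path.
#' @param lengths named numeric vector of transcript lengths.
#' @return data.frame, rows named by transcript id, columns per
#'   [repeat_feature_schema()].
#' @export
repeat_feature_matrix <- function(hits, lengths) {
  if (!is.data.frame(hits)) hits <- parse_repeatmasker_out(hits)
  by_tx <- split(hits, hits$query_id)
  schema <- repeat_feature_schema()
  out <- matrix(0, nrow = length(lengths), ncol = nrow(schema),
                dimnames = list(names(lengths), schema$name))
  for (id in names(lengths)) {
    h <- by_tx[[id]]
    resolved <- if (is.null(h)) hits[0, , drop = FALSE] else resolve_overlaps(h)
    out[id, ] <- compute_repeat_features(resolved, lengths[[id]])
  }
  as.data.frame(out)
}
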