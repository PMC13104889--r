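#' Read a transcript/biotype annotation table
#'
#' Accepts either a TSV with columns `transcript_id`, `biotype` (and
#' optionally `gene_id`, `length`) or a GTF file, from which the biotype is
#' taken from a transcript attribute (default `transcript_type`). Biotypes
#' are normalized to the three-way vocabulary `protein_coding` / `lncRNA` /
#' `other` through a user-extensible synonym map.
#'
#' @param path file path (`.gtf`/`.gff` triggers GTF parsing, anything else
#'   is read as TSV).
#' @param release_tag string recorded in the `release_tag` column.
#' @param attribute GTF attribute holding the biotype.
#' @param synonyms named character vector mapping raw biotype strings to the
#'   normalized vocabulary; unmapped values become `other`.
#' @return data.frame with `transcript_id`, `gene_id`, `biotype`, `length`,
#'   `release_tag`.
#' @export
read_annotation <- function(path, release_tag = basename(path),
                            attribute = "transcript_type",
                            synonyms = c(protein_coding = "protein_coding",
                                         lncRNA = "lncRNA",
                                         lincRNA = "lncRNA",
                                         antisense = "lncRNA")) {
  if (grepl("\\.g[tf]f[0-9]?(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("GTF input requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "transcript"]
    raw <- as.character(S4Vectors::mcols(gr)[[attribute]])
    df <- data.frame(
      transcript_id = gr$transcript_id,
      gene_id = gr$gene_id %||% NA_character_,
      biotype = raw,
      length = BiocGenerics::width(gr),
      stringsAsFactors = FALSE
    )
  } else {
    df <- as.data.frame(data.table::fread(path, sep = "\t"))
    if (!all(c("transcript_id", "biotype") %in% colnames(df))) {
      stop("annotation TSV must have 'transcript_id' and 'biotype' columns")
    }
    if (!"gene_id" %in% colnames(df)) df$gene_id <- NA_character_
    if (!"length" %in% colnames(df)) df$length <- NA_integer_
  }
  mapped <- unname(synonyms[df$biotype])
  df$biotype <- ifelse(is.na(mapped), "other", mapped)
  df$release_tag <- release_tag
  df[, c("transcript_id", "gene_id", "biotype", "length", "release_tag")]
}

#' Label-stable intersection of two annotation releases
#'
#' Returns the transcript ids present in both releases with the same
#' protein-coding or lncRNA biotype in both — the cross-release filter that
#' removes transcripts whose class annotation churned between releases
#' (transcripts classed `other` in either release are excluded too).
#'
#' @param rel_a,rel_b data.frames with `transcript_id` and `biotype`
#'   (e.g. from [read_annotation()]); transcript ids must be unique within
#'   each release.
#' @return character vector of label-stable transcript ids, in `rel_a`
#'   order.
#' @export
intersect_releases <- function(rel_a, rel_b) {
  for (nm in c("a", "b")) {
    rel <- if (nm == "a") rel_a else rel_b
    dup <- rel$transcript_id[duplicated(rel$transcript_id)]
    if (length(dup)) {
      stop(sprintf("duplicate transcript_id in release %s: %s", nm, dup[1]))
    }
  }
  keep <- c("protein_coding", "lncRNA")
  a <- rel_a[rel_a$biotype %in% keep, ]
  b <- rel_b[rel_b$biotype %in% keep, ]
  bt_b <- stats::setNames(b$biotype, b$transcript_id)
  a$transcript_id[a$transcript_id %in% b$transcript_id &
                    a$biotype == bt_b[a$transcript_id]]
}

#' Parse a CD-HIT .clstr file
#'
#' @param x character vector of lines, a single string with newlines, or a
#'   path to a `.clstr` file.
#' @return data.frame with `cluster` (0-based id), `id`, `length`
#'   (nucleotides as printed), `is_representative` (the `*` member).
#' @export
parse_clstr <- function(x) {
  lines <- clstr_lines(x)
  cluster <- -1L
  rows <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (line == "") next
    if (startsWith(line, ">")) {
      cl <- sub("^>Cluster\\s+(\\d+)\\s*$", "\\1", line)
      if (identical(cl, line)) stop("malformed .clstr header at line ", i)
      cluster <- as.integer(cl)
      next
    }
    m <- regmatches(line,
      regexec("^\\d+\\s+(\\d+)(?:nt|aa),\\s+>(.+?)\\.{3}\\s+(.*)$", line))[[1]]
    if (length(m) != 4 || cluster < 0) stop("malformed .clstr line at line ", i)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cluster, id = m[3], length = as.integer(m[2]),
      is_representative = m[4] == "*", stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(cluster = integer(), id = character(), length = integer(),
                      is_representative = logical()))
  }
  do.call(rbind, rows)
}

clstr_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else if (length(x) == 1 && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    x
  }
}

#' Select the longest sequence per cluster
#'
#' One representative per cluster: the longest member, with ties broken by
#' the lexicographically smallest id. Lengths come from the supplied table
#' (not the lengths printed in the .clstr file) so that selection uses the
#' authoritative annotation lengths.
#'
#' @param clstr parsed cluster table from [parse_clstr()] (or raw text/path,
#'   which is parsed first).
#' @param lengths named numeric vector, id to length; every clustered id
#'   must be present.
#' @return character vector of representative ids, one per cluster, ordered
#'   by cluster id.
#' @export
select_cluster_representatives <- function(clstr, lengths) {
  if (!is.data.frame(clstr)) clstr <- parse_clstr(clstr)
  missing <- setdiff(clstr$id, names(lengths))
  if (length(missing)) {
    stop("no length known for clustered id(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  vapply(split(clstr$id, clstr$cluster), function(members) {
    l <- lengths[members]
    sort(members[l == max(l)])[1]
  }, character(1), USE.NAMES = FALSE)
}

#' Balanced cross-validation fold construction
#'
#' Implements the class-imbalance-aware splitting scheme: both classes are
#' partitioned into `k` folds (after a seeded shuffle; remainders go to the
#' lowest-index folds). For fold `i`:
#' \itemize{
#'   \item training minority = the other `k - 1` minority partitions
#'     (the whole minority class minus the held-out partition);
#'   \item training majority = a seeded uniform sample without replacement,
#'     of the same size, drawn from majority transcripts outside fold `i`'s
#'     majority partition — so training is exactly class-balanced;
#'   \item test = held-out minority partition plus every majority transcript
#'     not used for training (the held-out majority partition and the
#'     unsampled remainder), preserving the class imbalance of the cohort;
#'   \item strict held-out set = the two partitions of fold `i`; each
#'     transcript belongs to exactly one fold's strict held-out set, which
#'     is where its out-of-fold prediction comes from.
#' }
#'
#' @param ids_by_class named list of two character vectors of transcript ids
#'   (names are the class labels); the minority class is the smaller one.
#' @param k number of folds (default 5; must be >= 2 and <= minority size).
#' @param seed integer seed for the shuffles and the majority sample.
#' @return list of `k` folds, each a list with `fold_index` (0-based),
#'   `train_ids_by_class`, `test_ids_by_class`, `heldout_ids_by_class`, `k`,
#'   `seed`.
#' @export
make_fold_splits <- function(ids_by_class, k = 5, seed = 1L) {
  stopifnot(is.list(ids_by_class), length(ids_by_class) == 2,
            !is.null(names(ids_by_class)))
  sizes <- lengths(ids_by_class)
  minority <- names(sizes)[which.min(sizes)]
  majority <- setdiff(names(sizes), minority)
  if (k < 2) stop("k must be >= 2: no held-out partition possible otherwise")
  if (k > sizes[[minority]]) stop("k exceeds the minority class size")
  partition <- function(ids) {
    n <- length(ids)
    base <- n %/% k
    extra <- n %% k
    fold_sizes <- base + as.integer(seq_len(k) <= extra)
    split(ids, rep(seq_len(k), fold_sizes))
  }
  with_seed(seed, {
    shuf_min <- sample(ids_by_class[[minority]])
    shuf_maj <- sample(ids_by_class[[majority]])
    part_min <- partition(shuf_min)
    part_maj <- partition(shuf_maj)
    lapply(seq_len(k), function(i) {
      train_min <- unlist(part_min[-i], use.names = FALSE)
      maj_pool <- setdiff(ids_by_class[[majority]], part_maj[[i]])
      if (length(train_min) > length(maj_pool)) {
        stop("not enough majority transcripts outside the held-out partition")
      }
      train_maj <- sample(maj_pool, length(train_min))
      test_maj <- setdiff(ids_by_class[[majority]], train_maj)
      fold <- list(
        fold_index = i - 1L,
        train_ids_by_class = stats::setNames(
          list(train_min, train_maj), c(minority, majority)),
        test_ids_by_class = stats::setNames(
          list(part_min[[i]], test_maj), c(minority, majority)),
        heldout_ids_by_class = stats::setNames(
          list(part_min[[i]], part_maj[[i]]), c(minority, majority)),
        k = as.integer(k), seed = as.integer(seed)
      )
      fold
    })
  })
}

#' Flatten fold splits to a manifest table
#'
#' @param folds output of [make_fold_splits()].
#' @return data.frame with `transcript_id`, `class`, `fold` (0-based),
#'   `role` (`train`, `test`, `heldout`); held-out transcripts also appear in
#'   their fold's test rows.
#' @export
fold_manifest <- function(folds) {
  rows <- lapply(folds, function(f) {
    mk <- function(lst, role) {
      do.call(rbind, lapply(names(lst), function(cl) {
        if (!length(lst[[cl]])) return(NULL)
        data.frame(transcript_id = lst[[cl]], class = cl,
                   fold = f$fold_index, role = role, stringsAsFactors = FALSE)
      }))
    }
    rbind(mk(f$train_ids_by_class, "train"),
          mk(f$test_ids_by_class, "test"),
          mk(f$heldout_ids_by_class, "heldout"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
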