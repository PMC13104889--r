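#' Configuration for the synthetic benchmark cohort
#'
#' Bundles and validates all knobs of the seeded cohort generator. The
#' generator emulates the statistical structure the downstream analysis
#' assumes: an M-tool classifier ensemble with tool-specific calibration and
#' a "boundary" subpopulation of near-zero-signal transcripts that drives
#' high predictive entropy; correlated continuous feature blocks with
#' class-dependent shifts; planted repeat and non-B DNA motif annotations
#' with recorded ground truth; and two annotation releases differing by a
#' label-churn fraction.
#'
#' @param n_coding,n_lnc class sizes (counts >= 1).
#' @param n_tools number of ensemble tools M (>= 2).
#' @param boundary_fraction fraction of transcripts drawn from the
#'   low-signal boundary subpopulation.
#' @param signal_scale latent signal scale kappa (> 0).
#' @param tool_gain per-tool gain lambda_m (> 0); default evenly spaced in
#'   `[0.8, 1.2]`.
#' @param tool_noise per-tool logit-scale noise s.d. sigma_m (>= 0);
#'   default 1.
#' @param n_feature_blocks number of correlated continuous feature blocks.
#' @param block_sizes features per block; default 4 each.
#' @param block_class_shift per-block class shift (latent mean is
#'   `shift_b * (2 c_t - 1)`); default graded shifts with one null block.
#' @param n_categorical number of binary categorical features.
#' @param categorical_rates matrix `n_categorical x 2` of Bernoulli rates
#'   (columns: coding, lncRNA).
#' @param churn_fraction per-transcript probability that the biotype label
#'   flips between the two emitted releases.
#' @param missing_fraction per-(transcript, tool) probability of a missing
#'   score (tools that cannot score a transcript).
#' @param repeat_rate_coding,repeat_rate_lnc probability that a transcript of
#'   each class carries at least one planted repeat (defaults 0.3 and 0.7,
#'   the presence rates reported for real protein-coding transcripts and
#'   lncRNAs).
#' @param seed master integer seed; every artifact derives its own stream
#'   from it, so identical configs give byte-identical outputs.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_coding = 600, n_lnc = 400, n_tools = 8,
                              boundary_fraction = 0.15, signal_scale = 4,
                              tool_gain = NULL, tool_noise = NULL,
                              n_feature_blocks = 5, block_sizes = NULL,
                              block_class_shift = NULL, n_categorical = 4,
                              categorical_rates = NULL,
                              churn_fraction = 0.05, missing_fraction = 0,
                              repeat_rate_coding = 0.3, repeat_rate_lnc = 0.7,
                              seed = 1L) {
  tool_gain <- tool_gain %||% seq(0.8, 1.2, length.out = n_tools)
  tool_noise <- tool_noise %||% rep(1, n_tools)
  block_sizes <- block_sizes %||% rep(4L, n_feature_blocks)
  block_class_shift <- block_class_shift %||%
    seq(0.8, 0, length.out = n_feature_blocks)
  categorical_rates <- categorical_rates %||%
    cbind(coding = rep(c(0.6, 0.3), length.out = n_categorical),
          lncRNA = rep(c(0.3, 0.6), length.out = n_categorical))
  cfg <- list(
    n_coding = as.integer(n_coding), n_lnc = as.integer(n_lnc),
    n_tools = as.integer(n_tools), boundary_fraction = boundary_fraction,
    signal_scale = signal_scale, tool_gain = tool_gain,
    tool_noise = tool_noise, n_feature_blocks = as.integer(n_feature_blocks),
    block_sizes = as.integer(block_sizes),
    block_class_shift = block_class_shift,
    n_categorical = as.integer(n_categorical),
    categorical_rates = categorical_rates,
    churn_fraction = churn_fraction, missing_fraction = missing_fraction,
    repeat_rate_coding = repeat_rate_coding, repeat_rate_lnc = repeat_rate_lnc,
    seed = as.integer(seed)
  )
  nums <- unlist(cfg[c("boundary_fraction", "signal_scale", "tool_gain",
                       "tool_noise", "block_class_shift", "churn_fraction",
                       "missing_fraction", "repeat_rate_coding",
                       "repeat_rate_lnc", "categorical_rates")])
  if (any(!is.finite(nums))) stop("non-finite simulation config value")
  stopifnot(
    cfg$n_coding >= 1, cfg$n_lnc >= 1, cfg$n_tools >= 2,
    cfg$boundary_fraction >= 0, cfg$boundary_fraction <= 1,
    cfg$signal_scale > 0,
    length(cfg$tool_gain) == cfg$n_tools, all(cfg$tool_gain > 0),
    length(cfg$tool_noise) == cfg$n_tools, all(cfg$tool_noise >= 0),
    length(cfg$block_sizes) == cfg$n_feature_blocks, all(cfg$block_sizes >= 1),
    length(cfg$block_class_shift) == cfg$n_feature_blocks,
    cfg$churn_fraction >= 0, cfg$churn_fraction <= 1,
    cfg$missing_fraction >= 0, cfg$missing_fraction <= 1,
    all(cfg$categorical_rates >= 0), all(cfg$categorical_rates <= 1),
    cfg$repeat_rate_coding >= 0, cfg$repeat_rate_coding <= 1,
    cfg$repeat_rate_lnc >= 0, cfg$repeat_rate_lnc <= 1
  )
  structure(cfg, class = "simulation_config")
}

sim_ids_labels <- function(config) {
  n <- config$n_coding + config$n_lnc
  ids <- sprintf("T%06d", seq_len(n))
  labels <- c(rep("coding", config$n_coding), rep("lncRNA", config$n_lnc))
  list(ids = ids, labels = labels)
}

#' Simulate per-tool coding probabilities and labels
#'
#' Each transcript carries a latent coding signal
#' `s_t = (2 c_t - 1) * kappa * u_t`, with `u_t ~ U(0.3, 1)` for core
#' transcripts and `u_t ~ U(0, 0.1)` for the boundary subpopulation (whose
#' near-zero signal produces near-0.5 ensemble means and hence high
#' predictive entropy). Tool m reports
#' `p_tm = logistic(lambda_m * s_t + eps)`, `eps ~ N(0, sigma_m^2)`, and a
#' label by the 0.5 cutoff. Optionally a fraction of (transcript, tool)
#' scores is set missing.
#'
#' @param config a [simulation_config()].
#' @return list of class `prediction_set`: `transcript_id`,
#'   `reference_label`, `p` (n x M matrix), `label` (n x M character
#'   matrix), `tool_threshold`, and `truth` (boundary ids, complete ids,
#'   latent signals).
#' @export
generate_predictions <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  il <- sim_ids_labels(config)
  n <- length(il$ids)
  m <- config$n_tools
  tools <- sprintf("tool%02d", seq_len(m))
  with_seed(stage_seed(config$seed, "predictions"), {
    n_boundary <- round(config$boundary_fraction * n)
    boundary <- sort(sample.int(n, n_boundary))
    u <- stats::runif(n, 0.3, 1)
    u[boundary] <- stats::runif(n_boundary, 0, 0.1)
    sgn <- ifelse(il$labels == "coding", 1, -1)
    s <- sgn * config$signal_scale * u
    p <- matrix(NA_real_, n, m, dimnames = list(il$ids, tools))
    for (j in seq_len(m)) {
      eps <- stats::rnorm(n, 0, config$tool_noise[j])
      p[, j] <- stats::plogis(config$tool_gain[j] * s + eps)
    }
    if (config$missing_fraction > 0) {
      miss <- matrix(stats::runif(n * m) < config$missing_fraction, n, m)
      p[miss] <- NA_real_
    }
    label <- matrix(ifelse(p >= 0.5, "coding", "lncRNA"), n, m,
                    dimnames = dimnames(p))
    structure(list(
      transcript_id = il$ids,
      reference_label = il$labels,
      p = p, label = label,
      tool_threshold = stats::setNames(rep(0.5, m), tools),
      truth = list(boundary_ids = il$ids[boundary],
                   complete_ids = il$ids[rowSums(is.na(p)) == 0],
                   latent_signal = stats::setNames(s, il$ids))
    ), class = "prediction_set")
  })
}

#' Simulate a transcript feature table with correlated blocks
#'
#' Continuous features come in redundant blocks: block b has one latent
#' variable `g_bt ~ N(shift_b * (2 c_t - 1), 1)` and every feature in the
#' block is `g_bt + N(0, 0.2)`, so features within a block are strongly
#' rank-correlated while blocks are independent — the structure that feature
#' clustering and representative selection are meant to collapse. Binary
#' categorical features are Bernoulli with class-specific rates.
#'
#' @param config a [simulation_config()].
#' @param labels optional reference labels (defaults to the config's).
#' @return list with `table` (a [feature_table()]) and `truth` (block
#'   membership, per-block shifts, categorical rates).
#' @export
generate_features <- function(config, labels = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  il <- sim_ids_labels(config)
  labels <- labels %||% il$labels
  n <- length(labels)
  sgn <- ifelse(labels == "coding", 1, -1)
  with_seed(stage_seed(config$seed, "features"), {
    cols <- list()
    block_of <- character(0)
    for (b in seq_len(config$n_feature_blocks)) {
      g <- stats::rnorm(n, config$block_class_shift[b] * sgn, 1)
      for (j in seq_len(config$block_sizes[b])) {
        nm <- sprintf("blk%02d_f%02d", b, j)
        cols[[nm]] <- g + stats::rnorm(n, 0, 0.2)
        block_of[nm] <- sprintf("blk%02d", b)
      }
    }
    cat_names <- character(0)
    for (j in seq_len(config$n_categorical)) {
      nm <- sprintf("cat%02d", j)
      rate <- ifelse(labels == "coding",
                     config$categorical_rates[j, 1],
                     config$categorical_rates[j, 2])
      cols[[nm]] <- ifelse(stats::runif(n) < rate, "present", "absent")
      cat_names <- c(cat_names, nm)
    }
    data <- data.frame(cols, row.names = il$ids[seq_len(n)], check.names = FALSE)
    meta <- data.frame(
      name = names(cols),
      kind = ifelse(names(cols) %in% cat_names, "categorical", "continuous"),
      source = "ml_tool",
      units = "",
      stringsAsFactors = FALSE
    )
    list(table = feature_table(data, meta),
         truth = list(block_of = block_of,
                      block_class_shift = stats::setNames(
                        config$block_class_shift,
                        sprintf("blk%02d", seq_len(config$n_feature_blocks))),
                      categorical_rates = config$categorical_rates))
  })
}

repeat_class_vocab <- function() {
  data.frame(
    class = c("LINE", "SINE", "LTR", "DNA", "Simple_repeat", "Low_complexity"),
    family = c("L1", "Alu", "ERVL", "hAT", "", ""),
    stringsAsFactors = FALSE
  )
}

motif_type_vocab <- function() {
  c("APR", "DR", "IR", "MR", "STR", "Z", "TRI", "G4")
}

# summary statistics of a set of non-overlapping planted spans; the ground
# truth the parser + feature extractor must reproduce
planted_repeat_truth <- function(begin, end, len) {
  o <- order(begin)
  begin <- begin[o]; end <- end[o]
  widths <- end - begin + 1
  gaps <- if (length(begin) > 1) begin[-1] - end[-length(end)] - 1 else numeric(0)
  free <- c(begin[1] - 1, gaps, len - end[length(end)])
  list(count = length(begin), coverage = sum(widths) / len,
       max_gap = if (length(gaps)) max(gaps) else 0,
       mean_gap = if (length(gaps)) mean(gaps) else 0,
       longest_free = max(free))
}

#' Simulate annotation artifacts: releases, clusters, repeats, motifs, FASTA
#'
#' Emits the textual inputs the cohort and feature-extraction stages parse,
#' together with a recorded ground truth for every planted annotation:
#' \itemize{
#'   \item two release tables where `churn_fraction` of transcripts flip
#'     biotype in release B;
#'   \item a CD-HIT-dialect `.clstr` grouping of near-duplicate ids;
#'   \item RepeatMasker-format hits: per transcript, presence is Bernoulli
#'     with the class rate, 1-3 non-overlapping elements, each written as one
#'     or two fragments sharing an element ID;
#'   \item non-B DNA motif calls (BED intervals on a synthetic chromosome)
#'     within per-gene bounds, overlaps permitted;
#'   \item random-sequence FASTA records of the drawn transcript lengths.
#' }
#'
#' @param config a [simulation_config()].
#' @param labels optional reference labels (defaults to the config's).
#' @param include_fasta generate sequences (set `FALSE` to skip the most
#'   expensive artifact when only coordinates are needed).
#' @return list with `release_a`, `release_b` (data.frames), `clstr_text`,
#'   `repeat_hits` (data.frame in RepeatMasker column layout), `repeat_text`,
#'   `motif_calls` (BED-style data.frame), `genes` (gene interval table),
#'   `lengths`, `fasta` (DNAStringSet or NULL), and `truth`.
#' @export
generate_annotations <- function(config, labels = NULL, include_fasta = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  il <- sim_ids_labels(config)
  labels <- labels %||% il$labels
  ids <- il$ids
  n <- length(ids)
  with_seed(stage_seed(config$seed, "annotations"), {
    # transcript lengths: lognormal around published class medians
    len <- integer(n)
    is_c <- labels == "coding"
    len[is_c] <- round(stats::rlnorm(sum(is_c), log(1620), 0.5))
    len[!is_c] <- round(stats::rlnorm(sum(!is_c), log(1028), 0.6))
    len <- pmin(pmax(len, 250L), 20000L)
    names(len) <- ids

    biotype <- ifelse(labels == "coding", "protein_coding", "lncRNA")
    gene_id <- sprintf("G%06d", seq_len(n))
    release_a <- data.frame(transcript_id = ids, gene_id = gene_id,
                            biotype = biotype, length = len,
                            release_tag = "relA", stringsAsFactors = FALSE)
    churned <- stats::runif(n) < config$churn_fraction
    biotype_b <- biotype
    biotype_b[churned] <- ifelse(biotype[churned] == "protein_coding",
                                 "lncRNA", "protein_coding")
    release_b <- data.frame(transcript_id = ids, gene_id = gene_id,
                            biotype = biotype_b, length = len,
                            release_tag = "relB", stringsAsFactors = FALSE)

    # clusters of near-duplicates: sizes 1-3, mostly singletons
    sizes <- sample(c(1L, 1L, 1L, 2L, 3L), ceiling(n / 1), replace = TRUE)
    sizes <- sizes[cumsum(sizes) <= n]
    if (sum(sizes) < n) sizes <- c(sizes, n - sum(sizes))
    perm <- sample(ids)
    cluster_of <- rep(seq_along(sizes), sizes)
    clusters <- split(perm, cluster_of)
    clstr_text <- format_clstr(clusters, len)
    expected_reps <- vapply(clusters, function(members) {
      l <- len[members]
      cand <- members[l == max(l)]
      sort(cand)[1]
    }, character(1))

    # planted repeats
    rate <- ifelse(is_c, config$repeat_rate_coding, config$repeat_rate_lnc)
    has_rep <- stats::runif(n) < rate
    vocab <- repeat_class_vocab()
    hit_rows <- list()
    repeat_truth <- list()
    elem_id <- 0L
    for (i in which(has_rep)) {
      L <- len[[i]]
      n_elem <- sample(1:3, 1)
      # place elements in disjoint thirds of the transcript
      slots <- floor(seq(1, L + 1, length.out = n_elem + 1))
      spans_b <- integer(0); spans_e <- integer(0)
      n_planted <- 0L
      for (e in seq_len(n_elem)) {
        lo <- slots[e]; hi <- slots[e + 1] - 1
        if (hi - lo < 40) next
        w <- sample(30:min(300, hi - lo - 5), 1)
        b <- sample(lo:(hi - w), 1)
        elem_id <- elem_id + 1L
        n_planted <- n_planted + 1L
        cls <- vocab[sample.int(nrow(vocab), 1), ]
        frag2 <- w > 120 && stats::runif(1) < 0.3
        if (frag2) {
          cut <- b + floor(w / 2)
          gap <- sample(5:15, 1)
          e2 <- min(b + w + gap, hi)
          frags <- list(c(b, cut), c(min(cut + gap + 1, e2 - 1), e2))
        } else {
          frags <- list(c(b, b + w))
        }
        for (fr in frags) {
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            sw_score = sample(300:3000, 1),
            pct_div = round(stats::runif(1, 0, 30), 1),
            pct_del = round(stats::runif(1, 0, 5), 1),
            pct_ins = round(stats::runif(1, 0, 5), 1),
            query_id = ids[i], begin = fr[1], end = fr[2],
            q_left = L - fr[2],
            strand = sample(c("+", "C"), 1),
            repeat_name = paste0(ifelse(cls$family == "", cls$class, cls$family),
                                 "-", elem_id),
            repeat_class = cls$class, repeat_family = cls$family,
            r_begin = 1, r_end = fr[2] - fr[1] + 1, r_left = 0,
            element_id = elem_id, overlap_marker = FALSE,
            stringsAsFactors = FALSE
          )
          spans_b <- c(spans_b, fr[1]); spans_e <- c(spans_e, fr[2])
        }
      }
      if (length(spans_b)) {
        tt <- planted_repeat_truth(spans_b, spans_e, L)
        tt$element_count <- n_planted
        repeat_truth[[ids[i]]] <- tt
      }
    }
    repeat_hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
      utils::head(data.frame(sw_score = integer(), query_id = character()), 0)

    # genes laid end to end on one synthetic chromosome; motifs within bounds
    glen <- pmax(len * 3L, 3000L)
    gstart <- cumsum(c(0, glen[-n] + 1000L))
    genes <- data.frame(gene_id = gene_id, chrom = "chr1",
                        start = gstart, end = gstart + glen,
                        transcript_id = ids, stringsAsFactors = FALSE)
    types <- motif_type_vocab()
    motif_rows <- list()
    motif_truth <- list()
    for (i in seq_len(n)) {
      k <- stats::rpois(1, 3)
      if (k == 0) {
        motif_truth[[gene_id[i]]] <- list(total_count = 0, diversity = 0,
                                          total_coverage = 0)
        next
      }
      ty <- sample(types, k, replace = TRUE)
      w <- sample(20:200, k, replace = TRUE)
      st <- gstart[i] + vapply(w, function(wi) sample.int(glen[i] - wi, 1), integer(1))
      motif_rows[[i]] <- data.frame(chrom = "chr1", start = st, end = st + w,
                                    motif_type = ty,
                                    score = round(stats::runif(k, 0, 100), 2),
                                    strand = sample(c("+", "-", "."), k, replace = TRUE),
                                    stringsAsFactors = FALSE)
      motif_truth[[gene_id[i]]] <- list(
        total_count = k,
        diversity = length(unique(ty)),
        total_coverage = sum(w) / glen[[i]],
        counts_by_type = as.list(table(factor(ty, levels = types)))
      )
    }
    motif_calls <- if (length(motif_rows)) do.call(rbind, motif_rows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 motif_type = character(), score = numeric(), strand = character())

    fasta <- NULL
    if (include_fasta) {
      seqs <- vapply(len, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
        character(1))
      fasta <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
    }

    list(
      release_a = release_a, release_b = release_b,
      clstr_text = clstr_text,
      repeat_hits = repeat_hits,
      repeat_text = format_repeatmasker_out(repeat_hits),
      motif_calls = motif_calls, genes = genes,
      lengths = len, fasta = fasta,
      truth = list(
        churned_ids = ids[churned],
        clusters = clusters,
        expected_representatives = unname(expected_reps),
        repeat_truth = repeat_truth,
        motif_truth = motif_truth
      )
    )
  })
}

#' Simulate a full synthetic cohort
#'
#' Runs all three generators under one master seed and returns their outputs
#' plus the pooled ground truth.
#'
#' @param config a [simulation_config()].
#' @param include_fasta passed to [generate_annotations()].
#' @return list of class `synthetic_cohort` with `config`, `predictions`,
#'   `features`, `annotations`, and `reference_labels`.
#' @export
simulate_cohort <- function(config = simulation_config(), include_fasta = TRUE) {
  il <- sim_ids_labels(config)
  structure(list(
    config = config,
    reference_labels = stats::setNames(il$labels, il$ids),
    predictions = generate_predictions(config),
    features = generate_features(config),
    annotations = generate_annotations(config, include_fasta = include_fasta)
  ), class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Serializes every artifact in its field-standard format: prediction and
#' feature TSVs (with a JSON schema sidecar), two release TSVs, CD-HIT
#' `.clstr`, RepeatMasker `.out`, motif BED, gene-interval BED, FASTA, and a
#' JSON ground-truth sidecar.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  w <- function(name) {
    paths[[name]] <<- file.path(dir, name)
    paths[[name]]
  }
  pr <- cohort$predictions
  pred_df <- data.frame(transcript_id = pr$transcript_id,
                        reference_label = pr$reference_label,
                        stats::setNames(as.data.frame(pr$p), paste0("p_", colnames(pr$p))),
                        stats::setNames(as.data.frame(pr$label), paste0("label_", colnames(pr$label))),
                        check.names = FALSE)
  data.table::fwrite(pred_df, w("predictions.tsv"), sep = "\t")
  ft <- cohort$features$table
  data.table::fwrite(cbind(transcript_id = rownames(ft$data), ft$data),
                     w("features.tsv"), sep = "\t")
  jsonlite::write_json(ft$meta, w("features.schema.json"), dataframe = "rows")
  an <- cohort$annotations
  data.table::fwrite(an$release_a, w("release_a.tsv"), sep = "\t")
  data.table::fwrite(an$release_b, w("release_b.tsv"), sep = "\t")
  writeLines(an$clstr_text, w("clusters.clstr"))
  writeLines(an$repeat_text, w("repeats.out"))
  data.table::fwrite(an$motif_calls, w("motifs.bed"), sep = "\t", col.names = FALSE)
  data.table::fwrite(an$genes[, c("chrom", "start", "end", "gene_id")],
                     w("genes.bed"), sep = "\t", col.names = FALSE)
  if (!is.null(an$fasta)) {
    Biostrings::writeXStringSet(an$fasta, w("transcripts.fa"))
  }
  jsonlite::write_json(
    list(churned_ids = an$truth$churned_ids,
         expected_representatives = an$truth$expected_representatives,
         boundary_ids = pr$truth$boundary_ids,
         repeat_truth = an$truth$repeat_truth,
         motif_truth = an$truth$motif_truth),
    w("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(unlist(paths))
}

# ---- format writers -------------------------------------------------------

#' Format repeat hits as RepeatMasker .out text
#'
#' Standard layout: two header lines, one blank line, then one
#' whitespace-separated 15-column row per hit (plus the optional trailing
#' `*` overlap marker). Query coordinates are 1-based inclusive.
#'
#' @param hits data.frame with the RepeatMasker columns used by
#'   [parse_repeatmasker_out()] (see [generate_annotations()]).
#' @return character vector of lines.
#' @export
format_repeatmasker_out <- function(hits) {
  header <- c(
    "   SW   perc perc perc  query      position in query           matching       repeat              position in repeat",
    "score   div. del. ins.  sequence   begin end          (left)   repeat         class/family      begin end    (left)     ID",
    ""
  )
  if (nrow(hits) == 0) return(header)
  cls <- ifelse(hits$repeat_family == "", hits$repeat_class,
                paste0(hits$repeat_class, "/", hits$repeat_family))
  body <- sprintf("%6d %5.1f %4.1f %4.1f  %s %8d %8d (%d) %s %s %s %6d %6d (%d) %6d%s",
                  hits$sw_score, hits$pct_div, hits$pct_del, hits$pct_ins,
                  hits$query_id, hits$begin, hits$end, hits$q_left,
                  hits$strand, hits$repeat_name, cls,
                  hits$r_begin, hits$r_end, hits$r_left, hits$element_id,
                  ifelse(hits$overlap_marker, " *", ""))
  c(header, body)
}

#' Format clusters as CD-HIT .clstr text
#'
#' @param clusters list of character vectors of member ids; the first member
#'   of each cluster is written as the CD-HIT representative.
#' @param lengths named integer vector of sequence lengths.
#' @return character vector of lines.
#' @export
format_clstr <- function(clusters, lengths) {
  out <- character(0)
  for (ci in seq_along(clusters)) {
    out <- c(out, sprintf(">Cluster %d", ci - 1))
    members <- clusters[[ci]]
    for (mi in seq_along(members)) {
      id <- members[mi]
      tail <- if (mi == 1) "*" else
        sprintf("at +/%.2f%%", 90 + (mi %% 10))
      out <- c(out, sprintf("%d\t%dnt, >%s... %s", mi - 1, lengths[[id]], id, tail))
    }
  }
  out
}
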