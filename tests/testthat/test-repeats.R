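test_that("RepeatMasker parsing handles the standard layout and format rules", {
  hits <- make_hits("tx1", begin = c(100, 400), end = c(200, 500),
                    sw_score = c(500, 300))
  txt <- format_repeatmasker_out(hits)
  parsed <- parse_repeatmasker_out(txt)
  expect_equal(nrow(parsed), 2)
  expect_equal(parsed$begin, c(100L, 400L))
  expect_equal(parsed$end, c(200L, 500L))
  expect_equal(parsed$sw_score, c(500L, 300L))
  # class/family split on "/"
  expect_identical(parsed$repeat_class, c("LINE", "LINE"))
  expect_identical(parsed$repeat_family, c("L1", "L1"))
  simple <- make_hits("tx1", 10, 60, 400, repeat_class = "Simple_repeat",
                      repeat_family = "")
  expect_identical(parse_repeatmasker_out(format_repeatmasker_out(simple))$repeat_family, "")
  # empty body -> empty hit list
  expect_equal(nrow(parse_repeatmasker_out(format_repeatmasker_out(hits[0, ]))), 0)
  # wrong column count -> parse error naming the line
  bad <- c(format_repeatmasker_out(hits), "500 1.0 1.0 1.0 tx1 10")
  expect_error(parse_repeatmasker_out(bad), "line 3")
  # trailing '*' overlap marker is captured
  hits$overlap_marker <- c(FALSE, TRUE)
  expect_identical(parse_repeatmasker_out(format_repeatmasker_out(hits))$overlap_marker,
                   c(FALSE, TRUE))
})

test_that("overlap resolution trims, drops, and leaves disjoint hits untouched", {
  # partial overlap: lower-scoring hit trimmed to its uncovered remainder
  h <- make_hits("tx1", begin = c(100, 250), end = c(300, 400),
                 sw_score = c(500, 300))
  res <- resolve_overlaps(h)
  expect_equal(res$begin, c(100L, 301L))
  expect_equal(res$end, c(300L, 400L))
  # full containment with lower score: dropped
  h <- make_hits("tx1", begin = c(100, 150), end = c(300, 200),
                 sw_score = c(500, 300))
  res <- resolve_overlaps(h)
  expect_equal(nrow(res), 1)
  expect_equal(res$begin, 100L)
  # no overlaps: input returned sorted by begin
  h <- make_hits("tx1", begin = c(400, 100), end = c(500, 200),
                 sw_score = c(300, 500))
  res <- resolve_overlaps(h)
  expect_equal(res$begin, c(100L, 400L))
  expect_equal(nrow(res), 2)
  # trimming keeps the largest single uncovered segment
  h <- make_hits("tx1", begin = c(200, 100), end = c(260, 400),
                 sw_score = c(900, 500))
  res <- resolve_overlaps(h)  # low hit split by [200,260]: [100,199] vs [261,400]
  low <- res[res$sw_score == 500, ]
  expect_equal(c(low$begin, low$end), c(261L, 400L))
})

test_that("overlap resolution is idempotent and overlap-free on random inputs", {
  set.seed(13)
  for (r in 1:25) {
    n <- sample(2:12, 1)
    b <- sample(1:900, n, replace = TRUE)
    w <- sample(20:150, n, replace = TRUE)
    h <- make_hits("tx1", begin = b, end = pmin(b + w, 1000),
                   sw_score = sample(100:2000, n),
                   element_id = seq_len(n))
    res <- resolve_overlaps(h)
    # pairwise overlap is zero
    if (nrow(res) > 1) {
      expect_true(all(res$begin[-1] > res$end[-nrow(res)]))
    }
    # idempotence
    res2 <- resolve_overlaps(res)
    expect_equal(res2$begin, res$begin)
    expect_equal(res2$end, res$end)
  }
})

test_that("fragments sharing an element ID aggregate into one element", {
  h <- make_hits("tx1", begin = c(100, 200), end = c(179, 319),
                 sw_score = c(700, 600), element_id = c(7, 7))
  el <- aggregate_elements(h)
  expect_equal(nrow(el), 1)
  expect_equal(el$length, 80 + 120)
  expect_equal(el$n_fragments, 2)
  expect_equal(el$sw_score, 700)
  # one fragment: element equals hit
  single <- aggregate_elements(make_hits("tx1", 10, 50, 300))
  expect_equal(single$length, 41)
  expect_equal(single$n_fragments, 1)
  # distinct ids stay distinct
  two <- aggregate_elements(make_hits("tx1", c(10, 500), c(50, 600),
                                      c(300, 400), element_id = c(1, 2)))
  expect_equal(nrow(two), 2)
  # conflicting class within an element: warning, highest-scoring kept
  hx <- make_hits("tx1", c(10, 100), c(50, 150), c(800, 200),
                  element_id = c(3, 3))
  hx$repeat_class <- c("LINE", "SINE")
  expect_warning(el <- aggregate_elements(hx), "conflicting")
  expect_identical(el$repeat_class, "LINE")
})

test_that("repeat feature vectors match hand computations", {
  h <- make_hits("tx1", begin = c(101, 301), end = c(200, 400),
                 sw_score = c(500, 400), element_id = c(1, 2))
  v <- compute_repeat_features(resolve_overlaps(h), 1000)
  expect_equal(unname(v["total_hit_count"]), 2)
  expect_equal(unname(v["total_element_count"]), 2)
  expect_equal(unname(v["total_coverage_fraction"]), 0.2)
  expect_equal(unname(v["max_gap"]), 100)
  expect_equal(unname(v["longest_repeat_free_stretch"]), 600)
  expect_equal(unname(v["hits_per_kb"]), 2)
  expect_equal(unname(v["count_class_LINE"]), 2)
  expect_equal(unname(v["presence_class_LINE"]), 1)
  # coverage identity: sum of resolved span lengths = coverage * length
  expect_equal(sum(h$end - h$begin + 1), unname(v["total_coverage_fraction"]) * 1000)
  # no repeats
  v0 <- compute_repeat_features(h[0, ], 750)
  expect_equal(unname(v0["total_coverage_fraction"]), 0)
  expect_equal(unname(v0["longest_repeat_free_stretch"]), 750)
  expect_true(all(v0[grep("presence", names(v0))] == 0))
  # span outside the transcript is an error
  expect_error(compute_repeat_features(make_hits("tx1", 900, 1100, 300), 1000),
               "outside")
  # schema-fixed order
  expect_identical(names(v), repeat_feature_schema()$name)
})

test_that("planted synthetic repeats round-trip exactly through parser and features", {
  cfg <- simulation_config(n_coding = 150, n_lnc = 150, seed = 47)
  an <- generate_annotations(cfg, include_fasta = FALSE)
  parsed <- parse_repeatmasker_out(an$repeat_text)
  feats <- repeat_feature_matrix(parsed, an$lengths)
  truth <- an$truth$repeat_truth
  expect_gt(length(truth), 0)
  for (id in names(truth)) {
    tt <- truth[[id]]
    expect_equal(unname(feats[id, "total_hit_count"]), tt$count)
    expect_equal(unname(feats[id, "total_element_count"]), tt$element_count)
    expect_equal(unname(feats[id, "total_coverage_fraction"]), tt$coverage)
    expect_equal(unname(feats[id, "max_gap"]), tt$max_gap)
    expect_equal(unname(feats[id, "longest_repeat_free_stretch"]), tt$longest_free)
  }
  # transcripts without planted repeats have zero coverage
  none <- setdiff(names(an$lengths), names(truth))
  expect_true(all(feats[none, "total_coverage_fraction"] == 0))
})

test_that("class-specific repeat presence rates are recovered at scale", {
  # planted presence: ~70% of lncRNAs vs ~30% of coding transcripts
  cfg <- simulation_config(n_coding = 5000, n_lnc = 5000, seed = 29)
  an <- generate_annotations(cfg, include_fasta = FALSE)
  feats <- repeat_feature_matrix(an$repeat_hits, an$lengths)
  labels <- sim_labels(cfg)
  present <- feats$total_hit_count > 0
  expect_equal(mean(present[labels == "lncRNA"]), 0.7, tolerance = 0.03)
  expect_equal(mean(present[labels == "coding"]), 0.3, tolerance = 0.07)
})
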