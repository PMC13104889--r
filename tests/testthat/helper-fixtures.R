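# Small shared fixtures built in code.

tiny_config <- function(seed = 1L, ...) {
  simulation_config(n_coding = 60, n_lnc = 40, seed = seed, ...)
}

# hits table in the parse_repeatmasker_out() column layout
make_hits <- function(query_id, begin, end, sw_score,
                      repeat_class = "LINE", repeat_family = "L1",
                      element_id = seq_along(begin), pct_div = 10) {
  n <- length(begin)
  data.frame(
    sw_score = as.integer(sw_score), pct_div = rep_len(pct_div, n),
    pct_del = 1, pct_ins = 1,
    query_id = rep_len(query_id, n),
    begin = as.integer(begin), end = as.integer(end),
    q_left = 0L, strand = "+",
    repeat_name = paste0("rep", seq_len(n)),
    repeat_class = rep_len(repeat_class, n),
    repeat_family = rep_len(repeat_family, n),
    r_begin = 1L, r_end = as.integer(end - begin + 1L), r_left = 0L,
    element_id = as.integer(element_id),
    overlap_marker = FALSE, stringsAsFactors = FALSE)
}

sim_labels <- function(cfg) {
  c(rep("coding", cfg$n_coding), rep("lncRNA", cfg$n_lnc))
}

motif_vocab_fixture <- function() {
  c("APR", "DR", "IR", "MR", "STR", "Z", "TRI", "G4")
}

with_seed_fixture <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
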