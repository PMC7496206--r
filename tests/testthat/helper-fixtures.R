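# shared fixture builders and independent oracles

# build a one-row wide evidence table from a hit list, bypassing
# merge_evidence so tests of the predicate do not depend on the merger
make_evidence <- function(mirna = "m1", gene = "g1", strong = FALSE,
                          weak = FALSE, hits = list()) {
  tools <- c("miranda", "pita", "targetscan", "rnahybrid")
  out <- data.frame(mirna = mirna, gene = gene,
                    experimental_strong = strong, experimental_weak = weak,
                    stringsAsFactors = FALSE)
  for (tool in tools) {
    h <- hits[[tool]]
    out[[paste0(tool, "_score")]] <- if (is.null(h)) NA_real_ else h[[1]]
    out[[paste0(tool, "_mfe")]] <- if (is.null(h)) NA_real_ else h[[2]]
  }
  out
}

# naive independent re-statement of the consensus rule, working directly on
# a hit list rather than the wide table
oracle_consensus <- function(hits, min_tools = 3, min_miranda_score = 140,
                             mfe_cutoff = -10) {
  if (length(hits) < min_tools) return(FALSE)
  mfes <- vapply(hits, function(h) h[[2]], 0)
  if (!any(mfes <= mfe_cutoff)) return(FALSE)
  if ("miranda" %in% names(hits) &&
      hits$miranda[[1]] < min_miranda_score) return(FALSE)
  TRUE
}

# naive per-row differential call used as an oracle
oracle_call <- function(s, r, up_fc, down_fc, min_ab, inclusive = TRUE) {
  if (s < min_ab && r < min_ab) return("filtered")
  fc <- if (r == 0) (if (s > 0) Inf else 1) else s / r
  if (inclusive) {
    if (fc >= up_fc) return("up")
    if (fc <= down_fc) return("down")
  } else {
    if (fc > up_fc) return("up")
    if (fc < down_fc) return("down")
  }
  "nc"
}

# exhaustive upper-tail hypergeometric by direct combinatorial enumeration
oracle_hypergeom <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# tiny hand-checkable edge fixture
star_edges <- function(n_targets, mirna = "mirA", condition = "high",
                       direction = "down") {
  data.frame(
    mirna = mirna, gene = sprintf("g%02d", seq_len(n_targets)),
    condition = condition, mirna_direction = direction, level = 3L,
    mirna_profile = "HD", gene_profile = "HI", stringsAsFactors = FALSE
  )
}
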