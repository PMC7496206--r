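#' miRNA-target interaction evidence
#'
#' Candidate miRNA-target interactions (MTIs) carry two classes of evidence:
#' experimental flags (strong: luciferase reporter assay / Western blot;
#' weak: CLIP-seq class) and computational prediction hits from up to four
#' tools (miRanda, PITA, TargetScan, RNAhybrid). Predicted-only candidates
#' must pass a consensus rule - at least three supporting tools, a duplex
#' minimum free energy at or below -10 kcal/mol, and a miRanda score of at
#' least 140 when miRanda is among the supporting tools. Candidates resolve
#' to evidence levels: 1 (strong experimental), 2 (weak experimental),
#' 3 (consensus prediction); level 4 is reserved for Ago2 IP-seq support
#' (see [promote_level4()]).
#'
#' @name mti
NULL

MTI_TOOLS <- c("miranda", "pita", "targetscan", "rnahybrid")

empty_evidence <- function() {
  cols <- c("mirna", "gene", "experimental_strong", "experimental_weak",
            paste0(rep(MTI_TOOLS, each = 2), c("_score", "_mfe")))
  out <- data.frame(mirna = character(), gene = character(),
                    experimental_strong = logical(),
                    experimental_weak = logical(),
                    stringsAsFactors = FALSE)
  for (tool in MTI_TOOLS) {
    out[[paste0(tool, "_score")]] <- numeric()
    out[[paste0(tool, "_mfe")]] <- numeric()
  }
  out[, cols]
}

#' Merge experimental and prediction fragments into one evidence table
#'
#' Merging is keyed on (mirna, gene). Experimental flags are OR-combined
#' (evidence is never downgraded by a duplicate row); duplicate hits from the
#' same tool keep the best one - lowest minimum free energy, ties broken by
#' highest score. The result is sorted by (mirna, gene), so merging is
#' order-independent.
#'
#' @param experimental Data frame `mirna`, `gene`, `evidence_class`
#'   (`strong`/`weak`), e.g. from [load_experimental()]; may be `NULL`.
#' @param predictions Data frame `mirna`, `gene`, `tool`, `score`, `mfe`,
#'   e.g. from [load_predictions()]; may be `NULL`.
#'
#' @return One row per candidate pair with logical experimental flags and,
#'   per tool, `<tool>_score` / `<tool>_mfe` columns (`NA` when the tool has
#'   no hit for the pair).
#' @export
merge_evidence <- function(experimental = NULL, predictions = NULL) {
  keys <- character()
  if (!is.null(experimental) && nrow(experimental))
    keys <- c(keys, paste(experimental$mirna, experimental$gene, sep = "\r"))
  if (!is.null(predictions) && nrow(predictions))
    keys <- c(keys, paste(predictions$mirna, predictions$gene, sep = "\r"))
  keys <- sort(unique(keys))
  if (!length(keys)) return(empty_evidence())
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(mirna = parts[, 1L], gene = parts[, 2L],
                    experimental_strong = FALSE, experimental_weak = FALSE,
                    stringsAsFactors = FALSE)
  for (tool in MTI_TOOLS) {
    out[[paste0(tool, "_score")]] <- NA_real_
    out[[paste0(tool, "_mfe")]] <- NA_real_
  }
  if (!is.null(experimental) && nrow(experimental)) {
    ek <- paste(experimental$mirna, experimental$gene, sep = "\r")
    idx <- match(ek, keys)
    strong <- experimental$evidence_class == "strong"
    out$experimental_strong[idx[strong]] <- TRUE
    out$experimental_weak[idx[!strong]] <- TRUE
  }
  if (!is.null(predictions) && nrow(predictions)) {
    bad_tool <- !predictions$tool %in% MTI_TOOLS
    if (any(bad_tool))
      stop("unknown prediction tool: ",
           paste(unique(predictions$tool[bad_tool]), collapse = ", "),
           call. = FALSE)
    # best-hit dedup: lowest mfe first, then highest score
    ord <- order(predictions$mfe, -predictions$score)
    predictions <- predictions[ord, ]
    dup <- duplicated(predictions[, c("mirna", "gene", "tool")])
    predictions <- predictions[!dup, ]
    idx <- match(paste(predictions$mirna, predictions$gene, sep = "\r"), keys)
    for (tool in MTI_TOOLS) {
      sel <- predictions$tool == tool
      out[[paste0(tool, "_score")]][idx[sel]] <- predictions$score[sel]
      out[[paste0(tool, "_mfe")]][idx[sel]] <- predictions$mfe[sel]
    }
  }
  rownames(out) <- NULL
  out
}

evidence_n_tools <- function(evidence) {
  hits <- !is.na(as.matrix(evidence[, paste0(MTI_TOOLS, "_score")]))
  rowSums(hits)
}

evidence_best_mfe <- function(evidence) {
  mfe <- as.matrix(evidence[, paste0(MTI_TOOLS, "_mfe")])
  out <- suppressWarnings(apply(mfe, 1L, min, na.rm = TRUE))
  out[!is.finite(out)] <- NA_real_
  out
}

#' Consensus acceptance of predicted MTIs
#'
#' A candidate passes the consensus rule when (a) at least `min_tools` tools
#' predict it, (b) the minimum free energy constraint holds - by default at
#' least one supporting hit has `mfe <= mfe_cutoff`; with `mfe_all_hits` every
#' hit must - and (c) if a miRanda hit supports the pair its score is at
#' least `min_miranda_score`. The score constraint binds only when miRanda is
#' among the supporting tools (three other tools can satisfy the rule without
#' it) unless `require_miranda` is set.
#'
#' @param evidence Evidence table from [merge_evidence()] (vectorised over
#'   rows).
#' @param min_tools Minimum number of supporting tools (default 3).
#' @param min_miranda_score Minimum miRanda alignment score (default 140).
#' @param mfe_cutoff Duplex minimum free energy ceiling in kcal/mol
#'   (default -10; more negative duplexes are more stable).
#' @param require_miranda Require a miRanda hit to be present.
#' @param mfe_all_hits Require every supporting hit, not just one, to meet
#'   the free-energy cutoff.
#'
#' @return Logical vector, one flag per row.
#' @export
consensus_accept <- function(evidence, min_tools = 3,
                             min_miranda_score = 140, mfe_cutoff = -10,
                             require_miranda = FALSE, mfe_all_hits = FALSE) {
  if (nrow(evidence) == 0L) return(logical())
  n_tools <- evidence_n_tools(evidence)
  mfe <- as.matrix(evidence[, paste0(MTI_TOOLS, "_mfe")])
  mfe_pass_any <- rowSums(mfe <= mfe_cutoff, na.rm = TRUE) > 0
  mfe_pass_all <- rowSums(mfe > mfe_cutoff, na.rm = TRUE) == 0 & n_tools > 0
  mfe_ok <- if (mfe_all_hits) mfe_pass_all else mfe_pass_any
  has_miranda <- !is.na(evidence$miranda_score)
  miranda_ok <- !has_miranda | evidence$miranda_score >= min_miranda_score
  if (require_miranda) miranda_ok <- miranda_ok & has_miranda
  n_tools >= min_tools & mfe_ok & miranda_ok
}

#' Resolve candidates to evidence levels
#'
#' Level precedence follows evidence strength: 1 (strong experimental) over
#' 2 (weak experimental) over 3 (consensus prediction). Candidates with no
#' qualifying evidence get `NA` and are discarded from networks.
#'
#' @param evidence Evidence table from [merge_evidence()].
#' @param ... Consensus rule settings passed to [consensus_accept()].
#'
#' @return Integer vector of levels (1, 2, 3, or `NA`).
#' @export
evidence_level <- function(evidence, ...) {
  if (nrow(evidence) == 0L) return(integer())
  level <- rep(NA_integer_, nrow(evidence))
  level[consensus_accept(evidence, ...)] <- 3L
  level[evidence$experimental_weak] <- 2L
  level[evidence$experimental_strong] <- 1L
  level
}

#' Summarise an evidence table with resolved levels
#'
#' @param evidence Evidence table from [merge_evidence()].
#' @param drop_unresolved Drop candidates that resolve to no level.
#' @param ... Passed to [consensus_accept()].
#' @return Data frame `mirna`, `gene`, `level`, `n_tools`, `best_mfe`,
#'   `miranda_score`.
#' @export
resolve_evidence <- function(evidence, drop_unresolved = TRUE, ...) {
  out <- data.frame(
    mirna = evidence$mirna,
    gene = evidence$gene,
    level = evidence_level(evidence, ...),
    n_tools = evidence_n_tools(evidence),
    best_mfe = evidence_best_mfe(evidence),
    miranda_score = evidence$miranda_score,
    stringsAsFactors = FALSE
  )
  if (drop_unresolved) out <- out[!is.na(out$level), , drop = FALSE]
  rownames(out) <- NULL
  out
}
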