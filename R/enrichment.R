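#' Functional over-representation analysis
#'
#' Gene-set enrichment on network gene sets is an exact upper-tail
#' hypergeometric test (the standard over-representation statistic), with
#' Benjamini-Hochberg correction by default. Raw p-values are always
#' reported alongside adjusted ones. G/O/E/C keyword tagging carves the
#' network into functional sub-networks.
#'
#' @name enrichment
NULL

#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) where X ~ Hypergeometric(N, K, n): drawing `n` genes from a
#' background of `N` of which `K` carry the term, the probability of seeing
#' `k` or more carriers.
#'
#' @param k Carriers observed in the query.
#' @param K Term size in the background.
#' @param n Query size.
#' @param N Background size.
#' @return p-value in (0, 1].
#' @export
hypergeom_test <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 1 | k > pmin(K, n) | K > N | n > N
  if (any(bad))
    stop("hypergeometric bounds violated (need k <= min(K, n), K <= N, ",
         "n <= N)", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation test of a query gene set against term sets
#'
#' Terms are tested only when they intersect the query (`k >= 1`); results
#' are ranked by raw p ascending (ties by term id) and truncated to the top
#' `top` rows.
#'
#' @param query Character gene ids (must be a subset of `background`).
#' @param term_sets Named list of character vectors (e.g. from
#'   [read_gmt()]); genes outside the background are ignored.
#' @param background Character background universe (typically the
#'   filter-passing expressed genes).
#' @param correction `"bh"` (Benjamini-Hochberg, default) or
#'   `"bonferroni"`; applied over all tested terms before truncation.
#' @param top Rows to keep after ranking (default 20; `Inf` for all).
#' @return Data frame `term`, `k`, `K`, `n`, `N`, `p_value`, `adjusted_p`.
#' @export
enrich <- function(query, term_sets, background,
                   correction = c("bh", "bonferroni"), top = 20) {
  correction <- match.arg(correction)
  background <- unique(background)
  if (!length(background)) stop("empty background", call. = FALSE)
  query <- unique(query)
  if (!all(query %in% background))
    stop("query must be a subset of the background", call. = FALSE)
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(term_sets), function(term) {
    members <- intersect(unique(term_sets[[term]]), background)
    K <- length(members)
    k <- length(intersect(members, query))
    if (k < 1L) return(NULL)
    data.frame(term = term, k = k, K = K, n = n, N = N,
               p_value = hypergeom_test(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      adjusted_p = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  method <- if (correction == "bh") "BH" else "bonferroni"
  out$adjusted_p <- stats::p.adjust(out$p_value, method = method)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  if (is.finite(top)) out <- utils::head(out, top)
  rownames(out) <- NULL
  out
}

#' Keyword-filtered sub-networks
#'
#' Retains an edge in category c in {G, O, E, C} iff its target gene carries
#' that keyword; a gene tagged with several keywords contributes its edges
#' to each corresponding sub-network. Untagged genes appear only in the
#' unfiltered network.
#'
#' @param edges MTI edge data frame.
#' @param annotations Annotation data frame (`gene`, `categories`, `terms`),
#'   e.g. from [generate_annotations()] or [read_annotations()].
#' @return Named list `G`, `O`, `E`, `C` of edge data frames.
#' @export
keyword_networks <- function(edges, annotations) {
  cats <- annotation_categories(annotations)
  out <- lapply(c(G = "G", O = "O", E = "E", C = "C"), function(cat) {
    tagged <- names(cats)[vapply(cats, function(v) cat %in% v, TRUE)]
    sub <- edges[edges$gene %in% tagged, , drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
  out
}
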