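#' Fold-change and differential-expression calling
#'
#' Differential expression between glucose conditions is called on fold
#' changes alone: each condition was sequenced as a single library, so there
#' is no replicate variance to model. Entities below an abundance floor in
#' both compared samples are filtered before any fold-change verdict.
#'
#' @name diffexpr
NULL

#' Construct a fold-change threshold set
#'
#' @param up_fc Fold change at or above which an entity is called up
#'   (must be > 1).
#' @param down_fc Fold change at or below which an entity is called down
#'   (must be in (0, 1)).
#' @param min_abundance Abundance floor: entities strictly below this value in
#'   both compared samples are filtered (FPKM for genes, RPM for miRNAs).
#' @param inclusive If `TRUE` (default) the up/down bounds are inclusive
#'   (fold change exactly equal to the bound is called).
#'
#' @return A `glucomir_thresholds` list.
#' @export
thresholds <- function(up_fc, down_fc, min_abundance = 10, inclusive = TRUE) {
  stopifnot(is.numeric(up_fc), length(up_fc) == 1L,
            is.numeric(down_fc), length(down_fc) == 1L,
            is.numeric(min_abundance), length(min_abundance) == 1L)
  if (!(down_fc > 0 && down_fc < 1 && up_fc > 1))
    stop("thresholds require down_fc in (0, 1) and up_fc > 1", call. = FALSE)
  if (min_abundance < 0)
    stop("min_abundance must be non-negative", call. = FALSE)
  structure(
    list(up_fc = up_fc, down_fc = down_fc,
         min_abundance = min_abundance, inclusive = isTRUE(inclusive)),
    class = "glucomir_thresholds"
  )
}

#' Default gene (mRNA) thresholds
#'
#' The shipped default is the differentially-expressed-gene definition used
#' for network construction: fold change >= 1.5 up, <= 0.67 down, FPKM floor
#' 10. A stricter quantification-level preset (1.2/0.83) is also available.
#'
#' @param preset `"network"` (1.5/0.67, default) or `"methods"` (1.2/0.83).
#' @return A `glucomir_thresholds` list.
#' @export
gene_thresholds <- function(preset = c("network", "methods")) {
  preset <- match.arg(preset)
  switch(preset,
    network = thresholds(1.5, 0.67, min_abundance = 10),
    methods = thresholds(1.2, 0.83, min_abundance = 10)
  )
}

#' Default miRNA thresholds
#'
#' Fold change >= 1.4 up, <= 0.71 down, RPM floor 10, inclusive bounds.
#'
#' @return A `glucomir_thresholds` list.
#' @export
mirna_thresholds <- function() {
  thresholds(1.4, 0.71, min_abundance = 10)
}

#' Fold change with explicit zero handling
#'
#' Computes `(sample + pseudocount) / (reference + pseudocount)`. With a zero
#' pseudocount and a zero reference the result is `Inf` when the sample is
#' positive and 1 when both are zero (no change observed). Vectorised.
#'
#' @param sample_value,reference_value Non-negative abundances.
#' @param pseudocount Non-negative value added to both terms (default 0).
#'
#' @return Numeric vector of fold changes (sample relative to reference).
#' @export
fold_change <- function(sample_value, reference_value, pseudocount = 0) {
  if (any(sample_value < 0, na.rm = TRUE) ||
      any(reference_value < 0, na.rm = TRUE) || pseudocount < 0)
    stop("abundances and pseudocount must be non-negative", call. = FALSE)
  s <- sample_value + pseudocount
  r <- reference_value + pseudocount
  fc <- s / r
  zero_ref <- r == 0
  fc[zero_ref & s > 0] <- Inf
  fc[zero_ref & s == 0] <- 1
  fc
}

comparison_columns <- function(comparison) {
  switch(comparison,
    low_vs_mod  = c(sample = "low",  reference = "moderate"),
    high_vs_mod = c(sample = "high", reference = "moderate"),
    stop("unknown comparison: ", comparison, call. = FALSE)
  )
}

#' Call differential expression for one comparison
#'
#' One verdict per entity: `filtered` when abundance is strictly below
#' `min_abundance` in both compared samples (an entity exactly at the floor is
#' retained), otherwise `up`/`down`/`nc` by fold change against the
#' thresholds. The filter is applied per comparison, so an entity can be
#' filtered in one comparison yet called in the other.
#'
#' @param matrix An expression matrix data frame (see [expression_matrix()]).
#' @param thresholds A `glucomir_thresholds` object.
#' @param comparison `"low_vs_mod"` or `"high_vs_mod"`.
#' @param pseudocount Passed to [fold_change()].
#'
#' @return A data frame with columns `entity`, `comparison`, `fold_change`,
#'   `log2_fc`, `verdict`, in input entity order.
#' @export
call_differential <- function(matrix, thresholds, comparison,
                              pseudocount = 0) {
  stopifnot(inherits(thresholds, "glucomir_thresholds"))
  matrix <- validate_expression(matrix)
  cols <- comparison_columns(comparison)
  s <- matrix[[cols[["sample"]]]]
  r <- matrix[[cols[["reference"]]]]
  fc <- fold_change(s, r, pseudocount)
  filtered <- s < thresholds$min_abundance & r < thresholds$min_abundance
  if (thresholds$inclusive) {
    up <- fc >= thresholds$up_fc
    down <- fc <= thresholds$down_fc
  } else {
    up <- fc > thresholds$up_fc
    down <- fc < thresholds$down_fc
  }
  verdict <- rep("nc", nrow(matrix))
  verdict[up] <- "up"
  verdict[down] <- "down"
  verdict[filtered] <- "filtered"
  data.frame(
    entity = matrix$id,
    comparison = comparison,
    fold_change = fc,
    log2_fc = log2(fc),
    verdict = verdict,
    stringsAsFactors = FALSE
  )
}

#' Up/down identifier sets per comparison
#'
#' @param calls_low,calls_high Call tables from [call_differential()] for the
#'   `low_vs_mod` and `high_vs_mod` comparisons over the same entities.
#'
#' @return A nested list `list(low_vs_mod = list(up=, down=),
#'   high_vs_mod = list(up=, down=))` of character id vectors.
#' @export
de_sets <- function(calls_low, calls_high) {
  if (!setequal(calls_low$entity, calls_high$entity))
    stop("the two comparisons cover different entity sets", call. = FALSE)
  one <- function(calls) {
    list(up = calls$entity[calls$verdict == "up"],
         down = calls$entity[calls$verdict == "down"])
  }
  list(low_vs_mod = one(calls_low), high_vs_mod = one(calls_high))
}
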