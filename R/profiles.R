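#' Glucose-response profile taxonomy
#'
#' Each entity's pair of verdicts (low vs moderate, high vs moderate) maps to
#' one of eight glucose-response shapes, plus FLAT for no change in either
#' comparison:
#'
#' * `I`  — increased continuously (below moderate at low glucose, above at
#'   high): verdicts (down, up)
#' * `D`  — decreased continuously: (up, down)
#' * `M`  — decreased under both low and high glucose: (down, down)
#' * `V`  — increased under both low and high glucose: (up, up)
#' * `LD` — decreased under low glucose only: (down, nc)
#' * `LI` — increased under low glucose only: (up, nc)
#' * `HI` — increased under high glucose only: (nc, up)
#' * `HD` — decreased under high glucose only: (nc, down)
#' * `FLAT` — (nc, nc); excluded from network pairing
#'
#' @name profiles
NULL

#' All profile type labels, FLAT last
#' @export
PROFILE_TYPES <- c("I", "D", "M", "V", "LD", "LI", "HI", "HD", "FLAT")

.profile_grid <- c(
  "down.up"   = "I",
  "up.down"   = "D",
  "down.down" = "M",
  "up.up"     = "V",
  "down.nc"   = "LD",
  "up.nc"     = "LI",
  "nc.up"     = "HI",
  "nc.down"   = "HD",
  "nc.nc"     = "FLAT"
)

#' Classify a verdict pair into a profile type
#'
#' @param low_call,high_call Verdicts (`up`, `down`, `nc`) for the low-vs-
#'   moderate and high-vs-moderate comparisons. Vectorised. `filtered` is not
#'   accepted here: callers must resolve filtered entities first (see
#'   [classify_entities()]).
#'
#' @return Character vector of profile types.
#' @export
classify_profile <- function(low_call, high_call) {
  ok <- c("up", "down", "nc")
  if (!all(low_call %in% ok) || !all(high_call %in% ok))
    stop("verdicts must be up/down/nc (filtered entities are not classifiable)",
         call. = FALSE)
  unname(.profile_grid[paste(low_call, high_call, sep = ".")])
}

#' Inverse profile type
#'
#' The inverse-expression partner of each shape: I<->D, M<->V, LD<->LI,
#' HI<->HD. A miRNA of one type pairs with target genes of the inverse type.
#' FLAT has no inverse and raises an error.
#'
#' @param t Character vector of profile types (no FLAT).
#' @return Character vector of inverse types.
#' @export
inverse_type <- function(t) {
  inv <- c(I = "D", D = "I", M = "V", V = "M",
           LD = "LI", LI = "LD", HI = "HD", HD = "HI")
  if (any(!t %in% names(inv)))
    stop("inverse_type is undefined for FLAT or unknown types", call. = FALSE)
  unname(inv[t])
}

#' Classify all entities from their two call tables
#'
#' Entities filtered in one or both comparisons are assigned FLAT (recorded in
#' the `note` column) rather than dropped: this keeps the bookkeeping total
#' while still excluding them from network pairing, which only uses non-FLAT
#' entities.
#'
#' @param calls_low,calls_high Call tables from [call_differential()].
#' @return Data frame with columns `entity`, `profile`, `note`
#'   (`""`, `"filtered_one"`, or `"filtered_both"`).
#' @export
classify_entities <- function(calls_low, calls_high) {
  if (!identical(calls_low$entity, calls_high$entity))
    calls_high <- calls_high[match(calls_low$entity, calls_high$entity), ]
  if (anyNA(calls_high$entity) ||
      !identical(calls_low$entity, calls_high$entity))
    stop("the two comparisons cover different entity sets", call. = FALSE)
  lf <- calls_low$verdict == "filtered"
  hf <- calls_high$verdict == "filtered"
  low <- ifelse(lf, "nc", calls_low$verdict)
  high <- ifelse(hf, "nc", calls_high$verdict)
  profile <- classify_profile(low, high)
  profile[lf | hf] <- "FLAT"
  note <- rep("", length(profile))
  note[xor(lf, hf)] <- "filtered_one"
  note[lf & hf] <- "filtered_both"
  if (any(note == "filtered_one"))
    warning(sum(note == "filtered_one"),
            " entities filtered in exactly one comparison were assigned FLAT",
            call. = FALSE)
  data.frame(entity = calls_low$entity, profile = profile, note = note,
             stringsAsFactors = FALSE)
}

#' Count entities per profile type
#'
#' @param assignments Character vector of profile types, or a data frame with
#'   a `profile` column.
#' @return Named integer vector over all nine types (zero-filled).
#' @export
type_counts <- function(assignments) {
  if (is.data.frame(assignments)) assignments <- assignments$profile
  counts <- table(factor(assignments, levels = PROFILE_TYPES))
  stats::setNames(as.integer(counts), PROFILE_TYPES)
}
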