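# Phosphosite localization filtering. The Ascore is -10 * log10 of the
# localization p-value, so Ascore >= 13 corresponds to ~95% localization
# confidence. A site is retained in a cell state when confidently localized
# AND either reproducibly detected (>= 2 of 3 replicates) or already present
# in an external phosphosite catalog.

#' Localization confidence implied by an Ascore
#'
#' `confidence = 1 - 10^(-ascore / 10)`; an Ascore of 13 is approximately
#' 95% confidence, 20 is exactly 99%.
#'
#' @param ascore Non-negative Ascore value(s).
#' @return Confidence in `[0, 1)`.
#' @export
ascore_confidence <- function(ascore) {
  if (any(ascore < 0)) stop("ascore must be >= 0")
  1 - 10^(-ascore / 10)
}

#' Ascore required for a given localization confidence
#'
#' Inverse of [ascore_confidence()]: `-10 * log10(1 - confidence)`.
#'
#' @param confidence Confidence level in `[0, 1)`.
#' @return The corresponding Ascore.
#' @export
ascore_for_confidence <- function(confidence) {
  if (any(confidence < 0 | confidence >= 1)) {
    stop("confidence must be in [0, 1)")
  }
  -10 * log10(1 - confidence)
}

phospho_states <- function(records) {
  det <- grep("_rep[0-9]+$", names(records), value = TRUE)
  states <- unique(sub("_rep[0-9]+$", "", det))
  if (length(states) == 0) stop("no per-state replicate detection columns")
  for (st in states) {
    if (length(grep(paste0("^", st, "_rep"), det)) != 3) {
      stop("each state needs exactly 3 replicate detection columns")
    }
  }
  states
}

#' Apply the phosphosite retention filter per cell state
#'
#' A site is retained in a state iff `ascore >= ascore_min` AND (it was
#' detected in at least `min_replicates` of that state's 3 replicates OR it
#' is a known site from an external catalog).
#'
#' @param records Phosphosite data frame with columns `protein`, `position`,
#'   `residue`, `ascore`, `known_site` and `<state>_rep1..3` logical
#'   detection columns for each state.
#' @param ascore_min Minimum Ascore (default 13, ~95% confidence).
#' @param min_replicates Minimum supporting replicates (default 2 of 3).
#' @return `records` with one added logical `retained_<state>` column per
#'   state.
#' @export
retain_sites <- function(records, ascore_min = 13, min_replicates = 2L) {
  states <- phospho_states(records)
  for (st in states) {
    det <- as.matrix(records[paste0(st, "_rep", 1:3)])
    n_det <- rowSums(det)
    records[[paste0("retained_", st)]] <-
      records$ascore >= ascore_min &
      (n_det >= min_replicates | records$known_site)
  }
  attr(records, "states") <- states
  records
}

#' Summarize retained phosphosites
#'
#' Counts retained sites per residue class (pS/pT/pY) and partitions the
#' retained union into state-specific and shared sites. The residue-class
#' counts always sum to the total retained.
#'
#' @param records Output of [retain_sites()].
#' @return List with `residue_counts` (named S/T/Y vector over the retained
#'   union), `total`, `partition` (named counts: one `<state>_specific`
#'   entry per state plus `shared`), and `sites` (per-site table with the
#'   partition label).
#' @export
classify_sites <- function(records) {
  states <- attr(records, "states")
  if (is.null(states)) states <- phospho_states(records)
  ret_cols <- paste0("retained_", states)
  if (!all(ret_cols %in% names(records))) {
    stop("run retain_sites() before classify_sites()")
  }
  ret <- as.matrix(records[ret_cols])
  any_ret <- rowSums(ret) > 0
  sites <- records[any_ret, c("protein", "position", "residue"), drop = FALSE]
  ret <- ret[any_ret, , drop = FALSE]
  label <- character(nrow(sites))
  for (i in seq_along(states)) {
    only <- ret[, i] & rowSums(ret) == 1
    label[only] <- paste0(states[i], "_specific")
  }
  label[rowSums(ret) == length(states)] <- "shared"
  label[rowSums(ret) > 1 & rowSums(ret) < length(states)] <- "shared"
  sites$partition <- label
  residue_counts <- vapply(c("S", "T", "Y"), function(r)
    sum(sites$residue == r), integer(1))
  partition <- vapply(c(paste0(states, "_specific"), "shared"), function(l)
    sum(label == l), integer(1))
  list(residue_counts = residue_counts, total = nrow(sites),
       partition = partition, sites = sites)
}
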