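#' Call-level filter thresholds
#'
#' The default thresholds reproduce the study-grade long-read SV filter:
#' SV length between 1 bp and 1,000,000 bp, supporting reads at least
#' 1000 bp long, and mapping quality at least 20. All thresholds are
#' inclusive, so a record at exactly the minimum passes.
#'
#' @param min_sv_length Minimal SV length, bp (default 1).
#' @param max_sv_length Maximal SV length, bp (default 1e6).
#' @param min_read_length Minimal supporting-read length, bp (default 1000).
#' @param min_mapping_quality Minimal mapping quality, phred (default 20).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(min_sv_length = 1L, max_sv_length = 1000000L,
                          min_read_length = 1000L,
                          min_mapping_quality = 20) {
  stopifnot(min_sv_length >= 1, max_sv_length >= min_sv_length,
            min_read_length >= 0, min_mapping_quality >= 0)
  structure(list(min_sv_length = as.integer(min_sv_length),
                 max_sv_length = as.integer(max_sv_length),
                 min_read_length = as.integer(min_read_length),
                 min_mapping_quality = min_mapping_quality),
            class = "filter_params")
}

#' Filter a call set on length, read length and mapping quality
#'
#' Retains exactly the records with
#' `min_sv_length <= length <= max_sv_length`,
#' `min_supporting_read_length >= min_read_length` and
#' `mapping_quality >= min_mapping_quality` (all inclusive). A rejected
#' record is tallied once, under the first criterion it fails, in the
#' order: too short, too long, read length, mapping quality — so the
#' output size plus the tally sum equals the input size.
#'
#' @param calls An `sv_callset`.
#' @param params A [filter_params()].
#' @return The filtered `sv_callset`; attribute `"rejections"` holds the
#'   per-criterion tally, attribute `"audit"` a data.frame of rejected
#'   record ids and reasons.
#' @export
filter_calls <- function(calls, params = filter_params()) {
  stopifnot(inherits(calls, "sv_callset"), inherits(params, "filter_params"))
  rec <- calls$records
  reason <- rep(NA_character_, nrow(rec))
  reason[is.na(reason) & rec$length < params$min_sv_length] <- "too_short"
  reason[is.na(reason) & rec$length > params$max_sv_length] <- "too_long"
  reason[is.na(reason) &
           rec$min_supporting_read_length < params$min_read_length] <-
    "read_length"
  reason[is.na(reason) &
           rec$mapping_quality < params$min_mapping_quality] <- "low_mapq"
  keep <- is.na(reason)
  out <- calls
  out$records <- sort_records(rec[keep, , drop = FALSE])
  tal <- table(factor(reason[!keep],
                      levels = c("too_short", "too_long", "read_length",
                                 "low_mapq")))
  attr(out, "rejections") <- setNames(as.integer(tal), names(tal))
  attr(out, "audit") <- data.frame(id = rec$id[!keep],
                                   reason = reason[!keep],
                                   stringsAsFactors = FALSE)
  out
}

#' Per-type SV size distribution
#'
#' Summarizes SV lengths per type, plus an `INDEL` aggregate (DEL and
#' INS together). Quartiles use linear interpolation
#' (`stats::quantile` type 7).
#'
#' @param calls An `sv_callset`.
#' @return A data.frame with one row per type present (and `INDEL`):
#'   `sv_type`, `n`, `median`, `q1`, `q3`; attribute `"lengths"` holds
#'   the per-type length multisets.
#' @export
size_table <- function(calls) {
  stopifnot(inherits(calls, "sv_callset"))
  rec <- calls$records
  groups <- split(rec$length, factor(rec$sv_type, levels = SV_TYPES))
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  indel <- rec$length[rec$sv_type %in% c("DEL", "INS")]
  if (length(indel) > 0) groups$INDEL <- indel
  if (length(groups) == 0) {
    out <- data.frame(sv_type = character(0), n = integer(0),
                      median = numeric(0), q1 = numeric(0), q3 = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "lengths") <- list()
    return(out)
  }
  out <- data.frame(
    sv_type = names(groups),
    n = vapply(groups, length, integer(1)),
    median = vapply(groups, median, numeric(1)),
    q1 = vapply(groups, function(v) unname(quantile(v, 0.25, type = 7)),
                numeric(1)),
    q3 = vapply(groups, function(v) unname(quantile(v, 0.75, type = 7)),
                numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "lengths") <- groups
  out
}
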