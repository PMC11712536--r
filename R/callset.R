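#' @importFrom stats quantile median pchisq setNames aggregate
#' @importFrom utils read.table write.table head modifyList
NULL

SV_TYPES <- c("DEL", "INS", "DUP", "INV", "INVDUP")
GENOTYPES <- c("WT", "atm", "atr", "atm_atr", "other")
TREATMENTS <- c("none", "UV_B", "UV_C", "protons")

RECORD_COLS <- c("id", "chrom", "start", "end", "sv_type", "length",
                 "inserted_seq", "read_support", "min_supporting_read_length",
                 "mapping_quality")

#' Build an empty SV record table
#'
#' @return A zero-row data.frame with the canonical record columns.
#' @keywords internal
empty_records <- function() {
  data.frame(id = character(0), chrom = character(0),
             start = integer(0), end = integer(0),
             sv_type = character(0), length = integer(0),
             inserted_seq = character(0),
             read_support = integer(0),
             min_supporting_read_length = integer(0),
             mapping_quality = numeric(0),
             stringsAsFactors = FALSE)
}

#' Construct a structural-variant call set
#'
#' An `sv_callset` bundles one sample's SV calls with its metadata
#' (genotype, treatment, replicate). Records are stored in VCF
#' conventions: `start`/`end` are 1-based positions as printed in the
#' VCF (`POS`/`END`); for deletions the deleted run is the half-open
#' interval `[start, end)` in 0-based coordinates (Sniffles anchors
#' `POS` on the base preceding the deleted bases, so
#' `end - start == length`). Insertions anchor at a single point
#' (`end == start`).
#'
#' @param records Data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `sv_type` (one of DEL, INS, DUP, INV, INVDUP), `length`,
#'   `inserted_seq` (NA unless an INS with reported sequence),
#'   `read_support`, `min_supporting_read_length`, `mapping_quality`.
#' @param sample_id Sample identifier (unique within a study).
#' @param genotype One of `"WT"`, `"atm"`, `"atr"`, `"atm_atr"`, `"other"`.
#' @param treatment One of `"none"`, `"UV_B"`, `"UV_C"`, `"protons"`.
#' @param replicate Positive integer replicate index.
#' @return An object of class `sv_callset`.
#' @export
sv_callset <- function(records = empty_records(), sample_id = "sample",
                       genotype = "WT", treatment = "none", replicate = 1L) {
  genotype <- match.arg(genotype, GENOTYPES)
  treatment <- match.arg(treatment, TREATMENTS)
  replicate <- as.integer(replicate)
  stopifnot(length(replicate) == 1L, replicate >= 1L)
  records <- validate_records(records)
  records <- sort_records(records)
  structure(list(sample_id = sample_id, genotype = genotype,
                 treatment = treatment, replicate = replicate,
                 records = records),
            class = "sv_callset")
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(RECORD_COLS, names(records))
  if (length(missing_cols) > 0)
    stop("records missing columns: ", paste(missing_cols, collapse = ", "))
  records <- records[, RECORD_COLS]
  records$id <- as.character(records$id)
  records$chrom <- as.character(records$chrom)
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  records$sv_type <- as.character(records$sv_type)
  records$length <- as.integer(records$length)
  records$inserted_seq <- as.character(records$inserted_seq)
  records$read_support <- as.integer(records$read_support)
  records$min_supporting_read_length <-
    as.integer(records$min_supporting_read_length)
  records$mapping_quality <- as.numeric(records$mapping_quality)
  if (nrow(records) == 0) return(records)
  if (anyDuplicated(records$id))
    stop("record ids are not unique within the call set")
  bad_type <- setdiff(unique(records$sv_type), SV_TYPES)
  if (length(bad_type) > 0)
    stop("unknown sv_type: ", paste(bad_type, collapse = ", "))
  if (any(records$start < 1)) stop("start must be >= 1")
  non_ins <- records$sv_type != "INS"
  if (any(records$end[non_ins] < records$start[non_ins]))
    stop("end < start for a non-insertion record")
  if (any(records$length < 1)) stop("length must be >= 1")
  ins <- which(records$sv_type == "INS" & !is.na(records$inserted_seq))
  if (length(ins) > 0 &&
      any(nchar(records$inserted_seq[ins]) != records$length[ins]))
    stop("inserted_seq length disagrees with record length")
  records
}

sort_records <- function(records) {
  ord <- order(records$chrom, records$start, records$end, records$sv_type,
               records$id, method = "radix")
  rec <- records[ord, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' @export
print.sv_callset <- function(x, ...) {
  cat(sprintf("<sv_callset> %s (genotype %s, treatment %s, replicate %d): %d records\n",
              x$sample_id, x$genotype, x$treatment, x$replicate,
              nrow(x$records)))
  if (nrow(x$records) > 0) {
    tab <- table(factor(x$records$sv_type, levels = SV_TYPES))
    cat("  ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.sv_callset <- function(object, ...) {
  list(sample_id = object$sample_id,
       n_records = nrow(object$records),
       by_type = table(factor(object$records$sv_type, levels = SV_TYPES)),
       size = size_table(object))
}

#' Number of records in a call set
#' @param x An `sv_callset`.
#' @return Integer count.
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "sv_callset"))
  nrow(x$records)
}

#' Convert call-set records to a GRanges
#'
#' Insertions become 1-bp anchors at their `start` position; for all
#' other types the range is the stored `[start, end]` interval (1-based
#' inclusive, as printed in the VCF).
#'
#' @param x An `sv_callset` or its records data.frame.
#' @return A `GRanges` with record metadata columns.
#' @export
callset_granges <- function(x) {
  rec <- if (inherits(x, "sv_callset")) x$records else x
  if (nrow(rec) == 0)
    return(GenomicRanges::GRanges())
  ins <- rec$sv_type == "INS"
  gstart <- rec$start
  gend <- ifelse(ins, rec$start, rec$end)
  gr <- GenomicRanges::GRanges(rec$chrom,
                               IRanges::IRanges(gstart, gend))
  S4Vectors::mcols(gr)$id <- rec$id
  S4Vectors::mcols(gr)$sv_type <- rec$sv_type
  gr
}
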