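# Sniffles v1 is the reference INFO dialect; synonyms normalized here:
#   read support: RE, then SUPPORT; mapping quality: MAPQ;
#   minimal supporting-read length: MINRL (emitted by our writer; absent
#   in stock Sniffles output -> sentinel 0, likewise RE/MAPQ -> 0).
SVTYPE_ALIASES <- c("INV/INVDUP" = "INVDUP", "INVDUP" = "INVDUP",
                    "DUP:TANDEM" = "DUP", "DUP:INT" = "DUP",
                    "DEL" = "DEL", "INS" = "INS", "DUP" = "DUP",
                    "INV" = "INV")

parse_info_field <- function(info) {
  # one INFO string -> named character vector
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  has_eq <- grepl("=", parts, fixed = TRUE)
  kv <- strsplit(parts[has_eq], "=", fixed = TRUE)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), character(1))
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  flags <- parts[!has_eq]
  c(vals, setNames(rep("TRUE", length(flags)), flags))
}

info_num <- function(info, keys, default = NA_real_) {
  for (k in keys) {
    v <- suppressWarnings(as.numeric(info[k]))
    if (!is.na(v)) return(v)
  }
  default
}

looks_like_sequence <- function(x) {
  !is.na(x) & nchar(x) > 1 & grepl("^[ACGTNacgtn]+$", x)
}

#' Read a Sniffles-style structural-variant VCF
#'
#' Parses a VCF 4.x file (plain or gzipped) of structural-variant calls
#' into an [sv_callset()]. `SVTYPE` strings are normalized to the
#' five-class vocabulary (DEL, INS, DUP, INV, INVDUP; dialects such as
#' `"INV/INVDUP"` map to `INVDUP`). Breakend (`BND`/`TRA`) records and
#' lines without an `SVTYPE` are skipped and counted; unknown types are
#' skipped with a warning. Absent quality annotations map to sentinels
#' (`read_support = 0`, `mapping_quality = 0`,
#' `min_supporting_read_length = 0`).
#'
#' @param path Path to the VCF file.
#' @param sample_id Sample identifier for the resulting call set.
#' @param genotype,treatment,replicate Sample metadata, see [sv_callset()].
#' @param honor_filter If `TRUE` (default) only records whose FILTER
#'   column is `PASS` or `.` are kept; set `FALSE` to ingest all lines.
#' @return An `sv_callset`; attribute `"skipped"` holds the per-reason
#'   skip counts (`bnd`, `non_sv`, `unknown_type`, `filtered`).
#' @export
parse_sv_vcf <- function(path, sample_id = "sample", genotype = "WT",
                         treatment = "none", replicate = 1L,
                         honor_filter = TRUE) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("malformed VCF '", path, "': ", conditionMessage(e),
                         call. = FALSE))
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  skipped <- c(bnd = 0L, non_sv = 0L, unknown_type = 0L, filtered = 0L)
  n <- nrow(fix)
  rows <- vector("list", n)
  auto_id <- 0L
  for (i in seq_len(n)) {
    filt <- fix[i, "FILTER"]
    if (honor_filter && !is.na(filt) && !(filt %in% c("PASS", ".", ""))) {
      skipped["filtered"] <- skipped["filtered"] + 1L
      next
    }
    info <- parse_info_field(fix[i, "INFO"])
    svtype_raw <- unname(info["SVTYPE"])
    if (is.na(svtype_raw)) {
      skipped["non_sv"] <- skipped["non_sv"] + 1L
      next
    }
    svtype_raw <- toupper(svtype_raw)
    if (svtype_raw %in% c("BND", "TRA")) {
      skipped["bnd"] <- skipped["bnd"] + 1L
      next
    }
    sv_type <- unname(SVTYPE_ALIASES[svtype_raw])
    if (is.na(sv_type)) {
      warning("unknown SVTYPE '", svtype_raw, "' skipped")
      skipped["unknown_type"] <- skipped["unknown_type"] + 1L
      next
    }
    pos <- as.integer(fix[i, "POS"])
    svlen <- info_num(info, "SVLEN")
    endpos <- info_num(info, "END")
    alt <- fix[i, "ALT"]
    seq <- unname(info["SEQ"])
    if (is.na(seq) && looks_like_sequence(alt)) seq <- alt
    if (sv_type == "INS") {
      len <- if (!is.na(svlen)) abs(svlen)
             else if (!is.na(seq)) nchar(seq) else NA_real_
      endpos <- pos
    } else {
      len <- if (!is.na(svlen)) abs(svlen)
             else if (!is.na(endpos)) endpos - pos else NA_real_
      if (is.na(endpos) && !is.na(len)) endpos <- pos + len
      seq <- NA_character_
    }
    if (is.na(len) || len < 1) {
      warning("record at ", fix[i, "CHROM"], ":", pos,
              " has no usable length; skipped")
      skipped["unknown_type"] <- skipped["unknown_type"] + 1L
      next
    }
    id <- fix[i, "ID"]
    if (is.na(id) || id %in% c(".", "")) {
      auto_id <- auto_id + 1L
      id <- sprintf("%s_sv%05d", sample_id, auto_id)
    }
    rows[[i]] <- data.frame(
      id = id, chrom = fix[i, "CHROM"], start = pos,
      end = as.integer(endpos), sv_type = sv_type, length = as.integer(len),
      inserted_seq = if (sv_type == "INS") seq else NA_character_,
      read_support = as.integer(info_num(info, c("RE", "SUPPORT"), 0)),
      min_supporting_read_length = as.integer(info_num(info, "MINRL", 0)),
      mapping_quality = info_num(info, "MAPQ", 0),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  records <- if (length(rows) > 0) do.call(rbind, rows) else empty_records()
  if (anyDuplicated(records$id)) {
    dup <- duplicated(records$id) | duplicated(records$id, fromLast = TRUE)
    records$id[dup] <- sprintf("%s_%d", records$id[dup], seq_len(sum(dup)))
  }
  out <- sv_callset(records, sample_id = sample_id, genotype = genotype,
                    treatment = treatment, replicate = replicate)
  attr(out, "skipped") <- skipped
  out
}

#' Write a call set as a structural-variant VCF
#'
#' Emits a minimal VCF 4.2 with the INFO dialect read back by
#' [parse_sv_vcf()] (`SVTYPE`, `END`, `SVLEN`, `SEQ`, `RE`, `MAPQ`,
#' `MINRL`), so write-then-parse is a fixed point on record fields.
#' If the records carry a `filter_reason` column (added by
#' [filter_calls()] audits) it is written to the FILTER column.
#'
#' @param calls An `sv_callset`.
#' @param path Output path.
#' @param contigs Optional named integer vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path, contigs = NULL) {
  stopifnot(inherits(calls, "sv_callset"))
  rec <- calls$records
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=svradiate"),
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
           "##INFO=<ID=SEQ,Number=1,Type=String,Description=\"Inserted sequence\">",
           "##INFO=<ID=RE,Number=1,Type=Integer,Description=\"Number of supporting reads\">",
           "##INFO=<ID=MAPQ,Number=1,Type=Float,Description=\"Mean mapping quality of supporting reads\">",
           "##INFO=<ID=MINRL,Number=1,Type=Integer,Description=\"Minimal supporting read length\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  filt <- if ("filter_reason" %in% names(rec)) rec$filter_reason else
    rep("PASS", nrow(rec))
  lines <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    svlen <- if (r$sv_type == "DEL") -r$length else r$length
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;RE=%d;MAPQ=%g;MINRL=%d",
                    r$sv_type, r$end, svlen, r$read_support,
                    r$mapping_quality, r$min_supporting_read_length)
    if (!is.na(r$inserted_seq))
      info <- paste0(info, ";SEQ=", r$inserted_seq)
    alt <- if (r$sv_type == "INS" && !is.na(r$inserted_seq)) r$inserted_seq
           else sprintf("<%s>", r$sv_type)
    lines[i] <- paste(r$chrom, r$start, r$id, "N", alt, ".", filt[i], info,
                      sep = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
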