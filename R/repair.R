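#' Read a reference genome FASTA
#'
#' @param path FASTA path.
#' @return A named `DNAStringSet` (names truncated at first whitespace).
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# genome argument throughout: named DNAStringSet or named character
# vector of chromosome sequences
chrom_string <- function(genome, chrom) {
  if (!(chrom %in% names(genome)))
    stop("chromosome '", chrom, "' absent from genome")
  toupper(as.character(genome[[chrom]]))
}

#' Repair-pathway classification thresholds
#'
#' Junction microhomology length separates end-joining signatures:
#' 0-1 bp is scored NHEJ, `mh_min_mmej`..`mh_max_mmej` bp (default
#' 2-19) MMEJ, and `mh_ssa_threshold` bp or more (default 20) a
#' canonical single-strand-annealing candidate.
#'
#' @param flank_window Flank window, bp (default 50).
#' @param mh_min_mmej,mh_max_mmej MMEJ band, bp (defaults 2 and 19).
#' @param mh_ssa_threshold SSA floor, bp (default 20).
#' @param max_n_fraction Maximum tolerated fraction of N bases in a
#'   flank before the call is labelled UNDETERMINED (default 0: any N).
#' @return An object of class `repair_params`.
#' @export
repair_params <- function(flank_window = 50L, mh_min_mmej = 2L,
                          mh_max_mmej = 19L, mh_ssa_threshold = 20L,
                          max_n_fraction = 0) {
  stopifnot(1 <= mh_min_mmej, mh_min_mmej <= mh_max_mmej,
            mh_max_mmej < mh_ssa_threshold,
            mh_ssa_threshold <= flank_window,
            max_n_fraction >= 0, max_n_fraction <= 1)
  structure(list(flank_window = as.integer(flank_window),
                 mh_min_mmej = as.integer(mh_min_mmej),
                 mh_max_mmej = as.integer(mh_max_mmej),
                 mh_ssa_threshold = as.integer(mh_ssa_threshold),
                 max_n_fraction = max_n_fraction),
            class = "repair_params")
}

del_bounds <- function(record) {
  # 0-based half-open deleted interval [s, e): POS anchors the base
  # before the deleted run (Sniffles convention), so s = start, e = end
  if (record$sv_type != "DEL") stop("record is not a deletion")
  list(s = record$start, e = record$end)
}

#' Fetch the reference flanks of a deletion
#'
#' Returns the `window` bp immediately upstream of the deletion start
#' and downstream of the deletion end (0-based half-open internal
#' coordinates `[s-window, s)` and `[e, e+window)`). Windows are
#' truncated at chromosome ends, with truncation flagged.
#'
#' @param deletion A one-row DEL record.
#' @param genome Named `DNAStringSet` or character vector of sequences.
#' @param window Flank window, bp.
#' @return List with `left`, `right` (uppercase strings),
#'   `left_truncated`, `right_truncated`.
#' @export
fetch_flanks <- function(deletion, genome, window = 50L) {
  b <- del_bounds(deletion)
  chr <- chrom_string(genome, deletion$chrom)
  L <- nchar(chr)
  if (b$e > L) stop("deletion extends beyond chromosome end")
  left_from <- max(1L, b$s - window + 1L)
  left <- substr(chr, left_from, b$s)
  right_to <- min(L, b$e + window)
  right <- substr(chr, b$e + 1L, right_to)
  list(left = left, right = right,
       left_truncated = nchar(left) < window,
       right_truncated = nchar(right) < window)
}

#' Junction microhomology of a deletion
#'
#' Measures the breakpoint-ambiguity homology of a deletion `[s, e)` on
#' reference `R`: the right extension is the largest `k <= window` with
#' `R[s..s+k) == R[e..e+k)`, the left extension the largest `j` with
#' `R[s-j..s) == R[e-j..e)`; the total is `j + k` and the reported
#' microhomology sequence is `R[s-j..s+k)`. Comparison is
#' case-insensitive and stops at any N or at a chromosome end. The
#' total is invariant under shifting the reported breakpoints along the
#' homology tract.
#'
#' @param deletion A one-row DEL record.
#' @param genome Named `DNAStringSet` or character vector.
#' @param window Maximal extension per side, bp (default 50).
#' @return List with `mh_left`, `mh_right`, `mh_total`, `mh_sequence`.
#' @export
microhomology <- function(deletion, genome, window = 50L) {
  b <- del_bounds(deletion)
  if (b$e - b$s < 1) stop("deletion shorter than 1 bp")
  chr <- chrom_string(genome, deletion$chrom)
  L <- nchar(chr)
  ch <- function(i) substr(chr, i, i)  # 1-based single base
  k <- 0L
  while (k < window && b$s + k + 1L <= L && b$e + k + 1L <= L) {
    x <- ch(b$s + k + 1L); y <- ch(b$e + k + 1L)
    if (x == "N" || y == "N" || x != y) break
    k <- k + 1L
  }
  j <- 0L
  while (j < window && b$s - j >= 1L && b$e - j >= 1L) {
    x <- ch(b$s - j); y <- ch(b$e - j)
    if (x == "N" || y == "N" || x != y) break
    j <- j + 1L
  }
  seq <- paste0(substr(chr, b$s - j + 1L, b$s),
                substr(chr, b$s + 1L, b$s + k))
  list(mh_left = j, mh_right = k, mh_total = j + k, mh_sequence = seq)
}

#' Classify the repair signature of one deletion
#'
#' UNDETERMINED when either flank is truncated at a chromosome end or
#' carries N bases above `max_n_fraction` (the reference-based analogue
#' of low sequence quality in a flanking region); otherwise NHEJ, MMEJ
#' or SSA_CANDIDATE by total junction microhomology against the
#' thresholds in [repair_params()].
#'
#' @param deletion A one-row DEL record.
#' @param genome Named `DNAStringSet` or character vector.
#' @param params A [repair_params()].
#' @return A one-row data.frame: `record_id`, `left_flank`,
#'   `right_flank`, `mh_left`, `mh_right`, `mh_total`, `mh_sequence`,
#'   `label`.
#' @export
classify_repair <- function(deletion, genome, params = repair_params()) {
  if (deletion$sv_type != "DEL") stop("record is not a deletion")
  fl <- fetch_flanks(deletion, genome, params$flank_window)
  n_frac <- function(s) {
    if (nchar(s) == 0) return(1)
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / nchar(s)
  }
  if (fl$left_truncated || fl$right_truncated ||
      n_frac(fl$left) > params$max_n_fraction ||
      n_frac(fl$right) > params$max_n_fraction) {
    return(data.frame(record_id = deletion$id, left_flank = fl$left,
                      right_flank = fl$right, mh_left = NA_integer_,
                      mh_right = NA_integer_, mh_total = NA_integer_,
                      mh_sequence = NA_character_, label = "UNDETERMINED",
                      stringsAsFactors = FALSE))
  }
  mh <- microhomology(deletion, genome, params$flank_window)
  label <- if (mh$mh_total >= params$mh_ssa_threshold) "SSA_CANDIDATE"
           else if (mh$mh_total >= params$mh_min_mmej &&
                    mh$mh_total <= params$mh_max_mmej) "MMEJ"
           else "NHEJ"
  data.frame(record_id = deletion$id, left_flank = fl$left,
             right_flank = fl$right, mh_left = mh$mh_left,
             mh_right = mh$mh_right, mh_total = mh$mh_total,
             mh_sequence = mh$mh_sequence, label = label,
             stringsAsFactors = FALSE)
}

REPAIR_LABELS <- c("NHEJ", "MMEJ", "SSA_CANDIDATE", "UNDETERMINED")

#' Repair-signature summary of a call set
#'
#' Classifies every deletion in the call set and tabulates label counts
#' and fractions, plus the microhomology-length histogram over MMEJ
#' events (the bubble-chart data: length vs frequency).
#'
#' @param calls An `sv_callset`.
#' @param genome Named `DNAStringSet` or character vector.
#' @param params A [repair_params()].
#' @return A list of class `sv_repair_summary`: `classifications`
#'   (per-deletion data.frame), `counts`, `fractions`, `mh_histogram`
#'   (named counts keyed by mh_total over MMEJ records), `n_deletions`.
#' @export
repair_summary <- function(calls, genome, params = repair_params()) {
  stopifnot(inherits(calls, "sv_callset"))
  dels <- calls$records[calls$records$sv_type == "DEL", , drop = FALSE]
  if (nrow(dels) == 0) {
    cls <- data.frame(record_id = character(0), left_flank = character(0),
                      right_flank = character(0), mh_left = integer(0),
                      mh_right = integer(0), mh_total = integer(0),
                      mh_sequence = character(0), label = character(0),
                      stringsAsFactors = FALSE)
  } else {
    cls <- do.call(rbind, lapply(seq_len(nrow(dels)), function(i)
      classify_repair(dels[i, ], genome, params)))
  }
  counts <- table(factor(cls$label, levels = REPAIR_LABELS))
  n <- nrow(cls)
  mmej_mh <- cls$mh_total[cls$label == "MMEJ"]
  hist <- table(mmej_mh)
  structure(list(classifications = cls,
                 counts = setNames(as.integer(counts), names(counts)),
                 fractions = if (n > 0)
                   setNames(as.numeric(counts) / n, names(counts))
                 else setNames(rep(NA_real_, 4), REPAIR_LABELS),
                 mh_histogram = setNames(as.integer(hist), names(hist)),
                 n_deletions = n),
            class = "sv_repair_summary")
}

#' @export
print.sv_repair_summary <- function(x, ...) {
  cat(sprintf("<sv_repair_summary> %d deletions\n", x$n_deletions))
  print(x$counts)
  invisible(x)
}
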