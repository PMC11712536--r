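#' Parameters for insertion-origin tracing
#'
#' The donor search is an exact k-mer seeded, locally extended
#' alignment of the inserted sequence against the reference, on both
#' strands. Scoring defaults (match +1, mismatch -2, gap open 4, gap
#' extend 1) sit near standard nucleotide-BLAST defaults.
#'
#' @param seed_k Seed k-mer length, nt (default 15, minimum 8).
#' @param min_identity Minimal alignment identity of a resolved hit
#'   (default 0.8).
#' @param min_query_coverage Minimal fraction of the insert covered by
#'   the alignment (default 0.8).
#' @param max_hits_reported Hits retained in the report (default 5).
#' @param self_exclusion_radius Hits within this distance of the
#'   insertion site are discarded, bp (default 100).
#' @param te_coverage_full Donor coverage of a TE span at or above which
#'   the copy counts as a full (non-truncated) TE (default 0.95).
#' @return An object of class `origin_params`.
#' @export
origin_params <- function(seed_k = 15L, min_identity = 0.8,
                          min_query_coverage = 0.8,
                          max_hits_reported = 5L,
                          self_exclusion_radius = 100L,
                          te_coverage_full = 0.95) {
  stopifnot(seed_k >= 8, min_identity > 0, min_identity <= 1,
            min_query_coverage > 0, min_query_coverage <= 1)
  structure(list(seed_k = as.integer(seed_k), min_identity = min_identity,
                 min_query_coverage = min_query_coverage,
                 max_hits_reported = as.integer(max_hits_reported),
                 self_exclusion_radius = as.integer(self_exclusion_radius),
                 te_coverage_full = te_coverage_full),
            class = "origin_params")
}

as_dnastringset <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) genome
  else Biostrings::DNAStringSet(unlist(lapply(genome, toupper)))
}

empty_origin <- function(record_id = NA_character_, status = "no_hit",
                         reason = NA_character_) {
  structure(list(record_id = record_id, status = status, reason = reason,
                 donor_chrom = NA_character_, donor_start = NA_integer_,
                 donor_end = NA_integer_, donor_strand = NA_character_,
                 identity = NA_real_, query_coverage = NA_real_,
                 score = NA_real_, hits = NULL,
                 donor_element_class = NA_character_,
                 donor_te_superfamily = NA_character_,
                 intrachromosomal = NA, truncated_te = NA),
            class = "insertion_origin")
}

#' @export
print.insertion_origin <- function(x, ...) {
  if (x$status == "resolved")
    cat(sprintf("<insertion_origin> resolved %s:%d-%d (%s) id %.2f cov %.2f\n",
                x$donor_chrom, x$donor_start, x$donor_end, x$donor_strand,
                x$identity, x$query_coverage))
  else cat(sprintf("<insertion_origin> %s\n", x$status))
  invisible(x)
}

# candidate donor windows from exact seed hits, merged per chrom/strand;
# returns data.frame(chrom, strand, win_start, win_end) in 1-based
# inclusive coordinates
seed_windows <- function(query, genome, params, margin = 25L) {
  L <- nchar(query)
  k <- params$seed_k
  step <- max(1L, k %/% 2L)
  seed_pos <- unique(c(seq(1L, L - k + 1L, by = step), L - k + 1L))
  out <- list()
  for (p in seed_pos) {
    seed <- substr(query, p, p + k - 1L)
    if (grepl("N", seed, fixed = TRUE)) next
    m <- Biostrings::vmatchPattern(seed, genome)
    for (ci in seq_along(m)) {
      st <- BiocGenerics::start(m[[ci]])
      if (length(st) == 0) next
      ws <- pmax(1L, st - (p - 1L) - margin)
      we <- pmin(Biostrings::width(genome)[ci], st - (p - 1L) + L - 1L +
                   margin)
      out[[length(out) + 1L]] <- data.frame(
        chrom = names(genome)[ci], win_start = ws, win_end = we,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), win_start = integer(0),
                      win_end = integer(0)))
  win <- do.call(rbind, out)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    win$chrom, IRanges::IRanges(win$win_start, win$win_end)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             win_start = GenomicRanges::start(gr),
             win_end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Trace an inserted sequence to its genomic donor locus
#'
#' Seed-and-extend search of the insert against the reference: exact
#' `seed_k`-mer hits on both strands nominate candidate windows, each
#' window is aligned locally (affine gaps, match +1 / mismatch -2 /
#' gap open 4 / gap extend 1), hits within `self_exclusion_radius` of
#' the insertion site are discarded, and the best-scoring hit wins.
#' The origin is `resolved` when the best hit passes the identity and
#' query-coverage floors *and* strictly outscores the best hit at any
#' other locus; `ambiguous` when it passes the floors but is tied;
#' `no_hit` otherwise.
#'
#' @param insert_seq Inserted nucleotide sequence.
#' @param genome Named `DNAStringSet` or character vector.
#' @param insertion_chrom,insertion_pos Location of the insertion
#'   anchor (used for self-exclusion and the intrachromosomal flag).
#' @param params An [origin_params()].
#' @param record_id Optional id copied into the result.
#' @return An object of class `insertion_origin`. Donor coordinates are
#'   1-based inclusive; `donor_strand` is `"+"` or `"-"`.
#' @export
find_origin <- function(insert_seq, genome, insertion_chrom = NA,
                        insertion_pos = NA, params = origin_params(),
                        record_id = NA_character_) {
  genome <- as_dnastringset(genome)
  if (is.na(insert_seq) || nchar(insert_seq) < params$seed_k)
    return(empty_origin(record_id, "no_hit", "insert shorter than seed_k"))
  q <- toupper(insert_seq)
  L <- nchar(q)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -2, baseOnly = FALSE)
  cands <- list()
  for (strand in c("+", "-")) {
    query <- if (strand == "+") q else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
    win <- seed_windows(query, genome, params)
    for (w in seq_len(nrow(win))) {
      subject <- Biostrings::subseq(genome[[win$chrom[w]]],
                                    win$win_start[w], win$win_end[w])
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(query), subject = subject,
        type = "local", substitutionMatrix = submat,
        gapOpening = 4, gapExtension = 1)
      sc <- Biostrings::score(aln)
      if (sc <= 0) next
      srange <- Biostrings::subject(aln)
      prange <- Biostrings::pattern(aln)
      d_start <- win$win_start[w] + Biostrings::start(srange) - 1L
      d_end <- win$win_start[w] + Biostrings::end(srange) - 1L
      alen <- Biostrings::nchar(aln)
      ident <- Biostrings::nmatch(aln) / alen
      qcov <- (Biostrings::end(prange) - Biostrings::start(prange) + 1L) / L
      cands[[length(cands) + 1L]] <- data.frame(
        chrom = win$chrom[w], start = d_start, end = d_end,
        strand = strand, score = sc, identity = ident, coverage = qcov,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cands) == 0)
    return(empty_origin(record_id, "no_hit", "no seed hits"))
  hits <- do.call(rbind, cands)
  # self-exclusion: drop hits at/near the insertion's own locus
  if (!is.na(insertion_chrom) && !is.na(insertion_pos)) {
    d <- ifelse(hits$chrom == insertion_chrom,
                pmax(0, pmax(hits$start - insertion_pos,
                             insertion_pos - hits$end)), Inf)
    hits <- hits[d > params$self_exclusion_radius, , drop = FALSE]
  }
  if (nrow(hits) == 0)
    return(empty_origin(record_id, "no_hit",
                        "only self-locus hits within exclusion radius"))
  # collapse to one best hit per locus (overlapping donor intervals on
  # one chromosome count as the same locus)
  hits <- hits[order(-hits$score, hits$chrom, hits$start,
                     method = "radix"), , drop = FALSE]
  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start, hits$end))
  locus <- paste(hits$chrom, GenomicRanges::findOverlaps(
    gr, GenomicRanges::reduce(gr), select = "first"))
  best_per_locus <- hits[!duplicated(locus), , drop = FALSE]
  best <- best_per_locus[1L, ]
  runner_score <- if (nrow(best_per_locus) > 1)
    best_per_locus$score[2L] else -Inf
  out <- empty_origin(record_id)
  out$hits <- head(best_per_locus, params$max_hits_reported)
  if (best$identity >= params$min_identity &&
      best$coverage >= params$min_query_coverage) {
    out$status <- if (best$score > runner_score) "resolved" else "ambiguous"
  } else {
    out$status <- "no_hit"
    out$reason <- "best hit below identity/coverage floors"
    return(out)
  }
  if (out$status == "resolved") {
    out$donor_chrom <- best$chrom
    out$donor_start <- as.integer(best$start)
    out$donor_end <- as.integer(best$end)
    out$donor_strand <- best$strand
    out$identity <- best$identity
    out$query_coverage <- best$coverage
    out$score <- best$score
    out$intrachromosomal <- if (is.na(insertion_chrom)) NA
                            else best$chrom == insertion_chrom
  }
  out
}

#' Annotate a resolved insertion origin
#'
#' Enriches a resolved origin with the donor's element class (maximal
#' bp overlap over TE/PCG/IR, reusing the annotation rules), the donor
#' TE superfamily, the intrachromosomal flag, and truncated-TE
#' detection: the donor counts as a truncated TE copy when it overlaps
#' a TE annotation but covers less than `te_coverage_full` (default
#' 95%) of that TE's span.
#'
#' @param origin A resolved `insertion_origin`.
#' @param ann A [genome_annotation()].
#' @param insertion_record Optional one-row INS record (for the
#'   intrachromosomal flag when not set by [find_origin()]).
#' @param params An [origin_params()].
#' @return The enriched `insertion_origin`.
#' @export
classify_origin <- function(origin, ann, insertion_record = NULL,
                            params = origin_params()) {
  stopifnot(inherits(origin, "insertion_origin"))
  if (origin$status != "resolved")
    stop("cannot classify an unresolved origin (status ", origin$status, ")")
  donor <- GenomicRanges::GRanges(
    origin$donor_chrom,
    IRanges::IRanges(origin$donor_start, origin$donor_end))
  ov <- c(TE = overlap_bp(donor, ann$te),
          PCG = overlap_bp(donor, ann$pcg),
          IR = overlap_bp(donor, ann$ir))
  ov <- ov[ELEMENT_CLASSES]
  origin$donor_element_class <- ELEMENT_CLASSES[which.max(ov)]
  hits <- GenomicRanges::findOverlaps(donor, ann$te)
  if (length(hits) > 0) {
    te_hits <- ann$te[S4Vectors::subjectHits(hits)]
    w <- IRanges::width(IRanges::pintersect(
      rep(donor, length(te_hits)), te_hits))
    best <- which.max(w)
    origin$donor_te_superfamily <-
      S4Vectors::mcols(te_hits)$superfamily[best]
    te_cov <- w[best] / IRanges::width(te_hits)[best]
    origin$truncated_te <- te_cov < params$te_coverage_full
  } else {
    origin$truncated_te <- FALSE
  }
  if (!is.null(insertion_record))
    origin$intrachromosomal <- origin$donor_chrom == insertion_record$chrom
  origin
}

#' Donor-by-recipient origin matrix for a call set's insertions
#'
#' Traces every insertion carrying a reported sequence, classifies
#' resolved donors, and crosses donor element class with the element
#' class at the insertion site.
#'
#' @param calls An `sv_callset`.
#' @param genome Named `DNAStringSet` or character vector.
#' @param ann A [genome_annotation()].
#' @param params An [origin_params()].
#' @return A list of class `sv_origin_summary`: `matrix` (donor class x
#'   recipient class counts over resolved insertions), `status_counts`
#'   (resolved/ambiguous/no_hit; sums to the INS count),
#'   `intrachromosomal_fraction`, `truncated_te_count`, `origins`
#'   (per-insertion data.frame).
#' @export
origin_summary <- function(calls, genome, ann, params = origin_params()) {
  stopifnot(inherits(calls, "sv_callset"))
  genome <- as_dnastringset(genome)
  ins <- calls$records[calls$records$sv_type == "INS", , drop = FALSE]
  mat <- matrix(0L, 3, 3, dimnames = list(donor = ELEMENT_CLASSES,
                                          recipient = ELEMENT_CLASSES))
  status <- c(resolved = 0L, ambiguous = 0L, no_hit = 0L)
  rows <- list()
  intra <- logical(0)
  trunc <- 0L
  if (nrow(ins) > 0) {
    recipient <- assign_elements(
      sv_callset(ins, sample_id = calls$sample_id,
                 genotype = calls$genotype, treatment = calls$treatment,
                 replicate = calls$replicate), ann)
    recipient <- setNames(recipient$element_class, recipient$id)
    for (i in seq_len(nrow(ins))) {
      r <- ins[i, ]
      o <- find_origin(r$inserted_seq, genome, r$chrom, r$start, params,
                       record_id = r$id)
      if (o$status == "resolved") {
        o <- classify_origin(o, ann, r, params)
        mat[o$donor_element_class, recipient[[r$id]]] <-
          mat[o$donor_element_class, recipient[[r$id]]] + 1L
        intra <- c(intra, o$intrachromosomal)
        if (isTRUE(o$truncated_te)) trunc <- trunc + 1L
      }
      status[o$status] <- status[o$status] + 1L
      rows[[i]] <- data.frame(
        record_id = r$id, status = o$status,
        donor_chrom = o$donor_chrom, donor_start = o$donor_start,
        donor_end = o$donor_end, donor_strand = o$donor_strand,
        identity = o$identity, query_coverage = o$query_coverage,
        donor_element_class = o$donor_element_class,
        donor_te_superfamily = o$donor_te_superfamily,
        recipient_element_class = unname(recipient[r$id]),
        intrachromosomal = o$intrachromosomal,
        truncated_te = o$truncated_te, stringsAsFactors = FALSE)
    }
  }
  origins <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(record_id = character(0), status = character(0))
  structure(list(matrix = mat, status_counts = status,
                 intrachromosomal_fraction = if (length(intra) > 0)
                   mean(intra) else NA_real_,
                 truncated_te_count = trunc,
                 origins = origins), class = "sv_origin_summary")
}

#' @export
print.sv_origin_summary <- function(x, ...) {
  cat("<sv_origin_summary> status: ")
  cat(paste(sprintf("%s=%d", names(x$status_counts), x$status_counts),
            collapse = " "), "\n")
  print(x$matrix)
  invisible(x)
}
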