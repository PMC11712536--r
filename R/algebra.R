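#' Tolerance parameters for call identity
#'
#' Two SV calls are considered identical when they are of the same type,
#' on the same chromosome, and both their start and end coordinates
#' agree within `tolerance` bp (the +/- 50 bp rule).
#'
#' @param tolerance Coordinate tolerance in bp (default 50).
#' @param require_same_type Require identical `sv_type` (default TRUE).
#' @return An object of class `match_params`.
#' @export
match_params <- function(tolerance = 50L, require_same_type = TRUE) {
  stopifnot(tolerance >= 0)
  structure(list(tolerance = as.integer(tolerance),
                 require_same_type = isTRUE(require_same_type)),
            class = "match_params")
}

#' Do two SV records denote the same call?
#'
#' @param a,b Single records (one-row data.frames or lists with fields
#'   `chrom`, `start`, `end`, `sv_type`).
#' @param params A [match_params()].
#' @return TRUE iff same chromosome, same type (when required), and both
#'   start and end offsets are within the tolerance.
#' @export
records_match <- function(a, b, params = match_params()) {
  a$chrom == b$chrom &&
    (!params$require_same_type || a$sv_type == b$sv_type) &&
    abs(a$start - b$start) <= params$tolerance &&
    abs(a$end - b$end) <= params$tolerance
}

# all matching (i, j) index pairs between two record tables, with
# distances; split by chromosome (and type) so only candidate blocks are
# compared
match_candidates <- function(ra, rb, params) {
  if (nrow(ra) == 0 || nrow(rb) == 0)
    return(data.frame(i = integer(0), j = integer(0),
                      d_start = integer(0), d_end = integer(0)))
  key_a <- if (params$require_same_type)
    paste(ra$chrom, ra$sv_type) else ra$chrom
  key_b <- if (params$require_same_type)
    paste(rb$chrom, rb$sv_type) else rb$chrom
  out <- list()
  for (k in intersect(unique(key_a), unique(key_b))) {
    ia <- which(key_a == k); ib <- which(key_b == k)
    ds <- abs(outer(ra$start[ia], rb$start[ib], "-"))
    de <- abs(outer(ra$end[ia], rb$end[ib], "-"))
    hit <- which(ds <= params$tolerance & de <= params$tolerance,
                 arr.ind = TRUE)
    if (nrow(hit) > 0)
      out[[length(out) + 1L]] <- data.frame(
        i = ia[hit[, 1]], j = ib[hit[, 2]],
        d_start = ds[hit], d_end = de[hit])
  }
  if (length(out) == 0)
    return(data.frame(i = integer(0), j = integer(0),
                      d_start = integer(0), d_end = integer(0)))
  do.call(rbind, out)
}

#' One-to-one pairing of two call sets under the tolerance rule
#'
#' Resolves the (non-transitive) identity relation into a one-to-one
#' pairing: candidate pairs are taken greedily by ascending total
#' coordinate distance (`|start offset| + |end offset|`), ties broken by
#' (chromosome, start, record id) lexicographically.
#'
#' @param A,B `sv_callset` objects.
#' @param params A [match_params()].
#' @return An object of class `sv_match_pairing`: list with `pairs`
#'   (data.frame `id_a`, `id_b`, `d_start`, `d_end`), `unmatched_a`,
#'   `unmatched_b` (character vectors of record ids).
#' @export
match_sets <- function(A, B, params = match_params()) {
  stopifnot(inherits(A, "sv_callset"), inherits(B, "sv_callset"))
  ra <- A$records; rb <- B$records
  cand <- match_candidates(ra, rb, params)
  if (nrow(cand) > 0) {
    ord <- order(cand$d_start + cand$d_end,
                 ra$chrom[cand$i], ra$start[cand$i], ra$id[cand$i],
                 rb$id[cand$j], method = "radix")
    cand <- cand[ord, , drop = FALSE]
  }
  used_a <- logical(nrow(ra)); used_b <- logical(nrow(rb))
  take <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_a[i] && !used_b[j]) {
      take[r] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  sel <- cand[take, , drop = FALSE]
  pairs <- data.frame(id_a = ra$id[sel$i], id_b = rb$id[sel$j],
                      d_start = sel$d_start, d_end = sel$d_end,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 unmatched_a = ra$id[!used_a],
                 unmatched_b = rb$id[!used_b]),
            class = "sv_match_pairing")
}

#' @export
print.sv_match_pairing <- function(x, ...) {
  cat(sprintf("<sv_match_pairing> %d pairs, %d unmatched in A, %d in B\n",
              nrow(x$pairs), length(x$unmatched_a), length(x$unmatched_b)))
  invisible(x)
}

#' Pool call sets by concatenation
#'
#' Pooling concatenates records without deduplication, so the pooled
#' size equals the sum of the input sizes even when replicates share
#' calls (the arithmetic used to assemble a pedigree reference from
#' replicate call sets: 248 + 339 + 291 = 878). Each record keeps a
#' `source_sample` provenance tag and ids are prefixed with their sample
#' of origin.
#'
#' @param sets A list of `sv_callset` objects (distinct `sample_id`s).
#' @param sample_id Identifier for the pooled set.
#' @return An `sv_callset` whose records carry a `source_sample`
#'   provenance attribute.
#' @export
pool <- function(sets, sample_id = NULL) {
  if (inherits(sets, "sv_callset")) sets <- list(sets)
  stopifnot(length(sets) >= 1,
            all(vapply(sets, inherits, logical(1), "sv_callset")))
  ids <- vapply(sets, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample_ids in pool: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  recs <- lapply(sets, function(s) {
    r <- s$records
    if (nrow(r) > 0) r$id <- paste(s$sample_id, r$id, sep = ":")
    r$source_sample <- rep(s$sample_id, nrow(r))
    r
  })
  all_rec <- do.call(rbind, recs)
  prov <- all_rec$source_sample
  names(prov) <- all_rec$id
  all_rec$source_sample <- NULL
  geno <- unique(vapply(sets, `[[`, character(1), "genotype"))
  trt <- unique(vapply(sets, `[[`, character(1), "treatment"))
  out <- sv_callset(all_rec,
                    sample_id = if (is.null(sample_id))
                      paste0("pool(", paste(ids, collapse = "+"), ")")
                    else sample_id,
                    genotype = if (length(geno) == 1) geno else "other",
                    treatment = if (length(trt) == 1) trt else "none",
                    replicate = 1L)
  attr(out, "provenance") <- prov
  out
}

#' Subtract control calls from a target call set
#'
#' Removes every target record that matches at least one record in the
#' pooled controls under the tolerance identity rule; what remains are
#' the target-specific (e.g. radiation-induced) calls. An audit trail
#' names, for each removed record, the control record that removed it.
#'
#' @param target An `sv_callset`.
#' @param controls A list of `sv_callset` objects (possibly empty), or a
#'   single `sv_callset`.
#' @param params A [match_params()].
#' @return The remaining `sv_callset`; attribute `"audit"` is a
#'   data.frame of removed record ids and the matching control id.
#' @export
subtract <- function(target, controls, params = match_params()) {
  stopifnot(inherits(target, "sv_callset"))
  if (inherits(controls, "sv_callset")) controls <- list(controls)
  out <- target
  if (length(controls) == 0) {
    attr(out, "audit") <- data.frame(id = character(0),
                                     removed_by = character(0),
                                     stringsAsFactors = FALSE)
    return(out)
  }
  ctrl <- pool(controls)
  cand <- match_candidates(target$records, ctrl$records, params)
  removed <- sort(unique(cand$i))
  first_hit <- vapply(removed, function(i)
    ctrl$records$id[min(cand$j[cand$i == i])], character(1))
  keep <- setdiff(seq_len(nrow(target$records)), removed)
  out$records <- sort_records(target$records[keep, , drop = FALSE])
  attr(out, "audit") <- data.frame(id = target$records$id[removed],
                                   removed_by = first_hit,
                                   stringsAsFactors = FALSE)
  out
}

#' Three-way replicate Venn partition under tolerant identity
#'
#' The tolerance rule is not transitive, so the partition is defined on
#' connected components of the match graph: nodes are all records of the
#' three sets, edges join matching records from *different* sets. Each
#' component is counted in the Venn region given by the set labels
#' present in it. Components holding more than one record from a single
#' sample are additionally counted as "inconsistent".
#'
#' @param A,B,C `sv_callset` objects (e.g. three biological replicates).
#' @param params A [match_params()].
#' @return An object of class `sv_venn`: list with `region_counts`
#'   (named vector over A, B, C, AB, AC, BC, ABC), `n_components`,
#'   `n_inconsistent`, and `components` (data.frame mapping record id /
#'   sample slot to component id).
#' @export
venn_partition <- function(A, B, C, params = match_params()) {
  sets <- list(A = A, B = B, C = C)
  stopifnot(all(vapply(sets, inherits, logical(1), "sv_callset")))
  recs <- lapply(sets, `[[`, "records")
  ns <- vapply(recs, nrow, integer(1))
  slot <- rep(names(sets), ns)
  all_rec <- do.call(rbind, recs)
  n <- nrow(all_rec)
  if (n == 0) {
    regions <- setNames(integer(7),
                        c("A", "B", "C", "AB", "AC", "BC", "ABC"))
    return(structure(list(region_counts = regions, n_components = 0L,
                          n_inconsistent = 0L,
                          components = data.frame(id = character(0),
                                                  slot = character(0),
                                                  component = integer(0))),
                     class = "sv_venn"))
  }
  edges <- integer(0)
  for (p in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    ia <- which(slot == p[1]); ib <- which(slot == p[2])
    cand <- match_candidates(all_rec[ia, , drop = FALSE],
                             all_rec[ib, , drop = FALSE], params)
    if (nrow(cand) > 0)
      edges <- c(edges, rbind(ia[cand$i], ib[cand$j]))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  labels <- vapply(split(slot, comp), function(s)
    paste(sort(unique(s)), collapse = ""), character(1))
  regions <- setNames(integer(7), c("A", "B", "C", "AB", "AC", "BC", "ABC"))
  tab <- table(labels)
  regions[names(tab)] <- as.integer(tab)
  inconsistent <- sum(vapply(split(slot, comp),
                             function(s) any(table(s) > 1), logical(1)))
  structure(list(region_counts = regions,
                 n_components = max(comp),
                 n_inconsistent = as.integer(inconsistent),
                 components = data.frame(id = all_rec$id, slot = slot,
                                         component = as.integer(comp),
                                         stringsAsFactors = FALSE)),
            class = "sv_venn")
}

#' @export
print.sv_venn <- function(x, ...) {
  cat("<sv_venn> components:", x$n_components,
      "(inconsistent:", x$n_inconsistent, ")\n")
  print(x$region_counts)
  invisible(x)
}

#' Identify radiation-induced SVs by control subtraction
#'
#' Composes [subtract()] according to the experimental design:
#' * treated wild type: controls are the pedigree pool (the untreated
#'   replicate call sets of the same stock);
#' * treated mutant: controls are the untreated calls of the same
#'   genotype *and* the calls of wild-type plants given the same
#'   treatment.
#'
#' @param treated The treated sample's filtered `sv_callset`.
#' @param untreated_same_genotype The untreated control(s) of the same
#'   genotype: pedigree pool for WT, untreated mutant calls for mutants.
#'   A single `sv_callset` or a list.
#' @param wt_treated For mutant samples, the WT call set under the same
#'   treatment; ignored for WT samples.
#' @param params A [match_params()].
#' @return The induced `sv_callset`; attribute `"provenance"` names each
#'   subtraction step, attribute `"audit"` the removal trail.
#' @export
induced_sv_workflow <- function(treated, untreated_same_genotype,
                                wt_treated = NULL,
                                params = match_params()) {
  stopifnot(inherits(treated, "sv_callset"))
  if (treated$treatment == "none")
    stop("sample ", treated$sample_id, " is untreated; nothing to induce")
  if (inherits(untreated_same_genotype, "sv_callset"))
    untreated_same_genotype <- list(untreated_same_genotype)
  if (length(untreated_same_genotype) == 0)
    stop("missing untreated control for ", treated$sample_id)
  controls <- untreated_same_genotype
  steps <- sprintf("subtract untreated %s calls (%s)",
                   treated$genotype,
                   paste(vapply(controls, `[[`, character(1), "sample_id"),
                         collapse = ", "))
  if (treated$genotype != "WT") {
    if (is.null(wt_treated))
      stop("mutant treated sample ", treated$sample_id,
           " requires the WT ", treated$treatment, " call set as control")
    stopifnot(inherits(wt_treated, "sv_callset"))
    controls <- c(controls, list(wt_treated))
    steps <- c(steps, sprintf("subtract WT %s-treated calls (%s)",
                              treated$treatment, wt_treated$sample_id))
  }
  out <- subtract(treated, controls, params)
  attr(out, "provenance") <- steps
  out
}
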