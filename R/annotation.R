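ELEMENT_CLASSES <- c("TE", "PCG", "IR")  # tie-break precedence order

#' Build a genome annotation from interval layers
#'
#' Assembles the interval layers used to locate SVs: protein-coding
#' genes (PCG), transposable elements (TE, with superfamily labels),
#' the derived intergenic complement (IR), chromatin states (CS1..CS9),
#' centromeric/pericentromeric windows and rearrangement hotspot (HOT)
#' regions. IR is computed per chromosome as the complement of the
#' union of PCG and TE.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param pcg,te,cs,centromeric,hot `GRanges` layers; `te` must carry a
#'   `superfamily` metadata column (missing labels become "unknown"),
#'   `cs` a `state` column.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(chrom_lengths, pcg, te,
                              cs = GenomicRanges::GRanges(),
                              centromeric = GenomicRanges::GRanges(),
                              hot = GenomicRanges::GRanges()) {
  stopifnot(!is.null(names(chrom_lengths)))
  chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  # layers are strand-agnostic: keep everything unstranded so interval
  # arithmetic (complement, overlap) never splits by strand
  unstrand <- function(gr) { BiocGenerics::strand(gr) <- "*"; gr }
  pcg <- unstrand(pcg); te <- unstrand(te); cs <- unstrand(cs)
  centromeric <- unstrand(centromeric); hot <- unstrand(hot)
  layers <- list(pcg = pcg, te = te, cs = cs, centromeric = centromeric,
                 hot = hot)
  for (nm in names(layers)) {
    gr <- layers[[nm]]
    if (length(gr) == 0) next
    bad <- as.character(GenomicRanges::seqnames(gr)) %in%
      names(chrom_lengths) &
      GenomicRanges::end(gr) > chrom_lengths[
        as.character(GenomicRanges::seqnames(gr))]
    if (any(bad))
      stop("layer '", nm, "' has intervals beyond chromosome length: ",
           paste(head(which(bad)), collapse = ", "))
    unknown <- !(as.character(GenomicRanges::seqnames(gr)) %in%
                   names(chrom_lengths))
    if (any(unknown))
      stop("layer '", nm, "' uses chromosomes absent from chrom_lengths")
  }
  if (length(te) > 0 && is.null(S4Vectors::mcols(te)$superfamily))
    S4Vectors::mcols(te)$superfamily <- "unknown"
  if (length(te) > 0) {
    sf <- S4Vectors::mcols(te)$superfamily
    sf[is.na(sf)] <- "unknown"
    S4Vectors::mcols(te)$superfamily <- sf
  }
  genome_gr <- GenomicRanges::GRanges(
    names(chrom_lengths),
    IRanges::IRanges(1L, unname(chrom_lengths)))
  genic <- GenomicRanges::reduce(c(GenomicRanges::granges(pcg),
                                   GenomicRanges::granges(te)))
  ir <- GenomicRanges::setdiff(genome_gr, genic)
  structure(list(chrom_lengths = chrom_lengths, pcg = pcg, te = te,
                 ir = ir, cs = cs, centromeric = centromeric, hot = hot),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d chromosomes, %d bp\n",
              length(x$chrom_lengths), sum(x$chrom_lengths)))
  cat(sprintf("  PCG %d, TE %d, IR %d, CS %d, centromeric %d, HOT %d intervals\n",
              length(x$pcg), length(x$te), length(x$ir), length(x$cs),
              length(x$centromeric), length(x$hot)))
  invisible(x)
}

#' Load a genome annotation from standard files
#'
#' Reads a GFF3 for genes and transposable elements, BED files for
#' chromatin states, centromeric windows and HOT regions, and a
#' two-column chromosome-sizes TSV. GFF3 features with type `gene` (or
#' `protein_coding_gene`) populate the PCG layer; types
#' `transposable_element`, `transposon_fragment` or
#' `transposable_element_gene` populate the TE layer, with the
#' superfamily read from the `superfamily` (or `Alias`) attribute. BED
#' inputs are 0-based half-open and converted on import; the BED name
#' column carries the chromatin-state label.
#'
#' @param gff_path GFF3 file path.
#' @param chrom_sizes_path TSV of chromosome name and length.
#' @param cs_bed,centromere_bed,hot_bed Optional BED4/BED3 paths.
#' @return A [genome_annotation()].
#' @export
load_annotation <- function(gff_path, chrom_sizes_path, cs_bed = NULL,
                            centromere_bed = NULL, hot_bed = NULL) {
  sizes <- read.table(chrom_sizes_path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "length"),
                      stringsAsFactors = FALSE)
  chrom_lengths <- setNames(as.integer(sizes$length), sizes$chrom)
  gff <- rtracklayer::import(gff_path, format = "gff3")
  types <- as.character(S4Vectors::mcols(gff)$type)
  pcg <- gff[types %in% c("gene", "protein_coding_gene")]
  te <- gff[types %in% c("transposable_element", "transposon_fragment",
                         "transposable_element_gene")]
  sf <- S4Vectors::mcols(te)$superfamily
  if (is.null(sf)) {
    alias <- S4Vectors::mcols(te)$Alias
    sf <- if (is.null(alias)) rep(NA_character_, length(te))
          else vapply(alias, function(a)
            if (length(a) > 0) a[[1]] else NA_character_, character(1))
  }
  sf[is.na(sf)] <- "unknown"
  te <- GenomicRanges::granges(te)
  S4Vectors::mcols(te)$superfamily <- unname(sf)
  pcg <- GenomicRanges::granges(pcg)
  read_bed <- function(path, label_col = FALSE) {
    if (is.null(path)) return(GenomicRanges::GRanges())
    gr <- rtracklayer::import(path, format = "bed")
    if (label_col) {
      st <- S4Vectors::mcols(gr)$name
      S4Vectors::mcols(gr) <- NULL
      S4Vectors::mcols(gr)$state <- st
    } else S4Vectors::mcols(gr) <- NULL
    gr
  }
  genome_annotation(chrom_lengths, pcg = pcg, te = te,
                    cs = read_bed(cs_bed, label_col = TRUE),
                    centromeric = read_bed(centromere_bed),
                    hot = read_bed(hot_bed))
}

overlap_bp <- function(query, layer) {
  # total bp of query covered by the (reduced) layer, per query range
  if (length(layer) == 0) return(rep(0L, length(query)))
  red <- GenomicRanges::reduce(GenomicRanges::granges(layer))
  hits <- GenomicRanges::findOverlaps(query, red)
  w <- IRanges::width(IRanges::pintersect(
    query[S4Vectors::queryHits(hits)], red[S4Vectors::subjectHits(hits)]))
  out <- rep(0L, length(query))
  agg <- tapply(w, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

# label of the interval in `layer` with maximal bp overlap per query
# range; ties broken by lower start then label order; NA when no overlap
max_overlap_label <- function(query, layer, labels) {
  out <- rep(NA_character_, length(query))
  if (length(layer) == 0 || length(query) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(query, layer)
  if (length(hits) == 0) return(out)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  w <- IRanges::width(IRanges::pintersect(query[qh], layer[sh]))
  df <- data.frame(q = qh, s = sh, w = w,
                   start = GenomicRanges::start(layer)[sh],
                   lab = labels[sh], stringsAsFactors = FALSE)
  # aggregate by label within query: a state split across intervals
  # competes with its total overlap
  agg <- aggregate(w ~ q + lab, data = df, FUN = sum)
  agg <- agg[order(agg$q, -agg$w, agg$lab, method = "radix"), ]
  first <- !duplicated(agg$q)
  out[agg$q[first]] <- agg$lab[first]
  out
}

#' Assign SV records to genetic elements and genomic contexts
#'
#' Each record is assigned to exactly one element class — the layer
#' (TE, PCG or IR) with maximal bp overlap over its query interval,
#' ties broken by the precedence TE > PCG > IR. Insertions are queried
#' as their 1-bp anchor. In addition: the TE superfamily of the
#' maximally-overlapping TE, the chromatin state with maximal overlap
#' (NA when none covers the record), centromeric membership (interval
#' midpoint inside a centromeric window) and HOT membership (any
#' overlap of at least 1 bp).
#'
#' @param calls An `sv_callset`.
#' @param ann A [genome_annotation()].
#' @return A data.frame with one row per record: `id`, `sv_type`,
#'   `element_class`, `te_superfamily`, `overlap_bp`, `chromatin_state`,
#'   `centromeric`, `hot`.
#' @export
assign_elements <- function(calls, ann) {
  stopifnot(inherits(calls, "sv_callset"),
            inherits(ann, "genome_annotation"))
  rec <- calls$records
  missing_chr <- setdiff(unique(rec$chrom), names(ann$chrom_lengths))
  if (length(missing_chr) > 0)
    stop("record chromosome(s) absent from annotation: ",
         paste(missing_chr, collapse = ", "))
  query <- callset_granges(calls)
  if (length(query) == 0)
    return(data.frame(id = character(0), sv_type = character(0),
                      element_class = character(0),
                      te_superfamily = character(0),
                      overlap_bp = integer(0),
                      chromatin_state = character(0),
                      centromeric = logical(0), hot = logical(0),
                      stringsAsFactors = FALSE))
  ov <- cbind(TE = overlap_bp(query, ann$te),
              PCG = overlap_bp(query, ann$pcg),
              IR = overlap_bp(query, ann$ir))
  ov <- ov[, ELEMENT_CLASSES, drop = FALSE]
  pick <- apply(ov, 1L, which.max)  # column order = precedence on ties
  element <- ELEMENT_CLASSES[pick]
  best_bp <- ov[cbind(seq_len(nrow(ov)), pick)]
  sf <- max_overlap_label(query, ann$te,
                          S4Vectors::mcols(ann$te)$superfamily)
  sf[element != "TE"] <- NA_character_
  cs <- max_overlap_label(query, ann$cs, S4Vectors::mcols(ann$cs)$state)
  mid <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(query)),
    IRanges::IRanges(floor((GenomicRanges::start(query) +
                              GenomicRanges::end(query)) / 2), width = 1L))
  centro <- if (length(ann$centromeric) == 0) rep(FALSE, length(query))
            else IRanges::overlapsAny(mid, ann$centromeric)
  hot <- if (length(ann$hot) == 0) rep(FALSE, length(query))
         else IRanges::overlapsAny(query, ann$hot)
  data.frame(id = rec$id, sv_type = rec$sv_type,
             element_class = element, te_superfamily = sf,
             overlap_bp = as.integer(best_bp), chromatin_state = cs,
             centromeric = centro, hot = hot, stringsAsFactors = FALSE)
}

#' Assign a single SV record
#'
#' Single-record convenience wrapper around [assign_elements()].
#'
#' @param record A one-row records data.frame.
#' @param ann A [genome_annotation()].
#' @param calls Optional `sv_callset` the record belongs to (metadata).
#' @return A one-row assignment data.frame.
#' @export
assign_element <- function(record, ann, calls = NULL) {
  cs <- sv_callset(record,
                   sample_id = if (is.null(calls)) "one" else calls$sample_id)
  assign_elements(cs, ann)
}

layer_bp <- function(gr, what = NULL) {
  sum(as.numeric(IRanges::width(GenomicRanges::reduce(
    GenomicRanges::granges(gr)))))
}

#' Element, chromatin-state and context distribution of a call set
#'
#' Tabulates assignments from [assign_elements()]: counts per element
#' class, per SV type x element class, per TE superfamily, per
#' chromatin state (with CS8/CS9 additionally grouped as constitutive
#' heterochromatin, "CH"), the centromeric fraction and HOT overlap
#' count. The genome background is reported both as bp fraction of each
#' layer (default comparison baseline) and as element-count fraction.
#'
#' @param calls An `sv_callset`.
#' @param ann A [genome_annotation()].
#' @return A list of class `sv_element_distribution`: `element_counts`,
#'   `type_by_element` (matrix), `superfamily_counts`, `cs_counts`,
#'   `cs_grouped`, `centromeric_fraction`, `hot_count`, `hot_fraction`,
#'   `background_bp`, `background_counts`, `assignments`.
#' @export
element_distribution <- function(calls, ann) {
  asg <- assign_elements(calls, ann)
  el <- table(factor(asg$element_class, levels = ELEMENT_CLASSES))
  tby <- table(factor(asg$sv_type, levels = SV_TYPES),
               factor(asg$element_class, levels = ELEMENT_CLASSES))
  sfc <- table(asg$te_superfamily[!is.na(asg$te_superfamily)])
  cs_levels <- paste0("CS", 1:9)
  csc <- table(factor(asg$chromatin_state,
                      levels = union(cs_levels,
                                     unique(asg$chromatin_state[
                                       !is.na(asg$chromatin_state)]))))
  grouped <- c(CH = sum(csc[intersect(c("CS8", "CS9"), names(csc))]),
               other = sum(csc) -
                 sum(csc[intersect(c("CS8", "CS9"), names(csc))]))
  n <- nrow(asg)
  bg_bp <- c(TE = layer_bp(ann$te), PCG = layer_bp(ann$pcg),
             IR = layer_bp(ann$ir))
  bg_counts <- c(TE = length(ann$te), PCG = length(ann$pcg),
                 IR = length(ann$ir))
  structure(list(
    element_counts = setNames(as.integer(el), names(el)),
    type_by_element = unclass(tby),
    superfamily_counts = setNames(as.integer(sfc), names(sfc)),
    cs_counts = setNames(as.integer(csc), names(csc)),
    cs_grouped = grouped,
    centromeric_fraction = if (n > 0) mean(asg$centromeric) else NA_real_,
    hot_count = sum(asg$hot),
    hot_fraction = if (n > 0) mean(asg$hot) else NA_real_,
    background_bp = bg_bp / sum(bg_bp),
    background_counts = bg_counts / sum(bg_counts),
    assignments = asg), class = "sv_element_distribution")
}

#' @export
print.sv_element_distribution <- function(x, ...) {
  cat("<sv_element_distribution>\n  elements: ")
  print(x$element_counts)
  cat(sprintf("  centromeric fraction %.3f, HOT count %d\n",
              x$centromeric_fraction, x$hot_count))
  invisible(x)
}

#' Circos-ready BED track of SV positions
#'
#' @param calls An `sv_callset`.
#' @param path Output BED path (0-based half-open; name = sv_type).
#' @return `path` invisibly.
#' @export
write_sv_bed <- function(calls, path) {
  rec <- calls$records
  ins <- rec$sv_type == "INS"
  bed <- data.frame(chrom = rec$chrom,
                    start = rec$start - 1L,
                    end = ifelse(ins, rec$start, rec$end),
                    name = rec$sv_type)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
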