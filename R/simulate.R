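TE_SUPERFAMILIES <- c("LTR/Gypsy", "LTR/Copia", "MuDR", "DNA/HAT", "LINE/L1")

#' Scenario specification for the synthetic-data generator
#'
#' Defines a hermetic study scenario: a toy genome with annotated
#' layers, three untreated replicate call sets sharing a pedigree core,
#' and a treated sample carrying the pedigree plus implanted induced
#' SVs with known ground truth. All randomness flows from `seed`.
#'
#' Defaults emulate the structure of the irradiation study at desk
#' scale: INDEL-dominant type mix, a replicate-shared pedigree core,
#' an NHEJ-dominant deletion-junction microhomology spectrum with an
#' MMEJ tail at 2-6 bp, insertion donors biased to the insertion's own
#' chromosome and copied as truncated TEs, and coordinate jitter small
#' enough (2 x 25 bp <= 50 bp) that tolerant matching recovers
#' replicate identity exactly.
#'
#' @param seed Integer seed (mandatory).
#' @param n_chromosomes,chrom_length Genome shape (default 3 x 150 kb).
#' @param centromere_fraction Central centromeric fraction per
#'   chromosome (default 0.2), built from a 180-bp tandem repeat.
#' @param te_density_arm,te_density_cen TE bp densities by zone.
#' @param pcg_density_arm,pcg_density_cen PCG bp densities by zone.
#' @param n_pedigree_sv,n_induced_sv Implanted SV counts (60, 40).
#' @param sv_type_mix Named proportions over DEL/INS/DUP/INV/INVDUP.
#' @param deletion_mh_spectrum Named proportions over junction
#'   microhomology lengths (names "0".."25").
#' @param element_mix Optional named proportions over TE/PCG/IR: when
#'   given, SV loci are placed fully inside elements of the sampled
#'   class; when `NULL` (default) loci are placed uniformly.
#' @param intrachromosomal_bias Probability an insertion's donor lies
#'   on the insertion's own chromosome (default 0.7).
#' @param donor_element_mix Donor element-class proportions for
#'   insertions (default TE .5, IR .4, PCG .1).
#' @param te_truncation_fraction Fraction of TE-donor insertions copied
#'   as truncated TEs (default 1: full-span TE copies are not emitted,
#'   matching the absence of clean transposition signatures).
#' @param revcomp_fraction Fraction of insertion donors copied in
#'   reverse complement (default 0.25).
#' @param replicate_core_fraction Pedigree fraction shared by all three
#'   replicates (default 0.5).
#' @param jitter_sd Half-width of the per-record uniform coordinate
#'   jitter applied to pedigree calls in each emitted sample, bp
#'   (default 25; two jittered copies then differ by at most 50 bp).
#' @param false_negative_rate Per-record drop-out rate at emission.
#' @param del_length_range,ins_length_range,other_length_range SV
#'   length ranges, bp.
#' @param treatment Treatment label of the treated sample.
#' @param genotype Genotype of the scenario's samples.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(seed,
                          n_chromosomes = 3L, chrom_length = 150000L,
                          centromere_fraction = 0.2,
                          te_density_arm = 0.15, te_density_cen = 0.5,
                          pcg_density_arm = 0.3, pcg_density_cen = 0.05,
                          n_pedigree_sv = 60L, n_induced_sv = 40L,
                          sv_type_mix = c(DEL = 0.45, INS = 0.35,
                                          DUP = 0.08, INV = 0.07,
                                          INVDUP = 0.05),
                          deletion_mh_spectrum = c("0" = 0.60, "1" = 0.25,
                                                   "2" = 0.05, "3" = 0.04,
                                                   "4" = 0.03, "5" = 0.02,
                                                   "6" = 0.01),
                          element_mix = NULL,
                          intrachromosomal_bias = 0.7,
                          donor_element_mix = c(TE = 0.5, IR = 0.4,
                                                PCG = 0.1),
                          te_truncation_fraction = 1,
                          revcomp_fraction = 0.25,
                          replicate_core_fraction = 0.5,
                          jitter_sd = 25L,
                          false_negative_rate = 0,
                          del_length_range = c(50L, 2000L),
                          ins_length_range = c(40L, 200L),
                          other_length_range = c(100L, 1000L),
                          treatment = "UV_B", genotype = "WT") {
  stopifnot(!missing(seed), is.numeric(seed))
  stopifnot(abs(sum(sv_type_mix) - 1) < 1e-9,
            abs(sum(deletion_mh_spectrum) - 1) < 1e-9,
            is.null(element_mix) || abs(sum(element_mix) - 1) < 1e-9,
            replicate_core_fraction >= 0, replicate_core_fraction <= 1,
            false_negative_rate >= 0, false_negative_rate < 1,
            jitter_sd >= 0)
  structure(as.list(environment()), class = "scenario_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample a [start, start+len-1] interval inside [lo, hi] leaving
# `margin` bp to every interval in `occ` (IRanges); NULL if no room
sample_free_interval <- function(len, lo, hi, occ, margin = 300L,
                                 tries = 300L) {
  if (hi - len + 1L < lo) return(NULL)
  for (t in seq_len(tries)) {
    s <- sample(seq.int(lo, hi - len + 1L), 1L)
    cand <- IRanges::IRanges(s - margin, s + len - 1L + margin)
    if (length(occ) == 0 ||
        sum(IRanges::countOverlaps(cand, occ)) == 0)
      return(c(start = s, end = s + len - 1L))
  }
  NULL
}

#' Generate a toy annotated genome
#'
#' Builds a deterministic random genome: chromosome arms of random
#' sequence, a central centromeric zone made of a mutated 180-bp tandem
#' repeat, non-overlapping PCG and TE intervals placed to the requested
#' bp densities by zone (TE superfamilies sampled from a fixed panel),
#' chromatin states CS8/CS9 tiled over the centromeric zone and CS1-CS7
#' over the arms, and HOT regions sampled on the arms.
#'
#' @param spec A [scenario_spec()].
#' @return A list of class `sv_genome_bundle`: `seqs` (named character
#'   vector), `annotation` ([genome_annotation()]), `centromeres`
#'   (data.frame), `repeat_unit`, `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  chroms <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  L <- spec$chrom_length
  repeat_unit <- random_dna(180L)
  seqs <- character(0)
  cen <- list()
  pcg <- list(); te <- list(); cs <- list(); hot <- list()
  for (ci in seq_along(chroms)) {
    cen_len <- round(spec$centromere_fraction * L)
    cen_start <- floor((L - cen_len) / 2) + 1L
    cen_end <- cen_start + cen_len - 1L
    # centromeric zone: tandem 180-bp repeat with 3% per-copy mutation
    n_copies <- ceiling(cen_len / 180)
    copies <- vapply(seq_len(n_copies), function(i) {
      u <- strsplit(repeat_unit, "")[[1]]
      nmut <- stats::rbinom(1, 180, 0.03)
      if (nmut > 0) {
        at <- sample(180, nmut)
        u[at] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
      }
      paste(u, collapse = "")
    }, character(1))
    cen_seq <- substr(paste(copies, collapse = ""), 1L, cen_len)
    seqs[chroms[ci]] <- paste0(random_dna(cen_start - 1L), cen_seq,
                               random_dna(L - cen_end))
    cen[[ci]] <- data.frame(chrom = chroms[ci], start = cen_start,
                            end = cen_end)
    # feature placement to target bp densities, arms vs centromere
    occ <- IRanges::IRanges()
    place_layer <- function(target_bp, len_range, lo, hi, occ) {
      placed <- list()
      got <- 0L
      while (target_bp - got >= len_range[1]) {
        len <- sample(seq.int(len_range[1],
                              min(len_range[2], target_bp - got)), 1L)
        iv <- sample_free_interval(len, lo, hi, occ, margin = 2L,
                                   tries = 200L)
        if (is.null(iv)) break
        occ <- c(occ, IRanges::IRanges(iv["start"], iv["end"]))
        placed[[length(placed) + 1L]] <- iv
        got <- got + len
      }
      list(placed = placed, occ = occ)
    }
    zones <- list(arm_l = c(1L, cen_start - 1L),
                  cen = c(cen_start, cen_end),
                  arm_r = c(cen_end + 1L, L))
    for (zn in names(zones)) {
      z <- zones[[zn]]
      zl <- z[2] - z[1] + 1L
      dens_te <- if (zn == "cen") spec$te_density_cen else
        spec$te_density_arm
      dens_pcg <- if (zn == "cen") spec$pcg_density_cen else
        spec$pcg_density_arm
      r <- place_layer(round(dens_te * zl), c(500L, 2500L), z[1], z[2],
                       occ)
      occ <- r$occ
      for (iv in r$placed)
        te[[length(te) + 1L]] <- data.frame(
          chrom = chroms[ci], start = iv["start"], end = iv["end"],
          superfamily = sample(TE_SUPERFAMILIES, 1L))
      r <- place_layer(round(dens_pcg * zl), c(1000L, 3000L), z[1], z[2],
                       occ)
      occ <- r$occ
      for (iv in r$placed)
        pcg[[length(pcg) + 1L]] <- data.frame(
          chrom = chroms[ci], start = iv["start"], end = iv["end"])
    }
    # chromatin states: 2-kb tiles; CS8/9 over the centromeric zone
    tile_starts <- seq.int(1L, L, by = 2000L)
    for (ts in tile_starts) {
      tend <- min(ts + 1999L, L)
      mid <- (ts + tend) %/% 2
      state <- if (mid >= cen_start && mid <= cen_end)
        sample(c("CS8", "CS9"), 1L) else sample(paste0("CS", 1:7), 1L)
      cs[[length(cs) + 1L]] <- data.frame(chrom = chroms[ci], start = ts,
                                          end = tend, state = state)
    }
    for (h in seq_len(4L)) {
      side <- if (h %% 2 == 0) zones$arm_l else zones$arm_r
      len <- sample(2000:5000, 1L)
      s <- sample(seq.int(side[1], side[2] - len), 1L)
      hot[[length(hot) + 1L]] <- data.frame(chrom = chroms[ci], start = s,
                                            end = s + len - 1L)
    }
  }
  df2gr <- function(lst, extra = NULL) {
    if (length(lst) == 0) return(GenomicRanges::GRanges())
    df <- do.call(rbind, lst)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end))
    if (!is.null(extra)) S4Vectors::mcols(gr)[[extra]] <- df[[extra]]
    gr
  }
  cen_df <- do.call(rbind, cen)
  ann <- genome_annotation(
    setNames(rep(L, length(chroms)), chroms),
    pcg = df2gr(pcg), te = df2gr(te, "superfamily"),
    cs = df2gr(cs, "state"),
    centromeric = GenomicRanges::GRanges(
      cen_df$chrom, IRanges::IRanges(cen_df$start, cen_df$end)),
    hot = df2gr(hot))
  structure(list(seqs = seqs, annotation = ann, centromeres = cen_df,
                 repeat_unit = repeat_unit, spec = spec),
            class = "sv_genome_bundle")
}

mutate_to_differ <- function(base_avoid) {
  sample(setdiff(c("A", "C", "G", "T"), base_avoid), 1L)
}

# rewrite `seqs[[chrom]]` so the deletion [s, e) (0-based half-open)
# has junction microhomology exactly m: copy R[s+1..s+m] over
# R[e+1..e+m] (1-based), then mismatch-guard both flanks
implant_deletion_mh <- function(seq, s, e, m) {
  if (m > 0)
    for (i in seq_len(m))
      substr(seq, e + i, e + i) <- substr(seq, s + i, s + i)
  if (substr(seq, s + m + 1L, s + m + 1L) ==
      substr(seq, e + m + 1L, e + m + 1L))
    substr(seq, e + m + 1L, e + m + 1L) <-
      mutate_to_differ(substr(seq, s + m + 1L, s + m + 1L))
  if (substr(seq, s, s) == substr(seq, e, e))
    substr(seq, e, e) <- mutate_to_differ(substr(seq, s, s))
  seq
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Implant ground-truth SVs into a generated genome
#'
#' Plans pedigree and induced SVs per the scenario's type mix and
#' places them at mutually distant loci (>= 300 bp apart, clear of
#' chromosome ends). Deletions are junction-engineered: the reference
#' is rewritten so that exactly the planned number of bases extend
#' across the deletion junction, with mismatch guards on both sides,
#' making the truth microhomology exact by construction. Insertions
#' copy a donor segment of the planned element class (TE donors as
#' truncated sub-spans by default, optionally reverse-complemented),
#' honoring the intrachromosomal bias; donors avoid the repeat-rich
#' centromeric zone so they stay unique. DUP/INV/INVDUP occupy
#' non-overlapping loci.
#'
#' @param gb An `sv_genome_bundle` from [generate_genome()].
#' @param spec The same [scenario_spec()].
#' @return A list of class `sv_truth_bundle`: `truth` (manifest
#'   data.frame), `seqs` (edited genome), `annotation`, `spec`.
#' @export
implant_svs <- function(gb, spec = gb$spec) {
  stopifnot(inherits(gb, "sv_genome_bundle"))
  set.seed(spec$seed + 1L)
  seqs <- gb$seqs
  ann <- gb$annotation
  chroms <- names(seqs)
  L <- spec$chrom_length
  occ <- lapply(setNames(chroms, chroms), function(x) IRanges::IRanges())
  edge <- 400L
  n_total <- spec$n_pedigree_sv + spec$n_induced_sv
  cohort <- rep(c("pedigree", "induced"),
                c(spec$n_pedigree_sv, spec$n_induced_sv))
  types <- sample(names(spec$sv_type_mix), n_total, replace = TRUE,
                  prob = spec$sv_type_mix)
  mh_levels <- as.integer(names(spec$deletion_mh_spectrum))
  # arm-only element intervals for targeted placement and donors
  arm_layer <- function(layer) {
    out <- GenomicRanges::setdiff(GenomicRanges::granges(layer),
                                  ann$centromeric)
    out[IRanges::width(out) >= 60]
  }
  layers_arm <- list(TE = arm_layer(ann$te), PCG = arm_layer(ann$pcg),
                     IR = arm_layer(ann$ir))
  pick_site <- function(len, target_class = NULL, want_chrom = NULL) {
    for (t in seq_len(400L)) {
      if (is.null(target_class)) {
        chrom <- if (is.null(want_chrom)) sample(chroms, 1L) else
          want_chrom
        iv <- sample_free_interval(len, edge, L - edge, occ[[chrom]])
        if (!is.null(iv)) return(list(chrom = chrom, start = iv[["start"]],
                                      end = iv[["end"]]))
      } else {
        lay <- layers_arm[[target_class]]
        if (!is.null(want_chrom))
          lay <- lay[as.character(GenomicRanges::seqnames(lay)) ==
                       want_chrom]
        lay <- lay[IRanges::width(lay) >= len + 4L]
        if (length(lay) == 0) return(NULL)
        k <- sample(length(lay), 1L)
        h <- lay[k]
        chrom <- as.character(GenomicRanges::seqnames(h))
        lo <- max(edge, GenomicRanges::start(h) + 2L)
        hi <- min(L - edge, GenomicRanges::end(h) - 2L)
        if (hi - lo + 1L < len) next
        iv <- sample_free_interval(len, lo, hi, occ[[chrom]])
        if (!is.null(iv)) return(list(chrom = chrom, start = iv[["start"]],
                                      end = iv[["end"]]))
      }
    }
    NULL
  }
  reserve <- function(chrom, start, end) {
    occ[[chrom]] <<- c(occ[[chrom]], IRanges::IRanges(start, end))
  }
  rows <- list()
  for (i in seq_len(n_total)) {
    tp <- types[i]
    target_class <- if (!is.null(spec$element_mix))
      sample(names(spec$element_mix), 1L, prob = spec$element_mix)
    else NULL
    row <- list(truth_id = sprintf("%s%04d",
                                   if (cohort[i] == "pedigree") "ped"
                                   else "ind", i),
                cohort = cohort[i], sv_type = tp,
                mh_total = NA_integer_, donor_chrom = NA_character_,
                donor_start = NA_integer_, donor_end = NA_integer_,
                donor_strand = NA_character_,
                donor_class = NA_character_, donor_te_coverage = NA_real_,
                inserted_seq = NA_character_)
    if (tp == "DEL") {
      len <- sample(seq.int(spec$del_length_range[1],
                            spec$del_length_range[2]), 1L)
      site <- pick_site(len, target_class)
      if (is.null(site)) stop("unable to place DEL; lower counts")
      m <- sample(mh_levels, 1L, prob = spec$deletion_mh_spectrum)
      # VCF convention: POS anchors the base before the deleted run
      s0 <- site$start - 1L           # 0-based deletion start
      e0 <- s0 + len
      seqs[[site$chrom]] <- implant_deletion_mh(seqs[[site$chrom]],
                                                s0, e0, m)
      row$chrom <- site$chrom; row$start <- s0; row$end <- e0
      row$length <- len; row$mh_total <- m
      reserve(site$chrom, site$start, site$end)
    } else if (tp == "INS") {
      dclass <- sample(names(spec$donor_element_mix), 1L,
                       prob = spec$donor_element_mix)
      truncate_te <- dclass == "TE" &&
        stats::runif(1) < spec$te_truncation_fraction
      # donor segment fully inside an arm element of the wanted class
      donor <- NULL
      for (t in seq_len(200L)) {
        lay <- layers_arm[[dclass]]
        lay <- lay[IRanges::width(lay) >=
                     max(spec$ins_length_range[1] + 4L, 60L)]
        if (length(lay) == 0) break
        h <- lay[sample(length(lay), 1L)]
        hw <- IRanges::width(h)
        dlen <- if (truncate_te)
          max(spec$ins_length_range[1],
              min(spec$ins_length_range[2], round(hw * stats::runif(1, 0.3, 0.7))))
        else sample(seq.int(spec$ins_length_range[1],
                            min(spec$ins_length_range[2], hw - 4L)), 1L)
        if (dlen > hw - 4L) next
        dchrom <- as.character(GenomicRanges::seqnames(h))
        dstart <- sample(seq.int(GenomicRanges::start(h) + 2L,
                                 GenomicRanges::end(h) - 2L - dlen + 1L),
                         1L)
        dend <- dstart + dlen - 1L
        if (sum(IRanges::countOverlaps(
          IRanges::IRanges(dstart - 150L, dend + 150L),
          occ[[dchrom]])) > 0) next
        donor <- list(chrom = dchrom, start = dstart, end = dend,
                      host_width = hw)
        break
      }
      if (is.null(donor)) stop("unable to place INS donor; lower counts")
      intra <- stats::runif(1) < spec$intrachromosomal_bias
      want_chrom <- if (intra) donor$chrom else
        sample(setdiff(chroms, donor$chrom), 1L)
      site <- pick_site(1L, target_class, want_chrom)
      if (is.null(site)) stop("unable to place INS site; lower counts")
      strand <- if (stats::runif(1) < spec$revcomp_fraction) "-" else "+"
      dseq <- substr(seqs[[donor$chrom]], donor$start, donor$end)
      if (strand == "-") dseq <- revcomp_chr(dseq)
      row$chrom <- site$chrom; row$start <- site$start
      row$end <- site$start; row$length <- nchar(dseq)
      row$inserted_seq <- dseq
      row$donor_chrom <- donor$chrom; row$donor_start <- donor$start
      row$donor_end <- donor$end; row$donor_strand <- strand
      row$donor_class <- dclass
      row$donor_te_coverage <- if (dclass == "TE")
        (donor$end - donor$start + 1) / donor$host_width else NA_real_
      reserve(site$chrom, site$start, site$start)
      reserve(donor$chrom, donor$start, donor$end)
    } else {
      len <- sample(seq.int(spec$other_length_range[1],
                            spec$other_length_range[2]), 1L)
      site <- pick_site(len, target_class)
      if (is.null(site)) stop("unable to place ", tp, "; lower counts")
      row$chrom <- site$chrom; row$start <- site$start
      row$end <- site$start + len; row$length <- len
      reserve(site$chrom, site$start, site$end)
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    truth <- data.frame(truth_id = character(0), cohort = character(0),
                        sv_type = character(0), mh_total = integer(0),
                        donor_chrom = character(0),
                        donor_start = integer(0), donor_end = integer(0),
                        donor_strand = character(0),
                        donor_class = character(0),
                        donor_te_coverage = numeric(0),
                        inserted_seq = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        length = integer(0), rep1 = logical(0),
                        rep2 = logical(0), rep3 = logical(0),
                        in_treated = logical(0),
                        element_class = character(0),
                        stringsAsFactors = FALSE)
    return(structure(list(truth = truth, seqs = seqs, annotation = ann,
                          spec = spec), class = "sv_truth_bundle"))
  }
  truth <- do.call(rbind, rows)
  # replicate membership of pedigree SVs: a shared core in all three,
  # the rest in one (70%) or two (30%) replicates
  ped <- which(truth$cohort == "pedigree")
  n_core <- round(spec$replicate_core_fraction * length(ped))
  member <- matrix(FALSE, nrow(truth), 3,
                   dimnames = list(NULL, paste0("rep", 1:3)))
  core <- ped[seq_len(n_core)]
  member[core, ] <- TRUE
  for (i in setdiff(ped, core)) {
    k <- if (stats::runif(1) < 0.7) 1L else 2L
    member[i, sample(3L, k)] <- TRUE
  }
  # the treated plant carries the core plus a random half of the rest
  in_treated <- truth$cohort == "induced"
  in_treated[core] <- TRUE
  for (i in setdiff(ped, core)) in_treated[i] <- stats::runif(1) < 0.5
  truth <- cbind(truth, member,
                 in_treated = in_treated)
  # realized element class at each truth locus (from the truth coords)
  tr_rec <- data.frame(id = truth$truth_id, chrom = truth$chrom,
                       start = truth$start, end = truth$end,
                       sv_type = truth$sv_type, length = truth$length,
                       inserted_seq = truth$inserted_seq,
                       read_support = 10L,
                       min_supporting_read_length = 5000L,
                       mapping_quality = 60,
                       stringsAsFactors = FALSE)
  asg <- assign_elements(sv_callset(tr_rec, sample_id = "truth"), ann)
  truth$element_class <- asg$element_class[match(truth$truth_id, asg$id)]
  structure(list(truth = truth, seqs = seqs, annotation = ann,
                 spec = spec), class = "sv_truth_bundle")
}

truth_records <- function(truth) {
  if (nrow(truth) == 0) return(empty_records())
  data.frame(id = truth$truth_id, chrom = truth$chrom,
             start = truth$start, end = truth$end,
             sv_type = truth$sv_type, length = truth$length,
             inserted_seq = truth$inserted_seq, read_support = 10L,
             min_supporting_read_length = 5000L, mapping_quality = 60,
             stringsAsFactors = FALSE)
}

jitter_records <- function(rec, jitter_sd) {
  if (nrow(rec) == 0 || jitter_sd == 0) return(rec)
  off <- sample(seq.int(-jitter_sd, jitter_sd), nrow(rec), replace = TRUE)
  rec$start <- pmax(1L, rec$start + off)
  ins <- rec$sv_type == "INS"
  rec$end <- ifelse(ins, rec$start, rec$end + off)
  rec
}

#' Emit per-sample call sets (and VCFs) from a truth bundle
#'
#' Builds the scenario's samples: three untreated replicates holding
#' each pedigree SV per its replicate membership, and one treated
#' sample holding its pedigree complement plus all induced SVs.
#' Pedigree records are independently coordinate-jittered in every
#' sample (uniform on `[-jitter_sd, jitter_sd]`); induced records are
#' reported at their precise breakpoints, as they exist in only one
#' sample. False negatives are dropped at the configured rate.
#'
#' @param tb An `sv_truth_bundle` from [implant_svs()].
#' @param spec The same [scenario_spec()].
#' @param dir Optional directory: when given, one VCF per sample is
#'   written there.
#' @param force Allow `2 * jitter_sd` to exceed the 50 bp matching
#'   tolerance (breaks the subtraction recovery contract).
#' @return A list of class `sv_emitted`: `callsets` (named list of
#'   `sv_callset`: rep1..rep3, treated), `mapping` (sample/record/truth
#'   table), `truth`.
#' @export
emit_callsets <- function(tb, spec = tb$spec, dir = NULL, force = FALSE) {
  stopifnot(inherits(tb, "sv_truth_bundle"))
  if (2L * spec$jitter_sd > 50L && !force)
    stop("2 * jitter_sd exceeds the 50 bp matching tolerance; ",
         "pass force = TRUE for a stress scenario")
  set.seed(spec$seed + 2L)
  truth <- tb$truth
  rec_all <- truth_records(truth)
  samples <- list()
  mapping <- list()
  take <- function(sel, sample_id, treatment, replicate, jitter = TRUE) {
    rec <- rec_all[sel, , drop = FALSE]
    if (spec$false_negative_rate > 0 && nrow(rec) > 0)
      rec <- rec[stats::runif(nrow(rec)) >= spec$false_negative_rate, ,
                 drop = FALSE]
    ped <- rec$id %in% truth$truth_id[truth$cohort == "pedigree"]
    rec[ped, ] <- jitter_records(rec[ped, , drop = FALSE], spec$jitter_sd)
    cs <- sv_callset(rec, sample_id = sample_id,
                     genotype = spec$genotype, treatment = treatment,
                     replicate = replicate)
    mapping[[length(mapping) + 1L]] <<- data.frame(
      sample = rep(sample_id, nrow(rec)), record_id = rec$id,
      truth_id = rec$id, stringsAsFactors = FALSE)
    cs
  }
  for (r in 1:3)
    samples[[paste0("rep", r)]] <-
      take(truth[[paste0("rep", r)]] & truth$cohort == "pedigree",
           sprintf("%s_untreated_rep%d", spec$genotype, r), "none", r)
  samples$treated <- take(truth$in_treated,
                          sprintf("%s_%s", spec$genotype, spec$treatment),
                          spec$treatment, 1L)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    contigs <- tb$annotation$chrom_lengths
    for (nm in names(samples))
      write_sv_vcf(samples[[nm]],
                   file.path(dir, paste0(samples[[nm]]$sample_id, ".vcf")),
                   contigs = contigs)
  }
  structure(list(callsets = samples,
                 mapping = do.call(rbind, mapping), truth = truth),
            class = "sv_emitted")
}

#' Run the full synthetic scenario generator
#'
#' Convenience wrapper: [generate_genome()], [implant_svs()],
#' [emit_callsets()], optionally writing the whole bundle (FASTA, GFF3,
#' BED tracks, chrom.sizes, per-sample VCFs, truth manifest) to a
#' directory.
#'
#' @param spec A [scenario_spec()].
#' @param dir Optional output directory.
#' @return A list of class `sv_scenario`: `genome` (`DNAStringSet`),
#'   `seqs`, `annotation`, `truth`, `callsets`, `mapping`, `spec`,
#'   and when `dir` is given, `paths`.
#' @export
simulate_scenario <- function(spec, dir = NULL) {
  gb <- generate_genome(spec)
  tb <- implant_svs(gb, spec)
  em <- emit_callsets(tb, spec, dir = dir)
  genome <- Biostrings::DNAStringSet(tb$seqs)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ann <- tb$annotation
    fasta <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(genome, fasta)
    sizes <- file.path(dir, "chrom.sizes")
    write.table(data.frame(names(ann$chrom_lengths),
                           unname(ann$chrom_lengths)),
                sizes, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    gff <- file.path(dir, "annotation.gff3")
    write_annotation_gff3(ann, gff)
    beds <- c(cs = file.path(dir, "chromatin_states.bed"),
              centromere = file.path(dir, "centromeres.bed"),
              hot = file.path(dir, "hot_regions.bed"))
    write_bed4 <- function(gr, path, name = ".") {
      if (length(gr) == 0) { writeLines(character(0), path); return() }
      nm <- if (name %in% names(S4Vectors::mcols(gr)))
        S4Vectors::mcols(gr)[[name]] else rep(".", length(gr))
      write.table(data.frame(as.character(GenomicRanges::seqnames(gr)),
                             GenomicRanges::start(gr) - 1L,
                             GenomicRanges::end(gr), nm),
                  path, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
    write_bed4(ann$cs, beds["cs"], "state")
    write_bed4(ann$centromeric, beds["centromere"])
    write_bed4(ann$hot, beds["hot"])
    truth_path <- file.path(dir, "truth.tsv")
    write.table(em$truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- list(fasta = fasta, chrom_sizes = sizes, gff = gff,
                  cs_bed = unname(beds["cs"]),
                  centromere_bed = unname(beds["centromere"]),
                  hot_bed = unname(beds["hot"]), truth = truth_path,
                  vcfs = file.path(dir, paste0(
                    vapply(em$callsets, `[[`, character(1), "sample_id"),
                    ".vcf")))
  }
  structure(list(genome = genome, seqs = tb$seqs,
                 annotation = tb$annotation, truth = em$truth,
                 callsets = em$callsets, mapping = em$mapping,
                 spec = spec, paths = paths),
            class = "sv_scenario")
}

write_annotation_gff3 <- function(ann, path) {
  lines <- "##gff-version 3"
  fmt <- function(gr, type, attrs) {
    if (length(gr) == 0) return(character(0))
    sprintf("%s\tsvradiate\t%s\t%d\t%d\t.\t+\t.\t%s",
            as.character(GenomicRanges::seqnames(gr)),
            type, GenomicRanges::start(gr), GenomicRanges::end(gr),
            attrs)
  }
  pcg_attr <- sprintf("ID=gene%05d", seq_along(ann$pcg))
  te_attr <- sprintf("ID=te%05d;superfamily=%s", seq_along(ann$te),
                     S4Vectors::mcols(ann$te)$superfamily)
  writeLines(c(lines, fmt(ann$pcg, "gene", pcg_attr),
               fmt(ann$te, "transposable_element", te_attr)), path)
  invisible(path)
}
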