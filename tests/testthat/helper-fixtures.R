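# shared fixtures and independent oracles; scenarios are generated once
# per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_scenario <- function() {
  cached("default", simulate_scenario(scenario_spec(seed = 42)))
}

small_scenario <- function() {
  cached("small", simulate_scenario(scenario_spec(
    seed = 7, n_chromosomes = 2L, chrom_length = 80000L,
    n_pedigree_sv = 18L, n_induced_sv = 10L)))
}

# quick synthetic record tables --------------------------------------------

make_records <- function(n, chrom = "chr1", start0 = 1000L, gap = 500L,
                         sv_type = "DEL", len = 100L, prefix = "r") {
  start <- start0 + gap * (seq_len(n) - 1L)
  data.frame(id = sprintf("%s%03d", prefix, seq_len(n)), chrom = chrom,
             start = start,
             end = if (sv_type == "INS") start else start + len,
             sv_type = sv_type, length = len, inserted_seq = NA_character_,
             read_support = 10L, min_supporting_read_length = 5000L,
             mapping_quality = 60, stringsAsFactors = FALSE)
}

random_records <- function(n, prefix = "r") {
  # coarse coordinate grid so tolerant matches actually occur
  start <- sample(seq(100L, 4000L, by = 25L), n, replace = TRUE)
  len <- sample(seq(50L, 250L, by = 25L), n, replace = TRUE)
  tp <- sample(c("DEL", "INS", "DUP", "INV", "INVDUP"), n, replace = TRUE,
               prob = c(.4, .3, .1, .1, .1))
  data.frame(id = sprintf("%s%04d", prefix, seq_len(n)),
             chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             start = start,
             end = ifelse(tp == "INS", start, start + len),
             sv_type = tp, length = len, inserted_seq = NA_character_,
             read_support = 10L, min_supporting_read_length = 5000L,
             mapping_quality = 60, stringsAsFactors = FALSE)
}

# brute-force one-to-one pairing oracle: full O(n*m) scan of all pairs,
# same greedy distance rule and tie-breaks as the contract prescribes
brute_force_pairing <- function(A, B, params = match_params()) {
  ra <- A$records; rb <- B$records
  cand <- NULL
  for (i in seq_len(nrow(ra))) {
    same_chrom <- rb$chrom == ra$chrom[i]
    same_type <- if (params$require_same_type)
      rb$sv_type == ra$sv_type[i] else TRUE
    ds <- abs(rb$start - ra$start[i])
    de <- abs(rb$end - ra$end[i])
    j <- which(same_chrom & same_type & ds <= params$tolerance &
                 de <= params$tolerance)
    if (length(j) > 0)
      cand <- rbind(cand, data.frame(i = i, j = j, d_start = ds[j],
                                     d_end = de[j]))
  }
  pairs <- data.frame(id_a = character(0), id_b = character(0),
                      d_start = integer(0), d_end = integer(0),
                      stringsAsFactors = FALSE)
  used_a <- logical(nrow(ra)); used_b <- logical(nrow(rb))
  if (!is.null(cand)) {
    ord <- order(cand$d_start + cand$d_end, ra$chrom[cand$i],
                 ra$start[cand$i], ra$id[cand$i], rb$id[cand$j],
                 method = "radix")
    cand <- cand[ord, ]
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        pairs <- rbind(pairs, data.frame(
          id_a = ra$id[i], id_b = rb$id[j], d_start = cand$d_start[r],
          d_end = cand$d_end[r], stringsAsFactors = FALSE))
      }
    }
  }
  list(pairs = pairs, unmatched_a = ra$id[!used_a],
       unmatched_b = rb$id[!used_b])
}

# substring-comparison microhomology oracle (enumerates extensions from
# the window down, no character walking)
brute_force_mh <- function(seq, s, e, window = 50L) {
  L <- nchar(seq)
  seq <- toupper(seq)
  clean <- function(x) !grepl("N", x, fixed = TRUE)
  mh_right <- 0L
  for (k in seq.int(min(window, L - e), 0L)) {
    if (k == 0L) break
    a <- substr(seq, s + 1L, s + k); b <- substr(seq, e + 1L, e + k)
    if (nchar(a) == k && nchar(b) == k && a == b && clean(a) && clean(b)) {
      mh_right <- k; break
    }
  }
  mh_left <- 0L
  for (j in seq.int(min(window, s, e), 0L)) {
    if (j == 0L) break
    a <- substr(seq, s - j + 1L, s); b <- substr(seq, e - j + 1L, e)
    if (nchar(a) == j && nchar(b) == j && a == b && clean(a) && clean(b)) {
      mh_left <- j; break
    }
  }
  mh_left + mh_right
}

del_record <- function(chrom, s, e, id = "d1") {
  data.frame(id = id, chrom = chrom, start = s, end = e, sv_type = "DEL",
             length = e - s, inserted_seq = NA_character_,
             read_support = 10L, min_supporting_read_length = 5000L,
             mapping_quality = 60, stringsAsFactors = FALSE)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# direct-formula statistics oracles ----------------------------------------

oracle_gof <- function(observed, p) {
  E <- sum(observed) * p
  st <- sum((observed - E)^2 / E)
  list(statistic = st, df = length(observed) - 1L,
       p_value = pchisq(st, length(observed) - 1L, lower.tail = FALSE))
}

oracle_homogeneity <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  st <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = st, df = df,
       p_value = pchisq(st, df, lower.tail = FALSE))
}

oracle_mww <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- U - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
  list(u = U, p_value = min(1, p))
}

empty_origin_for_test <- function() svradiate:::empty_origin()

scenario_dir <- function() {
  cached("pipe_dir", {
    dir <- file.path(tempdir(), "svr_pipe")
    simulate_scenario(scenario_spec(seed = 23, n_chromosomes = 2L,
                                    chrom_length = 80000L,
                                    n_pedigree_sv = 18L,
                                    n_induced_sv = 8L), dir = dir)
    dir
  })
}

pipe_config <- function(out_dir, extra_samples = list()) {
  d <- scenario_dir()
  list(reference = file.path(d, "genome.fa"),
       gff = file.path(d, "annotation.gff3"),
       chrom_sizes = file.path(d, "chrom.sizes"),
       cs_bed = file.path(d, "chromatin_states.bed"),
       centromere_bed = file.path(d, "centromeres.bed"),
       hot_bed = file.path(d, "hot_regions.bed"),
       out_dir = out_dir,
       samples = c(list(
         list(path = file.path(d, "WT_untreated_rep1.vcf"),
              sample_id = "rep1", genotype = "WT", treatment = "none",
              replicate = 1),
         list(path = file.path(d, "WT_untreated_rep2.vcf"),
              sample_id = "rep2", genotype = "WT", treatment = "none",
              replicate = 2),
         list(path = file.path(d, "WT_untreated_rep3.vcf"),
              sample_id = "rep3", genotype = "WT", treatment = "none",
              replicate = 3),
         list(path = file.path(d, "WT_UV_B.vcf"), sample_id = "uvb",
              genotype = "WT", treatment = "UV_B", replicate = 1)),
         extra_samples))
}

toy_annotation <- function() {
  # 1 chromosome of 10 kb: PCG [1001,2000], TEs [3001,4000] (Gypsy) and
  # [4501,5500] (Copia), centromere [6001,8000], CS over all, HOT [501,1500]
  te <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(3001, 4501),
                                                c(4000, 5500)))
  S4Vectors::mcols(te)$superfamily <- c("LTR/Gypsy", "LTR/Copia")
  cs <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1, 5001),
                                                c(5000, 10000)))
  S4Vectors::mcols(cs)$state <- c("CS2", "CS8")
  genome_annotation(
    c(chr1 = 10000L),
    pcg = GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000)),
    te = te, cs = cs,
    centromeric = GenomicRanges::GRanges("chr1",
                                         IRanges::IRanges(6001, 8000)),
    hot = GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 1500)))
}
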