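test_that("intergenic regions are the complement of PCG and TE", {
  te <- GenomicRanges::GRanges("c1", IRanges::IRanges(301, 400))
  S4Vectors::mcols(te)$superfamily <- "MuDR"
  ann <- genome_annotation(c(c1 = 1000L),
                           pcg = GenomicRanges::GRanges(
                             "c1", IRanges::IRanges(101, 200)),
                           te = te)
  ir <- as.data.frame(ann$ir)[, c("start", "end")]
  expect_equal(ir$start, c(1, 201, 401))
  expect_equal(ir$end, c(100, 300, 1000))
  # overlapping PCG/TE: complement after union
  te2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(201, 400))
  S4Vectors::mcols(te2)$superfamily <- "MuDR"
  ann2 <- genome_annotation(c(c1 = 1000L),
                            pcg = GenomicRanges::GRanges(
                              "c1", IRanges::IRanges(101, 250)),
                            te = te2)
  ir2 <- as.data.frame(ann2$ir)[, c("start", "end")]
  expect_equal(ir2$start, c(1, 401))
  expect_equal(ir2$end, c(100, 1000))
  # per-chromosome bp conservation: PCG∪TE plus IR spans the genome
  genic <- sum(IRanges::width(GenomicRanges::reduce(
    c(GenomicRanges::granges(ann$pcg), GenomicRanges::granges(ann$te)))))
  expect_equal(genic + sum(IRanges::width(ann$ir)), 1000L)
  expect_error(genome_annotation(
    c(c1 = 1000L),
    pcg = GenomicRanges::GRanges("c1", IRanges::IRanges(900, 1100)),
    te = te), "beyond chromosome length")
})

test_that("element assignment follows maximal overlap with TE-first ties", {
  ann <- toy_annotation()
  # fully inside a TE
  a <- assign_element(del_record("chr1", 3100, 3300), ann)
  expect_equal(a$element_class, "TE")
  expect_equal(a$te_superfamily, "LTR/Gypsy")
  # 300 bp of PCG vs 100 bp of IR -> PCG (deletion [1700,2100])
  a <- assign_element(del_record("chr1", 1699, 2100), ann)
  expect_equal(a$element_class, "PCG")
  # insertion anchored in IR between the two TEs
  ins <- make_records(1, sv_type = "INS", start0 = 4100L)
  a <- assign_element(ins, ann)
  expect_equal(a$element_class, "IR")
  expect_true(is.na(a$te_superfamily))
  # exact 100/100 bp IR-vs-TE tie resolves to TE by precedence
  b <- assign_element(del_record("chr1", 2901, 3100), ann)
  expect_equal(b$element_class, "TE")
  # centromere midpoint rule and HOT any-overlap rule
  a <- assign_element(del_record("chr1", 5900, 6300), ann)  # mid 6100 in cen
  expect_true(a$centromeric)
  a <- assign_element(del_record("chr1", 5500, 5900), ann)  # mid outside
  expect_false(a$centromeric)
  a <- assign_element(del_record("chr1", 1500, 1600), ann)  # 1bp HOT touch
  expect_true(a$hot)
  expect_equal(a$chromatin_state, "CS2")
  expect_error(assign_element(del_record("chrX", 10, 20), ann),
               "absent from annotation")
})

test_that("interval queries agree with a naive full scan on random annotations", {
  set.seed(5)
  L <- 20000L
  starts <- sort(sample(seq(1, L - 600, by = 200), 12))
  pcg <- GenomicRanges::GRanges("c1", IRanges::IRanges(starts[1:6],
                                                       starts[1:6] + 399))
  te <- GenomicRanges::GRanges("c1", IRanges::IRanges(starts[7:12],
                                                      starts[7:12] + 399))
  S4Vectors::mcols(te)$superfamily <- "MuDR"
  ann <- genome_annotation(c(c1 = L), pcg = pcg, te = te)
  naive_bp <- function(qs, qe, layer) {
    df <- as.data.frame(layer)
    sum(vapply(seq_len(nrow(df)), function(i)
      max(0L, min(qe, df$end[i]) - max(qs, df$start[i]) + 1L), integer(1)))
  }
  for (rep in 1:25) {
    qs <- sample(L - 1000L, 1)
    qe <- qs + sample(50:1000, 1)
    qe <- min(qe, L)
    a <- assign_element(del_record("c1", qs - 1L, qe), ann)
    bp <- c(TE = naive_bp(qs, qe, ann$te), PCG = naive_bp(qs, qe, ann$pcg),
            IR = naive_bp(qs, qe, ann$ir))
    want <- names(bp)[which.max(bp)]  # same precedence order
    expect_equal(a$element_class, want)
  }
})

test_that("distribution tables conserve counts and report the genome background", {
  sc <- small_scenario()
  cs <- sc$callsets$treated
  d <- element_distribution(cs, sc$annotation)
  expect_equal(sum(d$element_counts), n_records(cs))
  expect_equal(sum(d$type_by_element), n_records(cs))
  expect_equal(sum(d$background_bp), 1)
  # background bp fractions equal hand-computed layer totals
  w <- function(gr) sum(IRanges::width(GenomicRanges::reduce(
    GenomicRanges::granges(gr))))
  tot <- sum(sc$annotation$chrom_lengths)
  expect_equal(unname(d$background_bp["TE"]), w(sc$annotation$te) / tot)
  expect_equal(unname(d$background_bp["IR"]), w(sc$annotation$ir) / tot)
  # induced records (reported at exact coordinates) match the manifest's
  # realized element classes; jittered pedigree copies may shift at edges
  asg <- d$assignments
  truth <- sc$truth[match(asg$id, sc$truth$truth_id), ]
  keep <- !is.na(truth$truth_id) & truth$cohort == "induced"
  expect_equal(asg$element_class[keep], truth$element_class[keep])
})

test_that("targeted element placement recovers the implant plan exactly", {
  spec <- scenario_spec(seed = 12, n_chromosomes = 2L,
                        chrom_length = 100000L, n_pedigree_sv = 0L,
                        n_induced_sv = 20L,
                        element_mix = c(TE = 0.6, IR = 0.3, PCG = 0.1),
                        sv_type_mix = c(DEL = 0.6, INS = 0.4, DUP = 0,
                                        INV = 0, INVDUP = 0),
                        del_length_range = c(50L, 300L))
  sc <- simulate_scenario(spec)
  d <- element_distribution(sc$callsets$treated, sc$annotation)
  truth_tab <- table(factor(sc$truth$element_class,
                            levels = c("TE", "PCG", "IR")))
  expect_equal(d$element_counts[names(truth_tab)],
               setNames(as.integer(truth_tab), names(truth_tab)))
})

test_that("annotation files round-trip through GFF3/BED loaders", {
  sc <- cached("small_dir", {
    dir <- file.path(tempdir(), "svr_small")
    simulate_scenario(scenario_spec(seed = 7, n_chromosomes = 2L,
                                    chrom_length = 80000L,
                                    n_pedigree_sv = 18L,
                                    n_induced_sv = 10L), dir = dir)
  })
  ann2 <- load_annotation(sc$paths$gff, sc$paths$chrom_sizes,
                          cs_bed = sc$paths$cs_bed,
                          centromere_bed = sc$paths$centromere_bed,
                          hot_bed = sc$paths$hot_bed)
  ann <- sc$annotation
  expect_equal(ann2$chrom_lengths, ann$chrom_lengths)
  expect_equal(length(ann2$te), length(ann$te))
  expect_equal(sort(S4Vectors::mcols(ann2$te)$superfamily),
               sort(S4Vectors::mcols(ann$te)$superfamily))
  expect_equal(sum(IRanges::width(ann2$ir)), sum(IRanges::width(ann$ir)))
  expect_equal(length(ann2$cs), length(ann$cs))
  expect_equal(as.data.frame(ann2$centromeric)[, 1:3],
               as.data.frame(ann$centromeric)[, 1:3])
})
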