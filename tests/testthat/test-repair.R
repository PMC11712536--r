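test_that("flank fetching indexes the reference exactly and flags truncation", {
  seq <- c(chr1 = paste0(strrep("A", 95), "CGTGA", strrep("T", 100),
                         strrep("G", 100)))
  # deletion [100,200) 0-based; window 5
  fl <- fetch_flanks(del_record("chr1", 100, 200), seq, window = 5L)
  expect_equal(fl$left, "CGTGA")          # bases 96..100 (1-based)
  expect_equal(fl$right, "GGGGG")         # bases 201..205
  expect_false(fl$left_truncated)
  # window truncated at the chromosome start
  fl <- fetch_flanks(del_record("chr1", 3, 60), seq, window = 50L)
  expect_equal(nchar(fl$left), 3L)
  expect_true(fl$left_truncated)
  # flanks + deleted segment reconstruct the reference substring
  s <- 100L; e <- 200L; w <- 20L
  fl <- fetch_flanks(del_record("chr1", s, e), seq, window = w)
  deleted <- substr(seq[["chr1"]], s + 1L, e)
  expect_equal(paste0(fl$left, deleted, fl$right),
               substr(seq[["chr1"]], s - w + 1L, e + w))
})

test_that("microhomology measures junction identity extensions", {
  # R = AAAACGTTTT, deletion [4,7) removes CGT: no homology either side
  seq <- c(c1 = "AAAACGTTTT")
  mh <- microhomology(del_record("c1", 4, 7), seq, window = 3L)
  expect_equal(mh$mh_total, 0L)
  # constructed two-sided homology: TA|GCA ... TA GCA -> deletion of the
  # middle copy has left TA and right GCA extensions
  seq2 <- c(c1 = "GGGGTAGCATTTTTAGCACCCC")
  # deletion [9,18) 0-based removes TTTTTAGCA; R[s-2..s)="CA"? use oracle
  d <- del_record("c1", 9, 18)
  mh <- microhomology(d, seq2, window = 10L)
  expect_equal(mh$mh_total, brute_force_mh(seq2[["c1"]], 9, 18, 10L))
  expect_equal(nchar(mh$mh_sequence), mh$mh_total)
})

test_that("microhomology equals the enumeration oracle on random sequences", {
  set.seed(202)
  for (rep in 1:80) {
    L <- 400L
    seq <- random_dna_str(L)
    s <- sample(60:180, 1)
    e <- s + sample(30:150, 1)
    got <- microhomology(del_record("c1", s, e), c(c1 = seq), window = 50L)
    expect_equal(got$mh_total, brute_force_mh(seq, s, e, 50L))
    expect_equal(got$mh_left + got$mh_right, got$mh_total)
  }
})

test_that("breakpoint representation shifts within the homology tract preserve mh_total", {
  set.seed(303)
  cases <- 0L
  while (cases < 500L) {
    seq <- random_dna_str(400L)
    s <- sample(80:150, 1)
    e <- s + sample(40:120, 1)
    g <- c(c1 = seq)
    base <- microhomology(del_record("c1", s, e), g, window = 50L)
    if (base$mh_right == 0 && base$mh_left == 0) {
      # manufacture homology so shifts are possible
      m <- sample(1:8, 1)
      substr(seq, e + 1L, e + m) <- substr(seq, s + 1L, s + m)
      g <- c(c1 = seq)
      base <- microhomology(del_record("c1", s, e), g, window = 50L)
    }
    for (d in seq_len(base$mh_right)) {
      shifted <- microhomology(del_record("c1", s + d, e + d), g,
                               window = 50L)
      expect_equal(shifted$mh_total, base$mh_total)
      cases <- cases + 1L
    }
    for (d in seq_len(base$mh_left)) {
      shifted <- microhomology(del_record("c1", s - d, e - d), g,
                               window = 50L)
      expect_equal(shifted$mh_total, base$mh_total)
      cases <- cases + 1L
    }
  }
  expect_gte(cases, 500L)
})

test_that("repair labels follow the microhomology thresholds", {
  # engineered deletions with exact truth homology
  mk <- function(m) {
    seq <- random_dna_str(400L)
    s <- 150L; e <- 250L
    if (m > 0) substr(seq, e + 1L, e + m) <- substr(seq, s + 1L, s + m)
    # guards
    if (substr(seq, s + m + 1L, s + m + 1L) ==
        substr(seq, e + m + 1L, e + m + 1L))
      substr(seq, e + m + 1L, e + m + 1L) <-
        setdiff(c("A", "C", "G", "T"),
                substr(seq, s + m + 1L, s + m + 1L))[1]
    if (substr(seq, s, s) == substr(seq, e, e))
      substr(seq, e, e) <- setdiff(c("A", "C", "G", "T"),
                                   substr(seq, s, s))[1]
    list(g = c(c1 = seq), rec = del_record("c1", s, e))
  }
  set.seed(404)
  f <- mk(0)
  expect_equal(classify_repair(f$rec, f$g)$label, "NHEJ")
  f <- mk(1)
  expect_equal(classify_repair(f$rec, f$g)$label, "NHEJ")
  f <- mk(4)
  expect_equal(classify_repair(f$rec, f$g)$label, "MMEJ")
  f <- mk(19)
  expect_equal(classify_repair(f$rec, f$g)$label, "MMEJ")
  f <- mk(20)
  expect_equal(classify_repair(f$rec, f$g)$label, "SSA_CANDIDATE")
  # an N in a flank -> UNDETERMINED
  f <- mk(4)
  substr(f$g[["c1"]], 120, 120) <- "N"
  expect_equal(classify_repair(f$rec, f$g)$label, "UNDETERMINED")
  # flank truncated at the chromosome start -> UNDETERMINED
  g <- c(c1 = random_dna_str(300L))
  expect_equal(classify_repair(del_record("c1", 10, 100), g)$label,
               "UNDETERMINED")
  expect_error(classify_repair(make_records(1, sv_type = "INS")[1, ],
                               g), "not a deletion")
})

test_that("repair summaries conserve counts and key the bubble data by mh length", {
  sc <- default_scenario()
  ind <- induced_sv_workflow(sc$callsets$treated, sc$callsets[1:3])
  rs <- repair_summary(ind, sc$seqs)
  dels <- sum(ind$records$sv_type == "DEL")
  expect_equal(rs$n_deletions, dels)
  expect_equal(sum(rs$counts), dels)
  expect_equal(sum(rs$mh_histogram), unname(rs$counts["MMEJ"]))
  expect_equal(sum(rs$fractions), 1)
  # zero-deletion set: empty table, no error
  ins_only <- sv_callset(make_records(2, sv_type = "INS"),
                         sample_id = "ins")
  rs0 <- repair_summary(ins_only, sc$seqs)
  expect_equal(rs0$n_deletions, 0L)
  expect_equal(sum(rs0$counts), 0L)
})

test_that("an implanted NHEJ/MMEJ cohort is recovered at its planned fractions", {
  spec <- scenario_spec(seed = 77, n_chromosomes = 2L,
                        chrom_length = 120000L, n_pedigree_sv = 0L,
                        n_induced_sv = 40L,
                        sv_type_mix = c(DEL = 1, INS = 0, DUP = 0,
                                        INV = 0, INVDUP = 0),
                        deletion_mh_spectrum = c("0" = 0.85, "4" = 0.15),
                        del_length_range = c(50L, 400L))
  sc <- simulate_scenario(spec)
  rs <- repair_summary(sc$callsets$treated, sc$seqs)
  truth_mmej <- sum(sc$truth$mh_total >= 2)
  expect_equal(unname(rs$counts["MMEJ"]), truth_mmej)
  expect_equal(unname(rs$counts["NHEJ"]), 40L - truth_mmej)
  expect_equal(unname(rs$fractions["MMEJ"]), truth_mmej / 40)
})
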