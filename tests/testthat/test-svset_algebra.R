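test_that("the tolerant identity rule compares chrom, type and both breakpoints", {
  p <- match_params(tolerance = 50)
  a <- del_record("chr1", 100, 500)
  expect_true(records_match(a, del_record("chr1", 140, 460), p))
  expect_false(records_match(a, del_record("chr1", 151, 500), p))
  ins <- make_records(1, sv_type = "INS", start0 = 100L)
  expect_false(records_match(a, ins[1, ], p))           # type differs
  dup <- del_record("chr1", 100, 500); dup$sv_type <- "DUP"
  expect_false(records_match(a, dup, p))
  expect_true(records_match(a, dup,
                            match_params(require_same_type = FALSE)))
  # reflexivity and symmetry at any tolerance
  expect_true(records_match(a, a, match_params(tolerance = 0)))
  b <- del_record("chr1", 130, 530)
  expect_equal(records_match(a, b, p), records_match(b, a, p))
})

test_that("greedy pairing picks the nearest candidate and leaves the rest", {
  A <- sv_callset(del_record("chr1", 100, 500), sample_id = "A")
  rb <- rbind(del_record("chr1", 110, 510, "b_off10"),
              del_record("chr1", 140, 540, "b_off40"))
  B <- sv_callset(rb, sample_id = "B")
  m <- match_sets(A, B)
  expect_equal(m$pairs$id_b, "b_off10")
  expect_equal(m$unmatched_b, "b_off40")
  # disjoint chromosomes: nothing pairs
  C <- sv_callset(del_record("chr2", 100, 500), sample_id = "C")
  m2 <- match_sets(A, C)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$unmatched_a, A$records$id)
})

test_that("pairing equals the brute-force oracle on random instances", {
  set.seed(314)
  for (rep in 1:12) {
    n <- sample(20:200, 1)
    m <- sample(20:200, 1)
    A <- sv_callset(random_records(n, "a"), sample_id = "A")
    B <- sv_callset(random_records(m, "b"), sample_id = "B")
    got <- match_sets(A, B)
    want <- brute_force_pairing(A, B)
    expect_equal(got$pairs[order(got$pairs$id_a), ],
                 want$pairs[order(want$pairs$id_a), ],
                 ignore_attr = TRUE)
    expect_setequal(got$unmatched_a, want$unmatched_a)
    expect_setequal(got$unmatched_b, want$unmatched_b)
  }
})

test_that("pooling concatenates without deduplication", {
  sets <- lapply(c(A = 5L, B = 7L, C = 4L), function(n)
    sv_callset(make_records(n), sample_id = paste0("s", n)))
  pooled <- pool(unname(sets))
  expect_equal(n_records(pooled), 16L)   # sum, not union: records shared
  one <- pool(list(sets[[1]]))
  expect_equal(n_records(one), 5L)
  dup <- sets
  dup[[2]]$sample_id <- dup[[1]]$sample_id
  expect_error(pool(unname(dup)), "duplicate sample_id")
})

test_that("subtraction removes exactly the control-matched records", {
  A <- sv_callset(make_records(8), sample_id = "A")
  expect_equal(n_records(subtract(A, list(A))), 0L)     # self-subtraction
  expect_equal(subtract(A, list())$records, A$records)  # empty controls
  # anti-monotone in controls
  set.seed(99)
  B <- sv_callset(random_records(60, "b"), sample_id = "B")
  C1 <- sv_callset(random_records(40, "c"), sample_id = "C1")
  C2 <- sv_callset(random_records(40, "d"), sample_id = "C2")
  r1 <- subtract(B, list(C1))
  r2 <- subtract(B, list(C1, C2))
  expect_true(all(r2$records$id %in% r1$records$id))
  expect_true(all(r1$records$id %in% B$records$id))
})

test_that("replicate Venn counts components and degenerates to exact algebra at tolerance 0", {
  one <- make_records(1)
  v <- venn_partition(sv_callset(one, sample_id = "a"),
                      sv_callset(one, sample_id = "b"),
                      sv_callset(one, sample_id = "c"))
  expect_equal(unname(v$region_counts["ABC"]), 1L)
  expect_equal(sum(v$region_counts), 1L)
  # tolerance 0 + integer-distinct coordinates == exact key algebra
  set.seed(21)
  for (rep in 1:5) {
    mk <- function(prefix) {
      r <- random_records(40, prefix)
      r <- r[!duplicated(paste(r$chrom, r$start, r$end, r$sv_type)), ]
      r
    }
    ra <- mk("a"); rb <- mk("b"); rc <- mk("c")
    v <- venn_partition(sv_callset(ra, sample_id = "a"),
                        sv_callset(rb, sample_id = "b"),
                        sv_callset(rc, sample_id = "c"),
                        match_params(tolerance = 0))
    key <- function(r) paste(r$chrom, r$start, r$end, r$sv_type)
    ka <- key(ra); kb <- key(rb); kc <- key(rc)
    all_keys <- unique(c(ka, kb, kc))
    membership <- paste0(ifelse(all_keys %in% ka, "A", ""),
                         ifelse(all_keys %in% kb, "B", ""),
                         ifelse(all_keys %in% kc, "C", ""))
    want <- table(membership)
    expect_equal(sum(v$region_counts), v$n_components)
    for (region in names(want))
      expect_equal(unname(v$region_counts[region]),
                   unname(as.integer(want[region])), label = region)
  }
})

test_that("the replicate core of the synthetic pedigree is recovered as the ABC region", {
  sc <- default_scenario()
  v <- venn_partition(sc$callsets$rep1, sc$callsets$rep2,
                      sc$callsets$rep3)
  truth_core <- sum(sc$truth$rep1 & sc$truth$rep2 & sc$truth$rep3)
  expect_equal(unname(v$region_counts["ABC"]), truth_core)
  expect_equal(sum(v$region_counts), v$n_components)
  expect_equal(v$n_inconsistent, 0L)
})

test_that("control subtraction isolates exactly the implanted induced SVs", {
  sc <- default_scenario()
  ind <- induced_sv_workflow(sc$callsets$treated, sc$callsets[1:3])
  truth_ind <- sc$truth$truth_id[sc$truth$cohort == "induced"]
  expect_setequal(ind$records$id, truth_ind)
  expect_length(attr(ind, "provenance"), 1L)
})

test_that("mutant workflows subtract both the untreated mutant and WT treated controls", {
  # treated mutant = untreated-mutant calls + WT-treated calls + own induced
  untr <- sv_callset(make_records(6, start0 = 1000L, prefix = "m"),
                     sample_id = "atm_untr", genotype = "atm")
  wt_tr <- sv_callset(make_records(4, start0 = 50000L, prefix = "w"),
                      sample_id = "WT_protons", genotype = "WT",
                      treatment = "protons")
  own <- make_records(3, start0 = 100000L, prefix = "ind")
  treated <- sv_callset(rbind(untr$records, wt_tr$records, own),
                        sample_id = "atm_protons", genotype = "atm",
                        treatment = "protons")
  ind <- induced_sv_workflow(treated, untr, wt_treated = wt_tr)
  expect_setequal(ind$records$id, own$id)
  expect_error(induced_sv_workflow(treated, untr), "WT")
  # treated == untreated control leaves nothing
  same <- sv_callset(untr$records, sample_id = "atm_uvb", genotype = "atm",
                     treatment = "UV_B")
  wt_uvb <- sv_callset(make_records(2, start0 = 70000L),
                       sample_id = "WT_UV_B", genotype = "WT",
                       treatment = "UV_B")
  expect_equal(n_records(induced_sv_workflow(same, untr,
                                             wt_treated = wt_uvb)), 0L)
})
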