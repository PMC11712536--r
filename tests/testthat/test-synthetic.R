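test_that("genome generation is deterministic and honors the layer densities", {
  spec <- scenario_spec(seed = 9, n_chromosomes = 2L,
                        chrom_length = 80000L)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(g1$seqs, g2$seqs)
  expect_identical(as.data.frame(g1$annotation$te),
                   as.data.frame(g2$annotation$te))
  # centromeric fraction is exact by construction
  cen_bp <- sum(g1$centromeres$end - g1$centromeres$start + 1)
  expect_equal(cen_bp, 2 * round(0.2 * 80000))
  # genome-wide TE bp within 2% of the mixed-zone target
  te_bp <- sum(IRanges::width(GenomicRanges::reduce(
    GenomicRanges::granges(g1$annotation$te))))
  target <- 2 * (0.2 * 80000 * 0.5 + 0.8 * 80000 * 0.15)
  expect_lt(abs(te_bp / 160000 - target / 160000), 0.02)
  # centromeric zone is built from the 180-bp repeat unit (3% divergence)
  cen <- g1$centromeres[1, ]
  copy1 <- substr(g1$seqs[[cen$chrom]], cen$start, cen$start + 179)
  mismatches <- sum(strsplit(copy1, "")[[1]] !=
                      strsplit(g1$repeat_unit, "")[[1]])
  expect_lt(mismatches, 25)
})

test_that("implanted deletion junctions carry their planned microhomology exactly", {
  sc <- default_scenario()
  dels <- sc$truth[sc$truth$sv_type == "DEL", ]
  got <- vapply(seq_len(nrow(dels)), function(i)
    microhomology(del_record(dels$chrom[i], dels$start[i], dels$end[i]),
                  sc$seqs)$mh_total, integer(1))
  expect_equal(got, dels$mh_total)
})

test_that("insertion donors are copied from their recorded loci", {
  sc <- default_scenario()
  ins <- sc$truth[sc$truth$sv_type == "INS", ]
  for (i in seq_len(nrow(ins))) {
    donor <- substr(sc$seqs[[ins$donor_chrom[i]]], ins$donor_start[i],
                    ins$donor_end[i])
    if (ins$donor_strand[i] == "-")
      donor <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(donor)))
    expect_equal(ins$inserted_seq[i], donor)
  }
  # truncated TE donors cover less than the full TE span
  te_donors <- ins[ins$donor_class == "TE", ]
  expect_true(all(te_donors$donor_te_coverage < 0.95))
})

test_that("emission is deterministic, membership-faithful and jitter-capped", {
  spec <- scenario_spec(seed = 31, n_chromosomes = 2L,
                        chrom_length = 80000L, n_pedigree_sv = 20L,
                        n_induced_sv = 8L)
  d1 <- file.path(tempdir(), "emit1"); d2 <- file.path(tempdir(), "emit2")
  sc1 <- simulate_scenario(spec, dir = d1)
  sc2 <- simulate_scenario(spec, dir = d2)
  for (f in list.files(d1, pattern = "\\.vcf$"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # replicate membership: core present in all three emitted sets
  truth <- sc1$truth
  core <- truth$truth_id[truth$rep1 & truth$rep2 & truth$rep3]
  for (r in 1:3)
    expect_true(all(core %in%
                      sc1$callsets[[paste0("rep", r)]]$records$id))
  expect_equal(round(0.5 * 20), length(core))
  # jittered coordinates stay within jitter_sd of truth
  rec <- sc1$callsets$rep1$records
  tr <- truth[match(rec$id, truth$truth_id), ]
  expect_true(all(abs(rec$start - tr$start) <= spec$jitter_sd))
  # oversized jitter violates the recovery contract unless forced
  spec_bad <- scenario_spec(seed = 31, jitter_sd = 40L)
  gb <- generate_genome(scenario_spec(seed = 31, n_chromosomes = 2L,
                                      chrom_length = 80000L,
                                      n_pedigree_sv = 5L,
                                      n_induced_sv = 2L))
  tb <- implant_svs(gb)
  tb$spec$jitter_sd <- 40L
  expect_error(emit_callsets(tb), "tolerance")
  expect_s3_class(emit_callsets(tb, force = TRUE)$callsets$rep1,
                  "sv_callset")
})

test_that("zero jitter and zero drop-out emit every truth record verbatim", {
  spec <- scenario_spec(seed = 13, n_chromosomes = 2L,
                        chrom_length = 80000L, n_pedigree_sv = 10L,
                        n_induced_sv = 5L, jitter_sd = 0L,
                        false_negative_rate = 0)
  sc <- simulate_scenario(spec)
  truth <- sc$truth
  treated <- sc$callsets$treated$records
  want <- truth[truth$in_treated, ]
  expect_setequal(treated$id, want$truth_id)
  m <- match(treated$id, want$truth_id)
  expect_equal(treated$start, want$start[m])
  expect_equal(treated$end, want$end[m])
  # zero planned SVs -> empty truth
  sc0 <- simulate_scenario(scenario_spec(seed = 13, n_chromosomes = 2L,
                                         chrom_length = 60000L,
                                         n_pedigree_sv = 0L,
                                         n_induced_sv = 0L))
  expect_equal(nrow(sc0$truth), 0L)
  expect_equal(n_records(sc0$callsets$treated), 0L)
})

test_that("false negatives thin the emitted call sets at the configured rate", {
  spec <- scenario_spec(seed = 17, n_chromosomes = 2L,
                        chrom_length = 100000L, n_pedigree_sv = 40L,
                        n_induced_sv = 0L, false_negative_rate = 0.3)
  sc <- simulate_scenario(spec)
  truth <- sc$truth
  for (r in 1:3) {
    present <- sum(truth[[paste0("rep", r)]])
    emitted <- n_records(sc$callsets[[paste0("rep", r)]])
    expect_lte(emitted, present)
  }
  total_present <- sum(truth$rep1) + sum(truth$rep2) + sum(truth$rep3)
  total_emitted <- sum(vapply(1:3, function(r)
    n_records(sc$callsets[[paste0("rep", r)]]), integer(1)))
  expect_lt(total_emitted / total_present, 0.95)
  expect_gt(total_emitted / total_present, 0.4)
})
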