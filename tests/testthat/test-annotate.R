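chrlen <- c(tst = 10000L)

empty_reads_df <- function() {
  recs <- data.frame(flag = 0L, rname = "tst", pos = 1L, cigar = "10M")
  bam <- write_test_bam(recs, chrlen)
  collect_reads(bam$bam, "tst", 5000, 5100)
}

test_that("collect_reads applies the 1-bp half-open overlap rule and filters", {
  recs <- data.frame(
    qname = c("partial", "inside", "abut", "secondary", "dup"),
    flag = c(0L, 0L, 0L, 256L, 1024L),
    rname = "tst",
    pos = c(96L, 120L, 201L, 130L, 140L),   # 1-based
    cigar = c("100M", "10M", "100M", "50M", "50M"),
    stringsAsFactors = FALSE)
  bam <- write_test_bam(recs, chrlen)
  got <- collect_reads(bam$bam, "tst", 100, 200)   # 0-based [100, 200)
  expect_setequal(got$qname, c("partial", "inside"))
  # read aligned [200, 300) 0-based abuts the region end: excluded
  expect_false("abut" %in% got$qname)
  expect_error(collect_reads("/nonexistent.bam", "tst", 0, 10), "index")
})

test_that("region_depth matches exact pileup arithmetic", {
  # 10 reads of length 100 tiling [0, 100) x10 -> depth 10
  recs <- data.frame(flag = 0L, rname = "tst", pos = rep(1L, 10),
                     cigar = "100M")
  bam <- write_test_bam(recs, chrlen)
  reads <- collect_reads(bam$bam, "tst", 0, 100)
  expect_equal(region_depth(reads, 0, 100), 10)
  # read overlapping half the region contributes half its bases
  recs2 <- data.frame(flag = 0L, rname = "tst", pos = 51L, cigar = "100M")
  bam2 <- write_test_bam(recs2, chrlen)
  reads2 <- collect_reads(bam2$bam, "tst", 0, 100)
  expect_equal(region_depth(reads2, 0, 100), 0.5)
  # deletion segments contribute no depth: 40M20D40M over [0, 100)
  recs3 <- data.frame(flag = 0L, rname = "tst", pos = 1L, cigar = "40M20D40M")
  bam3 <- write_test_bam(recs3, chrlen)
  reads3 <- collect_reads(bam3$bam, "tst", 0, 100)
  expect_equal(region_depth(reads3, 0, 100), 0.8)
  expect_equal(region_depth(empty_reads_df(), 0, 100), 0)
  expect_error(region_depth(reads3, 100, 100), "empty")
})

test_that("insert size follows the end-to-end definition including overlap", {
  # mates of 100 bp separated by a 50-bp gap: insert 250
  recs <- rbind(pair_recs("a", "tst", 101, 251, 100),
                # overlapping mates, gap -20: insert 180
                pair_recs("b", "tst", 1001, 1081, 100))
  bam <- write_test_bam(recs, chrlen)
  r1 <- collect_reads(bam$bam, "tst", 100, 210)
  expect_equal(unname(insert_size_stats(r1)[["mean"]]), 250)
  r2 <- collect_reads(bam$bam, "tst", 1000, 1100)
  expect_equal(unname(insert_size_stats(r2)[["mean"]]), 180)
  # single-end data has no usable pairs -> masked
  se <- data.frame(flag = 0L, rname = "tst", pos = 1L, cigar = "100M")
  bamse <- write_test_bam(se, chrlen)
  expect_true(is.na(insert_size_stats(collect_reads(bamse$bam, "tst", 0, 100))[["mean"]]))
})

test_that("clipping fraction counts clips of at least min_clip on either end", {
  recs <- data.frame(flag = 0L, rname = "tst", pos = c(1L, 1L, 1L, 1L),
                     cigar = c("100M", "50S50M", "97M3S", "95M5H"))
  bam <- write_test_bam(recs, chrlen)
  reads <- collect_reads(bam$bam, "tst", 0, 100)
  # 50S and 5H count; the 3-base clip does not
  expect_equal(clipping_fraction(reads, min_clip = 5), 0.5)
  expect_equal(clipping_fraction(reads, min_clip = 3), 0.75)
  expect_true(is.na(clipping_fraction(empty_reads_df())))
})

test_that("discordance splits mate-unmapped from discordant correctly", {
  proper <- rbind(pair_recs("p1", "tst", 101, 301, 100),
                  pair_recs("p2", "tst", 121, 321, 100))
  # mate unmapped read
  mu <- data.frame(qname = "mu", flag = 1L + 8L + 64L, rname = "tst",
                   pos = 141L, cigar = "100M", rnext = "=", pnext = 141L,
                   tlen = 0L, stringsAsFactors = FALSE)
  # same-strand pair (both forward: mate-reverse bit unset)
  ss <- data.frame(qname = "ss", flag = 1L + 64L, rname = "tst", pos = 161L,
                   cigar = "100M", rnext = "=", pnext = 361L, tlen = 300L,
                   stringsAsFactors = FALSE)
  # stretched insert
  st <- data.frame(qname = "st", flag = 1L + 32L + 64L, rname = "tst",
                   pos = 181L, cigar = "100M", rnext = "=", pnext = 3001L,
                   tlen = 2920L, stringsAsFactors = FALSE)
  recs <- data.table::rbindlist(list(proper, mu, ss, st), fill = TRUE)
  recs <- as.data.frame(recs)
  bam <- write_test_bam(recs, chrlen)
  reads <- collect_reads(bam$bam, "tst", 100, 300)
  d <- discordance_fractions(reads, insert_cutoff = 1000)
  # 5 paired reads start in [100, 300): the left mates of p1/p2 (right mates
  # begin past the region), mu, ss, st -> 1 mate-unmapped, 2 discordant
  expect_equal(unname(d[["mate_unmapped"]]), 1 / 5)
  expect_equal(unname(d[["discordant"]]), 2 / 5)
  # proper-only input: zero fractions
  bam2 <- write_test_bam(proper, chrlen)
  d2 <- discordance_fractions(collect_reads(bam2$bam, "tst", 100, 300), 1000)
  expect_equal(unname(d2), c(0, 0))
})

test_that("long-read indel rates normalize by the baseline per read base", {
  recs <- data.frame(flag = 0L, rname = "tst", pos = 1L,
                     cigar = c("900M100D100M", "1000M"))
  bam <- write_test_bam(recs, chrlen)
  reads <- collect_reads(bam$bam, "tst", 0, 1000)
  # read 1: 100 deleted bases over 1000 query bases -> 0.1; mean over 2 reads
  r0 <- longread_indel_rates(reads, baseline = c(0, 0))
  expect_equal(r0$norm_del, 0.05)
  expect_equal(r0$norm_ins, 0)
  expect_equal(r0$del_ins_diff, 0.05)
  rb <- longread_indel_rates(reads, baseline = c(0.0428, 0.0948))
  expect_equal(rb$norm_del, 0.05 - 0.0428)
  expect_equal(rb$norm_ins, -0.0948)
  # no-indel reads with zero baseline -> all zero
  recs2 <- data.frame(flag = 0L, rname = "tst", pos = 1L, cigar = "1000M")
  bam2 <- write_test_bam(recs2, chrlen)
  r2 <- longread_indel_rates(collect_reads(bam2$bam, "tst", 0, 1000), c(0, 0))
  expect_equal(unlist(r2), c(norm_del = 0, norm_ins = 0, del_ins_diff = 0))
})

test_that("reference context computes GC, repeat fractions and SNP counts", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">ctx", paste0(strrep("A", 100), "GGCC", strrep("T", 96))), fa)
  rep_f <- tempfile()
  writeLines("ctx\t100\t150\tSINE/Alu", rep_f)  # covers half of M = [100, 200)
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=ctx,length=200>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "ctx\t110\t.\tA\tG\t50\tPASS\t.\tGT\t0/1",
               "ctx\t120\t.\tA\tG\t50\tPASS\t.\tGT\t0/1",
               "ctx\t130\t.\tA\tG\t50\tPASS\t.\tGT\t1/1"), vcf)
  sv <- sv_calls("ctx", 100, 200, sv_type = "deletion")
  ctx <- reference_context(sv, fa, read_repeat_track(rep_f),
                           read_snp_genotypes(vcf))
  expect_equal(ctx$RepFrac_SINE, 0.5)
  expect_equal(ctx$HetSNP, 2)
  expect_equal(ctx$HomSNP, 1)
  expect_equal(ctx$SVLen, 100)
  # GC of [100, 200): GGCC + 96 T -> 4/100
  expect_equal(ctx$GC, 0.04)
  gc_all <- reference_context(sv_calls("ctx", 100, 104), fa, NULL, NULL)
  expect_equal(gc_all$GC, 1)    # "GGCC"
})

test_that("annotate_sites is deterministic and masks failing sites", {
  fx <- get_fixture()
  sites <- head(fx$sim$truth, 4)
  t1 <- annotate_sites(sites, fx$datasets[[1]], subset = "oneclass")
  t2 <- annotate_sites(sites, fx$datasets[[1]], subset = "oneclass")
  expect_identical(t1$values, t2$values)
  # a site beyond the contig ends up masked and flagged, not an error
  bad <- rbind(sites, sv_calls("sim1", 1, 9e7, source = "bad"))
  tb <- suppressWarnings(annotate_sites(bad, fx$datasets[[1]], subset = "oneclass"))
  expect_equal(length(attr(tb, "failed_sites")), 1)
  expect_true(all(tb$mask[nrow(tb$values), ]))
})

test_that("one-class subsets expose only technology-appropriate columns", {
  fx <- get_fixture()
  sites <- head(fx$sim$truth, 2)
  tp <- annotate_sites(sites, fx$datasets[[1]], subset = "oneclass")
  expect_setequal(colnames(tp$values),
                  c("LM_Cov", "M_Cov", "RM_Cov", "L_SoftClip", "R_SoftClip",
                    "L_InsertMean", "L_InsertSd", "R_InsertMean", "R_InsertSd",
                    "L_Discord", "R_Discord", "L_MateUnmapped", "R_MateUnmapped"))
  tl <- annotate_sites(sites, fx$datasets[[3]], subset = "oneclass")
  expect_setequal(colnames(tl$values),
                  c("LM_Cov", "M_Cov", "RM_Cov", "L_SoftClip", "R_SoftClip",
                    "M_DelInsDiff"))
  expect_false(any(grepl("Insert", colnames(tl$values))))
  # reference-only columns stay out of the one-class subset
  tf <- annotate_sites(sites, fx$datasets[[1]], fasta = fx$fasta,
                       subset = "full")
  expect_true(all(c("GC", "SVLen", "L_MapQ") %in% colnames(tf$values)))
  expect_false(any(c("GC", "SVLen", "L_MapQ") %in% colnames(tp$values)))
})

test_that("simulated deletion depth scales with zygosity against flanks", {
  fx <- get_fixture()
  truth <- fx$sim$truth
  dels <- truth[truth$sv_type == "deletion", ]
  tab <- annotate_sites(dels, fx$datasets[[1]], subset = "full")
  m <- tab$values[, "M_Cov"]
  fl <- (tab$values[, "L_Cov"] + tab$values[, "R_Cov"]) / 2
  hom <- dels$zygosity == "hom"
  expect_lt(max(m[hom] / fl[hom]), 0.15)
  # het sites carry one haplotype's coverage: half depth on average, each
  # site within generous binomial noise for these region sizes
  het_ratio <- m[!hom] / fl[!hom]
  expect_lt(abs(mean(het_ratio) - 0.5), 0.12)
  expect_true(all(het_ratio > 0.15 & het_ratio < 0.85))
})
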