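#' Collect primary alignments overlapping a region
#'
#' Returns every primary, non-duplicate, QC-pass alignment whose aligned
#' reference span overlaps the region by at least 1 bp (partially overlapping
#' reads included), exactly once.  Secondary and supplementary alignments are
#' excluded.
#'
#' @param bam_path Indexed BAM.
#' @param chrom,start,end Region, 0-based half-open.
#' @return A data.frame of reads: `qname`, `flag`, `pos` (1-based leftmost),
#'   `ref_end` (1-based inclusive), `mapq`, `cigar`, `strand`, `mrnm`,
#'   `mpos`, `isize`, `rname`.
#' @export
collect_reads <- function(bam_path, chrom, start, end) {
  collect_reads_multi(bam_path,
                      data.frame(chrom = chrom, start = start, end = end))[[1]]
}

BAM_WHAT <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
              "mrnm", "mpos", "isize")

read_filter_flags <- function() Rsamtools::scanBamFlag(
  isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
  isSupplementaryAlignment = FALSE, isDuplicate = FALSE,
  isNotPassingQualityControls = FALSE)

#' @rdname collect_reads
#' @param regions Data.frame of regions (`chrom`, `start`, `end`, 0-based
#'   half-open); zero-width regions yield empty read sets.
#' @return For `collect_reads_multi`, a list of read data.frames, one per
#'   region row.
#' @export
collect_reads_multi <- function(bam_path, regions) {
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("missing BAM index for ", bam_path)
  nonempty <- which(regions$end > regions$start)
  out <- rep(list(empty_reads()), nrow(regions))
  if (length(nonempty) == 0L) return(out)
  which_gr <- GenomicRanges::GRanges(
    regions$chrom[nonempty],
    IRanges::IRanges(regions$start[nonempty] + 1, regions$end[nonempty]))
  param <- Rsamtools::ScanBamParam(which = which_gr, what = BAM_WHAT,
                                   flag = read_filter_flags())
  res <- Rsamtools::scanBam(bam_path, param = param)
  # scanBam may reorder multi-chromosome queries; match results back by the
  # range label, consuming duplicates in order
  want <- sprintf("%s:%d-%d", regions$chrom[nonempty],
                  regions$start[nonempty] + 1, regions$end[nonempty])
  have <- names(res)
  pool <- split(seq_along(have), have)
  taken <- integer(length(want))
  for (i in seq_along(want)) {
    ids <- pool[[want[i]]]
    if (is.null(ids) || !length(ids))
      stop("scanBam result missing range ", want[i])
    taken[i] <- ids[1]
    pool[[want[i]]] <- ids[-1]
  }
  res <- res[taken]
  for (i in seq_along(nonempty)) {
    r <- res[[i]]
    df <- data.frame(qname = r$qname, flag = r$flag,
                     rname = as.character(r$rname),
                     strand = as.character(r$strand),
                     pos = r$pos, mapq = r$mapq, cigar = r$cigar,
                     mrnm = as.character(r$mrnm), mpos = r$mpos,
                     isize = r$isize, stringsAsFactors = FALSE)
    df$ref_end <- if (nrow(df)) df$pos +
      GenomicAlignments::cigarWidthAlongReferenceSpace(df$cigar) - 1L else integer()
    out[[nonempty[i]]] <- df
  }
  out
}

empty_reads <- function() data.frame(
  qname = character(), flag = integer(), rname = character(),
  strand = character(), pos = integer(), mapq = integer(), cigar = character(),
  mrnm = character(), mpos = integer(), isize = integer(), ref_end = integer())

#' Mean per-base depth of aligned bases over a region
#'
#' Sum over the region of per-base coverage by aligned (CIGAR M/=/X) read
#' bases, divided by the region length.  Deletion segments (D) of a read do
#' not contribute depth.
#'
#' @param reads Reads from [collect_reads()].
#' @param start,end Region, 0-based half-open; must be non-empty.
#' @return Mean depth (x).
#' @export
region_depth <- function(reads, start, end) {
  if (end <= start) stop("region_depth: empty region")
  if (nrow(reads) == 0L) return(0)
  rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar, pos = reads$pos, ops = c("M", "=", "X"))
  rng <- unlist(rng, use.names = FALSE)
  covered <- sum(overlap_width(IRanges::start(rng) - 1, IRanges::end(rng),
                               start, end))
  covered / (end - start)
}

# Per-read soft+hard clip lengths at each end, from CIGAR strings.
clip_lengths <- function(cigar) {
  left <- right <- numeric(length(cigar))
  has_l <- grepl("^[0-9]+[SH]", cigar)
  left[has_l] <- as.numeric(sub("^([0-9]+)[SH].*", "\\1", cigar[has_l]))
  has_r <- grepl("[0-9]+[SH]$", cigar)
  right[has_r] <- as.numeric(sub(".*?([0-9]+)[SH]$", "\\1", cigar[has_r]))
  cbind(left = left, right = right)
}

#' Fraction of reads clipped at either end
#'
#' Reads crossing an SV breakpoint typically map only partially, leaving
#' soft/hard clips; this counts reads with a clip of at least `min_clip`
#' bases on either end.
#'
#' @param reads Reads from [collect_reads()].
#' @param min_clip Minimum clip length in bases (default 5).
#' @return Fraction in \code{[0, 1]}, or `NA` if there are no reads.
#' @export
clipping_fraction <- function(reads, min_clip = 5) {
  if (nrow(reads) == 0L) return(NA_real_)
  cl <- clip_lengths(reads$cigar)
  mean(pmax(cl[, 1], cl[, 2]) >= min_clip)
}

#' Insert-size statistics of proper pairs in a region
#'
#' The insert is the end-to-end distance of a pair (length of both reads plus
#' the gap separating them, negative gaps allowed for overlapping mates),
#' i.e. the SAM TLEN of an FR pair.  Only primary proper pairs with both
#' mates mapped to the same chromosome are used, counted once via the
#' leftmost mate's record.
#'
#' @param reads Reads from [collect_reads()] (paired technology).
#' @return `c(mean, sd)`; masked (`NA`) components when there are no usable
#'   pairs (or a single pair, for the sd).
#' @export
insert_size_stats <- function(reads) {
  if (nrow(reads) == 0L) return(c(mean = NA_real_, sd = NA_real_))
  f <- reads$flag
  use <- bitwAnd(f, 1L) > 0 & bitwAnd(f, 2L) > 0 & bitwAnd(f, 8L) == 0 &
    !is.na(reads$mrnm) & reads$mrnm == reads$rname &
    !is.na(reads$isize) & reads$isize > 0
  ins <- reads$isize[use]
  if (length(ins) == 0L) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(ins), sd = if (length(ins) >= 2L) sd(ins) else NA_real_)
}

#' Discordant-pair and mate-unmapped fractions
#'
#' Among paired reads in the region: a read is discordant when its mate maps
#' to a different chromosome, the pair has same-strand orientation, or the
#' absolute insert exceeds `insert_cutoff`; mate-unmapped reads are counted
#' separately.  Both fractions share the all-paired-reads denominator.
#'
#' @param reads Reads from [collect_reads()] (paired technology).
#' @param insert_cutoff Discordance cutoff in bp; see
#'   [estimate_insert_cutoff()].
#' @return `c(discordant, mate_unmapped)`, `NA` when there are no paired
#'   reads.
#' @export
discordance_fractions <- function(reads, insert_cutoff) {
  f <- reads$flag
  paired <- bitwAnd(f, 1L) > 0
  n <- sum(paired)
  if (n == 0L) return(c(discordant = NA_real_, mate_unmapped = NA_real_))
  f <- f[paired]
  mate_unmapped <- bitwAnd(f, 8L) > 0
  diff_chrom <- !mate_unmapped &
    (is.na(reads$mrnm[paired]) | reads$mrnm[paired] != reads$rname[paired])
  same_strand <- !mate_unmapped & (bitwAnd(f, 16L) > 0) == (bitwAnd(f, 32L) > 0)
  long_insert <- !mate_unmapped & !diff_chrom &
    !is.na(reads$isize[paired]) & abs(reads$isize[paired]) > insert_cutoff
  c(discordant = sum(diff_chrom | same_strand | long_insert) / n,
    mate_unmapped = sum(mate_unmapped) / n)
}

#' Estimate the discordant-insert cutoff for a dataset
#'
#' Mean + 4 sd of the insert-size distribution, estimated from a random
#' sample of proper pairs.
#'
#' @param bam_path Indexed BAM.
#' @param n Sample size (default 1000 pairs).
#' @param seed Seed for the subsample.
#' @return Cutoff in bp.
#' @export
estimate_insert_cutoff <- function(bam_path, n = 1000, seed = 1) {
  param <- Rsamtools::ScanBamParam(
    what = c("flag", "isize"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isProperPair = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE))
  r <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  ins <- r$isize[!is.na(r$isize) & r$isize > 0]
  if (length(ins) == 0L) stop("no proper pairs in ", bam_path)
  if (length(ins) > n) ins <- with_seed(seed, sample(ins, n))
  mean(ins) + 4 * sd(ins)
}

#' Normalized long-read indel rates
#'
#' Per-read deleted (CIGAR D) and inserted (CIGAR I) bases divided by read
#' length, averaged over reads, then normalized by subtracting the
#' random-region baseline means.  The published baseline constants are
#' `c(0.0428, 0.0948)`.
#'
#' @param reads Reads from [collect_reads()] (long-read technology).
#' @param baseline `c(mean_del, mean_ins)` per read base over random regions.
#' @return List `norm_del`, `norm_ins`, `del_ins_diff`
#'   (`norm_del - norm_ins`); all `NA` if there are no reads.
#' @export
longread_indel_rates <- function(reads, baseline = c(0.0428, 0.0948)) {
  if (nrow(reads) == 0L)
    return(list(norm_del = NA_real_, norm_ins = NA_real_, del_ins_diff = NA_real_))
  ops <- GenomicAlignments::explodeCigarOps(reads$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(reads$cigar)
  per_read <- mapply(function(o, l) {
    qlen <- sum(l[o %in% c("M", "I", "S", "=", "X")])
    c(del = sum(l[o == "D"]) / qlen, ins = sum(l[o == "I"]) / qlen)
  }, ops, lens)
  norm_del <- mean(per_read["del", ]) - baseline[1]
  norm_ins <- mean(per_read["ins", ]) - baseline[2]
  list(norm_del = norm_del, norm_ins = norm_ins,
       del_ins_diff = norm_del - norm_ins)
}

#' Reference and sample context of a candidate site
#'
#' GC fraction (N bases excluded from the denominator), per-class repeat
#' coverage fractions, and het/hom SNP counts, all over the SV interval M.
#'
#' @param sv Single-row [sv_calls()] data.frame.
#' @param fasta Path to an indexed FASTA (a `.fai` is created if absent).
#' @param repeats A [read_repeat_track()] object, or `NULL`.
#' @param snps A [read_snp_genotypes()] object, or `NULL`.
#' @return Named list: `GC`, `RepFrac_SINE`, `RepFrac_LINE`, `RepFrac_LTR`,
#'   `LowComplexity`, `SimpleRepeat`, `RepFrac_Other`, `HetSNP`, `HomSNP`,
#'   `SVLen`.
#' @export
reference_context <- function(sv, fasta, repeats = NULL, snps = NULL) {
  chrom <- as.character(sv$chrom[1])
  start <- as.numeric(sv$start[1]); end <- as.numeric(sv$end[1])
  len <- end - start
  gc <- NA_real_
  if (!is.null(fasta)) {
    if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
    seq <- Rsamtools::scanFa(fasta, GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start + 1, end)))[[1]]
    counts <- Biostrings::alphabetFrequency(seq)
    acgt <- sum(counts[c("A", "C", "G", "T")])
    gc <- if (acgt > 0) sum(counts[c("G", "C")]) / acgt else NA_real_
  }
  rep_frac <- setNames(rep(0, length(REPEAT_CLASSES)), REPEAT_CLASSES)
  if (!is.null(repeats)) {
    hits <- repeat_query(repeats, chrom, start, end)
    for (cl in REPEAT_CLASSES) {
      h <- hits[hits$repeat_class == cl, , drop = FALSE]
      if (nrow(h) == 0L) next
      ir <- IRanges::reduce(IRanges::IRanges(
        pmax(h$start, start) + 1, pmin(h$end, end)))
      rep_frac[cl] <- sum(IRanges::width(ir)) / len
    }
  }
  het <- hom <- 0L
  if (!is.null(snps)) {
    in_m <- snps$records$chrom == chrom & snps$records$pos >= start &
      snps$records$pos < end
    het <- sum(in_m & snps$records$genotype == "het")
    hom <- sum(in_m & snps$records$genotype == "hom_alt")
  }
  list(GC = gc,
       RepFrac_SINE = rep_frac[["SINE"]], RepFrac_LINE = rep_frac[["LINE"]],
       RepFrac_LTR = rep_frac[["LTR"]],
       LowComplexity = rep_frac[["low_complexity"]],
       SimpleRepeat = rep_frac[["simple_repeat"]],
       RepFrac_Other = rep_frac[["other"]],
       HetSNP = het, HomSNP = hom, SVLen = len)
}

oneclass_columns <- function(technology) {
  if (technology == "paired_short")
    c("LM_Cov", "M_Cov", "RM_Cov", "L_SoftClip", "R_SoftClip",
      "L_InsertMean", "L_InsertSd", "R_InsertMean", "R_InsertSd",
      "L_Discord", "R_Discord", "L_MateUnmapped", "R_MateUnmapped")
  else
    c("LM_Cov", "M_Cov", "RM_Cov", "L_SoftClip", "R_SoftClip", "M_DelInsDiff")
}

#' Annotate candidate sites against one dataset
#'
#' Computes the per-site annotation vector from one BAM plus reference
#' context: per region (L, LM, M, RM, R) the mean depth, read count, clipped
#' fraction and mean MAPQ; for paired data additionally insert mean/sd and
#' discordant / mate-unmapped fractions; for long reads the per-read deletion
#' and insertion rates plus the normalized `M_DelInsDiff`.  With a FASTA /
#' repeat track / SNP set, GC, repeat-class fractions, SNP counts and SV
#' length are appended.
#'
#' Subsets: `full` is everything; `clustering` drops the read-count
#' bookkeeping columns; `oneclass` keeps only the technology-appropriate
#' read-evidence columns (reference-only context such as GC, repeats, SNPs,
#' size, and MAPQ is excluded, since atypical values there do not by
#' themselves indicate an SV).
#'
#' @param sites [sv_calls()] data.frame.
#' @param dataset A [dataset_spec()].
#' @param fasta,repeats,snps Optional reference inputs (see
#'   [reference_context()]).
#' @param flank_size Flank width in bp (default 100).
#' @param subset `"full"`, `"clustering"` or `"oneclass"`.
#' @param min_clip Clip-length threshold for [clipping_fraction()].
#' @param insert_cutoff Discordance cutoff; estimated from the BAM via
#'   [estimate_insert_cutoff()] when `NULL`.
#' @param site_ids Optional row labels (default `source:chrom:start-end`).
#' @return An [annotation_table()]; sites whose partition fails (e.g. contig
#'   too short) have fully masked rows, listed in attribute `failed_sites`.
#' @export
annotate_sites <- function(sites, dataset, fasta = NULL, repeats = NULL,
                           snps = NULL, flank_size = 100,
                           subset = c("full", "clustering", "oneclass"),
                           min_clip = 5, insert_cutoff = NULL,
                           site_ids = NULL) {
  subset <- match.arg(subset)
  stopifnot(inherits(dataset, "dataset_spec"))
  paired <- dataset$technology == "paired_short"
  if (paired && is.null(insert_cutoff))
    insert_cutoff <- estimate_insert_cutoff(dataset$bam_path)
  contigs <- Rsamtools::scanBamHeader(dataset$bam_path)[[1]]$targets
  n <- nrow(sites)
  if (is.null(site_ids))
    site_ids <- paste0(sites$source, ":", sites$chrom, ":",
                       format(sites$start, scientific = FALSE, trim = TRUE), "-",
                       format(sites$end, scientific = FALSE, trim = TRUE))
  site_ids <- make.unique(site_ids)

  parts <- vector("list", n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    ctg <- contigs[[as.character(sites$chrom[i])]]
    parts[i] <- list(tryCatch(
      if (is.null(ctg)) stop("unknown contig ", sites$chrom[i])
      else partition_site(sites[i, ], flank_size, ctg),
      error = function(e) NULL))
    failed[i] <- is.null(parts[[i]])
  }

  # one indexed-BAM pass for all (site, region) windows
  reg <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (failed[i]) return(data.frame(chrom = "*", start = 0, end = 0)[rep(1, 5), ])
    p <- parts[[i]]
    data.frame(chrom = p$chrom,
               start = vapply(p$regions, `[`, 0, 1),
               end = vapply(p$regions, `[`, 0, 2))
  }))
  reads <- collect_reads_multi(dataset$bam_path, reg)

  per_region_cols <- c("Cov", "ReadCount", "SoftClip", "MapQ",
                       if (paired) c("InsertMean", "InsertSd", "Discord", "MateUnmapped")
                       else c("DelRate", "InsRate"))
  cols <- as.vector(outer(REGION_NAMES, per_region_cols, paste, sep = "_"))
  cols <- sort(cols)
  if (!paired) cols <- c(cols, "M_DelInsDiff")
  ref_cols <- c("GC", "RepFrac_SINE", "RepFrac_LINE", "RepFrac_LTR",
                "LowComplexity", "SimpleRepeat", "RepFrac_Other",
                "HetSNP", "HomSNP", "SVLen")
  has_ref <- !is.null(fasta) || !is.null(repeats) || !is.null(snps)
  if (has_ref) cols <- c(cols, ref_cols)
  vals <- matrix(NA_real_, n, length(cols), dimnames = list(site_ids, cols))

  for (i in seq_len(n)) {
    if (failed[i]) next
    p <- parts[[i]]
    for (ri in seq_along(REGION_NAMES)) {
      rn <- REGION_NAMES[ri]
      b <- p$regions[[rn]]
      rr <- reads[[(i - 1) * 5 + ri]]
      if (b[2] <= b[1]) next    # zero-width (truncated/tiny) -> stays masked
      vals[i, paste0(rn, "_Cov")] <- region_depth(rr, b[1], b[2])
      vals[i, paste0(rn, "_ReadCount")] <- nrow(rr)
      vals[i, paste0(rn, "_SoftClip")] <- clipping_fraction(rr, min_clip)
      vals[i, paste0(rn, "_MapQ")] <- if (nrow(rr)) mean(rr$mapq) else NA_real_
      if (paired) {
        iss <- insert_size_stats(rr)
        vals[i, paste0(rn, "_InsertMean")] <- iss[["mean"]]
        vals[i, paste0(rn, "_InsertSd")] <- iss[["sd"]]
        disc <- discordance_fractions(rr, insert_cutoff)
        vals[i, paste0(rn, "_Discord")] <- disc[["discordant"]]
        vals[i, paste0(rn, "_MateUnmapped")] <- disc[["mate_unmapped"]]
      } else {
        lr <- longread_indel_rates(rr, dataset$long_read_indel_baseline)
        vals[i, paste0(rn, "_DelRate")] <- lr$norm_del
        vals[i, paste0(rn, "_InsRate")] <- lr$norm_ins
        if (rn == "M") vals[i, "M_DelInsDiff"] <- lr$del_ins_diff
      }
    }
    if (has_ref) {
      rc <- reference_context(sites[i, ], fasta, repeats, snps)
      vals[i, ref_cols] <- unlist(rc)
    }
  }

  keep <- switch(subset,
    full = cols,
    clustering = cols[!grepl("_ReadCount$", cols)],
    oneclass = intersect(oneclass_columns(dataset$technology), cols))
  out <- annotation_table(vals[, keep, drop = FALSE])
  attr(out, "failed_sites") <- site_ids[failed]
  attr(out, "dataset") <- dataset$name
  out
}

#' Estimate the long-read indel baseline from random regions
#'
#' Mean deleted and inserted bases per read base over a set of regions,
#' pooling all reads; used to normalize [longread_indel_rates()].
#'
#' @param bam_path Indexed BAM of long reads.
#' @param regions [sv_calls()] data.frame (typically the training random
#'   regions).
#' @return `c(mean_del, mean_ins)`.
#' @export
compute_indel_baseline <- function(bam_path, regions) {
  reads <- collect_reads_multi(bam_path, regions)
  rates <- lapply(reads, function(rr) {
    if (nrow(rr) == 0L) return(NULL)
    unlist(longread_indel_rates(rr, baseline = c(0, 0))[c("norm_del", "norm_ins")])
  })
  rates <- do.call(rbind, rates)
  if (is.null(rates)) stop("no reads in any region; cannot estimate baseline")
  c(mean_del = mean(rates[, 1]), mean_ins = mean(rates[, 2]))
}
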