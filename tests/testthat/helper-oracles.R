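# Naive, independent re-implementations used as oracles.  They parse SAM
# text and FASTA directly (no Rsamtools / GenomicAlignments) and compute
# every annotation by explicit per-base loops.

oracle_read_sam <- function(sam_path) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) return(NULL)
  f <- strsplit(lines, "\t")
  out <- data.frame(
    qname = vapply(f, `[`, "", 1), flag = as.integer(vapply(f, `[`, "", 2)),
    rname = vapply(f, `[`, "", 3), pos = as.integer(vapply(f, `[`, "", 4)),
    mapq = as.integer(vapply(f, `[`, "", 5)), cigar = vapply(f, `[`, "", 6),
    rnext = vapply(f, `[`, "", 7), pnext = as.integer(vapply(f, `[`, "", 8)),
    tlen = as.integer(vapply(f, `[`, "", 9)),
    stringsAsFactors = FALSE)
  out$ref_span <- NA_integer_
  mapped <- out$cigar != "*"
  out$ref_span[mapped] <- vapply(out$cigar[mapped], oracle_ref_span, 0L,
                                 USE.NAMES = FALSE)
  out
}

oracle_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  tok <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  data.frame(op = substr(tok, nchar(tok), nchar(tok)),
             len = as.integer(substr(tok, 1, nchar(tok) - 1)),
             stringsAsFactors = FALSE)
}

oracle_ref_span <- function(cigar) {
  cg <- oracle_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
}

oracle_query_len <- function(cigar) {
  cg <- oracle_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "I", "S", "=", "X")])
}

# Primary, mapped, non-duplicate reads whose reference span overlaps the
# 0-based half-open region by >= 1 bp.  Spans are computed once per SAM.
oracle_reads_in_region <- function(sam, chrom, start, end) {
  if (is.null(sam)) return(NULL)
  if (is.null(sam$ref_span))
    sam$ref_span <- vapply(sam$cigar, oracle_ref_span, 0L, USE.NAMES = FALSE)
  keep <- bitwAnd(sam$flag, 4L + 256L + 512L + 1024L + 2048L) == 0 &
    sam$rname == chrom
  sam <- sam[keep, , drop = FALSE]
  if (nrow(sam) == 0) return(sam)
  s0 <- sam$pos - 1L            # 0-based start
  e0 <- s0 + sam$ref_span      # 0-based exclusive end
  sam[e0 > start & s0 < end, , drop = FALSE]
}

oracle_depth <- function(reads, start, end) {
  # enumerate every aligned base of every read, then count those in range
  covered <- lapply(seq_len(NROW(reads)), function(i) {
    cg <- oracle_cigar(reads$cigar[i])
    ref <- reads$pos[i] - 1L      # 0-based cursor
    out <- integer()
    for (j in seq_len(nrow(cg))) {
      if (cg$op[j] %in% c("M", "=", "X")) {
        out <- c(out, seq.int(ref, ref + cg$len[j] - 1L))
        ref <- ref + cg$len[j]
      } else if (cg$op[j] %in% c("D", "N")) ref <- ref + cg$len[j]
    }
    out
  })
  pos <- unlist(covered)
  sum(pos >= start & pos < end) / (end - start)
}

oracle_clip_fraction <- function(reads, min_clip = 5) {
  if (NROW(reads) == 0) return(NA_real_)
  clipped <- vapply(reads$cigar, function(cg) {
    o <- oracle_cigar(cg)
    first <- o$op[1] %in% c("S", "H") && o$len[1] >= min_clip
    last <- o$op[nrow(o)] %in% c("S", "H") && o$len[nrow(o)] >= min_clip
    first || last
  }, NA)
  mean(clipped)
}

oracle_insert_stats <- function(reads) {
  if (NROW(reads) == 0) return(c(NA_real_, NA_real_))
  use <- bitwAnd(reads$flag, 1L) > 0 & bitwAnd(reads$flag, 2L) > 0 &
    bitwAnd(reads$flag, 8L) == 0 & reads$rnext %in% c("=", reads$rname) &
    reads$tlen > 0
  ins <- reads$tlen[use]
  if (length(ins) == 0) return(c(NA_real_, NA_real_))
  c(mean(ins), if (length(ins) >= 2) stats::sd(ins) else NA_real_)
}

oracle_discordance <- function(reads, cutoff) {
  paired <- reads[bitwAnd(reads$flag, 1L) > 0, , drop = FALSE]
  if (NROW(paired) == 0) return(c(NA_real_, NA_real_))
  mu <- bitwAnd(paired$flag, 8L) > 0
  disc <- vapply(seq_len(nrow(paired)), function(i) {
    if (mu[i]) return(FALSE)
    if (!(paired$rnext[i] %in% c("=", paired$rname[i]))) return(TRUE)
    self_rev <- bitwAnd(paired$flag[i], 16L) > 0
    mate_rev <- bitwAnd(paired$flag[i], 32L) > 0
    if (self_rev == mate_rev) return(TRUE)
    abs(paired$tlen[i]) > cutoff
  }, NA)
  c(mean(disc), mean(mu))
}

oracle_indel_rates <- function(reads, baseline) {
  if (NROW(reads) == 0) return(c(NA_real_, NA_real_, NA_real_))
  dr <- ir <- numeric(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    cg <- oracle_cigar(reads$cigar[i])
    qlen <- sum(cg$len[cg$op %in% c("M", "I", "S", "=", "X")])
    dr[i] <- sum(cg$len[cg$op == "D"]) / qlen
    ir[i] <- sum(cg$len[cg$op == "I"]) / qlen
  }
  nd <- mean(dr) - baseline[1]
  ni <- mean(ir) - baseline[2]
  c(nd, ni, nd - ni)
}

oracle_read_fasta <- function(path) {
  lines <- readLines(path)
  idx <- grep("^>", lines)
  out <- list()
  for (i in seq_along(idx)) {
    to <- if (i < length(idx)) idx[i + 1] - 1 else length(lines)
    out[[sub("^>(\\S+).*", "\\1", lines[idx[i]])]] <-
      paste(lines[(idx[i] + 1):to], collapse = "")
  }
  out
}

oracle_gc <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  acgt <- sum(chars %in% c("A", "C", "G", "T"))
  if (acgt == 0) return(NA_real_)
  sum(chars %in% c("G", "C")) / acgt
}

# Fraction of [start, end) covered by repeat records of one class (linear scan).
oracle_repeat_fraction <- function(records, chrom, start, end, class) {
  covered <- logical(end - start)
  rec <- records[records$chrom == chrom & records$repeat_class == class, ,
                 drop = FALSE]
  for (i in seq_len(NROW(rec))) {
    lo <- max(rec$start[i], start); hi <- min(rec$end[i], end)
    if (hi > lo) covered[(lo - start + 1):(hi - start)] <- TRUE
  }
  mean(covered)
}
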