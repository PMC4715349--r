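# Shared fixtures, built once per test run.

fixture_env <- new.env()

get_fixture <- function() {
  if (is.null(fixture_env$fx))
    fixture_env$fx <- make_fixture_suite(file.path(tempdir(), "svarb_fixture"),
                                         seed = 42)
  fixture_env$fx
}

# Write a BAM (and keep the SAM) from hand-specified alignment records.
write_test_bam <- function(recs, chrom_lengths, prefix = tempfile()) {
  sam <- paste0(prefix, ".sam")
  fill <- function(col, default) {
    v <- if (col %in% names(recs)) recs[[col]] else rep(default, nrow(recs))
    v[is.na(v)] <- default
    v
  }
  seqs <- fill("seq", "*")
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)),
             sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                     fill("qname", "r"), recs$flag, recs$rname, recs$pos,
                     fill("mapq", 60L), recs$cigar, fill("rnext", "*"),
                     fill("pnext", 0L), fill("tlen", 0L), seqs))
  writeLines(lines, sam)
  Rsamtools::asBam(sam, destination = prefix, overwrite = TRUE,
                   indexDestination = TRUE)
  list(bam = paste0(prefix, ".bam"), sam = sam)
}

# A no-frills paired-end record pair at given positions (1-based).
pair_recs <- function(qname, chrom, pos1, pos2, read_len, proper = TRUE,
                      mapq = 60L) {
  tlen <- pos2 + read_len - pos1
  base <- 1L + if (proper) 2L else 0L
  data.frame(qname = qname, flag = c(base + 32L + 64L, base + 16L + 128L),
             rname = chrom, pos = c(pos1, pos2), mapq = mapq,
             cigar = paste0(read_len, "M"), rnext = "=",
             pnext = c(pos2, pos1), tlen = c(tlen, -tlen),
             stringsAsFactors = FALSE)
}
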