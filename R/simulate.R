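#' Configuration for the genome/read simulator
#'
#' Defaults emulate a small two-haplotype donor genome carrying planted
#' homozygous and heterozygous deletions (and optionally insertions) on a
#' random reference, read by short paired-end and long single-end datasets.
#'
#' @param chrom_lengths Named vector of contig lengths in bp.
#' @param gc Reference GC composition.
#' @param n_hom_del,n_het_del,n_hom_ins,n_het_ins Planted event counts.
#' @param del_size_range,ins_size_range Event size bounds in bp (sizes drawn
#'   log-uniformly).
#' @param ins_span_range Replaced-reference span for insertions.
#' @param min_spacing Minimum separation between planted events and from
#'   contig ends (default 200 bp = twice the default flank).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(sim1 = 3e5), gc = 0.41,
                       n_hom_del = 8, n_het_del = 8,
                       n_hom_ins = 0, n_het_ins = 0,
                       del_size_range = c(150, 800),
                       ins_size_range = c(150, 500),
                       ins_span_range = c(2, 10),
                       min_spacing = 200) {
  stopifnot(all(chrom_lengths > 0), gc > 0, gc < 1)
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Place n non-overlapping events with the given sizes on the chromosomes,
# min_spacing apart from each other and from contig ends.
place_events <- function(chrom_lengths, sizes, min_spacing, max_attempts = 2000) {
  placed <- data.frame(chrom = character(), start = numeric(), end = numeric())
  for (s in sizes) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      ci <- sample(seq_along(chrom_lengths), 1L,
                   prob = as.numeric(chrom_lengths))
      L <- chrom_lengths[ci]
      if (L < s + 2 * min_spacing) next
      start <- floor(runif(1, min_spacing, L - s - min_spacing))
      same <- placed[placed$chrom == names(chrom_lengths)[ci], , drop = FALSE]
      if (nrow(same) == 0 ||
          all(overlap_width(start - min_spacing, start + s + min_spacing,
                            same$start, same$end) == 0)) {
        placed <- rbind(placed, data.frame(chrom = names(chrom_lengths)[ci],
                                           start = start, end = start + s))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("overcrowded genome: cannot place a ", s,
                  " bp event with spacing ", min_spacing)
  }
  placed
}

#' Simulate a reference genome with planted SVs
#'
#' Generates a random reference, plants non-overlapping deletions and
#' insertions, and builds the pair of donor haplotypes realizing them
#' (homozygous events on both haplotypes, heterozygous on haplotype 1 only).
#' Reads are later sampled from the donor haplotypes and lifted back to
#' reference coordinates analytically, so truth is exact by construction.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `sv_simulation`: `reference` (named character),
#'   `truth` ([sv_calls()] with zygosity), `haplotypes` (per chrom, per
#'   haplotype: donor sequence and segment map), `config`, `seed`.
#' @export
simulate_genome <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    ref <- lapply(config$chrom_lengths, random_dna, gc = config$gc)
    n_del <- config$n_hom_del + config$n_het_del
    n_ins <- config$n_hom_ins + config$n_het_ins
    lu <- function(n, r) if (n == 0) numeric() else
      round(exp(runif(n, log(r[1]), log(r[2]))))
    del_sizes <- lu(n_del, config$del_size_range)
    ins_spans <- if (n_ins) round(runif(n_ins, config$ins_span_range[1],
                                        config$ins_span_range[2])) else numeric()
    placed <- place_events(config$chrom_lengths, c(del_sizes, ins_spans),
                           config$min_spacing)
    type <- c(rep("deletion", n_del), rep("insertion", n_ins))
    zyg <- c(rep("hom", config$n_hom_del), rep("het", config$n_het_del),
             rep("hom", config$n_hom_ins), rep("het", config$n_het_ins))
    alt <- rep(NA_character_, n_del + n_ins)
    if (n_ins) {
      ins_lens <- lu(n_ins, config$ins_size_range)
      alt[n_del + seq_len(n_ins)] <- vapply(ins_lens, random_dna, "",
                                            gc = config$gc)
    }
    truth <- if (nrow(placed)) {
      o <- order(placed$chrom, placed$start)
      sv_calls(placed$chrom[o], placed$start[o], placed$end[o],
               sv_type = type[o], alt_seq = alt[o], source = "truth",
               zygosity = zyg[o])
    } else sv_calls(character(), numeric(), numeric(), source = "truth")
    haps <- lapply(names(config$chrom_lengths), function(ch) {
      lapply(1:2, function(h) {
        ev <- truth[truth$chrom == ch &
                      (truth$zygosity == "hom" | h == 1L), , drop = FALSE]
        build_haplotype(ref[[ch]], ev)
      })
    })
    names(haps) <- names(config$chrom_lengths)
    structure(list(reference = ref, truth = truth, haplotypes = haps,
                   config = config, seed = seed),
              class = "sv_simulation")
  })
}

# Donor haplotype for one chromosome: sequence plus a segment map.  Map rows
# (0-based half-open donor coords): type "M" (matched; ref_start gives the
# aligned reference start) or "I" (inserted sequence; ref_start is the
# reference anchor where it attaches).
build_haplotype <- function(ref_seq, events) {
  L <- nchar(ref_seq)
  pieces <- character(); map <- NULL
  d <- 0; prev <- 0
  add_seg <- function(map, d0, d1, type, ref_start)
    rbind(map, data.frame(donor_start = d0, donor_end = d1, type = type,
                          ref_start = ref_start))
  if (nrow(events)) events <- events[order(events$start), , drop = FALSE]
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$start > prev) {
      len <- ev$start - prev
      pieces <- c(pieces, substr(ref_seq, prev + 1, ev$start))
      map <- add_seg(map, d, d + len, "M", prev)
      d <- d + len
    }
    if (ev$sv_type == "insertion" && !is.na(ev$alt_seq)) {
      len <- nchar(ev$alt_seq)
      pieces <- c(pieces, ev$alt_seq)
      map <- add_seg(map, d, d + len, "I", ev$start)
      d <- d + len
    }
    prev <- ev$end   # reference span [start, end) absent from the donor
  }
  if (prev < L) {
    pieces <- c(pieces, substr(ref_seq, prev + 1, L))
    map <- add_seg(map, d, d + nchar(ref_seq) - prev, "M", prev)
  }
  if (is.null(map)) map <- data.frame(donor_start = numeric(),
                                      donor_end = numeric(), type = character(),
                                      ref_start = numeric())
  list(seq = paste(pieces, collapse = ""), map = map)
}

# Lift a donor interval [d0, d1) to a reference alignment: 1-based POS plus a
# run-length CIGAR (ops, lens).  Leading/trailing inserted sequence becomes
# soft clips; spanned reference gaps up to max_del_span become D ops (larger
# ones get the minor side soft-clipped, as a short-read aligner would); a
# read entirely inside inserted sequence is unmapped.
align_donor_interval <- function(map, d0, d1, max_del_span = Inf) {
  segs <- map[map$donor_end > d0 & map$donor_start < d1, , drop = FALSE]
  ops <- character(); lens <- numeric()
  pos <- NA_real_; prev_ref_end <- NA_real_
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    p0 <- max(s$donor_start, d0); p1 <- min(s$donor_end, d1)
    if (s$type == "I") {
      ops <- c(ops, "I"); lens <- c(lens, p1 - p0)
    } else {
      rs <- s$ref_start + (p0 - s$donor_start); re <- rs + (p1 - p0)
      if (is.na(pos)) {
        pos <- rs
      } else if (rs > prev_ref_end) {    # deletion spanned by the read
        ops <- c(ops, "D"); lens <- c(lens, rs - prev_ref_end)
      }
      prev_ref_end <- re
      ops <- c(ops, "M"); lens <- c(lens, p1 - p0)
    }
  }
  if (is.na(pos)) return(list(mapped = FALSE))
  big <- which(ops == "D" & lens > max_del_span)
  if (length(big)) {
    # keep the chunk with the most aligned bases; soft-clip the rest
    chunk_of <- findInterval(seq_along(ops), big + 0.5) + 1L
    chunk_of[big] <- NA
    m_by_chunk <- tapply(lens * (ops == "M"), chunk_of, sum)
    best <- as.integer(names(m_by_chunk)[which.max(m_by_chunk)])
    keep <- which(!is.na(chunk_of) & chunk_of == best)
    pre_q <- if (min(keep) > 1)
      sum(lens[seq_len(min(keep) - 1)][ops[seq_len(min(keep) - 1)] %in% c("M", "I", "S")]) else 0
    post_idx <- if (max(keep) < length(ops)) (max(keep) + 1L):length(ops) else integer()
    post_q <- sum(lens[post_idx][ops[post_idx] %in% c("M", "I", "S")])
    # pos of first kept M op
    ref_consumed <- cumsum(c(0, (lens * (ops %in% c("M", "D")))))[seq_along(ops)]
    pos <- pos + ref_consumed[min(keep)] - ref_consumed[1]
    ops <- c(if (pre_q > 0) "S", ops[keep], if (post_q > 0) "S")
    lens <- c(if (pre_q > 0) pre_q, lens[keep], if (post_q > 0) post_q)
  }
  norm <- normalize_cigar(ops, lens, pos)
  list(mapped = TRUE, pos = norm$pos + 1,   # 1-based POS
       ops = norm$ops, lens = norm$lens,
       ref_end = norm$pos + sum(norm$lens[norm$ops %in% c("M", "D")]))
}

# Merge runs, turn edge I into S, drop edge D (adjusting pos); pos 0-based in.
normalize_cigar <- function(ops, lens, pos) {
  keep <- lens > 0
  ops <- ops[keep]; lens <- lens[keep]
  repeat {
    changed <- FALSE
    if (length(ops) && ops[1] == "D") {
      pos <- pos + lens[1]; ops <- ops[-1]; lens <- lens[-1]; changed <- TRUE
    }
    if (length(ops) && ops[length(ops)] == "D") {
      ops <- ops[-length(ops)]; lens <- lens[-length(lens)]; changed <- TRUE
    }
    if (length(ops) && ops[1] == "I") { ops[1] <- "S"; changed <- TRUE }
    if (length(ops) && ops[length(ops)] == "I") {
      ops[length(ops)] <- "S"; changed <- TRUE
    }
    if (!changed) break
  }
  r <- rle_merge(ops, lens)
  list(ops = r$ops, lens = r$lens, pos = pos)
}

rle_merge <- function(ops, lens) {
  if (length(ops) <= 1L) return(list(ops = ops, lens = lens))
  grp <- cumsum(c(TRUE, ops[-1] != ops[-length(ops)]))
  list(ops = ops[!duplicated(grp)],
       lens = as.numeric(tapply(lens, grp, sum)))
}

cigar_string <- function(ops, lens)
  paste0(format(lens, scientific = FALSE, trim = TRUE), ops, collapse = "")

#' Describe a simulated dataset's read model
#'
#' @param name Dataset label.
#' @param type `"paired"` (short paired-end) or `"long"` (single-end).
#' @param depth Mean genome-wide depth (x).
#' @param read_length Read length (paired).
#' @param insert_mean,insert_sd End-to-end insert distribution (paired).
#' @param len_range Read-length bounds (long).
#' @param del_rate,ins_rate Per-base sequencing indel error rates (long).
#' @param max_del_span Largest deletion a read may span with a D op; larger
#'   deletions soft-clip the minor side (default 30 for paired short reads,
#'   unlimited for long reads, mimicking aligner behavior).
#' @param mapq Mapping quality assigned to reads (default 60).
#' @param low_mapq_regions Optional data.frame (`chrom`, `start`, `end`,
#'   `mapq`): reads starting inside get the given MAPQ instead.
#' @return A list of class `read_model`.
#' @export
read_model <- function(name, type = c("paired", "long"), depth = 30,
                       read_length = 100, insert_mean = 300, insert_sd = 30,
                       len_range = c(1000, 3000), del_rate = 0.04,
                       ins_rate = 0.09, max_del_span = NULL, mapq = 60,
                       low_mapq_regions = NULL) {
  type <- match.arg(type)
  if (is.null(max_del_span)) max_del_span <- if (type == "paired") 30 else Inf
  structure(as.list(environment()), class = "read_model")
}

#' Simulate reads from the donor haplotypes into a sorted, indexed BAM
#'
#' Reads are sampled from the donor haplotypes at the configured depth and
#' their reference alignments computed analytically from the segment maps (no
#' aligner): reads crossing deleted sequence acquire deletion-spanning CIGARs
#' or soft clips, pairs spanning deletions get stretched inserts, reads fully
#' inside inserted sequence become unmapped mates.  Long reads receive
#' per-base insertion/deletion sequencing errors at the configured rates.
#'
#' @param sim An [simulate_genome()] result.
#' @param model A [read_model()].
#' @param seed Integer seed.
#' @param out_prefix Output prefix; writes `<prefix>.bam` + `.bam.bai` (and
#'   `<prefix>.sam` if `keep_sam`).
#' @param keep_sam Keep the intermediate SAM text (useful for independent
#'   checks).
#' @return Path to the BAM file.
#' @export
simulate_reads <- function(sim, model, seed = 1, out_prefix, keep_sam = FALSE) {
  stopifnot(inherits(sim, "sv_simulation"), inherits(model, "read_model"))
  recs <- with_seed(seed, {
    out <- list()
    for (ch in names(sim$reference)) {
      for (h in 1:2) {
        hap <- sim$haplotypes[[ch]][[h]]
        out[[paste(ch, h)]] <- if (model$type == "paired")
          sim_pairs_chrom(hap, ch, h, model)
        else sim_long_chrom(hap, ch, h, model)
      }
    }
    data.table::rbindlist(out)
  })
  recs <- apply_low_mapq(recs, model)
  write_bam_records(recs, sim, out_prefix, keep_sam)
}

sim_pairs_chrom <- function(hap, chrom, hapno, model) {
  dlen <- nchar(hap$seq)
  rl <- model$read_length
  n <- round(model$depth / 2 * dlen / (2 * rl))
  if (n == 0) return(NULL)
  fl <- pmax(rl + 5, pmin(round(rnorm(n, model$insert_mean, model$insert_sd)),
                          dlen))
  s <- floor(runif(n, 0, dlen - fl + 1))
  proper_cut <- model$insert_mean + 4 * model$insert_sd
  rows <- vector("list", 2 * n)
  for (i in seq_len(n)) {
    qname <- sprintf("%s_%s_h%d_p%d", model$name, chrom, hapno, i)
    a1 <- align_donor_interval(hap$map, s[i], s[i] + rl, model$max_del_span)
    a2 <- align_donor_interval(hap$map, s[i] + fl[i] - rl, s[i] + fl[i],
                               model$max_del_span)
    seq1 <- substr(hap$seq, s[i] + 1, s[i] + rl)
    seq2 <- substr(hap$seq, s[i] + fl[i] - rl + 1, s[i] + fl[i])
    if (!a1$mapped && !a2$mapped) next
    if (a1$mapped && a2$mapped) {
      tlen <- a2$ref_end - a1$pos + 1
      proper <- tlen > 0 & tlen <= proper_cut
      base <- 1L + if (proper) 2L else 0L
      rows[[2 * i - 1]] <- sam_rec(qname, base + 32L + 64L, chrom, a1$pos,
                                   model$mapq, cigar_string(a1$ops, a1$lens),
                                   "=", a2$pos, tlen, seq1)
      rows[[2 * i]] <- sam_rec(qname, base + 16L + 128L, chrom, a2$pos,
                               model$mapq, cigar_string(a2$ops, a2$lens),
                               "=", a1$pos, -tlen, seq2)
    } else {
      m <- if (a1$mapped) a1 else a2
      mseq <- if (a1$mapped) seq1 else seq2
      useq <- if (a1$mapped) seq2 else seq1
      fbits <- if (a1$mapped) c(64L, 128L) else c(128L, 64L)
      rows[[2 * i - 1]] <- sam_rec(qname, 1L + 8L + fbits[1], chrom, m$pos,
                                   model$mapq, cigar_string(m$ops, m$lens),
                                   "=", m$pos, 0L, mseq)
      rows[[2 * i]] <- sam_rec(qname, 1L + 4L + fbits[2], chrom, m$pos,
                               0L, "*", "=", m$pos, 0L, useq)
    }
  }
  data.table::rbindlist(rows)
}

sim_long_chrom <- function(hap, chrom, hapno, model) {
  dlen <- nchar(hap$seq)
  mean_len <- mean(model$len_range)
  n <- round(model$depth / 2 * dlen / mean_len)
  if (n == 0) return(NULL)
  rl <- pmin(round(runif(n, model$len_range[1], model$len_range[2])), dlen - 1)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    d_err <- rbinom(1, rl[i], model$del_rate)
    i_err <- rbinom(1, rl[i], model$ins_rate)
    span <- max(1, rl[i] + d_err - i_err)
    s <- floor(runif(1, 0, max(1, dlen - span)))
    a <- align_donor_interval(hap$map, s, s + span, model$max_del_span)
    if (!a$mapped) next
    seq <- substr(hap$seq, s + 1, s + span)
    e <- inject_indel_errors(a$ops, a$lens, a$pos, seq, d_err, i_err)
    flag <- if (runif(1) < 0.5) 0L else 16L
    rows[[i]] <- sam_rec(sprintf("%s_%s_h%d_r%d", model$name, chrom, hapno, i),
                         flag, chrom, e$pos, model$mapq,
                         cigar_string(e$ops, e$lens), "*", 0L, 0L, e$seq)
  }
  data.table::rbindlist(rows)
}

# Convert d_err aligned bases to D ops and add i_err inserted bases, keeping
# SEQ consistent; pos is 1-based.  Works on per-alignment-column vectors.
inject_indel_errors <- function(ops, lens, pos, seq, d_err, i_err) {
  if (d_err == 0 && i_err == 0)
    return(list(ops = ops, lens = lens, pos = pos, seq = seq))
  cols <- rep(ops, lens)
  qidx <- cumsum(cols %in% c("M", "I", "S"))  # query base per column
  m_cols <- which(cols == "M")
  chars <- strsplit(seq, "")[[1]]
  drop_q <- integer()
  if (d_err > 0 && length(m_cols) > 1) {
    del_at <- sample(m_cols, min(d_err, length(m_cols) - 1))
    cols[del_at] <- "D"
    drop_q <- qidx[del_at]
    m_cols <- setdiff(m_cols, del_at)
  }
  ins_at <- integer()
  if (i_err > 0 && length(m_cols) > 1)
    ins_at <- sample(m_cols, i_err, replace = TRUE)   # insert after these cols
  # rebuild SEQ: drop deleted bases, append inserted bases after their anchor
  keep <- rep(TRUE, length(chars)); keep[drop_q] <- FALSE
  pieces <- as.list(chars)
  pieces[drop_q] <- list("")
  for (cidx in ins_at) {
    q <- qidx[cidx]
    pieces[[q]] <- paste0(pieces[[q]], sample(c("A", "C", "G", "T"), 1))
  }
  new_seq <- paste(unlist(pieces), collapse = "")
  # rebuild the column vector with an I column after each anchor
  if (length(ins_at)) {
    counts <- tabulate(ins_at, nbins = length(cols))
    out <- rep("I", length(cols) + sum(counts))
    orig_pos <- seq_along(cols) + c(0, cumsum(counts))[seq_along(cols)]
    out[orig_pos] <- cols
    cols <- out
  }
  r <- rle(cols)
  norm <- normalize_cigar(r$values, r$lengths, pos - 1)
  list(ops = norm$ops, lens = norm$lens, pos = norm$pos + 1, seq = new_seq)
}

sam_rec <- function(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq)
  data.table::data.table(qname = qname, flag = flag, rname = rname,
                         pos = as.integer(pos), mapq = as.integer(mapq),
                         cigar = cigar, rnext = rnext,
                         pnext = as.integer(pnext), tlen = as.integer(tlen),
                         seq = seq)

apply_low_mapq <- function(recs, model) {
  lm <- model$low_mapq_regions
  if (is.null(lm) || nrow(recs) == 0) return(recs)
  for (i in seq_len(nrow(lm))) {
    hit <- recs$rname == lm$chrom[i] & recs$flag %% 8 < 4 &
      recs$pos - 1 >= lm$start[i] & recs$pos - 1 < lm$end[i]
    recs$mapq[hit] <- as.integer(lm$mapq[i])
  }
  recs
}

write_bam_records <- function(recs, sim, out_prefix, keep_sam = FALSE) {
  chroms <- names(sim$reference)
  recs <- recs[order(match(recs$rname, chroms), recs$pos)]
  sam_path <- paste0(out_prefix, ".sam")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms,
                      vapply(sim$reference, nchar, 0L)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                  recs$qname, recs$flag, recs$rname, recs$pos, recs$mapq,
                  recs$cigar, recs$rnext, recs$pnext, recs$tlen, recs$seq)
  writeLines(c(header, body), sam_path)
  bam <- Rsamtools::asBam(sam_path, destination = out_prefix,
                          overwrite = TRUE, indexDestination = TRUE)
  if (!keep_sam) unlink(sam_path)
  bam
}

#' Write the simulated reference as an indexed FASTA
#'
#' @param sim An [simulate_genome()] result.
#' @param path Output FASTA path.
#' @export
write_sim_fasta <- function(sim, path) {
  dna <- Biostrings::DNAStringSet(unlist(sim$reference))
  names(dna) <- names(sim$reference)
  Biostrings::writeXStringSet(dna, path)
  Rsamtools::indexFa(path)
  invisible(path)
}

#' Build a complete synthetic fixture suite on disk
#'
#' A deterministic bundle exercising every reader and the whole pipeline:
#' reference FASTA (+fai), two paired-end and one long-read BAM (+bai), truth
#' BED, random non-SV regions BED, a RepeatMasker-style repeat track, a SNP
#' genotype VCF, and the dataset table.  Small enough for the full pipeline
#' to run in well under two minutes.
#'
#' @param dir Output directory (created).
#' @param seed Integer seed; same seed, same files.
#' @param n_random Number of random non-SV regions to include.
#' @return Named list of paths plus the `sv_simulation` object and
#'   [dataset_spec()] list.
#' @export
make_fixture_suite <- function(dir, seed = 1, n_random = 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(chrom_lengths = c(sim1 = 8e4, sim2 = 6e4),
                    n_hom_del = 6, n_het_del = 6, n_hom_ins = 2, n_het_ins = 2,
                    del_size_range = c(150, 600), ins_size_range = c(150, 400))
  sim <- simulate_genome(cfg, seed = seed)
  fasta <- file.path(dir, "ref.fa")
  write_sim_fasta(sim, fasta)
  models <- list(
    read_model("ill100", "paired", depth = 30, read_length = 100,
               insert_mean = 300, insert_sd = 30),
    read_model("ill150", "paired", depth = 20, read_length = 150,
               insert_mean = 400, insert_sd = 40),
    read_model("pacb", "long", depth = 12, len_range = c(800, 2500),
               del_rate = 0.04, ins_rate = 0.09))
  bams <- vapply(seq_along(models), function(i)
    simulate_reads(sim, models[[i]], seed = seed + i,
                   out_prefix = file.path(dir, models[[i]]$name),
                   keep_sam = TRUE), "")
  truth_bed <- file.path(dir, "truth.bed")
  write_sv_calls(sim$truth, truth_bed, dialect = "bed0")
  layout <- genome_layout(names(cfg$chrom_lengths),
                          as.numeric(cfg$chrom_lengths),
                          exclude = sim$truth[, c("chrom", "start", "end")])
  rand <- sample_random_regions_loguniform(layout, n_random, min_size = 50,
                                           max_size = 2000, seed = seed + 10)
  random_bed <- file.path(dir, "random.bed")
  write_sv_calls(rand, random_bed, dialect = "bed0")
  repeats_tsv <- file.path(dir, "repeats.tsv")
  write_sim_repeats(cfg, repeats_tsv, seed = seed + 20)
  snps_vcf <- file.path(dir, "snps.vcf")
  write_sim_snps(sim, snps_vcf, seed = seed + 30)
  datasets <- list(
    dataset_spec("ill100", "paired_short", bams[1], 30),
    dataset_spec("ill150", "paired_short", bams[2], 20),
    dataset_spec("pacb", "unpaired_long", bams[3], 12))
  list(dir = dir, fasta = fasta, bams = setNames(bams, c("ill100", "ill150", "pacb")),
       truth_bed = truth_bed, random_bed = random_bed,
       repeats_tsv = repeats_tsv, snps_vcf = snps_vcf,
       sim = sim, datasets = datasets)
}

write_sim_repeats <- function(cfg, path, seed = 1, n = 120) {
  with_seed(seed, {
    classes <- c("SINE/Alu", "LINE/L1", "LTR/ERVL", "Low_complexity",
                 "Simple_repeat", "DNA/hAT")
    ci <- sample(seq_along(cfg$chrom_lengths), n, replace = TRUE)
    len <- round(runif(n, 50, 400))
    start <- floor(runif(n, 0, cfg$chrom_lengths[ci] - len))
    writeLines(sprintf("%s\t%d\t%d\t%s", names(cfg$chrom_lengths)[ci],
                       start, start + len, sample(classes, n, replace = TRUE)),
               path)
  })
  invisible(path)
}

write_sim_snps <- function(sim, path, seed = 1, n = 200) {
  with_seed(seed, {
    lens <- vapply(sim$reference, nchar, 0L)
    ci <- sample(seq_along(lens), n, replace = TRUE)
    pos1 <- floor(runif(n, 1, lens[ci]))
    o <- order(ci, pos1)
    ci <- ci[o]; pos1 <- pos1[o]
    gt <- sample(c("0/1", "1/1", "1|1", "0|1"), n, replace = TRUE,
                 prob = c(0.45, 0.35, 0.1, 0.1))
    ref <- substr(unlist(sim$reference)[ci], pos1, pos1)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample1",
                 sprintf("%s\t%d\t.\t%s\t%s\t50\tPASS\t.\tGT\t%s",
                         names(lens)[ci], pos1, ref, alt, gt)),
               path)
  })
  invisible(path)
}
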