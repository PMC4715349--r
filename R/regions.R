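#' Describe the sampling frame for random regions
#'
#' @param chrom Chromosome names.
#' @param length Chromosome lengths in bp.
#' @param exclude Optional data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) of intervals random regions must avoid (e.g. assembly gaps).
#' @return A list of class `genome_layout`.
#' @export
genome_layout <- function(chrom, length, exclude = NULL) {
  stopifnot(base::length(chrom) == base::length(length), all(length > 0))
  if (!is.null(exclude))
    stopifnot(all(c("chrom", "start", "end") %in% names(exclude)),
              all(exclude$end > exclude$start))
  structure(list(chroms = data.frame(chrom = as.character(chrom),
                                     length = as.numeric(length),
                                     stringsAsFactors = FALSE),
                 exclude = exclude),
            class = "genome_layout")
}

#' @rdname genome_layout
#' @param bam_path Indexed BAM whose header supplies the chromosome sizes.
#' @export
genome_layout_from_bam <- function(bam_path, exclude = NULL) {
  tl <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  genome_layout(names(tl), as.numeric(tl), exclude = exclude)
}

# Place one region of the given size uniformly on the layout (chromosomes
# weighted by length), avoiding excluded intervals; bounded rejection sampling.
place_region <- function(layout, size, max_attempts = 1000) {
  ok_chrom <- layout$chroms$length >= size
  if (!any(ok_chrom)) stop("no chromosome can hold a region of ", size, " bp")
  chroms <- layout$chroms[ok_chrom, , drop = FALSE]
  w <- chroms$length / sum(chroms$length)
  for (i in seq_len(max_attempts)) {
    ci <- sample.int(nrow(chroms), 1L, prob = w)
    start <- floor(runif(1, 0, chroms$length[ci] - size + 1))
    end <- start + size
    if (!is.null(layout$exclude)) {
      ex <- layout$exclude[layout$exclude$chrom == chroms$chrom[ci], , drop = FALSE]
      if (nrow(ex) > 0 && any(overlap_width(start, end, ex$start, ex$end) > 0)) next
    }
    return(list(chrom = chroms$chrom[ci], start = start, end = end))
  }
  stop("could not place a ", size, " bp region after ", max_attempts,
       " attempts (excluded intervals too dense?)")
}

#' Sample random non-SV regions with log-uniform sizes
#'
#' Sizes are drawn with `log(size) ~ Uniform[log(min_size), log(max_size)]`
#' and placed uniformly on the genome (chromosomes weighted by length),
#' avoiding any excluded intervals.  This is the sampling scheme behind the
#' training class of likely non-SVs.
#'
#' @param layout A [genome_layout()].
#' @param n Number of regions.
#' @param min_size,max_size Size bounds in bp (defaults 50 and 997527, the
#'   published training range).
#' @param seed Integer seed; same seed, same output.
#' @param max_attempts Rejection-sampling cap per region.
#' @return An [sv_calls()] data.frame of type `random`.
#' @export
sample_random_regions_loguniform <- function(layout, n, min_size = 50,
                                             max_size = 997527, seed = NULL,
                                             max_attempts = 1000) {
  stopifnot(min_size >= 1, max_size > min_size, n >= 0)
  with_seed(seed, {
    sizes <- pmin(pmax(round(exp(runif(n, log(min_size), log(max_size)))),
                       min_size), max_size)
    sample_regions_of_sizes(layout, sizes, max_attempts, source = "random_loguniform")
  })
}

#' Sample random regions matching a template size distribution
#'
#' One region per template size (the size multiset is copied exactly), placed
#' like [sample_random_regions_loguniform()].
#'
#' @inheritParams sample_random_regions_loguniform
#' @param template_sizes Sizes in bp to replicate.
#' @return An [sv_calls()] data.frame of type `random`.
#' @export
sample_random_regions_matched <- function(layout, template_sizes, seed = NULL,
                                          max_attempts = 1000) {
  stopifnot(length(template_sizes) > 0, all(template_sizes >= 1))
  with_seed(seed,
    sample_regions_of_sizes(layout, round(template_sizes), max_attempts,
                            source = "random_matched"))
}

sample_regions_of_sizes <- function(layout, sizes, max_attempts, source) {
  placed <- lapply(sizes, function(s) place_region(layout, s, max_attempts))
  if (length(placed) == 0L)
    return(sv_calls(character(), numeric(), numeric(), source = source))
  sv_calls(vapply(placed, `[[`, "", "chrom"),
           vapply(placed, `[[`, 0, "start"),
           vapply(placed, `[[`, 0, "end"),
           sv_type = "random", source = source)
}

#' Sample repeat elements of a class from a repeat track
#'
#' Uniform sample without replacement, e.g. random LINEs/SINEs/LTRs used as
#' additional likely-non-SV sets.
#'
#' @param track A [read_repeat_track()] object.
#' @param repeat_class One of the track's classes (e.g. `"LINE"`).
#' @param n Sample size.
#' @param seed Integer seed.
#' @return An [sv_calls()] data.frame of type `repeat_element`.
#' @export
sample_repeat_elements <- function(track, repeat_class, n, seed = NULL) {
  rec <- track$records[track$records$repeat_class == repeat_class, , drop = FALSE]
  if (nrow(rec) < n)
    stop("track has only ", nrow(rec), " ", repeat_class, " elements; need ", n)
  idx <- with_seed(seed, sample.int(nrow(rec), n))
  rec <- rec[idx, , drop = FALSE]
  sv_calls(rec$chrom, rec$start, rec$end, sv_type = "repeat_element",
           source = paste0("repeat_", repeat_class))
}

#' Deduplicate and merge SV call sets
#'
#' Within each set, any call overlapping another call of the same set by at
#' least `min_overlap` bp is discarded (both members: overlapping calls may be
#' compound heterozygous or imprecise).  Across sets, earlier sets take
#' priority: a later call overlapping any retained earlier call is dropped.
#' The result has no pairwise overlaps of `min_overlap` bp or more.
#'
#' @param sets List of [sv_calls()] data.frames, ordered by priority.
#' @param min_overlap Minimum overlap in bp that counts (default 1).
#' @return An [sv_calls()] data.frame.
#' @export
deduplicate_calls <- function(sets, min_overlap = 1) {
  stopifnot(length(sets) >= 1)
  as_gr <- function(calls) GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$start + 1, calls$end))
  survivors <- lapply(sets, function(calls) {
    if (nrow(calls) <= 1L) return(calls)
    gr <- as_gr(calls)
    hits <- GenomicRanges::findOverlaps(gr, minoverlap = min_overlap,
                                        drop.self = TRUE)
    calls[setdiff(seq_len(nrow(calls)), S4Vectors::queryHits(hits)), , drop = FALSE]
  })
  kept <- survivors[[1]]
  for (calls in survivors[-1]) {
    if (nrow(calls) == 0L) next
    if (nrow(kept) == 0L) { kept <- calls; next }
    # disjoint chromosome sets legitimately share no seqlevels
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(as_gr(calls), as_gr(kept),
                                  minoverlap = min_overlap))
    keep <- setdiff(seq_len(nrow(calls)), S4Vectors::queryHits(hits))
    kept <- rbind(kept, calls[keep, , drop = FALSE])
  }
  rownames(kept) <- NULL
  kept
}

#' Match a query call against targets by reciprocal overlap
#'
#' A target matches when the overlap covers at least `fraction` of the query
#' AND at least `fraction` of the target (boundary inclusive).  Among multiple
#' matches the largest overlap wins; ties go to the smallest target start.
#'
#' @param query Single-row [sv_calls()] data.frame (or list with `chrom`,
#'   `start`, `end`).
#' @param targets [sv_calls()] data.frame.
#' @param fraction Required reciprocal fraction in (0, 1].
#' @return Integer row index into `targets`, or `NA_integer_` if no match.
#' @export
reciprocal_overlap_match <- function(query, targets, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  if (nrow(targets) == 0L) return(NA_integer_)
  qs <- as.numeric(query$start[1]); qe <- as.numeric(query$end[1])
  same <- targets$chrom == as.character(query$chrom[1])
  ov <- ifelse(same, overlap_width(qs, qe, targets$start, targets$end), 0)
  qlen <- qe - qs
  tlen <- targets$end - targets$start
  match <- ov >= fraction * qlen & ov >= fraction * tlen
  if (!any(match)) return(NA_integer_)
  cand <- which(match)
  cand <- cand[order(-ov[cand], targets$start[cand])]
  cand[1]
}
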