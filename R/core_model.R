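#' Construct a genomic interval
#'
#' Intervals are 0-based half-open: `start` is the first base, `end` is one
#' past the last base, so `end - start` is the length in bp.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @return A list with elements `chrom`, `start`, `end`.
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || end <= start)
    stop("invalid interval: ", chrom, ":", start, "-", end)
  list(chrom = as.character(chrom), start = start, end = end)
}

#' Overlap in bp between two genomic intervals
#'
#' Returns `max(0, min(ends) - max(starts))`; 0 for different chromosomes or
#' half-open abutment.
#'
#' @param a,b Intervals from [genomic_interval()] (any list with `chrom`,
#'   `start`, `end`).
#' @return Overlap width in bp (non-negative).
#' @export
interval_overlap <- function(a, b) {
  if (!identical(as.character(a$chrom), as.character(b$chrom))) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

# Vectorized overlap width on parallel start/end vectors (same chromosome).
overlap_width <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

SV_TYPES <- c("deletion", "insertion", "random", "repeat_element")

#' Construct a table of SV candidate calls
#'
#' The common currency of the package: one row per candidate site or random
#' region, 0-based half-open coordinates.
#'
#' @param chrom,start,end Parallel coordinate vectors (0-based half-open).
#' @param sv_type One of `"deletion"`, `"insertion"`, `"random"`,
#'   `"repeat_element"` (recycled).
#' @param alt_seq Optional inserted sequence (insertions only).
#' @param source Free-text call-set label (recycled).
#' @param zygosity Optional `"het"`, `"hom"` or `NA`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `sv_type`,
#'   `alt_seq`, `source`, `zygosity`.
#' @export
sv_calls <- function(chrom, start, end, sv_type = "random", alt_seq = NA_character_,
                     source = "user", zygosity = NA_character_) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    sv_type = rep_len(as.character(sv_type), n),
    alt_seq = rep_len(as.character(alt_seq), n),
    source = rep_len(as.character(source), n),
    zygosity = rep_len(as.character(zygosity), n),
    stringsAsFactors = FALSE
  )
  validate_sv_calls(df)
}

#' @rdname sv_calls
#' @param calls A candidate data.frame to validate.
#' @export
validate_sv_calls <- function(calls) {
  stopifnot(all(c("chrom", "start", "end") %in% names(calls)))
  if (any(calls$end <= calls$start | calls$start < 0))
    stop("sv_calls: every interval needs 0 <= start < end")
  if (!all(is.na(calls$sv_type) | calls$sv_type %in% SV_TYPES))
    stop("sv_calls: unknown sv_type")
  bad <- !is.na(calls$alt_seq) & calls$sv_type != "insertion"
  if (any(bad)) stop("sv_calls: alt_seq is only meaningful for insertions")
  calls
}

REGION_NAMES <- c("L", "LM", "M", "RM", "R")

#' Partition a candidate site into the five evaluation windows
#'
#' Around a candidate SV `[start, end)` the classifier looks at five windows:
#' the left flank `L`, the left-inner window `LM`, the SV interval `M`, the
#' right-inner window `RM`, and the right flank `R`.  `L`/`R` have length
#' `flank_size`, truncated at contig bounds; `LM`/`RM` are capped at half the
#' SV length so they never overlap each other.
#'
#' @param sv A single-row candidate (`chrom`, `start`, `end`) or a list with
#'   those fields.
#' @param flank_size Flank width in bp (default 100, roughly a short-read
#'   length).
#' @param contig_length Length of the contig holding the site.
#' @return A list of class `region_partition`: `chrom`, `flank_size`,
#'   `regions` (named list of `c(start, end)`), `truncated` (named logical).
#' @export
partition_site <- function(sv, flank_size = 100, contig_length) {
  chrom <- as.character(sv$chrom[1])
  start <- as.numeric(sv$start[1]); end <- as.numeric(sv$end[1])
  if (start < 0 || end > contig_length)
    stop("contig ", chrom, " (length ", contig_length,
         ") cannot hold site ", chrom, ":", start, "-", end)
  w <- min(flank_size, floor((end - start) / 2))
  L <- c(max(0, start - flank_size), start)
  R <- c(end, min(contig_length, end + flank_size))
  structure(list(
    chrom = chrom,
    flank_size = flank_size,
    regions = list(
      L = L,
      LM = c(start, start + w),
      M = c(start, end),
      RM = c(end - w, end),
      R = R
    ),
    truncated = c(L = (L[2] - L[1]) < flank_size,
                  R = (R[2] - R[1]) < flank_size)
  ), class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("region partition on", x$chrom, "(flank", x$flank_size, "bp)\n")
  for (r in REGION_NAMES)
    cat(sprintf("  %-2s [%d, %d)%s\n", r, x$regions[[r]][1], x$regions[[r]][2],
                if (r %in% names(x$truncated) && isTRUE(x$truncated[[r]])) " [truncated]" else ""))
  invisible(x)
}

#' Describe a sequencing dataset
#'
#' @param name Dataset label used as an annotation prefix in combined tables.
#' @param technology `"paired_short"` (paired-end short reads) or
#'   `"unpaired_long"` (single-end long reads).
#' @param bam_path Path to a coordinate-sorted, indexed BAM.
#' @param mean_coverage Expected genome-wide depth.
#' @param long_read_indel_baseline Length-2 numeric, mean deleted and inserted
#'   bases per read base over random regions; required for long reads.  The
#'   defaults are the published constants; `run_pipeline()` re-estimates them
#'   from the training random regions.
#' @return A list of class `dataset_spec`.
#' @export
dataset_spec <- function(name, technology = c("paired_short", "unpaired_long"),
                         bam_path, mean_coverage,
                         long_read_indel_baseline = c(0.0428, 0.0948)) {
  technology <- match.arg(technology)
  if (technology == "unpaired_long") {
    stopifnot(length(long_read_indel_baseline) == 2L,
              all(is.finite(long_read_indel_baseline)))
  } else {
    long_read_indel_baseline <- NULL
  }
  structure(list(name = name, technology = technology, bam_path = bam_path,
                 mean_coverage = mean_coverage,
                 long_read_indel_baseline = long_read_indel_baseline),
            class = "dataset_spec")
}

#' Construct an annotation table
#'
#' A sites-by-annotations numeric matrix; `NA` cells are "masked" (no usable
#' evidence, e.g. insert-size statistics in a region with no proper pairs) and
#' are imputed downstream by [apply_transform()].
#'
#' @param values Numeric matrix with rownames = site ids, colnames =
#'   annotation names.
#' @return A list of class `annotation_table`: `values`, `mask`, `site_ids`,
#'   `annotation_names`.
#' @export
annotation_table <- function(values) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (anyDuplicated(colnames(values))) stop("duplicate annotation names")
  if (is.null(rownames(values))) rownames(values) <- paste0("site_", seq_len(nrow(values)))
  if (any(is.infinite(values))) stop("annotation values must be finite or NA")
  structure(list(values = values, mask = is.na(values),
                 site_ids = rownames(values),
                 annotation_names = colnames(values)),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("annotation table:", nrow(x$values), "sites x", ncol(x$values),
      "annotations;", sum(x$mask), "masked cells\n")
  invisible(x)
}
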