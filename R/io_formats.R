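#' Read candidate SV calls from a BED-like file
#'
#' Two dialects are understood: `bed0` (0-based half-open, BED) and `tsv1`
#' (1-based fully-closed, as in most SV supplementary tables).  Columns beyond
#' the first three are optional: type, alt_sequence, zygosity.  Malformed
#' records (end before start after conversion) are skipped and counted.
#'
#' @param path TSV/BED file, no header, >= 3 columns.
#' @param dialect `"bed0"` or `"tsv1"`.
#' @param source Call-set label stored with each record.
#' @return An [sv_calls()] data.frame (0-based half-open) with attributes
#'   `n_skipped` and `skipped_lines`.
#' @export
read_sv_calls <- function(path, dialect = c("bed0", "tsv1"), source = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 3L) stop(path, ": need at least 3 columns (chrom, start, end)")
  chrom <- as.character(dt[[1]])
  start <- suppressWarnings(as.numeric(dt[[2]]))
  end <- suppressWarnings(as.numeric(dt[[3]]))
  if (dialect == "tsv1") start <- start - 1    # 1-based inclusive -> 0-based
  clean <- function(x) { x[x %in% c(".", "", "NA")] <- NA_character_; x }
  type <- if (ncol(dt) >= 4L) normalize_sv_type(as.character(dt[[4]])) else "random"
  alt <- if (ncol(dt) >= 5L) clean(as.character(dt[[5]])) else NA_character_
  zyg <- if (ncol(dt) >= 6L) clean(tolower(as.character(dt[[6]]))) else NA_character_
  bad <- is.na(start) | is.na(end) | start < 0 | end <= start
  if (any(bad)) {
    warning(path, ": skipped ", sum(bad), " malformed record(s) at line(s) ",
            paste(which(bad), collapse = ","))
  }
  out <- sv_calls(chrom[!bad], start[!bad], end[!bad],
                  sv_type = rep_len(type, length(chrom))[!bad],
                  alt_seq = rep_len(alt, length(chrom))[!bad],
                  source = source,
                  zygosity = rep_len(zyg, length(chrom))[!bad])
  attr(out, "n_skipped") <- sum(bad)
  attr(out, "skipped_lines") <- which(bad)
  out
}

normalize_sv_type <- function(x) {
  x <- tolower(x)
  out <- rep("random", length(x))
  out[grepl("^del", x)] <- "deletion"
  out[grepl("^ins", x)] <- "insertion"
  out[grepl("repeat|line|sine|ltr", x)] <- "repeat_element"
  out[x %in% SV_TYPES] <- x[x %in% SV_TYPES]
  out
}

#' Write SV calls back to a BED-like file
#'
#' @param calls An [sv_calls()] data.frame.
#' @param path Output path.
#' @param dialect Coordinate dialect to emit (see [read_sv_calls()]).
#' @export
write_sv_calls <- function(calls, path, dialect = c("bed0", "tsv1")) {
  dialect <- match.arg(dialect)
  start <- if (dialect == "tsv1") calls$start + 1 else calls$start
  dt <- data.table::data.table(calls$chrom, format(start, scientific = FALSE, trim = TRUE),
                               format(calls$end, scientific = FALSE, trim = TRUE),
                               calls$sv_type,
                               ifelse(is.na(calls$alt_seq), ".", calls$alt_seq),
                               ifelse(is.na(calls$zygosity), ".", calls$zygosity))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

REPEAT_CLASSES <- c("SINE", "LINE", "LTR", "low_complexity", "simple_repeat", "other")

map_repeat_class <- function(x) {
  out <- rep("other", length(x))
  out[grepl("^SINE", x)] <- "SINE"
  out[grepl("^LINE", x)] <- "LINE"
  out[grepl("^LTR", x)] <- "LTR"
  out[grepl("^Low_complexity", x, ignore.case = TRUE)] <- "low_complexity"
  out[grepl("^Simple_repeat", x, ignore.case = TRUE)] <- "simple_repeat"
  out
}

#' Read a RepeatMasker-style repeat track
#'
#' UCSC rmsk-style TSV.  Repeat classes are mapped by prefix to
#' SINE/LINE/LTR/low_complexity/simple_repeat; anything else becomes `other`.
#'
#' @param path TSV file, no header.
#' @param cols Named integer vector giving the column positions of
#'   `genoName`, `genoStart` (0-based), `genoEnd`, `repClass`.
#' @return A list of class `repeat_track` with `records` (data.frame `chrom`,
#'   `start`, `end`, `repeat_class`, 0-based half-open) and a `GRanges` index
#'   `gr` for overlap queries.
#' @export
read_repeat_track <- function(path, cols = c(genoName = 1L, genoStart = 2L,
                                             genoEnd = 3L, repClass = 4L)) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      repeat_class = character(), stringsAsFactors = FALSE)
  dt <- tryCatch(suppressWarnings(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)),
    error = function(e) NULL)
  n_skipped <- 0L
  if (is.null(dt) || nrow(dt) == 0L || ncol(dt) < max(cols)) {
    rec <- empty
  } else {
    chrom <- as.character(dt[[cols[["genoName"]]]])
    start <- suppressWarnings(as.numeric(dt[[cols[["genoStart"]]]]))
    end <- suppressWarnings(as.numeric(dt[[cols[["genoEnd"]]]]))
    cls <- map_repeat_class(as.character(dt[[cols[["repClass"]]]]))
    bad <- is.na(start) | is.na(end) | end <= start
    n_skipped <- sum(bad)
    rec <- data.frame(chrom = chrom[!bad], start = start[!bad], end = end[!bad],
                      repeat_class = cls[!bad], stringsAsFactors = FALSE)
  }
  new_repeat_track(rec, n_skipped)
}

new_repeat_track <- function(records, n_skipped = 0L) {
  gr <- GenomicRanges::GRanges(
    records$chrom,
    IRanges::IRanges(start = records$start + 1, end = records$end))
  structure(list(records = records, gr = gr, n_skipped = n_skipped),
            class = "repeat_track")
}

#' Query a repeat track for records overlapping an interval
#'
#' @param track A [read_repeat_track()] object.
#' @param chrom,start,end Query interval, 0-based half-open.
#' @return The overlapping rows of `track$records`.
#' @export
repeat_query <- function(track, chrom, start, end) {
  if (nrow(track$records) == 0L || end <= start) return(track$records[0, ])
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  hits <- GenomicRanges::findOverlaps(q, track$gr)
  track$records[S4Vectors::subjectHits(hits), , drop = FALSE]
}

#' Read SNP genotype calls from a VCF
#'
#' Keeps biallelic-style SNP records only (REF and first ALT both length 1);
#' `0/1`, `1/0` (or phased) map to `het`, `1/1` to `hom_alt`; anything else,
#' including missing GT, is ignored.
#'
#' @param path VCF file (plain text or gzip).
#' @return A list of class `snp_genotypes` with `records` (data.frame `chrom`,
#'   `pos` 0-based, `genotype`).
#' @export
read_snp_genotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- data.frame(chrom = character(), pos = numeric(),
                      genotype = character(), stringsAsFactors = FALSE)
  if (nrow(v@fix) == 0L) return(structure(list(records = empty), class = "snp_genotypes"))
  ref <- v@fix[, "REF"]
  alt1 <- vapply(strsplit(v@fix[, "ALT"], ","), `[`, "", 1L)  # first ALT only
  is_snp <- !is.na(ref) & !is.na(alt1) & nchar(ref) == 1L & nchar(alt1) == 1L
  gt_raw <- tryCatch(vcfR::extract.gt(v, element = "GT")[, 1L],
                     error = function(e) rep(NA_character_, nrow(v@fix)))
  alleles <- strsplit(gt_raw, "[/|]")
  geno <- vapply(alleles, function(a) {
    if (length(a) != 2L || anyNA(suppressWarnings(as.integer(a)))) return(NA_character_)
    a <- sort(as.integer(a))
    if (a[1] == 0L && a[2] == 1L) "het"
    else if (a[1] == 1L && a[2] == 1L) "hom_alt"
    else NA_character_
  }, "")
  keep <- is_snp & !is.na(geno)
  rec <- data.frame(chrom = as.character(v@fix[keep, "CHROM"]),
                    pos = as.numeric(v@fix[keep, "POS"]) - 1,
                    genotype = geno[keep], stringsAsFactors = FALSE)
  structure(list(records = rec), class = "snp_genotypes")
}

#' Write / read an annotation table as CSV
#'
#' First column `site_id`, then one column per annotation; masked cells are
#' serialized as `NA`.  `read_annotation_table(write_annotation_table(x))`
#' round-trips up to float formatting.
#'
#' @param table An [annotation_table()].
#' @param path CSV path.
#' @export
write_annotation_table <- function(table, path) {
  dt <- data.table::data.table(site_id = table$site_ids)
  vals <- data.table::as.data.table(table$values)
  data.table::fwrite(cbind(dt, vals), path, na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_annotation_table
#' @export
read_annotation_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, na.strings = "NA")
  if (anyDuplicated(names(dt))) stop(path, ": duplicate column names")
  if (names(dt)[1] != "site_id") stop(path, ": first column must be site_id")
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(dt$site_id)
  annotation_table(m)
}

#' Write classified candidate calls as a BED-like TSV
#'
#' One row per input site: coordinates (restored to the requested dialect),
#' type, per-dataset rho scores, ensemble score and votes, stratum, and
#' pre-filter flags.
#'
#' @param results Data.frame as produced by [run_pipeline()]: columns `chrom`,
#'   `start`, `end`, `sv_type`, one `rho_<dataset>` per dataset,
#'   `ensemble_rho`, `votes`, `call`, `stratum`, `high_flank_coverage`,
#'   `low_flank_mapq`.
#' @param path Output TSV path.
#' @param dialect Coordinate dialect for `start` (see [read_sv_calls()]).
#' @export
write_classified_calls <- function(results, path, dialect = c("tsv1", "bed0")) {
  dialect <- match.arg(dialect)
  out <- results
  if (dialect == "tsv1") out$start <- out$start + 1
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_classified_calls
#' @export
read_classified_calls <- function(path, dialect = c("tsv1", "bed0")) {
  dialect <- match.arg(dialect)
  out <- as.data.frame(data.table::fread(path, header = TRUE, na.strings = "NA"))
  if (dialect == "tsv1") out$start <- out$start - 1
  out
}
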