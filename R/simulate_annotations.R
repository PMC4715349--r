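#' Simulate per-site annotation vectors directly
#'
#' Draws annotation vectors from a parametric sketch of what
#' [annotate_sites()] produces on each site class, without constructing a
#' genome or BAM — the route for experiments at the published scale (for
#' example 4000 training random regions with sizes up to ~1 Mb, which no
#' desk-size genome can hold).  Random sites follow the null distribution of
#' read evidence around the dataset's mean coverage; planted heterozygous and
#' homozygous deletions scale the inner-region depth by 0.5 and ~0 and raise
#' flank clipping/discordance (or the long-read deletion rate) accordingly.
#' Columns are the `oneclass` annotation subset of [annotate_sites()], so the
#' tables plug directly into the transform and the classifiers.
#'
#' All draws are independent across sites given the class, so training and
#' held-out tables of the same class are exchangeable — the property behind
#' the calibration of the rho score.
#'
#' @param n Number of sites.
#' @param technology `"paired_short"` or `"unpaired_long"`.
#' @param class Site class: `"random"`, `"het_del"` or `"hom_del"`.
#' @param seed Integer seed.
#' @param mean_coverage Dataset mean depth (default 200, a deep short-read
#'   genome; use lower values for long reads).
#' @param size_range Site sizes are drawn log-uniformly from this range
#'   (default the published random-region range 50–997527 bp for random
#'   sites; deletions default to 100–10000 bp).
#' @param read_length,insert_mean,insert_sd Short-read model parameters.
#' @param long_read_length Typical long-read length.
#' @param indel_baseline Long-read per-base deletion/insertion rates around
#'   which random regions fluctuate.
#' @param flank_size Flank width (default 100).
#' @return An [annotation_table()] with attribute `class` = `class`.
#' @export
simulate_annotation_table <- function(n, technology = c("paired_short", "unpaired_long"),
                                      class = c("random", "het_del", "hom_del"),
                                      seed = NULL, mean_coverage = 200,
                                      size_range = NULL, read_length = 100,
                                      insert_mean = 300, insert_sd = 30,
                                      long_read_length = 2000,
                                      indel_baseline = c(0.0428, 0.0948),
                                      flank_size = 100) {
  technology <- match.arg(technology)
  class <- match.arg(class)
  if (is.null(size_range))
    size_range <- if (class == "random") c(50, 997527) else c(100, 10000)
  with_seed(seed, {
    len <- round(exp(runif(n, log(size_range[1]), log(size_range[2]))))
    mult_inner <- switch(class, random = 1, het_del = 0.5, hom_del = 0.02)
    rl <- if (technology == "paired_short") read_length else long_read_length
    c0 <- mean_coverage
    # mean depth over a w-bp window: relative sd ~ sqrt(rl / (c * w))
    draw_cov <- function(w, mult) pmax(0, rnorm(n, c0 * mult,
      c0 * mult * sqrt(rl / (c0 * pmax(w, 1))) + 1e-3))
    inner_w <- pmin(flank_size, floor(len / 2))
    flank_reads <- pmax(4, round(c0 * (flank_size + rl) / rl))
    frac <- function(p) rbinom(n, flank_reads, p) / flank_reads
    clip_p <- switch(class, random = 0.004, het_del = 0.18, hom_del = 0.35)
    if (technology == "paired_short") {
      n_pairs <- pmax(5, round(c0 * flank_size / (2 * rl)))
      disc_p <- switch(class, random = 0.001, het_del = 0.04, hom_del = 0.08)
      vals <- cbind(
        LM_Cov = draw_cov(inner_w, mult_inner),
        M_Cov = draw_cov(len, mult_inner),
        RM_Cov = draw_cov(inner_w, mult_inner),
        L_SoftClip = frac(clip_p), R_SoftClip = frac(clip_p),
        L_InsertMean = rnorm(n, insert_mean, insert_sd / sqrt(n_pairs)),
        L_InsertSd = insert_sd * sqrt(stats::rchisq(n, n_pairs - 1) / (n_pairs - 1)),
        R_InsertMean = rnorm(n, insert_mean, insert_sd / sqrt(n_pairs)),
        R_InsertSd = insert_sd * sqrt(stats::rchisq(n, n_pairs - 1) / (n_pairs - 1)),
        L_Discord = frac(disc_p), R_Discord = frac(disc_p),
        L_MateUnmapped = frac(0.001), R_MateUnmapped = frac(0.001))
    } else {
      clip_p <- switch(class, random = 0.01, het_del = 0.13, hom_del = 0.25)
      del_shift <- switch(class, random = 0, het_del = 0.5, hom_del = 1) *
        pmin(0.4, len / long_read_length)
      del_rate <- pmax(0, rnorm(n, indel_baseline[1] + del_shift, 0.004))
      ins_rate <- pmax(0, rnorm(n, indel_baseline[2], 0.005))
      vals <- cbind(
        LM_Cov = draw_cov(inner_w, mult_inner),
        M_Cov = draw_cov(len, mult_inner),
        RM_Cov = draw_cov(inner_w, mult_inner),
        L_SoftClip = frac(clip_p), R_SoftClip = frac(clip_p),
        M_DelInsDiff = (del_rate - indel_baseline[1]) -
          (ins_rate - indel_baseline[2]))
    }
    rownames(vals) <- sprintf("%s_%05d", class, seq_len(n))
    out <- annotation_table(vals)
    attr(out, "class_label") <- class
    out
  })
}

#' Stack annotation tables row-wise
#'
#' @param ... [annotation_table()] objects with identical columns.
#' @return One [annotation_table()]; row names made unique.
#' @export
rbind_annotation_tables <- function(...) {
  tabs <- list(...)
  cols <- colnames(tabs[[1]]$values)
  stopifnot(all(vapply(tabs, function(t)
    identical(colnames(t$values), cols), NA)))
  m <- do.call(rbind, lapply(tabs, `[[`, "values"))
  rownames(m) <- make.unique(rownames(m))
  annotation_table(m)
}
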