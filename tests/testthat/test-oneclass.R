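# A small training table with continuous columns for model fitting.
train_table <- function(n = 200, seed = 44) {
  set.seed(seed)
  annotation_table(cbind(M_Cov = rexp(n, 1 / 30), L_SoftClip = runif(n, 0, 0.05),
                         R_Discord = runif(n, 0, 0.1)))
}

test_that("L1 model centroid and distances match direct recomputation", {
  tab <- train_table()
  tm <- fit_transform_model(tab)
  m <- fit_l1_model(tab, tm, min_train = 100)
  z <- apply_transform(tm, tab)$values
  expect_equal(m$M, colMeans(z))
  d <- sort(rowSums(abs(sweep(z, 2, colMeans(z)))))
  expect_equal(m$distances, unname(d))
  # shuffled rows give the identical model
  perm <- sample.int(nrow(tab$values))
  m2 <- fit_l1_model(annotation_table(tab$values[perm, ]), tm, min_train = 100)
  expect_equal(m2$M, m$M)
  expect_equal(m2$distances, m$distances)
  # identical rows -> all distances zero
  same <- annotation_table(matrix(5, 120, 2,
                                  dimnames = list(NULL, c("a", "b"))))
  tm0 <- suppressWarnings(fit_transform_model(
    annotation_table(cbind(a = c(rep(5, 119), 6), b = c(rep(5, 119), 7)))))
  expect_error(fit_l1_model(train_table(50), tm, min_train = 100), "at least 100")
})

test_that("rho is the fraction of training sites strictly closer than the site", {
  tab <- train_table()
  tm <- fit_transform_model(tab)
  m <- fit_l1_model(tab, tm, min_train = 100)
  m$distances <- c(1, 2, 3, 4); m$n_train <- 4    # frozen toy distances
  mk <- function(d) { v <- m$M; v[1] <- v[1] + d; v }
  expect_equal(rho_score(m, mk(2.5)), 0.5)
  expect_equal(rho_score(m, m$M), 0)           # at the centroid
  expect_equal(rho_score(m, mk(99)), 1)        # beyond all training sites
  expect_equal(rho_score(m, mk(2)), 0.25)      # tie counts as not closer
  expect_error(rho_score(m, 1:2), "model expects")
})

test_that("classifying the training set at p keeps exactly ceil(p*n)/n inside", {
  tab <- train_table(300)
  tm <- fit_transform_model(tab)
  m <- fit_l1_model(tab, tm, min_train = 100)
  z <- apply_transform(tm, tab)$values
  for (p in c(0.9, 0.95, 0.99)) {
    calls <- apply(z, 1, function(v) classify_l1(m, v, p))
    expect_equal(mean(calls == "non-SV"), ceiling(p * 300) / 300)
  }
  # boundary: a site at exactly t_p is non-SV (strict >)
  tp <- l1_threshold(m, 0.95)
  v <- m$M; v[1] <- v[1] + tp
  expect_equal(classify_l1(m, v, 0.95), "non-SV")
})

test_that("an SV call at p stays an SV call at any smaller p", {
  tab <- train_table(150, seed = 45)
  tm <- fit_transform_model(tab)
  m <- fit_l1_model(tab, tm, min_train = 100)
  set.seed(46)
  p_grid <- c(0.5, 0.7, 0.9, 0.95, 0.99)
  for (i in 1:20) {
    v <- m$M + rnorm(length(m$M), 0, 2)
    calls <- vapply(p_grid, function(p) classify_l1(m, v, p), "")
    # once non-SV, never SV again as p grows
    expect_false(is.unsorted(rev(calls == "SV")))
  }
})

test_that("directional CDF transform sends deviants toward 0", {
  tab <- train_table(400, seed = 47)
  tm <- fit_transform_model(tab)
  svm <- fit_svm_model(tab, tm)
  z <- apply_transform(tm, tab)$values
  u <- svarbiter:::svm_directional_transform(svm, z)
  expect_true(all(u > 0 & u <= 1))
  # brute-force check of u = 1 - #{v_j < v}/n on a sample
  for (a in colnames(z)) {
    v <- svarbiter:::deviation_value(z[, a], svm$directions[[a]])
    for (i in sample.int(length(v), 10))
      expect_equal(u[i, a], 1 - sum(v < v[i]) / length(v))
  }
  # the median training value of a low-deviant annotation sits near 0.5
  med_idx <- which.min(abs(z[, "M_Cov"] - median(z[, "M_Cov"])))
  expect_lt(abs(u[med_idx, "M_Cov"] - 0.5), 0.05)
  # the most deviant training value attains the minimum u = 1/n
  worst <- which.min(z[, "M_Cov"])   # depth: low is deviant
  expect_equal(u[worst, "M_Cov"], min(u[, "M_Cov"]))
  expect_equal(min(u[, "M_Cov"]), 1 / nrow(z))
})

test_that("nu controls the training outlier fraction of each boundary", {
  tab <- train_table(500, seed = 48)
  tm <- fit_transform_model(tab)
  svm <- fit_svm_model(tab, tm)
  z <- apply_transform(tm, tab)$values
  u <- svarbiter:::svm_directional_transform(svm, z)
  for (i in seq_along(svm$nu_grid)) {
    frac_out <- 1 - mean(as.logical(predict(svm$models[[i]], u)))
    expect_lte(frac_out, svm$nu_grid[i] + 0.02)
    expect_gte(frac_out, svm$nu_grid[i] - 0.02)
  }
  expect_error(fit_svm_model(tab, tm, nu_grid = c(0.1, 1.5)), "nu_grid")
})

test_that("svm scores agree with exhaustive per-nu membership evaluation", {
  tab <- train_table(300, seed = 49)
  tm <- fit_transform_model(tab)
  svm <- fit_svm_model(tab, tm)
  cand <- annotation_table(cbind(M_Cov = c(30, 0.01, 28),
                                 L_SoftClip = c(0.02, 0.9, 0.01),
                                 R_Discord = c(0.05, 0.9, 0.04)))
  scores <- score_sites(svm, cand)
  z <- apply_transform(tm, cand)$values
  u <- svarbiter:::svm_directional_transform(svm, z)
  for (i in seq_len(nrow(u))) {
    inside <- vapply(svm$models, function(m)
      as.logical(predict(m, u[i, , drop = FALSE])), NA)
    want <- if (!any(inside)) 1 else 1 - max(svm$nu_grid[inside])
    expect_equal(unname(scores[i]), want)
  }
  # a typical site is inside every boundary; an extreme outlier none
  expect_equal(unname(scores[1]), 1 - max(svm$nu_grid))
  expect_equal(unname(scores[2]), 1)
})

test_that("ensemble votes and the k-th largest rho are equivalent", {
  expect_equal(ensemble_vote(c("SV", "SV", "SV", "non-SV"), 3), "SV")
  expect_equal(ensemble_vote(c("SV", "SV", "non-SV", "non-SV"), 3), "non-SV")
  expect_error(ensemble_vote(c("SV", "SV"), 3), "k <= ")
  set.seed(50)
  for (i in 1:100) {
    rhos <- runif(4)
    p <- runif(1)
    for (k in 1:4) {
      votes <- ifelse(rhos > p, "SV", "non-SV")
      expect_identical(ensemble_vote(votes, k) == "SV",
                       ensemble_rho(rhos, k) > p)
    }
  }
})

test_that("prefilters apply AND over coverage and OR over mapping quality", {
  fs <- data.frame(L_Cov = c(400, 400, 50, 310),
                   R_Cov = c(50, 400, 50, 320),
                   L_MapQ = c(10, 60, 60, 60),
                   R_MapQ = c(60, 60, 29, 60))
  pf <- prefilter_sites(fs, max_flank_coverage = 300, min_flank_mapq = 30)
  expect_equal(pf$high_flank_coverage, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(pf$low_flank_mapq, c(TRUE, FALSE, TRUE, FALSE))
  fs_na <- data.frame(L_Cov = NA_real_, R_Cov = 50, L_MapQ = 60, R_MapQ = 60)
  expect_true(prefilter_sites(fs_na)$unfilterable)
})

test_that("strata reproduce the published tiers as half-open bins", {
  rho <- c(0, 0.5, 0.68, 0.89, 0.95, 0.98, 0.995, 0.998, 0.9995, 1)
  s <- stratify(rho)
  expect_equal(as.character(s),
               c("<0.68", "<0.68", "0.68-0.9", "0.68-0.9", "0.9-0.97",
                 "0.97-0.99", "0.99-0.997", "0.997-0.999", ">0.999", ">0.999"))
  # every site lands in exactly one stratum
  expect_false(anyNA(s))
  expect_equal(as.character(stratify(0.995)), "0.99-0.997")
})

test_that("ROC behaves on separated, identical and tied score sets", {
  r <- roc_curve(c(0.9, 0.95, 1), c(0.1, 0.2, 0.3))
  expect_equal(r$auc, 1)
  expect_false(is.unsorted(r$points$tpr))
  expect_false(is.unsorted(r$points$fpr))
  set.seed(51)
  x <- runif(400)
  r2 <- roc_curve(x, x)    # identical distributions
  expect_equal(r2$auc, 0.5, tolerance = 1e-9)
  # AUC equals the Mann-Whitney probability (independent oracle)
  pos <- rnorm(150, 1); neg <- rnorm(150)
  r3 <- roc_curve(pos, neg)
  w <- wilcox.test(pos, neg)$statistic / (150 * 150)
  expect_equal(r3$auc, unname(w), tolerance = 1e-9)
})

test_that("rho depends on the data only through the standardized space", {
  tab <- train_table(150, seed = 52)
  tm <- fit_transform_model(tab)
  m <- fit_l1_model(tab, tm, min_train = 100)
  cand <- annotation_table(tab$values[1:20, ] * 1)
  r1 <- score_sites(m, cand)
  # rescaling raw values changes scores unless the transform is refit:
  # identical standardized input must give identical rho
  r2 <- score_sites(m, annotation_table(tab$values[1:20, ]))
  expect_identical(r1, r2)
})
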