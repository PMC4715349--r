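#' Inverse hyperbolic sine transform
#'
#' `y = log(x + sqrt(x^2 + 1))`: log-like variance stabilization that, unlike
#' the log, is defined at zero and for negative values and is odd.  Applied to
#' every annotation before standardization, clustering and classification.
#'
#' @param x Finite numeric vector.
#' @return Transformed values.
#' @export
asinh_transform <- function(x) {
  if (any(!is.finite(x))) stop("asinh_transform: non-finite input")
  asinh(x)
}

# Inverse, used in tests: x = sinh(y)
asinh_inverse <- function(y) sinh(y)

#' Fit the transform/standardization model on training data
#'
#' Per annotation, the mean and standard deviation of asinh-transformed
#' training values (masked cells excluded).  Annotations with fewer than two
#' unmasked values or zero variance carry no information for a
#' distance-to-centroid model and are dropped (recorded in `$dropped`).
#'
#' @param training An [annotation_table()] of training sites (random
#'   regions); at least 2 rows.
#' @return A list of class `transform_model`: `params` (data.frame
#'   `annotation`, `mu`, `sigma`), `dropped` (character).
#' @export
fit_transform_model <- function(training) {
  stopifnot(inherits(training, "annotation_table"), nrow(training$values) >= 2)
  ann <- colnames(training$values)
  mu <- sigma <- setNames(numeric(length(ann)), ann)
  ok <- logical(length(ann))
  for (j in seq_along(ann)) {
    v <- training$values[, j]
    v <- v[!is.na(v)]
    if (length(v) < 2L) next
    tv <- asinh_transform(v)
    s <- sd(tv)
    if (!is.finite(s) || s == 0) next
    mu[j] <- mean(tv); sigma[j] <- s; ok[j] <- TRUE
  }
  if (any(!ok))
    warning("dropping constant/empty annotation(s): ",
            paste(ann[!ok], collapse = ", "))
  structure(list(params = data.frame(annotation = ann[ok], mu = mu[ok],
                                     sigma = sigma[ok], row.names = NULL,
                                     stringsAsFactors = FALSE),
                 dropped = ann[!ok]),
            class = "transform_model")
}

#' Apply a fitted transform to an annotation table
#'
#' `z = (asinh(x) - mu) / sigma` per cell, columns ordered as in the model.
#' Masked cells are imputed with 0 — the standardized training mean, neutral
#' under L1 distance from the training centroid — and flagged in `$imputed`.
#'
#' @param model A [fit_transform_model()] object.
#' @param table An [annotation_table()] whose columns include the model's
#'   annotations.
#' @return An [annotation_table()] of standardized values (no masked cells)
#'   with an `$imputed` logical matrix.
#' @export
apply_transform <- function(model, table) {
  stopifnot(inherits(model, "transform_model"), inherits(table, "annotation_table"))
  ann <- model$params$annotation
  missing <- setdiff(ann, colnames(table$values))
  if (length(missing))
    stop("table lacks model annotation(s): ", paste(missing, collapse = ", "))
  x <- table$values[, ann, drop = FALSE]
  z <- sweep(sweep(asinh(x), 2, model$params$mu), 2, model$params$sigma, "/")
  imputed <- is.na(z)
  z[imputed] <- 0
  out <- annotation_table(z)
  out$imputed <- imputed
  out
}

#' Serialize / load a transform model as CSV
#'
#' @param model A [fit_transform_model()] object.
#' @param path CSV path (`annotation`, `mu`, `sigma`).
#' @export
write_transform_model <- function(model, path) {
  data.table::fwrite(model$params, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_transform_model
#' @export
read_transform_model <- function(path) {
  params <- as.data.frame(data.table::fread(path, header = TRUE))
  stopifnot(identical(names(params), c("annotation", "mu", "sigma")))
  structure(list(params = params, dropped = character()),
            class = "transform_model")
}
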