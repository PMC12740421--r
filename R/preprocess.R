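#' Discrete histogram equalization
#'
#' Flattens an image's gray-level distribution with the classical rounded
#' cumulative-histogram mapping. Pixels are quantized to `levels` gray levels
#' over `range`, the cumulative histogram is accumulated, and each level `p`
#' is remapped to
#' `q = round((levels - 1) * cumsum(H)(p) / (M * N))`,
#' the discrete approximation of the continuous brightness transform that
#' would make the output histogram exactly uniform. The mapping is monotone
#' non-decreasing and idempotent: a second equalization leaves the histogram
#' unchanged.
#'
#' @param image Numeric matrix; values are clamped to `range` before
#'   quantization.
#' @param levels Number of gray levels (>= 2); 256 matches 8-bit practice.
#' @param range Length-2 numeric giving the gray scale `[p0, pk]` the image
#'   lives on; output is returned on the same scale.
#' @return Equalized numeric matrix, same dimensions, values in `range`.
#' @examples
#' img <- matrix(runif(64)^3, 8, 8)   # dark-skewed
#' eq <- histogram_equalize(img, levels = 16)
#' @export
histogram_equalize <- function(image, levels = 256L, range = c(0, 1)) {
  if (!is.matrix(image) || length(image) == 0L)
    stop("`image` must be a non-empty numeric matrix", call. = FALSE)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) stop("`levels` must be >= 2", call. = FALSE)
  r0 <- range[1]; r1 <- range[2]
  if (!(r1 > r0)) stop("`range` must be increasing", call. = FALSE)

  p <- round((levels - 1) * (pmin(pmax(image, r0), r1) - r0) / (r1 - r0))
  counts <- tabulate(p + 1L, nbins = levels)
  cum <- cumsum(counts)
  mapping <- round((levels - 1) * cum / length(image))  # q = T(p), levels 0..k
  q <- matrix(mapping[p + 1L], nrow(image), ncol(image))
  q / (levels - 1) * (r1 - r0) + r0
}

#' Standardize an image by training-set moments
#'
#' Elementwise `(image - mu) / sigma` where `mu` and `sigma` are the scalar
#' mean and standard deviation of all pixels across the training-set images
#' (see [image_moments()]).
#'
#' @param image Numeric matrix.
#' @param mu,sigma Scalar training-set mean and sd; `sigma > 0`.
#' @return Real-valued matrix of the same dimensions.
#' @export
standardize_image <- function(image, mu, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  (image - mu) / sigma
}

#' @describeIn standardize_image Pooled scalar pixel mean and sd over a list
#'   of images (the training split).
#' @param images List of numeric matrices.
#' @export
image_moments <- function(images) {
  v <- unlist(lapply(images, as.numeric), use.names = FALSE)
  list(mu = mean(v), sigma = stats::sd(v))
}

#' Fit a tabular encoding schema on the training split
#'
#' Records, per continuous variable, the training mean and sd used for
#' Z-scoring and, per categorical variable, its frozen level list (sorted
#' lexicographically). Logical columns are treated as categorical with levels
#' `FALSE`/`TRUE`. The schema is fitted once on the training split and then
#' applied unchanged to validation/test records.
#'
#' @param data Data frame of training records.
#' @param continuous,categorical Character vectors of column names.
#' @return An object of class `tabular_schema`.
#' @seealso [encode_tabular()], [write_schema()]
#' @export
tabular_schema <- function(data,
                           continuous = c("age", "smoking_years", "fev1_fvc"),
                           categorical = c("sex", "smoker", "gene_variant")) {
  miss <- setdiff(c(continuous, categorical), names(data))
  if (length(miss))
    stop("columns absent from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cont <- lapply(continuous, function(nm) {
    x <- data[[nm]]
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0)
      stop("continuous variable `", nm, "` has sd <= 0 on the training split",
           call. = FALSE)
    list(mean = mean(x), sd = s)
  })
  names(cont) <- continuous
  cat_lv <- lapply(categorical, function(nm) {
    lv <- sort(unique(as.character(data[[nm]])))
    if (length(lv) == 0L) stop("categorical `", nm, "` has no levels", call. = FALSE)
    lv
  })
  names(cat_lv) <- categorical
  schema <- list(continuous = cont, categorical = cat_lv)
  class(schema) <- "tabular_schema"
  schema
}

#' Encode records against a fitted schema
#'
#' Continuous fields are Z-scored with the schema's training mean and sd,
#' `x' = (x - mu) / sigma`; categorical fields become one-hot blocks in the
#' schema's frozen level order. An unseen categorical level is an error, never
#' a silent extra column. Output column order is: all continuous fields in
#' schema order, then one-hot blocks.
#'
#' @param data Data frame of records conforming to the schema.
#' @param schema A [tabular_schema()].
#' @return Numeric matrix, one row per record, with named columns.
#' @export
encode_tabular <- function(data, schema) {
  stopifnot(inherits(schema, "tabular_schema"))
  n <- nrow(data)
  blocks <- list()
  for (nm in names(schema$continuous)) {
    p <- schema$continuous[[nm]]
    blocks[[nm]] <- matrix((data[[nm]] - p$mean) / p$sd, ncol = 1,
                           dimnames = list(NULL, nm))
  }
  for (nm in names(schema$categorical)) {
    lv <- schema$categorical[[nm]]
    x <- as.character(data[[nm]])
    bad <- setdiff(unique(x), lv)
    if (length(bad))
      stop("unseen level(s) for `", nm, "`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    oh <- matrix(0, n, length(lv),
                 dimnames = list(NULL, paste(nm, lv, sep = ".")))
    oh[cbind(seq_len(n), match(x, lv))] <- 1
    blocks[[nm]] <- oh
  }
  do.call(cbind, blocks)
}

#' Persist / restore a tabular schema as JSON
#'
#' @param schema A [tabular_schema()].
#' @param path JSON file path.
#' @return `write_schema()` returns `path` invisibly; `read_schema()` the
#'   schema object.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  schema <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema$categorical <- lapply(schema$categorical, as.character)
  class(schema) <- "tabular_schema"
  schema
}
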