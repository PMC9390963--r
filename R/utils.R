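# Internal helpers shared across modules.

# Row-wise z-score with the n-1 denominator; constant rows become all-zero.
# Returns list(values, constant) where constant flags the degenerate rows.
row_zscore <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  constant <- !is.finite(s) | s < .Machine$double.eps^0.5
  z <- (x - mu) / ifelse(constant, 1, s)
  z[constant, ] <- 0
  list(values = z, constant = constant)
}

# k-means++ seeding: returns a k x ncol(x) matrix of initial centres.
# Deterministic given the RNG state at call time.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  stopifnot(k >= 1, n >= k)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k == 1) return(centers)
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    centers[j, ] <- x[idx, ]
    d2j <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, d2j)
  }
  centers
}

# Validate an expression matrix: numeric, named dims, non-negative.
check_expression_matrix <- function(x, arg = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x samples)", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must have gene rownames and sample colnames", arg))
  }
  if (anyDuplicated(rownames(x))) {
    abort(sprintf("duplicate gene ids in `%s`: %s", arg,
                  paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(x))) {
    abort(sprintf("duplicate sample ids in `%s`", arg))
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be finite and non-negative", arg))
  }
  invisible(x)
}

expr_layer <- function(x) attr(x, "layer") %||% "counts"

set_expr_layer <- function(x, layer) {
  attr(x, "layer") <- layer
  x
}
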