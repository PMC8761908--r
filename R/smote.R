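# SMOTE (synthetic minority oversampling) implemented from scratch:
# each synthetic row interpolates between a minority sample and one of its K
# nearest minority neighbours (Euclidean distance), with a Uniform[0,1]
# interpolation factor. Applied only inside training folds by the
# cross-validation harness.

#' SMOTE parameters
#'
#' @param k_neighbors number of nearest minority neighbours considered per
#'   minority sample (default 5). When the minority class has fewer than
#'   `k_neighbors + 1` members, `minority - 1` neighbours are used instead.
#' @param seed integer seed making the oversampling deterministic.
#' @return An object of class `smote_params`.
#' @export
smote_params <- function(k_neighbors = 5, seed = 1L) {
  if (k_neighbors < 1) stop("`k_neighbors` must be at least 1")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "smote_params")
}

#' Balance a two-class sample by SMOTE oversampling
#'
#' The minority class is oversampled until the class counts are equal. Each
#' synthetic row is `x_i + gap * (x_nn - x_i)` with `gap ~ Uniform[0,1]` and
#' `x_nn` one of the `k_neighbors` nearest minority neighbours of minority
#' sample `x_i` — every coordinate of a synthetic row therefore lies in the
#' closed interval spanned by its two parents. When the deficit is not a
#' multiple of the minority size, extra synthetics are assigned round-robin
#' over the minority rows in order. Original rows are preserved as a prefix
#' of the output; neighbour search never crosses class boundaries.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y class labels (factor or vector) with exactly two observed classes.
#' @param params a [smote_params()].
#' @return A list with the augmented `X`, `y`, the number of synthetic rows
#'   `n_synthetic`, and the neighbour count actually used `k_used`.
#' @export
smote_fit_resample <- function(X, y, params = smote_params()) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) != 2)
    stop("SMOTE requires exactly two classes present; got ", length(classes))
  counts <- table(y)
  minority <- names(counts)[which.min(counts)]
  deficit <- as.integer(max(counts) - min(counts))
  if (deficit == 0)
    return(list(X = X, y = y, n_synthetic = 0L, k_used = params$k_neighbors))
  min_idx <- which(y == minority)
  n_min <- length(min_idx)
  if (n_min < 2)
    stop("SMOTE needs at least 2 minority samples to interpolate")
  k <- min(params$k_neighbors, n_min - 1L)
  Xm <- X[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nnarray <- apply(d, 1, function(r) order(r)[seq_len(k)])
  nnarray <- matrix(nnarray, nrow = k)  # k x n_min, ties broken by row order

  donors <- rep(seq_len(n_min), length.out = deficit)  # round-robin
  synth <- with_seed(params$seed, {
    nn_pick <- nnarray[cbind(sample.int(k, deficit, replace = TRUE), donors)]
    gap <- runif(deficit)
    Xm[donors, , drop = FALSE] +
      gap * (Xm[nn_pick, , drop = FALSE] - Xm[donors, , drop = FALSE])
  })
  list(X = rbind(X, synth),
       y = c(y, rep(minority, deficit)),
       n_synthetic = deficit,
       k_used = k)
}
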