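# Class-imbalance handling: inverse-frequency class weights and a
# from-scratch SMOTE resampler.

#' Inverse-frequency class weights
#'
#' Weight of class *c* is `n / (2 * n_c)`, so the weighted mass of the two
#' classes is equal: `w0 * n0 = w1 * n1 = n / 2`. The data themselves are
#' untouched; the weights are metadata consumed by the classifiers.
#'
#' @param labels 0/1 labels; both classes must be present.
#' @return Named numeric vector `c("0" = w0, "1" = w1)`.
#' @examples
#' class_weights(c(rep(1, 700), rep(0, 300)))
#' @export
class_weights <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n0 <- sum(labels == 0)
  n1 <- sum(labels == 1)
  if (n0 == 0 || n1 == 0) stop("class weights need both classes present")
  n <- n0 + n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

# The rarer of the two classes (ties go to the positive class).
minority_class <- function(y) if (sum(y == 1) <= sum(y == 0)) 1 else 0

#' SMOTE minority oversampling
#'
#' Synthetic Minority Over-sampling Technique: each synthetic sample is
#' drawn on the segment between a minority sample `x_i` and one of its `k`
#' Euclidean nearest minority neighbors `x_nn`:
#' `x_new = x_i + u * (x_nn - x_i)`, `u ~ Uniform(0, 1)`.
#' Original rows (both classes) are preserved verbatim; only synthetic
#' minority rows are appended, until the minority/majority ratio reaches
#' `target_ratio` (count rounded to the nearest integer). Binary inputs are
#' interpolated in real space and left unrounded by default.
#'
#' @param X numeric matrix (compounds x features).
#' @param y 0/1 labels aligned to rows of `X`; the minority class is the
#'   rarer one. Minority size must be at least 2.
#' @param k number of nearest neighbors (default 5); silently clamped to
#'   minority size - 1.
#' @param target_ratio desired minority/majority ratio after resampling,
#'   in (0, 1] (default 1, full balance). If the ratio is already met the
#'   input is returned unchanged.
#' @param round_bits round synthetic values to {0,1} (for binary
#'   fingerprints; default `FALSE`).
#' @param seed optional integer seed for reproducible draws.
#' @return A list: `X` (original rows then synthetic rows), `y`, and
#'   `n_synthetic`.
#' @export
smote_resample <- function(X, y, k = 5, target_ratio = 1,
                           round_bits = FALSE, seed = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y differ in length")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (!(target_ratio > 0 && target_ratio <= 1))
    stop("target_ratio must be in (0, 1]")
  if (k < 1) stop("k must be at least 1")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  minority <- if (n1 <= n0) 1 else 0
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  if (n_min < 2) stop("SMOTE needs at least 2 minority samples")

  n_target <- round(target_ratio * n_maj)
  n_synth <- n_target - n_min
  if (n_synth <= 0)
    return(list(X = X, y = y, n_synthetic = 0L))

  k <- min(k, n_min - 1)
  min_idx <- which(y == minority)
  Xm <- X[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  # k nearest minority neighbors of each minority sample (deterministic
  # tie-break by index order)
  ord <- apply(d, 1, function(row) order(row)[seq_len(k)])
  nn <- if (k == 1) matrix(ord, ncol = 1) else t(ord)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  base <- sample.int(n_min, n_synth, replace = TRUE)
  pick <- sample.int(k, n_synth, replace = TRUE)
  u <- runif(n_synth)
  synth <- Xm[base, , drop = FALSE] +
    u * (Xm[nn[cbind(base, pick)], , drop = FALSE] - Xm[base, , drop = FALSE])
  if (round_bits) synth <- round(synth)
  rownames(synth) <- NULL
  list(X = rbind(X, synth),
       y = c(y, rep(minority, n_synth)),
       n_synthetic = as.integer(n_synth))
}
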