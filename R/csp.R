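#' Fit a Common Spatial Patterns filter
#'
#' Estimates the spatial weight vector `w` maximizing the variance ratio
#' between stimulation and baseline epochs,
#' `(w' C_stim w) / (w' C_base w)`, where each class covariance is the
#' average of per-epoch channel covariance matrices normalized by their
#' trace (removing inter-trial amplitude nuisance). The solution is the
#' top eigenvector of the generalized symmetric eigenproblem
#' `C_stim w = lambda C_base w`, solved by whitening `C_base`. A small
#' ridge (`ridge * mean(diag) * I`) regularizes both covariances, which
#' narrow-band filtering can leave nearly rank-deficient.
#'
#' Weights are scaled to unit Euclidean norm and the sign fixed so the
#' first nonzero weight is positive (the projection's power is
#' sign-invariant; the convention makes serialized filters reproducible).
#'
#' @param stim stimulation-class [epoch_set()], narrow-band filtered.
#' @param base baseline-class [epoch_set()] with matching channels.
#' @param ridge relative ridge regularization strength.
#' @param normalize trace-normalize per-epoch covariances (default). With
#'   `FALSE` the raw average covariance is used and the eigenvalue is the
#'   raw stimulation/baseline variance ratio along `w`.
#' @return An object of class `csp_filter`: `weights`, `eigenvalue`
#'   (achieved variance ratio), `frequency`, `channel_labels`.
#' @export
fit_csp <- function(stim, base, ridge = 1e-9, normalize = TRUE) {
  stopifnot(inherits(stim, "ssvep_epochs"), inherits(base, "ssvep_epochs"))
  if (!identical(stim$channel_labels, base$channel_labels))
    stop("stimulation and baseline epochs have mismatched channels")
  if (stim$sampling_rate != base$sampling_rate)
    stop("stimulation and baseline epochs have mismatched sampling rates")
  if (n_trials(stim) < 2 || n_trials(base) < 2)
    stop("need at least 2 epochs per class")

  c_stim <- class_covariance(stim$epochs, normalize)
  c_base <- class_covariance(base$epochs, normalize)
  n_ch <- nrow(c_stim)
  ridge_base <- ridge * mean(diag(c_base))
  c_stim <- c_stim + ridge * mean(diag(c_stim)) * diag(n_ch)
  c_base <- c_base + ridge_base * diag(n_ch)

  eb <- eigen(c_base, symmetric = TRUE)
  if (min(eb$values) <= 3 * ridge_base)
    stop("baseline covariance is rank-deficient after regularization")
  whitener <- eb$vectors %*% diag(1 / sqrt(eb$values), n_ch) %*% t(eb$vectors)
  es <- eigen(whitener %*% c_stim %*% whitener, symmetric = TRUE)
  w <- as.numeric(whitener %*% es$vectors[, 1])
  w <- w / sqrt(sum(w^2))
  first <- which(abs(w) > 1e-12)[1]
  if (!is.na(first) && w[first] < 0) w <- -w
  lambda <- as.numeric((t(w) %*% c_stim %*% w) / (t(w) %*% c_base %*% w))

  structure(list(weights = stats::setNames(w, stim$channel_labels),
                 eigenvalue = lambda, frequency = stim$frequency,
                 channel_labels = stim$channel_labels),
            class = "csp_filter")
}

# Average of (optionally trace-normalized) per-epoch channel covariances.
class_covariance <- function(epochs, normalize = TRUE) {
  d <- dim(epochs)
  acc <- matrix(0, d[2], d[2])
  for (tr in seq_len(d[1])) {
    x <- matrix(epochs[tr, , ], d[2], d[3])
    x <- x - rowMeans(x)
    cc <- tcrossprod(x) / (d[3] - 1)
    if (normalize) cc <- cc / sum(diag(cc))
    acc <- acc + cc
  }
  acc / d[1]
}

#' @export
print.csp_filter <- function(x, ...) {
  cat(sprintf("<csp_filter> %g Hz, variance ratio %.3f\n",
              x$frequency, x$eigenvalue))
  print(round(x$weights, 3))
  invisible(x)
}

#' Project epochs through a CSP filter
#'
#' Applies the spatial weight vector to every epoch, producing
#' one-dimensional signals: output trial `i` is `w' X_i` for the
#' channels x samples matrix `X_i`.
#'
#' @param epochs an [epoch_set()] whose channel order matches the filter.
#' @param filter a [fit_csp()] object.
#' @return An `ssvep_epochs` with a single channel `"CSP"`.
#' @export
apply_csp <- function(epochs, filter) {
  stopifnot(inherits(epochs, "ssvep_epochs"), inherits(filter, "csp_filter"))
  if (!identical(epochs$channel_labels, filter$channel_labels))
    stop("epoch channels do not match the CSP filter's training channels")
  d <- dim(epochs$epochs)
  out <- array(0, c(d[1], 1, d[3]))
  for (tr in seq_len(d[1]))
    out[tr, 1, ] <- as.numeric(filter$weights %*%
                                 matrix(epochs$epochs[tr, , ], d[2], d[3]))
  epoch_set(out, epochs$sampling_rate, epochs$frequency, epochs$condition,
            epochs$klass, "CSP", filtered = epochs$filtered)
}

# JSON-serializable record of a fitted filter.
csp_provenance <- function(filter) {
  list(frequency = filter$frequency,
       eigenvalue = filter$eigenvalue,
       channel_labels = filter$channel_labels,
       weights = as.numeric(filter$weights))
}
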