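#' Direct discrete Fourier transform (reference implementation)
#'
#' Evaluates the DFT sum
#' \deqn{HR_k = \sum_{n=0}^{N-1} hr_n e^{-i 2\pi k n / N}}
#' term by term in O(N^2). This is the oracle the fast path
#' (`stats::fft`) is tested against; it is not used in the pipeline
#' itself.
#'
#' @param x Finite real (or complex) sequence.
#' @return Complex vector of the `N` frequency components.
#' @export
dft_oracle <- function(x) {
  n_len <- length(x)
  if (n_len == 0) stop("empty input", call. = FALSE)
  stopifnot(all(is.finite(Re(x))))
  n <- 0:(n_len - 1)
  k <- 0:(n_len - 1)
  kernel <- exp(-1i * 2 * pi * outer(k, n) / n_len)
  as.vector(kernel %*% as.complex(x))
}

#' Inverse discrete Fourier transform
#'
#' Evaluates \deqn{hr_n = \frac{1}{N} \sum_{k=0}^{N-1} HR_k e^{i 2\pi k n / N}}
#' directly, recovering the time-domain sequence from a spectrum of a real
#' signal.
#'
#' @param spec Complex spectrum (from [dft_oracle()] or `stats::fft`).
#' @return Real vector of length `N`.
#' @export
idft <- function(spec) {
  n_len <- length(spec)
  if (n_len == 0) return(numeric(0))
  n <- 0:(n_len - 1)
  k <- 0:(n_len - 1)
  kernel <- exp(1i * 2 * pi * outer(n, k) / n_len)
  out <- as.vector(kernel %*% as.complex(spec)) / n_len
  Re(out)
}

#' Fourier half-spectrum magnitude features of one day vector
#'
#' For a real-valued day vector the spectrum is conjugate-symmetric, so
#' only the first half carries information; the features are the magnitudes
#' `|HR_k|` for `k = 0 .. N/2 - 1` (the DC bin is kept, the Nyquist bin is
#' dropped). A 480-point day yields 240 features.
#'
#' @param x Numeric day vector of even length (480 in the default
#'   pipeline).
#' @return Numeric vector of `length(x)/2` magnitudes.
#' @export
fft_features <- function(x) {
  n_len <- length(x)
  if (n_len < 2 || n_len %% 2 != 0) {
    stop("day vector length must be even, got ", n_len, call. = FALSE)
  }
  Mod(stats::fft(x))[seq_len(n_len / 2)]
}

#' Continuous Morlet wavelet transform on an integer scale grid
#'
#' Convolves the day vector with scaled complex Morlet kernels
#' \deqn{\psi(t) = \pi^{-1/4} e^{i\omega_0 t} e^{-t^2/2}}
#' at integer scales `j = 1 .. J` and returns the coefficient modulus. The
#' kernel at scale `j` is `psi(m/j)/sqrt(j)` truncated at `|m| <= 5j`
#' (beyond which the Gaussian envelope is negligible); the convolution
#' zero-pads the signal at the boundaries. The day's mean is subtracted
#' before convolving: the DC level carries no time-frequency information,
#' and removing it keeps coefficients of a constant signal exactly zero
#' even at the smallest scales, where the integer-sampled Morlet kernel is
#' not perfectly zero-mean.
#'
#' @param x Numeric day vector.
#' @param scales Number of consecutive integer scales `J` (>= 1), or an
#'   explicit integer scale vector.
#' @param omega0 Morlet central frequency (dimensionless), default 5.
#' @param value One of `"modulus"` (default), `"real"` or `"power"` --
#'   which real-valued summary of the complex coefficients to return.
#' @return A `wavelet_coefficients` object: matrix of dim `J x length(x)`
#'   with attributes `scales` and `omega0`.
#' @export
morlet_cwt <- function(x, scales = 10, omega0 = 5, value = c("modulus", "real", "power")) {
  value <- match.arg(value)
  if (length(scales) == 1) {
    if (scales < 1) stop("scale count J must be >= 1", call. = FALSE)
    scales <- seq_len(scales)
  }
  n_len <- length(x)
  x <- x - mean(x)
  W <- matrix(0, nrow = length(scales), ncol = n_len)
  for (si in seq_along(scales)) {
    j <- scales[si]
    M <- ceiling(5 * j)
    m <- (-M):M
    psi <- pi^(-0.25) * exp(1i * omega0 * m / j - (m / j)^2 / 2) / sqrt(j)
    # W[k] = sum_n x[n] psi((n-k)/j) via zero-padded linear convolution
    L <- stats::nextn(n_len + length(psi) - 1, 2)
    conv <- stats::fft(stats::fft(c(x, rep(0, L - n_len))) *
                         stats::fft(c(rev(psi), rep(0, L - length(psi)))),
                       inverse = TRUE) / L
    coef <- conv[M + seq_len(n_len)]
    W[si, ] <- switch(value,
                      modulus = Mod(coef),
                      real = Re(coef),
                      power = Mod(coef)^2)
  }
  if (!all(is.finite(W))) stop("non-finite wavelet coefficients", call. = FALSE)
  structure(W, scales = scales, omega0 = omega0, value = value,
            class = c("wavelet_coefficients", "matrix", "array"))
}

#' Per-day PCA compression of wavelet coefficients
#'
#' Treats the `J` scale rows of one day's coefficient matrix as
#' observations and the positions as variables, fits a PCA on that single
#' day (so feature extraction never mixes information across days), and
#' projects each scale row onto the leading `n_components` components.
#' Flattening the resulting `J x n_components` score matrix gives the
#' `5*J` wavelet features.
#'
#' @param coeffs A `wavelet_coefficients` matrix (`J x N`).
#' @param n_components Number of components retained (default 5).
#' @return List with `scores` (`J x n_components`), `explained_variance`
#'   (fraction captured by the retained components) and `features` (the
#'   flattened score matrix, length `n_components * J`).
#' @export
perday_pca <- function(coeffs, n_components = 5) {
  J <- nrow(coeffs)
  if (J < n_components) {
    stop("need at least ", n_components, " scale rows, got ", J, call. = FALSE)
  }
  pr <- stats::prcomp(unclass(coeffs), center = TRUE, scale. = FALSE)
  scores <- pr$x[, seq_len(n_components), drop = FALSE]
  evf <- sum(pr$sdev[seq_len(n_components)]^2) / sum(pr$sdev^2)
  list(scores = scores, explained_variance = evf,
       features = as.numeric(t(scores)))
}

modality_width <- function(modality, n = 480) {
  switch(modality,
         org = n,
         fft = n / 2,
         wave50 = 50, wave150 = 150, wave250 = 250,
         stop("unknown modality: ", modality, call. = FALSE))
}

modality_scales <- c(wave50 = 10, wave150 = 30, wave250 = 50)

#' Build a feature set for one modality
#'
#' Transforms a regularized day table into the days-by-features matrix of
#' one of the five modalities: `org` (the raw day vector, width 480),
#' `fft` (half-spectrum magnitudes, width 240), or `wave50`/`wave150`/
#' `wave250` (Morlet modulus at J = 10/30/50 scales compressed by per-day
#' PCA to 5 components, widths 50/150/250).
#'
#' @param day_tbl Output of [regularize_days()] (day vectors plus labels).
#' @param modality One of `"org"`, `"fft"`, `"wave50"`, `"wave150"`,
#'   `"wave250"`.
#' @param omega0 Morlet central frequency for the wavelet modalities.
#' @return A `feature_set`: list with `X` (matrix days x width), `labels`
#'   (integer 0/1), `modality`, `participant_id`, `date`, and for wavelet
#'   modalities `explained_variance` (per-day fractions).
#' @export
build_features <- function(day_tbl, modality = c("org", "fft", "wave50", "wave150", "wave250"),
                           omega0 = 5) {
  modality <- match.arg(modality)
  if (nrow(day_tbl) == 0) stop("no days to featurize", call. = FALSE)
  X0 <- day_matrix(day_tbl)
  n <- ncol(X0)
  evf <- NULL
  if (modality == "org") {
    X <- X0
  } else if (modality == "fft") {
    X <- t(apply(X0, 1, fft_features))
  } else {
    J <- modality_scales[[modality]]
    rows <- vector("list", nrow(X0))
    evf <- numeric(nrow(X0))
    for (i in seq_len(nrow(X0))) {
      p <- perday_pca(morlet_cwt(X0[i, ], scales = J, omega0 = omega0))
      rows[[i]] <- p$features
      evf[i] <- p$explained_variance
    }
    X <- do.call(rbind, rows)
    rownames(X) <- rownames(X0)
  }
  width <- modality_width(modality, n)
  if (ncol(X) != width) {
    stop("modality ", modality, " produced width ", ncol(X), ", expected ", width,
         call. = FALSE)
  }
  structure(
    list(X = X, labels = as.integer(day_tbl$stressful), modality = modality,
         participant_id = day_tbl$participant_id, date = day_tbl$date,
         explained_variance = evf),
    class = "feature_set"
  )
}

#' @exportS3Method base::print
print.feature_set <- function(x, ...) {
  cat("<feature_set> modality=", x$modality, ", ", nrow(x$X), " days x ",
      ncol(x$X), " features, ", sum(x$labels == 1), " stressful\n", sep = "")
  invisible(x)
}
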