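#' AR(1) calcium-transient deconvolution
#'
#' Recovers a nonnegative spike train from a fluorescence trace under the
#' AR(1) transient model `c(t) = gamma * c(t-1) + s(t)`, by solving
#' `minimize 0.5 * ||c - y||^2 + lambda * sum(s)` subject to `s >= 0`,
#' with a pool-adjacent-violators pass over the decay constraints (an
#' online active-set scheme for the AR(1) case). With `lambda = 0` and a
#' noiseless AR(1) input the recursion is inverted exactly.
#'
#' @param trace Numeric fluorescence trace (baseline-subtracted).
#' @param gamma AR(1) coefficient in (0, 1).
#' @param lambda Sparsity weight (>= 0) on the total spike mass.
#' @return List with `denoised` (the fitted calcium trace, an exact AR(1)
#'   convolution of `spikes`) and `spikes` (nonnegative, same length).
#' @export
deconvolve_ar1 <- function(trace, gamma, lambda = 0) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 || gamma >= 1)
    stop("gamma must be a scalar in (0, 1)")
  if (lambda < 0) stop("lambda must be >= 0")
  n <- length(trace)
  if (n == 0) stop("empty trace")
  # The sparsity term sum(s) telescopes to (1-gamma) * sum(c[1:(n-1)]) + c[n],
  # so it acts as a per-frame subtraction from the target trace.
  ty <- trace - lambda * (1 - gamma)
  ty[n] <- trace[n] - lambda
  v <- ty; w <- rep(1, n); t0 <- seq_len(n); len <- rep(1L, n)
  np <- n
  merge_at <- function(i) {
    g <- gamma^len[i]
    v[i] <<- (w[i] * v[i] + g * w[i + 1] * v[i + 1]) / (w[i] + g^2 * w[i + 1])
    w[i] <<- w[i] + g^2 * w[i + 1]
    len[i] <<- len[i] + len[i + 1]
    if (np > i + 1) {
      sel <- (i + 2):np
      v[sel - 1L] <<- v[sel]; w[sel - 1L] <<- w[sel]
      t0[sel - 1L] <<- t0[sel]; len[sel - 1L] <<- len[sel]
    }
    np <<- np - 1L
  }
  i <- 1L
  while (i < np) {
    if (v[i + 1] >= gamma^len[i] * v[i] - 1e-15) {
      i <- i + 1L
    } else {
      merge_at(i)
      while (i > 1L && v[i] < gamma^len[i - 1] * v[i - 1] - 1e-15) {
        i <- i - 1L
        merge_at(i)
      }
    }
  }
  denoised <- numeric(n)
  for (k in seq_len(np)) {
    vk <- max(v[k], 0)
    idx <- t0[k]:(t0[k] + len[k] - 1L)
    denoised[idx] <- vk * gamma^(seq_along(idx) - 1)
  }
  spikes <- denoised - gamma * c(0, denoised[-n])
  spikes[spikes < 1e-12] <- 0
  list(denoised = denoised, spikes = spikes)
}

# AR(1) decay coefficient from the trace autocovariance. The trace is first
# detrended with a running median (window much longer than a transient) so
# slow background drift does not inflate long-lag autocovariance; under
# white observation noise the autocovariance at lags >= 1 then decays as
# gamma^lag, and the decay rate is fit by log-linear regression over lags
# 1-5.
estimate_gamma <- function(trace, clip = c(0.6, 0.98), median_window = 201L,
                           max_lag = 5L) {
  n <- length(trace)
  if (n < 10L * max_lag) return(mean(clip))
  mw <- min(median_window, if (n %% 2L == 1L) n else n - 1L)
  x <- trace - stats::runmed(trace, mw)
  x <- x - mean(x)
  ac <- vapply(seq_len(max_lag), function(l)
    sum(x[seq_len(n - l)] * x[-seq_len(l)]) / n, numeric(1))
  pos <- ac > 0
  if (sum(pos) < 2L) return(mean(clip))
  lags <- seq_len(max_lag)[pos]
  g <- exp(stats::coef(stats::lm(log(ac[pos]) ~ lags))[[2]])
  if (!is.finite(g)) g <- mean(clip)
  min(max(g, clip[1]), clip[2])
}
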