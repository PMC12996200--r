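#' Takens delay embedding
#'
#' Point `i` is `(x[i], x[i+tau], ..., x[i+(dim-1)*tau])` (0-based indexing
#' of the series); the number of points is `length(x) - (dim-1)*tau`.
#'
#' @param x numeric series.
#' @param dim embedding dimension (>= 1).
#' @param tau delay in samples (>= 1).
#' @return A numeric matrix with `dim` columns.
#' @export
delay_embedding <- function(x, dim, tau) {
  x <- as.numeric(x)
  if (dim < 1 || tau < 1) stop("dim and tau must be >= 1")
  N <- length(x) - (dim - 1) * tau
  if (N < 1) stop("series too short for this (dim, tau)")
  out <- matrix(0, nrow = N, ncol = dim)
  for (k in seq_len(dim)) out[, k] <- x[seq_len(N) + (k - 1) * tau]
  out
}

#' Select an embedding delay by average mutual information
#'
#' Histogram-based average mutual information (AMI) is computed for lags
#' `1..max_lag`; the delay is the first local minimum of the AMI curve. If
#' the AMI at some lag is already indistinguishable from the independence
#' floor (estimated from shuffled surrogates with a fixed internal seed),
#' that lag is taken instead — for serially independent noise this yields
#' `tau = 1`. If neither rule fires, the first lag where the
#' autocorrelation drops below `1/e` is used.
#'
#' @param x numeric series.
#' @param max_lag largest lag considered (must be `< length(x)/2`).
#' @param bins number of equal-width histogram bins.
#' @return Integer delay in samples.
#' @export
select_delay <- function(x, max_lag = NULL, bins = 16) {
  x <- as.numeric(x)
  n <- length(x)
  if (sd(x) == 0) stop("degenerate input: constant series")
  max_lag <- max_lag %||% max(10L, min(floor(n / 4), 200L))
  if (max_lag >= n / 2) stop("max_lag must be < length(x)/2")
  ami <- vapply(seq_len(max_lag), function(k) ami_lag(x, k, bins), numeric(1))
  floor_val <- withr::with_seed(104729, {
    mean(vapply(1:3, function(i) ami_lag(sample(x), 1L, bins), numeric(1)))
  })
  local_min <- NA_integer_
  for (k in seq_len(max_lag - 1)) {
    if (ami[k] < ami[k + 1] && (k == 1 || ami[k] < ami[k - 1])) {
      local_min <- k
      break
    }
  }
  floor_hit <- which(ami <= 1.5 * floor_val)[1]
  cand <- c(local_min, floor_hit)
  cand <- cand[!is.na(cand)]
  if (length(cand)) return(as.integer(min(cand)))
  ac <- acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  cross <- which(ac < exp(-1))[1]
  if (!is.na(cross)) return(as.integer(cross))
  warning("no AMI minimum or 1/e autocorrelation crossing; returning max_lag")
  as.integer(max_lag)
}

ami_lag <- function(x, lag, bins) {
  n <- length(x)
  a <- x[1:(n - lag)]
  b <- x[(1 + lag):n]
  br <- seq(min(x), max(x), length.out = bins + 1)
  ia <- pmin(pmax(findInterval(a, br, rightmost.closed = TRUE), 1L), bins)
  ib <- pmin(pmax(findInterval(b, br, rightmost.closed = TRUE), 1L), bins)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  pj <- joint / sum(joint)
  pa <- tabulate(ia, bins) / length(ia)
  pb <- tabulate(ib, bins) / length(ib)
  pij <- matrix(pj, bins, bins)
  denom <- outer(pa, pb)
  nz <- pij > 0 & denom > 0
  sum(pij[nz] * log(pij[nz] / denom[nz]))
}

#' Select an embedding dimension by false nearest neighbours
#'
#' Kennel's criterion with a Theiler exclusion window: for each candidate
#' dimension `m`, the fraction of nearest neighbours whose separation grows
#' disproportionately when the `(m+1)`-th coordinate is added. Returns the
#' smallest `m` whose false-neighbour fraction falls below `fnn_tol`;
#' returns `max_dim` with a warning if the tolerance is never reached
#' (typical for stochastic signals).
#'
#' @param x numeric series.
#' @param tau embedding delay (see [select_delay()]).
#' @param max_dim largest dimension tried (>= 2).
#' @param fnn_tol acceptable false-neighbour fraction.
#' @param rtol,atol Kennel thresholds (distance-ratio and attractor-size).
#' @param theiler temporal exclusion window in samples.
#' @param max_points cap on reference points (strided) for the search.
#' @return Integer embedding dimension.
#' @export
select_embedding_dim <- function(x, tau, max_dim = 8, fnn_tol = 0.02,
                                 rtol = 10, atol = 2, theiler = tau,
                                 max_points = 2000) {
  x <- as.numeric(x)
  if (max_dim < 2) stop("max_dim must be >= 2")
  if (length(x) <= max_dim * tau + 10) stop("series too short for max_dim")
  frac <- cpp_fnn_fractions(x, as.integer(tau), as.integer(max_dim),
                            as.integer(theiler), rtol, atol,
                            as.integer(max_points))
  ok <- which(!is.na(frac) & frac < fnn_tol)
  if (length(ok)) return(as.integer(ok[1]))
  warning("false-neighbour fraction never fell below fnn_tol; returning max_dim")
  as.integer(max_dim)
}
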