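#' Random-matrix-theory threshold scan for a correlation matrix
#'
#' Scans a grid of candidate cut-offs. For each candidate t, off-diagonal
#' entries with |r| < t are zeroed, taxa left with no surviving
#' off-diagonal entry are dropped, and the eigenvalue spectrum of the
#' thresholded matrix is examined: eigenvalues are unfolded with a
#' smoothing-spline fit of the empirical cumulative spectral density, and
#' the nearest-neighbour spacing distribution (NNSD) of the unfolded
#' eigenvalues is tested by chi-square goodness of fit against the Poisson
#' (exponential, `exp(-s)`) law. Random-matrix theory predicts Poisson
#' spacings once the matrix has decomposed into independent modules, and
#' Gaussian-orthogonal-ensemble statistics while dense noise remains; the
#' chosen threshold is the smallest t whose Poisson fit p-value exceeds
#' `p_min` while at least `min_eigen` eigenvalues remain.
#'
#' @param R symmetric taxon x taxon correlation matrix (unit diagonal).
#' @param grid_start,grid_stop,grid_step candidate threshold grid,
#'   defaults 0.3 to 0.95 by 0.01.
#' @param min_eigen minimum number of eigenvalues for a candidate to be
#'   eligible, default 50.
#' @param p_min Poisson-fit p-value a candidate must exceed, default 0.05.
#' @param s_max spacings are truncated at this value for the chi-square
#'   fit, default 3.
#' @param unfold_df equivalent degrees of freedom of the unfolding
#'   spline, default 5. Unfolding must remove only the global trend of
#'   the spectral density: a stiff low-df smooth does that, whereas a
#'   flexible fit tracks individual eigenvalues and forces all spacings
#'   towards 1, wrecking the spacing statistics.
#' @return An object of class `rmt_scan`: data.frame `scan` with columns
#'   `threshold`, `n_taxa`, `n_offdiag`, `n_spacings`, `chisq`, `p_value`,
#'   plus `chosen` (numeric, NA when no candidate qualifies) and `found`
#'   (logical).
#' @export
rmt_threshold <- function(R, grid_start = 0.3, grid_stop = 0.95,
                          grid_step = 0.01, min_eigen = 50, p_min = 0.05,
                          s_max = 3, unfold_df = 5) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  if (nrow(R) < min_eigen)
    stop("too few taxa (", nrow(R), ") for an RMT scan with min_eigen = ",
         min_eigen)
  grid <- seq(grid_start, grid_stop, by = grid_step)
  absR <- abs(R)
  diag(absR) <- Inf                       # diagonal always kept
  scan <- data.frame(threshold = grid, n_taxa = NA_integer_,
                     n_offdiag = NA_integer_, n_spacings = NA_integer_,
                     chisq = NA_real_, p_value = NA_real_)
  for (k in seq_along(grid)) {
    t <- grid[k]
    keepmask <- absR >= t                 # diagonal is Inf, always TRUE
    taxa_keep <- rowSums(keepmask) > 1L   # at least one surviving partner
    scan$n_taxa[k] <- sum(taxa_keep)
    M <- R[taxa_keep, taxa_keep, drop = FALSE]
    M[abs(M) < t & row(M) != col(M)] <- 0
    scan$n_offdiag[k] <- sum(M[upper.tri(M)] != 0)
    if (sum(taxa_keep) < min_eigen) next
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    s <- tryCatch(unfold_eigenvalues(ev, df = unfold_df),
                  error = function(e) numeric())
    if (length(s) < 10L) next
    fit <- nnsd_poisson_fit(s, s_max = s_max)
    scan$n_spacings[k] <- fit$n_spacings
    scan$chisq[k] <- fit$chisq
    scan$p_value[k] <- fit$p_value
  }
  ok <- !is.na(scan$p_value) & scan$p_value > p_min &
    scan$n_taxa >= min_eigen
  chosen <- if (any(ok)) scan$threshold[which(ok)[1L]] else NA_real_
  structure(list(scan = scan, chosen = chosen, found = !is.na(chosen),
                 min_eigen = min_eigen, p_min = p_min),
            class = "rmt_scan")
}

#' @export
print.rmt_scan <- function(x, ...) {
  if (x$found)
    cat(sprintf("rmt_scan: chosen threshold %.2f (Poisson fit p = %.3f)\n",
                x$chosen,
                x$scan$p_value[match(x$chosen, x$scan$threshold)]))
  else
    cat("rmt_scan: no threshold found; fall back to a fixed r_min\n")
  invisible(x)
}

#' Unfold an eigenvalue spectrum
#'
#' Maps eigenvalues onto a scale where the mean nearest-neighbour spacing
#' is 1, by fitting a stiff cubic smoothing spline (default 5 equivalent
#' degrees of freedom) to the empirical cumulative spectral density and
#' evaluating it at each (distinct) eigenvalue. The low df is essential:
#' unfolding should capture the global spectral density only, and an
#' overfitted spline (e.g. the GCV choice on a step function) maps every
#' eigenvalue near its rank, collapsing all spacings to 1. Exactly
#' duplicated eigenvalues (within `tol`) are collapsed first --
#' degenerate multiplicities otherwise flood the NNSD with zero spacings.
#'
#' @param ev numeric eigenvalues (any order).
#' @param df equivalent degrees of freedom for [stats::smooth.spline()],
#'   default 5.
#' @param tol duplicate-collapse tolerance, default 1e-8.
#' @return numeric vector of nearest-neighbour spacings of the unfolded
#'   spectrum (non-negative, mean approximately 1).
#' @export
unfold_eigenvalues <- function(ev, df = 5, tol = 1e-8) {
  ev <- sort(ev)
  ev <- ev[c(TRUE, diff(ev) > tol)]
  n <- length(ev)
  if (n < 5L) return(numeric())
  cdf <- (seq_len(n) - 0.5) / n
  fit <- stats::smooth.spline(ev, cdf, df = min(df, n - 1L))
  unfolded <- n * stats::predict(fit, ev)$y
  s <- diff(sort(unfolded))
  pmax(s, 0)
}

#' Chi-square goodness of fit of spacings against the Poisson law
#'
#' Tests whether nearest-neighbour spacings follow the exponential density
#' `exp(-s)` expected for uncorrelated (Poissonian) eigenvalues. Spacings
#' above `s_max` are discarded and the expected bin probabilities are
#' renormalised over `[0, s_max]`; the histogram uses `ceiling(sqrt(n))`
#' equal-width bins unless `nbins` is given.
#'
#' @param s numeric spacings (non-negative).
#' @param s_max truncation point, default 3.
#' @param nbins number of histogram bins; default `ceiling(sqrt(n))`.
#' @return list with `chisq`, `df`, `p_value`, `n_spacings`, `nbins`.
#' @export
nnsd_poisson_fit <- function(s, s_max = 3, nbins = NULL) {
  s <- s[s >= 0 & s <= s_max]
  n <- length(s)
  if (n < 10L) stop("too few spacings (", n, ") for a chi-square fit")
  if (is.null(nbins)) nbins <- ceiling(sqrt(n))
  breaks <- seq(0, s_max, length.out = nbins + 1L)
  obs <- tabulate(findInterval(s, breaks, rightmost.closed = TRUE),
                  nbins = nbins)
  # exponential probability mass per bin, renormalised over [0, s_max]
  pbin <- diff(-exp(-breaks)) / (1 - exp(-s_max))
  expd <- n * pbin
  chisq <- sum((obs - expd)^2 / expd)
  df <- nbins - 1L
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
       n_spacings = n, nbins = nbins)
}
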