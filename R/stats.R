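#' Histogram of sheath counts per cell
#'
#' @param counts Non-negative integer vector of occurrences, indexed by
#'   sheath number `0..K` (the first element is the number of cells with no
#'   sheath).
#' @return An object of class `t6_sheath_histogram`.
#' @seealso [tabulate_sheaths()] to build one from per-cell counts.
#' @export
sheath_histogram <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) >= 1, all(counts >= 0),
            all(abs(counts - round(counts)) < 1e-8))
  structure(list(counts = round(counts)), class = "t6_sheath_histogram")
}

#' Build a sheath histogram from per-cell counts
#' @param n_sheaths Integer vector of per-cell sheath counts.
#' @return A [sheath_histogram()].
#' @export
tabulate_sheaths <- function(n_sheaths) {
  stopifnot(all(n_sheaths >= 0))
  sheath_histogram(tabulate(n_sheaths + 1L, nbins = max(n_sheaths) + 1L))
}

#' @export
print.t6_sheath_histogram <- function(x, ...) {
  cat("Sheath-count histogram (N = 0..", length(x$counts) - 1, "):\n", sep = "")
  print(setNames(x$counts, seq_along(x$counts) - 1L))
  cat(sprintf("total %d cells, mean %.3f sheaths/cell\n",
              sum(x$counts), histogram_mean(x)))
  invisible(x)
}

#' Mean of a sheath histogram
#' @param hist A [sheath_histogram()].
#' @return The mean sheath number.
#' @export
histogram_mean <- function(hist) {
  stopifnot(inherits(hist, "t6_sheath_histogram"))
  tot <- sum(hist$counts)
  if (tot == 0) stop("empty histogram")
  sum((seq_along(hist$counts) - 1) * hist$counts) / tot
}

# pool adjacent bins (left to right) until every group's expected count is
# >= min_expected; a trailing underweight group is merged into its neighbour
pool_bins <- function(observed, expected, min_expected = 5) {
  groups <- integer(length(expected))
  g <- 1L
  acc <- 0
  for (i in seq_along(expected)) {
    groups[i] <- g
    acc <- acc + expected[i]
    if (acc >= min_expected && i < length(expected)) {
      g <- g + 1L
      acc <- 0
    }
  }
  obs <- tapply(observed, groups, sum)
  exp_ <- tapply(expected, groups, sum)
  if (length(exp_) > 1 && exp_[length(exp_)] < min_expected) {
    k <- length(exp_)
    obs[k - 1] <- obs[k - 1] + obs[k]
    exp_[k - 1] <- exp_[k - 1] + exp_[k]
    obs <- obs[-k]; exp_ <- exp_[-k]
  }
  list(observed = as.numeric(obs), expected = as.numeric(exp_))
}

#' Chi-squared goodness of fit of a sheath histogram to a Poisson law
#'
#' Compares the observed sheath-count distribution with the Poisson
#' distribution sharing its mean. Expected counts cover `N = 0..K-1` with
#' the upper tail lumped into the last bin; adjacent bins are pooled until
#' every expected count is at least 5, and the degrees of freedom are the
#' number of pooled bins minus 2 (one for the total, one for the estimated
#' mean).
#'
#' @param hist A [sheath_histogram()] with total count >= 20.
#' @return An object of class `htest` with the statistic, degrees of
#'   freedom, and upper-tail p-value.
#' @export
poisson_gof_test <- function(hist) {
  stopifnot(inherits(hist, "t6_sheath_histogram"))
  obs <- hist$counts
  tot <- sum(obs)
  if (tot < 20) stop("need a total count of at least 20")
  m <- histogram_mean(hist)
  if (m <= 0) stop("degenerate histogram: zero mean")
  k <- length(obs) - 1L
  expected <- tot * c(dpois(0:(k - 1), m), ppois(k - 1, m, lower.tail = FALSE))
  pooled <- pool_bins(obs, expected)
  df <- length(pooled$expected) - 2L
  if (df < 1) stop("too few bins after pooling for a chi-squared test")
  stat <- sum((pooled$observed - pooled$expected)^2 / pooled$expected)
  structure(list(
    statistic = c("X-squared" = stat),
    parameter = c(df = df),
    p.value = pchisq(stat, df, lower.tail = FALSE),
    method = "Chi-squared goodness-of-fit test against Poisson (pooled bins)",
    data.name = deparse(substitute(hist))), class = "htest")
}

#' Two-sample chi-squared comparison of sheath histograms
#'
#' Contingency-table chi-squared test of whether two sheath-count histograms
#' come from the same distribution. Sheath-number bins are pooled until each
#' pooled column's expected count (under the margins) is at least 5 in both
#' samples.
#'
#' @param hist_a,hist_b Two [sheath_histogram()] objects (totals >= 20).
#' @return An object of class `htest`.
#' @export
two_sample_chi2 <- function(hist_a, hist_b) {
  stopifnot(inherits(hist_a, "t6_sheath_histogram"),
            inherits(hist_b, "t6_sheath_histogram"))
  ka <- length(hist_a$counts); kb <- length(hist_b$counts)
  k <- max(ka, kb)
  a <- c(hist_a$counts, rep(0, k - ka))
  b <- c(hist_b$counts, rep(0, k - kb))
  na <- sum(a); nb <- sum(b)
  if (na < 20 || nb < 20) stop("both histograms need totals of at least 20")
  coltot <- a + b
  # pool columns until the expected count under the margins (computed with
  # the smaller row's share, the binding constraint) reaches 5
  share <- min(na, nb) / (na + nb)
  groups <- integer(k); g <- 1L; acc <- 0
  for (i in seq_len(k)) {
    groups[i] <- g
    acc <- acc + coltot[i] * share
    if (acc >= 5 && i < k) { g <- g + 1L; acc <- 0 }
  }
  ag <- as.numeric(tapply(a, groups, sum))
  bg <- as.numeric(tapply(b, groups, sum))
  ng <- length(ag)
  if (ng > 1) {
    ct <- (ag + bg) * share
    if (ct[ng] < 5) {
      ag[ng - 1] <- ag[ng - 1] + ag[ng]; bg[ng - 1] <- bg[ng - 1] + bg[ng]
      ag <- ag[-ng]; bg <- bg[-ng]
    }
  }
  tab <- rbind(ag, bg)
  if (ncol(tab) < 2) stop("too few bins after pooling for a chi-squared test")
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - exp_tab)^2 / exp_tab)
  df <- (ncol(tab) - 1L)
  structure(list(
    statistic = c("X-squared" = stat),
    parameter = c(df = df),
    p.value = pchisq(stat, df, lower.tail = FALSE),
    method = "Two-sample chi-squared test on pooled sheath-count bins",
    data.name = "hist_a vs hist_b"), class = "htest")
}
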