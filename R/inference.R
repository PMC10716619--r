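#' Kruskal-Wallis rank test (tie-corrected)
#'
#' Midranks are used for ties and the statistic carries the standard tie
#' correction \eqn{C = 1 - \sum (t^3 - t) / (N^3 - N)}. When every value is
#' identical the statistic is defined as 0 with p = 1.
#'
#' @param groups List of at least two non-empty numeric vectors.
#' @return List `H`, `df` (= k - 1), `p` (upper-tail chi-square).
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)                       # midranks
  g <- rep(seq_len(k), n)
  Rsum <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / n) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) {                      # all values identical
    return(list(H = 0, df = k - 1L, p = 1))
  }
  H <- H / C
  list(H = H, df = k - 1L, p = pchisq(H, df = k - 1, lower.tail = FALSE))
}

#' Dunn's pairwise post-hoc tests with Holm adjustment
#'
#' For each pair (i, j) the z statistic is the mean-rank difference divided
#' by \eqn{\sqrt{(N(N+1)/12 - \sum(t^3-t)/(12(N-1))) (1/n_i + 1/n_j)}}, with
#' two-sided normal p values. Holm's step-down adjustment is applied across
#' the pair family of this one test (never pooled across outcomes).
#'
#' @param groups List of at least two non-empty numeric vectors; names are
#'   used as group labels (defaults to `g1`, `g2`, ...).
#' @return `data.table` with columns `group_a, group_b, z, p_raw, p_holm`.
#' @export
dunn_posthoc <- function(groups) {
  check_groups(groups)
  k <- length(groups)
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("g", seq_len(k))
  n <- lengths(groups)
  N <- sum(n)
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)
  g <- rep(seq_len(k), n)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  base_var <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    se <- sqrt(base_var * (1 / n[i] + 1 / n[j]))
    z[c] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p_raw[c] <- 2 * pnorm(-abs(z[c]))
  }
  data.table::data.table(
    group_a = labs[pairs[1, ]], group_b = labs[pairs[2, ]],
    z = z, p_raw = p_raw, p_holm = p.adjust(p_raw, method = "holm")
  )
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("argument error: need at least 2 groups", call. = FALSE)
  }
  if (any(lengths(groups) == 0)) {
    stop("argument error: every group must be non-empty", call. = FALSE)
  }
  if (sum(lengths(groups)) < 3) {
    stop("argument error: total N must be >= 3", call. = FALSE)
  }
  invisible(TRUE)
}

#' Percent change from a log-scale coefficient
#'
#' Converts a coefficient estimated on a log-transformed outcome to the
#' percentage-change scale, `(exp(beta) - 1) * 100`, with a Wald interval
#' transformed monotonically from the log scale using a t quantile on `df`
#' denominator degrees of freedom (`df = Inf` gives the normal interval).
#'
#' @param beta Log-scale estimate.
#' @param se Standard error (>= 0).
#' @param df Denominator degrees of freedom (default `Inf`).
#' @param level Confidence level, default 0.95.
#' @return List `point`, `ci_low`, `ci_high`, in percent.
#' @export
percent_change <- function(beta, se = 0, df = Inf, level = 0.95) {
  stopifnot(se >= 0)
  tcrit <- qt(1 - (1 - level) / 2, df = df)
  list(point = (exp(beta) - 1) * 100,
       ci_low = (exp(beta - tcrit * se) - 1) * 100,
       ci_high = (exp(beta + tcrit * se) - 1) * 100)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column j on
#' all other columns (auxiliary regressions include an intercept).
#'
#' @param X Numeric matrix or data.frame of design columns, no intercept
#'   column; at least 2 columns and `ncol + 1` rows.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(ncol(X) >= 2, nrow(X) >= ncol(X) + 1)
  out <- numeric(ncol(X))
  names(out) <- colnames(X)
  for (j in seq_len(ncol(X))) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) { out[j] <- 1; next }
    r2 <- 1 - rss / tss
    out[j] <- if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }
  if (any(is.infinite(out))) {
    stop("infinite-VIF error: exactly collinear column(s): ",
         paste(names(out)[is.infinite(out)], collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @importFrom stats lm.fit
NULL
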