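#' Repeated-measures (within-subject) correlation
#'
#' The Bland-Altman estimator of the common within-subject correlation
#' between two repeatedly measured variables: both variables are centered by
#' their subject means and \eqn{r} is the Pearson correlation of the pooled
#' residuals, with \eqn{df = N - k - 1} (N observations, k subjects) and a
#' two-tailed p from the t distribution. Subject-level offsets cancel by
#' construction, so \eqn{r} reflects only the shared within-subject
#' variation.
#'
#' @param x,y numeric vectors, one observation per row.
#' @param subjects subject labels aligned with \code{x}.
#' @param minObs subjects with fewer complete (x,y) pairs than this are
#'   dropped with a warning (default 2: a single observation carries no
#'   within-subject information).
#' @return data.frame(r, df, p_value, n_obs, k_subjects, valid). \code{valid}
#'   is FALSE (with NA r) when a residual variance is zero or df < 1.
#' @examples
#' # subject offsets do not matter:
#' x <- c(1, 2, 101, 102); y <- c(2, 3, 102, 103)
#' rmCorrelation(x, y, c(1, 1, 2, 2))  # r = 1, df = 1
#' @export
rmCorrelation <- function(x, y, subjects, minObs = 2L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]; subjects <- as.character(subjects[ok])
  nPer <- table(subjects)
  small <- names(nPer)[nPer < minObs]
  if (length(small)) {
    warning(length(small), " subject(s) with < ", minObs, " observations dropped")
    keep <- !(subjects %in% small)
    x <- x[keep]; y <- y[keep]; subjects <- subjects[keep]
  }
  N <- length(x)
  k <- length(unique(subjects))
  if (k < 1L || N < 3L)
    return(data.frame(r = NA_real_, df = NA_integer_, p_value = NA_real_,
                      n_obs = N, k_subjects = k, valid = FALSE))
  xc <- x - stats::ave(x, subjects)
  yc <- y - stats::ave(y, subjects)
  sx <- sum(xc^2); sy <- sum(yc^2)
  df <- N - k - 1L
  if (sx <= 0 || sy <= 0 || df < 1L)
    return(data.frame(r = NA_real_, df = as.integer(df), p_value = NA_real_,
                      n_obs = N, k_subjects = k, valid = FALSE))
  r <- sum(xc * yc) / sqrt(sx * sy)
  r <- max(-1, min(1, r))
  tstat <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  data.frame(r = r, df = as.integer(df), p_value = p, n_obs = N,
             k_subjects = k, valid = TRUE)
}

#' All pairwise repeated-measures correlations among columns
#'
#' Columns are subject-centered once, then all pairwise Pearson correlations
#' of the residuals are taken (equivalent to [rmCorrelation] per pair when
#' data are complete). Columns with zero residual variance give NA.
#'
#' @param m numeric matrix, observations x variables (complete data).
#' @param subjects subject labels per row.
#' @return list: \code{r} (variables x variables correlation matrix),
#'   \code{df} (shared residual df = N - k - 1), \code{p} (matrix of
#'   two-tailed p-values).
#' @export
rmCorrelationMatrix <- function(m, subjects) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("rmCorrelationMatrix needs complete data")
  subjects <- as.character(subjects)
  N <- nrow(m)
  k <- length(unique(subjects))
  df <- N - k - 1L
  if (df < 1L) stop("not enough residual degrees of freedom (N - k - 1 < 1)")
  cen <- m - apply(m, 2L, function(col) stats::ave(col, subjects))
  sd0 <- apply(cen, 2L, function(col) sum(col^2)) <= 0
  R <- suppressWarnings(stats::cor(cen))
  R[sd0, ] <- NA_real_
  R[, sd0] <- NA_real_
  diag(R) <- 1
  Tm <- R * sqrt(df) / sqrt(pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * stats::pt(abs(Tm), df, lower.tail = FALSE)
  diag(P) <- 0
  list(r = R, df = df, p = P)
}
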