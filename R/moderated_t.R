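#' Empirical-Bayes moderated t-test
#'
#' Per-feature two-group (or paired one-sample) contrast with variance
#' shrinkage. Per-feature residual variances s2_g with d_g degrees of
#' freedom are shrunk toward a prior (d0, s0^2) estimated by the standard
#' method of moments on log s2: with e_g = log s2_g - digamma(d_g/2) +
#' log(d_g/2), the prior df solves trigamma(d0/2) = var(e) - trigamma(d_g/2)
#' and s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2)). The posterior
#' variance is (d0 s0^2 + d_g s2_g)/(d0 + d_g); the moderated t uses it in
#' place of s2_g and has d0 + d_g degrees of freedom. When the moment
#' estimate leaves no excess variability (e.g. all s2_g identical), d0 is
#' set infinite and the posterior variance is s0^2 for every feature.
#'
#' @param group_a numeric matrix (features x arrays) for group A, or for a
#'   paired/one-sample design the matrix of per-array log ratios (then leave
#'   \code{group_b} NULL).
#' @param group_b numeric matrix for group B, or NULL for the one-sample
#'   test of mean 0.
#' @return object of class \code{contrast_result}: data frame with columns
#'   \code{feature_id}, \code{logFC}, \code{t}, \code{df_total},
#'   \code{p_value}, \code{q_value}, \code{significant} (initialized FALSE;
#'   see \code{\link{call_significant}}); attributes \code{d0}, \code{s0_sq}.
#' @export
fit_moderated_t <- function(group_a, group_b = NULL) {
  a <- as.matrix(group_a)
  if (is.null(group_b)) {
    n <- ncol(a)
    if (n < 2L) stop("one-sample design needs >= 2 arrays")
    logfc <- rowMeans(a)
    s2 <- apply(a, 1, stats::var)
    dg <- n - 1L
    scale2 <- 1 / n                      # Var(mean) = s2 / n
  } else {
    b <- as.matrix(group_b)
    stopifnot(nrow(a) == nrow(b))
    na <- ncol(a); nb <- ncol(b)
    dg <- na + nb - 2L
    if (dg < 1L) stop("zero residual degrees of freedom")
    logfc <- rowMeans(a) - rowMeans(b)
    ssa <- if (na > 1) apply(a, 1, stats::var) * (na - 1) else 0
    ssb <- if (nb > 1) apply(b, 1, stats::var) * (nb - 1) else 0
    s2 <- (ssa + ssb) / dg
    scale2 <- 1 / na + 1 / nb
  }
  pr <- estimate_prior(s2, dg)
  if (is.finite(pr$d0)) {
    s2_post <- (pr$d0 * pr$s0_sq + dg * s2) / (pr$d0 + dg)
    df_total <- pr$d0 + dg
  } else {
    s2_post <- rep(pr$s0_sq, length(s2))
    df_total <- Inf
  }
  denom <- sqrt(s2_post * scale2)
  tstat <- ifelse(denom == 0, ifelse(logfc == 0, 0, sign(logfc) * Inf),
                  logfc / denom)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  ids <- rownames(a)
  if (is.null(ids)) ids <- paste0("f", seq_along(logfc))
  out <- data.frame(feature_id = ids, logFC = logfc, t = tstat,
                    df_total = df_total, p_value = p,
                    q_value = bh_adjust(p), significant = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- pr$d0
  attr(out, "s0_sq") <- pr$s0_sq
  class(out) <- c("contrast_result", "data.frame")
  out
}

# method-of-moments prior for the scaled inverse-chi-square variance model,
# via moments of log s2 (finite-sample chi-square log-moments)
estimate_prior <- function(s2, dg) {
  s2 <- pmax(s2, 1e-300)
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  n <- length(e)
  if (n < 2L) return(list(d0 = Inf, s0_sq = exp(emean)))
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(dg / 2)
  if (evar <= 0) return(list(d0 = Inf, s0_sq = exp(emean)))
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of trigamma on (0, Inf)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("contrast_result:", nrow(x), "features; prior df d0 =",
      format(attr(x, "d0"), digits = 4), ", s0^2 =",
      format(attr(x, "s0_sq"), digits = 4), "\n",
      sum(x$significant), "significant\n")
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: monotone in p-rank and capped at 1.
#'
#' @param p numeric p-values in [0, 1].
#' @return q-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Apply significance calls to a contrast result
#'
#' significant iff |logFC| >= log2(fc_threshold) AND (p < alpha under the
#' \code{raw_p} criterion, or q <= alpha under \code{bh_q}).
#'
#' @param result \code{contrast_result}.
#' @param fc_threshold linear fold-change threshold.
#' @param alpha significance level.
#' @param criterion \code{"bh_q"} (default) or \code{"raw_p"}.
#' @return the result with \code{significant} recomputed; the criterion is
#'   recorded in attribute \code{criterion}.
#' @export
call_significant <- function(result, fc_threshold = 2.0, alpha = 0.05,
                             criterion = c("bh_q", "raw_p")) {
  criterion <- match.arg(criterion)
  gate <- abs(result$logFC) >= log2(fc_threshold)
  stat <- if (criterion == "raw_p") result$p_value < alpha else result$q_value <= alpha
  result$significant <- gate & stat
  attr(result, "criterion") <- list(fc_threshold = fc_threshold, alpha = alpha,
                                    criterion = criterion)
  result
}

#' Dye-balance (self-self) contrast
#'
#' Tests, per feature, whether the mean LOWESS-corrected log ratio M across
#' self-self arrays differs from 0, then partitions the significant features
#' by feature class. Any biologically-classed significant feature raises a
#' dye-bias warning.
#'
#' @param m_corrected numeric matrix (features x arrays) of corrected M
#'   values from self-self hybridizations (>= 2 arrays).
#' @param feature_class character vector per feature (\code{biological},
#'   \code{spikein}, \code{stringency}, \code{replicate}, \code{corner}).
#' @param fc_threshold,alpha,criterion significance settings (see
#'   \code{\link{call_significant}}).
#' @return list with \code{result} (\code{contrast_result}),
#'   \code{significant_by_class} (table), \code{dye_bias_warning} (logical).
#' @export
dye_balance_contrast <- function(m_corrected, feature_class,
                                 fc_threshold = 2.0, alpha = 0.05,
                                 criterion = "raw_p") {
  m <- as.matrix(m_corrected)
  if (ncol(m) < 2L) stop("need >= 2 self-self arrays")
  stopifnot(length(feature_class) == nrow(m))
  res <- fit_moderated_t(m, NULL)
  res <- call_significant(res, fc_threshold, alpha, criterion)
  sig_class <- feature_class[res$significant]
  list(result = res,
       significant_by_class = table(factor(sig_class,
                                           levels = sort(unique(feature_class)))),
       dye_bias_warning = any(sig_class == "biological"))
}

#' Two-group isolation-reproducibility contrast
#'
#' Standard two-group moderated-t contrast on normalized single-channel
#' values, e.g. comparing arrays hybridized from two independent RNA
#' isolations of the same pool.
#'
#' @param iso1,iso2 numeric matrices (features x arrays), same features.
#' @param fc_threshold,alpha,criterion significance settings.
#' @return \code{contrast_result} with significance called.
#' @export
isolation_contrast <- function(iso1, iso2, fc_threshold = 2.0, alpha = 0.05,
                               criterion = "raw_p") {
  if (!ncol(as.matrix(iso1)) || !ncol(as.matrix(iso2)))
    stop("both isolation groups must be non-empty")
  res <- fit_moderated_t(as.matrix(iso2), as.matrix(iso1))  # iso2 vs iso1
  call_significant(res, fc_threshold, alpha, criterion)
}
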