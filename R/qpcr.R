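#' Fit a qPCR standard curve and amplification efficiency
#'
#' Least-squares fit of Ct on log10 template input. Amplification efficiency
#' is E = (10^(-1/slope) - 1) * 100%; a perfect doubling per cycle gives a
#' slope of -log2(10) ~ -3.3219 and E = 100%.
#'
#' @param log10_inputs log10 template amounts (>= 3 points, strictly
#'   monotone).
#' @param ct_values observed Ct per point.
#' @return object of class \code{standard_curve}: list with \code{slope},
#'   \code{intercept}, \code{efficiency_percent}, \code{r_squared},
#'   \code{n}.
#' @export
fit_standard_curve <- function(log10_inputs, ct_values) {
  stopifnot(length(log10_inputs) == length(ct_values))
  if (length(log10_inputs) < 3L) stop("standard curve needs >= 3 dilution points")
  d <- diff(log10_inputs)
  if (!(all(d > 0) || all(d < 0)))
    stop("log10 inputs must be strictly increasing or decreasing")
  fit <- stats::lm(ct_values ~ log10_inputs)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= -1e-12) stop("non-physical standard curve: slope must be negative")
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency_percent = (10^(-1 / slope) - 1) * 100,
                 r_squared = stats::cor(ct_values, log10_inputs)^2,
                 n = length(ct_values)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: slope %.4f, intercept %.2f, efficiency %.1f%% (n = %d)\n",
              x$slope, x$intercept, x$efficiency_percent, x$n))
  invisible(x)
}

#' Relative expression as -delta-Ct
#'
#' Means over technical replicates for target and reference gene, then
#' -dCt = -(mean Ct_target - mean Ct_reference). Higher values indicate
#' higher relative abundance. No replicate-outlier rejection is performed.
#'
#' @param gene_ct numeric Ct replicates for the target gene.
#' @param reference_ct numeric Ct replicates for the reference gene.
#' @param gene optional gene name carried into the record.
#' @return one-row data frame with \code{gene}, \code{ct_mean},
#'   \code{ct_reference_mean}, \code{minus_delta_ct}.
#' @export
compute_minus_delta_ct <- function(gene_ct, reference_ct, gene = NA_character_) {
  if (!length(gene_ct) || !length(reference_ct)) stop("empty Ct replicates")
  ct_mean <- mean(gene_ct)
  ref_mean <- mean(reference_ct)
  data.frame(gene = gene, ct_mean = ct_mean, ct_reference_mean = ref_mean,
             minus_delta_ct = -(ct_mean - ref_mean), stringsAsFactors = FALSE)
}

#' Cross-platform concordance: array intensity vs -delta-Ct
#'
#' Least-squares fit of qPCR -dCt on array mean processed signal per gene,
#' with the Pearson correlation and its two-sided p-value (t transform,
#' n - 2 df).
#'
#' @param array_signal mean processed array signal per gene.
#' @param minus_delta_ct qPCR -dCt per gene (paired with
#'   \code{array_signal}).
#' @param genes optional gene names.
#' @return object of class \code{concordance_result}: list with
#'   \code{slope}, \code{intercept}, \code{pearson_r}, \code{p_value},
#'   \code{n}, \code{genes}.
#' @export
platform_concordance <- function(array_signal, minus_delta_ct, genes = NULL) {
  stopifnot(length(array_signal) == length(minus_delta_ct))
  n <- length(array_signal)
  if (n < 3L) stop("concordance needs >= 3 paired genes")
  if (stats::var(array_signal) == 0 || stats::var(minus_delta_ct) == 0)
    stop("zero variance in one platform's values")
  fit <- stats::lm(minus_delta_ct ~ array_signal)
  r <- stats::cor(array_signal, minus_delta_ct)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = r, p_value = p, n = n, genes = genes),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance: slope %.4g, intercept %.4g, Pearson R = %.3f (n = %d, p = %.3g)\n",
              x$slope, x$intercept, x$pearson_r, x$n, x$p_value))
  invisible(x)
}

#' Read a qPCR Ct table
#'
#' @param path TSV with columns gene, replicate, ct, role (target/reference)
#'   and optionally dilution (log10 input for standard curves).
#' @return data frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "replicate", "ct", "role")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  df
}
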