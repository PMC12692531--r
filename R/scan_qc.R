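#' Per-spot signal-to-noise ratio
#'
#' SNR = (median_signal - bg_median) / bg_pix_sd. May be negative; the
#' denominator must be strictly positive. Invariant under a common
#' multiplicative gain applied to all three inputs.
#'
#' @param median_signal spot foreground median intensity.
#' @param bg_median local background median intensity.
#' @param bg_pix_sd background pixel standard deviation (> 0).
#' @return numeric SNR (vectorized).
#' @export
compute_snr <- function(median_signal, bg_median, bg_pix_sd) {
  if (any(bg_pix_sd <= 0)) stop("bg_pix_sd must be > 0 (degenerate background)")
  (median_signal - bg_median) / bg_pix_sd
}

#' Detection class from median SNR and the well-above-background flag
#'
#' robust iff well_above_bg AND snr >= 3; else cautionary iff snr >= 1.5;
#' else low_confidence. Both boundaries are closed from below.
#'
#' @param median_snr median SNR over replicate spots.
#' @param well_above_bg logical well-above-background flag.
#' @return character vector in \code{robust}/\code{cautionary}/
#'   \code{low_confidence}.
#' @export
classify_detection <- function(median_snr, well_above_bg) {
  out <- rep("low_confidence", length(median_snr))
  out[median_snr >= 1.5] <- "cautionary"
  out[well_above_bg & median_snr >= 3] <- "robust"
  out
}

#' Collapse replicate spots of one probe on one array
#'
#' Median of per-spot SNRs; arithmetic means of signal and background;
#' adverse flag true iff any spot is a non-uniformity outlier, a population
#' outlier, or saturated.
#'
#' @param spots data frame of spots for one probe on one array with columns
#'   \code{median_signal}, \code{bg_median}, \code{bg_pix_sd},
#'   \code{processed_signal}, \code{well_above_bg},
#'   \code{feat_nonunif_outlier}, \code{feat_popn_outlier}, \code{saturated}
#'   (and optionally \code{array_id}, \code{probe_id}).
#' @return one-row data frame of class \code{probe_array_summary} with
#'   \code{median_snr}, \code{mean_signal}, \code{mean_bg},
#'   \code{mean_processed}, \code{well_above_bg} (all spots),
#'   \code{any_adverse_flag}, \code{detection_class}.
#' @export
collapse_replicate_spots <- function(spots) {
  if (!nrow(spots)) stop("no spots to collapse")
  snr <- compute_snr(spots$median_signal, spots$bg_median, spots$bg_pix_sd)
  med_snr <- stats::median(snr)
  wab <- all(spots$well_above_bg)
  out <- data.frame(
    array_id = if ("array_id" %in% names(spots)) spots$array_id[1] else NA_character_,
    probe_id = if ("probe_id" %in% names(spots)) spots$probe_id[1] else NA_character_,
    n_spots = nrow(spots),
    median_snr = med_snr,
    mean_signal = mean(spots$median_signal),
    mean_bg = mean(spots$bg_median),
    mean_processed = mean(spots$processed_signal),
    well_above_bg = wab,
    any_adverse_flag = any(spots$feat_nonunif_outlier | spots$feat_popn_outlier |
                             spots$saturated),
    stringsAsFactors = FALSE
  )
  out$detection_class <- classify_detection(out$median_snr, out$well_above_bg)
  class(out) <- c("probe_array_summary", "data.frame")
  out
}

#' Across-array QC summary for one probe
#'
#' Arrays carrying any adverse flag are excluded from the SNR statistics but
#' counted in \code{flagged_array_count}. The present-call rate is the
#' fraction of unflagged arrays on which the probe is robustly detected.
#'
#' @param per_array data frame of per-array summaries for one probe (rows as
#'   returned by \code{\link{collapse_replicate_spots}}).
#' @return one-row data frame of class \code{probe_qc_summary} with
#'   \code{median_snr}, \code{min_snr}, \code{max_snr},
#'   \code{mean_processed_signal}, \code{present_call_rate},
#'   \code{flagged_array_count}, \code{n_arrays}, \code{snr_available}.
#' @export
summarize_probe <- function(per_array) {
  if (!nrow(per_array)) stop("no per-array summaries")
  ok <- !per_array$any_adverse_flag
  use <- per_array[ok, , drop = FALSE]
  avail <- nrow(use) > 0
  out <- data.frame(
    probe_id = if ("probe_id" %in% names(per_array)) per_array$probe_id[1] else NA_character_,
    n_arrays = nrow(per_array),
    flagged_array_count = sum(!ok),
    snr_available = avail,
    median_snr = if (avail) stats::median(use$median_snr) else NA_real_,
    min_snr = if (avail) min(use$median_snr) else NA_real_,
    max_snr = if (avail) max(use$median_snr) else NA_real_,
    mean_processed_signal = if (avail) mean(use$mean_processed) else NA_real_,
    present_call_rate = if (avail) mean(use$detection_class == "robust") else NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("probe_qc_summary", "data.frame")
  out
}

#' Run spot-level QC over a full scan table
#'
#' Convenience wrapper: collapses replicate spots per probe x array, then
#' summarizes each probe across arrays.
#'
#' @param spots long data frame of spot measurements with \code{array_id}
#'   and \code{probe_id} columns (see \code{\link{read_fe_table}}).
#' @return list with \code{per_array} (one row per probe x array) and
#'   \code{per_probe} (one row per probe).
#' @export
qc_summarize <- function(spots) {
  key <- interaction(spots$array_id, spots$probe_id, drop = TRUE)
  per_array <- do.call(rbind, lapply(split(spots, key), collapse_replicate_spots))
  per_probe <- do.call(rbind, lapply(split(per_array, per_array$probe_id),
                                     summarize_probe))
  rownames(per_array) <- rownames(per_probe) <- NULL
  list(per_array = per_array, per_probe = per_probe)
}

#' Derivative log-ratio spread (DLRSpread)
#'
#' Robust spread of adjacent log-ratio differences: the 1.349-scaled IQR of
#' first differences of consecutive log ratios (in array position order),
#' divided by sqrt(2). For i.i.d. Gaussian log ratios this estimates their
#' standard deviation.
#'
#' @param log_ratios numeric vector of per-feature log ratios ordered by
#'   array position (>= 3 values).
#' @return numeric DLRS.
#' @export
compute_dlrs <- function(log_ratios) {
  if (length(log_ratios) < 3L) stop("DLRS needs at least 3 log ratios")
  d <- diff(log_ratios)
  (stats::IQR(d) / 1.349) / sqrt(2)
}

#' Spike-in panel check: observed vs expected log ratios
#'
#' Least-squares slope and Pearson correlation of observed on expected
#' log ratios across spike-in levels. Both statistics are invariant to a
#' constant offset in the observations.
#'
#' @param observed observed mean log ratio per spike level.
#' @param expected expected (nominal) log ratio per spike level.
#' @return list with \code{slope}, \code{intercept}, \code{correlation},
#'   \code{n}.
#' @export
spike_in_check <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  if (length(observed) < 3L) stop("need >= 3 spike levels")
  if (stats::var(expected) == 0) stop("zero variance in expected log ratios")
  fit <- stats::lm(observed ~ expected)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       correlation = stats::cor(observed, expected),
       n = length(observed))
}

#' Read a feature-extraction style per-spot TSV
#'
#' Expects the conventional two-color column names (gMedianSignal,
#' gBGMedianSignal, gBGPixSDev, gProcessedSignal, gIsWellAboveBG,
#' gIsFeatNonUnifOL, gIsFeatPopnOL, gIsSaturated, gIsPosAndSignif; optionally
#' the r-prefixed red-channel set) plus ProbeName. Unknown columns are
#' ignored with a notice. Returns a long table with one row per spot and
#' channel.
#'
#' @param path TSV path.
#' @param array_id identifier recorded in the output (default: file name).
#' @param channels channels to extract (\code{"green"}, \code{"red"}).
#' @return data frame with columns \code{array_id}, \code{probe_id},
#'   \code{feature_class} (if present in the file), \code{channel},
#'   \code{median_signal}, \code{bg_median}, \code{bg_pix_sd},
#'   \code{processed_signal}, \code{well_above_bg}, \code{pos_and_signif},
#'   \code{feat_nonunif_outlier}, \code{feat_popn_outlier}, \code{saturated}.
#' @export
read_fe_table <- function(path, array_id = basename(path),
                          channels = c("green", "red")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  prefix <- c(green = "g", red = "r")
  need <- function(p) paste0(p, c("MedianSignal", "BGMedianSignal", "BGPixSDev",
                                  "ProcessedSignal", "IsWellAboveBG",
                                  "IsPosAndSignif", "IsFeatNonUnifOL",
                                  "IsFeatPopnOL", "IsSaturated"))
  known <- c("ProbeName", "FeatureNum", "Row", "Col", "ControlType",
             "feature_class", need("g"), need("r"))
  unknown <- setdiff(names(df), known)
  if (length(unknown))
    message("read_fe_table: ignoring unknown column(s): ",
            paste(unknown, collapse = ", "))
  out <- list()
  for (ch in channels) {
    p <- prefix[[ch]]
    cols <- need(p)
    if (!all(cols %in% names(df))) {
      if (identical(ch, "red")) next  # single-channel file
      stop("missing required column(s): ",
           paste(setdiff(cols, names(df)), collapse = ", "))
    }
    out[[ch]] <- data.frame(
      array_id = array_id,
      probe_id = df$ProbeName,
      feature_class = if ("feature_class" %in% names(df)) df$feature_class else NA_character_,
      channel = ch,
      median_signal = df[[cols[1]]],
      bg_median = df[[cols[2]]],
      bg_pix_sd = df[[cols[3]]],
      processed_signal = df[[cols[4]]],
      well_above_bg = df[[cols[5]]] == 1,
      pos_and_signif = df[[cols[6]]] == 1,
      feat_nonunif_outlier = df[[cols[7]]] == 1,
      feat_popn_outlier = df[[cols[8]]] == 1,
      saturated = df[[cols[9]]] == 1,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
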