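#' Enrichment score of a functional cluster
#'
#' ES = -log10 of the geometric mean of the cluster's term p-values,
#' computed as the arithmetic mean of -log10(p) (algebraically identical,
#' numerically safer). Clusters with ES >= 1.3 are conventionally called
#' significantly enriched (roughly p < 0.05).
#'
#' @param p_values term p-values, all in (0, 1].
#' @return numeric enrichment score.
#' @export
enrichment_score <- function(p_values) {
  if (!length(p_values)) stop("no term p-values")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  mean(-log10(p_values))
}

#' Score a table of clusters and call enrichment
#'
#' @param clusters data frame with columns \code{cluster_id} and \code{p}.
#' @param threshold ES significance threshold.
#' @return data frame with one row per cluster: \code{cluster_id},
#'   \code{n_terms}, \code{enrichment_score}, \code{significant}.
#' @export
score_clusters <- function(clusters, threshold = 1.3) {
  stopifnot(all(c("cluster_id", "p") %in% names(clusters)))
  sp <- split(clusters$p, clusters$cluster_id)
  out <- data.frame(cluster_id = names(sp),
                    n_terms = lengths(sp),
                    enrichment_score = vapply(sp, enrichment_score, numeric(1)),
                    stringsAsFactors = FALSE)
  out$significant <- out$enrichment_score >= threshold
  rownames(out) <- NULL
  out
}

#' Directional summary of a gene category
#'
#' Counts up- (logFC > 0), down- (logFC < 0) and unchanged (logFC == 0)
#' genes in a category and reports the mean and median logFC. Genes without
#' a logFC are dropped with a message.
#'
#' @param category_genes gene ids in the category.
#' @param logfc named numeric vector gene id -> logFC.
#' @param category_id optional identifier carried into the output.
#' @return one-row data frame with \code{category_id}, \code{n_genes},
#'   \code{n_up}, \code{n_down}, \code{n_unchanged}, \code{mean_logfc},
#'   \code{median_logfc}.
#' @export
category_direction_summary <- function(category_genes, logfc,
                                       category_id = NA_character_) {
  present <- category_genes %in% names(logfc)
  if (any(!present))
    message("category_direction_summary: dropping ", sum(!present),
            " gene(s) without logFC")
  x <- logfc[category_genes[present]]
  if (!length(x)) stop("empty category after dropping unmapped genes")
  data.frame(category_id = category_id,
             n_genes = length(x),
             n_up = sum(x > 0),
             n_down = sum(x < 0),
             n_unchanged = sum(x == 0),
             mean_logfc = mean(x),
             median_logfc = stats::median(x),
             stringsAsFactors = FALSE)
}

#' Percentage of a count relative to a total, at printed precision
#'
#' The rounding used in reported class breakdowns (e.g. 745 of 856 mRNA
#' features -> 87.03%).
#'
#' @param n count.
#' @param total denominator.
#' @param digits decimal places to round to.
#' @return numeric percentage.
#' @export
percent_of <- function(n, total, digits = 2) {
  stopifnot(total > 0)
  round(100 * n / total, digits)
}

#' Biotype/class breakdown of a detected feature set
#'
#' @param classes character vector of feature classes (one per detected
#'   feature).
#' @param digits decimal places for percentages.
#' @return data frame with \code{class}, \code{n}, \code{percent}.
#' @export
class_breakdown <- function(classes, digits = 2) {
  cnt <- table(classes)
  data.frame(class = names(cnt), n = as.integer(cnt),
             percent = percent_of(as.integer(cnt), length(classes), digits),
             stringsAsFactors = FALSE)
}
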