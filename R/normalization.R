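#' Expression matrix with normalization provenance
#'
#' A numeric matrix (probes x arrays) carrying an append-only, ordered
#' provenance record of the normalization steps applied. Re-applying a step
#' already in the provenance is an error.
#'
#' @param values numeric matrix, rownames = probe ids, colnames = array ids.
#' @param channel optional per-array channel annotation.
#' @param provenance character vector of steps already applied.
#' @return object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, channel = NULL, provenance = character()) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) rownames(values) <- paste0("f", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("a", seq_len(ncol(values)))
  structure(list(values = values, channel = channel, provenance = provenance),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "features x", ncol(x$values),
      "arrays; provenance:",
      if (length(x$provenance)) paste(x$provenance, collapse = " -> ") else "(raw)",
      "\n")
  invisible(x)
}

add_provenance <- function(em, step) {
  if (step %in% em$provenance)
    stop("normalization step '", step, "' already applied (provenance: ",
         paste(em$provenance, collapse = " -> "), ")")
  em$provenance <- c(em$provenance, step)
  em
}

#' Log2-transform raw intensities
#'
#' Values <= 0 are replaced, per array, by half the smallest positive value
#' on that array before taking log2; substitutions are recorded in the
#' provenance.
#'
#' @param raw numeric matrix of raw intensities (probes x arrays), or an
#'   \code{expression_matrix} holding raw values.
#' @return \code{expression_matrix} in log2 space.
#' @export
log2_transform <- function(raw) {
  em <- if (inherits(raw, "expression_matrix")) raw else expression_matrix(raw)
  v <- em$values
  n_sub <- 0L
  for (j in seq_len(ncol(v))) {
    pos <- v[, j] > 0
    if (!any(pos)) stop("array '", colnames(v)[j], "' has no positive values")
    if (any(!pos)) {
      v[!pos, j] <- min(v[pos, j]) / 2
      n_sub <- n_sub + sum(!pos)
    }
  }
  em$values <- log2(v)
  add_provenance(em, sprintf("log2[%d substituted]", n_sub))
}

#' Within-array LOWESS dye normalization on MA coordinates
#'
#' For paired green/red log2 intensities, M = log2(red) - log2(green) and
#' A = (log2(red) + log2(green))/2. The intensity-dependent dye trend is the
#' LOWESS fit of M on A (span \code{span}, \code{iter} robustness
#' iterations); the corrected M is the residual.
#'
#' @param log2_green,log2_red per-probe log2 intensities of one array.
#' @param span LOWESS smoother span.
#' @param iter robustness iterations.
#' @return data frame with columns \code{A}, \code{M}, \code{M_corrected}.
#' @export
lowess_ma_normalize <- function(log2_green, log2_red, span = 0.3, iter = 3L) {
  stopifnot(length(log2_green) == length(log2_red))
  if (length(log2_green) < 10L) stop("LOWESS fit unsupported below 10 probes")
  M <- log2_red - log2_green
  A <- (log2_red + log2_green) / 2
  fit <- stats::lowess(A, M, f = span, iter = iter)
  trend <- stats::approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
  data.frame(A = A, M = M, M_corrected = M - trend)
}

#' 75th-percentile within-array normalization
#'
#' Subtracts each array's 75th percentile (linear-interpolation quantile)
#' from that array's log2 values, so the post-normalization 75th percentile
#' of every array is 0.
#'
#' @param em \code{expression_matrix} of log2 values.
#' @return shifted \code{expression_matrix}.
#' @export
percentile75_normalize <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  q75 <- apply(em$values, 2, stats::quantile, probs = 0.75, type = 7, names = FALSE)
  em$values <- sweep(em$values, 2, q75, "-")
  add_provenance(em, "percentile75")
}

#' Baseline transformation to the median of all samples
#'
#' Subtracts each probe's cross-array median, so every probe's median over
#' arrays is 0 afterwards.
#'
#' @param em \code{expression_matrix} of log2 values.
#' @return centered \code{expression_matrix}.
#' @export
baseline_to_median <- function(em) {
  stopifnot(inherits(em, "expression_matrix"), ncol(em$values) >= 1)
  med <- apply(em$values, 1, stats::median)
  em$values <- sweep(em$values, 1, med, "-")
  add_provenance(em, "baseline_to_median")
}

#' Collapse probe-level values to gene level
#'
#' Per gene and array, the median over that gene's probes (a resistant
#' consensus); single-probe genes pass through unchanged.
#'
#' @param em \code{expression_matrix} with probe rownames.
#' @param probe_to_gene named character vector probe_id -> gene_id covering
#'   every retained probe.
#' @return gene-level \code{expression_matrix}.
#' @export
collapse_gene_level <- function(em, probe_to_gene) {
  stopifnot(inherits(em, "expression_matrix"))
  probes <- rownames(em$values)
  missing <- probes[!probes %in% names(probe_to_gene)]
  if (length(missing))
    stop("probe(s) without gene mapping: ", paste(missing, collapse = ", "))
  gene <- probe_to_gene[probes]
  idx <- split(seq_along(probes), gene)
  vals <- do.call(rbind, lapply(idx, function(i) {
    if (length(i) == 1L) em$values[i, ] else
      apply(em$values[i, , drop = FALSE], 2, stats::median)
  }))
  dimnames(vals) <- list(names(idx), colnames(em$values))
  out <- expression_matrix(vals, channel = em$channel,
                           provenance = em$provenance)
  add_provenance(out, "collapse_gene_level")
}
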