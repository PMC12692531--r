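#' Mask vector, low-complexity and ambiguous segments of a sequence
#'
#' Produces a \code{masked_sequence}: the input sequence plus a sorted set of
#' disjoint 0-based half-open masked intervals, each tagged with its source.
#' Three mask sources are applied:
#' \itemize{
#'   \item \strong{vector}: all maximal exact matches of length >=
#'     \code{min_vector_match} to any supplied vector sequence or its reverse
#'     complement;
#'   \item \strong{low_complexity}: a DUST-style triplet-count score computed
#'     over sliding windows; windows scoring above \code{dust_threshold} are
#'     masked;
#'   \item \strong{ambiguous}: every N position.
#' }
#' Overlapping intervals are merged; when intervals from different sources
#' merge, the tag of the earliest-starting contributing interval is kept.
#'
#' @param seq uppercase A/C/G/T/N nucleotide string.
#' @param vectors character vector of vector/adapter sequences to screen
#'   against (may be empty).
#' @param dust_window sliding window size for the low-complexity score.
#' @param dust_threshold score above which a window is masked. The score of a
#'   window with triplet counts c_t is sum(c_t*(c_t-1)/2)/(k-1), k the number
#'   of triplets in the window; ~0.5 for random sequence, ~k/2 for a
#'   homopolymer.
#' @param min_vector_match minimum length of an exact vector match to mask.
#' @return object of class \code{masked_sequence}: list with \code{sequence},
#'   \code{length}, and \code{masked} (data frame start, end, source; 0-based
#'   half-open).
#' @export
mask_sequence <- function(seq, vectors = character(), dust_window = 64L,
                          dust_threshold = 2.0, min_vector_match = 15L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence")
  if (grepl("[^ACGTN]", seq)) stop("sequence must be uppercase A/C/G/T/N")
  n <- nchar(seq)

  iv <- list()
  # ambiguous: N runs
  nn <- gregexpr("N+", seq)[[1]]
  if (nn[1] != -1L) {
    len <- attr(nn, "match.length")
    iv[[length(iv) + 1L]] <- data.frame(start = as.integer(nn) - 1L,
                                        end = as.integer(nn) - 1L + len,
                                        source = "ambiguous")
  }
  # vector: maximal exact matches >= min_vector_match, either strand
  for (v in vectors) {
    for (vs in unique(c(v, revcomp(v)))) {
      m <- maximal_exact_matches(seq, vs, min_vector_match)
      if (nrow(m)) iv[[length(iv) + 1L]] <- data.frame(start = m$start, end = m$end,
                                                       source = "vector")
    }
  }
  # low complexity: DUST-style windows
  lc <- dust_intervals(seq, dust_window, dust_threshold)
  if (nrow(lc)) iv[[length(iv) + 1L]] <- cbind(lc, source = "low_complexity")

  masked <- if (length(iv)) merge_intervals(do.call(rbind, iv)) else
    data.frame(start = integer(), end = integer(), source = character())
  structure(list(sequence = seq, length = n, masked = masked),
            class = "masked_sequence")
}

#' @export
print.masked_sequence <- function(x, ...) {
  cat("masked_sequence:", x$length, "nt,", nrow(x$masked), "masked interval(s),",
      sum(x$masked$end - x$masked$start), "nt masked\n")
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# maximal exact matches of query segments (length >= minlen) within subject;
# seed 12-mers of the query, extend both ways, deduplicate. 0-based half-open
# on the subject.
maximal_exact_matches <- function(subject, query, minlen) {
  ns <- nchar(subject); nq <- nchar(query)
  out <- data.frame(start = integer(), end = integer())
  if (nq < minlen || ns < minlen) return(out)
  k <- min(minlen, 12L)
  sub_raw <- charToRaw(subject); q_raw <- charToRaw(query)
  # index subject k-mers
  hits <- list()
  q_kmers <- substring(query, 1:(nq - k + 1L), k:nq)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (qi in seq_along(q_kmers)) {
    km <- q_kmers[qi]
    pos <- get0(km, envir = seen)
    if (is.null(pos)) {
      g <- gregexpr(km, subject, fixed = TRUE)[[1]]
      pos <- if (g[1] == -1L) integer() else as.integer(g)
      assign(km, pos, envir = seen)
    }
    for (sp in pos) {
      # extend the diagonal (sp - qi) maximally
      s0 <- sp; q0 <- qi
      while (s0 > 1L && q0 > 1L && sub_raw[s0 - 1L] == q_raw[q0 - 1L]) { s0 <- s0 - 1L; q0 <- q0 - 1L }
      s1 <- sp + k - 1L; q1 <- qi + k - 1L
      while (s1 < ns && q1 < nq && sub_raw[s1 + 1L] == q_raw[q1 + 1L]) { s1 <- s1 + 1L; q1 <- q1 + 1L }
      if (s1 - s0 + 1L >= minlen)
        hits[[length(hits) + 1L]] <- c(s0 - 1L, s1)  # 0-based half-open
    }
  }
  if (!length(hits)) return(out)
  m <- unique(do.call(rbind, hits))
  data.frame(start = m[, 1], end = m[, 2])
}

# DUST-style low-complexity windows: triplet-count score per sliding window,
# step 8; windows over threshold masked in full. 0-based half-open.
dust_intervals <- function(seq, window, threshold) {
  n <- nchar(seq)
  out <- data.frame(start = integer(), end = integer())
  if (n < 3L) return(out)
  w <- min(window, n)
  starts <- if (n <= w) 0L else unique(c(seq(0L, n - w, by = 8L), n - w))
  bad <- logical(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    bad[i] <- dust_score(substr(seq, s + 1L, s + w)) > threshold
  }
  if (!any(bad)) return(out)
  data.frame(start = starts[bad], end = pmin(starts[bad] + w, n))
}

# score = sum c_t(c_t-1)/2 / (k-1) over overlapping triplet counts
dust_score <- function(s) {
  k <- nchar(s) - 2L
  if (k < 2L) return(0)
  trip <- substring(s, 1:k, 3:(k + 2L))
  trip <- trip[!grepl("N", trip, fixed = TRUE)]
  k <- length(trip)
  if (k < 2L) return(0)
  cnt <- table(trip)
  sum(cnt * (cnt - 1) / 2) / (k - 1)
}

# merge overlapping/adjacent intervals; tag of earliest-starting contributor wins
merge_intervals <- function(df) {
  df <- df[order(df$start, df$end), , drop = FALSE]
  if (nrow(df) <= 1L) { rownames(df) <- NULL; return(df) }
  out <- df[1, , drop = FALSE]
  for (i in 2:nrow(df)) {
    j <- nrow(out)
    if (df$start[i] <= out$end[j]) {
      out$end[j] <- max(out$end[j], df$end[i])
    } else {
      out <- rbind(out, df[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}
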