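#' Scoring parameters for probe candidates
#'
#' Surrogate base-composition scoring: penalties for GC deviation from a
#' target fraction, for homopolymer runs beyond a cap, and for distance from
#' the 3' end. Weights are declared configuration, reported in output
#' metadata.
#'
#' @param gc_target target GC fraction.
#' @param gc_weight,homopolymer_weight,position_weight non-negative penalty
#'   weights.
#' @param max_homopolymer longest un-penalized homopolymer run (nt).
#' @param score_floor minimum acceptable score; candidates all below it give
#'   a \code{design_fail} gene.
#' @return object of class \code{scoring_params}.
#' @export
scoring_params <- function(gc_target = 0.45, gc_weight = 1, homopolymer_weight = 0.1,
                           position_weight = 0.25, max_homopolymer = 6L,
                           score_floor = -1) {
  stopifnot(gc_target > 0, gc_target < 1, gc_weight >= 0,
            homopolymer_weight >= 0, position_weight >= 0, max_homopolymer >= 1)
  structure(list(gc_target = gc_target, gc_weight = gc_weight,
                 homopolymer_weight = homopolymer_weight,
                 position_weight = position_weight,
                 max_homopolymer = as.integer(max_homopolymer),
                 score_floor = score_floor),
            class = "scoring_params")
}

#' Cross-hybridization screen parameters
#'
#' @param seed_length exact k-mer seed length (nt).
#' @param flag_exact_run contiguous exact match length that flags a probe.
#' @param flag_identity matching positions (out of 60) in the best ungapped
#'   alignment that flag a probe.
#' @return object of class \code{xhyb_params}.
#' @export
xhyb_params <- function(seed_length = 15L, flag_exact_run = 25L, flag_identity = 45L) {
  stopifnot(seed_length <= flag_exact_run, flag_exact_run <= 60L, flag_identity <= 60L)
  structure(list(seed_length = as.integer(seed_length),
                 flag_exact_run = as.integer(flag_exact_run),
                 flag_identity = as.integer(flag_identity)),
            class = "xhyb_params")
}

#' Enumerate 3'-anchored probe candidates on a masked sequence
#'
#' All probe-length windows that lie entirely within the last
#' \code{min(length, window)} nt of the transcript and overlap no masked
#' base. Starts are 0-based.
#'
#' @param ms a \code{masked_sequence} (the gene's representative transcript).
#' @param window 3' window size in nt.
#' @param probe_len probe length in nt.
#' @return data frame with columns \code{start}, \code{sequence},
#'   \code{distance_to_3prime}; zero rows when nothing survives.
#' @export
enumerate_candidates <- function(ms, window = 1000L, probe_len = 60L) {
  stopifnot(inherits(ms, "masked_sequence"), probe_len >= 1L)
  n <- ms$length
  if (n < probe_len)
    return(data.frame(start = integer(), sequence = character(),
                      distance_to_3prime = integer()))
  lo <- max(0L, n - as.integer(window))     # window start, 0-based
  starts <- lo:(n - probe_len)
  if (nrow(ms$masked)) {
    ok <- rep(TRUE, length(starts))
    for (i in seq_len(nrow(ms$masked))) {
      # candidate [s, s+probe_len) overlaps mask [a, b) iff s < b and s+probe_len > a
      ok <- ok & !(starts < ms$masked$end[i] & (starts + probe_len) > ms$masked$start[i])
    }
    starts <- starts[ok]
  }
  if (!length(starts))
    return(data.frame(start = integer(), sequence = character(),
                      distance_to_3prime = integer()))
  data.frame(start = starts,
             sequence = substring(ms$sequence, starts + 1L, starts + probe_len),
             distance_to_3prime = n - (starts + probe_len))
}

#' Score a probe candidate
#'
#' score = -gc_weight*|GC - gc_target|
#'         - homopolymer_weight*max(0, longest_run - max_homopolymer)
#'         - position_weight*(distance_to_3prime/window).
#' A perfect candidate (on-target GC, no long runs, at the 3' terminus)
#' scores 0, the maximum.
#'
#' @param sequence probe sequence (or vector of sequences).
#' @param distance_to_3prime distance from probe end to transcript 3' end (nt).
#' @param params \code{scoring_params}.
#' @param window 3' window size used for the positional term.
#' @return numeric score(s), <= 0.
#' @export
score_candidate <- function(sequence, distance_to_3prime, params = scoring_params(),
                            window = 1000L) {
  gc <- gc_fraction(sequence)
  runs <- longest_run(sequence)
  -params$gc_weight * abs(gc - params$gc_target) -
    params$homopolymer_weight * pmax(0L, runs - params$max_homopolymer) -
    params$position_weight * (distance_to_3prime / window)
}

gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  gc / n
}

longest_run <- function(x) {
  vapply(x, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

#' Design one probe per gene with a full exclusion ledger
#'
#' Per gene, in order: \code{too_short} if the representative is shorter than
#' the probe length; \code{masked} if no candidate survives enumeration;
#' \code{design_fail} if no candidate reaches \code{score_floor}; otherwise
#' the top-scoring candidate is selected (ties broken by smallest start).
#' After selection, any gene whose chosen 60-mer is identical to an earlier
#' gene's (gene_id order) is reclassified \code{duplicate}; the first keeper
#' is retained.
#'
#' @param genes \code{gene_models} data frame (from
#'   \code{\link{collapse_to_genes}}).
#' @param masks named list of \code{masked_sequence}, one per gene_id; by
#'   default each representative is masked with \code{\link{mask_sequence}}
#'   and no vector library.
#' @param params \code{scoring_params}.
#' @param window,probe_len 3' window and probe length (nt).
#' @param vectors vector library used when \code{masks} is NULL.
#' @return object of class \code{probe_set}: data frame with columns
#'   \code{probe_id}, \code{gene_id}, \code{transcript_id}, \code{start},
#'   \code{sequence}, \code{score}, \code{status}, \code{xhyb_flag};
#'   attribute \code{accounting} (see \code{\link{design_accounting}}) and
#'   \code{params}.
#' @export
design_probes <- function(genes, masks = NULL, params = scoring_params(),
                          window = 1000L, probe_len = 60L, vectors = character()) {
  if (!nrow(genes)) {
    out <- data.frame(probe_id = character(), gene_id = character(),
                      transcript_id = character(), start = integer(),
                      sequence = character(), score = numeric(),
                      status = character(), xhyb_flag = logical())
    return(new_probe_set(out, params))
  }
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  n <- nrow(genes)
  status <- character(n); start <- rep(NA_integer_, n)
  seqs <- rep(NA_character_, n); score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rep_len <- genes$length[i]
    if (rep_len < probe_len) { status[i] <- "too_short"; next }
    ms <- if (!is.null(masks)) masks[[genes$gene_id[i]]] else
      mask_sequence(genes$sequence[i], vectors = vectors)
    if (is.null(ms)) stop("no mask supplied for gene ", genes$gene_id[i])
    cand <- enumerate_candidates(ms, window = window, probe_len = probe_len)
    if (!nrow(cand)) { status[i] <- "masked"; next }
    sc <- score_candidate(cand$sequence, cand$distance_to_3prime, params, window)
    if (max(sc) < params$score_floor) { status[i] <- "design_fail"; next }
    best <- which(sc == max(sc))
    pick <- best[which.min(cand$start[best])]
    status[i] <- "designed"
    start[i] <- cand$start[pick]; seqs[i] <- cand$sequence[pick]; score[i] <- sc[pick]
  }
  # duplicates: identical selected 60-mer to an earlier gene (gene_id order)
  des <- which(status == "designed")
  dup <- des[duplicated(seqs[des])]
  status[dup] <- "duplicate"
  out <- data.frame(
    probe_id = ifelse(status == "designed", paste0("PR_", genes$gene_id), NA_character_),
    gene_id = genes$gene_id,
    transcript_id = genes$transcript_id,
    start = start, sequence = seqs, score = score,
    status = status, xhyb_flag = FALSE,
    stringsAsFactors = FALSE
  )
  out$sequence[out$status != "designed"] <- NA_character_
  rownames(out) <- NULL
  new_probe_set(out, params)
}

new_probe_set <- function(df, params = NULL) {
  class(df) <- c("probe_set", "data.frame")
  attr(df, "accounting") <- design_accounting(df)
  attr(df, "params") <- params
  df
}

#' @export
print.probe_set <- function(x, ...) {
  a <- attr(x, "accounting")
  cat("probe_set:", a$submitted, "genes submitted,", a$designed, "probes designed",
      sprintf("(too_short %d, duplicate %d, masked %d, design_fail %d), %d x-hyb flagged\n",
              a$too_short, a$duplicate, a$masked, a$design_fail,
              sum(x$xhyb_flag, na.rm = TRUE)))
  invisible(x)
}

#' Exclusion accounting for a probe design
#'
#' Counts probes by status and enforces the ledger identity
#' submitted == designed + too_short + duplicate + masked + design_fail.
#'
#' @param probes \code{probe_set} or data frame with a \code{status} column.
#' @return object of class \code{design_accounting}: list with counts
#'   \code{submitted}, \code{designed}, \code{too_short}, \code{duplicate},
#'   \code{masked}, \code{design_fail}.
#' @export
design_accounting <- function(probes) {
  known <- c("designed", "too_short", "duplicate", "masked", "design_fail")
  st <- probes$status
  if (length(st) && any(!st %in% known))
    stop("unknown probe status: ", paste(setdiff(unique(st), known), collapse = ", "))
  cnt <- vapply(known, function(k) sum(st == k), integer(1))
  acc <- c(list(submitted = length(st)), as.list(cnt))
  stopifnot(acc$submitted == acc$designed + acc$too_short + acc$duplicate +
              acc$masked + acc$design_fail)
  structure(acc, class = "design_accounting")
}

#' Assemble accounting from pre-tabulated exclusion counts
#'
#' The companion constructor for published design arithmetic: given the
#' number of submitted sequences and the per-reason exclusion counts, the
#' number of designed probes is implied by the ledger identity.
#'
#' @param submitted number of gene models submitted to design.
#' @param too_short,duplicate,masked,design_fail exclusion counts.
#' @return \code{design_accounting} with \code{designed} computed as
#'   submitted minus the exclusions.
#' @export
accounting_from_counts <- function(submitted, too_short = 0L, duplicate = 0L,
                                   masked = 0L, design_fail = 0L) {
  stopifnot(submitted >= too_short + duplicate + masked + design_fail)
  designed <- submitted - (too_short + duplicate + masked + design_fail)
  structure(list(submitted = as.integer(submitted), designed = as.integer(designed),
                 too_short = as.integer(too_short), duplicate = as.integer(duplicate),
                 masked = as.integer(masked), design_fail = as.integer(design_fail)),
            class = "design_accounting")
}

#' @export
print.design_accounting <- function(x, ...) {
  cat(sprintf(paste0("design accounting: %d submitted -> %d designed ",
                     "(too_short %d, duplicate %d, masked %d, design_fail %d)\n"),
              x$submitted, x$designed, x$too_short, x$duplicate, x$masked,
              x$design_fail))
  invisible(x)
}

#' Screen designed probes for cross-hybridization potential
#'
#' Seed-and-extend screen of every designed probe against all transcripts of
#' other genes. A probe is flagged iff, against some transcript of a
#' different gene, it has (a) an exact contiguous match of at least
#' \code{flag_exact_run} nt, or (b) at least \code{flag_identity} matching
#' positions in the best ungapped full-probe alignment reachable from an
#' exact \code{seed_length}-mer seed. Same-gene isoforms never trigger flags.
#'
#' @param probes \code{probe_set}.
#' @param ts \code{transcript_set} the probes were designed against.
#' @param params \code{xhyb_params}.
#' @return the probe set with \code{xhyb_flag} updated.
#' @export
cross_hyb_screen <- function(probes, ts, params = xhyb_params()) {
  des <- which(probes$status == "designed")
  if (!length(des)) return(probes)
  k <- params$seed_length
  tx_seq <- ts$sequence; tx_gene <- ts$gene_id
  tx_raw <- lapply(tx_seq, charToRaw)
  # k-mer index over all transcripts: kmer -> (transcript, pos) pairs
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (t in seq_along(tx_seq)) {
    nt <- nchar(tx_seq[t])
    if (nt < k) next
    km <- substring(tx_seq[t], 1:(nt - k + 1L), k:nt)
    for (p in seq_along(km)) {
      key <- km[p]
      idx[[key]] <- rbind(get0(key, envir = idx), c(t, p))
    }
  }
  flag <- probes$xhyb_flag
  for (i in des) {
    pseq <- probes$sequence[i]
    praw <- charToRaw(pseq)
    plen <- length(praw)
    pk <- substring(pseq, 1:(plen - k + 1L), k:plen)
    offsets_seen <- new.env(hash = TRUE, parent = emptyenv())
    hit <- FALSE
    for (qi in seq_along(pk)) {
      locs <- get0(pk[qi], envir = idx)
      if (is.null(locs)) next
      for (r in seq_len(nrow(locs))) {
        t <- locs[r, 1]
        if (tx_gene[t] == probes$gene_id[i]) next
        o <- locs[r, 2] - qi            # alignment offset: probe pos j ~ transcript pos j+o
        key <- paste0(t, ":", o)
        if (!is.null(get0(key, envir = offsets_seen))) next
        assign(key, TRUE, envir = offsets_seen)
        st <- alignment_stats(praw, tx_raw[[t]], o)
        if (st["run"] >= params$flag_exact_run || st["matches"] >= params$flag_identity) {
          hit <- TRUE; break
        }
      }
      if (hit) break
    }
    flag[i] <- hit
  }
  probes$xhyb_flag <- flag
  attr(probes, "accounting") <- design_accounting(probes)
  probes
}

# matches and longest exact run of probe vs transcript at a fixed ungapped
# offset o (probe position j aligns to transcript position j + o; 1-based)
alignment_stats <- function(praw, traw, o) {
  plen <- length(praw); tlen <- length(traw)
  j0 <- max(1L, 1L - o); j1 <- min(plen, tlen - o)
  if (j1 < j0) return(c(matches = 0L, run = 0L))
  eq <- praw[j0:j1] == traw[(j0:j1) + o]
  r <- rle(eq)
  run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  c(matches = sum(eq), run = run)
}

#' Write a probe design table
#'
#' @param probes \code{probe_set}
#' @param path output TSV path
#' @export
write_probe_table <- function(probes, path) {
  utils::write.table(as.data.frame(probes), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probe design table written by \code{\link{write_probe_table}}
#'
#' @param path TSV path
#' @return \code{probe_set}
#' @export
read_probe_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$xhyb_flag <- as.logical(df$xhyb_flag)
  new_probe_set(df)
}
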