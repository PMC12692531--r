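#' Parameters for the synthetic transcriptome generator
#'
#' Defaults emulate an isoform-rich, partially duplicated transcriptome:
#' genes carry two to fourteen isoforms with distinct exon composition,
#' high-identity paralog families mimic globin-like duplicates, transcripts
#' end in poly(A), and a small fraction of exons carry injected
#' vector/repeat contamination. Biotype frequencies follow a landscape
#' dominated by mRNA with minor ncRNA/miscRNA classes.
#'
#' @param n_genes number of ordinary (non-paralog-family) genes.
#' @param isoform_range integer range of isoform counts per gene, within
#'   [1, 14].
#' @param n_paralog_families,paralog_family_size,paralog_identity paralog
#'   family count, members per family, and per-member sequence identity to
#'   the family seed.
#' @param polyA_length poly(A) tail length appended to each gene's 3' exon.
#' @param vector_injection_rate,repeat_injection_rate per-gene probability
#'   of an injected vector / low-complexity segment.
#' @param biotype_probs probabilities for mRNA/ncRNA/miscRNA gene classes.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return object of class \code{synthetic_transcriptome_params}.
#' @export
synthetic_transcriptome_params <- function(n_genes = 50L, isoform_range = c(2L, 14L),
                                           n_paralog_families = 2L,
                                           paralog_family_size = 3L,
                                           paralog_identity = 0.92,
                                           polyA_length = 30L,
                                           vector_injection_rate = 0.05,
                                           repeat_injection_rate = 0.05,
                                           biotype_probs = c(mRNA = 0.8703,
                                                             ncRNA = 0.1262,
                                                             miscRNA = 0.0035),
                                           seed = 1L) {
  stopifnot(isoform_range[1] >= 1L, isoform_range[2] <= 14L,
            isoform_range[1] <= isoform_range[2],
            paralog_identity > 0, paralog_identity <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 isoform_range = as.integer(isoform_range),
                 n_paralog_families = as.integer(n_paralog_families),
                 paralog_family_size = as.integer(paralog_family_size),
                 paralog_identity = paralog_identity,
                 polyA_length = as.integer(polyA_length),
                 vector_injection_rate = vector_injection_rate,
                 repeat_injection_rate = repeat_injection_rate,
                 biotype_probs = biotype_probs,
                 seed = as.integer(seed)),
            class = "synthetic_transcriptome_params")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

mutate_sequence <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) {
    alt <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(alt, b), 1L), character(1))
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic transcriptome as FASTA + GFF3
#'
#' Writes one contig per gene (plus-strand gene models), with isoforms built
#' as exon subsets that share the gene's 3'-terminal exon (so the probe
#' target region is common to all isoforms), paralog families produced by
#' mutating a family seed to the target identity, poly(A) appended to the
#' terminal exon, and vector / low-complexity segments injected into a
#' random exon at the stated per-gene rates.
#'
#' @param params \code{\link{synthetic_transcriptome_params}}.
#' @param dir output directory (created if needed).
#' @return list with \code{fasta}, \code{gff} (paths), \code{vectors}
#'   (the injected vector library), and \code{genes} (data frame gene_id,
#'   n_isoforms, biotype, family, vector_injected, repeat_injected).
#' @export
generate_transcriptome <- function(params = synthetic_transcriptome_params(),
                                   dir = tempfile("synthtx")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(params$seed)
  vectors <- c(vec1 = random_dna(120L), vec2 = random_dna(150L))

  fasta <- file.path(dir, "transcriptome.fasta")
  gff <- file.path(dir, "transcriptome.gff3")
  fa_lines <- character(); gff_lines <- "##gff-version 3"
  gene_rows <- list()

  n_fam_genes <- params$n_paralog_families * params$paralog_family_size
  total <- params$n_genes + n_fam_genes
  fam_of <- c(rep(NA_integer_, params$n_genes),
              rep(seq_len(params$n_paralog_families), each = params$paralog_family_size))
  fam_seed_seq <- replicate(params$n_paralog_families,
                            random_dna(900L + sample.int(300L, 1L)))

  for (g in seq_len(total)) {
    gid <- sprintf("gene%04d", g)
    fam <- fam_of[g]
    biotype <- sample(names(params$biotype_probs), 1L, prob = params$biotype_probs)
    if (is.na(fam)) {
      n_iso <- sample(params$isoform_range[1]:params$isoform_range[2], 1L)
      n_ex <- sample(3:8, 1L)
      exons <- vapply(seq_len(n_ex), function(i) random_dna(sample(100:400, 1L)),
                      character(1))
    } else {
      # paralog family member: single-exon gene mutated from the family seed
      n_iso <- 1L
      base <- fam_seed_seq[[fam]]
      member_idx <- (g - params$n_genes - 1L) %% params$paralog_family_size
      exons <- if (member_idx == 0L) base else
        mutate_sequence(base, 1 - params$paralog_identity)
      n_ex <- 1L
      biotype <- "mRNA"
    }
    vector_injected <- is.na(fam) && stats::runif(1) < params$vector_injection_rate
    repeat_injected <- is.na(fam) && stats::runif(1) < params$repeat_injection_rate
    if (vector_injected) {
      ex <- sample.int(n_ex, 1L)
      at <- sample.int(nchar(exons[ex]), 1L)
      v <- vectors[[sample.int(length(vectors), 1L)]]
      exons[ex] <- paste0(substr(exons[ex], 1L, at), v,
                          substr(exons[ex], at + 1L, nchar(exons[ex])))
    }
    if (repeat_injected) {
      ex <- sample.int(n_ex, 1L)
      run <- paste(rep(sample(c("A", "AT", "CA"), 1L), 60L), collapse = "")
      at <- sample.int(nchar(exons[ex]), 1L)
      exons[ex] <- paste0(substr(exons[ex], 1L, at), run,
                          substr(exons[ex], at + 1L, nchar(exons[ex])))
    }
    # poly(A) on the terminal exon: shared 3' end across isoforms
    exons[n_ex] <- paste0(exons[n_ex], strrep("A", params$polyA_length))

    introns <- if (n_ex > 1L) vapply(seq_len(n_ex - 1L),
                                     function(i) random_dna(sample(60:200, 1L)),
                                     character(1)) else character()
    contig <- paste0("ctg_", gid)
    pieces <- character(2L * n_ex - 1L)
    pieces[seq(1L, by = 2L, length.out = n_ex)] <- exons
    if (n_ex > 1L) pieces[seq(2L, by = 2L, length.out = n_ex - 1L)] <- introns
    contig_seq <- paste(pieces, collapse = "")
    ex_len <- nchar(exons); in_len <- if (n_ex > 1L) nchar(introns) else integer()
    ex_start <- integer(n_ex); pos <- 1L
    for (i in seq_len(n_ex)) {
      ex_start[i] <- pos
      pos <- pos + ex_len[i] + if (i < n_ex) in_len[i] else 0L
    }
    ex_end <- ex_start + ex_len - 1L

    fa_lines <- c(fa_lines, paste0(">", contig),
                  substring(contig_seq, seq(1L, nchar(contig_seq), 70L),
                            pmin(seq(1L, nchar(contig_seq), 70L) + 69L,
                                 nchar(contig_seq))))
    tx_type <- switch(biotype, mRNA = "mRNA", ncRNA = "ncRNA", miscRNA = "misc_RNA")
    gff_lines <- c(gff_lines, sprintf(
      "%s\tsynth\tgene\t%d\t%d\t.\t+\t.\tID=%s", contig, 1L, ex_end[n_ex], gid))
    # isoforms: distinct exon subsets, each containing the terminal exon
    subsets <- unique_isoform_subsets(n_ex, n_iso)
    for (k in seq_along(subsets)) {
      tid <- sprintf("%s.t%02d", gid, k)
      keep <- subsets[[k]]
      gff_lines <- c(gff_lines, sprintf(
        "%s\tsynth\t%s\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
        contig, tx_type, ex_start[keep[1]], ex_end[n_ex], tid, gid))
      gff_lines <- c(gff_lines, sprintf(
        "%s\tsynth\texon\t%d\t%d\t.\t+\t.\tParent=%s",
        contig, ex_start[keep], ex_end[keep], tid))
    }
    gene_rows[[g]] <- data.frame(gene_id = gid, n_isoforms = length(subsets),
                                 biotype = biotype,
                                 family = ifelse(is.na(fam), NA_character_,
                                                 paste0("fam", fam)),
                                 vector_injected = vector_injected,
                                 repeat_injected = repeat_injected,
                                 stringsAsFactors = FALSE)
  }
  writeLines(fa_lines, fasta)
  writeLines(gff_lines, gff)
  list(fasta = fasta, gff = gff, vectors = vectors,
       genes = do.call(rbind, gene_rows))
}

# up to n_iso distinct exon subsets of 1..n_ex, all containing exon n_ex,
# always including the full model; ordered by decreasing size
unique_isoform_subsets <- function(n_ex, n_iso) {
  subsets <- list(seq_len(n_ex))
  if (n_ex == 1L) return(subsets)
  tries <- 0L
  while (length(subsets) < n_iso && tries < 50L * n_iso) {
    tries <- tries + 1L
    k <- sample.int(n_ex - 1L, 1L)               # exons dropped
    drop <- sample.int(n_ex - 1L, k)             # never the terminal exon
    cand <- setdiff(seq_len(n_ex), drop)
    if (!any(vapply(subsets, identical, logical(1), y = cand)))
      subsets[[length(subsets) + 1L]] <- cand
  }
  subsets
}

#' Simulate a feature-extraction style scan of one subarray
#'
#' The foreground signal of a feature with true log2 expression x is
#' gain * 2^(x + e), e ~ N(0, sd_log2), plus a background draw; background
#' statistics come from a truncated-Gaussian background model. Processed
#' signal is foreground minus background floored at a small positive value.
#' Adverse flags are injected at the stated rates. Deterministic given
#' \code{seed}.
#'
#' @param layout data frame of one subarray's features (columns
#'   \code{position}, \code{feature_class}, \code{probe_id}).
#' @param truth list with \code{expr_green} (named: probe_id -> true log2
#'   expression, green), optional \code{expr_red} (two-channel),
#'   \code{spike_logratio} (named: spike-in level "L01".. -> expected log2
#'   red/green ratio), \code{spike_base} (green log2 level of spike-ins),
#'   \code{control_base} (log2 level of stringency/corner features).
#' @param noise list: \code{bg_mean}, \code{bg_sd}, \code{sd_log2}.
#' @param flag_rates list: \code{nonunif}, \code{popn}, \code{saturated}.
#' @param gain scanner gain.
#' @param array_id identifier stored in the table.
#' @param seed integer seed.
#' @return FE-style data frame (one row per feature) with g* and, for
#'   two-channel truth, r* column sets.
#' @export
simulate_scan <- function(layout, truth,
                          noise = list(bg_mean = 100, bg_sd = 15, sd_log2 = 0.25),
                          flag_rates = list(nonunif = 0, popn = 0, saturated = 0),
                          gain = 1, array_id = "array1", seed = 1L) {
  set.seed(seed)
  n <- nrow(layout)
  cls <- layout$feature_class
  ids <- layout$probe_id
  bio <- cls %in% c("biological", "replicate")
  miss <- setdiff(unique(ids[bio]), names(truth$expr_green))
  if (length(miss)) stop("missing truth for probe(s): ", paste(utils::head(miss, 5), collapse = ", "))
  spike_level <- ifelse(cls == "spikein", sub("^E1A_r60_(L[0-9]+)_.*$", "\\1", ids),
                        NA_character_)
  control_base <- if (!is.null(truth$control_base)) truth$control_base else 5
  spike_base <- if (!is.null(truth$spike_base)) truth$spike_base else 10

  true_g <- numeric(n)
  true_g[bio] <- truth$expr_green[ids[bio]]
  true_g[cls == "spikein"] <- spike_base
  true_g[cls %in% c("stringency", "corner")] <- control_base

  two_channel <- !is.null(truth$expr_red)
  if (two_channel) {
    true_r <- numeric(n)
    true_r[bio] <- truth$expr_red[ids[bio]]
    sl <- truth$spike_logratio
    lev <- spike_level[cls == "spikein"]
    if (!is.null(sl) && !all(lev %in% names(sl)))
      stop("spike_logratio missing level(s): ",
           paste(setdiff(unique(lev), names(sl)), collapse = ", "))
    true_r[cls == "spikein"] <- spike_base + if (!is.null(sl)) sl[lev] else 0
    true_r[cls %in% c("stringency", "corner")] <- control_base
  }

  channel_block <- function(true_log2, prefix) {
    fg <- gain * 2^(true_log2 + stats::rnorm(n, 0, noise$sd_log2))
    bg_med <- pmax(1, stats::rnorm(n, noise$bg_mean, noise$bg_sd / 3))
    bg_sd <- noise$bg_sd * stats::runif(n, 0.8, 1.2)
    med <- fg + bg_med
    proc <- pmax(med - bg_med, 0.5)
    snr <- (med - bg_med) / bg_sd
    out <- data.frame(
      a = med, b = bg_med, c = bg_sd, d = proc,
      e = as.integer(snr >= 2.6), f = as.integer(snr >= 2.0),
      g = as.integer(stats::runif(n) < flag_rates$nonunif),
      h = as.integer(stats::runif(n) < flag_rates$popn),
      i = as.integer(stats::runif(n) < flag_rates$saturated)
    )
    names(out) <- paste0(prefix, c("MedianSignal", "BGMedianSignal", "BGPixSDev",
                                   "ProcessedSignal", "IsWellAboveBG",
                                   "IsPosAndSignif", "IsFeatNonUnifOL",
                                   "IsFeatPopnOL", "IsSaturated"))
    out
  }
  res <- cbind(data.frame(ProbeName = ids, feature_class = cls,
                          stringsAsFactors = FALSE),
               channel_block(true_g, "g"))
  if (two_channel) res <- cbind(res, channel_block(true_r, "r"))
  attr(res, "array_id") <- array_id
  res
}

#' Write a simulated scan as a feature-extraction style TSV
#'
#' @param scan data frame from \code{\link{simulate_scan}}.
#' @param path output TSV path.
#' @export
write_fe_table <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fabricate_probe_set <- function(n_probes, seed = 1L) {
  set.seed(seed)
  df <- data.frame(
    probe_id = sprintf("PR_%05d", seq_len(n_probes)),
    gene_id = sprintf("gene%05d", seq_len(n_probes)),
    transcript_id = sprintf("gene%05d.t01", seq_len(n_probes)),
    start = 0L,
    sequence = vapply(seq_len(n_probes), function(i) random_dna(60L), character(1)),
    score = 0, status = "designed", xhyb_flag = FALSE,
    stringsAsFactors = FALSE
  )
  new_probe_set(df)
}

preset_layout <- function(n_probes, seed) {
  probes <- fabricate_probe_set(n_probes, seed)
  cm <- control_manifest(control_count = 132L, spike_levels = 10L, n_corner = 4L)
  spec <- layout_spec(subarrays = 1L,
                      features_per_subarray = n_probes + 200L + nrow(cm),
                      control_count = nrow(cm),
                      replicate_probe_count = 20L, replicate_copies = 10L,
                      seed = seed, control_manifest = cm)
  list(probes = probes, layout = build_layout(probes, spec), spec = spec)
}

#' Self-self dye-balance preset
#'
#' End-to-end fixture for the dye-balance design: the same pool labeled in
#' both channels and co-hybridized on \code{n_arrays} subarrays. Biological
#' truth is identical in both channels (no dye effect); spike-in features
#' follow their declared expected inter-channel log ratios (10 levels
#' spanning -2..+2).
#'
#' @param n_arrays number of self-self arrays.
#' @param n_probes biological probes on the (synthetic-scale) array.
#' @param noise,flag_rates see \code{\link{simulate_scan}}.
#' @param seed integer seed.
#' @return list with \code{layout}, \code{truth}, \code{scans} (one
#'   FE-style data frame per array), \code{spec}.
#' @export
preset_selfself <- function(n_arrays = 3L, n_probes = 5000L,
                            noise = list(bg_mean = 100, bg_sd = 15, sd_log2 = 0.25),
                            flag_rates = list(nonunif = 0, popn = 0, saturated = 0),
                            seed = 1L) {
  pl <- preset_layout(n_probes, seed)
  set.seed(seed + 1L)
  expr <- stats::rnorm(n_probes, 10, 1.5)
  names(expr) <- pl$probes$probe_id
  truth <- list(expr_green = expr, expr_red = expr,
                spike_logratio = stats::setNames(seq(-2, 2, length.out = 10),
                                                 sprintf("L%02d", 1:10)),
                spike_base = 10, control_base = 5)
  scans <- lapply(seq_len(n_arrays), function(k)
    simulate_scan(pl$layout, truth, noise, flag_rates,
                  array_id = paste0("selfself_", k), seed = seed + 10L + k))
  names(scans) <- vapply(scans, attr, character(1), "array_id")
  list(layout = pl$layout, truth = truth, scans = scans, spec = pl$spec)
}

#' Two-isolation reproducibility preset
#'
#' End-to-end fixture for the isolation-reproducibility design: two RNA
#' isolations of the same pool, each hybridized single-channel on
#' \code{n_per_group} subarrays. Exactly \code{shifted_probes} probes carry
#' an injected expression shift of \code{shift_log2} log2 units in
#' isolation 2; all other probes are null.
#'
#' @param n_per_group arrays per isolation.
#' @param shifted_probes number of truly shifted probes.
#' @param shift_log2 injected shift (log2 units) in isolation 2.
#' @param n_probes biological probes on the array.
#' @param noise,flag_rates see \code{\link{simulate_scan}}.
#' @param seed integer seed.
#' @return list with \code{layout}, \code{truth} (including
#'   \code{shifted_ids}), \code{scans_iso1}, \code{scans_iso2}, \code{spec}.
#' @export
preset_two_isolations <- function(n_per_group = 8L, shifted_probes = 12L,
                                  shift_log2 = 1.23, n_probes = 5000L,
                                  noise = list(bg_mean = 100, bg_sd = 15,
                                               sd_log2 = 0.25),
                                  flag_rates = list(nonunif = 0, popn = 0,
                                                    saturated = 0),
                                  seed = 1L) {
  pl <- preset_layout(n_probes, seed)
  set.seed(seed + 1L)
  base <- stats::rnorm(n_probes, 10, 1.5)
  names(base) <- pl$probes$probe_id
  shifted_ids <- sample(pl$probes$probe_id, shifted_probes)
  expr2 <- base
  expr2[shifted_ids] <- expr2[shifted_ids] + shift_log2
  truth1 <- list(expr_green = base, spike_base = 10, control_base = 5)
  truth2 <- list(expr_green = expr2, spike_base = 10, control_base = 5)
  scans1 <- lapply(seq_len(n_per_group), function(k)
    simulate_scan(pl$layout, truth1, noise, flag_rates,
                  array_id = paste0("iso1_", k), seed = seed + 100L + k))
  scans2 <- lapply(seq_len(n_per_group), function(k)
    simulate_scan(pl$layout, truth2, noise, flag_rates,
                  array_id = paste0("iso2_", k), seed = seed + 200L + k))
  names(scans1) <- vapply(scans1, attr, character(1), "array_id")
  names(scans2) <- vapply(scans2, attr, character(1), "array_id")
  list(layout = pl$layout,
       truth = list(expr_iso1 = base, expr_iso2 = expr2,
                    shifted_ids = shifted_ids, shift_log2 = shift_log2),
       scans_iso1 = scans1, scans_iso2 = scans2, spec = pl$spec)
}

#' Collapse simulated scans to a probe x array signal matrix
#'
#' Means of the processed signal over a probe's spots on each array, for
#' biological and replicate features.
#'
#' @param scans list of FE-style data frames (one per array).
#' @param channel \code{"green"} or \code{"red"}.
#' @return numeric matrix probes x arrays of processed signals.
#' @export
scans_to_matrix <- function(scans, channel = c("green", "red")) {
  channel <- match.arg(channel)
  col <- if (channel == "green") "gProcessedSignal" else "rProcessedSignal"
  per_array <- lapply(scans, function(sc) {
    keep <- sc$feature_class %in% c("biological", "replicate")
    tapply(sc[[col]][keep], sc$ProbeName[keep], mean)
  })
  ids <- sort(unique(unlist(lapply(per_array, names))))
  m <- vapply(per_array, function(v) v[ids], numeric(length(ids)))
  rownames(m) <- ids
  colnames(m) <- names(scans)
  m
}

#' LOWESS-corrected M matrix from two-channel self-self scans
#'
#' Per array: collapse spots per probe in each channel, log2-transform, and
#' return the LOWESS-corrected M values for biological, replicate and
#' spike-in features.
#'
#' @param scans list of two-channel FE-style data frames.
#' @param span,iter LOWESS settings.
#' @return list with \code{M} (features x arrays matrix of corrected M) and
#'   \code{feature_class} (per feature).
#' @export
selfself_m_matrix <- function(scans, span = 0.3, iter = 3L) {
  one <- function(sc) {
    keep <- sc$feature_class %in% c("biological", "replicate", "spikein")
    g <- tapply(sc$gProcessedSignal[keep], sc$ProbeName[keep], mean)
    r <- tapply(sc$rProcessedSignal[keep], sc$ProbeName[keep], mean)
    cls <- tapply(sc$feature_class[keep], sc$ProbeName[keep], function(x) x[1])
    ids <- sort(names(g))
    ma <- lowess_ma_normalize(log2(g[ids]), log2(r[ids]), span = span, iter = iter)
    list(m = stats::setNames(ma$M_corrected, ids), cls = cls[ids])
  }
  parts <- lapply(scans, one)
  ids <- names(parts[[1]]$m)
  M <- vapply(parts, function(p) p$m[ids], numeric(length(ids)))
  rownames(M) <- ids
  colnames(M) <- names(scans)
  list(M = M, feature_class = unname(parts[[1]]$cls[ids]))
}
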