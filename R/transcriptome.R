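#' Load a transcriptome from FASTA + GFF3/GTF
#'
#' Reads genomic sequences and an annotation, assembles the spliced sequence
#' of every annotated transcript (exons concatenated in genomic order,
#' reverse-complemented for minus-strand transcripts) and returns a
#' \code{transcript_set}: a data frame with one row per transcript and a
#' gene index attribute.
#'
#' Annotation intervals are interpreted 1-based inclusive (GFF3 convention).
#' Transcripts lacking a gene parent are kept as single-isoform genes with
#' \code{gene_id == transcript_id}. Biotype is read from the annotation
#' (transcript/gene biotype attribute, falling back on the feature type of
#' the transcript record); the default class is \code{"mRNA"}.
#'
#' @param fasta_path path to a (multi-record, possibly line-wrapped) FASTA
#'   file of genomic or contig sequences.
#' @param annotation_path path to a GFF3 (\code{.gff}/\code{.gff3}) or GTF
#'   (\code{.gtf}) annotation declaring the gene/transcript/exon hierarchy.
#' @return An object of class \code{transcript_set}: a data frame with
#'   columns \code{transcript_id}, \code{gene_id}, \code{sequence},
#'   \code{length}, \code{biotype}, and attribute \code{gene_index}
#'   (named list gene_id -> transcript ids).
#' @export
load_transcriptome <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  fmt <- if (grepl("\\.gtf(\\.gz)?$", annotation_path, ignore.case = TRUE)) "gtf" else "gff3"
  ann <- rtracklayer::import(annotation_path, format = fmt)

  type <- as.character(ann$type)
  meta <- S4Vectors::mcols(ann)
  get_col <- function(nm) if (nm %in% colnames(meta)) as.character(meta[[nm]]) else rep(NA_character_, length(ann))

  tx_types <- c("mRNA", "transcript", "ncRNA", "lnc_RNA", "miscRNA", "misc_RNA",
                "tRNA", "rRNA", "snoRNA", "snRNA", "miRNA", "primary_transcript")
  is_tx <- type %in% tx_types
  id_col <- get_col("ID")
  txid_col <- get_col("transcript_id")
  gid_attr <- get_col("gene_id")
  parent_col <- if ("Parent" %in% colnames(meta)) {
    vapply(meta$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_, character(1))
  } else rep(NA_character_, length(ann))

  tx_key <- ifelse(is.na(txid_col), id_col, txid_col)
  tx_idx <- which(is_tx & !is.na(tx_key))

  # gene_id of each transcript: Parent (GFF3) or gene_id attribute (GTF)
  gene_of_feature <- stats::setNames(gid_attr, id_col)
  tx_ids <- tx_key[tx_idx]
  if (anyDuplicated(tx_ids))
    stop("duplicate transcript_id in annotation: ",
         paste(unique(tx_ids[duplicated(tx_ids)]), collapse = ", "))
  tx_gene <- gid_attr[tx_idx]
  par <- parent_col[tx_idx]
  need <- is.na(tx_gene) & !is.na(par)
  tx_gene[need] <- par[need]
  tx_gene[is.na(tx_gene)] <- tx_ids[is.na(tx_gene)]  # orphans: gene = transcript

  biotype_attr <- get_col("transcript_biotype")
  bt2 <- get_col("gene_biotype")
  tx_bio <- biotype_attr[tx_idx]
  tx_bio[is.na(tx_bio)] <- bt2[tx_idx][is.na(tx_bio)]
  tx_bio[is.na(tx_bio)] <- type[tx_idx][is.na(tx_bio)]
  tx_bio <- normalize_biotype(tx_bio)

  # exon assignment: Parent (GFF3) or transcript_id (GTF)
  is_exon <- type == "exon"
  exon_tx <- parent_col
  exon_tx[is.na(exon_tx)] <- txid_col[is.na(exon_tx)]
  exon_idx <- which(is_exon & !is.na(exon_tx))

  # transcripts with no exon children: use the transcript interval itself
  exons_by_tx <- split(exon_idx, exon_tx[exon_idx])

  seq_chr <- stats::setNames(toupper(as.character(seqs)), names(seqs))
  seq_len_chr <- nchar(seq_chr)
  chrom_all <- as.character(GenomicRanges::seqnames(ann))
  start_all <- GenomicRanges::start(ann)
  end_all <- GenomicRanges::end(ann)
  strand_all <- as.character(BiocGenerics::strand(ann))

  records <- vector("list", length(tx_ids))
  for (k in seq_along(tx_ids)) {
    tid <- tx_ids[k]
    rows <- exons_by_tx[[tid]]
    if (is.null(rows)) rows <- tx_idx[k]
    chrom <- chrom_all[rows[1]]
    if (!chrom %in% names(seq_chr))
      stop("transcript '", tid, "' references absent sequence '", chrom, "'")
    st <- start_all[rows]; en <- end_all[rows]
    if (any(st < 1L) || any(en > seq_len_chr[[chrom]]))
      stop("exon outside sequence bounds for transcript '", tid, "'")
    o <- order(st)
    spliced <- paste(substring(seq_chr[[chrom]], st[o], en[o]), collapse = "")
    if (identical(strand_all[rows[1]], "-")) spliced <- revcomp_chr(spliced)
    records[[k]] <- spliced
  }

  out <- data.frame(
    transcript_id = tx_ids,
    gene_id = tx_gene,
    sequence = unlist(records, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  out$length <- nchar(out$sequence)
  out$biotype <- tx_bio
  new_transcript_set(out)
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

normalize_biotype <- function(x) {
  x <- tolower(x)
  out <- rep("other", length(x))
  out[x %in% c("mrna", "protein_coding", "transcript")] <- "mRNA"
  out[grepl("ncrna|lnc_rna|lncrna|antisense", x)] <- "ncRNA"
  out[x %in% c("trna", "rrna", "snorna", "snrna", "mirna")] <- "ncRNA"
  out[x %in% c("miscrna", "misc_rna")] <- "miscRNA"
  out[is.na(x)] <- "mRNA"
  out
}

#' Construct a transcript_set from a transcript table
#'
#' @param df data frame with columns transcript_id, gene_id, sequence and
#'   optionally length and biotype.
#' @return validated \code{transcript_set}.
#' @export
new_transcript_set <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("transcript_id", "gene_id", "sequence") %in% names(df)))
  if (!"length" %in% names(df)) df$length <- nchar(df$sequence)
  if (!"biotype" %in% names(df)) df$biotype <- "mRNA"
  if (anyDuplicated(df$transcript_id))
    stop("duplicate transcript_id: ",
         paste(unique(df$transcript_id[duplicated(df$transcript_id)]), collapse = ", "))
  if (any(df$length != nchar(df$sequence))) stop("length field inconsistent with sequence")
  if (any(df$length < 1L)) stop("empty transcript sequence")
  rownames(df) <- NULL
  attr(df, "gene_index") <- split(df$transcript_id, df$gene_id)
  class(df) <- c("transcript_set", "data.frame")
  df
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x), "transcripts,",
      length(attr(x, "gene_index")), "genes\n")
  print(utils::head(as.data.frame(x)[c("transcript_id", "gene_id", "length", "biotype")]), ...)
  invisible(x)
}

#' Collapse a transcript set to one representative transcript per gene
#'
#' The longest isoform is chosen as each gene's representative; ties are
#' broken by the lexicographically smallest transcript_id. This mirrors the
#' gene-level design strategy for isoform-rich genomes: one probe target per
#' locus rather than one per transcript.
#'
#' @param ts a \code{transcript_set}.
#' @return data frame of class \code{gene_models}: one row per gene with
#'   columns \code{gene_id}, \code{transcript_id} (the representative),
#'   \code{sequence}, \code{length}, \code{biotype}, \code{isoform_count}.
#' @export
collapse_to_genes <- function(ts) {
  stopifnot(inherits(ts, "transcript_set"), nrow(ts) > 0)
  df <- as.data.frame(ts)
  # order: gene, then length desc, then transcript_id asc -> first row per gene wins
  o <- order(df$gene_id, -df$length, df$transcript_id)
  df <- df[o, , drop = FALSE]
  keep <- !duplicated(df$gene_id)
  reps <- df[keep, c("gene_id", "transcript_id", "sequence", "length", "biotype")]
  cnt <- table(df$gene_id)
  reps$isoform_count <- as.integer(cnt[reps$gene_id])
  reps <- reps[order(reps$gene_id), , drop = FALSE]
  rownames(reps) <- NULL
  class(reps) <- c("gene_models", "data.frame")
  reps
}

#' Write a transcript summary table
#'
#' @param ts transcript_set
#' @param path output TSV path
#' @export
write_transcript_table <- function(ts, path) {
  utils::write.table(as.data.frame(ts)[c("transcript_id", "gene_id", "length", "biotype")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
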