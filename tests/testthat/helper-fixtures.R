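# fixture builders shared across test files

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# write a FASTA file from a named character vector
write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  path
}

# write a GFF3 from a data frame with columns seqid, type, start, end,
# strand, attributes
write_gff3 <- function(df, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3",
               sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       df$seqid, df$type, df$start, df$end, df$strand,
                       df$attributes)),
             path)
  path
}

gff_row <- function(seqid, type, start, end, strand, attributes) {
  data.frame(seqid = seqid, type = type, start = start, end = end,
             strand = strand, attributes = attributes,
             stringsAsFactors = FALSE)
}

# two genes, three transcripts on one plus-strand contig
tiny_annotated_fixture <- function() {
  set.seed(42)
  contig <- rand_dna(400)
  fa <- write_fasta(c(chr1 = contig))
  gff <- write_gff3(rbind(
    gff_row("chr1", "gene", 1, 200, "+", "ID=gA"),
    gff_row("chr1", "mRNA", 1, 200, "+", "ID=gA.t1;Parent=gA"),
    gff_row("chr1", "exon", 1, 100, "+", "Parent=gA.t1"),
    gff_row("chr1", "exon", 151, 200, "+", "Parent=gA.t1"),
    gff_row("chr1", "mRNA", 1, 100, "+", "ID=gA.t2;Parent=gA"),
    gff_row("chr1", "exon", 1, 100, "+", "Parent=gA.t2"),
    gff_row("chr1", "gene", 201, 400, "+", "ID=gB"),
    gff_row("chr1", "mRNA", 201, 400, "+", "ID=gB.t1;Parent=gB"),
    gff_row("chr1", "exon", 201, 400, "+", "Parent=gB.t1")
  ))
  list(fasta = fa, gff = gff, contig = contig)
}

# transcript_set built directly from sequences (no files)
ts_from_seqs <- function(seqs, genes = names(seqs)) {
  new_transcript_set(data.frame(
    transcript_id = names(seqs), gene_id = genes,
    sequence = unname(seqs), stringsAsFactors = FALSE))
}

# spot-measurement rows for scan_qc tests
spot_row <- function(median_signal, bg_median = 100, bg_pix_sd = 50,
                     processed_signal = median_signal - bg_median,
                     well_above_bg = TRUE, nonunif = FALSE, popn = FALSE,
                     saturated = FALSE, array_id = "a1", probe_id = "p1") {
  data.frame(array_id = array_id, probe_id = probe_id,
             median_signal = median_signal, bg_median = bg_median,
             bg_pix_sd = bg_pix_sd, processed_signal = processed_signal,
             well_above_bg = well_above_bg, feat_nonunif_outlier = nonunif,
             feat_popn_outlier = popn, saturated = saturated,
             stringsAsFactors = FALSE)
}
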