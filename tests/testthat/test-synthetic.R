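test_that("transcriptome generation is deterministic under the seed", {
  p <- synthetic_transcriptome_params(n_genes = 15L, seed = 1L)
  g1 <- generate_transcriptome(p, dir = tempfile())
  g2 <- generate_transcriptome(p, dir = tempfile())
  expect_identical(readLines(g1$fasta), readLines(g2$fasta))
  expect_identical(readLines(g1$gff), readLines(g2$gff))
  g3 <- generate_transcriptome(synthetic_transcriptome_params(n_genes = 15L, seed = 2L),
                               dir = tempfile())
  expect_false(identical(readLines(g3$fasta), readLines(g1$fasta)))
})

test_that("paralog family members sit near the target identity", {
  p <- synthetic_transcriptome_params(n_genes = 5L, n_paralog_families = 1L,
                                      paralog_family_size = 2L,
                                      paralog_identity = 0.92, seed = 5L)
  gen <- generate_transcriptome(p, dir = tempfile())
  ts <- load_transcriptome(gen$fasta, gen$gff)
  fam <- gen$genes$gene_id[!is.na(gen$genes$family)]
  s1 <- ts$sequence[ts$gene_id == fam[1]]
  s2 <- ts$sequence[ts$gene_id == fam[2]]
  # members differ only by substitutions from a common seed (plus a shared
  # poly(A) tail), so alignment is positional
  expect_equal(nchar(s1), nchar(s2))
  ident <- mean(strsplit(s1, "")[[1]] == strsplit(s2, "")[[1]])
  expect_equal(ident, 0.92, tolerance = 0.02)
})

test_that("isoform counts respect the requested range and land in the GFF3", {
  p <- synthetic_transcriptome_params(n_genes = 20L, isoform_range = c(2L, 5L),
                                      n_paralog_families = 0L, seed = 7L)
  gen <- generate_transcriptome(p, dir = tempfile())
  ts <- load_transcriptome(gen$fasta, gen$gff)
  counts <- lengths(attr(ts, "gene_index"))
  expect_true(all(counts >= 2L & counts <= 5L))
  expect_equal(unname(counts[gen$genes$gene_id]), gen$genes$n_isoforms)
  # poly(A) present at the 3' end of every transcript
  expect_true(all(substr(ts$sequence, ts$length - 9, ts$length) == strrep("A", 10)))
  expect_error(synthetic_transcriptome_params(paralog_identity = 1.5))
})

test_that("scan simulation follows the stated signal arithmetic", {
  probes <- carpoligo:::fabricate_probe_set(20, seed = 11L)
  cm <- control_manifest(control_count = 8L, spike_levels = 2L, n_corner = 1L)
  spec <- layout_spec(subarrays = 1L, features_per_subarray = 40L,
                      control_count = 8L, replicate_probe_count = 2L,
                      replicate_copies = 3L, seed = 11L, control_manifest = cm)
  layout <- build_layout(probes, spec)
  truth <- list(expr_green = setNames(rep(10, 20), probes$probe_id))
  # zero noise, unit gain: median = 2^10 + background mean
  scan <- simulate_scan(layout, truth,
                        noise = list(bg_mean = 100, bg_sd = 0, sd_log2 = 0),
                        seed = 12L)
  bio <- scan$feature_class %in% c("biological", "replicate")
  expect_true(all(abs(scan$gMedianSignal[bio] - 1124) < 1e-9))
  expect_true(all(scan$gIsFeatNonUnifOL == 0 & scan$gIsFeatPopnOL == 0 &
                    scan$gIsSaturated == 0))
  # nonzero flag rates inject flags; missing truth errors
  scan2 <- simulate_scan(layout, truth,
                         flag_rates = list(nonunif = 0.5, popn = 0, saturated = 0),
                         seed = 13L)
  expect_gt(sum(scan2$gIsFeatNonUnifOL), 0)
  expect_error(simulate_scan(layout, list(expr_green = c(PR_00001 = 10)),
                             seed = 1L),
               "missing truth")
})

test_that("experiment presets encode their designs and are seed-deterministic", {
  ss <- preset_selfself(n_arrays = 2L, n_probes = 150L, seed = 21L)
  expect_length(ss$scans, 2L)
  expect_identical(ss$truth$expr_green, ss$truth$expr_red)
  ss2 <- preset_selfself(n_arrays = 2L, n_probes = 150L, seed = 21L)
  expect_identical(ss$scans, ss2$scans)

  ti <- preset_two_isolations(n_per_group = 2L, n_probes = 150L, seed = 22L)
  diffs <- ti$truth$expr_iso2 - ti$truth$expr_iso1
  expect_equal(sum(diffs != 0), 12L)
  expect_true(all(abs(diffs[ti$truth$shifted_ids] - 1.23) < 1e-12))
  ti2 <- preset_two_isolations(n_per_group = 2L, n_probes = 150L, seed = 22L)
  expect_identical(ti$scans_iso1, ti2$scans_iso1)
})

test_that("designed probes re-locate uniquely to their source gene unless flagged", {
  p <- synthetic_transcriptome_params(n_genes = 12L, n_paralog_families = 1L,
                                      paralog_family_size = 2L,
                                      paralog_identity = 0.95, seed = 31L)
  gen <- generate_transcriptome(p, dir = tempfile())
  ts <- load_transcriptome(gen$fasta, gen$gff)
  gm <- collapse_to_genes(ts)
  ps <- design_probes(gm, vectors = gen$vectors)
  ps <- cross_hyb_screen(ps, ts)
  des <- ps[ps$status == "designed", ]
  for (i in seq_len(nrow(des))) {
    hit_genes <- unique(ts$gene_id[vapply(ts$sequence, grepl,
                                          logical(1), pattern = des$sequence[i],
                                          fixed = TRUE)])
    if (!des$xhyb_flag[i]) {
      expect_equal(hit_genes, des$gene_id[i])
    } else {
      expect_true(des$gene_id[i] %in% hit_genes)
    }
  }
})

test_that("the full chain recovers injected shifts end to end", {
  # design -> layout -> simulate -> qc -> normalize -> contrast at small scale
  p <- synthetic_transcriptome_params(n_genes = 40L, n_paralog_families = 0L,
                                      isoform_range = c(1L, 3L), seed = 41L)
  gen <- generate_transcriptome(p, dir = tempfile())
  ts <- load_transcriptome(gen$fasta, gen$gff)
  gm <- collapse_to_genes(ts)
  ps <- design_probes(gm, vectors = gen$vectors)
  des <- ps[ps$status == "designed", ]
  cm <- control_manifest(control_count = 14L, spike_levels = 3L, n_corner = 2L)
  spec <- layout_spec(subarrays = 1L,
                      features_per_subarray = nrow(des) + 20L + 14L,
                      control_count = 14L, replicate_probe_count = 4L,
                      replicate_copies = 5L, seed = 41L, control_manifest = cm)
  layout <- build_layout(ps, spec)

  set.seed(42)
  base <- setNames(rnorm(nrow(des), 10, 1.5), des$probe_id)
  shifted <- sample(des$probe_id, 5)
  expr2 <- base; expr2[shifted] <- expr2[shifted] + 2.0
  noise <- list(bg_mean = 100, bg_sd = 15, sd_log2 = 0.25)
  scans1 <- lapply(1:4, function(k)
    simulate_scan(layout, list(expr_green = base), noise, array_id = paste0("g1_", k),
                  seed = 400 + k))
  scans2 <- lapply(1:4, function(k)
    simulate_scan(layout, list(expr_green = expr2), noise, array_id = paste0("g2_", k),
                  seed = 500 + k))
  names(scans1) <- paste0("g1_", 1:4); names(scans2) <- paste0("g2_", 1:4)

  # QC: simulated spots are overwhelmingly robust at these signal levels
  spots <- do.call(rbind, lapply(names(scans1), function(a) {
    f <- tempfile(); write_fe_table(scans1[[a]], f)
    read_fe_table(f, array_id = a, channels = "green")
  }))
  qc <- qc_summarize(spots[spots$feature_class %in% c("biological", "replicate"), ])
  expect_gt(mean(qc$per_probe$present_call_rate), 0.95)

  m <- cbind(scans_to_matrix(scans1), scans_to_matrix(scans2))
  em <- percentile75_normalize(log2_transform(m))
  res <- isolation_contrast(em$values[, 1:4], em$values[, 5:8], criterion = "raw_p")
  hits <- res$feature_id[res$significant]
  expect_gte(length(intersect(hits, shifted)), 4L)
  expect_lte(length(setdiff(hits, shifted)), 2L)
})
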