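test_that("zero event spec leaves the genome untouched", {
  dref <- small_dref()
  spec <- event_spec(n_tl_taqi = 0, n_tl_homologous = 0, n_bir = 0,
                     n_sgc = 0, n_aneuploidy_gain = 0, n_aneuploidy_loss = 0)
  out <- plant_events(dref, spec, seed = 1)
  expect_equal(nrow(out$truth$events), 0L)
  expect_equal(length(out$genome$copies), 2L * length(dref$pairing))
  for (ch in names(dref$pairing)) {
    sg <- out$genome$copies[[paste0("A:", ch)]]$segments
    expect_equal(nrow(sg), 1L)
    expect_equal(sg$end, unname(dref$A$lengths[[ch]]))
  }
})

test_that("same seed and spec give byte-identical simulator output", {
  dref <- small_dref()
  spec <- event_spec(n_tl_taqi = 2, n_tl_homologous = 1, n_bir = 2,
                     n_sgc = 5, n_aneuploidy_gain = 1, n_aneuploidy_loss = 0)
  a <- plant_events(dref, spec, seed = 9)
  b <- plant_events(dref, spec, seed = 9)
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(restructured_seqs(a$genome, dref),
                   restructured_seqs(b$genome, dref))
  c <- plant_events(dref, spec, seed = 10)
  expect_false(identical(a$truth$events, c$truth$events))
})

test_that("restriction-direct junctions reconstitute the motif with zero loss", {
  dref <- std_dref()
  sim <- std_experiment()
  jn <- sim$truth$junctions
  taqi <- jn[jn$mechanism == "taqi_direct", , drop = FALSE]
  expect_gt(nrow(taqi), 0)
  seqs <- restructured_seqs(sim$genome, dref)
  for (k in seq_len(nrow(taqi))) {
    j <- taqi[k, ]
    left <- haplome_of_test(dref, j$hap_left)
    ## audit the emitted derivative sequence: find the copy whose segment
    ## ends at the left breakpoint and read across the join
    hit <- NULL
    for (cp in sim$genome$copies) {
      sg <- cp$segments
      i <- which(sg$hap == j$hap_left & sg$chrom == j$chrom_left &
                   sg$end == j$pos_left)
      if (length(i) == 1 && i < nrow(sg)) { hit <- list(cp = cp, i = i); break }
    }
    expect_false(is.null(hit))
    offset <- sum(hit$cp$segments$end[seq_len(hit$i)] -
                    hit$cp$segments$start[seq_len(hit$i)] + 1L)
    der <- as.character(seqs[[hit$cp$id]])
    win <- substr(der, offset - 3L, offset + 4L)
    expect_true(grepl("TCGA", win, fixed = TRUE))
    ## both breakpoints at canonical cut positions: zero net loss
    sites_l <- scan_restriction_sites(haplome_of_test(dref, j$hap_left))
    sites_r <- scan_restriction_sites(haplome_of_test(dref, j$hap_right))
    expect_true(j$pos_left %in% sites_l$sites[[j$chrom_left]])
    expect_true((j$pos_right - 1L) %in% sites_r$sites[[j$chrom_right]])
  }
})

test_that("planted SGC lengths stay inside the specified range", {
  sim <- std_experiment()
  sgc <- sim$truth$events[sim$truth$events$type == "SGC", ]
  expect_equal(nrow(sgc), 40L)
  expect_true(all(sgc$length >= 700 & sgc$length <= 30000))
  bir <- sim$truth$events[sim$truth$events$type == "BIR", ]
  expect_true(all(bir$extends_to_end))
})

test_that("homologous TL junctions sit inside same-class repeat annotations", {
  dref <- std_dref()
  sim <- std_experiment()
  jn <- sim$truth$junctions
  hom <- jn[jn$mechanism == "homologous", , drop = FALSE]
  expect_gt(nrow(hom), 0)
  reps <- dref$A$repeats
  for (k in seq_len(nrow(hom))) {
    j <- hom[k, ]
    in_rep <- function(ch, pos) {
      sub <- reps[reps$chrom == ch & reps$start <= pos & reps$end >= pos, ]
      if (nrow(sub)) sub$class[1] else NA_character_
    }
    cl <- in_rep(j$chrom_left, j$pos_left)
    cr <- in_rep(j$chrom_right, j$pos_right)
    expect_false(is.na(cl))
    expect_equal(cl, cr)
  }
})

test_that("microhomology CNV junctions carry a 2-3 nt overlap and no motif", {
  dref <- small_dref()
  spec <- event_spec(n_tl_taqi = 0, n_tl_homologous = 0, n_bir = 0, n_sgc = 0,
                     n_aneuploidy_gain = 0, n_aneuploidy_loss = 0,
                     n_large_deletion = 2, microhomology_fraction = 1,
                     cnv_length_range = c(8000, 20000))
  out <- plant_events(dref, spec, seed = 4)
  ev <- out$truth$events
  expect_equal(nrow(ev), 2L)
  for (k in seq_len(nrow(ev))) {
    expect_true(ev$overlap_len[k] %in% 2:3)
    seq <- as.character(haplome_of_test(dref, ev$hap_a[k])$seqs[[ev$chrom_a[k]]])
    x <- ev$pos_a[k]; y2 <- ev$pos_b[k]
    ## the recorded overlap is an exact suffix match of both flanks
    expect_equal(substr(seq, x - ev$overlap_len[k] + 1, x),
                 substr(seq, y2 - 1 - ev$overlap_len[k] + 1, y2 - 1))
    win <- paste0(substr(seq, x - 3, x), substr(seq, y2, y2 + 3))
    expect_false(grepl("TCGA", win, fixed = TRUE))
  }
})

test_that("coverage synthesis follows the copy-number oracle", {
  dref <- small_dref()
  spec0 <- event_spec(n_tl_taqi = 0, n_tl_homologous = 0, n_bir = 0,
                      n_sgc = 0, n_aneuploidy_gain = 0, n_aneuploidy_loss = 0)
  flat <- plant_events(dref, spec0, seed = 1)
  cov <- simulate_coverage(flat$genome, dref, mean_depth = 80, noise = "none")
  expect_true(all(cov$A$depth == 80))
  expect_true(all(cov$B$depth == 80))

  spec1 <- event_spec(n_tl_taqi = 0, n_tl_homologous = 0, n_bir = 0,
                      n_sgc = 3, n_aneuploidy_gain = 1, n_aneuploidy_loss = 0,
                      sgc_length_range = c(2000, 8000))
  out <- plant_events(dref, spec1, seed = 2)
  cov <- simulate_coverage(out$genome, dref, mean_depth = 80, noise = "none")
  sgc <- out$truth$events[out$truth$events$type == "SGC", ]
  for (k in seq_len(nrow(sgc))) {
    acc <- cov[[sgc$hap_a[k]]]
    inner <- acc$chrom == sgc$chrom_a[k] & acc$start >= sgc$start[k] + 100 &
      acc$end <= sgc$end[k] - 100
    expect_true(all(acc$depth[inner] == 0))
    don <- cov[[sgc$hap_b[k]]]
    lift <- liftover(dref, sgc$hap_a[k], sgc$chrom_a[k], sgc$start[k], sgc$end[k])
    inner_d <- don$chrom == lift$chrom & don$start >= lift$start + 100 &
      don$end <= lift$end - 100
    expect_true(all(don$depth[inner_d] == 160))
  }
  ## trisomy: combined chromosome mean / genome median = 1.5
  gain <- out$truth$events[out$truth$events$type == "aneuploidy_gain", ]
  rA <- normalize_coverage(cov$A); rB <- normalize_coverage(cov$B)
  comb <- (median(rA$ratio[rA$chrom == gain$chrom_a & !rA$masked]) +
             median(rB$ratio[rB$chrom == gain$chrom_a & !rB$masked])) / 2
  expect_equal(comb, 1.5, tolerance = 0.01)
})

test_that("copy-number conservation: planted gains minus losses equal the track integral", {
  dref <- small_dref()
  spec <- event_spec(n_tl_taqi = 1, n_tl_homologous = 0, n_bir = 1, n_sgc = 3,
                     n_aneuploidy_gain = 1, n_aneuploidy_loss = 1,
                     sgc_length_range = c(1000, 5000))
  out <- plant_events(dref, spec, seed = 6)
  cov <- simulate_coverage(out$genome, dref, mean_depth = 10, noise = "none")
  bin <- 100
  integral <- (sum(cov$A$cn - 1) + sum(cov$B$cn - 1)) * bin
  ## expected: every acceptor base lost is donated by the homolog (net 0
  ## for SGC/BIR/TL), aneuploidy gain adds a chromosome, loss removes one
  ev <- out$truth$events
  gain_bp <- sum(ev$length[ev$type == "aneuploidy_gain"])
  loss_bp <- sum(ev$length[ev$type == "aneuploidy_loss"])
  ## bin quantization and InDel drift allow a small absolute slack
  expect_lt(abs(integral - (gain_bp - loss_bp)), 3000)
})

test_that("aCGH probes report log10 copy ratios around the truth", {
  dref <- small_dref()
  spec0 <- event_spec(n_tl_taqi = 0, n_tl_homologous = 0, n_bir = 0,
                      n_sgc = 0, n_aneuploidy_gain = 0, n_aneuploidy_loss = 0)
  flat <- plant_events(dref, spec0, seed = 1)
  arr <- simulate_acgh(flat$genome, dref, probe_spacing = 500,
                       noise_sd = 0.02, seed = 3)
  expect_lt(abs(mean(arr$log10_ratio)), 0.01)
  ## chromosome loss in a tetraploid baseline: median log10(3/4)
  spec1 <- event_spec(n_tl_taqi = 0, n_tl_homologous = 0, n_bir = 0,
                      n_sgc = 0, n_aneuploidy_gain = 0, n_aneuploidy_loss = 1)
  out <- plant_events(dref, spec1, seed = 2)
  arr4 <- simulate_acgh(out$genome, dref, probe_spacing = 500,
                        noise_sd = 0.02, baseline_ploidy = 2, seed = 3)
  lost <- out$truth$events$chrom_a[1]
  expect_equal(median(arr4$log10_ratio[arr4$chrom == lost]), log10(1 / 2),
               tolerance = 0.02)
  expect_error(simulate_acgh(out$genome, dref, probe_spacing = 0), "positive")
})

test_that("junction evidence is empty at depth zero and anchored when present", {
  dref <- small_dref()
  spec <- event_spec(n_tl_taqi = 1, n_tl_homologous = 0, n_bir = 0, n_sgc = 0,
                     n_aneuploidy_gain = 0, n_aneuploidy_loss = 0)
  out <- plant_events(dref, spec, seed = 3)
  ev0 <- simulate_junction_evidence(out$genome, out$truth, dref, mean_depth = 0)
  expect_equal(nrow(ev0$clips), 0L)
  expect_equal(nrow(ev0$pairs), 0L)
  ev <- simulate_junction_evidence(out$genome, out$truth, dref,
                                   mean_depth = 30, seed = 8)
  jn <- out$truth$junctions[1, ]
  side_r <- ev$clips[ev$clips$side == "right" & ev$clips$chrom == jn$chrom_left &
                       ev$clips$pos == jn$pos_left, ]
  expect_gte(nrow(side_r), 1L)
  ## the clipped tail is the partner-side sequence
  partner <- as.character(haplome_of_test(dref, jn$hap_right)$seqs[[jn$chrom_right]])
  expect_equal(substr(partner, jn$pos_right,
                      jn$pos_right + nchar(side_r$seq[1]) - 1L),
               side_r$seq[1])
  expect_error(simulate_junction_evidence(out$genome, out$truth, dref,
                                          read_len = 40), "read length")
})


test_that("noise-only evidence never passes the clustering thresholds", {
  dref <- small_dref()
  spec0 <- event_spec(n_tl_taqi = 0, n_tl_homologous = 0, n_bir = 0, n_sgc = 0,
                      n_aneuploidy_gain = 0, n_aneuploidy_loss = 0)
  out <- plant_events(dref, spec0, seed = 1)
  for (s in 1:5) {
    ev <- simulate_junction_evidence(out$genome, out$truth, dref,
                                     mean_depth = 80, seed = s)
    regions <- find_boundary_regions(ev)
    expect_equal(nrow(regions), 0L)
  }
})

test_that("synthetic coordinate model stays inside the nucleus", {
  dref <- small_dref()
  cm <- simulate_coordinate_model(dref, nuclear_diameter_um = 2, seed = 5)
  rad <- sqrt(cm$anchors$x^2 + cm$anchors$y^2 + cm$anchors$z^2)
  expect_true(all(rad <= 1 + 1e-9))
  expect_equal(pair_distance(cm, "chr1", 5000, "chr1", 5000), 0)
  null <- random_pair_null(cm, n = 500, seed = 1)
  expect_lt(null$mean, 2)
  expect_error(simulate_coordinate_model(dref, nuclear_diameter_um = 0),
               "positive")
})
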