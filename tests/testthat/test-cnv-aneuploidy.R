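## hand-built ratio track helpers
flat_track <- function(chroms, nbins, depth = 80, bin = 100) {
  do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch, start = (seq_len(nbins) - 1) * bin + 1,
               end = seq_len(nbins) * bin, cn = 1, depth = depth,
               masked = FALSE)
  }))
}

test_that("normalization maps a flat track to ratio 1 and ignores masked spikes", {
  tr <- flat_track(c("c1", "c2"), 100)
  out <- normalize_coverage(tr)
  expect_true(all(out$ratio == 1))
  ## a masked spike must not shift the median
  tr2 <- tr
  tr2$depth[1:10] <- 5000
  tr2$masked[1:10] <- TRUE
  out2 <- normalize_coverage(tr2)
  expect_equal(attr(out2, "genome_median"), 80)
  ## without the mask the same spike is part of the statistics
  tr3 <- tr
  tr3$depth[1:150] <- 5000
  expect_gt(attr(normalize_coverage(tr3), "genome_median"), 80)
  tr4 <- tr; tr4$masked <- TRUE
  expect_error(normalize_coverage(tr4), "masked")
})

test_that("a chromosome at 1.5x has median ratio 1.5 after normalization", {
  tr <- flat_track(c("c1", "c2", "c3"), 200)
  tr$depth[tr$chrom == "c3"] <- 120
  out <- normalize_coverage(tr)
  expect_equal(median(out$ratio[out$chrom == "c3"]), 1.5)
})

test_that("aneuploidy calls require dual platform support", {
  dref <- small_dref()
  spec <- event_spec(n_tl_taqi = 0, n_tl_homologous = 0, n_bir = 0, n_sgc = 0,
                     n_aneuploidy_gain = 0, n_aneuploidy_loss = 1)
  out <- plant_events(dref, spec, seed = 21)
  lost <- out$truth$events$chrom_a[1]
  cov <- simulate_coverage(out$genome, dref, noise = "none")
  arr <- simulate_acgh(out$genome, dref, seed = 2)
  ratio <- list(A = normalize_coverage(cov$A), B = normalize_coverage(cov$B))
  calls <- call_aneuploidy(ratio, arr, dref)
  hit <- calls[calls$chrom == lost, ]
  expect_equal(hit$direction, "loss")
  expect_equal(hit$status, "aneuploidy")
  expect_true(hit$seq_support && hit$array_support)
  ## flat array: same sequencing signal downgrades to unconfirmed
  flat_arr <- arr
  flat_arr$log10_ratio <- rnorm(nrow(arr), 0, 0.01)
  calls2 <- call_aneuploidy(ratio, flat_arr, dref)
  expect_equal(calls2$status[calls2$chrom == lost], "unconfirmed")
  ## missing array: warning, never an aneuploidy status
  expect_warning(calls3 <- call_aneuploidy(ratio, NULL, dref), "array")
  expect_false(any(calls3$status == "aneuploidy"))
})

test_that("dual-support gating is absolute over random platform inputs", {
  dref <- small_dref()
  spec0 <- event_spec(n_tl_taqi = 0, n_tl_homologous = 0, n_bir = 0, n_sgc = 0,
                      n_aneuploidy_gain = 0, n_aneuploidy_loss = 0)
  out <- plant_events(dref, spec0, seed = 1)
  cov <- simulate_coverage(out$genome, dref, noise = "none")
  set.seed(99)
  for (i in 1:20) {
    covA <- cov$A; covB <- cov$B
    ## random per-chromosome scaling on the sequencing side
    for (ch in unique(covA$chrom)) {
      f <- sample(c(0.5, 1, 1.5), 1)
      covA$depth[covA$chrom == ch] <- covA$depth[covA$chrom == ch] * f
      covB$depth[covB$chrom == ch] <- covB$depth[covB$chrom == ch] * f
    }
    arr <- data.frame(chrom = sample(unique(covA$chrom), 200, TRUE),
                      pos = sample(1e4, 200),
                      log10_ratio = rnorm(200, 0, 0.3))
    ratio <- list(A = normalize_coverage(covA), B = normalize_coverage(covB))
    calls <- call_aneuploidy(ratio, arr, dref)
    if (nrow(calls)) {
      expect_true(all(calls$seq_support[calls$status == "aneuploidy"]))
      expect_true(all(calls$array_support[calls$status == "aneuploidy"]))
    }
  }
})

test_that("raising the gain threshold never increases gain calls", {
  dref <- small_dref()
  spec <- event_spec(n_tl_taqi = 0, n_tl_homologous = 0, n_bir = 0, n_sgc = 0,
                     n_aneuploidy_gain = 1, n_aneuploidy_loss = 0)
  out <- plant_events(dref, spec, seed = 31)
  cov <- simulate_coverage(out$genome, dref, noise = "nb", seed = 5)
  arr <- simulate_acgh(out$genome, dref, seed = 6)
  ratio <- list(A = normalize_coverage(cov$A), B = normalize_coverage(cov$B))
  n_prev <- Inf
  for (th in c(1.1, 1.35, 1.6, 2.5)) {
    calls <- call_aneuploidy(ratio, arr, dref, gain_threshold = th)
    n <- sum(calls$direction == "gain" & calls$seq_support)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("local CNV segmentation finds planted deletions at the right length", {
  dref <- small_dref()
  spec <- event_spec(n_tl_taqi = 0, n_tl_homologous = 0, n_bir = 0, n_sgc = 0,
                     n_aneuploidy_gain = 0, n_aneuploidy_loss = 0,
                     n_large_deletion = 1, cnv_length_range = c(10000, 20000))
  out <- plant_events(dref, spec, seed = 8)
  cov <- simulate_coverage(out$genome, dref, noise = "none")
  ratio <- list(A = normalize_coverage(cov$A), B = normalize_coverage(cov$B))
  comb <- taqing:::combined_ratio_track(ratio, dref)
  segs <- segment_local_cnv(comb, min_length = 5000)
  del <- out$truth$events[1, ]
  hit <- segs[segs$chrom == del$chrom_a & segs$direction == "loss", ]
  expect_equal(nrow(hit), 1L)
  expect_lte(abs(hit$start - del$start), 200)
  expect_lte(abs(hit$end - del$end), 200)
  ## flat track has no segments
  spec0 <- event_spec(n_tl_taqi = 0, n_tl_homologous = 0, n_bir = 0,
                      n_sgc = 0, n_aneuploidy_gain = 0, n_aneuploidy_loss = 0)
  flat <- plant_events(dref, spec0, seed = 1)
  cov0 <- simulate_coverage(flat$genome, dref, noise = "none")
  comb0 <- taqing:::combined_ratio_track(
    list(A = normalize_coverage(cov0$A), B = normalize_coverage(cov0$B)), dref)
  expect_equal(nrow(segment_local_cnv(comb0, min_length = 5000)), 0L)
  expect_error(segment_local_cnv(comb0, min_length = 10), "bin")
})

test_that("adjacent beyond-threshold runs merge across small gaps", {
  bin <- 100
  tr <- data.frame(chrom = "c1", start = (0:199) * bin + 1,
                   end = (1:200) * bin, ratio = 1, masked = FALSE)
  attr(tr, "bin_size") <- bin
  tr$ratio[51:80] <- 0.4
  tr$ratio[81:85] <- 1      # 500 bp gap
  tr$ratio[86:110] <- 0.4
  merged <- segment_local_cnv(tr, min_length = 1000, merge_gap = 600)
  expect_equal(nrow(merged), 1L)
  split <- segment_local_cnv(tr, min_length = 1000, merge_gap = 200)
  expect_equal(nrow(split), 2L)
  ## whole-chromosome runs are flagged for the aneuploidy logic
  tr$ratio <- 0.4
  whole <- segment_local_cnv(tr, min_length = 1000)
  expect_true(all(whole$whole_chrom))
})
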