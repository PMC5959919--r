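test_that("boundary regions obey the 10% clipped-fraction rule", {
  ## 7 clips at depth 80 -> fraction 0.0875, below threshold
  ev <- structure(list(
    clips = data.frame(hap = "A", chrom = "chr1", pos = 5000L, side = "right",
                       seq = replicate(7, paste(rep("A", 60), collapse = ""))),
    pairs = data.frame(), mean_depth = 80, read_len = 150),
    class = "JunctionEvidence")
  expect_equal(nrow(find_boundary_regions(ev)), 0L)
  ## 9 clips -> fraction 0.1125, a region
  ev$clips <- do.call(rbind, replicate(9, ev$clips[1, ], simplify = FALSE))
  out <- find_boundary_regions(ev)
  expect_equal(nrow(out), 1L)
  expect_equal(out$anchor_pos, 5000L)
  ## empty evidence: no regions
  ev0 <- structure(list(clips = data.frame(), pairs = data.frame(),
                        mean_depth = 80), class = "JunctionEvidence")
  expect_equal(nrow(find_boundary_regions(ev0)), 0L)
})

test_that("a verbatim clip resolves to its unique source locus", {
  dref <- small_dref()
  seq1 <- as.character(dref$A$seqs[["chr2"]])
  clip <- substr(seq1, 20001, 20100)
  hit <- locate_partner(clip, dref, side = "right")
  expect_equal(hit$hap, "A")
  expect_equal(hit$chrom, "chr2")
  expect_equal(hit$start, 20001L)
  expect_false(hit$ambiguous)
  expect_lt(hit$evalue, 1e-4)
})

test_that("random clips find no partner below the E-value threshold", {
  dref <- small_dref()
  set.seed(12)
  for (i in 1:5) {
    clip <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    hit <- locate_partner(clip, dref, side = "right")
    ## a chance hit would need >= 28/30 identity in a 720 kb search space
    expect_null(hit)
  }
  ## short consensus below min_clip is unusable
  expect_null(locate_partner("ACGTACGT", dref))
})

test_that("a clip matching two identical loci is flagged ambiguous deterministically", {
  s <- paste(sample(c("A", "C", "G", "T"), 30000, TRUE), collapse = "")
  dup <- substr(s, 5001, 5100)
  s2 <- paste0(substr(s, 1, 15000), dup, substr(s, 15101, 30000))
  hA <- Haplome("A", Biostrings::DNAStringSet(c(c1 = s2)))
  hB <- Haplome("B", Biostrings::DNAStringSet(c(c1 = chartr("ACGT", "TGCA", s2))))
  dref <- DualReference(hA, hB, c(c1 = "c1"),
                        list(c1 = data.frame(a_start = 1L, b_start = 1L,
                                             len = 30000L)))
  h1 <- locate_partner(dup, dref, side = "right")
  h2 <- locate_partner(dup, dref, side = "right")
  expect_true(h1$ambiguous)
  expect_equal(h1$start, 5001L)          # deterministic lexicographic pick
  expect_identical(h1, h2)
})

test_that("Karlin-Altschul E-values scale with score and search space", {
  e1 <- ka_evalue(20, 20, 1e6)
  e2 <- ka_evalue(30, 30, 1e6)
  expect_gt(e1, e2)
  expect_equal(ka_evalue(20, 20, 2e6) / e1, 2)
})

test_that("discordant-pair confirmation counts only consistent orientations", {
  j <- data.frame(hap_left = "A", chrom_left = "c1", pos_left = 1000L,
                  hap_right = "B", chrom_right = "c2", pos_right = 5000L)
  ev <- structure(list(clips = data.frame(), pairs = data.frame(
    hap_a = "A", chrom_a = "c1", pos_a = c(700L, 800L, 900L),
    hap_b = "B", chrom_b = "c2", pos_b = c(5200L, 5300L, 5400L),
    orient = c("junction", "junction", "inverted")),
    mean_depth = 30), class = "JunctionEvidence")
  out <- confirm_discordant_pairs(j, ev)
  expect_equal(out$n_pairs, 2L)
  expect_true(out$confirmed)
  ev$pairs$orient <- "inverted"
  expect_false(confirm_discordant_pairs(j, ev)$confirmed)
  ev$pairs <- data.frame()
  expect_equal(confirm_discordant_pairs(j, ev)$n_pairs, 0L)
})

test_that("junction reconstruction reports overlap, insertions and motif spanning", {
  ## hand-built references with a planted 3 nt overlap "AGC" and no motif
  set.seed(77)
  base <- paste(sample(c("A", "C", "G"), 4000, TRUE), collapse = "")  # no T: no TCGA
  l1 <- base
  substr(l1, 1998, 2000) <- "AGC"
  l2 <- paste(sample(c("A", "C", "G"), 4000, TRUE), collapse = "")
  substr(l2, 2498, 2500) <- "AGC"
  hA <- Haplome("A", Biostrings::DNAStringSet(c(c1 = l1, c2 = l2)))
  hB <- Haplome("B", Biostrings::DNAStringSet(c(c1 = l1, c2 = l2)))
  blocks <- list(c1 = data.frame(a_start = 1L, b_start = 1L, len = 4000L),
                 c2 = data.frame(a_start = 1L, b_start = 1L, len = 4000L))
  dref <- DualReference(hA, hB, c(c1 = "c1", c2 = "c2"), blocks)
  idx <- list(A = scan_restriction_sites(dref$A),
              B = scan_restriction_sites(dref$B))
  region <- data.frame(hap = "A", chrom = "c1", window_start = 1501L,
                       side = "right", n_clips = 10L, fraction = 0.4,
                       anchor_pos = 2000L)
  partner <- list(hap = "A", chrom = "c2", start = 2501L, end = 2560L,
                  strand = "+", score = 60, evalue = 1e-20, inserted = 0L,
                  ambiguous = FALSE)
  j <- reconstruct_junction(region, partner, dref, idx)
  expect_gte(j$overlap_len, 3L)
  expect_true(grepl("AGC", j$overlap_seq, fixed = TRUE))
  expect_false(j$contains_restriction_site)
  ## blunt join with an insertion: overlap may exist but insertion recorded
  partner$inserted <- 1L
  j2 <- reconstruct_junction(region, partner, dref, idx)
  expect_equal(j2$inserted, 1L)
  expect_false(j2$contains_restriction_site)
})

test_that("mechanism rules are mutually exclusive and fire in priority order", {
  base <- data.frame(repeat_left = NA_character_, repeat_right = NA_character_,
                     contains_restriction_site = FALSE, at_site_left = FALSE,
                     at_site_right = FALSE, inserted = 0L, overlap_len = 0L)
  expect_equal(classify_mechanism(base)$mechanism, "unclassified")
  ty <- base; ty$repeat_left <- ty$repeat_right <- "ty_like"
  expect_equal(classify_mechanism(ty)$mechanism, "homologous")
  ## repeat context wins even over a motif-spanning junction
  ty2 <- ty; ty2$contains_restriction_site <- TRUE
  ty2$at_site_left <- ty2$at_site_right <- TRUE
  expect_equal(classify_mechanism(ty2)$mechanism, "homologous")
  taqi <- base; taqi$contains_restriction_site <- TRUE
  taqi$at_site_left <- taqi$at_site_right <- TRUE
  expect_equal(classify_mechanism(taqi)$mechanism, "taqi_direct")
  mh <- base; mh$overlap_len <- 2L
  expect_equal(classify_mechanism(mh)$mechanism, "microhomology")
  ## a 2-3 nt overlap that spans a motif is not microhomology
  mh2 <- mh; mh2$contains_restriction_site <- TRUE
  expect_equal(classify_mechanism(mh2)$mechanism, "unclassified")
  ## property: over random flag combinations exactly one mechanism returns
  set.seed(3)
  for (i in 1:200) {
    jj <- base
    jj$repeat_left <- sample(c(NA, "ty_like", "rDNA"), 1)
    jj$repeat_right <- sample(c(NA, "ty_like", "rDNA"), 1)
    jj$contains_restriction_site <- sample(c(TRUE, FALSE), 1)
    jj$at_site_left <- sample(c(TRUE, FALSE), 1)
    jj$at_site_right <- sample(c(TRUE, FALSE), 1)
    jj$inserted <- sample(0:2, 1)
    jj$overlap_len <- sample(0:5, 1)
    m <- classify_mechanism(jj)$mechanism
    expect_true(m %in% c("homologous", "taqi_direct", "microhomology",
                         "unclassified"))
  }
})

test_that("planted junctions are reconstructed reciprocally with correct mechanisms", {
  dref <- std_dref()
  sim <- std_experiment()
  calls <- std_detection()$junctions
  jn <- sim$truth$junctions
  for (k in seq_len(nrow(jn))) {
    hit <- calls$hap_left == jn$hap_left[k] &
      calls$chrom_left == jn$chrom_left[k] &
      calls$pos_left == jn$pos_left[k] &
      calls$pos_right == jn$pos_right[k]
    expect_equal(sum(hit), 1L)
    expect_equal(calls$mechanism[hit], jn$mechanism[k])
    expect_true(calls$reciprocal[hit])
    expect_equal(calls$status[hit], "confirmed")
  }
})
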