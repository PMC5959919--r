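toy_yeast_calls <- function() {
  ## 10 records over 3 samples: 3 masked, 2 low-coverage, 1 shared by all
  data.frame(
    sample = c("s1", "s1", "s1", "s2", "s2", "s2", "s3", "s3", "s1", "s2"),
    chrom = "c1",
    pos = c(50, 500, 900, 1500, 2500, 3500, 4500, 5500, 6500, 6500),
    ref = "A",
    alt = c("T", "G", "C", "T", "G", "C", "T", "G", "C", "C"),
    type = "SNV",
    depth = c(80, 80, 80, 39, 30, 80, 80, 80, 80, 80))
}

test_that("yeast post-filters match brute-force rule application", {
  calls <- toy_yeast_calls()
  ## make pos 6500 alt C present in every sample
  calls <- rbind(calls, data.frame(sample = "s3", chrom = "c1", pos = 6500,
                                   ref = "A", alt = "C", type = "SNV",
                                   depth = 80))
  masks <- data.frame(chrom = "c1", start = c(1, 800, 2400),
                      end = c(100, 1000, 2600),
                      class = c("telomere", "AT_rich", "rDNA"))
  cov <- c(s1 = 80, s2 = 80, s3 = 80)
  out <- filter_yeast_variants(calls, cov, masks)
  ## independent brute-force oracle
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    masked <- any(masks$start <= calls$pos[i] & masks$end >= calls$pos[i])
    low <- calls$depth[i] < 0.5 * cov[[calls$sample[i]]]
    key <- paste(calls$chrom[i], calls$pos[i], calls$ref[i], calls$alt[i])
    keys <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
    shared <- length(unique(calls$sample[keys == key])) == 3
    keep[i] <- !masked && !low && !shared
  }
  expect_equal(nrow(out$passed), sum(keep))
  expect_setequal(paste(out$passed$sample, out$passed$pos),
                  paste(calls$sample[keep], calls$pos[keep]))
  ## boundary: coverage ratio 0.49 is removed (strict < 0.5); a record both
  ## masked and low-coverage reports the mask reason first
  expect_true(1500 %in% out$removed$pos[out$removed$reason == "low_coverage"])
  expect_true(2500 %in% out$removed$pos[out$removed$reason == "masked_region"])
  b <- calls[4, ]; b$depth <- 39        # 39/80 = 0.4875
  expect_equal(nrow(filter_yeast_variants(b, cov, masks)$passed), 0L)
  b$depth <- 40                          # exactly 0.5: kept
  expect_equal(nrow(filter_yeast_variants(b, cov, masks)$passed), 1L)
  expect_error(filter_yeast_variants(calls, c(s1 = 80), masks), "coverage")
})

toy_plant_calls <- function() {
  data.frame(
    sample = "p1", chrom = "c1",
    pos = c(100, 200, 300, 400, 500, 500, 600, 700, 703, 900),
    ref = c("A", "A", "A", "A", "A", "A", "ATT", "ATTT", "A", "AG"),
    alt = c("T", "G", "C", "T", "G", "T", "A", "A", "AGG", "A"),
    type = c("SNV", "SNV", "SNV", "SNV", "SNV", "SNV", "InDel", "InDel",
             "InDel", "InDel"),
    depth = rep(100, 10),
    alt_count = c(50, 40, 60, 80, 55, 50, 70, 80, 60, 90))
}

test_that("plant post-filters apply frequency, control and uniqueness rules", {
  calls <- toy_plant_calls()
  control <- data.frame(chrom = "c1", pos = 100, ref = "A", alt = "T")
  ctrl_ev <- data.frame(chrom = "c1", pos = c(600, 700, 703, 900),
                        ref = c("ATT", "ATTT", "A", "AG"),
                        alt = c("A", "A", "AGG", "A"),
                        n_reads = c(0, 1, 0, 2))
  out <- filter_plant_variants(calls, control, ctrl_ev)
  passed_pos <- out$passed$pos
  ## pos 100: in control -> out.  pos 200: freq 0.40 exactly -> out (strict >).
  expect_false(100 %in% passed_pos)
  expect_false(200 %in% passed_pos)
  ## pos 500 twice with different alts: multi-allelic SNV locus -> out
  expect_false(500 %in% passed_pos)
  ## pos 700/703 overlap in footprint: InDels not unique -> out
  expect_false(700 %in% passed_pos)
  expect_false(703 %in% passed_pos)
  ## pos 900: 2 control reads -> out (strict < 2)
  expect_false(900 %in% passed_pos)
  ## survivors: 300, 400, 600
  expect_setequal(passed_pos, c(300, 400, 600))
  ## an InDel without control evidence is held, not passed
  calls2 <- calls[calls$pos == 600, ]
  out2 <- filter_plant_variants(calls2, control,
                                data.frame(chrom = character(),
                                           pos = numeric(), ref = character(),
                                           alt = character(),
                                           n_reads = numeric()))
  expect_equal(nrow(out2$passed), 0L)
  expect_equal(out2$held$pos, 600)
})

test_that("filters are pure predicates: survivor sets are order-independent", {
  calls <- toy_plant_calls()
  control <- data.frame(chrom = "c1", pos = 100, ref = "A", alt = "T")
  ctrl_ev <- data.frame(chrom = "c1", pos = c(600, 700, 703, 900),
                        ref = c("ATT", "ATTT", "A", "AG"),
                        alt = c("A", "A", "AGG", "A"),
                        n_reads = c(0, 1, 0, 2))
  ref_out <- filter_plant_variants(calls, control, ctrl_ev)
  set.seed(8)
  for (i in 1:5) {
    perm <- sample(nrow(calls))
    out <- filter_plant_variants(calls[perm, ], control, ctrl_ev)
    expect_setequal(paste(out$passed$pos, out$passed$alt),
                    paste(ref_out$passed$pos, ref_out$passed$alt))
  }
})

test_that("the AT-rich helper masks windows above the threshold", {
  s <- paste0(paste(rep("AT", 100), collapse = ""),              # 200 bp AT
              paste(rep("GC", 200), collapse = ""))              # 400 bp GC
  h <- Haplome("A", Biostrings::DNAStringSet(c(c1 = s)))
  m <- at_rich_mask(h, window = 100)
  expect_true(all(m$end <= 220))
  expect_gte(nrow(m), 2L)
})
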