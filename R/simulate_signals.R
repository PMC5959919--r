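## expected copy number per bin on one parental reference, from segment maps
cn_bins <- function(genome, dual_ref, hap, bin_size) {
  hp <- haplome_of(dual_ref, hap)
  out <- list()
  for (ch in names(hp$lengths)) {
    L <- hp$lengths[[ch]]
    nb <- ceiling(L / bin_size)
    cn <- numeric(nb)
    for (cp in genome$copies) {
      sg <- cp$segments
      sg <- sg[sg$hap == hap & sg$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(sg))) {
        b1 <- (sg$start[i] - 1L) %/% bin_size + 1L
        b2 <- (sg$end[i] - 1L) %/% bin_size + 1L
        cn[b1:b2] <- cn[b1:b2] + 1
      }
    }
    out[[ch]] <- cn
  }
  out
}

## logical mask per bin (telomeres + rDNA) for one haplome
mask_bins <- function(haplome, bin_size) {
  out <- list()
  rdna <- haplome$repeats
  rdna <- if (is.null(rdna)) NULL else rdna[rdna$class == "rDNA", , drop = FALSE]
  for (ch in names(haplome$lengths)) {
    nb <- ceiling(haplome$lengths[[ch]] / bin_size)
    m <- logical(nb)
    mark <- function(df) {
      if (is.null(df) || nrow(df) == 0) return(invisible(NULL))
      sub <- df[df$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        b1 <- (sub$start[i] - 1L) %/% bin_size + 1L
        b2 <- (sub$end[i] - 1L) %/% bin_size + 1L
        m[b1:b2] <<- TRUE
      }
    }
    mark(haplome$telomeres)
    mark(rdna)
    out[[ch]] <- m
  }
  out
}

#' Simulate per-haplotype binned coverage tracks
#'
#' Coverage is synthesized from the copy-number oracle implied by the
#' restructured genome's segment maps (reads from each haplotype map to
#' their own parental reference), then optionally noised with a negative
#' binomial (variance \code{mu + dispersion * mu^2}).  This replaces
#' read simulation + alignment, which the detection logic does not need:
#' it consumes tracks.
#'
#' @param genome \code{RestructuredGenome} from \code{\link{plant_events}}.
#' @param dual_ref matching \code{\link{DualReference}}.
#' @param mean_depth sequencing depth per chromosome copy (default 80).
#' @param bin_size bin width in bp (default 100).
#' @param noise \code{"none"} (expected depth) or \code{"nb"}.
#' @param dispersion negative-binomial dispersion (default 0.1).
#' @param seed RNG seed used when \code{noise = "nb"}.
#' @return list with elements \code{A} and \code{B}; each a
#'   \code{CoverageTrack} data.frame \code{chrom,start,end,cn,depth,masked}
#'   with attributes \code{haplotype}, \code{bin_size}, \code{mean_depth}.
#' @export
simulate_coverage <- function(genome, dual_ref, mean_depth = 80,
                              bin_size = 100, noise = c("none", "nb"),
                              dispersion = 0.1, seed = 1L) {
  noise <- match.arg(noise)
  if (bin_size > min(c(dual_ref$A$lengths, dual_ref$B$lengths))) {
    stop_input("bin size exceeds chromosome length")
  }
  set.seed(seed)
  out <- list()
  for (hap in c("A", "B")) {
    hp <- haplome_of(dual_ref, hap)
    cn <- cn_bins(genome, dual_ref, hap, bin_size)
    msk <- mask_bins(hp, bin_size)
    rows <- lapply(names(cn), function(ch) {
      nb <- length(cn[[ch]])
      start <- (seq_len(nb) - 1L) * bin_size + 1L
      end <- pmin(seq_len(nb) * bin_size, hp$lengths[[ch]])
      mu <- cn[[ch]] * mean_depth
      depth <- if (noise == "none") mu else {
        rnbinom(nb, mu = mu, size = 1 / dispersion)
      }
      data.frame(chrom = ch, start = start, end = end, cn = cn[[ch]],
                 depth = depth, masked = msk[[ch]])
    })
    tr <- do.call(rbind, rows)
    attr(tr, "haplotype") <- hap
    attr(tr, "bin_size") <- bin_size
    attr(tr, "mean_depth") <- mean_depth
    out[[hap]] <- tr
  }
  out
}

#' Simulate array-CGH probe log-ratios
#'
#' Probes tile parent A coordinates; each reports
#' \code{log10(total copy number / baseline ploidy)} plus Gaussian noise,
#' emulating two-color relative fluorescence intensity.
#'
#' @param genome,dual_ref as in \code{\link{simulate_coverage}}.
#' @param probe_spacing distance between probes in bp (> 0).
#' @param noise_sd Gaussian noise SD on the log10 scale.
#' @param baseline_ploidy copy number of the euploid state (2 for the fused
#'   diploid).
#' @param seed RNG seed.
#' @return \code{ArrayTrack} data.frame \code{chrom,pos,log10_ratio}.
#' @export
simulate_acgh <- function(genome, dual_ref, probe_spacing = 1000,
                          noise_sd = 0.03, baseline_ploidy = 2, seed = 1L) {
  if (probe_spacing <= 0) stop_input("probe spacing must be positive")
  set.seed(seed)
  bin_size <- 100L
  cnA <- cn_bins(genome, dual_ref, "A", bin_size)
  cnB <- cn_bins(genome, dual_ref, "B", bin_size)
  rows <- lapply(names(dual_ref$A$lengths), function(ch) {
    L <- dual_ref$A$lengths[[ch]]
    pos <- seq(probe_spacing, L - 1L, by = probe_spacing)
    if (length(pos) == 0) return(NULL)
    bA <- (pos - 1L) %/% bin_size + 1L
    posB <- vapply(pos, function(p) liftover_pos(dual_ref, "A", ch, p), numeric(1))
    chB <- homolog_chrom(dual_ref, "A", ch)
    bB <- pmin((posB - 1L) %/% bin_size + 1L, length(cnB[[chB]]))
    total <- cnA[[ch]][bA] + cnB[[chB]][bB]
    data.frame(chrom = ch, pos = pos,
               log10_ratio = log10(pmax(total, 0.05) / baseline_ploidy) +
                 rnorm(length(pos), 0, noise_sd))
  })
  do.call(rbind, rows)
}

#' Simulate soft-clip and discordant-pair junction evidence
#'
#' For every truth junction, emits soft-clip records on both sides (anchor
#' locus on the parental reference, clipped tail copied from the partner
#' side of the derivative chromosome) and discordant read pairs straddling
#' the junction, at rates proportional to depth.  Background clips and
#' pairs with random loci/sequences are added at a configurable rate; they
#' never accumulate past the boundary-region detection threshold.
#'
#' @param genome,dual_ref as in \code{\link{simulate_coverage}} (the
#'   genome's truth junctions are taken from \code{truth}).
#' @param truth \code{TruthSet} from \code{\link{plant_events}}.
#' @param read_len read length in nt (>= 60: clipped tails need a minimal
#'   anchor plus enough sequence to span any microhomology).
#' @param mean_depth per-copy depth; 0 yields no records.
#' @param clip_rate,pair_rate expected records per junction side as a
#'   fraction of depth.
#' @param bg_clip_per_mb background clip records per Mb of reference.
#' @param seed RNG seed.
#' @return \code{JunctionEvidence}: list with \code{clips} (data.frame
#'   \code{hap,chrom,pos,side,seq}), \code{pairs} (data.frame
#'   \code{hap_a,chrom_a,pos_a,hap_b,chrom_b,pos_b,orient}),
#'   \code{mean_depth}, \code{read_len}.
#' @export
simulate_junction_evidence <- function(genome, truth, dual_ref,
                                       read_len = 150, mean_depth = 80,
                                       clip_rate = 0.4, pair_rate = 0.3,
                                       bg_clip_per_mb = 10, seed = 1L) {
  if (read_len < 60) stop_input("read length too short for junction anchoring")
  set.seed(seed)
  clips <- list(); pairs <- list()
  max_clip <- read_len - 20L
  if (mean_depth > 0) {
    jn <- truth$junctions
    for (i in seq_len(nrow(jn))) {
      hl <- jn$hap_left[i]; cl <- jn$chrom_left[i]; pl <- jn$pos_left[i]
      hr <- jn$hap_right[i]; cr <- jn$chrom_right[i]; pr <- jn$pos_right[i]
      n1 <- rpois(1, clip_rate * mean_depth)
      if (n1 > 0) {
        lens <- sample(60:max_clip, n1, replace = TRUE)
        seqs <- vapply(lens, function(w) {
          subseq_chr(haplome_of(dual_ref, hr), cr, pr, pr + w - 1L)
        }, character(1))
        clips[[length(clips) + 1L]] <- data.frame(
          hap = hl, chrom = cl, pos = pl, side = "right", seq = seqs)
      }
      n2 <- rpois(1, clip_rate * mean_depth)
      if (n2 > 0) {
        lens <- sample(60:max_clip, n2, replace = TRUE)
        seqs <- vapply(lens, function(w) {
          subseq_chr(haplome_of(dual_ref, hl), cl, pl - w + 1L, pl)
        }, character(1))
        clips[[length(clips) + 1L]] <- data.frame(
          hap = hr, chrom = cr, pos = pr, side = "left", seq = seqs)
      }
      n3 <- rpois(1, pair_rate * mean_depth)
      if (n3 > 0) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          hap_a = hl, chrom_a = cl, pos_a = pl - sample(150:600, n3, TRUE),
          hap_b = hr, chrom_b = cr, pos_b = pr + sample(150:600, n3, TRUE),
          orient = "junction")
      }
    }
    ## background noise
    gsize <- sum(dual_ref$A$lengths) + sum(dual_ref$B$lengths)
    n_bg <- rpois(1, bg_clip_per_mb * gsize / 1e6)
    if (n_bg > 0) {
      hap <- sample(c("A", "B"), n_bg, TRUE)
      chs <- vapply(hap, function(h) {
        sample1(names(haplome_of(dual_ref, h)$lengths))
      }, character(1))
      pos <- vapply(seq_len(n_bg), function(i) {
        sample(200:(haplome_of(dual_ref, hap[i])$lengths[[chs[i]]] - 200L), 1L)
      }, integer(1))
      clips[[length(clips) + 1L]] <- data.frame(
        hap = hap, chrom = chs, pos = pos,
        side = sample(c("left", "right"), n_bg, TRUE),
        seq = vapply(sample(60:max_clip, n_bg, TRUE), rand_dna, character(1)))
      pairs[[length(pairs) + 1L]] <- data.frame(
        hap_a = hap, chrom_a = chs, pos_a = pos,
        hap_b = sample(c("A", "B"), n_bg, TRUE),
        chrom_b = sample(names(dual_ref$A$lengths), n_bg, TRUE),
        pos_b = pos + sample(-5000:5000, n_bg, TRUE),
        orient = sample(c("tandem", "inverted"), n_bg, TRUE))
    }
  }
  empty_clips <- data.frame(hap = character(), chrom = character(),
                            pos = integer(), side = character(),
                            seq = character())
  empty_pairs <- data.frame(hap_a = character(), chrom_a = character(),
                            pos_a = integer(), hap_b = character(),
                            chrom_b = character(), pos_b = integer(),
                            orient = character())
  structure(list(
    clips = if (length(clips)) do.call(rbind, clips) else empty_clips,
    pairs = if (length(pairs)) do.call(rbind, pairs) else empty_pairs,
    mean_depth = mean_depth, read_len = read_len),
    class = "JunctionEvidence")
}

#' Simulate a 3D chromosome coordinate model
#'
#' Each parent-A chromosome becomes a confined random-walk polyline inside
#' a nucleus of the given diameter, with anchors at fixed genomic spacing.
#' Used to exercise the 3D-proximity null machinery without the published
#' coordinate model.
#'
#' @param dual_ref a \code{\link{DualReference}}.
#' @param nuclear_diameter_um nuclear diameter in micrometres (default 2).
#' @param anchor_spacing genomic distance between anchors in bp.
#' @param step_sd per-step displacement SD in micrometres.
#' @param seed RNG seed.
#' @return A \code{\link{CoordinateModel}}.
#' @export
simulate_coordinate_model <- function(dual_ref, nuclear_diameter_um = 2,
                                      anchor_spacing = 5000, step_sd = 0.08,
                                      seed = 1L) {
  if (nuclear_diameter_um <= 0) stop_input("nuclear diameter must be positive")
  set.seed(seed)
  r <- nuclear_diameter_um / 2
  rows <- lapply(names(dual_ref$A$lengths), function(ch) {
    L <- dual_ref$A$lengths[[ch]]
    pos <- unique(c(seq(1L, L, by = anchor_spacing), L))
    n <- length(pos)
    xyz <- matrix(0, n, 3)
    repeat {
      p0 <- runif(3, -r, r)
      if (sqrt(sum(p0^2)) < 0.8 * r) break
    }
    xyz[1, ] <- p0
    for (i in 2:n) {
      repeat {
        cand <- xyz[i - 1, ] + rnorm(3, 0, step_sd)
        if (sqrt(sum(cand^2)) <= r) break
      }
      xyz[i, ] <- cand
    }
    data.frame(chrom = ch, pos = pos, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  CoordinateModel(do.call(rbind, rows))
}
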