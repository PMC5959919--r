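#' Normalize a coverage track to copy-ratio scale
#'
#' Divides per-bin depth by the genome-wide median depth of unmasked bins.
#' Masked bins (telomeres, rDNA, optional extra masks) keep their ratio but
#' are excluded from all statistics downstream.
#'
#' @param track a \code{CoverageTrack} data.frame from
#'   \code{\link{simulate_coverage}} (columns \code{chrom,start,end,depth,
#'   masked}).
#' @param extra_masks optional data.frame \code{chrom,start,end} of
#'   additional regions to mask.
#' @return The track with an added \code{ratio} column and attribute
#'   \code{"genome_median"}.
#' @export
normalize_coverage <- function(track, extra_masks = NULL) {
  masked <- track$masked
  if (!is.null(extra_masks) && nrow(extra_masks) > 0) {
    for (i in seq_len(nrow(extra_masks))) {
      masked <- masked | (track$chrom == extra_masks$chrom[i] &
                            track$start <= extra_masks$end[i] &
                            track$end >= extra_masks$start[i])
    }
  }
  if (all(masked)) stop_input("all bins masked; cannot normalize")
  med <- median(track$depth[!masked])
  if (!is.finite(med) || med <= 0) stop_input("genome-wide median depth is zero")
  out <- track
  out$masked <- masked
  out$ratio <- track$depth / med
  attr(out, "genome_median") <- med
  attr(out, "haplotype") <- attr(track, "haplotype")
  attr(out, "bin_size") <- attr(track, "bin_size")
  out
}

## combined (A+B)/2 ratio on parent-A bin coordinates; homolog bins are
## matched by index (bin drift from InDels is < one bin at desk scale)
combined_ratio_track <- function(ratio_tracks, dual_ref) {
  a <- ratio_tracks$A; b <- ratio_tracks$B
  rows <- lapply(unique(a$chrom), function(ch) {
    ra <- a[a$chrom == ch, , drop = FALSE]
    chB <- homolog_chrom(dual_ref, "A", ch)
    rb <- b[b$chrom == chB, , drop = FALSE]
    n <- nrow(ra)
    idx <- pmin(seq_len(n), nrow(rb))
    data.frame(chrom = ch, start = ra$start, end = ra$end,
               ratio = (ra$ratio + rb$ratio[idx]) / 2,
               masked = ra$masked | rb$masked[idx])
  })
  out <- do.call(rbind, rows)
  attr(out, "bin_size") <- attr(a, "bin_size")
  out
}

#' Call whole-chromosome copy-number changes (aneuploidy)
#'
#' A chromosome is a candidate gain when its median sequencing copy ratio
#' (averaged over the two haplotype tracks) is at or above
#' \code{gain_threshold}, and a candidate loss below \code{loss_threshold};
#' the array platform is tested symmetrically on median probe log-ratio.
#' Only chromosome-wide changes supported by \emph{both} platforms are
#' given status \code{aneuploidy}; single-platform candidates are emitted
#' as \code{unconfirmed}.  A missing array yields a warning and only
#' unconfirmed calls, never an aneuploidy.
#'
#' @param ratio_tracks list \code{A}/\code{B} of normalized tracks from
#'   \code{\link{normalize_coverage}}.
#' @param array_track \code{ArrayTrack} data.frame or \code{NULL}.
#' @param dual_ref the \code{\link{DualReference}}.
#' @param gain_threshold,loss_threshold sequencing copy-ratio thresholds
#'   (defaults 1.35 / 0.65: midway between euploid and a single-copy change
#'   in a diploid).
#' @param array_gain,array_loss array log10-ratio thresholds (defaults
#'   +/- log10(1.25)).
#' @param baseline_ploidy ploidy of the euploid state.
#' @return data.frame of \code{CnvCall}s: \code{chrom, whole_chrom,
#'   direction, copy_estimate, seq_ratio, array_ratio, seq_support,
#'   array_support, status}.
#' @export
call_aneuploidy <- function(ratio_tracks, array_track, dual_ref,
                            gain_threshold = 1.35, loss_threshold = 0.65,
                            array_gain = log10(1.25),
                            array_loss = -log10(1.25),
                            baseline_ploidy = 2) {
  have_array <- !is.null(array_track) && nrow(array_track) > 0
  if (!have_array) {
    warning("array track missing: chromosome-wide calls cannot be ",
            "confirmed as aneuploidy")
  }
  rows <- lapply(names(dual_ref$pairing), function(ch) {
    ra <- ratio_tracks$A
    rb <- ratio_tracks$B
    chB <- homolog_chrom(dual_ref, "A", ch)
    medA <- median(ra$ratio[ra$chrom == ch & !ra$masked])
    medB <- median(rb$ratio[rb$chrom == chB & !rb$masked])
    seq_ratio <- (medA + medB) / 2
    seq_dir <- if (seq_ratio >= gain_threshold) "gain"
      else if (seq_ratio <= loss_threshold) "loss" else "none"
    if (have_array) {
      arr <- median(array_track$log10_ratio[array_track$chrom == ch])
      arr_dir <- if (arr >= array_gain) "gain"
        else if (arr <= array_loss) "loss" else "none"
    } else {
      arr <- NA_real_; arr_dir <- "none"
    }
    if (seq_dir == "none" && arr_dir == "none") return(NULL)
    direction <- if (seq_dir != "none") seq_dir else arr_dir
    seq_support <- seq_dir == direction && seq_dir != "none"
    array_support <- arr_dir == direction && arr_dir != "none"
    data.frame(chrom = ch, whole_chrom = TRUE, direction = direction,
               copy_estimate = round(seq_ratio * baseline_ploidy, 2),
               seq_ratio = seq_ratio, array_ratio = arr,
               seq_support = seq_support, array_support = array_support,
               status = if (seq_support && array_support) "aneuploidy"
                        else "unconfirmed")
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), whole_chrom = logical(),
                      direction = character(), copy_estimate = numeric(),
                      seq_ratio = numeric(), array_ratio = numeric(),
                      seq_support = logical(), array_support = logical(),
                      status = character())
  }
  out
}

#' Segment local (sub-chromosomal) CNVs from a copy-ratio track
#'
#' Run-length thresholding: maximal runs of unmasked bins at or beyond the
#' gain/loss thresholds, merged across gaps up to \code{merge_gap} bp, kept
#' when at least \code{min_length} long.  Runs covering essentially a whole
#' chromosome are routed to the aneuploidy logic instead (flagged
#' \code{whole_chrom}).
#'
#' @param ratio_track combined copy-ratio track (data.frame
#'   \code{chrom,start,end,ratio,masked}), e.g. from the internal combined
#'   A/B track used by \code{\link{detect_rearrangements}}.
#' @param min_length minimum segment length in bp (default 100 kb; must be
#'   at least one bin).
#' @param gain_threshold,loss_threshold ratio thresholds as in
#'   \code{\link{call_aneuploidy}}.
#' @param merge_gap bridge sub-threshold gaps up to this many bp.
#' @param whole_chrom_frac fraction of the chromosome above which a run is
#'   considered chromosome-wide.
#' @return data.frame \code{chrom,start,end,length,direction,mean_ratio,
#'   whole_chrom}.
#' @export
segment_local_cnv <- function(ratio_track, min_length = 1e5,
                              gain_threshold = 1.35, loss_threshold = 0.65,
                              merge_gap = 1000, whole_chrom_frac = 0.95) {
  bin_size <- attr(ratio_track, "bin_size") %||%
    (ratio_track$end[1] - ratio_track$start[1] + 1L)
  if (min_length < bin_size) stop_input("min_length smaller than bin size")
  rows <- list()
  for (ch in unique(ratio_track$chrom)) {
    tr <- ratio_track[ratio_track$chrom == ch, , drop = FALSE]
    chrom_len <- max(tr$end)
    for (dir in c("gain", "loss")) {
      hit <- if (dir == "gain") tr$ratio >= gain_threshold
             else tr$ratio <= loss_threshold
      hit[tr$masked] <- FALSE
      if (!any(hit)) next
      r <- rle(hit)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      segs <- data.frame(b1 = starts[r$values], b2 = ends[r$values])
      ## merge across small gaps
      if (nrow(segs) > 1) {
        merged <- segs[1, , drop = FALSE]
        for (i in 2:nrow(segs)) {
          gap_bp <- (segs$b1[i] - merged$b2[nrow(merged)] - 1L) * bin_size
          if (gap_bp <= merge_gap) {
            merged$b2[nrow(merged)] <- segs$b2[i]
          } else {
            merged <- rbind(merged, segs[i, ])
          }
        }
        segs <- merged
      }
      for (i in seq_len(nrow(segs))) {
        s <- tr$start[segs$b1[i]]; e <- tr$end[segs$b2[i]]
        len <- e - s + 1L
        if (len < min_length) next
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = s, end = e, length = len, direction = dir,
          mean_ratio = mean(tr$ratio[segs$b1[i]:segs$b2[i]]),
          whole_chrom = len >= whole_chrom_frac * chrom_len)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               length = integer(), direction = character(),
               mean_ratio = numeric(), whole_chrom = logical())
  }
}
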