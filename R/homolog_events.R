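#' Find zero-coverage candidate regions on one haplotype
#'
#' Maximal runs of unmasked bins with depth at or below
#' \code{zero_cutoff}, merged across gaps (of covered or masked bins) up to
#' \code{merge_gap} bp, kept when at least \code{min_len} long.  These are
#' the candidate loss-of-heterozygosity tracts to be tested for reciprocal
#' double coverage on the homolog.
#'
#' @param track raw \code{CoverageTrack} data.frame for one haplotype.
#' @param min_len minimum candidate length in bp (default 500).
#' @param merge_gap bridge gaps up to this many bp (default 200).
#' @param zero_cutoff maximum depth for a "zero" bin (default 0).
#' @return data.frame \code{hap,chrom,start,end,length}.
#' @export
find_zero_coverage_regions <- function(track, min_len = 500, merge_gap = 200,
                                       zero_cutoff = 0) {
  hap <- attr(track, "haplotype")
  bin_size <- attr(track, "bin_size") %||%
    (track$end[1] - track$start[1] + 1L)
  rows <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    zero <- tr$depth <= zero_cutoff & !tr$masked
    bridge <- tr$masked                    # masked bins neither break nor count
    if (!any(zero)) next
    idx <- which(zero)
    grp <- cumsum(c(1L, diff(idx) > 1L))
    ## allow masked-bin and short gaps to merge neighbouring runs
    segs <- do.call(rbind, lapply(split(idx, grp), function(ii) {
      data.frame(b1 = min(ii), b2 = max(ii))
    }))
    if (nrow(segs) > 1) {
      merged <- segs[1, , drop = FALSE]
      for (i in 2:nrow(segs)) {
        gap_bins <- (merged$b2[nrow(merged)] + 1L):(segs$b1[i] - 1L)
        gap_open <- gap_bins[!bridge[gap_bins]]
        if (length(gap_open) * bin_size <= merge_gap) {
          merged$b2[nrow(merged)] <- segs$b2[i]
        } else {
          merged <- rbind(merged, segs[i, ])
        }
      }
      segs <- merged
    }
    for (i in seq_len(nrow(segs))) {
      s <- tr$start[segs$b1[i]]; e <- tr$end[segs$b2[i]]
      if (e - s + 1L < min_len) next
      rows[[length(rows) + 1L]] <- data.frame(hap = hap, chrom = ch,
                                              start = s, end = e,
                                              length = e - s + 1L)
    }
  }
  if (length(rows)) do.call(rbind, rows) else {
    data.frame(hap = character(), chrom = character(), start = integer(),
               end = integer(), length = integer())
  }
}

#' Test a candidate tract for reciprocal double coverage on the homolog
#'
#' Lifts the candidate interval onto the homologous chromosome and compares
#' the homolog's mean copy ratio over the lifted interval against
#' \code{double_threshold}.  A candidate that fails (homolog at single
#' copy) is explained by a deletion and belongs to the CNV module, not to
#' the inter-homolog event classes.
#'
#' @param candidate one row of \code{\link{find_zero_coverage_regions}}
#'   output (list or single-row data.frame with \code{hap,chrom,start,end}).
#' @param homolog_ratio_track normalized track of the \emph{other}
#'   haplotype.
#' @param dual_ref the \code{\link{DualReference}}.
#' @param double_threshold minimum homolog mean ratio (default 1.6,
#'   expected 2.0 for a converted tract).
#' @return list \code{pass, homolog_ratio, lifted} (the lifted interval).
#' @export
test_homolog_reciprocity <- function(candidate, homolog_ratio_track, dual_ref,
                                     double_threshold = 1.6) {
  lift <- liftover(dual_ref, candidate$hap, candidate$chrom,
                   candidate$start, candidate$end)
  tr <- homolog_ratio_track
  sel <- tr$chrom == lift$chrom & tr$start <= lift$end & tr$end >= lift$start &
    !tr$masked
  ratio <- if (any(sel)) mean(tr$ratio[sel]) else NA_real_
  list(pass = isTRUE(ratio >= double_threshold), homolog_ratio = ratio,
       lifted = lift)
}

#' Classify a reciprocity-passing tract as BIR or SGC
#'
#' A chimeric tract that reaches a chromosome end (within the telomere mask
#' plus \code{end_slack}) is a break-induced repair; an internal tract is a
#' short gene conversion with its length recorded.  A tract covering
#' essentially the whole chromosome is routed out (aneuploidy /
#' whole-chromosome LOH review), as is any candidate that failed
#' reciprocity.
#'
#' @param candidate,support as in \code{\link{test_homolog_reciprocity}}.
#' @param dual_ref the \code{\link{DualReference}}.
#' @param end_slack slack beyond the telomere mask in bp (default 1000).
#' @return data.frame row with \code{type} in \code{BIR,SGC,routed_out},
#'   acceptor/donor haplotypes, interval and support, or \code{NULL} when
#'   reciprocity failed.
#' @export
classify_homolog_event <- function(candidate, support, dual_ref,
                                   end_slack = 1000) {
  if (!support$pass) return(NULL)
  hp <- haplome_of(dual_ref, candidate$hap)
  L <- hp$lengths[[candidate$chrom]]
  tel <- hp$telomeres[hp$telomeres$chrom == candidate$chrom, , drop = FALSE]
  left_lim <- max(1L, tel$end[tel$start == 1]) + end_slack
  right_lim <- min(L, tel$start[tel$end == L]) - end_slack
  reaches_left <- candidate$start <= left_lim
  reaches_right <- candidate$end >= right_lim
  typ <- if (reaches_left && reaches_right) "routed_out"
         else if (reaches_left || reaches_right) "BIR" else "SGC"
  data.frame(type = typ, acceptor_hap = candidate$hap,
             donor_hap = if (candidate$hap == "A") "B" else "A",
             chrom = candidate$chrom, start = candidate$start,
             end = candidate$end, length = candidate$end - candidate$start + 1L,
             extends_to_end = typ == "BIR",
             homolog_ratio = support$homolog_ratio)
}

#' Detect inter-homolog events (BIR and SGC) from a coverage track pair
#'
#' Runs the three-stage procedure: zero-coverage candidates on each
#' haplotype, reciprocal double-coverage test on the homolog, and
#' terminal/internal classification.
#'
#' @param cov_tracks list \code{A}/\code{B} of raw coverage tracks.
#' @param dual_ref the \code{\link{DualReference}}.
#' @param min_len,merge_gap,zero_cutoff see
#'   \code{\link{find_zero_coverage_regions}}.
#' @param double_threshold see \code{\link{test_homolog_reciprocity}}.
#' @param end_slack see \code{\link{classify_homolog_event}}.
#' @return data.frame of classified events (BIR/SGC only).
#' @export
call_homolog_events <- function(cov_tracks, dual_ref, min_len = 500,
                                merge_gap = 200, zero_cutoff = 0,
                                double_threshold = 1.6, end_slack = 1000) {
  ratio <- list(A = normalize_coverage(cov_tracks$A),
                B = normalize_coverage(cov_tracks$B))
  rows <- list()
  for (hap in c("A", "B")) {
    oth <- if (hap == "A") "B" else "A"
    cands <- find_zero_coverage_regions(cov_tracks[[hap]], min_len = min_len,
                                        merge_gap = merge_gap,
                                        zero_cutoff = zero_cutoff)
    for (i in seq_len(nrow(cands))) {
      cand <- cands[i, ]
      sup <- test_homolog_reciprocity(cand, ratio[[oth]], dual_ref,
                                      double_threshold = double_threshold)
      ev <- classify_homolog_event(cand, sup, dual_ref, end_slack = end_slack)
      if (!is.null(ev) && ev$type %in% c("BIR", "SGC")) {
        rows[[length(rows) + 1L]] <- ev
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else {
    data.frame(type = character(), acceptor_hap = character(),
               donor_hap = character(), chrom = character(),
               start = integer(), end = integer(), length = integer(),
               extends_to_end = logical(), homolog_ratio = numeric())
  }
}
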