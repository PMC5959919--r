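## Karlin-Altschul lambda for +1/-2 scoring over uniform base composition:
## solves sum p_i p_j exp(lambda * s_ij) = 1
ka_lambda <- function() {
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1
  uniroot(f, c(1e-3, 5))$root
}
KA_K <- 0.28   # scale constant; order-of-magnitude approximation

#' Karlin-Altschul E-value for an ungapped local alignment score
#'
#' @param score alignment score under match +1 / mismatch -2.
#' @param m query length.
#' @param n search-space length (both strands of the reference).
#' @return Expected number of chance hits at or above \code{score}.
#' @export
ka_evalue <- function(score, m, n) {
  KA_K * m * n * exp(-ka_lambda() * score)
}

#' Find CNV-boundary / junction regions from soft-clip accumulation
#'
#' Windows of the reference where the fraction of partially unmapped
#' (soft-clipped) reads exceeds \code{min_fraction} (default 0.10) become
#' boundary regions, with their clip records attached.  By default the
#' whole genome is scanned; with \code{genome_wide = FALSE} only windows
#' near the boundaries of supplied CNV calls are considered.
#'
#' @param evidence \code{JunctionEvidence} from
#'   \code{\link{simulate_junction_evidence}} (or equivalent records
#'   extracted from alignments).
#' @param cnv_calls optional CNV call data.frame (\code{chrom,start,end});
#'   required when \code{genome_wide = FALSE}.
#' @param window window size in bp (default 500).
#' @param min_fraction clipped-read fraction threshold (strict \code{>}).
#' @param genome_wide scan everywhere, not just CNV boundaries.
#' @param boundary_slack bp around each CNV boundary considered "near".
#' @return data.frame of regions: \code{hap,chrom,window_start,side,
#'   n_clips,fraction,anchor_pos} with clip sequences in the
#'   \code{clip_seqs} list-column.
#' @export
find_boundary_regions <- function(evidence, cnv_calls = NULL, window = 500,
                                  min_fraction = 0.10, genome_wide = TRUE,
                                  boundary_slack = 2000) {
  cl <- evidence$clips
  if (nrow(cl) == 0) return(empty_regions())
  if (!genome_wide && (is.null(cnv_calls) || nrow(cnv_calls) == 0)) {
    message("no CNV calls and genome-wide scan disabled: no boundary regions")
    return(empty_regions())
  }
  key <- paste(cl$hap, cl$chrom, cl$side, (cl$pos - 1L) %/% window, sep = "|")
  rows <- lapply(split(seq_len(nrow(cl)), key), function(ii) {
    sub <- cl[ii, , drop = FALSE]
    frac <- nrow(sub) / evidence$mean_depth
    if (frac <= min_fraction) return(NULL)
    anchor <- modal_int(sub$pos)
    if (!genome_wide) {
      near <- any(cnv_calls$chrom == sub$chrom[1] &
                    (abs(cnv_calls$start - anchor) <= boundary_slack |
                       abs(cnv_calls$end - anchor) <= boundary_slack))
      if (!near) return(NULL)
    }
    data.frame(hap = sub$hap[1], chrom = sub$chrom[1],
               window_start = ((sub$pos[1] - 1L) %/% window) * window + 1L,
               side = sub$side[1], n_clips = nrow(sub),
               fraction = min(frac, 1), anchor_pos = anchor,
               clip_seqs = I(list(sub$seq)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) do.call(rbind, rows) else empty_regions()
}

empty_regions <- function() {
  data.frame(hap = character(), chrom = character(), window_start = integer(),
             side = character(), n_clips = integer(), fraction = numeric(),
             anchor_pos = integer(), clip_seqs = I(list()))
}

#' Locate the partner locus of a clipped-sequence consensus
#'
#' Searches both haplomes (both strands) for the best local match of the
#' clip consensus under +1/-2 scoring, implemented as a mismatch-tolerant
#' full-width pattern search, and converts the best score to a
#' Karlin-Altschul E-value.  Hits are reported only below
#' \code{e_threshold} (the classical \code{e < 1e-4} cut-off).  Score ties
#' at distinct loci are broken deterministically (haplotype, chromosome,
#' position) and flagged ambiguous.
#'
#' @param clip_seq clip consensus (>= \code{min_clip} nt).
#' @param dual_ref the \code{\link{DualReference}}.
#' @param e_threshold maximum E-value (default 1e-4).
#' @param min_clip minimum usable consensus length (default 20).
#' @param max_mismatch mismatches tolerated in the search (default 2).
#' @param max_trim bases trimmed from the junction-proximal end to absorb
#'   inserted (non-templated) bases (default 5).
#' @param side which clip end abuts the junction: \code{"right"}-side clips
#'   start at the junction, \code{"left"}-side clips end at it.
#' @return \code{NULL} when unresolved, else list \code{hap, chrom, start,
#'   end, strand, score, evalue, inserted, ambiguous}.
#' @export
locate_partner <- function(clip_seq, dual_ref, e_threshold = 1e-4,
                           min_clip = 20, max_mismatch = 2, max_trim = 5,
                           side = c("right", "left")) {
  side <- match.arg(side)
  if (nchar(clip_seq) < min_clip) return(NULL)
  n_space <- 2 * (sum(dual_ref$A$lengths) + sum(dual_ref$B$lengths))
  for (trim in 0:max_trim) {
    q <- if (side == "right") {
      substr(clip_seq, 1 + trim, nchar(clip_seq))
    } else {
      substr(clip_seq, 1, nchar(clip_seq) - trim)
    }
    if (nchar(q) < min_clip) break
    hits <- search_both_haplomes(q, dual_ref, max_mismatch)
    if (nrow(hits) == 0) next
    hits$score <- nchar(q) - 3 * hits$mismatch
    best <- max(hits$score)
    ev <- ka_evalue(best, nchar(q), n_space)
    if (ev >= e_threshold) next
    top <- hits[hits$score == best, , drop = FALSE]
    top <- top[order(top$hap, top$chrom, top$start), , drop = FALSE]
    return(list(hap = top$hap[1], chrom = top$chrom[1], start = top$start[1],
                end = top$start[1] + nchar(q) - 1L, strand = top$strand[1],
                score = best, evalue = ev, inserted = trim,
                ambiguous = nrow(top) > 1))
  }
  NULL
}

## mismatch-tolerant search of a query over both haplomes and strands
search_both_haplomes <- function(q, dual_ref, max_mismatch) {
  pat <- Biostrings::DNAString(q)
  rc <- Biostrings::reverseComplement(pat)
  rows <- list()
  for (hap in c("A", "B")) {
    hp <- haplome_of(dual_ref, hap)
    for (ch in names(hp$lengths)) {
      for (str in c("+", "-")) {
        p <- if (str == "+") pat else rc
        m <- Biostrings::matchPattern(p, hp$seqs[[ch]],
                                      max.mismatch = max_mismatch)
        if (length(m) == 0) next
        qs <- as.character(p)
        mm <- vapply(as.character(m), function(s) str_hamming(s, qs),
                     numeric(1), USE.NAMES = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          hap = hap, chrom = ch, start = Biostrings::start(m),
          strand = str, mismatch = mm)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else {
    data.frame(hap = character(), chrom = character(), start = integer(),
               strand = character(), mismatch = integer())
  }
}

#' Count discordant read pairs supporting a junction
#'
#' Pairs whose ends flank the two junction loci with
#' junction-consistent orientation; wrong-orientation pairs are not
#' counted.  At least \code{min_pairs} (default 2) are required for a
#' junction to be pair-confirmed.
#'
#' @param junction list/row with \code{hap_left,chrom_left,pos_left,
#'   hap_right,chrom_right,pos_right}.
#' @param evidence \code{JunctionEvidence}.
#' @param window how far upstream/downstream of the breakpoints pair ends
#'   may start (bp).
#' @param min_pairs confirmation threshold.
#' @return list \code{n_pairs, confirmed}.
#' @export
confirm_discordant_pairs <- function(junction, evidence, window = 1000,
                                     min_pairs = 2) {
  pr <- evidence$pairs
  if (nrow(pr) == 0) return(list(n_pairs = 0L, confirmed = FALSE))
  hit <- pr$orient == "junction" &
    pr$hap_a == junction$hap_left & pr$chrom_a == junction$chrom_left &
    pr$pos_a <= junction$pos_left & pr$pos_a >= junction$pos_left - window &
    pr$hap_b == junction$hap_right & pr$chrom_b == junction$chrom_right &
    pr$pos_b >= junction$pos_right & pr$pos_b <= junction$pos_right + window
  n <- sum(hit)
  list(n_pairs = n, confirmed = n >= min_pairs)
}

#' Reconstruct a junction from a boundary region and its partner locus
#'
#' Computes the exact-overlap (microhomology) shared by the two flanks at
#' the join, any inserted bases, whether the restriction motif spans the
#' join, and whether each breakpoint sits at a canonical restriction cut
#' position.
#'
#' @param region one boundary region row (\code{\link{find_boundary_regions}}).
#' @param partner result of \code{\link{locate_partner}} for the region's
#'   clip consensus.
#' @param dual_ref the \code{\link{DualReference}}.
#' @param site_indexes list \code{A}/\code{B} of
#'   \code{RestrictionSiteIndex} objects.
#' @param motif recognition motif (default TCGA).
#' @return one-row data.frame \code{Junction}: left/right loci, overlap,
#'   insertion, restriction-site flags, repeat context per side.
#' @export
reconstruct_junction <- function(region, partner, dual_ref, site_indexes,
                                 motif = "TCGA") {
  if (region$side == "right") {
    hl <- region$hap; cl <- region$chrom; pl <- region$anchor_pos
    hr <- partner$hap; cr <- partner$chrom; pr <- partner$start
  } else {
    hl <- partner$hap; cl <- partner$chrom; pl <- partner$end
    hr <- region$hap; cr <- region$chrom; pr <- region$anchor_pos
  }
  refL <- haplome_of(dual_ref, hl); refR <- haplome_of(dual_ref, hr)
  ## exact overlap: extend left from the join on both flanks, then right
  k_left <- 0L
  while (k_left < 20L) {
    aL <- subseq_chr(refL, cl, pl - k_left, pl - k_left)
    aR <- subseq_chr(refR, cr, pr - 1L - k_left, pr - 1L - k_left)
    if (aL == "" || aR == "" || aL != aR) break
    k_left <- k_left + 1L
  }
  k_right <- 0L
  while (k_right < 20L) {
    aL <- subseq_chr(refL, cl, pl + 1L + k_right, pl + 1L + k_right)
    aR <- subseq_chr(refR, cr, pr + k_right, pr + k_right)
    if (aL == "" || aR == "" || aL != aR) break
    k_right <- k_right + 1L
  }
  overlap_len <- k_left + k_right
  overlap_seq <- if (overlap_len > 0) {
    subseq_chr(refL, cl, pl - k_left + 1L, pl + k_right)
  } else ""
  inserted <- partner$inserted %||% 0L
  ## does the motif span the join?
  w <- nchar(motif) - 1L
  left_win <- subseq_chr(refL, cl, pl - w, pl)
  right_win <- subseq_chr(refR, cr, pr, pr + w)
  junc_seq <- paste0(left_win, right_win)
  span <- FALSE
  if (inserted == 0L) {
    occ <- gregexpr(motif, junc_seq, fixed = TRUE)[[1]]
    if (occ[1] != -1) {
      span <- any(occ <= nchar(left_win) & occ + nchar(motif) - 1L > nchar(left_win))
    }
  }
  sitesL <- site_indexes[[hl]]$sites[[cl]]
  sitesR <- site_indexes[[hr]]$sites[[cr]]
  data.frame(hap_left = hl, chrom_left = cl, pos_left = pl,
             hap_right = hr, chrom_right = cr, pos_right = pr,
             overlap_len = overlap_len, overlap_seq = overlap_seq,
             inserted = inserted,
             contains_restriction_site = span,
             at_site_left = pl %in% sitesL,
             at_site_right = (pr - 1L) %in% sitesR,
             repeat_left = repeat_class_at(dual_ref, hl, cl, pl),
             repeat_right = repeat_class_at(dual_ref, hr, cr, pr),
             stringsAsFactors = FALSE)
}

#' Classify the repair mechanism of a reconstructed junction
#'
#' Rules applied in priority order:
#' \enumerate{
#'   \item \code{homologous}: both breakpoints inside annotated repeats of
#'     the same class (repeat-mediated events need not preserve
#'     junction-level signatures, so this is tested first);
#'   \item \code{taqi_direct}: the restriction motif spans the join, both
#'     breakpoints sit at canonical cut positions and no bases were
#'     inserted or lost (cohesive-overhang religation);
#'   \item \code{microhomology}: a 2-3 nt exact overlap without the motif;
#'   \item \code{unclassified} otherwise.
#' }
#'
#' @param junction one-row data.frame from \code{\link{reconstruct_junction}}.
#' @return list \code{mechanism, rationale}.
#' @export
classify_mechanism <- function(junction) {
  j <- junction
  if (!is.na(j$repeat_left) && !is.na(j$repeat_right) &&
      j$repeat_left == j$repeat_right) {
    return(list(mechanism = "homologous",
                rationale = paste0("both flanks in ", j$repeat_left,
                                   " repeats")))
  }
  if (isTRUE(j$contains_restriction_site) && isTRUE(j$at_site_left) &&
      isTRUE(j$at_site_right) && j$inserted == 0) {
    return(list(mechanism = "taqi_direct",
                rationale = "motif spans join at canonical cut positions, no loss"))
  }
  if (j$overlap_len >= 2 && j$overlap_len <= 3 &&
      !isTRUE(j$contains_restriction_site)) {
    return(list(mechanism = "microhomology",
                rationale = paste0(j$overlap_len, " nt exact overlap, no motif")))
  }
  list(mechanism = "unclassified", rationale = "no rule matched")
}

#' Detect and classify junctions from soft-clip / discordant-pair evidence
#'
#' Full junction pipeline: boundary regions, partner search with reciprocal
#' confirmation (the same junction must be reconstructable from the clip
#' regions on both of its sides), discordant-pair confirmation, junction
#' reconstruction and mechanism classification.  Junctions joining
#' different chromosomes are typed \code{TL}; same-chromosome junctions are
#' typed \code{deletion_junction} or \code{duplication_junction} by flank
#' order.
#'
#' @param evidence \code{JunctionEvidence}.
#' @param dual_ref the \code{\link{DualReference}}.
#' @param cnv_calls optional CNV calls for restricted scanning.
#' @param window,min_fraction see \code{\link{find_boundary_regions}}.
#' @param e_threshold,min_clip see \code{\link{locate_partner}}.
#' @param min_pairs see \code{\link{confirm_discordant_pairs}}.
#' @param genome_wide scan all windows (default) or only CNV boundaries.
#' @return data.frame of junction calls with mechanism, support counts,
#'   \code{reciprocal} and \code{status} (\code{confirmed} /
#'   \code{clip_only}) columns.
#' @export
call_breakpoints <- function(evidence, dual_ref, cnv_calls = NULL,
                             window = 500, min_fraction = 0.10,
                             e_threshold = 1e-4, min_clip = 20,
                             min_pairs = 2, genome_wide = TRUE) {
  regions <- find_boundary_regions(evidence, cnv_calls = cnv_calls,
                                   window = window,
                                   min_fraction = min_fraction,
                                   genome_wide = genome_wide)
  if (nrow(regions) == 0) return(empty_junction_calls())
  site_indexes <- list(A = scan_restriction_sites(dual_ref$A),
                       B = scan_restriction_sites(dual_ref$B))
  found <- list()
  for (i in seq_len(nrow(regions))) {
    region <- regions[i, ]
    seqs <- region$clip_seqs[[1]]
    consensus <- seqs[which.max(nchar(seqs))]
    partner <- locate_partner(consensus, dual_ref, e_threshold = e_threshold,
                              min_clip = min_clip, side = region$side)
    if (is.null(partner) || partner$strand != "+") next
    j <- reconstruct_junction(region, partner, dual_ref, site_indexes)
    j$n_clips <- region$n_clips
    j$ambiguous <- partner$ambiguous
    j$from_side <- region$side
    found[[length(found) + 1L]] <- j
  }
  if (length(found) == 0) return(empty_junction_calls())
  jdf <- do.call(rbind, found)
  key <- paste(jdf$hap_left, jdf$chrom_left, jdf$pos_left,
               jdf$hap_right, jdf$chrom_right, jdf$pos_right, sep = "|")
  rows <- lapply(split(seq_len(nrow(jdf)), key), function(ii) {
    sub <- jdf[ii, , drop = FALSE]
    out <- sub[1, !(names(sub) %in% c("n_clips", "from_side")), drop = FALSE]
    out$n_clips <- sum(sub$n_clips)
    out$reciprocal <- length(unique(sub$from_side)) == 2
    out
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  calls$n_pairs <- vapply(seq_len(nrow(calls)), function(i) {
    confirm_discordant_pairs(calls[i, ], evidence, min_pairs = min_pairs)$n_pairs
  }, integer(1))
  calls$status <- ifelse(calls$n_pairs >= min_pairs, "confirmed", "clip_only")
  mech <- lapply(seq_len(nrow(calls)), function(i) classify_mechanism(calls[i, ]))
  calls$mechanism <- vapply(mech, `[[`, character(1), "mechanism")
  calls$rationale <- vapply(mech, `[[`, character(1), "rationale")
  calls$event_type <- ifelse(
    calls$chrom_left != calls$chrom_right | calls$hap_left != calls$hap_right,
    "TL",
    ifelse(calls$pos_right > calls$pos_left, "deletion_junction",
           "duplication_junction"))
  ## rDNA junctions are reported but cannot be independently verified
  calls$verifiable <- !(calls$repeat_left %in% "rDNA" |
                          calls$repeat_right %in% "rDNA")
  calls
}

empty_junction_calls <- function() {
  data.frame(hap_left = character(), chrom_left = character(),
             pos_left = integer(), hap_right = character(),
             chrom_right = character(), pos_right = integer(),
             overlap_len = integer(), overlap_seq = character(),
             inserted = integer(), contains_restriction_site = logical(),
             at_site_left = logical(), at_site_right = logical(),
             repeat_left = character(), repeat_right = character(),
             ambiguous = logical(), n_clips = integer(),
             reciprocal = logical(), n_pairs = integer(),
             status = character(), mechanism = character(),
             rationale = character(), event_type = character(),
             verifiable = logical())
}
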