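#' Specify counts and parameters for planted rearrangement events
#'
#' Defaults reproduce the event spectrum used throughout the package's
#' round-trip validation: 6 restriction-site direct-join translocations,
#' 3 repeat-mediated (homologous) translocations, 10 break-induced repairs,
#' 40 short gene conversions and 2 whole-chromosome aneuploidies.  The DSB
#' count per cell is drawn from Poisson(\code{dsb_mean}); only the requested
#' events resolve into rearrangements, the remaining breaks religate
#' silently and leave no sequence change.
#'
#' @param n_tl_taqi non-homologous translocations joined directly at
#'   restriction half-sites (cohesive-overhang religation, motif
#'   reconstituted, zero net loss).
#' @param n_tl_homologous translocations by recombination between dispersed
#'   repeat copies of the same family.
#' @param n_bir break-induced repairs (terminal chimeric tracts).
#' @param n_sgc short gene conversions (internal tracts).
#' @param n_aneuploidy_gain,n_aneuploidy_loss whole-chromosome copy changes.
#' @param n_large_deletion,n_tandem_duplication segmental CNVs with a
#'   sequence-resolved junction.
#' @param sgc_length_range SGC tract lengths, sampled log-uniformly
#'   (default 0.7-30 kb).
#' @param cnv_length_range segmental CNV lengths (bp).
#' @param microhomology_fraction fraction of segmental-CNV junctions joined
#'   via 2-3 nt microhomology; the rest are restriction-site direct joins.
#' @param microhomology_lengths allowed exact-overlap lengths.
#' @param dsb_mean mean of the Poisson DSB count (metadata only).
#' @param seed optional default seed for \code{\link{plant_events}}.
#' @return An object of class \code{EventSpec}.
#' @export
event_spec <- function(n_tl_taqi = 6, n_tl_homologous = 3, n_bir = 10,
                       n_sgc = 40, n_aneuploidy_gain = 1,
                       n_aneuploidy_loss = 1, n_large_deletion = 0,
                       n_tandem_duplication = 0,
                       sgc_length_range = c(700, 30000),
                       cnv_length_range = c(30000, 80000),
                       microhomology_fraction = 1,
                       microhomology_lengths = 2:3,
                       dsb_mean = 200, seed = NULL) {
  counts <- c(n_tl_taqi, n_tl_homologous, n_bir, n_sgc, n_aneuploidy_gain,
              n_aneuploidy_loss, n_large_deletion, n_tandem_duplication)
  if (any(counts < 0)) stop_input("event counts must be >= 0")
  if (sgc_length_range[1] > sgc_length_range[2]) {
    stop_input("invalid SGC length range")
  }
  structure(list(n_tl_taqi = n_tl_taqi, n_tl_homologous = n_tl_homologous,
                 n_bir = n_bir, n_sgc = n_sgc,
                 n_aneuploidy_gain = n_aneuploidy_gain,
                 n_aneuploidy_loss = n_aneuploidy_loss,
                 n_large_deletion = n_large_deletion,
                 n_tandem_duplication = n_tandem_duplication,
                 sgc_length_range = sgc_length_range,
                 cnv_length_range = cnv_length_range,
                 microhomology_fraction = microhomology_fraction,
                 microhomology_lengths = microhomology_lengths,
                 dsb_mean = dsb_mean, seed = seed),
            class = "EventSpec")
}

#' Read an event specification from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   \code{\link{event_spec}}.
#' @return An \code{EventSpec}.
#' @export
event_spec_from_yaml <- function(path) {
  do.call(event_spec, yaml::read_yaml(path))
}

## ---- segment-map plumbing ---------------------------------------------------

new_copy <- function(id, hap, chrom, len) {
  list(id = id, segments = data.frame(hap = hap, chrom = chrom,
                                      start = 1L, end = len))
}

## first copy containing source position (hap, chrom, pos) with margin intact
find_copy_with <- function(copies, hap, chrom, pos, margin = 0L) {
  for (id in names(copies)) {
    sg <- copies[[id]]$segments
    hit <- sg$hap == hap & sg$chrom == chrom &
      sg$start <= pos - margin & sg$end >= pos + margin
    if (any(hit)) return(id)
  }
  NULL
}

## split a segment map at source position (left part ends at pos)
split_segments <- function(segs, hap, chrom, pos) {
  i <- which(segs$hap == hap & segs$chrom == chrom &
               segs$start <= pos & segs$end >= pos)[1]
  if (is.na(i)) return(NULL)
  left <- segs[seq_len(i), , drop = FALSE]
  left$end[i] <- pos
  right <- segs[i:nrow(segs), , drop = FALSE]
  right$start[1] <- pos + 1L
  if (left$end[i] < left$start[i]) left <- left[-i, , drop = FALSE]
  if (right$end[1] < right$start[1]) right <- right[-1, , drop = FALSE]
  rownames(left) <- rownames(right) <- NULL
  list(left = left, right = right)
}

## expected copy number of source interval (hap, chrom, [s, e]) over copies;
## counts segments fully covering the interval
covering_count <- function(copies, hap, chrom, s, e) {
  n <- 0L
  for (cp in copies) {
    sg <- cp$segments
    n <- n + sum(sg$hap == hap & sg$chrom == chrom & sg$start <= s & sg$end >= e)
  }
  n
}

#' Synthesize the sequence of a restructured chromosome copy
#'
#' @param dual_ref the \code{\link{DualReference}} the copy draws from.
#' @param copy one element of \code{genome$copies}.
#' @return Character scalar DNA sequence.
#' @export
build_copy_seq <- function(dual_ref, copy) {
  sg <- copy$segments
  parts <- vapply(seq_len(nrow(sg)), function(i) {
    subseq_chr(haplome_of(dual_ref, sg$hap[i]), sg$chrom[i], sg$start[i], sg$end[i])
  }, character(1))
  paste(parts, collapse = "")
}

#' All restructured chromosome sequences as a DNAStringSet
#'
#' @param genome a \code{RestructuredGenome} from \code{\link{plant_events}}.
#' @param dual_ref the matching \code{\link{DualReference}}.
#' @return Named \code{DNAStringSet}, one record per chromosome copy.
#' @export
restructured_seqs <- function(genome, dual_ref) {
  Biostrings::DNAStringSet(vapply(genome$copies, function(cp) {
    build_copy_seq(dual_ref, cp)
  }, character(1)))
}

## ---- planting ---------------------------------------------------------------

#' Plant rearrangement events into a dual-haplotype genome
#'
#' Applies mechanism-faithful sequence-level edits to the fused diploid
#' (one chromosome copy per haplotype per chromosome) and records a truth
#' set for every edit:
#' \itemize{
#'   \item restriction-direct translocations cut two TCGA sites after the T
#'     and religate the 2-nt cohesive overhangs crosswise, so both junction
#'     sequences reconstitute the motif with zero net loss (reciprocal,
#'     copy-number neutral);
#'   \item homologous translocations cross over inside two same-family
#'     repeat copies on different chromosomes;
#'   \item BIR replaces a terminal tract of one haplotype with the homolog
#'     from an internal breakpoint to the chromosome end;
#'   \item SGC replaces an internal tract with homolog sequence
#'     (log-uniform 0.7-30 kb by default);
#'   \item aneuploidies duplicate or drop whole chromosome copies;
#'   \item segmental deletions/duplications join flanks over a planted 2-3 nt
#'     microhomology (or at restriction half-sites).
#' }
#'
#' Junction breakpoints are placed where the local sequence distinguishes
#' the haplotypes (and, for repeat-mediated events, the repeat copies), so
#' that junction reads have a unique best partner locus -- the property the
#' source strains' inter-haplotype variant density provides in real data.
#' Colliding placements are re-sampled up to \code{retry_cap}, then error.
#'
#' @param dual_ref a \code{\link{DualReference}}.
#' @param spec an \code{\link{event_spec}}.
#' @param seed RNG seed (falls back to \code{spec$seed}, then 1).
#' @param retry_cap placement retries per event before giving up.
#' @return list with \code{genome} (class \code{RestructuredGenome}: named
#'   \code{copies}, each a segment map over the parental references) and
#'   \code{truth} (class \code{TruthSet}: \code{events} and \code{junctions}
#'   data.frames plus metadata).
#' @export
plant_events <- function(dual_ref, spec = event_spec(), seed = NULL,
                         retry_cap = 200) {
  seed <- seed %||% spec$seed %||% 1L
  set.seed(seed)
  chroms <- names(dual_ref$pairing)
  lensA <- dual_ref$A$lengths
  lensB <- dual_ref$B$lengths
  telw <- if (!is.null(dual_ref$A$telomeres)) {
    max(dual_ref$A$telomeres$end[dual_ref$A$telomeres$start == 1])
  } else 0L

  copies <- list()
  for (ch in chroms) {
    copies[[paste0("A:", ch)]] <- new_copy(paste0("A:", ch), "A", ch, lensA[[ch]])
    copies[[paste0("B:", ch)]] <- new_copy(paste0("B:", ch), "B", ch,
                                           lensB[[homolog_chrom(dual_ref, "A", ch)]])
  }

  occ <- data.frame(hap = character(), chrom = character(),
                    start = integer(), end = integer())
  occ_hit <- function(hap, chrom, s, e) {
    sub <- occ[occ$hap == hap & occ$chrom == chrom, , drop = FALSE]
    nrow(sub) > 0 && any(ivl_overlaps(sub$start, sub$end, s, e))
  }
  occ_add <- function(hap, chrom, s, e, pad = 2000L) {
    occ <<- rbind(occ, data.frame(hap = hap, chrom = chrom,
                                  start = max(1L, s - pad), end = e + pad))
  }

  sitesA <- scan_restriction_sites(dual_ref$A)
  sitesB <- scan_restriction_sites(dual_ref$B)
  sites_of <- function(hap) if (hap == "A") sitesA else sitesB
  len_of <- function(hap, ch) if (hap == "A") lensA[[ch]] else lensB[[ch]]
  varpos <- list(A = lapply(setNames(chroms, chroms), function(ch) {
    variant_positions(dual_ref, "A", ch)
  }), B = lapply(setNames(chroms, chroms), function(ch) {
    variant_positions(dual_ref, "B", ch)
  }))
  has_var_in <- function(hap, ch, lo, hi) {
    vp <- varpos[[hap]][[ch]]
    length(vp) > 0 && any(vp >= lo & vp <= hi)
  }
  in_annot <- function(hap, ch, pos, slack = 0) {
    h <- haplome_of(dual_ref, hap)
    ivl_hits_df(h$centromeres, ch, pos - slack, pos + slack) ||
      ivl_hits_df(h$telomeres, ch, pos - slack, pos + slack) ||
      ivl_hits_df(h$repeats, ch, pos - slack, pos + slack)
  }
  ## a breakpoint usable for a sequence-resolved junction: interior, outside
  ## annotation, unoccupied, and haplotype-distinguishing variants both sides
  junction_ok <- function(hap, ch, pos) {
    L <- len_of(hap, ch)
    pos > telw + 1000 && pos < L - telw - 1000 &&
      !in_annot(hap, ch, pos, slack = 80) &&
      !occ_hit(hap, ch, pos - 200L, pos + 200L) &&
      has_var_in(hap, ch, pos - 55L, pos - 1L) &&
      has_var_in(hap, ch, pos + 2L, pos + 56L)
  }

  events <- list(); junctions <- list()
  eid <- 0L; jid <- 0L
  add_event <- function(...) {
    eid <<- eid + 1L
    events[[eid]] <<- data.frame(event_id = eid, ..., stringsAsFactors = FALSE)
    eid
  }
  add_junction <- function(event_id, hl, cl, pl, hr, cr, pr, mechanism,
                           overlap_len = NA_integer_,
                           repeat_class = NA_character_) {
    jid <<- jid + 1L
    junctions[[jid]] <<- data.frame(
      junction_id = jid, event_id = event_id,
      hap_left = hl, chrom_left = cl, pos_left = as.integer(pl),
      hap_right = hr, chrom_right = cr, pos_right = as.integer(pr),
      mechanism = mechanism, overlap_len = overlap_len,
      repeat_class = repeat_class, stringsAsFactors = FALSE)
  }
  ## apply a (reciprocal) two-sided translocation: derivative X = left(a) +
  ## right(b); derivative Y = left(b-1) + right(a+1)
  apply_tl <- function(h1, c1, a, h2, c2, b) {
    id1 <- find_copy_with(copies, h1, c1, a, margin = 150L)
    id2 <- find_copy_with(copies, h2, c2, b, margin = 150L)
    if (is.null(id1) || is.null(id2) || id1 == id2) return(FALSE)
    sp1 <- split_segments(copies[[id1]]$segments, h1, c1, a)
    sp2 <- split_segments(copies[[id2]]$segments, h2, c2, b - 1L)
    if (is.null(sp1) || is.null(sp2)) return(FALSE)
    nid1 <- paste0("der(", id1, ";", id2, ")")
    nid2 <- paste0("der(", id2, ";", id1, ")")
    copies[[id1]] <<- NULL; copies[[id2]] <<- NULL
    copies[[nid1]] <<- list(id = nid1, segments = rbind(sp1$left, sp2$right))
    copies[[nid2]] <<- list(id = nid2, segments = rbind(sp2$left, sp1$right))
    TRUE
  }

  ## ---- aneuploidies (reserved chromosomes) --------------------------------
  ## keep aneuploidies off repeat-bearing chromosomes: the rDNA array is
  ## masked in coverage, and dispersed repeats are the substrate pool for
  ## homologous translocations
  rep_chroms <- unique(dual_ref$A$repeats$chrom)
  aneu_pool <- setdiff(chroms, rep_chroms)
  if (length(aneu_pool) < spec$n_aneuploidy_gain + spec$n_aneuploidy_loss) {
    aneu_pool <- setdiff(chroms, unique(
      dual_ref$A$repeats$chrom[dual_ref$A$repeats$class == "rDNA"]))
  }
  n_aneu <- spec$n_aneuploidy_gain + spec$n_aneuploidy_loss
  if (n_aneu > length(aneu_pool)) stop_input("not enough chromosomes for aneuploidies")
  aneu_chroms <- if (n_aneu > 0) sample(aneu_pool, n_aneu) else character()
  k <- 0L
  for (i in seq_len(spec$n_aneuploidy_gain)) {
    k <- k + 1L; ch <- aneu_chroms[k]
    hap <- sample1(c("A", "B"))
    src <- paste0(hap, ":", ch)
    copies[[paste0("gain:", src)]] <- list(id = paste0("gain:", src),
                                           segments = copies[[src]]$segments)
    add_event(type = "aneuploidy_gain", mechanism = NA_character_, hap_a = hap,
              chrom_a = ch, pos_a = NA_integer_, hap_b = NA_character_,
              chrom_b = NA_character_, pos_b = NA_integer_,
              start = 1L, end = lensA[[ch]], length = lensA[[ch]],
              extends_to_end = NA, overlap_len = NA_integer_,
              overlap_seq = NA_character_, repeat_class = NA_character_)
    occ_add("A", ch, 1L, lensA[[ch]], pad = 0L)
    occ_add("B", ch, 1L, lensB[[ch]], pad = 0L)
  }
  for (i in seq_len(spec$n_aneuploidy_loss)) {
    k <- k + 1L; ch <- aneu_chroms[k]
    hap <- sample1(c("A", "B"))
    copies[[paste0(hap, ":", ch)]] <- NULL
    add_event(type = "aneuploidy_loss", mechanism = NA_character_, hap_a = hap,
              chrom_a = ch, pos_a = NA_integer_, hap_b = NA_character_,
              chrom_b = NA_character_, pos_b = NA_integer_,
              start = 1L, end = lensA[[ch]], length = lensA[[ch]],
              extends_to_end = NA, overlap_len = NA_integer_,
              overlap_seq = NA_character_, repeat_class = NA_character_)
    occ_add("A", ch, 1L, lensA[[ch]], pad = 0L)
    occ_add("B", ch, 1L, lensB[[ch]], pad = 0L)
  }
  busy_chrom <- aneu_chroms

  ## ---- homologous TLs ------------------------------------------------------
  if (spec$n_tl_homologous > 0) {
    reps <- dual_ref$A$repeats
    fam_ok <- reps[reps$class %in% c("ty_like", "transposon"), , drop = FALSE]
    fam_ok <- fam_ok[!fam_ok$chrom %in% busy_chrom, , drop = FALSE]
    fam_ok$subfam <- sub("[ab]$", "", fam_ok$copy_id)
    for (i in seq_len(spec$n_tl_homologous)) {
      ok <- FALSE
      for (try in seq_len(retry_cap)) {
        tab <- table(fam_ok$subfam)
        full <- names(tab)[tab == 2]
        if (length(full) == 0) break
        sf <- sample1(full)
        cand <- fam_ok[fam_ok$subfam == sf, , drop = FALSE]
        r1 <- cand[1, ]; r2 <- cand[2, ]
        cls <- r1$class
        if (r1$chrom == r2$chrom) { fam_ok <- fam_ok[fam_ok$subfam != sf, ]; next }
        v <- pick_crossover_offset(dual_ref, r1, r2, reps)
        if (is.null(v)) next
        a <- r1$start + v - 2L          # left flank of junction 1 ends here
        b <- r2$start + v - 1L          # right flank of junction 1 starts here
        if (occ_hit("A", r1$chrom, a - 200L, a + 200L) ||
            occ_hit("A", r2$chrom, b - 200L, b + 200L)) next
        if (!apply_tl("A", r1$chrom, a, "A", r2$chrom, b)) next
        occ_add("A", r1$chrom, a, a); occ_add("A", r2$chrom, b, b)
        ev <- add_event(type = "TL_homologous", mechanism = "homologous",
                        hap_a = "A", chrom_a = r1$chrom, pos_a = a,
                        hap_b = "A", chrom_b = r2$chrom, pos_b = b,
                        start = NA_integer_, end = NA_integer_,
                        length = NA_integer_, extends_to_end = NA,
                        overlap_len = NA_integer_, overlap_seq = NA_character_,
                        repeat_class = cls)
        add_junction(ev, "A", r1$chrom, a, "A", r2$chrom, b, "homologous",
                     repeat_class = cls)
        add_junction(ev, "A", r2$chrom, b - 1L, "A", r1$chrom, a + 1L,
                     "homologous", repeat_class = cls)
        fam_ok <- fam_ok[fam_ok$subfam != sf, , drop = FALSE]
        ok <- TRUE
        break
      }
      if (!ok) stop_input("could not place homologous TL ", i)
    }
  }

  ## ---- restriction-direct TLs ---------------------------------------------
  for (i in seq_len(spec$n_tl_taqi)) {
    ok <- FALSE
    for (try in seq_len(retry_cap)) {
      h1 <- sample1(c("A", "B")); h2 <- sample1(c("A", "B"))
      c1 <- sample1(setdiff(chroms, busy_chrom))
      c2 <- sample1(setdiff(chroms, c(busy_chrom, c1)))
      s1 <- pick_taqi_site(sites_of(h1), h1, c1, junction_ok)
      s2 <- pick_taqi_site(sites_of(h2), h2, c2, junction_ok)
      if (is.null(s1) || is.null(s2)) next
      a <- s1            # cut T^CGA: left fragment keeps the T at s1
      b <- s2 + 1L       # right fragment starts at the C of site 2
      if (!apply_tl(h1, c1, a, h2, c2, b)) next
      occ_add(h1, c1, a, a); occ_add(h2, c2, s2, s2)
      ev <- add_event(type = "TL_nonhomologous", mechanism = "taqi_direct",
                      hap_a = h1, chrom_a = c1, pos_a = a,
                      hap_b = h2, chrom_b = c2, pos_b = b,
                      start = NA_integer_, end = NA_integer_,
                      length = NA_integer_, extends_to_end = NA,
                      overlap_len = NA_integer_, overlap_seq = NA_character_,
                      repeat_class = NA_character_)
      add_junction(ev, h1, c1, a, h2, c2, b, "taqi_direct")
      add_junction(ev, h2, c2, s2, h1, c1, a + 1L, "taqi_direct")
      ok <- TRUE
      break
    }
    if (!ok) stop_input("could not place restriction-direct TL ", i)
  }

  ## ---- BIR ----------------------------------------------------------------
  for (i in seq_len(spec$n_bir)) {
    ok <- FALSE
    for (try in seq_len(retry_cap)) {
      hap <- sample1(c("A", "B")); oth <- if (hap == "A") "B" else "A"
      ch <- sample1(setdiff(chroms, busy_chrom))
      L <- len_of(hap, ch)
      side <- sample1(c("left", "right"))
      frac <- runif(1, 0.10, 0.45)
      p <- if (side == "right") round(L * (1 - frac)) else round(L * frac)
      ## the internal breakpoint must stay clear of masked (rDNA) bins or
      ## its boundary is not measurable from coverage
      rdna <- haplome_of(dual_ref, hap)$repeats
      rdna <- rdna[rdna$class == "rDNA", , drop = FALSE]
      if (ivl_hits_df(rdna, ch, p - 1500L, p + 1500L)) next
      s <- if (side == "right") p else 1L
      e <- if (side == "right") L else p
      lift_p <- liftover_pos(dual_ref, hap, ch, p)
      oth_ch <- homolog_chrom(dual_ref, hap, ch)
      oL <- len_of(oth, oth_ch)
      os <- if (side == "right") lift_p else 1L
      oe <- if (side == "right") oL else lift_p
      if (occ_hit(hap, ch, s - 1000L, e + 1000L) ||
          occ_hit(oth, oth_ch, os - 1000L, oe + 1000L)) next
      id <- find_copy_with(copies, hap, ch, p)
      if (is.null(id) ||
          covering_count(copies, hap, ch, s, e) != 1L ||
          covering_count(copies, oth, oth_ch, os, oe) != 1L) next
      if (side == "right") {
        sp <- split_segments(copies[[id]]$segments, hap, ch, p - 1L)
        if (is.null(sp)) next
        donor <- data.frame(hap = oth, chrom = oth_ch, start = lift_p, end = oL)
        copies[[id]]$segments <- rbind(sp$left, donor)
      } else {
        sp <- split_segments(copies[[id]]$segments, hap, ch, p)
        if (is.null(sp)) next
        donor <- data.frame(hap = oth, chrom = oth_ch, start = 1L,
                            end = max(1L, lift_p - 1L))
        copies[[id]]$segments <- rbind(donor, sp$right)
      }
      occ_add(hap, ch, s, e); occ_add(oth, oth_ch, os, oe)
      add_event(type = "BIR", mechanism = "homologous", hap_a = hap,
                chrom_a = ch, pos_a = p, hap_b = oth, chrom_b = oth_ch,
                pos_b = lift_p, start = s, end = e, length = e - s + 1L,
                extends_to_end = TRUE, overlap_len = NA_integer_,
                overlap_seq = NA_character_, repeat_class = NA_character_)
      ok <- TRUE
      break
    }
    if (!ok) stop_input("could not place BIR ", i, " after ", retry_cap, " tries")
  }

  ## ---- SGC ----------------------------------------------------------------
  for (i in seq_len(spec$n_sgc)) {
    ok <- FALSE
    for (try in seq_len(retry_cap)) {
      hap <- sample1(c("A", "B")); oth <- if (hap == "A") "B" else "A"
      ch <- sample1(setdiff(chroms, busy_chrom))
      L <- len_of(hap, ch)
      len <- round(exp(runif(1, log(spec$sgc_length_range[1]),
                             log(spec$sgc_length_range[2]))))
      lo <- telw + 3000L; hi <- L - telw - 3000L - len
      if (hi <= lo) next
      s <- sample(lo:hi, 1L); e <- s + len - 1L
      lift <- liftover(dual_ref, hap, ch, s, e)
      if (occ_hit(hap, ch, s - 1000L, e + 1000L) ||
          occ_hit(oth, lift$chrom, lift$start - 1000L, lift$end + 1000L)) next
      rdna <- haplome_of(dual_ref, hap)$repeats
      rdna <- rdna[rdna$class == "rDNA", , drop = FALSE]
      if (ivl_hits_df(rdna, ch, s - 500L, e + 500L)) next
      id <- find_copy_with(copies, hap, ch, s)
      if (is.null(id) ||
          covering_count(copies, hap, ch, s, e) != 1L ||
          covering_count(copies, oth, lift$chrom, lift$start, lift$end) != 1L) next
      sp1 <- split_segments(copies[[id]]$segments, hap, ch, s - 1L)
      if (is.null(sp1)) next
      sp2 <- split_segments(sp1$right, hap, ch, e)
      if (is.null(sp2)) next
      donor <- data.frame(hap = oth, chrom = lift$chrom,
                          start = lift$start, end = lift$end)
      copies[[id]]$segments <- rbind(sp1$left, donor, sp2$right)
      occ_add(hap, ch, s, e); occ_add(oth, lift$chrom, lift$start, lift$end)
      add_event(type = "SGC", mechanism = "homologous", hap_a = hap,
                chrom_a = ch, pos_a = s, hap_b = oth, chrom_b = lift$chrom,
                pos_b = lift$start, start = s, end = e, length = len,
                extends_to_end = FALSE, overlap_len = NA_integer_,
                overlap_seq = NA_character_, repeat_class = NA_character_)
      ok <- TRUE
      break
    }
    if (!ok) stop_input("could not place SGC ", i, " after ", retry_cap, " tries")
  }

  ## ---- segmental CNVs with sequence-resolved junctions --------------------
  n_cnv <- spec$n_large_deletion + spec$n_tandem_duplication
  cnv_types <- c(rep("large_deletion", spec$n_large_deletion),
                 rep("tandem_duplication", spec$n_tandem_duplication))
  for (i in seq_len(n_cnv)) {
    typ <- cnv_types[i]
    use_mh <- runif(1) < spec$microhomology_fraction
    ok <- FALSE
    for (try in seq_len(retry_cap)) {
      hap <- sample1(c("A", "B"))
      ch <- sample1(setdiff(chroms, busy_chrom))
      jj <- if (use_mh) {
        pick_mh_junction(dual_ref, hap, ch, len_of(hap, ch),
                         spec$cnv_length_range, spec$microhomology_lengths,
                         junction_ok)
      } else {
        pick_taqi_cnv_junction(sites_of(hap), hap, ch, spec$cnv_length_range,
                               junction_ok)
      }
      if (is.null(jj)) next
      x <- jj$x; y <- jj$y
      if (occ_hit(hap, ch, x - 1000L, y + 1000L)) next
      id <- find_copy_with(copies, hap, ch, x, margin = 150L)
      if (is.null(id) || covering_count(copies, hap, ch, x, y + 1L) != 1L) next
      if (typ == "large_deletion") {
        sp1 <- split_segments(copies[[id]]$segments, hap, ch, x)
        if (is.null(sp1)) next
        sp2 <- split_segments(sp1$right, hap, ch, y)
        if (is.null(sp2)) next
        copies[[id]]$segments <- rbind(sp1$left, sp2$right)
        jl <- x; jr <- y + 1L
      } else {
        sp <- split_segments(copies[[id]]$segments, hap, ch, y)
        if (is.null(sp)) next
        dup <- data.frame(hap = hap, chrom = ch, start = x + 1L, end = y)
        copies[[id]]$segments <- rbind(sp$left, dup, sp$right)
        jl <- y; jr <- x + 1L
      }
      occ_add(hap, ch, x, y)
      mech <- if (use_mh) "microhomology" else "taqi_direct"
      ev <- add_event(type = typ, mechanism = mech, hap_a = hap, chrom_a = ch,
                      pos_a = jl, hap_b = hap, chrom_b = ch, pos_b = jr,
                      start = x + 1L, end = y, length = y - x,
                      extends_to_end = FALSE,
                      overlap_len = jj$k %||% NA_integer_,
                      overlap_seq = jj$mh %||% NA_character_,
                      repeat_class = NA_character_)
      add_junction(ev, hap, ch, jl, hap, ch, jr, mech,
                   overlap_len = jj$k %||% NA_integer_)
      ok <- TRUE
      break
    }
    if (!ok) stop_input("could not place ", typ, " ", i)
  }

  events_df <- if (eid > 0) do.call(rbind, events) else data.frame(
    event_id = integer(), type = character(), mechanism = character(),
    hap_a = character(), chrom_a = character(), pos_a = integer(),
    hap_b = character(), chrom_b = character(), pos_b = integer(),
    start = integer(), end = integer(), length = integer(),
    extends_to_end = logical(), overlap_len = integer(),
    overlap_seq = character(), repeat_class = character())
  junc_df <- if (jid > 0) do.call(rbind, junctions) else data.frame(
    junction_id = integer(), event_id = integer(), hap_left = character(),
    chrom_left = character(), pos_left = integer(), hap_right = character(),
    chrom_right = character(), pos_right = integer(), mechanism = character(),
    overlap_len = integer(), repeat_class = character())
  truth <- structure(list(events = events_df, junctions = junc_df,
                          meta = list(seed = seed, spec = spec,
                                      n_dsb = rpois(1, spec$dsb_mean))),
                     class = "TruthSet")
  genome <- structure(list(copies = copies), class = "RestructuredGenome")
  list(genome = genome, truth = truth)
}

#' @export
print.TruthSet <- function(x, ...) {
  cat("TruthSet:", nrow(x$events), "events,", nrow(x$junctions),
      "junctions (seed", x$meta$seed, ")\n")
  if (nrow(x$events)) print(table(x$events$type))
  invisible(x)
}

#' @export
print.RestructuredGenome <- function(x, ...) {
  cat("RestructuredGenome:", length(x$copies), "chromosome copies\n")
  invisible(x)
}

## ---- breakpoint pickers -----------------------------------------------------

## restriction site whose cut position satisfies the junction constraints
pick_taqi_site <- function(site_index, hap, chrom, junction_ok) {
  ss <- site_index$sites[[chrom]]
  if (length(ss) == 0) return(NULL)
  for (s in sample(ss, min(length(ss), 40L))) {
    if (junction_ok(hap, chrom, s) && junction_ok(hap, chrom, s + 1L)) return(s)
  }
  NULL
}

## crossover offset v inside the two copies of a repeat subfamily such that
## the copies differ at v (junction base-exact), the junction windows carry
## an inter-haplotype SNV (unique vs the homolog), and the windows differ
## from every other same-class copy (unique among repeats)
pick_crossover_offset <- function(dual_ref, r1, r2, all_reps) {
  w <- 120L
  len <- min(r1$end - r1$start, r2$end - r2$start) + 1L
  s1 <- subseq_chr(dual_ref$A, r1$chrom, r1$start, r1$start + len - 1L)
  s2 <- subseq_chr(dual_ref$A, r2$chrom, r2$start, r2$start + len - 1L)
  v1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  v2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  div <- which(v1 != v2)
  div <- div[div > w + 10 & div < len - w - 10]
  if (length(div) == 0) return(NULL)
  others <- all_reps[all_reps$class == r1$class &
                       !(all_reps$copy_id %in% c(r1$copy_id, r2$copy_id)), ,
                     drop = FALSE]
  other_seqs <- lapply(seq_len(nrow(others)), function(i) {
    subseq_chr(dual_ref$A, others$chrom[i], others$start[i],
               others$start[i] + len - 1L)
  })
  snv_in <- function(chrom, lo, hi) {
    vp <- variant_positions(dual_ref, "A", chrom)
    length(vp) > 0 && any(vp >= lo & vp <= hi)
  }
  for (v in sample(div, min(length(div), 80L))) {
    ## the two copies must also differ upstream of the crossover, so that
    ## left-flank clips cannot match the partner copy exactly
    if (!any(div >= v - w & div <= v - 1L)) next
    right2 <- substr(s2, v, v + w - 1L)           # partner window, junction 1
    right1 <- substr(s1, v, v + w - 1L)           # partner window, junction 2
    left1 <- substr(s1, v - w, v - 1L)            # anchor-side window, jct 1
    left2 <- substr(s2, v - w, v - 1L)            # anchor-side window, jct 2
    ok_copies <- all(vapply(other_seqs, function(o) {
      str_hamming(substr(o, v, v + w - 1L), right2) >= 1 &&
        str_hamming(substr(o, v, v + w - 1L), right1) >= 1 &&
        str_hamming(substr(o, v - w, v - 1L), left1) >= 1 &&
        str_hamming(substr(o, v - w, v - 1L), left2) >= 1
    }, logical(1)))
    if (!ok_copies) next
    ## distinguish haplotypes: an inter-haplotype SNV inside every window
    g1 <- r1$start + v - 1L; g2 <- r2$start + v - 1L
    if (snv_in(r1$chrom, g1 - w, g1 - 1L) && snv_in(r1$chrom, g1, g1 + w - 1L) &&
        snv_in(r2$chrom, g2 - w, g2 - 1L) && snv_in(r2$chrom, g2, g2 + w - 1L)) {
      return(v)
    }
  }
  NULL
}

## deletion/duplication junction with an exact 2-3 nt flank overlap and no
## restriction motif spanning the join
pick_mh_junction <- function(dual_ref, hap, ch, L, len_range, mh_lens,
                             junction_ok) {
  hp <- haplome_of(dual_ref, hap)
  seq <- chrom_seq(hp, ch)
  for (try in 1:80) {
    k <- if (length(mh_lens) == 1) mh_lens else sample(mh_lens, 1L)
    x <- sample(seq(floor(L * 0.1), floor(L * 0.6)), 1L)
    if (!junction_ok(hap, ch, x)) next
    mh <- substr(seq, x - k + 1L, x)
    lo <- x + len_range[1]; hi <- min(x + len_range[2], L - 5000L)
    if (hi <= lo) next
    ys <- lo:hi
    suff <- substring(seq, ys - k + 1L, ys)
    cand <- ys[suff == mh]
    for (y in cand) {
      if (!junction_ok(hap, ch, y)) next
      if (substr(seq, x + 1L, x + 1L) == substr(seq, y + 1L, y + 1L)) next
      if (substr(seq, x - k, x - k) == substr(seq, y - k, y - k)) next
      win <- paste0(substr(seq, x - 3L, x), substr(seq, y + 1L, y + 4L))
      if (grepl("TCGA", win, fixed = TRUE)) next
      return(list(x = x, y = y, k = k, mh = mh))
    }
  }
  NULL
}

## deletion/duplication junction between two restriction cut positions
pick_taqi_cnv_junction <- function(site_index, hap, ch, len_range, junction_ok) {
  ss <- site_index$sites[[ch]]
  if (length(ss) < 2) return(NULL)
  for (try in 1:80) {
    s1 <- sample1(ss)
    cand <- ss[ss >= s1 + len_range[1] & ss <= s1 + len_range[2]]
    if (length(cand) == 0) next
    s2 <- sample1(cand)
    if (junction_ok(hap, ch, s1) && junction_ok(hap, ch, s2)) {
      return(list(x = s1, y = s2, k = NULL, mh = NULL))
    }
  }
  NULL
}
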