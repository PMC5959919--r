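#' Parental haplotype genome (haplome)
#'
#' A haplome is one parental genome of the fused hybrid: a set of named
#' chromosome sequences plus centromere, telomere-mask and repeat
#' annotations.  All coordinates in this package are 1-based closed
#' intervals; BED-family exports convert to 0-based half-open.
#'
#' @param name haplome label, e.g. \code{"A"} or \code{"B"}.
#' @param seqs named \code{DNAStringSet} (or named character vector) of
#'   chromosome sequences; names are chromosome ids and must be unique.
#' @param centromeres,telomeres,repeats data.frames with columns
#'   \code{chrom,start,end} (repeats additionally \code{class}, one of
#'   \code{ty_like}, \code{rDNA}, \code{transposon}, \code{other}, and
#'   \code{copy_id}).  Telomere masks must touch the chromosome ends.
#' @return An object of class \code{Haplome}.
#' @export
Haplome <- function(name, seqs, centromeres = NULL, telomeres = NULL,
                    repeats = NULL) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) > 0) {
    stop_input("chromosome ids must be named and unique")
  }
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  chk <- function(df, what, need_ends = FALSE) {
    if (is.null(df) || nrow(df) == 0) return(invisible(NULL))
    if (!all(df$chrom %in% names(lens))) {
      stop_input(what, " annotation references unknown chromosome")
    }
    bad <- df$start < 1 | df$end > lens[df$chrom] | df$start > df$end
    if (any(bad)) stop_input(what, " interval outside [1, chromosome length]")
    if (need_ends) {
      touches <- df$start == 1 | df$end == lens[df$chrom]
      if (!all(touches)) stop_input("telomere masks must touch chromosome ends")
    }
    invisible(NULL)
  }
  chk(centromeres, "centromere")
  chk(telomeres, "telomere", need_ends = TRUE)
  chk(repeats, "repeat")
  structure(list(name = name, seqs = seqs, lengths = lens,
                 centromeres = centromeres, telomeres = telomeres,
                 repeats = repeats),
            class = "Haplome")
}

#' @export
print.Haplome <- function(x, ...) {
  cat("Haplome", x$name, "-", length(x$lengths), "chromosomes,",
      sum(x$lengths), "bp total\n")
  invisible(x)
}

#' Chromosome lengths of a haplome
#' @param haplome a \code{\link{Haplome}}.
#' @return Named integer vector of lengths.
#' @export
chrom_lengths <- function(haplome) haplome$lengths

## chromosome sequence as plain character
chrom_seq <- function(haplome, chrom) as.character(haplome$seqs[[chrom]])

## substring of a chromosome, clamped to [1, length]
subseq_chr <- function(haplome, chrom, start, end) {
  L <- haplome$lengths[[chrom]]
  start <- max(1L, as.integer(start)); end <- min(L, as.integer(end))
  if (start > end) return("")
  as.character(Biostrings::subseq(haplome$seqs[[chrom]], start, end))
}

#' Dual-haplotype hybrid reference
#'
#' Combines the two parental haplomes with their homolog pairing, a set of
#' colinear alignment blocks (sparse anchors for coordinate liftover) and
#' the inter-haplotype variant map.
#'
#' @param haplomeA,haplomeB \code{\link{Haplome}} objects.
#' @param pairing named character vector mapping chromosome ids of A to the
#'   homologous chromosome ids of B; must be a bijection.
#' @param blocks named list (by A chromosome id) of data.frames with columns
#'   \code{a_start,b_start,len}: colinear gap-free alignment blocks between
#'   the homologs, sorted, non-overlapping.
#' @param variant_map data.frame as produced by
#'   \code{\link{build_variant_map}}; if \code{NULL} it is computed from the
#'   blocks.
#' @return An object of class \code{DualReference} with elements \code{A},
#'   \code{B}, \code{pairing}, \code{blocks}, \code{variant_map}.
#' @export
DualReference <- function(haplomeA, haplomeB, pairing, blocks,
                          variant_map = NULL) {
  if (anyDuplicated(pairing) > 0 || anyDuplicated(names(pairing)) > 0) {
    stop_input("homolog pairing must be a bijection")
  }
  if (!all(names(pairing) %in% names(haplomeA$lengths)) ||
      !all(pairing %in% names(haplomeB$lengths))) {
    stop_input("pairing references unknown chromosomes")
  }
  if (!all(names(blocks) %in% names(pairing))) {
    stop_input("alignment blocks reference unpaired chromosome")
  }
  if (is.null(variant_map)) {
    variant_map <- build_variant_map(haplomeA, haplomeB, blocks)
  }
  structure(list(A = haplomeA, B = haplomeB, pairing = pairing,
                 blocks = blocks, variant_map = variant_map),
            class = "DualReference")
}

#' @export
print.DualReference <- function(x, ...) {
  cat("DualReference:", length(x$pairing), "homolog pairs;",
      nrow(x$variant_map), "inter-haplotype variants\n")
  invisible(x)
}

## fetch the haplome for a haplotype label
haplome_of <- function(dual_ref, haplotype) {
  switch(haplotype, A = dual_ref$A, B = dual_ref$B,
         stop_input("haplotype must be 'A' or 'B'"))
}

## homologous chromosome id for (haplotype, chrom)
homolog_chrom <- function(dual_ref, haplotype, chrom) {
  if (haplotype == "A") {
    if (!chrom %in% names(dual_ref$pairing)) {
      stop_input("chromosome ", chrom, " has no homolog pairing")
    }
    unname(dual_ref$pairing[[chrom]])
  } else {
    hit <- names(dual_ref$pairing)[dual_ref$pairing == chrom]
    if (length(hit) != 1) stop_input("chromosome ", chrom, " has no homolog pairing")
    hit
  }
}

#' Scan a haplome for restriction recognition sites
#'
#' Finds every forward-strand occurrence of a recognition motif.  For a
#' palindromic motif (like TCGA) the forward scan is exhaustive; a
#' non-palindromic motif is scanned on both strands only when
#' \code{both_strands = TRUE}, otherwise an error is raised.  \code{N}
#' bases never match.
#'
#' @param haplome a \code{\link{Haplome}}.
#' @param motif recognition sequence (default \code{"TCGA"}); length >= 2.
#' @param both_strands scan the reverse strand of a non-palindromic motif.
#' @param cut_after offset of the cut position within the motif (TaqI cuts
#'   T^CGA, i.e. after base 1, leaving a 5' \code{"CG"} cohesive overhang).
#' @return A \code{RestrictionSiteIndex}: list with \code{motif},
#'   \code{overhang}, \code{cut_after} and \code{sites}, a named list of
#'   sorted 1-based motif start positions per chromosome (with a
#'   \code{strand} attribute when both strands are scanned).
#' @export
scan_restriction_sites <- function(haplome, motif = "TCGA",
                                   both_strands = FALSE, cut_after = 1L) {
  if (nchar(motif) < 2) stop_input("motif length must be >= 2")
  palindromic <- identical(motif, revcomp(motif))
  if (!palindromic && !both_strands) {
    stop_input("motif ", motif, " is not palindromic; set both_strands = TRUE")
  }
  pat <- Biostrings::DNAString(motif)
  sites <- lapply(names(haplome$lengths), function(ch) {
    fwd <- Biostrings::start(Biostrings::matchPattern(pat, haplome$seqs[[ch]],
                                                      fixed = TRUE))
    if (palindromic) return(sort(fwd))
    rev <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::reverseComplement(pat), haplome$seqs[[ch]], fixed = TRUE))
    pos <- c(fwd, rev)
    o <- order(pos)
    out <- pos[o]
    attr(out, "strand") <- c(rep("+", length(fwd)), rep("-", length(rev)))[o]
    out
  })
  names(sites) <- names(haplome$lengths)
  overhang <- substr(motif, cut_after + 1L, nchar(motif) - cut_after)
  structure(list(motif = motif, overhang = overhang,
                 cut_after = as.integer(cut_after), sites = sites),
            class = "RestrictionSiteIndex")
}

#' @export
print.RestrictionSiteIndex <- function(x, ...) {
  cat("RestrictionSiteIndex", x$motif, "-", sum(lengths(x$sites)),
      "sites on", length(x$sites), "chromosomes\n")
  invisible(x)
}

#' Build the inter-haplotype variant map from colinear alignment blocks
#'
#' Given gap-free colinear blocks between homologous chromosomes (from the
#' simulator, or converted from an external pairwise alignment), emits SNV
#' records by per-base comparison inside blocks and InDel records for the
#' gaps between consecutive blocks (VCF-style, anchored on the preceding
#' matched base).
#'
#' @param haplomeA,haplomeB \code{\link{Haplome}} objects.
#' @param blocks named list by A-chromosome id of data.frames
#'   \code{a_start,b_start,len}.
#' @return data.frame with columns \code{chrom_a,pos_a,chrom_b,pos_b,type,
#'   ref,alt}; attribute \code{"density"} holds per-chromosome SNV/InDel
#'   densities per kb.
#' @export
build_variant_map <- function(haplomeA, haplomeB, blocks) {
  out <- vector("list", length(blocks))
  dens <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    ca <- names(blocks)[i]
    cb <- ca  # homolog naming is shared; pairing validated by DualReference
    if (!cb %in% names(haplomeB$lengths)) {
      stop_input("no homologous chromosome for ", ca)
    }
    bl <- blocks[[i]]
    if (nrow(bl) == 0) stop_input("empty block table for ", ca)
    if (is.unsorted(bl$a_start) || is.unsorted(bl$b_start)) {
      stop_input("alignment blocks must be sorted for ", ca)
    }
    if (any(bl$a_start[-1] < (bl$a_start + bl$len)[-nrow(bl)]) ||
        any(bl$b_start[-1] < (bl$b_start + bl$len)[-nrow(bl)])) {
      stop_input("overlapping alignment blocks for ", ca)
    }
    sa <- strsplit(chrom_seq(haplomeA, ca), "", fixed = TRUE)[[1]]
    sb <- strsplit(chrom_seq(haplomeB, cb), "", fixed = TRUE)[[1]]
    snvs <- vector("list", nrow(bl))
    indels <- vector("list", nrow(bl))
    for (k in seq_len(nrow(bl))) {
      ia <- bl$a_start[k]:(bl$a_start[k] + bl$len[k] - 1L)
      ib <- bl$b_start[k]:(bl$b_start[k] + bl$len[k] - 1L)
      mm <- which(sa[ia] != sb[ib])
      if (length(mm)) {
        snvs[[k]] <- data.frame(chrom_a = ca, pos_a = ia[mm], chrom_b = cb,
                                pos_b = ib[mm], type = "SNV",
                                ref = sa[ia[mm]], alt = sb[ib[mm]])
      }
      if (k < nrow(bl)) {
        a_end <- bl$a_start[k] + bl$len[k] - 1L
        b_end <- bl$b_start[k] + bl$len[k] - 1L
        gap_a <- bl$a_start[k + 1L] - a_end - 1L
        gap_b <- bl$b_start[k + 1L] - b_end - 1L
        if (gap_a > 0 || gap_b > 0) {
          ref <- paste(sa[a_end:(a_end + gap_a)], collapse = "")
          alt <- paste(sb[b_end:(b_end + gap_b)], collapse = "")
          indels[[k]] <- data.frame(chrom_a = ca, pos_a = a_end, chrom_b = cb,
                                    pos_b = b_end, type = "InDel",
                                    ref = ref, alt = alt)
        }
      }
    }
    vm <- rbind(do.call(rbind, snvs), do.call(rbind, indels))
    if (is.null(vm)) {
      vm <- data.frame(chrom_a = character(), pos_a = integer(),
                       chrom_b = character(), pos_b = integer(),
                       type = character(), ref = character(),
                       alt = character())
    }
    vm <- vm[order(vm$pos_a), , drop = FALSE]
    kb <- haplomeA$lengths[[ca]] / 1000
    dens[[i]] <- data.frame(chrom = ca,
                            snv_per_kb = sum(vm$type == "SNV") / kb,
                            indel_per_kb = sum(vm$type == "InDel") / kb)
    out[[i]] <- vm
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "density") <- do.call(rbind, dens)
  res
}

## map a single position to the homolog; positions falling in a gap are
## clamped to the nearest aligned base on the left
liftover_pos <- function(dual_ref, haplotype, chrom, pos) {
  if (haplotype == "A") {
    bl <- dual_ref$blocks[[chrom]]
    if (is.null(bl)) stop_input("chromosome ", chrom, " is unpaired")
    from <- bl$a_start; to <- bl$b_start
  } else {
    ca <- homolog_chrom(dual_ref, "B", chrom)
    bl <- dual_ref$blocks[[ca]]
    if (is.null(bl)) stop_input("chromosome ", chrom, " is unpaired")
    from <- bl$b_start; to <- bl$a_start
  }
  k <- findInterval(pos, from)
  if (k == 0L) return(to[1L])
  off <- min(pos - from[k], bl$len[k] - 1L)
  to[k] + off
}

#' Lift an interval onto the homologous chromosome
#'
#' Uses the sparse colinear alignment blocks of the dual reference; bases
#' between blocks (InDel gaps) are clamped to the nearest aligned base, so
#' the lifted length differs from the input only by net InDel content.
#'
#' @param dual_ref a \code{\link{DualReference}}.
#' @param haplotype \code{"A"} or \code{"B"}: the haplotype the input
#'   interval lives on.
#' @param chrom chromosome id on that haplotype.
#' @param start,end 1-based closed interval.
#' @return list with \code{haplotype}, \code{chrom}, \code{start},
#'   \code{end} on the homolog.
#' @export
liftover <- function(dual_ref, haplotype, chrom, start, end) {
  s <- liftover_pos(dual_ref, haplotype, chrom, start)
  e <- liftover_pos(dual_ref, haplotype, chrom, end)
  list(haplotype = if (haplotype == "A") "B" else "A",
       chrom = homolog_chrom(dual_ref, haplotype, chrom),
       start = min(s, e), end = max(s, e))
}

## sorted variant positions for one haplotype/chromosome (SNVs only)
variant_positions <- function(dual_ref, haplotype, chrom) {
  vm <- dual_ref$variant_map
  if (haplotype == "A") {
    sort(vm$pos_a[vm$chrom_a == chrom & vm$type == "SNV"])
  } else {
    sort(vm$pos_b[vm$chrom_b == chrom & vm$type == "SNV"])
  }
}

## repeat class at (haplotype, chrom, pos) with slack, or NA
repeat_class_at <- function(dual_ref, haplotype, chrom, pos, slack = 50) {
  rep_df <- haplome_of(dual_ref, haplotype)$repeats
  if (is.null(rep_df) || nrow(rep_df) == 0) return(NA_character_)
  sub <- rep_df[rep_df$chrom == chrom &
                  rep_df$start - slack <= pos & rep_df$end + slack >= pos, ,
                drop = FALSE]
  if (nrow(sub) == 0) NA_character_ else sub$class[1L]
}
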