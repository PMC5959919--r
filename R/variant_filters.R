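variant_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "|")
}

#' Post-filter raw small-variant calls from the hybrid yeast analysis
#'
#' Applies the three elimination rules used after raw calling:
#' \enumerate{
#'   \item variants inside masked regions (AT-rich, rDNA, telomeres) are
#'     false positives;
#'   \item variants where local coverage is below 50\% of the sample's
#'     average coverage (strict \code{<}) are false positives;
#'   \item variants present in \emph{every} sample (controls included) are
#'     shared parental differences, not induced mutations.
#' }
#' Each rule is a pure predicate on the record, so the survivor set does
#' not depend on application order.
#'
#' @param calls data.frame with columns \code{sample, chrom, pos, ref, alt,
#'   type, depth} (local read depth at the call).
#' @param coverage_stats named numeric vector: average coverage per sample;
#'   must cover every sample present.
#' @param masks data.frame \code{chrom,start,end} (optionally \code{class})
#'   of masked regions.
#' @param low_cov_frac coverage-ratio cutoff (default 0.5).
#' @return list with \code{passed}, \code{removed} (with a \code{reason}
#'   column) and \code{report} (per-rule removal counts).
#' @export
filter_yeast_variants <- function(calls, coverage_stats, masks,
                                  low_cov_frac = 0.5) {
  if (nrow(calls) == 0) {
    return(list(passed = calls, removed = cbind(calls, reason = character(0)),
                report = data.frame(rule = character(), removed = integer())))
  }
  if (is.null(coverage_stats) || !all(calls$sample %in% names(coverage_stats))) {
    stop_input("coverage stats missing for one or more samples")
  }
  in_mask <- vapply(seq_len(nrow(calls)), function(i) {
    ivl_hits_df(masks, calls$chrom[i], calls$pos[i], calls$pos[i])
  }, logical(1))
  low_cov <- calls$depth < low_cov_frac * coverage_stats[calls$sample]
  n_samples <- length(unique(calls$sample))
  keys <- variant_key(calls)
  ## the commonality rule needs at least two samples to be meaningful
  shared_all <- if (n_samples < 2) rep(FALSE, nrow(calls)) else {
    keys %in% names(which(
      vapply(split(calls$sample, keys), function(s) {
        length(unique(s)) == n_samples
      }, logical(1))))
  }
  drop <- in_mask | low_cov | shared_all
  reason <- ifelse(in_mask, "masked_region",
                   ifelse(low_cov, "low_coverage", "shared_all_samples"))
  list(passed = calls[!drop, , drop = FALSE],
       removed = cbind(calls[drop, , drop = FALSE],
                       reason = reason[drop]),
       report = data.frame(rule = c("masked_region", "low_coverage",
                                    "shared_all_samples"),
                           removed = c(sum(in_mask), sum(low_cov),
                                       sum(shared_all))))
}

#' Post-filter raw small-variant calls from the plant analysis
#'
#' Rules:
#' \enumerate{
#'   \item variants also called in control plants are excluded;
#'   \item only variants with mutation frequency (alt reads / total reads)
#'     strictly above \code{min_freq} (default 0.4) are kept;
#'   \item InDels additionally require fewer than \code{max_control_reads}
#'     (default 2, strict \code{<}) supporting reads in controls and locus
#'     uniqueness: no second candidate InDel within the record's reference
#'     footprint;
#'   \item SNVs at multi-allelic loci (two alternate alleles at one
#'     position in one sample) are excluded, operationalizing the manual
#'     single-locus rule.
#' }
#' An InDel with no control-evidence entry cannot be resolved and is held,
#' not passed.
#'
#' @param calls data.frame \code{sample, chrom, pos, ref, alt, type, depth,
#'   alt_count}.
#' @param control_calls data.frame of control-plant calls (same key
#'   columns).
#' @param control_evidence data.frame \code{chrom,pos,ref,alt,n_reads}:
#'   reads supporting each candidate InDel in controls.
#' @param min_freq,max_control_reads rule thresholds.
#' @return list \code{passed}, \code{held}, \code{removed}, \code{report}.
#' @export
filter_plant_variants <- function(calls, control_calls, control_evidence,
                                  min_freq = 0.4, max_control_reads = 2) {
  if (nrow(calls) == 0) {
    return(list(passed = calls, held = calls,
                removed = cbind(calls, reason = character(0)),
                report = data.frame(rule = character(), removed = integer())))
  }
  keys <- variant_key(calls)
  in_control <- keys %in% variant_key(control_calls)
  freq <- calls$alt_count / calls$depth
  low_freq <- !(freq > min_freq)
  is_indel <- calls$type == "InDel"
  footprint_end <- calls$pos + nchar(calls$ref) - 1L
  not_unique <- vapply(seq_len(nrow(calls)), function(i) {
    if (!is_indel[i]) return(FALSE)
    other <- is_indel & calls$sample == calls$sample[i] &
      calls$chrom == calls$chrom[i] & seq_len(nrow(calls)) != i &
      calls$pos <= footprint_end[i] & footprint_end >= calls$pos[i]
    any(other)
  }, logical(1))
  ctrl_key <- if (nrow(control_evidence) > 0) {
    setNames(control_evidence$n_reads, variant_key(control_evidence))
  } else setNames(integer(), character())
  ctrl_reads <- unname(ctrl_key[keys])
  held <- is_indel & is.na(ctrl_reads) & !in_control & !low_freq & !not_unique
  ctrl_fail <- is_indel & !is.na(ctrl_reads) & !(ctrl_reads < max_control_reads)
  multi <- vapply(seq_len(nrow(calls)), function(i) {
    if (is_indel[i]) return(FALSE)
    sum(calls$sample == calls$sample[i] & calls$chrom == calls$chrom[i] &
          calls$pos == calls$pos[i] & calls$type == "SNV") > 1
  }, logical(1))
  drop <- in_control | low_freq | ctrl_fail | not_unique | multi
  reason <- rep(NA_character_, nrow(calls))
  reason[multi] <- "multi_allelic_locus"
  reason[not_unique] <- "indel_not_unique"
  reason[ctrl_fail] <- "control_indel_reads"
  reason[low_freq] <- "low_frequency"
  reason[in_control] <- "in_control"
  keep <- !drop & !held
  list(passed = calls[keep, , drop = FALSE],
       held = calls[held & !drop, , drop = FALSE],
       removed = cbind(calls[drop, , drop = FALSE], reason = reason[drop]),
       report = data.frame(
         rule = c("in_control", "low_frequency", "control_indel_reads",
                  "indel_not_unique", "multi_allelic_locus", "held_unresolved"),
         removed = c(sum(in_control), sum(low_freq), sum(ctrl_fail),
                     sum(not_unique), sum(multi), sum(held & !drop))))
}

#' Compute an AT-rich mask from a haplome
#'
#' Windows whose AT fraction exceeds \code{at_frac} are masked; used when
#' no curated AT-rich annotation is supplied.
#'
#' @param haplome a \code{\link{Haplome}}.
#' @param window window size in bp (default 100).
#' @param at_frac AT-fraction threshold (strict \code{>}, default 0.80).
#' @return data.frame \code{chrom,start,end,class = "AT_rich"}.
#' @export
at_rich_mask <- function(haplome, window = 100, at_frac = 0.80) {
  rows <- list()
  for (ch in names(haplome$lengths)) {
    L <- haplome$lengths[[ch]]
    nb <- L %/% window
    if (nb == 0) next
    v <- Biostrings::letterFrequencyInSlidingView(
      haplome$seqs[[ch]], window, c("A", "T"))
    starts <- seq(1L, nb * window, by = window)
    frac <- rowSums(v[starts, , drop = FALSE]) / window
    hit <- which(frac > at_frac)
    if (length(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = starts[hit], end = starts[hit] + window - 1L,
        class = "AT_rich")
    }
  }
  if (length(rows)) do.call(rbind, rows) else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               class = character())
  }
}
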