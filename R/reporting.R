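#' Tally rearrangement events by category
#'
#' Counts events (truth or calls) by the standard summary categories:
#' SNV, insertion, deletion, aneuploid, BIR, SGC, TL (non-homologous),
#' TL (homologous), large CNV.
#'
#' @param events data.frame with a \code{type} column (truth events, or
#'   calls mapped onto the same vocabulary), or a character vector of
#'   types.
#' @param categories named character list mapping category label to the
#'   type tags it counts; defaults cover the package vocabulary.
#' @return data.frame \code{category, n}; unknown type tags are an error.
#' @export
tally_events <- function(events, categories = default_categories()) {
  types <- if (is.data.frame(events)) events$type else as.character(events)
  known <- unlist(categories, use.names = FALSE)
  if (length(types) && !all(types %in% known)) {
    stop_input("unknown event type tag: ",
               paste(setdiff(types, known), collapse = ", "))
  }
  data.frame(category = names(categories),
             n = vapply(categories, function(tags) {
               sum(types %in% tags)
             }, integer(1)),
             row.names = NULL)
}

#' @rdname tally_events
#' @export
default_categories <- function() {
  list("SNV" = "SNV",
       "Insertion" = "insertion",
       "Deletion" = "deletion",
       "Aneuploid" = c("aneuploidy_gain", "aneuploidy_loss"),
       "Break-induced repair" = "BIR",
       "Short gene conversion" = "SGC",
       "Translocation (non-homologous)" = "TL_nonhomologous",
       "Translocation (homologous)" = "TL_homologous",
       "Large CNV" = c("large_deletion", "tandem_duplication"))
}

#' Events per individual, rounded half-up
#'
#' @param event_count total events observed.
#' @param n_individuals number of individuals assayed (> 0).
#' @param decimals decimal places of the printed rate.
#' @return Rate per individual; the raw ratio is kept in attribute
#'   \code{"raw"} and the rounding mode in \code{"rounding"}.
#' @export
rate_per_individual <- function(event_count, n_individuals, decimals = 2) {
  if (n_individuals == 0) stop_input("n_individuals must be positive")
  r <- event_count / n_individuals
  out <- round_half_up(r, decimals)
  attr(out, "raw") <- r
  attr(out, "rounding") <- "half-up"
  out
}

#' Percentage of individuals carrying at least one event
#'
#' @param n_with individuals with >= 1 event.
#' @param n_total individuals assayed (> 0).
#' @param decimals decimal places.
#' @return Percentage (half-up), raw value in attribute \code{"raw"}.
#' @export
percent_with_event <- function(n_with, n_total, decimals = 1) {
  if (n_total == 0) stop_input("n_total must be positive")
  p <- 100 * n_with / n_total
  out <- round_half_up(p, decimals)
  attr(out, "raw") <- p
  attr(out, "rounding") <- "half-up"
  out
}

#' Two-sided F test for a ratio of variances
#'
#' Compares the dispersion of two samples (e.g. trait distributions of two
#' ploidy groups) via the variance ratio.  Accepts raw samples or
#' precomputed \code{list(var =, n =)} summaries.
#'
#' @param a,b numeric vectors, or lists with elements \code{var} and
#'   \code{n}.
#' @param larger_over_smaller report the ratio with the larger variance in
#'   the numerator.
#' @return list \code{ratio, statistic, df1, df2, p_value}.
#' @export
variance_ratio_test <- function(a, b, larger_over_smaller = FALSE) {
  unpack <- function(x) {
    if (is.list(x)) list(v = x$var, n = x$n) else list(v = var(x), n = length(x))
  }
  A <- unpack(a); B <- unpack(b)
  if (B$v == 0) stop_input("denominator variance is zero")
  if (larger_over_smaller && B$v > A$v) { tmp <- A; A <- B; B <- tmp }
  f <- A$v / B$v
  df1 <- A$n - 1; df2 <- B$n - 1
  p <- 2 * min(pf(f, df1, df2), 1 - pf(f, df1, df2))
  p <- min(p, 1)
  list(ratio = f, statistic = f, df1 = df1, df2 = df2, p_value = p)
}

#' Export karyotype and link files for circular plotting
#'
#' Writes a karyotype table (chromosome, length, haplotype tag) and a
#' BEDPE-compatible link file connecting the two loci of each junction or
#' inter-homolog event, ready for circular-plot tools.  Rendering is out
#' of scope.
#'
#' @param calls junction calls (\code{\link{call_breakpoints}} output or
#'   truth junctions) and/or homolog events with \code{chrom,start,end}.
#' @param dual_ref the \code{\link{DualReference}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths (\code{karyotype.tsv},
#'   \code{links.bedpe}).
#' @export
export_circular_links <- function(calls, dual_ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kar <- rbind(
    data.frame(chrom = paste0("A_", names(dual_ref$A$lengths)),
               length = unname(dual_ref$A$lengths), haplotype = "A"),
    data.frame(chrom = paste0("B_", names(dual_ref$B$lengths)),
               length = unname(dual_ref$B$lengths), haplotype = "B"))
  kar_path <- file.path(dir, "karyotype.tsv")
  write.table(kar, kar_path, sep = "\t", quote = FALSE, row.names = FALSE)
  links_path <- file.path(dir, "links.bedpe")
  if (!is.null(calls) && nrow(calls) > 0) {
    need <- c("hap_left", "chrom_left", "pos_left", "hap_right",
              "chrom_right", "pos_right")
    if (!all(need %in% names(calls))) {
      stop_input("calls must carry junction locus columns")
    }
    cl <- paste0(calls$hap_left, "_", calls$chrom_left)
    cr <- paste0(calls$hap_right, "_", calls$chrom_right)
    if (!all(c(cl, cr) %in% kar$chrom)) {
      stop_input("calls reference unknown chromosomes")
    }
    links <- data.frame(chrom1 = cl, start1 = calls$pos_left - 1L,
                        end1 = calls$pos_left, chrom2 = cr,
                        start2 = calls$pos_right - 1L,
                        end2 = calls$pos_right,
                        name = calls$mechanism %||% ".",
                        score = calls$n_clips %||% 0L)
    write.table(links, links_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    file.create(links_path)
  }
  invisible(c(karyotype = kar_path, links = links_path))
}
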