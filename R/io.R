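#' Write haplome or restructured-genome sequences to FASTA
#'
#' @param x a \code{\link{Haplome}} or a \code{DNAStringSet}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_genome_fasta <- function(x, path) {
  seqs <- if (methods::is(x, "Haplome")) x$seqs else x
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write an annotation data.frame as BED
#'
#' Converts the package's 1-based closed intervals to BED's 0-based
#' half-open convention; the \code{name} column is taken from
#' \code{class}/\code{type}/\code{name} when present.
#'
#' @param df data.frame with \code{chrom,start,end} (+ optional name-like
#'   column).
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_bed <- function(df, path) {
  name <- df$class %||% df$type %||% df$name %||% rep(".", nrow(df))
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    name = name)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' @param track \code{CoverageTrack} data.frame.
#' @param path output file.
#' @param column which value column to export (default \code{depth}).
#' @return Invisibly, \code{path}.
#' @export
write_bedgraph <- function(track, path, column = "depth") {
  out <- data.frame(chrom = track$chrom, start = track$start - 1L,
                    end = track$end, value = track[[column]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' @param path bedGraph file (chrom, 0-based start, end, value).
#' @param haplotype haplotype label to attach.
#' @return \code{CoverageTrack}-style data.frame (no mask column).
#' @export
read_bedgraph <- function(path, haplotype = NA_character_) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "depth"),
                          stringsAsFactors = FALSE)
  df$start <- df$start + 1L
  df$masked <- FALSE
  attr(df, "haplotype") <- haplotype
  attr(df, "bin_size") <- df$end[1] - df$start[1] + 1L
  df
}

#' Export the inter-haplotype variant map as VCF 4.2
#'
#' Records use parent-A coordinates; the homolog chromosome/position is
#' carried in the INFO field (\code{HOM_CHROM}, \code{HOM_POS}).
#'
#' @param dual_ref a \code{\link{DualReference}}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_variant_vcf <- function(dual_ref, path) {
  vm <- dual_ref$variant_map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=taqing",
               paste0("##INFO=<ID=HOM_CHROM,Number=1,Type=String,",
                      "Description=\"Homolog chromosome\">"),
               paste0("##INFO=<ID=HOM_POS,Number=1,Type=Integer,",
                      "Description=\"Homolog position\">"),
               paste0("##INFO=<ID=VT,Number=1,Type=String,",
                      "Description=\"Variant type\">"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(vm) > 0) {
    info <- paste0("HOM_CHROM=", vm$chrom_b, ";HOM_POS=", vm$pos_b,
                   ";VT=", vm$type)
    writeLines(paste(vm$chrom_a, vm$pos_a, ".", vm$ref, vm$alt, ".",
                     "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}

#' Write truth or called junctions as BEDPE
#'
#' @param junctions data.frame with left/right junction locus columns and a
#'   \code{mechanism} column.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_junctions_bedpe <- function(junctions, path) {
  if (nrow(junctions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  out <- data.frame(
    chrom1 = paste0(junctions$hap_left, "_", junctions$chrom_left),
    start1 = junctions$pos_left - 1L, end1 = junctions$pos_left,
    chrom2 = paste0(junctions$hap_right, "_", junctions$chrom_right),
    start2 = junctions$pos_right - 1L, end2 = junctions$pos_right,
    name = junctions$mechanism, score = junctions$n_clips %||% 0L,
    strand1 = "+", strand2 = "+")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
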