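#' 3D chromosome coordinate model
#'
#' Anchors map genomic positions to points in nuclear space (micrometres);
#' loci between anchors are placed by linear interpolation.
#'
#' @param anchors data.frame \code{chrom, pos, x, y, z}; per chromosome the
#'   positions must be sorted and the coordinates finite.
#' @return An object of class \code{CoordinateModel}.
#' @export
CoordinateModel <- function(anchors) {
  need <- c("chrom", "pos", "x", "y", "z")
  if (!all(need %in% names(anchors))) stop_input("anchors need chrom,pos,x,y,z")
  if (!all(is.finite(as.matrix(anchors[, c("x", "y", "z")])))) {
    stop_input("anchor coordinates must be finite")
  }
  anchors <- anchors[order(anchors$chrom, anchors$pos), , drop = FALSE]
  rownames(anchors) <- NULL
  structure(list(anchors = anchors), class = "CoordinateModel")
}

#' @export
print.CoordinateModel <- function(x, ...) {
  cat("CoordinateModel:", length(unique(x$anchors$chrom)), "chromosomes,",
      nrow(x$anchors), "anchors\n")
  invisible(x)
}

#' Read / write a coordinate model as TSV
#'
#' Plain five-column TSV (\code{chrom, pos_bp, x_um, y_um, z_um}); the
#' format a converter from any published model should produce (conversion
#' scaling belongs to the converter, recorded in its own metadata).
#'
#' @param path TSV file.
#' @return \code{read_coordinate_model}: a \code{\link{CoordinateModel}}.
#' @export
read_coordinate_model <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "pos", "x", "y", "z")
  CoordinateModel(df)
}

#' @rdname read_coordinate_model
#' @param model a \code{\link{CoordinateModel}}.
#' @export
write_coordinate_model <- function(model, path) {
  df <- model$anchors
  names(df) <- c("chrom", "pos_bp", "x_um", "y_um", "z_um")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Interpolate the 3D position of a genomic locus
#'
#' Exact anchor positions return the anchor coordinates; positions between
#' anchors are linearly interpolated; positions outside the anchor span are
#' an error (no extrapolation).
#'
#' @param model a \code{\link{CoordinateModel}}.
#' @param chrom chromosome id.
#' @param pos genomic position (bp).
#' @return Numeric xyz vector (micrometres).
#' @export
locus_to_point <- function(model, chrom, pos) {
  an <- model$anchors[model$anchors$chrom == chrom, , drop = FALSE]
  if (nrow(an) == 0) stop_input("chromosome ", chrom, " not in model")
  if (pos < an$pos[1] || pos > an$pos[nrow(an)]) {
    stop_input("position outside anchor span of ", chrom)
  }
  i <- findInterval(pos, an$pos)
  if (an$pos[i] == pos) return(c(an$x[i], an$y[i], an$z[i]))
  f <- (pos - an$pos[i]) / (an$pos[i + 1] - an$pos[i])
  (1 - f) * c(an$x[i], an$y[i], an$z[i]) +
    f * c(an$x[i + 1], an$y[i + 1], an$z[i + 1])
}

#' Euclidean 3D distance between two genomic loci
#'
#' @param model a \code{\link{CoordinateModel}}.
#' @param chrom_a,pos_a,chrom_b,pos_b the two loci.
#' @return Distance in micrometres.
#' @export
pair_distance <- function(model, chrom_a, pos_a, chrom_b, pos_b) {
  sqrt(sum((locus_to_point(model, chrom_a, pos_a) -
              locus_to_point(model, chrom_b, pos_b))^2))
}

#' Empirical random-pair distance null
#'
#' Draws \code{n} pairs of loci and computes their 3D distances to form
#' the empirical null against which observed translocation-partner
#' distances are placed.  By default both loci of a pair are sampled
#' uniformly per base pair of total genome span (chromosomes weighted by
#' their anchor span); \code{genomic_weighting = "chromosome"} samples
#' chromosomes uniformly instead.
#'
#' @param model a \code{\link{CoordinateModel}}.
#' @param n number of pairs (default 10000).
#' @param seed RNG seed (stored in the result).
#' @param genomic_weighting \code{"length"} (default) or
#'   \code{"chromosome"}.
#' @return \code{DistanceNull}: list \code{n, distances, mean, cdf, seed}.
#' @export
random_pair_null <- function(model, n = 10000, seed = 1L,
                             genomic_weighting = c("length", "chromosome")) {
  if (n < 1) stop_input("n must be >= 1")
  genomic_weighting <- match.arg(genomic_weighting)
  set.seed(seed)
  an <- model$anchors
  chroms <- unique(an$chrom)
  span <- vapply(chroms, function(ch) {
    p <- an$pos[an$chrom == ch]
    c(min(p), max(p))
  }, numeric(2))
  w <- span[2, ] - span[1, ] + 1
  if (genomic_weighting == "chromosome") w <- rep(1, length(chroms))
  draw <- function(k) {
    ci <- sample.int(length(chroms), k, replace = TRUE, prob = w)
    pos <- span[1, ci] + runif(k) * (span[2, ci] - span[1, ci])
    list(chrom = chroms[ci], pos = pos)
  }
  a <- draw(n); b <- draw(n)
  d <- vapply(seq_len(n), function(i) {
    pair_distance(model, a$chrom[i], a$pos[i], b$chrom[i], b$pos[i])
  }, numeric(1))
  structure(list(n = n, distances = d, mean = mean(d), cdf = ecdf(d),
                 seed = seed),
            class = "DistanceNull")
}

#' @export
print.DistanceNull <- function(x, ...) {
  cat("DistanceNull: n =", x$n, " mean =", round(x$mean, 3), "um\n")
  invisible(x)
}

#' Place observed locus pairs within the distance null
#'
#' Computes each pair's 3D distance and its empirical-CDF percentile
#' (rank / n against the stored null sample), plus the set mean.
#'
#' @param null a \code{DistanceNull} from \code{\link{random_pair_null}}.
#' @param model the \code{\link{CoordinateModel}} used for the null.
#' @param pair_set data.frame \code{chrom_a,pos_a,chrom_b,pos_b}.
#' @return list \code{pairs} (with \code{distance} and \code{percentile}
#'   columns) and \code{set_mean}.
#' @export
place_pairs <- function(null, model, pair_set) {
  if (is.null(pair_set) || nrow(pair_set) == 0) {
    stop_input("empty pair set")
  }
  d <- vapply(seq_len(nrow(pair_set)), function(i) {
    pair_distance(model, pair_set$chrom_a[i], pair_set$pos_a[i],
                  pair_set$chrom_b[i], pair_set$pos_b[i])
  }, numeric(1))
  out <- pair_set
  out$distance <- d
  out$percentile <- vapply(d, function(x) mean(null$distances <= x), numeric(1))
  list(pairs = out, set_mean = mean(d))
}
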