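#' Default repeat families for the simulated reference
#'
#' \code{ty_like}: dispersed LTR-retrotransposon-like copies;
#' \code{transposon}: a second dispersed family; \code{rDNA}: one tandem
#' array of near-identical units.  Dispersed families are organized as
#' subfamilies of two near-identical copies on different chromosomes
#' (mirroring retrotransposon subfamily structure); copies within a
#' subfamily diverge from its consensus by \code{divergence} substitutions
#' per base, keeping within-subfamily identity >= 99\% at the defaults,
#' while distinct subfamilies are unrelated.
#'
#' @return Named list of family specs.
#' @export
default_repeat_spec <- function() {
  list(
    ty_like    = list(n = 8, length = 5000, divergence = 0.005),
    transposon = list(n = 4, length = 2500, divergence = 0.005),
    rDNA       = list(n_units = 4, unit_length = 2000, divergence = 0.002)
  )
}

## mutate a character-vector sequence at a per-base substitution rate
mutate_chars <- function(chars, rate) {
  if (rate <= 0) return(chars)
  idx <- which(runif(length(chars)) < rate)
  if (length(idx)) {
    chars[idx] <- vapply(chars[idx], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  chars
}

#' Simulate a pair of diverged parental haplomes
#'
#' Generates parent A chromosomes as i.i.d. uniform DNA, plants repeat
#' families (annotated), then derives parent B by applying SNVs and short
#' InDels at the requested densities.  The two haplomes, their colinear
#' alignment blocks, homolog pairing and variant map are returned as a
#' \code{\link{DualReference}}.  Defaults emulate the hybrid of two haploid
#' parents diverged at 6.5 SNVs/kb and 0.7 InDels/kb (~0.72\% overall).
#'
#' @param chrom_lengths named integer vector of chromosome lengths; the
#'   default is a 16-chromosome, 2 Mb haplome.
#' @param snv_per_kb,indel_per_kb divergence densities (per kb of parent A).
#' @param repeat_spec repeat families, see \code{\link{default_repeat_spec}};
#'   \code{NULL} for none.
#' @param telomere_width,centromere_width mask widths in bp.
#' @param seed RNG seed; recorded in the result's metadata.
#' @return A \code{\link{DualReference}} with attribute \code{"meta"}
#'   (seed and parameters).
#' @export
simulate_parental_pair <- function(chrom_lengths = setNames(rep(125000L, 16),
                                                            paste0("chr", 1:16)),
                                   snv_per_kb = 6.5, indel_per_kb = 0.7,
                                   repeat_spec = default_repeat_spec(),
                                   telomere_width = 3000,
                                   centromere_width = 1000,
                                   seed = 1L) {
  if (length(chrom_lengths) < 1) stop_input("need at least one chromosome")
  if (snv_per_kb < 0 || indel_per_kb < 0) stop_input("densities must be >= 0")
  if ((snv_per_kb + indel_per_kb) / 1000 > 0.05) {
    warning("divergence above 5%: homolog pairing may be ambiguous")
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  set.seed(seed)
  chroms <- names(chrom_lengths)
  A_chars <- lapply(chrom_lengths, function(L) sample(DNA_BASES, L, replace = TRUE))

  telomeres <- do.call(rbind, lapply(chroms, function(ch) {
    L <- chrom_lengths[[ch]]
    w <- min(telomere_width, floor(L / 4))
    data.frame(chrom = ch, start = c(1L, L - w + 1L), end = c(w, L))
  }))
  centromeres <- do.call(rbind, lapply(chroms, function(ch) {
    L <- chrom_lengths[[ch]]
    mid <- floor(L / 2)
    data.frame(chrom = ch, start = mid - floor(centromere_width / 2) + 1L,
               end = mid + ceiling(centromere_width / 2))
  }))

  ## ---- plant repeats into parent A by overwriting windows -----------------
  repeats <- NULL
  if (!is.null(repeat_spec)) {
    occupied <- rbind(telomeres, centromeres)
    place_window <- function(len) {
      for (try in 1:500) {
        ch <- sample(chroms, 1L, prob = chrom_lengths)
        L <- chrom_lengths[[ch]]
        lo <- telomere_width + 1000L
        hi <- L - telomere_width - 1000L - len
        if (hi <= lo) next
        s <- sample(lo:hi, 1L)
        if (!ivl_hits_df(occupied, ch, s - 500L, s + len + 500L)) {
          return(list(chrom = ch, start = s))
        }
      }
      stop_input("could not place repeat copy; genome too small")
    }
    rows <- list()
    for (fam in names(repeat_spec)) {
      fs <- repeat_spec[[fam]]
      if (fam == "rDNA") {
        unit <- sample(DNA_BASES, fs$unit_length, replace = TRUE)
        total <- fs$n_units * fs$unit_length
        w <- place_window(total)
        arr <- unlist(lapply(seq_len(fs$n_units), function(i) {
          mutate_chars(unit, fs$divergence)
        }))
        A_chars[[w$chrom]][w$start:(w$start + total - 1L)] <- arr
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = w$chrom, start = w$start, end = w$start + total - 1L,
          class = "rDNA", copy_id = paste0("rDNA_array"))
        occupied <- rbind(occupied, data.frame(chrom = w$chrom, start = w$start,
                                               end = w$start + total - 1L))
      } else {
        n_sub <- max(1L, fs$n %/% 2L)
        for (sf in seq_len(n_sub)) {
          consensus <- sample(DNA_BASES, fs$length, replace = TRUE)
          ## the two copies of a subfamily go to different chromosomes
          ch_used <- character()
          for (i in 1:2) {
            copy <- mutate_chars(consensus, fs$divergence)
            placed <- FALSE
            for (try in 1:500) {
              ch <- sample1(setdiff(chroms, ch_used))
              L <- chrom_lengths[[ch]]
              lo <- telomere_width + 1000L
              hi <- L - telomere_width - 1000L - fs$length
              if (hi <= lo) next
              s <- sample(lo:hi, 1L)
              if (!ivl_hits_df(occupied, ch, s - 500L, s + fs$length + 500L)) {
                A_chars[[ch]][s:(s + fs$length - 1L)] <- copy
                rows[[length(rows) + 1L]] <- data.frame(
                  chrom = ch, start = s, end = s + fs$length - 1L,
                  class = fam, copy_id = paste0(fam, "_s", sf, c("a", "b")[i]))
                occupied <- rbind(occupied,
                                  data.frame(chrom = ch, start = s,
                                             end = s + fs$length - 1L))
                ch_used <- c(ch_used, ch)
                placed <- TRUE
                break
              }
            }
            if (!placed) stop_input("could not place repeat copy; genome too small")
          }
        }
      }
    }
    repeats <- do.call(rbind, rows)
  }

  ## ---- derive parent B: SNVs + InDels, colinear blocks --------------------
  p_snv <- snv_per_kb / 1000
  p_ind <- indel_per_kb / 1000
  B_chars <- vector("list", length(chroms)); names(B_chars) <- chroms
  blocks <- vector("list", length(chroms)); names(blocks) <- chroms
  for (ch in chroms) {
    L <- chrom_lengths[[ch]]
    a <- A_chars[[ch]]
    b <- a
    snv_pos <- which(runif(L) < p_snv)
    if (length(snv_pos)) {
      b[snv_pos] <- vapply(b[snv_pos], function(x) {
        sample(setdiff(DNA_BASES, x), 1L)
      }, character(1), USE.NAMES = FALSE)
    }
    ind_pos <- which(runif(L) < p_ind)
    ind_pos <- ind_pos[ind_pos > 20 & ind_pos < L - 40]
    if (length(ind_pos) > 1) {                       # keep edits >= 25 bp apart
      keep <- c(TRUE, diff(ind_pos) >= 25)
      ind_pos <- ind_pos[keep]
    }
    n_ind <- length(ind_pos)
    if (n_ind == 0) {
      B_chars[[ch]] <- b
      blocks[[ch]] <- data.frame(a_start = 1L, b_start = 1L, len = L)
      next
    }
    lens <- sample(1:10, n_ind, replace = TRUE, prob = 0.55^(1:10))
    is_ins <- runif(n_ind) < 0.5
    pieces <- vector("list", 2L * n_ind + 1L)
    bl <- data.frame(a_start = integer(n_ind + 1L),
                     b_start = integer(n_ind + 1L),
                     len = integer(n_ind + 1L))
    a_cur <- 1L; b_cur <- 1L
    for (k in seq_len(n_ind)) {
      p <- ind_pos[k]                  # edit occurs after A position p
      seg_len <- p - a_cur + 1L
      pieces[[2L * k - 1L]] <- b[a_cur:p]
      bl$a_start[k] <- a_cur; bl$b_start[k] <- b_cur; bl$len[k] <- seg_len
      if (is_ins[k]) {                 # B gains lens[k] bases after p
        pieces[[2L * k]] <- sample(DNA_BASES, lens[k], replace = TRUE)
        a_cur <- p + 1L
        b_cur <- b_cur + seg_len + lens[k]
      } else {                         # B lacks A[p+1 .. p+lens[k]]
        a_cur <- p + lens[k] + 1L
        b_cur <- b_cur + seg_len
      }
    }
    pieces[[2L * n_ind + 1L]] <- b[a_cur:L]
    bl$a_start[n_ind + 1L] <- a_cur; bl$b_start[n_ind + 1L] <- b_cur
    bl$len[n_ind + 1L] <- L - a_cur + 1L
    B_chars[[ch]] <- unlist(pieces)
    blocks[[ch]] <- bl
  }

  to_dss <- function(chlist) {
    Biostrings::DNAStringSet(vapply(chlist, paste, character(1), collapse = ""))
  }
  lift_df <- function(df, bl_list, b_lens) {
    if (is.null(df)) return(NULL)
    out <- df
    for (i in seq_len(nrow(df))) {
      bl <- bl_list[[df$chrom[i]]]
      k1 <- max(1L, findInterval(df$start[i], bl$a_start))
      k2 <- max(1L, findInterval(df$end[i], bl$a_start))
      out$start[i] <- bl$b_start[k1] + min(df$start[i] - bl$a_start[k1],
                                           bl$len[k1] - 1L)
      out$end[i] <- bl$b_start[k2] + min(df$end[i] - bl$a_start[k2],
                                         bl$len[k2] - 1L)
      out$start[i] <- max(1L, out$start[i])
      out$end[i] <- min(b_lens[[df$chrom[i]]], out$end[i])
    }
    out
  }
  seqsB <- to_dss(B_chars)
  b_lens <- setNames(Biostrings::width(seqsB), chroms)
  telB <- lift_df(telomeres, blocks, b_lens)
  ## force telomere masks to touch B chromosome ends despite indel drift
  for (i in seq_len(nrow(telB))) {
    if (telomeres$start[i] == 1L) telB$start[i] <- 1L
    else telB$end[i] <- b_lens[[telB$chrom[i]]]
  }
  hapA <- Haplome("A", to_dss(A_chars), centromeres = centromeres,
                  telomeres = telomeres, repeats = repeats)
  hapB <- Haplome("B", seqsB, centromeres = lift_df(centromeres, blocks, b_lens),
                  telomeres = telB, repeats = lift_df(repeats, blocks, b_lens))
  pairing <- setNames(chroms, chroms)
  dref <- DualReference(hapA, hapB, pairing, blocks)
  attr(dref, "meta") <- list(seed = seed, snv_per_kb = snv_per_kb,
                             indel_per_kb = indel_per_kb,
                             chrom_lengths = chrom_lengths)
  dref
}
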