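#' Simulate a full restructuring experiment
#'
#' Convenience wrapper: plants events into a dual reference and simulates
#' all downstream observation channels (coverage tracks, array log-ratios,
#' junction evidence).
#'
#' @param dual_ref a \code{\link{DualReference}}.
#' @param spec an \code{\link{event_spec}}.
#' @param mean_depth per-copy sequencing depth.
#' @param noise coverage noise model (\code{"none"} or \code{"nb"}).
#' @param dispersion negative-binomial dispersion when \code{noise="nb"}.
#' @param seed RNG seed for planting; signal channels derive their own
#'   sub-seeds from it.
#' @return list \code{genome, truth, coverage, array, evidence}.
#' @export
simulate_taqing_experiment <- function(dual_ref, spec = event_spec(),
                                       mean_depth = 80,
                                       noise = c("none", "nb"),
                                       dispersion = 0.1, seed = 1L) {
  noise <- match.arg(noise)
  planted <- plant_events(dual_ref, spec, seed = seed)
  sub <- function(k) (seed * 7L + k) %% .Machine$integer.max
  coverage <- simulate_coverage(planted$genome, dual_ref,
                                mean_depth = mean_depth, noise = noise,
                                dispersion = dispersion, seed = sub(1L))
  array <- simulate_acgh(planted$genome, dual_ref, seed = sub(2L))
  evidence <- simulate_junction_evidence(planted$genome, planted$truth,
                                         dual_ref, mean_depth = mean_depth,
                                         seed = sub(3L))
  list(genome = planted$genome, truth = planted$truth, coverage = coverage,
       array = array, evidence = evidence)
}

#' Run the full rearrangement-detection pipeline
#'
#' Applies all detectors to one sample's observation channels:
#' chromosome-wide CNVs with sequencing/array dual support
#' (\code{\link{call_aneuploidy}}), sub-chromosomal CNV segments
#' (\code{\link{segment_local_cnv}}), inter-homolog BIR/SGC events
#' (\code{\link{call_homolog_events}}) and junction calls with mechanism
#' classification (\code{\link{call_breakpoints}}).
#'
#' @param dual_ref the \code{\link{DualReference}}.
#' @param coverage list \code{A}/\code{B} of raw coverage tracks.
#' @param array array-CGH track (or \code{NULL}).
#' @param evidence junction evidence (or \code{NULL} to skip junctions).
#' @param min_cnv_length minimum reported local-CNV length (bp).
#' @param params optional overrides passed to the individual callers.
#' @return list \code{aneuploidy, local_cnv, homolog_events, junctions}.
#' @export
detect_rearrangements <- function(dual_ref, coverage, array = NULL,
                                  evidence = NULL, min_cnv_length = 1e4,
                                  params = list()) {
  ratio <- list(A = normalize_coverage(coverage$A),
                B = normalize_coverage(coverage$B))
  aneu <- call_aneuploidy(ratio, array, dual_ref)
  comb <- combined_ratio_track(ratio, dual_ref)
  cnv <- segment_local_cnv(comb, min_length = min_cnv_length)
  cnv <- cnv[!cnv$whole_chrom, , drop = FALSE]
  homolog <- do.call(call_homolog_events,
                     c(list(cov_tracks = coverage, dual_ref = dual_ref),
                       params$homolog %||% list()))
  junctions <- if (!is.null(evidence)) {
    do.call(call_breakpoints,
            c(list(evidence = evidence, dual_ref = dual_ref,
                   cnv_calls = cnv),
              params$breakpoints %||% list()))
  } else empty_junction_calls()
  list(aneuploidy = aneu, local_cnv = cnv, homolog_events = homolog,
       junctions = junctions)
}

#' Compare detected calls with a planted truth set
#'
#' Scores one pipeline run against the simulator's truth: translocations
#' are recovered when at least one of their junctions is called at the
#' exact breakpoints (and mechanism-correct when its mechanism matches);
#' BIR/SGC events are recovered when a same-type call overlaps with both
#' boundaries within \code{boundary_tol} bp; aneuploidies must match
#' chromosome and direction with confirmed status.
#'
#' @param detected output of \code{\link{detect_rearrangements}}.
#' @param truth \code{TruthSet}.
#' @param boundary_tol boundary tolerance in bp for coverage-defined
#'   events (default: one 100-bp bin).
#' @return list of per-class recovery statistics.
#' @export
score_against_truth <- function(detected, truth, boundary_tol = 100) {
  ev <- truth$events
  jn <- truth$junctions
  calls <- detected$junctions
  ## translocations
  tl_ev <- ev[ev$type %in% c("TL_nonhomologous", "TL_homologous"), ,
              drop = FALSE]
  tl_found <- logical(nrow(tl_ev)); tl_mech <- logical(nrow(tl_ev))
  for (i in seq_len(nrow(tl_ev))) {
    jj <- jn[jn$event_id == tl_ev$event_id[i], , drop = FALSE]
    for (k in seq_len(nrow(jj))) {
      hit <- calls$hap_left == jj$hap_left[k] &
        calls$chrom_left == jj$chrom_left[k] &
        calls$pos_left == jj$pos_left[k] &
        calls$hap_right == jj$hap_right[k] &
        calls$chrom_right == jj$chrom_right[k] &
        calls$pos_right == jj$pos_right[k]
      if (any(hit)) {
        tl_found[i] <- TRUE
        if (any(calls$mechanism[hit] == jj$mechanism[k])) tl_mech[i] <- TRUE
      }
    }
  }
  ## BIR / SGC boundaries
  hs_ev <- ev[ev$type %in% c("BIR", "SGC"), , drop = FALSE]
  hcalls <- detected$homolog_events
  hs_found <- vapply(seq_len(nrow(hs_ev)), function(i) {
    base <- hcalls$type == hs_ev$type[i] &
      hcalls$acceptor_hap == hs_ev$hap_a[i] &
      hcalls$chrom == hs_ev$chrom_a[i]
    if (hs_ev$type[i] == "BIR") {
      ## only the internal breakpoint is measurable: the telomere-side
      ## boundary sits under the telomere mask by definition
      if (hs_ev$start[i] == 1) {
        any(base & abs(hcalls$end - hs_ev$end[i]) <= boundary_tol)
      } else {
        any(base & abs(hcalls$start - hs_ev$start[i]) <= boundary_tol)
      }
    } else {
      any(base & abs(hcalls$start - hs_ev$start[i]) <= boundary_tol &
            abs(hcalls$end - hs_ev$end[i]) <= boundary_tol)
    }
  }, logical(1))
  ## aneuploidy
  an_ev <- ev[ev$type %in% c("aneuploidy_gain", "aneuploidy_loss"), ,
              drop = FALSE]
  acalls <- detected$aneuploidy
  an_found <- vapply(seq_len(nrow(an_ev)), function(i) {
    dir <- if (an_ev$type[i] == "aneuploidy_gain") "gain" else "loss"
    any(acalls$chrom == an_ev$chrom_a[i] & acalls$direction == dir &
          acalls$status == "aneuploidy")
  }, logical(1))
  false_aneu <- acalls[acalls$status == "aneuploidy" &
                         !(acalls$chrom %in% an_ev$chrom_a), , drop = FALSE]
  list(
    tl = list(n = nrow(tl_ev), recovered = sum(tl_found),
              mechanism_correct = sum(tl_mech),
              recall = if (nrow(tl_ev)) mean(tl_found) else NA_real_,
              mechanism_accuracy = if (nrow(tl_ev)) mean(tl_mech) else NA_real_),
    homolog = list(n = nrow(hs_ev), recovered = sum(hs_found),
                   recall = if (nrow(hs_ev)) mean(hs_found) else NA_real_),
    aneuploidy = list(n = nrow(an_ev), recovered = sum(an_found),
                      false_calls = nrow(false_aneu))
  )
}
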