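## Shared fixtures, built once per test run and cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## small dual reference: fast enough for most unit tests
small_dref <- function() {
  cached("small_dref", function() {
    simulate_parental_pair(
      chrom_lengths = setNames(rep(60000L, 6), paste0("chr", 1:6)),
      repeat_spec = list(
        ty_like = list(n = 4, length = 3000, divergence = 0.005),
        rDNA = list(n_units = 2, unit_length = 1500, divergence = 0.002)),
      telomere_width = 2000, seed = 101)
  })
}

## full-size reference + noise-free experiment at the default event spectrum
std_dref <- function() {
  cached("std_dref", function() simulate_parental_pair(seed = 11))
}

std_experiment <- function() {
  cached("std_experiment", function() {
    simulate_taqing_experiment(std_dref(), event_spec(), noise = "none",
                               seed = 42)
  })
}

std_detection <- function() {
  cached("std_detection", function() {
    sim <- std_experiment()
    detect_rearrangements(std_dref(), sim$coverage, sim$array, sim$evidence)
  })
}

## hand-built haplome from explicit sequences
toy_haplome <- function(seqs, name = "A", telomere = NULL) {
  Haplome(name, Biostrings::DNAStringSet(seqs), telomeres = telomere)
}

## access the haplome of a haplotype label (mirrors the internal helper)
haplome_of_test <- function(dref, hap) if (hap == "A") dref$A else dref$B

## brute-force sliding-window motif scan (oracle for site scanning)
brute_force_sites <- function(seq, motif) {
  n <- nchar(seq); k <- nchar(motif)
  if (n < k) return(integer())
  which(vapply(seq_len(n - k + 1L), function(i) {
    substr(seq, i, i + k - 1L) == motif
  }, logical(1)))
}
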