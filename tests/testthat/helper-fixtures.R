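# small genome and simulation fixtures shared across tests

tiny_layout <- function() {
  genome_layout(chrom = c("c1", "c2", "c3"),
                length = c(400000L, 300000L, 250000L),
                centromere = c(200000L, 120000L, 90000L))
}

# a quick cohort: few isolates, zero noise unless stated
quick_sim <- function(seed = 1, isolates = 4, passages = 2, noise = FALSE,
                      ...) {
  cfg <- sim_config(seed = seed, isolates = isolates, passages = passages,
                    ...)
  if (!noise) cfg <- zero_noise(cfg)
  simulate_lineages(cfg)
}

# merge intervals (sorted sweep), independent of merge_track
merge_sweep <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- me <- numeric(0)
  for (i in seq_along(start)) {
    if (length(ms) && start[i] <= me[length(me)]) {
      me[length(me)] <- max(me[length(me)], end[i])
    } else {
      ms <- c(ms, start[i]); me <- c(me, end[i])
    }
  }
  cbind(start = ms, end = me)
}

random_dna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
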