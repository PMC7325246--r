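# Shared fixtures, built in code.

# Unit match/mismatch scheme with gap open = extend = 1 (toy DP cases).
unit_scheme <- function() scoring_scheme(c(1, -1), 1, 1)

# Small deterministic family with known duplicates.
toy_family <- function() {
  seq_family(
    id = paste0("r", 1:5),
    sequence = c("MKLAVGW", "MKLAVGW", "MKAAVGW", "MKLAVGW", "MKAAVGY"),
    provenance = "toy")
}

# Additive distance matrix from a random tree: path-length sums are the
# brute-force oracle for NJ exactness.
additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 3)
  list(tree = ape::unroot(tr), dm = ape::cophenetic.phylo(tr))
}

# Pure-decay time-course config: constant OD (od_r = 0) so normalization
# leaves the exponential intact.
decay_config <- function(noise_cv = 0, n_replicates = 1, seed = 1,
                         decay_rate = 0.2, f0 = 1000) {
  timecourse_sim_config(t_grid = 0:24, synthesis_rate = 0, f0 = f0,
                        decay_rate = decay_rate, od_k = 2, od_r = 0,
                        noise_cv = noise_cv, n_replicates = n_replicates,
                        seed = seed)
}
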