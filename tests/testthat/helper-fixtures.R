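# Shared in-code fixtures.

# A fragment as used throughout: covered site indices, 0/1 calls, errors.
frag <- function(snps, alleles, eps = 0.001, id = "f") {
  list(id = id, snps = as.integer(snps), alleles = as.integer(alleles),
       eps = rep(eps, length.out = length(snps)))
}

fm_of <- function(individual, n_snps, ...) {
  fragment_matrix(individual, list(...), n_snps)
}

# Tetraploid duplex/duplex pair used in several tests: columns are
# s1 = (0,0,1,1), s2 = (1,1,0,0) for both parents (the worked trio case).
trio_parents <- function() {
  H <- cbind(c(0L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L))
  list(H_m = H, H_f = H)
}

# Error-free fragments sampled from the rows of a phasing, covering sliding
# windows of `span` sites: enough to phase unambiguously at eps ~ 0.
truth_fragments <- function(individual, H, span = 3L, per_row = 4L,
                            eps = 0.001) {
  l <- ncol(H)
  frs <- list()
  for (r in seq_len(nrow(H))) {
    for (rep in seq_len(per_row)) {
      for (s in seq_len(max(1L, l - span + 1L))) {
        j <- s:min(l, s + span - 1L)
        frs[[length(frs) + 1L]] <- frag(j, H[r, j], eps)
      }
    }
  }
  fragment_matrix(individual, frs, l)
}

# Row-sorted canonical form for comparing phasings up to homolog labels.
canon_rows_test <- function(H) {
  storage.mode(H) <- "double"
  H[order(apply(H, 1, paste, collapse = "")), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small simulated family with spec-default depths, fixed seed.
quick_sim <- function(n_offspring = 4L, seed = 11L, ...) {
  sim_f1_population(n_offspring = n_offspring, seed = seed, ...)
}
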