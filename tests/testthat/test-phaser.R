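# The greedy Bayesian extension engine: read likelihoods, branching and
# pruning, posterior normalization, oracle equivalence, recovery.

test_that("pair read likelihood mixes uniformly over the relevant homologs", {
  H_m <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 1, 1))
  H_f <- rbind(c(0, 0, 1), c(0, 0, 1), c(1, 1, 0), c(1, 1, 0))
  # fragment identical to exactly one of 4 maternal rows -> 1/4 at eps -> 0
  f1 <- frag(1:3, c(0, 1, 0), eps = 1e-6)
  expect_equal(pair_read_likelihood(f1, "mother", H_m, H_f), 0.25,
               tolerance = 1e-4)
  # fragment matching 2 of 4 rows -> 1/2
  f2 <- frag(1:2, c(1, 1), eps = 1e-6)
  expect_equal(pair_read_likelihood(f2, "mother", H_m, H_f), 0.5,
               tolerance = 1e-4)
  # single-SNP offspring fragment: parents jointly duplex+duplex at site 1
  # (dosage 4 of 8) -> 4/8 mixture
  f3 <- frag(1, 1, eps = 1e-6)
  expect_equal(pair_read_likelihood(f3, "offspring", H_m, H_f), 0.5,
               tolerance = 1e-4)
  # explicit row-enumeration oracle for an offspring fragment
  f4 <- frag(c(1, 3), c(1, 0), eps = 0.05)
  rows <- rbind(H_m, H_f)
  oracle <- mean(apply(rows[, c(1, 3)], 1, function(h)
    prod(ifelse(h == c(1, 0), 0.95, 0.05))))
  expect_equal(pair_read_likelihood(f4, "offspring", H_m, H_f), oracle)
  # sites beyond `upto` are ignored; none scored -> 1
  expect_equal(pair_read_likelihood(frag(3, 1), "mother", H_m, H_f,
                                    upto = 2), 1)
})

test_that("row permutations never change read likelihoods", {
  set.seed(41)
  for (rep in 1:10) {
    H_m <- matrix(rbinom(12, 1, 0.5), 4, 3)
    H_f <- matrix(rbinom(12, 1, 0.5), 4, 3)
    f <- frag(sort(sample(3, 2)), rbinom(2, 1, 0.5), eps = runif(1, 0.001, 0.3))
    for (role in c("mother", "father", "offspring")) {
      base <- pair_read_likelihood(f, role, H_m, H_f)
      pm <- sample(4); pf <- sample(4)
      expect_equal(pair_read_likelihood(f, role, H_m[pm, ], H_f[pf, ]), base)
    }
  }
})

test_that("branching and pruning thresholds act as documented", {
  # {0.5, 0.47, 0.03}: 0.03 < rho = 0.2; 0.47 >= 0.94 * 0.5
  bp <- branch_prune(c(0.5, 0.47, 0.03), rho = 0.2, kappa = 0.94)
  expect_equal(sort(bp$keep), c(1L, 2L))
  expect_equal(bp$posterior, c(0.5, 0.47) / 0.97)
  # kappa = 1: only maxima survive
  bp1 <- branch_prune(c(0.4, 0.35, 0.25), rho = 0.01, kappa = 1)
  expect_equal(bp1$keep, 1L)
  # rho -> 0, kappa = 0: everything survives
  bp0 <- branch_prune(c(0.4, 0.35, 0.25), rho = 1e-9, kappa = 0)
  expect_length(bp0$keep, 3L)
  expect_equal(sum(bp0$posterior), 1)
  # argmax always retained even when it fails rho
  bp2 <- branch_prune(rep(0.1, 10), rho = 0.5, kappa = 0)
  expect_length(bp2$keep, 1L)
  # the cap keeps the highest posteriors
  bp3 <- branch_prune(c(0.3, 0.3, 0.2, 0.2), rho = 0.01, kappa = 0,
                      max_candidates = 2L)
  expect_length(bp3$keep, 2L)
  expect_equal(sum(bp3$posterior), 1)
})

test_that("candidate posteriors are normalized after every extension", {
  sim <- quick_sim(n_offspring = 3L, seed = 51L)
  res <- phase_parents(sim$fragments, sim$genotypes,
                       rho = 0.01, kappa = 0.5)
  for (blk in res) {
    if (is.null(blk$candidates)) next
    expect_equal(sum(vapply(blk$candidates, `[[`, numeric(1), "posterior")),
                 1, tolerance = 1e-9)
  }
})

test_that("noiseless deep coverage recovers the true parental phasing", {
  set.seed(61)
  for (rep in 1:5) {
    l <- 6L
    H_m <- matrix(rbinom(4 * l, 1, 0.5), 4, l)
    H_f <- matrix(rbinom(4 * l, 1, 0.5), 4, l)
    frs <- list(mother = truth_fragments("mother", H_m, span = l),
                father = truth_fragments("father", H_f, span = l))
    G <- rbind(mother = colSums(H_m), father = colSums(H_f))
    res <- phase_parents(frs, G, roles = c("mother", "father"))
    top <- res[[1L]]$candidates[[1L]]
    expect_equal(canon_rows_test(top$H_m), canon_rows_test(H_m))
    expect_equal(canon_rows_test(top$H_f), canon_rows_test(H_f))
  }
})

test_that("simplex/nulliplex blocks resolve to a single surviving candidate", {
  # every site simplex in the mother, nulliplex in the father: the father
  # is forced, and default pruning leaves one maternal placement
  l <- 4L
  G <- rbind(mother = rep(1L, l), father = rep(0L, l))
  frs <- list(mother = fm_of("mother", l, frag(1:2, c(1, 1))),
              father = fm_of("father", l, frag(2:3, c(0, 0)),
                             frag(3:4, c(0, 0))))
  res <- phase_parents(frs, G, roles = c("mother", "father"))
  blk <- res[[1L]]
  expect_length(blk$candidates, 1L)
  expect_equal(blk$candidates[[1L]]$posterior, 1)
  expect_equal(colSums(blk$candidates[[1L]]$H_m), rep(1, length(blk$sites)))
  expect_equal(sum(blk$candidates[[1L]]$H_f), 0)
})

# Exhaustive diploid oracle: enumerate every labelled placement sequence,
# weight by the full-fragment pair likelihood, group by canonical pair.
exhaustive_diploid <- function(frs, G, l) {
  per_site_m <- lapply(seq_len(l), function(s) placements(2, G["mother", s]))
  per_site_f <- lapply(seq_len(l), function(s) placements(2, G["father", s]))
  combos_m <- expand.grid(lapply(per_site_m, function(p) seq_len(ncol(p))))
  combos_f <- expand.grid(lapply(per_site_f, function(p) seq_len(ncol(p))))
  score <- new.env()
  for (i in seq_len(nrow(combos_m))) {
    H_m <- vapply(seq_len(l), function(s)
      per_site_m[[s]][, combos_m[i, s]], numeric(2))
    for (j in seq_len(nrow(combos_f))) {
      H_f <- vapply(seq_len(l), function(s)
        per_site_f[[s]][, combos_f[j, s]], numeric(2))
      lik <- 1
      for (ind in names(frs)) {
        role <- if (ind %in% c("mother", "father")) ind else "offspring"
        for (f in frs[[ind]]$fragments)
          lik <- lik * pair_read_likelihood(f, role, H_m, H_f)
      }
      key <- paste(paste(sort(apply(H_m, 1, paste, collapse = "")),
                         collapse = "|"),
                   paste(sort(apply(H_f, 1, paste, collapse = "")),
                         collapse = "|"), sep = "//")
      score[[key]] <- (score[[key]] %||% 0) + lik
    }
  }
  keys <- ls(score)
  w <- vapply(keys, function(k) score[[k]], numeric(1))
  data.frame(key = keys, posterior = w / sum(w), stringsAsFactors = FALSE)
}

test_that("greedy equals exhaustive enumeration for diploids when nothing is pruned", {
  set.seed(71)
  for (rep in 1:4) {
    l <- 4L
    H_m <- matrix(rbinom(2 * l, 1, 0.5), 2, l)
    H_f <- matrix(rbinom(2 * l, 1, 0.5), 2, l)
    tr <- list(maternal = sample(2, 1), paternal = sample(2, 1))
    H_c <- rbind(H_m[tr$maternal, ], H_f[tr$paternal, ])
    frs <- list(mother = truth_fragments("mother", H_m, span = 2, per_row = 2,
                                         eps = 0.05),
                father = truth_fragments("father", H_f, span = 2, per_row = 2,
                                         eps = 0.05),
                kid = truth_fragments("kid", H_c, span = 2, per_row = 1,
                                      eps = 0.05))
    G <- rbind(mother = colSums(H_m), father = colSums(H_f),
               kid = colSums(H_c))
    res <- phase_parents(frs, G, roles = c("mother", "father", "offspring"),
                         ploidy = rep(2L, 3), rho = 1e-300, kappa = 0,
                         max_candidates = 10000L)
    blk <- res[[1L]]
    expect_length(blk$sites, l)  # nothing excluded
    got <- data.frame(
      key = vapply(blk$candidates, function(cd)
        paste(paste(sort(apply(cd$H_m, 1, paste, collapse = "")),
                    collapse = "|"),
              paste(sort(apply(cd$H_f, 1, paste, collapse = "")),
                    collapse = "|"), sep = "//"), character(1)),
      posterior = vapply(blk$candidates, `[[`, numeric(1), "posterior"))
    oracle <- exhaustive_diploid(frs, G, l)
    m <- match(got$key, oracle$key)
    expect_false(anyNA(m))
    expect_equal(got$posterior, oracle$posterior[m], tolerance = 1e-8)
    # same ranking of the top candidate
    expect_equal(got$key[which.max(got$posterior)],
                 oracle$key[which.max(oracle$posterior)])
  }
})

test_that("canonicalizing candidate rows never changes posteriors", {
  sim <- quick_sim(n_offspring = 2L, seed = 81L)
  res <- phase_parents(sim$fragments, sim$genotypes)
  for (blk in res) {
    if (is.null(blk$candidates)) next
    for (cd in blk$candidates) {
      # recompute the total fragment likelihood with permuted rows
      for (ind in names(sim$fragments)) {
        role <- sim$roles[match(ind, sim$individuals)]
        loc <- match(blk$sites, seq_len(nrow(sim$sites)))
        ll1 <- ll2 <- 0
        pm <- sample(4); pf <- sample(4)
        for (f in sim$fragments[[ind]]$fragments) {
          keep <- f$snps %in% blk$sites
          if (!any(keep)) next
          f2 <- list(snps = match(f$snps[keep], blk$sites),
                     alleles = f$alleles[keep], eps = f$eps[keep])
          ll1 <- ll1 + log(pair_read_likelihood(f2, role, cd$H_m, cd$H_f))
          ll2 <- ll2 + log(pair_read_likelihood(f2, role, cd$H_m[pm, ],
                                                cd$H_f[pf, ]))
        }
        expect_equal(ll1, ll2)
      }
    }
    break  # one block suffices
  }
})

test_that("erroneous parental dosage calls are repaired during extension", {
  set.seed(91)
  l <- 5L
  H_m <- rbind(c(0, 1, 0, 1, 0), c(0, 1, 1, 0, 0),
               c(1, 0, 0, 1, 1), c(1, 0, 1, 0, 1))
  H_f <- rbind(c(0, 0, 0, 0, 1), c(0, 1, 1, 1, 0),
               c(1, 0, 0, 1, 0), c(1, 1, 1, 0, 0))
  frs <- list(mother = truth_fragments("mother", H_m),
              father = truth_fragments("father", H_f))
  for (i in 1:2) {
    tr <- list(maternal = sort(sample(4, 2)), paternal = sort(sample(4, 2)))
    H_c <- rbind(H_m[tr$maternal, ], H_f[tr$paternal, ])
    frs[[paste0("kid", i)]] <- truth_fragments(paste0("kid", i), H_c,
                                               per_row = 2)
  }
  G <- rbind(mother = colSums(H_m), father = colSums(H_f),
             kid1 = rep(NA_integer_, l), kid2 = rep(NA_integer_, l))
  # an uncalled maternal dosage (and all offspring uncalled) triggers the
  # joint re-estimation, which must restore the true value from the reads
  G["mother", 3L] <- NA
  res <- phase_parents(frs, G,
                       roles = c("mother", "father", "offspring", "offspring"))
  blk <- res[[1L]]
  expect_equal(unname(blk$genotypes["mother", 3L]), sum(H_m[, 3L]))
  expect_true(!is.null(blk$corrections) && nrow(blk$corrections) >= 1L)
  top <- blk$candidates[[1L]]
  expect_equal(canon_rows_test(top$H_m), canon_rows_test(H_m))
})

test_that("runtime grows about linearly in the number of SNPs and offspring", {
  time_phase <- function(n_off, region_length) {
    set.seed(101)
    sim <- sim_f1_population(n_offspring = n_off,
                             region_length = region_length)
    t0 <- proc.time()[["elapsed"]]
    phase_population(sim)
    proc.time()[["elapsed"]] - t0
  }
  t_small <- time_phase(4L, 1000L)
  t_long <- time_phase(4L, 4000L)   # ~4x the SNPs
  t_many <- time_phase(16L, 1000L)  # 4x the offspring
  # linear scaling with generous slack for timer noise and constant terms
  expect_lt(t_long, 16 * max(t_small, 0.05))
  expect_lt(t_many, 16 * max(t_small, 0.05))
})
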