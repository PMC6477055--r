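# Mendelian machinery for even-ploidy balanced meiosis without recombination:
# gamete and offspring dosage distributions, enumeration of parental-haplotype
# transmissions, and haplotype-tagging SNP (htSNP) selection.

check_even_ploidy <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 2 || k %% 2 != 0)
    stop("ploidy must be an even integer >= 2 (balanced meiosis)", call. = FALSE)
  as.integer(k)
}

#' Gamete dosage distribution under random polysomic segregation
#'
#' Probability mass function of the alternative-allele dosage carried by a
#' gamete of a `k`-ploid parent with dosage `g`, under balanced meiosis:
#' the gamete receives a uniformly random subset of `k/2` of the `k`
#' homologs, so the transmitted dosage is hypergeometric.  No double
#' reduction and no preferential pairing are modelled.
#'
#' @param k Parent ploidy (even integer, >= 2).
#' @param g Parent dosage of the alternative allele, in `0..k`.
#' @return Named numeric vector of probabilities over gamete dosages
#'   `0..k/2`, summing to 1.
#' @examples
#' gamete_dosage_pmf(4, 2)  # 1/6, 4/6, 1/6
#' @export
gamete_dosage_pmf <- function(k, g) {
  k <- check_even_ploidy(k)
  stopifnot(g >= 0, g <= k)
  t <- 0:(k / 2)
  setNames(dhyper(t, g, k - g, k / 2), t)
}

#' Offspring dosage distribution given parental dosages
#'
#' Convolution of the two parental gamete dosage distributions
#' ([gamete_dosage_pmf()]): the probability of each offspring dosage in an
#' F1 cross, conditional on the parental dosages, under balanced meiosis
#' without recombination.
#'
#' @param k_m,k_f Maternal and paternal ploidies (even).
#' @param g_m,g_f Maternal and paternal dosages.
#' @return Named numeric vector over offspring dosages `0..(k_m + k_f)/2`.
#' @examples
#' offspring_dosage_pmf(4, 2, 4, 2)["2"]  # 0.5
#' @export
offspring_dosage_pmf <- function(k_m, g_m, k_f, g_f) {
  pm <- gamete_dosage_pmf(k_m, g_m)
  pf <- gamete_dosage_pmf(k_f, g_f)
  ko <- (check_even_ploidy(k_m) + check_even_ploidy(k_f)) / 2
  out <- setNames(numeric(ko + 1L), 0:ko)
  for (a in seq_along(pm)) {
    for (b in seq_along(pf)) {
      d <- (a - 1L) + (b - 1L)
      out[d + 1L] <- out[d + 1L] + pm[a] * pf[b]
    }
  }
  out
}

# Index pairs (maternal subset, paternal subset) for all transmissions.
transmission_subsets <- function(k_m, k_f) {
  k_m <- check_even_ploidy(k_m)
  k_f <- check_even_ploidy(k_f)
  sm <- combn(k_m, k_m / 2)
  sf <- combn(k_f, k_f / 2)
  list(maternal = sm, paternal = sf,
       pairs = expand.grid(m = seq_len(ncol(sm)), f = seq_len(ncol(sf))))
}

#' Enumerate transmissions of parental haplotypes to an offspring
#'
#' Under balanced meiosis without recombination each parent transmits exactly
#' half of its homologs, so a `k_m`-ploid x `k_f`-ploid cross admits
#' `choose(k_m, k_m/2) * choose(k_f, k_f/2)` candidate offspring phasings
#' (36 for a tetraploid x tetraploid cross).  Transmissions whose induced
#' offspring phasings coincide (because a parent carries duplicated
#' haplotypes) are all retained in the list, with `class_id` marking the
#' distinct induced phasings for probability bookkeeping.
#'
#' @param H_m,H_f Parental phasings: `k x l` 0/1 matrices (rows = homologs).
#' @return List with one element per transmission:
#'   `maternal`/`paternal` (transmitted row indices), `phasing` (the induced
#'   `(k_m + k_f)/2 x l` offspring phasing), and `class_id` (integer label of
#'   the distinct induced phasing).
#' @examples
#' H <- rbind(c(0, 1), c(0, 1), c(1, 0), c(1, 0))
#' length(enumerate_transmissions(H, H))  # 36
#' @export
enumerate_transmissions <- function(H_m, H_f) {
  stopifnot(is.matrix(H_m), is.matrix(H_f), ncol(H_m) == ncol(H_f))
  ts <- transmission_subsets(nrow(H_m), nrow(H_f))
  out <- vector("list", nrow(ts$pairs))
  keys <- character(nrow(ts$pairs))
  for (i in seq_len(nrow(ts$pairs))) {
    mi <- ts$maternal[, ts$pairs$m[i]]
    fi <- ts$paternal[, ts$pairs$f[i]]
    ph <- rbind(H_m[mi, , drop = FALSE], H_f[fi, , drop = FALSE])
    keys[i] <- row_key(ph)
    out[[i]] <- list(maternal = mi, paternal = fi, phasing = ph)
  }
  cls <- match(keys, unique(keys))
  for (i in seq_along(out)) out[[i]]$class_id <- cls[i]
  out
}

# Dosage vectors induced by every transmission: a T x l integer matrix where
# T = choose(k_m, k_m/2) * choose(k_f, k_f/2).
transmission_dosages <- function(H_m, H_f) {
  ts <- transmission_subsets(nrow(H_m), nrow(H_f))
  gm <- t(apply(ts$maternal, 2L, function(r) colSums(H_m[r, , drop = FALSE])))
  gf <- t(apply(ts$paternal, 2L, function(r) colSums(H_f[r, , drop = FALSE])))
  if (ncol(H_m) == 1L) { gm <- t(gm); gf <- t(gf) }  # apply() drops dims
  gm[ts$pairs$m, , drop = FALSE] + gf[ts$pairs$f, , drop = FALSE]
}

#' Select haplotype-tagging SNPs
#'
#' Finds a small ordered subset of SNPs whose joint dosages discriminate all
#' distinct transmissions of the parental haplotypes, so that an offspring
#' genotyped only at these SNPs can be assigned its inherited haplotypes.
#' Selection is greedy set cover over the pairs of distinct transmission
#' classes still to be separated: each step adds the SNP separating the most
#' remaining pairs.  Transmission classes whose dosage vectors coincide over
#' *all* SNPs cannot be separated by dosage data and are reported as
#' unresolvable equivalence classes rather than raising an error.
#'
#' @param H_m,H_f Parental phasings (`k x l` 0/1 matrices).
#' @param redundancy Number of extra SNPs appended greedily (by residual
#'   separating power) after full separation, as insurance against failed
#'   genotyping.
#' @return List with `snps` (selected SNP column indices, in selection
#'   order), `resolved` (logical: all separable pairs separated),
#'   `unresolvable` (list of integer vectors of transmission class ids that
#'   are dosage-indistinguishable over all SNPs), and `class_dosages`
#'   (distinct-class x l dosage matrix).
#' @export
select_htsnps <- function(H_m, H_f, redundancy = 0L) {
  D <- transmission_dosages(H_m, H_f)
  trans <- enumerate_transmissions(H_m, H_f)
  cls <- vapply(trans, `[[`, integer(1), "class_id")
  Dc <- D[!duplicated(cls), , drop = FALSE]  # one dosage vector per class
  nc <- nrow(Dc)
  l <- ncol(Dc)
  if (nc == 1L) {
    return(list(snps = integer(0), resolved = TRUE, unresolvable = list(),
                class_dosages = Dc))
  }
  pairs <- combn(nc, 2L)
  # sep[p, s]: does SNP s separate class pair p?
  sep <- matrix(FALSE, ncol(pairs), l)
  for (s in seq_len(l)) sep[, s] <- Dc[pairs[1L, ], s] != Dc[pairs[2L, ], s]
  separable <- rowSums(sep) > 0L
  unresolved_pairs <- pairs[, !separable, drop = FALSE]
  need <- separable
  chosen <- integer(0)
  while (any(need)) {
    gain <- colSums(sep[need, , drop = FALSE])
    best <- which.max(gain)
    if (gain[best] == 0L) break
    chosen <- c(chosen, best)
    need <- need & !sep[, best]
  }
  if (redundancy > 0L) {
    for (i in seq_len(redundancy)) {
      rest <- setdiff(seq_len(l), chosen)
      if (!length(rest)) break
      gain <- colSums(sep[separable, rest, drop = FALSE])
      chosen <- c(chosen, rest[which.max(gain)])
    }
  }
  # Merge unresolvable pairs into equivalence classes.
  unres <- list()
  if (ncol(unresolved_pairs)) {
    g <- igraph::graph_from_edgelist(t(unresolved_pairs), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nc - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    for (cc in unique(comp)) {
      members <- which(comp == cc)
      if (length(members) > 1L) unres <- c(unres, list(members))
    }
  }
  list(snps = chosen, resolved = !length(unres), unresolvable = unres,
       class_dosages = Dc)
}
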