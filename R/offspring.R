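# Offspring phasing: each offspring's haplotypes are chosen from the
# Mendelian transmissions of the estimated parental haplotypes by the
# minimum error correction (MEC) criterion against its own reads; sites
# whose offspring genotypes admit no transmission are excluded from
# phasing; complete solution sets are ranked by parental posterior and the
# sum of offspring MEC scores.

#' MEC score of a phasing against a set of fragments
#'
#' The minimum error correction score: the number of allele calls that must
#' be flipped so that every fragment matches some haplotype perfectly, i.e.
#' the sum over fragments of the minimum Hamming mismatch count against any
#' row of the phasing.  Sites not covered by a fragment (or outside
#' `sites`) are ignored.
#'
#' @param phasing `k x m` 0/1 matrix over the phased sites.
#' @param fragments A [fragment_matrix()] (or plain list of fragments).
#' @param sites Global SNP indices of the phasing columns (defaults to
#'   columns `1..m`, matching fragment indices directly).
#' @return Non-negative integer.
#' @examples
#' H <- rbind(c(0, 0), c(1, 1))
#' f <- list(list(snps = 1:2, alleles = c(0L, 1L), eps = c(0.01, 0.01)))
#' mec_score(H, fragment_matrix("x", f, 2))  # 1
#' @export
mec_score <- function(phasing, fragments, sites = seq_len(ncol(phasing))) {
  frs <- if (inherits(fragments, "fragment_matrix")) fragments$fragments
         else fragments
  total <- 0L
  for (f in frs) {
    j <- match(f$snps, sites)
    ok <- !is.na(j)
    if (!any(ok)) next
    a <- f$alleles[ok]
    sub <- phasing[, j[ok], drop = FALSE]
    mism <- apply(sub, 1L, function(h) sum(h != a))
    total <- total + min(mism)
  }
  as.integer(total)
}

# MEC of all transmissions at once, plus dosage-match tie-break counts.
# dn: dense fragments over `sites`; G_c: the offspring's called dosages
# over `sites` (NA allowed).  Returns list(mec, match, trans).
mec_all_transmissions <- function(H_m, H_f, dn, G_c = NULL) {
  trans <- enumerate_transmissions(H_m, H_f)
  A <- dn$A
  cov <- !is.na(A)
  A1 <- cov & !is.na(A) & A == 1L
  A0 <- cov & !is.na(A) & A == 0L
  mode(A1) <- "numeric"; mode(A0) <- "numeric"
  mec <- integer(length(trans))
  match_n <- integer(length(trans))
  for (t in seq_along(trans)) {
    Ht <- trans[[t]]$phasing
    if (nrow(A)) {
      mism <- A1 %*% t(1 - Ht) + A0 %*% t(Ht)  # fragments x rows
      mec[t] <- as.integer(sum(apply(mism, 1L, min)))
    }
    if (!is.null(G_c)) {
      d <- colSums(Ht)
      match_n[t] <- sum(!is.na(G_c) & d == G_c)
    }
  }
  list(mec = mec, match = match_n, trans = trans)
}

#' Exclude sites whose offspring genotypes admit no transmission
#'
#' Walks the phased sites in order keeping, for every offspring, the set of
#' parental-haplotype transmissions compatible with its called dosages at
#' the sites accepted so far.  A site where some offspring's set would
#' become empty is evidence of a genotype that cannot arise from any
#' transmission of the parental haplotypes without recombination; since the
#' method assumes none, the site is excluded from phasing.  With
#' `scope = "population"` (default) the site is dropped for every
#' individual; with `scope = "offspring"` only the offending offspring is
#' left unphased there.
#'
#' @param H_m,H_f Parental phasings (`k x l` over the block's phased sites).
#' @param G_off Integer matrix offspring x l of called dosages (`NA` = no
#'   constraint).
#' @param scope `"population"` or `"offspring"`.
#' @return List with `include` (logical vector over the l columns: kept for
#'   the population) and `offspring_include` (offspring x l logical).
#' @export
offspring_site_exclusion <- function(H_m, H_f, G_off,
                                     scope = c("population", "offspring")) {
  scope <- match.arg(scope)
  l <- ncol(H_m)
  n_off <- nrow(G_off)
  D <- transmission_dosages(H_m, H_f)  # transmissions x l
  sets <- rep(list(seq_len(nrow(D))), n_off)
  include <- rep(TRUE, l)
  off_inc <- matrix(TRUE, n_off, l)
  for (s in seq_len(l)) {
    upd <- sets
    bad <- logical(n_off)
    for (c in seq_len(n_off)) {
      g <- G_off[c, s]
      if (is.na(g)) next
      keep <- sets[[c]][D[sets[[c]], s] == g]
      if (!length(keep)) bad[c] <- TRUE else upd[[c]] <- keep
    }
    if (any(bad)) {
      if (scope == "population") {
        include[s] <- FALSE
        off_inc[, s] <- FALSE
        next  # no constraint committed at an excluded site
      }
      off_inc[bad, s] <- FALSE
      sets[!bad] <- upd[!bad]
    } else {
      sets <- upd
    }
  }
  list(include = include, offspring_include = off_inc)
}

#' Select an offspring's phasing from the parental transmissions by MEC
#'
#' Evaluates all `choose(k_m, k_m/2) * choose(k_f, k_f/2)` candidate
#' offspring phasings induced by transmissions of the parental haplotypes
#' (36 in a tetraploid cross) and returns the one with the smallest MEC
#' score against the offspring's own fragments.  Ties are broken toward the
#' candidate whose induced dosages match more of the offspring's called
#' dosages, then by canonical transmission order.  When `called_dosages`
#' are supplied and `exclude = TRUE`, sites at which no transmission is
#' jointly compatible with the offspring's genotypes are first excluded
#' (see [offspring_site_exclusion()]); an offspring with no informative
#' reads still receives a phasing (imputation from the parents).
#'
#' @param H_m,H_f Parental phasings over the block's phased sites.
#' @param fragments The offspring's [fragment_matrix()].
#' @param sites Global SNP indices of the phasing columns.
#' @param called_dosages Optional integer vector (length `ncol(H_m)`) of
#'   the offspring's called dosages at those sites.
#' @param exclude Apply transmission-compatibility site exclusion?
#' @return List of class `mec_result`: `transmission` (maternal and
#'   paternal transmitted row indices), `phasing` (the selected offspring
#'   phasing over the included sites), `sites` (their global indices),
#'   `excluded` (global indices dropped), `mec` (the minimal score) and
#'   `mec_all` (scores of all transmissions).
#' @export
select_offspring_phasing <- function(H_m, H_f, fragments,
                                     sites = seq_len(ncol(H_m)),
                                     called_dosages = NULL, exclude = TRUE) {
  include <- rep(TRUE, ncol(H_m))
  if (exclude && !is.null(called_dosages)) {
    include <- offspring_site_exclusion(
      H_m, H_f, matrix(called_dosages, nrow = 1L))$include
  }
  Hm2 <- H_m[, include, drop = FALSE]
  Hf2 <- H_f[, include, drop = FALSE]
  sites2 <- sites[include]
  fm <- if (inherits(fragments, "fragment_matrix")) fragments
        else fragment_matrix("offspring", fragments, max(sites))
  dn <- frag_dense(fm, cols = sites2)
  res <- mec_all_transmissions(Hm2, Hf2, dn,
                               if (!is.null(called_dosages))
                                 called_dosages[include])
  best <- order(res$mec, -res$match, seq_along(res$mec))[1L]
  structure(list(
    transmission = list(maternal = res$trans[[best]]$maternal,
                        paternal = res$trans[[best]]$paternal),
    phasing = res$trans[[best]]$phasing,
    sites = sites2, excluded = sites[!include],
    mec = res$mec[best], mec_all = res$mec), class = "mec_result")
}

#' @export
print.mec_result <- function(x, ...) {
  cat("<mec_result> MEC", x$mec, "over", length(x$sites), "sites;",
      "maternal rows", paste(x$transmission$maternal, collapse = ","),
      "/ paternal rows", paste(x$transmission$paternal, collapse = ","),
      "\n")
  invisible(x)
}

#' Rank complete solution sets
#'
#' Orders candidate population solutions lexicographically: by decreasing
#' posterior probability of the parental phasing pair, then by increasing
#' sum of offspring MEC scores (the parental posterior already integrates
#' all reads; MEC disambiguates near-ties).
#'
#' @param posterior Numeric vector of parental-pair posteriors.
#' @param mec_sum Integer vector of summed offspring MEC scores.
#' @return Integer permutation ranking the solution sets (best first).
#' @export
rank_solution_sets <- function(posterior, mec_sum) {
  stopifnot(length(posterior) == length(mec_sum), length(posterior) >= 1L)
  order(-posterior, mec_sum)
}
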