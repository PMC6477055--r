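# Site-wise genotype likelihoods from reads and joint MAP population
# genotypes under Mendelian transmission: used to correct erroneous dosages
# and impute missing ones.

#' Likelihood of a dosage given one individual's reads at a site
#'
#' Each sequenced base at a bi-allelic site is modelled as drawn from a
#' uniformly random homolog of the individual and miscalled with its
#' base-calling error probability.  For dosage `g` in a `k`-ploid the
#' probability of observing an alternative-allele call with error `e` is
#' `(g/k) (1 - e) + (1 - g/k) e`, and symmetrically for a reference call;
#' the site likelihood is the product over calls.
#'
#' @param alleles Integer vector of allele calls (0 = reference,
#'   1 = alternative) at the site for one individual.
#' @param eps Per-call error probabilities, same length as `alleles`.
#' @param k Ploidy.
#' @param g Dosage, in `0..k`.
#' @param log Return the log likelihood?
#' @return The (log) likelihood; 1 (0) when there are no calls.
#' @examples
#' site_dosage_likelihood(1L, 1e-6, k = 4, g = 2)  # ~0.5
#' @export
site_dosage_likelihood <- function(alleles, eps, k, g, log = FALSE) {
  stopifnot(length(alleles) == length(eps), g >= 0, g <= k)
  eps <- clamp_eps(eps)
  p_alt <- (g / k) * (1 - eps) + (1 - g / k) * eps
  ll <- sum(log(ifelse(alleles == 1L, p_alt, 1 - p_alt)))
  if (log) ll else exp(ll)
}

site_dosage_loglik_all <- function(alleles, eps, k) {
  vapply(0:k, function(g) site_dosage_likelihood(alleles, eps, k, g, log = TRUE),
         numeric(1))
}

#' Posterior over the pair of parental dosages at a site
#'
#' Combines the two parents' read evidence at one site under a uniform prior
#' over the `(k_m + 1)(k_f + 1)` dosage pairs.  Offspring reads are not used
#' here; they enter through the joint population MAP
#' ([map_population_genotypes()]).
#'
#' @param alleles_m,eps_m,alleles_f,eps_f Allele calls and error
#'   probabilities for mother and father (possibly empty vectors).
#' @param k_m,k_f Parental ploidies.
#' @return Matrix `(k_m + 1) x (k_f + 1)` of posterior probabilities
#'   (rows = maternal dosage 0..k_m), summing to 1.  With no reads for
#'   either parent the uniform prior is returned.
#' @export
parental_genotype_posterior <- function(alleles_m, eps_m, alleles_f, eps_f,
                                        k_m = 4L, k_f = 4L) {
  llm <- site_dosage_loglik_all(alleles_m, eps_m, k_m)
  llf <- site_dosage_loglik_all(alleles_f, eps_f, k_f)
  lp <- outer(llm, llf, `+`)
  if (all(!is.finite(lp))) {
    warning("all-zero parental likelihoods; returning uniform posterior")
    lp[] <- 0
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  dimnames(p) <- list(0:k_m, 0:k_f)
  p
}

#' Joint MAP genotypes for an F1 population at one site
#'
#' Maximizes the joint posterior of all dosages at a bi-allelic site:
#' parental dosages get a uniform prior times their read likelihoods, and
#' offspring dosages are conditionally independent given the parents, each
#' weighted by the Mendelian transmission distribution
#' ([offspring_dosage_pmf()]) times its own read likelihood.  An offspring
#' with no reads receives the transmission-PMF maximizer.  This is the
#' dosage correction/imputation step: it is invoked at sites with missing
#' calls and at sites where phasing extension finds all candidates
#' impossible, and guarantees Mendelian consistency of the returned dosages.
#'
#' Ties are broken toward the originally called dosage, then toward the
#' smaller dosage.
#'
#' @param evidence List with one element per individual (mother, father,
#'   then offspring), each a list with `alleles` and `eps` vectors (possibly
#'   empty) for that individual's calls at the site.
#' @param k_m,k_f Parental ploidies (offspring ploidy is their mean).
#' @param called Optional integer vector of originally called dosages
#'   (NA allowed), same order as `evidence`; used only for tie-breaking.
#' @return Integer vector of MAP dosages (mother, father, offspring...).
#' @export
map_population_genotypes <- function(evidence, k_m = 4L, k_f = 4L,
                                     called = NULL) {
  n_ind <- length(evidence)
  stopifnot(n_ind >= 2L)
  if (is.null(called)) called <- rep(NA_integer_, n_ind)
  n_off <- n_ind - 2L
  k_c <- (check_even_ploidy(k_m) + check_even_ploidy(k_f)) / 2
  llm <- site_dosage_loglik_all(evidence[[1L]]$alleles, evidence[[1L]]$eps, k_m)
  llf <- site_dosage_loglik_all(evidence[[2L]]$alleles, evidence[[2L]]$eps, k_f)
  lloff <- lapply(seq_len(n_off), function(i) {
    ev <- evidence[[i + 2L]]
    site_dosage_loglik_all(ev$alleles, ev$eps, k_c)
  })

  best <- NULL
  for (g_m in 0:k_m) {
    for (g_f in 0:k_f) {
      ltr <- log(offspring_dosage_pmf(k_m, g_m, k_f, g_f))
      score <- llm[g_m + 1L] + llf[g_f + 1L]
      g_off <- integer(n_off)
      for (i in seq_len(n_off)) {
        v <- ltr + lloff[[i]]
        g_off[i] <- pick_argmax_dosage(v, called[i + 2L])
        score <- score + v[g_off[i] + 1L]
      }
      cand <- list(g_m = g_m, g_f = g_f, g_off = g_off, score = score)
      if (is.null(best) || cand$score > best$score + 1e-12 ||
          (abs(cand$score - best$score) <= 1e-12 &&
           prefer_pair(cand, best, called))) {
        best <- cand
      }
    }
  }
  as.integer(c(best$g_m, best$g_f, best$g_off))
}

# argmax over dosages 0..k with ties toward `called`, then smaller dosage.
pick_argmax_dosage <- function(logp, called) {
  m <- max(logp)
  tied <- which(logp >= m - 1e-12) - 1L
  if (!is.na(called) && called %in% tied) return(as.integer(called))
  as.integer(min(tied))
}

prefer_pair <- function(cand, best, called) {
  cm <- called[1L]; cf <- called[2L]
  match_c <- sum(c(!is.na(cm) && cand$g_m == cm, !is.na(cf) && cand$g_f == cf))
  match_b <- sum(c(!is.na(cm) && best$g_m == cm, !is.na(cf) && best$g_f == cf))
  if (match_c != match_b) return(match_c > match_b)
  if (cand$g_m != best$g_m) return(cand$g_m < best$g_m)
  cand$g_f < best$g_f
}
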