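# Greedy Bayesian SNP-by-SNP extension of parental phasing pairs over each
# haplotype block, with branching (hard posterior threshold rho) and pruning
# (soft threshold kappa * P_max).  All population reads inform the parental
# phasing: parental fragments are scored against their own parent's
# haplotypes, offspring fragments against the union of both parents'
# haplotypes (no recombination: every offspring read originates from some
# parental homolog).

#' Likelihood of one fragment given a pair of parental phasings
#'
#' A fragment from the mother is a uniform mixture over the maternal
#' homologs: `(1/k_m) * sum over rows of prod over covered sites of (1 - e)`
#' for a matching call and `e` for a mismatch; symmetrically for the father.
#' An offspring fragment is a uniform mixture over *all* `k_m + k_f`
#' parental homologs.  Sites beyond `upto` (and sites not in the phasing)
#' are ignored; a fragment covering no scored site contributes 1.
#'
#' @param fragment List with `snps` (column indices into the phasings),
#'   `alleles` (0/1) and `eps`.
#' @param role `"mother"`, `"father"` or `"offspring"`.
#' @param H_m,H_f Parental phasings (`k x l` 0/1 matrices over the same
#'   SNP columns).
#' @param upto Last column to include (default: all).
#' @return Probability of the fragment's calls.
#' @export
pair_read_likelihood <- function(fragment, role = c("mother", "father",
                                                    "offspring"),
                                 H_m, H_f, upto = ncol(H_m)) {
  role <- match.arg(role)
  H <- switch(role, mother = H_m, father = H_f, offspring = rbind(H_m, H_f))
  j <- fragment$snps[fragment$snps <= upto]
  if (!length(j)) return(1)
  a <- fragment$alleles[fragment$snps <= upto]
  e <- clamp_eps(fragment$eps[fragment$snps <= upto])
  per_row <- apply(H[, j, drop = FALSE], 1L, function(h)
    prod(ifelse(h == a, 1 - e, e)))
  mean(per_row)
}

#' Branch and prune a set of candidate posteriors
#'
#' Branching with hard thresholding discards candidates whose posterior is
#' below `rho`; pruning then discards those below `kappa * P_max`, where
#' `P_max` is the maximum posterior among the branched candidates.  The
#' argmax is always retained (the result is never empty), a safety cap
#' keeps at most `max_candidates` highest-posterior candidates, and the
#' survivors are renormalized.
#'
#' @param posterior Numeric vector of normalized candidate posteriors.
#' @param rho Hard branching threshold in `(0, 1]`.
#' @param kappa Soft pruning factor in `[0, 1]`.
#' @param max_candidates Safety cap on the number of survivors.
#' @return List with `keep` (indices into `posterior`, in decreasing
#'   posterior order) and `posterior` (renormalized survivor posteriors).
#' @examples
#' branch_prune(c(0.5, 0.47, 0.03))  # keeps the first two
#' @export
branch_prune <- function(posterior, rho = 0.2, kappa = 0.94,
                         max_candidates = 256L) {
  stopifnot(rho > 0, rho <= 1, kappa >= 0, kappa <= 1)
  o <- order(posterior, decreasing = TRUE)
  p_max <- posterior[o[1L]]
  keep <- o[posterior[o] >= rho & posterior[o] >= kappa * p_max - 1e-15]
  if (!length(keep)) keep <- o[1L]
  if (length(keep) > max_candidates) keep <- keep[seq_len(max_candidates)]
  list(keep = keep, posterior = posterior[keep] / sum(posterior[keep]))
}

# ---- internal extension machinery ------------------------------------------

# Dense per-individual read context for one block.
block_context <- function(fragments, roles, cols) {
  dense <- lapply(fragments, frag_dense, cols = cols)
  list(dense = dense, roles = roles, n = length(cols))
}

# Log-likelihood-ratio matrix over column extensions (cols_m x cols_f) for
# one base candidate.  `incl` = local columns already phased (in the order
# of the candidate's H columns), `s` = the local column being added.
extension_loglik <- function(cand, s, incl, cols_m, cols_f, ctx) {
  n_m <- ncol(cols_m); n_f <- ncol(cols_f)
  LR <- matrix(0, n_m, n_f)
  lr_m <- numeric(n_m); lr_f <- numeric(n_f)
  k_m <- nrow(cand$H_m); k_f <- nrow(cand$H_f)
  for (i in seq_along(ctx$dense)) {
    dn <- ctx$dense[[i]]
    if (!nrow(dn$A)) next
    role <- ctx$roles[i]
    cov_s <- !is.na(dn$A[, s])
    if (!any(cov_s)) next
    cov_prev <- if (length(incl))
      rowSums(!is.na(dn$A[, incl, drop = FALSE])) > 0L else
      rep(FALSE, nrow(dn$A))
    straddle <- which(cov_s & cov_prev)
    if (!length(straddle)) next
    H <- switch(role, mother = cand$H_m, father = cand$H_f,
                offspring = rbind(cand$H_m, cand$H_f))
    A <- dn$A[straddle, incl, drop = FALSE]
    E <- dn$E[straddle, incl, drop = FALSE]
    m_prev <- matrix(0, length(straddle), nrow(H))
    for (r in seq_len(nrow(H))) {
      M <- sweep(A, 2L, H[r, ], `==`)
      ll <- log(ifelse(M, 1 - E, E))
      m_prev[, r] <- exp(rowSums(ll, na.rm = TRUE))
    }
    scale <- pmax(apply(m_prev, 1L, max), .Machine$double.xmin)
    m_prev <- m_prev / scale  # cancels in the ratio; avoids underflow
    a_s <- dn$A[straddle, s]
    e_s <- dn$E[straddle, s]
    t0 <- ifelse(a_s == 0L, 1 - e_s, e_s)
    t1 <- 1 - t0
    part <- function(mp, cols) (mp * t0) %*% (1 - cols) + (mp * t1) %*% cols
    prev <- rowSums(m_prev)
    if (role == "mother") {
      P <- part(m_prev, cols_m)
      lr_m <- lr_m + colSums(log(P)) - sum(log(prev))
    } else if (role == "father") {
      P <- part(m_prev, cols_f)
      lr_f <- lr_f + colSums(log(P)) - sum(log(prev))
    } else {
      Pm <- part(m_prev[, seq_len(k_m), drop = FALSE], cols_m)
      Pf <- part(m_prev[, k_m + seq_len(k_f), drop = FALSE], cols_f)
      lp <- sum(log(prev))
      for (jm in seq_len(n_m))
        LR[jm, ] <- LR[jm, ] + colSums(log(Pm[, jm] + Pf)) - lp
    }
  }
  LR + matrix(lr_m, n_m, n_f) + matrix(lr_f, n_m, n_f, byrow = TRUE)
}

# Extend a candidate set by one site.  Returns NULL when every extension has
# zero probability (caller excludes the site).
extend_step <- function(cands, s, incl, g_m, g_f, ctx, cfg) {
  k_m <- nrow(cands[[1L]]$H_m); k_f <- nrow(cands[[1L]]$H_f)
  cols_m <- placements(k_m, g_m)
  cols_f <- placements(k_f, g_f)
  new <- list()
  logw <- numeric(0)
  keys <- character(0)
  for (cand in cands) {
    LR <- extension_loglik(cand, s, incl, cols_m, cols_f, ctx)
    for (jm in seq_len(ncol(cols_m))) {
      for (jf in seq_len(ncol(cols_f))) {
        w <- cand$log_post + LR[jm, jf]
        if (!is.finite(w)) next
        H_m2 <- cbind(cand$H_m, cols_m[, jm], deparse.level = 0L)
        H_f2 <- cbind(cand$H_f, cols_f[, jf], deparse.level = 0L)
        key <- paste(row_key(H_m2), row_key(H_f2), sep = "//")
        hit <- match(key, keys)
        if (is.na(hit)) {
          new[[length(new) + 1L]] <- list(H_m = H_m2, H_f = H_f2, log_post = w)
          keys <- c(keys, key)
          logw <- c(logw, w)
        } else {  # same phasing reached through another placement: pool mass
          logw[hit] <- logsumexp(c(logw[hit], w))
          new[[hit]]$log_post <- logw[hit]
        }
      }
    }
  }
  if (!length(new)) return(NULL)
  lz <- logsumexp(logw)
  post <- exp(logw - lz)
  o <- order(-post, keys)  # descending posterior, canonical key: reproducible
  post <- post[o]; new <- new[o]
  bp <- branch_prune(post, cfg$rho, cfg$kappa, cfg$max_candidates)
  out <- new[bp$keep]
  for (i in seq_along(out)) out[[i]]$log_post <- log(bp$posterior[i])
  attr(out, "eta") <- length(out)
  out
}

# Ensure the dosages at local column s are usable: re-estimate via the joint
# population MAP when a parental or offspring call is missing or an
# offspring call is Mendelian-impossible given the parents.
resolve_site_dosages <- function(G, s, ctx, k_m, k_f) {
  g <- G[, s]
  need <- any(is.na(g))
  if (!need && nrow(G) > 2L) {
    pmf <- offspring_dosage_pmf(k_m, g[1L], k_f, g[2L])
    need <- any(pmf[g[-(1:2)] + 1L] == 0)
  }
  if (!need) return(list(g = g, corrected = FALSE))
  evidence <- lapply(seq_len(nrow(G)), function(i) {
    dn <- ctx$dense[[i]]
    cov <- which(!is.na(dn$A[, s]))
    list(alleles = dn$A[cov, s], eps = dn$E[cov, s])
  })
  g_new <- map_population_genotypes(evidence, k_m, k_f, called = g)
  list(g = g_new, corrected = TRUE)
}

#' Estimate parental phasings over haplotype blocks
#'
#' The core engine: for each block with at least two SNPs, starts from the
#' canonical single-column phasing given by the dosages at the first site
#' (all placements of one column are equivalent up to homolog relabelling)
#' and repeatedly (i) fixes the dosages at the next site, re-estimating them
#' from the population reads when calls are missing or Mendelian-impossible
#' ([map_population_genotypes()]); (ii) enumerates all dosage-consistent
#' allele placements on the maternal and paternal homologs; (iii) scores
#' each extension by the likelihood of the fragments that link the new site
#' to the phased prefix (incrementally, fragments covering the new site
#' together with at least one earlier phased site); and (iv) normalizes the
#' posteriors over all extensions of all surviving candidates and applies
#' [branch_prune()].  A site whose extensions all carry zero probability
#' even after dosage re-estimation is excluded from phasing and skipped.
#'
#' @param fragments Named list of [fragment_matrix()] objects, mother and
#'   father first.
#' @param genotypes Integer matrix individuals x SNPs of called dosages
#'   (`NA` = missing), rows ordered as `fragments`.
#' @param blocks A [find_blocks()] partition (computed from `fragments` if
#'   `NULL`).
#' @param roles Character vector (`"mother"`, `"father"`, `"offspring"`...)
#'   aligned with `fragments`.
#' @param ploidy Named/plain integer vector of ploidies (even), aligned
#'   with `fragments`.
#' @param rho,kappa,max_candidates Branching/pruning controls
#'   (see [branch_prune()]); defaults `rho = 0.2`, `kappa = 0.94`.
#' @return List with one element per block: for multi-SNP blocks a list
#'   with `sites` (global SNP indices phased, in order), `excluded`
#'   (global indices dropped), `candidates` (surviving pairs, each
#'   `H_m`, `H_f`, `posterior`), `eta` (trajectory of surviving counts),
#'   `genotypes` (corrected dosage matrix for the block), and
#'   `corrections` (data frame individual/site/old/new); singleton blocks
#'   are returned with `candidates = NULL` (dosage-only, no phase
#'   information).
#' @export
phase_parents <- function(fragments, genotypes, blocks = NULL,
                          roles = c("mother", "father",
                                    rep("offspring",
                                        length(fragments) - 2L)),
                          ploidy = rep(4L, length(fragments)),
                          rho = 0.2, kappa = 0.94, max_candidates = 256L) {
  stopifnot(length(fragments) >= 2L, roles[1L] == "mother",
            roles[2L] == "father")
  n_snps <- ncol(genotypes)
  if (is.null(blocks)) blocks <- find_blocks(fragments, n_snps)
  k_m <- check_even_ploidy(ploidy[1L])
  k_f <- check_even_ploidy(ploidy[2L])
  cfg <- list(rho = rho, kappa = kappa, max_candidates = max_candidates)
  inds <- names(fragments) %||% as.character(seq_along(fragments))

  lapply(blocks, function(bsites) {
    Gb <- genotypes[, bsites, drop = FALSE]
    ctx <- block_context(fragments, roles, bsites)
    corrections <- list()
    record <- function(old, new, s) {
      ch <- which(is.na(old) != is.na(new) |
                    (!is.na(old) & !is.na(new) & old != new))
      for (i in ch)
        corrections[[length(corrections) + 1L]] <<- data.frame(
          individual = inds[i], site = bsites[s],
          old = old[i], new = new[i])
    }

    if (length(bsites) == 1L) {
      rs <- resolve_site_dosages(Gb, 1L, ctx, k_m, k_f)
      if (rs$corrected) { record(Gb[, 1L], rs$g, 1L); Gb[, 1L] <- rs$g }
      return(list(sites = integer(0), excluded = integer(0),
                  candidates = NULL, eta = integer(0), genotypes = Gb,
                  corrections = do.call(rbind, corrections),
                  singleton = bsites))
    }

    l <- length(bsites)
    rs <- resolve_site_dosages(Gb, 1L, ctx, k_m, k_f)
    if (rs$corrected) { record(Gb[, 1L], rs$g, 1L); Gb[, 1L] <- rs$g }
    base_m <- matrix(sort(c(rep(0L, k_m - Gb[1L, 1L]), rep(1L, Gb[1L, 1L]))),
                     ncol = 1L)
    base_f <- matrix(sort(c(rep(0L, k_f - Gb[2L, 1L]), rep(1L, Gb[2L, 1L]))),
                     ncol = 1L)
    cands <- list(list(H_m = base_m, H_f = base_f, log_post = 0))
    incl <- 1L
    excluded <- integer(0)
    eta <- integer(0)
    for (s in 2:l) {
      rs <- resolve_site_dosages(Gb, s, ctx, k_m, k_f)
      if (rs$corrected) { record(Gb[, s], rs$g, s); Gb[, s] <- rs$g }
      res <- extend_step(cands, s, incl, Gb[1L, s], Gb[2L, s], ctx, cfg)
      if (is.null(res)) {
        excluded <- c(excluded, s)
        next
      }
      cands <- res
      incl <- c(incl, s)
      eta <- c(eta, attr(res, "eta"))
    }
    list(sites = bsites[incl], excluded = bsites[excluded],
         candidates = lapply(cands, function(cd)
           list(H_m = cd$H_m, H_f = cd$H_f, posterior = exp(cd$log_post))),
         eta = eta, genotypes = Gb,
         corrections = do.call(rbind, corrections), singleton = NULL)
  })
}
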