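# Haplotype evaluation metrics: reconstruction rate (RR), pairwise phasing
# accuracy rate (PAR), SNP missing rate (SMR), incorrect dosage rate (IDR),
# and nucleotide diversity.  All metrics are invariant to homolog-row
# permutations of both truth and estimate; RR uses the exact optimal row
# assignment.

as_est_blocks <- function(estimate, sites = NULL) {
  if (is.matrix(estimate))
    return(list(list(sites = sites %||% seq_len(ncol(estimate)),
                     H = estimate)))
  estimate
}

#' Haplotype reconstruction rate (RR)
#'
#' Overall similarity between true and estimated haplotypes: per estimated
#' block, `1 - D / (k * l_block)` where `D` is the total Hamming distance
#' under the best one-to-one assignment of estimated to true homologs
#' (solved exactly by enumeration over the `k!` assignments).  Blocks are
#' aggregated SNP-weighted.
#'
#' @param truth `k x l` 0/1 matrix of true haplotypes (columns = all SNPs).
#' @param estimate Either a `k x m` matrix with `sites` giving its SNP
#'   columns, or a list of blocks (each `list(sites, H)`).
#' @param sites SNP indices of the estimate's columns when it is a matrix.
#' @return RR in `[0, 1]`, or `NA` if nothing is co-phased.
#' @export
reconstruction_rate <- function(truth, estimate, sites = NULL) {
  blocks <- as_est_blocks(estimate, sites)
  k <- nrow(truth)
  tot_mism <- 0; tot <- 0
  perms <- permutations(k)
  for (blk in blocks) {
    if (!length(blk$sites)) next
    Tr <- truth[, blk$sites, drop = FALSE]
    H <- blk$H
    stopifnot(nrow(H) == k, ncol(H) == length(blk$sites))
    cost <- matrix(0L, k, k)  # cost[i, j] = Hamming(Tr[i, ], H[j, ])
    for (i in seq_len(k)) for (j in seq_len(k))
      cost[i, j] <- sum(Tr[i, ] != H[j, ])
    d <- min(apply(perms, 1L, function(p) sum(cost[cbind(seq_len(k), p)])))
    tot_mism <- tot_mism + d
    tot <- tot + k * ncol(H)
  }
  if (tot == 0) return(NA_real_)
  1 - tot_mism / tot
}

#' Pairwise phasing accuracy rate (PAR)
#'
#' Proportion of correctly phased SNP pairs: over all pairs of SNPs
#' co-phased within one estimated block, a pair is correct when the
#' multiset of the k two-allele haplotypes it carries in the estimate
#' equals that of the truth.  Pairs across blocks are not counted (phase
#' between blocks is undefined).
#'
#' @inheritParams reconstruction_rate
#' @return PAR in `[0, 1]`, or `NA` when no block has two or more SNPs.
#' @export
pairwise_accuracy <- function(truth, estimate, sites = NULL) {
  blocks <- as_est_blocks(estimate, sites)
  good <- 0L; total <- 0L
  for (blk in blocks) {
    m <- length(blk$sites)
    if (m < 2L) next
    Tr <- truth[, blk$sites, drop = FALSE]
    H <- blk$H
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        key_t <- sort(paste0(Tr[, i], Tr[, j]))
        key_e <- sort(paste0(H[, i], H[, j]))
        good <- good + all(key_t == key_e)
        total <- total + 1L
      }
    }
  }
  if (total == 0L) return(NA_real_)
  good / total
}

#' SNP missing rate and incorrect dosage rate
#'
#' `SMR` is the fraction of true (segregating) SNPs absent from the
#' individual's estimated phasing; `IDR` is the fraction of phased SNPs
#' whose estimated column dosage differs from the true dosage.  A site
#' excluded from phasing therefore raises SMR but never IDR.
#'
#' @param truth_dosage Integer vector of true dosages at all `l` SNPs.
#' @param estimate Estimated phasing (matrix + `sites`, or list of
#'   blocks).
#' @param sites SNP indices when `estimate` is a matrix.
#' @return Named numeric vector `c(smr = , idr = )`; `idr` is `NA` when
#'   nothing is phased.
#' @export
missing_and_dosage_rates <- function(truth_dosage, estimate, sites = NULL) {
  blocks <- as_est_blocks(estimate, sites)
  l <- length(truth_dosage)
  phased <- integer(0)
  wrong <- 0L
  for (blk in blocks) {
    if (!length(blk$sites)) next
    phased <- c(phased, blk$sites)
    wrong <- wrong + sum(colSums(blk$H) != truth_dosage[blk$sites])
  }
  c(smr = (l - length(unique(phased))) / l,
    idr = if (length(phased)) wrong / length(phased) else NA_real_)
}

#' Nucleotide diversity of a set of haplotypes
#'
#' Expected per-site difference between two randomly chosen (distinct)
#' haplotypes: the mean pairwise Hamming distance divided by the number of
#' sites.
#'
#' @param haplotypes `k x L` matrix (`k >= 2`) of 0/1 alleles (or any
#'   comparable symbols).
#' @return Numeric in `[0, 1]`.
#' @export
nucleotide_diversity <- function(haplotypes) {
  k <- nrow(haplotypes)
  stopifnot(k >= 2L)
  L <- ncol(haplotypes)
  tot <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    tot <- tot + sum(haplotypes[i, ] != haplotypes[j, ])
  tot / (choose(k, 2L) * L)
}

#' Evaluate a fit against simulator truth
#'
#' Computes RR, PAR, SMR and IDR per individual, plus the region NGPS, by
#' comparing a [phase_population()] fit with the ground truth of the
#' [sim_f1_population()] object (or an equivalent truth list with
#' `phasings` and `dosage`).
#'
#' @param fit A `pop_phase` object.
#' @param truth An `f1_sim` object or its `truth` component.
#' @return Object of class `phase_eval`: data frame (individual, role, rr,
#'   par, smr, idr) with attributes `ngps` and `means` (population-level
#'   averages; `rr_parents`/`rr_offspring` split as reported in practice).
#' @export
evaluate_phasing <- function(fit, truth) {
  stopifnot(inherits(fit, "pop_phase"))
  if (inherits(truth, "f1_sim")) truth <- truth$truth
  inds <- fit$individuals
  rows <- lapply(seq_along(inds), function(i) {
    ind <- inds[i]
    tr_H <- truth$phasings[[ind]]
    est <- fit$phasings[[ind]]
    md <- missing_and_dosage_rates(truth$dosage[ind, ], est)
    data.frame(individual = ind, role = fit$roles[i],
               rr = reconstruction_rate(tr_H, est),
               par = pairwise_accuracy(tr_H, est),
               smr = unname(md["smr"]), idr = unname(md["idr"]))
  })
  out <- do.call(rbind, rows)
  means <- c(
    rr = mean(out$rr, na.rm = TRUE),
    par = mean(out$par, na.rm = TRUE),
    smr = mean(out$smr, na.rm = TRUE),
    idr = mean(out$idr, na.rm = TRUE),
    rr_parents = mean(out$rr[out$role != "offspring"], na.rm = TRUE),
    rr_offspring = mean(out$rr[out$role == "offspring"], na.rm = TRUE),
    par_parents = mean(out$par[out$role != "offspring"], na.rm = TRUE),
    par_offspring = mean(out$par[out$role == "offspring"], na.rm = TRUE),
    ngps = ngps(fit$partition, ncol(fit$genotypes)))
  structure(out, ngps = means[["ngps"]], means = means,
            class = c("phase_eval", "data.frame"))
}

#' @export
print.phase_eval <- function(x, ...) {
  cat("Haplotype evaluation (NGPS =", signif(attr(x, "ngps"), 3), "):\n")
  print.data.frame(x, digits = 3)
  m <- attr(x, "means")
  cat("population means: RR", signif(m["rr"], 3), "PAR", signif(m["par"], 3),
      "SMR", signif(m["smr"], 3), "IDR", signif(m["idr"], 3), "\n")
  invisible(x)
}
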