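# The main model-fitting entry point: estimate haplotypes for a whole F1
# population (two parents + n offspring) from fragments and called dosages.

#' Phase an F1 population
#'
#' Fits the family-based phasing model: SNPs are partitioned into haplotype
#' blocks from the pooled population fragments ([find_blocks()]); within
#' each block the parental phasing pair is estimated by greedy Bayesian
#' extension with branching and pruning ([phase_parents()]), correcting or
#' imputing dosages from Mendelian segregation where needed; each
#' offspring's phasing is then selected from the transmissions of the
#' parental haplotypes by the MEC criterion
#' ([select_offspring_phasing()]), after excluding sites whose offspring
#' genotypes admit no recombination-free transmission
#' ([offspring_site_exclusion()]).  Complete solution sets are ranked by
#' parental posterior and summed offspring MEC ([rank_solution_sets()]);
#' the rank-1 set is the reported fit.
#'
#' @param fragments Named list of [fragment_matrix()] objects, one per
#'   individual.  An `f1_sim` object may be passed instead, in which case
#'   `genotypes` defaults to its (true) genotype table.
#' @param genotypes Integer matrix individuals x SNPs of called dosages
#'   (`NA` = missing); rownames must match `names(fragments)`.
#' @param sites Optional site table (`chrom`, `pos`, `ref`, `alt`); used
#'   for output only.
#' @param mother,father Names (or indices) of the two parents; all other
#'   individuals are offspring.
#' @param ploidy Even ploidy (scalar, or named vector per individual).
#' @param rho Hard branching threshold, default 0.2.
#' @param kappa Soft pruning factor, default 0.94.
#' @param max_candidates Safety cap on surviving candidates per step.
#' @param exclude_scope `"population"`: a transmission-incompatible site is
#'   dropped for everyone; `"offspring"`: only for the offending offspring.
#' @param top_sets How many ranked solution sets to retain (>= 1).
#' @return An object of class `pop_phase`; see [summary.pop_phase()].  Key
#'   components: `phasings` (per individual: list of blocks with `sites`
#'   and `H`), `genotypes` (final dosage table: corrections applied,
#'   offspring dosages at phased sites induced by their transmissions),
#'   `partition`, `blocks` (per-block detail incl. ranked solution sets),
#'   `corrections`, `excluded` (global SNP indices left unphased), and
#'   `config`.
#' @examples
#' sim <- sim_f1_population(n_offspring = 4, seed = 7)
#' fit <- phase_population(sim)
#' fit
#' @export
phase_population <- function(fragments, genotypes = NULL, sites = NULL,
                             mother = 1L, father = 2L, ploidy = 4L,
                             rho = 0.2, kappa = 0.94, max_candidates = 256L,
                             exclude_scope = c("population", "offspring"),
                             top_sets = 1L) {
  exclude_scope <- match.arg(exclude_scope)
  if (inherits(fragments, "f1_sim")) {
    sim <- fragments
    fragments <- sim$fragments
    genotypes <- genotypes %||% sim$genotypes
    sites <- sites %||% sim$sites
    ploidy <- sim$ploidy
  }
  inds <- names(fragments)
  if (is.null(inds)) stop("fragments must be a named list")
  stopifnot(!is.null(genotypes), all(rownames(genotypes) %in% inds) || is.null(rownames(genotypes)))
  if (is.null(rownames(genotypes))) rownames(genotypes) <- inds
  mother <- if (is.numeric(mother)) inds[mother] else mother
  father <- if (is.numeric(father)) inds[father] else father
  offspring <- setdiff(inds, c(mother, father))
  ord <- c(mother, father, offspring)
  fragments <- fragments[ord]
  genotypes <- genotypes[ord, , drop = FALSE]
  if (length(ploidy) == 1L) ploidy <- setNames(rep(ploidy, length(ord)), ord)
  ploidy <- ploidy[ord]
  roles <- c("mother", "father", rep("offspring", length(offspring)))
  n_snps <- ncol(genotypes)
  n_off <- length(offspring)

  partition <- find_blocks(fragments, n_snps)
  parent_fit <- phase_parents(fragments, genotypes, partition, roles, ploidy,
                              rho = rho, kappa = kappa,
                              max_candidates = max_candidates)

  geno_final <- genotypes
  phasings <- setNames(rep(list(list()), length(ord)), ord)
  blocks_out <- vector("list", length(partition))
  corrections <- list()
  excluded_all <- integer(0)

  for (b in seq_along(partition)) {
    pf <- parent_fit[[b]]
    if (!is.null(pf$corrections)) corrections[[b]] <- pf$corrections
    geno_final[, partition[[b]]] <- pf$genotypes
    if (is.null(pf$candidates)) {  # singleton: dosage only, no phase
      blocks_out[[b]] <- list(sites = integer(0), excluded = integer(0),
                              singleton = pf$singleton, sets = NULL)
      next
    }
    bsites <- pf$sites
    loc <- match(bsites, partition[[b]])
    G_off <- pf$genotypes[-(1:2), loc, drop = FALSE]

    sets <- lapply(pf$candidates, function(cd) {
      excl <- offspring_site_exclusion(cd$H_m, cd$H_f, G_off, exclude_scope)
      inc <- excl$include
      off_sel <- lapply(seq_len(n_off), function(c) {
        keep <- excl$offspring_include[c, ] & inc
        sel <- select_offspring_phasing(
          cd$H_m[, keep, drop = FALSE], cd$H_f[, keep, drop = FALSE],
          fragments[[c + 2L]], sites = bsites[keep], exclude = FALSE)
        sel
      })
      list(H_m = cd$H_m, H_f = cd$H_f, posterior = cd$posterior,
           include = inc, offspring = off_sel,
           mec_sum = sum(vapply(off_sel, `[[`, integer(1), "mec")))
    })
    rk <- rank_solution_sets(vapply(sets, `[[`, numeric(1), "posterior"),
                             vapply(sets, `[[`, numeric(1), "mec_sum"))
    sets <- sets[rk]
    best <- sets[[1L]]
    keep_sites <- bsites[best$include]
    phasings[[mother]] <- c(phasings[[mother]], list(list(
      sites = keep_sites, H = best$H_m[, best$include, drop = FALSE])))
    phasings[[father]] <- c(phasings[[father]], list(list(
      sites = keep_sites, H = best$H_f[, best$include, drop = FALSE])))
    for (c in seq_len(n_off)) {
      sel <- best$offspring[[c]]
      if (!length(sel$sites)) next
      phasings[[offspring[c]]] <- c(phasings[[offspring[c]]], list(list(
        sites = sel$sites, H = sel$phasing)))
      # Offspring dosages at phased sites are induced by the transmission.
      geno_final[offspring[c], sel$sites] <- colSums(sel$phasing)
    }
    blocks_out[[b]] <- list(
      sites = keep_sites,
      excluded = sort(c(pf$excluded, bsites[!best$include])),
      eta = pf$eta, singleton = NULL,
      sets = sets[seq_len(min(top_sets, length(sets)))],
      posterior = best$posterior, mec_sum = best$mec_sum)
    excluded_all <- c(excluded_all, blocks_out[[b]]$excluded)
  }

  structure(list(
    individuals = ord, roles = roles, ploidy = ploidy, sites = sites,
    partition = partition, blocks = blocks_out, phasings = phasings,
    genotypes = geno_final, input_genotypes = genotypes,
    corrections = if (length(corrections)) do.call(rbind, corrections),
    excluded = sort(unique(c(excluded_all,
                             unlist(lapply(blocks_out, `[[`, "singleton"))))),
    config = list(rho = rho, kappa = kappa, max_candidates = max_candidates,
                  exclude_scope = exclude_scope)),
    class = "pop_phase")
}

#' @export
print.pop_phase <- function(x, ...) {
  l <- ncol(x$genotypes)
  n_phased <- length(unique(unlist(lapply(x$phasings[[1L]], `[[`, "sites"))))
  cat("<pop_phase> ", length(x$individuals), " individuals (",
      sum(x$roles == "offspring"), " offspring), ", l, " SNPs in ",
      length(x$partition), " block(s)\n", sep = "")
  cat("  phased ", n_phased, "/", l, " SNPs; NGPS = ",
      signif(ngps(x$partition, l), 3), "; rho = ", x$config$rho,
      ", kappa = ", x$config$kappa, "\n", sep = "")
  invisible(x)
}

#' Summarize a population phasing fit
#'
#' @param object A `pop_phase` fit.
#' @param ... Unused.
#' @return Data frame with one row per block: number of SNPs, phased and
#'   excluded counts, final number of surviving candidate pairs, top
#'   posterior, and summed offspring MEC.
#' @export
summary.pop_phase <- function(object, ...) {
  rows <- lapply(seq_along(object$partition), function(b) {
    blk <- object$blocks[[b]]
    data.frame(
      block = b, n_snps = length(object$partition[[b]]),
      phased = length(blk$sites), excluded = length(blk$excluded),
      eta = if (length(blk$eta)) blk$eta[length(blk$eta)] else NA_integer_,
      posterior = blk$posterior %||% NA_real_,
      mec_sum = blk$mec_sum %||% NA_integer_)
  })
  out <- do.call(rbind, rows)
  n_corr <- if (is.null(object$corrections)) 0L else nrow(object$corrections)
  attr(out, "n_corrections") <- n_corr
  class(out) <- c("summary.pop_phase", class(out))
  out
}

#' @export
print.summary.pop_phase <- function(x, ...) {
  cat("Per-block phasing summary (", attr(x, "n_corrections"),
      " dosage corrections):\n", sep = "")
  print.data.frame(x)
  invisible(x)
}

#' Plot the rank-1 parental haplotypes of a fit
#'
#' Draws the maternal and paternal haplotype mosaics (one row per homolog,
#' one column per phased SNP; dark = alternative allele), with block
#' boundaries marked.
#'
#' @param x A `pop_phase` fit.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.pop_phase <- function(x, ...) {
  mother <- x$individuals[1L]; father <- x$individuals[2L]
  Hs <- lapply(c(mother, father), function(ind) {
    blks <- x$phasings[[ind]]
    if (!length(blks)) return(NULL)
    do.call(cbind, lapply(blks, `[[`, "H"))
  })
  if (is.null(Hs[[1L]])) {
    warning("nothing phased; no plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(2L, 1L), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- grDevices::grey(c(0.92, 0.15))
  for (i in 1:2) {
    H <- Hs[[i]]
    graphics::image(seq_len(ncol(H)), seq_len(nrow(H)), t(H)[, nrow(H):1],
                    col = cols, axes = FALSE, xlab = "phased SNP",
                    ylab = "homolog",
                    main = c(mother, father)[i], ...)
    graphics::axis(1); graphics::axis(2, at = seq_len(nrow(H)),
                                      labels = nrow(H):1)
    graphics::box()
  }
  invisible(x)
}
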