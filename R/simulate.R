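# Synthetic F1-population generator: random reference region, lognormally
# spaced bi-allelic SNPs, parental dosage sampling conditioned on
# segregation, balanced meiosis without recombination, and paired-end
# fragments with a uniform per-base error rate.  This is the fixture source
# for all tests and the benchmark.

# Lognormal parameters by moment matching: mean m, standard deviation s on
# the natural scale.
lognormal_pars <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Simulate a tetraploid (or other even-ploid) F1 population
#'
#' Generates one genomic region for a two-parent F1 cross and all data the
#' phasing pipeline consumes: reference sequence, bi-allelic SNP sites with
#' lognormal inter-SNP spacing, parental haplotypes with dosages drawn from
#' a configurable distribution (conditioned on segregation: never both
#' parents homozygous for the same allele), offspring produced by uniform
#' random transmission of half the homologs from each parent (no
#' recombination), and paired-end sequencing fragments with a uniform
#' per-base error rate.
#'
#' Depths are per *homolog*: an individual's expected total coverage is
#' `ploidy * depth`.  The number of templates per individual is
#' `round(depth * ploidy * region_length / (2 * read_length))`; each
#' template picks a uniform homolog and start, a Gaussian insert length
#' (truncated at `2 * read_length`), and covers the SNPs falling in its two
#' read segments, flipping each covered allele with probability
#' `base_error`.
#'
#' All randomness comes from R's global RNG stream: call `set.seed()` or
#' pass `seed` for reproducibility.  Draw order is fixed (reference, SNP
#' gaps, alt alleles, dosages, allele placements, transmissions, then
#' fragments per individual in pedigree order).
#'
#' @param n_offspring Number of F1 offspring.
#' @param ploidy Even ploidy of both parents (default tetraploid).
#' @param region_length Region length in bp.
#' @param snp_gap_mean,snp_gap_sd Mean/SD (bp) of the lognormal inter-SNP
#'   distance (defaults: one SNP per 50 bp, SD 90 bp).
#' @param dosage_probs Probability of parental dosage 0..ploidy for the
#'   alternative allele (default favors low dosages:
#'   0.4, 0.3, 0.15, 0.1, 0.05 for a tetraploid).
#' @param read_length,insert_mean,insert_sd Paired-end read geometry (bp).
#' @param depth_mother,depth_father,depth_offspring Per-homolog depths.
#' @param base_error Per-base miscall probability (reported quality is
#'   `-10 log10(base_error)`).
#' @param seed Optional integer seed (`set.seed(seed)` is called first).
#' @param min_snps Minimum number of SNPs; regions drawing fewer are
#'   resampled (up to 100 attempts).
#' @param chrom Chromosome name used on the sites.
#' @return Object of class `f1_sim`: list with `sites` (data frame `chrom`,
#'   `pos`, `ref`, `alt`), `ref_seq` (character), `truth` (list `H_m`,
#'   `H_f`, `transmissions`, `phasings`, `dosage` matrix individuals x SNPs),
#'   `genotypes` (the true dosage matrix, what the simulator's VCF reports),
#'   `fragments` (named list of [fragment_matrix()]), `individuals`,
#'   `roles`, `ploidy`, and `config`.
#' @examples
#' sim <- sim_f1_population(n_offspring = 2, seed = 1)
#' sim
#' @export
sim_f1_population <- function(n_offspring, ploidy = 4L, region_length = 1000L,
                              snp_gap_mean = 50, snp_gap_sd = 90,
                              dosage_probs = c(0.4, 0.3, 0.15, 0.1, 0.05),
                              read_length = 125L, insert_mean = 350,
                              insert_sd = 35, depth_mother = 5,
                              depth_father = 5, depth_offspring = 2,
                              base_error = 0.001, seed = NULL,
                              min_snps = 2L, chrom = "region1") {
  k <- check_even_ploidy(ploidy)
  stopifnot(n_offspring >= 0, region_length > 0, length(dosage_probs) == k + 1,
            all(dosage_probs >= 0), read_length > 0, insert_mean > 0,
            base_error > 0, base_error < 0.5)
  if (!is.null(seed)) set.seed(seed)
  dosage_probs <- dosage_probs / sum(dosage_probs)
  bases <- c("A", "C", "G", "T")

  for (attempt in 1:100) {
    ref_seq <- paste(sample(bases, region_length, replace = TRUE),
                     collapse = "")
    pars <- lognormal_pars(snp_gap_mean, snp_gap_sd)
    pos <- integer(0)
    cur <- 0
    repeat {
      gap <- max(1, round(rlnorm(1, pars$meanlog, pars$sdlog)))
      cur <- cur + gap
      if (cur > region_length) break
      pos <- c(pos, cur)
    }
    if (length(pos) >= min_snps) break
    if (attempt == 100) stop("region too short to host ", min_snps, " SNPs")
  }
  l <- length(pos)
  ref_al <- substring(ref_seq, pos, pos)
  alt_al <- vapply(ref_al, function(b) sample(setdiff(bases, b), 1L),
                   character(1), USE.NAMES = FALSE)
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref_al, alt = alt_al,
                      stringsAsFactors = FALSE)

  # Parental dosages, conditioned on segregation.
  g_m <- integer(l); g_f <- integer(l)
  for (s in seq_len(l)) {
    repeat {
      gm <- sample.int(k + 1L, 1L, prob = dosage_probs) - 1L
      gf <- sample.int(k + 1L, 1L, prob = dosage_probs) - 1L
      if (!((gm == 0L && gf == 0L) || (gm == k && gf == k))) break
    }
    g_m[s] <- gm; g_f[s] <- gf
  }
  place <- function(g) {
    col <- integer(k)
    if (g > 0L) col[sample.int(k, g)] <- 1L
    col
  }
  H_m <- vapply(g_m, place, integer(k))
  H_f <- vapply(g_f, place, integer(k))
  if (l == 1L) { H_m <- matrix(H_m, ncol = 1L); H_f <- matrix(H_f, ncol = 1L) }

  offspring_ids <- if (n_offspring > 0)
    sprintf("offspring%02d", seq_len(n_offspring)) else character(0)
  individuals <- c("mother", "father", offspring_ids)
  roles <- c("mother", "father", rep("offspring", n_offspring))

  transmissions <- lapply(seq_len(n_offspring), function(i)
    list(maternal = sort(sample.int(k, k / 2)),
         paternal = sort(sample.int(k, k / 2))))
  phasings <- c(list(mother = H_m, father = H_f),
                setNames(lapply(transmissions, function(tr)
                  rbind(H_m[tr$maternal, , drop = FALSE],
                        H_f[tr$paternal, , drop = FALSE])), offspring_ids))

  dosage <- do.call(rbind, lapply(phasings, colSums))
  rownames(dosage) <- individuals
  storage.mode(dosage) <- "integer"

  depths <- c(depth_mother, depth_father, rep(depth_offspring, n_offspring))
  fragments <- setNames(vector("list", length(individuals)), individuals)
  for (i in seq_along(individuals)) {
    fragments[[i]] <- sim_fragments_one(
      phasings[[i]], pos, region_length, depths[i], read_length,
      insert_mean, insert_sd, base_error, individuals[i])
  }

  structure(list(
    sites = sites, ref_seq = ref_seq,
    truth = list(H_m = H_m, H_f = H_f, transmissions = transmissions,
                 phasings = phasings, dosage = dosage),
    genotypes = dosage, fragments = fragments,
    individuals = individuals, roles = roles,
    ploidy = setNames(rep(k, length(individuals)), individuals),
    config = list(n_offspring = n_offspring, ploidy = k,
                  region_length = region_length, snp_gap_mean = snp_gap_mean,
                  snp_gap_sd = snp_gap_sd, dosage_probs = dosage_probs,
                  read_length = read_length, insert_mean = insert_mean,
                  insert_sd = insert_sd, depth_mother = depth_mother,
                  depth_father = depth_father,
                  depth_offspring = depth_offspring,
                  base_error = base_error, seed = seed)),
    class = "f1_sim")
}

# Paired-end fragments for one individual.  Vectorized draws in a fixed
# order: homolog rows, insert sizes, starts, then per-template allele flips.
sim_fragments_one <- function(H, pos, region_length, depth_per_homolog,
                              read_length, insert_mean, insert_sd,
                              base_error, individual) {
  k <- nrow(H)
  n_templates <- round(depth_per_homolog * k * region_length /
                         (2 * read_length))
  if (n_templates < 1L)
    return(fragment_matrix(individual, list(), length(pos)))
  rows <- sample.int(k, n_templates, replace = TRUE)
  ins <- pmax(2L * read_length, as.integer(round(rnorm(n_templates,
                                                       insert_mean,
                                                       insert_sd))))
  starts <- vapply(ins, function(I)
    sample.int(max(1L, region_length - I + 1L), 1L), integer(1))
  frags <- vector("list", n_templates)
  for (t in seq_len(n_templates)) {
    x <- starts[t]; I <- ins[t]
    covered <- which((pos >= x & pos <= x + read_length - 1L) |
                       (pos >= x + I - read_length & pos <= x + I - 1L))
    if (!length(covered)) next
    alleles <- H[rows[t], covered]
    flip <- rbinom(length(covered), 1L, base_error) == 1L
    alleles[flip] <- 1L - alleles[flip]
    frags[[t]] <- list(id = sprintf("%s_t%04d", individual, t),
                       snps = covered, alleles = alleles,
                       eps = rep(base_error, length(covered)))
  }
  fragment_matrix(individual, Filter(Negate(is.null), frags), length(pos))
}

#' @export
print.f1_sim <- function(x, ...) {
  cat("<f1_sim>", x$config$n_offspring, "offspring,",
      nrow(x$sites), "SNPs over", x$config$region_length, "bp,",
      "ploidy", x$config$ploidy, "\n")
  cat("  per-homolog depths (m-f-c):", x$config$depth_mother, "-",
      x$config$depth_father, "-", x$config$depth_offspring,
      "; base error", x$config$base_error, "\n")
  invisible(x)
}

#' Call dosages from simulated reads, individual by individual
#'
#' Per-site maximum-likelihood dosage calls from each individual's own reads
#' ([site_dosage_likelihood()]), ignoring the pedigree: the kind of
#' genotype table a naive variant caller would feed the phaser.  Sites with
#' no reads are `NA`.  Useful for exercising the dosage
#' correction/imputation machinery on realistic, error-prone input.
#'
#' @param sim An `f1_sim` object.
#' @return Integer matrix individuals x SNPs with `NA` for uncovered sites.
#' @export
call_genotypes <- function(sim) {
  stopifnot(inherits(sim, "f1_sim"))
  l <- nrow(sim$sites)
  out <- matrix(NA_integer_, length(sim$individuals), l,
                dimnames = list(sim$individuals, NULL))
  for (i in seq_along(sim$individuals)) {
    k <- sim$ploidy[i]
    dn <- frag_dense(sim$fragments[[i]])
    for (s in seq_len(l)) {
      cov <- !is.na(dn$A[, s])
      if (!any(cov)) next
      ll <- site_dosage_loglik_all(dn$A[cov, s], dn$E[cov, s], k)
      out[i, s] <- pick_argmax_dosage(ll, NA_integer_)
    }
  }
  out
}

#' Write simulator output to files
#'
#' Emits the reference FASTA, a VCF with the *true* genotypes (unphased
#' dosage genotypes), a HapCUT-style fragment file for the whole population,
#' and a truth JSON (parental haplotypes, transmissions, dosages, SNP
#' positions) usable by [evaluate_phasing()].
#'
#' @param sim An `f1_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_f1_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "f1_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "reference.fasta"),
             vcf = file.path(dir, "truth.vcf"),
             fragments = file.path(dir, "fragments.txt"),
             truth = file.path(dir, "truth.json"))
  writeLines(c(paste0(">", sim$sites$chrom[1]),
               strsplit(sim$ref_seq, "(?<=.{60})", perl = TRUE)[[1]]),
             paths["fasta"])
  write_phased_vcf(paths["vcf"], sim$sites, sim$genotypes,
                   phasings = NULL, ploidy = sim$ploidy)
  write_fragment_file(sim$fragments, paths["fragments"])
  truth <- list(
    positions = sim$sites$pos,
    H_m = sim$truth$H_m, H_f = sim$truth$H_f,
    transmissions = sim$truth$transmissions,
    dosage = sim$truth$dosage, individuals = sim$individuals,
    ploidy = unname(sim$ploidy[1]))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(paths)
}
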