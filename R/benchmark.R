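# Benchmark driver: simulate a grid of F1 scenarios, phase each region
# end-to-end, evaluate against the truth, and aggregate the quality
# measures (with empirical 95% intervals) per scenario.

#' Run the simulation benchmark grid
#'
#' For each population size in `n_offspring`, simulates `n_regions`
#' independent regions, runs the full pipeline (simulate, partition into
#' blocks, phase parents, select offspring phasings) and evaluates RR, PAR,
#' SMR, IDR and NGPS against the simulated truth.  Defaults mirror the
#' reference study conditions: 1 kb tetraploid regions, lognormal SNP
#' spacing (mean 50 bp, SD 90 bp), paired-end 2 x 125 bp reads with 350 bp
#' inserts, per-homolog depths 5-5-2x (mother-father-offspring).
#'
#' @param n_offspring Integer vector of population sizes (offspring counts).
#' @param n_regions Regions simulated per scenario.
#' @param seed Integer seed; the whole grid runs in one RNG stream.
#' @param rho,kappa Phaser thresholds.
#' @param ... Further arguments to [sim_f1_population()] (depths, error
#'   rate, region length...).
#' @return Object of class `phase_benchmark`: data frame with one row per
#'   (scenario, region) and columns `n_offspring`, `region`, `n_snps`,
#'   `rr_offspring`, `rr_parents`, `par_all`, `smr_all`, `idr_all`,
#'   `ngps`; `summary(x)` aggregates per scenario and overall.
#' @export
benchmark_grid <- function(n_offspring = c(2L, 6L, 10L, 30L),
                           n_regions = 20L, seed = 1L,
                           rho = 0.2, kappa = 0.94, ...) {
  set.seed(seed)
  rows <- list()
  for (n in n_offspring) {
    for (r in seq_len(n_regions)) {
      sim <- sim_f1_population(n_offspring = n, ...)
      fit <- phase_population(sim, rho = rho, kappa = kappa)
      ev <- evaluate_phasing(fit, sim)
      m <- attr(ev, "means")
      rows[[length(rows) + 1L]] <- data.frame(
        n_offspring = n, region = r, n_snps = nrow(sim$sites),
        rr_offspring = m[["rr_offspring"]], rr_parents = m[["rr_parents"]],
        par_all = m[["par"]], par_offspring = m[["par_offspring"]],
        smr_all = m[["smr"]], idr_all = m[["idr"]], ngps = m[["ngps"]])
    }
  }
  structure(do.call(rbind, rows), class = c("phase_benchmark", "data.frame"),
            seed = seed)
}

#' Summarize a benchmark run
#'
#' @param object A [benchmark_grid()] result.
#' @param ... Unused.
#' @return List with `per_scenario` (means per population size),
#'   `overall` (mean of the scenario means for each measure) and
#'   `interval` (empirical 2.5%/97.5% quantiles over all regions).
#' @export
summary.phase_benchmark <- function(object, ...) {
  meas <- c("rr_offspring", "rr_parents", "par_all", "par_offspring",
            "smr_all", "idr_all", "ngps")
  per <- aggregate(object[meas], by = list(n_offspring = object$n_offspring),
                   FUN = mean, na.rm = TRUE)
  overall <- colMeans(per[meas], na.rm = TRUE)
  interval <- t(vapply(meas, function(m)
    stats::quantile(object[[m]], c(0.025, 0.975), na.rm = TRUE,
                    names = FALSE), numeric(2)))
  colnames(interval) <- c("q2.5", "q97.5")
  out <- list(per_scenario = per, overall = overall, interval = interval)
  class(out) <- "summary.phase_benchmark"
  out
}

#' @export
print.summary.phase_benchmark <- function(x, ...) {
  cat("Per-scenario means:\n")
  print(x$per_scenario, digits = 3)
  cat("\nOverall means (of scenario means):\n")
  print(signif(x$overall, 3))
  invisible(x)
}

#' @importFrom stats aggregate
NULL

#' Read a truth JSON written by [write_f1_sim()]
#'
#' @param path Path to `truth.json`.
#' @return Truth list compatible with [evaluate_phasing()]: `H_m`, `H_f`,
#'   `transmissions`, per-individual `phasings` and the `dosage` matrix.
#' @export
read_truth_json <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_mat <- function(rows)
    do.call(rbind, lapply(rows, function(r) as.integer(unlist(r))))
  H_m <- as_mat(tr$H_m)
  H_f <- as_mat(tr$H_f)
  inds <- unlist(tr$individuals)
  n_off <- length(inds) - 2L
  transmissions <- lapply(tr$transmissions, function(t2)
    list(maternal = as.integer(unlist(t2$maternal)),
         paternal = as.integer(unlist(t2$paternal))))
  phasings <- c(list(H_m, H_f),
                lapply(transmissions, function(t2)
                  rbind(H_m[t2$maternal, , drop = FALSE],
                        H_f[t2$paternal, , drop = FALSE])))
  names(phasings) <- inds
  dosage <- as_mat(tr$dosage)
  rownames(dosage) <- inds
  list(H_m = H_m, H_f = H_f, transmissions = transmissions,
       phasings = phasings, dosage = dosage,
       positions = as.integer(unlist(tr$positions)))
}
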