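# Fragment containers and text I/O.  A "fragment" is the set of SNP allele
# calls (with base-calling error probabilities) carried by one sequencing
# template (both mates of a read pair merged); a fragment matrix is one
# individual's sparse read x SNP allele matrix.

#' Construct a fragment matrix
#'
#' @param individual Individual identifier.
#' @param fragments List of fragments; each a list with `snps` (1-based SNP
#'   indices, strictly increasing), `alleles` (0/1 calls), `eps` (error
#'   probabilities in (0, 0.5]) and optionally `id`.  Fragments covering no
#'   SNP are dropped.
#' @param n_snps Total number of SNP sites in the region.
#' @return Object of class `fragment_matrix`.
#' @export
fragment_matrix <- function(individual, fragments, n_snps) {
  fragments <- Filter(function(f) length(f$snps) > 0L, fragments)
  for (i in seq_along(fragments)) {
    f <- fragments[[i]]
    stopifnot(length(f$snps) == length(f$alleles),
              length(f$snps) == length(f$eps))
    if (any(f$snps < 1L | f$snps > n_snps)) stop("fragment SNP index out of range")
    o <- if (is.unsorted(f$snps, strictly = TRUE)) order(f$snps)
         else seq_along(f$snps)
    fragments[[i]]$snps <- as.integer(unname(f$snps[o]))
    fragments[[i]]$alleles <- as.integer(unname(f$alleles[o]))
    fragments[[i]]$eps <- unname(clamp_eps(f$eps[o]))
    if (is.null(fragments[[i]]$id)) fragments[[i]]$id <- paste0("frag", i)
  }
  structure(list(individual = individual, fragments = fragments,
                 n_snps = as.integer(n_snps)),
            class = "fragment_matrix")
}

#' @export
print.fragment_matrix <- function(x, ...) {
  cat("<fragment_matrix> individual", x$individual, "-", length(x$fragments),
      "fragments over", x$n_snps, "SNPs\n")
  invisible(x)
}

# Dense view over a column subset: allele matrix A (NA = uncovered) and
# error matrix E, fragments x length(cols).  Only fragments covering at
# least one of `cols` are kept; `rows` maps back into fm$fragments.
frag_dense <- function(fm, cols = seq_len(fm$n_snps)) {
  keep <- which(vapply(fm$fragments, function(f) any(f$snps %in% cols),
                       logical(1)))
  A <- matrix(NA_integer_, length(keep), length(cols))
  E <- matrix(NA_real_, length(keep), length(cols))
  for (i in seq_along(keep)) {
    f <- fm$fragments[[keep[i]]]
    j <- match(f$snps, cols)
    ok <- !is.na(j)
    A[i, j[ok]] <- f$alleles[ok]
    E[i, j[ok]] <- f$eps[ok]
  }
  list(A = A, E = E, rows = keep)
}

#' Write fragments to a HapCUT-style text file
#'
#' One fragment per line: fragment id, individual id, then one
#' `index:allele:phred` triple per covered SNP (1-based SNP index, 0/1
#' allele, integer Phred-scaled error probability), tab/space separated.
#'
#' @param x A `fragment_matrix` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fragment_file <- function(x, path) {
  if (inherits(x, "fragment_matrix")) x <- list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (fm in x) {
    for (f in fm$fragments) {
      trip <- paste(f$snps, f$alleles, eps_to_phred(f$eps), sep = ":")
      writeLines(paste(f$id, fm$individual, paste(trip, collapse = " "),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a HapCUT-style fragment file
#'
#' @param path Input file written by [write_fragment_file()].
#' @param n_snps Total number of SNP sites (taken as the maximum observed
#'   index if `NULL`).
#' @return Named list of `fragment_matrix` objects, one per individual.
#' @export
read_fragment_file <- function(path, n_snps = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "[\t ]+")[[1]]
    if (length(parts) < 3L) stop("malformed fragment line: ", ln)
    trip <- do.call(rbind, strsplit(parts[-(1:2)], ":", fixed = TRUE))
    storage.mode(trip) <- "character"
    list(id = parts[1L], individual = parts[2L],
         snps = as.integer(trip[, 1L]), alleles = as.integer(trip[, 2L]),
         eps = phred_to_eps(as.numeric(trip[, 3L])))
  })
  inds <- unique(vapply(recs, `[[`, character(1), "individual"))
  if (is.null(n_snps))
    n_snps <- max(vapply(recs, function(r) max(r$snps), integer(1)))
  out <- lapply(inds, function(ind) {
    fr <- Filter(function(r) r$individual == ind, recs)
    fragment_matrix(ind, fr, n_snps)
  })
  names(out) <- inds
  out
}

#' Extract SNP fragments from an alignment file
#'
#' Converts aligned reads into allele-call fragments at the given bi-allelic
#' SNP sites.  The two mates of a read pair are merged into a single
#' fragment; where overlapping mates disagree at a SNP the site is dropped
#' from the fragment (keeping either call would double-count an uncertain
#' base), and where they agree the smaller error probability is kept.  A
#' base matching neither the reference nor the alternative allele, or below
#' the base-quality threshold, leaves the SNP uncovered.  Error
#' probabilities are `10^(-Q/10)` from the base qualities, clamped to
#' `(1e-6, 0.5)`; `Q = 0` bases are excluded.
#'
#' @param alignment_file Indexed BAM file (sorted by coordinate).
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` describing the bi-allelic SNPs of one region, in increasing
#'   `pos` order.
#' @param individual Individual id recorded in the fragment matrix
#'   (defaults to the file name).
#' @param min_base_quality,min_mapping_quality Quality thresholds.
#' @return A [fragment_matrix()] with `n_snps = nrow(sites)`; fragments
#'   covering no SNP are dropped.
#' @export
read_fragments <- function(alignment_file, sites, individual = NULL,
                           min_base_quality = 13L, min_mapping_quality = 20L) {
  for (pkg in c("Rsamtools", "GenomicAlignments", "Biostrings", "S4Vectors",
                "BiocGenerics", "GenomeInfoDb"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("package '", pkg, "' is required to read alignments", call. = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (is.unsorted(sites$pos, strictly = TRUE))
    stop("SNP positions must be strictly increasing within the region")
  individual <- individual %||% basename(alignment_file)

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "seq", "qual", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  aln <- GenomicAlignments::readGAlignments(alignment_file, param = param)
  mc <- S4Vectors::mcols(aln)
  keep <- !is.na(mc$mapq) & mc$mapq >= min_mapping_quality
  aln <- aln[keep]; mc <- mc[keep, ]
  if (!length(aln)) return(fragment_matrix(individual, list(), nrow(sites)))

  # Lay sequences and qualities out in reference space (CIGAR-aware).
  seq_ref <- GenomicAlignments::sequenceLayer(mc$seq,
                                              GenomicAlignments::cigar(aln))
  qual_ref <- GenomicAlignments::sequenceLayer(
    Biostrings::BStringSet(as.character(mc$qual)),
    GenomicAlignments::cigar(aln))

  calls <- list()  # per template: named list snp -> c(allele, eps)
  starts <- BiocGenerics::start(aln)
  ends <- BiocGenerics::end(aln)
  chrom <- as.character(GenomeInfoDb::seqnames(aln))
  seq_chr <- as.character(seq_ref)
  qual_chr <- as.character(qual_ref)
  for (i in seq_along(aln)) {
    hit <- which(sites$chrom == chrom[i] & sites$pos >= starts[i] &
                   sites$pos <= ends[i])
    if (!length(hit)) next
    off <- sites$pos[hit] - starts[i] + 1L
    bases <- substring(seq_chr[i], off, off)
    quals <- utf8ToInt(qual_chr[i])[off] - 33L
    qname <- mc$qname[i]
    for (j in seq_along(hit)) {
      q <- quals[j]
      if (is.na(q) || q < min_base_quality || q <= 0L) next
      allele <- if (bases[j] == sites$ref[hit[j]]) 0L
                else if (bases[j] == sites$alt[hit[j]]) 1L else NA_integer_
      if (is.na(allele)) next
      eps <- phred_to_eps(q)
      key <- as.character(hit[j])
      cur <- calls[[qname]][[key]]
      if (is.null(cur)) {
        if (is.null(calls[[qname]])) calls[[qname]] <- list()
        calls[[qname]][[key]] <- c(allele, eps)
      } else if (!is.na(cur[1L]) && cur[1L] != allele) {
        calls[[qname]][[key]] <- c(NA_real_, NA_real_)  # mate conflict: drop site
      } else if (!is.na(cur[1L])) {
        calls[[qname]][[key]] <- c(allele, min(cur[2L], eps))
      }
    }
  }

  frags <- lapply(names(calls), function(qname) {
    m <- calls[[qname]]
    snps <- as.integer(names(m))
    al <- vapply(m, `[`, numeric(1), 1L)
    ep <- vapply(m, `[`, numeric(1), 2L)
    ok <- !is.na(al)
    if (!any(ok)) return(NULL)
    list(id = qname, snps = snps[ok], alleles = as.integer(al[ok]),
         eps = ep[ok])
  })
  frags <- Filter(Negate(is.null), frags)
  fragment_matrix(individual, frags, nrow(sites))
}
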