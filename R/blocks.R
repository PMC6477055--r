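# SNP-connectivity graph over the pooled population fragments and its
# connected components: the haplotype blocks ("solvable islands") within
# which phase is resolvable, plus the NGPS continuity measure.

#' Partition SNPs into haplotype blocks
#'
#' Builds the SNP-connectivity graph whose nodes are the SNP sites and whose
#' edges join two sites co-covered by at least one fragment, pooling the
#' fragments of *all* individuals (parental phasing uses the whole
#' population's reads, so connectivity is a population property; offspring
#' blocks inherit the partition).  Haplotype blocks are the connected
#' components; SNPs covered by no multi-SNP fragment form singleton blocks.
#'
#' @param fragment_matrices List of [fragment_matrix()] objects (all
#'   individuals), or a single one.
#' @param n_snps Total number of SNP sites.
#' @return Object of class `block_partition`: list of sorted integer
#'   vectors of SNP indices (blocks ordered by first SNP), with `n_snps`
#'   as an attribute.
#' @export
find_blocks <- function(fragment_matrices, n_snps) {
  stopifnot(n_snps >= 1)
  if (inherits(fragment_matrices, "fragment_matrix"))
    fragment_matrices <- list(fragment_matrices)
  edges <- list()
  for (fm in fragment_matrices) {
    for (f in fm$fragments) {
      s <- f$snps
      if (length(s) >= 2L)  # chain of consecutive covered sites spans the clique
        edges[[length(edges) + 1L]] <- rbind(s[-length(s)], s[-1L])
    }
  }
  g <- igraph::make_empty_graph(n = n_snps, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  memb <- igraph::components(g)$membership
  blocks <- split(seq_len(n_snps), memb)
  blocks <- lapply(blocks, function(b) sort(as.integer(b)))
  blocks <- blocks[order(vapply(blocks, min, integer(1)))]
  names(blocks) <- NULL
  structure(blocks, class = "block_partition", n_snps = as.integer(n_snps))
}

#' @export
print.block_partition <- function(x, ...) {
  sizes <- lengths(x)
  cat("<block_partition>", length(x), "blocks over", attr(x, "n_snps"),
      "SNPs (", sum(sizes == 1L), "singletons ); NGPS =",
      signif(ngps(x), 3), "\n")
  invisible(x)
}

#' Number of phasing gaps per SNP (NGPS)
#'
#' Phasing continuity measure: the number of haplotype blocks minus one,
#' normalized by the number of SNPs `l`.  0 means a single block; the fully
#' disconnected limit is `(l - 1)/l`.
#'
#' @param partition A `block_partition` (or anything whose `length()` is the
#'   number of blocks).
#' @param l Number of SNPs (taken from the partition if missing).
#' @return Numeric in `[0, 1)`.
#' @export
ngps <- function(partition, l = attr(partition, "n_snps")) {
  if (is.null(l) || l < 1) stop("number of SNPs must be >= 1")
  (length(partition) - 1) / l
}
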