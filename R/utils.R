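# Internal helpers shared across modules.

#' @importFrom stats dhyper rbinom rlnorm rnorm setNames
#' @importFrom utils combn
NULL

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# All distinct binary columns of length k with sum g, as a k x choose(k, g)
# matrix.  Columns are the possible placements of g alternative alleles on k
# homologs.
placements <- function(k, g) {
  stopifnot(g >= 0, g <= k)
  if (g == 0) return(matrix(0L, nrow = k, ncol = 1L))
  if (g == k) return(matrix(1L, nrow = k, ncol = 1L))
  idx <- combn(k, g)
  out <- matrix(0L, nrow = k, ncol = ncol(idx))
  for (j in seq_len(ncol(idx))) out[idx[, j], j] <- 1L
  out
}

# Lexicographic row sort; homolog labels carry no meaning, so phasings are
# compared through this canonical form.
canon_rows <- function(H) {
  if (nrow(H) <= 1L) return(H)
  keys <- apply(H, 1L, paste0, collapse = "")
  H[order(keys), , drop = FALSE]
}

row_key <- function(H) {
  paste(sort(apply(H, 1L, paste0, collapse = "")), collapse = "|")
}

# All permutations of 1..n as an n! x n matrix.  Exact row assignment in the
# reconstruction rate only needs small n (ploidy), where full enumeration is
# the reference method.
permutations <- function(n) {
  stopifnot(n >= 1, n <= 7)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      out[r, ] <- c(i, rest[sub[j, ]])
      r <- r + 1L
    }
  }
  out
}

clamp_eps <- function(eps, lo = 1e-6, hi = 0.5) pmin(pmax(eps, lo), hi)

phred_to_eps <- function(q) clamp_eps(10^(-q / 10))

eps_to_phred <- function(eps) as.integer(round(-10 * log10(eps)))

`%||%` <- function(a, b) if (is.null(a)) b else a
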