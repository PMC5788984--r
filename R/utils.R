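#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Bases accepted in input alignments. IUPAC ambiguity codes are kept on read
# but treated as missing (like N) by every downstream computation.
.DNA_STRICT <- c("A", "C", "G", "T")
.DNA_MISSING <- c("-", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "?")
.DNA_ALPHABET <- c(.DNA_STRICT, .DNA_MISSING)

# Run code under a temporary RNG state when a seed is given; leave the
# global stream untouched either way.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Derive child seeds from a master seed without disturbing the caller's RNG.
spawn_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(.Machine$integer.max, n))
}

# Weighted empirical quantiles (type-4-style, linear in cumulative weight).
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) {
    i <- which(cw >= p)[1]
    if (is.na(i)) x[length(x)] else x[i]
  }, numeric(1))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
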