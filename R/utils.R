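#' Derive a deterministic child seed from a run seed and a stage label
#'
#' A single run seed fans out to per-stage seeds so that, for example,
#' changing only the bootstrap stage seed leaves the simulation stages
#' untouched. The derivation is a small multiplicative string hash kept
#' below 2^31 so it is a valid R integer seed on all platforms.
#'
#' @param seed Integer run seed.
#' @param stage Character stage label (e.g. `"cohort"`, `"bootstrap"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  as.integer(h)
}

#' Apportion trial counts to conditions by largest-remainder rounding
#'
#' Realized per-condition counts honor the requested proportions exactly in
#' the sense that they differ from `n * proportions` by less than one and
#' always sum to `n`. Ties in the fractional remainders are broken by
#' condition order.
#'
#' @param proportions Named numeric vector summing to 1.
#' @param n Total number of trials.
#' @return Named integer vector of counts summing to `n`.
#' @export
allocate_counts <- function(proportions, n) {
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("condition proportions must sum to 1, got ", sum(proportions))
  }
  raw <- proportions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Vectors of community labels over the same elements.
#' @return Adjusted Rand index; 1 means identical partitions up to label
#'   permutation, 0 is chance-level agreement.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)
  (nij - expected) / (mx - expected)
}

# Canonical form of a partition: relabel communities 1, 2, ... in order of
# first appearance so label-permuted partitions compare equal.
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}
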