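# Shared fixtures, built in code. Two geometries:
#  - tiny_config(): a small genome for sequence-level checks (k-mers,
#    round-trips) — fast to realize.
#  - scaled_config(): mirrors the studied locus geometry (repeat inside
#    PAR1 ~5.3 kb distal of the PAB, paralog ~109 kb proximal) at reduced
#    chromosome size, for profiling studies.

tiny_config <- function(seed = 11, snp_density = 2e-3, ...) {
  genome_config(seed = seed, x_length = 70000, pab_position = 30000,
                repeatA_start = 25500, repeatB_start = 50000,
                y_length = 45000, snp_density = snp_density, ...)
}

scaled_config <- function(seed = 11, ...) {
  genome_config(seed = seed, x_length = 450000, pab_position = 300000,
                repeatA_start = 294651, repeatB_start = 399549,
                y_length = 350000, ...)
}

scaled_window <- c(280000, 420000)

# full-coordinate geometry (used where the printed
# coordinates themselves are the input)
analog_config <- function(seed = 11, ...) {
  genome_config(seed = seed, ...)
}

# site table built directly (no simulation), for profiler unit tests
make_sites <- function(pos, n_ref, n_alt, n_mq_fail = 0, n_bq_fail = 0,
                       n_pair_fail = 0, chrom = "toyX") {
  n <- length(pos)
  structure(
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
               n_ref = n_ref, n_alt = n_alt,
               n_mq_fail = rep_len(n_mq_fail, n),
               n_bq_fail = rep_len(n_bq_fail, n),
               n_pair_fail = rep_len(n_pair_fail, n),
               stringsAsFactors = FALSE),
    class = c("site_table", "data.frame"), seed = 0L, config_hash = "test")
}

# brute-force maximum-likelihood band assignment under the min-run
# constraint (independent oracle for the segmentation DP)
brute_force_assign <- function(ll, min_run) {
  n <- nrow(ll)
  nb <- ncol(ll)
  best <- -Inf
  best_a <- NULL
  for (code in 0:(nb^n - 1)) {
    a <- integer(n)
    c0 <- code
    for (i in seq_len(n)) {
      a[i] <- c0 %% nb + 1L
      c0 <- c0 %/% nb
    }
    if (any(rle(a)$lengths < min_run)) next
    sc <- sum(ll[cbind(seq_len(n), a)])
    if (sc > best) {
      best <- sc
      best_a <- a
    }
  }
  list(score = best, assign = best_a)
}

# brute-force minimal contiguous-block partition of an origin vector on
# its informative positions (independent oracle for run segmentation)
brute_force_min_blocks <- function(origins) {
  v <- origins[origins != "missing"]
  if (length(v) == 0L) return(0L)
  for (k in seq_along(v)) {
    if (feasible_blocks(v, k)) return(k)
  }
  length(v)
}

feasible_blocks <- function(v, k) {
  n <- length(v)
  if (k == 1L) return(length(unique(v)) == 1L)
  if (k > n) return(FALSE)
  for (cut in seq_len(n - 1L)) {
    if (length(unique(v[seq_len(cut)])) == 1L &&
        feasible_blocks(v[(cut + 1L):n], k - 1L)) {
      return(TRUE)
    }
  }
  FALSE
}
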