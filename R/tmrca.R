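## Y-STR based TMRCA estimation. Haplotype relatedness is summarized as
## the number of differing loci; the per-locus probability that two
## patrilines separated by t generations each differ at locus i is
## approximated as 1 - exp(-2 mu_i t) (infinite-alleles style: any
## mutation on either lineage makes the locus differ, back-mutation
## ignored). The stepwise-mutation simulator quantifies how well that
## approximation holds at the time scales of interest.

#' Load a per-locus Y-STR mutation rate table
#'
#' @param path TSV with columns `locus, mu`; defaults to the packaged
#'   synthetic rate table (representative magnitudes only — supply
#'   measured rates for real data).
#' @return Named numeric vector of rates (mutations/generation).
#' @export
default_ystr_rates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ystr_rates_default.tsv",
                        package = "parshift")
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  mu <- setNames(as.numeric(tab$mu), tab$locus)
  validate_rates(mu)
  mu
}

validate_rates <- function(mu) {
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 0.05)) {
    stop("mutation rates must satisfy 0 < mu < 0.05 per generation")
  }
  invisible(mu)
}

#' Pairwise differing-locus counts between Y-STR haplotypes
#'
#' @param panel data.frame or matrix, samples in rows (rownames = sample
#'   ids), loci in columns, entries = integer repeat counts; `NA` entries
#'   exclude that locus from the affected pairs.
#' @param loci optional subset of locus names.
#' @return A list with `d` (symmetric matrix of differing-locus counts,
#'   zero diagonal) and `n_compared` (loci compared per pair, after `NA`
#'   exclusion).
#' @export
pairwise_diff_matrix <- function(panel, loci = NULL) {
  m <- as.matrix(panel)
  if (!is.null(loci)) {
    miss <- setdiff(loci, colnames(m))
    if (length(miss)) stop("panel lacks locus(es): ",
                           paste(miss, collapse = ", "))
    m <- m[, loci, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  nc <- matrix(ncol(m), n, n, dimnames = dimnames(d))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok])
      nc[i, j] <- nc[j, i] <- sum(ok)
    }
  }
  list(d = d, n_compared = nc)
}

new_tmrca_posterior <- function(t, log_lik, prior = "flat") {
  ll <- log_lik - max(log_lik)
  lik <- exp(ll)
  post <- lik / sum(lik)
  structure(list(t = t, log_lik = log_lik, posterior = post,
                 prior = prior), class = "tmrca_posterior")
}

#' @export
print.tmrca_posterior <- function(x, ...) {
  ci <- credible_interval(x)
  cat(sprintf(
    "TMRCA posterior on t = %g..%g generations (grid step %g)\n",
    min(x$t), max(x$t), if (length(x$t) > 1L) x$t[2] - x$t[1] else NA))
  cat(sprintf("  mode %g, median %g, 95%% credible interval [%d, %d]\n",
              x$t[which.max(x$posterior)], posterior_median(x),
              ci[1], ci[2]))
  invisible(x)
}

posterior_median <- function(p) {
  p$t[which(cumsum(p$posterior) >= 0.5)[1]]
}

#' TMRCA posterior for a pair of haplotypes
#'
#' Per-locus difference probability `p_i(t) = 1 - exp(-2 mu_i t)` (two
#' lineages of `t` generations each); likelihood
#' `L(t) = prod_i p_i(t)^{d_i} (1 - p_i(t))^{1 - d_i}` over the
#' difference indicators, with a flat prior on the grid `[0, t_max]`.
#'
#' @param d named 0/1 vector: locus differs between the pair.
#' @param rates named per-locus mutation rates (see
#'   [default_ystr_rates()]).
#' @param t_max grid upper bound in generations (default 500).
#' @param dt grid step (default 1).
#' @return A `tmrca_posterior` (grid, log-likelihood, normalized
#'   posterior). Warns when all loci differ and posterior mass abuts
#'   `t_max`.
#' @export
tmrca_pair_posterior <- function(d, rates, t_max = 500, dt = 1) {
  stopifnot(t_max > 0, dt > 0)
  rates <- rates[names(d)]
  if (any(is.na(rates))) stop("rates missing for some loci in d")
  validate_rates(rates)
  t <- seq(0, t_max, by = dt)
  p <- 1 - exp(-2 * outer(t, rates))          # grid x loci
  ## guard log(0) at t = 0 when a locus differs
  log_lik <- as.vector(log(pmax(p, 1e-300)) %*% d + log1p(-p) %*% (1 - d))
  post <- new_tmrca_posterior(t, log_lik)
  if (all(d == 1) && sum(post$posterior[t > 0.9 * t_max]) > 0.5) {
    warning("posterior mass abuts t_max; increase t_max")
  }
  post
}

#' Locus-wise modal founder haplotype of a cluster
#'
#' The founder allele at each locus is the modal repeat count; ties are
#' broken by the median count (rounded to integer). Falls back to the
#' median with a flag when no locus has a defined mode (all alleles
#' distinct).
#'
#' @param panel sample x locus matrix of repeat counts.
#' @return Named integer vector with attribute `tie_loci` (loci where the
#'   mode was tied) and `fallback` (TRUE when the modal strategy failed
#'   everywhere).
#' @export
founder_haplotype <- function(panel) {
  m <- as.matrix(panel)
  tie <- character(0)
  all_distinct <- logical(ncol(m))
  f <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    v <- v[!is.na(v)]
    tb <- table(v)
    top <- names(tb)[tb == max(tb)]
    all_distinct[j] <<- max(tb) == 1L
    if (length(top) > 1L) {
      tie <<- c(tie, colnames(m)[j])
      as.integer(round(median(v)))
    } else {
      as.integer(top)
    }
  }, integer(1))
  names(f) <- colnames(m)
  attr(f, "tie_loci") <- tie
  attr(f, "fallback") <- all(all_distinct)
  f
}

#' TMRCA posterior for a haplotype cluster under a star genealogy
#'
#' The founder is the locus-wise modal haplotype; every sampled lineage is
#' treated as an independent descent of `t` generations from the founder,
#' so a lineage differs from the founder at locus i with probability
#' `p_i(t) = 1 - exp(-mu_i t)`. The joint likelihood is the product over
#' lineages and loci; flat prior on the grid.
#'
#' @param panel sample x locus matrix of repeat counts (>= 3 haplotypes).
#' @param rates named per-locus mutation rates.
#' @param t_max,dt posterior grid (defaults 500, 1).
#' @return A `tmrca_posterior`; attribute `founder` carries the founder
#'   haplotype used.
#' @export
cluster_tmrca <- function(panel, rates, t_max = 500, dt = 1) {
  m <- as.matrix(panel)
  if (nrow(m) < 3L) stop("cluster TMRCA needs at least 3 haplotypes")
  rates <- rates[colnames(m)]
  if (any(is.na(rates))) stop("rates missing for some panel loci")
  validate_rates(rates)
  founder <- founder_haplotype(m)
  if (isTRUE(attr(founder, "fallback"))) {
    warning("modal founder undefined at every locus; median fallback used")
  }
  ## D_i: number of lineages differing from the founder at locus i
  D <- colSums(sweep(m, 2L, founder, `!=`), na.rm = TRUE)
  N <- colSums(!is.na(m))
  t <- seq(0, t_max, by = dt)
  p <- 1 - exp(-outer(t, rates))              # grid x loci
  ## guard log(0) at t = 0 when D_i > 0
  log_lik <- as.vector(log(pmax(p, 1e-300)) %*% D + log1p(-p) %*% (N - D))
  post <- new_tmrca_posterior(t, log_lik)
  attr(post, "founder") <- founder
  post
}

#' Equal-tailed credible interval of a grid posterior
#'
#' Endpoints from cumulative grid sums, reported as integer generations
#' rounded outward (floor on the lower, ceiling on the upper).
#'
#' @param posterior a `tmrca_posterior`.
#' @param mass credible mass in (0, 1] (default 0.95).
#' @return Integer vector `c(t_lo, t_hi)`.
#' @export
credible_interval <- function(posterior, mass = 0.95) {
  stopifnot(is(posterior, "tmrca_posterior"))
  if (!(mass > 0 && mass <= 1)) stop("mass must be in (0, 1]")
  tail_mass <- (1 - mass) / 2
  cum <- cumsum(posterior$posterior)
  eps <- 1e-12
  lo <- posterior$t[which(cum >= tail_mass - eps)[1]]
  hi <- posterior$t[which(cum >= 1 - tail_mass - eps)[1]]
  c(floor(lo), ceiling(hi))
}

#' Simulate a Y-STR haplotype cluster under stepwise mutation
#'
#' Each of `n_lineages` descends independently from the founder over `t`
#' generations; per lineage and locus the mutation count is Poisson with
#' mean `mu_i t`, and each mutation shifts the repeat count by +1 or -1
#' with equal probability. Counts that would drop below 1 are clamped to 1
#' and flagged.
#'
#' @param founder named integer vector of founder repeat counts.
#' @param t generations since the founder (>= 0).
#' @param rates named per-locus mutation rates.
#' @param n_lineages number of sampled descendants.
#' @param seed integer seed.
#' @return Integer matrix (lineage x locus) with attribute `clamped`
#'   (count of clamp events).
#' @export
simulate_str_cluster <- function(founder, t, rates, n_lineages,
                                 seed = 1L) {
  stopifnot(t >= 0, n_lineages >= 1)
  rates <- rates[names(founder)]
  if (any(is.na(rates))) stop("rates missing for some founder loci")
  set.seed(component_seed(seed, "ystr"))
  nl <- length(founder)
  n_mut <- matrix(rpois(n_lineages * nl, rep(rates * t, each = n_lineages)),
                  n_lineages, nl)
  steps <- vapply(as.vector(n_mut), function(k) {
    if (k == 0L) 0L else sum(sample(c(-1L, 1L), k, replace = TRUE))
  }, integer(1))
  out <- matrix(rep(founder, each = n_lineages) + steps,
                n_lineages, nl,
                dimnames = list(sprintf("lineage_%02d", seq_len(n_lineages)),
                                names(founder)))
  clamped <- sum(out < 1L)
  out[out < 1L] <- 1L
  attr(out, "clamped") <- clamped
  out
}

#' Convert a generation interval to calendar years
#'
#' `year_old = ref_year - t_hi * span`;
#' `year_recent = ref_year - t_lo * span`.
#'
#' @param t_interval `c(t_lo, t_hi)` in generations, `t_lo <= t_hi`.
#' @param span generation span in years (> 0).
#' @param ref_year reference calendar year.
#' @return A list of class `calendar_interval` with `year_old`,
#'   `year_recent`, `span`, `ref_year`.
#' @examples
#' calendar_convert(c(7, 33), span = 25, ref_year = 2010)  # 1185..1835
#' @export
calendar_convert <- function(t_interval, span, ref_year) {
  if (span <= 0) stop("generation span must be positive")
  if (t_interval[1] > t_interval[2]) stop("t_lo exceeds t_hi")
  structure(list(year_old = ref_year - t_interval[2] * span,
                 year_recent = ref_year - t_interval[1] * span,
                 span = span, ref_year = ref_year),
            class = "calendar_interval")
}

#' @export
print.calendar_interval <- function(x, ...) {
  cat(sprintf(
    "between %d and %d (generation span of %g years, reference %d)\n",
    x$year_old, x$year_recent, x$span, x$ref_year))
  invisible(x)
}
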