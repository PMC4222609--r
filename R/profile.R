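## Variant-frequency profiling: per-site frequencies from filtered counts,
## heterozygote calling (depth >= 100 and frequency between 25% and 75%),
## likelihood-based segmentation of the folded frequencies into expected
## bands (1/2 and 1/3), breakpoint delineation between bands, repeat
## annotation and copy-model inference.

#' Configuration for the allele-frequency profiler
#'
#' Filter thresholds follow the targeted-resequencing protocol the package
#' models: reads failing proper pairing, mapping quality below 30 or base
#' quality below 20 are discarded (the simulator pre-classifies those
#' counts), and a call is considered heterozygous if its passing depth is
#' at least 100 and the variant frequency lies between 25% and 75%
#' (inclusive).
#'
#' @param min_mq,min_bq filter thresholds, recorded for provenance (the
#'   site table already separates failing reads into categories).
#' @param require_proper_pair whether pairing failures are excluded from
#'   the effective depth.
#' @param min_depth minimum passing depth for a call (default 100).
#' @param het_band inclusive unfolded frequency band for heterozygotes.
#' @param band_means expected folded variant fractions of the candidate
#'   copy states (1/2 for one alt copy of two; 1/3 for one of three).
#' @param min_run minimum heterozygous sites per segment (default 3).
#' @param ambiguity_margin log-likelihood margin below which a copy-model
#'   call is flagged ambiguous.
#' @return A list of class `profiler_config`.
#' @export
profiler_config <- function(min_mq = 30L, min_bq = 20L,
                            require_proper_pair = TRUE,
                            min_depth = 100L,
                            het_band = c(0.25, 0.75),
                            band_means = c(1/2, 1/3),
                            min_run = 3L,
                            ambiguity_margin = 2) {
  if (!(het_band[1] >= 0 && het_band[1] < het_band[2] && het_band[2] <= 1)) {
    stop("het_band must satisfy 0 <= lower < upper <= 1")
  }
  folded <- pmin(band_means, 1 - band_means)
  if (any(folded < het_band[1] - 1e-9)) {
    stop("band_means must lie within het_band once folded")
  }
  structure(list(min_mq = min_mq, min_bq = min_bq,
                 require_proper_pair = require_proper_pair,
                 min_depth = min_depth, het_band = het_band,
                 band_means = band_means, min_run = as.integer(min_run),
                 ambiguity_margin = ambiguity_margin),
            class = "profiler_config")
}

#' Per-site variant frequencies from filtered read counts
#'
#' The effective depth is the number of reads passing all filters
#' (`n_ref + n_alt`); the variant frequency is `n_alt / depth`. Sites below
#' `min_depth` (including zero-depth sites) yield no call rather than a
#' division error.
#'
#' @param table a `site_table`.
#' @param cfg a [profiler_config()].
#' @return data.frame with `chrom, pos, depth, f, callable`.
#' @export
filter_and_frequency <- function(table, cfg = profiler_config()) {
  stopifnot(is.data.frame(table))
  depth <- table$n_ref + table$n_alt
  f <- ifelse(depth > 0, table$n_alt / depth, NA_real_)
  data.frame(chrom = table$chrom, pos = table$pos,
             depth = depth, n_alt = table$n_alt, f = f,
             callable = depth >= cfg$min_depth,
             stringsAsFactors = FALSE)
}

#' Call heterozygous sites
#'
#' Inclusive band test on the unfolded frequency; the output stores the
#' folded (minor-allele) frequency `f_folded = min(f, 1 - f)`, since the
#' banding of a duplication is one-sided once phase is unknowable.
#'
#' @param frequencies output of [filter_and_frequency()].
#' @param cfg a [profiler_config()].
#' @return data.frame of heterozygous sites with
#'   `chrom, pos, depth, n_alt, f, f_folded`.
#' @export
call_het_sites <- function(frequencies, cfg = profiler_config()) {
  ok <- frequencies$callable &
    !is.na(frequencies$f) &
    frequencies$f >= cfg$het_band[1] &
    frequencies$f <= cfg$het_band[2]
  het <- frequencies[ok, c("chrom", "pos", "depth", "n_alt", "f"),
                     drop = FALSE]
  het$f_folded <- pmin(het$f, 1 - het$f)
  rownames(het) <- NULL
  het
}

## folded per-site log-likelihood of a band mean: the alt-allele labelling
## is arbitrary, so a band mean b is compatible with observed counts near
## b or 1-b; take the better side.
band_loglik <- function(n_alt, depth, band_mean) {
  pmax(dbinom(n_alt, depth, band_mean, log = TRUE),
       dbinom(n_alt, depth, 1 - band_mean, log = TRUE))
}

## exact DP: assign each het site to one band, maximizing the summed
## per-site log-likelihood subject to every maximal run having at least
## min_run sites. O(n^2 * bands^2); n is the number of het sites.
segment_assign_dp <- function(ll, min_run) {
  n <- nrow(ll)
  nb <- ncol(ll)
  cum <- apply(ll, 2L, cumsum)
  cum <- matrix(cum, nrow = n)
  ## best[i, b]: max score of sites 1..i whose final run (band b, length
  ## >= min_run) ends at i. A run starting at s contributes
  ## cum[i,b] - cum[s-1,b] on top of the best partition of 1..s-1 ending
  ## in another band, so best[i,b] = cum[i,b] + max_{s <= i-min_run+1}
  ## A_b(s) with A_b(s) = max_{b' != b} best[s-1,b'] - cum[s-1,b]
  ## (A_b(1) = 0). The admissible-s set grows by one per step: a running
  ## maximum gives O(n * bands).
  best <- matrix(-Inf, n, nb)
  back <- matrix(NA_integer_, n, nb)   # run start achieving best[i, b]
  rm_val <- rep(-Inf, nb)
  rm_arg <- rep(NA_integer_, nb)
  for (i in seq_len(n)) {
    s_new <- i - min_run + 1L          # s entering the admissible set
    if (s_new >= 1L) {
      for (b in seq_len(nb)) {
        a <- if (s_new == 1L) 0 else {
          prev <- max(best[s_new - 1L, -b])
          if (is.finite(prev)) prev - cum[s_new - 1L, b] else -Inf
        }
        if (a > rm_val[b]) {
          rm_val[b] <- a
          rm_arg[b] <- s_new
        }
      }
      for (b in seq_len(nb)) {
        if (is.finite(rm_val[b])) {
          best[i, b] <- rm_val[b] + cum[i, b]
          back[i, b] <- rm_arg[b]
        }
      }
    }
  }
  if (all(!is.finite(best[n, ]))) return(NULL)  # constraint unsatisfiable
  b <- which.max(best[n, ])
  assign <- integer(n)
  i <- n
  while (i >= 1L) {
    s <- back[i, b]
    assign[s:i] <- b
    if (s == 1L) break
    cand <- setdiff(seq_len(nb), b)
    b <- cand[which.max(best[s - 1L, cand])]
    i <- s - 1L
  }
  assign
}

#' Segment a heterozygous-frequency profile into bands
#'
#' Each heterozygous site is assigned to the expected band (folded mean 1/2
#' or 1/3 by default) by binomial likelihood; the assignment maximizes the
#' joint log-likelihood under the constraint that every segment contains at
#' least `min_run` sites, which suppresses single-site noise segments.
#' Adjacent same-band runs are merged. A male carrier of the insertion
#' shows exactly three segments: 1/2 (distal PAR1), 1/3 (triplicated
#' proximal PAR1), 1/2 (duplicated X-specific sequence).
#'
#' @param het_sites output of [call_het_sites()] (one chromosome).
#' @param cfg a [profiler_config()].
#' @return data.frame of segments with `start, end` (first/last site
#'   position), `band` (expected folded fraction), `mean_f_folded`,
#'   `n_sites`, `first_index, last_index` (row indices into `het_sites`)
#'   and a `low_confidence` attribute when fewer than `min_run` sites were
#'   available.
#' @export
segment_het_profile <- function(het_sites, cfg = profiler_config()) {
  n <- nrow(het_sites)
  folded_means <- pmin(cfg$band_means, 1 - cfg$band_means)
  if (n == 0L) {
    out <- data.frame(start = numeric(0), end = numeric(0),
                      band = numeric(0), mean_f_folded = numeric(0),
                      n_sites = integer(0), first_index = integer(0),
                      last_index = integer(0))
    attr(out, "low_confidence") <- TRUE
    return(out)
  }
  het_sites <- het_sites[order(het_sites$pos), , drop = FALSE]
  ll <- vapply(folded_means,
               function(b) band_loglik(het_sites$n_alt, het_sites$depth, b),
               numeric(n))
  ll <- matrix(ll, nrow = n)
  low_conf <- n < cfg$min_run
  assign <- if (low_conf) {
    rep(which.max(colSums(ll)), n)  # single unsegmented report
  } else {
    a <- segment_assign_dp(ll, cfg$min_run)
    if (is.null(a)) rep(which.max(colSums(ll)), n) else a
  }
  r <- rle(assign)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  out <- data.frame(
    start = het_sites$pos[first], end = het_sites$pos[last],
    band = folded_means[r$values],
    mean_f_folded = vapply(seq_along(first), function(k) {
      mean(het_sites$f_folded[first[k]:last[k]])
    }, numeric(1)),
    n_sites = r$lengths,
    first_index = first, last_index = last)
  attr(out, "low_confidence") <- low_conf
  out
}

#' Delineate breakpoints between adjacent frequency bands
#'
#' For every transition between adjacent segments, the breakpoint interval
#' is the open interval between the boundary-adjacent informative sites:
#' the last site of the distal segment and the first site of the proximal
#' segment (no sub-site interpolation). In the studied locus this is the
#' rule "most proximal 50% SNP, most distal 33% SNP".
#'
#' @param segments output of [segment_het_profile()].
#' @param het_sites the het-site table the segments were built from.
#' @return data.frame of breakpoint calls with `left_pos, right_pos`
#'   (evidence-site coordinates bounding the open interval), `left_band,
#'   right_band`; zero rows when fewer than two segments exist.
#' @export
delineate_breakpoints <- function(segments, het_sites) {
  het_sites <- het_sites[order(het_sites$pos), , drop = FALSE]
  k <- nrow(segments)
  if (k < 2L) {
    return(data.frame(left_pos = numeric(0), right_pos = numeric(0),
                      left_band = numeric(0), right_band = numeric(0)))
  }
  i <- seq_len(k - 1L)
  data.frame(
    left_pos = segments$end[i],
    right_pos = segments$start[i + 1L],
    left_band = segments$band[i],
    right_band = segments$band[i + 1L])
}

#' Annotate breakpoint calls with overlapping repeats and MQ0 evidence
#'
#' Each call is labelled with the repeat annotations its open interval
#' overlaps, and flagged `mq0_flag` when more than 99% of the raw reads at
#' catalogued sites strictly inside the interval failed the
#' mapping-quality filter — the signature of a breakpoint buried in
#' two-copy repeat homology.
#'
#' @param calls output of [delineate_breakpoints()].
#' @param repeats data.frame with `id, start, end` (0-based half-open), or
#'   a `GRanges` (1-based) as imported from BED.
#' @param table the raw `site_table` (for MQ0 evidence); optional.
#' @param mq0_threshold fraction of MQ-failed raw reads above which the
#'   flag is set (default 0.99).
#' @return `calls` with `repeats` (comma-separated ids, "" if none) and
#'   `mq0_flag` columns added.
#' @export
annotate_with_repeats <- function(calls, repeats, table = NULL,
                                  mq0_threshold = 0.99) {
  if (is(repeats, "GRanges")) {
    repeats <- data.frame(
      id = repeats$name %||% as.character(seq_along(repeats)),
      start = GenomicRanges::start(repeats) - 1L,
      end = GenomicRanges::end(repeats), stringsAsFactors = FALSE)
  }
  n <- nrow(calls)
  calls$repeats <- character(n)
  calls$mq0_flag <- logical(n)
  if (n == 0L) return(calls)
  qry <- IRanges::IRanges(start = calls$left_pos + 1L, end = calls$right_pos)
  sbj <- IRanges::IRanges(start = repeats$start + 1L, end = repeats$end)
  ov <- IRanges::findOverlaps(qry, sbj)
  if (length(ov)) {
    hits <- split(repeats$id[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov))
    for (q in names(hits)) {
      calls$repeats[as.integer(q)] <-
        paste(unique(hits[[q]]), collapse = ",")
    }
  }
  if (!is.null(table)) {
    for (i in seq_len(n)) {
      inside <- table$pos > calls$left_pos[i] & table$pos < calls$right_pos[i]
      if (!any(inside)) next
      raw <- with(table[inside, , drop = FALSE],
                  sum(n_ref + n_alt + n_mq_fail + n_bq_fail + n_pair_fail))
      mq <- sum(table$n_mq_fail[inside])
      calls$mq0_flag[i] <- raw > 0 && mq / raw > mq0_threshold
    }
  }
  calls
}

#' Infer the copy model of a segment by pooled binomial likelihood
#'
#' Compares candidate `(m, c)` copy states (one alt copy of two — the
#' pseudoautosomal expectation of 50% — versus one of three, the 33%
#' triplication signature) by the summed folded binomial log-likelihood
#' over the segment's sites, and reports the winning model with its
#' log-likelihood margin. Margins below the configured threshold are
#' flagged ambiguous.
#'
#' @param segment one row of [segment_het_profile()] output.
#' @param het_sites the het-site table the segment indexes into.
#' @param cfg a [profiler_config()].
#' @param models list of candidate `c(m, c)` pairs.
#' @return A list with `m, c, loglik, margin, ambiguous` and the per-model
#'   log-likelihood table.
#' @export
infer_copy_counts <- function(segment, het_sites, cfg = profiler_config(),
                              models = list(c(1L, 2L), c(1L, 3L))) {
  idx <- segment$first_index:segment$last_index
  sites <- het_sites[order(het_sites$pos), , drop = FALSE][idx, , drop = FALSE]
  ll <- vapply(models, function(mc) {
    b <- min(mc[1] / mc[2], 1 - mc[1] / mc[2])
    sum(band_loglik(sites$n_alt, sites$depth, b))
  }, numeric(1))
  ord <- order(ll, decreasing = TRUE)
  margin <- if (length(ll) > 1L) ll[ord[1]] - ll[ord[2]] else Inf
  best <- models[[ord[1]]]
  list(m = best[1], c = best[2], loglik = ll[ord[1]], margin = margin,
       ambiguous = margin < cfg$ambiguity_margin,
       model_logliks = data.frame(
         m = vapply(models, `[`, integer(1), 1L),
         c = vapply(models, `[`, integer(1), 2L),
         loglik = ll))
}
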