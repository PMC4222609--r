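## Site-level read-count simulation. The downstream inference consumes
## per-position variant frequencies, so reads are summarized directly as
## passing ref/alt counts plus the failure categories the profiler's
## filters act on (mapping quality, base quality, proper pairing); no
## read-level alignment is emulated.

#' Configuration for the site-level pileup simulator
#'
#' @param seed integer seed for the pileup component.
#' @param mean_depth expected passing-read depth at copy number 2
#'   (reads/site). Depth at copy number `c` scales as `mean_depth * c / 2`.
#' @param base_error symmetric per-base error rate, folded into the
#'   binomial success probability (default 0.01).
#' @param proper_pair_rate fraction of reads mapped in a proper pair.
#' @param mq0_rate_in_repeat fraction of reads failing the mapping-quality
#'   filter at sites inside the paralogous repeats (default 0.995; in the
#'   studied locus more than 99% of reads around the frequency changes map
#'   with quality 0 because the repeats are two-copy).
#' @param mq_fail_rate_background mapping-quality failure rate outside the
#'   repeats.
#' @param bq_fail_rate base-quality failure rate per read.
#' @return A validated list of class `pileup_config`.
#' @export
pileup_config <- function(seed = 1L, mean_depth = 300,
                          base_error = 0.01,
                          proper_pair_rate = 0.98,
                          mq0_rate_in_repeat = 0.995,
                          mq_fail_rate_background = 0.005,
                          bq_fail_rate = 0.01) {
  cfg <- list(seed = as.integer(seed), mean_depth = mean_depth,
              base_error = base_error, proper_pair_rate = proper_pair_rate,
              mq0_rate_in_repeat = mq0_rate_in_repeat,
              mq_fail_rate_background = mq_fail_rate_background,
              bq_fail_rate = bq_fail_rate)
  if (base_error < 0 || base_error >= 0.5) {
    stop("base_error must be in [0, 0.5)")
  }
  rates <- c(proper_pair_rate, mq0_rate_in_repeat,
             mq_fail_rate_background, bq_fail_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  class(cfg) <- "pileup_config"
  cfg
}

#' Simulate a site table from a truth copy profile
#'
#' For every catalogued SNP with copy count `c` and variant copies `m`, the
#' raw depth is Poisson with mean `mean_depth * c / 2`; reads are thinned
#' through mapping-quality, pairing and base-quality failures (sites inside
#' the repeat homology lose `mq0_rate_in_repeat` of their reads to the MQ
#' filter); surviving reads support the alt allele with probability
#' `f (1 - e) + (1 - f) e` where `f = m / c` and `e` is the base error.
#'
#' @param profile a `copy_profile` from [truth_copy_profile()].
#' @param config a [pileup_config()].
#' @param window optional `c(lo, hi)` restricting simulated sites to
#'   catalogue positions in `[lo, hi)`.
#' @return A data.frame of class `site_table`, sorted by position, with
#'   columns `chrom, pos, ref, alt, n_ref, n_alt, n_mq_fail, n_bq_fail,
#'   n_pair_fail` and attributes `seed` and `config_hash`.
#' @export
simulate_site_table <- function(profile, config = pileup_config(),
                                window = NULL) {
  stopifnot(is(profile, "copy_profile"), is(config, "pileup_config"))
  set.seed(component_seed(config$seed, "pileup"))
  snps <- profile$snps
  if (!is.null(window)) {
    snps <- snps[snps$pos >= window[1] & snps$pos < window[2], , drop = FALSE]
  }
  n <- nrow(snps)
  cov <- snps$c
  raw <- rpois(n, config$mean_depth * cov / 2)
  p_mq <- ifelse(snps$in_repeat, config$mq0_rate_in_repeat,
                 config$mq_fail_rate_background)
  n_mq <- rbinom(n, raw, p_mq)
  rem <- raw - n_mq
  n_pair <- rbinom(n, rem, 1 - config$proper_pair_rate)
  rem <- rem - n_pair
  n_bq <- rbinom(n, rem, config$bq_fail_rate)
  eff <- rem - n_bq
  f <- ifelse(cov > 0, snps$m / cov, 0)
  p_alt <- f * (1 - config$base_error) + (1 - f) * config$base_error
  n_alt <- rbinom(n, eff, p_alt)

  tab <- data.frame(chrom = profile$chrom, pos = snps$pos,
                    ref = snps$ref, alt = snps$alt,
                    n_ref = eff - n_alt, n_alt = n_alt,
                    n_mq_fail = n_mq, n_bq_fail = n_bq,
                    n_pair_fail = n_pair, stringsAsFactors = FALSE)
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("site_table", "data.frame"),
            seed = config$seed,
            config_hash = config_hash(unclass(config)))
}

#' Write a site table as TSV
#'
#' A plain tab-separated file with a `#`-prefixed provenance header (seed
#' and configuration hash) followed by a column-name line; round-trips
#' losslessly through [read_site_table()].
#'
#' @param table a `site_table`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_site_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# parshift site table\tseed=%s\tconfig_hash=%s",
                     attr(table, "seed") %||% NA,
                     attr(table, "config_hash") %||% NA), con)
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a site table written by [write_site_table()]
#'
#' @param path TSV file.
#' @return A `site_table` data.frame with provenance attributes restored.
#' @export
read_site_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  needed <- c("chrom", "pos", "ref", "alt", "n_ref", "n_alt",
              "n_mq_fail", "n_bq_fail", "n_pair_fail")
  if (length(body) == 0L) stop("site table has no header line")
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1L]]
  miss <- setdiff(needed, cols)
  if (length(miss)) stop("site table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab <- tryCatch(
    read.delim(text = body, sep = "\t", stringsAsFactors = FALSE,
               colClasses = c(chrom = "character", ref = "character",
                              alt = "character")),
    error = function(e) stop("malformed site table: ", conditionMessage(e)))
  counts <- tab[c("n_ref", "n_alt", "n_mq_fail", "n_bq_fail", "n_pair_fail")]
  bad <- which(!stats::complete.cases(counts) |
                 apply(counts, 1L, function(r) any(r < 0)))
  if (length(bad)) {
    stop(sprintf("malformed site table row at line %d",
                 bad[1] + length(hdr) + 1L))
  }
  seed <- NA
  ch <- NA
  if (length(hdr)) {
    m <- regmatches(hdr[1], regexec("seed=([^\t]*)\tconfig_hash=(\\S*)", hdr[1]))[[1]]
    if (length(m) == 3L) {
      seed <- suppressWarnings(as.integer(m[2]))
      ch <- m[3]
    }
  }
  structure(tab, class = c("site_table", "data.frame"),
            seed = seed, config_hash = ch)
}
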