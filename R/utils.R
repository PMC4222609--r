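## Shared helpers: deterministic seed fan-out, config fingerprints,
## coordinate parsing.

#' Derive a component seed from a root seed and a label
#'
#' A single root seed is fanned out to the package's stochastic components
#' by fixed text labels, so that each component is independently
#' reproducible (re-running one module never perturbs another's stream).
#'
#' @param root_seed integer root seed.
#' @param label character label naming the component (e.g. "genome").
#' @return An integer seed in [0, 2^31 - 2].
#' @export
component_seed <- function(root_seed, label) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L,
            is.character(label), length(label) == 1L, nzchar(label))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(root_seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

#' FNV-1a hash of a character string
#'
#' 32-bit Fowler-Noll-Vo fingerprint, used to stamp outputs with the
#' configuration that produced them so that mismatched intermediates can be
#' refused.
#'
#' @param x character scalar.
#' @return Hex string of 8 characters.
#' @export
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (code in utf8ToInt(enc2utf8(x))) {
    # xor and multiply mod 2^32, via 16-bit halves to stay in exact doubles
    hl <- h %% 65536L
    hh <- (h - hl) / 65536L
    cl <- code %% 65536L
    ch <- ((code - cl) / 65536L) %% 65536L
    h <- bitwXor(as.integer(hh), as.integer(ch)) * 65536 +
      bitwXor(as.integer(hl), as.integer(cl))
    hl <- h %% 65536
    hh <- (h - hl) / 65536
    h <- (((hh * 16777619) %% 65536) * 65536 + hl * 16777619) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

#' Fingerprint an R object
#'
#' Serializes the object to canonical JSON and hashes it; used as the config
#' hash echoed into every output header.
#'
#' @param obj any jsonlite-serializable object.
#' @return Hex string of 8 characters.
#' @export
config_hash <- function(obj) {
  fnv1a32(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' Parse a genomic range written as "chr:start-end"
#'
#' Ranges printed in the field's "chrX:2,694,151-2,694,702" style are parsed
#' end-exclusively: the length of the range is \code{end - start}, which
#' reproduces the printed sizes of the two LTR6B repeats (551 bp and 548 bp)
#' from their printed coordinate pairs. Commas are ignored.
#'
#' @param x character vector of range strings.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{width} (= end - start).
#' @examples
#' parse_region("chrX:2,694,151-2,694,702")$width  # 551
#' @export
parse_region <- function(x) {
  stopifnot(is.character(x))
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed range string(s): ", paste(x[bad], collapse = ", "))
  }
  chrom <- vapply(m, `[[`, "", 2L)
  strip <- function(i) as.numeric(gsub(",", "", vapply(m, `[[`, "", i)))
  start <- strip(3L)
  end <- strip(4L)
  if (any(end < start)) stop("range end precedes start")
  data.frame(chrom = chrom, start = start, end = end,
             width = end - start, stringsAsFactors = FALSE)
}

#' Format a 0-based half-open interval in "chr:start-end" style
#' @param chrom chromosome label.
#' @param start,end 0-based half-open bounds.
#' @return character vector.
#' @export
format_region <- function(chrom, start, end) {
  sprintf("%s:%s-%s", chrom,
          formatC(start, format = "d", big.mark = ","),
          formatC(end, format = "d", big.mark = ","))
}

## internal: draw a random DNA string of length n at a given GC fraction
random_dna <- function(n, gc_fraction = 0.41) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## internal: replace single characters of a string at 1-based positions
str_assign <- function(s, pos1, chars) {
  if (length(pos1) == 0L) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  v[pos1] <- chars
  paste(v, collapse = "")
}

## internal: 0-based half-open substring of a plain-character sequence
subseq0 <- function(s, start0, end0) {
  if (end0 <= start0) return("")
  substr(s, start0 + 1L, end0)
}
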