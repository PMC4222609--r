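## PSV-based typing of fusion-repeat amplicons. The two paralogous repeats
## differ at a fixed set of diagnostic positions (PSVs); reading the base
## at each PSV assigns that position's origin (X-specific or
## pseudoautosomal), and the pattern of origin blocks classifies the
## junction: Junc1 (recombinant: distal X block, proximal PAR block),
## Junc1c (Junc1 plus the rs211656-analog extra variant), Junc2 (fully
## X-specific, the gene-conversion product), reference classes, or a
## merged/complex profile as seen in the reciprocal deletion.

JUNCTION_CLASSES <- c("JUNC1", "JUNC1C", "JUNC2", "X_REF", "PAR_REF",
                      "MERGED_COMPLEX", "AMBIGUOUS")

#' Extract PSV origin states from a junction amplicon
#'
#' Each PSV is located by exact match of its flanking anchor k-mers (taken
#' from the repeat consensus, which is invariant between the two repeat
#' copies away from the diagnostic positions); the base between the
#' anchors is compared with the X-specific and PAR states. Orientation is
#' normalized by also scanning the reverse complement and keeping the
#' orientation that locates more PSVs. Registered non-PSV extra variants
#' (analogs of rs2316283 and rs211656) are detected the same way.
#'
#' @param amplicon character; the amplicon sequence.
#' @param pair the `chrom_pair` carrying the repeat references, PSV table
#'   and extra-variant registry.
#' @param anchor flanking anchor length in bp (default 10).
#' @param context where the sequence sits: `"junction"` for a
#'   junction-spanning amplicon, `"reference_X"` / `"reference_PAR"` for a
#'   reference locus (used to resolve the Junc2 / X-reference alias).
#' @return An object of class `junction_profile`: list with `origins`
#'   (character vector over PSVs, values `X`, `PAR`, `other`, `missing`),
#'   `extra_variants` (labels detected), `context`, `orientation`.
#' @export
extract_states <- function(amplicon, pair, anchor = 10L,
                           context = "junction") {
  stopifnot(is.character(amplicon), length(amplicon) == 1L,
            is(pair, "chrom_pair"))
  read_one <- function(seq) {
    vapply(seq_len(nrow(pair$psv)), function(i) {
      locate_state(seq, pair$repeat_seq_PAR, pair$psv$offset[i], anchor)
    }, "")
  }
  classify_base <- function(base, i) {
    if (is.na(base) || base == "") return("missing")
    if (base == pair$psv$state_X[i]) return("X")
    if (base == pair$psv$state_PAR[i]) return("PAR")
    "other"
  }
  fw <- read_one(amplicon)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(amplicon)))
  rv <- read_one(rc)
  use_rc <- sum(rv != "") > sum(fw != "")
  seq_used <- if (use_rc) rc else amplicon
  bases <- if (use_rc) rv else fw
  origins <- vapply(seq_along(bases), function(i) {
    classify_base(if (bases[i] == "") NA_character_ else bases[i], i)
  }, "")
  if (mean(origins != "missing") < 0.5) {
    stop(sprintf(
      "alignment failure: only %d of %d PSV positions located in amplicon",
      sum(origins != "missing"), length(origins)))
  }
  xv <- pair$extra_variants
  xv_found <- character(0)
  if (nrow(xv)) {
    xb <- vapply(seq_len(nrow(xv)), function(i) {
      b <- locate_state(seq_used, pair$repeat_seq_PAR, xv$offset[i], anchor)
      !is.na(b) && b != "" && b == xv$alt[i]
    }, logical(1))
    xv_found <- xv$label[xb]
  }
  structure(list(origins = origins, extra_variants = xv_found,
                 context = context,
                 orientation = if (use_rc) "reverse" else "forward"),
            class = "junction_profile")
}

## find the base at a repeat offset inside an amplicon by flanking anchors;
## "" when the anchors are absent or inconsistent
locate_state <- function(amplicon, consensus, offset, anchor) {
  L <- nchar(consensus)
  a_lo <- max(0L, offset - anchor)
  left <- subseq0(consensus, a_lo, offset)
  right <- subseq0(consensus, offset + 1L, min(L, offset + 1L + anchor))
  if (nchar(left) < 4L && nchar(right) < 4L) return("")
  hits <- gregexpr(left, amplicon, fixed = TRUE)[[1L]]
  if (hits[1] == -1L) return("")
  found <- ""
  for (h in hits) {
    bpos <- h + nchar(left)          # 1-based position of the queried base
    cand <- substr(amplicon, bpos, bpos)
    after <- substr(amplicon, bpos + 1L, bpos + nchar(right))
    if (nchar(right) == 0L || after == right) {
      if (found != "" && found != cand) return("")  # conflicting hits
      found <- cand
    }
  }
  found
}

#' Classify a junction profile
#'
#' Rules, applied to the origin vector (missing positions ignored):
#' all-X in a junction context is the gene-conversion class `JUNC2` (the
#' identical sequence at a reference X locus is `X_REF`); all-PAR is
#' `PAR_REF`; a single distal-X / proximal-PAR switch is the canonical
#' recombinant `JUNC1`, promoted to `JUNC1C` when the rs211656-analog
#' extra variant is present; any other recombinant pattern (two or more
#' switches, or the deletion-type PAR-distal / X-proximal single switch)
#' is `MERGED_COMPLEX`; profiles dominated by missing positions are
#' `AMBIGUOUS`.
#'
#' @param profile a `junction_profile`.
#' @return An object of class `junction_call`: list with `class`,
#'   `switch_count`, `crossover_intervals` (list of index pairs),
#'   `extra_variants`, `blocks`.
#' @export
classify_junction <- function(profile) {
  stopifnot(is(profile, "junction_profile"))
  org <- profile$origins
  blocks <- min_switch_segmentation(org)
  informative <- org[org != "missing"]
  n_sw <- max(0L, nrow(blocks) - 1L)
  xover <- list()
  if (nrow(blocks) > 1L) {
    for (i in seq_len(nrow(blocks) - 1L)) {
      xover[[i]] <- c(blocks$last_index[i], blocks$first_index[i + 1L])
    }
  }
  cls <- if (length(informative) == 0L ||
             mean(org == "missing") > 0.5) {
    "AMBIGUOUS"
  } else if (all(informative == "X")) {
    if (identical(profile$context, "junction")) "JUNC2" else "X_REF"
  } else if (all(informative == "PAR")) {
    "PAR_REF"
  } else if (n_sw == 1L && blocks$origin[1] == "X" &&
             blocks$origin[2] == "PAR") {
    if ("rs211656_analog" %in% profile$extra_variants) "JUNC1C" else "JUNC1"
  } else {
    "MERGED_COMPLEX"
  }
  structure(list(class = cls, switch_count = n_sw,
                 crossover_intervals = xover,
                 extra_variants = profile$extra_variants,
                 blocks = blocks),
            class = "junction_call")
}

#' @export
print.junction_call <- function(x, ...) {
  cat(sprintf("Junction call: %s (%d switch%s)\n", x$class,
              x$switch_count, if (x$switch_count == 1L) "" else "es"))
  if (nrow(x$blocks)) {
    cat("  blocks:",
        paste(sprintf("%s x%d", x$blocks$origin, x$blocks$n), collapse = " | "),
        "\n")
  }
  if (length(x$extra_variants)) {
    cat("  extra variants:", paste(x$extra_variants, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Minimal same-origin block partition of an origin vector
#'
#' Maximal runs of identical origin, ignoring missing positions (a missing
#' position neither breaks nor extends a run). Equals the brute-force
#' minimal-block partition of the informative positions.
#'
#' @param origins character vector over PSV positions, values in
#'   `{X, PAR, other, missing}` (distal to proximal order).
#' @return data.frame with `origin`, `n` (informative positions in the
#'   block), `first_index`, `last_index` (1-based indices into the input of
#'   the block's first/last informative positions). Zero rows when all
#'   positions are missing.
#' @export
min_switch_segmentation <- function(origins) {
  stopifnot(length(origins) > 0L)
  keep <- which(origins != "missing")
  if (length(keep) == 0L) {
    return(data.frame(origin = character(0), n = integer(0),
                      first_index = integer(0), last_index = integer(0)))
  }
  r <- rle(origins[keep])
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  data.frame(origin = r$values, n = r$lengths,
             first_index = keep[first], last_index = keep[last],
             stringsAsFactors = FALSE)
}

#' Load a junction-typing reference from a truth JSON file
#'
#' Reconstructs the minimal reference needed by [extract_states()] — the
#' PSV table, the extra-variant registry and the two repeat reference
#' sequences — from the truth JSON written by [write_genome()], so
#' amplicons can be typed without rebuilding the genome.
#'
#' @param path truth JSON written by [write_genome()].
#' @return A `chrom_pair`-compatible typing reference.
#' @export
read_typing_reference <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("psv", "extra_variants", "repeat_seq_X", "repeat_seq_PAR")
  miss <- setdiff(needed, names(truth))
  if (length(miss)) stop("truth JSON lacks field(s): ",
                         paste(miss, collapse = ", "))
  structure(list(psv = as.data.frame(truth$psv),
                 extra_variants = as.data.frame(truth$extra_variants),
                 repeat_seq_X = truth$repeat_seq_X,
                 repeat_seq_PAR = truth$repeat_seq_PAR),
            class = "chrom_pair")
}

#' Read a per-sample junction call table
#'
#' Long-format TSV with columns `family, sample, method, call`, where
#' `call` uses the field's shorthand (`1` = JUNC1, `1c` = JUNC1C,
#' `2` = JUNC2) or full class names; empty calls are dropped.
#'
#' @param path TSV file (e.g. the packaged encoding of the study's sample
#'   table, `system.file("extdata", "junction_calls_table.tsv",
#'   package = "parshift")`).
#' @return data.frame with `family, sample, method, class`.
#' @export
read_junction_calls <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character", comment.char = "#")
  needed <- c("family", "sample", "method", "call")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) stop("junction table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab <- tab[!is.na(tab$call) & nzchar(trimws(tab$call)), , drop = FALSE]
  shorthand <- c("1" = "JUNC1", "1c" = "JUNC1C", "2" = "JUNC2")
  cls <- trimws(tab$call)
  mapped <- unname(shorthand[cls])
  cls <- ifelse(is.na(mapped), toupper(cls), mapped)
  bad <- !cls %in% JUNCTION_CLASSES
  if (any(bad)) stop("unknown junction call(s): ",
                     paste(unique(tab$call[bad]), collapse = ", "))
  data.frame(family = tab$family, sample = tab$sample,
             method = tab$method, class = cls, stringsAsFactors = FALSE)
}

#' Tabulate junction calls across samples and methods
#'
#' Counts calls per class and method, counts distinct samples per class
#' (a sample carries a class if any method assigns it), and checks
#' cross-method concordance per sample. Conflicting calls for one
#' sample-method combination are flagged.
#'
#' @param calls data.frame with `sample, method, class` (e.g. from
#'   [read_junction_calls()]).
#' @return A list with `by_method` (class x method count table),
#'   `distinct_samples` (named vector: distinct samples per class),
#'   `concordance` (per-sample data.frame with `concordant` flag over
#'   samples typed by >= 2 methods), `conflicts` (flagged sample-method
#'   rows).
#' @export
tabulate_calls <- function(calls) {
  stopifnot(all(c("sample", "method", "class") %in% names(calls)))
  cls_f <- factor(calls$class, levels = JUNCTION_CLASSES)
  by_method <- table(class = cls_f, method = calls$method)
  conflicts <- unique(do.call(rbind, lapply(
    split(calls, paste(calls$sample, calls$method, sep = "\r")),
    function(g) {
      if (length(unique(g$class)) > 1L) {
        data.frame(sample = g$sample[1], method = g$method[1])
      }
    })))
  per_sample <- split(calls$class, calls$sample)
  distinct <- vapply(JUNCTION_CLASSES, function(k) {
    sum(vapply(per_sample, function(v) k %in% v, logical(1)))
  }, integer(1))
  multi <- per_sample[vapply(split(calls$method, calls$sample),
                             function(m) length(unique(m)) > 1L,
                             logical(1))]
  concordance <- data.frame(
    sample = names(multi),
    concordant = vapply(multi, function(v) length(unique(v)) == 1L,
                        logical(1)),
    row.names = NULL)
  list(by_method = by_method, distinct_samples = distinct,
       concordance = concordance,
       conflicts = if (is.null(conflicts)) {
         data.frame(sample = character(0), method = character(0))
       } else conflicts)
}
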