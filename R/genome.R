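## Synthetic X/Y genome with two paralogous repeats, and the NAHR event
## producing the insertion-bearing Y (derY) and the reciprocal deletion X
## (delX), with full truth records.
##
## Coordinates are 0-based half-open throughout. The toy X mirrors the
## studied locus 1:1: a repeat inside PAR1 ~5 kb distal of the PAB and a
## paralogous repeat ~110 kb proximal of the PAB in X-specific sequence.

#' Configuration for the synthetic X/Y reference pair
#'
#' Defaults mirror the studied locus at unscaled coordinates: the PAR1
#' repeat at 2,694,151 and the X-specific repeat at 2,808,549, with the PAB
#' placed at 2,699,500 (the true PAB coordinate is an analog choice, not a
#' genome-build claim), so that the proximal ~5 kb PAR1 / ~110 kb X-specific
#' duplicon structure is reproduced qualitatively.
#'
#' @param seed integer root seed for the genome component.
#' @param pab_position pseudoautosomal boundary, bp offset; equals the PAR1
#'   length (PAR1 is `[0, pab_position)`).
#' @param repeatA_start start of the PAR1-internal repeat (id `A_PAR`), bp.
#' @param repeatB_start start of the X-specific repeat (id `B_XSPEC`), bp.
#' @param repeat_length shared repeat length, bp (default 548).
#' @param n_psv number of diagnostic paralogous sequence variants carried by
#'   the repeat pair (default 15).
#' @param snp_density expected catalogued SNPs per bp along X.
#' @param x_length,y_length total chromosome lengths, bp. `y_length` must
#'   exceed `pab_position` (Y carries the whole of PAR1 plus a Y-specific
#'   tail).
#' @param gc_fraction GC content of the random background sequence.
#' @return A validated list of class `genome_config`.
#' @export
genome_config <- function(seed = 1L,
                          pab_position = 2699500,
                          repeatA_start = 2694151,
                          repeatB_start = 2808549,
                          repeat_length = 548,
                          n_psv = 15,
                          snp_density = 3e-3,
                          x_length = 3e6,
                          y_length = pab_position + 1e6,
                          gc_fraction = 0.41) {
  cfg <- list(seed = as.integer(seed), pab_position = pab_position,
              par1_length = pab_position,
              repeatA_start = repeatA_start, repeatB_start = repeatB_start,
              repeat_length = repeat_length, n_psv = n_psv,
              snp_density = snp_density, x_length = x_length,
              y_length = y_length, gc_fraction = gc_fraction)
  class(cfg) <- "genome_config"
  validate_genome_config(cfg)
  cfg
}

validate_genome_config <- function(cfg) {
  with(cfg, {
    a <- c(repeatA_start, repeatA_start + repeat_length)
    b <- c(repeatB_start, repeatB_start + repeat_length)
    if (a[2] >= pab_position) {
      stop(sprintf(
        "configuration error: repeat A [%d, %d) must lie inside PAR1 [0, %d)",
        a[1], a[2], pab_position))
    }
    if (b[1] <= pab_position) {
      stop(sprintf(
        "configuration error: repeat B [%d, %d) must lie proximal of the PAB at %d",
        b[1], b[2], pab_position))
    }
    if (b[2] > x_length) {
      stop(sprintf("configuration error: repeat B [%d, %d) exceeds X length %d",
                   b[1], b[2], x_length))
    }
    if (repeat_length < n_psv) {
      stop("configuration error: repeat_length must be >= n_psv")
    }
    if (y_length <= pab_position) {
      stop(sprintf(
        "configuration error: y_length %d must exceed pab_position %d (Y carries PAR1)",
        y_length, pab_position))
    }
    if (snp_density < 0 || snp_density > 1) stop("snp_density must be in [0, 1]")
    if (gc_fraction <= 0 || gc_fraction >= 1) stop("gc_fraction must be in (0, 1)")
  })
  invisible(cfg)
}

## evenly-spread random offsets with a minimum spacing, kept away from the
## repeat edges so that PSV anchor windows fall on invariant sequence
pick_spaced_offsets <- function(L, k, margin = 10L, spacing = 21L) {
  if (k == 0L) return(integer(0))
  margin <- min(margin, max(0L, floor((L - k) / 2)))
  lo <- margin
  hi <- L - 1L - margin
  span <- hi - lo
  if (span + 1L < k) stop("repeat too short for requested variant count")
  spacing <- max(1L, min(spacing, if (k > 1L) floor(span / (k - 1L)) else span))
  slack <- span - (k - 1L) * spacing
  lo + sort(sample(0:slack, k, replace = TRUE)) + (seq_len(k) - 1L) * spacing
}

#' Build the reference X/Y chromosome pair
#'
#' Generates random background sequence, embeds the two paralogous repeats
#' (identical except at `n_psv` diagnostic PSV offsets plus two registered
#' extra-variant offsets), and draws a catalogue of SNPs with per-copy
#' alleles on three haplotype columns: the carrier's own X homolog, the
#' donor X that takes part in the NAHR event, and the Y (defined over PAR1
#' only). X and Y are identical over PAR1 except at catalogued SNP alleles
#' and at nothing else; Y carries the PAR repeat (`A_PAR`) but not
#' `B_XSPEC`.
#'
#' @param config a [genome_config()].
#' @param with_sequences if `FALSE`, skip realizing the nucleotide strings
#'   (coordinate-level truth only; an order of magnitude faster for
#'   simulation studies that never touch sequence).
#' @return An object of class `chrom_pair`.
#' @export
build_reference <- function(config, with_sequences = TRUE) {
  validate_genome_config(config)
  set.seed(component_seed(config$seed, "genome"))
  L <- config$repeat_length
  pab <- config$pab_position
  A <- config$repeatA_start
  B <- config$repeatB_start

  ## repeat pair: consensus = PAR state; X-specific copy differs at PSVs
  n_marks <- config$n_psv + 2L
  offs <- tryCatch(pick_spaced_offsets(L, n_marks),
                   error = function(e) pick_spaced_offsets(L, config$n_psv))
  if (length(offs) == n_marks) {
    xv_idx <- sort(sample(seq_len(n_marks), 2L))
    xv_offs <- offs[xv_idx]
    psv_offs <- offs[-xv_idx]
  } else {
    xv_offs <- integer(0)
    psv_offs <- offs
  }
  consensus <- random_dna(L, config$gc_fraction)
  cons_vec <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  state_par <- cons_vec[psv_offs + 1L]
  state_x <- vapply(state_par, other_base, "")
  psv <- data.frame(offset = psv_offs, state_X = unname(state_x),
                    state_PAR = state_par, stringsAsFactors = FALSE)
  xv_labels <- c("rs2316283_analog", "rs211656_analog")[seq_along(xv_offs)]
  extra_variants <- data.frame(
    label = xv_labels, offset = xv_offs,
    ref = cons_vec[xv_offs + 1L],
    alt = vapply(cons_vec[xv_offs + 1L], other_base, ""),
    stringsAsFactors = FALSE)
  seq_A <- consensus                       # PAR-side repeat
  seq_B <- str_assign(consensus, psv$offset + 1L, psv$state_X)  # X-specific

  ## SNP catalogue with per-copy alleles (1 = alt). Sites are polymorphic
  ## among the copies that can co-occur; Y alleles exist over PAR1 only.
  n_snp <- rbinom(1L, config$x_length, config$snp_density)
  pos <- sort(sample.int(config$x_length, n_snp) - 1L)
  mark_pos <- c(A + psv$offset, B + psv$offset,
                A + extra_variants$offset, B + extra_variants$offset)
  pos <- setdiff(pos, mark_pos)
  in_par <- pos < pab
  combos3 <- rbind(c(0,0,1), c(0,1,0), c(0,1,1), c(1,0,0), c(1,0,1), c(1,1,0))
  al <- matrix(NA_integer_, nrow = length(pos), ncol = 3,
               dimnames = list(NULL, c("allele_other_x", "allele_donor_x",
                                       "allele_y")))
  if (any(in_par)) {
    al[in_par, ] <- combos3[sample.int(6L, sum(in_par), replace = TRUE), ]
  }
  if (any(!in_par)) {
    flip <- sample(c(TRUE, FALSE), sum(!in_par), replace = TRUE)
    al[!in_par, 1:2] <- cbind(as.integer(flip), as.integer(!flip))
  }

  x_seq <- y_seq <- NULL
  ref <- alt <- rep(NA_character_, length(pos))
  in_repeat <- (pos >= A & pos < A + L) | (pos >= B & pos < B + L)
  if (with_sequences) {
    base_x <- random_dna(config$x_length, config$gc_fraction)
    base_x <- str_assign(base_x, A + seq_len(L),
                         strsplit(seq_A, "", fixed = TRUE)[[1L]])
    base_x <- str_assign(base_x, B + seq_len(L),
                         strsplit(seq_B, "", fixed = TRUE)[[1L]])
    ref <- vapply(pos, function(p) substr(base_x, p + 1L, p + 1L), "")
    alt <- vapply(ref, other_base, "")
    ## embed donor-X alleles into X, Y alleles into the PAR1 of Y; SNPs
    ## inside the repeats are catalogued but not embedded (the repeats are
    ## the amplicon references and must differ only at PSV/extra offsets)
    emb_x <- which(al[, "allele_donor_x"] == 1L & !in_repeat)
    x_seq <- str_assign(base_x, pos[emb_x] + 1L, alt[emb_x])
    y_par <- subseq0(base_x, 0, pab)
    emb_y <- which(!is.na(al[, "allele_y"]) & al[, "allele_y"] == 1L &
                     !in_repeat & pos < pab)
    y_par <- str_assign(y_par, pos[emb_y] + 1L, alt[emb_y])
    y_seq <- paste0(y_par, random_dna(config$y_length - pab,
                                      config$gc_fraction))
  } else {
    bases <- c("A", "C", "G", "T")
    ref <- bases[sample.int(4L, length(pos), replace = TRUE)]
    alt <- vapply(ref, other_base, "")
  }

  snp_catalog <- data.frame(pos = pos, ref = ref, alt = alt,
                            al, in_repeat = in_repeat,
                            stringsAsFactors = FALSE)
  repeats <- data.frame(
    id = c("A_PAR", "B_XSPEC", "A_PAR"),
    chrom = c("toyX", "toyX", "toyY"),
    start = c(A, B, A), end = c(A + L, B + L, A + L),
    stringsAsFactors = FALSE)

  structure(list(config = config, x_seq = x_seq, y_seq = y_seq,
                 pab = pab, repeats = repeats, psv = psv,
                 extra_variants = extra_variants,
                 repeat_seq_X = seq_B, repeat_seq_PAR = seq_A,
                 snp_catalog = snp_catalog,
                 config_hash = config_hash(unclass(config))),
            class = "chrom_pair")
}

#' @export
print.chrom_pair <- function(x, ...) {
  cat("Synthetic X/Y chromosome pair\n")
  cat(sprintf("  toyX %s bp, toyY %s bp, PAB at %s\n",
              format(x$config$x_length, big.mark = ","),
              format(x$config$y_length, big.mark = ","),
              format(x$pab, big.mark = ",")))
  cat(sprintf("  repeats: A_PAR %s, B_XSPEC %s (%d bp, %d PSVs)\n",
              format_region("toyX", x$repeats$start[1], x$repeats$end[1]),
              format_region("toyX", x$repeats$start[2], x$repeats$end[2]),
              x$config$repeat_length, nrow(x$psv)))
  cat(sprintf("  SNP catalogue: %d sites\n", nrow(x$snp_catalog)))
  invisible(x)
}

#' Describe an NAHR crossover between the two paralogous repeats
#'
#' The donor is the X-specific repeat (`B_XSPEC`) on the X chromosome and
#' the acceptor is the PAR1 repeat (`A_PAR`) on the Y. The crossover offset
#' `delta` splits the repeat half-open: fusion-repeat offsets `< delta`
#' originate from the donor (X) side, offsets `>= delta` from the acceptor
#' (PAR) side, so the emitted sequence and the truth origin vector always
#' agree.
#'
#' @param delta crossover offset within the repeat, in `[0, repeat_length]`.
#'   `NULL` defaults to `repeat_length / 2`.
#' @param conversion_tract optional `c(start, end)` half-open offsets of a
#'   gene-conversion tract applied post hoc (see
#'   [apply_gene_conversion()]).
#' @param extra_variants labels of registered non-PSV repeat variants to
#'   plant on the derived-Y fusion repeat (default: the rs2316283 analog,
#'   which the recombinant junction class carries).
#' @param allelic test-only mode: cross the `A_PAR` repeats of X and Y
#'   (a fully allelic exchange; products are structurally identical to the
#'   parents).
#' @return An object of class `nahr_event`.
#' @export
nahr_event <- function(delta = NULL, conversion_tract = NULL,
                       extra_variants = "rs2316283_analog",
                       allelic = FALSE) {
  structure(list(delta = delta, conversion_tract = conversion_tract,
                 extra_variants = extra_variants, allelic = allelic),
            class = "nahr_event")
}

#' Apply the NAHR crossover to the reference pair
#'
#' Produces the insertion-bearing Y (`derY`) and the reciprocal deletion X
#' (`delX`):
#' \preformatted{
#'   derY = donorX[0 .. B_start+delta) + Y[A_start+delta .. y_length)
#'   delX = Y[0 .. A_start+delta)     + donorX[B_start+delta .. x_length)
#' }
#' derY gains exactly `B_start - A_start` bp (the duplicon: X-specific
#' sequence plus proximal PAR1), carries the proximal PAR1 segment and the
#' PAB region twice (its own Y-PAB junction stays intact), and holds a
#' fusion repeat whose PSV origins are X distal of the crossover and PAR
#' proximal of it. delX loses the same span; total length is conserved.
#'
#' @param pair a `chrom_pair` from [build_reference()].
#' @param event an [nahr_event()].
#' @return An object of class `derived_genome` carrying the two derived
#'   sequences (when the pair has sequences), the fusion-repeat origin
#'   vectors for both products, and the length bookkeeping.
#' @export
apply_nahr <- function(pair, event = nahr_event()) {
  stopifnot(is(pair, "chrom_pair"), is(event, "nahr_event"))
  L <- pair$config$repeat_length
  delta <- if (is.null(event$delta)) floor(L / 2) else event$delta
  if (delta < 0 || delta > L) {
    stop(sprintf("crossover offset %s outside repeat [0, %d]", delta, L))
  }
  A <- pair$config$repeatA_start
  B <- if (event$allelic) A else pair$config$repeatB_start
  xl <- pair$config$x_length
  yl <- pair$config$y_length

  der_y_seq <- del_x_seq <- NULL
  if (!is.null(pair$x_seq)) {
    der_y_seq <- paste0(subseq0(pair$x_seq, 0, B + delta),
                        subseq0(pair$y_seq, A + delta, yl))
    del_x_seq <- paste0(subseq0(pair$y_seq, 0, A + delta),
                        subseq0(pair$x_seq, B + delta, xl))
  }
  gain <- B - A
  origin_derY <- ifelse(pair$psv$offset < delta, "X", "PAR")
  origin_delX <- ifelse(pair$psv$offset < delta, "PAR", "X")
  if (event$allelic) origin_derY <- origin_delX <- rep("PAR", nrow(pair$psv))

  planted <- character(0)
  if (!event$allelic && length(event$extra_variants)) {
    xv <- pair$extra_variants
    keep <- xv$label %in% event$extra_variants
    if (any(keep) && !is.null(der_y_seq)) {
      der_y_seq <- str_assign(der_y_seq, B + xv$offset[keep] + 1L,
                              xv$alt[keep])
    }
    planted <- xv$label[keep]
  }

  der <- structure(list(
    pair = pair, event = event, delta = delta,
    der_y_seq = der_y_seq, del_x_seq = del_x_seq,
    gain = gain,
    der_y_length = yl + gain, del_x_length = xl - gain,
    fusion_derY = data.frame(offset = pair$psv$offset, origin = origin_derY,
                             stringsAsFactors = FALSE),
    fusion_delX = data.frame(offset = pair$psv$offset, origin = origin_delX,
                             stringsAsFactors = FALSE),
    fusion_derY_extra = planted,
    fusion_derY_start = B, fusion_delX_start = A),
    class = "derived_genome")
  if (!is.null(event$conversion_tract)) {
    der <- apply_gene_conversion(der, event$conversion_tract)
  }
  der
}

#' @export
print.derived_genome <- function(x, ...) {
  cat("NAHR-derived genome\n")
  cat(sprintf("  crossover offset %d within the %d bp repeat\n",
              x$delta, x$pair$config$repeat_length))
  cat(sprintf("  derY %s bp (+%s), delX %s bp (-%s)\n",
              format(x$der_y_length, big.mark = ","),
              format(x$gain, big.mark = ","),
              format(x$del_x_length, big.mark = ","),
              format(x$gain, big.mark = ",")))
  cat(sprintf("  derY fusion-repeat PSV origins: %s\n",
              paste(x$fusion_derY$origin, collapse = "")))
  invisible(x)
}

#' Apply a gene-conversion tract to the derived-Y fusion repeat
#'
#' Rewrites PSV origins inside the half-open tract `[start, end)` (repeat
#' offsets) to X, with the X-specific repeat serving as donor; registered
#' extra variants inside the tract revert to the reference state. A tract
#' covering every PSV turns a recombinant (Junc1-type) fusion repeat back
#' into a fully X-specific one — the genesis of the Junc2 class.
#'
#' @param derived a `derived_genome`.
#' @param tract `c(start, end)` half-open repeat offsets; `start == end` is
#'   the empty tract (identity).
#' @return The modified `derived_genome`.
#' @export
apply_gene_conversion <- function(derived, tract) {
  stopifnot(is(derived, "derived_genome"), length(tract) == 2L)
  L <- derived$pair$config$repeat_length
  if (tract[1] < 0 || tract[2] > L || tract[1] > tract[2]) {
    stop(sprintf("conversion tract [%s, %s) outside repeat [0, %d]",
                 tract[1], tract[2], L))
  }
  if (tract[1] == tract[2]) return(derived)
  psv <- derived$pair$psv
  hit <- psv$offset >= tract[1] & psv$offset < tract[2]
  derived$fusion_derY$origin[hit] <- "X"
  if (!is.null(derived$der_y_seq) && any(hit)) {
    derived$der_y_seq <- str_assign(
      derived$der_y_seq,
      derived$fusion_derY_start + psv$offset[hit] + 1L,
      psv$state_X[hit])
  }
  xv <- derived$pair$extra_variants
  xv_hit <- xv$label %in% derived$fusion_derY_extra &
    xv$offset >= tract[1] & xv$offset < tract[2]
  if (any(xv_hit)) {
    if (!is.null(derived$der_y_seq)) {
      derived$der_y_seq <- str_assign(
        derived$der_y_seq,
        derived$fusion_derY_start + xv$offset[xv_hit] + 1L,
        xv$ref[xv_hit])
    }
    derived$fusion_derY_extra <-
      setdiff(derived$fusion_derY_extra, xv$label[xv_hit])
  }
  derived$event$conversion_tract <- tract
  derived
}

#' Truth copy-number profile for a stated karyotype
#'
#' Projects the chromosomal content of a karyotype onto reference X
#' coordinates as a piecewise-constant copy count, and annotates every
#' catalogued SNP with `(m, c)`: the number of copies carrying the alt
#' allele and the total copy count at the site. The expected variant read
#' fraction is `m / c` — the quantity whose 50% / 33% / 50% banding reveals
#' the rearrangement in a male carrier.
#'
#' @param derived a `derived_genome`.
#' @param karyotype one of `"male_carrier"` (X + derY), `"deletion_female"`
#'   (delX + X), `"male_control"` (X + Y), `"female_control"` (X + X).
#' @return An object of class `copy_profile` with elements `intervals`
#'   (start, end, copies) tiling `[0, x_length)` and `snps`
#'   (pos, ref, alt, m, c, expected fraction).
#' @export
truth_copy_profile <- function(derived,
                               karyotype = c("male_carrier",
                                             "deletion_female",
                                             "male_control",
                                             "female_control")) {
  stopifnot(is(derived, "derived_genome"))
  karyotype <- match.arg(karyotype)
  pair <- derived$pair
  cfg <- pair$config
  xl <- cfg$x_length
  pab <- cfg$pab_position
  a_cut <- cfg$repeatA_start + derived$delta
  b_cut <- cfg$repeatB_start + derived$delta
  cat_ <- pair$snp_catalog
  p <- cat_$pos

  ## which haplotype columns are present at each X position
  n <- length(p)
  tt <- rep(TRUE, n)
  ff <- rep(FALSE, n)
  present <- switch(
    karyotype,
    male_carrier = cbind(other_x = tt,
                         donor_x = p < b_cut,
                         y = p >= a_cut & p < pab),
    deletion_female = cbind(other_x = tt,
                            donor_x = p >= b_cut,
                            y = p < a_cut),
    male_control = cbind(other_x = tt, donor_x = ff, y = p < pab),
    female_control = cbind(other_x = tt, donor_x = tt, y = ff))

  alleles <- cbind(cat_$allele_other_x, cat_$allele_donor_x, cat_$allele_y)
  alleles[is.na(alleles)] <- 0L
  m <- rowSums(alleles * present)
  c_ <- rowSums(present)

  intervals <- switch(
    karyotype,
    male_carrier = data.frame(
      start = c(0, a_cut, pab, b_cut),
      end = c(a_cut, pab, b_cut, xl),
      copies = c(2L, 3L, 2L, 1L)),
    deletion_female = data.frame(
      start = c(0, a_cut, b_cut),
      end = c(a_cut, b_cut, xl),
      copies = c(2L, 1L, 2L)),
    male_control = data.frame(
      start = c(0, pab), end = c(pab, xl), copies = c(2L, 1L)),
    female_control = data.frame(start = 0, end = xl, copies = 2L))
  intervals <- intervals[intervals$end > intervals$start, , drop = FALSE]

  snps <- data.frame(pos = p, ref = cat_$ref, alt = cat_$alt,
                     m = as.integer(m), c = as.integer(c_),
                     in_repeat = cat_$in_repeat,
                     stringsAsFactors = FALSE)
  snps$expected_f <- ifelse(snps$c > 0, snps$m / snps$c, NA_real_)

  structure(list(karyotype = karyotype, intervals = intervals, snps = snps,
                 pab = pab, chrom = "toyX",
                 repeats = pair$repeats[pair$repeats$chrom == "toyX", ],
                 truth = list(a_cut = a_cut, b_cut = b_cut,
                              delta = derived$delta, gain = derived$gain),
                 config_hash = pair$config_hash, seed = cfg$seed),
            class = "copy_profile")
}

#' @export
print.copy_profile <- function(x, ...) {
  cat(sprintf("Copy profile (%s) on %s\n", x$karyotype, x$chrom))
  print(x$intervals, row.names = FALSE)
  cat(sprintf("  %d catalogued SNPs; heterozygous-capable: %d\n",
              nrow(x$snps), sum(x$snps$m > 0 & x$snps$m < x$snps$c)))
  invisible(x)
}

#' Expected array log2 ratio per copy-number interval
#'
#' A sanity-check helper for comparative-hybridization style tracks:
#' `log2(copies / reference_copy)` per interval. Zero-copy intervals yield
#' `-Inf` and are flagged.
#'
#' @param profile a `copy_profile`.
#' @param reference_copy copy number of the reference sample (> 0).
#' @return The profile's `intervals` data.frame with `log2_ratio` and
#'   `zero_copy` columns added.
#' @export
expected_log2 <- function(profile, reference_copy = 2) {
  stopifnot(is(profile, "copy_profile"), reference_copy > 0)
  iv <- profile$intervals
  iv$log2_ratio <- ifelse(iv$copies > 0,
                          log2(iv$copies / reference_copy), -Inf)
  iv$zero_copy <- iv$copies == 0
  iv
}

#' Extract a junction-spanning amplicon from a derived chromosome
#'
#' Pulls the fusion repeat plus flanking sequence from derY (the Y-extended
#' PAR junction, as amplified across the insertion boundary) or delX (the
#' merged repeat of the reciprocal deletion).
#'
#' @param derived a `derived_genome` built with sequences.
#' @param which `"derY"` or `"delX"`.
#' @param flank flanking bp on each side (default 150).
#' @return A list with `seq` (character), `repeat_start` (0-based offset of
#'   the fusion repeat within the amplicon) and `context` (`"junction"`).
#' @export
fusion_amplicon <- function(derived, which = c("derY", "delX"),
                            flank = 150L) {
  stopifnot(is(derived, "derived_genome"))
  which <- match.arg(which)
  seq <- if (which == "derY") derived$der_y_seq else derived$del_x_seq
  if (is.null(seq)) stop("derived genome was built without sequences")
  L <- derived$pair$config$repeat_length
  start <- if (which == "derY") derived$fusion_derY_start else
    derived$fusion_delX_start
  lo <- max(0L, start - flank)
  hi <- min(nchar(seq), start + L + flank)
  list(seq = subseq0(seq, lo, hi), repeat_start = start - lo,
       context = "junction", product = which)
}

#' PAB junction k-mers of the reference pair
#'
#' The k-mer spanning the Y-PAB (PAR1 to Y-specific transition on Y) and the
#' one spanning the X-PAB. The derived Y must contain each exactly once:
#' the insertion extends PAR1 without disrupting the Y's own boundary.
#'
#' @param pair a `chrom_pair` with sequences.
#' @param k k-mer length (default 40).
#' @return Named character vector with elements `y_pab` and `x_pab`.
#' @export
pab_junction_kmers <- function(pair, k = 40L) {
  stopifnot(is(pair, "chrom_pair"), !is.null(pair$x_seq))
  half <- floor(k / 2)
  c(y_pab = subseq0(pair$y_seq, pair$pab - half, pair$pab - half + k),
    x_pab = subseq0(pair$x_seq, pair$pab - half, pair$pab - half + k))
}

#' Count occurrences of a k-mer in a sequence
#'
#' @param seq character sequence.
#' @param kmer pattern to count (overlapping matches included).
#' @return Integer count.
#' @export
count_kmer <- function(seq, kmer) {
  Biostrings::countPattern(kmer, Biostrings::DNAString(seq))
}
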