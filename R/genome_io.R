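## On-disk interchange for the synthetic genome: FASTA (60-column wrap),
## BED6 features (0-based half-open; the PAB uses the zero-length
## start == end convention), and a JSON truth record echoing the seeded
## configuration.

features_granges <- function(pair, derived = NULL) {
  cfg <- pair$config
  gr <- GenomicRanges::GRanges(
    seqnames = c("toyX", "toyY",
                 "toyX", "toyY",
                 pair$repeats$chrom),
    ranges = IRanges::IRanges(
      start = c(1L, 1L, cfg$pab_position + 1L, cfg$pab_position + 1L,
                pair$repeats$start + 1L),
      end = c(cfg$pab_position, cfg$pab_position,
              cfg$pab_position, cfg$pab_position,  # zero-width PAB points
              pair$repeats$end)),
    name = c("PAR1", "PAR1", "PAB", "PAB", pair$repeats$id),
    score = 0L)
  snp <- pair$snp_catalog
  if (nrow(snp)) {
    gr_snp <- GenomicRanges::GRanges(
      seqnames = "toyX",
      ranges = IRanges::IRanges(start = snp$pos + 1L, width = 1L),
      name = sprintf("SNP_%s>%s", snp$ref, snp$alt),
      score = 0L)
    gr <- c(gr, gr_snp)
  }
  gr
}

#' Write a genome object to FASTA + BED + JSON
#'
#' @param x a `chrom_pair` or `derived_genome` (built with sequences).
#' @param dir output directory, created if needed.
#' @param prefix file-name prefix (default `"genome"`).
#' @return Invisibly, a named character vector of the written paths
#'   (`fasta`, `bed`, `json`).
#' @export
write_genome <- function(x, dir, prefix = "genome") {
  UseMethod("write_genome")
}

write_genome_files <- function(seqs, gr, truth, dir, prefix) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, paste0(prefix, ".fa")),
             bed = file.path(dir, paste0(prefix, "_features.bed")),
             json = file.path(dir, paste0(prefix, "_truth.json")))
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, paths[["fasta"]], width = 60L)
  rtracklayer::export(GenomicRanges::sort(gr), paths[["bed"]], format = "BED")
  jsonlite::write_json(truth, paths[["json"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @export
write_genome.chrom_pair <- function(x, dir, prefix = "genome") {
  if (is.null(x$x_seq)) stop("pair was built without sequences")
  truth <- list(
    kind = "reference_pair",
    config = unclass(x$config), config_hash = x$config_hash,
    psv = x$psv, extra_variants = x$extra_variants,
    repeat_seq_X = x$repeat_seq_X, repeat_seq_PAR = x$repeat_seq_PAR,
    repeats = x$repeats)
  write_genome_files(c(toyX = x$x_seq, toyY = x$y_seq),
                     features_granges(x), truth, dir, prefix)
}

#' @export
write_genome.derived_genome <- function(x, dir, prefix = "genome") {
  if (is.null(x$der_y_seq)) stop("derived genome was built without sequences")
  pair <- x$pair
  truth <- list(
    kind = "derived_genome",
    config = unclass(pair$config), config_hash = pair$config_hash,
    psv = pair$psv, extra_variants = pair$extra_variants,
    repeat_seq_X = pair$repeat_seq_X, repeat_seq_PAR = pair$repeat_seq_PAR,
    delta = x$delta, gain = x$gain,
    der_y_length = x$der_y_length, del_x_length = x$del_x_length,
    fusion_derY = x$fusion_derY, fusion_delX = x$fusion_delX,
    fusion_derY_extra = as.list(x$fusion_derY_extra),
    copy_profiles = lapply(
      c("male_carrier", "deletion_female", "male_control", "female_control"),
      function(k) {
        pr <- truth_copy_profile(x, k)
        list(karyotype = k, intervals = pr$intervals)
      }))
  write_genome_files(c(derY = x$der_y_seq, delX = x$del_x_seq),
                     features_granges(pair), truth, dir, prefix)
}

#' Read genome features back from BED
#'
#' @param path BED file written by [write_genome()].
#' @return A `GRanges` of the features.
#' @export
read_genome_features <- function(path) {
  rtracklayer::import(path, format = "BED")
}
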