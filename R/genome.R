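#' GRCh38 chromosome lengths
#'
#' Sequence lengths (bp) of the 24 human chromosomes in the GRCh38
#' reference assembly, used as multinomial weights when allocating
#' passenger mutations across chromosomes and as exposure offsets in
#' per-chromosome mutation-density tests.
#'
#' @return Named integer vector of lengths, names `"1"`..`"22"`, `"X"`, `"Y"`.
#' @examples
#' chrom_lengths()[["1"]]
#' @export
chrom_lengths <- function() {
  c(`1` = 248956422, `2` = 242193529, `3` = 198295559, `4` = 190214555,
    `5` = 181538259, `6` = 170805979, `7` = 159345973, `8` = 145138636,
    `9` = 138394717, `10` = 133797422, `11` = 135086622, `12` = 133275309,
    `13` = 114364328, `14` = 107043718, `15` = 101991189, `16` = 90338345,
    `17` = 83257441, `18` = 80373285, `19` = 58617616, `20` = 64444167,
    `21` = 46709983, `22` = 50818468, X = 156040895, Y = 57227415)
}

# Approximate GRCh38 centromere midpoints (bp); precision to a few Mb is
# sufficient for p/q arm assignment of multi-megabase mCA segments.
centromere_midpoints <- function() {
  c(`1` = 123400000, `2` = 93900000, `3` = 90900000, `4` = 50000000,
    `5` = 48800000, `6` = 59800000, `7` = 60100000, `8` = 45200000,
    `9` = 43000000, `10` = 39800000, `11` = 53400000, `12` = 35500000,
    `13` = 17700000, `14` = 17200000, `15` = 19000000, `16` = 36800000,
    `17` = 25100000, `18` = 18500000, `19` = 26200000, `20` = 28100000,
    `21` = 12000000, `22` = 15000000, X = 60600000, Y = 10400000)
}

#' Normalize chromosome labels
#'
#' Accepts labels with or without a "chr" prefix; validates against the 24
#' human chromosomes.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Character vector without the "chr" prefix.
#' @export
normalize_chrom <- function(chrom) {
  out <- sub("^chr", "", as.character(chrom))
  bad <- !(out %in% names(chrom_lengths()))
  if (any(bad)) {
    stop("unknown chromosome label(s): ",
         paste(unique(out[bad]), collapse = ", "))
  }
  out
}

#' Assign a chromosome arm to a segment
#'
#' A segment entirely telomeric of the centromere midpoint is assigned to
#' the arm it lies on; a segment spanning the centromere is labelled
#' `"whole"`. Acrocentric p arms are handled like any other since mCA
#' calls there are rare and multi-megabase.
#'
#' @param chrom Chromosome label(s).
#' @param start,end 1-based inclusive segment coordinates (bp).
#' @return Character vector in `c("p", "q", "whole")`.
#' @export
chrom_arm <- function(chrom, start, end) {
  chrom <- normalize_chrom(chrom)
  stopifnot(length(start) == length(chrom), length(end) == length(chrom))
  if (any(end <= start)) stop("segment end must exceed start")
  cen <- centromere_midpoints()[chrom]
  unname(ifelse(end <= cen, "p", ifelse(start >= cen, "q", "whole")))
}

#' Default CHIP-associated driver gene list
#'
#' Genes in which somatic driver mutations define clonal hematopoiesis of
#' indeterminate potential (CHIP). Variants annotated to these genes are
#' never counted as neutral passengers, and individuals carrying CHIP
#' driver mutations are excluded from the scored cohort. The bundled list
#' seeds the canonical examples; site-specific lists can be supplied
#' wherever a `chip_genes` argument is accepted.
#'
#' @return Character vector of gene symbols.
#' @export
chip_gene_defaults <- function() {
  path <- system.file("extdata", "chip_genes.txt", package = "pacermca")
  if (nzchar(path)) {
    genes <- readLines(path, warn = FALSE)
    genes <- trimws(genes[!grepl("^\\s*(#|$)", genes)])
    if (length(genes)) return(genes)
  }
  c("DNMT3A", "ASXL1", "TET2", "JAK2")
}
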