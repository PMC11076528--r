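#' Is a substitution clock-like?
#'
#' Clock-like somatic passengers are C>T and T>C base substitutions (the
#' spontaneous-deamination and age-associated signatures). Under the
#' standard pyrimidine-normalized representation of mutational signatures
#' the reverse-complement pairs G>A and A>G denote the same events and
#' also qualify; `literal_strand = TRUE` restricts to the literal C>T /
#' T>C pairs for sensitivity analysis.
#'
#' @param ref,alt Single reference / alternate bases (A, C, G or T);
#'   vectorized.
#' @param literal_strand Disable pyrimidine normalization?
#' @return Logical vector.
#' @examples
#' is_clocklike("C", "T")
#' is_clocklike("G", "A")  # reverse complement of C>T
#' @export
is_clocklike <- function(ref, alt, literal_strand = FALSE) {
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases)) {
    stop("ref and alt must be single bases A/C/G/T")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  lit <- (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  if (literal_strand) return(lit)
  lit | (ref == "G" & alt == "A") | (ref == "A" & alt == "G")
}

#' Somatic-singleton quality filter
#'
#' A variant qualifies as a candidate passenger observation when its
#' depth lies in \[25, 100\] (depths below 25 or above 100 are excluded),
#' its variant allele fraction does not exceed 0.35 (higher VAFs are
#' presumed germline), and it is not annotated to a CHIP-associated
#' driver gene. Bounds follow the stated strict exclusions, so depth 25,
#' depth 100 and VAF 0.35 all pass.
#'
#' @param variants Data frame with `depth`, `vaf` and optionally `gene`
#'   columns.
#' @param chip_genes Character vector of CHIP driver gene symbols;
#'   defaults to the bundled list.
#' @return Logical vector.
#' @export
passes_quality <- function(variants, chip_genes = chip_gene_defaults()) {
  stopifnot(all(c("depth", "vaf") %in% names(variants)))
  gene <- if ("gene" %in% names(variants)) variants$gene else ""
  variants$depth >= 25 & variants$depth <= 100 & variants$vaf <= 0.35 &
    !(gene %in% chip_genes)
}

#' Count clock-like passenger mutations per individual
#'
#' Counts variants passing both [is_clocklike()] and [passes_quality()],
#' in total and per chromosome. Indels / multi-nucleotide rows must have
#' been rejected at parse time ([read_variants()]); duplicated variant
#' records (same sample, chromosome, position, ref, alt) are an error.
#'
#' @param variants Data frame with `sample_id`, `chromosome`, `position`,
#'   `ref`, `alt`, `depth`, `vaf` and optionally `gene`.
#' @param chip_genes CHIP driver gene symbols.
#' @param literal_strand Passed to [is_clocklike()].
#' @param sample_ids Optional character vector fixing the output rows
#'   (samples with no passing variant get a zero row); defaults to the
#'   samples present in `variants`.
#' @return Object of class `passenger_counts`: data frame with
#'   `sample_id`, `total`, and one zero-filled column per chromosome
#'   (`chr1` ... `chrY`). Samples with zero passing variants are flagged
#'   in the `attr(, "zero_count")` log.
#' @export
count_passengers <- function(variants, chip_genes = chip_gene_defaults(),
                             literal_strand = FALSE, sample_ids = NULL) {
  need <- c("sample_id", "chromosome", "position", "ref", "alt",
            "depth", "vaf")
  stopifnot(is.data.frame(variants), all(need %in% names(variants)))
  variants$chromosome <- normalize_chrom(variants$chromosome)
  key <- with(variants, paste(sample_id, chromosome, position, ref, alt))
  if (anyDuplicated(key)) {
    stop("duplicate variant record(s): ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  }
  if (is.null(sample_ids)) sample_ids <- sort(unique(variants$sample_id))
  pass <- is_clocklike(variants$ref, variants$alt, literal_strand) &
    passes_quality(variants, chip_genes)
  hits <- variants[pass, , drop = FALSE]
  chroms <- names(chrom_lengths())
  tab <- table(factor(hits$sample_id, levels = sample_ids),
               factor(hits$chromosome, levels = chroms))
  per_chrom <- matrix(as.integer(tab), nrow = length(sample_ids),
                      dimnames = list(NULL, paste0("chr", chroms)))
  out <- data.frame(sample_id = sample_ids, total = rowSums(per_chrom),
                    per_chrom, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "zero_count") <- out$sample_id[out$total == 0]
  class(out) <- c("passenger_counts", "data.frame")
  out
}

#' Total passenger count excluding one chromosome
#'
#' Used for the mCA-chromosome sensitivity analysis: passenger counts
#' with the mCA-bearing (or a random) chromosome removed.
#'
#' @param counts A `passenger_counts` table from [count_passengers()].
#' @param chrom Chromosome label(s), length 1 or `nrow(counts)` (the
#'   per-sample mCA chromosome).
#' @return Integer vector of `total` minus that chromosome's count.
#' @export
total_excluding <- function(counts, chrom) {
  stopifnot(is.data.frame(counts), "total" %in% names(counts))
  chrom <- normalize_chrom(chrom)
  if (length(chrom) == 1) chrom <- rep(chrom, nrow(counts))
  stopifnot(length(chrom) == nrow(counts))
  cols <- paste0("chr", chrom)
  idx <- match(cols, names(counts))
  minus <- ifelse(is.na(idx), 0L,
                  as.integer(counts[cbind(seq_len(nrow(counts)), idx)]))
  as.integer(counts$total - minus)
}
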