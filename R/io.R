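#' Read a MoChA-style mCA call table
#'
#' Tab-separated with columns `sample_id`, `chromosome`, `start`, `end`,
#' `copy_type`, `clonal_fraction`, `lod_baf_phase`,
#' `relative_coverage`. Coordinates are 1-based inclusive.
#'
#' @param path File path.
#' @return Data frame of calls.
#' @export
read_mca_calls <- function(path) {
  calls <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chromosome", "start", "end", "copy_type",
            "clonal_fraction", "lod_baf_phase", "relative_coverage")
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    stop("mCA call table missing column(s): ", paste(miss, collapse = ", "))
  }
  calls$chromosome <- normalize_chrom(calls$chromosome)
  calls
}

#' Read a somatic variant table
#'
#' Tab-separated with columns `sample_id`, `chromosome`, `position`,
#' `ref`, `alt`, `depth`, `vaf` and optionally `gene`. Rows that are not
#' single-nucleotide substitutions (indels, multi-nucleotide alleles,
#' non-ACGT codes) are rejected at parse time and counted in
#' `attr(, "n_rejected")`.
#'
#' @param path File path.
#' @return Data frame of single-nucleotide variants.
#' @export
read_variants <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(ref = "character",
                                        alt = "character"))
  need <- c("sample_id", "chromosome", "position", "ref", "alt",
            "depth", "vaf")
  miss <- setdiff(need, names(v))
  if (length(miss)) {
    stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  }
  bases <- c("A", "C", "G", "T")
  snv <- v$ref %in% bases & v$alt %in% bases & v$ref != v$alt
  out <- v[snv, , drop = FALSE]
  out$chromosome <- normalize_chrom(out$chromosome)
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(!snv)
  out
}

#' Read a sample table
#'
#' @param path File path to a TSV with at least `sample_id`,
#'   `age_at_draw`, `sex`.
#' @return Data frame.
#' @export
read_samples <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age_at_draw", "sex")
  miss <- setdiff(need, names(s))
  if (length(miss)) {
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  }
  s
}

#' Read a 0/1/2 genotype matrix
#'
#' @param path TSV with a `sample_id` column followed by one column per
#'   variant.
#' @return Numeric matrix with sample-id rownames.
#' @export
read_genotypes <- function(path) {
  g <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  stopifnot("sample_id" %in% names(g))
  m <- as.matrix(g[, setdiff(names(g), "sample_id"), drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- g$sample_id
  m
}

write_tsv <- function(df, path) {
  utils::write.table(format(as.data.frame(df), trim = TRUE, digits = 15,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Chains every stage end to end — simulate, quality-filter samples and
#' calls, define the single-mCA CHIP-free cohort, count clock-like
#' passengers, fit PACER scores (with the mCA-chromosome exclusion
#' variant), aggregate per-mCA fitness with fold changes versus loss of
#' X, and scan the genotype matrix — writing each stage's table to
#' `out_dir` as TSV. Runs are fully determined by the configuration's
#' seed: identical configurations produce byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  bundle <- simulate_cohort(config)
  write_cohort(bundle, file.path(out_dir, "cohort"), truth = TRUE)

  fs <- filter_samples(bundle$samples)
  fc <- filter_calls(bundle$calls)
  cd <- define_cohort(fc$retained, bundle$samples, bundle$chip_carriers,
                      include_sex_chromosomes = TRUE,
                      retained_samples = fs$retained)
  counts <- count_passengers(bundle$variants,
                             sample_ids = cd$cohort$sample_id)
  fit <- pacer(counts, bundle$samples, cd)
  fitness <- fold_change(aggregate_fitness(fit, cd,
                                           samples = bundle$samples))
  scan <- single_variant_scan(bundle$genotypes, counts, bundle$samples,
                              cd, variant_meta = bundle$variant_meta)

  write_tsv(fs$exclusions, file.path(out_dir, "sample_exclusions.tsv"))
  write_tsv(fc$exclusions, file.path(out_dir, "call_exclusions.tsv"))
  write_tsv(cd$cohort, file.path(out_dir, "cohort_definition.tsv"))
  write_tsv(cd$exclusions, file.path(out_dir, "cohort_exclusions.tsv"))
  write_tsv(as.data.frame(counts), file.path(out_dir, "passenger_counts.tsv"))
  write_tsv(fit$scores, file.path(out_dir, "pacer_scores.tsv"))
  write_tsv(as.data.frame(fitness), file.path(out_dir, "fitness.tsv"))
  write_tsv(scan, file.path(out_dir, "association_scan.tsv"))

  invisible(list(bundle = bundle, sample_filter = fs, call_filter = fc,
                 cohort = cd, counts = counts, fit = fit,
                 fitness = fitness, scan = scan))
}
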