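# Shared fixtures: run the full observable pipeline on a synthetic cohort.
# Results are cached per (seed, n, extra-args) within a test run so several
# test files can reuse the same cohort without re-simulating.
.cohort_cache <- new.env(parent = emptyenv())

make_cohort <- function(seed = 101, n = 600, ...) {
  key <- paste(seed, n, paste(deparse(list(...)), collapse = ""),
               sep = "|")
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cfg <- sim_config(n_individuals = n, seed = seed, ...)
  b <- simulate_cohort(cfg)
  fs <- filter_samples(b$samples)
  fc <- filter_calls(b$calls)
  cd <- define_cohort(fc$retained, b$samples, b$chip_carriers,
                      retained_samples = fs$retained)
  pc <- count_passengers(b$variants, sample_ids = cd$cohort$sample_id)
  fit <- pacer(pc, b$samples, cd)
  out <- list(config = cfg, bundle = b, sample_filter = fs,
              call_filter = fc, cohort = cd, counts = pc, fit = fit)
  .cohort_cache[[key]] <- out
  out
}

# the reference validation cohort used by scoring / acceptance tests
acceptance_cohort <- function() make_cohort(seed = 20260923, n = 6200)

random_call_table <- function(n, seed) {
  set.seed(seed)
  chroms <- names(chrom_lengths())
  chrom <- sample(chroms, n, replace = TRUE)
  size <- 10^runif(n, 5.5, 8.2)
  start <- pmax(1, floor(runif(n) * (chrom_lengths()[chrom] - size)))
  data.frame(sample_id = sprintf("R%04d", seq_len(n)),
             chromosome = chrom, start = start,
             end = pmin(start + size, chrom_lengths()[chrom]),
             copy_type = sample(c("gain", "loss", "cnloh"), n, TRUE),
             clonal_fraction = runif(n, 0.01, 1),
             lod_baf_phase = runif(n, 0, 60),
             relative_coverage = runif(n, 0.2, 3),
             stringsAsFactors = FALSE)
}

# minimal hand-built pacer object for association unit tests
fake_pacer <- function(scores, mca = NULL) {
  structure(list(scores = scores, mca = mca,
                 covariates = c("age", "female", "cf"),
                 dropped = data.frame()), class = "pacer")
}
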