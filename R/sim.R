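#' Configuration for the synthetic clonal-expansion cohort generator
#'
#' Builds a validated configuration object for [simulate_cohort()]. The
#' generator realizes the clonal dynamics that passenger-based expansion
#' rate estimation rests on: each individual acquires a single mCA driver
#' at a uniformly distributed age, the clone grows logistically at a
#' per-year fitness `s` within an effective stem-cell pool, pre-driver
#' ("ancestral") clock-like passenger mutations accrue in the founding
#' lineage at rate `passenger_rate_mu` per year with Gamma-Poisson
#' overdispersion, and a clone is observable only once its cell fraction
#' reaches `detection_limit_cf`. A common germline variant multiplies `s`
#' per alternate allele, so downstream genotype associations have a known
#' sign and magnitude.
#'
#' @param n_individuals Number of individuals to draw (before the
#'   detection-limit retention filter).
#' @param age_distribution Numeric vector `c(mean, sd, min, max)` in years
#'   for age at blood draw (truncated normal).
#' @param frac_female Proportion of females.
#' @param mca_types Data frame with columns `chromosome`, `arm`
#'   (`"p"`, `"q"` or `"whole"`), `copy_type` (`"gain"`, `"loss"`,
#'   `"cnloh"`), `s` (per-year fitness of the driver) and `weight`
#'   (prevalence weight, normalized internally).
#' @param passenger_rate_mu Expected detectable clock-like passengers per
#'   year of pre-driver lineage.
#' @param overdispersion_k Negative-binomial shape for passenger counts;
#'   `Inf` gives the Poisson limit.
#' @param n_hsc Median effective hematopoietic stem-cell population size.
#' @param n_hsc_sd_log Lognormal SD of the per-individual effective pool
#'   size around `n_hsc`. Effective HSC numbers vary by around an order
#'   of magnitude across people; this heterogeneity also keeps the
#'   observed clonal fraction from being a deterministic function of
#'   fitness and driver age.
#' @param detection_limit_cf Minimum cell fraction at which a clone (and
#'   its passengers) is reliably observed; see [sim_presets()] for the
#'   38x-WGS SNV-detectability preset.
#' @param mean_depth Mean sequencing depth for variant observations.
#' @param fitness_sd_log SD of lognormal individual-level variation
#'   multiplying the type-level fitness `s`.
#' @param modifier_maf Allele frequency of the germline expansion-rate
#'   modifier SNP.
#' @param modifier_effect Multiplicative per-allele effect on `s`
#'   (e.g. -0.35 means each alternate allele scales `s` by 0.65).
#' @param modifier_partner_r2 Target LD r-squared between the modifier SNP
#'   and an emitted non-causal partner SNP (for conditional analyses).
#' @param n_null_snps Number of additional no-effect SNPs in the genotype
#'   matrix.
#' @param blood_count_model List of baseline blood-count means/SDs and
#'   `ery_coupling`, the slope (10^12 cells/L per unit `s`) linking
#'   erythrocyte count to individual fitness deviation for carriers of
#'   chromosome 9p CN-LOH/loss clones.
#' @param mca_chrom_enrichment Fraction of each individual's passengers
#'   forced onto the mCA chromosome (0 = allocation proportional to
#'   chromosome length; an adversarial setting for sensitivity checks).
#' @param nonclock_ratio Expected non-clock-like somatic variants per
#'   expected clock-like passenger.
#' @param n_germline_mean Mean number of leaked germline heterozygous
#'   variants (VAF near 0.5) per individual.
#' @param n_chipvar_mean Mean number of CHIP-gene-annotated variant rows
#'   per individual (annotation noise for the passenger filter).
#' @param frac_chip Proportion of individuals carrying a CHIP driver
#'   mutation (listed in the bundle's `chip_carriers`).
#' @param frac_multi_mca Proportion of retained individuals given a second
#'   mCA call (exercises the multiple-mCA exclusion).
#' @param qc_fail_rate Proportion of samples/calls emitted with failing QC
#'   metrics (BAF autocorrelation, sex discordance, low lod_baf_phase).
#' @param misspec_frailty If `TRUE`, passenger overdispersion uses a
#'   lognormal frailty instead of Gamma-Poisson (model misspecification
#'   switch for robustness checks).
#' @param seed Integer RNG seed; identical configurations produce
#'   byte-identical cohorts.
#' @return An object of class `sim_config`.
#' @seealso [simulate_cohort()], [clone_cell_fraction()], [sim_presets()]
#' @export
sim_config <- function(n_individuals = 1000,
                       age_distribution = c(mean = 67, sd = 9, min = 40, max = 95),
                       frac_female = 0.57,
                       mca_types = default_mca_types(),
                       passenger_rate_mu = 2.0,
                       overdispersion_k = 10,
                       n_hsc = 1e4,
                       n_hsc_sd_log = 0.75,
                       detection_limit_cf = 0.05,
                       mean_depth = 38,
                       fitness_sd_log = 0.3,
                       modifier_maf = 0.21,
                       modifier_effect = -0.15,
                       modifier_partner_r2 = 0.8,
                       n_null_snps = 50,
                       blood_count_model = default_blood_count_model(),
                       mca_chrom_enrichment = 0,
                       nonclock_ratio = 0.45,
                       n_germline_mean = 6,
                       n_chipvar_mean = 1,
                       frac_chip = 0.03,
                       frac_multi_mca = 0.05,
                       qc_fail_rate = 0.02,
                       misspec_frailty = FALSE,
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              age_distribution = age_distribution,
              frac_female = frac_female, mca_types = mca_types,
              passenger_rate_mu = passenger_rate_mu,
              overdispersion_k = overdispersion_k, n_hsc = n_hsc,
              n_hsc_sd_log = n_hsc_sd_log,
              detection_limit_cf = detection_limit_cf,
              mean_depth = mean_depth, fitness_sd_log = fitness_sd_log,
              modifier_maf = modifier_maf, modifier_effect = modifier_effect,
              modifier_partner_r2 = modifier_partner_r2,
              n_null_snps = as.integer(n_null_snps),
              blood_count_model = blood_count_model,
              mca_chrom_enrichment = mca_chrom_enrichment,
              nonclock_ratio = nonclock_ratio,
              n_germline_mean = n_germline_mean,
              n_chipvar_mean = n_chipvar_mean,
              frac_chip = frac_chip, frac_multi_mca = frac_multi_mca,
              qc_fail_rate = qc_fail_rate,
              misspec_frailty = isTRUE(misspec_frailty),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Default mCA type palette for simulation
#'
#' Five driver lesions spanning the fitness range typically estimated for
#' blood mCAs (roughly 0.1-0.3 per year), anchored to lesions with known
#' lineage associations: loss of chromosome X (the low-fitness reference),
#' gain of chromosome 12 (lymphoid), CN-LOH of 9p (the JAK2-affecting
#' polycythemia vera lesion, assigned a mid-range fitness so its clones
#' populate the informative, non-saturated clonal-fraction range), loss
#' of 20q (myeloid), and CN-LOH of 11q.
#'
#' @return Data frame with columns chromosome, arm, copy_type, s, weight.
#' @export
default_mca_types <- function() {
  data.frame(
    chromosome = c("X", "12", "9", "20", "11"),
    arm = c("whole", "whole", "p", "q", "q"),
    copy_type = c("loss", "gain", "cnloh", "loss", "cnloh"),
    s = c(0.10, 0.15, 0.20, 0.25, 0.30),
    # mosaic X loss is the most prevalent lesion in real female cohorts;
    # the extra weight also stabilizes the fold-change reference group
    weight = c(0.3, 0.175, 0.175, 0.175, 0.175),
    stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_blood_count_model <- function() {
  list(ery_mean = 4.6, ery_sd = 0.35, ery_coupling = 2,
       lymph_mean = 1.9, lymph_sd = 0.5,
       neut_mean = 3.8, neut_sd = 1.0,
       baso_mean = 0.05, baso_sd = 0.02,
       eos_mean = 0.15, eos_sd = 0.08,
       mono_mean = 0.5, mono_sd = 0.15,
       plt_mean = 250, plt_sd = 60)
}

#' Named generator presets
#'
#' Fixed parameter presets used in validation studies: effect sizes for
#' the germline modifier SNP, erythrocyte-fitness coupling strengths for
#' chromosome 9p clones, and detection limits (`wgs_38x` encodes the
#' roughly 8-10 percent clonal-fraction SNV detectability of 38x whole
#' genome sequencing; the default is a more permissive 5 percent).
#'
#' @return Named list of named numeric vectors.
#' @export
sim_presets <- function() {
  list(modifier_effect = c(none = 0, default = -0.15, strong = -0.35),
       ery_coupling = c(none = 0, default = 2, strong = 8),
       detection_limit = c(default = 0.05, wgs_38x = 0.09))
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_individuals < 0) stop("n_individuals must be >= 0")
  ad <- cfg$age_distribution
  if (length(ad) != 4 || any(!is.finite(ad)) || ad[2] < 0 || ad[3] <= 0 ||
      ad[4] < ad[3]) {
    stop("age_distribution must be c(mean, sd, min, max) with 0 < min <= max")
  }
  if (cfg$frac_female < 0 || cfg$frac_female > 1) {
    stop("frac_female must lie in [0, 1]")
  }
  mt <- cfg$mca_types
  need <- c("chromosome", "arm", "copy_type", "s", "weight")
  if (!is.data.frame(mt) || !all(need %in% names(mt)) || nrow(mt) < 1) {
    stop("mca_types must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  mt$chromosome <- normalize_chrom(mt$chromosome)
  if (!all(mt$copy_type %in% c("gain", "loss", "cnloh"))) {
    stop("mca_types$copy_type must be gain, loss or cnloh")
  }
  if (!all(mt$arm %in% c("p", "q", "whole"))) {
    stop("mca_types$arm must be p, q or whole")
  }
  if (any(mt$s < 0) || any(mt$weight < 0) || sum(mt$weight) <= 0) {
    stop("mca_types fitness and weights must be nonnegative with positive sum")
  }
  mt$weight <- mt$weight / sum(mt$weight)
  cfg$mca_types <- mt
  for (f in c("passenger_rate_mu", "overdispersion_k", "n_hsc", "mean_depth",
              "fitness_sd_log", "modifier_maf", "nonclock_ratio",
              "n_germline_mean", "n_chipvar_mean")) {
    if (cfg[[f]] < 0) stop(f, " must be >= 0")
  }
  if (cfg$n_hsc < 1) stop("n_hsc must be >= 1")
  if (cfg$n_hsc_sd_log < 0) stop("n_hsc_sd_log must be >= 0")
  # exactly 1 is allowed as a degenerate setting: no clone is detectable
  if (cfg$detection_limit_cf <= 0 || cfg$detection_limit_cf > 1) {
    stop("detection_limit_cf must lie within (0, 1]")
  }
  if (cfg$modifier_effect <= -1) stop("modifier_effect must exceed -1")
  if (cfg$mca_chrom_enrichment < 0 || cfg$mca_chrom_enrichment >= 1) {
    stop("mca_chrom_enrichment must lie in [0, 1)")
  }
  cfg
}

#' Deterministic clone growth: cell fraction after dt years
#'
#' Logistic expansion of a single-cell clone with per-year fitness `s`
#' inside an effective stem-cell pool of size `n_hsc`:
#' `cf = exp(s * dt) / (n_hsc + exp(s * dt) - 1)`. The founder clone
#' occupies `1 / n_hsc` at `dt = 0`, grows exponentially while rare, and
#' saturates at 1.
#'
#' @param s Per-year fitness (>= 0).
#' @param dt Years since driver acquisition (>= 0).
#' @param n_hsc Effective stem-cell population size (>= 1).
#' @return Cell fraction in (0, 1]; strictly increasing in `s` and `dt`.
#' @examples
#' clone_cell_fraction(0.2, 40, 1e4)
#' @export
clone_cell_fraction <- function(s, dt, n_hsc) {
  if (any(s < 0)) stop("invalid simulation state: negative fitness s")
  if (any(dt < 0)) stop("invalid simulation state: negative time dt")
  if (any(n_hsc < 1)) stop("n_hsc must be >= 1")
  # stable form of exp(s*dt) / (n_hsc + exp(s*dt) - 1)
  1 / (1 + (n_hsc - 1) * exp(-s * dt))
}

# Restore the caller's RNG state after seeded simulation.
with_sim_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

clocklike_subs <- function() {
  data.frame(ref = c("C", "T", "G", "A"), alt = c("T", "C", "A", "G"),
             stringsAsFactors = FALSE)
}

nonclock_subs <- function() {
  all <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                     stringsAsFactors = FALSE)
  all <- all[all$ref != all$alt, ]
  cl <- paste(clocklike_subs()$ref, clocklike_subs()$alt)
  all[!(paste(all$ref, all$alt) %in% cl), ]
}

# Draw the latent per-individual state for n attempts (vectorized).
sim_draw_individuals <- function(cfg, n) {
  ad <- cfg$age_distribution
  age <- rnorm(n, ad[1], ad[2])
  age <- pmin(pmax(age, ad[3]), ad[4])
  mt <- cfg$mca_types
  type_idx <- sample.int(nrow(mt), n, replace = TRUE, prob = mt$weight)
  sex <- ifelse(runif(n) < cfg$frac_female, "female", "male")
  # sex-chromosome lesions are sex-restricted (mosaic X loss is a female
  # phenomenon, Y loss male)
  sex[mt$chromosome[type_idx] == "X"] <- "female"
  sex[mt$chromosome[type_idx] == "Y"] <- "male"
  g_mod <- rbinom(n, 2, cfg$modifier_maf)
  s_true <- mt$s[type_idx] * (1 + cfg$modifier_effect)^g_mod *
    exp(rnorm(n, 0, cfg$fitness_sd_log))
  t_driver <- runif(n, 0, age)
  n_hsc_i <- pmax(cfg$n_hsc * exp(rnorm(n, 0, cfg$n_hsc_sd_log)), 2)
  cf_true <- clone_cell_fraction(s_true, age - t_driver, n_hsc_i)
  mu_i <- cfg$passenger_rate_mu * t_driver
  if (cfg$misspec_frailty) {
    sdl <- sqrt(log(1 + 1 / cfg$overdispersion_k))
    frail <- exp(rnorm(n, -sdl^2 / 2, sdl))
    n_anc <- rpois(n, mu_i * frail)
  } else if (is.infinite(cfg$overdispersion_k)) {
    n_anc <- rpois(n, mu_i)
  } else {
    n_anc <- rnbinom(n, size = cfg$overdispersion_k, mu = mu_i)
  }
  data.frame(age = age, sex = sex, type_idx = type_idx, g_mod = g_mod,
             s_true = s_true, t_driver = t_driver, cf_true = cf_true,
             n_anc = n_anc, stringsAsFactors = FALSE)
}

#' Simulate a single individual
#'
#' Draws one individual from the generative model of [simulate_cohort()]
#' using the current RNG stream (no seed is set). Returns `NULL` when the
#' clone's cell fraction at blood draw falls below the detection limit
#' (the individual would not enter an mCA cohort).
#'
#' @param config A [sim_config()] object.
#' @return `NULL`, or a list with elements `truth`, `sample`, `calls`,
#'   `variants` and `genotypes` (one-row tables as in the cohort bundle).
#' @export
simulate_individual <- function(config) {
  config <- validate_sim_config(config)
  ind <- sim_draw_individuals(config, 1L)
  if (ind$cf_true < config$detection_limit_cf) return(NULL)
  assemble_cohort(config, ind, ids = "S00001")
}

#' Simulate a synthetic mCA cohort
#'
#' Generates `n_individuals` candidate individuals and retains those whose
#' clone reached the detection limit by the age at blood draw. Emits the
#' five observable tables the analysis pipeline consumes (sample
#' covariates with blood counts and QC fields, MoChA-style mCA calls,
#' a somatic variant table, a genotype matrix) together with a ground
#' truth table that no pipeline stage reads.
#'
#' Variant rows mix true ancestral passengers (clock-like substitutions
#' at VAF near `cf/2`), non-clock-like somatic variants, leaked germline
#' heterozygous variants at VAF near 0.5, and CHIP-gene-annotated rows,
#' so the passenger filter has genuine true and false positives to
#' separate. Depths are Poisson around `mean_depth` and VAFs binomial at
#' the clone's heterozygous fraction.
#'
#' @param config A [sim_config()] object; `config$seed` fixes all
#'   randomness, and identical configurations yield identical bundles.
#' @return An object of class `cohort_bundle`: a list with data frames
#'   `samples`, `calls`, `variants`, `genotypes`, `variant_meta`,
#'   `truth`, and `chip_carriers` (character vector of sample ids).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 50, seed = 42))
#' nrow(cohort$samples)
#' @export
simulate_cohort <- function(config) {
  config <- validate_sim_config(config)
  if (config$n_individuals == 0) {
    stop("empty cohort: n_individuals is 0")
  }
  with_sim_seed(config$seed, {
    ind <- sim_draw_individuals(config, config$n_individuals)
    keep <- ind$cf_true >= config$detection_limit_cf
    if (!any(keep)) {
      stop("empty cohort: no simulated clone reached detection_limit_cf = ",
           config$detection_limit_cf,
           "; lower the detection limit, raise fitness, or simulate more ",
           "individuals")
    }
    ind <- ind[keep, , drop = FALSE]
    ids <- sprintf("S%05d", seq_len(nrow(ind)))
    assemble_cohort(config, ind, ids)
  })
}

# Build all observable tables for the retained individuals. Consumes the
# RNG stream; callers manage seeding.
assemble_cohort <- function(cfg, ind, ids) {
  n <- nrow(ind)
  mt <- cfg$mca_types
  lens <- chrom_lengths()
  cens <- centromere_midpoints()

  ## ---- mCA calls -------------------------------------------------------
  chrom <- mt$chromosome[ind$type_idx]
  arm <- mt$arm[ind$type_idx]
  ctype <- mt$copy_type[ind$type_idx]
  start <- ifelse(arm == "q", cens[chrom], 1)
  end <- ifelse(arm == "p", cens[chrom], lens[chrom])
  rel_cov <- 2 + ifelse(ctype == "gain", ind$cf_true,
                        ifelse(ctype == "loss", -ind$cf_true, 0)) +
    rnorm(n, 0, 0.03)
  sexchrom <- chrom %in% c("X", "Y")
  lod <- ifelse(sexchrom, 6 + rexp(n, 1 / 15), 21 + rexp(n, 1 / 30))
  qc_fail_call <- runif(n) < cfg$qc_fail_rate
  lod[qc_fail_call] <- runif(sum(qc_fail_call), 0,
                             ifelse(sexchrom[qc_fail_call], 5, 20) * 0.95)
  calls <- data.frame(sample_id = ids, chromosome = chrom,
                      start = as.numeric(start), end = as.numeric(end),
                      copy_type = ctype,
                      clonal_fraction = ind$cf_true,
                      lod_baf_phase = lod, relative_coverage = rel_cov,
                      stringsAsFactors = FALSE)
  # secondary mCAs for a fraction of individuals (multiple-mCA exclusion)
  n_multi <- rbinom(1, n, cfg$frac_multi_mca)
  if (n_multi > 0) {
    who <- sample.int(n, n_multi)
    alt_chrom <- sample(as.character(1:22), n_multi, replace = TRUE)
    extra <- data.frame(sample_id = ids[who], chromosome = alt_chrom,
                        start = 1, end = as.numeric(lens[alt_chrom]),
                        copy_type = sample(c("gain", "loss", "cnloh"),
                                           n_multi, replace = TRUE),
                        clonal_fraction = runif(n_multi, 0.05, 0.3),
                        lod_baf_phase = 21 + rexp(n_multi, 1 / 30),
                        relative_coverage = 2 + rnorm(n_multi, 0, 0.03),
                        stringsAsFactors = FALSE)
    calls <- rbind(calls, extra)
  }
  calls <- calls[order(calls$sample_id, calls$chromosome, calls$start), ]
  rownames(calls) <- NULL

  ## ---- genotypes -------------------------------------------------------
  copy_prob <- sqrt(cfg$modifier_partner_r2)
  # split the modifier genotype into two haplotype alleles
  hap1 <- ifelse(ind$g_mod == 1, rbinom(n, 1, 0.5), ind$g_mod / 2)
  hap2 <- ind$g_mod - hap1
  partner_allele <- function(h) {
    ifelse(runif(n) < copy_prob, h, rbinom(n, 1, cfg$modifier_maf))
  }
  g_partner <- partner_allele(hap1) + partner_allele(hap2)
  null_maf <- runif(cfg$n_null_snps, 0.05, 0.5)
  g_null <- vapply(null_maf, function(p) rbinom(n, 2, p), numeric(n))
  if (cfg$n_null_snps == 0) g_null <- matrix(numeric(0), nrow = n)
  geno <- cbind(modifier = ind$g_mod, modifier_partner = g_partner, g_null)
  colnames(geno) <- c("rs_mod", "rs_mod_partner",
                      if (cfg$n_null_snps > 0)
                        sprintf("rs_null%04d", seq_len(cfg$n_null_snps)))
  rownames(geno) <- ids
  variant_meta <- data.frame(
    id = colnames(geno),
    chromosome = c("14", "14",
                   if (cfg$n_null_snps > 0)
                     sample(as.character(1:22), cfg$n_null_snps,
                            replace = TRUE)),
    position = c(95700000, 95710000,
                 if (cfg$n_null_snps > 0)
                   round(runif(cfg$n_null_snps, 1e6, 2e8))),
    af = colMeans(geno) / 2,
    stringsAsFactors = FALSE)

  ## ---- somatic variant table ------------------------------------------
  n_nonclock <- rpois(n, cfg$nonclock_ratio * cfg$passenger_rate_mu *
                        ind$t_driver)
  n_germ <- rpois(n, cfg$n_germline_mean)
  n_chipv <- rpois(n, cfg$n_chipvar_mean)
  chip_genes <- chip_gene_defaults()

  alloc_chrom <- function(total, mca_chrom) {
    # length-proportional allocation, optionally enriching the mCA chromosome
    if (total == 0) return(character(0))
    if (cfg$mca_chrom_enrichment > 0) {
      on_mca <- rbinom(1, total, cfg$mca_chrom_enrichment)
      rest <- sample(names(lens), total - on_mca, replace = TRUE,
                     prob = lens)
      c(rep(mca_chrom, on_mca), rest)
    } else {
      sample(names(lens), total, replace = TRUE, prob = lens)
    }
  }

  variant_block <- function(i, m, class) {
    if (m == 0) return(NULL)
    if (class == "passenger") {
      sub <- clocklike_subs()[sample.int(4, m, replace = TRUE), ]
      p_alt <- ind$cf_true[i] / 2
      gene <- rep("", m)
    } else if (class == "nonclock") {
      nc <- nonclock_subs()
      sub <- nc[sample.int(nrow(nc), m, replace = TRUE), ]
      p_alt <- ind$cf_true[i] / 2
      gene <- rep("", m)
    } else if (class == "germline") {
      allsub <- rbind(clocklike_subs(), nonclock_subs())
      sub <- allsub[sample.int(nrow(allsub), m, replace = TRUE), ]
      p_alt <- 0.5
      gene <- rep("", m)
    } else { # chip-annotated
      sub <- clocklike_subs()[sample.int(4, m, replace = TRUE), ]
      p_alt <- pmax(ind$cf_true[i] / 2, 0.02)
      gene <- sample(chip_genes, m, replace = TRUE)
    }
    chromv <- alloc_chrom(m, mt$chromosome[ind$type_idx[i]])
    depth <- rpois(m, cfg$mean_depth)
    vaf <- ifelse(depth > 0, rbinom(m, depth, p_alt) / pmax(depth, 1), 0)
    data.frame(sample_id = ids[i], chromosome = chromv,
               position = 1 + floor(runif(m) * (lens[chromv] - 1)),
               ref = sub$ref, alt = sub$alt, depth = depth, vaf = vaf,
               gene = gene, class = class, stringsAsFactors = FALSE)
  }

  blocks <- vector("list", 4L * n)
  for (i in seq_len(n)) {
    blocks[[4 * i - 3]] <- variant_block(i, ind$n_anc[i], "passenger")
    blocks[[4 * i - 2]] <- variant_block(i, n_nonclock[i], "nonclock")
    blocks[[4 * i - 1]] <- variant_block(i, n_germ[i], "germline")
    blocks[[4 * i]] <- variant_block(i, n_chipv[i], "chip")
  }
  variants <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  if (is.null(variants)) {
    variants <- data.frame(sample_id = character(0), chromosome = character(0),
                           position = numeric(0), ref = character(0),
                           alt = character(0), depth = integer(0),
                           vaf = numeric(0), gene = character(0),
                           class = character(0), stringsAsFactors = FALSE)
  }
  # de-duplicate coincidental position collisions
  key <- with(variants, paste(sample_id, chromosome, position, ref, alt))
  variants <- variants[!duplicated(key), ]
  rownames(variants) <- NULL
  # truth-side detectability, computed with generator-local arithmetic:
  # true passengers passing the depth/VAF windows, and separately every row
  # a default-configured passenger filter is expected to admit (including
  # germline clock-like leaks below 35% VAF — genuine false positives)
  in_windows <- variants$depth >= 25 & variants$depth <= 100 &
    variants$vaf <= 0.35
  det <- variants$class == "passenger" & in_windows
  looks_clock <- paste(variants$ref, variants$alt) %in%
    c("C T", "T C", "G A", "A G")
  filt <- looks_clock & in_windows & variants$gene == ""
  n_detect <- as.integer(table(factor(variants$sample_id[det], levels = ids)))
  n_filter <- as.integer(table(factor(variants$sample_id[filt], levels = ids)))
  # observable table carries no truth columns
  observed_variants <- variants[, setdiff(names(variants), "class")]

  ## ---- sample table ----------------------------------------------------
  bc <- cfg$blood_count_model
  is_9p <- mt$chromosome[ind$type_idx] == "9" &
    mt$arm[ind$type_idx] == "p" & ctype %in% c("cnloh", "loss")
  s_dev <- ind$s_true - mt$s[ind$type_idx]
  ery <- rnorm(n, bc$ery_mean, bc$ery_sd) +
    ifelse(is_9p, bc$ery_coupling * s_dev, 0)
  draw_pos <- function(mean, sd) pmax(rnorm(n, mean, sd), 0.001)
  samples <- data.frame(
    sample_id = ids, age_at_draw = ind$age, sex = ind$sex,
    study = sample(c("STUDY_A", "STUDY_B", "STUDY_C"), n, replace = TRUE),
    erythrocytes = pmax(ery, 0.5),
    lymphocytes = draw_pos(bc$lymph_mean, bc$lymph_sd),
    neutrophils = draw_pos(bc$neut_mean, bc$neut_sd),
    basophils = draw_pos(bc$baso_mean, bc$baso_sd),
    eosinophils = draw_pos(bc$eos_mean, bc$eos_sd),
    monocytes = draw_pos(bc$mono_mean, bc$mono_sd),
    platelets = draw_pos(bc$plt_mean, bc$plt_sd),
    reported_sex_concordant = runif(n) >= cfg$qc_fail_rate / 4,
    baf_autocorrelation = runif(n, 0, 0.045),
    stringsAsFactors = FALSE)
  qc_baf <- runif(n) < cfg$qc_fail_rate / 2
  samples$baf_autocorrelation[qc_baf] <- runif(sum(qc_baf), 0.051, 0.2)

  chip_carriers <- ids[runif(n) < cfg$frac_chip]

  truth <- data.frame(sample_id = ids, s_true = ind$s_true,
                      t_driver = ind$t_driver, cf_true = ind$cf_true,
                      n_ancestral_passengers = ind$n_anc,
                      n_detectable_passengers = n_detect,
                      n_filter_expected = n_filter,
                      modifier_genotype = ind$g_mod,
                      mca_chromosome = chrom, mca_arm = arm,
                      mca_copy_type = ctype,
                      stringsAsFactors = FALSE)

  structure(list(samples = samples, calls = calls,
                 variants = observed_variants,
                 genotypes = geno, variant_meta = variant_meta,
                 truth = truth, chip_carriers = chip_carriers,
                 config = cfg),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic mCA cohort bundle\n")
  cat(sprintf("  retained individuals : %d (of %d simulated)\n",
              nrow(x$samples), x$config$n_individuals))
  cat(sprintf("  mCA calls            : %d\n", nrow(x$calls)))
  cat(sprintf("  somatic variant rows : %d\n", nrow(x$variants)))
  cat(sprintf("  genotyped SNPs       : %d\n", ncol(x$genotypes)))
  cat(sprintf("  CHIP carriers        : %d\n", length(x$chip_carriers)))
  invisible(x)
}

#' Write a cohort bundle to TSV files
#'
#' Writes the observable tables (`samples.tsv`, `mca_calls.tsv`,
#' `variants.tsv`, `genotypes.tsv`, `variant_meta.tsv`,
#' `chip_carriers.txt`) and the ground truth separately as `truth.tsv`,
#' so pipeline stages can be pointed at a directory that simply omits the
#' truth file.
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param truth Write the ground-truth table too? Default `TRUE`.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(bundle, dir, truth = TRUE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.table(format(df, trim = TRUE, digits = 15,
                              scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  geno_df <- data.frame(sample_id = rownames(bundle$genotypes),
                        bundle$genotypes, check.names = FALSE,
                        stringsAsFactors = FALSE)
  files <- c(wr(bundle$samples, "samples.tsv"),
             wr(bundle$calls, "mca_calls.tsv"),
             wr(bundle$variants, "variants.tsv"),
             wr(geno_df, "genotypes.tsv"),
             wr(bundle$variant_meta, "variant_meta.tsv"))
  chip_path <- file.path(dir, "chip_carriers.txt")
  writeLines(bundle$chip_carriers, chip_path)
  files <- c(files, chip_path)
  if (truth) files <- c(files, wr(bundle$truth, "truth.tsv"))
  invisible(files)
}
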