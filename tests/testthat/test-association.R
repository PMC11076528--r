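test_that("myeloid cell count sums its four components", {
  s <- data.frame(neutrophils = c(3.0, 2.5, 0),
                  basophils = c(0.1, NA, 0),
                  eosinophils = c(0.2, 0.1, 0),
                  monocytes = c(0.5, 0.4, 0))
  m <- myeloid_sum(s)
  expect_equal(m[1], 3.8)
  expect_true(is.na(m[2]))
  expect_equal(m[3], 0)
  expect_equal(attr(m, "n_missing"), 1)
})

test_that("blood-count model is honest under a null outcome", {
  set.seed(21)
  covers <- replicate(20, {
    n <- 200
    ids <- sprintf("n%03d", 1:n)
    scores <- data.frame(sample_id = ids, raw_count = rpois(n, 40),
                         score = rnorm(n), stringsAsFactors = FALSE)
    mca <- data.frame(sample_id = ids, chromosome = "12", arm = "whole",
                      copy_type = "gain",
                      clonal_fraction = runif(n, 0.05, 0.6),
                      stringsAsFactors = FALSE)
    samples <- data.frame(sample_id = ids,
                          age_at_draw = runif(n, 50, 85),
                          sex = sample(c("female", "male"), n, TRUE),
                          lymphocytes = rnorm(n, 1.9, 0.5),
                          stringsAsFactors = FALSE)
    bm <- blood_count_model(fake_pacer(scores, mca), samples, "lymphoid")
    bm$score_ci[1] <= 0 & bm$score_ci[2] >= 0
  })
  expect_gte(mean(covers), 0.9)
})

test_that("the chr9p erythrocyte coupling is detected at the strong preset", {
  bc <- default_blood_count_model()
  bc$ery_coupling <- unname(sim_presets()$ery_coupling["strong"])
  hits <- vapply(1:10, function(s) {
    co <- make_cohort(seed = 5000 + s, n = 800, blood_count_model = bc)
    bm <- blood_count_model(co$fit, co$bundle$samples, "pv")
    bm$score_p < 0.05 && bm$score_beta > 0
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("the pv model omits clonal fraction; others keep it", {
  co <- make_cohort(seed = 101, n = 400)
  bm_pv <- blood_count_model(co$fit, co$bundle$samples, "pv")
  expect_false("clonal_fraction" %in% bm_pv$coefficients$term)
  bm_my <- blood_count_model(co$fit, co$bundle$samples, "myeloid")
  expect_true("clonal_fraction" %in% bm_my$coefficients$term)
  expect_equal(bm_my$outcome, "myeloid_cells")
  # duplicated sample rows are rejected
  dup <- rbind(co$bundle$samples, co$bundle$samples[1, ])
  expect_error(blood_count_model(co$fit, dup, "pv"), "non-unique")
})

test_that("variant scan filters by MAF, skips constants, flips sign with coding", {
  co <- make_cohort(seed = 101, n = 400)
  g <- co$bundle$genotypes
  rare <- integer(nrow(g)); rare[1] <- 1L   # single carrier: MAF well below 1%
  flip <- 2 - g[, "rs_null0001"]
  g2 <- cbind(g, rs_rare = rare, rs_const = 0, rs_flip = flip)
  res <- single_variant_scan(g2, co$counts, co$bundle$samples, co$cohort)
  expect_false("rs_rare" %in% res$id)
  expect_false("rs_const" %in% res$id)
  sk <- attr(res, "skipped")
  expect_true("rs_const" %in% sk$id[sk$reason == "constant_genotype"])
  expect_true("rs_rare" %in% sk$id[sk$reason == "maf_filter"])
  b1 <- res$beta[res$id == "rs_null0001"]
  b2 <- res$beta[res$id == "rs_flip"]
  expect_equal(b1, -b2, tolerance = 1e-10)
})

test_that("conditioning on an all-zero covariate reproduces the marginal test", {
  co <- make_cohort(seed = 101, n = 400)
  g <- cbind(co$bundle$genotypes, rs_zero = 0L)
  marg <- single_variant_scan(g[, "rs_mod", drop = FALSE], co$counts,
                              co$bundle$samples, co$cohort, maf_min = 0)
  ct <- conditional_test("rs_mod", "rs_zero", g, co$counts,
                         co$bundle$samples, co$cohort)
  expect_equal(ct$conditional$beta, marg$beta, tolerance = 1e-10)
  expect_equal(ct$conditional$p, marg$p, tolerance = 1e-8)
})

test_that("perfectly correlated lead and conditioned variants are flagged", {
  co <- make_cohort(seed = 101, n = 400)
  g <- co$bundle$genotypes
  g <- cbind(g, rs_copy = g[, "rs_mod"])
  ct <- conditional_test("rs_mod", "rs_copy", g, co$counts,
                         co$bundle$samples, co$cohort)
  expect_true(ct$collinear)
  expect_true(is.na(ct$conditional$beta))
})

test_that("an independent conditioned variant leaves the lead effect intact", {
  set.seed(22)
  ok <- replicate(10, {
    co <- make_cohort(seed = 6000 + sample.int(1e6, 1), n = 500,
                      modifier_effect = -0.35, n_null_snps = 2)
    ct <- conditional_test("rs_mod", "rs_null0001",
                           co$bundle$genotypes, co$counts,
                           co$bundle$samples, co$cohort)
    abs(ct$conditional$beta - ct$marginal$beta) <
      2 * sqrt(ct$conditional$se^2 + ct$marginal$se^2)
  })
  expect_gte(mean(ok), 0.9)
})

test_that("a mediated signal attenuates under conditioning on the causal SNP", {
  atten <- vapply(1:10, function(s) {
    co <- make_cohort(seed = 7000 + s, n = 2000, modifier_effect = -0.35,
                      n_null_snps = 2)
    # rs_mod is causal; rs_mod_partner tags it at LD r2 ~ 0.8.
    # conditioning the partner's signal on the causal variant should
    # remove it.
    ct <- conditional_test("rs_mod_partner", "rs_mod",
                           co$bundle$genotypes, co$counts,
                           co$bundle$samples, co$cohort)
    ct$conditional$p > ct$marginal$p
  }, logical(1))
  expect_gte(mean(atten), 0.9)
})

test_that("composite LD r2 behaves like a squared correlation", {
  set.seed(23)
  g <- cbind(a = rbinom(10000, 2, 0.3), b = rbinom(10000, 2, 0.3),
             c = 1L)
  g <- cbind(g, d = g[, "a"])
  rownames(g) <- sprintf("z%05d", 1:10000)
  expect_equal(ld_r2(g, "a", "d"), 1)
  expect_lt(ld_r2(g, "a", "b"), 0.01)
  expect_error(ld_r2(g, "a", "c"), "constant genotype")
})
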