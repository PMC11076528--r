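toy_scores <- function(vals, ids = sprintf("t%02d", seq_along(vals))) {
  data.frame(sample_id = ids, raw_count = 10, score = vals,
             stringsAsFactors = FALSE)
}

toy_cohort <- function(ids, chromosome, arm, copy_type, cf = 0.2) {
  data.frame(sample_id = ids, chromosome = chromosome, arm = arm,
             copy_type = copy_type, clonal_fraction = cf,
             is_loss_of_x = chromosome == "X" & copy_type == "loss",
             stringsAsFactors = FALSE)
}

test_that("group fitness is the median score and ordering is by fitness", {
  sc <- toy_scores(c(-1, 0, 2, 0.5))
  co <- toy_cohort(sc$sample_id, c("12", "12", "12", "5"),
                   c("whole", "whole", "whole", "q"),
                   c("gain", "gain", "gain", "loss"))
  ft <- aggregate_fitness(sc, co)
  g12 <- ft[ft$chromosome == "12", ]
  expect_equal(g12$fitness, 0)
  expect_equal(g12$n, 3)
  g5 <- ft[ft$chromosome == "5", ]
  expect_equal(g5$fitness, 0.5)   # single-member group
  expect_equal(g5$n, 1)
  expect_equal(ft$fitness, sort(ft$fitness, decreasing = TRUE))
})

test_that("aggregation ignores within-group sample order", {
  co <- make_cohort(seed = 101, n = 400)
  ft1 <- aggregate_fitness(co$fit, co$cohort, samples = co$bundle$samples)
  perm <- sample(nrow(co$fit$scores))
  ft2 <- aggregate_fitness(co$fit$scores[perm, ], co$cohort,
                           samples = co$bundle$samples)
  expect_equal(ft1$fitness, ft2$fitness)
  expect_equal(ft1$n, ft2$n)
})

test_that("fold change is anchored at loss of X and scale-equivariant", {
  sc <- toy_scores(c(0.4, 0.4, 0.2, 0.2))
  co <- toy_cohort(sc$sample_id, c("1", "1", "X", "X"),
                   c("whole", "whole", "whole", "whole"),
                   c("gain", "gain", "loss", "loss"))
  ft <- fold_change(aggregate_fitness(sc, co))
  ref <- ft$chromosome == "X"
  expect_identical(ft$fold_change_vs_xloss[ref], 1)
  expect_equal(ft$fold_change_vs_xloss[!ref], 2)
  expect_false(any(ft$sign_warning))
  # scale equivariance: c * fitness leaves fold changes unchanged
  ft_scaled <- ft
  ft_scaled$fitness <- 3 * ft_scaled$fitness
  expect_equal(fold_change(ft_scaled)$fold_change_vs_xloss,
               ft$fold_change_vs_xloss)
  # negative reference flags every row but still computes
  sc2 <- toy_scores(c(0.4, 0.4, -0.2, -0.2))
  ft2 <- fold_change(aggregate_fitness(sc2, co))
  expect_true(all(ft2$sign_warning))
  expect_equal(ft2$fold_change_vs_xloss[ft2$chromosome == "1"], -2)
  # missing reference names the needed key
  sc3 <- toy_scores(c(0.4, 0.3))
  co3 <- toy_cohort(sc3$sample_id, c("1", "2"), "whole", "gain")
  expect_error(fold_change(aggregate_fitness(sc3, co3)), "loss-of-X")
})

test_that("external-fitness comparison filters groups and reports R2", {
  mk_table <- function(n_groups, n_each, fitness, external) {
    ft <- data.frame(chromosome = as.character(seq_len(n_groups)),
                     arm = "whole", copy_type = "gain", n = n_each,
                     fitness = fitness, median_age = runif(n_groups, 60, 75),
                     median_cf = runif(n_groups, 0.1, 0.5),
                     median_count = 40 + fitness * 10,
                     stringsAsFactors = FALSE)
    ext <- data.frame(chromosome = ft$chromosome, arm = "whole",
                      copy_type = "gain", fitness_external = external,
                      stringsAsFactors = FALSE)
    list(ft = ft, ext = ext)
  }
  set.seed(11)
  f <- rnorm(10)
  # exact affine relation: R2 = 1
  d <- mk_table(10, 60, f, 2 * f + 1)
  res <- suppressWarnings(compare_external(d$ft, d$ext))
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_equal(res$n_groups, 10)
  # the n > 25 filter: 3 of 10 groups at or below 25 leaves 7
  d2 <- mk_table(10, c(rep(60, 7), 25, 10, 2), f, 2 * f + 1)
  expect_equal(suppressWarnings(compare_external(d2$ft, d2$ext))$n_groups, 7)
  # too few overlapping groups is an explicit error
  d3 <- mk_table(4, 60, rnorm(4), rnorm(4))
  expect_error(compare_external(d3$ft, d3$ext), "insufficient")
})

test_that("independent external noise yields honest null inference", {
  set.seed(12)
  covers <- replicate(20, {
    f <- rnorm(100)
    ft <- data.frame(chromosome = as.character(1:100), arm = "whole",
                     copy_type = "gain", n = 60, fitness = f,
                     median_age = runif(100, 60, 75),
                     median_cf = runif(100, 0.1, 0.5),
                     median_count = rpois(100, 40),
                     stringsAsFactors = FALSE)
    ext <- data.frame(chromosome = ft$chromosome, arm = "whole",
                      copy_type = "gain", fitness_external = rnorm(100),
                      stringsAsFactors = FALSE)
    res <- compare_external(ft, ext)
    ci <- res$coefficients[res$coefficients$term == "fitness", ]
    c(res$r_squared, ci$ci_low <= 0 & ci$ci_high >= 0)
  })
  expect_lt(mean(covers[1, ]), 0.15)      # R2 stays small
  expect_gte(mean(covers[2, ]), 0.9)      # slope CI covers zero
})

test_that("curated malignancy sets classify exactly as defined", {
  # full round trip over every curated entry
  cls <- malignancy_classes()
  for (grp in c("lymphoid", "myeloid", "pv")) {
    spec <- cls[[grp]]
    for (i in seq_len(nrow(spec))) {
      arm <- if (spec$arm[i] == "any") "whole" else spec$arm[i]
      amb <- if (grp %in% c("lymphoid", "myeloid")) grp else "lymphoid"
      got <- classify_mca(spec$chromosome[i], arm, spec$copy_type[i],
                          ambiguous = amb)
      expect_equal(got, grp,
                   label = paste(grp, spec$chromosome[i], arm,
                                 spec$copy_type[i]))
    }
  }
  expect_equal(classify_mca("12", "whole", "gain"), "lymphoid")
  expect_equal(classify_mca("12", "p", "gain"), "lymphoid")  # any arm
  expect_equal(classify_mca("20", "q", "loss"), "myeloid")
  expect_equal(classify_mca("9", "p", "cnloh"), "pv")
  expect_equal(classify_mca("9", "p", "loss"), "pv")
  expect_equal(classify_mca("7", "q", "gain"), "neither")
  # whole-chromosome events match arm-level entries
  expect_equal(classify_mca("13", "whole", "cnloh"), "lymphoid")
  expect_equal(classify_mca("20", "whole", "loss"), "myeloid")
  # the 9q CN-LOH overlap between curated sets is resolved explicitly
  expect_equal(classify_mca("9", "q", "cnloh"), "lymphoid")
  expect_equal(classify_mca("9", "q", "cnloh", ambiguous = "myeloid"),
               "myeloid")
  expect_equal(classify_mca("9", "q", "cnloh", ambiguous = "both"), "both")
})

test_that("class contrast is calibrated under the null and powered under shift", {
  run_anova <- function(shift, seed) {
    set.seed(seed)
    n <- 50
    sc <- toy_scores(c(rnorm(n, shift), rnorm(n), rnorm(n)),
                     ids = sprintf("u%03d", 1:(3 * n)))
    co <- toy_cohort(sc$sample_id,
                     rep(c("12", "20", "7"), each = n),
                     rep(c("whole", "q", "q"), each = n),
                     rep(c("gain", "loss", "gain"), each = n))
    class_contrast(sc, co)$p
  }
  null_p <- vapply(1:200, function(s) run_anova(0, s), numeric(1))
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.04)
  ks <- suppressWarnings(ks.test(null_p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
  shift_p <- vapply(1:200, function(s) run_anova(0.5, 1000 + s),
                    numeric(1))
  expect_gt(mean(shift_p < 0.05), 0.5)
  # degenerate within-group variance is an explicit error
  sc0 <- toy_scores(rep(c(1, 2), each = 3))
  co0 <- toy_cohort(sc0$sample_id, rep(c("12", "20"), each = 3),
                    rep(c("whole", "q"), each = 3),
                    rep(c("gain", "loss"), each = 3))
  expect_error(class_contrast(sc0, co0), "zero within-group variance")
})
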