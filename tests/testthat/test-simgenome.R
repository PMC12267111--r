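test_that("pedigree validation rejects undefined parents and bad orders", {
  expect_error(pedigree_spec("f1",
                             data.frame(parent_a = "f1", parent_b = "ghost",
                                        child = "c1"),
                             "c1"),
               "undefined parent")
  expect_error(pedigree_spec(c("f1", "f2"),
                             data.frame(parent_a = "f1", parent_b = "f2",
                                        child = "f1"),
                             "f1"),
               "redefined")
  expect_error(pedigree_spec(c("f1", "f2"), NULL, "nobody"),
               "not in pedigree")
})

test_that("config invariants are enforced", {
  ped <- first_cousin_pedigree()
  expect_error(sim_config(ped, impact_fractions = c(HIGH = 0.5, MODERATE = 0.2,
                                                    LOW = 0.2, NONE = 0.2)),
               "sum to 1")
  expect_error(sim_config(ped, founder_het = 0.7), "no diallelic solution")
  expect_warning(sim_config(ped, scaffold_length_bp = 5e5), "1 Mb")
})

test_that("unrelated founders leave no truth tracts", {
  ped <- pedigree_spec(c("f1", "f2", "f3", "f4"),
                       data.frame(parent_a = c("f1", "f3"),
                                  parent_b = c("f2", "f4"),
                                  child = c("c1", "c2")),
                       focal_samples = c("c1", "c2"))
  sim <- simulate_pedigree_genomes(
    sim_config(ped, n_scaffolds = 2, scaffold_length_bp = 2e6, seed = 11))
  expect_equal(nrow(sim$truth), 0)
})

test_that("same seed reproduces the simulation exactly", {
  cfg <- small_cohort_config(seed = 5, n_scaffolds = 2,
                             scaffold_length_bp = 3e6,
                             genotype_error_rate = 0.01, missing_rate = 0.02)
  a <- simulate_pedigree_genomes(cfg)
  b <- simulate_pedigree_genomes(cfg)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$truth, b$truth)
  expect_identical(a$variants, b$variants)
  expect_identical(a$genotypes$gq, b$genotypes$gq)
})

test_that("every site inside a truth tract is homozygous when error-free", {
  sim <- simulate_pedigree_genomes(
    small_cohort_config(seed = 11, n_scaffolds = 4, scaffold_length_bp = 20e6))
  gt <- sim$genotypes
  expect_gt(nrow(sim$truth), 0)
  n_inside <- 0L
  n_het_inside <- 0L
  for (id in unique(sim$truth$sample)) {
    tr <- sim$truth[sim$truth$sample == id, ]
    g <- sample_calls(gt, id)
    inside <- rep(FALSE, nrow(gt$sites))
    for (i in seq_len(nrow(tr))) {
      inside <- inside | (gt$sites$scaffold == tr$scaffold[i] &
                            gt$sites$pos >= tr$start_bp[i] &
                            gt$sites$pos <= tr$end_bp[i])
    }
    n_inside <- n_inside + sum(inside)
    n_het_inside <- n_het_inside + sum(g[inside] == 1L, na.rm = TRUE)
  }
  expect_gt(n_inside, 0)
  expect_equal(n_het_inside, 0L)
})

test_that("truth tracts are non-overlapping and ordered per sample/scaffold", {
  sim <- simulate_pedigree_genomes(
    small_cohort_config(seed = 13, n_scaffolds = 4, scaffold_length_bp = 20e6))
  tr <- sim$truth
  expect_gt(nrow(tr), 0)
  violations <- 0L
  for (key in split(tr, paste(tr$sample, tr$scaffold))) {
    key <- key[order(key$start_bp), ]
    violations <- violations + sum(key$start_bp > key$end_bp)
    if (nrow(key) > 1)
      violations <- violations +
        sum(key$start_bp[-1] <= key$end_bp[-nrow(key)])
  }
  expect_equal(violations, 0L)
})

test_that("mean truth autozygosity matches the pedigree F from gene dropping", {
  ped <- first_cousin_pedigree()
  set.seed(123)
  f_oracle <- oracle_gene_drop_f(ped, "cousin_child", n_rep = 40000)
  expect_equal(f_oracle, 1 / 16, tolerance = 0.1)  # MC check of the 0.0625

  fracs <- vapply(1:12, function(s) {
    sim <- simulate_pedigree_genomes(
      sim_config(ped, n_scaffolds = 8, scaffold_length_bp = 50e6,
                 snp_density = 1 / 5000, seed = 100 + s))
    truth_fraction(sim$truth, sim$scaffold_lengths, "cousin_child")
  }, numeric(1))
  expect_equal(mean(fracs), 1 / 16, tolerance = 0.35)
  expect_equal(mean(fracs), f_oracle, tolerance = 0.35)
})

test_that("impact fractions are respected at large site counts", {
  frac <- c(HIGH = 0.01, MODERATE = 0.04, LOW = 0.05, NONE = 0.90)
  sim <- simulate_pedigree_genomes(
    sim_config(first_cousin_pedigree(), n_scaffolds = 2,
               scaffold_length_bp = 80e6, snp_density = 1 / 1000,
               impact_fractions = frac, seed = 3))
  n <- nrow(sim$variants)
  expect_gt(n, 1e5)
  obs <- table(factor(sim$variants$impact, levels = names(frac)))
  for (cls in names(frac)) {
    ci <- qbinom(c(0.005, 0.995), n, frac[[cls]])
    expect_gte(obs[[cls]], ci[1])
    expect_lte(obs[[cls]], ci[2])
  }
})

test_that("founder heterozygosity is recovered in a non-inbred child", {
  sim <- simulate_pedigree_genomes(
    sim_config(pedigree_spec(c("f1", "f2"),
                             data.frame(parent_a = "f1", parent_b = "f2",
                                        child = "c1"),
                             "c1"),
               n_scaffolds = 2, scaffold_length_bp = 30e6,
               founder_het = 0.3, seed = 21))
  g <- sample_calls(sim$genotypes, "c1")
  expect_equal(mean(g == 1L), 0.3, tolerance = 0.01)
})

test_that("outgroup carries the ancestral (reference) allele at every site", {
  sim <- simulate_pedigree_genomes(
    small_cohort_config(seed = 2, n_scaffolds = 2, scaffold_length_bp = 2e6))
  expect_identical(sim$outgroup$allele, sim$variants$ancestral)
  expect_identical(sim$variants$ancestral, sim$variants$ref)
  expect_identical(sim$variants$derived, sim$variants$alt)
})

test_that("simulate_lambda follows the reciprocal N_E scaling", {
  traj <- simulate_lambda(data.frame(0, 1e6, 5e4), mu = 1e-8,
                          boundaries = seq(0, 2800, 100))
  expect_s3_class(traj, "lambda_trajectory")
  expect_equal(nrow(traj), 28)
  expect_true(all(traj$lambda == 1000))

  traj2 <- simulate_lambda(data.frame(0, 1e6, 1e5), mu = 1e-8,
                           boundaries = seq(0, 2800, 100))
  expect_true(all(traj2$lambda == traj$lambda / 2))  # N_E doubled

  expect_error(simulate_lambda(data.frame(0, 100, -5), 1e-8, c(0, 50, 100)),
               "positive")
  expect_error(simulate_lambda(data.frame(0, 10, 1e4), 1e-8, c(0, 50, 100)),
               "cover")
})
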