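test_that("variant status follows the de novo / depleted / in-common definitions", {
  expect_equal(classify_variant_status(obs(0, 25), obs(8, 40), "missense"),
               "de_novo")
  expect_equal(classify_variant_status(obs(6, 25), obs(0, 22), "missense"),
               "completely_depleted")
  # parental coverage < 20 cannot certify absence
  expect_equal(classify_variant_status(obs(0, 15), obs(8, 40), "missense"),
               "undetermined")
  expect_equal(classify_variant_status(obs(3, 30), obs(5, 30), "missense"),
               "in_common")
  # one read with 20-fold coverage suffices for the in-common branch
  expect_equal(classify_variant_status(obs(1, 20), obs(1, 20), "missense"),
               "in_common")
  # frameshift: presence needs no depth, absence still needs 20x
  expect_equal(classify_variant_status(obs(0, 25), obs(2, 8), "frameshift"),
               "de_novo")
  expect_equal(classify_variant_status(obs(0, 15), obs(2, 8), "frameshift"),
               "undetermined")
  # missing observations are never evidence
  expect_equal(classify_variant_status(NULL, obs(8, 40), "missense"),
               "undetermined")
  expect_equal(classify_variant_status(obs(6, 25), NULL, "missense"),
               "undetermined")
})

test_that("fisher_af_shift matches hypergeometric enumeration and reports delta AF", {
  same <- fisher_af_shift(obs(10, 20), obs(10, 20))
  expect_equal(same$p, 1)
  expect_equal(same$delta_af, 0)

  shift <- fisher_af_shift(obs(2, 20), obs(12, 20))
  expect_equal(shift$p, fisher_oracle(2, 18, 12, 8), tolerance = 1e-10)
  expect_equal(shift$delta_af, 0.5)

  expect_error(fisher_af_shift(obs(0, 25), obs(5, 30)),
               class = "pdxresist_contract_error")
  expect_error(fisher_af_shift(obs(3, 15), obs(5, 30)),
               class = "pdxresist_contract_error")
})

test_that("two-sided Fisher p equals full enumeration across random tables (margins <= 30)", {
  set.seed(101)
  for (i in 1:250) {
    n1 <- sample(20:30, 1)
    n2 <- sample(20:30, 1)
    a1 <- sample(1:n1, 1)
    a2 <- sample(1:n2, 1)
    got <- fisher_af_shift(obs(a1, n1), obs(a2, n2))$p
    want <- fisher_oracle(a1, n1 - a1, a2, n2 - a2)
    expect_equal(got, want, tolerance = 1e-09)
  }
})

test_that("BH adjustment equals the step-up definition and validates input", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "pdxresist_validation_error")
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p & q <= 1))
  }
})

test_that("cohort classification resolves the in-common branch with FDR and the 10% rule", {
  roles <- sample_roles("GL", "PAR", c(cisplatin = "CIS"))
  # strong planted enrichment: AF 0.05 -> 0.30 at 200x, sole test
  enr <- toy_table(list(GL = c(0, 200), PAR = c(10, 200), CIS = c(60, 200)),
                   roles = roles)
  rec <- classify_cohort(apply_exclusion_filters(enr))
  expect_equal(rec$status, "enriched")
  expect_equal(rec$delta_af, 0.25)
  expect_equal(rec$fdr_q, rec$fisher_p)  # single-test BH identity
  expect_lt(rec$fdr_q, 0.05)

  # significant but sub-10% shift stays common_unchanged
  sub <- toy_table(list(GL = c(0, 2000), PAR = c(100, 2000), CIS = c(200, 2000)),
                   roles = roles)
  rec2 <- classify_cohort(apply_exclusion_filters(sub))
  expect_lt(rec2$fdr_q, 0.05)
  expect_equal(rec2$delta_af, 0.05)
  expect_equal(rec2$status, "common_unchanged")

  # arm with no common-branch variants yields no Fisher results
  dn <- toy_table(list(GL = c(0, 30), PAR = c(0, 25), CIS = c(8, 40)),
                  roles = roles)
  rec3 <- classify_cohort(apply_exclusion_filters(dn))
  expect_equal(rec3$status, "de_novo")
  expect_true(is.na(rec3$fisher_p))
})

test_that("every (somatic variant, arm) pair receives exactly one status", {
  sim <- simulate_variant_cohort(simulation_config(seed = 21))
  som <- apply_exclusion_filters(sim$table)
  rec <- classify_cohort(som)
  expect_equal(nrow(rec), nrow(som$variants) * 4)
  expect_equal(anyDuplicated(rec[, c("variant_id", "arm")]), 0)
  expect_true(all(rec$status %in% c("de_novo", "completely_depleted", "enriched",
                                    "partially_depleted", "common_unchanged",
                                    "undetermined")))
  # fisher p defined exactly on the common branch
  common <- rec$status %in% c("enriched", "partially_depleted", "common_unchanged")
  expect_true(all(!is.na(rec$fisher_p[common])))
  expect_true(all(is.na(rec$fisher_p[!common])))
  # the 10% rule holds for every called shift
  shifted <- rec[rec$status %in% c("enriched", "partially_depleted"), ]
  expect_true(all(abs(shifted$delta_af) >= 0.10))
})

test_that("noise-free planted cohorts are recovered without error", {
  sim <- simulate_variant_cohort(simulation_config(seed = 9, noise_free = TRUE))
  rec <- classify_cohort(apply_exclusion_filters(sim$table))
  joined <- dplyr::inner_join(rec, sim$truth, by = "variant_id")
  expect_true(all(joined$status == joined$category))
})

enrichment_recovery <- function(coverage, adapted_af, seed, n = 120) {
  cfg <- simulation_config(
    seed = seed, mean_coverage = coverage,
    n_variants = c(enriched = n),
    category_afs = list(enriched = c(parental = 0.05, adapted = adapted_af)),
    arms = "cisplatin")
  sim <- simulate_variant_cohort(cfg)
  rec <- classify_cohort(apply_exclusion_filters(sim$table))
  mean(rec$status == "enriched")
}

test_that("enrichment detection power rises with coverage and planted AF shift", {
  by_cov <- vapply(c(30, 100, 300), enrichment_recovery,
                   numeric(1), adapted_af = 0.30, seed = 5)
  expect_true(all(diff(by_cov) >= 0))
  expect_gt(by_cov[3], 0.8)

  by_shift <- vapply(c(0.15, 0.30, 0.55), enrichment_recovery,
                     numeric(1), coverage = 100, seed = 6)
  expect_true(all(diff(by_shift) >= 0))
})

test_that("null cohorts produce few false enrichment/depletion labels at FDR 5%", {
  rates <- vapply(1:4, function(s) {
    cfg <- simulation_config(
      seed = s, n_variants = c(common_unchanged = 250),
      category_afs = list(common_unchanged = c(parental = 0.3, adapted = 0.3)),
      arms = "cisplatin")
    sim <- simulate_variant_cohort(cfg)
    rec <- classify_cohort(apply_exclusion_filters(sim$table))
    common <- rec[!is.na(rec$fdr_q), ]
    mean(common$status %in% c("enriched", "partially_depleted"))
  }, numeric(1))
  expect_lt(mean(rates), 0.05 + 0.03)
})

test_that("overlap summary counts arm specificity and pools depleted categories", {
  rec4 <- function(vid, arms, status) {
    tibble::tibble(variant_id = vid, gene = vid, consequence = "missense",
                   arm = arms, status = status,
                   parental_af = NA_real_, adapted_af = NA_real_,
                   delta_af = NA_real_, fisher_p = NA_real_, fdr_q = NA_real_)
  }
  arms <- c("a1", "a2", "a3", "a4")
  # one variant de novo in all four arms
  full <- summarize_overlap(rec4("v1", arms, "de_novo"))
  m <- full$arm_multiplicity
  expect_equal(m$n_variants[m$status == "de_novo" & m$n_arms_with == 4], 1)
  expect_equal(full$shared_all$de_novo, "v1")

  # four disjoint de novo variants, one per arm
  disj <- summarize_overlap(rec4(paste0("v", 1:4), arms, "de_novo"))
  m <- disj$arm_multiplicity
  expect_equal(m$n_variants[m$status == "de_novo" & m$n_arms_with == 1], 4)
  expect_equal(length(disj$shared_all$de_novo), 0)

  # completely depleted in one arm, partially in another: pooled once
  mixed <- summarize_overlap(dplyr::bind_rows(
    rec4("v9", "a1", "completely_depleted"),
    rec4("v9", "a2", "partially_depleted")))
  m <- mixed$arm_multiplicity
  expect_equal(m$n_variants[m$status == "depleted" & m$n_arms_with == 2], 1)
})
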