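# A gei_data bundle with one planted interaction (G1 x protein high) and
# noise genes, built once per test via a seed.
planted_gei_data <- function(n_cases = 747, n_controls = 956, seed = 1,
                             or_int = 2.5, genes = c("G1", "G2", "G3", "G4")) {
  panel <- tiny_panel(genes, n_snps = 1, maf = 0.4)
  pe <- planted_effect("G1", logic_leaf("G1_rs1_dom"), "protein", "high",
                       log_or = log(or_int), log_hr = log(or_int),
                       log_or_main = 0.2)
  d <- simulation_design(n_cases = n_cases, n_controls = n_controls,
                         panel = panel, planted_effects = list(pe),
                         intercept = -0.3, seed = seed)
  st <- simulate_study(d)
  gcols <- st$indicators[, paste0(genes, "_rs1_dom"), drop = FALSE]
  colnames(gcols) <- genes
  list(data = gei_data(st$subjects, gcols), study = st)
}

test_that("the exact 2x2 logistic fit reproduces the cross-product odds ratio", {
  # printed alcohol counts: cases 556/191, controls 759/197
  y <- rep(c(1L, 1L, 0L, 0L), c(556, 191, 759, 197))
  heavy <- rep(c(0L, 1L, 0L, 1L), c(556, 191, 759, 197))
  f <- score_logit(list(logic_leaf(1L)), y, matrix(heavy, ncol = 1))
  expect_equal(exp(f$coefficients[2]), (191 * 759) / (556 * 197),
               tolerance = 1e-7)
  expect_equal(exp(f$coefficients[2]), 1.323531, tolerance = 1e-6)
})

test_that("risk model reports OR_INT with internally consistent stratum ORs", {
  pg <- planted_gei_data(seed = 21)
  terms <- candidate_terms("G1")
  fit <- fit_risk_model(terms, pg$data)
  t1 <- fit$terms[fit$terms$term_id == "G1:gst:protein:high", ]
  expect_equal(nrow(t1), 1L)
  # planted log-OR 2.5 recovered within Wald uncertainty
  expect_true(t1$ci_lo < log(2.5) && log(2.5) < t1$ci_hi)
  # reporting identities: OR_INT = exp(coefficient), stratum gene OR ratio
  expect_equal(t1$or_int, exp(t1$estimate))
  expect_equal(t1$gene_or_level / t1$gene_or_ref, t1$or_int)
  # hierarchy: GST main effect and exposure dummies always present
  expect_true(all(c("gst_G1", "protein_high", "smoking_lt20py",
                    "smoking_ge20py", "alcohol_heavy") %in% names(fit$coef)))
  # a GST and its complement with the same exposure level are one test:
  # the aliased direction is dropped, not double-counted
  expect_true(any(grepl("comp", fit$dropped)) || any(grepl("comp", fit$terms$term_id)))
  both <- sub(":(gst|comp):", ":", c(fit$dropped, fit$terms$term_id))
  expect_equal(anyDuplicated(fit$terms$term_id), 0L)
})

test_that("printed stratum gene ORs are consistent with printed OR_INT", {
  # the ratio of stratum-specific gene effects reproduces the interaction
  # estimate up to printed rounding
  expect_equal(1.47 / 0.85, 1.75, tolerance = 0.02)   # risk, protein GEI
  expect_equal(0.93 / 0.39, 2.41, tolerance = 0.02)   # survival, protein GEI
})

test_that("zero interaction means equal stratum-specific gene ORs", {
  set.seed(31)
  n <- 800
  subj <- synthetic_subjects(n)
  gcols <- cbind(G1 = rbinom(n, 1, 0.4))
  data <- gei_data(subj, gcols)
  fit <- fit_risk_model(candidate_terms("G1"), data)
  # forced by the formula: gene_or_level = gene_or_ref * exp(estimate)
  expect_equal(fit$terms$gene_or_level,
               fit$terms$gene_or_ref * exp(fit$terms$estimate))
})

test_that("survival model stratifies by stage and ignores eventless strata", {
  set.seed(37)
  n <- 500
  subj <- synthetic_subjects(n, case = rep(1L, n))
  subj$stage <- factor(rep(c("local", "regional"), length.out = n),
                       levels = c("in_situ", "local", "regional", "distant",
                                  "unknown"))
  subj$months <- rexp(n, 0.02) + 1
  subj$event <- rbinom(n, 1, 0.7)
  # one stratum entirely censored contributes nothing
  subj$event[subj$stage == "regional"] <- 0L
  gcols <- cbind(G1 = rbinom(n, 1, 0.4))
  full <- fit_survival_model(candidate_terms("G1"), gei_data(subj, gcols))
  keep <- subj$stage == "local"
  red <- fit_survival_model(candidate_terms("G1"),
                            gei_data(subj[keep, ], gcols[keep, , drop = FALSE]))
  expect_equal(full$terms$estimate, red$terms$estimate, tolerance = 1e-6)
  expect_error(fit_survival_model(candidate_terms("G1"),
                                  gei_data(transform(subj, event = 0L), gcols)),
               "at least one event")
})

test_that("survival interaction HR is recovered at scale", {
  pg <- planted_gei_data(n_cases = 3000, n_controls = 100, seed = 41,
                         or_int = 2, genes = "G1")
  fit <- fit_survival_model(candidate_terms("G1"), pg$data)
  t1 <- fit$terms[fit$terms$term_id == "G1:gst:protein:high", ]
  expect_equal(t1$estimate, log(2), tolerance = 0.2)
})

test_that("backward selection keeps the planted term and drops noise", {
  kept_planted <- logical(8)
  for (r in 1:8) {
    pg <- planted_gei_data(seed = 500 + r)
    sel <- suppressWarnings(
      backward_select_subpathway(candidate_terms(c("G1", "G2", "G3", "G4")),
                                 pg$data, "risk"))
    ids <- sel$retained$term_id
    kept_planted[r] <- "G1:gst:protein:high" %in% ids ||
      "G1:comp:protein:high" %in% ids
    # every retained term is significant at the threshold
    if (nrow(sel$retained) > 0) expect_true(all(sel$retained$p <= 0.05))
    # selection is a fixed point: re-running on the retained set changes
    # nothing
    if (nrow(sel$retained) > 0) {
      again <- backward_select_subpathway(
        sel$retained[, c("term_id", "gene", "direction", "exposure", "level")],
        pg$data, "risk")
      expect_setequal(again$retained$term_id, ids)
    }
    # termination in at most the initial number of candidate terms
    expect_lte(length(sel$eliminated), nrow(candidate_terms(c("G1", "G2",
                                                              "G3", "G4"))))
  }
  expect_gte(mean(kept_planted), 0.8)
})

test_that("backward selection handles trivial candidate sets", {
  pg <- planted_gei_data(seed = 77, genes = "G1")
  # empty candidate set: empty return, no error
  sel0 <- backward_select_subpathway(candidate_terms(character(0)), pg$data,
                                     "risk")
  expect_equal(nrow(sel0$retained), 0L)
  # a single strongly significant term survives untouched
  one <- candidate_terms("G1")
  one <- one[one$term_id == "G1:gst:protein:high", ]
  sel1 <- backward_select_subpathway(one, pg$data, "risk")
  expect_equal(sel1$retained$term_id, "G1:gst:protein:high")
  expect_equal(length(sel1$eliminated), 0L)
})

test_that("the joint model over one sub-pathway's survivors equals its fit", {
  pg <- planted_gei_data(seed = 91)
  sel <- suppressWarnings(
    backward_select_subpathway(candidate_terms(c("G1", "G2")), pg$data, "risk"))
  expect_gte(nrow(sel$retained), 1L)
  joint <- joint_final_model(sel$retained, pg$data, "risk")
  expect_equal(sort(joint$fit$terms$estimate), sort(sel$fit$terms$estimate),
               tolerance = 1e-8)
  # no survivors anywhere: significant count 0
  empty <- joint_final_model(NULL, pg$data, "risk")
  expect_equal(empty$n_significant, 0L)
})

test_that("permutation test is valid, deterministic and prevalence-preserving", {
  pg <- planted_gei_data(n_cases = 300, n_controls = 380, seed = 13,
                         genes = c("G1", "G2"))
  sp <- list(a = c("G1", "G2"))
  # an observed count of 0 forces empirical p = 1 under the >= convention
  s3_none <- run_step3(pg$data, sp, "risk", threshold = 1e-12)
  expect_equal(s3_none$n_significant, 0L)
  pt0 <- permutation_test(pg$data, sp, "risk", B = 5, seed = 3,
                          threshold = 1e-12, observed = s3_none)
  expect_equal(pt0$empirical_p, 1)
  # determinism in the seed
  s3 <- suppressWarnings(run_step3(pg$data, sp, "risk"))
  pt1 <- permutation_test(pg$data, sp, "risk", B = 8, seed = 4, observed = s3)
  pt2 <- permutation_test(pg$data, sp, "risk", B = 8, seed = 4, observed = s3)
  expect_identical(pt1$counts, pt2$counts)
  expect_gte(min(pt1$empirical_p, 1), 0)
  # column permutation preserves prevalence exactly (the mechanism the
  # correction relies on)
  set.seed(99)
  v <- rbinom(50, 1, 0.3)
  expect_equal(sum(v[sample.int(50)]), sum(v))
  expect_error(permutation_test(pg$data, sp, "risk", B = 0), "at least 1")
})

test_that("no fitted model contains an interaction without its main effects", {
  for (s in 1:3) {
    pg <- planted_gei_data(seed = 600 + s, genes = c("G1", "G2"))
    fit <- suppressWarnings(fit_risk_model(candidate_terms(c("G1", "G2")),
                                           pg$data))
    for (i in seq_len(nrow(fit$terms))) {
      expect_true(paste0("gst_", fit$terms$gene[i]) %in% names(fit$coef))
      lvl <- paste0(fit$terms$exposure[i], "_", fit$terms$level[i])
      expect_true(lvl %in% names(fit$coef))
    }
  }
})
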