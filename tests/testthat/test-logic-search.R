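test_that("logistic score matches closed forms", {
  set.seed(23)
  X <- matrix(rbinom(200, 1, 0.5), 100, 2)
  y <- rep(c(0L, 1L), each = 50)
  # intercept-only deviance: -2(k ln(k/n) + (n-k) ln(1-k/n))
  f0 <- score_logit(list(), y, X)
  expect_equal(f0$deviance, 138.6294, tolerance = 1e-4)
  # single binary column: exp(beta) equals the 2x2 cross-product OR
  t1 <- logic_leaf(1L)
  f1 <- score_logit(list(t1), y, X)
  tab <- table(X[, 1], y)
  or <- (tab["1", "1"] * tab["0", "0"]) / (tab["0", "1"] * tab["1", "0"])
  expect_equal(exp(f1$coefficients[2]), or, tolerance = 1e-7)
  expect_false(f1$separation)
})

test_that("a perfectly separating tree drives deviance to zero and is flagged", {
  y <- rep(c(0L, 1L), each = 20)
  X <- matrix(y, ncol = 1)
  f <- score_logit(list(logic_leaf(1L)), y, X)
  expect_true(f$separation)
  expect_lt(f$deviance, 1)
})

test_that("a constant tree column is held at zero and flagged degenerate", {
  y <- rep(c(0L, 1L), each = 10)
  X <- matrix(1L, 20, 1)
  f <- score_logit(list(logic_leaf(1L)), y, X)
  expect_true(f$degenerate)
  expect_equal(f$deviance, -2 * 20 * log(0.5), tolerance = 1e-6)
})

test_that("exponential score matches closed forms", {
  X <- matrix(0L, 4, 1)
  # 2 events over total time 4: lambda-hat 0.5, loglik 2 ln 0.5 - 2
  f <- score_exponential(list(), time = rep(1, 4), event = c(1, 1, 0, 0), X = X)
  expect_equal(exp(f$coefficients[1]), 0.5, tolerance = 1e-8)
  expect_equal(f$m2loglik, -2 * (2 * log(0.5) - 2), tolerance = 1e-6)
  # doubling all times shifts the log-rate by exactly -ln 2
  f2 <- score_exponential(list(), time = rep(2, 4), event = c(1, 1, 0, 0), X = X)
  expect_equal(f2$coefficients[1], f$coefficients[1] - log(2), tolerance = 1e-8)
  # one binary column: exp(beta) equals the ratio of group event rates
  set.seed(29)
  grp <- rbinom(200, 1, 0.5)
  tm <- rexp(200, ifelse(grp == 1, 0.2, 0.1))
  ev <- rbinom(200, 1, 0.8)
  tm <- ifelse(ev == 1, tm, tm / 2)
  Xg <- matrix(grp, ncol = 1)
  fg <- score_exponential(list(logic_leaf(1L)), tm, ev, Xg)
  rate <- function(g) sum(ev[grp == g]) / sum(tm[grp == g])
  expect_equal(exp(fg$coefficients[2]), rate(1) / rate(0), tolerance = 1e-6)
  expect_error(score_exponential(list(), time = 1:3, event = c(0, 0, 0),
                                 X = matrix(0, 3, 1)),
               "at least one event")
})

test_that("annealing finds the enumerated global optimum on a planted signal", {
  set.seed(31)
  n <- 500
  X <- matrix(rbinom(n * 4, 1, 0.5), n, 4)
  y <- rbinom(n, 1, plogis(-1 + 2.5 * (X[, 1] & X[, 2])))
  en <- enumerate_trees(4, 3)
  opt <- min(vapply(en$trees, function(t) score_logit(list(t), y, X)$deviance,
                    numeric(1)))
  hits <- vapply(1:8, function(s) {
    m <- anneal(X, y, "logit", size = c(1, 3),
                schedule = quick_schedule(seed = 1000 + s))
    m$score <= opt + 1e-6
  }, logical(1))
  expect_gte(mean(hits), 7 / 8)
})

test_that("optimisation never worsens the training fit, and seeds reproduce", {
  set.seed(37)
  X <- matrix(rbinom(3000, 1, 0.5), 300, 10)
  y <- rbinom(300, 1, 0.5)  # pure noise
  null_dev <- score_logit(list(), y, X)$deviance
  m <- anneal(X, y, "logit", size = c(1, 4), schedule = quick_schedule(seed = 5))
  expect_lte(m$score, null_dev)
  m2 <- anneal(X, y, "logit", size = c(1, 4), schedule = quick_schedule(seed = 5))
  expect_equal(m$score, m2$score)
  expect_equal(format_tree(m$trees[[1]]), format_tree(m2$trees[[1]]))
  # zero start temperature is greedy: still never worse than the start
  g <- anneal(X, y, "logit", size = c(1, 4),
              schedule = anneal_schedule(start_temperature = 0,
                                         n_iterations = 200, restarts = 1,
                                         seed = 6))
  expect_lte(g$score, null_dev)
  # zero iteration budget returns an initial (single-leaf) model
  m0 <- anneal(X, y, "logit", size = c(1, 4),
               schedule = anneal_schedule(n_iterations = 0, restarts = 1,
                                          seed = 7))
  expect_equal(n_leaves(m0$trees[[1]]), 1L)
})

test_that("cross-validation picks the planted size and shrinks under noise", {
  grid <- cv_grid(n_trees = 1, max_leaves = 1:3)
  noise_sizes <- integer(6)
  for (r in 1:6) {
    set.seed(4000 + r)
    X <- matrix(rbinom(300 * 6, 1, 0.5), 300, 6)
    y_noise <- rbinom(300, 1, 0.5)
    cvn <- cv_select(X, y_noise, "logit", grid, folds = 5,
                     schedule = quick_schedule(seed = 1, n_iterations = 200,
                                               restarts = 1))
    noise_sizes[r] <- cvn$chosen["max_leaves"]
  }
  # overfitting penalty: noise favours the smallest size
  expect_gte(mean(noise_sizes == 1), 0.5)
  # a strong 2-leaf signal is sized correctly (the larger leaf bound needs a
  # real search budget before its overfit becomes visible in validation)
  signal_sizes <- integer(5)
  for (r in 1:5) {
    set.seed(4000 + r)
    X <- matrix(rbinom(300 * 6, 1, 0.5), 300, 6)
    y_sig <- rbinom(300, 1, plogis(-1.5 + 3 * (X[, 1] & X[, 2])))
    cvs <- cv_select(X, y_sig, "logit", grid, folds = 5,
                     schedule = quick_schedule(seed = 2, n_iterations = 600))
    signal_sizes[r] <- cvs$chosen["max_leaves"]
  }
  expect_gte(mean(signal_sizes == 2), 0.8)
  # a one-entry grid is chosen trivially
  one <- cv_grid(n_trees = 1, max_leaves = 2)
  set.seed(99)
  cv1 <- cv_select(matrix(rbinom(600, 1, 0.5), 100, 6), rbinom(100, 1, 0.5),
                   "logit", one, folds = 4,
                   schedule = quick_schedule(seed = 3, n_iterations = 50,
                                             restarts = 1))
  expect_equal(unname(cv1$chosen), c(1, 2))
})

test_that("GST construction recovers planted per-gene structure", {
  set.seed(43)
  n <- 600
  counts <- matrix(rbinom(n * 3, 2, 0.3), n, 3,
                   dimnames = list(NULL, c("rsA", "rsB", "rsC")))
  g <- genotype_matrix(counts, gene_of_snp = c(rsA = "GX", rsB = "GX",
                                               rsC = "GY"))
  X <- encode_genotypes(g)
  # planted: dominant(rsA) AND dominant(rsB) within gene GX
  plant <- (counts[, "rsA"] >= 1) & (counts[, "rsB"] >= 1)
  y <- rbinom(n, 1, plogis(-1.5 + 2.5 * plant))
  hits <- 0L
  for (s in 1:5) {
    gst <- build_gst("GX", gene_columns(X, "GX"), y, "logit",
                     grid = cv_grid(1, 1:3), folds = 5,
                     schedule = quick_schedule(seed = 100 + s,
                                               n_iterations = 300))
    v <- eval_tree(gst$tree, X)
    if (identical(v, as.integer(plant)) ||
        identical(v, 1L - as.integer(plant))) hits <- hits + 1L
    # complement always evaluates to the pointwise NOT
    expect_identical(eval_tree(gst$complement, X), 1L - v)
    expect_equal(gst$prevalence, mean(v))
  }
  expect_gte(hits, 4L)
  # single-SNP gene: GST is one of that SNP's two indicators (possibly
  # complemented)
  gst_y <- build_gst("GY", gene_columns(X, "GY"), y, "logit",
                     grid = cv_grid(1, 1), folds = 5,
                     schedule = quick_schedule(seed = 7, n_iterations = 100))
  expect_equal(n_leaves(gst_y$tree), 1L)
  expect_match(format_tree(gst_y$tree), "^rsC_(dom|rec)(\\^c)?$")
  # monomorphic gene is flagged degenerate
  const <- matrix(0L, 10, 2, dimnames = list(NULL, c("z1_dom", "z1_rec")))
  gst_d <- build_gst("GZ", const, rep(c(0L, 1L), 5), "logit")
  expect_true(gst_d$degenerate)
})

test_that("pathway trees recover planted cross-gene structure", {
  set.seed(47)
  n <- 600
  gcols <- cbind(A = rbinom(n, 1, 0.4), B = rbinom(n, 1, 0.4),
                 C = rbinom(n, 1, 0.4), D = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-1.5 + 2 * (gcols[, "A"] | gcols[, "B"])))
  pw <- build_pathway_trees(gcols, y, "logit", grid = cv_grid(1, 1:3),
                            folds = 5,
                            schedule = quick_schedule(seed = 11,
                                                      n_iterations = 400))
  v <- evaluate_model(pw, gcols)[, 1]
  plant <- as.integer(gcols[, "A"] | gcols[, "B"])
  expect_true(identical(v, plant) || identical(v, 1L - plant))
  # composition consistency: model evaluation is eval_tree on the GST matrix
  expect_identical(v, eval_tree(pw$trees[[1]], gcols))
  expect_error(build_pathway_trees(gcols[, 1, drop = FALSE], y, "logit"),
               "at least 2")
})
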