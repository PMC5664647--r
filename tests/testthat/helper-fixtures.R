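# Shared fixture builders; everything is generated in code at test time.

# A small gene panel for fast simulations.
tiny_panel <- function(genes = c("G1", "G2", "G3"), n_snps = 2,
                       maf = 0.3) {
  data.frame(gene = rep(genes, each = n_snps),
             snp = paste0(rep(genes, each = n_snps), "_rs", seq_len(n_snps)),
             maf = maf, stringsAsFactors = FALSE)
}

# Reduced annealing budget for unit tests.
quick_schedule <- function(seed = NULL, n_iterations = 400L, restarts = 2L) {
  anneal_schedule(n_iterations = n_iterations, restarts = restarts,
                  seed = seed)
}

# Random logic tree over `p` integer columns, grown by the move set itself.
random_tree <- function(p, max_leaves = 4L) {
  t <- logic_leaf(sample.int(p, 1L), sample(c(TRUE, FALSE), 1L))
  for (i in seq_len(sample.int(max_leaves, 1L) - 1L)) {
    t <- propose_move(t, p, max_leaves, moves = c("split_leaf", "grow_branch"))
  }
  t
}

# Expand printed case/control level counts into a subject-level data frame.
counts_to_subjects <- function(levels, cases_n, controls_n, var = "x") {
  d <- data.frame(
    case = rep(c(1L, 0L), c(sum(cases_n), sum(controls_n))),
    v = c(rep(levels, cases_n), rep(levels, controls_n)),
    stringsAsFactors = FALSE)
  names(d)[2] <- var
  d
}

# Subject table with the covariate columns the GEI models adjust for.
synthetic_subjects <- function(n, case = rbinom(n, 1, 0.5)) {
  lv <- list(smoking = c("never", "lt20py", "ge20py"),
             alcohol = c("non_moderate", "heavy"),
             protein = c("low", "high"))
  data.frame(
    age = rnorm(n, 61, 10),
    sex = factor(sample(c("male", "female"), n, TRUE)),
    race = factor(sample(c("white", "hispanic", "african_american"), n, TRUE,
                         c(0.8, 0.1, 0.1))),
    center = factor(sample(c("utah", "norcal"), n, TRUE)),
    case = case,
    smoking = factor(sample(lv$smoking, n, TRUE, c(0.49, 0.23, 0.28)),
                     levels = lv$smoking),
    alcohol = factor(sample(lv$alcohol, n, TRUE, c(0.77, 0.23)),
                     levels = lv$alcohol),
    protein = factor(sample(lv$protein, n, TRUE, c(0.36, 0.64)),
                     levels = lv$protein))
}
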