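#' Default angiogenesis-style gene panel for simulation
#'
#' 34 genes carrying 257 SNPs in total, mirroring the size of the candidate
#' pathway the framework targets.  The handful of published rsIDs appearing
#' in the pathway's reported trees are used for their genes; the remaining
#' SNP identifiers are synthetic (`<gene>_snp<k>`).  Minor-allele
#' frequencies are assigned deterministically (low-discrepancy sequence on
#' `[0.05, 0.5]`) so the panel is a fixed configuration, not a random draw.
#'
#' @return data frame with columns `gene`, `snp`, `maf`.
#' @export
default_gene_panel <- function() {
  genes <- c("VEGFA", "FLT1", "KDR", "HIF1A", "PDGFB", "TEK", "TGFB1",
             "TGFBR1", "IGF1R", "NFKB1", "CXCL8", "CXCR1", "CXCR2", "IL1A",
             "IL1B", "TNF", "MMP1", "MMP3", "MMP7", "MMP9", "BMP1", "BMP2",
             "BMP4", "BMPR1A", "BMPR1B", "BMPR2", "GDF10", "TLR2", "TLR3",
             "TLR4", "EGR2", "EGFR", "IRS1", "VDR")
  # 257 SNPs over 34 genes: 19 genes with 8 SNPs, 15 with 7
  n_snps <- rep(c(8L, 7L), c(19L, 15L))
  known <- list(PDGFB = "rs4821877", IGF1R = "rs2139924", TNF = "rs1800630",
                MMP1 = "rs470215", TLR4 = c("rs1927911", "rs11536889"),
                EGR2 = c("rs2295814", "rs224082"), KDR = "rs6838752",
                CXCR1 = "rs1008562", TLR2 = "rs7656411", EGFR = "rs17151957")
  rows <- mapply(function(g, m) {
    ids <- known[[g]]
    extra <- paste0(g, "_snp", seq_len(m - length(ids)))
    data.frame(gene = g, snp = c(ids, extra), stringsAsFactors = FALSE)
  }, genes, n_snps, SIMPLIFY = FALSE)
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  # golden-ratio sequence spreads MAFs over (0.05, 0.5] deterministically
  j <- seq_len(nrow(panel))
  panel$maf <- round(0.05 + 0.45 * ((j * 0.6180339887) %% 1), 4)
  panel
}

#' Default exposure prevalences
#'
#' Marginal prevalences of the three exposure categories in the combined
#' case-control sample the generator emulates: smoking never/under-20/over-20
#' pack-years 48.7/23.4/27.9%, alcohol heavy 22.8%, high-protein 64.4%.
#' @export
default_exposure_prevalences <- function() {
  list(smoking = c(never = 0.487, lt20py = 0.234, ge20py = 0.279),
       alcohol = c(non_moderate = 0.772, heavy = 0.228),
       protein = c(low = 0.356, high = 0.644))
}

default_stage_probs <- function() {
  c(in_situ = 20, local = 395, regional = 255, distant = 63, unknown = 14) / 747
}

default_stage_hazards <- function() {
  # per-month exponential baselines by stage severity (5-year survival
  # roughly 0.89/0.79/0.55/0.09 for in-situ/local/regional/distant)
  c(in_situ = 0.002, local = 0.004, regional = 0.010, distant = 0.040,
    unknown = 0.008)
}

#' A planted gene-environment interaction effect
#'
#' Declares a Boolean tree over one gene's indicator columns whose product
#' with an exposure-level indicator enters the simulated outcome model.
#'
#' @param gene gene symbol in the design's panel.
#' @param tree `logic_tree` with character leaf references into the gene's
#'   indicator columns (e.g. `"rs1927911_dom"`).
#' @param exposure one of `"smoking"`, `"alcohol"`, `"protein"`.
#' @param level a non-reference level of that exposure.
#' @param log_or interaction log-odds-ratio entering the case-control model.
#' @param log_hr interaction log-hazard-ratio entering the survival model.
#' @param log_or_main,log_hr_main main effect of the tree (all exposure
#'   levels).
#' @export
planted_effect <- function(gene, tree, exposure, level, log_or = 0,
                           log_hr = 0, log_or_main = 0, log_hr_main = 0) {
  lv <- exposure_levels()
  exposure <- match.arg(exposure, names(lv))
  if (!level %in% lv[[exposure]][-1L]) {
    stop("'", level, "' is not a non-reference level of ", exposure)
  }
  list(gene = gene, tree = tree, exposure = exposure, level = level,
       log_or = log_or, log_hr = log_hr, log_or_main = log_or_main,
       log_hr_main = log_hr_main)
}

#' Simulation design for a synthetic case-control study
#'
#' Defaults emulate the target study's structure: 747 cases, 956 controls,
#' a 34-gene/257-SNP panel, the observed exposure prevalences, the observed
#' stage distribution, and over five years of potential follow-up for every
#' subject.
#'
#' @param n_cases,n_controls outcome quotas.
#' @param panel gene/SNP/MAF table as from [default_gene_panel()].
#' @param ld_rho within-gene correlation of the latent allele variables,
#'   in `[0, 1)`.
#' @param exposure_prevalences list as [default_exposure_prevalences()].
#' @param planted_effects list of [planted_effect()]s.
#' @param intercept logistic intercept of the prospective sampling model
#'   (case probability at baseline; quota sampling makes the analysis
#'   case-control).
#' @param stage_probs multinomial stage distribution for cases.
#' @param stage_hazards per-month baseline exponential hazard per stage.
#' @param censor_horizon administrative censoring horizon in months: a
#'   scalar, or a length-2 range from which per-subject horizons are drawn
#'   uniformly (every subject retains > 60 months potential follow-up).
#' @param seed integer master seed.
#' @export
simulation_design <- function(n_cases = 747L, n_controls = 956L,
                              panel = default_gene_panel(), ld_rho = 0.2,
                              exposure_prevalences = default_exposure_prevalences(),
                              planted_effects = list(),
                              intercept = -0.62,
                              stage_probs = default_stage_probs(),
                              stage_hazards = default_stage_hazards(),
                              censor_horizon = c(72, 126),
                              seed = 1L) {
  stopifnot(n_cases > 0L, n_controls > 0L, ld_rho >= 0, ld_rho < 1)
  if (any(panel$maf <= 0 | panel$maf > 0.5)) {
    stop("minor-allele frequencies must lie in (0, 0.5]")
  }
  for (pr in exposure_prevalences) {
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-8) {
      stop("exposure prevalences must be non-negative and sum to 1")
    }
  }
  if (any(stage_hazards <= 0)) stop("baseline hazards must be positive")
  for (pe in planted_effects) {
    cols <- unlist(tree_leaves(pe$tree)$col)
    snps <- sub("_(dom|rec)$", "", cols)
    ok <- snps %in% panel$snp[panel$gene == pe$gene]
    if (!all(ok)) {
      stop("planted tree for ", pe$gene, " references unconfigured SNP(s): ",
           paste(snps[!ok], collapse = ", "))
    }
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 panel = panel, ld_rho = ld_rho,
                 exposure_prevalences = exposure_prevalences,
                 planted_effects = planted_effects,
                 intercept = intercept,
                 stage_probs = stage_probs,
                 stage_hazards = stage_hazards,
                 censor_horizon = censor_horizon,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate a genotype matrix
#'
#' Per SNP, each subject receives two latent standard-normal draws; within a
#' gene the draws for the same allele copy share a common factor with
#' correlation `ld_rho` (emulating linkage disequilibrium), while a SNP's
#' two copies are independent, so Hardy-Weinberg equilibrium holds
#' marginally.  Each latent value below the MAF quantile becomes a minor
#' allele; counts are the per-SNP allele sums.  Uses the ambient RNG.
#'
#' @param design a [simulation_design()].
#' @param n number of subjects.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(design, n) {
  panel <- design$panel
  rho <- design$ld_rho
  cnt <- matrix(0L, n, nrow(panel))
  for (g in unique(panel$gene)) {
    ix <- which(panel$gene == g)
    m <- length(ix)
    thr <- stats::qnorm(panel$maf[ix])
    for (copy in 1:2) {
      u <- stats::rnorm(n)
      z <- sqrt(rho) * u + sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)
      al <- sweep(z, 2L, thr, "<")
      cnt[, ix] <- cnt[, ix] + al
    }
  }
  gene_of_snp <- stats::setNames(panel$gene, panel$snp)
  genotype_matrix(cnt, subject_ids = paste0("S", seq_len(n)),
                  snp_ids = panel$snp, gene_of_snp = gene_of_snp)
}

#' Simulate exposure categories
#'
#' Independent categorical draws at the design's prevalences.  Uses the
#' ambient RNG.
#'
#' @param design a [simulation_design()].
#' @param n number of subjects.
#' @return data frame with factor columns `smoking`, `alcohol`, `protein`.
#' @export
simulate_exposures <- function(design, n) {
  pr <- design$exposure_prevalences
  draw <- function(p) {
    factor(sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
  }
  data.frame(smoking = draw(pr$smoking), alcohol = draw(pr$alcohol),
             protein = draw(pr$protein))
}

simulate_covariates <- function(n) {
  data.frame(
    age = round(stats::rnorm(n, 61.7, 10.7), 1),
    sex = factor(sample(c("male", "female"), n, TRUE, c(0.581, 0.419)),
                 levels = c("male", "female")),
    race = factor(sample(c("white", "hispanic", "african_american"), n, TRUE,
                         c(0.845, 0.080, 0.075)),
                  levels = c("white", "hispanic", "african_american")),
    center = factor(sample(c("utah", "norcal"), n, TRUE, c(0.373, 0.627)),
                    levels = c("utah", "norcal")))
}

planted_linear_predictor <- function(design, X, exposures, what = c("or", "hr")) {
  what <- match.arg(what)
  lp <- rep(0, nrow(X))
  for (pe in design$planted_effects) {
    tv <- eval_tree(pe$tree, X)
    ev <- as.integer(exposures[[pe$exposure]] == pe$level)
    b_main <- if (what == "or") pe$log_or_main else pe$log_hr_main
    b_int <- if (what == "or") pe$log_or else pe$log_hr
    lp <- lp + b_main * tv + b_int * tv * ev
  }
  lp
}

#' Simulate a case-control sample by quota sampling
#'
#' Subjects are drawn prospectively from the logistic model
#' `logit(p) = intercept + sum(planted main and interaction terms)` and
#' accumulated until the case and control quotas are both met (the
#' retrospective design is approximated by quota sampling on the outcome;
#' interaction coefficients keep their odds-ratio interpretation).  Uses the
#' ambient RNG.
#'
#' @param design a [simulation_design()].
#' @return list with `subjects` (covariates, exposures, `case`),
#'   `genotypes` (a [genotype_matrix()]) and `truth` (per-subject planted
#'   tree values and the design's planted coefficients).
#' @export
simulate_case_control <- function(design) {
  want_cases <- design$n_cases
  want_controls <- design$n_controls
  batch <- max(1000L, want_cases + want_controls)
  got <- list()
  kept_geno <- list()
  n_cases <- 0L
  n_controls <- 0L
  for (b in seq_len(200L)) {
    geno <- simulate_genotypes(design, batch)
    X <- encode_genotypes(geno)
    expo <- simulate_exposures(design, batch)
    cov <- simulate_covariates(batch)
    lp <- design$intercept + planted_linear_predictor(design, X, expo, "or")
    pcase <- stats::plogis(lp)
    y <- stats::rbinom(batch, 1L, pcase)
    take_case <- which(y == 1L)[seq_len(min(sum(y == 1L), want_cases - n_cases))]
    take_ctrl <- which(y == 0L)[seq_len(min(sum(y == 0L), want_controls - n_controls))]
    take <- sort(c(take_case, take_ctrl))
    if (length(take) > 0L) {
      d <- cbind(cov[take, , drop = FALSE], expo[take, , drop = FALSE])
      d$case <- y[take]
      got[[length(got) + 1L]] <- d
      kept_geno[[length(kept_geno) + 1L]] <- geno$counts[take, , drop = FALSE]
      n_cases <- n_cases + length(take_case)
      n_controls <- n_controls + length(take_ctrl)
    }
    if (n_cases >= want_cases && n_controls >= want_controls) break
    if (b == 200L) {
      stop("case/control quota unattainable within the draw budget ",
           "(degenerate case probabilities?)")
    }
  }
  subjects <- do.call(rbind, got)
  subjects$subject_id <- paste0("S", seq_len(nrow(subjects)))
  rownames(subjects) <- NULL
  counts <- do.call(rbind, kept_geno)
  rownames(counts) <- subjects$subject_id
  genotypes <- genotype_matrix(counts, subject_ids = subjects$subject_id,
                               snp_ids = design$panel$snp,
                               gene_of_snp = stats::setNames(design$panel$gene,
                                                             design$panel$snp))
  X <- encode_genotypes(genotypes)
  truth <- lapply(design$planted_effects, function(pe) {
    list(gene = pe$gene, tree = format_tree(pe$tree),
         exposure = pe$exposure, level = pe$level,
         log_or = pe$log_or, log_hr = pe$log_hr,
         tree_values = eval_tree(pe$tree, X))
  })
  list(subjects = subjects, genotypes = genotypes, truth = truth)
}

#' Simulate survival outcomes for the cases
#'
#' Each case receives a SEER-style stage from the design's multinomial;
#' event times are exponential with rate
#' `stage_hazard * exp(sum planted log-HR terms)`, administratively censored
#' at the design's horizon.  Controls carry no survival fields.  Uses the
#' ambient RNG.
#'
#' @param design a [simulation_design()].
#' @param subjects subject table from [simulate_case_control()].
#' @param genotypes matching [genotype_matrix()].
#' @return data frame aligned with `subjects` rows: `months`, `event`,
#'   `stage` (NA for controls).
#' @export
simulate_survival <- function(design, subjects, genotypes) {
  n <- nrow(subjects)
  X <- encode_genotypes(genotypes)
  lp <- planted_linear_predictor(design, X, subjects, "hr")
  out <- data.frame(months = rep(NA_real_, n), event = rep(NA_integer_, n),
                    stage = factor(rep(NA_character_, n),
                                   levels = names(design$stage_probs)))
  ix <- which(subjects$case == 1L)
  stage <- sample(names(design$stage_probs), length(ix), TRUE,
                  design$stage_probs)
  rate <- design$stage_hazards[stage] * exp(lp[ix])
  t_event <- stats::rexp(length(ix), rate)
  horizon <- if (length(design$censor_horizon) == 2L) {
    stats::runif(length(ix), design$censor_horizon[1], design$censor_horizon[2])
  } else {
    rep(design$censor_horizon, length(ix))
  }
  out$months[ix] <- pmin(t_event, horizon)
  out$event[ix] <- as.integer(t_event <= horizon)
  out$stage[ix] <- stage
  out
}

#' Simulate a complete synthetic study
#'
#' Seeds the RNG from the design and runs genotype, exposure, case-control
#' and survival simulation; identical design and seed give byte-identical
#' output.
#'
#' @param design a [simulation_design()].
#' @return list with `subjects` (covariates, exposures, `case`, `months`,
#'   `event`, `stage`), `genotypes`, `indicators` (encoded), `truth` and
#'   `design`.
#' @export
simulate_study <- function(design) {
  set.seed(design$seed)
  cc <- simulate_case_control(design)
  surv <- simulate_survival(design, cc$subjects, cc$genotypes)
  subjects <- cbind(cc$subjects, surv)
  list(subjects = subjects, genotypes = cc$genotypes,
       indicators = encode_genotypes(cc$genotypes),
       truth = cc$truth, design = design)
}

#' Write a synthetic study to disk in the formats the readers accept
#'
#' Genotypes as a `subject_id` + rsID-columns TSV, phenotypes as TSV,
#' ground truth (planted trees, coefficients, seed) as JSON, and the
#' gene/sub-pathway structure as YAML.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @param subpathways optional named list mapping sub-pathway names to gene
#'   vectors, written into the pathway YAML.
#' @export
write_study <- function(study, dir, subpathways = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno <- data.frame(subject_id = study$genotypes$subject_ids,
                     study$genotypes$counts, check.names = FALSE)
  utils::write.table(geno, file.path(dir, "genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$subjects, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- lapply(study$truth, function(t) t[names(t) != "tree_values"])
  jsonlite::write_json(list(seed = study$design$seed, planted = truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  genes <- split(study$design$panel$snp, study$design$panel$gene)
  if (is.null(subpathways)) {
    subpathways <- list(all = names(genes))
  }
  yaml::write_yaml(list(genes = as.list(genes),
                        subpathways = subpathways),
                   file.path(dir, "pathway.yaml"))
  invisible(dir)
}
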