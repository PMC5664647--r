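#' Default sub-pathway grouping of the simulated gene panel
#'
#' Nine biologically coherent groups of the 34 panel genes (growth-factor
#' receptor axes, hypoxia response, inflammation, matrix remodelling, bone
#' morphogenetic proteins, innate-immunity receptors); user-overridable via
#' the pathway config.
#' @export
default_subpathways <- function() {
  list(vegf_receptor = c("VEGFA", "FLT1", "KDR"),
       hypoxia       = c("HIF1A", "EGR2"),
       pdgf_tek      = c("PDGFB", "TEK"),
       tgf_beta      = c("TGFB1", "TGFBR1"),
       igf           = c("IGF1R", "IRS1"),
       inflammation  = c("NFKB1", "CXCL8", "CXCR1", "CXCR2", "IL1A", "IL1B",
                         "TNF"),
       mmp           = c("MMP1", "MMP3", "MMP7", "MMP9"),
       bmp           = c("BMP1", "BMP2", "BMP4", "BMPR1A", "BMPR1B", "BMPR2",
                         "GDF10"),
       tlr_egfr      = c("TLR2", "TLR3", "TLR4", "EGFR", "VDR"))
}

#' Configuration for a full pipeline run
#'
#' @param design a [simulation_design()] to simulate inputs, or `NULL` to
#'   read them from files.
#' @param genotypes,phenotypes,pathway_config input paths (used when
#'   `design` is `NULL`).
#' @param subpathways named list of sub-pathway gene vectors; defaults to
#'   the pathway config's `subpathways` block or [default_subpathways()].
#' @param endpoint `"risk"`, `"survival"` or `"both"`.
#' @param schedule an [anneal_schedule()] for Steps 1-2.
#' @param grid,folds CV grid and fold count for Steps 1-2.
#' @param threshold GEI significance threshold (default 0.05).
#' @param permutations number of permutation runs (0 skips the correction).
#' @param seed master seed; per-stage streams are derived from it so adding
#'   permutations never changes the GSTs.
#' @param out output directory.
#' @export
pipeline_config <- function(design = NULL, genotypes = NULL, phenotypes = NULL,
                            pathway_config = NULL, subpathways = NULL,
                            endpoint = c("both", "risk", "survival"),
                            schedule = anneal_schedule(),
                            grid = cv_grid(), folds = 10L, threshold = 0.05,
                            permutations = 1000L, seed = 1L, out = NULL) {
  endpoint <- match.arg(endpoint)
  stopifnot(threshold > 0, threshold < 1, permutations >= 0)
  if (is.null(design) &&
      (is.null(genotypes) || is.null(phenotypes) || is.null(pathway_config))) {
    stop("either a simulation design or all three input paths are required")
  }
  list(design = design, genotypes = genotypes, phenotypes = phenotypes,
       pathway_config = pathway_config, subpathways = subpathways,
       endpoint = endpoint, schedule = schedule, grid = grid, folds = folds,
       threshold = threshold, permutations = as.integer(permutations),
       seed = as.integer(seed), out = out)
}

#' Run the full 3-step GEI pipeline
#'
#' Simulate (or read) -> encode -> descriptives -> Step 1 GSTs -> Step 2
#' pathway trees -> Step 3 GEI models (+ optional permutation correction),
#' per requested endpoint.  Risk models use all subjects under the logistic
#' score; survival Steps 1-2 use the exponential score on cases only and
#' Step 3 the stage-stratified Cox model.  With `config$out` set, all
#' result tables and a manifest (seeds, sizes, versions) are written there;
#' re-running an identical config reproduces the outputs.
#'
#' @param config a [pipeline_config()].
#' @return list with `subjects`, `descriptives`, and per-endpoint `gsts`,
#'   `pathway`, `step3`, `permutation`.
#' @export
run_pipeline <- function(config) {
  set.seed(config$seed)
  stage_seed <- sample.int(.Machine$integer.max, 8L)

  if (!is.null(config$design)) {
    design <- config$design
    design$seed <- stage_seed[1L]
    study <- simulate_study(design)
    subjects <- study$subjects
    X <- study$indicators
    subpathways <- config$subpathways
    if (is.null(subpathways)) {
      present <- unique(design$panel$gene)
      subpathways <- lapply(default_subpathways(), intersect, present)
      subpathways <- subpathways[lengths(subpathways) > 0L]
      if (length(subpathways) == 0L) subpathways <- list(all = present)
    }
    truth <- study$truth
  } else {
    cfg <- read_pathway_config(config$pathway_config)
    geno <- if (grepl("\\.vcf(\\.gz)?$", config$genotypes)) {
      read_genotype_vcf(config$genotypes, cfg$gene_of_snp)
    } else {
      read_genotype_tsv(config$genotypes, cfg$gene_of_snp)
    }
    subjects <- read_phenotypes(config$phenotypes)
    stopifnot(identical(as.character(subjects$subject_id), geno$subject_ids))
    X <- encode_genotypes(geno)
    subpathways <- if (!is.null(config$subpathways)) config$subpathways
                   else cfg$subpathways
    truth <- NULL
  }

  desc <- descriptive_table(subjects)
  endpoints <- if (config$endpoint == "both") c("risk", "survival")
               else config$endpoint
  out <- list(subjects = subjects, descriptives = desc, truth = truth,
              indicators = X, endpoints = list())

  for (i in seq_along(endpoints)) {
    ep <- endpoints[i]
    if (ep == "risk") {
      outcome <- subjects$case
      keep <- rep(TRUE, nrow(subjects))
      link <- "logit"
    } else {
      keep <- subjects$case != 0
      outcome <- list(time = subjects$months[keep],
                      event = subjects$event[keep])
      link <- "exponential"
    }
    sch <- config$schedule
    sch$seed <- stage_seed[2L + i]
    gsts <- build_gsts(X[keep, , drop = FALSE], outcome, link,
                       grid = config$grid, folds = config$folds,
                       schedule = sch)
    gcols_fit <- gst_columns(gsts, X[keep, , drop = FALSE])
    sch$seed <- stage_seed[4L + i]
    pathway <- if (ncol(gcols_fit) >= 2L) {
      build_pathway_trees(gcols_fit, outcome, link, grid = config$grid,
                          folds = config$folds, schedule = sch)
    } else NULL
    gcols_all <- gst_columns(gsts, X)
    pcols_all <- if (!is.null(pathway)) {
      pm <- evaluate_model(pathway, gcols_all)
      colnames(pm) <- paste0("pathway_tree", seq_len(ncol(pm)))
      pm
    } else NULL
    data <- gei_data(subjects, gcols_all, pcols_all)
    step3 <- run_step3(data, subpathways, ep, config$threshold)
    perm <- if (config$permutations > 0L) {
      permutation_test(data, subpathways, ep, B = config$permutations,
                       seed = stage_seed[7L + (i - 1L)],
                       threshold = config$threshold, observed = step3)
    } else NULL
    out$endpoints[[ep]] <- list(gsts = gsts, pathway = pathway,
                                data = data, step3 = step3,
                                permutation = perm)
  }

  if (!is.null(config$out)) write_run(out, config)
  out
}

write_run <- function(run, config) {
  dir <- config$out
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_descriptive_table(run$descriptives, file.path(dir, "descriptives.tsv"))
  for (ep in names(run$endpoints)) {
    r <- run$endpoints[[ep]]
    utils::write.table(
      gst_table(r$gsts, run$indicators, case = run$subjects$case),
      file.path(dir, paste0("gst_", ep, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- r$step3$joint$significant
    tab <- if (nrow(sig) > 0) {
      data.frame(term = sig$term_id, gene = sig$gene,
                 direction = sig$direction, exposure = sig$exposure,
                 level = sig$level,
                 effect = round(sig$or_int, 2),
                 ci_lo = round(sig$or_ci_lo, 2),
                 ci_hi = round(sig$or_ci_hi, 2),
                 p = round(sig$p, 3))
    } else {
      data.frame(term = character(0), gene = character(0),
                 direction = character(0), exposure = character(0),
                 level = character(0), effect = numeric(0),
                 ci_lo = numeric(0), ci_hi = numeric(0), p = numeric(0))
    }
    utils::write.table(tab, file.path(dir, paste0("gei_", ep, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(r$permutation)) {
      utils::write.table(
        data.frame(run = seq_len(r$permutation$B),
                   n_significant = r$permutation$counts),
        file.path(dir, paste0("permutation_", ep, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(endpoint = ep, observed = r$permutation$observed,
             B = r$permutation$B, empirical_p = r$permutation$empirical_p,
             seed = r$permutation$seed),
        file.path(dir, paste0("permutation_", ep, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  manifest <- list(
    seed = config$seed, endpoint = config$endpoint,
    threshold = config$threshold, permutations = config$permutations,
    folds = config$folds,
    schedule = unclass(config$schedule),
    grid = config$grid,
    n_subjects = nrow(run$subjects),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("pathgei")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# --- human-readable reports -------------------------------------------------

#' Render "447 (59.8%)"-style descriptive cells
#'
#' @param tab output of [descriptive_table()].
#' @return data frame with formatted `cases` and `controls` columns.
#' @export
report_descriptives <- function(tab) {
  cell <- function(n, pct, var) {
    ifelse(var == "age", sprintf("%.1f (%.1f)", n, pct),
           sprintf("%d (%.1f%%)", n, pct))
  }
  data.frame(variable = tab$variable, level = tab$level,
             cases = cell(tab$cases_n, tab$cases_pct, tab$variable),
             controls = cell(tab$controls_n, tab$controls_pct, tab$variable),
             p = ifelse(is.na(tab$p), "", format(round(tab$p, 3))),
             stringsAsFactors = FALSE)
}

#' Render a GST leaf or tree with genotype labels
#'
#' With per-SNP minor/major allele labels configured, an uncomplemented
#' dominant leaf renders as e.g. `"rs470215 (TT or TC)"` (carrier genotypes
#' for minor allele T), its complement as `"rs470215 (CC)"`, a recessive
#' leaf as the homozygous-minor genotype.
#'
#' @param tree a `logic_tree` with `<rsID>_dom` / `<rsID>_rec` leaf names.
#' @param alleles named list: `alleles[[rsID]]` is `list(minor =, major =)`.
#' @export
format_gst <- function(tree, alleles) {
  if (is_leaf(tree)) {
    ref <- as.character(tree$col)
    rs <- sub("_(dom|rec)$", "", ref)
    kind <- sub("^.*_", "", ref)
    al <- alleles[[rs]]
    if (is.null(al)) return(if (tree$neg) paste0(ref, "^c") else ref)
    m <- al$minor; M <- al$major
    lab <- if (kind == "dom" && !tree$neg) {
      sprintf("(%s%s or %s%s)", m, m, m, M)
    } else if (kind == "dom" && tree$neg) {
      sprintf("(%s%s)", M, M)
    } else if (kind == "rec" && !tree$neg) {
      sprintf("(%s%s)", m, m)
    } else {
      sprintf("(%s%s or %s%s)", m, M, M, M)
    }
    paste0(rs, " ", lab)
  } else {
    paste0("(", format_gst(tree$left, alleles), " ", toupper(tree$op), " ",
           format_gst(tree$right, alleles), ")")
  }
}

#' Render the significant-GEI table of a pipeline run
#'
#' @param run output of [run_pipeline()].
#' @param endpoint `"risk"` or `"survival"`.
#' @param alleles optional allele label map for [format_gst()].
#' @export
report_gei <- function(run, endpoint = "risk", alleles = NULL) {
  r <- run$endpoints[[endpoint]]
  if (is.null(r)) stop("run has no '", endpoint, "' endpoint results")
  sig <- r$step3$joint$significant
  if (nrow(sig) == 0) {
    return(data.frame(gst = character(0), gene = character(0),
                      exposure = character(0), level = character(0),
                      effect = character(0), p = character(0)))
  }
  gst_text <- vapply(seq_len(nrow(sig)), function(i) {
    g <- r$gsts[[sig$gene[i]]]
    tr <- if (sig$direction[i] == "gst") g$tree else g$complement
    if (is.null(alleles)) format_tree(tr) else format_gst(tr, alleles)
  }, character(1))
  lab <- if (endpoint == "risk") "OR_INT" else "HR_INT"
  data.frame(gst = gst_text, gene = sig$gene, exposure = sig$exposure,
             level = sig$level,
             effect = sprintf("%.2f (%.2f, %.2f)", sig$or_int,
                              sig$or_ci_lo, sig$or_ci_hi),
             p = sprintf("%.3f", sig$p),
             stringsAsFactors = FALSE,
             check.names = FALSE)
}
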