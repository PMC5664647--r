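#' Genotype matrix container
#'
#' Subjects x SNPs matrix of minor-allele counts (0, 1, 2 or `NA`) with the
#' SNP-to-gene map needed to restrict tree searches to one gene's SNPs.
#'
#' @param counts integer matrix, subjects in rows, SNPs in columns; values
#'   0/1/2/`NA`.
#' @param subject_ids character vector of subject identifiers.
#' @param snp_ids character vector of SNP (rsID) identifiers.
#' @param gene_of_snp named character vector mapping every rsID to exactly
#'   one gene symbol.
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(counts, subject_ids = rownames(counts),
                            snp_ids = colnames(counts), gene_of_snp) {
  counts <- as.matrix(counts)
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(counts)))
  stopifnot(length(subject_ids) == nrow(counts),
            length(snp_ids) == ncol(counts))
  bad <- !is.na(counts) & (counts %% 1 != 0 | counts < 0 | counts > 2)
  if (any(bad)) stop("genotype counts must be 0, 1, 2 or NA")
  miss <- setdiff(snp_ids, names(gene_of_snp))
  if (length(miss) > 0) {
    stop("SNP(s) absent from the gene map: ", paste(miss, collapse = ", "))
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(subject_ids, snp_ids)
  structure(list(counts = counts,
                 subject_ids = subject_ids,
                 snp_ids = snp_ids,
                 gene_of_snp = gene_of_snp[snp_ids]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$subject_ids), " subjects x ",
      length(x$snp_ids), " SNPs on ",
      length(unique(x$gene_of_snp)), " genes; ",
      sum(is.na(x$counts)), " missing calls\n", sep = "")
  invisible(x)
}

#' Encode genotypes as dominant/recessive indicator pairs
#'
#' Each SNP yields two binary columns: dominant (`>= 1` minor allele) and
#' recessive (`== 2` minor alleles), named `<rsID>_dom` / `<rsID>_rec`.
#' These indicator columns, rather than allele counts, are the leaves of all
#' logic trees.  Missing genotypes encode as 0 in both columns so Boolean
#' evaluation stays total; the number of affected calls is recorded in the
#' `n_missing` attribute.
#'
#' @param g a [genotype_matrix()].
#' @return an `indicator_matrix`: a subjects x (2 * SNPs) 0/1 matrix with a
#'   `provenance` attribute (data frame: column, snp, gene, kind).
#' @export
encode_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  cnt <- g$counts
  dom <- (!is.na(cnt) & cnt >= 1L) * 1L
  rec <- (!is.na(cnt) & cnt == 2L) * 1L
  m <- ncol(cnt)
  X <- matrix(0L, nrow(cnt), 2L * m)
  X[, seq(1L, 2L * m, by = 2L)] <- dom
  X[, seq(2L, 2L * m, by = 2L)] <- rec
  cols <- as.vector(rbind(paste0(g$snp_ids, "_dom"), paste0(g$snp_ids, "_rec")))
  dimnames(X) <- list(g$subject_ids, cols)
  prov <- data.frame(column = cols,
                     snp = rep(g$snp_ids, each = 2L),
                     gene = rep(unname(g$gene_of_snp), each = 2L),
                     kind = rep(c("dom", "rec"), m),
                     stringsAsFactors = FALSE)
  structure(X, provenance = prov, n_missing = sum(is.na(cnt)),
            class = c("indicator_matrix", class(X)))
}

#' @export
`[.indicator_matrix` <- function(x, i, j, ..., drop = FALSE) {
  n_idx <- nargs() - !missing(drop)
  y <- x
  attributes(y) <- attributes(x)[c("dim", "dimnames")]
  if (n_idx < 3L) {  # vector-style x[i] indexing
    return(if (missing(i)) y else y[i])
  }
  y <- if (missing(i) && missing(j)) y
       else if (missing(i)) y[, j, drop = drop]
       else if (missing(j)) y[i, , drop = drop]
       else y[i, j, drop = drop]
  if (!is.matrix(y)) return(y)
  prov <- attr(x, "provenance")
  prov <- prov[match(colnames(y), prov$column), , drop = FALSE]
  rownames(prov) <- NULL
  structure(y, provenance = prov,
            class = c("indicator_matrix", class(y)))
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat("<indicator_matrix> ", nrow(x), " subjects x ", ncol(x),
      " indicator columns (", ncol(x) / 2L, " SNPs)\n", sep = "")
  invisible(x)
}

#' Indicator columns belonging to one gene
#'
#' @param X an `indicator_matrix`.
#' @param gene gene symbol.
#' @export
gene_columns <- function(X, gene) {
  prov <- attr(X, "provenance")
  cols <- prov$column[prov$gene == gene]
  if (length(cols) == 0) stop("no indicator columns for gene '", gene, "'")
  X[, cols, drop = FALSE]
}

# --- exposure derivation ----------------------------------------------------

#' Derive the smoking exposure category
#'
#' Subjects with fewer than 100 lifetime cigarettes are never-smokers.
#' Otherwise pack-years = cigarettes/day x years smoked / 20, dichotomised at
#' 20 pack-years.
#'
#' @param cigs_per_day usual cigarettes smoked per day.
#' @param years_smoked total years of smoking.
#' @param lifetime_cigs lifetime cigarette count (never-smoker screen).
#' @return factor with levels `never`, `lt20py`, `ge20py`.
#' @export
derive_smoking <- function(cigs_per_day, years_smoked, lifetime_cigs) {
  if (any(c(cigs_per_day, years_smoked, lifetime_cigs) < 0, na.rm = TRUE)) {
    stop("smoking inputs must be non-negative")
  }
  pack_years <- cigs_per_day * years_smoked / 20
  out <- ifelse(lifetime_cigs < 100, "never",
                ifelse(pack_years < 20, "lt20py", "ge20py"))
  factor(out, levels = c("never", "lt20py", "ge20py"))
}

#' Derive the long-term alcohol exposure category
#'
#' Heavy if the mean of the consumption reported for 10 and 20 years prior
#' exceeds the sex-specific cut-off (20 g/week for men, 10 g/week for women),
#' strictly; otherwise none-to-moderate.
#'
#' @param grams_per_week_10y,grams_per_week_20y grams of alcohol per week at
#'   the two recall points.
#' @param sex factor/character with levels `male` / `female`.
#' @return factor with levels `non_moderate`, `heavy`.
#' @export
derive_alcohol <- function(grams_per_week_10y, grams_per_week_20y, sex) {
  if (any(c(grams_per_week_10y, grams_per_week_20y) < 0, na.rm = TRUE)) {
    stop("alcohol grams must be non-negative")
  }
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  cutoff <- ifelse(sex == "male", 20, 10)
  longterm <- (grams_per_week_10y + grams_per_week_20y) / 2
  factor(ifelse(longterm > cutoff, "heavy", "non_moderate"),
         levels = c("non_moderate", "heavy"))
}

#' Derive the dietary protein exposure category
#'
#' High if the animal/vegetable protein intake ratio strictly exceeds 1.5.
#' A zero vegetable intake makes the ratio unbounded: the subject is
#' assigned `high` with a warning.
#'
#' @param animal_g,vegetable_g daily animal and vegetable protein (grams).
#' @return factor with levels `low`, `high`.
#' @export
derive_protein <- function(animal_g, vegetable_g) {
  if (any(c(animal_g, vegetable_g) < 0, na.rm = TRUE)) {
    stop("protein grams must be non-negative")
  }
  zero_veg <- !is.na(vegetable_g) & vegetable_g == 0
  if (any(zero_veg)) {
    warning(sum(zero_veg),
            " subject(s) with zero vegetable protein assigned 'high'")
  }
  ratio <- animal_g / vegetable_g
  out <- ifelse(zero_veg, "high", ifelse(ratio > 1.5, "high", "low"))
  factor(out, levels = c("low", "high"))
}

#' Derive all three exposure categories from raw phenotype columns
#'
#' @param pheno data frame with columns `cigs_per_day`, `years_smoked`,
#'   `lifetime_cigs`, `alcohol_g_wk_10y`, `alcohol_g_wk_20y`, `sex`,
#'   `animal_protein_g`, `vegetable_protein_g`.
#' @return `pheno` with factor columns `smoking`, `alcohol`, `protein` added.
#' @export
derive_exposures <- function(pheno) {
  pheno$smoking <- derive_smoking(pheno$cigs_per_day, pheno$years_smoked,
                                  pheno$lifetime_cigs)
  pheno$alcohol <- derive_alcohol(pheno$alcohol_g_wk_10y,
                                  pheno$alcohol_g_wk_20y, pheno$sex)
  pheno$protein <- derive_protein(pheno$animal_protein_g,
                                  pheno$vegetable_protein_g)
  pheno
}

exposure_levels <- function() {
  list(smoking = c("never", "lt20py", "ge20py"),
       alcohol = c("non_moderate", "heavy"),
       protein = c("low", "high"))
}

# --- file readers -----------------------------------------------------------

#' Read a genotype matrix from a TSV file
#'
#' Expects rows = subjects, a `subject_id` first column, and one column per
#' rsID holding minor-allele counts 0/1/2 (or NA).
#'
#' @param path TSV file path.
#' @param gene_of_snp named character vector mapping rsIDs to genes
#'   (e.g. from [read_pathway_config()]).
#' @export
read_genotype_tsv <- function(path, gene_of_snp) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(colnames(d)[1], "subject_id")) {
    stop("first column of the genotype TSV must be 'subject_id'")
  }
  cnt <- as.matrix(d[, -1, drop = FALSE])
  genotype_matrix(cnt, subject_ids = as.character(d$subject_id),
                  snp_ids = colnames(cnt), gene_of_snp = gene_of_snp)
}

#' Read a genotype matrix from a VCF file
#'
#' Counts ALT alleles from the GT field (`./.` is missing).  The minor
#' allele is declared per SNP in the pathway config, not re-estimated from
#' the sample: if `minor_allele[[rsID]]` equals the record's REF base the
#' count is flipped to `2 - alt_count`.  Requires the `vcfR` package.
#'
#' @param path VCF path (plain or bgzipped).
#' @param gene_of_snp named character vector mapping rsIDs to genes.
#' @param minor_allele optional named character vector rsID -> minor-allele
#'   base.
#' @export
read_genotype_vcf <- function(path, gene_of_snp, minor_allele = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- vcfR::getID(v)
  ref <- vcfR::getREF(v)
  alt_count <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", "."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", x), "/"),
                  function(a) sum(a == "1"), integer(1)))
  }
  cnt <- apply(gt, 2L, alt_count)
  cnt <- matrix(cnt, nrow = nrow(gt),
                dimnames = list(ids, colnames(gt)))
  if (!is.null(minor_allele)) {
    flip <- ids %in% names(minor_allele) & minor_allele[ids] == ref
    flip[is.na(flip)] <- FALSE
    cnt[flip, ] <- 2L - cnt[flip, ]
  }
  genotype_matrix(t(cnt), gene_of_snp = gene_of_snp)
}

#' Read a phenotype/exposure table
#'
#' TSV with one row per subject.  Required columns: `subject_id`, `age`,
#' `sex`, `race`, `center`, `case`; raw exposure inputs (see
#' [derive_exposures()]) and, for cases, `months`, `event`, `stage`.
#'
#' @param path TSV file path.
#' @param derive derive the three exposure categories on read.
#' @export
read_phenotypes <- function(path, derive = TRUE) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "race", "center", "case")
  miss <- setdiff(need, colnames(d))
  if (length(miss) > 0) {
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  }
  d$sex <- factor(d$sex, levels = c("male", "female"))
  d$race <- factor(d$race)
  d$center <- factor(d$center)
  if ("stage" %in% colnames(d)) {
    d$stage <- factor(d$stage, levels = c("in_situ", "local", "regional",
                                          "distant", "unknown"))
  }
  if (derive) d <- derive_exposures(d)
  d
}

#' Read a pathway configuration (YAML)
#'
#' Expects blocks `genes: {GENE: [rsIDs]}` and `subpathways: {NAME: [GENEs]}`,
#' with optional `alleles: {rsID: {minor: X, major: Y}}` used for genotype
#' labels in reports.
#'
#' @param path YAML file path.
#' @return list with `genes`, `subpathways`, `gene_of_snp` (named vector) and
#'   `alleles`.
#' @export
read_pathway_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$genes) || is.null(cfg$subpathways)) {
    stop("pathway config must contain 'genes' and 'subpathways' blocks")
  }
  genes <- lapply(cfg$genes, as.character)
  snps <- unlist(genes, use.names = FALSE)
  if (anyDuplicated(snps)) {
    stop("rsID(s) mapped to more than one gene: ",
         paste(unique(snps[duplicated(snps)]), collapse = ", "))
  }
  gene_of_snp <- stats::setNames(rep(names(genes), lengths(genes)), snps)
  subp <- lapply(cfg$subpathways, as.character)
  unknown <- setdiff(unlist(subp), names(genes))
  if (length(unknown) > 0) {
    stop("sub-pathway gene(s) absent from 'genes': ",
         paste(unknown, collapse = ", "))
  }
  list(genes = genes, subpathways = subp, gene_of_snp = gene_of_snp,
       alleles = cfg$alleles)
}

# --- descriptive table ------------------------------------------------------

#' Case/control descriptive table
#'
#' Counts and within-group percentages by case status for each categorical
#' variable with a Pearson chi-square p-value (no continuity correction),
#' and mean (SD) with a two-sample t-test p-value for age.  Mirrors the
#' usual "Table 1/2" layout of case-control reports.
#'
#' @param subjects data frame with a 0/1 `case` column, an `age` column and
#'   the categorical variables to summarise.
#' @param vars character vector of categorical variable names; defaults to
#'   every factor/character column other than identifiers.
#' @return data frame with columns `variable`, `level`, `cases_n`,
#'   `cases_pct`, `controls_n`, `controls_pct`, `p` (p on the last row of
#'   each variable only).
#' @export
descriptive_table <- function(subjects, vars = NULL) {
  stopifnot("case" %in% colnames(subjects))
  case <- subjects$case != 0
  if (!any(case) || !any(!case)) stop("need at least one case and one control")
  if (is.null(vars)) {
    is_cat <- vapply(subjects, function(x) is.factor(x) || is.character(x),
                     logical(1))
    vars <- setdiff(colnames(subjects)[is_cat], c("subject_id", "stage"))
  }
  rows <- list()
  if ("age" %in% colnames(subjects)) {
    tt <- stats::t.test(subjects$age[case], subjects$age[!case])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "age", level = "mean_sd",
      cases_n = round(mean(subjects$age[case]), 1),
      cases_pct = round(stats::sd(subjects$age[case]), 1),
      controls_n = round(mean(subjects$age[!case]), 1),
      controls_pct = round(stats::sd(subjects$age[!case]), 1),
      p = tt$p.value, stringsAsFactors = FALSE)
  }
  for (v in vars) {
    x <- factor(subjects[[v]])
    tab <- table(x, factor(case, levels = c(TRUE, FALSE)))
    if (nrow(tab) < 2L) next
    pv <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    if (all(tab[, 1] / sum(tab[, 1]) == tab[, 2] / sum(tab[, 2]))) pv <- 1
    lv <- levels(x)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = lv,
      cases_n = as.integer(tab[, 1]),
      cases_pct = round(100 * tab[, 1] / sum(tab[, 1]), 1),
      controls_n = as.integer(tab[, 2]),
      controls_pct = round(100 * tab[, 2] / sum(tab[, 2]), 1),
      p = c(rep(NA_real_, length(lv) - 1L), pv),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a descriptive table as TSV
#' @param tab output of [descriptive_table()].
#' @param path output file.
#' @export
write_descriptive_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
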