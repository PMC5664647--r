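#' Bundle the inputs of the Step-3 GEI models
#'
#' @param subjects data frame with adjustment covariates (`age`, `sex`,
#'   `race`, `center`), the `case` indicator, the three exposure factors
#'   (`smoking`, `alcohol`, `protein`) and, for cases, `months`, `event`,
#'   `stage`.
#' @param gst_cols subjects x genes 0/1 matrix of GST values (from
#'   [gst_columns()] or a permutation thereof).
#' @param pathway_cols optional subjects x trees 0/1 matrix of pathway-tree
#'   values used as adjustment covariates.
#' @return a `gei_data` object.
#' @export
gei_data <- function(subjects, gst_cols, pathway_cols = NULL) {
  stopifnot(nrow(subjects) == nrow(gst_cols))
  need <- c("age", "sex", "race", "center", "case", "smoking", "alcohol",
            "protein")
  miss <- setdiff(need, colnames(subjects))
  if (length(miss) > 0) {
    stop("subjects table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.null(pathway_cols)) {
    pathway_cols <- as.matrix(pathway_cols)
    stopifnot(nrow(pathway_cols) == nrow(subjects))
    if (is.null(colnames(pathway_cols))) {
      colnames(pathway_cols) <- paste0("pathway_tree", seq_len(ncol(pathway_cols)))
    }
  }
  structure(list(subjects = subjects, gst_cols = as.matrix(gst_cols),
                 pathway_cols = pathway_cols),
            class = "gei_data")
}

#' Candidate GEI terms for a set of genes
#'
#' Every GST and its De Morgan complement crossed with every non-reference
#' level of the three exposures.
#'
#' @param genes gene symbols (must be columns of the data's GST matrix).
#' @param include_complement also generate complement-direction terms.
#' @return data frame with columns `term_id`, `gene`, `direction`,
#'   `exposure`, `level`.
#' @export
candidate_terms <- function(genes, include_complement = TRUE) {
  lv <- exposure_levels()
  rows <- list()
  dirs <- if (include_complement) c("gst", "comp") else "gst"
  for (g in genes) {
    for (d in dirs) {
      for (e in names(lv)) {
        for (l in lv[[e]][-1L]) {
          rows[[length(rows) + 1L]] <- data.frame(
            term_id = paste(g, d, e, l, sep = ":"),
            gene = g, direction = d, exposure = e, level = l,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(0), gene = character(0),
                      direction = character(0), exposure = character(0),
                      level = character(0), stringsAsFactors = FALSE)
  }
  out
}

# Design pieces for a set of candidate terms.  Returns the covariate block
# (adjustment + pathway trees + GST and exposure main effects) and one
# product column per term.  Hierarchy is guaranteed by construction: a
# term's GST main effect and its exposure's full dummy set are always
# present.
gei_design <- function(terms, data) {
  subj <- data$subjects
  A <- stats::model.matrix(~ age + sex + race + center, subj)[, -1L, drop = FALSE]
  blocks <- list(A)
  if (!is.null(data$pathway_cols)) blocks <- c(blocks, list(data$pathway_cols))
  for (g in unique(terms$gene)) {
    m <- matrix(data$gst_cols[, g], ncol = 1L,
                dimnames = list(NULL, paste0("gst_", g)))
    blocks <- c(blocks, list(m))
  }
  lv <- exposure_levels()
  for (e in unique(terms$exposure)) {
    f <- factor(subj[[e]], levels = lv[[e]])
    d <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
    colnames(d) <- paste0(e, "_", lv[[e]][-1L])
    blocks <- c(blocks, list(d))
  }
  Xc <- do.call(cbind, blocks)
  P <- matrix(0, nrow(subj), nrow(terms),
              dimnames = list(NULL, terms$term_id))
  for (i in seq_len(nrow(terms))) {
    g <- data$gst_cols[, terms$gene[i]]
    d <- if (terms$direction[i] == "gst") g else 1 - g
    L <- as.integer(subj[[terms$exposure[i]]] == terms$level[i])
    P[, i] <- d * L
  }
  list(covariates = Xc, products = P)
}

# Resolve rank deficiency within the covariate block.  A pathway tree can
# coincide with a GST main-effect column (e.g. a single-leaf pathway tree);
# aliased columns are dropped in priority order pathway trees > GST main
# effects; aliased adjustment or exposure columns are an error.
clean_covariates <- function(Xc, intercept = TRUE) {
  repeat {
    X <- cbind(if (intercept) matrix(1, nrow(Xc), 1L,
                                     dimnames = list(NULL, "(Intercept)")),
               Xc)
    q <- qr(X)
    if (q$rank == ncol(X)) return(Xc)
    aliased <- setdiff(colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]],
                       "(Intercept)")
    pw <- grep("^pathway_tree", aliased, value = TRUE)
    gm <- grep("^gst_", aliased, value = TRUE)
    drop1 <- if (length(pw) > 0) sort(pw)[1L]
             else if (length(gm) > 0) sort(gm)[1L]
             else stop("singular design among covariate columns: ",
                       paste(aliased, collapse = ", "))
    Xc <- Xc[, setdiff(colnames(Xc), drop1), drop = FALSE]
  }
}

# Drop product columns that are exactly collinear with the rest of the
# design (e.g. a GST and its complement crossed with the same exposure
# level), lowest-prevalence product first.  A rank deficiency among
# non-product columns is an error naming the columns.
drop_aliased_terms <- function(Xc, P, intercept = TRUE) {
  Xc <- clean_covariates(Xc, intercept)
  dropped <- character(0)
  repeat {
    X <- cbind(if (intercept) matrix(1, nrow(Xc), 1L,
                                     dimnames = list(NULL, "(Intercept)")),
               Xc, P)
    q <- qr(X)
    if (q$rank == ncol(X)) break
    aliased <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    cand <- intersect(aliased, colnames(P))
    if (length(cand) == 0L) {
      stop("singular design among covariate columns: ",
           paste(aliased, collapse = ", "))
    }
    prev <- colMeans(P[, cand, drop = FALSE])
    drop1 <- cand[order(prev, cand)][1L]
    dropped <- c(dropped, drop1)
    P <- P[, setdiff(colnames(P), drop1), drop = FALSE]
  }
  list(Xc = Xc, P = P, dropped = dropped)
}

wald_stats <- function(coef, se) {
  z <- coef / se
  data.frame(estimate = coef, se = se,
             ci_lo = coef - 1.96 * se, ci_hi = coef + 1.96 * se,
             p = 2 * stats::pnorm(-abs(z)))
}

fit_logistic_matrix <- function(X, y) {
  fit <- stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                        family = stats::binomial())
  p <- fit$rank
  piv <- fit$qr$pivot[seq_len(p)]
  covm <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- rep(NA_real_, ncol(X) + 1L)
  se[piv] <- sqrt(diag(covm))
  names(se) <- names(fit$coefficients)
  list(coef = fit$coefficients, se = se, converged = fit$converged,
       deviance = fit$deviance)
}

#' Fit the adjusted logistic GEI model for case-control risk
#'
#' Logistic model of case status on: adjustment covariates (age, sex, race,
#' center), pathway-tree columns, one main-effect column per involved GST,
#' full dummy sets for the involved exposures, and one product column per
#' candidate GEI term.  Interaction odds ratios (`OR_INT`) are the
#' exponentiated product-term coefficients with Wald 95% CIs; the
#' stratum-specific gene OR per exposure level is `exp(s b_GST + b_INT)`
#' (sign `s` = -1 for complement-direction terms).  Product columns exactly
#' collinear with the rest of the design (a GST and its complement with the
#' same exposure level carry the same test) are dropped and reported in
#' `dropped`.
#'
#' @param terms candidate-term data frame from [candidate_terms()].
#' @param data a [gei_data()].
#' @return a `gei_fit`: list with `endpoint`, `terms` (per-term estimate,
#'   CI, `or_int`, `p`, separation flag, stratum gene ORs), `coef`, `se`,
#'   `dropped`.
#' @export
fit_risk_model <- function(terms, data) {
  des <- gei_design(terms, data)
  al <- drop_aliased_terms(des$covariates, des$products, intercept = TRUE)
  X <- cbind(al$Xc, al$P)
  y <- data$subjects$case
  n_par <- ncol(X) + 1L
  if (nrow(X) < 10L * n_par) {
    warning("fewer than 10 complete-case rows per parameter (",
            nrow(X), " rows, ", n_par, " parameters)")
  }
  f <- fit_logistic_matrix(X, y)
  gei_fit_result(terms, al, f$coef, f$se, "risk", data)
}

#' Fit the stage-stratified Cox GEI model for survival among cases
#'
#' Cox partial likelihood (Efron ties) with baseline hazards stratified by
#' SEER stage, on cases only; same design columns as [fit_risk_model()]
#' apart from the intercept.  Strata without events contribute nothing.
#'
#' @inheritParams fit_risk_model
#' @return a `gei_fit` with hazard-ratio interpretation (`or_int` holds
#'   `HR_INT`).
#' @export
fit_survival_model <- function(terms, data) {
  cases <- data$subjects$case != 0
  sub <- data$subjects[cases, , drop = FALSE]
  if (sum(sub$event, na.rm = TRUE) < 1L) {
    stop("survival model needs at least one event")
  }
  data_c <- data
  data_c$subjects <- sub
  data_c$gst_cols <- data$gst_cols[cases, , drop = FALSE]
  if (!is.null(data$pathway_cols)) {
    data_c$pathway_cols <- data$pathway_cols[cases, , drop = FALSE]
  }
  des <- gei_design(terms, data_c)
  al <- drop_aliased_terms(des$covariates, des$products, intercept = FALSE)
  X <- cbind(al$Xc, al$P)
  fit <- survival::coxph(
    survival::Surv(sub$months, sub$event) ~ X + survival::strata(sub$stage),
    ties = "efron")
  coef <- fit$coefficients
  names(coef) <- sub("^X", "", names(coef))
  se <- sqrt(diag(fit$var))
  names(se) <- names(coef)
  gei_fit_result(terms, al, coef, se, "survival", data_c, fit = fit)
}

gei_fit_result <- function(terms, al, coef, se, endpoint, data, fit = NULL) {
  kept <- terms[terms$term_id %in% colnames(al$P), , drop = FALSE]
  st <- wald_stats(coef[kept$term_id], se[kept$term_id])
  sep <- !is.na(st$estimate) & abs(st$estimate) > SEPARATION_BOUND
  st$ci_lo[sep] <- -Inf
  st$ci_hi[sep] <- Inf
  gmain <- coef[paste0("gst_", kept$gene)]
  s <- ifelse(kept$direction == "gst", 1, -1)
  res <- cbind(kept, st)
  res$or_int <- exp(st$estimate)
  res$or_ci_lo <- exp(st$ci_lo)
  res$or_ci_hi <- exp(st$ci_hi)
  res$separation <- sep
  res$gene_or_ref <- exp(s * unname(gmain))
  res$gene_or_level <- exp(s * unname(gmain) + st$estimate)
  rownames(res) <- NULL
  structure(list(endpoint = endpoint, terms = res, coef = coef, se = se,
                 dropped = al$dropped, fit = fit),
            class = "gei_fit")
}

#' @export
print.gei_fit <- function(x, ...) {
  cat("<gei_fit> endpoint=", x$endpoint, ", ", nrow(x$terms),
      " interaction term(s)", if (length(x$dropped) > 0)
        paste0(" (", length(x$dropped), " aliased dropped)"), "\n", sep = "")
  if (nrow(x$terms) > 0) {
    show <- x$terms[, c("term_id", "or_int", "or_ci_lo", "or_ci_hi", "p")]
    show[-1] <- lapply(show[-1], round, 3)
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' Backward selection of GEI terms within one sub-pathway
#'
#' Starting from every candidate term for the sub-pathway's genes, the model
#' is refitted and the single least significant interaction term (highest
#' Wald p; ties broken by smaller `|estimate|`, then term name) is removed,
#' until every remaining term has `p <= threshold`.  Main effects and
#' adjustment covariates are never dropped.  Returns a possibly empty
#' retained set.
#'
#' @param terms candidate-term data frame.
#' @param data a [gei_data()].
#' @param endpoint `"risk"` or `"survival"`.
#' @param threshold significance threshold (default 0.05).
#' @return list with `retained` (term stats of the final fit), `fit` (the
#'   final `gei_fit`, `NULL` if nothing retained), `eliminated` (term ids in
#'   removal order, aliased drops included).
#' @export
backward_select_subpathway <- function(terms, data,
                                       endpoint = c("risk", "survival"),
                                       threshold = 0.05) {
  endpoint <- match.arg(endpoint)
  fit_fun <- if (endpoint == "risk") fit_risk_model else fit_survival_model
  eliminated <- character(0)
  cur <- terms
  fit <- NULL
  while (nrow(cur) > 0L) {
    fit <- fit_fun(cur, data)
    eliminated <- c(eliminated, fit$dropped)
    cur <- cur[cur$term_id %in% fit$terms$term_id, , drop = FALSE]
    if (nrow(cur) == 0L) break
    p <- fit$terms$p
    p[is.na(p)] <- 1
    if (all(p <= threshold)) break
    ord <- order(-p, abs(fit$terms$estimate), fit$terms$term_id)
    worst <- fit$terms$term_id[ord[1L]]
    eliminated <- c(eliminated, worst)
    cur <- cur[cur$term_id != worst, , drop = FALSE]
    fit <- NULL
  }
  retained <- if (nrow(cur) == 0L) {
    cur
  } else {
    fit$terms[fit$terms$term_id %in% cur$term_id, , drop = FALSE]
  }
  list(retained = retained, fit = fit, eliminated = eliminated)
}

#' Joint full-pathway GEI model over the sub-pathway survivors
#'
#' Fits the union of all retained sub-pathway terms in one model; the final
#' significant set is the terms with `p <= threshold` in that joint fit.
#'
#' @param retained data frame of retained terms (union across sub-pathways;
#'   deduplicated by `term_id`) or `NULL`/empty for none.
#' @inheritParams backward_select_subpathway
#' @return list with `fit` (`gei_fit` or `NULL`), `significant` (term stats
#'   with `p <= threshold`) and `n_significant`.
#' @export
joint_final_model <- function(retained, data,
                              endpoint = c("risk", "survival"),
                              threshold = 0.05) {
  endpoint <- match.arg(endpoint)
  cols <- c("term_id", "gene", "direction", "exposure", "level")
  if (is.null(retained) || nrow(retained) == 0L) {
    empty <- candidate_terms(character(0))
    return(list(fit = NULL, significant = empty, n_significant = 0L))
  }
  terms <- unique(retained[, cols, drop = FALSE])
  fit_fun <- if (endpoint == "risk") fit_risk_model else fit_survival_model
  fit <- fit_fun(terms, data)
  p <- fit$terms$p
  p[is.na(p)] <- 1
  sig <- fit$terms[p <= threshold, , drop = FALSE]
  list(fit = fit, significant = sig, n_significant = nrow(sig))
}

#' Run Step 3 end to end: sub-pathway selection then the joint model
#'
#' @param data a [gei_data()].
#' @param subpathways named list mapping sub-pathway names to gene vectors;
#'   genes without a (non-degenerate) GST column are ignored.
#' @inheritParams backward_select_subpathway
#' @return list with `subpathways` (per-sub-pathway selection results),
#'   `joint` (from [joint_final_model()]) and `n_significant`.
#' @export
run_step3 <- function(data, subpathways, endpoint = c("risk", "survival"),
                      threshold = 0.05) {
  endpoint <- match.arg(endpoint)
  sp_res <- list()
  retained <- list()
  for (nm in names(subpathways)) {
    genes <- intersect(subpathways[[nm]], colnames(data$gst_cols))
    if (length(genes) == 0L) next
    terms <- candidate_terms(genes)
    sel <- backward_select_subpathway(terms, data, endpoint, threshold)
    sp_res[[nm]] <- sel
    if (nrow(sel$retained) > 0L) {
      retained[[length(retained) + 1L]] <- sel$retained
    }
  }
  all_ret <- if (length(retained) > 0) do.call(rbind, retained) else NULL
  joint <- joint_final_model(all_ret, data, endpoint, threshold)
  list(subpathways = sp_res, joint = joint,
       n_significant = joint$n_significant)
}

#' Permutation-based multiple-testing correction for Step 3
#'
#' Repeats Step 3 on data in which every GST 0/1 column and every exposure
#' column has been independently permuted across subjects (outcomes and
#' adjustment covariates fixed), preserving each column's prevalence
#' exactly while destroying its link to the outcome.  The empirical p-value
#' is the fraction of permutation runs whose significant-GEI count reaches
#' the observed count (`>=` convention, so an observed count of 0 gives
#' p = 1).
#'
#' @param data a [gei_data()].
#' @param subpathways named list of sub-pathway gene vectors.
#' @param endpoint `"risk"` or `"survival"`.
#' @param B number of permutations (default 1000).
#' @param seed integer seed; per-permutation streams are derived from it, so
#'   results do not depend on execution order.
#' @param threshold significance threshold.
#' @param observed optionally, a precomputed [run_step3()] result for the
#'   observed data.
#' @return a `permutation_summary`: list with `observed`, `counts` (length
#'   `B`), `B`, `empirical_p`, `seed`, `failed` (indices of unfittable
#'   runs, counted as 0).
#' @export
permutation_test <- function(data, subpathways,
                             endpoint = c("risk", "survival"),
                             B = 1000L, seed = 1L, threshold = 0.05,
                             observed = NULL) {
  endpoint <- match.arg(endpoint)
  if (B < 1L) stop("B must be at least 1")
  if (is.null(observed)) {
    observed <- run_step3(data, subpathways, endpoint, threshold)
  }
  n <- nrow(data$subjects)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, B)
  counts <- integer(B)
  failed <- integer(0)
  for (b in seq_len(B)) {
    set.seed(run_seeds[b])
    pd <- data
    for (j in seq_len(ncol(pd$gst_cols))) {
      pd$gst_cols[, j] <- pd$gst_cols[sample.int(n), j]
    }
    for (e in c("smoking", "alcohol", "protein")) {
      pd$subjects[[e]] <- pd$subjects[[e]][sample.int(n)]
    }
    # separation warnings are routine on permuted columns; terms they affect
    # carry huge SEs and are never counted significant
    res <- tryCatch(suppressWarnings(run_step3(pd, subpathways, endpoint,
                                               threshold)),
                    error = function(e) NULL)
    if (is.null(res)) {
      failed <- c(failed, b)
      counts[b] <- 0L
    } else {
      counts[b] <- res$n_significant
    }
  }
  structure(list(observed = observed$n_significant, counts = counts, B = B,
                 empirical_p = mean(counts >= observed$n_significant),
                 seed = seed, failed = failed),
            class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat("<permutation_summary> observed=", x$observed, ", B=", x$B,
      ", empirical p=", format(x$empirical_p, digits = 4),
      if (length(x$failed) > 0) paste0(" (", length(x$failed),
                                       " unfittable runs counted 0)"),
      "\n", sep = "")
  invisible(x)
}
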