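#' @section Model fitting:
#' Logic-regression models are scored by exact maximum likelihood.  Because
#' every predictor is a Boolean tree, subjects collapse onto at most `2^k`
#' tree-value patterns; the Bernoulli or exponential likelihood is maximised
#' by Newton-Raphson on the aggregated table (step-halving, convergence
#' `|delta loglik| < 1e-10`, at most 100 iterations, separation flagged when
#' `|beta| > 15`).
#' @name pathgei-fitting
#' @keywords internal
NULL

SEPARATION_BOUND <- 15
NEWTON_TOL <- 1e-10
NEWTON_MAXIT <- 100L

# Aggregate subjects by tree-value pattern.
# tvals: n x k 0/1 matrix (k >= 0).  Returns design U (patterns x (k+1),
# intercept first), group index per subject, group sizes.
pattern_groups <- function(tvals, n) {
  k <- ncol(tvals)
  if (k == 0L) {
    return(list(U = matrix(1, 1L, 1L), idx = rep(1L, n)))
  }
  idx <- as.integer(tvals %*% 2^(seq_len(k) - 1L)) + 1L
  present <- sort(unique(idx))
  U <- cbind(1, (matrix(present - 1L, length(present), k) %/%
                   matrix(2^(seq_len(k) - 1L), length(present), k,
                          byrow = TRUE)) %% 2L)
  list(U = U, idx = match(idx, present))
}

# Newton-Raphson with step-halving on a concave log-likelihood.
# ll_grad_hess(beta) -> list(ll, grad, hess).  Aliased columns (detected by
# QR of the design) are held at zero and flagged.
newton_fit <- function(U, ll_fun, beta0) {
  qrU <- qr(U)
  keep <- sort(qrU$pivot[seq_len(qrU$rank)])
  degenerate <- qrU$rank < ncol(U)
  beta <- beta0
  cur <- ll_fun(beta)
  for (it in seq_len(NEWTON_MAXIT)) {
    g <- cur$grad[keep]
    H <- cur$hess[keep, keep, drop = FALSE]
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step)) {
      step <- -g / (diag(H) - 1e-8)
    }
    new_beta <- beta
    halve <- 1
    repeat {
      new_beta[keep] <- beta[keep] + halve * step
      cand <- ll_fun(new_beta)
      if (is.finite(cand$ll) && cand$ll >= cur$ll - 1e-12) break
      halve <- halve / 2
      if (halve < 1e-10) { new_beta <- beta; cand <- cur; break }
    }
    done <- abs(cand$ll - cur$ll) < NEWTON_TOL
    beta <- new_beta
    cur <- cand
    if (done) break
  }
  list(coef = beta, loglik = cur$ll, degenerate = degenerate,
       separation = max(abs(beta)) > SEPARATION_BOUND)
}

# Exact logistic MLE over tree-value patterns.
fit_logit_core <- function(tvals, y) {
  n <- length(y)
  pg <- pattern_groups(tvals, n)
  m <- tabulate(pg$idx, nrow(pg$U))
  s <- tabulate(pg$idx[y != 0], nrow(pg$U))
  U <- pg$U
  ll_fun <- function(beta) {
    eta <- drop(U %*% beta)
    p <- stats::plogis(eta)
    w <- m * p * (1 - p)
    list(ll = sum(s * eta - m * log1p(exp(eta))),
         grad = drop(crossprod(U, s - m * p)),
         hess = -crossprod(U, U * w))
  }
  fit <- newton_fit(U, ll_fun, rep(0, ncol(U)))
  fit$deviance <- -2 * fit$loglik
  fit$score <- fit$deviance
  fit
}

# Exact exponential-survival MLE over tree-value patterns.
fit_exponential_core <- function(tvals, time, event) {
  if (any(time <= 0)) stop("survival times must be positive")
  if (sum(event) == 0) stop("exponential model needs at least one event")
  n <- length(time)
  pg <- pattern_groups(tvals, n)
  D <- tabulate(pg$idx[event != 0], nrow(pg$U))
  Tt <- drop(rowsum(time, pg$idx, reorder = TRUE))
  U <- pg$U
  ll_fun <- function(beta) {
    eta <- drop(U %*% beta)
    lam <- exp(eta)
    list(ll = sum(D * eta - Tt * lam),
         grad = drop(crossprod(U, D - Tt * lam)),
         hess = -crossprod(U, U * (Tt * lam)))
  }
  beta0 <- c(log(sum(D) / sum(Tt)), rep(0, ncol(U) - 1L))
  fit <- newton_fit(U, ll_fun, beta0)
  fit$m2loglik <- -2 * fit$loglik
  fit$score <- fit$m2loglik
  fit
}

tree_values <- function(trees, X) {
  if (length(trees) == 0L) {
    return(matrix(integer(0), nrow(X), 0L))
  }
  vapply(trees, function(t) eval_tree(t, X), integer(nrow(X)))
}

fit_trees <- function(trees, outcome, link, X) {
  tvals <- tree_values(trees, X)
  if (link == "logit") {
    fit_logit_core(tvals, outcome$y)
  } else {
    fit_exponential_core(tvals, outcome$time, outcome$event)
  }
}

as_outcome <- function(outcome, link) {
  if (link == "logit") {
    if (is.list(outcome)) outcome else list(y = outcome)
  } else {
    stopifnot(is.list(outcome), !is.null(outcome$time), !is.null(outcome$event))
    outcome
  }
}

#' Score a set of logic trees under the logistic (case-control) likelihood
#'
#' Fits `logit(p) = b0 + sum_j b_j T_j(x)` by exact maximum likelihood and
#' returns the deviance (`-2 loglik`).  Constant tree columns are held at a
#' zero coefficient and flagged `degenerate`; separation (`|beta| > 15`) is
#' flagged, not silently reported.
#'
#' @param trees list of `logic_tree` objects bound to `X`.
#' @param y 0/1 case indicators.
#' @param X indicator matrix.
#' @return list with `deviance`, `coefficients` (intercept first),
#'   `separation`, `degenerate`.
#' @export
score_logit <- function(trees, y, X) {
  if (length(unique(y != 0)) < 2L) {
    stop("need at least one case and one control")
  }
  fit <- fit_trees(trees, list(y = y), "logit", X)
  list(deviance = fit$deviance, coefficients = fit$coef,
       separation = fit$separation, degenerate = fit$degenerate)
}

#' Score a set of logic trees under the exponential survival likelihood
#'
#' Fits `lambda_i = exp(b0 + sum_j b_j T_j(x_i))` with censoring,
#' `loglik = sum(delta_i log lambda_i - lambda_i t_i)`, and returns
#' `-2 loglik` at the MLE.
#'
#' @param trees list of `logic_tree` objects bound to `X`.
#' @param time follow-up times (months, positive).
#' @param event 0/1 event indicators (at least one event).
#' @param X indicator matrix.
#' @return list with `m2loglik`, `coefficients`, `separation`, `degenerate`.
#' @export
score_exponential <- function(trees, time, event, X) {
  fit <- fit_trees(trees, list(time = time, event = event),
                   "exponential", X)
  list(m2loglik = fit$m2loglik, coefficients = fit$coef,
       separation = fit$separation, degenerate = fit$degenerate)
}

# --- simulated annealing ----------------------------------------------------

#' Annealing schedule for the logic-regression search
#'
#' @param start_temperature initial temperature; `NULL` auto-calibrates so
#'   that roughly 90% of initial score-worsening moves are accepted.  A
#'   start temperature of 0 gives greedy hill-climbing.
#' @param end_temperature temperature at which cooling stops.
#' @param n_iterations Metropolis iterations per restart.
#' @param cooling geometric cooling factor per iteration (in (0,1)).
#' @param restarts independent restarts; the best-scoring model is kept.
#' @param seed integer seed making the search deterministic.
#' @export
anneal_schedule <- function(start_temperature = NULL, end_temperature = 1e-3,
                            n_iterations = 25000L, cooling = 0.999,
                            restarts = 10L, seed = NULL) {
  stopifnot(end_temperature > 0, cooling > 0, cooling < 1,
            n_iterations >= 0, restarts >= 1)
  if (!is.null(start_temperature)) {
    stopifnot(start_temperature >= 0)
  }
  structure(list(start_temperature = start_temperature,
                 end_temperature = end_temperature,
                 n_iterations = as.integer(n_iterations),
                 cooling = cooling, restarts = as.integer(restarts),
                 seed = seed),
            class = "anneal_schedule")
}

#' Fit a logic-regression model by simulated annealing
#'
#' Metropolis search over the tree move set with geometric cooling;
#' score-improving moves are always accepted, worsening moves with
#' probability `exp(-delta / temperature)`.  The best-scoring model visited
#' across all restarts is returned.  Deterministic given `schedule$seed`.
#'
#' @param X indicator matrix (0/1).
#' @param outcome for `link = "logit"` a 0/1 vector (or `list(y = )`); for
#'   `link = "exponential"` a `list(time = , event = )`.
#' @param link `"logit"` or `"exponential"`.
#' @param size integer pair `c(n_trees, max_total_leaves)`.
#' @param schedule an [anneal_schedule()].
#' @return a `logic_model`: list with `trees` (canonical), `coefficients`
#'   (intercept first), `link`, `score`, `size`, `separation`.
#' @export
anneal <- function(X, outcome, link = c("logit", "exponential"),
                   size = c(1L, 4L), schedule = anneal_schedule()) {
  link <- match.arg(link)
  outcome <- as_outcome(outcome, link)
  n_trees <- as.integer(size[1L])
  max_leaves <- as.integer(size[2L])
  stopifnot(n_trees >= 1L, max_leaves >= n_trees)
  p <- ncol(X)
  if (!is.null(schedule$seed)) set.seed(schedule$seed)

  best <- NULL
  for (r in seq_len(schedule$restarts)) {
    trees <- replicate(n_trees, random_leaf(p), simplify = FALSE)
    cur_fit <- fit_trees(trees, outcome, link, X)
    cur_score <- cur_fit$score
    if (is.null(best) || cur_score < best$score) {
      best <- list(trees = trees, score = cur_score, fit = cur_fit)
    }
    temp <- schedule$start_temperature
    if (is.null(temp)) {
      # calibrate: accept ~90% of initially worsening moves
      deltas <- numeric(0)
      for (i in seq_len(20L)) {
        j <- if (n_trees == 1L) 1L else sample.int(n_trees, 1L)
        pr <- propose_move(trees[[j]], p, max_leaves)
        if (identical(attr(pr, "move"), "none")) next
        cand <- trees
        cand[[j]] <- pr
        f <- fit_trees(cand, outcome, link, X)
        d <- f$score - cur_score
        if (is.finite(d) && d > 0) deltas <- c(deltas, d)
      }
      temp <- if (length(deltas) > 0) mean(deltas) / (-log(0.9)) else 1
    }
    for (it in seq_len(schedule$n_iterations)) {
      j <- if (n_trees == 1L) 1L else sample.int(n_trees, 1L)
      other_leaves <- if (n_trees == 1L) 0L else
        sum(vapply(trees[-j], n_leaves, integer(1)))
      budget <- max_leaves - other_leaves
      prop <- propose_move(trees[[j]], p, budget)
      if (!identical(attr(prop, "move"), "none")) {
        cand <- trees
        cand[[j]] <- prop
        fit <- fit_trees(cand, outcome, link, X)
        d <- fit$score - cur_score
        if (d <= 0 || (temp > 0 && stats::runif(1) < exp(-d / temp))) {
          trees <- cand
          cur_score <- fit$score
          if (cur_score < best$score) {
            best <- list(trees = trees, score = cur_score, fit = fit)
          }
        }
      }
      temp <- temp * schedule$cooling
      if (temp < schedule$end_temperature) temp <- schedule$end_temperature
    }
  }
  structure(list(trees = lapply(best$trees, canonical_tree),
                 coefficients = best$fit$coef,
                 link = link, score = best$score,
                 size = c(n_trees = n_trees, max_leaves = max_leaves),
                 separation = best$fit$separation,
                 degenerate = best$fit$degenerate),
            class = "logic_model")
}

#' @export
print.logic_model <- function(x, ...) {
  cat("<logic_model> link=", x$link, " score=", format(x$score), "\n", sep = "")
  for (i in seq_along(x$trees)) {
    cat("  tree ", i, ": ", format_tree(x$trees[[i]]),
        "  coef=", format(x$coefficients[i + 1L], digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Evaluate every tree of a logic model on an indicator matrix
#' @param model a `logic_model`.
#' @param X indicator matrix.
#' @return n x n_trees 0/1 matrix.
#' @export
evaluate_model <- function(model, X) {
  tree_values(model$trees, X)
}

# --- cross-validated model-size selection -----------------------------------

stratified_folds <- function(strata, folds) {
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    ix <- which(strata == s)
    fold[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  fold
}

validation_score <- function(trees, coef, outcome, link, X) {
  tvals <- tree_values(trees, X)
  eta <- drop(cbind(1, tvals) %*% coef)
  if (link == "logit") {
    y <- outcome$y != 0
    -2 * sum(y * eta - log1p(exp(eta))) / length(y)
  } else {
    -2 * sum(outcome$event * eta - outcome$time * exp(eta)) /
      length(outcome$time)
  }
}

#' Select logic-model size by stratified K-fold cross-validation
#'
#' For each candidate size (number of trees, maximum total leaves) the model
#' is fitted by [anneal()] on each training fold and scored on the held-out
#' fold (per-subject predictive deviance for the logistic link, per-subject
#' `-2 loglik` for the exponential link).  The size minimising the mean
#' validation score is chosen; ties go to fewer total leaves, then fewer
#' trees.  Folds are stratified by outcome class (logit) or event status
#' (exponential).
#'
#' @inheritParams anneal
#' @param grid data frame with columns `n_trees` and `max_leaves`.
#' @param folds number of folds (>= 2).
#' @return a `cv_selection`: list with `grid` (with a `cv_score` column),
#'   `chosen` (`c(n_trees, max_leaves)`) and `folds`.
#' @export
cv_select <- function(X, outcome, link = c("logit", "exponential"),
                      grid = cv_grid(), folds = 10L,
                      schedule = anneal_schedule()) {
  link <- match.arg(link)
  outcome <- as_outcome(outcome, link)
  stopifnot(folds >= 2L, nrow(grid) >= 1L)
  if (!is.null(schedule$seed)) set.seed(schedule$seed)
  strata <- if (link == "logit") outcome$y != 0 else outcome$event != 0
  if (min(table(strata)) < folds) {
    stop("cannot stratify ", folds, " folds: smallest outcome class has ",
         min(table(strata)), " subjects")
  }
  fold <- stratified_folds(strata, folds)
  inner <- schedule
  inner$seed <- NULL  # one master seed governs the whole CV stream
  scores <- matrix(NA_real_, nrow(grid), folds)
  for (g in seq_len(nrow(grid))) {
    for (f in seq_len(folds)) {
      tr <- fold != f
      out_tr <- lapply(outcome, function(v) v[tr])
      out_va <- lapply(outcome, function(v) v[!tr])
      m <- anneal(X[tr, , drop = FALSE], out_tr, link,
                  size = c(grid$n_trees[g], grid$max_leaves[g]),
                  schedule = inner)
      scores[g, f] <- validation_score(m$trees, m$coefficients, out_va,
                                       link, X[!tr, , drop = FALSE])
    }
  }
  grid$cv_score <- rowMeans(scores)
  ord <- order(round(grid$cv_score, 9), grid$max_leaves, grid$n_trees)
  chosen <- grid[ord[1L], c("n_trees", "max_leaves")]
  structure(list(grid = grid,
                 chosen = c(n_trees = chosen$n_trees,
                            max_leaves = chosen$max_leaves),
                 folds = folds),
            class = "cv_selection")
}

#' Default model-size grid: 1-2 trees, 1-8 total leaves
#' @param n_trees,max_leaves candidate values.
#' @export
cv_grid <- function(n_trees = 1:2, max_leaves = 1:8) {
  g <- expand.grid(n_trees = n_trees, max_leaves = max_leaves)
  g <- g[g$max_leaves >= g$n_trees, , drop = FALSE]
  rownames(g) <- NULL
  g
}

# --- Step 1: gene-specific trees --------------------------------------------

#' Build the gene-specific tree (GST) for one gene
#'
#' Step 1 of the framework: cross-validated size selection followed by a
#' full-data annealing fit restricted to the gene's dominant/recessive
#' indicator columns.  The single best tree becomes the GST (if CV selects a
#' two-tree model the tree with the larger `|coefficient|` is kept and the
#' event noted); its De Morgan complement, refitted coefficient and carrier
#' prevalence are attached.  A monomorphic gene (all indicator columns
#' constant) yields a GST flagged `degenerate` and is excluded downstream.
#'
#' @param gene gene symbol.
#' @param X_gene indicator columns of this gene (from [gene_columns()]).
#' @inheritParams cv_select
#' @return a `gst` object.
#' @export
build_gst <- function(gene, X_gene, outcome, link = c("logit", "exponential"),
                      grid = cv_grid(), folds = 10L,
                      schedule = anneal_schedule()) {
  link <- match.arg(link)
  outcome <- as_outcome(outcome, link)
  keep <- apply(X_gene, 2L, function(v) stats::var(v) > 0)
  if (!any(keep)) {
    return(structure(list(gene = gene, degenerate = TRUE), class = "gst"))
  }
  Xs <- X_gene[, keep, drop = FALSE]
  grid_g <- grid[grid$max_leaves <= max(8L, ncol(Xs)), , drop = FALSE]
  cv <- if (nrow(grid_g) > 1L) {
    cv_select(Xs, outcome, link, grid_g, folds, schedule)
  } else {
    list(grid = grid_g,
         chosen = c(n_trees = grid_g$n_trees[1], max_leaves = grid_g$max_leaves[1]))
  }
  model <- anneal(Xs, outcome, link, size = cv$chosen, schedule = schedule)
  note <- NULL
  tree <- if (length(model$trees) > 1L) {
    note <- "cv selected a 2-tree model; kept the larger-|coefficient| tree"
    model$trees[[which.max(abs(model$coefficients[-1L]))]]
  } else {
    model$trees[[1L]]
  }
  tree <- canonical_tree(bind_tree_names(tree, colnames(Xs)))
  refit <- fit_trees(list(tree), outcome, link, X_gene)
  vals <- eval_tree(tree, X_gene)
  structure(list(gene = gene,
                 tree = tree,
                 complement = canonical_tree(tree_complement(tree)),
                 coefficient = refit$coef[2L],
                 prevalence = mean(vals),
                 link = link,
                 cv = cv,
                 separation = refit$separation,
                 degenerate = FALSE,
                 note = note),
            class = "gst")
}

#' @export
print.gst <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<gst> ", x$gene, " [degenerate: monomorphic]\n", sep = "")
  } else {
    cat("<gst> ", x$gene, ": ", format_tree(x$tree),
        "  coef=", format(x$coefficient, digits = 4),
        "  prevalence=", format(x$prevalence, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Build GSTs for every gene on the pathway
#'
#' @param X full `indicator_matrix` (with provenance).
#' @inheritParams build_gst
#' @param genes gene symbols; defaults to every gene in the provenance map.
#' @return named list of `gst` objects.
#' @export
build_gsts <- function(X, outcome, link = c("logit", "exponential"),
                       genes = NULL, grid = cv_grid(), folds = 10L,
                       schedule = anneal_schedule()) {
  link <- match.arg(link)
  prov <- attr(X, "provenance")
  if (is.null(genes)) genes <- unique(prov$gene)
  if (!is.null(schedule$seed)) set.seed(schedule$seed)
  inner <- schedule
  inner$seed <- NULL
  out <- lapply(genes, function(g) {
    build_gst(g, gene_columns(X, g), outcome, link, grid, folds, inner)
  })
  stats::setNames(out, genes)
}

#' 0/1 GST columns for a set of subjects
#'
#' Evaluates each non-degenerate GST on the full indicator matrix, giving
#' the subjects x genes binary matrix that Steps 2 and 3 operate on.
#'
#' @param gsts named list of `gst` objects.
#' @param X full `indicator_matrix`.
#' @export
gst_columns <- function(gsts, X) {
  ok <- !vapply(gsts, function(g) isTRUE(g$degenerate), logical(1))
  vals <- vapply(gsts[ok], function(g) eval_tree(g$tree, X), integer(nrow(X)))
  colnames(vals) <- names(gsts)[ok]
  vals
}

# --- Step 2: pathway trees ---------------------------------------------------

#' Build pathway trees over the GST columns
#'
#' Step 2: logic regression in which the leaves are the 0/1 GST columns
#' (gene-level Boolean profiles).  The fitted trees are evaluated to 0/1
#' pathway-tree columns that serve as adjustment covariates in the Step-3
#' GEI models.
#'
#' @param gst_cols subjects x genes 0/1 matrix from [gst_columns()].
#' @inheritParams cv_select
#' @return a `logic_model` whose trees are bound to the gene column names.
#' @export
build_pathway_trees <- function(gst_cols, outcome,
                                link = c("logit", "exponential"),
                                grid = cv_grid(), folds = 10L,
                                schedule = anneal_schedule()) {
  link <- match.arg(link)
  if (ncol(gst_cols) < 2L) {
    stop("pathway-tree search needs at least 2 non-degenerate GSTs")
  }
  outcome <- as_outcome(outcome, link)
  if (!is.null(schedule$seed)) set.seed(schedule$seed)
  inner <- schedule
  inner$seed <- NULL
  cv <- if (nrow(grid) > 1L) {
    cv_select(gst_cols, outcome, link, grid, folds, inner)
  } else {
    list(grid = grid, chosen = c(n_trees = grid$n_trees[1],
                                 max_leaves = grid$max_leaves[1]))
  }
  model <- anneal(gst_cols, outcome, link, size = cv$chosen, schedule = inner)
  model$trees <- lapply(model$trees, function(t) {
    canonical_tree(bind_tree_names(t, colnames(gst_cols)))
  })
  model$cv <- cv
  model
}

#' GST summary table (one row per gene)
#'
#' @param gsts named list of `gst` objects.
#' @param X indicator matrix (for case/control prevalences).
#' @param case 0/1 case indicator aligned with `X` rows.
#' @export
gst_table <- function(gsts, X, case = NULL) {
  rows <- lapply(gsts, function(g) {
    if (isTRUE(g$degenerate)) {
      return(data.frame(gene = g$gene, tree = NA, complement = NA,
                        prevalence = NA, prev_cases = NA, prev_controls = NA,
                        coefficient = NA, stringsAsFactors = FALSE))
    }
    v <- eval_tree(g$tree, X)
    data.frame(gene = g$gene,
               tree = format_tree(g$tree),
               complement = format_tree(g$complement),
               prevalence = round(g$prevalence, 4),
               prev_cases = if (is.null(case)) NA else round(mean(v[case != 0]), 4),
               prev_controls = if (is.null(case)) NA else round(mean(v[case == 0]), 4),
               coefficient = round(g$coefficient, 4),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
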