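#' Boolean logic trees over binary indicator columns
#'
#' A logic tree is a binary tree whose internal nodes carry the operators
#' `"and"` / `"or"` and whose leaves reference a column of a binary indicator
#' matrix, optionally complemented.  Trees are the predictors of logic
#' regression: a gene-specific tree (GST) is a logic tree over one gene's
#' dominant/recessive SNP indicators, a pathway tree is a logic tree over
#' GST columns.
#'
#' Leaves may reference columns by integer index or by column name; names
#' make a tree portable across matrices that share column names.
#'
#' @param col column reference (integer index or character name).
#' @param neg logical; `TRUE` evaluates the logical complement of the column.
#' @return a `logic_tree` object.
#' @examples
#' X <- cbind(a = c(1, 1, 0), b = c(1, 0, 0))
#' t <- logic_and(logic_leaf("a"), logic_leaf("b", neg = TRUE))
#' eval_tree(t, X)
#' @export
logic_leaf <- function(col, neg = FALSE) {
  stopifnot(length(col) == 1L, is.logical(neg), length(neg) == 1L)
  structure(list(op = "leaf", col = col, neg = neg), class = "logic_tree")
}

#' @rdname logic_leaf
#' @param left,right child subtrees.
#' @export
logic_and <- function(left, right) logic_node("and", left, right)

#' @rdname logic_leaf
#' @export
logic_or <- function(left, right) logic_node("or", left, right)

#' @rdname logic_leaf
#' @param op operator, `"and"` or `"or"`.
#' @export
logic_node <- function(op, left, right) {
  op <- match.arg(op, c("and", "or"))
  structure(list(op = op, left = left, right = right), class = "logic_tree")
}

is_leaf <- function(tree) identical(tree$op, "leaf")

#' Number of leaves of a logic tree
#' @param tree a `logic_tree`.
#' @export
n_leaves <- function(tree) {
  if (is_leaf(tree)) 1L else n_leaves(tree$left) + n_leaves(tree$right)
}

#' Leaves of a logic tree
#'
#' @param tree a `logic_tree`.
#' @return data frame with columns `col` and `neg`, one row per leaf in
#'   left-to-right order.
#' @export
tree_leaves <- function(tree) {
  if (is_leaf(tree)) {
    data.frame(col = I(list(tree$col)), neg = tree$neg)
  } else {
    rbind(tree_leaves(tree$left), tree_leaves(tree$right))
  }
}

#' Evaluate a logic tree on an indicator matrix
#'
#' Missing indicator values evaluate as 0 (predicate false), so evaluation
#' is total even on incomplete genotype data.
#'
#' @param tree a `logic_tree` bound to `X`'s columns.
#' @param X numeric or logical matrix of 0/1 indicators.
#' @return integer vector of 0/1, one entry per row of `X`.
#' @export
eval_tree <- function(tree, X) {
  as.integer(eval_tree_l(tree, X))
}

eval_tree_l <- function(tree, X) {
  if (is_leaf(tree)) {
    col <- tree$col
    if (is.character(col) && !col %in% colnames(X)) {
      stop("logic tree leaf references unknown column '", col, "'")
    }
    if (is.numeric(col) && (col < 1L || col > ncol(X))) {
      stop("logic tree leaf references column index ", col,
           " outside 1..", ncol(X))
    }
    v <- X[, col] != 0
    v[is.na(v)] <- FALSE
    if (tree$neg) !v else v
  } else if (tree$op == "and") {
    eval_tree_l(tree$left, X) & eval_tree_l(tree$right, X)
  } else {
    eval_tree_l(tree$left, X) | eval_tree_l(tree$right, X)
  }
}

#' De Morgan complement of a logic tree
#'
#' Swaps AND and OR and flips every leaf's complement flag, producing a tree
#' that evaluates to the pointwise logical NOT of the input tree.  This is
#' how the complement of a GST (e.g. "carriers" vs "non-carriers" of a
#' Boolean genotype profile) is represented without a NOT node.
#'
#' @param tree a `logic_tree`.
#' @return the complemented `logic_tree`.
#' @export
tree_complement <- function(tree) {
  if (is_leaf(tree)) {
    logic_leaf(tree$col, !tree$neg)
  } else {
    logic_node(if (tree$op == "and") "or" else "and",
               tree_complement(tree$left), tree_complement(tree$right))
  }
}

#' Canonical form of a logic tree
#'
#' Sorts the two children of every (commutative) internal node by their
#' serialized form so that equivalent trees found in different search runs
#' print identically.
#'
#' @param tree a `logic_tree`.
#' @export
canonical_tree <- function(tree) {
  if (is_leaf(tree)) return(tree)
  l <- canonical_tree(tree$left)
  r <- canonical_tree(tree$right)
  if (format_tree(l) > format_tree(r)) {
    logic_node(tree$op, r, l)
  } else {
    logic_node(tree$op, l, r)
  }
}

#' Serialize a logic tree to text
#'
#' Produces the parenthesized form, e.g. `"(rs1927911_dom AND rs11536889_rec^c)"`,
#' where `^c` marks a complemented leaf.  With `labels` a named character
#' vector mapping column references to display labels (e.g. genotype labels
#' such as `"CC or CT"`), leaves are rendered with those labels instead.
#'
#' @param tree a `logic_tree`.
#' @param labels optional named character vector of leaf display labels.
#' @export
format_tree <- function(tree, labels = NULL) {
  if (is_leaf(tree)) {
    key <- as.character(tree$col)
    lab <- if (!is.null(labels) && key %in% names(labels)) labels[[key]] else key
    if (tree$neg) paste0(lab, "^c") else lab
  } else {
    paste0("(", format_tree(tree$left, labels), " ", toupper(tree$op), " ",
           format_tree(tree$right, labels), ")")
  }
}

#' @export
print.logic_tree <- function(x, ...) {
  cat("<logic_tree> ", format_tree(x), "\n", sep = "")
  invisible(x)
}

#' Parse the text serialization of a logic tree
#'
#' Inverse of [format_tree()] for unlabelled output.  Column references that
#' look like integers are parsed as indices, everything else as column names.
#'
#' @param text tree text, e.g. `"(a AND b^c)"`.
#' @export
parse_tree <- function(text) {
  toks <- regmatches(text, gregexpr("\\(|\\)|AND|OR|[^()[:space:]]+", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_node <- function() {
    t <- take()
    if (identical(t, "(")) {
      left <- parse_node()
      op <- take()
      if (!op %in% c("AND", "OR")) stop("expected AND/OR, got '", op, "'")
      right <- parse_node()
      if (!identical(take(), ")")) stop("expected ')'")
      logic_node(tolower(op), left, right)
    } else {
      neg <- grepl("\\^c$", t)
      ref <- sub("\\^c$", "", t)
      if (grepl("^[0-9]+$", ref)) ref <- as.integer(ref)
      logic_leaf(ref, neg)
    }
  }
  out <- parse_node()
  if (pos <= length(toks)) stop("trailing tokens in tree text")
  out
}

#' Convert a logic tree to/from a plain list (JSON round-trip)
#'
#' @param tree a `logic_tree`.
#' @export
tree_to_list <- function(tree) {
  if (is_leaf(tree)) {
    list(op = "leaf", col = tree$col, neg = tree$neg)
  } else {
    list(op = tree$op, left = tree_to_list(tree$left),
         right = tree_to_list(tree$right))
  }
}

#' @rdname tree_to_list
#' @param x a plain list as produced by [tree_to_list()] (or parsed from JSON).
#' @export
tree_from_list <- function(x) {
  if (identical(x$op, "leaf")) {
    logic_leaf(x$col, isTRUE(x$neg))
  } else {
    logic_node(x$op, tree_from_list(x$left), tree_from_list(x$right))
  }
}

#' Rebind integer leaf references to column names
#'
#' After a search over an indicator matrix, leaves hold integer column
#' indices; rebinding to the matrix's column names makes the tree portable.
#'
#' @param tree a `logic_tree` with integer leaf references.
#' @param cols character vector of column names (e.g. `colnames(X)`).
#' @export
bind_tree_names <- function(tree, cols) {
  if (is_leaf(tree)) {
    col <- tree$col
    if (is.numeric(col)) col <- cols[[col]]
    logic_leaf(col, tree$neg)
  } else {
    logic_node(tree$op, bind_tree_names(tree$left, cols),
               bind_tree_names(tree$right, cols))
  }
}

# --- annealing move set -----------------------------------------------------

# Paths to all nodes: list of integer vectors (2 = left, 3 = right child slot),
# root = integer(0).  leaf flag alongside.
tree_paths <- function(tree, path = integer(0)) {
  if (is_leaf(tree)) {
    list(list(path = path, leaf = TRUE))
  } else {
    c(list(list(path = path, leaf = FALSE)),
      tree_paths(tree$left, c(path, 2L)),
      tree_paths(tree$right, c(path, 3L)))
  }
}

subtree_at <- function(tree, path) {
  for (i in path) tree <- tree[[i]]
  tree
}

replace_at <- function(tree, path, new) {
  if (length(path) == 0L) return(new)
  tree[[path[1L]]] <- replace_at(tree[[path[1L]]], path[-1L], new)
  tree
}

random_leaf <- function(n_cols, exclude = NULL) {
  repeat {
    l <- logic_leaf(sample.int(n_cols, 1L), sample(c(FALSE, TRUE), 1L))
    if (is.null(exclude) ||
        !(identical(l$col, exclude$col) && identical(l$neg, exclude$neg))) {
      return(l)
    }
  }
}

#' Propose one annealing move on a logic tree
#'
#' Applies one move from the standard logic-regression move set:
#' alternate-leaf, alternate-operator, grow-branch, prune-branch, split-leaf,
#' delete-leaf.  The move type is drawn uniformly from the types that are
#' legal for the current tree (a single-leaf tree admits only alternate-leaf
#' and split-leaf; growing moves are disabled at the leaf-count bound).
#' Uses the ambient RNG: seed the session for reproducibility.
#'
#' @param tree a `logic_tree` with integer leaf references.
#' @param n_cols number of indicator columns available.
#' @param max_leaves maximum leaf count the result may have.
#' @param moves character vector restricting the admissible move types.
#' @return the proposed `logic_tree`, with attribute `"move"` naming the move
#'   applied (`"none"` if no legal move existed).
#' @export
propose_move <- function(tree, n_cols, max_leaves = 8L,
                         moves = c("alternate_leaf", "alternate_operator",
                                   "grow_branch", "prune_branch",
                                   "split_leaf", "delete_leaf")) {
  nl <- n_leaves(tree)
  has_internal <- nl >= 2L
  legal <- character(0)
  if ("alternate_leaf" %in% moves && (2L * n_cols) > 1L) {
    legal <- c(legal, "alternate_leaf")
  }
  if ("alternate_operator" %in% moves && has_internal) {
    legal <- c(legal, "alternate_operator")
  }
  if ("grow_branch" %in% moves && has_internal && nl < max_leaves) {
    legal <- c(legal, "grow_branch")
  }
  if ("prune_branch" %in% moves && has_internal) {
    legal <- c(legal, "prune_branch")
  }
  if ("split_leaf" %in% moves && nl < max_leaves) {
    legal <- c(legal, "split_leaf")
  }
  if ("delete_leaf" %in% moves && has_internal) {
    legal <- c(legal, "delete_leaf")
  }
  if (length(legal) == 0L) {
    return(structure(tree, move = "none"))
  }
  mv <- if (length(legal) == 1L) legal else sample(legal, 1L)
  paths <- tree_paths(tree)
  leaves <- Filter(function(p) p$leaf, paths)
  internals <- Filter(function(p) !p$leaf, paths)
  pick <- function(xs) xs[[if (length(xs) == 1L) 1L else sample.int(length(xs), 1L)]]
  new <- switch(mv,
    alternate_leaf = {
      p <- pick(leaves)
      old <- subtree_at(tree, p$path)
      replace_at(tree, p$path, random_leaf(n_cols, exclude = old))
    },
    alternate_operator = {
      p <- pick(internals)
      nd <- subtree_at(tree, p$path)
      replace_at(tree, p$path,
                 logic_node(if (nd$op == "and") "or" else "and",
                            nd$left, nd$right))
    },
    grow_branch = {
      p <- pick(internals)
      nd <- subtree_at(tree, p$path)
      replace_at(tree, p$path,
                 logic_node(sample(c("and", "or"), 1L), nd, random_leaf(n_cols)))
    },
    prune_branch = {
      p <- pick(internals)
      nd <- subtree_at(tree, p$path)
      keep <- if (sample(c(TRUE, FALSE), 1L)) nd$left else nd$right
      replace_at(tree, p$path, keep)
    },
    split_leaf = {
      p <- pick(leaves)
      nd <- subtree_at(tree, p$path)
      replace_at(tree, p$path,
                 logic_node(sample(c("and", "or"), 1L), nd, random_leaf(n_cols)))
    },
    delete_leaf = {
      # remove a leaf that has a parent; the sibling is promoted
      deep <- Filter(function(p) length(p$path) > 0L, leaves)
      p <- pick(deep)
      parent_path <- p$path[-length(p$path)]
      parent <- subtree_at(tree, parent_path)
      sib <- if (p$path[length(p$path)] == 2L) parent$right else parent$left
      replace_at(tree, parent_path, sib)
    })
  structure(new, move = mv)
}

# --- exhaustive enumeration (test oracle) -----------------------------------

#' Enumerate all logic trees up to Boolean equivalence
#'
#' Exhaustively builds every tree with at most `max_leaves` leaves over
#' `n_columns` indicator columns and deduplicates by truth table over all
#' `2^n_columns` input rows.  Intended as an exact oracle for the annealing
#' search on small instances; refuses instances beyond the enumeration bound.
#'
#' @param n_columns number of binary columns (at most 6).
#' @param max_leaves maximum leaves per tree (at most 3).
#' @return list with `trees` (canonical representative per equivalence class)
#'   and `truth` (classes x `2^n_columns` 0/1 matrix of truth tables, rows
#'   aligned with `trees`; the input grid is `expand.grid` of 0/1 per column,
#'   first column fastest).
#' @export
enumerate_trees <- function(n_columns, max_leaves) {
  if (n_columns > 6L || max_leaves > 3L) {
    stop("enumeration bounded to <= 6 columns and <= 3 leaves")
  }
  grid <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n_columns)))
  colnames(grid) <- NULL
  by_size <- vector("list", max_leaves)
  by_size[[1L]] <- unlist(lapply(seq_len(n_columns), function(j) {
    list(logic_leaf(j, FALSE), logic_leaf(j, TRUE))
  }), recursive = FALSE)
  if (max_leaves >= 2L) {
    for (L in 2:max_leaves) {
      acc <- list()
      for (i in seq_len(L - 1L)) {
        for (t1 in by_size[[i]]) {
          for (t2 in by_size[[L - i]]) {
            acc <- c(acc, list(logic_and(t1, t2), logic_or(t1, t2)))
          }
        }
      }
      # prune within-size duplicates to bound growth
      keys <- vapply(acc, function(t) paste(eval_tree(t, grid), collapse = ""),
                     character(1))
      by_size[[L]] <- acc[!duplicated(keys)]
    }
  }
  all_trees <- unlist(by_size, recursive = FALSE)
  tt <- t(vapply(all_trees, function(t) eval_tree(t, grid),
                 integer(nrow(grid))))
  keep <- !duplicated(apply(tt, 1L, paste, collapse = ""))
  list(trees = lapply(all_trees[keep], canonical_tree),
       truth = tt[keep, , drop = FALSE])
}
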