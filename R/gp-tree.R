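# Expression trees for symbolic feature synthesis. Leaves are feature names;
# inner nodes are operators in {+, -, *, /, log, sqrt}. Depth is counted in
# edges on the longest root-to-leaf path, so a bare leaf has depth 0 and the
# depth-3 budget allows up to 8 leaves.

.GP_BINARY <- c("+", "-", "*", "/")
.GP_UNARY <- c("log", "sqrt")

#' Build expression-tree nodes
#'
#' `gp_leaf(name)` makes a terminal referencing a feature column;
#' `gp_op(op, ...)` an operator node (`log`/`sqrt` take one child,
#' `+ - * /` two).
#'
#' @param name Feature name (character scalar).
#' @param op Operator string.
#' @param ... Child trees.
#' @return A `gp_tree`.
#' @export
gp_leaf <- function(name) {
  structure(list(type = "leaf", name = name), class = "gp_tree")
}

#' @rdname gp_leaf
#' @export
gp_op <- function(op, ...) {
  args <- list(...)
  arity <- if (op %in% .GP_UNARY) 1L else if (op %in% .GP_BINARY) 2L else
    stop("unknown operator: ", op)
  if (length(args) != arity) stop("operator ", op, " takes ", arity, " argument(s)")
  structure(list(type = "op", op = op, args = args), class = "gp_tree")
}

#' Tree depth in edges
#' @param tree A `gp_tree`.
#' @return Integer depth; 0 for a bare leaf.
#' @export
tree_depth <- function(tree) {
  if (tree$type == "leaf") return(0L)
  1L + max(vapply(tree$args, tree_depth, 0L))
}

#' Structural validity of a tree
#'
#' Checks arity, operator membership, leaf names and the depth bound.
#'
#' @param tree A `gp_tree`.
#' @param features Allowed leaf names.
#' @param max_depth Depth bound in edges.
#' @return Logical scalar.
#' @export
tree_valid <- function(tree, features, max_depth) {
  ok <- function(nd) {
    if (!is.list(nd) || is.null(nd$type)) return(FALSE)
    if (nd$type == "leaf") return(nd$name %in% features)
    if (nd$type != "op") return(FALSE)
    arity <- if (nd$op %in% .GP_UNARY) 1L else if (nd$op %in% .GP_BINARY) 2L else
      return(FALSE)
    length(nd$args) == arity && all(vapply(nd$args, ok, TRUE))
  }
  ok(tree) && tree_depth(tree) <= max_depth
}

#' Canonical infix expression string
#'
#' Binary subexpressions are parenthesized, unary operators rendered as
#' function calls, e.g. `"((TG*AST)+GLU)"`. The string is a valid R
#' expression and [parse_expression()] restores an equivalent tree.
#'
#' @param tree A `gp_tree`.
#' @return Character scalar.
#' @export
format_tree <- function(tree) {
  if (tree$type == "leaf") return(tree$name)
  if (tree$op %in% .GP_UNARY)
    return(paste0(tree$op, "(", format_tree(tree$args[[1]]), ")"))
  paste0("(", format_tree(tree$args[[1]]), tree$op, format_tree(tree$args[[2]]), ")")
}

#' @export
print.gp_tree <- function(x, ...) {
  cat("<gp_tree depth", tree_depth(x), ">", format_tree(x), "\n")
  invisible(x)
}

#' Parse an infix expression string back into a tree
#'
#' Accepts any R-parsable arithmetic over feature names with the operators
#' `+ - * / log sqrt`; parentheses are free.
#'
#' @param text Expression string, e.g. `"TG+log(ALT)"`.
#' @return A `gp_tree`.
#' @export
parse_expression <- function(text) {
  conv <- function(e) {
    if (is.name(e)) return(gp_leaf(as.character(e)))
    if (is.call(e)) {
      fn <- as.character(e[[1]])
      if (fn == "(") return(conv(e[[2]]))
      if (fn %in% .GP_UNARY) return(gp_op(fn, conv(e[[2]])))
      if (fn %in% .GP_BINARY && length(e) == 3)
        return(gp_op(fn, conv(e[[2]]), conv(e[[3]])))
    }
    stop("cannot parse expression node: ", deparse(e))
  }
  conv(str2lang(text))
}

#' Evaluate a tree over a cohort table
#'
#' Operators are protected so evaluation is total on finite inputs:
#' `log(x) = log(|x|)` with `log(0) = 0`, `sqrt(x) = sqrt(|x|)`, and
#' `x / y = 1` whenever `|y| < 1e-12`.
#'
#' @param tree A `gp_tree`.
#' @param table Data frame holding every leaf feature (complete, i.e. run
#'   after imputation).
#' @return Numeric vector with one value per row.
#' @export
evaluate_tree <- function(tree, table) {
  ev <- function(nd) {
    if (nd$type == "leaf") {
      if (is.null(table[[nd$name]]))
        stop("unknown feature in expression: ", nd$name)
      return(as.numeric(table[[nd$name]]))
    }
    switch(nd$op,
      "+" = ev(nd$args[[1]]) + ev(nd$args[[2]]),
      "-" = ev(nd$args[[1]]) - ev(nd$args[[2]]),
      "*" = ev(nd$args[[1]]) * ev(nd$args[[2]]),
      "/" = {
        num <- ev(nd$args[[1]]); den <- ev(nd$args[[2]])
        ifelse(abs(den) < 1e-12, 1, num / den)
      },
      "log" = {
        x <- ev(nd$args[[1]])
        ifelse(x == 0, 0, log(abs(x)))
      },
      "sqrt" = sqrt(abs(ev(nd$args[[1]]))),
      stop("unknown operator: ", nd$op)
    )
  }
  ev(tree)
}

# All node positions as root-relative paths (root = integer(0)).
tree_paths <- function(tree) {
  out <- list(integer(0))
  if (tree$type == "op") {
    for (i in seq_along(tree$args)) {
      sub <- tree_paths(tree$args[[i]])
      out <- c(out, lapply(sub, function(p) c(i, p)))
    }
  }
  out
}

subtree_at <- function(tree, path) {
  for (i in path) tree <- tree$args[[i]]
  tree
}

replace_at <- function(tree, path, sub) {
  if (length(path) == 0) return(sub)
  tree$args[[path[1]]] <- replace_at(tree$args[[path[1]]], path[-1], sub)
  tree
}

#' Grow a random expression tree
#'
#' Grow-style initialization: at depth `d` a node is a leaf with probability
#' `(d + 1) / (max_depth + 1)` (a forced leaf at `max_depth`); otherwise an
#' operator is drawn uniformly from `{+, -, *, /, log, sqrt}`. Uses the
#' current RNG state — seed the session (or wrap in `withr::with_seed`) for
#' reproducibility.
#'
#' @param features Candidate leaf names.
#' @param max_depth Depth budget in edges.
#' @return A `gp_tree` with `tree_depth(tree) <= max_depth`.
#' @export
random_tree <- function(features, max_depth) {
  grow <- function(d) {
    if (d >= max_depth || stats::runif(1) < (d + 1) / (max_depth + 1))
      return(gp_leaf(features[sample.int(length(features), 1)]))
    op <- c(.GP_BINARY, .GP_UNARY)[sample.int(6, 1)]
    if (op %in% .GP_UNARY) gp_op(op, grow(d + 1))
    else gp_op(op, grow(d + 1), grow(d + 1))
  }
  grow(0L)
}

#' Subtree crossover
#'
#' Replaces a uniformly chosen subtree of `a` with a uniformly chosen subtree
#' of `b`. If the child exceeds `max_depth` the draw is retried up to
#' `retries` times, after which a copy of `a` is returned; the result is
#' always a valid tree within the depth bound.
#'
#' @param a,b Parent trees.
#' @param max_depth Depth bound.
#' @param retries Resampling attempts before falling back to `a`.
#' @return A `gp_tree`.
#' @export
crossover <- function(a, b, max_depth, retries = 8L) {
  pa <- tree_paths(a)
  pb <- tree_paths(b)
  for (i in seq_len(retries)) {
    child <- replace_at(a, pa[[sample.int(length(pa), 1)]],
                        subtree_at(b, pb[[sample.int(length(pb), 1)]]))
    if (tree_depth(child) <= max_depth) return(child)
  }
  a
}

#' Subtree mutation
#'
#' Replaces a uniformly chosen subtree with a fresh [random_tree()] grown to
#' the depth budget remaining at that position, so the result always
#' satisfies the depth bound.
#'
#' @param tree Tree to mutate.
#' @param features Candidate leaf names.
#' @param max_depth Depth bound.
#' @return A `gp_tree`.
#' @export
mutate <- function(tree, features, max_depth) {
  paths <- tree_paths(tree)
  p <- paths[[sample.int(length(paths), 1)]]
  replace_at(tree, p, random_tree(features, max_depth - length(p)))
}
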