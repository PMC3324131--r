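# Boolean trees: leaves are (variable, negated?) literals, internal
# nodes are AND/OR. Used by the logic-regression learner and the
# planted-rule generator.

#' Construct a Boolean tree
#'
#' `btree_leaf(v)` is the literal x_v (negated when `neg`);
#' `btree(op, l, r)` combines two subtrees with `"and"` or `"or"`.
#'
#' @param op `"and"` or `"or"`
#' @param l,r subtrees
#' @return object of class `btree`
#' @export
btree <- function(op = c("and", "or"), l, r) {
  op <- match.arg(op)
  stopifnot(inherits(l, "btree"), inherits(r, "btree"))
  structure(list(type = "op", op = op, l = l, r = r), class = "btree")
}

#' @rdname btree
#' @param var covariate index (1-based)
#' @param neg negate the literal
#' @export
btree_leaf <- function(var, neg = FALSE) {
  structure(list(type = "leaf", var = as.integer(var), neg = isTRUE(neg)),
            class = "btree")
}

#' Evaluate a Boolean tree on binary rows
#' @param tree a `btree`
#' @param X binary matrix (rows = observations)
#' @return 0/1 numeric vector, one value per row
#' @export
eval_btree <- function(tree, X) {
  if (tree$type == "leaf") {
    v <- X[, tree$var]
    return(if (tree$neg) 1 - v else v + 0)
  }
  l <- eval_btree(tree$l, X)
  r <- eval_btree(tree$r, X)
  if (tree$op == "and") l * r else l + r - l * r
}

#' Variables appearing at the leaves of a Boolean tree
#' @param tree a `btree`
#' @return sorted unique covariate indices
#' @export
btree_vars <- function(tree) {
  if (tree$type == "leaf") return(tree$var)
  sort(unique(c(btree_vars(tree$l), btree_vars(tree$r))))
}

btree_n_leaves <- function(tree) {
  if (tree$type == "leaf") return(1L)
  btree_n_leaves(tree$l) + btree_n_leaves(tree$r)
}

#' Truth table of a Boolean tree over its variables
#'
#' Enumerates all assignments of the tree's variables; two trees are
#' Boolean-equivalent iff their tables (over the union of their
#' variables) agree.
#'
#' @param tree a `btree`
#' @param vars variable indices to enumerate (default: the tree's own)
#' @return 0/1 vector of length `2^length(vars)`, assignments in binary
#'   counting order
#' @export
btree_truth_table <- function(tree, vars = btree_vars(tree)) {
  stopifnot(all(btree_vars(tree) %in% vars))
  k <- length(vars)
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))
  X <- matrix(0, nrow(grid), max(vars))
  X[, vars] <- grid
  eval_btree(tree, X)
}

#' @export
format.btree <- function(x, ...) {
  if (x$type == "leaf") {
    paste0(if (x$neg) "!", "x", x$var)
  } else {
    paste0("(", format(x$l), if (x$op == "and") " & " else " | ",
           format(x$r), ")")
  }
}

#' @export
print.btree <- function(x, ...) {
  cat("<btree>", format(x), "\n")
  invisible(x)
}
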