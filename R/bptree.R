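#' Succinct balanced-parentheses phylogenetic tree
#'
#' A rooted (possibly multifurcating) tree stored as a length-2n balanced
#' parenthesis (BP) bit vector, where every node is one open/close pair and
#' subtrees are nested intervals. Node names and branch lengths are carried
#' per node in preorder; a missing branch length is `NA`, which is distinct
#' from a zero-length branch. Navigation queries are answered in O(1) from
#' rank/select-style indices precomputed at construction; succinctness of
#' space is not a goal, correctness of the navigation algebra is.
#'
#' Nodes are addressed by the 1-based position of their opening parenthesis
#' in the bit vector (the "opening position"), the convention every
#' navigation function below uses. `bp_preorder_select()` and
#' `bp_postorder_select()` convert traversal ranks to opening positions.
#'
#' @param bits logical vector of length 2n, `TRUE` = open parenthesis. Must
#'   be balanced (running excess never negative, zero at the end).
#' @param names character vector of length n, node names in preorder. Empty
#'   string for unnamed nodes.
#' @param lengths numeric vector of length n, branch lengths in preorder;
#'   `NA` where the input recorded no length.
#' @param allow_duplicate_tips if `FALSE` (default) duplicate tip names are
#'   an error; if `TRUE` duplicates are made unique by suffixing `_1`,
#'   `_2`, ... in preorder.
#' @return an object of class `bptree`.
#' @export
bptree <- function(bits, names, lengths, allow_duplicate_tips = FALSE) {
  stopifnot(is.logical(bits), !anyNA(bits))
  m <- length(bits)
  n <- m %/% 2L
  if (m == 0L || m %% 2L != 0L || sum(bits) != n)
    stop("bits is not a balanced parenthesis vector (need n opens, n closes)")
  if (!bits[1L]) stop("position 1 must be an opening parenthesis (the root)")
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) != n || length(lengths) != n)
    stop("names and lengths must have one entry per node (", n, ")")
  if (any(!is.na(lengths) & lengths < 0))
    stop("negative branch lengths are not allowed")

  idx <- bp_index_cpp(bits)
  open_pos <- idx$open_pos
  close_pos <- idx$close_pos
  parent <- idx$parent

  is_tip <- close_pos == open_pos + 1L
  tip_names <- names[is_tip]
  dup <- duplicated(tip_names) & nzchar(tip_names)
  if (any(dup)) {
    if (!allow_duplicate_tips)
      stop("duplicate tip name(s): ",
           paste(unique(tip_names[dup]), collapse = ", "))
    names[is_tip] <- make.unique(tip_names, sep = "_")
  }

  # tips inside [open, close] via a prefix sum over bit positions
  tip_mark <- integer(m)
  tip_mark[open_pos[is_tip]] <- 1L
  tip_cum <- c(0L, cumsum(tip_mark))
  tip_count <- tip_cum[close_pos + 1L] - tip_cum[open_pos]

  node_at <- integer(m)
  node_at[open_pos] <- seq_len(n)
  node_at[close_pos] <- seq_len(n)

  postorder <- order(close_pos)
  post_rank <- integer(n)
  post_rank[postorder] <- seq_len(n)

  structure(
    list(bits = bits, names = names, lengths = lengths,
         n_nodes = n, n_tips = sum(is_tip),
         open_pos = open_pos, close_pos = close_pos, parent = parent,
         is_tip = is_tip, tip_count = tip_count, node_at = node_at,
         postorder = postorder, post_rank = post_rank),
    class = "bptree")
}

#' @export
print.bptree <- function(x, ...) {
  cat("<bptree> ", x$n_nodes, " nodes, ", x$n_tips, " tips",
      if (nzchar(x$names[1L])) paste0(", root '", x$names[1L], "'") else "",
      "\n", sep = "")
  invisible(x)
}

#' @rdname bptree-accessors
#' @export
n_tips <- function(tree) tree$n_tips

#' Tree accessors
#'
#' @param tree a [bptree].
#' @return `n_tips()`/`n_nodes()` return counts; `tip_names()` the tip names
#'   in tree (preorder) order; `node_names()`/`node_lengths()` per-node
#'   vectors in preorder.
#' @name bptree-accessors
#' @export
n_nodes <- function(tree) tree$n_nodes

#' @rdname bptree-accessors
#' @export
tip_names <- function(tree) tree$names[tree$is_tip]

#' @rdname bptree-accessors
#' @export
node_names <- function(tree) tree$names

#' @rdname bptree-accessors
#' @export
node_lengths <- function(tree) tree$lengths

# opening position -> preorder rank, validating the index
node_of <- function(tree, i) {
  i <- as.integer(i)
  bad <- is.na(i) | i < 1L | i > length(tree$bits) | !tree$bits[pmax(i, 1L)]
  if (any(bad))
    stop("index ", paste(i[bad], collapse = ", "),
         " is not an opening position")
  tree$node_at[i]
}

#' Balanced-parentheses navigation primitives
#'
#' All queries take and return opening positions (1-based positions of `(`
#' in the bit vector); all are vectorized over `i`. `bp_parent()` of the
#' root is the sentinel `0L`, as are `bp_first_child()` of a leaf and
#' `bp_next_sibling()` of a last child.
#'
#' @param tree a [bptree].
#' @param i opening position(s).
#' @param j closing position(s), for `bp_open()`.
#' @param k traversal rank(s) in 1..n, for the select functions.
#' @return integer vector of opening positions (or `0L` sentinels);
#'   `bp_close()` returns closing positions; `bp_is_leaf()` a logical;
#'   `bp_subtree_tip_count()` tip counts; `bp_postorder_rank()` ranks.
#' @name bp-navigation
NULL

#' @rdname bp-navigation
#' @export
bp_parent <- function(tree, i) {
  p <- tree$parent[node_of(tree, i)]
  ifelse(p == 0L, 0L, tree$open_pos[pmax(p, 1L)])
}

#' @rdname bp-navigation
#' @export
bp_first_child <- function(tree, i) {
  nd <- node_of(tree, i)
  ifelse(tree$is_tip[nd], 0L, as.integer(i) + 1L)
}

#' @rdname bp-navigation
#' @export
bp_next_sibling <- function(tree, i) {
  j <- tree$close_pos[node_of(tree, i)] + 1L
  ok <- j <= length(tree$bits) & tree$bits[pmin(j, length(tree$bits))]
  ifelse(ok, j, 0L)
}

#' @rdname bp-navigation
#' @export
bp_is_leaf <- function(tree, i) tree$is_tip[node_of(tree, i)]

#' @rdname bp-navigation
#' @export
bp_close <- function(tree, i) tree$close_pos[node_of(tree, i)]

#' @rdname bp-navigation
#' @export
bp_open <- function(tree, j) {
  j <- as.integer(j)
  bad <- is.na(j) | j < 1L | j > length(tree$bits) | tree$bits[pmax(j, 1L)]
  if (any(bad))
    stop("index ", paste(j[bad], collapse = ", "),
         " is not a closing position")
  tree$open_pos[tree$node_at[j]]
}

#' @rdname bp-navigation
#' @export
bp_preorder_select <- function(tree, k) {
  k <- as.integer(k)
  if (any(is.na(k) | k < 1L | k > tree$n_nodes)) stop("rank out of range")
  tree$open_pos[k]
}

#' @rdname bp-navigation
#' @export
bp_postorder_select <- function(tree, k) {
  k <- as.integer(k)
  if (any(is.na(k) | k < 1L | k > tree$n_nodes)) stop("rank out of range")
  tree$open_pos[tree$postorder[k]]
}

#' @rdname bp-navigation
#' @export
bp_postorder_rank <- function(tree, i) tree$post_rank[node_of(tree, i)]

#' @rdname bp-navigation
#' @export
bp_subtree_tip_count <- function(tree, i) tree$tip_count[node_of(tree, i)]

# children of every node as a list of preorder ranks, in sibling order
children_list <- function(tree) {
  n <- tree$n_nodes
  ch <- vector("list", n)
  if (n > 1L) {
    sp <- split(2:n, tree$parent[-1L])
    ch[as.integer(names(sp))] <- sp
  }
  ch
}

# Build a bptree by iterative DFS over children lists (node ids are
# arbitrary; only nodes reachable from `root` are emitted, in the order
# the children lists give them). Shared by the fixture generator, shear,
# sibling sorting and from_pointer.
tree_from_children <- function(children, names, lengths, root = 1L) {
  n_old <- length(names)
  bits <- logical(0L)
  ord <- integer(0L)
  # explicit stack of (node, next-child cursor)
  stack_node <- integer(n_old + 1L)
  stack_ptr <- integer(n_old + 1L)
  top <- 1L
  stack_node[1L] <- root
  stack_ptr[1L] <- 0L
  bits_buf <- logical(2L * n_old)
  bp <- 0L
  ord_buf <- integer(n_old)
  op <- 0L
  bp <- bp + 1L; bits_buf[bp] <- TRUE
  op <- op + 1L; ord_buf[op] <- root
  while (top > 0L) {
    nd <- stack_node[top]
    ptr <- stack_ptr[top] + 1L
    kids <- children[[nd]]
    if (is.null(kids) || ptr > length(kids)) {
      bp <- bp + 1L; bits_buf[bp] <- FALSE
      top <- top - 1L
    } else {
      stack_ptr[top] <- ptr
      child <- kids[[ptr]]
      top <- top + 1L
      stack_node[top] <- child
      stack_ptr[top] <- 0L
      bp <- bp + 1L; bits_buf[bp] <- TRUE
      op <- op + 1L; ord_buf[op] <- child
    }
  }
  ord <- ord_buf[seq_len(op)]
  bptree(bits_buf[seq_len(bp)], names[ord], lengths[ord])
}

#' Restrict a tree to a set of tips
#'
#' Removes every tip not in `keep` and every internal node left with no
#' kept descendant tip. Internal nodes reduced to a single child
#' (unifurcations) are retained with their names and branch lengths, so
#' their metadata survives for colouring; `collapse_unifurcations = TRUE`
#' splices each one out, summing its branch length into its child's.
#' Relative sibling order is preserved.
#'
#' @param tree a [bptree].
#' @param keep character vector of tip names to retain; must intersect the
#'   tree's tips.
#' @param collapse_unifurcations splice out single-child internal nodes,
#'   summing branch lengths (absent lengths propagate: NA + x = NA only if
#'   both are NA is avoided by treating NA as 0 when the partner has a
#'   length; two NAs stay NA).
#' @return the sheared [bptree].
#' @export
shear <- function(tree, keep, collapse_unifurcations = FALSE) {
  keep <- as.character(keep)
  tips <- tip_names(tree)
  inter <- intersect(keep, tips)
  if (length(inter) == 0L) {
    missing <- setdiff(keep, tips)
    stop("none of the requested tips are in the tree; missing: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "")
  }
  n <- tree$n_nodes
  keep_node <- logical(n)
  keep_node[tree$is_tip & tree$names %in% keep] <- TRUE
  # parents precede children in preorder, so one reverse sweep closes the set
  if (n > 1L) for (nd in n:2L) if (keep_node[nd])
    keep_node[tree$parent[nd]] <- TRUE
  ch <- children_list(tree)
  ch <- lapply(ch, function(k) k[keep_node[k]])
  out <- tree_from_children(ch, tree$names, tree$lengths, root = 1L)
  if (collapse_unifurcations) out <- collapse_unary(out)
  out
}

# splice out internal nodes with exactly one child, summing branch lengths
collapse_unary <- function(tree) {
  n <- tree$n_nodes
  ch <- children_list(tree)
  n_child <- lengths(ch)
  unary <- !tree$is_tip & n_child == 1L
  if (!any(unary[-1L]) && !unary[1L]) return(tree)
  lens <- tree$lengths
  parent <- tree$parent
  # re-parent each unary node's child; accumulate lengths child-first
  for (nd in n:1L) {
    if (!unary[nd]) next
    child <- ch[[nd]][1L]
    a <- lens[child]; b <- lens[nd]
    lens[child] <- if (is.na(a) && is.na(b)) NA_real_ else
      sum(c(a, b), na.rm = TRUE)
    if (nd == 1L) next               # unary root: keep it as the root
    p <- parent[nd]
    ch[[p]][ch[[p]] == nd] <- child
    parent[child] <- p
  }
  root <- 1L
  while (unary[root]) root <- ch[[root]][1L]
  ch[unary] <- list(integer(0))
  tree_from_children(ch, tree$names, lens, root = root)
}

#' Reorder sibling clades by subtree tip count
#'
#' At every internal node, children are reordered by the number of tips in
#' their subtrees ("leaf sorting"). The sort is stable: ties keep their
#' original relative order. Names, lengths and the tip set are unchanged.
#'
#' @param tree a [bptree].
#' @param order `"ascending"` (smallest clade first) or `"descending"`.
#' @return the reordered [bptree].
#' @export
sort_siblings <- function(tree, order = c("ascending", "descending")) {
  order <- match.arg(order)
  ch <- children_list(tree)
  tc <- tree$tip_count
  ch <- lapply(ch, function(k) {
    if (length(k) < 2L) return(k)
    key <- if (order == "ascending") tc[k] else -tc[k]
    k[base::order(key, seq_along(k))]
  })
  tree_from_children(ch, tree$names, tree$lengths, root = 1L)
}

#' Convert between a bptree and a nested-list pointer tree
#'
#' The pointer representation is a plain nested list — each node a
#' `list(name=, length=, children=list(...))` — convenient for oracle-style
#' testing and small-scale manipulation. The two converters are mutual
#' inverses.
#'
#' @param tree a [bptree]; `pt` a pointer node as described.
#' @return `to_pointer()` the nested list; `from_pointer()` a [bptree].
#' @export
to_pointer <- function(tree) {
  ch <- children_list(tree)
  build <- function(nd) {
    list(name = tree$names[nd], length = tree$lengths[nd],
         children = lapply(ch[[nd]], build))
  }
  build(1L)
}

#' @rdname to_pointer
#' @param pt a pointer-tree node.
#' @export
from_pointer <- function(pt) {
  names <- character(0); lens <- numeric(0); children <- list()
  add <- function(node) {
    id <- length(names) + 1L
    names[[id]] <<- node$name %||% ""
    lens[[id]] <<- if (is.null(node$length)) NA_real_ else node$length
    children[[id]] <<- integer(0)
    for (k in node$children) {
      cid <- add(k)
      children[[id]] <<- c(children[[id]], cid)
    }
    id
  }
  add(pt)
  tree_from_children(children, names, lens, root = 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
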