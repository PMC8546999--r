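#' Tree layout algorithms
#'
#' Three classic layouts for rooted trees, all returning one coordinate
#' record per node (in preorder) plus layout-specific connector geometry:
#'
#' * **rectangular** — tips at integer y-positions 0..n_tips-1 in the order
#'   tips appear in a traversal (identical for pre- and postorder), each
#'   internal node at the arithmetic mean of its children's y; x grows
#'   root-to-tip by branch length. Internal nodes carry a vertical
#'   connector segment spanning their children.
#' * **circular** — the rectangular layout wrapped around a circle: tip k
#'   of n gets angle `start_angle + 2*pi*k/n`, internal angles are the mean
#'   of children's, radius grows root-to-tip by branch length; internal
#'   nodes carry an arc at their own radius spanning their children's
#'   angles.
#' * **unrooted (equal-angle)** — every node hands each child a contiguous
#'   angular sector proportional to the child's tip count (children in
#'   tree order, counterclockwise from angle 0 at the root, whose sector is
#'   the full circle); a child sits at branch-length distance from its
#'   parent along its sector's bisector. The root is treated as an
#'   interior vertex at the origin.
#'
#' `branch_mode = "actual"` uses the stored branch lengths, substituting 0
#' (with a warning) where a length is absent; `"unit"` gives every branch
#' length 1, which shows topology undistorted by rate variation. Negative
#' branch lengths are an error in either mode.
#'
#' @param tree a [bptree].
#' @param branch_mode `"actual"` or `"unit"`.
#' @param start_angle for the circular layout, angle of the first tip
#'   (radians).
#' @return a `tree_layout`: list with `kind`, `branch_mode`, a `nodes`
#'   data.frame (preorder: `node` opening position, `name`, `is_tip`, `x`,
#'   `y`, and for circular also `radius`/`angle`), and `connectors`
#'   (rectangular: `x`, `y_min`, `y_max` per internal node; circular:
#'   `radius`, `angle_start`, `angle_end`).
#' @name layouts
NULL

effective_lengths <- function(tree, branch_mode) {
  if (branch_mode == "unit") {
    ell <- rep(1, tree$n_nodes)
  } else {
    ell <- tree$lengths
    if (anyNA(ell[-1L])) {
      warning("absent branch length(s) substituted with 0 in actual mode")
    }
    ell[is.na(ell)] <- 0
  }
  if (any(ell < 0)) stop("negative branch lengths are not allowed")
  ell[1L] <- 0                       # the root contributes no depth
  ell
}

# per-node tip index (0-based, traversal order) for tips, NA for internal
tip_index <- function(tree) {
  ti <- rep(NA_real_, tree$n_nodes)
  ti[tree$is_tip] <- seq_len(tree$n_tips) - 1
  ti
}

# mean over children, evaluated children-first (children follow parents in
# preorder, so a reverse sweep suffices)
mean_up <- function(tree, value) {
  n <- tree$n_nodes
  sum_v <- value
  sum_v[!tree$is_tip] <- 0
  cnt <- as.numeric(tree$is_tip)
  parent <- tree$parent
  if (n > 1L) for (nd in n:2L) {
    p <- parent[nd]
    m <- sum_v[nd] / max(cnt[nd], 1)
    sum_v[p] <- sum_v[p] + m
    cnt[p] <- cnt[p] + 1
  }
  out <- value
  internal <- !tree$is_tip
  out[internal] <- sum_v[internal] / pmax(cnt[internal], 1)
  out
}

# cumulative depth from the root (parents precede children in preorder)
depth_down <- function(tree, ell) {
  n <- tree$n_nodes
  x <- numeric(n)
  parent <- tree$parent
  if (n > 1L) for (nd in 2:n) x[nd] <- x[parent[nd]] + ell[nd]
  x
}

child_range <- function(tree, value) {
  n <- tree$n_nodes
  lo <- rep(Inf, n); hi <- rep(-Inf, n)
  parent <- tree$parent
  if (n > 1L) for (nd in 2:n) {
    p <- parent[nd]
    if (value[nd] < lo[p]) lo[p] <- value[nd]
    if (value[nd] > hi[p]) hi[p] <- value[nd]
  }
  list(lo = lo, hi = hi)
}

layout_nodes_frame <- function(tree, x, y, extra = NULL) {
  df <- data.frame(node = tree$open_pos, name = tree$names,
                   is_tip = tree$is_tip, x = x, y = y,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  df
}

#' @rdname layouts
#' @export
rectangular_layout <- function(tree, branch_mode = c("actual", "unit")) {
  branch_mode <- match.arg(branch_mode)
  ell <- effective_lengths(tree, branch_mode)
  x <- depth_down(tree, ell)
  y <- mean_up(tree, tip_index(tree))
  if (tree$n_nodes == 1L) y <- 0
  rng <- child_range(tree, y)
  internal <- which(!tree$is_tip)
  connectors <- data.frame(node = tree$open_pos[internal],
                           x = x[internal],
                           y_min = rng$lo[internal],
                           y_max = rng$hi[internal])
  structure(list(kind = "rectangular", branch_mode = branch_mode,
                 nodes = layout_nodes_frame(tree, x, y),
                 connectors = connectors, n_tips = tree$n_tips,
                 tree = tree),
            class = "tree_layout")
}

#' @rdname layouts
#' @export
circular_layout <- function(tree, branch_mode = c("actual", "unit"),
                            start_angle = 0) {
  branch_mode <- match.arg(branch_mode)
  ell <- effective_lengths(tree, branch_mode)
  r <- depth_down(tree, ell)
  theta_tip <- start_angle + 2 * pi * tip_index(tree) / max(tree$n_tips, 1L)
  theta <- mean_up(tree, theta_tip)
  if (tree$n_nodes == 1L) theta <- start_angle
  rng <- child_range(tree, theta)
  internal <- which(!tree$is_tip)
  connectors <- data.frame(node = tree$open_pos[internal],
                           radius = r[internal],
                           angle_start = rng$lo[internal] %% (2 * pi),
                           angle_end = rng$hi[internal] %% (2 * pi),
                           span = rng$hi[internal] - rng$lo[internal])
  structure(list(kind = "circular", branch_mode = branch_mode,
                 start_angle = start_angle,
                 nodes = layout_nodes_frame(
                   tree, r * cos(theta), r * sin(theta),
                   extra = data.frame(radius = r,
                                      angle = theta %% (2 * pi))),
                 connectors = connectors, n_tips = tree$n_tips,
                 tree = tree),
            class = "tree_layout")
}

#' @rdname layouts
#' @export
unrooted_equal_angle_layout <- function(tree,
                                        branch_mode = c("actual", "unit")) {
  branch_mode <- match.arg(branch_mode)
  ell <- effective_lengths(tree, branch_mode)
  n <- tree$n_nodes
  parent <- tree$parent
  tc <- tree$tip_count
  # sector offsets: cumulative tip counts over earlier siblings
  offset <- numeric(n)
  if (n > 1L) {
    run <- numeric(n)                   # per-parent running tip total
    for (nd in 2:n) {
      p <- parent[nd]
      offset[nd] <- run[p]
      run[p] <- run[p] + tc[nd]
    }
  }
  sec_start <- numeric(n); sec_width <- numeric(n)
  sec_start[1L] <- 0; sec_width[1L] <- 2 * pi
  x <- numeric(n); y <- numeric(n); angle <- numeric(n)
  if (n > 1L) for (nd in 2:n) {
    p <- parent[nd]
    share <- sec_width[p] / tc[p]
    sec_start[nd] <- sec_start[p] + share * offset[nd]
    sec_width[nd] <- share * tc[nd]
    angle[nd] <- sec_start[nd] + sec_width[nd] / 2
    x[nd] <- x[p] + ell[nd] * cos(angle[nd])
    y[nd] <- y[p] + ell[nd] * sin(angle[nd])
  }
  structure(list(kind = "unrooted", branch_mode = branch_mode,
                 nodes = layout_nodes_frame(
                   tree, x, y,
                   extra = data.frame(angle = angle,
                                      sector_start = sec_start,
                                      sector_width = sec_width)),
                 connectors = NULL, n_tips = tree$n_tips, tree = tree),
            class = "tree_layout")
}

#' @export
print.tree_layout <- function(x, ...) {
  cat("<tree_layout:", x$kind, "> ", nrow(x$nodes), " nodes, ",
      x$n_tips, " tips, branch_mode=", x$branch_mode, "\n", sep = "")
  invisible(x)
}
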