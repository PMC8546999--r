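# Independent oracles used across the suite: a naive pointer-tree
# implementation of every navigation query, a recursive tip-filter for
# shearing, and a brute-force sliding-window enumerator. All operate on
# plain nested lists / data.frames and never touch the BP index.

# deterministic tip-count variation for parameterised property tests
sample_n_tips <- function(seed, max_tips = 64L) {
  2L + (seed * 17L) %% (max_tips - 1L)
}

random_tree <- function(n_tips, seed, multifurcation_prob = 0.15) {
  withr::with_seed(seed,
    phyloscape:::random_coalescent_tree(n_tips, multifurcation_prob))
}

# flatten a nested-list pointer tree into parallel arrays (preorder)
pt_flatten <- function(pt) {
  env <- new.env()
  env$name <- character(0); env$length <- numeric(0)
  env$parent <- integer(0); env$children <- list()
  rec <- function(node, parent) {
    id <- length(env$name) + 1L
    env$name[id] <- node$name
    env$length[id] <- if (is.null(node$length)) NA_real_ else node$length
    env$parent[id] <- parent
    env$children[[id]] <- integer(0)
    if (parent > 0L)
      env$children[[parent]] <- c(env$children[[parent]], id)
    for (ch in node$children) rec(ch, id)
    invisible(id)
  }
  rec(pt, 0L)
  list(name = env$name, length = env$length, parent = env$parent,
       children = env$children,
       is_tip = vapply(env$children, length, 1L) == 0L)
}

pt_postorder <- function(flat) {
  out <- integer(0)
  rec <- function(id) {
    for (ch in flat$children[[id]]) rec(ch)
    out <<- c(out, id)
  }
  rec(1L)
  out
}

pt_tip_count <- function(flat, id) {
  if (flat$is_tip[id]) return(1L)
  sum(vapply(flat$children[[id]], function(ch) pt_tip_count(flat, ch), 1L))
}

pt_descendant_tips <- function(flat, id) {
  if (flat$is_tip[id]) return(flat$name[id])
  unlist(lapply(flat$children[[id]], function(ch)
    pt_descendant_tips(flat, ch)))
}

# recursive shear of a pointer tree: keep only tips named in `keep`
pt_filter <- function(node, keep) {
  if (length(node$children) == 0L)
    return(if (node$name %in% keep) node else NULL)
  kids <- Filter(Negate(is.null),
                 lapply(node$children, pt_filter, keep = keep))
  if (length(kids) == 0L) return(NULL)
  node$children <- kids
  node
}

# verify every navigation primitive of `tree` against its pointer image
expect_navigation_matches_oracle <- function(tree) {
  flat <- pt_flatten(to_pointer(tree))
  n <- n_nodes(tree)
  pre_pos <- bp_preorder_select(tree, seq_len(n))
  pos2rank <- function(pos) ifelse(pos == 0L, 0L, match(pos, pre_pos))
  for (k in seq_len(n)) {
    i <- pre_pos[k]
    expect_identical(pos2rank(bp_parent(tree, i)), flat$parent[k])
    kids <- flat$children[[k]]
    expect_identical(pos2rank(bp_first_child(tree, i)),
                     if (length(kids)) kids[1L] else 0L)
    p <- flat$parent[k]
    sib <- if (p == 0L) 0L else {
      sibs <- flat$children[[p]]
      at <- match(k, sibs)
      if (at < length(sibs)) sibs[at + 1L] else 0L
    }
    expect_identical(pos2rank(bp_next_sibling(tree, i)), sib)
    expect_identical(bp_is_leaf(tree, i), flat$is_tip[k])
    expect_identical(bp_open(tree, bp_close(tree, i)), i)
    expect_identical(bp_subtree_tip_count(tree, i), pt_tip_count(flat, k))
  }
  post <- pt_postorder(flat)
  expect_identical(vapply(seq_len(n), function(k)
    pos2rank(bp_postorder_select(tree, k)), 1L), post)
  expect_identical(bp_preorder_select(tree, seq_len(n)), pre_pos)
}

# brute-force sliding-window communities: explicit double loop over
# (location, start date); returns sorted record sets keyed by sample id
bf_sliding_windows <- function(record_md, date_field, location_field,
                               window_days, min_records) {
  d <- as.Date(record_md[[date_field]])
  l <- as.character(record_md[[location_field]])
  ids <- rownames(record_md)
  ok <- !is.na(d) & !is.na(l)
  out <- list()
  for (g in sort(unique(l[ok]))) {
    dd <- d[ok & l == g]
    rr <- ids[ok & l == g]
    for (s in seq(min(dd), max(dd), by = "day")) {
      s <- as.Date(s, origin = "1970-01-01")
      hit <- dd >= s & dd <= s + window_days - 1
      if (sum(hit) >= min_records)
        out[[paste0(g, "@", format(s, "%Y-%m-%d"))]] <- sort(rr[hit])
    }
  }
  if (length(out) == 0L) return(list())
  out[order(names(out))]
}

# community-sample sets from a sliding-window feature table, same keying
table_window_sets <- function(tab) {
  if (ncol(tab) == 0L) return(list())
  sets <- lapply(colnames(tab), function(s)
    sort(rownames(tab)[tab[, s] > 0]))
  names(sets) <- colnames(tab)
  sets[order(names(sets))]
}

tiny_table <- function(values, features, samples) {
  as_feature_table(matrix(values, nrow = length(features), byrow = TRUE,
                          dimnames = list(features, samples)))
}
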