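test_that("rectangular layout reproduces the worked example", {
  tr <- read_newick("((a:1,b:1)i:1,c:2)r;")
  lay <- rectangular_layout(tr, "actual")
  nd <- lay$nodes
  coords <- setNames(split(nd[, c("x", "y")], seq_len(nrow(nd))), nd$name)
  expect_equal(nd$y, c(1.25, 0.5, 0, 1, 2))   # r, i, a, b, c
  expect_equal(nd$x, c(0, 1, 2, 2, 2))
  unit <- rectangular_layout(tr, "unit")
  expect_equal(unit$nodes$x, c(0, 1, 2, 2, 1))
  # internal connectors span the children
  i_row <- lay$connectors[lay$connectors$node == nd$node[2L], ]
  expect_equal(c(i_row$y_min, i_row$y_max), c(0, 1))
})

test_that("degenerate single-tip layouts are defined", {
  tr <- read_newick("a;")
  expect_equal(rectangular_layout(tr)$nodes[, c("x", "y")],
               data.frame(x = 0, y = 0))
  expect_equal(nrow(circular_layout(tr)$nodes), 1L)
  expect_equal(nrow(unrooted_equal_angle_layout(tr)$nodes), 1L)
})

test_that("circular layout places a symmetric star at the axis angles", {
  star <- read_newick("(a:1,b:1,c:1,d:1)r;")
  lay <- circular_layout(star, "actual", start_angle = 0)
  tips <- lay$nodes[lay$nodes$is_tip, ]
  expect_equal(sort(tips$angle), c(0, pi / 2, pi, 3 * pi / 2),
               tolerance = 1e-12)
  expect_equal(tips$radius, rep(1, 4))
  two <- circular_layout(read_newick("(a:1,b:1)r;"))
  expect_equal(sort(two$nodes$angle[two$nodes$is_tip]), c(0, pi),
               tolerance = 1e-12)
})

test_that("circular tip angles are equally spaced with exact gaps", {
  for (seed in 1:10) {
    tr <- random_tree(sample_n_tips(seed, 40), seed)
    lay <- circular_layout(tr)
    ang <- sort(lay$nodes$angle[lay$nodes$is_tip])
    expect_equal(diff(ang), rep(2 * pi / n_tips(tr), n_tips(tr) - 1L),
                 tolerance = 1e-9)
    expect_true(all(ang >= 0 & ang < 2 * pi))
    # radii never decrease root-to-tip
    nd <- lay$nodes
    parent_rank <- tr$parent
    expect_true(all(nd$radius[-1L] >= nd$radius[parent_rank[-1L]] - 1e-12))
  }
})

test_that("equal-angle layout gives the closed-form star solution", {
  star <- read_newick("(a:1,b:1,c:1,d:1)r;")
  lay <- unrooted_equal_angle_layout(star)
  tips <- lay$nodes[lay$nodes$is_tip, ]
  expect_equal(sort(tips$angle), pi * c(1, 3, 5, 7) / 4, tolerance = 1e-12)
  expect_equal(sqrt(tips$x^2 + tips$y^2), rep(1, 4), tolerance = 1e-12)
  a <- tips[tips$name == "a", ]
  expect_equal(c(a$x, a$y), c(sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-12)
})

test_that("equal-angle sectors conserve exactly at every node", {
  for (seed in 1:10) {
    tr <- random_tree(sample_n_tips(seed, 40), seed)
    lay <- unrooted_equal_angle_layout(tr)
    nd <- lay$nodes
    w <- nd$sector_width
    # children's sectors sum to the parent's sector
    child_sum <- tapply(w[-1L], tr$parent[-1L], sum)
    parents <- as.integer(names(child_sum))
    expect_equal(as.numeric(child_sum), w[parents], tolerance = 1e-9)
    expect_equal(sum(w[tr$parent == 1L & seq_len(n_nodes(tr)) > 1L]),
                 2 * pi, tolerance = 1e-9)
    # distinct tips get distinct ray angles
    tip_ang <- nd$angle[nd$is_tip]
    expect_equal(anyDuplicated(round(tip_ang, 12)), 0L)
  }
})

test_that("tip y positions are exactly 0..n-1 whatever the sibling order", {
  for (seed in 1:10) {
    tr <- random_tree(sample_n_tips(seed, 40), seed)
    lay <- rectangular_layout(tr)
    ys <- sort(lay$nodes$y[lay$nodes$is_tip])
    expect_equal(ys, as.numeric(seq_len(n_tips(tr)) - 1L))
    # x non-decreasing root to tip in both modes
    for (mode in c("actual", "unit")) {
      l2 <- rectangular_layout(tr, mode)
      expect_true(all(l2$nodes$x[-1L] >= l2$nodes$x[tr$parent[-1L]] - 1e-12))
    }
    # leaf sorting permutes tips but never the tip-coordinate multiset
    srt <- sort_siblings(tr, "descending")
    lay2 <- rectangular_layout(srt)
    expect_equal(sort(lay2$nodes$y[lay2$nodes$is_tip]), ys)
  }
})

test_that("branch-length handling: absent warns and substitutes 0", {
  tr <- read_newick("((a:1,b)i:1,c:2)r;")
  expect_warning(lay <- rectangular_layout(tr, "actual"), "absent branch")
  b_x <- lay$nodes$x[lay$nodes$name == "b"]
  i_x <- lay$nodes$x[lay$nodes$name == "i"]
  expect_equal(b_x, i_x)                     # zero-length branch
  expect_silent(rectangular_layout(tr, "unit"))
})

test_that("negative branch lengths are rejected at parse time", {
  expect_error(read_newick("(a:-1,b:2)r;"), "negative branch length")
})
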