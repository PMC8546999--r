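test_that("selecting samples highlights tips plus fully covered clades", {
  tr <- read_newick("((a:1,b:1)x:1,c:1)r;")
  tab <- tiny_table(c(1, 0,
                      1, 0,
                      0, 1), c("a", "b", "c"), c("s1", "s2"))
  p <- build_presence(tab)
  sel <- samples_to_nodes("s1", p, tr)
  hit <- node_names(tr)[match(bp_postorder_select(tr, sel$node_ids),
                              tr$open_pos)]
  expect_setequal(hit, c("a", "b", "x"))     # clade x fully covered
  tips_only <- samples_to_nodes("s1", p, tr, tips_only = TRUE)
  hit2 <- node_names(tr)[match(bp_postorder_select(tr, tips_only$node_ids),
                               tr$open_pos)]
  expect_setequal(hit2, c("a", "b"))
  # brute force over all nodes' descendant tip sets
  for (seed in 1:8) {
    fx <- generate_fixture(20, 8, 0.4, seed = seed)
    pp <- build_presence(fx$table)
    ss <- withr::with_seed(seed, sample(colnames(fx$table), 3))
    got <- samples_to_nodes(ss, pp, fx$tree)
    feats <- unique(unlist(pp$sample_features[ss], use.names = FALSE))
    flat <- pt_flatten(to_pointer(fx$tree))
    want <- which(vapply(seq_along(flat$name), function(k) {
      tipset <- pt_descendant_tips(flat, k)
      all(tipset %in% feats)
    }, logical(1)))
    got_rank <- match(bp_postorder_select(fx$tree, got$node_ids),
                      fx$tree$open_pos)
    expect_setequal(got_rank, want)
  }
  expect_error(samples_to_nodes("nope", p, tr), "unknown sample")
})

test_that("empty selections are allowed and empty, not errors", {
  tr <- read_newick("((a:1,b:1)x:1,c:1)r;")
  tab <- tiny_table(c(1, 0,
                      0, 0), c("zz", "ww"), c("s1", "s2"))
  p <- suppressWarnings(build_presence(tab))
  sel <- samples_to_nodes("s2", p, tr)
  expect_length(sel$node_ids, 0L)
})

test_that("node_to_samples unions descendant tip memberships", {
  tr <- read_newick("((a:1,b:1)x:1,c:1)r;")
  tab <- tiny_table(c(1, 0,
                      0, 1,
                      0, 0), c("a", "b", "c"), c("s1", "s2"))
  p <- build_presence(tab)
  x_pos <- tr$open_pos[match("x", node_names(tr))]
  expect_setequal(node_to_samples(x_pos, tr, p)$sample_ids, c("s1", "s2"))
  c_pos <- tr$open_pos[match("c", node_names(tr))]
  expect_length(node_to_samples(c_pos, tr, p)$sample_ids, 0L)
  root_sel <- node_to_samples(1L, tr, p)
  expect_setequal(root_sel$sample_ids, c("s1", "s2"))
})

test_that("sample-node queries are adjoint on tips", {
  for (seed in 1:8) {
    fx <- generate_fixture(20, 8, 0.4, seed = seed)
    p <- build_presence(fx$table)
    for (tip in intersect(tip_names(fx$tree), rownames(fx$table))) {
      if (length(p$feature_samples[[tip]]) == 0L) next
      pos <- fx$tree$open_pos[match(tip, fx$tree$names)]
      back <- samples_to_nodes(node_to_samples(pos, fx$tree, p)$sample_ids,
                               p, fx$tree)
      expect_true(bp_postorder_rank(fx$tree, pos) %in% back$node_ids)
    }
  }
})

test_that("selection summaries count categories and pool missing", {
  md <- metadata_table(c("s1", "s2", "s3"),
                       list(g = c("A", "A", "B"), h = c(NA, NA, NA)))
  sel <- phyloscape:::new_selection("samples", c("s1", "s2", "s3"),
                                    integer(0))
  expect_equal(summarize_selection(sel, md, "g"), c(A = 2L, B = 1L))
  expect_equal(summarize_selection(sel, md, "h"), c(`__missing__` = 3L))
  empty <- phyloscape:::new_selection("samples", character(0), integer(0))
  expect_length(summarize_selection(empty, md, "g"), 0L)
})

test_that("biplot arrows resolve by exact name, tips or internal nodes", {
  tr <- read_newick("((f3:1,g:1)inner:1,h:1)r;")
  ord <- structure(list(
    sample_ids = "s1", sample_coords = matrix(0, 1, 2,
                                              dimnames = list("s1", NULL)),
    proportion_explained = c(0.6, 0.4), eigvals = c(1, 0.5),
    feature_ids = c("f3", "inner", "nope"),
    feature_coords = matrix(0, 3, 2,
                            dimnames = list(c("f3", "inner", "nope"), NULL))),
    class = "ordination")
  expect_equal(resolve_biplot_arrow("f3", ord, tr),
               tr$open_pos[match("f3", node_names(tr))])
  expect_equal(resolve_biplot_arrow("inner", ord, tr),
               tr$open_pos[match("inner", node_names(tr))])
  expect_error(resolve_biplot_arrow("nope", ord, tr), "does not match")
  ord$feature_coords <- NULL
  expect_error(resolve_biplot_arrow("f3", ord, tr), "no biplot")
})

test_that("frames order by gradient and isolate per-trajectory features", {
  tab <- tiny_table(c(1, 0, 1, 0,
                      1, 1, 0, 0,
                      0, 1, 0, 1), c("f1", "f2", "f3"),
                    c("s1", "s2", "s3", "s4"))
  p <- build_presence(tab)
  md <- metadata_table(c("s1", "s2", "s3", "s4"),
                       list(t = c("t1", "t1", "t2", "t2"),
                            traj = c("X", "Y", "X", "Y")))
  fr <- build_frames(md, "t", "traj", p)
  expect_identical(fr$frame_keys, c("t1", "t2"))
  expect_setequal(fr$unique_features$t1$X, "f1")
  expect_setequal(fr$unique_features$t1$Y, "f3")
  # within every frame the unique sets are pairwise disjoint
  for (f in fr$frame_keys) {
    u <- fr$unique_features[[f]]
    if (length(u) > 1L)
      expect_length(Reduce(intersect, u), 0L)
    all_feats <- unlist(u, use.names = FALSE)
    expect_equal(anyDuplicated(all_feats), 0L)
  }
  # single trajectory keeps everything; identical sets annihilate
  md2 <- metadata_table(c("s1", "s2"), list(t = c("t1", "t1"),
                                            traj = c("X", "X")))
  fr2 <- build_frames(md2, "t", "traj", p)
  expect_setequal(fr2$unique_features$t1$X, c("f1", "f2", "f3"))
  md3 <- metadata_table(c("s1", "s1b"), list(t = c("t1", "t1"),
                                             traj = c("X", "Y")))
  tab3 <- tiny_table(c(1, 1), "f1", c("s1", "s1b"))
  fr3 <- build_frames(md3, "t", "traj", build_presence(tab3))
  expect_length(fr3$unique_features$t1$X, 0L)
  expect_length(fr3$unique_features$t1$Y, 0L)
  # numeric gradients sort numerically
  md4 <- metadata_table(c("s1", "s2", "s3"),
                        list(t = c(10, 2, 2), traj = c("X", "X", "X")))
  fr4 <- build_frames(md4, "t", "traj", p)
  expect_identical(fr4$frame_keys, c("2", "10"))
})

test_that("sliding windows emit exactly the qualifying windows", {
  # five records on one day, window 7: a single window at that day
  md <- metadata_table(sprintf("r%d", 1:5),
                       list(date = rep("2020-04-01", 5),
                            location = rep("NY", 5)))
  tab <- sliding_window_communities(md, "date", "location", 7, 5)
  expect_identical(colnames(tab), "NY@2020-04-01")
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab@x == 1))
  # never enough records: empty table
  md2 <- metadata_table(sprintf("r%d", 1:4),
                        list(date = rep("2020-04-01", 4),
                             location = rep("NY", 4)))
  expect_equal(ncol(sliding_window_communities(md2, "date", "location",
                                               7, 5)), 0L)
  # min_records = 1 with one record yields one window
  md3 <- metadata_table("r1", list(date = "2020-04-01", location = "NY"))
  tab3 <- sliding_window_communities(md3, "date", "location", 7, 1)
  expect_equal(dim(tab3), c(1L, 1L))
  expect_error(sliding_window_communities(
    metadata_table("r1", list(date = "04/01/2020", location = "NY")),
    "date", "location", 7, 1), "unparseable date")
})

test_that("location renaming merges groups before windowing", {
  md <- metadata_table(sprintf("r%d", 1:6),
                       list(date = rep("2020-04-01", 6),
                            location = c("Bronx", "Queens", "Brooklyn",
                                         "NY", "NY", "LA")))
  ren <- c(Bronx = "NY", Queens = "NY", Brooklyn = "NY")
  tab <- sliding_window_communities(md, "date", "location", 7, 5,
                                    location_rename = ren)
  expect_identical(colnames(tab), "NY@2020-04-01")
  expect_equal(nrow(tab), 5L)
})

test_that("sliding windows equal the brute-force enumeration", {
  for (seed in 1:10) {
    md <- generate_record_fixture(40 + seed, 3, 25, seed = seed)
    got <- table_window_sets(
      sliding_window_communities(md, "date", "location", 7, 5))
    want <- bf_sliding_windows(md, "date", "location", 7, 5)
    expect_identical(got, want)
    # threshold always honoured
    expect_true(all(lengths(got) >= 5L))
  }
})
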