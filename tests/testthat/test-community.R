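test_that("presence index matches stored entries and is self-transpose", {
  tab <- tiny_table(c(3, 0,
                      0, 1), c("f1", "f2"), c("s1", "s2"))
  p <- build_presence(tab)
  expect_equal(p$feature_samples, list(f1 = "s1", f2 = "s2"))
  expect_equal(p$sample_features, list(s1 = "f1", s2 = "f2"))
  fx <- generate_fixture(40, 15, 0.3, seed = 7)
  p2 <- build_presence(fx$table)
  expect_equal(sum(lengths(p2$feature_samples)), length(fx$table@x))
  expect_equal(sum(lengths(p2$sample_features)), length(fx$table@x))
  # transpose invariant
  pairs_f <- sort(unlist(mapply(function(f, ss) paste(f, ss),
                                names(p2$feature_samples),
                                p2$feature_samples), use.names = FALSE))
  pairs_s <- sort(unlist(mapply(function(s, ff) paste(ff, s),
                                names(p2$sample_features),
                                p2$sample_features), use.names = FALSE))
  expect_identical(pairs_f, pairs_s)
})

test_that("tip category proportions stratify and sum to one", {
  tr <- read_newick("((f:1,g:1)i:1,h:1)r;")
  tab <- tiny_table(c(1, 0, 1,
                      2, 0, 0,
                      0, 0, 0), c("f", "g", "h"), c("s1", "s2", "s3"))
  md <- metadata_table(c("s1", "s2", "s3"),
                       list(cat = c("A", "B", "B")))
  p <- build_presence(tab)
  layer <- tip_category_proportions(tr, p, md, "cat")
  expect_equal(layer$payload$f, c(A = 0.5, B = 0.5))
  expect_equal(layer$payload$g, c(A = 1.0))
  expect_identical(layer$payload$h, numeric(0))   # tip in no sample: no bar
  # missing metadata pools into the reserved category
  md2 <- metadata_table(c("s1", "s2", "s3"), list(cat = c("A", NA, NA)))
  layer2 <- tip_category_proportions(tr, p, md2, "cat")
  expect_equal(layer2$payload$f, c(A = 0.5, `__missing__` = 0.5))
  md3 <- metadata_table(c("s1", "s2", "s3"),
                        list(cat = c("A", "__missing__", "B")))
  expect_error(tip_category_proportions(tr, p, md3, "cat"), "reserved")
  expect_error(tip_category_proportions(tr, p, md, "nope"), "no column")
})

test_that("table features absent from the tree warn (or error in strict mode)", {
  tr <- read_newick("(f:1,g:1)r;")
  tab <- tiny_table(c(1, 1, 1), c("f", "g", "zz"), "s1")
  md <- metadata_table("s1", list(cat = "A"))
  p <- build_presence(tab)
  expect_warning(tip_category_proportions(tr, p, md, "cat"), "zz")
  expect_error(tip_category_proportions(tr, p, md, "cat", strict = TRUE),
               "zz")
})

test_that("numeric aggregates follow the missing-exclusion rule", {
  tab <- tiny_table(c(1, 1, 0,
                      0, 1, 1,
                      0, 0, 0), c("f1", "f2", "f3"), c("s1", "s2", "s3"))
  p <- build_presence(tab)
  md <- metadata_table(c("s1", "s2", "s3"), list(ph = c(6, 8, NA)))
  agg <- feature_numeric_aggregate(p, md, "ph", "mean")
  expect_equal(agg[["f1"]], 7)
  expect_equal(agg[["f2"]], 8)          # the missing-pH sample is excluded
  expect_true(is.na(agg[["f3"]]))
  med <- feature_numeric_aggregate(p, md, "ph", "median")
  expect_equal(med[["f1"]], 7)
  # count_log10 of a feature in 10 samples is exactly 1
  tab10 <- tiny_table(rep(1, 10), "f", sprintf("s%d", 1:10))
  md10 <- metadata_table(sprintf("s%d", 1:10), list(ph = rep(7, 10)))
  cl <- feature_numeric_aggregate(build_presence(tab10), md10, "ph",
                                  "count_log10")
  expect_equal(cl[["f"]], 1)
  expect_error(feature_numeric_aggregate(p, md, "absent", "mean"),
               "no column")
})

test_that("middle-fraction subsetting uses interpolated quantiles", {
  md <- metadata_table(sprintf("s%d", 1:100), list(v = as.numeric(1:100)))
  kept <- subset_samples_middle_fraction(md, "v", 0.9)
  expect_equal(length(kept), 90L)        # cutoffs 5.95 and 95.05
  expect_setequal(kept, sprintf("s%d", 6:95))
  expect_equal(length(subset_samples_middle_fraction(md, "v", 1)), 100L)
  one <- metadata_table("s1", list(v = 5))
  expect_identical(subset_samples_middle_fraction(one, "v", 0.5), "s1")
  miss <- metadata_table(c("a", "b"), list(v = c(NA_real_, NA_real_)))
  expect_error(subset_samples_middle_fraction(miss, "v", 0.9), "missing")
  # the min-max-range alternative differs from quantiles when skewed
  skew <- metadata_table(sprintf("s%d", 1:5), list(v = c(1, 2, 3, 4, 100)))
  expect_lt(length(subset_samples_middle_fraction(skew, "v", 0.5,
                                                  mode = "range")),
            length(subset_samples_middle_fraction(skew, "v", 0.9)))
})

test_that("uniform metadata propagates up with missing tolerance", {
  tr <- read_newick("((a:1,b:1)x:1,(c:1)y:1)r;")
  md <- metadata_table(c("a", "b", "c"), list(g = c("P", "P", "Q")))
  nv <- propagate_uniform_metadata(tr, md, "g")
  val <- setNames(nv$value, node_names(tr))
  expect_equal(val[["x"]], "P")
  expect_equal(val[["y"]], "Q")
  expect_true(is.na(val[["r"]]))
  md2 <- metadata_table(c("a", "b", "c"), list(g = c("P", NA, "Q")))
  nv2 <- propagate_uniform_metadata(tr, md2, "g")
  expect_equal(setNames(nv2$value, node_names(tr))[["x"]], "P")
  md3 <- metadata_table(c("a", "b", "c"), list(g = c("P", "Q", "Q")))
  nv3 <- propagate_uniform_metadata(tr, md3, "g")
  expect_true(is.na(setNames(nv3$value, node_names(tr))[["x"]]))
})

test_that("collapsing picks maximal uniform clades and honours exclusions", {
  tr <- read_newick("((a:1,b:1)x:1,(c:1)y:1)r;")
  md <- metadata_table(c("a", "b", "c"), list(g = c("P", "P", "Q")))
  nv <- propagate_uniform_metadata(tr, md, "g")
  cc <- collapse_uniform_clades(tr, nv)
  expect_setequal(cc$name, c("x", "y"))
  expect_equal(cc$n_tips[cc$name == "x"], 2L)
  # all tips uniform: only the root collapses (maximality)
  md_all <- metadata_table(c("a", "b", "c"), list(g = c("P", "P", "P")))
  cc_all <- collapse_uniform_clades(tr, propagate_uniform_metadata(tr, md_all,
                                                                   "g"))
  expect_identical(cc_all$name, "r")
  # excluding x recurses into it; x has no internal uniform descendants
  cc_ex <- collapse_uniform_clades(tr, nv, exclude = "x")
  expect_identical(cc_ex$name, "y")
  # collapsed tip sets are disjoint and value-consistent
  for (seed in 1:5) {
    fx <- generate_fixture(30, 8, 0.4, seed = seed)
    nvr <- propagate_uniform_metadata(fx$tree, fx$feature_metadata, "guild")
    ccr <- collapse_uniform_clades(fx$tree, nvr)
    seen <- character(0)
    for (r in seq_len(nrow(ccr))) {
      sel <- node_to_samples(ccr$node[r], fx$tree, build_presence(fx$table))
      nd <- which(fx$tree$open_pos == ccr$node[r])
      span <- which(fx$tree$open_pos > fx$tree$open_pos[nd] &
                    fx$tree$open_pos < fx$tree$close_pos[nd])
      tipset <- fx$tree$names[span][fx$tree$is_tip[span]]
      expect_length(intersect(tipset, seen), 0L)
      seen <- c(seen, tipset)
      vals <- fx$feature_metadata[tipset, "guild"]
      expect_true(all(is.na(vals) | vals == ccr$value[r]))
    }
  }
})

test_that("barplot layers commute with shearing to shared tips", {
  fx <- generate_fixture(25, 10, 0.4, seed = 13)
  p <- build_presence(fx$table)
  sheared <- shear(fx$tree, rownames(fx$table))
  l_full <- suppressWarnings(
    tip_category_proportions(fx$tree, p, fx$sample_metadata, "group"))
  l_shear <- tip_category_proportions(sheared, p, fx$sample_metadata, "group")
  shared <- tip_names(sheared)
  expect_identical(l_full$payload[shared], l_shear$payload[shared])
})
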