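#' Presence index
#'
#' Bidirectional membership maps derived from a feature table: for every
#' feature the set of samples where its count is > 0, and the transpose.
#' Presence is strictly "count > 0"; the two maps always describe the same
#' set of (feature, sample) pairs.
#'
#' @param table a feature table (features x samples `dgCMatrix`).
#' @return a `presence_index`: list with `feature_samples` (named list
#'   feature -> character vector of samples) and `sample_features`.
#' @export
build_presence <- function(table) {
  validate_feature_table(table)
  s <- Matrix::summary(table)
  s <- s[s$x > 0, , drop = FALSE]
  feats <- rownames(table)
  samps <- colnames(table)
  fs <- rep(list(character(0)), length(feats))
  names(fs) <- feats
  sf <- rep(list(character(0)), length(samps))
  names(sf) <- samps
  if (nrow(s)) {
    by_f <- split(samps[s$j], feats[s$i])
    fs[names(by_f)] <- lapply(by_f, unname)
    by_s <- split(feats[s$i], samps[s$j])
    sf[names(by_s)] <- lapply(by_s, unname)
  }
  structure(list(feature_samples = fs, sample_features = sf),
            class = "presence_index")
}

#' @export
print.presence_index <- function(x, ...) {
  cat("<presence_index> ", length(x$feature_samples), " features, ",
      length(x$sample_features), " samples, ",
      sum(lengths(x$feature_samples)), " present pairs\n", sep = "")
  invisible(x)
}

MISSING_CATEGORY <- "__missing__"

categorical_values <- function(sample_md, field) {
  v <- md_column(sample_md, field, "categorical")
  if (any(v == MISSING_CATEGORY, na.rm = TRUE))
    stop("category '", MISSING_CATEGORY, "' is reserved for missing values")
  v[is.na(v)] <- MISSING_CATEGORY
  v
}

# tips of the tree that have a matching feature; warn about table features
# missing from the tree (or error when strict)
match_tips_features <- function(tree, feature_ids, strict = FALSE) {
  tips <- tip_names(tree)
  orphan <- setdiff(feature_ids, tips)
  if (length(orphan)) {
    msg <- paste0(length(orphan), " table feature(s) absent from the tree: ",
                  paste(utils::head(orphan, 5L), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  tips
}

#' Stacked-barplot layer: per-tip category proportions
#'
#' For every tip that occurs in at least one sample, the proportion of its
#' samples falling in each level of a categorical sample-metadata field —
#' the payload of a stacked barplot drawn alongside the tips. Samples with
#' a missing field value are pooled into the reserved `"__missing__"`
#' category. Tips absent from the table get an empty payload (no bar).
#'
#' @param tree a [bptree].
#' @param presence a [build_presence()] index.
#' @param sample_md sample [metadata_table].
#' @param field name of a categorical column.
#' @param strict error (instead of warn) on table features missing from
#'   the tree.
#' @return a `barplot_layer` with `kind = "categorical_stacked"`: per-tip
#'   named proportion vectors in `payload`, plus `field` and `tips`.
#' @export
tip_category_proportions <- function(tree, presence, sample_md, field,
                                     strict = FALSE) {
  cat_of <- categorical_values(sample_md, field)
  fs <- presence$feature_samples
  tips <- match_tips_features(tree, names(fs), strict)
  at <- match(tips, names(fs))           # positional: no per-name scans
  payload <- vector("list", length(tips))
  names(payload) <- tips
  for (k in seq_along(tips)) {
    ss <- if (is.na(at[k])) character(0) else fs[[at[k]]]
    if (length(ss) == 0L) { payload[[k]] <- numeric(0); next }
    cats <- cat_of[ss]
    if (anyNA(cats))
      stop("sample(s) in table but not in metadata: ",
           paste(utils::head(setdiff(ss, names(cat_of)), 5L),
                 collapse = ", "))
    tab <- table(cats)
    payload[[k]] <- stats::setNames(as.numeric(tab) / length(ss), names(tab))
  }
  structure(list(kind = "categorical_stacked", field = field,
                 tips = tips, payload = payload),
            class = "barplot_layer")
}

#' Numeric barplot layer from a feature-metadata column
#'
#' @param tree a [bptree].
#' @param feature_md feature [metadata_table].
#' @param field numeric column to display.
#' @param encode how the value is shown: colour gradient, bar length, or
#'   both.
#' @return a `barplot_layer` with `kind = "numeric"`: per-tip scalar (NA
#'   where the tip has no value).
#' @export
tip_numeric_layer <- function(tree, feature_md, field,
                              encode = c("both", "color", "length")) {
  encode <- match.arg(encode)
  v <- md_column(feature_md, field, "numeric")
  tips <- tip_names(tree)
  payload <- stats::setNames(v[tips], tips)   # NA for unmatched tips
  structure(list(kind = "numeric", field = field, encode = encode,
                 tips = tips, payload = payload),
            class = "barplot_layer")
}

#' @export
print.barplot_layer <- function(x, ...) {
  cat("<barplot_layer:", x$kind, "> field '", x$field, "', ",
      length(x$tips), " tips\n", sep = "")
  invisible(x)
}

#' Per-feature aggregate of a numeric sample-metadata field
#'
#' For each feature, aggregates the field over the samples that contain it
#' (count > 0); samples with a missing value are excluded from the
#' aggregate. `count_log10` ignores the field's values and reports
#' log10 of the number of containing samples — the "number of samples
#' (log10) in which this feature occurred" summary used for large survey
#' tables. Features present in no sample get `NA`.
#'
#' @param presence a [build_presence()] index.
#' @param sample_md sample [metadata_table].
#' @param field numeric column.
#' @param stat `"mean"`, `"median"` or `"count_log10"`.
#' @return named numeric vector over features.
#' @export
feature_numeric_aggregate <- function(presence, sample_md, field,
                                      stat = c("mean", "median",
                                               "count_log10")) {
  stat <- match.arg(stat)
  v <- md_column(sample_md, field, "numeric")
  vapply(presence$feature_samples, function(ss) {
    if (length(ss) == 0L) return(NA_real_)
    if (stat == "count_log10") return(log10(length(ss)))
    vals <- v[ss]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) return(NA_real_)
    if (stat == "mean") mean(vals) else stats::median(vals)
  }, numeric(1))
}

#' Keep samples in the middle fraction of a numeric field
#'
#' Drops samples with a missing value, then keeps those whose value lies
#' between the `(1-f)/2` and `1-(1-f)/2` empirical quantiles (linear
#' interpolation, inclusive at both cutoffs) — the standard way to trim
#' symmetric outliers, e.g. restricting a survey to the middle 90% of its
#' pH range. `mode = "range"` instead cuts at those fractions of the
#' min-max span.
#'
#' @param sample_md sample [metadata_table].
#' @param field numeric column.
#' @param keep_fraction fraction to keep, in (0, 1].
#' @param mode `"quantile"` (default) or `"range"`.
#' @return character vector of retained sample ids.
#' @export
subset_samples_middle_fraction <- function(sample_md, field, keep_fraction,
                                           mode = c("quantile", "range")) {
  mode <- match.arg(mode)
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  v <- md_column(sample_md, field, "numeric")
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("all values of '", field, "' are missing")
  a <- (1 - keep_fraction) / 2
  if (mode == "quantile") {
    cuts <- stats::quantile(v, c(a, 1 - a), names = FALSE, type = 7)
  } else {
    cuts <- min(v) + c(a, 1 - a) * (max(v) - min(v))
  }
  names(v)[v >= cuts[1L] & v <= cuts[2L]]
}

#' Propagate a uniform feature-metadata value up the tree
#'
#' Tips take their metadata value (missing where the tip has none). An
#' internal node takes value v exactly when at least one descendant tip
#' has a non-missing value and every such tip has the same value v;
#' otherwise it is missing ("mixed" or uninformative).
#'
#' @param tree a [bptree].
#' @param feature_md feature [metadata_table].
#' @param field column to propagate (categorical or numeric).
#' @return a `node_values` object: list with `value` (per node, preorder;
#'   NA = missing/mixed) and `status` (`"none"`, `"uniform"`, `"mixed"`).
#' @export
propagate_uniform_metadata <- function(tree, feature_md, field) {
  v <- md_column(feature_md, field)
  n <- tree$n_nodes
  value <- rep(NA_character_, n)
  tip_v <- as.character(v[tree$names[tree$is_tip]])
  value[tree$is_tip] <- tip_v
  status <- ifelse(tree$is_tip & !is.na(value), "uniform", "none")
  parent <- tree$parent
  if (n > 1L) for (nd in n:2L) {       # children precede parents this way
    p <- parent[nd]
    s_c <- status[nd]; s_p <- status[p]
    if (s_c == "none") next
    if (s_p == "mixed") next
    if (s_c == "mixed" ||
        (s_p == "uniform" && !identical(value[p], value[nd]))) {
      status[p] <- "mixed"; value[p] <- NA_character_
    } else {
      status[p] <- "uniform"; value[p] <- value[nd]
    }
  }
  structure(list(value = value, status = status, field = field),
            class = "node_values")
}

#' Collapse maximal uniform clades
#'
#' Given propagated node values, finds the maximal internal nodes whose
#' subtree is uniform (non-missing propagated value and no uniform
#' ancestor). Each is reported with its value and subtree tip count; their
#' tip sets are mutually disjoint. Named nodes listed in `exclude` are
#' never collapsed themselves — the search recurses into them, so maximal
#' uniform clades strictly inside an excluded node are still reported.
#'
#' @param tree a [bptree].
#' @param node_values result of [propagate_uniform_metadata()].
#' @param exclude character vector of node names to keep expanded.
#' @return data.frame with `node` (opening position), `name`, `value`,
#'   `n_tips` — one row per collapsed clade.
#' @export
collapse_uniform_clades <- function(tree, node_values, exclude = character()) {
  stopifnot(inherits(node_values, "node_values"))
  uniform <- node_values$status == "uniform" & !tree$is_tip
  ch <- children_list(tree)
  hit <- integer(0)
  stack <- 1L
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (uniform[nd] && !(tree$names[nd] %in% exclude)) {
      hit <- c(hit, nd)
    } else if (!tree$is_tip[nd]) {
      stack <- c(stack, rev(ch[[nd]]))
    }
  }
  data.frame(node = tree$open_pos[hit], name = tree$names[hit],
             value = node_values$value[hit], n_tips = tree$tip_count[hit],
             stringsAsFactors = FALSE)
}
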