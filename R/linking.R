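#' Selections linking samples and tree nodes
#'
#' The bidirectional queries behind linked ordination/tree views: picking
#' samples highlights the parts of the tree they contain, and picking a
#' node recovers the samples containing its clade.
#'
#' `samples_to_nodes()` returns the tips whose feature occurs in at least
#' one selected sample, plus every internal node all of whose descendant
#' tips are in that tip set — so a clade highlights as a whole exactly when
#' it is fully covered. `tips_only = TRUE` restricts to tips.
#'
#' `node_to_samples()` returns the union, over the node's descendant tips,
#' of the samples containing each tip (for a tip node, just its own
#' samples).
#'
#' Node ids inside a `selection` are postorder ranks of the current tree
#' (convert with [bp_postorder_select()] / [bp_postorder_rank()]).
#'
#' @param sample_ids character sample ids (must exist in the index).
#' @param presence a [build_presence()] index.
#' @param tree a [bptree].
#' @param tips_only include only tip nodes in the selection.
#' @return a `selection`: list with `origin`, `sample_ids`, `node_ids`
#'   (postorder ranks) and `label`.
#' @export
samples_to_nodes <- function(sample_ids, presence, tree, tips_only = FALSE,
                             label = "") {
  sample_ids <- as.character(sample_ids)
  unknown <- setdiff(sample_ids, names(presence$sample_features))
  if (length(unknown))
    stop("unknown sample id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  feats <- unique(unlist(presence$sample_features[sample_ids],
                         use.names = FALSE))
  n <- tree$n_nodes
  covered <- logical(n)
  covered[tree$is_tip] <- tree$names[tree$is_tip] %in% feats
  nodes <- which(covered)
  if (!tips_only && n > 1L) {
    # an internal node is fully covered iff its covered-tip count equals
    # its subtree tip count; accumulate covered tips child-to-parent
    cov_tips <- integer(n)
    cov_tips[tree$is_tip] <- as.integer(covered[tree$is_tip])
    parent <- tree$parent
    for (nd in n:2L) cov_tips[parent[nd]] <- cov_tips[parent[nd]] + cov_tips[nd]
    full <- !tree$is_tip & cov_tips == tree$tip_count
    nodes <- c(nodes, which(full))
  }
  new_selection("samples", sample_ids, sort(tree$post_rank[nodes]), label)
}

new_selection <- function(origin, sample_ids, node_ids, label = "") {
  structure(list(origin = origin, sample_ids = sample_ids,
                 node_ids = as.integer(node_ids), label = label),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat("<selection:", x$origin, "> ", length(x$sample_ids), " samples, ",
      length(x$node_ids), " nodes",
      if (nzchar(x$label)) paste0(" ('", x$label, "')") else "",
      "\n", sep = "")
  invisible(x)
}

#' @rdname samples_to_nodes
#' @param i opening position of the query node.
#' @param label selection label.
#' @export
node_to_samples <- function(i, tree, presence, label = "") {
  nd <- node_of(tree, i)
  span <- which(tree$open_pos >= tree$open_pos[nd] &
                tree$open_pos <= tree$close_pos[nd])
  tips <- tree$names[span[tree$is_tip[span]]]
  found <- intersect(tips, names(presence$feature_samples))
  samples <- sort(unique(unlist(presence$feature_samples[found],
                                use.names = FALSE)))
  if (is.null(samples)) samples <- character(0)
  new_selection("node", samples, tree$post_rank[nd], label)
}

#' Summarize a selection over a categorical field
#'
#' Counts the selection's samples per level of a categorical
#' sample-metadata field; missing values pool into `"__missing__"`. The
#' counts sum to the number of selected samples.
#'
#' @param selection a `selection`.
#' @param sample_md sample [metadata_table].
#' @param field categorical column.
#' @return named integer vector of counts (empty for an empty selection).
#' @export
summarize_selection <- function(selection, sample_md, field) {
  stopifnot(inherits(selection, "selection"))
  cat_of <- categorical_values(sample_md, field)
  ids <- selection$sample_ids
  if (length(ids) == 0L) return(stats::setNames(integer(0), character(0)))
  unknown <- setdiff(ids, names(cat_of))
  if (length(unknown))
    stop("sample(s) missing from metadata: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  tab <- table(cat_of[ids])
  stats::setNames(as.integer(tab), names(tab))
}

#' Resolve a biplot arrow to a tree node
#'
#' Maps a feature arrow of a biplot ordination to the tree node with
#' exactly that name (tips for ordinary features; internal nodes match
#' too, since internal labels are names).
#'
#' @param feature_id the arrow's feature id.
#' @param ordination an `ordination` with feature (biplot) coordinates.
#' @param tree a [bptree].
#' @return the node's opening position.
#' @export
resolve_biplot_arrow <- function(feature_id, ordination, tree) {
  stopifnot(inherits(ordination, "ordination"))
  if (is.null(ordination$feature_coords))
    stop("ordination has no biplot (feature) coordinates")
  if (!feature_id %in% ordination$feature_ids)
    stop("feature '", feature_id, "' is not in the ordination's biplot")
  hit <- which(tree$names == feature_id)
  if (length(hit) == 0L)
    stop("feature '", feature_id, "' does not match any tree node")
  tree$open_pos[hit[1L]]
}

#' Animation frames: per-timepoint unique features of each trajectory
#'
#' Orders samples along a gradient field (e.g. time; numeric columns sort
#' numerically, categorical ones lexicographically) and groups them within
#' each frame by a trajectory field (e.g. location). For each frame and
#' trajectory the "unique features" are those present in that trajectory's
#' samples but in no other trajectory of the same frame — the tree nodes
#' an animation highlights as exclusive to the group at that timepoint.
#' Samples missing either field are dropped.
#'
#' @param sample_md sample [metadata_table].
#' @param gradient_field column ordering the frames.
#' @param trajectory_field column grouping samples within a frame.
#' @param presence a [build_presence()] index.
#' @return a `frame_series`: list with `gradient_field`,
#'   `trajectory_field`, `frame_keys` (ordered), `samples` (frame ->
#'   trajectory -> sample ids) and `unique_features` (frame -> trajectory
#'   -> feature ids).
#' @export
build_frames <- function(sample_md, gradient_field, trajectory_field,
                         presence) {
  grad <- md_column(sample_md, gradient_field)
  traj <- md_column(sample_md, trajectory_field)
  keep <- !is.na(grad) & !is.na(traj)
  grad <- grad[keep]; traj <- traj[keep]
  keys <- sort(unique(grad))                # numeric or lexicographic sort
  frame_keys <- as.character(keys)
  samples <- list(); uniq <- list()
  for (fk in seq_along(keys)) {
    in_frame <- names(grad)[grad == keys[fk]]
    by_traj <- split(in_frame, as.character(traj[in_frame]))
    featsets <- lapply(by_traj, function(ids) {
      unique(unlist(presence$sample_features[
        intersect(ids, names(presence$sample_features))],
        use.names = FALSE))
    })
    u <- lapply(seq_along(featsets), function(g) {
      others <- unique(unlist(featsets[-g], use.names = FALSE))
      setdiff(featsets[[g]], others)
    })
    names(u) <- names(featsets)
    samples[[frame_keys[fk]]] <- by_traj
    uniq[[frame_keys[fk]]] <- u
  }
  structure(list(gradient_field = gradient_field,
                 trajectory_field = trajectory_field,
                 frame_keys = frame_keys, samples = samples,
                 unique_features = uniq),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat("<frame_series> ", length(x$frame_keys), " frames over '",
      x$gradient_field, "' x '", x$trajectory_field, "'\n", sep = "")
  invisible(x)
}

#' Sliding-window community construction
#'
#' Builds per-location "community samples" from dated records (e.g.
#' genomes with collection dates): within each location a window of
#' `window_days` days slides one day at a time across the location's
#' observed date range; every window containing at least `min_records`
#' records is emitted as one community sample whose feature vector marks
#' each contained record once (presence). Community sample ids are
#' `"<location>@<window start ISO date>"`. Windows are inclusive:
#' a window starting on day d covers d .. d + window_days - 1.
#'
#' @param record_md record [metadata_table] (row ids are record ids).
#' @param date_field column of ISO-8601 dates (`YYYY-MM-DD`).
#' @param location_field categorical column of locations.
#' @param window_days window width in days (>= 1).
#' @param min_records minimum records for a window to be emitted (>= 1).
#' @param location_rename optional named character vector mapping raw
#'   location names to merged ones (e.g. boroughs to their city), applied
#'   before windowing.
#' @return a feature table (`dgCMatrix`) with records as rows and
#'   community samples as columns; 0 x 0 if no window qualifies.
#' @export
sliding_window_communities <- function(record_md, date_field, location_field,
                                       window_days = 7L, min_records = 5L,
                                       location_rename = NULL) {
  stopifnot(window_days >= 1L, min_records >= 1L)
  date_raw <- md_column(record_md, date_field)
  loc <- as.character(md_column(record_md, location_field))
  if (!is.null(location_rename)) {
    hit <- loc %in% names(location_rename)
    loc[hit] <- location_rename[loc[hit]]
  }
  dates <- as.Date(as.character(date_raw), format = "%Y-%m-%d")
  bad <- is.na(dates) & !is.na(date_raw)
  if (any(bad))
    stop("unparseable date(s): ",
         paste(utils::head(unique(date_raw[bad]), 5L), collapse = ", "))
  ok <- !is.na(dates) & !is.na(loc)
  ids <- rownames(record_md)[ok]
  dates <- dates[ok]; loc <- loc[ok]
  rec_i <- character(0); samp_j <- character(0)
  for (g in sort(unique(loc))) {
    in_g <- loc == g
    d <- as.integer(dates[in_g])
    r <- ids[in_g]
    for (start in seq(min(d), max(d))) {
      hit <- d >= start & d <= start + window_days - 1L
      if (sum(hit) >= min_records) {
        sid <- paste0(g, "@", format(as.Date(start, origin = "1970-01-01"),
                                     "%Y-%m-%d"))
        rec_i <- c(rec_i, r[hit])
        samp_j <- c(samp_j, rep(sid, sum(hit)))
      }
    }
  }
  if (length(rec_i) == 0L) {
    empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0), dims = c(0L, 0L))
    dimnames(empty) <- list(character(0), character(0))
    return(empty)
  }
  rec_lv <- sort(unique(rec_i))
  samp_lv <- unique(samp_j)                 # order of emission
  m <- Matrix::sparseMatrix(i = match(rec_i, rec_lv),
                            j = match(samp_j, samp_lv), x = 1,
                            dims = c(length(rec_lv), length(samp_lv)),
                            dimnames = list(rec_lv, samp_lv))
  as_feature_table(m)
}
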