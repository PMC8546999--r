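#' Deterministic synthetic fixtures
#'
#' Generates a random tree plus a matching sparse feature table and sample
#' and feature metadata, all reproducible from a single seed (the same seed
#' yields byte-identical outputs). The tree is grown by sequential random
#' coalescence — repeatedly merging randomly chosen lineages, occasionally
#' three at a time so multifurcations occur — with exponential branch
#' lengths (rate 1). Table features are a random subset of the tree's tips;
#' each (sample, feature) cell is occupied independently with probability
#' `density` and occupied cells carry 1 + Poisson(2) counts. Sample
#' metadata carries a categorical `group` column (with a few missing
#' values) and a numeric `ph` column spanning 4 to 10 (again with missing
#' values); feature metadata carries a categorical `guild` and a numeric
#' `score` column.
#'
#' @param n_tips number of tips (>= 2).
#' @param n_samples number of samples.
#' @param density probability a (sample, feature) cell is non-zero, in
#'   (0, 1].
#' @param seed integer seed fixing all randomness.
#' @param feature_fraction fraction of tips that appear in the table.
#' @param multifurcation_prob probability a coalescence merges three
#'   lineages instead of two.
#' @return list with `newick` (string), `tree` ([bptree]), `table`
#'   (features x samples `dgCMatrix`), `sample_metadata` and
#'   `feature_metadata` ([metadata_table]s).
#' @export
generate_fixture <- function(n_tips, n_samples, density, seed,
                             feature_fraction = 0.8,
                             multifurcation_prob = 0.15) {
  stopifnot(n_tips >= 2L, n_samples >= 1L, density > 0, density <= 1)
  withr::with_seed(seed, {
    tree <- random_coalescent_tree(n_tips, multifurcation_prob)
    newick <- write_newick(tree)
    feats <- sort(sample(tip_names(tree),
                         max(1L, round(feature_fraction * n_tips))))
    occ <- matrix(stats::runif(length(feats) * n_samples) < density,
                  nrow = length(feats))
    counts <- matrix(0, nrow = length(feats), ncol = n_samples,
                     dimnames = list(feats, sprintf("s%d", seq_len(n_samples))))
    counts[occ] <- 1 + stats::rpois(sum(occ), 2)
    table <- as_feature_table(counts)

    group <- sample(c("Soil", "Water", "Host"), n_samples, replace = TRUE)
    group[stats::runif(n_samples) < 0.05] <- NA
    ph <- round(stats::runif(n_samples, 4, 10), 2)
    ph[stats::runif(n_samples) < 0.05] <- NA
    sample_md <- metadata_table(colnames(counts),
                                list(group = group, ph = ph))

    guild <- sample(c("P", "Q", "R"), length(feats), replace = TRUE)
    score <- round(stats::rnorm(length(feats)), 3)
    feature_md <- metadata_table(feats, list(guild = guild, score = score))

    list(newick = newick, tree = tree, table = table,
         sample_metadata = sample_md, feature_metadata = feature_md)
  })
}

# sequential random coalescence over active lineages; O(n) bookkeeping
random_coalescent_tree <- function(n_tips, multifurcation_prob = 0.15) {
  n_max <- 2L * n_tips                       # generous upper bound on nodes
  names <- character(n_max)
  lens <- numeric(n_max)
  children <- vector("list", n_max)
  names[seq_len(n_tips)] <- sprintf("t%d", seq_len(n_tips))
  lens[seq_len(n_tips)] <- stats::rexp(n_tips)
  active <- seq_len(n_tips)
  n_active <- n_tips
  next_id <- n_tips + 1L
  internal <- 0L
  while (n_active > 1L) {
    k <- if (n_active > 2L &&
             stats::runif(1) < multifurcation_prob) 3L else 2L
    pick <- sort(sample.int(n_active, k))
    internal <- internal + 1L
    names[next_id] <- sprintf("n%d", internal)
    lens[next_id] <- stats::rexp(1)
    children[[next_id]] <- active[pick]
    active[pick[1L]] <- next_id                  # swap-remove: O(1) per merge
    for (j in rev(pick[-1L])) {
      active[j] <- active[n_active]
      n_active <- n_active - 1L
    }
    next_id <- next_id + 1L
  }
  root <- active[1L]
  lens[root] <- NA_real_                      # the root has no branch
  tree_from_children(children[seq_len(next_id - 1L)],
                     names[seq_len(next_id - 1L)],
                     lens[seq_len(next_id - 1L)], root = root)
}

#' Synthetic longitudinal record metadata
#'
#' Emulates per-record (e.g. per-genome) metadata for the sliding-window
#' community builder: each record gets an ISO collection date drawn
#' uniformly from a date range and a sampling location. Deterministic per
#' seed.
#'
#' @param n_records number of records.
#' @param n_locations number of distinct locations.
#' @param n_days span of the date range, starting 2020-03-01.
#' @param seed integer seed.
#' @return a [metadata_table] with `date` and `location` columns (both
#'   categorical; dates are ISO-8601 strings).
#' @export
generate_record_fixture <- function(n_records, n_locations = 3L,
                                    n_days = 30L, seed = 1L) {
  stopifnot(n_records >= 1L, n_locations >= 1L, n_days >= 1L)
  withr::with_seed(seed, {
    origin <- as.Date("2020-03-01")
    dates <- origin + sample.int(n_days, n_records, replace = TRUE) - 1L
    loc <- sample(sprintf("loc%d", seq_len(n_locations)), n_records,
                  replace = TRUE)
    metadata_table(sprintf("rec%d", seq_len(n_records)),
                   list(date = format(dates, "%Y-%m-%d"), location = loc))
  })
}
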