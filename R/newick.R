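#' Read and write Newick trees
#'
#' `read_newick()` parses a single `;`-terminated Newick statement into a
#' [bptree]. Multifurcations, internal-node labels, quoted labels (with
#' `''` escaping) and `[]` comments are supported; underscores are kept
#' verbatim; internal labels are treated as node names, not support values.
#' A branch with no `:length` keeps a missing (`NA`) length — distinct from
#' an explicit zero. Malformed input raises an error naming the 1-based
#' character offset.
#'
#' `write_newick()` is the exact inverse: reading its output reproduces the
#' topology, names and branch lengths bit for bit (lengths are printed with
#' round-trip-safe precision; absent lengths are omitted).
#'
#' @param text a Newick string (or, for `read_newick_file`, a path).
#' @param allow_duplicate_tips passed through to [bptree()].
#' @return `read_newick()` a [bptree]; `write_newick()` a Newick string.
#' @examples
#' tr <- read_newick("((a:1.0,b:2.0)c:3.0,d:4.0)e;")
#' n_tips(tr)            # 3
#' write_newick(tr)
#' @export
read_newick <- function(text, allow_duplicate_tips = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  parsed <- parse_newick_cpp(text)
  bptree(parsed$bits, parsed$names, parsed$lengths,
         allow_duplicate_tips = allow_duplicate_tips)
}

#' @rdname read_newick
#' @param path file containing one Newick statement.
#' @export
read_newick_file <- function(path, allow_duplicate_tips = FALSE) {
  read_newick(paste(readLines(path, warn = FALSE), collapse = "\n"),
              allow_duplicate_tips = allow_duplicate_tips)
}

# shortest decimal representation that parses back to the same double,
# verified against the same strtod the parser uses
format_length <- function(x) {
  out <- sprintf("%.15g", x)
  ok <- is.na(x) | strtod_cpp(out) == x
  out[!ok] <- sprintf("%.17g", x[!ok])
  out
}

needs_quoting <- function(s) grepl("[][ \t\n\r()':;,]", s)

format_label <- function(s) {
  q <- nzchar(s) & needs_quoting(s)
  s[q] <- paste0("'", gsub("'", "''", s[q], fixed = TRUE), "'")
  s
}

#' @rdname read_newick
#' @param tree a [bptree].
#' @export
write_newick <- function(tree) {
  m <- length(tree$bits)
  label <- format_label(tree$names)
  len <- character(tree$n_nodes)
  has <- !is.na(tree$lengths)
  len[has] <- paste0(":", format_length(tree$lengths[has]))
  suffix <- paste0(label, len)          # printed after each node's subtree

  tok <- character(m)
  internal <- !tree$is_tip
  tok[tree$open_pos[internal]] <- "("
  tok[tree$close_pos[internal]] <- paste0(")", suffix[internal])
  tok[tree$open_pos[tree$is_tip]] <- suffix[tree$is_tip]
  # tok at tip close positions stays ""
  # a "," goes between a close and the next (sibling) open
  sep <- c(FALSE, !tree$bits[-m]) & tree$bits
  tok[sep] <- paste0(",", tok[sep])
  paste0(paste(tok, collapse = ""), ";")
}

#' @rdname read_newick
#' @param path output file.
#' @export
write_newick_file <- function(tree, path) {
  writeLines(write_newick(tree), path)
  invisible(path)
}
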