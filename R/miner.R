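#' Mining parameters
#'
#' @param gap Gap constraint `G >= 1`. Consecutive matched positions `p`
#'   (earlier item) and `q` (later item) must satisfy `p < q < p + G`, so
#'   `G = 2` restricts patterns to contiguous substrings and `G = 1` admits
#'   no extension at all.
#' @param min_support Absolute minimum support count (integer `>= 1`), or
#'   `NULL` when `min_support_frac` is given.
#' @param min_support_frac Minimum support as a fraction of `N` in `(0, 1]`;
#'   resolved to `ceiling(frac * N)`.
#' @param min_length Patterns shorter than this are mined (they drive the
#'   recursion) but not reported. Default 1: single residues are legitimate
#'   patterns.
#' @param max_length Stop extending patterns at this length; `Inf` (default)
#'   relies on support pruning for termination.
#' @param report_positions Keep each reported pattern's counting matrix
#'   (per-sequence end positions) in the result.
#' @return An object of class `"mining_params"`.
#' @examples
#' mining_params(gap = 3, min_support = 3)
#' mining_params(gap = 5, min_support_frac = 0.9)
#' @export
mining_params <- function(gap, min_support = NULL, min_support_frac = NULL,
                          min_length = 1L, max_length = Inf,
                          report_positions = FALSE) {
  if (length(gap) != 1L || is.na(gap) || gap < 1)
    stop("gap constraint must be a single integer >= 1", call. = FALSE)
  if (is.null(min_support) && is.null(min_support_frac))
    stop("one of min_support or min_support_frac is required", call. = FALSE)
  if (!is.null(min_support) && !is.null(min_support_frac))
    stop("give min_support or min_support_frac, not both", call. = FALSE)
  if (!is.null(min_support) &&
      (length(min_support) != 1L || is.na(min_support) || min_support < 1))
    stop("min_support must be a single integer >= 1", call. = FALSE)
  if (!is.null(min_support_frac) &&
      (length(min_support_frac) != 1L || is.na(min_support_frac) ||
       min_support_frac <= 0 || min_support_frac > 1))
    stop("min_support_frac must lie in (0, 1]", call. = FALSE)
  if (min_length < 1) stop("min_length must be >= 1", call. = FALSE)
  if (max_length < 1) stop("max_length must be >= 1", call. = FALSE)
  structure(list(gap = as.integer(gap),
                 min_support = if (!is.null(min_support))
                   as.integer(min_support),
                 min_support_frac = min_support_frac,
                 min_length = as.integer(min_length),
                 max_length = max_length,
                 report_positions = isTRUE(report_positions)),
            class = "mining_params")
}

#' Resolve the absolute support threshold
#'
#' An absolute `min_support` is used as is; a fractional one resolves to
#' `ceiling(frac * N)`. A pattern qualifies when its support is greater than
#' or equal to the resolved threshold. A threshold above `N` is legal but
#' unreachable; a warning is issued since no pattern can then qualify.
#'
#' @param params A [mining_params()].
#' @param N Number of sequences in the database.
#' @return Integer threshold `>= 1`.
#' @examples
#' resolve_threshold(mining_params(gap = 3, min_support = 3), N = 3)
#' resolve_threshold(mining_params(gap = 3, min_support_frac = 0.9), N = 3000)
#' @export
resolve_threshold <- function(params, N) {
  stopifnot(inherits(params, "mining_params"), N >= 1)
  thr <- if (!is.null(params$min_support)) params$min_support
         else as.integer(ceiling(params$min_support_frac * N))
  thr <- max(thr, 1L)
  if (thr > N)
    warning(sprintf("support threshold %d exceeds N = %d: no pattern can qualify",
                    thr, N), call. = FALSE)
  thr
}

#' Counting matrix of a single item
#'
#' The counting matrix is the miner's sole per-pattern state: row `j` holds
#' the positions at which an occurrence of the current pattern can end in
#' sequence `j`. For a length-1 pattern these are simply all occurrence
#' positions of the item, i.e. the raw index rows.
#'
#' @param index A [build_index()] result.
#' @param item Single residue symbol.
#' @return A list of `N` strictly increasing integer vectors (class
#'   `"counting_matrix"`).
#' @examples
#' db <- seq_db(c("ATACGAT", "ATCACGA", "TAACGCA"), ids = c("X", "Y", "Z"))
#' idx <- build_index(db)
#' initial_matrix(idx, "C")  # (4), (3,5), (4,6)
#' @export
initial_matrix <- function(index, item) {
  check_index_item(index, item)
  structure(index$pos[[item]], class = "counting_matrix")
}

#' Extend a counting matrix by one item
#'
#' Row `j` of the result is the sorted, duplicate-free set of positions `q`
#' of `item` in sequence `j` for which some parent end position `p`
#' satisfies the gap constraint `p < q < p + G`. All qualifying positions
#' are retained: keeping only the smallest successor of each parent position
#' is provably incomplete, because a discarded later occurrence may be the
#' only one able to reach the next item (see the package vignette). The
#' `retain = "min-only"` variant implements exactly that crippled rule and
#' exists purely as a regression guard in the test suite.
#'
#' @param index A [build_index()] result.
#' @param parent Counting matrix of the current pattern.
#' @param item Residue symbol to append.
#' @param G Gap constraint.
#' @param retain `"all"` (correct, default) or `"min-only"` (deliberately
#'   incomplete reference behaviour).
#' @return A `"counting_matrix"`.
#' @examples
#' db <- seq_db(c("ATACGAT", "ATCACGA", "TAACGCA"), ids = c("X", "Y", "Z"))
#' idx <- build_index(db)
#' extend_matrix(idx, initial_matrix(idx, "C"), "A", G = 3)
#' @export
extend_matrix <- function(index, parent, item, G,
                          retain = c("all", "min-only")) {
  retain <- match.arg(retain)
  check_index_item(index, item)
  stopifnot(G >= 1)
  G <- as.integer(G)
  pos_rows <- index$pos[[item]]
  rows <- vector("list", index$N)
  for (j in seq_len(index$N)) {
    par <- parent[[j]]
    pos <- pos_rows[[j]]
    if (length(par) == 0L || length(pos) == 0L) {
      rows[[j]] <- integer(0)
    } else if (retain == "all") {
      # q qualifies iff some parent p lies in (q - G, q); count parents in
      # that open interval via two binary searches on the sorted parent row
      keep <- findInterval(pos - 1L, par) > findInterval(pos - G, par)
      rows[[j]] <- pos[keep]
    } else {
      # crippled rule: only the first in-window successor of each parent
      nxt <- findInterval(par, pos) + 1L
      ok <- nxt <= length(pos)
      q <- pos[nxt[ok]]
      q <- q[q < par[ok] + G]
      rows[[j]] <- sort(unique(q))
    }
  }
  structure(rows, class = "counting_matrix")
}

#' Support of a counting matrix
#'
#' The number of rows with at least one end position. A sequence contributes
#' at most one support count however many occurrences it holds.
#'
#' @param matrix A `"counting_matrix"`.
#' @return Integer support count.
#' @examples
#' support_of(structure(list(6L, c(4L, 7L), 7L), class = "counting_matrix"))
#' @export
support_of <- function(matrix) {
  sum(lengths(matrix) > 0L)
}

pattern_string <- function(items) paste(items, collapse = "*")

#' Mine gapped sequential patterns depth-first
#'
#' Builds the position index once, then spells candidate patterns one item
#' at a time in fixed alphabet order. Each candidate's counting matrix is
#' derived from its parent's by [extend_matrix()]; when the support meets
#' the threshold the pattern is reported and every one-item extension is
#' tried in turn, otherwise the whole subtree is pruned (support can never
#' recover under extension). Patterns are reported in depth-first preorder,
#' each exactly once; two runs on the same input produce identical output.
#'
#' @param db A [seq_db()].
#' @param params A [mining_params()].
#' @param sort Re-sort the result lexicographically by pattern string, ties
#'   by descending support (default keeps DFS preorder).
#' @return An object of class `"motif_set"`: list with `motifs` (data.frame
#'   with columns `pattern`, `length`, `support`, `support_fraction`),
#'   `positions` (named list of counting-matrix snapshots when
#'   `report_positions` was set, else `NULL`), `threshold`, `gap`, `N`.
#' @examples
#' db <- seq_db(c("ATACGAT", "ATCACGA", "TAACGCA"), ids = c("X", "Y", "Z"))
#' res <- mine(db, mining_params(gap = 3, min_support = 3))
#' subset(res$motifs, pattern == "C*A")
#' @export
mine <- function(db, params, sort = FALSE) {
  stopifnot(inherits(db, "seq_db"), inherits(params, "mining_params"))
  if (db$N == 0L) stop("empty sequence database", call. = FALSE)
  mine_impl(db, params, sort = sort, retain = "all")
}

# retain = "min-only" is reachable only from the test suite: it swaps in the
# incomplete extension rule so its failure mode stays demonstrable.
mine_impl <- function(db, params, sort = FALSE, retain = "all") {
  index <- build_index(db)
  thr <- resolve_threshold(params, db$N)
  items <- db$alphabet$items
  G <- params$gap

  acc <- new.env(parent = emptyenv())
  acc$pattern <- character(0)
  acc$length <- integer(0)
  acc$support <- integer(0)
  acc$positions <- list()

  emit <- function(its, supp, mat) {
    if (length(its) < params$min_length) return(invisible())
    key <- pattern_string(its)
    k <- length(acc$pattern) + 1L
    acc$pattern[k] <- key
    acc$length[k] <- length(its)
    acc$support[k] <- supp
    if (params$report_positions) {
      snap <- mat
      names(snap) <- db$ids
      acc$positions[[key]] <- snap
    }
    invisible()
  }

  spell <- function(its, mat, supp) {
    emit(its, supp, mat)
    if (length(its) >= params$max_length) return(invisible())
    for (it in items) {
      child <- extend_matrix(index, mat, it, G, retain = retain)
      s <- support_of(child)
      if (s >= thr) spell(c(its, it), child, s)
    }
    invisible()
  }

  if (thr <= db$N) {
    for (it in items) {
      mat <- initial_matrix(index, it)
      s <- support_of(mat)
      if (s >= thr) spell(it, mat, s)
    }
  }

  motifs <- data.frame(pattern = acc$pattern,
                       length = acc$length,
                       support = acc$support,
                       support_fraction = acc$support / db$N,
                       stringsAsFactors = FALSE)
  if (sort && nrow(motifs) > 0L) {
    o <- order(motifs$pattern, -motifs$support)
    motifs <- motifs[o, , drop = FALSE]
    rownames(motifs) <- NULL
  }
  structure(list(motifs = motifs,
                 positions = if (params$report_positions) acc$positions,
                 threshold = thr, gap = G, N = db$N,
                 alphabet = db$alphabet),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf(
    "<motif_set: %d patterns (threshold %d of %d sequences, gap %d)>\n",
    nrow(x$motifs), x$threshold, x$N, x$gap))
  if (nrow(x$motifs) > 0L)
    print(utils::head(x$motifs, 10L), row.names = FALSE)
  if (nrow(x$motifs) > 10L)
    cat(sprintf("  ... and %d more\n", nrow(x$motifs) - 10L))
  invisible(x)
}

#' Write mined motifs as TSV
#'
#' Columns: `pattern` (items joined by `*`), `length`, `support`,
#' `support_fraction` (support / N, 6 decimals). With `positions_path`, a
#' second TSV maps each pattern to its per-sequence end positions
#' (comma-separated; empty cell for sequences without an occurrence).
#'
#' @param x A `"motif_set"` from [mine()].
#' @param path Output TSV.
#' @param positions_path Optional output TSV for end positions (requires the
#'   motifs to have been mined with `report_positions = TRUE`).
#' @return `path`, invisibly.
#' @export
write_motifs <- function(x, path, positions_path = NULL) {
  stopifnot(inherits(x, "motif_set"))
  m <- x$motifs
  m$support_fraction <- sprintf("%.6f", m$support_fraction)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(positions_path)) {
    if (is.null(x$positions))
      stop("motifs were mined without report_positions = TRUE", call. = FALSE)
    rows <- lapply(names(x$positions), function(p) {
      snap <- x$positions[[p]]
      data.frame(pattern = p,
                 sequence_id = names(snap),
                 end_positions = vapply(snap, paste, "", collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    utils::write.table(out, positions_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
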