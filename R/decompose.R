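#' Root a tree at its center
#'
#' Regards a chemical tree as a rooted tree by choosing the center: the single
#' middle vertex of a longest path (even diameter) or the middle adjacent
#' vertex pair (odd diameter). For a pair root both vertices are roots and
#' the heights on either side are computed ignoring the root edge.
#'
#' @param tree a [chem_graph()] that is a tree.
#' @return An object of class `rooted_tree`: list with `graph`, `root`
#'   (1 or 2 vertex ids), `parent` (named character; `NA` at roots),
#'   `children` (named list), `height` (named integer), `depth`
#'   (named integer; distance to the nearest root).
#' @export
root_at_center <- function(tree) {
  root_tree_at(tree, find_center(tree))
}

#' Root a tree at a chosen vertex (or adjacent pair)
#'
#' Like [root_at_center()] but with an explicit root; used for fringe trees
#' and custom rootings.
#'
#' @param tree a [chem_graph()] that is a tree.
#' @param root one vertex id, or two ids of adjacent vertices.
#' @return a `rooted_tree`.
#' @export
root_tree_at <- function(tree, root) {
  validate_tree_shape(tree)
  adj <- adjacency_list(tree)
  ids <- tree$vertices$id
  parent <- stats::setNames(rep(NA_character_, length(ids)), ids)
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  # BFS from the root set; for a pair root, the root edge links two depth-0
  # vertices and is excluded from parent/child relations.
  queue <- root
  depth[root] <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]$ids) {
      if (!is.na(depth[w])) next
      depth[w] <- depth[v] + 1L
      parent[w] <- v
      queue <- c(queue, w)
    }
  }
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) children[[id]] <- character(0)
  for (id in ids) if (!is.na(parent[id])) children[[parent[id]]] <- c(children[[parent[id]]], id)
  height <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  ord <- ids[order(depth[ids], decreasing = TRUE)]
  for (id in ord) {
    kids <- children[[id]]
    height[id] <- if (length(kids)) 1L + max(height[kids]) else 0L
  }
  structure(list(graph = tree, root = root, parent = parent,
                 children = children, height = height, depth = depth),
            class = "rooted_tree")
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat("<rooted_tree> root:", paste(x$root, collapse = "+"),
      " n =", length(x$parent), " height =", max(x$height[x$root]), "\n")
  invisible(x)
}

is_root <- function(rt, v) v %in% rt$root

#' Branch decomposition of a rooted tree
#'
#' For a branch-parameter `k >= 0`, identifies the k-branches of a tree
#' rooted at its center and everything that follows from them:
#' \itemize{
#'   \item a \emph{leaf k-branch} is a non-root vertex of height exactly `k`;
#'   \item a \emph{non-leaf k-branch} is a non-root vertex with at least two
#'     children, all of height at least `k`;
#'   \item \emph{k-branch-paths} join root/branch endpoints with no root or
#'     branch internal vertex; their edge union is the \emph{k-branch-subtree}
#'     whose edges and vertices are the k-internal sets;
#'   \item contracting each branch-path to an edge yields the
#'     \emph{k-branch-tree}, whose height is `bh_k` and whose leaves are
#'     counted by `bl_k`;
#'   \item the connected components of the external edges are the
#'     \emph{k-fringe-trees}, each rooted at its unique internal vertex and of
#'     height at most `k`.
#' }
#' When the root is an adjacent pair, the root edge belongs to the internal
#' edge set. With no k-branch at all the branch-tree is the bare root and
#' `bl_k = bh_k = 0`.
#'
#' @param tree a `rooted_tree` from [root_at_center()].
#' @param k non-negative integer branch-parameter.
#' @return An object of class `branch_decomposition`; see fields in Details.
#' @export
decompose <- function(tree, k) {
  stopifnot(inherits(tree, "rooted_tree"), k >= 0)
  k <- as.integer(k)
  ids <- tree$graph$vertices$id
  h <- tree$height

  leaf_branches <- ids[!(ids %in% tree$root) & h[ids] == k]
  nonleaf_branches <- ids[
    !(ids %in% tree$root) &
      vapply(ids, function(v) {
        kids <- tree$children[[v]]
        length(kids) >= 2 && all(h[kids] >= k)
      }, logical(1))
  ]
  nonleaf_branches <- setdiff(nonleaf_branches, leaf_branches)
  branches <- union(leaf_branches, nonleaf_branches)

  # Internal edges: walk up from every branch to the first branch/root above;
  # plus the root edge for a pair root.
  ekey <- function(u, v) paste(pmin(u, v), pmax(u, v))
  internal_keys <- character(0)
  stop_set <- c(tree$root, branches)
  branch_paths <- list()
  for (b in branches) {
    path <- b
    v <- b
    repeat {
      p <- tree$parent[[v]]
      if (is.na(p)) break
      internal_keys <- c(internal_keys, ekey(v, p))
      path <- c(path, p)
      v <- p
      if (v %in% stop_set) break
    }
    branch_paths[[length(branch_paths) + 1L]] <- path
  }
  if (length(tree$root) == 2 && length(branches)) {
    # the root edge joins two root vertices, so it lies on a branch path;
    # with no k-branch at all the decomposition is fully degenerate (below)
    internal_keys <- c(internal_keys, ekey(tree$root[1], tree$root[2]))
    branch_paths[[length(branch_paths) + 1L]] <- tree$root
  }
  internal_keys <- unique(internal_keys)

  edges <- tree$graph$edges
  all_keys <- if (nrow(edges)) ekey(edges$u, edges$v) else character(0)
  in_mask <- all_keys %in% internal_keys
  E_in <- edges[in_mask, , drop = FALSE]
  E_ex <- edges[!in_mask, , drop = FALSE]

  if (length(branches)) {
    V_in <- unique(c(tree$root, E_in$u, E_in$v))
  } else {
    # degenerate case: no k-branch, so the branch-subtree is empty and the
    # whole tree counts as external (one fringe tree rooted at the center)
    V_in <- character(0)
  }
  V_ex <- setdiff(ids, V_in)

  # fringe trees: components of (V, E_ex) that contain >= 1 vertex; each
  # contains exactly one internal vertex (its root). Internal vertices with
  # no external edge give single-vertex fringe trees.
  fringe_trees <- if (length(branches)) {
    extract_fringe_trees(tree, V_in, E_ex)
  } else {
    list(root_tree_at(tree$graph, tree$root))
  }

  # branch-tree: contract branch-paths; vertices = root (pair folded) + branches
  bt_parent <- stats::setNames(rep(NA_character_, length(branches)), branches)
  for (b in branches) {
    v <- b
    repeat {
      p <- tree$parent[[v]]
      if (is.na(p)) { bt_parent[b] <- "<root>"; break }
      if (p %in% branches) { bt_parent[b] <- p; break }
      if (p %in% tree$root) { bt_parent[b] <- "<root>"; break }
      v <- p
    }
    if (is.na(bt_parent[b])) bt_parent[b] <- "<root>"
  }
  bt_depth <- stats::setNames(integer(length(branches)), branches)
  depth_of <- function(b) {
    p <- bt_parent[[b]]
    if (identical(p, "<root>")) 1L else 1L + depth_of(p)
  }
  for (b in branches) bt_depth[b] <- depth_of(b)
  bh <- if (length(branches)) max(bt_depth) else 0L
  bl <- length(leaf_branches)

  structure(list(
    k = k,
    leaf_branches = leaf_branches,
    nonleaf_branches = nonleaf_branches,
    branch_paths = branch_paths,
    E_in = E_in, E_ex = E_ex, V_in = V_in, V_ex = V_ex,
    branch_tree = list(parent = bt_parent, depth = bt_depth),
    fringe_trees = fringe_trees,
    bl = as.integer(bl), bh = as.integer(bh)
  ), class = "branch_decomposition")
}

#' @noRd
extract_fringe_trees <- function(tree, V_in, E_ex) {
  g <- tree$graph
  adj_ex <- stats::setNames(vector("list", nrow(g$vertices)), g$vertices$id)
  for (id in g$vertices$id) adj_ex[[id]] <- character(0)
  if (nrow(E_ex)) {
    for (i in seq_len(nrow(E_ex))) {
      u <- E_ex$u[i]; v <- E_ex$v[i]
      adj_ex[[u]] <- c(adj_ex[[u]], v)
      adj_ex[[v]] <- c(adj_ex[[v]], u)
    }
  }
  out <- list()
  for (r in V_in) {
    # component of external edges reachable from r
    seen <- r
    queue <- r
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj_ex[[v]]) if (!(w %in% seen)) { seen <- c(seen, w); queue <- c(queue, w) }
    }
    sub_v <- g$vertices[g$vertices$id %in% seen, , drop = FALSE]
    sub_e <- g$edges[(g$edges$u %in% seen) & (g$edges$v %in% seen), , drop = FALSE]
    # restrict to external edges only (r's internal edges must not leak in)
    if (nrow(sub_e)) {
      kx <- paste(pmin(sub_e$u, sub_e$v), pmax(sub_e$u, sub_e$v))
      ke <- if (nrow(E_ex)) paste(pmin(E_ex$u, E_ex$v), pmax(E_ex$u, E_ex$v)) else character(0)
      sub_e <- sub_e[kx %in% ke, , drop = FALSE]
    }
    ft <- root_tree_at(chem_graph(sub_v, sub_e), r)
    out[[length(out) + 1L]] <- ft
  }
  out
}

#' 2-fringe-tree size rule
#'
#' The target class restricts every 2-fringe-tree `T` with root `r` to
#' \eqn{n(T) \le 2 \deg_T(r) + 2}, where the degree is taken within the
#' fringe-tree.
#'
#' @param fringe_tree a `rooted_tree` (single root).
#' @return logical.
#' @export
fringe_size_ok <- function(fringe_tree) {
  stopifnot(inherits(fringe_tree, "rooted_tree"), length(fringe_tree$root) == 1)
  n <- nrow(fringe_tree$graph$vertices)
  degr <- length(fringe_tree$children[[fringe_tree$root]])
  n <= 2L * degr + 2L
}

#' Branch-decomposition roles as a tibble
#'
#' One row per vertex with its height and role (`leaf-branch`,
#' `nonleaf-branch`, `internal`, `external`); serialisable to JSON.
#'
#' @param tree a `rooted_tree`.
#' @param decomp a `branch_decomposition` of `tree`.
#' @return tibble with columns `id`, `height`, `role`.
#' @export
decomposition_roles <- function(tree, decomp) {
  ids <- tree$graph$vertices$id
  role <- ifelse(ids %in% decomp$leaf_branches, "leaf-branch",
          ifelse(ids %in% decomp$nonleaf_branches, "nonleaf-branch",
          ifelse(ids %in% decomp$V_in, "internal", "external")))
  tibble::tibble(id = ids, height = as.integer(tree$height[ids]), role = role)
}

#' @export
print.branch_decomposition <- function(x, ...) {
  cat("<branch_decomposition> k =", x$k, " bl =", x$bl, " bh =", x$bh,
      " |E_in| =", nrow(x$E_in), " |E_ex| =", nrow(x$E_ex), "\n")
  invisible(x)
}
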