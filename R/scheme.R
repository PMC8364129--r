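#' Degree-bounded rooted trees T(a, b, c)
#'
#' The complete rooted tree in which the root has `a` children, every other
#' internal vertex has `b` children, and every leaf is at distance `c` from
#' the root. Vertices are indexed in breadth-first order `v_1, ..., v_n` with
#' `n = a(b^c - 1)/(b - 1) + 1`; the first `a(b^{c-1} - 1)/(b - 1) + 1`
#' vertices are the non-leaves.
#'
#' @param a,b,c positive integers, `b >= 2`.
#' @return list with `n`, `n_nonleaf`, `parent` (prt, `NA` for the root),
#'   `children` (Cld, list over vertex index), `depth` (integer, root = 0).
#' @examples
#' t_abc(3, 2, 2)$n  # 10
#' @export
t_abc <- function(a, b, c) {
  stopifnot(a >= 1, b >= 2, c >= 1)
  n <- a * (b^c - 1) %/% (b - 1) + 1L
  n_nonleaf <- a * (b^(c - 1) - 1) %/% (b - 1) + 1L
  parent <- rep(NA_integer_, n)
  depth <- integer(n)
  children <- vector("list", n)
  nxt <- 2L
  queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (depth[v] >= c) next
    k <- if (v == 1L) a else b
    kids <- integer(0)
    for (j in seq_len(k)) {
      parent[nxt] <- v
      depth[nxt] <- depth[v] + 1L
      kids <- c(kids, nxt)
      queue <- c(queue, nxt)
      nxt <- nxt + 1L
    }
    children[[v]] <- kids
  }
  for (v in seq_len(n)) if (is.null(children[[v]])) children[[v]] <- integer(0)
  stopifnot(nxt - 1L == n)
  list(a = a, b = b, c = c, n = as.integer(n), n_nonleaf = as.integer(n_nonleaf),
       parent = parent, children = children, depth = depth)
}

#' Proper precedence set for T(a, b, c)
#'
#' A set of ordered index pairs over the vertices of `T(a, b, c)` used to
#' break selection symmetry: a prefix-closed vertex selection (closed under
#' "if the second of a pair is in, so is the first") loses no subtree of
#' `T(a, b, c)` up to root-fixed isomorphism. The construction takes all
#' parent-child pairs (which give condition (1), the parent-to-child chains)
#' together with consecutive-sibling pairs (whole sibling subtrees in
#' `T(a, b, c)` are interchangeable, which gives condition (2)).
#'
#' @param a,b,c as in [t_abc()].
#' @return tibble with columns `i`, `j` (vertex indices, `v_i` precedes `v_j`).
#' @export
proper_precedence_set <- function(a, b, c) {
  tb <- t_abc(a, b, c)
  pairs <- list()
  for (v in seq_len(tb$n)) {
    kids <- tb$children[[v]]
    for (k in kids) pairs[[length(pairs) + 1L]] <- c(v, k)
    if (length(kids) > 1) {
      for (j in seq_len(length(kids) - 1L)) {
        pairs[[length(pairs) + 1L]] <- c(kids[j], kids[j + 1L])
      }
    }
  }
  m <- do.call(rbind, pairs)
  tibble::tibble(i = as.integer(m[, 1]), j = as.integer(m[, 2]))
}

#' Check that a precedence set is proper
#'
#' Explicit verifier for small trees: condition (1) demands a pair-chain from
#' every parent to each of its children; condition (2) demands that every
#' subtree containing the root has a root-fixed isomorphic image that is
#' closed under the pair set. Subtrees are enumerated exhaustively, so this
#' is only for desk-scale `T(a, b, c)`.
#'
#' @param pprc tibble with columns `i`, `j`.
#' @param a,b,c as in [t_abc()].
#' @return logical.
#' @export
check_precedence_set <- function(pprc, a, b, c) {
  tb <- t_abc(a, b, c)
  if (tb$n > 1 && nrow(pprc) == 0) return(FALSE)
  # condition (1): reachability i -> j along pairs for every parent-child pair
  adj <- vector("list", tb$n)
  for (r in seq_len(nrow(pprc))) adj[[pprc$i[r]]] <- c(adj[[pprc$i[r]]], pprc$j[r])
  reach <- function(from, to) {
    seen <- from; queue <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == to) return(TRUE)
      for (w in adj[[v]]) if (!(w %in% seen)) { seen <- c(seen, w); queue <- c(queue, w) }
    }
    FALSE
  }
  for (v in seq_len(tb$n)) {
    for (k in tb$children[[v]]) if (!reach(v, k)) return(FALSE)
  }
  # condition (2): every root-containing subtree has a closed isomorphic image
  subtrees <- enumerate_root_subtrees(tb)
  for (S in subtrees) {
    img <- canonical_subtree_image(tb, S)
    closed <- all(vapply(seq_len(nrow(pprc)), function(r) {
      !(pprc$j[r] %in% img) || (pprc$i[r] %in% img)
    }, logical(1)))
    if (!closed) return(FALSE)
  }
  TRUE
}

#' @noRd
enumerate_root_subtrees <- function(tb) {
  # all vertex sets containing v_1 that induce a subtree; recursion over
  # candidate frontiers (desk scale only)
  out <- list()
  grow <- function(current, frontier) {
    out[[length(out) + 1L]] <<- current
    if (!length(frontier)) return(invisible())
    for (k in seq_along(frontier)) {
      v <- frontier[k]
      # include v; to avoid duplicates, only frontier members after v stay
      grow(c(current, v), c(frontier[-seq_len(k)], tb$children[[v]]))
    }
  }
  grow(1L, tb$children[[1L]])
  out
}

#' @noRd
canonical_subtree_image <- function(tb, S) {
  # push the selection into lowest-index sibling slots, ordering sibling
  # subtree shapes from largest; the image is isomorphic to S with the root
  # fixed and closed under parent-child + consecutive-sibling pairs.
  shape <- function(v) {
    kids <- intersect(tb$children[[v]], S)
    codes <- sort(vapply(kids, shape, character(1)), decreasing = TRUE)
    paste0("(", paste(codes, collapse = ""), ")")
  }
  img <- integer(0)
  place <- function(v_sel, v_slot) {
    img <<- c(img, v_slot)
    kids <- intersect(tb$children[[v_sel]], S)
    if (!length(kids)) return(invisible())
    codes <- vapply(kids, shape, character(1))
    kids <- kids[order(codes, decreasing = TRUE)]
    slots <- tb$children[[v_slot]]
    for (k in seq_along(kids)) place(kids[k], slots[k])
  }
  place(1L, 1L)
  img
}

#' Build a scheme graph
#'
#' The structural template from which the graph-existence part of the MILP
#' selects a target graph: a base tree `T_B = T(d_max, d_max - 1, bh*)`
#' (or, for a pair-rooted target with odd diameter, two copies of
#' `T(d_max - 1, d_max - 1, bh*)` joined at the roots), a link path
#' `P_{t*}` whose windows subdivide selected base-tree edges, the directed
#' arc set `F` between base-tree vertices and path positions (an entry arc
#' leaves the parent endpoint of a base edge into the path and an exit arc
#' returns to the child endpoint), and a fringe-tree skeleton of height `k*`
#' rooted at every base-tree and path vertex.
#'
#' @param spec a [target_spec()].
#' @param t_star number of link-path vertices; default `n* - bl* - 1`.
#' @param root_mode `"single"` or `"pair"`; default chosen by the parity of
#'   `dia*`.
#' @return object of class `scheme_graph` with fields `base` (per-side
#'   [t_abc()] structures), `roots`, `t_star`, `arcs` (tibble `edge_to`,
#'   `path_pos`, `dir`), and `skeleton` (fringe template sizes).
#' @export
build_scheme_graph <- function(spec, t_star = NULL, root_mode = NULL) {
  stopifnot(inherits(spec, "target_spec"))
  if (spec$bh_star < 1) stop("the scheme graph requires bh* >= 1")
  if (is.null(root_mode)) root_mode <- if (spec$dia_star %% 2 == 0) "single" else "pair"
  root_mode <- match.arg(root_mode, c("single", "pair"))
  if (is.null(t_star)) t_star <- spec$n_star - spec$bl_star - 1L
  if (t_star < 1) stop("t* must be >= 1")
  d <- spec$d_max
  base <- if (root_mode == "single") {
    list(t_abc(d, d - 1L, spec$bh_star))
  } else {
    list(t_abc(d - 1L, d - 1L, spec$bh_star), t_abc(d - 1L, d - 1L, spec$bh_star))
  }
  # F: for every base edge (prt(i), i) an entry arc to each path position and
  # an exit arc back from each path position
  arcs <- list()
  for (side in seq_along(base)) {
    tb <- base[[side]]
    for (i in 2:tb$n) {
      for (h in seq_len(t_star)) {
        arcs[[length(arcs) + 1L]] <- tibble::tibble(
          side = side, edge_to = i, path_pos = h, dir = c("entry", "exit"))
      }
    }
  }
  skeleton <- list(
    k_star = spec$k_star,
    children_base = d - 1L,       # fringe child slots at base-tree vertices
    children_path = max(d - 2L, 0L),  # path vertices already carry two spine edges
    grandchildren = if (spec$k_star >= 2) d - 1L else 0L
  )
  structure(list(base = base, root_mode = root_mode, t_star = as.integer(t_star),
                 arcs = dplyr::bind_rows(arcs), skeleton = skeleton, spec = spec),
            class = "scheme_graph")
}

#' @export
print.scheme_graph <- function(x, ...) {
  cat("<scheme_graph> root:", x$root_mode, " |T_B| =",
      sum(vapply(x$base, function(b) b$n, integer(1))),
      " t* =", x$t_star, " |F| =", nrow(x$arcs), "\n")
  invisible(x)
}
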