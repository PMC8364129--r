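#' Chemical graphs
#'
#' A chemical graph is a tuple \eqn{(H, \alpha, \beta)}: a simple connected
#' graph `H`, a vertex labelling \eqn{\alpha} into the element alphabet and an
#' edge multiplicity map \eqn{\beta} into \[1, 3\]. This package works with
#' the acyclic class, so `H` is a tree. Vertex ids are opaque strings; all
#' semantics flow through the labels and multiplicities.
#'
#' @param vertices data frame with columns `id` (character) and `label`.
#' @param edges data frame with columns `u`, `v` (vertex ids) and `m`
#'   (multiplicity in \[1, 3\]). May have zero rows.
#' @return An object of class `chem_graph`: a list with tibble fields
#'   `vertices` and `edges`.
#' @examples
#' g <- chem_graph(
#'   vertices = data.frame(id = c("1", "2"), label = c("C", "O")),
#'   edges = data.frame(u = "1", v = "2", m = 2)
#' )
#' @export
chem_graph <- function(vertices, edges = NULL) {
  vertices <- tibble::as_tibble(vertices)
  stopifnot(all(c("id", "label") %in% names(vertices)))
  vertices$id <- as.character(vertices$id)
  if (nrow(vertices) == 0) stop("a chemical graph needs at least one vertex")
  if (anyDuplicated(vertices$id)) stop("duplicate vertex ids")
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- tibble::tibble(u = character(), v = character(), m = integer())
  } else {
    edges <- tibble::as_tibble(edges)
    stopifnot(all(c("u", "v", "m") %in% names(edges)))
    edges$u <- as.character(edges$u)
    edges$v <- as.character(edges$v)
    edges$m <- as.integer(edges$m)
    if (any(edges$u == edges$v)) stop("self-loops are not allowed")
    if (any(edges$m < 1 | edges$m > 3)) stop("bond multiplicities must be in [1, 3]")
    bad <- setdiff(c(edges$u, edges$v), vertices$id)
    if (length(bad)) stop("edge endpoints not among vertex ids: ", paste(bad, collapse = ", "))
    key <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v))
    if (anyDuplicated(key)) stop("parallel edges are not allowed (the graph is simple)")
  }
  structure(list(vertices = vertices[, c("id", "label")], edges = edges[, c("u", "v", "m")]),
            class = "chem_graph")
}

#' @export
print.chem_graph <- function(x, ...) {
  cat("<chem_graph> ", nrow(x$vertices), " vertices, ", nrow(x$edges), " edges\n", sep = "")
  tab <- table(x$vertices$label)
  cat("  composition: ", paste(names(tab), tab, sep = ":", collapse = " "), "\n", sep = "")
  invisible(x)
}

n_vertices <- function(g) nrow(g$vertices)
n_edges <- function(g) nrow(g$edges)

#' @noRd
as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g$edges)) g$edges else data.frame(u = character(), v = character()),
    directed = FALSE,
    vertices = g$vertices
  )
}

#' Sum of bond multiplicities incident to each vertex
#'
#' \eqn{\beta(u) = \sum_{uv \in E} \beta(uv)}; the quantity bounded by the
#' valence of the element at `u`.
#'
#' @param graph a [chem_graph()].
#' @return named integer vector over vertex ids.
#' @export
beta_sums <- function(graph) {
  out <- stats::setNames(integer(nrow(graph$vertices)), graph$vertices$id)
  if (nrow(graph$edges)) {
    agg <- rowsum(c(graph$edges$m, graph$edges$m), c(graph$edges$u, graph$edges$v))
    out[rownames(agg)] <- as.integer(agg[, 1])
  }
  out
}

#' Validate a chemical graph
#'
#' Checks the defining conditions of a chemical acyclic graph over an element
#' alphabet and adjacency-configuration set: connectivity, acyclicity
#' (`|E| = |V| - 1` plus no cycles), membership of every edge's
#' adjacency-configuration in \eqn{\Gamma}, and the valence inequality
#' \eqn{\beta(u) \le val(\alpha(u))} at every vertex.
#'
#' Unknown element labels and an empty vertex set are hard errors; everything
#' else is reported as a violation row so a caller can see all problems at
#' once.
#'
#' @param graph a [chem_graph()].
#' @param elements an [element_table()].
#' @param gamma a `gamma_set` from [adjacency_configs()], or `NULL` to accept
#'   any valence-feasible configuration.
#' @return list with `ok` (logical) and `violations`, a tibble with columns
#'   `rule` and `witness`.
#' @export
validate_chemical_graph <- function(graph, elements, gamma = NULL) {
  if (!inherits(graph, "chem_graph")) stop("not a chem_graph")
  if (nrow(graph$vertices) == 0) stop("empty vertex set")
  unknown <- setdiff(graph$vertices$label, elements$label)
  if (length(unknown)) stop("unknown element label(s): ", paste(unknown, collapse = ", "))

  viol <- list()
  add <- function(rule, witness) viol[[length(viol) + 1L]] <<- tibble::tibble(rule = rule, witness = witness)

  ncomp <- n_components(graph)
  if (ncomp > 1) {
    add("connectivity", paste0(ncomp, " components"))
  }
  # a simple connected graph with |E| = |V| - 1 is exactly a tree
  if (n_edges(graph) != n_vertices(graph) - 1L) {
    add("acyclicity", paste0("|E| = ", n_edges(graph), " but |V| - 1 = ", n_vertices(graph) - 1L))
  }

  if (nrow(graph$edges)) {
    lab <- stats::setNames(graph$vertices$label, graph$vertices$id)
    cfg <- normalize_adjacency(elements, lab[graph$edges$u], lab[graph$edges$v], graph$edges$m)
    if (is.null(gamma)) gamma <- all_adjacency_configs(elements)
    ok <- gamma_key(cfg$a, cfg$b, cfg$m) %in% gamma_key(gamma$a, gamma$b, gamma$m)
    for (i in which(!ok)) {
      add("adjacency-configuration",
          paste0("edge ", graph$edges$u[i], "-", graph$edges$v[i], " has (",
                 cfg$a[i], ",", cfg$b[i], ",", cfg$m[i], ") outside Gamma"))
    }
  }

  bs <- beta_sums(graph)
  vals <- val_of(elements, graph$vertices$label)
  over <- which(bs[graph$vertices$id] > vals)
  for (i in over) {
    add("valence", paste0("vertex ", graph$vertices$id[i], " (", graph$vertices$label[i],
                          "): beta = ", bs[[graph$vertices$id[i]]], " > val = ", vals[i]))
  }

  violations <- if (length(viol)) dplyr::bind_rows(viol) else tibble::tibble(rule = character(), witness = character())
  list(ok = nrow(violations) == 0L, violations = violations)
}

#' @noRd
neighbour_index <- function(graph) {
  ids <- graph$vertices$id
  n <- length(ids)
  adj <- vector("list", n)
  if (nrow(graph$edges)) {
    ui <- match(graph$edges$u, ids)
    vi <- match(graph$edges$v, ids)
    for (k in seq_along(ui)) {
      adj[[ui[k]]] <- c(adj[[ui[k]]], vi[k])
      adj[[vi[k]]] <- c(adj[[vi[k]]], ui[k])
    }
  }
  adj
}

#' @noRd
bfs_dist <- function(adj, from, n) {
  d <- rep.int(NA_integer_, n)
  d[from] <- 0L
  queue <- from; head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; queue <- c(queue, w) }
  }
  d
}

#' @noRd
n_components <- function(graph) {
  n <- nrow(graph$vertices)
  adj <- neighbour_index(graph)
  seen <- rep(FALSE, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    seen[!is.na(bfs_dist(adj, s, n))] <- TRUE
  }
  comp
}

#' Tree metrics: degrees, distances, diameter
#'
#' Degrees ignore bond multiplicity. Distances are shortest-path lengths in
#' edge counts; the diameter is the maximum pairwise distance.
#'
#' @param graph a connected [chem_graph()].
#' @return list with `degree` (named integer vector), `dist` (matrix with
#'   dimnames = vertex ids), `diameter` (integer).
#' @export
tree_metrics <- function(graph) {
  ids <- graph$vertices$id
  n <- length(ids)
  adj <- neighbour_index(graph)
  d <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  for (s in seq_len(n)) d[s, ] <- bfs_dist(adj, s, n)
  if (anyNA(d)) stop("graph is disconnected (", n_components(graph), " components)")
  deg <- vapply(adj, length, integer(1))
  list(
    degree = stats::setNames(as.integer(deg), ids),
    dist = d,
    diameter = as.integer(max(d))
  )
}

#' Center of a tree
#'
#' The center of a tree with even diameter is the single middle vertex of any
#' longest path; with odd diameter it is the middle adjacent vertex pair. It
#' is found here as the set of vertices of minimum eccentricity.
#'
#' @param tree a [chem_graph()] that is a tree.
#' @return character vector of one (even diameter) or two (odd) vertex ids.
#' @export
find_center <- function(tree) {
  v <- validate_tree_shape(tree)
  m <- tree_metrics(tree)
  ecc <- apply(m$dist, 1, max)
  ctr <- names(ecc)[ecc == min(ecc)]
  if (length(ctr) == 2 && m$dist[ctr[1], ctr[2]] != 1) stop("internal error: center pair not adjacent")
  if (length(ctr) > 2) stop("internal error: more than two center vertices in a tree")
  sort(ctr)
}

#' @noRd
validate_tree_shape <- function(graph) {
  if (!inherits(graph, "chem_graph")) stop("not a chem_graph")
  if (n_edges(graph) != n_vertices(graph) - 1L) stop("not a tree: |E| != |V| - 1")
  if (n_components(graph) != 1) stop("not a tree: disconnected")
  invisible(TRUE)
}

#' Per-edge adjacency- and bond-configurations
#'
#' For every edge, the adjacency-configuration normalised into
#' \eqn{\Gamma_< \cup \Gamma_=} (the tuple of an edge whose first endpoint is
#' heavier is reported reversed) and the bond-configuration
#' \eqn{(d_1, d_2, m)} with \eqn{d_1 \le d_2}, where degrees ignore bond
#' multiplicity.
#'
#' @param graph a [chem_graph()].
#' @param elements an [element_table()].
#' @return tibble with one row per edge: `u`, `v`, `a`, `b`, `m`, `d1`, `d2`.
#' @export
edge_configs <- function(graph, elements) {
  if (nrow(graph$edges) == 0) {
    return(tibble::tibble(u = character(), v = character(), a = character(),
                          b = character(), m = integer(), d1 = integer(), d2 = integer()))
  }
  lab <- stats::setNames(graph$vertices$label, graph$vertices$id)
  deg <- tree_metrics(graph)$degree
  cfg <- normalize_adjacency(elements, lab[graph$edges$u], lab[graph$edges$v], graph$edges$m)
  d_u <- deg[graph$edges$u]
  d_v <- deg[graph$edges$v]
  tibble::tibble(
    u = graph$edges$u, v = graph$edges$v,
    a = cfg$a, b = cfg$b, m = cfg$m,
    d1 = as.integer(pmin(d_u, d_v)), d2 = as.integer(pmax(d_u, d_v))
  )
}

#' Canonical form of a chemical graph
#'
#' A string encoding invariant under vertex-id permutation: the AHU-style
#' encoding of the tree rooted at its center (taking the lexicographically
#' smaller side for a pair center), with element labels and incoming bond
#' multiplicities folded into each vertex code. Two chemical trees are
#' isomorphic (as labelled, multiplicity-annotated trees) iff their canonical
#' forms are equal.
#'
#' @param graph a [chem_graph()] that is a tree.
#' @return character scalar.
#' @export
canonical_form <- function(graph) {
  validate_tree_shape(graph)
  adj <- adjacency_list(graph)
  ctr <- find_center(graph)
  enc_root <- function(root, block) {
    # block: id of neighbour not to descend into (for pair centers)
    rec <- function(v, parent, in_m) {
      kids <- adj[[v]]
      codes <- character(0)
      for (k in seq_along(kids$ids)) {
        w <- kids$ids[k]
        if (identical(w, parent) || identical(w, block)) next
        codes <- c(codes, rec(w, v, kids$m[k]))
      }
      paste0("(", graph$vertices$label[match(v, graph$vertices$id)], in_m,
             paste(sort(codes), collapse = ""), ")")
    }
    rec(root, NA_character_, 0L)
  }
  if (length(ctr) == 1) {
    enc_root(ctr, NA_character_)
  } else {
    e1 <- enc_root(ctr[1], ctr[2])
    e2 <- enc_root(ctr[2], ctr[1])
    m_ctr <- graph$edges$m[(graph$edges$u == ctr[1] & graph$edges$v == ctr[2]) |
                           (graph$edges$u == ctr[2] & graph$edges$v == ctr[1])]
    parts <- sort(c(e1, e2))
    paste0("P", m_ctr, parts[1], parts[2])
  }
}

#' @noRd
adjacency_list <- function(graph) {
  ids <- graph$vertices$id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) adj[[id]] <- list(ids = character(0), m = integer(0))
  if (nrow(graph$edges)) {
    for (i in seq_len(nrow(graph$edges))) {
      u <- graph$edges$u[i]; v <- graph$edges$v[i]; m <- graph$edges$m[i]
      adj[[u]]$ids <- c(adj[[u]]$ids, v); adj[[u]]$m <- c(adj[[u]]$m, m)
      adj[[v]]$ids <- c(adj[[v]]$ids, u); adj[[v]]$m <- c(adj[[v]]$m, m)
    }
  }
  adj
}

#' Read / write the JSON graph dialect
#'
#' `{"vertices":[{"id","label"}],"edges":[{"u","v","m"}]}`.
#'
#' @param path file path.
#' @param graph a [chem_graph()].
#' @return `read_graph_json()` returns a [chem_graph()];
#'   `write_graph_json()` returns `path` invisibly.
#' @export
read_graph_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  chem_graph(vertices = x$vertices, edges = x$edges)
}

#' @rdname read_graph_json
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(
    list(vertices = graph$vertices, edges = graph$edges),
    path, dataframe = "rows", auto_unbox = TRUE
  )
  invisible(path)
}

#' Tidy a chemical graph into a vertex tibble
#'
#' @param x a [chem_graph()].
#' @param ... unused.
#' @return tibble with one row per vertex: `id`, `label`, `degree`,
#'   `beta` (incident multiplicity sum).
#' @method tidy chem_graph
#' @export
tidy.chem_graph <- function(x, ...) {
  deg <- if (nrow(x$edges)) tree_metrics(x)$degree else
    stats::setNames(integer(nrow(x$vertices)), x$vertices$id)
  bs <- beta_sums(x)
  tibble::tibble(
    id = x$vertices$id, label = x$vertices$label,
    degree = as.integer(deg[x$vertices$id]), beta = as.integer(bs[x$vertices$id])
  )
}
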