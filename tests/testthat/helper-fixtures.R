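# shared fixtures for the suite: small element tables, gamma sets, and
# independent oracles built from primitives the implementation does not use

elements_cno <- default_elements()
gamma_cno <- all_adjacency_configs(elements_cno)
spec_cno <- descriptor_spec(elements_cno, gamma_cno, k_star = 2L)

elements_co <- element_table(c("C", "O"), c(4L, 2L), c(12.01, 16.00))
gamma_co <- all_adjacency_configs(elements_co)
spec_co <- descriptor_spec(elements_co, gamma_co, k_star = 2L)

elements_c <- element_table("C", 4L, 12.01)
gamma_c1 <- adjacency_configs(elements_c, "C", "C", 1L)

path_graph <- function(n, label = "C", m = 1L) {
  ids <- as.character(seq_len(n))
  chem_graph(
    data.frame(id = ids, label = label),
    if (n > 1) data.frame(u = ids[-n], v = ids[-1], m = m) else NULL
  )
}

star_graph <- function(k, label = "C") {
  ids <- as.character(seq_len(k + 1))
  chem_graph(
    data.frame(id = ids, label = label),
    data.frame(u = ids[1], v = ids[-1], m = 1L)
  )
}

# independent BFS oracle (single-source, queue on id strings)
oracle_bfs <- function(g, from) {
  adj <- list()
  for (id in g$vertices$id) adj[[id]] <- character(0)
  for (i in seq_len(nrow(g$edges))) {
    adj[[g$edges$u[i]]] <- c(adj[[g$edges$u[i]]], g$edges$v[i])
    adj[[g$edges$v[i]]] <- c(adj[[g$edges$v[i]]], g$edges$u[i])
  }
  d <- stats::setNames(rep(NA_integer_, nrow(g$vertices)), g$vertices$id)
  d[from] <- 0L
  q <- from
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; q <- c(q, w) }
  }
  d
}

# Pruefer-sequence tree enumeration (independent of the package generator):
# all labelled trees on n vertices, degree-capped, reduced to isomorphism
# classes via the package's canonical form
pruefer_trees <- function(n, d_max = 4L) {
  if (n == 1) return(list(path_graph(1)))
  if (n == 2) return(list(path_graph(2)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  out <- list()
  seen <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(seqs))) {
    pr <- seqs[r, ]
    degree <- rep(1L, n)
    for (x in pr) degree[x] <- degree[x] + 1L
    if (max(degree) > d_max) next
    deg <- degree
    ptr <- pr
    edges <- matrix(0L, n - 1L, 2L)
    leafset <- which(deg == 1L)
    for (i in seq_len(n - 2L)) {
      leaf <- min(leafset)
      v <- ptr[i]
      edges[i, ] <- c(leaf, v)
      deg[leaf] <- 0L
      deg[v] <- deg[v] - 1L
      leafset <- setdiff(leafset, leaf)
      if (deg[v] == 1L && !(v %in% ptr[-seq_len(i)])) leafset <- c(leafset, v)
    }
    edges[n - 1L, ] <- which(deg == 1L)
    g <- chem_graph(data.frame(id = as.character(seq_len(n)), label = "C"),
                    data.frame(u = as.character(edges[, 1]),
                               v = as.character(edges[, 2]), m = 1L))
    cf <- canonical_form(g)
    if (is.null(seen[[cf]])) { seen[[cf]] <- TRUE; out[[length(out) + 1L]] <- g }
  }
  out
}

# class membership (enumeration target): bl_2 in {2,3} and the 2-fringe size rule
in_enum_class <- function(g) {
  dec <- decompose(root_at_center(g), 2L)
  dec$bl %in% c(2L, 3L) && all(vapply(dec$fringe_trees, fringe_size_ok, logical(1)))
}

# memoised census of the n = 7 graphs over C,O (shared by several files)
.census_cache <- new.env(parent = emptyenv())
co7_census <- function() {
  if (is.null(.census_cache$co7)) {
    gs <- exhaustive_graphs(7, elements_co, gamma_co)
    incl <- Filter(in_enum_class, gs)
    fvs <- lapply(incl, function(g) unclass(feature_vector(g, spec_co)))
    keys <- vapply(fvs, function(f) paste(round(f, 6), collapse = ","), character(1))
    cfs <- vapply(incl, canonical_form, character(1))
    .census_cache$co7 <- list(all = gs, incl = incl, fvs = fvs, keys = keys, cfs = cfs)
  }
  .census_cache$co7
}

# synthetic demonstration trees shipped with the package: constructed (not
# measured) trees with diameter 10/11, unique center, bl_k = (8, 5, 3, 2)
# and bh_k = (3, 3, 2, 1) for k = 0..3
demo_tree_even <- function() {
  read_graph_json(system.file("extdata", "synthetic_branchheight_even.json",
                              package = "treeqsar", mustWork = TRUE))
}

demo_tree_odd <- function() {
  read_graph_json(system.file("extdata", "synthetic_branchheight_odd.json",
                              package = "treeqsar", mustWork = TRUE))
}
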