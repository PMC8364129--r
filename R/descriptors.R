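#' Descriptor specification
#'
#' Fixes everything the feature function \eqn{f(G)} depends on besides the
#' graph itself: the element table, the adjacency-configuration set
#' \eqn{\Gamma}, the branch-parameter \eqn{k^*} and the bond-configuration
#' domain. The descriptor count is \eqn{K = 2|\Lambda| + 2|\Gamma| + 50} and
#' the canonical descriptor order is fixed so that training and inference
#' always agree:
#' `n`, `dia_bar`, `ms_bar`, `n_H`, `dg_{1..4}^{in}`, `dg_{1..4}^{ex}`,
#' `bl`, `bh`, `ce_a^{in}`, `ce_a^{ex}` (by mass order), `bd_{2,3}^{in}`,
#' `bd_{2,3}^{ex}`, `ac_gamma^{in}`, `ac_gamma^{ex}` (in \eqn{\Gamma} order),
#' `bc_mu^{in}`, `bc_mu^{ex}` (16 bond-configurations).
#'
#' @param elements an [element_table()].
#' @param gamma a `gamma_set` from [adjacency_configs()].
#' @param k_star branch-parameter, integer in \[1, 4\] (default 2).
#' @return object of class `descriptor_spec` with fields `elements`, `gamma`,
#'   `k_star`, `bc` (bond-config domain), `names` (canonical order), `K`.
#' @examples
#' spec <- descriptor_spec(default_elements(), all_adjacency_configs(default_elements()))
#' spec$K
#' @export
descriptor_spec <- function(elements, gamma, k_star = 2L) {
  stopifnot(inherits(elements, "element_table"))
  if (!(k_star %in% 1:4)) stop("k_star must be in [1, 4]")
  bc <- bond_config_domain(drop_trivial = TRUE)
  nm <- c(
    "n", "dia_bar", "ms_bar", "n_H",
    paste0("dg_", 1:4, "_in"), paste0("dg_", 1:4, "_ex"),
    "bl", "bh",
    paste0("ce_", elements$label, "_in"), paste0("ce_", elements$label, "_ex"),
    paste0("bd_", 2:3, "_in"), paste0("bd_", 2:3, "_ex"),
    paste0("ac_", gamma_key(gamma$a, gamma$b, gamma$m), "_in"),
    paste0("ac_", gamma_key(gamma$a, gamma$b, gamma$m), "_ex"),
    paste0("bc_", bc_key(bc$d1, bc$d2, bc$m), "_in"),
    paste0("bc_", bc_key(bc$d1, bc$d2, bc$m), "_ex")
  )
  K <- 2L * nrow(elements) + 2L * nrow(gamma) + 50L
  stopifnot(length(nm) == K)
  fq <- grep("^(ce|ac|dg|bc)_", nm, value = TRUE)
  fq_idx <- new.env(parent = emptyenv())
  for (i in seq_along(fq)) fq_idx[[fq[i]]] <- i
  structure(list(elements = elements, gamma = gamma, k_star = as.integer(k_star),
                 bc = bc, names = nm, K = K, fq_names = fq, fq_idx = fq_idx),
            class = "descriptor_spec")
}

#' @export
print.descriptor_spec <- function(x, ...) {
  cat("<descriptor_spec> |Lambda| =", nrow(x$elements), " |Gamma| =", nrow(x$gamma),
      " k* =", x$k_star, " K =", x$K, "\n")
  invisible(x)
}

#' Feature vector of a chemical acyclic graph
#'
#' Computes the K-dimensional descriptor vector: vertex count, normalised
#' diameter \eqn{dia(H)/n}, average mass\eqn{^*}, implicit hydrogen count,
#' and degree / element / bond / adjacency-configuration /
#' bond-configuration counts split by the \eqn{k^*}-internal and
#' \eqn{k^*}-external parts of the branch decomposition, plus
#' \eqn{bl_{k^*}} and \eqn{bh_{k^*}}. Degrees ignore bond multiplicity.
#'
#' @param graph a valid [chem_graph()] (a tree).
#' @param spec a [descriptor_spec()].
#' @return named numeric vector of length `spec$K`, class `feature_vector`.
#' @export
feature_vector <- function(graph, spec) {
  stopifnot(inherits(spec, "descriptor_spec"))
  v <- validate_chemical_graph(graph, spec$elements, spec$gamma)
  if (!v$ok) {
    stop("invalid graph: ", paste(v$violations$rule, v$violations$witness, collapse = "; "))
  }
  n <- n_vertices(graph)
  met <- tree_metrics(graph)
  rt <- root_at_center(graph)
  dec <- decompose(rt, spec$k_star)

  x <- stats::setNames(numeric(spec$K), spec$names)
  x["n"] <- n
  x["dia_bar"] <- met$diameter / n
  x["ms_bar"] <- sum(mass_star_of(spec$elements, graph$vertices$label)) / n
  x["bl"] <- dec$bl
  x["bh"] <- dec$bh

  v_in <- graph$vertices$id %in% dec$V_in
  deg <- met$degree[graph$vertices$id]
  for (i in 1:4) {
    x[paste0("dg_", i, "_in")] <- sum(deg == i & v_in)
    x[paste0("dg_", i, "_ex")] <- sum(deg == i & !v_in)
  }
  for (a in spec$elements$label) {
    sel <- graph$vertices$label == a
    x[paste0("ce_", a, "_in")] <- sum(sel & v_in)
    x[paste0("ce_", a, "_ex")] <- sum(sel & !v_in)
  }

  if (nrow(graph$edges)) {
    lab <- stats::setNames(graph$vertices$label, graph$vertices$id)
    cfg0 <- normalize_adjacency(spec$elements, lab[graph$edges$u], lab[graph$edges$v], graph$edges$m)
    d_u <- met$degree[graph$edges$u]; d_v <- met$degree[graph$edges$v]
    cfg <- tibble::tibble(u = graph$edges$u, v = graph$edges$v,
                          a = cfg0$a, b = cfg0$b, m = cfg0$m,
                          d1 = as.integer(pmin(d_u, d_v)), d2 = as.integer(pmax(d_u, d_v)))
    ek <- paste(pmin(cfg$u, cfg$v), pmax(cfg$u, cfg$v))
    in_k <- if (nrow(dec$E_in)) paste(pmin(dec$E_in$u, dec$E_in$v), pmax(dec$E_in$u, dec$E_in$v)) else character(0)
    e_in <- ek %in% in_k
    for (m in 2:3) {
      x[paste0("bd_", m, "_in")] <- sum(cfg$m == m & e_in)
      x[paste0("bd_", m, "_ex")] <- sum(cfg$m == m & !e_in)
    }
    gk <- gamma_key(cfg$a, cfg$b, cfg$m)
    for (i in seq_len(nrow(spec$gamma))) {
      key <- gamma_key(spec$gamma$a[i], spec$gamma$b[i], spec$gamma$m[i])
      x[paste0("ac_", key, "_in")] <- sum(gk == key & e_in)
      x[paste0("ac_", key, "_ex")] <- sum(gk == key & !e_in)
    }
    bk <- bc_key(cfg$d1, cfg$d2, cfg$m)
    for (i in seq_len(nrow(spec$bc))) {
      key <- bc_key(spec$bc$d1[i], spec$bc$d2[i], spec$bc$m[i])
      x[paste0("bc_", key, "_in")] <- sum(bk == key & e_in)
      x[paste0("bc_", key, "_ex")] <- sum(bk == key & !e_in)
    }
    if (n > 2 && any(cfg$d1 == 1 & cfg$d2 == 1)) {
      stop("internal error: (1,1,m) bond-configuration in a graph with n > 2")
    }
  }

  x["n_H"] <- hydrogen_count(graph, spec)
  class(x) <- c("feature_vector", class(x))
  x
}

#' Implicit hydrogen count
#'
#' \eqn{n_H(G) = \sum_a val(a) \, ce_a(G) - \sum_{(a,b,m)} 2 m \, ac_{(a,b,m)}(G)}:
#' total valence minus twice the bond multiplicity used, i.e. the number of
#' hydrogens to be restored to the hydrogen-suppressed graph. A negative
#' result means a valence-infeasible graph and raises an error.
#'
#' @inheritParams feature_vector
#' @return integer.
#' @export
hydrogen_count <- function(graph, spec) {
  vals <- val_of(spec$elements, graph$vertices$label)
  nH <- sum(vals) - 2L * sum(graph$edges$m)
  if (nH < 0) stop("negative hydrogen count: valence-infeasible graph")
  as.integer(nH)
}

#' Feature table for a batch of graphs
#'
#' One row per graph in the canonical descriptor order; round-trips through
#' CSV losslessly.
#'
#' @param graphs list of [chem_graph()]s.
#' @param spec a [descriptor_spec()].
#' @param ids optional character vector of row ids.
#' @return tibble with an `id` column followed by the K descriptors.
#' @export
feature_table <- function(graphs, spec, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(graphs))
  stopifnot(length(ids) == length(graphs))
  if (length(graphs) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      c(list(character(0)), replicate(spec$K, numeric(0), simplify = FALSE)),
      c("id", spec$names)))
    return(out)
  }
  rows <- purrr::map(graphs, function(g) {
    fv <- feature_vector(g, spec)
    tibble::as_tibble(as.list(unclass(fv)))
  })
  dplyr::bind_cols(tibble::tibble(id = ids), dplyr::bind_rows(rows))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> K =", length(x), "\n")
  nz <- unclass(x)[unclass(x) != 0]
  print(utils::head(nz, 20))
  invisible(x)
}

#' Tidy a feature vector
#' @param x a `feature_vector`.
#' @param ... unused.
#' @return tibble with columns `descriptor`, `value`.
#' @method tidy feature_vector
#' @export
tidy.feature_vector <- function(x, ...) {
  tibble::tibble(descriptor = names(x), value = as.numeric(x))
}
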