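#' Target specification for inverse inference
#'
#' Fixes the structural features of the graphs to be inferred: the element
#' alphabet and adjacency-configuration set, the vertex count `n*`, maximum
#' degree `d_max` (at most 3 when `d_max = 3`, exactly 4 when `d_max = 4`),
#' the exact diameter `dia*`, the branch-parameter `k*` and the exact
#' `k*`-branch height `bh*` and `k*`-branch-leaf number `bl*`, plus optional
#' extra linear bounds on adjacency-configuration counts.
#'
#' @param elements an [element_table()].
#' @param gamma a `gamma_set`.
#' @param n_star number of vertices (>= 3).
#' @param d_max 3 or 4.
#' @param dia_star diameter (>= 3, <= n* - 1).
#' @param k_star branch-parameter (>= 1).
#' @param bh_star k*-branch height (>= 1).
#' @param bl_star k*-branch-leaf number (>= 2).
#' @param ac_bounds optional tibble with columns `a`, `b`, `m`, `lo`, `hi`
#'   bounding total adjacency-configuration counts.
#' @return object of class `target_spec`.
#' @export
target_spec <- function(elements, gamma, n_star, d_max, dia_star,
                        k_star = 2L, bh_star = 1L, bl_star = 2L,
                        ac_bounds = NULL) {
  stopifnot(inherits(elements, "element_table"))
  n_star <- as.integer(n_star); dia_star <- as.integer(dia_star)
  if (n_star < 3) stop("n* must be >= 3")
  if (!(d_max %in% c(3L, 4L))) stop("d_max must be 3 or 4")
  if (dia_star < 3) stop("dia* must be >= 3")
  # dia* > n* - 1 exceeds any tree diameter; the MILP reports it infeasible
  # rather than erroring, mirroring how an empty class is surfaced.
  if (k_star < 1) stop("k* must be >= 1")
  if (bh_star < 1) stop("bh* must be >= 1")
  if (bl_star < 2) stop("bl* must be >= 2")
  structure(list(elements = elements, gamma = gamma,
                 n_star = n_star, d_max = as.integer(d_max),
                 dia_star = dia_star, k_star = as.integer(k_star),
                 bh_star = as.integer(bh_star), bl_star = as.integer(bl_star),
                 ac_bounds = ac_bounds),
            class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat("<target_spec> n* =", x$n_star, " d_max =", x$d_max, " dia* =", x$dia_star,
      " k* =", x$k_star, " bh* =", x$bh_star, " bl* =", x$bl_star, "\n")
  invisible(x)
}

#' Descriptor spec matching a target spec
#' @param spec a [target_spec()].
#' @return a [descriptor_spec()].
#' @export
as_descriptor_spec <- function(spec) {
  descriptor_spec(spec$elements, spec$gamma, spec$k_star)
}
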