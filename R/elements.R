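#' Element tables
#'
#' An element table fixes the alphabet \eqn{\Lambda} of a hydrogen-suppressed
#' chemical graph model: for every element label it records a unique valence
#' in \[1, 4\] and an atomic mass (in atomic mass units), from which the
#' integer mass \eqn{mass^* = \lfloor 10 \cdot mass \rfloor} is derived. The
#' table also fixes the total order over labels used to normalise
#' adjacency-configurations: `a < b` iff `mass(a) < mass(b)`.
#'
#' @param labels character vector of element symbols (must not contain "H";
#'   hydrogens are implicit in the hydrogen-suppressed model).
#' @param valence integer vector of valences, one per label, each in \[1, 4\].
#' @param mass numeric vector of atomic masses, one per label.
#' @return A tibble of class `element_table` with columns `label`, `valence`,
#'   `mass`, `mass_star`, ordered by increasing mass.
#' @examples
#' element_table(c("C", "N", "O"), c(4, 3, 2), c(12.01, 14.01, 16.00))
#' @export
element_table <- function(labels, valence, mass) {
  stopifnot(length(labels) == length(valence), length(labels) == length(mass))
  if (anyDuplicated(labels)) stop("duplicate element labels")
  if ("H" %in% labels) stop("hydrogen must not appear in a hydrogen-suppressed element table")
  if (any(valence < 1 | valence > 4 | valence != round(valence))) {
    stop("valences must be integers in [1, 4]")
  }
  if (anyDuplicated(mass)) stop("masses must be distinct (they define the label order)")
  ord <- order(mass)
  mass_sorted <- as.numeric(mass)[ord]
  out <- tibble::tibble(
    label = as.character(labels)[ord],
    valence = as.integer(valence)[ord],
    mass = mass_sorted,
    mass_star = as.integer(floor(10 * mass_sorted))
  )
  class(out) <- c("element_table", class(out))
  out
}

#' Default element table (C, N, O)
#'
#' Standard atomic weights; valences 4, 3 and 2. Only the relative mass order
#' matters for adjacency-configuration normalisation.
#'
#' @return An [element_table()].
#' @export
default_elements <- function() {
  element_table(c("C", "N", "O"), c(4L, 3L, 2L), c(12.01, 14.01, 16.00))
}

val_of <- function(elements, label) {
  i <- match(label, elements$label)
  if (anyNA(i)) stop("unknown element label(s): ", paste(unique(label[is.na(i)]), collapse = ", "))
  elements$valence[i]
}

mass_star_of <- function(elements, label) {
  i <- match(label, elements$label)
  if (anyNA(i)) stop("unknown element label(s): ", paste(unique(label[is.na(i)]), collapse = ", "))
  elements$mass_star[i]
}

#' Order rank of labels under the mass order
#' @noRd
label_rank <- function(elements, label) {
  i <- match(label, elements$label)
  if (anyNA(i)) stop("unknown element label(s): ", paste(unique(label[is.na(i)]), collapse = ", "))
  i
}

#' Adjacency-configuration sets
#'
#' An adjacency-configuration \eqn{\gamma = (a, b, m)} is the labelled,
#' multiplicity-annotated type of an edge. The working set
#' \eqn{\Gamma = \Gamma_< \cup \Gamma_=} holds each unordered pair once,
#' normalised by the element mass order (class `"lt"` when `a < b`, `"eq"`
#' when `a == b`). `adjacency_configs()` builds \eqn{\Gamma} from explicit
#' tuples; `all_adjacency_configs()` builds the full valence-feasible set.
#'
#' @param elements an [element_table()].
#' @param a,b,m parallel vectors of element labels and bond multiplicities.
#' @return A tibble of class `gamma_set` with columns `a`, `b`, `m`, `class`,
#'   one row per configuration, in a fixed canonical order.
#' @export
adjacency_configs <- function(elements, a, b, m) {
  stopifnot(length(a) == length(b), length(a) == length(m))
  if (any(m < 1 | m > 3)) stop("bond multiplicities must be in [1, 3]")
  ra <- label_rank(elements, a)
  rb <- label_rank(elements, b)
  swap <- ra > rb
  a2 <- ifelse(swap, b, a)
  b2 <- ifelse(swap, a, b)
  out <- tibble::tibble(a = a2, b = b2, m = as.integer(m)) |>
    dplyr::distinct() |>
    dplyr::mutate(class = ifelse(.data$a == .data$b, "eq", "lt"))
  out <- out[order(label_rank(elements, out$a), label_rank(elements, out$b), out$m), ]
  class(out) <- c("gamma_set", class(out))
  out
}

#' @rdname adjacency_configs
#' @export
all_adjacency_configs <- function(elements) {
  n <- nrow(elements)
  rows <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      # a double/triple bond needs multiplicity <= min valence of both ends;
      # an edge also needs residual valence, but that is a per-graph matter.
      mmax <- min(3L, elements$valence[i], elements$valence[j])
      for (m in seq_len(mmax)) {
        rows[[length(rows) + 1L]] <- list(a = elements$label[i], b = elements$label[j], m = m)
      }
    }
  }
  df <- dplyr::bind_rows(rows)
  adjacency_configs(elements, df$a, df$b, df$m)
}

#' Normalise adjacency tuples into the working set orientation
#'
#' Reorders each (a, b, m) tuple so that `a <= b` under the element mass
#' order (the reversal of a tuple in \eqn{\Gamma_>} lands in \eqn{\Gamma_<}).
#'
#' @inheritParams adjacency_configs
#' @return tibble with columns `a`, `b`, `m`.
#' @export
normalize_adjacency <- function(elements, a, b, m) {
  ra <- label_rank(elements, a)
  rb <- label_rank(elements, b)
  swap <- ra > rb
  a2 <- ifelse(swap, b, a)
  b2 <- ifelse(swap, a, b)
  tibble::tibble(a = a2, b = b2, m = as.integer(m))
}

#' Bond-configuration domain
#'
#' A bond-configuration \eqn{\mu = (d_1, d_2, m)} is the degree-pair plus
#' multiplicity type of an edge, normalised so \eqn{d_1 \le d_2}, subject to
#' \eqn{\max\{d_1, d_2\} + m \le 5}. The full domain has 19 members; the
#' descriptor domain `Bc'` drops the three \eqn{(1, 1, m)} members, which are
#' realisable only by the two-vertex graph, leaving 16 (this is what makes
#' the feature-vector length come out as \eqn{2|\Lambda| + 2|\Gamma| + 50}).
#'
#' @param drop_trivial drop the (1,1,m) configurations (default `TRUE`).
#' @return tibble with columns `d1`, `d2`, `m`.
#' @export
bond_config_domain <- function(drop_trivial = TRUE) {
  g <- expand.grid(d1 = 1:4, d2 = 1:4, m = 1:3)
  g <- g[g$d1 <= g$d2 & pmax(g$d1, g$d2) + g$m <= 5, ]
  if (drop_trivial) g <- g[!(g$d1 == 1 & g$d2 == 1), ]
  out <- tibble::as_tibble(g[order(g$m, g$d1, g$d2), ])
  out$d1 <- as.integer(out$d1); out$d2 <- as.integer(out$d2); out$m <- as.integer(out$m)
  out
}

#' Canonical key strings for configuration tables
#' @noRd
gamma_key <- function(a, b, m) paste0(a, "-", b, "-", m)

#' @noRd
bc_key <- function(d1, d2, m) paste0(d1, "-", d2, "-", m)
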