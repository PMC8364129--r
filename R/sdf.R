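#' Read chemical graphs from an SDF (V2000) file
#'
#' Parses with ChemmineR and maps each record onto the hydrogen-suppressed
#' model: explicit hydrogens are dropped (they are implicit here), element
#' symbols become vertex labels and bond orders 1-3 become multiplicities.
#'
#' @param path SDF file path.
#' @return list of [chem_graph()]s.
#' @export
read_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("reading SDF requires the ChemmineR package")
  }
  sdfs <- ChemmineR::read.SDFset(path)
  out <- list()
  for (i in seq_along(ChemmineR::cid(sdfs))) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    sym <- sub("_.*$", "", rownames(ab))
    keep <- sym != "H"
    idx_map <- cumsum(keep)
    verts <- tibble::tibble(id = as.character(idx_map[keep]), label = sym[keep])
    edges <- NULL
    if (!is.null(bb) && nrow(bb) > 0) {
      u <- as.integer(bb[, 1]); v <- as.integer(bb[, 2]); m <- as.integer(bb[, 3])
      ok <- keep[u] & keep[v]
      if (any(ok)) {
        edges <- tibble::tibble(u = as.character(idx_map[u[ok]]),
                                v = as.character(idx_map[v[ok]]),
                                m = m[ok])
      }
    }
    out[[length(out) + 1L]] <- chem_graph(verts, edges)
  }
  out
}

#' Write chemical graphs to an SDF (V2000) file
#'
#' Hydrogen-suppressed output: only the heavy atoms are written and
#' multiplicities map to bond orders 1-3 (hydrogens stay implicit). The
#' writer emits plain V2000 connection tables that round-trip through the
#' ChemmineR reader.
#'
#' @param graphs a [chem_graph()] or list of them.
#' @param path output path.
#' @param names optional record names.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(graphs, path, names = NULL) {
  if (inherits(graphs, "chem_graph")) graphs <- list(graphs)
  if (is.null(names)) names <- paste0("mol", seq_along(graphs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    idx <- stats::setNames(seq_len(nrow(g$vertices)), g$vertices$id)
    writeLines(c(names[i], "  treeqsar", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(g$vertices), nrow(g$edges)), con)
    for (j in seq_len(nrow(g$vertices))) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         0, 0, 0, g$vertices$label[j]), con)
    }
    if (nrow(g$edges)) {
      for (j in seq_len(nrow(g$edges))) {
        writeLines(sprintf("%3d%3d%3d  0  0  0  0",
                           idx[[g$edges$u[j]]], idx[[g$edges$v[j]]], g$edges$m[j]), con)
      }
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
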