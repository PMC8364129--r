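test_that("rooting at the center gives heights matching a longest-descent oracle", {
  rt <- root_at_center(path_graph(7))
  expect_identical(length(rt$root), 1L)
  expect_identical(max(rt$height), 3L)
  rt6 <- root_at_center(path_graph(6))
  expect_identical(length(rt6$root), 2L)

  height_oracle <- function(rt, v) {
    kids <- rt$children[[v]]
    if (!length(kids)) return(0L)
    1L + max(vapply(kids, function(k) height_oracle(rt, k), integer(1)))
  }
  for (seed in 1:20) {
    g <- random_chem_tree(sample(3:14, 1), elements_cno, gamma_cno, seed = seed + 500)
    rt <- root_at_center(g)
    for (v in g$vertices$id) expect_identical(rt$height[[v]], height_oracle(rt, v))
  }
})

test_that("the synthetic demonstration trees have the reference bl/bh profile", {
  for (g in list(demo_tree_even(), demo_tree_odd())) {
    rt <- root_at_center(g)
    bls <- vapply(0:3, function(k) decompose(rt, k)$bl, integer(1))
    bhs <- vapply(0:3, function(k) decompose(rt, k)$bh, integer(1))
    expect_identical(bls, c(8L, 5L, 3L, 2L))
    expect_identical(bhs, c(3L, 3L, 2L, 1L))
  }
  expect_identical(tree_metrics(demo_tree_even())$diameter, 10L)
  expect_identical(tree_metrics(demo_tree_odd())$diameter, 11L)
})

test_that("path decomposition has the forced structure", {
  rt <- root_at_center(path_graph(7))
  d1 <- decompose(rt, 1L)
  expect_identical(d1$bl, 2L)
  expect_identical(d1$bh, 1L)
  # the two leaf 1-branches are the vertices adjacent to the path ends
  expect_setequal(d1$leaf_branches, c("2", "6"))
})

test_that("decomposition fields satisfy the definitions on random trees", {
  brute <- function(rt, k) {
    ids <- rt$graph$vertices$id
    h <- rt$height
    leafb <- ids[!(ids %in% rt$root) & h[ids] == k]
    nonleafb <- setdiff(ids[!(ids %in% rt$root) & vapply(ids, function(v) {
      kids <- rt$children[[v]]
      length(kids) >= 2 && all(h[kids] >= k)
    }, logical(1))], leafb)
    list(leafb = sort(leafb), nonleafb = sort(nonleafb))
  }
  for (seed in 1:40) {
    g <- random_chem_tree(sample(4:14, 1), elements_cno, gamma_cno, seed = seed + 900)
    rt <- root_at_center(g)
    for (k in 0:3) {
      d <- decompose(rt, k)
      b <- brute(rt, k)
      expect_identical(sort(d$leaf_branches), b$leafb)
      expect_identical(sort(d$nonleaf_branches), b$nonleafb)
      expect_identical(d$bl, length(b$leafb))
      # E_in and E_ex partition E
      expect_identical(nrow(d$E_in) + nrow(d$E_ex), nrow(g$edges))
      ek <- function(e) if (nrow(e)) sort(paste(pmin(e$u, e$v), pmax(e$u, e$v))) else character(0)
      expect_identical(sort(c(ek(d$E_in), ek(d$E_ex))), ek(g$edges))
      # every fringe tree has height <= k; in the non-degenerate case each
      # contains exactly one internal vertex, its root
      for (ft in d$fringe_trees) {
        expect_lte(max(ft$height), k)
        if (!length(d$V_in)) next
        expect_identical(sum(ft$graph$vertices$id %in% d$V_in), 1L)
        expect_identical(ft$graph$vertices$id[ft$graph$vertices$id %in% d$V_in][1], ft$root[1])
      }
      # fringe trees + branch subtree reconstruct the whole vertex set
      fringe_v <- unlist(lapply(d$fringe_trees, function(ft) ft$graph$vertices$id))
      expect_setequal(unique(c(fringe_v, d$V_in)), g$vertices$id)
    }
  }
})

test_that("bl_k is monotone non-increasing in k", {
  for (seed in 1:30) {
    g <- random_chem_tree(sample(4:15, 1), elements_cno, gamma_cno, seed = seed + 1500)
    rt <- root_at_center(g)
    bls <- vapply(0:4, function(k) decompose(rt, k)$bl, integer(1))
    expect_true(all(diff(bls) <= 0))
  }
})

test_that("for k = 0 on a single-center tree with >= 3 vertices, bl_0 counts the leaves", {
  for (seed in 1:15) {
    g <- random_chem_tree(sample(3:14, 1), elements_cno, gamma_cno, seed = seed + 2100)
    rt <- root_at_center(g)
    if (length(rt$root) != 1) next
    deg <- tree_metrics(g)$degree
    expect_identical(decompose(rt, 0L)$bl, sum(deg == 1L & !(g$vertices$id %in% rt$root)))
  }
})

test_that("pair roots put the root edge among the internal edges", {
  g <- path_graph(6)
  rt <- root_at_center(g)
  d <- decompose(rt, 1L)
  ek <- paste(pmin(d$E_in$u, d$E_in$v), pmax(d$E_in$u, d$E_in$v))
  expect_true(paste(sort(rt$root)[1], sort(rt$root)[2]) %in% ek)
})

test_that("fringe size rule matches the direct inequality on exhaustive small trees", {
  expect_true(fringe_size_ok(root_at_center(path_graph(1))))
  # root with one child that has three children: n = 5 > 2*1 + 2
  g <- chem_graph(data.frame(id = as.character(1:5), label = "C"),
                  data.frame(u = c("1", "2", "2", "2"), v = c("2", "3", "4", "5"), m = 1))
  rt <- root_tree_at(g, "1")
  expect_false(fringe_size_ok(rt))
  for (g in pruefer_trees(7)) {
    for (r in g$vertices$id) {
      rt <- root_tree_at(g, r)
      degr <- length(rt$children[[r]])
      expect_identical(fringe_size_ok(rt), nrow(g$vertices) <= 2L * degr + 2L)
    }
  }
})

test_that("decomposition roles serialise one row per vertex", {
  g <- demo_tree_even()
  rt <- root_at_center(g)
  d <- decompose(rt, 2L)
  roles <- decomposition_roles(rt, d)
  expect_identical(nrow(roles), nrow(g$vertices))
  expect_setequal(unique(roles$role),
                  c("leaf-branch", "nonleaf-branch", "internal", "external"))
  expect_identical(sum(roles$role == "leaf-branch"), d$bl)
})
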