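toy_repo <- function() {
  pathway_repo(list(P1 = c("A", "B", "C"), P2 = c("C", "D"),
                    P3 = c("D", "E")))
}

test_that("one-mode projection counts co-annotating pathways exactly", {
  pr <- project_one_mode(build_bipartite(toy_repo()))
  expect_equal(pr$edges,
               data.frame(gene_a = c("A", "A", "B", "C", "D"),
                          gene_b = c("B", "C", "C", "D", "E"),
                          shared = rep(1L, 5)))

  pr2 <- project_one_mode(build_bipartite(
    pathway_repo(list(P1 = c("X", "Y"), P2 = c("X", "Y")))))
  expect_equal(pr2$edges$shared, 2L)

  pr3 <- project_one_mode(build_bipartite(pathway_repo(list(P = "G"))))
  expect_equal(nrow(pr3$edges), 0L)
})

test_that("projection agrees with igraph's bipartite projection", {
  skip_if_not_installed("igraph")
  for (seed in c(5, 23)) {
    repo <- random_repo(seed)
    b <- build_bipartite(repo)
    g <- igraph::graph_from_data_frame(b$edges, directed = FALSE)
    igraph::V(g)$type <- igraph::V(g)$name %in% b$pathway_nodes
    proj <- igraph::bipartite_projection(g, multiplicity = TRUE)$proj1
    ref <- igraph::as_data_frame(proj, "edges")
    ref_key <- paste(pmin(ref$from, ref$to), pmax(ref$from, ref$to))
    mine <- project_one_mode(b)$edges
    my_key <- paste(mine$gene_a, mine$gene_b)
    expect_setequal(my_key, ref_key)
    expect_equal(mine$shared[match(ref_key, my_key)], ref$weight)
  }
})

test_that("signature identification matches hand enumeration", {
  sig <- find_signatures(toy_repo())
  expect_equal(
    sig_key(sig),
    sig_key(data.frame(
      gene_a = c("A", "A", "A", "B", "B", "C", "D", "E"),
      gene_b = c("A", "B", "C", "B", "C", "D", "E", "E"),
      pathway = c("P1", "P1", "P1", "P1", "P1", "P2", "P3", "P3"))))

  # every pair shared between two pathways: no signatures at all
  none <- find_signatures(pathway_repo(list(P1 = c("X", "Y"),
                                            P2 = c("X", "Y"))))
  expect_equal(nrow(none), 0L)

  # single pathway owns every pair and both self-pairs
  own <- find_signatures(pathway_repo(list(P = c("G", "H"))))
  expect_setequal(sig_key(own),
                  c("G\rH\rP", "G\rG\rP", "H\rH\rP"))

  # self-pairs can be disabled
  no_self <- find_signatures(toy_repo(), include_self_pairs = FALSE)
  expect_true(all(no_self$gene_a != no_self$gene_b))
  expect_equal(nrow(no_self), 5L)
})

test_that("weights follow the average inverse membership formula", {
  expect_identical(gps_weight(1, 1), 1)
  expect_equal(gps_weight(4, 3), 7 / 24)
  expect_equal(gps_weight(2, 2), 0.5)
  expect_error(gps_weight(2, 2, scheme = "bogus"), "reciprocal")
  expect_equal(gps_weight(4, 3, scheme = "unit"), 1)
  expect_equal(gps_weight(4, 3, scheme = "min_inverse"), 0.25)
  register_weight_scheme("geom_inverse", function(i, j) 1 / sqrt(i * j))
  expect_equal(gps_weight(4, 4, scheme = "geom_inverse"), 0.25)
})

test_that("flat compilation equals single-pass identification plus weights", {
  repo <- random_repo(7)
  db <- build_gps_db(repo)
  expect_true(all(db$signatures$level == 1L))
  expect_equal(unname(db$pathway_levels), rep(1L, length(repo$pathways)))
  single <- find_signatures(repo)
  expect_setequal(sig_key(db$signatures), sig_key(single))
  self <- db$signatures$gene_a == db$signatures$gene_b
  expect_true(all(db$signatures$weight[self] == 1))
  expect_equal(db$signatures$weight[!self],
               gps_weight(db$signatures$deg_a[!self],
                          db$signatures$deg_b[!self]))
})

test_that("hierarchical compilation exposes child signatures level-wise", {
  repo <- pathway_repo(
    list(P = c("A", "B", "C", "D"), C1 = c("A", "B"), C2 = c("C", "D")),
    hierarchy = data.frame(child = c("C1", "C2"), parent = c("P", "P")))
  db <- build_gps_db(repo)
  l1 <- db$signatures[db$signatures$level == 1L, ]
  l2 <- db$signatures[db$signatures$level == 2L, ]
  # level 1: only cross-child pairs are unique to P; (A,B) and (C,D) are
  # shared with the children and A..D all have degree 2, so no self-pairs
  expect_setequal(sig_key(l1),
                  c("A\rC\rP", "A\rD\rP", "B\rC\rP", "B\rD\rP"))
  expect_equal(l1$weight, rep(0.5, 4))
  # level 2, parent removed: each child owns its pair and both self-pairs
  expect_setequal(sig_key(l2),
                  c("A\rB\rC1", "A\rA\rC1", "B\rB\rC1",
                    "C\rD\rC2", "C\rC\rC2", "D\rD\rC2"))
  expect_equal(l2$weight, rep(1, 6))
  expect_equal(db$pathway_levels, c(P = 1L, C1 = 2L, C2 = 2L))
})

test_that("a child duplicating its parent gets signatures only after removal", {
  repo <- pathway_repo(
    list(P = c("A", "B", "C"), C1 = c("A", "B", "C")),
    hierarchy = data.frame(child = "C1", parent = "P"))
  db <- build_gps_db(repo)
  expect_equal(sum(db$signatures$level == 1L), 0L)
  l2 <- db$signatures[db$signatures$level == 2L, ]
  expect_true(all(l2$pathway == "C1"))
  expect_equal(nrow(l2), choose(3, 2) + 3)   # all pairs + all self-pairs
})

test_that("global-degree weighting option uses full-repository degrees", {
  repo <- pathway_repo(
    list(P = c("A", "B", "C", "D"), C1 = c("A", "B"), C2 = c("C", "D")),
    hierarchy = data.frame(child = c("C1", "C2"), parent = c("P", "P")))
  db <- build_gps_db(repo, degrees = "global")
  l2 <- db$signatures[db$signatures$level == 2L &
                        db$signatures$gene_a != db$signatures$gene_b, ]
  # A and B keep their full-repository degree 2, so (A,B) weighs 1/2
  expect_equal(l2$weight[l2$pathway == "C1"], 0.5)
})

test_that("signature sets stay disjoint and weights bounded", {
  for (seed in c(2, 9)) {
    repo <- generate_repo(n_pathways = 12, gene_pool = 400,
                          size_range = c(3, 8), n_shared_blocks = 3,
                          block_size = 3, pathways_per_block = 3,
                          hierarchy_depth = 3, seed = seed)
    db <- build_gps_db(repo)
    s <- db$signatures
    expect_true(all(s$weight > 0 & s$weight <= 1))
    expect_equal(s$weight == 1,
                 (s$deg_a == 1 & s$deg_b == 1) | s$gene_a == s$gene_b)
    for (T in seq_len(max_level(db))) {
      at <- s[s$level <= T, ]
      expect_false(anyDuplicated(paste(at$gene_a, at$gene_b)) > 0)
    }
    # level of a child is never below its parent's
    h <- repo$hierarchy
    expect_true(all(db$pathway_levels[h$child] >=
                      db$pathway_levels[h$parent]))
    # no (pair, pathway) is emitted twice across levels
    expect_false(anyDuplicated(sig_key(s)) > 0)
  }
})

test_that("signature databases round-trip through TSV + JSON", {
  repo <- generate_repo(n_pathways = 6, gene_pool = 200,
                        size_range = c(3, 6), hierarchy_depth = 2, seed = 4)
  db <- build_gps_db(repo)
  prefix <- file.path(withr::local_tempdir(), "db")
  write_gps_db(db, prefix)
  back <- read_gps_db(prefix)
  expect_equal(back$signatures, db$signatures)
  expect_equal(back$pathway_levels, db$pathway_levels)
  expect_equal(back$options$scheme, db$options$scheme)
  expect_error(read_gps_db(file.path(tempdir(), "missing")), "missing")
})
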