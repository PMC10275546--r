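test_that("read_tree reads, validates, and round-trips", {
  tr <- read_tree("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "ou_phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tr$original_height, 2)

  expect_error(read_tree("((A:1,A:1):1,C:2);"), "duplicate tip")
  expect_error(read_tree("((A,B),C);"), "branch lengths")

  tr5 <- fix_tree5()
  tf <- tempfile(fileext = ".nwk")
  ape::write.tree(tr5, tf)
  back <- read_tree(tf)
  expect_equal(sort(back$tip.label), sort(tr5$tip.label))
  m1 <- phylo_matrices(tr5); m2 <- phylo_matrices(back)
  expect_equal(m2$s[rownames(m1$s), colnames(m1$s)], m1$s, tolerance = 1e-8)
})

test_that("scale_to_unit_height scales and preserves the original height", {
  tr <- scale_to_unit_height(read_tree("((A:1,B:1):1,C:2);"))
  expect_true(all(abs(ape::node.depth.edgelength(tr)[1:3] - 1) < 1e-9))
  expect_equal(tr$original_height, 2)

  # a 73-unit tree whose inner clade is 22 deep: after scaling, the clade
  # height is 22/73 of tree height
  tr73 <- scale_to_unit_height(read_tree("((A:22,B:22):51,C:73);"))
  d <- phylo_matrices(tr73)
  expect_equal(unname(d$d["A", "B"] / 2), 22 / 73, tolerance = 1e-9)
  expect_equal(tr73$original_height, 73)

  expect_error(scale_to_unit_height(read_tree("((A:1,B:1.5):1,C:2);")),
               "ultrametric")
})

test_that("paint_from_node_states applies the child-state convention", {
  tr <- fix_tree5()
  p_const <- paint_from_node_states(tr, rep("F", 9))
  for (tp in tr$tip.label) {
    h <- lineage_epochs(tr, p_const, tp)
    expect_equal(h$regime, "F")
    expect_equal(h$end - h$start, 1)
  }

  # parent F, child NF: the whole edge carries the child state
  p <- fix_painting5(tr)
  e_to_7 <- which(tr$edge[, 2] == 7)  # edge root -> (A,B) clade
  expect_equal(names(p$maps[[e_to_7]]), "NF")
  expect_equal(unname(p$maps[[e_to_7]]), tr$edge.length[e_to_7])

  expect_error(paint_from_node_states(tr, rep("F", 4)), "one state per node")
  expect_error(paint_from_node_states(tr, rep("X", 9), states = c("F", "NF")),
               "unknown regime")
})

test_that("lineage_epochs reproduces hand-traced histories", {
  tr <- fix_tree5()
  p <- fix_painting5(tr)
  hA <- lineage_epochs(tr, p, "A")
  # shift placed at the start of the edge into node 7, i.e. at time 0
  expect_equal(hA$regime, "NF")
  expect_equal(hA$start, 0)
  expect_equal(hA$end, 1)
  hC <- lineage_epochs(tr, p, "C")
  expect_equal(hC$regime, "F")
  expect_error(lineage_epochs(tr, p, "Z"), "unknown tip")

  # two shifts on one path, built from explicit node states:
  # E's path root(6) -> 8 -> E with states F -> NF -> F
  p2 <- paint_from_node_states(tr, c("F", "F", "F", "F", "F",
                                     "F", "F", "NF", "F"))
  hE <- lineage_epochs(tr, p2, "E")
  expect_equal(hE$regime, c("NF", "F"))
  expect_equal(hE$end - hE$start, c(0.3, 0.7), tolerance = 1e-9)
  expect_equal(sum(hE$end - hE$start), 1, tolerance = 1e-9)
})

test_that("epoch durations sum to tip depth and survive child reordering", {
  set.seed(7)
  tr <- simulate_tree(20, seed = 31)
  Q <- ouregime:::build_Q(c("a", "b", "c"), "ER", 1)
  dd <- simulate_discrete(tr, Q, seed = 32)
  for (tp in tr$tip.label) {
    h <- lineage_epochs(tr, dd$painting, tp)
    expect_equal(sum(h$end - h$start), 1, tolerance = 1e-9)
    expect_true(all(h$end > h$start))
  }
  # reordering children (ape::rotate) must not change any lineage history
  # derived from the same node states
  tr2 <- ape::rotate(tr, ape::Ntip(tr) + 1L)
  p1 <- paint_from_node_states(tr, dd$node_states)
  p2 <- paint_from_node_states(as_ou_phylo(tr2), dd$node_states)
  for (tp in tr$tip.label)
    expect_equal(lineage_epochs(as_ou_phylo(tr2), p2, tp),
                 lineage_epochs(tr, p1, tp),
                 ignore_attr = TRUE)
})

test_that("phylo_matrices gives shared times, distances, depths", {
  tr <- read_tree("((A:0.5,B:0.5):0.5,C:1);")
  m <- phylo_matrices(tr)
  expect_equal(unname(m$s["A", "B"]), 0.5)
  expect_equal(unname(m$d["A", "B"]), 1.0)
  expect_equal(unname(m$s["A", "C"]), 0)
  expect_equal(unname(m$d["A", "C"]), 2.0)
  expect_equal(unname(diag(m$d)), rep(0, 3))
  # d = T_i + T_j - 2 s exactly, and triangle inequality on a random tree
  tr2 <- simulate_tree(20, seed = 5)
  m2 <- phylo_matrices(tr2)
  expect_equal(m2$d, outer(m2$depths, m2$depths, "+") - 2 * m2$s)
  n <- 20
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_true(m2$d[i, j] <= m2$d[i, k] + m2$d[k, j] + 1e-12)
})

test_that("classify_diet follows the strictly-largest rule", {
  r <- classify_diet(10, 60, 20, 10)
  expect_true(r$frugivorous); expect_false(r$folivorous)

  r2 <- classify_diet(40, 30, 20, 10)
  expect_false(r2$frugivorous); expect_false(r2$folivorous)

  r3 <- classify_diet(5, 30, 60, 5, strict_member = FALSE)
  expect_true(r3$folivorous); expect_false(r3$strict_folivorous)
  r4 <- classify_diet(5, 30, 60, 5, strict_member = TRUE)
  expect_true(r4$strict_folivorous)

  expect_warning(rt <- classify_diet(10, 40, 40, 10), "tied")
  expect_false(rt$frugivorous); expect_false(rt$folivorous)
  expect_error(classify_diet(0, 0, 0, 0), "all-zero")

  # never both flags at once
  set.seed(1)
  m <- matrix(runif(400, 0, 100), ncol = 4)
  res <- suppressWarnings(classify_diet(m[, 1], m[, 2], m[, 3], m[, 4]))
  expect_true(all(!(res$frugivorous & res$folivorous)))
})

test_that("bin_group_size uses integer bounds with round-half-up", {
  expect_equal(as.character(bin_group_size(5)), "1-5")
  expect_equal(as.character(bin_group_size(26)), "26-50")
  expect_equal(as.character(bin_group_size(10.5)), "11-25")
  expect_equal(as.character(bin_group_size(5.4)), "1-5")
  expect_equal(as.character(bin_group_size(120)), ">50")
  expect_error(bin_group_size(0), "positive")
})

test_that("species_table validates invariants", {
  df <- data.frame(species = c("A", "B"), log_ecv = c(1, 2),
                   log_ecv_var = c(0.01, 0.02), pct_fauna = c(10, 20))
  expect_s3_class(species_table(df), "species_table")
  df2 <- df; df2$log_ecv_var[1] <- -1
  expect_error(species_table(df2), "variances")
  df3 <- df; df3$species[2] <- "A"
  expect_error(species_table(df3), "duplicate")
  tr <- fix_tree5()
  expect_error(species_table(rbind(df, data.frame(species = "ZZ", log_ecv = 0,
                                                  log_ecv_var = 0, pct_fauna = 0)),
                             tree = tr), "ZZ")
  # CSV round trip
  tf <- tempfile(fileext = ".csv")
  utils::write.csv(df, tf, row.names = FALSE)
  expect_equal(read_species_table(tf)$log_ecv, df$log_ecv)
})

test_that("cross_paintings covers edges with realized combinations only", {
  tr <- fix_tree5()
  p1 <- fix_painting5(tr)
  Q <- ouregime:::build_Q(c("x", "y"), "ER", 2)
  p2 <- simulate_discrete(tr, Q, seed = 9)$painting
  cx <- cross_paintings(tr, p1, p2)
  expect_silent(validate_painting(cx, tr))
  expect_true(all(grepl(":", cx$states)))
  combos_tips <- unique(paste(tip_regimes(tr, p1), tip_regimes(tr, p2), sep = ":"))
  expect_true(all(combos_tips %in% cx$states))
})

test_that("simmap export and edge table are consistent", {
  tr <- fix_tree5()
  p <- fix_painting5(tr)
  s <- write_simmap(tr, p)
  expect_match(s, "\\{NF,0\\.6")
  expect_match(s, ";$")
  et <- painting_edge_table(p)
  expect_equal(nrow(et), nrow(tr$edge))
  expect_equal(sum(et$length), sum(tr$edge.length), tolerance = 1e-9)
})
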