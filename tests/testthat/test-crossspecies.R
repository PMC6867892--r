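test_that("reciprocal best hits form groups; one-way hits do not", {
  sim <- data.frame(
    species1 = c("sp1", "sp1", "sp2"),
    gene1 = c("a", "b", "x"),
    species2 = c("sp2", "sp2", "sp1"),
    gene2 = c("x", "x", "a"),
    score = c(90, 40, 90), stringsAsFactors = FALSE)
  og <- build_orthogroups_rbh(sim)
  expect_equal(nrow(og), 2L)
  expect_equal(sort(og$gene_id), c("a", "x"))
  expect_equal(length(unique(og$group_id)), 1L)

  # a's best is x but x's best is b: no reciprocal edge
  sim2 <- data.frame(
    species1 = c("sp1", "sp1"), gene1 = c("a", "b"),
    species2 = c("sp2", "sp2"), gene2 = c("x", "x"),
    score = c(50, 80), stringsAsFactors = FALSE)
  og2 <- build_orthogroups_rbh(sim2)
  expect_false("a" %in% og2$gene_id)
  expect_setequal(og2$gene_id, c("b", "x"))

  dup <- data.frame(species1 = c("sp1", "sp2"), gene1 = c("a", "a"),
                    species2 = c("sp2", "sp3"), gene2 = c("x", "y"),
                    score = c(1, 1), stringsAsFactors = FALSE)
  expect_error(build_orthogroups_rbh(dup), "duplicate gene ids")
})

test_that("RBH recovers simulated orthology from scored similarities", {
  # complete single-copy catalog: every gene has a true hit in every other
  # species, so high-scoring true pairs dominate the low-scoring background
  # (with paralogs or missing members, RBH keeps one gene per species pair
  # and noise edges can win by default - inherent to reciprocal best hits)
  sim <- simulate_decay_experiment(sim_config(n_orthogroups = 60,
                                              single_copy_target = 1,
                                              paralog_prob = 0, seed = 41))
  og_true <- sim$orthogroups
  # similarity generated from truth with margin: within-group pairs score
  # high, plus low-scoring background pairs
  set.seed(41)
  pairs <- list()
  for (g in unique(og_true$group_id)) {
    mem <- og_true[og_true$group_id == g, ]
    if (nrow(mem) < 2) next
    cmb <- utils::combn(nrow(mem), 2)
    keep <- mem$species[cmb[1, ]] != mem$species[cmb[2, ]]
    if (!any(keep)) next
    pairs[[g]] <- data.frame(
      species1 = mem$species[cmb[1, keep]], gene1 = mem$gene_id[cmb[1, keep]],
      species2 = mem$species[cmb[2, keep]], gene2 = mem$gene_id[cmb[2, keep]],
      score = 100 + runif(sum(keep)), stringsAsFactors = FALSE)
  }
  sim_tab <- do.call(rbind, pairs)
  i1 <- sample(nrow(sim_tab)); i2 <- sample(nrow(sim_tab))
  bg <- data.frame(
    species1 = sim_tab$species1[i1], gene1 = sim_tab$gene1[i1],
    species2 = sim_tab$species2[i2], gene2 = sim_tab$gene2[i2],
    score = runif(nrow(sim_tab), 1, 10), stringsAsFactors = FALSE)
  og_hat <- build_orthogroups_rbh(rbind(sim_tab, bg))

  # same partition: every true multi-species group is one recovered group
  true_part <- split(og_true$gene_id, og_true$group_id)
  hat_part <- split(og_hat$gene_id, og_hat$group_id)
  canon <- function(p) unname(lapply(p[order(vapply(p, min, ""))], sort))
  expect_equal(canon(true_part), canon(hat_part))
})

test_that("ortho-DEG id mapping uses any-member rule and orphan ids", {
  og <- data.frame(group_id = c("MCL_7", "MCL_7", "MCL_7"),
                   species = c("sp1", "sp2", "sp2"),
                   gene_id = c("g1", "g2", "g2b"), stringsAsFactors = FALSE)
  sets <- list(
    sp1 = list(early = "g1", late = character(0)),
    sp2 = list(early = c("g2", "orphan1"), late = "g2b"))
  out <- assign_orthodeg_ids(sets, og)
  expect_equal(out$sp1$early, "MCL_7")
  expect_setequal(out$sp2$early, c("MCL_7", "sp2|orphan1"))
  expect_equal(out$sp2$late, "MCL_7")  # paralog counts for the group

  ann <- data.frame(gene_id = c("g1", "g2", "g2b"), stringsAsFactors = FALSE)
  expect_error(assign_orthodeg_ids(sets, og, annotation = ann),
               "absent from annotation")
})

test_that("Venn partition cells are disjoint and cover the union", {
  rot <- c(A = "brown", B = "brown", C = "white", D = "white")
  sets <- list(A = c("x", "y"), B = "x", C = character(0), D = character(0))
  v <- venn_partition(sets, rot)
  expect_equal(v$brown_unique, "x")
  expect_length(v$common_to_all, 0)
  expect_equal(length(v$cells), 15L)

  ident <- venn_partition(list(A = c("p", "q"), B = c("p", "q"),
                               C = c("p", "q"), D = c("p", "q")), rot)
  expect_setequal(ident$common_to_all, c("p", "q"))
  expect_true(all(lengths(ident$cells[names(ident$cells) != "A+B+C+D"]) == 0))

  set.seed(42)
  ids <- paste0("MCL_", 1:40)
  rs <- lapply(rot, function(i) sample(ids, sample(5:25, 1)))
  v2 <- venn_partition(rs, rot)
  flat <- unlist(v2$cells, use.names = FALSE)
  expect_false(anyDuplicated(flat) > 0)
  expect_setequal(flat, unique(unlist(rs)))
  expect_error(venn_partition(list(Z = "x"), rot), "unknown species")
})

test_that("early-to-late ratio follows its closed form and antisymmetry", {
  secs <- decay_sections()
  m <- rbind(c(8, 2, 2), c(2, 4, 4))
  colnames(m) <- secs
  expect_equal(early_late_ratio(m, eps = 0), c(2, -1))
  z <- matrix(0, 1, 3, dimnames = list(NULL, secs))
  expect_equal(early_late_ratio(z, eps = 0.1), 0)

  # swapping the early value with the late block negates r
  set.seed(43)
  for (i in 1:10) {
    a <- runif(1, 0, 50); b <- runif(1, 0, 50)
    fwd <- matrix(c(a, b, b), 1, dimnames = list(NULL, secs))
    rev <- matrix(c(b, a, a), 1, dimnames = list(NULL, secs))
    expect_equal(early_late_ratio(fwd), -early_late_ratio(rev))
  }
})

test_that("spearman correlation handles monotonicity, ties and sparsity", {
  x <- 1:8
  m <- cbind(up = x, up2 = exp(x), down = rev(x))
  cc <- correlation_matrix(m)
  expect_equal(cc["up", "up2"], 1)        # monotone-transform invariance
  expect_equal(cc["up", "down"], -1)
  expect_true(isSymmetric(cc))
  expect_equal(unname(diag(cc)), rep(1, 3))

  set.seed(44)
  for (i in 1:10) {
    a <- sample(1:4, 12, replace = TRUE)  # heavy ties
    b <- sample(1:4, 12, replace = TRUE)
    got <- correlation_matrix(cbind(a = a, b = b))["a", "b"]
    expect_equal(got, oracle_spearman(a, b), tolerance = 1e-12)
  }

  sparse <- cbind(p = c(1, 2, NA, NA, NA), q = c(2, 1, NA, NA, NA))
  expect_true(is.na(correlation_matrix(sparse)["p", "q"]))
})

test_that("correlation matrix of complete data is positive semidefinite", {
  set.seed(45)
  m <- matrix(rnorm(60), 12, 5)
  cc <- correlation_matrix(m)
  expect_gte(min(eigen(cc, symmetric = TRUE)$values), -1e-8)
})

test_that("complete-linkage clustering matches the naive oracle", {
  # identical rows merge first at height zero
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(3, 4))
  hc <- hierarchical_cluster(m)
  expect_equal(hc$height[1], 0)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("a", "b"))

  set.seed(46)
  for (i in 1:8) {
    x <- matrix(rnorm(sample(3:6, 1) * 3), ncol = 3)
    rownames(x) <- paste0("r", seq_len(nrow(x)))
    hc2 <- hierarchical_cluster(x)
    coph <- as.matrix(stats::cophenetic(hc2))
    ord <- match(paste0("r", seq_len(nrow(x))), rownames(coph))
    expect_equal(unname(coph[ord, ord]),
                 oracle_complete_cophenetic(dist(x)), tolerance = 1e-8)
  }
  expect_error(hierarchical_cluster(matrix(c(1, NA, 2, 3), 2)),
               "non-finite")
})

test_that("clustering is invariant to row permutation", {
  set.seed(47)
  x <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("r", 1:6), NULL))
  hc1 <- hierarchical_cluster(x)
  perm <- sample(6)
  hc2 <- hierarchical_cluster(x[perm, ])
  c1 <- as.matrix(stats::cophenetic(hc1))[paste0("r", 1:6), paste0("r", 1:6)]
  c2 <- as.matrix(stats::cophenetic(hc2))[paste0("r", 1:6), paste0("r", 1:6)]
  expect_equal(c1, c2)
})

test_that("dendrograms export as parseable Newick", {
  x <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("s", 1:5), NULL))
  nwk <- cluster_newick(hierarchical_cluster(x))
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, paste0("s", 1:5))
})
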