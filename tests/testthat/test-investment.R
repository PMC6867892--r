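test_that("family DEG counts pool per family and class", {
  ann <- data.frame(
    gene_id = paste0("g", 1:6),
    family = c("POD", "POD", "POD", "POD", "GH5", "GH5"),
    class = c("LOX", "LOX", "LOX", "LOX", "GH", "GH"),
    stringsAsFactors = FALSE)
  sets <- list(X = list(early = c("g1", "g2", "g3"), late = "g4"))
  fc <- family_deg_counts(sets, ann, rot_type = c(X = "brown"))
  pod <- fc$families[fc$families$family == "POD", ]
  expect_equal(c(pod$n_early, pod$n_late), c(3L, 1L))
  expect_equal(pod$delta, 2L)
  lox <- fc$classes[fc$classes$class == "LOX", ]
  expect_equal(c(lox$n_early, lox$n_late), c(3L, 1L))

  empty <- family_deg_counts(
    list(X = list(early = character(0), late = character(0))), ann)
  expect_equal(nrow(empty$families), 0L)

  expect_warning(
    family_deg_counts(list(X = list(early = "missing", late = character(0))),
                      ann, rot_type = c(X = "brown")),
    "missing annotation")
})

test_that("LOX shift tests match oracles and handle degeneracy", {
  # synthetic count summary with a strong brown-early skew
  fams <- data.frame(
    species = rep(c("b1", "w1"), each = 2),
    rot_type = rep(c("brown", "white"), each = 2),
    family = rep(c("POD", "LPMO"), 2),
    class = "LOX",
    n_early = c(6L, 4L, 1L, 1L),
    n_late = c(1L, 0L, 5L, 4L),
    stringsAsFactors = FALSE)
  fams$delta <- fams$n_early - fams$n_late
  cls <- stats::aggregate(fams[, c("n_early", "n_late")],
                          list(species = fams$species,
                               rot_type = fams$rot_type,
                               class = fams$class), sum)
  cls$delta <- cls$n_early - cls$n_late
  res <- lox_shift_tests(list(families = fams, classes = cls))
  expect_equal(res$fisher$table,
               rbind(brown = c(early = 10L, late = 1L),
                     white = c(early = 2L, late = 9L)))
  expect_equal(res$fisher$p, oracle_fisher_2x2(res$fisher$table),
               tolerance = 1e-10)
  expect_equal(res$fisher$p, fisher.test(res$fisher$table)$p.value,
               tolerance = 1e-10)
  expect_false(res$fisher$degenerate)
  expect_true(res$paired_t$p < 0.2)  # 2 families: weak but oriented

  # identical per-family deltas across rot types: t = 0, p = 1
  fams2 <- fams
  fams2[fams2$rot_type == "white", c("n_early", "n_late", "delta")] <-
    fams2[fams2$rot_type == "brown", c("n_early", "n_late", "delta")]
  cls2 <- cls
  cls2[cls2$rot_type == "white", c("n_early", "n_late", "delta")] <-
    cls2[cls2$rot_type == "brown", c("n_early", "n_late", "delta")]
  res2 <- lox_shift_tests(list(families = fams2, classes = cls2))
  expect_equal(res2$paired_t$t, 0)
  expect_equal(res2$paired_t$p, 1)

  # zero margin: degenerate flag and p = 1
  cls3 <- cls
  cls3[cls3$rot_type == "white", c("n_early", "n_late")] <- 0L
  res3 <- lox_shift_tests(list(families = fams, classes = cls3))
  expect_true(res3$fisher$degenerate)
  expect_equal(res3$fisher$p, 1)
})

test_that("term enrichment equals the hypergeometric tail", {
  universe <- paste0("g", 1:10)
  terms <- data.frame(gene_id = paste0("g", 1:5), term = "T1",
                      stringsAsFactors = FALSE)
  res <- fisher_enrichment(paste0("g", 1:5), universe, terms)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)  # 1/252

  whole <- data.frame(gene_id = universe, term = "ALL",
                      stringsAsFactors = FALSE)
  expect_equal(fisher_enrichment(paste0("g", 1:3), universe, whole)$p, 1)

  set.seed(51)
  for (i in 1:20) {
    N <- sample(20:60, 1)
    uni <- paste0("u", seq_len(N))
    tgt <- sample(uni, sample(3:(N / 2), 1))
    tm <- data.frame(gene_id = sample(uni, sample(2:N, 1)), term = "T",
                     stringsAsFactors = FALSE)
    got <- fisher_enrichment(tgt, uni, tm)
    k <- length(intersect(tm$gene_id, tgt))
    expect_equal(got$p,
                 oracle_hyper_tail(k, length(unique(tm$gene_id)), N,
                                   length(tgt)),
                 tolerance = 1e-10)
    expect_true(all(got$q >= got$p))
  }

  expect_error(fisher_enrichment("zz", universe, terms), "subset")
  expect_warning(
    fisher_enrichment(paste0("g", 1:2), universe,
                      data.frame(gene_id = "absent", term = "T9")),
    "absent from the universe")
})

test_that("GH:LOX investment ratio and its split invariance", {
  secs <- decay_sections()
  rp <- matrix(c(300, 300, 300, 100, 100, 100), 2, 3, byrow = TRUE,
               dimnames = list(c("gh1", "lox1"), secs))
  ann <- data.frame(gene_id = c("gh1", "lox1"), class = c("GH", "LOX"),
                    stringsAsFactors = FALSE)
  inv <- investment_ratio(list(S = rp), ann)
  expect_equal(inv$gh_lox_ratio, rep(3, 3))

  # GH sum zero: ratio 0; LOX sum zero: undefined, not infinite
  rp0 <- rp; rp0["gh1", ] <- 0
  expect_equal(investment_ratio(list(S = rp0), ann)$gh_lox_ratio, rep(0, 3))
  rpL <- rp; rpL["lox1", ] <- 0
  expect_true(all(is.na(investment_ratio(list(S = rpL), ann)$gh_lox_ratio)))

  # splitting a gene's RPKM between two genes of the same class
  rp_split <- rbind(gh1 = rp["gh1", ] * 0.3, gh2 = rp["gh1", ] * 0.7,
                    lox1 = rp["lox1", ])
  ann_split <- data.frame(gene_id = c("gh1", "gh2", "lox1"),
                          class = c("GH", "GH", "LOX"),
                          stringsAsFactors = FALSE)
  expect_equal(investment_ratio(list(S = rp_split), ann_split)$gh_lox_ratio,
               inv$gh_lox_ratio)
})

test_that("PCA conserves variance and matches the covariance oracle", {
  # collinear points: PC1 explains everything
  line <- cbind(1:6, 2 * (1:6))
  expect_equal(pca_expression(line)$explained[1], 1)

  set.seed(52)
  x <- matrix(rnorm(40), 10, 4)
  pc <- pca_expression(x)
  expect_equal(sum(pc$sdev^2), sum(apply(x, 2, var)))
  orc <- oracle_pca(x)
  expect_equal(pc$sdev^2, orc$values, tolerance = 1e-8)
  for (j in 1:4) {
    expect_equal(abs(sum(pc$loadings[, j] * orc$vectors[, j])), 1,
                 tolerance = 1e-8)  # same axis up to sign
  }
  expect_true(all(diff(pc$explained) <= 1e-12))

  const <- matrix(5, 4, 3)
  expect_length(pca_expression(const)$explained, 0)
})

test_that("Z-score scaling uses the sample-sd convention", {
  m <- rbind(a = c(1, 2, 3), b = c(7, 7, 7))
  z <- zscore_scale(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))  # sd with n - 1
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  set.seed(53)
  r <- matrix(rnorm(50), 5, 10)
  zr <- zscore_scale(r)
  expect_equal(unname(rowMeans(zr)), rep(0, 5))
  expect_equal(unname(apply(zr, 1, sd)), rep(1, 5))
  # column scaling
  zc <- zscore_scale(r, margin = 2L)
  expect_equal(unname(colMeans(zc)), rep(0, 10))
})

test_that("family expression matrix sums per family on the log scale", {
  secs <- decay_sections()
  rp <- matrix(c(3, 3, 3, 1, 1, 1), 2, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2"), secs))
  ann <- data.frame(gene_id = c("g1", "g2"), class = c("GH", "GH"),
                    family = c("GH5", "GH5"), stringsAsFactors = FALSE)
  fm <- family_expression_matrix(list(S = rp), ann)
  expect_equal(unname(fm[, "GH5"]), rep(log2(4 + 1), 3))
  expect_equal(rownames(fm), paste("S", secs, sep = "_"))
})
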