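test_that("preservation_z separates a real module from noise", {
  sim_ref <- small_sim(seed = 11)
  sim_test <- small_sim(seed = 12)   # independent replicate, same design
  module <- names(sim_ref$truth_modules)[sim_ref$truth_modules == "alpha"][1:40]
  pres <- preservation_z(sim_ref$expr, module, sim_test$expr,
                         n_perm = 200, seed = 1)
  expect_gte(pres$z_summary, 10)
  expect_equal(pres$z_summary, (pres$z_density + pres$z_connectivity) / 2)

  # the same module against i.i.d. noise has near-zero density z
  noise <- rand_expr(nrow(sim_test$expr), 60, seed = 50)
  dimnames(noise) <- dimnames(sim_test$expr)
  pres_noise <- preservation_z(sim_ref$expr, module, noise,
                               n_perm = 200, seed = 1)
  expect_lt(abs(pres_noise$z_density), 3)
  expect_lt(pres_noise$z_summary, 2)
})

test_that("preservation_z is invariant to gene and sample order", {
  sim_ref <- small_sim(seed = 11)
  sim_test <- small_sim(seed = 12)
  module <- names(sim_ref$truth_modules)[sim_ref$truth_modules == "beta"][1:30]
  p1 <- preservation_z(sim_ref$expr, module, sim_test$expr,
                       n_perm = 100, seed = 3)
  set.seed(51)
  perm_g <- sample(nrow(sim_test$expr)); perm_s <- sample(ncol(sim_test$expr))
  p2 <- preservation_z(sim_ref$expr, module,
                       sim_test$expr[perm_g, perm_s], n_perm = 100, seed = 3)
  expect_equal(p1$z_summary, p2$z_summary, tolerance = 1e-10)
  expect_error(preservation_z(sim_ref$expr, module[1:2], sim_test$expr),
               "at least 3")
})

test_that("random gene sets show no preservation on average", {
  sim_ref <- small_sim(seed = 11)
  sim_test <- small_sim(seed = 12)
  pool <- names(sim_ref$truth_modules)[sim_ref$truth_modules == "background"]
  set.seed(52)
  zs <- vapply(1:50, function(i) {
    genes <- sample(pool, 25)
    preservation_z(sim_ref$expr, genes, sim_test$expr,
                   n_perm = 100, seed = i)$z_summary
  }, numeric(1))
  expect_lt(mean(abs(zs)), 2)
})

test_that("immunopanning_boolean thresholds at the whole-matrix mean", {
  # constant matrix: nothing exceeds the mean
  const <- matrix(5, 10, 3,
                  dimnames = list(paste0("g", 1:10), c("n", "a", "o")))
  expect_true(all(immunopanning_boolean(const) == FALSE))

  # one dominant gene/cell-type pair
  set.seed(53)
  prof <- matrix(runif(50 * 4, 0, 0.02), 50,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 c("n", "a", "o", "m")))
  prof["g05", "o"] <- 100
  bm <- immunopanning_boolean(prof)
  expect_true(bm["g05", "o"])
  expect_equal(sum(bm["g05", ]), 1L)

  # replicate averaging + two-pass oracle
  prof2 <- matrix(rexp(50 * 6), 50,
                  dimnames = list(sprintf("g%02d", 1:50),
                                  c("n", "n", "a", "a", "o", "o")))
  bm2 <- immunopanning_boolean(prof2)
  avg <- sapply(c("n", "a", "o"), function(ct)
    rowMeans(prof2[, colnames(prof2) == ct]))
  lg <- log2(avg + 1)
  oracle <- (lg - mean(lg)) / sd(as.vector(lg)) > 0
  expect_identical(unname(bm2), unname(oracle))
})

test_that("singlecell_boolean applies the fold-change rule after cell filtering", {
  genes <- sprintf("g%02d", 1:5)
  counts <- rbind(c(9, 9, 1, 1, 1, 1),    # type mean 9 vs overall 3.67 -> <3x
                  c(9, 9, 0, 0, 0, 0),    # 9 vs 3 -> exactly 3x, TRUE
                  c(2, 2, 2, 2, 2, 2),    # uniform, FC 1
                  c(0, 0, 0, 0, 0, 0),    # silent gene
                  c(0, 0, 5, 5, 0, 0))
  dimnames(counts) <- list(genes, paste0("c", 1:6))
  labels <- c("A", "A", "B", "B", "C", "C")
  bm <- singlecell_boolean(counts, labels)
  expect_true(bm["g02", "A"])
  expect_false(bm["g01", "A"])  # 9 < 3 * 3.67
  expect_false(any(bm["g03", ]))
  expect_false(any(bm["g04", ]))
  expect_true(bm["g05", "B"])

  # planted markers: strong expression in A, near silence in 4 other types
  set.seed(54)
  base <- matrix(rpois(60 * 30, 2), 60,
                 dimnames = list(sprintf("g%02d", 1:60), sprintf("c%02d", 1:30)))
  labs <- rep(c("A", "B", "C", "D", "E"), each = 6)
  base[1:10, labs == "A"] <- rpois(60, 15) + 10
  base[1:10, labs != "A"] <- rpois(240, 0.2)
  base[, 5] <- 0                                  # dead cell gets dropped
  bm2 <- singlecell_boolean(base, labs, fc_threshold = 3)
  expect_gte(mean(bm2[1:10, "A"]), 0.95)
  expect_lt(mean(bm2[11:60, "A"]), 0.1)
})

test_that("overlap_test removes markers before testing", {
  bg <- sprintf("g%03d", 1:200)
  markers <- bg[1:20]
  pred <- bg[1:60]
  ref <- bg[c(1:50, 100:110)]
  out <- overlap_test(pred, ref, bg, exclude = markers)
  # oracle on the reduced sets
  expect_equal(out$p, hyper_tail_oracle(out$overlap, out$pred_size,
                                        out$reference_size,
                                        out$background_size),
               tolerance = 1e-12)
  expect_equal(out$background_size, 180L)
  expect_equal(out$pred_size, 40L)

  # disjoint sets give p = 1
  expect_equal(overlap_test(bg[30:40], bg[150:160], bg)$p, 1)

  # markers covering the whole prediction leave an empty test
  expect_warning(out2 <- overlap_test(bg[1:20], ref, bg, exclude = markers),
                 "empty prediction")
  expect_equal(out2$p, 1)
})

test_that("bootstrap_enrichment is exact at the extremes and monotone", {
  set.seed(55)
  spec <- matrix(runif(200 * 3), 200,
                 dimnames = list(sprintf("g%03d", 1:200), c("n", "a", "o")))
  spec <- spec / rowSums(spec)
  top <- rownames(spec)[order(-spec[, "n"])][1:8]
  out <- bootstrap_enrichment(top, spec, "n", n_boot = 500, seed = 2)
  expect_equal(out$p, 1 / 501)

  bottom <- rownames(spec)[order(spec[, "n"])][1:8]
  out2 <- bootstrap_enrichment(bottom, spec, "n", n_boot = 500, seed = 2)
  expect_gt(out2$p, out$p)
  expect_lte(out2$p, 1)

  expect_error(bootstrap_enrichment(top, spec, "n", n_boot = 0), "n_boot")
  expect_error(suppressMessages(bootstrap_enrichment(c("zzz"), spec, "n")),
               "no target genes")
})

test_that("hpo_enrichment computes coverage and fold change exactly", {
  module <- sprintf("m%03d", 1:100)
  bg <- c(module, sprintf("b%04d", 1:9900))
  terms <- list(T1 = c(module[1:5], sprintf("b%04d", 1:45)),  # 5/100 vs 50/10000
                T2 = c(module[1], sprintf("b%04d", 100:120)), # coverage 0.01
                T3 = module[1:10])                            # fully in module
  out <- hpo_enrichment(module, terms, bg)
  expect_equal(out$coverage[out$term == "T1"], 0.05)
  expect_equal(out$fold_change[out$term == "T1"], 10)
  expect_false("T2" %in% out$term)
  # algebra: term fully inside the module has FC = |bg| / |module|
  expect_equal(out$fold_change[out$term == "T3"], length(bg) / length(module))

  # module = background: FC 1 for every reported term
  out2 <- hpo_enrichment(bg, terms, bg, min_coverage = 0)
  expect_true(all(abs(out2$fold_change - 1) < 1e-12))
})
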