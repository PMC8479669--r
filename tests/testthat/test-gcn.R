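test_that("tom_matrix matches a triple-loop reference on random matrices", {
  for (seed in c(1, 2, 3)) {
    expr <- rand_expr(20, 15, seed = seed)
    tom <- tom_matrix(expr, power = 6)
    expect_lt(max(abs(tom - tom_oracle(expr, 6))), 1e-10)
    expect_lt(max(abs(tom - t(tom))), 1e-10)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(unname(diag(tom)), rep(1, 20))
  }
})

test_that("tom_matrix handles saturated and zero-overlap cases", {
  # three genes, all pairwise |cor| = 1
  base <- c(1, 2, 3, 4)
  expr <- rbind(g1 = base, g2 = 2 * base + 1, g3 = -base)
  colnames(expr) <- paste0("s", 1:4)
  expect_equal(unname(tom_matrix(expr, 6)), matrix(1, 3, 3))

  # mutually orthogonal (zero-correlation) rows
  expr2 <- rbind(g1 = c(1, -1, 1, -1), g2 = c(1, 1, -1, -1), g3 = c(1, -1, -1, 1))
  colnames(expr2) <- paste0("s", 1:4)
  tom2 <- tom_matrix(expr2, 6)
  expect_equal(unname(tom2), diag(3))

  expr3 <- expr2; expr3["g2", ] <- 5
  expect_error(tom_matrix(expr3, 6), "constant")
})

test_that("select_soft_power honors forced grids and small-matrix guard", {
  expr <- rand_expr(50, 20, seed = 4)
  p <- suppressWarnings(select_soft_power(expr, powers = 7))
  expect_equal(as.integer(p), 7L)
  expect_error(select_soft_power(rand_expr(5, 10, seed = 1)), "10 genes")
})

test_that("selected power reaches the scale-free fit on modular data", {
  sim <- small_sim(seed = 1)
  p <- select_soft_power(sim$expr)
  # recompute the fit independently: histogram regression of log10 p(k)
  C <- abs(cor(t(sim$expr)))^as.integer(p)
  diag(C) <- 0
  k <- rowSums(C)
  bin <- cut(k, seq(min(k), max(k), length.out = 11), include.lowest = TRUE)
  freq <- as.vector(table(bin))
  km <- tapply(k, bin, mean)
  keep <- freq > 0 & !is.na(km)
  fit <- summary(lm(log10(freq[keep]) ~ log10(km[keep])))
  expect_gte(-sign(fit$coefficients[2, 1]) * fit$r.squared, 0.80)
})

test_that("an unreachable fit threshold takes the warning path with the best power", {
  expr <- rand_expr(500, 50, seed = 99)
  expect_warning(p <- select_soft_power(expr, powers = 1:4), "no power")
  # independent check: the returned power maximizes the binned-histogram fit
  fit_of <- function(pw) {
    A <- abs(cor(t(expr)))^pw
    diag(A) <- 0
    k <- rowSums(A)
    bin <- cut(k, seq(min(k), max(k), length.out = 11), include.lowest = TRUE)
    freq <- as.vector(table(bin))
    km <- tapply(k, bin, mean)
    keep <- freq > 0 & !is.na(km)
    s <- summary(lm(log10(freq[keep]) ~ log10(km[keep])))
    -sign(s$coefficients[2, 1]) * s$r.squared
  }
  fits <- vapply(1:4, fit_of, numeric(1))
  expect_true(all(fits < 0.80))
  expect_equal(as.integer(p), which.max(fits))
})

test_that("initial_modules recovers planted blocks and applies the size rule", {
  # two clean 120-gene blocks: high within-block, near-zero between-block TOM
  set.seed(31)
  n_s <- 40
  u <- rnorm(n_s); v <- rnorm(n_s)
  expr <- rbind(
    outer(abs(rnorm(120, 1, 0.1)), u) + matrix(rnorm(120 * n_s, 0, 0.3), 120),
    outer(abs(rnorm(120, 1, 0.1)), v) + matrix(rnorm(120 * n_s, 0, 0.3), 120))
  dimnames(expr) <- list(sprintf("g%03d", 1:240), sprintf("s%02d", 1:n_s))
  planted <- rep(c("A", "B"), each = 120)
  tom <- tom_matrix(expr, power = 6)
  assign <- initial_modules(tom, min_module_size = 100)
  # the low-height cut yields pure clusters (possibly with unassigned tails)
  expect_equal(length(setdiff(unique(assign), "unassigned")), 2L)
  for (m in setdiff(unique(assign), "unassigned"))
    expect_length(unique(planted[assign == m]), 1L)
  # the k-means refinement completes the recovery: 2 modules, 0 unassigned
  refined <- kmeans_refine(expr, assign, min_module_size = 100)
  expect_equal(ari_oracle(refined, planted), 1)
  expect_equal(sum(refined == "unassigned"), 0L)

  # all-ones TOM: everything merges at height zero into one module
  ones <- matrix(1, 40, 40, dimnames = list(paste0("g", 1:40), paste0("g", 1:40)))
  a1 <- initial_modules(ones, min_module_size = 10)
  expect_equal(unname(a1), rep("M1", 40))

  expect_warning(a2 <- initial_modules(tom[1:50, 1:50], min_module_size = 100),
                 "unassigned")
  expect_true(all(a2 == "unassigned"))
})

test_that("clusters below the size floor are relabeled unassigned", {
  set.seed(32)
  n_s <- 30
  lat <- matrix(rnorm(3 * n_s), 3)
  sizes <- c(50, 40, 10)
  expr <- do.call(rbind, lapply(1:3, function(i)
    outer(abs(rnorm(sizes[i], 1, 0.1)), lat[i, ]) +
      matrix(rnorm(sizes[i] * n_s, 0, 0.3), sizes[i])))
  dimnames(expr) <- list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:n_s))
  assign <- initial_modules(tom_matrix(expr, 6), min_module_size = 30)
  planted <- rep(c("A", "B", "C"), sizes)
  # the 10-gene group is below the floor and stays unassigned
  expect_setequal(unique(assign[91:100]), "unassigned")
  for (m in setdiff(unique(assign), "unassigned"))
    expect_length(unique(planted[assign == m]), 1L)
  # refinement completes the two viable modules; C stays below the floor
  refined <- kmeans_refine(expr, assign, min_module_size = 30,
                           reassign_floor = 0.5)
  expect_length(unique(refined[1:50]), 1L)
  expect_length(unique(refined[51:90]), 1L)
  expect_false(refined[1] == refined[51])
})

test_that("module_eigengene matches an SVD oracle and fixes its sign", {
  # identical rows: eigengene equals the shared z-scored profile
  base <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expr <- rbind(g1 = base, g2 = base * 3 + 2, g3 = base - 1)
  colnames(expr) <- paste0("s", 1:8)
  e <- module_eigengene(expr, rownames(expr))
  expect_equal(unname(e), as.vector(scale(base)), tolerance = 1e-10)
  expect_equal(unname(cor(e, base)), 1, tolerance = 1e-10)

  # two perfectly anti-correlated genes
  expr2 <- rbind(g1 = base, g2 = -base)
  colnames(expr2) <- paste0("s", 1:8)
  e2 <- module_eigengene(expr2, rownames(expr2))
  cors <- cor(t(expr2), e2)
  expect_equal(abs(unname(cors[, 1])), c(1, 1), tolerance = 1e-10)
  expect_equal(sum(sign(cors)), 0)

  # random module vs independent SVD computation
  expr3 <- rand_expr(10, 25, seed = 12)
  e3 <- module_eigengene(expr3, rownames(expr3))
  Z <- t(scale(t(expr3)))
  pc <- svd(Z)$v[, 1]
  pc <- pc / sd(pc)
  expect_lt(min(max(abs(e3 - pc)), max(abs(e3 + pc))), 1e-8)

  expect_error(module_eigengene(expr3, c("g001", "nope")), "nope")
})

test_that("module_membership correlates genes with eigengenes", {
  expr <- rand_expr(12, 30, seed = 13)
  assign <- setNames(rep(c("M1", "M2"), each = 6), rownames(expr))
  E <- vapply(c("M1", "M2"),
              function(m) module_eigengene(expr, names(assign)[assign == m]),
              numeric(30))
  MM <- module_membership(expr, E)
  expect_equal(dim(MM), c(12L, 2L))
  expect_true(all(abs(MM) <= 1 + 1e-12))
  # a gene equal to an eigengene has MM 1; an orthogonalized gene has MM 0
  expr2 <- rbind(expr, hub = E[, "M1"])
  MM2 <- module_membership(expr2, E)
  expect_equal(unname(MM2["hub", "M1"]), 1, tolerance = 1e-10)
  g <- expr[1, ] - rowMeans(expr)[1]
  e1 <- E[, 1] - mean(E[, 1])
  gperp <- g - sum(g * e1) / sum(e1^2) * e1
  expr3 <- rbind(expr, perp = gperp)
  MM3 <- module_membership(expr3, E)
  expect_lt(abs(MM3["perp", 1]), 1e-10)
})

test_that("kmeans_refine is a no-op at fixed points and with zero iterations", {
  sim <- small_sim(seed = 5, n_multifunctional = 0)
  assign <- sim$truth_modules
  assign[assign == "background"] <- "unassigned"
  out0 <- kmeans_refine(sim$expr, assign, max_iter = 0, min_module_size = 30)
  expect_identical(out0[names(assign)], assign)

  out1 <- kmeans_refine(sim$expr, assign, min_module_size = 30)
  # planted truth is already (near) a fixed point of eigengene reassignment
  expect_gt(mean(out1[assign != "unassigned"] == assign[assign != "unassigned"]),
            0.99)
})

test_that("kmeans_refine returns deliberately mislabeled genes to their module", {
  sim <- small_sim(seed = 6, n_multifunctional = 0, n_background_genes = 0)
  assign <- sim$truth_modules
  mods <- unique(assign)
  set.seed(7)
  flipped <- sample(names(assign), ceiling(0.05 * length(assign)))
  wrong <- assign
  for (g in flipped) wrong[g] <- sample(setdiff(mods, assign[g]), 1)
  refined <- kmeans_refine(sim$expr, wrong, min_module_size = 30)
  expect_gte(mean(refined[flipped] == assign[flipped]), 0.95)
})

test_that("kmeans_refine converges to a fixed point and reduces mismatches", {
  sim <- small_sim(seed = 8)
  assign <- sim$truth_modules
  assign[assign == "background"] <- "unassigned"
  mismatches <- function(a) {
    E <- vapply(setdiff(sort(unique(a)), "unassigned"),
                function(m) module_eigengene(sim$expr, names(a)[a == m]),
                numeric(ncol(sim$expr)))
    MM <- cor(t(sim$expr), E)
    best <- colnames(E)[max.col(abs(MM), ties.method = "first")]
    sum(best != a[rownames(sim$expr)] & a[rownames(sim$expr)] != "unassigned")
  }
  # perturb 10% of assigned genes, refine, and check improvement + fixed point
  set.seed(33)
  mods <- setdiff(unique(assign), "unassigned")
  assigned <- names(assign)[assign != "unassigned"]
  flip <- sample(assigned, ceiling(0.1 * length(assigned)))
  wrong <- assign
  for (g in flip) wrong[g] <- sample(setdiff(mods, assign[g]), 1)
  refined <- kmeans_refine(sim$expr, wrong, min_module_size = 30)
  expect_lt(mismatches(refined), mismatches(wrong))
  again <- kmeans_refine(sim$expr, refined, min_module_size = 30)
  expect_identical(again, refined)
})

test_that("build_network recovers planted modules deterministically", {
  sim <- small_sim(seed = 2)
  net <- small_net(sim$expr)
  ev <- evaluate_recovery(net, sim)
  expect_gte(ev$ari_modules, 0.9)
  net2 <- small_net(sim$expr)
  expect_identical(net$assignment, net2$assignment)
  expect_equal(net$eigengenes, net2$eigengenes)

  # eigengene invariants: unit variance, non-negative mean member correlation
  for (m in colnames(net$eigengenes)) {
    e <- net$eigengenes[, m]
    expect_equal(sd(e), 1, tolerance = 1e-10)
    members <- names(net$assignment)[net$assignment == m]
    expect_gte(mean(cor(t(sim$expr[members, ]), e)), 0)
  }
  expect_true(all(abs(net$membership) <= 1 + 1e-12))
  expect_setequal(names(net$assignment), rownames(sim$expr))

  expect_error(build_network(rand_expr(2, 10, seed = 1)), "10 genes")
})

test_that("a planted hub gene has high membership in its own module", {
  sim <- small_sim(seed = 9)
  net <- small_net(sim$expr)
  enr <- assign_cell_types(net, sim$truth_markers)
  mod_alpha <- names(enr$mapping)[enr$mapping == "alpha"][1]
  hubs <- intersect(sim$truth_markers$alpha, names(net$assignment))
  mm <- net$membership[hubs, mod_alpha]
  expect_gt(max(mm), 0.8)
})
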