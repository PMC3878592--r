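test_that("two-block consensus equals the top singular pair of X1'X2", {
  ds <- seeded_dataset(42, M = 9, dims = c(A = 5, B = 4))
  cc <- extract_consensus_component(lapply(ds$blocks, `[[`, "values"))
  sv <- svd(crossprod(ds$blocks$A$values, ds$blocks$B$values))
  expect_lt(max(abs(cc$blocks$A$w - sign_align(cc$blocks$A$w, sv$u[, 1]))),
            1e-8)
  expect_lt(max(abs(cc$blocks$B$w - sign_align(cc$blocks$B$w, sv$v[, 1]))),
            1e-8)
  # objective trajectory is non-decreasing
  expect_true(all(diff(cc$objective) >= -1e-8 * abs(cc$objective[1])))
})

test_that("a noiseless rank-1 shared signal is recovered exactly", {
  set.seed(3)
  t0 <- stats::rnorm(9)
  t0 <- t0 - mean(t0)
  vs <- list(A = c(1, -2, 0.5), B = c(2, 1, 1, -1), C = c(0.3, -0.7))
  vs <- lapply(vs, function(v) v / sqrt(sum(v^2)))
  blocks <- lapply(names(vs), function(nm) {
    centered_block(tcrossprod(t0, vs[[nm]]), nm)
  })
  names(blocks) <- names(vs)
  cc <- extract_consensus_component(lapply(blocks, `[[`, "values"))
  for (nm in names(vs)) {
    expect_lt(max(abs(cc$blocks[[nm]]$w -
                        sign_align(cc$blocks[[nm]]$w, vs[[nm]]))), 1e-9)
    expect_gt(abs(stats::cor(cc$blocks[[nm]]$t, t0)), 1 - 1e-12)
  }
})

test_that("a pure-noise third block does not perturb the shared pair", {
  set.seed(8)
  t0 <- stats::rnorm(9); t0 <- t0 - mean(t0)
  v1 <- c(1, 2, -1) / sqrt(6); v2 <- c(2, -1, 1) / sqrt(6)
  # block 3 lives entirely orthogonal to t0
  Z <- matrix(stats::rnorm(27), 9, 3)
  Z <- Z - tcrossprod(t0 / sum(t0^2), drop(crossprod(Z, t0)))
  Z <- sweep(Z, 2, colMeans(Z))
  blocks <- list(A = centered_block(tcrossprod(t0, v1), "A"),
                 B = centered_block(tcrossprod(t0, v2), "B"),
                 C = centered_block(Z, "C"))
  cc <- extract_consensus_component(lapply(blocks, `[[`, "values"))
  expect_lt(max(abs(cc$blocks$A$w - sign_align(cc$blocks$A$w, v1))), 1e-6)
  expect_lt(max(abs(cc$blocks$B$w - sign_align(cc$blocks$B$w, v2))), 1e-6)
  # the objective is dominated by the (A, B) pair
  tA <- cc$blocks$A$t; tB <- cc$blocks$B$t; tC <- cc$blocks$C$t
  expect_gt(sum(tA * tB), 10 * (abs(sum(tA * tC)) + abs(sum(tB * tC))))
})

test_that("zero cross-covariance raises the no-joint-variation warning", {
  a <- c(1, -1, 0, 0); c_ <- c(0, 0, 1, -1)
  X1 <- tcrossprod(a, c(1, 2, 3))
  X2 <- tcrossprod(c_, c(2, -1))
  dimnames(X1) <- list(paste0("s", 1:4), paste0("a", 1:3))
  dimnames(X2) <- list(paste0("s", 1:4), paste0("b", 1:2))
  expect_warning(extract_consensus_component(list(A = X1, B = X2)),
                 "no appreciable joint variation")
  # an all-zero block is a hard error
  X0 <- matrix(0, 4, 2, dimnames = list(paste0("s", 1:4), c("z1", "z2")))
  expect_error(extract_consensus_component(list(A = X1, B = X0)),
               "no extractable variation")
})

test_that("orthogonal candidate recovers a constructed orthogonal direction", {
  set.seed(5)
  t0 <- stats::rnorm(9); t0 <- t0 - mean(t0)
  u <- 0.6 * t0 + stats::rnorm(9); u <- u - mean(u)   # correlated with t0
  w <- c(1, 1, 0, 0, 0) / sqrt(2)
  q <- c(0, 0, 1, -1, 0) / sqrt(2)                    # q orthogonal to w
  X <- tcrossprod(t0, w) + 3 * tcrossprod(u, q)
  dimnames(X) <- list(paste0("s", 1:9), paste0("v", 1:5))
  t_joint <- drop(X %*% w)
  p <- drop(crossprod(X, t_joint)) / sum(t_joint^2)
  cand <- extract_orthogonal_candidate(X, w, p, ortho_var_ratio = 0.05)
  expect_false(is.null(cand))
  expect_lt(max(abs(abs(cand$w) - abs(q))), 1e-8)

  # p parallel to w -> no orthogonal structure
  Xp <- tcrossprod(t0, w)
  dimnames(Xp) <- dimnames(X)
  pp <- drop(crossprod(Xp, drop(Xp %*% w))) / sum((Xp %*% w)^2)
  expect_null(extract_orthogonal_candidate(Xp, w, pp))

  # a candidate below the variance threshold is rejected
  expect_null(extract_orthogonal_candidate(X, w, p, ortho_var_ratio = 0.999))
})

test_that("variance additivity and reconstruction hold on noisy fits", {
  sr <- simulate_multiomics(sim_spec(seed = 17))
  spec <- model_spec_for(sr$spec)
  m <- fit_onpls(sr$dataset, spec)
  for (b in names(sr$dataset$blocks)) {
    X <- sr$dataset$blocks[[b]]$values
    bl <- m$blocks[[b]]
    parts <- Reduce(`+`, lapply(bl$components, function(cmp) {
      tcrossprod(cmp$t, cmp$p)
    }))
    # reconstruction X = sum t p' + E
    expect_lt(max(abs(X - parts - bl$residual)) / max(abs(X)), 1e-8)
    # norm additivity
    total <- sum(vapply(bl$components, function(cmp) {
      sum(cmp$t^2) * sum(cmp$p^2)
    }, numeric(1))) + sum(bl$residual^2)
    expect_lt(abs(total - bl$norm0) / bl$norm0, 1e-8)
    # scores of successive components are mutually orthogonal
    Tm <- vapply(bl$components, `[[`, numeric(9), "t")
    G <- crossprod(Tm)
    expect_lt(max(abs(G - diag(diag(G)))) / max(diag(G)), 1e-8)
  }
  # R2 rows sum to one
  num <- vapply(m$r2, is.numeric, logical(1))
  expect_lt(max(abs(rowSums(m$r2[, num]) - 1)), 1e-10)
})

test_that("fitting is symmetric in block order", {
  sr <- simulate_multiomics(sim_spec(seed = 4))
  spec <- model_spec_for(sr$spec)
  ds <- sr$dataset
  ref <- fit_onpls(ds, spec)
  ref_r2 <- ref$r2[order(ref$r2$block), ]
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(3, 2, 1))) {
    m <- fit_onpls(multiblock_dataset(ds$blocks[perm], ds$design), spec)
    r2 <- m$r2[order(m$r2$block), ]
    num <- vapply(r2, is.numeric, logical(1))
    expect_lt(max(abs(as.matrix(r2[, num]) - as.matrix(ref_r2[, num]))),
              1e-8)
    expect_lt(max(principal_angles(global_scores(ref), global_scores(m))),
              1e-8)
  }
})

test_that("fit_o2pls delegates and matches the SVD oracle when unfiltered", {
  ds <- seeded_dataset(42, M = 9, dims = c(A = 5, B = 4))
  spec <- onpls_spec(n_global = 1, filter_orthogonal = FALSE)
  m1 <- fit_onpls(ds, spec)
  m2 <- fit_o2pls(ds, spec)
  expect_equal(m1$r2, m2$r2)
  expect_identical(global_scores(m1), global_scores(m2))
  sv <- svd(crossprod(ds$blocks$A$values, ds$blocks$B$values))
  wA <- m2$blocks$A$components[[1]]$w
  expect_lt(max(abs(wA - sign_align(wA, sv$u[, 1]))), 1e-8)
  # three blocks are rejected
  sr <- simulate_multiomics(sim_spec(seed = 1))
  expect_error(fit_o2pls(sr$dataset, spec), "exactly 2 blocks")
})

test_that("variance decomposition matches direct Frobenius arithmetic", {
  ds <- seeded_dataset(13, M = 9, dims = c(A = 6, B = 5))
  spec <- onpls_spec(n_global = 1, filter_orthogonal = FALSE)
  m <- fit_onpls(ds, spec)
  cmp <- m$blocks$A$components[[1]]
  direct <- sum(tcrossprod(cmp$t, cmp$p)^2)
  expect_equal(m$r2$global[m$r2$block == "A"],
               direct / sum(ds$blocks$A$values^2), tolerance = 1e-12)
})

test_that("requesting more components than the rank bound errors early", {
  ds <- seeded_dataset(1, M = 4, dims = c(A = 6, B = 5))
  expect_error(fit_onpls(ds, onpls_spec(n_global = 2, n_unique = 2)),
               "rank bound")
})

test_that("projection reproduces training scores and handles new rows", {
  sr <- simulate_multiomics(sim_spec(seed = 5, noise_sd = 0.1))
  m <- fit_onpls(sr$dataset, model_spec_for(sr$spec))
  b <- "proteins"
  tr <- project_block(m, b, sr$dataset$blocks[[b]]$values)
  expect_lt(max(abs(tr - global_scores(m, b))), 1e-8)
  # the zero row projects to zero scores
  z <- project_block(m, b, matrix(0, 1, 243))
  expect_equal(unname(z), matrix(0, 1, 2))
  # held-out samples built from known true scores are recovered up to the
  # fitted scale (components may come out in either order)
  set.seed(99)
  t_new <- cbind(c(0, 3, 3, 0, -2, 2, 1, -1),
                 c(0, -2, 2, 1, 1, -1, 0, 2))
  P <- cbind(sr$truth$loadings[[b]]$global1, sr$truth$loadings[[b]]$global2)
  Xn <- t_new %*% t(P) + matrix(stats::rnorm(8 * 243, 0, 0.1), 8)
  colnames(Xn) <- names(sr$truth$loadings[[b]]$global1)
  pr <- project_block(m, b, Xn)
  cors <- abs(stats::cor(pr, t_new))
  best <- apply(cors, 2, max)
  expect_true(all(best > 0.99))
  expect_error(project_block(m, b, matrix(0, 1, 7)), "columns")
})

test_that("per-genotype CV matches its formula and degenerate cases", {
  sr <- simulate_multiomics(sim_spec(seed = 2))
  m <- fit_onpls(sr$dataset, model_spec_for(sr$spec))
  cv <- genotype_cv(m)
  s <- global_scores(m)[, 1]
  geno <- sr$design$genotype_of[sr$design$sample_ids]
  for (g in unique(geno)) {
    expect_equal(unname(cv[g]),
                 100 * stats::sd(s[geno == g]) / (max(s) - min(s)))
  }
  # the dominant genotype contrast spans a range near 4 with tau = 0.1
  # within-genotype spread, so CVs sit in the low percent range
  expect_true(all(cv < 10))
  # true-score oracle: same formula applied to the matched true score
  tt <- sr$truth$scores[, c("global1", "global2")]
  match_col <- which.max(abs(stats::cor(s, tt)))
  s_true <- tt[, match_col]
  cv_true <- vapply(unique(geno), function(g) {
    100 * stats::sd(s_true[geno == g]) / (max(s_true) - min(s_true))
  }, numeric(1))
  expect_lt(max(abs(cv - cv_true[names(cv)])), 1)
})

test_that("identical inputs give bit-identical models", {
  sr1 <- simulate_multiomics(sim_spec(seed = 9))
  sr2 <- simulate_multiomics(sim_spec(seed = 9))
  m1 <- fit_onpls(sr1$dataset, model_spec_for(sr1$spec))
  m2 <- fit_onpls(sr2$dataset, model_spec_for(sr2$spec))
  expect_identical(m1$r2, m2$r2)
  expect_identical(global_scores(m1), global_scores(m2))
})
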