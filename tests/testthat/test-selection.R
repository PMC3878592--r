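# builds a minimal fitted-model stub carrying prescribed global components,
# so closed-form VIP values can be checked independently of the fitter
vip_stub <- function(weights, scores, block = "A") {
  N <- nrow(weights)
  vids <- paste0("v", seq_len(N))
  comps <- lapply(seq_len(ncol(weights)), function(a) {
    w <- weights[, a]
    t <- scores[, a]
    # loading chosen so that SS_a = ||t||^2 * ||p||^2 with p = w here
    list(kind = "global", index = a,
         w = stats::setNames(w, vids),
         t = t,
         p = stats::setNames(w, vids))
  })
  structure(list(blocks = stats::setNames(list(
    list(components = comps, variable_ids = vids)), block),
    block_names = block),
    class = "onpls")
}

test_that("VIP closed forms match the formula", {
  # uniform single-component weights give VIP = 1 everywhere
  N <- 4
  stub <- vip_stub(matrix(rep(1 / sqrt(N), N), N),
                   matrix(c(1, -1, 2, -2), 4))
  expect_equal(unname(compute_vip(stub, "A")$vip), rep(1, N))

  # single component: VIP_k = sqrt(N) |w_k|
  w <- c(0.8, -0.6, 0, 0)
  stub <- vip_stub(matrix(w, 4), matrix(c(1, -1, 2, -2), 4))
  expect_equal(unname(compute_vip(stub, "A")$vip), sqrt(4) * abs(w))

  # two components, SS = (3, 1), N = 2, w1 = (1,0), w2 = (0,1)
  # -> VIP = (sqrt(2 * 3/4), sqrt(2 * 1/4))
  t1 <- c(sqrt(3), 0, 0)
  t2 <- c(0, 1, 0)
  stub <- vip_stub(cbind(c(1, 0), c(0, 1)), cbind(t1, t2), block = "A")
  vip <- compute_vip(stub, "A")$vip
  expect_equal(unname(vip), c(sqrt(2 * 3 / 4), sqrt(2 * 1 / 4)),
               tolerance = 1e-12)
  expect_equal(unname(vip), c(1.224744871, 0.7071067812), tolerance = 1e-9)
})

test_that("mean squared VIP is one on every fitted block", {
  sr <- simulate_multiomics(sim_spec(seed = 6))
  m <- fit_onpls(sr$dataset, model_spec_for(sr$spec))
  for (b in names(sr$dataset$blocks)) {
    vip <- compute_vip(m, b)$vip
    expect_lt(abs(mean(vip^2) - 1), 1e-10)
  }
})

test_that("jackknife SE matches an independent leave-one-out enumeration", {
  set.seed(7)
  ids <- paste0("s", 1:3)
  X1 <- matrix(stats::rnorm(9), 3, 3, dimnames = list(ids, paste0("a", 1:3)))
  X2 <- matrix(stats::rnorm(6), 3, 2, dimnames = list(ids, paste0("b", 1:2)))
  des <- sample_design(ids, c("WT", "WT", "MUT"), "WT")
  ds <- multiblock_dataset(list(centered_block(X1, "A", ids),
                                centered_block(X2, "B", ids)), des)
  spec <- onpls_spec(n_global = 1, filter_orthogonal = FALSE)
  jk <- suppressWarnings(jackknife(ds, spec, resample_preprocess = "center"))
  full <- suppressWarnings(fit_onpls(ds, spec))

  # brute force: enumerate the three leave-one-out fits and apply the
  # jackknife variance formula inline
  for (b in c("A", "B")) {
    p_full <- full$blocks[[b]]$components[[1]]$p
    th <- vapply(seq_along(ids), function(mi) {
      keep <- ids[-mi]
      d2 <- structure(list(sample_ids = keep,
                           genotype_of = des$genotype_of[keep],
                           reference_genotype = "WT",
                           replicate_index = des$replicate_index[keep]),
                      class = "sample_design")
      blocks2 <- lapply(ds$blocks, function(bb) {
        v <- bb$values[keep, , drop = FALSE]
        v <- sweep(v, 2, colMeans(v))
        omics_block(v, bb$name, state = "centered")
      })
      m2 <- suppressWarnings(fit_onpls(multiblock_dataset(blocks2, d2),
                                       spec))
      p <- m2$blocks[[b]]$components[[1]]$p
      if (sum(p * p_full) < 0) p <- -p
      p
    }, numeric(length(p_full)))
    for (k in seq_along(p_full)) {
      se_bf <- sqrt((3 - 1) / 3 *
                      sum((th[k, ] - mean(th[k, ]))^2))
      se_jk <- jk[[b]]$se[jk[[b]]$variable_id == names(p_full)[k]]
      expect_lt(abs(se_jk - se_bf), 1e-10)
    }
  }
})

test_that("the jackknife variance formula reproduces the worked value", {
  # M = 3 leave-one-out estimates (1, 2, 3):
  # var = (2/3) * 2 = 4/3, SE = 1.1547...
  expect_equal(jackknife_se(c(1, 2, 3)), sqrt(4 / 3))
  expect_equal(jackknife_se(c(1, 2, 3)), 1.154700538, tolerance = 1e-9)
  # identical estimates give a zero-width interval
  expect_equal(jackknife_se(c(2, 2, 2)), 0)
})

test_that("significance requires both the VIP gate and the CI gate", {
  mk_jk <- function(ci_low, ci_high) {
    structure(list(A = data.frame(
      variable_id = paste0("v", seq_along(ci_low)),
      component = 1L, estimate = (ci_low + ci_high) / 2, se = 1,
      ci_low = ci_low, ci_high = ci_high,
      n_resamples = 9L, stringsAsFactors = FALSE)),
      class = "jackknife_result")
  }
  mk_vip <- function(vip) {
    structure(list(block = "A",
                   vip = stats::setNames(vip,
                                         paste0("v", seq_along(vip)))),
              class = "vip_result")
  }
  # VIP 0.6 with CI (0.1, 0.4): significant
  tab <- call_significance(mk_vip(0.6), mk_jk(0.1, 0.4))
  expect_true(tab$significant)
  # CI spanning zero fails
  tab <- call_significance(mk_vip(0.6), mk_jk(-0.1, 0.4))
  expect_false(tab$significant)
  # VIP exactly at the threshold fails (strict inequality)
  tab <- call_significance(mk_vip(0.5), mk_jk(0.1, 0.4))
  expect_false(tab$significant)
  # VIP above threshold, negative CI: significant
  tab <- call_significance(mk_vip(0.7), mk_jk(-0.5, -0.1))
  expect_true(tab$significant)
})

test_that("direction arrows take the sign of the line mean", {
  d <- sample_design(c("WT-1", "WT-2", "A-1", "B-1"),
                     c("WT", "WT", "AS9", "AS24"), "WT")
  v <- matrix(c(-0.5, 0.5, 1.2, 0.8,
                -0.7, 0.7, 1.2, -0.3,
                -1, 1, 0.5, 0.5), ncol = 3,
              dimnames = list(d$sample_ids, c("g1", "g2", "g3")))
  b <- omics_block(v, "prot", state = "wt_scaled")
  tab <- data.frame(variable_id = c("g1", "g2", "g3"), block = "prot",
                    vip = c(1, 1, 0.2), estimate = 1, ci_low = 0.5,
                    ci_high = 1.5, significant = c(TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  class(tab) <- c("significance_table", "data.frame")
  out <- direction_arrows(b, d, tab)
  expect_equal(out$dir_AS9, c(1L, 1L, 0L))    # non-significant row gets 0
  expect_equal(out$dir_AS24, c(1L, -1L, 0L))  # discordant line directions
  expect_equal(out$mean_AS9, unname(v["A-1", ]))
  # a significant variable with exactly zero line mean warns and gets 0
  v0 <- v; v0["A-1", "g1"] <- 0
  b0 <- omics_block(v0, "prot", state = "wt_scaled")
  expect_warning(out0 <- direction_arrows(b0, d, tab), "zero mean")
  expect_equal(out0$dir_AS9[1], 0L)
  # state is enforced
  braw <- omics_block(v, "prot", state = "centered")
  expect_error(direction_arrows(braw, d, tab), "wt_scaled")
})

test_that("coregulation fraction counts concordant protein-transcript pairs", {
  mk_tab <- function(ids, sig, d1, d2) {
    tab <- data.frame(variable_id = ids, block = "x", vip = 1,
                      estimate = 1, ci_low = 0.5, ci_high = 1.5,
                      significant = sig, dir_L1 = d1, dir_L2 = d2,
                      stringsAsFactors = FALSE)
    class(tab) <- c("significance_table", "data.frame")
    tab
  }
  mapping <- c(p1 = "t1", p2 = "t2")
  prot <- mk_tab(c("p1", "p2"), c(TRUE, TRUE), c(1L, 1L), c(1L, -1L))

  # all transcripts significant and concordant -> 1
  tr <- mk_tab(c("t1", "t2"), c(TRUE, TRUE), c(1L, 1L), c(1L, -1L))
  expect_equal(coregulation_fraction(prot, tr, mapping), 1)

  # no transcript significant -> 0
  tr0 <- mk_tab(c("t1", "t2"), c(FALSE, FALSE), c(0L, 0L), c(0L, 0L))
  expect_equal(coregulation_fraction(prot, tr0, mapping), 0)

  # exactly one concordant pair of the four -> 0.25
  tr1 <- mk_tab(c("t1", "t2"), c(TRUE, FALSE), c(1L, 0L), c(-1L, 0L))
  expect_equal(coregulation_fraction(prot, tr1, mapping), 0.25)

  expect_error(coregulation_fraction(prot[0, ], tr, mapping), "empty")
  expect_error(coregulation_fraction(prot, tr, c(p1 = "t1")), "mapping")
})
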