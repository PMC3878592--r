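mk_raw <- function(v, name = "t") {
  if (is.null(rownames(v))) rownames(v) <- paste0("s", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- paste0("v", seq_len(ncol(v)))
  omics_block(v, name)
}

test_that("log2 transform maps known values and preserves missingness", {
  b <- mk_raw(matrix(c(8, 1, NA, 2), 2))
  lb <- log2_transform(b)
  expect_equal(lb$values[1, 1], 3)
  expect_equal(lb$values[2, 1], 0)
  expect_true(is.na(lb$values[1, 2]))
  expect_equal(lb$state, "log2")
  expect_error(log2_transform(lb), "raw")
  expect_error(log2_transform(mk_raw(matrix(c(0, 1, 2, 3), 2))),
               "non-positive")
  # offset admits zeros
  ob <- log2_transform(mk_raw(matrix(c(0, 1, 2, 3), 2)),
                       preprocess_params(log_offset = 1))
  expect_equal(ob$values[1, 1], 0)
})

test_that("censoring raises low log2 intensities to the floor, idempotently", {
  b <- mk_raw(matrix(c(32, 256, 2, 1024), 2))
  lb <- log2_transform(b)            # 5, 8, 1, 10
  cb <- censor_low(lb)               # threshold 7
  expect_equal(unname(cb$values[1, ]), c(7, 7))
  expect_equal(unname(cb$values[2, ]), c(8, 10))
  expect_identical(censor_low(cb)$values, cb$values)
  # all-above block unchanged
  hi <- log2_transform(mk_raw(matrix(c(256, 512, 1024, 2048), 2)))
  expect_identical(censor_low(hi)$values, hi$values)
})

test_that("dye-swap combination averages replicates and ignores missing", {
  v <- matrix(c(8, 10, 3, NA,
                8, NA, NA, NA), nrow = 4,
              dimnames = list(c("s1.a", "s1.b", "s2.a", "s2.b"),
                              c("g1", "g2")))
  b <- log2_transform(mk_raw(2^v))   # keep values as given, on log2 scale
  cb <- combine_dye_swap(b, list(s1 = c("s1.a", "s1.b"),
                                 s2 = c("s2.a", "s2.b")))
  expect_equal(cb$state, "combined")
  expect_equal(unname(cb$values["s1", "g1"]), 9)     # mean(8, 10)
  expect_equal(unname(cb$values["s1", "g2"]), 8)     # (8, NA) -> 8
  expect_true(is.na(cb$values["s2", "g2"]))          # (NA, NA) -> NA
  # invariant to replicate ordering
  cb2 <- combine_dye_swap(b, list(s1 = c("s1.b", "s1.a"),
                                  s2 = c("s2.b", "s2.a")))
  expect_identical(cb2$values, cb$values)
  expect_error(combine_dye_swap(b, list(s1 = c("s1.a", "nope"))), "nope")
})

test_that("per-sample centering zeroes row means over observed entries", {
  v <- matrix(c(1, 2, 3,
                4, NA, 8,
                5, 6, 10), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("v", 1:3)))
  cb <- center_per_sample(mk_raw(v))
  expect_equal(unname(cb$values[1, ]), c(-1, 0, 1))
  # row with a missing entry: mean over observed entries (here 6)
  expect_equal(unname(cb$values[2, ]), c(-2, NA, 2))
  # constant row annihilates
  cc <- center_per_sample(mk_raw(matrix(c(5, 1, 5, 2), 2)))
  expect_equal(unname(cc$values[1, ]), c(0, 0))
  allna <- matrix(c(NA, 1, NA, 2), 2,
                  dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(center_per_sample(omics_block(allna, "x")), "s1")
})

test_that("reference scaling standardises against WT statistics", {
  d <- sample_design(c("WT-1", "WT-2", "WT-3", "TG-1"),
                     c("WT", "WT", "WT", "TG"), "WT")
  v <- matrix(c(10, 12, 14, 16,     # WT mean 12, sd 2 -> TG value 2
                5, 5, 5, 9,         # zero reference sd -> dropped
                1, 2, 3, 4), ncol = 3,
              dimnames = list(d$sample_ids, c("a", "b", "c")))
  expect_warning(sb <- wt_reference_scale(mk_raw(v), d), "dropped")
  expect_equal(sb$state, "wt_scaled")
  expect_false("b" %in% variable_ids(sb))
  expect_equal(attr(sb, "dropped")$variable_id, "b")
  expect_equal(attr(sb, "dropped")$reason, "zero_reference_sd")
  expect_equal(unname(sb$values["TG-1", "a"]), 2)
  # reference rows: mean 0, sd 1 (n-1) per retained variable
  refs <- sb$values[1:3, ]
  expect_lt(max(abs(colMeans(refs))), 1e-12)
  expect_lt(max(abs(apply(refs, 2, stats::sd) - 1)), 1e-12)
})

test_that("reference scaling drops variables with under-observed references", {
  d <- sample_design(c("WT-1", "WT-2", "WT-3", "TG-1"),
                     c("WT", "WT", "WT", "TG"), "WT")
  v <- matrix(c(10, NA, NA, 16, 1, 2, 3, 4), ncol = 2,
              dimnames = list(d$sample_ids, c("a", "b")))
  expect_warning(sb <- wt_reference_scale(mk_raw(v), d), "dropped")
  expect_equal(attr(sb, "dropped")$reason, "insufficient_reference_values")
  expect_equal(variable_ids(sb), "b")
})

test_that("imputation fills by variable mean or drops variables", {
  v <- matrix(c(1, NA, 3, 4, 5, 6), ncol = 2,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  b <- mk_raw(v)
  ib <- impute_missing(b, "variable_mean")
  expect_equal(unname(ib$values[, "a"]), c(1, 2, 3))
  expect_equal(nrow(attr(ib, "imputed")), 1)
  # complete block unchanged
  full <- mk_raw(matrix(1:4 + 0.5, 2))
  expect_identical(impute_missing(full)$values, full$values)
  db <- impute_missing(b, "drop_variable")
  expect_equal(variable_ids(db), "b")
})

test_that("direction arrows are invariant to positive block rescaling", {
  sr <- simulate_multiomics(sim_spec(seed = 21))
  spec <- model_spec_for(sr$spec)
  m <- fit_onpls(sr$dataset_scaled, spec)
  jk <- jackknife(sr$dataset_scaled, spec, resample_preprocess = "none",
                  model = m)
  b <- "metabolites"
  tab <- call_significance(compute_vip(m, b), jk)
  t1 <- direction_arrows(sr$dataset_scaled$blocks[[b]], sr$design, tab)
  # multiply the *raw* block by a positive scalar; reference scaling
  # divides it out, so the arrows cannot change
  raw <- sr$dataset$blocks[[b]]
  raw$values <- raw$values * 37
  rescaled <- wt_reference_scale(raw, sr$design)
  t2 <- direction_arrows(rescaled, sr$design, tab)
  expect_identical(t1$dir_LINE1, t2$dir_LINE1)
  expect_identical(t1$dir_LINE2, t2$dir_LINE2)
})
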