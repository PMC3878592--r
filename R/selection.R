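#' Variable importance in projection (VIP) for one block
#'
#' Adapted to the unsupervised multi-block setting: each globally joint
#' component `a` of the block contributes its squared unit-norm weight
#' `w_{a,k}^2`, weighted by the within-block joint variance it captures,
#' `SS_a = ||t_a p_a'||_F^2`:
#' `VIP_k = sqrt( N * sum_a SS_a w_{a,k}^2 / sum_a SS_a )`.
#' Because the weights are unit-norm, the mean of `VIP^2` over variables is
#' exactly 1; with a single component the formula collapses to
#' `VIP_k = sqrt(N) * |w_k|`.
#'
#' @param model A fitted [fit_onpls()] model.
#' @param block_name Name of the block.
#' @return An object of class `vip_result` with elements `block`, `vip`
#'   (named vector), `ss` (per-component joint variance) and `weights`
#'   (N x A matrix).
#' @export
compute_vip <- function(model, block_name) {
  bl <- model$blocks[[block_name]]
  if (is.null(bl)) stop("unknown block '", block_name, "'")
  cmps <- bl$components
  globals <- cmps[vapply(cmps, `[[`, character(1), "kind") == "global"]
  if (length(globals) == 0) stop("model has no global components")
  W <- vapply(globals, `[[`, numeric(length(bl$variable_ids)), "w")
  W <- matrix(W, ncol = length(globals))
  ss <- vapply(globals, function(cmp) sum(cmp$t^2) * sum(cmp$p^2),
               numeric(1))
  if (sum(ss) == 0) {
    stop("no joint variance in block '", block_name, "'")
  }
  N <- length(bl$variable_ids)
  vip <- sqrt(N * drop(W^2 %*% ss) / sum(ss))
  structure(list(block = block_name,
                 vip = stats::setNames(vip, bl$variable_ids),
                 ss = ss, weights = W),
            class = "vip_result")
}

#' Jackknife standard error of a vector of leave-one-out estimates
#'
#' `var = ((M - 1) / M) * sum_m (theta_(-m) - mean(theta))^2`, the standard
#' delete-one jackknife variance; the returned value is its square root.
#'
#' @param thetas Numeric vector of M leave-one-out estimates (`NA`s dropped).
#' @return The jackknife standard error.
#' @export
jackknife_se <- function(thetas) {
  thetas <- thetas[!is.na(thetas)]
  m <- length(thetas)
  if (m < 2) return(NA_real_)
  sqrt((m - 1) / m * sum((thetas - mean(thetas))^2))
}

#' Jackknife confidence intervals for global loadings
#'
#' Refits the model on every leave-one-sample-out subset of the data (the
#' biological plants are the resampling unit) and attaches a confidence
#' interval to each variable's loading on its dominant globally joint
#' component (the component with the largest absolute loading in the
#' full-data model). How preprocessing is handled inside a resample is
#' controlled by `resample_preprocess`:
#'
#' * `"reference"`: reference scaling is recomputed on the remaining
#'   reference samples (falling back, with a message, to the full-data
#'   reference statistics if fewer than two remain). The intervals then also
#'   carry the uncertainty of the reference statistics themselves, which
#'   with very few reference samples (2 left out of 3) dominates everything
#'   else.
#' * `"center"`: each resample is column-recentred; for models fitted on
#'   centred (unscaled) matrices.
#' * `"none"`: the resample keeps the training preprocessing and the model
#'   is refit on the row subset as-is -- the convention of the PLS
#'   jackknife literature, and the mode the full pipeline uses on
#'   reference-scaled data.
#' Every resample's global components are aligned to the full model by an
#' orthogonal Procrustes rotation of the loading matrix (which reduces to a
#' sign flip by the loading inner product when there is a single component;
#' with several components of comparable strength it also removes the
#' rotational indeterminacy of the joint subspace, without which every
#' loading's resampling variance would be inflated by arbitrary rotations).
#' The interval is `theta_full +/- t_{(1+conf)/2, M-1} * SE_jack`.
#'
#' @param dataset A [multiblock_dataset()]. With
#'   `resample_preprocess = "reference"` the blocks must not yet be
#'   reference-scaled.
#' @param spec An [onpls_spec()].
#' @param params [preprocess_params()] used when rescaling.
#' @param resample_preprocess `"reference"`, `"center"` or `"none"` (see
#'   above; default `"reference"`).
#' @param conf_level Confidence level (default 0.95).
#' @param model Optional precomputed full-data model (must be the fit of this
#'   dataset after the same preprocessing); refitted if `NULL`.
#' @return An object of class `jackknife_result`: a named list of per-block
#'   data frames with columns `variable_id`, `component`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `n_resamples`, plus attributes `M`, `conf_level`
#'   and `model` (the full-data model used).
#' @export
jackknife <- function(dataset, spec = onpls_spec(),
                      params = preprocess_params(),
                      resample_preprocess = c("reference", "center", "none"),
                      conf_level = 0.95, model = NULL) {
  resample_preprocess <- match.arg(resample_preprocess)
  design <- dataset$design
  M <- length(design$sample_ids)
  if (M < 3) stop("jackknife needs at least 3 samples")
  if (resample_preprocess == "reference" &&
      any(vapply(dataset$blocks, function(b) b$state, character(1)) ==
          "wt_scaled")) {
    stop("with resample_preprocess = \"reference\" pass the dataset from ",
         "before reference scaling; scaling is redone inside every resample")
  }

  prep_full <- function(ds) {
    blocks <- switch(
      resample_preprocess,
      reference = lapply(ds$blocks, function(b) {
        suppressWarnings(wt_reference_scale(b, ds$design, params))
      }),
      center = lapply(ds$blocks, function(b) {
        v <- sweep(b$values, 2, colMeans(b$values), "-")
        set_block_values(b, v, state = "centered")
      }),
      none = ds$blocks)
    multiblock_dataset(blocks, ds$design)
  }

  full_model <- if (is.null(model)) {
    fit_onpls(prep_full(dataset), spec)
  } else {
    model
  }

  loading_matrix <- function(m, b) {
    cmps <- m$blocks[[b]]$components
    g <- cmps[vapply(cmps, `[[`, character(1), "kind") == "global"]
    P <- vapply(g, `[[`, numeric(length(m$blocks[[b]]$variable_ids)), "p")
    P <- matrix(P, ncol = length(g),
                dimnames = list(m$blocks[[b]]$variable_ids,
                                paste0("global", seq_along(g))))
    P
  }
  nms <- sort(names(dataset$blocks))
  P_full <- stats::setNames(lapply(nms, function(b) {
    loading_matrix(full_model, b)
  }), nms)

  subdesign <- function(drop_id) {
    keep <- setdiff(design$sample_ids, drop_id)
    # resample designs bypass the full-design invariants on purpose: a
    # leave-one-out subset may lose a genotype or drop the reference below
    # two samples and must still be fittable
    structure(list(sample_ids = keep,
                   genotype_of = design$genotype_of[keep],
                   reference_genotype = design$reference_genotype,
                   replicate_index = design$replicate_index[keep]),
              class = "sample_design")
  }

  # per block: variables x M matrix of resampled dominant loadings, by comp
  thetas <- stats::setNames(lapply(nms, function(b) {
    array(NA_real_, dim = c(dim(P_full[[b]]), M),
          dimnames = c(dimnames(P_full[[b]]), list(design$sample_ids)))
  }), nms)

  for (m_i in seq_len(M)) {
    drop_id <- design$sample_ids[m_i]
    keep <- setdiff(design$sample_ids, drop_id)
    sub_des <- subdesign(drop_id)
    sub_blocks <- lapply(dataset$blocks, function(b) {
      set_block_values(b, b$values[keep, , drop = FALSE])
    })
    if (resample_preprocess == "reference") {
      ref_left <- sum(sub_des$genotype_of[keep] ==
                        design$reference_genotype)
      if (ref_left < 2) {
        # fall back to full-data reference statistics for this resample
        message("resample without '", drop_id, "': fewer than 2 reference ",
                "samples left; using full-data reference statistics")
        sub_blocks <- lapply(seq_along(sub_blocks), function(k) {
          b <- sub_blocks[[k]]
          full_scaled <- suppressWarnings(
            wt_reference_scale(dataset$blocks[[k]], design, params))
          kept_vars <- colnames(full_scaled$values)
          set_block_values(
            b, full_scaled$values[keep, kept_vars, drop = FALSE],
            state = "wt_scaled")
        })
      } else {
        sub_blocks <- lapply(sub_blocks, function(b) {
          suppressWarnings(wt_reference_scale(b, sub_des, params))
        })
      }
    } else if (resample_preprocess == "center") {
      sub_blocks <- lapply(sub_blocks, function(b) {
        v <- sweep(b$values, 2, colMeans(b$values), "-")
        set_block_values(b, v, state = "centered")
      })
    }
    sub_ds <- multiblock_dataset(sub_blocks, sub_des)
    sub_model <- suppressWarnings(fit_onpls(sub_ds, spec))
    for (b in nms) {
      P_sub <- loading_matrix(sub_model, b)
      common <- intersect(rownames(P_sub), rownames(P_full[[b]]))
      A <- P_sub[common, , drop = FALSE]
      B <- P_full[[b]][common, , drop = FALSE]
      na <- min(ncol(A), ncol(B))
      # orthogonal Procrustes alignment of the resample's components onto
      # the full model; the single-component case reduces to a sign flip
      sv <- svd(crossprod(A[, seq_len(na), drop = FALSE],
                          B[, seq_len(na), drop = FALSE]))
      Q <- sv$u %*% t(sv$v)
      thetas[[b]][common, seq_len(na), m_i] <-
        A[, seq_len(na), drop = FALSE] %*% Q
    }
  }

  tcrit <- stats::qt((1 + conf_level) / 2, df = M - 1)
  out <- stats::setNames(lapply(nms, function(b) {
    P <- P_full[[b]]
    dominant <- max.col(abs(P), ties.method = "first")
    est <- P[cbind(seq_len(nrow(P)), dominant)]
    se <- vapply(seq_len(nrow(P)), function(k) {
      jackknife_se(thetas[[b]][k, dominant[k], ])
    }, numeric(1))
    n_res <- vapply(seq_len(nrow(P)), function(k) {
      sum(!is.na(thetas[[b]][k, dominant[k], ]))
    }, integer(1))
    data.frame(variable_id = rownames(P),
               component = dominant,
               estimate = est,
               se = se,
               ci_low = est - tcrit * se,
               ci_high = est + tcrit * se,
               n_resamples = n_res,
               stringsAsFactors = FALSE, row.names = NULL)
  }), nms)
  structure(out, class = "jackknife_result", M = M,
            conf_level = conf_level, model = full_model)
}

#' Call significant variables from VIP and jackknife evidence
#'
#' A variable is significant when its VIP strictly exceeds `threshold`
#' (default 0.5) **and** its jackknife confidence interval excludes zero.
#'
#' @param vip A [compute_vip()] result.
#' @param jk A [jackknife()] result (its entry for the same block is used).
#' @param threshold VIP threshold; strict inequality (default 0.5).
#' @return A `significance_table` data frame with columns `variable_id`,
#'   `block`, `vip`, `estimate`, `ci_low`, `ci_high`, `significant`.
#' @export
call_significance <- function(vip, jk, threshold = 0.5) {
  stopifnot(inherits(vip, "vip_result"), inherits(jk, "jackknife_result"))
  jt <- jk[[vip$block]]
  if (is.null(jt)) stop("jackknife result has no block '", vip$block, "'")
  if (!setequal(jt$variable_id, names(vip$vip))) {
    stop("VIP and jackknife results cover different variables for block '",
         vip$block, "'")
  }
  jt <- jt[match(names(vip$vip), jt$variable_id), ]
  excl0 <- !is.na(jt$ci_low) & !is.na(jt$ci_high) &
    (jt$ci_low > 0 | jt$ci_high < 0)
  out <- data.frame(variable_id = names(vip$vip),
                    block = vip$block,
                    vip = unname(vip$vip),
                    estimate = jt$estimate,
                    ci_low = jt$ci_low,
                    ci_high = jt$ci_high,
                    significant = unname(vip$vip) > threshold & excl0,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("significance_table", "data.frame")
  out
}

#' Attach per-line direction arrows to a significance table
#'
#' For every significant variable and every non-reference genotype the
#' direction is the sign of the genotype's mean reference-scaled value: `+1`
#' (up in the transgenic line relative to the reference), `-1` (down) or `0`
#' (rendered "-") for non-significant rows. The per-genotype means are also
#' stored (columns `mean_<genotype>`) for the continuous export modes.
#'
#' @param block A reference-scaled [omics_block()] (`state = "wt_scaled"`).
#' @param design A [sample_design()].
#' @param table A `significance_table` from [call_significance()].
#' @return The table with added `dir_<genotype>` and `mean_<genotype>`
#'   columns.
#' @export
direction_arrows <- function(block, design, table) {
  if (block$state != "wt_scaled") {
    stop("direction arrows require a reference-scaled block (state ",
         "'wt_scaled'); got '", block$state, "'")
  }
  v <- block$values
  miss <- setdiff(table$variable_id, colnames(v))
  if (length(miss) > 0) {
    stop("variables absent from block '", block$name, "': ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  geno <- design$genotype_of[design$sample_ids]
  lines <- non_reference_genotypes(design)
  for (g in lines) {
    rows <- which(geno == g)
    if (length(rows) == 0) stop("genotype '", g, "' has no samples")
    mg <- colMeans(v[rows, table$variable_id, drop = FALSE], na.rm = TRUE)
    dir <- ifelse(table$significant, sign(mg), 0)
    if (any(table$significant & mg == 0)) {
      warning("variable(s) with exactly zero mean in genotype '", g,
              "'; direction set to 0")
    }
    table[[paste0("dir_", g)]] <- as.integer(dir)
    table[[paste0("mean_", g)]] <- unname(mg)
  }
  table
}

#' Fraction of significant proteins coregulated with their transcript
#'
#' Over all (significant protein, transgenic line) pairs, the fraction whose
#' mapped transcript is also significant with the same direction in that
#' line.
#'
#' @param protein_table A `significance_table` with direction columns
#'   ([direction_arrows()]).
#' @param transcript_table Likewise for the transcript block.
#' @param mapping Named character vector: protein id -> transcript id; must
#'   cover every protein row.
#' @return A single fraction in `[0, 1]` (`NA` with a warning when no protein
#'   is significant).
#' @export
coregulation_fraction <- function(protein_table, transcript_table, mapping) {
  if (nrow(protein_table) == 0) stop("empty protein table")
  unmapped <- setdiff(protein_table$variable_id, names(mapping))
  if (length(unmapped) > 0) {
    stop("protein(s) without a transcript mapping: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  }
  dir_cols <- grep("^dir_", colnames(protein_table), value = TRUE)
  if (length(dir_cols) == 0 ||
      !all(dir_cols %in% colnames(transcript_table))) {
    stop("both tables need matching dir_<line> columns; run ",
         "direction_arrows() first")
  }
  sig_prot <- protein_table[protein_table$significant, , drop = FALSE]
  n_pairs <- nrow(sig_prot) * length(dir_cols)
  if (n_pairs == 0) {
    warning("no significant proteins; coregulation fraction undefined")
    return(NA_real_)
  }
  tr_idx <- match(mapping[sig_prot$variable_id],
                  transcript_table$variable_id)
  concordant <- 0L
  for (dc in dir_cols) {
    pd <- sig_prot[[dc]]
    td <- transcript_table[[dc]][tr_idx]
    ts <- transcript_table$significant[tr_idx]
    ok <- !is.na(ts) & ts & !is.na(td) & td == pd & pd != 0
    concordant <- concordant + sum(ok)
  }
  concordant / n_pairs
}
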