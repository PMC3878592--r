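#' Preprocessing parameters
#'
#' @param censor_threshold Censoring floor on the log2 scale; intensities
#'   below it are raised to it (default 7, the conventional cutoff for
#'   non-expressed genes on normalised two-colour arrays).
#' @param log_offset Non-negative constant added before the log2 transform
#'   (default 0).
#' @param min_reference_sd Smallest admissible reference standard deviation;
#'   variables below it are dropped during reference scaling (default 1e-12).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(censor_threshold = 7, log_offset = 0,
                              min_reference_sd = 1e-12) {
  stopifnot(is.finite(censor_threshold), log_offset >= 0,
            min_reference_sd > 0)
  structure(list(censor_threshold = censor_threshold,
                 log_offset = log_offset,
                 min_reference_sd = min_reference_sd),
            class = "preprocess_params")
}

#' Log2-transform a raw block
#'
#' Each entry `x` becomes `log2(x + log_offset)`; missing entries pass
#' through. The block must be in `raw` state and all finite entries plus the
#' offset must be strictly positive.
#'
#' @param block An [omics_block()] with `state = "raw"`.
#' @param params A [preprocess_params()].
#' @return The transformed block with `state = "log2"`.
#' @export
log2_transform <- function(block, params = preprocess_params()) {
  if (block$state != "raw") {
    stop("log2_transform expects a raw block; got state '", block$state, "'")
  }
  v <- block$values
  bad <- which(!is.na(v) & v + params$log_offset <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(utils::head(bad, 10), 1, function(ij) {
      paste0("(", rownames(v)[ij[1]], ", ", colnames(v)[ij[2]], ")")
    })
    stop("non-positive entries cannot be log2-transformed with offset ",
         params$log_offset, ": ", paste(cells, collapse = ", "),
         if (nrow(bad) > 10) " ..." else "")
  }
  set_block_values(block, log2(v + params$log_offset), state = "log2")
}

#' Censor low intensities
#'
#' Raises every value below `censor_threshold` to the threshold, damping the
#' influence of non-expressed genes. Applies on the log2 scale; missing
#' entries pass through. Idempotent.
#'
#' @param block An [omics_block()] on the log2 scale (`state` `"log2"` or
#'   `"combined"`).
#' @param params A [preprocess_params()].
#' @return The censored block (state unchanged).
#' @export
censor_low <- function(block, params = preprocess_params()) {
  if (!block$state %in% c("log2", "combined")) {
    stop("censor_low expects a log2-scale block; got state '",
         block$state, "'")
  }
  v <- block$values
  v[!is.na(v) & v < params$censor_threshold] <- params$censor_threshold
  set_block_values(block, v)
}

#' Combine technical (dye-swap) replicates into one row per sample
#'
#' For every biological sample the listed replicate rows are averaged per
#' variable, ignoring missing values; a variable missing in every replicate
#' stays missing. The result has one row per sample, in `replicate_map`
#' order, and is invariant to the order of replicate labels.
#'
#' @param block An [omics_block()] whose rows are technical replicates.
#' @param replicate_map Named list: sample id -> character vector of replicate
#'   row labels present in the block.
#' @return An [omics_block()] with `state = "combined"`.
#' @export
combine_dye_swap <- function(block, replicate_map) {
  if (is.null(names(replicate_map)) || any(names(replicate_map) == "")) {
    stop("`replicate_map` must be a named list (sample id -> replicate rows)")
  }
  v <- block$values
  all_labels <- unlist(replicate_map, use.names = FALSE)
  absent <- setdiff(all_labels, rownames(v))
  if (length(absent) > 0) {
    stop("replicate row(s) absent from block '", block$name, "': ",
         paste(absent, collapse = ", "))
  }
  if (any(lengths(replicate_map) < 1)) {
    stop("every sample needs at least one replicate row")
  }
  out <- t(vapply(replicate_map, function(rows) {
    sub <- v[rows, , drop = FALSE]
    m <- colMeans(sub, na.rm = TRUE)
    m[colSums(!is.na(sub)) == 0] <- NA_real_
    m
  }, numeric(ncol(v))))
  rownames(out) <- names(replicate_map)
  colnames(out) <- colnames(v)
  set_block_values(block, out, state = "combined")
}

#' Center each sample (row) at zero
#'
#' Subtracts from every row its mean over observed entries; missing entries
#' pass through. A row with no observed entry is an error.
#'
#' @param block An [omics_block()] (any state before `wt_scaled`).
#' @return The block with `state = "centered"`.
#' @export
center_per_sample <- function(block) {
  if (block$state == "wt_scaled") {
    stop("block is already reference-scaled; centering would be meaningless")
  }
  v <- block$values
  nobs <- rowSums(!is.na(v))
  if (any(nobs == 0)) {
    stop("row(s) entirely missing in block '", block$name, "': ",
         paste(rownames(v)[nobs == 0], collapse = ", "))
  }
  m <- rowMeans(v, na.rm = TRUE)
  set_block_values(block, v - m, state = "centered")
}

#' Scale all samples by reference-genotype statistics
#'
#' For every variable `j` the mean and standard deviation (n-1 denominator)
#' over the reference-genotype samples are computed, and every sample's value
#' is standardised as `(x - mean_ref) / sd_ref` -- the reference genotype
#' becomes the common origin across platforms, so after scaling the reference
#' rows of every retained variable have mean 0 and standard deviation 1.
#' Variables with fewer than two observed reference values, or a reference
#' standard deviation below `min_reference_sd`, are dropped with a warning;
#' the dropped ids and reasons are attached as attribute `"dropped"`.
#'
#' @param block An [omics_block()] whose rows match the design's sample order.
#' @param design A [sample_design()].
#' @param params A [preprocess_params()].
#' @return The scaled block with `state = "wt_scaled"`.
#' @export
wt_reference_scale <- function(block, design, params = preprocess_params()) {
  v <- block$values
  if (!identical(rownames(v), design$sample_ids)) {
    stop("block '", block$name, "' rows must match the design sample order; ",
         "run align_blocks() first")
  }
  ref_rows <- design$genotype_of[design$sample_ids] ==
    design$reference_genotype
  refs <- v[ref_rows, , drop = FALSE]
  n_obs <- colSums(!is.na(refs))
  mu <- colMeans(refs, na.rm = TRUE)
  sd_ref <- apply(refs, 2, stats::sd, na.rm = TRUE)
  reason <- rep(NA_character_, ncol(v))
  reason[n_obs < 2] <- "insufficient_reference_values"
  reason[is.na(reason) & sd_ref < params$min_reference_sd] <-
    "zero_reference_sd"
  drop <- !is.na(reason)
  if (any(drop)) {
    warning(sum(drop), " variable(s) dropped during reference scaling in ",
            "block '", block$name, "'")
  }
  keep <- which(!drop)
  z <- sweep(sweep(v[, keep, drop = FALSE], 2, mu[keep], "-"),
             2, sd_ref[keep], "/")
  out <- set_block_values(block, z, state = "wt_scaled")
  attr(out, "dropped") <- data.frame(
    variable_id = colnames(v)[drop],
    reason = reason[drop],
    stringsAsFactors = FALSE)
  out
}

#' Impute or drop missing values
#'
#' `variable_mean` replaces each missing entry by its variable's mean over
#' observed samples (variables observed nowhere are dropped with a warning);
#' `drop_variable` removes any variable with a missing entry. Imputed cell
#' positions are attached as attribute `"imputed"`.
#'
#' @param block An [omics_block()].
#' @param strategy `"variable_mean"` or `"drop_variable"`.
#' @return A complete block (no missing entries), same state.
#' @export
impute_missing <- function(block, strategy = c("variable_mean",
                                               "drop_variable")) {
  strategy <- match.arg(strategy)
  v <- block$values
  if (!anyNA(v)) return(block)
  if (strategy == "drop_variable") {
    keep <- colSums(is.na(v)) == 0
    out <- set_block_values(block, v[, keep, drop = FALSE])
    attr(out, "imputed") <- data.frame(sample_id = character(0),
                                       variable_id = character(0))
    return(out)
  }
  nobs <- colSums(!is.na(v))
  if (any(nobs == 0)) {
    warning(sum(nobs == 0), " all-missing variable(s) dropped in block '",
            block$name, "'")
    v <- v[, nobs > 0, drop = FALSE]
  }
  idx <- which(is.na(v), arr.ind = TRUE)
  mu <- colMeans(v, na.rm = TRUE)
  v[idx] <- mu[idx[, 2]]
  out <- set_block_values(block, v)
  attr(out, "imputed") <- data.frame(
    sample_id = rownames(v)[idx[, 1]],
    variable_id = colnames(v)[idx[, 2]],
    stringsAsFactors = FALSE)
  out
}
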