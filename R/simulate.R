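#' Specification of a synthetic multi-omic dataset
#'
#' The defaults emulate a three-genotype field-style design: 9 samples = a
#' reference genotype (`WT`) plus two transgenic lines, 3 biological
#' replicates each, measured on three platforms of 243, 243 and 61 variables.
#' The genotype effect lives in two globally joint components: on the first
#' both lines separate jointly from the reference (means 0 / 3 / 3), on the
#' second the two lines separate from each other (means 0 / -2 / 2). One
#' locally joint component is shared by the transcript and protein blocks and
#' each block carries one unique component.
#'
#' @param genotypes Named integer vector: genotype label -> replicate count.
#' @param reference Reference genotype label (first name by default).
#' @param block_dims Named integer vector of block sizes.
#' @param n_global Number of globally joint components.
#' @param global_genotype_means List (one per global component) of named
#'   numeric vectors: genotype -> mean score.
#' @param within_genotype_sd Within-genotype score noise `tau` (default 0.1).
#' @param local_parts List of `list(blocks = <names>, n = <count>)` entries
#'   (default one component shared by transcripts and proteins).
#' @param n_unique Unique components per block (single value, recycled).
#' @param signal_fraction Fraction of variables carrying each joint
#'   component's loading (default 0.1).
#' @param loading_scale Standard deviation of nonzero joint loadings
#'   (default 1).
#' @param min_abs_loading Magnitude floor of nonzero joint loadings, as a
#'   multiple of `loading_scale` (default 0.15): effect variables are
#'   guaranteed a detectable effect.
#' @param unique_loading_scale Standard deviation of the dense unique
#'   loadings (default 0.3, so the globally joint part dominates each block's
#'   variance as in real genotype-contrast data).
#' @param noise_sd I.i.d. Gaussian noise level `sigma` (default 0.2).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(genotypes = c(WT = 3L, LINE1 = 3L, LINE2 = 3L),
                     reference = names(genotypes)[1],
                     block_dims = c(transcripts = 243L, proteins = 243L,
                                    metabolites = 61L),
                     n_global = 2L,
                     global_genotype_means = list(
                       c(WT = 0, LINE1 = 3, LINE2 = 3),
                       c(WT = 0, LINE1 = -2, LINE2 = 2)),
                     within_genotype_sd = 0.1,
                     local_parts = list(
                       list(blocks = c("transcripts", "proteins"), n = 1L)),
                     n_unique = 1L,
                     signal_fraction = 0.1, loading_scale = 1,
                     min_abs_loading = 0.15, unique_loading_scale = 0.3,
                     noise_sd = 0.2, seed = 1L) {
  stopifnot(length(genotypes) >= 2, all(genotypes >= 1),
            !is.null(names(genotypes)), !is.null(names(block_dims)),
            length(block_dims) >= 2, all(block_dims >= 1),
            n_global >= 1, length(global_genotype_means) == n_global,
            within_genotype_sd >= 0, signal_fraction > 0,
            signal_fraction <= 1, loading_scale > 0, min_abs_loading >= 0,
            unique_loading_scale >= 0, noise_sd >= 0)
  M <- sum(genotypes)
  n_parts_max <- n_global +
    sum(vapply(local_parts, function(lp) as.integer(lp$n), integer(1))) +
    as.integer(n_unique)
  if (n_parts_max > M - 1) {
    stop("total number of components (", n_parts_max,
         ") exceeds M - 1 = ", M - 1)
  }
  structure(list(genotypes = genotypes, reference = reference,
                 block_dims = block_dims, n_global = as.integer(n_global),
                 global_genotype_means = global_genotype_means,
                 within_genotype_sd = within_genotype_sd,
                 local_parts = local_parts, n_unique = as.integer(n_unique),
                 signal_fraction = signal_fraction,
                 loading_scale = loading_scale,
                 min_abs_loading = min_abs_loading,
                 unique_loading_scale = unique_loading_scale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Large-model preset dimensions
#'
#' The all-variable-scale preset (14619 transcripts, 271 proteins, 386
#' metabolites) for performance testing; all other parameters keep the
#' defaults.
#'
#' @param ... Overrides forwarded to [sim_spec()].
#' @return A [sim_spec()].
#' @export
sim_spec_large <- function(...) {
  sim_spec(block_dims = c(transcripts = 14619L, proteins = 271L,
                          metabolites = 386L), ...)
}

draw_truncated_loadings <- function(n, scale, floor_abs) {
  x <- stats::rnorm(n, 0, scale)
  while (any(small <- abs(x) < floor_abs)) {
    x[small] <- stats::rnorm(sum(small), 0, scale)
  }
  x
}

#' Simulate a multi-block dataset with known ground truth
#'
#' Builds `X_i = sum_parts t p_i' + E_i` from genotype-structured global
#' scores, standard-normal local and unique scores, sparse joint loadings and
#' dense unique loadings. All scores are centred and mutually orthogonalised
#' at generation time, the sparse supports of a block's joint parts are
#' disjoint, and its unique loading is orthogonalised against them, so every
#' part's variance contribution is exactly separable and the generated
#' decomposition is the unique optimum a fitted model should recover. The
#' generator emits the exactly-centred matrices (state `"centered"`) plus,
#' when the reference rows have positive spread, a reference-scaled variant.
#'
#' @param spec A [sim_spec()].
#' @return A list of class `sim_result` with elements `dataset` (centred
#'   blocks), `dataset_scaled` (reference-scaled variant or `NULL` when the
#'   reference spread is zero), `truth` (scores, loadings, masks, variance
#'   fractions, WT-centred score variants) and `spec`.
#' @export
simulate_multiomics <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  geno_labels <- rep(names(spec$genotypes), spec$genotypes)
  M <- length(geno_labels)
  sample_ids <- paste0(geno_labels, "-",
                       unlist(lapply(spec$genotypes, seq_len)))
  design <- sample_design(sample_ids, geno_labels, spec$reference)
  bn <- names(spec$block_dims)

  # part bookkeeping: label + which blocks it touches
  parts <- list()
  for (a in seq_len(spec$n_global)) {
    parts[[paste0("global", a)]] <- bn
  }
  for (lp in spec$local_parts) {
    if (!all(lp$blocks %in% bn)) stop("local part names unknown block(s)")
    for (k in seq_len(as.integer(lp$n))) {
      parts[[paste0("local:", subset_key(lp$blocks),
                    if (lp$n > 1) paste0(":", k) else "")]] <- lp$blocks
    }
  }
  for (b in bn) {
    for (k in seq_len(spec$n_unique)) {
      parts[[paste0("unique:", b, if (spec$n_unique > 1)
        paste0(":", k) else "")]] <- b
    }
  }

  # scores: centred, then orthogonalised against all previous scores
  scores <- matrix(0, M, length(parts),
                   dimnames = list(sample_ids, names(parts)))
  for (k in seq_along(parts)) {
    lab <- names(parts)[k]
    if (startsWith(lab, "global")) {
      a <- as.integer(sub("global", "", lab))
      mu <- spec$global_genotype_means[[a]]
      if (!all(names(spec$genotypes) %in% names(mu))) {
        stop("global component ", a, " lacks a mean for some genotype")
      }
      t_k <- mu[geno_labels] + stats::rnorm(M, 0, spec$within_genotype_sd)
    } else {
      t_k <- stats::rnorm(M)
    }
    t_k <- t_k - mean(t_k)
    if (k > 1) {
      for (j in seq_len(k - 1)) {
        prev <- scores[, j]
        t_k <- t_k - sum(t_k * prev) / sum(prev * prev) * prev
      }
    }
    if (sqrt(sum(t_k^2)) < 1e-8) {
      stop("score orthogonalisation left a zero vector; ",
           "too many components for M = ", M, " samples")
    }
    scores[, k] <- t_k
  }

  loadings <- list()   # loadings[[block]][[part]]
  masks <- list()
  blocks <- list()
  noise_norm2 <- stats::setNames(numeric(length(bn)), bn)
  for (b in bn) {
    N <- spec$block_dims[[b]]
    vids <- sprintf("%s_%04d", b, seq_len(N))
    joint_parts <- names(parts)[vapply(parts, function(p) {
      b %in% p && length(p) > 1
    }, logical(1))]
    unique_parts <- names(parts)[vapply(parts, function(p) {
      identical(p, b)
    }, logical(1))]
    n_sig <- ceiling(spec$signal_fraction * N)
    if (n_sig * length(joint_parts) > N) {
      stop("block '", b, "': disjoint supports need ",
           n_sig * length(joint_parts), " variables but only ", N, " exist")
    }
    P <- stats::setNames(vector("list", length(parts)), names(parts))
    avail <- seq_len(N)
    for (lab in joint_parts) {
      idx <- if (length(avail) == 1) avail else sample(avail, n_sig)
      avail <- setdiff(avail, idx)
      p <- numeric(N)
      p[idx] <- draw_truncated_loadings(
        n_sig, spec$loading_scale,
        spec$min_abs_loading * spec$loading_scale)
      P[[lab]] <- p
    }
    for (lab in unique_parts) {
      p <- stats::rnorm(N, 0, spec$unique_loading_scale)
      for (jl in joint_parts) {       # keep unique structure separable
        q <- P[[jl]]
        p <- p - sum(p * q) / sum(q * q) * q
      }
      P[[lab]] <- p
    }
    X <- matrix(0, M, N, dimnames = list(sample_ids, vids))
    for (lab in c(joint_parts, unique_parts)) {
      X <- X + tcrossprod(scores[, lab], P[[lab]])
    }
    E <- matrix(stats::rnorm(M * N, 0, spec$noise_sd), M, N)
    noise_norm2[b] <- frob2(E)
    X <- X + E
    loadings[[b]] <- lapply(P, function(p) {
      if (is.null(p)) NULL else stats::setNames(p, vids)
    })
    global_labels <- paste0("global", seq_len(spec$n_global))
    masks[[b]] <- stats::setNames(
      Reduce(`|`, lapply(global_labels, function(lab) P[[lab]] != 0)), vids)
    blocks[[b]] <- omics_block(X, name = b, platform = "synthetic",
                               state = "centered")
  }

  # exact per-part variance fractions: scores are mutually orthogonal and a
  # block's loadings are separable, so parts + noise account for everything
  var_fractions <- lapply(bn, function(b) {
    contrib <- vapply(names(parts), function(lab) {
      p <- loadings[[b]][[lab]]
      if (is.null(p) || !(b %in% parts[[lab]])) 0
      else sum(scores[, lab]^2) * sum(p^2)
    }, numeric(1))
    tot <- sum(contrib) + noise_norm2[b]
    c(contrib / tot, noise = unname(noise_norm2[b] / tot))
  })
  names(var_fractions) <- bn

  ref_rows <- geno_labels == spec$reference
  scores_wt <- sweep(scores, 2, colMeans(scores[ref_rows, , drop = FALSE]))

  dataset <- multiblock_dataset(blocks, design)
  dataset_scaled <- tryCatch({
    scaled <- lapply(blocks, wt_reference_scale, design = design)
    if (any(vapply(scaled, function(b) ncol(b$values), integer(1)) == 0)) {
      NULL
    } else {
      multiblock_dataset(scaled, design)
    }
  }, warning = function(w) NULL, error = function(e) NULL)

  truth <- list(parts = parts, scores = scores, scores_wt = scores_wt,
                loadings = loadings, masks = masks,
                noise_norm2 = noise_norm2, var_fractions = var_fractions,
                global_labels = paste0("global", seq_len(spec$n_global)))
  structure(list(dataset = dataset, dataset_scaled = dataset_scaled,
                 truth = truth, spec = spec, design = design),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Synthetic multi-omic dataset (seed", x$spec$seed, ")\n")
  print(x$dataset)
  invisible(x)
}

#' Principal angles between two column spaces
#'
#' Uses the combined cosine/sine formulation: large angles come from the
#' singular values of `Qa' Qb` via `acos`, small ones from the singular
#' values of `Qb - Qa (Qa' Qb)` via `asin` -- `acos` alone cannot resolve
#' angles below about `1e-8` because of floating-point cancellation near 1.
#'
#' @param A,B Matrices with the same number of rows.
#' @return Numeric vector of principal angles in radians (length =
#'   min(rank(A), rank(B))), in increasing order.
#' @export
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  C <- crossprod(qa, qb)
  cosines <- svd(C, nu = 0, nv = 0)$d          # decreasing
  sines <- svd(qb - qa %*% C, nu = 0, nv = 0)$d
  k <- length(cosines)
  sines <- rev(sines[seq_len(k)])              # align with cosine order
  ifelse(cosines^2 < 0.5,
         acos(pmin(pmax(cosines, -1), 1)),
         asin(pmin(pmax(sines, 0), 1)))
}

#' Score a fitted model against the generator's ground truth
#'
#' Reports (a) the principal angles between the true and estimated global
#' score subspaces (the WT-centred true scores are used automatically when
#' the model was fitted on the reference-scaled variant), (b) the absolute
#' error of every variance-decomposition entry against the true fractions
#' (exact in the generation space; reported only there), and (c) when
#' significance tables are supplied, the confusion of the significance calls
#' against the generator's signal masks.
#'
#' @param model A model fitted on the simulated dataset.
#' @param truth The `truth` element of a [simulate_multiomics()] result (or
#'   the full `sim_result`).
#' @param selection Optional named list (block -> `significance_table`).
#' @return A list of class `recovery_report` with elements `angles`,
#'   `r2_errors` (or `NULL` in the scaled space) and `confusion`.
#' @export
evaluate_recovery <- function(model, truth, selection = NULL) {
  if (inherits(truth, "sim_result")) truth <- truth$truth
  est <- global_scores(model)
  scaled <- any(model$state == "wt_scaled")
  true_scores <- if (scaled) truth$scores_wt else truth$scores
  if (nrow(est) != nrow(true_scores)) {
    stop("sample count mismatch between model (", nrow(est),
         ") and truth (", nrow(true_scores), ")")
  }
  angles <- principal_angles(true_scores[, truth$global_labels, drop = FALSE],
                             est)

  r2_errors <- NULL
  if (!scaled) {
    r2 <- model$r2
    r2_errors <- do.call(rbind, lapply(seq_len(nrow(r2)), function(i) {
      b <- r2$block[i]
      vf <- truth$var_fractions[[b]]
      true_global <- sum(vf[truth$global_labels])
      is_local <- startsWith(names(vf), "local:")
      touches <- vapply(names(vf)[is_local], function(lab) {
        b %in% truth$parts[[lab]]
      }, logical(1))
      true_local <- sum(vf[is_local][touches])
      is_unique <- startsWith(names(vf), paste0("unique:", b))
      true_unique <- sum(vf[is_unique])
      fit_local <- sum(unlist(r2[i, startsWith(colnames(r2), "local:")]))
      data.frame(block = b,
                 global = abs(r2$global[i] - true_global),
                 local = abs(fit_local - true_local),
                 unique = abs(r2$unique[i] - true_unique),
                 residual = abs(r2$residual[i] - vf[["noise"]]),
                 stringsAsFactors = FALSE)
    }))
  }

  confusion <- NULL
  if (!is.null(selection)) {
    tp <- fp <- tn <- fn <- 0L
    for (b in names(selection)) {
      mask <- truth$masks[[b]]
      tab <- selection[[b]]
      called <- stats::setNames(tab$significant, tab$variable_id)
      common <- intersect(names(mask), names(called))
      m <- mask[common]
      s <- called[common]
      tp <- tp + sum(m & s); fn <- fn + sum(m & !s)
      fp <- fp + sum(!m & s); tn <- tn + sum(!m & !s)
    }
    confusion <- list(tp = tp, fp = fp, tn = tn, fn = fn,
                      sensitivity = tp / (tp + fn),
                      specificity = tn / (tn + fp))
  }
  structure(list(angles = angles, r2_errors = r2_errors,
                 confusion = confusion, space = if (scaled)
                   "wt_scaled" else "centered"),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery report (", x$space, " space)\n", sep = "")
  cat("  max principal angle:", format(max(x$angles), digits = 4), "rad\n")
  if (!is.null(x$r2_errors)) {
    cat("  max |R2 error|:",
        format(max(as.matrix(x$r2_errors[, -1])), digits = 4), "\n")
  }
  if (!is.null(x$confusion)) {
    cat(sprintf("  selection: sensitivity %.3f, specificity %.3f\n",
                x$confusion$sensitivity, x$confusion$specificity))
  }
  invisible(x)
}
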