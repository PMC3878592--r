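#' OnPLS model specification
#'
#' @param n_global Number of globally joint components shared by all blocks
#'   (default 2, the usual choice for a genotype contrast with two transgenic
#'   lines against a reference).
#' @param n_local Named list mapping a block-subset key (sorted block names
#'   joined by `+`, e.g. `"proteins+transcripts"`) to a locally joint
#'   component count, or the string `"auto"`. Subsets not listed get 0.
#' @param n_unique Unique component count per block: a single value recycled
#'   over blocks, or a named vector/list per block name; each entry an
#'   integer >= 0 or `"auto"`.
#' @param filter_orthogonal Interleave O2PLS-style orthogonal filtering with
#'   the globally joint extraction (default `TRUE`).
#' @param ortho_var_ratio Minimum fraction of the current residual variance an
#'   orthogonal-filter component must capture to be kept (default 0.05).
#' @param tol Convergence tolerance on the maximal weight change per
#'   alternating-least-squares cycle (default 1e-9).
#' @param max_iter Maximum ALS cycles per component (default 500).
#' @param auto_var_ratio Variance-ratio floor, relative to each block's
#'   preprocessed squared Frobenius norm, used by `"auto"` component counts
#'   (default 0.05).
#' @return A list of class `onpls_spec`.
#' @export
onpls_spec <- function(n_global = 2L, n_local = list(), n_unique = 0L,
                       filter_orthogonal = TRUE, ortho_var_ratio = 0.05,
                       tol = 1e-9, max_iter = 500L, auto_var_ratio = 0.05) {
  stopifnot(n_global >= 1, ortho_var_ratio > 0, ortho_var_ratio < 1,
            tol > 0, max_iter >= 1, auto_var_ratio > 0)
  structure(list(n_global = as.integer(n_global), n_local = as.list(n_local),
                 n_unique = n_unique,
                 filter_orthogonal = isTRUE(filter_orthogonal),
                 ortho_var_ratio = ortho_var_ratio, tol = tol,
                 max_iter = as.integer(max_iter),
                 auto_var_ratio = auto_var_ratio),
            class = "onpls_spec")
}

#' Canonical key of a block subset: sorted names joined by "+"
#' @param block_names Character vector of block names.
#' @return A single string.
#' @export
subset_key <- function(block_names) paste(sort(block_names), collapse = "+")

frob2 <- function(x) sum(x * x)

#' Extract one consensus component across a set of blocks
#'
#' Maximises the sum of pairwise score covariances
#' `J = sum_{i<j} (X_i w_i)' (X_j w_j)` over unit-norm weight vectors by
#' cyclic alternating least squares: each weight is updated to the normalised
#' back-projection of the other blocks' summed scores,
#' `w_i <- normalise(X_i' sum_{j != i} X_j w_j)`, which makes `J`
#' non-decreasing over cycles. Weights are initialised from the leading left
#' singular vector of the concatenated cross-covariances
#' `[X_i' X_j]_{j != i}` (computed through the M x M Gram matrix of the other
#' blocks, which is exact and cheap for tall blocks). After convergence the
#' signs are fixed so that the largest-magnitude element of the first block's
#' weight (blocks taken in sorted name order) is positive and every other
#' block's score has non-negative inner product with that reference score.
#'
#' @param blocks_residual Named list (>= 2) of column-centred residual
#'   matrices sharing the same rows.
#' @param tol Convergence tolerance on the maximal weight change per cycle.
#' @param max_iter Maximum number of cycles.
#' @return A list with elements `blocks` (named list of `w`, `t`, `p` per
#'   block), `objective` (the `J` trajectory, one value per cycle),
#'   `iterations` and `converged`.
#' @export
extract_consensus_component <- function(blocks_residual, tol = 1e-9,
                                        max_iter = 500L) {
  if (length(blocks_residual) < 2) stop("need at least 2 blocks")
  if (is.null(names(blocks_residual)) || any(names(blocks_residual) == "")) {
    stop("`blocks_residual` must be a named list")
  }
  nms <- sort(names(blocks_residual))
  Xs <- blocks_residual[nms]
  M <- nrow(Xs[[1]])
  if (M < 2) stop("need at least 2 samples")
  norms <- vapply(Xs, function(x) sqrt(frob2(x)), numeric(1))
  if (any(norms == 0)) {
    stop("no extractable variation: block '", nms[which(norms == 0)[1]],
         "' has an all-zero residual")
  }
  K <- length(Xs)
  scale_pairs <- 0
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    scale_pairs <- scale_pairs + norms[i] * norms[j]
  }

  # init: leading left singular vector of [X_i' X_j]_{j != i}, via the
  # M x M Gram matrix G = sum_{j != i} X_j X_j' = L L'
  W <- vector("list", K)
  for (i in seq_len(K)) {
    G <- matrix(0, M, M)
    for (j in seq_len(K)) if (j != i) G <- G + tcrossprod(Xs[[j]])
    eg <- eigen(G, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    L_t <- sqrt(d) * t(eg$vectors)           # L' such that G = L L'
    sv <- svd(L_t %*% Xs[[i]], nu = 0, nv = 1)
    w <- sv$v[, 1]
    nw <- sqrt(sum(w^2))
    if (nw == 0) w <- rep(1 / sqrt(ncol(Xs[[i]])), ncol(Xs[[i]]))
    W[[i]] <- w / sqrt(sum(w^2))
  }
  Ts <- lapply(seq_len(K), function(i) drop(Xs[[i]] %*% W[[i]]))

  objective_of <- function(Ts) {
    J <- 0
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      J <- J + sum(Ts[[i]] * Ts[[j]])
    }
    J
  }
  traj <- objective_of(Ts)
  converged <- FALSE
  iter <- 0L
  degenerate <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    delta <- 0
    for (i in seq_len(K)) {
      s <- Reduce(`+`, Ts[-i])
      wnew <- drop(crossprod(Xs[[i]], s))
      nw <- sqrt(sum(wnew^2))
      if (nw <= .Machine$double.eps * norms[i]) {
        degenerate <- TRUE
        next
      }
      wnew <- wnew / nw
      delta <- max(delta, sqrt(sum((wnew - W[[i]])^2)))
      W[[i]] <- wnew
      Ts[[i]] <- drop(Xs[[i]] %*% wnew)
    }
    traj <- c(traj, objective_of(Ts))
    if (degenerate || delta < tol) {
      converged <- !degenerate
      break
    }
  }
  if (!converged && !degenerate && iter >= max_iter) {
    warning("consensus extraction did not converge in ", max_iter,
            " iterations (last weight change above tol); returning last ",
            "iterate")
  }
  J_final <- traj[length(traj)]
  if (scale_pairs > 0 && abs(J_final) <= 1e-12 * scale_pairs) {
    warning("no appreciable joint variation between the blocks ",
            "(consensus objective ~ 0)")
  }

  # sign convention
  ref <- 1L
  wr <- W[[ref]]
  if (wr[which.max(abs(wr))] < 0) {
    W[[ref]] <- -W[[ref]]
    Ts[[ref]] <- -Ts[[ref]]
  }
  for (i in seq_len(K)) {
    if (i != ref && sum(Ts[[i]] * Ts[[ref]]) < 0) {
      W[[i]] <- -W[[i]]
      Ts[[i]] <- -Ts[[i]]
    }
  }
  out <- lapply(seq_len(K), function(i) {
    t <- Ts[[i]]
    tt <- sum(t^2)
    p <- if (tt > 0) drop(crossprod(Xs[[i]], t)) / tt else rep(0, ncol(Xs[[i]]))
    list(w = stats::setNames(W[[i]], colnames(Xs[[i]])),
         t = stats::setNames(t, rownames(Xs[[i]])),
         p = stats::setNames(p, colnames(Xs[[i]])))
  })
  names(out) <- nms
  list(blocks = out, objective = traj, iterations = iter,
       converged = converged || degenerate)
}

#' Extract an orthogonal (unique) candidate component from one block
#'
#' Given a joint weight `w` and the corresponding loading `p` of a block, the
#' part of `p` orthogonal to `w`, `w_o = p - (w'p) w`, points at systematic
#' within-block variation not aligned with the joint direction (the O2PLS
#' split of a block into joint and unique variation). A candidate is kept
#' only if two conditions hold, both governed by `ortho_var_ratio`: the
#' orthogonal part must carry at least that share of the loading's squared
#' norm (`||w_o||^2 / ||p||^2`) -- genuine orthogonal structure shows up as a
#' large share, while mere noise misalignment between weight and loading
#' yields a tiny one -- and the candidate component must capture at least
#' that fraction of the block's preprocessed variance `norm0`. With few
#' samples and many variables any unit direction "captures" roughly
#' `1/(M-1)` of a block by regression alone, so a variance gate on its own
#' cannot separate structure from noise; the loading-share gate is what
#' makes the filter selective.
#'
#' When the model has several joint components, pass their weight matrix as
#' `weight_space`: the candidate is then orthogonalised against the whole
#' joint weight span, which is the O2PLS definition of unique variation
#' (orthogonal to the joint *space*, not to one direction). Without this,
#' two joint components of comparable strength -- whose individual loadings
#' freely rotate within their shared subspace -- would let the filter strip
#' one joint direction as "unique".
#'
#' @param block_residual Residual matrix of the block.
#' @param w Unit-norm joint weight vector.
#' @param p Joint loading vector of the same block.
#' @param ortho_var_ratio Acceptance threshold (default 0.05).
#' @param norm0 Squared Frobenius norm of the block's preprocessed matrix;
#'   defaults to that of `block_residual`.
#' @param weight_space Optional matrix whose columns span the block's joint
#'   weight space; defaults to `w` alone.
#' @return A list `w`, `t`, `p` for the accepted unique component, or `NULL`.
#' @export
extract_orthogonal_candidate <- function(block_residual, w, p,
                                         ortho_var_ratio = 0.05,
                                         norm0 = NULL, weight_space = NULL) {
  w <- as.numeric(w)
  p <- as.numeric(p)
  if (is.null(norm0)) norm0 <- frob2(block_residual)
  if (is.null(weight_space)) weight_space <- matrix(w, ncol = 1)
  Q <- qr.Q(qr(weight_space))
  w_o <- p - drop(Q %*% crossprod(Q, p))
  n2 <- sum(w_o^2)
  p2 <- sum(p^2)
  if (p2 == 0 || n2 <= 1e-24 * p2) return(NULL)
  if (n2 / p2 < ortho_var_ratio) return(NULL)
  w_o <- w_o / sqrt(n2)
  t_o <- drop(block_residual %*% w_o)
  tt <- sum(t_o^2)
  if (tt == 0) return(NULL)
  p_o <- drop(crossprod(block_residual, t_o)) / tt
  if (tt * sum(p_o^2) / norm0 < ortho_var_ratio) return(NULL)
  list(w = stats::setNames(w_o, colnames(block_residual)),
       t = stats::setNames(t_o, rownames(block_residual)),
       p = stats::setNames(p_o, colnames(block_residual)))
}

local_count_for <- function(spec, key) {
  v <- spec$n_local[[key]]
  if (is.null(v)) 0L else v
}

unique_count_for <- function(spec, block_name, n_blocks_names) {
  nu <- spec$n_unique
  if (is.list(nu) || (!is.null(names(nu)) && length(nu) > 1)) {
    v <- nu[[block_name]]
    if (is.null(v)) 0L else v
  } else if (length(nu) == 1) {
    nu
  } else {
    stop("`n_unique` must be a single value or named per block")
  }
}

#' Fit an OnPLS decomposition
#'
#' Decomposes every block of a complete, centred (or reference-scaled)
#' multi-block dataset into globally joint, locally joint and unique
#' components plus a residual, `X_i = sum_a t_a p_a' + E_i`. The stages are:
#'
#' * **Global:** for each of `n_global` components a consensus component is
#'   extracted across all blocks ([extract_consensus_component()]); when
#'   `filter_orthogonal` is on, orthogonal candidates
#'   ([extract_orthogonal_candidate()]) are deflated from each block and the
#'   consensus re-extracted until no candidate passes, after which the global
#'   component is recorded and deflated everywhere.
#' * **Local:** proper block subsets of size >= 2 are visited in decreasing
#'   size; among equal-size subsets the one whose converged consensus
#'   objective is largest is extracted first (ties broken by sorted subset
#'   key), deflating only the subset's blocks, until the requested counts are
#'   exhausted.
#' * **Unique:** per block, leading principal components of the residual --
#'   the requested number, or under `"auto"` as long as each captures at
#'   least `auto_var_ratio` of the block's preprocessed variance.
#'
#' Deflation (`X <- X - t p'` with `p = X't/(t't)`) makes successive scores
#' within a block mutually orthogonal, so the squared Frobenius norms of the
#' parts and the residual add up exactly to the preprocessed block norm.
#' All internal block loops run in sorted block-name order, which makes the
#' fit independent of the order in which the blocks are supplied.
#'
#' @param dataset A [multiblock_dataset()] whose blocks are complete and in
#'   state `"centered"` or `"wt_scaled"`.
#' @param spec An [onpls_spec()].
#' @return An object of class `onpls`; see [variance_decomposition()],
#'   [project_block()], [compute_vip()].
#' @export
fit_onpls <- function(dataset, spec = onpls_spec()) {
  stopifnot(inherits(dataset, "multiblock_dataset"),
            inherits(spec, "onpls_spec"))
  blocks <- dataset$blocks
  nms_input <- names(blocks)
  nms <- sort(nms_input)
  M <- length(dataset$design$sample_ids)
  for (b in blocks) {
    if (!b$state %in% c("centered", "wt_scaled")) {
      stop("block '", b$name, "' must be centered or reference-scaled ",
           "before fitting (state is '", b$state, "')")
    }
    if (anyNA(b$values)) {
      stop("block '", b$name, "' contains missing values; impute first")
    }
  }

  # rank bound: total requested components per block must fit in M - 1
  for (b in nms) {
    n_loc <- 0L
    for (key in names(spec$n_local)) {
      if (b %in% strsplit(key, "+", fixed = TRUE)[[1]] &&
          !identical(spec$n_local[[key]], "auto")) {
        n_loc <- n_loc + as.integer(spec$n_local[[key]])
      }
    }
    n_uni <- unique_count_for(spec, b, nms)
    n_uni <- if (identical(n_uni, "auto")) 0L else as.integer(n_uni)
    if (spec$n_global + n_loc + n_uni > M - 1) {
      stop("requested components for block '", b,
           "' exceed the rank bound M - 1 = ", M - 1)
    }
  }

  R <- lapply(blocks[nms], function(b) b$values)
  norms0 <- vapply(R, frob2, numeric(1))
  comps <- stats::setNames(vector("list", length(nms)), nms)
  for (b in nms) comps[[b]] <- list()
  convergence <- list()

  add_comp <- function(b, kind, index, cmp) {
    comps[[b]][[length(comps[[b]]) + 1L]] <<- list(
      kind = kind, index = index, w = cmp$w, t = cmp$t, p = cmp$p)
    R[[b]] <<- R[[b]] - tcrossprod(cmp$t, cmp$p)
  }

  # Stage A: globally joint components. All of them are extracted
  # tentatively, orthogonal-filter candidates are judged against the FULL
  # global weight space (the O2PLS sense of "unique": orthogonal to the
  # joint space, not to one direction), accepted uniques are deflated and
  # the round repeats; the globals are committed once no candidate passes.
  extract_globals <- function(R) {
    Rtmp <- R
    ccs <- vector("list", spec$n_global)
    for (a in seq_len(spec$n_global)) {
      cc <- extract_consensus_component(Rtmp, tol = spec$tol,
                                        max_iter = spec$max_iter)
      for (b in nms) {
        cmp <- cc$blocks[[b]]
        Rtmp[[b]] <- Rtmp[[b]] - tcrossprod(cmp$t, cmp$p)
      }
      ccs[[a]] <- cc
    }
    ccs
  }
  repeat {
    ccs <- extract_globals(R)
    if (!spec$filter_orthogonal) break
    accepted <- FALSE
    for (b in nms) {
      W_b <- matrix(vapply(ccs, function(cc) {
        as.numeric(cc$blocks[[b]]$w)
      }, numeric(ncol(R[[b]]))), ncol = spec$n_global)
      for (a in seq_len(spec$n_global)) {
        cand <- extract_orthogonal_candidate(
          R[[b]], ccs[[a]]$blocks[[b]]$w, ccs[[a]]$blocks[[b]]$p,
          ortho_var_ratio = spec$ortho_var_ratio, norm0 = norms0[[b]],
          weight_space = W_b)
        if (!is.null(cand)) {
          add_comp(b, "unique", NA_integer_, cand)
          accepted <- TRUE
          break   # this block's residual changed; re-extract first
        }
      }
    }
    if (!accepted) break
  }
  for (a in seq_len(spec$n_global)) {
    for (b in nms) add_comp(b, "global", a, ccs[[a]]$blocks[[b]])
    convergence[[paste0("global", a)]] <- list(
      iterations = ccs[[a]]$iterations, objective = ccs[[a]]$objective,
      converged = ccs[[a]]$converged)
  }

  # Stage B: locally joint components, largest subsets first
  if (length(nms) > 2 || length(spec$n_local) > 0) {
    subsets <- list()
    for (size in seq(length(nms) - 1, 2)) {
      if (size < 2) break
      cmb <- utils::combn(nms, size, simplify = FALSE)
      keys <- vapply(cmb, subset_key, character(1))
      cmb <- cmb[order(keys)]
      for (s in cmb) subsets[[subset_key(s)]] <- s
    }
    sizes <- vapply(subsets, length, integer(1))
    for (size in sort(unique(sizes), decreasing = TRUE)) {
      state <- list()
      for (key in names(subsets)[sizes == size]) {
        cnt <- local_count_for(spec, key)
        if (identical(cnt, "auto")) {
          state[[key]] <- list(auto = TRUE, left = Inf)
        } else if (as.integer(cnt) > 0) {
          state[[key]] <- list(auto = FALSE, left = as.integer(cnt))
        }
      }
      local_idx <- stats::setNames(rep(0L, length(state)), names(state))
      while (length(state) > 0) {
        cands <- list()
        for (key in names(state)) {
          S <- subsets[[key]]
          cc <- tryCatch(
            suppressWarnings(extract_consensus_component(
              R[S], tol = spec$tol, max_iter = spec$max_iter)),
            error = function(e) NULL)
          if (is.null(cc)) next
          cands[[key]] <- cc
        }
        if (length(cands) == 0) break
        Js <- vapply(cands, function(cc) {
          cc$objective[length(cc$objective)]
        }, numeric(1))
        best <- names(cands)[order(-Js, names(cands))][1]
        cc <- cands[[best]]
        S <- subsets[[best]]
        if (state[[best]]$auto) {
          ratios <- vapply(S, function(b) {
            cmp <- cc$blocks[[b]]
            sum(cmp$t^2) * sum(cmp$p^2) / norms0[[b]]
          }, numeric(1))
          if (any(ratios < spec$auto_var_ratio)) {
            state[[best]] <- NULL
            next
          }
        }
        local_idx[best] <- local_idx[best] + 1L
        for (b in S) add_comp(b, paste0("local:", best), local_idx[best],
                              cc$blocks[[b]])
        convergence[[paste0("local:", best, ":", local_idx[best])]] <- list(
          iterations = cc$iterations, objective = cc$objective,
          converged = cc$converged)
        if (!state[[best]]$auto) {
          state[[best]]$left <- state[[best]]$left - 1L
          if (state[[best]]$left == 0L) state[[best]] <- NULL
        }
      }
    }
  }

  # Stage C: unique components = leading principal components of residuals
  for (b in nms) {
    req <- unique_count_for(spec, b, nms)
    auto <- identical(req, "auto")
    k_max <- if (auto) M - 1L else as.integer(req)
    if (k_max <= 0) next
    kk <- min(k_max, nrow(R[[b]]), ncol(R[[b]]))
    sv <- svd(R[[b]], nu = 0, nv = kk)
    taken <- 0L
    for (k in seq_len(kk)) {
      varfrac <- sv$d[k]^2 / norms0[[b]]
      if (auto && varfrac < spec$auto_var_ratio) break
      if (sv$d[k]^2 <= 1e-12 * max(norms0[[b]], 1)) {
        if (!auto) {
          warning("block '", b, "': residual exhausted after ", taken,
                  " unique component(s); ", req, " requested")
        }
        break
      }
      v <- sv$v[, k]
      if (v[which.max(abs(v))] < 0) v <- -v
      t_k <- drop(R[[b]] %*% v)
      tt <- sum(t_k^2)
      p_k <- drop(crossprod(R[[b]], t_k)) / tt
      add_comp(b, "unique", k, list(
        w = stats::setNames(v, colnames(R[[b]])),
        t = stats::setNames(t_k, rownames(R[[b]])),
        p = stats::setNames(p_k, colnames(R[[b]]))))
      taken <- taken + 1L
    }
  }

  model <- structure(
    list(spec = spec, design = dataset$design,
         block_names = nms_input,
         state = stats::setNames(
           vapply(blocks, function(b) b$state, character(1)), nms_input),
         blocks = stats::setNames(lapply(nms, function(b) {
           list(components = comps[[b]], residual = R[[b]],
                norm0 = norms0[[b]],
                variable_ids = colnames(blocks[[b]]$values))
         }), nms),
         convergence = convergence),
    class = "onpls")
  model$r2 <- variance_decomposition(model)
  model
}

#' Fit the two-block (O2PLS) special case
#'
#' Delegates to [fit_onpls()] after checking that exactly two blocks are
#' supplied. With orthogonal filtering the globally joint weights equal the
#' leading singular pair of the cross-covariance of the filtered matrices;
#' with filtering off and one component they equal the leading singular pair
#' of `X_1' X_2` itself.
#'
#' @param dataset A [multiblock_dataset()] with exactly 2 blocks.
#' @param spec An [onpls_spec()].
#' @return An object of class `onpls`.
#' @export
fit_o2pls <- function(dataset, spec = onpls_spec()) {
  if (length(dataset$blocks) != 2) {
    stop("fit_o2pls requires exactly 2 blocks; got ",
         length(dataset$blocks))
  }
  fit_onpls(dataset, spec)
}

part_of_kind <- function(kind) {
  if (kind == "global") "global"
  else if (startsWith(kind, "local:")) kind
  else "unique"
}

#' Variance decomposition (R-squared ledger) of a fitted model
#'
#' For every block, the fraction of the preprocessed squared Frobenius norm
#' captured by the globally joint part, each locally joint subset, the unique
#' part and the residual. Because deflation keeps within-block scores
#' orthogonal, the fractions plus the residual sum to 1.
#'
#' @param model A fitted [fit_onpls()] model.
#' @return A data frame with one row per block, columns `block`, `global`,
#'   one `local:<subset>` column per subset that received components,
#'   `unique` and `residual`.
#' @export
variance_decomposition <- function(model) {
  stopifnot(inherits(model, "onpls"))
  nms <- sort(model$block_names)
  local_keys <- sort(unique(unlist(lapply(nms, function(b) {
    kinds <- vapply(model$blocks[[b]]$components, `[[`, character(1), "kind")
    kinds[startsWith(kinds, "local:")]
  }))))
  rows <- lapply(model$block_names, function(b) {
    bl <- model$blocks[[b]]
    parts <- stats::setNames(
      rep(0, 3 + length(local_keys)),
      c("global", local_keys, "unique", "residual"))
    for (cmp in bl$components) {
      part <- part_of_kind(cmp$kind)
      parts[part] <- parts[part] + sum(cmp$t^2) * sum(cmp$p^2) / bl$norm0
    }
    parts["residual"] <- frob2(bl$residual) / bl$norm0
    c(list(block = b), as.list(parts))
  })
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)
  }))
}

#' @export
print.onpls <- function(x, ...) {
  cat("OnPLS model:", length(x$blocks), "blocks,",
      x$spec$n_global, "globally joint component(s)\n")
  r2 <- x$r2
  num <- vapply(r2, is.numeric, logical(1))
  r2[num] <- lapply(r2[num], function(v) round(100 * v, 1))
  print(r2, row.names = FALSE)
  invisible(x)
}

#' Global scores of a model
#'
#' @param model A fitted [fit_onpls()] model.
#' @param block_name A block name, or `NULL` (default) for the consensus
#'   scores, the unweighted mean of the per-block global scores.
#' @return An M x `n_global` matrix of scores.
#' @export
global_scores <- function(model, block_name = NULL) {
  nms <- sort(model$block_names)
  one <- function(b) {
    cmps <- model$blocks[[b]]$components
    cols <- lapply(cmps[vapply(cmps, `[[`, character(1), "kind") == "global"],
                   `[[`, "t")
    do.call(cbind, cols)
  }
  if (!is.null(block_name)) {
    s <- one(block_name)
  } else {
    s <- Reduce(`+`, lapply(nms, one)) / length(nms)
  }
  colnames(s) <- paste0("global", seq_len(ncol(s)))
  s
}

#' Project new samples onto a block's components
#'
#' Applies the block's components in extraction order: `t_a = x w_a`,
#' `x <- x - t_a p_a'`, and returns the scores of the globally joint
#' components. New rows must be preprocessed exactly as the training rows
#' (same centering/reference statistics).
#'
#' @param model A fitted [fit_onpls()] model.
#' @param block_name Name of the block to project onto.
#' @param new_rows Matrix (rows = new samples) whose columns match the
#'   block's variable ids (any order; matched by name when named).
#' @return Matrix of global scores (rows = new samples).
#' @export
project_block <- function(model, block_name, new_rows) {
  bl <- model$blocks[[block_name]]
  if (is.null(bl)) stop("unknown block '", block_name, "'")
  if (is.null(dim(new_rows))) new_rows <- matrix(new_rows, nrow = 1)
  vids <- bl$variable_ids
  if (!is.null(colnames(new_rows))) {
    if (!setequal(colnames(new_rows), vids)) {
      stop("columns of `new_rows` do not match the variables of block '",
           block_name, "'")
    }
    new_rows <- new_rows[, vids, drop = FALSE]
  } else if (ncol(new_rows) != length(vids)) {
    stop("`new_rows` has ", ncol(new_rows), " columns; block '", block_name,
         "' has ", length(vids), " variables")
  }
  x <- new_rows
  out <- list()
  for (cmp in bl$components) {
    t_a <- drop(x %*% cmp$w)
    x <- x - tcrossprod(t_a, cmp$p)
    if (cmp$kind == "global") out[[length(out) + 1L]] <- t_a
  }
  s <- do.call(cbind, out)
  colnames(s) <- paste0("global", seq_len(ncol(s)))
  rownames(s) <- rownames(new_rows)
  s
}

#' Per-genotype coefficient of variation of the first joint score
#'
#' `CV_g = 100 * sd(score within genotype g) / (max - min of the score over
#' all samples)`, where the score is the first global consensus score (mean
#' over blocks of each block's first global score). Expresses within-genotype
#' biological spread as a percentage of the full genotype-effect range.
#'
#' @param model A fitted [fit_onpls()] model.
#' @param design A [sample_design()]; defaults to the model's design.
#' @return Named numeric vector, one percentage per genotype (`NaN` with a
#'   warning if the score range is zero; `NA` for single-sample genotypes).
#' @export
genotype_cv <- function(model, design = model$design) {
  s <- global_scores(model)[, 1]
  rng <- max(s) - min(s)
  geno <- design$genotype_of[design$sample_ids]
  out <- stats::setNames(rep(NA_real_, length(unique(geno))), unique(geno))
  if (rng == 0) {
    warning("first joint score has zero range; CV undefined")
    out[] <- NaN
    return(out)
  }
  for (g in unique(geno)) {
    v <- s[geno == g]
    out[g] <- if (length(v) >= 2) 100 * stats::sd(v) / rng else NA_real_
  }
  out
}
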