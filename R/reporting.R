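round_to_100 <- function(fracs) {
  # largest-remainder rounding to one decimal so the row sums to exactly 100
  pct <- fracs / sum(fracs) * 100
  tenths <- floor(pct * 10)
  short <- 1000L - as.integer(round(sum(tenths)))
  if (short > 0) {
    rem <- pct * 10 - tenths
    bump <- order(-rem, seq_along(rem))[seq_len(short)]
    tenths[bump] <- tenths[bump] + 1L
  }
  tenths / 10
}

#' Variance-decomposition report in percent
#'
#' One row per block with the percentage of the preprocessed variance
#' captured by the globally joint part, each locally joint subset, the unique
#' part and the residual, rounded to one decimal so that every row sums to
#' exactly 100.0.
#'
#' @param model A fitted [fit_onpls()] model.
#' @return A data frame of percentages.
#' @export
r2_report <- function(model) {
  r2 <- variance_decomposition(model)
  num <- vapply(r2, is.numeric, logical(1))
  out <- r2
  for (i in seq_len(nrow(r2))) {
    out[i, num] <- round_to_100(as.numeric(r2[i, num]))
  }
  out
}

write_tsv_formatted <- function(df, path, digits = 6) {
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) sprintf(paste0("%.", digits, "f"), x)
    else as.character(x)
  }
  body <- vapply(seq_len(nrow(df)), function(i) {
    paste(vapply(df[i, , drop = FALSE], fmt, character(1)), collapse = "\t")
  }, character(1))
  writeLines(c(paste(colnames(df), collapse = "\t"), body), path,
             useBytes = TRUE)
  invisible(path)
}

#' Write the variance-decomposition report to a TSV
#' @param model A fitted [fit_onpls()] model.
#' @param path Output path.
#' @export
write_r2_report <- function(model, path) {
  write_tsv_formatted(r2_report(model), path, digits = 1)
}

dir_string <- function(d) {
  ifelse(is.na(d) | d == 0, "-", ifelse(d > 0, "up", "down"))
}

#' Merge significance tables into a direction-arrow overview table
#'
#' With a protein-to-transcript mapping, builds one row per mapped protein
#' with `"up"`/`"down"`/`"-"` columns per transgenic line and molecular level
#' (protein and transcript); with a single table, one direction column per
#' line. Rows are sorted by annotation label, then feature id.
#'
#' @param tables Named list of `significance_table`s with direction columns;
#'   either `list(protein = ..., transcript = ...)` plus `mapping`, or a
#'   single table.
#' @param mapping Named character vector protein id -> transcript id
#'   (required for the two-level form; targets must be unique).
#' @param annotations Optional named character vector feature id -> label.
#' @return A data frame (`arrow_table`).
#' @export
merged_arrow_table <- function(tables, mapping = NULL, annotations = NULL) {
  if (inherits(tables, "significance_table")) tables <- list(tables)
  get_ann <- function(ids) {
    if (is.null(annotations)) rep("", length(ids))
    else ifelse(is.na(annotations[ids]), "", annotations[ids])
  }
  if (length(tables) == 1) {
    tab <- tables[[1]]
    dir_cols <- grep("^dir_", colnames(tab), value = TRUE)
    out <- data.frame(feature_id = tab$variable_id,
                      annotation = get_ann(tab$variable_id),
                      stringsAsFactors = FALSE)
    for (dc in dir_cols) {
      out[[sub("^dir_", "", dc)]] <- dir_string(tab[[dc]])
    }
  } else {
    if (length(tables) != 2 || is.null(mapping)) {
      stop("two-level form needs exactly two tables (protein, transcript) ",
           "and a protein -> transcript mapping")
    }
    if (anyDuplicated(mapping[!is.na(mapping)])) {
      stop("duplicate mapping targets: ",
           paste(unique(mapping[duplicated(mapping)]), collapse = ", "))
    }
    prot <- tables[[1]]
    trans <- tables[[2]]
    dir_cols <- grep("^dir_", colnames(prot), value = TRUE)
    prot <- prot[prot$variable_id %in% names(mapping), , drop = FALSE]
    tr_idx <- match(mapping[prot$variable_id], trans$variable_id)
    out <- data.frame(feature_id = prot$variable_id,
                      annotation = get_ann(prot$variable_id),
                      stringsAsFactors = FALSE)
    for (dc in dir_cols) {
      line <- sub("^dir_", "", dc)
      out[[paste0(line, "_P")]] <- dir_string(prot[[dc]])
      td <- trans[[dc]][tr_idx]
      ts <- trans$significant[tr_idx]
      td[is.na(ts) | !ts] <- 0L
      out[[paste0(line, "_T")]] <- dir_string(td)
    }
  }
  out <- out[order(out$annotation, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write MapMan painting input files
#'
#' One two-column file (`IDENTIFIER`, `VALUE`) per non-reference line,
#' holding the significant variables only; identifiers are lower-cased as
#' MapMan expects. `VALUE` is the direction (+1/-1), the line's mean
#' reference-scaled value, or the dominant-component loading.
#'
#' @param table A `significance_table` with direction and mean columns.
#' @param dir Output directory.
#' @param value One of `"direction"`, `"mean_scaled"`, `"loading"`.
#' @param prefix File-name prefix, typically the block name.
#' @return Invisibly, the written file paths.
#' @export
export_mapman <- function(table, dir = ".",
                          value = c("direction", "mean_scaled", "loading"),
                          prefix = "block") {
  value <- match.arg(value)
  dir_cols <- grep("^dir_", colnames(table), value = TRUE)
  if (length(dir_cols) == 0) stop("run direction_arrows() first")
  paths <- character(0)
  for (dc in dir_cols) {
    line <- sub("^dir_", "", dc)
    sig <- table[table$significant, , drop = FALSE]
    path <- file.path(dir, sprintf("mapman_%s_%s.txt", prefix, line))
    if (nrow(sig) == 0) {
      warning("no significant rows; writing header-only file ", path)
      writeLines("IDENTIFIER\tVALUE", path, useBytes = TRUE)
    } else {
      val <- switch(value,
                    direction = sprintf("%d", sig[[dc]]),
                    mean_scaled = sprintf("%.6f",
                                          sig[[paste0("mean_", line)]]),
                    loading = sprintf("%.6f", sig$estimate))
      writeLines(c("IDENTIFIER\tVALUE",
                   paste(tolower(sig$variable_id), val, sep = "\t")),
                 path, useBytes = TRUE)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write Paintomics input tables
#'
#' One TSV per molecular level: first column the feature id, then one numeric
#' column per non-reference line holding the line's mean reference-scaled
#' value, for the significant features.
#'
#' @param tables Named list level -> `significance_table` (with mean
#'   columns), e.g. `list(gene = ..., protein = ..., metabolite = ...)`.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
export_paintomics <- function(tables, dir = ".") {
  paths <- character(0)
  for (level in names(tables)) {
    tab <- tables[[level]]
    mean_cols <- grep("^mean_", colnames(tab), value = TRUE)
    lines_nm <- sub("^mean_", "", mean_cols)
    path <- file.path(dir, sprintf("paintomics_%s.tsv", level))
    sig <- tab[tab$significant, , drop = FALSE]
    header <- paste(c("feature_id", lines_nm), collapse = "\t")
    if (nrow(sig) == 0) {
      warning("no significant rows for level '", level,
              "'; writing header-only file")
      writeLines(header, path, useBytes = TRUE)
    } else {
      body <- vapply(seq_len(nrow(sig)), function(i) {
        paste(c(sig$variable_id[i],
                sprintf("%.6f", unlist(sig[i, mean_cols]))),
              collapse = "\t")
      }, character(1))
      writeLines(c(header, body), path, useBytes = TRUE)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write global scores (per block and consensus) to a TSV
#' @param model A fitted [fit_onpls()] model.
#' @param path Output path.
#' @export
write_global_scores <- function(model, path) {
  nms <- sort(model$block_names)
  cons <- global_scores(model)
  df <- data.frame(sample_id = rownames(cons), stringsAsFactors = FALSE)
  for (a in seq_len(ncol(cons))) {
    df[[paste0("consensus_global", a)]] <- cons[, a]
  }
  for (b in nms) {
    s <- global_scores(model, b)
    for (a in seq_len(ncol(s))) df[[paste0(b, "_global", a)]] <- s[, a]
  }
  write_tsv_formatted(df, path, digits = 10)
}

#' Write per-block loadings and weights to TSVs
#' @param model A fitted [fit_onpls()] model.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_block_loadings <- function(model, dir = ".") {
  paths <- character(0)
  for (b in sort(model$block_names)) {
    cmps <- model$blocks[[b]]$components
    g <- cmps[vapply(cmps, `[[`, character(1), "kind") == "global"]
    df <- data.frame(variable_id = model$blocks[[b]]$variable_ids,
                     stringsAsFactors = FALSE)
    dfw <- df
    for (a in seq_along(g)) {
      df[[paste0("loading_global", a)]] <- unname(g[[a]]$p)
      dfw[[paste0("weight_global", a)]] <- unname(g[[a]]$w)
    }
    p1 <- file.path(dir, sprintf("loadings_%s.tsv", b))
    p2 <- file.path(dir, sprintf("weights_%s.tsv", b))
    write_tsv_formatted(df, p1, digits = 10)
    write_tsv_formatted(dfw, p2, digits = 10)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}

#' Write the per-block significance tables to TSVs
#' @param tables Named list block -> `significance_table`.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_significance_tables <- function(tables, dir = ".") {
  paths <- character(0)
  for (b in names(tables)) {
    tab <- tables[[b]]
    dir_cols <- grep("^dir_", colnames(tab), value = TRUE)
    for (dc in dir_cols) tab[[dc]] <- dir_string(tab[[dc]])
    tab$significant <- ifelse(tab$significant, "yes", "no")
    path <- file.path(dir, sprintf("significance_%s.tsv", b))
    write_tsv_formatted(tab, path, digits = 6)
    paths <- c(paths, path)
  }
  invisible(paths)
}
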