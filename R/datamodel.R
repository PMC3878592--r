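#' Sample design for a multi-omic experiment
#'
#' A sample design names the biological samples, assigns each to exactly one
#' genotype, and singles out one genotype as the internal reference (typically
#' the wild type, `"WT"`). The reference genotype must contribute at least two
#' samples so that a per-variable reference standard deviation exists. Sample
#' order in the design is the canonical row order of every data block.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param genotypes Character vector (same length) giving each sample's
#'   genotype label.
#' @param reference_genotype Label of the reference genotype; must occur among
#'   `genotypes` with at least two samples.
#' @param replicates Optional positive integer vector of within-genotype
#'   replicate indices; defaults to 1, 2, ... within each genotype.
#' @return An object of class `sample_design`.
#' @examples
#' sample_design(c("WT-1", "WT-2", "M-1", "M-2"),
#'               c("WT", "WT", "MUT", "MUT"), "WT")
#' @export
sample_design <- function(sample_ids, genotypes, reference_genotype,
                          replicates = NULL) {
  sample_ids <- as.character(sample_ids)
  genotypes <- as.character(genotypes)
  if (length(sample_ids) != length(genotypes)) {
    stop("`sample_ids` and `genotypes` must have the same length")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (length(unique(genotypes)) < 2) {
    stop("a design needs at least 2 distinct genotypes")
  }
  if (!reference_genotype %in% genotypes) {
    stop("reference genotype '", reference_genotype,
         "' is absent from the design")
  }
  if (sum(genotypes == reference_genotype) < 2) {
    stop("reference genotype '", reference_genotype,
         "' needs at least 2 samples (a standard deviation is required)")
  }
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_along(genotypes), genotypes,
                             FUN = seq_along)
  }
  replicates <- as.integer(replicates)
  if (any(is.na(replicates)) || any(replicates < 1L)) {
    stop("replicate indices must be positive integers")
  }
  structure(
    list(sample_ids = sample_ids,
         genotype_of = stats::setNames(genotypes, sample_ids),
         reference_genotype = reference_genotype,
         replicate_index = stats::setNames(replicates, sample_ids)),
    class = "sample_design")
}

#' @export
print.sample_design <- function(x, ...) {
  tab <- table(x$genotype_of)
  cat("Sample design:", length(x$sample_ids), "samples,",
      length(tab), "genotypes (reference:", x$reference_genotype, ")\n")
  print(tab)
  invisible(x)
}

#' @export
as.data.frame.sample_design <- function(x, ...) {
  data.frame(sample_id = x$sample_ids,
             genotype = unname(x$genotype_of[x$sample_ids]),
             replicate = unname(x$replicate_index[x$sample_ids]),
             stringsAsFactors = FALSE)
}

#' Non-reference genotype labels of a design, in order of first appearance
#' @param design A [sample_design()].
#' @return Character vector of non-reference genotype labels.
#' @export
non_reference_genotypes <- function(design) {
  g <- unname(design$genotype_of[design$sample_ids])
  setdiff(unique(g), design$reference_genotype)
}

block_states <- c("raw", "log2", "combined", "centered", "wt_scaled")

#' One platform's samples-by-variables matrix
#'
#' An omics block holds a numeric matrix with samples in rows and variables in
#' columns, plus a block name, a free-form platform tag and a processing-state
#' tag (one of `raw`, `log2`, `combined`, `centered`, `wt_scaled`). Missing
#' measurements are `NA` and are distinct from zero throughout the package.
#'
#' @param values Numeric matrix, samples x variables, with row and column
#'   names (sample and variable identifiers).
#' @param name Block name (unique within a dataset).
#' @param platform Free-form platform tag (e.g. `"microarray"`).
#' @param state Processing-state tag.
#' @return An object of class `omics_block`.
#' @export
omics_block <- function(values, name, platform = "unspecified",
                        state = "raw") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs sample row names and variable column names")
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate variable ids in block '", name, "': ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids in block '", name, "'")
  }
  state <- match.arg(state, block_states)
  if (ncol(values) > 0 && any(colSums(!is.na(values)) == 0)) {
    bad <- colnames(values)[colSums(!is.na(values)) == 0]
    stop("block '", name, "' has entirely missing variables: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(name = name, platform = platform, state = state,
                 values = values),
            class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("Omics block '%s' [%s]: %d samples x %d variables, state = %s\n",
              x$name, x$platform, nrow(x$values), ncol(x$values), x$state))
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat("  missing entries:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.omics_block <- function(x) dim(x$values)

#' Variable identifiers of a block
#' @param block An [omics_block()].
#' @return Character vector of variable ids (column names).
#' @export
variable_ids <- function(block) colnames(block$values)

set_block_values <- function(block, values, state = block$state) {
  block$values <- values
  block$state <- state
  block
}

#' Co-aligned multi-block dataset
#'
#' Bundles two or more [omics_block()]s that share one [sample_design()]. All
#' blocks must have exactly the design's samples, in design order; use
#' [align_blocks()] to reorder rows first.
#'
#' @param blocks Named or unnamed list of [omics_block()]s (>= 2); block names
#'   must be unique.
#' @param design A [sample_design()].
#' @return An object of class `multiblock_dataset` with elements `design` and
#'   `blocks` (a named list).
#' @export
multiblock_dataset <- function(blocks, design) {
  stopifnot(inherits(design, "sample_design"))
  if (length(blocks) < 2) stop("a multi-block dataset needs at least 2 blocks")
  nms <- vapply(blocks, function(b) b$name, character(1))
  if (anyDuplicated(nms)) stop("block names must be unique")
  names(blocks) <- nms
  for (b in blocks) {
    if (!identical(rownames(b$values), design$sample_ids)) {
      stop("block '", b$name, "' rows do not match the design sample order; ",
           "run align_blocks() first")
    }
  }
  structure(list(design = design, blocks = blocks),
            class = "multiblock_dataset")
}

#' @export
print.multiblock_dataset <- function(x, ...) {
  cat("Multi-block dataset:", length(x$blocks), "blocks,",
      length(x$design$sample_ids), "samples\n")
  for (b in x$blocks) {
    cat(sprintf("  %-14s %5d variables  (state: %s)\n",
                b$name, ncol(b$values), b$state))
  }
  invisible(x)
}

#' Align blocks to a sample design
#'
#' Reorders each block's rows to the design's sample order. A block missing a
#' design sample is an error; samples present in a block but absent from the
#' design are an error unless `drop_extra = TRUE`.
#'
#' @param blocks List of [omics_block()]s whose rows are labelled by sample id.
#' @param design A [sample_design()].
#' @param drop_extra Drop block samples not present in the design instead of
#'   erroring.
#' @return A [multiblock_dataset()].
#' @export
align_blocks <- function(blocks, design, drop_extra = FALSE) {
  aligned <- lapply(blocks, function(b) {
    rn <- rownames(b$values)
    missing <- setdiff(design$sample_ids, rn)
    if (length(missing) > 0) {
      stop("block '", b$name, "' is missing design sample(s): ",
           paste(missing, collapse = ", "))
    }
    extra <- setdiff(rn, design$sample_ids)
    if (length(extra) > 0 && !drop_extra) {
      stop("block '", b$name, "' has samples not in the design: ",
           paste(extra, collapse = ", "),
           " (set drop_extra = TRUE to drop them)")
    }
    set_block_values(b, b$values[design$sample_ids, , drop = FALSE])
  })
  multiblock_dataset(aligned, design)
}

#' Read an omics matrix from a tab-delimited file
#'
#' The file must be UTF-8, tab-separated with a `.` decimal separator, one
#' header row and one leading identifier column. Cells are numeric or equal to
#' `missing_token`. With `orientation = "variables_in_rows"` the matrix is
#' transposed so the returned block is always samples x variables.
#'
#' @param path Path to the TSV file.
#' @param name Block name; defaults to the file name without extension.
#' @param orientation `"samples_in_rows"` (default) or `"variables_in_rows"`.
#' @param missing_token String marking missing values (default `"NA"`).
#' @param platform Platform tag forwarded to [omics_block()].
#' @return An [omics_block()] with `state = "raw"`.
#' @export
read_block_tsv <- function(path, name = NULL,
                           orientation = c("samples_in_rows",
                                           "variables_in_rows"),
                           missing_token = "NA", platform = "unspecified") {
  orientation <- match.arg(orientation)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "",
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("'", path, "': expected an id column plus data")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("'", path, "': duplicate row ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cn <- colnames(raw)[-1]
  if (anyDuplicated(cn)) {
    stop("'", path, "': duplicate column ids: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  is_missing <- cells == missing_token
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is_missing, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("'", path, "': non-numeric cell at row '", ids[bad[1, 1]],
         "', column '", cn[bad[1, 2]], "': \"",
         cells[bad[1, 1], bad[1, 2]], "\"")
  }
  num[is_missing] <- NA_real_
  dimnames(num) <- list(ids, cn)
  if (orientation == "variables_in_rows") num <- t(num)
  omics_block(num, name = name, platform = platform, state = "raw")
}

#' Write an omics block to a tab-delimited file
#'
#' Values are written with 17 significant digits so that a read/write/read
#' round trip reproduces finite entries bit-exactly; missing entries are
#' written as `missing_token`.
#'
#' @param block An [omics_block()].
#' @param path Output path.
#' @param missing_token String marking missing values.
#' @param id_header Header of the leading identifier column.
#' @export
write_block_tsv <- function(block, path, missing_token = "NA",
                            id_header = "sample_id") {
  v <- block$values
  txt <- matrix(formatC(v, digits = 17, format = "g"), nrow = nrow(v))
  txt[is.na(v)] <- missing_token
  lines <- c(paste(c(id_header, colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i], txt[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a sample design table
#'
#' Expects a TSV with columns `sample_id`, `genotype` and `replicate`.
#'
#' @param path Path to the design TSV.
#' @param reference_genotype Reference genotype label; must be present.
#' @return A [sample_design()].
#' @export
read_design_tsv <- function(path, reference_genotype) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "replicate")
  if (!all(need %in% colnames(d))) {
    stop("'", path, "': design table needs columns ",
         paste(need, collapse = ", "))
  }
  sample_design(d$sample_id, d$genotype, reference_genotype,
                replicates = d$replicate)
}

#' Write a sample design table
#' @param design A [sample_design()].
#' @param path Output path.
#' @export
write_design_tsv <- function(design, path) {
  d <- as.data.frame(design)
  lines <- c("sample_id\tgenotype\treplicate",
             sprintf("%s\t%s\t%d", d$sample_id, d$genotype, d$replicate))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a flat YAML run configuration
#'
#' Flat keys mirror the model and preprocessing parameters: `seed`,
#' `n_global`, `n_local` (map from `"a+b"` subset keys to counts), `n_unique`,
#' `filter_orthogonal`, `ortho_var_ratio`, `tol`, `max_iter`,
#' `auto_var_ratio`, `censor_threshold`, `log_offset`, `min_reference_sd`,
#' `vip_threshold`, `output_dir`. Missing keys take the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("'", path, "' did not parse to a key/value map")
  defaults <- list(seed = 1L, n_global = 2L, n_local = list(),
                   n_unique = 0L, filter_orthogonal = TRUE,
                   ortho_var_ratio = 0.05, tol = 1e-9, max_iter = 500L,
                   auto_var_ratio = 0.05, censor_threshold = 7,
                   log_offset = 0, min_reference_sd = 1e-12,
                   vip_threshold = 0.5, output_dir = ".")
  out <- utils::modifyList(defaults, cfg)
  num <- c("ortho_var_ratio", "tol", "auto_var_ratio", "censor_threshold",
           "log_offset", "min_reference_sd", "vip_threshold")
  if (!all(is.finite(unlist(out[num])))) {
    stop("all numeric thresholds in the run configuration must be finite")
  }
  out$seed <- as.integer(out$seed)
  structure(out, class = "run_config")
}
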