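# shared fixture builders; everything is generated in code at test time

toy_design <- function(n_geno = c(WT = 3, L1 = 3, L2 = 3), reference = "WT") {
  geno <- rep(names(n_geno), n_geno)
  ids <- paste0(geno, "-", unlist(lapply(n_geno, seq_len)))
  sample_design(ids, geno, reference)
}

centered_block <- function(values, name, ids = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- if (is.null(ids)) paste0("s", seq_len(nrow(values)))
    else ids
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0(name, "_v", seq_len(ncol(values)))
  }
  values <- sweep(values, 2, colMeans(values))
  omics_block(values, name, state = "centered")
}

seeded_dataset <- function(seed = 42, M = 9, dims = c(A = 5, B = 4),
                           design = NULL) {
  set.seed(seed)
  if (is.null(design)) {
    design <- toy_design(c(WT = ceiling(M / 3),
                           L1 = floor(M / 3),
                           L2 = M - ceiling(M / 3) - floor(M / 3)))
  }
  ids <- design$sample_ids
  blocks <- lapply(names(dims), function(nm) {
    centered_block(matrix(stats::rnorm(M * dims[[nm]]), M,
                          dimnames = list(ids, NULL)), nm)
  })
  multiblock_dataset(blocks, design)
}

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

sign_align <- function(target, x) if (sum(target * x) < 0) -x else x
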