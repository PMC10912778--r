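#' Expression dataset container
#'
#' A genes-by-samples value matrix paired with a sample sheet (sample id,
#' genotype, day, replicate). Values are expected on a normalized log scale
#' after [normalize_expression()]; the synthetic generator produces them on
#' that scale directly unless count simulation is requested.
#'
#' @param values numeric matrix, genes in rows, samples in columns; dimnames
#'   required.
#' @param samples data.frame with at least columns `sample`, `genotype`,
#'   `day`, `replicate`; `sample` must match `colnames(values)`.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, samples) {
  .assert(is.matrix(values) && is.numeric(values),
          "values must be a numeric matrix")
  .assert(!is.null(rownames(values)) && !is.null(colnames(values)),
          "values must carry gene and sample dimnames")
  .assert(!anyDuplicated(colnames(values)), "sample ids must be unique")
  .assert(!anyDuplicated(rownames(values)), "gene ids must be unique")
  .assert(all(c("sample", "genotype", "day", "replicate") %in% names(samples)),
          "samples needs columns sample, genotype, day, replicate")
  .assert(identical(colnames(values), samples$sample),
          "samples$sample must match colnames(values) in order")
  .assert(!anyNA(values), "values must not contain missing entries")
  structure(list(values = values, samples = samples),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%d genotypes, %d days)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$genotype)),
              length(unique(x$samples$day))))
  invisible(x)
}

#' Library-size normalization and log transform
#'
#' Scales each sample to a common library size (counts per million) and
#' applies log2(x + 1). This is the package's defined stand-in for a
#' variance-stabilizing transform: the pipeline downstream consumes only a
#' monotone, roughly variance-stabilized log-scale matrix. Scaling to a
#' fixed target makes normalized values invariant to sequencing depth.
#'
#' @param raw nonnegative genes-by-samples matrix (counts or abundances).
#' @param samples sample sheet, see [expression_dataset()].
#' @param target common library size (default 1e6).
#' @return an [expression_dataset()] of normalized log2 values.
#' @export
normalize_expression <- function(raw, samples, target = 1e6) {
  .assert(is.matrix(raw) && all(raw >= 0), "raw must be a nonnegative matrix")
  lib <- colSums(raw)
  if (any(lib == 0)) stop("all-zero sample(s): ",
                          paste(colnames(raw)[lib == 0], collapse = ", "),
                          call. = FALSE)
  scaled <- sweep(raw, 2, target / lib, `*`)
  expression_dataset(log2(scaled + 1), samples)
}

#' Subset an expression dataset by samples
#'
#' @param expr an [expression_dataset()].
#' @param keep logical or character selector over samples.
#' @return an [expression_dataset()] with the selected samples.
#' @export
subset_samples <- function(expr, keep) {
  if (is.character(keep)) keep <- expr$samples$sample %in% keep
  expression_dataset(expr$values[, keep, drop = FALSE],
                     expr$samples[keep, , drop = FALSE])
}
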