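# Readers and writers for the pipeline's artifacts: counts (TSV or
# MatrixMarket with name sidecars), sample annotation CSV, DE tables and
# signature models (JSON).

#' Read a gene-by-sample count matrix
#'
#' Accepts either a TSV (gene ids in the first column, header row of
#' sample ids) or a MatrixMarket `.mtx` triplet file accompanied by
#' `<path>.rows` / `<path>.cols` sidecars holding gene and sample ids,
#' one per line. Duplicate ids and non-integer entries are rejected with
#' context.
#'
#' @param path file path; format inferred from the `.mtx` extension.
#' @return Validated numeric count matrix with dimnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rows <- paste0(path, ".rows")
    cols <- paste0(path, ".cols")
    if (!file.exists(rows) || !file.exists(cols)) {
      stop("missing sidecar file(s) ", rows, " / ", cols)
    }
    rownames(m) <- readLines(rows)
    colnames(m) <- readLines(cols)
    storage.mode(m) <- "double"
    return(validate_counts(m))
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed count TSV (need gene column + samples): ", path)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric entries in column '%s' of %s",
                 names(df)[-1][bad], path))
  }
  rownames(m) <- genes
  storage.mode(m) <- "double"
  validate_counts(m)
}

#' Write a count matrix as TSV and/or MatrixMarket
#'
#' @param counts gene-by-sample count matrix.
#' @param path output path; a `.mtx` extension selects MatrixMarket with
#'   `.rows`/`.cols` sidecars, anything else selects TSV with the gene id
#'   in a leading `gene` column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_counts(counts)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rows"))
    writeLines(colnames(counts), paste0(path, ".cols"))
  } else {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a sample annotation table
#'
#' CSV with columns `sample_id`, `batch`, `class` (classes `V`, `B`, `VB`,
#' `NI`).
#'
#' @param path file path.
#' @return Data frame with the three columns.
#' @export
read_sample_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "batch", "class")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample_id in annotation")
  bacterial_label(ann$class)  # validates class values
  ann[, need]
}

#' @rdname read_sample_annotation
#' @param annotation data frame to write.
#' @export
write_sample_annotation <- function(annotation, path) {
  utils::write.csv(annotation[, c("sample_id", "batch", "class")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a differential-expression result table as TSV
#'
#' @param de a `de_result` from [nb_wald_test()].
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  write.table(de[, c("gene", "baseMean", "log2FC", "se", "wald", "p", "q")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  de <- read.delim(path, stringsAsFactors = FALSE)
  class(de) <- c("de_result", "data.frame")
  de
}

#' Serialize / restore a fitted signature model as JSON
#'
#' The JSON records the selected genes, coefficients and intercept, the
#' per-gene transform constants, the chosen tuning parameters and the
#' coefficient scale, so a stored model is a pure function of new
#' expression data.
#'
#' @param model a `signature_model`.
#' @param path output path.
#' @export
write_signature_model <- function(model, path) {
  obj <- list(genes = model$genes,
              beta = unname(model$coefficients),
              intercept = model$intercept,
              center = unname(model$transform$center),
              scale = unname(model$transform$scale),
              lambda = model$tuning$lambda,
              gamma = model$tuning$gamma,
              tau = model$tuning$tau,
              inner_auc = model$tuning$inner_auc,
              sparsity_budget = model$tuning$sparsity_budget,
              coefficient_scale = model$coefficient_scale,
              n_features = model$n_features,
              n_samples = model$n_samples,
              pipeline_version = as.character(packageVersion("bactsig")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  genes <- as.character(obj$genes)
  structure(list(
    genes = genes,
    coefficients = setNames(as.numeric(obj$beta), genes),
    intercept = as.numeric(obj$intercept),
    transform = structure(list(gene = genes,
                               center = setNames(as.numeric(obj$center), genes),
                               scale = setNames(as.numeric(obj$scale), genes)),
                          class = "transform_spec"),
    tuning = list(lambda = obj$lambda, gamma = obj$gamma, tau = obj$tau,
                  inner_auc = obj$inner_auc,
                  sparsity_budget = obj$sparsity_budget),
    coefficient_scale = obj$coefficient_scale,
    n_features = obj$n_features, n_samples = obj$n_samples
  ), class = "signature_model")
}
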