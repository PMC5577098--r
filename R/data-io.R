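#' Construct an expression dataset
#'
#' Bundles a genes-by-samples expression matrix with a two-class phenotype
#' label per sample and the label designated "positive" for metric
#' computation. All downstream functions (`screen_de_genes()`,
#' `fit_pathway_ensemble()`, `evaluate_on_test()`, ...) take this container.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique row names (gene IDs) and column names (sample IDs). Values are
#'   assumed to be on an additive (log-like) scale; finiteness is enforced,
#'   the scale is not.
#' @param labels Named character vector mapping every sample ID to one of
#'   exactly two class labels, or `NULL` for an unlabeled matrix (as returned
#'   by [read_expression()] before labels are attached).
#' @param positive_label The class treated as "positive" when computing
#'   precision, sensitivity, specificity and F-score. Must be one of the two
#'   labels when labels are present.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `labels`, `positive_label`.
#'
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' lab <- setNames(rep(c("pCR", "RD"), 2), colnames(m))
#' expression_dataset(m, lab, positive_label = "pCR")
#' @export
expression_dataset <- function(values, labels = NULL, positive_label = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort("`values` must have gene IDs as row names and sample IDs as column names.")
  }
  if (anyDuplicated(gene_ids)) {
    abort(sprintf(
      "Duplicate gene ID(s): %s",
      paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(sample_ids)) {
    abort(sprintf(
      "Duplicate sample ID(s): %s",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")
    ))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "Non-finite expression value at gene '%s', sample '%s'. Missing values are not supported.",
      gene_ids[bad[1L]], sample_ids[bad[2L]]
    ))
  }
  if (!is.null(labels)) {
    if (is.null(names(labels))) abort("`labels` must be named by sample ID.")
    labels <- labels[sample_ids]
    if (anyNA(labels) || anyNA(names(labels))) {
      missing_ids <- setdiff(sample_ids, names(labels))
      abort(sprintf(
        "Missing label(s) for sample(s): %s",
        paste(head(missing_ids, 5L), collapse = ", ")
      ))
    }
    classes <- sort(unique(unname(labels)))
    if (length(classes) != 2L) {
      abort(sprintf(
        "Expected exactly 2 class labels, found %d: %s",
        length(classes), paste(classes, collapse = ", ")
      ))
    }
    if (any(table(labels) < 2L)) {
      abort("Each class must contain at least 2 samples.")
    }
    if (is.null(positive_label)) positive_label <- classes[1L]
    if (!positive_label %in% classes) {
      abort(sprintf(
        "`positive_label` '%s' is not one of the observed labels (%s).",
        positive_label, paste(classes, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      values = values,
      labels = if (is.null(labels)) NULL else as.character(labels) |> setNames(sample_ids),
      positive_label = positive_label
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %d genes x %d samples\n",
    nrow(x$values), ncol(x$values)
  ))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(sprintf(
      "  classes: %s (positive: %s)\n",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      x$positive_label
    ))
  } else {
    cat("  unlabeled\n")
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

sample_ids <- function(x) colnames(x$values)
gene_ids <- function(x) rownames(x$values)

# Subset an expression_dataset by sample index/ID, keeping labels aligned.
subset_samples <- function(x, idx) {
  expression_dataset(
    x$values[, idx, drop = FALSE],
    labels = if (is.null(x$labels)) NULL else x$labels[idx],
    positive_label = x$positive_label
  )
}

#' Read a gene expression matrix from tab-separated text
#'
#' The expected layout is the microarray convention: first row sample IDs,
#' first column gene IDs, numeric cells. Use `transpose = TRUE` for
#' samples-in-rows files.
#'
#' @param path Path to a TSV file.
#' @param transpose If `TRUE`, the file holds samples in rows and is
#'   transposed after reading.
#' @return An unlabeled [expression_dataset()] preserving the file's row and
#'   column order; attach labels with [read_labels()] and
#'   [label_dataset()].
#' @export
read_expression <- function(path, transpose = FALSE) {
  if (!file.exists(path)) abort(sprintf("Expression file not found: %s", path))
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "character", row.names = NULL)
  if (ncol(df) < 2L) abort("Expression file needs a gene-ID column plus at least one sample column.")
  ids <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                dimnames = dimnames(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
    if (nrow(bad) == 0L) bad <- which(is.na(num), arr.ind = TRUE)
    abort(sprintf(
      "Non-numeric cell at row %d (gene '%s'), column '%s'.",
      bad[1L, 1L], ids[bad[1L, 1L]], colnames(cells)[bad[1L, 2L]]
    ))
  }
  rownames(num) <- ids
  if (transpose) num <- t(num)
  expression_dataset(num)
}

#' Write an expression matrix to tab-separated text
#'
#' Inverse of [read_expression()]: first column `gene_id`, one column per
#' sample.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene_id = gene_ids(dataset), dataset$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read two-class phenotype labels
#'
#' @param path Two-column TSV (`sample_id`, `label`), no header required; a
#'   header line is detected and skipped when its second field equals
#'   `"label"`.
#' @param positive_label The class to treat as positive; must occur in the
#'   file.
#' @return Named character vector of labels with attribute
#'   `positive_label`.
#' @export
read_labels <- function(path, positive_label) {
  if (!file.exists(path)) abort(sprintf("Label file not found: %s", path))
  df <- read.delim(path, header = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) abort("Label file must have two tab-separated columns: sample_id, label.")
  if (nrow(df) > 0L && identical(tolower(df[[2L]][1L]), "label")) {
    df <- df[-1L, , drop = FALSE]
  }
  labels <- setNames(df[[2L]], df[[1L]])
  classes <- sort(unique(unname(labels)))
  if (length(classes) != 2L) {
    abort(sprintf(
      "Expected exactly 2 distinct labels, found %d: %s",
      length(classes), paste(classes, collapse = ", ")
    ))
  }
  if (!positive_label %in% classes) {
    abort(sprintf(
      "positive_label '%s' not present; observed labels: %s",
      positive_label, paste(classes, collapse = ", ")
    ))
  }
  attr(labels, "positive_label") <- positive_label
  labels
}

#' Write phenotype labels
#' @param labels Named character vector (sample ID -> label).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write.table(
    data.frame(sample_id = names(labels), label = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Attach labels to an unlabeled expression dataset
#'
#' @param dataset An [expression_dataset()], typically from
#'   [read_expression()].
#' @param labels Named character vector as returned by [read_labels()].
#' @param positive_label Positive class; defaults to the vector's
#'   `positive_label` attribute.
#' @return A labeled [expression_dataset()].
#' @export
label_dataset <- function(dataset, labels, positive_label = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  positive_label <- positive_label %||% attr(labels, "positive_label")
  expression_dataset(dataset$values, labels = labels,
                     positive_label = positive_label)
}

#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: each line is
#' `pathway_id <TAB> description <TAB> gene1 <TAB> gene2 ...`. Duplicate
#' genes within a line are deduplicated (first occurrence kept); a line whose
#' gene list is empty after deduplication is rejected.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: a named list of character vectors
#'   (pathway ID -> member genes), in file order, with a `pathway_names`
#'   attribute carrying the description field.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  descs <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      abort(sprintf(
        "GMT line %d: expected at least 3 tab-separated fields (id, description, >=1 gene).",
        i
      ))
    }
    ids[i] <- fields[1L]
    descs[i] <- fields[2L]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "Duplicate pathway ID(s) in GMT: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  names(sets) <- ids
  structure(sets, pathway_names = setNames(descs, ids),
            class = c("gene_set_collection", "list"))
}

#' Write gene sets to a GMT file
#' @param gene_sets Named list of character vectors (a
#'   `gene_set_collection`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  pn <- attr(gene_sets, "pathway_names") %||%
    setNames(names(gene_sets), names(gene_sets))
  lines <- vapply(names(gene_sets), function(id) {
    paste(c(id, pn[[id]] %||% id, gene_sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf(
    "<gene_set_collection> %d pathways, %d-%d genes each\n",
    length(x), min(sizes), max(sizes)
  ))
  invisible(x)
}

#' Write a fitted ensemble and its evaluation metrics to JSON
#'
#' Serializes the selected pathways, per-learner feature genes, the full
#' selection trace (accuracy order S, diversity order S*, prefix size m,
#' prefix S', final ensemble S'', pruning decisions, theta) and the metric
#' means/SDs. Round-trips through [read_results()].
#'
#' @param model A fitted `pathway_ensemble` from [fit_pathway_ensemble()].
#' @param metrics An `ensemble_metrics` object from [evaluate_on_test()], or
#'   `NULL` to write the model alone.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_results <- function(model, metrics, path) {
  stopifnot(inherits(model, "pathway_ensemble"))
  if (!is.null(metrics)) {
    if (!inherits(metrics, "ensemble_metrics") || nrow(metrics$runs) == 0L) {
      abort("`metrics` must be a non-empty ensemble_metrics object (or NULL).")
    }
  }
  tr <- model$trace
  out <- list(
    selected_pathways = names(model$learners),
    feature_genes = lapply(model$learners, function(l) l$feature_genes),
    trace = list(
      S = tr$S, S_star = tr$S_star, m = tr$m,
      S_prime = tr$S_prime, S_doubleprime = tr$S_doubleprime,
      theta = tr$theta,
      prefix_accuracies = tr$prefix_accuracies,
      removed_pairs = tr$removed_pairs
    ),
    metrics = if (is.null(metrics)) NULL else tidy(metrics)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read back a results JSON written by [write_results()]
#' @param path Path to the JSON file.
#' @return A list with elements `selected_pathways`, `feature_genes`,
#'   `trace`, `metrics`.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
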