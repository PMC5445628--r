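#' Construct an expression dataset
#'
#' Bundles a genes x samples matrix of log2-scale expression values with a
#' case/control label per sample. This is the input object for all profile
#' construction: z-scores are always computed against the `"control"` samples.
#'
#' @param values Numeric matrix, genes in rows (unique rownames = gene ids),
#'   samples in columns (unique colnames = sample ids). Values are expected on
#'   the log2 scale; see [read_expression()] for on-the-fly transformation.
#' @param labels Character or factor vector with values `"case"`/`"control"`.
#'   Either named by sample id or given in column order of `values`.
#' @return An object of class `peep_dataset`: a list with elements `values`
#'   and `labels` (named factor, levels `control`, `case`).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' d <- peep_dataset(m, c(s1 = "case", s2 = "case",
#'                        s3 = "control", s4 = "control"))
#' d
#' @export
peep_dataset <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (gene ids) and colnames (sample ids)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("`values` contains non-finite entries")
  labels <- as.character(labels)
  if (is.null(names(labels)) && length(labels) == ncol(values))
    names(labels) <- colnames(values)
  if (!all(colnames(values) %in% names(labels)))
    stop("samples without a label: ",
         paste(setdiff(colnames(values), names(labels)), collapse = ", "))
  labels <- labels[colnames(values)]
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad))
    stop("labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  labels <- factor(labels, levels = c("control", "case"))
  if (sum(labels == "control") < 2)
    stop("need at least 2 control samples to estimate a reference dispersion")
  structure(list(values = values, labels = labels), class = "peep_dataset")
}

#' @export
print.peep_dataset <- function(x, ...) {
  cat(sprintf("peep_dataset: %d genes x %d samples (%d cases, %d controls)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' @export
dim.peep_dataset <- function(x) dim(x$values)

#' Gene and sample identifiers of a dataset
#' @param data A `peep_dataset`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(data) rownames(data$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(data) colnames(data$values)

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix and its sample labels
#'
#' The matrix file is delimited text with a header row of sample ids and gene
#' ids in the first column; the labels file has two columns, sample id and
#' label (`case`/`control`), with an optional header. The delimiter is chosen
#' from the file extension (`.csv` = comma, anything else = tab). Samples are
#' intersected between the two files: matrix samples without a label are
#' dropped with a warning, labelled samples absent from the matrix are
#' ignored with a warning. Column order follows the matrix header.
#'
#' @param matrix_path Path to the expression matrix.
#' @param labels_path Path to the two-column label table.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to raw-scale input.
#'   The default assumes values are already log2-transformed.
#' @return A [peep_dataset()].
#' @export
read_expression <- function(matrix_path, labels_path, log2_transform = FALSE) {
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(labels_path)) stop("labels file not found: ", labels_path)
  sep <- .delim_for(matrix_path)
  tab <- utils::read.table(matrix_path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"")
  if (ncol(tab) < 2) stop("matrix file has no sample columns: ", matrix_path)
  ids <- as.character(tab[[1]])
  smp <- colnames(tab)[-1]
  if (anyDuplicated(smp))
    stop("duplicate sample id in matrix header: ",
         paste(unique(smp[duplicated(smp)]), collapse = ", "))
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(conv <- as.numeric(vals[[j]]))
      bad <- which(is.na(conv) & !is.na(vals[[j]]))[1]
      stop(sprintf("non-numeric value '%s' at row %d (gene '%s'), column '%s'",
                   vals[[j]][bad], bad, ids[bad], smp[j]))
    }
  }
  values <- as.matrix(vals)
  dimnames(values) <- list(ids, smp)

  lsep <- .delim_for(labels_path)
  lab <- utils::read.table(labels_path, sep = lsep, header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  if (ncol(lab) < 2) stop("labels file needs two columns (sample id, label)")
  if (nrow(lab) > 0 && !tolower(lab[1, 2]) %in% c("case", "control"))
    lab <- lab[-1, , drop = FALSE]  # header row
  labels <- stats::setNames(tolower(lab[[2]]), as.character(lab[[1]]))
  if (anyDuplicated(names(labels)))
    stop("duplicate sample id in labels file")

  extra <- setdiff(names(labels), smp)
  if (length(extra))
    warning("labels for samples not in the matrix ignored: ",
            paste(extra, collapse = ", "))
  missing <- setdiff(smp, names(labels))
  if (length(missing)) {
    warning("matrix samples without a label dropped: ",
            paste(missing, collapse = ", "))
    values <- values[, setdiff(smp, missing), drop = FALSE]
  }
  if (log2_transform) values <- log2(values + 1)
  peep_dataset(values, labels[colnames(values)])
}

#' Write an expression dataset back to delimited text
#'
#' Inverse of [read_expression()]; a read-write-read round trip reproduces
#' the values bit-exactly (values are printed with full precision).
#'
#' @param data A `peep_dataset`.
#' @param matrix_path,labels_path Output paths; delimiter chosen by extension.
#' @return Invisibly, `data`.
#' @export
write_expression <- function(data, matrix_path, labels_path) {
  sep <- .delim_for(matrix_path)
  df <- data.frame(gene_id = rownames(data$values), data$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     matrix_path, sep = sep, quote = FALSE, row.names = FALSE)
  ldf <- data.frame(sample_id = names(data$labels),
                    label = as.character(data$labels))
  utils::write.table(ldf, labels_path, sep = .delim_for(labels_path),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(data)
}

#' Collapse probe-level rows to gene level
#'
#' When several probes map to the same gene, the single probe row with the
#' highest mean expression across all samples is kept intact and relabelled
#' with the gene id; keeping one whole row (rather than a per-sample maximum)
#' preserves the within-row covariance structure. Probes without a mapping
#' are dropped.
#'
#' @param values Numeric matrix, probes x samples, with probe rownames.
#' @param probe_to_gene Named character vector mapping probe id to gene id,
#'   or a two-column data frame (probe, gene).
#' @return Numeric matrix with one row per mapped gene.
#' @export
collapse_probes <- function(values, probe_to_gene) {
  if (is.data.frame(probe_to_gene))
    probe_to_gene <- stats::setNames(as.character(probe_to_gene[[2]]),
                                     as.character(probe_to_gene[[1]]))
  if (length(probe_to_gene) == 0) stop("empty probe-to-gene mapping")
  if (anyDuplicated(names(probe_to_gene)))
    stop("a probe maps to more than one gene")
  probes <- intersect(rownames(values), names(probe_to_gene))
  if (length(probes) == 0) stop("no probe in `values` has a mapping")
  values <- values[probes, , drop = FALSE]
  genes <- probe_to_gene[probes]
  means <- rowMeans(values)
  keep <- vapply(split(seq_along(probes), genes),
                 function(idx) idx[which.max(means[idx])], integer(1))
  out <- values[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  out[order(rownames(out)), , drop = FALSE]
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: term id, description, then gene ids, tab-separated.
#' Genes repeated within a line are deduplicated; lines with fewer than three
#' fields are skipped with a warning; a duplicated term id is an error.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (one per term) with a
#'   `descriptions` attribute; class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      warning(sprintf("GMT line %d has fewer than 3 fields; skipped", i))
      next
    }
    if (f[1] %in% names(sets)) stop("duplicate term id in GMT: ", f[1])
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms (set sizes %s)\n", length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "-") else "-"))
  invisible(x)
}

#' Write perturbation profiles as a barcode matrix
#'
#' Writes a genes x subjects TSV of values in \{-1, 0, +1\} (down, absent,
#' up) together with a JSON sidecar recording the threshold and universe, and
#' reads it back.
#'
#' @param peeps A list of [new_peep()] objects.
#' @param universe Character vector of gene ids forming the rows.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return Invisibly, the barcode matrix.
#' @export
write_barcodes <- function(peeps, universe, path) {
  mat <- matrix(0L, length(universe), length(peeps),
                dimnames = list(universe,
                                vapply(peeps, `[[`, "", "subject_id")))
  for (p in peeps) {
    mat[intersect(p$up, universe), p$subject_id] <- 1L
    mat[intersect(p$down, universe), p$subject_id] <- -1L
  }
  df <- data.frame(gene_id = universe, mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  z_thresh <- unique(vapply(peeps, `[[`, 0, "z_thresh"))
  jsonlite::write_json(
    list(z_thresh = z_thresh, n_genes = length(universe),
         n_subjects = length(peeps)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(mat)
}

#' @rdname write_barcodes
#' @return `read_barcodes()`: a list of [new_peep()] objects.
#' @export
read_barcodes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  side <- paste0(path, ".json")
  z_thresh <- if (file.exists(side))
    jsonlite::read_json(side)$z_thresh else NA_real_
  lapply(colnames(mat), function(s)
    new_peep(s, rownames(mat)[mat[, s] > 0], rownames(mat)[mat[, s] < 0],
             z_thresh))
}
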