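#' @title Expression matrix I/O and validation
#' @name data_io
#' @description
#' Readers and writers for the pipeline's external formats: genes x samples
#' expression matrices (TSV or MatrixMarket), GMT gene set collections, and
#' clinical tables. Every reader validates into the package's domain types;
#' invalid input fails loudly rather than propagating silently.
NULL

#' Validate a genes x samples expression matrix
#'
#' Checks the invariants of the expression container: unique gene and sample
#' identifiers, all values finite and non-negative, at least 2 genes and 1
#' sample. Returns the matrix with class `ExpressionMatrix` prepended.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   complete dimnames.
#' @return the validated matrix, class `c("ExpressionMatrix", "matrix", ...)`.
#' @export
as_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (nrow(values) < 2L) stop("expression matrix needs at least 2 genes")
  if (ncol(values) < 1L) stop("expression matrix needs at least 1 sample")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("invalid expression value at gene '%s', sample '%s': %s",
                 rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]],
                 format(values[bad[1L, , drop = FALSE]])))
  }
  class(values) <- unique(c("ExpressionMatrix", class(values)))
  values
}

# Collapse duplicated gene rows by per-sample maximum (symbol-level convention).
collapse_duplicate_genes <- function(values) {
  dup <- duplicated(rownames(values))
  if (!any(dup)) return(values)
  dup_names <- unique(rownames(values)[dup])
  warning("collapsing ", length(dup_names), " duplicated gene row(s) by maximum: ",
          paste(utils::head(dup_names, 5L), collapse = ", "),
          if (length(dup_names) > 5L) ", ..." else "")
  grp <- factor(rownames(values), levels = unique(rownames(values)))
  out <- do.call(rbind, lapply(split(seq_len(nrow(values)), grp), function(ix) {
    apply(values[ix, , drop = FALSE], 2L, max)
  }))
  rownames(out) <- levels(grp)
  out
}

#' Read an expression matrix from TSV or MatrixMarket
#'
#' TSV layout: header row of sample identifiers, first column of gene symbols.
#' MTX layout: a MatrixMarket coordinate file plus sidecar text files listing
#' gene and sample identifiers, one per line. Duplicated gene rows are
#' collapsed by per-sample maximum with a warning.
#'
#' @param path path to the TSV or MTX file.
#' @param format `"tsv"` or `"mtx"`.
#' @param genes_path,samples_path sidecar identifier lists, required for MTX.
#' @return an [as_expression_matrix()]-validated `ExpressionMatrix`.
#' @export
read_expression <- function(path, format = c("tsv", "mtx"),
                            genes_path = NULL, samples_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("malformed expression TSV header in ", path)
    genes <- as.character(df[[1L]])
    values <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(values)) stop("non-numeric expression values in ", path)
    storage.mode(values) <- "double"
    rownames(values) <- genes
  } else {
    if (is.null(genes_path) || is.null(samples_path))
      stop("MTX input requires genes_path and samples_path sidecar files")
    m <- Matrix::readMM(path)
    genes <- readLines(genes_path)
    samples <- readLines(samples_path)
    if (nrow(m) != length(genes) || ncol(m) != length(samples))
      stop("MTX dimensions do not match sidecar identifier lists")
    values <- as.matrix(m)
    dimnames(values) <- list(genes, samples)
  }
  values <- collapse_duplicate_genes(values)
  as_expression_matrix(values)
}

#' Write an expression matrix as TSV
#'
#' @param expr `ExpressionMatrix`.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), as.data.frame(unclass(expr), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene set collection
#'
#' One set per line: `name TAB description TAB member TAB member ...`.
#' Member order is preserved; duplicate members within a set are dropped with
#' a warning. Lines with fewer than three fields are a parse error.
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors, class `GeneSetCollection`,
#'   with a `descriptions` attribute (named character).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    # sentinel keeps trailing empty fields (strsplit drops them)
    fields <- strsplit(paste0(lines[[i]], "\t."), "\t", fixed = TRUE)[[1L]]
    fields <- fields[-length(fields)]
    if (length(fields) < 3L)
      stop(sprintf("GMT parse error at line %d: fewer than 3 tab-separated fields", i))
    name <- fields[[1L]]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("GMT parse error at line %d: empty member list for set '%s'", i, name))
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': dropping %d duplicated member(s)",
                      name, sum(duplicated(members))))
      members <- members[!duplicated(members)]
    }
    if (name %in% names(sets)) stop("duplicate set name in GMT: ", name)
    sets[[name]] <- members
    desc[[name]] <- fields[[2L]]
  }
  as_gene_sets(sets, descriptions = desc)
}

#' Construct a validated gene set collection
#'
#' @param sets named list of character vectors (non-empty, no duplicates).
#' @param descriptions optional named character vector of free-text notes.
#' @return class `GeneSetCollection` list.
#' @export
as_gene_sets <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be a fully named list")
  if (anyDuplicated(names(sets))) stop("gene set names must be unique")
  for (nm in names(sets)) {
    if (length(sets[[nm]]) == 0L) stop("gene set '", nm, "' is empty")
    if (anyDuplicated(sets[[nm]])) stop("gene set '", nm, "' has duplicate members")
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions, class = c("GeneSetCollection", "list"))
}

#' Write a gene set collection as GMT
#'
#' @param sets `GeneSetCollection` (or plain named list).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else ""
    if (!nzchar(d)) d <- "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Default anatomic-site to sidedness mapping
#'
#' Right-side disease runs from the cecum to the transverse colon; left-side
#' from the splenic flexure to the rectum (rectal tumors are treated as
#' left-sided).
#'
#' @return named character vector mapping lower-case site labels to
#'   `"right"`/`"left"`.
#' @export
default_side_map <- function() {
  c(cecum = "right", ascending = "right", `hepatic flexure` = "right",
    transverse = "right",
    `splenic flexure` = "left", descending = "left", sigmoid = "left",
    rectum = "left",
    right = "right", left = "left")
}

#' Read and validate a clinical table
#'
#' Required columns: `sample_id`, `os_days` (non-negative integers, time to
#' the day), `event` (0 censored / 1 death from any cause), `side`. Side
#' labels are mapped through `side_map` (anatomic sites or right/left);
#' unrecognized labels become `"unknown"` with a warning. Extra columns
#' (mutation flags, stage) are carried through untouched.
#'
#' @param path TSV path.
#' @param side_map named character vector, see [default_side_map()].
#' @return a `data.frame` with class `ClinicalTable` prepended.
#' @export
read_clinical <- function(path, side_map = default_side_map()) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  as_clinical_table(df, side_map = side_map)
}

#' Validate a clinical data.frame
#'
#' @param df data.frame with the required clinical columns.
#' @inheritParams read_clinical
#' @return validated `ClinicalTable`.
#' @export
as_clinical_table <- function(df, side_map = default_side_map()) {
  required <- c("sample_id", "os_days", "event", "side")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("clinical table missing required column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table")
  od <- df$os_days
  if (!is.numeric(od) || any(!is.finite(od)) || any(od < 0) || any(od != round(od)))
    stop("os_days must be non-negative integers (days)")
  df$os_days <- as.integer(od)
  if (!all(df$event %in% c(0L, 1L)))
    stop("event must be 0 (censored) or 1 (death); offending values: ",
         paste(unique(df$event[!df$event %in% c(0L, 1L)]), collapse = ", "))
  df$event <- as.integer(df$event)
  raw_side <- tolower(trimws(as.character(df$side)))
  mapped <- unname(side_map[raw_side])
  unknown <- is.na(mapped) & raw_side != "unknown"
  if (any(unknown)) {
    warning("unrecognized side label(s) mapped to 'unknown': ",
            paste(unique(raw_side[unknown]), collapse = ", "))
  }
  mapped[is.na(mapped)] <- "unknown"
  df$side <- mapped
  class(df) <- unique(c("ClinicalTable", class(df)))
  df
}

#' Write a clinical table as TSV
#' @param clinical `ClinicalTable`.
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(as.data.frame(clinical), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Intersect an expression matrix with a clinical table
#'
#' Keeps exactly the samples present in both inputs, in the expression
#' matrix's column order restricted to the intersection. Order-independent
#' in content.
#'
#' @param expr `ExpressionMatrix`.
#' @param clinical `ClinicalTable`.
#' @return list with elements `expr` and `clinical`, sample-aligned.
#' @export
align_cohort <- function(expr, clinical) {
  keep <- intersect(colnames(expr), clinical$sample_id)
  if (length(keep) == 0L) stop("no samples shared between expression and clinical inputs")
  expr2 <- unclass(expr)[, keep, drop = FALSE]
  clin2 <- clinical[match(keep, clinical$sample_id), , drop = FALSE]
  rownames(clin2) <- NULL
  list(expr = as_expression_matrix(expr2), clinical = clin2)
}
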