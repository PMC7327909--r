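#' Construct and validate a count cohort
#'
#' The raw input of the whole pipeline: a genes x samples matrix of
#' non-negative integer counts, a per-gene role (endogenous or
#' housekeeping) and a per-sample diagnostic group (SN, AST or MST).
#' Library sizes are the column totals and are recomputed (and asserted)
#' on construction.
#'
#' @param counts genes x samples numeric matrix of non-negative integers,
#'   with unique rownames (gene ids) and colnames (sample ids).
#' @param group character/factor of length `ncol(counts)` assigning each
#'   sample to a group; conventionally `"SN"`, `"AST"`, `"MST"`.
#' @param gene_role per-gene role, `"endogenous"` or `"housekeeping"`;
#'   defaults to all endogenous.
#' @param gene_info optional data.frame of extra per-gene annotation
#'   (e.g. simulation ground truth), rownames matching the count matrix.
#' @return An object of class `count_cohort`: a list with elements
#'   `counts`, `gene_ids`, `gene_role`, `sample_ids`, `group`,
#'   `library_size` and (optionally) `gene_info`.
#' @export
count_cohort <- function(counts, group, gene_role = NULL, gene_info = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_param("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_param("duplicate gene identifiers in counts")
  if (anyDuplicated(colnames(counts)))
    stop_param("duplicate sample identifiers in counts")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop_param(sprintf(
      "counts must be non-negative integers; offending cell [%s, %s] = %s",
      rownames(counts)[i[1L]], colnames(counts)[i[2L]], counts[bad[1L]]))
  }
  group <- as.character(group)
  if (length(group) != ncol(counts))
    stop_param("group must have one label per sample")
  if (anyNA(group)) stop_param("every sample needs a group label")
  if (is.null(gene_role)) gene_role <- rep("endogenous", nrow(counts))
  gene_role <- as.character(gene_role)
  if (length(gene_role) != nrow(counts))
    stop_param("gene_role must have one entry per gene")
  if (!all(gene_role %in% c("endogenous", "housekeeping")))
    stop_param("gene_role must be 'endogenous' or 'housekeeping'")
  if (!is.null(gene_info)) {
    gene_info <- as.data.frame(gene_info)
    stopifnot(nrow(gene_info) == nrow(counts))
  }
  structure(list(
    counts = counts,
    gene_ids = rownames(counts),
    gene_role = setNames(gene_role, rownames(counts)),
    sample_ids = colnames(counts),
    group = setNames(group, colnames(counts)),
    library_size = colSums(counts),
    gene_info = gene_info
  ), class = "count_cohort")
}

#' @export
print.count_cohort <- function(x, ...) {
  cat(sprintf("count_cohort: %d genes (%d housekeeping) x %d samples\n",
              length(x$gene_ids), sum(x$gene_role == "housekeeping"),
              length(x$sample_ids)))
  print(table(x$group))
  cat(sprintf("library sizes: %d .. %d (median %s)\n",
              min(x$library_size), max(x$library_size),
              format(median(x$library_size))))
  invisible(x)
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a count matrix with its sample sheet
#'
#' The counts file is a genes x samples table (TSV, or CSV by extension)
#' whose first column holds gene ids and whose header holds sample ids.
#' The sample sheet must contain columns `sample_id` and `group` and
#' cover exactly the samples of the count matrix. An optional gene sheet
#' (columns `gene_id`, `role`, plus free annotation) assigns the
#' housekeeping flags.
#'
#' @param counts_path path to the counts table.
#' @param samples_path path to the sample sheet.
#' @param genes_path optional path to the gene sheet.
#' @return A [count_cohort()].
#' @export
read_counts <- function(counts_path, samples_path, genes_path = NULL) {
  tab <- read_table_auto(counts_path)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- as.character(tab[[1L]])
  if (!is.numeric(mat)) stop_param("non-numeric entries in ", counts_path)

  smp <- read_table_auto(samples_path)
  if (!all(c("sample_id", "group") %in% names(smp)))
    stop_param("sample sheet needs columns 'sample_id' and 'group'")
  missing_in_sheet <- setdiff(colnames(mat), smp$sample_id)
  missing_in_counts <- setdiff(smp$sample_id, colnames(mat))
  if (length(missing_in_sheet))
    stop_param("samples missing from sheet: ",
               paste(missing_in_sheet, collapse = ", "))
  if (length(missing_in_counts))
    stop_param("sheet samples absent from counts: ",
               paste(missing_in_counts, collapse = ", "))
  group <- smp$group[match(colnames(mat), smp$sample_id)]

  role <- NULL; ginfo <- NULL
  if (!is.null(genes_path)) {
    gen <- read_table_auto(genes_path)
    if (!all(c("gene_id", "role") %in% names(gen)))
      stop_param("gene sheet needs columns 'gene_id' and 'role'")
    if (!setequal(gen$gene_id, rownames(mat)))
      stop_param("gene sheet does not match the count matrix genes")
    gen <- gen[match(rownames(mat), gen$gene_id), , drop = FALSE]
    role <- gen$role
    extra <- setdiff(names(gen), c("gene_id", "role"))
    if (length(extra)) {
      ginfo <- gen[, extra, drop = FALSE]
      rownames(ginfo) <- gen$gene_id
    }
  }
  count_cohort(mat, group, gene_role = role, gene_info = ginfo)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then member gene ids.
#'
#' @param path path to a `.gmt` file.
#' @return An object of class `gene_set_collection`: a named list of
#'   character vectors with attribute `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), class = "gene_set_collection", source = path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop_param("GMT line ", short[1L], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop_param("duplicate set names in GMT")
  structure(sets, class = "gene_set_collection", source = path)
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
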