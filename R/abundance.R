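#' Construct an abundance table for one data source
#'
#' An abundance table holds the measurements of one data source (for
#' example a transcriptome or a proteome): a genes-by-samples numeric
#' matrix plus an optional phenotype label per sample. It is the input
#' to [build_correlation_network()] and [differential_integrate()].
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#'   Row names are gene identifiers, column names sample identifiers;
#'   both must be unique. Missing entries (`NA`) are allowed and are
#'   handled pairwise during correlation.
#' @param phenotype Optional phenotype assignment: either a named
#'   character vector (names are sample identifiers) or a data frame
#'   with columns `sample_id` and `phenotype`. Required for
#'   differential integration, where exactly two labels with at least
#'   three samples each must be present.
#' @param source_name Free-text name of the data source (e.g.
#'   `"transcriptome"`); carried through to networks and results.
#'
#' @return An object of class `abundance_table`.
#' @seealso [read_abundance()] to build one from delimited files.
#' @export
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' abundance_table(m, source_name = "transcriptome")
abundance_table <- function(values, phenotype = NULL, source_name = "source") {
  if (is.data.frame(values)) {
    values <- df_to_matrix(values)
  }
  if (!is.matrix(values)) {
    abort("`values` must be a matrix or a data frame with a gene-id first column.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene identifiers as row names and sample identifiers as column names.")
  }
  if (anyDuplicated(rownames(values))) {
    abort("Duplicated gene identifiers in abundance table.")
  }
  if (anyDuplicated(colnames(values))) {
    abort("Duplicated sample identifiers in abundance table.")
  }
  if (!is.numeric(values)) {
    bad <- which(!is.na(values) & is.na(suppressWarnings(array(as.numeric(values), dim(values)))),
                 arr.ind = TRUE)
    coord <- if (nrow(bad) > 0) {
      sprintf(" First offender: gene %s, sample %s.",
              rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]])
    } else ""
    abort(paste0("Abundance values must be numeric.", coord))
  }
  phenotype <- normalize_phenotype(phenotype, colnames(values))
  structure(
    list(
      gene_ids = rownames(values),
      sample_ids = colnames(values),
      values = values,
      phenotype = phenotype,
      source_name = source_name
    ),
    class = "abundance_table"
  )
}

normalize_phenotype <- function(phenotype, sample_ids) {
  if (is.null(phenotype)) return(NULL)
  if (is.data.frame(phenotype)) {
    if (!all(c("sample_id", "phenotype") %in% names(phenotype))) {
      abort("Phenotype metadata needs columns `sample_id` and `phenotype`.")
    }
    phenotype <- setNames(as.character(phenotype$phenotype),
                          as.character(phenotype$sample_id))
  }
  if (is.null(names(phenotype))) {
    abort("`phenotype` must be named by sample identifier.")
  }
  missing <- setdiff(sample_ids, names(phenotype))
  if (length(missing) > 0) {
    abort(sprintf("No phenotype label for sample(s): %s.",
                  paste(head(missing, 5), collapse = ", ")))
  }
  phenotype[sample_ids]
}

df_to_matrix <- function(df) {
  ids <- as.character(df[[1]])
  raw <- as.matrix(df[, -1, drop = FALSE])
  m <- suppressWarnings(array(as.numeric(raw), dim(raw), dimnames(raw)))
  bad <- which(!is.na(raw) & is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Abundance values must be numeric. First offender: gene %s, sample %s.",
                  ids[bad[1, 1]], colnames(raw)[bad[1, 2]]))
  }
  rownames(m) <- ids
  m
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %s: %d genes x %d samples\n",
              x$source_name, length(x$gene_ids), length(x$sample_ids)))
  if (!is.null(x$phenotype)) {
    tab <- table(x$phenotype)
    cat("  phenotypes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read an abundance table from delimited text
#'
#' The abundance file is TSV with gene identifiers in the first column
#' and one column per sample (header row holds sample identifiers). The
#' optional metadata file is TSV with columns `sample_id` and
#' `phenotype`.
#'
#' @param path Path to the abundance TSV.
#' @param metadata Optional path to the sample-metadata TSV.
#' @param source_name Data-source name recorded in the table.
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path, metadata = NULL, source_name = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  pheno <- NULL
  if (!is.null(metadata)) {
    pheno <- readr::read_tsv(metadata, col_types = readr::cols(), progress = FALSE)
  }
  abundance_table(df, phenotype = pheno,
                  source_name = source_name %||% basename(path))
}

#' Subset an abundance table to given samples or phenotypes
#'
#' For differential integration the abundance vector of each gene
#' concatenates the samples of both phenotypes in a fixed order: all
#' samples of the first label, then all samples of the second, each
#' block in original column order.
#'
#' @param table An [abundance_table()].
#' @param phenotypes Character vector of phenotype labels to retain
#'   (order defines the concatenation order).
#' @return An [abundance_table()] restricted to the selected samples.
#' @export
subset_phenotypes <- function(table, phenotypes) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$phenotype)) {
    abort("Abundance table has no phenotype labels.")
  }
  missing <- setdiff(phenotypes, unique(table$phenotype))
  if (length(missing) > 0) {
    abort(sprintf("Phenotype(s) %s absent from source '%s'.",
                  paste(missing, collapse = ", "), table$source_name))
  }
  keep <- unlist(lapply(phenotypes, function(ph) {
    which(table$phenotype == ph)
  }))
  abundance_table(table$values[, keep, drop = FALSE],
                  phenotype = table$phenotype[keep],
                  source_name = table$source_name)
}

#' Equalize sample counts across data sources
#'
#' Imbalanced sample counts between assays (e.g. more proteome than
#' transcriptome samples) can bias co-expression network inference
#' toward the better-sampled source. This sub-samples every table,
#' without replacement, so each phenotype retains the minimum count
#' observed for that phenotype across all tables.
#'
#' @param tables List of [abundance_table()] objects.
#' @param seed Integer seed; the selection is deterministic given the
#'   seed.
#' @return List of abundance tables with equalized per-phenotype counts.
#' @export
equalize_samples <- function(tables, seed) {
  stopifnot(length(tables) >= 2)
  labs <- lapply(tables, function(t) {
    if (is.null(t$phenotype)) setNames(rep("all", length(t$sample_ids)), t$sample_ids)
    else t$phenotype
  })
  common <- Reduce(intersect, lapply(labs, unique))
  if (length(common) == 0) abort("Tables share no phenotype label.")
  target <- vapply(common, function(ph) {
    min(vapply(labs, function(l) sum(l == ph), integer(1)))
  }, integer(1))
  with_seed(seed, {
    lapply(seq_along(tables), function(ti) {
      t <- tables[[ti]]
      l <- labs[[ti]]
      keep <- unlist(lapply(common, function(ph) {
        idx <- which(l == ph)
        if (length(idx) > target[[ph]]) sort(sample(idx, target[[ph]])) else idx
      }))
      keep <- sort(keep)
      abundance_table(t$values[, keep, drop = FALSE],
                      phenotype = if (is.null(t$phenotype)) NULL else t$phenotype[keep],
                      source_name = t$source_name)
    })
  })
}
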