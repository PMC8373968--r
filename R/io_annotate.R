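# Reading/writing expression matrices, annotation, probe maps and GMT
# gene-set collections; lncRNA biotype filtering; probe collapse.

#' Havana-style biotypes treated as lncRNA
#'
#' The lncRNA whitelist: lincRNA, antisense, 3-prime overlapping ncRNA,
#' bidirectional promoter lncRNA, misc RNA, processed transcript, sense
#' intronic and sense overlapping. Matching is performed on a canonical
#' form that is case-insensitive and ignores separator characters, so
#' dialects such as `"Sense_intronic"`, `"sense intronic"` and
#' `"sense-intronic"` are all recognised.
#'
#' @format character vector of canonical biotype tokens.
#' @seealso [filter_lncrna()], [canon_biotype()]
#' @export
LNCRNA_BIOTYPES <- c(
  "lincrna", "antisense", "3primeoverlappingncrna",
  "bidirectionalpromoterlncrna", "miscrna", "processedtranscript",
  "senseintronic", "senseoverlapping"
)

# Biotypes that are expected but not lncRNA; anything outside the union is
# "unknown" and gets flagged (kept, never dropped silently).
.known_other_biotypes <- c(
  "proteincoding", "pseudogene", "processedpseudogene",
  "unprocessedpseudogene", "rrna", "trna", "snrna", "snorna", "mirna",
  "tec", "retainedintron"
)

#' Canonicalise a biotype label
#'
#' Lower-cases and strips every non-alphanumeric character, collapsing the
#' spelling dialects (underscore / hyphen / space, mixed case) that
#' annotation tables mix freely.
#'
#' @param x character vector of biotype labels.
#' @return character vector of canonical tokens.
#' @export
canon_biotype <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Histological group labels understood by the pipeline
#' @format character vector (NT is the reference in every contrast).
#' @export
GROUP_LEVELS <- c("NT", "FA", "FTC", "fvPTC", "clPTC", "ATC")

#' Construct an expression dataset
#'
#' Bundles one platform's gene-by-sample matrix with its sample metadata.
#' Count matrices (platform `"rnaseq"`) must be non-negative integers with
#' no missing cells; microarray matrices hold real log2 intensities.
#'
#' @param values numeric gene-by-sample matrix with gene ids as rownames
#'   and sample ids as colnames.
#' @param samples data.frame with columns `sample_id` and `group`; one row
#'   per column of `values`, in the same order.
#' @param platform `"rnaseq"` or `"microarray"`.
#' @param dataset_id character scalar identifying the dataset.
#' @return an object of class `expression_dataset`: a list with fields
#'   `values`, `samples`, `platform`, `dataset_id`.
#' @export
expression_dataset <- function(values, samples, platform, dataset_id) {
  platform <- match.arg(platform, c("rnaseq", "microarray"))
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression matrix must have gene ids as rownames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup)) stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  if (!is.data.frame(samples) || !all(c("sample_id", "group") %in% names(samples)))
    stop("samples must be a data.frame with columns sample_id and group")
  if (nrow(samples) != ncol(values))
    stop("samples has ", nrow(samples), " rows but matrix has ", ncol(values), " columns")
  if (!is.null(colnames(values)) && !identical(colnames(values), as.character(samples$sample_id)))
    stop("column names of values do not match samples$sample_id")
  colnames(values) <- as.character(samples$sample_id)
  if (anyNA(samples$group) || any(!nzchar(as.character(samples$group))))
    stop("every sample must have exactly one group label")
  if (anyNA(values)) stop("missing cells are not allowed in an expression matrix")
  if (platform == "rnaseq") {
    bad <- which(values < 0 | values != round(values), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "non-integer or negative count at gene '%s', sample '%s' (value %s)",
        rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
        format(values[bad[1, , drop = FALSE]])
      ))
    }
  }
  structure(
    list(
      values = values,
      samples = data.frame(
        sample_id = as.character(samples$sample_id),
        group = as.character(samples$group),
        stringsAsFactors = FALSE
      ),
      platform = platform,
      dataset_id = as.character(dataset_id)
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset '%s'> platform=%s, %d genes x %d samples\n",
    x$dataset_id, x$platform, nrow(x$values), ncol(x$values)
  ))
  print(table(x$samples$group))
  invisible(x)
}

#' Read a gene-by-sample expression table with sample metadata
#'
#' The matrix file is tab-delimited with a header row of sample ids and a
#' first column of gene ids. The metadata file maps every sample id to a
#' group label (columns `sample_id`, `group`, optional `dataset_id`).
#'
#' @param path path to the expression TSV.
#' @param platform `"rnaseq"` (integer counts) or `"microarray"` (log2
#'   intensities).
#' @param metadata_path path to the sample metadata TSV.
#' @param dataset_id dataset identifier; defaults to the metadata's
#'   `dataset_id` column when present, otherwise the file name.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(path, platform, metadata_path, dataset_id = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs a gene id column plus >=1 sample")
  gene_ids <- as.character(tab[[1]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("metadata must have columns sample_id and group")
  missing <- setdiff(colnames(m), meta$sample_id)
  if (length(missing))
    stop("sample(s) missing from metadata: ", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  if (is.null(dataset_id)) {
    dataset_id <- if ("dataset_id" %in% names(meta)) meta$dataset_id[1] else basename(path)
  }
  expression_dataset(m, meta[, c("sample_id", "group")], platform, dataset_id)
}

#' Write an expression dataset (matrix + metadata) to TSV
#'
#' @param ds an [expression_dataset()].
#' @param path output path for the matrix TSV.
#' @param metadata_path optional output path for the sample metadata TSV.
#' @return invisibly, `path`.
#' @export
write_expression <- function(ds, path, metadata_path = NULL) {
  df <- data.frame(gene_id = rownames(ds$values), ds$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    meta <- cbind(ds$samples, dataset_id = ds$dataset_id)
    utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects columns `gene_id`, `symbol`, `biotype`. Unknown biotype labels
#' are preserved but flagged via a warning and the
#' `"unknown_biotypes"` attribute.
#'
#' @param path path to the annotation TSV.
#' @return data.frame with attribute `unknown_biotypes`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "biotype") %in% names(ann)))
    stop("annotation must have columns gene_id and biotype")
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(dup)) stop("duplicate gene id(s) in annotation: ", paste(dup, collapse = ", "))
  canon <- canon_biotype(ann$biotype)
  unknown <- sort(unique(ann$biotype[!(canon %in% c(LNCRNA_BIOTYPES, .known_other_biotypes))]))
  if (length(unknown))
    warning("unknown biotype label(s) preserved: ", paste(unknown, collapse = ", "))
  attr(ann, "unknown_biotypes") <- unknown
  ann
}

#' Restrict an expression dataset to lncRNA genes
#'
#' Keeps exactly the genes whose (canonicalised) biotype is on the lncRNA
#' whitelist; protein-coding and other non-lncRNA biotypes are removed.
#' The sample set is unchanged. An empty result is allowed (downstream
#' stages reject empties).
#'
#' @param ds an [expression_dataset()].
#' @param ann annotation data.frame with `gene_id` and `biotype`.
#' @return the filtered [expression_dataset()].
#' @export
filter_lncrna <- function(ds, ann) {
  absent <- setdiff(rownames(ds$values), ann$gene_id)
  if (length(absent))
    stop("gene(s) absent from annotation: ", paste(absent, collapse = ", "))
  biotype <- canon_biotype(ann$biotype[match(rownames(ds$values), ann$gene_id)])
  keep <- biotype %in% LNCRNA_BIOTYPES
  out <- ds
  out$values <- ds$values[keep, , drop = FALSE]
  out
}

#' Collapse a probe-by-sample matrix to gene level
#'
#' Probes absent from the probe map (i.e. not uniquely mapped) are
#' dropped. Genes measured by several probes are summarised by the
#' per-sample median of their probes' values.
#'
#' @param probe_matrix numeric probe-by-sample matrix, probe ids as
#'   rownames.
#' @param probe_map data.frame with columns `probe_id`, `gene_id`; each
#'   probe maps to exactly one gene.
#' @return numeric gene-by-sample matrix (genes sorted by id).
#' @export
collapse_probes <- function(probe_matrix, probe_map) {
  if (!all(c("probe_id", "gene_id") %in% names(probe_map)))
    stop("probe_map must have columns probe_id and gene_id")
  dup <- unique(probe_map$probe_id[duplicated(probe_map$probe_id)])
  if (length(dup)) stop("probe(s) mapped more than once: ", paste(dup, collapse = ", "))
  keep <- rownames(probe_matrix) %in% probe_map$probe_id
  if (!any(keep)) stop("no probe in the matrix is present in the probe map")
  m <- probe_matrix[keep, , drop = FALSE]
  gene <- probe_map$gene_id[match(rownames(m), probe_map$probe_id)]
  genes <- sort(unique(gene))
  idx <- split(seq_len(nrow(m)), gene)
  out <- matrix(NA_real_, length(genes), ncol(m),
                dimnames = list(genes, colnames(m)))
  for (g in genes) {
    i <- idx[[g]]
    out[g, ] <- if (length(i) == 1L) m[i, ] else apply(m[i, , drop = FALSE], 2, stats::median)
  }
  out
}

#' Read a probe map TSV (columns probe_id, gene_id)
#' @param path path to the TSV.
#' @return data.frame.
#' @export
read_probe_map <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(pm)))
    stop("probe map must have columns probe_id and gene_id")
  pm
}

#' Read a GMT gene-set collection
#'
#' GMT lines are tab-separated: term id, description, then member gene
#' ids. Duplicate members within a line are deduplicated (sets).
#'
#' @param path path to the GMT file.
#' @return a `gene_set_collection`: list with `sets` (named list of
#'   character vectors) and `term_names` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no gene sets in ", path)
  sets <- list()
  term_names <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("line %d of %s has %d field(s); need term, description, >=1 member",
                   i, path, length(f)))
    id <- f[1]
    if (id %in% names(sets)) stop("duplicate term id: ", id)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("line %d of %s has an empty member set", i, path))
    sets[[id]] <- members
    term_names[id] <- f[2]
  }
  structure(list(sets = sets, term_names = term_names),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param gsc a `gene_set_collection`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(id) {
    paste(c(id, gsc$term_names[[id]], gsc$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d terms, member counts %s\n",
              length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' Write a result table as tab-separated text with a header
#' @param x data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
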