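#' Read an OTU count table
#'
#' Wide format: TSV with `sample_id` in the first column and one integer
#' column per OTU. Sparse-triplet format: TSV with columns `otu_id`,
#' `sample_id`, `count`; omitted pairs are 0 (sample universe taken from the
#' triplets unless `sample_ids` is given).
#'
#' @param path TSV file path.
#' @param format `"wide"` or `"triplet"`.
#' @param taxonomy_path Optional TSV with columns `otu_id`, `lineage`.
#' @param sample_ids Optional full sample universe for triplet input.
#' @return An [otu_count_table()].
#' @export
read_otu_table <- function(path, format = c("wide", "triplet"),
                           taxonomy_path = NULL, sample_ids = NULL) {
  format <- match.arg(format)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "wide") {
    if (names(df)[1] != "sample_id") stop("wide OTU table must start with a sample_id column")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df$sample_id)
    if (!is.numeric(m)) stop("parse error: non-numeric count entries")
    bad <- which(m != round(m) | m < 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("parse error: invalid count at sample %s, OTU %s",
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
  } else {
    need <- c("otu_id", "sample_id", "count")
    if (!all(need %in% names(df))) stop("triplet OTU table needs otu_id, sample_id, count columns")
    if (any(df$count != round(df$count) | df$count < 0)) {
      stop("parse error: invalid count in triplet file")
    }
    sids <- sample_ids %||% sort(unique(as.character(df$sample_id)))
    oids <- sort(unique(as.character(df$otu_id)))
    m <- matrix(0L, length(sids), length(oids), dimnames = list(sids, oids))
    m[cbind(match(df$sample_id, sids), match(df$otu_id, oids))] <-
      as.integer(df$count)
  }
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- read.delim(taxonomy_path, stringsAsFactors = FALSE)
    lineage <- as.character(tx$lineage)
    lineage[is.na(lineage)] <- ""
    taxonomy <- setNames(lineage, tx$otu_id)
  }
  otu_count_table(m, taxonomy = taxonomy)
}

#' Write an OTU count table
#'
#' @param table An [otu_count_table()].
#' @param path Output TSV path.
#' @param format `"wide"` or `"triplet"` (BIOM-style sparse triplets:
#'   otu_id, sample_id, count, zero entries omitted).
#' @param taxonomy_path Optional path for a taxonomy TSV.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, format = c("wide", "triplet"),
                            taxonomy_path = NULL) {
  format <- match.arg(format)
  if (format == "wide") {
    df <- data.frame(sample_id = rownames(table$counts), table$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    nz <- which(table$counts > 0, arr.ind = TRUE)
    df <- data.frame(otu_id = colnames(table$counts)[nz[, 2]],
                     sample_id = rownames(table$counts)[nz[, 1]],
                     count = table$counts[nz],
                     stringsAsFactors = FALSE)
    df <- df[order(df$otu_id, df$sample_id), , drop = FALSE]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(taxonomy_path)) {
    write.table(data.frame(otu_id = names(table$taxonomy),
                           lineage = unname(table$taxonomy)),
                taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read/write a metabolite matrix
#'
#' TSV with `sample_id` first; empty cells or `NA` are missing values.
#'
#' @param path TSV path.
#' @param scale Transform state of the stored values.
#' @return A [metabolite_matrix()].
#' @export
read_metabolite_matrix <- function(path, scale = "raw") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  if (names(df)[1] != "sample_id") stop("metabolite table must start with a sample_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$sample_id)
  storage.mode(m) <- "double"
  metabolite_matrix(m, scale = scale)
}

#' @rdname read_metabolite_matrix
#' @param matrix A [metabolite_matrix()] to write (missing entries become
#'   empty cells).
#' @export
write_metabolite_matrix <- function(matrix, path) {
  df <- data.frame(sample_id = rownames(matrix$values), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read/write sample metadata
#'
#' TSV with columns `sample_id`, `treatment`, `core`, `replicate`.
#'
#' @param path TSV path.
#' @param treatments Allowed treatment labels; supply a different vector as a
#'   label map for non-default schemes.
#' @return A metadata `data.frame`.
#' @export
read_metadata <- function(path, treatments = c("D-W", "W-D", "Sat")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "treatment", "core", "replicate")
  if (!all(need %in% names(df))) {
    stop("metadata must have sample_id, treatment, core, replicate columns")
  }
  sample_metadata(df$sample_id, df$treatment, df$core, df$replicate,
                  treatments = treatments)
}

#' @rdname read_metadata
#' @param meta Metadata `data.frame` to write.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Writes `otus.tsv` (wide), `otus_sparse.tsv` (triplets), `taxonomy.tsv`,
#' `metabolites.tsv`, `metadata.tsv` and `truth.json`.
#'
#' @param dataset An `om_dataset` from [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(dataset$otus, file.path(outdir, "otus.tsv"), "wide",
                  taxonomy_path = file.path(outdir, "taxonomy.tsv"))
  write_otu_table(dataset$otus, file.path(outdir, "otus_sparse.tsv"), "triplet")
  write_metabolite_matrix(dataset$metabolites, file.path(outdir, "metabolites.tsv"))
  write_metadata(dataset$meta, file.path(outdir, "metadata.tsv"))
  truth <- dataset$truth
  truth$latent_log2 <- NULL  # large; regenerable from the config seed
  truth$treatment_effects <- as.data.frame(truth$treatment_effects)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
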