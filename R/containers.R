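#' OTU count table
#'
#' Container for a samples-by-OTUs matrix of non-negative integer counts from
#' 16S rRNA amplicon sequencing, with an optional taxonomy lineage string per
#' OTU. Samples are rows; OTUs are columns.
#'
#' @param counts Numeric matrix of non-negative integer counts with sample IDs
#'   as row names and OTU IDs as column names.
#' @param taxonomy Optional named character vector of lineage strings
#'   (phylum...genus, possibly partial), one per OTU. Missing entries default
#'   to `""`.
#' @return An object of class `otu_count_table` with elements `counts` and
#'   `taxonomy`.
#' @export
#' @examples
#' m <- matrix(c(0L, 3L, 1L, 0L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
#' otu_count_table(m)
otu_count_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("counts must carry sample IDs as rownames and OTU IDs as colnames")
  }
  if (ncol(counts) == 0 && is.null(colnames(counts))) {
    colnames(counts) <- character(0)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample IDs in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU IDs in counts")
  if (!is.numeric(counts) || anyNA(counts) || any(!is.finite(counts))) {
    stop("counts must be finite and non-missing")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  tax <- setNames(rep("", ncol(counts)), colnames(counts))
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) stop("taxonomy must be named by OTU ID")
    unknown <- setdiff(names(taxonomy), colnames(counts))
    if (length(unknown)) {
      stop("taxonomy names absent from count table: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    tax[names(taxonomy)] <- as.character(taxonomy)
  }
  structure(list(counts = counts, taxonomy = tax), class = "otu_count_table")
}

#' @export
print.otu_count_table <- function(x, ...) {
  cat(sprintf("<otu_count_table> %d samples x %d OTUs; %.1f%% zero entries\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(x$counts == 0)))
  invisible(x)
}

#' Metabolite abundance matrix
#'
#' Container for a samples-by-metabolites matrix of GC-MS abundances with
#' explicit missingness (`NA`) and a transform-state marker. The marker
#' enforces the one-way processing order raw -> log2 -> log2-centered.
#'
#' @param values Numeric matrix (samples in rows) with sample IDs as row names
#'   and metabolite IDs as column names; `NA` marks a missing observation.
#' @param scale One of `"raw"`, `"log2"`, `"log2-centered"`.
#' @param imputation_value Value used to fill missing entries, or `NULL` if no
#'   imputation has been applied.
#' @return An object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(values, scale = c("raw", "log2", "log2-centered"),
                              imputation_value = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry sample IDs as rownames and metabolite IDs as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample IDs")
  if (anyDuplicated(colnames(values))) stop("duplicate metabolite IDs")
  if (!is.numeric(values)) stop("values must be numeric")
  if (any(is.infinite(values))) stop("values must be finite or NA")
  if (scale == "raw" && any(values <= 0, na.rm = TRUE)) {
    stop("raw-scale abundances must be positive")
  }
  structure(list(values = values, scale = scale,
                 imputation_value = imputation_value),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("<metabolite_matrix> %d samples x %d metabolites; scale=%s; %.1f%% missing%s\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values)),
              if (is.null(x$imputation_value)) "" else
                sprintf("; imputed at %.7g", x$imputation_value)))
  invisible(x)
}

#' Sample metadata table
#'
#' Builds and validates the per-sample design table aligning the 16S and
#' metabolite blocks: moisture treatment, soil core, and technical replicate
#' index. Technical replicates are nested within cores, cores within
#' treatments.
#'
#' @param sample_id Character vector of unique sample IDs.
#' @param treatment Treatment label per sample.
#' @param core Soil-core ID per sample.
#' @param replicate Technical-replicate index per sample.
#' @param treatments Allowed treatment labels (factor level order).
#' @return A `data.frame` with columns `sample_id`, `treatment` (factor),
#'   `core`, `replicate`.
#' @export
sample_metadata <- function(sample_id, treatment, core, replicate,
                            treatments = c("D-W", "W-D", "Sat")) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample IDs in metadata")
  if (length(treatment) != length(sample_id) ||
      length(core) != length(sample_id) ||
      length(replicate) != length(sample_id)) {
    stop("metadata columns must have one entry per sample")
  }
  bad <- setdiff(unique(as.character(treatment)), treatments)
  if (length(bad)) {
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "))
  }
  data.frame(sample_id = sample_id,
             treatment = factor(as.character(treatment), levels = treatments),
             core = as.character(core),
             replicate = as.integer(replicate),
             stringsAsFactors = FALSE)
}

# Internal: assert a block's sample IDs match the metadata's, in order.
check_alignment <- function(block_ids, meta, what = "block") {
  if (!identical(as.character(block_ids), as.character(meta$sample_id))) {
    offenders <- union(setdiff(block_ids, meta$sample_id),
                       setdiff(meta$sample_id, block_ids))
    if (length(offenders) == 0) offenders <- "(same set, different order)"
    stop(sprintf("%s sample IDs are not aligned to metadata: %s", what,
                 paste(utils::head(offenders, 5), collapse = ", ")))
  }
  invisible(TRUE)
}
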