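#' Construct a read table (samples x OTU counts with metadata and registry)
#'
#' The analysis substrate: an integer count matrix whose rows are sequenced
#' samples and columns are OTUs, per-sample metadata (site, design, pooling
#' strategy, coordinates or composite membership, total reads), and an OTU
#' registry recording each OTU's origin (biological species or artefact with
#' its generating PCR).
#'
#' @param counts Integer matrix, samples x OTUs, with dimnames.
#' @param sample_meta data.frame with at least `sample_id`, `site`,
#'   `design`, `strategy`, `total_reads`; rows match `counts` rows.
#' @param otu_registry data.frame with `otu_id`, `origin`
#'   (`"biological"`/`"artefact"`), `parent`; covers all columns.
#' @return An object of class `read_table`.
#' @export
read_table <- function(counts, sample_meta, otu_registry) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  stopifnot(nrow(counts) == nrow(sample_meta),
            all(c("sample_id", "site", "design", "strategy", "total_reads")
                %in% names(sample_meta)))
  if (any(counts < 0)) stop("negative counts")
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicate sample ids")
  # drop never-observed OTU columns so every column is non-empty
  keep <- colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  if (!all(colnames(counts) %in% otu_registry$otu_id))
    stop("registry does not cover all OTUs")
  otu_registry <- otu_registry[otu_registry$otu_id %in% colnames(counts), ,
                               drop = FALSE]
  if (!isTRUE(all.equal(unname(rowSums(counts)),
                        as.numeric(sample_meta$total_reads))))
    stop("row sums must equal recorded total reads")
  rownames(counts) <- sample_meta$sample_id
  structure(list(counts = counts, sample_meta = sample_meta,
                 otu_registry = otu_registry),
            class = "read_table")
}

#' @export
print.read_table <- function(x, ...) {
  cat("Read table: ", nrow(x$counts), " samples x ", ncol(x$counts),
      " OTUs (", sum(x$otu_registry$origin == "artefact"),
      " artefactual), ", sum(x$counts), " reads\n", sep = "")
  invisible(x)
}

#' Subset a read table by sample metadata
#'
#' @param table A `read_table`.
#' @param site,design,strategy Optional values to keep (vectors allowed).
#' @param drop_empty_otus Drop OTU columns with zero reads after subsetting
#'   (default TRUE).
#' @return A `read_table`.
#' @export
subset_read_table <- function(table, site = NULL, design = NULL,
                              strategy = NULL, drop_empty_otus = TRUE) {
  stopifnot(inherits(table, "read_table"))
  keep <- rep(TRUE, nrow(table$counts))
  m <- table$sample_meta
  if (!is.null(site)) keep <- keep & m$site %in% site
  if (!is.null(design)) keep <- keep & m$design %in% design
  if (!is.null(strategy)) keep <- keep & m$strategy %in% strategy
  counts <- table$counts[keep, , drop = FALSE]
  meta <- m[keep, , drop = FALSE]
  if (drop_empty_otus) {
    nz <- colSums(counts) > 0
    counts <- counts[, nz, drop = FALSE]
  }
  reg <- table$otu_registry[table$otu_registry$otu_id %in% colnames(counts), ,
                            drop = FALSE]
  structure(list(counts = counts, sample_meta = meta, otu_registry = reg),
            class = "read_table")
}

#' Write / read the OTU table trio as TSV
#'
#' The on-disk dialect: an OTU-table TSV whose first column is `sample_id`
#' and remaining columns are OTU ids with integer cells; a sample-metadata
#' TSV joined on `sample_id`; an OTU-registry TSV. Validation is strict and
#' errors carry the offending row/column.
#'
#' @param table A `read_table`.
#' @param path Base path; writes `<path>_otu.tsv`, `<path>_meta.tsv`,
#'   `<path>_registry.tsv`.
#' @return `write_otu_table`: the base path, invisibly. `read_otu_table`:
#'   a `read_table`.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "read_table"))
  otu <- data.frame(sample_id = rownames(table$counts), table$counts,
                    check.names = FALSE)
  utils::write.table(otu, paste0(path, "_otu.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(table$sample_meta, paste0(path, "_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$otu_registry, paste0(path, "_registry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  otu <- utils::read.table(paste0(path, "_otu.tsv"), sep = "\t",
                           header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(otu)[1] != "sample_id") stop("first column must be sample_id")
  counts <- as.matrix(otu[, -1, drop = FALSE])
  if (!is.numeric(counts))
    stop("non-numeric count cells in OTU table")
  bad <- which(counts != floor(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("invalid count at row ", bad[1, 1], " (sample ",
         otu$sample_id[bad[1, 1]], "), column ", colnames(counts)[bad[1, 2]])
  rownames(counts) <- otu$sample_id
  meta <- utils::read.table(paste0(path, "_meta.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(otu$sample_id, meta$sample_id)
  if (length(missing))
    stop("metadata missing for sample(s): ", paste(missing, collapse = ", "))
  meta <- meta[match(otu$sample_id, meta$sample_id), , drop = FALSE]
  reg <- utils::read.table(paste0(path, "_registry.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  read_table(counts, meta, reg)
}
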