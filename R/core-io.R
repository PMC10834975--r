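#' Construct an expression matrix with sample metadata
#'
#' The central container of the pipeline: a non-negative numeric matrix of
#' features (mature miRNAs or genes) by samples, a sample sheet describing
#' each column (tissue/compartment, age, replicate, count unit), and an
#' explicit scale tag so that downstream stages can enforce their input
#' contracts.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param samples Data frame with columns \code{sample_id}, \code{tissue},
#'   \code{age}, \code{replicate} and optionally \code{count_unit}
#'   ("reads" or "UMI"); one row per matrix column, in column order.
#' @param scale One of \code{raw_count}, \code{tpm}, \code{log2tpm},
#'   \code{qnorm_log2tpm}, \code{relative_abundance}.
#' @param tissues,ages Allowed vocabulary; defaults to the five profiled
#'   tissues plus the Worm/EV compartments and ages D1/D8.
#' @return An object of class \code{ExpressionMatrix}.
#' @export
expression_matrix <- function(values, samples,
                              scale = c("raw_count", "tpm", "log2tpm",
                                        "qnorm_log2tpm", "relative_abundance"),
                              tissues = c(worm_tissues(), worm_compartments()),
                              ages = worm_ages()) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(samples$count_unit)) samples$count_unit <- "reads"
  required <- c("sample_id", "tissue", "age", "replicate", "count_unit")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(samples) != ncol(values)) {
    stop("sample sheet has ", nrow(samples), " rows but the matrix has ",
         ncol(values), " columns")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id in sample sheet: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  if (is.null(rownames(values))) stop("values must carry feature ids as rownames")
  if (anyDuplicated(rownames(values))) {
    stop("duplicated feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyNA(values)) stop("values contain NA")
  if (any(values < 0)) stop("values contain negative entries")
  check_vocab(samples$tissue, tissues, "tissue")
  check_vocab(samples$age, ages, "age")
  if (any(samples$replicate < 1)) stop("replicate must be >= 1")
  bad_unit <- setdiff(unique(samples$count_unit), c("reads", "UMI"))
  if (length(bad_unit) > 0) stop("unknown count_unit label: ", paste(bad_unit, collapse = ", "))
  colnames(values) <- samples$sample_id
  structure(list(values = values, samples = samples, scale = scale),
            class = "ExpressionMatrix")
}

check_vocab <- function(x, vocab, what) {
  bad <- setdiff(unique(x), vocab)
  if (length(bad) > 0) {
    stop("unknown ", what, " label: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(vocab, collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d features x %d samples\n",
              x$scale, nrow(x$values), ncol(x$values)))
  cat("  tissues:", paste(unique(x$samples$tissue), collapse = ", "), "\n")
  cat("  ages:   ", paste(unique(x$samples$age), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# %.17g survives a double -> text -> double round trip exactly
format_num <- function(x) sprintf("%.17g", x)

#' Read and write expression matrices and sample sheets
#'
#' Tables are TSV with a header row; the count table carries feature ids in
#' its first column and one column per sample; the sample sheet has columns
#' \code{sample_id}, \code{tissue}, \code{age}, \code{replicate},
#' \code{count_unit}. Matrix columns are reordered to follow the sample
#' sheet. Writing then reading reproduces values exactly (doubles are
#' serialized with 17 significant digits).
#'
#' @param path Path of the count TSV.
#' @param meta Path of the sample-sheet TSV.
#' @inheritParams expression_matrix
#' @return An \code{ExpressionMatrix}.
#' @export
read_expression_matrix <- function(path, meta,
                                   scale = "raw_count",
                                   tissues = c(worm_tissues(), worm_compartments()),
                                   ages = worm_ages()) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count table needs a feature-id column plus >=1 sample column")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric values in count table ", path)
  rownames(values) <- ids
  sheet <- read.delim(meta, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  missing_samples <- setdiff(sheet$sample_id, colnames(values))
  extra_samples <- setdiff(colnames(values), sheet$sample_id)
  if (length(missing_samples) > 0 || length(extra_samples) > 0) {
    stop("sample sheet and count-table columns disagree",
         if (length(missing_samples) > 0)
           paste0("; missing from table: ", paste(missing_samples, collapse = ", ")),
         if (length(extra_samples) > 0)
           paste0("; missing from sheet: ", paste(extra_samples, collapse = ", ")))
  }
  values <- values[, sheet$sample_id, drop = FALSE]
  expression_matrix(values, sheet, scale = scale, tissues = tissues, ages = ages)
}

#' @param x An \code{ExpressionMatrix}.
#' @param meta_path Optional path for the sample sheet; omitted when NULL.
#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  out <- data.frame(feature_id = rownames(x$values), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(x$values))) out[[colnames(x$values)[j]]] <- format_num(x$values[, j])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    write.table(x$samples, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read and write promoter-activity transcription maps
#'
#' Long-format TSV with columns \code{gene}, \code{tissue}, \code{age},
#' \code{call} (0/1). Combinations absent from the file default to FALSE (a
#' message reports how many were filled in). Unknown tissue or age labels
#' raise an error naming the offending token.
#'
#' @param path TSV path.
#' @param genes Optional gene universe; defaults to the genes present.
#' @param tissues,ages Allowed vocabulary. Transcription is only defined for
#'   the somatic tissues, not the Worm/EV compartments.
#' @return A \code{TranscriptionMap}: logical array gene x tissue x age.
#' @export
read_transcription_map <- function(path, genes = NULL,
                                   tissues = worm_tissues(),
                                   ages = worm_ages()) {
  tab <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) data.frame(gene = character(), tissue = character(),
                                   age = character(), call = integer())
  )
  if (nrow(tab) == 0) {
    warning("empty transcription map in ", path, "; all calls default to FALSE")
    if (is.null(genes)) genes <- character()
  } else {
    names(tab) <- tolower(names(tab))
    stopifnot(all(c("gene", "tissue", "age", "call") %in% names(tab)))
    check_vocab(tab$tissue, tissues, "tissue")
    check_vocab(tab$age, ages, "age")
    if (!all(tab$call %in% c(0, 1))) stop("transcription calls must be 0/1")
    if (is.null(genes)) genes <- unique(tab$gene)  # keep file order
  }
  calls <- array(FALSE, dim = c(length(genes), length(tissues), length(ages)),
                 dimnames = list(genes, tissues, ages))
  if (nrow(tab) > 0) {
    tab <- tab[tab$gene %in% genes, , drop = FALSE]
    calls[cbind(tab$gene, tab$tissue, tab$age)] <- tab$call == 1
    n_missing <- length(calls) - nrow(unique(tab[, c("gene", "tissue", "age")]))
    if (n_missing > 0) {
      message(n_missing, " (gene, tissue, age) combinations absent from ",
              path, " defaulted to FALSE")
    }
  }
  transcription_map(calls)
}

#' @param calls Logical array gene x tissue x age.
#' @param provenance Optional character vector per gene (e.g. reporter strain).
#' @rdname read_transcription_map
#' @export
transcription_map <- function(calls, provenance = NULL) {
  stopifnot(is.array(calls), length(dim(calls)) == 3, is.logical(calls))
  structure(list(calls = calls, provenance = provenance),
            class = "TranscriptionMap")
}

#' @param tmap A \code{TranscriptionMap}.
#' @rdname read_transcription_map
#' @export
write_transcription_map <- function(tmap, path) {
  stopifnot(inherits(tmap, "TranscriptionMap"))
  d <- dimnames(tmap$calls)
  long <- expand.grid(gene = d[[1]], tissue = d[[2]], age = d[[3]],
                      stringsAsFactors = FALSE)
  long$call <- as.integer(tmap$calls[cbind(long$gene, long$tissue, long$age)])
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.TranscriptionMap <- function(x, ...) {
  d <- dim(x$calls)
  cat(sprintf("TranscriptionMap: %d genes x %d tissues x %d ages (%d TRUE calls)\n",
              d[1], d[2], d[3], sum(x$calls)))
  invisible(x)
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers around Biostrings that return a plain named character
#' vector. Sequences are upper-cased and T is normalized to U, so mature
#' miRNA and 3'UTR sequences share the RNA alphabet used by the seed-site
#' matcher. Duplicate ids and empty sequences are errors.
#'
#' @param path FASTA path.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicated FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence in ", path, " for id: ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  names(seqs) <- ids
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad)) {
    stop("non-ACGU/T characters in sequences: ", paste(ids[bad], collapse = ", "))
  }
  seqs
}

#' @param seqs Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a miRNA annotation table
#'
#' MirGeneDB-style TSV with columns \code{mature_id}, \code{gene_id},
#' \code{family_id}, \code{arm} (3p/5p/unspecified),
#' \code{conserved_in_mammals} (0/1) and optionally \code{mature_sequence}.
#'
#' @param path TSV path.
#' @return Data frame, one row per mature miRNA.
#' @export
read_mirna_annotation <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("mature_id", "gene_id", "family_id", "arm", "conserved_in_mammals")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$mature_id)) stop("duplicated mature_id in annotation")
  bad_arm <- setdiff(unique(tab$arm), c("3p", "5p", "unspecified"))
  if (length(bad_arm) > 0) stop("unknown arm label: ", paste(bad_arm, collapse = ", "))
  tab$conserved_in_mammals <- as.logical(tab$conserved_in_mammals)
  tab
}
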