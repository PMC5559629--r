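#' OTU relative-abundance table
#'
#' OTU x sample matrix of relative abundances with OTU taxonomy lineages and
#' sample metadata (animal, sampling day). Every (animal, day) sample must
#' be nonnegative and sum to at most 1 (plus numerical slack).
#'
#' @param values numeric matrix, OTUs in rows, samples in columns.
#' @param otus data frame with columns `otu_id` and `taxonomy`
#'   (`domain;phylum;class;order;family;genus` lineage strings).
#' @param samples data frame with columns `sample_id`, `animal`, `day`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, otus, samples) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(otus)) stop("one otus row per value row required")
  if (ncol(values) != nrow(samples))
    stop("one samples row per value column required")
  if (anyDuplicated(otus$otu_id)) stop("otu ids must be unique")
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  if (any(values < 0)) stop("abundances must be nonnegative")
  cs <- colSums(values)
  if (any(cs > 1 + 1e-9))
    stop("sample ", samples$sample_id[which(cs > 1 + 1e-9)[1L]],
         " sums to more than 1")
  rownames(values) <- otus$otu_id
  colnames(values) <- samples$sample_id
  structure(list(values = values, otus = otus, samples = samples),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$values), "OTUs x", ncol(x$values),
      "samples (", length(unique(x$samples$animal)), "animals x",
      length(unique(x$samples$day)), "days )\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Subset an abundance table to a set of OTUs
#' @param t an [abundance_table()].
#' @param otu_ids OTU ids to retain (order preserved from the table).
#' @return An [abundance_table()].
#' @export
subset_otus <- function(t, otu_ids) {
  stopifnot(inherits(t, "abundance_table"))
  keep <- t$otus$otu_id %in% otu_ids
  abundance_table(t$values[keep, , drop = FALSE],
                  t$otus[keep, , drop = FALSE], t$samples)
}

#' Write / read an OTU table TSV
#'
#' Columns: `otu_id`, `taxonomy`, then one column per animal-day sample
#' named `<animal>_d<day>`.
#'
#' @param t an [abundance_table()].
#' @param path file path.
#' @return `write_otu_table()` invisibly returns `path`; `read_otu_table()`
#'   returns an [abundance_table()].
#' @export
write_otu_table <- function(t, path) {
  stopifnot(inherits(t, "abundance_table"))
  df <- data.frame(otu_id = t$otus$otu_id, taxonomy = t$otus$taxonomy,
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(t$values)
  colnames(vals) <- t$samples$sample_id
  write.table(cbind(df, vals), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("otu_id", "taxonomy") %in% colnames(df)[1:2]))
    stop("OTU table must start with otu_id and taxonomy columns")
  sample_ids <- colnames(df)[-(1:2)]
  m <- regmatches(sample_ids, regexec("^(.*)_d([0-9]+)$", sample_ids))
  if (any(lengths(m) != 3L))
    stop("sample columns must be named <animal>_d<day>")
  abundance_table(
    as.matrix(df[, -(1:2), drop = FALSE]),
    otus = df[, 1:2],
    samples = data.frame(sample_id = sample_ids,
                         animal = vapply(m, `[[`, "", 2L),
                         day = as.integer(vapply(m, `[[`, "", 3L)),
                         stringsAsFactors = FALSE))
}

#' Write / read a trait table TSV
#'
#' Rows are animals (first column `animal`), remaining columns are numeric
#' indices; missing values allowed.
#'
#' @param traits data frame as produced by [simulate_traits()].
#' @param path file path.
#' @return `write_trait_table()` invisibly returns `path`;
#'   `read_trait_table()` returns the data frame.
#' @export
write_trait_table <- function(traits, path) {
  write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "animal")
    stop("trait table must start with an 'animal' column")
  df
}

#' Sequence set
#'
#' Named nucleotide sequences (one per OTU, alphabet ACGTN) with optional
#' taxonomy lineages.
#'
#' @param seqs named character vector of sequences.
#' @param taxonomy optional named character vector of lineage strings.
#' @return An object of class `sequence_set`.
#' @export
sequence_set <- function(seqs, taxonomy = NULL) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named by OTU id")
  if (anyDuplicated(names(seqs))) stop("sequence ids must be unique")
  if (any(!nzchar(seqs))) stop("sequences must be nonempty")
  if (any(grepl("[^ACGTN]", seqs)))
    stop("sequences may contain only A, C, G, T, N")
  structure(list(seqs = seqs, taxonomy = taxonomy), class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("sequence_set:", length(x$seqs), "sequences, lengths",
      min(nchar(x$seqs)), "-", max(nchar(x$seqs)), "nt\n")
  invisible(x)
}

#' Write / read a sequence set as FASTA
#' @param s a [sequence_set()].
#' @param path FASTA path.
#' @param taxonomy optional named taxonomy to attach on read.
#' @return `write_fasta()` invisibly returns `path`; `read_fasta()` returns
#'   a [sequence_set()].
#' @export
write_fasta <- function(s, path) {
  stopifnot(inherits(s, "sequence_set"))
  x <- Biostrings::DNAStringSet(s$seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path, taxonomy = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  sequence_set(setNames(as.character(x), names(x)), taxonomy = taxonomy)
}
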