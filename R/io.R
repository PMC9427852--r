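#' Read a gene-level count or TPM matrix from TSV
#'
#' The expected layout is the one produced by featureCounts-style
#' summaries after tidying: first column `gene_id`, remaining columns one
#' per sample, header row of sample ids.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, genes x samples, gene ids as rownames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count matrix needs a gene_id column plus >= 1 sample")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  assert_count_matrix(m, basename(path))
  m
}

#' Write a matrix as TSV with a gene_id first column
#'
#' @param mat Numeric matrix with rownames.
#' @param path Output path.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Columns: sample_id, layer (transcriptome|translatome), stage, species,
#' replicate. (sample_id, layer) pairs must be unique.
#'
#' @param path Path to TSV.
#' @return data.frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  needed <- c("sample_id", "layer", "stage")
  if (!all(needed %in% names(df)))
    stop("sample sheet needs columns: ", paste(needed, collapse = ", "))
  bad <- !df$layer %in% c("transcriptome", "translatome")
  if (any(bad))
    stop("unknown layer value(s): ", paste(unique(df$layer[bad]), collapse = ", "))
  if (anyDuplicated(df[c("sample_id", "layer")]))
    stop("(sample_id, layer) pairs must be unique")
  df
}

#' Read a gene annotation table
#'
#' Columns: gene_id, gene_name, biotype, effective_length. The effective
#' length is the length (nt) used for TPM; typically the union-exon
#' length, but any transcript-model length can be supplied.
#'
#' @param path Path to TSV.
#' @return data.frame of gene annotation.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  assert_annotation(df)
  df
}

#' Derive a gene annotation table from a GTF file
#'
#' Minimal reader for Ensembl/GENCODE-style GTFs: effective length is the
#' union-exon length per gene (overlapping exons merged), biotype taken
#' from the `gene_biotype` or `gene_type` attribute, name from
#' `gene_name` (falling back to the id).
#'
#' @param path Path to an (uncompressed) GTF file.
#' @return data.frame with gene_id, gene_name, biotype, effective_length.
#' @export
read_gtf_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 9 && x[3] == "exon", logical(1))
  f <- f[keep]
  if (!length(f)) stop("no exon records found in ", path)
  attr_field <- vapply(f, `[[`, character(1), 9)
  grab <- function(key) {
    hit <- grepl(paste0(key, ' "'), attr_field, fixed = TRUE)
    val <- sub(paste0('.*', key, ' "([^"]*)".*'), "\\1", attr_field)
    ifelse(hit, val, NA_character_)
  }
  gene_id <- grab("gene_id")
  if (anyNA(gene_id)) stop("exon record without gene_id attribute")
  gene_name <- grab("gene_name")
  biotype <- grab("gene_biotype")
  alt <- grab("gene_type")
  biotype[is.na(biotype)] <- alt[is.na(biotype)]
  start <- as.integer(vapply(f, `[[`, character(1), 4))
  end <- as.integer(vapply(f, `[[`, character(1), 5))
  union_len <- function(i) {
    o <- order(start[i]); s <- start[i][o]; e <- end[i][o]
    tot <- 0L; cs <- s[1]; ce <- e[1]
    for (k in seq_along(s)[-1]) {
      if (s[k] <= ce + 1L) ce <- max(ce, e[k])
      else { tot <- tot + ce - cs + 1L; cs <- s[k]; ce <- e[k] }
    }
    tot + ce - cs + 1L
  }
  idx <- split(seq_along(gene_id), gene_id)
  data.frame(
    gene_id = names(idx),
    gene_name = vapply(idx, function(i) {
      nm <- gene_name[i][!is.na(gene_name[i])]
      if (length(nm)) nm[1] else gene_id[i[1]]
    }, character(1)),
    biotype = vapply(idx, function(i) {
      bt <- biotype[i][!is.na(biotype[i])]
      if (length(bt)) bt[1] else "other"
    }, character(1)),
    effective_length = vapply(idx, union_len, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Read 3'-UTR sequences from FASTA
#'
#' Headers are taken as gene ids (first whitespace-delimited token).
#' Sequences are uppercased and U is folded to T internally; both RNA and
#' DNA alphabets are accepted.
#'
#' @param path Path to an uncompressed FASTA file.
#' @return Named character vector of sequences (DNA alphabet, uppercase).
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids in ", path)
  seqs
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_utr_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a two-column homolog map
#'
#' @param path TSV with two columns: gene id in species A, homolog in B.
#' @return data.frame with columns a, b.
#' @export
read_homolog_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("homolog map needs two columns")
  names(df)[1:2] <- c("a", "b")
  df[1:2]
}
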