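# residues accepted in protein records: the 20 canonical letters plus X
.AA_OK <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"

#' Read a protein FASTA file
#'
#' Reads amino-acid sequences into an [Biostrings::AAStringSet]. Sequence ids
#' are the first whitespace-delimited token of each header; the remainder of
#' the header is kept as the description. Residues are uppercased and must be
#' drawn from the 20 canonical amino-acid letters plus `X` (ambiguous residue,
#' common in GenBank proteomes); gaps, stops and digits are rejected.
#'
#' @param path Path to a FASTA file.
#' @return An `AAStringSet` whose `names()` are the original headers. Use
#'   [seq_ids()] to extract the id tokens.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  xs <- Biostrings::readAAStringSet(path)
  if (length(xs) == 0L) stop("no records in FASTA file: ", path)
  xs <- Biostrings::AAStringSet(toupper(as.character(xs)))
  ids <- seq_ids(xs)
  if (any(ids == "")) stop("empty sequence id in FASTA file: ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  bad <- !grepl(.AA_OK, as.character(xs))
  if (any(bad)) {
    stop("invalid residues in record(s): ", paste(head(ids[bad], 5), collapse = ", "))
  }
  if (any(Biostrings::width(xs) < 1L)) stop("zero-length sequence record")
  xs
}

#' Sequence id tokens of a FASTA record set
#'
#' @param xs An `AAStringSet` as returned by [read_fasta()].
#' @return Character vector of ids (first whitespace-delimited header token).
#' @export
seq_ids <- function(xs) {
  sub("\\s.*$", "", names(xs))
}

#' Write a protein FASTA file
#'
#' @param xs An `AAStringSet`.
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(xs, path, width = 60L) {
  Biostrings::writeXStringSet(xs, filepath = path, width = width)
  invisible(path)
}

.CATEGORIES <- c("nine_exon_or", "other_or", "non_or")

#' Read gene models from a GFF3 annotation
#'
#' Imports a GFF3 file and keeps features of type `gene`, returning one row
#' per gene with 1-based inclusive coordinates exactly as annotated. Gene ids
#' come from the `ID` attribute. Genes absent from `category_map` are labelled
#' `non_or`.
#'
#' Strandless genes (`.` in GFF3) are rejected: tandem-array detection
#' requires orientation.
#'
#' @param path Path to a GFF3 file.
#' @param category_map Named character vector mapping gene id to one of
#'   `nine_exon_or`, `other_or`, `non_or`. When `NULL`, a `category`
#'   attribute present in the file (as written by [write_gff3()]) is used
#'   instead.
#' @return A data.frame with columns `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`, `category`.
#' @export
read_gff3 <- function(path, category_map = NULL) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(), scaffold = character(),
                      start = integer(), end = integer(), strand = character(),
                      category = character(), stringsAsFactors = FALSE))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    stop("strandless gene feature(s) (strand '.'): ",
         paste(head(gr$ID[strand == "*"], 5), collapse = ", "))
  }
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(ids == "")) stop("gene feature without ID attribute in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.null(category_map) && !is.null(gr$category) && !anyNA(gr$category)) {
    category_map <- setNames(as.character(gr$category), ids)
  }
  gene_models(
    gene_id = ids,
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand,
    category_map = category_map
  )
}

#' Construct a validated gene-model table
#'
#' @param gene_id,scaffold,start,end,strand Parallel vectors describing genes;
#'   coordinates are 1-based inclusive base pairs.
#' @param category_map Named character vector gene id -> category, or `NULL`
#'   (everything `non_or`).
#' @return data.frame of gene models.
#' @export
gene_models <- function(gene_id, scaffold, start, end, strand, category_map = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(start > end)) stop("invalid gene coordinates (need 1 <= start <= end)")
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (anyDuplicated(gene_id)) stop("duplicate gene id(s)")
  category <- rep("non_or", length(gene_id))
  if (!is.null(category_map)) {
    if (!all(category_map %in% .CATEGORIES)) {
      stop("unknown category value(s): ",
           paste(setdiff(unique(category_map), .CATEGORIES), collapse = ", "))
    }
    hit <- gene_id %in% names(category_map)
    category[hit] <- unname(category_map[gene_id[hit]])
  }
  data.frame(gene_id = as.character(gene_id), scaffold = as.character(scaffold),
             start = start, end = end, strand = as.character(strand),
             category = category, stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#'
#' Coordinates are written exactly as stored (1-based inclusive); a round trip
#' through [read_gff3()] reproduces them bit-exactly.
#'
#' @param genes data.frame from [read_gff3()] or [gene_models()].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "orstrat") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s;category=%s",
                     genes$scaffold, source, genes$start, genes$end,
                     genes$strand, genes$gene_id, genes$category))
  writeLines(lines, path)
  invisible(path)
}

.BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read similarity hits in 12-column BLAST tabular format
#'
#' Parses the standard `outfmt 6` dialect (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore) and resolves each
#' subject to its source species.
#'
#' @param path Path to a BLAST tabular file (may be empty).
#' @param species_of Named character vector mapping subject id to species.
#' @return A hit table (see [hit_table()]).
#' @export
read_blast_tab <- function(path, species_of) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) {
    return(hit_table(empty_hits()))
  }
  tab <- read.delim(path, header = FALSE, col.names = .BLAST_COLS,
                    colClasses = c(rep("character", 2), rep("numeric", 10)),
                    stringsAsFactors = FALSE)
  if (anyNA(tab$evalue) || anyNA(tab$bitscore)) stop("non-numeric evalue/bitscore in ", path)
  missing <- setdiff(unique(tab$sseqid), names(species_of))
  if (length(missing)) {
    stop("subject id(s) missing from species map: ", paste(head(missing, 5), collapse = ", "))
  }
  df <- data.frame(query_id = tab$qseqid, subject_id = tab$sseqid,
                   subject_species = unname(species_of[tab$sseqid]),
                   pident = tab$pident, length = tab$length,
                   mismatch = tab$mismatch, gapopen = tab$gapopen,
                   qstart = tab$qstart, qend = tab$qend,
                   sstart = tab$sstart, send = tab$send,
                   evalue = tab$evalue, bitscore = tab$bitscore,
                   stringsAsFactors = FALSE)
  hit_table(df)
}

#' Write a hit table in 12-column BLAST tabular format
#'
#' Numeric fields are printed at BLAST-like precision (`pident` to two
#' decimals, `evalue` in scientific notation, `bitscore` to one decimal) so a
#' read/write cycle is stable at the printed precision.
#'
#' @param hits A hit table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  if (nrow(hits) == 0L) { file.create(path); return(invisible(path)) }
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                   hits$query_id, hits$subject_id, hits$pident,
                   as.integer(hits$length), as.integer(hits$mismatch),
                   as.integer(hits$gapopen), as.integer(hits$qstart),
                   as.integer(hits$qend), as.integer(hits$sstart),
                   as.integer(hits$send), format(hits$evalue, scientific = TRUE, digits = 3),
                   hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a transcript count matrix with a sample-to-tissue map
#'
#' @param counts Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Values are raw (un-normalized) counts
#'   and may be fractional, as produced by pseudo-alignment.
#' @param tissue_of Named character vector mapping every sample id to a tissue
#'   label.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, tissue_of) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("duplicate gene or sample ids")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) stop("counts must be finite and >= 0")
  unmapped <- setdiff(colnames(counts), names(tissue_of))
  if (length(unmapped)) {
    stop("sample(s) without tissue label: ", paste(unmapped, collapse = ", "))
  }
  structure(list(counts = counts,
                 tissue_of = tissue_of[colnames(counts)]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", names(table(x$tissue_of)), table(x$tissue_of)),
                    collapse = ", ")))
  invisible(x)
}

#' Tissues present in a count matrix
#' @param counts A `count_matrix`.
#' @return Character vector of distinct tissue labels.
#' @export
tissues <- function(counts) unique(unname(counts$tissue_of))

#' Read transcript counts from disk
#'
#' Two layouts are supported: a single TSV with a `gene_id` column plus one
#' column per sample, or a set of per-sample two-column TSVs
#' (`target_id`, `est_count`), as written by pseudo-aligners. In the
#' per-sample layout the gene universe is the union across samples and genes
#' missing from a sample get count 0 (with a warning).
#'
#' @param path A single TSV path, or a named character vector of per-sample
#'   paths (names are the sample ids).
#' @param tissue_of Named character vector mapping sample id to tissue.
#' @return A `count_matrix`.
#' @export
read_counts <- function(path, tissue_of) {
  if (length(path) == 1L && is.null(names(path))) {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"gene_id" %in% names(tab)) stop("count TSV must have a gene_id column")
    m <- as.matrix(tab[setdiff(names(tab), "gene_id")])
    rownames(m) <- tab$gene_id
  } else {
    if (is.null(names(path)) || any(names(path) == "")) {
      stop("per-sample count files must be a named vector (names = sample ids)")
    }
    gone <- !file.exists(path)
    if (any(gone)) {
      stop("count file missing for sample(s): ", paste(names(path)[gone], collapse = ", "))
    }
    per <- lapply(path, function(p) {
      t <- read.delim(p, stringsAsFactors = FALSE)
      if (!all(c("target_id", "est_count") %in% names(t))) {
        stop("per-sample file needs columns target_id, est_count: ", p)
      }
      setNames(t$est_count, t$target_id)
    })
    genes <- sort(unique(unlist(lapply(per, names))))
    if (!all(vapply(per, function(v) setequal(names(v), genes), logical(1)))) {
      warning("per-sample gene sets differ; missing entries set to 0")
    }
    m <- vapply(per, function(v) {
      out <- setNames(numeric(length(genes)), genes)
      out[names(v)] <- v
      out
    }, numeric(length(genes)))
    colnames(m) <- names(path)
  }
  if (any(m < 0, na.rm = TRUE)) stop("negative count value")
  count_matrix(m, tissue_of)
}

#' Write a count matrix to a single TSV
#' @param counts A `count_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  tab <- data.frame(gene_id = rownames(counts$counts), counts$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
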