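# Similarity search: a deterministic local-alignment stand-in for external
# BLAST output, plus the per-species best-hit reduction used downstream.

#' Construct a hit table
#'
#' A hit table is a data.frame of similarity records with (at least) columns
#' `query_id`, `subject_id`, `subject_species`, `evalue`, `bitscore`. The
#' e-value threshold applied when it was produced, if any, is stored in the
#' `threshold_applied` attribute.
#'
#' @param records data.frame of hit records.
#' @param threshold_applied E-value threshold already applied, or `NULL`.
#' @return data.frame of class `hit_table`.
#' @export
hit_table <- function(records, threshold_applied = NULL) {
  need <- c("query_id", "subject_id", "subject_species", "evalue", "bitscore")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("hit table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) > 0) {
    if (any(records$evalue < 0)) stop("negative e-value")
    if (any(!nzchar(records$subject_species))) stop("empty subject species")
    if (!is.null(threshold_applied) && any(records$evalue > threshold_applied)) {
      stop("record exceeds threshold_applied")
    }
  }
  structure(as.data.frame(records, stringsAsFactors = FALSE),
            threshold_applied = threshold_applied,
            class = c("hit_table", "data.frame"))
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             subject_species = character(), evalue = numeric(),
             bitscore = numeric(), stringsAsFactors = FALSE)
}

.sub_matrix <- function(name) {
  known <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
             "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!name %in% known) stop("unknown substitution matrix: ", name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score under affine gap penalties: a gap of length
#' L costs `gap_open + L * gap_extend`. The empty alignment scores 0, so the
#' result is never negative. Deterministic; intended as a stand-in for
#' external blastp scores on synthetic panels.
#'
#' @param a,b Amino-acid sequences (character or `AAString`).
#' @param matrix Substitution matrix name (e.g. `"BLOSUM62"`).
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return Integer optimal local alignment score.
#' @export
local_align_score <- function(a, b, matrix = "BLOSUM62", gap_open = 10, gap_extend = 1) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  m <- .sub_matrix(matrix)
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = m, gapOpening = gap_open, gapExtension = gap_extend,
    scoreOnly = TRUE)
  max(0L, as.integer(round(s)))
}

#' Karlin-Altschul e-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * score)`. The default constants are the
#' usual gapped-BLOSUM62 convention; they are fixed for determinism — only
#' threshold-crossing behaviour matters downstream.
#'
#' @param score Alignment score.
#' @param m Query length (residues).
#' @param n Database length (total subject residues).
#' @param K,lambda Karlin-Altschul parameters, both > 0.
#' @return Expected number of chance alignments at or above `score`.
#' @export
score_to_evalue <- function(score, m, n, K = 0.041, lambda = 0.267) {
  stopifnot(m >= 1, n >= 1, K > 0, lambda > 0)
  K * m * n * exp(-lambda * score)
}

#' All-pairs similarity search over protein sets
#'
#' Scores every query against every subject with [local_align_score()],
#' converts scores to e-values with [score_to_evalue()] (database length =
#' total subject residues), and retains records with `E <= evalue_threshold`.
#' Exhaustive exact dynamic programming — no seeding or masking — suitable
#' for the small synthetic panels this package generates; real analyses feed
#' externally computed BLAST tabular files through [read_blast_tab()]
#' instead.
#'
#' @param queries,subjects `AAStringSet`s (see [read_fasta()]).
#' @param species_of Named character vector mapping subject id to species.
#' @param evalue_threshold Retention threshold, > 0 (default 1e-5).
#' @param matrix,gap_open,gap_extend Passed to [local_align_score()].
#' @return A `hit_table` with `threshold_applied` recorded.
#' @export
similarity_search <- function(queries, subjects, species_of,
                              evalue_threshold = 1e-5,
                              matrix = "BLOSUM62", gap_open = 10, gap_extend = 1) {
  if (evalue_threshold <= 0) stop("evalue_threshold must be > 0")
  if (length(subjects) == 0L) {
    warning("empty subject set")
    return(hit_table(empty_hits(), threshold_applied = evalue_threshold))
  }
  qid <- seq_ids(queries); sid <- seq_ids(subjects)
  miss <- setdiff(sid, names(species_of))
  if (length(miss)) stop("subject id(s) missing from species map: ",
                         paste(head(miss, 5), collapse = ", "))
  db_len <- sum(Biostrings::width(subjects))
  sub_mat <- .sub_matrix(matrix)
  recs <- vector("list", length(subjects))
  for (j in seq_along(subjects)) {
    sc <- Biostrings::pairwiseAlignment(
      queries, subjects[[j]], type = "local", substitutionMatrix = sub_mat,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
    sc <- pmax(0, round(sc))
    ev <- score_to_evalue(sc, m = Biostrings::width(queries), n = db_len)
    keep <- ev <= evalue_threshold
    if (any(keep)) {
      recs[[j]] <- data.frame(query_id = qid[keep], subject_id = sid[j],
                              subject_species = unname(species_of[sid[j]]),
                              evalue = ev[keep], bitscore = sc[keep],
                              stringsAsFactors = FALSE)
    }
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- if (length(recs)) do.call(rbind, recs) else empty_hits()
  out <- out[order(out$query_id, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  hit_table(out, threshold_applied = evalue_threshold)
}

#' Keep the best hit per (query, species)
#'
#' For every query and subject species, retains the single record with the
#' lowest e-value (the most significant hit). Ties are broken by higher
#' bitscore, then lexicographically smallest subject id, so the reduction is
#' deterministic. With `rank_by = "pident"` the record with the highest
#' percent identity is kept instead (gated by whatever e-value threshold was
#' applied upstream) — the ranking used when associating hand-annotated ORs
#' with reference proteins.
#'
#' @param hits A `hit_table`.
#' @param rank_by `"evalue"` (default) or `"pident"` (requires a `pident`
#'   column).
#' @return A `hit_table` with at most one record per (query, species);
#'   idempotent.
#' @export
best_hit_per_species <- function(hits, rank_by = c("evalue", "pident")) {
  rank_by <- match.arg(rank_by)
  if (nrow(hits) == 0L) return(hits)
  if (rank_by == "pident" && !"pident" %in% names(hits)) {
    stop("rank_by = 'pident' requires a pident column")
  }
  key <- paste(hits$query_id, hits$subject_species, sep = "\r")
  primary <- if (rank_by == "evalue") hits$evalue else -hits$pident
  ord <- order(key, primary, -hits$bitscore, hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- h[keep, , drop = FALSE]
  out <- out[order(out$query_id, out$subject_species), , drop = FALSE]
  rownames(out) <- NULL
  hit_table(out, threshold_applied = attr(hits, "threshold_applied"))
}
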