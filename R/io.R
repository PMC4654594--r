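#' Read a 3' UTR FASTA file
#'
#' Sequences are uppercased and `U` is transliterated to `T`; the record id
#' is the first whitespace-delimited token of the header. Only
#' `A`,`C`,`G`,`T`,`N` are accepted after normalisation.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_utr_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- gsub("U", "T", toupper(as.character(ss)), fixed = TRUE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in sequence(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "), call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA
#' @param seqs Named character vector, or a tibble with `gene_id` and `seq`.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_utr_fasta <- function(seqs, path, width = 70L) {
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs$seq, seqs$gene_id)
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Assemble a per-species UTR table
#'
#' The pipeline's canonical sequence container: one row per (species, gene),
#' as produced by reading one FASTA per species.
#'
#' @param ... Named arguments, one per species: each a named character
#'   vector of sequences (as from [read_utr_fasta()]).
#' @return Tibble with columns `species`, `gene_id`, `seq`.
#' @export
utr_table <- function(...) {
  colls <- list(...)
  if (is.null(names(colls)) || any(names(colls) == "")) {
    stop("each argument must be named by its species id", call. = FALSE)
  }
  dplyr::bind_rows(lapply(names(colls), function(sp) {
    tibble::tibble(species = sp, gene_id = names(colls[[sp]]),
                   seq = unname(colls[[sp]]))
  }))
}

#' Read a rooted phylogeny with branch lengths (newick)
#'
#' @param path Path to a newick file.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick in ", path, call. = FALSE)
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  if (is.null(tr$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tr$edge.length < 0)) stop("negative branch length in tree", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  invisible(tr)
}

#' Read an ortholog table
#'
#' Tab-delimited with columns `anchor`, `species`, `ortholog` (lines starting
#' with `#` are comments). Multiple rows per (anchor, species) are allowed;
#' a species absent for an anchor means "no ortholog" (a missing call).
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `anchor`, `species`, `ortholog`.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("anchor", "species", "ortholog")
  if (!all(need %in% names(df))) {
    stop("ortholog table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df[need])
}

#' Read a two-species ortholog pair map
#'
#' Tab-delimited, two columns (`gene_a`, `gene_b`); header optional.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `gene_a`, `gene_b`.
#' @export
read_pair_map <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          header = FALSE)
  if (identical(tolower(unlist(df[1, ])), c("gene_a", "gene_b"))) df <- df[-1, ]
  if (ncol(df) < 2L || nrow(df) == 0L) stop("pair map needs two columns", call. = FALSE)
  tibble::tibble(gene_a = as.character(df[[1]]), gene_b = as.character(df[[2]]))
}

#' Read degenerate motifs from a text file
#'
#' One bracket-notation motif per line. Blank lines separate collections;
#' within a collection, alternative member motifs may be given on separate
#' lines or joined with `" or "`. `U` is accepted and transliterated.
#'
#' @param path Path to the motif file.
#' @return List of `cons_motif_set` objects.
#' @export
read_motif_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!grepl("^#", lines)]
  blocks <- split(lines, cumsum(lines == ""))
  blocks <- lapply(blocks, function(b) b[b != ""])
  blocks <- blocks[vapply(blocks, length, integer(1)) > 0L]
  if (length(blocks) == 0L) stop("no motifs in ", path, call. = FALSE)
  lapply(blocks, function(b) {
    pats <- unlist(strsplit(b, "\\s+or\\s+", perl = TRUE))
    pats <- sub("^or\\s+", "", pats)
    do.call(motif_set, as.list(pats[pats != ""]))
  })
}

# tab-delimited writer with '#'-comment header lines (coordinates documented
# as 0-based half-open wherever offsets appear)
write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a presence matrix as TSV (1/0/NA)
#' @param calls Long tibble from [presence_calls()].
#' @param path Output path.
#' @export
write_presence_tsv <- function(calls, path) {
  wide <- tidyr::pivot_wider(calls, names_from = "species", values_from = "present")
  write_tsv_commented(wide, path,
                      c("presence calls: 1 = motif match, 0 = no match, NA = no ortholog"))
}

#' Write per-ortholog-set conservation results as TSV
#' @param results Tibble from [conservation_analysis()] / [tidy()].
#' @param path Output path.
#' @export
write_conservation_tsv <- function(results, path) {
  write_tsv_commented(results, path,
                      c("conservation scores (branch-length weighted) with permuted-motif FDR",
                        "fdr_raw uncapped; fdr capped at 1; conserved at the stated threshold"))
}
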