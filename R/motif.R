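#' Degenerate nucleotide motifs
#'
#' A degenerate motif is an ordered list of positions, each admitting a
#' non-empty set of nucleotides, written in bracket notation
#' (e.g. `"TGTA[ACT]ATA"`). RNA input (`U`) is transliterated to DNA (`T`)
#' on parse; lower case is accepted. A `.` position admits all four bases.
#'
#' @param x A bracket-notation string, or a list of character vectors
#'   (one non-empty subset of `A`,`C`,`G`,`T` per position).
#' @param label Optional free-text label.
#' @return A `cons_motif` object.
#' @examples
#' puf3 <- motif("TGTA[ACT]ATA", label = "Puf3")
#' motif_length(puf3)
#' @export
motif <- function(x, label = NULL) {
  if (is.character(x) && length(x) == 1L) {
    positions <- parse_bracket_notation(x)
  } else if (is.list(x)) {
    positions <- lapply(x, function(s) {
      s <- normalize_bases(s)
      if (length(s) == 0L) stop("motif position with empty nucleotide set", call. = FALSE)
      sort(unique(s))
    })
  } else {
    stop("`x` must be a bracket-notation string or a list of base sets", call. = FALSE)
  }
  if (length(positions) == 0L) stop("motif must have length >= 1", call. = FALSE)
  structure(list(positions = positions, label = label), class = "cons_motif")
}

normalize_bases <- function(s) {
  s <- toupper(as.character(s))
  s[s == "U"] <- "T"
  bad <- setdiff(s, c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    stop("invalid nucleotide(s) in motif: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  s
}

parse_bracket_notation <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      set <- character()
      while (j <= length(chars) && chars[j] != "]") {
        set <- c(set, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) stop("unbalanced '[' in motif: ", x, call. = FALSE)
      if (length(set) == 0L) stop("empty bracket class in motif: ", x, call. = FALSE)
      positions[[length(positions) + 1L]] <- sort(unique(normalize_bases(set)))
      i <- j + 1L
    } else if (ch == ".") {
      positions[[length(positions) + 1L]] <- c("A", "C", "G", "T")
      i <- i + 1L
    } else {
      positions[[length(positions) + 1L]] <- normalize_bases(ch)
      i <- i + 1L
    }
  }
  positions
}

#' @export
print.cons_motif <- function(x, ...) {
  cat("<motif> ", format(x), if (!is.null(x$label)) paste0("  (", x$label, ")"), "\n", sep = "")
  invisible(x)
}

#' @export
format.cons_motif <- function(x, ...) {
  paste(vapply(x$positions, function(s) {
    if (length(s) == 4L) "." else if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' @export
as.character.cons_motif <- function(x, ...) format(x)

#' Motif length in nucleotides
#' @param m A `cons_motif` or `cons_motif_set`.
#' @return Integer length (for a set, the common length, or `NA` if mixed).
#' @export
motif_length <- function(m) {
  if (inherits(m, "cons_motif")) return(length(m$positions))
  if (inherits(m, "cons_motif_set")) {
    lens <- unique(vapply(m$motifs, function(x) length(x$positions), integer(1)))
    return(if (length(lens) == 1L) lens else NA_integer_)
  }
  stop("not a motif object", call. = FALSE)
}

#' Collections of alternative motifs
#'
#' A collection matches a sequence if at least one member motif matches.
#' Several of the regular expressions characterising one binding specificity
#' are alternatives of equal length (e.g. the two Saccharomycotina Puf4
#' motifs), and position permutation is applied jointly to all members.
#'
#' @param ... `cons_motif` objects or bracket-notation strings.
#' @param label Optional label for the collection.
#' @return A `cons_motif_set`.
#' @examples
#' puf4 <- motif_set("TGTA[ACT]A[ACT]TA", "TGTA[ACT][ACT]ATA", label = "Puf4")
#' @export
motif_set <- function(..., label = NULL) {
  motifs <- lapply(list(...), function(m) if (inherits(m, "cons_motif")) m else motif(m))
  if (length(motifs) == 0L) stop("motif collection must be non-empty", call. = FALSE)
  structure(list(motifs = motifs, label = label), class = "cons_motif_set")
}

#' @export
print.cons_motif_set <- function(x, ...) {
  cat("<motif collection", if (!is.null(x$label)) paste0(" '", x$label, "'"), "> ",
      paste(vapply(x$motifs, format, character(1)), collapse = " or "), "\n", sep = "")
  invisible(x)
}

as_motif_set <- function(m) {
  if (inherits(m, "cons_motif_set")) return(m)
  if (inherits(m, "cons_motif")) return(structure(list(motifs = list(m), label = m$label),
                                                  class = "cons_motif_set"))
  if (is.character(m)) return(do.call(motif_set, as.list(m)))
  stop("cannot interpret as a motif collection", call. = FALSE)
}

# PCRE for one motif; N never matches because classes enumerate only ACGT.
motif_regex <- function(m) {
  paste(vapply(m$positions, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Scan a sequence for all (overlapping) motif matches
#'
#' Slides the motif along the sequence and reports every window where each
#' position's base belongs to the motif's set at that position. `N` bases
#' never match. Overlapping matches are all reported.
#'
#' @param seq A single DNA string over `A`,`C`,`G`,`T`,`N` (case-insensitive,
#'   `U` accepted as `T`).
#' @param m A `cons_motif` (or bracket-notation string).
#' @return A tibble with columns `start` (0-based offset) and `match`
#'   (the matched substring). Empty sequence gives zero rows.
#' @examples
#' scan_sequence("ACTGTACATAGG", motif("TGTA[ACT]ATA"))
#' @export
scan_sequence <- function(seq, m) {
  if (inherits(m, "cons_motif_set")) {
    hits <- dplyr::bind_rows(lapply(m$motifs, function(mm) scan_sequence(seq, mm)))
    return(dplyr::arrange(dplyr::distinct(hits), .data$start))
  }
  if (!inherits(m, "cons_motif")) m <- motif(m)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  len <- length(m$positions)
  if (nchar(seq) < len) {
    return(tibble::tibble(start = integer(), match = character()))
  }
  # lookahead capture reports overlapping windows
  re <- paste0("(?=(", motif_regex(m), "))")
  g <- gregexpr(re, seq, perl = TRUE)[[1]]
  if (g[1] == -1L) {
    return(tibble::tibble(start = integer(), match = character()))
  }
  starts <- as.integer(g)
  tibble::tibble(start = starts - 1L,
                 match = substring(seq, starts, starts + len - 1L))
}

#' Which sequences contain at least one match to a collection?
#'
#' Vectorised presence screen used throughout the pipeline: a sequence
#' "matches the collection" iff it matches at least one member motif.
#'
#' @param seqs Character vector of DNA sequences (names preserved).
#' @param m A `cons_motif`, `cons_motif_set`, or bracket-notation string(s).
#' @return Named logical vector.
#' @export
seq_has_match <- function(seqs, m) {
  m <- as_motif_set(m)
  seqs <- gsub("U", "T", toupper(seqs), fixed = TRUE)
  out <- rep(FALSE, length(seqs))
  for (mm in m$motifs) {
    out <- out | grepl(motif_regex(mm), seqs, perl = TRUE)
  }
  names(out) <- names(seqs)
  out
}

#' Enumerate position permutations of a motif collection
#'
#' Positions are reordered jointly: the same reordering is applied to every
#' member of the collection, so a two-motif collection keeps its redundant
#' structure under permutation. A bracketed class travels as a single
#' indivisible symbol. Reorderings that reproduce an identical collection
#' (including the original ordering) are excluded, so the count equals the
#' multinomial coefficient of the joint position-symbol multiset minus one.
#'
#' @param m Motif or collection (members must share one length).
#' @param max_count `"all"` (default) or an integer; when fewer than the
#'   total are requested, a seeded uniform sample without replacement.
#' @param seed Optional integer seed for the sample.
#' @return List of `cons_motif_set` objects.
#' @examples
#' length(permute_motif(motif("TGTA[ACT]ATA"))) # 1119
#' @export
permute_motif <- function(m, max_count = "all", seed = NULL) {
  ms <- as_motif_set(m)
  lens <- vapply(ms$motifs, function(x) length(x$positions), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all motifs in the collection must have the same length to permute jointly",
         call. = FALSE)
  }
  L <- lens[1]
  if (L == 1L) return(list())

  # joint symbol at position i: the tuple of member sets at i
  key_of <- function(i) paste(vapply(ms$motifs, function(mm)
    paste(mm$positions[[i]], collapse = ""), character(1)), collapse = "|")
  keys <- vapply(seq_len(L), key_of, character(1))
  ukeys <- sort(unique(keys))
  counts <- as.integer(table(factor(keys, levels = ukeys)))
  total <- multinomial_count(counts)

  build_set <- function(key_seq) {
    # any original index with a given key carries identical sets for all members
    idx_for_key <- match(key_seq, keys)
    motifs <- lapply(seq_along(ms$motifs), function(k) {
      structure(list(positions = lapply(idx_for_key, function(i)
        ms$motifs[[k]]$positions[[i]]), label = NULL), class = "cons_motif")
    })
    structure(list(motifs = motifs, label = NULL), class = "cons_motif_set")
  }

  want_all <- identical(max_count, "all")
  n_want <- if (want_all) total - 1 else min(as.integer(max_count), total - 1)
  if (n_want <= 0) return(list())

  gen <- function() {
    if (total <= 2e5) {
      seqs <- multiset_permutations(ukeys, counts)
      seqs <- seqs[vapply(seqs, function(s) !identical(s, keys), logical(1))]
      if (!want_all && n_want < length(seqs)) {
        seqs <- seqs[sample.int(length(seqs), n_want)]
      }
      seqs
    } else {
      # space too large to enumerate: rejection-sample distinct orderings
      seen <- new.env(hash = TRUE)
      out <- vector("list", n_want)
      got <- 0L; tries <- 0L
      while (got < n_want && tries < 200L * n_want) {
        tries <- tries + 1L
        s <- keys[sample.int(L)]
        id <- paste(s, collapse = "\r")
        if (identical(s, keys) || !is.null(seen[[id]])) next
        seen[[id]] <- TRUE
        got <- got + 1L
        out[[got]] <- s
      }
      out[seq_len(got)]
    }
  }
  seqs <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  lapply(seqs, build_set)
}

multinomial_count <- function(counts) {
  n <- sum(counts)
  exp(lgamma(n + 1) - sum(lgamma(counts + 1)))
}

# all distinct permutations of a multiset given unique symbols + their counts
multiset_permutations <- function(symbols, counts) {
  n <- sum(counts)
  out <- list()
  rec <- function(prefix, counts) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (k in seq_along(symbols)) {
      if (counts[k] > 0L) {
        counts[k] <- counts[k] - 1L
        rec(c(prefix, symbols[k]), counts)
        counts[k] <- counts[k] + 1L
      }
    }
  }
  rec(character(), counts)
  out
}

#' Derive a regular-expression motif from a set of k-mers
#'
#' A nucleotide is included in the derived motif at a position if it occurs
#' in strictly more than `threshold` (default 10%) of the (weighted) k-mers;
#' a base at exactly the threshold is excluded.
#'
#' @param kmers Character vector of equal-length k-mers.
#' @param weights Optional non-negative weights (e.g. per-k-mer match counts).
#' @param threshold Frequency threshold (strict inequality), default `0.10`.
#' @param label Optional label for the derived motif.
#' @return A `cons_motif`.
#' @examples
#' derive_regex(c("TGTAAATA", "TGTACATA", "TGTATATA"))
#' @export
derive_regex <- function(kmers, weights = NULL, threshold = 0.10, label = NULL) {
  stopifnot(length(kmers) >= 1L)
  pfm <- position_freq_matrix(kmers, weights)
  freqs <- sweep(pfm, 2, colSums(pfm), "/")
  positions <- lapply(seq_len(ncol(freqs)), function(j) {
    rownames(freqs)[freqs[, j] > threshold]
  })
  motif(positions, label = label)
}

#' Position frequency matrix of a k-mer set
#'
#' @inheritParams derive_regex
#' @return A 4 x L numeric matrix with rows `A`,`C`,`G`,`T` of (weighted)
#'   occurrence counts per position.
#' @export
position_freq_matrix <- function(kmers, weights = NULL) {
  kmers <- gsub("U", "T", toupper(kmers), fixed = TRUE)
  L <- unique(nchar(kmers))
  if (length(L) != 1L) stop("k-mers must share one length", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(kmers))
  stopifnot(length(weights) == length(kmers), all(weights >= 0))
  mat <- matrix(0, nrow = 4, ncol = L, dimnames = list(c("A", "C", "G", "T"), NULL))
  chars <- matrix(unlist(strsplit(kmers, "")), ncol = L, byrow = TRUE)
  for (b in rownames(mat)) {
    mat[b, ] <- colSums((chars == b) * weights)
  }
  mat
}
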