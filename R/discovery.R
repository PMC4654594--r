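#' Mutual information of a 2 x 2 joint count table (bits)
#'
#' MI = sum over cells of p_ij * log2(p_ij / (p_i * p_j)), with 0 * log(0/x)
#' defined as 0. Here the margins are in-group vs out-group membership and
#' k-mer match vs no match.
#'
#' @param a,b,c,d Counts: `a` = in-group with match, `b` = in-group without,
#'   `c` = out-group with, `d` = out-group without. Alternatively `a` may be
#'   a 2 x 2 matrix. All arguments may be equal-length vectors for a
#'   vectorised computation.
#' @return Mutual information in bits (vectorised).
#' @examples
#' mutual_information(50, 0, 0, 50) # 1 bit
#' @export
mutual_information <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  n <- a + b + c + d
  stopifnot(all(n > 0))
  term <- function(x, rm, cm) {
    out <- numeric(length(x))
    pos <- x > 0
    out[pos] <- (x[pos] / n[pos]) *
      log2((x[pos] * n[pos]) / (rm[pos] * cm[pos]))
    out
  }
  if (length(n) == 1L) {
    a <- rep_len(a, 1); b <- rep_len(b, 1); c <- rep_len(c, 1); d <- rep_len(d, 1)
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  term(a, r1, c1) + term(b, r1, c2) + term(c, r2, c1) + term(d, r2, c2)
}

# all k-mers beginning with `anchor` occurring in a sequence (overlapping,
# windows containing N dropped); returns unique k-mers
anchored_kmers <- function(seq, anchor = "TGTA", k = 10L) {
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  g <- gregexpr(paste0("(?=", anchor, ")"), seq, perl = TRUE)[[1]]
  if (g[1] == -1L) return(character())
  starts <- as.integer(g)
  starts <- starts[starts + k - 1L <= nchar(seq)]
  if (length(starts) == 0L) return(character())
  kms <- substring(seq, starts, starts + k - 1L)
  unique(kms[!grepl("N", kms, fixed = TRUE)])
}

#' Iterative anchored k-mer search by mutual information with masking
#'
#' Greedy discovery of the k-mers (default 10mers beginning with `TGTA`)
#' that best discriminate an in-group of UTRs from an out-group. At each
#' round every candidate k-mer is scored by the mutual information between
#' group membership and match status over the currently unmasked UTRs; the
#' highest-MI k-mer is kept (ties broken toward the lexicographically
#' smallest) and all UTRs it matches, in either group, are masked for
#' subsequent rounds. The search stops after `rounds` k-mers or when no
#' candidate has positive MI.
#'
#' @param in_utrs,out_utrs Named character vectors of UTR sequences.
#' @param anchor Fixed k-mer prefix (default `"TGTA"`).
#' @param k Total k-mer length (default 10).
#' @param rounds Maximum number of k-mers to select (default 250).
#' @return A `ranked_kmers` tibble: `kmer`, `round`, `mi`, `tpr`, `fpr`,
#'   `n_masked` (UTRs newly masked), with cumulative TPR/FPR over the
#'   original group sizes.
#' @export
iterative_search <- function(in_utrs, out_utrs, anchor = "TGTA", k = 10L,
                             rounds = 250L) {
  stopifnot(length(in_utrs) > 0, length(out_utrs) > 0)
  anchor <- gsub("U", "T", toupper(anchor), fixed = TRUE)
  if (nchar(anchor) > k) stop("anchor longer than k-mer length", call. = FALSE)
  free <- k - nchar(anchor)
  bases <- c("A", "C", "G", "T")
  tails <- do.call(paste0, rev(expand.grid(rep(list(bases), free),
                                           stringsAsFactors = FALSE)))
  candidates <- sort(paste0(anchor, tails))   # lexicographic tie-break order
  ncand <- length(candidates)

  # per-UTR candidate membership, computed once
  member <- function(seqs) lapply(seqs, function(s) {
    idx <- match(anchored_kmers(s, anchor, k), candidates)
    idx[!is.na(idx)]
  })
  mem_in <- member(in_utrs)
  mem_out <- member(out_utrs)
  n_in0 <- length(in_utrs); n_out0 <- length(out_utrs)

  active_in <- rep(TRUE, n_in0)
  active_out <- rep(TRUE, n_out0)
  masked_in <- 0L; masked_out <- 0L
  res <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    n_in <- sum(active_in); n_out <- sum(active_out)
    if (n_in + n_out == 0L) break
    cnt_in <- tabulate(as.integer(unlist(mem_in[active_in])), nbins = ncand)
    cnt_out <- tabulate(as.integer(unlist(mem_out[active_out])), nbins = ncand)
    mi <- mutual_information(cnt_in, n_in - cnt_in, cnt_out, n_out - cnt_out)
    best <- which.max(mi)
    if (mi[best] <= 1e-15) break
    hit_in <- active_in & vapply(mem_in, function(ix) best %in% ix, logical(1))
    hit_out <- active_out & vapply(mem_out, function(ix) best %in% ix, logical(1))
    masked_in <- masked_in + sum(hit_in)
    masked_out <- masked_out + sum(hit_out)
    active_in[hit_in] <- FALSE
    active_out[hit_out] <- FALSE
    res[[r]] <- tibble::tibble(kmer = candidates[best], round = r,
                               mi = mi[best],
                               tpr = masked_in / n_in0,
                               fpr = masked_out / n_out0,
                               n_masked = sum(hit_in) + sum(hit_out))
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("ranked_kmers", class(out))
  out
}

#' ROC local-slope cutoff for ranked k-mers
#'
#' Walks the cumulative (TPR, FPR) curve in selection order and computes
#' the local slope dFPR/dTPR by least squares over a centred window
#' (default 11 points). Under the default rule the kept set ends just
#' before the first point whose local slope exceeds 1 (false positives
#' accumulating faster than true positives); if the slope never exceeds 1,
#' all k-mers are kept. A window with no TPR variation has slope +Inf
#' (triggering the cutoff) unless FPR is also flat (slope 0). The
#' alternative rule `"fpr_gt_tpr"` cuts at the first point where cumulative
#' FPR exceeds cumulative TPR. `override` forces an exact keep-count
#' (mirroring a deliberately stricter cutoff).
#'
#' @param ranked A `ranked_kmers` tibble from [iterative_search()].
#' @param window Centred window size (shrunk, with a message, if larger
#'   than the list).
#' @param rule `"slope_gt_1"` (default) or `"fpr_gt_tpr"`.
#' @param override Optional integer: keep exactly this many.
#' @return Integer keep-count.
#' @export
roc_cutoff <- function(ranked, window = 11L, rule = c("slope_gt_1", "fpr_gt_tpr"),
                       override = NULL) {
  rule <- match.arg(rule)
  n <- nrow(ranked)
  stopifnot(n >= 1L)
  if (!is.null(override)) return(min(as.integer(override), n))
  if (window > n) {
    message("window larger than ranked list; shrunk to ", n)
    window <- n
  }
  if (rule == "fpr_gt_tpr") {
    idx <- which(ranked$fpr > ranked$tpr)
    return(if (length(idx) == 0L) n else idx[1] - 1L)
  }
  half <- (window - 1L) %/% 2L
  slopes <- vapply(seq_len(n), function(i) {
    w <- max(1L, i - half):min(n, i + half)
    local_slope(ranked$tpr[w], ranked$fpr[w])
  }, numeric(1))
  idx <- which(slopes > 1)
  if (length(idx) == 0L) n else idx[1] - 1L
}

# least-squares slope of fpr ~ tpr; flat-TPR windows are +Inf unless FPR is
# also flat (then 0)
local_slope <- function(tpr, fpr) {
  vx <- stats::var(tpr)
  if (is.na(vx) || vx == 0) {
    if (length(unique(fpr)) == 1L) return(0)
    return(Inf)
  }
  stats::cov(tpr, fpr) / vx
}

#' Hamming-distance-1 network of k-mers
#'
#' @param kmers Character vector of equal-length k-mers.
#' @return A `kmer_network`: list with `nodes` and an `edges` tibble
#'   (`from`, `to`) joining k-mers exactly one substitution apart.
#' @export
build_network <- function(kmers) {
  kmers <- unique(kmers)
  L <- unique(nchar(kmers))
  if (length(L) > 1L) stop("k-mers must share one length", call. = FALSE)
  n <- length(kmers)
  edges <- tibble::tibble(from = character(), to = character())
  if (n >= 2L) {
    chars <- matrix(unlist(strsplit(kmers, "")), nrow = n, byrow = TRUE)
    dist <- matrix(0L, n, n)
    for (j in seq_len(L)) {
      dist <- dist + outer(chars[, j], chars[, j], "!=")
    }
    idx <- which(dist == 1L & upper.tri(dist), arr.ind = TRUE)
    edges <- tibble::tibble(from = kmers[idx[, 1]], to = kmers[idx[, 2]])
  }
  structure(list(nodes = kmers, edges = edges), class = "kmer_network")
}

#' @export
print.kmer_network <- function(x, ...) {
  cat("<k-mer network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " distance-1 edges\n", sep = "")
  invisible(x)
}

#' Group k-mers by network connectivity
#'
#' Default grouping is the connected components of the Hamming-distance-1
#' network (an automated stand-in for manual grouping of a network layout).
#' With `merge_similar = TRUE`, components whose derived regular expressions
#' agree at all but at most one of the free (post-anchor) positions are
#' merged.
#'
#' @param network A `kmer_network` from [build_network()].
#' @param merge_similar Merge components with near-identical derived
#'   regexes (default `FALSE`).
#' @param anchor_length Number of leading anchor positions excluded from
#'   the similarity comparison (default 4).
#' @return Tibble `kmer`, `group` (integer component labels).
#' @export
group_kmers <- function(network, merge_similar = FALSE, anchor_length = 4L) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  comp <- igraph::components(g)$membership
  groups <- tibble::tibble(kmer = names(comp), group = as.integer(comp))
  if (merge_similar && max(groups$group) > 1L) {
    L <- nchar(network$nodes[1])
    free <- (anchor_length + 1L):L
    regex_sets <- lapply(split(groups$kmer, groups$group), function(km) {
      m <- derive_regex(km)
      m$positions[free]
    })
    ids <- as.integer(names(regex_sets))
    parent <- stats::setNames(ids, ids)
    find <- function(x) { while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]; x }
    for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
      agree <- sum(mapply(identical, regex_sets[[i]], regex_sets[[j]]))
      if (agree >= length(free) - 1L) {
        parent[[as.character(find(ids[i]))]] <- find(ids[j])
      }
    }
    groups$group <- vapply(groups$group, find, numeric(1))
    groups$group <- as.integer(factor(groups$group))
  }
  groups
}
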