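#' Filter all-by-all hits into paralogous pairs
#'
#' Applies the duplicate-pair criteria to a nucleotide all-by-all hit table:
#' E-value at most `evalue_max`, percent identity at least `pident_min`,
#' alignment length at least `alnlen_min` (all thresholds inclusive).
#' Self-hits are dropped and the two directions of each pair are merged,
#' keeping the row with the smallest supporting E-value (ties: larger bit
#' score).
#'
#' @param hits Hit data.frame from [readHits()].
#' @param evalue_max,pident_min,alnlen_min Inclusive thresholds.
#' @return Data.frame with columns id_a, id_b (id_a < id_b), evalue,
#'   pident, aln_len; one row per unordered pair.
#' @export
filterParalogPairs <- function(hits, evalue_max = 1e-5, pident_min = 40,
                               alnlen_min = 150) {
  keep <- hits$qid != hits$sid &
    hits$evalue <= evalue_max &
    hits$pident >= pident_min &
    hits$aln_len >= alnlen_min
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      evalue = numeric(0), pident = numeric(0),
                      aln_len = integer(0), stringsAsFactors = FALSE))
  }
  id_a <- pmin(h$qid, h$sid)
  id_b <- pmax(h$qid, h$sid)
  df <- data.frame(id_a = id_a, id_b = id_b, evalue = h$evalue,
                   pident = h$pident, aln_len = h$aln_len,
                   stringsAsFactors = FALSE)
  df <- df[order(df$id_a, df$id_b, df$evalue, -df$pident), , drop = FALSE]
  df <- df[!duplicated(paste(df$id_a, df$id_b, sep = "\r")), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Single-linkage gene families from paralogous pairs
#'
#' Gene families are the connected components of the paralog-pair graph
#' (single-linkage clustering on a similarity graph). Family ids are
#' assigned in order of each family's lexicographically smallest member.
#'
#' @param pairs Data.frame from [filterParalogPairs()].
#' @return Data.frame with columns family_id (integer) and id (member);
#'   the `families` attribute holds a list of member-id vectors.
#' @export
singleLinkageFamilies <- function(pairs) {
  if (nrow(pairs) == 0L) {
    out <- data.frame(family_id = integer(0), id = character(0))
    attr(out, "families") <- list()
    return(out)
  }
  g <- igraph::graph_from_data_frame(pairs[, c("id_a", "id_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, function(m) sort(m))
  ord <- order(vapply(members, `[`, character(1), 1))
  members <- members[ord]
  names(members) <- NULL
  out <- data.frame(
    family_id = rep(seq_along(members), lengths(members)),
    id = unlist(members), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "families") <- members
  out
}

#' Pairwise Ks estimates within each family
#'
#' Runs the chosen estimator on every member pair of every family. Pairs
#' whose alignment or estimation fails (or whose Ks is saturated) keep
#' their row with ks = Inf, so family membership - a similarity-graph
#' property - is preserved while the pair cannot seed a finite node height.
#'
#' @param families Output of [singleLinkageFamilies()].
#' @param cds Named [Biostrings::DNAStringSet] of in-frame coding sequences
#'   covering the family members (members without a CDS are skipped with a
#'   log entry).
#' @param method `"YN00"` or `"NG86"`.
#' @return Data.frame: family_id, id_a, id_b, method, S, N, Sd, Nd, kappa,
#'   ka, ks, flags; ks is Inf where estimation failed.
#' @export
familyPairKs <- function(families, cds, method = c("YN00", "NG86")) {
  method <- match.arg(method)
  fams <- attr(families, "families")
  rows <- list()
  for (f in seq_along(fams)) {
    mem <- intersect(fams[[f]], names(cds))
    if (length(mem) < 2L) next
    cmb <- utils::combn(mem, 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      row <- tryCatch(
        pairKs(cds[[a]], cds[[b]], method = method, id_a = a, id_b = b),
        error = function(e) {
          r <- .ks_row(a, b, method, NA, NA, NA, NA, NA, NA, NA,
                       "estimation_failed")
          r
        })
      if (is.na(row$ks)) row$ks <- Inf
      if (is.na(row$ka)) row$ka <- Inf
      row <- cbind(family_id = f, row)
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) {
    return(data.frame(family_id = integer(0), id_a = character(0),
                      id_b = character(0), method = character(0),
                      S = numeric(0), N = numeric(0), Sd = numeric(0),
                      Nd = numeric(0), kappa = numeric(0), ka = numeric(0),
                      ks = numeric(0), flags = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Node-wise Ks values for one family
#'
#' Agglomerative single-linkage clustering on the family's pairwise Ks
#' matrix: at each of the m-1 merges the node contributes one Ks value,
#' summarised from all cross-cluster pairwise Ks at that merge (default:
#' median; `"min"` is the linkage height itself, `"mean"` also available).
#' This de-weights multicopy families: a family of m genes contributes m-1
#' node values instead of m(m-1)/2 pairwise values. Node values equal to
#' zero are removed; values outside `ks_range` are kept but flagged
#' `in_range = FALSE` so the age distribution can exclude them.
#'
#' @param pair_ks Data.frame with id_a, id_b, ks for the members of one
#'   family (e.g. one family's rows of [familyPairKs()]); missing pairs are
#'   treated as infinitely distant.
#' @param summary `"median"`, `"min"` or `"mean"`.
#' @param ks_range Half-open interval (lower exclusive via the zero-removal
#'   rule, upper exclusive) delimiting the age-distribution universe.
#' @param ka Optional matching ka values (same rows as `pair_ks`) summarised
#'   alongside.
#' @return Data.frame: node_index, ks, ka, n_left, n_right, left_members,
#'   right_members (comma-joined), in_range. Zero rows when the family has
#'   fewer than 2 members with Ks estimates.
#' @export
nodeKs <- function(pair_ks, summary = c("median", "min", "mean"),
                   ks_range = c(0, 2)) {
  summary <- match.arg(summary)
  ids <- sort(unique(c(pair_ks$id_a, pair_ks$id_b)))
  m <- length(ids)
  empty <- data.frame(node_index = integer(0), ks = numeric(0),
                      ka = numeric(0), n_left = integer(0),
                      n_right = integer(0), left_members = character(0),
                      right_members = character(0), in_range = logical(0))
  if (m < 2L) return(empty)
  D <- matrix(Inf, m, m, dimnames = list(ids, ids))
  KA <- matrix(Inf, m, m, dimnames = list(ids, ids))
  for (r in seq_len(nrow(pair_ks))) {
    a <- pair_ks$id_a[r]; b <- pair_ks$id_b[r]
    v <- pair_ks$ks[r]
    if (is.na(v)) v <- Inf
    D[a, b] <- D[b, a] <- v
    va <- if ("ka" %in% names(pair_ks)) pair_ks$ka[r] else NA_real_
    KA[a, b] <- KA[b, a] <- if (is.na(va)) Inf else va
  }
  diag(D) <- 0; diag(KA) <- 0

  clusters <- as.list(seq_len(m))
  sfun <- switch(summary, median = stats::median, mean = mean,
                 min = function(x) min(x))
  out <- empty
  for (step in seq_len(m - 1L)) {
    ## single linkage: find the pair of clusters at minimum Ks
    best <- c(NA_integer_, NA_integer_); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        h <- min(D[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(j, i) }
      }
    }
    if (!is.finite(best_h)) {
      ## remaining clusters unlinkable (all failed pairs): merge the two
      ## smallest-indexed clusters with an Inf node so counts stay honest
      best <- c(1L, 2L); best_h <- Inf
    }
    ci <- clusters[[best[1]]]; cj <- clusters[[best[2]]]
    cross_ks <- as.vector(D[ci, cj, drop = FALSE])
    cross_ka <- as.vector(KA[ci, cj, drop = FALSE])
    ks_val <- if (summary == "min") best_h else sfun(cross_ks)
    ka_val <- sfun(cross_ka[is.finite(cross_ka)] %||% Inf)
    out <- rbind(out, data.frame(
      node_index = step, ks = ks_val,
      ka = if (length(cross_ka[is.finite(cross_ka)])) ka_val else Inf,
      n_left = length(ci), n_right = length(cj),
      left_members = paste(ids[ci], collapse = ","),
      right_members = paste(ids[cj], collapse = ","),
      in_range = is.finite(ks_val) && ks_val > ks_range[1] &&
        ks_val < ks_range[2]))
    clusters[[best[1]]] <- c(ci, cj)
    clusters[[best[2]]] <- NULL
  }
  out <- out[!(out$ks == 0), , drop = FALSE]  # zero-Ks nodes removed
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (length(a)) a else b

#' Node-Ks values across all families
#'
#' @param pair_ks_all Output of [familyPairKs()].
#' @param ... Passed to [nodeKs()].
#' @return Data.frame with a leading family_id column, one block per family.
#' @export
allNodeKs <- function(pair_ks_all, ...) {
  out <- lapply(split(pair_ks_all, pair_ks_all$family_id), function(df) {
    nd <- nodeKs(df, ...)
    if (nrow(nd)) cbind(family_id = df$family_id[1], nd) else NULL
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out)) {
    out <- data.frame(family_id = integer(0), node_index = integer(0),
                      ks = numeric(0), ka = numeric(0), n_left = integer(0),
                      n_right = integer(0), left_members = character(0),
                      right_members = character(0), in_range = logical(0))
  }
  rownames(out) <- NULL
  out
}
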