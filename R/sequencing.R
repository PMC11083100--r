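#' Likelihood of a full event sequence
#'
#' Approximates the chain likelihood of an ordering by the product, over
#' all ordered pairs `(a before b)` implied by the sequence, of the
#' pairwise precedence probability `p[a, b]`.  For `k` events the product
#' runs over `choose(k, 2)` pairs.
#'
#' @param pm A `cepa_precedence` matrix.
#' @param order Character vector: a permutation of the matrix labels.
#' @return Likelihood in `[0, 1]`; 0 if any required probability is zero.
#' @examples
#' p <- as_precedence(matrix(c(NA, .2, .8, NA), 2, 2,
#'                           dimnames = list(c("a", "b"), c("a", "b"))))
#' sequence_likelihood(p, c("a", "b"))
#' @export
sequence_likelihood <- function(pm, order) {
  labels <- rownames(pm)
  if (!setequal(order, labels) || length(order) != length(labels))
    stop("order must be a permutation of the matrix labels")
  idx <- match(order, labels)
  k <- length(idx)
  L <- 1
  for (a in seq_len(k - 1))
    for (b in (a + 1):k)
      L <- L * pm[idx[a], idx[b]]
  unname(L)
}

#' Score of a sequence likelihood
#'
#' `score = -log10(L)`: lower scores mark more probable sequences.  Base
#' 10 makes a two-percent score difference at score 6.90 correspond to a
#' likelihood ratio of `10^(0.02 * 6.90) = 1.37`.
#'
#' @param L Likelihood in `(0, 1]` (vectorised).
#' @return Nonnegative score; `Inf` for `L <= 0`.
#' @export
sequence_score <- function(L) {
  ifelse(L > 0, -log10(L), Inf)
}

#' Likelihood ratio implied by two scores
#'
#' For scores `s_a <= s_b` (negative log10 likelihoods), the factor by
#' which the first sequence is more probable: `10^(s_b - s_a)`.
#'
#' @param score_a,score_b Sequence scores.
#' @return `10^(score_b - score_a)`.
#' @examples
#' score_likelihood_ratio(6.90, 6.90 * 1.02)  # about 1.37
#' @export
score_likelihood_ratio <- function(score_a, score_b) {
  10^(score_b - score_a)
}

#' Rank all event sequences by score
#'
#' Enumerates every permutation of the event labels, scores each with
#' [sequence_likelihood()] and [sequence_score()], and sorts ascending by
#' score.  `rate` is the percent excess of a score over the best score.
#' Ties are broken lexicographically by the sequence string so that the
#' ranking is deterministic.
#'
#' @param pm A `cepa_precedence` matrix with at most 10 events (full
#'   enumeration of `k!` permutations).
#' @return A data frame of class `cepa_ranking`: columns `order` (labels
#'   joined by `" -> "`), `log10_likelihood`, `score`, `rate`.
#' @export
rank_sequences <- function(pm) {
  labels <- rownames(pm)
  k <- length(labels)
  if (k > 10)
    stop("full enumeration is limited to 10 events; ",
         "use a heuristic search for larger problems")
  perms <- permutations(k)
  # score = sum over ordered pairs of -log10 p[a, b]; accumulate over the
  # C(k,2) pair positions for all permutations at once
  lp <- -log10(unclass(pm))
  score <- numeric(nrow(perms))
  for (a in seq_len(k - 1))
    for (b in (a + 1):k)
      score <- score + lp[cbind(perms[, a], perms[, b])]
  order_str <- apply(perms, 1, function(ix) paste(labels[ix],
                                                  collapse = " -> "))
  ord <- order(score, order_str)
  score <- score[ord]
  best <- score[1]
  out <- data.frame(
    order = order_str[ord],
    log10_likelihood = -score,
    score = score,
    rate = if (best > 0) 100 * (score - best) / best else
      ifelse(score == best, 0, Inf),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cepa_ranking", "data.frame")
  out
}

# all permutations of 1..k as a k!-row matrix (recursive construction)
permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1)
  out <- matrix(0L, k * nrow(sub), k)
  row <- 1
  for (first in seq_len(k)) {
    rest <- c(seq_len(k))[-first]
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1
    }
  }
  out
}

#' Select valid sequences by the percent-excess rule
#'
#' A sequence is valid when its score exceeds the best score by less than
#' `threshold_pct` percent.  The strict inequality places a sequence whose
#' rate rounds to the threshold itself (e.g. 2.03 at a 2 percent rule)
#' outside the valid set; the best sequence (rate 0) is always valid.
#'
#' @param ranked A [rank_sequences()] result (sorted ascending by score).
#' @param threshold_pct Percent threshold; default 2.
#' @return The subset of `ranked` with `rate < threshold_pct`, plus the
#'   best row regardless.
#' @export
valid_sequences <- function(ranked, threshold_pct = 2) {
  stopifnot(nrow(ranked) >= 1, threshold_pct >= 0)
  keep <- ranked$rate < threshold_pct
  keep[1] <- TRUE
  out <- ranked[keep, , drop = FALSE]
  class(out) <- class(ranked)
  out
}

#' Precedence network from valid sequences
#'
#' Nodes are the event labels.  For every adjacent pair in any valid
#' sequence an edge is added in the majority precedence direction, unless
#' the pairwise probability is within `bidir_band` of 1/2, in which case
#' the pair has no practical priority and the edge is bidirectional.
#' Each unordered pair contributes at most one edge.
#'
#' @param valid A [valid_sequences()] result.
#' @param pm The `cepa_precedence` matrix the sequences were scored on.
#' @param bidir_band Half-width of the no-priority band around 0.5;
#'   default 0.05 (a 52 percent precedence chance is bidirectional).
#' @return A `cepa_network`: list with `nodes` and an `edges` data frame
#'   (`from`, `to`, `p`, `bidirectional`).
#' @export
build_network <- function(valid, pm, bidir_band = 0.05) {
  stopifnot(nrow(valid) >= 1)
  labels <- rownames(pm)
  seen <- character(0)
  from <- character(0); to <- character(0)
  prob <- numeric(0); bidir <- logical(0)
  for (s in valid$order) {
    seq_labels <- strsplit(s, " -> ", fixed = TRUE)[[1]]
    for (a in seq_len(length(seq_labels) - 1)) {
      u <- seq_labels[a]; v <- seq_labels[a + 1]
      key <- paste(sort(c(u, v)), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      p_uv <- pm[u, v]
      if (abs(p_uv - 0.5) <= bidir_band) {
        from <- c(from, u); to <- c(to, v)
        prob <- c(prob, p_uv); bidir <- c(bidir, TRUE)
      } else if (p_uv > 0.5) {
        from <- c(from, u); to <- c(to, v)
        prob <- c(prob, p_uv); bidir <- c(bidir, FALSE)
      } else {
        from <- c(from, v); to <- c(to, u)
        prob <- c(prob, 1 - p_uv); bidir <- c(bidir, FALSE)
      }
    }
  }
  structure(list(nodes = labels,
                 edges = data.frame(from = from, to = to, p = prob,
                                    bidirectional = bidir,
                                    stringsAsFactors = FALSE)),
            class = "cepa_network")
}

#' @export
print.cepa_network <- function(x, ...) {
  cat(sprintf("<precedence network: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    arrows <- ifelse(x$edges$bidirectional, "<->", "->")
    cat(sprintf("  %s %s %s (p = %.2f)\n", x$edges$from, arrows, x$edges$to,
                x$edges$p), sep = "")
  }
  invisible(x)
}

#' Convert a precedence network to an igraph object
#' @param net A `cepa_network`.
#' @return An igraph directed graph; bidirectional pairs carry edges in
#'   both directions, each flagged with a `bidirectional` attribute.
#' @export
network_igraph <- function(net) {
  e <- net$edges
  if (nrow(e)) {
    bi <- e[e$bidirectional, , drop = FALSE]
    if (nrow(bi)) {
      rev <- data.frame(from = bi$to, to = bi$from, p = 1 - bi$p,
                        bidirectional = TRUE)
      e <- rbind(e, rev)
    }
  }
  # 0/1 rather than logical: the DOT writer has no boolean attribute type
  e$bidirectional <- as.integer(e$bidirectional)
  igraph::graph_from_data_frame(e, directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

#' Export a precedence network to GraphML or DOT
#' @param net A `cepa_network`.
#' @param path Output file.
#' @param format `"graphml"` or `"dot"`.
#' @export
write_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- network_igraph(net)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
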