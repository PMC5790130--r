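# Summary-tree construction: majority-rule consensus of parsimony tree sets
# and half-compatibility summaries of Bayesian posterior samples.  Both keep
# exactly the clades present in (more than) half the sample; clades occurring
# in a strict majority are automatically pairwise compatible, which is why
# strict majority is the default rule.

.clade_key <- function(labels) paste(sort(labels), collapse = "\x1f")

#' Weighted clade frequencies in a tree sample
#'
#' @param sample a [tree_sample].
#' @return a numeric vector of frequencies in (0, 1], one entry per distinct
#'   nontrivial clade observed anywhere in the sample, with the clades
#'   themselves (sorted character vectors) in attribute `"clades"`.
#' @export
clade_frequencies <- function(sample) {
  stopifnot(inherits(sample, "tree_sample"))
  w <- sample$weights
  total <- sum(w)
  acc <- new.env(parent = emptyenv())
  clades <- list()
  for (i in seq_along(sample$trees)) {
    for (cl in nontrivial_clades(sample$trees[[i]])) {
      key <- .clade_key(cl)
      if (is.null(acc[[key]])) {
        acc[[key]] <- w[i]
        clades[[key]] <- cl
      } else acc[[key]] <- acc[[key]] + w[i]
    }
  }
  keys <- names(clades)
  freq <- vapply(keys, function(k) acc[[k]] / total, numeric(1))
  names(freq) <- keys
  attr(freq, "clades") <- clades
  freq
}

# TRUE iff `cl` is disjoint from or nested with every clade in `others`
.compatible_with <- function(cl, others) {
  for (o in others) {
    inter <- length(intersect(cl, o))
    if (inter > 0L && inter < length(cl) && inter < length(o)) return(FALSE)
  }
  TRUE
}

#' Majority-rule consensus / half-compatibility summary
#'
#' Builds the summary topology containing the clades supported by (more
#' than) half of a tree sample.  Two rules are offered:
#' \describe{
#'   \item{`"strict"`}{keep clades with frequency strictly greater than
#'     `threshold` (default 0.5).  A strict majority guarantees the kept
#'     clades are pairwise compatible.}
#'   \item{`"halfcompat"`}{keep clades with frequency `>= 0.5`, considered in
#'     order of decreasing frequency (ties broken by first occurrence),
#'     adding each only if compatible with those already kept — the
#'     MrBayes "halfcompat" convention.}
#' }
#'
#' @param sample a [tree_sample].
#' @param threshold minimum frequency, `>= 0.5`; default 0.5.
#' @param rule `"strict"` (default) or `"halfcompat"`.
#' @return a canonical `phylo`; internal node labels carry the clade
#'   frequencies (as formatted numbers; root label empty).
#' @export
majority_rule <- function(sample, threshold = 0.5,
                          rule = c("strict", "halfcompat")) {
  rule <- match.arg(rule)
  stopifnot(inherits(sample, "tree_sample"))
  if (threshold < 0.5) stop_domain("`threshold` must be >= 0.5")
  freq <- clade_frequencies(sample)
  clades <- attr(freq, "clades")
  taxa <- sort(sample$trees[[1]]$tip.label)
  if (rule == "strict") {
    keep <- which(freq > threshold)
    kept <- clades[keep]
    kfreq <- as.numeric(freq[keep])
  } else {
    ord <- order(-freq, seq_along(freq))
    kept <- list(); kfreq <- numeric(0)
    for (i in ord) {
      if (freq[i] < threshold) next
      if (.compatible_with(clades[[i]], kept)) {
        kept <- c(kept, clades[i])
        kfreq <- c(kfreq, freq[i])
      }
    }
  }
  .build_from_clades(taxa, kept, kfreq)
}

# assemble a rooted tree from a pairwise-compatible clade set, annotating
# internal nodes with the supplied values
.build_from_clades <- function(taxa, clades, freqs) {
  k <- length(clades)
  if (k) {
    ord <- order(vapply(clades, length, 1L), decreasing = TRUE)
    clades <- clades[ord]
    freqs <- freqs[ord]
  }
  sizes <- vapply(clades, length, 1L)
  # parent of clade i = smallest strictly containing clade before it (0 = root)
  parent <- integer(k)
  for (i in seq_len(k)) {
    parent[i] <- 0L
    best <- Inf
    for (j in seq_len(k)) {
      if (j == i) next
      if (sizes[j] > sizes[i] && sizes[j] < best &&
          all(clades[[i]] %in% clades[[j]])) {
        parent[i] <- j; best <- sizes[j]
      }
    }
  }
  # tip home = smallest clade containing it (0 = root)
  tip_home <- vapply(taxa, function(tp) {
    holds <- which(vapply(clades, function(cl) tp %in% cl, logical(1)))
    if (!length(holds)) 0L else holds[which.min(sizes[holds])]
  }, integer(1))
  emit <- function(node) {
    child_cl <- which(parent == node)
    tips <- taxa[tip_home == node]
    parts <- c(vapply(child_cl, emit, character(1)), .quote_label(tips))
    keys <- c(vapply(child_cl, function(j) clades[[j]][1L], character(1)), tips)
    parts <- parts[order(keys, method = "radix")]
    lab <- if (node == 0L) "" else format(freqs[node], digits = 4)
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  ape::read.tree(text = paste0(emit(0L), ";"))
}
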