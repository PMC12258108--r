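# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf formatting and no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

msgf <- function(fmt, ...) message(sprintf(fmt, ...))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# full-precision numeric formatting used by every writer so that a
# write -> read round trip reproduces doubles bit-exactly
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# connected components of an undirected edge set over `nodes`;
# returns an integer membership vector named by node
components_of <- function(nodes, from, to) {
  idx <- seq_along(nodes)
  names(idx) <- nodes
  parent <- idx
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    ri <- find(idx[[from[k]]]); rj <- find(idx[[to[k]]])
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(idx, find, integer(1))
  memb <- match(roots, unique(roots))
  names(memb) <- nodes
  memb
}

# Benjamini-Hochberg, kept explicit for the survive CLI output
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
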