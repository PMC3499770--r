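#' Hypergeometric gene-set over-representation analysis
#'
#' Tests each gene set for over-representation among the selected genes
#' relative to a background universe, using the upper tail of the
#' hypergeometric distribution: with population size N = |background|,
#' m set members in the background, and n selected genes, the p-value is
#' P(X >= overlap).  P-values are corrected across all tested sets by the
#' Benjamini-Hochberg step-up procedure; a set is called enriched when its
#' q-value is at most \code{fdrCutoff}.  Sets are intersected with the
#' background first, and sets smaller than \code{minSetSize} after
#' intersection are skipped (reported via \code{message}).  Output rows
#' are ordered deterministically by q-value, then p-value, then set id.
#'
#' @param selected character vector of selected gene ids (must be a subset
#'   of \code{background}).
#' @param background character vector: the gene universe (typically all
#'   genes that entered the multi-table analysis after filtering).
#' @param sets a \code{\link{GeneSetCollection}}.
#' @param fdrCutoff FDR threshold for the \code{enriched} call
#'   (default 0.01).
#' @param minSetSize minimum in-background set size tested (default 3).
#' @return data.frame with columns \code{set_id}, \code{description},
#'   \code{set_size_in_background}, \code{n_selected}, \code{n_overlap},
#'   \code{p_value}, \code{q_value}, \code{enriched}.
#' @export
hypergeometricEnrichment <- function(selected, background, sets,
                                     fdrCutoff = 0.01, minSetSize = 3L) {
  stopifnot(is(sets, "GeneSetCollection"))
  background <- unique(as.character(background))
  selected <- unique(as.character(selected))
  stopIfNot(length(background) > 0L, "background must be non-empty")
  if (!all(selected %in% background))
    stop("'selected' must be a subset of 'background'")
  N <- length(background)
  n_sel <- length(selected)

  mem <- lapply(sets@members, intersect, y = background)
  keep <- lengths(mem) >= minSetSize
  if (any(!keep))
    message(sprintf("hypergeometricEnrichment: skipped %d set(s) below minSetSize=%d after background intersection",
                    sum(!keep), minSetSize))
  ids <- sets@setIds[keep]
  if (length(ids) == 0L) {
    return(data.frame(set_id = character(), description = character(),
                      set_size_in_background = integer(),
                      n_selected = integer(), n_overlap = integer(),
                      p_value = double(), q_value = double(),
                      enriched = logical(), stringsAsFactors = FALSE))
  }
  m <- lengths(mem[ids])
  k <- vapply(mem[ids], function(g) length(intersect(g, selected)), 0L)
  p <- phyper(k - 1L, m, N - m, n_sel, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  out <- data.frame(set_id = ids,
                    description = unname(sets@descriptions[ids]),
                    set_size_in_background = unname(m),
                    n_selected = n_sel, n_overlap = unname(k),
                    p_value = unname(p), q_value = unname(q),
                    enriched = unname(q <= fdrCutoff),
                    stringsAsFactors = FALSE)
  out[order(out$q_value, out$p_value, out$set_id, method = "radix"), ,
      drop = FALSE]
}
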